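# Detection-history construction: daily matrix, occasion collapsing, effort.

#' Build the sites x days detection matrix
#'
#' Converts daily species records into a binary site-by-day matrix aligned to
#' each site's deployment window. Days are deployment-relative (day 1 is each
#' site's own start date), so occasion bins later anchor at deployment start,
#' not calendar weeks. Days outside a site's active window are `NA`.
#'
#' @param records Data frame with `site_id`, `date` (Date), `species`.
#' @param deployments Data frame with `site_id`, `start_date`, `end_date`.
#' @param species Species label to tabulate.
#' @return Binary matrix (sites x days) with `NA` for inactive days; row
#'   names are site ids in deployment order, columns `day_1..day_D`.
#' @export
build_daily_matrix <- function(records, deployments, species) {
  if (any(deployments$end_date < deployments$start_date))
    stop2("inverted deployment window for site(s): ",
          paste(deployments$site_id[deployments$end_date <
                                    deployments$start_date], collapse = ", "))
  unknown <- setdiff(unique(records$site_id), deployments$site_id)
  if (length(unknown))
    stop2("records reference unknown site(s): ",
          paste(unknown, collapse = ", "))
  ndays <- as.integer(deployments$end_date - deployments$start_date) + 1L
  D <- max(ndays)
  m <- matrix(NA_integer_, nrow(deployments), D,
              dimnames = list(deployments$site_id,
                              paste0("day_", seq_len(D))))
  for (i in seq_len(nrow(deployments))) m[i, seq_len(ndays[i])] <- 0L

  rec <- records[records$species == species, , drop = FALSE]
  if (nrow(rec)) {
    idx <- match(rec$site_id, deployments$site_id)
    day <- as.integer(rec$date - deployments$start_date[idx]) + 1L
    bad <- day < 1L | day > ndays[idx]
    if (any(bad))
      stop2("record(s) outside deployment window at rows: ",
            paste(rownames(rec)[bad] %||% which(bad), collapse = ", "))
    m[cbind(idx, day)] <- 1L
  }
  class(m) <- c("detection_matrix", class(m))
  m
}

#' Collapse daily detections into sampling occasions
#'
#' Groups consecutive day columns into bins of `bin_days` (the emulated
#' design: 21 days, 7-day bins, 3 occasions). An occasion is 1 if any day in
#' the bin has a detection, 0 if the bin has at least one active
#' non-detection day, and `NA` only when every day in the bin was inactive:
#' an active camera that saw nothing is a real non-detection trial.
#'
#' @param daily Sites x days binary matrix from [build_daily_matrix()].
#' @param bin_days Occasion length in days (>= 1).
#' @return Sites x occasions matrix (`occ_1..occ_K`,
#'   `K = ceiling(days / bin_days)`).
#' @export
collapse_occasions <- function(daily, bin_days) {
  if (!is.numeric(bin_days) || bin_days < 1) stop2("bin_days must be >= 1")
  bin_days <- as.integer(bin_days)
  D <- ncol(daily)
  K <- ceiling(D / bin_days)
  grp <- rep(seq_len(K), each = bin_days, length.out = D)
  occ <- vapply(seq_len(K), function(k) {
    sub <- daily[, grp == k, drop = FALSE]
    any1 <- rowSums(sub == 1L, na.rm = TRUE) > 0
    allna <- rowSums(!is.na(sub)) == 0
    ifelse(allna, NA_integer_, as.integer(any1))
  }, integer(nrow(daily)))
  occ <- matrix(occ, nrow = nrow(daily),
                dimnames = list(rownames(daily), paste0("occ_", seq_len(K))))
  class(occ) <- c("detection_matrix", class(occ))
  occ
}

#' Survey effort in trap nights
#'
#' One trap night is one camera active for one 24-hour period; effort is the
#' total number of active camera-days across sites.
#'
#' @param deployments Data frame with `site_id`, `start_date`, `end_date`.
#' @return Integer trap-night total.
#' @export
#' @examples
#' d <- data.frame(site_id = "A", start_date = as.Date("2022-12-01"),
#'                 end_date = as.Date("2022-12-21"))
#' effort(d)  # 21
effort <- function(deployments) {
  days <- as.integer(deployments$end_date - deployments$start_date) + 1L
  if (any(days < 1L))
    stop2("inverted deployment window for site(s): ",
          paste(deployments$site_id[days < 1L], collapse = ", "))
  sum(days)
}

#' Naive occupancy
#'
#' Fraction of sites with at least one detection, uncorrected for imperfect
#' detection.
#'
#' @param matrix Detection matrix (daily or occasion level).
#' @return List with `n_detected` and `fraction`.
#' @export
naive_occupancy <- function(matrix) {
  if (!nrow(matrix)) stop2("empty detection matrix")
  det <- rowSums(matrix == 1L, na.rm = TRUE) > 0
  list(n_detected = sum(det), fraction = sum(det) / nrow(matrix))
}

#' Write / read a detection matrix CSV
#'
#' Rows are sites, columns the occasion (or day) labels; missing cells are
#' literal `NA`.
#'
#' @param matrix Detection matrix.
#' @param path File path.
#' @return `write_detection_csv` invisibly returns `path`;
#'   `read_detection_csv` returns the matrix.
#' @export
write_detection_csv <- function(matrix, path) {
  df <- data.frame(site_id = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_detection_csv
#' @export
read_detection_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$site_id
  class(m) <- c("detection_matrix", class(m))
  m
}
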