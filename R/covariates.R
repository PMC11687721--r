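# Covariate preparation: standardization, collinearity screen, and the
# derived large-predator activity covariate.

#' Standardize covariate columns
#'
#' z-scores each column with the sample mean and sample SD (denominator
#' n - 1), retaining the raw moments so values can be back-transformed. All
#' model predictors are standardized to put them on a common scale.
#'
#' @param raw Data frame of per-site covariate columns; may include a
#'   `site_id` column, which is carried through unstandardized.
#' @return A `covariate_table`: data frame of z-scored columns with
#'   attributes `raw_means` and `raw_sds`.
#' @export
#' @examples
#' standardize(data.frame(a = c(1, 2, 3)))$a  # -1 0 1
standardize <- function(raw) {
  id <- raw[["site_id"]]
  num <- raw[setdiff(names(raw), "site_id")]
  if (nrow(num) < 2) stop2("need >= 2 sites to standardize")
  if (!all(vapply(num, is.numeric, logical(1))))
    stop2("non-numeric covariate column(s): ",
          paste(names(num)[!vapply(num, is.numeric, logical(1))],
                collapse = ", "))
  mus <- vapply(num, mean, numeric(1))
  sds <- vapply(num, sd, numeric(1))
  if (any(sds == 0))
    stop2("cannot standardize constant column(s): ",
          paste(names(num)[sds == 0], collapse = ", "))
  z <- as.data.frame(mapply(function(x, m, s) (x - m) / s, num, mus, sds,
                            SIMPLIFY = FALSE))
  if (!is.null(id)) z <- cbind(data.frame(site_id = id,
                                          stringsAsFactors = FALSE), z)
  structure(z, raw_means = mus, raw_sds = sds,
            class = c("covariate_table", "data.frame"))
}

#' Invert a standardization
#'
#' Recovers raw covariate values from a [standardize()] result using the
#' stored moments.
#'
#' @param table A `covariate_table`.
#' @return Data frame of raw-scale columns.
#' @export
unstandardize <- function(table) {
  mus <- attr(table, "raw_means"); sds <- attr(table, "raw_sds")
  if (is.null(mus)) stop2("not a covariate_table: raw moments missing")
  out <- as.data.frame(mapply(function(x, m, s) x * s + m,
                              table[names(mus)], mus, sds,
                              SIMPLIFY = FALSE))
  if ("site_id" %in% names(table))
    out <- cbind(table["site_id"], out)
  out
}

#' Screen covariate pairs for collinearity
#'
#' Flags every unordered pair of covariates whose Pearson correlation
#' exceeds `threshold` in absolute value (conventional cutoff |r| > 0.7).
#' An empty result means all predictors can be retained.
#'
#' @param table Covariate data frame (a `site_id` column is ignored).
#' @param threshold Absolute correlation cutoff.
#' @return Data frame with `var1`, `var2`, `r` for each flagged pair
#'   (zero rows if none).
#' @export
correlation_screen <- function(table, threshold = 0.7) {
  num <- table[setdiff(names(table), "site_id")]
  if (nrow(num) < 3) stop2("need >= 3 sites for a correlation screen")
  r <- cor(as.matrix(num))
  pairs <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  out <- data.frame(var1 = rownames(r)[pairs[, 1]],
                    var2 = colnames(r)[pairs[, 2]],
                    r = r[pairs], stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Derived large-predator activity covariate
#'
#' Per site, the fraction of sampling occasions with at least one record of
#' any listed predator species, pooled (tiger and leopard collectively by
#' default), using the same occasion binning as the focal-species matrix.
#' This is the naive occasion-level detection frequency — the simplest
#' site-level activity measure consistent with pooling the two carnivores.
#'
#' @param records Daily records data frame (`site_id`, `date`, `species`).
#' @param deployments Deployment table.
#' @param predator_species Predator labels to pool (default tiger, leopard).
#' @param bin_days Occasion length (default 7).
#' @return Named numeric vector of per-site fractions in site order.
#' @export
predator_covariate <- function(records, deployments,
                               predator_species = c("tiger", "leopard"),
                               bin_days = 7) {
  if (!length(predator_species)) stop2("predator_species must be nonempty")
  present <- unique(records$species)
  missing <- setdiff(predator_species, present)
  if (length(missing))
    warning("no records for predator label(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  # pooled daily presence of any listed predator
  pooled <- records[records$species %in% predator_species, , drop = FALSE]
  pooled$species <- rep("any_predator", nrow(pooled))
  daily <- build_daily_matrix(pooled, deployments, "any_predator")
  occ <- collapse_occasions(daily, bin_days)
  hits <- rowSums(occ == 1L, na.rm = TRUE)
  trials <- rowSums(!is.na(occ))
  frac <- ifelse(trials > 0, hits / trials, 0)
  names(frac) <- rownames(occ)
  frac
}

#' Assemble the standardized model covariate table
#'
#' Maps the raw site table onto the seven canonical model covariates
#' (settlement, livestock, predators, cropland, canopycover, human, road),
#' replacing the predator column with the record-derived activity fraction
#' from [predator_covariate()] when records are supplied, then standardizes
#' everything together.
#'
#' @param sites SiteTable.
#' @param records,deployments Optional daily records and deployments; when
#'   given, the predators covariate is derived from them.
#' @param bin_days Occasion length for the predator covariate.
#' @return A standardized `covariate_table` with `site_id` and the seven
#'   canonical columns.
#' @export
prepare_covariates <- function(sites, records = NULL, deployments = NULL,
                               bin_days = 7) {
  raw <- .site_raw_covariates(sites)
  if (!is.null(records) && !is.null(deployments)) {
    frac <- predator_covariate(records, deployments, bin_days = bin_days)
    raw$predators <- as.numeric(frac[sites$site_id])
  }
  raw <- cbind(data.frame(site_id = sites$site_id,
                          stringsAsFactors = FALSE), raw)
  standardize(raw)
}

#' Write / read the covariate CSV
#'
#' Header names the columns in the canonical beta order; raw moments are not
#' serialized (the CSV carries the standardized values the model consumes).
#'
#' @param table A `covariate_table`.
#' @param path File path.
#' @export
write_covariates_csv <- function(table, path) {
  cols <- c("site_id", occu_covariate_names())
  write.csv(as.data.frame(table)[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates_csv
#' @export
read_covariates_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(occu_covariate_names(), names(df))
  if (length(miss))
    stop2("covariate CSV missing canonical column(s): ",
          paste(miss, collapse = ", "))
  structure(df[c("site_id", occu_covariate_names())],
            class = c("covariate_table", "data.frame"))
}
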