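# Synthetic survey generator: landscapes, covariates, latent occupancy and
# daily detection records with the statistical structure the downstream
# analysis assumes.

#' Default covariate moment specification
#'
#' Per-covariate target moments and sampling families for
#' [simulate_landscape()]. Canopy cover and the two distances are truncated
#' normals whose underlying parameters are solved so the *truncated* moments
#' hit the targets; human and livestock counts are negative binomial (their
#' reported SDs far exceed their means, i.e. strong overdispersion); farmland
#' area is log-normal capped at the 500 m buffer area; predator activity is a
#' right-skewed Beta fraction.
#'
#' Default means/SDs for canopy, humans, livestock and the two distances are
#' the field-reported values for the emulated study area (canopy
#' 42.19 +/- 21.36 %, humans 76.72 +/- 244.55, livestock 36.74 +/- 102.45,
#' road 741.69 +/- 1138.91 m, settlement 2182.80 +/- 1691.33 m).
#'
#' @return Named list of per-covariate specs, each a list with `dist`,
#'   `mean`, `sd` and (where relevant) `lower`, `upper`, `shape1`, `shape2`.
#' @export
occu_default_moments <- function() {
  list(
    canopy          = list(dist = "truncnorm", mean = 42.19, sd = 21.36,
                           lower = 0, upper = 100),
    humans          = list(dist = "negbin",    mean = 76.72, sd = 244.55),
    livestock       = list(dist = "negbin",    mean = 36.74, sd = 102.45),
    farmland        = list(dist = "lognormal", mean = 1.5e5, sd = 1.5e5,
                           upper = pi * 500^2),
    road_dist       = list(dist = "truncnorm", mean = 741.69, sd = 1138.91,
                           lower = 0, upper = Inf),
    settlement_dist = list(dist = "truncnorm", mean = 2182.80, sd = 1691.33,
                           lower = 0, upper = Inf),
    predator_rate   = list(dist = "beta", shape1 = 1.2, shape2 = 6.8)
  )
}

# Moments of a normal(mu, sigma) truncated to [a, b].
.truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  da <- dnorm(al); db <- dnorm(be)
  m <- mu + sigma * (da - db) / Z
  t1 <- if (is.finite(al)) al * da else 0
  t2 <- if (is.finite(be)) be * db else 0
  v <- sigma^2 * (1 + (t1 - t2) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for underlying (mu, sigma) so the truncated moments match the target.
.truncnorm_solve <- function(mean, sd, lower, upper) {
  obj <- function(par) {
    m <- .truncnorm_moments(par[1], exp(par[2]), lower, upper)
    (m["mean"] - mean)^2 / max(sd, 1)^2 + (m["sd"] - sd)^2 / max(sd, 1)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Inverse-CDF sampler for the truncated normal (fixed RNG draw count).
# u is clamped away from {0, 1} so qnorm stays finite.
.rtruncnorm <- function(n, mu, sigma, a, b) {
  u <- runif(n, pnorm((a - mu) / sigma), pnorm((b - mu) / sigma))
  u <- pmin(pmax(u, 1e-16), 1 - 1e-16)
  mu + sigma * stats::qnorm(u)
}

.rlnorm_moments <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
}

.draw_covariate <- function(n, spec) {
  if (!is.null(spec$sd) && spec$sd == 0)     # degenerate: everything at mean
    return(rep(spec$mean, n))
  if (spec$dist == "beta")
    return(rbeta(n, spec$shape1, spec$shape2))
  switch(spec$dist,
    truncnorm = {
      par <- .truncnorm_solve(spec$mean, spec$sd, spec$lower, spec$upper)
      got <- .truncnorm_moments(par$mu, par$sigma, spec$lower, spec$upper)
      # A zero-truncated normal cannot exceed CV ~ 1; when the requested
      # moments are infeasible (solver residual > 1%) fall back to a
      # log-normal, which matches any positive mean/SD exactly.
      feasible <- abs(got["mean"] - spec$mean) < 0.01 * max(spec$mean, 1) &&
        abs(got["sd"] - spec$sd) < 0.01 * max(spec$sd, 1)
      if (feasible)
        .rtruncnorm(n, par$mu, par$sigma, spec$lower, spec$upper)
      else {
        x <- .rlnorm_moments(n, spec$mean - spec$lower, spec$sd) + spec$lower
        if (is.finite(spec$upper)) pmin(x, spec$upper) else x
      }
    },
    negbin = {
      v <- spec$sd^2
      if (v > spec$mean) {
        size <- spec$mean^2 / (v - spec$mean)
        rnbinom(n, size = size, mu = spec$mean)
      } else stats::rpois(n, spec$mean)
    },
    lognormal = {
      s2 <- log(1 + (spec$sd / spec$mean)^2)
      x <- rlnorm(n, log(spec$mean) - s2 / 2, sqrt(s2))
      if (!is.null(spec$upper)) pmin(x, spec$upper) else x
    },
    stop2("unknown distribution family: ", spec$dist)
  )
}

# Sequential-inhibition placement: darts in a planar box, rejecting candidates
# closer than min_sep to an accepted site. The box grows if the requested
# density is infeasible.
.place_sites <- function(n, min_sep, bbox) {
  area <- (bbox[2] - bbox[1]) * (bbox[4] - bbox[3])
  need <- n * (2 * min_sep)^2
  if (need > area) {
    f <- sqrt(need / area)
    bbox <- c(bbox[1], bbox[1] + (bbox[2] - bbox[1]) * f,
              bbox[3], bbox[3] + (bbox[4] - bbox[3]) * f)
  }
  x <- numeric(n); y <- numeric(n); k <- 0L; tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > 200L * n) stop2("could not place ", n, " sites at ",
                                min_sep, " m separation")
    cx <- runif(1, bbox[1], bbox[2]); cy <- runif(1, bbox[3], bbox[4])
    if (k == 0L || min((x[seq_len(k)] - cx)^2 + (y[seq_len(k)] - cy)^2) >=
        min_sep^2) {
      k <- k + 1L; x[k] <- cx; y[k] <- cy
    }
  }
  list(x = x, y = y, bbox = bbox)
}

#' Simulate a survey landscape with site covariates
#'
#' Places `n_sites` cameras in a planar frame with a minimum pairwise
#' separation and draws the raw site covariates from distributions whose
#' moments match the requested specification (see [occu_default_moments()]).
#'
#' @param n_sites Number of camera sites (>= 2).
#' @param seed Integer RNG seed; the result is bit-reproducible given the
#'   seed and parameters.
#' @param moments Per-covariate moment specification; defaults to the
#'   study-area values in [occu_default_moments()]. Entries may be partially
#'   overridden (e.g. `moments$humans$mean <- 50`).
#' @param min_separation Minimum pairwise site distance in metres
#'   (default 1000, the emulated design's camera spacing).
#' @param bbox Bounding box `c(xmin, xmax, ymin, ymax)` in metres; expanded
#'   automatically if too dense for the separation constraint.
#' @return A `data.frame` ("SiteTable") with columns `site_id`, `x`, `y`,
#'   `canopy`, `humans`, `livestock`, `farmland`, `road_dist`,
#'   `settlement_dist`, `predator_rate`, `in_protected_area`.
#' @export
#' @examples
#' sites <- simulate_landscape(10, seed = 1)
#' summary(sites$canopy)
simulate_landscape <- function(n_sites, seed,
                               moments = occu_default_moments(),
                               min_separation = 1000,
                               bbox = c(0, 150000, 0, 65000)) {
  if (!is.numeric(n_sites) || length(n_sites) != 1 || n_sites < 2)
    stop2("n_sites must be a single integer >= 2")
  n_sites <- as.integer(n_sites)
  sds <- vapply(moments, function(s) s$sd %||% 0, numeric(1))
  if (any(sds < 0)) stop2("negative SD in moments spec for: ",
                          paste(names(moments)[sds < 0], collapse = ", "))
  set.seed(as.integer(seed))
  pos <- .place_sites(n_sites, min_separation, bbox)
  cov <- lapply(moments, function(s) .draw_covariate(n_sites, s))
  # Protected areas anchor the west and east ends of the complex.
  xr <- pos$bbox[1:2]
  protected <- pos$x < xr[1] + 0.18 * diff(xr) | pos$x > xr[1] + 0.85 * diff(xr)
  out <- data.frame(
    site_id = sprintf("S%03d", seq_len(n_sites)),
    x = pos$x, y = pos$y,
    canopy = cov$canopy, humans = cov$humans, livestock = cov$livestock,
    farmland = cov$farmland, road_dist = cov$road_dist,
    settlement_dist = cov$settlement_dist, predator_rate = cov$predator_rate,
    in_protected_area = protected,
    stringsAsFactors = FALSE
  )
  class(out) <- c("site_table", "data.frame")
  out
}

# Raw-site -> canonical model covariate mapping (canonical beta order).
.site_raw_covariates <- function(sites) {
  data.frame(
    settlement  = sites$settlement_dist,
    livestock   = sites$livestock,
    predators   = sites$predator_rate,
    cropland    = sites$farmland,
    canopycover = sites$canopy,
    human       = sites$humans,
    road        = sites$road_dist
  )
}

# z-score that maps constant columns to 0 (generator-internal; the public
# standardize() rejects constant columns instead).
.zscore0 <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Simulate latent occupancy truth
#'
#' Applies the occupancy linear predictor `logit(psi) = beta0 + X beta` to
#' the standardized site covariates (canonical order
#' [occu_covariate_names()]) and draws the latent presence state
#' `z ~ Bernoulli(psi)`. Detection probability per occasion is constant.
#'
#' @param sites SiteTable from [simulate_landscape()].
#' @param beta Numeric coefficient vector: intercept followed by the seven
#'   slopes in canonical order (length 8).
#' @param p Per-occasion detection probability in (0, 1).
#' @param seed Integer RNG seed.
#' @return A `data.frame` ("TruthRecord" rows) with `site_id`, `psi_true`,
#'   `z_true`, `p_true`, plus `predator_rate` carried along for record
#'   simulation.
#' @export
simulate_truth <- function(sites, beta, p, seed) {
  covs <- occu_covariate_names()
  if (length(beta) != 1 + length(covs))
    stop2("beta must have length ", 1 + length(covs),
          ": intercept then slopes in order (",
          paste(covs, collapse = ", "), ")")
  if (!is.numeric(p) || p <= 0 || p >= 1)
    stop2("p must be in (0, 1)")
  raw <- .site_raw_covariates(sites)
  X <- vapply(raw, .zscore0, numeric(nrow(raw)))
  eta <- beta[1] + drop(X %*% beta[-1])
  psi <- plogis(eta)
  set.seed(as.integer(seed))
  z <- rbinom(nrow(sites), 1, psi)
  data.frame(site_id = sites$site_id, psi_true = psi, z_true = z,
             p_true = p, predator_rate = sites$predator_rate,
             stringsAsFactors = FALSE)
}

#' Simulate daily detection records
#'
#' For occupied sites, each active day yields a focal-species detection with
#' a daily probability `q` solving `1 - (1 - q)^bin_days = p_true`, so that
#' the per-occasion detection probability after collapsing equals `p_true`.
#' Unoccupied sites yield no focal detections (no false positives). Large
#' predators (tiger and leopard) are co-simulated at each site's
#' `predator_rate` (on the same occasion scale) for covariate derivation.
#'
#' @param truth TruthRecord rows from [simulate_truth()].
#' @param n_days Days each camera is active (>= 1).
#' @param seed Integer RNG seed.
#' @param bin_days Occasion length in days used to back-solve the daily
#'   probability (default 7).
#' @param species Focal species label in the records (default "porcupine").
#' @param predator_species Predator labels, sampled uniformly per predator
#'   detection day.
#' @param start_date Deployment start date for all sites (ISO Date).
#' @return List with `records` (data.frame: `site_id`, `date`, `species`,
#'   `count`) and `deployments` (data.frame: `site_id`, `start_date`,
#'   `end_date`).
#' @export
simulate_records <- function(truth, n_days, seed, bin_days = 7,
                             species = "porcupine",
                             predator_species = c("tiger", "leopard"),
                             start_date = as.Date("2022-12-01")) {
  if (!is.numeric(n_days) || n_days < 1) stop2("n_days must be >= 1")
  n_days <- as.integer(n_days)
  set.seed(as.integer(seed))
  n <- nrow(truth)
  q_focal <- 1 - (1 - truth$p_true)^(1 / bin_days)
  q_pred  <- 1 - (1 - truth$predator_rate)^(1 / bin_days)
  days <- start_date + seq_len(n_days) - 1L

  # site x day Bernoulli fields, drawn row-wise for seed stability
  rec <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    hit <- if (truth$z_true[i] == 1) which(rbinom(n_days, 1, q_focal[i]) == 1)
           else integer(0)
    if (length(hit))
      rec[[i]] <- data.frame(site_id = truth$site_id[i], date = days[hit],
                             species = species, count = 1L,
                             stringsAsFactors = FALSE)
    phit <- which(rbinom(n_days, 1, q_pred[i]) == 1)
    if (length(phit))
      rec[[n + i]] <- data.frame(
        site_id = truth$site_id[i], date = days[phit],
        species = sample(predator_species, length(phit), replace = TRUE),
        count = 1L, stringsAsFactors = FALSE)
  }
  rec <- rec[!vapply(rec, is.null, logical(1))]
  records <- if (length(rec)) do.call(rbind, rec)
             else data.frame(site_id = character(0),
                             date = as.Date(character(0)),
                             species = character(0), count = integer(0),
                             stringsAsFactors = FALSE)
  records <- records[order(records$site_id, records$date, records$species), ,
                     drop = FALSE]
  rownames(records) <- NULL
  deployments <- data.frame(site_id = truth$site_id,
                            start_date = start_date,
                            end_date = start_date + n_days - 1L,
                            stringsAsFactors = FALSE)
  list(records = records, deployments = deployments)
}

#' Simulate a complete survey
#'
#' Convenience wrapper chaining [simulate_landscape()], [simulate_truth()]
#' and [simulate_records()] with sub-seeds derived from `seed`.
#'
#' @param n_sites,n_days,bin_days Survey design; defaults are the emulated
#'   study design (154 sites, 21 days, 7-day occasions).
#' @param beta,p Truth parameters passed to [simulate_truth()].
#' @param seed Master seed; stage seeds are derived as small offsets.
#' @param moments Covariate moment spec for [simulate_landscape()].
#' @return List with `sites`, `truth`, `records`, `deployments` and the
#'   design settings.
#' @export
simulate_survey <- function(n_sites = 154, n_days = 21, bin_days = 7,
                            beta = c(-0.75, 0, 0, 0, 1.5, -1.0, 0, 0),
                            p = 0.3, seed = 1,
                            moments = occu_default_moments()) {
  seed <- as.integer(seed)
  sites <- simulate_landscape(n_sites, seed = seed, moments = moments)
  truth <- simulate_truth(sites, beta = beta, p = p, seed = seed + 1L)
  sim <- simulate_records(truth, n_days = n_days, seed = seed + 2L,
                          bin_days = bin_days)
  list(sites = sites, truth = truth, records = sim$records,
       deployments = sim$deployments,
       design = list(n_sites = n_sites, n_days = n_days, bin_days = bin_days,
                     beta = beta, p = p, seed = seed))
}

#' Write synthetic survey CSVs
#'
#' Writes the deployments, records and raw site-covariate tables as CSV with
#' ISO-8601 dates.
#'
#' @param sim Result of [simulate_survey()] (or a compatible list).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_survey_csvs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(deployments = file.path(dir, "deployments.csv"),
             records = file.path(dir, "records.csv"),
             sites = file.path(dir, "sites.csv"))
  dep <- sim$deployments
  dep$start_date <- format(dep$start_date); dep$end_date <- format(dep$end_date)
  write.csv(dep, paths["deployments"], row.names = FALSE)
  rec <- sim$records; rec$date <- format(rec$date)
  write.csv(rec, paths["records"], row.names = FALSE)
  write.csv(as.data.frame(sim$sites), paths["sites"], row.names = FALSE)
  invisible(paths)
}

#' Read survey CSVs
#'
#' Counterpart of [write_survey_csvs()]: reads deployments, records and site
#' tables, parsing ISO dates.
#'
#' @param dir Directory containing `deployments.csv`, `records.csv`,
#'   `sites.csv`.
#' @return List with `deployments`, `records`, `sites`.
#' @export
read_survey_csvs <- function(dir) {
  dep <- read.csv(file.path(dir, "deployments.csv"),
                  stringsAsFactors = FALSE)
  dep$start_date <- as.Date(dep$start_date)
  dep$end_date <- as.Date(dep$end_date)
  rec <- read.csv(file.path(dir, "records.csv"), stringsAsFactors = FALSE)
  rec$date <- as.Date(rec$date)
  sites <- read.csv(file.path(dir, "sites.csv"), stringsAsFactors = FALSE)
  class(sites) <- c("site_table", "data.frame")
  list(deployments = dep, records = rec, sites = sites)
}
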