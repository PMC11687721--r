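# Convergence diagnostics and posterior summaries.

# Split each column (chain) of an iterations x chains matrix in half,
# yielding a matrix with 2x the chains; drops one draw if odd.
.split_chains <- function(x) {
  n <- nrow(x) - nrow(x) %% 2L
  h <- n %/% 2L
  cbind(x[seq_len(h), , drop = FALSE], x[h + seq_len(h), , drop = FALSE])
}

#' Split-chain Gelman-Rubin Rhat
#'
#' Potential scale reduction factor on split chains: each chain is halved so
#' within-chain trends register as between-chain variance. Values near 1
#' indicate convergence; the conventional warning threshold in this pipeline
#' is 1.1.
#'
#' @param x Draws for one parameter: an iterations x chains matrix (>= 2
#'   chains, >= 10 draws each).
#' @return Rhat value, or `NA` when all draws are identical (zero-variance
#'   sentinel).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop2("Rhat needs >= 2 chains")
  if (nrow(x) < 10) stop2("Rhat needs >= 10 draws per chain")
  x <- .split_chains(x)
  n <- nrow(x); m <- ncol(x)
  mu <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(mu)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Effective sample size
#'
#' Autocorrelation-adjusted count of independent draws, computed on split
#' chains with the multi-chain correction
#' `rho_t = 1 - (W - mean_c acov_t,c) / var_plus` and Geyer's initial
#' monotone positive-pair truncation of the autocorrelation sum.
#'
#' @inheritParams rhat
#' @return Effective sample size (capped at the total draw count), or `NA`
#'   for zero-variance draws.
#' @export
ess <- function(x) {
  x <- as.matrix(x)
  x <- .split_chains(x)
  n <- nrow(x); m <- ncol(x)
  W <- mean(apply(x, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(colMeans(x))
  var_plus <- (n - 1) / n * W + B / n
  max_lag <- min(n - 1L, 1000L)
  # per-chain autocovariances (biased, denominator n — standard here)
  acov <- vapply(seq_len(m), function(c) {
    a <- acf(x[, c], lag.max = max_lag, type = "covariance",
             plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  }, numeric(max_lag + 1L))
  rho <- 1 - (W - rowMeans(acov)) / var_plus   # rho[1] is lag 0 (= ~1)
  # Geyer: sum consecutive pairs while positive and non-increasing
  tau <- 0; prev <- Inf
  t <- 2L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + pair
    prev <- pair
    t <- t + 2L
  }
  ess <- n * m / (1 + 2 * tau)
  min(ess, n * m)
}

.param_matrix <- function(chains, param) {
  if (inherits(chains, "occu_chains")) chains$draws[, , param]
  else chains[, , param]
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, SD, 95% credible interval (LCI/UCI as the
#' 2.5%/97.5% quantiles), split-chain Rhat, effective sample size, the
#' `overlap0` flag (does the 95% CrI contain zero) and the `f` statistic
#' (fraction of draws sharing the sign of the posterior mass — computed as
#' `max(P(draw >= 0), P(draw <= 0))`, so `f` is in [0.5, 1] and equals 1 for
#' constant-sign draws).
#'
#' Parameters with Rhat above `rhat_warn` trigger a warning (reported, not
#' enforced).
#'
#' @param chains An `occu_chains` object (or an iterations x chains x
#'   parameters array with dimnames).
#' @param spec Optional model spec (unused beyond parameter naming; kept for
#'   interface symmetry).
#' @param rhat_warn Convergence warning threshold (default 1.1).
#' @return Data frame of class `occu_summary` with columns `parameter`,
#'   `mean`, `sd`, `LCI`, `UCI`, `Rhat`, `n.eff`, `overlap0`, `f`.
#' @export
summarize_posterior <- function(chains, spec = NULL, rhat_warn = 1.1) {
  draws <- if (inherits(chains, "occu_chains")) chains$draws else chains
  params <- dimnames(draws)[[3]] %||% paste0("par", seq_len(dim(draws)[3]))
  multi <- dim(draws)[2] >= 2 && dim(draws)[1] >= 10
  rows <- lapply(seq_along(params), function(i) {
    m <- draws[, , i, drop = FALSE]; dim(m) <- dim(draws)[1:2]
    v <- as.numeric(m)
    q <- quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(parameter = params[i], mean = mean(v), sd = sd(v),
               LCI = q[1], UCI = q[2],
               Rhat = if (multi) rhat(m) else NA_real_,
               n.eff = if (multi) ess(m) else NA_real_,
               overlap0 = q[1] <= 0 && q[2] >= 0,
               f = max(mean(v >= 0), mean(v <= 0)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bad <- !is.na(out$Rhat) & out$Rhat > rhat_warn
  if (any(bad))
    warning("Rhat > ", rhat_warn, " for: ",
            paste(out$parameter[bad], collapse = ", "),
            " — chains may not have converged", call. = FALSE)
  class(out) <- c("occu_summary", "data.frame")
  out
}

#' Derived occupancy quantities
#'
#' From posterior draws, computes per-site posterior mean occupancy
#' `psi_i`, the posterior distribution of the landscape mean occupancy
#' (mean of `psi_i` across sites, per draw; reported as mean +/- SD), and the
#' conditional occupancy given each site's detection history:
#' `psi (1-p)^J / (psi (1-p)^J + 1 - psi)` for undetected sites, 1 for
#' detected sites.
#'
#' @param chains An `occu_chains` object from [run_mcmc()].
#' @param covariates Covariate table the model was fitted to (checked for
#'   consistency).
#' @return List with `psi_site` (per-site posterior means), `mean_occupancy`,
#'   `sd_occupancy`, `conditional` (per-site posterior mean conditional
#'   occupancy), and `p_mean`.
#' @export
derived_occupancy <- function(chains, covariates = NULL) {
  dat <- chains$data
  if (!is.null(covariates)) {
    cn <- chains$spec$covariate_names
    X_check <- cbind(1, as.matrix(as.data.frame(covariates)[cn]))
    if (!isTRUE(all.equal(unname(X_check), unname(dat$X),
                          tolerance = 1e-12)))
      stop2("covariates do not match those the chains were fitted to")
  }
  draws <- chains$draws
  nb <- length(chains$params) - 1L
  bmat <- matrix(draws[, , seq_len(nb), drop = FALSE],
                 ncol = nb)            # (iter*chain) x nbeta, pooled
  pvec <- as.numeric(draws[, , "p"])
  psi_draws <- plogis(dat$X %*% t(bmat))          # n_sites x ndraws
  mean_by_draw <- colMeans(psi_draws)
  detected <- dat$d > 0
  q <- (1 - matrix(pvec, dat$n_sites, length(pvec),
                   byrow = TRUE))^dat$J           # (1-p)^J per site x draw
  cond <- psi_draws * q / (psi_draws * q + 1 - psi_draws)
  cond[detected, ] <- 1
  list(psi_site = rowMeans(psi_draws),
       mean_occupancy = mean(mean_by_draw),
       sd_occupancy = sd(mean_by_draw),
       conditional = rowMeans(cond),
       p_mean = mean(pvec))
}

#' Write / read the posterior summary CSV
#'
#' Serializes the summary table with the standard column schema
#' (`parameter, mean, sd, LCI, UCI, Rhat, n.eff, overlap0, f`).
#'
#' @param summary An `occu_summary` data frame.
#' @param path File path.
#' @export
write_summary_csv <- function(summary, path) {
  cols <- c("parameter", "mean", "sd", "LCI", "UCI", "Rhat", "n.eff",
            "overlap0", "f")
  write.csv(as.data.frame(summary)[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("occu_summary", "data.frame")
  out
}
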