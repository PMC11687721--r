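# Bayesian single-season, single-species occupancy model with constant
# detection: marginalized likelihood, priors, and an adaptive random-walk
# Metropolis sampler (no latent-state augmentation, so the likelihood can be
# checked directly against latent-state enumeration).

#' Occupancy model specification
#'
#' @param covariate_names Ordered covariate names; must match the canonical
#'   covariate order of the covariate table.
#' @param prior_sd_beta SD of the independent Normal(0, sd) priors on the
#'   logit-scale intercept and slopes. The default 2.5 is the conventional
#'   weakly-informative scale for standardized predictors on the logit
#'   scale; much wider priors (e.g. 10) put substantial mass on the
#'   quasi-separation ridge (huge slopes compensated by tiny detection) and
#'   degrade recovery of moderate effects.
#' @param p_prior Prior on the per-occasion detection probability:
#'   `"uniform"` (Uniform(0,1), default) or `"logit-normal"` with
#'   `prior_sd_logit_p`.
#' @param prior_sd_logit_p SD of the logit-normal detection prior when
#'   `p_prior = "logit-normal"`.
#' @param fix_p Optional: hold the detection probability fixed at this
#'   value instead of sampling it (used for reduced models and sampler
#'   validation).
#' @return An object of class `occu_model_spec`.
#' @export
occu_model_spec <- function(covariate_names = occu_covariate_names(),
                            prior_sd_beta = 2.5,
                            p_prior = c("uniform", "logit-normal"),
                            prior_sd_logit_p = 1.5, fix_p = NULL) {
  p_prior <- match.arg(p_prior)
  if (prior_sd_beta <= 0) stop2("prior_sd_beta must be positive")
  if (!is.null(fix_p) && (fix_p <= 0 || fix_p >= 1))
    stop2("fix_p must be in (0, 1)")
  structure(list(covariate_names = covariate_names,
                 prior_sd_beta = prior_sd_beta, p_prior = p_prior,
                 prior_sd_logit_p = prior_sd_logit_p, fix_p = fix_p,
                 detection_model = "constant"),
            class = "occu_model_spec")
}

#' MCMC configuration
#'
#' Defaults mirror the emulated study's sampler settings: 3 chains, 1000
#' adaptation iterations (proposal-scale tuning, then frozen), 1000 burn-in,
#' 10,000 retained iterations. `occu_mcmc_fast()` is a cheaper profile
#' (3 x 2000) for CI-scale runs.
#'
#' @param n_chains Number of chains (>= 2 for Rhat).
#' @param n_adapt Adaptation iterations; proposal scales are tuned toward a
#'   20-40% acceptance rate and then frozen.
#' @param n_burnin Post-adaptation iterations discarded.
#' @param n_iter Retained iterations per chain.
#' @param seed Integer seed; chains use derived sub-seeds.
#' @param init_scale Initial random-walk proposal SD per parameter.
#' @return An object of class `occu_mcmc_config`.
#' @export
occu_mcmc_config <- function(n_chains = 3, n_adapt = 1000, n_burnin = 1000,
                             n_iter = 10000, seed = 1, init_scale = 0.3) {
  stopifnot(n_chains >= 1, n_adapt >= 1, n_burnin >= 1, n_iter >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_adapt = as.integer(n_adapt),
                 n_burnin = as.integer(n_burnin),
                 n_iter = as.integer(n_iter),
                 seed = as.integer(seed), init_scale = init_scale),
            class = "occu_mcmc_config")
}

#' @rdname occu_mcmc_config
#' @export
occu_mcmc_fast <- function(seed = 1) {
  occu_mcmc_config(n_chains = 3, n_adapt = 500, n_burnin = 500,
                   n_iter = 2000, seed = seed)
}

# Align matrix + covariates into sufficient statistics. Under constant p the
# per-site marginal likelihood depends only on (detections d, trials J).
.occu_data <- function(matrix, covariates, covariate_names) {
  cn <- intersect(covariate_names, names(covariates))
  if (length(cn) != length(covariate_names))
    stop2("covariate table lacks column(s): ",
          paste(setdiff(covariate_names, names(covariates)), collapse = ", "))
  if (nrow(matrix) != nrow(covariates))
    stop2("site count mismatch: matrix has ", nrow(matrix),
          " rows, covariates ", nrow(covariates))
  if (!is.null(rownames(matrix)) && "site_id" %in% names(covariates) &&
      !identical(rownames(matrix), as.character(covariates$site_id)))
    stop2("site order differs between detection matrix and covariates")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(covariates)[covariate_names]))
  d <- as.integer(rowSums(matrix == 1L, na.rm = TRUE))
  J <- as.integer(rowSums(!is.na(matrix)))
  list(X = X, d = d, J = J, A0 = as.numeric(d == 0L),
       n_sites = nrow(matrix))
}

# Core marginal log-likelihood from sufficient statistics.
# l_i = log( psi_i p^d (1-p)^(J-d) + (1-psi_i) 1[d=0] )
.occu_ll <- function(eta, detlik, A0) {
  psi <- plogis(eta)
  contrib <- psi * detlik + (1 - psi) * A0
  if (any(contrib <= 0)) return(-Inf)
  sum(log(contrib))
}

.detlik <- function(p, d, J) exp(d * log(p) + (J - d) * log1p(-p))

#' Marginal log-likelihood of the occupancy model
#'
#' The latent occupancy state is marginalized out analytically: each site
#' contributes `psi_i * p^d_i (1-p)^(J_i - d_i) + (1 - psi_i) * 1[d_i = 0]`,
#' where `d_i` counts occasions with detections and `J_i` the non-missing
#' occasions. Missing occasions are skipped. An empty matrix (zero sites)
#' yields 0.
#'
#' @param beta Coefficient vector (intercept first) matching the covariate
#'   order.
#' @param p Per-occasion detection probability in (0, 1).
#' @param matrix Sites x occasions detection matrix (`NA` = missing).
#' @param covariates Covariate table aligned to the matrix rows.
#' @param covariate_names Covariate order (default canonical).
#' @return Finite log-likelihood (or `-Inf` for impossible configurations).
#' @export
log_likelihood <- function(beta, p, matrix, covariates,
                           covariate_names = occu_covariate_names()) {
  if (p <= 0 || p >= 1) stop2("p must be in (0, 1)")
  if (nrow(matrix) == 0L) return(0)
  dat <- .occu_data(matrix, covariates, covariate_names)
  if (length(beta) != ncol(dat$X))
    stop2("beta must have length ", ncol(dat$X))
  .occu_ll(drop(dat$X %*% beta), .detlik(p, dat$d, dat$J), dat$A0)
}

.log_prior <- function(beta, p, spec) {
  lp <- sum(dnorm(beta, 0, spec$prior_sd_beta, log = TRUE))
  if (spec$p_prior == "logit-normal")
    lp <- lp + dnorm(qlogis(p), 0, spec$prior_sd_logit_p, log = TRUE)
  lp  # Uniform(0,1) on p adds 0
}

#' Log-posterior density
#'
#' [log_likelihood()] plus independent Normal(0, `prior_sd_beta`) log-priors
#' on the intercept and slopes and the detection prior from the model spec.
#' With an empty matrix this is the log-prior alone.
#'
#' @inheritParams log_likelihood
#' @param spec An [occu_model_spec()].
#' @return Log-posterior value (unnormalized).
#' @export
log_posterior <- function(beta, p, matrix, covariates,
                          spec = occu_model_spec()) {
  ll <- if (nrow(matrix) == 0L) 0
        else log_likelihood(beta, p, matrix, covariates,
                            spec$covariate_names)
  ll + .log_prior(beta, p, spec)
}

# One chain of componentwise adaptive random-walk Metropolis on
# (beta, logit p). Linear predictor is updated incrementally per component.
.occu_chain <- function(dat, spec, config, chain_seed, init_jitter = TRUE) {
  set.seed(chain_seed)
  k <- ncol(dat$X)
  npar <- k + 1L
  p_fixed <- !is.null(spec$fix_p)
  beta <- if (init_jitter) rnorm(k, 0, 0.25) else numeric(k)
  u <- if (p_fixed) qlogis(spec$fix_p)
       else if (init_jitter) rnorm(1, 0, 0.25) else 0   # logit p
  eta <- drop(dat$X %*% beta)
  p <- plogis(u)
  detlik <- .detlik(p, dat$d, dat$J)
  # uniform p prior on the logit scale carries the Jacobian log(p(1-p))
  pr_u <- function(u, p) {
    if (spec$p_prior == "logit-normal") dnorm(u, 0, spec$prior_sd_logit_p,
                                              log = TRUE)
    else log(p) + log1p(-p)
  }
  ll <- .occu_ll(eta, detlik, dat$A0)
  if (!is.finite(ll)) stop2("non-finite log-posterior at initial state")
  lp_beta <- dnorm(beta, 0, spec$prior_sd_beta, log = TRUE)
  lp_u <- pr_u(u, p)

  scales <- rep(config$init_scale, npar)
  total <- config$n_adapt + config$n_burnin + config$n_iter
  draws <- matrix(NA_real_, config$n_iter, npar)
  acc <- integer(npar); acc_win <- integer(npar); win <- 0L
  n_acc_total <- integer(npar)

  for (it in seq_len(total)) {
    adapting <- it <= config$n_adapt
    for (j in seq_len(k)) {
      dlt <- rnorm(1, 0, scales[j])
      eta_new <- eta + dat$X[, j] * dlt
      ll_new <- .occu_ll(eta_new, detlik, dat$A0)
      lp_new <- dnorm(beta[j] + dlt, 0, spec$prior_sd_beta, log = TRUE)
      if (log(runif(1)) < (ll_new + lp_new) - (ll + lp_beta[j])) {
        beta[j] <- beta[j] + dlt; eta <- eta_new
        ll <- ll_new; lp_beta[j] <- lp_new
        acc_win[j] <- acc_win[j] + 1L; n_acc_total[j] <- n_acc_total[j] + 1L
      }
    }
    ju <- npar
    if (!p_fixed) {
      du <- rnorm(1, 0, scales[ju])
      u_new <- u + du; p_new <- plogis(u_new)
      detlik_new <- .detlik(p_new, dat$d, dat$J)
      ll_new <- .occu_ll(eta, detlik_new, dat$A0)
      lpu_new <- pr_u(u_new, p_new)
      if (log(runif(1)) < (ll_new + lpu_new) - (ll + lp_u)) {
        u <- u_new; p <- p_new; detlik <- detlik_new
        ll <- ll_new; lp_u <- lpu_new
        acc_win[ju] <- acc_win[ju] + 1L
        n_acc_total[ju] <- n_acc_total[ju] + 1L
      }
    }
    win <- win + 1L
    if (adapting && win == 50L) {
      rate <- acc_win / win
      scales[rate < 0.20] <- scales[rate < 0.20] * 0.75
      scales[rate > 0.40] <- scales[rate > 0.40] * 1.30
      acc_win[] <- 0L; win <- 0L
    } else if (!adapting && win == 50L) { acc_win[] <- 0L; win <- 0L }
    if (it > config$n_adapt + config$n_burnin)
      draws[it - config$n_adapt - config$n_burnin, ] <- c(beta, p)
  }
  list(draws = draws, scales = scales,
       accept = n_acc_total / total)
}

#' Fit the occupancy model by adaptive random-walk Metropolis
#'
#' Samples `(beta, logit p)` against the marginalized likelihood with
#' componentwise Gaussian random-walk proposals. During the adaptation phase
#' the proposal scales are tuned toward a 20-40% acceptance rate and then
#' frozen; inference uses only the post-adaptation, post-burn-in draws.
#' Detection draws are stored on the probability scale.
#'
#' @param matrix Sites x occasions detection matrix.
#' @param covariates Aligned covariate table (standardized).
#' @param spec An [occu_model_spec()]; pass `covariate_names = character(0)`
#'   for an intercept-only model.
#' @param config An [occu_mcmc_config()].
#' @return An `occu_chains` object: `draws` is an
#'   `n_iter x n_chains x n_param` array with parameters `beta0`,
#'   `beta_<covariate>...`, `p`; plus acceptance rates, frozen proposal
#'   scales, the data sufficient statistics and both input specs.
#' @export
run_mcmc <- function(matrix, covariates, spec = occu_model_spec(),
                     config = occu_mcmc_config()) {
  dat <- .occu_data(matrix, covariates, spec$covariate_names)
  pnames <- c("beta0",
              if (length(spec$covariate_names))
                paste0("beta_", spec$covariate_names), "p")
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    chain_seed <- (config$seed + 104729L * ch) %% .Machine$integer.max
    chains[[ch]] <- .occu_chain(dat, spec, config, chain_seed)
  }
  draws <- array(NA_real_,
                 dim = c(config$n_iter, config$n_chains, length(pnames)),
                 dimnames = list(NULL, paste0("chain", seq_len(config$n_chains)),
                                 pnames))
  for (ch in seq_along(chains)) draws[, ch, ] <- chains[[ch]]$draws
  structure(list(draws = draws, params = pnames,
                 accept = t(vapply(chains, `[[`, numeric(length(pnames)),
                                   "accept")),
                 scales = t(vapply(chains, `[[`, numeric(length(pnames)),
                                   "scales")),
                 data = dat, spec = spec, config = config),
            class = "occu_chains")
}

#' @export
print.occu_chains <- function(x, ...) {
  cat("occu_chains:", dim(x$draws)[2], "chains x", dim(x$draws)[1],
      "draws,", length(x$params), "parameters\n")
  cat("parameters:", paste(x$params, collapse = ", "), "\n")
  cat("mean acceptance:", round(mean(x$accept), 3), "\n")
  invisible(x)
}
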