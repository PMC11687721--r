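# Shared fixtures, all built in code.

# Covariate table with given values in the canonical columns; unspecified
# columns get fixed small non-constant fillers.
tiny_covariates <- function(n, ...) {
  over <- list(...)
  base <- as.data.frame(setNames(
    lapply(seq_along(occu_covariate_names()),
           function(i) seq_len(n) / n - 0.5 + 0.01 * i),
    occu_covariate_names()))
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# Deployment table: every site active for n_days from the same start.
tiny_deployments <- function(site_ids, n_days,
                             start = as.Date("2022-12-01")) {
  data.frame(site_id = site_ids, start_date = start,
             end_date = start + n_days - 1L, stringsAsFactors = FALSE)
}

record_row <- function(site, day, species = "porcupine",
                       start = as.Date("2022-12-01")) {
  data.frame(site_id = site, date = start + day - 1L, species = species,
             count = 1L, stringsAsFactors = FALSE)
}

# Brute-force marginal likelihood by enumerating all 2^n latent occupancy
# configurations; the independent oracle for log_likelihood.
enumerate_loglik <- function(beta, p, y, covariates,
                             covariate_names = occu_covariate_names()) {
  n <- nrow(y)
  X <- cbind(1, as.matrix(as.data.frame(covariates)[covariate_names]))
  psi <- plogis(drop(X %*% beta))
  total <- 0
  for (k in 0:(2^n - 1)) {
    z <- as.integer(intToBits(k))[seq_len(n)]
    pr <- 1
    for (i in seq_len(n)) {
      pr <- pr * if (z[i] == 1) psi[i] else 1 - psi[i]
      for (j in seq_len(ncol(y))) {
        if (is.na(y[i, j])) next
        pd <- if (z[i] == 1) { if (y[i, j] == 1) p else 1 - p
        } else { if (y[i, j] == 1) 0 else 1 }
        pr <- pr * pd
      }
    }
    total <- total + pr
  }
  log(total)
}

# Minimal occu_chains-shaped object with prescribed pooled draws, for
# summary/derived-quantity tests that need exact posterior draws.
fake_chains <- function(beta_draws, p_draws, y, covariates,
                        covariate_names = occu_covariate_names()) {
  spec <- occu_model_spec(covariate_names = covariate_names)
  cfg <- occu_mcmc_config(n_chains = 2, n_iter = nrow(beta_draws) / 2,
                          seed = 1)
  ch <- run_mcmc(y, covariates, spec,
                 occu_mcmc_config(n_chains = 2, n_adapt = 1, n_burnin = 1,
                                  n_iter = nrow(beta_draws) / 2, seed = 1))
  for (j in seq_len(ncol(beta_draws)))
    ch$draws[, , j] <- matrix(beta_draws[, j], ncol = 2)
  ch$draws[, , "p"] <- matrix(p_draws, ncol = 2)
  ch
}
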