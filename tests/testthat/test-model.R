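# occupancy_model module: likelihood, posterior, sampler, diagnostics.

test_that("marginal likelihood matches hand-computed cases", {
  cv1 <- tiny_covariates(1)
  # psi -> 1 limit (huge intercept), single occasion y = 1, p = 0.5
  y1 <- matrix(1L, 1, 1)
  expect_equal(log_likelihood(c(40, rep(0, 7)), 0.5, y1, cv1), log(0.5),
               tolerance = 1e-12)
  # 3 empty occasions, psi = 0.5, p = 0.5:
  # log(0.5 * 0.5^3 + 0.5) = log(0.5625)
  y0 <- matrix(0L, 1, 3)
  cv0 <- tiny_covariates(1)
  cv0[1, ] <- 0                        # zero covariates -> psi = plogis(b0)
  expect_equal(log_likelihood(rep(0, 8), 0.5, y0, cv0), log(0.5625),
               tolerance = 1e-12)
})

test_that("marginal likelihood equals latent-state enumeration (oracle)", {
  set.seed(41)
  for (case in 1:6) {
    n <- sample(2:8, 1)
    y <- matrix(rbinom(n * 3, 1, 0.35), n, 3)
    if (case %% 2 == 0) y[sample(n, 1), sample(3, 1)] <- NA
    cv <- tiny_covariates(n)
    cv[] <- lapply(cv, function(col) rnorm(n))
    beta <- rnorm(8, 0, 0.8)
    p <- runif(1, 0.15, 0.7)
    expect_equal(log_likelihood(beta, p, y, cv),
                 enumerate_loglik(beta, p, y, cv), tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to site permutation", {
  set.seed(42)
  n <- 25
  y <- matrix(rbinom(n * 3, 1, 0.3), n, 3)
  cv <- tiny_covariates(n)
  beta <- rnorm(8, 0, 0.5)
  ll <- log_likelihood(beta, 0.3, y, cv)
  for (i in 1:5) {
    perm <- sample(n)
    expect_lt(abs(log_likelihood(beta, 0.3, y[perm, ], cv[perm, ]) - ll),
              1e-12)
  }
})

test_that("log_likelihood validates alignment and p", {
  y <- matrix(0L, 3, 3)
  expect_error(log_likelihood(rep(0, 8), 0.3, y, tiny_covariates(4)),
               "mismatch")
  expect_error(log_likelihood(rep(0, 8), 1, y, tiny_covariates(3)),
               "p must be")
})

test_that("log_posterior adds the stated priors", {
  y <- matrix(0L, 0, 3)
  cv <- tiny_covariates(1)[0, ]
  spec <- occu_model_spec(prior_sd_beta = 10)
  beta <- c(1, rep(0, 7))
  # empty data: posterior is the prior alone (uniform on p adds 0)
  expect_equal(log_posterior(beta, 0.3, y, cv, spec),
               sum(dnorm(beta, 0, 10, log = TRUE)), tolerance = 1e-12)
  # prior mode maximizes over beta for fixed p
  expect_gt(log_posterior(rep(0, 8), 0.3, y, cv, spec),
            log_posterior(beta, 0.3, y, cv, spec))
  # with data: equals likelihood + closed-form normal density
  set.seed(43)
  y2 <- matrix(rbinom(15, 1, 0.4), 5, 3)
  cv2 <- tiny_covariates(5)
  expect_equal(log_posterior(beta, 0.3, y2, cv2, spec),
               log_likelihood(beta, 0.3, y2, cv2) +
                 sum(dnorm(beta, 0, 10, log = TRUE)), tolerance = 1e-12)
})

test_that("run_mcmc is deterministic given the seed", {
  set.seed(44)
  y <- matrix(rbinom(30, 1, 0.4), 10, 3)
  cv <- tiny_covariates(10)
  cfg <- occu_mcmc_config(n_chains = 2, n_adapt = 50, n_burnin = 50,
                          n_iter = 100, seed = 5)
  a <- run_mcmc(y, cv, config = cfg)
  b <- run_mcmc(y, cv, config = cfg)
  expect_identical(a$draws, b$draws)
})

test_that("intercept-only recovery: psi and p near truth at n = 500", {
  set.seed(45)
  n <- 500
  z <- rbinom(n, 1, 0.5)
  y <- matrix(rbinom(n * 3, 1, 0.5), n, 3) * z
  cv <- data.frame(row.names = seq_len(n))
  spec <- occu_model_spec(covariate_names = character(0))
  ch <- run_mcmc(y, cv, spec, occu_mcmc_config(
    n_chains = 3, n_adapt = 400, n_burnin = 400, n_iter = 2000, seed = 6))
  s <- suppressWarnings(summarize_posterior(ch))
  psi_draws <- plogis(as.numeric(ch$draws[, , "beta0"]))
  expect_lt(abs(mean(psi_draws) - 0.5), 3 * sd(psi_draws))
  p_row <- s[s$parameter == "p", ]
  expect_lt(abs(p_row$mean - 0.5), 3 * p_row$sd)
})

test_that("rhat distinguishes mixed from separated chains", {
  set.seed(46)
  mixed <- matrix(rnorm(4000), 2000, 2)
  expect_lt(rhat(mixed), 1.05)
  separated <- cbind(rnorm(2000, 0), rnorm(2000, 10))
  expect_gt(rhat(separated), 3)
  expect_true(is.na(rhat(matrix(2, 100, 2))))   # zero-variance sentinel
  expect_error(rhat(matrix(rnorm(100), 100, 1)), "2 chains")
})

test_that("ess is near n for iid draws and small for sticky chains", {
  set.seed(47)
  iid <- matrix(rnorm(6000), 3000, 2)
  expect_gt(ess(iid), 4000)
  expect_lte(ess(iid), 6000)
  sticky <- matrix(0, 1000, 2)
  for (c in 1:2) {
    x <- 0
    for (i in 1:1000) { x <- 0.99 * x + rnorm(1, sd = 0.1); sticky[i, c] <- x }
  }
  expect_lt(ess(sticky), 300)
})

test_that("summarize_posterior semantics on constructed draws", {
  y <- matrix(c(1L, 0L, 0L), 1, 3)
  cv <- tiny_covariates(1)
  ch <- fake_chains(matrix(2, 400, 8), rep(0.4, 400), y, cv)
  s <- suppressWarnings(summarize_posterior(ch))
  b0 <- s[s$parameter == "beta0", ]
  expect_equal(b0$mean, 2)
  expect_equal(b0$sd, 0)
  expect_false(b0$overlap0)
  expect_equal(b0$f, 1)
  # symmetric draws: overlap0 true, f ~ 0.5
  set.seed(48)
  sym <- rnorm(400)
  ch2 <- fake_chains(matrix(sym, 400, 8), rep(0.4, 400), y, cv)
  s2 <- suppressWarnings(summarize_posterior(ch2))
  expect_true(s2$overlap0[1])
  expect_lt(abs(s2$f[1] - 0.5), 0.08)
  # overlap0 <=> CrI contains 0, on every parameter
  expect_equal(s2$overlap0, s2$LCI <= 0 & s2$UCI >= 0)
  expect_true(all(s2$f >= 0.5 & s2$f <= 1))
})

test_that("summary quantiles match the normal closed form", {
  set.seed(49)
  draws <- rnorm(10000)
  y <- matrix(c(1L, 0L, 0L), 1, 3)
  ch <- fake_chains(matrix(draws, 10000, 8), rep(0.4, 10000), y,
                    tiny_covariates(1))
  s <- suppressWarnings(summarize_posterior(ch))
  expect_lt(abs(s$LCI[1] - (-1.96)), 0.05)
  expect_lt(abs(s$UCI[1] - 1.96), 0.05)
})

test_that("derived_occupancy computes exact hand cases", {
  # site 1 detected, site 2 undetected; force beta = 0, p = 0.5
  y <- rbind(c(1L, 0L, 1L), c(0L, 0L, 0L))
  cv <- tiny_covariates(2)
  ch <- fake_chains(matrix(0, 200, 8), rep(0.5, 200), y, cv)
  d <- derived_occupancy(ch)
  expect_equal(d$mean_occupancy, 0.5)
  expect_equal(d$sd_occupancy, 0)
  expect_equal(unname(d$conditional[1]), 1)
  # psi = 0.5, p = 0.5, J = 3: 0.5*(0.125)/(0.5*0.125 + 0.5) = 1/9
  expect_equal(unname(d$conditional[2]), 1 / 9, tolerance = 1e-12)
  # covariate mismatch is rejected
  cv_bad <- tiny_covariates(2)
  cv_bad$road <- cv_bad$road + 1
  expect_error(derived_occupancy(ch, cv_bad), "do not match")
})
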