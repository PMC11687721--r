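# synthetic_data module

test_that("simulate_landscape hits the requested covariate moments", {
  sites <- simulate_landscape(154, seed = 1)
  # canopy sample mean within 3 standard errors of the target mean
  sem <- 21.36 / sqrt(154)
  expect_lt(abs(mean(sites$canopy) - 42.19), 3 * sem)
  expect_true(all(sites$canopy >= 0 & sites$canopy <= 100))
  expect_true(all(sites$humans >= 0))
  expect_true(all(sites$road_dist >= 0 & is.finite(sites$road_dist)))
  expect_true(all(sites$predator_rate >= 0 & sites$predator_rate <= 1))
  expect_false(any(duplicated(sites$site_id)))
})

test_that("degenerate SD = 0 moments put every covariate at its mean", {
  m <- list(canopy = list(dist = "truncnorm", mean = 40, sd = 0,
                          lower = 0, upper = 100),
            humans = list(dist = "negbin", mean = 10, sd = 0),
            livestock = list(dist = "negbin", mean = 5, sd = 0),
            farmland = list(dist = "lognormal", mean = 1e5, sd = 0),
            road_dist = list(dist = "truncnorm", mean = 700, sd = 0,
                             lower = 0, upper = Inf),
            settlement_dist = list(dist = "truncnorm", mean = 2000, sd = 0,
                                   lower = 0, upper = Inf),
            predator_rate = list(dist = "beta", mean = 0.15, sd = 0))
  s <- simulate_landscape(2, seed = 3, moments = m)
  expect_equal(s$canopy, c(40, 40))
  expect_equal(s$humans, c(10, 10))
  expect_equal(s$farmland, c(1e5, 1e5))
  expect_equal(s$road_dist, c(700, 700))
  expect_equal(s$predator_rate, c(0.15, 0.15))
})

test_that("large-sample moments match targets and an independent re-draw", {
  n <- 5000
  sites <- simulate_landscape(n, seed = 7)
  # humans: negative binomial, mean 76.72 SD 244.55
  expect_lt(abs(mean(sites$humans) - 76.72) / 76.72, 0.05)
  expect_lt(abs(sd(sites$humans) - 244.55) / 244.55, 0.05)
  # independent oracle: Poisson-gamma mixture representation of the same
  # negative binomial, drawn with a separate generator path
  set.seed(99)
  size <- 76.72^2 / (244.55^2 - 76.72)
  oracle <- rpois(n, rgamma(n, shape = size, rate = size / 76.72))
  expect_lt(abs(mean(oracle) - mean(sites$humans)) / 76.72, 0.1)
  expect_lt(abs(sd(oracle) - sd(sites$humans)) / 244.55, 0.1)
  # settlement distance: truncated normal with feasible CV
  expect_lt(abs(mean(sites$settlement_dist) - 2182.80) / 2182.80, 0.05)
  expect_lt(abs(sd(sites$settlement_dist) - 1691.33) / 1691.33, 0.05)
  # road distance: CV > 1 is infeasible for a zero-truncated normal, so the
  # generator falls back to a moment-matched log-normal
  expect_lt(abs(mean(sites$road_dist) - 741.69) / 741.69, 0.05)
  expect_lt(abs(sd(sites$road_dist) - 1138.91) / 1138.91, 0.1)
})

test_that("simulate_landscape validates its inputs", {
  expect_error(simulate_landscape(1, seed = 1), "n_sites")
  m <- occu_default_moments()
  m$canopy$sd <- -1
  expect_error(simulate_landscape(10, seed = 1, moments = m), "negative SD")
})

test_that("generator is bit-reproducible and respects site separation", {
  a <- simulate_landscape(60, seed = 11)
  b <- simulate_landscape(60, seed = 11)
  expect_identical(a, b)
  d <- as.matrix(dist(cbind(a$x, a$y)))
  diag(d) <- Inf
  expect_gte(min(d), 1000)
})

test_that("simulate_truth evaluates the linear predictor exactly", {
  sites <- simulate_landscape(10, seed = 2)
  t0 <- simulate_truth(sites, beta = rep(0, 8), p = 0.3, seed = 1)
  expect_equal(t0$psi_true, rep(0.5, 10))
  t1 <- simulate_truth(sites, beta = c(-0.5, rep(0, 7)), p = 0.3, seed = 1)
  expect_equal(t1$psi_true, rep(plogis(-0.5), 10), tolerance = 1e-12)
  expect_equal(unique(round(t1$psi_true, 4)), 0.3775)
})

test_that("a unit-slope covariate moves psi to logit^-1(+/-1)", {
  sites <- simulate_landscape(3, seed = 5)
  # canopy (20, 40, 30) standardizes exactly to (-1, +1, 0)
  sites$canopy <- c(20, 40, 30)
  beta <- c(0, 0, 0, 0, 0, -1, 0, 0)   # beta_canopycover = -1
  tr <- simulate_truth(sites, beta, p = 0.3, seed = 1)
  expect_equal(tr$psi_true[1:2], plogis(c(1, -1)), tolerance = 1e-12)
  expect_equal(tr$psi_true[3], 0.5, tolerance = 1e-12)
})

test_that("simulate_truth rejects a wrong-length beta with the order", {
  sites <- simulate_landscape(4, seed = 2)
  expect_error(simulate_truth(sites, beta = rep(0, 5), p = 0.3, seed = 1),
               "settlement, livestock, predators")
})

test_that("unoccupied sites never yield focal records", {
  sites <- simulate_landscape(30, seed = 4)
  tr <- simulate_truth(sites, beta = c(-20, rep(0, 7)), p = 0.5, seed = 2)
  expect_true(all(tr$z_true == 0))
  sim <- simulate_records(tr, n_days = 21, seed = 3)
  expect_false(any(sim$records$species == "porcupine"))
})

test_that("near-certain detection fills every occasion at occupied sites", {
  sites <- simulate_landscape(15, seed = 6)
  tr <- simulate_truth(sites, beta = c(20, rep(0, 7)), p = 1 - 1e-9,
                       seed = 2)
  expect_true(all(tr$z_true == 1))
  sim <- simulate_records(tr, n_days = 21, seed = 3)
  daily <- build_daily_matrix(sim$records, sim$deployments, "porcupine")
  occ <- collapse_occasions(daily, 7)
  expect_true(all(occ == 1L))
})

test_that("occasion-level detection frequency converges to p_true", {
  sites <- simulate_landscape(400, seed = 8)
  tr <- simulate_truth(sites, beta = c(20, rep(0, 7)), p = 0.3, seed = 2)
  sim <- simulate_records(tr, n_days = 21, seed = 3)
  daily <- build_daily_matrix(sim$records, sim$deployments, "porcupine")
  occ <- collapse_occasions(daily, 7)
  n_trials <- sum(!is.na(occ))          # 1200 occupied site-occasions
  freq <- sum(occ == 1L, na.rm = TRUE) / n_trials
  se <- sqrt(0.3 * 0.7 / n_trials)
  expect_lt(abs(freq - 0.3), 3 * se)
})

test_that("occupied fraction converges to mean psi (binomial tolerance)", {
  sites <- simulate_landscape(2000, seed = 9)
  tr <- simulate_truth(sites, beta = c(-0.75, 0, 0, 0, 1.5, -1, 0, 0),
                       p = 0.3, seed = 4)
  se <- sqrt(mean(tr$psi_true) * (1 - mean(tr$psi_true)) / nrow(tr))
  expect_lt(abs(mean(tr$z_true) - mean(tr$psi_true)), 3.5 * se)
})

test_that("survey CSVs round-trip with ISO dates", {
  sim <- simulate_survey(n_sites = 12, n_days = 7, seed = 5)
  dir <- withr::local_tempdir()
  write_survey_csvs(sim, dir)
  back <- read_survey_csvs(dir)
  expect_identical(back$deployments$start_date, sim$deployments$start_date)
  expect_identical(back$records$date, sim$records$date)
  expect_equal(back$sites$canopy, sim$sites$canopy)
})
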