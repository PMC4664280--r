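test_that("equal-tail interval follows the linear-interpolation quantile rule", {
  ci <- equal_tail_interval(1:1000)
  expect_equal(unname(ci), c(25.975, 975.025))
  expect_equal(unname(equal_tail_interval(rep(3.2, 10))), c(3.2, 3.2))
  set.seed(8)
  x <- rnorm(20000)
  ci2 <- equal_tail_interval(c(x, -x)) # exactly symmetric draws
  expect_equal(ci2[["lower"]], -ci2[["upper"]], tolerance = 1e-10)
  ci80 <- equal_tail_interval(1:1000, level = 0.8)
  expect_equal(unname(ci80), unname(quantile(1:1000, c(0.1, 0.9), type = 7)))
  expect_error(equal_tail_interval(numeric(0)), "2 draws")
})

test_that("Gelman-Rubin statistic matches an independent reference", {
  set.seed(12)
  chains <- list(rnorm(400, 0, 1), rnorm(400, 0.3, 1.4), rnorm(400, -0.2, 0.8))
  expect_equal(gelman_rubin(chains), oracle_gelman_rubin(chains),
               tolerance = 1e-12)
  # i.i.d. same-distribution chains are close to 1
  for (s in 1:5) {
    set.seed(100 + s)
    iid <- replicate(3, rnorm(2500), simplify = FALSE)
    expect_gte(gelman_rubin(iid), 0.99)
    expect_lte(gelman_rubin(iid), 1.03)
  }
  # grossly separated chains
  expect_gt(gelman_rubin(list(rnorm(200, 0, 1), rnorm(200, 10, 1))), 3)
  # degenerate chains: 1 by convention
  expect_identical(gelman_rubin(list(rep(2, 50), rep(2, 50))), 1.0)
  # chain order is irrelevant
  expect_equal(gelman_rubin(chains), gelman_rubin(rev(chains)), tolerance = 1e-14)
  expect_error(gelman_rubin(list(rnorm(10))), "2 chains")
  expect_error(gelman_rubin(list(rnorm(10), rnorm(11))), "equal lengths")
})

test_that("fits are deterministic given a seed and retain the right draw count", {
  sim <- simulate_baci(baci_condition("single", n_units = 8, n_plots = 4),
                       seed = 9)
  f1 <- occu_fit(sim$data, "single", chains = 2, n_iter = 500, burnin = 200,
                 thin = 3, seed = 42)
  f2 <- occu_fit(sim$data, "single", chains = 2, n_iter = 500, burnin = 200,
                 thin = 3, seed = 42)
  expect_identical(f1$draws, f2$draws)
  expect_identical(nrow(f1$draws[[1]]), (500L - 200L) %/% 3L)
  # interval ordering invariant
  expect_true(all(f1$summary$lower <= f1$summary$median + 1e-12))
  expect_true(all(f1$summary$median <= f1$summary$upper + 1e-12))
  # multi-scale determinism
  simm <- simulate_baci(baci_condition("multi", n_units = 8, n_plots = 4),
                        seed = 10)
  m1 <- occu_fit(simm$data, "multi", chains = 2, n_iter = 500, burnin = 200,
                 thin = 2, seed = 7)
  m2 <- occu_fit(simm$data, "multi", chains = 2, n_iter = 500, burnin = 200,
                 thin = 2, seed = 7)
  expect_identical(m1$draws, m2$draws)
})

test_that("datasets with zero observed visits are rejected", {
  y <- array(NA_integer_, dim = c(2, 2, 2, 2))
  expect_error(occu_data(y), "zero non-missing")
})

test_that("uninformative data reproduce the prior on occupancy parameters", {
  # detection pinned at ~0, all histories zero: the likelihood is flat in the
  # occupancy block, so the posterior must return the prior
  y <- array(0L, dim = c(4, 2, 3, 2))
  d <- occu_data(y, treatment = c(0L, 0L, 1L, 1L), year_after = c(0L, 1L))
  fit <- occu_fit(d, "single", chains = 2, n_iter = 22000, burnin = 2000,
                  thin = 4, seed = 5,
                  fixed = list(gamma = -50, b0 = 0, sigma_b = 1))
  draws <- as.matrix(fit)[, "beta0"]
  expect_lt(abs(mean(draws)), 0.12)                  # prior mean 0
  expect_lt(abs(sd(draws) - sqrt(3)) / sqrt(3), 0.1) # prior SD sqrt(3)
  ks <- suppressWarnings(ks.test(draws[seq(1, length(draws), by = 40)],
                                 "pnorm", 0, sqrt(3)))
  expect_gt(ks$p.value, 0.01)
})

test_that("posterior for a one-parameter model matches numeric quadrature", {
  # one unit-year, 25 plots, single visit, detection fixed at 0.6, no random
  # effects: only the occupancy intercept is sampled
  set.seed(14)
  K <- 25
  u <- rbinom(K, 1, plogis(0.4))
  y <- array(as.integer(rbinom(K, 1, u * 0.6)), dim = c(1, 1, K, 1))
  d <- occu_data(y, treatment = 0L, year_after = 0L)
  lp <- qlogis(0.6)
  fit <- occu_fit(d, "single", chains = 3, n_iter = 22000, burnin = 2000,
                  thin = 2, seed = 15,
                  fixed = list(beta = c(NA, 0, 0, 0), gamma = lp,
                               b0 = 0, sigma_b = 1))
  draws <- as.matrix(fit)[, "beta0"]
  # quadrature oracle on a fine grid
  grid <- seq(-9, 9, length.out = 4001)
  loglik <- vapply(grid, function(b)
    loglik_single_scale(d, list(beta = c(b, 0, 0, 0), b0 = 0, gamma = lp)), 0)
  lpost <- loglik + dnorm(grid, 0, sqrt(3), log = TRUE)
  w <- exp(lpost - max(lpost)); w <- w / sum(w)
  qmean <- sum(w * grid)
  qsd <- sqrt(sum(w * (grid - qmean)^2))
  mcse <- qsd / sqrt(length(draws) / 20) # conservative ESS guess
  expect_lt(abs(mean(draws) - qmean), 3 * mcse)
  expect_lt(abs(sd(draws) - qsd) / qsd, 0.05)
})

test_that("the sampler recovers generating parameters on a large dataset", {
  cond <- baci_condition("single", n_units = 100, n_plots = 7, p_detect = 0.5,
                         post_plot_occ = 0.3, sigma_b_true = 1)
  sim <- simulate_baci(cond, seed = 17)
  fit <- occu_fit(sim$data, "single", chains = 2, n_iter = 4000, burnin = 2000,
                  thin = 1, seed = 18)
  truth <- c(sim$truth$beta, sim$truth$gamma)
  est <- fit$summary[match(c("beta0", "beta1", "beta2", "beta3", "gamma0"),
                           fit$summary$parameter), ]
  expect_true(all(abs(est$mean - truth) < 3 * est$sd))
  expect_true(all(fit$rhat < 1.1))
})
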