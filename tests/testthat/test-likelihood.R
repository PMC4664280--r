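test_that("detection history log-likelihood handles boundaries and missingness", {
  expect_identical(detection_history_loglik(1, 1.0), 0)
  expect_equal(detection_history_loglik(c(0, 0, 0), rep(0.5, 3)), 3 * log(0.5))
  expect_equal(detection_history_loglik(c(1, 0, NA), rep(0.3, 3)),
               log(0.3) + log(0.7))
  expect_identical(detection_history_loglik(c(NA, NA), c(0.4, 0.4)), 0)
  expect_identical(detection_history_loglik(1, 0), -Inf)
  expect_error(detection_history_loglik(c(1, 0), 0.5), "same length")
  expect_error(detection_history_loglik(2, 0.5), "0, 1 or NA")
})

test_that("single-scale marginal log-likelihood matches trivial closed forms", {
  y1 <- array(1L, dim = c(1, 1, 1, 1))
  d1 <- occu_data(y1, treatment = 0, year_after = 0)
  # psi = 0.5, p = 1: must be occupied, detected with certainty
  expect_equal(loglik_single_scale(d1, list(beta = c(0, 0, 0, 0), b0 = 0,
                                            p_detect = 1)),
               log(0.5))
  # psi = 1, p = 1, all detections: probability-1 event
  yall <- array(1L, dim = c(2, 2, 2, 2))
  dall <- occu_data(yall, treatment = c(0, 1), year_after = c(0, 1))
  expect_equal(loglik_single_scale(dall, list(beta = c(50, 0, 0, 0),
                                              b0 = c(0, 0), p_detect = 1)),
               0)
  # impossible event: detection with p = 0
  expect_identical(loglik_single_scale(d1, list(beta = c(0, 0, 0, 0), b0 = 0,
                                                p_detect = 0)),
                   -Inf)
})

test_that("single-scale marginal log-likelihood equals brute-force enumeration", {
  set.seed(421)
  for (r in 1:30) {
    pr <- random_single_problem()
    d <- occu_data(pr$y, treatment = pr$treatment, year_after = pr$year_after)
    got <- loglik_single_scale(d, list(beta = pr$beta, gamma = pr$gamma,
                                       b0 = pr$b0))
    arr <- single_prob_arrays(pr)
    expect_equal(got, oracle_loglik_single(pr$y, arr$psi, arr$p),
                 tolerance = 1e-10)
  }
})

test_that("multi-scale marginal log-likelihood equals brute-force enumeration", {
  set.seed(99)
  for (r in 1:30) {
    I <- 2L; J <- 2L; K <- 2L; L <- 2L
    y <- array(rbinom(I * J * K * L, 1, 0.35), dim = c(I, J, K, L))
    if (r %% 3 == 0) y[sample(length(y), 2)] <- NA
    alpha <- rnorm(4, 0, 1.2); a0 <- rnorm(I, 0, 0.8)
    psi <- runif(1, 0.2, 0.8); p <- runif(1, 0.2, 0.8)
    d <- occu_data(y, treatment = c(0L, 1L), year_after = c(0L, 1L))
    got <- loglik_multi_scale(d, list(alpha = alpha, a0 = a0,
                                      psi_plot = psi, p_detect = p))
    theta <- array(0, dim = c(I, J))
    for (i in 1:I) for (j in 1:J)
      theta[i, j] <- plogis(alpha[1] + a0[i] + alpha[2] * (j == 2) +
                              alpha[3] * (i == 2) + alpha[4] * (i == 2) * (j == 2))
    expect_equal(got, oracle_loglik_multi(y, theta, psi, p), tolerance = 1e-10)
  }
})

test_that("multi-scale likelihood with certain unit occupancy reduces to single-scale", {
  set.seed(7)
  y <- array(rbinom(24, 1, 0.4), dim = c(2, 2, 3, 2))
  d <- occu_data(y, treatment = c(0L, 1L), year_after = c(0L, 1L))
  psi <- 0.45; p <- 0.6
  got_multi <- loglik_multi_scale(d, list(alpha = c(60, 0, 0, 0), a0 = c(0, 0),
                                          psi_plot = psi, p_detect = p))
  got_single <- loglik_single_scale(d, list(beta = c(qlogis(psi), 0, 0, 0),
                                            b0 = c(0, 0), p_detect = p))
  expect_equal(got_multi, got_single, tolerance = 1e-12)
  # unoccupied unit level, no detections: probability 1
  y0 <- array(0L, dim = c(1, 1, 2, 2))
  d0 <- occu_data(y0, treatment = 0, year_after = 0)
  expect_equal(loglik_multi_scale(d0, list(alpha = c(-60, 0, 0, 0), a0 = 0,
                                           psi_plot = 0.5, p_detect = 0.3)),
               0, tolerance = 1e-12)
})

test_that("likelihood is additive over units and invariant to unit permutation", {
  set.seed(55)
  pr <- random_single_problem()
  d <- occu_data(pr$y, treatment = pr$treatment, year_after = pr$year_after)
  full <- loglik_single_scale(d, list(beta = pr$beta, gamma = pr$gamma, b0 = pr$b0))
  # per-unit pieces (treatment covariate carried along with each unit)
  parts <- sapply(1:2, function(i) {
    di <- occu_data(pr$y[i, , , , drop = FALSE], treatment = pr$treatment[i],
                    year_after = pr$year_after)
    loglik_single_scale(di, list(beta = pr$beta, gamma = pr$gamma, b0 = pr$b0[i]))
  })
  expect_equal(full, sum(parts), tolerance = 1e-12)
  # permute units
  perm <- c(2, 1)
  dp <- occu_data(pr$y[perm, , , ], treatment = pr$treatment[perm],
                  year_after = pr$year_after)
  expect_equal(loglik_single_scale(dp, list(beta = pr$beta, gamma = pr$gamma,
                                            b0 = pr$b0[perm])),
               full, tolerance = 1e-12)
})

test_that("all-zero history likelihood decreases in detection and occupancy", {
  y <- array(0L, dim = c(1, 1, 1, 3))
  d <- occu_data(y, treatment = 0, year_after = 0)
  ll_at <- function(psi, p)
    loglik_single_scale(d, list(beta = c(qlogis(psi), 0, 0, 0), b0 = 0,
                                p_detect = p))
  ps <- seq(0.05, 0.95, by = 0.1)
  ll_p <- sapply(ps, function(p) ll_at(0.5, p))
  ll_psi <- sapply(ps, function(psi) ll_at(psi, 0.5))
  expect_true(all(diff(ll_p) < 0))
  expect_true(all(diff(ll_psi) < 0))
})

test_that("log prior matches reference density computations", {
  # closed form at zero fixed effects, sigma_b = 1, no intercepts
  expect_equal(log_prior(list(beta = c(0, 0, 0, 0), gamma = 0, sigma_b = 1),
                         "default"),
               dnorm(0, 0, sqrt(3), log = TRUE) * 2 +
                 3 * dnorm(0, 0, sqrt(4), log = TRUE) +
                 dgamma(1, 2, rate = 1, log = TRUE))
  # fixture vector against stats:: densities
  set.seed(31)
  pars <- list(beta = rnorm(4), gamma = rnorm(4), b0 = rnorm(5), sigma_b = 0.8)
  expected <- dnorm(pars$beta[1], 0, sqrt(3), log = TRUE) +
    sum(dnorm(pars$beta[2:4], 0, sqrt(4), log = TRUE)) +
    dnorm(pars$gamma[1], 0, sqrt(3), log = TRUE) +
    sum(dnorm(pars$gamma[2:4], 0, sqrt(4), log = TRUE)) +
    dgamma(pars$sigma_b, shape = 2, rate = 1, log = TRUE) +
    sum(dnorm(pars$b0, 0, pars$sigma_b, log = TRUE))
  expect_equal(log_prior(pars, "default"), expected, tolerance = 1e-10)
  # default vs relaxed differ only in the covariate terms
  diff_lp <- log_prior(pars, "relaxed") - log_prior(pars, "default")
  cov_terms <- sum(dnorm(c(pars$beta[2:4], pars$gamma[2:4]), 0, sqrt(10), log = TRUE)) -
    sum(dnorm(c(pars$beta[2:4], pars$gamma[2:4]), 0, sqrt(4), log = TRUE))
  expect_equal(diff_lp, cov_terms, tolerance = 1e-10)
  # invalid sigma
  expect_identical(log_prior(list(beta = 0, sigma_b = -1)), -Inf)
})
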