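test_that("condition grid enumerates the full factorial design", {
  expect_length(condition_grid("single"), 90)
  expect_length(condition_grid("multi"), 90)
  expect_length(condition_grid("single", n_units = 20), 18)
  # deterministic ordering: same call twice yields identical conditions
  g1 <- condition_grid("multi"); g2 <- condition_grid("multi")
  expect_identical(study_fields <- lapply(g1, unclass), lapply(g2, unclass))
  # levels present
  ps <- sapply(g1, function(cd) cd$p_detect)
  expect_setequal(unique(ps), c(0.15, 0.3, 0.5))
  expect_setequal(unique(sapply(g1, `[[`, "post_stand_occ")), c(0.3, 0.6))
})

test_that("condition probabilities map to logit-scale coefficients", {
  p1 <- params_from_condition(baci_condition("single", pre_plot_occ = 0.7,
                                             post_plot_occ = 0.1))
  expect_equal(p1$effect, qlogis(0.1) - qlogis(0.7), tolerance = 1e-12)
  expect_equal(p1$beta, c(qlogis(0.7), 0, 0, p1$effect))
  p2 <- params_from_condition(baci_condition("multi", pre_stand_occ = 0.95,
                                             post_stand_occ = 0.6))
  expect_equal(p2$effect, qlogis(0.6) - qlogis(0.95), tolerance = 1e-12)
  # null effect when post equals pre
  p3 <- params_from_condition(baci_condition("single", post_plot_occ = 0.7))
  expect_identical(p3$effect, 0)
  # degenerate occupancy has no logit
  expect_error(params_from_condition(
    baci_condition("single", pre_plot_occ = 1, post_plot_occ = 0.5)),
    "no logit")
  expect_error(baci_condition("single", n_units = 21), "even")
})

test_that("simulated BACI data are reproducible and respect the design", {
  cond <- baci_condition("single", n_units = 12, n_plots = 5, p_detect = 0.4,
                         seed = 77)
  s1 <- simulate_baci(cond)
  s2 <- simulate_baci(cond)
  expect_identical(s1$data$detections, s2$data$detections)
  expect_identical(s1$latent$u, s2$latent$u)
  # even treatment split, two years
  expect_identical(sum(s1$data$treatment), 6L)
  expect_identical(s1$data$year_after, c(0L, 1L))
  # no removal missingness in the simulation design
  expect_false(anyNA(s1$data$detections))
})

test_that("degenerate probabilities give all-1 detections", {
  cond <- baci_condition("single", n_units = 4, n_plots = 3,
                         pre_plot_occ = 1, post_plot_occ = 1, p_detect = 1)
  s <- simulate_baci(cond, seed = 5)
  expect_true(all(s$data$detections == 1L))
})

test_that("detection frequencies match psi * p without unit heterogeneity", {
  cond <- baci_condition("single", n_units = 500, n_plots = 10,
                         pre_plot_occ = 0.7, post_plot_occ = 0.7,
                         p_detect = 0.4, sigma_b_true = 0)
  s <- simulate_baci(cond, seed = 11)
  n <- length(s$data$detections)
  phat <- mean(s$data$detections)
  p0 <- 0.7 * 0.4
  expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / n))
  # occupancy frequency itself
  uhat <- mean(s$latent$u)
  expect_lt(abs(uhat - 0.7), 3 * sqrt(0.7 * 0.3 / length(s$latent$u)))
})

test_that("multi-scale latent states are nested", {
  cond <- baci_condition("multi", n_units = 40, n_plots = 7, p_detect = 0.5,
                         post_stand_occ = 0.3)
  s <- simulate_baci(cond, seed = 13)
  for (i in seq_len(40)) for (j in 1:2) {
    if (s$latent$z[i, j] == 0) {
      expect_true(all(s$latent$u[i, j, ] == 0L))
      expect_true(all(s$data$detections[i, j, , ] == 0L))
    }
  }
  # unit-level occupancy frequency in the control arm tracks 0.95
  ctrl <- s$data$treatment == 0
  zf <- mean(s$latent$z[ctrl, ])
  expect_lt(abs(zf - 0.95), 4 * sqrt(0.95 * 0.05 / sum(ctrl) / 2) + 0.05)
})

test_that("removal rule stops visits only after both species are seen", {
  # both species certain to be present and detected: only visit 1 realized
  sure <- list(beta = c(50, 0, 0, 0), gamma = c(50, 0, 0, 0), sigma_b = 0)
  s <- simulate_empirical_like(n_units = 4, n_plots = 3,
                               species = list(a = sure, b = sure), seed = 2)
  y <- s$a$data$detections
  expect_true(all(y[, , , 1] == 1L))
  expect_true(all(is.na(y[, , , 2:3])))
  # one species absent everywhere: the "both species" rule never triggers
  none <- list(beta = c(-50, 0, 0, 0), gamma = c(0, 0, 0, 0), sigma_b = 0)
  s2 <- simulate_empirical_like(n_units = 4, n_plots = 3,
                                species = list(a = sure, b = none), seed = 3)
  expect_false(anyNA(s2$a$data$detections))
  expect_false(anyNA(s2$b$data$detections))
})

test_that("empirical-like data have monotone missingness and valid structure", {
  s <- simulate_empirical_like(n_units = 10, seed = 21)
  for (sp in s) {
    y <- sp$data$detections
    mono <- apply(y, c(1, 2, 3), function(h) !any(diff(is.na(h)) < 0))
    expect_true(all(mono))
    # latent invariant: unoccupied plots yield no detections
    det_somewhere <- apply(y, c(1, 2, 3), function(h) any(h == 1, na.rm = TRUE))
    expect_true(all(sp$truth$u[det_somewhere] == 1L))
  }
  # 66 units x 2 years x 7 plots -> 924 rows in the table dialect
  s66 <- simulate_empirical_like(n_units = 66, seed = 4)
  expect_identical(nrow(s66$sp1$table), 924L)
})

test_that("the CSV dialect round-trips through writer and reader", {
  s <- simulate_empirical_like(n_units = 6, seed = 31)
  path <- withr::local_tempfile(fileext = ".csv")
  write_empirical_csv(s$sp1$data, path)
  suppressMessages(tab <- read_empirical(path))
  orig <- s$sp1$table
  expect_equal(tab$cwd, orig$cwd)
  for (l in 1:3) {
    expect_equal(tab[[paste0("y", l)]], orig[[paste0("y", l)]])
    expect_equal(tab[[paste0("jd", l)]], orig[[paste0("jd", l)]])
  }
  # and back into an identical detection array
  d2 <- suppressMessages(standardize_covariates(tab))$data
  expect_identical(d2$detections, s$sp1$data$detections)
  expect_identical(d2$block, s$sp1$data$block)
})

test_that("malformed detection files are rejected with located errors", {
  s <- simulate_empirical_like(n_units = 4, seed = 41)
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- s$sp1$table
  tab$y2[5] <- 2
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  expect_error(suppressMessages(read_empirical(path)), "row 5")
  tab <- s$sp1$table
  names(tab)[names(tab) == "cwd"] <- "woody"
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  expect_error(suppressMessages(read_empirical(path)), "cwd")
  # column map adapts foreign headers
  suppressMessages(tab2 <- read_empirical(path, column_map = list(cwd = "woody")))
  expect_equal(tab2$cwd, s$sp1$table$cwd)
})
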