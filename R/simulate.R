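#' A single BACI simulation condition
#'
#' One cell of the factorial simulation design: a number of harvest units
#' (split evenly between control and impact arms, followed for a "before"
#' and an "after" year), plots per unit (re-drawn each year, so plots are
#' independent across years), visits per plot, the occupancy probabilities
#' before and after treatment, the per-visit detection probability and the
#' unit random-intercept SD on the logit scale.
#'
#' For the single-scale process the occupancy probabilities are plot-level;
#' for the multi-scale process the pre/post probabilities are unit-level
#' (`pre_stand_occ`, `post_stand_occ`) and plot occupancy conditional on
#' unit occupancy is the constant `pre_plot_occ`.
#'
#' @param model_kind `"single"` or `"multi"`.
#' @param n_units even number of harvest units.
#' @param n_plots plots per unit per year.
#' @param n_visits visits per plot.
#' @param pre_plot_occ,post_plot_occ plot-level occupancy before/after
#'   treatment (single-scale; for multi-scale `pre_plot_occ` is the constant
#'   conditional plot occupancy).
#' @param pre_stand_occ,post_stand_occ unit-level occupancy before/after
#'   treatment (multi-scale only).
#' @param p_detect per-visit detection probability.
#' @param sigma_b_true random-intercept SD used to generate data.
#' @param seed optional integer seed stored with the condition.
#' @return An object of class `baci_condition`.
#' @examples
#' baci_condition("single", n_units = 20, n_plots = 7, p_detect = 0.3)
#' @export
baci_condition <- function(model_kind = c("single", "multi"), n_units = 20,
                           n_plots = 7, n_visits = 3,
                           pre_plot_occ = if (model_kind == "single") 0.7 else 0.5,
                           post_plot_occ = if (model_kind == "single") 0.1 else pre_plot_occ,
                           pre_stand_occ = 0.95, post_stand_occ = 0.3,
                           p_detect = 0.3, sigma_b_true = 1, seed = NULL) {
  model_kind <- match.arg(model_kind)
  if (n_units %% 2 != 0) stop("'n_units' must be even (two equal arms)")
  probs <- c(pre_plot_occ, post_plot_occ, p_detect,
             if (model_kind == "multi") c(pre_stand_occ, post_stand_occ))
  if (any(probs <= 0 | probs > 1)) stop("probabilities must lie in (0, 1]")
  if (sigma_b_true < 0) stop("'sigma_b_true' must be non-negative")
  structure(list(model_kind = model_kind, n_units = as.integer(n_units),
                 n_plots = as.integer(n_plots), n_visits = as.integer(n_visits),
                 pre_plot_occ = pre_plot_occ, post_plot_occ = post_plot_occ,
                 pre_stand_occ = if (model_kind == "multi") pre_stand_occ else NA,
                 post_stand_occ = if (model_kind == "multi") post_stand_occ else NA,
                 p_detect = p_detect, sigma_b_true = sigma_b_true, seed = seed),
            class = "baci_condition")
}

#' @export
print.baci_condition <- function(x, ...) {
  cat(sprintf("BACI condition (%s-scale): %d units, %d plots, %d visits\n",
              x$model_kind, x$n_units, x$n_plots, x$n_visits))
  if (x$model_kind == "single")
    cat(sprintf("  plot occupancy %.2f -> %.2f, detection %.2f, sigma_b %.2f\n",
                x$pre_plot_occ, x$post_plot_occ, x$p_detect, x$sigma_b_true))
  else
    cat(sprintf("  stand occupancy %.2f -> %.2f, plot occupancy %.2f, detection %.2f, sigma_b %.2f\n",
                x$pre_stand_occ, x$post_stand_occ, x$pre_plot_occ, x$p_detect,
                x$sigma_b_true))
  invisible(x)
}

#' Full factorial grid of simulation conditions
#'
#' The factorial design crosses unit counts (20-60), plots per unit
#' (5, 7, 9), two post-treatment occupancy levels and three detection
#' probabilities (0.15, 0.3, 0.5), with three visits per plot: 90 unique
#' conditions per model. Single-scale: plot occupancy 0.7 before, 0.1 or
#' 0.3 after. Multi-scale: unit occupancy 0.95 before, 0.3 or 0.6 after,
#' with constant conditional plot occupancy 0.5.
#'
#' @param model_kind `"single"` or `"multi"`.
#' @param n_units,n_plots,post_occ,p_detect optional restrictions of the
#'   factor levels (defaults: the full design).
#' @param sigma_b_true random-intercept SD for data generation.
#' @return A list of [baci_condition()] objects in deterministic order
#'   (units slowest, then plots, post occupancy, detection).
#' @examples
#' length(condition_grid("single"))           # 90
#' length(condition_grid("multi", n_units = 20)) # 18
#' @export
condition_grid <- function(model_kind = c("single", "multi"),
                           n_units = c(20, 30, 40, 50, 60),
                           n_plots = c(5, 7, 9),
                           post_occ = NULL,
                           p_detect = c(0.15, 0.3, 0.5),
                           sigma_b_true = 1) {
  model_kind <- match.arg(model_kind)
  if (is.null(post_occ))
    post_occ <- if (model_kind == "single") c(0.1, 0.3) else c(0.3, 0.6)
  g <- expand.grid(p = p_detect, post = post_occ, K = n_plots, N = n_units)
  lapply(seq_len(nrow(g)), function(r) {
    if (model_kind == "single")
      baci_condition("single", n_units = g$N[r], n_plots = g$K[r],
                     pre_plot_occ = 0.7, post_plot_occ = g$post[r],
                     p_detect = g$p[r], sigma_b_true = sigma_b_true)
    else
      baci_condition("multi", n_units = g$N[r], n_plots = g$K[r],
                     pre_plot_occ = 0.5, pre_stand_occ = 0.95,
                     post_stand_occ = g$post[r], p_detect = g$p[r],
                     sigma_b_true = sigma_b_true)
  })
}

#' Map a condition's probabilities to logit-scale model coefficients
#'
#' Convention: the intercept is the logit of the pre-treatment occupancy,
#' the year and treatment main effects are 0 (control occupancy constant
#' across years; arms identical before treatment), and the entire
#' treatment effect loads on the interaction:
#' `effect = logit(post) - logit(pre)`. Probabilities are interpreted
#' conditional on a random intercept of 0 (the median unit).
#'
#' @param cond a [baci_condition()].
#' @return For single-scale: list with `beta` (length 4), `gamma`
#'   (logit detection), `sigma_b`, `effect` (= `beta[4]`). For multi-scale:
#'   list with `alpha`, `lpsi`, `lp`, `sigma_b`, `effect` (= `alpha[4]`).
#' @examples
#' params_from_condition(baci_condition("single", post_plot_occ = 0.1))$effect
#' # logit(0.1) - logit(0.7)
#' @export
params_from_condition <- function(cond) {
  stopifnot(inherits(cond, "baci_condition"))
  lg <- function(p) {
    if (p <= 0 || p >= 1) stop("occupancy of exactly 0 or 1 has no logit")
    stats::qlogis(p)
  }
  if (cond$model_kind == "single") {
    b3 <- lg(cond$post_plot_occ) - lg(cond$pre_plot_occ)
    list(beta = c(lg(cond$pre_plot_occ), 0, 0, b3),
         gamma = stats::qlogis(cond$p_detect),
         sigma_b = cond$sigma_b_true, effect = b3)
  } else {
    a3 <- lg(cond$post_stand_occ) - lg(cond$pre_stand_occ)
    list(alpha = c(lg(cond$pre_stand_occ), 0, 0, a3),
         lpsi = lg(cond$pre_plot_occ), lp = stats::qlogis(cond$p_detect),
         sigma_b = cond$sigma_b_true, effect = a3)
  }
}

# occupancy probability with a logit-scale shift, tolerating degenerate
# boundary probabilities (0 stays 0, 1 stays 1 whatever the shift)
plogis_shift <- function(p, shift) {
  ifelse(p <= 0, 0, ifelse(p >= 1, 1, stats::plogis(stats::qlogis(p) + shift)))
}

#' Simulate one BACI dataset
#'
#' Draws unit random intercepts from Normal(0, `sigma_b_true`^2), latent
#' occupancy states per the condition's process, and full detection
#' histories (every visit realized: the simulation design does not apply a
#' removal rule). Units are split evenly into control and impact arms and
#' followed for a before and an after year; plots are drawn fresh each year.
#'
#' @param cond a [baci_condition()].
#' @param seed integer seed; defaults to the seed stored in `cond`.
#' @return List with `data` (an [occu_data()]), `latent` (list with plot
#'   occupancy array `u` and, for the multi-scale process, unit occupancy
#'   `z`), and `truth` (generating parameters from
#'   [params_from_condition()], or `NULL` when a boundary probability makes
#'   the logit mapping undefined).
#' @examples
#' sim <- simulate_baci(baci_condition("single", n_units = 4), seed = 42)
#' dim(sim$data$detections)
#' @export
simulate_baci <- function(cond, seed = cond$seed) {
  stopifnot(inherits(cond, "baci_condition"))
  if (!is.null(seed)) set.seed(seed)
  I <- cond$n_units; J <- 2L; K <- cond$n_plots; L <- cond$n_visits
  treatment <- rep(c(0L, 1L), each = I %/% 2)
  year_after <- c(0L, 1L)
  b0 <- stats::rnorm(I, 0, cond$sigma_b_true)
  u <- array(0L, dim = c(I, J, K))
  z <- NULL
  if (cond$model_kind == "single") {
    for (i in seq_len(I)) for (j in seq_len(J)) {
      pocc <- if (treatment[i] == 1L && year_after[j] == 1L)
        cond$post_plot_occ else cond$pre_plot_occ
      psi <- plogis_shift(pocc, b0[i])
      u[i, j, ] <- stats::rbinom(K, 1L, psi)
    }
  } else {
    z <- array(0L, dim = c(I, J))
    for (i in seq_len(I)) for (j in seq_len(J)) {
      socc <- if (treatment[i] == 1L && year_after[j] == 1L)
        cond$post_stand_occ else cond$pre_stand_occ
      theta <- plogis_shift(socc, b0[i])
      z[i, j] <- stats::rbinom(1L, 1L, theta)
      u[i, j, ] <- stats::rbinom(K, 1L, z[i, j] * cond$pre_plot_occ)
    }
  }
  y <- array(stats::rbinom(I * J * K * L, 1L,
                           rep(as.vector(u), times = L) * cond$p_detect),
             dim = c(I, J, K, L))
  truth <- tryCatch(params_from_condition(cond), error = function(e) NULL)
  if (!is.null(truth)) truth$b0 <- b0
  list(data = occu_data(y, treatment = treatment, year_after = year_after),
       latent = list(u = u, z = z), truth = truth)
}

#' Simulate a two-species plot-survey dataset with removal sampling
#'
#' Emulates a terrestrial salamander survey: harvest units in two blocks
#' followed for two years, a fresh set of plots per unit each year, up to
#' three timed visits per plot on a single day, a per-plot coarse woody
#' debris (CWD) count, and a removal rule under which visits stop in a plot
#' once *both* species have been detected there (later visits are missing
#' for both species). Occupancy follows the hierarchical single-scale model
#' with CWD, year and block effects; detection is a quadratic function of
#' the (standardized) Julian date plus a year effect.
#'
#' Species parameter defaults are plausible values for a pair of
#' plethodontid salamanders: one strongly associated with CWD and one
#' habitat generalist with lower detectability.
#'
#' @param n_units number of harvest units.
#' @param n_plots plots per unit per year.
#' @param n_visits maximum visits per plot.
#' @param n_block1 units in the first block (indicator 1); the rest are 0.
#' @param species named list of per-species parameter lists, each with
#'   `beta` (intercept, CWD, year, block on the logit-occupancy scale),
#'   `gamma` (intercept, JD, JD^2, year on the logit-detection scale;
#'   JD standardized) and `sigma_b`.
#' @param cwd_mean,cwd_size negative-binomial mean and dispersion for CWD
#'   counts.
#' @param jd_range inclusive day-of-year window for survey dates
#'   (April-June).
#' @param seed integer seed.
#' @return List with one element per species, each a list of `data` (an
#'   [occu_data()] with covariates and removal missingness), `truth` (the
#'   generating parameters, including the drawn random intercepts), and
#'   `table` (the dataset in the one-row-per-unit-plot-year CSV dialect of
#'   [write_empirical_csv()]).
#' @examples
#' sim <- simulate_empirical_like(n_units = 6, seed = 1)
#' names(sim)
#' @export
simulate_empirical_like <- function(n_units = 66, n_plots = 7, n_visits = 3,
                                    n_block1 = ceiling(n_units / 2),
                                    species = list(
                                      sp1 = list(beta = c(-0.3, 0.75, 0, 0.9),
                                                 gamma = c(-0.7, 0.2, -0.03, -0.6),
                                                 sigma_b = 0.75),
                                      sp2 = list(beta = c(0.5, 0, 2, -1.9),
                                                 gamma = c(-1.8, -0.2, 0.035, -0.6),
                                                 sigma_b = 0.75)),
                                    cwd_mean = 3, cwd_size = 1,
                                    jd_range = c(91, 181), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(species) >= 1, n_block1 <= n_units)
  for (sp in species)
    if (length(sp$beta) != 4 || length(sp$gamma) != 4 || sp$sigma_b < 0)
      stop("each species needs beta (4), gamma (4) and sigma_b >= 0")
  I <- n_units; J <- 2L; K <- n_plots; L <- n_visits
  block <- c(rep(1L, n_block1), rep(0L, I - n_block1))
  year_after <- c(0L, 1L)
  cwd <- array(stats::rnbinom(I * J * K, mu = cwd_mean, size = cwd_size),
               dim = c(I, J, K))
  # all visits to a plot happen on one day
  jd_day <- array(sample(seq(jd_range[1], jd_range[2]), I * J * K,
                         replace = TRUE), dim = c(I, J, K))
  jd <- array(rep(as.vector(jd_day), times = L), dim = c(I, J, K, L))
  cwd_std <- (cwd - mean(cwd)) / stats::sd(cwd)
  jd_std <- (jd_day - mean(jd_day)) / stats::sd(jd_day)

  dets <- lapply(species, function(sp) {
    b0 <- stats::rnorm(I, 0, sp$sigma_b)
    y <- array(0L, dim = c(I, J, K, L))
    u <- array(0L, dim = c(I, J, K))
    for (i in seq_len(I)) for (j in seq_len(J)) for (k in seq_len(K)) {
      psi <- stats::plogis(sp$beta[1] + b0[i] + sp$beta[2] * cwd_std[i, j, k] +
                             sp$beta[3] * year_after[j] + sp$beta[4] * block[i])
      u[i, j, k] <- stats::rbinom(1L, 1L, psi)
      x <- jd_std[i, j, k]
      p <- stats::plogis(sp$gamma[1] + sp$gamma[2] * x + sp$gamma[3] * x^2 +
                           sp$gamma[4] * year_after[j])
      y[i, j, k, ] <- stats::rbinom(L, 1L, u[i, j, k] * p)
    }
    list(y = y, u = u, b0 = b0)
  })

  # removal rule: visits stop once every species has been detected in the plot
  miss <- array(FALSE, dim = c(I, J, K, L))
  if (length(species) >= 2 && L > 1) {
    for (i in seq_len(I)) for (j in seq_len(J)) for (k in seq_len(K)) {
      seen <- rep(FALSE, length(species))
      stop_after <- NA_integer_
      for (l in seq_len(L)) {
        for (s in seq_along(species))
          if (dets[[s]]$y[i, j, k, l] == 1L) seen[s] <- TRUE
        if (all(seen)) { stop_after <- l; break }
      }
      if (!is.na(stop_after) && stop_after < L)
        miss[i, j, k, (stop_after + 1L):L] <- TRUE
    }
  }

  out <- lapply(seq_along(species), function(s) {
    y <- dets[[s]]$y
    y[miss] <- NA_integer_
    d <- occu_data(y, treatment = rep(0L, I), year_after = year_after,
                   cwd = cwd, julian_date = jd, block = block, removal = TRUE)
    truth <- species[[s]]
    truth$b0 <- dets[[s]]$b0
    truth$u <- dets[[s]]$u
    list(data = d, truth = truth, table = empirical_table_from_data(d))
  })
  names(out) <- names(species)
  out
}

# one row per (unit, year, plot): the CSV dialect shared by the writer,
# the reader and the fitting stage
empirical_table_from_data <- function(data) {
  I <- data$n_units; J <- data$n_years; K <- data$n_plots; L <- data$n_visits
  g <- expand.grid(plot_id = seq_len(K), year = seq_len(J), unit_id = seq_len(I))
  g <- g[, c("unit_id", "year", "plot_id")]
  tab <- data.frame(unit_id = g$unit_id,
                    block = data$block[g$unit_id],
                    year = 2012L + g$year,
                    plot_id = g$plot_id,
                    cwd = data$cwd[cbind(g$unit_id, g$year, g$plot_id)])
  for (l in seq_len(L))
    tab[[paste0("y", l)]] <- data$detections[cbind(g$unit_id, g$year, g$plot_id, l)]
  for (l in seq_len(L))
    tab[[paste0("jd", l)]] <- data$julian_date[cbind(g$unit_id, g$year, g$plot_id, l)]
  class(tab) <- c("empirical_table", "data.frame")
  tab
}

#' Write a plot-survey dataset in the one-row-per-plot-year CSV dialect
#'
#' Columns: `unit_id`, `block` (0/1), `year`, `plot_id`, `cwd`, detection
#' columns `y1..yL` (0/1, empty for missing visits) and Julian-date columns
#' `jd1..jdL`.
#'
#' @param x an [occu_data()] with `cwd`, `julian_date` and `block`, or an
#'   `empirical_table` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_empirical_csv <- function(x, path) {
  tab <- if (inherits(x, "occu_data")) empirical_table_from_data(x) else x
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
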