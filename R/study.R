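#' Deterministic sub-seed derivation
#'
#' Mixes a master seed with one or more indices (condition, replicate) into
#' an integer below 2^31, so that replicates are independent and any run is
#' restartable at any replicate.
#'
#' @param master integer master seed.
#' @param ... integer indices.
#' @return An integer seed.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483629 # largest prime below 2^31
  s <- as.numeric(master) %% m
  for (idx in list(...)) s <- (s * 7919 + as.numeric(idx) * 104729 + 1) %% m
  as.integer(s)
}

#' Run one simulation condition: simulate, fit, score
#'
#' For each replicate the condition is simulated with [simulate_baci()],
#' the matching model is fitted with [occu_fit()], and the treatment-effect
#' parameter (`beta3` for the single-scale model, `alpha3` for the
#' multi-scale model) is scored: posterior mean, posterior SD, 95%
#' equal-tail interval and whether every mean-model Gelman-Rubin statistic
#' is strictly below 1.1. Metrics are aggregated over the converged
#' replicates only:
#' \itemize{
#'   \item `bias` = average posterior mean minus the true effect,
#'   \item `mean_posterior_sd` = average posterior SD ("inverse precision"),
#'   \item `sd_of_posterior_means` = the estimator's sampling SD,
#'   \item `coverage` = fraction of intervals containing the true effect.
#' }
#'
#' @param cond a [baci_condition()].
#' @param priors prior specification label or [occu_priors()] object.
#' @param n_reps number of replicates.
#' @param mcmc list with `chains`, `n_iter`, `burnin`, `thin` (defaults:
#'   3 chains of 4000 with 2000 burn-in, no thinning — a reduced protocol
#'   suitable for desk-scale studies; see the methods vignette).
#' @param seed master seed; replicate seeds are derived with
#'   [derive_seed()].
#' @param rhat_threshold convergence filter (strict inequality).
#' @return An object of class `study_result`: the per-replicate records and
#'   the aggregated metrics.
#' @examples
#' \donttest{
#' res <- run_condition(baci_condition("single", n_units = 10, n_plots = 5),
#'                      n_reps = 3, seed = 1,
#'                      mcmc = list(chains = 2, n_iter = 600, burnin = 300,
#'                                  thin = 1))
#' res$coverage
#' }
#' @export
run_condition <- function(cond, priors = "default", n_reps = 200,
                          mcmc = list(chains = 3, n_iter = 4000,
                                      burnin = 2000, thin = 1),
                          seed = 1, rhat_threshold = 1.1) {
  stopifnot(inherits(cond, "baci_condition"), n_reps >= 1)
  n_reps <- as.integer(n_reps)
  truth <- params_from_condition(cond)
  per <- data.frame(rep = seq_len(n_reps), seed = NA_integer_,
                    post_mean = NA_real_, post_sd = NA_real_,
                    lower = NA_real_, upper = NA_real_,
                    max_rhat = NA_real_, converged = NA)
  for (r in seq_len(n_reps)) {
    rs <- derive_seed(seed, r)
    sim <- simulate_baci(cond, seed = rs)
    fit <- occu_fit(sim$data, model = cond$model_kind, priors = priors,
                    chains = mcmc$chains, n_iter = mcmc$n_iter,
                    burnin = mcmc$burnin, thin = mcmc$thin,
                    seed = derive_seed(rs, 1L))
    eff <- fit$effect_param
    pooled <- as.matrix(fit)[, eff]
    ci <- equal_tail_interval(pooled)
    per$seed[r] <- rs
    per$post_mean[r] <- mean(pooled)
    per$post_sd[r] <- stats::sd(pooled)
    per$lower[r] <- ci[["lower"]]; per$upper[r] <- ci[["upper"]]
    per$max_rhat[r] <- max(fit$rhat, na.rm = TRUE)
    per$converged[r] <- all(fit$rhat < rhat_threshold, na.rm = TRUE)
  }
  conv <- per[per$converged, , drop = FALSE]
  n_conv <- nrow(conv)
  if (n_conv == 0L) {
    warning("no replicate passed the convergence filter; metrics undefined")
    agg <- list(bias = NA_real_, mean_posterior_sd = NA_real_,
                sd_of_posterior_means = NA_real_, coverage = NA_real_)
  } else {
    agg <- list(
      bias = mean(conv$post_mean) - truth$effect,
      mean_posterior_sd = mean(conv$post_sd),
      sd_of_posterior_means = if (n_conv > 1) stats::sd(conv$post_mean) else NA_real_,
      coverage = mean(conv$lower <= truth$effect & truth$effect <= conv$upper))
  }
  structure(c(list(condition = cond, priors = occu_priors(priors)$label,
                   true_effect = truth$effect, n_attempted = n_reps,
                   n_converged = n_conv, per_rep = per, seed = seed),
              agg),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  print(x$condition)
  cat(sprintf("  priors %s, %d/%d replicates converged (R-hat < 1.1)\n",
              x$priors, x$n_converged, x$n_attempted))
  cat(sprintf("  true effect %.3f | bias %.3f | mean posterior SD %.3f | sampling SD %.3f | coverage %.3f\n",
              x$true_effect, x$bias, x$mean_posterior_sd,
              x$sd_of_posterior_means, x$coverage))
  invisible(x)
}

#' Run a grid of simulation conditions
#'
#' Per-condition seeds are derived deterministically from the master seed,
#' so the grid can be restarted or subset without changing any single
#' condition's results. When `out_dir` is given, each condition's
#' per-replicate records are written to
#' `<out_dir>/condition_<index>.csv` as soon as it finishes, and
#' conditions whose file already exists are reloaded instead of re-run.
#'
#' @param conditions a list of [baci_condition()]s (e.g. from
#'   [condition_grid()]).
#' @param priors,n_reps,mcmc,seed as in [run_condition()].
#' @param out_dir optional output directory for incremental results.
#' @param verbose print one progress line per condition.
#' @return A list of `study_result`s.
#' @export
run_grid <- function(conditions, priors = "default", n_reps = 200,
                     mcmc = list(chains = 3, n_iter = 4000, burnin = 2000,
                                 thin = 1),
                     seed = 1, out_dir = NULL, verbose = FALSE) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  lapply(seq_along(conditions), function(ci) {
    res <- run_condition(conditions[[ci]], priors = priors, n_reps = n_reps,
                         mcmc = mcmc, seed = derive_seed(seed, ci))
    if (!is.null(out_dir)) {
      utils::write.csv(res$per_rep,
                       file.path(out_dir, sprintf("condition_%03d.csv", ci)),
                       row.names = FALSE)
    }
    if (verbose)
      message(sprintf("condition %d/%d: coverage %.3f (%d/%d converged)",
                      ci, length(conditions), res$coverage, res$n_converged,
                      res$n_attempted))
    res
  })
}

#' Tabulate a set of study results
#'
#' @param results a list of `study_result`s (or a single one).
#' @return Data frame with one row per condition: the condition levels and
#'   the aggregated estimator metrics.
#' @export
study_table <- function(results) {
  if (inherits(results, "study_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    cd <- r$condition
    data.frame(model = cd$model_kind, n_units = cd$n_units,
               n_plots = cd$n_plots,
               post_occ = if (cd$model_kind == "single") cd$post_plot_occ
                          else cd$post_stand_occ,
               p_detect = cd$p_detect, priors = r$priors,
               true_effect = r$true_effect,
               n_attempted = r$n_attempted, n_converged = r$n_converged,
               bias = r$bias, mean_posterior_sd = r$mean_posterior_sd,
               sd_of_posterior_means = r$sd_of_posterior_means,
               coverage = r$coverage)
  }))
}

#' Calibration of posterior spread against sampling spread
#'
#' Compares, per condition, the average posterior SD of the treatment
#' effect with the SD of its posterior means across replicates. A ratio
#' above 1 means the posterior spread overstates the estimator's sampling
#' variability, producing conservative credible intervals.
#'
#' @param results a list of `study_result`s (or one).
#' @return The [study_table()] columns plus `calibration_ratio`
#'   (= `mean_posterior_sd / sd_of_posterior_means`) and the logical flag
#'   `conservative` (ratio > 1).
#' @export
calibration_table <- function(results) {
  tab <- study_table(results)
  tab$calibration_ratio <- tab$mean_posterior_sd / tab$sd_of_posterior_means
  tab$conservative <- tab$calibration_ratio > 1
  tab
}
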