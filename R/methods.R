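#' @export
print.occu_fit <- function(x, ...) {
  kind <- switch(x$model,
                 single = "hierarchical single-scale occupancy model",
                 multi = "multi-scale occupancy model",
                 empirical = "single-scale occupancy model with covariates")
  cat(kind, "\n")
  cat(sprintf("  data: %d units x %d years x %d plots x %d visits\n",
              x$data_dims[1], x$data_dims[2], x$data_dims[3], x$data_dims[4]))
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thin %d), priors: %s\n",
              x$config$chains, x$config$n_iter, x$config$burnin,
              x$config$thin, x$priors$label))
  keep <- x$summary$parameter %in% x$mean_params
  print(format(x$summary[keep, c("parameter", "mean", "sd", "lower", "upper")],
               digits = 3), row.names = FALSE)
  if (length(x$rhat) && any(is.finite(x$rhat)))
    cat(sprintf("  max R-hat (mean model): %.3f\n", max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Summarize a fitted occupancy model
#'
#' @param object an `occu_fit` object.
#' @param random include the unit random intercepts in the table.
#' @param ... unused.
#' @return A `summary.occu_fit` object: the posterior summary table
#'   (mean, SD, equal-tail 95% interval, median) with R-hat merged in for
#'   the mean-model parameters.
#' @export
summary.occu_fit <- function(object, random = FALSE, ...) {
  tab <- object$summary
  tab$rhat <- object$rhat[tab$parameter]
  if (!random)
    tab <- tab[!grepl("^(b0|a0)\\[", tab$parameter), , drop = FALSE]
  structure(list(table = tab, model = object$model, config = object$config,
                 n_draws = sum(vapply(object$draws, nrow, 0L))),
            class = "summary.occu_fit")
}

#' @export
print.summary.occu_fit <- function(x, ...) {
  cat(sprintf("posterior summary (%d retained draws)\n", x$n_draws))
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.occu_fit <- function(object, ...) {
  keep <- setdiff(object$mean_params, "sigma_b")
  stats::setNames(object$summary$mean[match(keep, object$summary$parameter)],
                  keep)
}

#' Equal-tail credible intervals for model parameters
#'
#' @param object an `occu_fit` object.
#' @param parm parameter names (default: the mean-model parameters).
#' @param level interval probability.
#' @param ... unused.
#' @return Matrix with one row per parameter and columns `lower`, `upper`.
#' @export
confint.occu_fit <- function(object, parm = NULL, level = 0.95, ...) {
  if (is.null(parm)) parm <- object$mean_params
  pooled <- as.matrix(object)
  out <- t(vapply(parm, function(pn) equal_tail_interval(pooled[, pn], level),
                  c(lower = 0, upper = 0)))
  out
}

#' @export
as.matrix.occu_fit <- function(x, ...) {
  do.call(rbind, x$draws)
}

#' Trace plots for a fitted occupancy model
#'
#' @param x an `occu_fit` object.
#' @param parm parameters to plot (default: mean-model parameters).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.occu_fit <- function(x, parm = NULL, ...) {
  if (is.null(parm)) parm <- x$mean_params
  old <- graphics::par(mfrow = c(ceiling(length(parm) / 2), min(2, length(parm))),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (pn in parm) {
    tr <- sapply(x$draws, function(d) d[, pn])
    graphics::matplot(tr, type = "l", lty = 1, main = pn, xlab = "", ylab = "",
                      ...)
  }
  invisible(x)
}

#' Write posterior draws to CSV in long format
#'
#' One row per retained draw and parameter: `chain`, `iteration`,
#' `parameter`, `value`.
#'
#' @param fit an `occu_fit` object.
#' @param path output file path.
#' @param parm parameters to write (default: mean-model parameters).
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path, parm = NULL) {
  if (is.null(parm)) parm <- fit$mean_params
  rows <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
    d <- fit$draws[[ch]][, parm, drop = FALSE]
    data.frame(chain = ch, iteration = rep(seq_len(nrow(d)), times = ncol(d)),
               parameter = rep(parm, each = nrow(d)), value = as.vector(d))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
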