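#' Conditional detection log-likelihood of one plot detection history
#'
#' Log-probability of a detection history given that the plot is occupied:
#' the sum over non-missing visits of `y*log(p) + (1-y)*log(1-p)`. Missing
#' visits contribute a factor of 1 (they are skipped), so a history with all
#' visits missing returns 0. A recorded detection with `p = 0` is an
#' impossible event and returns `-Inf`.
#'
#' @param history numeric vector of 0/1 detections with `NA` for missed
#'   visits.
#' @param p per-visit detection probabilities, same length as `history`.
#' @return The conditional log-likelihood (a scalar).
#' @examples
#' detection_history_loglik(c(1, 0, NA), c(0.3, 0.3, 0.3)) # log(.3) + log(.7)
#' @export
detection_history_loglik <- function(history, p) {
  if (length(history) != length(p))
    stop("'history' and 'p' must have the same length")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("detection probabilities must lie in [0, 1]")
  obs <- !is.na(history)
  if (!all(history[obs] %in% c(0, 1)))
    stop("detections must be 0, 1 or NA")
  y <- history[obs]; pp <- p[obs]
  # branch to avoid 0 * -Inf at the boundaries p = 0, 1
  sum(0, ifelse(y == 1, log(pp), log1p(-pp)))
}

# design matrices in the flattened (unit, year, plot[, visit]) cell order
# shared with the C++ code
design_single_baci <- function(data) {
  g <- cell_index_grid(data$n_units, data$n_years, data$n_plots)
  trt <- data$treatment[g$i]; yr <- data$year_after[g$j]
  Xpsi <- cbind(1, yr, trt, trt * yr)
  colnames(Xpsi) <- c("beta0", "beta1", "beta2", "beta3")
  nv <- nrow(Xpsi) * data$n_visits
  Xdet <- matrix(1, nv, 1, dimnames = list(NULL, "gamma0"))
  list(Xpsi = Xpsi, Xdet = Xdet)
}

design_empirical <- function(data) {
  if (is.null(data$cwd) || is.null(data$julian_date) || is.null(data$block))
    stop("empirical model needs 'cwd', 'julian_date' and 'block' covariates")
  g <- cell_index_grid(data$n_units, data$n_years, data$n_plots)
  cwd <- data$cwd[cbind(g$i, g$j, g$k)]
  Xpsi <- cbind(1, cwd, data$year_after[g$j], data$block[g$i])
  colnames(Xpsi) <- c("beta0", "beta_cwd", "beta_year", "beta_block")
  gv <- visit_index_grid(data$n_units, data$n_years, data$n_plots, data$n_visits)
  jd <- data$julian_date[cbind(gv$i, gv$j, gv$k, gv$l)]
  jd[is.na(jd)] <- 0 # only entered for observed visits; masked otherwise
  Xdet <- cbind(1, jd, jd^2, data$year_after[gv$j])
  colnames(Xdet) <- c("gamma0", "gamma_jd", "gamma_jd2", "gamma_year")
  list(Xpsi = Xpsi, Xdet = Xdet)
}

design_multi_baci <- function(data) {
  g <- expand.grid(j = seq_len(data$n_years), i = seq_len(data$n_units))
  trt <- data$treatment[g$i]; yr <- data$year_after[g$j]
  Xtheta <- cbind(1, yr, trt, trt * yr)
  colnames(Xtheta) <- c("alpha0", "alpha1", "alpha2", "alpha3")
  Xtheta
}

#' Marginal log-likelihood of the hierarchical single-scale occupancy model
#'
#' Exact marginal log-likelihood with the latent plot occupancy indicators
#' summed out analytically, conditional on the unit random intercepts: the
#' sum over plot-year cells of
#' `log(psi * P(history | occupied) + (1 - psi) * I(no detection))`,
#' where `logit(psi) = X beta + b0[unit]`.
#'
#' @param data an [occu_data()] object.
#' @param params list with `beta` (occupancy coefficients: intercept, year,
#'   treatment, treatment x year for the BACI design, or the CWD/year/block
#'   design for `design = "empirical"`), `b0` (per-unit random intercepts),
#'   and either `gamma` (logit-scale detection coefficients) or `p_detect`
#'   (a constant detection probability).
#' @param design `"baci"` (intercept/year/treatment/interaction occupancy,
#'   constant detection) or `"empirical"` (CWD/year/block occupancy,
#'   Julian-date quadratic detection).
#' @return Marginal log-likelihood (scalar); `-Inf` for impossible data.
#' @examples
#' y <- array(1L, dim = c(1, 1, 1, 1))
#' d <- occu_data(y, treatment = 0, year_after = 0)
#' loglik_single_scale(d, list(beta = c(0, 0, 0, 0), b0 = 0, p_detect = 1))
#' @export
loglik_single_scale <- function(data, params, design = c("baci", "empirical")) {
  design <- match.arg(design)
  stopifnot(inherits(data, "occu_data"))
  X <- if (design == "baci") design_single_baci(data) else design_empirical(data)
  gamma <- params$gamma
  if (is.null(gamma)) {
    if (is.null(params$p_detect)) stop("supply 'gamma' or 'p_detect'")
    gamma <- stats::qlogis(params$p_detect)
  }
  stopifnot(length(params$beta) == ncol(X$Xpsi), length(gamma) == ncol(X$Xdet))
  b0 <- if (is.null(params$b0)) rep(0, data$n_units) else params$b0
  stopifnot(length(b0) == data$n_units)
  f <- flatten_occu(data)
  cpp_loglik_single(f$y, f$miss, f$I, f$J, f$K, f$L, X$Xpsi, X$Xdet,
                    as.numeric(params$beta), as.numeric(gamma),
                    as.numeric(b0))
}

#' Marginal log-likelihood of the multi-scale occupancy model
#'
#' Exact marginal log-likelihood with both latent levels (unit-year
#' occupancy `z` and plot occupancy `u`) summed out analytically,
#' conditional on the unit random intercepts. Conditional plot occupancy
#' and detection probability are constants, as in the BACI simulation
#' design.
#'
#' @param data an [occu_data()] object.
#' @param params list with `alpha` (unit-level occupancy coefficients:
#'   intercept, year, treatment, treatment x year), `a0` (per-unit random
#'   intercepts), and the constant conditional plot occupancy and detection
#'   probability as either probabilities (`psi_plot`, `p_detect`) or
#'   logit-scale values (`lpsi`, `lp`).
#' @return Marginal log-likelihood (scalar).
#' @examples
#' y <- array(0L, dim = c(1, 1, 2, 2))
#' d <- occu_data(y, treatment = 0, year_after = 0)
#' loglik_multi_scale(d, list(alpha = c(-20, 0, 0, 0), a0 = 0,
#'                            psi_plot = 0.5, p_detect = 0.3)) # ~ log(1)
#' @export
loglik_multi_scale <- function(data, params) {
  stopifnot(inherits(data, "occu_data"))
  Xtheta <- design_multi_baci(data)
  lpsi <- if (!is.null(params$lpsi)) params$lpsi else stats::qlogis(params$psi_plot)
  lp <- if (!is.null(params$lp)) params$lp else stats::qlogis(params$p_detect)
  stopifnot(length(params$alpha) == ncol(Xtheta))
  a0 <- if (is.null(params$a0)) rep(0, data$n_units) else params$a0
  stopifnot(length(a0) == data$n_units)
  f <- flatten_occu(data)
  cpp_loglik_multi(f$y, f$miss, f$I, f$J, f$K, f$L, Xtheta,
                   as.numeric(params$alpha), as.numeric(a0),
                   as.numeric(lpsi), as.numeric(lp))
}
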