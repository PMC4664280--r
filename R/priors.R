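#' Prior specifications for the occupancy models
#'
#' Builds the prior specification used by [occu_fit()] and [log_prior()].
#' The `"default"` specification places Normal(0, variance 3) priors on the
#' occupancy and detection intercepts (all parameters on the logit scale),
#' Normal(0, variance 4) priors on occupancy and detection covariate
#' coefficients, and a Gamma(shape 2, rate 1) prior on the random-intercept
#' standard deviation `sigma_b`. The `"relaxed"` specification widens the
#' covariate priors to Normal(0, variance 10) and leaves everything else
#' unchanged. All second parameters are variances, not standard deviations.
#'
#' @param spec `"default"`, `"relaxed"`, or a list with elements
#'   `occ_int`, `occ_cov`, `det_int`, `det_cov` (each `c(mean, var)`) and
#'   `sigma` (`c(shape, rate)`) to override individual pieces.
#' @return An object of class `occu_priors`.
#' @examples
#' occu_priors("relaxed")$occ_cov
#' @export
occu_priors <- function(spec = "default") {
  if (inherits(spec, "occu_priors")) return(spec)
  base <- list(occ_int = c(mean = 0, var = 3), occ_cov = c(mean = 0, var = 4),
               det_int = c(mean = 0, var = 3), det_cov = c(mean = 0, var = 4),
               sigma = c(shape = 2, rate = 1), label = "default")
  if (is.character(spec)) {
    spec <- match.arg(spec, c("default", "relaxed"))
    if (spec == "relaxed") {
      base$occ_cov <- c(mean = 0, var = 10)
      base$det_cov <- c(mean = 0, var = 10)
      base$label <- "relaxed"
    }
  } else if (is.list(spec)) {
    lbl <- if (!is.null(spec$label)) spec$label else "custom"
    base[names(spec)] <- spec
    base$label <- lbl
  } else stop("'spec' must be a character label or a list")
  structure(base, class = "occu_priors")
}

# per-parameter (mean, variance) vectors for a coefficient block whose first
# entry is the intercept and the rest are covariate coefficients
prior_block <- function(priors, n, intercept, covariate) {
  if (n == 0L) return(list(mean = numeric(0), var = numeric(0)))
  m <- c(intercept["mean"], rep(covariate["mean"], n - 1L))
  v <- c(intercept["var"], rep(covariate["var"], n - 1L))
  list(mean = unname(m), var = unname(v))
}

#' Log prior density of a parameter vector
#'
#' Sum of Normal log-densities for the fixed effects (intercepts and
#' covariate coefficients use the variances given by `priors`), a
#' Gamma(shape, rate) log-density for `sigma_b`, and Normal(0, `sigma_b`^2)
#' log-densities for the unit random intercepts.
#'
#' @param params a list with elements `beta` (occupancy fixed effects,
#'   intercept first), `gamma` (detection fixed effects, intercept first;
#'   for the multi-scale model use `lpsi` and `lp`, the logit-scale constant
#'   plot occupancy and detection, which carry intercept priors), optionally
#'   `b0` (unit random intercepts) and `sigma_b`.
#' @param priors an [occu_priors()] specification or its label.
#' @return The log prior density; `-Inf` if `sigma_b <= 0`.
#' @examples
#' log_prior(list(beta = c(0, 0), sigma_b = 1), "default")
#' @export
log_prior <- function(params, priors = "default") {
  priors <- occu_priors(priors)
  lp <- 0
  if (!is.null(params$beta)) {
    pb <- prior_block(priors, length(params$beta), priors$occ_int, priors$occ_cov)
    lp <- lp + sum(stats::dnorm(params$beta, pb$mean, sqrt(pb$var), log = TRUE))
  }
  if (!is.null(params$alpha)) {
    pb <- prior_block(priors, length(params$alpha), priors$occ_int, priors$occ_cov)
    lp <- lp + sum(stats::dnorm(params$alpha, pb$mean, sqrt(pb$var), log = TRUE))
  }
  if (!is.null(params$gamma)) {
    pb <- prior_block(priors, length(params$gamma), priors$det_int, priors$det_cov)
    lp <- lp + sum(stats::dnorm(params$gamma, pb$mean, sqrt(pb$var), log = TRUE))
  }
  if (!is.null(params$lpsi))
    lp <- lp + stats::dnorm(params$lpsi, priors$occ_int["mean"],
                            sqrt(priors$occ_int["var"]), log = TRUE)
  if (!is.null(params$lp))
    lp <- lp + stats::dnorm(params$lp, priors$det_int["mean"],
                            sqrt(priors$det_int["var"]), log = TRUE)
  if (!is.null(params$sigma_b)) {
    if (params$sigma_b <= 0) return(-Inf)
    lp <- lp + stats::dgamma(params$sigma_b, shape = priors$sigma["shape"],
                             rate = priors$sigma["rate"], log = TRUE)
    if (!is.null(params$b0))
      lp <- lp + sum(stats::dnorm(params$b0, 0, params$sigma_b, log = TRUE))
  } else if (!is.null(params$b0) && length(params$b0)) {
    stop("random intercepts supplied without 'sigma_b'")
  }
  unname(lp)
}
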