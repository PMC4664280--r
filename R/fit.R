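#' Fit a hierarchical occupancy model by MCMC
#'
#' Posterior sampling for the three model variants via adaptive random-walk
#' Metropolis-within-Gibbs on the *marginal* likelihood (latent occupancy
#' states summed out analytically; only the continuous parameters are
#' sampled). Proposal scales adapt toward ~44% acceptance during burn-in
#' only; the post-burn-in kernel is fixed.
#'
#' Model variants:
#' \describe{
#'   \item{`"single"`}{hierarchical single-scale model for the BACI design:
#'     plot occupancy `logit(psi) = beta0 + b0_i + beta1*Year +
#'     beta2*Treatment + beta3*Treatment*Year`, constant detection
#'     `logit(p) = gamma0`.}
#'   \item{`"multi"`}{multi-scale model: unit occupancy `logit(theta) =
#'     alpha0 + a0_i + alpha1*Year + alpha2*Treatment +
#'     alpha3*Treatment*Year`, constant conditional plot occupancy (`lpsi`)
#'     and detection (`lp`) on the logit scale.}
#'   \item{`"empirical"`}{single-scale model with plot occupancy
#'     `logit(psi) = beta0 + b0_i + beta_cwd*CWD + beta_year*Year +
#'     beta_block*Block` and detection `logit(p) = gamma0 + gamma_jd*JD +
#'     gamma_jd2*JD^2 + gamma_year*Year` (covariates standardized upstream,
#'     see [standardize_covariates()]).}
#' }
#'
#' @param data an [occu_data()] object.
#' @param model model variant, see Details.
#' @param priors an [occu_priors()] specification or its label.
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iter total iterations per chain, including burn-in.
#' @param burnin burn-in iterations (adaptation window).
#' @param thin thinning interval; iterations `burnin + thin, burnin + 2*thin,
#'   ...` are retained, so each chain keeps `floor((n_iter - burnin)/thin)`
#'   draws.
#' @param seed integer seed for reproducibility (chains are drawn from one
#'   RNG stream, so the full fit is deterministic given the seed).
#' @param fixed optional list pinning parameters at known values instead of
#'   sampling them: numeric vectors for `beta`/`gamma` (or `alpha`) with
#'   `NA` for free entries, and scalars for `b0` (all intercepts), `lpsi`,
#'   `lp` or `sigma_b`.
#' @param max_init_tries number of redraws of initial values allowed when
#'   the likelihood is non-finite at the starting point.
#' @return An object of class `occu_fit` with components `draws` (list of
#'   per-chain matrices of retained draws), `summary` (posterior mean, SD,
#'   equal-tail 95% interval and median per parameter), `rhat` (Gelman-Rubin
#'   statistic for the mean-model parameters: fixed effects plus `sigma_b`),
#'   `accept` (post-burn-in acceptance rates), and bookkeeping fields.
#' @seealso [summary.occu_fit()], [coef.occu_fit()], [confint.occu_fit()]
#' @examples
#' sim <- simulate_baci(baci_condition("single", n_units = 10, n_plots = 5,
#'                                     p_detect = 0.5), seed = 1)
#' fit <- occu_fit(sim$data, "single", chains = 2, n_iter = 400,
#'                 burnin = 200, thin = 1, seed = 1)
#' coef(fit)
#' @export
occu_fit <- function(data, model = c("single", "multi", "empirical"),
                     priors = "default", chains = 3, n_iter = 10000,
                     burnin = 5000, thin = 10, seed = NULL, fixed = NULL,
                     max_init_tries = 50) {
  model <- match.arg(model)
  stopifnot(inherits(data, "occu_data"))
  if (sum(!is.na(data$detections)) == 0L)
    stop("dataset has zero non-missing visits")
  if (burnin >= n_iter) stop("'burnin' must be smaller than 'n_iter'")
  if (thin < 1) stop("'thin' must be >= 1")
  if (chains < 1) stop("need at least one chain")
  priors <- occu_priors(priors)
  if (!is.null(seed)) set.seed(seed)
  f <- flatten_occu(data)
  n_keep <- (n_iter - burnin) %/% thin
  if (n_keep < 1) stop("no draws retained; increase 'n_iter' or lower 'thin'")

  res <- if (model == "multi") {
    fit_multi_chains(data, f, priors, chains, n_iter, burnin, thin, fixed,
                     max_init_tries)
  } else {
    fit_single_chains(data, f, model, priors, chains, n_iter, burnin, thin,
                      fixed, max_init_tries)
  }

  pooled <- do.call(rbind, res$draws)
  qs <- t(apply(pooled, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
                type = 7, names = FALSE))
  summ <- data.frame(parameter = colnames(pooled),
                     mean = colMeans(pooled),
                     sd = apply(pooled, 2, stats::sd),
                     lower = qs[, 1], median = qs[, 2], upper = qs[, 3],
                     row.names = NULL)
  rhat <- if (chains >= 2) {
    vapply(res$mean_params, function(pn)
      gelman_rubin(lapply(res$draws, function(d) d[, pn])), 0)
  } else {
    stats::setNames(rep(NA_real_, length(res$mean_params)), res$mean_params)
  }
  structure(list(model = model, draws = res$draws,
                 param_names = colnames(pooled),
                 mean_params = res$mean_params,
                 effect_param = res$effect_param,
                 summary = summ, rhat = rhat, accept = res$accept,
                 priors = priors,
                 config = list(chains = chains, n_iter = n_iter,
                               burnin = burnin, thin = thin, seed = seed),
                 data_dims = c(n_units = data$n_units, n_years = data$n_years,
                               n_plots = data$n_plots, n_visits = data$n_visits),
                 call = match.call()),
            class = "occu_fit")
}

# resolve a 'fixed' entry for a coefficient vector: returns list(init_mask)
fixed_vector <- function(fixed_entry, n) {
  if (is.null(fixed_entry)) return(list(value = rep(NA_real_, n),
                                        update = rep(TRUE, n)))
  stopifnot(length(fixed_entry) == n)
  list(value = as.numeric(fixed_entry), update = is.na(fixed_entry))
}

draw_inits <- function(n, update, fixed_value) {
  x <- ifelse(update, stats::rnorm(n, 0, 0.5), fixed_value)
  as.numeric(x)
}

fit_single_chains <- function(data, f, model, priors, chains, n_iter, burnin,
                              thin, fixed, max_init_tries) {
  X <- if (model == "single") design_single_baci(data) else design_empirical(data)
  P <- ncol(X$Xpsi); Q <- ncol(X$Xdet); I <- data$n_units
  bnames <- colnames(X$Xpsi); gnames <- colnames(X$Xdet)
  pb <- prior_block(priors, P, priors$occ_int, priors$occ_cov)
  pg <- prior_block(priors, Q, priors$det_int, priors$det_cov)
  fb <- fixed_vector(fixed$beta, P)
  fg <- fixed_vector(fixed$gamma, Q)
  upd_b0 <- is.null(fixed$b0)
  b0_fix <- if (upd_b0) 0 else as.numeric(fixed$b0)
  upd_sig <- is.null(fixed$sigma_b)
  sig_fix <- if (upd_sig) NA else as.numeric(fixed$sigma_b)

  names_all <- c(bnames, gnames, paste0("b0[", seq_len(I), "]"), "sigma_b")
  draws <- vector("list", chains); accept <- NULL
  for (ch in seq_len(chains)) {
    out <- NULL
    for (try in seq_len(max_init_tries)) {
      beta0 <- draw_inits(P, fb$update, fb$value)
      gamma0 <- draw_inits(Q, fg$update, fg$value)
      sig0 <- if (upd_sig) stats::rgamma(1, shape = priors$sigma["shape"],
                                         rate = priors$sigma["rate"]) else sig_fix
      b00 <- rep(b0_fix, I)
      out <- tryCatch(
        cpp_mcmc_single(f$y, f$miss, f$I, f$J, f$K, f$L, X$Xpsi, X$Xdet,
                        beta0, gamma0, b00, sig0,
                        pb$mean, pb$var, pg$mean, pg$var,
                        priors$sigma[["shape"]], priors$sigma[["rate"]],
                        n_iter, burnin, thin,
                        fb$update, fg$update, upd_b0, upd_sig),
        error = function(e) {
          if (grepl("non-finite log-likelihood", conditionMessage(e))) NULL
          else stop(e)
        })
      if (!is.null(out)) break
    }
    if (is.null(out))
      stop("could not find finite-likelihood initial values after ",
           max_init_tries, " attempts")
    colnames(out$draws) <- names_all
    draws[[ch]] <- out$draws
    if (ch == 1L) accept <- stats::setNames(out$accept, names_all)
  }
  mean_params <- c(bnames[fb$update], gnames[fg$update],
                   if (upd_sig) "sigma_b")
  list(draws = draws, accept = accept, mean_params = mean_params,
       effect_param = if (model == "single") "beta3" else NULL)
}

fit_multi_chains <- function(data, f, priors, chains, n_iter, burnin, thin,
                             fixed, max_init_tries) {
  Xtheta <- design_multi_baci(data)
  P <- ncol(Xtheta); I <- data$n_units
  anames <- colnames(Xtheta)
  pa <- prior_block(priors, P, priors$occ_int, priors$occ_cov)
  fa <- fixed_vector(fixed$alpha, P)
  upd_lpsi <- is.null(fixed$lpsi); lpsi_fix <- if (upd_lpsi) NA else fixed$lpsi
  upd_lp <- is.null(fixed$lp); lp_fix <- if (upd_lp) NA else fixed$lp
  upd_a0 <- is.null(fixed$a0)
  a0_fix <- if (upd_a0) 0 else as.numeric(fixed$a0)
  upd_sig <- is.null(fixed$sigma_b)
  sig_fix <- if (upd_sig) NA else as.numeric(fixed$sigma_b)

  names_all <- c(anames, "lpsi", "lp", paste0("a0[", seq_len(I), "]"), "sigma_b")
  draws <- vector("list", chains); accept <- NULL
  for (ch in seq_len(chains)) {
    out <- NULL
    for (try in seq_len(max_init_tries)) {
      alpha0 <- draw_inits(P, fa$update, fa$value)
      lpsi0 <- if (upd_lpsi) stats::rnorm(1, 0, 0.5) else as.numeric(lpsi_fix)
      lp0 <- if (upd_lp) stats::rnorm(1, 0, 0.5) else as.numeric(lp_fix)
      sig0 <- if (upd_sig) stats::rgamma(1, shape = priors$sigma["shape"],
                                         rate = priors$sigma["rate"]) else sig_fix
      a00 <- rep(a0_fix, I)
      out <- tryCatch(
        cpp_mcmc_multi(f$y, f$miss, f$I, f$J, f$K, f$L, Xtheta,
                       alpha0, lpsi0, lp0, a00, sig0,
                       pa$mean, pa$var,
                       priors$occ_int[["mean"]], priors$occ_int[["var"]],
                       priors$det_int[["mean"]], priors$det_int[["var"]],
                       priors$sigma[["shape"]], priors$sigma[["rate"]],
                       n_iter, burnin, thin,
                       fa$update, upd_lpsi, upd_lp, upd_a0, upd_sig),
        error = function(e) {
          if (grepl("non-finite log-likelihood", conditionMessage(e))) NULL
          else stop(e)
        })
      if (!is.null(out)) break
    }
    if (is.null(out))
      stop("could not find finite-likelihood initial values after ",
           max_init_tries, " attempts")
    colnames(out$draws) <- names_all
    draws[[ch]] <- out$draws
    if (ch == 1L) accept <- stats::setNames(out$accept, names_all)
  }
  mean_params <- c(anames[fa$update], if (upd_lpsi) "lpsi", if (upd_lp) "lp",
                   if (upd_sig) "sigma_b")
  list(draws = draws, accept = accept, mean_params = mean_params,
       effect_param = "alpha3")
}
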