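#' Read a plot-survey detection table from CSV
#'
#' Reads the one-row-per-(unit, year, plot) dialect written by
#' [write_empirical_csv()]. A `column_map` adapts files with different
#' headers: a named list with entries `unit`, `block`, `year`, `plot`,
#' `cwd`, and character vectors `y` and `jd` naming the per-visit detection
#' and Julian-date columns in visit order.
#'
#' @param path CSV file path.
#' @param column_map optional column mapping (defaults to the native
#'   dialect: `unit_id`, `block`, `year`, `plot_id`, `cwd`, `y1..y3`,
#'   `jd1..jd3`).
#' @return An `empirical_table` data frame with canonical column names.
#'   Blank detection cells become `NA` (missing visits).
#' @export
read_empirical <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  map <- list(unit = "unit_id", block = "block", year = "year",
              plot = "plot_id", cwd = "cwd",
              y = c("y1", "y2", "y3"), jd = c("jd1", "jd2", "jd3"))
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  need <- c(map$unit, map$block, map$year, map$plot, map$cwd, map$y, map$jd)
  absent <- setdiff(need, names(raw))
  if (length(absent))
    stop("required column(s) not found in ", path, ": ",
         paste(absent, collapse = ", "))
  L <- length(map$y)
  tab <- data.frame(unit_id = raw[[map$unit]], block = raw[[map$block]],
                    year = raw[[map$year]], plot_id = raw[[map$plot]],
                    cwd = raw[[map$cwd]])
  for (l in seq_len(L)) {
    v <- raw[[map$y[l]]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    if (length(bad))
      stop("non-binary detection value in column '", map$y[l], "', row ",
           bad[1])
    tab[[paste0("y", l)]] <- as.integer(v)
  }
  for (l in seq_len(L))
    tab[[paste0("jd", l)]] <- suppressWarnings(as.numeric(raw[[map$jd[l]]]))
  dup <- duplicated(tab[, c("unit_id", "year", "plot_id")])
  if (any(dup))
    stop("duplicated (unit, year, plot) key at row ", which(dup)[1])
  obs <- !is.na(as.matrix(tab[, paste0("y", seq_len(L)), drop = FALSE]))
  jdm <- is.na(as.matrix(tab[, paste0("jd", seq_len(L)), drop = FALSE]))
  if (any(obs & jdm))
    stop("observed detection with missing Julian date at row ",
         which(rowSums(obs & jdm) > 0)[1])
  message(sprintf("read %d plot-year rows (%d units, %d years) from %s",
                  nrow(tab), length(unique(tab$unit_id)),
                  length(unique(tab$year)), path))
  class(tab) <- c("empirical_table", "data.frame")
  tab
}

# empirical_table -> occu_data (no standardization)
empirical_data_from_table <- function(tab) {
  L <- sum(grepl("^y[0-9]+$", names(tab)))
  units <- sort(unique(tab$unit_id))
  years <- sort(unique(tab$year))
  I <- length(units); J <- length(years)
  ui <- match(tab$unit_id, units); yi <- match(tab$year, years)
  K <- max(stats::ave(seq_len(nrow(tab)), ui, yi, FUN = seq_along))
  ki <- stats::ave(seq_len(nrow(tab)), ui, yi, FUN = seq_along)
  y <- array(NA_integer_, dim = c(I, J, K, L))
  jd <- array(NA_real_, dim = c(I, J, K, L))
  cwd <- array(NA_real_, dim = c(I, J, K))
  for (l in seq_len(L)) {
    y[cbind(ui, yi, ki, l)] <- tab[[paste0("y", l)]]
    jd[cbind(ui, yi, ki, l)] <- tab[[paste0("jd", l)]]
  }
  cwd[cbind(ui, yi, ki)] <- tab$cwd
  blk <- tab$block
  if (is.character(blk)) blk <- as.integer(tolower(blk) == "clackamas")
  block <- integer(I)
  block[ui] <- blk
  occu_data(y, treatment = rep(0L, I),
            year_after = as.integer(years == max(years)),
            cwd = cwd, julian_date = jd, block = block)
}

#' Center and scale the survey covariates
#'
#' CWD counts and Julian dates are each centered by their overall mean and
#' scaled by their overall standard deviation (pooled across years and
#' blocks; Julian dates over non-missing visits only). The quadratic
#' detection term is computed downstream from the *standardized* Julian
#' date. The scaling constants are returned for back-transformation.
#'
#' @param x an `empirical_table` (from [read_empirical()] or
#'   [simulate_empirical_like()]) or an [occu_data()] with `cwd` and
#'   `julian_date`.
#' @return List with `data` (an [occu_data()] whose `cwd` and `julian_date`
#'   hold standardized values) and `scaling` (list with `cwd_mean`,
#'   `cwd_sd`, `jd_mean`, `jd_sd`).
#' @export
standardize_covariates <- function(x) {
  data <- if (inherits(x, "occu_data")) x else empirical_data_from_table(x)
  if (is.null(data$cwd) || is.null(data$julian_date))
    stop("'cwd' and 'julian_date' covariates are required")
  cm <- mean(data$cwd, na.rm = TRUE); cs <- stats::sd(data$cwd, na.rm = TRUE)
  jm <- mean(data$julian_date, na.rm = TRUE)
  js <- stats::sd(data$julian_date, na.rm = TRUE)
  if (!is.finite(cs) || cs == 0) stop("zero-variance covariate: cwd")
  if (!is.finite(js) || js == 0) stop("zero-variance covariate: julian_date")
  data$cwd <- (data$cwd - cm) / cs
  data$julian_date <- (data$julian_date - jm) / js
  list(data = data,
       scaling = list(cwd_mean = cm, cwd_sd = cs, jd_mean = jm, jd_sd = js))
}

#' Fit the covariate occupancy model to a plot-survey dataset
#'
#' Fits the hierarchical single-scale model with CWD, year and block
#' effects on plot occupancy and a quadratic Julian-date plus year effect
#' on detection (all covariates standardized first). The default chain
#' protocol is 3 chains of 55,000 iterations with 5,000 burn-in and 1/10
#' thinning.
#'
#' @param x an `empirical_table` or [occu_data()] (unstandardized; this
#'   function standardizes internally and stores the scaling record).
#' @param priors prior specification, see [occu_priors()].
#' @param chains,n_iter,burnin,thin MCMC protocol.
#' @param seed integer seed.
#' @return An `occu_fit` with an added `scaling` component.
#' @export
fit_empirical <- function(x, priors = "default", chains = 3, n_iter = 55000,
                          burnin = 5000, thin = 10, seed = NULL) {
  std <- standardize_covariates(x)
  fit <- occu_fit(std$data, model = "empirical", priors = priors,
                  chains = chains, n_iter = n_iter, burnin = burnin,
                  thin = thin, seed = seed)
  fit$scaling <- std$scaling
  fit$data <- std$data
  fit
}

#' Posterior summaries of derived occupancy and detection probabilities
#'
#' For each posterior draw: (a) the mean plot-level occupancy per block,
#' averaging `psi` (random intercepts included) over every sampled plot in
#' the block and over both years; (b) the year-specific detection
#' probability evaluated at the mean survey date (standardized Julian date
#' 0). Posterior means of these quantities are reported.
#'
#' @param fit an `occu_fit` from [fit_empirical()] (model `"empirical"`).
#' @param data the standardized [occu_data()] used in the fit (defaults to
#'   the copy stored on the fit).
#' @param chunk draws processed per block of computation (memory control).
#' @return Data frame with columns `quantity`, `group`, `estimate`.
#' @export
derived_summaries <- function(fit, data = fit$data, chunk = 500L) {
  stopifnot(inherits(fit, "occu_fit"), fit$model == "empirical")
  if (is.null(data)) stop("supply the standardized dataset used in the fit")
  X <- design_empirical(data)
  g <- cell_index_grid(data$n_units, data$n_years, data$n_plots)
  pooled <- as.matrix(fit)
  bn <- c("beta0", "beta_cwd", "beta_year", "beta_block")
  b0n <- paste0("b0[", seq_len(data$n_units), "]")
  blocks <- sort(unique(data$block), decreasing = TRUE)
  occ_sum <- numeric(length(blocks)); det_sum <- numeric(2); n <- 0L
  for (start in seq(1, nrow(pooled), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(pooled))
    beta <- pooled[idx, bn, drop = FALSE]
    b0 <- pooled[idx, b0n, drop = FALSE]
    eta <- X$Xpsi %*% t(beta) + t(b0)[g$i, , drop = FALSE]
    psi <- stats::plogis(eta)
    for (bi in seq_along(blocks)) {
      rows <- data$block[g$i] == blocks[bi]
      occ_sum[bi] <- occ_sum[bi] + sum(colMeans(psi[rows, , drop = FALSE]))
    }
    gmat <- pooled[idx, c("gamma0", "gamma_year"), drop = FALSE]
    det_sum[1] <- det_sum[1] + sum(stats::plogis(gmat[, 1]))
    det_sum[2] <- det_sum[2] + sum(stats::plogis(gmat[, 1] + gmat[, 2]))
    n <- n + length(idx)
  }
  data.frame(
    quantity = c(rep("mean_plot_occupancy", length(blocks)),
                 "detection", "detection"),
    group = c(paste0("block_", blocks), "year_before", "year_after"),
    estimate = c(occ_sum / n, det_sum / n))
}
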