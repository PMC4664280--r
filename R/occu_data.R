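#' Detection/non-detection dataset for nested occupancy designs
#'
#' Container for a four-level detection array indexed by harvest unit, year,
#' plot and visit, together with the unit-, year-, plot- and visit-level
#' covariates used by the occupancy models in this package. Missing visits
#' (e.g. visits never made under a removal sampling protocol) are encoded as
#' `NA` in `detections`.
#'
#' @param detections integer array of dimension
#'   `c(n_units, n_years, n_plots, n_visits)` with values 0, 1 or `NA`.
#' @param treatment integer vector of length `n_units`; 1 = impact arm.
#' @param year_after integer vector of length `n_years`; 1 = "after" period.
#' @param cwd optional numeric array `c(n_units, n_years, n_plots)` of coarse
#'   woody debris counts (pieces per plot).
#' @param julian_date optional numeric array
#'   `c(n_units, n_years, n_plots, n_visits)` of survey Julian dates (days).
#' @param block optional integer vector of length `n_units`; 1 = Clackamas
#'   block.
#' @param removal logical; if `TRUE` the missingness pattern is checked to be
#'   monotone within each plot-year (once a visit is missing, all later visits
#'   are missing), as produced by a removal sampling protocol.
#'
#' @return An object of class `occu_data`: a list with the validated fields
#'   plus `n_units`, `n_years`, `n_plots`, `n_visits`.
#' @examples
#' y <- array(rbinom(2 * 2 * 3 * 3, 1, 0.3), dim = c(2, 2, 3, 3))
#' d <- occu_data(y, treatment = c(0, 1), year_after = c(0, 1))
#' d$n_plots
#' @export
occu_data <- function(detections, treatment = NULL, year_after = NULL,
                      cwd = NULL, julian_date = NULL, block = NULL,
                      removal = FALSE) {
  if (!is.array(detections) || length(dim(detections)) != 4L)
    stop("'detections' must be a 4-dimensional array (unit, year, plot, visit)")
  dm <- dim(detections)
  I <- dm[1]; J <- dm[2]; K <- dm[3]; L <- dm[4]
  vals <- detections[!is.na(detections)]
  if (length(vals) == 0L)
    stop("dataset has zero non-missing visits")
  if (!all(vals %in% c(0L, 1L)))
    stop("detection entries must be 0, 1 or NA")
  if (is.null(treatment)) treatment <- rep(0L, I)
  if (is.null(year_after)) year_after <- as.integer(seq_len(J) > 1L)
  stopifnot(length(treatment) == I, all(treatment %in% c(0, 1)),
            length(year_after) == J, all(year_after %in% c(0, 1)))
  if (!is.null(cwd) && !identical(dim(cwd), dm[1:3]))
    stop("'cwd' must have dimension (n_units, n_years, n_plots)")
  if (!is.null(julian_date) && !identical(dim(julian_date), dm))
    stop("'julian_date' must have the same dimension as 'detections'")
  if (!is.null(block)) stopifnot(length(block) == I, all(block %in% c(0, 1)))
  if (removal && !all(apply(detections, c(1, 2, 3), function(h) {
    miss <- is.na(h)
    !any(diff(miss) < 0) # once missing, stays missing
  })))
    stop("removal data must have monotone missingness within each plot-year")
  structure(
    list(detections = detections, treatment = as.integer(treatment),
         year_after = as.integer(year_after), cwd = cwd,
         julian_date = julian_date,
         block = if (is.null(block)) NULL else as.integer(block),
         n_units = I, n_years = J, n_plots = K, n_visits = L,
         removal = removal),
    class = "occu_data")
}

#' @export
print.occu_data <- function(x, ...) {
  cat("Occupancy detection dataset\n")
  cat(sprintf("  %d units x %d years x %d plots x %d visits\n",
              x$n_units, x$n_years, x$n_plots, x$n_visits))
  nobs <- sum(!is.na(x$detections))
  cat(sprintf("  %d observed visits (%d missing), naive detection rate %.3f\n",
              nobs, sum(is.na(x$detections)),
              mean(x$detections, na.rm = TRUE)))
  covs <- c(if (!is.null(x$cwd)) "cwd", if (!is.null(x$julian_date)) "julian_date",
            if (!is.null(x$block)) "block")
  if (length(covs)) cat("  covariates:", paste(covs, collapse = ", "), "\n")
  invisible(x)
}

# flatten the detection array and covariates in the row-major (unit, year,
# plot, visit) order used by the C++ likelihood code
flatten_occu <- function(data) {
  y4 <- data$detections
  I <- data$n_units; J <- data$n_years; K <- data$n_plots; L <- data$n_visits
  # aperm so that visit varies fastest, then plot, year, unit
  yy <- as.integer(aperm(y4, c(4, 3, 2, 1)))
  miss <- is.na(yy)
  yy[miss] <- 0L
  list(y = yy, miss = miss, I = I, J = J, K = K, L = L)
}

# index helpers matching the C++ layout: cell c = ((i-1)*J + (j-1))*K + k
cell_index_grid <- function(I, J, K) {
  # returns data.frame of (i, j, k) in cell order
  expand.grid(k = seq_len(K), j = seq_len(J), i = seq_len(I))[, c("i", "j", "k")]
}
visit_index_grid <- function(I, J, K, L) {
  expand.grid(l = seq_len(L), k = seq_len(K), j = seq_len(J),
              i = seq_len(I))[, c("i", "j", "k", "l")]
}
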