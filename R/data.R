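#' Observed intensity data
#'
#' Holds the observed mean intensity and its standard deviation on a q grid.
#' When the experiment provides no standard deviation, the mean itself is used
#' in its place (the assumption that measurement error scales with the
#' measured amplitude); this fallback must be requested explicitly.
#'
#' @param q A [q_grid()].
#' @param mean Observed mean intensity: vector (M = 1) or matrix (M = 2)
#'   matching the grid.
#' @param std Observational standard deviation, same shape, strictly positive.
#'   `NULL` with `std_fallback = TRUE` sets `std := |mean|`.
#' @param dq Optional per-point q-resolution widths (M = 1 only).
#' @param std_fallback Allow the `std := mean` substitution.
#' @return An object of class `intensity_data`.
#' @export
intensity_data <- function(q, mean, std = NULL, dq = NULL,
                           std_fallback = is.null(std)) {
  stopifnot(inherits(q, "q_grid"))
  dims <- q_grid_lengths(q)
  mean <- if (q$M == 1L) as.numeric(mean) else as.matrix(mean)
  if (!identical(unname(as.integer(dim(as.array(mean)))), unname(as.integer(dims)))) {
    stop("shape error: mean does not match the q grid")
  }
  if (any(!is.finite(mean))) stop("data error: mean must be finite")
  if (is.null(std)) {
    if (!std_fallback) stop("data error: std absent and fallback not requested")
    std <- abs(mean)
  } else {
    std <- if (q$M == 1L) as.numeric(std) else as.matrix(std)
  }
  if (!identical(dim(as.array(std)), dim(as.array(mean)))) {
    stop("shape error: std does not match mean")
  }
  if (any(!is.finite(std)) || any(std <= 0)) {
    stop("data error: std must be finite and > 0")
  }
  if (!is.null(dq)) {
    if (q$M != 1L) stop("dq resolution widths apply to 1D data")
    dq <- as.numeric(dq)
    if (length(dq) != dims[1]) stop("shape error: dq length mismatch")
    if (any(dq < 0)) stop("data error: dq must be >= 0")
  }
  structure(list(q = q, mean = mean, std = std, dq = dq),
            class = "intensity_data")
}

#' @export
print.intensity_data <- function(x, ...) {
  cat(sprintf("<intensity_data> %s points (M = %d), I in [%.3g, %.3g]\n",
              paste(q_grid_lengths(x$q), collapse = " x "), x$q$M,
              min(x$mean), max(x$mean)))
  invisible(x)
}

#' Normalized intensity misfit
#'
#' The sigma-normalized residual `(I_pred - mean) / std`, the quantity whose
#' squared Frobenius norm is the chi-squared fitting error. Normalizing by the
#' observational standard deviation downweights uncertain points and puts the
#' decades-spanning intensity values on a common scale.
#'
#' @param pred Predicted intensity in the shape of the data.
#' @param data An [intensity_data()].
#' @return The misfit array, same shape as the data.
#' @export
normalized_misfit <- function(pred, data) {
  stopifnot(inherits(data, "intensity_data"))
  if (length(pred) != length(data$mean)) {
    stop("shape error: prediction does not match data")
  }
  (pred - data$mean) / data$std
}

#' Chi-squared fitting error
#'
#' Sum of squares of the normalized misfit (its squared Frobenius norm for 2D
#' data); the negative log-likelihood up to constants.
#'
#' @param eps Normalized misfit as returned by [normalized_misfit()].
#' @return A non-negative scalar, zero iff the prediction matches the mean.
#' @export
chi_squared <- function(eps) {
  if (any(!is.finite(eps))) stop("misfit must be finite")
  sum(eps^2)
}
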