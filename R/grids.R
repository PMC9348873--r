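#' Discretized model-parameter axis
#'
#' A `param_grid` holds the discretization of one polydisperse model parameter
#' (e.g. sphere radius in angstroms, or a cylinder orientation angle in
#' radians): an ordered vector of values together with a label and the spacing
#' convention used to build it.
#'
#' @param name Parameter label, e.g. `"radius"`.
#' @param values Strictly increasing numeric vector of length >= 2. Values must
#'   be positive for length-like parameters (the default); set
#'   `positive = FALSE` for parameters such as angles where zero is admissible.
#' @param spacing `"linear"` or `"logarithmic"`; metadata recording how the
#'   grid was constructed.
#' @param positive Require all values > 0 (the rule for lengths and radii).
#' @return An object of class `param_grid`.
#' @export
param_grid <- function(name, values, spacing = c("linear", "logarithmic"),
                       positive = TRUE) {
  spacing <- match.arg(spacing)
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("invalid parameter grid '", name, "': need at least 2 values")
  }
  if (any(!is.finite(values))) {
    stop("invalid parameter grid '", name, "': non-finite values")
  }
  if (any(diff(values) <= 0)) {
    stop("invalid parameter grid '", name, "': values must be strictly increasing")
  }
  if (positive && any(values <= 0)) {
    stop("invalid parameter grid '", name, "': values must be positive")
  }
  structure(list(name = name, values = values, spacing = spacing),
            class = "param_grid")
}

#' Build a parameter grid from a (min, max, n) specification
#'
#' @param name Parameter label.
#' @param min,max Range endpoints (inclusive).
#' @param n Number of grid points.
#' @param spacing `"linear"` or `"logarithmic"` point placement.
#' @param positive Passed to [param_grid()].
#' @return A `param_grid`.
#' @export
param_grid_spec <- function(name, min, max, n,
                            spacing = c("linear", "logarithmic"),
                            positive = TRUE) {
  spacing <- match.arg(spacing)
  if (!(is.finite(min) && is.finite(max) && min < max)) {
    stop("invalid parameter grid '", name, "': need min < max")
  }
  values <- if (spacing == "logarithmic") {
    if (min <= 0) stop("invalid parameter grid '", name,
                       "': logarithmic spacing needs min > 0")
    exp(seq(log(min), log(max), length.out = n))
  } else {
    seq(min, max, length.out = n)
  }
  param_grid(name, values, spacing, positive = positive)
}

#' Scattering-vector grid
#'
#' Holds the q-axes on which intensities are observed: one axis (M = 1, a 1D
#' curve) or two axes (M = 2, a detector image on a rectilinear
#' (q_x, q_y) grid). Units are inverse angstroms.
#'
#' @param ... One or two strictly increasing numeric vectors, optionally named
#'   (default names `"q"` for M = 1 and `"qx"`, `"qy"` for M = 2).
#' @return An object of class `q_grid` with fields `axes` (named list) and `M`.
#' @export
q_grid <- function(...) {
  axes <- list(...)
  if (length(axes) == 1L && is.list(axes[[1]]) && !is.numeric(axes[[1]])) {
    axes <- axes[[1]]
  }
  M <- length(axes)
  if (!M %in% 1:2) stop("invalid q grid: M must be 1 or 2, got ", M)
  axes <- lapply(axes, as.numeric)
  for (a in axes) {
    if (length(a) < 1L || any(!is.finite(a))) {
      stop("invalid q grid: axes must be finite")
    }
    if (length(a) > 1L && any(diff(a) <= 0)) {
      stop("invalid q grid: axes must be strictly increasing")
    }
  }
  if (is.null(names(axes)) || any(names(axes) == "")) {
    names(axes) <- if (M == 1L) "q" else c("qx", "qy")
  }
  structure(list(axes = axes, M = M), class = "q_grid")
}

q_grid_lengths <- function(q) vapply(q$axes, length, integer(1))

#' @export
print.param_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<param_grid> %s: %d points in [%g, %g] (%s)\n",
              x$name, length(v), v[1], v[length(v)], x$spacing))
  invisible(x)
}

#' @export
print.q_grid <- function(x, ...) {
  cat(sprintf("<q_grid> M = %d: %s\n", x$M,
              paste(sprintf("%s[%d]", names(x$axes), q_grid_lengths(x)),
                    collapse = " x ")))
  invisible(x)
}

# Total number of observation points (product of q-axis lengths).
n_q_points <- function(q) prod(q_grid_lengths(q))

# Flattened |q| magnitudes in array (column-major) order, used by isotropic
# corrections (structure factor, power-law background) on 2D grids.
q_magnitudes <- function(q) {
  if (q$M == 1L) {
    q$axes[[1]]
  } else {
    qx <- q$axes[[1]]; qy <- q$axes[[2]]
    sqrt(outer(qx^2, qy^2, `+`))
  }
}
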