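#' Background specification
#'
#' @param kind `"flat"` (constant level `b`) or `"power_law"`
#'   (`b(q) = A * q^(-B)`, evaluated on `|q|`, the usual empirical form for
#'   diffuse scattering backgrounds).
#' @param b Flat level.
#' @param A,B Power-law coefficients (`A >= 0`, `B >= 0` expected).
#' @return An object of class `background_spec`.
#' @export
background_spec <- function(kind = c("flat", "power_law"), b = 0, A = 0, B = 0) {
  kind <- match.arg(kind)
  structure(list(kind = kind, b = b, A = A, B = B), class = "background_spec")
}

#' Power-law background on a q grid
#'
#' Evaluates `b(q) = A * q^(-B)` on the grid (on `|q|` for 2D grids, i.e. an
#' isotropic background).
#'
#' @param q A [q_grid()] or numeric vector of positive q values.
#' @param A Amplitude (>= 0).
#' @param B Exponent (>= 0 for the typical decreasing background).
#' @return Background values in the shape of the q grid.
#' @export
power_law_background <- function(q, A, B) {
  qm <- if (inherits(q, "q_grid")) q_magnitudes(q) else as.numeric(q)
  if (B != 0 && any(qm <= 0)) {
    stop("domain error: power-law background needs q > 0")
  }
  A * qm^(-B)
}

eval_background <- function(bg, q) {
  if (bg$kind == "flat") {
    qm <- q_magnitudes(q)
    qm * 0 + bg$b
  } else {
    power_law_background(q, bg$A, bg$B)
  }
}

#' Set of parameter distributions plus scale and background
#'
#' Bundles the N density vectors (one per model parameter, each non-negative
#' and summing to one), the compound scale `xi` (total volume fraction over
#' mean particle volume, times the squared contrast when the Green tensor was
#' built with unit contrast) and the background.
#'
#' @param weights Named list of N numeric densities matching the parameter
#'   grids of the Green tensor they will be contracted with.
#' @param xi Non-negative scalar scale.
#' @param background A [background_spec()] (default flat zero).
#' @param extras Named list of extra scalar variables (e.g. `r_eff`, `V_f`,
#'   power-law `A`/`B`) recorded with a solution.
#' @param normalize Renormalize each weight vector to sum to one (default
#'   FALSE: off-simplex input is an error).
#' @return An object of class `distribution_set`.
#' @export
distribution_set <- function(weights, xi = 1, background = background_spec(),
                             extras = list(), normalize = FALSE) {
  if (!is.list(weights)) weights <- list(weights)
  weights <- lapply(weights, as.numeric)
  for (k in seq_along(weights)) {
    w <- weights[[k]]
    if (any(!is.finite(w)) || any(w < 0)) {
      stop("weights must be finite and non-negative")
    }
    s <- sum(w)
    if (normalize) {
      if (s <= 0) stop("cannot normalize an all-zero weight vector")
      weights[[k]] <- w / s
    } else if (abs(s - 1) > 1e-10) {
      stop("weights must sum to 1 (got ", format(s), ")")
    }
  }
  if (!is.finite(xi) || xi < 0) stop("xi must be finite and >= 0")
  structure(list(weights = weights, xi = xi, background = background,
                 extras = extras), class = "distribution_set")
}

# ---- tensor contraction ----------------------------------------------------

# Contract the trailing parameter axes of a Green-tensor data array with the
# weight vectors, optionally skipping one parameter ('skip', index within the
# parameter list). Returns the intensity array over the q axes (skip = NULL)
# or the partially contracted matrix with the skipped axis last.
contract_data <- function(data, M, weights, skip = NULL) {
  d <- dim(data)
  N <- length(d) - M
  stopifnot(length(weights) == N)
  if (!is.null(skip)) {
    # move the kept axis to just after the q axes so the loop below can
    # consume the remaining parameter axes from the tail
    perm <- c(seq_len(M), M + skip, setdiff(M + seq_len(N), M + skip))
    data <- aperm(data, perm)
    d <- dim(data)
    ord <- setdiff(seq_len(N), skip)
  } else {
    ord <- seq_len(N)
  }
  # contract trailing axes; axes are consumed from the tail so no
  # intermediate ever exceeds the input size
  for (i in rev(seq_along(ord))) {
    k <- ord[i]
    nd <- length(d)
    data <- matrix(data, prod(d[-nd]), d[nd]) %*% weights[[k]]
    d <- d[-nd]
    dim(data) <- d
  }
  data
}

# Full contraction of a green_tensor with a list of weights; returns the
# intensity array on the q grid (no xi, no background).
contract_green <- function(G, weights, skip = NULL) {
  contract_data(G$data, G$q_grid$M, weights, skip = skip)
}

# Chunked contraction along the first q axis: pure plumbing, must agree with
# contract_green to machine precision for any partition.
contract_green_chunked <- function(G, weights, n_chunks = 2L) {
  d <- dim(G$data)
  M <- G$q_grid$M
  idx <- parallel_splits(d[1], n_chunks)
  out <- array(0, d[seq_len(M)])
  for (rows in idx) {
    blk <- slice_first_axis(G$data, rows, d)
    res <- contract_data(blk, M, weights)
    if (M == 1L) out[rows] <- res else out[rows, ] <- res
  }
  out
}

parallel_splits <- function(n, k) {
  k <- max(1L, min(as.integer(k), n))
  breaks <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) (breaks[i] + 1):breaks[i + 1])
}

slice_first_axis <- function(data, rows, d) {
  m <- matrix(data, d[1], prod(d[-1]))[rows, , drop = FALSE]
  array(m, c(length(rows), d[-1]))
}

#' Forward intensity of a distribution set
#'
#' Evaluates the multi-linear forward map: the Green tensor is contracted with
#' every parameter distribution, scaled by `xi`, and the background is added:
#' `I = xi * sum_j G[., j1..jN] prod_k w_k[jk] + b(q)`.
#'
#' @param G A `green_tensor`.
#' @param d A [distribution_set()] whose weights match `G`'s parameter grids.
#' @return The intensity on the q grid: a vector (M = 1) or matrix (M = 2).
#' @export
intensity <- function(G, d) {
  stopifnot(inherits(G, "green_tensor"), inherits(d, "distribution_set"))
  nk <- vapply(G$param_grids, function(p) length(p$values), integer(1))
  got <- vapply(d$weights, length, integer(1))
  if (length(got) != length(nk) || any(got != nk)) {
    stop("contraction error: weights do not match the parameter grids")
  }
  base <- contract_green(G, d$weights)
  out <- d$xi * base + eval_background(d$background, G$q_grid)
  if (G$q_grid$M == 1L) as.numeric(out) else out
}

#' Uniform-contrast equivalence of two populations
#'
#' Two sphere populations with different contrasts `(xiA, wA)` and
#' `(xiB, wB)` on the same grid produce the same intensity as a single
#' uniform-contrast population `(xiU, wU)` with `xiU * wU = xiA * wA +
#' xiB * wB`. This is why inversion with multiple free contrasts is
#' fundamentally underdetermined.
#'
#' @param xiA,xiB Non-negative scales.
#' @param wA,wB Densities on a common grid.
#' @return A list with `xi` and `w` of the equivalent uniform population.
#' @export
uniform_contrast_equivalence <- function(xiA, wA, xiB, wB) {
  if (length(wA) != length(wB)) stop("shape error: densities on different grids")
  xiU <- xiA + xiB
  if (xiU == 0) return(list(xi = 0, w = wA))
  if (xiB == 0) return(list(xi = xiA, w = wA))
  if (xiA == 0) return(list(xi = xiB, w = wB))
  list(xi = xiU, w = (xiA * wA + xiB * wB) / xiU)
}
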