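#' Resolution smearing matrix
#'
#' Builds the row-stochastic linear operator that models instrumental
#' q-resolution smearing of a 1D intensity curve. Each row i is a Gaussian
#' kernel of standard deviation `dq[i]` centred at `q[i]`, evaluated at the
#' grid points, truncated at plus/minus 3 `dq[i]` and renormalized to sum to
#' one; `dq[i] = 0` gives a delta row (no smearing at that point).
#'
#' @param q A [q_grid()] with M = 1 or a numeric q vector.
#' @param dq Per-point resolution standard deviations (same length as q,
#'   >= 0). If `NULL`, `dq_fraction` of the local grid spacing is used.
#' @param dq_fraction Fallback width as a fraction of the local q spacing,
#'   used when `dq` is absent (default 0.5).
#' @return An object of class `smearing_matrix`: the weight matrix `W` with
#'   non-negative rows summing to one.
#' @export
smearing_matrix <- function(q, dq = NULL, dq_fraction = 0.5) {
  qv <- if (inherits(q, "q_grid")) {
    if (q$M != 1L) stop("smearing is defined on 1D q grids")
    q$axes[[1]]
  } else as.numeric(q)
  n <- length(qv)
  if (is.null(dq)) {
    h <- diff(qv)
    dq <- dq_fraction * c(h[1], (h[-1] + h[-(n - 1)]) / 2, h[n - 1])
  }
  dq <- as.numeric(dq)
  if (length(dq) != n) stop("shape error: dq must have the same length as q")
  if (any(!is.finite(dq)) || any(dq < 0)) stop("dq must be finite and >= 0")
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (dq[i] == 0) {
      W[i, i] <- 1
    } else {
      w <- exp(-0.5 * ((qv - qv[i]) / dq[i])^2)
      w[abs(qv - qv[i]) > 3 * dq[i]] <- 0
      W[i, ] <- w / sum(w)
    }
  }
  structure(list(weights = W, q = qv, dq = dq), class = "smearing_matrix")
}

#' Apply resolution smearing to a Green tensor
#'
#' Left-multiplies the q axis of a 1D-data Green tensor by the smearing
#' weights, so that the smeared forward intensity equals the smearing of the
#' unsmeared intensity (the correction commutes with the multi-linear
#' contraction).
#'
#' @param G A `green_tensor` with M = 1.
#' @param W A [smearing_matrix()] on the same q grid.
#' @return The smeared `green_tensor` (same shape).
#' @export
apply_smearing <- function(G, W) {
  stopifnot(inherits(G, "green_tensor"), inherits(W, "smearing_matrix"))
  if (G$q_grid$M != 1L) stop("smearing is defined on 1D q grids")
  d <- dim(G$data)
  if (nrow(W$weights) != d[1]) stop("shape error: smearing matrix does not match q grid")
  dat <- W$weights %*% matrix(G$data, d[1], prod(d[-1]))
  G$data <- array(dat, d)
  G$meta$corrections <- union(G$meta$corrections, "smearing")
  G
}
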