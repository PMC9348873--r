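#' Green tensor of polydispersity
#'
#' The Green tensor G is a rank-(M + N) array mapping N model-parameter
#' distributions to the M-dimensional scattering intensity by multi-linear
#' contraction. Entry G[i1..iM, j1..jN] is the squared scattering amplitude
#' (the form factor) of a monodisperse system with parameters
#' (p1[j1], ..., pN[jN]) observed at q-point (q1[i1], ..., qM[iM]).
#'
#' @param data Numeric array of dim `c(q-axis lengths, parameter-grid lengths)`.
#' @param q_grid A [q_grid()].
#' @param param_grids Named list of [param_grid()]s, in tensor-axis order.
#' @param contrast Scattering-length-density contrast used (default 1; the
#'   unknown true contrast is then absorbed into the compound scale xi).
#' @param volumes Particle volume per parameter combination, in cubic
#'   angstroms: a vector over the single size axis (N = 1) or an array over the
#'   parameter axes it depends on, named by `volume_dims`.
#' @param volume_dims Names of the parameter grids the `volumes` array spans.
#' @param meta List of free-form metadata (model name, corrections applied).
#' @return An object of class `green_tensor`.
#' @export
green_tensor <- function(data, q_grid, param_grids, contrast = 1,
                         volumes = NULL, volume_dims = NULL, meta = list()) {
  stopifnot(inherits(q_grid, "q_grid"))
  if (is.null(names(param_grids))) {
    names(param_grids) <- vapply(param_grids, function(p) p$name, character(1))
  }
  want <- c(q_grid_lengths(q_grid),
            vapply(param_grids, function(p) length(p$values), integer(1)))
  data <- as.array(data)
  if (!identical(unname(dim(data)), unname(as.integer(want)))) {
    stop("green tensor shape ", paste(dim(data), collapse = "x"),
         " inconsistent with grids ", paste(want, collapse = "x"))
  }
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("green tensor entries must be finite and >= 0 (a squared amplitude)")
  }
  if (is.null(meta$corrections)) meta$corrections <- character(0)
  structure(list(data = data, q_grid = q_grid, param_grids = param_grids,
                 contrast = contrast, volumes = volumes,
                 volume_dims = volume_dims, meta = meta),
            class = "green_tensor")
}

#' @export
print.green_tensor <- function(x, ...) {
  cat(sprintf("<green_tensor> %s: %s (M = %d, N = %d)%s\n",
              x$meta$model %||% "custom",
              paste(dim(x$data), collapse = " x "),
              x$q_grid$M, length(x$param_grids),
              if (length(x$meta$corrections))
                paste0(" [", paste(x$meta$corrections, collapse = ", "), "]")
              else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rayleigh sphere amplitude factor Phi(x) = 3 (sin x - x cos x) / x^3.
# The closed form loses ~3 eps / x^2 significant digits to cancellation as
# x -> 0 (its numerator is O(x^3)), so the series is used below x = 0.01,
# where its truncation error (~x^6/15120) is below machine epsilon.
sphere_phi <- function(x) {
  out <- x * 0
  small <- abs(x) < 1e-2
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Sphere form-factor Green tensor
#'
#' Builds the rank-2 Green tensor for polydisperse uniform spheres on a 1D q
#' grid: `G[i, j] = (v_j * contrast * Phi(q_i * r_j))^2` with
#' `Phi(x) = 3 (sin x - x cos x) / x^3` (the Rayleigh amplitude) and
#' `v_j = (4/3) pi r_j^3` the sphere volume.
#'
#' @param q A [q_grid()] with M = 1 and positive values.
#' @param r A [param_grid()] of sphere radii (angstroms, > 0).
#' @param contrast Scattering-length-density contrast (default 1).
#' @return A `green_tensor` of shape `(|q|, |r|)` with sphere volumes attached.
#' @export
sphere_form_green <- function(q, r, contrast = 1) {
  if (inherits(q, "param_grid")) stop("q must be a q_grid")
  if (is.numeric(q)) q <- q_grid(q)
  stopifnot(inherits(q, "q_grid"), inherits(r, "param_grid"))
  if (q$M != 1L) stop("invalid grid: sphere model expects M = 1")
  qv <- q$axes[[1]]
  rv <- r$values
  if (any(qv <= 0)) stop("invalid grid: q values must be positive")
  if (any(rv <= 0)) stop("invalid grid: radii must be positive")
  v <- (4 / 3) * pi * rv^3
  amp <- sphere_phi(outer(qv, rv)) # |q| x |r|
  G <- sweep(amp, 2L, v * contrast, `*`)^2
  green_tensor(G, q, list(radius = r), contrast = contrast,
               volumes = v, volume_dims = "radius",
               meta = list(model = "sphere"))
}

# sin(x)/x with series fill-in near 0
sinc <- function(x) {
  out <- x * 0
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- 1 - xs^2 / 6 + xs^4 / 120
  xl <- x[!small]
  out[!small] <- sin(xl) / xl
  out
}

# 2 J1(x) / x with series fill-in near 0
bessel_j1c <- function(x) {
  out <- x * 0
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- 1 - xs^2 / 8 + xs^4 / 192
  xl <- x[!small]
  out[!small] <- 2 * besselJ(xl, 1) / xl
  out
}

# Scalar cylinder kernel: squared amplitude of a uniform right cylinder of
# length l, radius r, axis direction (theta from beam, phi about beam), at
# in-plane scattering vector (qx, qy). Exposed for the oracle tests.
cylinder_kernel_scalar <- function(qx, qy, l, r, theta, phi, contrast = 1) {
  qn <- sqrt(qx^2 + qy^2)
  v <- pi * r^2 * l
  if (qn == 0) return((v * contrast)^2)
  cosa <- (qx * sin(theta) * cos(phi) + qy * sin(theta) * sin(phi)) / qn
  cosa <- max(-1, min(1, cosa))
  sina <- sqrt(1 - cosa^2)
  A <- v * contrast * sinc(qn * l * cosa / 2) * bessel_j1c(qn * r * sina)
  A^2
}

#' Cylinder form-factor Green tensor on a 2D detector grid
#'
#' Builds the rank-6 Green tensor for polydisperse right cylinders observed as
#' a 2D intensity image. The four model parameters are length `l`, radius `r`,
#' the angle `theta` from the cylinder axis to the beam, and the rotation `phi`
#' of the axis projection about the beam (both radians). With `alpha` the angle
#' between the in-plane scattering vector `(qx, qy, 0)` and the cylinder axis,
#' the amplitude is
#' `A = v * contrast * sinc(q l cos(alpha) / 2) * 2 J1(q r sin(alpha)) / (q r sin(alpha))`
#' and `G = A^2`, with `v = pi r^2 l`. Removable singularities (forward
#' scattering, `alpha` at 0 or pi/2) are evaluated by their series limits.
#'
#' @param qx,qy Numeric q-axes (inverse angstroms), strictly increasing; zero
#'   and negative values are allowed (detector coordinates).
#' @param l,r [param_grid()]s of cylinder lengths and radii (> 0).
#' @param theta,phi [param_grid()]s of orientation angles in radians.
#' @param contrast Scattering-length-density contrast (default 1).
#' @param mem_budget_bytes In-core memory budget; a tensor exceeding it is
#'   refused with a size estimate unless `store` names a directory, in which
#'   case the tensor is built and written chunk-wise along the `qx` axis and
#'   the store path is returned.
#' @param store Optional directory for the chunked on-disk build.
#' @return A `green_tensor` of shape `(|qx|, |qy|, |l|, |r|, |theta|, |phi|)`,
#'   or (chunked path) the store directory, invisibly.
#' @export
cylinder_form_green_2d <- function(qx, qy, l, r, theta, phi, contrast = 1,
                                   mem_budget_bytes = 4e9, store = NULL) {
  stopifnot(inherits(l, "param_grid"), inherits(r, "param_grid"),
            inherits(theta, "param_grid"), inherits(phi, "param_grid"))
  qx <- as.numeric(qx); qy <- as.numeric(qy)
  if (any(diff(qx) <= 0) || any(diff(qy) <= 0)) {
    stop("invalid grid: q axes must be strictly increasing")
  }
  dims <- c(length(qx), length(qy), length(l$values), length(r$values),
            length(theta$values), length(phi$values))
  bytes <- 8 * prod(dims)
  if (bytes > mem_budget_bytes && is.null(store)) {
    stop(sprintf(paste0("cylinder Green tensor of shape %s requires %.3g GB, ",
                        "exceeding the %.3g GB memory budget; pass a 'store' ",
                        "directory for the chunked on-disk build"),
                 paste(dims, collapse = " x "), bytes / 1e9,
                 mem_budget_bytes / 1e9))
  }

  build_block <- function(qx_block) {
    d <- c(length(qx_block), dims[-1])
    G <- array(0, d)
    lv <- l$values; rv <- r$values; tv <- theta$values; pv <- phi$values
    qn <- sqrt(outer(qx_block^2, qy^2, `+`))
    qpos <- qn > 0
    for (it in seq_along(tv)) {
      st <- sin(tv[it])
      for (ip in seq_along(pv)) {
        # cos(alpha) on the (qx, qy) block; forward-scattering points get 0
        # (their factors are 1 by the series limits anyway)
        ca <- outer(qx_block * st * cos(pv[ip]), rep(st * sin(pv[ip]),
                    length(qy)) * qy, `+`)
        ca[qpos] <- ca[qpos] / qn[qpos]
        ca[!qpos] <- 0
        ca <- pmin(1, pmax(-1, ca))
        sa <- sqrt(1 - ca^2)
        for (il in seq_along(lv)) {
          axial <- sinc(qn * lv[il] * ca / 2)
          for (ir in seq_along(rv)) {
            v <- pi * rv[ir]^2 * lv[il]
            A <- (v * contrast) * axial * bessel_j1c(qn * rv[ir] * sa)
            G[, , il, ir, it, ip] <- A^2
          }
        }
      }
    }
    G
  }

  qg <- q_grid(qx = qx, qy = qy)
  pgrids <- list(length = l, radius = r, theta = theta, phi = phi)
  vols <- pi * outer(l$values, r$values^2)
  if (is.null(store)) {
    G <- build_block(qx)
    return(green_tensor(G, qg, pgrids, contrast = contrast,
                        volumes = vols, volume_dims = c("length", "radius"),
                        meta = list(model = "cylinder")))
  }
  # chunk-to-disk path: blocks along qx sized so each chunk <= budget / 4
  rows_per_chunk <- max(1L, floor(mem_budget_bytes / 4 / (8 * prod(dims[-1]))))
  starts <- seq(1L, length(qx), by = rows_per_chunk)
  dir.create(store, recursive = TRUE, showWarnings = FALSE)
  chunk_files <- character(0)
  for (ci in seq_along(starts)) {
    idx <- starts[ci]:min(starts[ci] + rows_per_chunk - 1L, length(qx))
    blk <- build_block(qx[idx])
    f <- file.path(store, sprintf("data_chunk_%04d.bin", ci))
    con <- file(f, "wb")
    writeBin(as.vector(blk), con, size = 8, endian = "little")
    close(con)
    chunk_files <- c(chunk_files, basename(f))
  }
  write_green_meta(store, model = "cylinder", dims = dims, q_grid = qg,
                   param_grids = pgrids, contrast = contrast,
                   corrections = character(0), chunk_rows = rows_per_chunk,
                   chunk_files = chunk_files)
  invisible(store)
}

#' Apply a structure factor along the q axes
#'
#' Implements the "G = P S" factorization: the form-factor Green tensor is
#' multiplied entry-wise by the (isotropic) structure factor evaluated on the
#' q grid, correcting for inter-particle interference in non-dilute systems.
#'
#' @param G A `green_tensor`.
#' @param S Numeric structure-factor values: a vector over the q axis (M = 1)
#'   or a matrix over the (qx, qy) grid (M = 2), as returned by
#'   [hard_sphere_structure()].
#' @return The corrected `green_tensor`.
#' @export
apply_structure <- function(G, S) {
  nq <- n_q_points(G$q_grid)
  if (length(S) != nq) stop("structure factor length does not match q grid")
  if (any(!is.finite(S)) || any(S <= 0)) stop("structure factor must be positive")
  d <- dim(G$data)
  dat <- array(as.vector(G$data) * as.vector(S), d) # q axes vary fastest
  G$data <- dat
  G$meta$corrections <- union(G$meta$corrections, "structure_factor")
  G
}

#' Volume weighting of a Green tensor
#'
#' Divides the tensor by the particle volume `v_j` along the size axes, so
#' that inversion with the weighted tensor yields the volume-weighted
#' distribution directly (the conventional presentation of size-inversion
#' results).
#'
#' @param G A `green_tensor` with `volumes` metadata.
#' @return The volume-weighted `green_tensor`.
#' @export
volume_weight <- function(G) {
  if (is.null(G$volumes)) {
    stop("configuration error: green tensor has no volumes metadata")
  }
  if (any(G$volumes <= 0)) stop("volumes must be positive")
  pnames <- names(G$param_grids)
  vdims <- match(G$volume_dims, pnames) + G$q_grid$M
  d <- dim(G$data)
  # broadcast 1/v over the non-volume axes
  perm <- c(vdims, setdiff(seq_along(d), vdims))
  dat <- aperm(G$data, perm)
  dat <- array(as.vector(dat) / as.vector(G$volumes), dim(dat))
  G$data <- aperm(dat, order(perm))
  G$meta$corrections <- union(G$meta$corrections, "volume_weighted")
  G
}
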