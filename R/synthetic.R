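#' Benchmark case container
#'
#' @param truth The generating [distribution_set()].
#' @param G The `green_tensor` used.
#' @param data The [intensity_data()] observation (mean is the exact forward
#'   intensity of the truth; noise enters only through the assumed standard
#'   deviation).
#' @param provenance List recording generator name, seed and parameters.
#' @return An object of class `benchmark_case`.
#' @export
benchmark_case <- function(truth, G, data, provenance) {
  structure(list(truth = truth, G = G, data = data, provenance = provenance),
            class = "benchmark_case")
}

#' @export
print.benchmark_case <- function(x, ...) {
  cat(sprintf("<benchmark_case> %s (seed %s)\n", x$provenance$generator,
              format(x$provenance$seed)))
  print(x$G)
  print(x$data)
  invisible(x)
}

#' Bimodal sphere benchmark (Gaussian + Boltzmann size distribution)
#'
#' Polydisperse spheres whose radius density is an equal-mass mixture of a
#' Gaussian (centre 500 A, width 20 A) and a Boltzmann-type two-sided
#' exponential (centre 650 A, width 30 A), discretized by `n_r` points on
#' `r_range`. The q grid is log-spaced on `q_range` with `n_q` points. The
#' observed mean is the exact forward intensity (no additive noise), and the
#' assumed per-point standard deviation is drawn uniformly in 20-30% of the
#' mean, so the maximum-likelihood estimator is the truth itself regardless of
#' the assumed error.
#'
#' @param seed Integer seed for the per-point error fractions.
#' @param n_r,n_q Grid resolutions (defaults 500 and 200).
#' @param r_range,q_range Grid ranges in angstroms / inverse angstroms.
#' @return A [benchmark_case()].
#' @export
bimodal_sphere_benchmark <- function(seed = 1L, n_r = 500L, n_q = 200L,
                                     r_range = c(400, 800),
                                     q_range = c(1e-3, 1)) {
  r <- param_grid_spec("radius", r_range[1], r_range[2], n_r)
  q <- q_grid(q = exp(seq(log(q_range[1]), log(q_range[2]),
                          length.out = n_q)))
  rv <- r$values
  gauss <- exp(-0.5 * ((rv - 500) / 20)^2)
  boltz <- exp(-abs(rv - 650) / 30)
  w <- gauss / sum(gauss) / 2 + boltz / sum(boltz) / 2
  w <- w / sum(w)
  truth <- distribution_set(list(radius = w), xi = 1,
                            background = background_spec("flat", b = 0))
  G <- sphere_form_green(q, r)
  mu <- intensity(G, truth)
  set.seed(seed)
  frac <- stats::runif(n_q, 0.2, 0.3)
  data <- intensity_data(q, mu, std = frac * mu)
  benchmark_case(truth, G, data,
                 list(generator = "bimodal_sphere_benchmark", seed = seed,
                      n_r = n_r, n_q = n_q, r_range = r_range,
                      q_range = q_range))
}

#' Stochastic sphere benchmark (white-noise size distribution)
#'
#' A drastically varying size distribution: independent uniform positive
#' white noise over `n_r` radius bins, normalized to the simplex. The mean
#' intensity is exact and the standard deviation is set equal to the mean,
#' the conventional stand-in when no experimental error estimate exists.
#' Recovery of this truth requires driving chi-squared deep into the
#' overfitting regime.
#'
#' @param seed Integer seed for the white-noise truth.
#' @param n_r,n_q Grid resolutions (defaults 300 and 2000).
#' @param r_range,q_range Grid ranges.
#' @return A [benchmark_case()].
#' @export
stochastic_sphere_benchmark <- function(seed = 1L, n_r = 300L, n_q = 2000L,
                                        r_range = c(400, 800),
                                        q_range = c(1e-3, 1)) {
  r <- param_grid_spec("radius", r_range[1], r_range[2], n_r)
  q <- q_grid(q = exp(seq(log(q_range[1]), log(q_range[2]),
                          length.out = n_q)))
  set.seed(seed)
  w <- stats::runif(n_r)
  w <- w / sum(w)
  truth <- distribution_set(list(radius = w), xi = 1,
                            background = background_spec("flat", b = 0))
  G <- sphere_form_green(q, r)
  mu <- intensity(G, truth)
  data <- intensity_data(q, mu, std = mu)
  benchmark_case(truth, G, data,
                 list(generator = "stochastic_sphere_benchmark", seed = seed,
                      n_r = n_r, n_q = n_q, r_range = r_range,
                      q_range = q_range))
}

#' Four-parameter cylinder benchmark (2D intensity image)
#'
#' Polydisperse cylinders with four parameter distributions -- length,
#' radius, axis-to-beam angle theta and axis rotation phi -- observed as a 2D
#' intensity image on a square (qx, qy) grid spanning -1 to 1 inverse
#' angstroms. Truths are smooth unimodal (Gaussian) densities per parameter.
#' The full paper-scale problem (40 bins per parameter, 120 x 120 image)
#' yields a 295 GB Green tensor and is refused unless explicitly
#' acknowledged; the `mini` scale (10 bins per parameter, 32 x 32 image) is
#' the desk-sized stand-in.
#'
#' @param scale `"mini"` or `"full"`.
#' @param seed Integer seed (recorded; the generator itself is deterministic
#'   apart from provenance).
#' @param acknowledge_memory Must be TRUE to attempt the full scale.
#' @param n_bins,n_q Mini-scale resolutions (defaults 10 and 32).
#' @return A [benchmark_case()].
#' @export
cylinder_benchmark <- function(scale = c("mini", "full"), seed = 1L,
                               acknowledge_memory = FALSE,
                               n_bins = 10L, n_q = 32L) {
  scale <- match.arg(scale)
  if (scale == "full") {
    dims <- c(120, 120, 40, 40, 40, 40)
    gb <- 8 * prod(dims) / 1e9
    if (!acknowledge_memory) {
      stop(sprintf(paste0("full-scale cylinder benchmark: Green tensor ",
                          "%d x %d x %d x %d x %d x %d requires %.0f GB of ",
                          "memory; pass acknowledge_memory = TRUE (and a ",
                          "chunked store) to proceed"),
                   dims[1], dims[2], dims[3], dims[4], dims[5], dims[6], gb))
    }
    n_bins <- 40L
    n_q <- 120L
  }
  qx <- seq(-1, 1, length.out = n_q)
  qy <- seq(-1, 1, length.out = n_q)
  l <- param_grid_spec("length", 50, 150, n_bins)
  r <- param_grid_spec("radius", 10, 40, n_bins)
  theta <- param_grid("theta", seq(0.1, 1.47, length.out = n_bins))
  # phi at midpoints of its pi-period so a uniform phi-truth is exactly
  # azimuthally symmetric on the square grid
  phi <- param_grid("phi", (seq_len(n_bins) - 0.5) * pi / n_bins)
  gpeak <- function(v, centre_frac, width_frac) {
    c0 <- v[1] + centre_frac * (v[length(v)] - v[1])
    s0 <- width_frac * (v[length(v)] - v[1])
    w <- exp(-0.5 * ((v - c0) / s0)^2)
    w / sum(w)
  }
  truth <- distribution_set(
    list(length = gpeak(l$values, 0.4, 0.15),
         radius = gpeak(r$values, 0.5, 0.18),
         theta = gpeak(theta$values, 0.6, 0.2),
         phi = gpeak(phi$values, 0.45, 0.22)),
    xi = 1, background = background_spec("flat", b = 0))
  G <- cylinder_form_green_2d(qx, qy, l, r, theta, phi)
  mu <- intensity(G, truth)
  data <- intensity_data(q_grid(qx = qx, qy = qy), mu, std = mu)
  benchmark_case(truth, G, data,
                 list(generator = "cylinder_benchmark", seed = seed,
                      scale = scale, n_bins = n_bins, n_q = n_q))
}
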