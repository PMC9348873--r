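test_that("sphere kernel matches the quadrature oracle", {
  # independent oracle: A(q, r) = 4 pi int_0^r sin(qs)/(qs) s^2 ds, G = A^2,
  # by composite Simpson quadrature (deterministic, ~1e-13 relative accuracy
  # at these panel counts; the integrand is smooth)
  quad_amp <- function(q, r) {
    n <- 40000L
    svals <- seq(0, r, length.out = n + 1L)[-1]
    f <- sin(q * svals) / (q * svals) * svals^2
    wts <- rep(c(4, 2), length.out = n - 1L)
    h <- r / n
    4 * pi * h / 3 * (0 + sum(wts * f[-n]) + f[n])
  }
  cases <- expand.grid(q = c(1e-4, 1e-2, 0.1), r = c(0.5, 10, 500))
  cases <- rbind(cases, data.frame(q = 0.01, r = 500)) # the spec's example
  for (i in seq_len(nrow(cases))) {
    q <- cases$q[i]; r <- cases$r[i]
    G <- sphere_form_green(q_grid(q = c(q, 2 * q)),
                           param_grid("radius", c(r, r + 1)))
    expected <- quad_amp(q, r)^2
    if (abs(expected) > 1e-6 * ((4 / 3) * pi * r^3)^2) {
      expect_equal(G$data[1, 1], expected, tolerance = 1e-10)
    } else {
      expect_lt(abs(G$data[1, 1] - expected), 1e-10 * ((4 / 3) * pi * r^3)^2)
    }
  }
})

test_that("sphere kernel limits and degenerate inputs", {
  # q -> 0: G -> (v * contrast)^2 = (4 pi / 3)^2 for r = 1
  G <- sphere_form_green(q_grid(q = c(1e-9, 2e-9)), param_grid("radius", c(1, 2)))
  expect_equal(G$data[1, 1], (4 * pi / 3)^2, tolerance = 1e-10)
  # zero contrast kills the tensor
  G0 <- sphere_form_green(q_grid(q = c(0.01, 0.02)),
                          param_grid("radius", c(1, 2)), contrast = 0)
  expect_true(all(G0$data == 0))
  # invalid grids
  expect_error(param_grid("radius", c(-1, 2)), "positive")
  expect_error(param_grid("radius", c(2, 1)), "increasing")
  expect_error(sphere_form_green(q_grid(q = c(-0.1, 0.2)),
                                 param_grid("radius", c(1, 2))), "positive")
})

test_that("sphere tensors are finite and non-negative over wide q*r sweeps", {
  set.seed(3)
  for (rep in 1:5) {
    q <- q_grid(q = sort(stats::runif(40, 1e-3, 10)))
    r <- param_grid("radius", sort(stats::runif(30, 0.5, 100)))
    G <- sphere_form_green(q, r)
    expect_true(all(is.finite(G$data)))
    expect_true(all(G$data >= 0))
  }
  # extreme arguments q*r in [1e-3, 1e3]
  G <- sphere_form_green(q_grid(q = c(1e-3, 1)), param_grid("radius", c(1, 1000)))
  expect_true(all(is.finite(G$data)) && all(G$data >= 0))
})

test_that("cylinder kernel agrees with an independent scalar oracle", {
  # one-line independent evaluation of the standard cylinder amplitude
  oracle <- function(qx, qy, l, r, th, ph) {
    qn <- sqrt(qx^2 + qy^2)
    ca <- (qx * sin(th) * cos(ph) + qy * sin(th) * sin(ph)) / qn
    sa <- sqrt(1 - ca^2)
    f1 <- if (abs(qn * l * ca / 2) < 1e-12) 1 else
      sin(qn * l * ca / 2) / (qn * l * ca / 2)
    x2 <- qn * r * sa
    f2 <- if (abs(x2) < 1e-12) 1 else 2 * besselJ(x2, 1) / x2
    (pi * r^2 * l * f1 * f2)^2
  }
  qx <- c(-0.8, 0.3); qy <- c(-0.5, 0.6)
  l <- param_grid("length", c(40, 90))
  r <- param_grid("radius", c(15, 25))
  th <- param_grid("theta", c(0.4, 1.1))
  ph <- param_grid("phi", c(0.3, 2.0))
  G <- cylinder_form_green_2d(qx, qy, l, r, th, ph)
  set.seed(11)
  for (rep in 1:10) {
    i <- sample(2, 6, replace = TRUE)
    expect_equal(G$data[i[1], i[2], i[3], i[4], i[5], i[6]],
                 oracle(qx[i[1]], qy[i[2]], l$values[i[3]], r$values[i[4]],
                        th$values[i[5]], ph$values[i[6]]),
                 tolerance = 1e-12)
  }
  expect_true(all(is.finite(G$data)) && all(G$data >= 0))
})

test_that("cylinder kernel geometry limits", {
  # theta = 0 (axis along beam): axial factor is 1, G depends on r only
  # through the radial factor with sin(alpha) = 1, hence G / v^2 is
  # independent of the length
  qx <- c(0.2, 0.5); qy <- c(-0.3, 0.4)
  th <- param_grid("theta", c(0, 0.8), positive = FALSE)
  G <- cylinder_form_green_2d(qx, qy, param_grid("length", c(30, 70)),
                              param_grid("radius", c(10, 20)), th,
                              param_grid("phi", c(0.5, 1.5)))
  for (ir in 1:2) {
    rv <- c(10, 20)[ir]
    expect_equal(G$data[, , 1, ir, 1, 1] / (pi * rv^2 * 30)^2,
                 G$data[, , 2, ir, 1, 1] / (pi * rv^2 * 70)^2,
                 tolerance = 1e-12)
  }
  # forward-scattering limit: G -> (v * contrast)^2
  expect_equal(cylinder_kernel_scalar(0, 0, 50, 10, 0.7, 0.3),
               (pi * 10^2 * 50)^2, tolerance = 1e-12)
})

test_that("Percus-Yevick structure factor limits and monotonicity", {
  q <- exp(seq(log(1e-4), log(10), length.out = 400))
  # dilute limit: identically 1
  expect_equal(hard_sphere_structure(q, r_eff = 50, V_f = 0), rep(1, 400))
  # compressibility limit at V_f = 0.2
  S0 <- (1 - 0.2)^4 / (1 + 2 * 0.2)^2
  expect_equal(hard_sphere_structure(1e-9, r_eff = 50, V_f = 0.2), S0,
               tolerance = 1e-10)
  expect_equal(S0, 0.2090, tolerance = 1e-3)
  # the series and closed-form branches agree across their threshold
  expect_equal(hard_sphere_structure(0.0301 / 100, 50, 0.2),
               hard_sphere_structure(0.0299 / 100, 50, 0.2), tolerance = 1e-6)
  # large-q limit -> 1, monotonically beyond the principal peak
  expect_equal(hard_sphere_structure(1e4, 50, 0.3), 1, tolerance = 1e-6)
  S3 <- hard_sphere_structure(q, r_eff = 50, V_f = 0.3)
  peak <- which.max(S3)
  tail_dev <- abs(S3[peak:length(S3)] - 1)
  # the envelope of |S - 1| decays beyond the principal peak
  env <- cummax(rev(tail_dev))
  expect_true(all(diff(env) >= -1e-12))
  # domain errors
  expect_error(hard_sphere_structure(q, 50, 0.8), "V_f")
  expect_error(hard_sphere_structure(q, -1, 0.2), "r_eff")
  # positivity everywhere
  for (vf in c(0.05, 0.2, 0.4, 0.6)) {
    expect_true(all(hard_sphere_structure(q, 30, vf) > 0))
  }
})

test_that("smearing matrix is row-stochastic and matches a brute-force kernel", {
  q <- seq(0.01, 0.2, length.out = 25)
  # dq = 0 gives the identity
  W0 <- smearing_matrix(q, dq = rep(0, 25))
  expect_equal(W0$weights, diag(25))
  # general rows sum to one
  dq <- stats::runif(25, 0, 0.01)
  W <- smearing_matrix(q, dq = dq)
  expect_true(all(W$weights >= 0))
  expect_equal(rowSums(W$weights), rep(1, 25), tolerance = 1e-12)
  # single row equals explicitly normalized Gaussian weights
  i <- 13
  w_ref <- exp(-0.5 * ((q - q[i]) / dq[i])^2)
  w_ref[abs(q - q[i]) > 3 * dq[i]] <- 0
  expect_equal(W$weights[i, ], w_ref / sum(w_ref), tolerance = 1e-14)
  # length mismatch
  expect_error(smearing_matrix(q, dq = rep(0.01, 10)), "shape")
})

test_that("smearing preserves constants and commutes with the contraction", {
  set.seed(5)
  G <- random_green_1d(20, c(6), seed = 5)
  qv <- G$q_grid$axes[[1]]
  W <- smearing_matrix(qv, dq = stats::runif(20, 0, 0.05))
  # constant tensor unchanged (row-stochasticity)
  Gc <- G; Gc$data <- matrix(3.7, 20, 6)
  expect_equal(apply_smearing(Gc, W)$data, Gc$data, tolerance = 1e-12)
  # smear-then-contract equals contract-then-smear
  w <- random_simplex(6)
  lhs <- as.vector(contract_green(apply_smearing(G, W), list(w)))
  rhs <- as.vector(W$weights %*% contract_green(G, list(w)))
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # same shape
  expect_equal(dim(apply_smearing(G, W)$data), dim(G$data))
})

test_that("volume weighting divides by the particle volume", {
  # direct scaling oracle on a random 3x3 tensor
  set.seed(9)
  q <- q_grid(q = c(0.1, 0.2, 0.3))
  r <- param_grid("radius", c(1, 2, 4))
  dat <- matrix(stats::runif(9), 3, 3)
  G <- green_tensor(dat, q, list(radius = r), volumes = c(1, 2, 4),
                    volume_dims = "radius")
  Gw <- volume_weight(G)
  expect_equal(Gw$data, sweep(dat, 2, c(1, 2, 4), `/`), tolerance = 1e-15)
  # unit volumes leave the tensor unchanged
  G1 <- green_tensor(dat, q, list(radius = r), volumes = rep(1, 3),
                     volume_dims = "radius")
  expect_equal(volume_weight(G1)$data, dat)
  # sphere tensor at q -> 0 becomes v_j * contrast^2 after weighting
  Gs <- sphere_form_green(q_grid(q = c(1e-9, 2e-9)),
                          param_grid("radius", c(1, 3)))
  Gsv <- volume_weight(Gs)
  v <- (4 / 3) * pi * c(1, 3)^3
  expect_equal(Gsv$data[1, ], v, tolerance = 1e-8)
  # missing volumes is a configuration error
  Gn <- green_tensor(dat, q, list(radius = r))
  expect_error(volume_weight(Gn), "volumes")
})

test_that("oversize cylinder tensors are refused with a size estimate", {
  l <- param_grid_spec("length", 50, 150, 40)
  r <- param_grid_spec("radius", 10, 40, 40)
  th <- param_grid_spec("theta", 0.1, 1.5, 40)
  ph <- param_grid_spec("phi", 0.1, 3.1, 40)
  expect_error(
    cylinder_form_green_2d(seq(-1, 1, length.out = 120),
                           seq(-1, 1, length.out = 120), l, r, th, ph),
    "295 GB")
})
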