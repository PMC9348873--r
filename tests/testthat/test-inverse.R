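test_that("normalized misfit and chi-squared match direct oracles", {
  set.seed(70)
  q <- q_grid(q = sort(stats::runif(10, 0.01, 1)))
  mu <- stats::runif(10, 1, 5)
  sig <- stats::runif(10, 0.1, 0.5)
  data <- intensity_data(q, mu, std = sig)
  pred <- stats::runif(10, 1, 5)
  eps <- normalized_misfit(pred, data)
  for (i in 1:10) expect_equal(eps[i], (pred[i] - mu[i]) / sig[i])
  expect_equal(normalized_misfit(mu, data), rep(0, 10))
  expect_equal(chi_squared(eps), sum(((pred - mu) / sig)^2))
  expect_equal(chi_squared(c(1, -2)), 5)
  expect_equal(chi_squared(rep(0, 4)), 0)
  # sigma validation
  expect_error(intensity_data(q, mu, std = c(sig[-1], 0)), "std")
  # std fallback takes the mean
  d2 <- intensity_data(q, mu)
  expect_equal(d2$std, mu)
})

test_that("slack encoding round-trips and always decodes feasibly", {
  # uniform density encodes to 1/sqrt(n)
  d <- distribution_set(list(rep(0.25, 4)))
  s <- slack_encode(d)
  expect_equal(s$s[[1]], rep(0.5, 4))
  expect_equal(slack_decode(s)$weights[[1]], rep(0.25, 4), tolerance = 1e-12)
  # one-hot round trip
  d1 <- distribution_set(list(c(1, 0)))
  expect_equal(slack_decode(slack_encode(d1))$weights[[1]], c(1, 0))
  # random densities round-trip to 1e-12; arbitrary signs stay feasible
  set.seed(71)
  for (rep in 1:20) {
    w <- random_simplex(sample(2:30, 1))
    d <- distribution_set(list(w), xi = stats::runif(1, 0, 5))
    rt <- slack_decode(slack_encode(d))
    expect_equal(rt$weights[[1]], w, tolerance = 1e-12)
    expect_equal(rt$xi, d$xi, tolerance = 1e-12)
    st <- slack_encode(d)
    st$s[[1]] <- st$s[[1]] * sample(c(-1, 1), length(w), replace = TRUE) * 3.7
    dec <- slack_decode(st)$weights[[1]]
    expect_true(all(dec >= 0))
    expect_equal(sum(dec), 1, tolerance = 1e-12)
    expect_equal(dec, w, tolerance = 1e-12)
  }
  # degenerate slack state
  bad <- slack_encode(distribution_set(list(c(0.5, 0.5))))
  bad$s[[1]] <- c(0, 0)
  expect_error(slack_decode(bad), "degenerate")
})

test_that("autoscale normalizes to unit max and round-trips the solution", {
  cs <- tiny_sphere_case(seed = 72)
  sc <- autoscale(cs$G, cs$data)
  expect_equal(max(sc$data$mean), 1)
  expect_equal(max(sc$G$data), 1)
  expect_equal(sc$scale$c_I, max(cs$data$mean))
  expect_equal(sc$scale$c_G, max(cs$G$data))
  # already-unit inputs give identity scaling
  sc2 <- autoscale(sc$G, sc$data)
  expect_equal(sc2$scale$c_I, 1)
  expect_equal(sc2$scale$c_G, 1)
  # chi-squared is invariant under the scaling
  d <- cs$truth
  eps1 <- normalized_misfit(intensity(cs$G, d), cs$data)
  d_s <- d; d_s$xi <- d$xi * sc$scale$c_G / sc$scale$c_I
  eps2 <- normalized_misfit(intensity(sc$G, d_s), sc$data)
  expect_equal(chi_squared(eps1), chi_squared(eps2), tolerance = 1e-10)
})

test_that("solutions are invariant across 12 orders of input magnitude", {
  cs <- tiny_sphere_case(seed = 73, n_r = 6, n_q = 40)
  ref <- sas_solve(cs$G, cs$data, solver_options(max_iter = 60))
  for (p in c(-6, 6)) {
    d <- cs$data
    d$mean <- d$mean * 10^p
    d$std <- d$std * 10^p
    sol <- sas_solve(cs$G, d, solver_options(max_iter = 60))
    expect_equal(sol$mle$weights[[1]], ref$mle$weights[[1]], tolerance = 1e-8)
    expect_equal(sol$mle$xi / 10^p, ref$mle$xi, tolerance = 1e-8)
    expect_equal(sol$chi2, ref$chi2, tolerance = 1e-6)
  }
})

test_that("analytic gradient matches central finite differences", {
  set.seed(74)
  for (case in 1:3) {
    nk <- list(c(5), c(4, 3), c(3))[[case]]
    G <- random_green_1d(12, nk, seed = 74 + case)
    mu <- stats::runif(12, 0.5, 2)
    data <- intensity_data(G$q_grid, mu, std = 0.1 * mu)
    bg <- if (case == 3) background_spec("power_law", A = 0.01, B = 1)
          else background_spec("flat")
    nlp <- make_nlp(G, data, background = bg)
    theta <- nlp$pack(distribution_set(lapply(nk, random_simplex),
                                       xi = 1.3, background = bg))
    theta[nlp$idx_bg[1]] <- 0.2
    g_an <- nlp$gr(theta)
    h <- 1e-6
    g_fd <- vapply(seq_along(theta), function(i) {
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      (nlp$fn(tp) - nlp$fn(tm)) / (2 * h)
    }, numeric(1))
    scale <- pmax(abs(g_an), max(abs(g_an)) * 1e-3)
    expect_lt(max(abs(g_an - g_fd) / scale), 1e-6)
  }
})

test_that("monodisperse one-hot truth is recovered to high precision", {
  w <- rep(0, 8); w[5] <- 1
  cs <- tiny_sphere_case(seed = 75, n_r = 8, n_q = 60, w = w)
  sol <- sas_solve(cs$G, cs$data, solver_options(max_iter = 150))
  expect_gt(sol$mle$weights[[1]][5], 1 - 1e-6)
  expect_equal(sol$mle$xi, 1, tolerance = 1e-6)
  expect_lt(abs(sol$mle$background$b) / max(cs$data$mean), 1e-8)
})

test_that("background-only data drives xi to zero", {
  q <- q_grid(q = exp(seq(log(0.01), log(0.5), length.out = 30)))
  G <- sphere_form_green(q, param_grid_spec("radius", 20, 80, 5))
  const <- 4.2
  data <- intensity_data(q, rep(const, 30), std = rep(0.4, 30))
  sol <- sas_solve(G, data, solver_options(max_iter = 100))
  expect_lt(sol$chi2, 1e-18)
  expect_equal(sol$mle$background$b, const, tolerance = 1e-6)
  # xi's contribution to the intensity is negligible
  expect_lt(sol$mle$xi * max(G$data) / const, 1e-6)
})

test_that("solver chi2 agrees with an independent recomputation", {
  cs <- tiny_sphere_case(seed = 76, n_r = 10, n_q = 50)
  sol <- sas_solve(cs$G, cs$data, solver_options(max_iter = 80))
  eps <- normalized_misfit(intensity(cs$G, sol$mle), cs$data)
  expect_equal(chi_squared(eps), sol$chi2,
               tolerance = 1e-10 * max(1, sol$chi2) / max(sol$chi2, 1e-300))
  # feasibility of the returned MLE
  expect_true(all(sol$mle$weights[[1]] >= 0))
  expect_equal(sum(sol$mle$weights[[1]]), 1, tolerance = 1e-10)
  # feasibility held at every recorded iterate
  expect_true(all(sol$trace$feas_err <= 1e-12))
  # chi2 non-increasing across accepted iterations
  expect_true(all(diff(sol$trace$chi2) <= 1e-12))
})

test_that("monitor_and_reduce freezes converged distributions", {
  cur <- list(c(0.5, 0.5), c(0.2, 0.8))
  prev <- list(c(0.5, 0.5), c(0.3, 0.7))
  # identical records freeze; L1 = 0.2 does not at tol 1e-4
  mon <- monitor_and_reduce(cur, prev, reduce_tol = 1e-4)
  expect_equal(mon$frozen, c(TRUE, FALSE))
  expect_equal(mon$l1, c(0, 0.2))
  # records differing by 2 eps in one bin freeze iff 2 eps < tol
  eps <- 1e-5
  mon2 <- monitor_and_reduce(list(c(0.5 + eps, 0.5 - eps)),
                             list(c(0.5 - eps, 0.5 + eps)),
                             reduce_tol = 1e-4)
  expect_true(mon2$frozen)
  expect_equal(mon2$l1, 4 * eps)
  mon3 <- monitor_and_reduce(list(c(0.5 + eps, 0.5 - eps)),
                             list(c(0.5 - eps, 0.5 + eps)),
                             reduce_tol = 1e-5)
  expect_false(mon3$frozen)
  # already-frozen parameters stay frozen
  mon4 <- monitor_and_reduce(cur, prev, reduce_tol = 1e-4,
                             frozen = c(FALSE, TRUE))
  expect_equal(mon4$frozen, c(TRUE, TRUE))
})

test_that("dimension reduction freezes parameters consistently with its trace", {
  set.seed(77)
  G <- random_green_1d(40, c(6, 5), seed = 77)
  w <- list(random_simplex(6), random_simplex(5))
  truth <- distribution_set(w, xi = 2)
  mu <- intensity(G, truth)
  data <- intensity_data(G$q_grid, mu, std = 0.2 * mu)
  sol <- sas_solve(G, data, solver_options(max_iter = 200, monitor_every = 5,
                                           reduce_tol = 1e-6, reduce = TRUE))
  # frozen flags must match what the recorded L1 history implies
  if (length(sol$l1_history)) {
    l1 <- do.call(rbind, sol$l1_history)[, -1, drop = FALSE]
    implied <- apply(l1 < 1e-6, 2, any)
    expect_equal(unname(sol$frozen), unname(implied))
  }
  # recovery still sound
  expect_lt(sum(abs(sol$mle$weights[[1]] - w[[1]])), 0.05)
})

test_that("grid search runs one short solve per candidate and picks the truth", {
  set.seed(78)
  q <- q_grid(q = exp(seq(log(2e-3), log(0.3), length.out = 80)))
  r <- param_grid_spec("radius", 50, 300, 20)
  G0 <- sphere_form_green(q, r)
  w <- exp(-0.5 * ((r$values - 150) / 40)^2); w <- w / sum(w)
  Gt <- apply_structure(G0, hard_sphere_structure(q, 150, 0.2))
  mu <- intensity(Gt, distribution_set(list(radius = w)))
  data <- intensity_data(q, mu, std = 0.15 * mu)
  gs <- grid_search_structure_init(G0, data,
                                   r_eff_candidates = c(100, 150, 250),
                                   V_f_candidates = c(0.05, 0.2, 0.35))
  expect_equal(gs$n_solves, 9L)
  expect_equal(gs$r_eff, 150)
  expect_equal(gs$V_f, 0.2)
  # single candidate pair returns trivially
  gs1 <- grid_search_structure_init(G0, data, 150, 0.2,
                                    opts = solver_options(max_iter = 5))
  expect_equal(gs1$n_solves, 1L)
  expect_equal(gs1$r_eff, 150)
  expect_error(grid_search_structure_init(G0, data, numeric(0), 0.2),
               "non-empty")
})

test_that("free structure-factor variables are recovered from a grid start", {
  set.seed(79)
  q <- q_grid(q = exp(seq(log(2e-3), log(0.3), length.out = 80)))
  r <- param_grid_spec("radius", 50, 300, 15)
  G0 <- sphere_form_green(q, r)
  w <- exp(-0.5 * ((r$values - 160) / 50)^2); w <- w / sum(w)
  Gt <- apply_structure(G0, hard_sphere_structure(q, 140, 0.18))
  mu <- intensity(Gt, distribution_set(list(radius = w)))
  data <- intensity_data(q, mu, std = 0.1 * mu)
  sol <- sas_solve(G0, data, solver_options(max_iter = 200),
                   structure_init = list(r_eff = 120, V_f = 0.25))
  expect_equal(sol$mle$extras$r_eff, 140, tolerance = 0.02)
  expect_equal(sol$mle$extras$V_f, 0.18, tolerance = 0.05)
})

test_that("2D preparatory decimated solve feeds the full-resolution solve", {
  set.seed(80)
  qx <- seq(-0.5, 0.5, length.out = 12)
  l <- param_grid_spec("length", 50, 150, 4)
  r <- param_grid_spec("radius", 10, 40, 4)
  G <- cylinder_form_green_2d(qx, qx, l, r,
                              param_grid("theta", c(0.3, 0.9)),
                              param_grid("phi", c(0.5, 2.0)))
  truth <- distribution_set(list(random_simplex(4), random_simplex(4),
                                 random_simplex(2), random_simplex(2)))
  mu <- intensity(G, truth)
  data <- intensity_data(G$q_grid, mu, std = mu)
  dec <- decimate_q(G, data, factor = 2)
  expect_equal(dim(dec$G$data)[1:2], c(6, 6))
  expect_equal(dec$data$mean, data$mean[seq(1, 12, 2), seq(1, 12, 2)])
  sol <- sas_solve_2d_prep(G, data, factor = 2,
                           opts = solver_options(max_iter = 100))
  expect_lt(sol$chi2, 1e-16)
})
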