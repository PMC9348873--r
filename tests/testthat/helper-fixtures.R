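# shared fixtures: tiny random instances built in code under fixed seeds

random_simplex <- function(n) {
  w <- stats::runif(n)
  w / sum(w)
}

# a small random green_tensor with M = 1 and given parameter bin counts
random_green_1d <- function(nq, nk, seed = 1) {
  set.seed(seed)
  q <- q_grid(q = sort(stats::runif(nq, 0.01, 1)))
  grids <- lapply(seq_along(nk), function(k) {
    param_grid(paste0("p", k), sort(stats::runif(nk[k], 10, 100)))
  })
  data <- array(stats::runif(nq * prod(nk)), c(nq, nk))
  green_tensor(data, q, grids)
}

# brute-force forward map by nested loops (the independent oracle)
brute_force_intensity <- function(G, weights, xi, b) {
  d <- dim(G$data)
  M <- G$q_grid$M
  nk <- d[-seq_len(M)]
  out <- array(0, d[seq_len(M)])
  combos <- expand.grid(lapply(nk, seq_len))
  for (i in seq_len(nrow(combos))) {
    jj <- as.integer(combos[i, ])
    wprod <- prod(mapply(function(w, j) w[j], weights, jj))
    slice <- do.call(`[`, c(list(G$data), as.list(rep(TRUE, M)), as.list(jj)))
    out <- out + slice * wprod
  }
  xi * out + b
}

# tiny solvable sphere instance used across inverse-module tests
tiny_sphere_case <- function(seed = 7, n_r = 8, n_q = 60, w = NULL, b = 0,
                             frac = 0.25) {
  set.seed(seed)
  q <- q_grid(q = exp(seq(log(5e-3), log(0.5), length.out = n_q)))
  r <- param_grid_spec("radius", 20, 120, n_r)
  G <- sphere_form_green(q, r)
  if (is.null(w)) w <- random_simplex(n_r)
  truth <- distribution_set(list(radius = w), xi = 1,
                            background = background_spec("flat", b = b))
  mu <- intensity(G, truth)
  data <- intensity_data(q, mu, std = frac * abs(mu) + frac * max(mu) * 1e-12)
  list(G = G, data = data, truth = truth)
}
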