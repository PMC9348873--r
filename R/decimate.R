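#' Strided decimation of 2D data and Green tensor for a preparatory solve
#'
#' Large 2D problems are best attacked in two steps: a low-resolution solve on
#' a decimated (strided-subsampled) q grid provides a good initial guess for
#' the full-resolution inversion. This helper subsamples both the data and the
#' Green tensor by the same stride along each q axis.
#'
#' @param G A `green_tensor` with M = 2.
#' @param data The matching [intensity_data()].
#' @param factor Integer stride (every `factor`-th point is kept).
#' @return A list with decimated `G` and `data`.
#' @export
decimate_q <- function(G, data, factor = 2L) {
  stopifnot(G$q_grid$M == 2L, factor >= 1L)
  d <- dim(G$data)
  ix <- seq(1L, d[1], by = factor)
  iy <- seq(1L, d[2], by = factor)
  qg <- q_grid(qx = G$q_grid$axes[[1]][ix], qy = G$q_grid$axes[[2]][iy])
  idx <- as.list(rep(TRUE, length(d)))
  idx[[1]] <- ix
  idx[[2]] <- iy
  Gd <- G
  Gd$data <- do.call(`[`, c(list(G$data), idx, list(drop = FALSE)))
  Gd$q_grid <- qg
  dd <- intensity_data(qg, data$mean[ix, iy], std = data$std[ix, iy])
  list(G = Gd, data = dd)
}

#' Two-stage 2D inversion with a preparatory low-resolution solve
#'
#' Runs [sas_solve()] on the decimated problem first and feeds its solution as
#' the initial state of the full-resolution solve.
#'
#' @param G A `green_tensor` with M = 2.
#' @param data The matching [intensity_data()].
#' @param factor Decimation stride for the preparatory stage.
#' @param opts,prep_opts [solver_options()] for the two stages.
#' @param ... Passed to both [sas_solve()] calls.
#' @return The full-resolution `sas_solution`.
#' @export
sas_solve_2d_prep <- function(G, data, factor = 2L, opts = solver_options(),
                              prep_opts = opts, ...) {
  dec <- decimate_q(G, data, factor)
  prep <- sas_solve(dec$G, dec$data, prep_opts, ...)
  sas_solve(G, data, opts, init = prep$mle, ...)
}
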