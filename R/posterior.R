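#' Flatten a solution's variables into one vector
#'
#' Concatenates all distribution weights, the scale `xi` and the background
#' level into the flattened variable vector used by the sensitivity analysis,
#' with an index map back to named blocks.
#'
#' @param d A [distribution_set()].
#' @return A list with `X` (numeric vector) and `map` (data frame of block
#'   name and within-block index per entry).
#' @export
flatten_variables <- function(d) {
  stopifnot(inherits(d, "distribution_set"))
  nm <- names(d$weights) %||% paste0("w", seq_along(d$weights))
  X <- c(unlist(d$weights, use.names = FALSE), d$xi,
         if (d$background$kind == "flat") d$background$b
         else c(d$background$A, d$background$B))
  blocks <- c(rep(nm, vapply(d$weights, length, integer(1))), "xi",
              if (d$background$kind == "flat") "b" else c("A", "B"))
  within <- unlist(lapply(vapply(d$weights, length, integer(1)), seq_len),
                   use.names = FALSE)
  map <- data.frame(block = blocks,
                    index = c(within, rep(1L, length(blocks) - length(within))))
  list(X = X, map = map)
}

# Jacobian of the model intensity with respect to the flattened variables
# (w's, xi, background), divided by sigma: the building block of both the
# sensitivity scores and the uncertainty propagation.
model_jacobian_X <- function(solution, G, data) {
  d <- solution$mle
  nq <- n_q_points(G$q_grid)
  sig <- as.vector(data$std)
  qm <- as.vector(q_magnitudes(G$q_grid))
  N <- length(d$weights)
  S <- if (!is.null(d$extras$r_eff)) {
    hard_sphere_structure(qm, d$extras$r_eff, d$extras$V_f)
  } else 1
  cols <- list()
  cc <- NULL
  for (k in seq_len(N)) {
    Pk <- contract_green(G, d$weights, skip = k)
    Pk <- matrix(Pk, nq)
    if (is.null(cc)) cc <- as.vector(Pk %*% d$weights[[k]])
    cols[[k]] <- d$xi * S * Pk / sig
  }
  J_xi <- S * cc / sig
  J_bg <- if (d$background$kind == "flat") {
    matrix(1 / sig, ncol = 1)
  } else {
    qB <- qm^(-d$background$B)
    cbind(qB / sig, -d$background$A * qB * log(qm) / sig)
  }
  list(J = cbind(do.call(cbind, cols), J_xi, J_bg), partial = cols,
       S = S, cc = cc, sig = sig)
}

#' Normalized sensitivity of the misfit at the MLE
#'
#' Scores each flattened variable by the local curvature of chi-squared
#' weighted by the variable's squared value, `s_a = H_aa * X_a^2`, normalized
#' to unit maximum. Because the forward map is linear in each variable, the
#' diagonal curvature is exact: `H_aa = 2 sum_q (dI_q/dX_a / sigma_q)^2`.
#' Large scores mark the parameters and parameter ranges that dominate the
#' local behaviour of the misfit around the maximum-likelihood estimate; the
#' precise normalization is implementation-defined.
#'
#' @param solution A `sas_solution`.
#' @param G The `green_tensor` used for the fit (original, unscaled).
#' @param data The [intensity_data()] used for the fit.
#' @return An object of class `sas_sensitivity`: list with `values` (per-block
#'   list of scores in `[0, 1]`), `flat` (flattened scores) and `map`.
#' @export
sas_sensitivity <- function(solution, G, data) {
  stopifnot(inherits(solution, "sas_solution"))
  fv <- flatten_variables(solution$mle)
  mj <- model_jacobian_X(solution, G, data)
  H_diag <- 2 * colSums(mj$J^2)
  score <- H_diag * fv$X^2
  if (max(score) > 0) {
    score <- score / max(score)
  } else {
    warning("all sensitivities are zero (degenerate curvature)")
  }
  blocks <- split(score, fv$map$block)
  structure(list(values = blocks[unique(fv$map$block)], flat = score,
                 map = fv$map), class = "sas_sensitivity")
}

#' Linearized posterior uncertainty of the distributions
#'
#' Error bars for each parameter distribution by back-propagating the
#' observational covariance through the conditionally-linear forward map at
#' the MLE. With `G~` the Green tensor contracted with all MLE weights except
#' parameter k (a matrix over flattened q by the bins of k) and `C = diag(
#' sigma^2)`, the standard deviations are the square roots of the diagonal of
#' `(xi^2 G~' C^-1 G~)^-1` (the no-prior linearized posterior covariance).
#' Rank-deficient normal matrices (e.g. more bins than data points) are
#' handled by SVD pseudo-inversion with a relative cutoff and flagged.
#'
#' @param solution A `sas_solution`.
#' @param G The `green_tensor` used for the fit (original, unscaled).
#' @param data The [intensity_data()] used for the fit.
#' @param svd_rtol Relative singular-value cutoff for the pseudo-inverse.
#' @return An object of class `sas_uncertainty`: `delta_w` (list of per-bin
#'   standard deviations), plus per-parameter `rank`, `n_bins` and condition
#'   diagnostics.
#' @export
sas_uncertainty <- function(solution, G, data, svd_rtol = 1e-10) {
  stopifnot(inherits(solution, "sas_solution"))
  d <- solution$mle
  nq <- n_q_points(G$q_grid)
  sig <- as.vector(data$std)
  qm <- as.vector(q_magnitudes(G$q_grid))
  S <- if (!is.null(d$extras$r_eff)) {
    hard_sphere_structure(qm, d$extras$r_eff, d$extras$V_f)
  } else 1
  N <- length(d$weights)
  delta_w <- vector("list", N)
  rank <- integer(N)
  cond <- numeric(N)
  deficient <- logical(N)
  for (k in seq_len(N)) {
    Gt <- matrix(contract_green(G, d$weights, skip = k), nq) * S
    A <- d$xi * Gt / sig # so crossprod(A) = xi^2 G~' C^-1 G~
    sv <- svd(crossprod(A))
    keep <- sv$d > svd_rtol * sv$d[1]
    rank[k] <- sum(keep)
    cond[k] <- sv$d[1] / sv$d[rank[k]]
    deficient[k] <- rank[k] < ncol(A)
    if (deficient[k]) {
      warning(sprintf(
        "parameter '%s': normal matrix rank %d < %d bins; pseudo-inverse used",
        names(d$weights)[k] %||% k, rank[k], ncol(A)))
    }
    Cov <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
    delta_w[[k]] <- sqrt(pmax(diag(Cov), 0))
  }
  names(delta_w) <- names(d$weights)
  structure(list(delta_w = delta_w, rank = rank, cond = cond,
                 deficient = deficient), class = "sas_uncertainty")
}
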