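#' Grid-search initialization for structure-factor variables
#'
#' The hard-sphere structure factor introduces two variables, the effective
#' radius `r_eff` and the volume fraction `V_f`, which break the convexity of
#' the inverse problem: the solution then depends on their initial guess. This
#' brute-force search runs a short solve for every candidate pair on a coarse
#' grid and returns the pair with the lowest chi-squared (ties broken by the
#' smaller `V_f`), from which a full solve can be started.
#'
#' @param G The bare form-factor `green_tensor` (no structure factor applied).
#' @param data An [intensity_data()].
#' @param r_eff_candidates,V_f_candidates Non-empty candidate vectors.
#' @param opts [solver_options()] for the short solves (default: 40
#'   iterations plus the conditionally-linear polish, which is what separates
#'   the candidate misfits cleanly).
#' @param background A [background_spec()] passed to the short solves.
#' @return A list with `r_eff`, `V_f` (the selected pair), `chi2` (its short-
#'   solve misfit), `table` (a data frame of all candidates and their chi2)
#'   and `n_solves` (the number of short solves executed).
#' @export
grid_search_structure_init <- function(G, data, r_eff_candidates,
                                       V_f_candidates,
                                       opts = solver_options(max_iter = 40L),
                                       background = background_spec()) {
  if (!length(r_eff_candidates) || !length(V_f_candidates)) {
    stop("candidate lists must be non-empty")
  }
  qm <- q_magnitudes(G$q_grid)
  grid <- expand.grid(r_eff = as.numeric(r_eff_candidates),
                      V_f = as.numeric(V_f_candidates))
  chi2 <- rep(NA_real_, nrow(grid))
  errors <- character(0)
  n_solves <- 0L
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      S <- hard_sphere_structure(qm, grid$r_eff[i], grid$V_f[i])
      Gc <- apply_structure(G, S)
      n_solves <- n_solves + 1L
      sas_solve(Gc, data, opts, background = background)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, conditionMessage(res))
    } else {
      chi2[i] <- res$chi2
    }
  }
  if (all(is.na(chi2))) {
    stop("all candidate solves failed: ",
         paste(unique(errors), collapse = "; "))
  }
  # lowest chi2; ties (within floating-point equality) broken by smaller V_f
  ord <- order(chi2, grid$V_f)
  best <- ord[1]
  list(r_eff = grid$r_eff[best], V_f = grid$V_f[best], chi2 = chi2[best],
       table = cbind(grid, chi2 = chi2), n_solves = n_solves)
}
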