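#' Slack-variable encoding of a distribution set
#'
#' The inequality constraints `w_i >= 0` are removed by writing each density
#' as the square of a slack vector, `w_i = s_i^2 / sum_j s_j^2`; on the unit
#' sphere (`sum s^2 = 1`) this reduces to `w = s^2`, and any sign pattern of
#' `s` decodes to the same feasible density. The scale enters as
#' `xi = xi_raw^2` and the flat background level is carried unconstrained.
#'
#' @param d A [distribution_set()].
#' @return An object of class `slack_state` with fields `s` (list of unit-norm
#'   slack vectors), `xi_raw`, `b_raw` and `extras`.
#' @export
slack_encode <- function(d) {
  stopifnot(inherits(d, "distribution_set"))
  s <- lapply(d$weights, function(w) sqrt(w))
  structure(list(s = s, xi_raw = sqrt(d$xi),
                 b_raw = if (d$background$kind == "flat") d$background$b else NULL,
                 background = d$background, extras = d$extras),
            class = "slack_state")
}

#' Decode slack variables back to a distribution set
#'
#' @param state A `slack_state`. Slack vectors need not be exactly unit norm:
#'   the decoded weights are `s^2 / sum(s^2)`, always a valid density.
#' @return A [distribution_set()].
#' @export
slack_decode <- function(state) {
  stopifnot(inherits(state, "slack_state"))
  weights <- lapply(state$s, function(s) {
    ns2 <- sum(s^2)
    if (ns2 <= 0 || !is.finite(ns2)) {
      stop("degenerate slack state: zero-norm slack vector")
    }
    s^2 / ns2
  })
  bg <- state$background %||% background_spec()
  if (!is.null(state$b_raw)) bg$b <- state$b_raw
  distribution_set(weights, xi = state$xi_raw^2, background = bg,
                   extras = state$extras)
}
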