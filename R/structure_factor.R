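#' Percus-Yevick hard-sphere structure factor
#'
#' Closed-form solution of the Percus-Yevick integral equation for hard
#' spheres, the standard correction for inter-particle interference in
#' moderately concentrated colloidal systems. `S(q)` depends on the effective
#' hard-sphere radius `r_eff` and the volume fraction `V_f`; in the dilute
#' limit `V_f = 0` it is identically 1, and its long-wavelength limit is the
#' compressibility value `S(0) = (1 - V_f)^4 / (1 + 2 V_f)^2`.
#'
#' @param q A [q_grid()] or numeric q vector (inverse angstroms).
#' @param r_eff Effective hard-sphere radius (angstroms, > 0).
#' @param V_f Hard-sphere volume fraction, in `[0, 0.74)` (0.74 is close
#'   packing; the Percus-Yevick closure is used well below that).
#' @return `S(q)` evaluated on the q grid: a vector (M = 1) or matrix of the
#'   (qx, qy) shape (M = 2), strictly positive and finite.
#' @export
hard_sphere_structure <- function(q, r_eff, V_f) {
  if (!is.finite(V_f) || V_f < 0 || V_f >= 0.74) {
    stop("domain error: V_f must lie in [0, 0.74), got ", V_f)
  }
  if (!is.finite(r_eff) || r_eff <= 0) {
    stop("domain error: r_eff must be positive")
  }
  qm <- if (inherits(q, "q_grid")) q_magnitudes(q) else abs(as.numeric(q))
  if (V_f == 0) {
    out <- qm * 0 + 1
    return(out)
  }
  eta <- V_f
  alpha <- (1 + 2 * eta)^2 / (1 - eta)^4
  beta <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  gamma <- eta * alpha / 2
  u <- 2 * r_eff * qm # q times hard-sphere diameter
  Gu_over_u <- u * 0
  # the closed-form terms lose all significant digits from cancellation for
  # small u (the third term's numerator is O(u^6)); switch to the series of
  # G(u)/u below a threshold where both branches are accurate to ~1e-8
  small <- abs(u) < 0.03
  us <- u[small]
  Gu_over_u[small] <- (alpha / 3 + beta / 4 + gamma / 6) +
    us^2 * (-alpha / 30 - beta / 36 - gamma / 48)
  ul <- u[!small]
  Gl <- alpha * (sin(ul) - ul * cos(ul)) / ul^2 +
    beta * (2 * ul * sin(ul) + (2 - ul^2) * cos(ul) - 2) / ul^3 +
    gamma * (-ul^4 * cos(ul) +
             4 * ((3 * ul^2 - 6) * cos(ul) + (ul^3 - 6 * ul) * sin(ul) + 6)) / ul^5
  Gu_over_u[!small] <- Gl / ul
  S <- 1 / (1 + 24 * eta * Gu_over_u)
  if (any(!is.finite(S)) || any(S <= 0)) {
    stop("Percus-Yevick structure factor evaluated to a non-positive value")
  }
  S
}
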