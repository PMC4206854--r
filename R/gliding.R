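# Tangential gliding propulsion and stochastic polarity reversals.

#' Gliding propulsion forces along a trichome
#'
#' Gliding cyanobacteria are propelled tangentially along their whole length
#' (slime extrusion at every cell junction). The model applies at every
#' vertex a force of magnitude `zeta * v0` along the local unit tangent,
#' signed by the trichome polarity `P`:
#' \deqn{F^g_i = \zeta\, v_0\, P\, \hat t_i.}
#' For a free straight trichome this composes with the tangential mobility
#' `1/zeta` to an exact gliding speed of `v0`.
#'
#' @param vertices (N+1) x 3 matrix of vertex positions.
#' @param polarity +1 or -1, the gliding direction along the tangent field.
#' @param zeta per-vertex drag coefficient (force x time / length).
#' @param v0 target gliding speed (length / time).
#' @return (N+1) x 3 matrix of forces.
#' @examples
#' v <- cbind(0:5, 0, 0)
#' gliding_forces(v, +1, zeta = 2, v0 = 1.5)
#' @export
gliding_forces <- function(vertices, polarity, zeta, v0) {
  if (!polarity %in% c(-1, 1)) stop("gliding_forces: polarity must be -1 or +1")
  if (zeta <= 0 || v0 < 0) stop("gliding_forces: zeta > 0 and v0 >= 0 required")
  zeta * v0 * polarity * vertex_tangents(vertices)
}

#' Sample stochastic gliding reversals
#'
#' Each trichome reverses its polarity during a step of length `dt` with
#' probability `omega * dt` (one uniform draw per trichome per accepted
#' step), giving exponentially distributed reversal intervals with mean
#' `1/omega` in the small-step limit. The step size must satisfy
#' `omega * dt < 1` for the Bernoulli approximation to be valid; the
#' integrator caps `dt` so that `omega * dt <= 0.05`.
#'
#' @param polarity vector of +1/-1 polarities (one per trichome).
#' @param omega reversal frequency (1/time).
#' @param dt step duration (time).
#' @return New polarity vector; draws come from the current R RNG stream in
#'   trichome order.
#' @examples
#' set.seed(1)
#' table(sample_reversals(rep(1, 1000), omega = 1 / 300, dt = 1))
#' @export
sample_reversals <- function(polarity, omega, dt) {
  if (omega < 0 || dt <= 0) stop("sample_reversals: omega >= 0 and dt > 0 required")
  if (omega * dt >= 1)
    stop("sample_reversals: omega * dt must be < 1 (step too large)")
  if (omega == 0) return(polarity)
  flip <- runif(length(polarity)) < omega * dt
  ifelse(flip, -polarity, polarity)
}
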