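# Capsule-segment contact geometry and Lennard-Jones steric/cohesion forces.
#
# Each trichome segment is a capsule: a cylinder of diameter theta around an
# edge, cut perpendicular to the local tangent at shared vertices and capped
# with semi-spheres at trichome tips. Contact between two edges acts at
# discrete points parameterised by (a, b) in [0,1]^2 along the two edges.

.dot3 <- function(u, v) sum(u * v)

#' Closest-point parameters of the infinite lines through two edges
#'
#' For edges `<x1,x2>` and `<x3,x4>`, returns the unclamped parameters
#' `(a, b)` of the mutually closest points of the two supporting lines. The
#' connecting vector `h(a, b)` is perpendicular to both edges. For (near-)
#' parallel edges the system is singular and `NULL` is returned, signalling
#' fallback to the vertex-edge candidate interactions.
#'
#' @param x1,x2,x3,x4 numeric length-3 vertex positions.
#' @param tol relative tolerance on the normal-equation determinant below
#'   which the edges are treated as parallel.
#' @return Numeric `c(a, b)` (unclamped, may lie outside \[0,1\]) or `NULL`
#'   for parallel edges.
#' @examples
#' line_closest_parameters(c(0,0,0), c(1,0,0), c(0.5,-0.5,1), c(0.5,0.5,1))
#' @export
line_closest_parameters <- function(x1, x2, x3, x4, tol = 1e-12) {
  d1 <- x2 - x1
  d2 <- x4 - x3
  r <- x3 - x1
  d11 <- .dot3(d1, d1)
  d22 <- .dot3(d2, d2)
  d12 <- .dot3(d1, d2)
  if (d11 == 0 || d22 == 0)
    stop("line_closest_parameters: degenerate edge")
  det <- d11 * d22 - d12 * d12
  if (det <= tol * d11 * d22) return(NULL)  # parallel/collinear
  a <- (d22 * .dot3(d1, r) - d12 * .dot3(d2, r)) / det
  b <- (d12 * .dot3(d1, r) - d11 * .dot3(d2, r)) / det
  c(a = a, b = b)
}

#' Projection of a point onto an edge, clamped to the segment
#'
#' Returns the parameter in \[0, 1\] of the point on edge `<xi, xj>` closest
#' to `xk`.
#'
#' @param xi,xj edge endpoints (length-3).
#' @param xk query point (length-3).
#' @return Scalar parameter in \[0, 1\].
#' @examples
#' point_edge_projection(c(0,0,0), c(2,0,0), c(1,5,0))  # 0.5
#' @export
point_edge_projection <- function(xi, xj, xk) {
  rij <- xj - xi
  d <- .dot3(rij, rij)
  if (d == 0) stop("point_edge_projection: degenerate edge")
  min(1, max(0, .dot3(xk - xi, rij) / d))
}

.h_of <- function(x1, x2, x3, x4, a, b) {
  (b * x4 + (1 - b) * x3) - (a * x2 + (1 - a) * x1)
}

#' Admissible contact interactions between two capsule segments
#'
#' If the two edges cross when projected onto their common-parallel plane
#' (both unclamped line closest-point parameters strictly inside (0, 1)),
#' the single crossing interaction is returned. Otherwise the four
#' vertex-against-opposing-edge candidates are tested against the segment
#' domain conditions: a candidate is admissible only when the involved
#' vertex lies inside the perpendicular "cut" slab of the opposing segment
#' (relaxed at trichome tips, whose semi-spherical caps extend the domain)
#' and on the owning side of its own cut plane (so that a contact at a
#' shared vertex is assigned to exactly one of the two adjacent segments;
#' again relaxed at tips). Duplicate candidates that clamp to the same
#' `(a, b)` pair are merged, and at most the two nearest candidates are
#' kept: a pair of capsules has at most two distinct contact regions.
#'
#' @param x1,x2 first edge endpoints; `t1`, `t2` unit head-ward tangents at
#'   those vertices; `end1` logical length-2, whether `x1`/`x2` are trichome
#'   tip vertices.
#' @param x3,x4,t3,t4,end2 likewise for the second edge.
#' @return List of interactions, each a list with elements `a`, `b`,
#'   `h` (displacement vector from the point on edge 1 to the point on
#'   edge 2) and `dist`. May be empty.
#' @examples
#' # skew perpendicular crossing edges: single interaction at (0.5, 0.5)
#' admissible_interactions(c(0,0,0), c(1,0,0), c(0.5,-0.5,1), c(0.5,0.5,1),
#'   t1 = c(1,0,0), t2 = c(1,0,0), t3 = c(0,1,0), t4 = c(0,1,0))
#' @export
admissible_interactions <- function(x1, x2, x3, x4, t1, t2, t3, t4,
                                    end1 = c(FALSE, FALSE),
                                    end2 = c(FALSE, FALSE)) {
  ab <- line_closest_parameters(x1, x2, x3, x4)
  if (!is.null(ab) && ab[1] > 0 && ab[1] < 1 && ab[2] > 0 && ab[2] < 1) {
    h <- .h_of(x1, x2, x3, x4, ab[1], ab[2])
    return(list(list(a = unname(ab[1]), b = unname(ab[2]), h = h,
                     dist = sqrt(.dot3(h, h)))))
  }
  slab <- function(xk, xi, xj, ti, tj, ei, ej) {
    (.dot3(xk - xi, ti) >= 0 || ei) && (.dot3(xk - xj, tj) < 0 || ej)
  }
  out <- list()
  seen <- matrix(numeric(0), ncol = 2)
  push <- function(a, b) {
    if (nrow(seen) > 0 && any(abs(seen[, 1] - a) < 1e-12 &
                              abs(seen[, 2] - b) < 1e-12)) return()
    h <- .h_of(x1, x2, x3, x4, a, b)
    seen <<- rbind(seen, c(a, b))
    out[[length(out) + 1]] <<- list(a = a, b = b, h = h,
                                    dist = sqrt(.dot3(h, h)))
  }
  # h1: vertex x3 against edge <x1,x2>
  if (slab(x3, x1, x2, t1, t2, end1[1], end1[2])) {
    a <- point_edge_projection(x1, x2, x3)
    h <- .h_of(x1, x2, x3, x4, a, 0)
    if (.dot3(h, t3) <= 0 || end2[1]) push(a, 0)
  }
  # h2: vertex x4 against edge <x1,x2>
  if (slab(x4, x1, x2, t1, t2, end1[1], end1[2])) {
    a <- point_edge_projection(x1, x2, x4)
    h <- .h_of(x1, x2, x3, x4, a, 1)
    if (.dot3(h, t4) > 0 || end2[2]) push(a, 1)
  }
  # h3: vertex x1 against edge <x3,x4>
  if (slab(x1, x3, x4, t3, t4, end2[1], end2[2])) {
    b <- point_edge_projection(x3, x4, x1)
    h <- .h_of(x1, x2, x3, x4, 0, b)
    if (.dot3(h, t1) <= 0 || end1[1]) push(0, b)
  }
  # h4: vertex x2 against edge <x3,x4>
  if (slab(x2, x3, x4, t3, t4, end2[1], end2[2])) {
    b <- point_edge_projection(x3, x4, x2)
    h <- .h_of(x1, x2, x3, x4, 1, b)
    if (.dot3(h, t2) > 0 || end1[2]) push(1, b)
  }
  # a capsule pair has at most two true contact regions: keep the two
  # nearest candidates
  if (length(out) > 2) {
    d <- vapply(out, function(i) i$dist, numeric(1))
    out <- out[order(d)[1:2]]
  }
  out
}

#' Signed Lennard-Jones contact force magnitude
#'
#' Steric repulsion and slime cohesion between capsule centerlines at
#' separation `h`:
#' \deqn{f(h) = \tfrac12 \epsilon \left[(\Theta/h)^{13} - (\Theta/h)^{7}\right]}
#' Positive values are repulsive (the two edges are pushed apart), negative
#' attractive. The repulsive branch is capped at `cap_R` to tame numerical
#' stiffness, and the force is truncated to zero at separations `h >= 2 *
#' theta` (consistent with the neighbour-list cutoff). Zero crossing at
#' `h = theta`; peak attraction `~0.112 * epsilon` at
#' `h = (13/7)^(1/6) * theta`.
#'
#' @param h separation(s), same unit as `theta`; must be positive.
#' @param theta trichome diameter.
#' @param epsilon cohesion strength (force unit).
#' @param cap_R repulsion cap (force unit).
#' @return Signed magnitude(s), vectorised over `h`.
#' @examples
#' lj_force_magnitude(1.5, theta = 1.5, epsilon = 1e-12, cap_R = 1)  # 0
#' @export
lj_force_magnitude <- function(h, theta, epsilon, cap_R = Inf) {
  if (any(h <= 0)) stop("lj_force_magnitude: separation must be positive (overlapping centerlines)")
  if (theta <= 0 || epsilon < 0 || cap_R < 0)
    stop("lj_force_magnitude: invalid parameters")
  s <- theta / h
  f <- 0.5 * epsilon * (s^13 - s^7)
  f <- ifelse(f > cap_R, cap_R, f)
  ifelse(h >= 2 * theta, 0, f)
}

#' Distribute a contact force from edge interaction points to vertices
#'
#' A contact force `Fc` acting on edge 1 at interpolation parameter `a`
#' (with the reaction `-Fc` on edge 2 at parameter `b`) is translated to
#' statically equivalent vertex forces by linear interpolation:
#' `F1 = (1-a) Fc`, `F2 = a Fc`, `F3 = -(1-b) Fc`, `F4 = -b Fc`.
#' The net force and net torque of the four vertex forces vanish, so
#' momentum and angular momentum bookkeeping is exact.
#'
#' @param Fc length-3 force vector acting on edge 1.
#' @param a,b interpolation parameters in \[0, 1\].
#' @return 4 x 3 matrix of vertex forces (rows: x1, x2, x3, x4).
#' @examples
#' distribute_contact_force(c(0, 0, 1), a = 0.25, b = 0.75)
#' @export
distribute_contact_force <- function(Fc, a, b) {
  if (a < 0 || a > 1 || b < 0 || b > 1)
    stop("distribute_contact_force: a and b must be in [0, 1]")
  rbind((1 - a) * Fc, a * Fc, -(1 - b) * Fc, -b * Fc)
}

#' Total contact force increments for one edge pair
#'
#' Composes [admissible_interactions()], [lj_force_magnitude()] and
#' [distribute_contact_force()]: every admissible interaction contributes a
#' force along its displacement direction, repulsive for separations below
#' `theta` and cohesive up to the `2 * theta` truncation. With
#' `repulsion_only = TRUE` (the cohesionless regime) the attractive branch
#' is suppressed and the hard core uses the repulsion strength `eps_rep`
#' (the epsilon equivalent to a cohesion ratio of 0.125).
#'
#' @inheritParams admissible_interactions
#' @param params a [system_params()] object (or any list with `theta` in um
#'   plus `epsilon`, `cap_R` in N) giving `theta`, `epsilon`, `cap_R`.
#'   Positions must be in the same length unit as `params$theta`.
#' @param repulsion_only logical; suppress attraction (cohesionless runs).
#' @return List with `forces` (4 x 3 matrix of vertex force increments) and
#'   `interactions` (as [admissible_interactions()]).
#' @export
edge_pair_forces <- function(x1, x2, x3, x4, t1, t2, t3, t4,
                             end1 = c(FALSE, FALSE), end2 = c(FALSE, FALSE),
                             params, repulsion_only = FALSE) {
  theta <- params$theta
  f_glide <- params$zeta * params$v0 * .um
  eps <- if (repulsion_only) 0.125 * f_glide else params$epsilon
  ints <- admissible_interactions(x1, x2, x3, x4, t1, t2, t3, t4, end1, end2)
  F <- matrix(0, 4, 3)
  for (it in ints) {
    if (it$dist <= 0) stop("edge_pair_forces: overlapping centerlines")
    f <- lj_force_magnitude(it$dist, theta, eps, params$cap_R)
    if (repulsion_only && f < 0) f <- 0
    if (f == 0) next
    Fc1 <- -f * it$h / it$dist      # force on edge 1 (repulsion pushes apart)
    F <- F + distribute_contact_force(Fc1, it$a, it$b)
  }
  list(forces = F, interactions = ints)
}
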