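# Discrete elastic rod geometry and bending mechanics for naturally
# straight, inextensible, torsion-free filaments, represented by their
# centerline vertices (an (N+1) x 3 matrix).

.check_chain <- function(vertices, min_vertices = 2) {
  if (!is.matrix(vertices) || ncol(vertices) != 3)
    stop("vertices must be an n x 3 matrix")
  if (nrow(vertices) < min_vertices)
    stop("chain needs at least ", min_vertices, " vertices")
  if (!all(is.finite(vertices)))
    stop("vertices must be finite")
  invisible(vertices)
}

.edge_vectors <- function(vertices) {
  n <- nrow(vertices)
  vertices[-1, , drop = FALSE] - vertices[-n, , drop = FALSE]
}

.row_norms <- function(m) sqrt(rowSums(m * m))

.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Unit tangent vectors along a trichome centerline
#'
#' The tangent at an interior vertex points along `x[i+1] - x[i-1]`; at the
#' two endpoints it is the direction of the single adjacent edge. All
#' tangents are oriented head-ward (from vertex i-1 towards i+1) so that they
#' form a consistent orientation field; the gliding direction is obtained by
#' multiplying with the trichome polarity.
#'
#' @param vertices (N+1) x 3 matrix of vertex positions.
#' @return (N+1) x 3 matrix of unit tangents.
#' @examples
#' v <- cbind(0:3, 0, 0)
#' vertex_tangents(v)
#' @export
vertex_tangents <- function(vertices) {
  .check_chain(vertices, 2)
  n <- nrow(vertices)
  e <- .edge_vectors(vertices)
  if (any(.row_norms(e) == 0))
    stop("vertex_tangents: coincident adjacent vertices")
  t <- matrix(0, n, 3)
  t[1, ] <- e[1, ]
  t[n, ] <- e[n - 1, ]
  if (n > 2)
    t[2:(n - 1), ] <- vertices[3:n, , drop = FALSE] -
      vertices[1:(n - 2), , drop = FALSE]
  nrm <- .row_norms(t)
  if (any(nrm == 0))
    stop("vertex_tangents: degenerate interior tangent (folded chain)")
  t / nrm
}

#' Discrete curvature binormal of a centerline
#'
#' At each interior vertex i the curvature binormal
#' \deqn{(\kappa b)_i = \frac{2\, e_{i-1} \times e_i}
#'   {\|e_{i-1}\|\|e_i\| + e_{i-1}\cdot e_i}}
#' is perpendicular to the osculating plane of the two adjacent edges and has
#' magnitude \eqn{2\tan(\phi/2)} for a turning angle \eqn{\phi}. It vanishes
#' exactly where the chain is locally straight and diverges as adjacent edges
#' become anti-parallel (a 180 degree fold, excluded sterically in the
#' dynamics).
#'
#' @param vertices (N+1) x 3 matrix of vertex positions (N >= 2).
#' @return (N-1) x 3 matrix, one row per interior vertex.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
#' curvature_binormal(v)  # (0, 0, 2)
#' @export
curvature_binormal <- function(vertices) {
  .check_chain(vertices, 3)
  n <- nrow(vertices)
  e <- .edge_vectors(vertices)
  nrm <- .row_norms(e)
  if (any(nrm == 0))
    stop("curvature_binormal: coincident adjacent vertices")
  e0 <- e[-(n - 1), , drop = FALSE]
  e1 <- e[-1, , drop = FALSE]
  denom <- nrm[-(n - 1)] * nrm[-1] + rowSums(e0 * e1)
  if (any(denom <= 1e-12 * nrm[-(n - 1)] * nrm[-1]))
    stop("curvature_binormal: anti-parallel adjacent edges (180 degree fold)")
  2 * .cross_rows(e0, e1) / denom
}

#' Bending energy of a discrete rod
#'
#' For a naturally straight rod of bending modulus `alpha` discretised into
#' edges of rest length `l`, the bending energy is
#' \eqn{E = (\alpha/l) \sum_j \|(\kappa b)_j\|^2} summed over interior
#' vertices. It is zero iff the chain is straight, and invariant under rigid
#' motions.
#'
#' @param vertices (N+1) x 3 matrix of vertex positions.
#' @param alpha bending modulus (energy x length).
#' @param l rest segment length (same length unit as `vertices`).
#' @return Scalar energy.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
#' bending_energy(v, alpha = 1, l = 1)  # 4
#' @export
bending_energy <- function(vertices, alpha, l) {
  if (alpha < 0 || l <= 0) stop("bending_energy: alpha >= 0 and l > 0 required")
  if (nrow(vertices) < 3) return(0)
  kb <- curvature_binormal(vertices)
  (alpha / l) * sum(kb * kb)
}

#' Bending forces on the vertices of a discrete rod
#'
#' Exact negative gradient of [bending_energy()] with respect to the vertex
#' positions. Each interior vertex contributes force to itself and its two
#' neighbours; the total force and total torque over the chain vanish
#' identically (translation and rotation invariance of the energy).
#'
#' @inheritParams bending_energy
#' @return (N+1) x 3 matrix of forces.
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
#' colSums(bending_forces(v, 1, 1))  # ~0: momentum conservation
#' @export
bending_forces <- function(vertices, alpha, l) {
  .check_chain(vertices, 2)
  if (alpha < 0 || l <= 0) stop("bending_forces: alpha >= 0 and l > 0 required")
  n <- nrow(vertices)
  F <- matrix(0, n, 3)
  if (n < 3) return(F)
  e <- .edge_vectors(vertices)
  nrm <- .row_norms(e)
  if (any(nrm == 0)) stop("bending_forces: coincident adjacent vertices")
  e0 <- e[-(n - 1), , drop = FALSE]   # e_{j-1} for interior vertex j
  e1 <- e[-1, , drop = FALSE]         # e_j
  n0 <- nrm[-(n - 1)]
  n1 <- nrm[-1]
  denom <- n0 * n1 + rowSums(e0 * e1)
  if (any(denom <= 1e-12 * n0 * n1))
    stop("bending_forces: anti-parallel adjacent edges (180 degree fold)")
  kb <- 2 * .cross_rows(e0, e1) / denom
  kb2 <- rowSums(kb * kb)
  # d||kb||^2 / d e0 and / d e1 (full gradient, edge lengths free)
  g0 <- (4 / denom) * .cross_rows(e1, kb) -
    (2 * kb2 / denom) * ((n1 / n0) * e0 + e1)
  g1 <- (4 / denom) * .cross_rows(kb, e0) -
    (2 * kb2 / denom) * ((n0 / n1) * e1 + e0)
  # scatter to vertices: E depends on e0 = x_j - x_{j-1}, e1 = x_{j+1} - x_j
  idx <- seq_len(n - 2)            # interior vertex j = idx + 1
  pref <- alpha / l
  add <- function(Fm, rows, val) { Fm[rows, ] <- Fm[rows, ] + val; Fm }
  F <- add(F, idx,     pref * g0)                 # -dE/dx_{j-1} = +pref*g0
  F <- add(F, idx + 1, pref * (g1 - g0))
  F <- add(F, idx + 2, -pref * g1)
  F
}
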