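# Independent oracles used across the suite. These deliberately avoid the
# package's own force/geometry code paths: finite differences for gradients,
# dense grid search for closest points, Newton-Lagrange for constraints.

# Central finite-difference gradient of a scalar field f over an n x 3
# vertex matrix.
fd_gradient <- function(f, vertices, h = 1e-7) {
  g <- matrix(0, nrow(vertices), 3)
  for (i in seq_len(nrow(vertices))) {
    for (d in 1:3) {
      vp <- vertices; vp[i, d] <- vp[i, d] + h
      vm <- vertices; vm[i, d] <- vm[i, d] - h
      g[i, d] <- (f(vp) - f(vm)) / (2 * h)
    }
  }
  g
}

# Random smooth open chain with n vertices and bond length ~l.
random_chain <- function(n, l = 1, wiggle = 0.6) {
  t <- c(1, 0, 0)
  v <- matrix(0, n, 3)
  for (k in 2:n) {
    t <- t + wiggle * rnorm(3)
    t <- t / sqrt(sum(t * t))
    v[k, ] <- v[k - 1, ] + l * t
  }
  v
}

# Brute-force closest distance between two segments via two-stage dense
# (a, b) grid search. Returns list(dist, a, b).
grid_segment_distance <- function(x1, x2, x3, x4, n1 = 101, n2 = 101) {
  eval_grid <- function(al, bl) {
    g <- expand.grid(a = al, b = bl)
    h <- cbind(g$b * x4[1] + (1 - g$b) * x3[1] - (g$a * x2[1] + (1 - g$a) * x1[1]),
               g$b * x4[2] + (1 - g$b) * x3[2] - (g$a * x2[2] + (1 - g$a) * x1[2]),
               g$b * x4[3] + (1 - g$b) * x3[3] - (g$a * x2[3] + (1 - g$a) * x1[3]))
    d <- sqrt(rowSums(h * h))
    i <- which.min(d)
    list(dist = d[i], a = g$a[i], b = g$b[i])
  }
  c1 <- eval_grid(seq(0, 1, length.out = n1), seq(0, 1, length.out = n1))
  # refine around the coarse optimum
  w <- 1.5 / (n1 - 1)
  al <- seq(max(0, c1$a - w), min(1, c1$a + w), length.out = n2)
  bl <- seq(max(0, c1$b - w), min(1, c1$b + w), length.out = n2)
  eval_grid(al, bl)
}

# Direct tridiagonal Lagrange solve for the bond-length constraints of a
# chain, linearized along the REFERENCE bond directions (the same
# linearization LINCS uses) but solved with dense base-R solve() and
# iterated to convergence: an independent implementation of the projection.
lagrange_constrain_chain <- function(proposed, reference, l, tol = 1e-10,
                                     maxit = 500) {
  x <- proposed
  nb <- nrow(x) - 1
  e <- reference[-1, , drop = FALSE] - reference[-nrow(x), , drop = FALSE]
  u <- e / sqrt(rowSums(e * e))
  S <- diag(2, nb)
  if (nb > 1) {
    cp <- rowSums(u[-nb, , drop = FALSE] * u[-1, , drop = FALSE])
    S[cbind(1:(nb - 1), 2:nb)] <- -cp
    S[cbind(2:nb, 1:(nb - 1))] <- -cp
  }
  for (it in seq_len(maxit)) {
    d <- x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE]
    g <- sqrt(rowSums(d * d)) - l
    if (max(abs(g)) < tol * l) return(x)
    lam <- solve(S, g)
    for (j in seq_len(nrow(x))) {
      dx <- 0
      if (j <= nb) dx <- dx + lam[j] * u[j, ]
      if (j > 1) dx <- dx - lam[j - 1] * u[j - 1, ]
      x[j, ] <- x[j, ] + dx
    }
  }
  stop("lagrange_constrain_chain did not converge")
}

# Engine parameter list for unit-level C++ calls (SI).
engine_par <- function(p, gliding = TRUE, cohesion = TRUE, reversals = TRUE) {
  trichosim:::.engine_params(p, gliding = gliding, cohesion = cohesion,
                             reversals = reversals)
}

# A small consistent multi-trichome system built by hand from a list of
# chains (um coordinates), for engine-level tests.
manual_system <- function(params, chains_um, polarity = NULL) {
  pos <- do.call(rbind, chains_um) * 1e-6
  if (is.null(polarity)) polarity <- rep(1L, length(chains_um))
  structure(list(params = params, pos = pos,
                 polarity = as.integer(polarity),
                 offsets = as.integer(cumsum(c(0, vapply(chains_um, nrow, integer(1))))),
                 t = 0, dt = 0.01),
            class = "trichome_system")
}

# Straight trichome chain along direction phi (xy plane) centred at c(um).
straight_chain <- function(n_vertices, l, center = c(0, 0, 3.75), phi = 0) {
  k <- seq(0, n_vertices - 1) - (n_vertices - 1) / 2
  cbind(center[1] + k * l * cos(phi),
        center[2] + k * l * sin(phi),
        center[3])
}
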