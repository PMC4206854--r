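# Capsule contact geometry, Lennard-Jones force law, force distribution and
# the neighbour list, against symmetry arguments and brute-force oracles.

test_that("line closest-point parameters: symmetry and perpendicularity", {
  ab <- line_closest_parameters(c(0, 0, 0), c(1, 0, 0),
                                c(0.5, -0.5, 1), c(0.5, 0.5, 1))
  expect_equal(unname(ab), c(0.5, 0.5))

  # parallel edges signal fallback
  expect_null(line_closest_parameters(c(0, 0, 0), c(1, 0, 0),
                                      c(0, 1, 0), c(1, 1, 0)))

  set.seed(21)
  for (rep in 1:50) {
    x1 <- rnorm(3); x2 <- x1 + rnorm(3)
    x3 <- rnorm(3); x4 <- x3 + rnorm(3)
    ab <- line_closest_parameters(x1, x2, x3, x4)
    if (is.null(ab)) next
    h <- (ab[2] * x4 + (1 - ab[2]) * x3) - (ab[1] * x2 + (1 - ab[1]) * x1)
    expect_lt(abs(sum(h * (x2 - x1))), 1e-9 * sqrt(sum((x2 - x1)^2)))
    expect_lt(abs(sum(h * (x4 - x3))), 1e-9 * sqrt(sum((x4 - x3)^2)))
  }
})

test_that("point-edge projection clamps to the segment", {
  expect_equal(point_edge_projection(c(0, 0, 0), c(2, 0, 0), c(1, 5, 0)), 0.5)
  expect_equal(point_edge_projection(c(0, 0, 0), c(2, 0, 0), c(-1, 1, 0)), 0)
  expect_equal(point_edge_projection(c(0, 0, 0), c(2, 0, 0), c(3, 0, 0)), 1)
  expect_error(point_edge_projection(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               "degenerate")
})

test_that("admissible interactions: crossing edges give the single crossing", {
  tx <- c(1, 0, 0); ty <- c(0, 1, 0)
  ints <- admissible_interactions(c(0, 0, 0), c(1, 0, 0),
                                  c(0.5, -0.5, 1), c(0.5, 0.5, 1),
                                  tx, tx, ty, ty)
  expect_length(ints, 1)
  expect_equal(ints[[1]]$a, 0.5)
  expect_equal(ints[[1]]$b, 0.5)
  expect_equal(ints[[1]]$h, c(0, 0, 1))
})

test_that("collinear end-to-end edges interact tip-to-tip through the caps", {
  # two single-edge trichomes along x with a 0.5 gap; all 4 vertices tips
  tx <- c(1, 0, 0)
  ints <- admissible_interactions(c(0, 0, 0), c(1, 0, 0),
                                  c(1.5, 0, 0), c(2.5, 0, 0),
                                  tx, tx, tx, tx,
                                  end1 = c(TRUE, TRUE), end2 = c(TRUE, TRUE))
  d <- vapply(ints, function(i) i$dist, numeric(1))
  # nearest interaction is the tip-tip pair (a=1, b=0) at the gap distance
  i <- which.min(d)
  expect_equal(ints[[i]]$a, 1)
  expect_equal(ints[[i]]$b, 0)
  expect_equal(ints[[i]]$dist, 0.5)
  # with theta = 0.7 only the tip-tip interaction carries force: the gap of
  # 0.5 is inside the hard core, the other candidates are beyond 2 theta
  f <- vapply(ints, function(i)
    lj_force_magnitude(i$dist, theta = 0.7, epsilon = 1, cap_R = 1e6),
    numeric(1))
  expect_equal(sum(f != 0), 1)
})

test_that("parallel overlapping interior edges interact perpendicularly", {
  tx <- c(1, 0, 0)
  ints <- admissible_interactions(c(0, 0, 0), c(1, 0, 0),
                                  c(0, 1, 0), c(1, 1, 0),
                                  tx, tx, tx, tx)
  expect_gt(length(ints), 0)
  expect_lte(length(ints), 2)
  for (i in ints) {
    expect_equal(i$h / sqrt(sum(i$h^2)), c(0, 1, 0))  # cylinder normal
    expect_equal(i$dist, 1)
  }
})

test_that("head/tail symmetry: reversing both chains leaves contacts intact", {
  set.seed(31)
  for (rep in 1:40) {
    c1 <- random_chain(3, l = 1)
    c2 <- random_chain(3, l = 1) + matrix(c(0.4, 0.4, 0.4), 3, 3, byrow = TRUE)
    t1 <- vertex_tangents(c1); t2 <- vertex_tangents(c2)
    args <- list(c1[1, ], c1[2, ], c2[1, ], c2[2, ],
                 t1[1, ], t1[2, ], t2[1, ], t2[2, ])
    ints <- do.call(admissible_interactions,
                    c(args, list(end1 = c(TRUE, FALSE), end2 = c(TRUE, FALSE))))
    # reverse both chains: vertices swap, tangents negate, tip flags swap
    argsR <- list(c1[2, ], c1[1, ], c2[2, ], c2[1, ],
                  -t1[2, ], -t1[1, ], -t2[2, ], -t2[1, ])
    intsR <- do.call(admissible_interactions,
                     c(argsR, list(end1 = c(FALSE, TRUE), end2 = c(FALSE, TRUE))))
    d <- sort(vapply(ints, function(i) i$dist, numeric(1)))
    dR <- sort(vapply(intsR, function(i) i$dist, numeric(1)))
    expect_equal(d, dR, tolerance = 1e-12)
  }
})

test_that("LJ force law: zero crossing, peak attraction, cap, truncation", {
  th <- 1.5; eps <- 2e-12
  expect_equal(lj_force_magnitude(th, th, eps, 1), 0)

  # maximum attraction at (13/7)^(1/6) theta with magnitude ~0.1121 eps
  hstar <- (13 / 7)^(1 / 6) * th
  f <- lj_force_magnitude(hstar, th, eps, 1)
  expect_equal(f, -0.11209 * eps, tolerance = 1e-3)
  hh <- seq(th, 2 * th, length.out = 400)
  expect_equal(min(lj_force_magnitude(hh, th, eps, 1)), f, tolerance = 1e-4)

  # hard core value and cap
  expect_equal(lj_force_magnitude(0.5 * th, th, eps, cap_R = Inf),
               0.5 * eps * (2^13 - 2^7))
  expect_equal(lj_force_magnitude(0.5 * th, th, eps, cap_R = 7 * eps), 7 * eps)

  # truncation at 2 theta; the discarded magnitude there is ~3.4% of the
  # peak attraction (the truncation error bound)
  expect_identical(lj_force_magnitude(2 * th, th, eps, 1), 0)
  expect_identical(lj_force_magnitude(5 * th, th, eps, 1), 0)
  f2 <- 0.5 * eps * (0.5^13 - 0.5^7)
  expect_equal(abs(f2) / abs(f), 0.034, tolerance = 0.02)
  expect_error(lj_force_magnitude(0, th, eps, 1), "positive")
})

test_that("contact force distribution conserves force and torque", {
  F <- distribute_contact_force(c(0, 0, 1), a = 0, b = 0.5)
  expect_equal(F[1, ], c(0, 0, 1))
  expect_equal(F[2, ], c(0, 0, 0))

  F <- distribute_contact_force(c(0, 0, 1), a = 0.25, b = 0.75)
  expect_equal(F[, 3], c(0.75, 0.25, -0.25, -0.75))

  set.seed(41)
  for (rep in 1:30) {
    a <- runif(1); b <- runif(1); Fc <- rnorm(3)
    x1 <- rnorm(3); x2 <- rnorm(3); x3 <- rnorm(3); x4 <- rnorm(3)
    # the interaction points are collinear with Fc for a real contact; use
    # the actual h direction so torque balance is meaningful
    pa <- (1 - a) * x1 + a * x2
    pb <- (1 - b) * x3 + b * x4
    h <- pb - pa
    Fc <- rnorm(1) * h
    F <- distribute_contact_force(Fc, a, b)
    expect_lt(max(abs(colSums(F))), 1e-12 * max(abs(F)))
    pts <- rbind(x1, x2, x3, x4)
    tq <- colSums(cbind(pts[, 2] * F[, 3] - pts[, 3] * F[, 2],
                        pts[, 3] * F[, 1] - pts[, 1] * F[, 3],
                        pts[, 1] * F[, 2] - pts[, 2] * F[, 1]))
    expect_lt(max(abs(tq)), 1e-12 * max(abs(F)) * max(abs(pts)) * 10)
  }
})

test_that("edge pair forces: equilibrium, repulsion-only mode, symmetry", {
  p <- system_params(domain = c(100, 7.5, 100), lam = 12, n_segments = 2,
                     rho = 0, beta = 1)
  tx <- c(1, 0, 0)
  mk <- function(gap) list(c(0, 0, 0), c(6, 0, 0), c(0, gap, 0), c(6, gap, 0))
  # exactly theta apart: zero force
  r <- do.call(edge_pair_forces,
               c(mk(1.5), list(tx, tx, tx, tx, params = p)))
  expect_equal(max(abs(r$forces)), 0)
  # 1.2 theta with repulsion_only: attraction suppressed
  r <- do.call(edge_pair_forces,
               c(mk(1.8), list(tx, tx, tx, tx, params = p,
                               repulsion_only = TRUE)))
  expect_equal(max(abs(r$forces)), 0)
  # same geometry with cohesion on: attractive (edge 1 pulled towards +y)
  r <- do.call(edge_pair_forces,
               c(mk(1.8), list(tx, tx, tx, tx, params = p)))
  expect_gt(sum(r$forces[1:2, 2]), 0)
  # 0.9 theta: repulsive and momentum-conserving
  r <- do.call(edge_pair_forces,
               c(mk(1.35), list(tx, tx, tx, tx, params = p)))
  expect_lt(sum(r$forces[1:2, 2]), 0)
  expect_equal(colSums(r$forces), c(0, 0, 0), tolerance = 1e-25)
})

test_that("neighbour list is a superset of truly close pairs", {
  p <- system_params(domain = c(120, 7.5, 120), lam = 24, n_segments = 4,
                     rho = 0)
  # two trichomes far apart: empty list
  sys <- manual_system(p, list(straight_chain(5, 6, c(20, 20, 3)),
                               straight_chain(5, 6, c(80, 80, 5))))
  expect_equal(nrow(build_neighbor_list(sys)$pairs), 0)

  # parallel straight trichomes 1.5 theta apart: all lateral pairs present
  sys <- manual_system(p, list(straight_chain(5, 6, c(60, 60, 3)),
                               straight_chain(5, 6, c(60, 62.25, 3))))
  pr <- build_neighbor_list(sys)$pairs
  for (e in 1:4) expect_true(any(pr[, 1] == e & pr[, 2] == e + 4))

  # random systems: list contains every pair with true separation < 2 theta
  set.seed(51)
  for (rep in 1:3) {
    chains <- lapply(1:20, function(i)
      straight_chain(5, 6, c(runif(1, 0, 120), runif(1, 0, 120),
                             runif(1, 0.75, 6.75)), phi = runif(1, 0, 2 * pi)))
    sys <- manual_system(p, chains)
    nl <- build_neighbor_list(sys)
    listed <- paste(nl$pairs[, 1], nl$pairs[, 2])
    pos <- sys$pos / 1e-6
    ef <- unlist(lapply(0:19, function(f) 4 * f + f + 1:4))  # first vertex row
    ne <- length(ef)
    for (e1 in 1:(ne - 1)) {
      for (e2 in (e1 + 1):ne) {
        if (nl$edge_trichome[e1] == nl$edge_trichome[e2]) next
        # minimum image shift of edge 2
        m <- (pos[ef[e1], 1:2] + pos[ef[e1] + 1, 1:2]) / 2 -
             (pos[ef[e2], 1:2] + pos[ef[e2] + 1, 1:2]) / 2
        sh <- c(120 * round(m[1] / 120), 120 * round(m[2] / 120), 0)
        d <- grid_segment_distance(pos[ef[e1], ], pos[ef[e1] + 1, ],
                                   pos[ef[e2], ] + sh, pos[ef[e2] + 1, ] + sh,
                                   41, 41)$dist
        if (d < 3) # 2 theta
          expect_true(paste(e1, e2) %in% listed,
                      label = sprintf("pair %d-%d at %.2f um listed", e1, e2, d))
      }
    }
  }
})

test_that("at most two non-null interactions per edge pair", {
  set.seed(61)
  th <- 1
  maxn <- 0
  for (rep in 1:500) {
    c1 <- random_chain(3, l = 2)
    c2 <- random_chain(3, l = 2) +
      matrix(rnorm(3, 0, 1.2), 3, 3, byrow = TRUE)
    t1 <- vertex_tangents(c1); t2 <- vertex_tangents(c2)
    ints <- admissible_interactions(c1[1, ], c1[2, ], c2[1, ], c2[2, ],
                                    t1[1, ], t1[2, ], t2[1, ], t2[2, ],
                                    end1 = c(TRUE, FALSE), end2 = c(TRUE, FALSE))
    f <- vapply(ints, function(i)
      lj_force_magnitude(max(i$dist, 1e-9), th, 1, 1e6), numeric(1))
    maxn <- max(maxn, sum(f != 0))
  }
  expect_lte(maxn, 2)
})

test_that("engine admissibility agrees with the R reference implementation", {
  set.seed(71)
  for (rep in 1:200) {
    c1 <- random_chain(3, l = 1.5)
    c2 <- random_chain(3, l = 1.5) + matrix(rnorm(3, 0, 1), 3, 3, byrow = TRUE)
    t1 <- vertex_tangents(c1); t2 <- vertex_tangents(c2)
    for (tips in list(c(TRUE, FALSE, TRUE, FALSE), c(TRUE, TRUE, TRUE, TRUE))) {
      rint <- admissible_interactions(c1[1, ], c1[2, ], c2[1, ], c2[2, ],
                                      t1[1, ], t1[2, ], t2[1, ], t2[2, ],
                                      end1 = tips[1:2], end2 = tips[3:4])
      cint <- trichosim:::cpp_admissible(c1[1, ], c1[2, ], c2[1, ], c2[2, ],
                                         t1[1, ], t1[2, ], t2[1, ], t2[2, ],
                                         tips)
      expect_equal(length(rint), nrow(cint))
      if (length(rint) > 0) {
        rmat <- t(sapply(rint, function(i) c(i$a, i$b, i$dist)))
        o1 <- order(rmat[, 1], rmat[, 2])
        o2 <- order(cint[, 1], cint[, 2])
        expect_equal(rmat[o1, , drop = FALSE],
                     unname(cint[o2, , drop = FALSE]), tolerance = 1e-12)
      }
    }
  }
})
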