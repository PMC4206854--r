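# Equations of motion, constraint projection, integrator and the simulation
# loop.

test_that("wall forces: support boundaries and signs", {
  expect_equal(wall_forces(7.5 - 0.75, H = 7.5, theta = 1.5, wall_c = 2), 0)
  expect_equal(wall_forces(7.0, H = 7.5, theta = 1.5, wall_c = 1), -0.25)
  expect_equal(wall_forces(0.75 - 0.1, H = 7.5, theta = 1.5, wall_c = 3),
               3 * 0.1)
  expect_equal(wall_forces(c(3, 7.4), 7.5, 1.5, 1), c(0, -0.65))
})

test_that("velocity projection implements anisotropic mobility", {
  t <- c(1, 0, 0)
  expect_equal(project_velocity(c(2, 0, 0), t, zeta = 4, b = 2), c(0.5, 0, 0))
  expect_equal(project_velocity(c(0, 2, 0), t, zeta = 4, b = 2), c(0, 0.25, 0))
  # 45 degrees: v = (F_par + F_perp / 2) / zeta componentwise
  F <- c(1, 1, 0)
  expect_equal(project_velocity(F, t, 1, 2), c(1, 0.5, 0))
  # matrix form consistent with vector form
  Fm <- rbind(c(1, 1, 0), c(0, 0, 3))
  tm <- rbind(t, c(0, 1, 0))
  vm <- project_velocity(Fm, tm, 2, 2)
  expect_equal(vm[1, ], project_velocity(F, t, 2, 2))
  expect_equal(vm[2, ], c(0, 0, 0.75))
})

test_that("LINCS projection restores bond lengths minimally", {
  # fixed point: already-satisfying chain returned unchanged
  ref <- cbind(0:5, 0, 0)
  expect_equal(lincs_project(ref, ref, 1), ref, tolerance = 1e-14)

  # 2-vertex rod stretched axially: symmetric restoration
  ref2 <- rbind(c(0, 0, 0), c(1, 0, 0))
  prop <- rbind(c(0, 0, 0), c(1.01, 0, 0))
  out <- lincs_project(prop, ref2, 1)
  expect_equal(out[2, 1] - out[1, 1], 1, tolerance = 1e-8)
  expect_equal(out[1, 1] - 0, 0.005, tolerance = 1e-8)   # both ends move

  # random perturbed chains: bond lengths exact, matches Newton-Lagrange
  set.seed(71)
  for (rep in 1:10) {
    n <- 10
    ref <- random_chain(n, l = 1, wiggle = 0.3)
    prop <- ref + matrix(rnorm(3 * n, 0, 0.02), n, 3)
    out <- lincs_project(prop, ref, 1, tol = 1e-10)
    bl <- sqrt(rowSums((out[-1, ] - out[-n, ])^2))
    expect_lt(max(abs(bl - 1)), 1e-6)
    oracle <- lagrange_constrain_chain(prop, ref, 1)
    expect_lt(max(abs(out - oracle)), 1e-7)  # same projection
  }
})

test_that("compute_forces decomposes into the R reference force terms", {
  p <- system_params(domain = c(120, 7.5, 120), lam = 30, n_segments = 5,
                     rho = 0, beta = 0.5)
  # one bent and one straight trichome, far apart: bending + gliding + wall
  set.seed(81)
  bent <- straight_chain(6, 6, c(30, 30, 7.2))  # near top wall
  bent[, 2] <- bent[, 2] + c(0, 0.5, 1.5, 1.2, 0.3, 0)
  straightc <- straight_chain(6, 6, c(90, 90, 3.75), phi = 1)
  sys <- manual_system(p, list(bent, straightc), polarity = c(1L, -1L))
  F <- compute_forces(sys)
  z <- p$zeta; v0m <- p$v0 * 1e-6
  for (ch in 1:2) {
    rows <- (6 * (ch - 1) + 1):(6 * ch)
    vm <- sys$pos[rows, ] # metres
    Fr <- bending_forces(vm, p$alpha, p$l * 1e-6) +
      gliding_forces(vm, sys$polarity[ch], z, v0m)
    Fr[, 3] <- Fr[, 3] + wall_forces(vm[, 3], 7.5e-6, 1.5e-6, p$wall_c)
    expect_equal(F[rows, ], Fr, tolerance = 1e-10)
  }
})

test_that("contact forces in the engine match the R edge-pair composition", {
  p <- system_params(domain = c(120, 7.5, 120), lam = 12, n_segments = 2,
                     rho = 0, epsilon = 2e-12, cap_R = 1e-9)
  set.seed(82)
  for (rep in 1:10) {
    # two straight 3-vertex trichomes close enough to touch; no bending or
    # wall terms, so engine forces = gliding + contact
    c1 <- straight_chain(3, 6, c(60, 60, 3), phi = runif(1, 0, pi))
    c2 <- straight_chain(3, 6, c(60 + runif(1, -2, 2), 60 + runif(1, -2, 2),
                                 3 + runif(1, 0.3, 1.2)), phi = runif(1, 0, pi))
    sys <- manual_system(p, list(c1, c2))
    F <- compute_forces(sys)
    posu <- sys$pos / 1e-6   # edge_pair_forces uses the same unit as theta
    t1 <- vertex_tangents(posu[1:3, ]); t2 <- vertex_tangents(posu[4:6, ])
    Fr <- rbind(gliding_forces(posu[1:3, ], 1, p$zeta, p$v0 * 1e-6),
                gliding_forces(posu[4:6, ], 1, p$zeta, p$v0 * 1e-6))
    for (e1 in 1:2) {
      for (e2 in 1:2) {
        i1 <- e1; i3 <- 3 + e2
        r <- edge_pair_forces(posu[i1, ], posu[i1 + 1, ],
                              posu[i3, ], posu[i3 + 1, ],
                              t1[e1, ], t1[e1 + 1, ], t2[e2, ], t2[e2 + 1, ],
                              end1 = c(e1 == 1, e1 == 2),
                              end2 = c(e2 == 1, e2 == 2),
                              params = p)
        Fr[i1, ] <- Fr[i1, ] + r$forces[1, ]
        Fr[i1 + 1, ] <- Fr[i1 + 1, ] + r$forces[2, ]
        Fr[i3, ] <- Fr[i3, ] + r$forces[3, ]
        Fr[i3 + 1, ] <- Fr[i3 + 1, ] + r$forces[4, ]
      }
    }
    expect_lt(max(abs(F - Fr)), 1e-9 * max(abs(Fr)))
  }
})

test_that("global contact momentum balances in a crowded system", {
  p <- system_params(domain = c(120, 7.5, 120), lam = 24, n_segments = 4,
                     rho = 0, epsilon = 2e-12, cap_R = 1e-9)
  set.seed(83)
  chains <- lapply(1:12, function(i)
    straight_chain(5, 6, c(runif(1, 50, 70), runif(1, 50, 70),
                           runif(1, 1, 6.5)), phi = runif(1, 0, 2 * pi)))
  sys <- manual_system(p, chains)
  # straight mid-height chains: engine force = gliding + contact; gliding
  # is analytic, so the remainder is the contact sum
  Fg <- do.call(rbind, lapply(seq_along(chains), function(i)
    gliding_forces(sys$pos[(5 * i - 4):(5 * i), ], 1, p$zeta, p$v0 * 1e-6)))
  Fc <- compute_forces(sys) - Fg
  scale <- max(abs(Fc))
  expect_gt(scale, 0)
  expect_lt(max(abs(colSums(Fc))), 1e-10 * scale)
})

test_that("an isolated trichome glides straight at v0", {
  p <- system_params(domain = c(400, 7.5, 400), lam = 60, n_segments = 10,
                     rho = 0, omega = 0)
  sys <- manual_system(p, list(straight_chain(11, 6, c(100, 200, 3.75),
                                              phi = 0.3)))
  x0 <- sys$pos
  t_end <- 100
  sys2 <- trichosim:::.advance_to(sys, t_target = t_end)
  disp <- (sys2$pos - x0) / 1e-6
  speed <- mean(sqrt(rowSums(disp^2))) / t_end
  expect_equal(speed, 1.3, tolerance = 0.01)      # within 1% of v0
  # straight path along the initial tangent
  dir <- disp / sqrt(rowSums(disp^2))
  expect_lt(max(abs(dir[, 1] - cos(0.3))), 1e-4)
  expect_lt(max(abs(dir[, 2] - sin(0.3))), 1e-4)
  # bond lengths maintained
  bl <- sqrt(rowSums((sys2$pos[-1, ] - sys2$pos[-11, ])^2)) / 1e-6
  expect_lt(max(abs(bl - 6)) / 6, 1e-6)
})

test_that("adaptive stepping meets the accuracy target and converges", {
  p <- system_params(domain = c(200, 7.5, 200), lam = 30, n_segments = 5,
                     rho = 0, omega = 0)
  bent <- straight_chain(6, 6, c(100, 100, 3.75))
  bent[, 2] <- bent[, 2] + c(0, 2, 3, 3, 2, 0)   # strongly bent
  run_to <- function(acc) {
    pp <- p; pp$abs_accuracy <- acc
    sys <- manual_system(pp, list(bent))
    sys$dt <- 0.01
    trichosim:::.advance_to(sys, t_target = 50)
  }
  s1 <- run_to(0.1)
  st <- attr(s1, "step_stats")
  expect_lte(st$max_err, 0.1e-6 + 1e-12)   # per-step error within target
  # halving the tolerance halves the endpoint error (first order in dt,
  # second order per step); allow a generous band around the ratio 2
  ref <- run_to(1e-4)
  e1 <- max(abs(s1$pos - ref$pos))
  s2 <- run_to(0.05)
  e2 <- max(abs(s2$pos - ref$pos))
  expect_gt(e1 / e2, 1.2)
  expect_lt(e1 / e2, 5)
})

test_that("initialization: counts, bounds, polarity and bond lengths", {
  p <- system_params(domain = c(300, 7.5, 300), lam = 150, n_segments = 25,
                     rho = 0.025)
  set.seed(91)
  sys <- initialize_system(p)
  expect_equal(length(sys$polarity), p$n_trichomes)
  expect_true(all(sys$polarity %in% c(-1L, 1L)))
  z <- sys$pos[, 3] / 1e-6
  expect_true(all(z >= 0.75 - 1e-9 & z <= 6.75 + 1e-9))
  bl <- c()
  nv <- p$n_segments + 1
  for (f in seq_len(p$n_trichomes)) {
    rows <- ((f - 1) * nv + 1):(f * nv)
    bl <- c(bl, sqrt(rowSums(diff(sys$pos[rows, ])^2)) / 1e-6)
  }
  expect_equal(max(abs(bl - p$l)) / p$l, 0, tolerance = 1e-12)

  # rho = 0 gives a valid empty system
  p0 <- system_params(domain = c(300, 7.5, 300), lam = 150, n_segments = 25,
                      rho = 0)
  expect_equal(initialize_system(p0)$params$n_trichomes, 0)
})

test_that("overlap relaxation separates crossing trichomes", {
  p <- system_params(domain = c(200, 7.5, 200), lam = 60, n_segments = 10,
                     rho = 0)
  # two trichomes crossing at a small height offset
  c1 <- straight_chain(11, 6, c(100, 100, 3.7), phi = 0)
  c2 <- straight_chain(11, 6, c(100, 100, 3.8), phi = pi / 3)
  sys <- manual_system(p, list(c1, c2))
  par <- engine_par(p, gliding = FALSE, reversals = FALSE)
  sep0 <- trichosim:::cpp_min_separation(sys$pos, sys$offsets, par)
  expect_lt(sep0 / 1e-6, 0.2)
  rel <- relax_overlaps(sys)
  sep <- trichosim:::cpp_min_separation(rel$pos, rel$offsets, par)
  expect_gte(sep / 1e-6, 0.99 * 1.5)
  expect_equal(rel$t, 0)

  # already-relaxed configuration is a fixed point (no force-bearing steps)
  rel2 <- relax_overlaps(rel)
  expect_equal(rel2$pos, rel$pos, tolerance = 1e-12)
})

test_that("full runs are reproducible and respect invariants", {
  p <- system_params(domain = c(150, 7.5, 150), lam = 36, n_segments = 6,
                     rho = 0.01)
  sim1 <- run_simulation(p, t_end = 60, frame_interval = 20, seed = 5)
  sim2 <- run_simulation(p, t_end = 60, frame_interval = 20, seed = 5)
  expect_equal(as.data.frame(sim1$trajectory$frames),
               as.data.frame(sim2$trajectory$frames))

  fr <- sim1$trajectory$frames
  expect_equal(sort(unique(fr$time)), c(0, 20, 40, 60))
  # z containment with wall tolerance theta
  expect_true(all(fr$z > -1.5 & fr$z < 9))
  # inextensibility at every frame
  for (tt in unique(fr$time)) {
    f <- fr[fr$time == tt, ]
    for (tri in unique(f$trichome)) {
      v <- as.matrix(f[f$trichome == tri, c("x", "y", "z")])
      bl <- sqrt(rowSums(diff(v)^2))
      expect_lt(max(abs(bl - p$l)) / p$l, 1e-6)
    }
  }
  # a different seed gives a different trajectory
  sim3 <- run_simulation(p, t_end = 60, frame_interval = 20, seed = 6)
  expect_false(identical(sim1$trajectory$frames$x, sim3$trajectory$frames$x))
})
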