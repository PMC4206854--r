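# Pattern observables: nematic alignment (global and local), local cluster
# size, tangent correlation length, sector director autocorrelation time and
# sector density distributions. All metrics consume trajectory frames (um
# coordinates) through the documented schema only.

# ---- frame -> edge representation ------------------------------------------

#' Edge midpoints, directions and endpoints of one trajectory frame
#'
#' Converts a frame table (columns `trichome`, `vertex`, `x`, `y`, `z`) into
#' per-edge quantities used by the alignment and density metrics.
#'
#' @param frame a data.frame for a single time point.
#' @return List of class `trichome_edges` with `mid` (E x 3 midpoints),
#'   `dir` (E x 3 unit directions), `p1`, `p2` (E x 3 endpoints),
#'   `trichome` (edge owner ids) and `angle_xy` (xy-projected edge angle,
#'   radians).
#' @export
frame_edges <- function(frame) {
  o <- order(frame$trichome, frame$vertex)
  x <- cbind(frame$x, frame$y, frame$z)[o, , drop = FALSE]
  tri <- frame$trichome[o]
  n <- nrow(x)
  same <- tri[-n] == tri[-1]
  p1 <- x[-n, , drop = FALSE][same, , drop = FALSE]
  p2 <- x[-1, , drop = FALSE][same, , drop = FALSE]
  d <- p2 - p1
  nrm <- sqrt(rowSums(d * d))
  structure(list(mid = (p1 + p2) / 2, dir = d / nrm, p1 = p1, p2 = p2,
                 trichome = tri[-n][same],
                 angle_xy = atan2(d[, 2], d[, 1])),
            class = "trichome_edges")
}

# ---- global alignment ------------------------------------------------------

#' Global nematic alignment of a set of edge angles
#'
#' Length of the mean direction vector in the angle-doubled (nematic)
#' representation:
#' \deqn{S = \left\| \frac{1}{M}\sum_k (\cos 2\theta_k, \sin 2\theta_k) \right\|}
#' where the `theta_k` are the edge angles projected onto the xy plane.
#' Angle doubling makes the measure indifferent to head/tail direction:
#' 1 for a perfectly (nematically) aligned system, ~`M^{-1/2}` for random
#' orientations, and exactly 0 for two edge populations at 90 degrees.
#'
#' @param angles numeric vector of edge angles (radians, xy projection).
#' @return Scalar in \[0, 1\].
#' @examples
#' global_alignment(rep(pi / 6, 10))       # 1
#' global_alignment(c(0, pi / 2))          # 0
#' @export
global_alignment <- function(angles) {
  if (length(angles) == 0) stop("global_alignment: no edges")
  sqrt(mean(cos(2 * angles))^2 + mean(sin(2 * angles))^2)
}

# ---- local neighbourhood machinery -----------------------------------------

# Vectorised closest distance between segment pairs (rows of P1-Q1 vs
# P2-Q2), Ericson's clamped closest-point scheme.
.segseg_distance <- function(P1, Q1, P2, Q2) {
  d1 <- Q1 - P1
  d2 <- Q2 - P2
  r <- P1 - P2
  a <- rowSums(d1 * d1); e <- rowSums(d2 * d2)
  b <- rowSums(d1 * d2); cc <- rowSums(d1 * r); f <- rowSums(d2 * r)
  den <- a * e - b * b
  clamp01 <- function(x) pmin(1, pmax(0, x))
  s <- ifelse(den > 0, clamp01((b * f - cc * e) / den), 0)
  t0 <- (b * s + f) / e
  s <- ifelse(t0 < 0, clamp01(-cc / a),
              ifelse(t0 > 1, clamp01((b - cc) / a), s))
  t <- clamp01(t0)
  c1 <- P1 + d1 * s
  c2 <- P2 + d2 * t
  sqrt(rowSums((c1 - c2)^2))
}

# Chunked neighbour scan over edges; calls fn(i_rows, nbr_mask) where
# nbr_mask[r, k] marks edges k whose minimum segment separation from chunk
# edge r is within radius (midpoint prefilter at radius + l_max, then exact
# closest-point distance). Minimum-image in x and y when domain is given.
.with_neighbors <- function(edges, radius, domain = NULL, chunk = 256L, fn) {
  mid <- edges$mid
  n <- nrow(mid)
  l_max <- max(sqrt(rowSums((edges$p2 - edges$p1)^2)))
  pre2 <- (radius + l_max)^2
  out <- vector("list", ceiling(n / chunk))
  for (ci in seq_along(out)) {
    rows <- ((ci - 1L) * chunk + 1L):min(ci * chunk, n)
    dx <- outer(mid[rows, 1], mid[, 1], "-")
    dy <- outer(mid[rows, 2], mid[, 2], "-")
    dz <- outer(mid[rows, 3], mid[, 3], "-")
    sx <- sy <- 0
    if (!is.null(domain)) {
      sx <- domain[1] * round(dx / domain[1])
      sy <- domain[2] * round(dy / domain[2])
      dx <- dx - sx
      dy <- dy - sy
    }
    nbr <- dx * dx + dy * dy + dz * dz <= pre2
    idx <- which(nbr, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      i <- rows[idx[, 1]]; j <- idx[, 2]
      q1 <- edges$p1[j, , drop = FALSE]
      q2 <- edges$p2[j, , drop = FALSE]
      if (!is.null(domain)) {
        shift <- cbind(sx[idx], sy[idx], 0)
        q1 <- q1 + shift
        q2 <- q2 + shift
      }
      d <- .segseg_distance(edges$p1[i, , drop = FALSE],
                            edges$p2[i, , drop = FALSE], q1, q2)
      nbr[idx] <- d <= radius
    }
    out[[ci]] <- fn(rows, nbr)
  }
  unlist(out, use.names = FALSE)
}

#' Local nematic alignment around every edge
#'
#' For each edge j, the norm of the mean angle-doubled vector of the
#' relative orientations `theta_jk` (full 3-D angles between edge
#' directions, not projected) over all edges k that pass within `radius`
#' of edge j (minimum segment-segment separation). The edge itself is
#' included, so an isolated edge scores 1 and values always lie in
#' \[0, 1\]. The conventional radius is the trichome diameter theta, i.e.
#' the neighbourhood of physical contact.
#'
#' @param edges a `trichome_edges` object (see [frame_edges()]).
#' @param radius neighbourhood radius (same unit as the coordinates).
#' @param domain optional `c(W, D)` periodic box lengths for minimum-image
#'   neighbour distances.
#' @return List with `values` (per edge) and `mean`.
#' @export
local_alignment <- function(edges, radius, domain = NULL) {
  dir <- edges$dir
  vals <- .with_neighbors(edges, radius, domain, fn = function(rows, nbr) {
    # cos of 3-D angle between row edge and every other edge
    ct <- dir[rows, , drop = FALSE] %*% t(dir)
    ct[ct > 1] <- 1
    ct[ct < -1] <- -1
    st <- sqrt(pmax(0, 1 - ct * ct))
    c2 <- 2 * ct * ct - 1          # cos(2 theta)
    s2 <- 2 * ct * st              # sin(2 theta), theta in [0, pi]
    sapply(seq_along(rows), function(r) {
      k <- nbr[r, ]
      sqrt(mean(c2[r, k])^2 + mean(s2[r, k])^2)
    })
  })
  list(values = vals, mean = mean(vals))
}

#' Local cluster size around every edge
#'
#' Number of distinct trichomes (including the edge's own) that have at
#' least one edge passing within `radius` (minimum segment separation) of
#' the edge. The conventional radius is twice the trichome diameter.
#'
#' @param edges a `trichome_edges` object (see [frame_edges()]).
#' @param radius neighbourhood radius.
#' @param domain optional `c(W, D)` periodic box for minimum-image distances.
#' @return List with `values` (per-edge counts >= 1) and `mean`.
#' @export
local_cluster_size <- function(edges, radius, domain = NULL) {
  trichome <- edges$trichome
  vals <- .with_neighbors(edges, radius, domain, fn = function(rows, nbr) {
    sapply(seq_along(rows), function(r)
      length(unique(trichome[nbr[r, ]])))
  })
  list(values = vals, mean = mean(vals))
}

# ---- tangent correlation length --------------------------------------------

# Exponential-decay fit acf(k) ~ exp(-x_k / scale); lags after the first
# non-positive acf value are discarded. Returns Inf (sentinel) when the acf
# never decays, NA when no fit is possible.
.fit_exp_decay <- function(x, acf) {
  keep <- seq_along(acf)
  nz <- which(acf <= 0)
  if (length(nz) > 0) keep <- seq_len(nz[1] - 1)
  x <- x[keep]; acf <- acf[keep]
  if (length(acf) < 2) return(NA_real_)
  if (all(acf >= 1 - 1e-9)) return(Inf)
  slope <- sum(x * log(acf)) / sum(x * x)   # through (0, 1)
  if (slope >= 0) return(Inf)
  start <- -1 / slope
  fit <- tryCatch(
    minpack.lm::nlsLM(acf ~ exp(-x / s), start = list(s = start),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) start else unname(coef(fit)[["s"]])
}

#' Mean tangent correlation length of the trichome population
#'
#' For each trichome the tangent (edge direction) autocorrelation
#' \deqn{acf_f(k) = \frac{1}{N-k} \sum_{i=1}^{N-k} e_{f,i} \cdot e_{f,i+k}}
#' is averaged over trichomes and fitted with \eqn{\exp(-k\,l/\xi)} by
#' nonlinear least squares (lags beyond the first zero crossing are
#' discarded). Straight trichomes give an `Inf` sentinel. The result is the
#' arc length over which the filaments stay directionally correlated — a
#' persistence length of the instantaneous shapes.
#'
#' @param chains list of (N+1) x 3 vertex matrices, or a single matrix.
#' @param l segment length (same unit as the coordinates).
#' @param max_lag maximum lag used (default: all, N - 1).
#' @return List with `xi` (correlation length, unit of `l`; may be `Inf`),
#'   `acf` (mean autocorrelation) and `lags`.
#' @export
tangent_correlation_length <- function(chains, l, max_lag = NULL) {
  if (is.matrix(chains)) chains <- list(chains)
  if (length(chains) == 0) stop("tangent_correlation_length: no chains")
  nseg <- nrow(chains[[1]]) - 1
  if (nseg < 3) stop("tangent_correlation_length: chains need >= 3 edges")
  if (is.null(max_lag)) max_lag <- nseg - 1
  max_lag <- min(max_lag, nseg - 1)
  acfs <- sapply(chains, function(v) {
    e <- v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE]
    e <- e / sqrt(rowSums(e * e))
    sapply(0:max_lag, function(k) {
      i <- seq_len(nrow(e) - k)
      mean(rowSums(e[i, , drop = FALSE] * e[i + k, , drop = FALSE]))
    })
  })
  m <- if (is.matrix(acfs)) rowMeans(acfs) else acfs
  lags <- 0:max_lag
  xi <- .fit_exp_decay(lags * l, m)
  list(xi = xi, acf = m, lags = lags)
}

#' Synthetic worm-like chains with known persistence length
#'
#' Generates discrete chains whose unit tangents perform a random walk on
#' the sphere: at every joint the tangent is deflected by independent
#' Gaussian angles (variance `l / persistence` in each of the two normal
#' directions), giving tangent correlations `exp(-k l / persistence)` in the
#' small-angle regime. Used to validate the correlation-length estimator
#' against a known ground truth.
#'
#' @param n_chains number of chains.
#' @param n_edges edges per chain.
#' @param l edge length.
#' @param persistence target persistence length (same unit as `l`).
#' @return List of (n_edges + 1) x 3 vertex matrices.
#' @export
synthetic_wormlike_chains <- function(n_chains, n_edges, l, persistence) {
  stopifnot(n_chains >= 1, n_edges >= 3, l > 0, persistence > 0)
  sdv <- sqrt(l / persistence)
  lapply(seq_len(n_chains), function(i) {
    # random initial direction
    t <- rnorm(3); t <- t / sqrt(sum(t * t))
    v <- matrix(0, n_edges + 1, 3)
    for (k in seq_len(n_edges)) {
      v[k + 1, ] <- v[k, ] + l * t
      # orthonormal frame around t
      a <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      n1 <- a - sum(a * t) * t; n1 <- n1 / sqrt(sum(n1 * n1))
      n2 <- c(t[2] * n1[3] - t[3] * n1[2], t[3] * n1[1] - t[1] * n1[3],
              t[1] * n1[2] - t[2] * n1[1])
      th <- rnorm(2, 0, sdv)
      t <- t + th[1] * n1 + th[2] * n2
      t <- t / sqrt(sum(t * t))
    }
    v
  })
}

# ---- sector analyses -------------------------------------------------------

# Sector index grid: nx x ny cells of ~`sector` um over the periodic box.
.sector_grid <- function(W, D, sector) {
  nx <- max(1L, as.integer(round(W / sector)))
  ny <- max(1L, as.integer(round(D / sector)))
  list(nx = nx, ny = ny, wx = W / nx, wy = D / ny)
}

.sector_index <- function(mid, W, D, g) {
  ix <- pmin(g$nx - 1L, as.integer(floor((mid[, 1] %% W) / g$wx)))
  iy <- pmin(g$ny - 1L, as.integer(floor((mid[, 2] %% D) / g$wy)))
  iy * g$nx + ix + 1L
}

#' Sector alignment autocorrelation time
#'
#' Measures the temporal stability of the pattern: the domain is divided
#' into square sectors, each sector's nematic director (angle-doubled mean
#' of the xy-projected edge angles inside it) is followed over the analysis
#' window, and the director autocorrelation
#' `acf(k) = <cos 2(psi_{t+k} - psi_t)>` (averaged over sectors occupied
#' throughout the window) is fitted with `exp(-k dt / T)`. Long times T mean
#' a frozen-in stream pattern; times near zero mean the local orientation
#' decorrelates between frames.
#'
#' @param traj a `trichome_trajectory` (or `trichome_sim`).
#' @param sector sector edge length (um); the grid uses the nearest integer
#'   subdivision of the box.
#' @param window analysis window: the last `window` seconds of the
#'   trajectory (default 7200 s).
#' @return List with `T_corr` (s; `Inf` if the pattern never decorrelates,
#'   capped reporting at the window length via `sentinel`), `acf`, `lags`
#'   (s), `n_sectors` used.
#' @export
sector_alignment_autocorrelation_time <- function(traj, sector = 100,
                                                  window = 7200) {
  traj <- .as_trajectory(traj)
  fr <- traj$frames
  times <- sort(unique(fr$time))
  tmax <- max(times)
  times <- times[times >= tmax - window - 1e-9]
  if (length(times) < 3)
    stop("sector_alignment_autocorrelation_time: need >= 3 frames in the ",
         "window, have ", length(times))
  W <- traj$params$domain[1]; D <- traj$params$domain[3]
  g <- .sector_grid(W, D, sector)
  # director angle psi per sector per frame (NA when empty)
  psi <- matrix(NA_real_, g$nx * g$ny, length(times))
  for (j in seq_along(times)) {
    ed <- frame_edges(fr[fr$time == times[j], ])
    s <- .sector_index(ed$mid, W, D, g)
    c2 <- tapply(cos(2 * ed$angle_xy), s, mean)
    s2 <- tapply(sin(2 * ed$angle_xy), s, mean)
    idx <- as.integer(names(c2))
    psi[idx, j] <- atan2(s2, c2) / 2
  }
  occupied <- rowSums(is.na(psi)) == 0
  if (!any(occupied))
    stop("sector_alignment_autocorrelation_time: no sector occupied in all frames")
  psi <- psi[occupied, , drop = FALSE]
  nf <- length(times)
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-6 * max(dt))
    warning("frames in window are not equally spaced; using mean interval")
  dtm <- mean(dt)
  lags <- 0:(nf - 2)
  acf <- sapply(lags, function(k) {
    i <- seq_len(nf - k)
    mean(cos(2 * (psi[, i + k, drop = FALSE] - psi[, i, drop = FALSE])))
  })
  Tc <- .fit_exp_decay(lags * dtm, acf)
  if (is.na(Tc)) Tc <- 0  # decorrelated within a single frame interval
  sentinel <- (nf - 1) * dtm
  list(T_corr = if (is.infinite(Tc)) sentinel else Tc,
       uncapped = Tc, sentinel = sentinel,
       acf = acf, lags = lags * dtm, n_sectors = nrow(psi))
}

#' Sector density distribution
#'
#' Per-sector edge counts of a configuration, as a raw histogram and
#' standardised against a reference configuration (typically the random
#' initial state, whose sector counts are approximately Gaussian with mean
#' `mu` and standard deviation `sigma`). Self-organisation into streams or
#' bands shows up as positive skewness relative to the initial Gaussian.
#'
#' @param frame a single-frame data.frame (or `trichome_system`).
#' @param params a [system_params()] object supplying the domain (not
#'   needed if `frame` is a system).
#' @param sector sector edge length (um).
#' @param reference optional reference frame (same format); defaults to
#'   `frame` itself.
#' @return List with `counts` (per sector), `mu`, `sigma` (of the reference),
#'   `standardized` (counts minus mu over sigma), `skewness` (of the raw
#'   counts) and `density` (normalised histogram table).
#' @export
sector_density_distribution <- function(frame, params = NULL, sector = 100,
                                        reference = NULL) {
  if (inherits(frame, "trichome_system")) {
    params <- frame$params
    frame <- .frame_record(frame, frame$t)
  }
  if (is.null(params)) stop("sector_density_distribution: params required")
  W <- params$domain[1]; D <- params$domain[3]
  g <- .sector_grid(W, D, sector)
  count_of <- function(fdf) {
    ed <- frame_edges(fdf)
    s <- .sector_index(ed$mid, W, D, g)
    cnt <- integer(g$nx * g$ny)
    tab <- table(s)
    cnt[as.integer(names(tab))] <- as.integer(tab)
    cnt
  }
  counts <- count_of(frame)
  ref_counts <- if (is.null(reference)) counts else count_of(reference)
  mu <- mean(ref_counts)
  sigma <- sd(ref_counts)
  m2 <- mean((counts - mean(counts))^2)
  m3 <- mean((counts - mean(counts))^3)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  tab <- table(counts)
  list(counts = counts, mu = mu, sigma = sigma,
       standardized = if (sigma > 0) (counts - mu) / sigma else counts * 0,
       skewness = skew,
       density = as.numeric(tab) / sum(tab))
}

# ---- report ----------------------------------------------------------------

.as_trajectory <- function(x) {
  if (inherits(x, "trichome_sim")) return(x$trajectory)
  if (inherits(x, "trichome_trajectory")) return(x)
  stop("expected a trichome_sim or trichome_trajectory")
}

#' Pattern metrics report for a trajectory
#'
#' Per-frame global alignment, mean local alignment (radius theta), mean
#' local cluster size (radius 2 theta) and tangent correlation length, plus
#' the sector alignment autocorrelation time over the final window and the
#' sector density skewness of the last frame relative to the first.
#'
#' @param traj a `trichome_sim` or `trichome_trajectory`.
#' @param sector sector edge length (um) for the sector analyses.
#' @param window window (s) for the autocorrelation time.
#' @param local logical; compute the (more expensive) per-edge local
#'   metrics for every frame (otherwise first and last frame only).
#' @return A `trichome_metrics` object: data.frame `per_frame` plus
#'   `T_corr`, `density` and the call parameters.
#' @export
compute_metrics <- function(traj, sector = 100, window = 7200,
                            local = FALSE) {
  tr <- .as_trajectory(traj)
  fr <- tr$frames
  params <- tr$params
  dom <- c(params$domain[1], params$domain[3])
  times <- sort(unique(fr$time))
  do_local <- if (local) rep(TRUE, length(times)) else
    times %in% c(times[1], times[length(times)])
  rows <- lapply(seq_along(times), function(j) {
    f <- fr[fr$time == times[j], ]
    ed <- frame_edges(f)
    la <- cs <- NA_real_
    if (do_local[j]) {
      la <- local_alignment(ed, params$theta, dom)$mean
      cs <- local_cluster_size(ed, 2 * params$theta, dom)$mean
    }
    chains <- lapply(split(seq_len(nrow(f)), f$trichome), function(i) {
      o <- i[order(f$vertex[i])]
      cbind(f$x[o], f$y[o], f$z[o])
    })
    xi <- tangent_correlation_length(chains, params$l)$xi
    data.frame(time = times[j],
               global_alignment = global_alignment(ed$angle_xy),
               local_alignment = la, cluster_size = cs,
               xi_corr = xi)
  })
  per_frame <- do.call(rbind, rows)
  Tc <- if (length(times) >= 3)
    tryCatch(sector_alignment_autocorrelation_time(tr, sector, window),
             error = function(e) NULL) else NULL
  dens <- sector_density_distribution(
    fr[fr$time == times[length(times)], ], params, sector,
    reference = fr[fr$time == times[1], ])
  structure(list(per_frame = per_frame, T_corr = Tc, density = dens,
                 sector = sector, window = window),
            class = "trichome_metrics")
}

#' @export
print.trichome_metrics <- function(x, ...) {
  cat("Pattern metrics\n")
  print(x$per_frame, row.names = FALSE, digits = 4)
  if (!is.null(x$T_corr))
    cat(sprintf("sector alignment autocorrelation time: %.4g s (%d sectors)\n",
                x$T_corr$T_corr, x$T_corr$n_sectors))
  cat(sprintf("sector density skewness (final vs initial Gaussian mu=%.3g sd=%.3g): %.3g\n",
              x$density$mu, x$density$sigma, x$density$skewness))
  invisible(x)
}
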