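#' Per-vertex drag coefficient of a slender gliding trichome
#'
#' Slender-body drag of a thin cylinder of length `lam` and diameter `theta`
#' in a medium of viscosity `mu`, divided evenly over the `n_segments + 1`
#' vertices of the discretised centerline:
#' \deqn{\zeta = \frac{1}{N+1}\,\frac{4\pi\mu\Lambda}{\ln(2\Lambda/\Theta) + c}}
#' The shape constant `c_shape` is of order unity; 1/2 is the conventional
#' choice for a straight filament.
#'
#' @param mu medium viscosity (Pa s).
#' @param lam trichome length (m).
#' @param theta trichome diameter (m).
#' @param n_segments number of edges N in the discretised centerline.
#' @param c_shape dimensionless slender-body shape constant.
#' @return Per-vertex drag coefficient (N s/m).
#' @examples
#' drag_coefficient(1, 750e-6, 1.5e-6, 125)  # ~1.01e-5 N s/m
#' @export
drag_coefficient <- function(mu, lam, theta, n_segments, c_shape = 0.5) {
  stopifnot(is.numeric(mu), is.numeric(lam), is.numeric(theta))
  if (mu <= 0 || lam <= 0 || theta <= 0 || n_segments < 1 || c_shape <= 0)
    stop("drag_coefficient: all parameters must be positive (n_segments >= 1)")
  if (2 * lam / theta <= 1)
    stop("drag_coefficient: requires a slender filament (2*lam/theta > 1)")
  (1 / (n_segments + 1)) * 4 * pi * mu * lam / (log(2 * lam / theta) + c_shape)
}

#' Characteristic scales of the nondimensionalised model
#'
#' The overdamped equations of motion admit a natural length and time scale:
#' taking the characteristic velocity as the gliding speed `V = v0` and the
#' characteristic length as \eqn{L = \sqrt{\alpha/(\zeta v_0)}} reduces the
#' bending and gliding force coefficients to unity, leaving a single
#' dimensionless group, the cohesion strength
#' \eqn{\beta = \epsilon/(\zeta v_0)}.
#'
#' @param alpha bending modulus (N m^2).
#' @param zeta per-vertex drag (N s/m), see [drag_coefficient()].
#' @param v0 gliding speed (m/s).
#' @param epsilon cohesion strength (N); may be 0.
#' @return A list of class `characteristic_scales` with elements `L` (m),
#'   `V` (m/s), `T` (s) and the dimensionless `beta`.
#' @examples
#' characteristic_scales(2e-21, 1.01e-5, 1.3e-6)
#' @export
characteristic_scales <- function(alpha, zeta, v0, epsilon = 0) {
  if (alpha <= 0 || zeta <= 0 || v0 <= 0 || epsilon < 0)
    stop("characteristic_scales: alpha, zeta, v0 must be positive; epsilon >= 0")
  L <- sqrt(alpha / (zeta * v0))
  structure(list(L = L, V = v0, T = L / v0, beta = epsilon / (zeta * v0)),
            class = "characteristic_scales")
}

#' @export
print.characteristic_scales <- function(x, ...) {
  cat("Characteristic scales:\n")
  cat(sprintf("  L    = %.4g um\n", x$L / .um))
  cat(sprintf("  V    = %.4g um/s\n", x$V / .um))
  cat(sprintf("  T    = %.4g s\n", x$T))
  cat(sprintf("  beta = %.4g\n", x$beta))
  invisible(x)
}

#' Bending modulus from thermal persistence length (and back)
#'
#' Under purely thermal flexure the persistence length \eqn{\xi} of a
#' filament is proportional to its bending modulus,
#' \eqn{\alpha = k_B T \xi}. These helpers convert in both directions with
#' the exact SI Boltzmann constant.
#'
#' @param xi persistence length (m).
#' @param alpha bending modulus (N m^2).
#' @param temperature absolute temperature (K); default 293.15 K (20 C).
#' @return `alpha_from_persistence`: bending modulus (N m^2);
#'   `persistence_from_alpha`: persistence length (m).
#' @examples
#' alpha_from_persistence(480e-6)        # ~1.94e-24 N m^2
#' persistence_from_alpha(2e-21)         # ~0.49 m
#' @export
alpha_from_persistence <- function(xi, temperature = 293.15) {
  if (xi <= 0 || temperature <= 0)
    stop("alpha_from_persistence: xi and temperature must be positive")
  .kB * temperature * xi
}

#' @rdname alpha_from_persistence
#' @export
persistence_from_alpha <- function(alpha, temperature = 293.15) {
  if (alpha <= 0 || temperature <= 0)
    stop("persistence_from_alpha: alpha and temperature must be positive")
  alpha / (.kB * temperature)
}

#' Young's modulus of the cell wall implied by a bending modulus (and back)
#'
#' Treats the trichome cross-section as a hollow cylinder whose bending
#' resistance resides in the cell wall: with outer radius `r = diameter/2`
#' and wall thickness `t`,
#' \deqn{Y = \frac{4\alpha}{\pi\,(r^4 - (r-t)^4)}.}
#' This converts a filament-level stiffness into a material stiffness that
#' can be compared across species with different diameters.
#'
#' @param alpha bending modulus (N m^2).
#' @param young Young's modulus (Pa).
#' @param diameter trichome outer diameter (m).
#' @param wall_thickness cell wall thickness (m); must be < diameter/2.
#' @return `young_from_alpha`: Young's modulus (Pa);
#'   `alpha_from_young`: bending modulus (N m^2).
#' @examples
#' young_from_alpha(1.94e-24, 2.1e-6, 10e-9)  # ~54 Pa
#' @export
young_from_alpha <- function(alpha, diameter, wall_thickness) {
  r <- diameter / 2
  t <- wall_thickness
  if (alpha <= 0 || diameter <= 0 || t <= 0)
    stop("young_from_alpha: all arguments must be positive")
  if (t >= r)
    stop("young_from_alpha: wall thickness must be smaller than the radius")
  4 * alpha / (pi * (r^4 - (r - t)^4))
}

#' @rdname young_from_alpha
#' @export
alpha_from_young <- function(young, diameter, wall_thickness) {
  r <- diameter / 2
  t <- wall_thickness
  if (young <= 0 || diameter <= 0 || t <= 0)
    stop("alpha_from_young: all arguments must be positive")
  if (t >= r)
    stop("alpha_from_young: wall thickness must be smaller than the radius")
  young * pi * (r^4 - (r - t)^4) / 4
}

# Defaults: observed Pseudanabaena geometry and motility in a shallow
# 3.5 x 3.5 mm culture domain. Units here are the user-facing ones
# (um, s, K); alpha, mu and epsilon are SI (N m^2, Pa s, N).
.param_defaults <- function() {
  list(
    theta        = 1.5,      # trichome diameter, um
    lam          = 750,      # trichome length, um
    n_segments   = 125L,     # edges per trichome (segment length ~6 um = 4*theta)
    alpha        = 2e-21,    # bending modulus, N m^2
    mu           = 1,        # medium viscosity, Pa s
    c_shape      = 0.5,      # slender-body shape constant
    v0           = 1.3,      # gliding speed, um/s
    omega        = 1 / 300,  # reversal frequency, 1/s
    beta         = 0,        # dimensionless cohesion eps/(zeta*v0); 0 = steric only
    epsilon      = NULL,     # cohesion strength, N (overrides beta if given)
    b_aniso      = 2,        # perpendicular/tangential drag ratio
    cap_R        = NULL,     # repulsive force cap, N (default 100*zeta*v0)
    wall_c       = NULL,     # wall stiffness, N/m (default 100*zeta*v0/theta)
    domain       = c(3500, 7.5, 3500),  # W, H, D in um
    rho          = 0.025,    # trichome volume fraction
    abs_accuracy = 0.1,      # integrator absolute accuracy, um
    temperature  = 293.15,   # K, only used in persistence-length conversions
    seed         = 1L
  )
}

#' Construct and validate a full simulation parameter set
#'
#' Fills unspecified entries with the default \emph{Pseudanabaena} culture
#' values, checks all invariants and derives the internal SI quantities used
#' by the dynamics: segment length `l`, per-vertex drag `zeta`, cohesion
#' `epsilon` (from `beta` unless given explicitly), repulsion cap `cap_R`,
#' wall stiffness `wall_c` and the characteristic `scales`.
#'
#' User-facing lengths (`theta`, `lam`, `domain`, `abs_accuracy`) and speeds
#' (`v0`) are in micrometres and seconds; `alpha` (N m^2), `mu` (Pa s),
#' `epsilon` (N), `cap_R` (N) and `wall_c` (N/m) are SI.
#'
#' @param ... named parameters overriding the defaults; see
#'   [load_config()] for the full key list.
#' @param .overrides optional named list merged after `...`.
#' @return An object of class `system_params`: the resolved list plus
#'   derived fields `l` (um), `zeta` (N s/m), `epsilon` (N), `cap_R`,
#'   `wall_c`, `n_trichomes` and `scales`.
#' @examples
#' p <- system_params(domain = c(500, 7.5, 500), lam = 250, n_segments = 42)
#' p$n_trichomes
#' @export
system_params <- function(..., .overrides = NULL) {
  defaults <- .param_defaults()
  user <- c(list(...), .overrides)
  if (length(user) > 0 && (is.null(names(user)) || any(names(user) == "")))
    stop("system_params: all parameters must be named")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("system_params: unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- modifyList(defaults, user, keep.null = TRUE)

  # -- validation -----------------------------------------------------------
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("system_params: ", msg)
  chk(p$theta > 0, "theta must be > 0")
  chk(p$lam > 0, "lam must be > 0")
  chk(is.numeric(p$n_segments) && p$n_segments >= 2 && p$n_segments == round(p$n_segments),
      "n_segments must be an integer >= 2")
  chk(p$alpha > 0, "alpha must be > 0")
  chk(p$mu > 0, "mu must be > 0")
  chk(p$c_shape > 0, "c_shape must be > 0")
  chk(p$v0 > 0, "v0 must be > 0")
  chk(p$omega >= 0, "omega must be >= 0")
  chk(p$b_aniso >= 1, "b_aniso must be >= 1")
  chk(is.numeric(p$domain) && length(p$domain) == 3 && all(p$domain > 0),
      "domain must be positive W, H, D")
  chk(p$domain[2] < p$domain[1] && p$domain[2] < p$domain[3],
      "shallow domain required: H < W and H < D")
  chk(p$rho >= 0 && p$rho < 1, "rho must be in [0, 1)")
  chk(p$abs_accuracy > 0, "abs_accuracy must be > 0")
  chk(p$temperature > 0, "temperature must be > 0")
  if (!is.null(p$epsilon)) chk(p$epsilon >= 0, "epsilon must be >= 0")
  chk(is.null(p$beta) || p$beta >= 0, "beta must be >= 0")

  # -- derived quantities ---------------------------------------------------
  p$n_segments <- as.integer(p$n_segments)
  p$l <- p$lam / p$n_segments                     # segment length, um
  p$zeta <- drag_coefficient(p$mu, p$lam * .um, p$theta * .um,
                             p$n_segments, p$c_shape)
  f_glide <- p$zeta * p$v0 * .um                  # gliding force scale, N
  if (is.null(p$epsilon)) p$epsilon <- p$beta * f_glide
  p$beta <- p$epsilon / f_glide
  if (is.null(p$cap_R)) p$cap_R <- 100 * f_glide
  if (is.null(p$wall_c)) p$wall_c <- 100 * f_glide / (p$theta * .um)
  p$n_trichomes <- trichome_count(p$rho, p$domain, p$theta, p$lam)
  p$scales <- characteristic_scales(p$alpha, p$zeta, p$v0 * .um, p$epsilon)
  p$seed <- as.integer(p$seed)
  class(p) <- "system_params"
  p
}

#' Number of trichomes implied by a target volume fraction
#'
#' The trichome count is the domain volume times the volume fraction `rho`
#' divided by the volume of one cylindrical trichome \eqn{\pi(\Theta/2)^2\Lambda}
#' (end caps ignored; <0.1% at the default aspect ratio), rounded to the
#' nearest integer.
#'
#' @param rho volume fraction in \[0, 1).
#' @param domain numeric W, H, D (um).
#' @param theta trichome diameter (um).
#' @param lam trichome length (um).
#' @return Integer trichome count.
#' @examples
#' trichome_count(0.025, c(3500, 7.5, 3500), 1.5, 750)  # 1733
#' @export
trichome_count <- function(rho, domain, theta, lam) {
  as.integer(round(rho * prod(domain) / (pi * (theta / 2)^2 * lam)))
}

#' @export
print.system_params <- function(x, ...) {
  cat("Gliding-trichome system parameters\n")
  cat(sprintf("  trichomes: %d (rho = %.4g), lam = %g um, theta = %g um, N = %d (l = %.3g um)\n",
              x$n_trichomes, x$rho, x$lam, x$theta, x$n_segments, x$l))
  cat(sprintf("  domain: %g x %g x %g um (W x H x D), periodic in x,y\n",
              x$domain[1], x$domain[2], x$domain[3]))
  cat(sprintf("  alpha = %.3g N m^2, zeta = %.3g N s/m, v0 = %g um/s, omega = %.4g 1/s\n",
              x$alpha, x$zeta, x$v0, x$omega))
  cat(sprintf("  beta = %.4g (epsilon = %.3g N), cap_R = %.3g N, wall_c = %.3g N/m\n",
              x$beta, x$epsilon, x$cap_R, x$wall_c))
  cat(sprintf("  scales: L = %.4g um, T = %.4g s; abs accuracy %.3g um; seed %d\n",
              x$scales$L / .um, x$scales$T, x$abs_accuracy, x$seed))
  invisible(x)
}

# Internal: flat list of engine parameters, all in SI, passed to C++.
.engine_params <- function(p, gliding = TRUE, cohesion = TRUE,
                           reversals = TRUE) {
  f_glide <- p$zeta * p$v0 * .um
  # beta=0 runs keep the hard core with the epsilon of beta = 0.125
  eps_rep <- if (p$epsilon > 0) p$epsilon else 0.125 * f_glide
  list(
    theta = p$theta * .um, l = p$l * .um,
    alpha = p$alpha, zeta = p$zeta,
    v0 = if (gliding) p$v0 * .um else 0,
    omega = if (reversals) p$omega else 0,
    epsilon = if (cohesion) p$epsilon else 0,
    eps_rep = eps_rep,
    b_aniso = p$b_aniso, cap_R = p$cap_R, wall_c = p$wall_c,
    W = p$domain[1] * .um, H = p$domain[2] * .um, D = p$domain[3] * .um,
    abs_accuracy = p$abs_accuracy * .um,
    dt_max = if (p$omega > 0 && reversals) 0.05 / p$omega else 30,
    dt_min = 1e-9,
    lincs_tol = 1e-8, lincs_maxit = 100L
  )
}
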