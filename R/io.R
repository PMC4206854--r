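# Configuration files, trajectory containers, VTK export and demo runs.
# Trajectory schema (version 1): one CSV with columns
#   time (s), trichome (1-based id), vertex (0-based index),
#   x, y, z (um, unwrapped), polarity (+1/-1)
# plus manifest.json holding the fully resolved parameters and seed.

.SCHEMA_VERSION <- 1L

#' Read a simulation configuration from JSON
#'
#' The file must contain a flat JSON object whose keys are parameter names
#' (see [system_params()]): `theta`, `lam`, `n_segments`, `alpha`, `mu`,
#' `c_shape`, `v0`, `omega`, `beta` or `epsilon`, `b_aniso`, `cap_R`,
#' `wall_c`, `domain` (array W, H, D), `rho`, `abs_accuracy`,
#' `temperature`, `seed`. Lengths and speeds are in micrometres and
#' seconds; `alpha` (N m^2), `mu` (Pa s), `epsilon`/`cap_R` (N) and
#' `wall_c` (N/m) are SI. Missing keys fall back to the documented
#' defaults; unknown keys are an error.
#'
#' @param path JSON file path.
#' @return A validated [system_params()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(cfg) > 0 && is.null(names(cfg)))
    stop("load_config: top level must be a JSON object")
  system_params(.overrides = cfg)
}

#' Write a resolved configuration back to JSON
#'
#' @param params a [system_params()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  stopifnot(inherits(params, "system_params"))
  keys <- names(.param_defaults())
  out <- unclass(params)[keys]
  out$epsilon <- params$epsilon
  out$cap_R <- params$cap_R
  out$wall_c <- params$wall_c
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

.new_trajectory <- function(frames, params, seed) {
  structure(list(frames = frames, params = params, seed = seed,
                 schema = .SCHEMA_VERSION),
            class = "trichome_trajectory")
}

#' @export
print.trichome_trajectory <- function(x, ...) {
  tt <- unique(x$frames$time)
  cat(sprintf("trichome_trajectory: %d frames (t = %.0f..%.0f s), %d trichomes, schema v%d\n",
              length(tt), min(tt), max(tt), length(unique(x$frames$trichome)),
              x$schema))
  invisible(x)
}

.run_manifest <- function(params, seed, t_end, frame_interval) {
  list(schema = .SCHEMA_VERSION,
       package_version = as.character(utils::packageVersion("trichosim")),
       seed = as.integer(seed), t_end = t_end,
       frame_interval = frame_interval,
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       params = {
         keys <- names(.param_defaults())
         p <- unclass(params)[keys]
         p$epsilon <- params$epsilon; p$cap_R <- params$cap_R
         p$wall_c <- params$wall_c
         p
       })
}

#' Write a simulation trajectory to disk
#'
#' Creates `manifest.json` (schema version, resolved parameters, seed) and
#' `frames.csv` (the frame table) in `dir`. A run is fully reproducible
#' from its manifest alone via [run_simulation()] on the same platform.
#'
#' @param sim a `trichome_sim` (or a `trichome_trajectory` plus `manifest`).
#' @param dir output directory (created if missing).
#' @param manifest manifest list when `sim` is a bare trajectory.
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(sim, dir, manifest = NULL) {
  if (inherits(sim, "trichome_sim")) {
    traj <- sim$trajectory
    manifest <- sim$manifest
  } else {
    traj <- .as_trajectory(sim)
    if (is.null(manifest))
      manifest <- .run_manifest(traj$params, traj$seed, max(traj$frames$time),
                                NA_real_)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  data.table::fwrite(traj$frames, file.path(dir, "frames.csv"))
  invisible(dir)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Validates the schema version and the column set; on a truncated or
#' corrupt frame table the error names the offending frame.
#'
#' @param dir directory containing `manifest.json` and `frames.csv`.
#' @return A `trichome_trajectory`.
#' @export
read_trajectory <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  fpath <- file.path(dir, "frames.csv")
  if (!file.exists(mpath) || !file.exists(fpath))
    stop("read_trajectory: ", dir, " lacks manifest.json / frames.csv")
  manifest <- jsonlite::fromJSON(mpath)
  if (is.null(manifest$schema) || manifest$schema != .SCHEMA_VERSION)
    stop("read_trajectory: unsupported schema version ", manifest$schema)
  fr <- data.table::fread(fpath)
  need <- c("time", "trichome", "vertex", "x", "y", "z", "polarity")
  if (!all(need %in% names(fr)))
    stop("read_trajectory: frames.csv missing columns: ",
         paste(setdiff(need, names(fr)), collapse = ", "))
  if (anyNA(fr)) {
    bad <- fr$time[which(rowSums(is.na(fr)) > 0)[1]]
    stop("read_trajectory: corrupt record in frame t = ", bad)
  }
  params <- system_params(.overrides = manifest$params[
    names(manifest$params) %in% names(.param_defaults())])
  .new_trajectory(fr, params, manifest$seed)
}

#' Export a trajectory frame as legacy VTK polylines
#'
#' Writes one ASCII VTK polydata file per requested frame; each trichome is
#' one polyline with N+1 points. Viewable in ParaView.
#'
#' @param traj a `trichome_sim` or `trichome_trajectory`.
#' @param dir output directory.
#' @param times frame times to export (default: all).
#' @return Character vector of files written, invisibly.
#' @export
export_vtk <- function(traj, dir, times = NULL) {
  tr <- .as_trajectory(traj)
  fr <- tr$frames
  if (is.null(times)) times <- unique(fr$time)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (tt in times) {
    f <- fr[fr$time == tt, ]
    f <- f[order(f$trichome, f$vertex), ]
    npts <- nrow(f)
    tris <- split(seq_len(npts), f$trichome)
    path <- file.path(dir, sprintf("frame_%010.0f.vtk", tt))
    con <- file(path, "w")
    writeLines(c("# vtk DataFile Version 3.0",
                 sprintf("trichomes t=%g s", tt), "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d float", npts)), con)
    writeLines(sprintf("%.6g %.6g %.6g", f$x, f$y, f$z), con)
    writeLines(sprintf("LINES %d %d", length(tris),
                       length(tris) + npts), con)
    for (idx in tris)
      writeLines(paste(c(length(idx), idx - 1L), collapse = " "), con)
    close(con)
    files <- c(files, path)
  }
  invisible(files)
}

# ---- demos -----------------------------------------------------------------

.demo_scenarios <- function() {
  base <- list(domain = c(300, 7.5, 300), lam = 150, n_segments = 25L,
               rho = 0.025)
  list(
    smoke   = list(params = c(base, list(rho = 0.006)), t_end = 60,
                   frame_interval = 30,
                   about = "tiny fast run exercising the full pipeline"),
    streams = list(params = c(base, list(beta = 0)), t_end = 1800,
                   frame_interval = 180,
                   about = "no cohesion: broad locally aligned streams"),
    bands   = list(params = c(base, list(beta = 0.25)), t_end = 1800,
                   frame_interval = 180,
                   about = "weak cohesion: thin nematically aligned bands"),
    chaotic = list(params = c(base, list(beta = 1)), t_end = 1800,
                   frame_interval = 180,
                   about = "comparable cohesion and gliding: churning network"),
    mesh    = list(params = c(base, list(beta = 5)), t_end = 1800,
                   frame_interval = 180,
                   about = "strong cohesion: dynamic mesh of thin bands")
  )
}

#' Run a documented, scaled-down demonstration scenario
#'
#' Named scenarios mirror the qualitative cohesion regimes (streams at
#' beta = 0, bands at 0.25, chaos at 1, mesh at 5) on a reduced
#' 300 x 300 um domain with 150 um trichomes, so each completes on a
#' desktop in minutes. The same seed always reproduces the same output.
#'
#' @param name one of `"smoke"`, `"streams"`, `"bands"`, `"chaotic"`,
#'   `"mesh"`.
#' @param seed RNG seed.
#' @param out_dir optional output directory for the trajectory, metrics CSV
#'   and a text summary.
#' @param t_end optional override of the scenario duration (s).
#' @return A list with `sim` (`trichome_sim`) and `metrics`
#'   (`trichome_metrics`).
#' @export
run_demo <- function(name, seed = 1, out_dir = NULL, t_end = NULL) {
  sc <- .demo_scenarios()
  if (!name %in% names(sc))
    stop("run_demo: unknown scenario '", name, "'; available: ",
         paste(names(sc), collapse = ", "))
  s <- sc[[name]]
  params <- do.call(system_params, c(s$params, list(seed = as.integer(seed))))
  sim <- run_simulation(params, t_end = if (is.null(t_end)) s$t_end else t_end,
                        frame_interval = s$frame_interval, seed = seed,
                        out_dir = out_dir)
  met <- compute_metrics(sim, sector = 50,
                         window = min(3600, sim$manifest$t_end))
  if (!is.null(out_dir)) {
    utils::write.csv(met$per_frame, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    summary_txt <- c(
      sprintf("scenario: %s (%s)", name, s$about),
      sprintf("seed: %d, t_end: %g s", seed,
              if (is.null(t_end)) s$t_end else t_end),
      utils::capture.output(print(met)))
    writeLines(summary_txt, file.path(out_dir, "summary.txt"))
  }
  list(sim = sim, metrics = met)
}
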