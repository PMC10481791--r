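# Configuration-driven runs: a run_config fully describes coil, core,
# material, drive and solver options, so a run is reproducible from its
# config alone. Configs serialize to YAML with SI units throughout.

#' Run configuration
#'
#' @param coil coil spec: `list(type = "circular_loop", radius, wire_radius,
#'   n_segments, n_filaments)`, `list(type = "helical_spiral", ...)` (see
#'   [helical_spiral_coil()]), or `list(type = "csv", path)`
#' @param core core spec: `list(shape, dimensions, resolution)` for
#'   [generate_core()], `list(stl, h)` for an imported STL,
#'   `list(node, ele)` for an external tet mesh, or `NULL` for a coreless run
#' @param material material spec: `list(preset = 1|2|3)`,
#'   `list(kind, a1, a2)`, `list(mu_r = ...)` for a linear core, or
#'   `list(loci_csv, kind)` for a datasheet fit
#' @param drive `list(I0 = <A>, dIdt = <A/s>)`
#' @param solver solver options: `alpha`, `beta`, `tol_e1`, `tol_e2`,
#'   `max_iter`, `gmres_tol`
#' @param probes optional observation points: a matrix, data frame, or
#'   `list(csv = path)`
#' @return an object of class `run_config`
#' @export
run_config <- function(coil, core = NULL, material = NULL,
                       drive = list(I0 = 1, dIdt = 0),
                       solver = list(), probes = NULL) {
  cfg <- list(coil = coil, core = core, material = material, drive = drive,
              solver = solver, probes = probes)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[intersect(names(cfg),
                                    c("coil", "core", "material", "drive",
                                      "solver", "probes"))])
}

#' @rdname run_config
#' @param config a `run_config`
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the coil described by a run config
#' @param config a [run_config()]
#' @return a [filament_coil()]
#' @export
config_coil <- function(config) {
  spec <- config$coil
  I0 <- config$drive$I0 %||% 1
  if (is.null(spec$type)) rlang::abort("coil spec needs a `type`", class = "coremag_config_error")
  build_one <- function(spec) {
    switch(spec$type,
      circular_loop = circular_loop_coil(
        radius = spec$radius, wire_radius = spec$wire_radius %||% 0,
        n_segments = spec$n_segments %||% 256L,
        n_filaments = spec$n_filaments %||% 1L, I0 = I0),
      helical_spiral = helical_spiral_coil(
        radius = spec$radius, n_turns = spec$n_turns,
        pitch = unlist(spec$pitch), skew_angle = spec$skew_angle %||% 0,
        bundle_radius = spec$bundle_radius %||% 0,
        n_bundle_filaments = spec$n_bundle_filaments %||% 1L,
        twist_pitch = spec$twist_pitch %||% Inf,
        n_segments_per_turn = spec$n_segments_per_turn %||% 64L,
        phase = spec$phase %||% 0, I0 = I0),
      csv = read_coil_csv(spec$path, I0 = I0),
      helmholtz = helmholtz_pair(radius = spec$radius,
                                 n_segments = spec$n_segments %||% 128L, I0 = I0),
      rlang::abort(sprintf("unknown coil type '%s'", spec$type),
                   class = "coremag_config_error"))
  }
  if (!is.null(config$coil$windings)) {
    coils <- lapply(config$coil$windings, build_one)
    segs <- do.call(rbind, lapply(seq_along(coils), function(i) {
      df <- as_tibble.filament_coil(coils[[i]])
      df$filament <- df$filament + 1000L * i
      df
    }))
    filament_coil(segs, I0 = I0)
  } else build_one(spec)
}

#' Build the core mesh described by a run config
#' @param config a [run_config()]
#' @return a [tet_mesh()] or `NULL` for a coreless run
#' @export
config_core <- function(config) {
  spec <- config$core
  if (is.null(spec)) return(NULL)
  if (!is.null(spec$stl))
    return(tetrahedralize_surface(import_stl(spec$stl, scale = spec$scale %||% 1e-3),
                                  h = spec$h))
  if (!is.null(spec$node)) return(read_tet_mesh(spec$node, spec$ele,
                                                scale = spec$scale %||% 1))
  if (identical(spec$shape, "sphere"))
    return(ball_mesh(spec$dimensions$radius, n = spec$resolution$n %||% 8L))
  generate_core(spec$shape, spec$dimensions, spec$resolution %||% list())
}

#' Build the material described by a run config
#' @param config a [run_config()]
#' @return a [bh_curve()], a number (constant `mu_r`), or `NULL`
#' @export
config_material <- function(config) {
  spec <- config$material
  if (is.null(spec)) return(NULL)
  if (!is.null(spec$mu_r)) return(spec$mu_r)
  if (!is.null(spec$preset)) return(preset_material(spec$preset))
  if (!is.null(spec$loci_csv))
    return(fit_bh_curve(utils::read.csv(spec$loci_csv), kind = spec$kind))
  bh_curve(spec$kind, spec$a1, spec$a2)
}

#' Execute a configured coil + core solve
#'
#' Builds the coil, core and material from the config and dispatches to the
#' free-space, linear-core or nonlinear-core solver. The returned report
#' carries the inductances, mean core permeability and the convergence log;
#' when probe points are configured, the total induced electric field at the
#' drive's `dIdt` is attached (the rate is purely linear and can be changed
#' after the solve via [total_E()]).
#'
#' @param config a [run_config()]
#' @param verbose print nonlinear iteration lines
#' @return a list of class `coremag_report` with elements `solution`,
#'   `summary` (one-row tibble), `log`, and optionally `probe_fields`
#' @export
run_solve <- function(config, verbose = FALSE) {
  coil <- config_coil(config)
  mesh <- config_core(config)
  mat <- config_material(config)
  so <- config$solver %||% list()
  solution <-
    if (is.null(mesh) || is.null(mat)) {
      free_space_solution(coil)
    } else if (is.numeric(mat)) {
      solve_linear_core(mesh, mu_r = mat, coil = coil,
                        tol = so$gmres_tol %||% 1e-8)
    } else {
      solve_nonlinear_core(mesh, mat, coil,
                           alpha = so$alpha %||% 0.7, beta = so$beta %||% 0,
                           tol_e1 = so$tol_e1 %||% 1e-3,
                           tol_e2 = so$tol_e2 %||% 5e-3,
                           max_iter = so$max_iter %||% 30L,
                           gmres_tol = so$gmres_tol %||% 1e-8,
                           verbose = verbose)
    }
  out <- list(solution = solution, summary = glance(solution), log = solution$log)
  pts <- config_probes(config)
  if (!is.null(pts)) {
    dIdt <- config$drive$dIdt %||% 0
    out$probe_fields <- if (inherits(solution, "coremag_solution"))
      total_E(solution, pts, dIdt) else coil_E(coil, pts, dIdt)
  }
  class(out) <- "coremag_report"
  out
}

config_probes <- function(config) {
  p <- config$probes
  if (is.null(p)) return(NULL)
  if (is.list(p) && !is.null(p$csv)) return(as_point_matrix(utils::read.csv(p$csv)))
  as_point_matrix(if (is.list(p) && !is.data.frame(p)) do.call(rbind, p) else p)
}

# coreless runs share the solution interface (no mesh, no charges)
free_space_solution <- function(coil) {
  L_p <- self_inductance(coil, check = FALSE)
  structure(list(coil = coil, mesh = NULL, faces = NULL, rho = numeric(0),
                 mu_r = NULL, H_total = NULL, M = NULL, curve = NULL,
                 L_p = L_p, L_s = 0, I0 = coil$I0,
                 log = tibble::tibble(iteration = 1L, e1 = NA_real_, e2 = NA_real_,
                                      gmres_iterations = 0L, mean_mu_r = NA_real_,
                                      min_mu_r = NA_real_, max_mu_r = NA_real_),
                 converged = TRUE, kind = "free_space"),
            class = "coremag_solution")
}

#' @export
print.coremag_report <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Built-in validation fixtures
#'
#' Ready-made run configurations used throughout the test suite:
#'
#' * `"loop_cylinder"`: a solid cylindrical core (radius 15 mm, height
#'   40 mm) symmetrically located inside a one-turn Litz loop (radius 30 mm,
#'   conductor radius 3 mm). Dimensions are this package's own reference
#'   values for the classic loose coil-core configuration.
#' * `"sphere_uniform"`: a sphere (radius 10 mm) centered in a
#'   Helmholtz-style coil pair (radius 100 mm, separation 100 mm) whose
#'   applied field is uniform across the sphere to well below 1%; used for
#'   closed-form magnetized-sphere validation.
#' * `"rat_coil_like"`: a small-animal TMS coil: two skewed 20-turn helical
#'   spirals (radii 9 mm and 16 mm, the outer rotated by 180 degrees, 15
#'   degree skew, 110 mm total length with a linearly tapered pitch
#'   profile), an optional 6-turn booster winding, and a long square-bar
#'   core (12 x 12 x 120 mm).
#'
#' @param name fixture name
#' @param resolution `"default"` (fast) or `"fine"` (validation scale)
#' @param booster include the 6-turn booster winding (rat coil only)
#' @param dir optional directory; when given, the config (YAML) and coil
#'   CSV are written there
#' @return a [run_config()]
#' @export
make_fixture <- function(name = c("loop_cylinder", "sphere_uniform", "rat_coil_like"),
                         resolution = c("default", "fine"), booster = FALSE,
                         dir = NULL) {
  name <- match.arg(name)
  resolution <- match.arg(resolution)
  fine <- resolution == "fine"
  cfg <- switch(name,
    loop_cylinder = run_config(
      coil = list(type = "circular_loop", radius = 30e-3, wire_radius = 3e-3,
                  n_segments = if (fine) 128L else 64L,
                  n_filaments = if (fine) 19L else 7L),
      core = list(shape = "cylinder",
                  dimensions = list(radius = 15e-3, height = 40e-3),
                  resolution = if (fine) list(nxy = 6L, nz = 6L)
                               else list(nxy = 3L, nz = 3L)),
      material = list(preset = 1L),
      drive = list(I0 = 20e3, dIdt = 1e8)),
    sphere_uniform = run_config(
      coil = list(windings = list(
        list(type = "circular_loop", radius = 0.1, n_segments = 128L),
        list(type = "circular_loop", radius = 0.1, n_segments = 128L)),
        type = "helmholtz"),
      core = list(shape = "sphere", dimensions = list(radius = 10e-3),
                  resolution = list(n = if (fine) 16L else 8L)),
      material = list(mu_r = 3),
      drive = list(I0 = 100, dIdt = 1e6)),
    rat_coil_like = run_config(
      coil = list(windings = c(list(
        list(type = "helical_spiral", radius = 9e-3, n_turns = 20L,
             pitch = rat_pitch_profile(), skew_angle = 15 * pi / 180,
             bundle_radius = 2e-3, n_bundle_filaments = if (fine) 19L else 7L,
             twist_pitch = 30e-3, n_segments_per_turn = if (fine) 64L else 32L),
        list(type = "helical_spiral", radius = 16e-3, n_turns = 20L,
             pitch = rat_pitch_profile(), skew_angle = 15 * pi / 180,
             bundle_radius = 2e-3, n_bundle_filaments = if (fine) 19L else 7L,
             twist_pitch = 30e-3, n_segments_per_turn = if (fine) 64L else 32L,
             phase = pi)),
        if (booster) list(list(
          type = "helical_spiral", radius = 16e-3, n_turns = 6L,
          pitch = rep(110e-3 / 20, 6), skew_angle = 15 * pi / 180,
          bundle_radius = 2e-3, n_bundle_filaments = if (fine) 19L else 7L,
          twist_pitch = 30e-3, n_segments_per_turn = if (fine) 64L else 32L,
          phase = pi / 2)) else NULL),
        type = "assembly"),
      core = list(shape = "cuboid",
                  dimensions = list(lx = 12e-3, ly = 12e-3, lz = 120e-3),
                  resolution = list(n = if (fine) c(6L, 6L, 40L) else c(3L, 3L, 20L))),
      material = list(preset = 2L),
      drive = list(I0 = 100, dIdt = 1e8)))
  if (name == "sphere_uniform")
    cfg$coil <- list(type = "helmholtz", radius = 0.1, n_segments = 128L)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_run_config(cfg, file.path(dir, paste0(name, ".yaml")))
    write_coil_csv(config_coil(cfg), file.path(dir, paste0(name, "_coil.csv")))
  }
  cfg
}

# linearly tapered per-turn pitch profile summing to the 110 mm coil length
rat_pitch_profile <- function(n_turns = 20L, total = 110e-3) {
  taper <- seq(1.3, 0.7, length.out = n_turns)
  total * taper / sum(taper)
}
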