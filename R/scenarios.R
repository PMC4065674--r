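# Packaged free-swelling experiments: quasi-1D validation column, full 3D
# confined sample, degeneration parameter sweeps, and phase segmentation.

#' Free-swelling scenario configuration
#'
#' @param preset `"table1"` (quasi-1D healthy column), `"table2"` (full 3D
#'   healthy sample) or `"custom"`.
#' @param overrides named list of [material_parameters()] overrides (e.g.
#'   `list(c0F = 110)`); values in SI units (mol m^-3 for concentrations).
#' @param mesh mesh resolution: for the quasi-1D column a list with
#'   `n_elems`; otherwise a list with `nx`, `ny`, `nz`. Defaults: 50-element
#'   column / 2 x 2 x 50 block.
#' @param c_star_old,c_star_new bath concentration before / after the step at
#'   `t = 0` (mol m^-3; defaults 150 -> 125, i.e. 0.15 M -> 0.125 M).
#' @param t_final total simulated time (s).
#' @param solver a [solver_config()]; built from `t_final` and
#'   `profile_times` when omitted.
#' @param profile_times times (s) at which nodal snapshots are stored.
#' @param height,diameter sample geometry (m); taken from the preset unless
#'   given.
#' @param bc boundary-condition family; `"quasi1d"` for the table1 preset,
#'   `"confined3d"` otherwise.
#' @return A list of class `free_swelling_config`.
#' @export
free_swelling_config <- function(preset = c("table2", "table1", "custom"),
                                 overrides = list(), mesh = NULL,
                                 c_star_old = 150, c_star_new = 125,
                                 t_final = 3600, solver = NULL,
                                 profile_times = 100,
                                 height = NULL, diameter = NULL, bc = NULL) {
  preset <- match.arg(preset)
  if (c_star_old <= 0 || c_star_new <= 0) {
    stop("invalid parameter: bath concentrations must be positive",
         call. = FALSE)
  }
  if (t_final <= 0) stop("invalid parameter: t_final must be > 0",
                         call. = FALSE)
  base <- switch(preset,
                 table1 = do.call(table1_parameters, overrides),
                 table2 = do.call(table2_parameters, overrides),
                 custom = list(params = do.call(material_parameters,
                                                overrides),
                               height = 0.5e-3, diameter = 1.5e-3))
  if (is.null(height)) height <- base$height
  if (is.null(diameter)) diameter <- base$diameter
  if (is.null(bc)) bc <- if (preset == "table1") "quasi1d" else "confined3d"
  if (is.null(mesh)) {
    mesh <- if (bc == "quasi1d") list(n_elems = 50L)
            else list(nx = 2L, ny = 2L, nz = 50L)
  }
  if (is.null(solver)) {
    solver <- solver_config(t_final = t_final, profile_times = profile_times)
  }
  structure(list(preset = preset, params = base$params, height = height,
                 diameter = diameter, mesh = mesh, bc = bc,
                 c_star_old = c_star_old, c_star_new = c_star_new,
                 solver = solver),
            class = "free_swelling_config")
}

config_mesh <- function(config) {
  if (config$bc == "quasi1d") {
    build_column_mesh(config$mesh$n_elems, config$height, config$diameter)
  } else {
    build_block_mesh(config$mesh$nx, config$mesh$ny, config$mesh$nz,
                     config$diameter, config$height)
  }
}

config_problem <- function(config, mesh = config_mesh(config)) {
  swell_problem(mesh, config$params, config$c_star_old, config$c_star_new,
                bc = config$bc)
}

# Shared scenario core: march, segment phases, compare with the analytic
# confined-swelling oracle.
run_scenario <- function(config, mesh = config_mesh(config)) {
  problem <- config_problem(config, mesh)
  traj <- time_march(problem, config$solver)
  report <- detect_phases(traj)
  orc <- confined_steady_state_oracle(config$params, config$c_star_old,
                                      config$c_star_new, config$height)
  n <- length(traj$times)
  u_fem <- if (n) traj$u_top_mm[n] else NA_real_
  u_orc <- 1e3 * orc$u_top
  summary <- data.frame(
    preset = config$preset, c0F = config$params$c0F,
    Phi0w = config$params$Phi0w, Phi = config$params$Phi,
    c_star_old = config$c_star_old, c_star_new = config$c_star_new,
    peak_u_mm = report$peak_u_mm, t_peak_s = report$t_peak_s,
    t_plateau_s = report$t_plateau_s, final_u_mm = u_fem,
    min_u_mm = report$min_u_mm, t_positive_s = report$t_positive_s,
    theta_f = orc$theta_f, u_top_oracle = u_orc, u_top_fem = u_fem,
    relative_gap = if (u_orc != 0) (u_fem - u_orc) / u_orc else 0,
    converged = traj$converged)
  list(trajectory = traj, report = report, summary = summary,
       problem = problem)
}

#' Quasi-1D free-swelling validation run
#'
#' Healthy-cartilage column (table1 preset, 50 elements in depth by default,
#' in-plane displacements suppressed throughout): bath stepped 0.15 M ->
#' 0.125 M at `t = 0`, 3600 s of simulated swelling. The summary records the
#' peak top displacement and its time, the plateau value, the cation
#' concentration at the bottom and top of the sample at `t = 100` s, and the
#' comparison against the analytic confined-swelling oracle.
#'
#' @param config a [free_swelling_config()]; defaults to the table1 preset.
#' @return A list with `trajectory`, `report` (phase segmentation),
#'   `summary` (one-row data.frame), `profile` (nodal state at the first
#'   profile time) and `problem`.
#' @export
run_validation_1d <- function(config = free_swelling_config("table1")) {
  if (config$bc != "quasi1d") {
    stop("run_validation_1d expects a quasi-1D (column) configuration",
         call. = FALSE)
  }
  out <- run_scenario(config)
  prof <- NULL
  if (length(out$trajectory$snapshots)) {
    snap <- out$trajectory$snapshots[[1]]
    prof <- nodal_point_state(out$problem, snap$x)
    prof$time <- snap$time
    H <- out$problem$mesh$extent["Lz"]
    out$summary$c_plus_bottom <- mean(prof$c_plus[prof$z == 0])
    out$summary$c_plus_top <- mean(prof$c_plus[prof$z == H])
    out$summary$profile_time_s <- snap$time
  }
  out$profile <- prof
  out
}

#' Full 3D free-swelling run
#'
#' Confined 1.5 mm diameter, 0.5 mm high sample (table2 preset by default):
#' lateral walls and bottom impermeable and laterally confining, top surface
#' in contact with the bath, which is stepped 0.15 M -> 0.125 M at `t = 0`.
#'
#' @param config a [free_swelling_config()]; defaults to the table2 preset.
#' @param mesh optional prebuilt mesh (reused across sweep members).
#' @return A list with `trajectory`, `report`, `summary`, `problem`.
#' @export
run_free_swelling_3d <- function(config = free_swelling_config("table2"),
                                 mesh = NULL) {
  if (config$bc != "confined3d") {
    stop("run_free_swelling_3d expects a 3D (block) configuration",
         call. = FALSE)
  }
  if (is.null(mesh)) mesh <- config_mesh(config)
  run_scenario(config, mesh)
}

#' Parameter sweep specification
#'
#' @param param swept parameter: `"c0F"` (mol m^-3), `"Phi0w"` or `"Phi"`.
#' @param values values to sweep; defaults per parameter: fixed charge
#'   density `{200, 135, 110, 60}` mol m^-3 (young healthy, aged healthy and
#'   two degenerated tissues), porosity `{0.70, 0.75, 0.78, 0.85}`, osmotic
#'   coefficient `{0.6, 0.7, 0.8}`.
#' @param base a [free_swelling_config()] providing every other parameter.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(param = c("c0F", "Phi0w", "Phi"), values = NULL,
                       base = free_swelling_config("table2")) {
  param <- match.arg(param)
  if (is.null(values)) {
    values <- switch(param,
                     c0F = c(200, 135, 110, 60),
                     Phi0w = c(0.70, 0.75, 0.78, 0.85),
                     Phi = c(0.6, 0.7, 0.8))
  }
  ok <- switch(param,
               c0F = all(values >= 0),
               Phi0w = all(values > 0 & values < 1),
               Phi = all(values > 0 & values <= 1))
  if (!ok) stop("invalid parameter: sweep values outside physical bounds",
                call. = FALSE)
  structure(list(param = param, values = values, base = base),
            class = "sweep_spec")
}

#' Run a degeneration parameter sweep
#'
#' Reruns the free-swelling scenario for each value of the swept parameter
#' (fixed charge density, initial porosity or osmotic coefficient), reusing
#' one mesh so that members differ only in the parameter. A failing member is
#' reported with a warning and kept as an `NA` row, never silently dropped.
#'
#' @param spec a [sweep_spec()].
#' @return A list with `metrics` (one row per value: peak and plateau
#'   displacement, time-to-peak, shrink-delay metrics, oracle comparison) and
#'   `runs` (the per-value scenario results).
#' @export
sweep_parameter <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  base <- spec$base
  mesh <- config_mesh(base)
  runs <- vector("list", length(spec$values))
  rows <- vector("list", length(spec$values))
  for (i in seq_along(spec$values)) {
    v <- spec$values[i]
    over <- stats::setNames(list(v), spec$param)
    cfg <- free_swelling_config(base$preset, overrides = over,
                                mesh = base$mesh,
                                c_star_old = base$c_star_old,
                                c_star_new = base$c_star_new,
                                solver = base$solver,
                                height = base$height,
                                diameter = base$diameter, bc = base$bc)
    res <- tryCatch(run_scenario(cfg, mesh), error = function(e) e)
    if (inherits(res, "error")) {
      warning("sweep member ", spec$param, " = ", v, " failed: ",
              conditionMessage(res), call. = FALSE)
      rows[[i]] <- data.frame(param = spec$param, value = v,
                              peak_u_mm = NA_real_, t_peak_s = NA_real_,
                              t_plateau_s = NA_real_, final_u_mm = NA_real_,
                              min_u_mm = NA_real_, t_positive_s = NA_real_,
                              u_top_oracle = NA_real_,
                              relative_gap = NA_real_, converged = FALSE)
    } else {
      runs[[i]] <- res
      s <- res$summary
      rows[[i]] <- data.frame(param = spec$param, value = v,
                              peak_u_mm = s$peak_u_mm,
                              t_peak_s = s$t_peak_s,
                              t_plateau_s = s$t_plateau_s,
                              final_u_mm = s$final_u_mm,
                              min_u_mm = s$min_u_mm,
                              t_positive_s = s$t_positive_s,
                              u_top_oracle = s$u_top_oracle,
                              relative_gap = s$relative_gap,
                              converged = s$converged)
    }
  }
  list(metrics = do.call(rbind, rows), runs = runs)
}
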