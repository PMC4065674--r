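# Configuration files, structured outputs and VTK snapshots.

CONFIG_KEYS <- c("preset", "overrides", "mesh", "c_star_old", "c_star_new",
                 "t_final", "solver", "profile_times", "height", "diameter",
                 "bc")
SOLVER_KEYS <- c("dt", "dt_initial", "t_initial_phase", "t_final",
                 "cn_weight", "newton_tol", "newton_max_iter", "jac_refresh",
                 "dt_min", "profile_times", "verbose", "seed")

#' Load a scenario configuration from a preset name or a YAML file
#'
#' A configuration file is a YAML mapping with any subset of the keys
#' `preset`, `overrides` (material-parameter overrides, SI units), `mesh`,
#' `c_star_old`, `c_star_new`, `t_final`, `solver` (keys of
#' [solver_config()]), `profile_times`, `height`, `diameter`, `bc`. Unknown
#' keys and out-of-range values raise a descriptive error naming the key.
#' Loading the echo written by [write_outputs()] reproduces the identical
#' resolved configuration.
#'
#' @param source a preset name (`"table1"`, `"table2"`) or a path to a YAML
#'   file.
#' @return A [free_swelling_config()].
#' @export
load_config <- function(source) {
  if (source %in% c("table1", "table2")) {
    return(free_swelling_config(source))
  }
  if (!file.exists(source)) {
    stop("config error: '", source,
         "' is neither a known preset nor an existing file", call. = FALSE)
  }
  raw <- yaml::read_yaml(source)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown)) {
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$solver)) {
    bad <- setdiff(names(raw$solver), SOLVER_KEYS)
    if (length(bad)) {
      stop("config error: unknown solver key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    raw$solver <- do.call(solver_config, raw$solver)
  }
  args <- raw[!vapply(raw, is.null, logical(1))]
  do.call(free_swelling_config, args)
}

config_as_list <- function(config) {
  list(preset = config$preset,
       overrides = material_overrides(config),
       mesh = config$mesh,
       c_star_old = config$c_star_old, c_star_new = config$c_star_new,
       solver = unclass(config$solver)[SOLVER_KEYS],
       height = config$height, diameter = config$diameter, bc = config$bc)
}

# material parameters that differ from the preset baseline
material_overrides <- function(config) {
  base <- switch(config$preset, table1 = table1_parameters()$params,
                 table2 = table2_parameters()$params,
                 material_parameters())
  keys <- c("E", "nu", "alpha", "D_plus", "D_minus", "c0F", "gamma_plus",
            "gamma_minus", "R", "T", "Phi", "Phi0w", "Bw", "Fc")
  over <- list()
  for (k in keys) {
    if (!identical(config$params[[k]], base[[k]])) {
      over[[k]] <- config$params[[k]]
    }
  }
  over
}

#' Write the structured outputs of a run
#'
#' Emits into `outdir`: `series.csv` (time series with unit-suffixed
#' headers), `summary.csv` (scenario summary including the oracle-comparison
#' columns), `phases.csv` (phase boundaries, peak and shrink-delay metrics),
#' `config.yaml` (the resolved configuration echo), `run.log` (parameter
#' echo and per-step Newton iteration counts), and optionally VTK snapshots
#' of the stored profile states. Content is deterministic for a
#' deterministic run; an aborted run still produces the partial series plus
#' a failure record with the last converged time.
#'
#' @param trajectory a `swell_trajectory`.
#' @param report a `phase_report` (or `NULL`).
#' @param config the [free_swelling_config()] of the run.
#' @param outdir output directory (created if needed; must be writable).
#' @param summary optional scenario summary data.frame (written as given).
#' @param vtk also write VTK snapshots of the stored profiles.
#' @return (invisibly) the vector of files written.
#' @export
write_outputs <- function(trajectory, report, config, outdir,
                          summary = NULL, vtk = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(outdir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("I/O error: output directory '", outdir,
                        "' is not writable", call. = FALSE)
  unlink(probe)

  files <- character()
  series <- data.frame(t_s = trajectory$times,
                       u_top_mm = trajectory$u_top_mm,
                       Jw_top_m3s = trajectory$Jw_top,
                       Jp_top_mols = trajectory$Jp_top,
                       Jm_top_mols = trajectory$Jm_top,
                       newton_iters = trajectory$newton_iters)
  f <- file.path(outdir, "series.csv")
  utils::write.csv(series, f, row.names = FALSE)
  files <- c(files, f)

  if (is.null(summary)) {
    n <- length(trajectory$times)
    summary <- data.frame(final_u_mm = if (n) trajectory$u_top_mm[n]
                          else NA_real_,
                          converged = trajectory$converged,
                          failure_time_s = trajectory$failure_time)
  } else {
    summary$failure_time_s <- trajectory$failure_time
  }
  f <- file.path(outdir, "summary.csv")
  utils::write.csv(summary, f, row.names = FALSE)
  files <- c(files, f)

  if (!is.null(report) && report$n_phases > 1L) {
    ph <- data.frame(boundary = names(report$boundaries_s),
                     t_s = as.numeric(report$boundaries_s))
    extra <- data.frame(boundary = c("peak", "plateau_onset",
                                     "min_displacement",
                                     "positive_swelling"),
                        t_s = c(report$t_peak_s, report$t_plateau_s,
                                report$min_u_mm, report$t_positive_s))
    ph <- rbind(ph, extra)
  } else {
    ph <- data.frame(boundary = "equilibrium", t_s = NA_real_)
  }
  f <- file.path(outdir, "phases.csv")
  utils::write.csv(ph, f, row.names = FALSE)
  files <- c(files, f)

  f <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config_as_list(config), f)
  files <- c(files, f)

  f <- file.path(outdir, "run.log")
  con <- file(f, "w")
  writeLines(c("# resolved configuration",
               yaml::as.yaml(config_as_list(config)),
               "# material parameters",
               utils::capture.output(print(config$params)),
               "# per-step newton iterations",
               paste(trajectory$newton_iters, collapse = " "),
               if (!trajectory$converged)
                 sprintf("# RUN ABORTED: last converged time %.6g s",
                         trajectory$failure_time)), con)
  close(con)
  files <- c(files, f)

  if (vtk && length(trajectory$snapshots)) {
    for (s in trajectory$snapshots) {
      f <- file.path(outdir, sprintf("snapshot_t%07.1fs.vtk", s$time))
      write_snapshot_vtk(trajectory$problem, s$x, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Write a legacy-ASCII VTK unstructured-grid snapshot
#'
#' Point data: displacement vector, modified potentials, ion concentrations,
#' fluid pressure, electrical potential; cell data: element-mean dilatation,
#' porosity and fixed charge density.
#'
#' @param problem a [swell_problem()].
#' @param x packed dof vector.
#' @param file output path.
#' @export
write_snapshot_vtk <- function(problem, x, file) {
  mesh <- problem$mesh
  ns <- nodal_point_state(problem, x)
  st <- gp_level_state(gather_elem(problem, x), problem$ops,
                       problem$params)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(v) paste(formatC(v, format = "g", digits = 9),
                           collapse = " ")
  w("# vtk DataFile Version 3.0")
  w("triphasic free swelling snapshot")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", mesh$n_nodes)
  for (i in seq_len(mesh$n_nodes)) w("%s", num(mesh$nodes[i, ]))
  w("CELLS %d %d", mesh$n_elems, 9L * mesh$n_elems)
  for (e in seq_len(mesh$n_elems)) w("8 %s",
                                     paste(mesh$elems[e, ] - 1L,
                                           collapse = " "))
  w("CELL_TYPES %d", mesh$n_elems)
  writeLines(rep("12", mesh$n_elems), con)
  w("POINT_DATA %d", mesh$n_nodes)
  w("VECTORS u double")
  for (i in seq_len(mesh$n_nodes)) w("%s", num(c(ns$ux[i], ns$uy[i],
                                                 ns$uz[i])))
  scalars <- c("eps_w", "eps_plus", "eps_minus", "c_plus", "c_minus", "P",
               "psi")
  for (s in scalars) {
    w("SCALARS %s double 1", s)
    w("LOOKUP_TABLE default")
    writeLines(formatC(ns[[s]], format = "g", digits = 9), con)
  }
  w("CELL_DATA %d", mesh$n_elems)
  cell <- list(theta = rowMeans(st$theta), Phiw = rowMeans(st$Phiw),
               cF = rowMeans(st$cF))
  for (s in names(cell)) {
    w("SCALARS %s double 1", s)
    w("LOOKUP_TABLE default")
    writeLines(formatC(cell[[s]], format = "g", digits = 9), con)
  }
  invisible(file)
}
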