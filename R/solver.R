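# Crank-Nicolson time stepping with (modified) Newton iteration.

#' Solver configuration
#'
#' @param dt base time step (s).
#' @param dt_initial refined time step used while `t < t_initial_phase`, to
#'   resolve the early boundary-layer transient after the bath step.
#' @param t_initial_phase duration of the refined-step phase (s).
#' @param t_final total simulated time (s).
#' @param cn_weight Crank-Nicolson weight of the new time level (0.5).
#' @param newton_tol convergence tolerance on the scaled Newton increment
#'   (displacements scaled by 1 um, potentials by the initial bath
#'   concentration).
#' @param newton_max_iter Newton iteration cap per attempt.
#' @param jac_refresh refactorize the (numerical) tangent at least every this
#'   many steps; it is also refreshed whenever an attempt stalls.
#' @param dt_min floor for automatic step halving on Newton failure; reaching
#'   it aborts the run with the failing time reported.
#' @param profile_times times (s) at which full nodal snapshots are kept.
#' @param verbose log per-step Newton iteration counts via `message()`.
#' @param seed unused placeholder; the solver is deterministic.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(dt = 5, dt_initial = 0.5, t_initial_phase = 50,
                          t_final = 3600, cn_weight = 0.5,
                          newton_tol = 1e-6, newton_max_iter = 12,
                          jac_refresh = 25, dt_min = 1e-3,
                          profile_times = numeric(), verbose = FALSE,
                          seed = NULL) {
  stopifnot(dt > 0, dt_initial > 0, t_final > 0,
            cn_weight >= 0, cn_weight <= 1, newton_tol > 0,
            newton_max_iter >= 1, dt_min > 0)
  structure(list(dt = dt, dt_initial = dt_initial,
                 t_initial_phase = t_initial_phase, t_final = t_final,
                 cn_weight = cn_weight, newton_tol = newton_tol,
                 newton_max_iter = newton_max_iter,
                 jac_refresh = jac_refresh, dt_min = dt_min,
                 profile_times = sort(unique(as.numeric(
                   unlist(profile_times)))),
                 verbose = verbose, seed = seed),
            class = "solver_config")
}

# Factor the tangent with row/column equilibration: columns are scaled by
# the per-dof characteristic magnitudes, rows to unit Euclidean norm. The
# equation blocks (momentum vs. flux vs. mass) differ by many orders of
# magnitude in natural units; equilibration keeps the sparse LU well
# conditioned without nondimensionalizing the unknowns themselves.
factor_tangent <- function(J, dof_scale) {
  Jc <- J %*% Matrix::Diagonal(x = dof_scale)
  rn <- sqrt(Matrix::rowSums(Jc^2))
  rn[rn == 0] <- 1
  Dr <- 1 / rn
  list(fac = Matrix::lu(Matrix::Diagonal(x = Dr) %*% Jc),
       Dr = Dr, Dc = dof_scale)
}

solve_tangent <- function(ft, r) {
  ft$Dc * as.numeric(Matrix::solve(ft$fac, ft$Dr * r))
}

# One Newton solve of a step. Returns list(x, iters, converged, refreshed).
newton_solve <- function(problem, x_guess, sto, dt, cfg, fac_env) {
  x <- x_guess
  x[problem$dir_dofs] <- problem$dir_vals
  refreshed <- FALSE
  for (it in seq_len(cfg$newton_max_iter)) {
    r <- assemble_residual_full(problem, x, sto, dt, cfg$cn_weight)
    if (!all(is.finite(r))) {
      return(list(x = x, iters = it, converged = FALSE,
                  refreshed = refreshed))
    }
    r[problem$dir_dofs] <- x[problem$dir_dofs] - problem$dir_vals
    if (is.null(fac_env$fac) ||
        (!refreshed && it > ceiling(cfg$newton_max_iter / 2))) {
      J <- assemble_jacobian_core(problem, x, sto, dt, cfg$cn_weight)
      fac_env$fac <- factor_tangent(J, problem$dof_scale)
      refreshed <- TRUE
    }
    delta <- solve_tangent(fac_env$fac, r)
    if (!all(is.finite(delta))) {
      return(list(x = x, iters = it, converged = FALSE,
                  refreshed = refreshed))
    }
    x <- x - delta
    err <- max(abs(delta) / problem$dof_scale)
    if (err < cfg$newton_tol) {
      return(list(x = x, iters = it, converged = TRUE,
                  refreshed = refreshed))
    }
  }
  list(x = x, iters = cfg$newton_max_iter, converged = FALSE,
       refreshed = refreshed)
}

top_uz_mm <- function(problem, x) {
  1e3 * mean(x[dof_indices(problem$mesh, "uz",
                           problem$mesh$node_sets$top)])
}

# Consistent (variational) boundary fluxes through the top surface from the
# unconstrained residual: for a prescribed-potential node the full weak-form
# row equals minus the boundary integral of the outward normal flux weighted
# by that node's shape function; summed over the top nodes this gives the
# total flux, positive into the sample.
consistent_top_fluxes <- function(problem, r_full) {
  top <- problem$mesh$node_sets$top
  list(Jw = sum(r_full[dof_indices(problem$mesh, "eps_w", top)]),
       Jp = sum(r_full[dof_indices(problem$mesh, "eps_plus", top)]),
       Jm = sum(r_full[dof_indices(problem$mesh, "eps_minus", top)]))
}

# Volume integrals used by the conservation bookkeeping.
content_integrals <- function(problem, x) {
  st <- gp_level_state(gather_elem(problem, x), problem$ops, problem$params)
  w <- problem$ops$detJ
  list(theta = w * sum(st$theta),
       mass_p = w * sum(st$Mp),
       mass_m = w * sum(st$Mm))
}

#' March the coupled system through time
#'
#' Crank-Nicolson time integration of the free-swelling problem with Newton
#' iteration per step (lazily refreshed numerical tangent, automatic step
#' halving on failure). The bath switches to its new concentration at
#' `t = 0` exactly: the prescribed top-surface potentials jump with no ramp.
#'
#' @param problem a [swell_problem()].
#' @param config a [solver_config()].
#' @return An object of class `swell_trajectory` with the time series
#'   (`times`, `u_top_mm`, step-averaged consistent top-surface fluxes
#'   `Jw_top` (m^3/s), `Jp_top`, `Jm_top` (mol/s), all positive into the
#'   sample), conservation bookkeeping (`int_theta`, `int_mass_p`,
#'   `int_mass_m`, cumulative influxes), nodal `snapshots` at the requested
#'   profile times, the final state `x_final`, per-step Newton iteration
#'   counts, and `converged` / `failure_time`.
#' @export
time_march <- function(problem, config) {
  cfg <- config
  x_old <- problem$init$x
  n_guess <- ceiling(cfg$t_initial_phase / cfg$dt_initial) +
    ceiling((cfg$t_final - cfg$t_initial_phase) / cfg$dt) + 16L
  times <- u_top <- jw <- jp <- jm <- numeric(n_guess)
  qth <- qp <- qm <- cw <- cp <- cm <- numeric(n_guess)
  iters <- integer(n_guess)
  snapshots <- list()
  profile_left <- cfg$profile_times

  fac_env <- new.env(parent = emptyenv())
  t <- 0; k <- 0L
  steps_since_refresh <- 0L
  cum_w <- cum_p <- cum_m <- 0
  converged <- TRUE; failure_time <- NA_real_

  while (t < cfg$t_final - 1e-9) {
    dt <- if (t < cfg$t_initial_phase - 1e-9) cfg$dt_initial else cfg$dt
    dt <- min(dt, cfg$t_final - t)
    if (length(profile_left) && profile_left[1] > t + 1e-9) {
      dt <- min(dt, profile_left[1] - t)
    }
    sto <- gp_level_state(gather_elem(problem, x_old), problem$ops,
                          problem$params)
    repeat {
      if (steps_since_refresh >= cfg$jac_refresh) fac_env$fac <- NULL
      res <- newton_solve(problem, x_old, sto, dt, cfg, fac_env)
      if (res$converged) break
      fac_env$fac <- NULL
      res2 <- newton_solve(problem, x_old, sto, dt, cfg, fac_env)
      if (res2$converged) { res <- res2; break }
      dt <- dt / 2
      if (dt < cfg$dt_min) {
        warning("Newton failed to converge at t = ", signif(t, 6),
                " s despite step halving; aborting run", call. = FALSE)
        converged <- FALSE; failure_time <- t
        break
      }
    }
    if (!converged) break
    if (res$refreshed) steps_since_refresh <- 0L
    steps_since_refresh <- steps_since_refresh + 1L

    x_new <- res$x
    t <- t + dt
    k <- k + 1L
    r_full <- assemble_residual_full(problem, x_new, sto, dt, cfg$cn_weight)
    fl <- consistent_top_fluxes(problem, r_full)
    ci <- content_integrals(problem, x_new)
    cum_w <- cum_w + dt * fl$Jw
    cum_p <- cum_p + dt * fl$Jp
    cum_m <- cum_m + dt * fl$Jm
    times[k] <- t; u_top[k] <- top_uz_mm(problem, x_new)
    jw[k] <- fl$Jw; jp[k] <- fl$Jp; jm[k] <- fl$Jm
    qth[k] <- ci$theta; qp[k] <- ci$mass_p; qm[k] <- ci$mass_m
    cw[k] <- cum_w; cp[k] <- cum_p; cm[k] <- cum_m
    iters[k] <- res$iters
    if (cfg$verbose) {
      message(sprintf("t = %8.2f s  dt = %6.3f  newton %2d  u_top = %.6g mm",
                      t, dt, res$iters, u_top[k]))
    }
    if (length(profile_left) && t >= profile_left[1] - 1e-9) {
      snapshots[[length(snapshots) + 1L]] <- list(time = t, x = x_new)
      profile_left <- profile_left[-1]
    }
    x_old <- x_new
  }

  idx <- seq_len(k)
  structure(list(times = times[idx], u_top_mm = u_top[idx],
                 Jw_top = jw[idx], Jp_top = jp[idx], Jm_top = jm[idx],
                 int_theta = qth[idx], int_mass_p = qp[idx],
                 int_mass_m = qm[idx],
                 cum_influx_w = cw[idx], cum_influx_p = cp[idx],
                 cum_influx_m = cm[idx],
                 newton_iters = iters[idx], snapshots = snapshots,
                 x_final = x_old, x0 = problem$init$x,
                 converged = converged, failure_time = failure_time,
                 problem = problem, config = cfg),
            class = "swell_trajectory")
}

#' @export
print.swell_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Free-swelling trajectory: %d steps to t = %.6g s%s\n", n,
              if (n) x$times[n] else 0,
              if (x$converged) "" else
                sprintf("  [ABORTED at t = %.6g s]", x$failure_time)))
  if (n) {
    cat(sprintf("  peak u_top = %.6g mm at t = %.6g s; final u_top = %.6g mm\n",
                max(x$u_top_mm), x$times[which.max(x$u_top_mm)],
                x$u_top_mm[n]))
  }
  invisible(x)
}

#' Boundary fluxes through a tagged surface
#'
#' Surface-integrated normal fluxes of water, cations and anions (sign
#' convention: positive into the sample). The lateral and bottom surfaces are
#' impermeable by construction (the no-flux condition is imposed), so their
#' fluxes are exactly zero. For the top surface two evaluations are offered:
#' `"consistent"` recovers the variational boundary flux from the
#' unconstrained residual rows of the prescribed-potential nodes (this is the
#' flux against which the discrete water and ion balances hold to solver
#' tolerance), `"quadrature"` integrates the pointwise flux laws over the
#' face Gauss points.
#'
#' @param problem a [swell_problem()].
#' @param x_new,x_old converged states delimiting a step.
#' @param dt the step length (s).
#' @param surface_tag `"top"`, `"lateral"` or `"bottom"`.
#' @param method `"consistent"` or `"quadrature"`.
#' @param cn_weight Crank-Nicolson weight used for the step.
#' @return list with `Jw` (m^3/s), `Jp`, `Jm` (mol/s).
#' @export
boundary_flux <- function(problem, x_new, x_old, dt,
                          surface_tag = c("top", "lateral", "bottom"),
                          method = c("consistent", "quadrature"),
                          cn_weight = 0.5) {
  surface_tag <- match.arg(surface_tag)
  method <- match.arg(method)
  if (surface_tag %in% c("lateral", "bottom")) {
    return(list(Jw = 0, Jp = 0, Jm = 0))
  }
  sto <- gp_level_state(gather_elem(problem, x_old), problem$ops,
                        problem$params)
  if (method == "consistent") {
    r_full <- assemble_residual_full(problem, x_new, sto, dt, cn_weight)
    return(consistent_top_fluxes(problem, r_full))
  }
  tops <- problem$top_ops
  sub <- tops$elems
  Xn <- gather_elem(problem, x_new)[sub, , drop = FALSE]
  Xo <- gather_elem(problem, x_old)[sub, , drop = FALSE]
  ops_f <- list(tN = tops$tN, tGx = tops$tGx, tGy = tops$tGy,
                tGz = tops$tGz)
  stn <- gp_level_state(Xn, ops_f, problem$params)
  stof <- gp_level_state(Xo, ops_f, problem$params)
  cn <- cn_weight; cno <- 1 - cn
  vsz <- (stn$vuz - stof$vuz) / dt
  Tw <- cn * stn$Jwz + cno * stof$Jwz
  Tp <- cn * stn$Jpz + cno * stof$Jpz
  Tm <- cn * stn$Jmz + cno * stof$Jmz
  if (problem$include_convective) {
    Tp <- Tp + (cn * stn$Mp + cno * stof$Mp) * vsz
    Tm <- Tm + (cn * stn$Mm + cno * stof$Mm) * vsz
  }
  aw <- tops$area_w
  list(Jw = -aw * sum(Tw), Jp = -aw * sum(Tp), Jm = -aw * sum(Tm))
}

#' Pointwise state recovered at the mesh nodes
#'
#' Nodal dilatation is evaluated per element at its corners and averaged over
#' the elements sharing each node; porosity, fixed charge density, ion
#' concentrations, fluid pressure and the (diagnostic) electrical potential
#' follow from the nodal potentials through the constitutive laws.
#'
#' @param problem a [swell_problem()].
#' @param x packed dof vector.
#' @return A data.frame with one row per node: coordinates, displacements,
#'   potentials, `theta`, `Phiw`, `cF`, `c_plus`, `c_minus` (mol m^-3),
#'   `P` (Pa), `psi` (V).
#' @export
nodal_point_state <- function(problem, x) {
  mesh <- problem$mesh; par <- problem$params
  if (is.null(problem$corner_ops)) {
    so <- element_shape_ops(mesh, HEX_LOCAL)
    problem$corner_ops <- list(tGx = t(so$Gx), tGy = t(so$Gy),
                               tGz = t(so$Gz))
  }
  co <- problem$corner_ops
  X <- gather_elem(problem, x)
  theta_c <- X[, 1:8, drop = FALSE] %*% co$tGx +
    X[, 9:16, drop = FALSE] %*% co$tGy +
    X[, 17:24, drop = FALSE] %*% co$tGz
  theta <- as.numeric(tapply(as.numeric(theta_c), as.integer(mesh$elems),
                             mean))
  n <- mesh$n_nodes
  ux <- x[dof_indices(mesh, "ux")]; uy <- x[dof_indices(mesh, "uy")]
  uz <- x[dof_indices(mesh, "uz")]
  ew <- x[dof_indices(mesh, "eps_w")]
  ep <- x[dof_indices(mesh, "eps_plus")]
  em <- x[dof_indices(mesh, "eps_minus")]
  cF <- update_fcd(theta, par$c0F, par$Phi0w)
  Phiw <- update_porosity(theta, par$phi0s)
  ions <- ion_concentrations(ep, em, cF, par$gamma_plus, par$gamma_minus)
  P <- fluid_pressure(ew, ions$c_plus, ions$c_minus, theta, par)
  psi <- recover_electric_potential(ep, ions$c_plus, par$gamma_plus, par)
  data.frame(node = seq_len(n), x = mesh$nodes[, 1], y = mesh$nodes[, 2],
             z = mesh$nodes[, 3], ux = ux, uy = uy, uz = uz,
             eps_w = ew, eps_plus = ep, eps_minus = em,
             theta = theta, Phiw = Phiw, cF = cF,
             c_plus = ions$c_plus, c_minus = ions$c_minus,
             P = P, psi = psi)
}
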