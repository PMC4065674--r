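# Time marching: null test, determinism, discrete conservation, flux
# recovery, in-plane uniformity and the failure path.

test_that("unchanged bath yields a flat zero trajectory", {
  pr <- tiny_column(4, c_new = 150)
  tr <- time_march(pr, fast_solver(t_final = 20))
  expect_true(tr$converged)
  expect_lt(max(abs(tr$u_top_mm)), 1e-9)       # mm
  expect_lt(max(abs(tr$Jw_top)), 1e-15)
  expect_lt(max(abs(tr$Jp_top)), 1e-15)
  rep <- detect_phases(tr)
  expect_equal(rep$n_phases, 1L)
})

test_that("repeated runs are bit-identical", {
  pr <- tiny_column(4)
  cfg <- fast_solver(t_final = 20)
  t1 <- time_march(pr, cfg)
  t2 <- time_march(pr, cfg)
  expect_identical(t1$u_top_mm, t2$u_top_mm)
  expect_identical(t1$Jw_top, t2$Jw_top)
  expect_identical(t1$x_final, t2$x_final)
})

test_that("discrete water and ion balances close against the top fluxes", {
  pr <- tiny_column(8)
  tr <- time_march(pr, fast_solver(t_final = 100, dt = 4))
  n <- length(tr$times)
  # water: d(int theta dV) = time-integrated top water influx
  expect_lt(abs(tr$int_theta[n] - tr$cum_influx_w[n]) /
              abs(tr$cum_influx_w[n]), 0.01)
  # ions: d(int Phiw c dV) = time-integrated total (diffusive + convective)
  # top influx; initial contents from the uniform Donnan state
  V <- prod(pr$mesh$extent)
  st0 <- pr$init
  m0 <- pr$params$Phi0w * V * c(st0$c_plus, st0$c_minus)
  dp <- tr$int_mass_p[n] - m0[1]
  dm <- tr$int_mass_m[n] - m0[2]
  expect_lt(abs(dp - tr$cum_influx_p[n]) / max(abs(dp), 1e-30), 0.01)
  expect_lt(abs(dm - tr$cum_influx_m[n]) / max(abs(dm), 1e-30), 0.01)
})

test_that("quadrature and consistent boundary fluxes agree", {
  pr <- tiny_column(8)
  cfg <- fast_solver(t_final = 60, dt = 2, profile_times = c(30, 32))
  tr <- time_march(pr, cfg)
  s <- tr$snapshots
  expect_length(s, 2L)
  dt <- s[[2]]$time - s[[1]]$time
  fc <- boundary_flux(pr, s[[2]]$x, s[[1]]$x, dt, "top", "consistent")
  fq <- boundary_flux(pr, s[[2]]$x, s[[1]]$x, dt, "top", "quadrature")
  expect_equal(fq$Jw, fc$Jw, tolerance = 0.05)
  expect_equal(fq$Jp, fc$Jp, tolerance = 0.05)
  expect_equal(fq$Jm, fc$Jm, tolerance = 0.05)
  # impermeable surfaces: imposed zero
  expect_equal(boundary_flux(pr, s[[2]]$x, s[[1]]$x, dt, "lateral"),
               list(Jw = 0, Jp = 0, Jm = 0))
  expect_equal(boundary_flux(pr, s[[2]]$x, s[[1]]$x, dt, "bottom"),
               list(Jw = 0, Jp = 0, Jm = 0))
})

test_that("confined 3D fields stay uniform in-plane", {
  mesh <- build_block_mesh(2, 2, 6, 1.5e-3, 0.5e-3)
  pr <- swell_problem(mesh, par_t2(), 150, 125)
  tr <- time_march(pr, fast_solver(t_final = 30, dt = 2))
  ns <- nodal_point_state(pr, tr$x_final)
  spread <- function(v, ref) {
    max(vapply(split(v, ns$z), function(z) diff(range(z)), numeric(1))) / ref
  }
  expect_lt(spread(ns$uz, max(abs(ns$uz))), 1e-10)
  expect_lt(spread(ns$eps_plus, max(ns$eps_plus)), 1e-10)
  expect_lt(spread(ns$c_plus, max(ns$c_plus)), 1e-10)
})

test_that("in-plane refinement does not change the top displacement", {
  cfg1 <- free_swelling_config("table2", mesh = list(nx = 1, ny = 1, nz = 6),
                               t_final = 30, profile_times = numeric(),
                               solver = fast_solver(t_final = 30, dt = 2))
  cfg2 <- free_swelling_config("table2", mesh = list(nx = 3, ny = 2, nz = 6),
                               t_final = 30, profile_times = numeric(),
                               solver = fast_solver(t_final = 30, dt = 2))
  o1 <- run_free_swelling_3d(cfg1)
  o2 <- run_free_swelling_3d(cfg2)
  expect_equal(o2$trajectory$u_top_mm, o1$trajectory$u_top_mm,
               tolerance = 1e-3)
})

test_that("a hopeless step aborts with the failing time recorded", {
  cfg <- free_swelling_config(
    "table1", mesh = list(n_elems = 4),
    solver = solver_config(dt = 3600, dt_initial = 3600,
                           t_initial_phase = 0, t_final = 3600,
                           newton_tol = 1e-14, newton_max_iter = 1,
                           dt_min = 3000))
  expect_warning(out <- run_validation_1d(cfg), "aborting")
  expect_false(out$trajectory$converged)
  expect_equal(out$trajectory$failure_time, 0)
})
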