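# Shared small fixtures. Everything is built in code; runs are deterministic.

par_t1 <- function(...) table1_parameters(...)$params
par_t2 <- function(...) table2_parameters(...)$params

# tiny quasi-1D column problem (n elements) with an optional bath step
tiny_column <- function(n = 4, params = par_t1(), c_old = 150, c_new = 125) {
  mesh <- build_column_mesh(n, 0.5e-3, 0.0005e-3)
  swell_problem(mesh, params, c_old, c_new, bc = "quasi1d")
}

# a random admissible state near the initial equilibrium (bounded
# perturbations keep ion potentials positive)
perturbed_state <- function(problem, scale_u = 1e-7, scale_eps = 2,
                            seed = 42) {
  set.seed(seed)
  x <- problem$init$x
  n <- problem$mesh$n_nodes
  pert <- stats::rnorm(length(x)) *
    rep(c(scale_u, scale_u, scale_u, scale_eps, scale_eps, scale_eps), n)
  x <- x + pert
  x[problem$dir_dofs] <- problem$dir_vals
  x
}

# short solver settings for fast transient tests
fast_solver <- function(t_final = 50, dt = 2, ...) {
  solver_config(dt = dt, dt_initial = 0.5, t_initial_phase = 10,
                t_final = t_final, ...)
}
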