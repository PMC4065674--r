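# Donnan equilibrium with the bath and the analytic confined-swelling oracle.

test_that("bath potentials follow the gauge conventions", {
  par <- par_t1()
  b <- bath_potentials(150, par)
  expect_equal(b$eps_w_star, -300)
  expect_equal(b$eps_plus_star, 150)
  expect_equal(b$eps_minus_star, 150)
  b2 <- bath_potentials(125, par)
  expect_equal(b2$eps_w_star, -250)
  expect_equal(b2$eps_plus_star, 125)
  # non-ideal coefficients scale the potentials
  p2 <- par_t2()
  b3 <- bath_potentials(150, p2)
  expect_equal(b3$eps_w_star, -2 * 0.8 * 150)
  expect_equal(b3$eps_plus_star, 0.86 * 150)
  expect_equal(b3$eps_minus_star, 0.85 * 150)
  expect_error(bath_potentials(0, par), "invalid parameter")
})

test_that("Donnan partition solves the product/electroneutrality pair", {
  par <- par_t1()
  d <- donnan_concentrations(150, 200, par)
  expect_equal(d$c_plus, (200 + sqrt(200^2 + 4 * 150^2)) / 2,
               tolerance = 1e-14)
  expect_equal(d$c_plus, 280.2776, tolerance = 1e-6)
  expect_equal(donnan_concentrations(150, 0, par),
               list(c_plus = 150, c_minus = 150))
  d2 <- donnan_concentrations(125, 200, par)
  expect_equal(d2$c_plus, (200 + sqrt(4e4 + 4 * 125^2)) / 2)
  # Donnan product c+ c- = c*^2 (equal activity coefficients), any cF
  for (cF in c(0, 60, 135, 200)) {
    d3 <- donnan_concentrations(137, cF, par_t2())
    expect_equal(d3$c_plus * d3$c_minus, 137^2, tolerance = 1e-10)
  }
})

test_that("initial tissue state is the zero-displacement bath equilibrium", {
  par <- par_t1()
  mesh <- build_column_mesh(4, 0.5e-3, 0.0005e-3)
  st <- initial_tissue_state(150, par, mesh)
  expect_equal(unname(st$x[dof_indices(mesh, "ux")]),
               rep(0, mesh$n_nodes))
  expect_equal(unname(st$x[dof_indices(mesh, "eps_plus")]),
               rep(150, mesh$n_nodes))
  expect_equal(st$c_plus, 280.2776, tolerance = 1e-6)
  expect_equal(st$P_ref,
               par$R * par$T * (sqrt(200^2 + 9e4) - 300), tolerance = 1e-12)
  # uncharged tissue: no Donnan pressure
  st0 <- initial_tissue_state(150, material_parameters(c0F = 0), mesh)
  expect_equal(st0$P_ref, 0)
})

test_that("confined steady-state oracle solves the swelling balance", {
  par <- par_t1()
  orc <- confined_steady_state_oracle(par, 150, 125, 0.5e-3)
  # frozen value from the bracketed root solve (u_top ~ 0.0134 mm)
  expect_equal(1e3 * orc$u_top, 0.0134179, tolerance = 1e-5)
  # the root satisfies the balance equation
  RT <- par$R * par$T
  cF <- update_fcd(orc$theta_f, par$c0F, par$Phi0w)
  lhs <- (par$lambda_s + 2 * par$mu_s) * orc$theta_f
  rhs <- RT * par$Phi * (sqrt(cF^2 + 4 * 125^2) - 250) -
    RT * par$Phi * (sqrt(200^2 + 4 * 150^2) - 300)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # trivial limits
  expect_equal(confined_steady_state_oracle(par, 150, 150),
               list(theta_f = 0, u_top = 0))
  expect_equal(confined_steady_state_oracle(material_parameters(c0F = 0),
                                            150, 125),
               list(theta_f = 0, u_top = 0))
  # swelling monotone in the bath drop and in Phi
  u1 <- confined_steady_state_oracle(par, 150, 140)$u_top
  u2 <- confined_steady_state_oracle(par, 150, 125)$u_top
  expect_gt(u2, u1)
  uA <- confined_steady_state_oracle(par_t2(Phi = 0.6), 150, 125)$u_top
  uB <- confined_steady_state_oracle(par_t2(Phi = 0.8), 150, 125)$u_top
  expect_gt(uB, uA)
})
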