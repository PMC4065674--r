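# Pointwise material laws: closed-form values, independent root-finding
# oracles, and the algebraic invariants they must satisfy.

test_that("Lame constants match the isotropic-elasticity formulas", {
  l <- lame_from_elastic_moduli(3.85e5, 0.28)
  expect_equal(l$lambda_s, 3.85e5 * 0.28 / (1.28 * 0.44))
  expect_equal(l$mu_s, 3.85e5 / 2.56)
  # zero-Poisson limit and round-trip through (E, nu)
  l0 <- lame_from_elastic_moduli(2e5, 0)
  expect_equal(l0$lambda_s, 0)
  expect_equal(l0$mu_s, 1e5)
  mu <- 1.5e5; nu <- 0.3
  lr <- lame_from_elastic_moduli(2 * mu * (1 + nu), nu)
  expect_equal(lr$mu_s, mu)
  expect_equal(lr$lambda_s, 2 * mu * nu / (1 - 2 * nu))
  expect_error(lame_from_elastic_moduli(1e5, 0.5), "invalid parameter")
  expect_error(material_parameters(nu = 0.6), "invalid parameter")
})

test_that("porosity and fixed charge density follow the dilatation", {
  expect_equal(update_porosity(0, 0.25), 0.75)
  expect_equal(update_porosity(0.1, 0.25), 1 - 0.25 / 1.1)
  expect_lt(1 - update_porosity(1e6, 0.25), 1e-5)  # full-fluid limit
  expect_error(update_porosity(-1.5, 0.25), "degenerate")

  expect_equal(update_fcd(0, 200, 0.75), 200)
  expect_equal(update_fcd(0.75, 200, 0.75), 100)
  expect_equal(update_fcd(-0.075, 200, 0.75), 200 / 0.9)
  expect_error(update_fcd(-0.8, 200, 0.75), "degenerate")

  # monotonicity: cF strictly decreasing, Phiw strictly increasing in theta
  th <- seq(-0.4, 2, length.out = 81)
  expect_true(all(diff(update_fcd(th, 200, 0.75)) < 0))
  expect_true(all(diff(update_porosity(th, 0.25)) > 0))
})

test_that("ion concentrations are the nonnegative electroneutral root", {
  expect_equal(ion_concentrations(150, 150, 0, 1, 1),
               list(c_plus = 150, c_minus = 150))
  # independent quadratic-root oracle: c+^2 - cF c+ - q = 0
  cases <- expand.grid(eps = c(50, 129, 150), cF = c(0, 60, 200, 500),
                       g = c(1, 0.86))
  for (i in seq_len(nrow(cases))) {
    eps <- cases$eps[i]; cF <- cases$cF[i]; g <- cases$g[i]
    q <- eps * eps / (g * g)
    roots <- Re(polyroot(c(-q, -cF, 1)))
    cp_oracle <- max(roots)
    got <- ion_concentrations(eps, eps, cF, g, g)
    expect_equal(got$c_plus, cp_oracle, tolerance = 1e-12)
    expect_gte(got$c_minus, 0)
    # electroneutrality to machine precision
    expect_equal(got$c_plus - got$c_minus, cF, tolerance = 1e-14)
  }
  expect_error(ion_concentrations(-1, 150, 0, 1, 1), "invalid state")
})

test_that("potential inversion round-trips through the definitions", {
  par <- par_t2()
  RT <- par$R * par$T
  set.seed(7)
  for (k in 1:20) {
    cF <- runif(1, 0, 400)
    psi <- runif(1, -0.05, 0.02)
    c_minus <- runif(1, 20, 300)
    c_plus <- c_minus + cF
    ep <- par$gamma_plus * c_plus * exp(par$Fc * psi / RT)
    em <- par$gamma_minus * c_minus * exp(-par$Fc * psi / RT)
    got <- ion_concentrations(ep, em, cF, par$gamma_plus, par$gamma_minus)
    expect_equal(got$c_plus, c_plus, tolerance = 1e-12)
    expect_equal(got$c_minus, c_minus, tolerance = 1e-12)
    expect_equal(recover_electric_potential(ep, got$c_plus,
                                            par$gamma_plus, par),
                 psi, tolerance = 1e-12)
  }
})

test_that("fluid pressure is gauged to the bath and reproduces Donnan", {
  par <- par_t1()
  # bath reference state: exactly zero
  cs <- 150
  expect_equal(fluid_pressure(-2 * par$Phi * cs, cs, cs, 0, par), 0)
  # interior Donnan state at c* = 150: P = RT (sqrt(cF^2+4c*^2) - 2c*)
  ions <- donnan_concentrations(cs, par$c0F, par)
  P <- fluid_pressure(-2 * par$Phi * cs, ions$c_plus, ions$c_minus, 0, par)
  expect_equal(P, par$R * par$T * (sqrt(200^2 + 4 * 150^2) - 300),
               tolerance = 1e-12)
  expect_equal(P, 1.501e5, tolerance = 2e-3)
  # Bw lowers P in proportion to theta
  parB <- material_parameters(Bw = 5e4)
  expect_equal(fluid_pressure(0, 100, 100, 0.1, parB),
               fluid_pressure(0, 100, 100, 0.1, par) - 5e4 * 0.1)
})

test_that("total stress follows the incremental elastic law", {
  par <- par_t1()
  expect_equal(total_stress(0, matrix(0, 3, 3), 0, par), matrix(0, 3, 3))
  # confined compression: sigma_zz = (lambda + 2 mu) theta when P = 0
  th <- 0.02
  eps <- diag(c(0, 0, th))
  s <- total_stress(th, eps, 0, par)
  expect_equal(s[3, 3], (par$lambda_s + 2 * par$mu_s) * th)
  expect_equal(s[1, 2], 0)
  # traction-free swelling balance: P = (lambda + 2 mu) theta -> sigma_zz = 0
  s0 <- total_stress(th, eps, (par$lambda_s + 2 * par$mu_s) * th, par)
  expect_equal(s0[3, 3], 0)
  expect_equal(s0, t(s0))
  expect_error(total_stress(0, matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3), 0,
                            par), "symmetric")
})

test_that("electric potential diagnostic has the Donnan sign", {
  par <- par_t1()
  expect_equal(recover_electric_potential(150, 150, 1, par), 0)
  # interior of a negatively charged matrix: c+ above bath level -> psi < 0
  ions <- donnan_concentrations(150, 200, par)
  psi <- recover_electric_potential(150, ions$c_plus, 1, par)
  expect_lt(psi, 0)
  expect_error(recover_electric_potential(-1, 150, 1, par), "invalid state")
})

test_that("permeability is porosity over drag", {
  expect_equal(permeability(0.75, 7e14), 0.75 / 7e14)
})
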