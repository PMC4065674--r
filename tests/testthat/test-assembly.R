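# Assembly of the coupled weak form: equilibrium null test, an element-level
# elastic oracle, tangent/residual consistency and structural properties.

test_that("initial equilibrium with an unchanged bath has zero residual", {
  pr <- tiny_column(4, c_new = 150)
  x0 <- pr$init$x
  r <- assemble_residual(pr, x0, x0, dt = 1)
  expect_lt(max(abs(r)), 1e-18)
})

test_that("uniform uniaxial strain reproduces the confined elastic force", {
  # uncharged matrix + unchanged bath isolates the elastic operator
  par <- material_parameters(c0F = 0)
  mesh <- build_column_mesh(2, 0.5e-3, 0.0005e-3)
  pr <- swell_problem(mesh, par, 150, 150, bc = "quasi1d")
  a <- 0.01
  x <- pr$init$x
  x[dof_indices(mesh, "uz")] <- a * mesh$nodes[, 3]
  r <- assemble_residual(pr, x, x, dt = 1)  # x_old = x_new: no fluxes
  uzdof <- dof_indices(mesh, "uz")
  interior <- setdiff(uzdof, c(pr$dir_dofs,
                               dof_indices(mesh, "uz",
                                           mesh$node_sets$top)))
  A <- unname(mesh$extent["Lx"] * mesh$extent["Ly"])
  Fz <- (par$lambda_s + 2 * par$mu_s) * a * A
  # interior nodes are in equilibrium; the top carries the section force
  expect_lt(max(abs(r[interior])), 1e-9 * Fz)
  expect_equal(sum(r[dof_indices(mesh, "uz", mesh$node_sets$top)]), Fz,
               tolerance = 1e-10)
})

test_that("numerical tangent matches residual directional derivatives", {
  pr <- tiny_column(2)
  x0 <- pr$init$x
  xa <- perturbed_state(pr, seed = 3)
  J <- assemble_jacobian(pr, xa, x0, dt = 2)
  n <- length(xa)
  scale <- rep(c(1e-7, 1e-7, 1e-7, 1, 1, 1), pr$mesh$n_nodes)
  set.seed(17)
  for (k in 1:10) {
    v <- stats::rnorm(n) * scale
    v[pr$dir_dofs] <- 0
    h <- 1e-3
    fd <- (assemble_residual(pr, xa + h * v, x0, 2) -
           assemble_residual(pr, xa - h * v, x0, 2)) / (2 * h)
    jv <- as.numeric(J %*% v)
    expect_lt(max(abs(fd - jv)) / max(abs(jv)), 1e-5)
  }
})

test_that("Dirichlet rows of the tangent are identity rows", {
  pr <- tiny_column(2)
  J <- assemble_jacobian(pr, pr$init$x, pr$init$x, dt = 1)
  Jd <- as.matrix(J[pr$dir_dofs, ])
  expected <- matrix(0, length(pr$dir_dofs), ncol(J))
  expected[cbind(seq_along(pr$dir_dofs), pr$dir_dofs)] <- 1
  expect_equal(Jd, expected, ignore_attr = TRUE)
})

test_that("displacement block of the tangent is symmetric", {
  # potentials uniform (frozen at bath values), displacements perturbed
  pr <- tiny_column(3, c_new = 150)
  x <- pr$init$x
  set.seed(5)
  uz <- dof_indices(pr$mesh, "uz")
  x[uz] <- 1e-7 * stats::rnorm(length(uz))
  x[pr$dir_dofs] <- pr$dir_vals
  J <- assemble_jacobian(pr, x, pr$init$x, dt = 1)
  free_u <- setdiff(uz, pr$dir_dofs)
  B <- as.matrix(J[free_u, free_u])
  expect_lt(max(abs(B - t(B))) / max(abs(B)), 1e-8)
})

test_that("convective ion transport terms are active", {
  mesh <- build_column_mesh(3, 0.5e-3, 0.0005e-3)
  par <- par_t1()
  pr_conv <- swell_problem(mesh, par, 150, 125, include_convective = TRUE,
                           bc = "quasi1d")
  pr_nocv <- swell_problem(mesh, par, 150, 125, include_convective = FALSE,
                           bc = "quasi1d")
  x0 <- pr_conv$init$x
  xn <- perturbed_state(pr_conv, seed = 9)  # vs != 0 and c_k != 0
  r1 <- assemble_residual(pr_conv, xn, x0, dt = 1)
  r2 <- assemble_residual(pr_nocv, xn, x0, dt = 1)
  ion_rows <- c(dof_indices(mesh, "eps_plus"), dof_indices(mesh, "eps_minus"))
  expect_gt(max(abs((r1 - r2)[ion_rows])), 0)
  # and inactive when the solid does not move
  r3 <- assemble_residual(pr_conv, x0, x0, dt = 1)
  r4 <- assemble_residual(pr_nocv, x0, x0, dt = 1)
  expect_equal(r3, r4)
})

test_that("electroneutrality holds at every quadrature point", {
  pr <- tiny_column(3)
  x <- perturbed_state(pr, seed = 21)
  st <- triswell:::gp_level_state(triswell:::gather_elem(pr, x), pr$ops,
                                  pr$params)
  rel <- abs(st$cp - st$cm - st$cF) / pmax(abs(st$cF), 1)
  expect_lt(max(rel), 1e-10)
})
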