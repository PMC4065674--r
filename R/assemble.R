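# Assembly of the coupled triphasic weak form on trilinear hexahedra with
# 2x2x2 Gauss integration.
#
# Unknowns per node: (ux, uy, uz, eps_w, eps_plus, eps_minus). The residual
# implements the Galerkin weak form of the governing balances:
#   momentum:  int grad(du) : sigma dV = 0           (quasi-static)
#   water:     int dw div(vs) dV - int grad(dw).Jw dV = 0
#   each ion:  int dp d(Phiw c)/dt dV - int grad(dp).(J + Phiw c vs) dV = 0
# with Crank-Nicolson weighting of the spatial (flux) terms and backward
# differences for vs = (u_new - u_old)/dt. Element kernels are vectorized
# across all elements (the structured meshes are uniform bricks, so one set
# of shape-derivative matrices serves every element).

# local dof layout within an element: columns (f-1)*8 + a for field f, node a
LOCAL_BLOCK <- function(f) (f - 1L) * 8L + 1:8

# Evaluate all Gauss-point fields of one time level from the element-local
# dof matrix X (n_elems x 48). Returns matrices n_elems x n_gp.
gp_level_state <- function(X, ops, par) {
  tN <- ops$tN; tGx <- ops$tGx; tGy <- ops$tGy; tGz <- ops$tGz
  ux <- X[, 1:8, drop = FALSE]
  uy <- X[, 9:16, drop = FALSE]
  uz <- X[, 17:24, drop = FALSE]
  w  <- X[, 25:32, drop = FALSE]
  p  <- X[, 33:40, drop = FALSE]
  m  <- X[, 41:48, drop = FALSE]

  gxux <- ux %*% tGx; gyux <- ux %*% tGy; gzux <- ux %*% tGz
  gxuy <- uy %*% tGx; gyuy <- uy %*% tGy; gzuy <- uy %*% tGz
  gxuz <- uz %*% tGx; gyuz <- uz %*% tGy; gzuz <- uz %*% tGz
  theta <- gxux + gyuy + gzuz

  vw <- w %*% tN; gwx <- w %*% tGx; gwy <- w %*% tGy; gwz <- w %*% tGz
  vp <- p %*% tN; gpx <- p %*% tGx; gpy <- p %*% tGy; gpz <- p %*% tGz
  vm <- m %*% tN; gmx <- m %*% tGx; gmy <- m %*% tGy; gmz <- m %*% tGz

  RT <- par$R * par$T
  den_f <- 1 + theta / par$Phi0w
  cF <- par$c0F / den_f
  Phiw <- 1 - par$phi0s / (1 + theta)
  qq <- cF * cF + 4 * vp * vm / (par$gamma_plus * par$gamma_minus)
  S <- sqrt(pmax(qq, 0))
  S[qq < 0] <- NA_real_
  cp <- (cF + S) / 2
  cm <- (S - cF) / 2
  P <- RT * vw + RT * par$Phi * S - par$Bw * theta
  kap <- RT * Phiw / par$alpha
  rp <- cp / vp
  rm <- cm / vm
  Jwx <- -kap * (gwx + rp * gpx + rm * gmx)
  Jwy <- -kap * (gwy + rp * gpy + rm * gmy)
  Jwz <- -kap * (gwz + rp * gpz + rm * gmz)
  dp <- Phiw * par$D_plus * rp
  dm <- Phiw * par$D_minus * rm

  list(theta = theta,
       exx = gxux, eyy = gyuy, ezz = gzuz,
       exy = (gyux + gxuy) / 2, exz = (gzux + gxuz) / 2,
       eyz = (gzuy + gyuz) / 2,
       vux = ux %*% tN, vuy = uy %*% tN, vuz = uz %*% tN,
       cF = cF, Phiw = Phiw, cp = cp, cm = cm, ck = S, P = P,
       Jwx = Jwx, Jwy = Jwy, Jwz = Jwz,
       Jpx = cp * Jwx - dp * gpx, Jpy = cp * Jwy - dp * gpy,
       Jpz = cp * Jwz - dp * gpz,
       Jmx = cm * Jwx - dm * gmx, Jmy = cm * Jwy - dm * gmy,
       Jmz = cm * Jwz - dm * gmz,
       Mp = Phiw * cp, Mm = Phiw * cm)
}

# Element residual contributions (n_elems x 48) from new/old level states.
elem_residual <- function(stn, sto, dt, ops, par, P_ref, cn,
                          include_convective = TRUE) {
  WN <- ops$WN; WGx <- ops$WGx; WGy <- ops$WGy; WGz <- ops$WGz
  lam <- par$lambda_s; mu2 <- 2 * par$mu_s

  dP <- stn$P - P_ref
  sxx <- lam * stn$theta - dP + mu2 * stn$exx
  syy <- lam * stn$theta - dP + mu2 * stn$eyy
  szz <- lam * stn$theta - dP + mu2 * stn$ezz
  sxy <- mu2 * stn$exy; sxz <- mu2 * stn$exz; syz <- mu2 * stn$eyz
  r_ux <- sxx %*% WGx + sxy %*% WGy + sxz %*% WGz
  r_uy <- sxy %*% WGx + syy %*% WGy + syz %*% WGz
  r_uz <- sxz %*% WGx + syz %*% WGy + szz %*% WGz

  divvs <- (stn$theta - sto$theta) / dt
  cno <- 1 - cn
  Jwx <- cn * stn$Jwx + cno * sto$Jwx
  Jwy <- cn * stn$Jwy + cno * sto$Jwy
  Jwz <- cn * stn$Jwz + cno * sto$Jwz
  r_w <- divvs %*% WN - (Jwx %*% WGx + Jwy %*% WGy + Jwz %*% WGz)

  Tpx <- cn * stn$Jpx + cno * sto$Jpx
  Tpy <- cn * stn$Jpy + cno * sto$Jpy
  Tpz <- cn * stn$Jpz + cno * sto$Jpz
  Tmx <- cn * stn$Jmx + cno * sto$Jmx
  Tmy <- cn * stn$Jmy + cno * sto$Jmy
  Tmz <- cn * stn$Jmz + cno * sto$Jmz
  if (include_convective) {
    vsx <- (stn$vux - sto$vux) / dt
    vsy <- (stn$vuy - sto$vuy) / dt
    vsz <- (stn$vuz - sto$vuz) / dt
    MpCN <- cn * stn$Mp + cno * sto$Mp
    MmCN <- cn * stn$Mm + cno * sto$Mm
    Tpx <- Tpx + MpCN * vsx; Tpy <- Tpy + MpCN * vsy; Tpz <- Tpz + MpCN * vsz
    Tmx <- Tmx + MmCN * vsx; Tmy <- Tmy + MmCN * vsy; Tmz <- Tmz + MmCN * vsz
  }
  r_p <- ((stn$Mp - sto$Mp) / dt) %*% WN -
    (Tpx %*% WGx + Tpy %*% WGy + Tpz %*% WGz)
  r_m <- ((stn$Mm - sto$Mm) / dt) %*% WN -
    (Tmx %*% WGx + Tmy %*% WGy + Tmz %*% WGz)

  cbind(r_ux, r_uy, r_uz, r_w, r_p, r_m)
}

#' Set up a free-swelling boundary-value problem
#'
#' Binds a mesh, material parameters and the bath step into a problem object
#' holding everything the assembly and the time marcher need: precomputed
#' shape-function matrices, scatter maps, the Dirichlet dof set and the
#' reference (Donnan) pressure of the incremental stress law.
#'
#' Boundary conditions:
#' \describe{
#'   \item{`"confined3d"`}{`ux = uy = 0` on the lateral surface, `u = 0` on
#'     the bottom, nodal potentials on the top surface prescribed to the new
#'     bath; lateral and bottom surfaces impermeable (natural no-flux).}
#'   \item{`"quasi1d"`}{as `"confined3d"` but with `ux = uy = 0` on every
#'     node, so only `uz` remains active (the column validation).}
#' }
#'
#' @param mesh a `hex_mesh`.
#' @param params a [material_parameters()] object.
#' @param c_star_old,c_star_new bath NaCl concentration before / after the
#'   step at `t = 0` (mol m^-3).
#' @param bc `"confined3d"` or `"quasi1d"`.
#' @param include_convective include the convective ion-transport terms
#'   `Phiw c vs` (on by default; exposed for term-activation checks).
#' @return An object of class `swell_problem`.
#' @export
swell_problem <- function(mesh, params, c_star_old, c_star_new,
                          bc = c("confined3d", "quasi1d"),
                          include_convective = TRUE) {
  bc <- match.arg(bc)
  bath_old <- bath_potentials(c_star_old, params)
  bath_new <- bath_potentials(c_star_new, params)
  init <- initial_tissue_state(c_star_old, params, mesh)

  g <- gauss_hex()
  so <- element_shape_ops(mesh, g$points)
  w <- so$detJ * g$weights
  ops <- list(tN = t(so$N), tGx = t(so$Gx), tGy = t(so$Gy), tGz = t(so$Gz),
              WN = w * so$N, WGx = w * so$Gx, WGy = w * so$Gy,
              WGz = w * so$Gz, detJ = so$detJ, n_gp = length(w))

  ne <- mesh$n_elems
  conn <- mesh$elems
  dofmat <- matrix(0L, ne, 48L)
  for (f in 1:6) dofmat[, LOCAL_BLOCK(f)] <- (conn - 1L) * 6L + f
  ndof <- 6L * mesh$n_nodes

  scatter <- Matrix::sparseMatrix(i = as.integer(dofmat),
                                  j = seq_len(ne * 48L),
                                  x = 1, dims = c(ndof, ne * 48L))

  a_of <- rep(1:48, times = 48)  # row-local dof per jacobian column block
  b_of <- rep(1:48, each = 48)
  jac_i <- as.integer(dofmat[, a_of])
  jac_j <- as.integer(dofmat[, b_of])

  ns <- mesh$node_sets
  dir_dofs <- c(dof_indices(mesh, "uz", ns$bottom),
                dof_indices(mesh, "eps_w", ns$top),
                dof_indices(mesh, "eps_plus", ns$top),
                dof_indices(mesh, "eps_minus", ns$top))
  dir_vals <- c(rep(0, length(ns$bottom)),
                rep(bath_new$eps_w_star, length(ns$top)),
                rep(bath_new$eps_plus_star, length(ns$top)),
                rep(bath_new$eps_minus_star, length(ns$top)))
  if (bc == "quasi1d") {
    all_n <- seq_len(mesh$n_nodes)
    dir_dofs <- c(dof_indices(mesh, "ux", all_n),
                  dof_indices(mesh, "uy", all_n), dir_dofs)
    dir_vals <- c(rep(0, 2L * mesh$n_nodes), dir_vals)
  } else {
    lat <- union(ns$lateral, ns$bottom)  # in-plane displacements suppressed
    dir_dofs <- c(dof_indices(mesh, "ux", lat),
                  dof_indices(mesh, "uy", lat), dir_dofs)
    dir_vals <- c(rep(0, 2L * length(lat)), dir_vals)
  }
  o <- order(dir_dofs)
  dir_dofs <- dir_dofs[o]; dir_vals <- dir_vals[o]
  stopifnot(!anyDuplicated(dir_dofs))

  # FD steps for the numerical tangent and Newton convergence scales, per
  # local dof: displacements scaled by the element height, potentials by the
  # initial bath concentration.
  fd_h <- numeric(48)
  fd_h[1:24] <- 1e-5 * mesh$spacing["hz"]
  fd_h[25:48] <- 1e-5 * c_star_old
  dof_scale <- rep(c(1e-6, 1e-6, 1e-6, c_star_old, c_star_old, c_star_old),
                   mesh$n_nodes)

  # surface quadrature operators on the top facets (for quadrature fluxes)
  gtop <- HEX_LOCAL[5:8, 1:2] / sqrt(3)
  top_pts <- cbind(gtop, 1)
  so_top <- element_shape_ops(mesh, top_pts)
  top_ops <- list(tN = t(so_top$N), tGx = t(so_top$Gx), tGy = t(so_top$Gy),
                  tGz = t(so_top$Gz),
                  area_w = prod(mesh$spacing[c("hx", "hy")]) / 4,
                  elems = unique(mesh$tags$top[, "elem"]))

  structure(list(mesh = mesh, params = params,
                 bath_old = bath_old, bath_new = bath_new,
                 init = init, P_ref = init$P_ref, bc = bc,
                 include_convective = include_convective,
                 ops = ops, dofmat = dofmat, ndof = ndof,
                 scatter = scatter, jac_i = jac_i, jac_j = jac_j,
                 jac_dir_row = jac_i %in% dir_dofs,
                 dir_dofs = dir_dofs, dir_vals = dir_vals,
                 fd_h = fd_h, dof_scale = dof_scale,
                 top_ops = top_ops),
            class = "swell_problem")
}

#' @export
print.swell_problem <- function(x, ...) {
  cat(sprintf("Triphasic free-swelling problem (%s): %d dofs, %d Dirichlet\n",
              x$bc, x$ndof, length(x$dir_dofs)))
  cat(sprintf("  bath step %.6g -> %.6g mol m^-3, reference Donnan pressure %.6g Pa\n",
              x$bath_old$c_star, x$bath_new$c_star, x$P_ref))
  invisible(x)
}

gather_elem <- function(problem, x) {
  matrix(x[problem$dofmat], nrow = problem$mesh$n_elems, ncol = 48L)
}

# Core residual without Dirichlet-row replacement (used for consistent
# boundary-flux recovery). `sto` is the cached old-level GP state.
assemble_residual_full <- function(problem, x_new, sto, dt, cn_weight) {
  Xn <- gather_elem(problem, x_new)
  stn <- gp_level_state(Xn, problem$ops, problem$params)
  rel <- elem_residual(stn, sto, dt, problem$ops, problem$params,
                       problem$P_ref, cn_weight, problem$include_convective)
  as.numeric(problem$scatter %*% as.numeric(rel))
}

#' Assemble the global residual of a Crank-Nicolson step
#'
#' Residual of the coupled discrete system at the new time level, given the
#' previous converged level. Dirichlet rows hold the constraint residual
#' `x[dof] - value`. The residual of a converged step is zero to solver
#' tolerance; at the initial equilibrium with an unchanged bath it vanishes
#' identically.
#'
#' @param problem a [swell_problem()].
#' @param x_new,x_old packed dof vectors at the new / previous time level.
#' @param dt time step (s).
#' @param cn_weight Crank-Nicolson weight of the new level (0.5 default).
#' @return numeric residual vector of length `problem$ndof`.
#' @export
assemble_residual <- function(problem, x_new, x_old, dt, cn_weight = 0.5) {
  Xo <- gather_elem(problem, x_old)
  sto <- gp_level_state(Xo, problem$ops, problem$params)
  Xn <- gather_elem(problem, x_new)
  stn <- gp_level_state(Xn, problem$ops, problem$params)
  rel <- elem_residual(stn, sto, dt, problem$ops, problem$params,
                       problem$P_ref, cn_weight, problem$include_convective)
  if (!all(is.finite(rel))) {
    bad <- which(!apply(is.finite(rel), 1, all))
    stop("assembly error: non-finite residual in element(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  r <- as.numeric(problem$scatter %*% as.numeric(rel))
  r[problem$dir_dofs] <- x_new[problem$dir_dofs] - problem$dir_vals
  r
}

# Jacobian from element-level central differences; sto is the old GP state.
assemble_jacobian_core <- function(problem, x_new, sto, dt, cn_weight) {
  ops <- problem$ops; par <- problem$params
  Xn <- gather_elem(problem, x_new)
  ne <- nrow(Xn)
  Jval <- matrix(0, ne, 48L * 48L)
  for (b in 1:48) {
    h <- problem$fd_h[b]
    Xp <- Xn; Xp[, b] <- Xp[, b] + h
    Xm <- Xn; Xm[, b] <- Xm[, b] - h
    relp <- elem_residual(gp_level_state(Xp, ops, par), sto, dt, ops, par,
                          problem$P_ref, cn_weight,
                          problem$include_convective)
    relm <- elem_residual(gp_level_state(Xm, ops, par), sto, dt, ops, par,
                          problem$P_ref, cn_weight,
                          problem$include_convective)
    Jval[, (b - 1L) * 48L + 1:48] <- (relp - relm) / (2 * h)
  }
  xv <- as.numeric(Jval)
  xv[problem$jac_dir_row] <- 0
  nd <- length(problem$dir_dofs)
  Matrix::sparseMatrix(i = c(problem$jac_i, problem$dir_dofs),
                       j = c(problem$jac_j, problem$dir_dofs),
                       x = c(xv, rep(1, nd)),
                       dims = c(problem$ndof, problem$ndof))
}

#' Assemble the Newton tangent of a Crank-Nicolson step
#'
#' Consistent numerical tangent of [assemble_residual()], built from
#' element-level central differences with per-field step scaling. Dirichlet
#' rows are identity rows. Finite-difference directional derivatives of the
#' residual agree with products of this matrix to well below 1e-5 relative.
#'
#' @inheritParams assemble_residual
#' @return a sparse `dgCMatrix` of dimension `ndof x ndof`.
#' @export
assemble_jacobian <- function(problem, x_new, x_old, dt, cn_weight = 0.5) {
  Xo <- gather_elem(problem, x_old)
  sto <- gp_level_state(Xo, problem$ops, problem$params)
  assemble_jacobian_core(problem, x_new, sto, dt, cn_weight)
}
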