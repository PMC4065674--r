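# Donnan equilibrium between the tissue and the external bathing solution,
# plus an analytic steady-state oracle for laterally confined free swelling.

#' Modified potentials of the external bathing solution
#'
#' With the bath at the pressure and electrical-potential gauge
#' (`P* = 0`, `psi* = 0`) the modified potentials of a NaCl bath of
#' concentration `c_star` are `eps_w* = -2 Phi c_star`,
#' `eps_plus* = gamma_plus c_star`, `eps_minus* = gamma_minus c_star`.
#' The bath uses the same activity and osmotic coefficients as the tissue
#' (overridable through `gamma_plus_bath`, `gamma_minus_bath`, `Phi_bath`).
#'
#' @param c_star bath NaCl concentration (mol m^-3), > 0.
#' @param params a [material_parameters()] object.
#' @param gamma_plus_bath,gamma_minus_bath,Phi_bath optional bath-side
#'   coefficients; default to the tissue values in `params`.
#' @return An object of class `bath_state` with fields `c_star`,
#'   `eps_w_star`, `eps_plus_star`, `eps_minus_star`.
#' @export
bath_potentials <- function(c_star, params,
                            gamma_plus_bath = params$gamma_plus,
                            gamma_minus_bath = params$gamma_minus,
                            Phi_bath = params$Phi) {
  if (!is.numeric(c_star) || length(c_star) != 1L || c_star <= 0) {
    stop("invalid parameter: bath concentration c_star must be > 0",
         call. = FALSE)
  }
  structure(list(c_star = c_star,
                 eps_w_star = -2 * Phi_bath * c_star,
                 eps_plus_star = gamma_plus_bath * c_star,
                 eps_minus_star = gamma_minus_bath * c_star),
            class = "bath_state")
}

#' @export
print.bath_state <- function(x, ...) {
  cat(sprintf("Bath: c* = %.6g mol m^-3  (eps_w* = %.6g, eps+* = %.6g, eps-* = %.6g)\n",
              x$c_star, x$eps_w_star, x$eps_plus_star, x$eps_minus_star))
  invisible(x)
}

#' Donnan ion concentrations inside a charged tissue at bath equilibrium
#'
#' With equal tissue and bath activity coefficients the interior
#' concentrations at equilibrium with a bath of concentration `c_star`
#' satisfy `c_plus * c_minus = c_star^2` and electroneutrality
#' `c_plus - c_minus = cF`, so
#' `c_plus = (cF + sqrt(cF^2 + 4 c_star^2)) / 2`.
#'
#' @param c_star bath concentration (mol m^-3).
#' @param cF fixed charge density (mol m^-3).
#' @param params a [material_parameters()] object (activity coefficients are
#'   used through the potential inversion; with equal bath/tissue values they
#'   cancel).
#' @return A list with `c_plus` and `c_minus` (mol m^-3).
#' @examples
#' donnan_concentrations(150, 200, material_parameters())  # 280.28 / 80.28
#' @export
donnan_concentrations <- function(c_star, cF, params) {
  bath <- bath_potentials(c_star, params)
  ion_concentrations(bath$eps_plus_star, bath$eps_minus_star, cF,
                     params$gamma_plus, params$gamma_minus)
}

#' Initial (reference) tissue state in equilibrium with the bath
#'
#' The free-swollen equilibrium with the initial bath is the reference
#' configuration: displacements and dilatation are zero, the nodal modified
#' potentials equal the bath values, interior ion concentrations follow the
#' Donnan partition, and the interior fluid pressure is the Donnan osmotic
#' pressure (the reference pressure of the incremental stress law).
#'
#' @param c_star initial bath concentration (mol m^-3).
#' @param params a [material_parameters()] object.
#' @param mesh a [build_column_mesh()] / [build_block_mesh()] mesh.
#' @return A list of class `initial_state` with: `x` the packed dof vector
#'   (per node `ux, uy, uz, eps_w, eps_plus, eps_minus`), `bath` the
#'   `bath_state`, `c_plus`, `c_minus` (interior concentrations), and `P_ref`
#'   the interior Donnan pressure (Pa).
#' @export
initial_tissue_state <- function(c_star, params, mesh) {
  bath <- bath_potentials(c_star, params)
  ions <- donnan_concentrations(c_star, params$c0F, params)
  P_ref <- fluid_pressure(bath$eps_w_star, ions$c_plus, ions$c_minus, 0,
                          params)
  n <- mesh$n_nodes
  x <- numeric(6L * n)
  x[dof_indices(mesh, "eps_w")] <- bath$eps_w_star
  x[dof_indices(mesh, "eps_plus")] <- bath$eps_plus_star
  x[dof_indices(mesh, "eps_minus")] <- bath$eps_minus_star
  structure(list(x = x, bath = bath, c_plus = ions$c_plus,
                 c_minus = ions$c_minus, P_ref = P_ref),
            class = "initial_state")
}

#' Analytic steady state of laterally confined free swelling
#'
#' Independent scalar oracle for the final equilibrium after a bath step
#' `c_star_old -> c_star_new` under lateral confinement (`ux = uy = 0`): the
#' final dilatation is uniform and uniaxial, and the traction-free condition
#' on the top surface balances the confined-compression stiffness against the
#' change in Donnan osmotic pressure:
#' `(lambda_s + 2 mu_s + Bw) theta =
#'    RT Phi (sqrt(cF(theta)^2 + 4 c_new^2) - 2 c_new)
#'  - RT Phi (sqrt(c0F^2 + 4 c_old^2) - 2 c_old)`
#' with `cF(theta) = c0F / (1 + theta / Phi0w)`. Solved by bracketed scalar
#' root finding to 1e-12 absolute on `theta`.
#'
#' @param params a [material_parameters()] object.
#' @param c_star_old,c_star_new bath concentrations before/after the step
#'   (mol m^-3).
#' @param height sample height (m); used to convert dilatation to top
#'   displacement.
#' @return A list with `theta_f` (final dilatation) and `u_top` (final top
#'   displacement, m).
#' @export
confined_steady_state_oracle <- function(params, c_star_old, c_star_new,
                                         height = 0.5e-3) {
  RT <- params$R * params$T
  H2mu <- params$lambda_s + 2 * params$mu_s + params$Bw
  ck <- function(cF, cs) sqrt(cF^2 + 4 * cs^2)
  pi_old <- RT * params$Phi * (ck(params$c0F, c_star_old) - 2 * c_star_old)
  f <- function(theta) {
    cF <- update_fcd(theta, params$c0F, params$Phi0w)
    H2mu * theta -
      (RT * params$Phi * (ck(cF, c_star_new) - 2 * c_star_new) - pi_old)
  }
  if (c_star_new == c_star_old || params$c0F == 0) {
    return(list(theta_f = 0, u_top = 0))
  }
  lo <- -params$Phi0w + 1e-6
  hi <- 5
  if (f(lo) * f(hi) > 0) {
    stop("oracle failure: no sign change in the bracket (",
         signif(f(lo), 4), ", ", signif(f(hi), 4), ")", call. = FALSE)
  }
  theta_f <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  list(theta_f = theta_f, u_top = theta_f * height)
}
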