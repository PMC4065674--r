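# Pointwise material laws of the triphasic mixture. All functions are
# vectorized over their state arguments; parameters enter through a
# `material_parameters` object where they are needed.

#' Current porosity from the solid dilatation
#'
#' `Phiw = 1 - phi0s / (1 + theta)`: with an intrinsically incompressible
#' solid, dilatation changes only the water fraction of the mixture.
#'
#' @param theta solid dilatation `div u` (dimensionless).
#' @param phi0s solid volume fraction at the reference configuration,
#'   `phi0s = 1 - Phi0w`.
#' @return current porosity (water volume fraction).
#' @export
update_porosity <- function(theta, phi0s) {
  if (any(phi0s <= 0) || any(phi0s >= 1)) {
    stop("invalid parameter: phi0s must lie in (0, 1)", call. = FALSE)
  }
  if (any(1 + theta <= 0)) {
    stop("degenerate deformation: 1 + theta must be > 0", call. = FALSE)
  }
  1 - phi0s / (1 + theta)
}

#' Current fixed charge density from the solid dilatation
#'
#' `cF = c0F / (1 + theta / Phi0w)`: the matrix-bound charges are conserved,
#' so their concentration per fluid volume dilutes as the tissue swells and
#' concentrates as it shrinks.
#'
#' @param theta solid dilatation.
#' @param c0F initial fixed charge density (mol m^-3).
#' @param Phi0w initial porosity.
#' @return current fixed charge density (mol m^-3).
#' @export
update_fcd <- function(theta, c0F, Phi0w) {
  den <- 1 + theta / Phi0w
  if (any(den <= 0)) {
    stop("degenerate deformation: 1 + theta/Phi0w must be > 0", call. = FALSE)
  }
  c0F / den
}

#' Ion concentrations from the modified electrochemical potentials
#'
#' Inverts the potential definitions under electroneutrality: the pair
#' `(c_plus, c_minus)` is the unique nonnegative root of
#' `c_plus - c_minus = cF` and
#' `gamma_plus * gamma_minus * c_plus * c_minus = eps_plus * eps_minus`,
#' i.e. `c_plus = (cF + sqrt(cF^2 + 4 eps_plus eps_minus / (g+ g-))) / 2`.
#'
#' @param eps_plus,eps_minus modified electrochemical potentials (mol m^-3
#'   scale); their product must be nonnegative.
#' @param cF fixed charge density (mol m^-3), nonnegative.
#' @param gamma_plus,gamma_minus ion activity coefficients.
#' @return A list with components `c_plus` and `c_minus` (mol m^-3). The
#'   outputs satisfy `c_plus - c_minus == cF` exactly.
#' @examples
#' ion_concentrations(150, 150, 200, 1, 1)  # 280.28 / 80.28 mol m^-3
#' @export
ion_concentrations <- function(eps_plus, eps_minus, cF, gamma_plus,
                               gamma_minus) {
  q <- eps_plus * eps_minus / (gamma_plus * gamma_minus)
  if (any(q < 0)) {
    stop("invalid state: eps_plus * eps_minus must be nonnegative",
         call. = FALSE)
  }
  if (any(cF < 0)) stop("invalid state: cF must be nonnegative", call. = FALSE)
  s <- sqrt(cF^2 + 4 * q)
  c_minus <- (s - cF) / 2
  list(c_plus = c_minus + cF, c_minus = c_minus)
}

#' Fluid pressure from the water potential, ion content and dilatation
#'
#' Rearranges the water-potential definition
#' `eps_w = P/(RT) - Phi (c_plus + c_minus) + (Bw/(RT)) theta` to
#' `P = RT eps_w + RT Phi (c_plus + c_minus) - Bw theta`. The gauge is the
#' external bath: at the bath state (`eps_w = -2 Phi c_star`,
#' `c_plus = c_minus = c_star`, `theta = 0`) the pressure is exactly zero.
#'
#' @param eps_w modified chemical potential of water (mol m^-3 scale).
#' @param c_plus,c_minus ion concentrations (mol m^-3).
#' @param theta solid dilatation.
#' @param params a [material_parameters()] object.
#' @return fluid pressure (Pa).
#' @export
fluid_pressure <- function(eps_w, c_plus, c_minus, theta, params) {
  RT <- params$R * params$T
  RT * eps_w + RT * params$Phi * (c_plus + c_minus) - params$Bw * theta
}

#' Total (mixture) stress tensor
#'
#' `sigma = -P I + lambda_s theta I + 2 mu_s strain` for the small-strain,
#' isotropic linear elastic solid matrix.
#'
#' @param theta solid dilatation, `trace(strain)`.
#' @param strain 3x3 symmetric small-strain tensor.
#' @param P fluid pressure (Pa).
#' @param params a [material_parameters()] object.
#' @return 3x3 total stress tensor (Pa).
#' @export
total_stress <- function(theta, strain, P, params) {
  strain <- as.matrix(strain)
  if (!isTRUE(all.equal(strain, t(strain), tolerance = 1e-10))) {
    stop("invalid input: strain tensor must be symmetric", call. = FALSE)
  }
  (-P + params$lambda_s * theta) * diag(3) + 2 * params$mu_s * strain
}

#' Electrical potential recovered from the cation potential
#'
#' `psi = (RT/Fc) log(eps_plus / (gamma_plus c_plus))`. The electrical
#' potential is eliminated from the solved system and only recovered as a
#' diagnostic; the bath convention is `psi* = 0`.
#'
#' @param eps_plus modified cation potential (> 0).
#' @param c_plus cation concentration (> 0).
#' @param gamma_plus cation activity coefficient.
#' @param params a [material_parameters()] object.
#' @return electrical potential (V).
#' @export
recover_electric_potential <- function(eps_plus, c_plus, gamma_plus, params) {
  if (any(eps_plus <= 0) || any(c_plus <= 0)) {
    stop("invalid state: eps_plus and c_plus must be > 0", call. = FALSE)
  }
  (params$R * params$T / params$Fc) * log(eps_plus / (gamma_plus * c_plus))
}

#' Hydraulic permeability from porosity and drag
#'
#' `k = Phiw / alpha` links the solid-water drag coefficient and the current
#' porosity to Darcy-type flow.
#'
#' @param Phiw current porosity.
#' @param alpha solid-water drag coefficient (N s m^-4).
#' @return permeability (m^4 N^-1 s^-1).
#' @export
permeability <- function(Phiw, alpha) Phiw / alpha
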