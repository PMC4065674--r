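#' Lame constants from engineering elastic moduli
#'
#' Converts Young's modulus and Poisson ratio of the (isotropic, linear
#' elastic) solid matrix into the Lame constants used by the stress law.
#'
#' @param E Young's modulus (Pa), `E > 0`.
#' @param nu Poisson ratio (dimensionless), `-1 < nu < 0.5`.
#' @return A list with components `lambda_s` and `mu_s` (Pa).
#' @examples
#' lame_from_elastic_moduli(3.85e5, 0.28)
#' @export
lame_from_elastic_moduli <- function(E, nu) {
  if (!is.numeric(E) || any(E <= 0)) {
    stop("invalid parameter: Young's modulus E must be > 0", call. = FALSE)
  }
  if (!is.numeric(nu) || any(nu >= 0.5) || any(nu <= -1)) {
    stop("invalid parameter: Poisson ratio nu must lie in (-1, 0.5)",
         call. = FALSE)
  }
  list(lambda_s = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu_s     = E / (2 * (1 + nu)))
}

#' Convert a fixed charge density from mEq/mL to mol/m^3
#'
#' For monovalent species 1 mEq/mL = 1000 mol/m^3.
#'
#' @param x value in mEq/mL.
#' @return value in mol/m^3.
#' @export
meq_per_ml_to_mol_m3 <- function(x) 1000 * x

#' Material and physical parameters of the triphasic tissue model
#'
#' Collects all tissue and physical constants used by the model and validates
#' them. Lame constants are derived from `E` and `nu`. Defaults correspond to
#' the healthy-cartilage column (quasi-1D) preset; see [table1_parameters()]
#' and [table2_parameters()].
#'
#' @param E Young's modulus of the solid matrix (Pa).
#' @param nu Poisson ratio of the solid matrix.
#' @param alpha drag coefficient between solid and water phases (N s m^-4).
#' @param D_plus,D_minus diffusivities of cations / anions (m^2 s^-1).
#' @param c0F initial fixed charge density (mol m^-3, per fluid volume).
#' @param gamma_plus,gamma_minus activity coefficients of cations / anions.
#' @param R gas constant (J mol^-1 K^-1).
#' @param T absolute temperature (K).
#' @param Phi osmotic coefficient.
#' @param Phi0w initial porosity (water volume fraction) of the tissue.
#' @param Bw fluid-solid coupling coefficient (Pa); defaults to 0.
#' @param Fc Faraday constant (C mol^-1).
#' @return An object of class `material_parameters` (a named list that also
#'   carries `lambda_s`, `mu_s` and the reference solid fraction
#'   `phi0s = 1 - Phi0w`).
#' @export
material_parameters <- function(E = 3.85e5, nu = 0.28, alpha = 7e14,
                                D_plus = 5e-10, D_minus = 8e-10,
                                c0F = 200, gamma_plus = 1, gamma_minus = 1,
                                R = 8.314, T = 298, Phi = 1, Phi0w = 0.75,
                                Bw = 0, Fc = 96485) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameter: ", msg,
                                                 call. = FALSE)
  chk(is.numeric(E) && E > 0, "E must be > 0")
  chk(is.numeric(nu) && nu > 0 && nu < 0.5, "nu must lie in (0, 0.5)")
  chk(alpha > 0, "alpha must be > 0")
  chk(D_plus > 0 && D_minus > 0, "diffusivities must be > 0")
  chk(c0F >= 0, "c0F must be >= 0")
  chk(gamma_plus > 0 && gamma_plus <= 1, "gamma_plus must lie in (0, 1]")
  chk(gamma_minus > 0 && gamma_minus <= 1, "gamma_minus must lie in (0, 1]")
  chk(R > 0 && T > 0, "R and T must be > 0")
  chk(Phi > 0 && Phi <= 1, "Phi must lie in (0, 1]")
  chk(Phi0w > 0 && Phi0w < 1, "Phi0w must lie in (0, 1)")
  chk(Bw >= 0, "Bw must be >= 0")
  lame <- lame_from_elastic_moduli(E, nu)
  structure(list(E = E, nu = nu,
                 lambda_s = lame$lambda_s, mu_s = lame$mu_s,
                 alpha = alpha, D_plus = D_plus, D_minus = D_minus,
                 c0F = c0F, gamma_plus = gamma_plus,
                 gamma_minus = gamma_minus, R = R, T = T, Phi = Phi,
                 Phi0w = Phi0w, phi0s = 1 - Phi0w, Bw = Bw, Fc = Fc),
            class = "material_parameters")
}

#' @export
print.material_parameters <- function(x, ...) {
  cat("Triphasic material parameters\n")
  cat(sprintf("  E       = %.4g Pa   nu = %.3g  (lambda_s = %.4g, mu_s = %.4g Pa)\n",
              x$E, x$nu, x$lambda_s, x$mu_s))
  cat(sprintf("  alpha   = %.4g N s m^-4   D+ = %.3g  D- = %.3g m^2 s^-1\n",
              x$alpha, x$D_plus, x$D_minus))
  cat(sprintf("  c0F     = %.4g mol m^-3   gamma+ = %.3g  gamma- = %.3g\n",
              x$c0F, x$gamma_plus, x$gamma_minus))
  cat(sprintf("  Phi     = %.3g   Phi0w = %.3g   Bw = %.3g Pa\n",
              x$Phi, x$Phi0w, x$Bw))
  cat(sprintf("  R = %.4g J mol^-1 K^-1   T = %.4g K   Fc = %.5g C mol^-1\n",
              x$R, x$T, x$Fc))
  invisible(x)
}

#' Healthy-cartilage parameter preset for the quasi-1D column model
#'
#' Material parameters and geometry of the simplified (quasi-1D) healthy
#' cartilage free-swelling validation: 0.5 mm high column with a cross-section
#' four orders of magnitude smaller than the height, 50 elements in depth,
#' unit activity and osmotic coefficients.
#'
#' @param ... overrides forwarded to [material_parameters()].
#' @return A list with components `params` ([material_parameters()]),
#'   `height` (m), `diameter` (m) and `n_elems`.
#' @export
table1_parameters <- function(...) {
  over <- list(...)
  base <- list(E = 3.85e5, nu = 0.28, alpha = 7e14,
               D_plus = 5e-10, D_minus = 8e-10,
               c0F = meq_per_ml_to_mol_m3(0.2),
               gamma_plus = 1, gamma_minus = 1,
               R = 8.314, T = 298, Phi = 1, Phi0w = 0.75)
  base[names(over)] <- over
  list(params = do.call(material_parameters, base),
       height = 0.5e-3, diameter = 0.0005e-3, n_elems = 50)
}

#' Healthy-cartilage parameter preset for the full 3D sample
#'
#' As [table1_parameters()] but with the full 1.5 mm sample diameter and the
#' non-ideal solution coefficients (gamma+ = 0.86, gamma- = 0.85, Phi = 0.8).
#'
#' @param ... overrides forwarded to [material_parameters()].
#' @return A list with components `params`, `height` (m), `diameter` (m).
#' @export
table2_parameters <- function(...) {
  over <- list(...)
  base <- list(E = 3.85e5, nu = 0.28, alpha = 7e14,
               D_plus = 5e-10, D_minus = 8e-10,
               c0F = meq_per_ml_to_mol_m3(0.2),
               gamma_plus = 0.86, gamma_minus = 0.85,
               R = 8.314, T = 298, Phi = 0.8, Phi0w = 0.75)
  base[names(over)] <- over
  list(params = do.call(material_parameters, base),
       height = 0.5e-3, diameter = 1.5e-3)
}
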