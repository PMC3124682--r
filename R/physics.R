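#' Physical constants used throughout the package
#'
#' A single table of the physical constants the Compton kinematics rely on.
#' Every routine that needs one of these values reads it from here (or from a
#' [physics_params()] object, which can override them), so there is exactly one
#' place where they are defined.
#'
#' @format A named list with components
#' \describe{
#'   \item{mec2_keV}{electron rest energy \eqn{m_e c^2}, 510.999 keV}
#'   \item{re_cm}{classical electron radius, cm}
#'   \item{compton_wavelength_cm}{Compton wavelength \eqn{h/(m_e c)}, cm}
#'   \item{hc_keV_cm}{\eqn{hc} in keV cm, used to convert wavelength to energy}
#'   \item{euler_gamma}{Euler--Mascheroni constant \eqn{\gamma}}
#' }
#' @export
scatter_constants <- list(
  mec2_keV             = 510.999,
  re_cm                = 2.8179403e-13,
  compton_wavelength_cm = 2.42631024e-10,
  hc_keV_cm            = 1.23984198e-7,
  euler_gamma          = 0.577215664901532861
)

#' Physics parameters for scatter imaging
#'
#' Bundles the source energy, the dimensionless ratio
#' \eqn{\epsilon = E_0 / (m_e c^2)}, the classical electron radius, the
#' (uniform) electron density of the scattering medium and an optional uniform
#' linear attenuation coefficient.
#'
#' @param E0_keV photon energy of the source line, keV (Tc-99m: 140 keV).
#' @param ne_per_cm3 electron density of the scattering medium, electrons/cm^3.
#' @param mu_per_mm uniform linear attenuation coefficient, 1/mm; 0 disables
#'   attenuation.
#' @param mec2_keV electron rest energy, keV; override only for testing.
#' @param re_cm classical electron radius, cm.
#' @return An object of class `physics_params` with fields `E0_keV`, `epsilon`,
#'   `re_cm`, `ne_per_cm3`, `mu_per_mm`.
#' @examples
#' p <- physics_params(140)
#' p$epsilon  # 140 / 510.999
#' @export
physics_params <- function(E0_keV = 140, ne_per_cm3 = 3.5e23, mu_per_mm = 0,
                           mec2_keV = scatter_constants$mec2_keV,
                           re_cm = scatter_constants$re_cm) {
  stopifnot(is.numeric(E0_keV), length(E0_keV) == 1L, E0_keV > 0,
            is.numeric(ne_per_cm3), ne_per_cm3 > 0,
            is.numeric(mu_per_mm), mu_per_mm >= 0)
  structure(list(
    E0_keV     = E0_keV,
    epsilon    = E0_keV / mec2_keV,
    re_cm      = re_cm,
    ne_per_cm3 = ne_per_cm3,
    mu_per_mm  = mu_per_mm,
    mec2_keV   = mec2_keV
  ), class = "physics_params")
}

#' @export
print.physics_params <- function(x, ...) {
  cat("Physics parameters for scattered-radiation imaging\n")
  cat(sprintf("  E0      : %g keV  (epsilon = %.6f)\n", x$E0_keV, x$epsilon))
  cat(sprintf("  n_e     : %g electrons/cm^3\n", x$ne_per_cm3))
  cat(sprintf("  mu      : %g /mm%s\n", x$mu_per_mm,
              if (x$mu_per_mm == 0) " (attenuation off)" else ""))
  invisible(x)
}

.check_omega <- function(omega, open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(omega) || anyNA(omega))
    stop("scattering angle 'omega' must be numeric and non-missing", call. = FALSE)
  lo <- if (open_lower) all(omega > 0) else all(omega >= 0)
  hi <- if (open_upper) all(omega < pi) else all(omega <= pi)
  if (!lo || !hi)
    stop("scattering angle 'omega' outside its domain [0, pi] (radians)", call. = FALSE)
  invisible(omega)
}

#' Scattered photon energy after Compton scattering
#'
#' Energy form of the Compton formula,
#' \deqn{E(\omega) = \frac{E_0}{1 + \epsilon (1 - \cos\omega)},
#'   \qquad \epsilon = E_0 / (m_e c^2).}
#' The energy decreases monotonically from \eqn{E_0} at \eqn{\omega = 0} to the
#' backscatter energy \eqn{E_0/(1 + 2\epsilon)} at \eqn{\omega = \pi}, so each
#' detector energy window corresponds to exactly one scattering angle: this
#' bijection is what lets a motionless camera acquire an angle-indexed
#' projection series.
#'
#' @param E0_keV source energy, keV.
#' @param omega scattering angle(s), radians, in `[0, pi]`.
#' @param mec2_keV electron rest energy, keV.
#' @return Scattered energy (keV), same length as `omega`.
#' @seealso [angle_from_energy()], [scattered_wavelength()]
#' @export
scattered_energy <- function(E0_keV, omega,
                             mec2_keV = scatter_constants$mec2_keV) {
  stopifnot(E0_keV > 0)
  .check_omega(omega)
  eps <- E0_keV / mec2_keV
  E0_keV / (1 + eps * (1 - cos(omega)))
}

#' Scattered photon wavelength after Compton scattering
#'
#' Wavelength form of the Compton formula,
#' \eqn{\lambda = \lambda_0 + (h / m_e c)(1 - \cos\omega)}; the shift is
#' independent of the incident wavelength.
#'
#' @param lambda0_cm incident wavelength, cm.
#' @param omega scattering angle(s), radians, in `[0, pi]`.
#' @param compton_wavelength_cm the Compton wavelength \eqn{h/(m_e c)}, cm.
#' @return Scattered wavelength (cm), `>= lambda0_cm`.
#' @export
scattered_wavelength <- function(lambda0_cm, omega,
                                 compton_wavelength_cm = scatter_constants$compton_wavelength_cm) {
  stopifnot(lambda0_cm > 0)
  .check_omega(omega)
  lambda0_cm + compton_wavelength_cm * (1 - cos(omega))
}

#' Scattering angle from the detected energy
#'
#' Inverts the energy form of the Compton formula on the kinematically allowed
#' band \eqn{E_0/(1+2\epsilon) \le E \le E_0}.
#'
#' @param E0_keV source energy, keV.
#' @param E_keV detected (scattered) energy, keV.
#' @param mec2_keV electron rest energy, keV.
#' @return Scattering angle, radians, in `[0, pi]`.
#' @export
angle_from_energy <- function(E0_keV, E_keV,
                              mec2_keV = scatter_constants$mec2_keV) {
  stopifnot(E0_keV > 0)
  eps <- E0_keV / mec2_keV
  Emin <- E0_keV / (1 + 2 * eps)
  tol <- 1e-12 * E0_keV
  if (any(E_keV < Emin - tol) || any(E_keV > E0_keV + tol))
    stop(sprintf("energy outside the kinematically allowed band [%.6g, %.6g] keV",
                 Emin, E0_keV), call. = FALSE)
  cosw <- 1 - (E0_keV / pmin(pmax(E_keV, Emin), E0_keV) - 1) / eps
  acos(pmin(pmax(cosw, -1), 1))
}

#' Klein-Nishina angular probability
#'
#' Angular density of Compton scattering,
#' \deqn{\mathcal{P}(\omega) = \pi r_e^2 \frac{1}{2\pi}
#'   \frac{1}{[1+\epsilon(1-\cos\omega)]^2}
#'   \left(1 + \cos^2\omega + \frac{s(\omega)}{1+\epsilon(1-\cos\omega)}\right)}
#' with \eqn{s(\omega) = 1 - \cos^2\omega} for the default `variant =
#' "printed"` and the quantum-electrodynamics textbook recoil term
#' \eqn{s(\omega) = \epsilon^2 (1-\cos\omega)^2} for `variant = "textbook"`.
#' The textbook variant reduces to the Thomson shape
#' \eqn{\propto 1 + \cos^2\omega} as \eqn{\epsilon \to 0}; the printed form
#' becomes isotropic there (its last term contributes \eqn{\sin^2\omega}
#' even without recoil). Both are symmetric about \eqn{\pi/2} in that limit
#' and favour forward scattering for \eqn{\epsilon > 0}.
#'
#' @param omega scattering angle(s), radians, in `(0, pi]`.
#' @param params a [physics_params()] object.
#' @param variant `"printed"` (default) or `"textbook"`; see Details.
#' @return Strictly positive angular weight(s), per steradian scale.
#' @export
klein_nishina <- function(omega, params = physics_params(),
                          variant = c("printed", "textbook")) {
  variant <- match.arg(variant)
  .check_omega(omega, open_lower = TRUE)
  eps <- params$epsilon
  d <- 1 + eps * (1 - cos(omega))
  last <- switch(variant,
                 printed  = 1 - cos(omega)^2,
                 textbook = eps^2 * (1 - cos(omega))^2)
  pi * params$re_cm^2 * (1 / (2 * pi)) * d^-2 * (1 + cos(omega)^2 + last / d)
}

#' Compton kinematic factor
#'
#' The multiplicative angular weight applied to a whole projection at fixed
#' scattering angle: \eqn{K(\omega) = \pi r_e^2 n_e \mathcal{P}(\omega)}. The
#' same expression is used in two and in three dimensions (in 2D the electron
#' density is the per-area restriction of its volume value; the numerical
#' value supplied in `params` is used as is).
#'
#' @inheritParams klein_nishina
#' @param dims 2 or 3; retained for interface clarity, the weight is the same.
#' @return Positive weight(s), proportional to [klein_nishina()].
#' @export
kinematic_factor <- function(omega, params = physics_params(), dims = 3,
                             variant = c("printed", "textbook")) {
  stopifnot(dims %in% c(2, 3))
  pi * params$re_cm^2 * params$ne_per_cm3 *
    klein_nishina(omega, params, match.arg(variant))
}
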