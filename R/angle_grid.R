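#' Scattering-angle grid
#'
#' An ordered grid of Compton scattering angles \eqn{\omega} together with the
#' derived quantities every projector needs: \eqn{t = \tan\omega} and the
#' scattered energies \eqn{E(\omega)}. The angles play the role of the
#' rotation angle of a conventional SPECT acquisition: each angle corresponds
#' to one detector energy window, so the grid is the "energy axis" of the
#' sinogram. Bin edges are carried along so that binned forward projectors and
#' point-sampled inversions refer to the same partition of the angular range.
#'
#' @param omegas strictly increasing scattering angles, radians, each in
#'   `(0, pi)`. `pi/2` is excluded (where `tan` diverges) unless
#'   `allow_right_angle = TRUE`.
#' @param E0_keV source energy used to derive the energy axis.
#' @param edges optional bin edges, length `length(omegas) + 1`, strictly
#'   increasing and bracketing the angles; defaults to midpoints.
#' @param allow_right_angle keep an angle exactly at `pi/2` (2D V-line grids
#'   never contain it; 3D cone grids must not).
#' @return An object of class `scatter_angle_grid`: list with `omegas`, `ts`,
#'   `energies`, `edges`, `E0_keV`.
#' @seealso [angle_grid_uniform()], [angle_grid_exp_t()], [angle_grid_vline()]
#' @export
scatter_angle_grid <- function(omegas, E0_keV = 140, edges = NULL,
                               allow_right_angle = FALSE) {
  stopifnot(is.numeric(omegas), length(omegas) >= 1L)
  if (is.unsorted(omegas, strictly = TRUE))
    stop("'omegas' must be strictly increasing", call. = FALSE)
  if (any(omegas <= 0) || any(omegas >= pi))
    stop("'omegas' must lie strictly inside (0, pi)", call. = FALSE)
  if (!allow_right_angle && any(abs(omegas - pi / 2) < 1e-12))
    stop("'omegas' may not contain pi/2 (tan omega diverges there)", call. = FALSE)
  if (is.null(edges)) {
    mid <- (omegas[-1] + omegas[-length(omegas)]) / 2
    d1 <- if (length(omegas) > 1) omegas[2] - omegas[1] else 0.01
    dn <- if (length(omegas) > 1) diff(utils::tail(omegas, 2)) else 0.01
    edges <- c(max(omegas[1] - d1 / 2, .Machine$double.eps), mid,
               min(omegas[length(omegas)] + dn / 2, pi))
  }
  stopifnot(length(edges) == length(omegas) + 1L, !is.unsorted(edges, strictly = TRUE))
  structure(list(
    omegas   = omegas,
    ts       = tan(omegas),
    energies = scattered_energy(E0_keV, omegas),
    edges    = edges,
    E0_keV   = E0_keV,
    guard    = 0        # half-width of the event-exclusion band around pi/2
  ), class = "scatter_angle_grid")
}

#' @export
print.scatter_angle_grid <- function(x, ...) {
  n <- length(x$omegas)
  cat(sprintf("Scattering-angle grid: %d angles in [%.3f, %.3f] rad (%.1f..%.1f deg)\n",
              n, x$omegas[1], x$omegas[n], x$omegas[1] * 180 / pi, x$omegas[n] * 180 / pi))
  cat(sprintf("  energies %.3f..%.3f keV at E0 = %g keV\n",
              x$energies[n], x$energies[1], x$E0_keV))
  invisible(x)
}

#' @export
length.scatter_angle_grid <- function(x) length(x$omegas)

#' Uniform scattering-angle grid
#'
#' Angles at bin centres of a uniform partition of `[omega_min, omega_max]`.
#'
#' @param omega_min,omega_max angular range, radians.
#' @param n number of angles.
#' @param E0_keV source energy, keV.
#' @return A [scatter_angle_grid()].
#' @export
angle_grid_uniform <- function(omega_min, omega_max, n, E0_keV = 140) {
  stopifnot(omega_min > 0, omega_max < pi, omega_max > omega_min, n >= 1)
  edges <- seq(omega_min, omega_max, length.out = n + 1)
  scatter_angle_grid((edges[-1] + edges[-(n + 1)]) / 2, E0_keV, edges = edges)
}

#' V-line scattering-angle grid at a fixed angular step
#'
#' The 2D acquisition grid: angles `k * domega` for `k = 1, ..,
#' floor(omega_max / domega)`. With the reference step `domega = 0.005` rad
#' over a quarter-turn range this yields exactly 314 projections.
#'
#' @param domega angular sampling step, radians.
#' @param omega_max upper end of the range (exclusive of `pi/2` issues since
#'   the last angle is `<= omega_max`), radians; default a quarter turn.
#' @param E0_keV source energy, keV.
#' @return A [scatter_angle_grid()] whose angles stay below `pi/2`.
#' @examples
#' length(angle_grid_vline(0.005))  # 314
#' @export
angle_grid_vline <- function(domega = 0.005, omega_max = pi / 2, E0_keV = 140) {
  stopifnot(domega > 0, omega_max <= pi / 2 + 1e-12)
  n <- floor(omega_max / domega)
  om <- domega * seq_len(n)
  om <- om[om < pi / 2]  # tan must stay finite
  scatter_angle_grid(om, E0_keV,
                     edges = c(om - domega / 2, om[length(om)] + domega / 2),
                     allow_right_angle = FALSE)
}

#' Exponentially sampled tangent grid for the 3D cone transform
#'
#' Builds the two-branch grid the Fourier-Bessel inversion expects:
#' \eqn{|t| = |\tan\omega|} is sampled exponentially on each side of
#' \eqn{\omega = \pi/2}, which concentrates angles near the ends of the range
#' (weakly scattered and back-scattered photons, carrying the high axial
#' frequencies) while keeping the node count modest near \eqn{\pi/2} where the
#' Bessel kernel oscillates slowly. A guard band around \eqn{\pi/2} is always
#' excluded.
#'
#' @param omega_min_deg,omega_max_deg angular range, degrees (default the
#'   reference acquisition 5..175).
#' @param n_per_branch number of angles on each side of 90 degrees.
#' @param guard_deg half-width of the excluded band around 90 degrees.
#' @param E0_keV source energy, keV.
#' @return A [scatter_angle_grid()] with geometric spacing in `|tan(omega)|`.
#' @export
angle_grid_exp_t <- function(omega_min_deg = 5, omega_max_deg = 175,
                             n_per_branch = 160, guard_deg = 1, E0_keV = 140) {
  stopifnot(omega_min_deg > 0, omega_max_deg < 180,
            omega_min_deg < 90 - guard_deg, omega_max_deg > 90 + guard_deg,
            guard_deg > 0, n_per_branch >= 2)
  to_rad <- pi / 180
  t_lo <- tan(omega_min_deg * to_rad)
  t_hi <- tan((90 - guard_deg) * to_rad)
  t_fwd <- exp(seq(log(t_lo), log(t_hi), length.out = n_per_branch))
  # backward branch: |t| from tan(180 - omega_max) up to the guard
  t_lo_b <- tan((180 - omega_max_deg) * to_rad)
  t_bwd <- exp(seq(log(t_lo_b), log(t_hi), length.out = n_per_branch))
  om <- sort(c(atan(t_fwd), pi - atan(t_bwd)))
  # geometric-midpoint edges within each branch; scattering events inside
  # the guard band are excluded by the binned projectors (field `guard`)
  fwd <- om[om < pi / 2]
  bwd <- om[om > pi / 2]
  gm <- function(o) {
    t <- tan(o)
    sqrt(t[-1] * t[-length(t)])
  }
  e_fwd <- c(atan(tan(fwd[1])^2 / gm(fwd)[1]), atan(gm(fwd)))
  tb <- abs(tan(bwd))
  gmb <- sqrt(tb[-1] * tb[-length(tb)])
  e_bwd <- c(pi - atan(gmb), pi - atan(tb[length(tb)]^2 / gmb[length(gmb)]))
  # the two branches share a single edge at pi/2; the guard band is covered
  # by the innermost bins (no angle node lies inside it)
  g <- scatter_angle_grid(om, E0_keV, edges = sort(c(e_fwd, pi / 2, e_bwd)))
  g$guard <- guard_deg * to_rad
  g
}

#' Scattering-angle grid induced by an energy binning
#'
#' Partitions the detected-energy band `[E0/(1+2 eps) .. E0]` (intersected
#' with an angular range) into bins of width `dE_keV` and maps bin centres to
#' scattering angles. Because the energy-angle map is nonlinear the induced
#' angular grid is non-uniform: a fixed energy resolution samples densely
#' around \eqn{\omega = \pi/2}.
#'
#' @param params a [physics_params()] object.
#' @param dE_keV energy bin width, keV.
#' @param omega_min,omega_max angular range to cover, radians.
#' @param guard half-width of the excluded band around `pi/2`, radians.
#' @return A [scatter_angle_grid()]; attribute `energy_edges` holds the bin
#'   edges in keV.
#' @export
angle_grid_from_energy <- function(params, dE_keV = 0.5,
                                   omega_min = 5 * pi / 180,
                                   omega_max = 175 * pi / 180,
                                   guard = pi / 180) {
  stopifnot(dE_keV > 0)
  E_hi <- scattered_energy(params$E0_keV, omega_min)
  E_lo <- scattered_energy(params$E0_keV, omega_max)
  if (dE_keV >= E_hi - E_lo)
    stop("'dE_keV' is wider than the kinematic energy band of this angle range",
         call. = FALSE)
  edges_E <- seq(E_lo, E_hi, by = dE_keV)
  if (edges_E[length(edges_E)] < E_hi) edges_E <- c(edges_E, E_hi)
  om_edges <- rev(angle_from_energy(params$E0_keV, edges_E))  # increasing in omega
  centres_E <- (edges_E[-1] + edges_E[-length(edges_E)]) / 2
  om <- rev(angle_from_energy(params$E0_keV, centres_E))
  keep <- abs(om - pi / 2) > guard
  g <- scatter_angle_grid(om[keep], params$E0_keV)
  attr(g, "energy_edges") <- edges_E
  g
}
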