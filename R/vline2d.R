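#' V-line sinogram container
#'
#' Scatter projection data of the 2D modality: a matrix indexed by detector
#' abscissa `zeta` (rows) and scattering angle (columns).
#'
#' @param values numeric matrix, `length(zeta) x length(angles)`.
#' @param zeta detector abscissas, mm, uniformly spaced.
#' @param angles a [scatter_angle_grid()] with all angles below `pi/2`.
#' @param pitch source-grid pitch the data was generated from (mm); used by
#'   the inversions to set the reconstruction grid.
#' @param y_origin y coordinate (mm) of the first reconstruction row.
#' @param ny number of reconstruction rows.
#' @return An object of class `v_sinogram`.
#' @export
v_sinogram <- function(values, zeta, angles, pitch = 1, y_origin = pitch / 2,
                       ny = nrow(values)) {
  values <- as.matrix(values)
  stopifnot(inherits(angles, "scatter_angle_grid"),
            nrow(values) == length(zeta),
            ncol(values) == length(angles$omegas))
  if (any(!is.finite(values))) stop("sinogram values must be finite", call. = FALSE)
  if (any(angles$omegas >= pi / 2))
    stop("V-line data requires scattering angles below pi/2", call. = FALSE)
  dz <- diff(zeta)
  if (length(dz) && max(abs(dz - dz[1])) > 1e-9 * abs(dz[1]))
    stop("'zeta' must be uniformly spaced", call. = FALSE)
  structure(list(values = values, zeta = zeta, angles = angles,
                 pitch = pitch, y_origin = y_origin, ny = ny),
            class = "v_sinogram")
}

#' @export
print.v_sinogram <- function(x, ...) {
  cat(sprintf("V-line sinogram: %d detector positions x %d angles\n",
              nrow(x$values), ncol(x$values)))
  print(x$angles)
  invisible(x)
}

# Filon-trapezoidal weights for oscillatory cosine integrals: returns the
# matrix M with sum_k M[i, k] g(tau_k) = int g(tau) cos(a_i tau) dtau for g
# piecewise linear on the (possibly nonuniform) nodes tau. The cosine is
# integrated exactly on each interval, so undersampled oscillation attenuates
# the data instead of aliasing it.
.filon_cos_matrix <- function(a, tau, tcap = NULL, tmin = 0) {
  K <- length(tau)
  na <- length(a)
  M <- matrix(0, na, K)
  if (K < 2L) return(M)
  if (is.null(tcap)) tcap <- rep(Inf, na)
  t0 <- tau[-K]; t1 <- tau[-1]
  d <- t1 - t0
  T0 <- matrix(t0, na, K - 1, byrow = TRUE)
  E0 <- pmax(T0, tmin)
  E1 <- pmin(matrix(t1, na, K - 1, byrow = TRUE), tcap)   # row-wise clip
  act <- E1 > E0
  dd <- pmax(E1 - E0, 0)
  m2 <- (E0 + E1) / 2
  Dfull <- matrix(d, na, K - 1, byrow = TRUE)
  small <- abs(a) < 1e-12
  A <- ifelse(small, 1, a)   # placeholder, small rows overwritten below
  sh <- sin(A * dd / 2)
  S <- 2 * cos(A * m2) * sh / A
  # Q = int_{E0}^{E1} (tau - t0) cos(a tau) dtau
  Q <- ((E1 - T0) * sin(A * E1) - (E0 - T0) * sin(A * E0)) / A -
    2 * sin(A * m2) * sh / (A * A)
  Tt <- Q / Dfull
  if (any(small)) {
    S[small, ]  <- dd[small, , drop = FALSE]
    Tt[small, ] <- (dd * (m2 - T0))[small, , drop = FALSE] / Dfull[small, , drop = FALSE]
  }
  S[!act] <- 0; Tt[!act] <- 0
  M[, -K] <- M[, -K] + (S - Tt)
  M[, -1] <- M[, -1] + Tt
  M
}

# Spectral cosine back-projection over tau: returns the complex spectrum
# H(u, y) (P x ny) of  2 |u| y int_{tmin}^{...} cos(2 pi u y tau) D(u, tau)
# dtau  with Filon quadrature on the tau grid. Two caps bound the integral:
# the closure cap 1/(2 u dy) (beyond it the kernel outruns the y grid; on the
# half-integer grid the sharp cap makes the discrete closure exact) and an
# optional aperture cap per row.
.spectral_vbp <- function(Dk, P, dzeta, tau, y, pitch, aperture = Inf,
                          tmin = 0) {
  ny <- length(y)
  iu <- 1:(P %/% 2 + 1)
  upos <- (iu - 1) / (P * dzeta)
  H <- matrix(0 + 0i, P, ny)
  tcap <- ifelse(upos > 0, 1 / (2 * upos * pitch), Inf)
  for (q in seq_len(ny)) {
    W <- .filon_cos_matrix(2 * pi * upos * y[q], tau,
                           tcap = pmin(tcap, aperture / y[q]), tmin = tmin)
    H[iu, q] <- 2 * upos * y[q] * rowSums(W * Dk[iu, , drop = FALSE])
  }
  H[P:(P %/% 2 + 2), ] <- Conj(H[2:(P %/% 2), ])
  H
}

# Repair of the aperture-limited low detector frequencies. The zero frequency
# is indeterminate in the inversion formula (its prefactor |u| vanishes) and
# the few lowest |u| modes would need V arms far beyond any finite detector;
# both are restored from the compact-support assumption: for each
# reconstruction row the coefficients of the lowest-frequency basis functions
# are re-fitted by least squares so that the row vanishes on the region known
# to hold no activity (everything outside `support`, by default the central
# `1 - 2 * margin_frac` stretch of the detector).
.repair_low_modes <- function(hr, sinogram, P, dzeta, margin_frac,
                              n_modes = NULL) {
  nz <- nrow(hr)
  zeta <- sinogram$zeta
  supp <- attr(sinogram, "x_support")
  if (is.null(supp)) {
    w <- margin_frac * (max(zeta) - min(zeta))
    supp <- c(min(zeta) + w, max(zeta) - w)
  }
  empty <- which(zeta < supp[1] - 2 * dzeta | zeta > supp[2] + 2 * dzeta)
  if (length(empty) < 8L) {  # no usable margin: only anchor the mean
    return(sweep(hr, 2, colMeans(hr)))
  }
  if (is.null(n_modes))
    n_modes <- if (isTRUE(attr(sinogram, "periodic"))) 0L else 2L
  # smooth low-order basis over the detector span; a low-order polynomial
  # spans the aperture-broken modes and stays well conditioned. With periodic
  # sampling only the zero frequency is indeterminate (constant per row).
  X <- if (n_modes >= 1L) cbind(1, stats::poly(zeta, degree = n_modes))
       else matrix(1, length(zeta), 1)
  qe <- qr(X[empty, , drop = FALSE])
  coefs <- qr.coef(qe, hr[empty, , drop = FALSE])
  coefs[is.na(coefs)] <- 0
  hr - X %*% coefs
}

# Internal smeared-map container: like an activity map but allowed negative.
smeared_map <- function(values, pitch, origin) {
  structure(as.matrix(values), pitch = rep_len(pitch, 2),
            origin = rep_len(origin, 2), class = "smeared_map")
}

#' @export
print.smeared_map <- function(x, ...) {
  cat(sprintf("Smeared map h(x, y): %d x %d, values in [%.4g, %.4g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

.check_support_above_detector <- function(f) {
  y <- map_axis(f, 2)
  if (min(y) <= 0)
    stop("activity support must lie strictly above the detector line y = 0 ",
         "(the 1/eta photometric factor is undefined at the detector)",
         call. = FALSE)
  invisible(f)
}

# Generic V-line projector of a sampled field with the dr/r measure.
#
# vals: Nx x Ny matrix of a field sampled at x = x0 + (i-1)*px (uniform) and
# strictly positive heights y = y0 + (m-1)*py. Substituting y = r cos(omega)
# in the slant integral gives dr/r = dy/y, so the projector sums over the
# field's own rows,
#   sum_m (py / y_m) * [vals(zeta + y_m tau, y_m) + vals(zeta - y_m tau, y_m)],
# with tau = tan(omega) and linear interpolation along x only (zero outside,
# or wrapped when `periodic`). The slant nodes r_m = y_m / cos(omega) are
# midpoint nodes of step py / cos(omega), so the quadrature never touches the
# vertex singularity at r = 0.
.v_project <- function(vals, x0, px, y0, py, zeta, omegas, dr = py,
                       periodic = FALSE) {
  nx <- nrow(vals); ny <- ncol(vals)
  nz <- length(zeta)
  y <- y0 + (seq_len(ny) - 1) * py
  keep <- which(y > py / 4)   # guard against a row sitting on the detector
  out <- matrix(0, nz, length(omegas))
  wq <- py / y[keep]
  V <- vals[, keep, drop = FALSE]
  for (k in seq_along(omegas)) {
    tauk <- tan(omegas[k])
    acc <- numeric(nz)
    for (sgn in c(1, -1)) {
      xf <- (outer(zeta, sgn * tauk * y[keep], `+`) - x0) / px  # nz x |keep|
      ilo <- floor(xf); wx <- xf - ilo
      base <- (col(xf) - 1L) * nx
      if (periodic) {
        v1 <- V[(ilo %% nx) + 1L + base]
        v2 <- V[((ilo + 1L) %% nx) + 1L + base]
      } else {
        glo <- ilo + 1L
        v1 <- ifelse(glo >= 1 & glo <= nx, V[pmin(pmax(glo, 1L), nx) + base], 0)
        v2 <- ifelse(glo + 1L >= 1 & glo + 1L <= nx,
                     V[pmin(pmax(glo + 1L, 1L), nx) + base], 0)
      }
      acc <- acc + as.numeric((v1 * (1 - wx) + v2 * wx) %*% wq)
    }
    out[, k] <- acc
  }
  out
}

#' Compounded V-line Radon transform (forward projector)
#'
#' Projects a 2D activity map onto scatter data
#' \deqn{\hat f(\zeta, \omega) = K^*(\omega) \int_0^\infty \frac{d\eta}{\eta}
#'   \int_0^\infty \frac{dr}{r}\,
#'   [\, f(\zeta + r\sin\omega,\ \eta + r\cos\omega) +
#'       f(\zeta - r\sin\omega,\ \eta + r\cos\omega) \,]}
#' for every detector abscissa \eqn{\zeta} and scattering angle. The vertex of
#' the "V" sits at height \eqn{\eta} above the detector point (weight
#' \eqn{1/\eta}, the 2D photometric propagation factor) and the two half-lines
#' climb at angle \eqn{\omega} from the vertical (weight \eqn{1/r}).
#'
#' Both singular integrals are evaluated by midpoint-type rules that never
#' touch their singular endpoints: the vertex-height integral uses nodes
#' `eta = (j + 1/2) * pitch` (realized by [smear_eta()]), and the slant
#' integral is taken over the grid's own rows via the substitution
#' `y = r cos(omega)` (so `dr/r = dy/y`), with linear interpolation along the
#' detector direction only. The result is numerically identical to the direct
#' double Riemann sum over `(r, eta)` with those node sets.
#'
#' With `periodic = TRUE` the detector is laterally periodic: V arms leaving
#' one edge re-enter at the other. This matches the discrete Fourier model
#' that [invert_vlrt()] inverts exactly and is the recommended mode for
#' studying the inversion itself; a finite (truncated) detector is the
#' physical acquisition.
#'
#' @param f a 2D [activity_map()] supported strictly above `y = 0`.
#' @param angles a [scatter_angle_grid()] with angles in `(0, pi/2)`.
#' @param zeta detector abscissas, mm; defaults to the x-axis of `f`. For a
#'   wider detector supply a uniform grid with the same pitch.
#' @param params a [physics_params()] supplying the kinematic factor
#'   \eqn{K^*(\omega)}.
#' @param periodic logical: laterally periodic detector (see Details).
#'   Requires `zeta` to be pitch-aligned with the map's x grid.
#' @return A [v_sinogram()].
#' @export
forward_cvlrt <- function(f, angles, zeta = NULL, params = physics_params(),
                          periodic = FALSE) {
  stopifnot(inherits(f, "activity_map"), length(dim(f)) == 2L,
            inherits(angles, "scatter_angle_grid"))
  if (any(angles$omegas >= pi / 2))
    stop("V-line projection requires omega < pi/2", call. = FALSE)
  .check_support_above_detector(f)
  px <- map_pitch(f)[1]; py <- map_pitch(f)[2]
  x0 <- map_origin(f)[1]; y0 <- map_origin(f)[2]
  if (is.null(zeta)) zeta <- map_axis(f, 1)
  fv <- .vals(f)
  hm <- unclass(smear_eta(f))
  attributes(hm) <- list(dim = dim(hm))
  if (periodic) {
    # embed the field on the detector grid so arms wrap consistently
    if (length(zeta) < nrow(hm))
      stop("periodic projection needs a detector at least as wide as the map",
           call. = FALSE)
    emb <- matrix(0, length(zeta), ncol(hm))
    i0 <- round((x0 - zeta[1]) / px)
    emb[i0 + seq_len(nrow(hm)), ] <- hm
    raw <- .v_project(emb, zeta[1], px, y0, py, zeta, angles$omegas,
                      periodic = TRUE)
  } else {
    raw <- .v_project(hm, x0, px, y0, py, zeta, angles$omegas)
  }
  Kst <- kinematic_factor(angles$omegas, params, dims = 2)
  s <- v_sinogram(sweep(raw, 2, Kst, `*`), zeta, angles,
                  pitch = py, y_origin = y0, ny = ncol(fv))
  attr(s, "x_support") <- range(map_axis(f, 1))
  attr(s, "periodic") <- periodic
  s
}

# Plain V-line Radon transform of an already-smeared field h (no kinematic
# factor, no eta smear): the operator the analytic back-projection inverts.
# h: matrix with x origin x0/pitch px and y rows at y0 + (m-1)*py.
.vlrt_forward <- function(h, x0, px, y0, py, zeta, omegas, dr = py,
                          periodic = FALSE) {
  .v_project(h, x0, px, y0, py, zeta, omegas, dr, periodic = periodic)
}

#' Photometric smear along the vertical axis
#'
#' The first factor of the two-step 2D model:
#' \eqn{h(x, y) = \int_0^\infty \frac{d\eta}{\eta} f(x, \eta + y)}, evaluated
#' by the same midpoint rule as [forward_cvlrt()] (nodes
#' `eta = (j + 1/2) * pitch`). The smear is one-sided: voxels only contribute
#' to rows below them, and `h` vanishes above the top of the support.
#'
#' @param f a 2D [activity_map()] supported strictly above `y = 0`.
#' @return A `smeared_map` on the grid of `f`.
#' @export
smear_eta <- function(f) {
  stopifnot(inherits(f, "activity_map"), length(dim(f)) == 2L)
  .check_support_above_detector(f)
  fv <- .vals(f)
  py <- map_pitch(f)[2]
  ny <- ncol(fv)
  # midpoint nodes: h(y_q) = sum_j f(x, y_q + (j+1/2) py) / (j+1/2); the
  # half-offset samples are bilinear (here: two-point) averages of f rows
  W <- matrix(0, ny, ny)
  for (q in seq_len(ny)) {
    j <- 0:(ny - q)     # sample between rows q+j and q+j+1
    W[cbind(pmin(q + j, ny), q)] <- W[cbind(pmin(q + j, ny), q)] + 0.5 / (j + 0.5)
    jj <- j[q + j + 1 <= ny]
    if (length(jj))
      W[cbind(q + jj + 1, q)] <- W[cbind(q + jj + 1, q)] + 0.5 / (jj + 0.5)
  }
  smeared_map(fv %*% W, map_pitch(f), map_origin(f))
}

# One-sided kernel of the discrete midpoint eta-smear: offsets 0..(n-1) in
# grid rows, kappa[m+1] = weight of f at m rows above the evaluation row.
.eta_smear_kernel <- function(n) {
  kappa <- numeric(n + 1L)
  j <- 0:(n - 1L)
  w <- 1 / (j + 0.5)
  kappa[j + 1L] <- kappa[j + 1L] + 0.5 * w
  kappa[j + 2L] <- kappa[j + 2L] + 0.5 * w
  kappa[seq_len(n)]
}

#' Regularized Fourier symbol of the 1/eta smear
#'
#' The one-sided integral \eqn{\int_0^\infty \frac{d\eta}{\eta}
#' e^{-2\pi i k \eta}} diverges logarithmically at the origin; its Hadamard
#' finite part is \eqn{-[\log 2\pi|k| + \gamma] - i\frac{\pi}{2}\,
#' \mathrm{sgn}\,k} with \eqn{\gamma} Euler's constant. This function returns
#' that finite part; it is the scale-free idealization of the discrete smear
#' symbol (which carries an extra `log(pitch)`-type regularization constant).
#'
#' @param k frequencies, cycles/mm (nonzero).
#' @return Complex filter values.
#' @seealso [euler_gamma_from_eta_integral()] for a numerical verification of
#'   the constant.
#' @export
eta_fourier_symbol <- function(k) {
  g <- scatter_constants$euler_gamma
  ifelse(k == 0, NA_complex_,
         -(log(2 * pi * abs(k)) + g) - (0+1i) * (pi / 2) * sign(k))
}

#' Recover Euler's constant from the regularized 1/eta Fourier integral
#'
#' Evaluates \eqn{-\mathrm{Re}\int_0^\infty \frac{d\eta}{\eta}
#' e^{-2\pi i k \eta} - \log 2\pi|k|} by adaptive quadrature of the
#' convergent rearrangement
#' \eqn{\int_0^1 \frac{\cos(a\eta) - 1}{\eta} d\eta +
#'      \int_1^\infty \frac{\cos(a\eta)}{\eta} d\eta + \log a} with
#' \eqn{a = 2\pi|k|}, which equals \eqn{\gamma} for every `k != 0`.
#'
#' @param k any nonzero frequency (the result does not depend on it).
#' @param rel_tol quadrature tolerance.
#' @return A numerical estimate of Euler's constant.
#' @export
euler_gamma_from_eta_integral <- function(k = 1 / (2 * pi), rel_tol = 1e-12) {
  stopifnot(k != 0)
  a <- 2 * pi * abs(k)
  i1 <- stats::integrate(function(e) (cos(a * e) - 1) / e, 0, 1,
                         rel.tol = rel_tol, abs.tol = rel_tol)$value
  # tail int_1^Inf cos(a e)/e de: adaptive quadrature to a large cutoff X,
  # then the asymptotic expansion of the remaining oscillatory integral
  # (integration by parts: sin(x)(1/x - 2/x^3 + 24/x^5) - cos(x)(1/x^2 -
  # 6/x^4), error O(x^-6))
  X <- 200
  tail <- 0
  for (e0 in seq(1, X - 1, by = 10))
    tail <- tail + stats::integrate(function(e) cos(a * e) / e, e0,
                                    min(e0 + 10, X),
                                    rel.tol = rel_tol, abs.tol = 1e-14,
                                    subdivisions = 500L)$value
  x <- a * X
  tail <- tail - sin(x) * (1 / x - 2 / x^3 + 24 / x^5) +
    cos(x) * (1 / x^2 - 6 / x^4)
  -(i1 + tail) - log(a)
}

#' Deconvolve the 1/eta smear
#'
#' Second step of the 2D inversion: given \eqn{h(x, y)}, recover `f`. With
#' `filter = "matched"` (default) the operator inverted is exactly the
#' discrete midpoint smear that [smear_eta()] and [forward_cvlrt()] apply: on
#' the grid this is an upper-triangular Toeplitz correlation along `y` (each
#' row of `h` collects activity from the rows above it) with unit diagonal,
#' and it is inverted exactly by back-substitution, making the pair an exact
#' inverse. With `filter = "analytic"` the recovery follows the Fourier
#' route: the transform along `y` is divided by the scale-free finite-part
#' symbol \eqn{-[\log 2\pi|k| + \gamma - i\frac{\pi}{2}\mathrm{sgn}\,k]}
#' (see [eta_fourier_symbol()]); the indeterminate zero frequency is then
#' fixed by requiring zero mean on the known-empty padding above the support
#' (the compact-support assumption). The analytic symbol is the continuum
#' idealization; it differs from the grid operator by a `log(pitch)`-type
#' regularization constant, which is why the matched route is the default for
#' round trips on gridded data.
#'
#' @param h a `smeared_map` (or plain matrix with `pitch`/`origin` attributes).
#' @param filter `"matched"` or `"analytic"`.
#' @param pad zero-padding factor along y for the analytic route (`>= 2`).
#' @param lambda Tikhonov weight (second-difference penalty) for the matched
#'   route; `0` gives the exact triangular inverse. See Details.
#' @return A 2D [activity_map()]; negative values are clipped to zero, the
#'   unclipped field is kept in attribute `raw`.
#' @export
deconvolve_eta <- function(h, filter = c("matched", "analytic"), pad = 4,
                           lambda = 0.05) {
  filter <- match.arg(filter)
  stopifnot(pad >= 2, lambda >= 0)
  hv <- as.matrix(unclass(h))
  pitch <- attr(h, "pitch"); origin <- attr(h, "origin")
  if (is.null(pitch)) { pitch <- c(1, 1); origin <- c(0.5, 0.5) }
  ny <- ncol(hv)
  if (filter == "matched") {
    kap <- .eta_smear_kernel(ny)
    U <- matrix(0, ny, ny)
    idx <- which(col(U) - row(U) >= 0)
    U[idx] <- kap[col(U)[idx] - row(U)[idx] + 1L]
    if (lambda <= 0) {
      out <- t(backsolve(U, t(hv)))
    } else {
      # the smear annihilates the grid-Nyquist band (its kernel is a
      # two-point average), so the plain triangular inverse amplifies any
      # Nyquist-band error in h without bound; a small roughness penalty
      # (second differences) restores stability at negligible bias for
      # smooth fields
      L <- diff(diag(ny), differences = 2)
      A <- crossprod(U) + lambda^2 * crossprod(L)
      out <- t(solve(A, crossprod(U, t(hv))))
    }
  } else {
    P <- stats::nextn(pad * ny, 2)
    Hp <- cbind(hv, matrix(0, nrow(hv), P - ny))
    Hk <- t(stats::mvfft(t(Hp)))        # FFT along y
    k <- c(0:(P %/% 2), -(P - P %/% 2 - 1):-1)[1:P] / (P * pitch[2])
    sym <- Conj(eta_fourier_symbol(k)) * pitch[2]
    sym[1] <- Inf                       # DC removed, restored below
    Fk <- sweep(Hk, 2, sym, `/`)
    Fk[, 1] <- 0
    fr <- Re(t(stats::mvfft(t(Fk), inverse = TRUE))) / P
    empty <- (ny + 1):min(P, ny + max(2, ny %/% 2))
    fr <- fr - rowMeans(fr[, empty, drop = FALSE])
    out <- fr[, seq_len(ny), drop = FALSE]
  }
  res <- activity_map(pmax(out, 0), pitch = pitch, origin = origin)
  attr(res, "raw") <- out
  res
}

#' Analytic inversion of the V-line Radon transform
#'
#' Recovers the smeared field `h` from its V-line projections (kinematic
#' factor already divided out). Per detector frequency `u` the formula is the
#' filtered cosine back-projection over \eqn{\tau = \tan\omega}
#' \deqn{\tilde h(u, y) = 2\,|u|\, y \int_0^\infty d\tau\,
#'   \cos(2\pi u y \tau)\, \hat f(u, \tau),}
#' the spectral form of the principal-value-filtered derivative
#' back-projection (the \eqn{|u|} factor combines \eqn{\partial_\zeta} with
#' the Hilbert-type principal-value kernel). The `tau` integral is evaluated
#' by Filon-type quadrature: the oscillatory kernel \eqn{\cos(2\pi u y \tau)}
#' is integrated exactly against a piecewise-linear interpolant of the data,
#' so the strongly scattered angles (large \eqn{\tau}, where the angular grid
#' no longer resolves the kernel oscillation) are attenuated gracefully
#' instead of aliasing. The zero frequency is fixed per row by requiring zero
#' mean on the empty lateral margins.
#'
#' Two sampling limits bound the usable `tau` range. First, beyond
#' `tau = 1/(2 u dy)` the kernel oscillates faster than the reconstruction
#' grid resolves (`dy` the row spacing); on the half-integer row grid a sharp
#' cap there makes the discrete closure exact. Second, a finite detector only
#' captures the V arms out to `tau` of about `aperture / y` (`aperture` the
#' lateral margin between the detector edge and the object): beyond that the
#' data is truncated and integrating it would inject aperture artifacts, so
#' the integral is capped there as well. The second cap is the physical
#' resolution limit of a finite camera.
#'
#' @param sinogram a [v_sinogram()] of VLRT data (no kinematic factor).
#' @param pad zero-padding factor along `zeta`.
#' @param margin_frac fraction of the lateral extent assumed activity-free,
#'   used to anchor the per-row DC.
#' @param aperture lateral aperture margin, mm: the distance from the edge of
#'   the object region to the detector edge. Defaults to one third of the
#'   detector span.
#' @return A `smeared_map` on the reconstruction grid recorded in the
#'   sinogram.
#' @export
invert_vlrt <- function(sinogram, pad = 4, margin_frac = 0.1, aperture = NULL,
                        n_modes = NULL) {
  stopifnot(inherits(sinogram, "v_sinogram"))
  ang <- sinogram$angles
  if (length(ang$omegas) < 2L)
    stop("at least two scattering angles are required", call. = FALSE)
  D <- sinogram$values
  nz <- nrow(D)
  dzeta <- if (nz > 1) sinogram$zeta[2] - sinogram$zeta[1] else sinogram$pitch
  periodic <- isTRUE(attr(sinogram, "periodic"))
  P <- if (periodic) nz else stats::nextn(pad * nz, 2)
  Dk <- stats::mvfft(rbind(D, matrix(0, P - nz, ncol(D))))  # FFT along zeta
  u <- c(0:(P %/% 2), -(P - P %/% 2 - 1):-1)[1:P] / (P * dzeta)
  tau <- ang$ts
  ny <- sinogram$ny
  y <- sinogram$y_origin + (seq_len(ny) - 1) * sinogram$pitch
  if (is.null(aperture)) aperture <- Inf
  H <- .spectral_vbp(Dk, P, dzeta, tau, y, sinogram$pitch, aperture)
  hr <- Re(stats::mvfft(H, inverse = TRUE)) / P
  hr <- hr[seq_len(nz), , drop = FALSE]
  hr <- .repair_low_modes(hr, sinogram, P, dzeta, margin_frac, n_modes)
  smeared_map(hr, pitch = c(dzeta, sinogram$pitch),
              origin = c(sinogram$zeta[1], sinogram$y_origin))
}

#' Two-step analytic inversion of the compounded V-line transform
#'
#' Divides the kinematic factor out of the data, inverts the V-line Radon
#' transform ([invert_vlrt()]) to recover the smeared field, and deconvolves
#' the 1/eta smear ([deconvolve_eta()]) to recover the activity map.
#'
#' @param sinogram a [v_sinogram()] produced by [forward_cvlrt()].
#' @param params the [physics_params()] used for the forward model.
#' @param filter passed to [deconvolve_eta()].
#' @param pad,margin_frac passed to [invert_vlrt()].
#' @return A 2D [activity_map()].
#' @export
invert_cvlrt <- function(sinogram, params = physics_params(),
                         filter = "matched", pad = 4, margin_frac = 0.1) {
  stopifnot(inherits(sinogram, "v_sinogram"))
  Kst <- kinematic_factor(sinogram$angles$omegas, params, dims = 2)
  s2 <- sinogram
  s2$values <- sweep(sinogram$values, 2, Kst, `/`)
  h <- invert_vlrt(s2, pad = pad, margin_frac = margin_frac)
  deconvolve_eta(h, filter = filter)
}

#' Filtered back-projection inversion of the compounded V-line transform
#'
#' The fast variant of [invert_cvlrt()]: each projection is ramp-filtered
#' (multiplication by `|u|` in the detector frequency domain), back-projected
#' in real space along the two half-lines of its "V" (the projection at angle
#' \eqn{\omega} is read at \eqn{\zeta = x \mp y\tau} with linear
#' interpolation), weighted by `y` and integrated over \eqn{\tau}; the 1/eta
#' smear is then deconvolved as in the analytic route. Mathematically the two
#' routes coincide in the continuum; numerically they differ by the
#' interpolation scheme.
#'
#' @inheritParams invert_cvlrt
#' @return A 2D [activity_map()].
#' @export
fbp_cvlrt <- function(sinogram, params = physics_params(),
                      filter = "matched", pad = 4, margin_frac = 0.1,
                      tau_split = 8) {
  stopifnot(inherits(sinogram, "v_sinogram"))
  ang <- sinogram$angles
  Kst <- kinematic_factor(ang$omegas, params, dims = 2)
  D <- sweep(sinogram$values, 2, Kst, `/`)
  nz <- nrow(D)
  dzeta <- if (nz > 1) sinogram$zeta[2] - sinogram$zeta[1] else sinogram$pitch
  periodic <- isTRUE(attr(sinogram, "periodic"))
  P <- if (periodic) nz else stats::nextn(pad * nz, 2)
  Dk <- stats::mvfft(rbind(D, matrix(0, P - nz, ncol(D))))
  u <- c(0:(P %/% 2), -(P - P %/% 2 - 1):-1)[1:P] / (P * dzeta)
  tau <- ang$ts
  ny <- sinogram$ny
  y <- sinogram$y_origin + (seq_len(ny) - 1) * sinogram$pitch
  x <- sinogram$zeta
  # split the tau integral at a grid node: weakly-to-moderately scattered
  # angles (tau below the split) are back-projected in real space; the
  # strongly scattered tail, whose kernel oscillation the zeta sampling can
  # no longer follow pixel-by-pixel, is integrated spectrally with the same
  # Filon rule as the analytic route
  ks <- max(2L, sum(tau <= tau_split))
  ks <- min(ks, length(tau))
  # ramp filter with a per-projection cutoff: a projection at tan(omega) =
  # tau resolves image frequencies only up to |u| = 1/(2 tau dy) on the row
  # grid, so each column is band-limited there before back-projection
  ramp <- outer(abs(u), tau, function(a, t) a * (a * t <= 1 / (2 * sinogram$pitch)))
  Pf <- Re(stats::mvfft(Dk * ramp, inverse = TRUE)) / P  # filtered projections
  hr <- matrix(0, nz, ny)
  backproject <- function(p, tk, w) {
    for (sgn in c(-1, 1)) {
      Zf <- (outer(x, sgn * y * tk, `+`) - sinogram$zeta[1]) / dzeta
      ilo <- floor(Zf); wx <- Zf - ilo
      if (periodic) {
        g1 <- p[(ilo %% P) + 1]
        g2 <- p[((ilo + 1) %% P) + 1]
      } else {
        g1 <- ifelse(ilo >= 0 & ilo < P, p[pmin(pmax(ilo, 0), P - 1) + 1], 0)
        g2 <- ifelse(ilo + 1 >= 0 & ilo + 1 < P, p[pmin(pmax(ilo + 1, 0), P - 1) + 1], 0)
      }
      hr <<- hr + w * (g1 * (1 - wx) + g2 * wx)
    }
  }
  # real-space part: subdivide each angular interval (interpolating the
  # filtered projections linearly) so the arm argument moves by about half a
  # pixel per substep
  ymax <- max(y)
  for (k in seq_len(ks - 1)) {
    d <- tau[k + 1] - tau[k]
    nsub <- max(1L, ceiling(2 * ymax * d / dzeta))
    for (s in seq_len(nsub)) {
      frac <- (s - 0.5) / nsub
      backproject(Pf[, k] * (1 - frac) + Pf[, k + 1] * frac,
                  tau[k] + frac * d, d / nsub)
    }
  }
  hr <- sweep(hr, 2, y, `*`)
  # spectral tail from the split node onward
  if (ks < length(tau)) {
    Htail <- .spectral_vbp(Dk, P, dzeta, tau, y, sinogram$pitch,
                           tmin = tau[ks])
    hr <- hr + Re(stats::mvfft(Htail, inverse = TRUE))[seq_len(nz), ] / P
  }
  hr <- .repair_low_modes(hr, sinogram, P, dzeta, margin_frac)
  h <- smeared_map(hr, pitch = c(dzeta, sinogram$pitch),
                   origin = c(sinogram$zeta[1], sinogram$y_origin))
  deconvolve_eta(h, filter = filter)
}
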