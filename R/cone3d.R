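#' Detector geometry for the 3D modalities
#'
#' A planar pixel detector in the plane `z = 0` with the scattering medium in
#' `z > 0`. The medium is a rectangular box starting `standoff` mm above the
#' detector plane; scattering vertices exist only inside it.
#'
#' @param n_pixels integer pair `(nx, ny)`.
#' @param pixel_pitch pixel size, mm.
#' @param standoff distance from the detector plane to the nearest face of
#'   the scattering medium, mm.
#' @param medium_depth axial (z) extent of the scattering medium, mm.
#' @param collimated logical: `TRUE` for the collimated geometry (vertices on
#'   the vertical axis through each pixel), `FALSE` for the open geometry.
#' @param periodic logical: laterally periodic sampling (cone rings leaving
#'   one edge re-enter at the other), the model the spectral forward and the
#'   Fourier-Bessel inversion share.
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(n_pixels = c(48, 48), pixel_pitch = 1,
                              standoff = 200, medium_depth = 16,
                              collimated = TRUE, periodic = TRUE) {
  n_pixels <- rep_len(as.integer(n_pixels), 2)
  stopifnot(all(n_pixels > 0), pixel_pitch > 0, standoff > 0, medium_depth > 0)
  structure(list(n_pixels = n_pixels, pixel_pitch = pixel_pitch,
                 standoff = standoff, medium_depth = medium_depth,
                 collimated = collimated, periodic = periodic),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("%s planar detector: %d x %d pixels at %.3g mm, standoff %.4g mm\n",
              if (x$collimated) "Collimated" else "Uncollimated",
              x$n_pixels[1], x$n_pixels[2], x$pixel_pitch, x$standoff))
  invisible(x)
}

#' Cone-sinogram container
#'
#' Energy-indexed scatter projections of the 3D modalities: a 3D array over
#' (detector pixel x, detector pixel y, scattering angle).
#'
#' @param values numeric 3D array `(nx, ny, n_angles)`, finite.
#' @param detector a [detector_geometry()].
#' @param angles a [scatter_angle_grid()].
#' @param map_geom internal list recording the source grid (pitch, z planes,
#'   transverse embedding) so inversions can reconstruct on the same grid.
#' @return An object of class `cone_sinogram`.
#' @export
cone_sinogram <- function(values, detector, angles, map_geom = NULL) {
  stopifnot(length(dim(values)) == 3L,
            inherits(detector, "detector_geometry"),
            inherits(angles, "scatter_angle_grid"),
            dim(values)[3] == length(angles$omegas),
            all(dim(values)[1:2] == detector$n_pixels))
  if (any(!is.finite(values))) stop("sinogram values must be finite", call. = FALSE)
  structure(list(values = values, detector = detector, angles = angles,
                 map_geom = map_geom), class = "cone_sinogram")
}

#' @export
print.cone_sinogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Cone sinogram: %d x %d pixels x %d angles\n", d[1], d[2], d[3]))
  print(x$angles)
  invisible(x)
}

# Geometry helpers -----------------------------------------------------------

# z coordinates of the source planes and the vertex (scattering site) nodes
# for a map embedded in the medium: sources at plane centres, vertices at
# plane boundaries (offset half a pitch), so source-vertex z offsets are
# half-integer multiples of the pitch and never vanish.
.axial_grids <- function(det, nz, dz) {
  l <- det$standoff
  list(z_src = l + (seq_len(nz) - 0.5) * dz,
       z_ver = l + (0:nz) * dz)
}

# embed the transverse (x, y) planes of an activity map centred on the
# detector grid; returns the 3D array (L, L, nz) and the index offset
.embed_transverse <- function(fv, L) {
  nx <- dim(fv)[1]; ny <- dim(fv)[2]; nz <- dim(fv)[3]
  stopifnot(L >= nx, L >= ny)
  off <- c((L - nx) %/% 2, (L - ny) %/% 2)
  emb <- array(0, dim = c(L, L, nz))
  emb[off[1] + seq_len(nx), off[2] + seq_len(ny), ] <- fv
  list(emb = emb, off = off)
}

# attenuation factor along both legs of an event with axial offset sigma at
# tangent t, vertex height z_ver: exp(-mu (SN + ND)), SN = sigma sqrt(1+t^2)
.atten_factor <- function(mu, sigma, t_abs, z_ver) {
  if (mu <= 0) return(1)
  exp(-mu * (sigma * sqrt(1 + t_abs^2) + z_ver))
}

#' Compounded conical Radon transform (collimated forward projector)
#'
#' Maps a 3D activity map to energy-indexed scatter projections on a
#' collimated planar detector. For each detector pixel `D` and scattering
#' angle \eqn{\omega}, activity is integrated over the family of circular
#' cones with vertical axis through `D`, vertex `N` on that axis inside the
#' scattering medium, and half-angle \eqn{\omega} (opening upward for
#' \eqn{\omega < \pi/2}, downward for \eqn{\omega > \pi/2}), with weights:
#' photometric \eqn{1/SN^2} and \eqn{1/ND^2} on the two legs, the
#' Klein-Nishina kinematic factor, and optionally uniform attenuation
#' \eqn{e^{-\mu(SN + ND)}}.
#'
#' Two numerically different evaluations of the same discretization are
#' provided. `method = "binned"` sums voxel-level events, assigning each
#' (source voxel, vertex) pair to the angle bin containing its exact
#' scattering angle; it is identical, term by term, to
#' [brute_force_single_scatter()] and is organized as per-plane ring
#' convolutions for speed. `method = "spectral"` evaluates the transverse
#' ring integral exactly in the Fourier domain (the ring spectrum is the
#' Bessel kernel \eqn{J_0(2\pi q \sigma |\tan\omega|)}), i.e. no angular
#' binning and no transverse discretization error; it is the transform whose
#' analytic inversion [invert_ccrt()] implements, and the two methods
#' converge as the bins shrink.
#'
#' @param f a 3D [activity_map()]; its z extent must fit the medium depth.
#' @param det a [detector_geometry()] with `collimated = TRUE`. The pixel
#'   grid must be at least as large as the map's transverse grid; the map is
#'   centred on it.
#' @param angles a [scatter_angle_grid()] avoiding `pi/2`.
#' @param params a [physics_params()].
#' @param method `"binned"` or `"spectral"` (see Details).
#' @return A [cone_sinogram()].
#' @export
forward_ccrt <- function(f, det, angles, params = physics_params(),
                         method = c("binned", "spectral"), z_oversample = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(f, "activity_map"), length(dim(f)) == 3L,
            inherits(det, "detector_geometry"))
  if (!det$collimated)
    stop("detector is uncollimated: use forward_gccrt()", call. = FALSE)
  pitch <- map_pitch(f)
  if (max(abs(pitch - pitch[1])) > 1e-9)
    stop("forward_ccrt expects cubic voxels", call. = FALSE)
  dz <- pitch[3]
  nz <- dim(f)[3]
  if (nz * dz > det$medium_depth + 1e-9)
    stop("map deeper than the scattering medium", call. = FALSE)
  L <- det$n_pixels[1]
  if (det$n_pixels[1] != det$n_pixels[2])
    stop("collimated projector expects a square pixel grid", call. = FALSE)
  emb <- .embed_transverse(.vals(f), L)
  ax <- .axial_grids(det, nz, dz)
  K <- kinematic_factor(angles$omegas, params)
  nu <- 1 / ax$z_ver^2
  mu <- params$mu_per_mm
  vol_N <- det$pixel_pitch^2 * dz      # vertex volume measure (see gCCRT)
  out <- if (method == "spectral") {
    .ccrt_forward_spectral(emb$emb, ax, angles, K, nu, dz, mu, det,
                           z_oversample)
  } else {
    .ccrt_forward_binned(emb$emb, ax, angles, K, nu, dz, mu, det)
  }
  cone_sinogram(out * vol_N, det, angles,
                map_geom = list(pitch = pitch, nz = nz, off = emb$off,
                                dims = dim(f), vol_N = vol_N))
}

# spectral evaluation: per angle and axial offset, multiply the transverse
# FFT of the nu-weighted plane correlation by the exact ring spectrum J0.
# With z_oversample > 1 the axial quadrature (source planes within each
# voxel, and vertex nodes) is refined by that factor while the phantom stays
# piecewise constant: data generated this way carries genuine
# discretization mismatch with respect to the reconstruction grid, as real
# acquisitions do.
.ccrt_forward_spectral <- function(emb, ax, angles, K, nu, dz, mu, det,
                                   z_oversample = 1L) {
  os <- as.integer(z_oversample)
  L <- dim(emb)[1]; nz <- dim(emb)[3]
  nang <- length(angles$omegas)
  ft <- array(0 + 0i, dim = c(L, L, nz))
  for (i in seq_len(nz)) ft[, , i] <- stats::fft(emb[, , i])
  q <- .freq_radius(L, det$pixel_pitch)
  t_abs <- abs(angles$ts)
  upward <- angles$omegas < pi / 2
  l <- det$standoff
  dzf <- dz / os
  z_src <- l + (seq_len(nz * os) - 0.5) * dzf     # fine source sub-planes
  src_plane <- rep(seq_len(nz), each = os)        # parent voxel plane
  z_ver <- l + (0:(nz * os)) * dzf                # fine vertex nodes
  nuf <- 1 / z_ver^2
  # group (sub-plane, vertex) pairs by |sigma| and branch
  pairs_i <- rep(seq_along(z_src), times = length(z_ver))
  pairs_j <- rep(seq_along(z_ver), each = length(z_src))
  sg_all <- z_src[pairs_i] - z_ver[pairs_j]
  key <- round(abs(sg_all) / dzf * 2)             # half-integer multiples
  out <- array(0, dim = c(L, L, nang))
  for (br in 1:2) {
    sel0 <- if (br == 1) sg_all > 0 else sg_all < 0
    kk <- sort(unique(key[sel0]))
    Pσ <- vector("list", length(kk))
    sgv <- numeric(length(kk))
    zvm <- numeric(length(kk))   # nu-weighted mean vertex height (attenuation)
    for (a in seq_along(kk)) {
      sel <- which(sel0 & key == kk[a])
      sgv[a] <- abs(sg_all[sel[1]])
      acc <- matrix(0 + 0i, L, L)
      wsum <- 0
      for (p in sel) {
        w <- dzf * dzf / dz * nuf[pairs_j[p]] / sgv[a]
        acc <- acc + w * ft[, , src_plane[pairs_i[p]]]
        wsum <- wsum + w
      }
      Pσ[[a]] <- acc
      zvm[a] <- sum(z_ver[pairs_j[sel]] * 1) / length(sel)
    }
    want <- if (br == 1) which(upward) else which(!upward)
    for (k in want) {
      acc <- matrix(0 + 0i, L, L)
      for (a in seq_along(kk)) {
        at <- .atten_factor(mu, sgv[a], t_abs[k], zvm[a])
        acc <- acc + at * besselJ(2 * pi * q * sgv[a] * t_abs[k], 0) * Pσ[[a]]
      }
      out[, , k] <- out[, , k] + Re(stats::fft(acc, inverse = TRUE)) / L^2 *
        (K[k] * sin(angles$omegas[k]) / 2)
    }
  }
  out
}

# binned evaluation: events at voxel centres, each assigned to the angle bin
# containing its exact scattering angle; organized as periodic ring-kernel
# convolutions per axial offset, identical term-by-term to the brute-force
# event sum (up to floating-point summation order).
.ccrt_forward_binned <- function(emb, ax, angles, K, nu, dz, mu, det) {
  L <- dim(emb)[1]; nz <- dim(emb)[3]
  nang <- length(angles$omegas)
  px <- det$pixel_pitch
  edges <- angles$edges
  dwk <- diff(edges)
  ft <- array(0 + 0i, dim = c(L, L, nz))
  for (i in seq_len(nz)) ft[, , i] <- stats::fft(emb[, , i])
  out_sp <- array(0 + 0i, dim = c(L, L, nang))
  # wrapped lattice offsets in FFT order
  cc <- c(0:(L %/% 2), -((L - L %/% 2 - 1):1))[1:L] * px
  RHO <- sqrt(outer(cc^2, cc^2, `+`))
  pair_i <- rep(seq_len(nz), times = nz + 1L)
  pair_j <- rep(0:nz, each = nz)
  sig <- (pair_i - 0.5 - pair_j) * dz      # signed source-vertex z offset
  nu_mu <- nu * exp(-mu * ax$z_ver)        # vertex weight incl. exit leg
  for (s_abs in unique(abs(sig))) {
    for (br in 1:2) {   # 1: source above vertex (omega < pi/2), 2: below
      sel <- which(if (br == 1) abs(sig - s_abs) < 1e-12 else
                     abs(sig + s_abs) < 1e-12)
      if (!length(sel)) next
      Csig <- matrix(0 + 0i, L, L)
      for (p in sel) Csig <- Csig + nu_mu[pair_j[p] + 1L] * ft[, , pair_i[p]]
      theta <- atan2(RHO, s_abs)
      if (br == 2) theta <- pi - theta
      bin <- findInterval(theta, edges)
      bin[RHO == 0 | bin < 1 | bin > nang] <- NA
      guard <- if (is.null(angles$guard)) 0 else angles$guard
      if (guard > 0) bin[abs(theta - pi / 2) < guard] <- NA
      SN <- sqrt(RHO^2 + s_abs^2)
      W <- px^2 * dz / (4 * pi) / SN^3
      if (mu > 0) W <- W * exp(-mu * SN)
      for (b in unique(bin[!is.na(bin)])) {
        km <- matrix(0, L, L)
        m <- which(bin == b)
        km[m] <- W[m] / dwk[b]
        out_sp[, , b] <- out_sp[, , b] + (K[b] * stats::fft(km)) * Csig
      }
    }
  }
  out <- array(0, dim = c(L, L, nang))
  for (k in seq_len(nang))
    out[, , k] <- Re(stats::fft(out_sp[, , k], inverse = TRUE)) / L^2
  out
}

# radial frequency magnitude on the L x L FFT grid, cycles/mm
.freq_radius <- function(L, pitch) {
  fr <- c(0:(L %/% 2), -((L - L %/% 2 - 1):1))[1:L] / (L * pitch)
  sqrt(outer(fr^2, fr^2, `+`))
}

#' Brute-force single-scatter projection (reference oracle)
#'
#' Direct event-level evaluation of the collimated single-scatter model: for
#' every detector pixel, every scattering site on the vertical axis through
#' it, and every source voxel, the exact scattering angle is computed,
#' assigned to its angle bin, and the event weight (isotropic emission,
#' inverse-square propagation on both legs, Klein-Nishina factor, optional
#' uniform attenuation) accumulated. Slow by construction; restricted to
#' grids of at most `32^3` voxels. [forward_ccrt()] with
#' `method = "binned"` reproduces these sums through ring convolutions.
#'
#' @inheritParams forward_ccrt
#' @return A [cone_sinogram()].
#' @export
brute_force_single_scatter <- function(f, det, angles,
                                       params = physics_params()) {
  stopifnot(inherits(f, "activity_map"), length(dim(f)) == 3L)
  if (any(dim(f) > 32L))
    stop("brute-force oracle is limited to grids of at most 32^3 voxels",
         call. = FALSE)
  pitch <- map_pitch(f)
  dz <- pitch[3]
  nz <- dim(f)[3]
  L <- det$n_pixels[1]
  px <- det$pixel_pitch
  emb <- .embed_transverse(.vals(f), L)
  ax <- .axial_grids(det, nz, dz)
  K <- kinematic_factor(angles$omegas, params)
  edges <- angles$edges
  dwk <- diff(edges)
  nang <- length(angles$omegas)
  mu <- params$mu_per_mm
  out <- array(0, dim = c(L, L, nang))
  coords <- seq_len(L) * px          # absolute transverse positions
  vol_N <- px^2 * dz
  fv <- emb$emb
  for (ipx in seq_len(L)) for (ipy in seq_len(L)) {
    dx2 <- (coords - coords[ipx])^2
    dy2 <- (coords - coords[ipy])^2
    R2 <- outer(dx2, dy2, `+`)
    acc <- numeric(nang)
    for (j in seq_along(ax$z_ver)) {
      zv <- ax$z_ver[j]
      for (i in seq_len(nz)) {
        plane <- fv[, , i]
        if (all(plane == 0)) next
        sgn_sig <- ax$z_src[i] - zv
        # same floating-point expression as the ring-kernel path, so that
        # events on bin boundaries land identically
        theta <- if (sgn_sig > 0) atan2(sqrt(R2), sgn_sig) else
          pi - atan2(sqrt(R2), -sgn_sig)
        bin <- findInterval(theta, edges)
        guard <- if (is.null(angles$guard)) 0 else angles$guard
        if (guard > 0) bin[abs(theta - pi / 2) < guard] <- 0L
        ok <- which(R2 > 0 & bin >= 1 & bin <= nang & plane != 0)
        if (!length(ok)) next
        SN <- sqrt(R2[ok] + sgn_sig^2)
        b <- bin[ok]
        w <- plane[ok] * px^2 * dz / (4 * pi) / SN^3 / dwk[b] *
          K[b] * (1 / zv^2) * vol_N
        if (mu > 0) w <- w * exp(-mu * (SN + zv))
        for (u in seq_along(ok)) acc[b[u]] <- acc[b[u]] + w[u]
      }
    }
    out[ipx, ipy, ] <- acc
  }
  cone_sinogram(out, det, angles,
                map_geom = list(pitch = pitch, nz = nz, off = emb$off,
                                dims = dim(f), vol_N = vol_N))
}

#' Point spread function of the collimated cone transform
#'
#' Detector image of a unit point source at a fixed scattering angle. For a
#' source above the scattering medium the image is a superposition of rings
#' of radius \eqn{(z_s - z_N)|\tan\omega|} over the vertex heights
#' \eqn{z_N} in the medium, weighted by the photometric and kinematic
#' factors: rotationally symmetric, with a central hole and an off-centre
#' maximum for \eqn{\omega < \pi/2} -- the "Mexican hat" shape.
#'
#' @param source numeric length-3, source position (x, y, z) in mm; must lie
#'   above the detector plane (and typically above the medium).
#' @param det a [detector_geometry()].
#' @param omega one scattering angle, radians.
#' @param params a [physics_params()].
#' @param n_phi azimuthal quadrature nodes per ring.
#' @return A matrix (`n_pixels`) with the detector response.
#' @export
psf_ccrt <- function(source, det, omega, params = physics_params(),
                     n_phi = 720) {
  stopifnot(length(source) == 3)
  if (source[3] <= 0)
    stop("source must lie above the detector plane", call. = FALSE)
  .check_omega(omega, open_lower = TRUE, open_upper = TRUE)
  L <- det$n_pixels
  px <- det$pixel_pitch
  K <- kinematic_factor(omega, params)
  t_abs <- abs(tan(omega))
  mu <- params$mu_per_mm
  # vertex nodes inside the medium, on the correct side of the source
  zv <- det$standoff + seq(0, det$medium_depth, by = px)
  zv <- if (omega < pi / 2) zv[zv < source[3]] else zv[zv > source[3]]
  img <- matrix(0, L[1], L[2])
  if (!length(zv)) return(img)
  xs <- (seq_len(L[1]) - (L[1] + 1) / 2) * px
  ys <- (seq_len(L[2]) - (L[2] + 1) / 2) * px
  for (z in zv) {
    sg <- abs(source[3] - z)
    rho <- sg * t_abs
    # ring of emission directions hitting the axis at height z: spread the
    # ring over the pixel grid by azimuthal quadrature with bilinear deposit
    phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
    cx <- source[1] + rho * cos(phi)
    cy <- source[2] + rho * sin(phi)
    SN <- sqrt(rho^2 + sg^2)
    # per-node weight: the continuum ring mass K nu volN sin(omega)/(2 sigma)
    # for a unit point source, spread over the azimuthal nodes
    w <- K * (1 / z^2) * (px^2 * px) * sin(omega) / (2 * sg * n_phi)
    if (mu > 0) w <- w * exp(-mu * (SN + z))
    ixf <- (cx - xs[1]) / px; iyf <- (cy - ys[1]) / px
    i0 <- floor(ixf); j0 <- floor(iyf)
    wx <- ixf - i0; wy <- iyf - j0
    for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
      ii <- i0 + 1L + corner[1]; jj <- j0 + 1L + corner[2]
      ww <- w * (if (corner[1]) wx else 1 - wx) * (if (corner[2]) wy else 1 - wy)
      ok <- ii >= 1 & ii <= L[1] & jj >= 1 & jj <= L[2]
      if (any(ok)) {
        idx <- cbind(ii[ok], jj[ok])
        for (u in seq_len(nrow(idx)))
          img[idx[u, 1], idx[u, 2]] <- img[idx[u, 1], idx[u, 2]] + ww[ok][u]
      }
    }
  }
  img
}

# cumulative integral of J0 on a fine grid, cached per session
.j0_cumint_env <- new.env(parent = emptyenv())
.j0_cumint <- function(x) {
  xmax <- max(4000, max(x) * 1.05)
  if (is.null(.j0_cumint_env$xmax) || .j0_cumint_env$xmax < xmax) {
    g <- seq(0, xmax, by = 0.01)
    v <- besselJ(g, 0)
    cum <- c(0, cumsum((v[-1] + v[-length(v)]) / 2 * 0.01))
    .j0_cumint_env$grid <- g
    .j0_cumint_env$cum <- cum
    .j0_cumint_env$xmax <- xmax
  }
  stats::approx(.j0_cumint_env$grid, .j0_cumint_env$cum, xout = x,
                rule = 2)$y
}

# Filon weights for  int_{t_1}^{T} t J1(b t) dG(t)  rewritten by parts as
#   [t J1(bt) G]_{t_1}^{T} - b int t J0(bt) G dt,
# with G piecewise linear on the t grid and the kernel integrated in closed
# form:  int t J0(bt) dt = t J1(bt)/b,
#        int t^2 J0(bt) dt = (1/b^3) [x^2 J1 + x J0 - int J0]_{x = bt}.
# Vectorized over b (columns); the upper limit T (common to all b, from the
# axial Nyquist cap) clips the last interval. Returns a K x nb matrix W with
# colSums(W * G(t)) the value of the expression for each b.
.hankel_byparts_weights <- function(bvec, tg, tcap = Inf) {
  K <- length(tg)
  nb <- length(bvec)
  W <- matrix(0, K, nb)
  T_ <- min(tcap, tg[K])
  if (T_ <= tg[1]) return(W)
  t0 <- tg[-K]; t1 <- tg[-1]; d <- t1 - t0
  E1 <- pmin(t1, T_)
  act <- E1 > t0
  X0 <- outer(t0, bvec); X1 <- outer(E1, bvec)
  J1_0 <- besselJ(X0, 1); J1_1 <- besselJ(X1, 1)
  B2 <- matrix(bvec^2, K - 1, nb, byrow = TRUE)
  B3 <- matrix(bvec^3, K - 1, nb, byrow = TRUE)
  I1 <- (X1 * J1_1 - X0 * J1_0) / B2
  IJ0_0 <- matrix(.j0_cumint(as.numeric(X0)), K - 1, nb)
  IJ0_1 <- matrix(.j0_cumint(as.numeric(X1)), K - 1, nb)
  I2 <- (X1^2 * J1_1 + X1 * besselJ(X1, 0) - IJ0_1 -
         (X0^2 * J1_0 + X0 * besselJ(X0, 0) - IJ0_0)) / B3
  Qm <- I2 - t0 * I1
  c0 <- (I1 - Qm / d) * act
  c1 <- (Qm / d) * act
  Bm <- matrix(bvec, K - 1, nb, byrow = TRUE)
  W[-K, ] <- W[-K, ] - Bm * c0
  W[-1, ] <- W[-1, ] - Bm * c1
  # boundary terms: -t_1 J1(b t_1) G(t_1) + T J1(b T) G(T), G interpolated
  W[1, ] <- W[1, ] - tg[1] * besselJ(bvec * tg[1], 1)
  if (T_ >= tg[K]) {
    W[K, ] <- W[K, ] + tg[K] * besselJ(bvec * tg[K], 1)
  } else {
    kT <- findInterval(T_, tg)
    lam <- (T_ - tg[kT]) / (tg[kT + 1] - tg[kT])
    bc <- T_ * besselJ(bvec * T_, 1)
    W[kT, ] <- W[kT, ] + bc * (1 - lam)
    W[kT + 1, ] <- W[kT + 1, ] + bc * lam
  }
  W
}

#' Analytic Fourier-Bessel inversion of the cone transform
#'
#' Recovers the activity map from collimated cone-scatter data. Per
#' transverse spatial frequency \eqn{(u, v)} with radius \eqn{q}: the data
#' are normalized by the kinematic and geometric factors to
#' \eqn{G(u, v, t)}, the two hemispheres \eqn{\omega \lessgtr \pi/2} are
#' treated as separate branches in \eqn{t = \tan\omega}, and the axial
#' correlation profile is recovered through the Hankel-type identity
#' \deqn{C(\sigma) = -2\pi q \sigma \int_0^\infty t\, J_1(2\pi q \sigma t)\,
#'   \partial_t G(u, v, t)\, dt,}
#' evaluated after integration by parts (so the quadrature acts on `G`
#' itself, with the Bessel kernels integrated in closed form against a
#' piecewise-linear interpolant on the exponential `t` grid). The remaining
#' photometric smear over vertex heights is a small Toeplitz system in the
#' axial planes, solved by least squares using both branches; a 3D inverse
#' Fourier transform then yields the map. The transverse zero frequency is
#' indeterminate (the identity degenerates at \eqn{q = 0}) and is restored
#' per plane from the empty border frame of the reconstruction.
#'
#' @param sino a [cone_sinogram()] from [forward_ccrt()] covering both
#'   hemispheres.
#' @param params the [physics_params()] used for the forward model.
#' @param deriv `"by_parts"` (default) integrates by parts; `"central"`
#'   differentiates `G` with 3-point Lagrange formulas on the nonuniform
#'   grid and integrates `t J1 dG` with trapezoid weights.
#' @param cap_frac fraction of the axial Nyquist cap `1/(2 q dz)` at which
#'   the `t` integral is truncated per transverse frequency.
#' @param lambda relative weight of the axial second-difference penalty in
#'   the least-squares plane solve.
#' @param z_model_oversample even refinement factor of the model's internal
#'   axial quadrature (vertex nodes and source sub-planes); the unknowns
#'   remain the `nz` plane values.
#' @return A 3D [activity_map()] on the grid recorded in the sinogram.
#' @export
invert_ccrt <- function(sino, params = physics_params(),
                        deriv = c("by_parts", "central"),
                        cap_frac = 1, lambda = 0.02, z_model_oversample = 2L) {
  deriv <- match.arg(deriv)
  stopifnot(inherits(sino, "cone_sinogram"))
  det <- sino$detector
  ang <- sino$angles
  mg <- sino$map_geom
  if (is.null(mg)) stop("sinogram lacks source-grid information", call. = FALSE)
  L <- det$n_pixels[1]
  nz <- mg$nz
  dz <- mg$pitch[3]
  ax <- .axial_grids(det, nz, dz)
  nu <- 1 / ax$z_ver^2
  up <- ang$omegas < pi / 2
  if (!any(up) || !any(!up))
    warning("angle grid covers only one hemisphere: degraded reconstruction")
  K <- kinematic_factor(ang$omegas, params)
  # normalize data to G(u, v, t): FFT transversely, divide the kinematic and
  # geometric factors of the forward model
  nang <- length(ang$omegas)
  Gf <- array(0 + 0i, dim = c(L, L, nang))
  for (k in seq_len(nang))
    Gf[, , k] <- stats::fft(sino$values[, , k]) /
      (K[k] * sin(ang$omegas[k]) / 2 * mg$vol_N)
  q <- .freq_radius(L, det$pixel_pitch)
  # internal vertex lattice of the reconstruction model, refined by an even
  # factor (staggered so source-vertex offsets never vanish); sources stay
  # at the voxel plane centres, which are the unknowns
  os <- as.integer(z_model_oversample)
  dzf <- dz / os
  # reconstruction model: the same fine axial quadrature as the spectral
  # projector (source sub-planes within each voxel, vertex nodes on the fine
  # lattice), collapsed onto the nz unknown plane values. C_m collects the
  # weight that plane i sends to axial offset sigma_m = (m - 1/2) dzf.
  z_srcf <- det$standoff + (seq_len(nz * os) - 0.5) * dzf
  parent <- rep(seq_len(nz), each = os)
  z_verf <- det$standoff + (0:(nz * os)) * dzf
  nuf <- 1 / z_verf^2
  nsig <- nz * os
  sig <- (seq_len(nsig) - 0.5) * dzf       # positive axial offsets
  B <- matrix(0, 2 * nsig, nz)
  for (a in seq_along(z_srcf)) for (j in seq_along(z_verf)) {
    off <- z_srcf[a] - z_verf[j]
    m <- round(abs(off) / dzf + 0.5)
    if (m < 1 || m > nsig) next
    row <- if (off > 0) m else nsig + m
    B[row, parent[a]] <- B[row, parent[a]] + dzf^2 / dz * nuf[j]
  }
  Lz <- diff(diag(nz), differences = 2)
  # per-frequency Hankel recovery of C, then axial solve
  tf <- ang$ts[up]; tb <- abs(ang$ts[!up])
  of <- order(tf); ob <- order(tb)
  tf <- tf[of]; tb <- tb[ob]
  iu_f <- which(up)[of]; iu_b <- which(!up)[ob]
  have_f <- length(tf) >= 2L
  have_b <- length(tb) >= 2L
  Fz <- array(0 + 0i, dim = c(L, L, nz))
  qv <- as.numeric(q)
  Gmat_f <- if (have_f) sapply(iu_f, function(k) as.vector(Gf[, , k]))
  Gmat_b <- if (have_b) sapply(iu_b, function(k) as.vector(Gf[, , k]))
  Fmat <- matrix(0 + 0i, nz, L * L)
  uq <- sort(unique(round(qv, 12)))
  uq <- uq[uq > 0]
  for (qq in uq) {
    cols <- which(abs(qv - qq) < 1e-12)
    bvec <- 2 * pi * qq * sig
    # axial Nyquist cap: beyond t = 1/(2 q dz) the recovery kernel
    # oscillates in sigma faster than the plane grid resolves
    tcap <- cap_frac / (2 * qq * dz)
    mk_w <- function(tg) {
      if (deriv == "by_parts") .hankel_byparts_weights(bvec, tg, tcap)
      else sapply(bvec, .hankel_deriv_weights, tg = tg, tcap = tcap)
    }
    pref <- -2 * pi * qq * sig
    Chat <- NULL; A <- NULL
    for (br in c("f", "b")) {
      if (br == "f" && !have_f) next
      if (br == "b" && !have_b) next
      tg <- if (br == "f") tf else tb
      Gm <- if (br == "f") Gmat_f else Gmat_b
      rows <- if (br == "f") seq_len(nsig) else nsig + seq_len(nsig)
      Wq <- mk_w(tg)
      Chat <- rbind(Chat, t(Gm[cols, , drop = FALSE] %*% Wq) * pref)
      if (deriv == "by_parts") {
        # exact action of the capped Hankel quadrature on the Bessel basis:
        # Chat = P a with a_m = C_m / sigma_m and C = B f, so solve the
        # combined system A f = Chat in the least-squares sense with a small
        # axial roughness penalty (the sigma-Nyquist band is only half
        # determined)
        P <- pref * crossprod(Wq, besselJ(outer(tg, bvec), 0))
        A <- rbind(A, P %*% (B[rows, ] / sig))
      } else {
        # printed-formula route: take Chat as the profile C itself and undo
        # only the photometric smear over vertex heights
        A <- rbind(A, B[rows, ])
      }
    }
    lam2 <- (lambda * mean(abs(A)))^2
    Fmat[, cols] <- solve(crossprod(A) + lam2 * crossprod(Lz),
                          crossprod(A, Chat))
  }
  for (i in seq_len(nz))
    Fz[, , i] <- matrix(Fmat[i, ], L, L)
  # inverse transverse FFT per plane; q = 0 column is zero and is restored
  # from the empty border frame (compact support)
  rec <- array(0, dim = c(L, L, nz))
  off <- mg$off; dims <- mg$dims
  inner_x <- off[1] + seq_len(dims[1]); inner_y <- off[2] + seq_len(dims[2])
  border <- matrix(TRUE, L, L); border[inner_x, inner_y] <- FALSE
  for (i in seq_len(nz)) {
    pl <- Re(stats::fft(Fz[, , i], inverse = TRUE)) / L^2
    pl <- pl - mean(pl[border])
    rec[, , i] <- pl
  }
  out <- rec[inner_x, inner_y, , drop = FALSE]
  res <- activity_map(pmax(out, 0), pitch = mg$pitch)
  attr(res, "raw") <- out
  res
}

# trapezoid weights for  int t J1(bt) dG  with dG/dt from 3-point Lagrange
# differentiation on the nonuniform t grid (the printed-formula route)
.hankel_deriv_weights <- function(b, tg, tcap = Inf) {
  sub <- which(tg <= tcap)
  if (length(sub) < 3L) sub <- 1:3
  ts <- tg[sub]
  K <- length(ts)
  D <- matrix(0, K, K)      # differentiation matrix: (D g)[k] = g'(t_k)
  for (k in seq_len(K)) {
    idx <- if (k == 1) 1:3 else if (k == K) (K - 2):K else (k - 1):(k + 1)
    x <- ts[idx]; t0 <- ts[k]
    for (m in 1:3) {
      oth <- x[-m]
      D[k, idx[m]] <- ((t0 - oth[1]) + (t0 - oth[2])) /
        ((x[m] - oth[1]) * (x[m] - oth[2]))
    }
  }
  wtrap <- c(diff(ts) / 2, 0) + c(0, diff(ts) / 2)
  w <- numeric(length(tg))
  w[sub] <- as.numeric(t(D) %*% (wtrap * ts * besselJ(b * ts, 1)))
  w
}

#' Map energy-binned detector data to angle-indexed projections
#'
#' Detector events are acquired in energy windows; the Compton relation maps
#' each window to one scattering-angle bin. Given data binned on a uniform
#' energy grid, this regroups (sums) the counts into the angular bins induced
#' by the requested energy resolution `dE_keV`, conserving the total count,
#' and returns a [cone_sinogram()] on the induced (non-uniform) angle grid.
#'
#' @param sino_by_energy list with `values` (3D array, third index = energy
#'   bin, ordered by increasing energy), `energy_edges` (keV, length
#'   `dim(values)[3] + 1`) and `detector` (a [detector_geometry()]).
#' @param params a [physics_params()].
#' @param dE_keV target energy bin width, keV.
#' @return A [cone_sinogram()]; angles increase as energy decreases.
#' @export
energy_binning <- function(sino_by_energy, params, dE_keV = 0.5) {
  v <- sino_by_energy$values
  ee <- sino_by_energy$energy_edges
  stopifnot(length(dim(v)) == 3L, length(ee) == dim(v)[3] + 1L,
            !is.unsorted(ee), dE_keV > 0)
  eps <- params$epsilon
  band <- c(params$E0_keV / (1 + 2 * eps), params$E0_keV)
  if (dE_keV >= band[2] - band[1])
    stop("'dE_keV' is wider than the kinematic energy band", call. = FALSE)
  lo <- max(band[1], ee[1]); hi <- min(band[2], ee[length(ee)])
  tgt <- seq(lo, hi, by = dE_keV)
  if (tgt[length(tgt)] < hi) tgt <- c(tgt, hi)
  centres_E <- (ee[-1] + ee[-length(ee)]) / 2
  grp <- findInterval(centres_E, tgt, rightmost.closed = TRUE)
  ok <- grp >= 1 & grp <= length(tgt) - 1
  nb <- length(tgt) - 1
  out <- array(0, dim = c(dim(v)[1], dim(v)[2], nb))
  for (b in seq_len(nb)) {
    sel <- which(ok & grp == b)
    if (length(sel))
      out[, , b] <- apply(v[, , sel, drop = FALSE], c(1, 2), sum)
  }
  om <- angle_from_energy(params$E0_keV, (tgt[-1] + tgt[-length(tgt)]) / 2)
  om_edges <- rev(angle_from_energy(params$E0_keV, tgt))
  ordr <- order(om)
  g <- scatter_angle_grid(om[ordr], params$E0_keV, edges = om_edges,
                          allow_right_angle = TRUE)
  cone_sinogram(out[, , ordr, drop = FALSE], sino_by_energy$detector, g)
}
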