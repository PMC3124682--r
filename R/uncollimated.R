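#' Collimator-free single-scatter forward projector (gCCRT)
#'
#' Removing the collimator lets every scattering vertex in the upper
#' half-space contribute to every detector pixel: the data at pixel `D` and
#' scattering angle \eqn{\omega} sums conical projections over all vertices
#' `N` inside the scattering medium, with the scattering angle measured
#' between the legs `S -> N` and `N -> D`. Event weights follow the same
#' convention as [forward_ccrt()] (isotropic emission, inverse-square
#' propagation on both legs, Klein-Nishina factor, angle binning by exact
#' angle, optional uniform attenuation), so the collimated event set --
#' vertices on the vertical axis through the pixel -- is a subset with equal
#' weights and the open-geometry data dominates the collimated data
#' pixel-wise.
#'
#' Vertices are placed on the voxel grid of the medium: transversely at the
#' voxel centres, axially at the plane boundaries (the same axial lattice as
#' the collimated projector). Directions are induced by the (S, N, D)
#' triples rather than an explicit angular mesh.
#'
#' @param f a 3D [activity_map()] spanning the medium (anisotropic voxels
#'   allowed).
#' @param det a [detector_geometry()] with `collimated = FALSE`; its pixel
#'   grid is centred under the medium.
#' @param angles a [scatter_angle_grid()].
#' @param params a [physics_params()].
#' @return A [cone_sinogram()].
#' @export
forward_gccrt <- function(f, det, angles, params = physics_params()) {
  stopifnot(inherits(f, "activity_map"), length(dim(f)) == 3L,
            inherits(det, "detector_geometry"))
  if (det$collimated)
    stop("detector is collimated: use forward_ccrt()", call. = FALSE)
  geo <- .gccrt_geometry(dim(f), map_pitch(f), det)
  K <- kinematic_factor(angles$omegas, params)
  guard <- if (is.null(angles$guard)) 0 else angles$guard
  raw <- gccrt_accumulate(as.numeric(f), geo$src, geo$ver, geo$pix,
                          angles$edges, K, guard,
                          geo$volS, geo$volN, params$mu_per_mm, 0L)
  vals <- array(raw, dim = c(det$n_pixels[1], det$n_pixels[2],
                             length(angles$omegas)))
  cone_sinogram(vals, det, angles,
                map_geom = list(pitch = map_pitch(f), nz = dim(f)[3],
                                dims = dim(f)))
}

# voxel-centre, vertex-node and pixel-centre coordinate tables shared by the
# open-geometry routines; everything centred on the detector axis
.gccrt_geometry <- function(dims, pitch, det) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  px <- (seq_len(nx) - (nx + 1) / 2) * pitch[1]
  py <- (seq_len(ny) - (ny + 1) / 2) * pitch[2]
  pz <- det$standoff + (seq_len(nz) - 0.5) * pitch[3]
  src <- as.matrix(expand.grid(x = px, y = py, z = pz))
  vz <- det$standoff + (0:nz) * pitch[3]
  ver <- as.matrix(expand.grid(x = px, y = py, z = vz))
  dx <- (seq_len(det$n_pixels[1]) - (det$n_pixels[1] + 1) / 2) * det$pixel_pitch
  dy <- (seq_len(det$n_pixels[2]) - (det$n_pixels[2] + 1) / 2) * det$pixel_pitch
  pix <- as.matrix(expand.grid(x = dx, y = dy))
  list(src = src, ver = ver, pix = pix,
       volS = prod(pitch), volN = pitch[1] * pitch[2] * pitch[3])
}

# plain-R event-level triple loop over (S, N, D); the independent reference
# implementation the compiled projector is tested against on tiny grids
.gccrt_triple_loop <- function(f, det, angles, params = physics_params()) {
  stopifnot(all(dim(f) <= 8L))
  geo <- .gccrt_geometry(dim(f), map_pitch(f), det)
  K <- kinematic_factor(angles$omegas, params)
  guard <- if (is.null(angles$guard)) 0 else angles$guard
  edges <- angles$edges
  dwk <- diff(edges)
  nang <- length(angles$omegas)
  mu <- params$mu_per_mm
  fv <- as.numeric(f)
  npix <- nrow(geo$pix)
  out <- matrix(0, npix, nang)
  for (s in seq_len(nrow(geo$src))) {
    if (fv[s] == 0) next
    for (n in seq_len(nrow(geo$ver))) {
      u <- geo$ver[n, ] - geo$src[s, ]
      sn2 <- sum(u^2)
      if (sn2 <= 0) next
      sn <- sqrt(sn2)
      for (d in seq_len(npix)) {
        v <- c(geo$pix[d, 1], geo$pix[d, 2], 0) - geo$ver[n, ]
        nd2 <- sum(v^2)
        cth <- sum(u * v) / (sn * sqrt(nd2))
        theta <- acos(min(1, max(-1, cth)))
        if (guard > 0 && abs(theta - pi / 2) < guard) next
        if (theta <= edges[1] || theta > edges[nang + 1]) next
        b <- findInterval(theta, edges)
        if (b < 1 || b > nang) next
        w <- fv[s] * geo$volS * geo$volN /
          (4 * pi * sn2 * sn) * K[b] / (dwk[b] * nd2)
        if (mu > 0) w <- w * exp(-mu * sn) * exp(-mu * sqrt(nd2))
        out[d, b] <- out[d, b] + w
      }
    }
  }
  cone_sinogram(array(out, c(det$n_pixels[1], det$n_pixels[2], nang)),
                det, angles)
}

#' Point spread function of the open (uncollimated) geometry
#'
#' Detector response to a unit point source at a fixed scattering angle,
#' computed by the same event accumulation as [forward_gccrt()] restricted
#' to a single source. The vertices contributing to a given (source, pixel)
#' pair lie on the surface of a torus of revolution whose axis is the line
#' joining the source to the pixel (the inscribed-angle condition
#' \eqn{\angle SND = \pi - \omega}); summing over the vertex lattice samples
#' that torus, and the resulting profile has no central hole -- unlike the
#' collimated "Mexican hat".
#'
#' @param source numeric length-3 source position (x, y, z), mm, in the
#'   detector-centred frame.
#' @param det a [detector_geometry()] with `collimated = FALSE`.
#' @param omega one scattering angle, radians.
#' @param params a [physics_params()].
#' @param grid list with `dims` (3 integers) and `pitch` (mm, length 3)
#'   describing the scattering-medium lattice supplying the vertices.
#' @param domega width of the angle bin around `omega`, radians.
#' @return Matrix (`n_pixels`) with the detector image; attribute
#'   `"vertices"` holds the vertex nodes that contributed to the centre
#'   pixel.
#' @export
psf_gccrt <- function(source, det, omega, params = physics_params(),
                      grid = list(dims = c(13, 13, 9),
                                  pitch = c(300 / 13, 300 / 13, 150 / 9)),
                      domega = 0.05) {
  stopifnot(length(source) == 3)
  if (source[3] <= 0)
    stop("source must lie above the detector plane", call. = FALSE)
  .check_omega(omega, open_lower = TRUE, open_upper = TRUE)
  geo <- .gccrt_geometry(grid$dims, grid$pitch, det)
  ang <- scatter_angle_grid(omega, params$E0_keV,
                            edges = c(omega - domega / 2, omega + domega / 2),
                            allow_right_angle = TRUE)
  K <- kinematic_factor(omega, params)
  raw <- gccrt_accumulate(1, matrix(source, 1, 3), geo$ver, geo$pix,
                          ang$edges, K, 0, geo$volS, geo$volN,
                          params$mu_per_mm, 0L)
  img <- matrix(raw, det$n_pixels[1], det$n_pixels[2])
  # vertices satisfying the inscribed-angle condition for the centre pixel
  ctr <- c(geo$pix[which.min(geo$pix[, 1]^2 + geo$pix[, 2]^2), ], 0)
  u <- sweep(geo$ver, 2, source)          # S -> N
  v <- cbind(ctr[1] - geo$ver[, 1], ctr[2] - geo$ver[, 2], -geo$ver[, 3])
  cth <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  th <- acos(pmin(1, pmax(-1, cth)))
  attr(img, "vertices") <- geo$ver[abs(th - omega) <= domega / 2, , drop = FALSE]
  img
}

#' Weight matrix of the open-geometry system
#'
#' Assembles the discrete linear map from voxel activities to
#' (pixel x angle) measurements by accumulating, for every voxel of the
#' mesh, its point response at each scattering angle -- column `j` is the
#' vectorized [forward_gccrt()] of unit activity in voxel `j`. Applying the
#' matrix to an activity vector therefore reproduces the projector exactly.
#'
#' @param dims medium dimensions, voxels (length 3).
#' @param det a [detector_geometry()] with `collimated = FALSE`.
#' @param angles a [scatter_angle_grid()].
#' @param params a [physics_params()].
#' @param pitch voxel pitch, mm (length 3).
#' @return An object of class `weight_matrix`: the dense matrix
#'   (`prod(n_pixels) * n_angles` rows, `prod(dims)` columns) with the
#'   geometry stored in attributes.
#' @export
build_weight_matrix <- function(dims, det, angles, params = physics_params(),
                                pitch = c(300 / 13, 300 / 13, 150 / 9)) {
  stopifnot(length(dims) == 3L, all(dims >= 1))
  nvox <- prod(dims)
  nrow_w <- prod(det$n_pixels) * length(angles$omegas)
  if (nvox * nrow_w > 2e8)
    stop("weight matrix would exceed the memory guard (",
         nvox, " x ", nrow_w, " entries)", call. = FALSE)
  geo <- .gccrt_geometry(dims, pitch, det)
  K <- kinematic_factor(angles$omegas, params)
  guard <- if (is.null(angles$guard)) 0 else angles$guard
  raw <- gccrt_accumulate(numeric(0), geo$src, geo$ver, geo$pix,
                          angles$edges, K, guard,
                          geo$volS, geo$volN, params$mu_per_mm, 1L)
  W <- matrix(raw, nrow = nrow_w, ncol = nvox)
  structure(W, class = c("weight_matrix", "matrix"),
            dims = dims, pitch = pitch, detector = det, angles = angles)
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("gCCRT weight matrix: %d measurements x %d voxels (%.1f%% nonzero)\n",
              nrow(x), ncol(x), 100 * mean(x != 0)))
  invisible(x)
}

#' Conjugate-gradient reconstruction with positivity constraint
#'
#' Solves the normal equations of `W f = g` by conjugate gradients,
#' projecting each accepted iterate onto the nonnegative orthant. Whenever
#' the projection clips a component, conjugacy is restarted from the
#' projected point; a step is only accepted if it does not increase the data
#' misfit (backtracking otherwise), so the misfit is non-increasing over
#' accepted iterates. The scheme is deterministic and parameter-free beyond
#' the iteration budget and tolerance.
#'
#' @param W a [build_weight_matrix()] result (or any numeric matrix).
#' @param g measurement vector, length `nrow(W)`.
#' @param max_iter iteration budget.
#' @param tol relative residual tolerance on the normal equations.
#' @return Numeric vector of nonnegative voxel activities; if `W` carries
#'   geometry attributes, an [activity_map()] with attribute `history`
#'   (misfit per accepted iterate).
#' @export
cg_positive <- function(W, g, max_iter = 500, tol = 1e-10) {
  g <- as.numeric(g)
  stopifnot(length(g) == nrow(W), all(is.finite(g)))
  if (all(W == 0)) stop("weight matrix is identically zero", call. = FALSE)
  Wm <- unclass(W); attributes(Wm) <- list(dim = dim(W))
  # Jacobi preconditioning: unit-norm columns; positive rescaling preserves
  # the nonnegativity constraint and the iteration stays deterministic
  cn <- sqrt(colSums(Wm^2))
  cn[cn == 0] <- 1
  Wm <- sweep(Wm, 2, cn, `/`)
  At <- function(x) as.numeric(crossprod(Wm, x))
  A <- function(x) as.numeric(Wm %*% x)
  f <- numeric(ncol(Wm))
  r <- At(g)                      # residual of the normal equations at f = 0
  r0n <- sqrt(sum(r^2))
  if (r0n == 0) return(.cg_wrap(f, W, numeric(0)))
  p <- r
  misfit <- sum((g - A(f))^2)
  history <- misfit
  bad_streak <- 0L
  for (it in seq_len(max_iter)) {
    Ap <- At(A(p))
    pAp <- sum(p * Ap)
    if (pAp <= 0) break
    alpha <- sum(r^2) / pAp
    repeat {
      f_try <- pmax(f + alpha * p, 0)
      m_try <- sum((g - A(f_try))^2)
      if (m_try <= misfit || alpha < 1e-14) break
      alpha <- alpha / 2           # backtrack: never accept a worse misfit
    }
    clipped <- any(f + alpha * p < 0)
    f_new <- pmax(f + alpha * p, 0)
    m_new <- sum((g - A(f_new))^2)
    if (m_new > misfit * (1 + 1e-12)) {
      bad_streak <- bad_streak + 1L
      if (bad_streak >= 5L)
        stop("cg_positive diverged: misfit grew over 5 successive iterations",
             call. = FALSE)
    } else bad_streak <- 0L
    f <- f_new
    misfit <- min(misfit, m_new)
    history <- c(history, misfit)
    r_new <- At(g) - At(A(f))
    if (sqrt(sum(r_new^2)) < tol * r0n) { r <- r_new; break }
    if (clipped) {
      p <- r_new                   # restart conjugacy after projection
    } else {
      beta <- sum(r_new^2) / sum(r^2)
      p <- r_new + beta * p
    }
    r <- r_new
  }
  .cg_wrap(f / cn, W, history)
}

.cg_wrap <- function(f, W, history) {
  dims <- attr(W, "dims")
  if (is.null(dims)) {
    attr(f, "history") <- history
    return(f)
  }
  out <- activity_map(array(f, dims), pitch = attr(W, "pitch"))
  attr(out, "history") <- history
  out
}
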