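#' Cylinder-in-cube phantom
#'
#' The reference 3D scene: a uniform-activity cylinder, axis along `z`,
#' centred in a cubic scattering medium of `N` voxels per edge. The cylinder
#' height is specified (the reference study uses 6 of 16 planes); its radius
#' is a free parameter of the reproduction and defaults to 4 voxels.
#'
#' @param N voxels per cube edge (`>= 4`).
#' @param height cylinder height, voxels (`0 < height <= N`).
#' @param radius cylinder radius, voxels (`< N/2`).
#' @param activity activity concentration inside the cylinder
#'   (counts min^-1 cm^-3).
#' @param pitch voxel edge, mm.
#' @return A 3D [activity_map()], nonzero only inside the cylinder.
#' @examples
#' ph <- make_cylinder_in_cube(16, height = 6)
#' range(apply(ph > 0, 3, any))  # support confined to 6 z-planes
#' @export
make_cylinder_in_cube <- function(N = 16, height = 6, radius = 4,
                                  activity = 4.84e10, pitch = 1) {
  stopifnot(N >= 4, height > 0, height <= N, radius > 0, radius < N / 2,
            activity >= 0, pitch > 0)
  cxy <- (N + 1) / 2
  i <- seq_len(N)
  r2 <- outer((i - cxy)^2, (i - cxy)^2, `+`)
  disk <- r2 <= radius^2
  z0 <- floor((N - height) / 2) + 1L
  vol <- array(0, dim = c(N, N, N))
  vol[, , z0:(z0 + height - 1L)] <- disk * activity
  activity_map(vol, pitch = pitch)
}

#' Nested concentric cubes phantom
#'
#' Two concentric boxes with different activity concentrations inside a zero
#' background, matching the collimator-free reconstruction scene (reference
#' discretization 13 x 13 x 9 voxels).
#'
#' @param N_xy transverse grid size, voxels.
#' @param N_z axial grid size, voxels.
#' @param outer_frac fraction of each grid dimension occupied by the outer box.
#' @param inner_frac fraction of the outer box occupied by the inner box,
#'   in `(0, 1)`.
#' @param a_outer,a_inner activity of the outer shell and the inner box.
#' @param pitch voxel pitch, mm; scalar or `(x, y, z)`.
#' @return A 3D [activity_map()] taking at most the three values
#'   `{0, a_outer, a_inner}`.
#' @export
make_nested_cubes <- function(N_xy = 13, N_z = 9, outer_frac = 0.7,
                              inner_frac = 0.45, a_outer = 1, a_inner = 3,
                              pitch = c(300 / 13, 300 / 13, 150 / 9)) {
  stopifnot(N_xy >= 3, N_z >= 3, outer_frac > 0, outer_frac <= 1,
            inner_frac > 0, inner_frac < 1)
  centred_band <- function(n, frac) {
    w <- max(1L, round(n * frac))
    lo <- floor((n - w) / 2) + 1L
    lo:(lo + w - 1L)
  }
  vol <- array(0, dim = c(N_xy, N_xy, N_z))
  oxy <- centred_band(N_xy, outer_frac); oz <- centred_band(N_z, outer_frac)
  vol[oxy, oxy, oz] <- a_outer
  ixy <- centred_band(N_xy, outer_frac * inner_frac)
  iz <- centred_band(N_z, outer_frac * inner_frac)
  vol[ixy, ixy, iz] <- a_inner
  m <- activity_map(vol, pitch = pitch)
  attr(m, "inner_index") <- list(x = ixy, y = ixy, z = iz)
  attr(m, "outer_index") <- list(x = oxy, y = oxy, z = oz)
  m
}

#' Stylized thyroid phantom with nodules
#'
#' A two-lobed gland (two tilted ellipses joined by an isthmus) carrying small
#' hot and cold nodules. The geometry is a parameterized stand-in constructed
#' from ellipses, not a pixel copy of any particular clinical image: tests
#' rely on the constructed truth (lobe level, nodule centres, nodule
#' contrast), which this function reports in attributes.
#'
#' @param size image side, pixels (`>= 64`).
#' @param lobe_activity activity of the gland tissue.
#' @param nodule_contrast multiplicative contrast of the nodules relative to
#'   the lobe level: hot nodules at `lobe_activity * (1 + nodule_contrast)`,
#'   cold ones at `lobe_activity * (1 - nodule_contrast)`.
#' @param pitch pixel pitch, mm.
#' @return A 2D [activity_map()] with attribute `nodules`: a data frame of
#'   nodule centres (pixels), radii and values.
#' @export
make_thyroid_2d <- function(size = 512, lobe_activity = 1,
                            nodule_contrast = 0.8, pitch = 1) {
  stopifnot(size >= 64, lobe_activity > 0,
            nodule_contrast > 0, nodule_contrast <= 1)
  s <- size
  xy <- seq_len(s) / s  # unit square, x across, y towards the top
  X <- matrix(xy, s, s)
  Y <- matrix(xy, s, s, byrow = TRUE)
  img <- matrix(0, s, s)
  in_ellipse <- function(cx, cy, a, b, phi) {
    xr <- (X - cx) * cos(phi) + (Y - cy) * sin(phi)
    yr <- -(X - cx) * sin(phi) + (Y - cy) * cos(phi)
    (xr / a)^2 + (yr / b)^2 <= 1
  }
  # two lobes, slightly tilted towards each other, plus a thin isthmus
  img[in_ellipse(0.36, 0.52, 0.095, 0.21,  0.22)] <- lobe_activity
  img[in_ellipse(0.64, 0.52, 0.095, 0.21, -0.22)] <- lobe_activity
  img[in_ellipse(0.50, 0.40, 0.085, 0.045, 0)] <- lobe_activity
  # nodules: radius capped at size/20 by construction (<= 0.025 of the side)
  nod <- data.frame(
    cx = c(0.37, 0.63, 0.345, 0.655),
    cy = c(0.62, 0.38, 0.435, 0.60),
    r  = c(0.022, 0.020, 0.016, 0.014),
    hot = c(TRUE, TRUE, FALSE, FALSE)
  )
  nod$value <- lobe_activity * (1 + ifelse(nod$hot, 1, -1) * nodule_contrast)
  for (k in seq_len(nrow(nod)))
    img[in_ellipse(nod$cx[k], nod$cy[k], nod$r[k], nod$r[k], 0)] <- nod$value[k]
  nod$cx_px <- nod$cx * s
  nod$cy_px <- nod$cy * s
  nod$r_px <- nod$r * s
  m <- activity_map(img, pitch = pitch)
  attr(m, "nodules") <- nod
  attr(m, "lobe_activity") <- lobe_activity
  m
}

# Standard Shepp-Logan ellipse table: intensity, semi-axes, centre, rotation
# (degrees). Summing the additive intensities inside each ellipse gives the
# classic head image with values in [0, 1] up to clipping.
.shepp_logan_table <- function() {
  data.frame(
    A   = c( 1.0, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
    a   = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b   = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    x0  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0  = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.605, -0.605),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0)
  )
}

#' Shepp-Logan phantom
#'
#' The standard 10-ellipse head phantom rasterized at voxel centres, with
#' values clipped to be nonnegative so the result is a valid activity map.
#'
#' @param size image side, pixels.
#' @param pitch pixel pitch, mm.
#' @return A 2D [activity_map()] with values in `[0, 1]`.
#' @export
make_shepp_logan <- function(size = 128, pitch = 1) {
  stopifnot(size >= 8)
  tab <- .shepp_logan_table()
  u <- (2 * seq_len(size) - size - 1) / size  # centres in (-1, 1)
  X <- matrix(u, size, size)
  Y <- matrix(u, size, size, byrow = TRUE)
  img <- matrix(0, size, size)
  for (k in seq_len(nrow(tab))) {
    phi <- tab$phi[k] * pi / 180
    xr <- (X - tab$x0[k]) * cos(phi) + (Y - tab$y0[k]) * sin(phi)
    yr <- -(X - tab$x0[k]) * sin(phi) + (Y - tab$y0[k]) * cos(phi)
    img <- img + tab$A[k] * ((xr / tab$a[k])^2 + (yr / tab$b[k])^2 <= 1)
  }
  activity_map(pmax(img, 0), pitch = pitch)
}

#' Poisson emission noise
#'
#' Replaces each voxel's activity concentration by a scaled Poisson draw: the
#' expected number of counts in a voxel during the dwell time is
#' `value * dwell / 60 * voxel_volume_cm3`, a Poisson variate is drawn, and
#' the result is converted back to a concentration. Longer dwell times give
#' relatively less noise; the limit `dwell -> Inf` returns the input.
#'
#' @param map an [activity_map()] whose values are activity concentrations in
#'   counts min^-1 cm^-3.
#' @param dwell acquisition (dwell) time, seconds.
#' @param seed integer seed; identical seeds give identical output. `NULL`
#'   uses (and advances) the current RNG state.
#' @return An [activity_map()] on the same grid.
#' @export
add_poisson_noise <- function(map, dwell = 0.1, seed = NULL) {
  stopifnot(inherits(map, "activity_map"))
  if (!is.numeric(dwell) || length(dwell) != 1L || dwell <= 0)
    stop("'dwell' must be a positive time in seconds", call. = FALSE)
  vox_cm3 <- prod(rep_len(map_pitch(map), length(dim(map))) / 10)
  scale <- dwell / 60 * vox_cm3   # concentration -> expected counts
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  lam <- as.numeric(map) * scale
  counts <- numeric(length(lam))
  big <- lam > 1e9  # rpois returns NA beyond integer range; Gaussian limit there
  counts[!big] <- stats::rpois(sum(!big), lambda = lam[!big])
  if (any(big))
    counts[big] <- pmax(0, round(stats::rnorm(sum(big), lam[big], sqrt(lam[big]))))
  out <- array(counts / scale, dim = dim(map))
  activity_map(out, pitch = map_pitch(map), origin = map_origin(map))
}
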