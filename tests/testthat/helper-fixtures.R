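# shared small fixtures and independent reference implementations

fix_params <- function(E0 = 140, ne = 3.5e23, mu = 0)
  physics_params(E0, ne_per_cm3 = ne, mu_per_mm = mu)

# compact 2D Gaussian blob with empty margins, for V-line round trips
fix_blob2d <- function(n = 64, cx = n / 2, cy = n * 0.45, sx = n / 10,
                       sy = n / 12) {
  x <- seq_len(n)
  activity_map(outer(exp(-((x - cx)^2) / (2 * sx^2)),
                     exp(-((x - cy)^2) / (2 * sy^2))) *
                 (outer(abs(x - cx), abs(x - cy), pmax) < n * 0.4),
               pitch = 1)
}

# periodic wide-detector V-line acquisition of a map
fix_vline_sino <- function(f, domega = 0.005, span = 2,
                           params = fix_params()) {
  n <- dim(f)[1]
  ex <- n * (span - 1) / 2
  zeta <- seq(0.5 - ex, n - 0.5 + ex, by = 1)
  forward_cvlrt(f, angle_grid_vline(domega), zeta = zeta, params = params,
                periodic = TRUE)
}

# crop a full-detector reconstruction back to the map's columns
fix_crop <- function(rec, sino, n) {
  i0 <- which.min(abs(sino$zeta - 0.5))
  unclass(rec)[i0:(i0 + n - 1), , drop = FALSE]
}

# independent direct double Riemann sum for the compounded V-line transform:
# eta at midpoint nodes (j + 1/2) dy, slant nodes on the y-levels
# r = y_m / cos(omega) (so dr/r = dy/y), bilinear sampling of f in x
fix_cvlrt_direct <- function(f, angles, zeta, params) {
  fv <- unclass(f); attributes(fv) <- list(dim = dim(f))
  nx <- nrow(fv); ny <- ncol(fv)
  px <- scatteremit::map_pitch(f)[1]; py <- scatteremit::map_pitch(f)[2]
  x0 <- scatteremit::map_origin(f)[1]; y0 <- scatteremit::map_origin(f)[2]
  sample_f <- function(x, col) {   # linear interp along x, exact row index
    if (col < 1 || col > ny) return(0)
    xf <- (x - x0) / px
    i <- floor(xf); w <- xf - i
    v1 <- if (i + 1 >= 1 && i + 1 <= nx) fv[i + 1, col] else 0
    v2 <- if (i + 2 >= 1 && i + 2 <= nx) fv[i + 2, col] else 0
    v1 * (1 - w) + v2 * w
  }
  Kst <- kinematic_factor(angles$omegas, params, dims = 2)
  out <- matrix(0, length(zeta), length(angles$omegas))
  yrow <- y0 + (seq_len(ny) - 1) * py
  for (k in seq_along(angles$omegas)) {
    tauk <- tan(angles$omegas[k])
    for (iz in seq_along(zeta)) {
      acc <- 0
      for (m in seq_len(ny)) {       # slant node at height y_m
        if (yrow[m] <= py / 4) next
        for (sgn in c(1, -1)) {
          xs <- zeta[iz] + sgn * yrow[m] * tauk
          # eta smear evaluated at (xs, y_m): midpoint nodes
          hval <- 0
          for (j in 0:(ny - m)) {
            eta <- (j + 0.5) * py
            yq <- yrow[m] + eta
            qf <- (yq - y0) / py
            qlo <- floor(qf); wq <- qf - qlo
            v1 <- if (qlo + 1 >= 1 && qlo + 1 <= ny) sample_f(xs, qlo + 1) else 0
            v2 <- if (qlo + 2 >= 1 && qlo + 2 <= ny) sample_f(xs, qlo + 2) else 0
            hval <- hval + (v1 * (1 - wq) + v2 * wq) / eta * py
          }
          acc <- acc + hval * py / yrow[m]
        }
      }
      out[iz, k] <- acc * Kst[k]
    }
  }
  out
}
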