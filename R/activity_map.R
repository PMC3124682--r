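#' Activity map on a regular grid
#'
#' The unknown of every reconstruction problem in this package: a nonnegative
#' emitter activity density sampled on a regular 2D or 3D grid. Axis order is
#' `(x, y)` in 2D and `(x, y, z)` in 3D; the detector-normal axis is `y` in 2D
#' (detector along the line `y = 0`) and `z` in 3D (detector in the plane
#' `z = 0`), with the object strictly on the positive side.
#'
#' @param values numeric array, 2D or 3D, nonnegative and finite.
#' @param pitch voxel edge length(s), mm; a scalar or one value per axis.
#' @param origin world coordinate (mm) of the centre of voxel `(1, 1[, 1])`;
#'   defaults to half a pitch on every axis, i.e. the grid starts at the
#'   coordinate origin.
#' @return An object of class `activity_map` (the array with attributes
#'   `pitch` and `origin`).
#' @export
activity_map <- function(values, pitch = 1, origin = NULL) {
  values <- as.array(values)
  nd <- length(dim(values))
  if (!nd %in% 2:3)
    stop("'values' must be a 2D or 3D array", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("activity values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("activity values must be nonnegative", call. = FALSE)
  pitch <- rep_len(as.numeric(pitch), nd)
  if (any(pitch <= 0)) stop("'pitch' must be positive", call. = FALSE)
  if (is.null(origin)) origin <- pitch / 2
  origin <- rep_len(as.numeric(origin), nd)
  structure(values, pitch = pitch, origin = origin, class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Activity map: %s voxels, pitch (%s) mm, origin (%s) mm\n",
              paste(d, collapse = " x "),
              paste(signif(attr(x, "pitch"), 4), collapse = ", "),
              paste(signif(attr(x, "origin"), 4), collapse = ", ")))
  cat(sprintf("  values in [%.4g, %.4g], total %.6g\n",
              min(x), max(x), sum(x)))
  invisible(x)
}

#' @rdname activity_map
#' @param x an `activity_map`.
#' @export
map_pitch <- function(x) attr(x, "pitch")

#' @rdname activity_map
#' @export
map_origin <- function(x) attr(x, "origin")

#' Axis coordinates of an activity map
#'
#' Voxel-centre world coordinates along one axis.
#'
#' @param x an [activity_map()].
#' @param axis axis index (1 = x, 2 = y, 3 = z).
#' @return Numeric vector of voxel-centre coordinates, mm.
#' @export
map_axis <- function(x, axis) {
  map_origin(x)[axis] + (seq_len(dim(x)[axis]) - 1) * map_pitch(x)[axis]
}

# strip class/attrs for raw numeric work
.vals <- function(x) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(x))
  a
}

.same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a), dim(b)) &&
    max(abs(map_pitch(a) - map_pitch(b))) < tol &&
    max(abs(map_origin(a) - map_origin(b))) < tol
}

#' Relative mean square error between two maps, in percent
#'
#' \deqn{\mathrm{RMSE} = 100 \, \lVert \hat f - f \rVert_2 / \lVert f \rVert_2.}
#' This relative-L2 definition is the package's figure of merit for all
#' reconstruction experiments.
#'
#' @param reconstruction,truth arrays or [activity_map()]s on the same grid.
#' @return RMSE in percent.
#' @export
rmse <- function(reconstruction, truth) {
  r <- as.numeric(reconstruction)
  t <- as.numeric(truth)
  if (length(r) != length(t))
    stop("'reconstruction' and 'truth' must have the same size", call. = FALSE)
  nt <- sqrt(sum(t^2))
  if (nt == 0) stop("'truth' is identically zero; relative error undefined", call. = FALSE)
  100 * sqrt(sum((r - t)^2)) / nt
}
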