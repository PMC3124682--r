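#' Write and read activity maps
#'
#' Two on-disk forms are supported. `format = "tiff"` writes 2D maps as a
#' single-page 32-bit float TIFF and 3D maps as a multi-page stack (one page
#' per z plane); pitch and origin travel in a sidecar `.json` next to the
#' image so the round trip preserves the grid. `format = "container"` writes
#' a single plain-text container (JSON) with an `/activity` dataset plus
#' `pitch`/`origin` attributes, readable anywhere.
#'
#' @param map an [activity_map()].
#' @param path output path; the format is inferred from the extension
#'   (`.tif`/`.tiff` or anything else for the container) unless given.
#' @param format `"tiff"` or `"container"`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, format = c("auto", "tiff", "container")) {
  stopifnot(inherits(map, "activity_map"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "container"
  if (format == "tiff") {
    v <- .vals(map)
    mx <- max(v)
    pages <- if (length(dim(v)) == 2L) list(t(v) / max(mx, 1)) else
      lapply(seq_len(dim(v)[3]), function(i) t(v[, , i]) / max(mx, 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta <- list(pitch = map_pitch(map), origin = map_origin(map),
                 dim = dim(map), scale = max(mx, 1))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE,
                         digits = NA)
  } else {
    obj <- list(datasets = list(`/activity` = as.numeric(map)),
                dim = dim(map),
                attributes = list(pitch = map_pitch(map),
                                  origin = map_origin(map)))
    jsonlite::write_json(obj, path, digits = NA)
  }
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path, format = c("auto", "tiff", "container")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "container"
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    v <- if (length(pages) == 1L) t(pages[[1]]) else {
      a <- array(0, dim = meta$dim)
      for (i in seq_along(pages)) a[, , i] <- t(pages[[i]])
      a
    }
    return(activity_map(v * meta$scale, pitch = meta$pitch,
                        origin = meta$origin))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$datasets$`/activity`))
    stop("malformed container: missing dataset /activity in ", path,
         call. = FALSE)
  if (is.null(obj$attributes$pitch))
    stop("malformed container: missing attribute pitch in ", path,
         call. = FALSE)
  activity_map(array(obj$datasets$`/activity`, dim = obj$dim),
               pitch = obj$attributes$pitch, origin = obj$attributes$origin)
}

#' Write and read sinograms
#'
#' Plain-text containers with named datasets: V-line data carries
#' `/sinogram`, `/zeta` and `/omega`; cone data carries `/sinogram` (3D) and
#' `/omega` plus the detector attributes. Floating-point values round-trip
#' at full precision. A missing dataset raises an error naming it.
#'
#' @param sino a [v_sinogram()] or [cone_sinogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  if (inherits(sino, "v_sinogram")) {
    obj <- list(kind = "vline",
                datasets = list(`/sinogram` = as.numeric(sino$values),
                                `/zeta` = sino$zeta,
                                `/omega` = sino$angles$omegas),
                dim = dim(sino$values),
                attributes = list(E0_keV = sino$angles$E0_keV,
                                  edges = sino$angles$edges,
                                  pitch = sino$pitch,
                                  y_origin = sino$y_origin, ny = sino$ny,
                                  periodic = isTRUE(attr(sino, "periodic")),
                                  x_support = attr(sino, "x_support")))
  } else if (inherits(sino, "cone_sinogram")) {
    det <- sino$detector
    obj <- list(kind = "cone",
                datasets = list(`/sinogram` = as.numeric(sino$values),
                                `/omega` = sino$angles$omegas,
                                `/energy` = sino$angles$energies),
                dim = dim(sino$values),
                attributes = list(E0_keV = sino$angles$E0_keV,
                                  edges = sino$angles$edges,
                                  guard = sino$angles$guard,
                                  n_pixels = det$n_pixels,
                                  pixel_pitch = det$pixel_pitch,
                                  standoff = det$standoff,
                                  medium_depth = det$medium_depth,
                                  collimated = det$collimated,
                                  map_geom = sino$map_geom))
  } else stop("unsupported sinogram class", call. = FALSE)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE, null = "null")
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (ds in c("/sinogram", "/omega"))
    if (is.null(obj$datasets[[ds]]))
      stop("malformed container: missing dataset ", ds, " in ", path,
           call. = FALSE)
  at <- obj$attributes
  ang <- scatter_angle_grid(obj$datasets$`/omega`, E0_keV = at$E0_keV,
                            edges = at$edges)
  if (identical(obj$kind[[1]], "vline")) {
    if (is.null(obj$datasets$`/zeta`))
      stop("malformed container: missing dataset /zeta in ", path,
           call. = FALSE)
    s <- v_sinogram(matrix(obj$datasets$`/sinogram`, obj$dim[1], obj$dim[2]),
                    zeta = obj$datasets$`/zeta`, angles = ang,
                    pitch = at$pitch, y_origin = at$y_origin, ny = at$ny)
    attr(s, "periodic") <- isTRUE(at$periodic)
    if (!is.null(at$x_support)) attr(s, "x_support") <- at$x_support
    return(s)
  }
  if (!is.null(at$guard)) ang$guard <- at$guard
  det <- detector_geometry(at$n_pixels, at$pixel_pitch, at$standoff,
                           at$medium_depth, collimated = isTRUE(at$collimated))
  mg <- at$map_geom
  if (!is.null(mg)) mg <- lapply(mg, unlist)
  cone_sinogram(array(obj$datasets$`/sinogram`, obj$dim), det, ang,
                map_geom = mg)
}
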