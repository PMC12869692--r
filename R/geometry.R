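# Projection geometry: point source above the chest-wall edge (half-cone
# mammographic arrangement), detector plane at the phantom's bottom surface,
# pixel grid covering the diverging shadow of the whole phantom.

#' Projection geometry for a phantom
#'
#' The source sits 35.46 cm above the top surface of the breast, over the
#' chest-wall edge at the lateral center (half-cone beam).  The detector
#' plane lies at the bottom surface, parallel to the top, with square pixels;
#' the pixel grid is sized so that every phantom voxel projects inside it.
#'
#' @param phantom A \code{voxel_phantom} the geometry should cover.
#' @param sid_mm Source height above the top surface in mm (default 354.6).
#' @param pixel_pitch_mm Detector pixel pitch in mm (default: the phantom's
#'   voxel pitch, giving one reconstruction ray per pixel).
#' @param margin_mm Extra detector margin beyond the magnified footprint.
#' @return A \code{projection_geometry} with the source position, detector
#'   plane height, pixel pitch, grid size, and grid origin.
#' @export
projection_geometry <- function(phantom, sid_mm = 354.6,
                                pixel_pitch_mm = phantom$pitch_mm,
                                margin_mm = 2) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  d <- dim(phantom$labels)
  p <- phantom$pitch_mm
  t <- d[3] * p
  source <- c(0, 0, -sid_mm)
  det_z <- t
  mag <- (sid_mm + t) / sid_mm   # worst case: top-surface voxels
  half_x <- d[1] * p / 2 * mag + margin_mm
  y_max <- d[2] * p * mag + margin_mm
  pp <- pixel_pitch_mm
  nx <- ceiling(2 * half_x / pp)
  ny <- ceiling(y_max / pp)
  structure(list(source_mm = source, det_z_mm = det_z, pixel_pitch_mm = pp,
                 det_nx = nx, det_ny = ny,
                 det_origin_mm = c(-nx * pp / 2, 0),
                 sid_mm = sid_mm),
            class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("<projection_geometry> source (%.4g, %.4g, %.4g) mm, detector z = %.4g mm\n",
              x$source_mm[1], x$source_mm[2], x$source_mm[3], x$det_z_mm))
  cat(sprintf("  %d x %d pixels @ %.3g mm\n", x$det_nx, x$det_ny, x$pixel_pitch_mm))
  invisible(x)
}

# physical centers of all detector pixels (n x 3 matrix, z = det plane)
.pixel_centers <- function(geom) {
  pp <- geom$pixel_pitch_mm
  xs <- geom$det_origin_mm[1] + (seq_len(geom$det_nx) - 0.5) * pp
  ys <- geom$det_origin_mm[2] + (seq_len(geom$det_ny) - 0.5) * pp
  cbind(rep(xs, times = geom$det_ny),
        rep(ys, each = geom$det_nx),
        geom$det_z_mm)
}

.pixel_center <- function(geom, ix, iy) {
  pp <- geom$pixel_pitch_mm
  c(geom$det_origin_mm[1] + (ix - 0.5) * pp,
    geom$det_origin_mm[2] + (iy - 0.5) * pp,
    geom$det_z_mm)
}
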