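# Siddon forward projection: exact ray-voxel traversal from the source to
# each detector pixel, Beer-Lambert primary-beam transmission images, and
# per-pixel glandular-fraction maps.

#' Trace one detector pixel's ray through a phantom
#'
#' Exact Siddon traversal from the source to the center of detector pixel
#' \code{(ix, iy)}: every voxel with positive intersection length appears
#' exactly once, ordered from source to detector.
#'
#' @param geom A [projection_geometry()].
#' @param phantom A \code{voxel_phantom}.
#' @param pixel Integer pair \code{c(ix, iy)} (1-based detector indices).
#' @return A data.frame with columns \code{ix}, \code{iy}, \code{iz}
#'   (1-based voxel indices) and \code{length_mm}; zero rows if the ray
#'   misses the grid.
#' @export
trace_ray <- function(geom, phantom, pixel) {
  stopifnot(inherits(geom, "projection_geometry"),
            inherits(phantom, "voxel_phantom"))
  if (pixel[1] < 1 || pixel[1] > geom$det_nx ||
      pixel[2] < 1 || pixel[2] > geom$det_ny) {
    stop("pixel outside the detector extent", call. = FALSE)
  }
  p1 <- .pixel_center(geom, pixel[1], pixel[2])
  res <- cpp_trace_ray(dim(phantom$labels), phantom$pitch_mm,
                       phantom$origin_mm, geom$source_mm, p1)
  as.data.frame(res)
}

# per-pixel per-material path lengths, det_nx*det_ny x 4 (mm)
.material_path_lengths <- function(phantom, geom) {
  cpp_path_lengths(phantom$labels, dim(phantom$labels), phantom$pitch_mm,
                   phantom$origin_mm, geom$source_mm, .pixel_centers(geom))
}

#' Forward-project a phantom
#'
#' Primary-beam (scatter-free) Beer-Lambert transmission: per pixel,
#' \eqn{\sum_E W_E \exp(-\sum_m \mu_m(E) L_m)} where \eqn{L_m} is the
#' intersection length with material \eqn{m} along the pixel's ray.  The
#' detector is ideal (photon-counting transmission fraction, 1 =
#' unattenuated); set \code{csi_weighting = TRUE} to weight each energy by
#' the absorption of a CsI layer.
#'
#' @param phantom A \code{voxel_phantom}.
#' @param spectrum An \code{energy_spectrum} (energies within 10-30 keV).
#' @param geom A [projection_geometry()].
#' @param csi_weighting Apply CsI detector-absorption weighting (default
#'   FALSE).
#' @param csi_mm CsI layer thickness in mm (used when \code{csi_weighting}).
#' @return A \code{projection_image}: matrix \code{det_nx x det_ny} of
#'   spectrum-weighted transmission plus geometry metadata.
#' @export
forward_project <- function(phantom, spectrum, geom,
                            csi_weighting = FALSE, csi_mm = 0.15) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  L <- .material_path_lengths(phantom, geom)   # n x 4, mm
  E <- spectrum$energies
  w <- spectrum$weights
  if (csi_weighting) {
    mu_csi <- linear_mu("csi", E) / 10
    w <- w * (1 - exp(-mu_csi * csi_mm))
    w <- w / sum(w)
  }
  mats <- c("air", "adipose", "fibroglandular", "skin")
  mu <- vapply(mats, function(m) linear_mu(m, E) / 10, numeric(length(E)))
  if (length(E) == 1L) mu <- matrix(mu, nrow = 1)
  sig <- as.vector(exp(-L %*% t(mu)) %*% w)    # n x nE times w
  img <- matrix(sig, geom$det_nx, geom$det_ny)
  structure(list(image = img, pixel_pitch_mm = geom$pixel_pitch_mm,
                 geom = geom), class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf("<projection_image> %d x %d pixels @ %.3g mm, signal range [%.4g, %.4g]\n",
              nrow(x$image), ncol(x$image), x$pixel_pitch_mm,
              min(x$image), max(x$image)))
  invisible(x)
}

#' Per-pixel glandular-fraction map
#'
#' For each detector pixel, the fibroglandular intersection length along its
#' ray divided by the compressed breast thickness (the idealized "perfect"
#' GF map).  Pixels whose rays meet no tissue are 0.
#'
#' @param phantom A \code{voxel_phantom}.
#' @param geom A [projection_geometry()].
#' @param thickness_mm Compressed thickness used as the denominator
#'   (default: phantom depth extent).
#' @return A \code{gf_map}: matrix \code{det_nx x det_ny} of glandular
#'   fractions plus the thickness and geometry metadata.
#' @export
compute_gf_map <- function(phantom, geom,
                           thickness_mm = dim(phantom$labels)[3] * phantom$pitch_mm) {
  L <- .material_path_lengths(phantom, geom)
  gf <- matrix(L[, 3] / thickness_mm, geom$det_nx, geom$det_ny)
  tissue <- matrix(L[, 2] + L[, 3] + L[, 4] > 0, geom$det_nx, geom$det_ny)
  structure(list(gf = gf, thickness_mm = thickness_mm, tissue = tissue,
                 geom = geom), class = "gf_map")
}

#' @export
print.gf_map <- function(x, ...) {
  cat(sprintf("<gf_map> %d x %d pixels, thickness %.4g mm, GF range [%.3g, %.3g]\n",
              nrow(x$gf), ncol(x$gf), x$thickness_mm, min(x$gf), max(x$gf)))
  invisible(x)
}
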