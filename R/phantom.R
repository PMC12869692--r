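# Voxelized compressed-breast phantoms.  A breast is a half-elliptic prism:
# half-ellipse footprint (semi-axes diameter/2 lateral, chest-wall-to-nipple
# in the anterior direction), flat at the chest-wall plane y = 0, with
# uniform compressed thickness (flat top and bottom, compression-paddle
# geometry).  The outermost voxel shell is skin; the interior is adipose with
# a fibroglandular region concentrated at the top (source side), center, or
# bottom (detector side).  The default fibroglandular region is a half-
# ellipsoid geometrically similar to the interior, scaled by
# lambda = (1.5 GF)^(1/3) and displaced in depth until it touches the
# interior top or bottom surface (or centered); a full-width depth slab is
# available as an alternative shape.
#
# Coordinates (mm): x lateral, centered on 0; y from the chest wall (y = 0)
# toward the nipple; z depth from the top surface (z = 0, source side) down
# to the bottom (z = thickness, detector side).  Voxel centers sit at
# origin + (index - 0.5) * pitch for 1-based indices.

#' Breast phantom specification
#'
#' @param diameter_cm Lateral diameter including skin, cm.
#' @param thickness_cm Compressed thickness including skin, cm.
#' @param cw_nipple_cm Chest-wall-to-nipple distance including skin, cm
#'   (defaults to \code{diameter_cm / 2}).
#' @param glandular_fraction Fibroglandular volume fraction of the interior
#'   (skin excluded), in \code{[0, 1]}.
#' @param placement One of \code{"top"}, \code{"center"}, \code{"bottom"}:
#'   where the fibroglandular region is concentrated in depth.
#' @param fg_shape \code{"ellipsoid"} (default): the fibroglandular region is
#'   a half-ellipsoid geometrically similar to the breast interior, scaled to
#'   the requested volume fraction and displaced in depth; \code{"slab"}: a
#'   full-width depth-contiguous stack of interior layers.
#' @param skin_mm Nominal skin thickness in mm (default 1.45; rounded to the
#'   nearest whole number of voxel layers when the phantom is built).
#' @param pitch_mm Voxel pitch in mm (default 1).
#' @return A \code{breast_spec} object.
#' @export
breast_spec <- function(diameter_cm, thickness_cm,
                        cw_nipple_cm = diameter_cm / 2,
                        glandular_fraction = 0.2,
                        placement = c("top", "center", "bottom"),
                        fg_shape = c("ellipsoid", "slab"),
                        skin_mm = 1.45, pitch_mm = 1) {
  placement <- match.arg(placement)
  fg_shape <- match.arg(fg_shape)
  if (glandular_fraction < 0 || glandular_fraction > 1) {
    stop("glandular_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(diameter_cm, thickness_cm, cw_nipple_cm) * 10 <= 2 * skin_mm)) {
    stop("breast dimensions must exceed twice the skin thickness", call. = FALSE)
  }
  if (pitch_mm <= 0) stop("pitch_mm must be positive", call. = FALSE)
  structure(list(diameter_cm = diameter_cm, thickness_cm = thickness_cm,
                 cw_nipple_cm = cw_nipple_cm,
                 glandular_fraction = glandular_fraction,
                 placement = placement, fg_shape = fg_shape,
                 skin_mm = skin_mm, pitch_mm = pitch_mm),
            class = "breast_spec")
}

#' @export
print.breast_spec <- function(x, ...) {
  cat(sprintf("<breast_spec> %.4g x %.4g cm (cw-nipple %.4g cm), GF %.0f%%, FG at %s\n",
              x$diameter_cm, x$thickness_cm, x$cw_nipple_cm,
              100 * x$glandular_fraction, x$placement))
  invisible(x)
}

.new_phantom <- function(labels, pitch_mm, origin_mm, spec = NULL) {
  structure(list(labels = labels, pitch_mm = pitch_mm, origin_mm = origin_mm,
                 spec = spec),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  n <- tabulate(as.vector(x$labels) + 1L, nbins = 4L)
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels @ %.3g mm\n", d[1], d[2], d[3],
              x$pitch_mm))
  cat(sprintf("  air %d | adipose %d | fibroglandular %d | skin %d\n",
              n[1], n[2], n[3], n[4]))
  invisible(x)
}

# erode a 2-D logical mask by one voxel (4-connectivity); cells beyond the
# chest-wall edge (y < 1) count as inside, so no skin forms on that face
.erode_xy <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- mask
  pad[, 1L] <- pad[, 2L]  # chest-wall face: replicate, not background
  m <- pad[2:(nx + 1L), 2:(ny + 1L)]
  m & pad[1:nx, 2:(ny + 1L)] & pad[3:(nx + 2L), 2:(ny + 1L)] &
    pad[2:(nx + 1L), 1:ny] & pad[2:(nx + 1L), 3:(ny + 2L)]
}

#' Build a voxelized breast phantom
#'
#' Realizes a [breast_spec()] on a voxel grid.  The footprint is the
#' half-ellipse with semi-axes \code{diameter/2} (lateral) and
#' \code{cw_nipple} (chest wall to nipple), flat at the chest-wall plane; the
#' thickness is uniform.  The outermost shell (lateral boundary plus top and
#' bottom layers, but not the chest-wall cut plane) is skin, rounded to the
#' nearest whole number of voxel layers.
#'
#' With the default \code{fg_shape = "ellipsoid"}, the fibroglandular region
#' is the half-ellipsoid \eqn{(x/\lambda a')^2 + (y/\lambda b')^2 +
#' ((z - z_c)/\lambda c')^2 \le 1} (anchored at the chest wall like the
#' breast itself), where \eqn{a', b', c'} are the interior semi-axes and the
#' scale \eqn{\lambda} is chosen on the voxel grid so the fibroglandular
#' voxel count best matches the requested volume fraction (continuum value
#' \eqn{\lambda = (1.5\,\mathrm{GF})^{1/3}}).  The depth center \eqn{z_c} is
#' set so the region touches the interior top surface (\code{"top"}), the
#' interior bottom surface (\code{"bottom"}), or is centered in depth
#' (\code{"center"}).  With \code{fg_shape = "slab"}, fibroglandular voxels
#' instead fill whole interior depth layers at the chosen placement.
#'
#' @param spec A [breast_spec()].
#' @return A \code{voxel_phantom}: integer label array (0 air, 1 adipose,
#'   2 fibroglandular, 3 skin) with voxel pitch and physical origin.
#' @export
build_breast <- function(spec) {
  stopifnot(inherits(spec, "breast_spec"))
  p <- spec$pitch_mm
  D <- spec$diameter_cm * 10; t <- spec$thickness_cm * 10
  b <- spec$cw_nipple_cm * 10
  nx <- round(D / p); ny <- round(b / p); nz <- round(t / p)
  s <- max(1L, round(spec$skin_mm / p))          # skin layers
  origin <- c(-nx * p / 2, 0, 0)

  xc <- origin[1] + (seq_len(nx) - 0.5) * p
  yc <- (seq_len(ny) - 0.5) * p
  a <- D / 2
  foot <- outer(xc, yc, function(x, y) (x / a)^2 + (y / b)^2 <= 1)
  if (!any(foot)) stop("degenerate footprint", call. = FALSE)

  interior_xy <- foot
  for (i in seq_len(s)) interior_xy <- .erode_xy(interior_xy)

  labels <- array(0L, dim = c(nx, ny, nz))
  z_interior <- seq.int(s + 1L, nz - s)
  if (length(z_interior) < 1L || !any(interior_xy)) {
    stop("phantom has no interior: dimensions too small for the skin shell",
         call. = FALSE)
  }
  # tissue everywhere in the footprint; skin where not interior
  for (iz in seq_len(nz)) {
    sl <- matrix(0L, nx, ny)
    if (iz %in% z_interior) {
      sl[foot] <- 3L
      sl[interior_xy] <- 1L
    } else {
      sl[foot] <- 3L
    }
    labels[, , iz] <- sl
  }

  gf <- spec$glandular_fraction
  if (identical(spec$fg_shape, "slab")) {
    # fibroglandular slab: whole interior z-layers, count chosen to best
    # match the requested volume fraction (every layer has the same area)
    nzi <- length(z_interior)
    n_fg <- round(gf * nzi)
    if (gf > 0 && n_fg == 0L) n_fg <- 1L
    if (gf == 0) n_fg <- 0L
    if (n_fg > nzi) {
      stop("requested glandular fraction unattainable within the interior",
           call. = FALSE)
    }
    if (n_fg > 0L) {
      fg_layers <- switch(spec$placement,
        top = z_interior[seq_len(n_fg)],
        bottom = z_interior[seq.int(nzi - n_fg + 1L, nzi)],
        center = {
          mid <- (z_interior[1] + z_interior[nzi]) / 2
          ord <- z_interior[order(abs(z_interior - mid), z_interior)]
          sort(ord[seq_len(n_fg)])
        })
      for (iz in fg_layers) {
        sl <- labels[, , iz]
        sl[sl == 1L] <- 2L
        labels[, , iz] <- sl
      }
    }
  } else if (gf > 0) {
    # half-ellipsoid fibroglandular region, similar to the interior and
    # scaled by lambda.  For each interior voxel the smallest lambda whose
    # region contains it has a closed form, so picking the k voxels with the
    # smallest thresholds realizes the best-matching region exactly.
    idx <- which(labels == 1L)
    ai <- arrayInd(idx, dim(labels))
    vx <- origin[1] + (ai[, 1] - 0.5) * p
    vy <- (ai[, 2] - 0.5) * p
    vz <- (ai[, 3] - 0.5) * p
    a_int <- a - s * p
    b_int <- b - s * p
    zt <- s * p
    zb <- nz * p - s * p
    c_int <- (zb - zt) / 2
    q <- (vx / a_int)^2 + (vy / b_int)^2
    # membership for scale lambda and depth center z_c:
    #   q / lambda^2 + ((z - z_c) / (lambda c'))^2 <= 1
    # top:    z_c = zt + lambda c'  ->  lambda >= (q + w^2) / (2 w), w = (z-zt)/c'
    # bottom: mirror of top
    # center: z_c = (zt+zb)/2      ->  lambda >= sqrt(q + (w-1)^2)
    lam <- switch(spec$placement,
      top = {
        w <- (vz - zt) / c_int
        (q + w^2) / (2 * w)
      },
      bottom = {
        w <- (zb - vz) / c_int
        (q + w^2) / (2 * w)
      },
      center = {
        w <- (vz - zt) / c_int
        sqrt(q + (w - 1)^2)
      })
    k <- min(length(idx), max(1L, round(gf * length(idx))))
    pick <- order(lam, idx)[seq_len(k)]
    labels[idx[pick]] <- 2L
  }
  .new_phantom(labels, p, origin, spec)
}

#' Achieved interior glandular fraction
#'
#' Fibroglandular voxel count divided by the interior (fibroglandular +
#' adipose) voxel count.
#'
#' @param phantom A \code{voxel_phantom}.
#' @return Volume fraction in \code{[0, 1]}.
#' @export
achieved_gf <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  n_fg <- sum(phantom$labels == 2L)
  n_ad <- sum(phantom$labels == 1L)
  if (n_fg + n_ad == 0L) {
    stop("phantom has no interior tissue voxels", call. = FALSE)
  }
  n_fg / (n_fg + n_ad)
}

#' Baseline study geometries
#'
#' The 18 baseline cases: four breast sizes (diameters 11.29-14.29 cm,
#' thicknesses 3.29-6.29 cm, chest-wall-to-nipple = diameter/2) at 20%
#' glandular fraction plus the 12.29 cm size at 30% and 50%, each with the
#' fibroglandular region at top, center, and bottom.
#'
#' @return List of 18 [breast_spec()] objects.
#' @export
table1_presets <- function() {
  sizes <- data.frame(
    diameter = c(11.29, 12.29, 13.29, 14.29),
    thickness = c(3.29, 4.29, 5.29, 6.29))
  cases <- rbind(
    cbind(sizes, gf = 0.20),
    data.frame(diameter = 12.29, thickness = 4.29, gf = c(0.30, 0.50)))
  out <- list()
  for (i in seq_len(nrow(cases))) {
    for (pl in c("top", "center", "bottom")) {
      out[[length(out) + 1L]] <- breast_spec(
        diameter_cm = cases$diameter[i], thickness_cm = cases$thickness[i],
        glandular_fraction = cases$gf[i], placement = pl)
    }
  }
  out
}
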