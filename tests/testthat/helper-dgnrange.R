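# Shared fixtures, memoized so expensive objects are built once per test run.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

test_beam <- function() .memo("beam", default_beam())

# small fast phantom for unit tests (60 x 30 x 24 voxels)
small_phantom <- function(placement = "center") {
  .memo(paste0("small_", placement),
        build_breast(breast_spec(6, 2.4, glandular_fraction = 0.25,
                                 placement = placement)))
}

small_geom <- function() .memo("small_geom", projection_geometry(small_phantom()))

# dense-sampling reference for Siddon: walk the ray in fine steps and
# accumulate per-voxel chord lengths by point-in-voxel lookup
dense_path_lengths <- function(phantom, geom, pixel, step_mm = 0.02) {
  p0 <- geom$source_mm
  p1 <- c(geom$det_origin_mm[1] + (pixel[1] - 0.5) * geom$pixel_pitch_mm,
          geom$det_origin_mm[2] + (pixel[2] - 0.5) * geom$pixel_pitch_mm,
          geom$det_z_mm)
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  u <- d / len
  ts <- seq(step_mm / 2, len, by = step_mm)
  pts <- cbind(p0[1] + ts * u[1], p0[2] + ts * u[2], p0[3] + ts * u[3])
  dims <- dim(phantom$labels)
  pitch <- phantom$pitch_mm
  org <- c(phantom$origin_mm[1], phantom$origin_mm[2], 0)
  ix <- floor((pts[, 1] - org[1]) / pitch) + 1
  iy <- floor((pts[, 2] - org[2]) / pitch) + 1
  iz <- floor((pts[, 3] - org[3]) / pitch) + 1
  ok <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] &
    iz >= 1 & iz <= dims[3]
  if (!any(ok)) return(data.frame(ix = integer(), iy = integer(),
                                  iz = integer(), length_mm = numeric()))
  key <- paste(ix[ok], iy[ok], iz[ok])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  data.frame(ix = as.integer(parts[, 1]), iy = as.integer(parts[, 2]),
             iz = as.integer(parts[, 3]),
             length_mm = as.numeric(tab) * step_mm)
}
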