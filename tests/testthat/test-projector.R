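test_that("detector grid covers the magnified footprint", {
  ph <- small_phantom()
  g <- small_geom()
  d <- dim(ph$labels)
  mag <- (g$sid_mm + d[3] * ph$pitch_mm) / g$sid_mm
  expect_gte(g$det_nx * g$pixel_pitch_mm, d[1] * ph$pitch_mm * mag)
  expect_gte(g$det_ny * g$pixel_pitch_mm, d[2] * ph$pitch_mm * mag)
  expect_equal(g$source_mm, c(0, 0, -354.6))
  expect_equal(g$det_z_mm, d[3] * ph$pitch_mm)
})

test_that("Siddon traversal matches dense sampling on random rays", {
  ph <- small_phantom()
  g <- small_geom()
  set.seed(7)
  for (k in 1:6) {
    px <- c(sample(g$det_nx, 1), sample(g$det_ny, 1))
    tr <- trace_ray(g, ph, px)
    dn <- dense_path_lengths(ph, g, px, step_mm = 0.02)
    key_t <- paste(tr$ix, tr$iy, tr$iz)
    key_d <- paste(dn$ix, dn$iy, dn$iz)
    # total in-grid path agrees to the sampling resolution
    expect_equal(sum(tr$length_mm), sum(dn$length_mm), tolerance = 0.005)
    # per-voxel: every voxel with length above the step size is found by both
    big_t <- key_t[tr$length_mm > 0.05]
    big_d <- key_d[dn$length_mm > 0.05]
    expect_true(all(big_t %in% key_d))
    expect_true(all(big_d %in% key_t))
    common <- intersect(key_t, key_d)
    lt <- tr$length_mm[match(common, key_t)]
    ld <- dn$length_mm[match(common, key_d)]
    expect_lt(max(abs(lt - ld)), 0.05)
  }
})

test_that("each traversed voxel appears once, ordered source to detector", {
  ph <- small_phantom()
  g <- small_geom()
  tr <- trace_ray(g, ph, c(round(g$det_nx / 2), 5))
  expect_gt(nrow(tr), 0)
  expect_false(any(duplicated(tr[, c("ix", "iy", "iz")])))
  expect_true(all(diff(tr$iz) >= 0))  # source above, detector below
  expect_true(all(tr$length_mm > 0))
  expect_lte(max(tr$length_mm), sqrt(3) * ph$pitch_mm + 1e-9)
})

test_that("rays that miss the grid return zero rows and bad pixels error", {
  ph <- small_phantom()
  g <- small_geom()
  expect_error(trace_ray(g, ph, c(0, 1)), "pixel")
  expect_error(trace_ray(g, ph, c(g$det_nx + 1, 1)), "pixel")
})

test_that("uniform slab transmission matches Beer-Lambert with obliquity", {
  # all-tissue phantom: replace every occupied voxel with adipose
  ph <- small_phantom()
  ph2 <- ph
  ph2$labels[ph2$labels > 0L] <- 1L
  g <- projection_geometry(ph2)
  E <- 20
  img <- forward_project(ph2, energy_spectrum(E, 1), g)$image
  px <- c(round(g$det_nx / 2), 4)   # central, near chest wall
  tr <- trace_ray(g, ph2, px)
  lab <- ph2$labels[cbind(tr$ix, tr$iy, tr$iz)]
  in_tissue <- sum(tr$length_mm[lab == 1L])
  in_air <- sum(tr$length_mm[lab == 0L])
  expected <- exp(-(linear_mu("adipose", E) * in_tissue +
                      linear_mu("air", E) * in_air) / 10)
  expect_equal(img[px[1], px[2]], expected, tolerance = 1e-9)
  # hand value: path = thickness / cos(theta) for this pixel's ray
  p1 <- c(g$det_origin_mm[1] + (px[1] - 0.5), g$det_origin_mm[2] + (px[2] - 0.5),
          g$det_z_mm)
  ct <- (g$det_z_mm - g$source_mm[3]) / sqrt(sum((p1 - g$source_mm)^2))
  t_mm <- dim(ph2$labels)[3] * ph2$pitch_mm
  expect_equal(in_tissue, t_mm / ct, tolerance = 1e-6)
})

test_that("projection images lie in (0, 1] and air pixels are 1", {
  ph <- small_phantom()
  img <- forward_project(ph, test_beam(), small_geom())$image
  expect_true(all(img > 0 & img <= 1 + 1e-12))
  expect_gt(max(img), 0.97)  # rays missing the breast see only air
})

test_that("top and bottom placements give near-identical projections", {
  pt <- build_breast(breast_spec(8, 3, glandular_fraction = 0.25,
                                 placement = "top"))
  pb <- build_breast(breast_spec(8, 3, glandular_fraction = 0.25,
                                 placement = "bottom"))
  g <- projection_geometry(pt)
  it <- forward_project(pt, test_beam(), g)$image
  ib <- forward_project(pb, test_beam(), g)$image
  rel <- abs(it - ib) / pmax(it, ib)
  tis <- compute_gf_map(pt, g)$tissue
  expect_lt(median(rel[tis]), 1e-9)          # vertical rays identical
  expect_gt(mean(rel[tis] <= 0.01), 0.75)    # oblique edge rays differ a little
})

test_that("CsI weighting softens the effective detected spectrum", {
  ph <- small_phantom()
  g <- small_geom()
  plain <- forward_project(ph, test_beam(), g)$image
  csi <- forward_project(ph, test_beam(), g, csi_weighting = TRUE)$image
  expect_false(isTRUE(all.equal(plain, csi)))
  # CsI absorbs low energies preferentially, so tissue looks more opaque
  tis <- compute_gf_map(ph, g)$tissue
  expect_lt(mean(csi[tis]), mean(plain[tis]))
})

test_that("GF map equals fibroglandular path over thickness", {
  ph <- small_phantom()
  g <- small_geom()
  gm <- compute_gf_map(ph, g)
  t_mm <- dim(ph$labels)[3] * ph$pitch_mm
  expect_equal(gm$thickness_mm, t_mm)
  px <- c(round(g$det_nx / 2), 6)
  tr <- trace_ray(g, ph, px)
  fg_len <- sum(tr$length_mm[ph$labels[cbind(tr$ix, tr$iy, tr$iz)] == 2L])
  expect_equal(gm$gf[px[1], px[2]], fg_len / t_mm, tolerance = 1e-9)
  expect_true(all(gm$gf >= 0 & gm$gf <= 1 + 1e-9))
})

test_that("GF map integral is consistent with the fibroglandular volume", {
  ph <- build_breast(breast_spec(11.29, 3.29, glandular_fraction = 0.2))
  g <- projection_geometry(ph)
  gm <- compute_gf_map(ph, g)
  t_mm <- dim(ph$labels)[3] * ph$pitch_mm
  # sum(gf) * pixel_area * thickness ~ FG volume x magnification^2 at the
  # FG centroid (divergent beam)
  fg_idx <- which(ph$labels == 2L, arr.ind = TRUE)
  z_bar <- mean(fg_idx[, 3] - 0.5) * ph$pitch_mm
  mag <- (g$sid_mm + t_mm) / (g$sid_mm + z_bar)
  vol_map <- sum(gm$gf) * g$pixel_pitch_mm^2 * t_mm
  vol_fg <- nrow(fg_idx) * ph$pitch_mm^3 * mag^2
  expect_equal(vol_map, vol_fg, tolerance = 0.02)
})

test_that("slab phantom GF map is near-uniform over the interior", {
  ph <- build_breast(breast_spec(11.29, 3.29, glandular_fraction = 0.2,
                                 fg_shape = "slab"))
  g <- projection_geometry(ph)
  gm <- compute_gf_map(ph, g)
  # interior pixel: 20% of the 31 mm interior = 6 layers over 33 mm thickness
  ctr <- gm$gf[round(g$det_nx / 2), 8]
  expect_gt(ctr, 0.17)
  expect_lt(ctr, 0.20)
})
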