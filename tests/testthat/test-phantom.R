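test_that("nominal grid size follows nearest-voxel rounding of the dimensions", {
  ph <- build_breast(breast_spec(11.29, 3.29))
  expect_equal(dim(ph$labels), c(113L, 56L, 33L))
  expect_equal(ph$pitch_mm, 1)
  expect_equal(ph$origin_mm[1], -113 / 2)
})

test_that("labels are restricted to the four tissue codes", {
  ph <- small_phantom()
  expect_true(all(ph$labels %in% 0:3))
})

test_that("skin forms the outer shell but not the chest-wall face", {
  ph <- build_breast(breast_spec(11.29, 3.29))
  d <- dim(ph$labels)
  # top and bottom layers of the footprint are skin
  expect_true(all(ph$labels[, , 1][ph$labels[, , 1] > 0] == 3L))
  expect_true(all(ph$labels[, , d[3]][ph$labels[, , d[3]] > 0] == 3L))
  # chest-wall face (iy = 1) exposes interior tissue at mid-depth
  face <- ph$labels[, 1, ceiling(d[3] / 2)]
  expect_true(any(face == 1L | face == 2L))
  # nipple-most occupied column is skin all the way through
  iy_max <- max(which(apply(ph$labels > 0, 2, any)))
  expect_true(all(ph$labels[, iy_max, ][ph$labels[, iy_max, ] > 0] == 3L))
})

test_that("achieved glandular fraction matches the request to one voxel", {
  for (gf in c(0.2, 0.3, 0.5)) {
    ph <- build_breast(breast_spec(12.29, 4.29, glandular_fraction = gf))
    n_int <- sum(ph$labels == 1L) + sum(ph$labels == 2L)
    expect_lt(abs(achieved_gf(ph) - gf), 1 / n_int + 1e-12)
  }
})

test_that("slab shape achieves the fraction within layer rounding", {
  ph <- build_breast(breast_spec(11.29, 3.29, glandular_fraction = 0.2,
                                 fg_shape = "slab"))
  expect_lt(abs(achieved_gf(ph) - 0.2), 0.5 / 31)
})

test_that("top and bottom placements are exact depth mirrors", {
  for (shape in c("ellipsoid", "slab")) {
    pt <- build_breast(breast_spec(8, 3, glandular_fraction = 0.25,
                                   placement = "top", fg_shape = shape))
    pb <- build_breast(breast_spec(8, 3, glandular_fraction = 0.25,
                                   placement = "bottom", fg_shape = shape))
    flipped <- pb$labels[, , dim(pb$labels)[3]:1]
    expect_identical(flipped == 2L, pt$labels == 2L)
  }
})

test_that("placements differ only in fibroglandular position", {
  specs <- lapply(c("top", "center", "bottom"), function(pl) {
    build_breast(breast_spec(8, 3, glandular_fraction = 0.25, placement = pl))
  })
  tissue <- lapply(specs, function(p) p$labels == 1L | p$labels == 2L)
  expect_identical(tissue[[1]], tissue[[2]])
  expect_identical(tissue[[1]], tissue[[3]])
  skin <- lapply(specs, function(p) p$labels == 3L)
  expect_identical(skin[[1]], skin[[2]])
})

test_that("fibroglandular depth ordering matches the placement", {
  mean_z <- vapply(c("top", "center", "bottom"), function(pl) {
    ph <- build_breast(breast_spec(8, 3, glandular_fraction = 0.25,
                                   placement = pl))
    mean(which(ph$labels == 2L, arr.ind = TRUE)[, 3])
  }, 0)
  expect_lt(mean_z[["top"]], mean_z[["center"]])
  expect_lt(mean_z[["center"]], mean_z[["bottom"]])
})

test_that("fibroglandular volume grows monotonically with the request", {
  counts <- vapply(c(0.1, 0.2, 0.3, 0.5), function(gf) {
    sum(build_breast(breast_spec(8, 3, glandular_fraction = gf))$labels == 2L)
  }, 0)
  expect_true(all(diff(counts) > 0))
})

test_that("the fibroglandular region touches the chest wall but stays interior", {
  ph <- build_breast(breast_spec(11.29, 3.29, glandular_fraction = 0.2,
                                 placement = "top"))
  fg <- which(ph$labels == 2L, arr.ind = TRUE)
  expect_true(any(fg[, 2] == 1L))            # present at the chest-wall face
  expect_true(all(ph$labels[fg] == 2L))
  # FG never overwrites skin or air
  adj <- ph$labels
  adj[adj == 2L] <- 1L
  expect_true(all(adj %in% c(0L, 1L, 3L)))
})

test_that("the baseline presets enumerate 18 cases", {
  pres <- table1_presets()
  expect_length(pres, 18L)
  gfs <- vapply(pres, function(s) s$glandular_fraction, 0)
  expect_equal(sort(unique(gfs)), c(0.2, 0.3, 0.5))
  expect_equal(sum(gfs == 0.2), 12L)
  pls <- vapply(pres, function(s) s$placement, "")
  expect_equal(sum(pls == "top"), 6L)
  cw <- vapply(pres, function(s) s$cw_nipple_cm, 0)
  di <- vapply(pres, function(s) s$diameter_cm, 0)
  expect_equal(cw, di / 2)
})

test_that("invalid specifications are rejected", {
  expect_error(breast_spec(11.29, 3.29, glandular_fraction = 1.2), "\\[0, 1\\]")
  expect_error(breast_spec(0.2, 0.2), "skin")
  expect_error(breast_spec(11.29, 3.29, pitch_mm = 0), "pitch")
})

test_that("gf = 0 builds an all-adipose interior and gf = 1 fills it", {
  p0 <- build_breast(breast_spec(8, 3, glandular_fraction = 0))
  expect_equal(sum(p0$labels == 2L), 0L)
  p1 <- build_breast(breast_spec(8, 3, glandular_fraction = 1))
  expect_equal(sum(p1$labels == 1L), 0L)
})
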