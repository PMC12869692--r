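test_that("spectrum weights are normalized, non-negative, strictly increasing energies", {
  s <- test_beam()
  expect_equal(sum(s$weights), 1, tolerance = 1e-9)
  expect_true(all(s$weights >= 0))
  expect_equal(s$energies, seq(13, 27, by = 2))
  expect_true(all(diff(s$energies) == 2))
})

test_that("constructor validates inputs", {
  expect_error(energy_spectrum(c(10, 20), c(1, 1, 1)), "equal length")
  expect_error(energy_spectrum(c(10, 20), c(1, -1)), "non-negative")
  expect_error(energy_spectrum(c(20, 10), c(1, 1)), "increasing")
  expect_error(energy_spectrum(c(10, 20), c(0, 0)), "zero total weight")
})

test_that("modeled spectrum vanishes above the tube potential", {
  s <- model_spectrum(kvp = 30, al_thickness_mm = 0.7)
  expect_true(all(s$weights[s$energies >= 30] == 0))
  expect_true(all(s$weights[s$energies < 30] > 0))
})

test_that("more filtration hardens the beam", {
  m1 <- mean_energy(bin_spectrum(model_spectrum(30, 0.3)))
  m2 <- mean_energy(bin_spectrum(model_spectrum(30, 0.7)))
  m3 <- mean_energy(bin_spectrum(model_spectrum(30, 1.5)))
  expect_true(m1 < m2 && m2 < m3)
})

test_that("default binned beam has a plausible mammographic mean energy", {
  expect_gt(mean_energy(test_beam()), 17)
  expect_lt(mean_energy(test_beam()), 23)
})

test_that("uniform fine spectrum bins to uniform weights", {
  # four 0.5 keV samples per 2 keV half-open bin, all of weight 1
  E <- seq(12.25, 27.75, by = 0.5)
  s <- energy_spectrum(E, rep(1, length(E)))
  b <- bin_spectrum(s, 13, 27, 2)
  expect_equal(b$weights, rep(1 / 8, 8), tolerance = 1e-12)
})

test_that("binned weights equal brute-force per-bin sums", {
  s <- model_spectrum(30, 0.7)
  b <- bin_spectrum(s, 13, 27, 2)
  in_span <- s$energies >= 12 & s$energies < 28
  manual <- vapply(seq(13, 27, by = 2), function(ctr) {
    sum(s$weights[s$energies >= ctr - 1 & s$energies < ctr + 1])
  }, 0) / sum(s$weights[in_span])
  expect_equal(b$weights, manual, tolerance = 1e-12)
})

test_that("bin edges are half-open toward the upper bin", {
  s <- energy_spectrum(c(13.9, 14.0, 14.1), c(1, 1, 1))
  b <- bin_spectrum(s, 13, 27, 2)
  # 13.9 -> bin 13; 14.0 and 14.1 -> bin 15
  expect_equal(b$weights[1], 1 / 3, tolerance = 1e-12)
  expect_equal(b$weights[2], 2 / 3, tolerance = 1e-12)
})

test_that("spectrum CSV round trip preserves energies and weights", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  s <- test_beam()
  save_spectrum_csv(s, tmp)
  s2 <- load_spectrum_csv(tmp)
  expect_equal(s2$energies, s$energies)
  expect_equal(s2$weights, s$weights, tolerance = 1e-12)
})

test_that("invalid spectrum CSV rows are rejected with row numbers", {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  writeLines(c("energy_keV,weight", "13,0.5", "15,-0.2"), tmp)
  expect_error(load_spectrum_csv(tmp), "row")
})

test_that("model_spectrum validates parameters", {
  expect_error(model_spectrum(kvp = 60), "kvp")
  expect_error(model_spectrum(30, al_thickness_mm = -1), "al_thickness_mm")
})
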