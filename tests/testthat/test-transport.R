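# A 3-energy spectrum keeps the Monte Carlo tests fast.
tri_beam <- function() energy_spectrum(c(15, 20, 25), c(0.3, 0.4, 0.3))

test_that("transport configuration is validated", {
  expect_error(transport_config(photons_per_bin = 0), "photons_per_bin")
  expect_error(transport_config(photons_per_bin = 100, batches = 7), "batches")
})

test_that("a phantom without fibroglandular tissue cannot be dose-scored", {
  ph <- build_breast(breast_spec(6, 2.4, glandular_fraction = 0))
  g <- projection_geometry(ph)
  cfg <- transport_config(photons_per_bin = 100, rng_seed = 1)
  expect_error(run_monte_carlo(ph, tri_beam(), g, cfg), "fibroglandular")
  cfg$score_dose <- FALSE
  r <- run_monte_carlo(ph, tri_beam(), g, cfg)
  expect_equal(r$d_e, rep(0, 3))
})

test_that("the energy ledger balances exactly", {
  ph <- small_phantom()
  g <- small_geom()
  cfg <- transport_config(photons_per_bin = 5000, rng_seed = 3)
  r <- run_monte_carlo(ph, tri_beam(), g, cfg)
  expect_equal(r$dep_total_kev + r$escaped_kev, r$emitted_kev,
               tolerance = 1e-9)
  expect_true(all(r$dep_fg_kev >= 0))
  expect_true(all(rowSums(r$dep_fg_kev) <= r$dep_total_kev + 1e-9))
})

test_that("fixed seeds reproduce bit-identical results", {
  ph <- small_phantom()
  g <- small_geom()
  cfg <- transport_config(photons_per_bin = 2000, rng_seed = 11)
  r1 <- run_monte_carlo(ph, tri_beam(), g, cfg)
  r2 <- run_monte_carlo(ph, tri_beam(), g, cfg)
  expect_identical(r1$dep_fg_kev, r2$dep_fg_kev)
  expect_identical(r1$n_kerma, r2$n_kerma)
  cfg$rng_seed <- 12L
  r3 <- run_monte_carlo(ph, tri_beam(), g, cfg)
  expect_false(identical(r1$dep_fg_kev, r3$dep_fg_kev))
})

test_that("scatter-off Monte Carlo agrees with the primary-dose oracle at 3 sigma", {
  ph <- small_phantom()
  g <- small_geom()
  cfg <- transport_config(photons_per_bin = 40000, rng_seed = 5,
                          scatter_enabled = FALSE)
  mc <- run_monte_carlo(ph, tri_beam(), g, cfg)
  oracle <- primary_dose_oracle(ph, tri_beam(), g, cfg, cell_mm = 0.5)
  # d_e is the sum over batches, so its standard error is sd(batch) * sqrt(n)
  db <- dgnrange:::.dose_batches(mc)
  se <- apply(db, 1, sd) * sqrt(ncol(db))
  expect_true(all(abs(mc$d_e - oracle$d_e) <= 3 * se + 1e-15))
  # kerma-plane counts agree within Poisson-scale tolerance
  expect_true(all(abs(mc$n - oracle$n) <= 4 * sqrt(pmax(oracle$n, 1))))
})

test_that("scatter builds up fibroglandular dose", {
  ph <- small_phantom()
  g <- small_geom()
  cfg_on <- transport_config(photons_per_bin = 20000, rng_seed = 9)
  cfg_off <- transport_config(photons_per_bin = 20000, rng_seed = 9,
                              scatter_enabled = FALSE)
  on <- run_monte_carlo(ph, tri_beam(), g, cfg_on)
  off <- run_monte_carlo(ph, tri_beam(), g, cfg_off)
  expect_true(all(on$d_e > off$d_e))
})

test_that("the entrance kerma matches the hand-computed anchor", {
  # 9e6 photons of 20 keV through 9 cm^2 of dry air give 1.727e-6 Gy
  k <- tally_entrance_kerma(list(energies = 20, n = 9e6))
  expect_equal(k, 1.727e-6, tolerance = 0.005)
  # linear in count and area
  expect_equal(tally_entrance_kerma(list(energies = 20, n = 4.5e6)), k / 2,
               tolerance = 1e-12)
  expect_equal(tally_entrance_kerma(list(energies = 20, n = 9e6),
                                    area_cm2 = 18), k / 2, tolerance = 1e-12)
})

test_that("kerma-plane counts respond to the scoring rectangle", {
  ph <- small_phantom()
  g <- small_geom()
  cfg_small <- transport_config(photons_per_bin = 5000, rng_seed = 2,
                                kerma_rect_mm = c(-5, 5, 0, 10))
  cfg_big <- transport_config(photons_per_bin = 5000, rng_seed = 2,
                              kerma_rect_mm = c(-30, 30, 0, 30))
  n_small <- run_monte_carlo(ph, tri_beam(), g, cfg_small)$n
  n_big <- run_monte_carlo(ph, tri_beam(), g, cfg_big)$n
  expect_true(all(n_big >= n_small))
  expect_true(all(n_big <= cfg_big$photons_per_bin))
})

test_that("dose CSV export round-trips the per-bin table", {
  ph <- small_phantom()
  g <- small_geom()
  cfg <- transport_config(photons_per_bin = 2000, rng_seed = 4)
  r <- run_monte_carlo(ph, tri_beam(), g, cfg)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  save_dose_csv(r, tmp)
  tab <- read.csv(tmp)
  expect_equal(tab$energy_keV, r$energies)
  expect_equal(tab$D_E_Gy, r$d_e, tolerance = 1e-12)
  expect_equal(tab$N, r$n)
  expect_equal(tab$K_E_Gy, tally_entrance_kerma(r), tolerance = 1e-12)
})
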