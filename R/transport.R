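# Desk-scale photon Monte Carlo: analog transport of the binned beam through
# the voxel phantom with photoelectric absorption, Klein-Nishina Compton
# scatter, and Rayleigh (Thomson-angle) scatter, scoring energy deposited in
# fibroglandular tissue under the kerma approximation (sub-0.02 mm electron
# ranges at these energies) and tallying entrance-plane photons for the air
# kerma normalization.

KEV_TO_J <- 1.602176634e-16

#' Transport configuration
#'
#' @param photons_per_bin Photon histories per energy bin (default 1e5).
#' @param rng_seed Integer seed; every run is bit-reproducible for a fixed
#'   seed.
#' @param batches Number of history batches used for standard-error
#'   estimation (must divide \code{photons_per_bin}).
#' @param scatter_enabled If FALSE, run in collision-kerma mode: at the first
#'   interaction the expected locally absorbed energy
#'   \eqn{E \mu_{en}/\mu} is deposited and the history ends.  This mode's
#'   expectation equals the deterministic primary-beam oracle and exists for
#'   validation.
#' @param rayleigh_enabled Include Rayleigh scatter (default TRUE).
#' @param kerma_rect_mm Entrance kerma scoring rectangle
#'   \code{c(x0, x1, y0, y1)} in mm on the plane just above the phantom;
#'   default the 3 cm x 3 cm region against the chest wall, centered
#'   laterally on the beam axis.
#' @param score_dose Require fibroglandular voxels and score dose (default
#'   TRUE).  With FALSE, a phantom without fibroglandular tissue is allowed
#'   and its dose is reported as zero.
#' @param e_cut_kev Photon cutoff energy; photons degraded below it deposit
#'   locally (default 10, the lower edge of the cross-section tables).
#' @return A \code{transport_config}.
#' @export
transport_config <- function(photons_per_bin = 1e5, rng_seed = 1L,
                             batches = 20L, scatter_enabled = TRUE,
                             rayleigh_enabled = TRUE,
                             kerma_rect_mm = c(-15, 15, 0, 30),
                             score_dose = TRUE, e_cut_kev = 10) {
  if (photons_per_bin < 1) stop("photons_per_bin must be >= 1", call. = FALSE)
  if (batches < 1 || photons_per_bin %% batches != 0) {
    stop("batches must divide photons_per_bin", call. = FALSE)
  }
  structure(list(photons_per_bin = as.integer(photons_per_bin),
                 rng_seed = as.integer(rng_seed), batches = as.integer(batches),
                 scatter_enabled = scatter_enabled,
                 rayleigh_enabled = rayleigh_enabled,
                 kerma_rect_mm = kerma_rect_mm, score_dose = score_dose,
                 e_cut_kev = e_cut_kev),
            class = "transport_config")
}

# entrance-field rectangle: bounding box of tissue-containing columns (mm)
.field_rect <- function(phantom) {
  any_xy <- apply(phantom$labels > 0L, c(1, 2), any)
  ix <- range(which(rowSums(any_xy) > 0))
  iy <- range(which(colSums(any_xy) > 0))
  p <- phantom$pitch_mm; o <- phantom$origin_mm
  c(o[1] + (ix[1] - 1) * p, o[1] + ix[2] * p,
    o[2] + (iy[1] - 1) * p, o[2] + iy[2] * p)
}

.fg_mass_kg <- function(phantom) {
  v_cm3 <- (phantom$pitch_mm / 10)^3
  sum(phantom$labels == 2L) * v_cm3 *
    material_table("fibroglandular")$density / 1000
}

.dose_result <- function(energies, dep_fg_kev, n_kerma, fg_mass_kg,
                         photons_per_bin, dep_total, escaped, emitted,
                         method, config = NULL) {
  batches <- ncol(dep_fg_kev)
  dep_bin <- rowSums(dep_fg_kev)
  n_bin <- rowSums(n_kerma)
  d_e <- if (fg_mass_kg > 0) dep_bin * KEV_TO_J / fg_mass_kg else rep(0, length(energies))
  structure(list(
    energies = energies,
    d_e = d_e,                                  # Gy per bin
    n = n_bin,                                  # kerma-plane photons per bin
    dep_fg_kev = dep_fg_kev,                    # bins x batches
    n_kerma = n_kerma,
    fg_mass_kg = fg_mass_kg,
    photons_per_bin = photons_per_bin,
    dep_total_kev = dep_total, escaped_kev = escaped, emitted_kev = emitted,
    method = method, config = config),
    class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("<dose_result> (%s) %d energy bins, %g photons/bin, FG mass %.4g kg\n",
              x$method, length(x$energies), x$photons_per_bin, x$fg_mass_kg))
  print(data.frame(energy_keV = x$energies, D_E_Gy = signif(x$d_e, 4),
                   N = x$n))
  invisible(x)
}

#' Run the Monte Carlo transport
#'
#' Simulates \code{photons_per_bin} histories per energy bin from a point
#' source collimated onto the phantom's entrance footprint.  Free paths are
#' sampled from the total linear attenuation; the interaction type follows
#' the tabulated component fractions.  Photoelectric events deposit the full
#' photon energy locally; Compton events deposit the Klein-Nishina electron
#' energy and the photon continues; Rayleigh events resample the direction
#' without deposition.  Dose \eqn{D_E} is the energy deposited in
#' fibroglandular voxels divided by the fibroglandular mass; \eqn{N} is the
#' count of source photons aimed through the entrance kerma rectangle.
#'
#' @param phantom A \code{voxel_phantom}.
#' @param spectrum An \code{energy_spectrum}; a simulation is run at every
#'   bin energy.
#' @param geom A [projection_geometry()] (fixes the source position).
#' @param config A [transport_config()].
#' @return A \code{dose_result} with per-energy dose, kerma-plane counts,
#'   batch tallies, and exact energy ledgers.
#' @export
run_monte_carlo <- function(phantom, spectrum, geom, config = transport_config()) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(spectrum, "energy_spectrum"),
            inherits(geom, "projection_geometry"),
            inherits(config, "transport_config"))
  fg_mass <- .fg_mass_kg(phantom)
  if (config$score_dose && fg_mass == 0) {
    stop("phantom contains no fibroglandular voxels but dose scoring was requested",
         call. = FALSE)
  }
  lut <- .transport_lookup()
  set.seed(config$rng_seed)
  res <- cpp_run_mc(phantom$labels, dim(phantom$labels), phantom$pitch_mm,
                    phantom$origin_mm, geom$source_mm, spectrum$energies,
                    config$photons_per_bin, config$batches,
                    lut$mu_mm, lut$p_pe, lut$p_pec, lut$muen_mu,
                    lut$e_lo, lut$e_hi,
                    .field_rect(phantom), config$kerma_rect_mm,
                    config$scatter_enabled, config$rayleigh_enabled,
                    config$e_cut_kev)
  .dose_result(spectrum$energies, res$dep_fg_kev, res$n_kerma, fg_mass,
               config$photons_per_bin, res$dep_total_kev, res$escaped_kev,
               res$emitted_kev, method = "monte_carlo", config = config)
}

#' Deterministic primary-beam dose oracle
#'
#' Scatter-free collision-kerma computation used to validate the Monte
#' Carlo: the entrance field is partitioned into cells, each cell's ray is
#' Siddon-traced, and fibroglandular dose accrues as Beer-Lambert-attenuated
#' fluence times \eqn{E (\mu_{en}/\mu)(1 - e^{-\mu \ell})} per traversed
#' voxel.  Its expectation equals [run_monte_carlo()] with
#' \code{scatter_enabled = FALSE}.
#'
#' @inheritParams run_monte_carlo
#' @param cell_mm Entrance-plane cell size in mm (default 1).
#' @return A \code{dose_result} (no stochastic batches; \code{n} is the
#'   expected kerma-plane count for \code{photons_per_bin} histories).
#' @export
primary_dose_oracle <- function(phantom, spectrum, geom,
                                config = transport_config(), cell_mm = 1) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  fg_mass <- .fg_mass_kg(phantom)
  if (config$score_dose && fg_mass == 0) {
    stop("phantom contains no fibroglandular voxels but dose scoring was requested",
         call. = FALSE)
  }
  fr <- .field_rect(phantom)
  xs <- seq(fr[1] + cell_mm / 2, fr[2] - cell_mm / 2 + 1e-9, by = cell_mm)
  ys <- seq(fr[3] + cell_mm / 2, fr[4] - cell_mm / 2 + 1e-9, by = cell_mm)
  cells <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  area <- (fr[2] - fr[1]) * (fr[4] - fr[3])
  n_per_cell <- config$photons_per_bin * cell_mm^2 / area
  lut <- .transport_lookup()
  res <- cpp_primary_dose(phantom$labels, dim(phantom$labels),
                          phantom$pitch_mm, phantom$origin_mm, geom$source_mm,
                          cells, n_per_cell, spectrum$energies,
                          lut$mu_mm, lut$muen_mu, lut$e_lo, lut$e_hi,
                          config$kerma_rect_mm)
  nb <- length(spectrum$energies)
  .dose_result(spectrum$energies, matrix(res$dep_fg_kev, nb, 1),
               matrix(res$n_kerma, nb, 1), fg_mass, config$photons_per_bin,
               dep_total = res$dep_fg_kev, escaped = rep(NA_real_, nb),
               emitted = rep(NA_real_, nb), method = "primary_oracle",
               config = config)
}

#' Entrance air kerma per energy bin
#'
#' \deqn{K_E = 1.602 \times 10^{-10} \cdot E \cdot 10^{-3} \cdot
#'   (\mu_{en}/\rho)_{air}(E) \cdot N / 9\,\mathrm{cm}^2}
#'
#' i.e. the photon fluence through the 3 cm x 3 cm entrance scoring plane
#' (\eqn{N / 9\,\mathrm{cm}^2}) times the photon energy times the air mass
#' energy-absorption coefficient.  Dimensionally: \eqn{E} [keV] times
#' \eqn{10^{-3} \times 1.602\times10^{-10}} J/keV-per-gram-to-kg equals
#' \eqn{1.602\times10^{-13}} J/kg per (keV cm^2/g cm^{-2}), so \eqn{K_E} is
#' in Gy.
#'
#' @param result A \code{dose_result} (its \code{n} and \code{energies} are
#'   used), or a list with those fields.
#' @param area_cm2 Scoring plane area (default 9).
#' @return Numeric vector of per-energy entrance air kerma in Gy.
#' @export
tally_entrance_kerma <- function(result, area_cm2 = 9) {
  E <- result$energies
  N <- result$n
  mu_en_air <- mu_en_over_rho("air", E)
  1.602e-10 * E * 1e-3 * mu_en_air * N / area_cm2
}

# per-batch kerma (Gy), bins x batches
.kerma_batches <- function(result, area_cm2 = 9) {
  E <- result$energies
  mu_en_air <- mu_en_over_rho("air", E)
  sweep(result$n_kerma, 1, 1.602e-10 * E * 1e-3 * mu_en_air / area_cm2, "*")
}

# per-batch fibroglandular dose (Gy), bins x batches
.dose_batches <- function(result) {
  if (result$fg_mass_kg <= 0) return(result$dep_fg_kev * 0)
  result$dep_fg_kev * KEV_TO_J / result$fg_mass_kg
}

#' Export a dose result as CSV
#'
#' One row per energy bin with the photon count, fibroglandular dose, kerma
#' plane tally, and derived entrance kerma.
#'
#' @param result A \code{dose_result}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
save_dose_csv <- function(result, path) {
  k <- tally_entrance_kerma(result)
  df <- data.frame(energy_keV = result$energies,
                   photons = result$photons_per_bin,
                   D_E_Gy = result$d_e, N = result$n, K_E_Gy = k)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
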