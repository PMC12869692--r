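# Generates the packaged photon cross-section tables under
# inst/extdata/materials/.  Run from the package root:
#   Rscript data-raw/make_material_tables.R
#
# Totals (mu/rho) and mass energy-absorption coefficients (mu_en/rho) for the
# tissue materials are mixture-rule combinations of elemental anchor values in
# the style of the standard compilations (Hubbell & Seltzer mass coefficients;
# anchors at 10, 15, 20, 30 keV, log-log interpolated to a 0.5 keV grid).
# Dry air uses the compiled air coefficients directly.  The partition into
# photoelectric / incoherent (Compton) / coherent (Rayleigh) components uses
# the Klein-Nishina free-electron cross section with a water-anchored binding
# correction for the incoherent part and a Z^2/A-scaled coherent estimate;
# the remainder is assigned to photoelectric absorption, which dominates and
# absorbs any residual of the estimates.  CsI is a power-law approximation
# included only for optional detector-absorption weighting; it never enters
# dose scoring.
#
# Compositions: adipose and skin per ICRU Report 44, fibroglandular tissue
# per the Hammerstein glandular composition (the community standard for
# mammography dosimetry).  Densities (g/cm^3): adipose 0.95, fibroglandular
# 1.02, skin 1.09, dry air 1.205e-3, CsI 4.51.

E_anchor <- c(10, 15, 20, 30)
E_fine <- seq(10, 30, by = 0.5)

loglog <- function(x, y, xout) exp(approx(log(x), log(y), xout = log(xout))$y)

# elemental mass attenuation / energy-absorption anchors, cm^2/g
elem <- list(
  H  = list(tot = c(0.3854, 0.3764, 0.3695, 0.3570),
            en  = c(0.00986, 0.01102, 0.01331, 0.01855),
            Z = 1,  A = 1.008),
  C  = list(tot = c(2.373, 0.8071, 0.4420, 0.2562),
            en  = c(2.078, 0.5627, 0.2238, 0.06614),
            Z = 6,  A = 12.011),
  N  = list(tot = c(3.879, 1.236, 0.6178, 0.3066),
            en  = c(3.545, 1.083, 0.4601, 0.1099),
            Z = 7,  A = 14.007),
  O  = list(tot = c(5.952, 1.836, 0.8651, 0.3779),
            en  = c(5.565, 1.545, 0.6370, 0.1729),
            Z = 8,  A = 15.999),
  Na = list(tot = c(15.33, 4.694, 2.057, 0.7197),
            en  = c(14.56, 4.350, 1.840, 0.5940),
            Z = 11, A = 22.990),
  P  = list(tot = c(40.10, 11.80, 5.000, 1.640),
            en  = c(38.10, 11.20, 4.700, 1.490),
            Z = 15, A = 30.974),
  S  = list(tot = c(49.70, 14.60, 6.200, 2.020),
            en  = c(47.20, 13.80, 5.800, 1.850),
            Z = 16, A = 32.06),
  Cl = list(tot = c(53.00, 15.60, 6.610, 2.150),
            en  = c(50.20, 14.70, 6.180, 1.970),
            Z = 17, A = 35.45),
  K  = list(tot = c(75.00, 22.10, 9.360, 3.020),
            en  = c(70.80, 20.80, 8.730, 2.760),
            Z = 19, A = 39.098)
)

# mass fractions
comp <- list(
  adipose = c(H = 0.114, C = 0.598, N = 0.007, O = 0.278,
              Na = 0.001, S = 0.001, Cl = 0.001),
  fibroglandular = c(H = 0.102, C = 0.184, N = 0.032, O = 0.677, P = 0.005),
  skin = c(H = 0.100, C = 0.204, N = 0.042, O = 0.645, Na = 0.002,
           P = 0.001, S = 0.002, Cl = 0.003, K = 0.001)
)
density <- c(air = 1.205e-3, adipose = 0.95, fibroglandular = 1.02,
             skin = 1.09, csi = 4.51)

# dry air, compiled values used directly
air_tot <- c(5.120, 1.614, 0.7779, 0.3538)
air_en  <- c(4.742, 1.334, 0.5389, 0.1537)
air_ZA  <- 0.4992

NA_AVOG <- 6.02214076e23
RE_CM <- 2.8179403262e-13

sigma_kn <- function(E) {  # cm^2 per electron
  k <- E / 510.998950
  2 * pi * RE_CM^2 *
    ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
       log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

# water-anchored incoherent binding correction (ratio of bound to
# free-electron incoherent cross section per gram)
s_corr <- function(E) loglog(E_anchor, c(0.62, 0.78, 0.86, 0.95), E)

# coherent scatter: water anchor 0.0955 cm^2/g at 20 keV scaled by the
# composition's sum(w Z^2/A) relative to water (3.663), ~E^-1.9
WATER_COH20 <- 0.0955
WATER_Z2A <- 3.663

mix_quantity <- function(w, field) {
  out <- rep(0, length(E_fine))
  for (el in names(w)) {
    out <- out + w[[el]] * loglog(E_anchor, elem[[el]][[field]], E_fine)
  }
  out
}
mix_scalar <- function(w, f) sum(vapply(names(w), function(el) w[[el]] * f(elem[[el]]), 0))

make_tissue <- function(w) {
  tot <- mix_quantity(w, "tot")
  en <- mix_quantity(w, "en")
  ZA <- mix_scalar(w, function(e) e$Z / e$A)
  Z2A <- mix_scalar(w, function(e) e$Z^2 / e$A)
  incoh <- sigma_kn(E_fine) * NA_AVOG * ZA * s_corr(E_fine)
  coh <- WATER_COH20 * (Z2A / WATER_Z2A) * (20 / E_fine)^1.9
  pe <- tot - incoh - coh
  stopifnot(all(pe > 0), all(en < tot))
  data.frame(energy_kev = E_fine, pe_cm2g = pe, compton_cm2g = incoh,
             rayleigh_cm2g = coh, mu_en_cm2g = en)
}

tabs <- lapply(comp, make_tissue)

# air
air_tot_f <- loglog(E_anchor, air_tot, E_fine)
air_en_f <- loglog(E_anchor, air_en, E_fine)
air_incoh <- sigma_kn(E_fine) * NA_AVOG * air_ZA * s_corr(E_fine)
air_Z2A <- 0.755 * 49 / 14.007 + 0.232 * 64 / 15.999 + 0.0128 * 18^2 / 39.948
air_coh <- WATER_COH20 * (air_Z2A / WATER_Z2A) * (20 / E_fine)^1.9
tabs$air <- data.frame(energy_kev = E_fine, pe_cm2g = air_tot_f - air_incoh - air_coh,
                       compton_cm2g = air_incoh, rayleigh_cm2g = air_coh,
                       mu_en_cm2g = air_en_f)
stopifnot(all(tabs$air$pe_cm2g > 0))

# CsI: power-law approximation anchored at 28 cm^2/g (20 keV); both Cs and I
# K edges lie above 30 keV so the band is smooth
csi_tot <- 28 * (20 / E_fine)^2.8
csi_ZA <- (55 + 53) / (132.905 + 126.904)
csi_incoh <- sigma_kn(E_fine) * NA_AVOG * csi_ZA * 0.80
csi_coh <- 1.5 * (20 / E_fine)^1.9
tabs$csi <- data.frame(energy_kev = E_fine, pe_cm2g = csi_tot - csi_incoh - csi_coh,
                       compton_cm2g = csi_incoh, rayleigh_cm2g = csi_coh,
                       mu_en_cm2g = 0.90 * csi_tot)

provenance <- c(
  air = "compiled dry-air mass coefficients (sea level)",
  adipose = "ICRU-44 adipose composition, mixture rule over elemental anchors",
  fibroglandular = "Hammerstein glandular composition, mixture rule over elemental anchors",
  skin = "ICRU-44 skin composition, mixture rule over elemental anchors",
  csi = "APPROXIMATE power-law model; detector weighting only, not for dosimetry"
)

dir.create("inst/extdata/materials", recursive = TRUE, showWarnings = FALSE)
for (m in names(tabs)) {
  path <- file.path("inst/extdata/materials", paste0(m, ".csv"))
  con <- file(path, "w")
  writeLines(c(
    sprintf("# material: %s", m),
    sprintf("# density_g_cm3: %.6g", density[[m]]),
    sprintf("# provenance: %s", provenance[[m]]),
    "# columns: energy_keV, photoelectric, compton(incoherent), rayleigh(coherent), mu_en  [cm^2/g]",
    "# partition: Klein-Nishina incoherent with water-anchored binding correction;",
    "#   Z^2/A-scaled coherent estimate; photoelectric as remainder of the total.",
    "# generated by data-raw/make_material_tables.R"
  ), con)
  df <- tabs[[m]]
  df[, -1] <- signif(df[, -1], 6)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
}
cat("wrote", length(tabs), "material tables\n")
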