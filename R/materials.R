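# Embedded photon cross-section data for the five materials used by the
# phantom, projector, and transport modules.  Tables ship as CSV assets under
# inst/extdata/materials/ and are cached on first access.

.materials_env <- new.env(parent = emptyenv())

.MATERIALS <- c("air", "adipose", "fibroglandular", "skin", "csi")
# integer labels used in voxel grids
.LABELS <- c(air = 0L, adipose = 1L, fibroglandular = 2L, skin = 3L)

#' List supported materials
#'
#' @return Character vector of material names recognized by the cross-section
#'   tables: dry air, adipose tissue, fibroglandular tissue, skin, and CsI
#'   (the latter only for optional detector-absorption weighting).
#' @export
list_materials <- function() .MATERIALS

.check_material <- function(material) {
  material <- match.arg(material, .MATERIALS)
  material
}

.check_energy <- function(E, material) {
  if (!is.numeric(E) || any(!is.finite(E))) {
    stop("energy must be finite numeric (keV)", call. = FALSE)
  }
  if (any(E < 10 | E > 30)) {
    stop(sprintf("energy %s keV outside the tabulated 10-30 keV band for material '%s'",
                 paste(format(E[E < 10 | E > 30]), collapse = ", "), material),
         call. = FALSE)
  }
  E
}

#' Material cross-section table
#'
#' Returns the embedded table for one material: photon mass attenuation split
#' into photoelectric, Compton (incoherent), and Rayleigh (coherent)
#' components, the mass energy-absorption coefficient, and the density.
#'
#' @param material One of [list_materials()].
#' @return A list with elements \code{material}, \code{density} (g/cm^3) and
#'   \code{table} (data.frame with columns \code{energy_kev}, \code{pe_cm2g},
#'   \code{compton_cm2g}, \code{rayleigh_cm2g}, \code{mu_en_cm2g}).
#' @export
material_table <- function(material) {
  material <- .check_material(material)
  if (!is.null(.materials_env[[material]])) {
    return(.materials_env[[material]])
  }
  path <- system.file("extdata", "materials", paste0(material, ".csv"),
                      package = "dgnrange", mustWork = TRUE)
  hdr <- readLines(path, n = 10L)
  dens_line <- grep("^# density_g_cm3:", hdr, value = TRUE)
  density <- as.numeric(sub("^# density_g_cm3:", "", dens_line[1]))
  tab <- read.csv(path, comment.char = "#")
  stopifnot(all(diff(tab$energy_kev) > 0))
  out <- list(material = material, density = density, table = tab)
  .materials_env[[material]] <- out
  out
}

# log-log linear interpolation; exact at grid nodes
.loglog_interp <- function(x, y, xout) {
  exp(approx(log(x), log(y), xout = log(xout), rule = 1)$y)
}

.interp_col <- function(material, col, E) {
  material <- .check_material(material)
  E <- .check_energy(E, material)
  tab <- material_table(material)$table
  .loglog_interp(tab$energy_kev, tab[[col]], E)
}

#' Total mass attenuation coefficient
#'
#' Log-log linear interpolation of the tabulated total (photoelectric +
#' Compton + Rayleigh) mass attenuation coefficient.
#'
#' @param material One of [list_materials()].
#' @param E Photon energy in keV, in the tabulated 10-30 keV band.
#' @return Mass attenuation coefficient in cm^2/g (vectorized over \code{E}).
#' @export
mu_over_rho <- function(material, E) {
  material <- .check_material(material)
  E <- .check_energy(E, material)
  tab <- material_table(material)$table
  tot <- tab$pe_cm2g + tab$compton_cm2g + tab$rayleigh_cm2g
  .loglog_interp(tab$energy_kev, tot, E)
}

#' Mass energy-absorption coefficient
#'
#' @inheritParams mu_over_rho
#' @return \eqn{\mu_{en}/\rho} in cm^2/g.
#' @export
mu_en_over_rho <- function(material, E) .interp_col(material, "mu_en_cm2g", E)

#' Linear attenuation coefficient
#'
#' Density times [mu_over_rho()].
#'
#' @inheritParams mu_over_rho
#' @return Linear attenuation coefficient in 1/cm.
#' @export
linear_mu <- function(material, E) {
  material <- .check_material(material)
  material_table(material)$density * mu_over_rho(material, E)
}

#' Interaction-type probabilities
#'
#' Fractions of the total cross-section carried by photoelectric absorption,
#' Compton (incoherent) scatter, and Rayleigh (coherent) scatter at energy
#' \code{E}; these are the branching probabilities used by the Monte Carlo
#' transport engine.
#'
#' @inheritParams mu_over_rho
#' @return For scalar \code{E}, a named numeric vector
#'   \code{(photoelectric, compton, rayleigh)} summing to 1; for vector
#'   \code{E}, a matrix with one row per energy.
#' @export
interaction_fractions <- function(material, E) {
  material <- .check_material(material)
  E <- .check_energy(E, material)
  tab <- material_table(material)$table
  pe <- .loglog_interp(tab$energy_kev, tab$pe_cm2g, E)
  co <- .loglog_interp(tab$energy_kev, tab$compton_cm2g, E)
  ra <- .loglog_interp(tab$energy_kev, tab$rayleigh_cm2g, E)
  tot <- pe + co + ra
  out <- cbind(photoelectric = pe / tot, compton = co / tot, rayleigh = ra / tot)
  if (length(E) == 1L) out[1L, ] else out
}

# Fine lookup tables for the C++ transport kernel: for each grid-label
# material (air, adipose, fibroglandular, skin) on a uniform energy grid,
# linear attenuation (1/mm), cumulative interaction probabilities, and the
# mu_en/mu absorbed fraction.
.transport_lookup <- function(e_lo = 10, e_hi = 30, n = 81L) {
  key <- sprintf("lookup_%g_%g_%d", e_lo, e_hi, n)
  if (!is.null(.materials_env[[key]])) return(.materials_env[[key]])
  E <- seq(e_lo, e_hi, length.out = n)
  mats <- names(.LABELS)
  mu_mm <- p_pe <- p_pec <- muen_mu <- matrix(0, n, length(mats))
  for (j in seq_along(mats)) {
    m <- mats[j]
    mu_mm[, j] <- linear_mu(m, E) / 10          # 1/mm
    fr <- interaction_fractions(m, E)
    p_pe[, j] <- fr[, "photoelectric"]
    p_pec[, j] <- fr[, "photoelectric"] + fr[, "compton"]
    muen_mu[, j] <- mu_en_over_rho(m, E) / mu_over_rho(m, E)
  }
  out <- list(e_lo = e_lo, e_hi = e_hi, energies = E, mu_mm = mu_mm,
              p_pe = p_pe, p_pec = p_pec, muen_mu = muen_mu)
  .materials_env[[key]] <- out
  out
}
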