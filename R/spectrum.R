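# X-ray spectrum modeling and binning.  The default beam is a tungsten-anode
# bremsstrahlung spectrum (Kramers shape, photon-count convention) filtered by
# aluminum, discretized into 2 keV bins at nominal energies 13, 15, ..., 27
# keV.  Beam weights W_E are photon-count weights normalized to sum 1.

# aluminum mass attenuation anchors for the filtration factor (cm^2/g);
# log-log interpolation with end-slope extrapolation (Al is edge-free and
# near power-law over 8-50 keV)
.AL_E <- c(10, 15, 20, 30, 40, 50)
.AL_MU <- c(26.23, 7.955, 3.441, 1.128, 0.5685, 0.3681)
.AL_RHO <- 2.699

.al_mu_linear <- function(E) {  # 1/cm
  lx <- log(.AL_E); ly <- log(.AL_MU)
  n <- length(lx)
  le <- log(E)
  y <- approx(lx, ly, xout = le, rule = 2)$y
  lo <- le < lx[1]
  hi <- le > lx[n]
  y[lo] <- ly[1] + (le[lo] - lx[1]) * (ly[2] - ly[1]) / (lx[2] - lx[1])
  y[hi] <- ly[n] + (le[hi] - lx[n]) * (ly[n] - ly[n - 1]) / (lx[n] - lx[n - 1])
  .AL_RHO * exp(y)
}

.new_spectrum <- function(energies, weights, kvp = NA_real_, filtration = "") {
  s <- sum(weights)
  if (s <= 0) stop("spectrum has zero total weight", call. = FALSE)
  structure(list(energies = energies, weights = weights / s,
                 kvp = kvp, filtration = filtration),
            class = "energy_spectrum")
}

#' Construct an energy spectrum
#'
#' @param energies Photon energies in keV (strictly increasing).
#' @param weights Non-negative beam weights; normalized to sum 1.
#' @param kvp Tube potential metadata (kV), optional.
#' @param filtration Free-text filtration description, optional.
#' @return An \code{energy_spectrum} object.
#' @export
energy_spectrum <- function(energies, weights, kvp = NA_real_, filtration = "") {
  if (length(energies) != length(weights)) {
    stop("energies and weights must have equal length", call. = FALSE)
  }
  if (any(weights < 0)) stop("spectrum weights must be non-negative", call. = FALSE)
  if (is.unsorted(energies, strictly = TRUE)) {
    stop("energies must be strictly increasing", call. = FALSE)
  }
  .new_spectrum(energies, weights, kvp, filtration)
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum> %d energies, %.3g-%.3g keV", length(x$energies),
              min(x$energies), max(x$energies)))
  if (!is.na(x$kvp)) cat(sprintf(", %g kVp", x$kvp))
  if (nzchar(x$filtration)) cat(" [", x$filtration, "]", sep = "")
  cat(sprintf("\n  mean energy %.2f keV\n", sum(x$energies * x$weights)))
  invisible(x)
}

#' Mean energy of a spectrum
#' @param spec An \code{energy_spectrum}.
#' @return Weight-averaged photon energy in keV.
#' @export
mean_energy <- function(spec) sum(spec$energies * spec$weights)

#' Model a filtered tungsten-anode spectrum
#'
#' Fine-grained (0.5 keV) bremsstrahlung spectrum in the Kramers shape with
#' photon-count convention, \eqn{w(E) \propto (kVp - E)/E}, multiplied by the
#' aluminum transmission \eqn{\exp(-\mu_{Al}(E) t)}.  Zero above the tube
#' potential.  Tungsten characteristic lines (all above 57 keV) are omitted.
#'
#' @param kvp Tube potential in kV, 20-49.
#' @param al_thickness_mm Aluminum filtration thickness in mm (>= 0).
#' @param e_min Lowest modeled energy in keV (default 8).
#' @param de Grid spacing in keV (default 0.5).
#' @return An \code{energy_spectrum} on the fine grid (pre-binning).
#' @export
model_spectrum <- function(kvp = 30, al_thickness_mm = 0.7, e_min = 8, de = 0.5) {
  if (!is.finite(kvp) || kvp < 20 || kvp > 49) {
    stop("kvp must lie in [20, 49]", call. = FALSE)
  }
  if (!is.finite(al_thickness_mm) || al_thickness_mm < 0) {
    stop("al_thickness_mm must be >= 0", call. = FALSE)
  }
  E <- seq(e_min, kvp, by = de)
  w <- pmax(kvp - E, 0) / E
  w <- w * exp(-.al_mu_linear(E) * (al_thickness_mm / 10))
  .new_spectrum(E, w, kvp = kvp,
                filtration = sprintf("%.2f mm Al", al_thickness_mm))
}

#' Rebin a fine spectrum into uniform bins
#'
#' Sums fine-grid weights into bins of width \code{width} centered at
#' \code{lo, lo + width, ..., hi}; energies outside the span are discarded and
#' the retained weights renormalized to sum 1.  A fine energy belongs to the
#' bin whose center is nearest (half-open intervals
#' \eqn{[c - width/2, c + width/2)}).
#'
#' @param spec An \code{energy_spectrum} (fine grid).
#' @param lo,hi First and last bin centers in keV.
#' @param width Bin width in keV; must divide \code{hi - lo}.
#' @return An \code{energy_spectrum} at the bin centers.
#' @export
bin_spectrum <- function(spec, lo = 13, hi = 27, width = 2) {
  stopifnot(inherits(spec, "energy_spectrum"))
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  nb <- (hi - lo) / width
  if (abs(nb - round(nb)) > 1e-9) {
    stop("width must divide (hi - lo) into an integer number of bins",
         call. = FALSE)
  }
  centers <- seq(lo, hi, by = width)
  idx <- floor((spec$energies - (lo - width / 2)) / width) + 1L
  keep <- idx >= 1L & idx <= length(centers)
  w <- vapply(seq_along(centers),
              function(i) sum(spec$weights[keep & idx == i]), 0)
  .new_spectrum(centers, w, kvp = spec$kvp, filtration = spec$filtration)
}

#' Read a spectrum from CSV
#'
#' Expects columns \code{energy_keV} and \code{weight}; lines starting with
#' \code{#} are treated as comments.  Weights are renormalized on load.
#'
#' @param path CSV file path.
#' @return An \code{energy_spectrum}.
#' @export
load_spectrum_csv <- function(path) {
  tab <- read.csv(path, comment.char = "#")
  if (!all(c("energy_keV", "weight") %in% names(tab))) {
    stop("spectrum CSV must have columns energy_keV, weight", call. = FALSE)
  }
  bad <- which(!is.finite(tab$energy_keV) | !is.finite(tab$weight) |
                 tab$weight < 0)
  if (length(bad)) {
    stop(sprintf("invalid spectrum row(s): %s (negative or non-finite values)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  o <- order(tab$energy_keV)
  energy_spectrum(tab$energy_keV[o], tab$weight[o])
}

#' Write a spectrum to CSV
#'
#' @param spec An \code{energy_spectrum}.
#' @param path Output CSV file path.
#' @return \code{path}, invisibly.
#' @export
save_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "energy_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kVp: %s", spec$kvp),
               sprintf("# filtration: %s", spec$filtration)), con)
  write.csv(data.frame(energy_keV = spec$energies, weight = spec$weights),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default binned mammographic beam
#'
#' The 30 kVp W/Al (0.7 mm) modeled spectrum binned into 2 keV bins at
#' 13-27 keV; the beam used throughout the dose studies.
#'
#' @return An \code{energy_spectrum} with 8 bins.
#' @export
default_beam <- function() {
  bin_spectrum(model_spectrum(30, 0.7), 13, 27, 2)
}
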