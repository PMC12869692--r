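---
title: "Patient-specific DgN ranges: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific DgN ranges: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgnrange)
```

## The problem

The normalized glandular dose (DgN) converts a measurable quantity — entrance
air kerma — into the mean dose absorbed by the radiosensitive fibroglandular
(FG) tissue of the compressed breast. Conventional DgN coefficients assume the
FG tissue is distributed homogeneously. In reality FG tissue is concentrated
somewhere in depth, and a single mammographic projection cannot reveal where:
two breasts with identical projections (and identical per-pixel
glandular-fraction maps) can differ substantially in dose, because FG tissue
near the entrance (source) surface absorbs far more than FG tissue near the
detector.

`dgnrange` therefore reports a *range*. From one glandular-fraction (GF) map
it reconstructs the two feasible breast volumes that extremize the dose —
all FG tissue pushed toward the source, or toward the detector — plus a
most-likely, depth-centered volume, and transports all three with a photon
Monte Carlo to produce `[DgN_min, DgN_max]` and a likely value.

## Phantoms

`build_breast()` realizes a `breast_spec()` on a 1 mm voxel grid:

* the footprint is a half-ellipse (semi-axes diameter/2 laterally and the
  chest-wall-to-nipple distance anteriorly), flat at the chest-wall plane;
* the compressed thickness is uniform (flat top and bottom, as under
  compression paddles);
* the outermost voxel layer is skin — except on the chest-wall cut plane,
  where the breast continues into the body;
* interior voxels are adipose or fibroglandular.

The default FG region is a half-ellipsoid *geometrically similar to the
breast interior*, scaled by $\lambda = (1.5\,\mathrm{GF})^{1/3}$ so that its
volume is exactly the requested fraction of the interior, anchored at the
chest wall, and displaced in depth until it touches the interior top surface
(`placement = "top"`), the interior bottom (`"bottom"`), or is centered
(`"center"`). On the voxel grid the scale is realized by an exact order
statistic: for every interior voxel the smallest $\lambda$ whose region
contains it has a closed form, so selecting the $k$ smallest thresholds
yields the best-matching discrete region and the achieved GF matches the
request to within one voxel.

This construction was chosen over a full-width depth slab deliberately. A
slab at 20% GF is only ~6 mm thick and sits at the extreme top or bottom of
the breast; the resulting top/bottom dose contrast (ratio ≈ 4.8 at 3.29 cm
compressed thickness, ≈ 15 at 6.29 cm) far exceeds what is observed for
realistic, blob-like FG distributions (≈ 1.85 and ≈ 2.96 with the ellipsoid
default — see *Results* below). The slab remains available via
`fg_shape = "slab"` for sensitivity analysis and for its one-dimensional
analytic correspondence (`two_slab_dose()`).

```{r phantom, eval = FALSE}
spec <- breast_spec(11.29, 3.29, glandular_fraction = 0.2, placement = "top")
ph <- build_breast(spec)
ph
achieved_gf(ph)   # 0.2000
```

## Beam model

`model_spectrum()` produces a tungsten-anode bremsstrahlung spectrum in the
Kramers shape (photon-count convention, $w(E) \propto (\mathrm{kVp} - E)/E$)
filtered by aluminum; `bin_spectrum()` discretizes it into 2 keV bins at
nominal energies 13, 15, …, 27 keV. The default beam (`default_beam()`) is
30 kVp with 0.7 mm Al and has a mean binned energy of ≈ 19.7 keV. Measured
spectra can be substituted via `load_spectrum_csv()`.

## Cross sections

Five materials ship as CSV tables under `inst/extdata/materials/`: dry air,
adipose, fibroglandular tissue, skin, and CsI (for optional detector
weighting only). Each table splits the mass attenuation into photoelectric,
incoherent (Compton), and coherent (Rayleigh) components on a 0.5 keV grid
over 10–30 keV, plus the mass energy-absorption coefficient. The tables are
generated by `data-raw/make_material_tables.R` from elemental anchors and
standard tissue compositions via the mixture rule; interpolation is log-log
linear and exact at the grid nodes. The air energy-absorption value at
20 keV (0.539 cm²/g) anchors the entrance-kerma computation.

## Projection and GF maps

`projection_geometry()` places a point source 354.6 mm above the breast's top
surface over the chest-wall edge (half-cone beam) and a detector plane at the
bottom surface. `trace_ray()` performs exact Siddon/Amanatides–Woo traversal:
every voxel a ray crosses appears exactly once with its chord length, which
the tests verify against a dense-sampling reference. `forward_project()`
produces Beer–Lambert primary-beam transmission images;
`compute_gf_map()` divides each pixel's FG path length by the compressed
thickness — the idealized "perfect" GF map that a spectral or dual-energy
estimator would aim to recover from a real mammogram.

## Monte Carlo transport

`run_monte_carlo()` simulates a fixed number of photon histories per energy
bin from the point source, collimated onto the breast footprint:

* free paths sampled from the total linear attenuation, per-voxel;
* photoelectric events deposit the full photon energy locally;
* Compton events sample the Klein–Nishina angle by rejection, deposit the
  electron energy, and the photon continues;
* Rayleigh events redirect with the Thomson angular law without deposition;
* photons below 10 keV deposit locally (kerma approximation — electron
  ranges at these energies are below voxel scale);
* dose is energy deposited in FG voxels divided by FG mass, per bin;
* `N`, the count of source photons aimed through a 3 cm × 3 cm entrance
  rectangle against the chest wall, feeds the entrance air kerma
  $K_E = 1.602\times10^{-10}\, E\, 10^{-3} (\mu_{en}/\rho)_{air}(E)\, N / 9\,\mathrm{cm}^2$.

R's own RNG drives the C++ kernel, so a fixed `rng_seed` reproduces results
bit-for-bit. Uncertainties come from 20 history batches. With
`scatter_enabled = FALSE` the engine runs in collision-kerma mode, whose
expectation equals the deterministic `primary_dose_oracle()` exactly — the
basis of a 3σ equivalence test. An exact energy ledger
(emitted = deposited + escaped) is asserted in the test suite.

DgN is the weighted ratio of sums
$\mathrm{DgN} = \sum_E D_E W_E \,/\, \sum_E K_E W_E$ (`compute_dgn()`), not a
weighted mean of per-energy ratios.

Deliberate idealizations: compression paddles, body scatter, the air column,
and any anti-scatter grid are not transported; the kerma tally counts photons
before the phantom. These mainly affect absolute dose levels, which the
package never claims — only ratios, orderings, and ranges.

## Constrained back-projection

`reconstruct_breast()` turns a GF map into a feasible volume. Every detector
pixel's ray is traced toward the source; rays that saw tissue mark the
support; the outermost support layer becomes skin (chest-wall face excluded);
then each positive-GF ray flips interior voxels from adipose to FG —
source-first (`max_dose`), detector-first (`min_dose`), or outward from the
mid-depth plane (`center`) — until its FG path length best matches
GF × thickness (a last-voxel rule bounds the per-ray error at half a voxel).
Rays are processed in raster order and FG voxels are never unflipped.

Two properties are only approximate, both because voxels are shared between
oblique rays in a divergent beam: (i) the max/min fills are per-ray
prefix/suffix reverses of each other for ~90–94% of rays rather than all;
(ii) re-projecting a reconstruction widens the tissue shadow slightly, so
idempotence holds exactly for the FG set (Jaccard ≥ 0.997 measured) but not
voxel-for-voxel for the support hull.

## Results at reduced photon counts

All results below use 10⁵ photons per bin (per-case standard errors ≈ 0.3–1%)
and were produced by `run_thickness_sweep()`, `run_gf_sweep()`, and
`run_reconstruction_comparison()`; `scripts/acceptance.R` re-computes them
for any seed.

* **Placement ordering.** DgN(top) > DgN(center) > DgN(bottom) at 3σ for
  every baseline size. For the 11.29 cm × 3.29 cm breast at 20% GF:
  0.423 ± 0.001 (top), 0.313 (center), 0.228 ± 0.001 (bottom).
* **Range vs thickness.** The top/bottom ratio grows with thickness:
  ≈ 1.85 at 3.29 cm rising to ≈ 2.96 at 6.29 cm — a patient whose projection
  is compatible with either extreme faces up to a ~3× dose ambiguity.
* **Range vs glandularity.** At fixed size the [min, max] width narrows as
  GF grows (the FG region fills more of the depth, leaving less freedom).
* **Containment.** Across all 18 baseline cases the original phantom's DgN
  falls inside the reconstructed [min, max] interval (18/18): the extreme
  fills genuinely bracket the truth.
* **Matched-configuration deviation.** The center reconstruction matches a
  depth-centered original within ~1%. The max/min reconstructions
  *overshoot* originals whose FG regions merely touch the top/bottom surface
  by 15–34%, because the per-ray extreme fill concentrates FG strictly at
  the surface while a blob's off-axis FG sits deeper. This is a conservative
  bias — the reported range is wider than the truth requires — and is the
  package's main known limitation.

```{r sweep, eval = FALSE}
sweep <- run_thickness_sweep(photons_per_bin = 1e5, seed = 42)
sweep$summary
#   thickness_cm  dgn_top dgn_center dgn_bottom    ratio
#           3.29   0.4233     0.3127     0.2283    1.854
#           ...
plot_dgn_report(sweep)
```

## Limitations

* Absolute DgN values inherit the idealized beam path and the modeled
  (not measured) spectrum; use ratios and ranges, not absolute levels.
* The matched-mode overshoot described above: the extreme reconstructions
  are maximally conservative rather than faithful to a particular original.
* Cross sections are mixture-rule approximations over 10–30 keV only.
* GF maps are taken as given ("perfect"); estimating them from real
  mammograms is outside the package's scope.
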