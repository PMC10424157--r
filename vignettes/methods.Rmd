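---
title: "Models and measurement procedures in shearscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement procedures in shearscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shearscope)
```

This vignette is the package's own account of its science: the flow
models and their assumptions, what the synthetic-tissue generator does and
does not emulate, the tunable parameters of the measurement pipeline, the
numerical choices, and the known limitations. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. Wall shear stress in a shallow channel slide

Cultured proximal tubule epithelium is exposed to flow in a commercial
channel slide whose fluid path is 0.4 mm high, 5 mm wide and 50 mm long
with 3.5 mm cylindrical ports (`ibidi_slide_geometry()`). Throughout,
flow is treated as steady, laminar, fully developed and Newtonian, with
medium approximated by water (μ = 1.0 mPa·s, ρ = 1000 kg/m³). Internally
everything is SI; µl/min, ml/day and dyn/cm² (1 dyn/cm² = 0.1 Pa) exist
only at the interface.

Three bottom-wall centerline models are provided, in increasing fidelity:

* **Parallel plate** (`plate_shear`): τ = 6μQ/(wh²), exact as w/h → ∞.
* **Rectangular duct** (`rect_duct_shear`): the exact Fourier-series
  solution for a duct of finite aspect ratio, evaluated at the bottom
  wall, lateral center, for prescribed Q. Side walls carry part of the
  pressure gradient, so at fixed Q the centerline shear exceeds the plate
  value (by ~5% at the slide's aspect ratio of 12.5). The series is
  truncated at 101 odd harmonics by default — far past convergence
  (doubling the truncation moves the result by < 1e-9 relative); the
  hyperbolic secant is evaluated in exp-scaled form so extreme aspect
  ratios do not overflow.
* **Plan profile** (`plan_shear_profile`): the slide's plan footprint is
  modeled as an ellipse of uniform height (major axis = length, minor =
  width). This resolves an ambiguity in how such slides are described —
  an elliptical *cross-section* of these dimensions would give roughly
  0.64 dyn/cm² at 300 µl/min, far from the 0.35–0.40 dyn/cm² that plate
  and duct models (and vendor CFD figures) give, whereas the physical
  part has a thin uniform gap with tapered (elliptical-plan) ends. In the
  lubrication (Hele-Shaw) limit each axial station carries the full Q
  through its local width, τ(x) = 6μQ/(w(x)h²), optionally multiplied by
  the duct correction at the local aspect ratio. The profile is clipped
  to the central 90% of the length by default (configurable), keeping
  away from the degenerate tips and undeveloped port regions.

An independent finite-difference solver (`fd_duct_shear`) discretizes the
duct Poisson problem on a 241×241 grid (second order, one-sided
second-order wall gradient) and shares nothing with the series route; the
two agree to ~0.1% or better across aspect ratios 1–50, which the test
suite asserts at 1%.

Entrance effects, the inlet jets, transient or pulsatile flow are not
modeled; agreement with full CFD of the real part is expected at the
~15% level, which is the band the acceptance checks use around the
0.35 dyn/cm² design value. One more caveat for users cross-checking
against vendor or literature numbers: a "velocity" quoted for a 1 ml/day
condition is sometimes printed as 1.2 × 10⁻⁸ m/s; dividing 1 ml/day by a
3.5 mm port area gives 1.2 × 10⁻⁶ m/s, so such figures are best treated
as carrying a typographic exponent slip, and no test here targets them.

`flow_rate_for_shear` inverts τ(Q) by bisection on [0, 10 × plate
estimate] to 1e-9 relative tolerance. Since every model is homogeneous of
degree one in Q (creeping flow), the inversion is exact up to that
tolerance and the two culture operating points scale exactly:
τ(1 ml/day)/τ(300 µl/min) = (1000/1440)/300 under every model.

## 2. The synthetic-tissue forward model

`generate_monolayer` renders what the five stains would show for a
confluent monolayer:

* **Footprints**: Voronoi tessellation of a hexagonal lattice whose
  spacing matches the seeding density (default 200,000 cells/cm², the
  routine density for these cells — about 90 cells in a 212.13 µm
  square field), jittered by a Gaussian of SD `jitter` × spacing.
  Footprint irregularity (hence circularity) is controlled purely by
  `jitter`; the squamous-vs-cuboidal contrast is encoded by
  `mean_cell_height` and `jitter` only (6 µm/0.25 vs 12 µm/0.12 in the
  recovery cohorts).
* **Heights**: per-cell Gaussian, default mean 8 µm with CV 0.08 — the
  modest height dispersion of a confluent immortalized monolayer.
* **Stains**: nuclei as smooth ellipsoidal blobs (σ = 0.25 × cell radius
  laterally, 0.25 × height axially); tight junction on the apical third
  of lateral borders; a continuous basal laminin sheet (default 1 µm);
  pump signal on lateral membranes plus a basal band; tubulin as a dim
  cytoplasmic body signal (0.2) plus, for each ciliated cell whose
  center lies in the field, a bright vertical rod of length ~N(3, 0.3) µm
  protruding above the apical surface. Default ciliated fraction 0.3.
* **Optics and noise, applied last**: anisotropic Gaussian PSF
  (σ = 0.25 µm lateral, 0.6 µm axial — the ≥2× axial/lateral ratio of a
  confocal pinhole), then Poisson photon noise (200 expected photons at
  full scale) and additive Gaussian read noise (2% of full scale), then
  quantization to 16 bits at 80% of full scale (headroom against
  clipping).

Ground truth records every cell's footprint polygon (as the label map),
area, circularity, height, ciliation and cilium length. Cells whose
Voronoi center falls outside the field are rendered (clipped) but carry
no cilium and are excluded from in-field summaries; the centroid-in-field
count is the unbiased density count.

**Sampling.** The default grid is 256 × 256 lateral pixels over the
212.13 µm field (0.829 µm/px) with a 0.4 µm z-step — cells are ~29 px
across, nuclei ~10 px, so every measured structure is comfortably
resolved while a full two-condition cohort (40 stacks) simulates and
measures in a few minutes. Finer sampling changes none of the metrics'
definitions and can be requested through `stack_spec`.

**What the simulator does not emulate**: uneven illumination, stain
bleed-through, depth-dependent attenuation, deconvolution artifacts,
stratified or multi-layered growth, tilted or curved cilia, cell debris.
Passing recovery tests therefore demonstrates the measurement code is
correct on geometry it claims to measure, not that it is robust to every
real-world artifact.

Cohorts (`generate_cohort`, `simulate_and_measure_cohort`) reproduce the
imaging study design — chips per condition × five fields per chip, each
field averaged into one chip-level record — with per-field sub-seeds
drawn once from the master seed, so any cohort regenerates bit-identically.

## 3. Measurement procedures and their parameters

All thresholds are data-derived by the iterative intermeans
(IsoData-family) rule, the conventional "default threshold" of particle
analysis (Otsu available as an option). Intermeans is scale-equivariant,
which makes every thresholded metric invariant under uniform intensity
rescaling — asserted bit-exactly in the tests.

* **Nuclei markers** (`find_nuclei_markers`): maxima of the 1 µm-smoothed
  projection with prominence ≥ 10% of the smoothed dynamic range,
  computed by the h-maxima transform (grayscale reconstruction by
  alternating raster sweeps) plus regional-maxima extraction; a 2 µm
  minimum separation merges split plateaus. Smoothing uses a spatial
  Gaussian with replicate boundary — FFT-based (circular) smoothing wraps
  content across edges and fabricates border maxima.
* **Cilia puncta** (`ciliated_fraction`): cilia are compact,
  near-full-scale puncta at the pixel scale, so they are detected on the
  *raw* projection (smoothing attenuates them faster than the noise
  floor) with a 25% prominence — a quarter-range noise tolerance that
  sits far above shot-noise maxima in the cytoplasmic signal and far
  below true puncta. Cells are counted as size-filtered (20–400 µm²)
  connected components of the thresholded nuclei image; the nucleus size
  bounds are a convention of this package, as particle-analysis size
  filters usually go unreported.
* **Segmentation** (`segment_cells`): marker-controlled region growing on
  the 0.5 µm-smoothed membrane relief (EBImage `propagate`, the
  CellProfiler geodesic algorithm, λ = 0.05). Region count always equals
  marker count.
* **Shape** (`cell_shape_stats`): area from pixel counts; perimeter from
  the 8-connected contour after a 3-point integer-exact vertex smoothing
  (rasterized disks come within ~2% of 2πr, squares near 4s);
  circularity 4πA/P² clamped at 1, the particle-analysis convention.
  Cells touching the border or outside 20–2000 µm² are excluded.
* **Thickness** (`thickness`): maximum projection of the selected
  channels along one lateral axis, binarized, then ten equal strips
  (excluding a 5% lateral margin) each contribute the count of distinct
  foreground z-rows × dz; the strip mean is reported. Counting *rows*
  rather than pixels makes the readout a thickness, not a mass — the
  natural reading of a "non-zero pixels in an ROI column" rule, adopted
  here as a documented convention. With laminin alone the same procedure
  reads the basement membrane.
* **Cilium length** (`cilia_length`): each channel's side view is
  binarized separately; apical tubulin = tubulin AND NOT (nuclei OR
  pump); length = (max − min foreground z-row) × dz, a *maximum-extent*
  definition. No surviving signal is reported as missing, distinct from
  zero.
* **Coverage** (`coverage_3d`): threshold fixed on the slice nearest the
  stack center, applied to all slices; suprathreshold voxels divided by
  the nuclei count.

Chip records average the fields per metric with pairwise missing-value
exclusion, and `compare_groups` applies the inference rule: both groups
must pass a Monte Carlo Lilliefors normality screen at α = 0.05 (the
"both groups" reading of an ambiguous gate is deliberate and
configurable) to use the unpaired t-test — Welch by default, since
pooled-variance equality is an extra assumption nothing here justifies —
otherwise the two-sided rank-sum test, exact by full midrank enumeration
for combined n ≤ 20. The Lilliefors null is simulated (≥10⁴ seeded
draws, cached per sample size) because the classical KS null is wrong
once parameters are estimated from the sample; which KS variant a desktop
statistics package applies usually goes unreported, and Lilliefors is the
defensible default. P-values are reported per metric with no
multiple-testing correction, and the output says so.

## 4. Numerical choices and degenerate inputs

* Series truncation 101 odd terms; convergence asserted by doubling.
* Bisection bracket [0, 10 × plate estimate], 1e-9 relative tolerance.
* Finite-difference grid 241×241 (odd, so the centerline is a node);
  sparse Cholesky solve.
* Grayscale reconstruction by 4-direction raster sweeps to fixpoint
  (comparison-only arithmetic, hence orientation-exact).
* Flat or empty images yield empty marker sets, zero thickness, zero
  coverage — never errors or NaN; zero nuclei or fully cancelled apical
  tubulin yield missing values, distinct from zero.
* Axis-flip invariance is bit-exact by construction: marker pixels are
  chosen by a flip-commuting rule (component pixel nearest the unrounded
  centroid, brightest on ties), and perimeter/shape aggregations sum in
  sorted order so float associativity cannot introduce orientation
  jitter.
* Voxel indices are 0-based in stored coordinates with z = 0 the
  basal-most plane; all lengths leave the package in µm.

## 5. Known limitations

* **Coverage needs a framed acquisition.** The center-slice threshold
  rule presumes the center slice intersects the tissue; a stack much
  taller than its tissue derives the threshold from noise and the
  metric degrades. Stacks in the tests frame each condition's tissue, as
  a microscopist would.
* **Coverage tracks structure, not brightness.** Because the threshold
  is data-derived (and the metric intensity-invariant by design),
  uniformly brighter staining does not raise coverage; more *stained
  structure* does (e.g. taller lateral membranes, more cilia). The
  monotonicity tests use structural drivers accordingly.
* **Maximum-extent cilium length is biased upward** by the spread of
  apical surface heights: the lowest visible rod base sits below the
  tallest tip by roughly the height SD. At the default condition
  (8 µm × CV 0.08) the bias is within the ±1 µm recovery band; at 12 µm
  cells it reaches about +1 µm. This is a property of the procedure
  being reproduced, not of the estimator.
* **Thickness inherits an envelope bias**: the side-view maximum
  projection reports the tallest structure in each strip, so the readout
  sits near the upper tail of the height distribution (~+1–2 SD),
  partially offset by the binarization cutting the blurred apical edge
  at half-maximum. Group contrasts survive this bias; absolute values
  carry it.
* The exact rank-sum enumeration is combinatorial and capped at combined
  n = 20 (beyond that the normal approximation with tie correction is
  used) — ample for chip-level designs.
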