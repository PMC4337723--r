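---
title: "Methods: shear-stress set-point analysis from gradient-chamber images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shear-stress set-point analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shearsetpoint)
```

This vignette documents the models, parameters and numerical choices behind
the package, in the spirit of a methods section: what is computed, under
which assumptions, and where the genuinely open design decisions were made.

## 1. The chamber model

A gradient flow chamber is a parallel-plate chamber whose channel width
narrows along the flow axis. Under ideal one-dimensional lubrication theory
(fully developed laminar flow, gap height h much smaller than width), the
wall shear stress at a station with local width $w$ is

$$\tau = \frac{6\,\mu\,Q}{h^2\,w},$$

with $\mu$ the medium viscosity, $Q$ the volumetric flow rate, in CGS units
(poise, cm³/s, cm, dyn·cm⁻²). The package adopts the width profile

$$w(x) = \frac{6\,\mu\,Q}{h^2\,\tau(x)}, \qquad
  \tau(x) = \tau_1 + (\tau_2 - \tau_1)\,\frac{x}{L},$$

which is the unique taper producing an exactly linear shear ramp under the
plate relation; `position_to_shear()`, `width_profile()` and
`plate_shear()` are therefore mutually consistent by construction, and the
test suite checks the round trip to $10^{-10}$ relative error. Entrance
effects, side-wall drag and taper-induced transverse flow are ignored: the
model is the *theoretical* shear field, which is how gradient-chamber data
are conventionally mapped to shear.

Two presets cover the published operating ranges: `"huvec"`
(h = 0.8 mm, 2–60 dyn·cm⁻²) and `"hdlec"` (h = 1.6 mm, 0.5–20 dyn·cm⁻²).
The published descriptions fix the gasket heights and shear ranges but not
the flow rate, channel length or absolute widths, so the presets adopt
Q = 0.533 cm³/s (32 ml/min) and L = 7 cm once, chosen to give
centimetre-scale widths typical of slide-based chambers; every quantity the
analysis consumes depends on the geometry only through $\tau(x)$, which is
range-matched exactly.

For in vivo reference values, `poiseuille_wall_shear()` implements
$\tau = 8\mu V/D$ for a cylindrical vessel. With the literature values
$\mu = 0.09$ P, $V = 7.1$ cm/s, $D = 4.1$ mm this gives 12.5 dyn·cm⁻²
(3 s.f.) for the umbilical vein. Note that the lower-viscosity endpoint
$\mu = 0.06$ P evaluates to 8.31 dyn·cm⁻², slightly below the commonly
quoted 8.4; the package reports what the formula gives and does not adjust
toward quoted values.

## 2. The biphasic response model and the synthetic generator

The generator exists so that segmentation, morphometry and set-point
estimation can be validated against known ground truth. It emulates the
study conditions: fields of elliptical nuclei along the chamber whose
statistics depend on local shear through `response_model()`:

* **Response weight.** With optimum $\tau_0$ and half-width $\Delta$,
  let $d = \max(0, |\tau - \tau_0| - \Delta)$ and
  $w(\tau) = 2^{-(d/\Delta)^2}$: the full response plateaus across
  $[\tau_0 - \Delta, \tau_0 + \Delta]$ and decays to half one further
  half-width out. Population targets (mean folded angle, mean nuclear
  fraction) interpolate linearly in $w$ between their optimal and baseline
  values. The defaults — optimum 15, half-width 5, aligned mean 20°,
  misaligned mean 45°, TF 0.3 at optimum vs 0.7 at baseline — encode a
  venous-like cell with a U-shaped NF-κB readout; `"hdlec"` moves the
  optimum to 5 dyn·cm⁻² with half-width 2.
* **Per-cell angles.** Nuclear orientation is axial, so angles live on a
  180°-periodic circle; the generator draws signed angles from a wrapped
  normal centred on the flow axis (or perpendicular to it for targets
  above 45°) and analysis folds them to [0, 90]. The wrapped-normal σ is
  solved numerically (quadrature over the wrapped density plus
  `uniroot`) so that the *population mean folded angle equals the target
  exactly* at the default `angle_concentration = 1`; smaller values
  broaden the distribution toward uniform and 0 gives uniform orientations
  (mean 45°, the no-flow condition). This is the simplest circular model
  that reproduces both the aligned and the random regime with one
  dispersion parameter.
* **Per-cell TF.** True nuclear fractions are Beta-distributed around the
  target with concentration 50 (s.d. ≈ 0.06 at mid-range); the degenerate
  targets 0 and 1 are returned exactly.
* **Geometry.** Nuclei are 8 × 5 µm semi-axis ellipses at 0.65 µm/pixel —
  a typical 20× confocal sampling; neither is published, so they are
  package defaults, stated here once. Centroids are rejection-sampled with
  a minimum spacing of 2.2 × the semi-major axis, which guarantees
  non-overlap; an infeasible request (too many cells for the field) is an
  explicit error, never silent truncation.
* **Rendering.** Channel 1 paints nuclei at constant intensity; channel 2
  splits each cell's total intensity between nucleus and a 6 µm
  cytoplasmic annulus as TF : (1 − TF), uniformly per region. Both
  channels get a Gaussian PSF (σ = 1 px), constant background (200
  counts), additive Gaussian noise (σ = 20 counts) and 16-bit
  quantisation. Default gains keep all pixels far from saturation;
  saturation, if provoked, is warned about and counted.

What the generator does **not** emulate: cell–cell junctions and confluent
packing, intensity inhomogeneity and vignetting, out-of-focus light,
nuclear texture, mitotic figures, debris, and shear-dependent changes in
nuclear *size*. Passing the recovery tests therefore demonstrates the
correctness of the measurement chain, not robustness to every real-world
artefact; parameters exposed on `segment_nuclei()` are the intended
adjustment points for real data.

## 3. Segmentation

`segment_nuclei()` follows the classic recipe for nuclear-stain masks:
CLAHE (8 × 8 tiles, clip limit 2) to flatten illumination, a relative
intensity threshold, connected components, and an area filter. Choices:

* The image is first rescaled to [0, 1] by its own range, which makes the
  whole chain invariant to positive intensity scaling (tested).
* Threshold rule: Otsu by default; an absolute-quantile rule is available
  since "intensity thresholding" is underdetermined.
* Connectivity is 8-fold. The underlying labeller is 4-connected, so a
  union–find pass merges components touching diagonally.
* Area bounds default to [25, 400] µm² — generous bounds on mammalian
  endothelial nuclear cross-sections — and are applied in physical units
  so they transfer across magnifications.
* Touching nuclei are *not* split by default (no watershed); a
  `split_touching` flag enables a distance-transform watershed.
* A blank or constant image yields zero labels, not an error.

The whole-cell region needed for the TF denominator has no stain of its
own in these experiments, so `derive_cell_regions()` must construct one.
The default strategy dilates each nucleus by 6 µm (matching the
generator's annulus) and partitions contested pixels by seeded geodesic
propagation, so regions are disjoint and each contains its nucleus — the
weakest assumption available. The alternative `"channel2"` strategy
restricts regions to the Otsu foreground of the transcription-factor
channel. Neither is privileged as "the" published method, because the
published description does not specify one.

## 4. Morphometry

**Orientation** comes from the second central moments of the binary
nucleus mask: $\theta = \tfrac12\,\mathrm{atan2}(2\mu_{11},
\mu_{20}-\mu_{02})$, folded to the acute angle against the flow axis.
A moment fit was chosen over boundary least squares because it is
deterministic, parameter-free, and standard for "fit an ellipse" on binary
masks. Degenerate moment tensors (circles) have no major axis; those cells
return `NA` and are excluded from averages. Folding to [0, 90] is forced
by the physics of the readout: 45° is the random expectation and 90° the
perpendicular response.

**Translocation factor** is
$\mathrm{TF} = \sum_{nucleus}(I - b) \,/\, \sum_{cell}(I - b)$, both sums
clipped at zero, undefined (flagged `NA`) if the denominator is
non-positive. The published formula has no background term, but with any
nonzero camera offset the ratio is then bounded away from 0 and 1; the
package therefore subtracts an estimated background by default — the mode
of the pixels outside all cell regions — and `background = 0` gives the
literal ratio. On noise-free fixtures the limits are exact: fully nuclear
signal → 1, fully cytoplasmic → 0 (tested as identities).

**Line-profile AUC** is a trapezoidal integral of the
background-subtracted profile; both the total (intensity·µm) and the
per-µm normalisation are reported, since which of the two is appropriate
depends on whether section thickness varies.

## 5. Response curves and the set point

`bin_by_shear()` maps each cell's chamber position to shear and averages
within equal-width shear bins (default 15 across the configured range,
matching a field-per-station acquisition). By default the response is
averaged per image first and bin statistics are computed over image means
— the unit of replication in the original curves — with pooled-cell mode
available. Empty bins are dropped with a notice.

`smooth_lowess()` wraps the canonical LOWESS smoother (tri-cube weights,
default span 0.5, 3 robustness iterations, no interpolation shortcut).
The published figures state LOWESS smoothing but not the span; 0.5 is the
package default, exposed as a parameter. One documented quirk of canonical
LOWESS (R and Python implementations agree): with a narrow span, the
robustness reweighting can zero out every neighbour that a gross outlier
distorted, in which case the fitted value *at the outlier's own abscissa*
falls back to the raw value while all surrounding points are cleaned; a
wider span removes the outlier everywhere.

`estimate_set_point()` operationalises "the range over which the response
is optimal": the optimum is the extremum of the smoothed curve (minimum
for orientation and NF-κB-like TF, maximum for Smad1-like TF) and the
optimal range is the maximal contiguous run of bins whose smoothed
response has covered at least a criterion fraction (default 0.8) of the
baseline-to-optimum span. The criterion is the package's own definition —
the published description gives only an approximate range — and it is
exposed as a parameter. The baseline defaults to the worst smoothed bin
but should be the no-flow measurement when available. Because the estimate
depends only on the ratio of spans it is invariant to affine rescaling of
the response (tested). A monotone curve puts the extremum on a boundary
bin; the estimate is still returned, flagged `at_boundary`.

`anova_shear_effect()` is a fixed-effects one-way ANOVA of the response
against shear bin, the test used for the published curves. Perfect
separation (zero within-group variance, distinct means) reports F = ∞;
all-equal data reports an undefined, flagged F. No multiple-testing
correction is applied across readouts, matching the per-readout reporting
convention; users comparing many readouts should correct externally.

## 6. Determinism and problem sizes

Every stochastic step (placement, angles, TF draws, noise) runs under a
seed derived deterministically from a single top-level seed, and sampling
restores the caller's RNG state. The validation suite uses 16 fields of
100 cells for end-to-end set-point recovery (recovering the generator
optimum within ±3 dyn·cm⁻² across 5 seeds), 10,000 cells for the
uniform-orientation mean-angle check, and 256–1024 px fields throughout —
sizes chosen so the full suite runs in a few minutes on a laptop while
leaving the statistical checks well-powered.

## 7. Known limitations

* The chamber model is ideal lubrication theory; near the inlet, outlet
  and side walls the true shear deviates from $\tau(x)$.
* Whole-cell regions are geometric constructions, not membrane
  segmentations; TF values on real data inherit that approximation.
* The set-point range depends on the smoothing span and criterion
  fraction; both are parameters, and conclusions should be checked for
  stability across reasonable values.
* The generator's simplifications (Section 2) mean real-data performance
  must be validated per dataset, e.g. by spot-checking segmentations.
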