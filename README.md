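# shearsetpoint

Endothelial cells prefer a particular magnitude of fluid shear stress — a
*set point*. Cells experiencing shear near their set point align with the
flow, suppress inflammatory NF-κB signalling and activate stabilizing Smad
signalling; shear above or below it pushes them toward remodeling
programmes. The set point differs between vessel types (venous cells sit
near physiological venous shear, lymphatic cells far lower), which is how
vessels can remodel their lumen until wall shear returns to the preferred
value.

`shearsetpoint` is an R package for quantifying this behaviour from
gradient flow-chamber experiments, aimed at vascular-biology labs doing
image-based shear-response assays. It covers the full analysis path:

* **Chamber physics** — a tapered parallel-plate chamber whose width
  profile w(x) = 6μQ / (h²τ(x)) produces a linear wall-shear ramp
  τ(x) = τ₁ + (τ₂ − τ₁)·x/L along one slide, so each microscope field along
  the axis samples a different shear (presets for the published 2–60 and
  0.5–20 dyn·cm⁻² ranges). A Poiseuille estimator τ = 8μV/D gives in vivo
  reference values (e.g. ~12.5 dyn·cm⁻² for the umbilical vein).
* **Segmentation** — nuclei from the nuclear-stain channel via CLAHE +
  Otsu thresholding + connected components with an area filter; whole-cell
  regions by fixed-radius dilation partitioned between neighbours (or an
  intensity-based alternative).
* **Morphometry** — per-cell nuclear orientation as the acute angle
  between the moment-ellipse major axis and the flow direction (0° =
  aligned, 45° = random, 90° = perpendicular); the translocation factor
  TF = nuclear / whole-cell integrated transcription-factor intensity
  (1 = fully nuclear, 0 = fully cytoplasmic); line-profile AUC for
  fluorescence line scans.
* **Response curves** — shear-binned means ± SEM, LOWESS smoothing,
  one-way ANOVA for a shear effect, and set-point estimation (extremum of
  the smoothed curve plus the contiguous shear range within a criterion
  fraction of the baseline-to-optimum span).
* **Synthetic data** — a ground-truthed generator that renders two-channel
  fields of elliptical nuclei whose orientation distribution and
  nuclear/cytoplasmic stain partitioning follow a parameterised biphasic
  response model, so the whole pipeline is testable without microscopy
  data.

## Worked example

Simulate a venous-like experiment (set point at 15 dyn·cm⁻², 16 fields of
100 cells along a 2–60 dyn·cm⁻² chamber), analyse it blind to the ground
truth, and estimate the set point:

```r
library(shearsetpoint)

cfg   <- chamber_preset("huvec")   # 0.8 mm gasket, 2-60 dyn/cm^2
model <- response_model()          # biphasic optimum at 15 dyn/cm^2
res   <- run_pipeline(cfg, model, n_positions = 16, n_cells = 100, seed = 1)

res$set_point
#> Shear-stress set point: 15.53 dyn/cm^2 (optimal range 7.80 - 15.53)
#>   response min = 21.744, baseline = 46.763, criterion = 80%

res$anova$F
#> [1] 26.50  # one-way ANOVA, df (12, 1587): shear strongly affects orientation

head(as.data.frame(res$curve), 4)
#>   bin_center mean  sem n smoothed
#> 1       3.93 34.2 5.26 2     30.1
#> 2       7.80 21.4 0.00 1     26.2
#> 3      11.67 21.6 0.00 1     22.9
#> 4      15.53 19.2 0.00 1     21.7
```

The estimated optimum (15.5 dyn·cm⁻²) recovers the generator's true set
point (15) to within half a bin width; the folded-angle minimum of ~20°
against a ~45° baseline reproduces the expected alignment contrast. A
lymphatic-like model (`response_model_preset("hdlec")`, optimum 5
dyn·cm⁻²) analysed the same way recovers the lower set point, reproducing
the venous/lymphatic ordering.

A thin command-line front end with `chamber`, `simulate`, `segment`,
`measure`, `curve`, `setpoint` and `run` subcommands is installed at
`system.file("cli/shearsetpoint", package = "shearsetpoint")`.

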