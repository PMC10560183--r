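# facemotion

Kinematic and statistical analysis of 4D facial-expression recordings in
R.

Video stereophotogrammetry records a face as a sequence of 3D surface
meshes (typically 60 fps). Once a template mesh is tracked through the
sequence, every vertex keeps its anatomical identity across frames —
*vertex-wise correspondence*. `facemotion` consumes such corresponded
sequences of two standardized expressions, **maximum smile** and **lip
purse**, and quantifies each recording with four parameters between the
last rest frame *s* and the first frame *e* at maximum extent:

| parameter | definition |
|---|---|
| magnitude (mm) | smile: (d<sub>cheilion&nbsp;right</sub> + d<sub>cheilion&nbsp;left</sub>) / 2; lip purse: (d<sub>labrale&nbsp;superius</sub> + d<sub>labrale&nbsp;inferius</sub>) / 2, where d is the Euclidean displacement of the landmark from *s* to *e* |
| shape change | Procrustes distance of the *lower face* (all vertices at or below a plane through subnasale parallel to Frankfort Horizontal) between *s* and *e*, after superimposition by translation, scaling and rotation |
| symmetry (mm) | &#124;d<sub>right</sub> − d<sub>left</sub>&#124; (smile), &#124;d<sub>superius</sub> − d<sub>inferius</sub>&#124; (lip purse) |
| time (s) | (e − s) / fps |

A statistics layer reproduces a paired pre/post surgical study design:
linear mixed-effects models `metric ~ time * skeletal_class +
(1 | subject)` with estimated marginal means and 95% CIs, paired
Wilcoxon signed-rank sensitivity tests, OLS models of per-subject change
on nine surgical movement covariates, and two-way intraclass correlation
coefficients for method-error analysis.

Because clinical 4D recordings are rarely shareable, the package ships a
synthetic generator: a parametric face template (930 vertices; its
lower-face cut contains exactly 559 vertices by construction) animated by
compact-support expression rigs whose commanded amplitude/asymmetry *are*
the ground-truth magnitude/symmetry exactly, plus a cohort simulator
calibrated to a 26-patient orthognathic study population. Every pipeline
stage is validated against that ground truth; see the methods vignette
(`vignettes/facial-motion-analysis.Rmd`) for the model, the calibration
derivations and the limitations.

## Worked example

Animate a smile on the template (16 mm amplitude, 2 mm asymmetry, 0.4 s
rise, 0.15 mm tracking noise), trim it, and measure it:

```r
library(facemotion)

tpl  <- build_face_template()
sim  <- animate_expression(tpl, "smile", amplitude = 16, asymmetry = 2,
                           time_to_peak = 0.4, noise_sd = 0.15, seed = 2024)
clip <- trim_clip(sim$sequence, tpl$landmarks, "smile")
clip
#> <expression_clip> frames 11 -> 34 (0.383 s @ 60 fps)
compute_motion_metrics(clip, tpl$landmarks)[
  , c("magnitude", "shape_change", "shape_change_mm", "symmetry", "time")]
#>   magnitude shape_change shape_change_mm symmetry   time
#> 1     15.86      0.06762           76.43    1.678 0.3833
```

The detected clip is one frame off the commanded rest/peak pair (10→34)
and the measured magnitude/symmetry sit within the tracking noise of the
commanded 16 mm / 2 mm — the zero-noise round trip is exact to 1e-6 mm.
`shape_change` is the size-normalized Procrustes distance;
`shape_change_mm` is the raw residual in mm (both are always reported,
since the two conventions differ by orders of magnitude on a dense ROI).

A full calibrated study, cohort statistics included:

```r
report <- run_study(default_cohort_config(n_subjects = 26, seed = 1))
subset(report$stats$pooled_table, expression == "smile")
#>  expression       metric timepoint  emmean   lower   upper  p_time
#>       smile    magnitude        T0 16.8005 14.7684 18.8326 0.00299
#>       smile    magnitude        T1 18.4473 16.4152 20.4795 0.00299
#>       smile shape_change        T0  0.0706  0.0624  0.0788 0.00232
#>       smile shape_change        T1  0.0774  0.0692  0.0856 0.00232
#>       smile     symmetry        T0  1.1036  0.6312  1.5761 0.01484
#>       smile     symmetry        T1  1.9434  1.4710  2.4159 0.01484
#>       smile         time        T0  0.4160  0.3738  0.4582 0.66743
#>       smile         time        T1  0.4071  0.3648  0.4493 0.66743
```

Each row is a model-based group mean with its 95% CI; `p_time` is the
type-III time main effect. This seed's cohort happens to sit ~1.5 mm
above the calibration centre for smile magnitude — a single 26-subject
draw has a sampling SD of ≈ 1 mm, which is why calibration agreement is
asserted on replicate averages (below). Real recordings enter the same
pipeline through `read_manifest()` / `load_manifest_sequences()` /
`analyze_sequences()`; `inst/cli/facemotion` exposes the verbs
`simulate`, `analyze`, `stats`, `run` and `method-error` for shell use.

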