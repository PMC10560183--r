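---
title: "Analysing 4D facial-expression recordings with facemotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing 4D facial-expression recordings with facemotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facemotion)
```

## The measurement problem

Video stereophotogrammetry ("4D" capture) records a subject's face as a
sequence of 3D surface meshes, typically at 60 frames per second. When a
generic template mesh is fitted to the face in the first frame and tracked
through the sequence, every vertex keeps its anatomical identity over
time: vertex *i* in frame 40 is the same skin point as vertex *i* in frame
0. `facemotion` consumes such *corresponded* sequences and quantifies two
standardized expressions — a maximum smile and a lip purse — with four
parameters per recording:

* **magnitude** (mm): the mean Euclidean displacement, between the last
  rest frame *s* and the first frame *e* at maximum extent, of the two
  most-moving landmarks — cheilion right and left (mouth corners) for the
  smile, labrale superius and inferius (midline vermilion points) for the
  lip purse;
* **shape change**: the Procrustes distance between the start- and
  end-frame configurations of the *lower face*, the region at or below a
  plane through subnasale oriented parallel to Frankfort Horizontal;
* **symmetry** (mm): the absolute difference between the two landmark
  displacements (0 = perfectly symmetric);
* **time** (s): `(e - s) / fps`, the time needed to reach the maximum
  expression.

Displacement is start-versus-end, not a cumulative path length, so the
parameters describe the excursion of the expression, not the trajectory.
The typical application is a paired surgical study: each subject is
recorded before (T0) and after (T1) orthognathic surgery, and the cohort
is compared over time and between skeletal classes II and III.

## Clip trimming

Clinical systems trim recordings manually from the last rest frame to the
first frame at maximum extent. Reproducibility requires an algorithmic
rule, so `trim_clip()` operationalizes it on the excursion curve
`a(t)`, the mean displacement of the two expression landmarks relative to
frame 0:

1. `a(t)` is smoothed with a short moving average (default 5 frames) to
   obtain a noise-robust maximum `M`; if `M` is below `min_motion`
   (default 1 mm) the recording is rejected as expressionless.
2. The **end frame** is the first frame whose raw excursion reaches
   `peak_fraction * M`. The default is 0.999: the smoothstep-like approach
   to a natural peak is flat near its maximum, and a laxer threshold
   (e.g. 0.98) systematically selects a frame two or more frames early,
   biasing the time parameter low. A strict argmax, conversely, is
   noise-fragile; 0.999 recovers the true peak frame exactly on noiseless
   input while tolerating tracking noise.
3. The **start frame** is found in two stages. A coarse motion onset is
   the first frame (before the end frame) whose smoothed landmark speed
   exceeds `rest_speed_threshold` (default 0.1 mm/frame) on two
   consecutive frames — the two-frame requirement suppresses isolated
   noise spikes. The start is then refined to the last frame whose
   excursion is within one robust SD (MAD) of the rest-phase median,
   re-estimating that baseline from the frames before the current start
   until the answer is stable; the iteration prevents a late onset from
   contaminating the baseline with ramp frames. A recording whose
   excursion rises strictly from frame 0 has no rest plateau and starts
   at frame 0.

Manual start/end overrides bypass detection for curated clips. On
noiseless synthetic input the rule recovers the commanded rest and peak
frames exactly; with 0.15 mm tracking noise the residual bias of the time
parameter is below half a frame (measured by simulation in the test
suite).

No rigid head-motion compensation is applied by default — subjects are
instructed to keep the head still, and the displacement definition is
taken directly on the recorded geometry. `stabilize_sequence()` offers
optional rigid alignment on the (undeforming) upper face for recordings
with visible drift.

## The lower-face region and Procrustes shape change

The lower-face ROI is computed once on the clip's start frame — every
vertex with signed distance ≤ 0 to the subnasale plane, vertices within
1e-9 mm counted as below so the on-plane subnasale vertex is included
deterministically — and transferred to all other frames by vertex index,
exactly as a fixed template topology transfers a region across frames and
subjects. Frankfort Horizontal is not reconstructible from the five lip
landmarks, so its orientation is supplied as capture metadata
(`fh_normal`); the synthetic generator records its ground-truth value.

`shape_change()` superimposes the end-frame ROI configuration onto the
start-frame configuration by translating, scaling and rotating (ordinary
Procrustes analysis; reflections are disallowed by sign-correcting the
smallest singular direction, since a face cannot mirror between frames)
and reports the residual root-sum-of-squares. Two conventions are
computed, because the field reports shape change both ways and they
differ by orders of magnitude on a dense ROI:

* `shape_change` — both configurations are first scaled to unit centroid
  size; the result is the classical (partial) Procrustes distance, of
  order 0.01–0.1 for subtle expression-induced deformation of a
  559-vertex region, matching the scale conventionally reported;
* `shape_change_mm` — the raw residual in millimetres after full
  similarity superimposition.

Both appear as separate columns in every metrics table. The superimposed
direction is end-onto-start, so change is expressed in the rest pose.

## The synthetic generator

No public 4D face dataset with vertex correspondence accompanies the
study design this package targets, so validation uses a generator whose
contract is *ground-truth fidelity, not realism*:

* **Template.** A bilaterally symmetric, face-like parametric surface on
  a structured 31 × 30 grid (930 vertices, 120 × 145 × 65 mm) with an
  ellipsoidal depth profile, a small lateral "cheek lift" making
  subnasale the unique lowest vertex of its row, and the five required
  landmarks at anatomically sensible grid positions. The subnasale row is
  placed so the lower-face cut contains exactly 559 vertices (558
  strictly below the plane plus subnasale on it), pinning the ROI
  contract; this constrains the column count to divisors of 558.
* **Rigs.** Expression deformation fields use compactly supported
  Wendland kernels: the smile pulls each mouth corner laterally-superiorly
  with a 40 mm support (shorter than the inter-cheilion distance, so the
  two sides are independent); the lip purse protrudes each labrale
  anteriorly with a 14 mm support (shorter than the inter-labrale
  distance). Consequently the commanded amplitude *is* the ground-truth
  magnitude and the commanded asymmetry (±a/2 split across sides) *is*
  the ground-truth symmetry, exactly — the zero-noise round trip is tested
  to 1e-6 mm. The supports also keep the commanded landmarks the
  most-moving vertices, consistent with their ROI role.
* **Motion.** Rest frames, a smoothstep ramp over the commanded
  time-to-peak (quantized to whole frames), then a short hold at peak.
  Tracking noise is i.i.d. isotropic Gaussian per vertex per frame
  (default SD 0.15 mm, a mid-range figure for stereophotogrammetric
  tracking).

What the generator does *not* emulate — biomechanical tissue coupling,
temporally correlated tracking drift, facial anatomy beyond a smooth
grid, head motion — bounds what passing tests show: they validate the
measurement and statistics pipeline, not robustness to every artefact of
real capture.

## Cohort calibration

`default_cohort_config()` encodes the study conditions of a 26-patient
orthognathic cohort (13 skeletal class II, 13 class III; 21 bimaxillary
and 5 mandible-only interventions; surgical movement covariates with
stated means and SDs, translations truncated at zero). Per-class,
per-timepoint means for magnitude, symmetry and time are taken from the
published per-class summaries the generator emulates; spreads are derived
rather than invented:

* between-subject SDs from the printed 95% CIs,
  `SD = half_width * sqrt(n) / 1.96` (e.g. smile magnitude
  2.17 × √26 / 1.96 ≈ 5.6 mm);
* within-subject (residual) SDs from the paired-test p-values of the
  pre/post comparison: a change of 2.03 mm with p = 0.002 at n = 26
  implies SE ≈ 0.60, SD of change ≈ 3.0, hence a residual SD of
  ≈ 2.1 mm per timepoint, with the between-subject intercept SD reduced
  accordingly so the marginal SD still matches the CI;
* the between/within split of the *time* parameter is not identified by
  the published summaries and is split evenly — a stated assumption;
* symmetry is generated as a gamma-distributed commanded asymmetry
  magnitude (matching mean; printed CIs imply an SD comparable to the
  mean, hence the skewed family) with a subject-level dominant side,
  independent across timepoints (the published change p-values imply
  near-zero within-subject correlation for this metric).

Magnitudes follow the paired structure
`mu[class, time] + b_subject + e`, so T0 and T1 are correlated within
subject exactly as the mixed model and the Wilcoxon test assume. All
randomness derives from one master seed; each recording additionally
carries its own derived noise seed so any single sequence is regenerable
in isolation.

## Statistics layer

`fit_time_class_model()` fits
`metric ~ time * class + (1 | subject)` by REML on complete cases and
reports estimated marginal means with 95% CIs, pooled over class and per
class, plus the type-III time-effect p-value (Satterthwaite degrees of
freedom — the t-based Wald form appropriate for a small balanced design;
under a null time effect the p-values are uniform, verified over 400
simulated cohorts). An exactly constant metric short-circuits to a
degenerate result (EMMs equal the constant, effect 0) rather than a
singular fit. `wilcoxon_paired()` drops zero differences (the original
convention; count reported), is exact for ≤ 25 non-zero differences and
uses the continuity-corrected normal approximation above.
`fit_surgical_model()` regresses each subject's T1−T0 change on the nine
surgical movement covariates plus class and intervention type by OLS,
erroring informatively on rank-deficient designs. `icc()` implements the
two-way single-measure forms — ICC(A,1) absolute agreement and ICC(C,1)
consistency — from explicit ANOVA mean squares with F-based confidence
intervals; no multiple-testing correction is applied anywhere, mirroring
per-metric reporting.

`method_error_run()` emulates repeated template application: each repeat
re-perturbs all vertices of the same recordings and re-runs the pipeline,
and the cases-by-repeats matrices of magnitude and lower-face shape
change yield both ICC forms.

## Numerical and validation choices

Problem sizes in the shipped tests are chosen to keep the full suite in
the minutes range on one core: zero-noise round trips over 20 random
rigs; Procrustes checks against an independent multi-start
numeric-optimization oracle (Nelder–Mead with BFGS polish over rotation
angles, log-scale and translation) on 20 noisy configurations; 100
replicate calibrated cohorts for the Monte-Carlo recovery study; 400
table-level replicates for the null calibration of the mixed model; 50
random matrices against an `aov()`-based ICC oracle.

Two validation conventions deserve note. First, a single 26-subject
cohort mean has a sampling SD of ≈ 1.1 mm for smile magnitude under the
calibrated spread, so no single run can resolve the calibration constant
to a few tenths of a millimetre; single-cohort checks therefore compare
the pipeline's recovered means against the same cohort's *commanded*
ground truth (what a measurement pipeline can be held to), while
agreement with the calibration constants themselves is asserted on
100-replicate averages (Monte-Carlo SE ≈ 0.08 mm), where the recovery
bias is additionally shown to be below 0.1 mm. Second, the acceptance
script reports replicate-averaged estimates for the same reason; its
replicate count (default 50) is a precision/runtime trade-off giving a
Monte-Carlo SE of ≈ 0.16 mm on the smile-magnitude EMM.

## Known limitations

* The expression rigs are kinematic, not biomechanical; transfer of the
  calibrated recovery results to real faces rests on the correspondence
  contract holding in the capture pipeline.
* Frankfort Horizontal must be supplied; the package does not estimate
  head pose from ear/orbital geometry.
* The statistics layer covers exactly two timepoints and two classes;
  longer longitudinal designs are out of scope.
* The size-normalization convention behind the conventionally reported
  shape-change scale is not standardized in the literature; both variants
  are therefore always exported, and no claim is made that either matches
  any particular published table's convention.

## A minimal session

```{r example, eval = FALSE}
library(facemotion)

# a small calibrated study end to end
report <- run_study(default_cohort_config(n_subjects = 26, seed = 1),
                    output_dir = "study_out")
report$stats$pooled_table

# method-error analysis: 10 cases re-tracked 3 times
me <- method_error_run(n_cases = 10, n_repeats = 3,
                       repeat_noise_sd = 0.15)
me$table
```
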