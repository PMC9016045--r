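---
title: "Quantifying immune-related adverse events on FDG-PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immune-related adverse events on FDG-PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iraePET)
```

## The problem

Immune-checkpoint inhibitors (ICI) can trigger immune-related adverse events
(irAE) — colitis, pneumonitis, thyroiditis — that are diagnosed clinically,
often late. Whole-body ^18^F-FDG PET/CT, already acquired for response
assessment in melanoma, is sensitive to the inflammation underlying these
toxicities. iraePET implements an automated, organ-level quantification of
that signal:

1. **SUV normalization.** Reconstructed activity (Bq/mL) is converted to
   standardized uptake values, `SUV = A * weight / dose` (g/mL), assuming
   decay correction was applied at reconstruction.
2. **Organ-masked percentile profiles.** Given a labeled organ mask (bowel,
   lung, thyroid), the percentiles SUV~X%~ of the within-organ SUV
   distribution are extracted. Percentiles are used instead of SUV~max~
   because they are far more robust to segmentation error: a handful of
   mislabeled out-of-distribution voxels moves the maximum but barely moves
   a percentile.
3. **Optimal percentile (SUV~OPT%~).** For each organ, the percentile
   maximizing the AUROC for discriminating patients with versus without an
   irAE of that organ, where each patient's score is the *maximum* SUV~X%~
   over on-treatment scans (`scan_day >= 0`; baselines are excluded from the
   predictor).
4. **Operating point.** The cutoff T~OPT~ maximizing Youden's
   J = sensitivity + specificity − 1, under the classification rule
   score > T ⇒ positive.
5. **Normative band and monitoring.** From baseline scans of patients with
   no irAE of *any* organ, the band CI~95~ = [μ − 1.96σ, μ + 1.96σ] of
   SUV~OPT%~ is computed per organ. Longitudinal series are flagged where
   they strictly exceed the upper bound; the lead time is the clinical
   detection day minus the first flagged day.

Because the underlying clinical images are not public, the package ships a
synthetic phantom cohort generator with the statistical structure the
analysis assumes, so every stage is testable end-to-end.

## Statistical conventions

Several conventions are not dictated by the mathematics and are therefore
fixed, documented and (where sensible) configurable:

* **Percentile convention.** Closest-rank linear interpolation: rank
  r = 1 + (n − 1)·X/100, interpolating between the floor and ceiling order
  statistics. This is `stats::quantile(type = 7)` and is the single most
  consequential reproducibility choice; `organPercentiles()` exposes `type`
  for sensitivity analyses. The default grid is {5, 10, …, 95, 100}.
* **AUROC ties.** Half credit (the Mann–Whitney identity
  AUROC = U/(n₁n₂)); verified against an independent rank-based U
  implementation in the tests.
* **Argmax ties in percentile selection.** The smallest tied percentile
  wins: lower percentiles are more robust to mis-segmentation, so when the
  data cannot distinguish them the conservative choice is preferred.
* **ROC polarity.** Strictly greater than the threshold ⇒ positive,
  matching cutoff statements of the form "SUV~95%~ > 2.7 g/mL".
* **Youden ties.** Higher specificity first, then the lower threshold.
* **Wilcoxon rank-sum.** Exact enumeration when the combined sample is ≤ 12
  and tie-free; otherwise the normal approximation with tie and continuity
  correction.
* **Flagging.** One-sided: only excursions *above* the band are flags
  (inflammation raises uptake); values exactly at the bound are not flagged.
* **Post-diagnosis scans** are included in the patient maximum by default;
  `censor_post_diagnosis` excludes them.
* **Scores after ties in patient exclusion.** Patients with baseline-only
  imaging are excluded from the score table with a message, not an error.

## The phantom and the uptake model

`phantomSpec()` defines a 256 × 256 × 384 mm field of view voxelized at 4 mm
(64 × 64 × 96) by default: lungs as two large ellipsoids, the thyroid as two
small lobes joined by an isthmus bridge, and bowel as a 14-mm-radius tube
folded in four serpentine passes through the abdomen. Geometry is specified
in millimetres, so the same spec voxelizes consistently at any resolution
(tests use 8 mm for speed; halving the voxel size multiplies organ voxel
counts ≈ 8-fold). Masks are resampled — nearest neighbour, labels never
interpolated — onto the PET grid, not the PET onto the mask grid, to avoid
inventing SUV values.

`uptakeModel()` generates baseline scans as:

* organ voxels ~ log-normal(location, scale) — SUV distributions are
  positive and right-skewed;
* a per-patient, per-organ multiplier ~ N(1, `patient_sd`), constant across
  that patient's scans. This between-patient component is essential: an
  organ of thousands of voxels pins its own percentile almost exactly, so
  voxel-level dispersion alone cannot generate the 12–20% between-patient
  coefficient of variation the normative bands imply;
* background ~ N(0.5, 0.1) g/mL clipped at zero;
* Gaussian point-spread blurring, FWHM 6 mm by default (separable,
  edge-renormalized);
* additive Gaussian voxel noise (sd 0.05 g/mL), clipped at zero.

### Inflammation events

`iraeEvent()` encodes the two morphologies that drive which percentile is
informative. *Diffuse* events (thyroiditis-like) multiply every organ voxel,
shifting the whole SUV histogram up uniformly — so AUROC is nearly flat
across percentiles. *Focal* events (colitis/pneumonitis-like) multiply a
connected sub-region of fraction f (default 0.1) of the organ volume — so
only percentiles above ≈ 100·(1 − f) move, and the optimum lands at 95–100.
The focal region is the f·n organ voxels nearest a seed point, i.e. a
ball-within-organ; it is fixed per event so it persists across a patient's
scans.

The uptake multiplier ramps from 1 to the peak k along a logistic curve
reaching ≈ 98% of k 30 days after onset — longitudinal series in practice
rise gradually, but no published dynamics exist, so the ramp shape and
30-day scale are explicit, overridable parameters. Clinical detection occurs
`clinical_lag` days after imaging-visible onset (default uniform 14–60
days), so imaging-leads-clinical scenarios occur by construction. If a
resolution day is set, the multiplier relaxes back exponentially (30-day
scale).

### Calibration

`calibrateBaseline()` tunes each organ's `location` and `patient_sd` so
that, across simulated irAE-free patients, the mean and sd of the organ's
target percentile (SUV~95%~ for bowel and lung, SUV~75%~ for thyroid) match
the published normative bands, inverted via μ = (lo + hi)/2,
σ = (hi − lo)/3.92: bowel [1.74, 2.86], lung [0.73, 1.46], thyroid
[0.86, 1.99] g/mL. The fixed-point iteration uses multiplicative updates
with damping 0.8 and common random numbers (the same per-patient seeds every
iteration), converging in ~3 iterations of 160 patients to within the 5%
relative tolerance; non-convergence after 15 iterations is an error carrying
the achieved versus target moments. Calibration and coverage checks render
each organ on its cropped bounding box (plus a margin exceeding the PSF
kernel radius) — statistically identical to rendering the full volume, since
the noise field is independent across voxels and the blur is local.

### Cohort schedules

`cohortSpec()` defaults reproduce the study conditions: 58 patients; organ
prevalences 6/58, 5/58, 9/58; a baseline scan near day −36; a first
follow-up near day 113 and further scans every ≈ 90 days (±14-day jitter);
scans per patient = 2 + Poisson(2), giving median 4 with a long right tail.
The within-patient scan-count distribution beyond the published
median/range is unknown; the Poisson tail is a free choice. One master seed
drives the cohort plan; per-patient and per-scan seeds are derived
deterministically so any subset can be regenerated bit-identically.

## What the simulations do and do not show

The generator reproduces the *statistical* structure the analysis relies on:
calibrated baseline percentile distributions, diffuse-versus-focal
inflammation geometry, gradual onset preceding clinical detection, and
realistic scan schedules. It does **not** model real anatomy,
attenuation/scatter physics, tumor lesions, scanner harmonization,
metformin-induced bowel uptake, or segmentation failure. Passing tests
therefore demonstrate that the pipeline's statistics are implemented
correctly and behave as designed under the assumed data-generating process —
not that the published clinical effect sizes would replicate on new
patients.

Problem sizes used by the validation studies (chosen to give stable Monte
Carlo estimates): calibration at 160 patients/iteration; band coverage on
1000 simulated irAE-free patients; percentile-pattern recovery on 50
case-control cohorts of 16 patients each per pattern; longitudinal
monitoring on 20 cohorts of 10 patients with 60-day scan intervals, onset
uniform in [30, 180] days, k in [2.5, 3.5] and clinical lag uniform in
[60, 120] days (a lag window wide enough that a 60-day schedule can catch
the pre-clinical rise); oracle sweeps on 500–1000 random cohorts.

## Numerical and degenerate-input choices

* Grids must agree (dims, spacing, origin within 1e-6 mm) before mask
  application; mismatches are errors, not silent resampling.
* An organ absent from a mask is an explicit empty-organ error, distinct
  from an empty value list.
* AUROC, ROC, Youden and the rank-sum test refuse single-class input with a
  signalled condition; the pipeline converts that into a per-organ "stage
  skipped" notice so zero-event cohorts still produce normative ranges.
* DSC with two empty masks and ASSD with any empty mask are signalled as
  undefined rather than returning a value.
* ASSD surfaces are 6-connected boundary voxels (the volume border counts
  as outside); distances are Euclidean between voxel centres in world mm.
* The normative band requires ≥ 2 contributing patients (n − 1 sd).
* SUV volumes are clipped at zero after additive noise to maintain the
  physical non-negativity invariant.

## Known limitations

* The phantom's bowel tube self-approaches at its U-turns; focal regions near
  a turn can span adjacent passes. Real colitis can likewise involve
  adjacent loops, but this is a geometric accident, not a modeling choice.
* The thyroid occupies only ~360 voxels at 4 mm, so PSF mixing with
  background is strong; calibration absorbs this into `location`, which is
  therefore not interpretable as pure tissue uptake.
* Between-patient variability is a single multiplicative factor per organ;
  real cohorts also vary in organ shape, position and texture.
* The monitoring false-flag rate among event-free patient-organs runs
  slightly above the nominal 2.5% one-sided tail (≈ 3–4%): the patient
  maximum over repeated scans takes multiple draws at the band, and the
  per-organ score distribution has a mild right skew.

## A worked example

```{r example, eval = FALSE}
library(iraePET)

mask <- buildPhantom(phantomSpec())
model <- calibrateBaseline(uptakeModel(), mask = mask, n = 160, seed = 1)

cohort <- simulateCohort(cohortSpec(seed = 1), model = model, mask = mask)
table <- buildScoreTable(cohort@profiles, cohort@truth)

sel <- selectOptimalPercentile(table, "bowel")
sc <- scoresAtOptimum(table, sel)
cut <- youdenCutoff(rocCurve(sc$score[sc$irae == 1],
                             sc$score[sc$irae == 0]), "bowel")

base <- simulateBaselines(200, model, mask, seed = 2)
rng <- normalRange(base$value[base$organ == "bowel"], "bowel")
series <- longitudinalSeries(cohort@profiles, cohort@truth$patient_id[1],
                             "bowel", sel@opt_percentile)
monitorSeries(series, rng, clinical_day = cohort@truth$clinical_day[1])
```

The same flow, with figures and JSON/CSV outputs, is available as
`cmdPipeline(runConfig(...))` or from the shell via
`inst/scripts/irquant.R`.
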