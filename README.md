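# iraePET

Quantitative ^18^F-FDG PET imaging biomarkers of immune-related adverse
events (irAE) for patients on immune-checkpoint inhibitors. The package is
aimed at imaging scientists who want an automated, organ-level alternative to
visual reads: given co-registered PET volumes and labeled organ masks
(bowel, lung, thyroid), it quantifies organ inflammation, selects an optimal
biomarker per organ, and monitors patients longitudinally — and it ships a
synthetic phantom cohort generator so the whole analysis can be exercised
and validated without clinical images.

## The method

For each organ *o* with mask *M*, the biomarker family is the percentile
profile of standardized uptake values over the organ's voxels,

> SUV_X% = X-th percentile of { SUV(v) : v ∈ M }, SUV = A · w / D (g/mL),

with activity *A* (Bq/mL), weight *w* (g) and injected dose *D* (Bq).
Percentiles, unlike SUV_max, are robust to the handful of mislabeled voxels
an automated segmentation inevitably produces. Each patient's predictor is
the maximum SUV_X% over on-treatment scans; the organ's optimal percentile
maximizes the discrimination of irAE-positive versus negative patients,

> SUV_OPT% = argmax over X of AUROC(X),

with AUROC computed by the Mann–Whitney identity (ties credited ½). The
operating cutoff T_OPT maximizes Youden's J = sensitivity + specificity − 1
under the rule score > T ⇒ positive. Normative ranges come from baseline
scans of patients with no irAE of any organ,

> CI95 = [μ − 1.96σ, μ + 1.96σ],

and a longitudinal series is flagged whenever it strictly exceeds the upper
bound; lead time is the clinical detection date minus the first flagged
scan. Group differences are tested with Wilcoxon rank-sum tests. Mask
quality is assessed with the Dice coefficient and average symmetric surface
distance. See `vignettes/irae-pet-methods.Rmd` for the models, conventions
and design choices.

## Worked example

```r
library(iraePET)

mask  <- buildPhantom(phantomSpec())                      # 4-mm digital phantom
model <- calibrateBaseline(uptakeModel(), mask = mask,    # match normative bands
                           n = 160, seed = 1)
cohort <- simulateCohort(cohortSpec(seed = 1), model = model, mask = mask)
cohort
#> SyntheticCohort: 58 patients, 232 scans, 17 irAE events (bowel=7, lung=4, thyroid=6)

table <- buildScoreTable(cohort@profiles, cohort@truth)
sel   <- selectOptimalPercentile(table, "bowel")
sel
#> BiomarkerSelection [bowel]: SUV_95% AUROC=1.000 (grid of 20 percentiles)

sc  <- scoresAtOptimum(table, sel)
youdenCutoff(rocCurve(sc$score[sc$irae == 1], sc$score[sc$irae == 0]), "bowel")
#> CutoffResult [bowel]: T_opt=3.24 g/mL J=1.000 sens=1.00 spec=1.00

base <- simulateBaselines(200, model, mask, seed = 2)
rng  <- normalRange(base$value[base$organ == "bowel"], "bowel")
rng
#> NormalRange [bowel]: mu=2.278 sigma=0.258 n=200 CI95=[1.77, 2.78] g/mL

series <- longitudinalSeries(cohort@profiles, "P025", "bowel",
                             sel@opt_percentile)
monitorSeries(series, rng, clinical_day = 122)$flags
#>   scan_day    value flagged
#> 1      -45 2.557391   FALSE
#> 2      109 3.996664    TRUE
#> 3      206 6.366616    TRUE
#> 4      295 6.328181    TRUE
```

Reading the output: the simulated cohort mirrors the pilot-study design (58
patients, prevalence-weighted bowel/lung/thyroid events). For the bowel —
where inflammation is focal — the AUROC-optimal percentile is SUV_95%, and
the synthetic events are strong enough for perfect separation at cutoff
3.24 g/mL. The normative band from 200 irAE-free baselines, [1.77, 2.78]
g/mL, reproduces the published bowel band [1.74, 2.86]. Patient P025's bowel
uptake first exceeds the band on day 109, thirteen days before the simulated
clinical diagnosis (day 122) — the imaging-leads-clinical pattern the
monitoring stage is designed to surface. For the thyroid, where simulated
inflammation is diffuse, AUROC is flat across percentiles 65–95 (spread
< 0.001 in this cohort), the signature that makes the optimal-percentile
choice organ-dependent.

The same flow with figures and JSON/CSV outputs:

```r
cmdPipeline(runConfig(outdir = "out", seed = 1))
```

or from a shell: `Rscript inst/scripts/irquant.R pipeline --seed 1
--outdir out`. Real data enter through `readSUVVolume()` /
`readOrganMask()` (NIfTI-1) with a CSV scan-metadata sidecar
(`readScanTable()`); masks on a different grid are moved onto the PET grid
with `resampleMaskTo()` (nearest-neighbour, labels never interpolated).

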