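---
title: "Methods: area-ratio viability scoring and clinical concordance for PTC drug testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: area-ratio viability scoring and clinical concordance for PTC drug testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptcscreen)
```

## The assay and its model

Patient-derived tumor-like cell clusters (PTCs) are matrix-free
multicellular clusters grown from dissociated tumor samples and used as
the unit of personalized drug testing. A drug test seeds 30–50 clusters
per well, images each well at baseline (day 0) and endpoint (day 7), and
quantifies the drug effect from whole-well cluster area:

* per replicate well *i*, the viability ratio is
  `p_i = S_{i,t1} / S_{i,t0}`, where `S` is the sum of areas of all
  clusters with equivalent diameter exceeding 40 µm;
* the test viability is the arithmetic mean `pA = mean(p_i)` over
  replicates (three wells by default);
* a drug is called **effective** when `pA < 0.7` and **not effective**
  when `pA ≥ 0.7`, for single agents and combinations alike;
* an untreated negative-control well set is scored the same way; when its
  viability `pNC < 0.9` the whole test is discarded (the culture is likely
  in its decline phase). The control is a quality gate only — viabilities
  are *not* normalized by `pNC` (a `normalize_by_control` flag exists for
  exploration and is off by default).

Both inequalities are implemented exactly as stated: the 0.7 boundary is
not effective, and a control exactly at 0.9 passes. These are the only two
places the scoring rule states inequalities, so the boundary conventions
are fixed rather than configurable.

Viability ratios are scale invariant in the areas (so pixel size cancels
within a well), may exceed 1 when clusters grow under drug, and are never
negative. Replicate wells with zero baseline area cannot yield a ratio;
they are excluded with a log entry and a test is dropped entirely when
fewer than two usable replicates remain (`min_replicates = 2`). We chose
exclusion over failing the whole test because a single empty well is a
seeding accident, not evidence about the drug.

## Image quantification

The quantification chain is: global Otsu threshold on the
(polarity-corrected) intensities → hole filling → morphological opening
(disc brush, radius 3 px by default — small relative to the 40 µm minimum
cluster) → connected-component labeling → per-component area in µm²
(`pixel count × pixel_size_um²`) and equivalent diameter `2·sqrt(area/π)`.
Polarity is auto-detected from the Otsu split (clusters are darker than
background in transmitted light), and a constant image yields zero regions
rather than an error. Primitives come from EBImage; the chain and its
defaults live in `imaging_config()`.

"Diameter" is operationalized as the equivalent-circle diameter, since
clusters are near-spherical and no alternative definition is given for the
assay. The 40 µm filter is strict (`>`), with an `inclusive` switch for
sensitivity analysis. The filter is applied independently at each
timepoint without tracking individual clusters between days: the scoring
formula uses whole-well area sums, so correspondence between clusters at
t0 and t1 is never needed.

## Synthetic data: what it emulates and what it does not

Every stage is testable against a seeded generator:

* **Growth** (`simulate_growth_trajectory`): a piecewise three-stage
  model — multiplicative growth at `exp_rate` per day until
  `plateau_start_day`, flat for `plateau_duration_days`, then
  multiplicative decay. Defaults: 40 clusters/well, initial diameters
  log-normal around 70 µm, 15 %/day exponential growth, plateau starting
  day 7 and lasting 5–25 days. Measurement noise is multiplicative
  log-normal — viabilities are ratios and must stay positive, and the
  replicate spread the assay reports is CV-like.
* **Images** (`render_well_image`, `place_clusters`): disk phantoms
  (darker disks on a brighter background, optional Gaussian noise and
  blur) with exact analytic and rasterized areas stored as ground truth.
  A pixel belongs to a disk when its centre lies inside the circle, so the
  rasterized area differs from `πr²` only by boundary quantization.
* **Drug response** (`simulate_drug_assay`): the endpoint/baseline ratio
  of a treated well is `growth_multiplier × Hill survival`, with the Hill
  curve (`potency`, `hill`, `max_kill`, per-sample sensitivity multiplier)
  chosen purely for monotone dose dependence — the assay itself never fits
  a dose-response model, so the generator's parametric form is a
  convenience, not a claim.
* **Cohorts** (`simulate_cohort`): one row per treatment with mean
  viability, merged RECIST class and prospective flag. Class sizes default
  to 8 CR/PR, 40 SD and 12 PD with 33 of 60 treatments prospective.
  Viabilities are normal per class, truncated at 0: CR/PR ~ N(0.40,
  0.15), SD ~ N(0.80, 0.22), PD ~ N(1.10, 0.20). These locations were set
  once so the expected class-wise effective fractions match the published
  contingency structure for this assay class (essentially all responders
  below the 0.7 cutoff, roughly a third of SD, essentially no PD), and are
  not tuned thereafter. `binormal_offset()` converts a target AUC into a
  class-location offset under the equal-variance binormal model,
  `AUC = Φ(δ / (σ√2))`, which the recovery tests invert.

All randomness flows from one master seed through `substream_seed()`
(a multiplicative integer mix), so each well's stream is indexed by
(sample, drug, concentration, replicate) and adding a condition never
perturbs another condition's draws.

The generator reproduces the *statistical* structure the analysis assumes
— positive ratio-scale viabilities, replicate spread, class-dependent
location shifts, monotone dose dependence — but not the biology of real
wells: no cluster-cluster contact or fusion, no intra-well heterogeneity
of drug response, no imaging artifacts beyond Gaussian noise and blur, no
sample-to-well allocation (wells are independent even though a real sample
yields hundreds to tens of thousands of clusters). Passing tests therefore
demonstrate that the pipeline computes its quantities correctly under the
stated model, not that the model captures everything in real micrographs.

## Efficacy-concentration calibration

For each drug tested over a 3–6 point concentration gradient, the
efficacy rate at concentration *c* is the fraction of assay-set samples
with `pA < 0.7` at *c* (samples unmeasured at *c* leave the denominator;
no imputation). The calibrated testing concentration Ec is the gradient
concentration minimizing `|ER(c) − ORR|`, where ORR is the clinical
objective response rate supplied as configuration (the ORR sources are
external trials, so the table is an input, not a constant). Ties are
broken toward the *lowest* concentration — the rule is otherwise
unspecified, and lower test concentrations limit off-target kill in the
assay. Efficacy rates are computed over all samples by default; when the
assay-set should be stratified (e.g. by subtype), filter the panel table
before calibration.

## Reproducibility metrics

Per drug-sample pair, the CV is the sample SD over replicate wells
divided by their mean. The pair-resampling analysis draws, 1,000 times,
two distinct replicate columns uniformly at random and correlates them
across all pairs (Pearson and Spearman with average-rank ties). We read
"two randomly selected results" as two replicate measurement vectors over
the same drug-sample pairs — the only reading under which a correlation
across hundreds of pairs is defined; draws are with replacement across
repeats. Correlations within 1e-12 of ±1 are snapped to ±1 so that
identical replicate columns yield exactly 1 despite floating-point
round-off in `stats::cor`.

`simulate_replicate_matrix()` inverts the small-sample bias of the sample
CV when generating: with *n* = 3 replicates the expected sample CV is
about 0.87× the generating CV (the normal-theory c4 factor times a
second-order term from the log-normal's right skew, via the correlation
between replicate SD and mean). The generating CV solves
`c4(n)·cv·(1 − (3cv + cv³)·cv/(2n)) = target`, so a matrix generated "at
CV 0.23" actually exhibits a mean replicate CV of 0.23.

## Clinical concordance

CR and PR are merged on input; the analysis unit is the treatment, not
the patient. For CR/PR-vs-PD comparisons, SD treatments are *excluded*
(not merged), giving the 20-treatment denominator when the cohort is
8 + 12; for the overall comparison SD merges with PD as the resistant
class. Concordance counts (CR/PR ∧ effective) and (resistant ∧ not
effective).

* **Rank test**: Mann-Whitney U with average ranks; exact two-sided p by
  full labeling enumeration when both groups have ≤ 8 observations and no
  ties (12,870 labelings at 8 vs 8 — enumeration is cheap at these sizes),
  otherwise the normal approximation with tie and continuity corrections.
* **ROC/AUC**: pairwise counting `P(score_pos > score_neg) + ½P(tie)`
  with score = −viability, so AUC > 0.5 means low viability predicts
  clinical sensitivity; this equals trapezoidal ROC integration, and a
  property test asserts the identity on 1,000 random cohorts.
* **CI**: DeLong's placement-value variance by default, truncated to
  [0, 1]. The method is a default choice, not a reproduction of any
  specific published interval (the CI method there is unstated). When
  separation is perfect the DeLong variance collapses, so AUC ∈ {0, 1}
  falls back to a stratified bootstrap (2,000 resamples, seeded) with a
  warning.
* **Fisher's exact test**: two-sided p as the hypergeometric sum over
  tables with probability ≤ the observed table's, with a 1e-7 relative
  slack so probability ties survive floating-point rounding.
* Batch p-values are adjusted with Benjamini-Hochberg (`adjust_bh`).

Whether an SD treatment with a pathological response should count as
concordant is a judgment call the data schema cannot settle; the
implementation counts strictly by RECIST class, and sensitivity analyses
can reclassify rows upstream of `concordance_accuracy()`.

## Numerical and degenerate-input conventions

* Baseline area 0 → explicit degenerate-well error naming the well.
* Constant input to `standardize_viability` → error (zero SD).
* All-identical pooled values in the rank test → p = 1 with a warning.
* Constant image → zero segments, not an error; NaN pixels → error.
* `classify_growth_phases` uses a day-over-day relative-change tolerance
  δ = 0.05/day; the three phases are drawn schematically in growth
  curves, so δ is a labeling convention, not an estimate.
* Growth-phase plateau length is the longest stationary run.

## Problem sizes in tests and drivers

The bundled analyses and tests run entirely on synthetic data at the
study's natural scales: 337 drug-sample pairs × 3 replicates for
reproducibility, cohorts of 60 treatments (8/40/12) for concordance,
200-sample panels for Ec recovery, 512×512 px wells with 25–30 clusters
for imaging, and 100–200 replicate cohorts per recovery sweep. These
sizes keep every recovery within tight Monte-Carlo bounds while the whole
suite completes in well under a minute of compute per module.

## Known limitations

* Segmentation assumes non-touching, roughly circular clusters; merged
  clusters would be measured as one. No watershed splitting is applied
  because whole-well area sums are insensitive to merging unless clusters
  overlap the 40 µm boundary.
* No time-lapse tracking, 3D/z-stack handling, or fluorescence channels.
* No IC50 / dose-response curve fitting — the cutoff-and-Ec design is the
  point of the assay, and the generator's Hill curve exists only to give
  the synthetic data monotone dose structure.
* The concordance module treats the outcome table as given; lesion-level
  RECIST evaluation happens upstream of this package.
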