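---
title: "CMD gating and slide-level evaluation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CMD gating and slide-level evaluation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytogate)
```

## The problem

In AI-assisted cervical cytology, a detector/classifier stack reduces each
slide to a large population of single cells, each carrying a vector of
per-class confidence values — here called CMD markers, by analogy with the
cluster-of-differentiation markers of flow cytometry. The values are
independent sigmoid outputs: each lies in [0,1] and the vector does not sum
to one. The scientific questions downstream are population-level: how many
LSIL- or HSIL-like cells does a slide carry, how does that burden relate to
the cytological diagnosis and to HPV status, and how well do count-based
slide scores detect low-grade-or-worse (LSIL+) and high-grade (HSIL+)
disease.

`cytogate` implements that downstream analysis end to end: hierarchical
gating of cells, per-slide aggregation, endpoint scoring, and the
statistical evaluation protocol, together with a synthetic cohort generator
that supplies ground truth, and a small z-stack component for the upstream
single-cell extraction geometry.

## Hierarchical gating

`gate_cell()` applies a fixed rule order: a cell whose *irrelevant*
confidence crosses that gate is discarded as debris/defocus; of the rest,
cells crossing the *leukocyte* gate are labelled leukocytes; of the rest,
cells crossing any lesion gate (LSIL, HSIL, adenocarcinoma) take the crossed
lesion class with the highest confidence (exact ties resolve by severity:
adenocarcinoma > HSIL > LSIL); everything else is assigned by argmax over
the normal epithelial classes. All gates use `>=`, so a threshold of 0
captures everything — this makes the hierarchy-dominance property exact.

Defaults: the lesion gates sit at 0.80, the per-cell probability threshold
used for positive classes throughout the analysis; the irrelevant and
leukocyte gates default to 0.5 and are configurable, since in the source
workflow they are set graphically on scatter plots and no numeric values
are published. Whether that graphical gate is an axis-aligned threshold or
a polygon is unknowable from the published material; we implement
axis-aligned thresholds, which reproduce the described behaviour exactly
for the histogram-based lesion gates and approximate the scatter gate.

Both the 10-class and the 11-class taxonomy (adding navicular cells, a
benign glycogen-rich phenotype that mimics LSIL and is frequent in younger
donors) are supported; navicular is a fallback (normal) class.

## Slide endpoints and scores

`endpoint_spec()` encodes the category sets: LSIL+ excludes ASC-US
(negatives NILM; positives LSIL, ASC-H, HSIL, SCC) and HSIL+ excludes ASC-H
(negatives NILM, ASC-US, LSIL; positives HSIL, SCC). The published material
also describes an all-sample ROC variant with no exclusions; both are
reachable (`all_samples = TRUE`). Two LSIL+ predictors appear in the source
descriptions — the LSIL+HSIL count sum and the LSIL count alone — and the
discrepancy is unresolved there; both are selectable (`score_rule`), with
the sum as default. The HSIL+ predictor is the HSIL count alone. The HPV+
endpoint uses the HPV assay result as the reference label with the same
count scores as predictors; slides with missing HPV results are excluded.

`threshold_sweep()` re-gates all cells with the lesion gates moved together
across a grid (default 0.60–0.99 in steps of 0.01; the published sweep
states the endpoints but not the step) and reports AUC with a
stratified-bootstrap percentile CI at each threshold.

## Statistical protocol

* **Mann–Whitney / Cliff's δ.** One-sided tests under the pre-specified
  alternatives (abnormal > NILM, HPV+ > HPV−). The U statistic counts
  reference wins with ties at 1/2. δ is the standard pairwise effect size,
  δ = 1 − 2U_ref/(n₁n₂) ∈ [−1,1], positive when the comparator tends
  larger; it is linearly tied to the AUC by AUC = (δ+1)/2, and the tests
  verify both identities against brute-force pair counting. Exact p-values
  (via the exact null distribution of U) are used when n₁n₂ ≤ 400 with no
  ties; otherwise a tie-corrected, continuity-corrected normal
  approximation. Which variant the original analysis used is not stated;
  the two agree within 0.01 at n = 15 per group, which the suite checks.
* **Multiplicity.** Benjamini–Hochberg q-values within each analysis
  family (`bh_adjust()`, delegating to `stats::p.adjust`).
* **ROC.** `score >= t` predicts positive; ties contribute 1/2 to AUC.
  `bootstrap_roc_band()` resamples positives and negatives separately
  (2,000 resamples by default), interpolates each resample's curve onto a
  uniform FPR grid (1,001 nodes — the grid is described as uniform but its
  size is not published) and takes pointwise 2.5/97.5 percentiles.
  Percentile intervals, not BCa, per the stated protocol.
* **Operating points.** Human triage rules (ASC-US+, LSIL+) become
  (sensitivity, specificity) points with 95% Wilson intervals.
  `compare_at_matched_operating_point()` reads the AI TPR at the human FPR
  (matched specificity) or inverts the curve at the human sensitivity
  (matched sensitivity), and bootstraps slides jointly; p = 2 × the smaller
  tail of the bootstrap Δ distribution. Whether the human point is held
  fixed or re-estimated per resample is ambiguous in the protocol
  description; we re-estimate both by default and expose
  `refit_human = FALSE` as the fixed-point variant.
* **Age trends.** `lowess_trend()` wraps `stats::lowess` with a
  percentile bootstrap band (100 resamples by default) and optional log
  transform; zero-count slides must be excluded upstream when fitting on
  the log scale.

## The synthetic cohort generator

`simulate_cohort()` defines the study conditions for every test. Its
defaults encode, per slide:

* **Design.** Four centres (C, T, K, J) with truncated-normal age models
  matched to the printed centre medians/IQRs; centre-specific Bethesda
  mixtures (the screening centre K is NILM-richer); HPV positivity
  conditional on diagnosis, with 28% missing results (matching the
  observed fraction of slides lacking HPV data).
* **Cellularity.** Log-normal totals (meanlog = log 15,000, sdlog = 1.15),
  so the central 99% of slides spans roughly 800 to 290,000 cells —
  thousands to hundreds of thousands, the reported dynamic range.
* **Composition.** Age-conditional mixture over the non-lesion classes:
  the superficial/intermediate share declines sigmoidally around age 50,
  navicular cells carry a Gaussian bump peaking at 22 (both published as
  qualitative trends; the functional forms and magnitudes are our
  modelling choices), fixed shares for irrelevant objects and leukocytes.
* **Abnormal burden.** Negative-binomial lesion-cell counts conditional on
  diagnosis and HPV (HPV+ multiplies the mean, ×4 by default). Only violin
  plots of these distributions are published, so the NB means and the
  dispersion (size = 0.8) are free parameters with documented defaults,
  chosen to reproduce the qualitative ordering of burdens across
  categories; they are illustrative, not calibrated to the real data.
* **CMD noise.** Independent Beta draws: the true class from Beta(16,2)
  (mean 0.889), off-classes from Beta(0.5,10) (mean 0.048), with optional
  confusion mass between morphologically adjacent phenotypes
  (navicular↔LSIL, LSIL↔HSIL). A single `concentration` multiplier scales
  all shapes: the means are fixed while the variance shrinks, and the
  `Inf` limit is exactly noiseless (true class 1, others 0). No noise law
  is published; independent Betas are the natural match to independent
  sigmoid outputs.
* **Seeding.** One master seed; each slide uses a substream seed derived
  by counter, so cohorts are byte-identical under the same config and any
  slide subset is reproducible independently of cohort size.

What the generator does **not** emulate: spatial structure on the slide,
optical artefacts, correlated classifier errors within a cell cluster,
centre-specific staining effects, and any calibration to the deposited
real measurements. Passing tests therefore demonstrate correctness of the
analysis machinery under a known data-generating process, not clinical
performance.

## Numerical choices and degenerate inputs

* ROC curves are step functions; interpolation onto the FPR grid takes the
  upper envelope at vertical segments.
* Tie-breaks are all deterministic: lesion-gate ties by severity, fallback
  argmax by taxonomy order, focus-layer ties toward the z-range midpoint
  then the lower index.
* `epithelial_fraction()` returns `NA` on an all-zero denominator; empty
  slides gate to all-zero counts; empty detection lists group to an empty
  instance list.
* The z-stack focus metric defaults to variance-of-Laplacian with
  Tenengrad as an alternative — the extraction procedure names only "local
  contrast or sharpness", so the metric is a declared design decision, as
  are the grouping thresholds (single-linkage, lateral tolerance = half
  the mean box diagonal, layer gap 0) which are likewise unpublished.
  Crops use reflection padding to avoid constant-border focus artefacts.

## Problem sizes used by the test suite

The suite verifies the rank statistics against brute-force enumeration on
500 random pairs (n ≤ 30), recovers a planted HPV effect on a 400-slide
cohort against a numerically integrated NB oracle, checks bootstrap AUC
interval coverage over replicate slide-level cohorts at 500 resamples, and
sweeps thresholds on cohorts of tens of slides with a few hundred cells
each. These sizes were chosen so the whole suite runs on a laptop in
minutes while keeping Monte-Carlo error well below the assertion margins
(coverage checks use ±3 binomial SEs; effect recovery uses ±3 SEs of the
estimator's own sampling distribution).

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_slides = 25, seed = 7)
cohort <- simulate_cohort(cfg)
cohort <- gate_cohort(cohort, gate_config())
slides <- cohort$slides

lab <- endpoint_label(slides$diagnosis, endpoint_spec("LSIL+"))
score <- slide_score(slides, endpoint_spec("LSIL+"))
band <- bootstrap_roc_band(score[lab != "excluded"], lab[lab != "excluded"],
                           n_resamples = 2000, seed = 7)
band$auc; band$auc_ci
```

## Known limitations

The generator's abnormal-burden and noise parameters are plausible rather
than fitted; absolute AUCs on synthetic cohorts are therefore properties
of the configuration, not predictions of clinical performance. The gating
approximates the graphical scatter gate by axis-aligned thresholds. UMAP
embedding of gated populations is deliberately out of scope (emit the gated
matrix and use an external embedding tool). The z-stack component covers
grouping, focus selection and crop geometry only — no detection and no
stain handling.
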