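---
title: "Methods: two-class lipidomics biomarker discovery with lipidsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-class lipidomics biomarker discovery with lipidsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsig)
```

`lipidsig` implements the complete discovery workflow used in untargeted
plasma-lipidomics case/control studies — here phrased for the motivating
setting, febrile children with confirmed bacterial versus confirmed viral
infection. The pipeline starts from a deconvolved feature-intensity table
(samples by features; raw spectra processing and MS/MS annotation are out
of scope) and proceeds through quality-control feature filtering,
multivariate modelling with validation, sparse signature selection, and
diagnostic evaluation. A synthetic-study generator with known ground
truth makes every stage testable without access to patient data.

## The data model

A `feature_table` couples a non-negative intensity matrix with per-sample
metadata (role: `study`, `sqc`, `ltr`, `dilution`; class; injection
order; dilution factor; age; sex) and per-feature metadata (m/z,
retention time, annotation, Metabolomics Standards Initiative annotation
level). Sample roles are explicit metadata and never inferred from
identifiers. All model fitting downstream operates on natural-log
intensities (LC-MS intensity noise is multiplicative); the pipeline
config can disable the transform to mimic raw-abundance analysis. The
log pseudocount defaults to 1.0 — robust to zero intensities and
negligible at LC-MS intensity scale.

## Quality-control filtering

Two per-feature filters, both computed on raw (pre-log) intensities of
QC-role samples only, so study-sample values never influence retention:

* **Pooled-QC CV filter.** The study quality control (SQC) pool is
  injected repeatedly through the run; a feature is retained only if its
  relative coefficient of variation sd/mean across the undiluted SQC
  injections is strictly below 15% (default). sd/mean on the raw scale
  is the standard pooled-QC practice. Only undiluted SQC injections
  enter the CV; the dilution endpoints are excluded.
* **Dilution-series filter.** The SQC pool is measured at seven relative
  concentrations; a feature is retained only if its Pearson correlation
  with the relative concentration is strictly above 0.9 (default).
  Features that are constant across the series (undefined correlation)
  are dropped — they cannot be shown to respond to analyte amount.
  Spearman correlation is available by config for saturating detectors.

Both thresholds use strict inequalities ("less than 15%", "greater than
0.9"). The filters are independent and therefore order-independent; the
retained set is the intersection.

Sample outliers are flagged by Hotelling's T² on the first two
pareto-scaled PCA score dimensions at α = 0.05. This formalizes the
visual score-plot inspection of routine practice. Flags are advisory:
removal requires listing the sample ids in the pipeline config
(`outlier_removal`), a deliberate two-pass flag–inspect–confirm design so
that no sample is ever dropped silently.

## Pareto scaling, PCA, OPLS-DA

Before multivariate modelling each feature column is pareto-scaled,
`(x − mean)/sqrt(sd)` — the metabolomics-standard compromise that damps
high-abundance features without amplifying pure noise the way full
unit-variance scaling does. PCA is computed by singular value
decomposition of the scaled matrix.

OPLS-DA models the scaled matrix against the class descriptor
(bacterial = 1, viral = 0) with one predictive component and `n_ortho`
class-orthogonal components, via the standard O-PLS deflation: compute
the PLS weight `w ∝ Xᵀy`; extract from the loading the part orthogonal
to `w`; deflate; fit the predictive component on the deflated matrix.
`n_ortho` defaults to 1, the minimal O-PLS-DA; with `n_ortho = 0` the
model is exactly single-component PLS-DA (a tested equivalence). The
predictive score is oriented so that larger means more bacterial-like.
Reported fractions: `R2X(cum)` (X sum of squares modelled by all
components), `R2Y(cum)` (y sum of squares explained), and `Q2(cum)`.

**Q2 and permutation validation.** Q2 = 1 − PRESS/SSY over stratified
7-fold cross-validation (the convention of the commercial SIMCA
software; fold count is configurable). Folds are assigned from a single
seeded permutation so that a sample's fold depends only on the class
partition — the procedure is exactly invariant to swapping the class
labelling convention. The label-permutation test refits the model and
its Q2 under `n_perm` (default 999) random permutations of class
membership and reports the add-one estimator
`p = (1 + #{Q2_perm ≥ Q2_obs})/(1 + n_perm)`, which is unbiased under
exchangeability and never zero. A model is *valid* when Q2 > 0 and
p < 0.05; an invalid model aborts signature selection with a warning,
which is the correct behaviour on degenerate (label-independent) data.
Note that Q2 ≤ 0 on pure noise is a tendency, not a guarantee: under
null simulations the median Q2 is negative but chance fold correlations
put an appreciable fraction of null Q2 values above zero — this is why
the permutation test, not the sign of Q2 alone, carries the validation.

**S-plot shortlisting.** For each feature the S-plot pairs `p1`, the
predictive-component covariance loading (`Xᵀt_p / t_pᵀt_p` against the
model-centered scaled matrix), with `pcorr`, the correlation between the
feature and the predictive score. Features with `|p1| ≥ 0.05` (default)
are shortlisted as candidate discriminators, with direction from the
sign of `p1`. The cutoff is applied to the covariance axis because 0.05
would be implausibly small for a correlation cutoff (the null spread of
`pcorr` at n ≈ 40 is ≈ 0.16); both axes are reported so either rule is
reproducible. The covariance axis has data-dependent scale, so the
shortlist *size* is emergent — on synthetic defaults roughly half a
percent of features pass, comparable to the tens-of-features shortlists
typical of real studies — and strongly enriched for true discriminators,
but the cutoff should be treated as a tunable operating point, not a
calibrated error rate.

## Covariate screen and FS-PLS signature selection

Before selection, shortlisted features are screened for age and sex
associations by a per-feature two-group t-test on log abundances (sex;
age dichotomized at the median age) with Benjamini–Hochberg adjustment
across the tested features at FDR 0.05. The default is the plain pooled
t-test: with a few dozen features and ~40 samples, empirical-Bayes
variance moderation changes little, but `moderated = TRUE` delegates to
limma for exact parity with transcriptomics-style screens.

**FS-PLS** builds a sparse signature of mutually uncorrelated features:

1. Fit one univariate regression of the class on each remaining
   (deflated) feature — logistic maximum likelihood with a Wald test by
   default — taking the current model's linear predictor as an offset,
   so each step tests the new feature against the *residual variation*
   of the response. For the linear family this offset formulation is
   exactly the Frisch–Waugh partial test. Without the offset, a plain
   univariate refit after deflation has essentially no power to extend a
   signature beyond one feature: projecting out the first selected
   column removes the shared class signal from every remaining column.
2. Select the smallest p-value (ties: larger maximized log-likelihood,
   then column order).
3. Stop before adding if that p-value exceeds `p_thresh` (default 0.01;
   deliberately config-exposed since the threshold is study-specific) or
   the safety cap `max_features` (default 10) is reached.
4. Project the selected column's variation out of all remaining columns
   (the rank-1 SVD projection `X ← X − s(sᵀX)/(sᵀs)`), so selected
   features are pairwise uncorrelated in the deflated basis and an exact
   duplicate of a selected feature can never be selected again.
5. Refit one joint model on the originally-scaled selected columns for
   the reported coefficients.

The logistic family matches a binary class descriptor; a linear family
is retained for continuous outcomes. Perfectly separating fits — routine
on small-n omics shortlists — fall back to a Firth-penalized likelihood
(Newton iteration on the modified score), recorded per step.

The **robustness check** reruns FS-PLS after removing screen-significant
features and reports whether the selected sets agree, mirroring the
standard concern that a signature might ride on age or sex structure
rather than disease class.

## Disease risk score and ROC evaluation

The disease risk score (DRS) collapses a signature into one scalar per
sample: the sum of per-feature z-scored log abundances over
up-in-bacterial features minus the same sum over up-in-viral features.
Z-scoring per feature across study samples makes the DRS invariant to
per-feature affine rescaling of raw abundances. The DRS generalizes the
published two-transcript disease risk score rather than reusing the
FS-PLS linear predictor; the linear predictor is emitted alongside, so
both conventions are available and the choice is explicit.

ROC analysis uses tie-aware concordant-pair counting, so the AUC equals
the Mann–Whitney concordance probability exactly. Confidence intervals
are stratified percentile bootstrap (default 500 iterations): resampling
within each class guarantees both classes in every draw; 2.5/97.5
percentiles of the bootstrap AUC distribution form the interval.
Percentile rather than BCa is the simplest defensible default for a
bounded statistic at this sample size. Single-feature ranking folds each
AUC to ≥ 0.5 and records the orientation; since AUC is invariant to
monotone transforms, raw versus log abundance is immaterial there.

## The synthetic-study generator

`simulate_study()` emulates the acquisition design the pipeline assumes,
with a multiplicative (log-normal) intensity model throughout:

* per-feature base abundances log-normal across features;
* a study sample multiplies base level, class effect (planted
  discriminatory features only; `effect_size` is the standardized mean
  log shift, default 1.0, half the features up in each class), a
  log-linear age effect on planted age-associated features, biological
  noise (`bio_cv`, default 0.35), injection-order drift, and technical
  noise (`tech_cv`, default 0.05). CVs are specified on the natural
  scale and converted exactly to log-normal sigma via
  `sqrt(log(1 + cv²))`;
* SQC injections measure the per-feature mean of the pooled study
  samples with technical noise only; the dilution series scales that
  pooled level by seven relative concentrations (default `2^0 … 2^-6`,
  two replicates per level, one block at each end of the run — replicate
  count is a config knob since acquisition protocols vary); long-term
  reference (LTR) injections measure an independent pool;
* drift is multiplicative and log-linear in injection index and applies
  to study, SQC and LTR injections alike, so the QC samples can reveal
  it;
* a fraction of features (default 10%) are non-dilution-responsive
  artifacts, constant across the dilution series;
* SQC/LTR injections interleave every ten study samples; ages are drawn
  log-uniformly on 1–102 months, matching a paediatric cohort with
  median age near nine months; sex is Bernoulli(0.5);
* missing values are off by default (a QC-filtered table is complete);
  an optional missingness rate exists.

A fixed seed gives bit-identical output. The generator reproduces the
*statistical structure* the pipeline relies on — planted effects,
QC replication, dilution response, drift — but not everything about real
LC-MS data: no retention-time structure, no correlated lipid families or
pathway blocks, no adducts/isotopes, no heteroscedastic detector floor,
no batch jumps. Passing tests therefore demonstrate that the pipeline
recovers truth under its own stated noise model, not that it is robust
to every artifact of a real acquisition.

## Numerical and design choices

* Zero-variance columns are rejected by `pareto_scale()` with the
  offending identifiers; degenerate (constant) deflated columns in
  FS-PLS are ineligible for selection rather than an error.
* FS-PLS ties on p-values break by maximized likelihood, then column
  order; selection is invariant to column permutation up to exact ties.
* The permutation p uses the add-one estimator, so the smallest
  attainable p with 999 permutations is 0.001.
* The Hotelling-T² critical value uses the
  `k(n²−1)/(n(n−k)) · F(1−α; k, n−k)` form for PCA scores.
* Q2 cross-validation re-centers the training block within each fold and
  applies training loadings to the held-out block; held-out predictive
  scores are exposed for cross-validated score plots.
* End-to-end runs are reproducible from the config: every stage seed is
  part of `pipeline_config()`, which serializes to YAML and round-trips.

Problem sizes in the test suite are the package's own choices: module
tests run on scaled-down studies (300 features) for speed; acceptance
properties run at the study's design scale (20 + 20 samples, 4000
features, 40 planted discriminators) with 99-permutation validation
inside multi-seed loops, 999 being reserved for single production runs.

## Known limitations

* The S-plot covariance cutoff has data-dependent scale (see above); the
  shortlist is precise but conservative, so weaker true discriminators
  can fall below the cutoff.
* FS-PLS p-values treat the current model as fixed (offset), so step
  p-values are mildly anti-conservative, which is inherent to the
  forward-selection design; the stopping threshold should be read as an
  operating point.
* Q2's sign is an unreliable null diagnostic on its own (median negative
  but with sizeable null spread); validity always pairs it with the
  permutation p.
* The bootstrap CI is percentile, which slightly undercovers extreme
  AUCs near 1; BCa is intentionally not implemented.
* No drift correction or retention-time alignment is applied: the QC
  filters only *measure* technical behaviour, matching studies where no
  correction was used.
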