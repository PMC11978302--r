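---
title: "Methods: compartment-specific proteomics and biomechanics of liver fibrosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-specific proteomics and biomechanics of liver fibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibromics)
```

## The analysis problem

Liver fibrosis is the scarring response to chronic injury: activated
stellate cells and other matrix-producing populations deposit
extracellular matrix (ECM) that stiffens the tissue, and — depending on the
etiology — the scar may largely resolve once the insult stops (the typical
course after hepatotoxic injury) or persist (typical of cholestatic
injury).  `fibromics` implements a time-resolved, compartment-specific
analysis of this process.  The design it targets has two mouse models
(hepatotoxic, here called `CCl4like`, with strong spontaneous healing; and
cholestatic, `DDClike`, with little), five terminal time points (control,
two progression points T1 and T2, two resolution points T3 and T4), six
animals per group, and three protein fractions per liver: the whole lysate
(`Total`), the detergent-soluble supernatant (`S`) and the
detergent-insoluble pellet (`E`), which is enriched for ECM and
ECM-associated ("matrisome") proteins.  Alongside the proteomes, the
design carries per-mouse histology (percentage of sirius-red-positive,
i.e. fibrillar-collagen-positive, area) and atomic force microscopy (AFM)
stiffness maps of defined tissue regions.

Because each mouse is sampled terminally, time courses are between-animal:
every statistical unit is one mouse at one time point.

## Quantification model

Protein quantification is label-free and fraction-aware.  Peptide
intensities from paired S/E runs of the same mouse are made comparable by
*proportional coefficients*: for every pair of runs in a normalization
unit, the median log2 ratio of peptides observed in both runs defines a
pairwise scaling target, and the per-run coefficients are the
least-squares solution of all pairwise targets in log space
(`estimate_proportional_coefficients()`).  The gauge is fixed by setting
the geometric mean of the coefficients to 1 within each connected
component; runs sharing no peptide with any other run get coefficient 1
with a warning.  This pairwise-median construction is the canonical
delayed-normalization estimator for label-free data; it admits a tiny
brute-force oracle (solve the same least-squares system directly), which
the test suite uses.  Protein intensity is then the sum of
coefficient-scaled unique + razor peptide intensities
(`assemble_protein_intensity()`); a protein with no observed peptide in a
run is *missing* there, never zero.

## Preprocessing

All downstream statistics work on log2 intensities.

* **Valid-value filter** (`filter_by_valid_values()`): keep proteins with
  at least 5 observed values in at least one (model, time point) group.
  The scope is a parameter: per model (default) or pooling both models per
  time point.
* **Normalization** (`normalize_columns()`): subtract each column's
  observed median and re-add the grand median, equalizing sample medians
  without changing the intensity scale.
* **Imputation** (`impute_downshift()`): missing values in label-free data
  are left-censored — low-abundance proteins drop below the detection
  limit.  Each missing cell is drawn from
  `Normal(m - 1.8 s, (0.3 s)^2)` where `m` and `s` are the mean and SD of
  the observed values of the scope.  The scope defaults to per column,
  the common implementation of this procedure; a whole-matrix scope is
  available because the phrase "total intensity distribution" is genuinely
  ambiguous between the two readings.  One seed controls the draws, which
  are consumed in row-major order over missing cells, so results are
  byte-reproducible.
* **Row z-scores** (`zscore_rows()`): population (divide-by-n) SD, fixed
  by convention so that heatmap profiles are reproducible across tools;
  with n = 6 the choice is immaterial for inference but must be pinned
  for tests.  Constant rows cannot be scaled and are excluded with a
  diagnostic.

## Statistical rules

All primitives live in the package and are cross-checked in the test suite
against independently coded textbook formulas and against base R.

* **Differential expression** (`de_contrast()`): per protein, log2 fold
  change of the fibrosis peak (T2) over the control mean, a
  pooled-variance two-sided t-test, BH adjustment across all tested
  proteins, and a significance flag requiring *both* adjusted p <= 0.05
  and at least a 1.5-fold change.  Student (pooled) rather than Welch is
  the default because it is the convention of the analysis platforms this
  pipeline mirrors; a zero-variance degenerate input returns a boundary
  p-value with a warning instead of crashing.
* **Time-course ANOVA** (`anova_time_course()`): one-way ANOVA across time
  points per protein, BH at 0.05.
* **Induced proteins** (`detect_induced()`): proteins with *zero* observed
  values in controls and detection in at least half of the replicates at
  T1 and at T2 (the detection fraction is a parameter; the source rule
  gives no count, so 50% is the package's choice, and the mask is an
  explicit input so an MS/MS-identification convention can be supplied
  instead).
* **Solubility profiling** (`es_ratio()`, `select_insolubilized()`): per E
  replicate, the log2 ratio to the protein's median S intensity (median
  over all S samples of the model by default — the singular phrasing
  "median S-fraction value" suggests a single global reference; a
  per-time-point scope is available).  Selection requires a mean ratio of
  at least threefold (inclusive, "minimum threefold") in at least one time
  point *and* a significant E-fraction time course (ANOVA, BH <= 0.05).
* **Clustering** (`hierarchical_cluster()`, `cut_clusters()`): Euclidean
  distance, complete linkage, on mean z-scored profiles per (model, time
  point); k is user-chosen (the figures this mirrors report cluster counts,
  not a rule; the workflow default k = 5 matches the planted class
  structure).  Labels are renumbered by leaf order so cluster 1 is always
  the leftmost.
* **Enrichment** (`cluster_annotation_enrichment()`): Fisher's exact test
  per (cluster, term) with BH at 0.04 across all pairs; the background is
  the clustered proteins (an all-detected background is a selectable
  alternative).
* **Cell-type signatures** (`signature_scores()`): mean z-score over the
  resolved signature proteins, aggregated per mouse *first* so that the
  ANOVA and Bonferroni post-tests run on n = 6 animal-level scores per
  group — group df should reflect animals, not measurements.
* **Fibrosis correlation** (`correlate_proteome_fibrosis()`): per protein,
  control-baselined abundance deltas are paired by mouse with
  control-baselined sirius-red area deltas; Pearson r, the regression
  slope, and the slope's two-sided p (t on n - 2 df) are computed and BH
  adjusted at 0.05 per compartment.  Control mice are *included* by
  default: they are measured animals with measured areas and anchor the
  regression at baseline; excluding them is available via
  `include_controls = FALSE`.  Proteins significantly positive in both the
  Total and E compartments are the "positive in both" class — the
  clusterin-like behaviour of tracking scar formation and resolution in
  both the lysate and the insoluble ECM.
* **AFM** (`find_contact_point()`, `fit_hertz_sphere()`): raw approach
  curves are split at the contact point by exhaustive two-segment least
  squares — a linear baseline (offset + tilt) before contact, the Hertz
  rise after — which is deterministic and robust to baseline drift, unlike
  derivative thresholding.  Piezo height converts to indentation as
  `delta = (z - z_c) - F/k`.  Young's modulus comes from the spherical
  Hertz model `F = 4/3 * E/(1 - nu^2) * sqrt(R) * delta^(3/2)` with
  nu = 0.45 and R = 2.85 um (a 5.7-um bead), fit over the post-contact
  segment capped at `delta <= 0.3 R` (the small-indentation regime; the
  cap is configurable because the upstream tooling does not state a fit
  range).  The spherical form is used rather than the paraboloid
  approximation; at these indentation depths the two differ by far less
  than the biological spread.  Region statistics pool pixels (not per-map
  medians) for the Kruskal-Wallis test with Dunn post-tests against
  control — the comparison is of frequency distributions; Dunn's
  adjustment defaults to Bonferroni, the convention of the graphing
  software this mirrors.  The stiffness-proteome correlation averages
  per-map median moduli per mouse, subtracts the mean control modulus, and
  reuses the Pearson/slope/BH machinery.

## The synthetic-study generator

Every stage is exercised end to end on `simulate_study()`, which plants
known structure and returns it as ground truth:

* **Baselines**: log2 abundances are `Normal(23, 2)` — the dynamic range
  of label-free intensities — shared across fractions.
* **Classes**: 10% of proteins are `tracking_pos` (rise with fibrosis),
  5% `declining` (mirror image), 5% `solubility_shift` (effect only in the
  E fraction), the rest null.  The planted log2 effect at T2 is 2 with
  residual SD 0.5.
* **Temporal profile**: piecewise linear 0 → 0.5 → 1 over Ctrl → T1 → T2,
  then reversal by the model's healing factor (half at T3, full at T4;
  healing 0.9 for `CCl4like`, 0.1 for `DDClike`).  This encodes
  "progression then resolution" without inventing kinetics the data do not
  constrain.
* **Missingness**: each value is masked with probability
  `1/(1 + exp(slope * (x - midpoint)))`.  The default midpoint is 18
  (2.5 baseline SDs below the mean) with slope 1, giving ~3–5% overall
  missingness concentrated in the lowest intensity decile — the
  completeness regime of a Total-lysate label-free experiment with
  match-between-runs.  Stronger censoring is available through the config;
  note that under heavy censoring the downshift-imputation + t-test chain
  genuinely loses sensitivity for low-abundance proteins (single imputed
  cells inflate group variance), which is a property of the method, not of
  the implementation.
* **Peptides**: each protein yields 3–8 peptides whose fixed fractional
  weights (log-normal ionization efficiencies, normalized per protein) sum
  to 1, so the sum of a protein's peptides reconstructs its intensity;
  per-sample log2 loading factors of SD 0.5 are what the proportional
  coefficients must undo; peptide-level measurement noise is 0.1 log2
  units.
* **Fibrosis areas**: per mouse, background 1% plus the planted burden
  profile scaled to a 12% (hepatotoxic) or 10% (cholestatic) peak, plus
  `Normal(0, 1)` noise, floored at 0.
* **AFM**: reference median moduli per region and treatment (collagen scar
  1.6 → 2.7 → 4.4 → 3.0 kPa over Ctrl/T1/T2/T4; injured hepatocytes
  1.3 → 1.9 → 2.8 → 2.5; interface hepatocytes 1.2 → 0.8 → 2.0 → 1.4,
  including the early interface softening).  Each 10 × 36 map carries one
  region; 7 maps per condition are spread over 3 mice.  Curves get
  multiplicative 5% force noise and a random linear pre-contact baseline,
  which makes contact detection non-trivial by construction.

What the generator does *not* emulate: correlated protein modules,
batch/run-order drift, peptide-level interference, razor-assignment
ambiguity, inter-animal biological variance components beyond the
per-sample noise (the design exposes these as config rather than fixing
values the data do not constrain), and the large real-world variability of
cholestatic scar deposition.  Consequently, passing recovery tests shows
the pipeline's statistical machinery is correct and calibrated — not that
real data would be as kind.  In particular the generator's cholestatic
model yields fibrosis correlates just as the hepatotoxic one does, whereas
real cholestatic data can be too variable to yield any.

## Numerical and reproducibility choices

* One master seed fans out to per-stage seeds by a stable hash of the
  stage name (`stage_seed()`), so adding a stage never perturbs another
  stage's random stream; the full pipeline is byte-identical across runs
  with one config and seed.
* Imputation draws are consumed in row-major order over missing cells.
* Distance ties in clustering break deterministically (lowest index).
* Degenerate inputs (zero variance, empty margins, all-tied ranks) return
  boundary p-values with warnings rather than errors wherever a pipeline
  run could plausibly encounter them.
* Test problem sizes: module tests use studies of 60–600 proteins;
  recovery properties average over 5–10 seeds; null-calibration properties
  use 40–100 seeds of smaller studies.  These sizes keep Monte-Carlo error
  comfortably below the margins being asserted.

## Known limitations

* The proportional-coefficient estimator assumes shared peptides between
  paired runs; designs without overlap degrade to per-run gauge freedom
  (reported via warnings).
* Downshift imputation biases low-abundance group means downward by
  construction; effect estimates for heavily censored proteins are
  attenuated and their variance inflated.  This is inherent to the
  procedure being reproduced.
* The Hertz fit assumes a homogeneous elastic half-space; real tissue is
  heterogeneous at the bead scale, so fitted moduli are effective values.
* `detect_induced()` is sensitive to the detection convention of the
  upstream search engine; the mask input makes the convention explicit
  rather than hiding it.
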