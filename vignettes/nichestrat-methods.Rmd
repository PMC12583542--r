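---
title: "Methods: spatial cell niches and niche-based risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial cell niches and niche-based risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models and procedures implemented in
`nichestrat`, the assumptions behind them, the tunable parameters and
their defaults, and the design decisions taken where more than one
reasonable construction existed. It is the package's account of its own
science; every quantitative statement about behavior is one the test
suite actually computes.

## Data model

The pipeline is image-free. Three tab-delimited tables carry everything:

* **cells** — `cell_id`, `patient_id`, `spot_id`, spot-local coordinates
  `x_um`/`y_um` in micrometers (origin at the spot-disk center), twelve
  boolean marker calls in the fixed order `CK, CD3, CD4, CD8, CD20,
  CD56, CD68, CD163, FOXP3, PD1, PDL1, GRB`, and a `compartment` from
  {carcinoma, stroma, necrosis, healthy, excluded}.
* **spots** — per-spot aligned tissue area and tumor (carcinoma ∪
  stroma) area in mm².
* **patients** — center, subtype, UICC8 stage, resection status,
  adjuvant flag, overall survival in months, event indicator.

Carrying the compartment per cell and scalar areas per spot replaces
pixel-wise masks. This is a deliberate simplification: the original
quality-control masks are raster objects, and a per-spot scalar area
cannot represent spatially heterogeneous misalignment. The density
denominators — what the masks are used for downstream — are preserved.

Spot quality control keeps spots with aligned area in [0.7, 3.0] mm².
The source thresholds are phrased as "less than" / "more than", so both
bounds are treated as inclusive: a spot at exactly 0.7 or 3.0 passes.

## Phenotype gating

Each cell's marker vector plus compartment is mapped to one of 43
fine-grained / 23 medium-grained phenotypes by an ordered first-match
rule table. The published gating table is not available in the open
text, so the default shipped here is a **reconstruction** from the
described rules, not a copy of the published table:

* lineage precedence CK > CD3 > CD20 > CD56 > CD68/CD163, avoiding
  marker combinations of unknown biological meaning;
* CK⁺ cells are carcinoma only in carcinoma/stroma compartments —
  elsewhere they are normal epithelium (pneumocytes and other epithelia
  share cytokeratin expression with carcinoma);
* granzyme B marks a lymphocyte as *activated*, PD-1 without granzyme B
  as *exhausted*, PD-L1 as *immunosuppressive* independent of lineage
  (applied with priority over the activation states when both would
  fire);
* regulatory T cells are CD3⁺FOXP3⁺; CD68⁺CD163⁻ macrophages are TAM1
  and all CD163⁺ macrophages (including CD68⁺CD163⁺ double positives)
  are TAM2;
* a terminal catch-all guarantees totality over all 4096 × 5 possible
  inputs (asserted by an enumeration test).

The table is a plain TSV (`read_gating_table()` / `write_gating_table()`)
so the exact published table can be substituted when available.

Densities are counts per mm² within either the tumor region
(carcinoma + stroma cells over tumor area) or total aligned tissue, and
are used as `log1p` values for all numerical work because the raw
per-spot densities are strongly right-skewed.

## Immune states and TME types

Per-spot density profiles are clustered by hierarchical agglomerative
clustering with Euclidean distance and single linkage after `log1p` and
per-column z-scoring, and the dendrogram is cut into *k* flat clusters.
*k* is a user choice (defaults expose 6 and 7 as reasonable values for
the two lung subtypes); no automatic cut criterion is imposed because
none is defined by the procedure this follows. Single linkage on
z-scored columns makes the result invariant to per-column affine
rescaling and row order (tested).

Tumor-microenvironment (TME) types follow the standard 2 × 2 rule over
PD-L1 status and tumor-infiltrating lymphocytes: PD-L1⁺/TIL⁺ → type 1,
PD-L1⁻/TIL⁻ → type 2 ("cold"), PD-L1⁺/TIL⁻ → type 3, PD-L1⁻/TIL⁺ →
type 4. The thresholds on immunosuppressive-carcinoma-cell density and
lymphocyte density are configurable ("high" means at or above the
threshold); cohort medians are a sensible default because the narrative
assignment this mirrors states no cutoffs.

## Niche detection

For every cell, the number of marker-positive cells within Euclidean
distance ≤ 34 µm is counted per marker (a cell contributes to every
marker it is positive for). The 34 µm radius spans first- and
second-order neighbors given lymphocyte (~8 µm) and macrophage (~30 µm)
diameters. Counts are `log1p`-transformed — saturating large counts so
presence matters more than multiplicity — and divided by their sum (the
"local mass") to give a relative composition.

Numerical choices, made once and documented here:

* **include_self = TRUE**: the index cell counts in its own
  neighborhood, guaranteeing nonzero mass for any marker-positive cell.
* The radius comparison is inclusive (≤ 34 µm), applied to exact
  squared distances; the spatial index (grid binning at the radius
  scale) only prefilters candidates, so the boundary is handled without
  floating-point surprises. An all-pairs brute-force oracle asserts
  exact equality on random spots.
* Zero-mass cells (no marker-positive neighbor) map to the zero vector
  and pass through the same nearest-centroid rule — no special class.
* The natural-log `log1p` matches the density convention; the source
  states only "logarithmically transformed".
* Neighborhoods never cross spot boundaries.

Composition vectors are clustered with **mini-batch k-means++** (batch
size 8000, k = 10 by default, 3 restarts keeping the lowest full-data
inertia, per-center streaming learning rates, deterministic given the
seed). The implementation is in-package because no installed library
provides mini-batch k-means; stats::kmeans on small planted fixtures and
a planted-prototype recovery test act as behavioral anchors. Niche
discovery is intended to run separately per tumor subtype so
subtype-specific spatial biology is not averaged away. Assignment is
nearest-centroid with exact ties going to the lowest niche id.

A niche is **hot** when its lymphocyte-lineage fraction (T, B, NK cells
including activated/exhausted/regulatory states) reaches 0.25
(configurable); macrophage-dominated niches therefore classify cold,
matching the grouping this reproduces. Spot-level dominance is compared
between groups by the Shannon entropy (nats) of per-spot niche
proportions with a two-sided label-permutation test.

An open question in the source is whether the neighborhood vector is
counted per marker (12-dimensional, per the methods text) or per cell
type (per a figure caption); this implementation follows the methods
text and uses the 12-marker space.

## Cross-subtype niche matching

Niche similarity is the symmetric chi-squared distance between
phenotype distributions, Σᵢ (xᵢ − yᵢ)²/(xᵢ + yᵢ), skipping empty terms.
It is symmetric, nonnegative and zero iff equal, but not a metric (no
triangle inequality).

Matching places uniform mass 1/k on each niche of each side — niches
are categorical prototypes, not frequency-weighted — and solves exact
partial optimal transport moving mass n/k for every n from 0 to k. With
uniform capacities the optimal plan is integral, so each subproblem
reduces to a minimum-cost n-matching, solved exactly via a padded
square assignment problem (dummy rows/columns absorb unmatched niches;
the dummy-dummy block carries a blocking cost). No entropic
regularization is used, so results are deterministic and costs exact.

The number of matched pairs n\* is the maximum of the discrete second
difference of log(cost + ε), ε = 10⁻¹², over n = 1..k−1 — the
maximum-curvature knee where cheaply matched pairs give way to forced
ones. The source invokes an "elbow" without a formula; this is the
standard discrete-curvature definition. If even the full matching has
zero cost the two sets are identical and n\* = k. Matched pairs are
plan entries carrying at least 1/(2k) mass (with uniform masses, every
matched pair carries exactly 1/k).

## Survival risk model

Cohort curation keeps patients with subtype of interest, UICC8 stage
1–3, complete resection (R0), no adjuvant therapy, and survival of at
least three months (earlier deaths are plausibly perioperative).
Training/validation centers are balanced by propensity-score matching:
a logistic regression predicts center of origin from UICC8 stage,
survival time and event indicator, and each test patient greedily takes
the unused training patient with the nearest logit (sampling without
replacement). Logistic regression is the simplest calibrated choice for
the unspecified "classifier".

The risk model is a **multiple-instance** design: each spot is a row
carrying its patient's outcome (rows are therefore not independent — a
bias accepted deliberately for fidelity to the late-fusion design this
implements), and the patient risk is the **maximum** over spot risks,
reflecting hot-spot reading of histological biomarkers; mean pooling is
available as an option.

Fitting pipeline, all parameters estimated on training rows only
(asserted by a test):

1. **Yeo-Johnson** power transform per feature (λ by profile maximum
   likelihood under a Gaussian model, searched on [−5, 5]), then
   standardization. The transform de-skews the right-skewed abundance
   features; λ estimation is in-package (no installed package exposes
   it) and is tested against `car::powerTransform`.
2. **mRMR for censored data**: relevance = training c-index of the
   univariate Cox fit; redundancy = mean |Pearson correlation| with the
   already-selected features ("cross-correlation" is read as Pearson);
   greedy selection up to `max_k` with ties broken by feature-name
   order; constant features get chance relevance 0.5.
3. **Ridge Cox** on the selected niche features plus UICC8 stage
   (entered as an ordinal integer by default — a config switch could
   one-hot it, and the integer choice is the simpler default given the
   source is silent). glmnet with `alpha = 0` at a fixed penalty, or
   `survival::coxph` with a ridge term when only one column remains.

Hyperparameters (`max_k` ∈ {3, 5, 8, 10, 11}, ridge strength ∈
{0.01, 0.1, 1, 10} by default) are tuned by inner cross-validation whose
folds split **patients**, never spots, scored by the mean held-out
max-pooled patient-level c-index; ties prefer fewer features, then
stronger regularization.

Evaluation: Harrell's concordance index is implemented directly from
its definition (pairs admissible when the earlier time has the event;
risk ties count 0.5) so it can be verified against pair enumeration,
and cross-checked against `survival::concordance`. Model-vs-baseline
comparisons use the relative improvement
(c_model − 0.5)/(c_baseline − 0.5), undefined when the baseline is at
or below chance (an error, not a silent NA). Risk tertiles RS1–RS3 cut
at the evaluated cohort's 1/3 and 2/3 quantiles (boundary ties go to
the lower group; boundaries can be frozen from a reference cohort for
prospective use), with Kaplan–Meier curves and log-rank tests from the
survival package. The bootstrap comparison resamples patients with
replacement and evaluates **both** models on the same resample (a
paired design — the source is silent on pairing; pairing removes
resample noise common to both models), comparing the two bootstrap
c-index samples with a two-sided Mann–Whitney U test.

## Whole-section validation

Virtual cores of 1.5 mm diameter (the TMA core size) are tiled on a
regular grid over the bounding box of tumor-compartment cells. The
stride defaults to 750 µm (half-diameter overlap) — the source states
exhaustive coverage but no stride — and cores are kept when they
contain at least 100 tumor cells, a proxy for the 0.7 mm² spot-area
floor in the absence of per-core area rasters. The section risk is the
maximum over kept cores, mirroring the spot-level max pooling; a
constructed fixture asserts it equals the TMA-derived maximum to
1 × 10⁻⁹. Heterogeneity is a one-way variance decomposition of spot
risks into within-patient (intra-tumoral) and between-patient
(inter-tumoral) components; the decomposition identity is exact.

## Reporting utilities

Stacked histograms are ordered by the first kernel principal component
using a Gaussian kernel exp(−‖x−y‖²/(2ℓ²)) with length scale ℓ = 1/d
(d = number of features). The phrasing "length scale of one over the
number of features" admits other parameterizations (e.g., a scale on
the squared distance); the convention above is the one implemented and
documented. The component sign is fixed so the first sorted row has the
smaller original index, making the order deterministic. The
implementation is an explicit centered-kernel eigendecomposition so
both conventions and sign handling are under the package's control.

The niche atlas is a UMAP embedding (via uwot) with 100 neighbors,
minimum distance 8 and spread 8. A minimum distance of 8 exceeds the
conventional (0, 1] range of the method; the value is passed through as
specified (with spread = 8 it remains a valid curve fit) and produces
the intentionally spread-out layout used for thumbnail overlays rather
than tight cluster separation. Neighbor counts are clipped to n − 1
with a warning on small inputs.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
tested; its defaults were chosen once, before any test outcome, and are
not tuning knobs:

* two centers × configurable subtypes, 4 spots of 1.5 mm per patient;
* per-spot cell counts Poisson with a log-normal patient-level
  intensity (mean ≈ 220 cells/spot, sdlog 0.35), reproducing the right
  skew with heavy tail that motivates the log transforms. The implied
  cell density is below that of real tissue cores — a deliberate
  desk-scale choice that leaves per-neighborhood statistics intact;
* four planted prototypes (carcinoma-dominant, PD-L1⁺ carcinoma,
  lymphocyte-rich, macrophage-rich) as Bernoulli marker profiles with
  spatial cluster σ of 15–18 µm, mixed by three patient archetypes
  (cold / hot / immunosuppressed); cells are placed by a cluster point
  process (uniform seed points in the spot disk with intensity
  proportional to mixture weight, isotropic Gaussian offsets, resampled
  to stay inside the disk);
* survival is exponential proportional hazards — the simplest
  PH-consistent choice; adequacy means parameter recovery, not
  realistic hazard shapes — with log-hazard linear in true niche
  abundance proportions and stage (defaults: lymphocyte −0.7,
  macrophage and PD-L1⁺ carcinoma +0.3, stage log 1.4 per step,
  baseline 0.012/month). Censoring is an independent exponential whose
  rate c solves meanᵢ c/(c + λᵢ) = target censored fraction (default
  0.35) by root finding — the formula is documented in the code;
* stage distribution (0.45, 0.30, 0.20, 0.05), 5% incomplete
  resections, 10% adjuvant-treated patients, so the cohort-selection
  rules have work to do.

What the generator does **not** emulate: imaging artifacts, staining
variation, cell shapes, marker-call errors correlated across channels,
spatial gradients within compartments, informative censoring, or
center-specific batch effects beyond sampling noise. Passing tests
therefore demonstrate correctness of the algorithms under a known
generative model, not performance claims on real cohorts — the original
cohort-level concordance indices are not reproducible without the
restricted data, and the package makes no attempt to force them.

## Problem sizes used by the test suite

The acceptance suite runs the survival calibration checks on one shared
synthetic cohort of 600 LUAD patients (2 centers × 300; 400 train / 200
test; ~500k cells), re-simulating the survival layer per replicate (200
null replicates for calibration, 50 for signal recovery) rather than
regenerating the spatial point pattern each time — the spatial features
are held fixed by design since the properties under test concern the
survival layer. Under the null (all hazard coefficients zero) the mean
hold-out c-index must sit within 0.5 ± 0.05 and the tertile log-rank
rejection rate at α = 0.05 within [0.01, 0.12]; with a planted hazard
ratio of 2 per SD of one niche abundance, the niche + stage model must
beat the stage-only baseline in at least 90% of replicates. Oracle
checks (all-pairs neighborhood features, pair-enumeration concordance,
hand-computed chi-squared values, brute-force tallies) assert exact
equality.

## Known limitations

* The default gating table is a reconstruction; fine-class membership
  beyond the documented rules is a package choice, not an assertion
  about the published table.
* Per-spot scalar areas cannot express spatially varying alignment
  quality; densities inherit whatever bias that introduces.
* Spot rows replicate patient outcomes, so spot-level partial
  likelihoods are not independent; standard errors of the Cox fit are
  therefore not reported, only predictive evaluation.
* Matching supports two niche sets; multi-way matching across more than
  two subtypes is out of scope.
* The mini-batch k-means solution depends on the seed (as any k-means
  does); restarts reduce but do not eliminate local-optimum risk.
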