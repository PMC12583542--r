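# nichestrat

Spatial cell niches and niche-based survival risk stratification for
multiplex-immunofluorescence (mIF) tissue-microarray cohorts.

## The problem

Clinical risk stratification of resected non-small cell lung cancer rests
on TNM-based staging (UICC8), which ignores the tumor microenvironment.
Modern mIF panels deliver, for every detected cell, a boolean call for
each of 12 markers (CK, CD3, CD4, CD8, CD20, CD56, CD68, CD163, FOXP3,
PD-1, PD-L1, granzyme B) plus a tissue compartment from H&E segmentation
(carcinoma, stroma, necrosis, healthy). `nichestrat` turns those per-cell
tables into prognostic information:

1. **Phenotyping** — an editable first-match gating table maps each
   marker vector and compartment to one of 43 fine / 23 medium cell
   phenotypes (lineage precedence CK > CD3 > CD20 > CD56 > CD68/CD163;
   granzyme B marks activation, PD-1 alone exhaustion, PD-L1
   immunosuppression regardless of lineage).
2. **Niche discovery** — for every cell, the marker-positive cells within
   a 34 µm radius are counted per marker; the count vector is `log1p`
   transformed and normalized to a composition, and the compositions are
   clustered with mini-batch k-means++ (batch 8000) into k = 10 prototype
   neighborhoods ("niches"). Cells are assigned to their nearest
   prototype; spots are summarized by niche proportions. Niches are
   called *hot* or *cold* by their lymphocyte-lineage content.
3. **Cross-subtype matching** — niche sets derived independently (e.g.,
   for adenocarcinoma and squamous carcinoma) are compared with the
   symmetric chi-squared distance on their phenotype distributions,
   `sum_i (x_i − y_i)² / (x_i + y_i)`, and matched by exact partial
   optimal transport; the number of matched pairs is chosen at the knee
   of the log transport-cost curve.
4. **Risk modelling** — spot rows (niche proportions + UICC8 stage,
   Yeo-Johnson-normalized) feed a ridge Cox model after a censored-data
   mRMR feature selection (relevance = univariate Cox c-index, redundancy
   = mean absolute correlation). Patient risk is the **maximum** over
   their spots (hot-spot / multiple-instance pooling). Evaluation is by
   Harrell's concordance index, with the relative improvement over the
   staging baseline measured on the informative range above chance:

   ```
   relative improvement = (c_model − 0.5) / (c_baseline − 0.5)
   ```

   plus Kaplan–Meier/log-rank analysis of risk tertiles (RS1–RS3),
   paired bootstrap c-index comparisons, and a stage-by-risk
   restratification table.
5. **Whole-section validation** — virtual 1.5 mm cores tiled over a
   resection, section risk as the maximum core risk, concordance with
   TMA-derived risks, and an intra- vs inter-tumoral variance
   decomposition.

Because the cohorts such pipelines are built on are restricted, the
package ships a **synthetic cohort generator** (`sim_config()`,
`generate_cohort()`) that plants known niche structure (cluster point
processes with prototype marker profiles) and proportional-hazards
survival tied to niche abundances and stage. Every stage of the pipeline
is tested against this ground truth.

## Worked example

```r
library(nichestrat)
library(dplyr)

cfg <- sim_config(n_patients_per_center_per_subtype = 40,
                  subtypes = "LUAD", seed = 7)
cohort <- generate_cohort(cfg)

cells <- assign_phenotypes(cohort$cells)
feats <- neighborhood_features(cells, radius_um = 34)
niche_model <- fit_niche_model(feats, k = 6, seed = 7)
cells$niche_id <- assign_niches(feats, niche_model)

niche_phenotype_profile(cells, k = 6)$summary
#> # A tibble: 6 × 5
#>   niche n_cells lymphocyte_fraction hot_cold label
#>   <int>   <int>               <dbl> <chr>    <chr>
#> 1     1    7661            0.00431  cold     carcinoma cell
#> 2     2    8103            0.000494 cold     carcinoma cell
#> 3     3   15150            0.00132  cold     carcinoma cell
#> 4     4   15440            0.860    hot      T cell
#> 5     5   12111            0.00239  cold     immunosuppressive carcinoma cell
#> 6     6    7748            0.0279   cold     TAM2
```

The discovered niches separate the planted carcinoma, immunosuppressive
carcinoma, lymphocyte and macrophage neighborhoods; the lymphocyte-rich
niche is the only *hot* one. Training a risk model on center A and
evaluating max-pooled patient risks on center B:

```r
abundance <- spot_niche_abundance(cells, k = 6, spot_ids = cohort$spots$spot_id) |>
  filter(n_cells > 0) |>
  left_join(cohort$spots[, c("spot_id", "patient_id")], by = "spot_id") |>
  left_join(cohort$patients, by = "patient_id")
train <- filter(abundance, center == "A")
test  <- filter(abundance, center == "B")

model <- fit_risk_model(train, sprintf("niche_%02d", 1:6), max_k = 4, alpha = 0.1)
risks <- predict_patient_risk(model, test) |>
  left_join(cohort$patients, by = "patient_id")

c_model <- concordance_index(risks$risk, risks$os_months, risks$event)
c_stage <- concordance_index(risks$uicc8, risks$os_months, risks$event)
relative_improvement(c_model, c_stage)
#> # A tibble: 1 × 4
#>   c_model c_baseline ratio improvement_pct
#>     <dbl>      <dbl> <dbl>           <dbl>
#> 1   0.682      0.680  1.01            1.19

km_logrank(stratify_tertiles(risks$risk), risks$os_months, risks$event)
#> <km_logrank> chi-squared = 5.139 on 2 df, p = 0.07658
```

The hold-out c-index (0.682) beats staging alone (0.680) only marginally
at this small simulated size — 80 patients per arm; the calibration and
signal-recovery properties at larger n are exercised by the test suite.
`tidy()`, `glance()` and `autoplot()` methods are provided for the
fitted niche model, risk model, match result, KM analysis and bootstrap
comparison.

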