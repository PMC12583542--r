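cell_row <- function(markers, compartment = "carcinoma") {
  mk <- stats::setNames(as.list(marker_panel() %in% markers), marker_panel())
  dplyr::bind_cols(tibble::as_tibble(mk),
                   tibble::tibble(compartment = compartment))
}

test_that("default gating table has 43 fine and 23 medium classes", {
  g <- default_gating_table()
  expect_equal(dplyr::n_distinct(g$phenotype_fine), 43)
  expect_equal(dplyr::n_distinct(g$phenotype_medium), 23)
  # hierarchy: each fine class maps to exactly one medium class
  h <- dplyr::distinct(g, phenotype_fine, phenotype_medium)
  expect_equal(nrow(h), 43)
})

test_that("gating reproduces the described lineage and modifier rules", {
  cases <- dplyr::bind_rows(
    cell_row(c("CK", "PDL1"), "carcinoma"),
    cell_row(c("CD3", "CD4", "FOXP3")),
    cell_row(c("CD3", "CD8", "PD1")),
    cell_row(c("CD3", "CD8", "PD1", "GRB")),
    cell_row(character(0)),
    cell_row("CK", "healthy"),
    cell_row(c("CD68", "CD163")),
    cell_row("CD68")
  )
  out <- assign_phenotypes(cases)
  expect_equal(out$phenotype_fine, c(
    "immunosuppressive carcinoma cell",
    "regulatory T cell",
    "exhausted cytotoxic T cell",
    "activated cytotoxic T cell",
    "other",
    "normal epithelial cell",
    "TAM2",
    "TAM1"
  ))
  expect_equal(out$lineage[6], "other")  # healthy CK+ is not carcinoma
})

test_that("gating is total and deterministic over the full input space", {
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 12))
  names(combos) <- marker_panel()
  all_cells <- tidyr::expand_grid(tibble::as_tibble(combos),
                                  compartment = compartment_levels())
  out <- assign_phenotypes(all_cells)
  expect_false(any(out$phenotype_fine == ""))
  expect_equal(dplyr::n_distinct(out$phenotype_fine), 43)
  expect_equal(dplyr::n_distinct(out$phenotype_medium), 23)
  # rerun: identical labels
  expect_identical(out$phenotype_fine, assign_phenotypes(all_cells)$phenotype_fine)
})

test_that("gating table round-trips through its text format", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "gating.tsv")
  write_gating_table(default_gating_table(), path)
  g2 <- read_gating_table(path)
  expect_equal(as.data.frame(g2), as.data.frame(default_gating_table()))
})

test_that("density arithmetic matches hand computation and partitions", {
  cells <- dplyr::bind_rows(
    cell_row("CK"), cell_row("CK"), cell_row("CK")
  )
  cells$patient_id <- "P1"; cells$spot_id <- "S1"
  cells$x_um <- 0; cells$y_um <- 0
  cells$cell_id <- paste0("C", 1:3)
  spots <- tibble::tibble(patient_id = "P1", spot_id = "S1",
                          aligned_area_mm2 = 2.5, tumor_area_mm2 = 2,
                          qc_pass = TRUE)
  d <- compute_densities(cells, spots, grain = "marker", region = "tumor")
  expect_equal(d$CK, 1.5)
  dl <- compute_densities(cells, spots, grain = "marker", region = "tumor",
                          log_transform = TRUE)
  expect_equal(dl$CK, log(2.5))
})

test_that("fine-grained densities sum to the all-cell density per spot", {
  cfg <- sim_config(n_patients_per_center_per_subtype = 2, seed = 17)
  co <- generate_cohort(cfg)
  cells <- assign_phenotypes(co$cells)
  d <- compute_densities(cells, co$spots, grain = "fine", region = "total")
  feature_cols <- setdiff(names(d), c("patient_id", "spot_id", "area_mm2", "n_cells"))
  expect_equal(rowSums(d[, feature_cols]), d$n_cells / d$area_mm2,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("densities equal a brute-force per-spot counting oracle", {
  cfg <- sim_config(n_patients_per_center_per_subtype = 2, seed = 23)
  co <- generate_cohort(cfg)
  cells <- assign_phenotypes(co$cells)
  d <- compute_densities(cells, co$spots, grain = "medium", region = "tumor")
  spots_qc <- co$spots[co$spots$qc_pass, ]
  for (s in sample(spots_qc$spot_id, 5)) {
    cc <- cells[cells$spot_id == s &
                  cells$compartment %in% c("carcinoma", "stroma"), ]
    area <- spots_qc$tumor_area_mm2[spots_qc$spot_id == s]
    for (ph in unique(cc$phenotype_medium)) {
      expect_equal(d[[ph]][d$spot_id == s],
                   sum(cc$phenotype_medium == ph) / area)
    }
  }
})

test_that("zero-area spots error only when they contain cells", {
  cells <- cell_row("CK")
  cells$patient_id <- "P1"; cells$spot_id <- "S1"
  spots <- tibble::tibble(patient_id = "P1", spot_id = c("S1", "S2"),
                          aligned_area_mm2 = c(0, 0), tumor_area_mm2 = c(0, 0),
                          qc_pass = TRUE)
  expect_error(compute_densities(cells, spots, "marker", "tumor"), "zero")
  d <- compute_densities(cells[0, ], spots, "marker", "tumor")
  expect_true(all(d$CK == 0))
})
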