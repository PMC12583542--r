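test_that("generator is deterministic and respects the spot geometry", {
  cfg <- sim_config(n_patients_per_center_per_subtype = 2, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$spots, b$spots)
  expect_identical(a$patients, b$patients)

  r <- cfg$spot_diameter_mm * 1000 / 2
  expect_true(all(a$cells$x_um^2 + a$cells$y_um^2 <= r^2))
  expect_true(all(a$cells$spot_id %in% a$spots$spot_id))
  expect_true(all(a$spots$patient_id %in% a$patients$patient_id))
})

test_that("degenerate Bernoulli prototype yields pure CK+ cells", {
  proto <- default_prototypes()[1, ]
  proto[, marker_panel()] <- 0
  proto[, "CK"] <- 1
  cfg <- sim_config(prototypes = proto, archetypes = matrix(1, 1, 1))
  cells <- generate_spot(1, cfg, seed = 3, n_cells = 200)
  expect_true(all(cells$CK))
  expect_true(all(!as.matrix(cells[, setdiff(marker_panel(), "CK")])))
})

test_that("marker frequencies converge to the prototype probabilities", {
  cfg <- sim_config()
  cells <- generate_spot(c(0, 0, 1, 0), cfg, seed = 5, n_cells = 1000)
  p <- as.numeric(default_prototypes()[3, marker_panel()])
  emp <- colMeans(as.matrix(cells[, marker_panel()]))
  se <- sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(emp - p) <= 3 * pmax(se, 1e-3)))
})

test_that("generate_spot rejects invalid inputs", {
  cfg <- sim_config()
  expect_error(generate_spot(numeric(0), cfg, seed = 1), "mixture weight")
  expect_error(generate_spot(c(0, 0, 0, 0), cfg, seed = 1), "mixture weight")
  bad <- cfg
  bad$prototypes$sigma_um[1] <- -1
  expect_error(generate_spot(c(1, 0, 0, 0), bad, seed = 1), "sigma")
  expect_error(sim_config(baseline_hazard = -1))
})

test_that("censoring control works: none at rate 0, calibrated otherwise", {
  cfg0 <- sim_config(censoring_rate = 0)
  z <- cbind(matrix(0, 500, 4), stage = rep(2, 500))
  s0 <- generate_survival(z, cfg0, seed = 1)
  expect_true(all(s0$event == 1))
  expect_true(all(s0$os_months > 0))

  cfg4 <- sim_config(censoring_rate = 0.4)
  s4 <- generate_survival(z, cfg4, seed = 1)
  expect_lt(abs(mean(s4$event == 0) - 0.4), 0.07)
})

test_that("a strong hazard coefficient is recoverable by univariate Cox", {
  cfg <- sim_config(hazard_betas = c(2, 0, 0, 0, 0))
  set.seed(2)
  x <- runif(400)
  z <- cbind(x, 0, 0, 0, 0)
  s <- generate_survival(z, cfg, seed = 9)
  fit <- survival::coxph(survival::Surv(s$os_months, s$event) ~ x)
  expect_gte(concordance_index(unname(coef(fit)) * x, s$os_months, s$event),
             0.65)
})

test_that("zero-patient config yields valid empty tables, files round-trip", {
  cfg <- sim_config(n_patients_per_center_per_subtype = 0)
  dir <- withr::local_tempdir()
  co <- generate_cohort(cfg, out_dir = dir)
  expect_equal(nrow(co$cells), 0)
  expect_equal(nrow(co$patients), 0)
  expect_true(all(file.exists(file.path(dir, c("cells.tsv", "spots.tsv",
                                               "patients.tsv", "truth.tsv")))))
})

test_that("archetype weight on a hazard-loaded niche raises true hazard", {
  arch <- rbind(low = c(0.70, 0.05, 0.10, 0.15),
                high = c(0.40, 0.05, 0.10, 0.45))
  cfg <- sim_config(n_patients_per_center_per_subtype = 15,
                    subtypes = "LUAD",
                    archetypes = arch,
                    hazard_betas = c(0, 0, 0, 2, 0), seed = 13)
  co <- generate_cohort(cfg)
  gt <- co$ground_truth
  expect_gt(mean(gt$true_hazard[gt$archetype == "high"]),
            mean(gt$true_hazard[gt$archetype == "low"]))
})

test_that("planted two-prototype structure is recoverable by clustering", {
  proto <- separated_prototypes()[1:2, ]
  cfg <- sim_config(prototypes = proto, archetypes = matrix(0.5, 1, 2))
  cells <- generate_spot(c(0.5, 0.5), cfg, seed = 21, n_cells = 500)
  f <- neighborhood_features(cells)
  m <- fit_niche_model(f, k = 2, seed = 4)
  ari <- mclust::adjustedRandIndex(assign_niches(f, m), cells$prototype)
  expect_gte(ari, 0.9)
})
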