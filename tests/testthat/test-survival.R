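toy_patients <- function() {
  tibble::tibble(
    patient_id = paste0("P", 1:6), center = "A", subtype = "LUAD",
    uicc8 = c(4L, 2L, 1L, 2L, 1L, 3L), r_status = c(0L, 1L, 0L, 0L, 0L, 0L),
    adjuvant = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    os_months = c(20, 30, 40, 2, 55, 60), event = c(1L, 1L, 0L, 1L, 0L, 1L)
  )
}

spot_fixture <- function(n_pat = 60, n_spots = 4, beta = 2, seed = 19,
                         censor = 0.25) {
  set.seed(seed)
  pat <- tibble::tibble(patient_id = sprintf("P%03d", seq_len(n_pat)),
                        uicc8 = sample(1:3, n_pat, TRUE))
  k <- 5
  f <- matrix(runif(n_pat * n_spots * k), ncol = k,
              dimnames = list(NULL, sprintf("niche_%02d", 1:k)))
  spots <- tibble::as_tibble(f)
  spots$patient_id <- rep(pat$patient_id, each = n_spots)
  pf <- rowsum(f[, 1:4], spots$patient_id) / n_spots
  cfg <- sim_config(hazard_betas = c(beta, 0, 0, 0, log(1.4)),
                    censoring_rate = censor)
  sv <- generate_survival(cbind(pf, stage = pat$uicc8), cfg, seed = seed + 1)
  pat$os_months <- sv$os_months
  pat$event <- sv$event
  dplyr::left_join(spots, pat, by = "patient_id")
}

test_that("cohort selection applies the eligibility rules in order", {
  sel <- select_cohort(toy_patients())
  expect_equal(nrow(sel$patients), 2)
  expect_setequal(sel$patients$patient_id, c("P5", "P6"))
  expect_equal(sel$exclusions$n_excluded, c(1, 1, 1, 1))

  expect_equal(nrow(select_cohort(toy_patients()[0, ])$patients), 0)
  ok <- toy_patients()[c(5, 6), ]
  expect_equal(select_cohort(ok)$patients, ok)
  expect_error(select_cohort(toy_patients(), rules = "bogus"), "unknown")
})

test_that("propensity matching pairs clones and is deterministic", {
  pats <- toy_patients()
  pm <- propensity_match(pats, pats, seed = 1)
  expect_equal(sort(pm$matched$patient_id), sort(pats$patient_id))
  expect_true(all(pm$pairs$logit_gap < 1e-8))
  pm2 <- propensity_match(pats, pats, seed = 1)
  expect_identical(pm$pairs, pm2$pairs)
  expect_error(propensity_match(pats[1:3, ], pats), "smaller")
})

test_that("matching removes a training stratum absent from the test side", {
  set.seed(4)
  n <- 150
  train <- tibble::tibble(
    patient_id = sprintf("T%03d", 1:n),
    uicc8 = c(sample(1:2, n / 3, TRUE), rep(3L, 2 * n / 3)),
    os_months = c(rexp(n / 3, 0.02), rexp(2 * n / 3, 0.08)),
    event = rbinom(n, 1, 0.7)
  )
  test <- tibble::tibble(
    patient_id = sprintf("C%03d", 1:50),
    uicc8 = sample(1:2, 50, TRUE),
    os_months = rexp(50, 0.02),
    event = rbinom(50, 1, 0.7)
  )
  pm <- propensity_match(train, test, seed = 2)
  # the stage-3 block should be largely left out of the matched subset
  expect_lt(mean(pm$matched$uicc8 == 3), mean(train$uicc8 == 3) / 2)
})

test_that("concordance index matches enumeration and its anchors", {
  expect_equal(concordance_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(concordance_index(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)
  expect_error(concordance_index(1:3, c(5, 5, 5), c(0, 0, 0)), "admissible")

  set.seed(14)
  for (rep in 1:10) {
    n <- 50
    risk <- sample(1:8, n, TRUE)   # deliberate risk ties
    time <- rexp(n, 0.05)
    event <- rbinom(n, 1, 0.6)
    expect_equal(concordance_index(risk, time, event),
                 brute_force_cindex(risk, time, event))
  }
  # anti-symmetry without risk ties; cross-check against survival pkg
  risk <- rnorm(80); time <- rexp(80, 0.05); event <- rbinom(80, 1, 0.7)
  c1 <- concordance_index(risk, time, event)
  expect_equal(c1 + concordance_index(-risk, time, event), 1)
  cs <- survival::concordance(survival::Surv(time, event) ~ risk)$concordance
  expect_equal(c1, 1 - cs, tolerance = 1e-12)
})

test_that("relative improvement reproduces the published arithmetic", {
  luad <- relative_improvement(0.644, 0.633)
  expect_equal(round(luad$improvement_pct), 8)
  lusc <- relative_improvement(0.674, 0.630)
  expect_equal(round(lusc$improvement_pct), 34)
  expect_equal(relative_improvement(0.7, 0.7)$improvement_pct, 0)
  expect_error(relative_improvement(0.6, 0.5), "0.5")
})

test_that("mRMR relevance and redundancy order features as designed", {
  set.seed(22)
  n <- 120
  time <- rexp(n, 0.05)
  event <- rep(1L, n)
  A <- -log(time) + rnorm(n, 0, 0.2)
  B <- -log(time) + rnorm(n, 0, 2)
  feats <- cbind(A = A, A2 = A, B = B)

  single <- mrmr_survival_select(feats[, "B", drop = FALSE], time, event, 1)
  expect_equal(single$feature, "B")

  sel <- mrmr_survival_select(feats, time, event, 3)
  expect_equal(sel$feature, c("A", "B", "A2"))

  # first pick is the univariate c-index argmax
  rels <- sapply(colnames(feats), function(f) {
    fit <- survival::coxph(survival::Surv(time, event) ~ feats[, f])
    concordance_index(unname(coef(fit)) * feats[, f], time, event)
  })
  expect_equal(sel$feature[1], names(which.max(rels))[1])

  # constant feature treated as chance relevance, not an error
  sel2 <- mrmr_survival_select(cbind(feats, konst = 1), time, event, 4)
  expect_equal(sel2$relevance[sel2$feature == "konst"], 0.5)
})

test_that("Yeo-Johnson lambda fit agrees with an established estimator", {
  set.seed(33)
  for (x in list(rexp(300), rlnorm(300), rnorm(300, 5, 2))) {
    ours <- yeo_johnson_lambda(x)
    ref <- car::powerTransform(x, family = "yjPower")$lambda
    expect_lt(abs(ours - unname(ref)), 0.05)
  }
  # transform is monotone
  x <- sort(rnorm(50))
  expect_true(all(diff(yeo_johnson(x, 0.3)) > 0))
  expect_true(all(diff(yeo_johnson(x, 2.5)) > 0))
})

test_that("risk model learns a perfectly ranking feature and shrinks with alpha", {
  set.seed(44)
  n_pat <- 60
  time <- sort(rexp(n_pat, 0.05))
  dat <- tibble::tibble(patient_id = sprintf("P%03d", 1:n_pat),
                        niche_01 = -rank(time) / n_pat,
                        niche_02 = runif(n_pat),
                        uicc8 = sample(1:3, n_pat, TRUE),
                        os_months = time, event = 1L)
  m <- fit_risk_model(dat, c("niche_01", "niche_02"), max_k = 2, alpha = 0.01)
  pr <- predict_patient_risk(m, dat)
  pr <- dplyr::left_join(pr, dat, by = "patient_id")
  expect_gte(concordance_index(pr$risk, pr$os_months, pr$event), 0.95)

  m_big <- fit_risk_model(dat, c("niche_01", "niche_02"), max_k = 2,
                          alpha = 1e5)
  expect_lt(max(abs(m_big$coefficients)), max(abs(m$coefficients)))
  expect_lt(max(abs(m_big$coefficients)), 0.05)

  # identical configuration reproduces the identical model
  m2 <- fit_risk_model(dat, c("niche_01", "niche_02"), max_k = 2, alpha = 0.01)
  expect_identical(m$coefficients, m2$coefficients)

  # transform parameters are a pure function of the training rows
  ref <- nichestrat:::fit_feature_transform(
    as.matrix(dat[, c("niche_01", "niche_02", "uicc8")]))
  expect_equal(m$transform$lambda,
               ref$lambda[match(m$transform$feature, ref$feature)])
})

test_that("patient risk pooling is the max (or mean) over spot risks", {
  sp <- spot_fixture(n_pat = 20)
  m <- fit_risk_model(sp, sprintf("niche_%02d", 1:5), max_k = 3, alpha = 0.1)
  spot_risk <- predict_spot_risk(m, sp)
  pr <- predict_patient_risk(m, sp)
  by_pat <- tapply(spot_risk, sp$patient_id, max)
  expect_equal(pr$risk, as.numeric(by_pat[pr$patient_id]))
  expect_true(all(pr$risk >= tapply(spot_risk, sp$patient_id, min)[pr$patient_id]))

  pm <- predict_patient_risk(m, sp, pooling = "mean")
  expect_equal(pm$risk,
               as.numeric(tapply(spot_risk, sp$patient_id, mean)[pm$patient_id]))

  one <- sp[sp$patient_id == sp$patient_id[1], ][1, ]
  expect_equal(predict_patient_risk(m, one)$risk,
               unname(predict_spot_risk(m, one)))

  expect_error(predict_patient_risk(m, sp, patients = c(sp$patient_id, "GHOST")),
               "GHOST")
})

test_that("hyperparameter tuning scores by patient-level folds", {
  sp <- spot_fixture(n_pat = 40)
  one <- tune_hyperparams(sp, sprintf("niche_%02d", 1:5),
                          max_k_grid = 3, alpha_grid = 0.1, n_folds = 3,
                          seed = 5)
  expect_equal(one$best$max_k, 3)
  expect_equal(one$best$alpha, 0.1)
  expect_equal(nrow(one$grid), 1)

  tu <- tune_hyperparams(sp, sprintf("niche_%02d", 1:5),
                         max_k_grid = c(2, 4), alpha_grid = c(0.1, 1),
                         n_folds = 3, seed = 5)
  expect_equal(nrow(tu$grid), 4)
  expect_true(tu$best$score == max(tu$grid$score))
  # planted informative niche is among the tuned model's features
  m <- fit_risk_model(sp, sprintf("niche_%02d", 1:5),
                      max_k = tu$best$max_k, alpha = tu$best$alpha)
  expect_true("niche_01" %in% m$features)
})

test_that("tertile stratification follows the boundary and tie rules", {
  expect_equal(as.character(stratify_tertiles(1:9)),
               rep(c("RS1", "RS2", "RS3"), each = 3))
  expect_warning(rs <- stratify_tertiles(rep(2, 6)), "identical")
  expect_true(all(rs == "RS1"))
  expect_error(stratify_tertiles(1:2), "at least 3")

  set.seed(55)
  for (rep in 1:10) {
    r <- rnorm(3 * sample(5:30, 1))
    tab <- table(stratify_tertiles(r))
    expect_lte(max(tab) - min(tab), 1)
  }
})

test_that("KM and log-rank behave at their closed-form anchors", {
  t1 <- c(5, 10, 15, 20)
  two_same <- km_logrank(rep(c("a", "b"), each = 4), rep(t1, 2),
                         rep(1, 8))
  expect_equal(two_same$statistic, 0, tolerance = 1e-12)
  expect_equal(two_same$p_value, 1)

  set.seed(66)
  early <- rexp(30, 1)
  late <- rexp(30, 0.01) + max(early)
  kl <- km_logrank(rep(c("a", "b"), each = 30), c(early, late),
                   rep(1, 60))
  expect_lte(kl$p_value, 0.01)

  # KM with no censoring equals the empirical survival function
  fit <- survival::survfit(survival::Surv(t1, rep(1, 4)) ~ 1)
  expect_equal(fit$surv, 1 - seq_len(4) / 4)

  expect_error(km_logrank(rep("a", 5), rexp(5), rep(1, 5)), "two nonempty")
})

test_that("paired bootstrap comparison separates strong from chance models", {
  set.seed(77)
  n <- 150
  time <- rexp(n, 0.05)
  event <- rbinom(n, 1, 0.7)
  strong <- -time + rnorm(n, 0, 2)
  chance <- rnorm(n)

  same <- bootstrap_compare(strong, strong, time, event, n_boot = 100, seed = 1)
  expect_equal(same$p_value, 1)
  expect_equal(same$boot$c_model, same$boot$c_baseline)

  cmp <- bootstrap_compare(strong, chance, time, event, n_boot = 500, seed = 2)
  expect_lte(cmp$p_value, 0.001)
  cmp2 <- bootstrap_compare(strong, chance, time, event, n_boot = 500, seed = 2)
  expect_identical(cmp$p_value, cmp2$p_value)
  expect_error(bootstrap_compare(strong, chance, time, event, n_boot = 10),
               "at least 100")
})

test_that("restratification table counts flows and conserves patients", {
  rt <- restratification_table(rep(1L, 4), c("RS1", "RS2", "RS2", "RS3"))
  expect_equal(rt$summary$stage1_upstaged_fraction, 0.75)

  all_low <- restratification_table(rep(1L, 5), rep("RS1", 5))
  expect_equal(all_low$summary$stage1_upstaged_fraction, 0)
  expect_equal(unlist(all_low$table[1, c("RS2", "RS3")], use.names = FALSE),
               c(0L, 0L))

  stages <- sample(1:3, 30, TRUE)
  rs <- sample(c("RS1", "RS2", "RS3"), 30, TRUE)
  rt2 <- restratification_table(stages, rs)
  expect_equal(rowSums(rt2$table[, c("RS1", "RS2", "RS3")]),
               as.numeric(table(stages)), ignore_attr = TRUE)
  expect_error(restratification_table(1:3, c("RS1", "RS9", "RS1")), "RS1/RS2")
})
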