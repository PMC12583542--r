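lone_cell <- function(markers, x = 0, y = 0) {
  mk <- stats::setNames(as.list(marker_panel() %in% markers), marker_panel())
  dplyr::bind_cols(tibble::tibble(x_um = x, y_um = y), tibble::as_tibble(mk))
}

test_that("neighborhood compositions handle singletons and the radius boundary", {
  one <- lone_cell("CK")
  f <- neighborhood_features(one)
  expect_equal(f[1, "CK"], c(CK = 1))
  expect_equal(sum(f), 1)

  two <- dplyr::bind_rows(lone_cell("CD3", 0, 0), lone_cell("CD3", 30, 0))
  f2 <- neighborhood_features(two)
  expect_equal(unname(f2[, "CD3"]), c(1, 1))

  far <- dplyr::bind_rows(lone_cell("CD3", 0, 0), lone_cell("CK", 35, 0))
  f3 <- neighborhood_features(far)  # 35 > 34: cells do not see each other
  expect_equal(unname(f3[1, "CD3"]), 1)
  expect_equal(unname(f3[2, "CK"]), 1)
  at <- dplyr::bind_rows(lone_cell("CD3", 0, 0), lone_cell("CK", 34, 0))
  f4 <- neighborhood_features(at)   # exactly 34 is inclusive
  expect_gt(f4[1, "CK"], 0)

  expect_error(neighborhood_features(lone_cell("CK", Inf, 0)), "finite")
  expect_error(neighborhood_features(one, radius_um = 0), "positive")
})

test_that("neighborhood features equal the all-pairs brute-force oracle", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 300
    cells <- tibble::tibble(x_um = runif(n, 0, 600), y_um = runif(n, 0, 600))
    mk <- matrix(runif(n * 12) < 0.25, n, 12,
                 dimnames = list(NULL, marker_panel()))
    cells <- dplyr::bind_cols(cells, tibble::as_tibble(mk))
    expect_equal(neighborhood_features(cells), brute_force_neighborhood(cells))
  }
  # all-marker-negative cells get the zero vector
  cells0 <- tibble::tibble(x_um = c(0, 10), y_um = c(0, 0))
  mk0 <- matrix(FALSE, 2, 12, dimnames = list(NULL, marker_panel()))
  f0 <- neighborhood_features(dplyr::bind_cols(cells0, tibble::as_tibble(mk0)))
  expect_true(all(f0 == 0))
})

test_that("pipeline is invariant to cell-row permutation within a spot", {
  cells <- planted_spot_cells(n_spots = 2, n_cells = 200, seed = 41)
  f <- neighborhood_features(cells)
  perm <- sample(nrow(cells))
  f2 <- neighborhood_features(cells[perm, ])
  expect_equal(f2, f[perm, ])
})

test_that("mini-batch k-means recovers exact and planted structure", {
  pts <- diag(4)[, 1:3]  # 4 distinct points, one per centroid
  m <- fit_niche_model(pts, k = 4, seed = 2)
  reord <- m$centroids[order(apply(m$centroids, 1, paste, collapse = ",")), ]
  expect_equal(reord, pts[order(apply(pts, 1, paste, collapse = ",")), ],
               tolerance = 1e-9, ignore_attr = TRUE)

  m2 <- fit_niche_model(pts, k = 4, seed = 2)
  expect_identical(m$centroids, m2$centroids)

  expect_error(fit_niche_model(pts, k = 5, seed = 1), "fewer")
})

test_that("niche assignment is a brute-force nearest-centroid scan", {
  set.seed(6)
  model <- fit_niche_model(matrix(runif(200 * 12), 200), k = 5, seed = 3)
  x <- matrix(runif(50 * 12), 50)
  got <- assign_niches(x, model)
  oracle <- apply(x, 1, function(v) {
    which.min(colSums((t(model$centroids) - v)^2))
  })
  expect_equal(got, unname(oracle))

  # vector equal to a centroid goes to that centroid
  expect_equal(assign_niches(model$centroids[3, , drop = FALSE], model), 3L)

  # exact tie between two centroids resolves to the lower id
  cen <- rbind(c(1, rep(0, 11)), c(0, 1, rep(0, 10)))
  tie_model <- structure(list(centroids = cen, k = 2), class = "niche_model")
  tied <- matrix(c(0.5, 0.5, rep(0, 10)), 1)
  expect_equal(assign_niches(tied, tie_model), 1L)

  expect_error(assign_niches(matrix(0, 1, 5), model), "dimension")
})

test_that("spot abundances tally cells exactly", {
  cells <- tibble::tibble(spot_id = rep(c("A", "B"), c(10, 8)),
                          niche_id = c(rep(3L, 10), rep(1:4, 2)))
  ab <- spot_niche_abundance(cells, k = 4)
  expect_equal(unname(unlist(ab[ab$spot_id == "A", sprintf("niche_%02d", 1:4)])),
               c(0, 0, 1, 0))
  expect_equal(unname(unlist(ab[ab$spot_id == "B", sprintf("niche_%02d", 1:4)])),
               rep(0.25, 4))
  # independent tally oracle
  for (s in c("A", "B")) {
    for (j in 1:4) {
      expect_equal(ab[[paste0("n_niche_", sprintf("%02d", j))]][ab$spot_id == s],
                   sum(cells$niche_id[cells$spot_id == s] == j))
    }
  }
  # empty spot flagged
  ab2 <- spot_niche_abundance(cells, k = 4, spot_ids = c("A", "B", "C"))
  expect_true(ab2$empty_spot[ab2$spot_id == "C"])
  expect_true(is.na(ab2$niche_01[ab2$spot_id == "C"]))
})

test_that("niche profiles classify hot and cold niches by lymphocyte content", {
  cells <- phenotyped_cells(
    niche_id = rep(1:3, each = 100),
    medium = c(rep("carcinoma cell", 100),
               rep(c("TAM1", "B cell"), c(92, 8)),
               rep(c("T helper cell", "carcinoma cell"), c(88, 12))),
    lineage = c(rep("carcinoma", 100),
                rep(c("macrophage", "B"), c(92, 8)),
                rep(c("T", "carcinoma"), c(88, 12)))
  )
  pr <- niche_phenotype_profile(cells, k = 3)
  expect_equal(pr$summary$hot_cold, c("cold", "cold", "hot"))
  # distributions sum to one
  sums <- tapply(pr$distribution$proportion, pr$distribution$niche, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-9)
  # empty niche flagged
  pr4 <- niche_phenotype_profile(cells, k = 4)
  expect_true(is.na(pr4$summary$hot_cold[4]))
})

test_that("dominance entropy test behaves at the closed-form anchors", {
  expect_equal(shannon_entropy(rep(0.1, 10)), log(10))

  uni <- matrix(0.1, 15, 10)
  same <- dominance_entropy_test(uni, uni, n_perm = 99, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  onehot <- diag(10)[sample(1:10, 30, TRUE), ]
  unif30 <- matrix(0.1, 30, 10)
  res <- dominance_entropy_test(onehot, unif30, n_perm = 999, seed = 2)
  expect_lte(res$p_value, 0.01)
  expect_lt(res$statistic, 0)

  expect_error(dominance_entropy_test(uni, uni, n_perm = 0), "n_perm")
})
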