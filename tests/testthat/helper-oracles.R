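# Independent oracles and small fixture builders shared across the suite.
# Oracles are deliberately naive (loops, all-pairs enumeration) so they
# stay independent of the implementation paths they check.

# O(n^2) all-pairs neighborhood marker counts -> transformed composition
brute_force_neighborhood <- function(cells, radius = 34, include_self = TRUE) {
  m <- sapply(marker_panel(), function(mk) as.integer(cells[[mk]]))
  n <- nrow(cells)
  out <- matrix(0, n, 12, dimnames = list(NULL, marker_panel()))
  grp <- if ("spot_id" %in% names(cells)) cells$spot_id else rep("s", n)
  for (i in seq_len(n)) {
    d2 <- (cells$x_um - cells$x_um[i])^2 + (cells$y_um - cells$y_um[i])^2
    keep <- d2 <= radius^2 & grp == grp[i]
    if (!include_self) keep[i] <- FALSE
    cnt <- colSums(m[keep, , drop = FALSE])
    v <- log1p(cnt)
    s <- sum(v)
    out[i, ] <- if (s > 0) v / s else 0
  }
  out
}

# pair-enumeration Harrell concordance with the 0.5 risk-tie rule
brute_force_cindex <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# elementwise-loop chi-squared distance
brute_force_chi2 <- function(x, y) {
  total <- 0
  for (i in seq_along(x)) {
    s <- x[i] + y[i]
    if (s > 0) total <- total + (x[i] - y[i])^2 / s
  }
  total
}

# mean silhouette width of labels on a 2-D embedding
silhouette_width <- function(xy, labels) {
  d <- as.matrix(dist(xy))
  n <- nrow(xy)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- labels == labels[i]
    same[i] <- FALSE
    other <- labels != labels[i]
    a <- mean(d[i, same])
    b <- min(tapply(d[i, other], labels[other], mean))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# three well-separated planted prototypes (pairwise chi-squared distance
# of the normalized marker profiles far above 0.5, sigma <= 20 um)
separated_prototypes <- function() {
  mk <- marker_panel()
  p <- matrix(0.01, nrow = 3, ncol = 12, dimnames = list(NULL, mk))
  p[1, "CK"] <- 0.95
  p[2, c("CD3", "CD4")] <- c(0.90, 0.60)
  p[3, c("CD68", "CD163")] <- c(0.90, 0.60)
  dplyr::bind_cols(
    tibble::tibble(prototype = c("carcinoma", "lymphocyte", "macrophage"),
                   compartment = c("carcinoma", "stroma", "stroma"),
                   sigma_um = c(15, 15, 15)),
    tibble::as_tibble(p)
  )
}

# spot cells with planted labels from the separated prototypes
planted_spot_cells <- function(n_spots = 20, n_cells = 400, seed = 11) {
  cfg <- sim_config(prototypes = separated_prototypes(),
                    archetypes = matrix(rep(1 / 3, 3), 1), seed = seed)
  purrr::map_dfr(seq_len(n_spots), function(s) {
    blk <- generate_spot(rep(1 / 3, 3), cfg, seed = seed + s, n_cells = n_cells)
    blk$spot_id <- sprintf("S%02d", s)
    blk
  })
}

# synthetic phenotype-annotated cells for profile tests
phenotyped_cells <- function(niche_id, medium, lineage, n = length(niche_id)) {
  mk <- matrix(FALSE, n, 12, dimnames = list(NULL, marker_panel()))
  mk[, "CK"] <- lineage == "carcinoma"
  mk[, "CD3"] <- lineage == "T"
  mk[, "CD20"] <- lineage == "B"
  mk[, "CD68"] <- lineage == "macrophage"
  dplyr::bind_cols(
    tibble::tibble(niche_id = niche_id, phenotype_medium = medium,
                   phenotype_fine = medium, lineage = lineage),
    tibble::as_tibble(mk)
  )
}

# deterministic matching fixture: 8 shared distributions plus 2 unique
# per side, the unique ones concentrated on disjoint support
shared_unique_profiles <- function(n_classes = 23) {
  shared <- t(sapply(1:8, function(i) {
    p <- rep(0.2 / (n_classes - 1), n_classes)
    p[i] <- 0.8
    p / sum(p)
  }))
  unique_on <- function(j) {
    p <- rep(0, n_classes)
    p[j] <- 0.9
    p[j + 1] <- 0.1
    p
  }
  a <- rbind(shared, unique_on(15), unique_on(17))
  b <- rbind(shared, unique_on(19), unique_on(21))
  list(a = a, b = b)
}
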