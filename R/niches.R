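# Niche detection: each cell is summarized by the marker composition of
# its 34 um spatial neighborhood, the composition vectors are clustered
# with mini-batch k-means++ into k prototype neighborhoods ("niches"),
# and every cell is assigned to its nearest prototype. Niche discovery is
# intended to be run separately per tumor subtype.

#' Neighborhood marker-composition features
#'
#' For every cell, counts the marker-positive cells within Euclidean
#' distance `radius_um` (inclusive; a cell contributes to the count of
#' every marker it is positive for, and by default to its own
#' neighborhood), applies `log1p` elementwise to saturate large counts,
#' and divides by the vector sum ("local mass") to obtain a relative
#' composition. Cells whose neighborhood contains no marker-positive cell
#' map to the zero vector. Neighborhoods never cross spot boundaries.
#'
#' @param cells Cell tibble with `x_um`, `y_um`, the 12 marker columns
#'   and (optionally) `spot_id`; without `spot_id` all cells are treated
#'   as one spot.
#' @param radius_um Neighborhood radius in micrometers (default 34).
#' @param include_self Count the index cell in its own neighborhood
#'   (default `TRUE`).
#' @return A numeric matrix, one row per cell (input order), 12 columns
#'   in canonical marker order; rows sum to 1 or 0.
#' @export
neighborhood_features <- function(cells, radius_um = 34, include_self = TRUE) {
  if (radius_um <= 0) stop("radius_um must be positive")
  if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um))) {
    stop("non-finite cell coordinates", call. = FALSE)
  }
  m <- marker_matrix(cells)
  n <- nrow(cells)
  counts <- matrix(0, n, 12L, dimnames = list(NULL, marker_panel()))
  grp <- if ("spot_id" %in% names(cells)) cells$spot_id else rep("spot", n)
  for (idx in split(seq_len(n), grp)) {
    counts[idx, ] <- neighborhood_counts_one(
      cells$x_um[idx], cells$y_um[idx], m[idx, , drop = FALSE],
      radius_um, include_self
    )
  }
  x <- log1p(counts)
  mass <- rowSums(x)
  pos <- mass > 0
  x[pos, ] <- x[pos, , drop = FALSE] / mass[pos]
  x[!pos, ] <- 0
  x
}

neighborhood_counts_one <- function(x, y, m, radius, include_self) {
  n <- length(x)
  if (n == 1) {
    return(if (include_self) m else matrix(0, 1, ncol(m)))
  }
  pairs <- radius_pairs(x, y, radius)
  i <- c(pairs$i, pairs$j)
  j <- c(pairs$j, pairs$i)
  if (include_self) {
    i <- c(i, seq_len(n)); j <- c(j, seq_len(n))
  }
  if (length(i) == 0) return(matrix(0, n, ncol(m)))
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  as.matrix(a %*% m)
}

# fixed-radius neighbor pairs (i < j, distance <= radius) via grid
# binning: candidates come from the 3x3 neighborhood of each bucket and
# are filtered on the exact squared distance, so the inclusive boundary
# is handled without floating-point surprises
radius_pairs <- function(x, y, radius) {
  n <- length(x)
  bx <- floor(x / radius); by <- floor(y / radius)
  key <- paste(bx, by)
  buckets <- split(seq_len(n), key)
  bi <- integer(0); bj <- integer(0)
  for (cell_idx in buckets) {
    cx <- bx[cell_idx[1]]; cy <- by[cell_idx[1]]
    neigh <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      if (dx < 0 || (dx == 0 && dy < 0)) next  # visit each bucket pair once
      nb <- buckets[[paste(cx + dx, cy + dy)]]
      if (dx == 0 && dy == 0) next
      neigh <- c(neigh, nb)
    }
    k <- length(cell_idx)
    if (k > 1) {  # within-bucket pairs
      cmb <- utils::combn(cell_idx, 2)
      bi <- c(bi, cmb[1, ]); bj <- c(bj, cmb[2, ])
    }
    if (length(neigh) > 0) {
      bi <- c(bi, rep(cell_idx, each = length(neigh)))
      bj <- c(bj, rep(neigh, times = k))
    }
  }
  if (length(bi) > 0) {
    d2 <- (x[bi] - x[bj])^2 + (y[bi] - y[bj])^2
    keep <- d2 <= radius^2
    bi <- bi[keep]; bj <- bj[keep]
  }
  list(i = bi, j = bj)
}

#' Fit a niche model by mini-batch k-means
#'
#' Clusters neighborhood composition vectors into `k` prototype
#' neighborhoods with k-means++-initialized mini-batch k-means
#' (per-center streaming learning rates, several restarts keeping the
#' lowest full-data inertia). Deterministic given `seed`.
#'
#' @param features Feature matrix from [neighborhood_features()].
#' @param k Number of niches (default 10).
#' @param minibatch_size Mini-batch size (default 8000, clipped to n).
#' @param seed Integer seed.
#' @param radius_um,include_self Metadata recorded on the model.
#' @param n_init Restarts (default 3).
#' @param max_iter Mini-batch iterations per restart (default 100).
#' @return An object of class `niche_model` with `centroids` (k x 12),
#'   fit metadata, and the full-data `inertia`.
#' @export
fit_niche_model <- function(features, k = 10, minibatch_size = 8000,
                            seed = 1L, radius_um = 34, include_self = TRUE,
                            n_init = 3, max_iter = 100) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < k) stop("fewer feature vectors than k")
  if (nrow(unique(features)) < k) stop("fewer than k distinct feature vectors")
  b <- min(minibatch_size, n)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      cen <- kmeanspp_init(features, k)
      v <- rep(0, k)
      prev <- cen
      for (it in seq_len(max_iter)) {
        idx <- if (b == n) seq_len(n) else sample.int(n, b)
        xb <- features[idx, , drop = FALSE]
        asg <- nearest_centroid(xb, cen)
        for (c_id in unique(asg)) {
          rows <- asg == c_id
          nc <- sum(rows)
          v[c_id] <- v[c_id] + nc
          eta <- nc / v[c_id]
          cen[c_id, ] <- (1 - eta) * cen[c_id, ] +
            eta * colMeans(xb[rows, , drop = FALSE])
        }
        if (max(abs(cen - prev)) < 1e-8) break
        prev <- cen
      }
      inertia <- sum(nearest_centroid_dist2(features, cen)$d2)
      if (is.null(best) || inertia < best$inertia) {
        best <- list(centroids = cen, inertia = inertia)
      }
    }
  })
  centroids <- best$centroids
  colnames(centroids) <- colnames(features) %||%
    (if (ncol(features) == 12) marker_panel() else
       paste0("f", seq_len(ncol(features))))
  structure(
    list(centroids = centroids, k = k, radius_um = radius_um,
         include_self = include_self, minibatch_size = minibatch_size,
         seed = seed, inertia = best$inertia,
         marker_order = colnames(centroids), n = n),
    class = "niche_model"
  )
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  cen <- matrix(0, k, ncol(x))
  cen[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, cen[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 <= 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    cen[j + 1, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, cen[j + 1, ])^2))
  }
  cen
}

nearest_centroid_dist2 <- function(x, cen) {
  d2 <- matrix(0, nrow(x), nrow(cen))
  for (j in seq_len(nrow(cen))) {
    d2[, j] <- rowSums(sweep(x, 2, cen[j, ])^2)
  }
  id <- max.col(-d2, ties.method = "first")
  list(id = id, d2 = d2[cbind(seq_len(nrow(x)), id)])
}

nearest_centroid <- function(x, cen) nearest_centroid_dist2(x, cen)$id

#' Assign cells to niches
#'
#' Nearest-prototype classification: each feature vector gets the id of
#' the centroid at minimum Euclidean distance; exact ties go to the
#' lowest niche id.
#'
#' @param features Feature matrix (columns must match the model).
#' @param model A fitted [fit_niche_model()].
#' @return Integer vector of niche ids in `1..k`.
#' @export
assign_niches <- function(features, model) {
  features <- as.matrix(features)
  if (ncol(features) != ncol(model$centroids)) {
    stop("feature dimension does not match the niche model")
  }
  nearest_centroid(features, model$centroids)
}

niche_feature_names <- function(k) sprintf("niche_%02d", seq_len(k))

#' Per-spot niche abundances
#'
#' Tallies how many cells of each spot fall into each niche and converts
#' the counts to proportions. Spots without cells are flagged
#' (`NA` proportions).
#'
#' @param cells Cell tibble with `spot_id` and `niche_id`.
#' @param k Number of niches.
#' @param spot_ids Optional spot universe (includes empty spots).
#' @return A tibble, one row per spot: `spot_id`, `n_cells`, count
#'   columns, then proportion columns named `niche_01 .. niche_k`.
#' @export
spot_niche_abundance <- function(cells, k, spot_ids = NULL) {
  spot_ids <- spot_ids %||% unique(cells$spot_id)
  tab <- table(factor(cells$spot_id, levels = spot_ids),
               factor(cells$niche_id, levels = seq_len(k)))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  n_cells <- rowSums(counts)
  props <- counts / ifelse(n_cells > 0, n_cells, NA_real_)
  colnames(props) <- niche_feature_names(k)
  count_tbl <- tibble::as_tibble(counts)
  names(count_tbl) <- paste0("n_", niche_feature_names(k))
  out <- dplyr::bind_cols(
    tibble::tibble(spot_id = spot_ids, n_cells = as.integer(n_cells)),
    count_tbl, tibble::as_tibble(props)
  )
  if (any(out$n_cells == 0)) {
    out$empty_spot <- out$n_cells == 0
  }
  out
}

#' Niche phenotype profiles with hot/cold classification
#'
#' Summarizes each niche by its distribution over cell phenotypes, its
#' marker-positivity proportions (radar-plot data), and a hot/cold call:
#' a niche is *hot* when its lymphocyte-lineage fraction (T, B and NK
#' cells, including activated/exhausted/regulatory states) reaches
#' `hot_threshold`; macrophage-dominated niches therefore classify cold.
#'
#' @param cells Cell tibble with `niche_id`, phenotype columns from
#'   [assign_phenotypes()] and the 12 marker columns.
#' @param k Number of niches.
#' @param grain Phenotype grain for the distribution (`"medium"` or
#'   `"fine"`).
#' @param hot_threshold Lymphocyte fraction at or above which a niche is
#'   hot (default 0.25).
#' @return A list of class `niche_profiles`: `distribution` (long tibble
#'   niche/phenotype/proportion), `markers` (long tibble of marker
#'   proportions) and `summary` (per-niche cell count, lymphocyte
#'   fraction, `hot_cold`, dominant-phenotype `label`; empty niches are
#'   flagged).
#' @export
niche_phenotype_profile <- function(cells, k, grain = c("medium", "fine"),
                                    hot_threshold = 0.25) {
  grain <- match.arg(grain)
  col <- paste0("phenotype_", grain)
  if (!col %in% names(cells) || !"lineage" %in% names(cells)) {
    stop("cells need phenotype columns; run assign_phenotypes() first",
         call. = FALSE)
  }
  niche <- factor(cells$niche_id, levels = seq_len(k))
  tab <- table(niche, cells[[col]])
  n_per <- rowSums(tab)
  dist <- as.data.frame(prop.table(tab + 0, margin = 1))
  names(dist) <- c("niche", "phenotype", "proportion")
  dist$niche <- as.integer(as.character(dist$niche))
  dist$proportion[!is.finite(dist$proportion)] <- 0

  m <- marker_matrix(cells)
  mk_counts <- matrix(0, k, ncol(m), dimnames = list(seq_len(k), colnames(m)))
  present <- rowsum(m, as.integer(niche))
  mk_counts[rownames(present), ] <- present
  mk_prop <- mk_counts / pmax(as.vector(n_per), 1)
  markers <- tibble::as_tibble(mk_prop)
  markers$niche <- seq_len(k)
  markers <- tidyr::pivot_longer(markers, -"niche", names_to = "marker",
                                 values_to = "proportion")

  lymph_counts <- rep(0, k)
  lp <- rowsum(as.numeric(cells$lineage %in% c("T", "B", "NK")),
               as.integer(niche))
  lymph_counts[as.integer(rownames(lp))] <- lp[, 1]
  lymph_frac <- lymph_counts / pmax(as.vector(n_per), 1)
  top <- apply(tab, 1, function(r) {
    if (sum(r) == 0) NA_character_ else colnames(tab)[which.max(r)]
  })
  summary <- tibble::tibble(
    niche = seq_len(k),
    n_cells = as.integer(n_per),
    lymphocyte_fraction = ifelse(n_per > 0, lymph_frac, NA_real_),
    hot_cold = dplyr::case_when(
      n_per == 0 ~ NA_character_,
      lymph_frac >= hot_threshold ~ "hot",
      TRUE ~ "cold"
    ),
    label = unname(top)
  )
  structure(
    list(distribution = tibble::as_tibble(dist), markers = markers,
         summary = summary, grain = grain, hot_threshold = hot_threshold),
    class = "niche_profiles"
  )
}

#' Phenotype-distribution matrix of niche profiles
#'
#' @param profiles A `niche_profiles` object.
#' @return Numeric matrix, one row per niche, columns ordered by
#'   phenotype name; rows sum to 1 (empty niches dropped).
#' @export
profile_matrix <- function(profiles) {
  wide <- tidyr::pivot_wider(profiles$distribution, names_from = "phenotype",
                             values_from = "proportion", values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$niche
  m <- m[, order(colnames(m)), drop = FALSE]
  m[rowSums(m) > 0, , drop = FALSE]
}

#' Permutation test for niche-dominance entropy
#'
#' Compares the mean Shannon entropy (nats) of per-spot niche proportion
#' vectors between two groups of spots: lower entropy means spots
#' dominated by fewer niches. The statistic is the difference in group
#' means; its two-sided p-value comes from random permutations of the
#' group labels, deterministic given `seed`.
#'
#' @param proportions_a,proportions_b Matrices of per-spot niche
#'   proportion vectors (rows sum to 1).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A tibble with `statistic` (mean entropy difference, a minus
#'   b), `p_value` and the group mean entropies.
#' @export
dominance_entropy_test <- function(proportions_a, proportions_b,
                                   n_perm = 999, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  ha <- apply(as.matrix(proportions_a), 1, shannon_entropy)
  hb <- apply(as.matrix(proportions_b), 1, shannon_entropy)
  obs <- mean(ha) - mean(hb)
  pooled <- c(ha, hb)
  na <- length(ha)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), na)
      mean(pooled[idx]) - mean(pooled[-idx])
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  tibble::tibble(statistic = obs, p_value = min(p, 1),
                 mean_entropy_a = mean(ha), mean_entropy_b = mean(hb))
}

#' Shannon entropy of a proportion vector (nats)
#'
#' @param p Nonnegative vector; zero entries contribute zero.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf("<niche_model> k = %d | radius = %g um | inertia = %.4g | n = %d\n",
              x$k, x$radius_um, x$inertia, x$n))
  invisible(x)
}

#' @export
print.niche_profiles <- function(x, ...) {
  cat(sprintf("<niche_profiles> %d niches (%s grain)\n",
              nrow(x$summary), x$grain))
  print(x$summary)
  invisible(x)
}
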