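# Immune-state clustering of per-spot density profiles, TME-type
# assignment, and the chi-squared group-composition test used for cohort
# comparisons.

#' Cluster spots into immune states
#'
#' Hierarchical agglomerative clustering (Euclidean distance, single
#' linkage) of per-spot density profiles. Columns are `log1p`-transformed
#' (unless already on log scale) and z-scored before clustering, making
#' the result invariant to per-column affine scaling; the dendrogram is
#' cut into `k` flat clusters. The number of immune states is a user
#' choice: no automatic cut criterion is applied.
#'
#' @param densities Density tibble from [compute_densities()] (meta
#'   columns are detected) or a plain numeric matrix, one row per spot.
#' @param k Number of flat clusters.
#' @param log_transform Apply `log1p` before z-scoring (default `TRUE`;
#'   set `FALSE` if the input is already log-scaled).
#' @return A list of class `immune_states`: `clusters` (tibble with
#'   `spot_id` when available and `cluster` in `1..k`), `hclust` (the
#'   linkage record), `profiles` (per-cluster mean input profile) and `k`.
#' @export
cluster_immune_states <- function(densities, k, log_transform = TRUE) {
  parts <- split_density_table(densities)
  x <- parts$x
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(x)) stop("k exceeds the number of spots")
  if (any(!is.finite(x))) stop("density matrix must be finite")
  z <- if (log_transform) log1p(x) else x
  z <- scale_safe(z)
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "single")
  cl <- stats::cutree(hc, k = k)
  profiles <- rowsum(x, cl) / as.vector(table(cl))
  clusters <- tibble::tibble(cluster = as.integer(cl))
  if (!is.null(parts$meta)) clusters <- dplyr::bind_cols(parts$meta, clusters)
  structure(
    list(clusters = clusters, hclust = hc,
         profiles = tibble::as_tibble(profiles, rownames = "cluster"), k = k),
    class = "immune_states"
  )
}

density_meta_cols <- function() c("patient_id", "spot_id", "area_mm2", "n_cells")

split_density_table <- function(densities) {
  if (is.matrix(densities)) {
    return(list(x = densities, meta = NULL))
  }
  meta_cols <- intersect(density_meta_cols(), names(densities))
  x <- as.matrix(densities[, setdiff(names(densities), meta_cols), drop = FALSE])
  meta <- if ("spot_id" %in% meta_cols) {
    densities[, "spot_id", drop = FALSE]
  } else NULL
  list(x = x, meta = meta)
}

# column z-score; constant columns map to zero rather than NaN
scale_safe <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  scale(x, center = mu, scale = sd)
}

#' Classify a tumor-microenvironment (TME) type
#'
#' Applies the 2x2 rule over PD-L1 status (density of immunosuppressive
#' carcinoma cells) and tumor-infiltrating lymphocyte (TIL) density:
#' PD-L1-high/TIL-high is type 1, PD-L1-low/TIL-low type 2 ("cold"),
#' PD-L1-high/TIL-low type 3, PD-L1-low/TIL-high type 4. "High" means at
#' or above the threshold. Thresholds are configurable because the
#' published narrative assigns types without stated cutoffs; cohort
#' medians are a reasonable default choice.
#'
#' @param icc_density Density of immunosuppressive carcinoma cells
#'   (cells/mm2); vectorized.
#' @param til_density Lymphocyte density (cells/mm2); vectorized.
#' @param thresholds Named list with `pdl1_pos_density` and `til_density`.
#' @return Integer TME type(s) in 1..4.
#' @export
#' @examples
#' classify_tme_type(645.51, 307.71,
#'                   thresholds = list(pdl1_pos_density = 50, til_density = 300))
classify_tme_type <- function(icc_density, til_density, thresholds) {
  if (is.null(thresholds$pdl1_pos_density) || is.null(thresholds$til_density)) {
    stop("thresholds must provide pdl1_pos_density and til_density",
         call. = FALSE)
  }
  if (any(is.na(icc_density)) || any(is.na(til_density))) {
    stop("missing densities", call. = FALSE)
  }
  pdl1_high <- icc_density >= thresholds$pdl1_pos_density
  til_high <- til_density >= thresholds$til_density
  dplyr::case_when(
    pdl1_high & til_high ~ 1L,
    !pdl1_high & !til_high ~ 2L,
    pdl1_high & !til_high ~ 3L,
    TRUE ~ 4L
  )
}

#' Chi-squared comparison of two composition vectors
#'
#' Pearson chi-squared test on the 2 x k contingency table formed by two
#' category count vectors (e.g., immune-state memberships per subtype).
#' Categories empty in both groups are dropped; no continuity correction.
#'
#' @param counts_a,counts_b Nonnegative integer count vectors over the
#'   same categories.
#' @return A tibble with `statistic`, `df` and `p_value`.
#' @export
group_composition_test <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) {
    stop("count vectors must cover the same categories", call. = FALSE)
  }
  if (any(counts_a < 0) || any(counts_b < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  tab <- rbind(counts_a, counts_b)
  if (sum(tab) == 0) stop("all-zero contingency table", call. = FALSE)
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  if (ncol(tab) < 2) {
    return(tibble::tibble(statistic = 0, df = 0L, p_value = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}
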