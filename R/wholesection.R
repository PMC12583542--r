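# Whole-section validation: virtual tissue cores tiled over a resection,
# section-level risk as the maximum over cores, and concordance /
# heterogeneity diagnostics of TMA-derived risks.

#' Tile virtual tissue cores over a section
#'
#' Lays a regular grid of circle centers (spacing `stride_um`) over the
#' bounding box of the tumor-compartment cells and keeps every core
#' containing at least `min_cells` tumor cells. With a stride of half
#' the diameter and sufficient density, every tumor cell is covered by
#' at least one kept core.
#'
#' @param cells Cell tibble with `x_um`, `y_um` and `compartment`.
#' @param diameter_um Core diameter (default 1500, the TMA core size).
#' @param stride_um Grid spacing (default 750, half-diameter overlap).
#' @param min_cells Minimum tumor cells for a core to be kept
#'   (default 100, a proxy for the spot-level area QC floor).
#' @return A list of class `virtual_cores`: `cores` (tibble `core_id`,
#'   `x_um`, `y_um`, `n_tumor_cells`) and `members` (list of cell row
#'   indices per kept core).
#' @export
tile_virtual_cores <- function(cells, diameter_um = 1500, stride_um = 750,
                               min_cells = 100) {
  if (stride_um <= 0) stop("stride_um must be positive", call. = FALSE)
  if (diameter_um <= 0) stop("diameter_um must be positive", call. = FALSE)
  tumor <- cells$compartment %in% tumor_compartments()
  if (!any(tumor)) {
    return(structure(list(
      cores = tibble::tibble(core_id = integer(0), x_um = numeric(0),
                             y_um = numeric(0), n_tumor_cells = integer(0)),
      members = list(), diameter_um = diameter_um
    ), class = "virtual_cores"))
  }
  tx <- cells$x_um[tumor]; ty <- cells$y_um[tumor]
  gx <- seq(min(tx), max(tx) + stride_um - 1e-9, by = stride_um)
  gy <- seq(min(ty), max(ty) + stride_um - 1e-9, by = stride_um)
  centers <- tidyr::expand_grid(x_um = gx, y_um = gy)
  r2 <- (diameter_um / 2)^2
  tumor_idx <- which(tumor)
  members <- list()
  keep_rows <- integer(0)
  for (i in seq_len(nrow(centers))) {
    d2 <- (cells$x_um - centers$x_um[i])^2 + (cells$y_um - centers$y_um[i])^2
    inside <- which(d2 <= r2)
    n_tum <- length(intersect(inside, tumor_idx))
    if (n_tum >= min_cells) {
      keep_rows <- c(keep_rows, i)
      members[[length(members) + 1]] <- inside
    }
  }
  cores <- centers[keep_rows, , drop = FALSE]
  cores$core_id <- seq_len(nrow(cores))
  cores$n_tumor_cells <- vapply(seq_along(members), function(j) {
    length(intersect(members[[j]], tumor_idx))
  }, integer(1))
  structure(list(cores = dplyr::relocate(cores, "core_id"),
                 members = members, diameter_um = diameter_um),
            class = "virtual_cores")
}

#' Section-level risk from virtual cores
#'
#' Computes each kept core's niche-abundance proportions from the
#' assigned niche ids, predicts the core's risk with the fitted risk
#' model (as if the core were a tissue spot), and pools by the maximum:
#' the section risk is the highest virtual-core risk.
#'
#' @param cores A [tile_virtual_cores()] result.
#' @param cells The same cell tibble, with `niche_id` assigned.
#' @param model A [fit_risk_model()] whose features are niche
#'   proportions (`niche_01 ..`) plus `uicc8`.
#' @param k Number of niches.
#' @param uicc8 The patient's stage (scalar).
#' @return A list: `section_risk` (the max), `core_risks` (tibble
#'   `core_id`, `risk`).
#' @export
section_risk <- function(cores, cells, model, k, uicc8) {
  if (length(cores$members) == 0) stop("no kept cores", call. = FALSE)
  feats <- purrr::map_dfr(seq_along(cores$members), function(j) {
    idx <- cores$members[[j]]
    counts <- tabulate(cells$niche_id[idx], nbins = k)
    props <- counts / sum(counts)
    out <- tibble::as_tibble(as.list(stats::setNames(props, niche_feature_names(k))))
    out$uicc8 <- uicc8
    out
  })
  risks <- predict_spot_risk(model, feats)
  list(section_risk = max(risks),
       core_risks = tibble::tibble(core_id = cores$cores$core_id, risk = risks))
}

#' Concordance of paired TMA and whole-section risks
#'
#' @param tma_risk,section_risk Paired per-patient risk vectors (>= 3
#'   pairs).
#' @param rs_tma,rs_section Optional risk-stratum labels; when given, the
#'   agreement fraction is reported.
#' @return A tibble with Pearson `r`, two-sided `p_value`, and
#'   `agreement` (NA without labels). Constant vectors flag `r` as NA.
#' @export
risk_concordance <- function(tma_risk, section_risk, rs_tma = NULL,
                             rs_section = NULL) {
  if (length(tma_risk) != length(section_risk) || length(tma_risk) < 3) {
    stop("need at least 3 paired risks", call. = FALSE)
  }
  if (stats::sd(tma_risk) == 0 || stats::sd(section_risk) == 0) {
    warning("constant risk vector; correlation undefined")
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(tma_risk, section_risk)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  agreement <- if (!is.null(rs_tma) && !is.null(rs_section)) {
    mean(as.character(rs_tma) == as.character(rs_section))
  } else NA_real_
  tibble::tibble(r = r, p_value = p, agreement = agreement,
                 n = length(tma_risk))
}

#' Intra- vs inter-tumoral risk variance decomposition
#'
#' One-way decomposition of per-spot risk variation: total sum of
#' squares splits exactly into the within-patient component (intra-
#' tumoral heterogeneity) and the between-patient component of the
#' patient means (inter-tumoral heterogeneity).
#'
#' @param spot_risks Tibble with `patient_id` and `risk`, one row per
#'   spot.
#' @return A tibble with `ss_total`, `ss_within`, `ss_between`,
#'   `var_within`, `var_between` (mean squares) and their ratio
#'   `inter_intra_ratio`.
#' @export
risk_variance_decomposition <- function(spot_risks) {
  x <- spot_risks$risk
  g <- spot_risks$patient_id
  grand <- mean(x)
  mu <- tapply(x, g, mean)
  n_g <- tapply(x, g, length)
  ss_within <- sum((x - mu[as.character(g)])^2)
  ss_between <- sum(n_g * (mu - grand)^2)
  ss_total <- sum((x - grand)^2)
  k <- length(mu); n <- length(x)
  var_within <- if (n - k > 0) ss_within / (n - k) else 0
  var_between <- if (k > 1) ss_between / (k - 1) else 0
  tibble::tibble(
    ss_total = ss_total, ss_within = ss_within, ss_between = ss_between,
    var_within = var_within, var_between = var_between,
    inter_intra_ratio = ifelse(var_within > 0, var_between / var_within, Inf)
  )
}
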