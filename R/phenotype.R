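# Phenotype gating: maps each cell's 12-marker boolean vector plus tissue
# compartment to a fine (43-class) and medium (23-class) phenotype via an
# ordered first-match rule table. The published gating table is not
# reproduced in the source text, so the default shipped here is a
# reconstruction from the described rules (lineage precedence
# CK > CD3 > CD20 > CD56 > CD68/CD163; granzyme B marks activation, PD-1
# alone exhaustion, PD-L1 immunosuppression independent of lineage;
# CD68+CD163+ macrophages count as TAM2). Users can substitute their own
# table via `read_gating_table()`.

lymphocyte_bases <- function() {
  tibble::tribble(
    ~base,                   ~required,          ~lineage, ~base_modifier,
    "NKT cell",              "CD3+CD56",         "NK",     "",
    "regulatory T cell",     "CD3+FOXP3",        "T",      "regulatory",
    "double-positive T cell","CD3+CD4+CD8",      "T",      "",
    "T helper cell",         "CD3+CD4",          "T",      "",
    "cytotoxic T cell",      "CD3+CD8",          "T",      "",
    "T cell",                "CD3",              "T",      "",
    "B cell",                "CD20",             "B",      "",
    "NK cell",               "CD56",             "NK",     ""
  )
}

#' Default phenotype gating table
#'
#' Builds the ordered rule table mapping marker vectors and compartments
#' to 43 fine-grained and 23 medium-grained phenotypes. Rules use
#' first-match semantics and end in a catch-all, so every cell receives
#' exactly one label. CK+ cells are carcinoma only in carcinoma/stroma
#' compartments; elsewhere they are normal epithelium.
#'
#' @return A tibble of class `gating_table` with columns `rule`,
#'   `required`, `forbidden`, `compartment_in` (all `+`-separated, empty
#'   for none / `any`), `phenotype_fine`, `phenotype_medium`, `lineage`,
#'   `modifiers`.
#' @export
#' @examples
#' g <- default_gating_table()
#' dplyr::n_distinct(g$phenotype_fine)
#' dplyr::n_distinct(g$phenotype_medium)
default_gating_table <- function() {
  tumor_cmp <- paste(tumor_compartments(), collapse = "+")
  non_tumor <- paste(setdiff(compartment_levels(), tumor_compartments()),
                     collapse = "+")
  rows <- list(
    list("CK+PDL1", "", tumor_cmp, "immunosuppressive carcinoma cell",
         "immunosuppressive carcinoma cell", "carcinoma", "immunosuppressive"),
    list("CK", "", tumor_cmp, "carcinoma cell", "carcinoma cell",
         "carcinoma", ""),
    list("CK+PDL1", "", non_tumor, "immunosuppressive normal epithelial cell",
         "normal epithelial cell", "other", "immunosuppressive"),
    list("CK", "", non_tumor, "normal epithelial cell",
         "normal epithelial cell", "other", "")
  )
  for (i in seq_len(nrow(lymphocyte_bases()))) {
    b <- lymphocyte_bases()[i, ]
    med_i <- paste("immunosuppressive", b$base)
    mods <- function(extra) {
      paste(setdiff(c(b$base_modifier, extra), ""), collapse = "+")
    }
    rows <- c(rows, list(
      list(paste0(b$required, "+PDL1"), "", "", paste("immunosuppressive", b$base),
           med_i, b$lineage, mods("immunosuppressive")),
      list(paste0(b$required, "+GRB"), "PDL1", "", paste("activated", b$base),
           b$base, b$lineage, mods("activated")),
      list(paste0(b$required, "+PD1"), "PDL1+GRB", "", paste("exhausted", b$base),
           b$base, b$lineage, mods("exhausted")),
      list(b$required, "PDL1+GRB+PD1", "", b$base, b$base, b$lineage, mods(""))
    ))
  }
  rows <- c(rows, list(
    list("CD163+PDL1", "", "", "immunosuppressive TAM2", "TAM2",
         "macrophage", "immunosuppressive"),
    list("CD163", "", "", "TAM2", "TAM2", "macrophage", ""),
    list("CD68+PDL1", "", "", "immunosuppressive TAM1", "TAM1",
         "macrophage", "immunosuppressive"),
    list("CD68", "", "", "TAM1", "TAM1", "macrophage", ""),
    list("PDL1", "", "", "immunosuppressive other", "immunosuppressive other",
         "other", "immunosuppressive"),
    list("GRB", "", "", "cytolytic other", "other", "other", "activated"),
    list("", "", "", "other", "other", "other", "")
  ))
  g <- purrr::map_dfr(rows, function(r) {
    tibble::tibble(required = r[[1]], forbidden = r[[2]],
                   compartment_in = r[[3]], phenotype_fine = r[[4]],
                   phenotype_medium = r[[5]], lineage = r[[6]],
                   modifiers = r[[7]])
  })
  g <- dplyr::mutate(g, rule = dplyr::row_number(), .before = 1)
  validate_gating_table(g)
}

split_plus <- function(x) {
  if (is.na(x) || x == "") character(0) else strsplit(x, "+", fixed = TRUE)[[1]]
}

#' Validate a gating table
#'
#' Checks totality (a terminal catch-all exists), marker-name validity,
#' and the consistency of the fine-to-medium hierarchy (each fine class
#' maps to exactly one medium class).
#'
#' @param gating A gating tibble as produced by [default_gating_table()].
#' @return The validated table, classed `gating_table`.
#' @export
validate_gating_table <- function(gating) {
  need <- setdiff(c("required", "forbidden", "compartment_in",
                    "phenotype_fine", "phenotype_medium", "lineage"),
                  names(gating))
  if (length(need) > 0) {
    stop("gating table missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  toks <- unlist(lapply(c(gating$required, gating$forbidden), split_plus))
  bad <- setdiff(toks, marker_panel())
  if (length(bad) > 0) {
    stop("unknown marker(s) in gating table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  last <- gating[nrow(gating), ]
  if (nzchar(last$required) || nzchar(last$forbidden) ||
      nzchar(last$compartment_in)) {
    stop("gating table must end in an unconditional catch-all rule",
         call. = FALSE)
  }
  h <- dplyr::distinct(gating, .data$phenotype_fine, .data$phenotype_medium)
  if (anyDuplicated(h$phenotype_fine)) {
    stop("a fine phenotype maps to more than one medium phenotype",
         call. = FALSE)
  }
  structure(tibble::as_tibble(gating), class = c("gating_table", class(tibble::tibble())))
}

#' Read / write a gating table
#'
#' Gating tables are stored as tab-delimited text, one rule per row, so
#' the published table can be dropped in as a replacement for the default
#' reconstruction.
#'
#' @param path File path.
#' @return `read_gating_table()` returns a validated `gating_table`.
#' @export
read_gating_table <- function(path) {
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       na = character())
  validate_gating_table(g)
}

#' @rdname read_gating_table
#' @param gating A gating table.
#' @export
write_gating_table <- function(gating, path) {
  readr::write_tsv(gating, path)
  invisible(path)
}

#' Assign phenotypes to cells
#'
#' Applies the ordered gating rules (first match wins) to label every cell
#' with `phenotype_fine`, `phenotype_medium`, `lineage` and `modifiers`.
#' Deterministic and total: the catch-all guarantees a label for every
#' marker combination in every compartment.
#'
#' @param cells Cell tibble with the 12 marker columns and `compartment`.
#' @param gating A gating table (default [default_gating_table()]).
#' @return `cells` with the four phenotype columns appended.
#' @export
#' @examples
#' cells <- generate_spot(c(1, 0, 0, 0), sim_config(), seed = 1, n_cells = 50)
#' table(assign_phenotypes(cells)$phenotype_medium)
assign_phenotypes <- function(cells, gating = default_gating_table()) {
  gating <- validate_gating_table(gating)
  m <- marker_matrix(cells) == 1
  n <- nrow(cells)
  fine <- character(n); med <- character(n)
  lin <- character(n); mod <- character(n)
  unassigned <- rep(TRUE, n)
  cmp <- cells$compartment
  for (i in seq_len(nrow(gating))) {
    if (!any(unassigned)) break
    req <- split_plus(gating$required[i])
    forb <- split_plus(gating$forbidden[i])
    cmp_in <- split_plus(gating$compartment_in[i])
    ok <- unassigned
    if (length(req) > 0) {
      ok <- ok & rowSums(m[, req, drop = FALSE]) == length(req)
    }
    if (length(forb) > 0) {
      ok <- ok & rowSums(m[, forb, drop = FALSE]) == 0
    }
    if (length(cmp_in) > 0) ok <- ok & cmp %in% cmp_in
    fine[ok] <- gating$phenotype_fine[i]
    med[ok] <- gating$phenotype_medium[i]
    lin[ok] <- gating$lineage[i]
    mod[ok] <- gating$modifiers[i]
    unassigned <- unassigned & !ok
  }
  if (any(unassigned)) {
    stop("gating table is not total: some cells received no label",
         call. = FALSE)
  }
  dplyr::mutate(cells, phenotype_fine = fine, phenotype_medium = med,
                lineage = lin, modifiers = mod)
}

#' Per-spot cell densities
#'
#' Computes per-spot density vectors (counts per square millimeter) at
#' marker, fine-phenotype, or medium-phenotype grain, within either the
#' tumor region (carcinoma + stroma compartments, tumor area denominator)
#' or the total aligned tissue. With `log_transform = TRUE` the densities
#' are returned as `log1p` values, the scale used for all numerical
#' downstream work because the raw densities are strongly right-skewed.
#'
#' @param cells Cell tibble; for phenotype grains it must carry the
#'   phenotype columns from [assign_phenotypes()].
#' @param spots Spot tibble with areas; only `qc_pass` spots are used when
#'   the column is present.
#' @param grain One of `"marker"`, `"fine"`, `"medium"`.
#' @param region One of `"tumor"`, `"total"`.
#' @param log_transform Apply `log1p` elementwise (default `FALSE`).
#' @return A wide tibble, one row per spot: `patient_id`, `spot_id`,
#'   `area_mm2`, `n_cells` (cells in the region), then one density column
#'   per feature.
#' @export
compute_densities <- function(cells, spots, grain = c("marker", "fine", "medium"),
                              region = c("tumor", "total"),
                              log_transform = FALSE) {
  grain <- match.arg(grain)
  region <- match.arg(region)
  if ("qc_pass" %in% names(spots)) {
    spots <- dplyr::filter(spots, .data$qc_pass)
  }
  area <- if (region == "tumor") spots$tumor_area_mm2 else spots$aligned_area_mm2
  spot_area <- tibble::tibble(patient_id = spots$patient_id,
                              spot_id = spots$spot_id, area_mm2 = area)
  cells <- dplyr::filter(cells, .data$spot_id %in% spots$spot_id)
  if (region == "tumor") {
    cells <- dplyr::filter(cells, .data$compartment %in% tumor_compartments())
  }

  if (grain == "marker") {
    counts <- matrix(0, nrow(spot_area), 12,
                     dimnames = list(spot_area$spot_id, marker_panel()))
    if (nrow(cells) > 0) {
      m <- marker_matrix(cells)
      rs <- rowsum(m, group = factor(cells$spot_id, levels = spot_area$spot_id))
      hit <- rownames(rs) %in% spot_area$spot_id
      counts[rownames(rs)[hit], ] <- rs[hit, , drop = FALSE]
    }
    wide <- tibble::as_tibble(counts)
    n_cells <- as.vector(table(factor(cells$spot_id, levels = spot_area$spot_id)))
  } else {
    col <- if (grain == "fine") "phenotype_fine" else "phenotype_medium"
    if (!col %in% names(cells)) {
      stop("cells lack ", col, "; run assign_phenotypes() first", call. = FALSE)
    }
    classes <- sort(unique(cells[[col]]))
    tab <- table(factor(cells$spot_id, levels = spot_area$spot_id),
                 factor(cells[[col]], levels = classes))
    wide <- tibble::as_tibble(as.data.frame.matrix(tab))
    n_cells <- rowSums(tab)
  }

  zero_area <- spot_area$area_mm2 <= 0
  if (any(zero_area & n_cells > 0)) {
    stop("spot with zero region area but nonzero cells: ",
         spot_area$spot_id[zero_area & n_cells > 0][1], call. = FALSE)
  }
  dens <- sweep(as.matrix(wide), 1, pmax(spot_area$area_mm2, .Machine$double.eps), "/")
  dens[zero_area, ] <- 0
  if (log_transform) dens <- log1p(dens)
  dplyr::bind_cols(spot_area,
                   tibble::tibble(n_cells = as.numeric(n_cells)),
                   tibble::as_tibble(dens))
}
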