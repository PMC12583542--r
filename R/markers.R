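#' Canonical 12-marker panel
#'
#' The fixed marker order used everywhere in the package: epithelial
#' cytokeratin (CK), lymphocyte lineage and subset markers (CD3, CD4, CD8,
#' CD20, CD56), macrophage markers (CD68, CD163), and functional markers
#' (FOXP3, PD1, PDL1, GRB for granzyme B). Column order is part of the data
#' contract: neighborhood feature vectors, niche centroids and marker
#' density tables all use this order.
#'
#' @return Character vector of the 12 marker names in canonical order.
#' @export
#' @examples
#' marker_panel()
marker_panel <- function() {
  c("CK", "CD3", "CD4", "CD8", "CD20", "CD56",
    "CD68", "CD163", "FOXP3", "PD1", "PDL1", "GRB")
}

#' Tissue compartment labels
#'
#' Closed set of per-cell tissue compartments produced by tissue
#' segmentation: carcinoma, tumor stroma, necrosis, healthy tissue, and an
#' excluded class for regions failing alignment quality control.
#'
#' @return Character vector of the five compartment labels.
#' @export
compartment_levels <- function() {
  c("carcinoma", "stroma", "necrosis", "healthy", "excluded")
}

# compartments counted as tumor region (denominator: tumor_area_mm2)
tumor_compartments <- function() c("carcinoma", "stroma")

# Extract the 12 marker columns of a cell table as a 0/1 matrix, in
# canonical order. Errors if a column is missing or non-boolean.
marker_matrix <- function(cells) {
  mk <- marker_panel()
  missing <- setdiff(mk, names(cells))
  if (length(missing) > 0) {
    stop("cell table is missing marker column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(as.data.frame(lapply(cells[mk], function(x) {
    if (is.logical(x)) return(as.integer(x))
    if (is.numeric(x) && all(x %in% c(0, 1))) return(as.integer(x))
    stop("marker columns must be logical or 0/1", call. = FALSE)
  })))
  colnames(m) <- mk
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
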