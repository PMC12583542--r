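# Tabular data model: cells, spots, patients as tab-delimited tables with
# fixed headers, plus referential-integrity validation and the spot-level
# quality-control filter. Compartments are carried per cell and areas per
# spot; this replaces pixel-wise masks while preserving the density
# denominators of the analysis (a deliberate simplification, see vignette).

cell_schema <- function() {
  c("cell_id", "patient_id", "spot_id", "x_um", "y_um",
    marker_panel(), "compartment")
}

#' Write a cohort to tab-delimited files
#'
#' Writes `cells.tsv`, `spots.tsv`, `patients.tsv` and, when ground truth
#' is present, `truth.tsv` into `dir`.
#'
#' @param cohort A `synthetic_cohort` or a plain list with `cells`,
#'   `spots`, `patients` (and optionally `ground_truth`) tibbles.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(cohort$cells, file.path(dir, "cells.tsv"))
  readr::write_tsv(cohort$spots, file.path(dir, "spots.tsv"))
  readr::write_tsv(cohort$patients, file.path(dir, "patients.tsv"))
  if (!is.null(cohort$ground_truth)) {
    readr::write_tsv(cohort$ground_truth, file.path(dir, "truth.tsv"))
  }
  invisible(dir)
}

#' Load and validate a cohort dataset
#'
#' Reads the three tab-delimited tables, coerces marker columns to
#' booleans, and enforces the schema and referential integrity
#' (cell -> spot -> patient). Violations raise errors naming the offending
#' column or id.
#'
#' @param cells_path,spots_path,patients_path Paths to the three tables.
#' @return A list of class `niche_dataset` with validated `cells`, `spots`
#'   and `patients` tibbles.
#' @export
load_dataset <- function(cells_path, spots_path, patients_path) {
  for (p in c(cells_path, spots_path, patients_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  cells <- readr::read_tsv(cells_path, show_col_types = FALSE, progress = FALSE)
  spots <- readr::read_tsv(spots_path, show_col_types = FALSE, progress = FALSE)
  patients <- readr::read_tsv(patients_path, show_col_types = FALSE, progress = FALSE)
  validate_dataset(cells, spots, patients)
}

#' Validate in-memory cohort tables
#'
#' @param cells,spots,patients Tibbles following the documented schema.
#' @return A list of class `niche_dataset`.
#' @export
validate_dataset <- function(cells, spots, patients) {
  need <- setdiff(cell_schema(), names(cells))
  if (length(need) > 0) {
    stop("cells table missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  need <- setdiff(c("patient_id", "spot_id", "aligned_area_mm2",
                    "tumor_area_mm2"), names(spots))
  if (length(need) > 0) {
    stop("spots table missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  need <- setdiff(c("patient_id", "center", "subtype", "uicc8", "r_status",
                    "adjuvant", "os_months", "event"), names(patients))
  if (length(need) > 0) {
    stop("patients table missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }

  for (mk in marker_panel()) {
    v <- cells[[mk]]
    if (is.logical(v)) next
    if (is.numeric(v) && all(v %in% c(0, 1))) {
      cells[[mk]] <- v == 1
    } else {
      bad <- which(!(v %in% c(0, 1, TRUE, FALSE)))[1]
      stop(sprintf("non-boolean marker value in column %s, row %d", mk, bad),
           call. = FALSE)
    }
  }
  if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um))) {
    stop("cell coordinates must be finite", call. = FALSE)
  }
  bad <- setdiff(unique(cells$compartment), compartment_levels())
  if (length(bad) > 0) {
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(cells$spot_id, spots$spot_id)
  if (length(orphan) > 0) {
    stop("cell references unknown spot_id: ", orphan[1], call. = FALSE)
  }
  orphan <- setdiff(spots$patient_id, patients$patient_id)
  if (length(orphan) > 0) {
    stop("spot references unknown patient_id: ", orphan[1], call. = FALSE)
  }
  if (any(spots$aligned_area_mm2 < 0) || any(spots$tumor_area_mm2 < 0)) {
    stop("spot areas must be nonnegative", call. = FALSE)
  }
  if (any(spots$tumor_area_mm2 > spots$aligned_area_mm2 + 1e-9)) {
    stop("tumor_area_mm2 may not exceed aligned_area_mm2", call. = FALSE)
  }
  if (any(!is.finite(patients$os_months)) || any(patients$os_months < 0)) {
    bad <- which(!is.finite(patients$os_months) | patients$os_months < 0)[1]
    stop(sprintf("invalid os_months for patient row %d", bad), call. = FALSE)
  }
  if (!all(patients$event %in% c(0, 1))) {
    stop("event must be 0/1", call. = FALSE)
  }
  if (!all(patients$uicc8 %in% 1:4)) {
    stop("uicc8 must be in 1..4", call. = FALSE)
  }
  structure(
    list(cells = tibble::as_tibble(cells), spots = tibble::as_tibble(spots),
         patients = tibble::as_tibble(patients)),
    class = "niche_dataset"
  )
}

#' @export
print.niche_dataset <- function(x, ...) {
  cat(sprintf("<niche_dataset> %d cells | %d spots | %d patients\n",
              nrow(x$cells), nrow(x$spots), nrow(x$patients)))
  invisible(x)
}

#' Quality-control filter for tissue spots
#'
#' Keeps spots whose aligned tissue area lies within the acceptance window
#' of 0.7 to 3.0 square millimeters. Undersized spots lack content;
#' oversized ones are typically shattered into shards that distort spatial
#' statistics. Bounds are inclusive: a spot at exactly 0.7 or 3.0 passes.
#'
#' @param spots Spot tibble with `aligned_area_mm2`.
#' @param min_area_mm2,max_area_mm2 Acceptance window (defaults 0.7, 3.0).
#' @return A list with `kept` (spot tibble, `qc_pass = TRUE`) and
#'   `rejected` (spot tibble plus a `reason` column, `too_small` or
#'   `too_large`).
#' @export
#' @examples
#' spots <- tibble::tibble(
#'   patient_id = "P1", spot_id = paste0("S", 1:5),
#'   aligned_area_mm2 = c(0.5, 0.7, 1.76, 3.0, 3.2),
#'   tumor_area_mm2 = c(0.4, 0.6, 1.5, 2.5, 3.0)
#' )
#' qc_filter_spots(spots)$rejected
qc_filter_spots <- function(spots, min_area_mm2 = 0.7, max_area_mm2 = 3.0) {
  if (any(spots$aligned_area_mm2 < 0)) {
    stop("negative aligned_area_mm2", call. = FALSE)
  }
  a <- spots$aligned_area_mm2
  keep <- a >= min_area_mm2 & a <= max_area_mm2
  kept <- dplyr::mutate(spots[keep, , drop = FALSE], qc_pass = TRUE)
  rejected <- dplyr::mutate(
    spots[!keep, , drop = FALSE],
    qc_pass = FALSE,
    reason = ifelse(a[!keep] < min_area_mm2, "too_small", "too_large")
  )
  list(kept = tibble::as_tibble(kept), rejected = tibble::as_tibble(rejected))
}
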