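# Cohort curation for survival modelling: eligibility rules and
# propensity-score matching of the training center to the test center.

#' Select the survival-analysis cohort
#'
#' Applies the eligibility rules in order and reports per-rule exclusion
#' counts: early stage (UICC8 1-3), complete resection (`r_status == 0`),
#' no adjuvant therapy, and observed or censored survival of at least
#' three months (earlier deaths are attributable to perioperative
#' complications rather than tumor biology).
#'
#' @param patients Patient tibble.
#' @param subtype Optional subtype filter applied before the rules.
#' @param rules Character vector of rules to apply, a subset of
#'   `"stage"`, `"r_status"`, `"adjuvant"`, `"min_os"`; unknown names
#'   error.
#' @param stages Allowed UICC8 stages (default 1:3).
#' @param min_os_months Minimum survival in months (default 3).
#' @return A list: `patients` (eligible rows) and `exclusions` (tibble of
#'   `rule`, `n_excluded`, sequential counts).
#' @export
#' @examples
#' toy <- tibble::tibble(
#'   patient_id = paste0("P", 1:6), center = "A", subtype = "LUAD",
#'   uicc8 = c(4L, 2L, 1L, 2L, 1L, 3L), r_status = c(0L, 1L, 0L, 0L, 0L, 0L),
#'   adjuvant = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
#'   os_months = c(20, 30, 40, 2, 55, 60), event = c(1L, 1L, 0L, 1L, 0L, 1L)
#' )
#' select_cohort(toy)$exclusions
select_cohort <- function(patients, subtype = NULL,
                          rules = c("stage", "r_status", "adjuvant", "min_os"),
                          stages = 1:3, min_os_months = 3) {
  known <- c("stage", "r_status", "adjuvant", "min_os")
  bad <- setdiff(rules, known)
  if (length(bad) > 0) {
    stop("unknown selection rule(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  kept <- patients
  if (!is.null(subtype)) kept <- dplyr::filter(kept, .data$subtype %in% !!subtype)
  counts <- integer(0)
  for (r in rules) {
    pass <- switch(
      r,
      stage = kept$uicc8 %in% stages,
      r_status = kept$r_status == 0,
      adjuvant = !kept$adjuvant,
      min_os = kept$os_months >= min_os_months
    )
    counts <- c(counts, sum(!pass))
    kept <- kept[pass, , drop = FALSE]
  }
  list(
    patients = tibble::as_tibble(kept),
    exclusions = tibble::tibble(rule = rules, n_excluded = counts)
  )
}

#' Propensity-score match the training cohort to the test cohort
#'
#' Fits a logistic center-origin classifier on the shared metadata
#' (UICC8 stage, overall survival, event indicator), then walks through
#' the test patients and pairs each with the still-unused training
#' patient of nearest logit (sampling without replacement). The returned
#' training subset has the size of the test cohort and its metadata
#' distribution matched to it.
#'
#' @param train_meta,test_meta Patient tibbles with `uicc8`, `os_months`,
#'   `event` (and `patient_id`).
#' @param seed Integer seed (tie order among equal logits is resolved by
#'   row order; the fit itself is deterministic, the seed is kept for
#'   interface stability).
#' @return A list: `matched` (training subset, one row per test
#'   patient), `pairs` (tibble `test_id`, `train_id`, `logit_gap`) and
#'   `model` (the fitted classifier).
#' @export
propensity_match <- function(train_meta, test_meta, seed = 1L) {
  if (nrow(train_meta) < nrow(test_meta)) {
    stop("training cohort smaller than test cohort", call. = FALSE)
  }
  dat <- dplyr::bind_rows(
    dplyr::mutate(train_meta[, c("patient_id", "uicc8", "os_months", "event")],
                  origin = 0),
    dplyr::mutate(test_meta[, c("patient_id", "uicc8", "os_months", "event")],
                  origin = 1)
  )
  fit <- stats::glm(origin ~ uicc8 + os_months + event,
                    family = stats::binomial(), data = dat)
  logit <- stats::predict(fit, type = "link")
  lt <- logit[dat$origin == 0]
  ls <- logit[dat$origin == 1]
  used <- rep(FALSE, length(lt))
  pick <- integer(length(ls))
  gap <- numeric(length(ls))
  for (i in seq_along(ls)) {
    d <- abs(lt - ls[i])
    d[used] <- Inf
    pick[i] <- which.min(d)
    gap[i] <- d[pick[i]]
    used[pick[i]] <- TRUE
  }
  list(
    matched = tibble::as_tibble(train_meta[pick, , drop = FALSE]),
    pairs = tibble::tibble(test_id = test_meta$patient_id,
                           train_id = train_meta$patient_id[pick],
                           logit_gap = gap),
    model = fit
  )
}
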