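# Harrell's concordance index and the relative-improvement scale used to
# compare a model's c-index with the clinical baseline.

#' Harrell's concordance index
#'
#' Fraction of admissible patient pairs whose risk ordering matches their
#' event-time ordering. A pair is admissible when the earlier time
#' belongs to a patient who experienced the event; tied risks count 0.5.
#' Implemented directly from this definition (quadratic in `n`), so it
#' can be checked against pair enumeration.
#'
#' @param risk Numeric risk scores (higher = expected earlier event).
#' @param os_months Follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return Concordance in `[0, 1]`.
#' @export
#' @examples
#' concordance_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))  # 1
concordance_index <- function(risk, os_months, event) {
  n <- length(risk)
  if (length(os_months) != n || length(event) != n) {
    stop("inputs must have equal length", call. = FALSE)
  }
  # pair (i, j) admissible iff t_i < t_j and event_i == 1
  earlier <- outer(os_months, os_months, "<")
  adm <- earlier & (event == 1)
  n_adm <- sum(adm)
  if (n_adm == 0) stop("no admissible pairs", call. = FALSE)
  gt <- outer(risk, risk, ">")
  eq <- outer(risk, risk, "==")
  (sum(gt & adm) + 0.5 * sum(eq & adm)) / n_adm
}

#' Relative improvement of a c-index over a baseline
#'
#' Rescales both concordance indices to their informative range above the
#' 0.5 chance level and reports their ratio:
#' `(c_model - 0.5) / (c_baseline - 0.5)`. A ratio of 1.083 corresponds
#' to an 8.3% improvement.
#'
#' @param c_model,c_baseline Concordance indices; `c_baseline` must
#'   exceed 0.5 (the scale is undefined otherwise).
#' @return A tibble with `c_model`, `c_baseline`, `ratio` and
#'   `improvement_pct` (`(ratio - 1) * 100`).
#' @export
#' @examples
#' relative_improvement(0.644, 0.633)
relative_improvement <- function(c_model, c_baseline) {
  if (any(c_baseline <= 0.5)) {
    stop("c_baseline must exceed 0.5 for the relative scale to be defined",
         call. = FALSE)
  }
  ratio <- (c_model - 0.5) / (c_baseline - 0.5)
  tibble::tibble(c_model = c_model, c_baseline = c_baseline, ratio = ratio,
                 improvement_pct = (ratio - 1) * 100)
}
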