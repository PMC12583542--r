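# Evaluation of patient-level risks: tertile strata, Kaplan-Meier and
# log-rank analysis, paired bootstrap comparison of two risk scores, and
# the stage-vs-risk restratification table.

#' Stratify patients into risk tertiles
#'
#' Boundaries sit at the evaluated cohort's 1/3 and 2/3 empirical
#' quantiles; RS1 is the lowest-risk third and ties at a boundary go to
#' the lower group. Boundaries can be frozen from a reference cohort for
#' prospective use via `boundaries`.
#'
#' @param risk Numeric patient risks (length >= 3).
#' @param boundaries Optional length-2 numeric vector of fixed
#'   boundaries.
#' @return Factor with levels `RS1`, `RS2`, `RS3`.
#' @export
#' @examples
#' stratify_tertiles(1:9)
stratify_tertiles <- function(risk, boundaries = NULL) {
  if (length(risk) < 3) stop("need at least 3 patients", call. = FALSE)
  q <- boundaries %||% unname(stats::quantile(risk, c(1, 2) / 3, type = 7))
  if (q[1] == q[2] && stats::sd(risk) == 0) {
    warning("all risks identical; every patient assigned RS1")
  }
  labs <- dplyr::case_when(risk <= q[1] ~ "RS1", risk <= q[2] ~ "RS2",
                           TRUE ~ "RS3")
  factor(labs, levels = c("RS1", "RS2", "RS3"))
}

#' Kaplan-Meier curves with a log-rank test
#'
#' @param groups Group labels (>= 2 nonempty groups).
#' @param os_months,event Outcome vectors.
#' @return A list of class `km_logrank`: `fit` (a
#'   [survival::survfit] object), `statistic`, `df`, `p_value`.
#' @export
km_logrank <- function(groups, os_months, event) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least two nonempty groups",
                                call. = FALSE)
  dat <- data.frame(t = os_months, e = event, g = groups)
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = dat)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g, data = dat)
  df <- length(sd$n) - 1
  structure(
    list(fit = fit, statistic = unname(sd$chisq), df = df,
         p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
    class = "km_logrank"
  )
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("<km_logrank> chi-squared = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Paired bootstrap comparison of two risk scores
#'
#' Resamples patients with replacement; each replicate evaluates both
#' risk scores' c-indices on the *same* resample (a paired design), and
#' the two bootstrap c-index samples are compared with a two-sided
#' Mann-Whitney U test. Replicates without admissible pairs are redrawn
#' and counted.
#'
#' @param risk_model,risk_baseline Patient-level risk vectors.
#' @param os_months,event Outcome vectors.
#' @param n_boot Bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @return A list of class `bootstrap_compare`: `boot` (tibble `rep`,
#'   `c_model`, `c_baseline`), `p_value`, `n_redrawn`, and the observed
#'   c-indices.
#' @export
bootstrap_compare <- function(risk_model, risk_baseline, os_months, event,
                              n_boot = 500, seed = 1L) {
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  n <- length(risk_model)
  stopifnot(length(risk_baseline) == n, length(os_months) == n,
            length(event) == n)
  n_redrawn <- 0L
  cm <- numeric(n_boot); cb <- numeric(n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        res <- tryCatch(
          list(cm = concordance_index(risk_model[idx], os_months[idx], event[idx]),
               cb = concordance_index(risk_baseline[idx], os_months[idx], event[idx])),
          error = function(e) NULL
        )
        if (!is.null(res)) {
          cm[b] <- res$cm
          cb[b] <- res$cb
          break
        }
        n_redrawn <- n_redrawn + 1L
      }
    }
  })
  p <- suppressWarnings(
    stats::wilcox.test(cm, cb, alternative = "two.sided", exact = FALSE)$p.value
  )
  if (is.nan(p)) p <- 1   # identical distributions with zero spread
  structure(
    list(boot = tibble::tibble(rep = seq_len(n_boot), c_model = cm,
                               c_baseline = cb),
         p_value = p, n_redrawn = n_redrawn,
         c_model = concordance_index(risk_model, os_months, event),
         c_baseline = concordance_index(risk_baseline, os_months, event)),
    class = "bootstrap_compare"
  )
}

#' @export
print.bootstrap_compare <- function(x, ...) {
  cat(sprintf("<bootstrap_compare> c_model = %.3f | c_baseline = %.3f | MWU p = %.3g\n",
              x$c_model, x$c_baseline, x$p_value))
  invisible(x)
}

#' Stage-by-risk restratification table
#'
#' Cross-tabulates the clinical UICC8 stages against the niche-based
#' risk strata and summarizes the flow of stage-1 patients into higher
#' risk groups (the potentially undertreated subgroup).
#'
#' @param uicc8 Integer stages.
#' @param rs Risk-stratum labels (`RS1`/`RS2`/`RS3`).
#' @return A list: `table` (stage x RS contingency tibble) and `summary`
#'   with `stage1_upstaged_fraction` (stage-1 patients assigned RS2 or
#'   RS3).
#' @export
restratification_table <- function(uicc8, rs) {
  if (length(uicc8) != length(rs)) {
    stop("stage and risk labels differ in length", call. = FALSE)
  }
  rs <- factor(rs, levels = c("RS1", "RS2", "RS3"))
  if (any(is.na(rs))) stop("risk labels must be RS1/RS2/RS3", call. = FALSE)
  tab <- as.data.frame.matrix(table(stage = uicc8, rs = rs))
  tab <- tibble::as_tibble(tab, rownames = "stage")
  s1 <- uicc8 == 1
  frac <- if (any(s1)) mean(rs[s1] %in% c("RS2", "RS3")) else NA_real_
  list(table = tab,
       summary = tibble::tibble(stage1_upstaged_fraction = frac))
}
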