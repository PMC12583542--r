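# ggplot2 displays for the main result types.

#' Plot a spot's cells colored by niche
#'
#' @param cells Cell tibble with `x_um`, `y_um` and `niche_id`.
#' @return A ggplot object.
#' @export
plot_niche_map <- function(cells) {
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               colour = factor(.data$niche_id))) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "niche", x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' @describeIn niche_phenotype_profile Stacked-bar display of the
#'   per-niche phenotype distributions, annotated hot/cold.
#' @param object A `niche_profiles` object.
#' @param ... Unused.
#' @export
autoplot.niche_profiles <- function(object, ...) {
  dat <- dplyr::left_join(object$distribution,
                          dplyr::select(object$summary, "niche", "hot_cold"),
                          by = "niche")
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = factor(.data$niche), y = .data$proportion,
                               fill = .data$phenotype)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(. ~ .data$hot_cold, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "niche", y = "phenotype proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' @describeIn match_niches Log transport-cost curve with the selected
#'   knee.
#' @param object A `niche_match` object.
#' @param ... Unused.
#' @export
autoplot.niche_match <- function(object, ...) {
  ggplot2::ggplot(object$costs, ggplot2::aes(x = .data$n, y = .data$log_cost)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_star, linetype = 2) +
    ggplot2::labs(x = "matched pairs n", y = "log transport cost") +
    ggplot2::theme_minimal()
}

#' @describeIn km_logrank Kaplan-Meier step curves per stratum.
#' @param object A `km_logrank` object.
#' @param ... Unused.
#' @export
autoplot.km_logrank <- function(object, ...) {
  fit <- object$fit
  strata <- rep(names(fit$strata) %||% "all",
                fit$strata %||% length(fit$time))
  dat <- tibble::tibble(time = fit$time, surv = fit$surv, stratum = strata)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$surv,
                                    colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "months", y = "survival probability",
                  subtitle = sprintf("log-rank p = %.3g", object$p_value)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @describeIn bootstrap_compare Paired bootstrap c-index distributions.
#' @param object A `bootstrap_compare` object.
#' @param ... Unused.
#' @export
autoplot.bootstrap_compare <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$boot, -"rep", names_to = "model",
                             values_to = "c_index")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$model, y = .data$c_index)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(subtitle = sprintf("Mann-Whitney p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
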