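# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_niche_model Tidy the centroids into a long tibble
#'   (`niche`, `marker`, `value`).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.niche_model <- function(x, ...) {
  cen <- tibble::as_tibble(x$centroids)
  cen$niche <- seq_len(x$k)
  tidyr::pivot_longer(cen, -"niche", names_to = "marker", values_to = "value")
}

#' @describeIn fit_niche_model One-row model summary.
#' @export
glance.niche_model <- function(x, ...) {
  tibble::tibble(k = x$k, radius_um = x$radius_um, inertia = x$inertia,
                 n = x$n, minibatch_size = x$minibatch_size, seed = x$seed)
}

#' @describeIn fit_risk_model Coefficients as a tibble (`term`,
#'   `estimate`, with the mRMR relevance where available).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.risk_model <- function(x, ...) {
  out <- tibble::tibble(term = names(x$coefficients),
                        estimate = unname(x$coefficients))
  dplyr::left_join(out,
                   dplyr::select(x$selection, term = "feature", "relevance"),
                   by = "term")
}

#' @describeIn fit_risk_model One-row model summary.
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(n_features = length(x$features), alpha = x$alpha,
                 max_k = x$max_k, include_stage = x$include_stage,
                 n_spots = x$n_spots, n_patients = x$n_patients)
}

#' @describeIn match_niches Matched pairs as a tibble.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.niche_match <- function(x, ...) x$pairs

#' @describeIn match_niches One-row match summary.
#' @export
glance.niche_match <- function(x, ...) {
  tibble::tibble(n_star = x$n_star,
                 cost_at_n_star = x$costs$cost[x$costs$n == x$n_star],
                 full_cost = x$costs$cost[nrow(x$costs)],
                 k_a = nrow(x$distance), k_b = ncol(x$distance))
}
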