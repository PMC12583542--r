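# The niche-based risk model: Yeo-Johnson feature normalization fitted on
# training rows, censored-data mRMR feature selection, a ridge-penalized
# Cox model on individual spot rows (patient outcomes replicated onto
# their spots, a deliberate multiple-instance design), and max-pooled
# patient-level risks.

#' Yeo-Johnson transform
#'
#' Monotone power transform defined for all reals; used to de-skew
#' features before Cox fitting.
#'
#' @param x Numeric vector.
#' @param lambda Transform parameter.
#' @return Transformed vector.
#' @export
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-10) {
    out[!pos] <- -((-x[!pos] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[!pos] <- -log1p(-x[!pos])
  }
  out
}

#' Fit the Yeo-Johnson parameter of one feature
#'
#' Profile maximum likelihood under a Gaussian model for the transformed
#' values: maximizes
#' `-n/2 log(sigma_hat^2(lambda)) + (lambda - 1) sum sign(x) log(|x| + 1)`
#' over a bounded lambda interval.
#'
#' @param x Numeric vector.
#' @param interval Search interval for lambda (default `c(-5, 5)`).
#' @return The fitted lambda; 1 (identity) for constant input.
#' @export
yeo_johnson_lambda <- function(x, interval = c(-5, 5)) {
  if (stats::sd(x) == 0 || length(x) < 2) return(1)
  jac <- sum(sign(x) * log1p(abs(x)))
  n <- length(x)
  ll <- function(l) {
    y <- yeo_johnson(x, l)
    v <- mean((y - mean(y))^2)
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (l - 1) * jac
  }
  stats::optimize(ll, interval = interval, maximum = TRUE, tol = 1e-6)$maximum
}

# fit per-feature Yeo-Johnson + standardization parameters on training rows
fit_feature_transform <- function(x_mat) {
  params <- purrr::map_dfr(colnames(x_mat), function(f) {
    x <- x_mat[, f]
    l <- yeo_johnson_lambda(x)
    y <- yeo_johnson(x, l)
    s <- stats::sd(y)
    tibble::tibble(feature = f, lambda = l, center = mean(y),
                   scale = ifelse(is.finite(s) && s > 0, s, 1))
  })
  params
}

apply_feature_transform <- function(x_mat, params) {
  out <- x_mat[, params$feature, drop = FALSE]
  for (i in seq_len(nrow(params))) {
    out[, i] <- (yeo_johnson(out[, i], params$lambda[i]) - params$center[i]) /
      params$scale[i]
  }
  out
}

#' mRMR feature selection for censored survival data
#'
#' Greedy maximum-relevance minimum-redundancy selection adapted to
#' censored outcomes: a feature's relevance is the training c-index of
#' its univariate Cox fit, its redundancy the mean absolute Pearson
#' correlation with the already-selected features. At each step the
#' candidate maximizing relevance minus redundancy is taken, with ties
#' broken by feature-name order. Constant features get chance relevance
#' (0.5).
#'
#' @param features Numeric matrix or data frame of candidate features
#'   (one row per spot/sample).
#' @param os_months,event Outcome replicated onto the rows.
#' @param max_k Number of features to select.
#' @return A tibble `feature`, `relevance`, `score`, `rank` in selection
#'   order.
#' @export
mrmr_survival_select <- function(features, os_months, event, max_k) {
  x <- as.matrix(features)
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("V", seq_len(ncol(x)))
  colnames(x) <- feats
  if (max_k > ncol(x)) stop("max_k exceeds the number of candidate features")

  relevance <- vapply(feats, function(f) {
    v <- x[, f]
    if (stats::sd(v) == 0) return(0.5)
    fit <- tryCatch(
      survival::coxph(survival::Surv(os_months, event) ~ v,
                      control = survival::coxph.control(iter.max = 50)),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(survival::coxph(survival::Surv(os_months, event) ~ v))
      })
    if (is.null(fit) || is.na(stats::coef(fit))) return(0.5)
    concordance_index(unname(stats::coef(fit)) * v, os_months, event)
  }, numeric(1))

  selected <- character(0)
  scores <- numeric(0)
  remaining <- feats
  for (step in seq_len(max_k)) {
    if (step == 1) {
      score <- relevance[remaining]
    } else {
      red <- vapply(remaining, function(f) {
        r <- suppressWarnings(stats::cor(x[, f], x[, selected, drop = FALSE]))
        mean(abs(ifelse(is.na(r), 0, r)))
      }, numeric(1))
      score <- relevance[remaining] - red
    }
    ord <- order(-score, remaining)
    pick <- remaining[ord[1]]
    selected <- c(selected, pick)
    scores <- c(scores, score[pick])
    remaining <- setdiff(remaining, pick)
  }
  tibble::tibble(feature = selected, relevance = unname(relevance[selected]),
                 score = unname(scores), rank = seq_along(selected))
}

# ridge Cox on a fixed design; glmnet for p >= 2, survival::coxph + ridge
# for a single column (glmnet requires two)
ridge_cox <- function(x, os_months, event, alpha) {
  if (ncol(x) >= 2) {
    fit <- glmnet::glmnet(x, survival::Surv(os_months, event),
                          family = "cox", alpha = 0, lambda = alpha,
                          standardize = FALSE)
    beta <- as.numeric(stats::coef(fit))
  } else {
    v <- x[, 1]
    fit <- survival::coxph(survival::Surv(os_months, event) ~
                             survival::ridge(v, theta = alpha, scale = FALSE))
    beta <- unname(stats::coef(fit))
  }
  if (any(!is.finite(beta))) {
    stop("ridge Cox fit did not converge to finite coefficients",
         call. = FALSE)
  }
  stats::setNames(beta, colnames(x))
}

#' Fit the spot-level risk model
#'
#' Fits the full training pipeline on spot rows carrying their patient's
#' outcome: per-feature Yeo-Johnson + standardization, mRMR selection of
#' up to `max_k` niche features, then a ridge Cox model on the selected
#' features plus the UICC8 stage covariate (entered as an integer by
#' default). All parameters are estimated from the training rows only.
#'
#' @param data Spot-level tibble with the feature columns, `uicc8`,
#'   `os_months`, `event` (and `patient_id`).
#' @param feature_cols Candidate feature columns (niche abundances or
#'   densities).
#' @param max_k Features to select (clipped to the number of candidates).
#' @param alpha Ridge strength.
#' @param include_stage Add `uicc8` as a covariate (default `TRUE`; set
#'   `FALSE` for a features-only model).
#' @return An object of class `risk_model`: transform parameters,
#'   selection table, coefficients, and the hyperparameters.
#' @export
fit_risk_model <- function(data, feature_cols, max_k = 10, alpha = 0.1,
                           include_stage = TRUE) {
  max_k <- min(max_k, length(feature_cols))
  x_raw <- as.matrix(data[, feature_cols, drop = FALSE])
  keep <- apply(x_raw, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(feature_cols[!keep], collapse = ", "))
    feature_cols <- feature_cols[keep]
    x_raw <- x_raw[, keep, drop = FALSE]
    max_k <- min(max_k, length(feature_cols))
  }
  if (length(feature_cols) == 0) stop("no usable features")

  all_cols <- c(feature_cols, if (include_stage) "uicc8")
  design_raw <- as.matrix(data[, all_cols, drop = FALSE])
  params <- fit_feature_transform(design_raw)
  design <- apply_feature_transform(design_raw, params)

  sel <- mrmr_survival_select(design[, feature_cols, drop = FALSE],
                              data$os_months, data$event, max_k)
  model_cols <- c(sel$feature, if (include_stage) "uicc8")
  beta <- ridge_cox(design[, model_cols, drop = FALSE],
                    data$os_months, data$event, alpha)
  structure(
    list(features = model_cols, selection = sel,
         transform = params[params$feature %in% model_cols, , drop = FALSE],
         coefficients = beta, alpha = alpha, max_k = max_k,
         include_stage = include_stage, n_spots = nrow(data),
         n_patients = dplyr::n_distinct(data$patient_id %||% seq_len(nrow(data)))),
    class = "risk_model"
  )
}

#' Predict spot-level risks
#'
#' Linear predictor of the ridge Cox model on new spot rows, using the
#' transform parameters frozen at training time.
#'
#' @param model A [fit_risk_model()].
#' @param data Spot-level tibble with the model's feature columns.
#' @return Numeric risk per row.
#' @export
predict_spot_risk <- function(model, data) {
  x <- as.matrix(data[, model$transform$feature, drop = FALSE])
  z <- apply_feature_transform(x, model$transform)
  drop(z[, model$features, drop = FALSE] %*% model$coefficients[model$features])
}

#' Pool spot risks into patient risks
#'
#' The patient risk is the maximum over their spots (the hot-spot
#' approach: the most aggressive region determines the prognosis), or
#' optionally the mean.
#'
#' @param model A [fit_risk_model()].
#' @param data Spot rows with `patient_id`.
#' @param pooling `"max"` (default) or `"mean"`.
#' @param patients Optional patient-id universe; ids without any spot row
#'   raise an error naming them.
#' @return Tibble `patient_id`, `risk`.
#' @export
predict_patient_risk <- function(model, data, pooling = c("max", "mean"),
                                 patients = NULL) {
  pooling <- match.arg(pooling)
  if (!is.null(patients)) {
    missing <- setdiff(patients, data$patient_id)
    if (length(missing) > 0) {
      stop("patient(s) without spots: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  risk <- predict_spot_risk(model, data)
  agg <- if (pooling == "max") max else mean
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(patient_id = data$patient_id, risk = risk),
                    .data$patient_id),
    risk = agg(.data$risk), .groups = "drop"
  )
  out
}

#' Tune the risk-model hyperparameters
#'
#' Grid search over `max_k` and ridge strength `alpha` with inner
#' cross-validation whose folds split *patients*, never spots; the score
#' is the mean held-out patient-level (max-pooled) c-index. Ties prefer
#' the smaller `max_k`, then the larger `alpha`.
#'
#' @param data Spot-level training tibble.
#' @param feature_cols Candidate feature columns.
#' @param max_k_grid,alpha_grid Hyperparameter grids (defaults
#'   `c(3, 5, 8, 10, 11)` clipped to the feature count, and
#'   `c(0.01, 0.1, 1, 10)`).
#' @param n_folds Inner folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param include_stage Passed to [fit_risk_model()].
#' @return A list: `best` (tibble row with `max_k`, `alpha`, `score`) and
#'   `grid` (all combinations with mean scores).
#' @export
tune_hyperparams <- function(data, feature_cols,
                             max_k_grid = c(3, 5, 8, 10, 11),
                             alpha_grid = c(0.01, 0.1, 1, 10),
                             n_folds = 5, seed = 1L, include_stage = TRUE) {
  max_k_grid <- sort(unique(pmin(max_k_grid, length(feature_cols))))
  pats <- unique(data$patient_id)
  n_folds <- min(n_folds, length(pats))
  fold_of <- with_seed(seed, {
    stats::setNames(sample(rep_len(seq_len(n_folds), length(pats))), pats)
  })
  grid <- tidyr::expand_grid(max_k = max_k_grid, alpha = alpha_grid)
  scores <- purrr::pmap_dbl(grid, function(max_k, alpha) {
    fold_scores <- vapply(seq_len(n_folds), function(f) {
      tr <- data[fold_of[data$patient_id] != f, , drop = FALSE]
      te <- data[fold_of[data$patient_id] == f, , drop = FALSE]
      te_pat <- dplyr::distinct(te, .data$patient_id, .data$os_months, .data$event)
      if (sum(te_pat$event) == 0 || sum(tr$event) == 0) {
        warning("fold without events skipped")
        return(NA_real_)
      }
      fit <- fit_risk_model(tr, feature_cols, max_k = max_k, alpha = alpha,
                            include_stage = include_stage)
      pr <- predict_patient_risk(fit, te)
      pr <- dplyr::left_join(pr, te_pat, by = "patient_id")
      concordance_index(pr$risk, pr$os_months, pr$event)
    }, numeric(1))
    mean(fold_scores, na.rm = TRUE)
  })
  grid$score <- scores
  ord <- order(-grid$score, grid$max_k, -grid$alpha)
  list(best = grid[ord[1], , drop = FALSE], grid = grid)
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d features | alpha = %g | %d spots / %d patients\n",
              length(x$features), x$alpha, x$n_spots, x$n_patients))
  print(round(x$coefficients, 4))
  invisible(x)
}
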