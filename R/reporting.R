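# Ordering and embedding utilities behind the figure panels: kernel-PCA
# one-dimensional ordering for stacked histograms, and the UMAP niche
# atlas. All are pure functions of (matrix, parameters, seed).

#' Kernel-PCA ordering of rows and columns
#'
#' Sorts rows (and, independently, columns) of a matrix by their score
#' on the first kernel principal component, using a Gaussian kernel
#' `exp(-||x - y||^2 / (2 l^2))` with length scale `l = 1/d` (`d` =
#' feature count), so that multidimensional neighbors end up adjacent in
#' stacked-histogram displays. The component's sign is fixed so the
#' first row of the sorted output carries the smaller original index.
#'
#' @param x Numeric matrix.
#' @return A list with `row_order`, `col_order`, `row_scores`,
#'   `col_scores`.
#' @export
kpca_order <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("matrix must be finite", call. = FALSE)
  ro <- kpca_order_one(x)
  co <- kpca_order_one(t(x))
  list(
    row_order = as.integer(ro), col_order = as.integer(co),
    row_scores = attr(ro, "scores"), col_scores = attr(co, "scores")
  )
}

kpca_order_one <- function(x) {
  n <- nrow(x)
  if (n == 1) {
    out <- 1L
    attr(out, "scores") <- 0
    return(out)
  }
  d <- ncol(x)
  ell <- 1 / d
  d2 <- as.matrix(stats::dist(x))^2
  k <- exp(-d2 / (2 * ell^2))
  # double centering in feature space
  one <- matrix(1 / n, n, n)
  kc <- k - one %*% k - k %*% one + one %*% k %*% one
  ev <- eigen(kc, symmetric = TRUE)
  scores <- ev$vectors[, 1]
  ord <- order(scores, seq_len(n))
  if (ord[1] > ord[n]) {
    scores <- -scores
    ord <- order(scores, seq_len(n))
  }
  out <- ord
  attr(out, "scores") <- scores
  out
}

#' UMAP niche atlas layout
#'
#' Two-dimensional embedding of per-spot niche abundance patterns. The
#' defaults (100 neighbors, minimum distance 8, spread 8) favor a
#' spread-out layout suitable for thumbnail overlays rather than tight
#' cluster separation. Deterministic given `seed`.
#'
#' @param x Numeric matrix of per-spot niche abundances.
#' @param n_neighbors Neighborhood size (default 100; clipped to
#'   `nrow(x) - 1` with a warning).
#' @param min_dist,spread Layout parameters (defaults 8 and 8).
#' @param seed Integer seed.
#' @return An object of class `atlas_layout`: a tibble with `x`, `y`
#'   (one row per input row) carrying the parameter record as
#'   attributes.
#' @export
umap_atlas <- function(x, n_neighbors = 100, min_dist = 8, spread = 8,
                       seed = 1L) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("matrix must be finite", call. = FALSE)
  if (n_neighbors > nrow(x) - 1) {
    warning("n_neighbors clipped to nrow(x) - 1")
    n_neighbors <- max(2, nrow(x) - 1)
  }
  emb <- with_seed(seed, {
    uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
               spread = spread, n_threads = 1, n_sgd_threads = 0,
               verbose = FALSE)
  })
  out <- tibble::tibble(x = emb[, 1], y = emb[, 2])
  attr(out, "params") <- list(n_neighbors = n_neighbors, min_dist = min_dist,
                              spread = spread, seed = seed)
  class(out) <- c("atlas_layout", class(out))
  out
}
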