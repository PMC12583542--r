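# Cross-subtype niche matching. Independently derived niche sets (e.g.,
# one per tumor subtype) are compared through the symmetric chi-squared
# distance between their phenotype distributions, and matched by exact
# partial optimal transport: every scenario from zero matches to full
# matches is solved, and the number of matched pairs is picked at the
# maximum-curvature knee of the log transport-cost curve.

#' Symmetric chi-squared distance between distributions
#'
#' `sum_i (x_i - y_i)^2 / (x_i + y_i)`, skipping terms where both entries
#' are zero. Symmetric, nonnegative, zero iff the distributions are
#' equal; it does not satisfy the triangle inequality.
#'
#' @param x,y Nonnegative vectors on the same support.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' chi2_distance(c(1, 0), c(0, 1))          # 2
#' chi2_distance(c(.5, .5), c(.25, .75))    # 0.1333...
chi2_distance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must share support")
  if (any(x < 0) || any(y < 0)) stop("entries must be nonnegative")
  s <- x + y
  keep <- s > 0
  sum((x[keep] - y[keep])^2 / s[keep])
}

chi2_distance_matrix <- function(a, b) {
  d <- matrix(0, nrow(a), nrow(b), dimnames = list(rownames(a), rownames(b)))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) d[i, j] <- chi2_distance(a[i, ], b[j, ])
  }
  d
}

# minimum-cost matching of exactly n pairs within cost matrix d,
# via a padded square assignment problem (dummy rows/columns absorb the
# unmatched niches; the dummy-dummy block is blocked by a large cost)
min_cost_n_matching <- function(d, n) {
  ka <- nrow(d); kb <- ncol(d)
  if (n == 0) {
    return(list(cost = 0, pairs = cbind(a = integer(0), b = integer(0))))
  }
  big <- sum(d) + 1
  size <- ka + kb - n
  m <- matrix(0, size, size)
  m[seq_len(ka), seq_len(kb)] <- d
  if (ka > n && kb > n) {
    m[(ka + 1):size, (kb + 1):size] <- big
  }
  sol <- as.integer(clue::solve_LSAP(m))
  a <- seq_len(ka)
  b <- sol[seq_len(ka)]
  real <- b <= kb
  pairs <- cbind(a = a[real], b = b[real])
  stopifnot(nrow(pairs) == n)
  list(cost = sum(d[pairs]), pairs = pairs)
}

#' Match two niche sets by partial optimal transport
#'
#' Places uniform mass `1/k` on every niche of each side, solves the
#' exact partial optimal transport problem moving mass `n/k` under the
#' chi-squared cost for every `n` from 0 to `min(k_a, k_b)` (with uniform
#' capacities this is a minimum-cost `n`-matching, solved exactly), and
#' selects `n*` at the maximum of the discrete second difference of
#' `log(cost + eps)` — the knee where easy matches give way to forced
#' ones. Matched pairs are plan entries carrying at least `1/(2k)` mass.
#' If even the full matching has (numerically) zero cost the sets are
#' identical and `n* = k`.
#'
#' @param profiles_a,profiles_b Matrices of per-niche phenotype
#'   distributions (rows sum to 1), or `niche_profiles` objects.
#' @param eps Offset inside the log (default 1e-12).
#' @return An object of class `niche_match`: `distance` (k_a x k_b
#'   chi-squared matrix), `costs` (tibble of `n`, `cost`, `log_cost`),
#'   `n_star`, and `pairs` (tibble `niche_a`, `niche_b`, `mass`, `cost`).
#' @export
match_niches <- function(profiles_a, profiles_b, eps = 1e-12) {
  a <- if (inherits(profiles_a, "niche_profiles")) profile_matrix(profiles_a) else as.matrix(profiles_a)
  b <- if (inherits(profiles_b, "niche_profiles")) profile_matrix(profiles_b) else as.matrix(profiles_b)
  if (nrow(a) < 1 || nrow(b) < 1) stop("need at least one profile per side")
  if (ncol(a) != ncol(b)) stop("profile supports differ")
  d <- chi2_distance_matrix(a, b)
  kk <- min(nrow(a), nrow(b))
  w <- 1 / max(nrow(a), nrow(b))

  sols <- lapply(0:kk, function(n) min_cost_n_matching(d, n))
  cost <- w * vapply(sols, `[[`, numeric(1), "cost")
  log_cost <- log(cost + eps)
  if (cost[kk + 1] <= eps) {
    n_star <- kk
  } else if (kk < 2) {
    n_star <- kk
  } else {
    curv <- vapply(2:kk, function(i) {
      log_cost[i + 1] - 2 * log_cost[i] + log_cost[i - 1]
    }, numeric(1))
    n_star <- which.max(curv)   # n in 1..kk-1
  }
  pr <- sols[[n_star + 1]]$pairs
  pairs <- tibble::tibble(
    niche_a = pr[, "a"], niche_b = pr[, "b"],
    mass = rep(w, nrow(pr)), cost = d[pr]
  )
  pairs <- pairs[pairs$mass >= 1 / (2 * max(nrow(a), nrow(b))), , drop = FALSE]
  structure(
    list(distance = d,
         costs = tibble::tibble(n = 0:kk, cost = cost, log_cost = log_cost),
         n_star = n_star, pairs = pairs),
    class = "niche_match"
  )
}

#' @export
print.niche_match <- function(x, ...) {
  cat(sprintf("<niche_match> %d x %d niches | n* = %d matched pairs\n",
              nrow(x$distance), ncol(x$distance), x$n_star))
  print(x$pairs)
  invisible(x)
}
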