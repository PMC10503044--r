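#' Chi-squared P-values for singular-vector scores under a Gaussian null
#'
#' Under the null hypothesis a feature's singular-vector score `u` is
#' Gaussian with standard deviation `sigma`, so `(u/sigma)^2` follows a
#' chi-squared distribution with one degree of freedom. The P-value is the
#' upper tail probability at the squared standardized score; it is symmetric
#' in the sign of `u`.
#'
#' @param scores Numeric vector of feature scores (a feature-mode singular
#'   vector column, or back-projected multiomics scores).
#' @param sigma Positive null standard deviation, typically from
#'   [optimize_sd()].
#' @return Numeric vector of P-values in `[0, 1]`.
#' @examples
#' compute_pvalues(c(0, 1.959964, -1.959964), sigma = 1)
#' @export
compute_pvalues <- function(scores, sigma) {
  if (!(length(sigma) == 1L && is.finite(sigma) && sigma > 0))
    stop("`sigma` must be a single positive number")
  if (!all(is.finite(scores))) stop("`scores` must be finite")
  stats::pchisq((scores / sigma)^2, df = 1, lower.tail = FALSE)
}

# Flatness objective: histogram 1-P into `bins` equal-width bins on [0,1],
# drop the bins nearest 1 (the large-|u| signal tail), return the SD of the
# remaining counts. Minimal when P is uniform outside the tail.
sd_objective <- function(scores, sigma, bins, tail_fraction, n_shifts = 8L) {
  p <- stats::pchisq((scores / sigma)^2, df = 1, lower.tail = FALSE)
  q <- 1 - p
  n <- length(scores)
  keepn <- bins - ceiling(tail_fraction * bins)
  # flatness is measured relative to the kept-bin occupancy (coefficient of
  # variation): the raw SD of counts shrinks as mass is pushed into the
  # excluded tail, which would make sigma -> 0 a spurious minimum. Averaging
  # over shifted bin grids (averaged shifted histograms) removes most of the
  # binning noise, which otherwise jitters the argmin by a few percent.
  vals <- vapply(seq_len(n_shifts) - 1L, function(k) {
    idx <- pmin(floor((q + k / (n_shifts * bins)) * bins) + 1L, bins + 1L)
    counts <- tabulate(idx, nbins = bins + 1L)
    kept <- counts[seq_len(keepn)]
    tot <- sum(kept)
    if (tot < n / 2) return(Inf)
    stats::sd(kept) / (tot / keepn)
  }, numeric(1))
  mean(vals)
}

#' Optimize the null standard deviation
#'
#' Chooses `sigma` so that the scores look as Gaussian as possible: P-values
#' computed via the chi-squared(1) tail are histogrammed as `1 - P` into
#' equal-width bins on `[0, 1]`, the bins nearest 1 (where genuine signal
#' accumulates) are excluded, and the coefficient of variation (SD over
#' mean) of the remaining bin counts is minimized over `sigma`; the mean
#' normalization keeps the objective comparable across `sigma` values that
#' leave different amounts of mass in the kept bins, and the objective is
#' averaged over shifted bin grids (averaged shifted histograms) to remove
#' binning noise. A uniform P-value distribution —
#' the hallmark of a correctly standardized Gaussian null — makes the kept
#' histogram flat, so the objective is minimal near the true null SD while
#' the excluded tail shields the estimate from planted signal.
#'
#' The search is deterministic: a log-spaced grid of `grid_points` values
#' over the bracket, followed by golden-section refinement between the
#' neighbours of the best grid point.
#'
#' @param scores Numeric vector of scores; at least ~100 recommended, not
#'   all zero.
#' @param bins Number of histogram bins (default 100).
#' @param tail_fraction Fraction of bins nearest 1 excluded as the signal
#'   tail (default 0.1).
#' @param bracket Length-2 multiplier range for the search, relative to
#'   `sd(scores)` (default `c(0.01, 10)`).
#' @param grid_points Size of the initial grid (default 64).
#' @param rel_tol Relative tolerance on sigma for the refinement stage.
#' @return An object of class `sd_fit`: list with `sigma`,
#'   `objective_value`, and `histogram` (bin `breaks` and `counts` of
#'   `1 - P` at the optimum).
#' @examples
#' set.seed(1)
#' fit <- optimize_sd(rnorm(5000, sd = 2))
#' fit$sigma
#' @export
optimize_sd <- function(scores, bins = 100L, tail_fraction = 0.1,
                        bracket = c(0.01, 10), grid_points = 64L,
                        rel_tol = 1e-4) {
  if (!all(is.finite(scores))) stop("`scores` must be finite")
  s0 <- stats::sd(scores)
  if (!is.finite(s0) || s0 == 0)
    stop("scores are constant (all zero variance); cannot optimize sigma")
  if (length(bracket) != 2L || any(bracket <= 0) || bracket[1] >= bracket[2])
    stop("`bracket` must be two increasing positive multipliers")
  lo <- bracket[1] * s0
  hi <- bracket[2] * s0
  grid <- exp(seq(log(lo), log(hi), length.out = grid_points))
  obj <- vapply(grid, function(s) sd_objective(scores, s, bins, tail_fraction),
                numeric(1))
  if (!any(is.finite(obj)))
    stop("sigma search bracket yields no finite objective; widen `bracket`")
  best <- which.min(obj)
  # deterministic fine-grid refinement between the neighbours of the best
  # point; the objective is piecewise constant, so grid scans are more
  # reliable than derivative-free local optimizers
  while ((grid[min(length(grid), best + 1L)] /
            grid[max(1L, best - 1L)] - 1) > rel_tol) {
    grid <- exp(seq(log(grid[max(1L, best - 1L)]),
                    log(grid[min(length(grid), best + 1L)]),
                    length.out = 33L))
    obj <- vapply(grid, function(s)
      sd_objective(scores, s, bins, tail_fraction), numeric(1))
    best <- which.min(obj)
  }
  sigma <- grid[best]
  p <- compute_pvalues(scores, sigma)
  idx <- pmin(floor((1 - p) * bins) + 1L, bins)
  structure(
    list(sigma = sigma,
         objective_value = sd_objective(scores, sigma, bins, tail_fraction),
         histogram = list(breaks = seq(0, 1, length.out = bins + 1L),
                          counts = tabulate(idx, nbins = bins))),
    class = "sd_fit"
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: the i-th smallest P-value is
#' mapped to `min_{j >= i} p_(j) * m / j`, capped at 1, in input order.
#' Input validation rejects values outside `[0, 1]`.
#'
#' @param p Numeric vector of raw P-values in `[0, 1]`.
#' @return Adjusted P-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!all(is.finite(p)) || any(p < 0) || any(p > 1))
    stop("P-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select features by SD-optimized chi-squared P-values
#'
#' The full single-vector selection step: optimize the null SD on the
#' scores, compute chi-squared(1) P-values, adjust them by
#' Benjamini-Hochberg, and flag features whose adjusted P falls below the
#' threshold (default 0.01).
#'
#' @param scores Numeric score vector (one entry per feature).
#' @param feature_ids Character vector of the same length.
#' @param threshold Adjusted-P selection threshold (default 0.01).
#' @param bins,tail_fraction,bracket Passed to [optimize_sd()].
#' @return An object of class `feature_selection`: list with `table` (a
#'   data.frame with columns `feature_id`, `score_u`, `p_value`,
#'   `adjusted_p`, `selected`, sorted by adjusted P then by decreasing
#'   `|score_u|`), `sigma`, `objective_value`, `histogram`, `threshold`,
#'   and `n_selected`.
#' @examples
#' set.seed(1)
#' u <- c(rnorm(500), rnorm(5, mean = 8))
#' sel <- select_features(u, paste0("g", seq_along(u)))
#' sel$n_selected
#' @export
select_features <- function(scores, feature_ids, threshold = 0.01,
                            bins = 100L, tail_fraction = 0.1,
                            bracket = c(0.01, 10)) {
  if (length(scores) != length(feature_ids))
    stop("`scores` and `feature_ids` lengths differ")
  s0 <- stats::sd(scores)
  if (!is.finite(s0) || s0 == 0) {
    # degenerate score vectors (constant, or a single score) carry no
    # distributional information; fall back to a unit-or-larger null SD so
    # P-values are defined and nothing can be spuriously selected
    sigma <- max(abs(scores), 1)
    fit <- list(sigma = sigma, objective_value = NA_real_,
                histogram = list(breaks = seq(0, 1, length.out = bins + 1L),
                                 counts = integer(bins)))
  } else {
    fit <- optimize_sd(scores, bins = bins, tail_fraction = tail_fraction,
                       bracket = bracket)
  }
  p <- compute_pvalues(scores, fit$sigma)
  adj <- bh_adjust(p)
  tab <- data.frame(feature_id = as.character(feature_ids),
                    score_u = scores, p_value = p, adjusted_p = adj,
                    selected = adj < threshold,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$adjusted_p, -abs(tab$score_u)), , drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(table = tab, sigma = fit$sigma,
         objective_value = fit$objective_value, histogram = fit$histogram,
         threshold = threshold, n_selected = sum(tab$selected)),
    class = "feature_selection"
  )
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf(
    "feature_selection: %d / %d features at adjusted P < %g (sigma = %.4g)\n",
    x$n_selected, nrow(x$table), x$threshold, x$sigma))
  invisible(x)
}

#' Write a feature table as TSV
#'
#' @param selection A `feature_selection` (or its `table` data.frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(selection, path) {
  tab <- if (inherits(selection, "feature_selection")) selection$table
         else selection
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
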