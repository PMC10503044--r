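#' Describe the sample layout of a single-omics tensor
#'
#' @param replicates Vector of replicate labels, one per mode-2 index.
#' @param conditions Ordered vector of condition levels, one per mode-3
#'   index (ordinal, e.g. tumour stages i..iv). Must contain at least two
#'   distinct levels.
#' @return An object of class `sample_design`.
#' @export
sample_design <- function(replicates, conditions) {
  if (length(unique(conditions)) < 2L)
    stop("`conditions` must contain at least 2 distinct ordered levels")
  structure(
    list(replicate_labels = as.character(replicates),
         condition_levels = as.character(conditions)),
    class = "sample_design"
  )
}

#' Replicate-constancy score of a factor column
#'
#' A sample-mode singular vector attributed to replicates should be constant
#' across replicates with a consistent sign. The score is
#' `|mean| / (SD + 1e-12)`: large for near-constant columns, near zero for
#' mean-zero ones.
#'
#' @param factor_column Numeric vector (a mode-2 factor column).
#' @return Non-negative score; 0 (with a warning) for an all-zero column.
#' @export
score_constancy <- function(factor_column) {
  if (all(factor_column == 0)) {
    warning("zero factor column: constancy score is 0")
    return(0)
  }
  s <- stats::sd(factor_column)
  if (!is.finite(s)) s <- 0  # length-1 column
  abs(mean(factor_column)) / (s + 1e-12)
}

#' Condition-monotonicity score of a factor column
#'
#' A sample-mode singular vector attributed to ordinal conditions should
#' depend monotonically on the condition level. The score is the absolute
#' Spearman rank correlation between the column and the ordinal levels; the
#' trend direction is returned alongside.
#'
#' @param factor_column Numeric vector (a mode-3 factor column).
#' @param levels Ordinal condition levels of the same length (numeric,
#'   ordered factor, or character in the intended order of appearance).
#' @return List with `score` (absolute Spearman correlation in `[0, 1]`) and
#'   `direction` (+1, -1 or 0).
#' @export
score_monotonicity <- function(factor_column, levels) {
  if (length(factor_column) != length(levels))
    stop("column and levels lengths differ")
  lv <- ordinal_codes(levels)
  if (length(unique(lv)) < 2L)
    stop("need at least 2 distinct condition levels")
  if (stats::sd(factor_column) == 0) {
    warning("constant factor column: monotonicity score is 0")
    return(list(score = 0, direction = 0))
  }
  rho <- suppressWarnings(stats::cor(factor_column, lv, method = "spearman"))
  if (!is.finite(rho)) rho <- 0
  list(score = abs(rho), direction = sign(rho))
}

# Map an ordinal label vector to integer codes preserving the intended
# order: numeric as-is, factors by level order, characters by order of
# first appearance.
ordinal_codes <- function(levels) {
  if (is.numeric(levels)) return(as.numeric(levels))
  if (is.factor(levels)) return(as.numeric(levels))
  as.numeric(factor(levels, levels = unique(levels)))
}

#' Choose the replicate- and condition-mode singular vectors
#'
#' Scores every mode-2 factor column for replicate constancy and every
#' mode-3 column for condition monotonicity, and returns the argmax of
#' each. An explicit `override` replaces the automatic choice (the
#' equivalent of an interactive pick), while the full score tables are
#' still reported for inspection.
#'
#' @param model A `tucker_model` fitted on the tensor.
#' @param design The tensor's [sample_design()].
#' @param override Optional integer vector `c(l2, l3)`.
#' @return List with `l2`, `l3`, `constancy_scores` (one per mode-2
#'   column) and `monotonicity_scores` (one per mode-3 column).
#' @export
choose_sample_vectors <- function(model, design, override = NULL) {
  stopifnot(inherits(model, "tucker_model"), inherits(design, "sample_design"))
  if (length(unique(design$condition_levels)) < 2L)
    stop("design must have at least 2 distinct condition levels")
  U2 <- model$factors[[2]]
  U3 <- model$factors[[3]]
  cscores <- apply(U2, 2L, function(v) suppressWarnings(score_constancy(v)))
  mscores <- apply(U3, 2L, function(v)
    suppressWarnings(score_monotonicity(v, design$condition_levels)$score))
  if (!is.null(override)) {
    override <- as.integer(override)
    if (length(override) != 2L || override[1] < 1L ||
        override[1] > ncol(U2) || override[2] < 1L || override[2] > ncol(U3))
      stop("override (l2, l3) out of range")
    l2 <- override[1]
    l3 <- override[2]
  } else {
    l2 <- which.max(cscores)
    # with few condition levels, exact |Spearman| ties at 1 are common (a
    # near-constant column can be monotone by noise); break exact ties
    # toward the column with the largest spread, i.e. a genuine trend
    tied <- which(mscores >= max(mscores) - 1e-8)
    l3 <- tied[which.max(apply(U3[, tied, drop = FALSE], 2L, stats::sd))]
  }
  list(l2 = l2, l3 = l3, constancy_scores = cscores,
       monotonicity_scores = mscores)
}

#' Choose the feature-mode singular vector through the core tensor
#'
#' With the sample-mode components `(l2, l3)` fixed, the feature-mode
#' component sharing the largest-magnitude core weight with them is
#' selected. Ties are broken by the smallest index.
#'
#' @param model A `tucker_model`.
#' @param l2,l3 Chosen mode-2 and mode-3 component indices.
#' @return Integer `l1`.
#' @export
choose_feature_vector <- function(model, l2, l3) {
  stopifnot(inherits(model, "tucker_model"))
  rk <- dim(model$core)
  if (l2 < 1L || l2 > rk[2] || l3 < 1L || l3 > rk[3])
    stop("(l2, l3) out of range for the core tensor")
  fiber <- abs(model$core[, l2, l3])
  which.max(fiber)  # ties: first (smallest l1)
}

#' Configuration for the single-tensor DEG pipeline
#'
#' @param preprocess One of `"none"`, `"log1p"`, `"feature_standardize"`;
#'   transformation applied to the tensor before decomposition.
#' @param threshold Adjusted-P selection threshold.
#' @param bins,tail_fraction,sigma_bracket Null-model parameters, see
#'   [optimize_sd()].
#' @param l2,l3 Optional manual component overrides.
#' @param ranks Optional HOSVD ranks.
#' @return A list of class `deg_config`.
#' @export
deg_config <- function(preprocess = c("none", "log1p", "feature_standardize"),
                       threshold = 0.01, bins = 100L, tail_fraction = 0.1,
                       sigma_bracket = c(0.01, 10), l2 = NULL, l3 = NULL,
                       ranks = NULL) {
  structure(
    list(preprocess = match.arg(preprocess), threshold = threshold,
         bins = bins, tail_fraction = tail_fraction,
         sigma_bracket = sigma_bracket, l2 = l2, l3 = l3, ranks = ranks),
    class = "deg_config"
  )
}

apply_preprocess <- function(values, preprocess) {
  switch(preprocess,
    none = values,
    log1p = {
      if (any(values < 0))
        stop("log1p preprocessing requires non-negative values")
      log1p(values)
    },
    feature_standardize = {
      d <- dim(values)
      m <- matrix(values, d[1], d[2] * d[3])
      mu <- rowMeans(m)
      sdv <- apply(m, 1L, stats::sd)
      sdv[sdv == 0] <- 1
      array((m - mu) / sdv, d)
    },
    stop("unknown preprocess mode: ", preprocess)
  )
}

#' Unsupervised DEG identification from a single omics tensor
#'
#' The full single-tensor pipeline: (optionally preprocess, then) decompose
#' the tensor by HOSVD; pick the mode-2 component most constant across
#' replicates and the mode-3 component most monotone in the ordinal
#' condition; pick the feature-mode component with the largest-magnitude
#' core weight at that pair; and select features from that singular vector
#' with SD-optimized chi-squared P-values and Benjamini-Hochberg
#' correction. Deterministic given the tensor and configuration.
#'
#' @param tensor An [omics_tensor()]; its `design` is used unless `design`
#'   is supplied.
#' @param design Optional [sample_design()] overriding `tensor$design`.
#' @param config A [deg_config()].
#' @return An object of class `deg_result`: list with `l1`, `l2`, `l3`,
#'   `constancy_scores`, `monotonicity_scores`, `core_slice` (the core
#'   fiber over l1 at the chosen pair), `selection` (a
#'   `feature_selection`), `sigma`, `model`, and `config`.
#' @examples
#' spec <- synthetic_spec(n_features = 200, n_planted = 20, seed = 7)
#' sim <- make_deg_tensor(spec)
#' res <- run_deg(sim$tensor)
#' res$selection$n_selected
#' @export
run_deg <- function(tensor, design = NULL, config = deg_config()) {
  stopifnot(inherits(tensor, "omics_tensor"))
  if (is.null(design)) design <- tensor$design
  if (is.null(design))
    stop("no sample design: supply `design` or build the tensor with one")
  values <- apply_preprocess(tensor$values, config$preprocess)
  model <- hosvd(values, ranks = config$ranks)
  override <- if (!is.null(config$l2) && !is.null(config$l3))
    c(config$l2, config$l3) else NULL
  picks <- choose_sample_vectors(model, design, override = override)
  l1 <- choose_feature_vector(model, picks$l2, picks$l3)
  sel <- select_features(model$factors[[1]][, l1], tensor$feature_ids,
                         threshold = config$threshold, bins = config$bins,
                         tail_fraction = config$tail_fraction,
                         bracket = config$sigma_bracket)
  structure(
    list(l1 = l1, l2 = picks$l2, l3 = picks$l3,
         constancy_scores = picks$constancy_scores,
         monotonicity_scores = picks$monotonicity_scores,
         core_slice = model$core[, picks$l2, picks$l3],
         selection = sel, sigma = sel$sigma, model = model, config = config),
    class = "deg_result"
  )
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf(
    "deg_result: components (l1, l2, l3) = (%d, %d, %d); %d / %d features selected at adjusted P < %g\n",
    x$l1, x$l2, x$l3, x$selection$n_selected, nrow(x$selection$table),
    x$selection$threshold))
  invisible(x)
}
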