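#' Bundle several omics layers sharing one sample axis
#'
#' @param layers List of K numeric matrices; layer k has shape `N_k x M`
#'   (features in rows, the M shared samples in columns, same order in every
#'   layer).
#' @param layer_names Character vector of K layer names (defaults to
#'   `layer1..layerK` or the list names).
#' @param sample_ids Character vector of the M shared sample identifiers
#'   (defaults to the first layer's column names).
#' @param feature_ids Optional list of per-layer feature identifier vectors
#'   (defaults to each layer's row names, or generated).
#' @return An object of class `multiomics_set`.
#' @export
multiomics_set <- function(layers, layer_names = NULL, sample_ids = NULL,
                           feature_ids = NULL) {
  if (!is.list(layers) || length(layers) < 1L)
    stop("`layers` must be a non-empty list of matrices")
  layers <- lapply(layers, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  if (is.null(layer_names))
    layer_names <- if (!is.null(names(layers)) && all(nzchar(names(layers))))
      names(layers) else paste0("layer", seq_along(layers))
  M <- ncol(layers[[1]])
  for (k in seq_along(layers)) {
    if (ncol(layers[[k]]) != M)
      stop(sprintf("layer '%s' has %d samples but '%s' has %d; all layers must share the sample axis",
                   layer_names[k], ncol(layers[[k]]), layer_names[1], M))
    if (nrow(layers[[k]]) < 1L)
      stop(sprintf("layer '%s' has no features", layer_names[k]))
    if (!all(is.finite(layers[[k]])))
      stop(sprintf("layer '%s' contains non-finite values", layer_names[k]))
  }
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(colnames(layers[[1]]))) colnames(layers[[1]])
                  else paste0("s", seq_len(M))
  if (length(sample_ids) != M) stop("`sample_ids` length must equal M")
  if (is.null(feature_ids))
    feature_ids <- lapply(seq_along(layers), function(k) {
      if (!is.null(rownames(layers[[k]]))) rownames(layers[[k]])
      else paste0(layer_names[k], "_f", seq_len(nrow(layers[[k]])))
    })
  structure(
    list(layers = lapply(layers, unname), layer_names = layer_names,
         sample_ids = as.character(sample_ids),
         feature_ids = lapply(feature_ids, as.character)),
    class = "multiomics_set"
  )
}

#' @export
print.multiomics_set <- function(x, ...) {
  cat(sprintf("multiomics_set: %d layers x %d shared samples\n",
              length(x$layers), length(x$sample_ids)))
  for (k in seq_along(x$layers))
    cat(sprintf("  %s: %d features\n", x$layer_names[k], nrow(x$layers[[k]])))
  invisible(x)
}

center_layer <- function(X) X - rowMeans(X)

#' Sample-space Gram tensor of a multiomics set
#'
#' For each omics layer, the sample-by-sample inner-product matrix is formed
#' by summing over that layer's features; stacking the K slices yields an
#' `M x M x K` tensor. This eliminates the (large) per-layer feature index
#' before decomposition, so memory scales with the number of samples, not
#' features. Each slice is symmetric positive semidefinite by construction.
#'
#' @param omics A [multiomics_set()].
#' @param center Centre each feature across samples before the product
#'   (default `TRUE`); uncentered Gram matrices are typically dominated by
#'   mean structure.
#' @return An object of class `gram_tensor`: list with `values`
#'   (`M x M x K` array), `sample_ids`, `layer_names`, `centered`.
#' @export
build_gram_tensor <- function(omics, center = TRUE) {
  stopifnot(inherits(omics, "multiomics_set"))
  M <- length(omics$sample_ids)
  K <- length(omics$layers)
  values <- array(0, c(M, M, K))
  for (k in seq_len(K)) {
    X <- omics$layers[[k]]
    if (center) X <- center_layer(X)
    G <- crossprod(X)
    values[, , k] <- (G + t(G)) / 2  # enforce exact symmetry
  }
  structure(
    list(values = values, sample_ids = omics$sample_ids,
         layer_names = omics$layer_names, centered = center),
    class = "gram_tensor"
  )
}

#' HOSVD of a Gram tensor
#'
#' Delegates to [hosvd()]. Because every slice is symmetric, the mode-1 and
#' mode-2 factors span the same subspace; columns whose singular values are
#' well separated from zero are checked to agree elementwise up to sign,
#' with a warning otherwise.
#'
#' @param gram A `gram_tensor` from [build_gram_tensor()].
#' @param ranks Optional HOSVD ranks.
#' @return A `tucker_model`.
#' @export
hosvd_gram <- function(gram, ranks = NULL) {
  stopifnot(inherits(gram, "gram_tensor"))
  model <- hosvd(gram$values, ranks = ranks)
  sv <- model$mode_sv[[1]]
  if (length(sv) && max(sv) > 0) {
    lead <- which(sv > 1e-8 * max(sv))
    lead <- lead[lead <= min(ncol(model$factors[[1]]), ncol(model$factors[[2]]))]
    mism <- vapply(lead, function(j)
      max(abs(abs(model$factors[[1]][, j]) - abs(model$factors[[2]][, j]))),
      numeric(1))
    if (any(mism > 1e-6))
      warning("mode-1/mode-2 factor mismatch beyond tolerance on a symmetric Gram tensor")
  }
  model
}

#' Choose the sample-mode component tracking the labels
#'
#' Scores every mode-1 factor column of a Gram-tensor decomposition against
#' the sample labels: absolute Spearman rank correlation for ordinal or
#' numeric labels, absolute point-biserial correlation for two-class
#' labels. Returns the argmax unless overridden.
#'
#' @param model A `tucker_model` from [hosvd_gram()].
#' @param labels Sample labels of length M: numeric, ordered factor,
#'   character (ordinal by order of appearance), or a two-level factor.
#' @param override Optional integer component index used verbatim.
#' @return List with `l1` and `scores` (one per mode-1 column).
#' @export
choose_label_vector <- function(model, labels, override = NULL) {
  stopifnot(inherits(model, "tucker_model"))
  U <- model$factors[[1]]
  if (length(labels) != nrow(U))
    stop("`labels` length must equal the number of samples")
  two_class <- (is.factor(labels) && nlevels(droplevels(as.factor(labels))) == 2L) ||
    (!is.numeric(labels) && length(unique(labels)) == 2L)
  codes <- if (two_class) as.numeric(factor(labels, levels = unique(labels)))
           else ordinal_codes(labels)
  if (length(unique(codes)) < 2L)
    stop("labels must contain at least 2 distinct values")
  method <- if (two_class) "pearson" else "spearman"
  scores <- apply(U, 2L, function(v) {
    if (stats::sd(v) == 0) return(0)
    r <- suppressWarnings(stats::cor(v, codes, method = method))
    if (is.finite(r)) abs(r) else 0
  })
  if (!is.null(override)) {
    override <- as.integer(override)
    if (length(override) != 1L || override < 1L || override > ncol(U))
      stop("component override out of range")
    l1 <- override
  } else {
    l1 <- which.max(scores)
  }
  list(l1 = l1, scores = scores)
}

#' Back-project a sample-mode singular vector onto each layer's features
#'
#' Each layer's feature scores are the layer matrix applied to the chosen
#' sample-mode singular vector: feature i of layer k scores
#' `sum_j u_j x_{i_k j}`.
#'
#' @param omics A [multiomics_set()].
#' @param label_vector Numeric vector of length M (a mode-1 factor column).
#' @param center Use the same per-feature centering as the Gram
#'   construction (default `TRUE`).
#' @return Named list of per-layer numeric score vectors (length `N_k`).
#' @export
project_features <- function(omics, label_vector, center = TRUE) {
  stopifnot(inherits(omics, "multiomics_set"))
  if (length(label_vector) != length(omics$sample_ids))
    stop("`label_vector` length must equal the number of shared samples")
  out <- lapply(omics$layers, function(X) {
    if (center) X <- center_layer(X)
    as.vector(X %*% label_vector)
  })
  names(out) <- omics$layer_names
  out
}

#' Configuration for the multiomics pipeline
#'
#' @param center Per-feature centering before the Gram product.
#' @param threshold Adjusted-P selection threshold.
#' @param bins,tail_fraction,sigma_bracket Null-model parameters.
#' @param component Optional manual sample-mode component override.
#' @param ranks Optional HOSVD ranks for the Gram tensor.
#' @return A list of class `multiomics_config`.
#' @export
multiomics_config <- function(center = TRUE, threshold = 0.01, bins = 100L,
                              tail_fraction = 0.1, sigma_bracket = c(0.01, 10),
                              component = NULL, ranks = NULL) {
  structure(
    list(center = center, threshold = threshold, bins = bins,
         tail_fraction = tail_fraction, sigma_bracket = sigma_bracket,
         component = component, ranks = ranks),
    class = "multiomics_config"
  )
}

#' Multiomics feature selection via the shared-sample Gram tensor
#'
#' The full multiomics pipeline: build the sample-space Gram tensor,
#' decompose it by HOSVD, choose the sample-mode singular vector tracking
#' the labels, back-project it onto each layer's features, and select
#' features per layer with SD-optimized chi-squared P-values (the null SD
#' is optimized independently per layer, since layer score scales differ
#' with `N_k`) and Benjamini-Hochberg correction.
#'
#' @param omics A [multiomics_set()].
#' @param labels Sample labels of length M (see [choose_label_vector()]).
#' @param config A [multiomics_config()].
#' @return An object of class `multiomics_result`: list with `tables`
#'   (named list of per-layer `feature_selection` objects), `l1`,
#'   `label_scores`, `sigmas` (named per-layer), `model`, and `config`.
#' @examples
#' sim <- make_multiomics_set(synthetic_spec(seed = 3,
#'   layer_sizes = c(80, 60), n_planted_per_layer = c(8, 6), n_samples = 24))
#' res <- run_multiomics(sim$set, sim$labels)
#' vapply(res$tables, function(t) t$n_selected, integer(1))
#' @export
run_multiomics <- function(omics, labels, config = multiomics_config()) {
  stopifnot(inherits(omics, "multiomics_set"))
  gram <- build_gram_tensor(omics, center = config$center)
  model <- hosvd_gram(gram, ranks = config$ranks)
  pick <- choose_label_vector(model, labels, override = config$component)
  u <- model$factors[[1]][, pick$l1]
  scores <- project_features(omics, u, center = config$center)
  tables <- lapply(seq_along(scores), function(k)
    select_features(scores[[k]], omics$feature_ids[[k]],
                    threshold = config$threshold, bins = config$bins,
                    tail_fraction = config$tail_fraction,
                    bracket = config$sigma_bracket))
  names(tables) <- omics$layer_names
  sigmas <- vapply(tables, function(t) t$sigma, numeric(1))
  structure(
    list(tables = tables, l1 = pick$l1, label_scores = pick$scores,
         sigmas = sigmas, model = model, config = config),
    class = "multiomics_result"
  )
}

#' @export
print.multiomics_result <- function(x, ...) {
  cat(sprintf("multiomics_result: component l1 = %d\n", x$l1))
  for (k in seq_along(x$tables))
    cat(sprintf("  %s: %d / %d selected (sigma = %.4g)\n",
                names(x$tables)[k], x$tables[[k]]$n_selected,
                nrow(x$tables[[k]]$table), x$sigmas[k]))
  invisible(x)
}
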