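#' Specification for synthetic fixtures
#'
#' Describes the synthetic tensors and multiomics sets used throughout the
#' test suite. Defaults mirror a staged-tumour bulk-expression layout: a
#' 1,000-feature x 9-replicate x 4-condition tensor with 100 planted
#' monotone-trend features at effect size 3 (in noise-SD units) and unit
#' Gaussian noise.
#'
#' @param n_features,n_replicates,n_conditions Tensor dimensions for the
#'   single-omics generator.
#' @param n_planted Number of features carrying the planted signal.
#' @param effect_size Peak trend amplitude in units of `noise_sd` (0 gives
#'   a pure-null fixture).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer RNG seed; fixed seed implies reproducible output.
#' @param distribution `"gaussian"` (what the null model assumes) or
#'   `"lognormal"` (count-like, for robustness checks).
#' @param layer_sizes Per-layer feature counts `N_k` for the multiomics
#'   generator.
#' @param n_planted_per_layer Planted feature counts per layer.
#' @param n_samples Number of shared samples M.
#' @param n_levels Number of ordinal label levels for the multiomics
#'   generator.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_features = 1000L, n_replicates = 9L,
                           n_conditions = 4L, n_planted = 100L,
                           effect_size = 3, noise_sd = 1, seed = 1L,
                           distribution = c("gaussian", "lognormal"),
                           layer_sizes = c(500L, 300L, 200L),
                           n_planted_per_layer = c(50L, 30L, 20L),
                           n_samples = 40L, n_levels = 4L) {
  distribution <- match.arg(distribution)
  if (n_planted > n_features)
    stop("`n_planted` cannot exceed `n_features`")
  if (effect_size < 0) stop("`effect_size` must be >= 0")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (length(layer_sizes) != length(n_planted_per_layer))
    stop("`layer_sizes` and `n_planted_per_layer` lengths differ")
  if (any(n_planted_per_layer > layer_sizes))
    stop("planted count exceeds layer size")
  structure(
    list(n_features = as.integer(n_features),
         n_replicates = as.integer(n_replicates),
         n_conditions = as.integer(n_conditions),
         n_planted = as.integer(n_planted),
         effect_size = effect_size, noise_sd = noise_sd,
         seed = as.integer(seed), distribution = distribution,
         layer_sizes = as.integer(layer_sizes),
         n_planted_per_layer = as.integer(n_planted_per_layer),
         n_samples = as.integer(n_samples), n_levels = as.integer(n_levels)),
    class = "synthetic_spec"
  )
}

#' Generate a single-omics tensor with planted monotone features
#'
#' Entry `(i, j, k)` is `baseline_i + planted_i * effect_size * noise_sd *
#' trend(k) + noise`, where the trend is linear and centred over the
#' ordinal condition levels and normalized to peak amplitude 1
#' (`trend(1) = -1`, `trend(K) = +1`), identical across replicates, and
#' the noise is iid Gaussian (or the exponentiated, count-like variant).
#' `effect_size` is therefore the largest per-entry mean shift in noise-SD
#' units; the planted last-minus-first condition difference is
#' `2 * effect_size * noise_sd`. Baselines are per-feature standard normal
#' draws, constant across samples.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `tensor` (an [omics_tensor()] with an attached
#'   [sample_design()]) and `truth` (logical planted mask over features).
#' @export
make_deg_tensor <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  N <- spec$n_features; M <- spec$n_replicates; K <- spec$n_conditions
  baseline <- stats::rnorm(N)
  truth <- rep(FALSE, N)
  truth[sample.int(N, spec$n_planted)] <- TRUE
  trend <- 2 * (seq_len(K) - (K + 1) / 2) / (K - 1)
  signal <- outer(as.numeric(truth) * spec$effect_size * spec$noise_sd, trend)
  x <- array(0, c(N, M, K))
  for (j in seq_len(M))
    x[, j, ] <- baseline + signal
  x <- x + array(stats::rnorm(N * M * K, sd = spec$noise_sd), c(N, M, K))
  if (spec$distribution == "lognormal") x <- exp(x)
  design <- sample_design(paste0("rep", seq_len(M)),
                          paste0("cond", seq_len(K)))
  tensor <- omics_tensor(x, feature_ids = paste0("f", seq_len(N)),
                         mode2_ids = design$replicate_labels,
                         mode3_ids = design$condition_levels,
                         design = design)
  list(tensor = tensor, truth = truth)
}

#' Generate a multiomics set with planted label-associated features
#'
#' Emulates several omics layers (distinct feature counts) measured on the
#' same samples under an ordinal phenotype. Each layer's planted features
#' carry a shared label-aligned sample factor (the standardized label
#' codes) scaled by `effect_size * noise_sd` with a random +/-1 loading per
#' feature; null features are pure Gaussian noise (or the count-like
#' variant).
#'
#' @param spec A [synthetic_spec()]; `layer_sizes`, `n_planted_per_layer`,
#'   `n_samples`, `n_levels`, `effect_size`, `noise_sd`, `seed` and
#'   `distribution` are used.
#' @param labels Optional sample labels of length `n_samples`; defaults to
#'   `n_levels` balanced ordinal levels.
#' @return List with `set` (a [multiomics_set()]), `labels`, and `truth`
#'   (list of per-layer logical planted masks).
#' @export
make_multiomics_set <- function(spec, labels = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  M <- spec$n_samples
  if (is.null(labels))
    labels <- factor(paste0("level", rep(seq_len(spec$n_levels),
                                         length.out = M)),
                     levels = paste0("level", seq_len(spec$n_levels)),
                     ordered = TRUE)
  if (length(labels) != M) stop("`labels` length must equal n_samples")
  codes <- ordinal_codes(labels)
  v <- as.vector(scale(codes))
  layers <- list()
  truth <- list()
  for (k in seq_along(spec$layer_sizes)) {
    Nk <- spec$layer_sizes[k]
    mask <- rep(FALSE, Nk)
    mask[sample.int(Nk, spec$n_planted_per_layer[k])] <- TRUE
    loading <- sample(c(-1, 1), Nk, replace = TRUE)
    X <- outer(as.numeric(mask) * loading * spec$effect_size * spec$noise_sd,
               v) +
      matrix(stats::rnorm(Nk * M, sd = spec$noise_sd), Nk, M)
    if (spec$distribution == "lognormal") X <- exp(X)
    rownames(X) <- paste0("L", k, "_f", seq_len(Nk))
    layers[[k]] <- X
    truth[[k]] <- mask
  }
  names(layers) <- paste0("layer", seq_along(layers))
  names(truth) <- names(layers)
  set <- multiomics_set(layers, sample_ids = paste0("s", seq_len(M)))
  list(set = set, labels = labels, truth = truth)
}
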