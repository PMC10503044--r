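test_that("the Gram tensor matches the brute-force triple loop", {
  set.seed(501)
  layers <- list(matrix(rnorm(50 * 10), 50, 10),
                 matrix(rnorm(30 * 10), 30, 10),
                 matrix(rnorm(20 * 10), 20, 10))
  omics <- multiomics_set(layers)
  for (center in c(TRUE, FALSE)) {
    gram <- build_gram_tensor(omics, center = center)
    expect_lt(max(abs(gram$values - oracle_gram(layers, center))), 1e-12)
  }
})

test_that("Gram slices are symmetric, PSD, and rank-1 for one feature row", {
  v <- c(1, -2, 3, 0.5)
  omics <- multiomics_set(list(matrix(v, 1, 4)))
  gram <- build_gram_tensor(omics, center = FALSE)
  expect_identical(gram$values[, , 1], outer(v, v))
  expect_equal(qr(gram$values[, , 1])$rank, 1)
  set.seed(503)
  omics2 <- multiomics_set(list(matrix(rnorm(80), 20, 4),
                                matrix(rnorm(40), 10, 4)))
  gram2 <- build_gram_tensor(omics2)
  for (k in 1:2) {
    slice <- gram2$values[, , k]
    expect_identical(slice, t(slice))
    expect_gte(min(eigen(slice, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("layers with mismatched sample counts are rejected by name", {
  expect_error(
    multiomics_set(list(a = matrix(0, 5, 4), b = matrix(0, 3, 6))),
    "'b' has 6 samples")
})

test_that("Gram-tensor HOSVD agrees with the symmetric eigen-decomposition (K = 1)", {
  set.seed(507)
  X <- matrix(rnorm(60 * 8), 60, 8)
  omics <- multiomics_set(list(X))
  gram <- build_gram_tensor(omics, center = FALSE)
  model <- hosvd_gram(gram)
  eig <- eigen(gram$values[, , 1], symmetric = TRUE)
  for (j in 1:8)
    expect_lt(min(max(abs(model$factors[[1]][, j] - eig$vectors[, j])),
                  max(abs(model$factors[[1]][, j] + eig$vectors[, j]))),
              1e-8)
  # slice symmetry forces |mode-1| = |mode-2| columns
  for (j in 1:8)
    expect_lt(max(abs(abs(model$factors[[1]][, j]) -
                      abs(model$factors[[2]][, j]))), 1e-8)
})

test_that("all-zero layers decompose to a zero core without failure", {
  omics <- multiomics_set(list(matrix(0, 10, 5), matrix(0, 7, 5)))
  model <- hosvd_gram(build_gram_tensor(omics))
  expect_true(all(model$core == 0))
})

test_that("label-vector choice finds the planted component and honors overrides", {
  sim <- make_multiomics_set(synthetic_spec(seed = 511))
  gram <- build_gram_tensor(sim$set)
  model <- hosvd_gram(gram)
  pick <- choose_label_vector(model, sim$labels)
  # the chosen component must track the ordinal labels almost perfectly
  expect_gte(pick$scores[pick$l1], 0.9)
  expect_equal(pick$l1, which.max(pick$scores))
  ov <- choose_label_vector(model, sim$labels, override = 3)
  expect_equal(ov$l1, 3)
  expect_error(choose_label_vector(model, sim$labels, override = 99), "range")
  # a column exactly equal to the two-class indicator wins with score 1
  U <- diag(6)[, 1:3]
  U[, 2] <- rep(c(1, -1), each = 3) / sqrt(6)
  m2 <- structure(list(core = array(0, c(3, 3, 1)),
                       factors = list(U, U, matrix(1, 1, 1)),
                       ranks = c(3L, 3L, 1L), dims = c(6L, 6L, 1L),
                       mode_sv = list(rep(1, 3), rep(1, 3), 1)),
                  class = "tucker_model")
  pick2 <- choose_label_vector(m2, factor(rep(c("case", "control"), each = 3)))
  expect_equal(pick2$l1, 2)
  expect_equal(pick2$scores[2], 1)
})

test_that("back-projection matches the double-loop oracle and edge cases", {
  set.seed(513)
  layers <- list(matrix(rnorm(40 * 6), 40, 6), matrix(rnorm(3 * 6), 3, 6))
  omics <- multiomics_set(layers)
  u <- rnorm(6)
  proj <- project_features(omics, u, center = FALSE)
  for (k in 1:2)
    expect_lt(max(abs(proj[[k]] - oracle_project(layers[[k]], u))), 1e-12)
  # indicator projection picks out column 1; zero vector gives zero scores
  e1 <- c(1, rep(0, 5))
  expect_equal(project_features(omics, e1, center = FALSE)[[1]],
               layers[[1]][, 1])
  expect_true(all(project_features(omics, rep(0, 6))[[1]] == 0))
  expect_error(project_features(omics, rnorm(5)), "length")
})

test_that("K = 1 Gram route agrees with the direct singular-vector route", {
  set.seed(517)
  sim <- make_multiomics_set(synthetic_spec(
    seed = 517, layer_sizes = 400L, n_planted_per_layer = 40L,
    n_samples = 32L))
  omics <- sim$set
  res <- run_multiomics(omics, sim$labels)
  # direct route: SVD of the centered layer; sample vectors are right
  # singular vectors, feature scores the corresponding left ones
  X <- omics$layers[[1]] - rowMeans(omics$layers[[1]])
  sv <- svd(X)
  lab_cor <- apply(sv$v, 2, function(v)
    abs(cor(v, as.numeric(sim$labels), method = "spearman")))
  l_direct <- which.max(lab_cor)
  direct_scores <- sv$u[, l_direct]
  gram_scores <- res$tables[[1]]$table$score_u[
    order(match(res$tables[[1]]$table$feature_id, omics$feature_ids[[1]]))]
  # proportional up to sign: least-squares constant, then residual check
  cc <- sum(gram_scores * direct_scores) / sum(direct_scores^2)
  expect_lt(max(abs(gram_scores - cc * direct_scores)) / max(abs(gram_scores)),
            1e-8)
  direct_sel <- select_features(direct_scores, omics$feature_ids[[1]])
  expect_identical(sort(selected_ids(res$tables[[1]])),
                   sort(selected_ids(direct_sel)))
})

test_that("run_multiomics recovers planted features in every layer", {
  sim <- make_multiomics_set(synthetic_spec(seed = 519))
  res <- run_multiomics(sim$set, sim$labels)
  for (k in seq_along(sim$set$layers)) {
    truth_ids <- sim$set$feature_ids[[k]][sim$truth[[k]]]
    expect_gte(f1_score(selected_ids(res$tables[[k]]), truth_ids), 0.85)
  }
})

test_that("pure-null layers select almost nothing", {
  sim <- make_multiomics_set(synthetic_spec(seed = 521, effect_size = 0))
  res <- run_multiomics(sim$set, sim$labels)
  for (k in seq_along(res$tables))
    expect_lte(mean(res$tables[[k]]$table$selected), 0.005)
})

test_that("sign flip of the label vector leaves P-values and selection unchanged", {
  sim <- make_multiomics_set(synthetic_spec(seed = 523,
                                            layer_sizes = c(300L, 200L),
                                            n_planted_per_layer = c(30L, 20L)))
  gram <- build_gram_tensor(sim$set)
  model <- hosvd_gram(gram)
  pick <- choose_label_vector(model, sim$labels)
  u <- model$factors[[1]][, pick$l1]
  p_plus <- project_features(sim$set, u)
  p_minus <- project_features(sim$set, -u)
  for (k in 1:2) {
    expect_equal(p_minus[[k]], -p_plus[[k]])
    s1 <- select_features(p_plus[[k]], sim$set$feature_ids[[k]])
    s2 <- select_features(p_minus[[k]], sim$set$feature_ids[[k]])
    expect_equal(s1$table$p_value, s2$table$p_value)
    expect_identical(selected_ids(s1), selected_ids(s2))
  }
})

test_that("the pipeline never materializes a feature-space tensor", {
  # memory contract: the largest intermediate is max(M^2 K, max_k N_k M)
  sim <- make_multiomics_set(synthetic_spec(seed = 527))
  gram <- build_gram_tensor(sim$set)
  M <- length(sim$set$sample_ids)
  K <- length(sim$set$layers)
  expect_identical(dim(gram$values), c(M, M, K))
  expect_lte(length(gram$values),
             max(M^2 * K, max(vapply(sim$set$layers, length, numeric(1)))))
})
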