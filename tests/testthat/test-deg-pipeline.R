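test_that("constancy score separates constant from mean-zero columns", {
  expect_gte(score_constancy(rep(0.5, 9)), 1e10)
  expect_lte(score_constancy(c(1, -1, 1, -1)), 1e-10)
  expect_warning(s0 <- score_constancy(rep(0, 4)), "zero")
  expect_equal(s0, 0)
  set.seed(211)
  v <- rnorm(9, mean = 1, sd = 0.1)
  expect_equal(score_constancy(v), abs(mean(v)) / (sd(v) + 1e-12),
               tolerance = 1e-10)
})

test_that("monotonicity score is the absolute Spearman correlation", {
  res <- score_monotonicity(c(0.1, 0.2, 0.4, 0.9), 1:4)
  expect_equal(res$score, 1)
  expect_equal(res$direction, 1)
  res2 <- score_monotonicity(c(0.9, 0.4, 0.2, 0.1), 1:4)
  expect_equal(res2$score, 1)
  expect_equal(res2$direction, -1)
  # brute-force rank-correlation oracle
  v <- c(0.1, 0.5, 0.3, 0.9)
  expect_equal(score_monotonicity(v, 1:4)$score,
               abs(cor(rank(v), rank(1:4))))
  expect_warning(rc <- score_monotonicity(rep(1, 4), 1:4), "constant")
  expect_equal(rc$score, 0)
  expect_error(score_monotonicity(1:4, rep(1, 4)), "distinct")
  expect_error(score_monotonicity(1:4, 1:3), "length")
})

test_that("sample-vector choice finds planted constant and monotone components", {
  # build a tensor whose mode-2 top component is constant and whose mode-3
  # trend component is known by construction
  set.seed(223)
  sim <- make_deg_tensor(synthetic_spec(n_features = 400, n_planted = 60,
                                        effect_size = 4, seed = 223))
  model <- hosvd(sim$tensor$values)
  picks <- choose_sample_vectors(model, sim$tensor$design)
  expect_equal(picks$l2, which.max(picks$constancy_scores))
  # the chosen mode-3 column must be near-perfectly monotone and have the
  # spread of a genuine trend, not a noise-tilted constant column
  col <- model$factors[[3]][, picks$l3]
  expect_equal(abs(cor(col, 1:4, method = "spearman")), 1)
  expect_gt(max(col) - min(col), 0.5)
  # override passthrough, with scores still reported
  ov <- choose_sample_vectors(model, sim$tensor$design, override = c(2, 2))
  expect_equal(c(ov$l2, ov$l3), c(2, 2))
  expect_length(ov$constancy_scores, ncol(model$factors[[2]]))
  expect_error(choose_sample_vectors(model, sim$tensor$design,
                                     override = c(99, 1)), "range")
})

test_that("single-condition designs are rejected", {
  expect_error(sample_design(1:3, rep("a", 3)), "2 distinct")
})

test_that("feature-vector choice scans the core fiber with first-index ties", {
  core <- array(0, c(6, 3, 3))
  core[4, 2, 3] <- -7
  model <- structure(list(core = core,
                          factors = list(diag(6), diag(3), diag(3)),
                          ranks = c(6L, 3L, 3L), dims = c(6L, 3L, 3L)),
                     class = "tucker_model")
  expect_equal(choose_feature_vector(model, 2, 3), 4)
  # seeded random core against a linear-scan oracle
  set.seed(227)
  model$core <- array(rnorm(54), c(6, 3, 3))
  for (l2 in 1:3) for (l3 in 1:3) {
    fiber <- abs(model$core[, l2, l3])
    expect_equal(choose_feature_vector(model, l2, l3),
                 which(fiber == max(fiber))[1])
  }
  # exact tie broken by the smaller index
  model$core <- array(0, c(6, 3, 3))
  model$core[2, 1, 1] <- 5
  model$core[5, 1, 1] <- -5
  expect_equal(choose_feature_vector(model, 1, 1), 2)
  expect_error(choose_feature_vector(model, 9, 1), "range")
})

test_that("run_deg recovers planted monotone features at the default spec", {
  sim <- make_deg_tensor(synthetic_spec(seed = 301))
  res <- run_deg(sim$tensor)
  truth_ids <- sim$tensor$feature_ids[sim$truth]
  expect_gte(f1_score(selected_ids(res), truth_ids), 0.9)
})

test_that("run_deg on a pure-null tensor selects almost nothing", {
  sim <- make_deg_tensor(synthetic_spec(effect_size = 0, seed = 303))
  res <- run_deg(sim$tensor)
  expect_lte(mean(res$selection$table$selected), 0.005)
})

test_that("run_deg is deterministic and scale-invariant", {
  sim <- make_deg_tensor(synthetic_spec(n_features = 300, n_planted = 30,
                                        seed = 307))
  r1 <- run_deg(sim$tensor)
  r2 <- run_deg(sim$tensor)
  expect_identical(r1$selection$table, r2$selection$table)
  scaled <- omics_tensor(sim$tensor$values * 37.5,
                         feature_ids = sim$tensor$feature_ids,
                         mode2_ids = sim$tensor$mode2_ids,
                         mode3_ids = sim$tensor$mode3_ids,
                         design = sim$tensor$design)
  r3 <- run_deg(scaled)
  expect_identical(selected_ids(r3), selected_ids(r1))
  expect_identical(c(r3$l1, r3$l2, r3$l3), c(r1$l1, r1$l2, r1$l3))
})

test_that("run_deg honors component overrides and preprocessing modes", {
  sim <- make_deg_tensor(synthetic_spec(n_features = 300, n_planted = 30,
                                        seed = 311))
  res <- run_deg(sim$tensor, config = deg_config(l2 = 2, l3 = 2))
  expect_equal(c(res$l2, res$l3), c(2, 2))
  expect_equal(res$l1, which.max(abs(res$model$core[, 2, 2])))
  # feature standardization changes the tensor but the pipeline still runs
  res_std <- run_deg(sim$tensor,
                     config = deg_config(preprocess = "feature_standardize"))
  expect_s3_class(res_std, "deg_result")
  shifted <- omics_tensor(abs(sim$tensor$values),
                          design = sim$tensor$design,
                          mode2_ids = sim$tensor$mode2_ids,
                          mode3_ids = sim$tensor$mode3_ids)
  expect_s3_class(run_deg(shifted, config = deg_config(preprocess = "log1p")),
                  "deg_result")
  neg <- omics_tensor(sim$tensor$values - 100, design = sim$tensor$design)
  expect_error(run_deg(neg, config = deg_config(preprocess = "log1p")),
               "non-negative")
})

test_that("recovery improves with effect size", {
  f1_at <- function(effect, seed) {
    sim <- make_deg_tensor(synthetic_spec(effect_size = effect, seed = seed))
    res <- run_deg(sim$tensor)
    f1_score(selected_ids(res), sim$tensor$feature_ids[sim$truth])
  }
  seeds <- 401:405
  f1s <- vapply(c(1, 2, 3), function(e)
    mean(vapply(seeds, function(s) f1_at(e, s), numeric(1))), numeric(1))
  # clear gain across the detection transition; at saturation the curve
  # plateaus and may wobble by a single selected feature (~0.005 in F1)
  expect_gt(f1s[2], f1s[1])
  expect_gte(f1s[3], f1s[2] - 0.005)
  expect_gte(f1s[3], 0.9)
})
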