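# Feature assembly, splitting, cross-validation, both classifiers,
# evaluation reports.

test_that("the canonical feature inventory is 12 + 7 periodic/aperiodic, x2", {
  cols <- feature_columns()
  expect_length(cols, 38)
  expect_length(grep("^abs_|^rel_", cols, value = TRUE), 24)   # 12 x 2
  expect_length(grep("^(offset|slope_)", cols, value = TRUE), 14)  # 7 x 2
  expect_length(grep("_norm$", cols), 19)
})

test_that("assemble_features builds a complete 38-column table", {
  cfg <- small_cohort_config(seed = 12, per_group = 2, duration = 8)
  gen <- generate_recording(cfg)
  rec <- gen$recording
  spec <- remove_line_noise(welch_psd(rec))
  feats <- assemble_features(band_powers(spec), aperiodic_feature_block(spec),
                             rec$channel_meta)
  expect_true(all(feature_columns() %in% names(feats)))
  expect_equal(sum(names(feats) %in% feature_columns()), 38)
  expect_true(all(feats$complete))
  # normalized features are in [0, 1] wherever the raw feature is
  # nonnegative (narrow-range exponents may dip below zero), and never
  # exceed the per-patient unit maximum
  norm_cols <- grep("_norm$", feature_columns(), value = TRUE)
  M <- as.matrix(feats[, norm_cols])
  expect_true(all(M <= 1 + 1e-12))
  periodic_norm <- grep("^(abs|rel)_.*_norm$", norm_cols, value = TRUE)
  expect_true(all(feats[, periodic_norm] >= 0 & feats[, periodic_norm] <= 1))
  # identical channels produce identical rows
  rec2 <- rec; rec2$samples[2, ] <- rec2$samples[1, ]
  rec2$channel_meta$label[2] <- rec2$channel_meta$label[1]
  rec2$channel_meta$patient_id[2] <- rec2$channel_meta$patient_id[1]
  spec2 <- remove_line_noise(welch_psd(rec2))
  f2 <- assemble_features(band_powers(spec2), aperiodic_feature_block(spec2),
                          rec2$channel_meta)
  expect_equal(unlist(f2[1, feature_columns()]),
               unlist(f2[2, feature_columns()]))
})

test_that("the 70/30 split reproduces the cohort arithmetic", {
  tbl <- data.frame(label = rep(c("tumoral", "close_peritumoral",
                                  "far_peritumoral", "healthy"),
                                c(121, 243, 210, 134)))  # 708 rows
  sp <- split_train_test(tbl, fraction = 0.7, stratified = FALSE, seed = 1)
  expect_equal(nrow(sp$train), 496)
  expect_equal(nrow(sp$test), 212)
  expect_equal(nrow(sp$train) + nrow(sp$test), 708)
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0)
  # small case: 10 rows -> 7/3
  tbl2 <- data.frame(label = rep(c("a", "b"), 5))
  sp2 <- split_train_test(tbl2, 0.7, stratified = TRUE, seed = 2)
  expect_equal(nrow(sp2$train), 7)
  # stratified split preserves class proportions within one row
  sp3 <- split_train_test(tbl, 0.7, stratified = TRUE, seed = 3)
  for (lv in unique(tbl$label)) {
    expect_equal(sum(sp3$train$label == lv), 0.7 * sum(tbl$label == lv),
                 tolerance = 1)
  }
})

test_that("cross-validation is reproducible and saturates on separable data", {
  tbl <- separable_features(n_per_class = 15, seed = 20)
  cv1 <- cross_validate(tbl, "knn_ensemble", k = 5, grid = c(1, 3), seed = 5,
                        n_learners = 5, subspace_dim = 19)
  cv2 <- cross_validate(tbl, "knn_ensemble", k = 5, grid = c(1, 3), seed = 5,
                        n_learners = 5, subspace_dim = 19)
  expect_identical(cv1$folds, cv2$folds)
  expect_true(all(cv1$folds == 1))   # fully separable: F1 = 1 in every fold
  expect_error(stratified_folds(rep(c("a", "b"), c(3, 50)), k = 5, seed = 1),
               "smallest class")
})

test_that("the subspace ensemble reduces to plain kNN and beats chance", {
  tbl <- separable_features(n_per_class = 20, seed = 30)
  sp <- split_train_test(tbl, 0.7, seed = 7)
  xy_tr <- list(x = as.matrix(sp$train[, feature_columns()]),
                y = factor(sp$train$label))
  xy_te <- list(x = as.matrix(sp$test[, feature_columns()]),
                y = factor(sp$test$label))
  # reduction law: 1 learner on the full space == class::knn
  m1 <- train_knn_subspace_ensemble(xy_tr$x, xy_tr$y, n_learners = 1,
                                    subspace_dim = 38, k_neighbors = 1,
                                    seed = 9)
  p1 <- predict(m1, xy_te$x)
  p_ref <- class::knn(xy_tr$x, xy_te$x, xy_tr$y, k = 1)
  expect_equal(as.character(p1), as.character(p_ref))
  # full ensemble: F1 >= 0.95 on wide-margin classes
  m30 <- train_knn_subspace_ensemble(xy_tr$x, xy_tr$y, n_learners = 30,
                                     subspace_dim = 19, k_neighbors = 3,
                                     seed = 9)
  rep30 <- evaluate(xy_te$y, predict(m30, xy_te$x))
  expect_gte(rep30$macro["f1"], 0.95)
  # cubic SVM matches on the same data
  ms <- train_svm(xy_tr$x, xy_tr$y)
  reps <- evaluate(xy_te$y, predict(ms, xy_te$x))
  expect_gte(reps$macro["f1"], 0.95)
  expect_error(train_knn_subspace_ensemble(xy_tr$x, xy_tr$y,
                                           k_neighbors = 1000), "below")
  expect_error(train_svm(xy_tr$x, factor(rep("a", nrow(xy_tr$x)))), "two classes")
})

test_that("evaluation reports match hand arithmetic", {
  # 2x2 confusion TP=3 FP=1 FN=1 TN=5 for the positive class
  truth <- c(rep("pos", 4), rep("neg", 6))
  pred <- c("pos", "pos", "pos", "neg", "pos", rep("neg", 5))
  r <- evaluate(truth, pred)
  pc <- r$per_class[r$per_class$class == "pos", ]
  expect_equal(pc$precision, 0.75)
  expect_equal(pc$recall, 0.75)
  expect_equal(pc$f1, 0.75)
  expect_equal(sum(r$confusion), 10)
  expect_equal(unname(rowSums(r$confusion)), c(6, 4))
  # perfect predictions: all metrics 1
  rp <- evaluate(truth, truth)
  expect_equal(unname(rp$macro), c(1, 1, 1))
  # label collapse rules
  labs <- c("tumoral", "close_peritumoral", "far_peritumoral", "healthy")
  expect_equal(as.character(collapse_labels(labs)),
               c("tumoral", rep("non_tumoral", 3)))
  expect_equal(is.na(collapse_labels(labs, "tumoral_vs_healthy")),
               c(FALSE, TRUE, TRUE, FALSE))
})

test_that("a uniform-random 4-class predictor sits at 25% accuracy", {
  lev <- letters[1:4]
  truth <- rep(lev, each = 25)
  acc <- withr::with_seed(40, mean(vapply(1:2000, function(i)
    mean(sample(lev, 100, replace = TRUE) == truth), numeric(1))))
  expect_equal(acc, 0.25, tolerance = 0.01)
  # permutation-null helper agrees
  pn <- permutation_null_accuracy(truth,
                                  withr::with_seed(41, sample(truth)),
                                  n_perm = 500, seed = 42)
  expect_equal(pn$null_mean, 0.25, tolerance = 0.02)
})
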