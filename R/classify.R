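# Compartment classification: 38-feature assembly, stratified splitting and
# cross-validation, a random-subspace kNN ensemble and a cubic-kernel SVM,
# with confusion-matrix / precision-recall-F1 reporting.

#' Canonical names of the 38 classification features
#'
#' 12 periodic (absolute + relative power over the six canonical bands) and
#' 7 aperiodic (offset + six range-restricted exponents), each in raw and
#' per-patient-normalized (`_norm`) form: 19 x 2 = 38.
#'
#' @return Character vector of length 38.
#' @export
feature_columns <- function() {
  bands <- names(default_bands())
  periodic <- c(paste0("abs_", bands), paste0("rel_", bands))
  aperiodic <- c("offset", paste0("slope_", sub("^r", "",
                                                names(default_fit_ranges()))))
  raw <- c(periodic, aperiodic)
  c(raw, paste0(raw, "_norm"))
}

#' Assemble the 38-feature classification table
#'
#' Merges the band-power block and the aperiodic block by channel, attaches
#' metadata (patient, compartment label), and adds the per-patient
#' normalized copy of every feature. Rows with any missing feature are kept
#' but flagged `complete = FALSE` (they are excluded from training, with a
#' logged count).
#'
#' @param band_power_set Output of [band_powers()].
#' @param aperiodic_block Output of [aperiodic_feature_block()].
#' @param channel_meta Data frame with `channel_id`, `patient_id`, `label`.
#' @param normalization Normalization mode, see [normalize_per_patient()].
#' @return Data frame: `channel_id`, `patient_id`, `label`, `complete`,
#'   then the 38 feature columns in canonical order.
#' @export
assemble_features <- function(band_power_set, aperiodic_block, channel_meta,
                              normalization = "per_feature") {
  tbl <- merge(band_power_set, aperiodic_block, by = "channel_id",
               sort = FALSE)
  tbl <- merge(channel_meta[, intersect(c("channel_id", "patient_id", "label"),
                                        names(channel_meta))],
               tbl, by = "channel_id", sort = FALSE)
  raw_cols <- feature_columns()[1:19]
  missing_cols <- setdiff(raw_cols, names(tbl))
  if (length(missing_cols))
    stop("feature assembly error: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  # The offset is a log10 power and may be negative throughout a patient;
  # normalize it on the power scale (10^offset), which is what "maximum
  # power" refers to, then return to a [0, 1] ratio.
  tbl$.offset_pow <- 10^tbl$offset
  tbl <- normalize_per_patient(tbl, cols = setdiff(raw_cols, "offset"),
                               mode = normalization)
  tbl <- normalize_per_patient(tbl, cols = ".offset_pow", mode = normalization)
  tbl$offset_norm <- tbl$.offset_pow_norm
  tbl$.offset_pow <- NULL; tbl$.offset_pow_norm <- NULL
  cols <- feature_columns()
  if (length(intersect(cols, names(tbl))) != 38L)
    stop("feature assembly error: expected 38 feature columns", call. = FALSE)
  out <- tbl[, c("channel_id", "patient_id", "label", cols)]
  out$complete <- complete.cases(out[, cols])
  n_bad <- sum(!out$complete)
  if (n_bad) message(sprintf("%d channel(s) have missing features and are excluded from training", n_bad))
  out[, c("channel_id", "patient_id", "label", "complete", cols)]
}

#' Random stratified train/test split
#'
#' The training set has exactly `round(fraction * n)` rows. Stratification
#' allocates `fraction` of each class (largest-remainder rounding, so class
#' proportions are preserved within one row) while keeping the exact total.
#'
#' @param tbl Feature table with a `label` column.
#' @param fraction Training fraction in (0, 1).
#' @param stratified Preserve class proportions?
#' @param seed Integer seed.
#' @return List with `train` and `test` data frames (disjoint, exhaustive).
#' @export
split_train_test <- function(tbl, fraction = 0.7, stratified = TRUE,
                             seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  n <- nrow(tbl)
  n_train <- round(fraction * n)
  idx <- with_seed(seed, {
    if (!stratified) {
      sample.int(n, n_train)
    } else {
      y <- factor(tbl$label)
      counts <- table(y)
      alloc <- floor(fraction * counts)
      rem <- fraction * counts - alloc
      short <- n_train - sum(alloc)
      if (short > 0) {
        bump <- order(rem, decreasing = TRUE)[seq_len(short)]
        alloc[bump] <- alloc[bump] + 1
      } else if (short < 0) {
        drop_ <- order(rem)[seq_len(-short)]
        alloc[drop_] <- alloc[drop_] - 1
      }
      unlist(lapply(levels(y), function(lv) {
        i <- which(y == lv)
        sample(i, alloc[[lv]])
      }), use.names = FALSE)
    }
  })
  train <- tbl[sort(idx), , drop = FALSE]
  test <- tbl[setdiff(seq_len(n), idx), , drop = FALSE]
  if (stratified && length(setdiff(unique(test$label), unique(train$label))))
    stop("a class is absent from the training split; use stratified = TRUE or more data",
         call. = FALSE)
  list(train = train, test = test)
}

# Stratified fold assignment, seeded.
stratified_folds <- function(y, k, seed) {
  y <- factor(y)
  if (min(table(y)) < k)
    stop("k exceeds the smallest class count", call. = FALSE)
  with_seed(seed, {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      i <- sample(which(y == lv))
      fold[i] <- rep_len(seq_len(k), length(i))
    }
    fold
  })
}

as_xy <- function(tbl, cols = feature_columns()) {
  keep <- if (!is.null(tbl$complete)) tbl$complete else
    complete.cases(tbl[, cols])
  list(x = as.matrix(tbl[keep, cols, drop = FALSE]),
       y = factor(tbl$label[keep]))
}

#' Train a random-subspace kNN ensemble
#'
#' A committee of `n_learners` k-nearest-neighbor classifiers, each seeing a
#' random subset of `subspace_dim` feature dimensions, combined by majority
#' vote with a deterministic tie-break (lowest class index). With one
#' learner on the full feature space this reduces exactly to plain kNN.
#'
#' @param x Numeric feature matrix (rows = electrodes).
#' @param y Class factor.
#' @param n_learners Number of ensemble members.
#' @param subspace_dim Features per member (default 19, half the feature set).
#' @param k_neighbors Neighborhood size (must be below the training size).
#' @param seed Integer seed for subspace draws.
#' @return Object of class `knn_subspace`.
#' @export
train_knn_subspace_ensemble <- function(x, y, n_learners = 30,
                                        subspace_dim = 19, k_neighbors = 5,
                                        seed = 1L) {
  x <- as.matrix(x); y <- factor(y)
  if (subspace_dim > ncol(x))
    stop("subspace_dim exceeds the number of features", call. = FALSE)
  if (k_neighbors >= nrow(x))
    stop("k_neighbors must be below the training size", call. = FALSE)
  subspaces <- with_seed(seed, lapply(seq_len(n_learners), function(i)
    sort(sample.int(ncol(x), subspace_dim))))
  structure(list(x = x, y = y, subspaces = subspaces,
                 k_neighbors = k_neighbors, seed = seed),
            class = "knn_subspace")
}

#' @export
predict.knn_subspace <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  lev <- levels(object$y)
  votes <- matrix(0L, nrow(newdata), length(lev),
                  dimnames = list(NULL, lev))
  with_seed(object$seed, {
    for (cols in object$subspaces) {
      pr <- class::knn(object$x[, cols, drop = FALSE],
                       newdata[, cols, drop = FALSE],
                       object$y, k = object$k_neighbors)
      for (l in lev) votes[, l] <- votes[, l] + (pr == l)
    }
  })
  # majority vote; ties broken toward the lowest class index
  factor(lev[apply(votes, 1, which.max)], levels = lev)
}

#' Train a cubic-kernel SVM
#'
#' One-vs-one multiclass SVM with a polynomial kernel of degree 3. Features
#' are standardized with means and SDs frozen from the training set only;
#' the fitted transform is applied automatically at prediction, so test-set
#' leakage into the scaling is impossible by construction.
#'
#' @param x Numeric feature matrix.
#' @param y Class factor (at least two classes).
#' @param degree Polynomial degree.
#' @param cost Soft-margin cost.
#' @param coef0 Kernel offset.
#' @return Object of class `ecog_svm`.
#' @export
train_svm <- function(x, y, degree = 3, cost = 1, coef0 = 1) {
  x <- as.matrix(x); y <- factor(y)
  if (nlevels(droplevels(y)) < 2)
    stop("training data must contain at least two classes", call. = FALSE)
  mu <- colMeans(x)
  sg <- apply(x, 2, sd); sg[sg == 0] <- 1
  xs <- scale(x, center = mu, scale = sg)
  fit <- e1071::svm(xs, y, kernel = "polynomial", degree = degree,
                    cost = cost, coef0 = coef0, scale = FALSE)
  structure(list(fit = fit, center = mu, scale = sg), class = "ecog_svm")
}

#' @export
predict.ecog_svm <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), center = object$center,
              scale = object$scale)
  predict(object$fit, xs)
}

#' Stratified k-fold cross-validation for hyperparameter selection
#'
#' Seeded, stratified folds; the hyperparameter with the best mean
#' validation macro-F1 wins.
#'
#' @param tbl Feature table (training split).
#' @param model `"knn_ensemble"` or `"svm"`.
#' @param k Number of folds.
#' @param grid Hyperparameter values: `k_neighbors` candidates for the kNN
#'   ensemble, `cost` candidates for the SVM.
#' @param seed Integer seed.
#' @param ... Fixed arguments passed to the trainer.
#' @return List with `folds` (per-fold, per-candidate macro F1), `best`
#'   (winning hyperparameter) and `mean_f1`.
#' @export
cross_validate <- function(tbl, model = c("knn_ensemble", "svm"), k = 5,
                           grid = NULL, seed = 1L, ...) {
  model <- match.arg(model)
  xy <- as_xy(tbl)
  if (is.null(grid))
    grid <- if (model == "knn_ensemble") seq(1, 19, by = 2) else
      c(0.1, 1, 10)
  fold <- stratified_folds(xy$y, k, seed)
  if (model == "knn_ensemble") {
    # a learner cannot ask for more neighbors than its fold's training rows
    min_train <- min(vapply(seq_len(k), function(f) sum(fold != f),
                            numeric(1)))
    grid <- grid[grid < min_train]
    if (!length(grid)) grid <- 1
  }
  res <- matrix(NA_real_, k, length(grid),
                dimnames = list(NULL, as.character(grid)))
  for (g in seq_along(grid)) {
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- if (model == "knn_ensemble") {
        train_knn_subspace_ensemble(xy$x[tr, , drop = FALSE], xy$y[tr],
                                    k_neighbors = grid[g], seed = seed, ...)
      } else {
        train_svm(xy$x[tr, , drop = FALSE], xy$y[tr], cost = grid[g], ...)
      }
      pr <- predict(m, xy$x[!tr, , drop = FALSE])
      res[f, g] <- evaluate(xy$y[!tr], pr)$macro["f1"]
    }
  }
  mean_f1 <- colMeans(res)
  list(folds = res, best = grid[which.max(mean_f1)], mean_f1 = mean_f1)
}

#' Confusion matrix and precision/recall/F1 report
#'
#' Per-class precision, recall and F1 from the confusion matrix of true
#' against predicted labels, plus their macro averages (robust to class
#' imbalance). Classes absent from the predictions score 0 precision by
#' convention.
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels.
#' @param scheme Optional label for the classification scheme.
#' @return Object of class `evaluation_report`: `confusion` (true x
#'   predicted counts), `per_class`, `macro`, `accuracy`, `scheme`.
#' @export
evaluate <- function(truth, predicted, scheme = NULL) {
  lev <- union(levels(factor(truth)), levels(factor(predicted)))
  truth <- factor(truth, levels = lev)
  predicted <- factor(predicted, levels = lev)
  cm <- table(truth = truth, predicted = predicted)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- rowSums(cm) > 0  # macro over classes present in the truth
  per_class <- data.frame(class = lev, precision = as.numeric(prec),
                          recall = as.numeric(rec), f1 = as.numeric(f1),
                          support = as.numeric(rowSums(cm)),
                          stringsAsFactors = FALSE)
  macro <- c(precision = mean(prec[present]), recall = mean(rec[present]),
             f1 = mean(f1[present]))
  structure(list(confusion = cm, per_class = per_class, macro = macro,
                 accuracy = sum(tp) / sum(cm), scheme = scheme),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  if (!is.null(x$scheme)) cat(sprintf("<evaluation_report> scheme: %s\n", x$scheme))
  print(x$confusion)
  cat(sprintf("accuracy %.3f | macro precision %.3f recall %.3f F1 %.3f\n",
              x$accuracy, x$macro["precision"], x$macro["recall"],
              x$macro["f1"]))
  invisible(x)
}

#' Collapse compartment labels into a two-class scheme
#'
#' `"tumoral_vs_rest"` (default) relabels every non-tumoral compartment as
#' `non_tumoral`; `"tumoral_vs_healthy"` keeps only tumoral and healthy
#' electrodes (dropping peritumoral rows).
#'
#' @param labels Compartment labels.
#' @param scheme Collapse rule.
#' @return Factor (with `NA` for dropped rows under `tumoral_vs_healthy`).
#' @export
collapse_labels <- function(labels, scheme = c("tumoral_vs_rest",
                                               "tumoral_vs_healthy")) {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  if (scheme == "tumoral_vs_rest") {
    factor(ifelse(labels == "tumoral", "tumoral", "non_tumoral"),
           levels = c("tumoral", "non_tumoral"))
  } else {
    factor(ifelse(labels == "tumoral", "tumoral",
                  ifelse(labels == "healthy", "healthy", NA_character_)),
           levels = c("tumoral", "healthy"))
  }
}

#' End-to-end classification run (split, tune, train, evaluate)
#'
#' Collapses labels for the requested scheme, splits 70/30 (stratified),
#' tunes the model hyperparameter by stratified 5-fold cross-validation on
#' the training split, retrains on the full training split and evaluates on
#' the held-out test split.
#'
#' @param features Output of [assemble_features()].
#' @param scheme `"4class"` or `"2class"`.
#' @param model `"knn_ensemble"` or `"svm"`.
#' @param train_fraction Training fraction.
#' @param cv_folds Cross-validation folds.
#' @param seed Integer seed controlling split, folds and subspaces.
#' @param two_class Two-class collapse rule, see [collapse_labels()].
#' @param ... Passed to the trainer.
#' @return List with `report` (an `evaluation_report`), `cv`, `model`,
#'   `n_train`, `n_test`.
#' @export
run_classification <- function(features, scheme = c("4class", "2class"),
                               model = c("knn_ensemble", "svm"),
                               train_fraction = 0.7, cv_folds = 5, seed = 1L,
                               two_class = "tumoral_vs_rest", ...) {
  scheme <- match.arg(scheme)
  model <- match.arg(model)
  tbl <- features[features$complete, , drop = FALSE]
  if (scheme == "2class") {
    tbl$label <- collapse_labels(tbl$label, two_class)
    tbl <- tbl[!is.na(tbl$label), , drop = FALSE]
  }
  sp <- split_train_test(tbl, fraction = train_fraction, stratified = TRUE,
                         seed = seed)
  cv <- cross_validate(sp$train, model = model, k = cv_folds, seed = seed,
                       ...)
  xy_tr <- as_xy(sp$train); xy_te <- as_xy(sp$test)
  fit <- if (model == "knn_ensemble") {
    train_knn_subspace_ensemble(xy_tr$x, xy_tr$y, k_neighbors = cv$best,
                                seed = seed, ...)
  } else {
    train_svm(xy_tr$x, xy_tr$y, cost = cv$best, ...)
  }
  pred <- predict(fit, xy_te$x)
  list(report = evaluate(xy_te$y, pred, scheme = scheme), cv = cv,
       model = fit, n_train = nrow(xy_tr$x), n_test = nrow(xy_te$x))
}

#' Permutation null for classification accuracy
#'
#' Permutes the true test labels against fixed predictions to obtain the
#' null distribution of accuracy, returning its mean, SD, and the z-score
#' of the observed accuracy.
#'
#' @param truth True test labels.
#' @param predicted Model predictions on the same rows.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `observed`, `null_mean`, `null_sd`, `z`.
#' @export
permutation_null_accuracy <- function(truth, predicted, n_perm = 1000,
                                      seed = 1L) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  obs <- mean(truth == predicted)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    mean(sample(truth) == predicted), numeric(1)))
  m <- mean(null); s <- sd(null)
  list(observed = obs, null_mean = m, null_sd = s,
       z = if (s > 0) (obs - m) / s else Inf)
}
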