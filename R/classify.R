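# Classification of ratio feature tables: train/test splitting, the three
# classifier families, confusion-matrix metrics and stratified k-fold
# cross-validation with inner grid search.

# Classifier feature set: ARV is computed and stored but excluded from the
# default model.
.default_features <- c("rms", "iemg", "mdf", "mpf")

#' Classifier specification
#'
#' One of three families: gradient-boosted decision trees (`"gbdt"`, via
#' xgboost), an RBF-kernel support vector machine (`"svm_rbf"`) or
#' k-nearest neighbours (`"knn"`, odd `k` to avoid ties). Hyperparameters
#' are selected from a small grid by inner cross-validated accuracy.
#'
#' @param kind `"gbdt"`, `"svm_rbf"` or `"knn"`.
#' @param grid data.frame of candidate hyperparameters; defaults: gbdt
#'   depth \{2,3,4\} x trees \{100,300\} at learning rate 0.1; svm cost
#'   \{1,10,100\} x gamma \{0.5,1,2\}/p (p = number of features); knn
#'   k \{3,5,7,9\}.
#' @param features feature columns used by the model.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("gbdt", "svm_rbf", "knn"), grid = NULL,
                            features = .default_features) {
  kind <- match.arg(kind)
  if (is.null(grid)) {
    grid <- switch(kind,
      gbdt = expand.grid(max_depth = c(2L, 3L, 4L), nrounds = c(100L, 300L),
                         eta = 0.1),
      svm_rbf = expand.grid(cost = c(1, 10, 100),
                            gamma_mult = c(0.5, 1, 2)),
      knn = data.frame(k = c(3L, 5L, 7L, 9L)))
  }
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    stopf("`grid` must be a non-empty data.frame")
  }
  if (kind == "knn" && any(grid$k %% 2 == 0)) {
    stopf("knn `k` values must be odd (tie avoidance)")
  }
  structure(list(kind = kind, grid = grid, features = features),
            class = "classifier_spec")
}

#' Confusion matrix from prediction/label vectors
#'
#' Positive class is immobilization (label 1), negative is nerve injury
#' (label 0).
#'
#' @param predicted,actual integer vectors of 0/1 labels.
#' @return an object of class `confusion_matrix` with counts `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_matrix <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stopf("predicted and actual must have equal length")
  }
  structure(list(tp = sum(predicted == 1L & actual == 1L),
                 tn = sum(predicted == 0L & actual == 0L),
                 fp = sum(predicted == 1L & actual == 0L),
                 fn = sum(predicted == 0L & actual == 1L)),
            class = "confusion_matrix")
}

#' Accuracy, specificity and sensitivity of a confusion matrix
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `specificity = TN / (TN + FP)`, `sensitivity = TP / (TP + FN)`.
#' A metric with a zero denominator is reported as `NA` (undefined), never
#' as zero.
#'
#' @param cm a [confusion_matrix()] or a list with `tp`, `tn`, `fp`, `fn`.
#' @return list of class `emg_metrics` with `accuracy`, `specificity`,
#'   `sensitivity` (fractions in `[0, 1]`) and `n`.
#' @export
compute_metrics <- function(cm) {
  counts <- c(cm$tp, cm$tn, cm$fp, cm$fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("confusion counts must be non-negative integers")
  }
  total <- sum(counts)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(accuracy = safe_div(cm$tp + cm$tn, total),
                 specificity = safe_div(cm$tn, cm$tn + cm$fp),
                 sensitivity = safe_div(cm$tp, cm$tp + cm$fn),
                 n = total),
            class = "emg_metrics")
}

#' @export
print.emg_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%, specificity %.2f%%, sensitivity %.2f%% (n = %d)\n",
              100 * x$accuracy, 100 * x$specificity, 100 * x$sensitivity,
              x$n))
  invisible(x)
}

#' Random train/test split of a feature table
#'
#' Row-level random split, stratified by label by default so class
#' proportions are preserved on both sides. Because many rows (windows,
#' acquisitions) can come from the same animal or patient, row-level
#' splitting leaks subject identity across the split; `subject_wise = TRUE`
#' instead assigns whole subjects to one side, which is the stricter
#' generalization test.
#'
#' @param table feature data.frame with a `label` column (and a
#'   `subject_id` column when `subject_wise`).
#' @param train_frac fraction of rows (or subjects) in the training set.
#' @param seed seed controlling the split.
#' @param stratified preserve class proportions.
#' @param subject_wise split at the subject level instead of the row level.
#' @return list with `train` and `test` data.frames.
#' @export
split_dataset <- function(table, train_frac = 0.8, seed = NULL,
                          stratified = TRUE, subject_wise = FALSE) {
  if (train_frac <= 0 || train_frac >= 1) {
    stopf("train_frac must be in (0, 1)")
  }
  if (length(unique(table$label)) < 2L) {
    stopf("both classes must be present")
  }
  if (subject_wise) {
    if (is.null(table$subject_id)) {
      stopf("subject-wise splitting needs a `subject_id` column")
    }
    subs <- unique(table[, c("subject_id", "label")])
    train_subs <- with_seed(seed, {
      if (stratified) {
        unlist(lapply(split(subs$subject_id, subs$label), function(ss) {
          sample(ss, max(1L, round(train_frac * length(ss))))
        }), use.names = FALSE)
      } else {
        sample(subs$subject_id, max(1L, round(train_frac * nrow(subs))))
      }
    })
    idx <- which(table$subject_id %in% train_subs)
  } else {
    idx <- with_seed(seed, {
      if (stratified) {
        unlist(lapply(split(seq_len(nrow(table)), table$label), function(ii) {
          sample(ii, round(train_frac * length(ii)))
        }), use.names = FALSE)
      } else {
        sample(seq_len(nrow(table)), round(train_frac * nrow(table)))
      }
    })
    idx <- sort(idx)
  }
  if (length(idx) == 0L || length(idx) == nrow(table)) {
    stopf("split produced an empty train or test set")
  }
  list(train = table[idx, , drop = FALSE],
       test = table[-idx, , drop = FALSE])
}

# Standardize features using training-set statistics only (no leakage).
.standardize <- function(train_x, test_x) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  list(train = sweep(sweep(train_x, 2L, mu), 2L, sdv, "/"),
       test = sweep(sweep(test_x, 2L, mu), 2L, sdv, "/"))
}

#' Fit a classifier on a training table and predict a test table
#'
#' Features are standardized with training-fold statistics only. The fitted
#' model never sees test labels; they are used solely to count the
#' confusion matrix (positive = immobilization).
#'
#' @param spec a [classifier_spec()].
#' @param train,test feature data.frames sharing the same schema.
#' @param params one row of `spec$grid`; defaults to the first row.
#' @param seed seed for classifier randomness (gbdt subsampling etc.).
#' @return a [confusion_matrix()].
#' @export
fit_predict <- function(spec, train, test, params = NULL, seed = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  missing_cols <- setdiff(c(spec$features, "label"), names(test))
  if (length(missing_cols)) {
    stopf("test table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  params <- params %||% spec$grid[1L, , drop = FALSE]
  xs <- .standardize(as.matrix(train[, spec$features, drop = FALSE]),
                     as.matrix(test[, spec$features, drop = FALSE]))
  ytr <- as.integer(train$label)
  pred <- with_seed(seed, switch(spec$kind,
    gbdt = {
      fit <- xgboost::xgboost(
        xs$train, factor(ytr, levels = c(0L, 1L)),
        nrounds = params$nrounds, max_depth = params$max_depth,
        learning_rate = params$eta, objective = "binary:logistic",
        nthreads = 1L, verbosity = 0)
      as.integer(as.numeric(stats::predict(fit, xs$test)) > 0.5)
    },
    svm_rbf = {
      gamma <- params$gamma_mult / length(spec$features)
      fit <- e1071::svm(xs$train, factor(ytr, levels = c(0L, 1L)),
                        kernel = "radial", cost = params$cost,
                        gamma = gamma, scale = FALSE)
      as.integer(as.character(stats::predict(fit, xs$test)))
    },
    knn = {
      as.integer(as.character(
        class::knn(xs$train, xs$test, factor(ytr, levels = c(0L, 1L)),
                   k = params$k)))
    }))
  confusion_matrix(pred, as.integer(test$label))
}

# Stratified fold assignment: returns an integer fold id per row.
.stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    ii <- which(labels == cl)
    if (length(ii) < k) {
      stopf("class %s has fewer rows (%d) than folds (%d)",
            format(cl), length(ii), k)
    }
    folds[ii] <- sample(rep_len(seq_len(k), length(ii)))
  }
  folds
}

#' Stratified k-fold cross-validation with inner grid search
#'
#' Rows are assigned to stratified folds; within each training fold a small
#' inner cross-validation selects the hyperparameter row of `spec$grid`
#' with the best mean accuracy, which is then fitted on the full training
#' fold and evaluated on the held-out fold.
#'
#' @param table feature data.frame with a `label` column.
#' @param k_folds number of outer folds (>= 2).
#' @param spec a [classifier_spec()].
#' @param seed seed controlling fold assignment and classifier randomness.
#' @param inner_folds folds of the inner hyperparameter selection.
#' @return list with `fold_metrics` (data.frame, one row per fold),
#'   `mean` / `sd` (named numeric over the three metrics), `chosen`
#'   (selected grid row per fold) and `confusion` (summed counts).
#' @export
run_cv <- function(table, k_folds = 5, spec = classifier_spec("gbdt"),
                   seed = NULL, inner_folds = 3) {
  if (k_folds < 2) stopf("k_folds must be >= 2")
  folds <- with_seed(seed, .stratified_folds(table$label, k_folds))
  fold_rows <- vector("list", k_folds)
  chosen <- vector("list", k_folds)
  cms <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- table[folds != f, , drop = FALSE]
    te <- table[folds == f, , drop = FALSE]
    if (length(unique(te$label)) < 2L || length(unique(tr$label)) < 2L) {
      stopf("degenerate single-class fold")
    }
    best <- 1L
    if (nrow(spec$grid) > 1L) {
      inner <- with_seed(derive_seed(seed %||% 0L, f, 1L),
                         .stratified_folds(tr$label, inner_folds))
      acc <- vapply(seq_len(nrow(spec$grid)), function(g) {
        accs <- vapply(seq_len(inner_folds), function(j) {
          cm <- fit_predict(spec, tr[inner != j, , drop = FALSE],
                            tr[inner == j, , drop = FALSE],
                            params = spec$grid[g, , drop = FALSE],
                            seed = derive_seed(seed %||% 0L, f, g, j))
          compute_metrics(cm)$accuracy
        }, numeric(1L))
        mean(accs)
      }, numeric(1L))
      best <- which.max(acc)
    }
    cm <- fit_predict(spec, tr, te,
                      params = spec$grid[best, , drop = FALSE],
                      seed = derive_seed(seed %||% 0L, f, 0L))
    m <- compute_metrics(cm)
    fold_rows[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                                 specificity = m$specificity,
                                 sensitivity = m$sensitivity, n = m$n)
    chosen[[f]] <- spec$grid[best, , drop = FALSE]
    cms[[f]] <- cm
  }
  fm <- do.call(rbind, fold_rows)
  metric_cols <- c("accuracy", "specificity", "sensitivity")
  total <- list(tp = sum(vapply(cms, `[[`, numeric(1L), "tp")),
                tn = sum(vapply(cms, `[[`, numeric(1L), "tn")),
                fp = sum(vapply(cms, `[[`, numeric(1L), "fp")),
                fn = sum(vapply(cms, `[[`, numeric(1L), "fn")))
  list(fold_metrics = fm,
       mean = colMeans(fm[, metric_cols]),
       sd = apply(fm[, metric_cols], 2L, stats::sd),
       chosen = chosen,
       confusion = total)
}
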