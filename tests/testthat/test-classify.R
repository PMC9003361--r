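# Classification: splitting, metrics, cross-validation, the three models.

# Separable two-cluster table: classes 3 SDs apart in all four features.
separable_table <- function(n_per_class = 300, sep = 3, seed = 1) {
  set.seed(seed)
  mk <- function(center, label) {
    data.frame(rms = rnorm(n_per_class, center), iemg = rnorm(n_per_class, center),
               mdf = rnorm(n_per_class, center), mpf = rnorm(n_per_class, center),
               label = label)
  }
  rbind(mk(0, 0L), mk(sep, 1L))
}

test_that("train/test splitting is stratified, sized and reproducible", {
  tab <- data.frame(rms = rnorm(1800), iemg = rnorm(1800),
                    mdf = rnorm(1800), mpf = rnorm(1800),
                    label = rep(c(0L, 1L), each = 900))
  sp <- split_dataset(tab, 0.8, seed = 1)
  expect_equal(nrow(sp$train), 1440)
  expect_equal(nrow(sp$test), 360)
  expect_equal(sum(sp$test$label == 1), 180)
  expect_equal(sum(sp$test$label == 0), 180)

  sp2 <- split_dataset(tab, 0.8, seed = 1)
  expect_identical(rownames(sp$train), rownames(sp2$train))

  expect_error(split_dataset(tab, 1.2), "train_frac")
  expect_error(split_dataset(tab[tab$label == 1, ], 0.8), "both classes")

  # subject-wise splitting keeps every subject on one side only
  tab$subject_id <- rep(sprintf("s%02d", 1:20), each = 90)
  sw <- split_dataset(tab, 0.8, seed = 2, subject_wise = TRUE)
  expect_length(intersect(unique(sw$train$subject_id),
                          unique(sw$test$subject_id)), 0)
  expect_equal(nrow(sw$train) + nrow(sw$test), 1800)
  expect_error(split_dataset(tab[, setdiff(names(tab), "subject_id")],
                             0.8, subject_wise = TRUE), "subject_id")
})

test_that("metrics follow the three defining formulas", {
  m <- compute_metrics(list(tp = 9, tn = 8, fp = 1, fn = 2))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$specificity, 8 / 9, tolerance = 1e-12)   # 0.8889
  expect_equal(m$sensitivity, 9 / 11, tolerance = 1e-12)  # 0.8182

  perfect <- compute_metrics(list(tp = 5, tn = 7, fp = 0, fn = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$sensitivity, 1)

  half <- compute_metrics(list(tp = 25, tn = 25, fp = 25, fn = 25))
  expect_equal(half$accuracy, 0.5)
  expect_equal(half$specificity, 0.5)
  expect_equal(half$sensitivity, 0.5)

  undef <- compute_metrics(list(tp = 0, tn = 3, fp = 1, fn = 0))
  expect_true(is.na(undef$sensitivity))
  expect_false(is.na(undef$accuracy))
})

test_that("metrics agree with brute-force counting and the decomposition identity", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    actual <- sample(c(0L, 1L), n, replace = TRUE)
    pred <- sample(c(0L, 1L), n, replace = TRUE)
    cm <- confusion_matrix(pred, actual)
    # brute force over pairs
    tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
    for (j in seq_len(n)) {
      if (pred[j] == 1 && actual[j] == 1) tp <- tp + 1L
      if (pred[j] == 0 && actual[j] == 0) tn <- tn + 1L
      if (pred[j] == 1 && actual[j] == 0) fp <- fp + 1L
      if (pred[j] == 0 && actual[j] == 1) fn <- fn + 1L
    }
    expect_identical(unclass(cm)[c("tp", "tn", "fp", "fn")],
                     list(tp = tp, tn = tn, fp = fp, fn = fn))
    m <- compute_metrics(cm)
    P <- tp + fn; N <- tn + fp
    if (P > 0 && N > 0) {
      expect_equal(m$accuracy,
                   (P * m$sensitivity + N * m$specificity) / (P + N),
                   tolerance = 1e-14)
    }
  }
})

test_that("all three classifier kinds separate well-separated clusters", {
  tab <- separable_table()
  for (kind in c("gbdt", "svm_rbf", "knn")) {
    cv <- run_cv(tab, 5, classifier_spec(kind), seed = 2)
    expect_gte(cv$mean[["accuracy"]], 0.99)
  }
})

test_that("fit_predict is exact on training data and honours knn k = 1", {
  tab <- separable_table()
  for (kind in c("gbdt", "svm_rbf", "knn")) {
    cm <- fit_predict(classifier_spec(kind), tab, tab, seed = 3)
    expect_equal(cm$fp + cm$fn, 0)
  }
  spec1 <- classifier_spec("knn", grid = data.frame(k = 1L))
  test_dup <- tab[c(1, 400), ]
  cm <- fit_predict(spec1, tab, test_dup)
  expect_equal(cm$tn, 1)
  expect_equal(cm$tp, 1)

  bad_test <- tab[1:5, setdiff(names(tab), "mdf")]
  expect_error(fit_predict(classifier_spec("knn"), tab, bad_test), "mdf")
})

test_that("test labels never influence the fitted model or its predictions", {
  tab <- separable_table(n_per_class = 40, sep = 1, seed = 4)
  sp <- split_dataset(tab, 0.8, seed = 5)
  shuffled <- sp$test
  set.seed(6)
  shuffled$label <- sample(shuffled$label)
  for (kind in c("gbdt", "svm_rbf", "knn")) {
    spec <- classifier_spec(kind)
    cm1 <- fit_predict(spec, sp$train, sp$test, seed = 7)
    cm2 <- fit_predict(spec, sp$train, shuffled, seed = 7)
    # identical predictions => identical predicted-positive counts
    expect_equal(cm1$tp + cm1$fp, cm2$tp + cm2$fp)
  }
})

test_that("cross-validation validates its inputs", {
  tab <- separable_table(n_per_class = 6)
  expect_error(run_cv(tab, k_folds = 1), "k_folds")
  expect_error(run_cv(tab, k_folds = 10, spec = classifier_spec("knn")),
               "fewer rows")
  expect_error(classifier_spec("knn", grid = data.frame(k = 4L)), "odd")
  expect_error(classifier_spec("gbdt", grid = data.frame()), "non-empty")
})

test_that("evoked-protocol features classify better than matched voluntary-protocol features", {
  # rat protocol: acquisition-level averaging of evoked responses
  rat <- small_rat_cohort(n_subj = 3, n_acq = 10, seed = 41)
  rat_ft <- rat_feature_table(rat)
  spec <- classifier_spec("knn", grid = data.frame(k = 5L))
  rat_acc <- run_cv(rat_ft, 5, spec, seed = 42)$mean[["accuracy"]]

  # patient protocol at matched sample count, with deliberately smaller
  # effect sizes (milder motor-unit loss and time-scale change)
  soft <- list(
    nerve_injury = condition_params("nerve_injury", mu_count = 14,
                                    tau_scale = 0.9),
    immobilization = condition_params("immobilization", mu_count = 19,
                                      amplitude_scale = 0.85))
  cfg <- cohort_config("patient_mvc",
                       groups = list(immobilization = 1, nerve_injury = 1),
                       record_duration = 30, conditions = soft)
  pat_ft <- patient_feature_table(generate_patient_cohort(cfg, seed = 43))
  set.seed(44)
  pat_ft <- pat_ft[sample(nrow(pat_ft), nrow(rat_ft)), ]
  pat_acc <- run_cv(pat_ft, 5, spec, seed = 42)$mean[["accuracy"]]
  expect_gte(rat_acc, pat_acc)
})
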