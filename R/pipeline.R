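# End-to-end pipeline: simulate -> preprocess -> features -> ratio
# normalization -> classification, with a self-describing report.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and validates them before any
#' computation starts. Every source of randomness (generators, splits, fold
#' assignment, classifier randomness) is derived from the single `seed`.
#'
#' @param cohort a [cohort_config()].
#' @param preprocess a [preprocess_config()].
#' @param windowing a [windowing_config()] or `NULL` for protocol defaults.
#' @param classifiers list of [classifier_spec()] objects.
#' @param folds cross-validation folds.
#' @param train_frac train fraction of the holdout split.
#' @param seed master seed.
#' @param output_dir directory for feature tables and the report, or `NULL`
#'   to skip writing.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config("rat_evoked"),
                            preprocess = preprocess_config(),
                            windowing = NULL,
                            classifiers = list(classifier_spec("gbdt"),
                                               classifier_spec("svm_rbf"),
                                               classifier_spec("knn")),
                            folds = 5, train_frac = 0.8, seed = 1L,
                            output_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(preprocess, "preprocess_config"))
  if (!is.null(windowing)) stopifnot(inherits(windowing, "windowing_config"))
  ok <- vapply(classifiers, inherits, logical(1L), what = "classifier_spec")
  if (length(classifiers) == 0L || !all(ok)) {
    stopf("`classifiers` must be a non-empty list of classifier_spec objects")
  }
  if (folds < 2) stopf("folds must be >= 2")
  if (train_frac <= 0 || train_frac >= 1) stopf("train_frac must be in (0, 1)")
  structure(list(cohort = cohort, preprocess = preprocess,
                 windowing = windowing, classifiers = classifiers,
                 folds = folds, train_frac = train_frac,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

# Deterministic md5 of a configuration (via its canonical JSON form).
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  json <- jsonlite::serializeJSON(config[setdiff(names(config), "output_dir")])
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> feature extraction -> ratio
#' normalization -> classification for the configured protocol and returns
#' a report: sample accounting, per-classifier cross-validation and holdout
#' metrics, and a provenance block (config hash, seed, package version).
#' Identical configuration and seed give an identical report.
#'
#' @param config a [pipeline_config()].
#' @param progress print stage-level progress.
#' @return a list of class `pipeline_report`.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (progress) message(...)
  seed <- config$seed

  say("stage: simulate (", config$cohort$protocol, ")")
  if (config$cohort$protocol == "rat_evoked") {
    cohort <- generate_rat_cohort(config$cohort, seed = seed)
    say("stage: features (", nrow(cohort$labels), " acquisitions)")
    features <- rat_feature_table(cohort, config$preprocess,
                                  progress = progress)
  } else {
    cohort <- generate_patient_cohort(config$cohort, seed = seed)
    say("stage: features (", nrow(cohort$labels), " patients)")
    features <- patient_feature_table(cohort, config$preprocess,
                                      win = config$windowing)
  }

  say("stage: classify (", nrow(features), " feature rows)")
  results <- lapply(config$classifiers, function(spec) {
    cv <- run_cv(features, k_folds = config$folds, spec = spec,
                 seed = derive_seed(seed, 101L))
    split <- split_dataset(features, train_frac = config$train_frac,
                           seed = derive_seed(seed, 102L))
    holdout <- compute_metrics(
      fit_predict(spec, split$train, split$test,
                  params = cv$chosen[[1L]],
                  seed = derive_seed(seed, 103L)))
    list(kind = spec$kind,
         cv_mean = as.list(cv$mean), cv_sd = as.list(cv$sd),
         fold_metrics = cv$fold_metrics,
         holdout = list(accuracy = holdout$accuracy,
                        specificity = holdout$specificity,
                        sensitivity = holdout$sensitivity,
                        n = holdout$n))
  })
  names(results) <- vapply(config$classifiers, `[[`, character(1L), "kind")

  report <- list(
    protocol = config$cohort$protocol,
    n_subjects = nrow(cohort$labels["subject_id"] |> unique()),
    n_samples = nrow(features),
    n_positive = sum(features$label == 1L),
    n_negative = sum(features$label == 0L),
    classifiers = results,
    provenance = list(config_hash = .config_hash(config), seed = seed,
                      package_version =
                        as.character(utils::packageVersion("emgatrophy")))
  )
  class(report) <- "pipeline_report"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      features, file.path(config$output_dir, "features.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    json <- jsonlite::toJSON(.report_json(report), auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    writeLines(json, file.path(config$output_dir, "report.json"))
  }
  report
}

# Flatten the report into plain lists for JSON serialization.
.report_json <- function(report) {
  r <- unclass(report)
  r$classifiers <- lapply(r$classifiers, function(cl) {
    cl$fold_metrics <- lapply(
      split(cl$fold_metrics, seq_len(nrow(cl$fold_metrics))), as.list)
    names(cl$fold_metrics) <- NULL
    cl
  })
  r
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %s: %d samples (%d positive / %d negative)\n",
              x$protocol, x$n_samples, x$n_positive, x$n_negative))
  for (nm in names(x$classifiers)) {
    cl <- x$classifiers[[nm]]
    cat(sprintf("  %-7s cv accuracy %.2f%% +/- %.2f%% | specificity %.2f%% | sensitivity %.2f%%\n",
                nm, 100 * cl$cv_mean$accuracy, 100 * cl$cv_sd$accuracy,
                100 * cl$cv_mean$specificity, 100 * cl$cv_mean$sensitivity))
  }
  cat("  config hash:", x$provenance$config_hash, "\n")
  invisible(x)
}
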