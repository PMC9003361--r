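# Whole-cohort generators reproducing the two study protocols, and the
# streaming feature pipelines that turn them into classifier tables.

#' Generate a rat evoked-stimulation cohort
#'
#' Reproduces the rat protocol: two groups (immobilization and nerve
#' injury, default 6 + 6 subjects) with `acquisitions_per_subject` (default
#' 150) evoked trains each, i.e. 1800 labeled samples at the defaults, plus
#' one pre-surgery healthy baseline train per subject used as the ratio
#' reference. The label convention is positive = immobilization (1),
#' negative = nerve injury (0).
#'
#' Records are not materialized up front (a full cohort is ~2 h of signal);
#' they are regenerated deterministically on demand by
#' [simulate_acquisition()] and [simulate_baseline()] from per-acquisition
#' sub-seeds. Subject-level severity factors (log-normal, 10% on amplitude,
#' 5% on duration) and per-acquisition gain (log-normal, 15%) emulate
#' electrode repositioning and between-animal variability.
#'
#' @param config a [cohort_config()] with `protocol = "rat_evoked"`.
#' @param seed master seed; defaults to `config$seed`.
#' @return an object of class `rat_cohort` with elements `labels`
#'   (data.frame: `subject_id`, `group`, `acquisition_id`, `label`),
#'   `subjects`, `config`, `seed`.
#' @export
generate_rat_cohort <- function(config = cohort_config("rat_evoked"),
                                seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$protocol != "rat_evoked") {
    stopf("config$protocol must be \"rat_evoked\"")
  }
  groups <- config$groups
  subjects <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(subject_id = sprintf("%s_%d", g, seq_len(groups[[g]])),
               group = g)
  }))
  subjects$subject_idx <- seq_len(nrow(subjects))
  fac <- t(vapply(subjects$subject_idx, function(i) {
    with_seed(derive_seed(seed, i, 0L),
              c(amp = exp(stats::rnorm(1, 0, 0.10)),
                dur = exp(stats::rnorm(1, 0, 0.05))))
  }, numeric(2L)))
  subjects$amp_factor <- fac[, "amp"]
  subjects$dur_factor <- fac[, "dur"]

  labels <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    data.frame(subject_id = subjects$subject_id[i],
               group = subjects$group[i],
               acquisition_id = seq_len(config$acquisitions_per_subject),
               label = as.integer(subjects$group[i] == "immobilization"))
  }))
  rownames(labels) <- NULL
  structure(list(labels = labels, subjects = subjects, config = config,
                 seed = as.integer(seed)),
            class = c("rat_cohort", "emg_cohort"))
}

#' Regenerate one evoked acquisition of a rat cohort
#'
#' @param cohort a [generate_rat_cohort()] object.
#' @param subject_id subject identifier from `cohort$labels`.
#' @param acquisition_id acquisition number (1-based).
#' @return as [simulate_evoked_train()]: list with `record` and `truth`.
#' @export
simulate_acquisition <- function(cohort, subject_id, acquisition_id) {
  stopifnot(inherits(cohort, "rat_cohort"))
  s <- cohort$subjects[cohort$subjects$subject_id == subject_id, ]
  if (nrow(s) != 1L) stopf("unknown subject_id `%s`", subject_id)
  aseed <- derive_seed(cohort$seed, s$subject_idx, acquisition_id)
  gain <- with_seed(derive_seed(cohort$seed, s$subject_idx,
                                acquisition_id, 7L),
                    exp(stats::rnorm(1, 0, 0.15)))
  base <- cohort_condition(cohort$config, s$group)
  cond <- condition_params(
    s$group,
    mu_count = base$mu_count,
    amplitude_scale = base$amplitude_scale * s$amp_factor * gain,
    tau_scale = base$tau_scale * s$dur_factor,
    latency_scale = base$latency_scale,
    firing_rate = base$firing_rate,
    noise_sd = base$noise_sd, powerline_amp = base$powerline_amp)
  out <- simulate_evoked_train(cond, cohort$config$stim,
                               fs = cohort$config$sampling_rate, seed = aseed)
  out$record$meta$subject_id <- subject_id
  out$record$meta$label <- as.integer(s$group == "immobilization")
  out
}

#' Regenerate the pre-surgery healthy baseline train of a rat
#'
#' A short healthy train (`config$baseline_epochs` stimuli, default 10)
#' recorded before surgery; its averaged features are the denominator of
#' the affected-versus-baseline ratios.
#'
#' @inheritParams simulate_acquisition
#' @return as [simulate_evoked_train()].
#' @export
simulate_baseline <- function(cohort, subject_id) {
  stopifnot(inherits(cohort, "rat_cohort"))
  s <- cohort$subjects[cohort$subjects$subject_id == subject_id, ]
  if (nrow(s) != 1L) stopf("unknown subject_id `%s`", subject_id)
  stim <- cohort$config$stim
  stim$train_duration <- cohort$config$baseline_epochs / stim$rate
  cond <- cohort_condition(cohort$config, "healthy")
  out <- simulate_evoked_train(cond, stim,
                               fs = cohort$config$sampling_rate,
                               seed = derive_seed(cohort$seed, s$subject_idx,
                                                  0L, 1L))
  out$record$meta$subject_id <- subject_id
  out
}

# Acquisition-level feature vector for an evoked train: preprocess, locate
# the stimulus artifacts, keep a post-blanking response window after each
# stimulus, concatenate those windows and compute the five features on the
# concatenation. Blanking excludes the artifact (and its filter ringing),
# which carries no condition information and would otherwise dominate the
# amplitude features identically in every group.
.evoked_feature_row <- function(record, stim, prep, blank_ms = 3,
                                response_ms = 50, band = c(20, 500)) {
  rec <- preprocess_record(record, prep)
  x <- rec$signals[, 1L]
  idx <- detect_stimuli(x, rec$fs, stim)
  b0 <- round(blank_ms / 1000 * rec$fs)
  b1 <- round(response_ms / 1000 * rec$fs)
  segs <- lapply(idx, function(i0) {
    j <- (i0 + b0):(i0 + b1)
    x[j[j <= length(x)]]
  })
  xx <- unlist(segs, use.names = FALSE)
  td <- time_domain_features(xx, rec$fs)
  sf <- spectral_features(xx, rec$fs, band = band)
  data.frame(rms = td$rms, iemg = td$iemg, arv = td$arv,
             mdf = sf$mdf, mpf = sf$mpf)
}

#' Feature table for a rat cohort
#'
#' Streams through every acquisition: simulate, preprocess, compute the
#' features (RMS, iEMG, ARV, MDF, MPF) over the concatenated post-stimulus
#' response windows, and divide by the mean features of the subject's
#' pre-surgery healthy baseline. One row per acquisition, 1800 rows at the
#' default configuration.
#'
#' @param cohort a [generate_rat_cohort()] object.
#' @param prep a [preprocess_config()].
#' @param progress print a line per subject.
#' @return data.frame: `subject_id`, `acquisition_id`, ratio features,
#'   `label`, `normalized = TRUE`.
#' @export
rat_feature_table <- function(cohort, prep = preprocess_config(),
                              progress = FALSE) {
  stopifnot(inherits(cohort, "rat_cohort"))
  stim <- cohort$config$stim
  out <- vector("list", nrow(cohort$labels))
  pos <- 0L
  for (sid in cohort$subjects$subject_id) {
    if (progress) message("subject ", sid)
    ref <- .evoked_feature_row(simulate_baseline(cohort, sid)$record,
                               stim, prep)
    acq_ids <- cohort$labels$acquisition_id[cohort$labels$subject_id == sid]
    lab <- cohort$labels$label[cohort$labels$subject_id == sid][1L]
    for (aid in acq_ids) {
      row <- .evoked_feature_row(
        simulate_acquisition(cohort, sid, aid)$record, stim, prep)
      pos <- pos + 1L
      out[[pos]] <- cbind(
        data.frame(subject_id = sid, acquisition_id = aid),
        row / as.numeric(ref[1L, ]),
        data.frame(label = lab, normalized = TRUE))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a patient maximum-voluntary-contraction cohort
#'
#' Reproduces the clinical protocol: each patient is recorded on four
#' channels (tibialis anterior and gastrocnemius of the affected and
#' unaffected limb) during a 60 s maximum voluntary contraction. Affected
#' channels use the patient's condition parameters, unaffected channels the
#' healthy parameters. The default template is 7 immobilization and 3
#' nerve-injury patients.
#'
#' @param config a [cohort_config()] with `protocol = "patient_mvc"`.
#' @param seed master seed; defaults to `config$seed`.
#' @return an object of class `patient_cohort`: `labels` (one row per
#'   patient), `records` (list of 4-channel [signal_record()]s), `config`,
#'   `seed`.
#' @export
generate_patient_cohort <- function(config = cohort_config("patient_mvc"),
                                    seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$protocol != "patient_mvc") {
    stopf("config$protocol must be \"patient_mvc\"")
  }
  if (length(config$channels) != 4L) {
    stopf("patient protocol requires exactly 4 channels")
  }
  groups <- config$groups
  labels <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(subject_id = sprintf("patient_%s_%d", g, seq_len(groups[[g]])),
               group = g,
               label = as.integer(g == "immobilization"))
  }))
  labels$subject_idx <- seq_len(nrow(labels))
  rownames(labels) <- NULL

  healthy <- cohort_condition(config, "healthy")
  records <- lapply(labels$subject_idx, function(i) {
    g <- labels$group[i]
    sev <- with_seed(derive_seed(seed, i, 0L, 2L),
                     c(amp = exp(stats::rnorm(1, 0, 0.10)),
                       tau = exp(stats::rnorm(1, 0, 0.05))))
    base <- cohort_condition(config, g)
    cond <- condition_params(
      g, mu_count = base$mu_count,
      amplitude_scale = base$amplitude_scale * sev[["amp"]],
      tau_scale = base$tau_scale * sev[["tau"]],
      latency_scale = base$latency_scale, firing_rate = base$firing_rate,
      noise_sd = base$noise_sd, powerline_amp = base$powerline_amp)
    chans <- vapply(seq_along(config$channels), function(j) {
      role <- config$channels[j]
      cnd <- if (startsWith(role, "unaffected")) healthy else cond
      with_seed(derive_seed(seed, i, j),
                .voluntary_channel(cnd, config$record_duration,
                                   config$sampling_rate))
    }, numeric(round(config$record_duration * config$sampling_rate)))
    colnames(chans) <- config$channels
    signal_record(chans, fs = config$sampling_rate,
                  meta = list(subject_id = labels$subject_id[i],
                              condition = g,
                              label = labels$label[i],
                              protocol = "patient_mvc"))
  })
  structure(list(labels = labels[, c("subject_id", "group", "label")],
                 records = records, config = config, seed = as.integer(seed)),
            class = c("patient_cohort", "emg_cohort"))
}

#' Feature table for a patient cohort
#'
#' Preprocesses each patient record, extracts per-window features on all
#' four channels over the stable segment (default the middle 30 s of the
#' 60 s move), and normalizes each affected channel by the contralateral
#' channel of the same muscle. One row per affected channel and window.
#'
#' @param cohort a [generate_patient_cohort()] object.
#' @param prep a [preprocess_config()].
#' @param win a [windowing_config()]; by default the stable segment is the
#'   middle 30 s of the record.
#' @return ratio-normalized feature data.frame with `label` per row.
#' @export
patient_feature_table <- function(cohort, prep = preprocess_config(),
                                  win = NULL) {
  stopifnot(inherits(cohort, "patient_cohort"))
  if (is.null(win)) {
    d <- cohort$config$record_duration
    win <- windowing_config(stable_segment = c(d / 4, 3 * d / 4))
  }
  pairing <- c(affected_ta = "unaffected_ta", affected_ga = "unaffected_ga")
  out <- lapply(seq_along(cohort$records), function(i) {
    rec <- preprocess_record(cohort$records[[i]], prep)
    tab <- build_feature_table(rec, win)
    aff <- tab[startsWith(tab$channel_role, "affected"), , drop = FALSE]
    ref <- tab[startsWith(tab$channel_role, "unaffected"), , drop = FALSE]
    ratio_normalize(aff, ref, pairing = pairing)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
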