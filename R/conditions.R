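# Condition, stimulation and cohort configuration objects.

.condition_labels <- c("healthy", "nerve_injury", "immobilization")

# Default generative parameters per condition. Effect sizes are calibrated so
# that evoked trains reproduce the clinical ordering (nerve injury: smaller
# amplitude, shorter duration, smaller AUC, longer latency than
# immobilization) while voluntary sEMG feature distributions of the two
# atrophy groups overlap yet remain separable.
.condition_defaults <- list(
  healthy = list(mu_count = 20L, amplitude_scale = 1.0, tau_scale = 1.0,
                 latency_scale = 1.0, firing_rate = 20, noise_sd = 0.02,
                 powerline_amp = 0.05),
  nerve_injury = list(mu_count = 8L, amplitude_scale = 1.0, tau_scale = 0.7,
                      latency_scale = 1.4, firing_rate = 20, noise_sd = 0.02,
                      powerline_amp = 0.05),
  immobilization = list(mu_count = 18L, amplitude_scale = 0.7, tau_scale = 1.0,
                        latency_scale = 1.0, firing_rate = 20, noise_sd = 0.02,
                        powerline_amp = 0.05)
)

#' Generative parameters for one condition
#'
#' Describes how a condition (healthy, nerve injury, or limb immobilization)
#' shapes simulated EMG. `mu_count` is the number of active motor units;
#' nerve injury loses motor units (default 8 of a healthy 20) and conducts
#' more slowly (`latency_scale` 1.4, `tau_scale` 0.7, i.e. briefer compound
#' responses), while immobilization mainly weakens per-unit amplitude
#' (`amplitude_scale` 0.7) with a mild unit loss (18 of 20).
#'
#' @param label one of `"healthy"`, `"nerve_injury"`, `"immobilization"`.
#' @param mu_count integer >= 1, active motor units.
#' @param amplitude_scale multiplicative amplitude factor (> 0).
#' @param tau_scale multiplicative MUAP time-scale factor (> 0); also scales
#'   evoked response duration.
#' @param latency_scale multiplicative factor on evoked response latency (> 0).
#' @param firing_rate mean motor-unit firing rate in Hz (voluntary mode).
#' @param noise_sd baseline Gaussian noise SD in mV (>= 0).
#' @param powerline_amp 50 Hz interference amplitude in mV (>= 0).
#' @return an object of class `condition_params`.
#' @export
condition_params <- function(label = c("healthy", "nerve_injury",
                                       "immobilization"),
                             mu_count = NULL, amplitude_scale = NULL,
                             tau_scale = NULL, latency_scale = NULL,
                             firing_rate = NULL, noise_sd = NULL,
                             powerline_amp = NULL) {
  label <- match.arg(label)
  def <- .condition_defaults[[label]]
  p <- list(label = label,
            mu_count = if (is.null(mu_count)) def$mu_count else mu_count,
            amplitude_scale = amplitude_scale %||% def$amplitude_scale,
            tau_scale = tau_scale %||% def$tau_scale,
            latency_scale = latency_scale %||% def$latency_scale,
            firing_rate = firing_rate %||% def$firing_rate,
            noise_sd = noise_sd %||% def$noise_sd,
            powerline_amp = powerline_amp %||% def$powerline_amp)
  if (!is.numeric(p$mu_count) || length(p$mu_count) != 1L ||
      p$mu_count < 1 || p$mu_count != round(p$mu_count)) {
    stopf("`mu_count` must be an integer >= 1 (got %s)", format(p$mu_count))
  }
  p$mu_count <- as.integer(p$mu_count)
  check_positive(p$amplitude_scale, "amplitude_scale")
  check_positive(p$tau_scale, "tau_scale")
  check_positive(p$latency_scale, "latency_scale")
  check_positive(p$firing_rate, "firing_rate")
  check_number(p$noise_sd, "noise_sd", lower = 0)
  check_number(p$powerline_amp, "powerline_amp", lower = 0)
  structure(p, class = "condition_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Electrical stimulation protocol
#'
#' Bipolar square-wave stimulation delivered to the sciatic nerve: 2 mA
#' amplitude (metadata only), 2 Hz, 100 microsecond pulse width, 30 s train,
#' producing `rate * train_duration` stimuli. The recorded stimulus artifact
#' is modeled as a 1 ms biphasic spike of fixed large amplitude (default
#' 50 mV, about 10x the healthy response peak) so that artifact detection is
#' realistic but unambiguous.
#'
#' @param rate stimulation frequency in Hz.
#' @param train_duration train length in seconds.
#' @param pulse_width stimulus pulse width in seconds (metadata only).
#' @param pulse_amplitude stimulus current in mA (metadata only).
#' @param artifact_amplitude recorded artifact amplitude in mV.
#' @param artifact_width recorded artifact width in seconds; must be shorter
#'   than the inter-stimulus interval.
#' @return an object of class `stimulus_config`.
#' @export
stimulus_config <- function(rate = 2, train_duration = 30,
                            pulse_width = 100e-6, pulse_amplitude = 2,
                            artifact_amplitude = 50, artifact_width = 0.001) {
  check_positive(rate, "rate")
  check_positive(train_duration, "train_duration")
  check_positive(pulse_width, "pulse_width")
  check_positive(artifact_amplitude, "artifact_amplitude")
  check_positive(artifact_width, "artifact_width")
  if (rate * train_duration < 1) {
    stopf("rate * train_duration must yield at least one stimulus")
  }
  if (artifact_width >= 1 / rate) {
    stopf("artifact_width (%g s) must be shorter than the inter-stimulus interval (%g s)",
          artifact_width, 1 / rate)
  }
  structure(list(rate = rate, train_duration = train_duration,
                 pulse_width = pulse_width, pulse_amplitude = pulse_amplitude,
                 artifact_amplitude = artifact_amplitude,
                 artifact_width = artifact_width),
            class = "stimulus_config")
}

#' Cohort-level study configuration
#'
#' Describes a whole simulated study. The rat protocol (`"rat_evoked"`)
#' defaults to two groups of 6 subjects with 150 evoked acquisitions each
#' (1800 labeled samples) plus a pre-surgery healthy baseline per subject;
#' the patient protocol (`"patient_mvc"`) defaults to 7 immobilization and 3
#' nerve-injury patients, each recorded on 4 channels (affected/unaffected
#' by tibialis anterior/gastrocnemius) during a 60 s maximum voluntary
#' contraction.
#'
#' @param protocol `"rat_evoked"` or `"patient_mvc"`.
#' @param groups named list mapping condition label to number of subjects;
#'   only `nerve_injury` and `immobilization` are allowed.
#' @param acquisitions_per_subject acquisitions per subject (rat protocol).
#' @param channels character vector of channel roles.
#' @param record_duration record length in seconds (patient protocol; the rat
#'   protocol record length is `stim$train_duration`).
#' @param sampling_rate sampling rate in Hz.
#' @param stim a [stimulus_config()] (rat protocol).
#' @param conditions optional named list of [condition_params()] overriding
#'   the per-label defaults.
#' @param baseline_epochs healthy pre-surgery baseline epochs per rat.
#' @param seed default master seed for generators.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(protocol = c("rat_evoked", "patient_mvc"),
                          groups = NULL, acquisitions_per_subject = NULL,
                          channels = NULL, record_duration = NULL,
                          sampling_rate = 2000, stim = stimulus_config(),
                          conditions = list(), baseline_epochs = 10L,
                          seed = 1L) {
  protocol <- match.arg(protocol)
  if (protocol == "rat_evoked") {
    groups <- groups %||% list(immobilization = 6L, nerve_injury = 6L)
    acquisitions_per_subject <- acquisitions_per_subject %||% 150L
    channels <- channels %||% "ta"
    record_duration <- record_duration %||% stim$train_duration
  } else {
    groups <- groups %||% list(immobilization = 7L, nerve_injury = 3L)
    acquisitions_per_subject <- acquisitions_per_subject %||% 1L
    channels <- channels %||% c("affected_ta", "affected_ga",
                                "unaffected_ta", "unaffected_ga")
    record_duration <- record_duration %||% 60
  }
  bad <- setdiff(names(groups), c("nerve_injury", "immobilization"))
  if (length(bad)) {
    stopf("unsupported group label(s): %s", paste(bad, collapse = ", "))
  }
  if (length(groups) == 0L || any(unlist(groups) < 1)) {
    stopf("each group must contain at least one subject")
  }
  if (protocol == "patient_mvc" && length(channels) != 4L) {
    stopf("patient protocol requires exactly 4 channels, got %d",
          length(channels))
  }
  check_positive(record_duration, "record_duration")
  check_positive(sampling_rate, "sampling_rate")
  if (length(conditions)) {
    ok <- vapply(conditions, inherits, logical(1L), what = "condition_params")
    if (!all(ok)) stopf("`conditions` must contain condition_params objects")
  }
  structure(list(protocol = protocol, groups = groups,
                 acquisitions_per_subject = as.integer(acquisitions_per_subject),
                 channels = channels, record_duration = record_duration,
                 sampling_rate = sampling_rate, stim = stim,
                 conditions = conditions,
                 baseline_epochs = as.integer(baseline_epochs),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Resolve the condition_params for a label, honouring cohort overrides.
cohort_condition <- function(config, label) {
  config$conditions[[label]] %||% condition_params(label)
}
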