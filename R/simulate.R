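# Synthetic EMG generators: voluntary-contraction sEMG and stimulus-evoked
# compound muscle action potential (CMAP) trains with per-epoch ground truth.

# Nominal healthy evoked-response geometry. Condition scales multiply these:
# latency (ms) by latency_scale, duration (ms) by tau_scale, and peak-to-peak
# amplitude is mu_count * amplitude_scale * muap_p2p (mV).
.evoked_base <- list(latency_ms = 5, duration_ms = 10, muap_p2p = 0.5)

# Default per-epoch multiplicative log-normal jitter SDs.
.evoked_jitter <- list(latency = 0.05, amplitude = 0.10, duration = 0.05)

# Stereotyped compound response template: one full sine cycle over the
# response support, peak-to-peak `amplitude`. Fast onset rise (5% of peak
# within 0.8% of the duration) keeps threshold-based onset detection sharp.
# Its rectified integral is amplitude * duration / pi (mV*ms with ms inputs).
.cmap_template <- function(t, onset_s, amplitude_mv, duration_s) {
  u <- (t - onset_s) / duration_s
  out <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  out[inside] <- (amplitude_mv / 2) * sin(2 * pi * u[inside])
  out
}

# Biphasic stimulus artifact over artifact_width seconds: a decaying half
# cosine, +A exactly at the stimulus sample followed by a smaller negative
# lobe. The strict maximum at the stimulus sample keeps artifact detection
# aligned to the stimulus at any sampling rate (a full sine cycle would
# sample to zero at 2 kHz, and a symmetric biphase has an ambiguous peak).
.artifact_template <- function(t, at_s, amplitude_mv, width_s) {
  u <- (t - at_s) / width_s
  out <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  out[inside] <- amplitude_mv * cos(pi * u[inside]) * (1 - 0.5 * u[inside])
  out
}

#' Simulate a single stimulus-evoked epoch
#'
#' Synthesizes one epoch starting at the stimulus: a narrow biphasic artifact
#' at time zero, a compound muscle response beginning at `latency_ms`, and
#' optional additive Gaussian noise. The noiseless response parameters are
#' returned as ground truth: the rectified area is
#' `amplitude_mv * duration_ms / pi`.
#'
#' @param fs sampling rate in Hz.
#' @param latency_ms stimulus-to-onset latency in ms.
#' @param amplitude_mv response peak-to-peak amplitude in mV.
#' @param duration_ms response duration in ms.
#' @param noise_sd additive Gaussian noise SD in mV.
#' @param artifact_amplitude,artifact_width artifact peak (mV) and width (s).
#' @param epoch_s epoch length in seconds.
#' @param seed optional seed for the noise.
#' @return list with `signal` (numeric vector) and `truth` (one-row
#'   data.frame: `latency_ms`, `amplitude_mv`, `duration_ms`, `auc_mvms`).
#' @export
simulate_evoked_epoch <- function(fs, latency_ms, amplitude_mv, duration_ms,
                                  noise_sd = 0, artifact_amplitude = 50,
                                  artifact_width = 0.001, epoch_s = 0.1,
                                  seed = NULL) {
  check_positive(fs, "fs")
  check_positive(latency_ms, "latency_ms")
  check_number(amplitude_mv, "amplitude_mv", lower = 0)
  check_positive(duration_ms, "duration_ms")
  if (artifact_width * 1000 >= latency_ms) {
    stopf("artifact_width (%g ms) must be shorter than the response latency (%g ms)",
          artifact_width * 1000, latency_ms)
  }
  n <- round(epoch_s * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- .artifact_template(t, 0, artifact_amplitude, artifact_width) +
    .cmap_template(t, latency_ms / 1000, amplitude_mv, duration_ms / 1000)
  if (noise_sd > 0) {
    x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  truth <- data.frame(latency_ms = latency_ms, amplitude_mv = amplitude_mv,
                      duration_ms = duration_ms,
                      auc_mvms = amplitude_mv * duration_ms / pi)
  list(signal = x, truth = truth)
}

#' Simulate a stimulus-evoked EMG train with ground truth
#'
#' Generates a full stimulation train: one artifact at each stimulus time
#' `k / rate` followed, after the epoch's true latency, by a compound
#' response whose peak-to-peak amplitude is
#' `mu_count * amplitude_scale * 0.5` mV (synchronized motor-unit recruitment),
#' duration `10 * tau_scale` ms and latency `5 * latency_scale` ms, each with
#' log-normal per-epoch jitter. At the condition defaults nerve injury has
#' larger latency and smaller amplitude, duration and AUC than
#' immobilization.
#'
#' @param cond a [condition_params()].
#' @param stim a [stimulus_config()].
#' @param fs sampling rate in Hz.
#' @param seed seed controlling jitter and noise.
#' @param jitter named list of log-normal SDs (`latency`, `amplitude`,
#'   `duration`); set to zeros for noiseless ground-truth checks.
#' @return list with `record` (a [signal_record()]) and `truth` (data.frame,
#'   one row per epoch with `epoch`, `stim_time_s` and the true parameters).
#' @export
simulate_evoked_train <- function(cond, stim = stimulus_config(), fs = 2000,
                                  seed = NULL,
                                  jitter = .evoked_jitter) {
  stopifnot(inherits(cond, "condition_params"),
            inherits(stim, "stimulus_config"))
  check_positive(fs, "fs")
  lat0 <- .evoked_base$latency_ms * cond$latency_scale
  if (stim$artifact_width * 1000 >= lat0) {
    stopf("artifact_width (%g ms) would overlap the response onset (latency %g ms)",
          stim$artifact_width * 1000, lat0)
  }
  n_stim <- round(stim$rate * stim$train_duration)
  n <- round(stim$train_duration * fs)
  t <- (seq_len(n) - 1L) / fs
  amp0 <- cond$mu_count * cond$amplitude_scale * .evoked_base$muap_p2p
  dur0 <- .evoked_base$duration_ms * cond$tau_scale

  with_seed(seed, {
    lat <- lat0 * exp(stats::rnorm(n_stim, 0, jitter$latency))
    amp <- amp0 * exp(stats::rnorm(n_stim, 0, jitter$amplitude))
    dur <- dur0 * exp(stats::rnorm(n_stim, 0, jitter$duration))
    x <- numeric(n)
    stim_times <- (seq_len(n_stim) - 1L) / stim$rate
    for (k in seq_len(n_stim)) {
      i0 <- round(stim_times[k] * fs) + 1L
      i1 <- min(n, i0 + round(0.2 * fs))
      idx <- i0:i1
      x[idx] <- x[idx] +
        .artifact_template(t[idx], stim_times[k], stim$artifact_amplitude,
                           stim$artifact_width) +
        .cmap_template(t[idx], stim_times[k] + lat[k] / 1000, amp[k],
                       dur[k] / 1000)
    }
    if (cond$noise_sd > 0) x <- x + stats::rnorm(n, 0, cond$noise_sd)
    if (cond$powerline_amp > 0) {
      x <- x + cond$powerline_amp * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
    }
    truth <- data.frame(epoch = seq_len(n_stim), stim_time_s = stim_times,
                        latency_ms = lat, amplitude_mv = amp,
                        duration_ms = dur, auc_mvms = amp * dur / pi)
    record <- signal_record(x, fs = fs, roles = "ta",
                            meta = list(condition = cond$label, seed = seed,
                                        protocol = "rat_evoked",
                                        stim_rate = stim$rate,
                                        train_duration = stim$train_duration))
    list(record = record, truth = truth)
  })
}

# One voluntary-contraction sEMG channel as a numeric vector: mu_count
# renewal-process spike trains (mean rate firing_rate, 20 ms refractory
# floor) convolved with per-unit MUAPs (tau jittered +/-20%, amplitude
# +/-30%), plus Gaussian noise and 50 Hz powerline interference.
.voluntary_channel <- function(cond, duration, fs) {
  n <- round(duration * fs)
  refractory <- 0.02
  if (cond$firing_rate >= 1 / refractory) {
    stopf("firing_rate must be below %g Hz (20 ms refractory floor)",
          1 / refractory)
  }
  exp_mean <- 1 / cond$firing_rate - refractory
  x <- numeric(n)
  for (i in seq_len(cond$mu_count)) {
    tau_i <- 0.003 * cond$tau_scale * stats::runif(1, 0.8, 1.2)
    amp_i <- 0.5 * cond$amplitude_scale * stats::runif(1, 0.7, 1.3)
    w <- muap_waveform(muap_shape(tau_i, amp_i), fs)
    m <- ceiling(duration * cond$firing_rate * 1.5) + 10L
    isi <- refractory + stats::rexp(m, rate = 1 / exp_mean)
    times <- cumsum(c(stats::runif(1, 0, 1 / cond$firing_rate), isi[-m]))
    times <- times[times < duration]
    idx <- round(times * fs) + 1L
    idx <- idx[idx <= n]
    lw <- length(w)
    for (j in idx) {
      jj <- j:min(n, j + lw - 1L)
      x[jj] <- x[jj] + w[seq_along(jj)]
    }
  }
  t <- (seq_len(n) - 1L) / fs
  if (cond$noise_sd > 0) x <- x + stats::rnorm(n, 0, cond$noise_sd)
  if (cond$powerline_amp > 0) {
    x <- x + cond$powerline_amp * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
  }
  x
}

#' Simulate voluntary maximum-contraction sEMG
#'
#' Superposition of `mu_count` motor-unit action potential trains: each unit
#' fires as a renewal process (mean rate `firing_rate`, 20 ms refractory
#' floor) and contributes a [muap_waveform()] with time-scale jittered within
#' +/-20%, on top of Gaussian baseline noise and a 50 Hz powerline sinusoid.
#'
#' @param cond a [condition_params()].
#' @param duration record length in seconds (> 1).
#' @param fs sampling rate in Hz.
#' @param seed seed for reproducibility.
#' @return a single-channel [signal_record()] with role `"emg"`.
#' @export
simulate_voluntary_emg <- function(cond, duration = 60, fs = 2000,
                                   seed = NULL) {
  stopifnot(inherits(cond, "condition_params"))
  check_positive(fs, "fs")
  if (duration <= 1) stopf("duration must exceed 1 s (got %g)", duration)
  x <- with_seed(seed, .voluntary_channel(cond, duration, fs))
  signal_record(x, fs = fs, roles = "emg",
                meta = list(condition = cond$label, seed = seed,
                            protocol = "patient_mvc"))
}
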