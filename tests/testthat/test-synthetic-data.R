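# Generators: MUAP waveform, voluntary sEMG, evoked trains, cohorts.

test_that("MUAP waveform matches its analytic shape and is linear in amplitude", {
  fs <- 10000
  w <- muap_waveform(muap_shape(tau = 0.003, amplitude = 1), fs)
  t_peak <- (which.max(w) - 1) / fs
  expect_lt(abs(t_peak - 0.003 / sqrt(2)), 0.5 / fs) # 2.1 ms, within half a sample
  expect_equal(max(w), (1 / sqrt(2)) * exp(-0.5), tolerance = 1e-3)
  expect_equal(w[1], 0)
  # decays below 1% of peak beyond 4 tau
  beyond <- w[((4 * 0.003) * fs):length(w)]
  expect_lt(max(abs(beyond)), 0.01 * max(w))

  expect_equal(muap_waveform(muap_shape(0.003, 0), fs), numeric(length(w)))
  w2 <- muap_waveform(muap_shape(0.003, 2), fs)
  expect_equal(w2, 2 * w)

  expect_error(muap_shape(-1e-3), "tau")
  expect_error(muap_waveform(muap_shape(0.003), fs = 500), "fs")
})

test_that("evoked train places one artifact per stimulus at the stimulus times", {
  st <- stimulus_config(rate = 2, train_duration = 30)
  tr <- simulate_evoked_train(condition_params("healthy"), st,
                              fs = 2000, seed = 42)
  expect_equal(nrow(tr$truth), 60) # 2 Hz x 30 s
  idx <- detect_stimuli(tr$record$signals[, 1], 2000, st)
  expect_length(idx, 60)
  expect_lte(max(abs(idx - (round((0:59) * 1000) + 1))), 1)
})

test_that("noiseless epoch ground truth is recovered by the extractor", {
  ep <- simulate_evoked_epoch(fs = 2000, latency_ms = 5, amplitude_mv = 8,
                              duration_ms = 10)
  p <- extract_evoked_parameters(ep$signal, fs = 2000)
  expect_true(p$response_present)
  expect_lt(abs(p$latency_ms - 5), 0.5)
  expect_lt(abs(p$amplitude_mv - 8) / 8, 0.02)
})

test_that("evoked condition defaults reproduce the clinical ordering", {
  st <- stimulus_config(train_duration = 25) # 50 epochs/group
  nv <- simulate_evoked_train(condition_params("nerve_injury"), st, seed = 1)
  im <- simulate_evoked_train(condition_params("immobilization"), st, seed = 2)
  hl <- simulate_evoked_train(condition_params("healthy"), st, seed = 3)
  # nerve injury vs immobilization: amplitude, duration, AUC down; latency up
  expect_lt(mean(nv$truth$amplitude_mv), mean(im$truth$amplitude_mv))
  expect_lt(mean(nv$truth$duration_ms), mean(im$truth$duration_ms))
  expect_lt(mean(nv$truth$auc_mvms), mean(im$truth$auc_mvms))
  expect_gt(mean(nv$truth$latency_ms), mean(im$truth$latency_ms))
  # vs healthy: amplitude ratio < 1, latency ratio > 1
  expect_lt(mean(nv$truth$amplitude_mv) / mean(hl$truth$amplitude_mv), 1)
  expect_gt(mean(nv$truth$latency_ms) / mean(hl$truth$latency_ms), 1)
})

test_that("generators are deterministic given a seed", {
  st <- stimulus_config(train_duration = 5)
  a <- simulate_evoked_train(condition_params("nerve_injury"), st, seed = 7)
  b <- simulate_evoked_train(condition_params("nerve_injury"), st, seed = 7)
  expect_identical(a$record$signals, b$record$signals)
  expect_identical(a$truth, b$truth)

  va <- simulate_voluntary_emg(condition_params("healthy"), 5, 2000, seed = 8)
  vb <- simulate_voluntary_emg(condition_params("healthy"), 5, 2000, seed = 8)
  expect_identical(va$signals, vb$signals)
})

test_that("voluntary sEMG is linear in amplitude_scale when noiseless", {
  c1 <- condition_params("healthy", noise_sd = 0, powerline_amp = 0)
  c3 <- condition_params("healthy", amplitude_scale = 3, noise_sd = 0,
                         powerline_amp = 0)
  x1 <- simulate_voluntary_emg(c1, 3, 2000, seed = 5)$signals[, 1]
  x3 <- simulate_voluntary_emg(c3, 3, 2000, seed = 5)$signals[, 1]
  expect_equal(x3, 3 * x1, tolerance = 1e-12)
})

test_that("voluntary sEMG rejects invalid parameters", {
  expect_error(condition_params("healthy", mu_count = 0), "mu_count")
  expect_error(simulate_voluntary_emg(condition_params("healthy"),
                                      duration = 0.5), "duration")
  expect_error(condition_params("healthy", firing_rate = -2), "firing_rate")
})

test_that("powerline-dominated configuration yields a 50 Hz line spectrum", {
  cond <- condition_params("healthy", mu_count = 1, firing_rate = 0.05,
                           amplitude_scale = 1e-6, noise_sd = 0,
                           powerline_amp = 0.5)
  x <- simulate_voluntary_emg(cond, 10, 2000, seed = 2)$signals[, 1]
  n <- length(x)
  p <- abs(stats::fft(x - mean(x)))^2
  half <- floor(n / 2) + 1
  f <- (seq_len(half) - 1) * 2000 / n
  p <- p[seq_len(half)]
  expect_gt(sum(p[f >= 49 & f <= 51]) / sum(p), 0.9)
})

test_that("post-filter voluntary RMS orders nerve below immobilization with overlap", {
  prep <- preprocess_config()
  win <- windowing_config(stable_segment = c(15, 59.5))
  tabs <- lapply(list(nerve = list("nerve_injury", 3),
                      immob = list("immobilization", 4)), function(s) {
    rec <- simulate_voluntary_emg(condition_params(s[[1]]), 60, 2000,
                                  seed = s[[2]])
    build_feature_table(preprocess_record(rec, prep), win)
  })
  expect_gte(nrow(tabs$nerve), 100)
  gap <- mean(tabs$immob$rms) - mean(tabs$nerve$rms)
  expect_gt(gap, 0)
  expect_gt(sd(tabs$nerve$rms), 0.25 * gap)
  expect_gt(sd(tabs$immob$rms), 0.25 * gap)
})

test_that("voluntary sEMG keeps >= 90% of post-band-pass power in 20-500 Hz", {
  rec <- simulate_voluntary_emg(condition_params("healthy"), 20, 2000,
                                seed = 5)
  x <- preprocess_record(rec, preprocess_config())$signals[, 1]
  x <- x[1001:length(x)] # skip warm-up
  n <- length(x)
  p <- abs(stats::fft(x - mean(x)))^2
  half <- floor(n / 2) + 1
  f <- (seq_len(half) - 1) * 2000 / n
  p <- p[seq_len(half)]
  expect_gt(sum(p[f >= 20 & f <= 500]) / sum(p), 0.9)
})

test_that("rat cohort accounting and determinism hold at small scale", {
  co <- generate_rat_cohort(
    cohort_config("rat_evoked",
                  groups = list(immobilization = 1, nerve_injury = 1),
                  acquisitions_per_subject = 2), seed = 3)
  expect_equal(nrow(co$labels), 4)
  expect_equal(sum(co$labels$label == 1), 2)
  expect_equal(sum(co$labels$label == 0), 2)

  co2 <- generate_rat_cohort(
    cohort_config("rat_evoked",
                  groups = list(immobilization = 1, nerve_injury = 1),
                  acquisitions_per_subject = 2), seed = 3)
  expect_identical(co$labels, co2$labels)
  expect_identical(co$subjects, co2$subjects)

  expect_error(cohort_config("rat_evoked", groups = list(healthy = 2)),
               "group label")
})

test_that("patient cohort template matches the clinical study layout", {
  co <- generate_patient_cohort(seed = 10)
  expect_equal(nrow(co$labels), 10)
  expect_equal(sum(co$labels$label == 1), 7)
  expect_equal(sum(co$labels$label == 0), 3)
  rec <- co$records[[1]]
  expect_equal(ncol(rec$signals), 4)
  expect_equal(nrow(rec$signals), 120000) # 60 s at 2 kHz
  expect_error(cohort_config("patient_mvc", channels = c("a", "b")),
               "4 channels")
})
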