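# Windowed feature extraction and ratio normalization.

test_that("window counts match the start-enumeration oracle", {
  fs <- 2000
  cfg30 <- windowing_config(stable_segment = c(0, 30))
  cfg40 <- windowing_config(stable_segment = c(0, 40))
  x <- numeric(41 * fs)
  expect_length(segment_windows(x, fs, cfg30), 68)
  expect_length(segment_windows(x, fs, cfg40), 91)
  expect_length(enumerate_window_starts(30, 0.5, 0.4375), 68)
  expect_length(enumerate_window_starts(40, 0.5, 0.4375), 91)
  # counts agree with the oracle across segment lengths
  for (L in c(2, 7.3, 12.25, 25)) {
    cfg <- windowing_config(stable_segment = c(0, L))
    expect_length(segment_windows(numeric(ceiling(L * fs) + 1), fs, cfg),
                  length(enumerate_window_starts(L, 0.5, 0.4375)))
  }
  # a segment of exactly one window
  expect_length(segment_windows(numeric(fs), fs,
                                windowing_config(stable_segment = c(0, 0.5))), 1)
  expect_error(segment_windows(numeric(fs), fs,
                               windowing_config(stable_segment = c(0, 0.3))),
               "shorter than one window")
})

test_that("time-domain features match closed forms", {
  fs <- 2000
  # constant window
  td <- time_domain_features(rep(-2, fs / 2), fs)
  expect_equal(td$rms, 2)
  expect_equal(td$arv, 2)
  expect_equal(td$iemg, 2 * 0.5)
  # unit sine over integer cycles
  x <- sin(2 * pi * 100 * (0:(fs / 2 - 1)) / fs)
  td <- time_domain_features(x, fs)
  expect_equal(td$rms, sqrt(0.5), tolerance = 1e-3)
  expect_equal(td$arv, 2 / pi, tolerance = 1e-2)
  expect_equal(td$iemg, (2 / pi) * 0.5, tolerance = 1e-2)
  # tiny window by direct arithmetic
  td <- time_domain_features(c(3, -4), fs = 2)
  expect_equal(td$rms, sqrt(12.5))
  expect_equal(td$arv, 3.5)
  expect_equal(td$iemg, 3.5)
  expect_error(time_domain_features(numeric(0), fs), "empty")
})

test_that("features match brute-force recomputation from definitions", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(16)
    td <- time_domain_features(x, 2000)
    bf <- bf_time_features(x, 2000)
    expect_equal(td$rms, bf$rms, tolerance = 1e-12)
    expect_equal(td$arv, bf$arv, tolerance = 1e-12)
    expect_equal(td$iemg, bf$iemg, tolerance = 1e-12)
  }
  # spectral features against an O(n^2) DFT oracle
  x <- rnorm(128)
  sf <- spectral_features(x, 2000)
  bf <- bf_spectral_features(x, 2000)
  expect_equal(sf$mdf, bf$mdf, tolerance = 1e-8)
  expect_equal(sf$mpf, bf$mpf, tolerance = 1e-8)
})

test_that("spectral features localize tones and flat noise correctly", {
  fs <- 2000
  tt <- (0:999) / fs
  sf <- spectral_features(sin(2 * pi * 100 * tt), fs)
  bin <- fs / 1024
  expect_equal(sf$mdf, 100, tolerance = 2 * bin)
  expect_equal(sf$mpf, 100, tolerance = 2 * bin)

  two <- sin(2 * pi * 100 * tt) + sin(2 * pi * 200 * tt)
  sf2 <- spectral_features(two, fs)
  expect_equal(sf2$mpf, 150, tolerance = 2 * bin)
  expect_gt(sf2$mdf, 100 - 2 * bin)
  expect_lt(sf2$mdf, 200 + 2 * bin)

  # flat 20-500 Hz noise: both moments at the band midpoint 260 Hz
  set.seed(6)
  ms <- replicate(50, {
    x <- flat_band_noise(1000, fs)
    unlist(spectral_features(x, fs))
  })
  expect_equal(mean(ms["mdf", ]), 260, tolerance = 10)
  expect_equal(mean(ms["mpf", ]), 260, tolerance = 10)

  expect_error(spectral_features(numeric(128), fs), "silent window")
  expect_error(spectral_features(rnorm(32), fs), "too short")
})

test_that("rms >= arv with equality only for constant magnitude, and scaling behaves", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(64)
    td <- time_domain_features(x, 2000)
    expect_gte(td$rms, td$arv)
  }
  td_const <- time_domain_features(c(2, -2, 2, -2), 2000)
  expect_equal(td_const$rms, td_const$arv)

  x <- rnorm(256)
  td1 <- time_domain_features(x, 2000); td3 <- time_domain_features(3 * x, 2000)
  expect_equal(td3$rms, 3 * td1$rms)
  expect_equal(td3$arv, 3 * td1$arv)
  expect_equal(td3$iemg, 3 * td1$iemg)
  sf1 <- spectral_features(x, 2000); sf3 <- spectral_features(3 * x, 2000)
  expect_equal(sf3$mdf, sf1$mdf)
  expect_equal(sf3$mpf, sf1$mpf)
})

test_that("feature tables have deterministic shape and order", {
  fs <- 2000
  set.seed(8)
  sig <- matrix(rnorm(4 * 31 * fs), ncol = 4)
  rec <- signal_record(sig, fs,
                       roles = c("unaffected_ta", "affected_ta",
                                 "unaffected_ga", "affected_ga"),
                       meta = list(subject_id = "p1", label = 1L))
  tab <- build_feature_table(rec, windowing_config(stable_segment = c(0, 30)))
  expect_equal(nrow(tab), 4 * 68)
  expect_equal(unique(tab$channel_role),
               c("affected_ta", "affected_ga", "unaffected_ta", "unaffected_ga"))
  tab2 <- build_feature_table(rec, windowing_config(stable_segment = c(0, 30)))
  expect_identical(tab, tab2)

  one <- build_feature_table(
    signal_record(sig[1:fs, 1], fs, roles = "emg"),
    windowing_config(stable_segment = c(0, 0.5)))
  expect_equal(nrow(one), 1)
  expect_true(all(c("rms", "iemg", "arv", "mdf", "mpf") %in% names(one)))
})

test_that("ratio normalization divides by the reference channel means", {
  fs <- 2000
  set.seed(9)
  sig <- matrix(rnorm(2 * 6 * fs), ncol = 2)
  rec <- signal_record(sig, fs, roles = c("affected_ta", "unaffected_ta"),
                       meta = list(subject_id = "p1", label = 1L))
  tab <- build_feature_table(rec, windowing_config(stable_segment = c(0, 5)))
  aff <- tab[tab$channel_role == "affected_ta", ]
  ref <- tab[tab$channel_role == "unaffected_ta", ]

  self <- ratio_normalize(aff, aff)
  feats <- c("rms", "iemg", "arv", "mdf", "mpf")
  expect_equal(unname(colMeans(self[, feats])), rep(1, 5), tolerance = 1e-12)
  expect_true(all(self$normalized))

  doubled <- aff
  doubled$rms <- 2 * doubled$rms
  rn <- ratio_normalize(doubled, aff)
  expect_equal(mean(rn$rms), 2, tolerance = 1e-12)
  expect_equal(mean(rn$mdf), 1, tolerance = 1e-12)

  pair <- ratio_normalize(aff, ref, pairing = c(affected_ta = "unaffected_ta"))
  expect_true(all(is.finite(unlist(pair[, feats]))))

  zero_ref <- aff
  zero_ref[, "rms"] <- 0
  expect_error(ratio_normalize(aff, zero_ref), "rms")
  expect_error(ratio_normalize(aff, ref[0, ]), "empty")
})

test_that("a null patient cohort (healthy both limbs) gives ratios near 1", {
  cfg <- cohort_config(
    "patient_mvc", groups = list(immobilization = 1, nerve_injury = 1),
    record_duration = 30,
    conditions = list(immobilization = condition_params("healthy"),
                      nerve_injury = condition_params("healthy")))
  co <- generate_patient_cohort(cfg, seed = 10)
  ft <- patient_feature_table(co)
  for (f in c("rms", "iemg", "arv", "mdf", "mpf")) {
    expect_gt(median(ft[[f]]), 0.8)
    expect_lt(median(ft[[f]]), 1.25)
  }
})
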