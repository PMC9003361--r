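# Shared helpers: independent oracles and steady-state measures used across
# the suite.

# RMS of the central portion of a filtered tone, excluding filter
# transients at both ends.
steady_rms <- function(x, fs, trim_s = 0.5) {
  i <- round(trim_s * fs)
  x <- x[(i + 1):(length(x) - i)]
  sqrt(mean(x^2))
}

# Enumeration oracle for window counting: walk candidate starts and count
# those whose full window fits in the segment.
enumerate_window_starts <- function(segment_length, window_length, step) {
  starts <- c()
  s <- 0
  while (s + window_length <= segment_length + 1e-9) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}

# Brute-force time-domain feature oracle: explicit accumulation loops,
# independent of the vectorized implementation.
bf_time_features <- function(x, fs) {
  ss <- 0; sa <- 0
  for (v in x) {
    ss <- ss + v * v
    sa <- sa + abs(v)
  }
  list(rms = sqrt(ss / length(x)), iemg = sa / fs, arv = sa / length(x))
}

# Brute-force spectral oracle: O(n^2) DFT of the Hann-tapered, mean-removed,
# zero-padded window, then the same band-restricted moment definitions.
bf_spectral_features <- function(x, fs, band = c(20, 500), nfft = 1024) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xt <- c((x - mean(x)) * w, numeric(nfft - n))
  half <- floor(nfft / 2) + 1
  p <- numeric(half)
  for (k in seq_len(half)) {
    re <- 0; im <- 0
    for (j in seq_len(nfft)) {
      ang <- -2 * pi * (k - 1) * (j - 1) / nfft
      re <- re + xt[j] * cos(ang)
      im <- im + xt[j] * sin(ang)
    }
    p[k] <- re^2 + im^2
  }
  f <- (seq_len(half) - 1) * fs / nfft
  keep <- f >= band[1] & f <= min(band[2], fs / 2)
  p <- p[keep]; f <- f[keep]
  tot <- sum(p)
  mpf <- sum(f * p) / tot
  cs <- cumsum(p)
  i <- which(cs >= tot / 2)[1]
  mdf <- if (i == 1) f[1] else
    f[i - 1] + (f[i] - f[i - 1]) * (tot / 2 - cs[i - 1]) / (cs[i] - cs[i - 1])
  list(mdf = mdf, mpf = mpf)
}

# Band-limited white noise, flat over `band`, via random-phase inverse FFT.
flat_band_noise <- function(n, fs, band = c(20, 500)) {
  half <- floor(n / 2) + 1
  f <- (seq_len(half) - 1) * fs / n
  mag <- as.numeric(f >= band[1] & f <= band[2])
  ph <- stats::runif(half, 0, 2 * pi)
  spec <- mag * exp(1i * ph)
  full <- c(spec, Conj(rev(spec[2:(half - 1)])))
  Re(stats::fft(full, inverse = TRUE)) / n
}

# Small rat cohort used by several tests.
small_rat_cohort <- function(n_subj = 2, n_acq = 3, seed = 123) {
  generate_rat_cohort(
    cohort_config("rat_evoked",
                  groups = list(immobilization = n_subj,
                                nerve_injury = n_subj),
                  acquisitions_per_subject = n_acq),
    seed = seed)
}
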