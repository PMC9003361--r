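# Windowed sEMG feature extraction (RMS, iEMG, ARV, MDF, MPF) and ratio
# normalization of feature tables.

.feature_cols <- c("rms", "iemg", "arv", "mdf", "mpf")

#' Windowing configuration for feature extraction
#'
#' Features are gathered on 0.5 s windows with an overlap of 1/8 of the
#' window (step 0.4375 s) over a stable segment chosen from the recording
#' (for a 60 s maximum-voluntary-contraction move, typically the stable 30 s
#' or 40 s period). The alternative reading of "overlap of 1/8" -- a step of
#' 1/8 window -- is available via `overlap_mode = "step_fraction"`.
#'
#' @param window_length window length in seconds.
#' @param overlap overlap fraction in `[0, 1)`.
#' @param stable_segment numeric length-2 `(start, end)` in seconds, or
#'   `NULL` to use the whole record after filter warm-up.
#' @param overlap_mode `"fraction"` (step = window * (1 - overlap), default)
#'   or `"step_fraction"` (step = window * overlap).
#' @return an object of class `windowing_config`.
#' @export
windowing_config <- function(window_length = 0.5, overlap = 1 / 8,
                             stable_segment = NULL,
                             overlap_mode = c("fraction", "step_fraction")) {
  overlap_mode <- match.arg(overlap_mode)
  check_positive(window_length, "window_length")
  check_number(overlap, "overlap", lower = 0)
  if (overlap_mode == "fraction" && overlap >= 1) {
    stopf("`overlap` must be < 1")
  }
  step <- if (overlap_mode == "fraction") {
    window_length * (1 - overlap)
  } else {
    window_length * overlap
  }
  if (step <= 0) stopf("window step must be > 0")
  if (!is.null(stable_segment)) {
    if (length(stable_segment) != 2L || stable_segment[2] <= stable_segment[1]) {
      stopf("`stable_segment` must be (start, end) with end > start")
    }
  }
  structure(list(window_length = window_length, overlap = overlap,
                 step = step, stable_segment = stable_segment,
                 overlap_mode = overlap_mode),
            class = "windowing_config")
}

#' Segment a channel into overlapping windows
#'
#' Window `k` starts at `stable_start + k * step`; a final partial window is
#' dropped, so the count is `floor((segment - window) / step) + 1`.
#'
#' @param x numeric vector, one channel.
#' @param fs sampling rate in Hz.
#' @param cfg a [windowing_config()]; `cfg$stable_segment` defaults to the
#'   whole vector.
#' @return list of numeric windows; window start times (s) in attribute
#'   `"starts"`.
#' @export
segment_windows <- function(x, fs, cfg = windowing_config()) {
  check_positive(fs, "fs")
  seg <- cfg$stable_segment %||% c(0, length(x) / fs)
  if (seg[2] > length(x) / fs + 1e-9) {
    stopf("stable segment end (%g s) exceeds record duration (%g s)",
          seg[2], length(x) / fs)
  }
  seg_len <- seg[2] - seg[1]
  if (seg_len < cfg$window_length - 1e-9) {
    stopf("stable segment (%g s) is shorter than one window (%g s)",
          seg_len, cfg$window_length)
  }
  n_win <- floor((seg_len - cfg$window_length) / cfg$step + 1e-9) + 1L
  wl_n <- round(cfg$window_length * fs)
  starts <- seg[1] + (seq_len(n_win) - 1L) * cfg$step
  wins <- lapply(starts, function(s0) {
    i0 <- round(s0 * fs) + 1L
    x[i0:(i0 + wl_n - 1L)]
  })
  attr(wins, "starts") <- starts
  wins
}

#' Time-domain features of one window
#'
#' Root mean square `rms = sqrt(mean(x^2))` (mV), average rectified value
#' `arv = mean(abs(x))` (mV), and integrated EMG as the time-integral of the
#' rectified signal `iemg = sum(abs(x)) / fs` (mV s).
#'
#' @param x numeric window.
#' @param fs sampling rate in Hz.
#' @return named list `rms`, `iemg`, `arv`.
#' @export
time_domain_features <- function(x, fs) {
  if (length(x) == 0L) stopf("empty window")
  check_positive(fs, "fs")
  list(rms = sqrt(mean(x^2)), iemg = sum(abs(x)) / fs, arv = mean(abs(x)))
}

#' Spectral features of one window
#'
#' Estimates the power spectral density with a Hann-tapered periodogram
#' zero-padded to at least 1024 points, restricted to the analysis band
#' (default 20-500 Hz). The mean power frequency is the power-weighted mean
#' `mpf = sum(f * P) / sum(P)`; the median frequency `mdf` is the frequency
#' splitting the in-band power in half, linearly interpolated between bins.
#'
#' @param x numeric window, at least 64 samples.
#' @param fs sampling rate in Hz.
#' @param band analysis band in Hz.
#' @param nfft transform length; default the larger of 1024 and the next
#'   power of two above `length(x)`.
#' @return named list `mdf`, `mpf` (Hz).
#' @export
spectral_features <- function(x, fs, band = c(20, 500), nfft = NULL) {
  if (length(x) < 64L) stopf("window too short for spectral features (need >= 64 samples)")
  check_positive(fs, "fs")
  n <- length(x)
  if (is.null(nfft)) nfft <- max(1024L, 2^ceiling(log2(n)))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  xt <- c((x - mean(x)) * w, numeric(nfft - n))
  sp <- abs(stats::fft(xt))^2
  half <- floor(nfft / 2) + 1L
  p <- sp[seq_len(half)]
  f <- (seq_len(half) - 1L) * fs / nfft
  keep <- f >= band[1] & f <= min(band[2], fs / 2)
  p <- p[keep]; f <- f[keep]
  tot <- sum(p)
  if (tot <= .Machine$double.eps) stopf("silent window: no in-band power")
  mpf <- sum(f * p) / tot
  cs <- cumsum(p)
  i <- which(cs >= tot / 2)[1L]
  mdf <- if (i == 1L) f[1L] else {
    f[i - 1L] + (f[i] - f[i - 1L]) * (tot / 2 - cs[i - 1L]) / (cs[i] - cs[i - 1L])
  }
  list(mdf = mdf, mpf = mpf)
}

#' Build a per-window feature table from a record
#'
#' For each channel (in canonical role order) the stable segment is windowed
#' and the five features computed per window. Row order is deterministic:
#' channel role, then window index.
#'
#' @param record a preprocessed [signal_record()].
#' @param cfg a [windowing_config()]; when its `stable_segment` is `NULL`
#'   the segment runs from the filter warm-up (recorded by
#'   [preprocess_record()], default 0.5 s) to the end of the record.
#' @param band spectral analysis band in Hz.
#' @return data.frame with columns `subject_id`, `channel_role`,
#'   `window_idx`, the five features, `label` and `normalized` (`FALSE`).
#' @export
build_feature_table <- function(record, cfg = windowing_config(),
                                band = c(20, 500)) {
  stopifnot(inherits(record, "signal_record"))
  if (is.null(cfg$stable_segment)) {
    warm <- record$meta$warmup_s %||% 0.5
    cfg$stable_segment <- c(warm, record_duration(record))
  }
  roles <- colnames(record$signals)
  pos <- match(roles, .canonical_roles)
  ord <- if (anyNA(pos)) seq_along(roles) else order(pos)
  subject <- record$meta$subject_id %||% NA_character_
  label <- record$meta$label %||% NA_integer_
  out <- lapply(roles[ord], function(role) {
    wins <- segment_windows(record$signals[, role], record$fs, cfg)
    rows <- lapply(seq_along(wins), function(k) {
      td <- time_domain_features(wins[[k]], record$fs)
      sf <- spectral_features(wins[[k]], record$fs, band = band)
      data.frame(subject_id = subject, channel_role = role, window_idx = k,
                 rms = td$rms, iemg = td$iemg, arv = td$arv,
                 mdf = sf$mdf, mpf = sf$mpf, label = label,
                 normalized = FALSE)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

#' Ratio-normalize a feature table against a reference
#'
#' Divides each feature of the affected table by the per-channel-role mean
#' of the reference table, producing dimensionless ratios. This removes
#' subject-specific gain (electrode contact, willingness to contract): for
#' patients the reference is the contralateral (unaffected) limb, for rats
#' the pre-surgery healthy baseline of the same animal.
#'
#' @param affected feature table (as from [build_feature_table()]).
#' @param reference feature table providing the denominator.
#' @param pairing named character vector mapping affected channel roles to
#'   reference roles (e.g. `c(affected_ta = "unaffected_ta")`); by default
#'   each role is paired with itself.
#' @param eps smallest admissible reference mean; smaller values raise an
#'   error naming the feature and channel.
#' @return the affected table with features replaced by ratios and
#'   `normalized = TRUE`.
#' @export
ratio_normalize <- function(affected, reference, pairing = NULL,
                            eps = 1e-9) {
  if (nrow(reference) == 0L) stopf("reference table is empty")
  roles <- unique(affected$channel_role)
  if (is.null(pairing)) {
    pairing <- stats::setNames(roles, roles)
  }
  out <- affected
  for (role in roles) {
    ref_role <- pairing[[role]] %||% role
    ref_rows <- reference[reference$channel_role == ref_role, , drop = FALSE]
    if (nrow(ref_rows) == 0L) {
      stopf("reference table has no rows for channel role `%s`", ref_role)
    }
    ref_mean <- colMeans(ref_rows[, .feature_cols, drop = FALSE])
    low <- which(ref_mean < eps)
    if (length(low)) {
      stopf("reference mean below %g for feature `%s` on channel `%s`",
            eps, .feature_cols[low[1L]], ref_role)
    }
    sel <- out$channel_role == role
    out[sel, .feature_cols] <-
      sweep(out[sel, .feature_cols, drop = FALSE], 2L, ref_mean, "/")
  }
  out$normalized <- TRUE
  out
}
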