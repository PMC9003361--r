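# Multichannel sampled EMG container and its plain-text on-disk format.

# Canonical channel ordering used throughout the pipeline. The four patient
# roles follow the electrode montage (affected limb first, tibialis anterior
# before gastrocnemius); "ta" is the single-channel rat montage and "emg" a
# generic single channel.
.canonical_roles <- c("affected_ta", "affected_ga",
                      "unaffected_ta", "unaffected_ga",
                      "ta", "emg")

#' Construct a multichannel EMG signal record
#'
#' A `signal_record` bundles a samples-by-channels matrix (millivolts) with
#' its sampling rate and free-form metadata (subject id, condition label,
#' seed, ...). Time is implicit: sample `i` is at `(i - 1) / fs` seconds.
#'
#' @param signals numeric matrix, one column per channel, or a numeric vector
#'   for a single channel.
#' @param fs sampling rate in Hz.
#' @param roles character vector of channel roles (see Details); defaults to
#'   the column names of `signals`.
#' @param meta named list of metadata carried through the pipeline.
#'
#' @details Recognized roles are `affected_ta`, `affected_ga`,
#'   `unaffected_ta`, `unaffected_ga` (patient montage), `ta` (rat tibialis
#'   anterior) and `emg` (generic). Unknown roles are tolerated at
#'   construction but rejected by [preprocess_record()].
#'
#' @return an object of class `signal_record`.
#' @export
signal_record <- function(signals, fs, roles = NULL, meta = list()) {
  if (is.numeric(signals) && is.null(dim(signals))) {
    signals <- matrix(signals, ncol = 1L)
  }
  if (!is.matrix(signals) || !is.numeric(signals)) {
    stopf("`signals` must be a numeric matrix (samples x channels)")
  }
  if (ncol(signals) < 1L) stopf("record must contain at least one channel")
  check_positive(fs, "fs")
  if (is.null(roles)) roles <- colnames(signals)
  if (is.null(roles)) {
    roles <- if (ncol(signals) == 1L) "emg" else
      paste0("ch", seq_len(ncol(signals)))
  }
  if (length(roles) != ncol(signals)) {
    stopf("length(roles) (%d) != number of channels (%d)",
          length(roles), ncol(signals))
  }
  if (anyDuplicated(roles)) stopf("channel roles must be unique")
  colnames(signals) <- roles
  structure(list(signals = signals, fs = fs, meta = meta),
            class = "signal_record")
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d samples x %d channel(s), fs = %g Hz (%.3g s)\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              nrow(x$signals) / x$fs))
  cat("  roles:", paste(colnames(x$signals), collapse = ", "), "\n")
  if (length(x$meta)) {
    keep <- intersect(c("subject_id", "condition", "label", "seed"),
                      names(x$meta))
    for (k in keep) cat(sprintf("  %s: %s\n", k, format(x$meta[[k]])))
  }
  invisible(x)
}

record_duration <- function(record) nrow(record$signals) / record$fs

#' Write a signal record as plain-text files
#'
#' The data file is tab-separated with a `time` column (seconds) followed by
#' one column per channel (millivolts). Metadata (sampling rate, channel
#' roles, subject, condition, seed) goes to a YAML sidecar at
#' `<path>.meta.yaml`. Values are written with 17 significant digits so that
#' a write/read round trip reproduces the record exactly.
#'
#' @param record a [signal_record()].
#' @param path path of the data file to create.
#' @return `path`, invisibly.
#' @export
write_signal_file <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  n <- nrow(record$signals)
  tt <- (seq_len(n) - 1L) / record$fs
  mat <- cbind(tt, record$signals)
  lines <- c(
    paste(c("time", colnames(record$signals)), collapse = "\t"),
    apply(mat, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  )
  writeLines(lines, path)
  side <- c(list(fs = record$fs, roles = as.list(colnames(record$signals))),
            record$meta)
  yaml::write_yaml(side, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a signal record written by [write_signal_file()]
#'
#' Parsing is strict: ragged rows and non-numeric cells raise an error naming
#' the offending line, and the metadata sidecar must declare the sampling
#' rate and at least one channel role.
#'
#' @param path path of the data file.
#' @return a [signal_record()].
#' @export
read_signal_file <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  side_path <- paste0(path, ".meta.yaml")
  if (!file.exists(side_path)) stopf("metadata sidecar not found: %s", side_path)
  side <- yaml::read_yaml(side_path)
  if (is.null(side$fs)) stopf("sidecar %s does not declare `fs`", side_path)
  roles <- unlist(side$roles)
  if (length(roles) < 1L) stopf("sidecar %s declares an empty channel set", side_path)

  lines <- readLines(path)
  if (length(lines) < 2L) stopf("%s has no data rows", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(parts[[1L]])
  if (ncols != length(roles) + 1L) {
    stopf("%s header has %d columns but sidecar declares %d channels",
          path, ncols, length(roles))
  }
  lens <- lengths(parts)
  bad <- which(lens != ncols)
  if (length(bad)) stopf("ragged row in %s at line %d", path, bad[1L])
  body <- parts[-1L]
  vals <- suppressWarnings(as.numeric(unlist(body, use.names = FALSE)))
  if (anyNA(vals)) {
    nab <- which(vapply(body, function(p) anyNA(suppressWarnings(as.numeric(p))),
                        logical(1L)))[1L]
    stopf("non-numeric cell in %s at line %d", path, nab + 1L)
  }
  mat <- matrix(vals, ncol = ncols, byrow = TRUE)
  signals <- mat[, -1L, drop = FALSE]
  colnames(signals) <- roles
  meta <- side[setdiff(names(side), c("fs", "roles"))]
  signal_record(signals, fs = side$fs, roles = roles, meta = meta)
}
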