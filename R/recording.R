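#' Standard 19-channel 10-20 montage used by the pipeline
#'
#' Channel order is fixed; input recordings are mapped to it by name.
#' @export
MONTAGE_1020 <- c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4",
                  "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6",
                  "FZ", "CZ", "PZ")

POSTERIOR_CHANNELS <- c("P3", "P4", "O1", "O2", "T5", "T6", "PZ")
FRONTAL_CHANNELS <- c("FP1", "FP2", "F3", "F4", "F7", "F8", "FZ")

#' Multichannel EEG recording with seizure annotations
#'
#' The raw-data currency of the pipeline: a channels x samples matrix in
#' microvolts, the sampling rate, channel names, and a data frame of
#' annotated intervals.
#'
#' @param signals Numeric matrix `[n_channels, n_samples]` (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one per row of `signals`.
#' @param annotations Data frame with columns `onset_s`, `offset_s`,
#'   `label` (label `"seizure"` marks ictal intervals). May be empty.
#' @param id Recording identifier carried into feature provenance.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, fs, channel_names,
                          annotations = empty_annotations(),
                          id = "recording") {
  signals <- as.matrix(signals)
  stopifnot(is.numeric(signals), fs > 0,
            length(channel_names) == nrow(signals))
  annotations <- as.data.frame(annotations)
  if (nrow(annotations)) {
    req <- c("onset_s", "offset_s", "label")
    if (!all(req %in% names(annotations))) {
      stop("annotations need columns onset_s, offset_s, label", call. = FALSE)
    }
    dur <- ncol(signals) / fs
    if (any(annotations$onset_s < 0) || any(annotations$offset_s > dur + 1e-9) ||
        any(annotations$onset_s >= annotations$offset_s)) {
      stop("annotations must satisfy 0 <= onset < offset <= duration",
           call. = FALSE)
    }
  }
  structure(
    list(signals = signals, fs = fs,
         channel_names = toupper(channel_names),
         annotations = annotations, id = id),
    class = "eeg_recording"
  )
}

empty_annotations <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> '%s': %d ch x %.1f s @ %g Hz, %d annotation(s)\n",
              x$id, nrow(x$signals), ncol(x$signals) / x$fs, x$fs,
              nrow(x$annotations)))
  invisible(x)
}

#' Map a recording onto the standard 19-channel montage
#'
#' Reorders channels by name to [MONTAGE_1020], dropping surplus channels.
#' Missing montage channels are an error. Recordings not sampled at
#' `target_fs` are resampled by polyphase filtering.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Sampling rate the pipeline runs at (250 Hz).
#' @return An [eeg_recording()] with 19 rows in montage order.
#' @export
conform_recording <- function(rec, target_fs = 250) {
  idx <- match(MONTAGE_1020, rec$channel_names)
  if (anyNA(idx)) {
    stop(sprintf("recording is missing montage channel(s): %s",
                 paste(MONTAGE_1020[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  sig <- rec$signals[idx, , drop = FALSE]
  fs <- rec$fs
  if (!isTRUE(all.equal(fs, target_fs))) {
    ratio <- target_fs / fs
    pq <- rational_approx(ratio)
    sig <- t(apply(sig, 1, function(ch) signal::resample(ch, pq[1], pq[2])))
    fs <- target_fs
  }
  eeg_recording(sig, fs, MONTAGE_1020, rec$annotations, rec$id)
}

rational_approx <- function(x, max_den = 1000) {
  f <- MASS_fractions(x, max_den)
  c(f$num, f$den)
}

# small continued-fraction rationalization (avoids a MASS dependency)
MASS_fractions <- function(x, max_den) {
  a <- floor(x); p0 <- 1; q0 <- 0; p1 <- a; q1 <- 1; r <- x - a
  while (abs(p1 / q1 - x) > 1e-12 && q1 < max_den && r > 1e-12) {
    a <- floor(1 / r); r <- 1 / r - a
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
  list(num = p1, den = q1)
}

#' Number of complete, non-overlapping analysis windows in a recording
#'
#' The segmentation arithmetic used by [segment_recording()]: trailing
#' partial windows are discarded, so 400 hours at 12-second windows give
#' 120,000 windows.
#'
#' @param duration_s Recording duration in seconds.
#' @param window_s Window length in seconds.
#' @return Integer window count.
#' @export
#' @examples
#' count_windows(400 * 3600, 12)  # 120000
count_windows <- function(duration_s, window_s = 12) {
  as.integer(floor(duration_s / window_s + 1e-9))
}

#' Split a recording into fixed-length labeled windows
#'
#' Cuts consecutive non-overlapping windows of `window_s` seconds
#' (trailing remainder discarded). A window is labeled `"seizure"` iff its
#' overlap with any annotated seizure interval is at least `label_rule`
#' times the window length; the default `label_rule = 0` labels on any
#' positive overlap.
#'
#' @param rec An [eeg_recording()].
#' @param window_s Window length in seconds (fs * window_s must be whole).
#' @param label_rule Minimum overlap fraction in `[0, 1]`; 0 means any
#'   overlap.
#' @return A list with `segments` (list of `[n_channels, fs*window_s]`
#'   matrices), `labels` (character), `onsets_s` (numeric).
#' @export
segment_recording <- function(rec, window_s = 12, label_rule = 0) {
  w <- rec$fs * window_s
  if (abs(w - round(w)) > 1e-9) {
    stop("fs * window_s must be an integer number of samples", call. = FALSE)
  }
  w <- as.integer(round(w))
  n_win <- count_windows(ncol(rec$signals) / rec$fs, window_s)
  if (n_win == 0L) {
    return(list(segments = list(), labels = character(0),
                onsets_s = numeric(0)))
  }
  sz <- rec$annotations[rec$annotations$label == "seizure", , drop = FALSE]
  segments <- vector("list", n_win)
  labels <- character(n_win)
  onsets <- (seq_len(n_win) - 1L) * window_s
  for (i in seq_len(n_win)) {
    a <- (i - 1L) * w
    segments[[i]] <- rec$signals[, (a + 1L):(a + w), drop = FALSE]
    labels[i] <- window_label(onsets[i], onsets[i] + window_s, sz, label_rule)
  }
  list(segments = segments, labels = labels, onsets_s = onsets)
}

window_label <- function(t0, t1, seizure_intervals, label_rule) {
  if (!nrow(seizure_intervals)) return("background")
  ov <- pmin(t1, seizure_intervals$offset_s) -
    pmax(t0, seizure_intervals$onset_s)
  ov <- sum(pmax(ov, 0))
  need <- if (label_rule <= 0) .Machine$double.eps else label_rule * (t1 - t0)
  if (ov >= need && ov > 0) "seizure" else "background"
}
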