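#' STFT featurization configuration
#'
#' Defaults follow the pipeline's contract for 250 Hz data: 250-sample
#' (1 s) analysis windows with 50% overlap, one-sided spectrum, DC bin
#' dropped — so a 12-s segment yields 23 frames x 125 frequency bins per
#' channel.
#'
#' @param window_samples Analysis window length in samples.
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in `[0, 1)`.
#' @param drop_dc Drop the 0 Hz bin of the one-sided spectrum.
#' @param window_function Taper: `"hann"` (periodic) or `"rectangular"`.
#' @param magnitude_mode `"log_magnitude"` (log(1 + |X|), default),
#'   `"magnitude"`, or `"power"`.
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(window_samples = 250L, overlap_fraction = 0.5,
                        drop_dc = TRUE,
                        window_function = c("hann", "rectangular"),
                        magnitude_mode = c("log_magnitude", "magnitude",
                                           "power")) {
  window_function <- match.arg(window_function)
  magnitude_mode <- match.arg(magnitude_mode)
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("`overlap_fraction` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(window_samples = as.integer(window_samples),
         overlap_fraction = overlap_fraction, drop_dc = isTRUE(drop_dc),
         window_function = window_function, magnitude_mode = magnitude_mode),
    class = "stft_config"
  )
}

stft_hop <- function(cfg) {
  as.integer(round(cfg$window_samples * (1 - cfg$overlap_fraction)))
}

#' Frame count of the STFT for a given segment length
#'
#' `floor((L - W) / hop) + 1` with `hop = W * (1 - overlap)`.
#' @param n_samples Segment length L in samples.
#' @param cfg An [stft_config()].
#' @return Integer number of frames.
#' @export
#' @examples
#' stft_n_frames(3000)  # 23
stft_n_frames <- function(n_samples, cfg = stft_config()) {
  as.integer((n_samples - cfg$window_samples) %/% stft_hop(cfg) + 1L)
}

#' Number of frequency bins of the one-sided STFT
#' @param cfg An [stft_config()].
#' @return Integer: `W/2 + 1`, minus one when the DC bin is dropped
#'   (125 for the default 250-sample window).
#' @export
stft_n_freqs <- function(cfg = stft_config()) {
  as.integer(cfg$window_samples %/% 2L + 1L - as.integer(cfg$drop_dc))
}

#' Time-frequency features of one multichannel segment
#'
#' Short-time Fourier transform per channel: the segment is cut into
#' overlapping tapered frames, transformed, reduced to the one-sided
#' spectrum (DC dropped by default) and mapped through the configured
#' magnitude function. For a 19-channel, 12-s segment at 250 Hz with
#' defaults the result is `[19, 23, 125]`.
#'
#' @param segment Numeric matrix `[n_channels, n_samples]`.
#' @param cfg An [stft_config()].
#' @return Numeric array `[n_channels, n_frames, n_freqs]` with an
#'   attribute `freqs_hz` when `fs` is supplied.
#' @param fs Optional sampling rate, used only to label frequencies.
#' @export
stft_features <- function(segment, cfg = stft_config(), fs = NULL) {
  segment <- as.matrix(segment)
  W <- cfg$window_samples
  L <- ncol(segment)
  if (W > L) {
    stop(sprintf("STFT window (%d) longer than segment (%d)", W, L),
         call. = FALSE)
  }
  hop <- stft_hop(cfg)
  nF <- stft_n_frames(L, cfg)
  nq <- W %/% 2L + 1L
  taper <- if (cfg$window_function == "hann") {
    0.5 - 0.5 * cos(2 * pi * (0:(W - 1L)) / W)   # periodic Hann
  } else rep(1, W)
  starts <- (seq_len(nF) - 1L) * hop
  frame_idx <- outer(seq_len(W), starts, "+")    # [W, nF]
  nch <- nrow(segment)
  keep <- if (cfg$drop_dc) 2:nq else 1:nq
  out <- array(0, dim = c(nch, nF, length(keep)))
  for (ch in seq_len(nch)) {
    Fm <- matrix(segment[ch, frame_idx], W, nF) * taper
    S <- stats::mvfft(Fm)[keep, , drop = FALSE]  # [freq, frame]
    mag <- Mod(S)
    mag <- switch(cfg$magnitude_mode,
                  magnitude = mag,
                  log_magnitude = log1p(mag),
                  power = mag^2)
    out[ch, , ] <- t(mag)
  }
  if (!is.null(fs)) {
    attr(out, "freqs_hz") <- (keep - 1L) * fs / W
  }
  out
}
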