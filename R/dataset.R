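#' Generate a labeled feature dataset through the full pipeline
#'
#' Emits `n_windows` 12-second windows: each window is synthesized
#' (background, plus one seizure burst for the windows drawn ictal, plus
#' optional blinks), optionally ICA-cleaned, then STFT-featurized and
#' optionally band-pooled. The number of seizure windows is
#' `round(n_windows * ictal_fraction)`, so the achieved label ratio is
#' within one window of the request. A manifest records the full generator
#' configuration.
#'
#' @param cfg A [sim_config()].
#' @param n_windows Number of 12-s windows.
#' @param ictal_fraction Fraction of windows containing a seizure.
#' @param seed Integer seed; every window derives its own sub-seed.
#' @param blinks Inject blink artifacts into each window.
#' @param ica_clean Run eye-artifact removal on each window before
#'   featurization (meaningful when `blinks = TRUE`; off by default
#'   because the generator emits blink-free windows unless asked).
#' @param stft An [stft_config()].
#' @param pool `NULL` for full `[19, 23, 125]` tensors, or a list of
#'   arguments for [pool_features()] (e.g. `list()` for the default
#'   band/time pooling).
#' @param window_s Window length in seconds.
#' @param shift Optional [ood_shift()] applied to `cfg` (used by
#'   [make_ood_dataset()]).
#' @param edf_dir Optional directory: the windows are concatenated into
#'   one EDF+ recording written there together with a sidecar annotation
#'   CSV and the manifest.
#' @return A list of class `eeg_dataset`: `x` (flattened feature matrix),
#'   `features` (list of tensors), `labels` (character), `y` (0/1),
#'   `manifest`.
#' @export
make_dataset <- function(cfg = sim_config(), n_windows = 400L,
                         ictal_fraction = 0.25, seed = cfg$seed,
                         blinks = FALSE, ica_clean = FALSE,
                         stft = stft_config(), pool = NULL,
                         window_s = 12, shift = NULL, edf_dir = NULL) {
  cfg <- apply_shift(cfg, shift)
  n_windows <- as.integer(n_windows)
  n_sz <- as.integer(round(n_windows * ictal_fraction))
  is_sz <- withr::with_seed(derive_seed(seed, 999L), {
    sample(rep(c(TRUE, FALSE), c(n_sz, n_windows - n_sz)))
  })
  w_samp <- as.integer(round(window_s * cfg$fs))
  features <- vector("list", n_windows)
  recs <- if (!is.null(edf_dir)) vector("list", n_windows) else NULL
  win_ann <- vector("list", n_windows)
  for (i in seq_len(n_windows)) {
    rec <- synth_window(cfg, window_s, is_sz[i], blinks,
                        seed = derive_seed(seed, i))
    win_ann[[i]] <- rec$annotations
    if (!is.null(recs)) recs[[i]] <- rec
    if (ica_clean) {
      rec <- clean_eye_artifacts(rec, n_components = cfg$n_channels,
                                 seed = derive_seed(seed, i))
    }
    fx <- stft_features(rec$signals[, seq_len(w_samp), drop = FALSE], stft)
    if (!is.null(pool)) fx <- do.call(pool_features, c(list(fx), pool))
    features[[i]] <- fx
  }
  labels <- ifelse(is_sz, "seizure", "background")
  manifest <- list(
    generator = unclass(cfg), n_windows = n_windows,
    ictal_fraction = ictal_fraction, achieved_fraction = mean(is_sz),
    seed = seed, blinks = blinks, ica_clean = ica_clean,
    stft = unclass(stft), pool = pool, window_s = window_s,
    shift = if (is.null(shift)) NULL else unclass(shift),
    flatten_order = "channel-major, then frame, then frequency (frequency fastest)"
  )
  out <- structure(
    list(x = flatten_features(features), features = features,
         labels = labels, y = as.integer(is_sz), manifest = manifest),
    class = "eeg_dataset"
  )
  if (!is.null(edf_dir)) {
    write_dataset_edf(recs, labels, cfg, manifest, edf_dir, window_s)
  }
  out
}

# one 12-s window; a seizure window carries a single burst whose interval
# overlaps the window by construction
synth_window <- function(cfg, window_s, seizure, blinks, seed) {
  rec <- gen_background(cfg, duration_s = window_s,
                        seed = derive_seed(seed, 1L))
  withr::with_seed(derive_seed(seed, 2L), {
    gains <- stats::runif(cfg$n_channels, cfg$channel_gain_range[1],
                          cfg$channel_gain_range[2])
    if (seizure) {
      d <- stats::runif(1, min(window_s * 0.5, 6), window_s)
      t0 <- stats::runif(1, 0, window_s - d)
      n <- as.integer(round(d * cfg$fs))
      a <- as.integer(round(t0 * cfg$fs))
      f0 <- stats::runif(1, cfg$seizure_freq_hz[1], cfg$seizure_freq_hz[2])
      burst <- spike_wave(n, cfg$fs, f0, stats::runif(1, 0, 2 * pi))
      w <- stats::runif(cfg$n_channels, 0.3, 1)
      sig <- rec$signals
      idx <- (a + 1L):(a + n)
      sig[, idx] <- sig[, idx] + draw_range(cfg$seizure_amp_uv) *
        tcrossprod(w, burst)
      rec <- eeg_recording(sig, cfg$fs, rec$channel_names,
                           data.frame(onset_s = a / cfg$fs,
                                      offset_s = (a + n) / cfg$fs,
                                      label = "seizure"),
                           rec$id)
    }
  })
  if (blinks) rec <- inject_blinks(rec, cfg, seed = derive_seed(seed, 3L))
  rec$signals <- rec$signals * gains
  rec
}

#' Generate an out-of-distribution dataset
#'
#' [make_dataset()] under an [ood_shift()]: the seizure fundamental moves
#' band, channel gains jitter, and the background slope changes. The
#' manifest records the shift. A zero shift with the same seed reproduces
#' [make_dataset()] exactly.
#'
#' @inheritParams make_dataset
#' @param shift An [ood_shift()].
#' @return An `eeg_dataset`.
#' @export
make_ood_dataset <- function(cfg = sim_config(), shift = ood_shift(),
                             n_windows = 400L, ictal_fraction = 0.25,
                             seed = cfg$seed, ...) {
  make_dataset(cfg, n_windows = n_windows, ictal_fraction = ictal_fraction,
               seed = seed, shift = shift, ...)
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset> %d windows (%d seizure), %d features each\n",
              length(x$labels), sum(x$y), ncol(x$x)))
  invisible(x)
}

write_dataset_edf <- function(recs, labels, cfg, manifest, dir, window_s) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- do.call(cbind, lapply(recs, `[[`, "signals"))
  ann <- do.call(rbind, lapply(seq_along(recs), function(i) {
    a <- recs[[i]]$annotations
    if (nrow(a)) {
      a$onset_s <- a$onset_s + (i - 1) * window_s
      a$offset_s <- a$offset_s + (i - 1) * window_s
    }
    a
  }))
  rec <- eeg_recording(sig, cfg$fs, recs[[1]]$channel_names, ann,
                       id = "synthetic-dataset")
  write_edf(rec, file.path(dir, "recording.edf"))
  utils::write.csv(ann, file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
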