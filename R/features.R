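#' Flatten a list of feature tensors into a model input matrix
#'
#' Flattening order is channel-major, then frame, then frequency (i.e. the
#' frequency index varies fastest), recorded so checkpoints are portable.
#'
#' @param tensors List of `[n_channels, n_frames, n_freqs]` arrays, or a
#'   single such array.
#' @return Numeric matrix `[n_windows, n_channels*n_frames*n_freqs]`.
#' @export
flatten_features <- function(tensors) {
  if (is.array(tensors) && length(dim(tensors)) == 3L) {
    tensors <- list(tensors)
  }
  t(vapply(tensors, function(a) as.numeric(aperm(a, c(3, 2, 1))),
           numeric(length(tensors[[1]]))))
}

#' Feature standardization statistics
#'
#' Per-feature mean and standard deviation computed on the training split
#' only; the identical affine transform is then applied everywhere (the
#' transform is deliberately not idempotent — applying saved stats twice
#' rescales twice). Standard deviations below `eps` are floored, so a
#' constant feature maps to 0.
#'
#' @param x Training feature matrix `[n, p]`.
#' @param eps Floor for the per-feature standard deviation.
#' @return An object of class `feature_stats` (`mean`, `sd`, `eps`).
#' @export
feature_stats <- function(x, eps = 1e-6) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- sqrt(pmax(colMeans(x^2) - mu^2, 0)) * sqrt(nrow(x) / max(nrow(x) - 1, 1))
  structure(list(mean = mu, sd = sd, eps = eps), class = "feature_stats")
}

#' Apply standardization statistics
#'
#' @param x Feature matrix `[n, p]`.
#' @param stats A [feature_stats()] object (computed on the training
#'   split).
#' @return Standardized matrix of the same shape.
#' @export
standardize_features <- function(x, stats) {
  stopifnot(inherits(stats, "feature_stats"))
  x <- as.matrix(x)
  if (ncol(x) != length(stats$mean)) {
    stop(sprintf("feature count %d does not match stats (%d)",
                 ncol(x), length(stats$mean)), call. = FALSE)
  }
  sweep(sweep(x, 2, stats$mean), 2, pmax(stats$sd, stats$eps), "/")
}

#' Pool STFT tensors into coarse band-power features
#'
#' Desk-scale summarization of the full `[19, 23, 125]` tensor: frequencies
#' are averaged within canonical EEG bands and frames within a few coarse
#' time bins, giving compact inputs that keep the spectral structure
#' seizure detection relies on while making wide baseline architectures
#' trainable on one CPU.
#'
#' @param tensor A `[n_channels, n_frames, n_freqs]` array (frequency bins
#'   assumed 1 Hz apart starting at 1 Hz, the default STFT layout at
#'   250 Hz).
#' @param bands_hz List of `c(lo, hi)` frequency bands (upper edge
#'   exclusive); defaults to delta, theta, alpha, beta, low/high gamma.
#' @param n_time_bins Number of coarse time bins frames are averaged into.
#' @return A `[n_channels, n_time_bins, length(bands_hz)]` array.
#' @export
pool_features <- function(tensor,
                          bands_hz = list(c(1, 4), c(4, 8), c(8, 13),
                                          c(13, 30), c(30, 60), c(60, 126)),
                          n_time_bins = 4L) {
  d <- dim(tensor)
  freqs <- seq_len(d[3])
  tcut <- cut(seq_len(d[2]), breaks = n_time_bins, labels = FALSE)
  out <- array(0, dim = c(d[1], n_time_bins, length(bands_hz)))
  for (b in seq_along(bands_hz)) {
    fidx <- which(freqs >= bands_hz[[b]][1] & freqs < bands_hz[[b]][2])
    for (tt in seq_len(n_time_bins)) {
      block <- tensor[, tcut == tt, fidx, drop = FALSE]
      out[, tt, b] <- apply(block, 1, mean)
    }
  }
  out
}
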