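#' Independent component analysis of an EEG recording
#'
#' Decomposes the centered channels x samples data `T` into
#' `T ~ M %*% A`: `M` holds the component time courses (columns,
#' unit variance) and `A` the topographic weights (one row per component,
#' one column per channel). The algorithm is a seeded FastICA: PCA
#' whitening followed by a fixed-point iteration with the logcosh
#' contrast, extracting components one at a time (deflation).
#'
#' To make runs reproducible the inherent ICA ambiguities are fixed by
#' convention: components are ordered by descending explained variance
#' (row sum of squares of `A`, with unit-variance time courses), and each
#' topography's largest-magnitude weight is made positive.
#'
#' @param rec An [eeg_recording()] (or a plain `[n_channels, n_samples]`
#'   matrix).
#' @param n_components Number of components (19 for the standard montage;
#'   must not exceed the channel count).
#' @param seed Integer seed for the random initial unmixing directions.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return An object of class `ica_decomposition`: `M` `[n_samples,
#'   n_components]`, `A` `[n_components, n_channels]`, `center`,
#'   `eye_scores` (NA until scored), `rejected` (empty), `residual`
#'   (relative reconstruction error), `converged`.
#' @export
run_ica <- function(rec, n_components = 19L, seed = 1L,
                    max_iter = 200L, tol = 1e-7) {
  X <- if (inherits(rec, "eeg_recording")) rec$signals else as.matrix(rec)
  n_ch <- nrow(X); n_s <- ncol(X)
  n_components <- as.integer(n_components)
  if (n_components > n_ch) {
    stop(sprintf("n_components (%d) exceeds channel count (%d)",
                 n_components, n_ch), call. = FALSE)
  }
  center <- rowMeans(X)
  Xc <- X - center
  # PCA whitening
  C <- Xc %*% t(Xc) / n_s
  eg <- eigen(C, symmetric = TRUE)
  ev <- eg$values[seq_len(n_components)]
  if (any(ev < 1e-12 * max(ev))) {
    stop(paste("rank-deficient data: a channel (or combination) is",
               "constant; reduce n_components"), call. = FALSE)
  }
  Kw <- diag(1 / sqrt(ev), n_components) %*%
    t(eg$vectors[, seq_len(n_components), drop = FALSE])   # whitening
  Z <- Kw %*% Xc                                           # [comp, samples]
  W <- withr::with_seed(seed, {
    matrix(stats::rnorm(n_components^2), n_components, n_components)
  })
  converged <- logical(n_components)
  for (p in seq_len(n_components)) {
    w <- W[p, ]
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wx <- drop(w %*% Z)
      g <- tanh(wx)
      gp <- 1 - g^2
      w_new <- drop(Z %*% g) / n_s - mean(gp) * w
      if (p > 1L) {     # deflation: orthogonalize against found rows
        Wp <- W[seq_len(p - 1L), , drop = FALSE]
        w_new <- w_new - drop(t(Wp) %*% (Wp %*% w_new))
      }
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- abs(abs(sum(w_new * w)) - 1)
      w <- w_new
      if (delta < tol) { converged[p] <- TRUE; break }
    }
    W[p, ] <- w
  }
  S <- W %*% Z                                  # unit-variance sources
  sds <- sqrt(pmax(rowMeans(S^2) - rowMeans(S)^2, 1e-300))
  S <- S / sds
  # mixing back to channel space: Xc ~ t(A) %*% S  with A [comp, ch]
  A <- t(Xc %*% t(S) %*% diag(1 / n_s, nrow(S)))
  # fix order (descending variance contribution) and sign
  pow <- rowSums(A^2)
  ord <- order(pow, decreasing = TRUE)
  A <- A[ord, , drop = FALSE]
  S <- S[ord, , drop = FALSE]
  sgn <- apply(A, 1, function(a) sign(a[which.max(abs(a))]))
  sgn[sgn == 0] <- 1
  A <- A * sgn
  S <- S * sgn
  M <- t(S)
  recon <- M %*% A
  residual <- sqrt(sum((t(Xc) - recon)^2) / max(sum(Xc^2), 1e-300))
  structure(
    list(M = M, A = A, center = center,
         channel_names = if (inherits(rec, "eeg_recording"))
           rec$channel_names else rownames(X),
         eye_scores = rep(NA_real_, n_components),
         rejected = integer(0), residual = residual,
         converged = converged, seed = seed),
    class = "ica_decomposition"
  )
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf(
    "<ica_decomposition> %d components, rel. residual %.3g, %d rejected\n",
    ncol(x$M), x$residual, length(x$rejected)))
  invisible(x)
}

#' Pearson correlation coefficient
#'
#' Plain textbook Pearson r; zero-variance input yields 0 with a warning
#' rather than NA so artifact screening degrades gracefully.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  stopifnot(length(a) == length(b))
  va <- stats::var(a); vb <- stats::var(b)
  if (is.na(va) || is.na(vb) || va == 0 || vb == 0) {
    warning("zero-variance input: Pearson r reported as 0")
    return(0)
  }
  stats::cor(a, b)
}

#' Score components against the fronto-polar channels
#'
#' For each independent component, the maximum absolute Pearson
#' correlation of its time course with the FP1 and FP2 signals — the
#' screen used to flag eye-movement components.
#'
#' @param dec An [run_ica()] decomposition.
#' @param rec The recording it was computed from (must contain FP1, FP2).
#' @return The decomposition with `eye_scores` filled in.
#' @export
score_eye_components <- function(dec, rec) {
  ch <- rec$channel_names
  if (!all(c("FP1", "FP2") %in% ch)) {
    stop("recording must contain FP1 and FP2 channels", call. = FALSE)
  }
  fp1 <- rec$signals[match("FP1", ch), ]
  fp2 <- rec$signals[match("FP2", ch), ]
  dec$eye_scores <- vapply(seq_len(ncol(dec$M)), function(c) {
    max(abs(pearson_r(dec$M[, c], fp1)), abs(pearson_r(dec$M[, c], fp2)))
  }, numeric(1))
  dec
}

#' Remove eye components and rebuild the recording
#'
#' Zeroes every component whose eye score meets the threshold (or, in
#' top-k mode, the k highest-scoring components) and reconstructs the
#' channel signals from the remainder. Channel count, sampling
#' rate and annotations are preserved.
#'
#' @param dec A scored [ica_decomposition][run_ica()].
#' @param rec The originating [eeg_recording()].
#' @param threshold Reject components with `eye_scores >= threshold`
#'   (default 0.8, in `(0, 1]`).
#' @param top_k Alternative rejection mode: reject the `top_k`
#'   highest-scoring components instead of thresholding.
#' @return A cleaned [eeg_recording()]; the rejected indices are attached
#'   as attribute `"rejected"`.
#' @export
remove_components <- function(dec, rec, threshold = 0.8, top_k = NULL) {
  if (anyNA(dec$eye_scores)) {
    stop("decomposition is unscored: call score_eye_components() first",
         call. = FALSE)
  }
  if (is.null(top_k)) {
    if (threshold <= 0 || threshold > 1) {
      stop("`threshold` must be in (0, 1]", call. = FALSE)
    }
    rejected <- which(dec$eye_scores >= threshold)
  } else {
    rejected <- utils::head(order(dec$eye_scores, decreasing = TRUE),
                            top_k)
  }
  if (length(rejected) == ncol(dec$M)) {
    stop("all components rejected: refusing to emit an all-zero recording",
         call. = FALSE)
  }
  keep <- setdiff(seq_len(ncol(dec$M)), rejected)
  recon <- dec$M[, keep, drop = FALSE] %*% dec$A[keep, , drop = FALSE]
  sig <- t(recon) + dec$center
  out <- eeg_recording(sig, rec$fs, rec$channel_names, rec$annotations,
                       rec$id)
  attr(out, "rejected") <- rejected
  out
}

#' One-call eye-artifact cleaning of a recording
#'
#' Convenience wrapper: [run_ica()], [score_eye_components()],
#' [remove_components()].
#'
#' @inheritParams run_ica
#' @inheritParams remove_components
#' @return A cleaned [eeg_recording()].
#' @export
clean_eye_artifacts <- function(rec, n_components = 19L, threshold = 0.8,
                                seed = 1L) {
  dec <- run_ica(rec, n_components = n_components, seed = seed)
  dec <- score_eye_components(dec, rec)
  remove_components(dec, rec, threshold = threshold)
}
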