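#' Assemble class-balanced train/validation/test splits
#'
#' Subsamples the available windows to the target background:seizure
#' ratio (75:25 by default), shuffles with the given seed, and partitions
#' into disjoint splits. If the requested ratio is infeasible with the
#' windows at hand, the majority class is what gets subsampled; when even
#' that cannot reach the ratio an error states the achievable maximum.
#'
#' @param x Feature matrix `[n, p]`.
#' @param labels Binary labels (1/`"seizure"` = seizure).
#' @param class_ratio Numeric pair `c(background, seizure)` target
#'   proportions.
#' @param fractions Numeric triple summing to 1: train/val/test share.
#' @param seed Integer seed.
#' @return A list with elements `train`, `val`, `test`, each a list
#'   `(x, y)`, plus `indices` giving the original row of every kept
#'   window.
#' @export
assemble_splits <- function(x, labels, class_ratio = c(75, 25),
                            fractions = c(0.7, 0.15, 0.15), seed = 1L) {
  x <- as.matrix(x)
  y <- as_binary_labels(labels)
  stopifnot(nrow(x) == length(y), length(class_ratio) == 2L,
            abs(sum(fractions) - 1) < 1e-9)
  bg <- which(y == 0L); sz <- which(y == 1L)
  if (!length(sz) || !length(bg)) {
    stop("need at least one window of each class", call. = FALSE)
  }
  r <- class_ratio[1] / class_ratio[2]       # background per seizure
  n_bg <- length(bg); n_sz <- length(sz)
  if (n_bg / n_sz >= r) {
    n_bg_keep <- min(n_bg, as.integer(floor(n_sz * r)))
    n_sz_keep <- n_sz
  } else {
    n_sz_keep <- as.integer(floor(n_bg / r))
    n_bg_keep <- n_bg
    if (n_sz_keep < 1L) {
      stop(sprintf(
        "ratio %g:%g infeasible: only %d background windows for %d seizure; achievable background share at most %.1f%%",
        class_ratio[1], class_ratio[2], n_bg, n_sz, 100 * n_bg / (n_bg + 1)),
        call. = FALSE)
    }
  }
  withr::with_seed(seed, {
    bg_keep <- sample(bg, n_bg_keep)
    sz_keep <- sample(sz, n_sz_keep)
    idx <- sample(c(bg_keep, sz_keep))
  })
  n <- length(idx)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  parts <- list(
    train = idx[seq_len(n_train)],
    val = idx[n_train + seq_len(n_val)],
    test = idx[setdiff(seq_len(n), seq_len(n_train + n_val))]
  )
  out <- lapply(parts, function(ii) list(x = x[ii, , drop = FALSE],
                                         y = y[ii]))
  out$indices <- parts
  out
}
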