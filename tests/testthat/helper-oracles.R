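# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths: scalar recursions and double loops only.

# Textbook Cox-de Boor recursion, one basis function at a time.
oracle_bspline <- function(x, knots, i, k) {
  if (k == 0) {
    return(as.numeric(x >= knots[i] & x < knots[i + 1]))
  }
  d1 <- knots[i + k] - knots[i]
  d2 <- knots[i + k + 1] - knots[i + 1]
  a <- if (d1 > 0) (x - knots[i]) / d1 * oracle_bspline(x, knots, i, k - 1) else 0
  b <- if (d2 > 0) (knots[i + k + 1] - x) / d2 *
    oracle_bspline(x, knots, i + 1, k - 1) else 0
  a + b
}

oracle_basis_row <- function(x, knots, k) {
  nb <- length(knots) - 1 - k
  vapply(seq_len(nb), function(i) oracle_bspline(x, knots, i, k), numeric(1))
}

# Double-loop layer forward: scalar edge activations summed at each node.
oracle_layer_forward <- function(layer, x) {
  vapply(seq_len(layer$out_dim), function(i) {
    sum(vapply(seq_len(layer$in_dim), function(j) {
      edge_activation(x[j], edge_coeffs(layer, i, j),
                      layer$base_weight[j, i], layer$spline_scale[j, i],
                      layer$cfg)
    }, numeric(1)))
  }, numeric(1))
}

oracle_model_forward <- function(model, x) {
  h <- x
  for (layer in model$layers) h <- oracle_layer_forward(layer, h)
  h
}

# Pairwise-comparison AUROC: mean over all (pos, neg) pairs with half
# credit for ties.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force PR curve: precision/recall at every unique threshold
# (descending), step integration over recall increments.
oracle_auprc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  n_pos <- sum(labels == 1)
  for (th in ths) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Textbook Pearson correlation.
oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

band_power <- function(x, fs, lo, hi) {
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  sum(p[f >= lo & f <= hi])
}
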