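#' Create one KAN layer
#'
#' A KAN layer maps an `in_dim` vector to an `out_dim` vector by summing,
#' at each output node, learnable univariate activations evaluated on each
#' input: `y_i = sum_j phi_ij(x_j)`. Each edge activation is
#' `phi_ij(x) = base_weight[i,j] * b(x) +
#'  spline_scale[i,j] * sum_c coef[i,j,c] * B_c(x)`
#' with `b` the configured residual base function and `B_c` the shared
#' B-spline basis of the layer.
#'
#' Internally the spline coefficients are stored as an array
#' `[n_basis, in_dim, out_dim]` so the batched forward pass is a single
#' matrix product; [edge_coeffs()] gives the per-edge view.
#'
#' @param in_dim,out_dim Fan-in and fan-out of the layer.
#' @param cfg A [spline_config()].
#' @param init `"random"` (default), or `"zero"` for all-zero parameters
#'   (useful to build identity/pass-through layers by hand).
#' @return An object of class `kan_layer`.
#' @export
kan_layer <- function(in_dim, out_dim, cfg = spline_config(),
                      init = c("random", "zero")) {
  init <- match.arg(init)
  in_dim <- as.integer(in_dim); out_dim <- as.integer(out_dim)
  stopifnot(in_dim >= 1L, out_dim >= 1L)
  nb <- n_basis(cfg)
  if (init == "random") {
    # small spline noise; Glorot-style scale for the residual branch
    coef <- array(stats::rnorm(nb * in_dim * out_dim, sd = 0.1 / sqrt(in_dim)),
                  dim = c(nb, in_dim, out_dim))
    lim <- sqrt(6 / (in_dim + out_dim))
    base_weight <- matrix(stats::runif(in_dim * out_dim, -lim, lim),
                          in_dim, out_dim)
  } else {
    coef <- array(0, dim = c(nb, in_dim, out_dim))
    base_weight <- matrix(0, in_dim, out_dim)
  }
  structure(
    list(in_dim = in_dim, out_dim = out_dim, cfg = cfg,
         grid = extend_grid(cfg),
         coef = coef,
         base_weight = base_weight,
         spline_scale = matrix(1, in_dim, out_dim)),
    class = "kan_layer"
  )
}

#' @export
print.kan_layer <- function(x, ...) {
  cat(sprintf("<kan_layer> %d -> %d, %d basis fns/edge, %d parameters\n",
              x$in_dim, x$out_dim, n_basis(x$cfg), layer_n_params(x)))
  invisible(x)
}

layer_n_params <- function(layer) {
  length(layer$coef) + length(layer$base_weight) + length(layer$spline_scale)
}

#' Spline coefficients of a single edge
#'
#' @param layer A [kan_layer()].
#' @param i Output node index; `j` input node index.
#' @param j Input node index.
#' @return Numeric vector of length `n_basis(layer$cfg)`.
#' @export
edge_coeffs <- function(layer, i, j) layer$coef[, j, i]

#' Evaluate one edge activation
#'
#' The scalar function a single KAN edge applies to its input:
#' residual base branch plus the spline expansion. Linear in the spline
#' coefficients.
#'
#' @param x Numeric vector of inputs.
#' @param coeffs Spline coefficient vector (length `n_basis(cfg)`).
#' @param base_weight,scale Scalars multiplying the base branch and the
#'   spline sum.
#' @param cfg A [spline_config()].
#' @return Numeric vector, `phi(x)`.
#' @export
#' @examples
#' cfg <- spline_config()
#' edge_activation(c(-0.5, 0, 0.5), rep(0, n_basis(cfg)), 1, 1, cfg)  # = silu
edge_activation <- function(x, coeffs, base_weight = 0, scale = 1,
                            cfg = spline_config()) {
  stopifnot(length(coeffs) == n_basis(cfg),
            all(is.finite(coeffs)), is.finite(base_weight), is.finite(scale))
  B <- bspline_basis(x, cfg)
  drop(base_weight * base_fun(x, cfg$base_function) +
         scale * (B %*% coeffs))
}

# Basis expansion of a batch X [n, in_dim] laid out to match the stacked
# coefficient matrix: returns [n, n_basis * in_dim] with basis index
# fastest. With deriv = TRUE also the derivative expansion.
basis_expand <- function(X, cfg, grid, deriv = FALSE) {
  n <- nrow(X); p <- ncol(X); nb <- length(grid) - 1L - cfg$spline_order
  r <- bspline_basis(as.numeric(X), grid = grid, order = cfg$spline_order,
                     deriv = deriv)
  reshape <- function(B) {
    dim(B) <- c(n, p, nb)
    B <- aperm(B, c(1, 3, 2))
    dim(B) <- c(n, nb * p)
    B
  }
  if (deriv) list(values = reshape(r$values), deriv = reshape(r$deriv))
  else reshape(r)
}

# Stacked effective coefficient matrix [n_basis*in_dim, out_dim] with the
# per-edge scale folded in.
layer_weight_matrix <- function(layer) {
  nb <- n_basis(layer$cfg)
  W <- layer$coef
  dim(W) <- c(nb * layer$in_dim, layer$out_dim)
  W * layer$spline_scale[rep(seq_len(layer$in_dim), each = nb), , drop = FALSE]
}

#' Layer forward pass
#'
#' Applies `y_i = sum_j phi_ij(x_j)` to a single input vector or to a batch
#' (rows = samples). Batched evaluation is exactly the per-sample map
#' applied row-wise.
#'
#' @param layer A [kan_layer()].
#' @param x Numeric vector of length `in_dim`, or a matrix
#'   `[n, in_dim]`.
#' @param cache If `TRUE`, attach the intermediates needed for
#'   backpropagation as an attribute (used by the trainer).
#' @return Vector of length `out_dim`, or matrix `[n, out_dim]`.
#' @export
layer_forward <- function(layer, x, cache = FALSE) {
  vec_in <- is.null(dim(x))
  X <- if (vec_in) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != layer$in_dim) {
    stop(sprintf("input has %d features but layer expects in_dim = %d",
                 ncol(X), layer$in_dim), call. = FALSE)
  }
  be <- basis_expand(X, layer$cfg, layer$grid, deriv = cache)
  Bas <- if (cache) be$values else be
  W <- layer_weight_matrix(layer)
  Y <- Bas %*% W
  if (layer$cfg$base_function != "none") {
    Y <- Y + base_fun(X, layer$cfg$base_function) %*% layer$base_weight
  }
  if (cache) {
    attr(Y, "cache") <- list(X = X, Bas = Bas, Bas_d = be$deriv, W = W)
  }
  if (vec_in && !cache) drop(Y) else Y
}

# Backward pass for one layer. dY [n, out_dim]; cache from layer_forward.
# Returns gradients for coef and base_weight plus dX for the layer below.
# spline_scale is treated as a fixed (non-trained) rescaling.
layer_backward <- function(layer, dY, cache, need_dx = TRUE) {
  nb <- n_basis(layer$cfg)
  dW <- crossprod(cache$Bas, dY)              # [nb*in, out]
  scale_rows <- layer$spline_scale[rep(seq_len(layer$in_dim), each = nb), ,
                                   drop = FALSE]
  dcoef <- dW * scale_rows
  dim(dcoef) <- dim(layer$coef)
  dbase <- NULL
  if (layer$cfg$base_function != "none") {
    dbase <- crossprod(base_fun(cache$X, layer$cfg$base_function), dY)
  } else {
    dbase <- matrix(0, layer$in_dim, layer$out_dim)
  }
  dX <- NULL
  if (need_dx) {
    P <- dY %*% t(cache$W)                    # [n, nb*in]
    M <- P * cache$Bas_d
    dim(M) <- c(nrow(M), nb, layer$in_dim)
    dX <- colSums(aperm(M, c(2, 1, 3)))       # sum over basis index
    if (layer$cfg$base_function != "none") {
      dX <- dX + (dY %*% t(layer$base_weight)) *
        base_fun_deriv(cache$X, layer$cfg$base_function)
    }
  }
  list(coef = dcoef, base_weight = dbase, dX = dX)
}
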