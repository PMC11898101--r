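#' Spline configuration for KAN edge activations
#'
#' Every edge of a KAN carries a univariate activation parametrized on a
#' B-spline basis over a fixed grid, optionally summed with a residual
#' "base" branch (a fixed nonlinearity with a learnable linear weight).
#' This object collects the spline hyperparameters shared by a model.
#'
#' @param grid_size Number of grid intervals G between `grid_range[1]` and
#'   `grid_range[2]`. Each edge then has `grid_size + spline_order` basis
#'   functions.
#' @param spline_order Polynomial degree k of the basis (3 = cubic).
#' @param grid_range Length-2 numeric, the nominal input range `(lo, hi)`.
#'   Inputs are expected to be standardized, so the default (-1, 1) covers
#'   the bulk of the mass; values outside are handled by linear
#'   extrapolation of the boundary polynomial piece.
#' @param base_function Residual branch applied alongside the spline:
#'   `"silu"` (x * sigmoid(x), the default), `"identity"`, or `"none"`.
#' @param grid_update If `TRUE`, training may adapt the grid to input
#'   quantiles between epochs. Off by default so runs are deterministic.
#'
#' @return An object of class `spline_config`.
#' @export
#' @examples
#' spline_config(grid_size = 5, spline_order = 3)
spline_config <- function(grid_size = 5L, spline_order = 3L,
                          grid_range = c(-1, 1),
                          base_function = c("silu", "identity", "none"),
                          grid_update = FALSE) {
  base_function <- match.arg(base_function)
  grid_size <- as.integer(grid_size)
  spline_order <- as.integer(spline_order)
  if (grid_size < 1L) stop("`grid_size` (G) must be >= 1", call. = FALSE)
  if (spline_order < 0L) stop("`spline_order` (k) must be >= 0", call. = FALSE)
  if (length(grid_range) != 2L || !all(is.finite(grid_range)) ||
      grid_range[1] >= grid_range[2]) {
    stop("`grid_range` must be a finite pair (lo, hi) with lo < hi",
         call. = FALSE)
  }
  structure(
    list(grid_size = grid_size, spline_order = spline_order,
         grid_range = as.numeric(grid_range), base_function = base_function,
         grid_update = isTRUE(grid_update)),
    class = "spline_config"
  )
}

#' @export
print.spline_config <- function(x, ...) {
  cat(sprintf(
    "<spline_config> G=%d, k=%d, range=[%g, %g], base=%s, n_basis=%d\n",
    x$grid_size, x$spline_order, x$grid_range[1], x$grid_range[2],
    x$base_function, x$grid_size + x$spline_order))
  invisible(x)
}

#' Number of B-spline basis functions per edge
#'
#' @param cfg A [spline_config()].
#' @return Integer, `grid_size + spline_order`.
#' @export
n_basis <- function(cfg) cfg$grid_size + cfg$spline_order

# Extended knot vector: base knots lo..hi split into G uniform intervals,
# padded with k extra uniform knots on each side so that G + k degree-k
# basis functions have support intersecting [lo, hi].
extend_grid <- function(cfg) {
  h <- diff(cfg$grid_range) / cfg$grid_size
  seq(cfg$grid_range[1] - cfg$spline_order * h,
      cfg$grid_range[2] + cfg$spline_order * h,
      by = h)
}

# Cox-de Boor evaluation of all degree-`order` B-spline basis functions on
# the knot vector `grid`, vectorized over x. Returns a matrix
# [length(x), length(grid) - 1 - order]. Assumes x within [min(grid),
# max(grid)); callers handle extrapolation.
cox_de_boor <- function(x, grid, order) {
  m <- length(x)
  nk <- length(grid)
  # degree 0: half-open interval indicators
  B <- outer(x, grid[-nk], ">=") & outer(x, grid[-1], "<")
  storage.mode(B) <- "double"
  if (order == 0L) return(B)
  for (d in seq_len(order)) {
    ncol_new <- nk - 1L - d
    left_den <- grid[(1L + d):(ncol_new + d)] - grid[1:ncol_new]
    right_den <- grid[(2L + d):(ncol_new + d + 1L)] - grid[2:(ncol_new + 1L)]
    idx <- 1:ncol_new
    left <- (x - rep(grid[idx], each = m)) * B[, idx, drop = FALSE] /
      rep(left_den, each = m)
    right <- (rep(grid[idx + d + 1L], each = m) - x) *
      B[, idx + 1L, drop = FALSE] / rep(right_den, each = m)
    left[!is.finite(left)] <- 0
    right[!is.finite(right)] <- 0
    B <- left + right
    dim(B) <- c(m, ncol_new)
  }
  B
}

#' Evaluate the B-spline basis underlying a KAN edge
#'
#' Computes the values of all `G + k` basis functions at each point of `x`,
#' on the uniformly extended knot vector implied by `cfg` (or an explicit
#' knot vector `grid`). For degree k >= 1 the basis is a partition of unity
#' on `grid_range`. Outside the grid range each basis function is continued
#' by first-order Taylor expansion at the nearest boundary (linear
#' extrapolation of the outermost polynomial piece), which keeps values and
#' first derivatives defined for arbitrarily standardized inputs.
#'
#' @param x Numeric vector of evaluation points (must be finite).
#' @param cfg A [spline_config()]; ignored if `grid` is given.
#' @param grid Optional explicit strictly increasing knot vector, already
#'   extended; the basis then has `length(grid) - 1 - order` functions.
#' @param order Spline degree; defaults to `cfg$spline_order`.
#' @param deriv If `TRUE`, also return the first derivatives.
#'
#' @return A matrix `[length(x), n_basis]`, or if `deriv` a list with
#'   elements `values` and `deriv` of that shape.
#' @export
#' @examples
#' cfg <- spline_config(grid_size = 5, spline_order = 3)
#' b <- bspline_basis(seq(-0.9, 0.9, by = 0.3), cfg)
#' rowSums(b)  # partition of unity: all 1
bspline_basis <- function(x, cfg = spline_config(), grid = NULL,
                          order = NULL, deriv = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("`x` must be finite numeric (no NA/NaN/Inf)", call. = FALSE)
  }
  if (is.null(grid)) {
    order <- cfg$spline_order
    grid <- extend_grid(cfg)
    lo <- cfg$grid_range[1]; hi <- cfg$grid_range[2]
  } else {
    if (is.null(order)) stop("`order` required with an explicit `grid`",
                             call. = FALSE)
    order <- as.integer(order)
    lo <- grid[1L + order]
    hi <- grid[length(grid) - order]
  }
  if (length(grid) < 2L) {
    stop("knot vector must contain at least 2 points", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) {
    stop("knot vector must be strictly increasing", call. = FALSE)
  }
  xc <- pmin(pmax(x, lo), hi * (1 - 1e-12) + lo * 1e-12)
  # keep strictly below the last base knot so the half-open indicator at
  # degree 0 lands in a valid interval; hi itself maps to the last piece
  xc <- pmin(xc, max(grid) - .Machine$double.eps * max(1, abs(max(grid))) * 4)
  B <- cox_de_boor(xc, grid, order)
  need_d <- deriv || any(x != xc)
  Bd <- NULL
  if (need_d) Bd <- bspline_deriv_at(xc, grid, order)
  out_idx <- which(x != xc)
  if (length(out_idx)) {
    dx <- x[out_idx] - xc[out_idx]
    B[out_idx, ] <- B[out_idx, , drop = FALSE] +
      Bd[out_idx, , drop = FALSE] * dx
    # derivative is held constant beyond the boundary (linear continuation)
  }
  if (deriv) list(values = B, deriv = Bd) else B
}

# First derivatives of the degree-`order` basis at points x (assumed inside
# the knot span): d/dx B_{i,k} = k * (B_{i,k-1}/(t_{i+k}-t_i)
#                                     - B_{i+1,k-1}/(t_{i+k+1}-t_{i+1})).
bspline_deriv_at <- function(x, grid, order) {
  m <- length(x)
  nb <- length(grid) - 1L - order
  if (order == 0L) return(matrix(0, m, nb))
  Blow <- cox_de_boor(x, grid, order - 1L)
  idx <- 1:nb
  den1 <- grid[idx + order] - grid[idx]
  den2 <- grid[idx + order + 1L] - grid[idx + 1L]
  D <- order * (sweep(Blow[, idx, drop = FALSE], 2, den1, "/") -
                  sweep(Blow[, idx + 1L, drop = FALSE], 2, den2, "/"))
  D[!is.finite(D)] <- 0
  D
}

# silu (swish) base function and derivative
silu <- function(x) x * stats::plogis(x)
silu_deriv <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

base_fun <- function(x, kind) {
  switch(kind,
         silu = silu(x),
         identity = x,
         none = 0 * x)
}
base_fun_deriv <- function(x, kind) {
  switch(kind,
         silu = silu_deriv(x),
         identity = 1 + 0 * x,
         none = 0 * x)
}
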