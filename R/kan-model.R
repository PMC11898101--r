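#' Build a KAN model from an architecture string
#'
#' The architecture grammar is `"I-<w1>-...-O"`: `I` resolves to
#' `input_dim`, `O` to `output_dim`, and the interior tokens are hidden
#' widths. `"I-O"` is the minimal single-layer network. The default output
#' dimension is 2 (seizure / non-seizure class scores, mapped to
#' probabilities by softmax downstream).
#'
#' @param spec Architecture string, e.g. `"I-32-16-O"`.
#' @param input_dim,output_dim Integers resolved for `I` and `O`.
#' @param cfg A [spline_config()] shared by all layers.
#' @param seed Optional integer; when given, parameter initialization is
#'   reproducible (the global RNG state is left untouched).
#' @return An object of class `kan_model`.
#' @export
#' @examples
#' m <- kan_model("I-4-O", input_dim = 3, output_dim = 2, seed = 1)
#' model_forward(m, c(0.1, -0.2, 0.3))
kan_model <- function(spec, input_dim, output_dim = 2L,
                      cfg = spline_config(), seed = NULL) {
  widths <- c(as.integer(input_dim), parse_arch_spec(spec),
              as.integer(output_dim))
  build <- function() {
    layers <- vector("list", length(widths) - 1L)
    for (t in seq_along(layers)) {
      layers[[t]] <- kan_layer(widths[t], widths[t + 1L], cfg)
    }
    layers
  }
  layers <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  structure(
    list(layers = layers, spec = spec,
         input_dim = as.integer(input_dim),
         output_dim = as.integer(output_dim), cfg = cfg),
    class = "kan_model"
  )
}

#' Exact Kolmogorov-Arnold representation form
#'
#' Constructs the two-layer network with the classical widths of the
#' superposition theorem: `n` inputs, `2n + 1` intermediate nodes, one
#' output, i.e. `f(x) = sum_q Phi_q( sum_p phi_qp(x_p) )` with
#' `q = 1..2n+1`.
#'
#' @param n Input dimension.
#' @inheritParams kan_model
#' @return A `kan_model` with widths `n -> 2n+1 -> 1`.
#' @export
kan_exact_form <- function(n, cfg = spline_config(), seed = NULL) {
  kan_model(sprintf("I-%d-O", 2L * as.integer(n) + 1L),
            input_dim = n, output_dim = 1L, cfg = cfg, seed = seed)
}

# "I-<ints>-O" -> integer vector of hidden widths (possibly empty)
parse_arch_spec <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || is.na(spec)) {
    stop("architecture spec must be a single string like \"I-32-16-O\"",
         call. = FALSE)
  }
  toks <- strsplit(trimws(spec), "-", fixed = TRUE)[[1]]
  if (length(toks) < 2L || toupper(toks[1]) != "I" ||
      toupper(toks[length(toks)]) != "O") {
    stop(sprintf("malformed architecture spec '%s': expected \"I-...-O\"",
                 spec), call. = FALSE)
  }
  hidden <- toks[-c(1L, length(toks))]
  if (!length(hidden)) return(integer(0))
  w <- suppressWarnings(as.integer(hidden))
  bad <- is.na(w) | w < 1L | hidden != as.character(w)
  if (any(bad)) {
    stop(sprintf("malformed architecture spec '%s': bad width token '%s'",
                 spec, hidden[which(bad)[1]]), call. = FALSE)
  }
  w
}

#' @export
print.kan_model <- function(x, ...) {
  widths <- c(x$input_dim, vapply(x$layers, `[[`, 1L, "out_dim"))
  cat(sprintf("<kan_model> %s  (%s), %d parameters\n", x$spec,
              paste(widths, collapse = " -> "),
              sum(vapply(x$layers, layer_n_params, 1L))))
  invisible(x)
}

#' Model forward pass
#'
#' Composes the layer maps; accepts a single input vector or a batch
#' matrix (rows = samples). Deterministic given the parameters.
#'
#' @param model A [kan_model()].
#' @param x Numeric vector of length `input_dim` or matrix
#'   `[n, input_dim]`.
#' @return Class-score vector of length `output_dim` or matrix
#'   `[n, output_dim]`.
#' @export
model_forward <- function(model, x) {
  vec_in <- is.null(dim(x))
  h <- if (vec_in) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(h) != model$input_dim) {
    stop(sprintf("input has %d features but model expects input_dim = %d",
                 ncol(h), model$input_dim), call. = FALSE)
  }
  for (layer in model$layers) h <- layer_forward(layer, h)
  if (vec_in) drop(h) else h
}

#' Seizure-class probabilities
#'
#' Softmax over the two output scores; column 2 (or the single output for
#' one-output models) is the seizure-class probability used as the
#' detector score.
#'
#' @param model A trained [kan_model()].
#' @param x Feature matrix `[n, input_dim]`.
#' @return Numeric vector of length `n`.
#' @export
predict_seizure_prob <- function(model, x) {
  s <- model_forward(model, x)
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  if (ncol(s) == 1L) return(drop(stats::plogis(s)))
  p <- softmax_rows(s)
  p[, ncol(p)]
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Architecture accounting
#'
#' Parses an architecture string and reports layer count, total hidden
#' neurons, and the exact parameter count of the concrete spline
#' parametrization (per edge: `G + k` spline coefficients, one base
#' weight, one spline scale). With a `baseline` spec, also reports hidden
#' neurons and parameters as percentages of the baseline, rounded half-up
#' to two decimals.
#'
#' @param spec Architecture string.
#' @param input_dim,output_dim Dimensions substituted for `I` and `O`
#'   (defaults: the 19-channel, 23-frame, 125-bin STFT input flattened,
#'   and 2 classes).
#' @param cfg A [spline_config()].
#' @param baseline Optional architecture string to compare against.
#' @return A one-row tibble of class `arch_stats`.
#' @export
#' @examples
#' arch_stats("I-32-32-O", baseline = "I-764-256-O")$neuron_reduction_pct
arch_stats <- function(spec, input_dim = 19L * 23L * 125L, output_dim = 2L,
                       cfg = spline_config(), baseline = NULL) {
  count <- function(s) {
    hidden <- parse_arch_spec(s)
    widths <- c(input_dim, hidden, output_dim)
    nb <- n_basis(cfg)
    edges <- sum(widths[-length(widths)] * widths[-1])
    # "layers" follows the conventional architecture-table accounting:
    # the number of hidden layers
    list(n_layers = length(hidden),
         hidden = sum(hidden),
         params = edges * (nb + 2L))
  }
  s <- count(spec)
  out <- tibble::tibble(
    spec = spec, n_layers = s$n_layers, hidden_neurons = s$hidden,
    n_parameters = s$params,
    neuron_reduction_pct = NA_real_, param_reduction_pct = NA_real_
  )
  if (!is.null(baseline)) {
    b <- count(baseline)
    out$neuron_reduction_pct <- round_half_up(100 * s$hidden / b$hidden, 2)
    out$param_reduction_pct <- round_half_up(100 * s$params / b$params, 2)
  }
  class(out) <- c("arch_stats", class(out))
  out
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# --- parameter vector helpers (used by the trainer and finite-difference
# --- checks): flatten/unflatten trainable parameters (coef + base_weight)

model_params <- function(model) {
  unlist(lapply(model$layers, function(l) c(l$coef, l$base_weight)))
}

model_set_params <- function(model, theta) {
  pos <- 0L
  for (t in seq_along(model$layers)) {
    l <- model$layers[[t]]
    nc <- length(l$coef)
    model$layers[[t]]$coef[] <- theta[pos + seq_len(nc)]
    pos <- pos + nc
    nb <- length(l$base_weight)
    model$layers[[t]]$base_weight[] <- theta[pos + seq_len(nb)]
    pos <- pos + nb
  }
  stopifnot(pos == length(theta))
  model
}

#' Save / load a KAN model checkpoint
#'
#' The checkpoint is a single self-describing file (uncompressed R
#' serialization, version 3) holding a format tag, the [spline_config()],
#' the architecture spec and all parameter tensors, plus any
#' standardization statistics attached to the model. Round-trips are
#' bit-exact and byte-stable: saving the same model twice yields identical
#' files.
#'
#' @param model A [kan_model()].
#' @param path File path.
#' @return `save_kan` returns `path` invisibly; `load_kan` the model.
#' @export
save_kan <- function(model, path) {
  stopifnot(inherits(model, "kan_model"))
  obj <- list(format = "eegkan-checkpoint", version = 1L, model = model)
  saveRDS(obj, path, compress = FALSE, version = 3L)
  invisible(path)
}

#' @rdname save_kan
#' @export
load_kan <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop(sprintf("'%s' is missing or empty: not a KAN checkpoint", path),
         call. = FALSE)
  }
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("'%s' is not a readable KAN checkpoint (%s)", path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "eegkan-checkpoint")) {
    stop(sprintf("'%s' is not an eegkan checkpoint", path), call. = FALSE)
  }
  if (!identical(obj$version, 1L)) {
    stop(sprintf("checkpoint format version %s not supported",
                 format(obj$version)), call. = FALSE)
  }
  obj$model
}
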