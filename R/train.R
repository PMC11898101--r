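#' Training configuration
#'
#' @param epochs Maximum number of passes over the training set.
#' @param batch_size Minibatch size.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param lr Learning rate.
#' @param seed Integer seed controlling initialization-independent
#'   randomness of the run (shuffling); the model seed is separate.
#' @param early_stop Patience in epochs on validation AUROC: training
#'   stops once AUROC has not improved for this many consecutive epochs,
#'   and the best-AUROC weights are kept (set `Inf` to disable). Default:
#'   10, capped at `epochs`.
#' @param class_ratio Target background:seizure ratio used by
#'   [assemble_splits()]; recorded here so a run config is self-contained.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L,
                         optimizer = c("adam", "sgd"), lr = 1e-3,
                         seed = 1L, early_stop = NULL,
                         class_ratio = c(75, 25)) {
  optimizer <- match.arg(optimizer)
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  if (is.null(early_stop)) early_stop <- min(10L, epochs)
  if (batch_size < 1L) stop("`batch_size` must be >= 1", call. = FALSE)
  if (is.finite(early_stop) && early_stop > epochs) {
    stop("`early_stop` patience cannot exceed `epochs`", call. = FALSE)
  }
  structure(
    list(epochs = epochs, batch_size = as.integer(batch_size),
         optimizer = optimizer, lr = lr, seed = as.integer(seed),
         early_stop = early_stop, class_ratio = class_ratio),
    class = "train_config"
  )
}

# mean softmax cross-entropy over 2+ classes; returns loss and dScores
softmax_xent <- function(scores, labels) {
  n <- nrow(scores)
  P <- softmax_rows(scores)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dS <- P
  dS[idx] <- dS[idx] - 1
  list(loss = loss, grad = dS / n)
}

# Forward + backward through the whole model; returns loss and per-layer
# gradients (coef, base_weight). Used by the trainer and by the
# finite-difference tests.
model_loss_grad <- function(model, X, labels) {
  nl <- length(model$layers)
  caches <- vector("list", nl)
  h <- X
  for (t in seq_len(nl)) {
    h <- layer_forward(model$layers[[t]], h, cache = TRUE)
    caches[[t]] <- attr(h, "cache")
    attr(h, "cache") <- NULL
  }
  ce <- softmax_xent(h, labels)
  grads <- vector("list", nl)
  dY <- ce$grad
  for (t in rev(seq_len(nl))) {
    g <- layer_backward(model$layers[[t]], dY, caches[[t]], need_dx = t > 1L)
    grads[[t]] <- list(coef = g$coef, base_weight = g$base_weight)
    dY <- g$dX
  }
  list(loss = ce$loss, grads = grads)
}

adam_init <- function(model) {
  lapply(model$layers, function(l) list(
    m_coef = array(0, dim(l$coef)), v_coef = array(0, dim(l$coef)),
    m_bw = matrix(0, nrow(l$base_weight), ncol(l$base_weight)),
    v_bw = matrix(0, nrow(l$base_weight), ncol(l$base_weight))))
}

adam_step <- function(model, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(model$layers)) {
    s <- state[[i]]; g <- grads[[i]]
    s$m_coef <- beta1 * s$m_coef + (1 - beta1) * g$coef
    s$v_coef <- beta2 * s$v_coef + (1 - beta2) * g$coef^2
    model$layers[[i]]$coef <- model$layers[[i]]$coef -
      lr * (s$m_coef / bc1) / (sqrt(s$v_coef / bc2) + eps)
    s$m_bw <- beta1 * s$m_bw + (1 - beta1) * g$base_weight
    s$v_bw <- beta2 * s$v_bw + (1 - beta2) * g$base_weight^2
    model$layers[[i]]$base_weight <- model$layers[[i]]$base_weight -
      lr * (s$m_bw / bc1) / (sqrt(s$v_bw / bc2) + eps)
    state[[i]] <- s
  }
  list(model = model, state = state)
}

sgd_step <- function(model, grads, lr) {
  for (i in seq_along(model$layers)) {
    model$layers[[i]]$coef <- model$layers[[i]]$coef - lr * grads[[i]]$coef
    model$layers[[i]]$base_weight <- model$layers[[i]]$base_weight -
      lr * grads[[i]]$base_weight
  }
  model
}

#' Train a KAN seizure classifier
#'
#' Minimizes softmax cross-entropy with minibatch Adam (or SGD), evaluates
#' the validation metrics after every epoch, applies the AUROC-patience
#' early-stopping rule of [select_weights()], and returns the weights from
#' the best validation-AUROC epoch (the epoch at which AUROC stopped
#' increasing). Deterministic given the seeds and single-threaded BLAS.
#'
#' @param model A [kan_model()]; `input_dim` must match `ncol(x_train)`.
#' @param x_train,y_train Training feature matrix `[n, input_dim]` and
#'   binary labels (1 = seizure).
#' @param x_val,y_val Validation split, used for per-epoch metrics and
#'   weight selection. If omitted, the final-epoch weights are returned
#'   and the history carries training loss only.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return A list of class `kan_fit`: `model` (selected weights),
#'   `final_model` (last epoch), `history` (tibble, one row per epoch),
#'   `selected_epoch`, `config`.
#' @export
train_kan <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                      cfg = train_config(), verbose = FALSE) {
  x_train <- as.matrix(x_train)
  y_train <- as_binary_labels(y_train)
  stopifnot(nrow(x_train) == length(y_train))
  if (ncol(x_train) != model$input_dim) {
    stop(sprintf("features have %d columns but model input_dim is %d",
                 ncol(x_train), model$input_dim), call. = FALSE)
  }
  has_val <- !is.null(x_val)
  if (has_val) {
    x_val <- as.matrix(x_val); y_val <- as_binary_labels(y_val)
  }
  n <- nrow(x_train)
  state <- if (cfg$optimizer == "adam") adam_init(model) else NULL
  step_t <- 0L
  hist <- vector("list", cfg$epochs)
  best_auroc <- -Inf; best_epoch <- NA_integer_; best_model <- model
  run <- function() {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        ix <- perm[s:min(s + cfg$batch_size - 1L, n)]
        lg <- model_loss_grad(model, x_train[ix, , drop = FALSE], y_train[ix])
        if (!is.finite(lg$loss)) {
          stop(sprintf(
            "non-finite training loss (epoch %d, batch at %d, lr %g)",
            epoch, s, cfg$lr), call. = FALSE)
        }
        ep_loss <- ep_loss + lg$loss * length(ix)
        if (cfg$optimizer == "adam") {
          step_t <<- step_t + 1L
          up <- adam_step(model, lg$grads, state, cfg$lr, step_t)
          model <<- up$model; state <<- up$state
        } else {
          model <<- sgd_step(model, lg$grads, cfg$lr)
        }
      }
      row <- tibble::tibble(epoch = epoch, train_loss = ep_loss / n,
                            auroc = NA_real_, auprc = NA_real_,
                            precision = NA_real_, recall = NA_real_,
                            f1 = NA_real_)
      if (has_val) {
        p <- predict_seizure_prob(model, x_val)
        em <- suppressMessages(compute_metrics(p, y_val))
        row[c("auroc", "auprc", "precision", "recall", "f1")] <-
          em[c("auroc", "auprc", "precision", "recall", "f1")]
        if (!is.na(em$auroc) && em$auroc > best_auroc) {
          best_auroc <<- em$auroc; best_epoch <<- epoch; best_model <<- model
        }
      }
      hist[[epoch]] <<- row
      if (verbose) {
        cat(sprintf("epoch %3d  loss %.4f  val AUROC %s\n", epoch,
                    row$train_loss,
                    if (is.na(row$auroc)) "-" else sprintf("%.4f", row$auroc)))
      }
      if (has_val && is.finite(cfg$early_stop) && !is.na(best_epoch) &&
          epoch - best_epoch >= cfg$early_stop) break
    }
  }
  withr::with_seed(cfg$seed, run())
  history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  if (!has_val || is.na(best_epoch)) {
    best_model <- model; best_epoch <- nrow(history)
  }
  structure(
    list(model = best_model, final_model = model, history = history,
         selected_epoch = best_epoch, config = cfg),
    class = "kan_fit"
  )
}

#' @export
print.kan_fit <- function(x, ...) {
  cat(sprintf("<kan_fit> %s, %d epoch(s) run, selected epoch %d\n",
              x$model$spec, nrow(x$history), x$selected_epoch))
  if (!all(is.na(x$history$auroc))) {
    cat(sprintf("  val AUROC at selection: %.4f\n",
                x$history$auroc[x$selected_epoch]))
  }
  invisible(x)
}

#' Select the weight epoch at which validation AUROC stopped increasing
#'
#' Scans a per-epoch AUROC sequence with a patience rule: the running best
#' epoch is tracked (ties keep the earliest), and scanning stops at the
#' first epoch lying `patience` epochs past the best. The selected epoch
#' is the best-AUROC epoch at that point. A monotone-increasing sequence
#' selects the last epoch; a constant sequence selects epoch 1.
#'
#' @param auroc Numeric vector of per-epoch validation AUROC, or a
#'   `kan_fit` history tibble with an `auroc` column.
#' @param patience Number of non-improving epochs tolerated.
#' @return Integer epoch index.
#' @export
#' @examples
#' select_weights(c(0.6, 0.8, 0.79, 0.78), patience = 2)  # 2
select_weights <- function(auroc, patience = 10L) {
  if (is.data.frame(auroc)) auroc <- auroc$auroc
  stopifnot(length(auroc) >= 1L, patience >= 1L)
  best <- 1L
  for (t in seq_along(auroc)) {
    if (auroc[t] > auroc[best]) best <- t
    if (t - best >= patience) return(best)
  }
  best
}

#' Fit a KAN to a real-valued target by full-batch Adam
#'
#' Least-squares regression with a single output node — the standard way
#' to verify that a small KAN recovers a smooth multivariate function.
#'
#' @param model A [kan_model()] with `output_dim = 1`.
#' @param x Input matrix `[n, input_dim]`.
#' @param y Numeric target vector.
#' @param iters Full-batch Adam iterations.
#' @param lr Learning rate.
#' @return The fitted model with the final mean-squared error attached as
#'   attribute `"mse"`.
#' @export
fit_kan_regression <- function(model, x, y, iters = 300L, lr = 0.02) {
  x <- as.matrix(x)
  stopifnot(model$output_dim == 1L, nrow(x) == length(y))
  n <- nrow(x)
  state <- adam_init(model)
  nl <- length(model$layers)
  mse <- NA_real_
  for (it in seq_len(iters)) {
    caches <- vector("list", nl)
    h <- x
    for (k in seq_len(nl)) {
      h <- layer_forward(model$layers[[k]], h, cache = TRUE)
      caches[[k]] <- attr(h, "cache"); attr(h, "cache") <- NULL
    }
    r <- drop(h) - y
    mse <- mean(r^2)
    dY <- matrix(2 * r / n, n, 1)
    grads <- vector("list", nl)
    for (k in rev(seq_len(nl))) {
      g <- layer_backward(model$layers[[k]], dY, caches[[k]], need_dx = k > 1L)
      grads[[k]] <- list(coef = g$coef, base_weight = g$base_weight)
      dY <- g$dX
    }
    up <- adam_step(model, grads, state, lr, it)
    model <- up$model; state <- up$state
  }
  attr(model, "mse") <- mse
  model
}

#' One-row summary of a fit
#'
#' @param x A `kan_fit`.
#' @return A one-row tibble: spec, epochs run, selected epoch and its
#'   validation metrics.
#' @export
fit_summary <- function(x) {
  stopifnot(inherits(x, "kan_fit"))
  sel <- x$selected_epoch
  tibble::tibble(
    spec = x$model$spec, epochs_run = nrow(x$history),
    selected_epoch = sel,
    val_auroc = x$history$auroc[sel], val_auprc = x$history$auprc[sel],
    final_train_loss = x$history$train_loss[nrow(x$history)]
  )
}

#' Plot a training history
#'
#' Training loss and validation AUROC per epoch, with the selected epoch
#' marked. Requires ggplot2.
#'
#' @param object A `kan_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kan_fit <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for autoplot()", call. = FALSE)
  }
  h <- object$history
  d <- rbind(
    data.frame(epoch = h$epoch, value = h$train_loss, metric = "train loss"),
    data.frame(epoch = h$epoch, value = h$auroc, metric = "val AUROC")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = epoch, y = value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_epoch, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

utils::globalVariables(c("epoch", "value"))
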