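#' Cross-entropy loss
#'
#' `H(p, q) = -sum_x p(x) log q(x)` with `p` the one-hot true
#' distribution, i.e. `-log q(true class)` per example, averaged over
#' the batch. Natural logarithm (nats). Predicted probabilities are
#' floored at `1e-12` so a confident wrong prediction yields a large
#' finite loss rather than `Inf`.
#'
#' @param probs n x 2 matrix of predicted class probabilities.
#' @param labels Integer labels in \{0, 1\} (fused = 0, flickering = 1).
#' @return Mean cross-entropy in nats.
#' @examples
#' cross_entropy(matrix(c(0.5, 0.5), 1), 1L)   # log(2)
#' cross_entropy(matrix(c(0.25, 0.75), 1), 1L) # -log(0.75)
#' @export
cross_entropy <- function(probs, labels) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  stopifnot(nrow(probs) == length(labels), all(labels %in% c(0L, 1L)))
  q <- probs[cbind(seq_len(nrow(probs)), as.integer(labels) + 1L)]
  mean(-log(pmax(q, 1e-12)))
}

#' Evaluate a model on a minibatch
#'
#' @param model A `crnn_model`.
#' @param batch A `flicker_minibatch`.
#' @param chunk_size Examples per forward chunk.
#' @return List with `loss` (mean cross-entropy) and `accuracy`
#'   (fraction of argmax-correct predictions).
#' @export
evaluate_model <- function(model, batch, chunk_size = 100L) {
  if (nrow(batch$x) == 0L) stop("empty minibatch")
  probs <- predict_probs(model, batch$x, chunk_size)
  pred <- max.col(probs, ties.method = "first") - 1L
  list(loss = cross_entropy(probs, batch$y),
       accuracy = mean(pred == batch$y))
}

# Adam optimizer state and update (keras-style defaults). Parameters
# are a two-level list: layer -> weight array.
.adam_init <- function(params) {
  lapply(params, function(layer) {
    lapply(layer, function(x) list(m = x * 0, v = x * 0))
  })
}

.adam_step <- function(params, grads, state, t, lr, beta1, beta2, eps) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    list(p = p, s = s)
  }
  for (layer in names(params)) {
    for (nm in names(params[[layer]])) {
      r <- upd(params[[layer]][[nm]], grads[[layer]][[nm]],
               state[[layer]][[nm]])
      params[[layer]][[nm]] <- r$p
      state[[layer]][[nm]] <- r$s
    }
  }
  list(params = params, state = state)
}

#' Train a CRNN on regenerated minibatches
#'
#' One iteration = one Adam update on a fresh 100-example training
#' minibatch (10 per PCF and label), followed by evaluation on a fresh
#' 500-example validation minibatch; both are regenerated from the CFF
#' bands at every iteration, so the network never sees the same
#' stimulus twice. Per-iteration minibatch seeds are derived
#' deterministically from the master seed and the iteration index, so a
#' fixed seed reproduces the whole training log.
#'
#' Weight snapshots are stored every `checkpoint_every` iterations so
#' [select_checkpoint()] can recover the weights of any logged
#' iteration.
#'
#' @param model A `crnn_model` (typically from [init_model()]).
#' @param table A [cff_table()].
#' @param intensity Training intensity in cd/ft^2 (a grid value). The
#'   two brightest intensities (5340, 534) train to low accuracy and
#'   are flagged with a message.
#' @param iterations Number of training iterations.
#' @param seed Master seed for minibatch generation and dropout.
#' @param geometry Optional geometry override (see [build_minibatch()]);
#'   must match the model's `input_len`.
#' @param n_train,n_val Examples per (PCF, label) cell (defaults 10/50).
#' @param batch_size Optimizer sub-batch size within each regenerated
#'   minibatch. `NULL` (default) performs one update on the whole
#'   minibatch per iteration; `32` reproduces the common stack
#'   behaviour of fitting a 100-example batch in shuffled sub-batches.
#' @param lr,beta1,beta2,eps Adam hyperparameters (defaults 0.001, 0.9,
#'   0.999, 1e-7).
#' @param fused_upper Validation fused-band dialect, see [label_ranges()].
#' @param checkpoint_every Snapshot cadence in iterations.
#' @param verbose Print progress every 50 iterations.
#' @return A `crnn_training` object: list with `log` (data.frame:
#'   iteration, train_loss, train_accuracy, val_loss, val_accuracy),
#'   `checkpoints` (named list of weight snapshots), `model` (final
#'   weights), and `config`.
#' @export
train_crnn <- function(model, table, intensity, iterations = 100L, seed = 1L,
                       geometry = NULL, n_train = 10L, n_val = 50L,
                       batch_size = NULL,
                       lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-7,
                       fused_upper = "absolute_100",
                       checkpoint_every = 1L, verbose = FALSE) {
  stopifnot(iterations >= 1L)
  if (intensity %in% c(5340, 534)) {
    message("note: intensity ", intensity,
            " cd/ft^2 is an expected-low-accuracy condition")
  }
  experiment <- model$spec$experiment
  geo <- geometry %||% experiment_geometry(experiment)
  if (geo$target_len != model$spec$input_len) {
    stop("geometry target_len (", geo$target_len,
         ") does not match model input_len (", model$spec$input_len, ")")
  }
  seed <- as.integer(seed)
  batch_seed <- function(iter, kind) {
    (abs(seed) * 7919L + iter * 2L + kind) %% .Machine$integer.max
  }

  params <- model$params
  state <- .adam_init(params)
  adam_t <- 0L
  log <- data.frame(iteration = seq_len(iterations), train_loss = NA_real_,
                    train_accuracy = NA_real_, val_loss = NA_real_,
                    val_accuracy = NA_real_)
  checkpoints <- list()

  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)  # dropout stream

  for (it in seq_len(iterations)) {
    tb <- build_minibatch(table, intensity, "training", experiment,
                          seed = batch_seed(it, 0L), n_per_cell = n_train,
                          geometry = geo, fused_upper = fused_upper)
    n_ex <- nrow(tb$x)
    ord <- if (is.null(batch_size)) list(seq_len(n_ex)) else {
      sh <- sample.int(n_ex)
      split(sh, ceiling(seq_along(sh) / batch_size))
    }
    it_loss <- 0; it_correct <- 0L
    for (idx in ord) {
      model$params <- params
      gr <- .crnn_grad(model, tb$x[idx, , drop = FALSE], tb$y[idx],
                       training = TRUE)
      if (!is.finite(gr$loss)) {
        stop("non-finite training loss at iteration ", it,
             "; aborting (check learning rate / inputs)")
      }
      pred <- max.col(gr$probs, ties.method = "first") - 1L
      it_loss <- it_loss + gr$loss * length(idx)
      it_correct <- it_correct + sum(pred == tb$y[idx])
      adam_t <- adam_t + 1L
      stepped <- .adam_step(params, gr$grads, state, adam_t, lr, beta1,
                            beta2, eps)
      params <- stepped$params
      state <- stepped$state
      if (experiment == 2) params$td$W[params$td$W < 0] <- 0  # kernel constraint
    }
    log$train_loss[it] <- it_loss / n_ex
    log$train_accuracy[it] <- it_correct / n_ex

    vb <- build_minibatch(table, intensity, "validation", experiment,
                          seed = batch_seed(it, 1L), n_per_cell = n_val,
                          geometry = geo, fused_upper = fused_upper)
    model$params <- params
    ev <- evaluate_model(model, vb)
    log$val_loss[it] <- ev$loss
    log$val_accuracy[it] <- ev$accuracy

    if (it %% checkpoint_every == 0L) {
      checkpoints[[as.character(it)]] <- params
    }
    if (verbose && it %% 50L == 0L) {
      cat(sprintf("iter %4d  train %.4f/%.3f  val %.4f/%.3f\n", it,
                  log$train_loss[it], log$train_accuracy[it],
                  log$val_loss[it], log$val_accuracy[it]))
    }
  }
  model$params <- params
  structure(list(log = log, checkpoints = checkpoints, model = model,
                 config = list(intensity = intensity, experiment = experiment,
                               iterations = iterations, seed = seed,
                               geometry = geo, n_train = n_train,
                               n_val = n_val, batch_size = batch_size,
                               adam = list(lr = lr, beta1 = beta1,
                                           beta2 = beta2, eps = eps),
                               fused_upper = fused_upper)),
            class = "crnn_training")
}

#' @export
print.crnn_training <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("CRNN training run: %d iterations, intensity %g cd/ft^2 (experiment %d)\n",
              n, x$config$intensity, x$config$experiment))
  cat(sprintf("  final val loss %.4f, val accuracy %.3f\n",
              x$log$val_loss[n], x$log$val_accuracy[n]))
  invisible(x)
}

# Gaussian smoothing with reflected boundaries; kernel truncated at
# 4 sigma, matching common discrete Gaussian filters.
.gaussian_smooth <- function(x, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
  # reflect: for r > n the reflection repeats; build by explicit folding
  pad <- function(i) {
    i <- abs(i - 1) %% (2 * (n - 1))
    ifelse(i >= n, 2 * (n - 1) - i, i) + 1
  }
  xi <- x[pad(seq(1 - r, n + r))]
  as.numeric(stats::filter(xi, k, sides = 2))[(r + 1):(r + n)]
}

#' Select a checkpoint from a training log
#'
#' Two selection rules: `"raw_min"` returns the iteration with the
#' lowest validation loss; `"gaussian_smoothed"` first convolves the
#' validation-loss curve with a Gaussian kernel (default sigma = 11
#' iterations, reflected boundaries) and returns the argmin of the
#' smoothed curve, which avoids selecting single-iteration dips in a
#' noisy loss trace. Ties break to the earliest iteration.
#'
#' @param run A `crnn_training` object, or a numeric validation-loss
#'   vector.
#' @param method `"raw_min"` or `"gaussian_smoothed"`.
#' @param sigma Gaussian sigma in iterations (default 11).
#' @return A `crnn_checkpoint`: list with `iteration`, `val_loss`,
#'   `val_accuracy` (when available), `smoothed_loss` (smoothed method),
#'   and `params` when the run stored a snapshot for that iteration.
#' @export
select_checkpoint <- function(run, method = c("raw_min", "gaussian_smoothed"),
                              sigma = 11) {
  method <- match.arg(method)
  if (is.numeric(run)) {
    losses <- run
    log <- NULL
  } else {
    log <- run$log
    losses <- log$val_loss
  }
  if (length(losses) == 0L) stop("empty training log")
  if (method == "raw_min" || length(losses) == 1L) {
    curve <- losses
  } else {
    curve <- .gaussian_smooth(losses, sigma)
  }
  it <- which.min(curve)
  out <- list(iteration = it, method = method,
              val_loss = losses[it],
              val_accuracy = if (!is.null(log)) log$val_accuracy[it] else NA_real_,
              smoothed_loss = if (method == "gaussian_smoothed") curve[it] else NA_real_)
  if (!is.numeric(run) && !is.null(run$checkpoints[[as.character(it)]])) {
    out$params <- run$checkpoints[[as.character(it)]]
  }
  structure(out, class = "crnn_checkpoint")
}

#' Restore the model at a selected checkpoint
#'
#' @param run A `crnn_training` object.
#' @param checkpoint A `crnn_checkpoint` from [select_checkpoint()].
#' @return A `crnn_model` carrying the checkpoint weights.
#' @export
checkpoint_model <- function(run, checkpoint) {
  if (is.null(checkpoint$params)) {
    stop("no weight snapshot stored for iteration ", checkpoint$iteration,
         "; lower checkpoint_every when training")
  }
  model <- run$model
  model$params <- checkpoint$params
  model
}
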