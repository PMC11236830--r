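#' Build a CRNN architecture specification
#'
#' Two fixed convolutional-recurrent architectures classify a flicker
#' stimulus time series as fused (0) or flickering (1):
#'
#' * Experiment 1: input (7168 samples) -> 1-D valid convolution
#'   (8 filters x 120 taps, leaky ReLU alpha = 0.3) -> simple recurrent
#'   cell final state (8 units, sigmoid, dropout 0.5) -> dense (8,
#'   sigmoid, dropout 0.5) -> output (2, softmax).
#' * Experiment 2: input (16384 samples at 0.5 ms) -> 1-D valid
#'   convolution (8 x 280, ReLU) -> time-distributed dense (4, ReLU,
#'   non-negative kernel constraint) -> simple recurrent cell final
#'   state (5 units, sigmoid, dropout 0.5) -> dense (5, sigmoid,
#'   dropout 0.5) -> output (2, softmax).
#'
#' All layers carry biases. Convolution is "valid" (no padding), so the
#' conv output has `input_len - kernel_len + 1` time steps. The
#' experiment-2 kernel length defaults to 280 taps (140 ms at 0.5 ms
#' sampling, and the value consistent with the published parameter count
#' 2248 = 8 x 281); `kernel_len = 140` reproduces the published conv
#' output length 16245 instead.
#'
#' `input_len` (and `kernel_len`) can be overridden to build
#' geometry-scaled variants of the same architecture for fast runs; the
#' layer structure and unit counts never change.
#'
#' @param experiment 1 or 2.
#' @param input_len Input length in samples (defaults: 7168 / 16384).
#' @param kernel_len Convolution kernel length (defaults: 120 / 280).
#' @return A `crnn_architecture` object: list of layer specifications
#'   with `experiment`, `input_len`, `dt_ms`.
#' @export
build_architecture <- function(experiment, input_len = NULL, kernel_len = NULL) {
  if (!experiment %in% c(1, 2)) stop("experiment must be 1 or 2")
  if (experiment == 1) {
    input_len <- input_len %||% 7168L
    kernel_len <- kernel_len %||% 120L
    layers <- list(
      list(kind = "input", width = 1L),
      list(kind = "conv1d", width = 8L, kernel_len = as.integer(kernel_len),
           activation = "leaky_relu", alpha = 0.3),
      list(kind = "rnn_final_state", width = 8L, activation = "sigmoid",
           dropout = 0.5),
      list(kind = "dense", width = 8L, activation = "sigmoid", dropout = 0.5),
      list(kind = "output", width = 2L, activation = "softmax"))
    dt_ms <- 1
  } else {
    input_len <- input_len %||% 16384L
    kernel_len <- kernel_len %||% 280L
    layers <- list(
      list(kind = "input", width = 1L),
      list(kind = "conv1d", width = 8L, kernel_len = as.integer(kernel_len),
           activation = "relu"),
      list(kind = "td_dense", width = 4L, activation = "relu",
           kernel_constraint = "nonnegative"),
      list(kind = "rnn_final_state", width = 5L, activation = "sigmoid",
           dropout = 0.5),
      list(kind = "dense", width = 5L, activation = "sigmoid", dropout = 0.5),
      list(kind = "output", width = 2L, activation = "softmax"))
    dt_ms <- 0.5
  }
  if (input_len <= kernel_len) stop("input_len must exceed kernel_len")
  structure(list(experiment = experiment, input_len = as.integer(input_len),
                 dt_ms = dt_ms, layers = layers),
            class = "crnn_architecture")
}

#' Conv-layer output length under valid convolution
#' @param spec A `crnn_architecture`.
#' @return `input_len - kernel_len + 1`.
#' @export
conv_output_len <- function(spec) {
  spec$input_len - spec$layers[[2]]$kernel_len + 1L
}

#' Count trainable parameters per layer
#'
#' Closed-form counts: convolution `filters * (kernel_len + 1)` (single
#' input channel, one bias per filter); dense and time-distributed dense
#' `in * out + out`; simple recurrent cell `in * units + units^2 +
#' units`.
#'
#' @param spec A `crnn_architecture`.
#' @return A data.frame with columns `layer`, `kind`, `params`, and the
#'   total in `attr(, "total")`.
#' @examples
#' count_parameters(build_architecture(1))$params  # 968 136 72 18
#' @export
count_parameters <- function(spec) {
  widths <- vapply(spec$layers, function(l) l$width, integer(1))
  out <- data.frame(layer = seq_along(spec$layers) - 1L,
                    kind = vapply(spec$layers, `[[`, "", "kind"),
                    params = 0L)
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    out$params[i] <- switch(l$kind,
      input = 0L,
      conv1d = l$width * (l$kernel_len + 1L),
      td_dense = widths[i - 1] * l$width + l$width,
      rnn_final_state = widths[i - 1] * l$width + l$width * l$width + l$width,
      dense = widths[i - 1] * l$width + l$width,
      output = widths[i - 1] * l$width + l$width)
  }
  out$params <- as.integer(out$params)
  attr(out, "total") <- sum(out$params)
  out
}

# Uniform fan-based (Glorot) initial weights.
.glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Random orthogonal matrix (QR of a Gaussian draw, sign-fixed), the
# standard initializer for recurrent kernels.
.orthogonal <- function(n) {
  qr_ <- qr(matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), n)
}

#' Initialize an untrained model
#'
#' Follows the customary initialization of the deep-learning stacks this
#' model family comes from: feed-forward and convolution kernels are
#' drawn from the uniform fan-based (Glorot) scheme, the recurrent
#' kernel is a random orthogonal matrix, and all biases start at zero.
#' The same seed reproduces the same model bit-for-bit; untrained models
#' serve as the random-weight baselines of the probe analyses.
#'
#' @param spec A `crnn_architecture`.
#' @param seed Integer seed.
#' @return A `crnn_model`: list with `spec` and `params` (named list of
#'   weight matrices/vectors per layer).
#' @export
init_model <- function(spec, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  widths <- vapply(spec$layers, function(l) l$width, integer(1))
  params <- list()
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind == "conv1d") {
      params$conv <- list(
        K = .glorot(l$kernel_len, l$width, l$kernel_len, l$kernel_len * l$width),
        b = rep(0, l$width))
    } else if (l$kind == "td_dense") {
      nin <- widths[i - 1]
      params$td <- list(W = .glorot(nin, l$width, nin, l$width),
                        b = rep(0, l$width))
    } else if (l$kind == "rnn_final_state") {
      nin <- widths[i - 1]
      params$rnn <- list(W = .glorot(nin, l$width, nin, l$width),
                         U = .orthogonal(l$width),
                         b = rep(0, l$width))
    } else if (l$kind == "dense") {
      nin <- widths[i - 1]
      params$dense <- list(W = .glorot(nin, l$width, nin, l$width),
                           b = rep(0, l$width))
    } else if (l$kind == "output") {
      nin <- widths[i - 1]
      params$out <- list(W = .glorot(nin, l$width, nin, l$width),
                         b = rep(0, l$width))
    }
  }
  structure(list(spec = spec, params = params), class = "crnn_model")
}

#' @export
print.crnn_model <- function(x, ...) {
  pc <- count_parameters(x$spec)
  cat(sprintf("CRNN (experiment %d geometry, input %d samples @ %g ms): %d parameters\n",
              x$spec$experiment, x$spec$input_len, x$spec$dt_ms,
              attr(pc, "total")))
  print(pc)
  invisible(x)
}

.act <- function(x, kind, alpha = 0.3) {
  switch(kind,
         relu = pmax(x, 0),
         leaky_relu = pmax(x, 0) + alpha * pmin(x, 0),
         sigmoid = 1 / (1 + exp(-x)),
         none = x)
}
.act_grad <- function(pre, kind, alpha = 0.3) {
  switch(kind,
         relu = (pre > 0) + 0,
         leaky_relu = (pre > 0) + alpha * (pre <= 0),
         none = pre * 0 + 1)
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Internal full forward pass. X: (n, T) matrix. Returns probabilities
# and, if taps = TRUE, the post-activation conv tap (To, F, n), the
# time-distributed dense tap (experiment 2), the RNN final state and
# the dense hidden activations. Dropout is applied only when
# `dropout_masks` are supplied (training); probes always run in
# inference mode.
.crnn_forward <- function(model, X, taps = TRUE, dropout_masks = NULL,
                          want_pre = FALSE) {
  spec <- model$spec
  p <- model$params
  conv_layer <- spec$layers[[2]]
  if (ncol(X) != spec$input_len) {
    stop("stimulus length ", ncol(X), " does not match architecture input_len ",
         spec$input_len)
  }
  conv_pre <- conv1d_forward_cpp(X, p$conv$K, p$conv$b)
  A1 <- .act(conv_pre, conv_layer$activation, conv_layer$alpha %||% 0.3)

  if (spec$experiment == 2) {
    td_pre <- td_dense_forward_cpp(A1, p$td$W, p$td$b)
    A2 <- .act(td_pre, "relu")
    rnn_in <- A2
  } else {
    td_pre <- NULL
    A2 <- NULL
    rnn_in <- A1
  }

  H <- rnn_forward_cpp(rnn_in, p$rnn$W, p$rnn$U, p$rnn$b)
  Tn <- dim(H)[1]
  hT <- t(H[Tn, , , drop = TRUE])          # (n, u); t() also fixes n = 1
  if (dim(H)[3] == 1L) hT <- matrix(H[Tn, , 1], nrow = 1)

  rate <- 0.5
  hT_d <- if (!is.null(dropout_masks)) hT * dropout_masks$rnn / (1 - rate) else hT
  dense_pre <- sweep(hT_d %*% p$dense$W, 2, p$dense$b, `+`)
  D <- .act(dense_pre, "sigmoid")
  D_d <- if (!is.null(dropout_masks)) D * dropout_masks$dense / (1 - rate) else D
  logits <- sweep(D_d %*% p$out$W, 2, p$out$b, `+`)
  probs <- .softmax(logits)

  out <- list(probs = probs)
  if (taps) {
    out$taps <- list(conv = A1, td = A2, rnn_final = hT, dense = D)
  }
  if (want_pre) {
    out$cache <- list(conv_pre = conv_pre, A1 = A1, td_pre = td_pre, A2 = A2,
                      H = H, hT = hT, hT_d = hT_d, dense_pre = dense_pre,
                      D = D, D_d = D_d)
  }
  out
}

#' Forward pass with activation taps
#'
#' Runs a stimulus (or a batch) through the model in inference mode
#' (dropout disabled) and returns the class probabilities together with
#' the intermediate-layer activations used by the probe analyses: the
#' post-activation convolution output for every filter, the
#' time-distributed dense output ("layer 2", experiment 2 only), the
#' final recurrent state and the dense hidden activations.
#'
#' @param model A `crnn_model`.
#' @param stim A `flicker_stimulus`, a numeric vector, or an examples x
#'   samples matrix whose width equals the architecture `input_len`.
#' @return List with `probs` (n x 2 matrix, rows sum to 1; columns =
#'   fused, flickering) and `taps` (`conv`: array time x filter x
#'   example; `td`: array or NULL; `rnn_final`, `dense`: n x units).
#' @export
forward_with_taps <- function(model, stim) {
  X <- .as_input_matrix(stim)
  .crnn_forward(model, X, taps = TRUE)
}

.as_input_matrix <- function(stim) {
  if (inherits(stim, "flicker_stimulus")) {
    matrix(stim$samples, nrow = 1)
  } else if (is.matrix(stim)) {
    stim
  } else {
    matrix(as.numeric(stim), nrow = 1)
  }
}

#' Convolution-layer tap for a stimulus of any length
#'
#' Applies only the (trained or untrained) convolution filters and their
#' activation to a stimulus. Because the convolution is length-agnostic,
#' probe stimuli may be longer or shorter than the classifier's input
#' length; only `length >= kernel_len` is required.
#'
#' @param model A `crnn_model`.
#' @param stim A `flicker_stimulus` or numeric vector.
#' @return Matrix (time x filter) of post-activation conv outputs.
#' @export
conv_tap <- function(model, stim) {
  x <- if (inherits(stim, "flicker_stimulus")) stim$samples else as.numeric(stim)
  l <- model$spec$layers[[2]]
  pre <- conv1d_forward_cpp(matrix(x, nrow = 1), model$params$conv$K,
                            model$params$conv$b)
  m <- pre[, , 1]
  if (is.null(dim(m))) m <- matrix(m, ncol = dim(pre)[2])
  .act(m, l$activation, l$alpha %||% 0.3)
}

#' Layer-2 (time-distributed dense) tap, experiment 2
#'
#' @param model An experiment-2 `crnn_model`.
#' @param stim A `flicker_stimulus` or numeric vector.
#' @return Matrix (time x unit) of post-ReLU layer-2 outputs.
#' @export
td_tap <- function(model, stim) {
  if (model$spec$experiment != 2) {
    stop("the time-distributed dense layer exists only in experiment 2")
  }
  A1 <- conv_tap(model, stim)
  pre <- sweep(A1 %*% model$params$td$W, 2, model$params$td$b, `+`)
  .act(pre, "relu")
}

# Loss, probabilities and parameter gradients for one labeled batch.
# Dropout masks are drawn from the current RNG stream.
.crnn_grad <- function(model, X, y, training = TRUE) {
  spec <- model$spec
  p <- model$params
  n <- nrow(X)
  rate <- 0.5
  masks <- if (training) {
    list(rnn = matrix(stats::rbinom(n * ncol(p$rnn$U), 1, 1 - rate),
                      n, ncol(p$rnn$U)),
         dense = matrix(stats::rbinom(n * ncol(p$dense$W), 1, 1 - rate),
                        n, ncol(p$dense$W)))
  } else NULL
  fw <- .crnn_forward(model, X, taps = FALSE, dropout_masks = masks,
                      want_pre = TRUE)
  cc <- fw$cache
  probs <- fw$probs
  loss <- cross_entropy(probs, y)

  onehot <- matrix(0, n, 2)
  onehot[cbind(seq_len(n), y + 1L)] <- 1
  dlogits <- (probs - onehot) / n

  g <- list()
  g$out <- list(W = t(cc$D_d) %*% dlogits, b = colSums(dlogits))
  dD_d <- dlogits %*% t(p$out$W)
  dD <- if (training) dD_d * masks$dense / (1 - rate) else dD_d
  dpre_dense <- dD * cc$D * (1 - cc$D)
  g$dense <- list(W = t(cc$hT_d) %*% dpre_dense, b = colSums(dpre_dense))
  dhT_d <- dpre_dense %*% t(p$dense$W)
  dhT <- if (training) dhT_d * masks$rnn / (1 - rate) else dhT_d

  rnn_in <- if (spec$experiment == 2) cc$A2 else cc$A1
  rb <- rnn_backward_cpp(rnn_in, cc$H, p$rnn$W, p$rnn$U, dhT)
  g$rnn <- list(W = rb$dW, U = rb$dU, b = as.numeric(rb$db))

  if (spec$experiment == 2) {
    dA2 <- rb$dZ
    dpre_td <- dA2 * .act_grad(cc$td_pre, "relu")
    tb <- td_dense_backward_cpp(cc$A1, p$td$W, dpre_td)
    g$td <- list(W = tb$dW, b = as.numeric(tb$db))
    dA1 <- tb$dZ
  } else {
    dA1 <- rb$dZ
  }
  conv_layer <- spec$layers[[2]]
  dpre_conv <- dA1 * .act_grad(cc$conv_pre, conv_layer$activation,
                               conv_layer$alpha %||% 0.3)
  cb <- conv1d_backward_cpp(X, dpre_conv, conv_layer$kernel_len)
  g$conv <- list(K = cb$dK, b = as.numeric(cb$db))

  list(loss = loss, probs = probs, grads = g)
}

#' Classify stimuli with a model
#'
#' Inference-mode forward pass in memory-bounded chunks.
#'
#' @param model A `crnn_model`.
#' @param x Examples x samples matrix, vector, or `flicker_stimulus`.
#' @param chunk_size Examples per forward chunk.
#' @return n x 2 matrix of class probabilities (fused, flickering).
#' @export
predict_probs <- function(model, x, chunk_size = 100L) {
  X <- .as_input_matrix(x)
  n <- nrow(X)
  out <- matrix(NA_real_, n, 2)
  for (s in seq(1, n, by = chunk_size)) {
    e <- min(s + chunk_size - 1, n)
    out[s:e, ] <- .crnn_forward(model, X[s:e, , drop = FALSE],
                                taps = FALSE)$probs
  }
  colnames(out) <- c("fused", "flickering")
  out
}
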