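# Shared fixtures: the packaged CFF grid, the scaled experiment-1
# geometry used for fast training runs, and tiny architectures for
# oracle checks. Everything is generated in code at test time.

fixture_table <- function() cff_table()

scaled_geometry <- function() {
  list(dt_ms = 1, source_len = 12000L, target_len = 1024L,
       max_crop = 3000L, max_fill = 500L)
}

tiny_geometry <- function() {
  list(dt_ms = 1, source_len = 2000L, target_len = 256L,
       max_crop = 100L, max_fill = 20L)
}

tiny_model <- function(experiment = 1, input_len = 256L, kernel_len = 16L,
                       seed = 1L) {
  init_model(build_architecture(experiment, input_len = input_len,
                                kernel_len = kernel_len), seed = seed)
}

# Brute-force valid cross-correlation oracle (the deep-learning "conv"
# convention): y[t, f] = sum_j x[t + j - 1] K[j, f] + b[f].
brute_conv <- function(x, K, b) {
  To <- length(x) - nrow(K) + 1L
  y <- matrix(NA_real_, To, ncol(K))
  for (f in seq_len(ncol(K))) {
    for (t in seq_len(To)) {
      y[t, f] <- sum(x[t:(t + nrow(K) - 1L)] * K[, f]) + b[f]
    }
  }
  y
}
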