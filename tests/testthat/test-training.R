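test_that("cross-entropy matches its closed form on hand cases", {
  expect_equal(cross_entropy(matrix(c(0, 1), 1), 1L), 0)
  expect_equal(cross_entropy(matrix(c(0.5, 0.5), 1), 1L), log(2))
  expect_equal(cross_entropy(matrix(c(0.25, 0.75), 1), 1L), -log(0.75))
  expect_equal(cross_entropy(matrix(c(0.25, 0.75), 1), 0L), -log(0.25))
  # batch loss is the mean over examples
  q <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(cross_entropy(q, c(1L, 1L)), mean(c(log(2), -log(0.75))))
  # numeric floor keeps a zero at the true class finite
  expect_true(is.finite(cross_entropy(matrix(c(1, 0), 1), 1L)))
})

test_that("a zero-weight model evaluates to the uninformative baseline", {
  m <- tiny_model(1)
  for (ly in names(m$params)) {
    for (nm in names(m$params[[ly]])) m$params[[ly]][[nm]][] <- 0
  }
  b <- build_minibatch(fixture_table(), 53.4, "validation", 1, seed = 6,
                       geometry = tiny_geometry(), n_per_cell = 2L)
  ev <- evaluate_model(m, b)
  expect_equal(ev$loss, log(2), tolerance = 1e-12)
  # uniform softmax ties break to class 0 (fused), which is half the batch
  expect_equal(ev$accuracy, 0.5)
})

test_that("raw-min checkpoint selection equals a brute-force scan", {
  ck <- select_checkpoint(c(0.5, 0.2, 0.4), "raw_min")
  expect_equal(ck$iteration, 2L)
  expect_equal(ck$val_loss, 0.2)
  set.seed(31)
  for (k in 1:25) {
    log <- runif(sample(3:200, 1))
    expect_equal(select_checkpoint(log, "raw_min")$iteration,
                 which.min(log))  # brute-force scan
  }
  # ties break to the first minimum under both rules
  flat <- rep(1, 40)
  expect_equal(select_checkpoint(flat, "raw_min")$iteration, 1L)
  expect_equal(select_checkpoint(flat, "gaussian_smoothed")$iteration, 1L)
  expect_error(select_checkpoint(numeric(0)), "empty")
})

test_that("gaussian-smoothed selection ignores single-iteration dips", {
  # high plateau with a one-iteration dip, plus a broad shallow valley
  losses <- rep(1, 200)
  losses[40] <- 0.05
  losses[120:160] <- 0.8
  raw <- select_checkpoint(losses, "raw_min")
  sm <- select_checkpoint(losses, "gaussian_smoothed", sigma = 11)
  expect_equal(raw$iteration, 40L)
  expect_true(sm$iteration %in% 120:160)

  # independent smoothing oracle: explicit weighted sum with reflection
  oracle_smooth <- function(x, sigma) {
    n <- length(x); r <- ceiling(4 * sigma)
    sapply(seq_len(n), function(i) {
      j <- (i - r):(i + r)
      jr <- abs(j - 1) %% (2 * (n - 1))
      jr <- ifelse(jr >= n, 2 * (n - 1) - jr, jr) + 1
      w <- dnorm(j - i, sd = sigma)
      sum(w * x[jr]) / sum(w)
    })
  }
  set.seed(8)
  noisy <- runif(150)
  expect_equal(select_checkpoint(noisy, "gaussian_smoothed", sigma = 11)$iteration,
               which.min(oracle_smooth(noisy, 11)))
  expect_equal(select_checkpoint(noisy, "gaussian_smoothed", sigma = 3)$iteration,
               which.min(oracle_smooth(noisy, 3)))
})

test_that("one training iteration fills the log and stores a checkpoint", {
  tab <- fixture_table()
  geo <- tiny_geometry()
  model <- tiny_model(1, input_len = geo$target_len, kernel_len = 16L)
  run <- train_crnn(model, tab, 53.4, iterations = 1L, seed = 2,
                    geometry = geo, n_train = 2L, n_val = 2L)
  expect_equal(nrow(run$log), 1L)
  expect_true(all(is.finite(unlist(run$log))))
  expect_named(run$checkpoints, "1")
  ck <- select_checkpoint(run, "raw_min")
  expect_equal(ck$iteration, 1L)
  m2 <- checkpoint_model(run, ck)
  expect_identical(m2$params, run$checkpoints[["1"]])
})

test_that("training is reproducible under a fixed master seed", {
  tab <- fixture_table()
  geo <- tiny_geometry()
  model <- tiny_model(1, input_len = geo$target_len, kernel_len = 16L)
  r1 <- train_crnn(model, tab, 53.4, iterations = 3L, seed = 7,
                   geometry = geo, n_train = 2L, n_val = 2L)
  r2 <- train_crnn(model, tab, 53.4, iterations = 3L, seed = 7,
                   geometry = geo, n_train = 2L, n_val = 2L)
  r3 <- train_crnn(model, tab, 53.4, iterations = 3L, seed = 8,
                   geometry = geo, n_train = 2L, n_val = 2L)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$model$params, r2$model$params)
  expect_false(identical(r1$log$train_loss, r3$log$train_loss))
})

test_that("experiment-2 training keeps the layer-2 kernel non-negative", {
  tab <- fixture_table()
  geo <- list(dt_ms = 0.5, source_len = 3000L, target_len = 512L,
              max_crop = 100L, max_fill = 20L)
  model <- tiny_model(2, input_len = 512L, kernel_len = 64L, seed = 4)
  run <- train_crnn(model, tab, 53.4, iterations = 2L, seed = 4,
                    geometry = geo, n_train = 2L, n_val = 2L)
  expect_equal(nrow(run$log), 2L)
  expect_true(all(is.finite(unlist(run$log))))
  expect_true(all(run$model$params$td$W >= 0))
  # sub-batched updates also run and respect the constraint
  run32 <- train_crnn(model, tab, 53.4, iterations = 1L, seed = 4,
                      geometry = geo, n_train = 2L, n_val = 2L,
                      batch_size = 8L)
  expect_true(all(is.finite(unlist(run32$log))))
  expect_true(all(run32$model$params$td$W >= 0))
})

test_that("geometry mismatches are rejected", {
  model <- tiny_model(1, input_len = 128L, kernel_len = 16L)
  expect_error(train_crnn(model, fixture_table(), 53.4, iterations = 1L,
                          geometry = tiny_geometry()),
               "does not match")
})
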