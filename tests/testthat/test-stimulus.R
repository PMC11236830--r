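test_that("square pulses realize the requested duty cycle", {
  s <- square_pulse(10, 1/2, 53.4, duration_s = 1, dt_ms = 1)
  expect_length(s$samples, 1000L)
  expect_setequal(unique(s$samples), c(0, 53.4))
  # each 100-sample period: 50 high, 50 low
  per <- matrix(s$samples, nrow = 100)
  expect_true(all(colSums(per == 53.4) == 50))

  s6 <- square_pulse(10, 1/6, 1, duration_s = 1, dt_ms = 1)
  expect_lt(abs(mean(s6$samples) - 1/6), 1 / 100)

  # sample-counting oracle over random draws; frequencies dividing the
  # sample rate give whole periods, so the high-sample fraction matches
  # the PCF to within one sample per period
  set.seed(11)
  for (k in 1:20) {
    f <- sample(c(4, 5, 8, 10, 20, 25, 40, 50), 1)
    pcf <- sample(c(1/6, 1/3, 1/2, 2/3, 5/6), 1)
    s <- square_pulse(f, pcf, 2, duration_s = 2, dt_ms = 1)
    expect_lte(abs(mean(s$samples) / 2 - pcf), f / 1000)
  }
})

test_that("square pulse rejects super-Nyquist and ragged durations", {
  expect_error(square_pulse(500, 1/2, 1, 1, dt_ms = 1), "Nyquist")
  expect_error(square_pulse(10, 1/2, 1, duration_s = 0.0015, dt_ms = 1),
               "integer sample count")
  expect_error(square_pulse(10, 0, 1, 1), "pcf")
})

test_that("constant stimuli are flat", {
  z <- constant_stimulus(0, 7168)
  expect_length(z$samples, 7168L)
  expect_true(all(z$samples == 0))
  c2 <- constant_stimulus(53.4, 10)
  expect_true(all(c2$samples == 53.4))
  expect_equal(max(c2$samples) - min(c2$samples), 0)
  expect_error(constant_stimulus(-1, 10), "non-negative")
})

test_that("sinusoidal flicker respects its modulation envelope", {
  s <- sinusoidal_stimulus(54.3, 0.1, 10, duration_s = 2, dt_ms = 1)
  expect_gte(min(s$samples), 54.3 * 0.9)
  expect_lte(max(s$samples), 54.3 * 1.1)
  expect_equal(range(s$samples), c(48.87, 59.73), tolerance = 1e-6)
  sp <- amplitude_spectrum(s)
  non_dc <- sp[sp$frequency > 0, ]
  peak <- non_dc$frequency[which.max(non_dc$amplitude)]
  expect_equal(peak, 10)
  # single non-DC component: everything else is numerically zero
  expect_lt(max(non_dc$amplitude[non_dc$frequency != peak]),
            1e-9 * max(non_dc$amplitude))
  expect_error(sinusoidal_stimulus(54.3, 1.2, 10, 1), "modulation depth")
})

test_that("onset randomization crops, fills, and reproduces under a seed", {
  src <- square_pulse(10, 1/2, 53.4, duration_s = 12, dt_ms = 1)
  set.seed(5)
  r <- randomize_onset(src, 7168L, 3000L, 500L)
  expect_length(r$samples, 7168L)
  expect_true(r$meta$crop_offset %in% 0:2999)
  expect_true(r$meta$fill_len %in% 0:499)
  if (r$meta$fill_len > 0) {
    expect_true(all(r$samples[seq_len(r$meta$fill_len)] == r$meta$fill_level))
  }
  # beyond the fill prefix the samples are untouched source values
  expect_equal(r$samples[(r$meta$fill_len + 1):7168],
               src$samples[(r$meta$crop_offset + r$meta$fill_len + 1):
                           (r$meta$crop_offset + 7168)])

  set.seed(77); a <- randomize_onset(src, 7168L, 3000L, 500L)
  set.seed(77); b <- randomize_onset(src, 7168L, 3000L, 500L)
  expect_identical(a$samples, b$samples)

  # degenerate windows give the plain prefix
  d <- randomize_onset(src, 7168L, 1L, 1L)
  expect_identical(d$samples, src$samples[1:7168])
  expect_error(randomize_onset(src, 11000L, 3000L, 500L), "too short")
})

test_that("minibatches have exact composition and class balance", {
  tab <- fixture_table()
  geo <- tiny_geometry()
  tr <- build_minibatch(tab, 53.4, "training", 1, seed = 3, geometry = geo)
  expect_equal(dim(tr$x), c(100L, geo$target_len))
  expect_equal(as.vector(table(tr$y)), c(50L, 50L))
  # 10 per (PCF, label) cell
  counts <- table(tr$meta$pcf, tr$meta$label)
  expect_true(all(counts == 10L))

  va <- build_minibatch(tab, 53.4, "validation", 1, seed = 3, geometry = geo)
  expect_equal(nrow(va$x), 500L)
  expect_true(all(table(va$meta$pcf, va$meta$label) == 50L))
  expect_true(all(va$meta$kind == "square"))
})

test_that("every generated frequency lies in its label band", {
  tab <- fixture_table()
  geo <- tiny_geometry()
  for (mode in c("training", "validation")) {
    b <- build_minibatch(tab, 53.4, mode, 1, seed = 9, geometry = geo)
    for (i in seq_len(nrow(b$meta))) {
      m <- b$meta[i, ]
      lr <- label_ranges(tab, 53.4, m$pcf, mode)
      if (m$kind == "square") {
        band <- if (m$label == 1L) lr$flicker_band else lr$fused_band
        expect_gte(m$frequency, band[1])
        expect_lte(m$frequency, band[2])
      } else {
        expect_equal(m$label, 0L)  # constants only in the fused class
      }
    }
  }
})

test_that("rectangular examples are two-valued beyond the fill window", {
  tab <- fixture_table()
  geo <- tiny_geometry()
  b <- build_minibatch(tab, 53.4, "training", 1, seed = 21, geometry = geo)
  sq <- which(b$meta$kind == "square")
  for (i in sq) {
    tail_vals <- unique(b$x[i, (geo$max_fill + 1):geo$target_len])
    expect_true(all(tail_vals %in% c(0, 53.4)))
  }
})

test_that("minibatches are reproducible and experiment geometries correct", {
  tab <- fixture_table()
  a <- build_minibatch(tab, 0.53, "training", 1, seed = 4, geometry = tiny_geometry())
  b <- build_minibatch(tab, 0.53, "training", 1, seed = 4, geometry = tiny_geometry())
  expect_identical(a$x, b$x)
  expect_identical(a$meta, b$meta)

  g1 <- experiment_geometry(1)
  g2 <- experiment_geometry(2)
  expect_equal(g1$target_len * g1$dt_ms / 1000, 7.168)   # exp 1: 7.168 s @ 1 ms
  expect_equal(g2$target_len * g2$dt_ms / 1000, 8.192)   # exp 2: 8.192 s @ 0.5 ms
  expect_true(g2$source_len >= g2$target_len + g2$max_crop)
  expect_error(experiment_geometry(3), "experiment")
})
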