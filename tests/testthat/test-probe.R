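test_that("amplitude spectra recover pure tones and reject short traces", {
  t <- (0:3999) / 1000
  x <- 3 * sin(2 * pi * 10 * t)
  sp <- amplitude_spectrum(x, dt_ms = 1)
  peak <- which.max(sp$amplitude)
  expect_equal(sp$frequency[peak], 10)
  expect_equal(sp$amplitude[peak], 3, tolerance = 1e-9)

  flat <- amplitude_spectrum(rep(2.5, 3000), dt_ms = 1)
  expect_equal(flat$amplitude[1], 2.5, tolerance = 1e-12)  # DC
  expect_lt(max(flat$amplitude[-1]), 1e-12)

  expect_error(amplitude_spectrum(rep(1, 100), dt_ms = 1), "too short")
  expect_silent(amplitude_spectrum(rep(1, 100), dt_ms = 1, min_duration_s = 0))
})

test_that("square-wave spectra show the 1 : 1/3 : 1/5 harmonic ladder", {
  s <- square_pulse(10, 1/2, 1, duration_s = 4, dt_ms = 1)
  sp <- amplitude_spectrum(s)
  amp_at <- function(f) sp$amplitude[which.min(abs(sp$frequency - f))]
  a10 <- amp_at(10); a30 <- amp_at(30); a50 <- amp_at(50)
  # discrete sampling turns the sinc envelope into a Dirichlet kernel,
  # so the odd-harmonic ratios match 1/3 and 1/5 to a few parts in 1e3
  expect_equal(a30 / a10, 1/3, tolerance = 0.005)
  expect_equal(a50 / a10, 1/5, tolerance = 0.01)
  # even harmonics absent for PCF 1/2
  expect_lt(amp_at(20) / a10, 1e-9)
})

test_that("discrete periods expose sampling commensurability", {
  expect_equal(discrete_period(10, 1), 100L)
  expect_equal(discrete_period(80, 1), 25L)    # two stimulus cycles
  expect_equal(discrete_period(8.5, 1), 2000L)
  expect_equal(discrete_period(79, 1), 1000L)
  expect_equal(discrete_period(40, 0.5), 50L)
})

test_that("harmonic closure is exact for conv taps of square stimuli", {
  set.seed(19)
  for (f in c(10, 80)) {
    m <- tiny_model(1, seed = sample.int(1e6, 1))
    s <- square_pulse(f, 1/2, 53.4, duration_s = 4, dt_ms = 1)
    tap <- conv_tap(m, s)
    hc <- harmonic_closure_fraction(tap[, 3], f, dt_ms = 1, transient_skip = 16)
    expect_gte(hc$fraction, 0.999)
  }
  # the aliased grid for 80 Hz @ 1 ms steps by 40 Hz (period 25 samples)
  hc <- harmonic_closure_fraction(square_pulse(80, 1/2, 1, 2, 1), 80, 1)
  expect_equal(hc$period, 25L)
  expect_equal(hc$grid_step, 40)
})

test_that("sinusoidality index is scale-invariant and calibrated", {
  t <- (0:9999) / 1000
  pure <- sin(2 * pi * 10 * t)
  sp <- amplitude_spectrum(pure, 1)
  expect_gt(sinusoidality_index(sp, 10), 1e3)

  two <- sin(2 * pi * 10 * t) + sin(2 * pi * 5 * t)
  sp2 <- amplitude_spectrum(two, 1)
  expect_equal(sinusoidality_index(sp2, 10), 1, tolerance = 1e-6)

  sp3 <- amplitude_spectrum(37.5 * two, 1)
  expect_equal(sinusoidality_index(sp3, 10), sinusoidality_index(sp2, 10),
               tolerance = 1e-12)

  sq <- amplitude_spectrum(square_pulse(10, 1/2, 1, 4, 1))
  expect_gt(sinusoidality_index(sq, 10), 5)  # squares have no subharmonics
})

test_that("envelopes interpolate windowed maxima exactly", {
  const <- extract_envelope(rep(4.2, 500), window = 25L)
  expect_equal(const$envelope, rep(4.2, 500), tolerance = 1e-9)

  t <- (0:7999) / 1000
  am <- (1 + 0.5 * sin(2 * pi * 10 * t)) * sin(2 * pi * 80 * t)
  env <- extract_envelope(am, window = 25L)
  expect_length(env$envelope, length(am))
  # envelope passes through every sampled maximum
  expect_equal(env$envelope[env$positions], env$maxima, tolerance = 1e-9)
  # and tracks the true amplitude modulation
  inner <- 200:7800
  expect_gt(cor(env$envelope[inner], 1 + 0.5 * sin(2 * pi * 10 * t)[inner]),
            0.95)
  expect_error(extract_envelope(rep(1, 30), window = 25L), "two windows")
})

test_that("fundamental profiles cover every filter and stay non-negative", {
  m <- tiny_model(1, input_len = 2000L, kernel_len = 50L, seed = 2)
  fp <- fundamental_profile(m, frequencies = seq(5, 50, by = 5),
                            intensity = 53.4, duration_s = 2)
  expect_equal(nrow(fp), 10L * 8L)
  expect_true(all(fp$amplitude >= 0))
  expect_setequal(unique(fp$neuron), 1:8)
  # an identity-like single-tap kernel reproduces the stimulus spectrum:
  # tap[t] = x[t + 49], so after the kernel-length transient the probed
  # segment is exactly x[100:2000]
  m$params$conv$K[] <- 0; m$params$conv$b[] <- 0
  m$params$conv$K[50, 1] <- 1
  fp1 <- fundamental_profile(m, frequencies = c(10, 20), intensity = 1,
                             duration_s = 2)
  for (f in c(10, 20)) {
    s <- square_pulse(f, 1/2, 1, duration_s = 2, dt_ms = 1)
    sp <- amplitude_spectrum(s$samples[100:2000], 1, min_duration_s = 0)
    want <- sp$amplitude[which.min(abs(sp$frequency - f))]
    got <- fp1$amplitude[fp1$stim_freq == f & fp1$neuron == 1]
    expect_equal(got, want, tolerance = 1e-9)
  }
  expect_error(fundamental_profile(m, frequencies = 600), "Nyquist")
})

test_that("interval range profiles are flat for steady inputs", {
  m2 <- tiny_model(2, input_len = 8000L, kernel_len = 280L, seed = 3)
  tap <- td_tap(m2, constant_stimulus(20, 8000, dt_ms = 0.5))
  per_neuron_range <- apply(tap, 2, function(y) max(y) - min(y))
  expect_equal(unname(per_neuron_range), rep(0, 4), tolerance = 1e-9)

  rp <- interval_range_profile(m2, frequencies = c(10, 40), intensity = 53.4,
                               duration_s = 4)
  expect_true(all(rp$range >= 0))
  expect_equal(nrow(rp), 2L * 4L)
  rp2 <- interval_range_profile(m2, frequencies = c(10, 40), intensity = 53.4,
                                duration_s = 4)
  expect_identical(rp, rp2)
  expect_error(interval_range_profile(tiny_model(1), frequencies = 10),
               "experiment-2")
})

test_that("response-frequency maps honor thresholds and linear support", {
  m <- tiny_model(1, input_len = 4000L, kernel_len = 40L, seed = 4)
  rm <- response_frequency_map(m, stim_freqs = c(10, 20),
                               resp_freqs = seq(5, 100, by = 5),
                               intensity = 53.4, duration_s = 4)
  expect_equal(dim(rm$map), c(2L, 20L))
  # any pointwise function of a 100-sample-periodic tap supports only
  # multiples of 10 Hz; skip 61 leaves a whole number of periods (3900)
  m$params$conv$b[] <- 0
  rml <- response_frequency_map(m, stim_freqs = 10,
                                resp_freqs = seq(5, 95, by = 5),
                                intensity = 1, duration_s = 4, neuron = 2,
                                transient_skip = 61)
  off <- rml$resp_freqs %% 10 != 0
  expect_lt(max(rml$map[1, off]), 1e-9 * max(rml$map))

  # zero weights give empty support
  for (nm in names(m$params$conv)) m$params$conv[[nm]][] <- 0
  rm0 <- response_frequency_map(m, stim_freqs = 10, resp_freqs = c(10, 20),
                                intensity = 1, duration_s = 4)
  expect_false(any(rm0$support))

  # sinusoidal probing runs end to end
  m2 <- tiny_model(1, input_len = 4000L, kernel_len = 40L, seed = 6)
  rms <- response_frequency_map(m2, stim_freqs = 10, resp_freqs = c(10, 20, 30),
                                intensity = 53.4, stimulus = "sinusoidal",
                                m = 0.1, duration_s = 4)
  expect_true(all(is.finite(rms$map)))
})
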