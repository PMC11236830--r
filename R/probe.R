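#' Amplitude spectrum of an activation trace
#'
#' Magnitude of the real-input discrete Fourier transform of the
#' post-transient segment of a tapped activation (or stimulus), with no
#' taper, mirroring direct visual inspection of raw FFT amplitudes.
#' Amplitudes are one-sided (`2 |X_k| / N`, DC `|X_0| / N`) so a pure
#' sinusoid of amplitude A shows a single non-DC peak of height A. The
#' frequency grid spans 0 to Nyquist with spacing `1 / segment
#' duration`.
#'
#' @param x Numeric vector (activation trace or stimulus samples), or a
#'   `flicker_stimulus`.
#' @param dt_ms Sampling interval in ms (taken from the stimulus when
#'   one is given).
#' @param transient_skip Leading samples to drop before the transform
#'   (the convolution transient; defaults to 0).
#' @param min_duration_s Guard: error if the post-skip segment is
#'   shorter than this (default 2 s, the shortest window that resolves
#'   the bands of interest; relax for toy signals).
#' @return A `spectrum_result` data.frame with columns `frequency` (Hz)
#'   and `amplitude`, and attributes `dt_ms`, `n`, `transient_skip`.
#' @export
amplitude_spectrum <- function(x, dt_ms = NULL, transient_skip = 0,
                               min_duration_s = 2) {
  if (inherits(x, "flicker_stimulus")) {
    dt_ms <- dt_ms %||% x$dt_ms
    x <- x$samples
  }
  if (is.null(dt_ms)) stop("dt_ms required for a bare numeric trace")
  if (transient_skip > 0) x <- x[-seq_len(transient_skip)]
  n <- length(x)
  if (n * dt_ms / 1000 < min_duration_s) {
    stop("segment too short: ", n, " samples (", n * dt_ms / 1000,
         " s) after transient skip; need >= ", min_duration_s, " s")
  }
  X <- stats::fft(x)
  half <- floor(n / 2) + 1L
  amp <- Mod(X[seq_len(half)]) / n
  amp[-1] <- 2 * amp[-1]
  if (n %% 2 == 0) amp[half] <- amp[half] / 2  # Nyquist bin is not doubled
  out <- data.frame(frequency = (seq_len(half) - 1) / (n * dt_ms / 1000),
                    amplitude = amp)
  attr(out, "dt_ms") <- dt_ms
  attr(out, "n") <- n
  attr(out, "transient_skip") <- transient_skip
  class(out) <- c("spectrum_result", "data.frame")
  out
}

# Best rational approximation a/b of x with b <= max_den (continued
# fractions). Used to find the discrete period of a sampled waveform.
.rat_approx <- function(x, max_den = 1e6, tol = 1e-9) {
  a0 <- floor(x); f <- x - a0
  h1 <- a0; h0 <- 1; k1 <- 1; k0 <- 0
  while (f > tol && k1 <= max_den) {
    a <- floor(1 / f); f <- 1 / f - a
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_den) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(h1 / k1 - x) < tol) break
  }
  c(num = h1, den = k1)
}

#' Discrete period of a sampled periodic waveform
#'
#' A waveform of frequency `f` Hz sampled every `dt_ms` ms repeats
#' exactly every `P` samples, where `f * dt_ms / 1000 = a / P` in lowest
#' terms. For sample-commensurate frequencies (10 Hz at 1 ms: P = 100)
#' this is one stimulus period; for incommensurate ones (80 Hz at 1 ms:
#' P = 25, spanning two stimulus cycles) the discrete fundamental
#' `1000 / (P * dt_ms)` Hz sits *below* the stimulus frequency, which is
#' how point sampling lodges real energy at frequencies such as 40 Hz
#' for an 80 Hz square wave.
#'
#' @param frequency Stimulus frequency in Hz.
#' @param dt_ms Sampling interval in ms.
#' @param max_period Cap on the reported period (rational-approximation
#'   denominator bound).
#' @return Integer sample period `P`.
#' @export
discrete_period <- function(frequency, dt_ms, max_period = 1e6) {
  r <- .rat_approx(frequency * dt_ms / 1000, max_den = max_period)
  as.integer(r["den"])
}

#' Harmonic-closure fraction of an activation spectrum
#'
#' Formalizes the claim that a temporal convolution (plus any pointwise
#' nonlinearity) creates no new frequencies: the sampled stimulus has
#' spectral support only on the aliased harmonic grid — multiples of its
#' discrete fundamental `fs / P`, where `P` is [discrete_period()] — and
#' therefore so does any conv-layer tap of it, for any weights. This
#' function measures the fraction of spectral energy (squared DFT
#' magnitude) lying within one frequency bin of that grid, computed on a
#' post-transient window trimmed to a whole number of discrete periods.
#' For exactly periodic inputs the fraction is 1 up to float error.
#'
#' For sample-commensurate frequencies the aliased grid coincides with
#' the integer multiples of the stimulus frequency; for incommensurate
#' ones it is strictly finer (e.g. multiples of 40 Hz for an 80 Hz
#' stimulus at 1 ms), which matches the 40 Hz "subharmonic" seen in
#' conv taps of 80 Hz square waves.
#'
#' @param x Activation trace (numeric vector) or `flicker_stimulus`.
#' @param frequency Stimulus frequency in Hz.
#' @param dt_ms Sampling interval in ms.
#' @param transient_skip Leading samples to drop (conv transient).
#' @param include_dc Count the DC bin as on-grid (default TRUE; biases
#'   and rectifying activations create a real DC component).
#' @return List with `fraction` (energy share on the aliased harmonic
#'   grid), `grid_step` (Hz, `fs / P`), `period` (samples), `n_used`.
#' @export
harmonic_closure_fraction <- function(x, frequency, dt_ms,
                                      transient_skip = 0, include_dc = TRUE) {
  if (inherits(x, "flicker_stimulus")) {
    dt_ms <- x$dt_ms
    x <- x$samples
  }
  if (transient_skip > 0) x <- x[-seq_len(transient_skip)]
  fs <- 1000 / dt_ms
  P <- discrete_period(frequency, dt_ms)
  n_per <- floor(length(x) / P)
  if (n_per < 1) {
    stop("trace shorter than one discrete period (", P, " samples)")
  }
  n <- n_per * P
  x <- x[seq_len(n)]
  X <- stats::fft(x)
  half <- floor(n / 2) + 1L
  en <- Mod(X[seq_len(half)])^2
  freqs <- (seq_len(half) - 1) * fs / n
  g <- fs / P
  binw <- fs / n
  dist <- abs(((freqs + g / 2) %% g) - g / 2)
  on_grid <- dist <= binw + 1e-9
  if (!include_dc) {
    en <- en[-1]; on_grid <- on_grid[-1]
  }
  tot <- sum(en)
  list(fraction = if (tot > 0) sum(en[on_grid]) / tot else 1,
       grid_step = g, period = P, n_used = n)
}

#' Sinusoidality index of a spectrum at a target frequency
#'
#' Ratio of the spectral amplitude at the stimulus frequency to the
#' largest amplitude at any lower frequency (excluding DC). A pure
#' sinusoid gives a very large ratio (bounded by the leakage floor);
#' equal components at `f` and `f/2` give 1. The package calls a
#' response "sinusoidal" when the index exceeds a configurable
#' threshold (default 5); the threshold is a reporting convention, not
#' a property of the data.
#'
#' The index is scale-invariant: multiplying the trace by any positive
#' constant leaves it unchanged.
#'
#' @param spec A `spectrum_result` from [amplitude_spectrum()].
#' @param frequency Target frequency in Hz (snapped to the nearest
#'   grid point).
#' @param guard_bins Bins below the target excluded from the
#'   sub-fundamental search (spectral-leakage skirt; default 2).
#' @return The amplitude ratio (possibly `Inf` for a numerically clean
#'   sinusoid).
#' @export
sinusoidality_index <- function(spec, frequency, guard_bins = 2L) {
  stopifnot(inherits(spec, "spectrum_result"))
  i_f <- which.min(abs(spec$frequency - frequency))
  sub <- seq_len(max(i_f - 1L - guard_bins, 0L))[-1]  # drop DC (bin 1)
  if (length(sub) == 0L) stop("no sub-fundamental grid points below ", frequency, " Hz")
  a_f <- spec$amplitude[i_f]
  a_sub <- max(spec$amplitude[sub])
  if (a_sub == 0) Inf else a_f / a_sub
}

#' Envelope extraction by windowed maxima and cubic spline
#'
#' Splits the trace into consecutive non-overlapping windows (default
#' 25 samples), takes each window's maximum anchored at its argmax
#' position, and reconstructs a smooth envelope as the natural cubic
#' spline through the (position, maximum) pairs, evaluated at every
#' sample index. The spline interpolates the sampled maxima exactly;
#' beyond the first and last anchors it continues the boundary
#' polynomial.
#'
#' @param x Numeric activation trace.
#' @param window Window length in samples (default 25).
#' @return An `envelope_result`: list with `positions` (anchor sample
#'   indices), `maxima` (values there), `envelope` (length of `x`), and
#'   `window`.
#' @export
extract_envelope <- function(x, window = 25L) {
  n <- length(x)
  if (n < 2L * window) stop("trace shorter than two windows")
  n_win <- n %/% window
  pos <- integer(n_win); val <- numeric(n_win)
  for (w in seq_len(n_win)) {
    lo <- (w - 1L) * window + 1L
    seg <- x[lo:(lo + window - 1L)]
    k <- which.max(seg)
    pos[w] <- lo + k - 1L
    val[w] <- seg[k]
  }
  env <- stats::spline(pos, val, xout = seq_len(n), method = "natural")$y
  structure(list(positions = pos, maxima = val, envelope = env,
                 window = as.integer(window)),
            class = "envelope_result")
}

# Shared synthesis of the standard probe pulse: PCF 1/2, no onset
# randomization, duration matching the model's input geometry.
.probe_pulse <- function(model, frequency, intensity, pcf = 1 / 2,
                         duration_s = NULL) {
  dt_ms <- model$spec$dt_ms
  duration_s <- duration_s %||% (model$spec$input_len * dt_ms / 1000)
  square_pulse(frequency, pcf, intensity, duration_s, dt_ms)
}

#' Fundamental-frequency profile of the conv layer
#'
#' For each stimulus frequency on a grid, synthesizes the standard test
#' pulse (PCF 1/2, no onset randomization, the model's native sampling
#' and duration), taps the convolution layer, and records the spectral
#' amplitude at the stimulus frequency for every filter. Trained
#' networks show resonance peaks (near 10, 20, 40, 80 Hz in the
#' reference condition) that untrained networks lack.
#'
#' @param model A `crnn_model`.
#' @param frequencies Stimulus frequency grid in Hz (default 2-100 in
#'   0.5 Hz steps).
#' @param intensity Pulse intensity in cd/ft^2.
#' @param pcf Pulse-to-cycle fraction of the probe pulses (default 1/2).
#' @param transient_skip Samples dropped before the FFT (default: the
#'   conv kernel length, i.e. the filter transient).
#' @param duration_s Probe duration in seconds (default: the model's
#'   input duration).
#' @return A `fundamental_profile` data.frame: `neuron`, `stim_freq`,
#'   `amplitude`.
#' @export
fundamental_profile <- function(model, frequencies = seq(2, 100, by = 0.5),
                                intensity = 53.4, pcf = 1 / 2,
                                transient_skip = NULL, duration_s = NULL) {
  nyq <- 1000 / (2 * model$spec$dt_ms)
  if (any(frequencies >= nyq)) stop("frequency grid exceeds Nyquist")
  skip <- transient_skip %||% model$spec$layers[[2]]$kernel_len
  rows <- vector("list", length(frequencies))
  for (i in seq_along(frequencies)) {
    f <- frequencies[i]
    tap <- conv_tap(model, .probe_pulse(model, f, intensity, pcf, duration_s))
    amps <- apply(tap, 2, function(tr) {
      sp <- amplitude_spectrum(tr, model$spec$dt_ms, transient_skip = skip,
                               min_duration_s = 0)
      sp$amplitude[which.min(abs(sp$frequency - f))]
    })
    rows[[i]] <- data.frame(neuron = seq_along(amps), stim_freq = f,
                            amplitude = amps)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("fundamental_profile", "data.frame")
  out
}

#' Interval range profile of the layer-2 output (experiment 2)
#'
#' For each stimulus frequency, taps the time-distributed dense layer
#' ("layer 2") of an experiment-2 model with a PCF 1/2 pulse, splits the
#' tap into non-overlapping 1 s intervals (2000 samples at 0.5 ms),
#' computes max - min per interval and neuron, and averages over the
#' intervals excluding the first (the onset transient). The profile of a
#' trained 53.4 cd/ft^2 network peaks near 10, 20 and 40 Hz.
#'
#' The profile is invariant to adding a constant to the tapped signal.
#'
#' @param model An experiment-2 `crnn_model`.
#' @param frequencies Stimulus frequency grid (Hz).
#' @param intensity Pulse intensity in cd/ft^2.
#' @param pcf Probe PCF (default 1/2).
#' @param interval_s Interval length in seconds (default 1).
#' @param duration_s Probe duration (default: the model's input
#'   duration).
#' @return A `range_profile` data.frame: `neuron`, `stim_freq`, `range`.
#' @export
interval_range_profile <- function(model, frequencies = seq(2, 100, by = 1),
                                   intensity = 53.4, pcf = 1 / 2,
                                   interval_s = 1, duration_s = NULL) {
  if (model$spec$experiment != 2) stop("requires an experiment-2 model")
  dt_ms <- model$spec$dt_ms
  ns_int <- as.integer(round(interval_s * 1000 / dt_ms))
  rows <- vector("list", length(frequencies))
  for (i in seq_along(frequencies)) {
    f <- frequencies[i]
    tap <- td_tap(model, .probe_pulse(model, f, intensity, pcf, duration_s))
    n_int <- nrow(tap) %/% ns_int
    if (n_int < 2L) stop("fewer than 2 complete ", interval_s, " s intervals")
    rng <- sapply(seq_len(ncol(tap)), function(j) {
      per_int <- sapply(seq_len(n_int), function(w) {
        seg <- tap[((w - 1L) * ns_int + 1L):(w * ns_int), j]
        max(seg) - min(seg)
      })
      mean(per_int[-1])
    })
    rows[[i]] <- data.frame(neuron = seq_along(rng), stim_freq = f, range = rng)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("range_profile", "data.frame")
  out
}

#' Response-frequency versus stimulus-frequency map
#'
#' For one tapped neuron, synthesizes a stimulus at each grid frequency
#' (square pulse by default, or sinusoidal flicker with modulation depth
#' `m`), taps the requested layer, and records the spectral amplitude at
#' each response frequency. The thresholded support (amplitudes above
#' `threshold` times the map maximum) is reported separately, so claims
#' about which components are "present" are explicit about the cut.
#'
#' @param model A `crnn_model`.
#' @param stim_freqs Stimulus frequency grid (Hz).
#' @param resp_freqs Response frequency grid (Hz), within Nyquist.
#' @param layer `"conv"` or `"td"` (layer 2, experiment 2 only).
#' @param neuron Filter/unit index to tap (default 1).
#' @param intensity Stimulus intensity (cd/ft^2); for sinusoidal
#'   stimuli this is the mean luminance I0.
#' @param stimulus `"square"` or `"sinusoidal"`.
#' @param pcf PCF for square probes.
#' @param m Modulation depth for sinusoidal probes (default 0.1).
#' @param threshold Relative support threshold (fraction of the map
#'   maximum, default 0.05).
#' @param transient_skip Samples dropped before each FFT (default:
#'   conv kernel length).
#' @param duration_s Probe duration (default: model input duration).
#' @return A `response_map`: list with `map` (stimulus x response
#'   amplitude matrix), `support` (logical matrix), grids, and the
#'   threshold used.
#' @export
response_frequency_map <- function(model, stim_freqs = seq(2, 100, by = 2),
                                   resp_freqs = seq(2, 100, by = 2),
                                   layer = c("conv", "td"), neuron = 1L,
                                   intensity = 53.4,
                                   stimulus = c("square", "sinusoidal"),
                                   pcf = 1 / 2, m = 0.1, threshold = 0.05,
                                   transient_skip = NULL, duration_s = NULL) {
  layer <- match.arg(layer)
  stimulus <- match.arg(stimulus)
  nyq <- 1000 / (2 * model$spec$dt_ms)
  if (any(c(stim_freqs, resp_freqs) >= nyq)) stop("grids must stay below Nyquist")
  skip <- transient_skip %||% model$spec$layers[[2]]$kernel_len
  dt_ms <- model$spec$dt_ms
  duration_s <- duration_s %||% (model$spec$input_len * dt_ms / 1000)

  map <- matrix(NA_real_, length(stim_freqs), length(resp_freqs),
                dimnames = list(stim_freqs, resp_freqs))
  for (i in seq_along(stim_freqs)) {
    f <- stim_freqs[i]
    stim <- if (stimulus == "square") {
      square_pulse(f, pcf, intensity, duration_s, dt_ms)
    } else {
      sinusoidal_stimulus(intensity, m, f, duration_s, dt_ms)
    }
    tap <- if (layer == "conv") conv_tap(model, stim) else td_tap(model, stim)
    sp <- amplitude_spectrum(tap[, neuron], dt_ms, transient_skip = skip,
                             min_duration_s = 0)
    map[i, ] <- sp$amplitude[vapply(resp_freqs, function(rf) {
      which.min(abs(sp$frequency - rf))
    }, integer(1))]
  }
  structure(list(map = map, support = map > threshold * max(map),
                 stim_freqs = stim_freqs, resp_freqs = resp_freqs,
                 layer = layer, neuron = neuron, stimulus = stimulus,
                 threshold = threshold),
            class = "response_map")
}
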