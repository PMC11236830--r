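#' Stimulus containers
#'
#' A `flicker_stimulus` is a uniformly sampled intensity time series
#' (cd/ft^2) with its sampling interval and a provenance record of any
#' randomizations applied (crop offset, fill length, fill level, seed).
#'
#' @param samples Numeric vector of intensities, all `>= 0`.
#' @param dt_ms Sampling interval in milliseconds.
#' @param meta Named list of generation metadata.
#' @return A `flicker_stimulus` object.
#' @keywords internal
new_stimulus <- function(samples, dt_ms, meta = list()) {
  stopifnot(is.numeric(samples), dt_ms > 0)
  if (any(samples < 0)) stop("stimulus intensities must be non-negative")
  structure(list(samples = as.numeric(samples), dt_ms = dt_ms, meta = meta),
            class = "flicker_stimulus")
}

#' @export
print.flicker_stimulus <- function(x, ...) {
  cat(sprintf("flicker stimulus: %d samples @ %g ms (%.3f s)\n",
              length(x$samples), x$dt_ms, length(x$samples) * x$dt_ms / 1000))
  if (!is.null(x$meta$kind)) {
    cat("  kind:", x$meta$kind,
        if (!is.null(x$meta$frequency)) sprintf("(%g Hz)", x$meta$frequency) else "",
        "\n")
  }
  invisible(x)
}

#' @export
length.flicker_stimulus <- function(x) length(x$samples)

# The +/-1 rectangular wave with duty cycle `pcf`, high phase first:
# sq(phi) = +1 while the fractional cycle position is < pcf, else -1.
.square_wave <- function(frequency, pcf, t) {
  phase <- (frequency * t) %% 1
  2 * (phase < pcf) - 1
}

#' Generate a rectangular photic-pulse train
#'
#' Samples a rectangular flicker waveform: a +/-1 square wave of the
#' requested frequency and pulse-to-cycle fraction (duty cycle) is
#' shifted and scaled to `{0, intensity}` by `(sq + 1)/2 * intensity`.
#' The wave starts in its high phase at t = 0; phase is randomized
#' downstream by the onset crop of [randomize_onset()].
#'
#' @param frequency Flicker frequency in Hz; must be below the Nyquist
#'   frequency `1 / (2 * dt_ms/1000)`.
#' @param pcf Pulse-to-cycle fraction in (0, 1).
#' @param intensity Pulse luminance in cd/ft^2 (`>= 0`).
#' @param duration_s Duration in seconds; `duration_s / dt_ms` must give
#'   an integer sample count (to within rounding noise).
#' @param dt_ms Sampling interval in milliseconds.
#' @return A `flicker_stimulus` whose samples take only the values 0 and
#'   `intensity`.
#' @examples
#' s <- square_pulse(10, 1/2, 53.4, duration_s = 1, dt_ms = 1)
#' table(s$samples)  # 500 samples at 0, 500 at 53.4
#' @export
square_pulse <- function(frequency, pcf, intensity, duration_s, dt_ms = 1) {
  if (pcf <= 0 || pcf >= 1) stop("pcf must lie strictly inside (0, 1)")
  if (intensity < 0) stop("intensity must be non-negative")
  nyquist <- 1000 / (2 * dt_ms)
  if (frequency >= nyquist) {
    stop("frequency ", frequency, " Hz is at or above the Nyquist frequency ",
         nyquist, " Hz")
  }
  n <- duration_s * 1000 / dt_ms
  if (abs(n - round(n)) > 1e-8) {
    stop("duration_s / dt_ms must yield an integer sample count")
  }
  n <- as.integer(round(n))
  t <- (seq_len(n) - 1) * dt_ms / 1000
  samples <- intensity * (.square_wave(frequency, pcf, t) + 1) / 2
  new_stimulus(samples, dt_ms,
               list(kind = "square", frequency = frequency, pcf = pcf,
                    intensity = intensity))
}

#' Generate a constant (steady) stimulus
#'
#' @param level Constant luminance in cd/ft^2 (`>= 0`).
#' @param n_samples Number of samples.
#' @param dt_ms Sampling interval in milliseconds.
#' @return A `flicker_stimulus` with all samples equal to `level`.
#' @export
constant_stimulus <- function(level, n_samples, dt_ms = 1) {
  if (level < 0) stop("level must be non-negative")
  new_stimulus(rep(level, n_samples), dt_ms,
               list(kind = "constant", level = level))
}

#' Generate sinusoidal flicker
#'
#' Samples `I(t) = I0 * (1 + m * sin(2 pi f t))`, the standard
#' sinusoidal flicker waveform with mean luminance `I0` and modulation
#' depth `m`.
#'
#' @param i0 Mean luminance in cd/ft^2.
#' @param m Modulation depth, strictly inside (0, 1).
#' @param frequency Flicker frequency in Hz (below Nyquist).
#' @param duration_s Duration in seconds.
#' @param dt_ms Sampling interval in milliseconds.
#' @return A `flicker_stimulus` with samples in `[I0 (1 - m), I0 (1 + m)]`.
#' @export
sinusoidal_stimulus <- function(i0, m, frequency, duration_s, dt_ms = 1) {
  if (m <= 0 || m >= 1) stop("modulation depth m must lie strictly inside (0, 1)")
  nyquist <- 1000 / (2 * dt_ms)
  if (frequency >= nyquist) stop("frequency at or above Nyquist")
  n <- as.integer(round(duration_s * 1000 / dt_ms))
  t <- (seq_len(n) - 1) * dt_ms / 1000
  samples <- i0 * (1 + m * sin(2 * pi * frequency * t))
  new_stimulus(samples, dt_ms,
               list(kind = "sinusoidal", frequency = frequency, i0 = i0, m = m))
}

#' Randomize stimulus onset by cropping and prefix filling
#'
#' Implements the two onset randomizations applied to every training and
#' validation pulse: (1) a window of `target_len` samples is cut out of
#' the longer source array, starting at an offset drawn uniformly from
#' the first `max_crop` positions (this randomizes phase and makes the
#' value of the final sample irrelevant to the label); (2) a prefix
#' length is drawn uniformly from `[0, max_fill)` and those leading
#' samples are replaced by a single constant level drawn uniformly from
#' `[0, intensity]` (small perturbations at stimulus onset must not
#' change the eventual percept).
#'
#' Randomness is taken from R's current RNG stream, so a fixed seed
#' gives bit-identical output.
#'
#' @param stim A `flicker_stimulus` (the long source array).
#' @param target_len Output length in samples.
#' @param max_crop Crop offsets are drawn from `0:(max_crop - 1)`.
#' @param max_fill Fill lengths are drawn from `0:(max_fill - 1)`.
#' @param intensity Upper bound of the uniform fill level; defaults to
#'   the stimulus' own intensity metadata (or its max sample).
#' @return A `flicker_stimulus` of exactly `target_len` samples; the
#'   crop offset, fill length, and fill level are recorded in `$meta`.
#' @export
randomize_onset <- function(stim, target_len, max_crop, max_fill,
                            intensity = NULL) {
  n <- length(stim$samples)
  if (n < target_len + max_crop) {
    stop("source stimulus too short: need at least ", target_len + max_crop,
         " samples, have ", n)
  }
  if (is.null(intensity)) {
    intensity <- if (!is.null(stim$meta$intensity)) stim$meta$intensity
                 else max(stim$samples)
  }
  offset <- if (max_crop > 1) sample.int(max_crop, 1L) - 1L else 0L
  samples <- stim$samples[(offset + 1):(offset + target_len)]
  fill_len <- if (max_fill > 1) sample.int(max_fill, 1L) - 1L else 0L
  fill_level <- NA_real_
  if (fill_len > 0) {
    fill_level <- stats::runif(1, 0, intensity)
    samples[seq_len(fill_len)] <- fill_level
  }
  meta <- stim$meta
  meta$crop_offset <- offset
  meta$fill_len <- fill_len
  meta$fill_level <- fill_level
  new_stimulus(samples, stim$dt_ms, meta)
}

#' Per-experiment stimulus geometry
#'
#' The two experiments use different sampling grids and randomization
#' windows: experiment 1 samples at 1 ms, sources 12 s (12000 samples)
#' and crops to 7168 samples (7.168 s) with crop window 3000 and fill
#' window 500; experiment 2 samples at 0.5 ms, sources 22384 samples and
#' crops to 16384 samples (8.192 s) with crop window 3000 and fill
#' window 700.
#'
#' @param experiment 1 or 2.
#' @return List with `dt_ms`, `source_len`, `target_len`, `max_crop`,
#'   `max_fill`.
#' @export
experiment_geometry <- function(experiment) {
  if (experiment == 1) {
    list(dt_ms = 1, source_len = 12000L, target_len = 7168L,
         max_crop = 3000L, max_fill = 500L)
  } else if (experiment == 2) {
    list(dt_ms = 0.5, source_len = 22384L, target_len = 16384L,
         max_crop = 3000L, max_fill = 700L)
  } else {
    stop("experiment must be 1 or 2")
  }
}

#' Assemble a labeled minibatch of flicker stimuli
#'
#' Builds one training (n = 10 per PCF and label, 100 examples) or
#' validation (n = 50, 500 examples) minibatch for a given intensity.
#' For each of the five PCFs, flickering examples are waves with
#' frequencies drawn uniformly from `[CFF - 2.5, CFF - 1.3]` Hz; fused
#' examples follow [label_ranges()]: in training, 50% waves in
#' `[CFF + 1.3, CFF + 10]` Hz, 25% constants at a uniform level in
#' `[0, intensity]`, 25% constants at 0; in validation, all waves up to
#' the dialect-dependent upper edge. Waves pass through
#' [randomize_onset()] with the geometry of the chosen experiment;
#' constants are generated directly at the target length.
#'
#' Labels are integers: fused = 0, flickering = 1. Class balance is
#' exact by construction.
#'
#' @param table A [cff_table()].
#' @param intensity One of the grid intensities (cd/ft^2).
#' @param mode `"training"` or `"validation"`.
#' @param experiment 1 or 2 (selects sampling interval and windows).
#' @param seed Integer seed; the batch is a pure function of its
#'   arguments.
#' @param n_per_cell Examples per (PCF, label) pair; defaults to 10 for
#'   training, 50 for validation.
#' @param geometry Optional [experiment_geometry()]-style list to
#'   override the stimulus geometry (used for scaled-down runs).
#' @param fused_upper Passed to [label_ranges()].
#' @return A `flicker_minibatch`: list with `x` (examples x samples
#'   matrix), `y` (integer labels), `meta` (data.frame: pcf, label,
#'   kind, frequency, level), plus `intensity`, `mode`, `experiment`,
#'   `dt_ms`, `seed`.
#' @export
build_minibatch <- function(table, intensity, mode = c("training", "validation"),
                            experiment = 1, seed = 1L, n_per_cell = NULL,
                            geometry = NULL,
                            fused_upper = c("absolute_100", "cff_plus_100")) {
  mode <- match.arg(mode)
  fused_upper <- match.arg(fused_upper)
  if (is.null(n_per_cell)) n_per_cell <- if (mode == "training") 10L else 50L
  geo <- geometry %||% experiment_geometry(experiment)
  if (geo$source_len < geo$target_len + geo$max_crop) {
    stop("geometry infeasible: source_len < target_len + max_crop")
  }
  src_dur <- geo$source_len * geo$dt_ms / 1000

  n_pcf <- length(table$pcf_num)
  n_total <- n_pcf * 2L * n_per_cell
  x <- matrix(0, nrow = n_total, ncol = geo$target_len)
  y <- integer(n_total)
  meta <- data.frame(pcf = numeric(n_total), label = integer(n_total),
                     kind = character(n_total), frequency = NA_real_,
                     level = NA_real_)

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  row <- 0L
  for (j in seq_len(n_pcf)) {
    pcf <- table$pcf_num[j] / table$pcf_den[j]
    lr <- label_ranges(table, intensity, pcf, mode, fused_upper)
    for (label in c(0L, 1L)) {
      band <- if (label == 1L) lr$flicker_band else lr$fused_band
      for (k in seq_len(n_per_cell)) {
        row <- row + 1L
        y[row] <- label
        meta$pcf[row] <- pcf
        meta$label[row] <- label
        if (label == 0L && mode == "training") {
          u <- stats::runif(1)
          if (u < 0.25) {
            lev <- stats::runif(1, 0, intensity)
            x[row, ] <- lev
            meta$kind[row] <- "constant_uniform"
            meta$level[row] <- lev
            next
          } else if (u < 0.5) {
            meta$kind[row] <- "constant_zero"
            meta$level[row] <- 0
            next
          }
        }
        f <- stats::runif(1, band[1], band[2])
        pulse <- square_pulse(f, pcf, intensity, src_dur, geo$dt_ms)
        pulse <- randomize_onset(pulse, geo$target_len, geo$max_crop,
                                 geo$max_fill, intensity)
        x[row, ] <- pulse$samples
        meta$kind[row] <- "square"
        meta$frequency[row] <- f
      }
    }
  }
  structure(list(x = x, y = y, meta = meta, intensity = intensity,
                 mode = mode, experiment = experiment, dt_ms = geo$dt_ms,
                 seed = as.integer(seed)),
            class = "flicker_minibatch")
}

#' @export
print.flicker_minibatch <- function(x, ...) {
  cat(sprintf("flicker minibatch: %d examples (%s, intensity %g cd/ft^2), %d samples @ %g ms\n",
              nrow(x$x), x$mode, x$intensity, ncol(x$x), x$dt_ms))
  invisible(x)
}

#' Export a minibatch as CSV
#'
#' One row per example: label, kind, pcf, frequency, level, then the
#' raw samples.
#'
#' @param batch A `flicker_minibatch`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_minibatch <- function(batch, path) {
  df <- cbind(batch$meta[c("label", "kind", "pcf", "frequency", "level")],
              as.data.frame(batch$x))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Save/restore the global RNG state so seeded generators do not disturb
# the caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
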