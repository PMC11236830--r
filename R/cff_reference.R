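#' Critical flicker frequency reference table
#'
#' Loads the packaged psychophysics reference grid: critical flicker
#' frequencies (CFF, in Hz) for rectangular flicker at five luminances
#' (5340, 534, 53.4, 5.34 and 0.53 cd/ft^2) and five pulse-to-cycle
#' fractions (PCF = duty cycle: 1/6, 1/3, 1/2, 2/3, 5/6), measured for a
#' single observer by the method of limits. This grid is the only
#' empirical input of the whole modelling pipeline: the label bands of
#' the synthetic training distribution are derived from it with
#' [label_ranges()].
#'
#' The printed grid contains one typographical anomaly: the cell at
#' 5.34 cd/ft^2, PCF 1/2 reads 5.67 Hz, which breaks the otherwise
#' smooth structure of the table (its neighbours are 27.2 and 25.2 Hz).
#' By default the loader replaces it with 25.67 Hz, the value consistent
#' with a dropped leading digit; the raw printed number is kept in
#' `attr(tab, "raw_printed")` and the cell can be overridden.
#'
#' PCFs are carried as exact integer fractions (`pcf_num`/`pcf_den`) and
#' only converted to floating point at stimulus-synthesis time, so duty
#' cycles never drift.
#'
#' @param path Path to a CSV mirroring the packaged reference file
#'   (columns `intensity, pcf_1_6, pcf_1_3, pcf_1_2, pcf_2_3, pcf_5_6`).
#'   Defaults to the packaged table.
#' @param correct_misprint Replace the anomalous 5.34 / PCF 1/2 cell by
#'   25.67 Hz (default `TRUE`).
#' @param override Optional named list of cell overrides, each element
#'   `list(intensity =, pcf =, cff =)`, applied after the misprint
#'   correction.
#' @return An object of class `cff_table`: a list with `intensities`
#'   (decreasing, cd/ft^2), `pcf_num`, `pcf_den` (exact fractions), and
#'   `cff`, a 5 x 5 matrix (rows = intensities, cols = PCFs) in Hz.
#' @examples
#' tab <- cff_table()
#' cff_lookup(tab, 53.4, 1/2)   # 36.33 Hz
#' @export
cff_table <- function(path = NULL, correct_misprint = TRUE, override = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cff_table.csv", package = "flickerprobe")
  }
  raw <- utils::read.csv(path, check.names = FALSE)
  expected <- c("intensity", "pcf_1_6", "pcf_1_3", "pcf_1_2", "pcf_2_3", "pcf_5_6")
  if (!identical(names(raw), expected)) {
    stop("CFF table must have columns: ", paste(expected, collapse = ", "))
  }
  intensities <- raw$intensity
  cff <- as.matrix(raw[, -1])
  dimnames(cff) <- list(format(intensities, trim = TRUE),
                        c("1/6", "1/3", "1/2", "2/3", "5/6"))
  raw_printed <- cff

  if (correct_misprint) {
    i <- match(5.34, intensities)
    if (!is.na(i) && isTRUE(all.equal(cff[i, "1/2"], 5.67))) {
      cff[i, "1/2"] <- 25.67
    }
  }
  tab <- structure(
    list(intensities = intensities,
         pcf_num = c(1L, 1L, 1L, 2L, 5L),
         pcf_den = c(6L, 3L, 2L, 3L, 6L),
         cff = cff),
    raw_printed = raw_printed,
    class = "cff_table")

  if (!is.null(override)) {
    for (ov in override) {
      idx <- .cff_index(tab, ov$intensity, ov$pcf)
      tab$cff[idx$i, idx$j] <- ov$cff
    }
  }
  validate_cff_table(tab)
  tab
}

#' @export
print.cff_table <- function(x, ...) {
  cat("CFF reference table (Hz); rows = intensity (cd/ft^2), cols = PCF\n")
  print(x$cff)
  invisible(x)
}

# Resolve (intensity, pcf) to grid indices; pcf may be numeric or "a/b".
.cff_index <- function(table, intensity, pcf) {
  i <- which(abs(table$intensities - intensity) <= 1e-9)
  if (length(i) != 1L) {
    stop("intensity ", intensity, " cd/ft^2 is not in the CFF grid")
  }
  if (is.character(pcf)) {
    parts <- strsplit(pcf, "/", fixed = TRUE)[[1]]
    pcf <- as.numeric(parts[1]) / as.numeric(parts[2])
  }
  j <- which(abs(table$pcf_num / table$pcf_den - pcf) <= 1e-9)
  if (length(j) != 1L) {
    stop("PCF ", format(pcf), " is not in the CFF grid")
  }
  list(i = i, j = j)
}

validate_cff_table <- function(tab) {
  stopifnot(inherits(tab, "cff_table"))
  if (any(diff(tab$intensities) >= 0) || anyDuplicated(tab$intensities)) {
    stop("intensities must be strictly decreasing and duplicate-free")
  }
  p <- tab$pcf_num / tab$pcf_den
  if (any(diff(p) <= 0) || any(p <= 0 | p >= 1)) {
    stop("PCFs must be strictly increasing fractions in (0, 1)")
  }
  if (any(!is.finite(tab$cff)) || any(tab$cff <= 0) || any(tab$cff >= 500)) {
    stop("all CFF values must be positive and below the 500 Hz stimulus Nyquist")
  }
  invisible(tab)
}

#' Look up a critical flicker frequency
#'
#' @param table A [cff_table()] object.
#' @param intensity Luminance in cd/ft^2; must be one of the grid values.
#' @param pcf Pulse-to-cycle fraction, numeric (e.g. `1/6`) or a string
#'   fraction (e.g. `"1/6"`).
#' @return The CFF in Hz.
#' @export
cff_lookup <- function(table, intensity, pcf) {
  idx <- .cff_index(table, intensity, pcf)
  unname(table$cff[idx$i, idx$j])
}

#' Write a CFF table back to CSV
#'
#' Serializes the raw printed grid (i.e. without the misprint
#' correction) in the same CSV layout the loader reads, so the packaged
#' reference round-trips exactly.
#'
#' @param table A [cff_table()] object.
#' @param path Output CSV path.
#' @param raw Write the raw printed values (default) rather than the
#'   corrected grid.
#' @return `path`, invisibly.
#' @export
write_cff_table <- function(table, path, raw = TRUE) {
  m <- if (raw) attr(table, "raw_printed") else table$cff
  df <- data.frame(intensity = table$intensities, m, check.names = FALSE)
  names(df) <- c("intensity", "pcf_1_6", "pcf_1_3", "pcf_1_2", "pcf_2_3", "pcf_5_6")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Label frequency bands around a CFF threshold
#'
#' Derives, for one (intensity, PCF) cell of the reference grid, the
#' frequency bands used to label synthetic photic pulses:
#'
#' * flickering: frequencies in `[CFF - 2.5, CFF - 1.3]` Hz (both modes);
#' * fused, training: waves in `[CFF + 1.3, CFF + 10]` Hz with
#'   probability 0.5, a constant stimulus at a uniform level in
#'   `[0, intensity]` with probability 0.25, and a constant 0 stimulus
#'   with probability 0.25;
#' * fused, validation: waves in `[CFF + 1.3, 100]` Hz (default) or
#'   `[CFF + 1.3, CFF + 100]` Hz with `fused_upper = "cff_plus_100"`.
#'
#' The flickering band is kept narrow (1.2 Hz) because a slow pulse of
#' finite duration is hard to tell from a steady light; the two constant
#' cases teach the network that steady inputs of any level are fused.
#'
#' @param table A [cff_table()] object.
#' @inheritParams cff_lookup
#' @param mode `"training"` or `"validation"`.
#' @param fused_upper Dialect for the validation fused band upper edge:
#'   `"absolute_100"` (default) or `"cff_plus_100"`.
#' @return An object of class `label_ranges`: list with `intensity`,
#'   `pcf`, `cff`, `mode`, `flicker_band`, `fused_band` (Hz intervals)
#'   and, for training, `constant_fractions = c(uniform = 0.25, zero
#'   = 0.25)` with `wave_fraction = 0.5`.
#' @export
label_ranges <- function(table, intensity, pcf, mode = c("training", "validation"),
                         fused_upper = c("absolute_100", "cff_plus_100")) {
  mode <- match.arg(mode)
  fused_upper <- match.arg(fused_upper)
  cff <- cff_lookup(table, intensity, pcf)
  flicker_band <- c(cff - 2.5, cff - 1.3)
  fused_band <- if (mode == "training") {
    c(cff + 1.3, cff + 10)
  } else if (fused_upper == "absolute_100") {
    c(cff + 1.3, 100)
  } else {
    c(cff + 1.3, cff + 100)
  }
  if (fused_band[2] <= fused_band[1]) {
    stop("degenerate fused band for CFF ", cff, " Hz under dialect ", fused_upper)
  }
  structure(
    list(intensity = intensity,
         pcf = if (is.character(pcf)) eval(parse(text = pcf)) else pcf,
         cff = cff, mode = mode,
         flicker_band = flicker_band,
         fused_band = fused_band,
         wave_fraction = if (mode == "training") 0.5 else 1.0,
         constant_fractions = if (mode == "training") {
           c(uniform = 0.25, zero = 0.25)
         } else {
           c(uniform = 0, zero = 0)
         }),
    class = "label_ranges")
}
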