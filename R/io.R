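#' Resolved configuration defaults
#'
#' All dialect switches and tunables of the pipeline in one flat list:
#'
#' * `fused_upper`: validation fused-band upper edge, `"absolute_100"`
#'   (default) or `"cff_plus_100"` (see [label_ranges()]);
#' * `exp2_kernel_len`: 280 (default, matches the published parameter
#'   count and the 140 ms kernel span) or 140 (reproduces the published
#'   conv output length 16245);
#' * `sinusoidality_threshold`: index above which a response is reported
#'   as sinusoidal (default 5);
#' * `cff_misprint_correction`: correct the 5.34 / PCF 1/2 cell
#'   (default TRUE) — see [cff_table()];
#' * `cff_override`: optional list of cell overrides passed through to
#'   [cff_table()];
#' * `adam`: optimizer hyperparameters (`lr` 0.001, `beta1` 0.9,
#'   `beta2` 0.999, `eps` 1e-7);
#' * `seed`: master seed (default 1).
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(fused_upper = "absolute_100",
       exp2_kernel_len = 280L,
       sinusoidality_threshold = 5,
       cff_misprint_correction = TRUE,
       cff_override = NULL,
       adam = list(lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-7),
       seed = 1L)
}

#' Load and validate a configuration file
#'
#' Reads a YAML file (any subset of the keys of [default_config()]),
#' fills in defaults, and validates every field with a field-naming
#' error message. `load_config(NULL)` returns the pure defaults.
#'
#' @param path Path to a YAML config, or `NULL` for defaults.
#' @return Validated configuration list with all defaults resolved.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown)) {
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
      }
      for (nm in names(user)) {
        if (nm == "adam") {
          bad <- setdiff(names(user$adam), names(cfg$adam))
          if (length(bad)) stop("unknown config field(s): adam.",
                                paste(bad, collapse = ", adam."))
          cfg$adam[names(user$adam)] <- user$adam
        } else {
          cfg[[nm]] <- user[[nm]]
        }
      }
    }
  }
  if (!cfg$fused_upper %in% c("absolute_100", "cff_plus_100")) {
    stop("config field 'fused_upper' must be 'absolute_100' or 'cff_plus_100'")
  }
  if (!cfg$exp2_kernel_len %in% c(280L, 140L)) {
    stop("config field 'exp2_kernel_len' must be 280 or 140")
  }
  if (!is.numeric(cfg$sinusoidality_threshold) ||
      cfg$sinusoidality_threshold <= 0) {
    stop("config field 'sinusoidality_threshold' must be a positive number")
  }
  if (!is.logical(cfg$cff_misprint_correction)) {
    stop("config field 'cff_misprint_correction' must be TRUE or FALSE")
  }
  for (nm in c("lr", "beta1", "beta2", "eps")) {
    v <- cfg$adam[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop("config field 'adam.", nm, "' must be a positive number")
    }
  }
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
    stop("config field 'seed' must be an integer")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$exp2_kernel_len <- as.integer(cfg$exp2_kernel_len)
  cfg
}

#' Write tabular results with round-trip safety
#'
#' @param records A non-empty data.frame (long-format probe output,
#'   training log, ...).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("records must be a non-empty data.frame")
  }
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read results written by [write_results()]
#'
#' @param path File path (.csv or .json).
#' @return A data.frame.
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
}

#' Write a reproducibility manifest for a run directory
#'
#' Records the resolved configuration, master seed, package and R
#' versions, a timestamp, and an MD5 checksum inventory of the listed
#' output files — enough to re-run and compare a pipeline invocation.
#'
#' @param outdir Run directory.
#' @param config Resolved configuration list.
#' @param seed Master seed used.
#' @param files Character vector of output file paths to inventory.
#' @param path Manifest path (default `<outdir>/manifest.json`).
#' @return The manifest list, invisibly; written as JSON.
#' @export
run_manifest <- function(outdir, config, seed, files = character(),
                         path = file.path(outdir, "manifest.json")) {
  inv <- lapply(files, function(f) {
    list(file = basename(f), md5 = unname(tools::md5sum(f)),
         bytes = file.size(f))
  })
  manifest <- list(
    package = "flickerprobe",
    version = as.character(utils::packageVersion("flickerprobe")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    files = inv)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
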