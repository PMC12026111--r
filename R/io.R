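# File formats and the seeded fixture generator.
#
# Traces are long-format CSV (time_s, channel, value) at the detector
# sampling rate; amplification curves are per-cycle CSV (cycle,
# fluorescence[, timestamp_s]); a run manifest maps sample files to
# concentrations. Fixtures are generated, never downloaded: every fixture
# ships with a sidecar JSON of the ground-truth parameters that produced
# it, so tests can make exact parameter-recovery assertions.

trace_channels <- c("green", "yellow", "orange", "red")

#' Read and write fluorescence traces
#'
#' CSV with header `time_s, channel, value`; channels are the detector's
#' four optical channels (green, yellow, orange, red); timestamps must be
#' strictly increasing within each channel. `write_trace()` /
#' `read_trace()` round-trip exactly at full double precision.
#'
#' @param path File path.
#' @return `read_trace()` returns a tibble (`time_s`, `channel`, `value`).
#' @export
read_trace <- function(path) {
  # numeric columns come in as text and go through strtod (as.numeric):
  # exact round-trip of the %.17g representation written by write_trace
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0L) {
    abort("trace file is empty.", class = "adaptivepcr_validation_error")
  }
  if (!all(c("time_s", "channel", "value") %in% names(df))) {
    abort("trace must have columns time_s, channel, value.",
          class = "adaptivepcr_validation_error")
  }
  df <- parse_num_cols(df, c("time_s", "value"))
  check_trace(df)
  df[c("time_s", "channel", "value")]
}

parse_num_cols <- function(df, cols) {
  for (col in cols) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !is.na(df[[col]]))
    if (length(bad) > 0L) {
      abort(sprintf("malformed value '%s' in column '%s' at data row %d.",
                    df[[col]][bad[1]], col, bad[1]),
            class = "adaptivepcr_validation_error")
    }
    df[[col]] <- x
  }
  df
}

check_trace <- function(df) {
  if (!all(c("time_s", "channel", "value") %in% names(df))) {
    abort("trace must have columns time_s, channel, value.",
          class = "adaptivepcr_validation_error")
  }
  bad_ch <- setdiff(unique(df$channel), trace_channels)
  if (length(bad_ch) > 0L) {
    abort(sprintf("unknown channel '%s' (expected %s).",
                  bad_ch[1], paste(trace_channels, collapse = ", ")),
          class = "adaptivepcr_validation_error")
  }
  for (ch in unique(df$channel)) {
    rows <- which(df$channel == ch)
    t <- df$time_s[rows]
    ooo <- which(diff(t) <= 0)
    if (length(ooo) > 0L) {
      abort(sprintf("timestamps not strictly increasing in channel '%s' at row %d.",
                    ch, rows[ooo[1] + 1L]),
            class = "adaptivepcr_validation_error")
    }
  }
  invisible(df)
}

# shortest exact decimal representation: %.17g round-trips every double
fmt_full <- function(x) {
  if (is.double(x)) sub("^ +", "", sprintf("%.17g", x)) else x
}

#' @param traces Tibble with `time_s`, `channel`, `value` (e.g.
#'   `pcr_run$traces`).
#' @rdname read_trace
#' @export
write_trace <- function(traces, path) {
  check_trace(traces)
  out <- traces[c("time_s", "channel", "value")]
  out$time_s <- fmt_full(out$time_s)
  out$value <- fmt_full(out$value)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write per-cycle amplification curves
#'
#' CSV with header `cycle, fluorescence` and optional `timestamp_s`; cycles
#' must be consecutive integers starting at 1.
#'
#' @param path File path.
#' @return `read_amplification()` returns a tibble.
#' @export
read_amplification <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!all(c("cycle", "fluorescence") %in% names(df))) {
    abort("curve must have `cycle` and `fluorescence` columns.",
          class = "adaptivepcr_validation_error")
  }
  df <- parse_num_cols(df, intersect(c("cycle", "fluorescence", "timestamp_s"),
                                     names(df)))
  df$cycle <- as.integer(df$cycle)
  check_amplification(df)
  as_tibble(df)
}

#' @param curve Amplification tibble (`cycle`, `fluorescence`[,
#'   `timestamp_s`]).
#' @rdname read_amplification
#' @export
write_amplification <- function(curve, path) {
  check_amplification(curve)
  out <- as_tibble(curve)
  for (col in intersect(c("fluorescence", "timestamp_s"), names(out))) {
    out[[col]] <- fmt_full(out[[col]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a run manifest
#'
#' CSV mapping sample files to their roles: columns `sample_id` (unique),
#' `concentration` (copies/uL, empty for NTC), `role` (`sample` or `NTC`)
#' and `file`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_run_manifest <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    concentration = readr::col_double(),
    role = readr::col_character(), file = readr::col_character()
  ), progress = FALSE)
  if (anyDuplicated(df$sample_id)) {
    abort("sample ids in the manifest must be unique.",
          class = "adaptivepcr_validation_error")
  }
  if (!all(df$role %in% c("sample", "NTC"))) {
    abort("manifest `role` must be 'sample' or 'NTC'.",
          class = "adaptivepcr_validation_error")
  }
  df
}

#' Generate seeded test fixtures
#'
#' Writes deterministic synthetic data sets of a given kind to `dir`,
#' together with a `*_truth.json` sidecar recording the exact generator
#' parameters, so downstream analyses can be checked against ground truth.
#'
#' * `"melt_trace"`: a short closed-loop simulated run; writes `trace.csv`.
#' * `"amplification_curve"`: one per-cycle curve; writes `curve.csv`.
#' * `"dilution_series"`: a 7-decade standard-curve/LoD experiment
#'   (10^5..10^-1 copies/uL, 4 replicates each, plus NTCs); writes one
#'   curve CSV per sample and `manifest.csv`.
#' * `"gain_curves"`: LED gain-response curves for a control and an
#'   attenuated sample; writes `gain_control.csv` and `gain_sample.csv`.
#'
#' @param kind Fixture kind (see above).
#' @param seed Integer seed; identical seeds give identical files.
#' @param dir Output directory (created if needed).
#' @param ... Overrides passed to the underlying generator
#'   ([sim_config()] fields for `melt_trace`, [simulate_amplification()] /
#'   [simulate_dilution_series()] arguments otherwise).
#' @return Invisibly, the paths written.
#' @export
generate_fixture <- function(kind = c("melt_trace", "amplification_curve",
                                      "dilution_series", "gain_curves"),
                             seed = 1L, dir = ".", ...) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  sidecar <- function(name, truth) {
    p <- file.path(dir, paste0(name, "_truth.json"))
    jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    p
  }
  if (kind == "melt_trace") {
    cfg <- sim_config(seed = seed, n_cycles = 2L, ...)
    run <- simulate_run(cfg)
    p <- file.path(dir, "trace.csv")
    write_trace(run$traces, p)
    paths <- c(p, sidecar("trace", list(
      seed = seed, n_cycles = cfg$n_cycles, sampling_hz = cfg$sampling_hz,
      noise_sd = cfg$noise_sd,
      anneal_tm = cfg$anneal_sensor$tm_celsius,
      melt_tm = cfg$melt_sensor$tm_celsius,
      heat_rate = cfg$thermal$heat_rate, cool_rate = cfg$thermal$cool_rate,
      switch_times = run$switch_points$time_s
    )))
  } else if (kind == "amplification_curve") {
    set.seed(as.integer(seed))
    curve <- simulate_amplification(...)
    p <- file.path(dir, "curve.csv")
    write_amplification(curve, p)
    paths <- c(p, sidecar("curve", c(list(seed = seed), attr(curve, "truth"))))
  } else if (kind == "dilution_series") {
    series <- simulate_dilution_series(seed = seed, ...)
    files <- file.path(dir, paste0(series$sample_id, ".csv"))
    purrr::walk2(series$curve, files, write_amplification)
    manifest <- tibble(
      sample_id = series$sample_id, concentration = series$concentration,
      role = series$role, file = basename(files)
    )
    mp <- file.path(dir, "manifest.csv")
    readr::write_csv(manifest, mp)
    paths <- c(files, mp, sidecar("dilution_series", list(
      seed = seed,
      efficiency = attr(series$curve[[1]], "truth")$efficiency,
      copies = setNames(as.list(series$copies), series$sample_id)
    )))
  } else if (kind == "gain_curves") {
    set.seed(as.integer(seed))
    power <- seq(10, 100, by = 10)
    blocking <- 0.45
    control <- tibble(power = power, fluorescence = 12 * power)
    sample <- tibble(power = power, fluorescence = blocking * 12 * power)
    pc <- file.path(dir, "gain_control.csv")
    ps <- file.path(dir, "gain_sample.csv")
    readr::write_csv(control, pc)
    readr::write_csv(sample, ps)
    paths <- c(pc, ps, sidecar("gain", list(seed = seed,
                                            blocking_fraction = blocking)))
  }
  invisible(paths)
}
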