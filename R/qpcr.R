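# Quantification methods for per-cycle amplification curves: baseline
# normalization, fractional Cq by threshold crossing with monotone-spline
# interpolation, window-of-linearity single-sample efficiency, standard
# curves, cycle-time and limit-of-detection summaries.

check_amplification <- function(curve) {
  if (!is.data.frame(curve) ||
      !all(c("cycle", "fluorescence") %in% names(curve))) {
    abort("`curve` must have `cycle` and `fluorescence` columns.",
          class = "adaptivepcr_validation_error")
  }
  if (!isTRUE(all.equal(as.numeric(curve$cycle), seq_len(nrow(curve))))) {
    abort("cycles must be consecutive integers starting at 1.",
          class = "adaptivepcr_validation_error")
  }
  invisible(curve)
}

#' Normalize an amplification curve to a 0-100 relative scale
#'
#' Subtracts the baseline (mean fluorescence over the first
#' `baseline_cycles` cycles), divides by the highest baseline-subtracted
#' fluorescence, and multiplies by 100, so curves from instruments with
#' different gains are directly comparable. The baseline mean and standard
#' deviation (raw units) and the post-subtraction maximum are retained as
#' attributes for threshold-based Cq calling.
#'
#' @param curve Data frame with columns `cycle` (consecutive from 1),
#'   `fluorescence`, and optionally `timestamp_s`.
#' @param baseline_cycles Number of initial cycles averaged for the
#'   baseline (default 15).
#' @return A tibble of class `normalized_curve` with columns `cycle`,
#'   `value` (0-100 scale) and `timestamp_s` (if supplied), and attributes
#'   `baseline_mean`, `baseline_sd`, `max_raw`, `baseline_cycles` and
#'   `flat`. A curve with no fluorescence rise above baseline is flagged
#'   `flat = TRUE` (values left on the subtracted scale, not divided) and
#'   will be called negative downstream.
#' @export
normalize_curve <- function(curve, baseline_cycles = 15L) {
  check_amplification(curve)
  n <- nrow(curve)
  if (n < baseline_cycles + 1L) {
    abort(sprintf("curve has %d cycles; need at least %d for a %d-cycle baseline.",
                  n, baseline_cycles + 1L, baseline_cycles),
          class = "adaptivepcr_validation_error")
  }
  f <- curve$fluorescence
  base <- f[seq_len(baseline_cycles)]
  baseline_mean <- mean(base)
  baseline_sd <- sd(base)
  sub <- f - baseline_mean
  max_raw <- max(sub)
  flat <- max_raw <= 0 || isTRUE(all.equal(min(sub), max_raw))
  out <- tibble(cycle = as.integer(curve$cycle),
                value = if (flat) sub else 100 * sub / max_raw)
  if ("timestamp_s" %in% names(curve)) out$timestamp_s <- curve$timestamp_s
  structure(out,
            class = c("normalized_curve", class(out)),
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            max_raw = max_raw, baseline_cycles = as.integer(baseline_cycles),
            flat = flat)
}

#' Call the quantification cycle (Cq)
#'
#' Cq is the first (fractional) cycle at which the baseline-subtracted
#' fluorescence reaches `k_sd` standard deviations of the baseline. The
#' threshold is applied on the baseline-subtracted raw scale, so it retains
#' instrument units; a shape-preserving monotone cubic spline through the
#' cycles around the first crossing interpolates the fractional value
#' (avoiding the overshoot a natural cubic spline can introduce). When the
#' curve carries timestamps, the quantification time is interpolated at the
#' fractional Cq the same way, giving the wall-clock analog of Cq for
#' instruments with variable cycle times.
#'
#' @param norm A [normalize_curve()] result.
#' @param k_sd Threshold multiplier (default 10 baseline SDs).
#' @param sd_floor Floor applied to the baseline SD when it is numerically
#'   zero (noiseless synthetic curves); a warning is emitted when used.
#' @return A one-row tibble of class `cq_result`: `cq` (fractional cycle or
#'   `NA`), `positive`, `threshold` (baseline-subtracted raw scale) and
#'   `quantification_time_s` (`NA` without timestamps).
#' @export
call_cq <- function(norm, k_sd = 10, sd_floor = 1e-6) {
  stopifnot(inherits(norm, "normalized_curve"))
  baseline_sd <- attr(norm, "baseline_sd")
  max_raw <- attr(norm, "max_raw")
  if (baseline_sd < sd_floor) {
    warn(sprintf("baseline SD %.3g below floor; using sd_floor = %.3g.",
                 baseline_sd, sd_floor))
    baseline_sd <- sd_floor
  }
  threshold <- k_sd * baseline_sd
  negative <- tibble(cq = NA_real_, positive = FALSE, threshold = threshold,
                     quantification_time_s = NA_real_)
  class(negative) <- c("cq_result", class(negative))
  if (isTRUE(attr(norm, "flat"))) return(negative)

  sub <- norm$value * max_raw / 100   # back to baseline-subtracted raw scale
  idx <- which(sub >= threshold)
  if (length(idx) == 0L) return(negative)
  i <- idx[1]
  if (i <= attr(norm, "baseline_cycles")) {
    warn(sprintf("threshold crossing at cycle %d falls inside the %d-cycle baseline window.",
                 i, attr(norm, "baseline_cycles")))
  }
  n <- nrow(norm)
  if (i == 1L) {
    cq <- 1
  } else if (sub[i] == threshold) {
    cq <- as.numeric(i)
  } else {
    lo <- max(1L, i - 3L)
    hi <- min(n, i + 2L)
    sf <- splinefun(norm$cycle[lo:hi], sub[lo:hi], method = "monoH.FC")
    cq <- uniroot(function(x) sf(x) - threshold,
                  lower = i - 1L, upper = i, tol = 1e-9)$root
  }
  qt <- NA_real_
  if ("timestamp_s" %in% names(norm)) {
    qt <- approx(norm$cycle, norm$timestamp_s, xout = cq)$y
  }
  out <- tibble(cq = cq, positive = TRUE, threshold = threshold,
                quantification_time_s = qt)
  class(out) <- c("cq_result", class(out))
  out
}

#' Single-sample efficiency from the window of linearity
#'
#' Estimates the per-cycle amplification factor of one reaction without a
#' standard curve: an ordinary least-squares line is fitted to the natural
#' log of the normalized fluorescence over a window of `window` consecutive
#' cycles centered on the nearest integer cycle to the fractional Cq (the
#' exponential phase), and the efficiency is `exp(slope)`. If the window
#' contains non-positive normalized values (log undefined), it is shifted
#' upward by the minimal number of cycles that avoids them, and the shift is
#' reported.
#'
#' @param norm A [normalize_curve()] result.
#' @param cq Fractional Cq (e.g. from [call_cq()]).
#' @param window Window length in cycles (default 5).
#' @return A one-row tibble: `efficiency`, `slope` (per cycle),
#'   `r_squared`, `window_start`, `window_end`, `shifted`.
#' @export
single_sample_efficiency <- function(norm, cq, window = 5L) {
  stopifnot(inherits(norm, "normalized_curve"))
  if (inherits(cq, "cq_result")) cq <- cq$cq
  if (is.na(cq)) {
    abort("cannot estimate efficiency for a negative sample (Cq is NA).",
          class = "adaptivepcr_validation_error")
  }
  window <- as.integer(window)
  n <- nrow(norm)
  half <- (window - 1L) %/% 2L
  start <- max(1L, round(cq) - half)
  shifted <- FALSE
  repeat {
    end <- start + window - 1L
    if (end > n) {
      abort("no window of positive normalized values fits within the curve.",
            class = "adaptivepcr_validation_error")
    }
    vals <- norm$value[start:end]
    if (all(vals > 0)) break
    start <- start + 1L
    shifted <- TRUE
  }
  if (shifted) {
    warn(sprintf("efficiency window shifted upward to cycles %d-%d to avoid non-positive values.",
                 start, end))
  }
  cyc <- norm$cycle[start:end]
  fit <- lm(log(vals) ~ cyc)
  slope <- unname(coef(fit)[2])
  # summary.lm warns on numerically exact fits; r.squared is still valid
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble(
    efficiency = exp(slope), slope = slope,
    r_squared = r2,
    window_start = start, window_end = end, shifted = shifted
  )
}

#' Normalize, call Cq and estimate efficiency for one curve
#'
#' Convenience wrapper chaining [normalize_curve()], [call_cq()] and (for
#' positive calls) [single_sample_efficiency()].
#'
#' @inheritParams normalize_curve
#' @inheritParams call_cq
#' @param efficiency_window Window length for the efficiency estimate.
#' @return A one-row tibble: `cq`, `positive`, `threshold`,
#'   `quantification_time_s`, `efficiency`, `slope`, `r_squared`.
#' @export
analyze_curve <- function(curve, baseline_cycles = 15L, k_sd = 10,
                          sd_floor = 1e-6, efficiency_window = 5L) {
  norm <- normalize_curve(curve, baseline_cycles)
  cq <- call_cq(norm, k_sd = k_sd, sd_floor = sd_floor)
  eff <- if (cq$positive) {
    single_sample_efficiency(norm, cq, window = efficiency_window)
  } else {
    tibble(efficiency = NA_real_, slope = NA_real_, r_squared = NA_real_,
           window_start = NA_integer_, window_end = NA_integer_,
           shifted = NA)
  }
  dplyr::bind_cols(as_tibble(cq),
                   eff[c("efficiency", "slope", "r_squared")])
}

#' Fit a qPCR standard curve
#'
#' Linear regression of Cq on log10 template concentration across a
#' dilution series; the overall amplification efficiency is the standard
#' convention `10^(-1/slope)` (slope -3.32 cycles/decade corresponds to
#' perfect doubling, E = 2).
#'
#' @param samples Data frame with one row per reaction: a concentration
#'   column (`log10_conc`, or `concentration` in copies/uL which will be
#'   log10-transformed) and `cq`; an optional logical `positive` column
#'   (rows that are `FALSE` or have `NA` Cq are excluded and counted).
#' @return An object of class `standard_curve`: list with the fitted `lm`,
#'   per-concentration summary `points`, `slope`, `intercept`, `r_squared`,
#'   `efficiency`, `n_used` and `n_excluded`. Requires positive calls at >=
#'   3 distinct concentrations.
#' @export
standard_curve <- function(samples) {
  if (!is.data.frame(samples) || !"cq" %in% names(samples)) {
    abort("`samples` must be a data frame with a `cq` column.",
          class = "adaptivepcr_validation_error")
  }
  if ("log10_conc" %in% names(samples)) {
    x <- samples$log10_conc
  } else if ("concentration" %in% names(samples)) {
    x <- log10(samples$concentration)
  } else {
    abort("`samples` needs a `log10_conc` or `concentration` column.",
          class = "adaptivepcr_validation_error")
  }
  keep <- !is.na(samples$cq) & is.finite(x)
  if ("positive" %in% names(samples)) keep <- keep & samples$positive
  n_excluded <- sum(!keep)
  dat <- tibble(log10_conc = x[keep], cq = samples$cq[keep])
  if (length(unique(dat$log10_conc)) < 3L) {
    abort("standard curve needs positive calls at >= 3 distinct concentrations.",
          class = "adaptivepcr_validation_error")
  }
  fit <- lm(cq ~ log10_conc, data = dat)
  slope <- unname(coef(fit)[2])
  points <- dplyr::summarise(
    dplyr::group_by(dat, .data$log10_conc),
    mean_cq = mean(.data$cq), sd_cq = sd(.data$cq), n = dplyr::n(),
    .groups = "drop"
  )
  structure(list(
    fit = fit, points = points, slope = slope,
    intercept = unname(coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    efficiency = 10^(-1 / slope),
    n_used = nrow(dat), n_excluded = n_excluded
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.4f cycles/decade, efficiency %.3f, r^2 %.4f (%d reactions, %d excluded)\n",
    x$slope, x$efficiency, x$r_squared, x$n_used, x$n_excluded))
  invisible(x)
}

#' Average cycle time over a cycle window
#'
#' Mean (and SD) of per-cycle durations over an inclusive cycle window,
#' default cycles 2-11: the first cycle is excluded because its duration
#' depends on the starting/environmental temperature.
#'
#' @param cycles A `pcr_run`/`control_result`, or its `cycles` tibble with
#'   `heat_duration_s` and `cool_duration_s` (or a `duration_s` column).
#' @param first,last Inclusive cycle window (default 2-11).
#' @return A one-row tibble: `mean_s`, `sd_s`, `n`.
#' @export
average_cycle_time <- function(cycles, first = 2L, last = 11L) {
  if (inherits(cycles, c("pcr_run", "control_result"))) cycles <- cycles$cycles
  if (!is.data.frame(cycles) || !"cycle" %in% names(cycles)) {
    abort("`cycles` must be a cycles tibble or a run object.",
          class = "adaptivepcr_validation_error")
  }
  if (max(cycles$cycle) < last) {
    abort(sprintf("need at least %d cycles; have %d.", last, max(cycles$cycle)),
          class = "adaptivepcr_validation_error")
  }
  dur <- if ("duration_s" %in% names(cycles)) {
    cycles$duration_s
  } else {
    cycles$heat_duration_s + cycles$cool_duration_s
  }
  w <- cycles$cycle >= first & cycles$cycle <= last
  tibble(mean_s = mean(dur[w]), sd_s = sd(dur[w]), n = sum(w))
}

#' Limit of detection from replicate calls
#'
#' The limit of detection is the lowest template concentration at which
#' every replicate is called positive.
#'
#' @param results Data frame with one row per reaction: `concentration`
#'   (copies/uL) and `positive` (logical). NTC rows (`NA` concentration)
#'   are ignored.
#' @return A list of class `lod_result`: `lod` (copies/uL, or `NA` when no
#'   concentration qualifies) and `table`, a per-concentration tibble
#'   (`concentration`, `n`, `n_positive`, `all_positive`).
#' @export
lod_call <- function(results) {
  if (!is.data.frame(results) ||
      !all(c("concentration", "positive") %in% names(results))) {
    abort("`results` must have `concentration` and `positive` columns.",
          class = "adaptivepcr_validation_error")
  }
  res <- dplyr::filter(results, !is.na(.data$concentration))
  if (nrow(res) == 0L) {
    abort("no concentrations to evaluate.", class = "adaptivepcr_validation_error")
  }
  table <- dplyr::arrange(dplyr::summarise(
    dplyr::group_by(res, .data$concentration),
    n = dplyr::n(), n_positive = sum(.data$positive),
    all_positive = all(.data$positive), .groups = "drop"
  ), dplyr::desc(.data$concentration))
  qualifying <- table$concentration[table$all_positive]
  lod <- if (length(qualifying)) min(qualifying) else NA_real_
  structure(list(lod = lod, table = table), class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> LoD = %s copies/uL\n",
              if (is.na(x$lod)) "not reached" else format(x$lod)))
  print(x$table)
  invisible(x)
}
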