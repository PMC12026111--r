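# The adaptive cycling-control algorithm.
#
# Instead of preset temperatures, the instrument watches the fluorescence of
# L-DNA sensor duplexes: during heating the melt-sensor channel rises as the
# duplex denatures, during cooling the anneal-sensor channel falls as it
# re-forms. A Gaussian is fitted, continuously as samples stream in, to the
# smoothed time-derivative of the watched channel; the controller switches
# phase when the derivative is predicted to have decayed to near zero, at
# t* = mu + alpha * sigma. Operating on the derivative makes the decision
# invariant to gain and offset changes in the raw fluorescence.

#' Controller tuning parameters
#'
#' @param smooth_window Width (odd number of samples, >= 3) of the centered
#'   moving average applied before differentiation. Default 7 samples
#'   (~0.23 s at 30 Hz).
#' @param alpha Switch threshold in sigmas past the fitted derivative peak:
#'   the phase switches at t* = mu + alpha*sigma, where the derivative has
#'   decayed to exp(-alpha^2/2) of its peak (~13.5% at the default 2).
#' @param min_phase_s Guard time: no switch earlier than this into a phase.
#' @param fit_min_points Minimum derivative samples before a fit is
#'   attempted.
#' @param peak_decline_samples Consecutive declining smoothed-derivative
#'   samples required past the maximum before the peak is considered passed
#'   (guards against noise-triggered early fits).
#' @param timeout_s Maximum phase duration before a control error is raised.
#' @return A list of class `control_params`.
#' @export
control_params <- function(smooth_window = 7L, alpha = 2, min_phase_s = 2,
                           fit_min_points = 10L, peak_decline_samples = 3L,
                           timeout_s = 60) {
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 3L || smooth_window %% 2L == 0L) {
    abort("`smooth_window` must be an odd integer >= 3.",
          class = "adaptivepcr_validation_error")
  }
  if (alpha < 0) abort("`alpha` must be >= 0.", class = "adaptivepcr_validation_error")
  if (min_phase_s < 0 || timeout_s <= 0) {
    abort("`min_phase_s` must be >= 0 and `timeout_s` > 0.",
          class = "adaptivepcr_validation_error")
  }
  structure(list(
    smooth_window = smooth_window, alpha = alpha, min_phase_s = min_phase_s,
    fit_min_points = as.integer(fit_min_points),
    peak_decline_samples = as.integer(peak_decline_samples),
    timeout_s = timeout_s
  ), class = "control_params")
}

#' Smoothed time-derivative of a fluorescence trace
#'
#' Applies a centered moving average of `window` samples, then central
#' finite differences on the smoothed values. Output timestamps are a
#' subset of the input timestamps (edges where the smoother or the
#' difference stencil is undefined are dropped).
#'
#' @param trace Data frame with columns `time_s` (strictly increasing) and
#'   `value`.
#' @param window Odd smoothing width in samples (>= 3).
#' @return A tibble with columns `time_s` and `deriv` (a.u./s).
#' @export
smoothed_derivative <- function(trace, window = 7L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    abort("`window` must be an odd integer >= 3.", class = "adaptivepcr_validation_error")
  }
  if (!is.data.frame(trace) || !all(c("time_s", "value") %in% names(trace))) {
    abort("`trace` must have `time_s` and `value` columns.",
          class = "adaptivepcr_validation_error")
  }
  n <- nrow(trace)
  if (n < window + 2L) {
    abort(sprintf("trace too short: %d samples, need at least %d.", n, window + 2L),
          class = "adaptivepcr_validation_error")
  }
  if (any(diff(trace$time_s) <= 0)) {
    abort("`time_s` must be strictly increasing.", class = "adaptivepcr_validation_error")
  }
  sm <- as.numeric(stats::filter(trace$value, rep(1 / window, window), sides = 2))
  keep <- which(!is.na(sm))
  idx <- keep[c(-1L, -length(keep))]
  deriv <- (sm[idx + 1L] - sm[idx - 1L]) / (trace$time_s[idx + 1L] - trace$time_s[idx - 1L])
  tibble(time_s = trace$time_s[idx], deriv = deriv)
}

#' Fit a Gaussian (with offset) to a derivative series
#'
#' Nonlinear least squares of `a * exp(-(t - mu)^2 / (2 sigma^2)) + c` to a
#' derivative series, by Levenberg-Marquardt. Initialization is empirical:
#' amplitude and mean from the extremum (relative to the early-sample
#' offset), sigma from the half-width at half-maximum. Fits whose sigma
#' collapses below a quarter of the sampling interval, or whose residual sum
#' of squares is no better than a constant model, are reported as failures
#' rather than switches.
#'
#' @param deriv Data frame with columns `time_s`, `deriv` (the output of
#'   [smoothed_derivative()]), at least 6 rows.
#' @param start Optional named list `(a, mu, sigma, c0)` of starting values
#'   (used for warm starts in streaming refits).
#' @return An object of class `gaussian_fit`: a list with `amplitude`,
#'   `mean`, `sigma` (> 0), `offset`, `rss`, `n` and `converged`. When
#'   `converged` is `FALSE` the parameter fields are `NA` and the caller is
#'   expected to retry on the next sample.
#' @export
fit_gaussian <- function(deriv, start = NULL) {
  if (!is.data.frame(deriv) || !all(c("time_s", "deriv") %in% names(deriv))) {
    abort("`deriv` must have `time_s` and `deriv` columns.",
          class = "adaptivepcr_validation_error")
  }
  if (nrow(deriv) < 6L) {
    abort("need at least 6 derivative samples to fit.", class = "adaptivepcr_validation_error")
  }
  fit_gaussian_core(deriv$time_s, deriv$deriv, start)
}

# Lean fitting core shared with the streaming monitor: Levenberg-Marquardt
# on plain vectors with an analytic Jacobian (the streaming controller
# refits on every sample, so the per-call overhead matters).
gauss_resid <- function(par, t, y) {
  par[1] * exp(-(t - par[2])^2 / (2 * par[3]^2)) + par[4] - y
}

gauss_jac <- function(par, t, y) {
  z <- (t - par[2]) / par[3]
  e <- exp(-z^2 / 2)
  cbind(e, par[1] * e * z / par[3], par[1] * e * z^2 / par[3], 1)
}

fit_gaussian_core <- function(t, y, start = NULL) {
  n <- length(y)
  failed <- structure(list(amplitude = NA_real_, mean = NA_real_,
                           sigma = NA_real_, offset = NA_real_,
                           rss = NA_real_, n = n, converged = FALSE),
                      class = "gaussian_fit")
  if (is.null(start)) {
    c0 <- mean(y[seq_len(min(5L, n))])
    ipk <- which.max(abs(y - c0))
    a0 <- y[ipk] - c0
    mu0 <- t[ipk]
    half <- abs(a0) / 2
    right <- which(abs(y - c0) < half & seq_len(n) > ipk)
    left <- which(abs(y - c0) < half & seq_len(n) < ipk)
    hw <- c(if (length(right)) t[min(right)] - mu0,
            if (length(left)) mu0 - t[max(left)])
    sigma0 <- if (length(hw)) mean(hw) / sqrt(2 * log(2)) else diff(range(t)) / 6
    if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- diff(range(t)) / 6
    start <- list(a = a0, mu = mu0, sigma = sigma0, c0 = c0)
  }
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = c(start$a, start$mu, start$sigma, start$c0),
      fn = gauss_resid, jac = gauss_jac, t = t, y = y,
      control = minpack.lm::nls.lm.control(maxiter = 60)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:3) return(failed)
  p <- fit$par
  rss <- sum(fit$fvec^2)
  dt_med <- stats::median(diff(t))
  ss_const <- sum((y - mean(y))^2)
  if (!all(is.finite(p)) || abs(p[3]) < dt_med / 4 || rss >= ss_const) {
    return(failed)
  }
  structure(list(
    amplitude = p[1], mean = p[2], sigma = abs(p[3]), offset = p[4],
    rss = rss, n = n, converged = TRUE
  ), class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<gaussian_fit> (fit failure)\n")
  } else {
    cat(sprintf(
      "<gaussian_fit> a = %.4g, mu = %.4g s, sigma = %.4g s, offset = %.4g (rss %.3g, n %d)\n",
      x$amplitude, x$mean, x$sigma, x$offset, x$rss, x$n))
  }
  invisible(x)
}

#' Predicted switch time from a fitted derivative peak
#'
#' The controller treats the derivative as having "approached zero" once it
#' has decayed to exp(-alpha^2/2) of its fitted peak, i.e. at
#' t* = mu + alpha * sigma.
#'
#' @param fit A converged [fit_gaussian()] result.
#' @param alpha Threshold in sigmas (>= 0).
#' @return The predicted switch time in seconds.
#' @export
predict_switch_time <- function(fit, alpha = 2) {
  stopifnot(inherits(fit, "gaussian_fit"))
  if (!isTRUE(fit$converged)) {
    abort("cannot predict a switch time from a failed fit.",
          class = "adaptivepcr_validation_error")
  }
  if (alpha < 0) abort("`alpha` must be >= 0.", class = "adaptivepcr_validation_error")
  fit$mean + alpha * fit$sigma
}

# ---------------------------------------------------------------------------
# Streaming phase monitor (internal).
#
# One monitor lives for the duration of one heating or cooling phase. It
# ingests one sample of the watched channel at a time, maintains the
# moving-average smoother and central-difference derivative incrementally,
# detects that the derivative peak has been passed (>= peak_decline_samples
# consecutive declines after the running maximum), then refits the Gaussian
# on every new sample and signals a switch once the current time reaches the
# predicted t*. `direction` is +1 for heating (rising signal, positive
# derivative peak) and -1 for cooling. All acceptance checks on the fit are
# relative (residual-based), so the decision is invariant to affine
# transforms of the raw signal.

monitor_new <- function(params, direction, phase_start, cap = 4096L) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$direction <- direction
  e$phase_start <- phase_start
  e$times <- numeric(cap)
  e$values <- numeric(cap)
  e$n <- 0L
  e$sm <- numeric(cap)        # smoothed values, index = center sample
  e$dt_times <- numeric(cap)  # derivative timestamps
  e$dv <- numeric(cap)        # signed derivative (direction applied)
  e$nd <- 0L
  e$max_d <- -Inf
  e$min_d <- Inf
  e$max_idx <- 0L
  e$decline_run <- 0L
  e$peak_detected <- FALSE
  e$fit_mode <- FALSE
  e$warm <- NULL
  e$fit <- NULL
  e$predicted_t <- NA_real_
  e$consec_accepts <- 0L
  e
}

monitor_grow <- function(e, need) {
  cap <- length(e$times)
  if (need <= cap) return(invisible(e))
  new_cap <- max(need, 2L * cap)
  for (f in c("times", "values", "sm", "dt_times", "dv")) {
    v <- e[[f]]
    length(v) <- new_cap
    e[[f]] <- v
  }
  invisible(e)
}

# Feed one sample; returns "continue", "switch" or "timeout".
monitor_add <- function(e, time_s, value) {
  p <- e$params
  w <- p$smooth_window
  h <- (w - 1L) %/% 2L
  n <- e$n + 1L
  monitor_grow(e, n)
  e$times[n] <- time_s
  e$values[n] <- value
  e$n <- n

  if (n >= w) {
    j <- n - h                       # center index of the newest full window
    e$sm[j] <- sum(e$values[(n - w + 1L):n]) / w
    if (j - 2L >= h + 1L) {          # central difference needs sm[j-2], sm[j]
      k <- e$nd + 1L
      e$dt_times[k] <- e$times[j - 1L]
      d <- (e$sm[j] - e$sm[j - 2L]) / (e$times[j] - e$times[j - 2L])
      e$dv[k] <- e$direction * d
      e$nd <- k
      if (k >= 2L) {
        e$decline_run <- if (e$dv[k] < e$dv[k - 1L]) e$decline_run + 1L else 0L
      }
      if (e$dv[k] > e$max_d) {
        e$max_d <- e$dv[k]
        e$max_idx <- k
        e$decline_run <- 0L
      }
      if (e$dv[k] < e$min_d) e$min_d <- e$dv[k]
      if (!e$peak_detected &&
          e$decline_run >= p$peak_decline_samples &&
          e$max_idx <= k - p$peak_decline_samples) {
        e$peak_detected <- TRUE
      }
      # Fitting starts once the passed peak is also prominent: the running
      # maximum must exceed the series median by 4 robust SDs. Plain
      # detector noise rarely reaches that, so the expensive refits engage
      # only when a real transition is underway. The test is relative
      # (median/MAD of the same series), preserving affine invariance.
      if (e$peak_detected && !e$fit_mode) {
        d <- e$dv[seq_len(k)]
        if (e$max_d > e$min_d &&
            e$max_d - stats::median(d) > 4 * stats::mad(d)) {
          e$fit_mode <- TRUE
        }
      }
      if (e$fit_mode && k >= p$fit_min_points) {
        tt <- e$dt_times[seq_len(k)]
        yy <- e$dv[seq_len(k)]
        fit <- fit_gaussian_core(tt, yy, start = e$warm)
        if (!fit$converged && !is.null(e$warm)) {
          fit <- fit_gaussian_core(tt, yy)  # cold restart if the warm start stalls
        }
        # Accept only physically plausible fits. All gates are relative to
        # the data (residual scale, observed derivative range, phase span,
        # sampling interval), so acceptance is invariant to affine
        # transforms of the raw signal: a positive peak well above the
        # residual noise, an amplitude commensurate with the observed
        # derivative excursion and a width resolved by several samples
        # (both reject degenerate narrow-spike fits on noise), a peak
        # located inside the phase and already passed, and a fit that
        # explains at least half the variance.
        dt_med <- stats::median(diff(e$dt_times[seq_len(k)]))
        ok <- fit$converged && fit$amplitude > 0 &&
          fit$amplitude >= 5 * sqrt(fit$rss / max(fit$n - 4L, 1L)) &&
          fit$amplitude <= 2 * (e$max_d - e$min_d) &&
          fit$sigma >= 4 * dt_med &&
          fit$rss <= 0.5 * sum((e$dv[seq_len(k)] - mean(e$dv[seq_len(k)]))^2) &&
          fit$mean >= e$phase_start && fit$mean <= time_s
        if (ok) {
          e$warm <- list(a = fit$amplitude, mu = fit$mean,
                         sigma = fit$sigma, c0 = fit$offset)
          # report the physical (unsigned-direction) amplitude
          fit$amplitude <- e$direction * fit$amplitude
          fit$offset <- e$direction * fit$offset
          e$fit <- fit
          e$predicted_t <- fit$mean + p$alpha * fit$sigma
          e$consec_accepts <- e$consec_accepts + 1L
        } else {
          # a stale prediction must not trigger a switch on its own
          e$predicted_t <- NA_real_
          e$consec_accepts <- 0L
        }
      }
    }
  }

  # Switch only on a streak of concordant accepted refits: single spurious
  # fits on detector noise are unstable from sample to sample, while the
  # refits that track a real transition are accepted continuously.
  if (!is.na(e$predicted_t) && e$consec_accepts >= 3L &&
      time_s >= e$predicted_t &&
      time_s - e$phase_start >= p$min_phase_s) {
    return("switch")
  }
  if (time_s - e$phase_start > p$timeout_s) return("timeout")
  "continue"
}

control_error <- function(phase, cycle, time_s) {
  abort(
    sprintf("control error: no valid switch in the %s phase of cycle %d within the timeout (t = %.2f s).",
            phase, cycle, time_s),
    class = "adaptivepcr_control_error",
    phase = phase, cycle = cycle, time_s = time_s
  )
}

#' Replay a recorded multi-channel trace through the cycling controller
#'
#' Runs the heat/cool state machine offline over a recorded (or simulated)
#' trace. During heating the melt-sensor (`yellow`) channel is watched;
#' during cooling the anneal-sensor (`orange`) channel. At each
#' cooling-to-heating switch a PCR reading is taken from the `green`
#' channel (if present) and a cycle record is emitted.
#'
#' @param trace Long-format data frame with columns `time_s`, `channel`,
#'   `value`; channels `yellow` and `orange` are required and must share
#'   timestamps, `green` is optional.
#' @param params A [control_params()] object.
#' @param n_cycles Stop after this many completed cycles (default: run to
#'   the end of the trace).
#' @param initial_phase Phase at the first sample, `"heating"` or
#'   `"cooling"`.
#' @return An object of class `control_result`: a list with tibbles
#'   `switch_points` (`cycle`, `kind`, `time_s`, `fluorescence_at_switch`)
#'   and `cycles` (`cycle`, `heat_duration_s`, `cool_duration_s`,
#'   `pcr_reading`, `pcr_timestamp_s`), plus `completed_cycles` and the
#'   parameters used.
#' @export
control_loop <- function(trace, params = control_params(), n_cycles = Inf,
                         initial_phase = c("heating", "cooling")) {
  initial_phase <- match.arg(initial_phase)
  wide <- trace_to_wide(trace)
  for (ch in c("yellow", "orange")) {
    if (!ch %in% names(wide)) {
      abort(sprintf("trace must contain the '%s' channel.", ch),
            class = "adaptivepcr_validation_error")
    }
  }
  has_green <- "green" %in% names(wide)
  nr <- nrow(wide)

  sp_cycle <- integer(0); sp_kind <- character(0)
  sp_time <- numeric(0); sp_fluo <- numeric(0)
  cyc_id <- integer(0); cyc_heat <- numeric(0); cyc_cool <- numeric(0)
  cyc_read <- numeric(0); cyc_ts <- numeric(0)

  phase <- initial_phase
  cycle <- 1L
  phase_start <- wide$time_s[1]
  heat_start <- if (phase == "heating") phase_start else NA_real_
  melt_time <- NA_real_
  mon <- monitor_new(params,
                     direction = if (phase == "heating") 1 else -1,
                     phase_start = phase_start)

  for (i in seq_len(nr)) {
    tm <- wide$time_s[i]
    val <- if (phase == "heating") wide$yellow[i] else wide$orange[i]
    decision <- monitor_add(mon, tm, val)
    if (decision == "timeout") control_error(phase, cycle, tm)
    if (decision == "switch") {
      if (phase == "heating") {
        sp_cycle <- c(sp_cycle, cycle); sp_kind <- c(sp_kind, "melt_switch")
        sp_time <- c(sp_time, tm); sp_fluo <- c(sp_fluo, wide$yellow[i])
        melt_time <- tm
        phase <- "cooling"
        mon <- monitor_new(params, direction = -1, phase_start = tm)
      } else {
        sp_cycle <- c(sp_cycle, cycle); sp_kind <- c(sp_kind, "anneal_switch")
        sp_time <- c(sp_time, tm); sp_fluo <- c(sp_fluo, wide$orange[i])
        cyc_id <- c(cyc_id, cycle)
        cyc_heat <- c(cyc_heat, melt_time - heat_start)
        cyc_cool <- c(cyc_cool, tm - melt_time)
        cyc_read <- c(cyc_read, if (has_green) wide$green[i] else NA_real_)
        cyc_ts <- c(cyc_ts, tm)
        cycle <- cycle + 1L
        if (cycle > n_cycles) break
        heat_start <- tm
        phase <- "heating"
        mon <- monitor_new(params, direction = 1, phase_start = tm)
      }
    }
  }

  structure(list(
    switch_points = tibble(cycle = sp_cycle, kind = sp_kind, time_s = sp_time,
                           fluorescence_at_switch = sp_fluo),
    cycles = tibble(cycle = cyc_id, heat_duration_s = cyc_heat,
                    cool_duration_s = cyc_cool, pcr_reading = cyc_read,
                    pcr_timestamp_s = cyc_ts),
    completed_cycles = length(cyc_id),
    params = params
  ), class = "control_result")
}

trace_to_wide <- function(trace) {
  if (!is.data.frame(trace) ||
      !all(c("time_s", "channel", "value") %in% names(trace))) {
    abort("`trace` must have columns time_s, channel, value.",
          class = "adaptivepcr_validation_error")
  }
  wide <- tidyr::pivot_wider(trace, id_cols = "time_s",
                             names_from = "channel", values_from = "value")
  wide <- dplyr::arrange(wide, .data$time_s)
  watched <- intersect(c("yellow", "orange"), names(wide))
  if (length(watched) && anyNA(wide[watched])) {
    abort("sensor channels must share timestamps (misaligned samples found).",
          class = "adaptivepcr_validation_error")
  }
  wide
}

#' Switch-point stability statistics
#'
#' Summarizes how reproducible the controller's switch points are over a
#' window of cycles (by default 2 through 16: the first cycle is excluded
#' because it starts from an arbitrary environmental temperature, and later
#' cycles are excluded because rising hydrolysis-probe fluorescence would
#' contaminate the sensor channels on a shared detector). For each switch
#' kind the fluorescence values at the switch points are averaged and
#' per-cycle deviations from that mean reported; heating and cooling
#' durations are summarized the same way.
#'
#' @param run A `pcr_run` (from [simulate_run()]) or `control_result` (from
#'   [control_loop()]) with at least `last_cycle` completed cycles.
#' @param first_cycle,last_cycle Inclusive cycle window.
#' @return An object of class `switch_stats`: list with tibbles
#'   `fluorescence` (per-kind mean and SD of switch fluorescence),
#'   `deviations` (per cycle and kind, deviation from the mean), and
#'   `durations` (mean and SD of heating and cooling durations).
#' @export
switch_stats <- function(run, first_cycle = 2L, last_cycle = 16L) {
  if (!inherits(run, c("pcr_run", "control_result"))) {
    abort("`run` must be a pcr_run or control_result.",
          class = "adaptivepcr_validation_error")
  }
  if (run$completed_cycles < last_cycle) {
    abort(sprintf("run has %d cycles; window [%d, %d] needs at least %d.",
                  run$completed_cycles, first_cycle, last_cycle, last_cycle),
          class = "adaptivepcr_validation_error")
  }
  sp <- dplyr::filter(run$switch_points,
                      .data$cycle >= first_cycle, .data$cycle <= last_cycle)
  fluo <- dplyr::summarise(
    dplyr::group_by(sp, .data$kind),
    mean_fluorescence = mean(.data$fluorescence_at_switch),
    sd_fluorescence = sd(.data$fluorescence_at_switch),
    n = dplyr::n(), .groups = "drop"
  )
  dev <- dplyr::mutate(
    dplyr::group_by(sp, .data$kind),
    deviation = .data$fluorescence_at_switch - mean(.data$fluorescence_at_switch)
  )
  dev <- dplyr::select(dplyr::ungroup(dev), "cycle", "kind", "deviation")
  cyc <- dplyr::filter(run$cycles,
                       .data$cycle >= first_cycle, .data$cycle <= last_cycle)
  durations <- tibble(
    phase = c("heating", "cooling"),
    mean_s = c(mean(cyc$heat_duration_s), mean(cyc$cool_duration_s)),
    sd_s = c(sd(cyc$heat_duration_s), sd(cyc$cool_duration_s)),
    n = nrow(cyc)
  )
  structure(list(fluorescence = fluo, deviations = dev, durations = durations,
                 window = c(first_cycle, last_cycle)),
            class = "switch_stats")
}

#' @export
print.switch_stats <- function(x, ...) {
  cat(sprintf("<switch_stats> cycles %d-%d\n", x$window[1], x$window[2]))
  print(x$fluorescence)
  print(x$durations)
  invisible(x)
}
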