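# Synthetic trace builders and a small cache for closed-loop runs shared
# across test files (the 40-cycle simulations are the expensive fixtures).

# A melt-style transition whose time-derivative is exactly Gaussian:
# value = baseline + span * pnorm((t - center)/sigma).
erf_transition <- function(t, center, sigma, baseline = 10, span = 100,
                           rising = TRUE) {
  s <- span * stats::pnorm((t - center) / sigma)
  if (rising) baseline + s else baseline + span - s
}

# A logistic transition: value = baseline + span / (1 + exp(-(t-center)/s)).
logistic_transition <- function(t, center, scale, baseline = 10, span = 100,
                                rising = TRUE) {
  s <- span / (1 + exp(-(t - center) / scale))
  if (rising) baseline + s else baseline + span - s
}

# Multi-cycle periodic replay trace with exactly-Gaussian derivatives.
# Within each period of length `period`: the orange (anneal) channel rises
# at +4 s (early heating), yellow (melt) rises at +8 s, yellow falls back at
# +18 s (early cooling, unobserved), orange falls at +22 s. Margins are
# several sigma wide so each watched transition is isolated in its phase.
make_cycle_trace <- function(n_cycles = 2, period = 30, hz = 30, sigma = 1.2,
                             shape = c("erf", "logistic"),
                             baseline = 10, span = 100, noise_sd = 0,
                             gain = 1, offset = 0) {
  shape <- match.arg(shape)
  trans <- if (shape == "erf") erf_transition else logistic_transition
  t <- seq(1 / hz, n_cycles * period, by = 1 / hz)
  ph <- t %% period
  cyc <- floor(t / period)
  yellow <- orange <- numeric(length(t))
  # build per-period, piecing rising/falling halves together
  yellow <- ifelse(ph < 13,
                   trans(ph, 8, sigma, baseline, span, rising = TRUE),
                   trans(ph, 18, sigma, baseline, span, rising = FALSE))
  orange <- ifelse(ph < 13,
                   trans(ph, 4, sigma, baseline, span, rising = TRUE),
                   trans(ph, 22, sigma, baseline, span, rising = FALSE))
  green <- rep(baseline, length(t))
  if (noise_sd > 0) {
    yellow <- yellow + rnorm(length(t), 0, noise_sd)
    orange <- orange + rnorm(length(t), 0, noise_sd)
    green <- green + rnorm(length(t), 0, noise_sd)
  }
  out <- tibble::tibble(
    time_s = rep(t, 3),
    channel = rep(c("yellow", "orange", "green"), each = length(t)),
    value = c(yellow, orange, green) * gain + offset
  )
  attr(out, "truth") <- list(period = period, sigma = sigma, hz = hz,
                             yellow_rise = 8, orange_fall = 22)
  out
}

# Brute-force switch-time oracle: smoothed empirical derivative, restricted
# to [from, to); peak = extremum in the watched direction; switch when the
# derivative first decays below exp(-alpha^2/2) of the peak (relative to the
# pre-peak offset level), scanning forward from the peak.
oracle_switch_time <- function(trace_one_channel, from, to, direction,
                               window = 7, alpha = 2) {
  d <- smoothed_derivative(trace_one_channel, window = window)
  d <- d[d$time_s >= from & d$time_s < to, ]
  dv <- direction * d$deriv
  ipk <- which.max(dv)
  off <- stats::median(dv[seq_len(max(1, ipk - 3 * window))])
  thr <- off + (dv[ipk] - off) * exp(-alpha^2 / 2)
  after <- which(seq_along(dv) > ipk & dv <= thr)
  if (!length(after)) return(NA_real_)
  d$time_s[after[1]]
}

# Cache for expensive closed-loop runs reused across test files. testthat
# sources helpers into one session per run, so this memoizes within a run.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fun) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- fun()
  .run_cache[[key]]
}

noiseless_40cycle_run <- function() {
  cached_run("noiseless40", function() {
    simulate_run(sim_config(n_cycles = 40L, seed = 101L, noise_sd = 0))
  })
}

ntc_40cycle_run <- function() {
  cached_run("ntc40", function() {
    simulate_run(sim_config(
      n_cycles = 40L, seed = 202L,
      chemistry = chemistry_params(initial_copies = 0)
    ))
  })
}
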