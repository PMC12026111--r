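test_that("smoothed derivative recovers slopes of simple signals", {
  t <- seq(0, 10, by = 1 / 30)
  ramp <- tibble::tibble(time_s = t, value = 3 * t)
  d <- smoothed_derivative(ramp, window = 7)
  expect_true(all(abs(d$deriv - 3) < 1e-9))
  flat <- tibble::tibble(time_s = t, value = rep(2, length(t)))
  expect_true(all(abs(smoothed_derivative(flat)$deriv) < 1e-12))
  # edges are truncated, timestamps are a subset of the input's
  expect_lt(nrow(d), length(t))
  expect_true(all(d$time_s %in% t))
  expect_error(smoothed_derivative(ramp[1:5, ], window = 7),
               class = "adaptivepcr_validation_error")
  expect_error(smoothed_derivative(ramp, window = 4),
               class = "adaptivepcr_validation_error")
})

test_that("smoothed derivative peaks at the melt-curve midpoint", {
  t <- seq(0, 30, by = 1 / 30)
  trc <- tibble::tibble(time_s = t,
                        value = logistic_transition(t, 15, 1.2))
  d <- smoothed_derivative(trc, window = 7)
  expect_lt(abs(d$time_s[which.max(d$deriv)] - 15), 1 / 30 + 1e-9)
})

test_that("the Gaussian fit recovers exact parameters to high precision", {
  t <- seq(0, 20, by = 0.05)
  gauss <- function(t, a, mu, sigma, c0) a * exp(-(t - mu)^2 / (2 * sigma^2)) + c0
  for (c0 in c(0, 1.0)) {
    f <- fit_gaussian(tibble::tibble(time_s = t,
                                     deriv = gauss(t, 5, 10, 2, c0)))
    expect_true(f$converged)
    expect_equal(f$amplitude, 5, tolerance = 1e-6)
    expect_equal(f$mean, 10, tolerance = 1e-6)
    expect_equal(f$sigma, 2, tolerance = 1e-6)
    expect_equal(f$offset, c0, tolerance = 1e-6)
    expect_lt(f$rss, 1e-10)
  }
  # negative-amplitude (cooling-side) peaks are fitted too
  f <- fit_gaussian(tibble::tibble(time_s = t, deriv = gauss(t, -4, 8, 1.5, 0)))
  expect_true(f$converged)
  expect_equal(f$amplitude, -4, tolerance = 1e-6)
})

test_that("the Gaussian fit tolerates noise and flags degenerate inputs", {
  t <- seq(0, 20, by = 1 / 30)
  set.seed(5)
  y <- 5 * exp(-(t - 10)^2 / 8) + rnorm(length(t), 0, 0.1)
  f <- fit_gaussian(tibble::tibble(time_s = t, deriv = y))
  expect_true(f$converged)
  expect_lt(abs(f$mean - 10) / 10, 0.05)
  expect_lt(abs(f$sigma - 2) / 2, 0.05)
  # pure constant data: no peak to fit
  flat <- tibble::tibble(time_s = t, deriv = rep(1, length(t)))
  expect_false(fit_gaussian(flat)$converged)
  expect_error(fit_gaussian(flat[1:4, ]), class = "adaptivepcr_validation_error")
})

test_that("switch-time prediction is mu + alpha * sigma", {
  f <- structure(list(amplitude = 5, mean = 10, sigma = 2, offset = 0,
                      rss = 0, n = 100, converged = TRUE),
                 class = "gaussian_fit")
  expect_equal(predict_switch_time(f, alpha = 2), 14)
  expect_equal(predict_switch_time(f, alpha = 0), 10)
  expect_gt(predict_switch_time(f, alpha = 3), predict_switch_time(f, alpha = 2))
  bad <- structure(list(converged = FALSE), class = "gaussian_fit")
  expect_error(predict_switch_time(bad), class = "adaptivepcr_validation_error")
})

test_that("the state machine alternates switch kinds, one cycle per anneal switch", {
  trc <- make_cycle_trace(n_cycles = 3)
  res <- control_loop(trc, n_cycles = 3)
  expect_equal(res$completed_cycles, 3L)
  expect_equal(nrow(res$switch_points), 6L)
  expect_equal(res$switch_points$kind,
               rep(c("melt_switch", "anneal_switch"), 3))
  expect_true(all(diff(res$switch_points$time_s) > 0))
  expect_true(all(res$cycles$heat_duration_s > 0))
  expect_true(all(res$cycles$cool_duration_s > 0))
  expect_equal(res$completed_cycles,
               sum(res$switch_points$kind == "anneal_switch"))
})

test_that("switch times match the brute-force derivative-threshold oracle", {
  # transitions with exactly Gaussian derivatives; one sampling interval
  # of tolerance (the controller acts on sample ticks)
  hz <- 30
  trc <- make_cycle_trace(n_cycles = 2, shape = "erf", hz = hz)
  res <- control_loop(trc, n_cycles = 2)
  yellow <- trc[trc$channel == "yellow", c("time_s", "value")]
  orange <- trc[trc$channel == "orange", c("time_s", "value")]
  sp <- res$switch_points
  for (cyc in 1:2) {
    p0 <- (cyc - 1) * 30
    melt <- sp$time_s[sp$kind == "melt_switch" & sp$cycle == cyc]
    oracle_m <- oracle_switch_time(yellow, from = p0, to = p0 + 14,
                                   direction = 1)
    expect_lt(abs(melt - oracle_m), 1 / hz + 1e-9)
    anneal <- sp$time_s[sp$kind == "anneal_switch" & sp$cycle == cyc]
    oracle_a <- oracle_switch_time(orange, from = p0 + 14, to = p0 + 30,
                                   direction = -1)
    expect_lt(abs(anneal - oracle_a), 1 / hz + 1e-9)
  }
})

test_that("on logistic transitions the switch lands after the midpoint, within 4 sigma", {
  trc <- make_cycle_trace(n_cycles = 2, shape = "logistic", sigma = 1.2)
  res <- control_loop(trc, n_cycles = 2)
  sp <- res$switch_points
  for (cyc in 1:2) {
    p0 <- (cyc - 1) * 30
    melt <- sp$time_s[sp$kind == "melt_switch" & sp$cycle == cyc]
    # never before the transition midpoint; not unreasonably far past it
    expect_gte(melt, p0 + 8)
    expect_lte(melt, p0 + 8 + 4 * 1.2 * 2)   # logistic scale ~ 2x Gaussian sigma
  }
})

test_that("switch decisions are invariant to gain and offset of the raw signal", {
  trc <- make_cycle_trace(n_cycles = 2, shape = "erf")
  base <- control_loop(trc, n_cycles = 2)
  scaled <- make_cycle_trace(n_cycles = 2, shape = "erf",
                             gain = 0.5, offset = 37)
  res <- control_loop(scaled, n_cycles = 2)
  expect_true(all(abs(base$switch_points$time_s -
                        res$switch_points$time_s) < 1 / 30 + 1e-9))
})

test_that("replaying the same trace is deterministic", {
  set.seed(99)
  trc <- make_cycle_trace(n_cycles = 2, shape = "erf", noise_sd = 0.5)
  r1 <- control_loop(trc, n_cycles = 2)
  r2 <- control_loop(trc, n_cycles = 2)
  expect_identical(r1$switch_points, r2$switch_points)
  expect_identical(r1$cycles, r2$cycles)
})

test_that("control_loop validates channels and enforces the timeout", {
  trc <- make_cycle_trace(n_cycles = 1)
  expect_error(control_loop(trc[trc$channel != "orange", ]),
               "orange", class = "adaptivepcr_validation_error")
  # a flat trace never produces a switch: timeout -> control error
  t <- seq(1 / 30, 70, by = 1 / 30)
  flat <- tibble::tibble(
    time_s = rep(t, 2),
    channel = rep(c("yellow", "orange"), each = length(t)),
    value = 50
  )
  expect_error(control_loop(flat), class = "adaptivepcr_control_error")
})

test_that("switch statistics summarize deviations and duration spread", {
  fake <- structure(list(
    switch_points = tibble::tibble(
      cycle = rep(1:20, each = 2),
      kind = rep(c("melt_switch", "anneal_switch"), 20),
      time_s = seq_len(40),
      fluorescence_at_switch = rep(c(100, 15), 20)
    ),
    cycles = tibble::tibble(
      cycle = 1:20,
      heat_duration_s = rep(10, 20),
      cool_duration_s = rep(9, 20),
      pcr_reading = rnorm(20), pcr_timestamp_s = cumsum(rep(19, 20))
    ),
    completed_cycles = 20L
  ), class = "control_result")
  s <- switch_stats(fake)
  expect_equal(nrow(s$deviations), 30L)    # 15 cycles x 2 kinds
  expect_true(all(s$deviations$deviation == 0))
  expect_equal(s$durations$sd_s, c(0, 0))
  expect_equal(s$fluorescence$n, c(15L, 15L))

  fake2 <- fake
  fake2$cycles$heat_duration_s <- rep(c(20, 22, 24), length.out = 20)
  idx <- fake2$cycles$cycle >= 2 & fake2$cycles$cycle <= 16
  s2 <- switch_stats(fake2)
  expect_equal(s2$durations$sd_s[1], sd(fake2$cycles$heat_duration_s[idx]))

  fake$completed_cycles <- 10L
  expect_error(switch_stats(fake), class = "adaptivepcr_validation_error")
})
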