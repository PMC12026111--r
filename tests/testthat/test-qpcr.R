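make_curve <- function(f, timestamps = FALSE) {
  out <- tibble::tibble(cycle = seq_along(f), fluorescence = f)
  if (timestamps) out$timestamp_s <- 20 + 21.76 * seq_along(f)
  out
}

# a clean curve: flat baseline of 15 cycles at `base`, doubling thereafter,
# capped at `plateau`
doubling_curve <- function(base = 10, a = 0.01, n = 40, plateau = 100) {
  f <- base + pmin(c(rep(0, 15), a * 2^(1:(n - 15))), plateau)
  make_curve(f)
}

test_that("normalization maps curves to the 0-100 scale with baseline stats", {
  crv <- make_curve(c(rep(10, 15), 20, 40, 80, 110, 110))
  norm <- normalize_curve(crv)
  expect_equal(max(norm$value), 100)
  expect_equal(attr(norm, "baseline_mean"), 10)
  expect_equal(attr(norm, "max_raw"), 100)
  expect_equal(norm$value[19], 100)
  expect_false(attr(norm, "flat"))
  # shift invariance: adding a constant changes nothing after normalization
  shifted <- normalize_curve(make_curve(crv$fluorescence + 55.5))
  expect_equal(norm$value, shifted$value, tolerance = 1e-12)
  expect_error(normalize_curve(crv[1:12, ]), class = "adaptivepcr_validation_error")
  expect_error(normalize_curve(make_curve(1:10)[c(2, 1, 3:10), ]),
               class = "adaptivepcr_validation_error")
})

test_that("normalization is idempotent and flags flat curves", {
  set.seed(21)
  crv <- doubling_curve()
  crv$fluorescence <- crv$fluorescence + rnorm(40, 0, 0.2)
  n1 <- normalize_curve(crv)
  n2 <- normalize_curve(make_curve(n1$value))
  expect_equal(n1$value, n2$value, tolerance = 1e-6)
  flat <- normalize_curve(make_curve(rep(7, 20)))
  expect_true(attr(flat, "flat"))
  # the zero baseline SD is floored, with notice, and the call is negative
  expect_warning(cq_flat <- call_cq(flat), "floor")
  expect_false(cq_flat$positive)
})

test_that("Cq calling crosses at k standard deviations above baseline", {
  set.seed(31)
  crv <- doubling_curve(base = 10, a = 0.02)
  crv$fluorescence <- crv$fluorescence + rnorm(40, 0, 0.3)
  norm <- normalize_curve(crv)
  cq <- call_cq(norm)
  expect_true(cq$positive)
  expect_gt(cq$cq, 15)
  expect_equal(cq$threshold, 10 * attr(norm, "baseline_sd"))
  # a flat noisy NTC stays negative
  ntc <- make_curve(10 + rnorm(40, 0, 0.3))
  expect_false(call_cq(normalize_curve(ntc))$positive)
})

test_that("an exact threshold hit gives an integer Cq; crossings interpolate", {
  # noiseless baseline: SD floored, threshold = 10 * floor
  crv <- doubling_curve(base = 0, a = 1)   # values 2,4,8,... from cycle 16
  norm <- normalize_curve(crv)
  expect_warning(cq <- call_cq(norm, sd_floor = 3.2), "floor")
  expect_equal(cq$cq, 20)                  # value at cycle 20 is exactly 32
  suppressWarnings({
    cq2 <- call_cq(norm, sd_floor = 4.4)   # threshold 44, between 32 and 64
  })
  expect_gt(cq2$cq, 20)
  expect_lt(cq2$cq, 21)
})

test_that("spline Cq stays within a quarter cycle of the linear oracle", {
  set.seed(47)
  worst <- 0
  for (i in 1:100) {
    base <- runif(1, 5, 50)
    rate <- runif(1, 1.4, 2)
    a <- 10^runif(1, -3, -1.5)
    noise <- runif(1, 0.05, 0.5)
    f <- base + pmin(c(rep(0, 15), a * rate^(1:25)), 100) +
      rnorm(40, 0, noise)
    norm <- normalize_curve(make_curve(f))
    cq <- suppressWarnings(call_cq(norm))
    if (!cq$positive) next
    # linear-interpolation oracle on the baseline-subtracted scale
    sub <- norm$value * attr(norm, "max_raw") / 100
    i1 <- which(sub >= cq$threshold)[1]
    if (i1 == 1) next
    oracle <- (i1 - 1) +
      (cq$threshold - sub[i1 - 1]) / (sub[i1] - sub[i1 - 1])
    worst <- max(worst, abs(cq$cq - oracle))
  }
  expect_lt(worst, 0.25)
})

test_that("Cq calls are invariant to affine transforms of the raw curve", {
  set.seed(13)
  f <- 10 + pmin(c(rep(0, 15), 0.02 * 2^(1:25)), 100) + rnorm(40, 0, 0.3)
  cq1 <- call_cq(normalize_curve(make_curve(f)))
  cq2 <- call_cq(normalize_curve(make_curve(3.7 * f + 120)))
  expect_equal(cq1$cq, cq2$cq, tolerance = 1e-9)
})

test_that("quantification time interpolates run timestamps at the fractional Cq", {
  f <- 10 + pmin(c(rep(0, 15), 0.02 * 2^(1:25)), 100)
  crv <- make_curve(f, timestamps = TRUE)
  crv$fluorescence <- crv$fluorescence + c(rep(c(-0.1, 0.1), 7), -0.1,
                                           rep(0, 25))
  norm <- normalize_curve(crv)
  cq <- call_cq(norm)
  expect_true(cq$positive)
  expect_equal(cq$quantification_time_s, 20 + 21.76 * cq$cq, tolerance = 1e-9)
})

test_that("window-of-linearity efficiency is exact on geometric curves", {
  for (r in seq(1.1, 2.0, by = 0.1)) {
    f <- c(rep(0, 15), r^(1:25))          # zero baseline, pure geometric
    norm <- normalize_curve(make_curve(f))
    # centre the window safely inside the exponential phase
    eff <- single_sample_efficiency(norm, cq = 20)
    expect_equal(eff$efficiency, r, tolerance = 1e-9)
    expect_equal(eff$r_squared, 1, tolerance = 1e-9)
  }
  # constant positive signal in the window: efficiency 1
  fconst <- c(rep(0, 15), rep(50, 25))
  effc <- single_sample_efficiency(normalize_curve(make_curve(fconst)), cq = 25)
  expect_equal(effc$efficiency, 1, tolerance = 1e-12)
})

test_that("the efficiency window recenters on round(cq) and shifts off zeros", {
  f <- c(rep(0, 15), 2^(1:25))
  norm <- normalize_curve(make_curve(f))
  eff <- single_sample_efficiency(norm, cq = 20.4)
  expect_equal(c(eff$window_start, eff$window_end), c(18L, 22L))
  # centred at 16 the window would hit zeros at cycles 14-15: shift upward
  expect_warning(eff2 <- single_sample_efficiency(norm, cq = 16), "shifted")
  expect_equal(eff2$window_start, 16L)
  expect_true(eff2$shifted)
  expect_equal(eff2$efficiency, 2, tolerance = 1e-9)
  expect_error(single_sample_efficiency(norm, cq = NA_real_),
               class = "adaptivepcr_validation_error")
})

test_that("standard curves recover efficiency from the Cq-vs-log10 slope", {
  # Cq generated with the ideal doubling slope -log2(10)
  conc <- rep(10^(1:5), each = 3)
  cqs <- 40 - log(10) / log(2) * log10(conc)
  sc <- standard_curve(tibble::tibble(concentration = conc, cq = cqs))
  expect_equal(sc$efficiency, 2, tolerance = 1e-9)
  expect_equal(sc$r_squared, 1, tolerance = 1e-12)
  expect_equal(sc$slope, -log(10) / log(2), tolerance = 1e-9)
  g <- glance(sc)
  expect_equal(g$efficiency, sc$efficiency)
  expect_equal(tidy(sc)$estimate[2], sc$slope)
  # negatives are excluded and counted
  with_neg <- tibble::tibble(concentration = c(conc, 1, 1),
                             cq = c(cqs, NA, NA),
                             positive = c(rep(TRUE, 15), FALSE, FALSE))
  sc2 <- standard_curve(with_neg)
  expect_equal(sc2$n_excluded, 2L)
  expect_error(standard_curve(tibble::tibble(concentration = c(1, 10),
                                             cq = c(30, 27))),
               class = "adaptivepcr_validation_error")
})

test_that("standard-curve and single-sample estimates agree on clean data", {
  series <- simulate_dilution_series(seed = 5, noise_sd = 0.05, n_ntc = 0)
  res <- dplyr::bind_cols(
    series[c("concentration", "role")],
    purrr::map_dfr(series$curve, function(crv) {
      suppressWarnings(analyze_curve(crv))
    })
  )
  sc <- standard_curve(res)
  single <- mean(res$efficiency[res$concentration >= 100], na.rm = TRUE)
  expect_lt(abs(sc$efficiency - single) / sc$efficiency, 0.1)
})

test_that("average cycle time uses the inclusive window and ignores cycle 1", {
  cyc <- tibble::tibble(cycle = 1:12,
                        heat_duration_s = c(40, rep(12, 11)),
                        cool_duration_s = c(30, rep(10.5, 11)))
  act <- average_cycle_time(cyc)
  expect_equal(act$mean_s, 22.5)
  expect_equal(act$sd_s, 0)
  expect_equal(act$n, 10L)
  # changing cycle 1 has no effect
  cyc2 <- cyc
  cyc2$heat_duration_s[1] <- 500
  expect_equal(average_cycle_time(cyc2)$mean_s, 22.5)
  # hand-computed mean of 20..29
  cyc3 <- tibble::tibble(cycle = 1:11, duration_s = c(99, 20:29))
  expect_equal(average_cycle_time(cyc3)$mean_s, 24.5)
  expect_error(average_cycle_time(cyc[1:5, ]),
               class = "adaptivepcr_validation_error")
})

test_that("limit of detection is the lowest all-positive concentration", {
  res <- tibble::tibble(
    concentration = rep(c(10, 1, 0.1), each = 4),
    positive = c(rep(TRUE, 8), rep(FALSE, 4))
  )
  expect_equal(lod_call(res)$lod, 1)
  # one miss disqualifies the level
  res$positive[6] <- FALSE
  expect_equal(lod_call(res)$lod, 10)
  # nothing qualifies
  res$positive <- FALSE
  expect_true(is.na(lod_call(res)$lod))
})
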