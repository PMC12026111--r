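# broom-style tidiers for the fitted objects.

#' Tidy a Gaussian derivative fit
#'
#' @param x A [fit_gaussian()] result.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble(term = c("amplitude", "mean", "sigma", "offset"),
         estimate = c(x$amplitude, x$mean, x$sigma, x$offset))
}

#' @rdname tidy.gaussian_fit
#' @return `glance()` returns a one-row tibble (`rss`, `n`, `converged`).
#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, converged = x$converged)
}

#' Tidy a standard curve
#'
#' @param x A [standard_curve()] object.
#' @param ... Unused.
#' @return `tidy()` returns the regression coefficient table; `glance()` a
#'   one-row model summary with the derived efficiency.
#' @export
tidy.standard_curve <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = rownames(s), estimate = unname(s[, 1]),
         std_error = unname(s[, 2]), statistic = unname(s[, 3]),
         p_value = unname(s[, 4]))
}

#' @rdname tidy.standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         efficiency = x$efficiency, n_used = x$n_used,
         n_excluded = x$n_excluded)
}

#' Tidy switch-point stability statistics
#'
#' @param x A [switch_stats()] object.
#' @param ... Unused.
#' @return `tidy()` returns the per-cycle deviations; `glance()` the
#'   per-kind and per-phase summary in one row.
#' @export
tidy.switch_stats <- function(x, ...) {
  x$deviations
}

#' @rdname tidy.switch_stats
#' @export
glance.switch_stats <- function(x, ...) {
  f <- x$fluorescence
  d <- x$durations
  tibble(
    melt_mean_fluorescence = f$mean_fluorescence[f$kind == "melt_switch"],
    anneal_mean_fluorescence = f$mean_fluorescence[f$kind == "anneal_switch"],
    heat_sd_s = d$sd_s[d$phase == "heating"],
    cool_sd_s = d$sd_s[d$phase == "cooling"],
    first_cycle = x$window[1], last_cycle = x$window[2]
  )
}
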