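# Beer-Lambert transmission arithmetic for laser heating and the nanorod
# fluorescence-blocking metric.
#
# In the plasmonic (808 nm) heating mode, gold nanorods absorb the laser
# power; the same nanorods also attenuate the excitation/emission light of
# the fluorescence channels. Transmission through the reaction follows
# Beer's law, T = 10^(-eps*c*L) with decadic attenuation eps (the field
# reasons in absorbance units, hence the base-10 convention; converters to
# the natural-log convention are provided).

#' Beer-Lambert transmittance through an absorbing path
#'
#' @param decadic_attenuation Decadic attenuation coefficient, per
#'   (concentration unit x mm); must be >= 0.
#' @param concentration Absorber concentration (same unit as the attenuation
#'   coefficient assumes, e.g. nM); must be >= 0.
#' @param path_mm Optical path length in mm; must be > 0.
#' @return A tibble with columns `absorbance` (A = eps*c*L) and
#'   `transmittance` (T = 10^-A). Vectorized over all arguments.
#' @examples
#' transmittance(0.05, 10, 2)  # A = 1, T = 0.1
#' @export
transmittance <- function(decadic_attenuation, concentration, path_mm) {
  if (any(decadic_attenuation < 0, na.rm = TRUE) ||
      any(concentration < 0, na.rm = TRUE)) {
    abort("attenuation and concentration must be >= 0.",
          class = "adaptivepcr_domain_error")
  }
  if (any(path_mm <= 0, na.rm = TRUE)) {
    abort("`path_mm` must be > 0.", class = "adaptivepcr_domain_error")
  }
  a <- decadic_attenuation * concentration * path_mm
  tibble(absorbance = a, transmittance = 10^(-a))
}

#' Rescale a transmittance to a new absorber concentration
#'
#' Given a measured or calibrated transmittance `t_ref` at concentration
#' `c_ref` over a fixed path, Beer's law gives the transmittance at any
#' other concentration of the same absorber over the same path as
#' \deqn{T_{new} = T_{ref}^{\,c_{new}/c_{ref}}}
#' This is how a single calibrated transmission anchors predictions across
#' a nanorod dilution series without knowing the attenuation coefficient or
#' path length individually.
#'
#' @param t_ref Reference transmittance in (0, 1].
#' @param c_ref Reference concentration (> 0).
#' @param c_new New concentration (>= 0), same unit as `c_ref`.
#' @return Numeric vector of transmittances.
#' @examples
#' scale_transmittance(0.037, 6.3, 9.45)  # ~0.0071
#' @export
scale_transmittance <- function(t_ref, c_ref, c_new) {
  if (any(t_ref <= 0) || any(t_ref > 1)) {
    abort("`t_ref` must lie in (0, 1].", class = "adaptivepcr_domain_error")
  }
  if (any(c_ref <= 0) || any(c_new < 0)) {
    abort("`c_ref` must be > 0 and `c_new` >= 0.",
          class = "adaptivepcr_domain_error")
  }
  t_ref^(c_new / c_ref)
}

#' Convert between decadic and natural attenuation coefficients
#'
#' @param x Coefficient(s) to convert.
#' @return `decadic_to_natural()` multiplies by ln(10);
#'   `natural_to_decadic()` divides by ln(10).
#' @export
decadic_to_natural <- function(x) x * log(10)

#' @rdname decadic_to_natural
#' @export
natural_to_decadic <- function(x) x / log(10)

#' Fluorescence blocking fraction from gain-response curves
#'
#' Quantifies how much of the fluorescence signal an absorber (e.g. gold
#' nanorods) blocks: LED excitation power is stepped up while fluorescence
#' is recorded for a sample and for an absorber-free control; at each power
#' setting the sample/control ratio gives the fraction of light remaining,
#' and the ratios are averaged across the whole gain-response curve. A value
#' of 1 means no blocking.
#'
#' @param sample,control Data frames with columns `power` (strictly
#'   increasing settings) and `fluorescence`; `sample` and `control` must
#'   share identical power settings. An optional `channel` column, present
#'   in both, computes the metric per channel.
#' @return A tibble with columns `channel` (if supplied),
#'   `blocking_fraction`, `n_settings` (ratios averaged) and `n_excluded`
#'   (settings dropped because the control read 0, reported with a warning).
#' @examples
#' ctl <- tibble::tibble(power = 1:3, fluorescence = c(10, 20, 30))
#' smp <- tibble::tibble(power = 1:3, fluorescence = c(8, 10, 30))
#' blocking_fraction(smp, ctl)  # mean of 0.8, 0.5, 1.0
#' @export
blocking_fraction <- function(sample, control) {
  check_gain_curve(sample, "sample")
  check_gain_curve(control, "control")
  has_channel <- "channel" %in% names(sample)
  if (has_channel != ("channel" %in% names(control))) {
    abort("`channel` column must be present in both curves or neither.",
          class = "adaptivepcr_validation_error")
  }
  if (!has_channel) {
    sample$channel <- control$channel <- "all"
  }
  channels <- sort(unique(sample$channel))
  if (!setequal(channels, unique(control$channel))) {
    abort("sample and control cover different channels.",
          class = "adaptivepcr_validation_error")
  }
  out <- purrr::map_dfr(channels, function(ch) {
    s <- dplyr::arrange(dplyr::filter(sample, .data$channel == ch), .data$power)
    k <- dplyr::arrange(dplyr::filter(control, .data$channel == ch), .data$power)
    if (nrow(s) != nrow(k) || !isTRUE(all.equal(s$power, k$power))) {
      abort(sprintf("power settings of sample and control differ (channel '%s').", ch),
            class = "adaptivepcr_validation_error")
    }
    zero <- k$fluorescence == 0
    if (any(zero)) {
      warn(sprintf("%d setting(s) with zero control fluorescence excluded (channel '%s').",
                   sum(zero), ch))
    }
    ratios <- s$fluorescence[!zero] / k$fluorescence[!zero]
    if (length(ratios) == 0L) {
      abort("no usable settings: control fluorescence is zero everywhere.",
            class = "adaptivepcr_validation_error")
    }
    tibble(channel = ch, blocking_fraction = mean(ratios),
           n_settings = length(ratios), n_excluded = sum(zero))
  })
  if (!has_channel) out$channel <- NULL
  out
}

check_gain_curve <- function(x, what) {
  if (!is.data.frame(x) || !all(c("power", "fluorescence") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with `power` and `fluorescence` columns.", what),
          class = "adaptivepcr_validation_error")
  }
  if (nrow(x) < 1L) {
    abort(sprintf("`%s` must have at least one row.", what),
          class = "adaptivepcr_validation_error")
  }
  split_powers <- if ("channel" %in% names(x)) split(x$power, x$channel) else list(x$power)
  for (p in split_powers) {
    if (any(diff(p[order(p)]) == 0) || is.unsorted(p)) {
      abort(sprintf("`%s` power settings must be strictly increasing.", what),
            class = "adaptivepcr_validation_error")
    }
  }
  invisible(x)
}
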