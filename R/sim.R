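# Closed-loop simulator of the laser-heated photothermal thermocycler.
#
# A lumped (zero-dimensional) thermal model drives two-state sensor melt
# models and a hydrolysis-probe amplification chemistry, sampled at 30 Hz
# with Gaussian detector noise. The cycling controller (control.R) closes
# the loop: the simulator has no preset temperatures or times beyond safety
# bounds; every phase change is decided from the simulated fluorescence.

#' Thermal parameters of the lumped heating/cooling model
#'
#' Heating is modelled as a constant net ramp (laser-power dominated);
#' cooling as Newtonian relaxation toward ambient, with the rate constant
#' calibrated so the mean cooling rate over `[t_max, t_min]` equals
#' `cool_rate`. Defaults are thermocouple estimates for a 1370 nm
#' direct-heating instrument (2.41 and 2.49 deg C/s). `t_min`/`t_max` are
#' simulator conveniences (a heater clip and a calibration span), not
#' setpoints: the controller never sees temperature.
#'
#' @param heat_rate Net heating rate, deg C/s (> 0).
#' @param cool_rate Mean net cooling rate over `[t_max, t_min]`, deg C/s (> 0).
#' @param ambient Ambient temperature, deg C.
#' @param t_min Anneal-side calibration floor, deg C (ambient < t_min < t_max).
#' @param t_max Denature-side ceiling at which heating clips, deg C.
#' @return A list of class `thermal_params` (includes the derived Newtonian
#'   rate constant `k_cool`, 1/s).
#' @export
thermal_params <- function(heat_rate = 2.41, cool_rate = 2.49, ambient = 21.5,
                           t_min = 50, t_max = 97) {
  if (heat_rate <= 0 || cool_rate <= 0) {
    abort("`heat_rate` and `cool_rate` must be > 0.", class = "adaptivepcr_validation_error")
  }
  if (!(ambient < t_min && t_min < t_max)) {
    abort("need ambient < t_min < t_max.", class = "adaptivepcr_validation_error")
  }
  k_cool <- cool_rate * log((t_max - ambient) / (t_min - ambient)) / (t_max - t_min)
  structure(list(heat_rate = heat_rate, cool_rate = cool_rate,
                 ambient = ambient, t_min = t_min, t_max = t_max,
                 k_cool = k_cool),
            class = "thermal_params")
}

#' One step of the lumped thermal model
#'
#' @param t Current temperature, deg C.
#' @param phase `"heating"` or `"cooling"`.
#' @param dt Time step, s (> 0).
#' @param p A [thermal_params()] object.
#' @return Temperature after `dt`. Heating advances linearly at `heat_rate`
#'   and clips at `t_max`; cooling relaxes exponentially toward `ambient`
#'   (exactly, so it never crosses ambient regardless of `dt`).
#' @export
thermal_step <- function(t, phase = c("heating", "cooling"), dt, p) {
  phase <- match.arg(phase)
  stopifnot(inherits(p, "thermal_params"))
  if (dt <= 0) abort("`dt` must be > 0.", class = "adaptivepcr_validation_error")
  if (phase == "heating") {
    min(t + p$heat_rate * dt, p$t_max)
  } else {
    p$ambient + (t - p$ambient) * exp(-p$k_cool * dt)
  }
}

#' Amplification chemistry parameters
#'
#' Per-cycle logistic growth with a hydrolysis-probe signal: each cycle
#' multiplies the template by `1 + (E - 1) * (1 - copies/K)`, so growth is
#' exponential at factor E far below the carrying capacity K and plateaus at
#' K. Probe fluorescence is cumulative and irreversible (TaqMan-style
#' hydrolysis): each replication event releases `probe_gain` fluorescence
#' units, saturating at `probe_total` when the probe pool is exhausted.
#'
#' Defaults place the detection threshold crossing for a 10^5 copies/uL
#' sample (2e6 copies in a 20 uL reaction) near cycle 18-20 under the
#' default detector noise, leaving all seven decades of the standard
#' dilution series detectable within a 40-cycle run.
#'
#' @param efficiency Per-cycle amplification factor E in (1, 2].
#' @param carrying_capacity Plateau copy number K (may be `Inf`).
#' @param initial_copies Template copies in the reaction (0 for an NTC).
#' @param probe_gain Fluorescence units per replicated copy (a.u./copy).
#' @param probe_total Saturation cap on cumulative probe signal (a.u.).
#' @return A list of class `chemistry_params`.
#' @export
chemistry_params <- function(efficiency = 2, carrying_capacity = 2e13,
                             initial_copies = 2e6, probe_gain = 1e-11,
                             probe_total = 100) {
  if (initial_copies > 0 && (efficiency <= 1 || efficiency > 2)) {
    abort("`efficiency` must lie in (1, 2] for positive samples.",
          class = "adaptivepcr_validation_error")
  }
  if (initial_copies < 0) {
    abort("`initial_copies` must be >= 0.", class = "adaptivepcr_validation_error")
  }
  if (carrying_capacity <= 0 || probe_gain < 0 || probe_total <= 0) {
    abort("chemistry parameters out of range.", class = "adaptivepcr_validation_error")
  }
  structure(list(efficiency = efficiency, carrying_capacity = carrying_capacity,
                 initial_copies = initial_copies, probe_gain = probe_gain,
                 probe_total = probe_total),
            class = "chemistry_params")
}

#' One PCR cycle of logistic amplification
#'
#' @param copies Current template copies (>= 0).
#' @param chem A [chemistry_params()] object.
#' @return A list with `copies` (after the cycle) and `probe_increment`
#'   (uncapped fluorescence released this cycle; the caller caps the
#'   cumulative signal at `probe_total`).
#' @export
amplify_cycle <- function(copies, chem) {
  stopifnot(inherits(chem, "chemistry_params"))
  if (copies < 0) abort("`copies` must be >= 0.", class = "adaptivepcr_validation_error")
  growth <- max(0, 1 - copies / chem$carrying_capacity)
  new_copies <- copies * (1 + (chem$efficiency - 1) * growth)
  list(copies = new_copies,
       probe_increment = chem$probe_gain * (new_copies - copies))
}

#' Full simulator configuration
#'
#' @param thermal A [thermal_params()] object.
#' @param chemistry A [chemistry_params()] object.
#' @param anneal_sensor,melt_sensor [melt_model()]s for the two L-DNA
#'   sensors; the anneal sensor must melt below the melt sensor. Defaults
#'   58.4 and 90.8 deg C (the design Tm values of the bundled sensor
#'   sequences) with a 2.5 deg C transition width.
#' @param sampling_hz Detector sampling rate (default 30 Hz).
#' @param noise_sd Gaussian detector noise SD, a.u. (sensor spans are 100).
#' @param blocking Optional named per-channel transmission multipliers in
#'   (0, 1], e.g. `c(yellow = 0.45, green = 0.5)`, applied to the final
#'   readings (nanorod attenuation).
#' @param n_cycles PCR cycles to run (default 40).
#' @param seed Integer RNG seed; fixed seed gives a bitwise-identical run.
#' @param baselines,spans Named channel baselines and sensor spans, a.u.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(thermal = thermal_params(),
                       chemistry = chemistry_params(),
                       anneal_sensor = melt_model(58.4, 2.5),
                       melt_sensor = melt_model(90.8, 2.5),
                       sampling_hz = 30, noise_sd = 0.5, blocking = NULL,
                       n_cycles = 40L, seed = 1L,
                       baselines = c(green = 5, yellow = 10, orange = 10),
                       spans = c(yellow = 100, orange = 100)) {
  stopifnot(inherits(thermal, "thermal_params"),
            inherits(chemistry, "chemistry_params"),
            inherits(anneal_sensor, "melt_model"),
            inherits(melt_sensor, "melt_model"))
  if (sampling_hz <= 0) abort("`sampling_hz` must be > 0.", class = "adaptivepcr_validation_error")
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.", class = "adaptivepcr_validation_error")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "adaptivepcr_validation_error")
  if (anneal_sensor$tm_celsius >= melt_sensor$tm_celsius) {
    abort("anneal sensor Tm must be below melt sensor Tm.",
          class = "adaptivepcr_validation_error")
  }
  if (!is.null(blocking)) {
    if (is.null(names(blocking)) || any(blocking <= 0) || any(blocking > 1)) {
      abort("`blocking` must be a named vector of fractions in (0, 1].",
            class = "adaptivepcr_validation_error")
    }
  }
  structure(list(
    thermal = thermal, chemistry = chemistry,
    anneal_sensor = anneal_sensor, melt_sensor = melt_sensor,
    sampling_hz = sampling_hz, noise_sd = noise_sd, blocking = blocking,
    n_cycles = as.integer(n_cycles), seed = as.integer(seed),
    baselines = baselines, spans = spans
  ), class = "sim_config")
}

# Channel blocking multiplier lookup (1 where unspecified).
blocking_mult <- function(cfg, channel) {
  if (is.null(cfg$blocking) || !channel %in% names(cfg$blocking)) return(1)
  unname(cfg$blocking[[channel]])
}

#' Noiseless or noisy per-channel sensor readings at a temperature
#'
#' The detector reports: `yellow` = melt-sensor channel (baseline + span x
#' single-stranded fraction of the melt sensor), `orange` = anneal-sensor
#' channel (same with the anneal sensor), `green` = hydrolysis-probe channel
#' (baseline + cumulative probe signal, constant within a cycle). Detector
#' noise is added per channel, then any per-channel blocking multiplier is
#' applied last.
#'
#' @param t Temperature, deg C (vectorized).
#' @param cfg A [sim_config()].
#' @param probe_signal Cumulative probe fluorescence, a.u.
#' @param noise If `TRUE`, add Gaussian noise with SD `cfg$noise_sd` using
#'   the current RNG state.
#' @return A tibble with columns `green`, `yellow`, `orange` (one row per
#'   temperature).
#' @export
sensor_fluorescence <- function(t, cfg, probe_signal = 0, noise = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- length(t)
  nz <- function() if (noise && cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else 0
  yellow <- (cfg$baselines[["yellow"]] +
               cfg$spans[["yellow"]] * ss_fraction(t, cfg$melt_sensor) + nz()) *
    blocking_mult(cfg, "yellow")
  orange <- (cfg$baselines[["orange"]] +
               cfg$spans[["orange"]] * ss_fraction(t, cfg$anneal_sensor) + nz()) *
    blocking_mult(cfg, "orange")
  green <- (cfg$baselines[["green"]] + probe_signal + nz()) *
    blocking_mult(cfg, "green")
  tibble(green = green, yellow = yellow, orange = orange)
}

#' Simulate a complete closed-loop adaptive PCR run
#'
#' Alternates heating and cooling under the cycling controller's decisions
#' for `n_cycles` cycles. During heating the controller watches the
#' simulated melt-sensor (`yellow`) channel, during cooling the
#' anneal-sensor (`orange`) channel. At each cooling-to-heating switch one
#' amplification cycle of the chemistry is applied and the `green` channel
#' reading at that instant is recorded as the cycle's PCR reading.
#'
#' @param cfg A [sim_config()].
#' @param control A [control_params()] object.
#' @return An object of class `pcr_run`: list with tibbles `traces`
#'   (`time_s`, `channel`, `value` at the sampling rate), `temperature`
#'   (`time_s`, `temp_c`; the latent state, for diagnostics), `switch_points`,
#'   `cycles`, `amplification` (`cycle`, `fluorescence`, `timestamp_s`),
#'   plus `completed_cycles`, the `config` and the `seed`. A phase that
#'   fails to produce a valid switch within `control$timeout_s` aborts the
#'   run with a control-error condition.
#' @examples
#' \donttest{
#' run <- simulate_run(sim_config(n_cycles = 3, seed = 7))
#' run$cycles
#' }
#' @export
simulate_run <- function(cfg = sim_config(), control = control_params()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(control, "control_params"))
  set.seed(cfg$seed)
  dt <- 1 / cfg$sampling_hz
  n_max <- ceiling(cfg$n_cycles * 2 * control$timeout_s * cfg$sampling_hz) + 16L

  times <- numeric(n_max)
  greens <- numeric(n_max); yellows <- numeric(n_max); oranges <- numeric(n_max)
  temps <- numeric(n_max)

  sp_cycle <- integer(0); sp_kind <- character(0)
  sp_time <- numeric(0); sp_fluo <- numeric(0)
  cyc_id <- integer(0); cyc_heat <- numeric(0); cyc_cool <- numeric(0)
  cyc_read <- numeric(0); cyc_ts <- numeric(0)

  temp <- cfg$thermal$ambient
  phase <- "heating"
  cycle <- 1L
  copies <- cfg$chemistry$initial_copies
  probe <- 0
  heat_start <- 0
  melt_time <- NA_real_
  mon <- monitor_new(control, direction = 1, phase_start = 0)

  # scalar channel constants, hoisted out of the sampling loop
  b_g <- cfg$baselines[["green"]]
  b_y <- cfg$baselines[["yellow"]]; s_y <- cfg$spans[["yellow"]]
  b_o <- cfg$baselines[["orange"]]; s_o <- cfg$spans[["orange"]]
  tm_m <- cfg$melt_sensor$tm_celsius; w_m <- cfg$melt_sensor$width_celsius
  tm_a <- cfg$anneal_sensor$tm_celsius; w_a <- cfg$anneal_sensor$width_celsius
  m_g <- blocking_mult(cfg, "green")
  m_y <- blocking_mult(cfg, "yellow")
  m_o <- blocking_mult(cfg, "orange")
  nsd <- cfg$noise_sd
  heat_rate <- cfg$thermal$heat_rate; t_max <- cfg$thermal$t_max
  ambient <- cfg$thermal$ambient
  cool_fac <- exp(-cfg$thermal$k_cool * dt)

  i <- 0L
  while (i < n_max) {
    i <- i + 1L
    tm <- i * dt
    temp <- if (phase == "heating") min(temp + heat_rate * dt, t_max)
            else ambient + (temp - ambient) * cool_fac
    nz <- if (nsd > 0) rnorm(3, 0, nsd) else c(0, 0, 0)
    g <- (b_g + probe + nz[1]) * m_g
    y <- (b_y + s_y / (1 + exp(-(temp - tm_m) / w_m)) + nz[2]) * m_y
    o <- (b_o + s_o / (1 + exp(-(temp - tm_a) / w_a)) + nz[3]) * m_o
    times[i] <- tm
    greens[i] <- g; yellows[i] <- y; oranges[i] <- o
    temps[i] <- temp

    val <- if (phase == "heating") y else o
    decision <- monitor_add(mon, tm, val)
    if (decision == "timeout") control_error(phase, cycle, tm)
    if (decision == "switch") {
      if (phase == "heating") {
        sp_cycle <- c(sp_cycle, cycle); sp_kind <- c(sp_kind, "melt_switch")
        sp_time <- c(sp_time, tm); sp_fluo <- c(sp_fluo, y)
        melt_time <- tm
        phase <- "cooling"
        mon <- monitor_new(control, direction = -1, phase_start = tm)
      } else {
        # end of cooling: this cycle's annealing/extension has happened
        amp <- amplify_cycle(copies, cfg$chemistry)
        copies <- amp$copies
        probe <- min(probe + amp$probe_increment, cfg$chemistry$probe_total)
        reading <- (b_g + probe + if (nsd > 0) rnorm(1, 0, nsd) else 0) * m_g
        greens[i] <- reading
        sp_cycle <- c(sp_cycle, cycle); sp_kind <- c(sp_kind, "anneal_switch")
        sp_time <- c(sp_time, tm); sp_fluo <- c(sp_fluo, o)
        cyc_id <- c(cyc_id, cycle)
        cyc_heat <- c(cyc_heat, melt_time - heat_start)
        cyc_cool <- c(cyc_cool, tm - melt_time)
        cyc_read <- c(cyc_read, reading)
        cyc_ts <- c(cyc_ts, tm)
        cycle <- cycle + 1L
        if (cycle > cfg$n_cycles) break
        heat_start <- tm
        phase <- "heating"
        mon <- monitor_new(control, direction = 1, phase_start = tm)
      }
    }
  }

  used <- seq_len(i)
  traces <- tibble(
    time_s = rep(times[used], 3L),
    channel = rep(c("green", "yellow", "orange"), each = i),
    value = c(greens[used], yellows[used], oranges[used])
  )
  structure(list(
    traces = traces,
    temperature = tibble(time_s = times[used], temp_c = temps[used]),
    switch_points = tibble(cycle = sp_cycle, kind = sp_kind, time_s = sp_time,
                           fluorescence_at_switch = sp_fluo),
    cycles = tibble(cycle = cyc_id, heat_duration_s = cyc_heat,
                    cool_duration_s = cyc_cool, pcr_reading = cyc_read,
                    pcr_timestamp_s = cyc_ts),
    amplification = tibble(cycle = cyc_id, fluorescence = cyc_read,
                           timestamp_s = cyc_ts),
    completed_cycles = length(cyc_id),
    config = cfg, seed = cfg$seed
  ), class = "pcr_run")
}

#' @export
print.pcr_run <- function(x, ...) {
  cat(sprintf("<pcr_run> %d cycles, %d samples at %g Hz, seed %d\n",
              x$completed_cycles, nrow(x$traces) / 3L,
              x$config$sampling_hz, x$seed))
  invisible(x)
}

#' Simulate a per-cycle amplification curve (no thermal loop)
#'
#' Fast cycle-level counterpart of [simulate_run()]: applies the same
#' amplification chemistry once per cycle and reports the green-channel PCR
#' reading (baseline + cumulative probe signal + detector noise) with
#' timestamps on a nominal cycle time. Used for dilution series, where the
#' full 30 Hz closed-loop trace is not needed.
#'
#' @param chem A [chemistry_params()] object.
#' @param n_cycles Number of cycles.
#' @param noise_sd Detector noise SD, a.u.
#' @param baseline Green-channel baseline, a.u.
#' @param cycle_time_s Nominal seconds per cycle for the timestamps.
#' @param first_cycle_extra_s Extra duration of cycle 1 (heating from
#'   ambient).
#' @return A tibble (`cycle`, `fluorescence`, `timestamp_s`) with the
#'   ground-truth parameters attached as attribute `"truth"`.
#' @export
simulate_amplification <- function(chem = chemistry_params(), n_cycles = 40L,
                                   noise_sd = 0.5, baseline = 5,
                                   cycle_time_s = 21.76,
                                   first_cycle_extra_s = 12) {
  stopifnot(inherits(chem, "chemistry_params"))
  copies <- chem$initial_copies
  probe <- 0
  fluo <- numeric(n_cycles)
  for (cyc in seq_len(n_cycles)) {
    amp <- amplify_cycle(copies, chem)
    copies <- amp$copies
    probe <- min(probe + amp$probe_increment, chem$probe_total)
    fluo[cyc] <- baseline + probe + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
  }
  out <- tibble(
    cycle = seq_len(n_cycles), fluorescence = fluo,
    timestamp_s = first_cycle_extra_s + cycle_time_s * seq_len(n_cycles)
  )
  attr(out, "truth") <- list(efficiency = chem$efficiency,
                             initial_copies = chem$initial_copies,
                             carrying_capacity = chem$carrying_capacity,
                             probe_gain = chem$probe_gain,
                             noise_sd = noise_sd, baseline = baseline,
                             cycle_time_s = cycle_time_s)
  out
}

#' Simulate a serial-dilution qPCR experiment
#'
#' Generates per-cycle amplification curves for a dilution series plus
#' no-template controls, mirroring a standard-curve / limit-of-detection
#' study design (seven decades, n replicates per concentration, 40 cycles,
#' 20 uL reactions). By default the template load per reaction is the
#' deterministic expectation `round(concentration x volume)`; set
#' `poisson = TRUE` to draw it from a Poisson distribution instead (the
#' physical low-copy sampling process).
#'
#' @param concentrations Template concentrations in copies/uL (default
#'   10^5 down to 10^-1).
#' @param n_replicates Replicates per concentration (default 4).
#' @param n_ntc Number of no-template controls (default 3).
#' @param volume_ul Reaction volume in uL (default 20).
#' @param chem Chemistry template; `initial_copies` is overridden per
#'   sample.
#' @param n_cycles,noise_sd,baseline,cycle_time_s Passed to
#'   [simulate_amplification()].
#' @param poisson Draw template copies from Poisson(concentration x volume)?
#' @param seed Integer seed; the whole series is reproducible from it.
#' @return A tibble with one row per sample: `sample_id`, `concentration`
#'   (copies/uL; `NA` for NTC), `role` (`"sample"`/`"NTC"`), `copies`
#'   (template actually seeded) and `curve` (list column of amplification
#'   tibbles).
#' @export
simulate_dilution_series <- function(concentrations = 10^(5:-1),
                                     n_replicates = 4L, n_ntc = 3L,
                                     volume_ul = 20,
                                     chem = chemistry_params(),
                                     n_cycles = 40L, noise_sd = 0.5,
                                     baseline = 5, cycle_time_s = 21.76,
                                     poisson = FALSE, seed = 1L) {
  set.seed(as.integer(seed))
  plan <- tidyr::expand_grid(concentration = concentrations,
                             replicate = seq_len(n_replicates))
  if (n_ntc > 0) {
    plan <- dplyr::bind_rows(plan, tibble(concentration = NA_real_,
                                          replicate = seq_len(n_ntc)))
  }
  plan <- dplyr::mutate(
    plan,
    role = ifelse(is.na(.data$concentration), "NTC", "sample"),
    sample_id = ifelse(
      .data$role == "NTC", sprintf("NTC_%d", .data$replicate),
      sprintf("c%0.0e_r%d", .data$concentration, .data$replicate)
    )
  )
  expected <- ifelse(is.na(plan$concentration), 0,
                     plan$concentration * volume_ul)
  copies <- if (poisson) stats::rpois(length(expected), expected)
            else round(expected)
  plan$copies <- copies
  plan$curve <- purrr::map(copies, function(cp) {
    ch <- chem
    ch$initial_copies <- cp
    simulate_amplification(ch, n_cycles = n_cycles, noise_sd = noise_sd,
                           baseline = baseline, cycle_time_s = cycle_time_s)
  })
  dplyr::select(plan, "sample_id", "concentration", "role", "copies", "curve")
}
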