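---
title: "Adaptive PCR: models, control algorithm and quantification methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive PCR: models, control algorithm and quantification methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptivepcr)
```

Adaptive PCR replaces the preset temperatures and hold times of a
conventional thermocycler with direct optical monitoring of DNA
hybridization. Fluorophore/quencher end-labelled L-DNA duplexes — mirror
image stereoisomers with the same hybridization thermodynamics as natural
DNA but no interaction with polymerases — are added to the reaction: a
*melt sensor* matched to the double-stranded target and an *anneal sensor*
matched to the primers. Their fluorescence reports, in real time, whether
the target is denatured and whether primers can anneal, under whatever
ambient conditions and sample impurities the reaction actually experiences.
This vignette documents the models implemented in this package, the
numerical decisions inside the controller, the tunable parameters and their
defaults, and what the bundled simulator does and does not emulate.

## The cycling-control algorithm

During heating the controller watches the melt-sensor channel (`yellow`),
which rises as the duplex denatures; during cooling it watches the
anneal-sensor channel (`orange`), which falls as the duplex re-forms. Both
transitions produce a single-peaked excursion in the time-derivative of the
watched signal. The controller:

1. smooths the incoming samples with a centered moving average
   (`smooth_window`, default 7 samples ≈ 0.23 s at the default 30 Hz);
2. differentiates with central finite differences;
3. once the derivative peak has been passed, fits
   $a\,e^{-(t-\mu)^2/(2\sigma^2)} + c$ to the phase's derivative series by
   Levenberg–Marquardt, refitting on every new sample;
4. switches phase at $t^\* = \mu + \alpha\sigma$, where the fitted
   derivative has decayed to $e^{-\alpha^2/2}$ of its peak.

"The derivative has approached zero" is not a sharp criterion; we
operationalize it with the threshold $\alpha$ (default **2**, i.e. the
derivative at ~13.5% of peak). Larger $\alpha$ waits longer past the
transition (more complete melting/annealing, slower cycles); $\alpha$ is a
`control_params()` field. Because every quantity involved — the derivative,
the fitted amplitude and offset, and all acceptance checks below — scales
and shifts with the raw signal, the switch decision is invariant to affine
transforms of the fluorescence (gain drift, baseline shifts, attenuation).
The test suite asserts this invariance directly.

### Peak detection and fit acceptance

Streaming fits on noisy derivatives can hallucinate peaks, and a single bad
fit that places $t^\*$ in the past would fire a switch immediately. Three
safeguards, all *relative* to the data so affine invariance is preserved:

* **peak passed**: the smoothed derivative must decline for
  `peak_decline_samples` (default 3) consecutive samples after its running
  maximum before fitting is considered;
* **peak prominent**: fitting engages only once the running maximum exceeds
  the median of the phase's derivative series by 4 robust SDs (median/MAD)
  — plain detector noise rarely reaches this, so the refits start only when
  a transition is actually underway;
* **fit plausibility**: an accepted fit must converge with the correct sign;
  amplitude at least 5 residual SDs and at most twice the observed
  derivative range (rejects degenerate narrow-spike solutions); $\sigma$ at
  least 4 sampling intervals (a peak an instrument at this rate can
  actually resolve); residual sum of squares at most half the variance of
  the series; and $\mu$ inside the phase, at or before the current time.
  Fits with $\sigma$ collapsing below a quarter sampling interval or worse
  than a constant model are fit *failures* (the caller retries on the next
  sample), never switches.

A switch additionally requires **three consecutive accepted refits**:
spurious fits on noise are unstable from sample to sample, while the refits
tracking a real transition are accepted continuously, so this costs at most
a tenth of a second at 30 Hz and removes the remaining false-trigger mode.
Guard rails: no switch earlier than `min_phase_s` (default 2 s) into a
phase, and a phase exceeding `timeout_s` (default 60 s) without a valid
switch raises a control error — the same failure mode a heavily
light-blocked reaction produces on the physical instrument.

The fit uses the whole phase's derivative series (not a sliding window),
warm-started from the previous accepted parameters; whether the original
firmware windows its fit is not documented anywhere we know of, and the
full-phase choice makes the estimate strictly more stable as the transition
completes. The PCR reading at each cooling→heating switch is a single
green-channel sample at the switch instant; averaging several samples would
be a trivial extension but is not what we model.

## The closed-loop simulator

`simulate_run()` couples the controller to a lumped (zero-dimensional)
photothermal model, producing the synthetic data every other module
consumes. Nothing in the loop knows a temperature setpoint: `t_min`/`t_max`
exist only as a heater clip and a calibration span.

* **Heating**: constant net ramp `heat_rate` (default 2.41 °C/s, a
  thermocouple estimate for a 1370 nm direct-heating instrument), clipped
  at `t_max` (97 °C).
* **Cooling**: Newtonian relaxation toward `ambient` (21.5 °C), with the
  rate constant calibrated so the *mean* rate over `[t_max, t_min]`
  (97→50 °C) equals `cool_rate` (default 2.49 °C/s) — only mean ramp rates
  are ever measurable on such instruments, so only the mean is pinned.
* **Sensors**: two-state melt models; the single-stranded fraction is
  logistic in temperature, $f_{ss}(T) = 1/(1+e^{-(T-T_m)/w})$, with design
  midpoints 58.4 °C (anneal) and 90.8 °C (melt). The transition width $w$
  (default 2.5 °C) is a free parameter: it sets, together with the ramp
  rate, the width of the derivative peak the controller sees. Channels:
  `yellow` = baseline + span·$f_{ss}$(melt sensor), `orange` = same with
  the anneal sensor, `green` = baseline + cumulative probe signal.
* **Chemistry**: per-cycle logistic growth,
  `copies' = copies · (1 + (E−1)(1 − copies/K))`, applied once per cycle at
  the cooling→heating switch (annealing/extension happens at the cool end
  of the cycle). The probe signal is cumulative and irreversible —
  `probe_gain` fluorescence units per replicated copy, capped at
  `probe_total` — because the modelled assay uses a hydrolysis (TaqMan)
  probe. Defaults (E = 2, K = 2×10¹³, gain 10⁻¹¹ a.u./copy, cap 100 a.u.)
  place the detection threshold crossing of a 10⁵ copies/µL sample near
  cycle 18–20 and keep all seven decades of the standard dilution series
  detectable within 40 cycles.
* **Detector**: 30 Hz sampling, i.i.d. Gaussian noise per channel
  (`noise_sd`, default 0.5 a.u. against sensor spans of 100 a.u. —
  emulating the clean photodiode traces such instruments produce; raise it
  to stress the controller). Optional per-channel `blocking` multipliers in
  (0, 1] model nanorod attenuation and are applied last.
* **Determinism**: everything is driven by one integer seed; identical
  configuration and seed give a bitwise-identical run.

What the simulator deliberately does **not** emulate: spatial temperature
and hybridization heterogeneity across the reaction volume (the lumped
model has one temperature), mineral-oil evaporation, laser-diode thermal
drift, and multiplex LED rise-time effects. Passing tests therefore show
that the algorithms are correct against the stated models, not that the
models capture every artefact of a physical instrument.

### Template load in dilution series

`simulate_dilution_series()` defaults to a *deterministic* template load,
`copies = round(concentration × volume)`, with 20 µL reactions. Physical
low-copy sampling is Poisson, and `poisson = TRUE` enables that; the
deterministic default was chosen once, because it separates what the
analysis modules are tested on (amplification, detection, regression) from
sampling stochasticity, and makes the limit-of-detection property exact:
the lowest concentration seeding ≥ 1 copy is detected in every replicate.
With Poisson sampling a 2-copy-mean sample is empty 13.5% of the time, and
LoD calls on n = 4 replicates become a coin flip — true to life, but a
property of sampling, not of the instrument or analysis.

## Quantification methods

* **Normalization**: subtract the baseline (mean of the first 15 cycles),
  divide by the maximum baseline-subtracted fluorescence, × 100. The
  baseline SD is computed on the raw scale (the convention when thresholds
  are quoted in instrument units); normalization is idempotent and the Cq
  call below is invariant to affine transforms of the raw curve.
* **Cq**: first fractional cycle at which the baseline-subtracted signal
  reaches `k_sd` (default 10) baseline SDs. The fractional crossing is
  interpolated with a shape-preserving monotone cubic spline
  (`splinefun(method = "monoH.FC")`) through the cycles bracketing the
  first crossing — a natural cubic spline can overshoot between knots and
  shift the crossing; the monotone spline cannot, and the test suite keeps
  a linear-interpolation oracle within 0.25 cycles of it. Degenerate case:
  a noiseless synthetic baseline has SD 0, which would make the threshold
  0; the SD is floored at `sd_floor` with a warning. If the crossing falls
  inside the baseline window a warning is emitted (the baseline always uses
  cycles 1–15, so very high template loads contaminate their own
  baseline — visible as compressed Cq spacing at the top of a dilution
  series).
* **Quantification time**: the wall-clock analog of Cq for instruments with
  variable cycle times — per-cycle timestamps interpolated at the
  fractional Cq.
* **Single-sample efficiency** (window of linearity): OLS of
  log(normalized fluorescence) on cycle over 5 cycles centred on
  `round(Cq)`; efficiency = `exp(slope)` (natural log, so a slope of ln 2
  is a doubling). Non-positive normalized values inside the window make the
  log undefined; the window is shifted upward by the minimal number of
  cycles that avoids them, and the shift is reported. On exact geometric
  curves the estimator is exact; near the detection threshold its
  per-sample spread is inherently large (the window bottom sits a few SD
  above baseline), which is why standard curves average many reactions.
* **Standard curve**: OLS of Cq on log10 concentration over all positive
  reactions; efficiency `10^(−1/slope)` (the universal qPCR convention;
  −3.32 cycles/decade ⇔ E = 2). Negative reactions are excluded and
  counted; at least three distinct concentrations are required.
* **Cycle time**: mean ± SD of per-cycle durations over cycles 2–11 — the
  first cycle starts from an arbitrary environmental temperature and is
  excluded. Switch-point stability (`switch_stats()`) uses cycles 2–16 for
  the same reason at the front, and stops before the hydrolysis-probe
  signal rises enough to bleed into the sensor channels on a shared
  detector.
* **LoD**: the lowest concentration at which *every* replicate is positive.

## Oligo melting temperatures

`salt_adjusted_tm()` implements the salt-adjusted formulas used for sensor
design: for length N > 13,
$T_m = 100.5 + 41\,\mathrm{GC}/N - 820/N + 16.6\log_{10}[\mathrm{Na}^+]$,
and for N ≤ 13 the 2·(A+T) + 4·(G+C) rule with the same salt correction
(threshold 13 is the convention of the web calculators this mirrors; all
bundled sequences use the long branch). The default 50 mM Na⁺ reproduces
the bundled short-sequence design values exactly; master-mix salt content
is typically proprietary, so the concentration is a parameter. On the long
(77/83-nt) sensor and target sequences this formula lands about 0.2 °C away
from the values computed by the original web tool — a counting-variant
discrepancy we document rather than force: the package's values are used
with a ±0.3 °C tolerance. Fluorophore/quencher labels and chirality are
metadata only; L-DNA pairs with the energetics of D-DNA, which is the
entire point of using it as a sensor.

## Optics

Transmission follows Beer's law in the decadic convention,
$T = 10^{-\varepsilon c L}$ (converters to the natural-log convention are
provided). Nanorod extinction coefficients and tube path lengths are vendor
proprietary / geometry dependent, so they are configuration inputs, not
constants; a single calibrated transmittance anchors the rest of a dilution
series through $T_{new} = T_{ref}^{\,c_{new}/c_{ref}}$, which is exactly
equivalent to recomputing Beer's law at the new concentration (asserted as
an oracle-equivalence property in the tests). Tube geometry is reduced to
two scalar path lengths (narrowest/thickest); no wavelength-resolved
plasmon spectra, scattering or ray tracing. The fluorescence-blocking
metric averages the sample/control fluorescence ratio over an LED
gain-response curve; settings where the control reads zero are excluded
with a warning count.

## Problem sizes and numerical conventions in the tests

The test and acceptance suites run two full 40-cycle closed-loop
simulations (one noiseless positive run for structure and stability, one
no-template control at default noise), a 7-decade × 4-replicate dilution
series, and batches of replayed synthetic traces; these sizes exercise every
code path while keeping a full run in tens of seconds on one core.
Controller oracle-equivalence at one-sample tolerance is asserted on traces
whose transition derivative is *exactly* Gaussian (error-function-shaped
melt curves): there the fitted $\mu + \alpha\sigma$ and the brute-force
"argmax, then first decay below $e^{-\alpha^2/2}$ of peak" rule coincide by
construction. On logistic transitions the two rules differ systematically —
a Gaussian fitted to a sech² peak has lighter tails, so no one-sample
agreement exists to assert — and the suite instead checks the bracketing
property (the switch lands after the transition midpoint, within 4σ of it)
and the never-switch-before-the-peak invariant.

## Known limitations

* The controller is tuned for transitions that are slow relative to the
  sampling rate (σ ≥ 4 samples); a much faster instrument would need a
  higher sampling rate or a narrower smoothing window.
* The simulator's noise is i.i.d. Gaussian; real detectors add 1/f drift
  and shot-noise scaling, which the affine-invariance of the controller
  mitigates but the tests do not model.
* Cq precision is limited by the 15-point baseline SD estimate (~19%
  relative error), which the 10·SD threshold inherits — visible as
  ~0.2–0.4 cycle spread between replicates at any noise level. This
  matches how per-sample thresholds behave on real instruments; fleet-wide
  fixed thresholds trade this for gain sensitivity.
* `single_sample_efficiency` assumes the 5-cycle window sits in the
  exponential phase; curves that plateau within two cycles of their Cq
  will bias it downward.
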