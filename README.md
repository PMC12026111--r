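# adaptivepcr

Tools for **adaptive PCR** — thermocycling controlled by real-time DNA
hybridization fluorescence rather than preset temperatures and times — and
for the quantitative PCR analyses used to evaluate such instruments.

In an adaptive thermocycler, fluorophore/quencher end-labelled **L-DNA**
sensor duplexes (mirror-image stereoisomers that hybridize exactly like
natural DNA but are invisible to polymerases) are added to the reaction. A
*melt sensor* mirrors the double-stranded target, an *anneal sensor* mirrors
the primers. During heating the instrument watches the melt-sensor channel;
during cooling, the anneal-sensor channel. A Gaussian
`a·exp(−(t−μ)²/(2σ²)) + c` is fitted, continuously as samples stream in at
30 Hz, to the smoothed time-derivative of the watched channel, and the phase
switches when the derivative is predicted to have decayed to near zero, at

    t* = μ + α·σ        (default α = 2: the derivative is at ~13.5% of its peak)

Because the decision depends only on the *derivative*, it is unaffected by
gain or offset drifts of the raw fluorescence. At each cooling-to-heating
switch a PCR reading is taken on the hydrolysis-probe channel, giving one
amplification point per cycle.

The package provides, for instrument developers and assay analysts:

* **adaptive cycling control** — streaming smoothed derivatives, Gaussian
  refits, switch-point prediction, the heat/cool state machine
  (`control_loop()`), and switch-point stability statistics
  (`switch_stats()`);
* **a closed-loop instrument simulator** — lumped photothermal dynamics
  (constant-rate laser heating, Newtonian fan cooling), two-state sensor melt
  models, logistic amplification with a TaqMan-style cumulative probe
  signal, detector noise and per-channel nanorod blocking
  (`simulate_run()`, `simulate_dilution_series()`);
* **qPCR quantification** — 0–100 normalization against a 15-cycle baseline,
  fractional Cq at 10 baseline SDs with monotone-spline interpolation,
  quantification *time* from per-cycle timestamps, LinRegPCR-style
  window-of-linearity single-sample efficiency (`exp(slope)` of log
  fluorescence over 5 cycles centred on the Cq), standard curves
  (`10^(−1/slope)`), cycle-time summaries and limit-of-detection calls;
* **oligo thermodynamics** — salt-adjusted melting temperatures
  (`Tm = 100.5 + 41·GC/N − 820/N + 16.6·log10[Na+]` for N > 13) with the
  bundled sensor/primer/target sequence set (`ldna_oligos()`);
* **Beer–Lambert optics** — transmittance, concentration rescaling
  (`T_new = T_ref^(c_new/c_ref)`) and the nanorod fluorescence-blocking
  metric from LED gain-response curves.

Everything is tibble-first: data frames in, tibbles out, `autoplot()`
methods for runs, curves and standard curves, `tidy()`/`glance()` for
fitted objects.

## Worked example

Sensor design: are the L-DNA sensors matched to the assay?

```r
library(adaptivepcr)
salt_adjusted_tm(ldna_oligos())[c(1, 3, 5, 8), c("name", "length", "gc_count", "tm_display")]
#> # A tibble: 4 × 4
#>   name                    length gc_count tm_display
#> 1 anneal_sensor_F             22        9       58.4
#> 2 melt_sensor_F               77       42       90.6
#> 3 smitis_forward_primer       21       10       59.4
#> 4 smitis_synthetic_target     83       41       89.3
```

The anneal sensor (58.4 °C) tracks the forward primer (59.4 °C); the melt
sensor (90.6 °C) sits above the target duplex (89.3 °C), so its fluorescence
only saturates once the target is fully denatured.

A closed-loop simulated run — no temperatures or times are programmed; every
switch is decided from the simulated sensor fluorescence:

```r
run <- simulate_run(sim_config(n_cycles = 3, seed = 1))
run$cycles
#> # A tibble: 3 × 5
#>   cycle heat_duration_s cool_duration_s pcr_reading pcr_timestamp_s
#> 1     1            31.8            17.8        4.56            49.7
#> 2     2            19.3            17.8        4.48            86.8
#> 3     3            19.3            17.8        4.47           124.
autoplot(run)
```

Cycle 1 heats from ambient, so it is longer; afterwards the controller
settles into a stable ~37 s cycle. A full standard-curve experiment
(7 decades, 10⁵ to 10⁻¹ copies/µL in 20 µL reactions, n = 4, plus NTCs):

```r
library(dplyr)
series <- simulate_dilution_series(seed = 42)
res <- bind_cols(
  series[c("concentration", "role")],
  purrr::map_dfr(series$curve, ~ suppressWarnings(analyze_curve(.x)))
)
sc <- standard_curve(filter(res, role == "sample"))
glance(sc)
#> # A tibble: 1 × 6
#>   slope intercept r_squared efficiency n_used n_excluded
#> 1 -3.29      34.5     0.998       2.01     28          0
lod_call(res)$lod
#> [1] 0.1
```

The fitted slope of −3.29 cycles per decade corresponds to an overall
amplification efficiency of 2.01 (perfect doubling would be
−log₂10 = −3.32), and every replicate down to 0.1 copies/µL (2 copies per
20 µL reaction) is detected, so the limit of detection equals the lowest
concentration that seeds at least one template copy.

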