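# cosmosdwell

Dwell-time kinetics for colocalization single-molecule spectroscopy
(CoSMoS), with presets for spliceosome activation.

In a CoSMoS experiment, fluorescently labeled subcomplexes bind
surface-tethered substrate molecules, and each binding event appears as a
step in the integrated intensity trace of an area of interest (AOI).  The
package covers the full analysis chain for such recordings, built around
censored dwell-time models: a dwell is only observable between the minimum
detectable dwell `t_m` (one frame spacing) and the recording length
`t_max`, so every density is renormalized over that window.

The core models are the censored exponential mixture (1–3 components)

    f(t) = [ sum_i A_i (e^(-t_m/tau_i) - e^(-t_max/tau_i)) ]^-1
           * sum_i (A_i / tau_i) e^(-t/tau_i),      t in [t_m, t_max]

and the censored two-step convolution

    f(t) = (e^(-t/tau1) - e^(-t/tau2)) /
           [ tau1 (e^(-t_m/tau1) - e^(-t_max/tau1))
             - tau2 (e^(-t_m/tau2) - e^(-t_max/tau2)) ],

fit by maximum likelihood (`fit_dwells()`, returning a classed object with
`print`/`summary`/`coef`/`logLik`/`predict`/`simulate`/`plot` methods),
with nonparametric bootstrap errors (`bootstrap_errors()`), BIC model
selection (`select_model()`), probability-density histograms with binomial
error bars (`histogram_pd()`), and a two-laser-power global fit with
power-proportional photobleaching (`global_power_fit()`).

Around the fitter:

* `kinetic_scheme()` / `scheme_preset()` / `simulate_molecules()` — a
  Gillespie simulator of multi-channel binding schedules, with presets for
  tri-snRNP engagement at 2 mM and 50 µM ATP (binding turns U4 and U5 on
  simultaneously; exits route to activation, discard, or rare U5-first
  loss; the NTC channel follows U4 release).
* `render_traces()` / `render_background()` — noisy integrated-intensity
  traces (1 s frames at 3 s spacing over 60 min by default), optional
  photobleaching, Poisson background binding on empty AOIs.
* `detect_events()` — the 3.2σ-rise / 1σ-fall hysteresis detector with
  robust baseline estimation and censoring flags; `extract_dwells()`.
* `match_coincident()` / `classify_outcomes()` — pairing of simultaneous
  two-channel arrivals and classification into four outcome routes;
  `multi_binding_summary()`, `rebinding_analysis()`,
  `ordering_offsets()` / `randomized_control()`, `dwell_correlation()`,
  `background_rate()`.
* `run_pipeline()` / `make_fixture()` / `write_report()` — seeded
  end-to-end runs producing CSV/JSON report bundles, and deterministic
  event-table fixtures reconstructed from published per-route counts.

## Worked example

Simulate 200 molecules under the 2 mM ATP preset, detect events, classify
outcome routes, and fit the simultaneous-release dwell distribution:

```r
library(cosmosdwell)
rep <- run_pipeline("2mM", n_molecules = 200, seed = 42)
rep$tally
#> Outcome routes for 288 coincident binding events:
#>   U4_FIRST             145  (50.3%)
#>   U5_FIRST               8  (2.8%)
#>   SIMULTANEOUS_LOSS    106  (36.8%)
#>   PERSIST               29  (10.1%)

summary(bootstrap_errors(rep$fit_release, n_boot = 200, seed = 42))
#> Censored dwell-time fit: exp3, N = 106 events, window [3, 3600] s
#>      Estimate Boot SD
#> A1     0.4917   0.082
#> A2     0.2687   0.090
#> A3     0.2396   0.065
#> tau1   5.3091   1.136
#> tau2  36.3989  19.559
#> tau3 211.2001  35.241
#> log-likelihood -523.428; converged; bootstrap n = 200
```

Reading the output: most coincident U4/U5 binding events end with U4 loss
first (the activation route); about a third release both spots
simultaneously (tri-snRNP discard).  The three-component fit of the
discard dwell distribution recovers the fast and intermediate generating
constants (4 and 34 s) well; the slow constant is biased downward because
late-arriving complexes see a shortened effective window — a limitation
discussed in the methods vignette (`vignettes/dwell-time-methods.Rmd`).

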