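# gliamod

Satellite glial cells (SGCs) wrap the somata of dorsal root ganglion (DRG)
sensory neurons and secrete factors — extracellular-matrix glycoproteins
among them — that tune how excitable those neurons are. One route for such
tuning is the transient A-type potassium current (I_A, carried by
Kv4.2/Kv4.3 channels): enhancing I_A raises the current needed to fire an
action potential and damps repetitive firing, which at the behavioural
level shifts mechanical and thermal sensitivity.

`gliamod` packages the computational side of that research programme for
R users:

- **A conductance-based DRG neuron simulator** (Rcpp core): a single
  compartment with Hodgkin–Huxley sodium and delayed-rectifier currents
  plus a Connor–Stevens-style A-current
  `I_A = g_A a^3 b (V − E_K)` whose inactivation gate `b` is available
  after a −100 mV prepulse and shut after a −40 mV prepulse. Drive it
  with the standard protocols: a 0.15 pA/ms current ramp with a
  hyperpolarizing onset, −60…+50 mV voltage-step families, and a slow
  −100…+20 mV (100 mV/s) voltage ramp.
- **Patch-clamp feature extraction**: AP detection by the 5 mV/ms
  rise-speed threshold, first-AP waveform parameters (threshold,
  amplitude, half-height duration, maximal rise rate, fAHP), rheobase
  and rheobase charge transfer measured from the resting-potential
  crossing to the first-AP threshold, and state-dependent input
  resistance fitted 2–12 mV below or 5–15 mV above rest, averaged over
  trials.
- **Voltage-clamp K⁺-current analysis**: P/5 leak subtraction, I_A
  isolation by prepulse subtraction (I_A = I_Total − I_K),
  capacitance-normalised step I–V curves, 0.1-mV quasi-steady-state ramp
  binning, the blocker-sensitive (Kv4) ramp component, and the fraction
  of a total-current change carried by I_A near threshold (−10 mV).
- **Secretome filtering**: conditioned-media vs media-control candidate
  filtering (Welch test on log2 intensities, fold change ≥ 2, minimal
  negative-control signal), matrisome classification, and hypergeometric
  enrichment with Benjamini–Hochberg FDR.
- **Cell-type integration**: pseudobulk aggregation of a single-cell
  atlas by major DRG cell class, in-package TMM/log-CPM joint
  normalisation, shared highly-variable-gene selection, Spearman
  similarity of a bulk profile to each class, and candidate ranking by
  glial expression and glial specificity.
- **Behaviour**: seeded up-down von Frey sessions against a logistic
  psychometric responder and Dixon-style 50% paw-withdrawal-threshold
  (PWT) estimation, plus plate-test latency censoring.

Each data-generating module is seeded and returns ground-truth labels, so
every analysis stage is testable against an independent oracle.

## Worked example

Contrast a control neuron with one whose Kv4 conductance is raised 1.5×
(the in-silico analogue of exposure to an A-current-enhancing glial
factor), then estimate a mechanical threshold:

```r
library(gliamod)
library(dplyr)

ctrl <- simulate_current_clamp(default_neuron_params("control"),
                               ramp_cc_protocol(), noise = noise_spec(seed = 1))
trt  <- simulate_current_clamp(default_neuron_params("high_kv4"),
                               ramp_cc_protocol(), noise = noise_spec(seed = 1))
bind_rows(control = excitability_profile(ctrl),
          high_kv4 = excitability_profile(trt), .id = "condition") %>%
  select(condition, ap_count, ap1_ap2_interval, rheobase, rheobase_norm,
         charge_transfer, rin_depol)
#> # A tibble: 2 × 7
#>   condition ap_count ap1_ap2_interval rheobase rheobase_norm charge_transfer rin_depol
#>   <chr>        <dbl>            <dbl>    <dbl>         <dbl>           <dbl>     <dbl>
#> 1 control         45             44.0     38.5          1.54            5.66     0.437
#> 2 high_kv4        42             48.0     43.8          1.75            7.26     0.389
```

Raising the A-type conductance lowers the AP count, lengthens the first
inter-spike interval, raises the rheobase (38.5 → 43.8 pA), the
per-capacitance rheobase (pA/pF) and the charge transferred before the
first spike (pC), and lowers the depolarized-state input resistance
(GΩ) — while resting potential, AP threshold, amplitude, duration and
fAHP barely move.

```r
f <- von_frey_filaments()
sess <- simulate_updown_session(true_threshold_g = 0.4, slope = 10,
                                filaments = f, seed = 7)
pwt_updown(sess, f)
#> # A tibble: 1 × 5
#>   pwt_g      k final_force_g n_trials boundary
#>   <dbl>  <dbl>         <dbl>    <int> <chr>
#> 1 0.366 -0.146           0.4        6 none
```

A six-trial staircase around the true 0.4 g threshold yields a 50% PWT
estimate of 0.37 g.

Every result type has a plot helper: `autoplot()` on recordings, I–V
curves, candidate rankings and up-down sessions.

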