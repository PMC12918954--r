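---
title: "Models and methods behind gliamod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gliamod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gliamod` models a specific biological circuit: satellite glial cells of
the dorsal root ganglion secrete extracellular-matrix proteins, some of
which enhance the A-type potassium conductance of the sensory neurons
they envelop, thereby reducing neuronal excitability and shifting pain
thresholds. The package provides the simulation and analysis machinery
for each stage of that chain — electrophysiology, proteomics,
transcriptomic integration, and behaviour — with synthetic data
generators that carry ground-truth labels so every estimator can be
audited. This vignette records the models, the conventions, and the
reasoning behind the design decisions.

## The neuron model

The simulator is a single-compartment conductance model of a
small/medium DRG neuron:

$$C_m \frac{dV}{dt} = I_{inj} - g_{Na} m^3 h (V - E_{Na})
  - g_{Kdr} n^4 (V - E_K) - g_A a^3 b (V - E_K) - g_{leak}(V - E_{leak})$$

Each gate follows first-order kinetics
$\dot{x} = (x_\infty(V) - x)/\tau_x(V)$ with a Boltzmann steady state
$x_\infty(V) = 1/(1+\exp(-(V-V_h)/k))$ (negative $k$ for inactivation
gates) and a bell-shaped time constant
$\tau(V) = \tau_b + \tau_a \exp(-((V-V_\tau)/\sigma)^2)$.

The A-current uses the Connor–Stevens gate structure
($a^3 b$): a well-characterised phenomenology whose steady-state
inactivation reproduces the prepulse logic that defines I_A
experimentally. With the default kinetics, the inactivation gate is
99.7% available at −100 mV and 1.5% available at −40 mV, so the
−100/−40 mV prepulse subtraction is meaningful by construction.
Temperature dependence (near-physiological recording temperature) is
folded into the rate constants rather than modelled explicitly.

**Parameter choice.** The experimental system gives phenomenological
constraints, not equations, so the preset was tuned once against its
stated post-conditions and then frozen: capacitance 25 pF (small/medium
soma, within the 15–40 pF range), resting potential between −65 and
−50 mV, a train of ≥ 3 APs under the 0.15 pA/ms ramp, passive input
resistance 0.5 GΩ ($g_{leak} = 2$ nS), and a depolarized-state input
resistance below the hyperpolarized-state one (the A-current window
around −50…−40 mV provides the extra slope conductance). Two further
constraints shaped the potassium kinetics: the delayed rectifier's
activation midpoint sits at −15 mV so that its steady activation at a
−40 mV prepulse is small (otherwise the prepulse-subtraction estimate
of I_A inherits a Kdr-onset transient), and the A-current inactivation
slope (6 mV) keeps the −40 mV prepulse family below 5% of the
hyperpolarized-prepulse peak. The `high_kv4` preset scales only $g_A$
(×1.5); `no_kv4` sets it to zero (a full Kv4 block, as with a selective
Kv4.2/Kv4.3 blocker). Whether an A-current-enhancing factor acts on
conductance density or on gating kinetics is an open biological
question; the conductance-scaling model is one consistent choice and is
flagged as an assumption.

**Integration.** Fixed-step explicit RK4. A fixed step was chosen over
an adaptive solver because recordings are sampled on a fixed grid and
bit-reproducibility matters for testing. The default step is
$dt = 0.005$ ms: with a ~40-spike train, accumulated spike-timing
error at coarser steps (e.g. 0.025 ms) moves late-train samples by
several mV relative to a half-step reference, while at 0.005 ms the
pointwise difference between $dt$ and $dt/2$ stays below 0.5 mV for
every preset and protocol — the convergence criterion the test suite
enforces. Command waveforms are defined as functions of absolute time
and sampled at $t = k\,dt$, so refining the step does not change the
stimulus. The integrator signals an error on any non-finite state
(unstable parameters or too coarse a step) rather than returning
garbage. Voltage clamp is ideal: the membrane follows the command
exactly and only the gate ODEs are integrated. Series-resistance
artifacts are deliberately out of scope — compensation is hardware-side
in the experiment and simulating it adds nothing testable.

**Noise.** Additive Gaussian noise on the recorded channel only
(defaults 2 pA / 0.2 mV), applied after deterministic integration under
a user-supplied seed; identical seeds give bit-identical recordings.
Five trials per cell is the default, matching common practice of
averaging repeated trials.

## Current-clamp feature extraction

All conventions follow the standard patch-clamp definitions:

- **AP threshold**: the voltage where dV/dt first reaches 5 mV/ms on
  the rise to the peak. dV/dt is computed by central differences on a
  Savitzky–Golay-smoothed trace (window 0.5 ms, order 2, configurable;
  0 disables smoothing) because the 5 mV/ms criterion is noise-sensitive.
  Crossing times are linearly interpolated between samples; peaks are
  refined by parabolic interpolation.
- **AP acceptance** (the experimental literature leaves this implicit):
  a local maximum above −10 mV, preceded within 10 ms by a 5 mV/ms
  crossing, with ≥ 2 ms refractory separation. All configurable.
- **Amplitude** = peak − threshold voltage; **duration** = width at the
  half-amplitude level; **fAHP** = threshold voltage minus the minimum
  within 5 ms after the peak (window anchored at the peak); only the
  first AP of a train is analysed for waveform parameters, to avoid
  cumulative channel inactivation.
- **Rheobase** = injected current at the first-AP threshold minus the
  injected current at the last preceding upward crossing of the resting
  potential; **charge transfer** = trapezoidal integral of the command
  between those two time points (reported in pC); **normalized
  rheobase** = rheobase / capacitance. An alternative reading of the
  rheobase baseline (zero current rather than the RMP crossing) exists;
  the RMP-crossing convention was chosen because it matches the stated
  definition of the charge-transfer interval, and it is recorded here
  as a convention rather than a derived fact.
- **Input resistance** is the OLS slope of voltage against current over
  samples whose voltage lies 2–12 mV below (hyperpolarized state) or
  5–15 mV above (depolarized state) the resting potential, restricted
  to the stimulated rising phase — from the voltage minimum after the
  hyperpolarizing onset to the first-AP threshold. Restricting to the
  rising phase matters: the onset-step RC transient and the
  post-stimulus decay pass through the same voltage windows with a
  different V–I relation and would bias the fit. The default ramp onset
  is −40 pA, deep enough that the onset transient has settled before
  the voltage re-enters the hyperpolarized fitting window. No
  capacitive correction is applied (the ramp is slow); the residual
  bias is bounded by the passive-recovery test (both states within 5%
  of $1/g_{leak}$).
- **Trial averaging**: every scalar feature is computed per trial and
  arithmetically averaged; trials on which a feature is undefined (no
  AP, say) are excluded from that feature's mean, and `ap_count`
  averages as a real number.

## Voltage-clamp analysis

- **P/5 leak subtraction** uses five same-polarity subpulses of 1/5
  amplitude from the prepulse level. Correction operates on
  baseline-subtracted excursions (each sweep's pre-step holding current
  removed), which is what makes a purely ohmic response cancel exactly;
  whether the hardware runs the subpulses before or after the main
  pulse does not enter the arithmetic.
- **I_A isolation**: pointwise subtraction of the depolarized-prepulse
  family (I_K) from the hyperpolarized-prepulse family (I_Total) at
  matching test potentials. The operation refuses swapped prepulse
  labels. Residual error comes from the small Kdr-onset transient and
  the 1.5% un-inactivated A-current; with the default kinetics the
  isolated peak stays within 5% of a ground-truth A-current-only
  simulation.
- **Step I–V**: per test potential, the holding baseline (mean of the
  50 ms before the step) is subtracted and the pulse is summarised as
  its maximum (`peak`, the right choice for transient currents — used
  for I_Total and I_A) or the mean over the last 50 ms (`sustained`,
  for the delayed rectifier); the experimental figures do not state
  which statistic they plot, so both are provided and the defaults are
  recorded as a package convention. Densities are per-capacitance
  (pA/pF).
- **Ramp I–V**: trials averaged pointwise first, then samples assigned
  to half-open 0.1-mV bins of the *command* voltage over the ramp span
  (1200 bins for −100…+20 mV) and averaged within bins — the
  quasi-steady-state approximation. Empty interior bins (sampling too
  coarse) and non-monotone commands are errors, not silent gaps.
- **Blocker-sensitive component**: binwise before-minus-during
  difference of ramp I–V curves; exactly linear, so scaling the blocked
  conductance scales the difference identically.
- **I_A fraction**: $\Delta I_A(v)/\Delta I_{Total}(v)$ at a probe
  potential (default −10 mV, near threshold). When a contrast changes
  only $g_A$, this fraction is ~1 by construction; sub-unity fractions
  arise when other conductances move too, as in biological recordings.

## Secretome screen

The generator emulates a conditioned-media (CM) / cell-pellet /
media-control MS experiment on the log2 scale: log-normal baseline
abundances (mean 20, SD 2 in log2 intensity units), replicate noise SD
0.5, a genuinely secreted subset elevated in CM by 3 log2 units and
absent (or present at a configurable residual rate) in the media
control. The default scale — 740 proteins, 73 secreted, 3 replicates —
mirrors the size of a typical SGC secretome screen. It does **not**
emulate peptide-level inference, intensity-dependent missingness, or
correlated contamination, so passing recovery tests demonstrate
correctness of the filtering logic, not robustness to every MS
pathology.

Filtering conventions, each configurable: Welch's t-test on
log2(intensity + 1) (the underlying experimental report does not state
its test; Welch on logs is the simplest defensible default), fold
change of raw group means with pseudo-count 1, and a two-part
negative-control rule (detection count ≤ 0 control replicates and
control/CM mean ratio ≤ 0.1). The fold-change comparison is inclusive
(≥ 2), so a protein sitting exactly at 2-fold passes; the boundary
behaviour is documented because prose criteria ("fold-change > 2") are
ambiguous at the boundary. With no between-group variance the test
returns p = 1 and the protein fails. Relaxing any threshold provably
yields a superset of passing proteins.

Enrichment is the hypergeometric upper tail against a user-supplied
annotation (the package ships no ontology), BH-adjusted across the
tested terms; the default reporting cutoff FDR < 0.5 is deliberately
permissive, as exploratory secretome annotation tends to be.
Matrisome classification is an exact case-insensitive symbol lookup
against a user-supplied six-category map, with `non-matrisome` for
unmapped genes.

## Cell-type integration

The expression generator plants class markers (elevated 2³ in the home
class and suppressed 2³ elsewhere — cell-type markers are near-absent
outside their class) on negative-binomial counts, and draws bulk
replicates from one source class mixed with a contamination fraction
(default 10% fibroblast), emulating the cultured-glia vs atlas
comparison at toy scale.

- **Pseudobulk**: counts summed per class, CPM per class column
  (columns sum to 10⁶ exactly), log2(CPM + 0.5). The 0.5 prior is the
  common default.
- **TMM** is implemented in-package per the standard definition —
  reference sample by upper-quartile closeness to the mean
  upper-quartile, 30%/5% double trimming on M/A values,
  precision-weighted mean of M — and is cross-checked in the tests
  against the independent edgeR implementation rather than delegated to
  it, so the check remains two-route. Factors are normalised to
  geometric mean 1 exactly.
- **Shared HVGs**: "top n highly variable genes shared between
  platforms" admits several readings (rank-then-intersect,
  intersect-then-rank); the package ranks every shared gene by the
  minimum of its two within-platform variance ranks and takes the top
  n — symmetric, deterministic, and equivalent to "highly variable in
  either platform". Ties break by the other platform's rank, then by
  symbol.
- **Similarity**: Spearman correlation (ties mid-ranked) of the bulk
  log-CPM profile against each pseudobulk class over the gene list —
  invariant under monotone transforms of either profile.
- **Candidate ranking**: per gene, glial CPM, maximum non-glial CPM,
  and their ratio with a 0.01-CPM pseudocount floor on the denominator
  (so genes absent outside glia get a large finite ratio). Two rank
  columns (by expression, by specificity) are combined as their mean —
  "ranked by both" does not specify a combination rule, and the mean of
  ranks is the simplest symmetric choice; ties break by specificity,
  then symbol.
- **ΔCT**: relative expression $2^{-(Ct_{gene} - Ct_{housekeeping})}$
  per sample; fold change across two conditions as the ratio of
  condition means of relative expression.

## Up-down withdrawal threshold

Sessions walk the standard mouse filament set (0.02–1.4 g,
log-spaced) by the up-down rule — down after a withdrawal, up after
none — with responses drawn from a logistic psychometric in log10
force, and continue four trials past the first response reversal; a
session that pushes against a set boundary before any reversal stops
there. All-negative sessions report the ceiling force, all-positive the
floor force: the exact stopping and boundary conventions are not
standardised in the behavioural literature, so these defaults are
recorded as assumptions and kept configurable.

The 50% threshold is $10^{X_f + k\delta}$ with $X_f$ the final
filament's log10 force and $\delta$ the mean log10 spacing. The
coefficient $k$ is obtained by its defining construction — the
maximum-likelihood location of a normal psychometric with SD equal to
the step size, evaluated on a fine grid ($\delta/200$) over the whole
response sequence — rather than from a transcribed lookup table. The
historical k-tables were derived under exactly this model, so computing
the coefficient removes a transcription risk while keeping the
estimator's definition; the tests cross-check it by median recovery of
known thresholds (within one filament step at 0.07, 0.16, 0.4 and
1.0 g over 200 seeded sessions) and by monotonicity in the true
threshold.

## Problem sizes and runtime choices

The test suite and the acceptance script run the full current-clamp
protocol at the 0.005-ms production step with a 0.001-ms oracle
re-simulation, voltage-clamp families at 0.02 ms (gate kinetics are
smooth and converge far below the tolerances there), a 740-protein
screen, 600-gene/140-cell atlas replicates over 20 seeds, and 200
up-down sessions — sizes chosen so each stage still exercises the full
pipeline while the whole audit completes on a single CPU in minutes.

## Known limitations

- One compartment, deterministic channels: no morphology, no channel
  noise, no slow adaptation currents beyond the A-current.
- Ideal clamp: no series-resistance or space-clamp error, no capacitive
  transients unless enabled.
- The A-current enhancement is modelled purely as a conductance-density
  change; kinetic modulation would produce different waveform
  signatures.
- The omics generators are deliberately simple (log-normal/NB with
  planted effects); they validate estimator logic, not robustness to
  batch structure, dropout, or compositional artifacts.
- The behavioural responder is stationary; real animals habituate and
  sensitise.
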