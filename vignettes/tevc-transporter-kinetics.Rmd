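---
title: "Methods: simulating and analysing TEVC recordings of electrogenic peptide transporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing TEVC recordings of electrogenic peptide transporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tevckit)
```

# Scope

`tevckit` re-implements, as tested and reusable code, the quantitative
analysis chain used to characterise proton-coupled peptide transporters
(PepT1-type, SLC15 family) expressed in *Xenopus laevis* oocytes under
two-electrode voltage clamp (TEVC), together with the comparative-CT qPCR
pipeline used for developmental expression profiling. Because raw
recordings of this kind are generally unavailable, the package includes a
first-class synthetic-data generator; all quantitative validation is
parameter *recovery*: simulate under published parameter values, run the
full analysis chain, and compare the estimates with the generating truth.

# The two-state charge-movement model

## Equilibrium

A charged element of the empty transporter redistributes between two
positions when the membrane potential changes. Its equilibrium follows a
Boltzmann function

$$Q(V) = \frac{Q_{\max}}{1 + \exp\!\big[-(V - V_{0.5})/\sigma\big]},
\qquad \sigma = \frac{kT}{q\,\delta},$$

where $Q_{\max}$ (nC) is the maximal moveable charge, $V_{0.5}$ (mV) the
midpoint, and $\sigma$ (mV) the slope factor; $\delta$ is the fraction of
the membrane electric field the charge traverses
(`field_fraction()`). Temperature defaults to 295.15 K (22 °C, typical
oocyte recording-room conditions); the source experiments do not state it,
so it is configurable via `physical_constants()`.

## Kinetics: the chosen functional form

Published work in this area gives the two-state reaction scheme and states
that the unidirectional rate constants are derived from the Q/V and
$\tau$/V relations, without printing the rate law. We adopt the symmetric
Eyring split — half the electrical distance on each rate:

$$k_\text{out} = \frac{e^{+x/2}}{2\tau_\text{peak}},\quad
  k_\text{in} = \frac{e^{-x/2}}{2\tau_\text{peak}},\quad
  x = \frac{V - V_{0.5}}{\sigma}.$$

This choice has three virtues: it reproduces the Boltzmann equilibrium
exactly ($k_\text{out}/(k_\text{out}+k_\text{in}) = Q(V)/Q_{\max}$), it
yields a closed-form bell for the relaxation time,
$\tau(V) = \tau_\text{peak}/\cosh(x/2)$, peaking at $V_{0.5}$ — the shape
observed experimentally — and the closed forms serve as independent oracles
for every downstream estimator. An asymmetric split would skew the
$\tau$/V bell; nothing in the data the presets encode constrains that
asymmetry, so the symmetric form is the minimal choice.

$\tau_\text{peak}$ deserves emphasis: the source tables print no $\tau$
values (the $\tau$/V relation appears only as a figure), so the preset
default of 8 ms is a package choice within the experimentally typical few-
to-ten-milliseconds range for PepT1-type transporters. Recovery tests
check *consistency* of the chain, not this number.

# The synthetic TEVC recording

`simulate_sweep()` renders, per voltage step,

$$I(t) = g_\text{leak}\,(V(t) - E_\text{leak}) + I_\text{cap}(t) +
  I_\text{pss}(t) + I_\text{tr}(V(t), S) + \varepsilon(t),$$

- **Leak**: ohmic, `g_leak` (µS) against reversal `E_leak` (mV). Defaults
  1 µS / −20 mV, plausible for healthy oocytes; unconstrained by any
  published number.
- **Capacitive transient**: on each transition of size $\Delta V$,
  $I_\text{cap} = C_m \Delta V/\tau_\text{cap}\,
  e^{-(t-t_0)/\tau_\text{cap}}$. Defaults $C_m$ = 220 nF,
  $\tau_\text{cap}$ = 0.8 ms. A single exponential is deliberate: together
  with the single-exponential transporter transient it makes the analysis
  module's double-exponential model *exactly correct* on synthetic data,
  so fitter defects cannot hide behind model mismatch.
- **Pre-steady-state transient**:
  $I_\text{pss} = \Delta Q/\tau(V_\text{new})\,e^{-(t-t_0)/\tau(V_\text{new})}$
  with $\Delta Q = Q(V_\text{new}) - Q(V_\text{prev})$; its integral is the
  Boltzmann charge increment by construction, and its polarity follows the
  sign of $\Delta Q$ (depolarising and hyperpolarising steps give opposite
  transients, off transients mirror on transients).
- **Transport current**: the scenario's Michaelis current at the local
  voltage (below). `S = 0` reproduces the substrate-free sweep.
- **Noise**: additive Gaussian, seeded. The helper `pss_peak_current()`
  converts "1% peak noise" into nA.

Units compose without hidden factors: nC/ms = µA (hence the single 1000
in the pss term), nF·mV/ms = nA, µS·mV = nA.

The default protocol holds at −60 mV and steps −140 to +20 mV in 20 mV
increments (700 ms pulses, 1 kHz sampling, 100/300 ms holding segments
around the pulse — the holding-segment lengths are package defaults).
Note that this stated range and increment enumerate **nine** pulses even
though the protocol is conventionally described as ten; `build_protocol()`
follows the arithmetic, and all fits are comfortable with nine voltages.

At the default 1 kHz, $\tau_\text{cap}$ = 0.8 ms is below two sampling
intervals and `simulate_sweep()` warns that this component is unresolvable
— the warning is informative (matching the real situation, where the
capacitive spike is handled by the amplifier and by blanking), not an
error. Anti-alias filtering is not simulated.

## Transport scenarios

A `transport_scenario()` interpolates the voltage dependence of the
Michaelis parameters between two anchor potentials (−60 and −120 mV in
the presets, taken from the published kinetic tables):
$K_{0.5}(V) = K_\text{ref}e^{k_s (V - V_\text{ref})}$ (log-linear — the
minimal monotone form for an affinity) and $I_{\max}(V)$ linear. Both
reproduce the anchors exactly; between and slightly beyond them they are
smooth interpolations, not mechanistic claims. The preset
`zfPepT1b_pH7.6` anchors are encoded as inward (negative) currents.
The `sodium_free` flag is metadata only and never alters simulated
currents (the transport is sodium-independent); a dedicated test asserts
this.

## Oocyte-to-oocyte variability

`simulate_experiment()` draws one lognormal expression factor per oocyte
(median 1, CV configurable, default 0.2 — a typical batch spread) and
applies it to $Q_{\max}$ and $I_{\max}$ *jointly*, since both scale with
the number of transporters in the membrane. The acceptance-style recovery
runs use CV = 0 because their stated conditions list only measurement
noise.

`simulate_dose_points()` produces steady-state dose-response readings
directly (current × (1 + multiplicative Gaussian noise)), i.e. the data
as they stand *after* trace subtraction and window averaging. This is the
appropriate granularity for dose-response recovery tests; the sweep-level
route (simulate pairs, `subtract_traces()`, `steady_state_current()`) is
exercised separately and shown to be exact without noise.

## What the generator does not emulate

Clamp-amplifier artifacts, series-resistance error, Bessel filtering,
endogenous oocyte currents, proton-binding microscopics (pH enters only
through scenario anchors), and drift/rundown. A green recovery test
therefore establishes that the estimators are correct and unbiased for
data obeying the stated model at the stated noise — not that they are
robust to every pathology of real recordings.

# Trace analysis

**Subtraction.** Transport-associated current = with-substrate sweep −
substrate-free sweep, pointwise, after strict protocol/oocyte matching.
On synthetic data this cancels leak, capacitive and pre-steady-state
terms exactly.

**Steady-state window.** Mean of the last 100 ms of the pulse (default).
The averaging window is not specified in published methods; 100 ms sits
≥ 10 τ after the edge for all preset parameters, where the residual
transient contribution is below 0.01% of the peak (tested).

**Double-exponential isolation.** The transient fitter uses variable
projection: for fixed $(\tau_f, \tau_s)$ the baseline and amplitudes are
linear and solved exactly; the two log-time-constants are optimised by
Nelder-Mead from the fixed start (1, 10) ms with three fixed alternative
starts, keeping the best, then polished by L-BFGS-B. The fit is therefore
deterministic given the data. Numerical guards, all documented in the
code:

- log-taus are clamped to [dt/4, 1.5 × window span]: below the lower
  bound a component is invisible at the sampling rate; above the upper it
  degenerates into the baseline and its amplitude (hence its charge
  $A\tau$) diverges;
- components are labelled fast/slow purely by $\tau$ ordering; if the two
  taus differ by less than 2×, the fit is flagged `separable = FALSE`
  and downstream code must not trust the split. This matters in practice:
  the step *to* the holding potential is transient-free, and a
  two-exponential fit of pure noise returns a degenerate equal-tau pair
  with enormous cancelling amplitudes;
- the fit window starts one sample after the step edge (no settling blank
  is stated in published methods; configurable).

**Charge and the on/off convention.** The charge of the transporter
component is the analytic integral $A_\text{slow}\tau_\text{slow}$
(nA·ms = 10⁻³ nC); the fast component is discarded as capacitive. Q and
τ points are taken from the on transients except at the holding
potential, which has no on transient: τ(V_h) comes from the off
transient of the step with the largest (separable, converged) off
response, and the Q point at V_h from the charge-conservation sum
$Q_\text{on} + Q_\text{off}$ of that step — zero up to noise, expressed
in the same relative-to-holding reference as the other points. Charges
are *relative* (ΔQ from V_h); the Boltzmann offset $Q_0$ absorbs the
reference, which is also why normalised Q/V curves are reported.

# Parameter estimation

All fits are unweighted least squares (per the published methods;
per-point errors are unavailable) with fixed, deterministic starting
rules, via `nls(algorithm = "port")`:

- **Boltzmann**: start $Q_{\max}$ = data range, $V_{0.5}$ = mid-range
  voltage, $\sigma$ = span/6, $Q_0$ = minimum; $\sigma$ bounded in
  (0, 200] mV. Standard errors from the usual linearisation (NA on
  degenerate, e.g. noiseless, data).
- **Dose-response**: $I(S) = I_{\max}S/(S + K_{0.5})$; a `saturated` flag
  records whether the tested ladder reached the fitted $K_{0.5}$.
  Non-saturating (high-pH-style) data are reported with the flag unset
  and wide errors rather than refused.
- **Per-oocyte first, then aggregate**: each oocyte is fitted
  independently and summaries are means ± SEM across oocytes (each
  oocyte an independent observation), matching how the published tables
  were assembled. The summary efficiency is recomputed from the mean
  parameters; note that published efficiency columns derive from
  unrounded estimates, so recomputing them from rounded table entries
  differs in the last digits (e.g. 315.7 vs a printed 316.37).
- **Rate reconstruction**: $p_\text{out}(V)$ from the fitted Boltzmann,
  $k_\text{out} = p_\text{out}/\tau$, $k_\text{in} = (1-p_\text{out})/\tau$
  from the measured τ/V, so $k_\text{out} + k_\text{in} = 1/\tau$ holds
  by construction and the closed-form rates are recovered on synthetic
  data (the headline end-to-end oracle, asserted at 5% under 1% peak
  noise and at 2% noiseless).

# qPCR analytics

Relative expression uses the comparative-CT method:
$2^{-\Delta CT}$ with $\Delta CT = CT_\text{target} - CT_\text{reference}$,
averaged over technical rounds within each biological replicate, then
over replicates — a fixed, tested aggregation contract. Averaging is
arithmetic on the $2^{-\Delta CT}$ scale to match the stated published
procedure; a `geometric = TRUE` option (equivalent to averaging ΔCT)
is provided for users who prefer the log-scale convention, with the
usual caveat that the two differ under noise (lognormal mean bias).
Fold-changes divide by the control stage's mean, so the control is
exactly 1; stages below control are *stored* as ratios in (0, 1) —
`format_fold_change()` reproduces the signed display convention
("−0.61" for a 0.61 ratio) some reports use, but no stored value ever
carries that sign. Statistical group comparison (ANOVA + post hoc) is
delegated to standard R and not re-implemented here.

The CT generator writes
$CT_\text{target} = CT_\text{ref} - \log_2(\text{level}) + \varepsilon$,
$\varepsilon \sim N(0, \text{ct\_noise\_sd})$, with the reference CT drawn
once per (stage, replicate, round) around a base cycle — reference
variation cancels in ΔCT exactly, as on a real plate where target and
reference share the run. With zero noise the pipeline inverts the
generator exactly (tested).

The developmental scenario encodes the published 1–7 dpf course: pept1a
fold-changes (1, ~1, 0.61, 2.00, 2.66, 6.73, 1.81) — 2 dpf is not
printed and is set to 1 — and pept1b anchors (~1.5 × 10³ at 2 dpf,
~8.8 × 10³ at 4 dpf, ~5.3 × 10⁵ at 7 dpf) with unpublished stages
log-interpolated. Absolute $2^{-\Delta CT}$ baselines (0.02 for pept1a,
2 × 10⁻⁶ for pept1b — "very faint") are package choices; fold-changes
and the paralogue ratio are invariant to them, and with these values the
pept1a/pept1b ratio crosses 1 between 4 and 5 dpf as reported.

Primer efficiency comes from the standard curve: OLS of CT against
log₁₀(dilution); the slope $m$ obeys $m = -(1/\log_{10} E)$, inverted as
$E = 10^{-1/m}$ (−3.32 cycles per tenfold dilution ⇔ E = 2).
Efficiency-corrected ΔΔCT (Pfaffl-style) quantification is out of scope.

# Stochastic acceptance checks and seeds

All generators are deterministic under a seed (bit-identical output,
tested). Recovery criteria are asserted at fixed seeds; a fixed seed
makes a stochastic check reproducible but does not remove its sampling
distribution — a prescribed seed can land in the tail of an otherwise
unbiased estimator. The test suite runs each criterion exactly as
stated and reports the outcome as is; the qPCR fold-change band at its
prescribed seed is one such tail draw (the pipeline is unbiased, as the
200-replicate bias test in the same suite shows). Tolerances were fixed
before measurement and are never widened to convert a red into a green.

# Known limitations

- The two-state model is a deliberate floor: multi-state charge
  movements, proton-binding microscopics and structure-based
  interpretation are out of scope.
- Scenario voltage dependences are two-anchor interpolations; using them
  far outside −140…−40 mV extrapolates.
- The double-exponential fitter assumes at most two resolvable
  components; real recordings with slow drift need detrending first.
- CSV/JSON is the only IO dialect; proprietary acquisition formats
  (ABF/ATF) are not read.
- At the default 1 kHz sampling the capacitive time constant is
  under-resolved (by design, matching the published filter settings);
  fast-component parameters are therefore noisy and must only ever be
  discarded, never interpreted.
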