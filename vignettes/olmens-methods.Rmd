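---
title: "Methods: desk-scale ensemble modeling of O-LM interneurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale ensemble modeling of O-LM interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modeling and numerical choices behind `olmens`:
the membrane model and its assumptions, the synthetic experimental cohort
and what it does and does not emulate, the distance/ranking machinery, the
cutoff and co-regulation detectors, and the problem sizes the package uses
at desk scale.

## The membrane model

Each model variant is a conductance-based multi-compartment cell. Per
compartment the membrane equation is

C_m dV/dt = −I_ionic − I_L − I_KL + I_axial + I_inj,

with the ionic current the sum of nine voltage-gated conductances known in
O-LM cells: transient sodium (somatic `Na_s` and dendritic/axonal `Na_d`),
fast and slow delayed rectifiers (`KDRf`, `KDRs`), A-type potassium (`A`),
the hyperpolarization-activated mixed cation current (`h`), L- and T-type
calcium (`CaL`, `CaT`), a calcium-activated potassium current (`AHP`) and
the M-current (`M`). Reversal potentials are fixed at E_Na = 50 mV,
E_K = −95 mV, E_h = −32.9 mV; calcium currents use a fixed E_Ca = +120 mV
(a simple ohmic convention rather than GHK). The potassium leak `gKL` from
the fitted passive sets is retained even though it is numerically tiny.

Gating kinetics are *not* part of the grid design and are therefore a
package default that can be overridden per channel
(`default_channel_set(overrides = ...)`): every voltage gate is a Boltzmann
steady state with a bell-shaped (or constant) voltage-dependent time
constant, and the AHP gate is a Hill function of a per-compartment calcium
pool (dCa/dt = −φ·I_Ca − (Ca − Ca_rest)/τ_Ca; shell depth 0.1 µm,
τ_Ca = 30 ms, Ca_rest = 50 nM). The default parameter set was assembled in
the style of published O-LM models and then adjusted so that the mid-grid
reference model reproduces the qualitative fingerprint of the cell type:
rest near −74 mV with a small holding current, tonic regular firing with a
long-lasting afterhyperpolarization under +90 pA, a slow depolarizing sag
under −90 pA, and depolarization block / failure-to-fire for strongly
unbalanced Na-vs-KDR combinations. The defaults are a *model*, not a fit
to any particular recording; all conclusions the package supports are
relative statements about the model database.

Two kinetic choices deserve emphasis:

* The h-current activates steeply below rest (half-activation −90 mV,
  slope 5 mV) with a slow, voltage-dependent time constant (60–700 ms).
  This gives a wide dynamic range between the holding potential and the
  hyperpolarized trough, so that sag amplitude grows with g_h at grid
  densities and saturates at a ceiling (≈13–14 mV on the surrogate) —
  beyond the saturation point additional h conductance collapses the
  input resistance faster than it deepens the rebound, and sag shrinks
  again. The non-monotonicity is a real feature of the mechanism, and
  the cohort calibration is written to respect it (below).
* The `CaL` current is high-voltage-activated (half-activation −10 mV);
  with a lower threshold the dendrites produce calcium plateau potentials
  that masquerade as spikes.

## Morphology and discretization

The original reconstructed morphologies are not available, so the package
builds a surrogate: a soma cylinder plus two symmetric dendritic trunks
(each bifurcating once) and a short axon, with the dendritic path length
solved by a 1-D search so that the passive somatic input resistance matches
a target (474 MΩ for passive set 1, 530 MΩ for set 2, within 5%). The
surrogate preserves the soma/dendrite/axon region semantics that the grid
design needs (which channels live where, somatic vs somatodendritic I_h)
and the passive load of a real cell; it does not reproduce the detailed
electrotonic structure of any reconstruction, so absolute dendritic
attenuation values should not be over-interpreted.

Compartment counts follow the λ₁₀₀ rule: each section is split into the
smallest odd number of segments no longer than `lambda_fraction` × λ₁₀₀,
λ₁₀₀ = ½·√(d/(π·f·R_a·C_m)) at f = 100 Hz. The package default is
`lambda_fraction = 0.1` (≈140 compartments on the surrogate); ensemble
presets use 0.35–0.5 (30–45 compartments), a deliberate resolution/cost
trade-off for database runs whose effect is shared by every model in the
ranking.

Integration is Crank–Nicolson on the cable and membrane terms with
staggered exponential gate updates and a Hines (tree-ordered) direct
solve; default dt = 0.025 ms (0.05 ms in the ensemble presets), outputs
sampled every 0.1 ms. An ideal somatic voltage clamp is a stiff series
conductance (default 10 µS, i.e. 0.1 MΩ access resistance — stiff enough
to hold even high-conductance variants); the clamp current is recorded.
Divergence (|V| > 200 mV at the soma) raises an error naming dt.

## Protocols and bias fitting

The experimental protocol being emulated holds the soma near −74 mV with
a small bias current, then applies ±90 pA for 1 s. `fit_bias_current`
reads the required bias directly from the steady-state clamp current of a
voltage clamp at the target, then verifies it in current clamp (settling
criterion |dV/dt| < 0.01 mV/ms over the last 100 ms, tolerance 0.5 mV,
bisection refinement if needed). Rejections mirror the two experimental
failure modes: a model that needs more positive bias than the admissible
window supplies is rejected as "bias window"; a model that needs more
negative bias than the floor *and* still fires when held at the floor is a
"premature firer". The window default, [−28, +12] pA, spans the
experimental holding currents (−8.0 ± 4.0 pA) at ±5 SD; the original
bound is unquantified, so the window is configurable.

The mixed VC/IC protocol (`run_vcic_protocol`) clamps the soma at −74 mV
while a tonic hyperpolarizing current (default −5 nA) enters a proximal
dendrite 30 µm from the soma, recording the soma and ≥3 positions along
the injected branch. With somatodendritic I_h at the top grid density the
dendritic traces show a trough-then-rebound sag that grows with distance;
with somatic-only I_h, or g_h = 0, the dendritic approach to steady state
is monotonic. This qualitative contrast is asserted in the acceptance
suite.

## The measure registry

Measures are named Period + Quantity (+ Statistic): `Ini` before the
step, `Pulse` during, `Recov` after; per-spike quantities carry `Mean` or
`Mode` suffixes. The published registry sizes are 11 hyperpolarizing and
92 depolarizing measures, but not the full list; the package therefore
composes its registry to those cardinalities: 11 subthreshold measures for
the −90 pA trace (period means/extrema, trough, in-step steady state, sag
amplitude `PulsePotSag` = V_ss − V_min with V_ss the mean of the last
100 ms of the step, and the sag time constant), and for the +90 pA trace
8 scalar counts/timings plus 14 per-spike shape quantities × 3 periods ×
{Mean, Mode} = 92. Undefined entries (spike statistics of a spikeless
period, sag τ of a monotonic trace) are invalid (`NA`), never zero-filled.
The distance engine takes any registry; the default is a structural
emulation, so per-measure values are not comparable to any published
table, only the pipeline's behaviour on them is.

The sag time constant is fitted as V(t) = V_ss − A·e^(−(t−t_trough)/τ)
from the trough to the end of the step by separable least squares (linear
solve for V_ss, A at each candidate τ; golden-section search on τ). A
trough in the last 5% of the step or a rebound under 0.5 mV is a "no sag"
verdict, distinct from a fit failure; fits pinned at the τ search bound
are rejected as failures.

## Distance, ranking, cutoffs

The distance between a model vector x and an experimental trace vector y
is the root-*mean*-square z-score over measures valid in both,
σ taken from the experimental cohort (sample SD per measure; SDs below
10⁻⁶·|mean| + 10⁻¹² are floored and flagged). Root-mean rather than
root-sum is a deliberate choice: vectors with different numbers of valid
measures stay comparable, and for complete vectors the two differ by a
constant factor that cannot change any ranking. d_x averages d(x,y) over
all experimental traces; ranking is ascending with ties broken by model
id, so it is stable and permutation-invariant.

The general cutoff automates what was originally a visual judgment on the
derivative of d_x vs rank: first differences are smoothed over a window of
1% of the database, the plateau slope is the median difference over the
middle 50% of ranks, and the cutoff is the first rank after entering the
plateau at which the smoothed difference exceeds 3× the plateau slope for
at least one full window. Both knobs (sensitivity, persistence) are
exposed, a manual override is honoured, and the diagnostics (plateau
slope, threshold, window) are returned so a human can audit the choice.
A perfectly linear sequence returns a "no cutoff" verdict. The
failure-to-fire cutoff interprets "more than one or two spikes" as
spike_floor = 2 and returns the rank before the first failure. The sag-τ
cutoff compares against the [min, max] of the experimental τ set — the
range, not a quantile band, because the comparison the procedure emulates
was against the histogram's extent — and requires exits to persist for the
same 1% window.

## CBDR and co-regulation classification

The dimensional-stack image nests parameters alternately on the x and y
axes (highest order = slowest varying); non-members of the subset render
at a fixed background value; clutter is the sum of absolute differences
between adjacent pixels. `cbdr_order` searches orderings exhaustively up
to 6 parameters (greedy insertion beyond), visiting candidates in
lexicographic name order and keeping strict improvements, so ties resolve
deterministically. Note that with exactly two varied parameters the stack
image of (a, b) is the transpose of (b, a) and clutter cannot distinguish
them; sensitivity-based "heavier first" ordering is only meaningful with
three or more parameters.

The original work classified conductance histograms visually and declined
formal statistics; to make the categories assertable the package adds a
quantitative *ridge score*: the count-weighted correlation between the two
parameters' grid ranks over the retained subset. A pair is a
*co-regulation* when |score| ≥ 0.4 and the per-level conditional modes are
monotone; a *local preference* when a single cell holds ≥ 2× the uniform
share without the monotone-ridge structure; otherwise *no interaction*.
The score is rank-based, hence invariant to unit relabeling.
`coreg_screen` classifies all pairs among the top-5 stack parameters plus
the next parameter as a boundary control, sorted by |score|.

## The synthetic cohort

The generator emulates the statistical structure of the experimental
dataset: 10 cells, 56 total ±90 pA sweeps (5–6 per cell, both polarities),
holding currents drawn from N(−8.0, 4.0²) pA, per-cell log-normal jitter
(SD 0.2 in log space) on all maximal conductances, and additive Gaussian
measurement noise (0.3 mV default) per sweep. Calibration adjusts the
reference model's g_h so that the cohort's mean `PulsePotSag` hits
14.2 mV: a geometric walk brackets the target on the rising limb of the
sag-vs-g_h curve (deliberately avoiding the saturated regime), the leak
reversal is co-adjusted so the scaled reference settles at −74 mV under
the mean drawn bias (the counterpart of the experimenter's holding-current
adjustment), and a bounded refinement loop targets the noisy cohort
statistic itself. If the target exceeds the mechanism's ceiling the
nearest-achieved value is accepted when within 10%, otherwise generation
fails loudly with the achieved statistics.

What the cohort does *not* emulate: electrode/bridge artifacts, junction
potential drift, per-cell sweep-count structure of the real dataset, and
the full cell-to-cell dispersion of sag amplitude — near the calibrated
point the sag is insensitive to the conductance jitter, so the cohort's
sag SD (≈0.5–1 mV plus noise) under-disperses relative to the 3.1 mV
target. Passing tests therefore demonstrate that the pipeline recovers
structure planted in data with this statistical shape, not that the
defaults reproduce any laboratory recording.

## Problem sizes and budgets

The package's reference grid is enumerable in full (933,120 rows) but
simulating it is cluster-scale work by design. Desk-scale presets used in
tests and in `scripts/acceptance.R`: a 3-values × 7-conductances ensemble
(2,187 models, surrogate morphology, λ-fraction 0.5, dt 0.05 ms, ~30
compartments, 400/1000/400 ms protocol) which one CPU ranks in about ten
minutes; a 10-cell/56-sweep cohort (~1–2 minutes including calibration);
and property-style experiments (planted distance breakpoints over 50
seeds, planted sag-τ recovery, VC/IC contrasts) that run in seconds to a
minute each. These sizes are the package's definition of "desk scale";
all are configurable upward.

## Known limitations

* Gating kinetics are literature-style defaults, not refits; absolute
  measure values (firing rates, sag τ) are plausible rather than matched
  to data. Cross-model comparisons — the package's purpose — are
  unaffected by shared kinetic assumptions, but any absolute statement
  should be checked against real recordings.
* The surrogate morphology cannot reproduce reconstruction-specific
  results (compartment counts, per-branch attenuation, the empirical
  cutoff ranks or acceptance counts of any full-scale database run).
* Sag amplitudes saturate near 13–14 mV on the surrogate; the cohort
  calibration lands at the target mean but compresses cell-to-cell sag
  variability (above).
* The calcium pool is a single-shell, single-pool approximation with an
  ohmic driving force; AHP kinetics inherit its simplicity.
* The ranking treats all 56 experimental traces independently in the
  d_x average (no per-cell pre-averaging); with per-cell sweep counts
  balanced across polarities this weighting is close to uniform over
  cells, and the choice is recorded here rather than configurable.
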