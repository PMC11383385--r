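---
title: "Intrinsic electrophysiology of thalamocortical neurons: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic electrophysiology: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdephys)
```

## Scope

`mdephys` analyses episodic current-clamp recordings of thalamic relay
neurons: 1,000-ms square current steps delivered from a holding potential
of −65 ± 3 mV, digitized at 20 kHz. From such recordings it extracts the
standard intrinsic-property vector — resting membrane potential (RMP),
membrane time constant (τ), input resistance (R_N), HCN-mediated voltage
sag, afterhyperpolarization (AHP), per-mode rheobase, spike thresholds
and the accommodation index — classifies spikes into burst, tonic and
rebound firing modes, and compares groups of cells with nonparametric
estimation statistics. A single-compartment conductance-model simulator
generates synthetic recordings with known ground truth so that every
estimator can be validated end to end.

Units are fixed throughout: time in ms, voltage in mV, current in pA,
conductance in nS, capacitance in pF, resistance in MΩ (so
R[MΩ] = 1000/g[nS], and pA/pF = mV/ms). Membrane potentials are stored
as recorded, without liquid-junction-potential correction; a sidecar may
carry an informational `ljp_mv` field that no computation applies.

## Subthreshold estimators

**RMP** is the mean voltage over the first 100 ms of a zero-bias
recording — the value read off just after going whole-cell, before any
holding current is applied. Recordings held with a bias current are
flagged not-measurable rather than silently reported.

**Input resistance** is the ordinary least-squares slope of steady-state
voltage (mean of the last 100 ms of the step) against step amplitude
over the spike-free sweeps of the fine protocol (−60 to +60 pA in 5 pA
increments). Sweeps containing spikes during the step are excluded from
the fit but kept in the returned V–I curve. The steady-state window is
100 ms (configurable); the sag estimator uses its own, shorter window
(below). At least three spike-free sweeps are required.

**Membrane time constant** comes from the point-wise average of ten
−10 pA repetitions: the time for the voltage deflection to cover all but
1/e of its span, located by linear interpolation between samples. Two
segments are supported and never silently mixed. The default is the
*onset* charging phase. The offset relaxation — often preferred because
depolarizing artefacts are absent there — is *not* reliably spike-free
in these cells: their rebound-burst rheobase is about −10 pA, so the tau
protocol itself routinely triggers rebound spikes within the post-offset
window. Offset mode is still available; it truncates the analysed
segment at the first rebound spike and flags the estimate when the 1/e
level is not reached before that.

**Voltage sag** for a hyperpolarizing sweep is the minimum voltage
during the step minus the mean of the last 25 ms of the step, signed
negative when the cell sags. Because sag grows with hyperpolarization,
the normalized per-cell readout selects, from the coarse protocol (−250
to +350 pA in 25 pA increments), the sweep whose peak is nearest
−100 mV (nearest peak, no interpolation across sweeps, with a ±5 mV
acceptability flag). Comparisons between groups use the magnitude;
the sign convention is recorded so either rendering is available.

**AHP** is the minimum voltage in the window after the offset of a
depolarizing step, and the per-recording AHP is the minimum across all
depolarizing sweeps. The window defaults to 250 ms and is configurable
to 500 ms (both conventions appear in the literature for this
measurement). For drug washin comparisons, the post-drug value is read
at exactly the time point of the pre-drug minimum, so that a drug that
abolishes the AHP is not credited with a spurious minimum elsewhere.

## Spike detection, threshold and classification

Spikes are local maxima that overshoot 0 mV (the usual inclusion
criterion for healthy recordings) with at least 1 ms separation; the
higher peak wins a conflict. Spike time means peak time everywhere ISIs
are computed — peaks are unambiguous, and thresholds are reported
separately.

The spike threshold uses the third-derivative criterion: smooth with a
0.2 ms boxcar, form the centered five-point third difference scaled to
mV/ms³, and scan up to 3 ms back from the peak for the earliest
contiguous excursion above the cutoff (0.3 by default). The cutoff value
is dimensionless in the original description; this package fixes the
units to mV/ms³ and records both cutoff and smoothing in its outputs so
the choice is reproducible. When no crossing exists, a fallback
threshold at 5% of the peak dV/dt is returned and flagged.

Classification follows the interspike-interval rules for thalamic dual
firing modes. The ISI ratio of spike *k* is ISI_k / ISI_(k−1) (current
over previous), so a ratio ≥ 2 marks a sudden doubling of the interval —
the burst-to-tonic transition. On depolarizing sweeps with at most 15
spikes during the step: a spike belongs to the onset burst when it lies
within 500 ms of step onset, its ISI is under 4 ms and its ratio falls
in [0.50, 1.99]; the second spike of a train has only one interval and
is admitted on the ISI criterion alone (otherwise two-spike bursts would
be unclassifiable); the spike leading a qualifying burst is the burst's
first spike. The first spike with ratio ≥ 2 is the first tonic spike and
everything after it is tonic. Sweeps with more than 15 in-step spikes
are labeled "total" wholesale — burst and tonic cannot be reliably
separated there. On hyperpolarizing sweeps, spikes within 1 s after step
offset are rebound spikes. The rules operate on the in-step subsequence
of spikes; off-step spikes on depolarizing sweeps are "other". A
zero-amplitude sweep follows the depolarizing branch. An independently
written, literal transcription of these rules lives in the test suite
and the classifier is required to agree with it spike for spike on 1,000
random trains.

**Rheobase** per mode is the smallest depolarizing amplitude whose sweep
contains a tonic (or burst) spike, and for rebound the hyperpolarizing
amplitude of smallest magnitude whose sweep contains at least two
rebound spikes — single rebound spikes do not count as a burst. The
threshold voltage of the first spike of the defining class at rheobase
is reported alongside, and for rebound also the in-step steady-state
voltage of that sweep.

**Accommodation** is measured in the lowest-amplitude depolarizing sweep
with at least 12 tonic spikes: the least-squares slope of tonic ISIs
against interval number (ms per interval). Note the arithmetic corner
this rule creates: with 2–4 burst spikes at the start of a sweep, twelve
tonic spikes bring the total close to the 15-spike gate, so qualifying
sweeps are genuinely rare — in real data as well as in the simulator.
The pipeline falls back to the coarse protocol when no fine sweep
qualifies, and flags the feature when none exists.

## The synthetic neuron

The simulator is a single compartment,

$$C \frac{dV}{dt} = -g_L (V - E_L) - g_h m_h (V - E_h)
  - g_T m_\infty^2(V)\, h_T (V - E_T) - g_{DR}(V)(V-E_K)
  - g_{Kir}(V)(V-E_K) - w (V - E_w) + I_{spike} + I_{inj} + \xi,$$

integrated with forward Euler on V and exponential Euler on the gates at
dt = 0.025 ms, emitted at 20 kHz after 2× decimation. The ingredients:

- **HCN** (`g_h`): one first-order gate with sigmoidal steady state
  (V½ = −70 mV, slope 6 mV) and a bell-shaped, capped time constant.
  E_h = −35 mV.
- **T-type calcium** (`g_t`): instantaneous squared activation times a
  first-order inactivation gate whose time constant is slow near rest
  and fast (a few ms) at depolarized potentials. This is the minimal
  mechanism that yields low-threshold spikes: brief onset bursts from a
  −65 mV hold, and rebound bursts after release from hyperpolarization.
- **Spiking**: exponential spike initiation (threshold −39 mV,
  sharpness 1.2 mV) with reset and refractory period. Emitted spikes are
  stamped onto the trace with a +35 mV peak, satisfying the
  overshoot-0 mV detection criterion. A slow sodium-availability gate
  with a per-spike decrement produces depolarization block at strong
  drive; an instantaneous delayed-rectifier ceiling bounds the block
  plateau, and an inward-rectifier potassium conductance bounds deep
  hyperpolarization under the largest negative steps.
- **Adaptation** (`w`): a spike-triggered conductance with reversal
  −75 mV. Using a conductance rather than a current matters: it
  saturates the post-burst dip, which prevents a burst → deep AHP →
  T-channel re-deinactivation → rebound limit cycle that a
  current-based adaptation produces in this parameter regime.
- **Noise**: seeded white current noise (2 pA SD per integration step by
  default) for trace texture. Identical parameters and seed give
  bit-identical traces.

The holding bias is solved in closed form from the steady-state current
balance at the holding potential (the subthreshold I–V curve is
available analytically), not by bisection; the pre-step baseline
therefore sits exactly at the requested holding potential in the
noise-free limit. The leak reversal is likewise solved so that the
zero-bias resting potential equals a target (−61 mV for both presets),
which is what makes RMP a null contrast between populations by
construction.

### Presets and what they encode

Two presets emulate the medial and lateral thalamocortical phenotypes.
Their calibration targets are the published population medians — high
R_N (~790 MΩ), slow τ, small sag (~−4.6 mV at −100 mV) for the
MD-M-like cell versus low R_N (~440 MΩ), fast τ, large sag (~−7.7 mV)
and larger AHP for the MD-L-like cell — not channel-literature values.
Three deliberately asymmetric choices deserve explanation:

- **HCN conductance and kinetics.** The MD-L-like preset carries ~2.4×
  the HCN conductance (1.0 vs 0.42 nS), which produces its lower R_N,
  faster τ, deeper sag and deeper HCN-dependent AHP, and which full
  block (the ZD7288 emulation, g_h → 0) removes — raising R_N to the
  common leak-determined level, zeroing sag and depolarizing the AHP.
  The presets additionally differ in the *speed* of HCN activation at
  strongly hyperpolarized potentials (h_taumin 140 vs 50 ms). A single
  two-state HCN model cannot otherwise reproduce a large conductance
  difference at rest together with the modest printed sag values at
  −100 mV: sag at a −100 mV peak measures the activation still pending
  at the time of the peak, so the fast-activating variant shows
  relatively less sag per unit conductance. Kinetic differences of this
  kind are the natural correlate of differing channel-subunit
  composition between cell populations.
- **T-channel availability.** The presets differ by 1.5 mV in the
  T-inactivation midpoint. This encodes a reported observation that is
  otherwise impossible to capture: HCN block does *not* change the
  burst rheobase in either cell type, even though it equalizes R_N — so
  the burst-rheobase difference between the populations cannot be
  R_N-mediated and must be intrinsic to the burst generator itself.
- **Everything else is shared**, so spike thresholds, spikes per burst
  and accommodation carry no built-in group signal.

`make_population()` draws per-cell capacitance, leak, HCN and T
conductances lognormally around a preset (median-preserving, CV 0.2 by
default — a typical between-cell spread for intrinsic properties) and
jitters the resting-potential target by 1.5 mV SD identically in both
groups.

### What the generator does and does not emulate

The synthetic cells reproduce the phenomena the estimators target:
square-step charging, HCN sag and rebound depolarization, onset and
rebound bursts of 2–8 spikes with sub-4-ms ISIs, tonic firing with
accommodation, depolarization block at strong drive, and the ZD7288
battery (sag abolished, R_N raised, AHP depolarized, fewer rebound
spikes). They do not emulate: electrode artefacts and series-resistance
errors, channel stochasticity, dendritic filtering, synaptic
bombardment, or realistic recording noise (the default 2 pA current
noise yields ~0.02 mV voltage noise, far cleaner than a real patch
recording). Passing the end-to-end tests therefore shows that the
estimators recover known ground truth from idealized recordings of the
right shape — not that they are robust to every artefact of real data.

One consequence is visible in the population battery: all seven
significant group contrasts (R_N, τ, sag, AHP, three rheobases)
reproduce robustly at n = 20 per group, but some of the reference
*null* contrasts — especially per-cell spike counts — come out
statistically significant between the synthetic populations. The
rheobase separation that must exist also shifts firing onset, and with
near-noise-free traces even ~0.3-spike or ~0.5-mV systematic
differences become detectable at n = 20. Real measurement noise would
dilute these; we chose not to inflate the noise parameter to launder
them away.

## Statistics

Two-sample comparisons use the Mann–Whitney test with U = min(U_x, U_y)
computed from midranks: exact p (full permutation distribution) for
tie-free samples with n ≤ 16 total, otherwise the normal approximation
with tie and continuity corrections. Paired comparisons use the Wilcoxon
signed-rank test in the signed-sum convention (W negative when the
measure decreases), zero differences dropped, exact p for n ≤ 15.
Two-sided p-values everywhere.

Medians are reported with distribution-free CIs from binomial order
statistics (the smallest symmetric pair with ≥95% coverage; below n = 6
the range is returned with an under-coverage flag). The
estimation-statistics quantity is the bootstrap median difference:
percentile CIs over 5,000 seeded resamples, with the full bootstrap
distribution retained for plotting. Percentile rather than BCa was
chosen for exact reproducibility; order-statistic median CIs will not
match plotting-software CIs digit for digit and are not treated as
reference values.

The effect size for rank tests is η² = z²/(N−1), with the conventional
small/medium/large cutoffs at 0.01/0.06/0.14, and it is computed only
when p < 0.05 (the reporting convention of the source analyses). This
formula is an inference — the original reports name η² without defining
it — but it reproduces every printed value from the printed (U, n)
pairs to within 0.006, which is the basis for adopting it. Spearman
correlations use midrank-based ρ with exact enumeration below n = 10.
The sample-size calculation is the two-sided normal-approximation
two-sample formula, n = ⌈2σ²(z₁₋α/₂ + z_power)²/δ²⌉; an iterative
exact-t variant (which typically adds one cell) is available behind a
flag.

## Numerical choices and degenerate inputs

- Integrator dt = 0.025 ms; an instability guard aborts with the
  offending time and dt if V leaves [−250, +250] mV. The exponential
  spike current saturates at its trigger-level value so the
  depolarization-block plateau stays bounded.
- The V–I fit requires ≥3 spike-free sweeps; τ requires the 1/e level
  to be reached inside the analysed window; every not-measurable
  feature propagates `NA` plus a reason string, never a zero.
- Ties in rank tests switch the implementation to midranks and the
  corrected normal approximation; all-zero paired differences return
  p = 1 with a degenerate flag.
- Protocol validation is report-only: missing amplitudes, timing
  deviations and holding-band violations (−65 ± 3 mV) are listed, and a
  recording passes iff the report is empty.
- CSV round-trips write 17 significant digits, so write-then-read is
  the identity on doubles.

## Problem sizes used in the shipped checks

The test-suite simulations are sized to exercise every code path at
population scale while staying quick on a laptop: passive recovery uses
50 random cells on a 7-amplitude V–I series and 3 tau repetitions; the
classifier equivalence uses 1,000 random trains; the contrast battery
uses the full fine/coarse/tau protocol set for 20 cells per group on
three master seeds with 200–1,000 bootstrap resamples; the type-I-error
check uses 1,000 seeded trials. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from scratch at
the same sizes.

## Known limitations

- The conductance model is a stand-in calibrated to functional readouts
  (population medians and directions), not a biophysically fitted MD
  neuron; absolute conductances and kinetics are implementation choices
  and are labeled as such in the ground-truth output.
- Deep hyperpolarizing steps (−250 pA) reach more negative potentials
  than real cells, whose stronger inward rectification we only sketch
  with a small Kir conductance; only the −100 mV-peak sweep feeds the
  sag readout, so this does not touch the reported features.
- The third-derivative threshold is sensitive to the smoothing and
  cutoff conventions; both are configurable and recorded, but absolute
  threshold values should be compared only within a convention.
- Null contrasts involving spike counts are systematically violated
  between the synthetic populations (see above); treat the battery's
  null half as a property of the generator, not of the estimators.
- No ABF/NWB readers: the sweep-table CSV + JSON sidecar is the
  canonical format, and converters are expected to produce it.
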