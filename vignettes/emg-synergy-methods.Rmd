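---
title: "Methods: muscle-synergy extraction, model selection and similarity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle-synergy extraction, model selection and similarity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgsynergy)
```

This vignette is the package's own account of the science it implements: the
generative model and its assumptions, the preprocessing conventions, the
factorisation and its numerical choices, the three synergy-number criteria,
the cross-validation and similarity machinery, the biomechanical model, and —
because the package ships a synthetic-data module in place of recorded
gymnast EMG — a candid statement of what the generator does and does not
emulate.

## The muscle-synergy model

The working hypothesis of synergy analysis is that the nervous system
coordinates many muscles through a small number of modules: each module
(synergy) is a fixed non-negative weighting across muscles (a column of
`W`) recruited by a single non-negative time course (a row of `C`). For `p`
muscles observed over `n` time points the EMG envelope matrix `E` is
approximated by `W C`, with both factors found by minimising the Frobenius
norm of the residual under non-negativity. Non-negativity is not a numerical
convenience: EMG envelopes are amplitudes, and parts-based, additive
decompositions are what makes the factors physiologically interpretable.

The factorisation is computed with the classic two-sided multiplicative
updates. These have two properties the implementation relies on: they never
produce negative entries, and they never increase the cost (the test suite
asserts both per iteration). They also converge only to local optima, which
is why the extraction protocol restarts from 20 independent uniform-random
initialisations and keeps the lowest-cost solution.

Because `(W, C)` and `(W D, D^{-1} C)` are equivalent for any positive
diagonal `D`, the returned `W` always has unit-Euclidean-norm columns with
the inverse scale folded into `C`. Synergies are ordered by the peak time of
their cycle-averaged activation, which makes like-numbered synergies
comparable across runs without changing the fit.

## Envelope preprocessing

The chain is fixed: band-pass (20–450 Hz, 2nd-order Butterworth) →
full-wave rectification → low-pass envelope (9 Hz, 2nd-order Butterworth) →
cycle segmentation, time-normalisation to `T = 200` samples per cycle, and
per-muscle amplitude normalisation to the maximum over all retained cycles.

Two deliberate choices:

- **Both filters are zero-phase** (forward–backward), with the stated order
  interpreted as the order of the underlying one-pass design. The envelope
  filter is conventionally zero-lag; the band-pass is run the same way
  because a mixed-phase chain would distort envelope timing, and timing
  (lag, in % of cycle) is a first-class output of the analysis. Edge
  transients are bounded by odd-reflection padding of roughly three filter
  time constants before filtering.
- **Cycles are half-open intervals** `[start, next start)`, resampled by
  linear interpolation. This avoids duplicating the boundary sample shared
  by consecutive cycles, so a signal that is exactly `k` copies of a
  `T`-sample cycle reproduces its cycle matrix exactly. When a series of
  linked cycles is segmented with `drop_edges = TRUE`, the first and last
  cycles — transients of starting and stopping the movement — are discarded.

Amplitude normalisation is per muscle across all retained cycles of one set,
never across subjects or sets. The analysis therefore speaks only to the
*shape* of muscle activity, not its absolute level. One consequence worth
keeping in mind: dividing each muscle's row by its own maximum rescales the
rows of the effective mixing matrix, so the basis recoverable from a
normalised matrix is `D^{-1} W` (columns renormalised), not `W` itself. The
test suite compares recovered synergies against this rescaled truth.

## Choosing the number of synergies

Three criteria are applied to the VAF-versus-`s` curve (`s = 1 … p`, each
point its own multi-restart extraction):

1. **Threshold.** The smallest `s` with VAF > 0.90; if the curve never
   crosses the threshold, the smallest `s` for which one more synergy adds
   at most 5% of the current VAF. The 5% rule is read as a *relative*
   increment (`ΔVAF / VAF ≤ 0.05`); the absolute reading (`ΔVAF ≤ 0.05`) is
   available via `relative = FALSE` since the conventional phrasing is
   ambiguous.
2. **Best linear fit (BLF).** The smallest `s` such that a least-squares
   line through points `s … p` of the curve has residual mean square below
   `5 × 10⁻⁵` — the point where the curve has flattened into a line.
3. **Knee point (KP).** The curve is recomputed on surrogate data obtained
   by shuffling the entries of `E` uniformly over all cells (destroying all
   muscle and time structure while preserving the amplitude distribution).
   The chosen `s` is the first at which the original curve's slope falls
   below 75% of the surrogate curve's slope. Slope is the forward first
   difference; no smoothing is applied.

Restart stochasticity can make the empirical VAF curve locally non-monotone
by a fraction of a point; the package's invariant tests allow 0.5 points.

## Cross-validation with fixed factors

Robustness of the modular structure is probed by reconstructing one dataset
under factors fixed from another. With `W` fixed the objective is convex in
`C` and the single-sided multiplicative update `C ← C · (WᵀE) / (WᵀWC)`
converges reliably from one random initialisation; the fixed-`C` refit uses
the mirrored rule `W ← W · (ECᵀ) / (WCCᵀ)`, the symmetric counterpart under
transposition of the Frobenius objective. Within subjects this validates one
set of cycles against another; across a cohort of `n` subjects every ordered
(control, compared) pair is evaluated — `n (n − 1)` comparisons, 72 for nine
subjects. A fixed-factor refit can never beat the compared subject's own
free fit; the suite asserts this bound with a small restart tolerance.
Muscles with `VAF_muscle` below 0.75 are flagged as inadequately
reconstructed, the conventional adequacy threshold.

On synthetic cohorts that share synergy vectors but differ in activation
timing, fixing the vectors transfers much better than fixing the
coefficients — the directional property the acceptance suite checks. The
package makes no claim that this asymmetry holds for arbitrary real data;
it is a property of timing-shifted cohorts.

## Similarity statistics

Waveform similarity between subjects uses the Pearson correlation `r` at
zero lag and the circular cross-correlation: `r` evaluated at every circular
shift in `(−T/2, T/2]`, with `r_max` the maximum and the lag the maximising
shift in % of cycle (ties broken toward zero lag, then toward the positive
shift). `r_max` is invariant to rotations of either input; `r` is not.

Synergy vectors are matched across subjects by the one-to-one assignment
maximising summed column-wise correlation (exhaustive over `s!` permutations
for `s ≤ 7`, greedy beyond). A matched pair is declared similar when its `r`
reaches the analytic critical value `r* = t* / sqrt(t*² + df)` with
`df = p − 2` (0.71 for 12 muscles at `α = 0.01`, two-sided). Because
non-negative weight vectors correlate positively by chance, the analytic
cut-off is complemented by a permutation null: each subject's weights are
permuted independently within the vector, `r` is computed for every
unordered pair, and the pooled distribution's 99th percentile (linear
interpolation between order statistics) serves as the empirical chance
threshold. For generic 12-muscle weight profiles this percentile falls in
the neighbourhood of the analytic 0.71 — the package's default study
computes ≈ 0.68 — which is the consistency the decision rule relies on.
Permuting both members of each pair independently is the default; permuting
only one is available (`joint = FALSE`) since either convention appears in
practice.

## Biomechanics of the giant swing

The body is modelled as five planar segments (forearm, arm, trunk, thigh,
shank) hanging from the bar, with bilateral limb masses doubled and head,
hand and foot masses folded into the trunk and distal limb segments so the
mass fractions sum to one. The shipped anthropometric table follows the
usual adjusted cadaver-based values and is configuration, not hard-coded
truth. Per frame the package computes: angular position `θ` of the
bar-to-hip axis from the downward vertical (0° under the bar, increasing in
the rotation direction, auto-detected from net rotation); angular velocity
by central differences on unwrapped `θ`; interior shoulder and hip angles;
segment and whole-body centres of gravity; the moment of inertia about the
whole-body CG, `I_G = Σ [I_i + (M m_i) d_i²]` with
`I_i = (M m_i)(l_i r_i)²` (instantaneous marker-to-marker lengths); and the
mass-normalised mechanical energy
`E_Tot = Σ (½ (M m_i) v_i² + ½ I_i ω_i² + (M m_i) g h_i) / M`.

Heights are measured from bar level. Only energy *differences* are
meaningful: horizontal translations of the origin leave `E_Tot` unchanged
and vertical translations shift it linearly (both tested), so all
conservation checks use relative spreads, never absolute values. Segment
angular velocities use the same central-difference scheme as `ω_G`, applied
to each segment's unwrapped orientation angle. Profiles can be re-indexed
from time to body-position angle (0–360°) by monotone interpolation within
each rotation.

## The synthetic-data generator

The generator replaces recordings that were never deposited, so its design
deserves scrutiny.

**Synergy vectors.** Each synergy dominates a disjoint subset of muscles
(round-robin partition of a random muscle order), with strong weights
(0.5–1) inside the group, weak co-activations (0–0.3) outside it, a
`sparsity` fraction of the weak weights zeroed, and unit-norm columns. An
earlier, fully random sparse design was discarded during development: in a
minority of draws its columns became so correlated — especially after the
per-muscle amplitude normalisation rescales rows — that a rank-2 fit
explained over 90% of the variance, i.e. the generated data no longer had an
unambiguous dimensionality of three. The group structure mirrors how
extracted synergies actually look (distinct muscle groups with modest
spillover), guarantees every muscle participates somewhere, and keeps the
VAF curve's knee sharp. A draw is rejected and repeated if any column pair
correlates at 0.9 or above.

**Activations.** Each synergy is a circular Gaussian bump train: main peaks
evenly staggered across the cycle (SD 5% of the cycle), even-numbered
synergies carrying a secondary peak of 0.3 relative amplitude half a cycle
away — the uni/bimodal shapes typical of cyclic whole-body movement. Between
cycles, peak times jitter (Gaussian SD, default 2% of the cycle) and
amplitudes jitter multiplicatively (default SD 0.10), providing the
inter-cycle variability on which extraction relies. Defaults for jitter and
noise are package choices: the magnitude of inter-cycle variability in elite
performance is not well characterised, so they are set to values a movement
scientist would call plausible for a highly practised skill and are exposed
as parameters, not buried.

**Noise and normalisation.** `E = W C + ε` with `ε` Gaussian at a SD equal
to `noise_sd` (default 0.10) times the RMS of `W C`, clipped at zero
(envelopes are non-negative), then per-muscle normalised to maximum 1 — the
same convention the preprocessing chain produces. Cohorts share `W` (each
subject's copy optionally perturbed and renormalised) and share `C` up to a
subject-specific circular time shift, with independent noise per subject.

**What passing tests do and do not show.** The generator produces
low-rank-plus-noise data whose model class matches the extraction model
exactly. Success on it demonstrates that the algorithms are implemented
correctly — recovery of known factors, correct dimensionality, correct
transfer asymmetries, correct lags — not that real gymnast EMG contains
three synergies. Real envelopes have amplitude-dependent noise,
non-stationary waveform shapes, crosstalk between electrodes and
task-correlated artifacts, none of which are modelled.

**The swing simulator** prescribes kinematics rather than integrating
forward dynamics: the rotation rate follows an energy balance in which the
configuration-dependent moment of inertia about the bar converts energy
between kinetic and potential form. With zero friction and zero length
modulation this is an exactly energy-conserving rigid pendulum (the
conservation check on the downstream energy computation is an independent
validation, since the simulator and the analysis compute energy by different
routes); with positive modulation the shoulder and hip flex during the
ascent (peak flexion `length_modulation × 90°` mid-ascent), shortening the
body exactly where a gymnast does. The quasi-static energy balance under
modulation is an approximation — adequate for exercising the kinematic and
inertial computations, not a dynamical model of bar elasticity or hand
friction.

## Numerical choices

- **Convergence.** A restart stops when the relative Frobenius-cost decrease
  over a 10-iteration window falls below `tol` (default `1e-5`) or at
  `max_iter` (default 1000). Multiplicative updates approach optima slowly;
  at these settings the residual VAF differs from a tightly converged run by
  well under `1e-4`, which is far below every decision threshold in the
  analysis.
- **Initialisation.** Uniform on (0.1, 1], never touching zero:
  multiplicative updates cannot move an entry off an exact zero.
- **Division guards.** Update denominators are floored at `1e-12`; zero rows
  or columns otherwise produce NaNs.
- **Degenerate inputs.** All-zero data matrices, all-zero muscle rows (named
  in the error), zero-variance waveforms (flagged `NA` and excluded from
  aggregates), coincident hip and bar markers, and zero-length segments all
  raise informative errors rather than propagating nonsense.
- **Determinism.** Every stochastic function takes a seed, draws from a
  locally seeded stream, and restores the caller's RNG state; identical
  seeds give bit-identical results, and the pipeline records its seed in
  every output.

## Problem sizes used in the tests

Unit tests run on reduced geometries (6–8 muscles, 30–100-sample cycles, 2–3
cycles) chosen so each property is exercised at the smallest size where it is
meaningful. The acceptance suite runs the protocol-fixed sizes in full — 12
muscles × 9 cycles × 200 samples for recovery, selection and transfer
checks (10 seeded replicates each), 20 random 6×40 matrices against an
independent NMF implementation, and 9-subject bookkeeping (72 ordered
comparisons, 36 unordered pairs) at reduced per-subject size, since the pair
counts do not depend on the matrix dimensions. The default study in
`scripts/acceptance.R` uses the full 9-subject, 12-muscle geometry with 20
restarts and 1000 permutation replicates.

## Known limitations

- The synthetic cohort is cleaner and more homogeneous than any real cohort;
  cohort-level numbers produced by the default study (VAF ≈ 0.99 at three
  synergies, near-unit between-subject correlations) are upper bounds that
  real data will not reach.
- Multiplicative-update NMF finds local optima; 20 restarts is a convention,
  not a guarantee. The acceptance suite's 1% cross-implementation agreement
  is evidence of adequacy at the tested sizes only.
- The best-linear-fit criterion's `5e-5` threshold is scale-sensitive: it
  presumes a VAF curve on [0, 1] from cycle-normalised EMG and will not
  transfer to differently scaled goodness-of-fit curves.
- The biomechanical model is planar and five-segmented; it cannot represent
  asymmetric or out-of-plane technique, and the simulator does not model bar
  elasticity, hand-bar friction or forward dynamics.
- Lag estimates are quantised at one sample (0.5% of cycle at `T = 200`).
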