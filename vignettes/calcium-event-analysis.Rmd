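---
title: "Methods: calcium transient analysis for injection and CPP sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium transient analysis for injection and CPP sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrans)
```

`catrans` analyzes single-cell calcium imaging sessions at the level of
discrete calcium transients. This vignette documents the statistical model
behind each stage, the parameters that matter and their defaults, what the
synthetic generator does and does not emulate, and the numerical choices
made where the procedure left genuine freedom.

## From traces to transients

Input traces are ΔF/noise values on a uniform grid (default 10 Hz, the
conventional miniscope frame rate). The calcium impulse response is modeled
as a single exponential with decay constant τ, i.e. an AR(1) process on the
frame grid with per-frame decay γ = exp(−1/(τ·rate)). The default τ = 1.0 s
is a GCaMP6m-scale value; at 10 Hz it gives γ ≈ 0.905.

`deconvolve_trace()` solves

  minimize ½‖y − c‖² + λ‖s‖₁  subject to  cₜ = γc₍ₜ₋₁₎ + sₜ, s ≥ 0, c ≥ 0

by the online active-set / pool-adjacent-violators scheme. After the
substitution zₜ = cₜγ⁻ᵗ the problem is a weighted isotonic regression with
a lower bound, whose bounded solution is the clipped unbounded solution —
so the pooled values can be clamped at zero at the end and the result is
the *exact* global optimum, not an approximation. The test suite verifies
this against two independent solvers: exhaustive enumeration of active
sets on small instances, and a bound-constrained quasi-Newton solve of the
same quadratic program on 50-frame instances.

λ defaults to 0: sparsification is done by the event-calling threshold
rather than the penalty, which keeps the solver an exact projection and
avoids the amplitude bias an L1 penalty introduces.

`detect_transients()` groups consecutive positive activity frames closer
than `min_separation` (default 2 frames) into candidate events and accepts
a candidate when its *total* activity mass exceeds k× the trace noise SD
(default k = 3), placing the event at the candidate's largest frame. Mass
thresholding, rather than per-frame peak thresholding, matters because the
solver legitimately splits one transient's mass across adjacent frames
when noise perturbs the rise; summing the cluster restores the transient's
amplitude before it meets the threshold. Supra-threshold peaks closer than
`min_separation` merge keeping the larger, so the merging semantics of
peak-based calling are preserved. The noise SD is estimated as the median
absolute deviation of the trace's first difference scaled by
1/(√2·0.6745) — a robust estimator that ignores the sparse signal. The
exact normalization Inscopix uses for "ΔF over noise" is proprietary; this
MAD estimate is the package's stand-in and is the one assumption event
calling inherits from the recording software.

## Injection-response classification

Two 10-min windows are compared, pre-injection (−600–0 s) and
post-injection (initial 0–600 s; decay 3000–3600 s), per
`phase_windows()`.

**Interval-shuffling permutation test** (`classify_by_transients()`). The
statistic is the actual transient change Δ = #post − #pre. The null is
built by placing the events of both windows on one concatenated
pseudo-timeline, permuting the intertransient intervals uniformly at
random (default 10,000 replicates), reconstructing event times from the
first event's original offset, and recording the shuffled change Δ*. A
neuron is excited when Δ strictly exceeds the 99th percentile of Δ*, and
inhibited when Δ falls strictly below the 1st percentile. Choices made
where the procedure is underdetermined:

- *Timeline order.* The chronologically earlier window is always placed
  first (for the standard comparison this is the pre window, so nothing
  changes). This makes the timeline independent of which window plays the
  "post" role, and therefore makes the classifier exactly antisymmetric:
  swapping the two windows maps excited↔inhibited neuron by neuron under
  the same seed — a property the test suite asserts.
- *Non-contiguous windows.* For the decay-phase comparison the two windows
  are abutted on the pseudo-timeline, preserving the interval structure
  within each window; the 40-min gap between them is not represented.
- *Anchor and gaps.* Only the intertransient intervals are permuted; the
  leading gap (timeline start to first event) is kept fixed as the
  reconstruction anchor, and events reconstructed past the timeline end —
  possible only through floating-point rounding, since interval
  permutation conserves the span — are dropped.
- *Percentiles.* Linear interpolation between order statistics (R type 7),
  with strict inequalities at both thresholds.
- *Degenerate trains.* At least 3 combined events (two intervals) are
  required; sparser neurons are nonresponsive by definition.
- *Reproducibility.* One master seed expands into a per-neuron substream
  keyed by neuron id, so results do not depend on iteration order or on
  how many neurons are analyzed.

The Monte-Carlo null is validated against exhaustive enumeration of all
interval orderings for small trains (total-variation distance < 2%), and
its type-I error against homogeneous-Poisson populations (responsive
fraction within [0.2%, 4%] of the nominal ~2%).

**Binned-trace test** (`classify_by_traces()`). The two window segments
are z-scored, averaged into ten 1-min bins per window, and compared with
the exact two-sided Wilcoxon signed-rank test on the ten paired bin means;
p < 0.05 with a positive mean paired difference ⇒ excited, negative ⇒
inhibited. Z-scoring is *joint* across the concatenated pre+post segment
by default: per-window standardization (arguably the literal reading of
"windows were z-scored") forces both window means to zero and leaves the
signed-rank test nothing to detect, so the joint mode is the default and
the per-window mode is kept as an option (`zscore = "per_window"`).
Zero differences are dropped (Wilcoxon convention); direction comes from
the sign of the mean paired difference.

## Exact rank tests

Both rank tests are implemented exactly, with midranks for ties, by
dynamic programming on doubled ranks (midranks are half-integers):
signed-rank over all 2^m sign assignments, Mann-Whitney over all
C(n, n₁) rank splits, each conditional on the observed tie pattern. The
exact path is used up to 20 observations (signed-rank: nonzero pairs;
Mann-Whitney: combined sample); beyond that a normal approximation with
tie-corrected variance and continuity correction takes over. Exactness
under ties matters here because per-episode transient frequencies of
low-rate neurons tie constantly (many zero-event episodes). The suite
checks both tests against naive full enumeration to 1e−12 and against
`stats::wilcox.test` on the cases that function covers.

## CPP-session analysis

`extract_episodes()` takes maximal constant-chamber runs of the occupancy
track as half-open `[start, end)` intervals and keeps those strictly
longer than 5 s. `classify_cace()` compares per-episode transient
frequencies (events/min = count/duration, the only reading of
"dividing staying time into numbers of transients" that yields the
plotted units) — or per-episode mean trace values — between cocaine- and
saline-chamber episodes with the two-sided exact Mann-Whitney test. At
least 3 episodes per chamber are required (the U test is powerless below
that); neurons failing the requirement are reported "nonclassifiable",
distinct from "nonresponsive". Whether the original tests were one- or
two-sided is unstated; two-sided is the conservative default, and both
directions are reported separately anyway.

`peri_entry_matrix()` aligns events on transitions into a chamber
(−5 to +5 s, 1-s bins, entry at 0). Every transition counts by default
regardless of the surrounding dwell times — with a `require_dwell` switch
to demand a minimum stay on both sides — and entries within 5 s of the
session edges are dropped rather than padded.

`cpp_score()` assigns the cocaine chamber as the less-preferred chamber of
the preconditioning track (the conditioning assignment rule), scores
post-minus-pre time in it, and flags animals whose baseline minority
preference falls below 25% as excluded. An explicit `cocaine_chamber`
argument overrides the assignment when the pairing is already known.

## The synthetic generator

`simulate_injection_session()` and `simulate_cpp_session()` produce the
statistical structure the analysis assumes, with known ground truth:

- *Events.* Inhomogeneous Poisson trains: baseline rate in the pre window
  (and between windows), baseline × multiplier inside post windows or the
  cocaine chamber. Defaults: 15% excited ×2.5, 30% inhibited ×0.4
  (injection); 5% chamber-excited ×2.5, 17% chamber-inhibited ×0.3 (CPP) —
  the response structure the analyses are designed to resolve.
- *Rates.* Per-neuron baselines are log-normal (median 4 events/min,
  σ_log = 0.5): real populations are rate-heterogeneous, and fixed rates
  would make the permutation nulls unrealistically uniform. No event-rate
  statistics were available for the population of interest, so these are
  simulator conventions, not measured values.
- *Traces.* Unit events convolved with exp(−t/τ), τ = 1 s, plus Gaussian
  noise (default SD 0.2 ΔF/noise units, i.e. event SNR 5).
- *Behavior.* Chamber dwells are shifted-exponential (floor 2 s, mean
  20 s, 15-min sessions) and strictly alternating — the simplest renewal
  model that produces both sub- and supra-5-s episodes so the dwell
  threshold is exercised.
- *Streams.* Behavior and spikes draw from separate substreams of one
  seed, and each neuron from its own substream, so changing `n_neurons`
  never perturbs the trajectory and every output is bit-reproducible.

What the generator does **not** emulate: pixel-level movies, motion
artifacts, calcium indicator nonlinearity/saturation, amplitude
variability across events, bursting/refractory structure, within-session
drift, or behavioral preference shifts. Passing recovery tests therefore
show that the statistical machinery is correct and calibrated under the
assumed point-process model — not that the thresholds are optimal for any
particular real recording.

## Validation design and problem sizes

The automated checks use sizes chosen to make their statistical targets
sharp while staying light: 500 homogeneous 6 events/min neurons with
1,000 shuffles for null calibration (nominal ~2% responsive); 400 neurons
for injection recovery (±5 percentage points); 300 neurons for CACE
recovery. Recovery checks run at a fixed 6 events/min baseline — the same
rate used for the null calibration — because recovery-within-tolerance is
a joint property of effect size, episode counts, and event rate: at the
generator's default median of 4 events/min a ×0.3 suppression leaves too
few events per 20-s episode for the Mann-Whitney test to resolve reliably
within a 15-min session, which is a power fact about the design, not a
defect of the classifier. Detection fidelity is measured on 30 noisy
traces of 20 events each with events at least 3τ apart, where a ±1-frame
matching tolerance is meaningful.

## Known limitations

- The AR(1) kernel has a single decay constant; rise times and AR(2)
  dynamics are out of scope.
- The MAD noise estimate assumes the trace is mostly signal-free; very
  high event rates inflate it and raise the effective threshold.
- No multiple-testing correction is applied across neurons — deliberately,
  to mirror the per-neuron classification convention; population fractions
  should be read against the calibrated ~2% (permutation) and ~5% (trace
  test) false-positive floors.
- The CPP generator holds occupancy statistics fixed across sessions; it
  validates the scoring arithmetic, not conditioning dynamics.
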