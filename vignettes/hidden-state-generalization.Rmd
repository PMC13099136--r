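---
title: "Measuring hidden-state generalization in neural populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hidden-state generalization in neural populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stategen)
```

## The scientific question

In a figure-8 odor sequence task, an animal runs two alternating four-odor
sequences (S1, S2). The outer positions P1 and P4 carry sequence-unique
odors; the middle positions P2 and P3 carry the same odors in both
sequences, so the two sequences are sensorially identical there. Whether a
trial at P2 belongs to S1 or S2 is task-irrelevant: both cases demand the
same response. A population that has learned the task's latent structure
should *compress* these situations — represent P2-in-S1 and P2-in-S2
identically — while still discriminating the genuinely different outer
positions. `stategen` quantifies this compression at three levels:

1. **Single units** — what fraction of neurons fire differently on S1
   versus S2 trials at the same position, epoch by epoch?
2. **Populations** — can a linear decoder read sequence identity out of
   pseudoensemble activity, and does a decoder trained to report position
   on S1 trials transfer to S2 trials?
3. **Population dynamics** — does a tensor decomposition of the full
   spatiotemporal activity contain *position-general* components, i.e.
   activity patterns expressed identically on every trial type?

Because the analyses are validated end to end on synthetic sessions with
planted ground truth, the package ships a generator of two population
archetypes: a `compressed` template whose only sequence asymmetry is the
physically different odors at P1/P4, and a `differentiated` template with
genuine sequence-selective firing planted at P1, the end of P3, and P4.

## Trial epochs and firing-rate extraction

Each trial is divided into nine epochs anchored on task events: `ITI-a`
(0.7 s before house-light onset), `Light`, `Poke`, `Odor`, `Unpoke`,
`Choice`, `Outcome`, `postOut`, `ITI-b`. On rewarded correct go trials,
`Choice` is the well entry and `Outcome` the reward delivery; otherwise
`Choice` is the end of the 2 s response window and the remaining anchors
follow at 0.7 s steps.

Around every anchor, spikes are counted in eight 100 ms bins spanning
−200 ms to +600 ms. Bins are half-open and left-closed, with edges rounded
to nanoseconds, so a spike exactly at an anchor lands in the first
post-anchor bin — an arbitrary but fixed convention chosen for
bit-reproducibility. Counts are smoothed per trial with a discrete
Gaussian kernel (σ = 50 ms = 0.5 bins, truncated at ±3σ and renormalized
to unit sum; we renormalize after truncation so that a constant input
stays constant in the window interior). The per-epoch activity measure is
the mean smoothed rate over the bins covering +100 to +600 ms.

For classification analyses, 30 correct trials are drawn at random from
each of the 8 trial types (sequence × position), giving 240-row
trials-by-units matrices per epoch. The selection RNG is seeded per
(session, trial type) by hashing the master seed, so a session's selection
does not depend on how many other sessions are loaded.

## Decoding

Decoders are linear support-vector machines (`e1071`, hinge loss). The
protocol leaves the regularization and preprocessing unspecified, so the
package fixes and records: cost C = 1, features z-scored with
training-fold statistics only, multiclass by one-vs-rest with ties broken
toward the lowest class index.

*Pseudoensembles* concatenate units recorded in different sessions,
aligned by trial type. Before each decode, every unit's trials are
independently re-ordered within each type. This destroys across-unit
trial-by-trial correlations — including between units from the same
session — while leaving each unit's per-type rate distribution exactly
unchanged.

Accuracy is estimated by repeated leave-one-out cross-validation: each
repetition holds out one random trial per class, trains on the rest, and
scores the held-out set (200 repetitions at protocol scale).
Significance comes from a label-shuffled null: the identical pipeline run
with permuted labels, summarized by its 2.5–97.5 percentile band. The
package exposes the number of pseudoensembles and shuffles as
configuration; the full-scale protocol value is 10,000 pseudoensembles,
while the tests and examples in this package use 10–100 (the estimates
are means, so the scale affects only Monte-Carlo error).

Position decoding uses 9-epoch rate vectors per trial as features
(a 120 × 9 matrix per unit and sequence at the standard 30 trials per
type). In each iteration one trial per position is withheld from S1; the
S1-trained decoder is scored on those trials (*within*-sequence) and on
the index-matched S2 trials (*across*-sequence). Equal within and across
accuracy is the population-level signature of compression.

## Tensor decomposition

The trial tensor stacks smoothed per-bin rates into units × 72 × trials
(9 epochs × 8 bins; trials blocked position-major — P1 trials of both
sequences first, then P2, P3, P4 — so rewarded trials occupy slices 1–80
and 241–320 of a complete 320-trial session). Each unit is soft-normalized
by its maximum rate + 1 Hz; the offset keeps near-silent units from being
blown up to the scale of active ones. The normalization is recorded in the
tensor object and can be disabled.

`cp_fit()` implements canonical polyadic decomposition with nonnegative
HALS updates by default (all displayed factors are nonnegative firing
patterns); unconstrained ALS is available by flag. Numerical choices that
matter:

* **Initialization**: factors are drawn uniform(0, 1) (nonnegative) or
  standard normal (unconstrained) from the seeded RNG, then rescaled so
  the initial model norm matches the tensor norm. Without the rescaling,
  HALS starves most components of a rank-10 fit to zero scale on
  realistic tensors.
* **Convergence**: sweeps stop when the normalized reconstruction error
  (‖X − X̂‖F / ‖X‖F) changes by less than `tol` (default 1e-6). The error
  is non-increasing at every sweep up to ~1e-8 float jitter from the
  inner-product error formula, which cancels catastrophically near zero
  error; the fitter warns if a sweep increases the error by more.
* **Degenerate columns**: a component whose scale collapses during HALS is
  revived with a small deterministic ramp rather than fresh random
  numbers, keeping fits bit-reproducible for a given seed.
* **Restart stability** (`restart_ensemble()`): 100 independently seeded
  fits; each model's similarity to the minimum-error model is the
  scale-weighted mean congruence over optimally matched components
  (congruence = product over the three modes of the absolute cosine;
  matching by the Hungarian algorithm). The score is invariant to
  component permutation and rescaling and equals 1 for identical models.

`component_summary()` classifies each component against the task: mean
temporal loading per epoch, mean trial loading per (position, sequence)
block, a rewarded-vs-nonrewarded contrast, and a **position-general
flag**. The flag is an artifact-defined diagnostic (the original analyses
identified such components by inspection): a component is position-general
when its 8 block means have a coefficient of variation below 0.2, it
carries at least 1% of the total component scale, and its epoch profile
has CV ≥ 0.5. The last condition excludes the baseline floor that any
strictly positive rate tensor produces — a component that is flat across
trials and carries at most a weak temporal tilt is the tensor's DC term
(possibly mixed with a little event structure), not a generalized
response pattern; genuinely event-locked components have epoch-profile
CVs near or above 1.

## Mutual information of trial factors

Trial-factor loadings are summarized by plug-in histogram MI (base-2
logs): against the 8 trial types with equal-width loading bins (8 by
default), and against *time*, operationalized as the chronological trial
index within the session, discretized into equal-count bins. The tensor's
trial mode is blocked by type, so the package records each slice's
chronological index (`chron_index`) and uses it as the time axis;
using the slice position instead would fold the session's drift into each
block and hide it. The plug-in estimator has the standard upward
small-sample bias (≈ (Kxy − Kx − Ky + 1)/(2N ln 2) ≈ 0.11 bits for an 8×8
table at 320 trials); a Miller–Madow correction flag removes it. Absolute
MI values therefore depend on the binning configuration, which is recorded
in the output; comparisons across components and groups are the meaningful
quantities. Over a restart ensemble, components are aligned to the
best-fit model by congruence matching, restarts with mean matched
congruence below 0.5 are dropped with a log message, and each component's
MI is reported as mean ± SEM over restarts.

## The synthetic session generator

The generator emulates the statistical structure the analyses assume, not
the biophysics of any particular circuit.

**Behavior.** Trials follow the task's timing rules exactly (0.5 s odor
onset delay, 0.5 s minimum hold, 2 s response window, reward after a
uniform 0.4–1.5 s delay, 4 s / 8 s inter-trial intervals). Correctness is
Bernoulli per trial type; latencies are lognormal (poke latency median
0.5 s, reaction time median 0.7 s capped just below the response window,
unpoke latency median 0.15 s). Sequence-dependent latency shifts are
additive on the log scale, following the general finding that response
time effects are multiplicative. The differentiated template shifts S2
latencies at P1/P3/P4 and lowers S2 accuracy there; the compressed
template is sequence-symmetric.

**Spiking.** Each unit is an inhomogeneous Poisson process. Baseline rates
are lognormal with median 5 Hz (firing-rate distributions are not
constrained by the protocol; this is a conventional cortical choice,
stated here rather than claimed to match any dataset). Event responses are
raised-cosine bumps of half-width 300 ms tied to the nine epoch anchors.
The bumps are centered 350 ms *after* the anchor — the middle of the
100–600 ms analysis window — because neural responses lag their triggering
events; centering them on the anchor itself would leave most response mass
outside the post-event window that all downstream statistics read.
Per-unit tuning is a lognormal gain per (epoch, position) cell
(σ_log = 0.7), identical across sequences. Sequence asymmetry is planted
as a multiplicative gain (lognormal, median 2) in a configurable fraction
of units (default 0.3), restricted to the template's (epoch, position)
mask: only the Odor epoch at P1/P4 for the compressed template (the odors
physically differ there), and additionally most P4 epochs plus the end of
P3 for the differentiated template. Spikes are drawn by thinning with a
piecewise-constant rate over 10 ms sub-bins — exactness is unnecessary
since the analysis bin is 100 ms.

**Population components.** Both templates share reward-outcome coding
(components active around Choice/Outcome on rewarded or non-rewarded
trials), a reward-anticipation component weighted toward the early
epochs (OFC populations are pervasively reward-modulated; without any
trial-type-dependent modulation of overall activity, the tensor's
grand-mean structure would be identical in both templates), and four
position-specific odor-sampling components, one per position (these are
sequence-independent: at P2/P3 the odors are physically identical across
sequences). The compressed template additionally carries three
*position-general* components — an early broadly-active component, and
two components whose expression drifts over the session (a linear ramp
and a half-period sinusoid), emulating slow temporal dynamics in
well-trained subjects; the differentiated template has none of these.
Per-unit component loadings are gamma-distributed (shape 2, mean 0.5).

**Correlated trial-to-trial noise.** Two shared noise sources act on top
of Poisson spiking: a per-trial population gain (lognormal, σ_log = 0.2),
and a per-trial amplitude jitter on every population component
(lognormal, σ_log = 0.25), shared across units. The component jitter is
*differential* noise — it fluctuates along the very directions that carry
the task signals — and is what keeps decodable information finite as
ensembles grow. Without it, linear decoding of position saturates at
ceiling with a handful of units, unlike real populations; with it, the
cross-sequence transfer comparison is made at 15-unit ensembles, where
the decoder operates below ceiling. The per-unit epoch-by-position
tuning spread (σ_log = 0.3, i.e. typical ±35% rate differences between
positions) is likewise chosen so that single units are informative but
not individually decisive.

**Sequence asymmetry.** For a sequence-selective unit the planted gain
applies with an independent boost direction per masked (epoch, position)
cell, so the asymmetry *remaps* the unit's response pattern across
sequences rather than scaling it uniformly — matching the observation
that poorly-generalizing populations diverge (rather than merely
rescale) across sequences, and lowering the cross-sequence preferred-
position correlation of the differentiated template below the compressed
one.

**What the generator does not emulate** — and hence what passing tests do
not establish about real recordings: refractoriness, bursting, and
non-Poisson count dispersion; electrode drift and unit-tracking artifacts;
correlated trial-by-trial noise between units (the pseudoensemble
construction removes such correlations anyway, but their effect on
single-session statistics is untested); behavioral states (satiety,
disengagement) beyond the planted slow drift; and any pharmacology — the
differentiated template mimics the *representational* signature of a
poorly-generalizing population, not a drug's mechanism.

## Problem sizes and test design

The packaged tests and the acceptance script run the pipeline at the
scale the package documents as its reference analysis: one complete
320-trial session with 300 units for the compressed group and 150 for the
differentiated comparison group; 100 restarts of the rank-10 decomposition
on the compressed tensor; decoding with 100-unit pseudoensembles, 12–20
pseudoensembles and 60 label shuffles per cell; and 500 repetitions for
the null-calibration coverage check. These sizes keep every quantity's
Monte-Carlo error comfortably inside the tolerances asserted while keeping
the full suite runnable on a laptop; the protocol-scale repetition counts
(10,000 pseudoensembles) are available through `pipeline_config()`.

Calibration notes: eighteen (position, epoch) cells are each compared with
a pointwise 95% null band in the compressed-template check, so the family
is expected to produce ~0.45 false exceedances; the tests therefore allow
at most two. The coverage check accepts exceedance rates up to 8% (500
repetitions of a 95% band, binomial noise plus the conservatism of
percentile bands on discrete accuracies).

## Known limitations

* The CP similarity definition (congruence with optimal matching,
  scale-weighted) follows the common convention but other software may
  weight pairs differently; cross-package comparisons of the *number*
  should use the packaged definition on both sides.
* The position-general flag thresholds (block CV < 0.2, epoch CV ≥ 0.3,
  scale ≥ 1%) are artifact-defined diagnostics for testability, not
  estimates of anything; they are reported alongside the underlying
  continuous quantities so users can apply their own criteria.
* `preferred_position_analysis()` correlates ordinal position codes 1–4
  (Pearson by default, Spearman by option); with only four levels the
  correlation is a coarse summary.
* No multiple-testing correction is applied across the 36 selectivity
  cells, matching the per-cell reporting style of the reference analysis;
  the fraction curves should be read as descriptive.
* Session containers are plain JSON + CSV for diffability; reading
  Plexon/NeuroExplorer/NWB native files is out of scope.
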