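---
title: "quadfret: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quadfret: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(quadfret)
```

This vignette documents the science inside `quadfret`: the generative
model behind the simulator, the estimators the analysis stack uses, the
numerical conventions, and the limits of what the synthetic tests can
show about real recordings.

## 1. The conformational model

Telomeric G-quadruplex dynamics are modelled as a continuous-time Markov
chain over labelled conformations — by default the unfolded state (UF),
the non-parallel fold (NP) and the parallel fold (P), optionally extended
with a protein-bound state (BD). A `KineticModel` carries a per-second
rate matrix `k(i -> j)` with zero diagonal; the dwell time in state *i*
is exponential with mean `1/sum_j k(i, j)`, and the jump target is chosen
with probability proportional to `k(i, j)`.

Each state emits a FRET efficiency level: UF 0.24, NP 0.47, P 0.66, and
BD 0.57 when present. The per-state spread (`emissionSd`, default 0.05)
is a free parameter of the generator: ensemble peak widths in real
recordings conflate molecular heterogeneity, fast unresolved dynamics and
shot noise, and the value 0.05 was chosen once as a realistic peak width
at 100-ms integration. It is a parameter, not an assertion about any
particular instrument.

### Construct presets

`presetModel()` encodes four telomere-variant constructs through three
ingredients:

| construct  | dwell UF / NP / P (s) | direct NP<->P branching | character |
|------------|----------------------|------------------------|-----------|
| TelG5      | 1.1 / 7.6 / 10.3     | 0.15                   | unfolding-mediated |
| TelG5TAA   | 4.3 / 6.1 / 11.1     | 0.05                   | unfolding-mediated |
| TelG5TTT   | 1.1 / 2.3 / 5.2      | 0.75                   | direct-dominated |
| TelG5TT    | 1.1 / 2.1 / 4.3      | 0.85                   | direct-dominated |

The NP and P dwell means and the TelG5TAA UF dwell are the published
per-construct values; the UF dwell of the other three constructs is a
quarter of TelG5TAA's (the reported ratio), and the direct-branching
probabilities were fixed once to reproduce the qualitative
transition-density signatures: short-loop variants (TelG5TTT, TelG5TT)
interconvert mostly directly between the folded states, the canonical
repeat and the TAA variant mostly rearrange through unfolding. The
remaining refolding split UF -> NP vs UF -> P per construct was chosen to
bring the stationary occupancy close to the published ensemble fractions.

### Docked molecules and why they get their own occupancy

Real recordings contain a large static ("docked") subpopulation — for the
canonical repeat roughly half of the molecules show no transition in
100 s. The generator reproduces this with `dockedFraction` (default
0.52): the first `floor(dockedFraction * n)` molecules are frozen in one
state for the whole movie.

The published ensemble fractions and the published dwell times are not
jointly realisable by a single time-homogeneous three-state chain: with
P dwelling twice as long as NP, the dynamic stationary distribution
necessarily over-weights P relative to the ensemble fractions measured in
short-window histograms. The package resolves this the way the data
suggest: the docked subpopulation need not sit at the dynamic stationary
distribution. Presets solve

```
docked_occupancy = (ensemble_target − (1 − f_docked) · π_dynamic) / f_docked
```

(clipped at zero and renormalised when infeasible), so the overall
short-window histogram reproduces the ensemble fractions while the
dynamic molecules keep the published dwell kinetics. For TelG5TAA the
target is not exactly reachable (its dynamic chain spends too much time
unfolded); the preset lands at an overall UF fraction near 0.15 instead
of 0.11, a documented residual mismatch.

### Initial states

A path observed from an arbitrary start time at equilibrium occupies
state *i* with its time-weighted (CTMC stationary) probability, not the
jump-chain's visit-weighted probability — the latter over-weights
short-dwell states and would distort every short-window histogram. The
simulator therefore draws initial states from the CTMC stationary
distribution when it exists, falling back to the embedded jump chain's
stationary vector and then to a uniform draw for chains with absorbing
states.

### The camera model

`renderIntensities()` integrates the FRET level over each 100-ms frame:
a frame spanning a jump carries the occupancy-weighted mean of the two
levels, which produces the blurred transition frames seen in real traces.
Per-frame emission jitter (occupancy-weighted `emissionSd`) is added to
the level, then donor and acceptor are rendered as
`total·(1−E) + ε` and `total·E + ε` with independent Gaussian channel
noise (default sd 60 on a total of 1000). Photobleaching, when enabled,
draws an exponential bleach time; frames from the first fully dark frame
on carry noise only, and that index is stored as ground truth. The noise
model is additive Gaussian per channel — deliberately simple; a
photon-counting (shot-noise) model would be the natural swap-in point.

What the generator does **not** emulate: fluorophore blinking, spectral
crosstalk dynamics, donor-only or acceptor-only molecules (dual labelling
is assumed upstream), surface artefacts and baseline drift. Tests passing
on synthetic data therefore validate the estimators under the stated
noise model, not robustness to every pathology of real recordings.

## 2. FRET efficiency and histograms

Efficiency is the ratiometric `E = (A − l·D) / (γ·D + A − l·D)` with
leakage `l = 0` and detection factor `γ = 1` by default (no correction),
clipped to [−0.2, 1.2]. Frames at or beyond the bleach index are
excluded from all statistics; the bleach index is the trace's recorded
ground truth when present, otherwise `detectBleach()` — a running median
(window 5) of total intensity crossing 30% of its initial level and
staying below — supplies it.

Histograms pool the first 2 s (20 frames) of every molecule, mirroring
short-movie ensemble acquisition, and are normalised to unit area on
0.025-wide bins over [−0.2, 1.2]. That width resolves peaks 0.1 apart
while keeping several bins per peak. Pooling weights every *frame*
equally; weighting every *molecule* equally instead would down-weight
molecules with early bleaches — with 2-s windows and rare early bleaching
the two conventions differ negligibly, and frame-pooling was chosen.

### Anchored mixture decomposition

`fitMixture()` performs bounded Levenberg–Marquardt least squares of a
sum of Gaussians against the binned density. Anchored components keep
their centers within ± 0.01 (default; 0 pins them exactly) of the
protein-free peak positions — the device that keeps fits comparable
across conditions. Free components (an emerging bound-state peak) are
seeded at the largest positive residual of the anchored-only fit.
Populations are component areas normalised to 1. The fit is
deterministic: a fixed initialisation rule (mass near each anchor), fixed
optimizer settings, no random restarts; negative weights are excluded by
a zero lower bound. Component widths are bounded to [0.01, 0.2] FRET
units to keep a component from degenerating into a spike or absorbing
the baseline.

Known bias: camera-rendered efficiency distributions are slightly skewed
and heavy-tailed relative to Gaussians (the ratio of noisy channels), so
a multi-Gaussian decomposition misattributes of order one percentage
point of mass between overlapping components. This is inherent to
Gaussian histogram fitting on ratio data, not an optimizer artefact.

`differentialDensity()` subtracts unit-normalised densities bin by bin
and refuses mismatched bin edges rather than silently rebinning. Its
`positiveSum` integrates the density gained by the condition and tracks
the mass redirected into a bound state; component overlap makes it a
slight underestimate of the true redirected fraction.

## 3. State-path inference

Segmentation is a Gaussian-emission hidden Markov model fit by
expectation–maximisation, with the iteration loop compiled (Rcpp):

* **Initialisation** (deterministic): emission means from a
  farthest-point ("maximin") seeding refined by Lloyd iterations —
  robust to states visited rarely, where plain quantile seeds collapse;
  spreads start at `sd(E)/K`; the transition matrix starts at 0.95
  self-transition; the initial distribution is uniform.
* **Convergence**: relative log-likelihood change below 1e-6, at most
  100 iterations; emission spreads floored at 0.005 to keep noiseless
  traces finite.
* **Model selection**: K = 2..4 (configurable) plus an always-included
  single-Gaussian baseline, compared by BIC with
  `p = (K−1) + K(K−1) + 2K` parameters. The baseline is what lets a
  docked (single-level) trace reject K = 2.
* **Degeneracy**: fitted states whose means are within 0.02 FRET units
  are merged (occupancy-weighted) before segmentation, so the reported
  state count can fall below the selected K.
* **Decoding**: the Viterbi path, collapsed to segments on the frame
  grid. Invalid frames (zero total intensity) carry the last valid
  efficiency forward to keep the chain contiguous.

States are then labelled against the anchors (UF/NP/P and optionally BD):
nearest anchor wins, exact ties (to 1e-9) resolve to the lower-efficiency
anchor, and states farther than 0.08 from every anchor become `"other"`.
Adjacent same-label segments merge.

Dwell means from Viterbi paths are biased for dwells of a few frames:
sub-frame visits vanish (merging the flanking dwells of the partner
state) and blurred boundary frames shift segment edges. At the default
noise the recovered NP/P means of all four presets stay within 10% of the
generating values; the shortest dwells (~1 s, ten frames) can exceed that.
This is the known resolution limit of frame-level maximum-likelihood
segmentation at 100-ms integration, shared with the standard tools of
the field.

### Classification, transitions, dwells

* `classifyTrajectory()` automates the docked/transitioning call that is
  traditionally manual: a molecule is transitioning iff its inferred path
  over the first 100 s contains a state change with an emission-center
  jump above 0.1. A two-level fit against the one-state baseline is
  sufficient to detect any such jump and keeps the call cheap.
* `countTransitions()` tallies the six ordered UF/NP/P pair types;
  transitions involving BD or `"other"` are tallied separately and
  excluded from the six-type denominator. The direct-transition density
  is `f_trans × (N(NP→P) + N(P→NP)) / N(six core types)` — the
  protein-free statistic; including BD transitions in the denominator
  would mix binding kinetics into a conformational quantity, so the
  six-type denominator was chosen and is documented here.
* `dwellAnalysis()` censors the first and last dwell of every trace
  (their true length is cut by the observation window; for an exponential
  dwell the first one is additionally length-biased at a stationary
  start) and reports per-state means over uncensored dwells only. A state
  with no uncensored dwell has an undefined mean, reported as `NA`, never
  as 0.
* `transitionDensityPlot()` places one point per state change at the
  inferred emission centers before and after (not the noisy frame
  values), binned on the FRET grid and normalised to unit mass. Adjacent
  segments always differ, so the diagonal is structurally empty.

## 4. Binding

`fitKd()` fits `Y = Bmax·X/(K_d + X)` by bounded Levenberg–Marquardt,
with Bmax fixed to 1 by default (the saturation constraint) and the
starting `K_d` set deterministically to the concentration whose response
is nearest half the maximum observed fraction. Uncertainty is the
asymptotic standard error; replicate curves aggregate by plain mean/SD
(`aggregateKd()`). Concentrations are handled in nM internally, with μM
accepted and converted. Bound fractions are taken as pre-quantified
input — densitometry is upstream of this package; the ratio convention
behind "bound fraction" is the caller's, which is why the curve container
stores whatever was quantified rather than enforcing one convention.

`dynamicsBindingTable()` inner-joins per-construct dynamics summaries
with relative binding intensities and reports Kendall's rank correlation
(undefined, flagged `NA`, with fewer than two shared constructs). The
table states co-ranking; it encodes no causal claim.

## 5. Problem sizes and determinism

The test suite and the acceptance script regenerate everything they
check. Sizes were chosen once as the smallest that keep Monte-Carlo error
comfortably inside each tolerance: occupancy and dwell-law checks on
10^4-s paths; oracle-equivalence on 30–40 noiseless molecules;
frame-accuracy on 100 molecules × 200 s; dwell recovery on 500 molecules
× 3 seeds per construct; mixture recovery on 2000 molecules × 2-s
windows × 3 seeds; classification on 2000 molecules × 110 s (the call
uses only the first 100 s); K_d bias on 200 noisy replicates. Every
random draw flows through a single seed (dataset-level `set.seed`), and
identical configurations produce bit-identical traces and byte-identical
CLI output tables.

## 6. Known limitations

* The additive-Gaussian camera model understates low-intensity noise
  structure (no shot noise, no blinking); estimator robustness to those
  is untested by construction.
* Gaussian mixture populations carry ~1 percentage point of
  misattribution bias on ratio-distributed data (Section 2).
* Viterbi dwell means are biased upward for states whose dwells approach
  the frame time (Section 3); rate-matrix maximum-likelihood estimation
  from the HMM posterior would be the principled upgrade and is out of
  scope.
* The docked-occupancy reconciliation (Section 1) is a modelling choice;
  nothing in a 2-s histogram window distinguishes it from slow
  heterogeneity among dynamic molecules.
* Molecule filtering by alternating-laser excitation, image registration
  and spot extraction are upstream of this package: it starts at
  extracted per-molecule traces.
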