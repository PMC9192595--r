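# quadfret

Single-molecule FRET analysis of telomeric G-quadruplex conformational
dynamics and protein binding.

## The problem

G-rich telomeric repeats fold into G-quadruplexes (G4) that interconvert
between an unfolded state (UF), a non-parallel fold (NP) and a parallel
fold (P). In single-molecule FRET (smFRET) recordings each conformation
appears as a characteristic FRET efficiency level (UF ≈ 0.24, NP ≈ 0.47,
P ≈ 0.66), and a protein-bound state (BD ≈ 0.57) emerges between the two
folded levels when a G4-binding protein is added. Understanding which
conformational pathway a protein recognises requires turning thousands of
noisy two-channel intensity traces into state paths, dwell times,
transition statistics and population fractions — and comparing those with
equilibrium binding measurements.

`quadfret` implements that pipeline end to end for anyone analysing
two-channel smFRET recordings of nucleic-acid folding:

* **trace I/O** — a plain-text trace dialect with manifests, plus
  single-step photobleach detection and truncation;
* **histogram analysis** — ensemble FRET histograms from short
  per-molecule windows, anchored multi-Gaussian decomposition (centers
  constrained to the protein-free peak positions ± 0.01), population
  quantification by relative Gaussian area, and differential density
  between conditions;
* **kinetics** — automated docked/transitioning classification,
  hidden-Markov state-path inference with 2–4-state selection by BIC,
  anchor-based state labelling, transition density plots, censored
  dwell-time tables, and the NP–P direct-transition density;
* **binding** — one-site K_d regression on titrations and the
  dynamics-versus-binding comparative table;
* **a trajectory simulator** — a continuous-time Markov generator with a
  camera model (frame-integrated FRET, Gaussian channel noise, single-step
  photobleaching, a static "docked" subpopulation) that provides ground
  truth for every stage, including presets for the TelG5, TelG5TAA,
  TelG5TTT and TelG5TT telomere repeat variants.

## The core statistic

The NP–P direct-transition density quantifies how much a construct
rearranges between its two folded conformations *without* unfolding:

```
direct_density = f_trans × (N(NP→P) + N(P→NP)) / N(all UF/NP/P transitions)
```

where `f_trans` is the fraction of molecules showing any transition within
the first 100 s of observation. Constructs dominated by direct NP↔P
interconversion (short-loop variants) score high; constructs that
rearrange through complete unfolding score low. The package pairs this
statistic with relative binding intensities and reports their rank
agreement.

Binding titrations are fit with the one-site specific binding model
`Y = Bmax·X / (K_d + X)` (Bmax fixed to 1 by default).

## Worked example

```r
library(quadfret)

model <- presetModel("TelG5")
model
#> KineticModel: 3 states (UF, NP, P)
#>   emission: UF=0.24 NP=0.47 P=0.66
#>   mean dwell (s): UF=1.1 NP=7.6 P=10.3
#>   docked fraction: 0.52

cfg <- simulationConfig(model, nMolecules = 200, duration = 200, seed = 42)
set <- simulateDataset(cfg)
trajs <- computeFretSet(set)

# ensemble histogram over 2-s windows, anchored three-Gaussian fit
fit <- fitMixture(buildHistogram(trajs, window = 2), defaultAnchors())
fit
#> MixtureFit:
#>   UF     center 0.236 sd 0.057 population 0.053
#>   NP     center 0.475 sd 0.071 population 0.543
#>   P      center 0.663 sd 0.063 population 0.404
#>   residual 0.286

# per-trajectory kinetics: classification, HMM segmentation, statistics
res <- analyzeKinetics(trajs, label = "TelG5")
res$summary
#> DynamicsSummary 'TelG5': 96/200 transitioning (0.480), NP-P direct density 0.0526
round(dwellMeans(res$dwell), 2)
#>    P   UF   NP
#> 9.65 1.22 8.00

# one-site Kd regression on a noisy titration
set.seed(7)
curve <- simulateBindingCurve(456, noiseSd = 0.05, construct = "TelG5TTT")
fitKd(curve)
#> BindingCurve 'TelG5TTT': 9 concentrations, Kd = 467.1 nM (se 54.5), Bmax = 1
```

The fitted populations track the planted ensemble fractions (P ≈ 0.37;
at n = 200 molecules they land within a few percentage points), the
recovered dwell means sit close to the generating values (NP 7.6 s,
P 10.3 s), and 48% of molecules are correctly called transitioning.

A command-line wrapper over the same functions is installed at
`inst/scripts/quadfret`:

```sh
quadfret simulate  --config sim.cfg --out traces.tsv
quadfret histogram --traces traces.tsv --anchors UF=0.24,NP=0.47,P=0.66 --out hist/
quadfret kinetics  --traces traces.tsv --anchors UF=0.24,NP=0.47,P=0.66 --out kin/
quadfret binding   --curve titration.tsv --out kd.tsv
```

All commands are byte-deterministic for a fixed seed and configuration.

## See also

The methods vignette (`vignettes/quadfret-methods.Rmd`) documents the
model, the estimator design choices, the numerical conventions and the
known limitations.
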