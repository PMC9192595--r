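#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Single-molecule two-channel fluorescence trace
#'
#' One surface-immobilised molecule's donor and acceptor intensity time
#' series, recorded at a fixed frame interval (100 ms by default). The
#' optional \code{bleachFrame} marks the first frame after single-step
#' photobleaching; all downstream statistics are truncated there.
#'
#' @slot moleculeId character scalar identifying the molecule.
#' @slot frameInterval frame duration in seconds (> 0).
#' @slot donor,acceptor intensity series in camera units, equal length.
#' @slot bleachFrame integer index in \code{[1, T]}, or \code{NA_integer_}
#'   when no bleach was observed.
#' @slot channelLabels names of the two channels (metadata only).
#' @export
setClass("FretTrace",
  representation(
    moleculeId    = "character",
    frameInterval = "numeric",
    donor         = "numeric",
    acceptor      = "numeric",
    bleachFrame   = "integer",
    channelLabels = "character"
  ),
  prototype(
    frameInterval = 0.1,
    bleachFrame   = NA_integer_,
    channelLabels = c("donor", "acceptor")
  )
)

setValidity("FretTrace", function(object) {
  msg <- character()
  T <- length(object@donor)
  if (length(object@moleculeId) != 1L || !nzchar(object@moleculeId))
    msg <- c(msg, "moleculeId must be a non-empty string")
  if (length(object@acceptor) != T)
    msg <- c(msg, "donor and acceptor must have equal length")
  if (T < 1L)
    msg <- c(msg, "trace must contain at least one frame")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a positive number")
  bf <- object@bleachFrame
  if (length(bf) != 1L)
    msg <- c(msg, "bleachFrame must be a single index or NA")
  else if (!is.na(bf) && (bf < 1L || bf > T))
    msg <- c(msg, sprintf("bleachFrame %d outside [1, %d]", bf, T))
  if (length(msg)) msg else TRUE
})

#' Collection of traces recorded under one condition
#'
#' Groups the per-molecule traces of one movie/condition together with a
#' manifest of condition labels (construct, protein concentration, salt,
#' temperature, ...). When the set was simulated, \code{truth} carries the
#' generator's ground truth (state paths, docked flags, bleach frames).
#'
#' @slot traces list of \linkS4class{FretTrace}, unique molecule ids.
#' @slot manifest named list of non-empty condition labels.
#' @slot truth named list of simulation ground truth (may be empty).
#' @export
setClass("TraceSet",
  representation(traces = "list", manifest = "list", truth = "list"),
  prototype(truth = list())
)

setValidity("TraceSet", function(object) {
  msg <- character()
  if (!all(vapply(object@traces, is, logical(1), class2 = "FretTrace")))
    msg <- c(msg, "all elements of traces must be FretTrace objects")
  ids <- vapply(object@traces, function(tr) tr@moleculeId, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "molecule ids must be unique within a TraceSet")
  if (length(object@manifest) == 0L)
    msg <- c(msg, "manifest must contain at least one condition label")
  else {
    lab <- vapply(object@manifest, function(x) as.character(x)[1], character(1))
    if (is.null(names(object@manifest)) || any(!nzchar(names(object@manifest))))
      msg <- c(msg, "manifest entries must be named")
    if (any(is.na(lab) | !nzchar(lab)))
      msg <- c(msg, "manifest condition labels must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' Continuous-time Markov model of conformational dynamics
#'
#' States (by default the unfolded UF, non-parallel NP and parallel P
#' quadruplex conformations, optionally the protein-bound BD state) with a
#' per-second transition rate matrix and Gaussian FRET emission per state.
#' The mean dwell time of state i is \code{1/sum(rates[i, ])}. A fraction
#' \code{dockedFraction} of simulated molecules is generated with all rates
#' zeroed, emulating the static ("docked") subpopulation seen in real
#' recordings.
#'
#' @slot states ordered state labels.
#' @slot rates square matrix of per-second rates k(i -> j), zero diagonal.
#' @slot emissionMean per-state FRET level, within [-0.2, 1.2].
#' @slot emissionSd per-state FRET spread (> 0).
#' @slot dockedFraction fraction of molecules frozen in one state, in [0, 1].
#' @slot dockedOccupancy optional state distribution of the docked
#'   subpopulation (length 0 means: use the dynamic stationary occupancy).
#' @export
setClass("KineticModel",
  representation(
    states          = "character",
    rates           = "matrix",
    emissionMean    = "numeric",
    emissionSd      = "numeric",
    dockedFraction  = "numeric",
    dockedOccupancy = "numeric"
  ),
  prototype(dockedFraction = 0, dockedOccupancy = numeric(0))
)

setValidity("KineticModel", function(object) {
  msg <- character()
  n <- length(object@states)
  if (n < 1L) msg <- c(msg, "at least one state required")
  if (!all(dim(object@rates) == c(n, n)))
    msg <- c(msg, "rates must be an n x n matrix matching states")
  else {
    if (any(object@rates < 0)) msg <- c(msg, "rates must be non-negative")
    if (any(diag(object@rates) != 0)) msg <- c(msg, "rate diagonal must be zero")
  }
  if (length(object@emissionMean) != n ||
      any(object@emissionMean < -0.2 | object@emissionMean > 1.2))
    msg <- c(msg, "emissionMean must lie within [-0.2, 1.2] for every state")
  if (length(object@emissionSd) != n || any(object@emissionSd <= 0))
    msg <- c(msg, "emissionSd must be positive for every state")
  if (length(object@dockedFraction) != 1L || object@dockedFraction < 0 ||
      object@dockedFraction > 1)
    msg <- c(msg, "dockedFraction must lie in [0, 1]")
  docc <- object@dockedOccupancy
  if (length(docc) && (length(docc) != n || any(docc < 0) ||
                       abs(sum(docc) - 1) > 1e-6))
    msg <- c(msg, "dockedOccupancy must be a probability vector over states")
  if (length(msg)) msg else TRUE
})

#' Simulation settings for a synthetic trace set
#'
#' @slot model the \linkS4class{KineticModel} to simulate.
#' @slot nMolecules number of molecules (>= 1).
#' @slot duration recording length in seconds.
#' @slot frameInterval camera integration time in seconds.
#' @slot totalIntensity donor + acceptor level in camera units.
#' @slot intensityNoiseSd additive Gaussian camera noise per channel.
#' @slot bleachLifetime mean of the exponential photobleach time in seconds,
#'   or \code{NA_real_} for no bleaching.
#' @slot seed RNG seed; identical configs give bit-identical output.
#' @export
setClass("SimulationConfig",
  representation(
    model            = "KineticModel",
    nMolecules       = "integer",
    duration         = "numeric",
    frameInterval    = "numeric",
    totalIntensity   = "numeric",
    intensityNoiseSd = "numeric",
    bleachLifetime   = "numeric",
    seed             = "integer"
  ),
  prototype(
    duration = 200, frameInterval = 0.1, totalIntensity = 1000,
    intensityNoiseSd = 60, bleachLifetime = NA_real_, seed = 1L
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nMolecules < 1L) msg <- c(msg, "nMolecules must be >= 1")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@duration < object@frameInterval)
    msg <- c(msg, "duration must be at least one frame interval")
  if (!is.na(object@bleachLifetime) && object@bleachLifetime <= 0)
    msg <- c(msg, "bleachLifetime must be positive or NA")
  if (length(msg)) msg else TRUE
})

#' Piecewise-constant state occupancy of one trajectory
#'
#' Either the simulator's ground truth or the Viterbi path of the hidden
#' Markov fit, collapsed to segments. Segments tile the observed interval
#' contiguously, and adjacent segments always carry distinct states.
#'
#' @slot moleculeId molecule identifier.
#' @slot segments data.frame with columns \code{state} (label), \code{start}
#'   and \code{end} (seconds).
#' @slot centers named per-state FRET emission centers (model truth or
#'   inferred means), used for labelling and transition-density coordinates.
#' @slot source \code{"simulated"} or \code{"inferred"}.
#' @export
setClass("StatePath",
  representation(
    moleculeId = "character",
    segments   = "data.frame",
    centers    = "numeric",
    source     = "character"
  )
)

setValidity("StatePath", function(object) {
  msg <- character()
  seg <- object@segments
  if (!all(c("state", "start", "end") %in% names(seg)))
    msg <- c(msg, "segments needs columns state, start, end")
  else if (nrow(seg) > 0) {
    if (any(seg$end - seg$start <= 0))
      msg <- c(msg, "segments must have strictly positive duration")
    if (nrow(seg) > 1) {
      if (any(abs(seg$start[-1] - seg$end[-nrow(seg)]) > 1e-9))
        msg <- c(msg, "segments must be contiguous and non-overlapping")
      if (any(seg$state[-1] == seg$state[-nrow(seg)]))
        msg <- c(msg, "adjacent segments must have distinct states")
    }
  }
  if (!object@source %in% c("simulated", "inferred"))
    msg <- c(msg, "source must be 'simulated' or 'inferred'")
  if (length(msg)) msg else TRUE
})

#' Per-molecule FRET efficiency trajectory
#'
#' @slot moleculeId molecule identifier.
#' @slot frameInterval seconds per frame.
#' @slot efficiency E_t series, clipped to [-0.2, 1.2]; NA marks frames that
#'   could not be computed (zero total intensity).
#' @slot validUntil last analysable frame (photobleach truncation); frames
#'   beyond it are excluded from every statistic.
#' @export
setClass("FretTrajectory",
  representation(
    moleculeId    = "character",
    frameInterval = "numeric",
    efficiency    = "numeric",
    validUntil    = "integer"
  )
)

setValidity("FretTrajectory", function(object) {
  msg <- character()
  if (object@validUntil < 0L || object@validUntil > length(object@efficiency))
    msg <- c(msg, "validUntil outside [0, T]")
  ok <- object@efficiency[seq_len(object@validUntil)]
  ok <- ok[!is.na(ok)]
  if (length(ok) && (min(ok) < -0.2 - 1e-9 || max(ok) > 1.2 + 1e-9))
    msg <- c(msg, "efficiency values must lie within [-0.2, 1.2]")
  if (length(msg)) msg else TRUE
})

#' Ensemble FRET-efficiency histogram
#'
#' Binned probability density of FRET efficiencies pooled over the first
#' few seconds of every molecule, normalised to unit area.
#'
#' @slot breaks bin edges in FRET units.
#' @slot density per-bin probability density (>= 0, integrates to 1).
#' @slot nMolecules number of molecules pooled.
#' @slot window seconds of each trajectory used.
#' @export
setClass("FretHistogram",
  representation(
    breaks     = "numeric",
    density    = "numeric",
    nMolecules = "integer",
    window     = "numeric"
  )
)

setValidity("FretHistogram", function(object) {
  msg <- character()
  if (length(object@density) != length(object@breaks) - 1L)
    msg <- c(msg, "density must have one entry per bin")
  if (any(object@density < 0)) msg <- c(msg, "density must be non-negative")
  w <- diff(object@breaks)
  if (sum(object@density) > 0 && abs(sum(object@density * w) - 1) > 1e-9)
    msg <- c(msg, "density must integrate to 1")
  if (length(msg)) msg else TRUE
})

#' Anchored multi-Gaussian decomposition of a FRET histogram
#'
#' @slot components data.frame with columns \code{label}, \code{center},
#'   \code{sd}, \code{weight} (Gaussian area in density units).
#' @slot anchors named FRET centers used as constraints.
#' @slot residual sum of squared density residuals of the fit.
#' @slot population named state fractions (component areas normalised to 1).
#' @export
setClass("MixtureFit",
  representation(
    components = "data.frame",
    anchors    = "numeric",
    residual   = "numeric",
    population = "numeric"
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character()
  cmp <- object@components
  if (!all(c("label", "center", "sd", "weight") %in% names(cmp)))
    msg <- c(msg, "components needs columns label, center, sd, weight")
  else {
    if (any(cmp$sd <= 0)) msg <- c(msg, "component sd must be positive")
    if (any(cmp$weight < 0)) msg <- c(msg, "component weights must be >= 0")
  }
  if (length(object@population) &&
      abs(sum(object@population) - 1) > 1e-9)
    msg <- c(msg, "populations must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Differential FRET density (condition minus reference)
#'
#' @slot breaks shared bin edges.
#' @slot deltaDensity signed per-bin density difference.
#' @slot positiveSum integral of the positive part of the difference; used
#'   as a proxy for the bound-state mass gained under protein.
#' @export
setClass("DifferentialHistogram",
  representation(
    breaks       = "numeric",
    deltaDensity = "numeric",
    positiveSum  = "numeric"
  )
)

#' Transition-type tallies over labelled state paths
#'
#' The six core UF/NP/P transition types are kept apart from transitions
#' involving the bound (BD) state or unassigned ("other") levels, which are
#' tallied in \code{extra} and excluded from the core total.
#'
#' @slot counts named counts over the six ordered UF/NP/P pairs.
#' @slot extra named counts of BD- or other-involving transitions.
#' @slot nTransitions total of the six core counts.
#' @export
setClass("TransitionCounts",
  representation(counts = "numeric", extra = "numeric", nTransitions = "numeric")
)

setValidity("TransitionCounts", function(object) {
  msg <- character()
  if (any(object@counts < 0) || any(object@extra < 0))
    msg <- c(msg, "counts must be non-negative")
  if (abs(object@nTransitions - sum(object@counts)) > 1e-9)
    msg <- c(msg, "nTransitions must equal the sum of core counts")
  if (length(msg)) msg else TRUE
})

#' Dwell-time table with censoring flags
#'
#' The first and last dwell of every trace are censored (their true length
#' is cut by the observation window) and excluded from the per-state means.
#'
#' @slot rows data.frame with columns \code{moleculeId}, \code{state},
#'   \code{duration} (s), \code{censored}.
#' @slot means named per-state mean dwell over uncensored rows;
#'   \code{NA} when a state has no uncensored dwell.
#' @export
setClass("DwellTable", representation(rows = "data.frame", means = "numeric"))

#' Per-condition dynamics summary
#'
#' Carries the fraction of transitioning molecules and the NP-P
#' direct-transition density: the relative fraction of NP->P plus P->NP
#' transitions multiplied by the fraction of molecules that transition at
#' all.
#'
#' @slot label condition label.
#' @slot nTotal,nTransitioning molecule counts.
#' @slot fractionTransitioning in [0, 1].
#' @slot directDensity in [0, fractionTransitioning].
#' @export
setClass("DynamicsSummary",
  representation(
    label                 = "character",
    nTotal                = "integer",
    nTransitioning        = "integer",
    fractionTransitioning = "numeric",
    directDensity         = "numeric"
  )
)

setValidity("DynamicsSummary", function(object) {
  msg <- character()
  f <- object@fractionTransitioning
  if (f < 0 || f > 1) msg <- c(msg, "fractionTransitioning outside [0, 1]")
  if (object@directDensity < -1e-12 || object@directDensity > f + 1e-12)
    msg <- c(msg, "directDensity must lie in [0, fractionTransitioning]")
  if (length(msg)) msg else TRUE
})

#' Equilibrium binding titration and one-site fit
#'
#' @slot construct probe label.
#' @slot concentrations protein concentrations in nM.
#' @slot boundFraction quantified bound fractions.
#' @slot kd fitted dissociation constant in nM (NA before fitting).
#' @slot bmax fitted or fixed saturation level.
#' @slot kdSe asymptotic standard error of kd in nM.
#' @slot residuals fit residuals.
#' @export
setClass("BindingCurve",
  representation(
    construct      = "character",
    concentrations = "numeric",
    boundFraction  = "numeric",
    kd             = "numeric",
    bmax           = "numeric",
    kdSe           = "numeric",
    residuals      = "numericOrNULL"
  ),
  prototype(kd = NA_real_, bmax = NA_real_, kdSe = NA_real_, residuals = NULL)
)

setValidity("BindingCurve", function(object) {
  msg <- character()
  if (length(object@boundFraction) != length(object@concentrations))
    msg <- c(msg, "concentrations and boundFraction must have equal length")
  if (any(object@concentrations < 0))
    msg <- c(msg, "concentrations must be non-negative")
  if (!is.na(object@kd) && object@kd <= 0)
    msg <- c(msg, "fitted kd must be positive")
  if (length(msg)) msg else TRUE
})

#' Analysis settings shared across the pipeline
#'
#' @slot histogramWindow seconds of each molecule pooled into histograms
#'   (default 2, the short-movie window).
#' @slot classificationWindow seconds inspected for the docked vs
#'   transitioning call (default 100).
#' @slot binWidth,binRange FRET histogram binning (0.025 over [-0.2, 1.2]).
#' @slot anchorTolerance allowed drift of anchored Gaussian centers
#'   (default 0.01; 0 fixes them exactly).
#' @slot stateCountRange HMM state counts tried (default 2:4).
#' @slot leakage,gamma donor leakage fraction and detection-correction
#'   factor used when computing E (defaults 0 and 1: E = A/(D+A)).
#' @slot minJump minimum anchor-level FRET jump that counts as a transition.
#' @slot dropFraction photobleach detector threshold.
#' @slot seed RNG seed.
#' @export
setClass("AnalysisConfig",
  representation(
    histogramWindow      = "numeric",
    classificationWindow = "numeric",
    binWidth             = "numeric",
    binRange             = "numeric",
    anchorTolerance      = "numeric",
    stateCountRange      = "integer",
    leakage              = "numeric",
    gamma                = "numeric",
    minJump              = "numeric",
    dropFraction         = "numeric",
    seed                 = "integer"
  ),
  prototype(
    histogramWindow = 2, classificationWindow = 100, binWidth = 0.025,
    binRange = c(-0.2, 1.2), anchorTolerance = 0.01, stateCountRange = 2:4,
    leakage = 0, gamma = 1, minJump = 0.1, dropFraction = 0.3, seed = 1L
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@histogramWindow > object@classificationWindow)
    msg <- c(msg, "histogramWindow must not exceed classificationWindow")
  if (object@anchorTolerance < 0) msg <- c(msg, "anchorTolerance must be >= 0")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
  if (length(msg)) msg else TRUE
})
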