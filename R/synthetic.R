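#' Simulation settings
#'
#' Convenience constructor for \linkS4class{SimulationConfig}. Defaults
#' mirror the recording conditions the analysis assumes: 200-s movies at
#' 100 ms per frame, a total (donor + acceptor) intensity of 1000 camera
#' units and additive Gaussian camera noise of 60 units per channel.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param nMolecules number of molecules to simulate.
#' @param duration movie length in seconds.
#' @param frameInterval camera integration time in seconds.
#' @param totalIntensity summed channel intensity in camera units.
#' @param intensityNoiseSd per-channel additive Gaussian noise sd.
#' @param bleachLifetime mean exponential photobleach time in seconds, or
#'   \code{NA} to disable bleaching.
#' @param seed integer RNG seed; identical configs give bit-identical sets.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(model, nMolecules, duration = 200,
                             frameInterval = 0.1, totalIntensity = 1000,
                             intensityNoiseSd = 60, bleachLifetime = NA,
                             seed = 1L) {
  new("SimulationConfig", model = model, nMolecules = as.integer(nMolecules),
      duration = duration, frameInterval = frameInterval,
      totalIntensity = totalIntensity, intensityNoiseSd = intensityNoiseSd,
      bleachLifetime = as.numeric(bleachLifetime), seed = as.integer(seed))
}

#' Simulate a continuous-time Markov state path
#'
#' Gillespie simulation of the conformational chain: the waiting time in
#' state i is exponential with rate sum_j k(i -> j) and the jump target is
#' drawn with probability proportional to k(i -> j). The initial state is
#' drawn from the chain's time-stationary occupancy (the CTMC stationary
#' distribution) when it exists, so that a path observed from time zero is
#' an equilibrium observation; when it does not exist the embedded jump
#' chain's stationary vector is used, and failing that a uniform draw. A
#' visited state with an all-zero rate row simply holds until the end of
#' the path. Segments tile \code{[0, duration]} exactly.
#'
#' Uses the current R random number generator; seed it with
#' \code{set.seed()} (or go through \code{\link{simulateDataset}}) for
#' reproducibility.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param duration path length in seconds (> 0).
#' @param moleculeId identifier stored on the path.
#' @param initialState optional state label overriding the stationary draw.
#' @return a \linkS4class{StatePath} with \code{source = "simulated"}.
#' @export
simulateStatePath <- function(model, duration, moleculeId = "sim",
                              initialState = NULL) {
  stopifnot(is(model, "KineticModel"))
  if (duration <= 0) stop("duration must be positive")
  states <- model@states
  n <- length(states)
  rates <- model@rates
  if (is.null(initialState)) {
    p0 <- tryCatch(as.numeric(ctmcStationary(model)), error = function(e) {
      mu <- embeddedStationary(model)
      if (is.null(mu)) rep(1 / n, n) else as.numeric(mu)
    })
    cur <- sample.int(n, 1L, prob = p0)
  } else {
    cur <- match(initialState, states)
    if (is.na(cur)) stop("unknown initial state: ", initialState)
  }
  st <- integer(0); t0 <- numeric(0); t1 <- numeric(0)
  now <- 0
  while (now < duration) {
    exit <- sum(rates[cur, ])
    if (exit == 0) {                      # absorbing: hold to the end
      st <- c(st, cur); t0 <- c(t0, now); t1 <- c(t1, duration)
      now <- duration
      break
    }
    wait <- stats::rexp(1L, rate = exit)
    end <- min(now + wait, duration)
    st <- c(st, cur); t0 <- c(t0, now); t1 <- c(t1, end)
    now <- end
    if (now < duration)
      cur <- sample.int(n, 1L, prob = rates[cur, ])
  }
  new("StatePath", moleculeId = moleculeId,
      segments = data.frame(state = states[st], start = t0, end = t1,
                            stringsAsFactors = FALSE),
      centers = stats::setNames(model@emissionMean, states),
      source = "simulated")
}

# occupancy-weighted per-frame mean of a per-state quantity `value`
frameOccupancyMean <- function(segments, stateIdx, value, nFrames, dt) {
  acc <- numeric(nFrames)
  for (i in seq_len(nrow(segments))) {
    v <- value[stateIdx[i]]
    f0 <- max(1L, floor(segments$start[i] / dt) + 1L)
    f1 <- min(nFrames, ceiling(segments$end[i] / dt - 1e-12))
    if (f1 < f0) next
    fr <- f0:f1
    ov <- pmin(segments$end[i], fr * dt) - pmax(segments$start[i], (fr - 1) * dt)
    acc[fr] <- acc[fr] + v * ov / dt
  }
  acc
}

#' Render camera intensities from a state path
#'
#' Camera model behind the simulator: each frame integrates the FRET level
#' over its exposure, so a frame spanning a transition carries the
#' occupancy-weighted mean of the two state levels (the blurred transition
#' frames seen in real traces). Per-frame emission jitter with the
#' occupancy-weighted state spread is added to the level, then
#' \code{donor = total * (1 - E) + noise} and
#' \code{acceptor = total * E + noise} with independent Gaussian channel
#' noise. When \code{bleachLifetime} is set an exponential bleach time is
#' drawn and both channels carry noise only from the first fully dark frame
#' on; that frame index is stored as the trace's \code{bleachFrame} ground
#' truth.
#'
#' Uses the current RNG; seed upstream for reproducibility.
#'
#' @param path a \linkS4class{StatePath} (simulated truth).
#' @param config a \linkS4class{SimulationConfig}.
#' @param model optional \linkS4class{KineticModel} supplying emission
#'   spreads (defaults to \code{config@model}).
#' @return a \linkS4class{FretTrace}.
#' @export
renderIntensities <- function(path, config, model = config@model) {
  stopifnot(is(path, "StatePath"), is(config, "SimulationConfig"))
  dt <- config@frameInterval
  if (dt <= 0) stop("frameInterval must be positive")
  seg <- path@segments
  dur <- seg$end[nrow(seg)]
  if (dur < dt) stop("path shorter than one frame interval")
  nFrames <- floor(dur / dt + 1e-9)
  idx <- match(seg$state, model@states)
  eMean <- frameOccupancyMean(seg, idx, model@emissionMean, nFrames, dt)
  eSd <- frameOccupancyMean(seg, idx, model@emissionSd, nFrames, dt)
  e <- eMean + stats::rnorm(nFrames, 0, 1) * eSd
  signal <- rep(1, nFrames)
  bleach <- NA_integer_
  if (!is.na(config@bleachLifetime)) {
    tb <- stats::rexp(1L, rate = 1 / config@bleachLifetime)
    bf <- as.integer(floor(tb / dt) + 1)
    if (bf <= nFrames) {
      bleach <- bf
      signal[bf:nFrames] <- 0
    }
  }
  noise <- config@intensityNoiseSd
  donor <- config@totalIntensity * (1 - e) * signal +
    stats::rnorm(nFrames, 0, 1) * noise
  acceptor <- config@totalIntensity * e * signal +
    stats::rnorm(nFrames, 0, 1) * noise
  new("FretTrace", moleculeId = path@moleculeId, frameInterval = dt,
      donor = donor, acceptor = acceptor, bleachFrame = bleach)
}

#' Simulate a complete trace set
#'
#' Generates \code{nMolecules} traces under the model: the first
#' \code{floor(dockedFraction * n)} molecules are rendered static (all rates
#' zeroed, state frozen at a draw from the model's docked occupancy vector,
#' or its stationary occupancy when none is set), the rest follow the full
#' Markov dynamics. The returned set's
#' \code{groundTruth()} records every state path, docked flag and bleach
#' frame; its manifest records the condition labels and the seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param label condition label stored in the manifest (default "synthetic").
#' @return a \linkS4class{TraceSet} with ground truth attached.
#' @examples
#' cfg <- simulationConfig(presetModel("TelG5"), nMolecules = 4,
#'                         duration = 20, seed = 7)
#' simulateDataset(cfg)
#' @export
simulateDataset <- function(config, label = "synthetic") {
  stopifnot(is(config, "SimulationConfig"))
  model <- config@model
  set.seed(config@seed)
  n <- config@nMolecules
  nDocked <- floor(model@dockedFraction * n)
  occ <- if (length(model@dockedOccupancy)) model@dockedOccupancy
  else tryCatch(as.numeric(ctmcStationary(model)), error = function(e) NULL)
  if (is.null(occ)) occ <- rep(1 / length(model@states), length(model@states))
  ids <- sprintf("mol%04d", seq_len(n))
  paths <- vector("list", n)
  trs <- vector("list", n)
  docked <- seq_len(n) <= nDocked
  for (i in seq_len(n)) {
    if (docked[i]) {
      s <- model@states[sample.int(length(model@states), 1L, prob = occ)]
      paths[[i]] <- new("StatePath", moleculeId = ids[i],
                        segments = data.frame(state = s, start = 0,
                                              end = config@duration,
                                              stringsAsFactors = FALSE),
                        centers = stats::setNames(model@emissionMean,
                                                  model@states),
                        source = "simulated")
    } else {
      paths[[i]] <- simulateStatePath(model, config@duration,
                                      moleculeId = ids[i])
    }
    trs[[i]] <- renderIntensities(paths[[i]], config, model)
  }
  names(paths) <- ids
  bleach <- stats::setNames(vapply(trs, function(x) x@bleachFrame,
                                   integer(1)), ids)
  new("TraceSet", traces = trs,
      manifest = list(condition = label,
                      construct = label,
                      seed = config@seed,
                      frame_interval = config@frameInterval,
                      duration = config@duration),
      truth = list(paths = paths,
                   docked = stats::setNames(docked, ids),
                   bleachFrame = bleach))
}

#' Simulate a binding titration
#'
#' Generative counterpart of the one-site specific binding model: bound
#' fraction \code{Y = bmax * X / (kd + X)} with optional additive Gaussian
#' noise, clipped to [0, 1].
#'
#' Uses the current RNG; seed with \code{set.seed()} for reproducibility.
#'
#' @param kd true dissociation constant in nM (> 0).
#' @param bmax saturation level (default 1).
#' @param concentrations protein concentrations in nM (default the
#'   9-point titration grid 0-1000 nM).
#' @param noiseSd additive noise sd on the bound fraction (default 0).
#' @param construct label stored on the curve.
#' @return a \linkS4class{BindingCurve} (unfitted).
#' @examples
#' simulateBindingCurve(456)
#' @export
simulateBindingCurve <- function(kd, bmax = 1,
                                 concentrations = c(0, 5, 10, 20, 50, 100,
                                                    200, 500, 1000),
                                 noiseSd = 0, construct = "synthetic") {
  if (kd <= 0) stop("kd must be positive")
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  y <- bmax * concentrations / (kd + concentrations)
  if (noiseSd > 0)
    y <- pmin(1, pmax(0, y + stats::rnorm(length(y), 0, noiseSd)))
  new("BindingCurve", construct = construct,
      concentrations = as.numeric(concentrations), boundFraction = y)
}
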