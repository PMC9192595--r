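# Shared fixtures: everything is generated in code at test time.

# a trace with constant donor/acceptor levels
constantTrace <- function(id = "m1", d = 500, a = 500, T = 100, dt = 0.1) {
  new("FretTrace", moleculeId = id, frameInterval = dt,
      donor = rep(d, T), acceptor = rep(a, T))
}

# wrap an efficiency series as a trajectory
makeTraj <- function(e, id = "m1", dt = 0.1, validUntil = length(e)) {
  new("FretTrajectory", moleculeId = id, frameInterval = dt,
      efficiency = e, validUntil = as.integer(validUntil))
}

# noise-free variant of a model (degenerate emission spread)
noiselessModel <- function(model) {
  kineticModel(stateLabels(model), transitionRates(model),
               model@emissionMean, emissionSd = 1e-8,
               dockedFraction = model@dockedFraction)
}

# exact (sampling-free) histogram of a Gaussian mixture on the default bins
exactMixtureHistogram <- function(centers, sds, weights,
                                  breaks = fretBreaks()) {
  dens <- numeric(length(breaks) - 1L)
  for (i in seq_along(centers))
    dens <- dens + weights[i] *
      diff(stats::pnorm(breaks, centers[i], sds[i]))
  dens <- dens / diff(breaks)
  dens <- dens / sum(dens * diff(breaks))
  new("FretHistogram", breaks = breaks, density = dens,
      nMolecules = 1L, window = 2)
}

# per-frame state labels of a path on the frame grid
frameStates <- function(path, nFrames, dt = 0.1) {
  seg <- segments(path)
  mid <- (seq_len(nFrames) - 0.5) * dt
  seg$state[findInterval(mid, c(seg$start[1], seg$end),
                         rightmost.closed = TRUE)]
}

# noiseless, frame-aligned simulated molecules rendered to trajectories;
# returns truth paths and computed FRET trajectories
simulateNoiseless <- function(model, n, duration, seed, dt = 0.1) {
  mN <- noiselessModel(model)
  cfg <- simulationConfig(mN, nMolecules = n, duration = duration,
                          frameInterval = dt, intensityNoiseSd = 0,
                          seed = seed)
  set.seed(seed)
  paths <- lapply(sprintf("m%04d", seq_len(n)), function(id)
    snapToFrames(simulateStatePath(mN, duration, id), dt))
  trajs <- lapply(paths, function(p)
    computeFret(renderIntensities(p, cfg, mN)))
  list(paths = paths, trajs = trajs)
}
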