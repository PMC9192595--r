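#' FRET histogram bin edges
#'
#' Default binning: width 0.025 over [-0.2, 1.2], fine enough to resolve
#' conformational peaks 0.1 apart while keeping several bins per peak
#' width.
#'
#' @param binWidth bin width in FRET units.
#' @param range two-element FRET range.
#' @return numeric vector of bin edges.
#' @export
fretBreaks <- function(binWidth = 0.025, range = c(-0.2, 1.2)) {
  if (binWidth <= 0) stop("binWidth must be positive")
  seq(range[1], range[2], by = binWidth)
}

#' Compute the FRET efficiency trajectory of a trace
#'
#' Ratiometric efficiency with optional donor-leakage and detection
#' (gamma) corrections:
#' \deqn{E_t = (A_t - l D_t) / (\gamma D_t + A_t - l D_t)}
#' The defaults \code{leakage = 0}, \code{gamma = 1} give the plain ratio
#' \code{E = A / (D + A)}. Frames at or past the bleach index (the trace's
#' recorded \code{bleachFrame}, or \code{\link{detectBleach}} when none is
#' recorded) are invalid; a pre-bleach frame with zero total intensity is
#' marked \code{NA} with a warning. Efficiencies are clipped to
#' [-0.2, 1.2].
#'
#' @param trace a \linkS4class{FretTrace}.
#' @param leakage donor-to-acceptor leakage fraction.
#' @param gamma detection-correction factor.
#' @param dropFraction threshold passed to \code{\link{detectBleach}} when
#'   the trace has no recorded bleach frame.
#' @return a \linkS4class{FretTrajectory}.
#' @examples
#' tr <- new("FretTrace", moleculeId = "m1", donor = c(500, 500),
#'           acceptor = c(500, 500))
#' efficiency(computeFret(tr))
#' @export
computeFret <- function(trace, leakage = 0, gamma = 1, dropFraction = 0.3) {
  stopifnot(is(trace, "FretTrace"))
  T <- length(trace@donor)
  bf <- trace@bleachFrame
  if (is.na(bf) && T >= 2L) bf <- detectBleach(trace, dropFraction)
  validUntil <- if (is.na(bf)) T else bf - 1L
  d <- trace@donor
  a <- trace@acceptor
  num <- a - leakage * d
  den <- gamma * d + num
  e <- num / den
  zero <- den == 0
  if (any(zero[seq_len(validUntil)])) {
    warning("zero total intensity on pre-bleach frame(s) of molecule ",
            trace@moleculeId, "; marked invalid")
  }
  e[zero] <- NA_real_
  e <- pmin(1.2, pmax(-0.2, e))
  new("FretTrajectory", moleculeId = trace@moleculeId,
      frameInterval = trace@frameInterval, efficiency = e,
      validUntil = as.integer(validUntil))
}

#' Compute FRET trajectories for a whole set
#'
#' @param set a \linkS4class{TraceSet}.
#' @param ... passed on to \code{\link{computeFret}}.
#' @return list of \linkS4class{FretTrajectory}, named by molecule id.
#' @export
computeFretSet <- function(set, ...) {
  stopifnot(is(set, "TraceSet"))
  out <- lapply(set@traces, computeFret, ...)
  names(out) <- vapply(set@traces, moleculeId, character(1))
  out
}

#' Build an ensemble FRET histogram
#'
#' Pools the first \code{floor(window / frameInterval)} valid frames of
#' every trajectory (frame-pooling: every frame counts equally), bins the
#' efficiencies and normalises to unit area. The short default window keeps
#' the ensemble close to the initial equilibrium mixture, mirroring
#' short-movie histogram acquisition.
#'
#' @param trajectories list of \linkS4class{FretTrajectory}.
#' @param window seconds of each trajectory pooled (default 2).
#' @param breaks bin edges (default \code{\link{fretBreaks}()}).
#' @return a \linkS4class{FretHistogram}.
#' @export
buildHistogram <- function(trajectories, window = 2, breaks = fretBreaks()) {
  if (is(trajectories, "FretTrajectory")) trajectories <- list(trajectories)
  pooled <- unlist(lapply(trajectories, function(tr) {
    nw <- floor(window / tr@frameInterval)
    idx <- seq_len(min(nw, tr@validUntil))
    e <- tr@efficiency[idx]
    e[!is.na(e)]
  }), use.names = FALSE)
  if (length(pooled) == 0L)
    stop("no valid frames inside the histogram window")
  h <- graphics::hist(pooled, breaks = breaks, plot = FALSE)
  new("FretHistogram", breaks = breaks, density = h$density,
      nMolecules = length(trajectories), window = window)
}

gaussMixDensity <- function(x, center, sd, weight) {
  y <- numeric(length(x))
  for (i in seq_along(center))
    y <- y + weight[i] * stats::dnorm(x, center[i], sd[i])
  y
}

#' Fit an anchored multi-Gaussian mixture to a FRET histogram
#'
#' Nonlinear least squares of a sum of Gaussians to the binned density.
#' Anchored components have their centers constrained to within
#' \code{tolerance} of the supplied anchor (the protein-free peak
#' positions); \code{tolerance = 0} fixes them exactly. Free components
#' (e.g. an emerging bound-state peak) have unconstrained centers,
#' initialised at the largest positive residual of an anchored-only fit.
#' Populations are the component areas normalised to one. The fit is
#' deterministic: fixed initialisation rule, fixed bounded
#' Levenberg-Marquardt settings, no random restarts.
#'
#' @param hist a \linkS4class{FretHistogram}.
#' @param anchors named FRET centers (e.g. \code{defaultAnchors()}).
#' @param freeComponents number of unanchored components (default 0).
#' @param tolerance allowed anchor drift in FRET units (default 0.01).
#' @param sdInit initial component sd (default 0.05).
#' @param sdRange allowed component sd range.
#' @return a \linkS4class{MixtureFit}.
#' @examples
#' set.seed(1)
#' e <- rnorm(5000, 0.47, 0.05)
#' traj <- new("FretTrajectory", moleculeId = "m", frameInterval = 0.1,
#'             efficiency = pmin(1.2, pmax(-0.2, e)),
#'             validUntil = length(e))
#' fitMixture(buildHistogram(traj, window = 1e6), c(NP = 0.47))
#' @export
fitMixture <- function(hist, anchors, freeComponents = 0, tolerance = 0.01,
                       sdInit = 0.05, sdRange = c(0.01, 0.2)) {
  stopifnot(is(hist, "FretHistogram"))
  if (length(anchors) + freeComponents < 1L)
    stop("at least one anchored or free component required")
  if (tolerance < 0) stop("tolerance must be >= 0")
  mid <- (hist@breaks[-1] + hist@breaks[-length(hist@breaks)]) / 2
  y <- hist@density
  if (sum(y) == 0) stop("empty histogram")

  nA <- length(anchors)
  labels <- names(anchors)
  centers0 <- as.numeric(anchors)
  # initial weights: density mass near each anchor
  w0 <- vapply(centers0, function(c0) {
    sel <- abs(mid - c0) <= 2 * sdInit
    max(sum(y[sel]) * diff(hist@breaks)[1], 0.05)
  }, numeric(1))

  fitOnce <- function(centers, sds, weights, lowerC, upperC) {
    k <- length(centers)
    p0 <- c(centers, log(sds), weights)
    lower <- c(lowerC, rep(log(sdRange[1]), k), rep(0, k))
    upper <- c(upperC, rep(log(sdRange[2]), k), rep(Inf, k))
    fn <- function(p) {
      gaussMixDensity(mid, p[1:k], exp(p[(k + 1):(2 * k)]),
                      p[(2 * k + 1):(3 * k)]) - y
    }
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  }

  lowerA <- centers0 - tolerance
  upperA <- centers0 + tolerance
  fit <- fitOnce(centers0, rep(sdInit, nA), w0, lowerA, upperA)

  if (freeComponents > 0) {
    centers <- fit$par[1:nA]
    sds <- exp(fit$par[(nA + 1):(2 * nA)])
    weights <- fit$par[(2 * nA + 1):(3 * nA)]
    for (j in seq_len(freeComponents)) {
      k <- length(centers)
      resid <- y - gaussMixDensity(mid, centers, sds, weights)
      cNew <- mid[which.max(resid)]
      wNew <- max(max(resid) * sdInit * sqrt(2 * pi), 0.01)
      centers <- c(centers, cNew)
      sds <- c(sds, sdInit)
      weights <- c(weights, wNew)
      fit <- fitOnce(centers, sds, weights,
                     c(lowerA, rep(min(mid), j)),
                     c(upperA, rep(max(mid), j)))
      centers <- fit$par[1:(nA + j)]
      sds <- exp(fit$par[(nA + j + 1):(2 * (nA + j))])
      weights <- fit$par[(2 * (nA + j) + 1):(3 * (nA + j))]
    }
    labels <- c(labels, paste0("free", seq_len(freeComponents)))
  }
  k <- nA + freeComponents
  centers <- fit$par[1:k]
  sds <- exp(fit$par[(k + 1):(2 * k)])
  weights <- pmax(fit$par[(2 * k + 1):(3 * k)], 0)
  if (sum(weights) == 0) stop("mixture fit collapsed to zero weight")
  pop <- weights / sum(weights)
  new("MixtureFit",
      components = data.frame(label = labels, center = centers, sd = sds,
                              weight = weights, stringsAsFactors = FALSE),
      anchors = anchors,
      residual = sum(fit$fvec^2),
      population = stats::setNames(pop, labels))
}

#' Differential FRET density between two conditions
#'
#' Per-bin density difference (condition minus reference) on identical
#' bins, as used to visualise the bound-state mass appearing under
#' protein. \code{positiveSum} integrates the positive part of the
#' difference and serves as a proxy for the redirected (bound) fraction.
#'
#' @param withProtein condition \linkS4class{FretHistogram}.
#' @param reference reference \linkS4class{FretHistogram} on the same bins.
#' @return a \linkS4class{DifferentialHistogram}.
#' @export
differentialDensity <- function(withProtein, reference) {
  stopifnot(is(withProtein, "FretHistogram"), is(reference, "FretHistogram"))
  if (!isTRUE(all.equal(withProtein@breaks, reference@breaks,
                        tolerance = 0)) ||
      length(withProtein@breaks) != length(reference@breaks))
    stop("incompatible histograms: bin edges differ (no silent rebinning)")
  delta <- withProtein@density - reference@density
  w <- diff(withProtein@breaks)
  new("DifferentialHistogram", breaks = withProtein@breaks,
      deltaDensity = delta, positiveSum = sum(pmax(delta, 0) * w))
}
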