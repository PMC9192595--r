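coreStates <- c("UF", "NP", "P")
coreTransitionTypes <- c("UF->NP", "NP->UF", "UF->P", "P->UF",
                         "NP->P", "P->NP")

# analytic single-Gaussian "HMM" baseline used in model selection
fitK1 <- function(e, sdFloor) {
  mu <- mean(e)
  sd <- max(stats::sd(e), sdFloor)
  if (is.na(sd)) sd <- sdFloor
  ll <- sum(stats::dnorm(e, mu, sd, log = TRUE))
  list(K = 1L, pi = 1, A = matrix(1, 1, 1), mu = mu, sigma = sd,
       loglik = ll, bic = -2 * ll + 2 * log(length(e)))
}

# Deterministic k-means-style initialisation: farthest-point (maximin)
# seeding from the median, then Lloyd iterations with empty clusters
# reseeded at the worst-fit point. Maximin seeding finds rarely visited
# levels that quantile seeds miss under heavily skewed occupancy.
initMeans <- function(e, K, iter = 25L) {
  mu <- stats::median(e)
  while (length(mu) < K) {
    d <- do.call(pmin, lapply(mu, function(m) abs(e - m)))
    mu <- c(mu, e[which.max(d)])
  }
  for (i in seq_len(iter)) {
    assign <- max.col(-abs(outer(e, mu, "-")), ties.method = "first")
    newMu <- mu
    for (k in seq_len(K)) {
      sel <- assign == k
      if (any(sel)) newMu[k] <- mean(e[sel])
      else newMu[k] <- e[which.max(abs(e - mu[assign]))]
    }
    if (max(abs(newMu - mu)) < 1e-10) { mu <- newMu; break }
    mu <- newMu
  }
  sort(mu)
}

# EM fit of a K-state Gaussian-emission HMM with deterministic
# quantile/k-means initialisation; iteration loop runs compiled.
fitHmmK <- function(e, K, maxIter = 100, tol = 1e-6, sdFloor = 0.005) {
  T <- length(e)
  mu <- initMeans(e, K)
  sigma <- rep(max(stats::sd(e) / K, 0.02), K)
  A <- matrix(0.05 / (K - 1), K, K)
  diag(A) <- 0.95
  pi <- rep(1 / K, K)
  fit <- hmm_fit(e, pi, A, mu, sigma, as.integer(maxIter), tol, sdFloor)
  p <- (K - 1) + K * (K - 1) + 2 * K
  list(K = K, pi = fit$pi, A = fit$A, mu = fit$mu, sigma = fit$sigma,
       loglik = fit$loglik, bic = -2 * fit$loglik + p * log(T))
}

#' Infer the hidden state path of a FRET trajectory
#'
#' Maximum-likelihood segmentation of one efficiency trajectory: for each
#' candidate state count K a Gaussian-emission hidden Markov model is fit
#' by expectation-maximisation (deterministic initialisation from the
#' efficiency quantiles, fixed iteration and tolerance settings), a
#' single-Gaussian baseline is always included, and the state count is
#' selected by BIC. The most probable (Viterbi) state sequence is collapsed
#' into contiguous segments. Fitted states whose emission means lie within
#' \code{mergeTol} of each other are merged before segmentation, so the
#' reported state count can fall below the selected K.
#'
#' @param traj a \linkS4class{FretTrajectory} with at least 20 valid frames.
#' @param kRange candidate state counts (default 2:4; a 1-state baseline is
#'   always considered).
#' @param mergeTol minimum emission-center separation of distinct states.
#' @param maxIter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param details if \code{TRUE}, also return the model-selection report.
#' @return a \linkS4class{StatePath} with \code{source = "inferred"} and
#'   per-state emission centers, or (with \code{details}) a list with
#'   elements \code{path} and \code{report}.
#' @export
inferStatePath <- function(traj, kRange = 2:4, mergeTol = 0.02,
                           maxIter = 100, tol = 1e-6, details = FALSE) {
  stopifnot(is(traj, "FretTrajectory"))
  e <- traj@efficiency[seq_len(traj@validUntil)]
  # carry the last valid efficiency over rare invalid frames to keep the
  # chain contiguous
  if (anyNA(e)) {
    ok <- which(!is.na(e))
    if (length(ok) == 0L) stop("no valid frames to segment")
    e <- e[cummax(ifelse(is.na(e), 0L, seq_along(e)))]
    e[seq_len(ok[1])] <- e[ok[1]]
  }
  if (length(e) < 20L) stop("state-path inference needs >= 20 valid frames")

  fits <- c(list(fitK1(e, 0.005)),
            lapply(sort(unique(as.integer(kRange))), function(K)
              fitHmmK(e, K, maxIter = maxIter, tol = tol)))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]

  if (best$K == 1L) {
    states <- as.integer(rep(1, length(e)))
    mu <- best$mu
  } else {
    states <- hmm_viterbi(e, best$pi, best$A, best$mu, best$sigma)
    mu <- best$mu
    # merge indistinguishable states (closest pair first)
    repeat {
      ks <- sort(unique(states))
      if (length(ks) < 2L) break
      mus <- mu[ks]
      d <- abs(outer(mus, mus, "-"))
      diag(d) <- Inf
      if (min(d) >= mergeTol) break
      ij <- which(d == min(d), arr.ind = TRUE)[1, ]
      a <- ks[min(ij)]; b <- ks[max(ij)]
      na <- sum(states == a); nb <- sum(states == b)
      mu[a] <- (mu[a] * na + mu[b] * nb) / (na + nb)
      states[states == b] <- a
    }
  }
  ks <- sort(unique(states))
  ord <- ks[order(mu[ks])]
  lab <- paste0("S", seq_along(ord))
  relabel <- stats::setNames(lab, as.character(ord))
  stateLab <- relabel[as.character(states)]
  centers <- stats::setNames(mu[ord], lab)

  r <- rle(stateLab)
  endFrame <- cumsum(r$lengths)
  startFrame <- c(0L, endFrame[-length(endFrame)])
  dt <- traj@frameInterval
  path <- new("StatePath", moleculeId = traj@moleculeId,
              segments = data.frame(state = unname(r$values),
                                    start = startFrame * dt,
                                    end = endFrame * dt,
                                    stringsAsFactors = FALSE),
              centers = centers, source = "inferred")
  if (!details) return(path)
  report <- data.frame(
    K = vapply(fits, `[[`, numeric(1), "K"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    bic = bics,
    selected = seq_along(fits) == which.min(bics))
  list(path = path, report = report, nStates = length(ord))
}

#' Classify a trajectory as docked or transitioning
#'
#' Automated version of the docked vs transitioning call: a molecule is
#' transitioning iff its inferred state path within the first
#' \code{window} seconds contains at least one state change whose
#' emission-center jump exceeds \code{minJump}. A two-level segmentation
#' (against the one-state baseline) suffices to detect any such jump, so
#' \code{kRange = 2} is the default here.
#'
#' @param traj a \linkS4class{FretTrajectory} with >= 2 valid frames in the
#'   window.
#' @param window seconds inspected (default 100); when the trace is
#'   shorter, the available valid frames are used with a warning.
#' @param minJump minimum FRET jump that counts as a transition.
#' @param kRange candidate state counts for the segmentation.
#' @return \code{"docked"} or \code{"transitioning"}.
#' @export
classifyTrajectory <- function(traj, window = 100, minJump = 0.1,
                               kRange = 2) {
  stopifnot(is(traj, "FretTrajectory"))
  nw <- floor(window / traj@frameInterval)
  nUse <- min(nw, traj@validUntil)
  if (nUse < nw)
    warning("trace '", traj@moleculeId,
            "' shorter than the classification window; using ", nUse,
            " frames")
  sub <- new("FretTrajectory", moleculeId = traj@moleculeId,
             frameInterval = traj@frameInterval,
             efficiency = traj@efficiency[seq_len(nUse)],
             validUntil = as.integer(nUse))
  if (sum(!is.na(sub@efficiency)) < 2L)
    stop("classification needs at least two valid frames")
  if (sum(!is.na(sub@efficiency)) < 20L) return("docked")
  path <- inferStatePath(sub, kRange = kRange)
  if (hasJump(path, minJump)) "transitioning" else "docked"
}

hasJump <- function(path, minJump) {
  seg <- path@segments
  if (nrow(seg) < 2L) return(FALSE)
  lev <- path@centers[seg$state]
  any(abs(diff(lev)) > minJump)
}

#' Label inferred states against FRET anchors
#'
#' Maps every inferred state to the anchor (UF/NP/P/BD level) with minimal
#' center distance; ties break toward the lower-efficiency anchor; states
#' farther than \code{maxDist} from every anchor are labelled
#' \code{"other"}. Adjacent segments that end up with the same label are
#' merged. The relabelled path keeps one emission center per label (the
#' occupancy-weighted mean of the merged inferred centers).
#'
#' @param path a \linkS4class{StatePath} with inferred emission centers.
#' @param anchors named anchor levels, e.g. \code{defaultAnchors()}.
#' @param maxDist maximum anchor distance before a state is "other".
#' @return the relabelled \linkS4class{StatePath}.
#' @export
assignStateLabels <- function(path, anchors, maxDist = 0.08) {
  stopifnot(is(path, "StatePath"))
  if (length(anchors) == 0L) stop("anchors must be non-empty")
  ord <- order(as.numeric(anchors))   # lower-E anchors first for tie-breaks
  anchors <- anchors[ord]
  lab <- vapply(path@centers, function(cc) {
    d <- round(abs(cc - as.numeric(anchors)), 9)  # robust exact-tie handling
    if (min(d) > maxDist) "other" else names(anchors)[which.min(d)]
  }, character(1))
  seg <- path@segments
  seg$state <- unname(lab[seg$state])
  # occupancy-weighted centers per label
  occ <- tapply(path@segments$end - path@segments$start,
                path@segments$state, sum)
  centers <- vapply(split(names(lab), lab), function(src) {
    w <- as.numeric(occ[src])
    sum(path@centers[src] * w) / sum(w)
  }, numeric(1))
  # merge adjacent segments sharing a label
  keep <- c(TRUE, seg$state[-1] != seg$state[-nrow(seg)])
  idx <- cumsum(keep)
  merged <- data.frame(
    state = seg$state[keep],
    start = tapply(seg$start, idx, min),
    end = tapply(seg$end, idx, max),
    stringsAsFactors = FALSE, row.names = NULL)
  new("StatePath", moleculeId = path@moleculeId, segments = merged,
      centers = centers, source = path@source)
}

#' Count transition types over labelled paths
#'
#' Tallies adjacent-segment label pairs. The six ordered UF/NP/P types form
#' the core counts; transitions involving the bound (BD) state or
#' unassigned ("other") levels are tallied separately and excluded from
#' the core total.
#'
#' @param paths a labelled \linkS4class{StatePath} or list of them.
#' @return a \linkS4class{TransitionCounts}.
#' @examples
#' p <- new("StatePath", moleculeId = "m",
#'          segments = data.frame(state = c("UF", "NP", "UF", "P"),
#'                                start = 0:3, end = 1:4),
#'          centers = c(UF = 0.24, NP = 0.47, P = 0.66),
#'          source = "simulated")
#' countTransitions(p)
#' @export
countTransitions <- function(paths) {
  if (is(paths, "StatePath")) paths <- list(paths)
  counts <- stats::setNames(numeric(length(coreTransitionTypes)),
                            coreTransitionTypes)
  extra <- numeric(0)
  for (p in paths) {
    st <- p@segments$state
    if (length(st) < 2L) next
    pair <- paste0(st[-length(st)], "->", st[-1])
    for (pp in pair) {
      if (pp %in% coreTransitionTypes) counts[pp] <- counts[pp] + 1
      else extra[pp] <- if (is.na(extra[pp])) 1 else extra[pp] + 1
    }
  }
  new("TransitionCounts", counts = counts, extra = extra,
      nTransitions = sum(counts))
}

#' Dwell-time table with censoring
#'
#' Emits every dwell of every path. The first and last segment of each
#' trace are flagged censored (their true duration is truncated by the
#' observation window) and excluded from the per-state means; a state with
#' no uncensored dwell has an undefined (NA) mean. Under Markov dynamics
#' the exponential maximum-likelihood rate is 1/mean.
#'
#' @param paths a labelled \linkS4class{StatePath} or list of them.
#' @return a \linkS4class{DwellTable}.
#' @export
dwellAnalysis <- function(paths) {
  if (is(paths, "StatePath")) paths <- list(paths)
  rows <- do.call(rbind, lapply(paths, function(p) {
    seg <- p@segments
    n <- nrow(seg)
    if (n == 0L) return(NULL)
    data.frame(moleculeId = p@moleculeId, state = seg$state,
               duration = seg$end - seg$start,
               censored = seq_len(n) %in% c(1L, n),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(moleculeId = character(), state = character(),
                       duration = numeric(), censored = logical())
  states <- unique(rows$state)
  means <- vapply(states, function(s) {
    d <- rows$duration[rows$state == s & !rows$censored]
    if (length(d) == 0L) NA_real_ else mean(d)
  }, numeric(1))
  new("DwellTable", rows = rows, means = stats::setNames(means, states))
}

#' Transition density plot
#'
#' One point per state change at (emission center before, emission center
#' after), binned on the FRET grid and normalised to unit total mass. The
#' diagonal is empty by construction since adjacent segments always differ.
#'
#' @param paths a labelled \linkS4class{StatePath} or list of them.
#' @param breaks FRET bin edges (default \code{\link{fretBreaks}()}).
#' @return list with \code{density} (matrix, rows = E before, columns =
#'   E after, summing to 1), \code{breaks}, \code{nTransitions} and
#'   \code{empty} (TRUE when no transition was seen).
#' @export
transitionDensityPlot <- function(paths, breaks = fretBreaks()) {
  if (is(paths, "StatePath")) paths <- list(paths)
  before <- numeric(0); after <- numeric(0)
  for (p in paths) {
    st <- p@segments$state
    if (length(st) < 2L) next
    lev <- unname(p@centers[st])
    before <- c(before, lev[-length(lev)])
    after <- c(after, lev[-1])
  }
  nb <- length(breaks) - 1L
  dens <- matrix(0, nb, nb)
  if (length(before) == 0L)
    return(list(density = dens, breaks = breaks, nTransitions = 0L,
                empty = TRUE))
  i <- findInterval(before, breaks, rightmost.closed = TRUE)
  j <- findInterval(after, breaks, rightmost.closed = TRUE)
  ok <- i >= 1 & i <= nb & j >= 1 & j <= nb
  for (t in which(ok)) dens[i[t], j[t]] <- dens[i[t], j[t]] + 1
  list(density = dens / sum(dens), breaks = breaks,
       nTransitions = length(before), empty = FALSE)
}

#' NP-P direct-transition density
#'
#' The comparative dynamics statistic: the relative fraction of NP->P plus
#' P->NP transitions (over the six core UF/NP/P types; bound-state
#' transitions are excluded) multiplied by the fraction of molecules that
#' transition at all. Defined as 0 when no molecule transitions.
#'
#' @param counts a \linkS4class{TransitionCounts} from the transitioning
#'   molecules.
#' @param nTotal total molecules observed.
#' @param nTransitioning molecules classified as transitioning.
#' @param label condition label.
#' @return a \linkS4class{DynamicsSummary}.
#' @examples
#' ct <- new("TransitionCounts",
#'           counts = c("UF->NP" = 5, "NP->UF" = 0, "UF->P" = 0,
#'                      "P->UF" = 0, "NP->P" = 3, "P->NP" = 2),
#'           extra = numeric(0), nTransitions = 10)
#' directDensity(directTransitionDensity(ct, 10, 5))   # 0.5 * 5/10
#' @export
directTransitionDensity <- function(counts, nTotal, nTransitioning,
                                    label = "condition") {
  stopifnot(is(counts, "TransitionCounts"))
  frac <- if (nTotal > 0) nTransitioning / nTotal else 0
  dd <- if (counts@nTransitions > 0)
    frac * (counts@counts[["NP->P"]] + counts@counts[["P->NP"]]) /
      counts@nTransitions
  else 0
  new("DynamicsSummary", label = label, nTotal = as.integer(nTotal),
      nTransitioning = as.integer(nTransitioning),
      fractionTransitioning = frac, directDensity = dd)
}

#' Snap a state path to the camera frame grid
#'
#' Rounds every segment boundary to the nearest frame edge, dropping
#' segments that collapse to zero length and merging resulting
#' same-state neighbours. Useful for constructing traces whose transitions
#' align with frame boundaries (no blurred transition frames).
#'
#' @param path a \linkS4class{StatePath}.
#' @param frameInterval frame duration in seconds.
#' @return a \linkS4class{StatePath} on the frame grid.
#' @export
snapToFrames <- function(path, frameInterval) {
  seg <- path@segments
  nFrames <- round(seg$end[nrow(seg)] / frameInterval)
  mid <- (seq_len(nFrames) - 0.5) * frameInterval
  stateAt <- seg$state[findInterval(mid, c(seg$start[1], seg$end),
                                    rightmost.closed = TRUE)]
  r <- rle(stateAt)
  ends <- cumsum(r$lengths) * frameInterval
  starts <- c(0, ends[-length(ends)])
  new("StatePath", moleculeId = path@moleculeId,
      segments = data.frame(state = r$values, start = starts, end = ends,
                            stringsAsFactors = FALSE),
      centers = path@centers, source = path@source)
}

#' Run the full per-trajectory kinetics pipeline
#'
#' Classifies every trajectory as docked or transitioning, infers and
#' labels the state paths of the transitioning molecules over their full
#' valid length, and assembles the transition counts, dwell table,
#' transition density plot and dynamics summary.
#'
#' @param trajectories list of \linkS4class{FretTrajectory} (e.g. from
#'   \code{\link{computeFretSet}}).
#' @param anchors named FRET anchors for labelling.
#' @param kRange HMM state counts tried per trace.
#' @param classificationWindow seconds used for the docked call.
#' @param minJump minimum FRET jump counting as a transition.
#' @param label condition label for the summary.
#' @return list with \code{classification} (named character),
#'   \code{paths} (labelled \linkS4class{StatePath} per transitioning
#'   molecule), \code{counts}, \code{dwell}, \code{tdp} and
#'   \code{summary}.
#' @export
analyzeKinetics <- function(trajectories, anchors = defaultAnchors(),
                            kRange = 2:4, classificationWindow = 100,
                            minJump = 0.1, label = "condition") {
  cls <- vapply(trajectories, classifyTrajectory,
                character(1), window = classificationWindow,
                minJump = minJump)
  names(cls) <- vapply(trajectories, function(x) x@moleculeId, character(1))
  trans <- trajectories[cls == "transitioning"]
  paths <- lapply(trans, function(tr)
    assignStateLabels(inferStatePath(tr, kRange = kRange), anchors))
  names(paths) <- names(cls)[cls == "transitioning"]
  counts <- countTransitions(paths)
  list(classification = cls,
       paths = paths,
       counts = counts,
       dwell = dwellAnalysis(paths),
       tdp = transitionDensityPlot(paths),
       summary = directTransitionDensity(counts, length(trajectories),
                                         sum(cls == "transitioning"),
                                         label = label))
}
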