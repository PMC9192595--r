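#' Default FRET anchors of the telomeric G-quadruplex states
#'
#' FRET levels of the unfolded (UF), non-parallel (NP), parallel (P) and
#' protein-bound (BD) states used throughout the pipeline for anchored
#' Gaussian fits and state labelling.
#'
#' @param includeBD include the bound-state anchor at 0.57.
#' @return named numeric vector of FRET anchors.
#' @examples
#' defaultAnchors()
#' @export
defaultAnchors <- function(includeBD = FALSE) {
  a <- c(UF = 0.24, NP = 0.47, P = 0.66)
  if (includeBD) a <- c(a, BD = 0.57)
  a
}

#' Construct a kinetic model
#'
#' Builds a \linkS4class{KineticModel} from state labels, a per-second rate
#' matrix and per-state Gaussian emission parameters.
#'
#' @param states ordered state labels.
#' @param rates n x n non-negative rate matrix (diagonal zero; it is zeroed
#'   if supplied non-zero).
#' @param emissionMean per-state FRET level.
#' @param emissionSd per-state FRET spread (recycled; default 0.05).
#' @param dockedFraction fraction of molecules simulated static (default 0).
#' @param dockedOccupancy optional state distribution for the docked
#'   subpopulation.
#' @return a \linkS4class{KineticModel}.
#' @examples
#' kineticModel(c("NP", "P"), matrix(c(0, .2, .1, 0), 2, byrow = TRUE),
#'              c(0.47, 0.66))
#' @export
kineticModel <- function(states, rates, emissionMean, emissionSd = 0.05,
                         dockedFraction = 0, dockedOccupancy = numeric(0)) {
  rates <- as.matrix(rates)
  if (any(rates < 0)) stop("transition rates must be non-negative")
  diag(rates) <- 0
  dimnames(rates) <- list(states, states)
  new("KineticModel", states = as.character(states), rates = rates,
      emissionMean = as.numeric(emissionMean),
      emissionSd = rep_len(as.numeric(emissionSd), length(states)),
      dockedFraction = dockedFraction,
      dockedOccupancy = as.numeric(dockedOccupancy))
}

#' Mean dwell time per state
#'
#' Under Markov dynamics the dwell in state i is exponential with mean
#' 1/sum_j k(i -> j); absorbing states (all-zero rate row) have infinite
#' mean dwell.
#'
#' @param model a \linkS4class{KineticModel}.
#' @return named numeric vector of mean dwell times in seconds.
#' @export
meanDwellTimes <- function(model) {
  stopifnot(is(model, "KineticModel"))
  r <- rowSums(model@rates)
  out <- ifelse(r > 0, 1 / r, Inf)
  names(out) <- model@states
  out
}

#' Stationary distribution of the continuous-time chain
#'
#' Solves pi Q = 0 with Q the generator (rates with diagonal set to minus
#' the row sum), normalised to sum to 1. Requires every state to have at
#' least one exit; used as the independent occupancy oracle for the
#' simulator.
#'
#' @param model a \linkS4class{KineticModel}.
#' @return named stationary probabilities.
#' @export
ctmcStationary <- function(model) {
  stopifnot(is(model, "KineticModel"))
  n <- length(model@states)
  if (n == 1L) return(stats::setNames(1, model@states))
  Q <- model@rates
  diag(Q) <- -rowSums(Q)
  if (any(rowSums(model@rates) == 0))
    stop("stationary distribution undefined: absorbing state present")
  # solve pi Q = 0, sum(pi) = 1 by replacing one balance equation
  A <- t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  pi <- solve(A, b)
  stats::setNames(pmax(pi, 0) / sum(pmax(pi, 0)), model@states)
}

#' Stationary distribution of the embedded jump chain
#'
#' The jump chain moves i -> j with probability k(i -> j) / sum_j k(i -> j).
#' Its stationary vector (when it exists) seeds the initial state of
#' simulated paths; when it does not (an absorbing state), a uniform draw
#' is used instead.
#'
#' @param model a \linkS4class{KineticModel}.
#' @return named stationary probabilities of the jump chain, or NULL when
#'   undefined.
#' @export
embeddedStationary <- function(model) {
  stopifnot(is(model, "KineticModel"))
  n <- length(model@states)
  if (n == 1L) return(stats::setNames(1, model@states))
  r <- rowSums(model@rates)
  if (any(r == 0)) return(NULL)
  P <- model@rates / r
  A <- t(P) - diag(n)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  mu <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(mu)) return(NULL)
  stats::setNames(pmax(mu, 0) / sum(pmax(mu, 0)), model@states)
}

# Build a 3-state UF/NP/P rate matrix from mean dwells and direct-transition
# branching. `direct` is the probability that a molecule leaving NP goes
# straight to P (and vice versa) rather than unfolding first; `ufToNP` splits
# refolding from UF between the two folded conformations.
g4RateMatrix <- function(dwellUF, dwellNP, dwellP, direct, ufToNP = 0.6) {
  k <- matrix(0, 3, 3)
  k[1, 2] <- ufToNP / dwellUF          # UF -> NP
  k[1, 3] <- (1 - ufToNP) / dwellUF    # UF -> P
  k[2, 1] <- (1 - direct) / dwellNP    # NP -> UF
  k[2, 3] <- direct / dwellNP          # NP -> P
  k[3, 1] <- (1 - direct) / dwellP     # P -> UF
  k[3, 2] <- direct / dwellP           # P -> NP
  k
}

#' Preset kinetic models of the telomeric repeat variants
#'
#' Three-state (UF/NP/P) models parameterised for the telomere-variant
#' constructs characterised by smFRET: mean dwell times per conformation,
#' FRET emission levels at the canonical anchors, and the balance between
#' direct NP<->P interconversion and unfolding-mediated rearrangement. The
#' loop variants with shortened loops (TelG5TTT, TelG5TT) interconvert
#' mostly directly between the two folded conformations, whereas TelG5 and
#' TelG5TAA mostly rearrange through the unfolded state; this is what the
#' transition-density plots and the NP-P direct-transition-density
#' statistic probe.
#'
#' The dynamic subpopulation carries the construct's dwell-time kinetics;
#' the docked (static) subpopulation gets its own occupancy vector, solved
#' so that the overall short-window histogram fractions
#' \code{docked * occupancy + (1 - docked) * stationary} reproduce the
#' construct's ensemble conformational fractions (entries clipped at zero
#' and renormalised where the two are not jointly realisable).
#'
#' @param construct one of "TelG5", "TelG5TAA", "TelG5TTT", "TelG5TT".
#' @param dockedFraction static-molecule fraction (default 0.52).
#' @param emissionSd per-state FRET spread (default 0.05).
#' @return a \linkS4class{KineticModel}.
#' @examples
#' presetModel("TelG5")
#' @export
presetModel <- function(construct = c("TelG5", "TelG5TAA", "TelG5TTT",
                                      "TelG5TT"),
                        dockedFraction = 0.52, emissionSd = 0.05) {
  construct <- match.arg(construct)
  # per construct: mean dwell (s) per state, direct NP<->P branching,
  # UF->NP refolding split, and target ensemble fractions (UF, NP, P).
  # UF dwell is 4.3 s for TelG5TAA and a quarter of that for the others.
  par <- switch(construct,
    TelG5    = list(dw = c(1.1, 7.6, 10.3), direct = 0.15, u = 0.70,
                    frac = c(0.06, 0.57, 0.37)),
    TelG5TAA = list(dw = c(4.3, 6.1, 11.1), direct = 0.05, u = 0.50,
                    frac = c(0.11, 0.66, 0.23)),
    TelG5TTT = list(dw = c(1.1, 2.3,  5.2), direct = 0.75, u = 0.60,
                    frac = c(0.08, 0.46, 0.46)),
    TelG5TT  = list(dw = c(1.1, 2.1,  4.3), direct = 0.85, u = 0.60,
                    frac = c(0.07, 0.40, 0.53)))
  rates <- g4RateMatrix(par$dw[1], par$dw[2], par$dw[3], par$direct, par$u)
  model <- kineticModel(c("UF", "NP", "P"), rates,
                        emissionMean = c(0.24, 0.47, 0.66),
                        emissionSd = emissionSd,
                        dockedFraction = dockedFraction)
  if (dockedFraction > 0) {
    piDyn <- as.numeric(ctmcStationary(model))
    occ <- pmax(par$frac - (1 - dockedFraction) * piDyn, 0) / dockedFraction
    model@dockedOccupancy <- occ / sum(occ)
    validObject(model)
  }
  model
}

#' Extend a model with the protein-bound state
#'
#' Adds the BD (bound) state as a plain fourth Markov state entered from the
#' NP and P conformations, reflecting that binding is observed right after
#' NP<->P transitions. Rates default to symmetric entry from NP and P.
#'
#' @param model a 3-state \linkS4class{KineticModel} with states UF, NP, P.
#' @param kOn per-second entry rate into BD from each of NP and P.
#' @param kOff per-second exit rate from BD (split equally back to NP and P).
#' @param emissionMean FRET level of the bound state (default 0.57).
#' @param emissionSd FRET spread of the bound state.
#' @return a 4-state \linkS4class{KineticModel}.
#' @export
withBoundState <- function(model, kOn = 0.1, kOff = 0.1,
                           emissionMean = 0.57, emissionSd = 0.05) {
  stopifnot(is(model, "KineticModel"),
            identical(model@states, c("UF", "NP", "P")))
  if (kOn < 0 || kOff < 0) stop("binding rates must be non-negative")
  r <- matrix(0, 4, 4)
  r[1:3, 1:3] <- model@rates
  r[2, 4] <- kOn
  r[3, 4] <- kOn
  r[4, 2] <- kOff / 2
  r[4, 3] <- kOff / 2
  kineticModel(c("UF", "NP", "P", "BD"), r,
               emissionMean = c(model@emissionMean, emissionMean),
               emissionSd = c(model@emissionSd, emissionSd),
               dockedFraction = model@dockedFraction,
               dockedOccupancy = if (length(model@dockedOccupancy))
                 c(model@dockedOccupancy, 0) else numeric(0))
}
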