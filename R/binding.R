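#' Fit a one-site specific binding curve
#'
#' Nonlinear least squares of \eqn{Y = B_{max} X / (K_d + X)} to a
#' titration of bound fractions. By default \code{Bmax} is fixed to 1 (the
#' saturation constraint); with \code{fixBmax = FALSE} it is estimated.
#' Initialisation is deterministic: the starting \eqn{K_d} is the
#' concentration whose response is nearest half of the maximum observed
#' bound fraction. Concentrations in micromolar can be supplied with
#' \code{unit = "uM"}; everything is fit and reported in nM.
#'
#' @param curve a \linkS4class{BindingCurve}, or a numeric vector of
#'   concentrations when \code{boundFraction} is given.
#' @param boundFraction bound fractions when \code{curve} is numeric.
#' @param fixBmax fix the saturation level to 1 (default TRUE).
#' @param unit concentration unit of numeric input, \code{"nM"} or
#'   \code{"uM"}.
#' @param construct label for the result when input is numeric.
#' @return the \linkS4class{BindingCurve} with \code{kd} (nM), \code{bmax},
#'   asymptotic \code{kdSe} and residuals filled in.
#' @examples
#' cv <- simulateBindingCurve(456)
#' kdEstimate(fitKd(cv))
#' @export
fitKd <- function(curve, boundFraction = NULL, fixBmax = TRUE, unit = "nM",
                  construct = "curve") {
  if (is.numeric(curve)) {
    conc <- curve
    if (unit == "uM") conc <- conc * 1000
    else if (unit != "nM") stop("unit must be 'nM' or 'uM'")
    curve <- new("BindingCurve", construct = construct,
                 concentrations = as.numeric(conc),
                 boundFraction = as.numeric(boundFraction))
  }
  stopifnot(is(curve, "BindingCurve"))
  x <- curve@concentrations
  y <- curve@boundFraction
  if (length(unique(x)) < 3L)
    stop("Kd fitting needs at least 3 distinct concentrations")
  if (any(!is.finite(y))) stop("bound fractions must be finite")
  if (all(y == 0))
    stop("all bound fractions are zero: Kd is not identifiable")
  if (stats::sd(y) > 0 && stats::cor(x, y) < 0)
    warning("bound fraction decreases with concentration; fit may be meaningless")

  half <- max(y) / 2
  kd0 <- x[which.min(abs(y - half))]
  if (kd0 <= 0) kd0 <- max(min(x[x > 0]), 1)

  dat <- data.frame(x = x, y = y)
  fit <- if (fixBmax) {
    minpack.lm::nlsLM(y ~ x / (kd + x), data = dat,
                      start = list(kd = kd0), lower = c(kd = 1e-6),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  } else {
    minpack.lm::nlsLM(y ~ bmax * x / (kd + x), data = dat,
                      start = list(kd = kd0, bmax = max(y)),
                      lower = c(kd = 1e-6, bmax = 1e-6),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["kd", "Std. Error"],
                 error = function(e) NA_real_)
  new("BindingCurve", construct = curve@construct,
      concentrations = x, boundFraction = y,
      kd = unname(est[["kd"]]),
      bmax = if (fixBmax) 1 else unname(est[["bmax"]]),
      kdSe = se, residuals = as.numeric(stats::residuals(fit)))
}

#' Aggregate replicate Kd fits
#'
#' Simple mean and standard deviation of the fitted dissociation constants
#' across replicate curves, the way replicate experiments are usually
#' summarised.
#'
#' @param curves list of fitted \linkS4class{BindingCurve} objects.
#' @return data.frame with \code{mean_kd}, \code{sd_kd} and \code{n}.
#' @export
aggregateKd <- function(curves) {
  kds <- vapply(curves, kdEstimate, numeric(1))
  data.frame(mean_kd = mean(kds), sd_kd = stats::sd(kds), n = length(kds))
}

#' Relative binding intensities across constructs
#'
#' Normalises raw band intensities to a reference construct; invariant
#' under global positive rescaling of the inputs.
#'
#' @param intensities named vector of raw intensities (arbitrary units).
#' @param reference name of the reference construct (intensity > 0).
#' @return data.frame with columns \code{construct}, \code{raw_intensity},
#'   \code{relative_intensity}; the reference row is exactly 1.
#' @examples
#' relativeBinding(c(TelG5 = 10, TelG5TTT = 90, TelG5TT = 130), "TelG5")
#' @export
relativeBinding <- function(intensities, reference) {
  if (!reference %in% names(intensities))
    stop("reference construct '", reference, "' not present")
  ref <- intensities[[reference]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference intensity must be positive")
  data.frame(construct = names(intensities),
             raw_intensity = as.numeric(intensities),
             relative_intensity = as.numeric(intensities) / ref,
             stringsAsFactors = FALSE)
}

#' Pair conformational dynamics with binding intensity
#'
#' Inner-joins per-construct dynamics summaries (the NP-P
#' direct-transition density) with relative binding intensities and
#' reports the Kendall rank correlation between the two. The table makes
#' the comparison; it encodes no causal claim.
#'
#' @param summaries list of \linkS4class{DynamicsSummary}, one per
#'   construct (labels are the join key).
#' @param binding data.frame from \code{\link{relativeBinding}}.
#' @return list with \code{table} (construct, direct_density,
#'   relative_intensity) and \code{rankCorrelation} (Kendall's tau;
#'   \code{NA} with fewer than two shared constructs).
#' @export
dynamicsBindingTable <- function(summaries, binding) {
  labs <- vapply(summaries, function(s) s@label, character(1))
  shared <- intersect(labs, binding$construct)
  if (length(shared) == 0L)
    stop("no shared constructs between dynamics and binding inputs")
  dd <- vapply(summaries[match(shared, labs)], directDensity, numeric(1))
  ri <- binding$relative_intensity[match(shared, binding$construct)]
  tab <- data.frame(construct = shared, direct_density = dd,
                    relative_intensity = ri, stringsAsFactors = FALSE,
                    row.names = NULL)
  tau <- if (length(shared) >= 2L)
    stats::cor(tab$direct_density, tab$relative_intensity,
               method = "kendall")
  else NA_real_
  list(table = tab, rankCorrelation = tau)
}
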