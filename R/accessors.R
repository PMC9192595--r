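#' Accessors for quadfret classes
#'
#' Slot accessors for the pipeline's S4 containers. Use these rather than
#' \code{@} access.
#'
#' @param x a quadfret object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("moleculeId", "FretTrace", function(x) x@moleculeId)
#' @rdname accessors
setMethod("moleculeId", "FretTrajectory", function(x) x@moleculeId)
#' @rdname accessors
setMethod("moleculeId", "StatePath", function(x) x@moleculeId)
#' @rdname accessors
setMethod("frameInterval", "FretTrace", function(x) x@frameInterval)
#' @rdname accessors
setMethod("frameInterval", "FretTrajectory", function(x) x@frameInterval)
#' @rdname accessors
setMethod("donor", "FretTrace", function(x) x@donor)
#' @rdname accessors
setMethod("acceptor", "FretTrace", function(x) x@acceptor)
#' @rdname accessors
setMethod("bleachFrame", "FretTrace", function(x) x@bleachFrame)
#' @rdname accessors
setMethod("traces", "TraceSet", function(x) x@traces)
#' @rdname accessors
setMethod("manifest", "TraceSet", function(x) x@manifest)
#' @rdname accessors
setMethod("groundTruth", "TraceSet", function(x) x@truth)
#' @rdname accessors
setMethod("segments", "StatePath", function(x) x@segments)
#' @rdname accessors
setMethod("stateCenters", "StatePath", function(x) x@centers)
#' @rdname accessors
setMethod("efficiency", "FretTrajectory", function(x) x@efficiency)
#' @rdname accessors
setMethod("validUntil", "FretTrajectory", function(x) x@validUntil)
#' @rdname accessors
setMethod("binDensity", "FretHistogram", function(x) x@density)
#' @rdname accessors
setMethod("binDensity", "DifferentialHistogram", function(x) x@deltaDensity)
#' @rdname accessors
setMethod("binEdges", "FretHistogram", function(x) x@breaks)
#' @rdname accessors
setMethod("binEdges", "DifferentialHistogram", function(x) x@breaks)
#' @rdname accessors
setMethod("components", "MixtureFit", function(x) x@components)
#' @rdname accessors
setMethod("population", "MixtureFit", function(x) x@population)
#' @rdname accessors
setMethod("positiveSum", "DifferentialHistogram", function(x) x@positiveSum)
#' @rdname accessors
setMethod("transitionCounts", "TransitionCounts", function(x) x@counts)
#' @rdname accessors
setMethod("dwellMeans", "DwellTable", function(x) x@means)
#' @rdname accessors
setMethod("dwellRows", "DwellTable", function(x) x@rows)
#' @rdname accessors
setMethod("fractionTransitioning", "DynamicsSummary",
          function(x) x@fractionTransitioning)
#' @rdname accessors
setMethod("directDensity", "DynamicsSummary", function(x) x@directDensity)
#' @rdname accessors
setMethod("kdEstimate", "BindingCurve", function(x) x@kd)
#' @rdname accessors
setMethod("bmaxEstimate", "BindingCurve", function(x) x@bmax)
#' @rdname accessors
setMethod("stateLabels", "KineticModel", function(x) x@states)
#' @rdname accessors
setMethod("transitionRates", "KineticModel", function(x) x@rates)

#' @rdname accessors
#' @aliases length,TraceSet-method
setMethod("length", "TraceSet", function(x) length(x@traces))

setMethod("show", "FretTrace", function(object) {
  cat(sprintf("FretTrace '%s': %d frames @ %.3g s, bleach %s\n",
              object@moleculeId, length(object@donor), object@frameInterval,
              if (is.na(object@bleachFrame)) "none"
              else as.character(object@bleachFrame)))
})

setMethod("show", "TraceSet", function(object) {
  m <- paste(sprintf("%s=%s", names(object@manifest),
                     vapply(object@manifest, function(x) as.character(x)[1],
                            character(1))), collapse = ", ")
  cat(sprintf("TraceSet: %d molecules [%s]%s\n", length(object@traces), m,
              if (length(object@truth)) " (with ground truth)" else ""))
})

setMethod("show", "KineticModel", function(object) {
  dw <- meanDwellTimes(object)
  cat(sprintf("KineticModel: %d states (%s)\n", length(object@states),
              paste(object@states, collapse = ", ")))
  cat("  emission:", paste(sprintf("%s=%.2f", object@states,
                                   object@emissionMean), collapse = " "), "\n")
  cat("  mean dwell (s):",
      paste(sprintf("%s=%.3g", object@states, dw), collapse = " "), "\n")
  cat(sprintf("  docked fraction: %.2f\n", object@dockedFraction))
})

setMethod("show", "StatePath", function(object) {
  cat(sprintf("StatePath '%s' (%s): %d segments over [%.4g, %.4g] s\n",
              object@moleculeId, object@source, nrow(object@segments),
              if (nrow(object@segments)) object@segments$start[1] else NA,
              if (nrow(object@segments))
                object@segments$end[nrow(object@segments)] else NA))
})

setMethod("show", "FretHistogram", function(object) {
  cat(sprintf("FretHistogram: %d bins on [%.3g, %.3g], %d molecules, %g s window\n",
              length(object@density), min(object@breaks), max(object@breaks),
              object@nMolecules, object@window))
})

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit:\n")
  cmp <- object@components
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("  %-6s center %.3f sd %.3f population %.3f\n",
                cmp$label[i], cmp$center[i], cmp$sd[i],
                object@population[[cmp$label[i]]]))
  cat(sprintf("  residual %.3g\n", object@residual))
})

setMethod("show", "DynamicsSummary", function(object) {
  cat(sprintf(
    "DynamicsSummary '%s': %d/%d transitioning (%.3f), NP-P direct density %.4f\n",
    object@label, object@nTransitioning, object@nTotal,
    object@fractionTransitioning, object@directDensity))
})

setMethod("show", "BindingCurve", function(object) {
  cat(sprintf("BindingCurve '%s': %d concentrations", object@construct,
              length(object@concentrations)))
  if (!is.na(object@kd))
    cat(sprintf(", Kd = %.4g nM (se %.3g), Bmax = %.3g", object@kd,
                object@kdSe, object@bmax))
  cat("\n")
})

setMethod("show", "DwellTable", function(object) {
  cat(sprintf("DwellTable: %d dwells (%d uncensored)\n", nrow(object@rows),
              sum(!object@rows$censored)))
  if (length(object@means))
    cat("  mean dwell (s):",
        paste(sprintf("%s=%.3g", names(object@means), object@means),
              collapse = " "), "\n")
})

setMethod("show", "TransitionCounts", function(object) {
  cat("TransitionCounts:",
      paste(sprintf("%s=%d", names(object@counts), as.integer(object@counts)),
            collapse = " "), "\n")
  if (length(object@extra) && sum(object@extra) > 0)
    cat("  extra:",
        paste(sprintf("%s=%d", names(object@extra), as.integer(object@extra)),
              collapse = " "), "\n")
})
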