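#' @rdname accessors
#' @export
setGeneric("moleculeId", function(x) standardGeneric("moleculeId"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("donor", function(x) standardGeneric("donor"))
#' @rdname accessors
#' @export
setGeneric("acceptor", function(x) standardGeneric("acceptor"))
#' @rdname accessors
#' @export
setGeneric("bleachFrame", function(x) standardGeneric("bleachFrame"))
#' @rdname accessors
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))
#' @rdname accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("stateCenters", function(x) standardGeneric("stateCenters"))
#' @rdname accessors
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))
#' @rdname accessors
#' @export
setGeneric("validUntil", function(x) standardGeneric("validUntil"))
#' @rdname accessors
#' @export
setGeneric("binDensity", function(x) standardGeneric("binDensity"))
#' @rdname accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))
#' @rdname accessors
#' @export
setGeneric("population", function(x) standardGeneric("population"))
#' @rdname accessors
#' @export
setGeneric("positiveSum", function(x) standardGeneric("positiveSum"))
#' @rdname accessors
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))
#' @rdname accessors
#' @export
setGeneric("dwellMeans", function(x) standardGeneric("dwellMeans"))
#' @rdname accessors
#' @export
setGeneric("dwellRows", function(x) standardGeneric("dwellRows"))
#' @rdname accessors
#' @export
setGeneric("fractionTransitioning", function(x) standardGeneric("fractionTransitioning"))
#' @rdname accessors
#' @export
setGeneric("directDensity", function(x) standardGeneric("directDensity"))
#' @rdname accessors
#' @export
setGeneric("kdEstimate", function(x) standardGeneric("kdEstimate"))
#' @rdname accessors
#' @export
setGeneric("bmaxEstimate", function(x) standardGeneric("bmaxEstimate"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("transitionRates", function(x) standardGeneric("transitionRates"))
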