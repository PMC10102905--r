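#' @rdname StormPanel-class
#' @export
setGeneric("panelCounts", function(x) standardGeneric("panelCounts"))

#' @rdname StormPanel-class
#' @export
setGeneric("treatmentMask", function(x) standardGeneric("treatmentMask"))

#' @rdname StormPanel-class
#' @export
setGeneric("panelOffsets", function(x) standardGeneric("panelOffsets"))

#' @rdname StormPanel-class
#' @export
setGeneric("treatedIds", function(x) standardGeneric("treatedIds"))

#' @rdname StormPanel-class
#' @export
setGeneric("controlIds", function(x) standardGeneric("controlIds"))

#' @rdname StormPanel-class
#' @export
setGeneric("treatmentStart", function(x) standardGeneric("treatmentStart"))

#' @rdname StormPanel-class
#' @export
setGeneric("stormId", function(x) standardGeneric("stormId"))

#' @rdname AnalyticSet-class
#' @export
setGeneric("exclusionLog", function(x) standardGeneric("exclusionLog"))

#' @rdname MCFit-class
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))

#' @rdname MCFit-class
#' @export
setGeneric("mcDiagnostics", function(x) standardGeneric("mcDiagnostics"))

#' @rdname CounterfactualDraws-class
#' @export
setGeneric("counterfactualCells", function(x) standardGeneric("counterfactualCells"))

#' @rdname CounterfactualDraws-class
#' @export
setGeneric("counterfactualMatrix", function(x) standardGeneric("counterfactualMatrix"))

#' @rdname EffectPosterior-class
#' @export
setGeneric("ieeDraws", function(x) standardGeneric("ieeDraws"))

#' @rdname EffectPosterior-class
#' @export
setGeneric("excessRateDraws", function(x) standardGeneric("excessRateDraws"))

#' @rdname ModularFit-class
#' @export
setGeneric("coefDraws", function(x, ...) standardGeneric("coefDraws"))

#' @rdname ModularFit-class
#' @export
setGeneric("coefSummary", function(x, ...) standardGeneric("coefSummary"))
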