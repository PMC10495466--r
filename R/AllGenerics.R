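#' Accessors for corstate objects
#'
#' Small generic accessors used across the package's S4 classes.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @return The corresponding slot content.
#' @name corstate-accessors
NULL

#' @rdname corstate-accessors
#' @export
setGeneric("voltages", function(x, ...) standardGeneric("voltages"))

#' @rdname corstate-accessors
#' @export
setGeneric("samplingRate", function(x, ...) standardGeneric("samplingRate"))

#' @rdname corstate-accessors
#' @export
setGeneric("taskLabels", function(x, ...) standardGeneric("taskLabels"))

#' @rdname corstate-accessors
#' @export
setGeneric("outcomes", function(x, ...) standardGeneric("outcomes"))

#' @rdname corstate-accessors
#' @export
setGeneric("reactionTimes", function(x, ...) standardGeneric("reactionTimes"))

#' @rdname corstate-accessors
#' @export
setGeneric("markers", function(x, ...) standardGeneric("markers"))

#' @rdname corstate-accessors
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))

#' @rdname corstate-accessors
#' @export
setGeneric("nTrials", function(x, ...) standardGeneric("nTrials"))

#' @rdname corstate-accessors
#' @export
setGeneric("nElectrodes", function(x, ...) standardGeneric("nElectrodes"))

#' @rdname corstate-accessors
#' @export
setGeneric("powerRatio", function(x, ...) standardGeneric("powerRatio"))

#' @rdname corstate-accessors
#' @export
setGeneric("logPowerRatio", function(x, ...) standardGeneric("logPowerRatio"))

#' @rdname corstate-accessors
#' @export
setGeneric("stateLabels", function(x, ...) standardGeneric("stateLabels"))

#' @rdname corstate-accessors
#' @export
setGeneric("populationLabels", function(x, ...) standardGeneric("populationLabels"))

#' @rdname corstate-accessors
#' @export
setGeneric("accuracies", function(x, ...) standardGeneric("accuracies"))

#' @rdname corstate-accessors
#' @export
setGeneric("pValue", function(x, ...) standardGeneric("pValue"))

#' @rdname corstate-accessors
#' @export
setGeneric("rejectedTrials", function(x, ...) standardGeneric("rejectedTrials"))

#' @rdname corstate-accessors
#' @export
setGeneric("excludedElectrodes", function(x, ...) standardGeneric("excludedElectrodes"))

#' Subset a session
#'
#' @param x An [EcogSession-class].
#' @param trials Integer or logical index of trials to keep.
#' @param electrodes Integer or logical index of electrodes to keep.
#' @return A new [EcogSession-class].
#' @export
setGeneric("subsetSession",
           function(x, trials = NULL, electrodes = NULL) standardGeneric("subsetSession"))
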