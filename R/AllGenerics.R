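#' Accessors for AECountData
#'
#' @param x an [AECountData-class] object.
#' @return `aeCounts`: named list of count matrices; `aeExposure`: named
#'   list of exposure vectors; `aeDesign`: the period design data.frame;
#'   `aeTypeIndex`: the AE-type vocabulary data.frame.
#' @export
setGeneric("aeCounts", function(x) standardGeneric("aeCounts"))

#' @rdname aeCounts
#' @export
setGeneric("aeExposure", function(x) standardGeneric("aeExposure"))

#' @rdname aeCounts
#' @export
setGeneric("aeDesign", function(x) standardGeneric("aeDesign"))

#' @rdname aeCounts
#' @export
setGeneric("aeTypeIndex", function(x) standardGeneric("aeTypeIndex"))

#' @rdname aeCounts
#' @export
setMethod("aeCounts", "AECountData", function(x) x@counts)

#' @rdname aeCounts
#' @export
setMethod("aeExposure", "AECountData", function(x) x@exposure)

#' @rdname aeCounts
#' @export
setMethod("aeDesign", "AECountData", function(x) x@design)

#' @rdname aeCounts
#' @export
setMethod("aeTypeIndex", "AECountData", function(x) x@typeIndex)

#' Accessors for AEFit
#'
#' @param x an [AEFit-class] object.
#' @return `fittedParams`: the MAP [AEModelParams-class]; `fitTrace`: the
#'   best-so-far log-posterior sequence; `patternOrder`: named list (by
#'   treatment) of pattern permutations in descending order of
#'   log-probability increase.
#' @export
setGeneric("fittedParams", function(x) standardGeneric("fittedParams"))

#' @rdname fittedParams
#' @export
setGeneric("fitTrace", function(x) standardGeneric("fitTrace"))

#' @rdname fittedParams
#' @export
setGeneric("patternOrder", function(x) standardGeneric("patternOrder"))

#' @rdname fittedParams
#' @export
setMethod("fittedParams", "AEFit", function(x) x@params)

#' @rdname fittedParams
#' @export
setMethod("fitTrace", "AEFit", function(x) x@trace)

#' @rdname fittedParams
#' @export
setMethod("patternOrder", "AEFit", function(x)
  lapply(x@contributions, function(d) d$pattern))
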