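#' @rdname MaskStack-class
#' @param x object.
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' @rdname PrintSchedule-class
#' @param x object.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname SyntheticRender-class
#' @param x object.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname SyntheticRender-class
#' @export
setGeneric("channelImage", function(x, channel) {
  standardGeneric("channelImage")
})

#' @rdname MorphometryReport-class
#' @param x object.
#' @export
setGeneric("alignmentErrors", function(x) standardGeneric("alignmentErrors"))

#' @rdname MorphometryReport-class
#' @export
setGeneric("fractionBelowThreshold", function(x) {
  standardGeneric("fractionBelowThreshold")
})
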