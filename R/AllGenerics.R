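#' @rdname MLCModel-accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname MLCModel-accessors
#' @export
setGeneric("leafWidths", function(x) standardGeneric("leafWidths"))

#' @rdname MLCModel-accessors
#' @export
setGeneric("leafBoundaries", function(x) standardGeneric("leafBoundaries"))

#' @rdname MLCModel-accessors
#' @export
setGeneric("overtravel", function(x) standardGeneric("overtravel"))

#' @rdname ArcBeam-accessors
#' @export
setGeneric("controlPoints", function(x) standardGeneric("controlPoints"))

#' @rdname ArcBeam-accessors
#' @export
setGeneric("beamMU", function(x) standardGeneric("beamMU"))

#' @rdname ArcBeam-accessors
#' @export
setGeneric("machine", function(x) standardGeneric("machine"))

#' @rdname ArcBeam-accessors
#' @export
setGeneric("constraints", function(x) standardGeneric("constraints"))

#' @rdname ArcBeam-accessors
#' @export
setGeneric("constraints<-", function(x, value) standardGeneric("constraints<-"))

#' @rdname RTPlan-accessors
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))

#' @rdname RTPlan-accessors
#' @export
setGeneric("planID", function(x) standardGeneric("planID"))
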