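#' @rdname DiversityProfile-class
#' @param object,x an object.
#' @export
setGeneric("windows", function(x) standardGeneric("windows"))

#' @rdname DiversityProfile-class
#' @export
setGeneric("hotspots", function(x) standardGeneric("hotspots"))

#' @rdname DiversityProfile-class
#' @export
setGeneric("hotspotThreshold", function(x) standardGeneric("hotspotThreshold"))

#' @rdname MultiplexPanel-class
#' @export
setGeneric("multiplexSets", function(x) standardGeneric("multiplexSets"))

#' @rdname MultiplexPanel-class
#' @export
setGeneric("panelTable", function(x) standardGeneric("panelTable"))

#' @rdname MultiplexPanel-class
#' @export
setGeneric("conflictEdges", function(x) standardGeneric("conflictEdges"))

#' @rdname MultiplexPanel-class
#' @export
setGeneric("excludedEntries", function(x) standardGeneric("excludedEntries"))
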