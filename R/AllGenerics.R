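#' @rdname GenomeAnnotation-class
#' @param x an object.
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname SimulatedCohort-class
#' @param x an object.
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))

#' @rdname HomologyClusterSet-class
#' @param x an object.
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname HomologyClusterSet-class
#' @export
setGeneric("lineageLabels", function(x) standardGeneric("lineageLabels"))

#' @rdname SyntenyBlockSet-class
#' @param x an object.
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @rdname SyntenyBlockSet-class
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' @rdname FoldResult-class
#' @param x an object.
#' @export
setGeneric("mfe", function(x) standardGeneric("mfe"))

#' @rdname FoldResult-class
#' @export
setGeneric("pairCount", function(x) standardGeneric("pairCount"))

#' @rdname FoldResult-class
#' @export
setGeneric("structureString", function(x) standardGeneric("structureString"))
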