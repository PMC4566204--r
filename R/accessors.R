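#' @rdname GenomeAnnotation-class
#' @aliases speciesId,GenomeAnnotation-method
setMethod("speciesId", "GenomeAnnotation", function(x) x@speciesId)

#' @rdname GenomeAnnotation-class
#' @aliases genes,GenomeAnnotation-method
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @rdname GenomeAnnotation-class
#' @aliases chromLengths,GenomeAnnotation-method
setMethod("chromLengths", "GenomeAnnotation",
          function(x) seqlengths(x@genes))

setMethod("show", "GenomeAnnotation", function(object) {
    g <- object@genes
    cat("GenomeAnnotation for", object@speciesId, "\n")
    cat(" ", length(seqlengths(g)), "chromosome(s),",
        sum(mcols(g)$kind == "protein_coding"), "protein-coding gene(s),",
        sum(mcols(g)$kind == "lnc_annotation"), "annotated lncRNA locus/loci\n")
})

#' @rdname SimulatedCohort-class
#' @aliases truth,SimulatedCohort-method
setMethod("truth", "SimulatedCohort", function(x) x@truth)

#' @rdname SimulatedCohort-class
#' @aliases speciesId,SimulatedCohort-method
setMethod("speciesId", "SimulatedCohort", function(x) names(x@annotations))

setMethod("show", "SimulatedCohort", function(object) {
    cat("SimulatedCohort:", length(object@annotations), "species in",
        length(object@config@lineages), "lineage(s)\n")
    cls <- table(unique(object@truth[c("truth_id", "conservation_class")])$conservation_class)
    cat("  planted lncRNAs:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
})

#' @rdname HomologyClusterSet-class
#' @aliases clusterMembers,HomologyClusterSet-method
setMethod("clusterMembers", "HomologyClusterSet", function(x) x@membership)

#' @rdname HomologyClusterSet-class
#' @aliases lineageLabels,HomologyClusterSet-method
setMethod("lineageLabels", "HomologyClusterSet", function(x) x@lineageLabels)

setMethod("show", "HomologyClusterSet", function(object) {
    cat("HomologyClusterSet at identity cutoff >=", object@cutoffPct, "%:",
        length(unique(object@membership$cluster_id)), "cluster(s) over",
        nrow(object@membership), "transcript(s)\n")
    if (length(object@lineageLabels)) {
        tb <- table(object@lineageLabels)
        cat("  lineage labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
    }
})

#' @rdname SyntenyBlockSet-class
#' @aliases blocks,SyntenyBlockSet-method
setMethod("blocks", "SyntenyBlockSet", function(x) x@blocks)

#' @rdname SyntenyBlockSet-class
#' @aliases anchors,SyntenyBlockSet-method
setMethod("anchors", "SyntenyBlockSet", function(x) x@anchors)

setMethod("show", "SyntenyBlockSet", function(object) {
    cat("SyntenyBlockSet", object@speciesA, "vs", object@speciesB, ":",
        nrow(object@blocks), "block(s),", nrow(object@anchors), "anchor(s)\n")
})

#' @rdname FoldResult-class
#' @aliases mfe,FoldResult-method
setMethod("mfe", "FoldResult", function(x) x@mfe)

#' @rdname FoldResult-class
#' @aliases pairCount,FoldResult-method
setMethod("pairCount", "FoldResult", function(x) x@pairCount)

#' @rdname FoldResult-class
#' @aliases structureString,FoldResult-method
setMethod("structureString", "FoldResult", function(x) x@structure)

setMethod("show", "FoldResult", function(object) {
    cat("FoldResult", object@sequenceId, ":", nchar(object@sequence), "nt,",
        object@pairCount, "pair(s), MFE", sprintf("%.2f", object@mfe),
        "kcal/mol,", object@stabilityClass,
        sprintf("(%s)\n", object@context))
})
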