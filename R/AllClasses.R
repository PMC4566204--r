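#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo Seqinfo
#' @importFrom IRanges IRanges
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Simulation configuration for the multi-lineage genome generator
#'
#' Captures the study design emulated by [simulateCohort()]: several lineages
#' of related species that share an ancestral gene order, protein-coding genes
#' at low nucleotide divergence, and planted lncRNA loci that are either
#' sequence-conserved, conserved in position only (diverged like intronic
#' sequence), or private to one lineage.
#'
#' Divergences are substitution probabilities per site on the branch from the
#' common ancestor to each lineage ancestor; the `withinLineage*` rates apply
#' on the short branch from a lineage ancestor to each of its species.
#'
#' @slot seed integer seed; the whole cohort is reproducible from it.
#' @slot lineages named integer vector, species count per lineage.
#' @slot genesPerGenome,geneLengthBp,intergenicMeanBp genome layout.
#' @slot cdsDivergence,lncDivergence lineage-branch substitution
#'   probabilities for coding genes and for diverged lncRNA loci.
#' @slot withinLineageCdsDivergence,withinLineageLncDivergence species-branch
#'   substitution probabilities.
#' @slot nLncSequenceConserved,nLncPositionalOnly,nLncPrivate planted counts.
#' @slot lncLengthBp,chromCount lncRNA length and chromosome count.
#' @slot gapLincBp,gapGatuBp,natOverlapBp placement offsets for the three
#'   lncRNA categories (LINC / GATU / NAT).
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        seed = "integer",
        lineages = "integer",
        genesPerGenome = "integer",
        geneLengthBp = "integer",
        intergenicMeanBp = "integer",
        cdsDivergence = "numeric",
        lncDivergence = "numeric",
        withinLineageCdsDivergence = "numeric",
        withinLineageLncDivergence = "numeric",
        nLncSequenceConserved = "integer",
        nLncPositionalOnly = "integer",
        nLncPrivate = "integer",
        lncLengthBp = "integer",
        chromCount = "integer",
        gapLincBp = "integer",
        gapGatuBp = "integer",
        natOverlapBp = "integer"
    ))

setValidity("SimConfig", function(object) {
    msg <- character()
    probs <- c(object@cdsDivergence, object@lncDivergence,
               object@withinLineageCdsDivergence, object@withinLineageLncDivergence)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "divergence probabilities must lie in [0, 1]")
    if (object@lncDivergence < object@cdsDivergence)
        msg <- c(msg, "lncDivergence must be >= cdsDivergence (intron-like lncRNA mutation rate)")
    counts <- c(object@genesPerGenome, object@geneLengthBp, object@intergenicMeanBp,
                object@nLncSequenceConserved, object@nLncPositionalOnly,
                object@nLncPrivate, object@lncLengthBp, object@chromCount)
    if (any(counts < 0)) msg <- c(msg, "all counts must be >= 0")
    if (length(object@lineages) < 1 || is.null(names(object@lineages)))
        msg <- c(msg, "lineages must be a named vector of species counts")
    if (length(msg)) msg else TRUE
})

#' Strand-aware gene annotation of one genome
#'
#' Chromosome lengths live in the `Seqinfo` of the `genes` `GRanges`; genes
#' carry `gene_id` and `kind` (`protein_coding` or `lnc_annotation`) metadata
#' columns. This is the coordinate frame for all distance and synteny logic.
#'
#' @slot speciesId single species identifier.
#' @slot genes `GRanges` of gene features with `gene_id` and `kind`.
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
    representation(speciesId = "character", genes = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
    msg <- character()
    g <- object@genes
    if (length(object@speciesId) != 1L)
        msg <- c(msg, "speciesId must be a single string")
    if (!all(c("gene_id", "kind") %in% colnames(mcols(g))))
        msg <- c(msg, "genes must carry gene_id and kind metadata columns")
    else {
        if (anyDuplicated(mcols(g)$gene_id))
            msg <- c(msg, "duplicated gene_id")
        if (!all(mcols(g)$kind %in% c("protein_coding", "lnc_annotation")))
            msg <- c(msg, "kind must be protein_coding or lnc_annotation")
    }
    if (length(g) && any(!as.character(strand(g)) %in% c("+", "-")))
        msg <- c(msg, "every gene needs a defined strand (+ or -)")
    sl <- seqlengths(g)
    if (any(is.na(sl)))
        msg <- c(msg, "all chromosome lengths must be known")
    else if (length(g) && any(end(g) > sl[as.character(seqnames(g))]))
        msg <- c(msg, "gene interval exceeds chromosome bounds")
    if (length(msg)) msg else TRUE
})

#' A simulated multi-species cohort with recorded ground truth
#'
#' @slot config the [SimConfig-class] the cohort was generated from.
#' @slot annotations named list of [GenomeAnnotation-class], one per species.
#' @slot genomes named list of `DNAStringSet` (one sequence per chromosome).
#' @slot transcripts named list of `DNAStringSet` (mRNAs plus transcribed
#'   lncRNAs per species).
#' @slot truth data.frame of planted lncRNA loci: one row per
#'   (truth_id, species) with class, coordinates, anchor and direction.
#' @exportClass SimulatedCohort
setClass("SimulatedCohort",
    representation(config = "SimConfig", annotations = "list",
                   genomes = "list", transcripts = "list",
                   truth = "data.frame"))

setValidity("SimulatedCohort", function(object) {
    sp <- names(object@annotations)
    if (!identical(sp, names(object@genomes)) ||
        !identical(sp, names(object@transcripts)))
        return("annotations, genomes and transcripts must cover the same species")
    need <- c("truth_id", "conservation_class", "species", "chrom", "start",
              "end", "strand", "anchor_gene_id", "relative_direction",
              "category", "transcript_id")
    if (!all(need %in% colnames(object@truth)))
        return(paste("truth table must have columns:", paste(need, collapse = ", ")))
    TRUE
})

#' Species-to-lineage assignment used for specificity labelling
#'
#' @slot speciesToLineage named character vector mapping species to lineage.
#' @slot minSpeciesTranscribed minimum distinct species of one lineage a
#'   cluster must contain to count as lineage-specific (default 2).
#' @slot outgroupDb optional path to an outgroup FASTA screen.
#' @exportClass LineageConfig
setClass("LineageConfig",
    representation(speciesToLineage = "character",
                   minSpeciesTranscribed = "integer",
                   outgroupDb = "characterOrNULL"))

setValidity("LineageConfig", function(object) {
    if (is.null(names(object@speciesToLineage)) ||
        any(!nzchar(names(object@speciesToLineage))))
        return("speciesToLineage must be a named character vector")
    if (object@minSpeciesTranscribed < 1L)
        return("minSpeciesTranscribed must be >= 1")
    TRUE
})

#' Cross-species transcript clusters at one identity cutoff
#'
#' @slot cutoffPct identity cutoff (percent of query length) used for the
#'   reciprocal-best-hit graph underlying this partition.
#' @slot membership data.frame with columns cluster_id, transcript_id,
#'   species_id; a partition of the input transcript set.
#' @slot lineageLabels named character vector (by cluster_id); empty until
#'   [assignLineageSpecificity()] is applied.
#' @slot converged whether Markov clustering reached its tolerance.
#' @exportClass HomologyClusterSet
setClass("HomologyClusterSet",
    representation(cutoffPct = "numeric", membership = "data.frame",
                   lineageLabels = "character", converged = "logical"))

setValidity("HomologyClusterSet", function(object) {
    m <- object@membership
    if (!all(c("cluster_id", "transcript_id", "species_id") %in% colnames(m)))
        return("membership needs cluster_id, transcript_id, species_id")
    if (anyDuplicated(m$transcript_id))
        return("clusters must partition the transcript set (duplicate member)")
    if (length(object@lineageLabels) &&
        !all(names(object@lineageLabels) %in% m$cluster_id))
        return("lineageLabels refer to unknown cluster ids")
    TRUE
})

#' Collinear anchor chains between two annotated genomes
#'
#' @slot speciesA,speciesB the two species compared (A is the query side).
#' @slot blocks data.frame: block_id, chrom_a, chrom_b, orientation
#'   (same/inverted), n_anchors, score.
#' @slot anchors data.frame: block_id, gene_a, gene_b, rank_a, rank_b,
#'   chrom_a, chrom_b; ranks are strictly monotone within a block.
#' @exportClass SyntenyBlockSet
setClass("SyntenyBlockSet",
    representation(speciesA = "character", speciesB = "character",
                   blocks = "data.frame", anchors = "data.frame"))

setValidity("SyntenyBlockSet", function(object) {
    a <- object@anchors
    b <- object@blocks
    need <- c("block_id", "gene_a", "gene_b", "rank_a", "rank_b")
    if (nrow(a) && !all(need %in% colnames(a)))
        return(paste("anchors need columns:", paste(need, collapse = ", ")))
    for (id in b$block_id) {
        ai <- a[a$block_id == id, , drop = FALSE]
        if (nrow(ai) < 1L) return(sprintf("block %s has no anchors", id))
        if (is.unsorted(ai$rank_a, strictly = TRUE))
            return(sprintf("block %s not strictly increasing in rank_a", id))
        ori <- b$orientation[b$block_id == id]
        rb <- if (identical(ori, "inverted")) rev(ai$rank_b) else ai$rank_b
        if (is.unsorted(rb, strictly = TRUE))
            return(sprintf("block %s not strictly monotone in rank_b", id))
    }
    TRUE
})

#' A predicted RNA secondary structure with its energy
#'
#' @slot sequenceId,sequence the folded RNA.
#' @slot structure dot-bracket string, same length as the sequence.
#' @slot mfe minimum free energy (kcal/mol) under the model that produced it.
#' @slot pairCount number of base pairs (count of `(` characters).
#' @slot stabilityClass `stable` or `unstable` (see [classifyStability()]).
#' @slot context the threshold context the class was derived under.
#' @exportClass FoldResult
setClass("FoldResult",
    representation(sequenceId = "character", sequence = "character",
                   structure = "character", mfe = "numeric",
                   pairCount = "integer", stabilityClass = "character",
                   context = "character"))

setValidity("FoldResult", function(object) {
    msg <- character()
    if (nchar(object@structure) != nchar(object@sequence))
        msg <- c(msg, "structure length must equal sequence length")
    ch <- strsplit(object@structure, "")[[1]]
    depth <- cumsum((ch == "(") - (ch == ")"))
    if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0))
        msg <- c(msg, "unbalanced brackets")
    if (object@pairCount != sum(ch == "("))
        msg <- c(msg, "pairCount must equal the number of '(' characters")
    if (length(msg)) msg else TRUE
})
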