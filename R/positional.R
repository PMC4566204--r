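#' Direction of a transcriptional unit relative to an anchor gene
#'
#' Directions are defined relative to the anchor gene's own strand, which
#' makes them invariant under block inversion (an inverted segment flips
#' both raw coordinates and gene strands, leaving the gene-relative side
#' unchanged): `upstream` = on the 5' side of the anchor, `downstream` = 3'
#' side, `antisense` = overlapping on the opposite strand, `overlapping` =
#' overlapping on the same strand.
#'
#' @param tu,gene length-1 `GRanges` with strands.
#' @return one of "upstream", "downstream", "antisense", "overlapping".
#' @export
relativeDirection <- function(tu, gene) {
    stopifnot(length(tu) == 1L, length(gene) == 1L)
    .rel_dir(start(tu), end(tu), as.character(strand(tu)),
             start(gene), end(gene), as.character(strand(gene)))
}

# vectorized over the TU arguments; plain coordinates, no S4 overhead
.rel_dir <- function(ts, te, tstr, gs, ge, gstr) {
    overlap <- ts <= ge & te >= gs
    right_of <- ts > ge
    gplus <- gstr == "+"
    ifelse(overlap, ifelse(tstr != gstr, "antisense", "overlapping"),
           ifelse(xor(right_of, gplus), "upstream", "downstream"))
}

# search window: the target anchor's gene body extended to the midpoint of
# the adjacent intergenic interval on the given gene-relative side
.anchor_window <- function(geneB, annotationB, direction) {
    if (direction %in% c("antisense", "overlapping"))
        return(GRanges(seqnames(geneB), IRanges(start(geneB), end(geneB))))
    gplus <- as.character(strand(geneB)) == "+"
    left <- xor(direction == "downstream", gplus) # upstream of a + gene = left
    pc <- genes(annotationB)
    pc <- pc[mcols(pc)$kind == "protein_coding" &
             as.character(seqnames(pc)) == as.character(seqnames(geneB))]
    if (left) {
        prev <- pc[end(pc) < start(geneB)]
        lo <- if (length(prev)) (max(end(prev)) + start(geneB)) %/% 2L else 1L
        hi <- end(geneB)
    } else {
        nxt <- pc[start(pc) > end(geneB)]
        chrlen <- seqlengths(genes(annotationB))[as.character(seqnames(geneB))]
        hi <- if (length(nxt)) (end(geneB) + min(start(nxt))) %/% 2L else
            as.integer(chrlen)
        lo <- start(geneB)
    }
    GRanges(seqnames(geneB), IRanges(lo, hi))
}

#' Test one lncRNA for positional conservation in a target genome
#'
#' Anchors the lncRNA on its nearest protein-coding gene, finds the anchor's
#' syntenic partner through the block set, and searches the partner's
#' neighbourhood (gene body extended to the midpoint of the adjacent
#' intergenic interval on the matched side) for a target lncRNA with the
#' same gene-relative direction.
#'
#' @param lnc one candidate row (list or 1-row data.frame) with chrom,
#'   start, end, strand, nearest_gene_id, transcript_id; `chrom = NA` means
#'   the transcript could not be located.
#' @param sourceAnnot,targetAnnot the two [GenomeAnnotation-class] objects.
#' @param blockSet a [SyntenyBlockSet-class] from source to target.
#' @param targetLnc candidate table of the target species (located lncRNAs).
#' @return list: status (`positionally_conserved`, `not_found`,
#'   `no_synteny`, `anchor_unlocated`), relative_direction, matched_lnc_id,
#'   anchor_gene_id.
#' @export
positionalCall <- function(lnc, sourceAnnot, targetAnnot, blockSet, targetLnc) {
    res <- list(status = "anchor_unlocated", relative_direction = NA_character_,
                matched_lnc_id = NA_character_,
                anchor_gene_id = NA_character_)
    if (is.null(lnc$chrom) || is.na(lnc$chrom)) return(res)
    res$anchor_gene_id <- lnc$nearest_gene_id
    if (!lnc$nearest_gene_id %in% names(genes(sourceAnnot))) {
        res$status <- "no_synteny"
        return(res)
    }
    geneA <- genes(sourceAnnot)[lnc$nearest_gene_id]
    d <- .rel_dir(lnc$start, lnc$end, lnc$strand,
                  start(geneA), end(geneA), as.character(strand(geneA)))
    res$relative_direction <- d
    adf <- anchors(blockSet)
    hit <- adf[adf$gene_a == lnc$nearest_gene_id, , drop = FALSE]
    if (nrow(hit) == 0L) { res$status <- "no_synteny"; return(res) }
    # blocks(blockSet) is score-ordered; anchors follow that order
    geneB <- genes(targetAnnot)[hit$gene_b[1L]]
    win <- .anchor_window(geneB, targetAnnot, d)
    if (nrow(targetLnc) == 0L) { res$status <- "not_found"; return(res) }
    tl <- targetLnc[targetLnc$chrom == as.character(seqnames(geneB)), ,
                    drop = FALSE]
    if (nrow(tl) == 0L) { res$status <- "not_found"; return(res) }
    tl <- tl[order(tl$transcript_id), , drop = FALSE]
    in_win <- tl$start <= end(win) & tl$end >= start(win)
    dir_ok <- .rel_dir(tl$start, tl$end, tl$strand, start(geneB), end(geneB),
                       as.character(strand(geneB))) == d
    ok <- which(in_win & dir_ok)
    if (length(ok)) {
        res$status <- "positionally_conserved"
        res$matched_lnc_id <- tl$transcript_id[ok[1L]]
    } else res$status <- "not_found"
    res
}

#' Summarize positional-conservation calls per lineage
#'
#' A locus counts as positionally conserved when at least one call against a
#' species of *another* lineage is `positionally_conserved`.
#'
#' @param calls data.frame with locus_id, source_species, target_species,
#'   status (one row per locus x target species).
#' @param lineageOf named character vector species -> lineage.
#' @return list: `perLineage` (lineage, n_lineage_specific,
#'   n_positionally_conserved, pct_positional; lineages without loci are
#'   absent) and `dualClass` (the sequence-diverged, positionally conserved
#'   loci).
#' @export
summarizePositional <- function(calls, lineageOf) {
    if (nrow(calls) == 0L)
        return(list(perLineage = data.frame(lineage = character(),
                                            n_lineage_specific = integer(),
                                            n_positionally_conserved = integer(),
                                            pct_positional = numeric()),
                    dualClass = data.frame(locus_id = character(),
                                           source_lineage = character())))
    calls$source_lineage <- unname(lineageOf[calls$source_species])
    calls$target_lineage <- unname(lineageOf[calls$target_species])
    per_locus <- split(calls, calls$locus_id)
    conserved <- vapply(per_locus, function(cc)
        any(cc$status == "positionally_conserved" &
            cc$target_lineage != cc$source_lineage), TRUE)
    locus_lineage <- vapply(per_locus, function(cc) cc$source_lineage[1L], "")
    perLineage <- do.call(rbind, lapply(unique(locus_lineage), function(l) {
        n <- sum(locus_lineage == l)
        k <- sum(conserved[locus_lineage == l])
        data.frame(lineage = l, n_lineage_specific = n,
                   n_positionally_conserved = k,
                   pct_positional = 100 * k / n, stringsAsFactors = FALSE)
    }))
    dualClass <- data.frame(locus_id = names(conserved)[conserved],
                            source_lineage = locus_lineage[conserved],
                            stringsAsFactors = FALSE)
    rownames(dualClass) <- NULL
    list(perLineage = perLineage, dualClass = dualClass)
}

#' Distance of loci to the nearest chromosome end
#'
#' Distance is `min(start - 1, chrom_length - end)` (bases outside the locus
#' towards the closer end); a locus is "within" when the distance does not
#' exceed `thresholdBp` (inclusive at exactly 2.5 Mb by default).
#'
#' @param loci a `GRanges` with known `seqlengths` (names are locus ids).
#' @param thresholdBp proximity threshold (default 2,500,000).
#' @return list: perLocus data.frame (lnc_id, chrom,
#'   distance_to_nearest_end_bp, within), threshold_bp, n_within, n_total,
#'   fraction_within, pct_within.
#' @export
telomereProximity <- function(loci, thresholdBp = 2.5e6) {
    sl <- seqlengths(loci)
    if (any(is.na(sl))) stop("all chromosome lengths must be known")
    len <- as.numeric(sl[as.character(seqnames(loci))])
    if (length(loci) && (any(start(loci) < 1L) || any(end(loci) > len)))
        stop("locus outside chromosome bounds")
    d <- pmin(start(loci) - 1, len - end(loci))
    within <- d <= thresholdBp
    ids <- if (is.null(names(loci))) sprintf("locus%03d", seq_along(loci)) else
        names(loci)
    list(perLocus = data.frame(lnc_id = ids,
                               chrom = as.character(seqnames(loci)),
                               distance_to_nearest_end_bp = d,
                               within = within, stringsAsFactors = FALSE),
         threshold_bp = thresholdBp,
         n_within = sum(within), n_total = length(loci),
         fraction_within = if (length(loci)) sum(within) / length(loci) else
             NA_real_,
         pct_within = if (length(loci)) 100 * sum(within) / length(loci) else
             NA_real_)
}
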