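#' Rank protein-coding genes along each chromosome
#'
#' @param annotation a [GenomeAnnotation-class].
#' @return data.frame: gene_id, chrom, rank (dense 0-based per chromosome,
#'   ordered by start coordinate then gene id).
#' @export
buildGeneOrder <- function(annotation) {
    g <- genes(annotation)
    g <- g[mcols(g)$kind == "protein_coding"]
    if (length(g) == 0L)
        return(data.frame(gene_id = character(), chrom = character(),
                          rank = integer()))
    df <- data.frame(gene_id = mcols(g)$gene_id,
                     chrom = as.character(seqnames(g)),
                     start = start(g), stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start, df$gene_id), ]
    df$rank <- unlist(lapply(split(df$gene_id, df$chrom),
                             function(x) seq_along(x) - 1L), use.names = FALSE)
    rownames(df) <- NULL
    df[c("gene_id", "chrom", "rank")]
}

#' Attach gene ranks to homologous gene pairs, producing synteny anchors
#'
#' Many-to-many homology pairs are all retained; chaining resolves them.
#'
#' @param annotationA,annotationB the two [GenomeAnnotation-class] objects.
#' @param genePairs data.frame with columns `gene_a`, `gene_b`.
#' @return data.frame: gene_a, gene_b, chrom_a, chrom_b, rank_a, rank_b.
#' @export
findAnchors <- function(annotationA, annotationB, genePairs) {
    oa <- buildGeneOrder(annotationA)
    ob <- buildGeneOrder(annotationB)
    m <- merge(genePairs, stats::setNames(oa, c("gene_a", "chrom_a", "rank_a")),
               by = "gene_a")
    m <- merge(m, stats::setNames(ob, c("gene_b", "chrom_b", "rank_b")),
               by = "gene_b")
    m <- m[order(m$chrom_a, m$rank_a, m$chrom_b, m$rank_b), ]
    rownames(m) <- NULL
    m[c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")]
}

# best chain by DP over anchors (ra strictly increasing; rb strictly
# increasing for orientation "same"). Score: +1 per anchor, minus
# gapPenalty * ((da-1)+(db-1)) per step; steps with max(da,db)-1 > maxGap
# are forbidden. Returns indices into ra/rb of the best chain.
.chain_dp <- function(ra, rb, maxGap, gapPenalty) {
    n <- length(ra)
    if (n == 0L) return(list(score = 0, chain = integer()))
    ord <- order(ra, rb)
    ra <- ra[ord]; rb <- rb[ord]
    S <- rep(1, n); P <- rep(0L, n)
    for (i in seq_len(n)) {
        for (j in seq_len(i - 1L)) {
            da <- ra[i] - ra[j]; db <- rb[i] - rb[j]
            if (da < 1L || db < 1L || max(da, db) - 1L > maxGap) next
            cand <- S[j] + 1 - gapPenalty * ((da - 1L) + (db - 1L))
            if (cand > S[i] + 1e-12) { S[i] <- cand; P[i] <- j }
        }
    }
    i <- which.max(S)
    chain <- integer()
    while (i > 0L) { chain <- c(i, chain); i <- P[i] }
    list(score = max(S), chain = ord[chain])
}

#' Chain synteny anchors into collinear blocks
#'
#' DAGchainer-style chaining in gene-rank space: per chromosome pair, the
#' maximum-score chain (+1 per anchor, gap penalty `gapPenalty` per skipped
#' rank, gaps larger than `maxGapGenes` forbidden) is extracted greedily in
#' both orientations (b-ranks strictly increasing, or strictly decreasing =
#' inverted), its anchors are removed, and the search repeats until no chain
#' of at least `minAnchors` anchors remains. Each anchor is used in at most
#' one block. Tandem duplicate anchors (same gene on one side at adjacent
#' ranks on the other) are collapsed before chaining.
#'
#' @param anchorTable anchors from [findAnchors()].
#' @param maxGapGenes largest allowed rank gap within a chain (default 20).
#' @param minAnchors minimum anchors per reported block (default 4).
#' @param gapPenalty score penalty per skipped rank (default 0.05).
#' @param speciesA,speciesB labels for the result object.
#' @return a [SyntenyBlockSet-class].
#' @export
chainAnchors <- function(anchorTable, maxGapGenes = 20L, minAnchors = 4L,
                         gapPenalty = 0.05, speciesA = "A", speciesB = "B") {
    blocks <- list(); anch <- list(); bn <- 0L
    if (nrow(anchorTable)) {
        anchorTable <- unique(anchorTable)
        # collapse tandem duplicates: same gene_a at consecutive rank_b (and
        # vice versa) -> keep the lowest-rank partner
        anchorTable <- anchorTable[order(anchorTable$gene_a, anchorTable$rank_b), ]
        dup_a <- duplicated(anchorTable$gene_a) &
            c(FALSE, diff(anchorTable$rank_b) == 1L)
        anchorTable <- anchorTable[!dup_a, , drop = FALSE]
        anchorTable <- anchorTable[order(anchorTable$gene_b, anchorTable$rank_a), ]
        dup_b <- duplicated(anchorTable$gene_b) &
            c(FALSE, diff(anchorTable$rank_a) == 1L)
        anchorTable <- anchorTable[!dup_b, , drop = FALSE]
        for (grp in split(anchorTable,
                          paste(anchorTable$chrom_a, anchorTable$chrom_b,
                                sep = "\r"))) {
            grp <- grp[order(grp$rank_a, grp$rank_b), ]
            repeat {
                same <- .chain_dp(grp$rank_a, grp$rank_b, maxGapGenes, gapPenalty)
                inv <- .chain_dp(grp$rank_a, -grp$rank_b, maxGapGenes, gapPenalty)
                ori <- if (same$score >= inv$score) "same" else "inverted"
                best <- if (ori == "same") same else inv
                if (length(best$chain) < minAnchors) break
                bn <- bn + 1L
                rows <- grp[best$chain, , drop = FALSE]
                rows <- rows[order(rows$rank_a), ]
                id <- sprintf("B%03d", bn)
                blocks[[bn]] <- data.frame(
                    block_id = id, chrom_a = rows$chrom_a[1L],
                    chrom_b = rows$chrom_b[1L], orientation = ori,
                    n_anchors = nrow(rows), score = best$score,
                    stringsAsFactors = FALSE)
                rows$block_id <- id
                anch[[bn]] <- rows
                grp <- grp[-best$chain, , drop = FALSE]
                if (nrow(grp) < minAnchors) break
            }
        }
    }
    if (bn == 0L)
        return(new("SyntenyBlockSet", speciesA = speciesA, speciesB = speciesB,
                   blocks = data.frame(block_id = character(),
                                       chrom_a = character(), chrom_b = character(),
                                       orientation = character(),
                                       n_anchors = integer(), score = numeric()),
                   anchors = data.frame(block_id = character(),
                                        gene_a = character(), gene_b = character(),
                                        rank_a = integer(), rank_b = integer(),
                                        chrom_a = character(), chrom_b = character())))
    bdf <- do.call(rbind, blocks)
    adf <- do.call(rbind, anch)
    ord <- order(-bdf$score, bdf$block_id)
    bdf <- bdf[ord, ]; rownames(bdf) <- NULL
    adf <- adf[order(match(adf$block_id, bdf$block_id), adf$rank_a), ]
    rownames(adf) <- NULL
    new("SyntenyBlockSet", speciesA = speciesA, speciesB = speciesB,
        blocks = bdf,
        anchors = adf[c("block_id", "gene_a", "gene_b", "rank_a", "rank_b",
                        "chrom_a", "chrom_b")])
}

#' Project a genomic region through a synteny block
#'
#' The region is mapped by its flanking anchors: the projected interval spans
#' the partner genes of the nearest anchors on the left and right (which
#' coincide when the region overlaps an anchor gene). Regions outside all
#' blocks yield `NULL`.
#'
#' @param queryRegion a length-1 `GRanges` in genome A coordinates.
#' @param blockSet a [SyntenyBlockSet-class] from A to B.
#' @param annotationA,annotationB the two annotations.
#' @param blockId project through this block; by default the best-scoring
#'   block covering the region.
#' @return a length-1 `GRanges` on genome B with an `orientation` metadata
#'   column, or `NULL` (no projection).
#' @export
projectRegion <- function(queryRegion, blockSet, annotationA, annotationB,
                          blockId = NULL) {
    stopifnot(length(queryRegion) == 1L)
    bdf <- blocks(blockSet); adf <- anchors(blockSet)
    ga <- genes(annotationA); gb <- genes(annotationB)
    cand <- if (is.null(blockId)) bdf$block_id else blockId
    qchrom <- as.character(seqnames(queryRegion))
    qs <- start(queryRegion); qe <- end(queryRegion)
    for (id in cand) {
        bi <- bdf[bdf$block_id == id, ]
        if (bi$chrom_a != qchrom) next
        ai <- adf[adf$block_id == id, , drop = FALSE]
        aw <- ga[ai$gene_a]
        astart <- start(aw); aend <- end(aw)
        if (qe < min(astart) || qs > max(aend)) next
        li <- max(which(astart <= qe))
        ri <- min(which(aend >= qs))
        lo <- min(li, ri); hi <- max(li, ri)
        partners <- gb[ai$gene_b[lo:hi]]
        out <- GRanges(bi$chrom_b,
                       IRanges(min(start(partners)), max(end(partners))),
                       seqinfo = seqinfo(gb))
        mcols(out)$orientation <- bi$orientation
        mcols(out)$block_id <- id
        return(out)
    }
    NULL
}

#' Write synteny blocks as TSV (plus paired BED intervals)
#'
#' @param blockSet a [SyntenyBlockSet-class].
#' @param annotationA,annotationB annotations supplying gene coordinates.
#' @param path TSV output path; `.bed` siblings are written next to it.
#' @export
writeBlocks <- function(blockSet, annotationA, annotationB, path) {
    bdf <- blocks(blockSet); adf <- anchors(blockSet)
    utils::write.table(merge(bdf, adf, by = "block_id"), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(adf)) {
        ga <- genes(annotationA)[adf$gene_a]
        gbr <- genes(annotationB)[adf$gene_b]
        bed <- function(gr, ids) data.frame(as.character(seqnames(gr)),
                                            start(gr) - 1L, end(gr), ids)
        utils::write.table(bed(ga, adf$block_id), sub("\\.tsv$", ".a.bed", path),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
        utils::write.table(bed(gbr, adf$block_id), sub("\\.tsv$", ".b.bed", path),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
    }
    invisible(path)
}
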