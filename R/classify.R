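#' Decide a transcript's genomic location from its self-genome hits
#'
#' A transcript is assumed to map to its correct locus only when it has
#' exactly one high-scoring segment pair (HSP) against its own genome and
#' that segment covers at least half of the query. Anything else is a
#' rejection with a reason, which conservatively discards split, repetitive
#' or unmappable transcripts.
#'
#' @param hits hit table from [searchHits()] restricted to one transcript
#'   (already e-value filtered).
#' @param queryLength transcript length in nt.
#' @param minCoverage minimum fraction of the query covered (default 0.5).
#' @return a list: `status` (`located` or `rejected`), and either
#'   `chrom`/`start`/`end`/`strand` or `reason`
#'   (`multi_hsp`, `low_coverage`, `no_hit`).
#' @export
locateTranscript <- function(hits, queryLength, minCoverage = 0.5) {
    if (nrow(hits) == 0L) return(list(status = "rejected", reason = "no_hit"))
    if (nrow(hits) >= 2L) return(list(status = "rejected", reason = "multi_hsp"))
    cov <- (hits$qend - hits$qstart + 1L) / queryLength
    if (cov < minCoverage) return(list(status = "rejected", reason = "low_coverage"))
    list(status = "located", chrom = hits$sseqid, start = hits$sstart,
         end = hits$send, strand = hits$strand)
}

#' Categorize a located transcriptional unit against the gene annotation
#'
#' The three categories of the classification: `NAT` when the TU overlaps a
#' protein-coding gene on the opposite strand; otherwise `GATU` when the
#' edge-to-edge gap to the nearest protein-coding gene is below
#' `thresholdBp`; otherwise `LINC` (at least `thresholdBp` away, on either
#' strand). A gap of exactly `thresholdBp` is LINC. Nearest-gene ties are
#' broken by the lexicographically smallest gene id.
#'
#' @param location list or `GRanges` with chrom/start/end/strand.
#' @param annotation a [GenomeAnnotation-class].
#' @param thresholdBp LINC/GATU distance boundary (default 500).
#' @return list with `category` (`LINC`/`GATU`/`NAT`/`unclassifiable`),
#'   `nearest_gene_id`, `distance_bp`.
#' @export
classifyLnc <- function(location, annotation, thresholdBp = 500L) {
    if (!is(location, "GRanges"))
        location <- GRanges(location$chrom,
                            IRanges(location$start, location$end),
                            strand = location$strand)
    pc <- genes(annotation)
    pc <- pc[mcols(pc)$kind == "protein_coding"]
    pc <- pc[as.character(seqnames(pc)) == as.character(seqnames(location))]
    if (length(pc) == 0L)
        return(list(category = "unclassifiable",
                    nearest_gene_id = NA_character_, distance_bp = NA_integer_))
    d <- GenomicRanges::distance(location, pc, ignore.strand = TRUE)
    dmin <- min(d)
    # NAT takes precedence: any opposite-strand overlap
    ov <- which(IRanges::overlapsAny(pc, location, ignore.strand = TRUE))
    opp <- ov[as.character(strand(pc))[ov] != as.character(strand(location))]
    if (length(opp)) {
        gid <- sort(mcols(pc)$gene_id[opp])[1L]
        return(list(category = "NAT", nearest_gene_id = gid, distance_bp = 0L))
    }
    near <- which(d == dmin)
    gid <- sort(mcols(pc)$gene_id[near])[1L]
    cat <- if (dmin < thresholdBp) "GATU" else "LINC"
    list(category = cat, nearest_gene_id = gid, distance_bp = as.integer(dmin))
}

#' Detect, locate and categorize lncRNA candidates for one species
#'
#' Runs the candidate filter (length and six-frame ORF scan), localizes the
#' surviving transcripts on their own genome by seeded alignment (both
#' strands, single-HSP rule), and categorizes the located TUs.
#'
#' @param transcripts named `DNAStringSet` of the species' transcripts.
#' @param genome named `DNAStringSet` of chromosome sequences.
#' @param annotation the species' [GenomeAnnotation-class].
#' @param scoring,evalueMax alignment scoring and e-value cutoff.
#' @param thresholdBp LINC/GATU boundary.
#' @param minLengthNt,maxOrfAa candidate filter thresholds.
#' @return list with `candidates` (one row per located candidate:
#'   transcript_id, species_id, chrom, start, end, strand, category,
#'   nearest_gene_id, distance_bp, transcript_length_nt, max_orf_aa) and
#'   `rejected` (transcript_id, reason).
#' @export
detectLncCandidates <- function(transcripts, genome, annotation,
                                scoring = alignScoring(), evalueMax = 1e-10,
                                thresholdBp = 500L, minLengthNt = 200L,
                                maxOrfAa = 100L) {
    sp <- speciesId(annotation)
    txs <- .as_char_seq(transcripts)
    names(txs) <- names(transcripts)
    orfmax <- vapply(txs, function(s) {
        o <- scanOrfs(s); if (nrow(o)) max(o$orf_length_aa) else 0L
    }, 0L)
    keep <- nchar(txs) >= minLengthNt & orfmax < maxOrfAa
    rejected <- data.frame(transcript_id = names(txs)[!keep],
                           reason = ifelse(nchar(txs)[!keep] < minLengthNt,
                                           "too_short", "coding_orf"),
                           stringsAsFactors = FALSE)
    cand <- txs[keep]
    rows <- list()
    if (length(cand)) {
        hits <- searchHits(cand, genome, scoring = scoring,
                           minSeedHits = 2L, evalueMax = evalueMax,
                           bothStrands = TRUE)
        for (tid in names(cand)) {
            h <- hits[hits$qseqid == tid, , drop = FALSE]
            loc <- locateTranscript(h, nchar(cand[[tid]]))
            if (loc$status != "located") {
                rejected <- rbind(rejected,
                                  data.frame(transcript_id = tid,
                                             reason = loc$reason,
                                             stringsAsFactors = FALSE))
                next
            }
            cl <- classifyLnc(loc, annotation, thresholdBp = thresholdBp)
            if (cl$category == "unclassifiable") {
                rejected <- rbind(rejected,
                                  data.frame(transcript_id = tid,
                                             reason = "unclassifiable",
                                             stringsAsFactors = FALSE))
                next
            }
            rows[[length(rows) + 1L]] <- data.frame(
                transcript_id = tid, species_id = sp, chrom = loc$chrom,
                start = loc$start, end = loc$end, strand = loc$strand,
                category = cl$category, nearest_gene_id = cl$nearest_gene_id,
                distance_bp = cl$distance_bp,
                transcript_length_nt = nchar(cand[[tid]]),
                max_orf_aa = orfmax[[tid]], stringsAsFactors = FALSE)
        }
    }
    candidates <- if (length(rows)) do.call(rbind, rows) else
        data.frame(transcript_id = character(), species_id = character(),
                   chrom = character(), start = integer(), end = integer(),
                   strand = character(), category = character(),
                   nearest_gene_id = character(), distance_bp = integer(),
                   transcript_length_nt = integer(), max_orf_aa = integer(),
                   stringsAsFactors = FALSE)
    rownames(candidates) <- NULL
    list(candidates = candidates, rejected = rejected)
}

#' Flag a transcript as a putative miRNA precursor
#'
#' A transcript is flagged when it matches a reference mature/hairpin miRNA
#' (>= `minIdentity` identity over >= `minRefCoverage` of the reference
#' length, exact local alignment) and its predicted secondary structure has a
#' free energy in the stable precursor window (-80 to -30 kcal/mol).
#'
#' @param seq the transcript sequence.
#' @param mirnaDb named `DNAStringSet` of reference miRNAs (empty allowed).
#' @param foldResult a [FoldResult-class] computed on the same sequence.
#' @param minIdentity,minRefCoverage match thresholds (defaults 0.9 / 0.9).
#' @param scoring alignment scoring.
#' @return `TRUE` or `FALSE`.
#' @export
flagMirnaPrecursor <- function(seq, mirnaDb, foldResult,
                               minIdentity = 0.9, minRefCoverage = 0.9,
                               scoring = alignScoring()) {
    s <- .as_char_seq(seq)
    if (length(mirnaDb) == 0L) {
        warning("empty miRNA reference database; nothing can be flagged")
        return(FALSE)
    }
    if (classifyStability(mfe(foldResult), "mirna_precursor") != "stable")
        return(FALSE)
    refs <- .as_char_seq(mirnaDb)
    strands <- c(s, .revcomp(s))
    for (r in refs) {
        rl <- nchar(r)
        for (ss in strands) {
            a <- smithWaterman(r, ss, scoring)
            if (a$score == 0) next
            if (a$nmatch / a$alnlen >= minIdentity &&
                (a$qend - a$qstart + 1L) / rl >= minRefCoverage)
                return(TRUE)
        }
    }
    FALSE
}

#' Write candidate tables as BED6 plus a companion TSV
#'
#' BED6: chrom, 0-based start, end, name = transcript id, score = longest ORF
#' (aa), strand. The TSV carries category, nearest gene and distance.
#'
#' @param candidates candidate table from [detectLncCandidates()].
#' @param bedPath,tsvPath output paths.
#' @export
writeCandidates <- function(candidates, bedPath, tsvPath) {
    bed <- data.frame(candidates$chrom, candidates$start - 1L, candidates$end,
                      candidates$transcript_id, candidates$max_orf_aa,
                      candidates$strand)
    utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(candidates, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(NULL)
}
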