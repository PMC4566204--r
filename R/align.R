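#' Scoring scheme for nucleotide local alignment
#'
#' BLASTN-like defaults: match +2, mismatch -3, and affine gaps where a gap of
#' length L costs `gapOpen + gapExtend * L`.
#'
#' @param match,mismatch,gapOpen,gapExtend integers (penalties positive).
#' @return a list with the four components plus the fitted Karlin-Altschul
#'   `lambda` for the ungapped scheme (uniform base composition) and the
#'   constant `K` used for e-values.
#' @export
alignScoring <- function(match = 2L, mismatch = -3L, gapOpen = 5L, gapExtend = 2L) {
    stopifnot(match > 0, mismatch < 0, gapOpen >= 0, gapExtend > 0)
    f <- function(lam) 0.25 * exp(lam * match) + 0.75 * exp(lam * mismatch) - 1
    lambda <- stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
         lambda = lambda, K = 0.3)
}

.as_char_seq <- function(x) {
    if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
    toupper(x)
}

#' Exact Smith-Waterman local alignment
#'
#' Full affine-gap dynamic programming; used as the exact reference for the
#' seeded engine and as the aligner of last resort for short sequences.
#'
#' @param query,subject nucleotide sequences (character or `DNAString`).
#' @param scoring see [alignScoring()].
#' @return a one-row data.frame: score, qstart, qend, sstart, send, nmatch,
#'   alnlen, gaps (1-based inclusive coordinates; all zero when the best local
#'   alignment is empty).
#' @export
smithWaterman <- function(query, subject, scoring = alignScoring()) {
    q <- .as_char_seq(query); s <- .as_char_seq(subject)
    r <- .sw_align_cpp(q, s, scoring$match, scoring$mismatch,
                       scoring$gapOpen, scoring$gapExtend)
    as.data.frame(r)
}

.evalue <- function(score, qlen, searchSpace, scoring) {
    scoring$K * qlen * searchSpace * exp(-scoring$lambda * score)
}

#' Seeded local alignment search of queries against subjects
#'
#' Word matches of length `wordSize` are grouped into diagonal bands; each
#' band is resolved by exact affine DP inside a subject window, so reported
#' HSPs are optimal within their window. E-values follow Karlin-Altschul with
#' search space = query length x total subject length.
#'
#' @param queries,subjects named character vectors or `DNAStringSet`s.
#' @param scoring see [alignScoring()].
#' @param wordSize seed word length (default 11, BLASTN-like).
#' @param minSeedHits minimum word matches in a band before it is extended.
#' @param evalueMax e-value cutoff; weaker HSPs are dropped.
#' @param bothStrands also search the reverse complement of each query.
#' @param minScore raw-score floor before the e-value test.
#' @return data.frame with qseqid, sseqid, strand, score, bitscore, evalue,
#'   pident (matches / alignment length), identity_pct (matches / query
#'   length), qstart, qend, sstart, send, nmatch, alnlen, gaps, mismatch.
#' @export
searchHits <- function(queries, subjects, scoring = alignScoring(),
                       wordSize = 11L, minSeedHits = 1L, evalueMax = 1e-10,
                       bothStrands = FALSE, minScore = 12L) {
    qn <- names(queries); sn <- names(subjects)
    if (is.null(qn) || is.null(sn)) stop("queries and subjects must be named")
    qs <- .as_char_seq(queries); ss <- .as_char_seq(subjects)
    run <- function(qvec, strand) {
        df <- .seed_search_cpp(qvec, ss, as.integer(wordSize),
                               scoring$match, scoring$mismatch,
                               scoring$gapOpen, scoring$gapExtend,
                               as.integer(minSeedHits), 32L, as.integer(minScore))
        if (nrow(df) == 0L) return(NULL)
        df$strand <- strand
        df
    }
    out <- run(qs, "+")
    if (bothStrands) {
        rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(qs)))
        df <- run(rc, "-")
        if (!is.null(df)) {
            qlen <- nchar(qs)[df$qidx]
            qstart <- qlen - df$qend + 1L
            df$qend <- qlen - df$qstart + 1L
            df$qstart <- qstart
            out <- rbind(out, df)
        }
    }
    if (is.null(out) || nrow(out) == 0L) return(.empty_hits())
    qlen <- nchar(qs)[out$qidx]
    space <- sum(as.numeric(nchar(ss)))
    out$evalue <- .evalue(out$score, qlen, space, scoring)
    out <- out[out$evalue <= evalueMax, , drop = FALSE]
    if (nrow(out) == 0L) return(.empty_hits())
    qlen <- nchar(qs)[out$qidx]
    data.frame(qseqid = qn[out$qidx], sseqid = sn[out$sidx],
               strand = out$strand, score = out$score,
               bitscore = (scoring$lambda * out$score - log(scoring$K)) / log(2),
               evalue = out$evalue,
               pident = 100 * out$nmatch / out$alnlen,
               identity_pct = 100 * out$nmatch / qlen,
               qstart = out$qstart, qend = out$qend,
               sstart = out$sstart, send = out$send,
               nmatch = out$nmatch, alnlen = out$alnlen, gaps = out$gaps,
               mismatch = out$alnlen - out$nmatch - out$gaps,
               stringsAsFactors = FALSE)
}

.empty_hits <- function() {
    data.frame(qseqid = character(), sseqid = character(), strand = character(),
               score = integer(), bitscore = numeric(), evalue = numeric(),
               pident = numeric(), identity_pct = numeric(),
               qstart = integer(), qend = integer(), sstart = integer(),
               send = integer(), nmatch = integer(), alnlen = integer(),
               gaps = integer(), mismatch = integer(), stringsAsFactors = FALSE)
}

#' Best local similarity between two sequences
#'
#' Seeded search of one query against one subject. When no seed word is
#' shared and the DP problem is small (<= 4e6 cells) the exact aligner is
#' used instead, so short diverged pairs are still scored optimally.
#'
#' @inheritParams searchHits
#' @param query,subject single sequences.
#' @param searchSpace subject-set length for the e-value; defaults to the
#'   subject length (a single-pair search).
#' @return a one-row hit data.frame as in [searchHits()], or `NULL` when no
#'   alignment attains `evalueMax`.
#' @export
pairwiseSimilarity <- function(query, subject, scoring = alignScoring(),
                               wordSize = 11L, evalueMax = 1e-10,
                               searchSpace = NULL) {
    q <- .as_char_seq(query); s <- .as_char_seq(subject)
    if (!nzchar(q) || !nzchar(s)) stop("sequences must be non-empty")
    if (grepl("[^ACGTN]", q) || grepl("[^ACGTN]", s))
        stop("sequences must be over A/C/G/T/N")
    hits <- searchHits(stats::setNames(q, "q"), stats::setNames(s, "s"),
                       scoring = scoring, wordSize = wordSize,
                       minSeedHits = 1L, evalueMax = Inf)
    if (nrow(hits) == 0L && as.numeric(nchar(q)) * nchar(s) <= 4e6) {
        r <- smithWaterman(q, s, scoring)
        if (r$score > 0)
            hits <- data.frame(qseqid = "q", sseqid = "s", strand = "+",
                               score = r$score,
                               bitscore = (scoring$lambda * r$score -
                                           log(scoring$K)) / log(2),
                               evalue = NA_real_, pident = 100 * r$nmatch / r$alnlen,
                               identity_pct = 100 * r$nmatch / nchar(q),
                               qstart = r$qstart, qend = r$qend,
                               sstart = r$sstart, send = r$send,
                               nmatch = r$nmatch, alnlen = r$alnlen,
                               gaps = r$gaps,
                               mismatch = r$alnlen - r$nmatch - r$gaps,
                               stringsAsFactors = FALSE)
    }
    if (nrow(hits) == 0L) return(NULL)
    if (is.null(searchSpace)) searchSpace <- nchar(s)
    hits$evalue <- .evalue(hits$score, nchar(q), searchSpace, scoring)
    hits <- hits[order(-hits$score), , drop = FALSE]
    best <- hits[1L, , drop = FALSE]
    if (best$evalue > evalueMax) return(NULL)
    rownames(best) <- NULL
    best
}

#' Write hits in 12-column outfmt-6 compatible TSV
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore.
#'
#' @param hits a hit table from [searchHits()].
#' @param path output path.
#' @export
writeHitsOutfmt6 <- function(hits, path) {
    out <- data.frame(hits$qseqid, hits$sseqid, sprintf("%.3f", hits$pident),
                      hits$alnlen, hits$mismatch, hits$gaps,
                      hits$qstart, hits$qend, hits$sstart, hits$send,
                      sprintf("%.2e", hits$evalue), sprintf("%.1f", hits$bitscore))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
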