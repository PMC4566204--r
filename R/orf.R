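.STOPS <- c("TAA", "TAG", "TGA")

# ORFs in one reading of a codon vector; returns starts (codon index) and
# lengths (aa, stop excluded). The codon run between two enders (stop codons,
# codons containing N, or the sequence end) holds at most one maximal ORF,
# beginning at its first ATG; an N-ender closes without being reported.
.orf_walk <- function(codons) {
    n <- length(codons)
    ender <- which(codons %in% .STOPS | grepl("N", codons, fixed = TRUE))
    seg_end <- c(ender, n + 1L)
    seg_beg <- c(1L, ender + 1L)
    atg <- which(codons == "ATG")
    starts <- integer(); lens <- integer()
    for (k in seq_along(seg_beg)) {
        if (seg_beg[k] >= seg_end[k]) next
        a <- atg[atg >= seg_beg[k] & atg < seg_end[k]][1L]
        if (is.na(a)) next
        starts <- c(starts, a); lens <- c(lens, seg_end[k] - a)
    }
    list(starts = starts, lens = lens)
}

#' Scan all six reading frames for open reading frames
#'
#' Every maximal ORF beginning at a strict ATG start codon and ending at the
#' first in-frame stop (TAA/TAG/TGA) or the sequence end is reported, with
#' amino-acid length excluding the stop codon. Frames -1/-2/-3 are read on
#' the reverse complement; their `orf_start_nt` is 1-based on the
#' reverse-complement strand.
#'
#' @param seq a nucleotide sequence over A/C/G/T/N.
#' @return data.frame with columns frame, orf_start_nt, orf_length_aa;
#'   zero rows when no ORF exists (or the sequence is empty).
#' @export
scanOrfs <- function(seq) {
    s <- .as_char_seq(seq)
    if (grepl("[^ACGTN]", s)) stop("sequence must be over A/C/G/T/N")
    out <- list()
    if (nchar(s) >= 3L) {
        strands <- list(`1` = s, `-1` = as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(s))))
        for (sgn in c(1L, -1L)) {
            ss <- strands[[as.character(sgn)]]
            for (f in 1:3) {
                n <- nchar(ss)
                ncod <- (n - f + 1L) %/% 3L
                if (ncod < 1L) next
                codons <- substring(ss, f + 3L * (seq_len(ncod) - 1L),
                                    f + 3L * seq_len(ncod) - 1L)
                w <- .orf_walk(codons)
                if (length(w$starts))
                    out[[length(out) + 1L]] <- data.frame(
                        frame = sgn * f,
                        orf_start_nt = f + 3L * (w$starts - 1L),
                        orf_length_aa = w$lens)
            }
        }
    }
    if (!length(out))
        return(data.frame(frame = integer(), orf_start_nt = integer(),
                          orf_length_aa = integer()))
    do.call(rbind, out)
}

#' Longest ORF length (aa) across all six frames
#'
#' @param seq nucleotide sequence.
#' @return integer; 0 when no ORF exists.
#' @export
maxOrfAa <- function(seq) {
    o <- scanOrfs(seq)
    if (nrow(o) == 0L) 0L else max(o$orf_length_aa)
}

#' Does a transcript qualify as an lncRNA candidate?
#'
#' The canonical filter: at least 200 nt long with no ORF of 100 amino acids
#' or more in any of the six frames.
#'
#' @param seq the transcript sequence.
#' @param orfReports optionally, the precomputed [scanOrfs()] table.
#' @param minLengthNt,maxOrfAa filter thresholds.
#' @return `TRUE` or `FALSE`.
#' @export
isLncCandidate <- function(seq, orfReports = NULL, minLengthNt = 200L,
                           maxOrfAa = 100L) {
    s <- .as_char_seq(seq)
    if (is.null(orfReports)) orfReports <- scanOrfs(s)
    longest <- if (nrow(orfReports)) max(orfReports$orf_length_aa) else 0L
    nchar(s) >= minLengthNt && longest < maxOrfAa
}
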