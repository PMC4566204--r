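# ---- independent oracles used by the test suite ---------------------------

# enumerate every valid secondary structure (pair sets over complementary
# bases, non-crossing by construction, hairpin loops >= minLoop) of a short
# RNA; returns a list of 2-column pair matrices including the empty one
enum_structures <- function(seq, minLoop = 3L) {
    v <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
    ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
    rec <- function(i, j) {
        if (i > j) return(list(matrix(0L, 0L, 2L)))
        out <- rec(i + 1L, j) # i unpaired
        k0 <- i + minLoop + 1L
        if (k0 <= j) for (k in k0:j) {
            if (!paste0(v[i], v[k]) %in% ok) next
            for (inner in rec(i + 1L, k - 1L))
                for (rest in rec(k + 1L, j))
                    out[[length(out) + 1L]] <- rbind(c(i, k), inner, rest)
        }
        out
    }
    rec(1L, length(v))
}

# maximum pair count by exhaustive enumeration
enum_max_pairs <- function(seq, minLoop = 3L)
    max(vapply(enum_structures(seq, minLoop), nrow, 0L))

# minimum energy by exhaustive enumeration + independent structure scoring
enum_min_energy <- function(seq, params = energyParams()) {
    n <- nchar(seq)
    es <- vapply(enum_structures(seq, params$minLoop), function(p) {
        # respect the DP's internal-loop size bound
        db <- pairsToDotBracket(p, n)
        scoreStructure(seq, db, params)
    }, 0)
    min(es)
}

# best collinear chain score by depth-first enumeration of all increasing
# chains (both orientations), matching the chaining score model
brute_best_chain <- function(ra, rb, maxGap, pen) {
    one <- function(ra, rb) {
        n <- length(ra)
        best <- 0
        rec <- function(last, sc) {
            if (sc > best) best <<- sc
            for (nxt in seq_len(n)) {
                da <- ra[nxt] - ra[last]; db <- rb[nxt] - rb[last]
                if (da < 1 || db < 1 || max(da, db) - 1 > maxGap) next
                rec(nxt, sc + 1 - pen * ((da - 1) + (db - 1)))
            }
        }
        for (st in seq_len(n)) rec(st, 1)
        best
    }
    max(one(ra, rb), one(ra, -rb))
}

# Smith-Waterman oracle through Biostrings (independent C implementation);
# returns score and nmatch of one optimal local alignment
biostrings_sw <- function(q, s, scoring = alignScoring()) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
        match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
    a <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
        substitutionMatrix = mat, gapOpening = scoring$gapOpen,
        gapExtension = scoring$gapExtend)
    list(score = Biostrings::score(a), nmatch = Biostrings::nmatch(a))
}
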