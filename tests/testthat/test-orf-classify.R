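test_that("scanOrfs finds maximal ORFs with strict ATG starts", {
    o <- scanOrfs("ATGAAATAA")
    o1 <- o[o$frame == 1L, ]
    expect_equal(nrow(o1), 1L)
    expect_equal(o1$orf_length_aa, 2L)
    expect_equal(o1$orf_start_nt, 1L)
    expect_equal(nrow(scanOrfs("CCCCCC")), 0L)
    # reverse complement of "TTATTTCAT" is "ATGAAATAA": frame -1, 2 aa
    o <- scanOrfs("TTATTTCAT")
    expect_equal(o$frame, -1L)
    expect_equal(o$orf_length_aa, 2L)
    # ORF running to sequence end without a stop still counts
    expect_equal(scanOrfs("ATGAAAAAA")$orf_length_aa[1], 3L)
    expect_equal(nrow(scanOrfs("")), 0L)
})

test_that("scanOrfs is strand-symmetric", {
    set.seed(4)
    for (rep in 1:20) {
        s <- rand_dna(120)
        rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
        a <- scanOrfs(s); b <- scanOrfs(rc)
        expect_identical(sort(a$orf_length_aa), sort(b$orf_length_aa))
        # frames flip sign as a multiset
        expect_identical(sort(table(sign(a$frame))),
                         sort(table(-sign(b$frame))))
    }
})

test_that("the lncRNA filter flips exactly at 200 nt and 100 aa", {
    base <- function(n) strrep("C", n)
    expect_false(isLncCandidate(base(199)))
    expect_true(isLncCandidate(base(200)))
    # ORF of exactly 99 aa: ATG + 98 codons + stop = 300 nt, padded to >= 200
    orf99 <- paste0("ATG", strrep("GCC", 98), "TAA")
    orf100 <- paste0("ATG", strrep("GCC", 99), "TAA")
    expect_equal(maxOrfAa(orf99), 99L)
    expect_equal(maxOrfAa(orf100), 100L)
    expect_true(isLncCandidate(orf99))
    expect_false(isLncCandidate(orf100))
    # long transcript, small ORF (padding chosen free of ATG on both strands)
    expect_true(isLncCandidate(paste0("ATGAAATAA", strrep("CTC", 170))))
})

test_that("locateTranscript applies the single-HSP >= 50 % coverage rule", {
    one <- data.frame(qseqid = "t", sseqid = "chr1", strand = "+", score = 100,
                      evalue = 1e-30, qstart = 1L, qend = 55L, sstart = 101L,
                      send = 155L)
    r <- locateTranscript(one, 100L)
    expect_equal(r$status, "located")
    expect_equal(r$chrom, "chr1")
    expect_equal(locateTranscript(one[0, ], 100L)$reason, "no_hit")
    expect_equal(locateTranscript(rbind(one, one), 100L)$reason, "multi_hsp")
    low <- one; low$qend <- 40L
    expect_equal(locateTranscript(low, 100L)$reason, "low_coverage")
    # boundary: exactly 50 % coverage is accepted
    half <- one; half$qend <- 50L
    expect_equal(locateTranscript(half, 100L)$status, "located")
})

test_that("TU categories follow the distance and strand rules", {
    an <- mk_annot(starts = c(10000L, 30000L), ends = c(12000L, 32000L),
                   strands = c("+", "-"))
    loc <- function(s, e, st = "+") list(chrom = "chr1", start = s, end = e,
                                         strand = st)
    # gap 600 -> LINC; gap exactly 500 -> LINC; gap 499 -> GATU
    expect_equal(classifyLnc(loc(12601L, 13100L), an)$category, "LINC")
    expect_equal(classifyLnc(loc(12501L, 13000L), an)$category, "LINC")
    expect_equal(classifyLnc(loc(12500L, 12999L), an)$category, "GATU")
    expect_equal(classifyLnc(loc(12500L, 12999L), an)$distance_bp, 499L)
    # opposite-strand overlap -> NAT (precedence over GATU)
    r <- classifyLnc(loc(11900L, 12300L, "-"), an)
    expect_equal(r$category, "NAT")
    expect_equal(r$distance_bp, 0L)
    # same-strand overlap -> distance 0 -> GATU, not NAT
    expect_equal(classifyLnc(loc(11900L, 12300L, "+"), an)$category, "GATU")
    expect_equal(classifyLnc(loc(11900L, 12300L), an)$nearest_gene_id,
                 "spA_g001")
})

test_that("category assignment is shift-invariant and handles edge cases", {
    sh <- 12345L
    an1 <- mk_annot(starts = 10000L, ends = 12000L, strands = "+")
    an2 <- mk_annot(starts = 10000L + sh, ends = 12000L + sh, strands = "+")
    l1 <- list(chrom = "chr1", start = 13000L, end = 13400L, strand = "+")
    l2 <- list(chrom = "chr1", start = 13000L + sh, end = 13400L + sh,
               strand = "+")
    r1 <- classifyLnc(l1, an1); r2 <- classifyLnc(l2, an2)
    expect_equal(r1$distance_bp, r2$distance_bp)
    expect_equal(r1$category, r2$category)
    # nearest-gene tie -> lexicographically smallest id
    tie <- mk_annot(starts = c(1000L, 3000L), ends = c(1400L, 3400L),
                    strands = c("+", "+"), ids = c("zz_gene", "aa_gene"))
    r <- classifyLnc(list(chrom = "chr1", start = 2100L, end = 2300L,
                          strand = "+"), tie)
    expect_equal(r$nearest_gene_id, "aa_gene")
    # chromosome without protein-coding genes -> unclassifiable
    empty <- mk_annot(starts = 1000L, ends = 1400L, strands = "+",
                      kinds = "lnc_annotation")
    expect_equal(classifyLnc(list(chrom = "chr1", start = 1L, end = 300L,
                                  strand = "+"), empty)$category,
                 "unclassifiable")
})

test_that("miRNA precursor flag needs both a reference hit and a stable fold", {
    set.seed(8)
    mir <- rand_dna(21)
    tx <- paste0(rand_dna(200), mir, rand_dna(200))
    db <- Biostrings::DNAStringSet(c(mir1 = mir))
    fake_fold <- function(e) new("FoldResult", sequenceId = "t", sequence = tx,
                                 structure = strrep(".", nchar(tx)), mfe = e,
                                 pairCount = 0L, stabilityClass = "unstable",
                                 context = "mirna_precursor")
    expect_true(flagMirnaPrecursor(tx, db, fake_fold(-71.8)))
    expect_false(flagMirnaPrecursor(tx, db, fake_fold(-10)))
    expect_false(flagMirnaPrecursor(tx, db, fake_fold(-85)))
    other <- Biostrings::DNAStringSet(c(mirX = rand_dna(21)))
    expect_false(flagMirnaPrecursor(tx, other, fake_fold(-50)))
    expect_warning(got <- flagMirnaPrecursor(tx, Biostrings::DNAStringSet(),
                                             fake_fold(-50)), "empty")
    expect_false(got)
})
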