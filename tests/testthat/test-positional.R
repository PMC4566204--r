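# Two collinear genomes sharing six anchor genes; helper builds the blocks
syn_fixture <- function(strandsA = rep("+", 6), strandsB = rep("+", 6),
                        inverted = FALSE) {
    starts <- seq(10000L, by = 5000L, length.out = 6L)
    a <- mk_annot(starts = starts, ends = starts + 1000L, strands = strandsA,
                  species = "A", chromLen = 60000L)
    if (!inverted) {
        b <- mk_annot(starts = starts, ends = starts + 1000L,
                      strands = strandsB, species = "B", chromLen = 60000L)
        pairs <- data.frame(gene_a = buildGeneOrder(a)$gene_id,
                            gene_b = buildGeneOrder(b)$gene_id)
    } else {
        # genome B carries the whole region inverted: mirrored coordinates,
        # flipped strands, reversed order
        L <- 60000L
        bstart <- L - (starts + 1000L)
        b <- mk_annot(starts = sort(bstart), ends = sort(bstart) + 1000L,
                      strands = rev(ifelse(strandsA == "+", "-", "+")),
                      species = "B", chromLen = L,
                      ids = sprintf("B_g%03d", 6:1))
        pairs <- data.frame(gene_a = buildGeneOrder(a)$gene_id,
                            gene_b = sprintf("B_g%03d", 1:6))
    }
    bs <- chainAnchors(findAnchors(a, b, pairs), speciesA = "A", speciesB = "B")
    list(a = a, b = b, bs = bs)
}

test_that("relative direction is anchor-strand aware", {
    gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000), "+")
    geneM <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000), "-")
    left <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 600), "+")
    right <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2500, 2900), "+")
    over <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 1700), "-")
    overS <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 1700), "+")
    expect_equal(relativeDirection(left, gene), "upstream")
    expect_equal(relativeDirection(right, gene), "downstream")
    expect_equal(relativeDirection(left, geneM), "downstream")
    expect_equal(relativeDirection(right, geneM), "upstream")
    expect_equal(relativeDirection(over, gene), "antisense")
    expect_equal(relativeDirection(overS, gene), "overlapping")
})

test_that("an upstream lncRNA is recovered at the syntenic anchor", {
    fx <- syn_fixture()
    g3a <- "A_g003"; g3b <- "B_g003"
    # lncRNA 800 bp upstream (left of a + gene), both genomes
    lnc <- mk_cand("A_lnc1", "A", "chr1", 18200L, 18700L, "+",
                   nearest_gene_id = g3a)
    tlnc <- mk_cand("B_lnc1", "B", "chr1", 18100L, 18600L, "+",
                    nearest_gene_id = g3b)
    r <- positionalCall(as.list(lnc), fx$a, fx$b, fx$bs, tlnc)
    expect_equal(r$status, "positionally_conserved")
    expect_equal(r$relative_direction, "upstream")
    expect_equal(r$matched_lnc_id, "B_lnc1")
    # same target lncRNA on the wrong side -> not found
    wrong <- mk_cand("B_lnc2", "B", "chr1", 21200L, 21700L, "+",
                     nearest_gene_id = g3b)
    r <- positionalCall(as.list(lnc), fx$a, fx$b, fx$bs, wrong)
    expect_equal(r$status, "not_found")
})

test_that("missing synteny, empty target sets and unlocated anchors are typed", {
    fx <- syn_fixture()
    lnc <- mk_cand("A_lnc1", "A", "chr1", 18200L, 18700L, "+",
                   nearest_gene_id = "A_g003")
    none <- mk_cand("dummy", "B", "chr1", 1L, 10L, "+")[0L, ]
    r <- positionalCall(as.list(lnc), fx$a, fx$b, fx$bs, none)
    expect_equal(r$status, "not_found") # vacuous-search safety
    # anchor gene absent from all blocks
    orphan <- lnc; orphan$nearest_gene_id <- "A_g999"
    bs_empty <- chainAnchors(data.frame(gene_a = character(),
                                        gene_b = character(),
                                        chrom_a = character(),
                                        chrom_b = character(),
                                        rank_a = integer(),
                                        rank_b = integer()))
    r <- positionalCall(as.list(orphan), fx$a, fx$b, bs_empty,
                        mk_cand("x", "B", "chr1", 1L, 10L, "+"))
    expect_equal(r$status, "no_synteny")
    unlocated <- lnc; unlocated$chrom <- NA_character_
    r <- positionalCall(as.list(unlocated), fx$a, fx$b, fx$bs, none)
    expect_equal(r$status, "anchor_unlocated")
})

test_that("direction matching survives block inversion", {
    fx <- syn_fixture(inverted = TRUE)
    expect_equal(blocks(fx$bs)$orientation, "inverted")
    # upstream of A_g003 (+ strand): left of it in genome A
    lnc <- mk_cand("A_lnc1", "A", "chr1", 18200L, 18700L, "+",
                   nearest_gene_id = "A_g003")
    # genome B: partner B_g003 is on '-' at mirrored coordinates; upstream
    # = 5' side = *right* of it in raw coordinates
    g3b <- genes(fx$b)["B_g003"]
    tstart <- GenomicRanges::end(g3b) + 800L
    good <- mk_cand("B_up", "B", "chr1", tstart, tstart + 500L, "-",
                    nearest_gene_id = "B_g003")
    bad <- mk_cand("B_down", "B", "chr1",
                   GenomicRanges::start(g3b) - 1300L,
                   GenomicRanges::start(g3b) - 800L, "-",
                   nearest_gene_id = "B_g003")
    r <- positionalCall(as.list(lnc), fx$a, fx$b, fx$bs, rbind(good, bad))
    expect_equal(r$status, "positionally_conserved")
    expect_equal(r$matched_lnc_id, "B_up")
    r <- positionalCall(as.list(lnc), fx$a, fx$b, fx$bs, bad)
    expect_equal(r$status, "not_found")
})

test_that("antisense lncRNAs match through the anchor gene body", {
    fx <- syn_fixture()
    lnc <- mk_cand("A_nat", "A", "chr1", 20500L, 21000L, "-",
                   nearest_gene_id = "A_g003", category = "NAT")
    tl <- mk_cand("B_nat", "B", "chr1", 20200L, 20700L, "-",
                  nearest_gene_id = "B_g003", category = "NAT")
    r <- positionalCall(as.list(lnc), fx$a, fx$b, fx$bs, tl)
    expect_equal(r$status, "positionally_conserved")
    expect_equal(r$relative_direction, "antisense")
})

test_that("summaries count a locus once and report per-lineage percentages", {
    lineageOf <- c(A = "L1", B = "L2", C = "L3")
    row <- function(id, src, tgt, status)
        data.frame(locus_id = id, source_species = src, target_species = tgt,
                   status = status, stringsAsFactors = FALSE)
    calls <- rbind(
        row("c1", "A", "B", "positionally_conserved"),
        row("c1", "A", "C", "not_found"),
        row("c2", "A", "B", "not_found"), row("c2", "A", "C", "no_synteny"),
        row("c3", "A", "B", "not_found"), row("c3", "A", "C", "not_found"),
        row("c4", "A", "B", "no_synteny"), row("c5", "A", "C", "not_found"),
        row("c6", "A", "B", "not_found"), row("c7", "A", "C", "not_found"),
        row("c8", "A", "B", "positionally_conserved"),
        row("c9", "A", "B", "positionally_conserved"))
    s <- summarizePositional(calls, lineageOf)
    expect_equal(s$perLineage$n_lineage_specific, 9L)
    expect_equal(s$perLineage$n_positionally_conserved, 3L)
    expect_equal(s$perLineage$pct_positional, 100 / 3, tolerance = 1e-9)
    expect_setequal(s$dualClass$locus_id, c("c1", "c8", "c9"))
    empty <- summarizePositional(calls[0, ], lineageOf)
    expect_equal(nrow(empty$perLineage), 0L)
})

test_that("telomere distances use the nearer chromosome end", {
    gr <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(1200001L, 14997501L), c(1205000L, 15002500L)),
        seqinfo = GenomeInfoDb::Seqinfo("chr1", 30000000L))
    names(gr) <- c("near", "mid")
    tp <- telomereProximity(gr)
    expect_equal(tp$perLocus$distance_to_nearest_end_bp, c(1200000, 14997500))
    expect_identical(tp$perLocus$within, c(TRUE, FALSE))
    # inclusive at exactly the threshold
    at <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2500001L, 2600000L),
                                 seqinfo = GenomeInfoDb::Seqinfo("chr1", 30000000L))
    expect_true(telomereProximity(at)$perLocus$within)
    suppressWarnings( # GRanges itself also flags the out-of-bound range
        out <- GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(1L, 40000000L),
            seqinfo = GenomeInfoDb::Seqinfo("chr1", 30000000L)))
    expect_error(telomereProximity(out), "outside chromosome bounds")
})

test_that("8 of 12 loci within threshold gives 66.7 % and reflection symmetry", {
    set.seed(61)
    L <- 30000000L
    starts <- c(sample(1:2000000, 8), sample(10000000:12000000, 4))
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, starts + 4999L),
                                 seqinfo = GenomeInfoDb::Seqinfo("chr1", L))
    tp <- telomereProximity(gr)
    expect_equal(tp$n_within, 8L)
    expect_equal(tp$n_total, 12L)
    expect_equal(tp$pct_within, 66.66667, tolerance = 1e-5)
    # reflecting all loci about the chromosome midpoint preserves the fraction
    refl <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(L - (starts + 4999L) + 1L, L - starts + 1L),
        seqinfo = GenomeInfoDb::Seqinfo("chr1", L))
    expect_equal(telomereProximity(refl)$fraction_within, tp$fraction_within)
})
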