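mk_anchor_df <- function(ra, rb, chrom_a = "chr1", chrom_b = "chr1") {
    data.frame(gene_a = sprintf("a%02d", seq_along(ra)),
               gene_b = sprintf("b%02d", seq_along(rb)),
               chrom_a = chrom_a, chrom_b = chrom_b,
               rank_a = ra, rank_b = rb, stringsAsFactors = FALSE)
}

test_that("gene ranks are dense, per chromosome, with deterministic ties", {
    an <- mk_annot(starts = c(100L, 900L, 5000L), ends = c(200L, 1000L, 5100L),
                   strands = c("+", "-", "+"))
    o <- buildGeneOrder(an)
    expect_equal(o$rank, 0:2)
    empty <- mk_annot(starts = 100L, ends = 200L, strands = "+",
                      kinds = "lnc_annotation")
    expect_equal(nrow(buildGeneOrder(empty)), 0L)
    tie <- mk_annot(starts = c(100L, 100L), ends = c(300L, 250L),
                    strands = c("+", "+"), ids = c("gB", "gA"))
    o <- buildGeneOrder(tie)
    expect_equal(o$gene_id[o$rank == 0L], "gA")
})

test_that("findAnchors retains many-to-many pairs with ranks attached", {
    a <- mk_annot(starts = c(100L, 1000L, 2000L, 3000L, 4000L),
                  ends = c(500L, 1400L, 2400L, 3400L, 4400L),
                  strands = rep("+", 5), species = "A")
    b <- mk_annot(starts = c(100L, 1000L, 2000L, 3000L, 4000L),
                  ends = c(500L, 1400L, 2400L, 3400L, 4400L),
                  strands = rep("+", 5), species = "B")
    ids_a <- buildGeneOrder(a)$gene_id; ids_b <- buildGeneOrder(b)$gene_id
    one2one <- data.frame(gene_a = ids_a, gene_b = ids_b)
    expect_equal(nrow(findAnchors(a, b, one2one)), 5L)
    multi <- rbind(one2one, data.frame(gene_a = ids_a[1], gene_b = ids_b[3]))
    expect_equal(nrow(findAnchors(a, b, multi)), 6L)
    none <- data.frame(gene_a = character(), gene_b = character())
    expect_equal(nrow(findAnchors(a, b, none)), 0L)
})

test_that("perfectly collinear and exactly reversed anchors give one block", {
    bs <- chainAnchors(mk_anchor_df(0:4, 0:4))
    expect_equal(nrow(blocks(bs)), 1L)
    expect_equal(blocks(bs)$orientation, "same")
    expect_equal(blocks(bs)$n_anchors, 5L)
    bs <- chainAnchors(mk_anchor_df(0:4, 4:0))
    expect_equal(nrow(blocks(bs)), 1L)
    expect_equal(blocks(bs)$orientation, "inverted")
    expect_equal(blocks(bs)$n_anchors, 5L)
})

test_that("a rank gap beyond maxGapGenes splits a chain into two blocks", {
    ra <- c(0:3, 34:37); rb <- c(0:3, 34:37)
    bs <- chainAnchors(mk_anchor_df(ra, rb), maxGapGenes = 20L, minAnchors = 4L)
    expect_equal(nrow(blocks(bs)), 2L)
    expect_equal(sort(blocks(bs)$n_anchors), c(4L, 4L))
})

test_that("chain DP equals exhaustive best-chain enumeration", {
    set.seed(31)
    for (rep in 1:50) {
        n <- sample(3:10, 1)
        ra <- sample(0:14, n); rb <- sample(0:14, n)
        brute <- brute_best_chain(ra, rb, maxGap = 6, pen = 0.05)
        bs <- chainAnchors(mk_anchor_df(ra, rb), maxGapGenes = 6L,
                           minAnchors = 1L)
        expect_equal(max(blocks(bs)$score), brute, tolerance = 1e-9)
    }
})

test_that("block anchors are strictly monotone in the stated orientation", {
    set.seed(32)
    ra <- sample(0:30, 20); rb <- sample(0:30, 20)
    bs <- chainAnchors(mk_anchor_df(ra, rb), minAnchors = 2L)
    expect_true(validObject(bs)) # validity enforces monotonicity per block
    a <- anchors(bs)
    expect_lte(anyDuplicated(a$gene_a), 0L)
})

test_that("regions project through blocks by their flanking anchors", {
    starts <- seq(1000L, by = 2000L, length.out = 6L)
    a <- mk_annot(starts = starts, ends = starts + 800L, strands = rep("+", 6),
                  species = "A")
    b <- mk_annot(starts = starts + 50L, ends = starts + 850L,
                  strands = rep("+", 6), species = "B")
    oa <- buildGeneOrder(a)$gene_id; ob <- buildGeneOrder(b)$gene_id
    bs <- chainAnchors(findAnchors(a, b, data.frame(gene_a = oa, gene_b = ob)),
                       speciesA = "A", speciesB = "B")
    # an anchor gene's own interval projects onto its partner's interval
    q <- genes(a)[oa[3]]
    pr <- projectRegion(q, bs, a, b)
    expect_true(IRanges::overlapsAny(pr, genes(b)[ob[3]]))
    expect_true(GenomicRanges::start(pr) <= GenomicRanges::start(genes(b)[ob[3]]))
    expect_true(GenomicRanges::end(pr) >= GenomicRanges::end(genes(b)[ob[3]]))
    # a region between anchors 2 and 3 projects between their partners
    mid <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4000L, 4200L))
    pr <- projectRegion(mid, bs, a, b)
    expect_true(GenomicRanges::start(pr) >= GenomicRanges::start(genes(b)[ob[2]]))
    expect_true(GenomicRanges::end(pr) <= GenomicRanges::end(genes(b)[ob[3]]))
    # no blocks on that chromosome -> no projection
    off <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1L, 100L))
    expect_null(projectRegion(off, bs, a, b))
})

test_that("inverted blocks swap the projected flanking order", {
    starts_a <- seq(1000L, by = 2000L, length.out = 6L)
    # genome B carries the region mirrored: partner of gene i sits at
    # mirrored coordinates with flipped strand
    L <- 20000L
    starts_b <- L - (starts_a + 800L)
    a <- mk_annot(starts = starts_a, ends = starts_a + 800L,
                  strands = rep("+", 6), species = "A")
    b <- mk_annot(starts = sort(starts_b), ends = sort(starts_b) + 800L,
                  strands = rep("-", 6), species = "B",
                  ids = sprintf("B_g%03d", 6:1))
    pairs <- data.frame(gene_a = buildGeneOrder(a)$gene_id,
                        gene_b = sprintf("B_g%03d", 1:6))
    bs <- chainAnchors(findAnchors(a, b, pairs), speciesA = "A", speciesB = "B")
    expect_equal(blocks(bs)$orientation, "inverted")
    # query between anchors 2 and 3 -> projected between partners 3 and 2
    mid <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4000L, 4200L))
    pr <- projectRegion(mid, bs, a, b)
    g2 <- genes(b)["B_g002"]; g3 <- genes(b)["B_g003"]
    expect_true(GenomicRanges::start(pr) >= GenomicRanges::start(g3))
    expect_true(GenomicRanges::end(pr) <= GenomicRanges::end(g2))
    expect_equal(S4Vectors::mcols(pr)$orientation, "inverted")
})

test_that("anchor projection round-trips between the genomes", {
    set.seed(33)
    starts <- seq(1000L, by = 1500L, length.out = 8L)
    a <- mk_annot(starts = starts, ends = starts + 700L, strands = rep("+", 8),
                  species = "A")
    b <- mk_annot(starts = starts + 123L, ends = starts + 823L,
                  strands = rep("+", 8), species = "B")
    oa <- buildGeneOrder(a)$gene_id; ob <- buildGeneOrder(b)$gene_id
    pairs <- data.frame(gene_a = oa, gene_b = ob)
    ab <- chainAnchors(findAnchors(a, b, pairs))
    ba <- chainAnchors(findAnchors(b, a, stats::setNames(pairs[2:1],
                                                         c("gene_a", "gene_b"))))
    for (i in c(1L, 4L, 8L)) {
        fwd <- projectRegion(genes(a)[oa[i]], ab, a, b)
        back <- projectRegion(fwd, ba, b, a)
        expect_true(IRanges::overlapsAny(back, genes(a)[oa[i]]))
    }
})

test_that("simulated cohorts yield exactly one block holding all shared anchors", {
    co <- simulateCohort(small_sim_config(seed = 44L))
    a <- co@annotations[["L1_sp1"]]; b <- co@annotations[["L2_sp2"]]
    pairs <- data.frame(gene_a = buildGeneOrder(a)$gene_id,
                        gene_b = buildGeneOrder(b)$gene_id)
    bs <- chainAnchors(findAnchors(a, b, pairs))
    expect_equal(nrow(blocks(bs)), 1L)
    expect_equal(blocks(bs)$n_anchors, nrow(pairs))
    expect_equal(blocks(bs)$orientation, "same")
})
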