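test_that("mutateSequence is identity at zero divergence and total at one", {
    expect_identical(mutateSequence("ACGT", 0), "ACGT")
    set.seed(1)
    s <- strrep("A", 10000)
    m <- mutateSequence(s, 1)
    expect_equal(nchar(m), 10000)
    expect_false(grepl("A", m, fixed = TRUE))
    expect_error(mutateSequence("ACGN", 0.1), "A/C/G/T")
    expect_error(mutateSequence("ACGT", 1.2), "\\[0, 1\\]")
})

test_that("observed substitution fraction matches the binomial expectation", {
    set.seed(42)
    s <- strrep("ACGT", 2500)
    m <- mutateSequence(s, 0.2)
    n <- nchar(s)
    frac <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]]) / n
    sd3 <- 3 * sqrt(0.2 * 0.8 / n)
    expect_lt(abs(frac - 0.2), sd3)
})

test_that("SimConfig enforces its invariants", {
    expect_error(simConfig(cdsDivergence = 0.5, lncDivergence = 0.2),
                 "lncDivergence")
    expect_error(simConfig(cdsDivergence = -0.1), "\\[0, 1\\]")
    expect_s4_class(simConfig(), "SimConfig")
})

test_that("same seed gives byte-identical FASTA/GFF3/TSV outputs", {
    cfg <- small_sim_config(seed = 5L)
    d1 <- file.path(tempdir(), "cohortA"); d2 <- file.path(tempdir(), "cohortB")
    writeCohort(simulateCohort(cfg), d1)
    writeCohort(simulateCohort(cfg), d2)
    for (f in list.files(d1)) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), label = f)
    }
    unlink(c(d1, d2), recursive = TRUE)
})

test_that("gene order and coordinates are collinear across all species", {
    co <- simulateCohort(small_sim_config())
    orders <- lapply(co@annotations, function(a) {
        o <- buildGeneOrder(a)
        sub("^[^_]+_sp[0-9]+_", "", o$gene_id[order(o$chrom, o$rank)])
    })
    for (i in seq_along(orders)[-1])
        expect_identical(orders[[i]], orders[[1]])
    st <- lapply(co@annotations, function(a) GenomicRanges::start(genes(a)))
    for (i in seq_along(st)[-1]) expect_identical(st[[i]], st[[1]])
})

test_that("zero divergence makes orthologous sequences identical", {
    cfg <- simConfig(seed = 3L, lineages = c(L1 = 2L, L2 = 2L),
                     genesPerGenome = 20L, nLncSequenceConserved = 2L,
                     nLncPositionalOnly = 2L, nLncPrivate = 0L,
                     cdsDivergence = 0, lncDivergence = 0,
                     withinLineageCdsDivergence = 0,
                     withinLineageLncDivergence = 0)
    co <- simulateCohort(cfg)
    g <- lapply(co@genomes, function(x) as.character(x))
    for (i in seq_along(g)[-1]) expect_identical(unname(g[[i]]), unname(g[[1]]))
})

test_that("private lncRNAs have loci in exactly one lineage", {
    cfg <- simConfig(seed = 9L, lineages = c(L1 = 3L),
                     genesPerGenome = 40L, nLncSequenceConserved = 0L,
                     nLncPositionalOnly = 0L, nLncPrivate = 5L)
    tr <- truth(simulateCohort(cfg))
    priv <- tr[tr$conservation_class == "private", ]
    expect_equal(length(unique(priv$truth_id)), 5L)
    lin <- sub("_sp[0-9]+$", "", priv$species)
    expect_true(all(tapply(lin, priv$truth_id,
                           function(x) length(unique(x))) == 1L))
})

test_that("positional_only loci share anchor index and direction across lineages", {
    co <- simulateCohort(small_sim_config())
    tr <- truth(co)
    po <- tr[tr$conservation_class == "positional_only", ]
    for (tid in unique(po$truth_id)) {
        rows <- po[po$truth_id == tid, ]
        expect_gt(length(unique(sub("_sp[0-9]+$", "", rows$species))), 1L)
        expect_equal(length(unique(rows$relative_direction)), 1L)
        expect_equal(length(unique(sub("^[^_]+_sp[0-9]+_", "",
                                       rows$anchor_gene_id))), 1L)
        expect_equal(length(unique(rows$start)), 1L)
    }
})

test_that("planted lncRNA identity decays faster than CDS identity", {
    co <- simulateCohort(small_sim_config(seed = 21L))
    tr <- truth(co)
    sc <- alignScoring()
    ident <- function(ids_a, ids_b, seqs_a, seqs_b) {
        vapply(seq_along(ids_a), function(i) {
            h <- pairwiseSimilarity(seqs_a[[ids_a[i]]], seqs_b[[ids_b[i]]],
                                    scoring = sc, evalueMax = Inf)
            if (is.null(h)) 0 else h$identity_pct
        }, 0)
    }
    spA <- "L1_sp1"; spB <- "L2_sp1" # cross-lineage comparison
    txA <- co@transcripts[[spA]]; txB <- co@transcripts[[spB]]
    po <- unique(tr$truth_id[tr$conservation_class == "positional_only"])
    lnc_a <- paste0(spA, "_", po); lnc_b <- paste0(spB, "_", po)
    gene_ids <- sprintf("g%04d", 1:20)
    cds_a <- paste0(spA, "_", gene_ids, ".t1")
    cds_b <- paste0(spB, "_", gene_ids, ".t1")
    lnc_id <- ident(lnc_a, lnc_b, txA, txB)
    cds_id <- ident(cds_a, cds_b, txA, txB)
    expect_gte(length(cds_id), 20L)
    expect_lt(mean(lnc_id), mean(cds_id))
})

test_that("oversubscribed genomes raise an explicit sizing error", {
    expect_error(simulateCohort(
        simConfig(genesPerGenome = 5L, nLncSequenceConserved = 3L,
                  nLncPositionalOnly = 3L, nLncPrivate = 3L)),
        "genome too small")
})
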