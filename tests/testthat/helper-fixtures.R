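rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")

# a related pair: ancestor + mutated copy at the given divergence
mutated_pair <- function(n, divergence) {
    a <- rand_dna(n)
    list(a = a, b = mutateSequence(a, divergence))
}

# minimal one-chromosome annotation from parallel vectors
mk_annot <- function(starts, ends, strands, ids = NULL, species = "spA",
                     chrom = "chr1", chromLen = 1000000L,
                     kinds = "protein_coding") {
    if (is.null(ids)) ids <- sprintf("%s_g%03d", species, seq_along(starts))
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(starts, ends), strand = strands,
        gene_id = ids, kind = rep_len(kinds, length(starts)),
        seqinfo = GenomeInfoDb::Seqinfo(chrom, chromLen))
    names(gr) <- ids
    new("GenomeAnnotation", speciesId = species, genes = gr)
}

# one candidate row in the shape detectLncCandidates() produces
mk_cand <- function(transcript_id, species, chrom, start, end, strand,
                    nearest_gene_id = NA, category = "LINC",
                    distance_bp = NA) {
    data.frame(transcript_id = transcript_id, species_id = species,
               chrom = chrom, start = start, end = end, strand = strand,
               category = category, nearest_gene_id = nearest_gene_id,
               distance_bp = distance_bp,
               transcript_length_nt = end - start + 1L, max_orf_aa = 0L,
               stringsAsFactors = FALSE)
}

# small simulation config for unit-scale end-to-end checks
small_sim_config <- function(seed = 11L)
    simConfig(seed = seed, lineages = c(L1 = 2L, L2 = 2L),
              genesPerGenome = 40L, nLncSequenceConserved = 3L,
              nLncPositionalOnly = 3L, nLncPrivate = 2L)
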