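#' Build a simulation configuration
#'
#' Defaults describe the default recovery design: three lineages of 3 + 2 + 2
#' species, one chromosome of 200 collinear genes per genome, and 10 planted
#' lncRNAs per conservation class. Coding genes diverge at 10 % per site on
#' the lineage branch; diverged lncRNA loci at 40 % (intron-like), which puts
#' cross-lineage lncRNA identity well below the 50 % clustering cutoff while
#' within-lineage identity stays far above it.
#'
#' @param seed integer RNG seed.
#' @param lineages named integer vector of species counts per lineage.
#' @param genesPerGenome,geneLengthBp,intergenicMeanBp genome layout (bp).
#' @param cdsDivergence,lncDivergence per-site substitution probabilities on
#'   the ancestor-to-lineage branch for coding genes and diverged lncRNAs.
#' @param withinLineageCdsDivergence,withinLineageLncDivergence per-site
#'   substitution probabilities on the lineage-to-species branch.
#' @param nLncSequenceConserved,nLncPositionalOnly,nLncPrivate planted counts
#'   per conservation class.
#' @param lncLengthBp planted lncRNA length.
#' @param chromCount chromosomes per genome.
#' @param gapLincBp,gapGatuBp anchor-gene offset for LINC- and GATU-type
#'   placements; `natOverlapBp` is the genic overlap of NAT-type placements.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(seed = 42L,
                      lineages = c(Aethionemeae = 3L, Brassicaceae = 2L,
                                   Cleomaceae = 2L),
                      genesPerGenome = 200L, geneLengthBp = 600L,
                      intergenicMeanBp = 1200L,
                      cdsDivergence = 0.10, lncDivergence = 0.40,
                      withinLineageCdsDivergence = 0.02,
                      withinLineageLncDivergence = 0.10,
                      nLncSequenceConserved = 10L, nLncPositionalOnly = 10L,
                      nLncPrivate = 10L, lncLengthBp = 500L, chromCount = 1L,
                      gapLincBp = 1000L, gapGatuBp = 100L, natOverlapBp = 100L) {
    new("SimConfig", seed = as.integer(seed),
        lineages = stats::setNames(as.integer(lineages), names(lineages)),
        genesPerGenome = as.integer(genesPerGenome),
        geneLengthBp = as.integer(geneLengthBp),
        intergenicMeanBp = as.integer(intergenicMeanBp),
        cdsDivergence = cdsDivergence, lncDivergence = lncDivergence,
        withinLineageCdsDivergence = withinLineageCdsDivergence,
        withinLineageLncDivergence = withinLineageLncDivergence,
        nLncSequenceConserved = as.integer(nLncSequenceConserved),
        nLncPositionalOnly = as.integer(nLncPositionalOnly),
        nLncPrivate = as.integer(nLncPrivate),
        lncLengthBp = as.integer(lncLengthBp),
        chromCount = as.integer(chromCount),
        gapLincBp = as.integer(gapLincBp), gapGatuBp = as.integer(gapGatuBp),
        natOverlapBp = as.integer(natOverlapBp))
}

.BASES <- c("A", "C", "G", "T")

.rand_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

#' Mutate a nucleotide sequence at a fixed per-site substitution probability
#'
#' Each site is independently substituted with the given probability to a
#' uniformly chosen *different* base; length is unchanged. Uses the session
#' RNG.
#'
#' @param seq a character string (or `DNAString`) over A/C/G/T.
#' @param divergence substitution probability per site, in \[0, 1\].
#' @return the mutated sequence as a character string.
#' @export
mutateSequence <- function(seq, divergence) {
    s <- .as_char_seq(seq)
    if (grepl("[^ACGT]", s)) stop("sequence must be over A/C/G/T only")
    if (!is.numeric(divergence) || divergence < 0 || divergence > 1)
        stop("divergence must lie in [0, 1]")
    .mutate_positions(s, rep(divergence, nchar(s)))
}

# per-position substitution with a rate vector (vectorized core)
.mutate_positions <- function(s, rates) {
    n <- nchar(s)
    if (n == 0L) return(s)
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(n) < rates)
    if (length(hit)) {
        cur <- match(v[hit], .BASES)
        off <- sample.int(3L, length(hit), replace = TRUE)
        v[hit] <- .BASES[((cur - 1L + off) %% 4L) + 1L]
    }
    paste(v, collapse = "")
}

# codons at Hamming distance >= 2 from every stop codon: a single per-site
# substitution can then never create a premature in-frame stop, emulating
# purifying selection on the reading frame without codon-aware evolution
.SAFE_CODONS <- local({
    b <- c("A", "C", "G", "T")
    all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
    stops <- c("TAA", "TAG", "TGA")
    hd <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    all3[vapply(all3, function(cd)
        all(vapply(stops, function(st) hd(cd, st) >= 2L, TRUE)), TRUE)]
})

# a coding gene: ATG + stop-robust codons + stop, length rounded to codons
.gene_seq <- function(len) {
    ncod <- max(3L, len %/% 3L)
    codons <- sample(.SAFE_CODONS, ncod - 2L, replace = TRUE)
    paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# a lncRNA-like sequence: random, rejection-sampled to keep the longest ORF
# comfortably below the 100 aa coding filter even after mutation
.lnc_seq <- function(len, maxOrf = 80L) {
    repeat {
        s <- .rand_seq(len)
        if (maxOrfAa(s) <= maxOrf) return(s)
    }
}

.revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Generate a multi-lineage cohort of genomes with planted lncRNA truth
#'
#' Draws one ancestral genome (gene order, gene sequences, intergenic space,
#' planted lncRNA loci), then evolves it along a two-level phylogeny: an
#' ancestor-to-lineage branch at `cdsDivergence` / `lncDivergence` and a
#' lineage-to-species branch at the `withinLineage*` rates. All species keep
#' identical gene order and coordinates (substitution-only model), so
#' collinearity holds by construction. Planted loci fall into three classes:
#'
#' * `sequence_conserved` — present in all species, mutating at the coding
#'   rate, recoverable by sequence clustering across lineages;
#' * `positional_only` — present in all species at the same position and
#'   relative direction next to the same anchor gene, but mutating at the
#'   intron-like lncRNA rate, so cross-lineage sequence identity collapses;
#' * `private` — present (and transcribed) in a single lineage; other
#'   lineages carry unrelated intergenic sequence at the locus.
#'
#' Every planted locus is transcribed in all species that carry it, so the
#' "transcribed in at least two species of a lineage" rule is satisfiable.
#'
#' @param config a [SimConfig-class].
#' @return a [SimulatedCohort-class].
#' @export
simulateCohort <- function(config) {
    validObject(config)
    withLocalSeed(config@seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(cfg) {
    nG <- cfg@genesPerGenome
    nLnc <- cfg@nLncSequenceConserved + cfg@nLncPositionalOnly + cfg@nLncPrivate
    if (nLnc > nG)
        stop("genome too small: ", nLnc, " planted lncRNAs need at least as ",
             "many anchor genes (have ", nG, ")")
    if (cfg@natOverlapBp >= min(cfg@lncLengthBp, cfg@geneLengthBp))
        stop("genome too small: natOverlapBp must be smaller than gene and lncRNA length")
    if (cfg@chromCount < 1L || nG < cfg@chromCount)
        stop("genome too small: need at least one gene per chromosome")

    lineage_of_species <- rep(names(cfg@lineages), cfg@lineages)
    species <- unlist(lapply(names(cfg@lineages), function(l)
        paste0(l, "_sp", seq_len(cfg@lineages[[l]]))))
    lineage_of_species <- stats::setNames(lineage_of_species, species)

    ## ---- ancestral plan ---------------------------------------------------
    per_chrom <- diff(floor(seq(0, nG, length.out = cfg@chromCount + 1L)))
    gene_chrom <- rep(seq_len(cfg@chromCount), per_chrom)
    gene_local <- unlist(lapply(per_chrom, seq_len))
    gene_strand <- sample(c("+", "-"), nG, replace = TRUE)
    gene_id <- sprintf("g%04d", seq_len(nG))

    classes <- rep(c("sequence_conserved", "positional_only", "private"),
                   c(cfg@nLncSequenceConserved, cfg@nLncPositionalOnly,
                     cfg@nLncPrivate))
    lnc_cat <- unlist(lapply(c(cfg@nLncSequenceConserved, cfg@nLncPositionalOnly,
                               cfg@nLncPrivate), function(k)
        rep_len(c("LINC", "GATU", "NAT"), k)), use.names = FALSE)
    truth_id <- sprintf("T%03d", seq_len(nLnc))
    private_lineage <- rep_len(names(cfg@lineages), cfg@nLncPrivate)

    # draw anchors in random order, each with a free intergenic gap on a
    # random (preferred) side; skip anchors whose both gaps are taken
    anchor_pool <- sample.int(nG)
    pref_side <- sample(c("left", "right"), nLnc, replace = TRUE)
    anchor_idx <- integer(nLnc); side <- character(nLnc)
    used_gap <- character()
    gap_key <- function(ch, gene_local_i, sd)
        sprintf("%d:%d", ch, if (sd == "left") gene_local_i - 1L else gene_local_i)
    pool_at <- 1L
    for (i in seq_len(nLnc)) {
        placed <- FALSE
        while (!placed && pool_at <= nG) {
            a <- anchor_pool[pool_at]; pool_at <- pool_at + 1L
            ch <- gene_chrom[a]; loc <- gene_local[a]
            for (sd in unique(c(pref_side[i], "left", "right"))) {
                k <- gap_key(ch, loc, sd)
                if (!k %in% used_gap) {
                    anchor_idx[i] <- a; side[i] <- sd
                    used_gap <- c(used_gap, k)
                    placed <- TRUE
                    break
                }
            }
        }
        if (!placed)
            stop("genome too small: could not find a free intergenic gap ",
                 "for planted lncRNA ", truth_id[i])
    }

    # gap widths: index "<chrom>:<gap>" with gap 0..k per chromosome
    lnc_needs <- function(i) {
        switch(lnc_cat[i],
               LINC = 2L * (cfg@gapLincBp + cfg@lncLengthBp) + 400L,
               GATU = 2L * (cfg@gapGatuBp + cfg@lncLengthBp) + 400L,
               NAT  = (cfg@lncLengthBp - cfg@natOverlapBp) +
                      max(400L, cfg@intergenicMeanBp))
    }
    gap_width <- list()
    for (ch in seq_len(cfg@chromCount))
        for (g in 0:per_chrom[ch])
            gap_width[[sprintf("%d:%d", ch, g)]] <-
                max(200L, as.integer(round(stats::rexp(1L, 1 / cfg@intergenicMeanBp))))
    for (i in seq_len(nLnc)) {
        ch <- gene_chrom[anchor_idx[i]]; loc <- gene_local[anchor_idx[i]]
        k <- gap_key(ch, loc, side[i])
        gap_width[[k]] <- max(gap_width[[k]], lnc_needs(i))
    }

    ## ---- ancestral coordinates -------------------------------------------
    glen <- 3L * max(3L, cfg@geneLengthBp %/% 3L)
    gene_start <- integer(nG); gene_end <- integer(nG)
    chrom_len <- integer(cfg@chromCount)
    for (ch in seq_len(cfg@chromCount)) {
        pos <- 0L
        for (g in seq_len(per_chrom[ch])) {
            pos <- pos + gap_width[[sprintf("%d:%d", ch, g - 1L)]]
            gi <- which(gene_chrom == ch & gene_local == g)
            gene_start[gi] <- pos + 1L
            gene_end[gi] <- pos + glen
            pos <- pos + glen
        }
        chrom_len[ch] <- pos + gap_width[[sprintf("%d:%d", ch, per_chrom[ch])]]
    }

    # lncRNA coordinates relative to their anchor
    lnc_start <- integer(nLnc); lnc_end <- integer(nLnc); lnc_strand <- character(nLnc)
    for (i in seq_len(nLnc)) {
        a <- anchor_idx[i]; L <- cfg@lncLengthBp
        off <- switch(lnc_cat[i], LINC = cfg@gapLincBp, GATU = cfg@gapGatuBp, NAT = 0L)
        if (lnc_cat[i] == "NAT") {
            ov <- cfg@natOverlapBp
            if (side[i] == "right") {
                lnc_start[i] <- gene_end[a] - ov + 1L
                lnc_end[i] <- gene_end[a] + (L - ov)
            } else {
                lnc_start[i] <- gene_start[a] - (L - ov)
                lnc_end[i] <- gene_start[a] + ov - 1L
            }
            lnc_strand[i] <- if (gene_strand[a] == "+") "-" else "+"
        } else {
            if (side[i] == "right") {
                lnc_start[i] <- gene_end[a] + off + 1L
                lnc_end[i] <- gene_end[a] + off + L
            } else {
                lnc_start[i] <- gene_start[a] - off - L
                lnc_end[i] <- gene_start[a] - off - 1L
            }
            lnc_strand[i] <- sample(c("+", "-"), 1L)
        }
    }
    rel_dir <- vapply(seq_len(nLnc), function(i) {
        if (lnc_cat[i] == "NAT") return("antisense")
        gplus <- gene_strand[anchor_idx[i]] == "+"
        left <- side[i] == "left"
        if (xor(gplus, left)) "downstream" else "upstream"
    }, "")

    ## ---- ancestral sequence ----------------------------------------------
    anc <- lapply(chrom_len, .rand_seq)
    put <- function(chrs, ch, from, to, s) {
        substr(chrs[[ch]], from, to) <- s
        chrs
    }
    for (g in seq_len(nG))
        anc <- put(anc, gene_chrom[g], gene_start[g], gene_end[g], .gene_seq(glen))
    for (i in seq_len(nLnc)) {
        ch <- gene_chrom[anchor_idx[i]]
        if (lnc_cat[i] == "NAT") {
            # only the non-genic overhang is planted; the genic part stays
            repeat {
                if (side[i] == "right") {
                    ov_from <- gene_end[anchor_idx[i]] + 1L
                    anc <- put(anc, ch, ov_from, lnc_end[i],
                               .rand_seq(lnc_end[i] - ov_from + 1L))
                } else {
                    ov_to <- gene_start[anchor_idx[i]] - 1L
                    anc <- put(anc, ch, lnc_start[i], ov_to,
                               .rand_seq(ov_to - lnc_start[i] + 1L))
                }
                tx <- substr(anc[[ch]], lnc_start[i], lnc_end[i])
                if (lnc_strand[i] == "-") tx <- .revcomp(tx)
                if (maxOrfAa(tx) <= 80L) break
            }
        } else {
            s <- .lnc_seq(cfg@lncLengthBp)
            if (lnc_strand[i] == "-") s <- .revcomp(s)
            anc <- put(anc, ch, lnc_start[i], lnc_end[i], s)
        }
    }

    # per-site mutation-rate class: coding rate for gene bodies and for
    # sequence_conserved loci, intron-like lncRNA rate everywhere else
    cds_like <- lapply(chrom_len, function(n) logical(n))
    for (g in seq_len(nG))
        cds_like[[gene_chrom[g]]][gene_start[g]:gene_end[g]] <- TRUE
    for (i in which(classes == "sequence_conserved"))
        cds_like[[gene_chrom[anchor_idx[i]]]][lnc_start[i]:lnc_end[i]] <- TRUE

    ## ---- evolve: ancestor -> lineage -> species --------------------------
    rates_for <- function(cds_rate, lnc_rate)
        lapply(cds_like, function(m) ifelse(m, cds_rate, lnc_rate))
    lineage_seqs <- list()
    lin_rates <- rates_for(cfg@cdsDivergence, cfg@lncDivergence)
    for (lin in names(cfg@lineages)) {
        chrs <- mapply(function(s, r) .mutate_positions(s, r), anc, lin_rates,
                       SIMPLIFY = FALSE)
        # private loci of other lineages are replaced by unrelated sequence
        for (i in which(classes == "private")) {
            if (private_lineage[i - cfg@nLncSequenceConserved -
                                cfg@nLncPositionalOnly] == lin) next
            ch <- gene_chrom[anchor_idx[i]]
            # keep genic bases of NAT loci; replace only non-genic bases
            a <- anchor_idx[i]
            repl_from <- lnc_start[i]; repl_to <- lnc_end[i]
            if (lnc_cat[i] == "NAT") {
                if (side[i] == "right") repl_from <- gene_end[a] + 1L
                else repl_to <- gene_start[a] - 1L
            }
            chrs <- put(chrs, ch, repl_from, repl_to,
                        .rand_seq(repl_to - repl_from + 1L))
        }
        lineage_seqs[[lin]] <- chrs
    }
    sp_rates <- rates_for(cfg@withinLineageCdsDivergence,
                          cfg@withinLineageLncDivergence)
    genomes <- lapply(species, function(sp) {
        chrs <- mapply(function(s, r) .mutate_positions(s, r),
                       lineage_seqs[[lineage_of_species[[sp]]]], sp_rates,
                       SIMPLIFY = FALSE)
        x <- Biostrings::DNAStringSet(unlist(chrs))
        names(x) <- sprintf("chr%d", seq_along(chrs))
        x
    })
    names(genomes) <- species

    ## ---- annotations, transcripts, truth ---------------------------------
    chrom_names <- sprintf("chr%d", seq_len(cfg@chromCount))
    annotations <- lapply(species, function(sp) {
        gr <- GRanges(chrom_names[gene_chrom],
                      IRanges(gene_start, gene_end), strand = gene_strand,
                      gene_id = paste0(sp, "_", gene_id),
                      kind = "protein_coding",
                      seqinfo = Seqinfo(chrom_names, chrom_len))
        names(gr) <- gr$gene_id
        new("GenomeAnnotation", speciesId = sp, genes = gr)
    })
    names(annotations) <- species

    carriers <- lapply(seq_len(nLnc), function(i) {
        if (classes[i] != "private") species
        else species[lineage_of_species ==
                     private_lineage[i - cfg@nLncSequenceConserved -
                                     cfg@nLncPositionalOnly]]
    })

    truth <- list(); transcripts <- list()
    for (sp in species) {
        seqs <- character(); ids <- character()
        for (g in seq_len(nG)) {
            s <- as.character(Biostrings::subseq(
                genomes[[sp]][[gene_chrom[g]]], gene_start[g], gene_end[g]))
            if (gene_strand[g] == "-") s <- .revcomp(s)
            seqs <- c(seqs, s); ids <- c(ids, paste0(sp, "_", gene_id[g], ".t1"))
        }
        for (i in seq_len(nLnc)) {
            if (!sp %in% carriers[[i]]) next
            ch <- gene_chrom[anchor_idx[i]]
            s <- as.character(Biostrings::subseq(
                genomes[[sp]][[ch]], lnc_start[i], lnc_end[i]))
            if (lnc_strand[i] == "-") s <- .revcomp(s)
            tid <- paste0(sp, "_", truth_id[i])
            seqs <- c(seqs, s); ids <- c(ids, tid)
            truth[[length(truth) + 1L]] <- data.frame(
                truth_id = truth_id[i], conservation_class = classes[i],
                species = sp, chrom = chrom_names[ch],
                start = lnc_start[i], end = lnc_end[i],
                strand = lnc_strand[i],
                anchor_gene_id = paste0(sp, "_", gene_id[anchor_idx[i]]),
                relative_direction = rel_dir[i], category = lnc_cat[i],
                transcript_id = tid, stringsAsFactors = FALSE)
        }
        x <- Biostrings::DNAStringSet(seqs); names(x) <- ids
        transcripts[[sp]] <- x
    }
    truth_df <- if (length(truth)) do.call(rbind, truth) else
        data.frame(truth_id = character(), conservation_class = character(),
                   species = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character(),
                   anchor_gene_id = character(),
                   relative_direction = character(), category = character(),
                   transcript_id = character(), stringsAsFactors = FALSE)
    new("SimulatedCohort", config = cfg, annotations = annotations,
        genomes = genomes, transcripts = transcripts, truth = truth_df)
}

#' Derive the lineage configuration of a simulated cohort
#'
#' @param cohort a [SimulatedCohort-class].
#' @param minSpeciesTranscribed see [lineageConfig()].
#' @return a [LineageConfig-class].
#' @export
cohortLineageConfig <- function(cohort, minSpeciesTranscribed = 2L) {
    sp <- names(cohort@annotations)
    lineageConfig(stats::setNames(sub("_sp[0-9]+$", "", sp), sp),
                  minSpeciesTranscribed = minSpeciesTranscribed)
}

#' Write a simulated cohort to disk as standard formats
#'
#' Per species: 60-column wrapped genome FASTA, GFF3 annotation and transcript
#' FASTA; plus the truth table as TSV and the configuration as YAML. Output is
#' byte-identical for identical cohorts.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (sp in names(cohort@annotations)) {
        writeFasta(cohort@genomes[[sp]], file.path(dir, paste0(sp, ".genome.fasta")))
        writeFasta(cohort@transcripts[[sp]],
                   file.path(dir, paste0(sp, ".transcripts.fasta")))
        writeGff3(cohort@annotations[[sp]], file.path(dir, paste0(sp, ".gff3")))
    }
    utils::write.table(cohort@truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- cohort@config
    yaml::write_yaml(list(
        seed = cfg@seed, lineages = as.list(cfg@lineages),
        genes_per_genome = cfg@genesPerGenome, gene_length_bp = cfg@geneLengthBp,
        intergenic_mean_bp = cfg@intergenicMeanBp,
        cds_divergence = cfg@cdsDivergence, lnc_divergence = cfg@lncDivergence,
        within_lineage_cds_divergence = cfg@withinLineageCdsDivergence,
        within_lineage_lnc_divergence = cfg@withinLineageLncDivergence,
        n_lnc_sequence_conserved = cfg@nLncSequenceConserved,
        n_lnc_positional_only = cfg@nLncPositionalOnly,
        n_lnc_private = cfg@nLncPrivate, lnc_length_bp = cfg@lncLengthBp,
        chrom_count = cfg@chromCount), file.path(dir, "config.yaml"))
    invisible(dir)
}
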