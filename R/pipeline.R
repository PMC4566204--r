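#' Load a cohort from per-species files on disk
#'
#' Counterpart of [writeCohort()]: reads genome FASTA, GFF3 and transcript
#' FASTA per species. Input validation happens before any analysis stage.
#'
#' @param genomePaths,gffPaths,transcriptPaths named (by species) path
#'   vectors.
#' @return a list with `annotations`, `genomes`, `transcripts` usable by
#'   [runPipeline()].
#' @export
loadCohort <- function(genomePaths, gffPaths, transcriptPaths) {
    sp <- names(genomePaths)
    if (is.null(sp) || !identical(sp, names(gffPaths)) ||
        !identical(sp, names(transcriptPaths)))
        stop("genomePaths, gffPaths and transcriptPaths must be named by the same species")
    missing <- c(genomePaths, gffPaths, transcriptPaths)
    missing <- missing[!file.exists(missing)]
    if (length(missing))
        stop("input file(s) not found: ", paste(missing, collapse = ", "))
    list(annotations = stats::setNames(lapply(sp, function(s)
             readGff3(gffPaths[[s]], s)), sp),
         genomes = stats::setNames(lapply(genomePaths, readFasta), sp),
         transcripts = stats::setNames(lapply(transcriptPaths, readFasta), sp))
}

.cohort_parts <- function(cohort) {
    if (is(cohort, "SimulatedCohort"))
        list(annotations = cohort@annotations, genomes = cohort@genomes,
             transcripts = cohort@transcripts)
    else cohort
}

# gene sequences (5'->3') extracted from the genome for synteny search
.gene_seqs <- function(annotation, genome) {
    g <- genes(annotation)
    g <- g[mcols(g)$kind == "protein_coding"]
    if (length(g) == 0L) return(Biostrings::DNAStringSet())
    s <- Biostrings::DNAStringSet(vapply(seq_along(g), function(i) {
        x <- as.character(Biostrings::subseq(genome[[as.character(seqnames(g)[i])]],
                                             start(g)[i], end(g)[i]))
        if (as.character(strand(g)[i]) == "-") .revcomp(x) else x
    }, ""))
    names(s) <- mcols(g)$gene_id
    s
}

# reciprocal-best-hit gene pairs between two species' gene sets; the local
# alignment score is symmetric, so one search provides best hits in both
# directions
.gene_rbh_pairs <- function(seqsA, seqsB, scoring, evalueMax) {
    h <- searchHits(seqsA, seqsB, scoring = scoring, minSeedHits = 2L,
                    evalueMax = evalueMax)
    if (nrow(h) == 0L)
        return(data.frame(gene_a = character(), gene_b = character()))
    h <- h[order(h$qseqid, -h$score, h$sseqid), ]
    a <- h[!duplicated(h$qseqid), , drop = FALSE]
    h <- h[order(h$sseqid, -h$score, h$qseqid), ]
    b <- h[!duplicated(h$sseqid), , drop = FALSE]
    fwd <- paste(a$qseqid, a$sseqid, sep = "\r")
    rev <- paste(b$qseqid, b$sseqid, sep = "\r")
    keep <- a[fwd %in% rev, , drop = FALSE]
    data.frame(gene_a = keep$qseqid, gene_b = keep$sseqid,
               stringsAsFactors = FALSE)
}

#' Run the full positional-conservation pipeline
#'
#' Stages, in order: lncRNA candidate detection and localization per species;
#' categorization (LINC/GATU/NAT); cross-species homology clustering at each
#' identity cutoff with lineage-specificity labels; anchor-gene synteny
#' blocks per species pair; positional-conservation calls for every
#' lineage-specific locus against every species of the other lineages;
#' telomere-proximity statistics and secondary-structure classification of
#' the positionally conserved loci.
#'
#' @param cohort a [SimulatedCohort-class] or a list from [loadCohort()].
#' @param lincfg a [LineageConfig-class]; derived from species names when
#'   omitted and the cohort is simulated.
#' @param identityCutoffs clustering cutoffs in percent (strictly increasing).
#' @param thresholdBp LINC/GATU distance boundary.
#' @param scoring,evalueMax alignment scoring and e-value cutoff.
#' @param maxGapGenes,minAnchors,gapPenalty synteny chaining controls.
#' @param telomereThresholdBp telomere proximity threshold.
#' @param inflation Markov clustering inflation.
#' @param foldStructures fold positionally conserved representatives?
#' @param mirnaDb optional `DNAStringSet` of reference miRNAs; when given,
#'   candidates are flagged as precursors.
#' @param outDir when set, all stage artifacts are written there as
#'   TSV/BED/JSON (byte-identical across re-runs on identical input).
#' @return a run-report list: `candidates`, `rejected`, `clusterings`,
#'   `blockSets`, `calls`, `summary`, `telomere`, `folds`, `counts`,
#'   `provenance`.
#' @export
runPipeline <- function(cohort, lincfg = NULL,
                        identityCutoffs = c(10, 20, 50), thresholdBp = 500L,
                        scoring = alignScoring(), evalueMax = 1e-10,
                        maxGapGenes = 20L, minAnchors = 4L, gapPenalty = 0.05,
                        telomereThresholdBp = 2.5e6, inflation = 1.5,
                        foldStructures = TRUE, mirnaDb = NULL, outDir = NULL) {
    if (is.unsorted(identityCutoffs, strictly = TRUE))
        stop("identityCutoffs must be strictly increasing")
    parts <- .cohort_parts(cohort)
    species <- names(parts$annotations)
    if (is.null(lincfg)) {
        if (is(cohort, "SimulatedCohort")) lincfg <- cohortLineageConfig(cohort)
        else stop("lincfg must be supplied for non-simulated cohorts")
    }
    lineageOf <- lincfg@speciesToLineage
    miss <- setdiff(species, names(lineageOf))
    if (length(miss))
        stop("species missing from lineage configuration: ",
             paste(miss, collapse = ", "))

    ## stage 1-3: candidates per species ------------------------------------
    det <- lapply(species, function(sp)
        detectLncCandidates(parts$transcripts[[sp]], parts$genomes[[sp]],
                            parts$annotations[[sp]], scoring = scoring,
                            evalueMax = evalueMax, thresholdBp = thresholdBp))
    names(det) <- species
    candidates <- do.call(rbind, lapply(det, `[[`, "candidates"))
    rejected <- do.call(rbind, lapply(det, function(x) x$rejected))
    rownames(candidates) <- rownames(rejected) <- NULL

    if (!is.null(mirnaDb) && nrow(candidates)) {
        flags <- vapply(seq_len(nrow(candidates)), function(i) {
            tid <- candidates$transcript_id[i]
            sp <- candidates$species_id[i]
            s <- as.character(parts$transcripts[[sp]][[tid]])
            flagMirnaPrecursor(s, mirnaDb, foldEnergy(s, id = tid),
                               scoring = scoring)
        }, TRUE)
        candidates$mirna_precursor <- flags
    } else if (nrow(candidates)) candidates$mirna_precursor <- NA
    candSeqs <- lapply(species, function(sp) {
        ids <- candidates$transcript_id[candidates$species_id == sp]
        parts$transcripts[[sp]][ids]
    })
    names(candSeqs) <- species

    ## stage 4: homology clustering + lineage labels ------------------------
    cl <- clusterTranscripts(candSeqs, cutoffs = identityCutoffs,
                             scoring = scoring, evalueMax = evalueMax,
                             inflation = inflation)
    outgroupIds <- character()
    if (!is.null(lincfg@outgroupDb)) {
        og <- readFasta(lincfg@outgroupDb)
        allCand <- do.call(c, unname(candSeqs))
        oh <- searchHits(allCand, og, scoring = scoring, minSeedHits = 1L,
                         evalueMax = evalueMax)
        oh <- oh[oh$identity_pct >= min(identityCutoffs), , drop = FALSE]
        outgroupIds <- unique(oh$qseqid)
    }
    clusterings <- lapply(cl$clusterings, assignLineageSpecificity,
                          lincfg = lincfg, outgroupHitIds = outgroupIds)

    ## stage 5: synteny blocks per ordered species pair ---------------------
    geneSeqs <- lapply(species, function(sp)
        .gene_seqs(parts$annotations[[sp]], parts$genomes[[sp]]))
    names(geneSeqs) <- species
    blockSets <- list()
    pair_needed <- function(a, b) lineageOf[[a]] != lineageOf[[b]]
    for (ai in seq_along(species)) for (bi in seq_along(species)) {
        if (ai >= bi) next
        a <- species[ai]; b <- species[bi]
        if (!pair_needed(a, b)) next
        pairs <- .gene_rbh_pairs(geneSeqs[[a]], geneSeqs[[b]], scoring, evalueMax)
        blockSets[[paste(a, b, sep = "|")]] <- chainAnchors(
            findAnchors(parts$annotations[[a]], parts$annotations[[b]], pairs),
            maxGapGenes = maxGapGenes, minAnchors = minAnchors,
            gapPenalty = gapPenalty, speciesA = a, speciesB = b)
        blockSets[[paste(b, a, sep = "|")]] <- chainAnchors(
            findAnchors(parts$annotations[[b]], parts$annotations[[a]],
                        stats::setNames(pairs[c("gene_b", "gene_a")],
                                        c("gene_a", "gene_b"))),
            maxGapGenes = maxGapGenes, minAnchors = minAnchors,
            gapPenalty = gapPenalty, speciesA = b, speciesB = a)
    }

    ## stage 6: positional calls for lineage-specific loci ------------------
    topCut <- as.character(max(identityCutoffs))
    labs <- lineageLabels(clusterings[[topCut]])
    memb <- clusterMembers(clusterings[[topCut]])
    lineage_names <- unique(unname(lineageOf[species]))
    ls_clusters <- names(labs)[labs %in% lineage_names]
    calls <- list()
    status_rank <- c(positionally_conserved = 4L, not_found = 3L,
                     no_synteny = 2L, anchor_unlocated = 1L)
    for (cid in ls_clusters) {
        mm <- memb[memb$cluster_id == cid, , drop = FALSE]
        mm <- mm[order(mm$transcript_id), , drop = FALSE]
        src_lineage <- labs[[cid]]
        targets <- species[lineageOf[species] != src_lineage]
        for (tsp in targets) {
            best <- NULL
            for (r in seq_len(nrow(mm))) {
                lrow <- candidates[candidates$transcript_id ==
                                   mm$transcript_id[r], , drop = FALSE]
                if (nrow(lrow) == 0L) next
                ssp <- lrow$species_id
                bs <- blockSets[[paste(ssp, tsp, sep = "|")]]
                if (is.null(bs)) next
                tl <- candidates[candidates$species_id == tsp, , drop = FALSE]
                pc <- positionalCall(as.list(lrow),
                                     parts$annotations[[ssp]],
                                     parts$annotations[[tsp]], bs, tl)
                pc$source_species <- ssp
                pc$source_transcript <- lrow$transcript_id
                if (is.null(best) ||
                    status_rank[[pc$status]] > status_rank[[best$status]])
                    best <- pc
                if (best$status == "positionally_conserved") break
            }
            if (is.null(best)) next
            calls[[length(calls) + 1L]] <- data.frame(
                locus_id = cid, lnc_id = best$source_transcript,
                source_species = best$source_species, target_species = tsp,
                status = best$status,
                relative_direction = best$relative_direction,
                matched_lnc_id = best$matched_lnc_id,
                anchor_gene_id = best$anchor_gene_id,
                stringsAsFactors = FALSE)
        }
    }
    calls <- if (length(calls)) do.call(rbind, calls) else
        data.frame(locus_id = character(), lnc_id = character(),
                   source_species = character(), target_species = character(),
                   status = character(), relative_direction = character(),
                   matched_lnc_id = character(), anchor_gene_id = character(),
                   stringsAsFactors = FALSE)
    summ <- summarizePositional(calls, lineageOf)

    ## stage 7: telomere proximity of positionally conserved loci -----------
    telomere <- NULL
    consLoci <- unique(calls[calls$status == "positionally_conserved",
                             c("locus_id", "lnc_id")])
    if (nrow(consLoci)) {
        rows <- candidates[match(consLoci$lnc_id, candidates$transcript_id), ]
        sp1 <- rows$species_id[1L]
        sl <- seqlengths(genes(parts$annotations[[sp1]]))
        gr <- GRanges(rows$chrom, IRanges(rows$start, rows$end),
                      seqinfo = Seqinfo(names(sl), as.integer(sl)))
        names(gr) <- rows$transcript_id
        telomere <- telomereProximity(gr, thresholdBp = telomereThresholdBp)
    } else {
        telomere <- list(perLocus = data.frame(), threshold_bp = telomereThresholdBp,
                         n_within = 0L, n_total = 0L,
                         fraction_within = NA_real_, pct_within = NA_real_)
    }

    ## stage 8: secondary structure of conserved representatives ------------
    folds <- list()
    if (foldStructures && nrow(consLoci)) {
        for (i in seq_len(nrow(consLoci))) {
            tid <- consLoci$lnc_id[i]
            sp <- candidates$species_id[candidates$transcript_id == tid]
            s <- as.character(parts$transcripts[[sp]][[tid]])
            folds[[tid]] <- foldEnergy(s, id = tid,
                                       context = "lncrna_structure")
        }
    }

    report <- list(
        candidates = candidates, rejected = rejected,
        clusterings = clusterings, blockSets = blockSets, calls = calls,
        summary = summ, telomere = telomere, folds = folds,
        counts = list(
            n_transcripts = sum(vapply(parts$transcripts, length, 0L)),
            n_candidates = nrow(candidates),
            n_rejected = nrow(rejected),
            n_clusters = vapply(clusterings, function(x)
                length(unique(clusterMembers(x)$cluster_id)), 0L),
            n_lineage_specific = length(ls_clusters),
            n_positionally_conserved = length(unique(consLoci$locus_id))),
        provenance = list(package_version = as.character(
                              utils::packageVersion("synterna")),
                          identity_cutoffs = identityCutoffs,
                          evalue_max = evalueMax, threshold_bp = thresholdBp))
    class(report) <- c("synternaReport", class(report))
    if (!is.null(outDir)) writeRunReport(report, outDir)
    report
}

#' @export
print.synternaReport <- function(x, ...) {
    cat("synterna run report\n")
    cat("  transcripts:", x$counts$n_transcripts,
        "| lncRNA candidates:", x$counts$n_candidates, "\n")
    cat("  clusters per cutoff:",
        paste(names(x$counts$n_clusters), x$counts$n_clusters,
              sep = "% = ", collapse = ", "), "\n")
    cat("  lineage-specific loci:", x$counts$n_lineage_specific,
        "| positionally conserved:", x$counts$n_positionally_conserved, "\n")
    if (!is.null(x$summary$perLineage) && nrow(x$summary$perLineage))
        print(x$summary$perLineage, row.names = FALSE)
    invisible(x)
}

#' Write all run-report artifacts to a directory
#'
#' @param report a run report from [runPipeline()].
#' @param dir output directory.
#' @export
writeRunReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report$candidates, file.path(dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$rejected, file.path(dir, "rejected.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (ct in names(report$clusterings))
        writeClusters(report$clusterings[[ct]],
                      file.path(dir, sprintf("clusters_%s.tsv", ct)))
    utils::write.table(report$calls, file.path(dir, "positional_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(report$summary$perLineage))
        utils::write.table(report$summary$perLineage,
                           file.path(dir, "summary_per_lineage.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$telomere$perLocus) && nrow(report$telomere$perLocus)) {
        utils::write.table(report$telomere$perLocus,
                           file.path(dir, "telomere.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        w <- report$telomere$perLocus
        w <- w[w$within, , drop = FALSE]
        if (nrow(w)) {
            rows <- report$candidates[match(w$lnc_id,
                                            report$candidates$transcript_id), ]
            utils::write.table(data.frame(rows$chrom, rows$start - 1L,
                                          rows$end, rows$transcript_id),
                               file.path(dir, "telomere_within.bed"),
                               sep = "\t", quote = FALSE, row.names = FALSE,
                               col.names = FALSE)
        }
    }
    if (length(report$folds))
        writeFolds(report$folds, file.path(dir, "folds.vienna"),
                   file.path(dir, "folds.tsv"))
    json <- list(counts = report$counts,
                 per_lineage = report$summary$perLineage,
                 telomere = report$telomere[c("threshold_bp", "n_within",
                                              "n_total", "fraction_within")],
                 provenance = report$provenance)
    jsonlite::write_json(json, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}

#' Score pipeline output against a simulated cohort's planted truth
#'
#' Maps clusters to planted truth ids through member transcripts, then
#' measures recovery of the three planted conservation classes.
#'
#' @param report a run report from [runPipeline()] on `cohort`.
#' @param cohort the [SimulatedCohort-class] that produced the input.
#' @return list: `positional_sensitivity`, `positional_precision`,
#'   `private_fp_rate`, `sequence_conserved_sensitivity`, plus the raw
#'   per-class tallies.
#' @export
scoreRecovery <- function(report, cohort) {
    tr <- truth(cohort)
    tx2truth <- stats::setNames(tr$truth_id, tr$transcript_id)
    tru <- unique(tr[c("truth_id", "conservation_class")])
    class_of <- stats::setNames(tru$conservation_class, tru$truth_id)
    topCut <- names(report$clusterings)[length(report$clusterings)]
    cs <- report$clusterings[[topCut]]
    memb <- clusterMembers(cs)
    labs <- lineageLabels(cs)
    cluster_truth <- vapply(split(memb$transcript_id, memb$cluster_id),
                            function(ids) {
        tt <- unique(stats::na.omit(unname(tx2truth[ids])))
        if (length(tt) == 1L) tt else NA_character_
    }, "")
    # positional_only recovery: truth ids called positionally conserved from
    # a lineage-specific cluster
    cons_clusters <- unique(report$calls$locus_id[
        report$calls$status == "positionally_conserved"])
    cons_truth <- unique(stats::na.omit(cluster_truth[cons_clusters]))
    pos_ids <- names(class_of)[class_of == "positional_only"]
    priv_ids <- names(class_of)[class_of == "private"]
    seqc_ids <- names(class_of)[class_of == "sequence_conserved"]
    tp <- sum(pos_ids %in% cons_truth)
    called <- cluster_truth[cons_clusters]
    prec <- if (length(cons_clusters))
        mean(!is.na(called) & class_of[called] == "positional_only") else NA_real_
    fp_priv <- if (length(priv_ids)) mean(priv_ids %in% cons_truth) else NA_real_
    all_label <- names(labs)[labs == "All"]
    seqc_recovered <- unique(stats::na.omit(cluster_truth[all_label]))
    list(positional_sensitivity = if (length(pos_ids)) tp / length(pos_ids)
             else NA_real_,
         positional_precision = prec,
         private_fp_rate = fp_priv,
         sequence_conserved_sensitivity = if (length(seqc_ids))
             mean(seqc_ids %in% seqc_recovered) else NA_real_,
         n_positional_truth = length(pos_ids),
         n_positional_recovered = tp,
         n_conserved_called = length(cons_clusters))
}
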