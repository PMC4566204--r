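#' Lineage configuration constructor
#'
#' @param speciesToLineage named character vector mapping each analyzed
#'   species to exactly one lineage.
#' @param minSpeciesTranscribed minimum distinct species of a lineage
#'   required for a lineage-specific call (default 2).
#' @param outgroupDb optional FASTA path used as the outgroup screen.
#' @return a [LineageConfig-class].
#' @export
lineageConfig <- function(speciesToLineage, minSpeciesTranscribed = 2L,
                          outgroupDb = NULL) {
    new("LineageConfig", speciesToLineage = speciesToLineage,
        minSpeciesTranscribed = as.integer(minSpeciesTranscribed),
        outgroupDb = outgroupDb)
}

#' Build the reciprocal-best-hit graph at an identity cutoff
#'
#' An (undirected) edge joins transcripts a and b when b is a's best-scoring
#' hit within b's species and vice versa, and both direction hits reach
#' `identityCutoffPct` (identical positions / query length) and the e-value
#' cutoff. Within-species hits never form edges; tied best scores are all
#' kept when testing reciprocity. Edge weight is the mean of the two hit
#' scores.
#'
#' @param hits combined hit table from [searchHits()] over all ordered
#'   cross-species pairs.
#' @param speciesOf named character vector: transcript id -> species.
#' @param identityCutoffPct identity cutoff in percent (e.g. 10, 20, 50).
#' @param evalueMax e-value cutoff.
#' @return an `igraph` undirected graph whose vertices are all transcripts
#'   in `speciesOf` (isolated vertices included).
#' @export
buildRbhGraph <- function(hits, speciesOf, identityCutoffPct,
                          evalueMax = 1e-10) {
    ids <- names(speciesOf)
    g0 <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
    g0 <- igraph::set_vertex_attr(g0, "name", value = ids)
    if (nrow(hits) == 0L) return(g0)
    h <- hits[hits$evalue <= evalueMax, , drop = FALSE]
    h <- h[speciesOf[h$qseqid] != speciesOf[h$sseqid], , drop = FALSE]
    if (nrow(h) == 0L) return(g0)
    # best HSP per transcript pair
    pairkey <- paste(h$qseqid, h$sseqid, sep = "\r")
    h <- h[order(pairkey, -h$score), , drop = FALSE]
    h <- h[!duplicated(paste(h$qseqid, h$sseqid, sep = "\r")), , drop = FALSE]
    # best score per (query, subject species); ties kept
    key <- paste(h$qseqid, speciesOf[h$sseqid], sep = "\r")
    bmax <- tapply(h$score, key, max)
    best <- h[h$score == bmax[key], , drop = FALSE]
    best <- best[best$identity_pct >= identityCutoffPct, , drop = FALSE]
    if (nrow(best) == 0L) return(g0)
    fwd <- paste(best$qseqid, best$sseqid, sep = "\r")
    rev <- paste(best$sseqid, best$qseqid, sep = "\r")
    mutual <- best[fwd %in% rev, , drop = FALSE]
    if (nrow(mutual) == 0L) return(g0)
    a <- pmin(mutual$qseqid, mutual$sseqid)
    b <- pmax(mutual$qseqid, mutual$sseqid)
    w <- tapply(mutual$score, paste(a, b, sep = "\r"), mean)
    uk <- unique(paste(a, b, sep = "\r"))
    ends <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
    g <- igraph::add_edges(g0, t(matrix(match(ends, ids), ncol = 2)),
                           weight = as.numeric(w[uk]))
    igraph::simplify(g, edge.attr.comb = "max")
}

#' Markov clustering of a weighted transcript graph
#'
#' Classic MCL on the column-stochastic adjacency matrix with self-loops
#' (loop weight = the column's largest edge weight, or 1 for isolated
#' nodes): alternate expansion (matrix power) and inflation (entrywise power
#' followed by column renormalization), prune small entries, and iterate to
#' convergence. Attractors (positive diagonal mass) define clusters;
#' overlapping attractor systems are merged and any node attached to several
#' clusters goes to the one with the lowest-id attractor. Deterministic for
#' fixed input.
#'
#' @param graph an `igraph` graph with non-negative edge weights.
#' @param inflation inflation exponent (default 1.5).
#' @param expansion expansion power (default 2).
#' @param maxIter,pruneBelow,convergeTol iteration controls.
#' @param cutoffPct identity cutoff annotation carried into the result.
#' @param speciesOf optional named map transcript -> species for the
#'   membership table (parsed from vertex names as `<species>_...` if absent).
#' @return a [HomologyClusterSet-class].
#' @export
markovCluster <- function(graph, inflation = 1.5, expansion = 2L,
                          maxIter = 100L, pruneBelow = 1e-5,
                          convergeTol = 1e-6, cutoffPct = NA_real_,
                          speciesOf = NULL) {
    ids <- igraph::V(graph)$name
    n <- length(ids)
    if (n == 0L)
        return(new("HomologyClusterSet", cutoffPct = cutoffPct,
                   membership = data.frame(cluster_id = character(),
                                           transcript_id = character(),
                                           species_id = character()),
                   lineageLabels = character(), converged = TRUE))
    A <- igraph::as_adjacency_matrix(graph, attr = if (is.null(igraph::E(graph)$weight) ||
                                                      igraph::ecount(graph) == 0L) NULL
                                                   else "weight", sparse = FALSE)
    A <- matrix(as.numeric(A), n, n, dimnames = list(ids, ids))
    loop <- apply(A, 2, max); loop[loop <= 0] <- 1
    diag(A) <- loop
    M <- sweep(A, 2, colSums(A), "/")
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        Mold <- M
        P <- M
        for (e in seq_len(expansion - 1L)) P <- P %*% M
        P <- P ^ inflation
        P <- sweep(P, 2, colSums(P), "/")
        P[P < pruneBelow] <- 0
        P <- sweep(P, 2, colSums(P), "/")
        stopifnot(all(abs(colSums(P) - 1) < 1e-9)) # stochastic invariant
        M <- P
        if (max(abs(M - Mold)) < convergeTol) { converged <- TRUE; break }
    }
    if (!converged)
        warning("Markov clustering did not converge within ", maxIter,
                " iterations; returning current partition")
    attractors <- which(diag(M) > 1e-3)
    if (length(attractors) == 0L) attractors <- seq_len(n)
    support <- lapply(attractors, function(i) which(M[i, ] > 1e-3))
    # merge overlapping attractor systems
    comp <- seq_along(attractors)
    repeat {
        changed <- FALSE
        for (i in seq_along(attractors)) for (j in seq_along(attractors)) {
            if (comp[i] != comp[j] &&
                length(intersect(support[[i]], support[[j]]))) {
                comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    assign <- integer(n)
    for (ci in unique(comp)) {
        members <- sort(unique(unlist(support[comp == ci])))
        free <- members[assign[members] == 0L]
        assign[free] <- ci
    }
    if (any(assign == 0L)) {
        # numerical stragglers: attach to the attractor holding most of the
        # node's column mass
        for (j in which(assign == 0L)) {
            i <- attractors[which.max(M[attractors, j])]
            assign[j] <- comp[match(i, attractors)]
        }
    }
    # deterministic cluster ids ordered by smallest member name
    grp <- split(ids, assign)
    grp <- grp[order(vapply(grp, min, ""))]
    membership <- data.frame(
        cluster_id = rep(sprintf("C%04d", seq_along(grp)),
                         vapply(grp, length, 0L)),
        transcript_id = unlist(grp, use.names = FALSE),
        stringsAsFactors = FALSE)
    membership <- membership[order(membership$cluster_id,
                                   membership$transcript_id), ]
    rownames(membership) <- NULL
    membership$species_id <- if (!is.null(speciesOf))
        unname(speciesOf[membership$transcript_id])
    else sub("^([^_]+_sp[0-9]+)_.*$", "\\1", membership$transcript_id)
    new("HomologyClusterSet", cutoffPct = cutoffPct, membership = membership,
        lineageLabels = character(), converged = converged)
}

#' Label clusters by lineage specificity
#'
#' A cluster is labelled `All` when its members span every configured
#' lineage; lineage `L` when all members belong to `L`, at least
#' `minSpeciesTranscribed` distinct species are represented, and no member
#' has an outgroup hit passing the same cutoffs; `unassigned` otherwise.
#'
#' @param clusterSet a [HomologyClusterSet-class].
#' @param lincfg a [LineageConfig-class].
#' @param outgroupHitIds transcript ids with a qualifying outgroup hit.
#' @return the cluster set with its `lineageLabels` slot filled.
#' @export
assignLineageSpecificity <- function(clusterSet, lincfg,
                                     outgroupHitIds = character()) {
    m <- clusterMembers(clusterSet)
    map <- lincfg@speciesToLineage
    missing <- setdiff(unique(m$species_id), names(map))
    if (length(missing))
        stop("species missing from lineage configuration: ",
             paste(missing, collapse = ", "))
    all_lineages <- unique(unname(map))
    labs <- vapply(split(m, m$cluster_id), function(mm) {
        lin <- unique(unname(map[mm$species_id]))
        if (all(all_lineages %in% lin)) return("All")
        if (length(lin) == 1L &&
            length(unique(mm$species_id)) >= lincfg@minSpeciesTranscribed &&
            !any(mm$transcript_id %in% outgroupHitIds))
            return(lin)
        "unassigned"
    }, "")
    clusterSet@lineageLabels <- labs
    validObject(clusterSet)
    clusterSet
}

#' Cross-species clustering of transcripts at several identity cutoffs
#'
#' Computes seeded-alignment hits for every ordered cross-species pair once,
#' then builds the RBH graph and Markov clustering independently at each
#' cutoff.
#'
#' @param seqsBySpecies named list of named `DNAStringSet`s.
#' @param cutoffs identity cutoffs in percent (default 10, 20, 50).
#' @param scoring,evalueMax,inflation see the respective functions.
#' @return list with `hits` (combined hit table), `speciesOf`, and
#'   `clusterings` (a [HomologyClusterSet-class] per cutoff, named by cutoff).
#' @export
clusterTranscripts <- function(seqsBySpecies, cutoffs = c(10, 20, 50),
                               scoring = alignScoring(), evalueMax = 1e-10,
                               inflation = 1.5) {
    species <- names(seqsBySpecies)
    speciesOf <- unlist(lapply(species, function(sp)
        stats::setNames(rep(sp, length(seqsBySpecies[[sp]])),
                        names(seqsBySpecies[[sp]]))))
    hits <- list()
    for (a in species) for (b in species) {
        if (a == b) next
        h <- searchHits(seqsBySpecies[[a]], seqsBySpecies[[b]],
                        scoring = scoring, minSeedHits = 1L,
                        evalueMax = evalueMax)
        if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
    hits <- if (length(hits)) do.call(rbind, hits) else .empty_hits()
    clusterings <- lapply(cutoffs, function(ct) {
        g <- buildRbhGraph(hits, speciesOf, identityCutoffPct = ct,
                           evalueMax = evalueMax)
        markovCluster(g, inflation = inflation, cutoffPct = ct,
                      speciesOf = speciesOf)
    })
    names(clusterings) <- as.character(cutoffs)
    list(hits = hits, speciesOf = speciesOf, clusterings = clusterings)
}

#' Write a clustering as TSV
#'
#' @param clusterSet a [HomologyClusterSet-class].
#' @param path output path.
#' @export
writeClusters <- function(clusterSet, path) {
    m <- clusterMembers(clusterSet)
    m$cutoff_pct <- clusterSet@cutoffPct
    labs <- lineageLabels(clusterSet)
    m$lineage_label <- if (length(labs)) unname(labs[m$cluster_id]) else NA
    utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
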