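mk_graph <- function(edges, n, prefix = "n") {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = sprintf("%s%02d", prefix,
                                                            seq_len(n)))
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    g
}

partition_of <- function(cs) {
    m <- clusterMembers(cs)
    unname(lapply(split(m$transcript_id, m$cluster_id), sort))
}

test_that("disconnected components never merge; isolated nodes are singletons", {
    tri2 <- mk_graph(rbind(c(1, 2), c(2, 3), c(1, 3),
                           c(4, 5), c(5, 6), c(4, 6)), 7)
    cs <- markovCluster(tri2, speciesOf = stats::setNames(rep("s", 7),
                                                          sprintf("n%02d", 1:7)))
    p <- partition_of(cs)
    expect_length(p, 3L)
    expect_true(list(c("n01", "n02", "n03")) %in% p)
    expect_true(list(c("n04", "n05", "n06")) %in% p)
    expect_true(list("n07") %in% p)
})

test_that("the barbell graph splits at the bridge under inflation 2", {
    cl <- function(off) t(utils::combn(off + 1:4, 2))
    edges <- rbind(cl(0), cl(4), c(4, 5)) # two 4-cliques + unit bridge
    g <- mk_graph(edges, 8)
    cs <- markovCluster(g, inflation = 2,
                        speciesOf = stats::setNames(rep("s", 8),
                                                    sprintf("n%02d", 1:8)))
    p <- partition_of(cs)
    # reference: a bare power/inflation iteration without pruning, with
    # clusters read off the converged rows (independent of the package code)
    A <- matrix(0, 8, 8)
    A[edges] <- 1; A <- A + t(A); diag(A) <- apply(A, 2, max)
    M <- sweep(A, 2, colSums(A), "/")
    for (it in 1:200) {
        M <- (M %*% M)^2
        M <- sweep(M, 2, colSums(M), "/")
    }
    att <- which(rowSums(M) > 1e-3)
    ref <- unique(lapply(att, function(i) which(M[i, ] > 1e-6)))
    ref <- lapply(ref, function(ix) sprintf("n%02d", ix))
    expect_length(p, length(ref))
    for (cluster in ref) expect_true(list(cluster) %in% p)
    expect_true(list(sprintf("n%02d", 1:4)) %in% p)
    expect_true(list(sprintf("n%02d", 5:8)) %in% p)
})

test_that("MCL is deterministic and clusters never span graph components", {
    set.seed(99)
    for (rep in 1:40) {
        n <- sample(3:8, 1)
        dens <- stats::runif(1, 0.2, 0.8)
        adj <- matrix(stats::runif(n * n) < dens, n, n)
        adj[lower.tri(adj, diag = TRUE)] <- FALSE
        edges <- which(adj, arr.ind = TRUE)
        g <- mk_graph(edges, n)
        so <- stats::setNames(rep("s", n), igraph::V(g)$name)
        cs1 <- markovCluster(g, speciesOf = so)
        cs2 <- markovCluster(g, speciesOf = so)
        expect_identical(clusterMembers(cs1), clusterMembers(cs2))
        # component oracle via igraph
        comp <- igraph::components(g)$membership
        m <- clusterMembers(cs1)
        for (cid in unique(m$cluster_id)) {
            members <- m$transcript_id[m$cluster_id == cid]
            expect_length(unique(comp[members]), 1L)
        }
    }
})

test_that("reciprocal best hits require mutuality and the identity cutoff", {
    so <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C")
    hit <- function(q, s, score, ident) data.frame(
        qseqid = q, sseqid = s, score = score, identity_pct = ident,
        evalue = 1e-30, stringsAsFactors = FALSE)
    # mutual best, passing -> edge
    h <- rbind(hit("a1", "b1", 100, 80), hit("b1", "a1", 100, 80))
    g <- buildRbhGraph(h, so, 50)
    expect_equal(igraph::ecount(g), 1L)
    # a1's best in B is b1, but b1's best in A is a2 -> no a1-b1 edge
    h2 <- rbind(hit("a1", "b1", 100, 80), hit("b1", "a1", 90, 80),
                hit("b1", "a2", 150, 80), hit("a2", "b1", 150, 80))
    g2 <- buildRbhGraph(h2, so, 50)
    expect_false(igraph::are_adjacent(g2, "a1", "b1"))
    expect_true(igraph::are_adjacent(g2, "a2", "b1"))
    # identity 45 %: edge at cutoff 20, none at cutoff 50
    h3 <- rbind(hit("a1", "b1", 100, 45), hit("b1", "a1", 100, 45))
    expect_equal(igraph::ecount(buildRbhGraph(h3, so, 50)), 0L)
    expect_equal(igraph::ecount(buildRbhGraph(h3, so, 20)), 1L)
    # within-species hits never form edges
    h4 <- rbind(hit("b1", "b2", 500, 99), hit("b2", "b1", 500, 99))
    expect_equal(igraph::ecount(buildRbhGraph(h4, so, 10)), 0L)
})

test_that("raising the cutoff never adds edges and never merges clusters", {
    set.seed(17)
    species <- c("A", "B", "C")
    ids <- as.vector(outer(species, 1:4, paste0))
    so <- stats::setNames(rep(species, 4), ids)
    hits <- list()
    for (q in ids) for (s in ids) {
        if (so[[q]] == so[[s]] || q == s) next
        sc <- sample(50:200, 1)
        hits[[length(hits) + 1L]] <- data.frame(
            qseqid = q, sseqid = s, score = sc,
            identity_pct = stats::runif(1, 5, 95), evalue = 1e-20,
            stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, hits)
    gs <- lapply(c(10, 20, 50), function(ct) buildRbhGraph(hits, so, ct))
    e <- lapply(gs, function(g) igraph::as_ids(igraph::E(g)))
    expect_true(all(e[[3]] %in% e[[2]]))
    expect_true(all(e[[2]] %in% e[[1]]))
    ncl <- vapply(gs, function(g)
        length(unique(clusterMembers(markovCluster(g, speciesOf = so))$cluster_id)),
        0L)
    expect_true(all(diff(ncl) >= 0))
})

test_that("lineage labels follow the specificity rules", {
    lc <- lineageConfig(c(A1 = "Aeth", A2 = "Aeth", A3 = "Aeth", A4 = "Aeth",
                          B1 = "Brass", C1 = "Cleo"))
    mk_cs <- function(members, species) {
        new("HomologyClusterSet", cutoffPct = 50,
            membership = data.frame(cluster_id = "C0001",
                                    transcript_id = members,
                                    species_id = species,
                                    stringsAsFactors = FALSE),
            lineageLabels = character(), converged = TRUE)
    }
    lab <- function(cs, out = character())
        unname(lineageLabels(assignLineageSpecificity(cs, lc, out))["C0001"])
    # spans all three lineages -> All
    expect_equal(lab(mk_cs(c("tA", "tB", "tC"), c("A1", "B1", "C1"))), "All")
    # four Aethionema species, no outgroup hit -> lineage-specific
    expect_equal(lab(mk_cs(paste0("t", 1:4), paste0("A", 1:4))), "Aeth")
    # same cluster with an outgroup hit -> unassigned
    expect_equal(lab(mk_cs(paste0("t", 1:4), paste0("A", 1:4)), out = "t2"),
                 "unassigned")
    # single species -> unassigned (needs >= 2 species of the lineage)
    expect_equal(lab(mk_cs(c("x1", "x2"), c("A1", "A1"))), "unassigned")
    # unmapped species -> configuration error
    expect_error(assignLineageSpecificity(mk_cs("t", "ZZ"), lc), "missing")
})
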