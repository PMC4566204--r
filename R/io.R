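#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are upper-cased; duplicate identifiers and non-IUPAC characters
#' are rejected with explicit errors.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`.
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    if (file.size(path) == 0L) stop("empty FASTA file: ", path)
    x <- Biostrings::readDNAStringSet(path)
    if (length(x) == 0L) stop("no records in FASTA file: ", path)
    names(x) <- sub("\\s.*$", "", names(x))
    dup <- names(x)[duplicated(names(x))]
    if (length(dup))
        stop("duplicate FASTA id: ", paste(unique(dup), collapse = ", "))
    Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write a DNAStringSet as 60-column wrapped FASTA
#'
#' @param x a named `DNAStringSet` (or named character vector).
#' @param path output path.
#' @export
writeFasta <- function(x, path) {
    if (is.character(x)) x <- Biostrings::DNAStringSet(x)
    if (is.null(names(x)) || any(!nzchar(names(x))))
        stop("all sequences must be named")
    Biostrings::writeXStringSet(x, filepath = path, width = 60L)
    invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Keeps `gene` features (and features typed `lnc_annotation`), requiring an
#' `ID` attribute and a defined strand. Chromosome lengths are taken from the
#' `##sequence-region` pragmas.
#'
#' @param path path to a GFF3 file.
#' @param speciesId species identifier to attach.
#' @return a [GenomeAnnotation-class].
#' @export
readGff3 <- function(path, speciesId) {
    if (!file.exists(path)) stop("GFF3 file not found: ", path)
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- as.character(gr$type) %in% c("gene", "lnc_annotation")
    gr <- gr[keep]
    if (length(gr) == 0L) stop("no gene features in ", path)
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
        stop("GFF3 gene feature without ID attribute in ", path)
    st <- as.character(strand(gr))
    bad <- which(!st %in% c("+", "-"))
    if (length(bad))
        stop("GFF3 gene feature with undefined strand ('.'): ",
             paste(ids[bad], collapse = ", "))
    kind <- ifelse(as.character(gr$type) == "gene", "protein_coding",
                   "lnc_annotation")
    if (!is.null(gr$gene_kind))
        kind[!is.na(gr$gene_kind)] <- gr$gene_kind[!is.na(gr$gene_kind)]
    sl <- seqlengths(gr)
    if (any(is.na(sl))) {
        # fall back to parsing ##sequence-region pragmas directly
        ln <- grep("^##sequence-region", readLines(path), value = TRUE)
        if (length(ln)) {
            parts <- strsplit(trimws(ln), "\\s+")
            nm <- vapply(parts, `[[`, "", 2L)
            len <- as.integer(vapply(parts, `[[`, "", 4L))
            sl[nm[nm %in% names(sl)]] <- len[nm %in% names(sl)]
        }
        sl[is.na(sl)] <- vapply(names(sl)[is.na(sl)], function(ch)
            max(end(gr)[as.character(seqnames(gr)) == ch]), 0L)
        seqlengths(gr) <- sl
    }
    out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)), strand = st,
                   gene_id = as.character(ids), kind = kind,
                   seqinfo = seqinfo(gr))
    names(out) <- out$gene_id
    new("GenomeAnnotation", speciesId = speciesId, genes = out)
}

#' Write a GenomeAnnotation as GFF3
#'
#' Emits the `##gff-version 3` pragma, one `##sequence-region` line per
#' chromosome, and `gene` features (with a child `mRNA` per protein-coding
#' gene) carrying `ID=` attributes, 1-based inclusive coordinates.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param path output path.
#' @export
writeGff3 <- function(annotation, path) {
    g <- genes(annotation)
    sl <- seqlengths(g)
    lines <- c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", names(sl), sl))
    fmt <- function(gr, type, attr) {
        sprintf("%s\tsynterna\t%s\t%d\t%d\t.\t%s\t.\t%s",
                as.character(seqnames(gr)), type, start(gr), end(gr),
                as.character(strand(gr)), attr)
    }
    ord <- order(as.character(seqnames(g)), start(g), g$gene_id)
    g <- g[ord]
    for (i in seq_along(g)) {
        gi <- g[i]
        lines <- c(lines,
                   fmt(gi, "gene", sprintf("ID=%s;gene_kind=%s",
                                           gi$gene_id, gi$kind)))
        if (gi$kind == "protein_coding")
            lines <- c(lines, fmt(gi, "mRNA",
                                  sprintf("ID=%s.t1;Parent=%s",
                                          gi$gene_id, gi$gene_id)))
    }
    writeLines(lines, path)
    invisible(path)
}

# seed the session RNG locally, restoring any previous state on exit
withLocalSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    code
}
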