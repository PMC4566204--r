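#' Parameters of the reduced nearest-neighbour energy model
#'
#' The built-in folding model uses stacking energies for the 36 ordered pair
#' stacks (rows = outer pair, columns = inner pair, over AU/UA/GC/CG/GU/UG)
#' plus affine loop penalties and a linear multiloop model. Values are
#' Turner-like in sign and ordering but deliberately reduced: absolute
#' kcal/mol outputs are **not** comparable with full Turner-model folders
#' such as RNAfold (see [foldWithRNAfold()] for an external adapter).
#'
#' @param minLoop minimum hairpin loop size in nt (default 3).
#' @param maxInternal largest internal/bulge loop considered (default 30).
#' @return a list of model parameters.
#' @export
energyParams <- function(minLoop = 3L, maxInternal = 30L) {
    pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
    stack <- matrix(c(
        #  AU    UA    GC    CG    GU    UG      (inner)
        -0.9, -1.1, -2.2, -2.1, -0.6, -1.4, # outer AU
        -1.3, -0.9, -2.4, -2.1, -1.0, -1.3, # outer UA
        -2.1, -2.3, -3.3, -2.4, -1.4, -2.1, # outer GC
        -2.4, -2.1, -3.4, -3.3, -1.5, -2.5, # outer CG
        -1.3, -1.4, -2.5, -2.1, -0.5, -0.4, # outer GU
        -1.0, -0.6, -1.5, -1.4, -0.3, -0.5  # outer UG
    ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
    list(stack = stack,
         hairpinA = 4.5, hairpinB = 0.12, hairpinCap = 30L,
         bulgeA = 3.6, bulgeB = 0.25,
         internalA = 3.0, internalB = 0.25,
         multiA = 3.4, multiB = 0.4, multiC = 0.1,
         minLoop = as.integer(minLoop), maxInternal = as.integer(maxInternal))
}

.as_rna <- function(seq) {
    s <- toupper(.as_char_seq(seq))
    s <- chartr("T", "U", s)
    if (grepl("[^ACGU]", s)) stop("sequence must be over A/C/G/U (or T)")
    s
}

#' Maximize base pairs (Nussinov algorithm)
#'
#' Maximum number of non-crossing AU/GC/GU pairs with hairpin loops of at
#' least `minLoop` unpaired bases, by the standard O(n^3) recursion; one
#' optimal structure is returned via a deterministic traceback that prefers
#' pairing the interval ends over bifurcation on ties.
#'
#' @param seq RNA (or DNA) sequence; T is treated as U.
#' @param minLoop minimum hairpin loop (default 3).
#' @return list with `pairCount` and `structure` (dot-bracket).
#' @export
foldNussinov <- function(seq, minLoop = 3L) {
    s <- .as_rna(seq)
    r <- .nussinov_cpp(s, as.integer(minLoop))
    list(pairCount = as.integer(r$pairs), structure = r$structure)
}

#' Minimum-free-energy folding under the reduced energy model
#'
#' Zuker-style recursion over the embedded parameter table (stacking +
#' affine loop penalties, no dangling ends). The open chain has energy 0, so
#' the reported MFE is never positive.
#'
#' @param seq RNA (or DNA) sequence; T is treated as U.
#' @param params model parameters from [energyParams()].
#' @param id sequence identifier carried into the result.
#' @param context stability context for [classifyStability()].
#' @param maxLen guard against accidental genome-scale inputs (default 5000).
#' @return a [FoldResult-class].
#' @export
foldEnergy <- function(seq, params = energyParams(), id = "seq",
                       context = "lncrna_structure", maxLen = 5000L) {
    s <- .as_rna(seq)
    if (nchar(s) > maxLen)
        stop("sequence longer than maxLen (", maxLen, " nt): ", nchar(s))
    r <- .zuker_cpp(s, params$stack,
                    params$hairpinA, params$hairpinB,
                    params$bulgeA, params$bulgeB,
                    params$internalA, params$internalB,
                    params$multiA, params$multiB, params$multiC,
                    params$minLoop, params$maxInternal, params$hairpinCap)
    structure <- r$structure
    m <- round(r$mfe, 6)
    new("FoldResult", sequenceId = id, sequence = s, structure = structure,
        mfe = m, pairCount = sum(strsplit(structure, "")[[1]] == "("),
        stabilityClass = classifyStability(m, context), context = context)
}

#' Parse a dot-bracket string into base pairs
#'
#' @param structure dot-bracket string.
#' @return two-column integer matrix (i, j), i < j, 1-based.
#' @export
dotBracketPairs <- function(structure) {
    ch <- strsplit(structure, "")[[1]]
    if (any(!ch %in% c("(", ")", ".")))
        stop("structure may contain only '(', ')' and '.'")
    stack <- integer(); out <- matrix(0L, 0L, 2L)
    for (i in seq_along(ch)) {
        if (ch[i] == "(") stack <- c(stack, i)
        else if (ch[i] == ")") {
            if (!length(stack)) stop("unbalanced brackets")
            out <- rbind(out, c(stack[length(stack)], i))
            stack <- stack[-length(stack)]
        }
    }
    if (length(stack)) stop("unbalanced brackets")
    out[order(out[, 1L]), , drop = FALSE]
}

#' Render base pairs as a dot-bracket string
#'
#' @param pairs two-column matrix of (i, j) pairs.
#' @param n sequence length.
#' @return dot-bracket string.
#' @export
pairsToDotBracket <- function(pairs, n) {
    ch <- rep(".", n)
    if (nrow(pairs)) { ch[pairs[, 1L]] <- "("; ch[pairs[, 2L]] <- ")" }
    paste(ch, collapse = "")
}

#' Independently re-score a secondary structure under the reduced model
#'
#' Decomposes the structure into its loops (hairpins, stacks, bulges,
#' internal loops, multiloops, external bases) and sums the model terms.
#' This is a direct implementation of the energy function, independent of
#' the dynamic-programming folder, and is used to verify that reported MFEs
#' equal the energy of the reported structure.
#'
#' @param seq RNA sequence.
#' @param structure dot-bracket string of the same length.
#' @param params model parameters.
#' @return energy in kcal/mol.
#' @export
scoreStructure <- function(seq, structure, params = energyParams()) {
    s <- .as_rna(seq)
    stopifnot(nchar(s) == nchar(structure))
    pr <- dotBracketPairs(structure)
    if (nrow(pr) == 0L) return(0)
    v <- strsplit(s, "")[[1]]
    pc <- function(i, j) paste0(v[i], v[j])
    partner <- integer(nchar(s))
    partner[pr[, 1L]] <- pr[, 2L]; partner[pr[, 2L]] <- pr[, 1L]
    children_of <- function(i, j) {
        kids <- matrix(0L, 0L, 2L)
        k <- i + 1L
        while (k < j) {
            if (partner[k] > k) { kids <- rbind(kids, c(k, partner[k])); k <- partner[k] + 1L }
            else k <- k + 1L
        }
        kids
    }
    e <- 0
    for (r in seq_len(nrow(pr))) {
        i <- pr[r, 1L]; j <- pr[r, 2L]
        kids <- children_of(i, j)
        nk <- nrow(kids)
        unp <- (j - i - 1L) - if (nk) sum(kids[, 2L] - kids[, 1L] + 1L) else 0L
        if (nk == 0L) {
            e <- e + params$hairpinA +
                params$hairpinB * min(unp, params$hairpinCap)
        } else if (nk == 1L) {
            k <- kids[1L, 1L]; l <- kids[1L, 2L]
            s1 <- k - i - 1L; s2 <- j - l - 1L
            if (s1 == 0L && s2 == 0L)
                e <- e + params$stack[pc(i, j), pc(k, l)]
            else if (s1 == 0L || s2 == 0L)
                e <- e + params$bulgeA + params$bulgeB * (s1 + s2)
            else
                e <- e + params$internalA + params$internalB * (s1 + s2)
        } else {
            e <- e + params$multiA + params$multiB * (nk + 1L) +
                params$multiC * unp
        }
    }
    e
}

#' Classify structural stability from a minimum free energy
#'
#' Two thresholds coexist in the workflow and are kept as distinct contexts:
#' a miRNA-precursor check treats structures with MFE between -80 and -30
#' kcal/mol as stable, while the lncRNA structure comparison treats
#' MFE >= -80 kcal/mol as unstable (stable only below -80).
#'
#' @param mfe minimum free energy, kcal/mol.
#' @param context `"mirna_precursor"` or `"lncrna_structure"`.
#' @return `"stable"` or `"unstable"`.
#' @export
classifyStability <- function(mfe,
                              context = c("lncrna_structure", "mirna_precursor")) {
    context <- match.arg(context)
    stopifnot(is.finite(mfe))
    if (context == "mirna_precursor") {
        if (mfe >= -80 && mfe <= -30) "stable" else "unstable"
    } else {
        if (mfe < -80) "stable" else "unstable"
    }
}

#' Fold with an external ViennaRNA RNAfold binary
#'
#' Optional adapter producing MFE values on the RNAfold scale (full Turner
#' model); the built-in reduced model remains the default engine. Requires
#' the `RNAfold` executable on the PATH.
#'
#' @param seq RNA (or DNA) sequence.
#' @param id sequence identifier.
#' @param context stability context.
#' @param binary name or path of the RNAfold executable.
#' @return a [FoldResult-class].
#' @export
foldWithRNAfold <- function(seq, id = "seq", context = "lncrna_structure",
                            binary = "RNAfold") {
    if (!nzchar(Sys.which(binary)))
        stop("RNAfold binary not found on PATH")
    s <- .as_rna(seq)
    out <- system2(binary, args = "--noPS", input = s, stdout = TRUE)
    line <- out[length(out)]
    m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
    if (length(m) != 3L) stop("could not parse RNAfold output: ", line)
    structure <- m[2L]; energy <- as.numeric(m[3L])
    new("FoldResult", sequenceId = id, sequence = s, structure = structure,
        mfe = energy, pairCount = sum(strsplit(structure, "")[[1]] == "("),
        stabilityClass = classifyStability(energy, context), context = context)
}

#' Write fold results in Vienna format and as TSV
#'
#' Vienna format: `>id`, sequence line, dot-bracket line with ` (mfe)`.
#'
#' @param results list of [FoldResult-class] objects.
#' @param viennaPath,tsvPath output paths (either may be `NULL`).
#' @export
writeFolds <- function(results, viennaPath = NULL, tsvPath = NULL) {
    if (!is.null(viennaPath)) {
        lines <- unlist(lapply(results, function(r)
            c(paste0(">", r@sequenceId), r@sequence,
              sprintf("%s (%.2f)", r@structure, r@mfe))))
        writeLines(lines, viennaPath)
    }
    if (!is.null(tsvPath)) {
        df <- do.call(rbind, lapply(results, function(r)
            data.frame(id = r@sequenceId, length_nt = nchar(r@sequence),
                       mfe = r@mfe, pair_count = r@pairCount,
                       stability_class = r@stabilityClass,
                       context = r@context, stringsAsFactors = FALSE)))
        utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(NULL)
}
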