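#' Construct a TraitMatrix
#'
#' @param counts genomes-by-genes matrix of non-negative integer copy
#'   counts, `NA` for missing (unknowable) cells; rownames are genome ids,
#'   colnames gene ids. This is the on-disk orientation; internally genes
#'   become rows, following the SummarizedExperiment convention.
#' @return a [TraitMatrix-class].
#' @examples
#' m <- matrix(c(1, 0, NA, 2), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("fliC", "fliD")))
#' TraitMatrix(m)
#' @export
TraitMatrix <- function(counts) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    obj <- new("TraitMatrix",
               SummarizedExperiment(assays = list(counts = t(counts))))
    validObject(obj)
    obj
}

#' @describeIn TraitMatrix genome (sample) identifiers.
#' @param x a TraitMatrix.
#' @export
genomeIds <- function(x) colnames(x)

#' @describeIn TraitMatrix gene (feature) identifiers.
#' @export
geneIds <- function(x) rownames(x)

#' Occurrence counts and binarized presence
#'
#' `occurrenceCounts()` returns the genes-by-genomes count matrix (`NA` =
#' missing); `presenceMatrix()` its binarized view (`TRUE` iff count >= 1).
#'
#' @param x a [TraitMatrix-class].
#' @export
occurrenceCounts <- function(x) assay(x, "counts")

#' @rdname occurrenceCounts
#' @export
presenceMatrix <- function(x) occurrenceCounts(x) >= 1

setMethod("show", "TraitMatrix", function(object) {
    m <- occurrenceCounts(object)
    cat("TraitMatrix:", ncol(m), "genomes x", nrow(m), "genes;",
        sum(is.na(m)), "missing cells\n")
})

#' Read a gene occurrence matrix from TSV
#'
#' Expects a header row of gene ids, a first column of genome ids, and cells
#' holding non-negative integer counts or `"?"` for missing. Validation
#' errors name the offending row/column.
#'
#' @param path TSV file path.
#' @return a [TraitMatrix-class].
#' @export
readTraitMatrix <- function(path) {
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character",
                             check.names = FALSE, row.names = NULL)
    if (ncol(raw) < 2L) stop("matrix must have a genome column and >= 1 gene")
    genomes <- raw[[1L]]
    genes <- colnames(raw)[-1L]
    if (anyDuplicated(genomes))
        stop("duplicate genome id(s): ",
             paste(unique(genomes[duplicated(genomes)]), collapse = ", "))
    if (anyDuplicated(genes))
        stop("duplicate gene id(s): ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    cells <- as.matrix(raw[, -1L, drop = FALSE])
    vals <- matrix(NA_real_, nrow(cells), ncol(cells),
                   dimnames = list(genomes, genes))
    is_missing <- cells == "?"
    ok <- is_missing | grepl("^[0-9]+$", cells)
    if (!all(ok)) {
        bad <- which(!ok, arr.ind = TRUE)[1L, ]
        stop("invalid cell '", cells[bad[1L], bad[2L]], "' at genome '",
             genomes[bad[1L]], "', gene '", genes[bad[2L]],
             "': expected a non-negative integer or '?'")
    }
    vals[!is_missing] <- as.numeric(cells[!is_missing])
    TraitMatrix(vals)
}

#' Write a TraitMatrix as TSV
#'
#' Inverse of [readTraitMatrix()]: genomes as rows, `"?"` for missing.
#'
#' @param x a [TraitMatrix-class].
#' @param path output file path.
#' @export
writeTraitMatrix <- function(x, path) {
    m <- t(occurrenceCounts(x))
    out <- matrix(as.character(m), nrow(m), ncol(m), dimnames = dimnames(m))
    out[is.na(m)] <- "?"
    df <- data.frame(genome = rownames(out), out, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Fraction of a gene set present in a genome
#'
#' (number of set genes with count >= 1) / (number of set genes with a
#' non-missing value). Missing cells are excluded from both numerator and
#' denominator so that genome incompleteness does not masquerade as absence;
#' if every set gene is missing the fraction is undefined (`NA`), never 0.
#'
#' @param x a [TraitMatrix-class].
#' @param genes character vector of member gene ids (must be in `x`).
#' @param genomes genome ids to evaluate (default: all).
#' @return named numeric vector of fractions in `[0, 1]`, `NA` = undefined.
#' @examples
#' m <- matrix(c(1, 1, 1, 0, 0, NA), 1, 6)
#' rownames(m) <- "g1"; colnames(m) <- paste0("gene", 1:6)
#' presenceFraction(TraitMatrix(m), paste0("gene", 1:6))
#' @export
presenceFraction <- function(x, genes, genomes = genomeIds(x)) {
    .check_known(genes, geneIds(x), "gene")
    .check_known(genomes, genomeIds(x), "genome")
    pres <- presenceMatrix(x)[genes, genomes, drop = FALSE]
    num <- colSums(pres, na.rm = TRUE)
    den <- colSums(!is.na(pres))
    out <- ifelse(den > 0, num / den, NA_real_)
    names(out) <- genomes
    out
}

.check_known <- function(q, universe, what) {
    miss <- setdiff(q, universe)
    if (length(miss))
        stop("unknown ", what, " id(s): ", paste(miss, collapse = ", "))
    invisible(TRUE)
}

#' Classify a presence fraction into a set state
#'
#' `present` when `fraction >= presentMin`, `absent` when
#' `<= absentMax`, `partial` in between, `unknown` when the fraction is
#' undefined (`NA`). Vectorized.
#'
#' @param fraction numeric vector in `[0, 1]` (NA allowed).
#' @param presentMin,absentMax thresholds, `0 <= absentMax < presentMin <= 1`.
#' @return character vector of states.
#' @export
classifySetState <- function(fraction, presentMin = 0.9, absentMax = 0.1) {
    if (!(absentMax >= 0 && absentMax < presentMin && presentMin <= 1))
        stop("thresholds must satisfy 0 <= absentMax < presentMin <= 1")
    out <- rep("partial", length(fraction))
    out[fraction >= presentMin] <- "present"
    out[fraction <= absentMax] <- "absent"
    out[is.na(fraction)] <- "unknown"
    names(out) <- names(fraction)
    out
}

#' Gene co-occurrence (Jaccard index)
#'
#' |genomes with both present| / |genomes with either present|, over the
#' genomes non-missing for both genes; 0 when the union is empty.
#' A diagnostic for "often co-occurring" core-set candidates, not an
#' automatic grouper.
#'
#' @param x a [TraitMatrix-class].
#' @param geneA,geneB gene ids.
#' @return numeric(1) in `[0, 1]`.
#' @export
cooccurrence <- function(x, geneA, geneB) {
    .check_known(c(geneA, geneB), geneIds(x), "gene")
    p <- presenceMatrix(x)
    a <- p[geneA, ]; b <- p[geneB, ]
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    uni <- sum(a | b)
    if (uni == 0) return(0)
    sum(a & b) / uni
}
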