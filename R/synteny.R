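#' @importFrom GenomicRanges GRanges start end strand
#' @importFrom IRanges IRanges
NULL

#' Read gene coordinates from GFF3 or TSV
#'
#' Builds a gene coordinate table as a `GRanges` (1-based inclusive, the
#' GFF3 convention; the TSV dialect uses the same convention) with metadata
#' columns `genome` and `gene_id`. GFF3 input is parsed with
#' [rtracklayer::import()] and restricted to `gene` features when a `type`
#' column is present; the gene id comes from the attribute named by
#' `attribute`. TSV input needs a header with columns `genome`, `contig`,
#' `gene`, `start`, `end`, `strand`.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @param genome genome id to assign to GFF3 records (defaults to the file
#'   name without extension; TSV carries its own genome column).
#' @param attribute GFF3 attribute holding the gene id (default `"ID"`).
#' @return `GRanges` with mcols `genome`, `gene_id`.
#' @export
readCoordinates <- function(path, format = c("auto", "gff3", "tsv"),
                            genome = NULL, attribute = "ID") {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
                  else "tsv"
    if (format == "gff3") {
        gr <- rtracklayer::import(path, format = "gff3")
        if ("type" %in% colnames(S4Vectors::mcols(gr)) &&
            any(gr$type == "gene"))
            gr <- gr[gr$type == "gene"]
        att <- S4Vectors::mcols(gr)[[attribute]]
        if (is.null(att))
            stop("GFF3 attribute '", attribute, "' not found")
        att <- as.character(att)
        if (any(is.na(att) | !nzchar(att)))
            stop("GFF3 record(s) ", paste(which(is.na(att) | !nzchar(att)),
                                          collapse = ", "),
                 " lack attribute '", attribute, "'")
        if (is.null(genome))
            genome <- sub("\\.[^.]*$", "", basename(path))
        out <- GRanges(GenomicRanges::seqnames(gr),
                       IRanges(start(gr), end(gr)),
                       strand = strand(gr))
        out$genome <- genome
        out$gene_id <- att
    } else {
        df <- utils::read.delim(path, header = TRUE, sep = "\t",
                                colClasses = "character")
        need <- c("genome", "contig", "gene", "start", "end", "strand")
        if (!all(need %in% colnames(df)))
            stop("coordinate TSV must have columns ",
                 paste(need, collapse = ", "))
        st <- suppressWarnings(as.numeric(df$start))
        en <- suppressWarnings(as.numeric(df$end))
        bad <- which(is.na(st) | is.na(en) | st < 1 | en < st)
        if (length(bad))
            stop("invalid coordinates (end < start or non-numeric) on ",
                 "line(s): ", paste(bad + 1L, collapse = ", "))
        badstr <- which(!df$strand %in% c("+", "-"))
        if (length(badstr))
            stop("unknown strand on line(s): ",
                 paste(badstr + 1L, collapse = ", "))
        out <- GRanges(df$contig, IRanges(st, en), strand = df$strand)
        out$genome <- df$genome
        out$gene_id <- df$gene
    }
    key <- paste(out$genome, GenomicRanges::seqnames(out), start(out),
                 end(out), out$gene_id)
    if (anyDuplicated(key))
        stop("duplicate coordinate record(s): ",
             paste(unique(key[duplicated(key)]), collapse = "; "))
    out
}

#' Write a gene coordinate table as TSV
#'
#' Inverse of the TSV dialect of [readCoordinates()].
#'
#' @param gr coordinate `GRanges` (mcols `genome`, `gene_id`).
#' @param path output file.
#' @export
writeCoordinates <- function(gr, path) {
    df <- data.frame(genome = gr$genome,
                     contig = as.character(GenomicRanges::seqnames(gr)),
                     gene = gr$gene_id,
                     start = start(gr), end = end(gr),
                     strand = as.character(strand(gr)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Detect synteny clusters of a gene set
#'
#' Per genome and contig, the genes of interest are sorted by start and
#' split into clusters wherever the intergenic gap
#' (`next start - previous end - 1`) exceeds `maxGap`. Overlapping genes
#' (negative gap) always co-cluster; singleton clusters are kept and
#' flagged. Foreign (non-set) genes lying inside a cluster's span do not
#' split it — they are counted as insertions when the table contains them.
#'
#' @param gr coordinate `GRanges` from [readCoordinates()] (may include
#'   non-set genes, used for the insertion count).
#' @param genes the gene ids of interest (non-empty).
#' @param maxGap maximum intergenic distance in bp within a cluster
#'   (default 10000).
#' @return `DataFrame` with one row per cluster: `genome`, `contig`,
#'   `cluster_index`, `genes` (comma-joined in start order), `strands`,
#'   `n_genes`, `span_start`, `span_end`, `n_insertions`, `singleton`.
#' @export
findClusters <- function(gr, genes, maxGap = 10000) {
    if (length(genes) == 0L) stop("empty gene set")
    if (maxGap < 0) stop("maxGap must be >= 0")
    sel <- gr[gr$gene_id %in% genes]
    rows <- list()
    for (g in unique(sel$genome)) {
        idx_counter <- 0L
        sub_g <- sel[sel$genome == g]
        all_g <- gr[gr$genome == g & !(gr$gene_id %in% genes)]
        for (ctg in unique(as.character(GenomicRanges::seqnames(sub_g)))) {
            sub <- sub_g[as.character(GenomicRanges::seqnames(sub_g)) == ctg]
            o <- order(start(sub), end(sub))
            sub <- sub[o]
            gaps <- if (length(sub) > 1L)
                start(sub)[-1L] - end(sub)[-length(sub)] - 1L else integer()
            brk <- c(0L, which(gaps > maxGap), length(sub))
            for (k in seq_len(length(brk) - 1L)) {
                idx_counter <- idx_counter + 1L
                mem <- sub[(brk[k] + 1L):brk[k + 1L]]
                sp0 <- min(start(mem)); sp1 <- max(end(mem))
                fore <- all_g[as.character(
                    GenomicRanges::seqnames(all_g)) == ctg &
                    start(all_g) >= sp0 & end(all_g) <= sp1]
                rows[[length(rows) + 1L]] <- DataFrame(
                    genome = g, contig = ctg, cluster_index = idx_counter,
                    genes = paste(mem$gene_id, collapse = ","),
                    strands = paste(as.character(strand(mem)),
                                    collapse = ","),
                    n_genes = length(mem), span_start = sp0, span_end = sp1,
                    n_insertions = length(fore),
                    singleton = length(mem) == 1L)
            }
        }
    }
    if (!length(rows))
        return(DataFrame(genome = character(), contig = character(),
                         cluster_index = integer(), genes = character(),
                         strands = character(), n_genes = integer(),
                         span_start = integer(), span_end = integer(),
                         n_insertions = integer(), singleton = logical()))
    do.call(rbind, rows)
}

## canonical orientation of a cluster: reverse when the members are mostly
## on the minus strand (a reverse-complemented cluster), with a
## lexicographic end-point tie-break so orientation is always deterministic
.canon_orient <- function(genes, strands = NULL) {
    rev_it <- FALSE
    if (!is.null(strands) && length(strands) == length(genes)) {
        nminus <- sum(strands == "-"); nplus <- sum(strands == "+")
        if (nminus > nplus) rev_it <- TRUE
        else if (nminus == nplus && length(genes) > 1L)
            rev_it <- genes[1L] > genes[length(genes)]
    } else if (length(genes) > 1L) {
        rev_it <- genes[1L] > genes[length(genes)]
    }
    if (rev_it) rev(genes) else genes
}

#' Shared-adjacency fraction between two cluster architectures
#'
#' Both clusters are first put into a canonical orientation (a cluster
#' lying on the minus strand is reversed, so reverse-complement order is
#' equivalent; without strand information a deterministic lexicographic
#' rule orients the cluster). The score is then the fraction of ordered
#' adjacent gene pairs of `a` also adjacent (same order) in `b`. Identical
#' single-gene clusters of the same gene score 1; otherwise a cluster with
#' no pairs scores 0.
#'
#' @param a,b clusters: either single rows of the [findClusters()] table or
#'   character vectors of gene ids in positional order.
#' @param strandA,strandB optional strand vectors when `a`/`b` are plain
#'   gene vectors.
#' @return numeric(1) in `[0, 1]`.
#' @export
compareArchitecture <- function(a, b, strandA = NULL, strandB = NULL) {
    unpack <- function(x, str) {
        if (is(x, "DataFrame") || is.data.frame(x)) {
            list(genes = strsplit(x$genes[1L], ",", fixed = TRUE)[[1L]],
                 strands = strsplit(x$strands[1L], ",", fixed = TRUE)[[1L]])
        } else list(genes = as.character(x), strands = str)
    }
    A <- unpack(a, strandA); B <- unpack(b, strandB)
    if (!length(A$genes) || !length(B$genes)) stop("empty cluster")
    ga <- .canon_orient(A$genes, A$strands)
    gb <- .canon_orient(B$genes, B$strands)
    if (length(ga) == 1L)
        return(if (length(gb) == 1L && ga == gb) 1 else 0)
    pa <- paste(ga[-length(ga)], ga[-1L], sep = ">")
    pb <- paste(gb[-length(gb)], gb[-1L], sep = ">")
    mean(pa %in% pb)
}

#' Write a cluster table as TSV
#' @param clusters output of [findClusters()].
#' @param path output file.
#' @export
writeClusters <- function(clusters, path) {
    utils::write.table(as.data.frame(clusters), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
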