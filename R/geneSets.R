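#' Construct a GeneSetCatalog
#'
#' @param gene_id,set_name,role parallel character vectors defining set
#'   membership; `role` is one of `"core"`, `"regulatory"`,
#'   `"intermittent"` (recycled if length 1).
#' @param presentMin,absentMax classification thresholds (see
#'   [classifySetState()]).
#' @return a [GeneSetCatalog-class].
#' @examples
#' GeneSetCatalog(c("fliC", "fliD", "fliS"), "flagellum", "core")
#' @export
GeneSetCatalog <- function(gene_id, set_name, role = "core",
                           presentMin = 0.9, absentMax = 0.1) {
    n <- length(gene_id)
    obj <- new("GeneSetCatalog",
               members = DataFrame(gene_id = as.character(gene_id),
                                   set_name = rep_len(as.character(set_name), n),
                                   role = rep_len(as.character(role), n)),
               presentMin = presentMin, absentMax = absentMax)
    validObject(obj)
    obj
}

#' @describeIn GeneSetCatalog names of the sets in the catalog.
#' @param x a GeneSetCatalog.
#' @export
setIds <- function(x) unique(x@members$set_name)

#' @describeIn GeneSetCatalog member gene ids of one set (optionally one
#'   role).
#' @param set set name.
#' @param role optional role filter.
#' @export
setMembers <- function(x, set, role = NULL) {
    m <- x@members
    if (!set %in% m$set_name) stop("unknown set: ", set)
    keep <- m$set_name == set
    if (!is.null(role)) keep <- keep & m$role == role
    m$gene_id[keep]
}

#' @describeIn GeneSetCatalog the membership table as a DataFrame.
#' @export
setMembership <- function(x) x@members

#' @describeIn GeneSetCatalog the `presentMin` threshold.
#' @export
presentMin <- function(x) x@presentMin

#' @describeIn GeneSetCatalog the `absentMax` threshold.
#' @export
absentMax <- function(x) x@absentMax

setMethod("show", "GeneSetCatalog", function(object) {
    m <- object@members
    cat("GeneSetCatalog:", length(unique(m$set_name)), "set(s),",
        nrow(m), "gene assignments\n")
    for (s in unique(m$set_name))
        cat("  ", s, ": ", sum(m$set_name == s), " genes\n", sep = "")
    cat("  thresholds: present >= ", object@presentMin,
        ", absent <= ", object@absentMax, "\n", sep = "")
})

#' Read a gene-set table from TSV
#'
#' Columns `gene_id`, `set_name`, `role` (header required).
#'
#' @param path TSV file.
#' @param presentMin,absentMax thresholds attached to the catalog.
#' @return a [GeneSetCatalog-class].
#' @export
readGeneSetCatalog <- function(path, presentMin = 0.9, absentMax = 0.1) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    need <- c("gene_id", "set_name", "role")
    if (!all(need %in% colnames(df)))
        stop("gene-set table must have columns ", paste(need, collapse = ", "))
    GeneSetCatalog(df$gene_id, df$set_name, df$role,
                   presentMin = presentMin, absentMax = absentMax)
}

#' Write a gene-set catalog as TSV
#' @param x a [GeneSetCatalog-class].
#' @param path output file.
#' @export
writeGeneSetCatalog <- function(x, path) {
    utils::write.table(as.data.frame(x@members), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
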