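#' Parse a rooted newick tree
#'
#' Reads a single newick statement into an [ape::phylo] object with the
#' conventions used throughout gleam: internal node labels are *names*
#' (taxon or clade identifiers), not support values, unless
#' `supportValues = TRUE` and the label is purely numeric, in which case it
#' is stored in the node annotation slot `"support"` instead. Trees without
#' branch lengths are first-class and flagged as cladograms
#' (see [isCladogram()]); mixed presence/absence of lengths is an error.
#' Rooting is required and never inferred: a basal polytomy (the unrooted
#' newick convention) is rejected.
#'
#' Square-bracket comments (including NHX blocks) are stripped before
#' parsing.
#'
#' @param text newick string ending in `";"`, or `NULL` if `file` is given.
#' @param file path to a newick file holding one tree.
#' @param supportValues interpret numeric-only internal labels as support
#'   values rather than names.
#' @return a rooted `phylo`; cladogram status is queried with
#'   [isCladogram()], annotations with [nodeAnnotations()].
#' @examples
#' tr <- parseNewick("((A,B),(C,D));")
#' isCladogram(tr)
#' @export
parseNewick <- function(text = NULL, file = NULL, supportValues = FALSE) {
    if (is.null(text)) {
        if (is.null(file)) stop("supply 'text' or 'file'")
        text <- paste(readLines(file, warn = FALSE), collapse = "")
    }
    stopifnot(is.character(text), length(text) == 1L)
    text <- trimws(text)
    if (!nzchar(text)) stop("newick parse error: empty input")
    ## strip [...] comments (NHX and otherwise); no nesting in newick
    text <- gsub("\\[[^]]*\\]", "", text)
    if (!grepl(";\\s*$", text))
        stop("newick parse error: statement must end in ';' (position ",
             nchar(text), ")")
    if (grepl(";", sub(";\\s*$", "", text)))
        stop("newick parse error: more than one statement")
    .check_parens(text)
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr) || !inherits(tr, "phylo"))
        stop("newick parse error: malformed tree")
    if (ape::Ntip(tr) < 2L)
        stop("newick parse error: need at least two tips")
    if (anyDuplicated(tr$tip.label)) {
        dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
        stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
    }
    if (any(!nzchar(tr$tip.label)))
        stop("newick parse error: empty tip label")
    root <- ape::Ntip(tr) + 1L
    if (sum(tr$edge[, 1L] == root) > 2L)
        stop("tree appears unrooted (basal polytomy); ",
             "gleam requires explicitly rooted input")
    if (!is.null(tr$edge.length)) {
        if (anyNA(tr$edge.length))
            stop("branch lengths must be uniformly present or absent")
        if (any(tr$edge.length < 0))
            stop("negative branch length")
    }
    ann <- list()
    if (supportValues && !is.null(tr$node.label)) {
        num <- grepl("^[0-9.eE+-]+$", tr$node.label) &
            !is.na(suppressWarnings(as.numeric(tr$node.label)))
        if (any(num)) {
            ids <- nodeIds(tr)
            for (k in which(num)) {
                nid <- paste0("N", ape::Ntip(tr) + k)
                ann[[nid]] <- c(support = tr$node.label[k])
            }
            tr$node.label[num] <- ""
        }
    }
    attr(tr, "annotations") <- ann
    tr
}

.check_parens <- function(text) {
    chars <- strsplit(text, "", fixed = TRUE)[[1L]]
    depth <- 0L
    for (i in seq_along(chars)) {
        if (chars[i] == "(") depth <- depth + 1L
        else if (chars[i] == ")") {
            depth <- depth - 1L
            if (depth < 0L)
                stop("newick parse error: unbalanced ')' at position ", i)
        }
    }
    if (depth != 0L)
        stop("newick parse error: ", depth, " unclosed '(' at end of input")
    invisible(TRUE)
}

#' Stable node identifiers
#'
#' Every node gets a character id: tips use their label; internal nodes use
#' their label when present, otherwise `"N<index>"` in ape's node numbering.
#' These ids are what all gleam tables report.
#'
#' @param tree a `phylo`.
#' @return character vector indexed by ape node number.
#' @export
nodeIds <- function(tree) {
    n <- ape::Ntip(tree); m <- tree$Nnode
    ids <- character(n + m)
    ids[seq_len(n)] <- tree$tip.label
    internal <- paste0("N", seq(n + 1L, n + m))
    if (!is.null(tree$node.label)) {
        has <- !is.na(tree$node.label) & nzchar(tree$node.label)
        internal[has] <- tree$node.label[has]
    }
    ids[n + seq_len(m)] <- internal
    ids
}

#' Is the tree a cladogram?
#'
#' TRUE when the tree carries no branch lengths. Mk-model operations reject
#' cladograms unless a unit-length substitution is explicitly requested;
#' Fitch parsimony does not use lengths at all.
#'
#' @param tree a `phylo`.
#' @export
isCladogram <- function(tree) is.null(tree$edge.length)

#' Node annotations
#'
#' gleam trees carry a free-form string-to-string annotation slot per node,
#' written out as NHX comments by [writeNewick()].
#'
#' @param tree a `phylo`.
#' @return named list: node id -> named character vector.
#' @export
nodeAnnotations <- function(tree) {
    ann <- attr(tree, "annotations")
    if (is.null(ann)) list() else ann
}

#' Annotate a node
#'
#' @param tree a `phylo`.
#' @param node node id (see [nodeIds()]) or ape node number.
#' @param key,value annotation key and value (strings).
#' @return the tree with the annotation attached.
#' @export
annotateNode <- function(tree, node, key, value) {
    ids <- nodeIds(tree)
    if (is.numeric(node)) node <- ids[node]
    if (!node %in% ids) stop("unknown node id: ", node)
    ann <- nodeAnnotations(tree)
    cur <- ann[[node]]
    cur[key] <- as.character(value)
    ann[[node]] <- cur
    attr(tree, "annotations") <- ann
    tree
}

#' Write a tree as newick or NHX
#'
#' Round-trip safe with [parseNewick()] on topology, labels and branch
#' lengths. With `annotations = TRUE`, node annotation slots are emitted as
#' `[&&NHX:key=value:...]` comments; with no annotations present the output
#' is plain newick.
#'
#' @param tree a `phylo`.
#' @param file optional path; when given the string is also written there.
#' @param annotations emit node annotations as NHX comments.
#' @return the newick string, invisibly when `file` is given.
#' @export
writeNewick <- function(tree, file = NULL, annotations = FALSE) {
    n <- ape::Ntip(tree)
    ids <- nodeIds(tree)
    ann <- if (annotations) nodeAnnotations(tree) else list()
    kids <- .children_list(tree)
    lens <- tree$edge.length
    edge_len <- rep(NA_real_, n + tree$Nnode)
    if (!is.null(lens)) edge_len[tree$edge[, 2L]] <- lens
    fmt_len <- function(i) {
        if (is.null(lens) || is.na(edge_len[i])) return("")
        paste0(":", sprintf("%.10g", edge_len[i]))
    }
    fmt_nhx <- function(i) {
        a <- ann[[ids[i]]]
        if (is.null(a) || !length(a)) return("")
        paste0("[&&NHX:", paste0(names(a), "=", a, collapse = ":"), "]")
    }
    build <- function(i) {
        ch <- kids[[i]]
        if (length(ch)) {
            lab <- if (!is.null(tree$node.label)) {
                l <- tree$node.label[i - n]
                if (is.na(l)) "" else l
            } else ""
            paste0("(", paste(vapply(ch, build, character(1L)),
                              collapse = ","),
                   ")", lab, fmt_len(i), fmt_nhx(i))
        } else {
            paste0(tree$tip.label[i], fmt_len(i), fmt_nhx(i))
        }
    }
    root <- n + 1L
    s <- build(root)
    if (!is.null(tree$root.edge))
        s <- paste0(s, ":", sprintf("%.10g", tree$root.edge))
    s <- paste0(s, ";")
    if (!is.null(file)) {
        writeLines(s, file)
        return(invisible(s))
    }
    s
}

.children_list <- function(tree) {
    N <- ape::Ntip(tree) + tree$Nnode
    kids <- vector("list", N)
    ## keep newick child order (edge rows are in cladewise order)
    for (r in seq_len(nrow(tree$edge)))
        kids[[tree$edge[r, 1L]]] <- c(kids[[tree$edge[r, 1L]]],
                                      tree$edge[r, 2L])
    kids
}

#' Node visiting orders
#'
#' Postorder visits every child before its parent; preorder visits every
#' parent before its children. Each node appears exactly once.
#'
#' @param tree a `phylo`.
#' @param order `"postorder"` or `"preorder"`.
#' @return integer vector of ape node numbers.
#' @export
nodeOrder <- function(tree, order = c("postorder", "preorder")) {
    order <- match.arg(order)
    root <- ape::Ntip(tree) + 1L
    if (order == "postorder") {
        e <- ape::reorder.phylo(tree, "postorder")$edge
        c(e[, 2L], root)
    } else {
        e <- ape::reorder.phylo(tree, "cladewise")$edge
        c(root, e[, 2L])
    }
}

## edge table in postorder with resolved lengths (unit substitution for
## cladograms when allowed)
.edge_table <- function(tree, unitLengths = FALSE, need_lengths = TRUE) {
    tr <- ape::reorder.phylo(tree, "postorder")
    lens <- tr$edge.length
    if (is.null(lens)) {
        if (need_lengths && !unitLengths)
            stop("tree is a cladogram (no branch lengths); pass ",
                 "unitLengths = TRUE to substitute unit lengths")
        lens <- rep(1, nrow(tr$edge))
    }
    list(edge = tr$edge, length = lens)
}
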