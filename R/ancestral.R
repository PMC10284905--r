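#' Ancestral state reconstruction for a panel of genes
#'
#' The single entry point for per-gene ancestral character state
#' reconstruction on a rooted genome phylogeny. The default method is Fitch
#' parsimony, which is what a cladogram supports; the Mk maximum-likelihood
#' alternative requires branch lengths (or an explicit unit-length
#' substitution) and reports marginal posteriors from rates fitted by
#' [fitMk()] pooled across the requested genes.
#'
#' @param tree rooted `phylo`.
#' @param x a [TraitMatrix-class] (binarized) or tips-by-genes 0/1/NA
#'   matrix. Every tree tip must be present; genomes not on the tree are
#'   ignored here (the pipeline warns about them).
#' @param genes genes to reconstruct (default: all in `x`).
#' @param method `"fitch"` (default) or `"mk"`.
#' @param rootPrior,unitLengths,bounds,tol Mk options, see [fitMk()].
#' @param fit optionally a pre-computed [MkFit-class] to reuse.
#' @return a [NodeStates-class].
#' @examples
#' tr <- parseNewick("((A,B),(C,D));")
#' m <- matrix(c(1, 1, 0, 0), 4, 1, dimnames = list(c("A", "B", "C", "D"), "fliC"))
#' ns <- ancestralStates(tr, m)
#' parsimonyScores(ns)
#' @export
ancestralStates <- function(tree, x, genes = NULL,
                            method = c("fitch", "mk"),
                            rootPrior = "stationary", unitLengths = FALSE,
                            bounds = c(1e-6, 1e3), tol = 1e-8, fit = NULL) {
    method <- match.arg(method)
    X <- .tip_matrix(tree, x)
    if (!is.null(genes)) {
        .check_known(genes, colnames(X), "gene")
        X <- X[, genes, drop = FALSE]
    }
    if (method == "mk") {
        if (is.null(fit))
            fit <- fitMk(tree, X, rootPrior = rootPrior,
                         unitLengths = unitLengths, bounds = bounds,
                         tol = tol)
        ns <- marginalAncestral(tree, X, fit = fit,
                                unitLengths = unitLengths)
        return(ns)
    }
    n <- ape::Ntip(tree)
    N <- n + tree$Nnode
    ids <- nodeIds(tree)
    set_str <- c("0", "1", "0/1")
    tabs <- vector("list", ncol(X))
    scores <- numeric(ncol(X))
    for (g in seq_len(ncol(X))) {
        r <- .fitch_one(tree, stats::setNames(X[, g], rownames(X)))
        scores[g] <- r$score
        tabs[[g]] <- DataFrame(
            gene_id = colnames(X)[g],
            node = seq_len(N),
            node_id = ids,
            state_set = set_str[r$sets],
            p0 = NA_real_, p1 = NA_real_,
            resolved = r$resolved)
    }
    names(scores) <- colnames(X)
    new("NodeStates", tree = tree, method = "fitch",
        states = do.call(rbind, tabs), tipStates = X, scores = scores,
        fit = NULL)
}

#' @describeIn ancestralStates per-gene minimum change counts (Fitch).
#' @param ns a NodeStates.
#' @export
parsimonyScores <- function(ns) ns@scores

#' @describeIn ancestralStates the per-gene, per-node state table.
#' @export
nodeStates <- function(ns) ns@states

#' @describeIn ancestralStates the reconstruction method tag.
#' @export
asrMethod <- function(ns) ns@method

setMethod("show", "NodeStates", function(object) {
    cat("NodeStates (", object@method, "): ",
        ncol(object@tipStates), " gene(s) x ",
        ape::Ntip(object@tree) + object@tree$Nnode, " nodes\n", sep = "")
})

#' Write a per-gene node-state table as TSV
#'
#' Columns: `gene_id`, `node_id`, `method`, `state_set`, `p0`, `p1`,
#' `resolved_state`.
#'
#' @param ns a [NodeStates-class].
#' @param path output file.
#' @export
writeNodeStates <- function(ns, path) {
    df <- as.data.frame(ns@states)
    out <- data.frame(gene_id = df$gene_id, node_id = df$node_id,
                      method = ns@method, state_set = df$state_set,
                      p0 = df$p0, p1 = df$p1, resolved_state = df$resolved)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

## resolved-state matrix (nodes x genes) from a NodeStates
.resolved_matrix <- function(ns) {
    df <- ns@states
    genes <- unique(df$gene_id)
    N <- ape::Ntip(ns@tree) + ns@tree$Nnode
    m <- matrix(NA_character_, N, length(genes),
                dimnames = list(NULL, genes))
    m[cbind(df$node, match(df$gene_id, genes))] <- df$resolved
    m
}
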