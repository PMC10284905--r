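#' Simulate a Yule (pure-birth) tree
#'
#' Lineages split with exponential waiting times at rate
#' `birthRate * (number of extant lineages)`; the lineage that splits is
#' chosen uniformly. Branch lengths are rescaled so the mean root-to-tip
#' height is 1, making rates directly interpretable per tree height.
#' Fully deterministic given `seed` (R's Mersenne-Twister RNG).
#'
#' @param nTips number of tips (>= 2).
#' @param birthRate speciation rate (> 0); only the relative waiting times
#'   matter after rescaling.
#' @param seed integer RNG seed.
#' @return rooted binary `phylo` with tips `t1 ... tn`.
#' @export
simulateTree <- function(nTips, birthRate = 1, seed = 1) {
    if (nTips < 2L) stop("nTips must be >= 2")
    if (birthRate <= 0) stop("birthRate must be > 0")
    set.seed(seed)
    ## grow forward in time; active lineages indexed by their pending tip slot
    n <- as.integer(nTips)
    Nnode <- n - 1L
    edge <- matrix(0L, 2L * n - 2L, 2L)
    elen <- numeric(2L * n - 2L)
    nexte <- 0L
    ## node bookkeeping: ids in creation order, remapped to ape numbering
    ## (tips 1..n, internals n+1..2n-1) once the tree is complete
    birth_time <- numeric(2L * n - 1L)
    parent <- integer(2L * n - 1L)
    t_now <- 0
    next_internal <- n + 1L            # root
    next_child <- next_internal + 1L
    lineages <- next_internal          # start with the root lineage
    start_time <- numeric(2L * n - 1L)
    start_time[next_internal] <- 0
    repeat {
        k <- length(lineages)
        if (k == n) break
        t_now <- t_now + stats::rexp(1L, rate = birthRate * k)
        who <- lineages[sample.int(k, 1L)]
        ## 'who' splits at t_now into two new lineages
        for (j in 1:2) {
            child <- next_child; next_child <- next_child + 1L
            parent[child] <- who
            start_time[child] <- t_now
            lineages <- c(lineages, child)
        }
        lineages <- setdiff(lineages, who)
        birth_time[who] <- t_now
    }
    t_end <- t_now + stats::rexp(1L, rate = birthRate * n)
    birth_time[lineages] <- t_end
    ## surviving lineages become tips 1..n (in creation order for
    ## determinism); internal placeholder ids get compacted to n+1..2n-1
    surv <- sort(lineages)
    internal <- setdiff(seq.int(n + 1L, next_child - 1L), surv)
    remap <- integer(next_child - 1L)
    remap[surv] <- seq_len(n)
    remap[internal] <- n + seq_along(internal)
    for (v in seq.int(n + 2L, next_child - 1L)) {
        nexte <- nexte + 1L
        edge[nexte, ] <- c(remap[parent[v]], remap[v])
        elen[nexte] <- birth_time[v] - start_time[v]
    }
    tr <- list(edge = edge, edge.length = elen, Nnode = Nnode,
               tip.label = paste0("t", seq_len(n)))
    class(tr) <- "phylo"
    tr <- ape::reorder.phylo(tr, "cladewise")
    depths <- ape::node.depth.edgelength(tr)
    mh <- mean(depths[seq_len(n)])
    tr$edge.length <- tr$edge.length / mh
    tr
}

#' True set-level events implied by a node-state matrix
#'
#' Classifies every node by the fraction of `genes` in state 1 and emits an
#' event on every branch where the classification changes, using the same
#' state-transition mapping as [callEvents()].
#'
#' @param tree `phylo` the states live on.
#' @param states nodes-by-genes 0/1 matrix (ape node numbering).
#' @param genes columns to use (default all).
#' @param presentMin,absentMax classification thresholds.
#' @return `DataFrame`: `parent`, `child`, `parent_id`, `child_id`,
#'   `event_type`.
#' @export
trueSetEvents <- function(tree, states, genes = colnames(states),
                          presentMin = 0.9, absentMax = 0.1) {
    if (is.null(genes)) genes <- seq_len(ncol(states))
    frac <- rowMeans(states[, genes, drop = FALSE])
    cls <- classifySetState(frac, presentMin, absentMax)
    ids <- nodeIds(tree)
    edge <- tree$edge
    rows <- list()
    for (r in seq_len(nrow(edge))) {
        u <- edge[r, 1L]; v <- edge[r, 2L]
        if (cls[u] == cls[v]) next
        type <- .event_map(cls[u], cls[v])
        if (is.na(type)) next
        rows[[length(rows) + 1L]] <- DataFrame(
            parent = u, child = v, parent_id = ids[u], child_id = ids[v],
            event_type = type)
    }
    if (!length(rows))
        return(DataFrame(parent = integer(), child = integer(),
                         parent_id = character(), child_id = character(),
                         event_type = character()))
    do.call(rbind, rows)
}

#' Simulate binary gene histories on a tree
#'
#' Each gene evolves independently down the tree under the two-state Mk
#' model (gain rate `alpha`, loss rate `beta`, transition probabilities per
#' branch from [mkTransitionProb()]). A forced loss names the child end of
#' a branch: the state is set to 0 there and in all descendants (absorbing,
#' creating unambiguous truth). Missingness (`NA`, written `"?"`) is
#' introduced independently at tips only, after the truth is recorded —
#' genome incompleteness affects observation, not history.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param nGenes number of genes.
#' @param alpha,beta gain and loss rates per unit branch length (> 0).
#' @param rootState `"stationary"` (Bernoulli(alpha/(alpha+beta))),
#'   `"present"` (all genes start in 1) or `"absent"`.
#' @param forcedLosses character vector of node ids (see [nodeIds()]) or
#'   integer node numbers naming forced-loss branches (child end).
#' @param missingness tip missingness probability in `[0, 1)`.
#' @param seed integer RNG seed.
#' @param geneNames optional gene names (default `g001 ...`).
#' @return list with `matrix` (a [TraitMatrix-class] of the observed tips)
#'   and `truth` (a [SimTruth-class]).
#' @export
simulateGeneHistories <- function(tree, nGenes, alpha, beta,
                                  rootState = c("stationary", "present",
                                                "absent"),
                                  forcedLosses = character(),
                                  missingness = 0, seed = 1,
                                  geneNames = NULL) {
    rootState <- match.arg(rootState)
    if (alpha <= 0 || beta <= 0) stop("rates must be positive")
    if (missingness < 0 || missingness >= 1)
        stop("missingness must be in [0, 1)")
    if (isCladogram(tree))
        stop("tree must have branch lengths to simulate on")
    n <- ape::Ntip(tree)
    N <- n + tree$Nnode
    ids <- nodeIds(tree)
    forced <- forcedLosses
    if (is.character(forced)) {
        idx <- match(forced, ids)
        if (anyNA(idx))
            stop("forced-loss branch id(s) not in tree: ",
                 paste(forced[is.na(idx)], collapse = ", "))
        forced <- idx
    }
    if (any(forced == n + 1L)) stop("cannot force a loss at the root")
    set.seed(seed)
    if (is.null(geneNames))
        geneNames <- sprintf("g%03d", seq_len(nGenes))
    states <- matrix(0L, N, nGenes)
    root <- n + 1L
    states[root, ] <- switch(rootState,
        stationary = stats::rbinom(nGenes, 1L, alpha / (alpha + beta)),
        present = 1L, absent = 0L)
    pre <- ape::reorder.phylo(tree, "cladewise")
    elen <- pre$edge.length
    forced_zone <- logical(N)
    forced_zone[forced] <- TRUE
    r <- alpha + beta
    for (e in seq_len(nrow(pre$edge))) {
        u <- pre$edge[e, 1L]; v <- pre$edge[e, 2L]
        if (forced_zone[u]) forced_zone[v] <- TRUE
        if (forced_zone[v]) { states[v, ] <- 0L; next }
        f <- 1 - exp(-r * elen[e])
        p01 <- alpha / r * f; p10 <- beta / r * f
        pto1 <- ifelse(states[u, ] == 1L, 1 - p10, p01)
        states[v, ] <- stats::rbinom(nGenes, 1L, pto1)
    }
    colnames(states) <- geneNames
    tips <- states[seq_len(n), , drop = FALSE] * 1.0
    rownames(tips) <- tree$tip.label
    if (missingness > 0) {
        mask <- matrix(stats::runif(n * nGenes) < missingness, n, nGenes)
        tips[mask] <- NA_real_
    }
    truth <- new("SimTruth", tree = tree, states = states,
                 events = trueSetEvents(tree, states),
                 params = list(alpha = alpha, beta = beta,
                               rootState = rootState,
                               forcedLosses = ids[forced],
                               missingness = missingness, seed = seed,
                               nGenes = nGenes))
    list(matrix = TraitMatrix(tips), truth = truth)
}

#' @describeIn simulateGeneHistories true node-state matrix of a SimTruth.
#' @param truth a SimTruth.
#' @export
trueStates <- function(truth) truth@states

#' @describeIn simulateGeneHistories true set-level event table.
#' @export
trueEvents <- function(truth) truth@events

#' @describeIn simulateGeneHistories generator parameter list.
#' @export
simParams <- function(truth) truth@params

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", ncol(object@states), "genes on",
        ape::Ntip(object@tree), "tips;", nrow(object@events),
        "true set-level event(s)\n")
})

.FLAGELLAR_CORE <- c("fliC", "fliD", "fliS", "fliE", "fliF", "fliG",
                     "fliH", "fliI", "fliJ", "fliK", "fliL", "fliM",
                     "fliN", "fliP", "fliQ", "fliR", "flhA", "flhB",
                     "flhF", "flhG", "flgB", "flgC", "flgD", "flgE",
                     "motA")
.PG_CORE <- c("murA", "murB", "murC", "murD", "murE", "murF", "mraY",
              "murG", "murJ", "ddlA", "dapA", "dapB", "dapF", "alr")
.CLUSTER1 <- c("fliC", "fliD", "fliS")
.CLUSTER2 <- c("fliE", "fliF", "fliG", "fliH", "fliI", "fliJ", "fliK",
               "fliL", "fliM", "fliN")
.CLUSTER3 <- c("fliP", "fliQ", "fliR", "flhA", "flhB", "flhF", "flhG",
               "flgB", "flgC", "flgD", "flgE", "motA")

#' Build the headline-topology fixture
#'
#' A deterministic desk-scale data set with the qualitative structure the
#' pipeline is designed to detect: a 25-leaf order-level cladogram
#' (`order01 ... order25`, a basal grade of orders 1-9 and a derived
#' 16-order clade), a 25-gene flagellar-style core set and a 14-gene
#' peptidoglycan-style core set present throughout the basal grade (with a
#' small amount of noise: at most one intermittently-absent gene per basal
#' genome, drawn from `fliE`/`fliM`, keeping every basal genome at
#' fraction >= 0.96) and fully absent in the derived clade, plus genome
#' layouts placing the flagellar genes into three synteny clusters
#' (cluster 1: `fliC`, `fliD`, `fliS`). One basal genome carries a foreign
#' insertion inside cluster 1 and two copies of `fliC`. The truth records
#' exactly one full loss per set on the branch into the most recent common
#' ancestor of orders 10-25.
#'
#' @param seed integer seed for the noise draws.
#' @param partialLossOrders optional tip labels of basal orders given a
#'   heavier partial loss (40% of genes) — off by default, so the headline
#'   single-loss structure holds exactly.
#' @param missingness tip missingness rate applied to the emitted matrix
#'   (default 0: the fixture emulates a completeness-filtered genome set).
#' @return list: `tree`, `matrix` ([TraitMatrix-class]), `catalog`
#'   ([GeneSetCatalog-class]), `coords` (`GRanges`), `truth`
#'   ([SimTruth-class] per set in `truths`, plus combined `truth` of the
#'   flagellar set for convenience), `mrcaNode` (ape number of the derived
#'   clade's MRCA).
#' @export
makePaperFixture <- function(seed = 1, partialLossOrders = character(),
                             missingness = 0) {
    set.seed(seed)
    tips <- sprintf("order%02d", 1:25)
    ## basal caterpillar of orders 1-9, derived balanced clade of 10-25
    balanced <- function(lv) {
        if (length(lv) == 1L) return(lv)
        h <- length(lv) %/% 2L
        paste0("(", balanced(lv[1:h]), ",",
               balanced(lv[(h + 1L):length(lv)]), ")")
    }
    nwk <- balanced(tips[10:25])
    for (i in 9:2) nwk <- paste0("(", tips[i], ",", nwk, ")")
    nwk <- paste0("(", tips[1], ",", nwk, ");")
    tree <- parseNewick(nwk)
    n <- ape::Ntip(tree); N <- n + tree$Nnode
    mrca <- ape::getMRCA(tree, tips[10:25])

    genes <- c(.FLAGELLAR_CORE, .PG_CORE)
    catalog <- GeneSetCatalog(
        gene_id = genes,
        set_name = c(rep("flagellum", length(.FLAGELLAR_CORE)),
                     rep("peptidoglycan", length(.PG_CORE))),
        role = c(ifelse(.FLAGELLAR_CORE %in% c("fliE", "fliM"),
                        "intermittent", "core"),
                 rep("core", length(.PG_CORE))))

    ## true states: present everywhere except the derived clade
    desc <- .descendants(tree, mrca)
    states <- matrix(1L, N, length(genes), dimnames = list(NULL, genes))
    states[c(mrca, desc), ] <- 0L

    ## observed tips = truth + noise (noise absences are real, recorded)
    for (i in 1:9) {
        tip <- match(tips[i], tree$tip.label)
        if (tips[i] %in% partialLossOrders) {
            drop_f <- sample(.FLAGELLAR_CORE, ceiling(0.4 * 25))
            drop_p <- sample(.PG_CORE, ceiling(0.4 * 14))
            states[tip, c(drop_f, drop_p)] <- 0L
        } else if (stats::runif(1) < 0.5) {
            states[tip, sample(c("fliE", "fliM"), 1L)] <- 0L
        }
    }
    tipm <- states[seq_len(n), , drop = FALSE] * 1.0
    rownames(tipm) <- tree$tip.label
    ## copy-number variation: order01 carries two copies of fliC
    tipm["order01", "fliC"] <- 2
    if (missingness > 0) {
        mask <- matrix(stats::runif(length(tipm)) < missingness,
                       nrow(tipm), ncol(tipm))
        tipm[mask] <- NA_real_
    }

    ev_f <- trueSetEvents(tree, states, .FLAGELLAR_CORE)
    ev_p <- trueSetEvents(tree, states, .PG_CORE)
    mk_truth <- function(ev) new("SimTruth", tree = tree, states = states,
        events = ev,
        params = list(seed = seed, missingness = missingness,
                      partialLossOrders = partialLossOrders,
                      forcedLosses = nodeIds(tree)[mrca]))
    truths <- list(flagellum = mk_truth(ev_f), peptidoglycan = mk_truth(ev_p))

    ## genome layouts for the basal (motile) genomes: three clusters on one
    ## contig, separated by 50 kb; ~1 kb genes with 300 bp intergenic gaps
    rows <- list()
    for (i in 1:9) {
        g <- tips[i]
        pos <- 1000L
        emit <- function(gene, len = 900L) {
            r <- DataFrame(genome = g, contig = "c1", gene = gene,
                           start = pos, end = pos + len - 1L, strand = "+")
            pos <<- pos + len + 300L
            r
        }
        for (cl in list(.CLUSTER1, .CLUSTER2, .CLUSTER3)) {
            for (gene in cl) {
                if (is.na(tipm[g, gene]) || tipm[g, gene] >= 1)
                    rows[[length(rows) + 1L]] <- emit(gene)
                if (gene == "fliD" && g == "order02") {
                    rows[[length(rows) + 1L]] <- emit("tnp1", len = 200L)
                }
            }
            pos <- pos + 50000L
        }
    }
    cdf <- as.data.frame(do.call(rbind, rows))
    coords <- GRanges(cdf$contig, IRanges(cdf$start, cdf$end),
                      strand = cdf$strand)
    coords$genome <- cdf$genome
    coords$gene_id <- cdf$gene

    list(tree = tree, matrix = TraitMatrix(tipm), catalog = catalog,
         coords = coords, truth = truths$flagellum, truths = truths,
         mrcaNode = mrca)
}

.descendants <- function(tree, node) {
    kids <- .children_list(tree)
    out <- integer()
    stack <- kids[[node]]
    while (length(stack)) {
        v <- stack[1L]; stack <- stack[-1L]
        out <- c(out, v)
        stack <- c(stack, kids[[v]])
    }
    out
}

#' Write a fixture or simulation to disk
#'
#' Emits the same formats the pipeline reads: `tree.nwk`, `matrix.tsv`,
#' `gene_sets.tsv`, `coords.tsv` (fixture only) and `truth.json`
#' (parameters, seed and true events).
#'
#' @param fx output of [makePaperFixture()] or [simulateGeneHistories()].
#' @param dir output directory (created if needed).
#' @return dir, invisibly.
#' @export
writeFixture <- function(fx, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(fx$truth)) {
        writeNewick(fx$truth@tree, file.path(dir, "tree.nwk"))
        truth <- fx$truth
    } else stop("object has no truth component")
    writeTraitMatrix(fx$matrix, file.path(dir, "matrix.tsv"))
    if (!is.null(fx$catalog))
        writeGeneSetCatalog(fx$catalog, file.path(dir, "gene_sets.tsv"))
    if (!is.null(fx$coords))
        writeCoordinates(fx$coords, file.path(dir, "coords.tsv"))
    tj <- list(params = truth@params,
               events = as.data.frame(truth@events))
    if (!is.null(fx$truths))
        tj$events_per_set <- lapply(fx$truths,
                                    function(t) as.data.frame(t@events))
    jsonlite::write_json(tj, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}
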