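#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
NULL

setOldClass("phylo")

#' TraitMatrix: genome-by-gene occurrence counts with explicit missing data
#'
#' A `TraitMatrix` stores non-negative integer gene copy counts for a panel of
#' genomes, with `NA` marking cells where the genome assembly is too incomplete
#' to decide (written as `"?"` on disk). It extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with genes as rows (features) and genomes as columns (samples), so the
#' usual Bioconductor subsetting and accessor machinery applies. The
#' binarized view used throughout the package calls a gene present in a
#' genome iff its count is >= 1.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment-class]; the single
#'   assay is named `"counts"`.
#'
#' @seealso [TraitMatrix()], [readTraitMatrix()], [presenceFraction()]
#' @export
setClass("TraitMatrix", contains = "SummarizedExperiment")

setValidity("TraitMatrix", function(object) {
    msg <- character()
    if (!("counts" %in% assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- assay(object, "counts")
        if (nrow(m) < 1L || ncol(m) < 1L)
            msg <- c(msg, "need at least one gene and one genome")
        if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
            msg <- c(msg, "gene ids must be unique and non-empty")
        if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
            msg <- c(msg, "genome ids must be unique and non-empty")
        v <- m[!is.na(m)]
        if (length(v) && (any(v < 0) || any(v != round(v))))
            msg <- c(msg, "counts must be non-negative integers or NA")
    }
    if (length(msg)) msg else TRUE
})

#' GeneSetCatalog: named gene sets with member roles and state thresholds
#'
#' Groups genes into named sets (e.g. a core structural flagellar set and a
#' regulatory set), tagging each member with a role (`core`, `regulatory` or
#' `intermittent`), and carries the two thresholds of the core-set rule:
#' a set is called *present* in a genome or ancestral node when the fraction
#' of its members present is `>= presentMin` (default 0.9, the ">90% of
#' members" rule rounded to a closed bound, which differs only on exact
#' boundaries that cannot occur for the set sizes in practice), *absent* when
#' `<= absentMax` (default 0.1, chosen by symmetry), and *partial* in
#' between.
#'
#' @slot members DataFrame with columns `gene_id`, `set_name`, `role`.
#' @slot presentMin numeric(1), lower bound of the "present" call.
#' @slot absentMax numeric(1), upper bound of the "absent" call.
#'
#' @seealso [GeneSetCatalog()], [classifySetState()]
#' @export
setClass("GeneSetCatalog",
    representation(members = "DataFrame", presentMin = "numeric",
                   absentMax = "numeric"))

.valid_roles <- c("core", "regulatory", "intermittent")

setValidity("GeneSetCatalog", function(object) {
    msg <- character()
    m <- object@members
    need <- c("gene_id", "set_name", "role")
    if (!all(need %in% colnames(m)))
        return(paste("members must have columns", paste(need, collapse = ", ")))
    if (nrow(m) < 1L) msg <- c(msg, "catalog must contain at least one gene")
    if (!all(m$role %in% .valid_roles))
        msg <- c(msg, paste("roles must be one of:",
                            paste(.valid_roles, collapse = ", ")))
    if (anyDuplicated(paste(m$set_name, m$gene_id)))
        msg <- c(msg, "a gene may appear at most once per set")
    pm <- object@presentMin; am <- object@absentMax
    if (length(pm) != 1L || length(am) != 1L || is.na(pm) || is.na(am) ||
        !(am >= 0 && am < pm && pm <= 1))
        msg <- c(msg, "thresholds must satisfy 0 <= absentMax < presentMin <= 1")
    if (length(msg)) msg else TRUE
})

#' MkFit: fitted two-state Mk gain/loss model
#'
#' Result of [fitMk()]: a continuous-time two-state Markov model with gain
#' rate (0 -> 1) and loss rate (1 -> 0) per unit branch length, fitted by
#' maximum likelihood pooled over genes.
#'
#' @slot gainRate numeric(1), fitted 0 -> 1 rate.
#' @slot lossRate numeric(1), fitted 1 -> 0 rate.
#' @slot logLik numeric(1), maximized pooled log-likelihood.
#' @slot rootPrior character(1), `"stationary"` or `"flat"`.
#' @slot converged logical(1), optimizer convergence at tolerance.
#' @slot boundary character, which rates (if any) sit at the search bounds.
#' @slot bounds numeric(2), rate search interval.
#' @export
setClass("MkFit",
    representation(gainRate = "numeric", lossRate = "numeric",
                   logLik = "numeric", rootPrior = "character",
                   converged = "logical", boundary = "character",
                   bounds = "numeric"))

setValidity("MkFit", function(object) {
    msg <- character()
    if (object@gainRate <= 0 || object@lossRate <= 0)
        msg <- c(msg, "rates must be positive")
    if (!object@rootPrior %in% c("stationary", "flat"))
        msg <- c(msg, "rootPrior must be 'stationary' or 'flat'")
    if (length(msg)) msg else TRUE
})

#' NodeStates: per-gene reconstructed states at every node of a tree
#'
#' Result of [ancestralStates()]. For every gene and every node the table
#' records the parsimony state set and/or marginal posterior pair, plus a
#' resolved state in `{"0", "1", "ambiguous", "unknown"}` ("unknown" marks
#' tips whose observed value was missing; missing data are never imputed).
#'
#' @slot tree the `phylo` tree the states live on.
#' @slot method `"fitch"` or `"mk"`.
#' @slot states DataFrame: `gene_id`, `node`, `node_id`, `state_set`,
#'   `p0`, `p1`, `resolved`.
#' @slot tipStates tips-by-genes matrix of observed 0/1/NA values.
#' @slot scores named numeric of parsimony scores (Fitch), else empty.
#' @slot fit the [MkFit-class] used (Mk), else `NULL`.
#' @export
setClass("NodeStates",
    representation(tree = "phylo", method = "character", states = "DataFrame",
                   tipStates = "matrix", scores = "numeric", fit = "ANY"))

#' SetStateProfile: gene-set state at every node
#'
#' Per-node presence fraction of a gene set over reconstructed member states
#' (ambiguous genes weigh 0.5; tip-missing genes are excluded) and the
#' corresponding present/partial/absent/unknown classification.
#'
#' @slot set character(1), set name.
#' @slot profile DataFrame: `node`, `node_id`, `fraction`, `state`.
#' @slot genes character, member genes used.
#' @slot presentMin,absentMax classification thresholds used.
#' @export
setClass("SetStateProfile",
    representation(set = "character", profile = "DataFrame",
                   genes = "character", presentMin = "numeric",
                   absentMax = "numeric"))

#' EventCalls: branch-localized gain/loss events of a gene set
#'
#' Result of [callEvents()]: one row per branch where the set state changes,
#' with the event type, the per-gene agreement fraction and whether the call
#' clears the consensus threshold `theta`. Unsupported calls are retained
#' with `supported = FALSE`; [consensusEvents()] filters to supported rows.
#'
#' @slot events DataFrame: `set_name`, `parent`, `child`, `parent_id`,
#'   `child_id`, `parent_state`, `child_state`, `event_type`, `agreement`,
#'   `n_agree`, `n_informative`, `supported`.
#' @slot genes DataFrame of per-gene changes behind each call.
#' @slot skipped DataFrame of branches touching unknown states (logged, no
#'   call emitted).
#' @slot theta numeric(1), consensus agreement threshold.
#' @export
setClass("EventCalls",
    representation(events = "DataFrame", genes = "DataFrame",
                   skipped = "DataFrame", theta = "numeric"))

#' SimTruth: ground truth of a simulated gene-history data set
#'
#' Records everything the generator knows: the tree, the true state of every
#' gene at every node (pre-missingness), the true set-level events implied by
#' those states at the default thresholds, and the simulation parameters.
#'
#' @slot tree the simulated-on `phylo`.
#' @slot states nodes-by-genes 0/1 integer matrix of true states.
#' @slot events DataFrame of true set-level events: `parent`, `child`,
#'   `parent_id`, `child_id`, `event_type`.
#' @slot params list of generator parameters (rates, seed, forced events,
#'   missingness, root policy).
#' @export
setClass("SimTruth",
    representation(tree = "phylo", states = "matrix", events = "DataFrame",
                   params = "list"))
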