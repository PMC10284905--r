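#' Gene-set state profile over all tree nodes
#'
#' Lifts per-gene reconstructed states to set level: at every node the
#' presence fraction over the set's member genes is computed as in
#' [presenceFraction()] but on reconstructed states — resolved `"1"` counts
#' 1, `"0"` counts 0, `"ambiguous"` counts 0.5, and `"unknown"` (tips whose
#' observed value was missing) is excluded from numerator and denominator.
#' Fractions are then classified with [classifySetState()].
#'
#' @param ns a [NodeStates-class] covering all member genes.
#' @param genes member gene ids, or a [GeneSetCatalog-class] together with
#'   `set`.
#' @param set set name (label, and catalog lookup when `genes` is a
#'   catalog).
#' @param presentMin,absentMax thresholds; defaulted from the catalog when
#'   one is supplied.
#' @return a [SetStateProfile-class].
#' @export
setStates <- function(ns, genes, set = "set", presentMin = 0.9,
                      absentMax = 0.1) {
    if (is(genes, "GeneSetCatalog")) {
        cat <- genes
        genes <- setMembers(cat, set)
        if (missing(presentMin)) presentMin <- presentMin(cat)
        if (missing(absentMax)) absentMax <- absentMax(cat)
    }
    have <- unique(ns@states$gene_id)
    .check_known(genes, have, "reconstructed gene")
    rm_ <- .resolved_matrix(ns)[, genes, drop = FALSE]
    w <- matrix(NA_real_, nrow(rm_), ncol(rm_))
    w[rm_ == "1"] <- 1
    w[rm_ == "0"] <- 0
    w[rm_ == "ambiguous"] <- 0.5
    num <- rowSums(w, na.rm = TRUE)
    den <- rowSums(!is.na(w))
    frac <- ifelse(den > 0, num / den, NA_real_)
    ids <- nodeIds(ns@tree)
    new("SetStateProfile", set = set,
        profile = DataFrame(node = seq_along(ids), node_id = ids,
                            fraction = frac,
                            state = classifySetState(frac, presentMin,
                                                     absentMax)),
        genes = genes, presentMin = presentMin, absentMax = absentMax)
}

#' @describeIn setStates the per-node profile table.
#' @param profile a SetStateProfile.
#' @export
setProfile <- function(profile) profile@profile

#' @describeIn setStates set state at the root node.
#' @param tree the tree the profile was computed on.
#' @export
rootState <- function(profile, tree) {
    root <- ape::Ntip(tree) + 1L
    profile@profile$state[profile@profile$node == root]
}

setMethod("show", "SetStateProfile", function(object) {
    tab <- table(object@profile$state)
    cat("SetStateProfile '", object@set, "': ", length(object@genes),
        " genes; node states: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
})

## event type from (parent state, child state); NA = no event
.event_map <- function(ps, cs, partialToAbsent = "loss") {
    key <- paste(ps, cs, sep = ">")
    switch(key,
           "present>absent" = "loss",
           "present>partial" = "partial_loss",
           "partial>absent" = partialToAbsent,
           "absent>present" = "gain",
           "absent>partial" = "partial_gain",
           "partial>present" = "gain",
           NA_character_)
}

#' Call consensus gain/loss events on branches
#'
#' Walks every branch of the tree; where the set state changes between
#' parent and child an event is emitted (present->absent: loss;
#' present->partial: partial_loss; partial->absent: loss — the set completes
#' its disappearance; absent->present: gain; absent->partial: partial_gain;
#' partial->present: gain). Branches touching `unknown` states emit no call
#' but are logged in the `skipped` slot.
#'
#' The per-branch agreement fraction is the share of member genes whose own
#' resolved state change across the branch matches the event direction
#' (gains: 0 -> 1; losses: 1 -> 0), computed over genes resolved 0/1 at
#' both endpoints; ambiguous or unknown genes neither support nor veto.
#' Calls with agreement below `theta` are retained with
#' `supported = FALSE` and excluded from [consensusEvents()].
#'
#' @param ns a [NodeStates-class].
#' @param profile a [SetStateProfile-class] from [setStates()] on `ns`.
#' @param theta consensus agreement threshold in (0, 1], default 0.9.
#' @param partialToAbsent grade of the partial->absent transition, `"loss"`
#'   (default) or `"partial_loss"`.
#' @return an [EventCalls-class].
#' @export
callEvents <- function(ns, profile, theta = 0.9,
                       partialToAbsent = c("loss", "partial_loss")) {
    partialToAbsent <- match.arg(partialToAbsent)
    if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta > 1)
        stop("theta must be in (0, 1]")
    tree <- ns@tree
    ids <- nodeIds(tree)
    st <- profile@profile$state[order(profile@profile$node)]
    rm_ <- .resolved_matrix(ns)[, profile@genes, drop = FALSE]
    edge <- tree$edge
    ev <- list(); gv <- list(); sk <- list()
    for (r in seq_len(nrow(edge))) {
        u <- edge[r, 1L]; v <- edge[r, 2L]
        ps <- st[u]; cs <- st[v]
        if (ps == "unknown" || cs == "unknown") {
            sk[[length(sk) + 1L]] <- DataFrame(
                set_name = profile@set, parent_id = ids[u],
                child_id = ids[v], parent_state = ps, child_state = cs)
            next
        }
        if (ps == cs) next
        type <- .event_map(ps, cs, partialToAbsent)
        if (is.na(type)) next
        dir_to <- if (type %in% c("gain", "partial_gain")) "1" else "0"
        dir_from <- if (dir_to == "1") "0" else "1"
        from <- rm_[u, ]; to <- rm_[v, ]
        informative <- from %in% c("0", "1") & to %in% c("0", "1")
        agrees <- informative & from == dir_from & to == dir_to
        n_inf <- sum(informative)
        agreement <- if (n_inf > 0) sum(agrees) / n_inf else NA_real_
        ev[[length(ev) + 1L]] <- DataFrame(
            set_name = profile@set, parent = u, child = v,
            parent_id = ids[u], child_id = ids[v],
            parent_state = ps, child_state = cs, event_type = type,
            agreement = agreement, n_agree = sum(agrees),
            n_informative = n_inf,
            supported = !is.na(agreement) && agreement >= theta)
        gv[[length(gv) + 1L]] <- DataFrame(
            set_name = profile@set, parent_id = ids[u], child_id = ids[v],
            gene_id = colnames(rm_), from = unname(from), to = unname(to),
            agrees = unname(agrees))
    }
    empty_ev <- DataFrame(set_name = character(), parent = integer(),
                          child = integer(), parent_id = character(),
                          child_id = character(), parent_state = character(),
                          child_state = character(), event_type = character(),
                          agreement = numeric(), n_agree = integer(),
                          n_informative = integer(), supported = logical())
    empty_g <- DataFrame(set_name = character(), parent_id = character(),
                         child_id = character(), gene_id = character(),
                         from = character(), to = character(),
                         agrees = logical())
    empty_sk <- DataFrame(set_name = character(), parent_id = character(),
                          child_id = character(), parent_state = character(),
                          child_state = character())
    new("EventCalls",
        events = if (length(ev)) do.call(rbind, ev) else empty_ev,
        genes = if (length(gv)) do.call(rbind, gv) else empty_g,
        skipped = if (length(sk)) do.call(rbind, sk) else empty_sk,
        theta = theta)
}

#' @describeIn callEvents all calls (supported and unsupported).
#' @param ec an EventCalls.
#' @export
eventTable <- function(ec) ec@events

#' @describeIn callEvents only the calls clearing the consensus threshold.
#' @export
consensusEvents <- function(ec) ec@events[ec@events$supported, , drop = FALSE]

setMethod("show", "EventCalls", function(object) {
    e <- object@events
    cat("EventCalls: ", nrow(e), " call(s), ", sum(e$supported),
        " supported at theta = ", object@theta, "\n", sep = "")
    if (nrow(e))
        for (r in seq_len(nrow(e)))
            cat("  ", e$set_name[r], ": ", e$event_type[r], " on ",
                e$parent_id[r], " -> ", e$child_id[r], " (agreement ",
                signif(e$agreement[r], 3),
                if (!e$supported[r]) ", unsupported" else "",
                ")\n", sep = "")
})

#' Score called events against simulation truth
#'
#' An event matches truth when branch (child node) and direction (gain vs
#' loss, ignoring the full/partial grade) agree. Precision =
#' matched/called, recall = matched/true; both 1.0 when called and truth
#' are empty, and the empty side scores 0 (flagged) when only one side is
#' empty.
#'
#' @param called an [EventCalls-class] (supported calls are scored) or a
#'   DataFrame/data.frame with columns `child_id`, `event_type`.
#' @param truth a [SimTruth-class] or a DataFrame with columns `child_id`,
#'   `event_type`.
#' @return list with `precision`, `recall`, `n_called`, `n_true`,
#'   `n_matched`, and `degenerate` flag for the empty-side conventions.
#' @export
scoreEventRecovery <- function(called, truth) {
    cd <- if (is(called, "EventCalls")) consensusEvents(called) else called
    td <- if (is(truth, "SimTruth")) truth@events else truth
    dir_class <- function(x) ifelse(grepl("gain", x), "gain", "loss")
    ckey <- unique(paste(cd$child_id, dir_class(cd$event_type)))
    tkey <- unique(paste(td$child_id, dir_class(td$event_type)))
    nm <- length(intersect(ckey, tkey))
    degenerate <- xor(length(ckey) == 0L, length(tkey) == 0L)
    prec <- if (length(ckey) == 0L && length(tkey) == 0L) 1
            else if (length(ckey) == 0L) 0 else nm / length(ckey)
    rec <- if (length(tkey) == 0L && length(ckey) == 0L) 1
           else if (length(tkey) == 0L) 0 else nm / length(tkey)
    list(precision = prec, recall = rec, n_called = length(ckey),
         n_true = length(tkey), n_matched = nm, degenerate = degenerate)
}

#' Write event calls as TSV
#'
#' `events.tsv` columns: `set_name`, `parent_id`, `child_id`, `event_type`,
#' `agreement`, `supported`; gene-level detail goes to a companion file.
#'
#' @param ec an [EventCalls-class].
#' @param path events TSV path.
#' @param genesPath optional companion per-gene TSV path.
#' @export
writeEvents <- function(ec, path, genesPath = NULL) {
    e <- as.data.frame(ec@events)
    utils::write.table(
        e[, c("set_name", "parent_id", "child_id", "event_type",
              "agreement", "supported")],
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(genesPath))
        utils::write.table(as.data.frame(ec@genes), genesPath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    invisible(path)
}
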