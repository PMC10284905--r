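## Fitch parsimony for a binary character, generalized to polytomies:
## at each internal node the candidate set is the set of states carried by
## the maximal number of child state sets, and the score grows by the number
## of children whose sets miss those states (intersection/union for the
## binary case). State sets are encoded as bitmasks: 1 = {0}, 2 = {1},
## 3 = {0,1}.

.fitch_one <- function(tree, x) {
    n <- ape::Ntip(tree)
    N <- n + tree$Nnode
    sets <- integer(N)
    idx <- match(tree$tip.label, names(x))
    if (anyNA(idx)) stop("tip state(s) missing for: ",
                         paste(tree$tip.label[is.na(idx)], collapse = ", "))
    xv <- x[idx]
    if (all(is.na(xv))) stop("all tips missing; nothing to reconstruct")
    sets[seq_len(n)] <- ifelse(is.na(xv), 3L, ifelse(xv >= 1, 2L, 1L))

    score <- 0L
    ## bottom-up: internal nodes in postorder (children before parents)
    post <- nodeOrder(tree, "postorder")
    post <- post[post > n]
    kids <- .children_list(tree)
    for (p in post) {
        ch <- kids[[p]]
        c0 <- sum(bitwAnd(sets[ch], 1L) > 0L)
        c1 <- sum(bitwAnd(sets[ch], 2L) > 0L)
        m <- max(c0, c1)
        sets[p] <- (if (c0 == m) 1L else 0L) + (if (c1 == m) 2L else 0L)
        score <- score + (length(ch) - m)
    }

    ## top-down resolution (DELTRAN-flavoured): ambiguous nodes adopt the
    ## parent's resolved state when compatible; a root tie falls to the
    ## majority observed tip state, or "ambiguous" on an exact tie.
    resolved <- character(N)
    root <- n + 1L
    if (sets[root] == 3L) {
        t1 <- sum(xv >= 1, na.rm = TRUE); t0 <- sum(xv == 0, na.rm = TRUE)
        resolved[root] <- if (t1 > t0) "1" else if (t0 > t1) "0"
                          else "ambiguous"
    } else resolved[root] <- if (sets[root] == 2L) "1" else "0"
    pre <- ape::reorder.phylo(tree, "cladewise")$edge
    parent_of <- integer(N); parent_of[pre[, 2L]] <- pre[, 1L]
    for (r in seq_len(nrow(pre))) {
        v <- pre[r, 2L]
        if (sets[v] != 3L) {
            resolved[v] <- if (sets[v] == 2L) "1" else "0"
        } else {
            ps <- resolved[pre[r, 1L]]
            resolved[v] <- if (ps %in% c("0", "1")) ps else "ambiguous"
        }
    }
    ## tips observed as missing stay unresolved: missingness is never imputed
    resolved[seq_len(n)][is.na(xv)] <- "unknown"
    list(sets = sets, resolved = resolved, score = score)
}

#' Fitch parsimony reconstruction of one gene
#'
#' Minimum-change reconstruction of a binary presence/absence character on a
#' rooted tree (polytomies handled natively). Missing tips carry the
#' uninformative state set \{0,1\} and are reported as `"unknown"`, never
#' imputed. The returned score is the minimum number of state changes.
#'
#' @param tree rooted `phylo` (branch lengths ignored).
#' @param tipStates named vector over all tip labels with values 0, 1 or NA
#'   (missing).
#' @return list with `stateSets` (list of sorted integer vectors per node),
#'   `resolved` (character per node), `score` (integer).
#' @seealso [ancestralStates()] for the multi-gene interface,
#'   [enumFitchScore()] for the exhaustive oracle.
#' @export
fitchParsimony <- function(tree, tipStates) {
    r <- .fitch_one(tree, tipStates)
    decode <- list(`1` = 0L, `2` = 1L, `3` = c(0L, 1L))
    list(stateSets = lapply(r$sets, function(s) decode[[s]]),
         resolved = r$resolved, score = r$score)
}

#' Exhaustive minimum-change oracle
#'
#' Brute-force minimum number of state changes over all assignments of 0/1
#' to internal nodes (and missing tips), by direct enumeration. Exponential
#' in tree size; intended as an independent reference for validating
#' [fitchParsimony()] on small trees.
#'
#' @inheritParams fitchParsimony
#' @return integer minimum change count.
#' @export
enumFitchScore <- function(tree, tipStates) {
    n <- ape::Ntip(tree)
    N <- n + tree$Nnode
    xv <- tipStates[match(tree$tip.label, names(tipStates))]
    if (all(is.na(xv))) stop("all tips missing")
    free <- c(which(is.na(xv)), (n + 1L):N)
    fixed <- integer(N)
    fixed[seq_len(n)] <- ifelse(is.na(xv), 0L, as.integer(xv >= 1))
    edge <- tree$edge
    best <- Inf
    for (mask in 0:(2^length(free) - 1L)) {
        lab <- fixed
        lab[free] <- bitwAnd(bitwShiftR(mask, seq_along(free) - 1L), 1L)
        changes <- sum(lab[edge[, 1L]] != lab[edge[, 2L]])
        if (changes < best) best <- changes
    }
    as.integer(best)
}
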