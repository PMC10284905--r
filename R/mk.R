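## Two-state Mk machinery: closed-form transition probabilities,
## Felsenstein pruning vectorized across genes, pooled ML rate fitting,
## and marginal (up-down) ancestral posteriors.

#' Two-state Mk transition probability matrix
#'
#' Closed form for the continuous-time chain with gain rate `alpha`
#' (0 -> 1) and loss rate `beta` (1 -> 0):
#' `P01(t) = alpha/(alpha+beta) * (1 - exp(-(alpha+beta) t))`,
#' `P10(t) = beta/(alpha+beta) * (1 - exp(-(alpha+beta) t))`,
#' diagonals completing rows to 1.
#'
#' @param alpha gain rate (> 0), per unit branch length.
#' @param beta loss rate (> 0).
#' @param t branch length (>= 0).
#' @return 2x2 row-stochastic matrix with dimnames `c("0","1")`.
#' @examples
#' mkTransitionProb(1, 1, log(2) / 2)["0", "1"]  # 0.25
#' @export
mkTransitionProb <- function(alpha, beta, t) {
    if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
        stop("rates must be positive and finite")
    if (!is.finite(t) || t < 0) stop("branch length must be >= 0")
    r <- alpha + beta
    f <- 1 - exp(-r * t)
    p01 <- alpha / r * f
    p10 <- beta / r * f
    matrix(c(1 - p01, p10, p01, 1 - p10), 2L, 2L,
           dimnames = list(c("0", "1"), c("0", "1")))
}

.root_prior <- function(rootPrior, alpha, beta) {
    switch(rootPrior,
           stationary = c(beta, alpha) / (alpha + beta),
           flat = c(0.5, 0.5),
           stop("rootPrior must be 'stationary' or 'flat'"))
}

## tip-state matrix (tips x genes, values 0/1/NA) from various inputs
.tip_matrix <- function(tree, x) {
    if (is(x, "TraitMatrix")) {
        p <- presenceMatrix(x)          # genes x genomes
        miss <- setdiff(tree$tip.label, colnames(p))
        if (length(miss))
            stop("matrix is missing tree tip(s): ",
                 paste(miss, collapse = ", "))
        m <- t(p[, tree$tip.label, drop = FALSE]) * 1
    } else if (is.matrix(x)) {
        miss <- setdiff(tree$tip.label, rownames(x))
        if (length(miss))
            stop("tip-state matrix is missing tip(s): ",
                 paste(miss, collapse = ", "))
        m <- x[tree$tip.label, , drop = FALSE] * 1
    } else {                             # single named vector
        m <- matrix(x[match(tree$tip.label, names(x))], ncol = 1L,
                    dimnames = list(tree$tip.label, "gene"))
    }
    bad <- !(m %in% c(0, 1)) & !is.na(m)
    if (any(bad)) stop("tip states must be 0, 1 or NA")
    if (any(apply(m, 2L, function(col) all(is.na(col)))))
        stop("gene(s) with all tips missing")
    m
}

## Felsenstein pruning, vectorized over genes. Returns per-gene log-lik and
## the scaled conditional likelihood matrices (for the up-down pass).
.mk_pruning <- function(tree, X, alpha, beta, rootPrior = "stationary",
                        unitLengths = FALSE) {
    n <- ape::Ntip(tree)
    N <- n + tree$Nnode
    G <- ncol(X)
    et <- .edge_table(tree, unitLengths = unitLengths)
    elen <- rep(NA_real_, N)
    elen[et$edge[, 2L]] <- et$length

    L0 <- matrix(1, N, G); L1 <- matrix(1, N, G)
    L0[seq_len(n), ] <- ifelse(is.na(X), 1, 1 - X)
    L1[seq_len(n), ] <- ifelse(is.na(X), 1, X)
    logscale <- numeric(G)

    kids <- .children_list(tree)
    post <- nodeOrder(tree, "postorder")
    post <- post[post > n]
    r <- alpha + beta
    for (p in post) {
        for (ch in kids[[p]]) {
            f <- 1 - exp(-r * elen[ch])
            p01 <- alpha / r * f; p10 <- beta / r * f
            s0 <- (1 - p01) * L0[ch, ] + p01 * L1[ch, ]
            s1 <- p10 * L0[ch, ] + (1 - p10) * L1[ch, ]
            L0[p, ] <- L0[p, ] * s0
            L1[p, ] <- L1[p, ] * s1
        }
        mx <- pmax(L0[p, ], L1[p, ])
        safe <- ifelse(mx > 0, mx, 1)
        L0[p, ] <- L0[p, ] / safe
        L1[p, ] <- L1[p, ] / safe
        logscale <- logscale + ifelse(mx > 0, log(mx), -Inf)
    }
    prior <- .root_prior(rootPrior, alpha, beta)
    root <- n + 1L
    lik <- prior[1L] * L0[root, ] + prior[2L] * L1[root, ]
    ll <- ifelse(lik > 0 & is.finite(logscale), log(lik) + logscale, -Inf)
    list(loglik = ll, L0 = L0, L1 = L1, elen = elen, prior = prior,
         kids = kids)
}

#' Mk log-likelihood of tip states
#'
#' Felsenstein pruning (postorder conditional-likelihood recursion) for the
#' two-state Mk model. Missing tips contribute the uninformative partial
#' likelihood (1, 1). Data with probability exactly zero (possible only
#' with zero-length branches) return `-Inf` with attribute
#' `impossible = TRUE`.
#'
#' @param tree rooted `phylo` with branch lengths, or a cladogram with
#'   `unitLengths = TRUE`.
#' @param tipStates named 0/1/NA vector over tips, a tips-by-genes matrix,
#'   or a [TraitMatrix-class] (binarized; all tree tips required).
#' @param alpha,beta gain and loss rates (> 0).
#' @param rootPrior `"stationary"` (`(beta, alpha)/(alpha+beta)`) or
#'   `"flat"`.
#' @param unitLengths substitute unit branch lengths on a cladogram.
#' @return per-gene log-likelihood (numeric; scalar for a single gene).
#' @seealso [enumMkLikelihood()] for the exhaustive oracle.
#' @export
mkLoglik <- function(tree, tipStates, alpha, beta,
                     rootPrior = "stationary", unitLengths = FALSE) {
    if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
        stop("rates must be positive and finite")
    X <- .tip_matrix(tree, tipStates)
    ll <- .mk_pruning(tree, X, alpha, beta, rootPrior, unitLengths)$loglik
    if (any(!is.finite(ll))) attr(ll, "impossible") <- TRUE
    if (length(ll) == 1L) names(ll) <- NULL
    ll
}

#' Fit pooled Mk gain/loss rates by maximum likelihood
#'
#' Maximizes the summed log-likelihood over all genes in
#' `(log alpha, log beta)` with a derivative-free Nelder-Mead simplex from
#' two fixed starting points (symmetric and loss-biased; the better optimum
#' is kept), within rate bounds. Deterministic given inputs.
#'
#' All-constant data push a rate to its lower bound; this is reported via
#' the `boundary` slot and a warning, not an error (the likelihood is
#' genuinely maximized there).
#'
#' @inheritParams mkLoglik
#' @param bounds rate search interval (default `c(1e-6, 1e3)`).
#' @param tol relative convergence tolerance (default 1e-8).
#' @return an [MkFit-class].
#' @export
fitMk <- function(tree, tipStates, rootPrior = "stationary",
                  unitLengths = FALSE, bounds = c(1e-6, 1e3), tol = 1e-8) {
    X <- .tip_matrix(tree, tipStates)
    lb <- log(bounds)
    obj <- function(par) {
        par <- pmin(pmax(par, lb[1L]), lb[2L])
        ll <- .mk_pruning(tree, X, exp(par[1L]), exp(par[2L]),
                          rootPrior, unitLengths)$loglik
        s <- sum(ll)
        if (!is.finite(s)) 1e10 else -s
    }
    starts <- list(log(c(0.5, 0.5)), log(c(0.1, 1.0)))
    best <- NULL
    for (s0 in starts) {
        o <- stats::optim(s0, obj, method = "Nelder-Mead",
                          control = list(reltol = tol, maxit = 5000L))
        if (is.null(best) || o$value < best$value) best <- o
    }
    par <- pmin(pmax(best$par, lb[1L]), lb[2L])
    rates <- exp(par)
    boundary <- character()
    eps <- 1e-3
    if (par[1L] <= lb[1L] + eps) boundary <- c(boundary, "gainRate:lower")
    if (par[1L] >= lb[2L] - eps) boundary <- c(boundary, "gainRate:upper")
    if (par[2L] <= lb[1L] + eps) boundary <- c(boundary, "lossRate:lower")
    if (par[2L] >= lb[2L] - eps) boundary <- c(boundary, "lossRate:upper")
    if (length(boundary))
        warning("rate estimate at search bound: ",
                paste(boundary, collapse = ", "))
    new("MkFit", gainRate = rates[1L], lossRate = rates[2L],
        logLik = -best$value, rootPrior = rootPrior,
        converged = best$convergence == 0L, boundary = boundary,
        bounds = bounds)
}

#' @describeIn fitMk fitted gain rate (0 -> 1).
#' @param fit an MkFit.
#' @export
gainRate <- function(fit) fit@gainRate

#' @describeIn fitMk fitted loss rate (1 -> 0).
#' @export
lossRate <- function(fit) fit@lossRate

setMethod("show", "MkFit", function(object) {
    cat("MkFit: gain =", signif(object@gainRate, 4),
        " loss =", signif(object@lossRate, 4),
        " logLik =", signif(object@logLik, 8),
        " prior =", object@rootPrior,
        if (!object@converged) " [not converged]" else "",
        if (length(object@boundary))
            paste0(" [at bound: ", paste(object@boundary, collapse = ","), "]")
        else "", "\n")
})

## Up-down pass: marginal posteriors at every node for every gene.
.mk_marginal <- function(tree, X, alpha, beta, rootPrior = "stationary",
                         unitLengths = FALSE) {
    n <- ape::Ntip(tree)
    N <- n + tree$Nnode
    G <- ncol(X)
    pr <- .mk_pruning(tree, X, alpha, beta, rootPrior, unitLengths)
    if (any(!is.finite(pr$loglik)))
        stop("data have zero likelihood under these rates/branch lengths")
    L0 <- pr$L0; L1 <- pr$L1; elen <- pr$elen; kids <- pr$kids
    A0 <- matrix(0, N, G); A1 <- matrix(0, N, G)
    root <- n + 1L
    A0[root, ] <- pr$prior[1L]; A1[root, ] <- pr$prior[2L]
    r <- alpha + beta
    Pmat <- function(ch) {
        f <- 1 - exp(-r * elen[ch])
        c(p01 = alpha / r * f, p10 = beta / r * f)
    }
    pre <- nodeOrder(tree, "preorder")
    for (u in pre) {
        ch <- kids[[u]]
        if (length(ch) < 1L) next
        ## per-child partial messages S_b(s) = sum_sb P(s -> sb) L_b(sb)
        S0 <- matrix(1, length(ch), G); S1 <- matrix(1, length(ch), G)
        for (j in seq_along(ch)) {
            b <- ch[j]; p <- Pmat(b)
            S0[j, ] <- (1 - p["p01"]) * L0[b, ] + p["p01"] * L1[b, ]
            S1[j, ] <- p["p10"] * L0[b, ] + (1 - p["p10"]) * L1[b, ]
        }
        for (j in seq_along(ch)) {
            b <- ch[j]; p <- Pmat(b)
            sib0 <- rep(1, G); sib1 <- rep(1, G)
            for (k in seq_along(ch)) {
                if (k == j) next
                sib0 <- sib0 * S0[k, ]
                sib1 <- sib1 * S1[k, ]
            }
            au0 <- A0[u, ] * sib0
            au1 <- A1[u, ] * sib1
            A0[b, ] <- au0 * (1 - p["p01"]) + au1 * p["p10"]
            A1[b, ] <- au0 * p["p01"] + au1 * (1 - p["p10"])
            mx <- pmax(A0[b, ], A1[b, ])
            mx[mx <= 0] <- 1
            A0[b, ] <- A0[b, ] / mx
            A1[b, ] <- A1[b, ] / mx
        }
    }
    w0 <- A0 * L0; w1 <- A1 * L1
    tot <- w0 + w1
    list(p0 = w0 / tot, p1 = w1 / tot, loglik = pr$loglik)
}

#' Marginal ancestral posteriors under a fitted Mk model
#'
#' Up-down algorithm: combines the below-tree conditional likelihoods with
#' above-tree likelihoods so each node's posterior is proportional to the
#' prior-weighted joint, integrating over all other nodes. Posteriors sum
#' to 1 at every node; tips with observed states get degenerate posteriors.
#'
#' @inheritParams mkLoglik
#' @param fit an [MkFit-class] (from [fitMk()]) supplying rates and root
#'   prior; alternatively pass `alpha`/`beta`/`rootPrior` directly.
#' @param tieTol posteriors closer than this are resolved `"ambiguous"`.
#' @return a [NodeStates-class] with posteriors and argmax-resolved states
#'   (`"ambiguous"` on a tie; observed-missing tips keep their genuine
#'   posterior but are tagged `"unknown"` in the resolved column).
#' @export
marginalAncestral <- function(tree, tipStates, fit = NULL, alpha = NULL,
                              beta = NULL, rootPrior = "stationary",
                              unitLengths = FALSE, tieTol = 1e-9) {
    if (!is.null(fit)) {
        alpha <- fit@gainRate; beta <- fit@lossRate
        rootPrior <- fit@rootPrior
    }
    if (is.null(alpha) || is.null(beta))
        stop("supply 'fit' or both 'alpha' and 'beta'")
    X <- .tip_matrix(tree, tipStates)
    mg <- .mk_marginal(tree, X, alpha, beta, rootPrior, unitLengths)
    n <- ape::Ntip(tree)
    N <- n + tree$Nnode
    G <- ncol(X)
    ids <- nodeIds(tree)
    genes <- colnames(X)
    if (is.null(genes)) genes <- paste0("gene", seq_len(G))
    resolved <- ifelse(mg$p1 > mg$p0 + tieTol, "1",
                ifelse(mg$p0 > mg$p1 + tieTol, "0", "ambiguous"))
    for (g in seq_len(G))
        resolved[seq_len(n), g][is.na(X[, g])] <- "unknown"
    tab <- DataFrame(
        gene_id = rep(genes, each = N),
        node = rep(seq_len(N), G),
        node_id = rep(ids, G),
        state_set = NA_character_,
        p0 = as.vector(mg$p0),
        p1 = as.vector(mg$p1),
        resolved = as.vector(resolved))
    new("NodeStates", tree = tree, method = "mk", states = tab,
        tipStates = X, scores = numeric(),
        fit = if (is.null(fit))
            new("MkFit", gainRate = alpha, lossRate = beta,
                logLik = sum(mg$loglik), rootPrior = rootPrior,
                converged = NA, boundary = character(),
                bounds = c(NA_real_, NA_real_))
        else fit)
}

#' Exhaustive Mk likelihood oracle
#'
#' Brute-force likelihood by summing, over every assignment of 0/1 to the
#' internal nodes (and to missing tips), the product of branch transition
#' probabilities times the root prior. Exponential in tree size; an
#' independent reference for [mkLoglik()] on small trees.
#'
#' @inheritParams mkLoglik
#' @param tipStates named 0/1/NA vector over tips (single gene).
#' @return log-likelihood (numeric(1)).
#' @export
enumMkLikelihood <- function(tree, tipStates, alpha, beta,
                             rootPrior = "stationary", unitLengths = FALSE) {
    post <- enumMarginalPosteriors(tree, tipStates, alpha, beta,
                                   rootPrior, unitLengths)
    attr(post, "loglik")
}

#' Exhaustive marginal posterior oracle
#'
#' Same enumeration as [enumMkLikelihood()], additionally accumulating the
#' probability mass per node and state; posteriors are mass ratios. The
#' total log-likelihood is attached as attribute `"loglik"`.
#'
#' @inheritParams enumMkLikelihood
#' @return nodes-by-2 matrix of posteriors (columns `"0"`, `"1"`), with
#'   attribute `loglik`.
#' @export
enumMarginalPosteriors <- function(tree, tipStates, alpha, beta,
                                   rootPrior = "stationary",
                                   unitLengths = FALSE) {
    n <- ape::Ntip(tree)
    N <- n + tree$Nnode
    xv <- tipStates[match(tree$tip.label, names(tipStates))]
    et <- .edge_table(tree, unitLengths = unitLengths)
    P <- lapply(et$length, function(t) mkTransitionProb(alpha, beta, t))
    prior <- .root_prior(rootPrior, alpha, beta)
    free <- c(which(is.na(xv)), (n + 1L):N)
    fixed <- integer(N)
    fixed[seq_len(n)] <- ifelse(is.na(xv), 0L, as.integer(xv >= 1))
    mass <- matrix(0, N, 2L, dimnames = list(NULL, c("0", "1")))
    total <- 0
    root <- n + 1L
    for (mask in 0:(2^length(free) - 1L)) {
        lab <- fixed
        lab[free] <- bitwAnd(bitwShiftR(mask, seq_along(free) - 1L), 1L)
        w <- prior[lab[root] + 1L]
        for (r in seq_len(nrow(et$edge)))
            w <- w * P[[r]][lab[et$edge[r, 1L]] + 1L,
                            lab[et$edge[r, 2L]] + 1L]
        total <- total + w
        mass[cbind(seq_len(N), lab + 1L)] <-
            mass[cbind(seq_len(N), lab + 1L)] + w
    }
    post <- mass / total
    attr(post, "loglik") <- if (total > 0) log(total) else -Inf
    post
}
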