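test_that("transition probabilities follow the closed form", {
    expect_equal(mkTransitionProb(0.3, 0.7, 0), diag(2),
                 ignore_attr = TRUE)
    P <- mkTransitionProb(1, 1, 100)
    expect_true(all(abs(P - 0.5) < 1e-12))
    expect_equal(mkTransitionProb(1, 1, log(2) / 2)["0", "1"], 0.25)
    expect_error(mkTransitionProb(-1, 1, 1), "positive")
    expect_error(mkTransitionProb(1, 1, -0.1), ">= 0")
})

test_that("transition matrices are stochastic and satisfy the semigroup", {
    set.seed(3)
    for (i in 1:20) {
        a <- runif(1, 0.05, 2); b <- runif(1, 0.05, 2)
        t1 <- runif(1, 0, 3); t2 <- runif(1, 0, 3)
        P1 <- mkTransitionProb(a, b, t1)
        expect_equal(rowSums(P1), c("0" = 1, "1" = 1))
        expect_true(all(P1 >= 0 & P1 <= 1))
        expect_equal(P1 %*% mkTransitionProb(a, b, t2),
                     mkTransitionProb(a, b, t1 + t2), tolerance = 1e-10)
    }
})

test_that("pruning log-likelihood matches hand cases and flags impossibles", {
    tr <- parseNewick("(A:0,B:0);")
    expect_equal(mkLoglik(tr, tip_vec(tr, c(1, 1)), 0.3, 0.7,
                          rootPrior = "flat"), log(0.5))
    ll <- mkLoglik(tr, tip_vec(tr, c(1, 0)), 0.3, 0.7)
    expect_identical(unname(ll[1]), -Inf)
    expect_true(isTRUE(attr(ll, "impossible")))
    ## cladogram guard
    cl <- parseNewick("((A,B),(C,D));")
    expect_error(mkLoglik(cl, tip_vec(cl, c(1, 1, 0, 0)), 1, 1),
                 "cladogram")
    expect_silent(mkLoglik(cl, tip_vec(cl, c(1, 1, 0, 0)), 1, 1,
                           unitLengths = TRUE))
})

test_that("pruning equals brute-force enumeration on random trees", {
    set.seed(9)
    for (seed in 1:40) {
        cs <- random_case(seed + 100, max_tips = 6,
                          p_missing = if (seed %% 4 == 0) 0.3 else 0)
        a <- runif(1, 0.05, 2); b <- runif(1, 0.05, 2)
        prior <- if (seed %% 2) "stationary" else "flat"
        ll <- mkLoglik(cs$tree, cs$x, a, b, rootPrior = prior)
        bf <- enumMkLikelihood(cs$tree, cs$x, a, b, rootPrior = prior)
        expect_equal(unname(ll), bf, tolerance = 1e-10,
                     info = paste("seed", seed))
    }
})

test_that("likelihood is invariant to child order and tip relabeling", {
    tr <- parseNewick("((A:0.5,B:1.2):0.3,(C:0.8,D:0.4):0.6);")
    sw <- parseNewick("((C:0.8,D:0.4):0.6,(B:1.2,A:0.5):0.3);")
    x <- c(A = 1, B = 0, C = 1, D = 0)
    expect_equal(mkLoglik(tr, x, 0.4, 0.9), mkLoglik(sw, x, 0.4, 0.9))
    ## permuting tips with matching state permutation
    perm <- parseNewick("((D:0.5,C:1.2):0.3,(B:0.8,A:0.4):0.6);")
    xp <- c(D = 1, C = 0, B = 1, A = 0)
    expect_equal(mkLoglik(tr, x, 0.4, 0.9), mkLoglik(perm, xp, 0.4, 0.9))
})

test_that("marginal posteriors normalize, honor tips and match enumeration", {
    set.seed(5)
    for (seed in 1:15) {
        cs <- random_case(seed + 300, max_tips = 6,
                          p_missing = if (seed %% 3 == 0) 0.3 else 0)
        a <- runif(1, 0.05, 2); b <- runif(1, 0.05, 2)
        ns <- marginalAncestral(cs$tree, cs$x, alpha = a, beta = b)
        df <- as.data.frame(nodeStates(ns))
        expect_true(all(abs(df$p0 + df$p1 - 1) <= 1e-12))
        bf <- enumMarginalPosteriors(cs$tree, cs$x, a, b)
        expect_equal(df$p1, unname(bf[, "1"]), tolerance = 1e-9)
        tipdf <- df[df$node <= length(cs$x), ]
        obs <- cs$x[tipdf$node_id]
        seen <- !is.na(obs)
        expect_equal(tipdf$p1[seen], unname(obs[seen]))
    }
})

test_that("symmetric two-tip case gives a 50/50 root posterior", {
    tr <- parseNewick("(A:1,B:1);")
    ns <- marginalAncestral(tr, c(A = 1, B = 0), alpha = 0.6, beta = 0.6)
    df <- as.data.frame(nodeStates(ns))
    expect_equal(df$p0[df$node == 3], 0.5, tolerance = 1e-12)
    expect_equal(df$resolved[df$node == 3], "ambiguous")
})

test_that("all-present data push every node posterior toward presence", {
    tr <- simulateTree(6, seed = 2)
    x <- stats::setNames(rep(1, 6), tr$tip.label)
    ns <- marginalAncestral(tr, x, alpha = 0.3, beta = 0.6)
    df <- as.data.frame(nodeStates(ns))
    expect_true(all(df$p1 >= df$p0))
})

test_that("rate fitting recovers simulated rates and flags boundaries", {
    tr <- simulateTree(48, seed = 21)
    sim <- simulateGeneHistories(tr, 300, 0.1, 0.5, seed = 22)
    f <- fitMk(tr, sim$matrix)
    expect_true(f@converged)
    expect_lt(abs(gainRate(f) - 0.1) / 0.1, 0.25)
    expect_lt(abs(lossRate(f) - 0.5) / 0.5, 0.25)

    ## optimum beats a probed grid
    g <- expand.grid(a = c(0.05, 0.1, 0.3, 1), b = c(0.1, 0.5, 1, 2))
    X <- occurrenceCounts(sim$matrix)
    lls <- mapply(function(a, b) sum(mkLoglik(tr, sim$matrix, a, b)),
                  g$a, g$b)
    expect_true(all(f@logLik >= lls - 1e-6))

    ## all-constant data: loss rate at lower bound, flagged
    x1 <- matrix(1, 48, 3, dimnames = list(tr$tip.label, c("a", "b", "c")))
    expect_warning(f0 <- fitMk(tr, x1), "bound")
    expect_true(any(grepl("lossRate:lower", f0@boundary)))
})
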