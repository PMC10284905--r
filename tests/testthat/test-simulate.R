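test_that("Yule trees are deterministic, correctly sized and unit-height", {
    tr <- simulateTree(2, seed = 1)
    expect_equal(ape::Ntip(tr), 2L)        # single cherry
    expect_identical(writeNewick(simulateTree(16, seed = 9)),
                     writeNewick(simulateTree(16, seed = 9)))
    tr64 <- simulateTree(64, seed = 3)
    expect_equal(ape::Ntip(tr64), 64L)
    expect_equal(tr64$Nnode, 63L)
    expect_equal(length(unique(tr64$tip.label)), 64L)
    d <- ape::node.depth.edgelength(tr64)[1:64]
    expect_equal(mean(d), 1)
    expect_error(simulateTree(1), "nTips")
})

test_that("gene histories hit the stationary frequency on long branches", {
    ## star-like tree: one cherry stretched to very long branches
    tr <- simulateTree(24, seed = 5)
    tr$edge.length <- tr$edge.length * 50   # ~stationary at every tip
    sim <- simulateGeneHistories(tr, 1000, 1, 1, seed = 6)
    p <- mean(presenceMatrix(sim$matrix))
    se <- sqrt(0.25 / (1000 * 24))
    expect_lt(abs(p - 0.5), 3 * se + 0.02)  # allow tip correlation slack
})

test_that("degenerate rates and forced losses behave as constructed", {
    tr <- simulateTree(16, seed = 7)
    sim <- simulateGeneHistories(tr, 30, 1e-9, 1e-9, rootState = "present",
                                 seed = 8)
    expect_true(all(presenceMatrix(sim$matrix)))
    expect_equal(nrow(trueEvents(sim$truth)), 0L)

    ## forced loss at an internal branch: whole clade zero, absorbing
    tr2 <- simulateTree(32, seed = 9)
    internal <- (34:63)[vapply(34:63, function(v)
        length(gleam:::.descendants(tr2, v)), numeric(1)) >= 7][1]
    nid <- nodeIds(tr2)[internal]
    sim2 <- simulateGeneHistories(tr2, 25, 0.01, 0.01,
                                  rootState = "present",
                                  forcedLosses = nid, seed = 10)
    clade_tips <- intersect(gleam:::.descendants(tr2, internal), 1:32)
    tipm <- t(occurrenceCounts(sim2$matrix))
    expect_true(all(tipm[tr2$tip.label[clade_tips], ] == 0))
    ev <- as.data.frame(trueEvents(sim2$truth))
    expect_true(nid %in% ev$child_id)
    expect_error(simulateGeneHistories(tr2, 5, 0.1, 0.1,
                                       forcedLosses = "nope"),
                 "not in tree")
})

test_that("emitted matrix equals truth tip states wherever non-missing", {
    tr <- simulateTree(20, seed = 12)
    sim <- simulateGeneHistories(tr, 40, 0.3, 0.5, missingness = 0.15,
                                 seed = 13)
    tipm <- t(occurrenceCounts(sim$matrix))[tr$tip.label, ]
    truth_tips <- trueStates(sim$truth)[1:20, ]
    seen <- !is.na(tipm)
    expect_true(any(!seen))  # missingness actually applied
    expect_equal(unname(tipm[seen]), unname(truth_tips[seen]))
    ## determinism
    sim2 <- simulateGeneHistories(tr, 40, 0.3, 0.5, missingness = 0.15,
                                  seed = 13)
    expect_identical(occurrenceCounts(sim$matrix),
                     occurrenceCounts(sim2$matrix))
})

test_that("the fixture encodes the headline structure by construction", {
    fx <- makePaperFixture(seed = 42)
    tips <- sprintf("order%02d", 10:25)
    expect_equal(fx$mrcaNode, ape::getMRCA(fx$tree, tips))
    for (s in c("flagellum", "peptidoglycan")) {
        ev <- as.data.frame(trueEvents(fx$truths[[s]]))
        expect_equal(nrow(ev), 1L)
        expect_equal(ev$event_type, "loss")
        expect_equal(ev$child, fx$mrcaNode)
    }
    ## derived orders have zero presence for both sets
    pm <- presenceMatrix(fx$matrix)
    expect_true(all(!pm[, tips]))
    ## basal orders stay at >= 0.96 presence of the flagellar set
    frac <- presenceFraction(fx$matrix, setMembers(fx$catalog, "flagellum"),
                             sprintf("order%02d", 1:9))
    expect_true(all(frac >= 0.96))
    ## copy-number variation present but binarization-invariant
    expect_gte(max(occurrenceCounts(fx$matrix)), 2)

    ## three synteny clusters per motile genome, cluster 1 = fliC,fliD,fliS
    cl <- findClusters(fx$coords, setMembers(fx$catalog, "flagellum"))
    for (g in sprintf("order%02d", 1:9)) {
        sub <- cl[cl$genome == g, ]
        expect_equal(nrow(sub), 3L)
        expect_equal(sub$genes[sub$cluster_index == 1], "fliC,fliD,fliS")
    }
    ## the configured insertion is reported, and only there
    expect_equal(sum(cl$n_insertions), 1L)
    expect_equal(cl$genome[cl$n_insertions == 1], "order02")
})

test_that("fixture files round-trip through the readers", {
    fx <- makePaperFixture(seed = 2)
    dir <- withr::local_tempdir()
    writeFixture(fx, dir)
    expect_setequal(list.files(dir),
                    c("tree.nwk", "matrix.tsv", "gene_sets.tsv",
                      "coords.tsv", "truth.json"))
    tm <- readTraitMatrix(file.path(dir, "matrix.tsv"))
    expect_equal(occurrenceCounts(tm), occurrenceCounts(fx$matrix))
    tr <- parseNewick(file = file.path(dir, "tree.nwk"))
    expect_equal(sort(tr$tip.label), sort(fx$tree$tip.label))
    tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
    expect_equal(nrow(tj$events), 1L)
})
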