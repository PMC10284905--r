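## shared builders for small in-code fixtures

quartet <- function() parseNewick("((A,B),(C,D));")

tip_vec <- function(tree, vals) stats::setNames(vals, tree$tip.label)

## random rooted tree with random binary tip states (NA allowed)
random_case <- function(seed, max_tips = 7, p_missing = 0) {
    set.seed(seed)
    n <- sample(3:max_tips, 1)
    tr <- simulateTree(n, seed = seed + 10000)
    x <- sample(0:1, n, replace = TRUE)
    if (p_missing > 0) x[runif(n) < p_missing] <- NA
    if (all(is.na(x))) x[1] <- 1
    list(tree = tr, x = stats::setNames(x, tr$tip.label))
}

small_trait_matrix <- function() {
    m <- matrix(c(1, 1, 0, 0,
                  1, 0, 1, 0,
                  1, 1, 1, NA,
                  2, 0, NA, 1),
                nrow = 4, byrow = FALSE,
                dimnames = list(paste0("g", 1:4),
                                c("geneA", "geneB", "geneC", "geneD")))
    TraitMatrix(m)
}
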