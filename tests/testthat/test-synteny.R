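coord_tsv <- function(rows) {
    path <- withr::local_tempfile(fileext = ".tsv", .local_envir =
                                  parent.frame())
    writeLines(c("genome\tcontig\tgene\tstart\tend\tstrand", rows), path)
    path
}

test_that("coordinate TSV parses, validates and round-trips", {
    path <- coord_tsv(c("g1\tc1\tfliC\t100\t1100\t+",
                        "g1\tc1\tfliD\t1200\t2400\t+"))
    gr <- readCoordinates(path)
    expect_equal(length(gr), 2L)
    expect_equal(GenomicRanges::start(gr)[1], 100L)
    expect_equal(GenomicRanges::end(gr)[1], 1100L)
    out <- withr::local_tempfile(fileext = ".tsv")
    writeCoordinates(gr, out)
    expect_equal(readLines(out), readLines(path))

    bad <- coord_tsv("g1\tc1\tfliC\t1100\t100\t+")
    expect_error(readCoordinates(bad), "line\\(s\\): 2")
    bad2 <- coord_tsv("g1\tc1\tfliC\t100\t1100\t*")
    expect_error(readCoordinates(bad2), "strand")
})

test_that("GFF3 input yields 1-based inclusive records with gene ids", {
    path <- withr::local_tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "c1\tsrc\tgene\t100\t1100\t.\t+\t.\tID=fliC",
                 "c1\tsrc\tgene\t1200\t2400\t.\t-\t.\tID=fliD"), path)
    gr <- readCoordinates(path, genome = "g1")
    expect_equal(length(gr), 2L)
    expect_equal(GenomicRanges::start(gr), c(100L, 1200L))
    expect_equal(gr$gene_id, c("fliC", "fliD"))
    expect_equal(unique(gr$genome), "g1")
})

test_that("clusters split on intergenic gaps above maxGap", {
    goi <- c("fliC", "fliD", "fliS")
    path <- coord_tsv(c("g1\tc1\tfliC\t100\t1100\t+",
                        "g1\tc1\tfliD\t1200\t2400\t+",
                        "g1\tc1\tfliS\t2500\t3000\t+"))
    cl <- findClusters(readCoordinates(path), goi, maxGap = 5000)
    expect_equal(nrow(cl), 1L)
    expect_equal(cl$genes, "fliC,fliD,fliS")

    ## fliS on another contig -> clusters of sizes 2 and 1
    path2 <- coord_tsv(c("g1\tc1\tfliC\t100\t1100\t+",
                         "g1\tc1\tfliD\t1200\t2400\t+",
                         "g1\tc2\tfliS\t2500\t3000\t+"))
    cl2 <- findClusters(readCoordinates(path2), goi, maxGap = 5000)
    expect_equal(sort(cl2$n_genes), c(1L, 2L))
    expect_true(any(cl2$singleton))

    ## 6000 bp gap with maxGap 5000 -> split (fliC,fliD) | (fliS)
    path3 <- coord_tsv(c("g1\tc1\tfliC\t100\t1100\t+",
                         "g1\tc1\tfliD\t1200\t2400\t+",
                         "g1\tc1\tfliS\t8401\t9000\t+"))
    cl3 <- findClusters(readCoordinates(path3), goi, maxGap = 5000)
    expect_equal(cl3$genes, c("fliC,fliD", "fliS"))
    expect_error(findClusters(readCoordinates(path3), character()), "empty")
})

test_that("clusters partition the located genes and ignore row order", {
    set.seed(4)
    rows <- c("g1\tc1\tfliC\t100\t1100\t+",
              "g1\tc1\tfliD\t1200\t2400\t+",
              "g1\tc1\tfliS\t20000\t21000\t+",
              "g1\tc2\tfliM\t500\t900\t-",
              "g2\tc1\tfliC\t10\t900\t+")
    goi <- c("fliC", "fliD", "fliS", "fliM")
    cl_a <- findClusters(readCoordinates(coord_tsv(rows)), goi)
    cl_b <- findClusters(readCoordinates(coord_tsv(sample(rows))), goi)
    df_a <- as.data.frame(cl_a); df_b <- as.data.frame(cl_b)
    key <- function(d) d[order(d$genome, d$contig, d$span_start), ]
    expect_equal(key(df_a)$genes, key(df_b)$genes)
    ## every located gene in exactly one cluster
    genes_out <- unlist(strsplit(df_a$genes, ","))
    expect_equal(sort(genes_out), sort(c("fliC", "fliD", "fliS", "fliM",
                                         "fliC")))
})

test_that("increasing maxGap never increases the number of clusters", {
    set.seed(11)
    rows <- vapply(1:12, function(i) {
        st <- cumsum(sample(c(200, 3000, 12000), 12, replace = TRUE))[i]
        sprintf("g1\tc1\tgene%02d\t%d\t%d\t+", i, st, st + 500)
    }, character(1))
    gr <- readCoordinates(coord_tsv(rows))
    goi <- sprintf("gene%02d", 1:12)
    ns <- vapply(c(0, 1000, 5000, 15000, 1e6),
                 function(g) nrow(findClusters(gr, goi, maxGap = g)),
                 numeric(1))
    expect_true(all(diff(ns) <= 0))
})

test_that("overlapping genes always co-cluster", {
    path <- coord_tsv(c("g1\tc1\tfliC\t100\t1100\t+",
                        "g1\tc1\tfliD\t900\t1500\t+"))
    cl <- findClusters(readCoordinates(path), c("fliC", "fliD"), maxGap = 0)
    expect_equal(nrow(cl), 1L)
})

test_that("architecture comparison is strand-normalized and ordered", {
    a <- c("fliC", "fliD", "fliS")
    expect_equal(compareArchitecture(a, a), 1)
    ## reverse-complemented cluster (reversed order, minus strand)
    expect_equal(compareArchitecture(a, rev(a),
                                     strandA = rep("+", 3),
                                     strandB = rep("-", 3)), 1)
    ## same genes, different internal order: no shared ordered adjacency
    expect_equal(compareArchitecture(a, c("fliC", "fliS", "fliD")), 0)
    ## singleton conventions
    expect_equal(compareArchitecture("fliC", "fliC"), 1)
    expect_equal(compareArchitecture("fliC", "fliD"), 0)
    expect_equal(compareArchitecture("fliC", a), 0)
    ## works on findClusters rows too
    path <- coord_tsv(c("g1\tc1\tfliC\t100\t1100\t+",
                        "g1\tc1\tfliD\t1200\t2400\t+",
                        "g2\tc1\tfliD\t100\t1100\t-",
                        "g2\tc1\tfliC\t1200\t2400\t-"))
    cl <- findClusters(readCoordinates(path), c("fliC", "fliD"))
    expect_equal(compareArchitecture(cl[cl$genome == "g1", ],
                                     cl[cl$genome == "g2", ]), 1)
})
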