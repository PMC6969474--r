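writeToyFiles <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
    counts <- file.path(dir, "counts.tsv")
    map <- file.path(dir, "map.tsv")
    writeLines(c("gene_id\tS1\tS2",
                 "G1\t5\t0",
                 "G2\t1\t2",
                 "G3\t0\t7"), counts)
    writeLines(c("sample_id\tcondition", "S1\tctl", "S2\ttrt"), map)
    list(counts = counts, map = map, dir = dir)
}

test_that("count TSV parsing keeps cells and rejects malformed inputs", {
    f <- writeToyFiles()
    cm <- readCounts(f$counts, f$map)
    expect_s4_class(cm, "CountMatrix")
    expect_identical(unname(counts(cm)),
                     matrix(c(5L, 1L, 0L, 0L, 2L, 7L), nrow = 3))
    expect_identical(condition(cm), c(S1 = "ctl", S2 = "trt"))

    ## sample present in counts but absent from the map
    writeLines(c("sample_id\tcondition", "S1\tctl"), f$map)
    expect_error(readCounts(f$counts, f$map), "absent from")

    ## duplicated gene row
    writeLines(c("sample_id\tcondition", "S1\tctl", "S2\ttrt"), f$map)
    writeLines(c("gene_id\tS1\tS2", "G1\t5\t0", "G1\t1\t2"), f$counts)
    expect_error(readCounts(f$counts, f$map), "duplicated gene ID")

    ## fractional and negative counts
    writeLines(c("gene_id\tS1\tS2", "G1\t5.5\t0", "G2\t1\t2"), f$counts)
    expect_error(readCounts(f$counts, f$map), "integer")
    writeLines(c("gene_id\tS1\tS2", "G1\t-5\t0", "G2\t1\t2"), f$counts)
    expect_error(readCounts(f$counts, f$map), "non-negative")
})

test_that("write/read round-trips a count matrix exactly", {
    cm <- toyCounts()
    dir <- withr::local_tempdir()
    writeCounts(cm, file.path(dir, "c.tsv"), file.path(dir, "m.tsv"))
    back <- readCounts(file.path(dir, "c.tsv"), file.path(dir, "m.tsv"))
    expect_identical(counts(back), counts(cm))
    expect_identical(condition(back), condition(cm))
})

test_that("GMT parsing deduplicates members and flags short lines", {
    dir <- withr::local_tempdir()
    gmt <- file.path(dir, "sets.gmt")

    writeLines("SPERM\tdesc\tG1\tG2", gmt)
    gsc <- readGeneSets(gmt)
    expect_identical(geneSetMembers(gsc, "SPERM"), c("G1", "G2"))

    writeLines("SPERM\tdesc\tG1\tG1", gmt)
    expect_length(geneSetMembers(readGeneSets(gmt), "SPERM"), 1)

    writeLines("SPERM\tdesc", gmt)
    expect_error(readGeneSets(gmt), "fewer than 3")

    writeLines(character(), gmt)
    expect_length(geneSetNames(readGeneSets(gmt)), 0)

    ## round trip
    gsc <- makeGeneSetCollection(list(A = c("G1", "G2"), B = "G9"),
                                 c(A = "first", B = "second"))
    writeGeneSets(gsc, gmt)
    back <- readGeneSets(gmt)
    expect_identical(geneSetMembers(back, "A"), c("G1", "G2"))
    expect_identical(unname(geneSetDescriptions(back)["B"]), "second")
})

test_that("CPM normalization matches its defining formula", {
    m <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("G1", "G2"), "S1"))
    cm <- makeCountMatrix(m, "ctl")
    expect_equal(unname(cpmValues(cm)[, 1]), c(5e5, 5e5))

    ## scale invariance: doubling all counts in a sample leaves CPM unchanged
    cm2 <- makeCountMatrix(m * 2L, "ctl")
    expect_equal(cpmValues(cm2), cpmValues(cm))

    ## derived spot value: count 0, library 1e6, prior 0.5
    m3 <- matrix(c(0L, 1000000L), 2, 1,
                 dimnames = list(c("G1", "G2"), "S1"))
    cm3 <- makeCountMatrix(m3, "ctl")
    got <- exprs(cpmLog2(cm3, prior = 0.5))["G1", 1]
    expect_equal(got, log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
    expect_equal(got, -1.0000014, tolerance = 1e-6)

    ## zero library size
    m4 <- matrix(c(0L, 0L), 2, 1, dimnames = list(c("G1", "G2"), "S1"))
    expect_error(cpmLog2(makeCountMatrix(m4, "ctl")), "library size")
})

test_that("log2-CPM is monotone in count within a sample", {
    set.seed(1)
    m <- matrix(sample.int(1000, 40), 20, 2,
                dimnames = list(sprintf("G%02d", 1:20), c("S1", "S2")))
    e <- exprs(cpmLog2(makeCountMatrix(m, c("a", "b"))))
    for (j in 1:2) {
        o <- order(m[, j])
        expect_true(all(diff(e[o, j]) >= 0))
    }
})

test_that("low-expression filter applies the CPM rule and keeps order", {
    m <- matrix(0L, 3, 2, dimnames = list(paste0("G", 1:3), c("S1", "S2")))
    m[2, ] <- c(2L, 0L)
    m[3, ] <- c(999998L, 1000000L)    # fills both libraries to 1e6
    cm <- makeCountMatrix(m, c("a", "b"))

    ## gene G2 has CPM 2 > 1 in one sample -> kept at minSamples = 1
    kept <- filterLowExpression(cm, minCpm = 1, minSamples = 1)
    expect_identical(rownames(kept), c("G2", "G3"))

    ## all-zero gene is removed even at the laxest nonzero setting
    expect_false("G1" %in% rownames(kept))

    ## minSamples = 0 is the identity
    expect_identical(rownames(filterLowExpression(cm, minSamples = 0)),
                     rownames(cm))
    expect_error(filterLowExpression(cm, minSamples = 5), "exceeds")
})

test_that("gene-set subsetting preserves order and reports absentees", {
    e <- makeExpressionMatrix(
        matrix(rnorm(12), 4, 3,
               dimnames = list(paste0("G", 1:4), paste0("S", 1:3))),
        c("a", "a", "b"))
    expect_identical(rownames(subsetToGeneSet(e, paste0("G", 4:1))),
                     paste0("G", 1:4))

    expect_message(out <- subsetToGeneSet(e, c("G2", "GX")), "absent")
    expect_identical(rownames(out), "G2")
    expect_identical(S4Vectors::metadata(out)$absentGenes, "GX")

    expect_error(subsetToGeneSet(e, c("GX", "GY")), "no gene")
})
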