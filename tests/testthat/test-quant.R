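test_that("extractSpacer finds anchored spacers and rejects broken reads", {
    sp <- "ACGTTGCAACGTTGCAACGT"
    good <- paste0("NNNN", "CCTTGTTTG", sp, "GTTTTAGAGCTA", "NN")
    noAnchor <- paste0("AAAA", sp, "GTTTTAGAGCTA")
    truncated <- paste0("CCTTGTTTG", substr(sp, 1, 10))
    noDown <- paste0("CCTTGTTTG", sp, "AAAAAA")
    got <- extractSpacer(c(good, noAnchor, truncated, noDown))
    expect_identical(got, c(sp, NA, NA, NA))

    # mismatched upstream anchor is rescued only when allowed
    fuzzy <- paste0("CCTTGTTAG", sp, "GTTTTA")
    expect_identical(extractSpacer(fuzzy), NA_character_)
    expect_identical(
        extractSpacer(fuzzy, extractionPolicy(anchorMismatches = 1L)), sp)
})

test_that("count assignment is exact-first with unique 1-mismatch rescue", {
    # two library spacers at Hamming distance 2; a read spacer at distance
    # 1 from both must stay unmapped (ambiguity rule)
    s1 <- "AAAACCCCGGGGTTTTAAAA"
    s2 <- "CAAACCCCGGGGTTTTAAAC"
    amb <- "CAAACCCCGGGGTTTTAAAA"   # 1 from s1 (pos 1), 1 from s2 (pos 20)
    resc <- "AAAACCCCGGGGTTTTAAAG"  # 1 from s1 (pos 20), 2 from s2
    guides <- S4Vectors::DataFrame(
        guide_id = c("g1", "g2"), gene_symbol = c("A", "B"),
        spacer = c(s1, s2), is_control = c(FALSE, FALSE))
    lib <- new("GuideLibrary", guides = guides, guidesPerGene = 1L,
        name = "tiny")
    mkRead <- function(s) paste0("CCTTGTTTG", s, "GTTTTA")
    res <- countSample(c(mkRead(s1), mkRead(amb), mkRead(resc)), lib)
    expect_equal(unname(guideCounts(res)), c(2L, 0L))  # s1 exact + rescue
    expect_equal(nUnmapped(res), 1L)                   # ambiguous read
    expect_equal(nTotalReads(res), 3L)

    res0 <- countSample(c(mkRead(s1), mkRead(resc)), lib,
        extractionPolicy(spacerMismatches = 0L))
    expect_equal(unname(guideCounts(res0)), c(1L, 0L))
})

test_that("empty FASTQ gives zero counts and the accounting identity holds", {
    lib <- makeSmallLib(nGenes = 5, guidesPerGene = 2, nControls = 0)
    f <- withr::local_tempfile(fileext = ".fastq")
    writeLines(character(0), f)
    res <- countSample(f, lib)
    expect_equal(sum(guideCounts(res)), 0L)
    expect_equal(nTotalReads(res), 0L)

    counts <- structure(rep(20L, nGuides(lib)), names = guideIds(lib))
    emitFastq(counts, lib, f, errorRate = 0.02, seed = 2)
    res <- countSample(f, lib)
    expect_equal(sum(guideCounts(res)) + nUnmapped(res), nTotalReads(res))
    expect_equal(nTotalReads(res), 200L)
})

test_that("1-mismatch rescue is monotone in recovered reads", {
    lib <- makeSmallLib(nGenes = 20, guidesPerGene = 4, nControls = 0)
    counts <- structure(rep(30L, nGuides(lib)), names = guideIds(lib))
    f <- withr::local_tempfile(fileext = ".fastq.gz")
    emitFastq(counts, lib, f, errorRate = 0.01, seed = 3)
    r0 <- countSample(f, lib, extractionPolicy(spacerMismatches = 0L))
    r1 <- countSample(f, lib, extractionPolicy(spacerMismatches = 1L))
    expect_gte(sum(guideCounts(r1)), sum(guideCounts(r0)))
})

test_that("emitFastq validates inputs and conserves record counts", {
    lib <- makeSmallLib(nGenes = 4, guidesPerGene = 2, nControls = 0)
    counts <- structure(c(3L, rep(0L, 7L)), names = guideIds(lib))
    f <- withr::local_tempfile(fileext = ".fastq")
    emitFastq(counts, lib, f, errorRate = 0, seed = 1)
    lines <- readLines(f)
    expect_length(lines, 12L)  # 3 reads x 4 lines
    cassette <- toupper(assembleArrayOligo(spacers(lib)[1]))
    expect_true(all(grepl(cassette, lines[c(2, 6, 10)], fixed = TRUE)))
    expect_error(emitFastq(counts, lib, f, readLength = 50), "cassette")
})

test_that("CPM normalisation scales to a million and inverts", {
    m <- matrix(c(1, 1, 2), ncol = 1, dimnames = list(NULL, "s1"))
    expect_equal(unname(cpmNormalize(m)[, 1]), c(250000, 250000, 500000))

    m2 <- matrix(rpois(40, 50) + 1, ncol = 4,
        dimnames = list(NULL, paste0("s", 1:4)))
    cpm <- cpmNormalize(m2)
    expect_equal(unname(colSums(cpm)), rep(1e6, 4))
    back <- sweep(cpm, 2, colSums(m2), "*") / 1e6
    expect_equal(unname(back), unname(m2))
    # scale invariance: uniform counts give uniform CPM at any depth
    u <- cbind(rep(5, 10), rep(500, 10))
    colnames(u) <- c("lo", "hi")
    expect_true(all(cpmNormalize(u) == 1e5))

    bad <- cbind(s1 = c(1, 2), empty = c(0, 0))
    expect_error(cpmNormalize(bad), "empty")
})

test_that("median-of-controls normalisation anchors to control guides", {
    lib <- makeSmallLib(nGenes = 4, guidesPerGene = 2, nControls = 4)
    m <- matrix(10, nGuides(lib), 2,
        dimnames = list(guideIds(lib), c("a", "b")))
    m[isControl(lib), 2] <- 20
    norm <- cpmNormalize(m, method = "medianControls", lib = lib)
    expect_equal(unname(norm[1, ]), c(1, 0.5))
    expect_true(all(norm[isControl(lib), ] == 1))
})
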