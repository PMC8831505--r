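test_that("buildLibrary produces the requested design", {
    lib <- buildLibrary(sprintf("PID%02d", 1:80), guidesPerGene = 5,
        nControls = 0, seed = 1)
    expect_s4_class(lib, "GuideLibrary")
    expect_equal(nGuides(lib), 400L)
    expect_equal(guidesPerGene(lib), 5L)

    lib1 <- buildLibrary("OnlyGene", guidesPerGene = 1, nControls = 0, seed = 1)
    expect_equal(nGuides(lib1), 1L)

    libc <- buildLibrary(c("A", "B"), 3, nControls = 5, seed = 2)
    expect_equal(sum(isControl(libc)), 5L)
    expect_setequal(unique(geneSymbols(libc)[isControl(libc)]), "CTRL")
})

test_that("buildLibrary validates its inputs", {
    expect_error(buildLibrary(c("A", "A"), 4), "duplicate")
    expect_error(buildLibrary(character(0), 4), "non-empty")
    expect_error(buildLibrary(c("A", "CTRL"), 4), "reserved")
})

test_that("spacer generation is deterministic, unique and homopolymer-free", {
    a <- buildLibrary(sprintf("G%03d", 1:50), 4, 20, seed = 7)
    b <- buildLibrary(sprintf("G%03d", 1:50), 4, 20, seed = 7)
    expect_identical(spacers(a), spacers(b))
    expect_false(anyDuplicated(spacers(a)) > 0)
    expect_false(any(grepl("A{6,}|C{6,}|G{6,}|T{6,}", spacers(a))))
    expect_true(all(nchar(spacers(a)) == 20L))

    c <- buildLibrary(sprintf("G%03d", 1:50), 4, 20, seed = 8)
    expect_length(intersect(spacers(a), spacers(c)), 0)
})

test_that("oligo assembly concatenates the exact cloning flanks", {
    sp <- "ACGTACGTACGTACGTACGT"
    expect_identical(assembleArrayOligo(sp),
        paste0("ggagaaaagccttgtttg", sp, "gttttagagctaggatcctagc"))
    expect_identical(assemblePoolOligo("AAAAAAAAAAAAAAAAAAAA"),
        "caattggagaaaagccttgtttgAAAAAAAAAAAAAAAAAAAAgttttagagctaggatcctagcaagtt")

    lib <- makeSmallLib()
    arr <- assembleArrayOligo(spacers(lib))
    pool <- assemblePoolOligo(spacers(lib))
    expect_true(all(nchar(arr) == 60L))
    expect_true(all(nchar(pool) == 70L))
    # pooled flanks extend the array flanks
    expect_true(all(mapply(grepl, arr, pool, fixed = TRUE)))
    # injective in the spacer
    expect_false(anyDuplicated(arr) > 0)
    # removing the spacer recovers the two flanks
    expect_identical(sub(spacers(lib)[1], "", arr[1]),
        paste0("ggagaaaagccttgtttg", "gttttagagctaggatcctagc"))
    expect_error(assembleArrayOligo("ACGT"), "20 nt")
    expect_error(assemblePoolOligo("ACGTACGTACGTACGTACGN"), "20 nt")
})

test_that("library CSV and FASTA round-trip losslessly", {
    lib <- makeSmallLib(nGenes = 12, guidesPerGene = 5, nControls = 6)
    csv <- withr::local_tempfile(fileext = ".csv")
    fa <- withr::local_tempfile(fileext = ".fasta")
    writeGuideLibrary(lib, csv, fastaPath = fa)
    back <- readGuideLibrary(csv, name = libraryName(lib))
    expect_identical(guideIds(back), guideIds(lib))
    expect_identical(unname(spacers(back)), unname(spacers(lib)))
    expect_identical(geneSymbols(back), geneSymbols(lib))
    expect_identical(isControl(back), isControl(lib))
    expect_equal(guidesPerGene(back), guidesPerGene(lib))

    fasta <- Biostrings::readDNAStringSet(fa)
    expect_length(fasta, nGuides(lib))
    expect_identical(unname(as.character(fasta)), unname(spacers(lib)))
    expect_identical(names(fasta), guideIds(lib))
})

test_that("malformed library CSVs are rejected with the row number", {
    lib <- makeSmallLib(nGenes = 3, guidesPerGene = 2, nControls = 0)
    df <- as.data.frame(lib@guides)
    df$spacer[4] <- substr(df$spacer[4], 1, 19)  # 19-nt spacer
    csv <- withr::local_tempfile(fileext = ".csv")
    write.csv(df, csv, row.names = FALSE, quote = FALSE)
    expect_error(readGuideLibrary(csv), "row.*4")

    df2 <- as.data.frame(lib@guides)
    df2$guide_id[5] <- df2$guide_id[1]
    write.csv(df2, csv, row.names = FALSE, quote = FALSE)
    expect_error(readGuideLibrary(csv), "duplicate guide_id")
})

test_that("control guides group into pseudo-genes of guidesPerGene size", {
    lib <- makeSmallLib(nGenes = 5, guidesPerGene = 4, nControls = 10)
    pg <- controlPseudoGenes(lib)
    expect_length(pg, 10)
    expect_equal(as.vector(table(pg)), c(4L, 4L, 2L))
    expect_equal(nlevels(pg), 3L)  # ceiling(10 / 4)
})
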