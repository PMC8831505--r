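test_that("plasmid pool abundances are normalised and match sigma", {
    lib <- makeSmallLib(nGenes = 100, guidesPerGene = 4, nControls = 0)
    cfg0 <- screenConfig(plasmidSigma = 0)
    expect_equal(unname(samplePlasmidPool(lib, cfg0)),
        rep(1 / 400, 400))

    cfg <- screenConfig(plasmidSigma = 0.5)
    a <- samplePlasmidPool(lib, cfg, seed = 5)
    expect_equal(sum(a), 1)
    expect_true(all(a > 0))
    expect_identical(a, samplePlasmidPool(lib, cfg, seed = 5))
    # moment check on the log scale at n = 400
    expect_equal(sd(log(a)), 0.5, tolerance = 0.12)
})

test_that("culture growth follows guide fitness", {
    lib <- makeSmallLib(nGenes = 20, guidesPerGene = 4, nControls = 0)
    cfg <- screenConfig(cultureStartCells = 4e5, cultureDoublings = 6,
        plasmidSigma = 0)
    ab <- samplePlasmidPool(lib, cfg)

    # neutral growth preserves relative abundance in expectation
    tr0 <- screenTruth(lib)
    cc <- simulateCulture(ab, tr0, lib, cfg, seed = 1)
    expect_equal(cc / sum(cc), ab, tolerance = 0.05)

    # fitness -1 stalls growth: expectation equals starting cells
    trStall <- screenTruth(lib, invitroFitness = c(G001 = -1))
    reps <- vapply(1:50, function(s)
        simulateCulture(ab, trStall, lib, cfg, seed = s)[1], numeric(1))
    start <- cfg@cultureStartCells * ab[[1]]
    expect_equal(mean(reps), start, tolerance = 0.05)

    # fitness -0.5 over 6 doublings: culture-vs-plasmid L2FC of -3
    trHalf <- screenTruth(lib, invitroFitness = c(G001 = -0.5))
    l2fc <- vapply(1:40, function(s) {
        cc <- simulateCulture(ab, trHalf, lib, cfg, seed = s)
        log2((cc[1] / sum(cc)) / ab[[1]])
    }, numeric(1))
    expect_equal(mean(l2fc), -3, tolerance = 0.1)
})

test_that("the transfer bottleneck thins cells at the engraftment rate", {
    lib <- buildLibrary("A", 1, 0, seed = 1)
    cfg <- screenConfig(transferPoolSize = 1000, engraftmentRate = 0.10,
        invivoDoublings = 0, sortCoverage = 10)
    eng <- vapply(1:300, function(s)
        sum(simulateMouse(c(A_sg1 = 2000), screenTruth(lib), lib, cfg,
            seed = s, returnStages = TRUE)$engrafted), numeric(1))
    expect_equal(mean(eng), 100, tolerance = 0.05)
})

test_that("simulateMouse conserves cells at every thinning stage", {
    lib <- makeSmallLib(nGenes = 15, guidesPerGene = 4, nControls = 4)
    cfg <- fastConfig()
    cc <- simulateCulture(samplePlasmidPool(lib, cfg, seed = 3),
        screenTruth(lib), lib, cfg, seed = 3)
    st <- simulateMouse(cc, screenTruth(lib), lib, cfg, seed = 4,
        returnStages = TRUE)
    expect_equal(sum(st$transferred), cfg@transferPoolSize)
    expect_true(all(st$engrafted <= st$transferred))
    expect_equal(sum(st$cells), sum(st$expanded))
    expect_true(all(colSums(st$sorted) <=
        pmin(colSums(st$cells), cfg@sortCoverage * nGuides(lib))))
    expect_error(simulateMouse(cc * 0 + 1, screenTruth(lib), lib, cfg),
        "smaller than transferPoolSize")
})

test_that("an impossible Tfh fate leaves only purity leakage in Tfh gates", {
    lib <- makeSmallLib(nGenes = 10, guidesPerGene = 4, nControls = 0)
    cfg <- fastConfig(sortPurity = 1)
    tr <- screenTruth(lib, tfhLogitShift = c(G001 = -Inf))
    cc <- simulateCulture(samplePlasmidPool(lib, cfg, seed = 2),
        screenTruth(lib), lib, cfg, seed = 2)
    st <- simulateMouse(cc, tr, lib, cfg, seed = 5, returnStages = TRUE)
    tgt <- geneSymbols(lib) == "G001"
    expect_true(all(st$cells[tgt, c("preTfh", "GCTfh")] == 0))
    expect_true(all(st$sorted[tgt, c("preTfh", "GCTfh")] == 0))
    expect_true(sum(st$sorted[tgt, "Th1"]) > 0)

    # with imperfect purity the Tfh gates may pick up leaked Th1 cells,
    # never more than the impurity share allows in expectation
    cfgImp <- fastConfig(sortPurity = 0.95)
    stImp <- simulateMouse(cc, tr, lib, cfgImp, seed = 5, returnStages = TRUE)
    leak <- sum(stImp$sorted[tgt, c("preTfh", "GCTfh")])
    sortedTfh <- sum(colSums(stImp$sorted)[c("preTfh", "GCTfh")])
    expect_lt(leak / sortedTfh, 0.05 * 2)
})

test_that("sequencing draws conserve depth and respect PCR dispersion", {
    cfg <- screenConfig(seqDepth = 100)
    x <- c(a = 0, b = 500, c = 0)
    col <- simulateSequencing(x, cfg, seed = 1)
    expect_equal(sum(col), 300)
    expect_equal(unname(col[c("a", "c")]), c(0, 0))  # degenerate multinomial

    expect_warning(z <- simulateSequencing(c(0, 0), cfg), "all-zero")
    expect_equal(unname(z), c(0L, 0L))

    # read fractions converge to cell fractions as pcr_shape grows
    cells <- c(200, 400, 400)
    fracVar <- vapply(c(2, 2000), function(shape) {
        cfgS <- screenConfig(seqDepth = 2000, pcrShape = shape)
        reps <- vapply(1:40, function(s)
            simulateSequencing(cells, cfgS, seed = s)[1] / 6000, numeric(1))
        var(reps)
    }, numeric(1))
    expect_lt(fracVar[2], fracVar[1])
})

test_that("simulateScreen emits the full sample design deterministically", {
    lib <- makeSmallLib(nGenes = 8, guidesPerGene = 4, nControls = 4)
    cfg <- fastConfig(nMice = 5L, nExperiments = 2L, seed = 21L)
    sc <- simulateScreen(lib, config = cfg)
    # 1 plasmid + 1 culture/experiment + 3 populations per mouse
    expect_equal(ncol(sc), 1L + 2L + 2L * 5L * 3L)
    cd <- SummarizedExperiment::colData(sc)
    expect_equal(sum(cd$population == "plasmid"), 1L)
    expect_equal(sum(cd$population == "culture"), 2L)
    expect_setequal(unique(cd$day[cd$population == "Th1"]), c(6L, 7L))

    sc2 <- simulateScreen(lib, config = cfg)
    expect_identical(SummarizedExperiment::assay(sc, "counts"),
        SummarizedExperiment::assay(sc2, "counts"))

    # pooled sorts: one sample per population per (experiment, day)
    cfgP <- fastConfig(nMice = 4L, nExperiments = 2L, pooledSort = TRUE,
        seed = 22L)
    scP <- simulateScreen(lib, config = cfgP)
    expect_equal(ncol(scP), 1L + 2L + 2L * 2L * 3L)
    expect_true(all(is.na(SummarizedExperiment::colData(scP)$mouse[
        SummarizedExperiment::colData(scP)$population %in%
            c("Th1", "preTfh", "GCTfh")])))
})

test_that("a neutral screen centres gene-level Tfh-vs-Th1 L2FC at zero", {
    lib <- makeSmallLib(nGenes = 20, guidesPerGene = 4, nControls = 8)
    means <- vapply(1:8, function(r) {
        cfg <- fastConfig(seed = 300L + r, nMice = 2L, nExperiments = 1L)
        sc <- simulateScreen(lib, config = cfg)
        gs <- geneSummary(overallMean(compareScreen(sc, "Tfh_vs_Th1")), lib)
        mean(gs$mean_l2fc[!gs$is_control])
    }, numeric(1))
    sem <- sd(means) / sqrt(length(means))
    expect_lt(abs(mean(means)), 3 * sem + 0.05)
})

test_that("spike-in cohorts mix the target gene at the requested frequency", {
    lib <- makeSmallLib(nGenes = 10, guidesPerGene = 4, nControls = 4)
    cfg <- fastConfig(nMice = 2L)
    # frequency 1: single-gene screen, all transferred cells are target
    coh <- spikeInCohort(lib, "G001", 1, -2, cfg, seed = 9)
    m <- SummarizedExperiment::assay(coh, "counts")
    tgt <- geneSymbols(lib) == "G001"
    expect_true(all(colSums(m[!tgt, ]) == 0))

    # effect 0: spiked Tfh share matches background in expectation
    l2fc <- vapply(1:12, function(s) {
        coh <- spikeInCohort(lib, "G001", 0.05, 0, cfg, seed = 400L + s)
        gs <- geneSummary(overallMean(compareScreen(coh, "Tfh_vs_Th1")), lib)
        gs$mean_l2fc[gs$gene == "G001"]
    }, numeric(1))
    expect_lt(abs(mean(l2fc)), 3 * sd(l2fc) / sqrt(length(l2fc)) + 0.05)

    expect_error(spikeInCohort(lib, "G001", 0, -2, cfg), "spikeFrequency")
    expect_error(spikeInCohort(lib, "nope", 0.1, -2, cfg), "not in library")
})
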