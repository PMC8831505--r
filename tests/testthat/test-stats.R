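test_that("guide L2FC follows the pseudocounted log ratio", {
    expect_equal(guideL2FC(100, 100, 0.5), 0)
    expect_equal(guideL2FC(200, 100, 0), 1)
    expect_equal(guideL2FC(0, 1000, 0.5), log2(0.5 / 1000.5))
    expect_equal(guideL2FC(c(200, 50), c(100, 100), 0), c(1, -1))
    expect_error(guideL2FC(0, 0, 0), "undefined")
    expect_error(guideL2FC(-1, 2), "non-negative")
})

test_that("hierarchical averaging weights experiments equally", {
    h <- hierarchicalAverage(c(1, 3, 5), experiment = c(1, 1, 2),
        mouse = c(1, 2, 1))
    expect_equal(h$overall, 3.5)  # not the pooled mean 3
    expect_equal(unname(h$experimentMeans), c(2, 5))

    expect_equal(hierarchicalAverage(7, 1, 1)$overall, 7)
    h2 <- hierarchicalAverage(rep(2, 6), rep(1:2, each = 3), rep(1:3, 2))
    expect_equal(h2$overall, 2)
    expect_true(all(h2$mouseMeans$mean == 2))
    expect_error(hierarchicalAverage(NA_real_, 1, 1), "missing")
})

test_that("hierarchical averaging matches the brute-force nested oracle", {
    set.seed(42)
    for (i in 1:200) {
        nExp <- sample(1:4, 1)
        experiment <- integer(0); mouse <- integer(0)
        for (e in seq_len(nExp)) {
            nM <- sample(1:5, 1)
            for (m in seq_len(nM)) {
                nV <- sample(1:3, 1)
                experiment <- c(experiment, rep(e, nV))
                mouse <- c(mouse, rep(m, nV))
            }
        }
        values <- rnorm(length(experiment))
        expect_equal(hierarchicalAverage(values, experiment, mouse)$overall,
            bruteHierarchical(values, experiment, mouse))
    }
})

test_that("gene summaries use the n-1 SEM and drop flagged guides", {
    lib <- makeSmallLib(nGenes = 2, guidesPerGene = 3, nControls = 0)
    v <- structure(c(1, 2, 3, 5, 5, NA), names = guideIds(lib))
    gs <- geneSummary(v, lib)
    expect_equal(gs$mean_l2fc[gs$gene == "G001"], 2)
    expect_equal(gs$sem_l2fc[gs$gene == "G001"], sd(1:3) / sqrt(3))
    # flagged guide excluded: G002 has two usable guides, zero variance
    expect_equal(gs$n_guides[gs$gene == "G002"], 2L)
    expect_equal(gs$sem_l2fc[gs$gene == "G002"], 0)

    lib1 <- buildLibrary("X", 1, 0, seed = 3)
    gs1 <- geneSummary(structure(4, names = guideIds(lib1)), lib1)
    expect_equal(gs1$mean_l2fc, 4)
    expect_true(is.na(gs1$sem_l2fc))  # SEM absent for single-guide genes
})

test_that("control-anchored z-scores centre and scale correctly", {
    ctrl <- c(-1, 0, 1)
    expect_equal(unname(controlZscore(c(g = 0), ctrl)), 0)
    expect_equal(unname(controlZscore(c(g = 2), ctrl)), 2)
    # affine shift invariance
    z1 <- controlZscore(c(a = 1.2, b = -0.4), ctrl)
    z2 <- controlZscore(c(a = 1.2, b = -0.4) + 3, ctrl + 3)
    expect_equal(z1, z2)
    expect_error(controlZscore(1, c(2, 2)), "zero")
    expect_error(controlZscore(1, 2), "at least 2")
    # leave-nothing-out convention: controls standardise to mean 0, sd 1
    zc <- controlZscore(structure(ctrl, names = letters[1:3]), ctrl)
    expect_equal(mean(zc), 0)
    expect_equal(sd(zc), 1)
})

test_that("alpha-RRA scores reward concentrated top ranks", {
    # all guides of a gene at the very top: smallest possible score
    uTop <- c(1, 2, 3) / 100
    uMid <- c(20, 40, 60) / 100
    expect_lt(rraScore(uTop, 0.25), rraScore(uMid, 0.25))
    expect_equal(rraScore(c(0.5, 0.8), alpha = 0.25), 1)  # nothing in top alpha
    expect_gte(rraScore(uTop, 0.25), 0)
    expect_lte(rraScore(uMid, 0.25), 1)
})

test_that("rraGeneTest ranks a planted depleted gene first", {
    lib <- makeSmallLib(nGenes = 15, guidesPerGene = 4, nControls = 12)
    set.seed(7)
    v <- structure(rnorm(nGuides(lib), 0, 0.3), names = guideIds(lib))
    v[geneSymbols(lib) == "G005"] <- c(-3, -2.5, -2.8, -2.2)
    res <- rraGeneTest(v, lib, direction = "depleted", nPerm = 2000, seed = 1)
    expect_equal(res$gene[which.min(res$rra_score)], "G005")
    # permutation granularity can tie several genes at the p floor
    expect_equal(res$p_value[res$gene == "G005"], min(res$p_value))
    expect_true(all(res$fdr >= res$p_value - 1e-12))
    # BH FDR is monotone along the p-value ranking
    o <- order(res$p_value)
    expect_true(all(diff(cummin(rev(res$fdr[o]))) <= 0))
    # enriched direction finds enrichment instead
    v2 <- -v
    res2 <- rraGeneTest(v2, lib, direction = "enriched", nPerm = 2000, seed = 1)
    expect_equal(res2$p_value[res2$gene == "G005"], min(res2$p_value))
})

test_that("rraGeneTest falls back to all guides without enough controls", {
    lib <- makeSmallLib(nGenes = 6, guidesPerGene = 4, nControls = 0)
    v <- structure(rnorm(nGuides(lib)), names = guideIds(lib))
    expect_warning(res <- rraGeneTest(v, lib, nPerm = 500, seed = 1),
        "fewer control guides")
    expect_equal(nrow(res), 6L)
})

test_that("quadrant classification matches its definition", {
    tfh <- c(A = -3, B = -2, C = 0, D = 2, E = 0.5)
    th1 <- c(A = -3, B = 0.2, C = -2, D = 2, E = -0.5)
    cat <- classifyHits(tfh, th1, -1, 1)
    expect_equal(as.character(cat[c("A", "B", "C", "D", "E")]),
        c("required_for_expansion", "required_for_Tfh", "required_for_Th1",
            "inhibits_expansion", "neutral"))
    expect_equal(as.character(classifyHits(c(X = 0), c(X = 0))), "neutral")
    expect_error(classifyHits(tfh, th1[c(2, 1, 3, 4, 5)]), "same gene set")
    expect_error(classifyHits(tfh, th1, depletionThreshold = 1), "negative")
})

test_that("compareScreen reproduces the nested hierarchy exactly", {
    lib <- makeSmallLib(nGenes = 8, guidesPerGene = 3, nControls = 6)
    sc <- simulateScreen(lib, config = fastConfig(seed = 33L))
    cmp <- compareScreen(sc, "Tfh_vs_Th1")
    reps <- replicateValues(cmp)
    ov <- overallMean(cmp)
    for (g in sample(guideIds(lib), 5)) {
        sub <- reps[reps$guide_id == g & !is.na(reps$value), ]
        expect_equal(unname(ov[g]),
            bruteHierarchical(sub$value, sub$experiment, sub$mouse))
    }
    # culture-vs-plasmid has one replicate per experiment
    cvp <- compareScreen(sc, "culture_vs_plasmid")
    expect_equal(nrow(unique(replicateValues(cvp)[, c("experiment", "mouse")])),
        2L)
    # Tfh aggregates the two Tfh sort gates: per-replicate values differ
    # from preTfh alone
    pre <- compareScreen(sc, "preTfh_vs_Th1")
    expect_false(isTRUE(all.equal(overallMean(pre), overallMean(cmp))))
})

test_that("screenResults assembles a coherent gene table", {
    lib <- makeSmallLib(nGenes = 10, guidesPerGene = 4, nControls = 8)
    tr <- screenTruth(lib, tfhLogitShift = c(G001 = -2))
    sc <- simulateScreen(lib, tr, fastConfig(seed = 55L))
    res <- screenResults(sc, "Tfh_vs_Th1", nPerm = 1000, seed = 2)
    expect_setequal(
        c("gene", "is_control", "n_guides", "mean_l2fc", "sem_l2fc",
            "zscore", "rra_score", "p_value", "fdr"),
        colnames(res))
    expect_equal(res$gene[which.min(res$mean_l2fc)], "G001")
    expect_lt(res$fdr[res$gene == "G001"], 0.25)
    # control pseudo-gene z-scores standardise to mean 0, sd 1
    zc <- res$zscore[res$is_control]
    expect_equal(mean(zc), 0, tolerance = 1e-10)
    expect_equal(sd(zc), 1, tolerance = 1e-10)
})
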