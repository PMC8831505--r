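# Shared fixtures: everything is generated in code, no stored data.

makeSmallLib <- function(nGenes = 10, guidesPerGene = 4, nControls = 8,
        seed = 101) {
    buildLibrary(sprintf("G%03d", seq_len(nGenes)), guidesPerGene,
        nControls, seed = seed, name = "test")
}

# Desk-scale simulator settings: small pools, shallow sequencing.
fastConfig <- function(...) {
    defaults <- list(transferPoolSize = 2e4, cultureStartCells = 5e3,
        sortCoverage = 200, seqDepth = 100, nMice = 3L,
        nExperiments = 2L, seed = 11L)
    do.call(screenConfig, utils::modifyList(defaults, list(...)))
}

# Independent oracle for the replicate hierarchy: explicit nested loops.
bruteHierarchical <- function(values, experiment, mouse) {
    expMeans <- c()
    for (e in unique(experiment)) {
        mMeans <- c()
        for (m in unique(mouse[experiment == e])) {
            mMeans <- c(mMeans, mean(values[experiment == e & mouse == m]))
        }
        expMeans <- c(expMeans, mean(mMeans))
    }
    mean(expMeans)
}

# Independent oracle for the order-statistic tail: P(U_(j) <= u) for k iid
# uniforms, via the binomial sum (at least j of k below u), not pbeta.
orderStatTailOracle <- function(u, j, k) {
    i <- j:k
    sum(choose(k, i) * u^i * (1 - u)^(k - i))
}

# Brute-force alpha-RRA score for one gene's normalised ranks.
bruteRraScore <- function(u, alpha) {
    us <- sort(u)
    k <- length(us)
    best <- 1
    for (j in seq_len(k)) {
        if (us[j] < alpha)
            best <- min(best, orderStatTailOracle(us[j], j, k))
    }
    best
}
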