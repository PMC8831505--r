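#' Construct a spike-in power grid
#'
#' Defaults mirror the titration that established the assay's detection
#' limit: spike frequencies 1/100 to 1/3000 in a 1e6-cell transfer pool,
#' detection by |z| >= 2 of the spiked gene's Tfh-vs-Th1 L2FC against the
#' background genes.
#'
#' @param spikeFrequencies spike frequencies in (0, 1].
#' @param effectSizes Tfh log-odds shifts carried by the spiked gene.
#' @param coverages sort-coverage values to test.
#' @param nReps Monte-Carlo replicates per grid cell.
#' @param zThreshold detection threshold on |z|.
#' @return A \linkS4class{PowerGrid}.
#' @export
powerGrid <- function(spikeFrequencies = c(1 / 100, 1 / 300, 1 / 1000, 1 / 3000),
        effectSizes = -2, coverages = 750, nReps = 25L, zThreshold = 2) {
    new("PowerGrid", spikeFrequencies = spikeFrequencies,
        effectSizes = effectSizes, coverages = coverages,
        nReps = as.integer(nReps), zThreshold = zThreshold)
}

#' Monte-Carlo spike-in titration power
#'
#' For every (frequency, effect, coverage) cell, simulates \code{nReps}
#' spike-in cohorts with [spikeInCohort()], computes the spiked gene's
#' Tfh-vs-Th1 hierarchical L2FC, standardises it against the background
#' targeting genes, and calls detection when \code{|z| >= zThreshold}.
#' Reports the detection fraction with its binomial Monte-Carlo standard
#' error and the mean observed L2FC of the spiked gene.
#'
#' @param lib a \linkS4class{GuideLibrary}; its first targeting gene is
#'   spiked unless \code{targetGene} is given.
#' @param grid a \linkS4class{PowerGrid}.
#' @param config a \linkS4class{ScreenConfig} (cohort size, engraftment,
#'   depths; \code{sortCoverage} is overridden per grid cell).
#' @param seed integer master seed.
#' @param targetGene gene symbol to spike.
#' @return data.frame with columns \code{frequency}, \code{effect},
#'   \code{coverage}, \code{detection_rate}, \code{se}, \code{mean_l2fc}.
#' @export
titrationPower <- function(lib, grid = powerGrid(), config = screenConfig(),
        seed = 1L, targetGene = setdiff(geneSymbols(lib), .CONTROL_GENE)[1]) {
    stopifnot(is(lib, "GuideLibrary"), is(grid, "PowerGrid"),
        is(config, "ScreenConfig"))
    cells <- expand.grid(frequency = grid@spikeFrequencies,
        effect = grid@effectSizes, coverage = grid@coverages,
        KEEP.OUT.ATTRS = FALSE)
    out <- cells
    out$detection_rate <- NA_real_
    out$se <- NA_real_
    out$mean_l2fc <- NA_real_
    stage <- 0L
    for (i in seq_len(nrow(cells))) {
        cfg <- config
        cfg@sortCoverage <- cells$coverage[i]
        det <- logical(grid@nReps)
        l2fc <- numeric(grid@nReps)
        for (r in seq_len(grid@nReps)) {
            stage <- stage + 1L
            res <- .spikeStat(lib, targetGene, cells$frequency[i],
                cells$effect[i], cfg, seed = .stageSeed(seed, stage))
            det[r] <- abs(res$z) >= grid@zThreshold
            l2fc[r] <- res$l2fc
        }
        p <- mean(det)
        out$detection_rate[i] <- p
        out$se[i] <- sqrt(p * (1 - p) / grid@nReps)
        out$mean_l2fc[i] <- mean(l2fc, na.rm = TRUE)
    }
    out
}

## One cohort: spiked gene's Tfh-vs-Th1 hierarchical L2FC and its z
## against the background targeting genes.
.spikeStat <- function(lib, targetGene, frequency, effect, config, seed) {
    cohort <- spikeInCohort(lib, targetGene, frequency, effect, config,
        seed = seed)
    cmp <- compareScreen(cohort, "Tfh_vs_Th1")
    gs <- geneSummary(overallMean(cmp), lib)
    gm <- structure(gs$mean_l2fc, names = gs$gene)
    bg <- gm[!gs$is_control & gs$gene != targetGene]
    z <- (gm[targetGene] - mean(bg)) / stats::sd(bg)
    list(z = unname(z), l2fc = unname(gm[targetGene]))
}

#' Minimum detectable spike frequency
#'
#' The smallest tested frequency whose detection rate reaches
#' \code{targetPower}, per (effect, coverage) combination; \code{NA} when
#' no tested frequency reaches it.
#'
#' @param powerResult data.frame from [titrationPower()].
#' @param targetPower required detection rate (default 0.8).
#' @return data.frame with columns \code{effect}, \code{coverage},
#'   \code{min_frequency}.
#' @export
minimumDetectableFrequency <- function(powerResult, targetPower = 0.8) {
    if (length(unique(powerResult$frequency)) < 2L)
        stop("grid must span at least two frequencies")
    key <- unique(powerResult[, c("effect", "coverage")])
    out <- key
    out$min_frequency <- NA_real_
    for (i in seq_len(nrow(key))) {
        sub <- powerResult[powerResult$effect == key$effect[i] &
            powerResult$coverage == key$coverage[i], ]
        hit <- sub$frequency[sub$detection_rate >= targetPower]
        if (length(hit)) out$min_frequency[i] <- min(hit)
    }
    rownames(out) <- NULL
    out
}
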