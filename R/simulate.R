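#' Construct a screen simulator configuration
#'
#' Returns a \linkS4class{ScreenConfig} with any named slot overridden.
#' Defaults encode the assay design: 1e6 cells transferred per mouse, a
#' ~90\% engraftment loss (rate 0.10), 750x per-guide sort coverage,
#' 300x per-guide sequencing depth, and 95\% sort purity.
#'
#' @param ... named values overriding slots of \linkS4class{ScreenConfig}.
#' @return A validated \linkS4class{ScreenConfig}.
#' @examples
#' cfg <- screenConfig(nMice = 10L, plasmidSigma = 0.3)
#' @export
screenConfig <- function(...) {
    args <- list(...)
    intSlots <- c("nMice", "nExperiments", "seed")
    for (s in intersect(names(args), intSlots))
        args[[s]] <- as.integer(args[[s]])
    do.call(new, c(list("ScreenConfig"), args))
}

#' Construct simulator ground truth
#'
#' Per-gene effects over the genes of a library (control guides always
#' carry zero effect). Effects may be given as a single value recycled to
#' all targeting genes or as a named vector assigning effects to specific
#' genes (unnamed genes get zero).
#'
#' @param lib a \linkS4class{GuideLibrary}.
#' @param invitroFitness per-doubling log2 growth advantage in culture.
#' @param invivoFitness per-doubling log2 growth advantage after transfer.
#' @param tfhLogitShift additive shift on the baseline Tfh log-odds;
#'   negative values mean knockout impairs Tfh differentiation.
#' @return A \linkS4class{ScreenTruth}.
#' @examples
#' lib <- buildLibrary(paste0("G", 1:5), 4, 4, seed = 1)
#' tr <- screenTruth(lib, tfhLogitShift = c(G1 = -2))
#' @export
screenTruth <- function(lib, invitroFitness = 0, invivoFitness = 0,
        tfhLogitShift = 0) {
    stopifnot(is(lib, "GuideLibrary"))
    genes <- unique(geneSymbols(lib))
    expand <- function(x) {
        out <- numeric(length(genes))
        names(out) <- genes
        if (is.null(names(x))) {
            out[genes != .CONTROL_GENE] <- x
        } else {
            unknown <- setdiff(names(x), genes)
            if (length(unknown))
                stop("effects given for genes not in library: ",
                    paste(unknown, collapse = ", "))
            out[names(x)] <- x
        }
        out[genes == .CONTROL_GENE] <- 0
        out
    }
    new("ScreenTruth", gene = genes,
        invitroFitness = expand(invitroFitness),
        invivoFitness = expand(invivoFitness),
        tfhLogitShift = expand(tfhLogitShift))
}

setMethod("show", "ScreenTruth", function(object) {
    nz <- object@tfhLogitShift != 0 | object@invitroFitness != 0 |
        object@invivoFitness != 0
    cat("ScreenTruth over ", length(object@gene), " genes (",
        sum(nz), " with non-zero effects)\n", sep = "")
})

## Per-guide lookup of a per-gene truth vector.
.guideEffect <- function(lib, truth, slot) {
    eff <- slot(truth, slot)
    names(eff) <- truth@gene
    unname(eff[geneSymbols(lib)])
}

#' Draw relative plasmid-pool abundances
#'
#' Models skew in the cloned plasmid library as log-normal relative
#' abundance with standard deviation \code{plasmidSigma} on the log scale
#' (\code{plasmidSigma = 0} gives an exactly uniform pool). Abundances are
#' strictly positive and normalised to sum to 1.
#'
#' @param lib a \linkS4class{GuideLibrary}.
#' @param config a \linkS4class{ScreenConfig}.
#' @param seed optional integer seed (NULL uses the current RNG stream).
#' @return Named numeric vector of per-guide relative abundances.
#' @export
samplePlasmidPool <- function(lib, config = screenConfig(), seed = NULL) {
    n <- nGuides(lib)
    x <- if (config@plasmidSigma == 0) {
        rep(1 / n, n)
    } else {
        .withSeed(seed, {
            v <- exp(stats::rnorm(n, 0, config@plasmidSigma))
            v / sum(v)
        })
    }
    names(x) <- guideIds(lib)
    x
}

#' Simulate in vitro expansion of the transduced pool
#'
#' Cells grow for \code{cultureDoublings} population doublings; a guide
#' with in vitro fitness f multiplies by \code{2^(d * (1 + f))}, so
#' \code{f = 0} is neutral growth and \code{f = -1} is complete stasis.
#' Realised counts are Poisson around the expectation.
#'
#' @param abundance per-guide relative abundance of the plasmid pool.
#' @param truth a \linkS4class{ScreenTruth}.
#' @param lib a \linkS4class{GuideLibrary}.
#' @param config a \linkS4class{ScreenConfig}.
#' @param seed optional integer seed.
#' @return Named integer-valued vector of cells per guide at end of culture.
#' @export
simulateCulture <- function(abundance, truth, lib, config = screenConfig(),
        seed = NULL) {
    stopifnot(length(abundance) == nGuides(lib))
    fit <- .guideEffect(lib, truth, "invitroFitness")
    mu <- config@cultureStartCells * abundance *
        2^(config@cultureDoublings * (1 + fit))
    .withSeed(seed, {
        x <- stats::rpois(length(mu), mu)
        names(x) <- guideIds(lib)
        x
    })
}

#' Simulate one mouse: transfer, engraftment, expansion, fate, sorting
#'
#' The in vivo stages for a single recipient: (1) a multinomial draw of
#' \code{transferPoolSize} cells from the culture pool; (2) independent
#' binomial engraftment at \code{engraftmentRate} (the ~90\% adoptive
#' transfer loss); (3) Poisson expansion around
#' \code{2^(invivoDoublings * (1 + invivoFitness))}; (4) per-cell
#' Bernoulli fate: Tfh with probability
#' \code{plogis(baselineTfhLogit + tfhLogitShift[gene])}, else Th1, with
#' Tfh further split into GC Tfh at \code{gcTfhFraction}; (5) sorting of
#' \code{min(available, sortCoverage * nGuides)} cells per population,
#' where with probability \code{1 - sortPurity} a sorted cell is drawn
#' from the complementary populations (gate impurity).
#'
#' @param cultureCounts per-guide cell counts of the culture pool.
#' @param truth a \linkS4class{ScreenTruth}.
#' @param lib a \linkS4class{GuideLibrary}.
#' @param config a \linkS4class{ScreenConfig}.
#' @param seed optional integer seed.
#' @param returnStages if TRUE, return all intermediate stage vectors.
#' @return Guides x population matrix of sorted cell counts (columns Th1,
#'   preTfh, GCTfh), or, with \code{returnStages = TRUE}, a list with
#'   elements \code{transferred}, \code{engrafted}, \code{expanded},
#'   \code{cells} (pre-sort population matrix) and \code{sorted}.
#' @export
simulateMouse <- function(cultureCounts, truth, lib, config = screenConfig(),
        seed = NULL, returnStages = FALSE) {
    stopifnot(length(cultureCounts) == nGuides(lib))
    if (sum(cultureCounts) < config@transferPoolSize)
        stop("culture pool (", sum(cultureCounts),
            " cells) smaller than transferPoolSize (",
            config@transferPoolSize, ")")
    .withSeed(seed, {
        n <- nGuides(lib)
        transferred <- as.vector(stats::rmultinom(1, config@transferPoolSize,
            cultureCounts))
        engrafted <- stats::rbinom(n, transferred, config@engraftmentRate)
        if (sum(engrafted) == 0L) {
            warning("no cells engrafted; returning an empty mouse")
            empty <- matrix(0L, n, 3,
                dimnames = list(guideIds(lib), .SORTED_POPULATIONS))
            if (returnStages)
                list(transferred = transferred, engrafted = engrafted,
                    expanded = integer(n), cells = empty, sorted = empty)
            else empty
        } else {
            fitVivo <- .guideEffect(lib, truth, "invivoFitness")
            expanded <- stats::rpois(n,
                engrafted * 2^(config@invivoDoublings * (1 + fitVivo)))
            shift <- .guideEffect(lib, truth, "tfhLogitShift")
            pTfh <- stats::plogis(config@baselineTfhLogit + shift)
            nTfh <- stats::rbinom(n, expanded, pTfh)
            nTh1 <- expanded - nTfh
            nGC <- stats::rbinom(n, nTfh, config@gcTfhFraction)
            cells <- cbind(Th1 = nTh1, preTfh = nTfh - nGC, GCTfh = nGC)
            rownames(cells) <- guideIds(lib)
            sorted <- .sortPopulations(cells, config)
            if (returnStages)
                list(transferred = transferred, engrafted = engrafted,
                    expanded = expanded, cells = cells, sorted = sorted)
            else sorted
        }
    })
}

## Sort each population gate at sortCoverage x nGuides cells, with
## symmetric cross-contamination: an impure sorted cell comes from the
## pooled complementary populations.
.sortPopulations <- function(cells, config) {
    n <- nrow(cells)
    target <- config@sortCoverage * n
    sorted <- matrix(0L, n, ncol(cells), dimnames = dimnames(cells))
    total <- rowSums(cells)
    for (j in seq_len(ncol(cells))) {
        pool <- cells[, j]
        comp <- total - pool
        m <- min(sum(pool), target)
        if (m == 0) next
        nPure <- if (sum(comp) > 0)
            stats::rbinom(1, m, config@sortPurity)
        else m
        draw <- as.vector(stats::rmultinom(1, nPure, pool))
        if (m - nPure > 0)
            draw <- draw + as.vector(stats::rmultinom(1, m - nPure, comp))
        sorted[, j] <- draw
    }
    sorted
}

#' Simulate amplicon sequencing of a cell sample
#'
#' Reads are a multinomial draw of \code{seqDepth * nGuides} reads with
#' weights proportional to cell counts perturbed by gamma-distributed PCR
#' amplification noise (shape \code{pcrShape}, mean 1; larger shape means
#' read fractions converge to cell fractions).
#'
#' @param cellCounts non-negative per-guide cell counts (or, for the
#'   plasmid sample, relative abundances).
#' @param config a \linkS4class{ScreenConfig}.
#' @param seed optional integer seed.
#' @return Integer vector of read counts summing to
#'   \code{seqDepth * length(cellCounts)} (all zero, with a warning, when
#'   the input is all zero).
#' @export
simulateSequencing <- function(cellCounts, config = screenConfig(),
        seed = NULL) {
    if (any(cellCounts < 0)) stop("cellCounts must be non-negative")
    n <- length(cellCounts)
    total <- round(config@seqDepth * n)
    if (sum(cellCounts) == 0) {
        warning("all-zero cell sample; emitting an all-zero read column")
        return(structure(integer(n), names = names(cellCounts)))
    }
    .withSeed(seed, {
        w <- cellCounts * stats::rgamma(n, shape = config@pcrShape,
            rate = config@pcrShape)
        if (sum(w) == 0) w <- cellCounts  # pathological gamma underflow
        structure(as.vector(stats::rmultinom(1, total, w)),
            names = names(cellCounts))
    })
}

#' Simulate a complete in vivo screen
#'
#' Runs the full forward model and returns a \linkS4class{ScreenCounts}
#' with one sequencing sample for the plasmid pool, one per-experiment
#' culture sample, and sorted-population samples: per mouse when
#' \code{pooledSort = FALSE} (populations Th1/preTfh/GCTfh for each mouse)
#' or pooled across the mice of each (experiment, day) group when
#' \code{pooledSort = TRUE}. Mice are split evenly across days 6 and 7.
#' The run is fully reproducible from \code{config@seed}.
#'
#' @param lib a \linkS4class{GuideLibrary}.
#' @param truth a \linkS4class{ScreenTruth} (defaults to all-zero effects).
#' @param config a \linkS4class{ScreenConfig}.
#' @return A \linkS4class{ScreenCounts}; the truth and config are stored in
#'   \code{metadata()}.
#' @examples
#' lib <- buildLibrary(paste0("G", 1:10), 4, 8, seed = 1)
#' sc <- simulateScreen(lib, config = screenConfig(
#'     nMice = 2L, nExperiments = 1L, transferPoolSize = 1e4,
#'     cultureStartCells = 2e3, sortCoverage = 100, seqDepth = 100,
#'     seed = 7L))
#' @export
simulateScreen <- function(lib, truth = screenTruth(lib),
        config = screenConfig()) {
    stopifnot(is(lib, "GuideLibrary"), is(truth, "ScreenTruth"),
        is(config, "ScreenConfig"))
    seed <- config@seed
    n <- nGuides(lib)
    cols <- list()
    meta <- list()
    addSample <- function(counts, population, mouse, experiment, day, id) {
        cols[[id]] <<- counts
        meta[[id]] <<- data.frame(population = population, mouse = mouse,
            experiment = experiment, day = day, stringsAsFactors = FALSE)
    }

    abundance <- samplePlasmidPool(lib, config, seed = .stageSeed(seed, 1L))
    addSample(simulateSequencing(abundance, config, seed = .stageSeed(seed, 2L)),
        "plasmid", NA_integer_, NA_integer_, NA_integer_, "plasmid")

    days <- rep(c(6L, 7L), each = ceiling(config@nMice / 2))[seq_len(config@nMice)]
    stage <- 10L
    for (e in seq_len(config@nExperiments)) {
        culture <- simulateCulture(abundance, truth, lib, config,
            seed = .stageSeed(seed, stage))
        addSample(simulateSequencing(culture, config,
                seed = .stageSeed(seed, stage + 1L)),
            "culture", NA_integer_, e, 0L, paste0("culture_e", e))
        stage <- stage + 2L
        if (config@pooledSort) {
            ## pool pre-sort cells over the mice of each day group, sort once
            for (d in unique(days)) {
                mice <- which(days == d)
                pooled <- matrix(0L, n, 3,
                    dimnames = list(guideIds(lib), .SORTED_POPULATIONS))
                for (m in mice) {
                    st <- simulateMouse(culture, truth, lib, config,
                        seed = .stageSeed(seed, stage), returnStages = TRUE)
                    pooled <- pooled + st$cells
                    stage <- stage + 1L
                }
                sorted <- .withSeed(.stageSeed(seed, stage),
                    .sortPopulations(pooled, config))
                stage <- stage + 1L
                for (pop in .SORTED_POPULATIONS) {
                    addSample(simulateSequencing(sorted[, pop], config,
                            seed = .stageSeed(seed, stage)),
                        pop, NA_integer_, e, d,
                        paste0(pop, "_e", e, "_d", d))
                    stage <- stage + 1L
                }
            }
        } else {
            for (m in seq_len(config@nMice)) {
                sorted <- simulateMouse(culture, truth, lib, config,
                    seed = .stageSeed(seed, stage))
                stage <- stage + 1L
                for (pop in .SORTED_POPULATIONS) {
                    addSample(simulateSequencing(sorted[, pop], config,
                            seed = .stageSeed(seed, stage)),
                        pop, m, e, days[m],
                        paste0(pop, "_e", e, "_m", m))
                    stage <- stage + 1L
                }
            }
        }
    }

    counts <- do.call(cbind, cols)
    rownames(counts) <- guideIds(lib)
    colData <- do.call(rbind, meta)
    rownames(colData) <- names(cols)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = lib@guides,
        colData = DataFrame(colData))
    out <- new("ScreenCounts", se)
    metadata(out) <- list(library = lib, truth = truth, config = config)
    out
}

setMethod("show", "ScreenCounts", function(object) {
    cd <- colData(object)
    cat("ScreenCounts: ", nrow(object), " guides x ", ncol(object),
        " samples\n", sep = "")
    print(table(population = cd$population))
})

#' Simulate a spike-in cohort
#'
#' Models the spike-in titration that measures the assay's detection
#' limit: the guides of \code{targetGene} together make up
#' \code{spikeFrequency} of the transferred pool and carry a Tfh log-odds
#' shift of \code{effect}; every other guide is neutral background at
#' equal share of \code{1 - spikeFrequency}. Each of \code{config@nMice}
#' mice is carried through transfer, engraftment, expansion, fate choice,
#' sorting and sequencing.
#'
#' @param lib a \linkS4class{GuideLibrary} providing target and background
#'   guides.
#' @param targetGene gene symbol of the spiked gene.
#' @param spikeFrequency fraction of the transferred pool carrying the
#'   spiked guides, in (0, 1].
#' @param effect Tfh log-odds shift of the spiked gene.
#' @param config a \linkS4class{ScreenConfig}.
#' @param seed optional integer seed (defaults to \code{config@seed}).
#' @return A \linkS4class{ScreenCounts} of sorted-population samples
#'   (one Th1/preTfh/GCTfh triple per mouse, single experiment).
#' @export
spikeInCohort <- function(lib, targetGene, spikeFrequency, effect,
        config = screenConfig(), seed = config@seed) {
    stopifnot(is(lib, "GuideLibrary"))
    if (spikeFrequency <= 0 || spikeFrequency > 1)
        stop("spikeFrequency must lie in (0, 1]")
    if (!targetGene %in% geneSymbols(lib))
        stop("targetGene not in library: ", targetGene)
    isTarget <- geneSymbols(lib) == targetGene
    abundance <- numeric(nGuides(lib))
    abundance[isTarget] <- spikeFrequency / sum(isTarget)
    if (spikeFrequency < 1)
        abundance[!isTarget] <- (1 - spikeFrequency) / sum(!isTarget)
    ## the transfer draw itself performs the pool sampling; the "culture"
    ## here is a large pool at the configured mixing proportions
    pool <- round(abundance * config@transferPoolSize * 20)
    names(pool) <- guideIds(lib)
    truth <- screenTruth(lib, tfhLogitShift = structure(effect, names = targetGene))

    n <- nGuides(lib)
    cols <- list()
    meta <- list()
    days <- rep(c(6L, 7L), each = ceiling(config@nMice / 2))[seq_len(config@nMice)]
    stage <- 1L
    for (m in seq_len(config@nMice)) {
        sorted <- simulateMouse(pool, truth, lib, config,
            seed = .stageSeed(seed, stage))
        stage <- stage + 1L
        for (pop in .SORTED_POPULATIONS) {
            cols[[paste0(pop, "_m", m)]] <- simulateSequencing(sorted[, pop],
                config, seed = .stageSeed(seed, stage))
            meta[[paste0(pop, "_m", m)]] <- data.frame(population = pop,
                mouse = m, experiment = 1L, day = days[m],
                stringsAsFactors = FALSE)
            stage <- stage + 1L
        }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- guideIds(lib)
    colData <- do.call(rbind, meta)
    rownames(colData) <- names(cols)
    out <- new("ScreenCounts", SummarizedExperiment(
        assays = list(counts = counts),
        rowData = lib@guides, colData = DataFrame(colData)))
    metadata(out) <- list(library = lib, truth = truth, config = config,
        targetGene = targetGene, spikeFrequency = spikeFrequency,
        effect = effect)
    out
}
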