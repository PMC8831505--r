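#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

## gene symbol family reserved for non-targeting guides
.CONTROL_GENE <- "CTRL"

## fixed sample vocabulary: sequencing stages + sorted populations
.POPULATIONS <- c("plasmid", "culture", "Th1", "preTfh", "GCTfh")
.SORTED_POPULATIONS <- c("Th1", "preTfh", "GCTfh")

#' GuideLibrary: a targeted sgRNA library
#'
#' Holds the design of a pooled sgRNA library: one row per guide with its
#' identifier, target gene symbol, 20-nt spacer, and non-targeting control
#' flag. Non-targeting guides carry the reserved gene symbol \code{"CTRL"}.
#'
#' @slot guides \code{DataFrame} with columns \code{guide_id},
#'   \code{gene_symbol}, \code{spacer}, \code{is_control}.
#' @slot guidesPerGene integer, guides designed per targeting gene.
#' @slot name character, library name.
#'
#' @seealso [buildLibrary()], [readGuideLibrary()]
#' @exportClass GuideLibrary
setClass("GuideLibrary",
    slots = c(
        guides = "DataFrame",
        guidesPerGene = "integer",
        name = "character"
    )
)

setValidity("GuideLibrary", function(object) {
    g <- object@guides
    need <- c("guide_id", "gene_symbol", "spacer", "is_control")
    if (!all(need %in% colnames(g)))
        return(paste("guides must have columns:", paste(need, collapse = ", ")))
    msgs <- character()
    bad <- nchar(g$spacer) != 20L | grepl("[^ACGT]", g$spacer)
    if (any(bad))
        msgs <- c(msgs, paste0("invalid spacer (must be 20 nt over A/C/G/T) for guide(s): ",
            paste(head(g$guide_id[bad], 5), collapse = ", ")))
    if (anyDuplicated(g$guide_id))
        msgs <- c(msgs, "duplicate guide_id")
    if (anyDuplicated(g$spacer))
        msgs <- c(msgs, "duplicate spacer")
    if (!identical(g$is_control, g$gene_symbol == .CONTROL_GENE))
        msgs <- c(msgs, sprintf("is_control must hold exactly for gene_symbol == \"%s\"",
            .CONTROL_GENE))
    if (length(object@guidesPerGene) != 1L || is.na(object@guidesPerGene) ||
        object@guidesPerGene < 1L)
        msgs <- c(msgs, "guidesPerGene must be a single positive integer")
    tab <- table(g$gene_symbol[!g$is_control])
    off <- tab != object@guidesPerGene
    if (length(tab) && any(off))
        msgs <- c(msgs, paste0("every targeting gene must have exactly ",
            object@guidesPerGene, " guides; offending gene(s): ",
            paste(head(names(tab)[off], 5), collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

#' ScreenConfig: forward-model parameters of the in vivo screen
#'
#' All tunable parameters of the screen simulator, one slot per biological
#' or technical stage. Defaults reflect the assay as run: 1e6 cells
#' transferred per mouse, ~90\% loss at engraftment (rate 0.10), sorting at
#' 750 cells per guide per population with 95\% gate purity, and sequencing
#' at 300 reads per guide.
#'
#' @slot plasmidSigma sd of log-normal plasmid abundance (0 = uniform pool).
#' @slot cultureStartCells cells seeding the in vitro culture.
#' @slot cultureDoublings population doublings during in vitro culture.
#' @slot transferPoolSize cells adoptively transferred per mouse.
#' @slot engraftmentRate probability a transferred cell engrafts.
#' @slot invivoDoublings population doublings after transfer.
#' @slot baselineTfhLogit log-odds a neutral cell adopts the Tfh fate.
#' @slot gcTfhFraction fraction of Tfh cells in the GC Tfh gate.
#' @slot sortCoverage sorted cells per guide per population.
#' @slot seqDepth sequencing reads per guide per sample.
#' @slot sortPurity probability a sorted cell truly belongs to its gate.
#' @slot pcrShape gamma shape of PCR amplification noise (larger = cleaner).
#' @slot nMice mice per experiment.
#' @slot nExperiments independent experiments.
#' @slot pooledSort pool mice (within experiment and day) before sorting?
#' @slot seed integer master seed for [simulateScreen()].
#'
#' @seealso [screenConfig()]
#' @exportClass ScreenConfig
setClass("ScreenConfig",
    slots = c(
        plasmidSigma = "numeric",
        cultureStartCells = "numeric",
        cultureDoublings = "numeric",
        transferPoolSize = "numeric",
        engraftmentRate = "numeric",
        invivoDoublings = "numeric",
        baselineTfhLogit = "numeric",
        gcTfhFraction = "numeric",
        sortCoverage = "numeric",
        seqDepth = "numeric",
        sortPurity = "numeric",
        pcrShape = "numeric",
        nMice = "integer",
        nExperiments = "integer",
        pooledSort = "logical",
        seed = "integer"
    ),
    prototype = list(
        plasmidSigma = 0.5,
        cultureStartCells = 5e5,
        cultureDoublings = 6,
        transferPoolSize = 1e6,
        engraftmentRate = 0.10,
        invivoDoublings = 8,
        baselineTfhLogit = 0,
        gcTfhFraction = 0.5,
        sortCoverage = 750,
        seqDepth = 300,
        sortPurity = 0.95,
        pcrShape = 10,
        nMice = 5L,
        nExperiments = 2L,
        pooledSort = FALSE,
        seed = 1L
    )
)

setValidity("ScreenConfig", function(object) {
    msgs <- character()
    probs <- c(engraftmentRate = object@engraftmentRate,
        gcTfhFraction = object@gcTfhFraction,
        sortPurity = object@sortPurity)
    bad <- probs < 0 | probs > 1
    if (any(bad))
        msgs <- c(msgs, paste0(names(probs)[bad], " must lie in [0,1]"))
    pos <- c(cultureStartCells = object@cultureStartCells,
        transferPoolSize = object@transferPoolSize,
        sortCoverage = object@sortCoverage,
        seqDepth = object@seqDepth,
        pcrShape = object@pcrShape,
        nMice = object@nMice,
        nExperiments = object@nExperiments)
    bad <- pos <= 0
    if (any(bad))
        msgs <- c(msgs, paste0(names(pos)[bad], " must be positive"))
    nonneg <- c(plasmidSigma = object@plasmidSigma,
        cultureDoublings = object@cultureDoublings,
        invivoDoublings = object@invivoDoublings)
    bad <- nonneg < 0
    if (any(bad))
        msgs <- c(msgs, paste0(names(nonneg)[bad], " must be >= 0"))
    if (length(msgs)) msgs else TRUE
})

#' ScreenTruth: simulator ground truth, one row per gene
#'
#' Per-gene effect sizes the simulator injects and the analysis is meant to
#' recover: in vitro fitness (per-doubling log2 growth advantage in
#' culture), in vivo fitness (post-transfer), and an additive shift on the
#' baseline Tfh log-odds. A negative \code{tfhLogitShift} means knockout
#' impairs Tfh differentiation, i.e. the intact gene promotes Tfh. The
#' control gene family carries all-zero effects by construction.
#'
#' @slot gene character vector of gene symbols (including \code{"CTRL"}).
#' @slot invitroFitness numeric per-gene culture fitness.
#' @slot invivoFitness numeric per-gene in vivo fitness.
#' @slot tfhLogitShift numeric per-gene Tfh log-odds shift.
#'
#' @seealso [screenTruth()]
#' @exportClass ScreenTruth
setClass("ScreenTruth",
    slots = c(
        gene = "character",
        invitroFitness = "numeric",
        invivoFitness = "numeric",
        tfhLogitShift = "numeric"
    )
)

setValidity("ScreenTruth", function(object) {
    n <- length(object@gene)
    msgs <- character()
    if (length(object@invitroFitness) != n || length(object@invivoFitness) != n ||
        length(object@tfhLogitShift) != n)
        msgs <- c(msgs, "all effect vectors must match length(gene)")
    if (anyDuplicated(object@gene))
        msgs <- c(msgs, "duplicate gene symbols")
    ctrl <- object@gene == .CONTROL_GENE
    if (any(ctrl) && (any(object@invitroFitness[ctrl] != 0) ||
        any(object@invivoFitness[ctrl] != 0) ||
        any(object@tfhLogitShift[ctrl] != 0)))
        msgs <- c(msgs, "control guides must carry all-zero effects")
    if (length(msgs)) msgs else TRUE
})

#' ScreenCounts: guide-by-sample counts with sample metadata
#'
#' A \linkS4class{SummarizedExperiment} with a \code{"counts"} assay of
#' non-negative integers (guides in library order as rows), \code{rowData}
#' describing the guides, and \code{colData} columns \code{population}
#' (one of plasmid/culture/Th1/preTfh/GCTfh), \code{mouse} (NA for
#' unsorted or pooled samples), \code{experiment}, and \code{day}.
#'
#' @exportClass ScreenCounts
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
    msgs <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("must carry a 'counts' assay")
    m <- assay(object, "counts")
    if (any(m < 0))
        msgs <- c(msgs, "counts must be non-negative")
    if (any(m != round(m)))
        msgs <- c(msgs, "counts must be integral")
    cd <- colData(object)
    need <- c("population", "mouse", "experiment", "day")
    if (!all(need %in% colnames(cd)))
        msgs <- c(msgs, paste("colData must have columns:",
            paste(need, collapse = ", ")))
    else if (!all(cd$population %in% .POPULATIONS))
        msgs <- c(msgs, paste("population labels must be among:",
            paste(.POPULATIONS, collapse = ", ")))
    if (length(msgs)) msgs else TRUE
})

#' ExtractionPolicy: anchored spacer extraction parameters
#'
#' How to locate the 20-nt spacer in an amplicon read: match
#' \code{anchorUp} (the 3' end of the upstream vector flank), take the
#' next 20 nt, and require \code{anchorDown} (the 5' end of the tracr
#' flank) immediately after. Defaults are substrings of the cloning-oligo
#' flanks, so simulator-emitted reads and real amplicons match identically.
#'
#' @slot anchorUp upstream anchor (default \code{"CCTTGTTTG"}).
#' @slot anchorDown downstream anchor (default \code{"GTTTTA"}).
#' @slot anchorMismatches mismatches tolerated in each anchor (default 0).
#' @slot spacerMismatches Hamming-distance rescue for spacer-to-library
#'   assignment (default 1; ambiguous rescues are left unmapped).
#'
#' @seealso [extractionPolicy()], [countSample()]
#' @exportClass ExtractionPolicy
setClass("ExtractionPolicy",
    slots = c(
        anchorUp = "character",
        anchorDown = "character",
        anchorMismatches = "integer",
        spacerMismatches = "integer"
    ),
    prototype = list(
        anchorUp = "CCTTGTTTG",
        anchorDown = "GTTTTA",
        anchorMismatches = 0L,
        spacerMismatches = 1L
    )
)

setValidity("ExtractionPolicy", function(object) {
    msgs <- character()
    if (!nzchar(object@anchorUp) || !nzchar(object@anchorDown))
        msgs <- c(msgs, "anchors must be non-empty")
    if (object@anchorMismatches < 0L || object@spacerMismatches < 0L)
        msgs <- c(msgs, "mismatch allowances must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' SampleCounts: per-sample guide counts with mapping accounting
#'
#' Result of counting one FASTQ sample against a library. The accounting
#' identity \code{sum(counts) + nUnmapped == nTotalReads} always holds.
#'
#' @slot counts named integer vector, one entry per library guide.
#' @slot nUnmapped reads with no (unique) library assignment.
#' @slot nTotalReads total reads in the sample.
#'
#' @seealso [countSample()]
#' @exportClass SampleCounts
setClass("SampleCounts",
    slots = c(
        counts = "integer",
        nUnmapped = "integer",
        nTotalReads = "integer"
    )
)

setValidity("SampleCounts", function(object) {
    if (any(object@counts < 0L))
        return("counts must be non-negative")
    if (sum(object@counts) + object@nUnmapped != object@nTotalReads)
        return("accounting identity violated: sum(counts) + nUnmapped != nTotalReads")
    TRUE
})

#' GuideComparison: per-guide log2 fold changes for one comparison
#'
#' Per-guide, per-replicate log2 fold changes for a named population
#' comparison, with the replicate hierarchy resolved: replicate values are
#' averaged per mouse within experiment, then across experiments.
#'
#' @slot name comparison name (e.g. \code{"Tfh_vs_Th1"}).
#' @slot replicates data.frame with columns \code{guide_id},
#'   \code{gene_symbol}, \code{experiment}, \code{mouse}, \code{value}.
#' @slot experimentMeans numeric matrix, guides x experiments.
#' @slot overallMean named numeric, the hierarchical average per guide.
#'
#' @seealso [compareScreen()]
#' @exportClass GuideComparison
setClass("GuideComparison",
    slots = c(
        name = "character",
        replicates = "data.frame",
        experimentMeans = "matrix",
        overallMean = "numeric"
    )
)

#' PowerGrid: design grid for spike-in power analysis
#'
#' @slot spikeFrequencies spike frequencies in (0, 1].
#' @slot effectSizes Tfh log-odds shifts carried by the spiked gene.
#' @slot coverages sort-coverage values (cells per guide per population).
#' @slot nReps Monte-Carlo replicates per grid cell.
#' @slot zThreshold detection threshold on |z| of the spiked gene.
#'
#' @seealso [powerGrid()], [titrationPower()]
#' @exportClass PowerGrid
setClass("PowerGrid",
    slots = c(
        spikeFrequencies = "numeric",
        effectSizes = "numeric",
        coverages = "numeric",
        nReps = "integer",
        zThreshold = "numeric"
    ),
    prototype = list(
        spikeFrequencies = c(1 / 100, 1 / 300, 1 / 1000, 1 / 3000),
        effectSizes = -2,
        coverages = 750,
        nReps = 25L,
        zThreshold = 2
    )
)

setValidity("PowerGrid", function(object) {
    msgs <- character()
    if (any(object@spikeFrequencies <= 0 | object@spikeFrequencies > 1))
        msgs <- c(msgs, "spikeFrequencies must lie in (0, 1]")
    if (object@nReps < 1L)
        msgs <- c(msgs, "nReps must be >= 1")
    if (object@zThreshold <= 0)
        msgs <- c(msgs, "zThreshold must be positive")
    if (length(msgs)) msgs else TRUE
})
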