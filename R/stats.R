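.COMPARISONS <- c("Tfh_vs_Th1", "Tfh_vs_culture", "Th1_vs_culture",
    "culture_vs_plasmid", "preTfh_vs_Th1", "GCTfh_vs_Th1")

#' Per-guide log2 fold change with pseudocount
#'
#' \code{log2((num + pseudocount) / (den + pseudocount))} on normalised
#' abundances. The 0.5-CPM default pseudocount bounds the statistic for
#' dropout guides.
#'
#' @param cpmNum,cpmDen non-negative normalised abundances (vectorised).
#' @param pseudocount added to both terms; must be positive whenever
#'   either input can be zero.
#' @return Numeric log2 ratios.
#' @examples
#' guideL2FC(200, 100, 0)   # 1
#' @export
guideL2FC <- function(cpmNum, cpmDen, pseudocount = 0.5) {
    if (any(cpmNum < 0) || any(cpmDen < 0))
        stop("abundances must be non-negative")
    if (pseudocount < 0) stop("pseudocount must be >= 0")
    if (pseudocount == 0 && any(cpmNum == 0 & cpmDen == 0))
        stop("log2 ratio undefined: both abundances zero with pseudocount 0")
    log2((cpmNum + pseudocount) / (cpmDen + pseudocount))
}

#' Hierarchical replicate averaging
#'
#' Replicate values are averaged per mouse within experiment, then the
#' mouse means are averaged within each experiment, then the experiment
#' means are averaged — so experiments with unequal mouse counts weight
#' equally at the top level. Groups that are entirely \code{NA} are
#' excluded with a warning.
#'
#' @param values numeric replicate values.
#' @param experiment,mouse grouping vectors aligned with \code{values}
#'   (\code{mouse} may be NA throughout for pooled designs, in which case
#'   each (experiment, mouse-slot) value stands alone).
#' @return List with \code{overall} (the top-level mean),
#'   \code{experimentMeans} (named numeric) and \code{mouseMeans}
#'   (data.frame experiment/mouse/mean).
#' @examples
#' hierarchicalAverage(c(1, 3, 5), experiment = c(1, 1, 2),
#'     mouse = c(1, 2, 1))$overall  # 3.5, not the pooled mean 3
#' @export
hierarchicalAverage <- function(values, experiment, mouse) {
    stopifnot(length(values) == length(experiment),
        length(values) == length(mouse))
    keep <- !is.na(values)
    if (!any(keep)) stop("all replicate values missing")
    if (!all(keep)) {
        warning(sum(!keep), " missing replicate value(s) excluded")
        values <- values[keep]; experiment <- experiment[keep]
        mouse <- mouse[keep]
    }
    mouseKey <- paste(experiment, mouse, sep = "\r")
    mm <- tapply(values, mouseKey, mean)
    mmExp <- sub("\r.*$", "", names(mm))
    em <- tapply(as.vector(mm), mmExp, mean)
    list(overall = mean(em),
        experimentMeans = structure(as.vector(em), names = names(em)),
        mouseMeans = data.frame(
            experiment = mmExp,
            mouse = sub("^.*\r", "", names(mm)),
            mean = as.vector(mm), row.names = NULL))
}

## Resolve a comparison name into the sample pairs (numerator/denominator
## count vectors per replicate unit) it implies. "Tfh" aggregates the
## preTfh and GCTfh sort gates by summing raw counts.
.resolveComparison <- function(sc, comparison) {
    cd <- as.data.frame(colData(sc))
    m <- assay(sc, "counts")
    parts <- strsplit(comparison, "_vs_")[[1]]
    numPop <- parts[1]; denPop <- parts[2]
    getCols <- function(pop, rows) {
        cols <- rows[cd$population[rows] %in%
            (if (pop == "Tfh") c("preTfh", "GCTfh") else pop)]
        if (!length(cols)) return(NULL)
        rowSums(m[, cols, drop = FALSE])
    }
    units <- list()
    if (denPop %in% c("culture", "plasmid")) {
        ## numerator per sorted replicate (or culture), denominator the
        ## matching upstream sample of the same experiment (plasmid shared)
        if (numPop == "culture") {
            for (e in unique(cd$experiment[cd$population == "culture"])) {
                num <- getCols("culture", which(cd$experiment %in% e))
                den <- getCols("plasmid", seq_len(nrow(cd)))
                if (is.null(num) || is.null(den)) next
                units[[length(units) + 1L]] <- list(num = num, den = den,
                    experiment = e, mouse = NA)
            }
        } else {
            sortRows <- which(cd$population %in% .SORTED_POPULATIONS)
            key <- unique(cd[sortRows, c("experiment", "mouse", "day")])
            for (i in seq_len(nrow(key))) {
                rows <- sortRows[
                    cd$experiment[sortRows] %in% key$experiment[i] &
                    (cd$mouse[sortRows] %in% key$mouse[i] |
                        (is.na(key$mouse[i]) & is.na(cd$mouse[sortRows]))) &
                    cd$day[sortRows] %in% key$day[i]]
                num <- getCols(numPop, rows)
                den <- getCols("culture",
                    which(cd$experiment %in% key$experiment[i]))
                if (is.null(num) || is.null(den)) next
                units[[length(units) + 1L]] <- list(num = num, den = den,
                    experiment = key$experiment[i],
                    mouse = if (is.na(key$mouse[i])) key$day[i] else key$mouse[i])
            }
        }
    } else {
        ## sorted-vs-sorted: paired within (experiment, mouse, day) unit
        sortRows <- which(cd$population %in% .SORTED_POPULATIONS)
        key <- unique(cd[sortRows, c("experiment", "mouse", "day")])
        for (i in seq_len(nrow(key))) {
            rows <- sortRows[
                cd$experiment[sortRows] %in% key$experiment[i] &
                (cd$mouse[sortRows] %in% key$mouse[i] |
                    (is.na(key$mouse[i]) & is.na(cd$mouse[sortRows]))) &
                cd$day[sortRows] %in% key$day[i]]
            num <- getCols(numPop, rows)
            den <- getCols(denPop, rows)
            if (is.null(num) || is.null(den)) next
            units[[length(units) + 1L]] <- list(num = num, den = den,
                experiment = key$experiment[i],
                mouse = if (is.na(key$mouse[i])) key$day[i] else key$mouse[i])
        }
    }
    units
}

#' Compute per-guide log2 fold changes for a named comparison
#'
#' For every replicate unit — a mouse within an experiment for sorted
#' populations (a day-pooled sample when mice were pooled before sorting),
#' an experiment for culture-vs-plasmid — raw counts of numerator and
#' denominator are CPM-normalised and converted to log2 ratios with a
#' pseudocount, then combined by [hierarchicalAverage()]: mouse means
#' within experiment, experiment means averaged on top. Guides with zero
#' raw counts in both members of a replicate pair are flagged (NA) and
#' excluded from that replicate.
#'
#' @param sc a \linkS4class{ScreenCounts}.
#' @param comparison one of \code{"Tfh_vs_Th1"}, \code{"Tfh_vs_culture"},
#'   \code{"Th1_vs_culture"}, \code{"culture_vs_plasmid"},
#'   \code{"preTfh_vs_Th1"}, \code{"GCTfh_vs_Th1"} (\code{"Tfh"} sums the
#'   preTfh and GCTfh gates).
#' @param pseudocount CPM pseudocount on both ratio terms.
#' @param normalization passed to [cpmNormalize()].
#' @return A \linkS4class{GuideComparison}.
#' @export
compareScreen <- function(sc, comparison = "Tfh_vs_Th1", pseudocount = 0.5,
        normalization = c("cpm", "medianControls")) {
    stopifnot(is(sc, "ScreenCounts"))
    comparison <- match.arg(comparison, .COMPARISONS)
    normalization <- match.arg(normalization)
    lib <- metadata(sc)$library
    units <- .resolveComparison(sc, comparison)
    if (!length(units))
        stop("no replicate pairs available for comparison ", comparison)
    gid <- rownames(sc)
    gene <- rowData(sc)$gene_symbol
    reps <- lapply(seq_along(units), function(i) {
        u <- units[[i]]
        numN <- cpmNormalize(matrix(u$num, ncol = 1), method = normalization,
            lib = lib)[, 1]
        denN <- cpmNormalize(matrix(u$den, ncol = 1), method = normalization,
            lib = lib)[, 1]
        v <- guideL2FC(numN, denN, pseudocount)
        v[u$num == 0 & u$den == 0] <- NA_real_   # absent from both: flagged
        data.frame(guide_id = gid, gene_symbol = gene,
            experiment = u$experiment, mouse = u$mouse, value = v,
            stringsAsFactors = FALSE, row.names = NULL)
    })
    reps <- do.call(rbind, reps)

    expLevels <- sort(unique(reps$experiment))
    expMeans <- matrix(NA_real_, length(gid), length(expLevels),
        dimnames = list(gid, paste0("experiment", expLevels)))
    overall <- structure(rep(NA_real_, length(gid)), names = gid)
    ## vectorised hierarchy: mouse means, then experiment means, then top
    mKey <- paste(reps$guide_id, reps$experiment, reps$mouse, sep = "\r")
    mm <- tapply(reps$value, mKey, mean, na.rm = TRUE)
    parts <- strsplit(names(mm), "\r", fixed = TRUE)
    mmGuide <- vapply(parts, `[`, "", 1L)
    mmExp <- vapply(parts, `[`, "", 2L)
    eKey <- paste(mmGuide, mmExp, sep = "\r")
    em <- tapply(as.vector(mm), eKey, mean, na.rm = TRUE)
    emGuide <- sub("\r.*$", "", names(em))
    emExp <- sub("^.*\r", "", names(em))
    expMeans[cbind(emGuide, paste0("experiment", emExp))] <- as.vector(em)
    ov <- tapply(as.vector(em), emGuide, mean, na.rm = TRUE)
    overall[names(ov)] <- as.vector(ov)
    overall[is.nan(overall)] <- NA_real_

    new("GuideComparison", name = comparison, replicates = reps,
        experimentMeans = expMeans, overallMean = overall)
}

#' Accessors for GuideComparison
#' @param x a \linkS4class{GuideComparison}.
#' @name GuideComparison-accessors
NULL

#' @rdname GuideComparison-accessors
#' @export
setMethod("overallMean", "GuideComparison", function(x) x@overallMean)

#' @rdname GuideComparison-accessors
#' @export
setMethod("replicateValues", "GuideComparison", function(x) x@replicates)

#' @rdname GuideComparison-accessors
#' @export
setMethod("experimentMeans", "GuideComparison", function(x) x@experimentMeans)

setMethod("show", "GuideComparison", function(object) {
    cat("GuideComparison \"", object@name, "\": ",
        length(object@overallMean), " guides, ",
        nrow(unique(object@replicates[, c("experiment", "mouse")])),
        " replicate units\n", sep = "")
})

#' Gene-level mean and SEM over guides
#'
#' The gene statistic is the arithmetic mean of its guides' hierarchical
#' L2FC means; the SEM uses the n-1 sample standard deviation over guides
#' and is \code{NA} for single-guide genes. Guides whose hierarchical mean
#' is missing (flagged in every replicate) are excluded.
#'
#' @param guideMeans named numeric vector of per-guide overall L2FC means
#'   (names are guide ids), e.g. \code{overallMean(compareScreen(...))}.
#' @param lib a \linkS4class{GuideLibrary}; control guides are grouped
#'   into pseudo-genes via [controlPseudoGenes()].
#' @return data.frame with columns \code{gene}, \code{is_control},
#'   \code{n_guides}, \code{mean_l2fc}, \code{sem_l2fc}.
#' @export
geneSummary <- function(guideMeans, lib) {
    stopifnot(is(lib, "GuideLibrary"))
    gid <- guideIds(lib)
    v <- guideMeans[gid]
    gene <- geneSymbols(lib)
    pseudo <- controlPseudoGenes(lib)
    gene[isControl(lib)] <- as.character(pseudo[gid[isControl(lib)]])
    keep <- !is.na(v)
    gene <- gene[keep]; v <- v[keep]
    mu <- tapply(v, gene, mean)
    nG <- tapply(v, gene, length)
    sdv <- tapply(v, gene, stats::sd)       # NA for n = 1 (n-1 denominator)
    out <- data.frame(
        gene = names(mu),
        is_control = startsWith(names(mu), paste0(.CONTROL_GENE, ".")),
        n_guides = as.integer(nG),
        mean_l2fc = as.vector(mu),
        sem_l2fc = as.vector(sdv) / sqrt(as.vector(nG)),
        row.names = NULL, stringsAsFactors = FALSE)
    out[order(match(out$gene, unique(gene))), , drop = FALSE]
}

#' Control-anchored Z-scores
#'
#' Standardises gene-level means against the non-targeting control
#' pseudo-genes: \code{z = (gene - mean(controls)) / sd(controls)}.
#' All control pseudo-genes enter the reference (nothing is left out), so
#' the controls' own z-scores have sample mean 0 and sd 1 by construction.
#' With \code{reference = "all"} the standardisation uses every gene
#' instead of the controls.
#'
#' @param geneMeans named numeric vector of gene-level means.
#' @param controlMeans numeric vector of control pseudo-gene means
#'   (ignored when \code{reference = "all"}).
#' @param reference \code{"controls"} (default) or \code{"all"}.
#' @return Named numeric z-scores aligned with \code{geneMeans}.
#' @export
controlZscore <- function(geneMeans, controlMeans = NULL,
        reference = c("controls", "all")) {
    reference <- match.arg(reference)
    ref <- if (reference == "all") geneMeans else controlMeans
    if (reference == "controls" && (is.null(ref) || length(ref) < 2L))
        stop("need at least 2 control pseudo-gene means to anchor z-scores")
    s <- stats::sd(ref)
    if (is.na(s) || s == 0)
        stop("reference standard deviation is zero; cannot standardise")
    (geneMeans - mean(ref)) / s
}

#' Quadrant classification of screen hits
#'
#' Classifies genes from the two against-culture comparisons: depleted in
#' both sorted arms means the gene is required for cell expansion;
#' enriched in both means it inhibits expansion; depletion in only one arm
#' assigns the fate-specific categories.
#'
#' @param tfhVsCulture,th1VsCulture named numeric gene-level mean L2FCs
#'   over the same gene set.
#' @param depletionThreshold L2FC below which a gene counts as depleted
#'   (default -1).
#' @param enrichmentThreshold L2FC above which a gene counts as enriched
#'   (default +1).
#' @return Named factor with levels \code{required_for_Tfh},
#'   \code{required_for_Th1}, \code{inhibits_expansion},
#'   \code{required_for_expansion}, \code{neutral}.
#' @examples
#' classifyHits(c(A = -3, B = -2, C = 0), c(A = -3, B = 0.2, C = 0))
#' @export
classifyHits <- function(tfhVsCulture, th1VsCulture,
        depletionThreshold = -1, enrichmentThreshold = 1) {
    if (!identical(names(tfhVsCulture), names(th1VsCulture)))
        stop("both comparisons must cover the same gene set in the same order")
    if (depletionThreshold >= 0) stop("depletionThreshold must be negative")
    if (enrichmentThreshold <= 0) stop("enrichmentThreshold must be positive")
    lev <- c("required_for_Tfh", "required_for_Th1", "inhibits_expansion",
        "required_for_expansion", "neutral")
    cat <- rep("neutral", length(tfhVsCulture))
    tfhLow <- tfhVsCulture < depletionThreshold
    th1Low <- th1VsCulture < depletionThreshold
    tfhHigh <- tfhVsCulture > enrichmentThreshold
    th1High <- th1VsCulture > enrichmentThreshold
    cat[tfhLow & th1Low] <- "required_for_expansion"
    cat[tfhHigh & th1High] <- "inhibits_expansion"
    cat[tfhLow & !th1Low] <- "required_for_Tfh"
    cat[th1Low & !tfhLow] <- "required_for_Th1"
    structure(factor(cat, levels = lev), names = names(tfhVsCulture))
}

#' One-stop gene-level screen results for a comparison
#'
#' Runs [compareScreen()], [geneSummary()], [controlZscore()] and
#' [rraGeneTest()] and merges them into a single gene-level table, the
#' screen's primary result: mean L2FC with SEM, control-anchored Z-score,
#' alpha-RRA score, permutation p-value and BH FDR per targeting gene
#' (control pseudo-genes carry the summary columns only).
#'
#' @param sc a \linkS4class{ScreenCounts}.
#' @param comparison comparison name, see [compareScreen()].
#' @param direction \code{"depleted"} or \code{"enriched"}: which tail of
#'   the guide ranking the RRA test targets.
#' @param pseudocount CPM pseudocount.
#' @param alpha top fraction of guide ranks the RRA score considers.
#' @param nPerm permutation count for the RRA null.
#' @param seed seed for the permutation null.
#' @param zReference passed to [controlZscore()] as \code{reference}.
#' @return data.frame with columns \code{gene}, \code{is_control},
#'   \code{n_guides}, \code{mean_l2fc}, \code{sem_l2fc}, \code{zscore},
#'   \code{rra_score}, \code{p_value}, \code{fdr}.
#' @export
screenResults <- function(sc, comparison = "Tfh_vs_Th1",
        direction = c("depleted", "enriched"), pseudocount = 0.5,
        alpha = 0.25, nPerm = 10000L, seed = 1L,
        zReference = c("controls", "all")) {
    direction <- match.arg(direction)
    zReference <- match.arg(zReference)
    lib <- metadata(sc)$library
    cmp <- compareScreen(sc, comparison, pseudocount = pseudocount)
    gs <- geneSummary(overallMean(cmp), lib)
    gm <- structure(gs$mean_l2fc, names = gs$gene)
    z <- if (zReference == "all") {
        controlZscore(gm, reference = "all")
    } else {
        controlZscore(gm, gm[gs$is_control])
    }
    gs$zscore <- as.vector(z[gs$gene])
    rra <- rraGeneTest(overallMean(cmp), lib, direction = direction,
        alpha = alpha, nPerm = nPerm, seed = seed)
    idx <- match(gs$gene, rra$gene)
    gs$rra_score <- rra$rra_score[idx]
    gs$p_value <- rra$p_value[idx]
    gs$fdr <- rra$fdr[idx]
    gs
}
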