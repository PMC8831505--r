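#' Construct a spacer extraction policy
#'
#' @param anchorUp upstream anchor sequence (3' end of the upstream flank).
#' @param anchorDown downstream anchor sequence (5' end of the tracr flank).
#' @param anchorMismatches mismatches tolerated in each anchor.
#' @param spacerMismatches Hamming-distance rescue when assigning extracted
#'   spacers to library guides (0 = exact only).
#' @return An \linkS4class{ExtractionPolicy}.
#' @export
extractionPolicy <- function(anchorUp = "CCTTGTTTG", anchorDown = "GTTTTA",
        anchorMismatches = 0L, spacerMismatches = 1L) {
    new("ExtractionPolicy", anchorUp = toupper(anchorUp),
        anchorDown = toupper(anchorDown),
        anchorMismatches = as.integer(anchorMismatches),
        spacerMismatches = as.integer(spacerMismatches))
}

#' Extract candidate spacers from amplicon reads
#'
#' Locates \code{anchorUp} in each read (allowing
#' \code{anchorMismatches}), takes the following 20 nt as the candidate
#' spacer, and requires \code{anchorDown} immediately after (same mismatch
#' allowance). Reads failing any step — no anchor, truncated cassette,
#' missing downstream anchor — yield \code{NA}. When the upstream anchor
#' matches at several positions the first position passing the downstream
#' check wins.
#'
#' @param reads character vector or \code{DNAStringSet} of uppercase reads.
#' @param policy an \linkS4class{ExtractionPolicy}.
#' @return Character vector of 20-nt spacers, \code{NA} where extraction
#'   failed.
#' @export
extractSpacer <- function(reads, policy = extractionPolicy()) {
    chr <- if (is(reads, "DNAStringSet")) as.character(reads) else
        as.character(reads)
    out <- rep(NA_character_, length(chr))
    if (!length(chr)) return(out)
    if (policy@anchorMismatches == 0L)
        .extractExactAnchor(chr, policy, out)
    else
        .extractFuzzyAnchor(chr, policy, out)
}

## Exact-anchor fast path: first occurrence via fixed regexpr; the rare
## read whose first anchor occurrence fails the downstream check is
## re-examined at all occurrences.
.extractExactAnchor <- function(chr, policy, out) {
    nUp <- nchar(policy@anchorUp)
    nDown <- nchar(policy@anchorDown)
    pos <- regexpr(policy@anchorUp, chr, fixed = TRUE)
    hasHit <- pos > 0L
    endPos <- as.integer(pos) + nUp - 1L
    fits <- hasHit & endPos + 20L + nDown <= nchar(chr)
    idx <- which(fits)
    cand <- substr(chr[idx], endPos[idx] + 1L, endPos[idx] + 20L)
    down <- substr(chr[idx], endPos[idx] + 21L, endPos[idx] + 20L + nDown)
    ok <- down == policy@anchorDown & !grepl("[^ACGT]", cand)
    out[idx[ok]] <- cand[ok]
    ## second pass: reads with an anchor hit but a failing first candidate
    retry <- union(which(hasHit & !fits), idx[!ok])
    for (i in retry) {
        starts <- gregexpr(policy@anchorUp, chr[i], fixed = TRUE)[[1]][-1]
        for (s in starts) {
            e <- s + nUp - 1L
            if (e + 20L + nDown > nchar(chr[i])) next
            sp <- substr(chr[i], e + 1L, e + 20L)
            dn <- substr(chr[i], e + 21L, e + 20L + nDown)
            if (dn == policy@anchorDown && !grepl("[^ACGT]", sp)) {
                out[i] <- sp
                break
            }
        }
    }
    out
}

## Mismatch-tolerant path via Biostrings pattern matching.
.extractFuzzyAnchor <- function(chr, policy, out) {
    nDown <- nchar(policy@anchorDown)
    reads <- Biostrings::DNAStringSet(chr)
    hits <- Biostrings::vmatchPattern(policy@anchorUp, reads,
        max.mismatch = policy@anchorMismatches)
    nHits <- S4Vectors::elementNROWS(hits)
    ir <- unlist(hits, use.names = FALSE)
    readIdx <- rep.int(seq_along(chr), nHits)
    endPos <- IRanges::end(ir)
    if (!length(endPos)) return(out)
    keep <- endPos + 20L + nDown <= nchar(chr)[readIdx]
    readIdx <- readIdx[keep]; endPos <- endPos[keep]
    if (!length(endPos)) return(out)
    rchr <- chr[readIdx]
    cand <- substr(rchr, endPos + 1L, endPos + 20L)
    down <- substr(rchr, endPos + 21L, endPos + 20L + nDown)
    ok <- .hammingTo(down, policy@anchorDown) <= policy@anchorMismatches &
        !grepl("[^ACGT]", cand)
    readIdx <- readIdx[ok]; cand <- cand[ok]
    if (!length(readIdx)) return(out)
    first <- !duplicated(readIdx)
    out[readIdx[first]] <- cand[first]
    out
}

## Hamming distance of each string in x to a single reference of equal width.
.hammingTo <- function(x, ref) {
    refChars <- strsplit(ref, "")[[1]]
    L <- length(refChars)
    d <- integer(length(x))
    for (i in seq_len(L))
        d <- d + (substr(x, i, i) != refChars[i])
    d
}

#' Count a FASTQ sample against a guide library
#'
#' Extracts spacers with [extractSpacer()] and assigns them to library
#' guides: exact spacer match first; if none and
#' \code{spacerMismatches >= 1}, a read is rescued to the unique library
#' spacer at Hamming distance 1 (a spacer equidistant from two library
#' members stays unmapped). Assignment is deterministic.
#'
#' @param fastq path to a FASTQ file (plain or gzip, Phred+33), or a
#'   character vector of read sequences.
#' @param lib a \linkS4class{GuideLibrary}.
#' @param policy an \linkS4class{ExtractionPolicy}.
#' @return A \linkS4class{SampleCounts}; \code{sum(guideCounts(x)) +
#'   nUnmapped(x) == nTotalReads(x)} always holds.
#' @export
countSample <- function(fastq, lib, policy = extractionPolicy()) {
    stopifnot(is(lib, "GuideLibrary"))
    reads <- if (is.character(fastq) && length(fastq) == 1L &&
            file.exists(fastq)) {
        tryCatch(
            Biostrings::readDNAStringSet(fastq, format = "fastq"),
            error = function(e) stop("failed to parse FASTQ '", fastq,
                "': ", conditionMessage(e), call. = FALSE))
    } else if (is.character(fastq)) {
        Biostrings::DNAStringSet(fastq)
    } else {
        stop("fastq must be a file path or a character vector of reads")
    }
    libSpacers <- spacers(lib)
    extracted <- extractSpacer(reads, policy)
    idx <- match(extracted, libSpacers)          # NA for no exact hit

    if (policy@spacerMismatches >= 1L) {
        miss <- which(is.na(idx) & !is.na(extracted))
        if (length(miss)) {
            uniq <- unique(extracted[miss])
            rescue <- .rescueHamming1(uniq, libSpacers)
            idx[miss] <- rescue[match(extracted[miss], uniq)]
        }
    }
    counts <- integer(nGuides(lib))
    tab <- tabulate(idx[!is.na(idx)], nbins = nGuides(lib))
    counts <- as.integer(tab)
    names(counts) <- guideIds(lib)
    new("SampleCounts", counts = counts,
        nUnmapped = as.integer(sum(is.na(idx))),
        nTotalReads = length(reads))
}

## For each query 20-mer, index of the unique library spacer at Hamming
## distance exactly 1; NA when none or when the assignment is ambiguous.
.rescueHamming1 <- function(queries, libSpacers) {
    libMat <- do.call(rbind, strsplit(libSpacers, ""))
    out <- rep(NA_integer_, length(queries))
    for (q in seq_along(queries)) {
        qc <- strsplit(queries[q], "")[[1]]
        d <- rowSums(libMat != matrix(qc, nrow = nrow(libMat), ncol = 20L,
            byrow = TRUE))
        hit <- which(d == 1L)
        if (length(hit) == 1L) out[q] <- hit
    }
    out
}

#' @rdname SampleCounts-accessors
#' @export
setMethod("guideCounts", "SampleCounts", function(x) x@counts)

#' @rdname SampleCounts-accessors
#' @export
setMethod("nUnmapped", "SampleCounts", function(x) x@nUnmapped)

#' Accessors for SampleCounts
#' @param x a \linkS4class{SampleCounts}.
#' @name SampleCounts-accessors
#' @rdname SampleCounts-accessors
#' @export
setMethod("nTotalReads", "SampleCounts", function(x) x@nTotalReads)

setMethod("show", "SampleCounts", function(object) {
    cat("SampleCounts: ", sum(object@counts), " mapped / ",
        object@nTotalReads, " reads (", object@nUnmapped, " unmapped)\n",
        sep = "")
})

#' Count several FASTQ samples into a ScreenCounts
#'
#' @param files named character vector of FASTQ paths (names become sample
#'   ids).
#' @param sampleInfo data.frame with one row per file and columns
#'   \code{population}, \code{mouse}, \code{experiment}, \code{day}.
#' @param lib a \linkS4class{GuideLibrary}.
#' @param policy an \linkS4class{ExtractionPolicy}.
#' @return A \linkS4class{ScreenCounts}; per-sample mapping statistics are
#'   stored in \code{metadata()$mapping}.
#' @export
countScreen <- function(files, sampleInfo, lib, policy = extractionPolicy()) {
    stopifnot(length(files) == nrow(sampleInfo))
    res <- lapply(files, countSample, lib = lib, policy = policy)
    counts <- vapply(res, guideCounts, integer(nGuides(lib)))
    rownames(counts) <- guideIds(lib)
    colnames(counts) <- names(files)
    cd <- DataFrame(sampleInfo)
    rownames(cd) <- names(files)
    out <- new("ScreenCounts", SummarizedExperiment(
        assays = list(counts = counts), rowData = lib@guides, colData = cd))
    metadata(out) <- list(library = lib, mapping = data.frame(
        sample = names(files),
        mapped = vapply(res, function(x) sum(guideCounts(x)), integer(1)),
        unmapped = vapply(res, nUnmapped, integer(1)),
        total = vapply(res, nTotalReads, integer(1))))
    out
}

#' Counts-per-million normalisation
#'
#' Scales each sample to one million mapped reads:
#' \code{cpm = count * 1e6 / sum(counts)}. The alternative
#' \code{method = "medianControls"} divides each sample by the median
#' count of its non-targeting control guides instead, anchoring the scale
#' to guides with no expected phenotype.
#'
#' @param x a counts matrix (guides x samples) or a
#'   \linkS4class{ScreenCounts}.
#' @param method \code{"cpm"} (default) or \code{"medianControls"}.
#' @param lib required for \code{"medianControls"} on a bare matrix.
#' @return Same shape as the input; for a \linkS4class{ScreenCounts} the
#'   normalised values are added as assay \code{"cpm"}.
#' @examples
#' cpmNormalize(matrix(c(1, 1, 2), ncol = 1))
#' @export
cpmNormalize <- function(x, method = c("cpm", "medianControls"), lib = NULL) {
    method <- match.arg(method)
    if (is(x, "ScreenCounts")) {
        m <- assay(x, "counts")
        if (is.null(lib)) lib <- metadata(x)$library
        norm <- cpmNormalize(m, method = method, lib = lib)
        SummarizedExperiment::assay(x, "cpm") <- norm
        return(x)
    }
    m <- as.matrix(x)
    totals <- colSums(m)
    if (any(totals == 0)) {
        bad <- colnames(m)[totals == 0]
        if (is.null(bad)) bad <- which(totals == 0)
        stop("sample(s) with zero mapped reads: ", paste(bad, collapse = ", "))
    }
    if (method == "cpm") {
        sweep(m, 2, totals, "/") * 1e6
    } else {
        if (is.null(lib))
            stop("medianControls normalisation needs the guide library")
        ctrl <- isControl(lib)
        if (!any(ctrl)) stop("library has no control guides")
        med <- apply(m[ctrl, , drop = FALSE], 2, stats::median)
        if (any(med == 0))
            stop("sample(s) with zero median control count: ",
                paste(colnames(m)[med == 0], collapse = ", "))
        sweep(m, 2, med, "/")
    }
}
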