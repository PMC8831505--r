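#' Emit synthetic amplicon FASTQ for a count column
#'
#' Writes one read per count. Each read embeds the uppercased array-oligo
#' cassette (upstream flank + spacer + downstream flank, 60 nt) of its
#' guide at a random offset inside random-nucleotide padding, then applies
#' independent per-base substitution errors at \code{errorRate}. Qualities
#' are constant Phred+33 'I' (Q40); quality modelling is out of scope.
#'
#' @param counts named non-negative integer vector in library order (names
#'   are guide ids) — typically one column of a \linkS4class{ScreenCounts}.
#' @param lib the \linkS4class{GuideLibrary} the counts refer to.
#' @param path output FASTQ path; a \code{.gz} suffix gzip-compresses.
#' @param readLength read length; must be at least the 60-nt cassette
#'   plus both anchors' worth of context (>= 75 recommended, the
#'   sequencing kit's read length).
#' @param errorRate per-base substitution probability.
#' @param seed optional integer seed.
#' @return \code{path}, invisibly. The file holds \code{sum(counts)}
#'   records in guide order.
#' @seealso [countSample()] for the inverse operation.
#' @export
emitFastq <- function(counts, lib, path, readLength = 75L, errorRate = 0,
        seed = NULL) {
    stopifnot(is(lib, "GuideLibrary"))
    if (length(counts) != nGuides(lib))
        stop("counts must have one entry per library guide")
    if (any(counts < 0)) stop("counts must be non-negative")
    cassette <- toupper(assembleArrayOligo(spacers(lib)))
    casLen <- nchar(cassette[1])
    if (readLength < casLen)
        stop("readLength (", readLength, ") shorter than the ", casLen,
            "-nt flank-spacer-flank cassette")
    .assertScalarNumber(errorRate, "errorRate", 0, 1)

    nReads <- sum(counts)
    seqs <- .withSeed(seed, {
        if (nReads == 0) character(0) else {
            guideIdx <- rep.int(seq_along(counts), counts)
            maxPad <- readLength - casLen
            offset <- if (maxPad > 0) sample.int(maxPad + 1L, nReads,
                replace = TRUE) - 1L else integer(nReads)
            pad <- .randomDNA(nReads, maxPad)
            reads <- paste0(substr(pad, 1L, offset), cassette[guideIdx])
            reads <- paste0(reads,
                substr(pad, maxPad + 1L - (readLength - nchar(reads)), maxPad))
            if (errorRate > 0) reads <- .mutateReads(reads, errorRate)
            reads
        }
    })
    ids <- if (nReads == 0) character(0) else
        paste0("@", rep.int(guideIds(lib), counts), ":", seq_len(nReads))
    qual <- strrep("I", readLength)
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    if (nReads > 0) {
        block <- character(4L * nReads)
        block[seq(1L, by = 4L, length.out = nReads)] <- ids
        block[seq(2L, by = 4L, length.out = nReads)] <- seqs
        block[seq(3L, by = 4L, length.out = nReads)] <- "+"
        block[seq(4L, by = 4L, length.out = nReads)] <- qual
        writeLines(block, con)
    }
    invisible(path)
}

## n random DNA strings of length L (L = 0 gives empty strings).
.randomDNA <- function(n, L) {
    if (L == 0L || n == 0L) return(rep("", n))
    m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## Independent per-base substitutions; an error always changes the base.
.mutateReads <- function(reads, errorRate) {
    L <- nchar(reads[1])
    nErr <- stats::rbinom(length(reads), L, errorRate)
    hit <- which(nErr > 0L)
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
        pos <- sample.int(L, nErr[i])
        for (p in pos) {
            cur <- substr(reads[i], p, p)
            substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1L)
        }
    }
    reads
}
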