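## Cloning-oligo flanks. Array-format oligos carry a partial mU6 sequence
## upstream and a partial tracrRNA sequence downstream of the 20-nt spacer;
## pool-format (array-synthesis) oligos extend both flanks for PCR handles.
## Flanks are kept lowercase and the spacer uppercase so the spacer
## boundaries are unambiguous both visually and programmatically.
.ARRAY_FLANK_UP <- "ggagaaaagccttgtttg"
.ARRAY_FLANK_DOWN <- "gttttagagctaggatcctagc"
.POOL_FLANK_UP <- "caattggagaaaagccttgtttg"
.POOL_FLANK_DOWN <- "gttttagagctaggatcctagcaagtt"

.checkSpacers <- function(spacer) {
    if (!is.character(spacer) || !length(spacer))
        stop("spacer must be a non-empty character vector", call. = FALSE)
    bad <- nchar(spacer) != 20L | grepl("[^ACGT]", spacer)
    if (any(bad))
        stop("invalid spacer (must be 20 nt over A/C/G/T): ",
            paste(utils::head(spacer[bad], 3), collapse = ", "), call. = FALSE)
    invisible(spacer)
}

#' Build a targeted sgRNA library with synthetic spacers
#'
#' Creates a \linkS4class{GuideLibrary} with \code{guidesPerGene} guides for
#' each targeting gene plus \code{nControls} non-targeting control guides
#' (gene symbol \code{"CTRL"}). Spacers are drawn uniformly at random over
#' 20-mers, rejecting duplicates and homopolymer runs of 6 or more;
#' generation is deterministic for a fixed seed. Synthetic spacers stand in
#' for designed guide sequences: sequence identity is irrelevant to the
#' counting and statistics pipeline, only uniqueness matters.
#'
#' @param geneSymbols character vector of unique targeting gene symbols
#'   (must not contain the reserved control symbol \code{"CTRL"}).
#' @param guidesPerGene guides designed per gene (e.g. 5 for a
#'   primary-immunodeficiency library, 4 for larger libraries).
#' @param nControls number of non-targeting control guides.
#' @param seed integer seed for spacer generation.
#' @param name library name.
#' @return A \linkS4class{GuideLibrary}.
#' @examples
#' lib <- buildLibrary(paste0("Gene", 1:10), guidesPerGene = 4,
#'     nControls = 8, seed = 1)
#' nGuides(lib)  # 48
#' @export
buildLibrary <- function(geneSymbols, guidesPerGene = 4L, nControls = 0L,
        seed = 1L, name = "library") {
    if (!is.character(geneSymbols) || !length(geneSymbols))
        stop("geneSymbols must be a non-empty character vector")
    if (anyDuplicated(geneSymbols))
        stop("duplicate gene symbols: ",
            paste(unique(geneSymbols[duplicated(geneSymbols)]), collapse = ", "))
    if (.CONTROL_GENE %in% geneSymbols)
        stop(sprintf("gene symbol \"%s\" is reserved for non-targeting controls",
            .CONTROL_GENE))
    guidesPerGene <- as.integer(guidesPerGene)
    nControls <- as.integer(nControls)
    if (guidesPerGene < 1L) stop("guidesPerGene must be >= 1")
    if (nControls < 0L) stop("nControls must be >= 0")
    nTarget <- length(geneSymbols) * guidesPerGene
    n <- nTarget + nControls
    if (n > 1e6)
        stop("cannot generate ", n, " unique spacers; reduce the library size")

    spacer <- .withSeed(seed, .generateSpacers(n))
    gene <- c(rep(geneSymbols, each = guidesPerGene), rep(.CONTROL_GENE, nControls))
    id <- c(paste0(rep(geneSymbols, each = guidesPerGene), "_sg",
            rep(seq_len(guidesPerGene), times = length(geneSymbols))),
        if (nControls > 0L) paste0(.CONTROL_GENE, "_sg", seq_len(nControls)))
    guides <- DataFrame(
        guide_id = id,
        gene_symbol = gene,
        spacer = spacer,
        is_control = gene == .CONTROL_GENE
    )
    rownames(guides) <- id
    new("GuideLibrary", guides = guides, guidesPerGene = guidesPerGene,
        name = as.character(name))
}

## Uniform random 20-mers, rejecting homopolymer runs >= 6 and duplicates.
.generateSpacers <- function(n) {
    out <- character(0)
    bases <- c("A", "C", "G", "T")
    homopolymer <- "A{6,}|C{6,}|G{6,}|T{6,}"
    tries <- 0L
    while (length(out) < n) {
        tries <- tries + 1L
        if (tries > 50L)
            stop("spacer generation failed to reach uniqueness", call. = FALSE)
        m <- matrix(sample(bases, 20L * (n - length(out) + 16L), replace = TRUE),
            ncol = 20L)
        cand <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
        cand <- cand[!grepl(homopolymer, cand)]
        out <- unique(c(out, cand))
    }
    out[seq_len(n)]
}

#' Assemble cloning oligos for a spacer
#'
#' \code{assembleArrayOligo()} flanks a 20-nt spacer with the array-format
#' cloning sequences (partial mU6 upstream, partial tracrRNA downstream);
#' \code{assemblePoolOligo()} uses the extended pooled-synthesis flanks.
#' Flanks are lowercase, the spacer uppercase. Both are vectorised and
#' injective in the spacer.
#'
#' @param spacer character vector of 20-nt uppercase spacers.
#' @return Character vector of oligo sequences (60 nt for array format,
#'   70 nt for pool format).
#' @examples
#' assembleArrayOligo("ACGTACGTACGTACGTACGT")
#' @export
assembleArrayOligo <- function(spacer) {
    .checkSpacers(spacer)
    paste0(.ARRAY_FLANK_UP, spacer, .ARRAY_FLANK_DOWN)
}

#' @rdname assembleArrayOligo
#' @export
assemblePoolOligo <- function(spacer) {
    .checkSpacers(spacer)
    paste0(.POOL_FLANK_UP, spacer, .POOL_FLANK_DOWN)
}

#' Read and write guide libraries
#'
#' Libraries round-trip losslessly through a four-column CSV
#' (\code{guide_id}, \code{gene_symbol}, \code{spacer}, \code{is_control}).
#' \code{writeGuideLibrary()} optionally also writes a FASTA of spacers
#' (one record per guide, id = guide_id). \code{readGuideLibrary()}
#' validates each row and reports offending row numbers.
#'
#' @param lib a \linkS4class{GuideLibrary}.
#' @param path CSV file path.
#' @param fastaPath optional path for a spacer FASTA export.
#' @param name library name for the object read back.
#' @return \code{readGuideLibrary()} returns a \linkS4class{GuideLibrary};
#'   \code{writeGuideLibrary()} returns \code{path} invisibly.
#' @export
writeGuideLibrary <- function(lib, path, fastaPath = NULL) {
    stopifnot(is(lib, "GuideLibrary"))
    df <- as.data.frame(lib@guides)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    if (!is.null(fastaPath))
        exportSpacersFasta(lib, fastaPath)
    invisible(path)
}

#' @rdname writeGuideLibrary
#' @export
readGuideLibrary <- function(path, name = tools::file_path_sans_ext(basename(path))) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
        colClasses = c(guide_id = "character", gene_symbol = "character",
            spacer = "character", is_control = "logical"))
    need <- c("guide_id", "gene_symbol", "spacer", "is_control")
    if (!all(need %in% colnames(df)))
        stop("library CSV must have columns: ", paste(need, collapse = ", "))
    bad <- which(nchar(df$spacer) != 20L | grepl("[^ACGT]", df$spacer))
    if (length(bad))
        stop("invalid spacer at row(s): ", paste(utils::head(bad, 5), collapse = ", "),
            " (spacers must be 20 nt over A/C/G/T)")
    dupId <- which(duplicated(df$guide_id))
    if (length(dupId))
        stop("duplicate guide_id at row(s): ",
            paste(utils::head(dupId, 5), collapse = ", "))
    dupSp <- which(duplicated(df$spacer))
    if (length(dupSp))
        stop("duplicate spacer at row(s): ",
            paste(utils::head(dupSp, 5), collapse = ", "))
    gpgTab <- table(df$gene_symbol[!df$is_control])
    gpg <- if (length(gpgTab)) as.integer(max(gpgTab)) else 1L
    guides <- DataFrame(df)
    rownames(guides) <- df$guide_id
    new("GuideLibrary", guides = guides, guidesPerGene = gpg,
        name = as.character(name))
}

#' @rdname writeGuideLibrary
#' @export
exportSpacersFasta <- function(lib, path) {
    stopifnot(is(lib, "GuideLibrary"))
    seqs <- Biostrings::DNAStringSet(spacers(lib))
    names(seqs) <- guideIds(lib)
    Biostrings::writeXStringSet(seqs, filepath = path)
    invisible(path)
}

#' Accessors for GuideLibrary
#'
#' @param x a \linkS4class{GuideLibrary}.
#' @return \code{guideIds()}, \code{geneSymbols()}, \code{spacers()} return
#'   character vectors; \code{isControl()} a logical vector; \code{nGuides()}
#'   and \code{guidesPerGene()} integers; \code{libraryName()} a string.
#' @name GuideLibrary-accessors
NULL

#' @rdname GuideLibrary-accessors
#' @export
setMethod("guideIds", "GuideLibrary", function(x) x@guides$guide_id)

#' @rdname GuideLibrary-accessors
#' @export
setMethod("geneSymbols", "GuideLibrary", function(x) x@guides$gene_symbol)

#' @rdname GuideLibrary-accessors
#' @export
setMethod("spacers", "GuideLibrary", function(x) {
    s <- x@guides$spacer
    names(s) <- x@guides$guide_id
    s
})

#' @rdname GuideLibrary-accessors
#' @export
setMethod("isControl", "GuideLibrary", function(x) x@guides$is_control)

#' @rdname GuideLibrary-accessors
#' @export
setMethod("nGuides", "GuideLibrary", function(x) nrow(x@guides))

#' @rdname GuideLibrary-accessors
#' @export
setMethod("guidesPerGene", "GuideLibrary", function(x) x@guidesPerGene)

#' @rdname GuideLibrary-accessors
#' @export
setMethod("libraryName", "GuideLibrary", function(x) x@name)

setMethod("show", "GuideLibrary", function(object) {
    g <- object@guides
    cat("GuideLibrary \"", object@name, "\": ", nrow(g), " guides (",
        sum(!g$is_control), " targeting ",
        length(unique(g$gene_symbol[!g$is_control])), " genes at ",
        object@guidesPerGene, "/gene, ", sum(g$is_control),
        " non-targeting controls)\n", sep = "")
})

#' Group control guides into pseudo-genes
#'
#' Non-targeting controls carry no shared gene, so gene-level null
#' statistics (Z-score anchoring, permutation baselines) group them into
#' consecutive pseudo-genes of \code{guidesPerGene(lib)} guides each (the
#' final pseudo-gene may be smaller). Returns a factor over control guide
#' ids, or a zero-length factor when the library has no controls.
#'
#' @param lib a \linkS4class{GuideLibrary}.
#' @return Named factor mapping control guide_id to pseudo-gene label
#'   (\code{"CTRL.1"}, \code{"CTRL.2"}, ...).
#' @export
controlPseudoGenes <- function(lib) {
    stopifnot(is(lib, "GuideLibrary"))
    ids <- guideIds(lib)[isControl(lib)]
    k <- guidesPerGene(lib)
    lab <- paste0(.CONTROL_GENE, ".", (seq_along(ids) - 1L) %/% k + 1L)
    structure(factor(lab, levels = unique(lab)), names = ids)
}
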