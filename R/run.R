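## Schema of the end-to-end run configuration: every leaf has a default,
## unknown keys are rejected.
.runConfigDefaults <- function() {
    list(
        seed = 1L,
        output = list(dir = "tfhscreen_run"),
        library = list(
            n_genes = 20L,
            guides_per_gene = 4L,
            n_controls = 12L,
            name = "demo"
        ),
        truth = list(
            n_tfh_genes = 2L,
            tfh_logit_shift = -2,
            n_fitness_genes = 0L,
            invivo_fitness = -0.3
        ),
        simulator = list(
            plasmid_sigma = 0.5,
            culture_start_cells = 2e4,
            culture_doublings = 6,
            transfer_pool_size = 5e4,
            engraftment_rate = 0.10,
            invivo_doublings = 8,
            baseline_tfh_logit = 0,
            gc_tfh_fraction = 0.5,
            sort_coverage = 750,
            seq_depth = 300,
            sort_purity = 0.95,
            pcr_shape = 10,
            n_mice = 3L,
            n_experiments = 2L,
            pooled_sort = FALSE
        ),
        extraction = list(
            from_fastq = TRUE,
            read_length = 75L,
            error_rate = 0.001,
            anchor_mismatches = 0L,
            spacer_mismatches = 1L
        ),
        statistics = list(
            comparisons = c("Tfh_vs_Th1", "Tfh_vs_culture", "Th1_vs_culture"),
            pseudocount = 0.5,
            rra_alpha = 0.25,
            n_perm = 2000L,
            fdr_alpha = 0.25,
            depletion_threshold = -1,
            enrichment_threshold = 1
        ),
        power = list(
            enabled = FALSE,
            frequencies = c(1 / 100, 1 / 1000),
            effect = -2,
            n_reps = 10L
        )
    )
}

#' Validate and complete an end-to-end run configuration
#'
#' Fills missing keys with defaults and rejects unknown keys, naming the
#' offending key.
#'
#' @param config nested list, e.g. from [readRunConfig()].
#' @return The completed configuration list.
#' @export
validateRunConfig <- function(config = list()) {
    .mergeSchema(config, .runConfigDefaults(), path = "")
}

.mergeSchema <- function(given, defaults, path) {
    if (!is.list(defaults)) return(given)
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown))
        stop("unknown configuration key(s): ",
            paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                collapse = ", "))
    out <- defaults
    for (k in names(given)) {
        out[[k]] <- if (is.list(defaults[[k]]))
            .mergeSchema(given[[k]], defaults[[k]], paste0(path, ".", k))
        else given[[k]]
    }
    out
}

#' Read an end-to-end run configuration from YAML
#'
#' @param path YAML file with any subset of the keys of
#'   [validateRunConfig()]'s schema.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
    validateRunConfig(yaml::read_yaml(path))
}

#' Run the pipeline end to end
#'
#' Executes the full demonstration path on synthetic data: build library
#' -> plant ground-truth effects -> simulate the screen -> (optionally)
#' emit per-sample FASTQ and re-count it -> gene-level statistics for the
#' configured comparisons -> quadrant classification -> (optionally)
#' spike-in power. All outputs are written under the configured output
#' directory along with \code{manifest.json} recording the seed, package
#' version and an md5 for every file, and \code{run.log} with stage
#' timings. A single master seed fans out to per-stage seeds, so the run
#' is fully reproducible.
#'
#' @param config configuration list (see [validateRunConfig()]); missing
#'   keys take defaults.
#' @param outDir output directory, overriding \code{config$output$dir}.
#' @param quiet suppress console log messages.
#' @return Invisibly, a list with \code{library}, \code{truth},
#'   \code{counts} (\linkS4class{ScreenCounts}), \code{results} (named
#'   list of gene tables), \code{categories}, \code{power} and
#'   \code{manifest}.
#' @export
runEndToEnd <- function(config = list(), outDir = NULL, quiet = FALSE) {
    config <- validateRunConfig(config)
    if (!is.null(outDir)) config$output$dir <- outDir
    dir.create(config$output$dir, recursive = TRUE, showWarnings = FALSE)
    logPath <- file.path(config$output$dir, "run.log")
    logLines <- character(0)
    logMsg <- function(...) {
        line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
        logLines <<- c(logLines, line)
        if (!quiet) message(line)
    }
    seed <- as.integer(config$seed)
    outFiles <- character(0)
    emit <- function(name) {
        outFiles <<- c(outFiles, file.path(config$output$dir, name))
        file.path(config$output$dir, name)
    }
    stageFail <- function(stageName, e)
        stop("stage '", stageName, "' failed: ", conditionMessage(e),
            " (partial outputs kept in ", config$output$dir, ")",
            call. = FALSE)

    ## -- library -----------------------------------------------------
    lc <- config$library
    lib <- tryCatch({
        genes <- sprintf("GENE%03d", seq_len(lc$n_genes))
        buildLibrary(genes, lc$guides_per_gene, lc$n_controls,
            seed = .stageSeed(seed, 1L), name = lc$name)
    }, error = function(e) stageFail("library", e))
    writeGuideLibrary(lib, emit("library.csv"), fastaPath = emit("spacers.fasta"))
    logMsg("library: ", nGuides(lib), " guides (",
        lc$n_genes, " genes x ", lc$guides_per_gene, " + ",
        lc$n_controls, " controls)")

    ## -- truth -------------------------------------------------------
    tc <- config$truth
    genes <- setdiff(unique(geneSymbols(lib)), .CONTROL_GENE)
    shift <- structure(rep(tc$tfh_logit_shift, tc$n_tfh_genes),
        names = utils::head(genes, tc$n_tfh_genes))
    fitGenes <- utils::head(setdiff(genes, names(shift)), tc$n_fitness_genes)
    fit <- structure(rep(tc$invivo_fitness, length(fitGenes)), names = fitGenes)
    truth <- screenTruth(lib,
        tfhLogitShift = if (length(shift)) shift else 0,
        invivoFitness = if (length(fit)) fit else 0)
    utils::write.csv(data.frame(gene = truth@gene,
        invitro_fitness = truth@invitroFitness,
        invivo_fitness = truth@invivoFitness,
        tfh_logit_shift = truth@tfhLogitShift),
        emit("truth.csv"), row.names = FALSE, quote = FALSE)
    logMsg("truth: ", tc$n_tfh_genes, " Tfh-shifted gene(s) at ",
        tc$tfh_logit_shift)

    ## -- simulate ----------------------------------------------------
    sp <- config$simulator
    scfg <- screenConfig(plasmidSigma = sp$plasmid_sigma,
        cultureStartCells = sp$culture_start_cells,
        cultureDoublings = sp$culture_doublings,
        transferPoolSize = sp$transfer_pool_size,
        engraftmentRate = sp$engraftment_rate,
        invivoDoublings = sp$invivo_doublings,
        baselineTfhLogit = sp$baseline_tfh_logit,
        gcTfhFraction = sp$gc_tfh_fraction,
        sortCoverage = sp$sort_coverage,
        seqDepth = sp$seq_depth,
        sortPurity = sp$sort_purity,
        pcrShape = sp$pcr_shape,
        nMice = sp$n_mice,
        nExperiments = sp$n_experiments,
        pooledSort = sp$pooled_sort,
        seed = .stageSeed(seed, 2L))
    sim <- tryCatch(simulateScreen(lib, truth, scfg),
        error = function(e) stageFail("simulate", e))
    logMsg("simulate: ", ncol(sim), " samples")

    ## -- fastq + count (or direct counts) ----------------------------
    ec <- config$extraction
    counts <- sim
    if (isTRUE(ec$from_fastq)) {
        fqDir <- file.path(config$output$dir, "fastq")
        dir.create(fqDir, showWarnings = FALSE)
        policy <- extractionPolicy(anchorMismatches = ec$anchor_mismatches,
            spacerMismatches = ec$spacer_mismatches)
        files <- character(0)
        for (j in seq_len(ncol(sim))) {
            f <- file.path(fqDir, paste0(colnames(sim)[j], ".fastq.gz"))
            emitFastq(assay(sim, "counts")[, j], lib, f,
                readLength = ec$read_length, errorRate = ec$error_rate,
                seed = .stageSeed(seed, 100L + j))
            files[colnames(sim)[j]] <- f
        }
        outFiles <- c(outFiles, unname(files))
        counts <- tryCatch(
            countScreen(files, as.data.frame(colData(sim)), lib, policy),
            error = function(e) stageFail("count", e))
        metadata(counts)$truth <- truth
        metadata(counts)$config <- scfg
        utils::write.table(metadata(counts)$mapping,
            emit("mapping_stats.tsv"), sep = "\t", row.names = FALSE,
            quote = FALSE)
        mapped <- sum(metadata(counts)$mapping$mapped)
        total <- sum(metadata(counts)$mapping$total)
        logMsg("count: ", mapped, "/", total, " reads mapped (",
            round(100 * mapped / total, 2), "%)")
    }
    utils::write.table(
        data.frame(guide_id = rownames(counts), assay(counts, "counts"),
            check.names = FALSE),
        emit("counts.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.csv(
        data.frame(sample_id = colnames(counts),
            as.data.frame(colData(counts))),
        emit("samples.csv"), row.names = FALSE, quote = FALSE)

    ## -- statistics --------------------------------------------------
    st <- config$statistics
    results <- list()
    for (cmpName in st$comparisons) {
        tab <- tryCatch(
            screenResults(counts, cmpName, pseudocount = st$pseudocount,
                alpha = st$rra_alpha, nPerm = st$n_perm,
                seed = .stageSeed(seed, 3L)),
            error = function(e) stageFail(paste0("analyze:", cmpName), e))
        results[[cmpName]] <- tab
        utils::write.table(tab, emit(paste0("gene_results_", cmpName, ".tsv")),
            sep = "\t", row.names = FALSE, quote = FALSE)
        nHit <- sum(tab$fdr < st$fdr_alpha, na.rm = TRUE)
        logMsg("analyze ", cmpName, ": ", nHit, " gene(s) at FDR < ",
            st$fdr_alpha)
    }
    categories <- NULL
    if (all(c("Tfh_vs_culture", "Th1_vs_culture") %in% names(results))) {
        a <- results$Tfh_vs_culture; b <- results$Th1_vs_culture
        common <- intersect(a$gene[!a$is_control], b$gene[!b$is_control])
        categories <- classifyHits(
            structure(a$mean_l2fc[match(common, a$gene)], names = common),
            structure(b$mean_l2fc[match(common, b$gene)], names = common),
            st$depletion_threshold, st$enrichment_threshold)
        utils::write.csv(data.frame(gene = names(categories),
            category = as.character(categories)),
            emit("hit_categories.csv"), row.names = FALSE, quote = FALSE)
        logMsg("classify: ",
            sum(categories != "neutral"), " non-neutral gene(s)")
    }

    ## -- power (optional) --------------------------------------------
    powerTab <- NULL
    if (isTRUE(config$power$enabled)) {
        grid <- powerGrid(spikeFrequencies = config$power$frequencies,
            effectSizes = config$power$effect,
            coverages = sp$sort_coverage, nReps = config$power$n_reps)
        powerTab <- tryCatch(
            titrationPower(lib, grid, scfg, seed = .stageSeed(seed, 4L)),
            error = function(e) stageFail("power", e))
        utils::write.table(powerTab, emit("power.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
        logMsg("power: ", nrow(powerTab), " grid cell(s)")
    }

    ## -- manifest ----------------------------------------------------
    writeLines(logLines, logPath)
    outFiles <- c(outFiles, logPath)
    manifest <- list(
        package = "tfhscreen",
        version = as.character(utils::packageVersion("tfhscreen")),
        seed = seed,
        files = lapply(stats::setNames(outFiles, basename(outFiles)),
            function(f) unname(tools::md5sum(f))))
    jsonlite::write_json(manifest,
        file.path(config$output$dir, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE)
    logMsg("done: manifest with ", length(outFiles), " file(s)")

    invisible(list(library = lib, truth = truth, counts = counts,
        results = results, categories = categories, power = powerTab,
        manifest = manifest))
}
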