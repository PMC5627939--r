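#' Pipeline configuration
#'
#' Declares the inputs and thresholds for an end-to-end serial-case run.
#' Sample order is chronological and defines the replacement-detection
#' axis. Copy-number input is either per-bin counts (segmented
#' internally) or a precomputed SEG file; catalog and expression inputs
#' are optional — their stages are skipped and flagged when absent.
#'
#' @param variant_files named character vector, chronological:
#'   sample label -> MAF-like TSV path.
#' @param cn_bin_file TSV of per-bin counts (\code{sample_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{tumor_count},
#'   \code{normal_count}), or \code{NULL}.
#' @param seg_file precomputed SEG path (bypasses segmentation), or
#'   \code{NULL}.
#' @param fusion_file fusion TSV path, or \code{NULL}.
#' @param catalog_file MAF catalog path, or \code{NULL}.
#' @param expression_file,reference_rpkm_file,gene_bed expression stage
#'   inputs, or \code{NULL}.
#' @param min_depth,min_vaf,max_normal_vaf somatic filter thresholds.
#' @param min_depth_all cross-sample competence depth.
#' @param presence_vaf strict presence threshold for clone tracking.
#' @param min_clone_size,merge_hamming clone partition parameters.
#' @param min_log2,max_span_bp focal-amplification thresholds.
#' @param purity,normal_ploidy copy-estimation model.
#' @param fusion_tolerance_bp breakpoint concordance tolerance.
#' @param min_fold candidate fold threshold.
#' @param out_dir directory for stage outputs, or \code{NULL} to skip
#'   persistence.
#' @param seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return validated \code{PipelineConfig} (list).
#' @export
pipelineConfig <- function(variant_files,
                           cn_bin_file = NULL, seg_file = NULL,
                           fusion_file = NULL, catalog_file = NULL,
                           expression_file = NULL,
                           reference_rpkm_file = NULL,
                           gene_bed = NULL,
                           min_depth = 20, min_vaf = 0.20,
                           max_normal_vaf = 0.0, min_depth_all = 20,
                           presence_vaf = 0.10, min_clone_size = 2,
                           merge_hamming = 1,
                           min_log2 = 0.5, max_span_bp = 10e6,
                           purity = 1.0, normal_ploidy = 2,
                           fusion_tolerance_bp = 0, min_fold = 5,
                           out_dir = NULL, seed = 1L) {
    stopIfNot1(length(variant_files) >= 2,
               "need >= 2 chronological samples")
    stopIfNot1(!is.null(names(variant_files)) &&
                   all(nzchar(names(variant_files))),
               "variant_files must be named by sample label")
    stopIfNot1(!anyDuplicated(names(variant_files)),
               "sample labels must be unique")
    paths <- c(variant_files, cn_bin_file, seg_file, fusion_file,
               catalog_file, expression_file, reference_rpkm_file,
               gene_bed)
    missing <- paths[!vapply(paths, file.exists, TRUE)]
    if (length(missing))
        stop(sprintf("input file(s) not found: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    cfg <- as.list(environment())
    cfg$paths <- NULL
    cfg$missing <- NULL
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Run the serial-case pipeline end to end
#'
#' Executes the stages in dependency order: per-sample somatic filtering,
#' cross-sample harmonization, clone partitioning and replacement
#' detection, copy-number segmentation with focal-amplification calling,
#' fusion breakpoint concordance with copy estimation, catalog
#' silent-fraction/recurrence summaries, and amplified-gene expression
#' ranking. Every report field is a stage output; intermediates are
#' persisted under \code{config$out_dir} when set. A stage whose input is
#' absent is skipped and flagged in \code{provenance$skipped}.
#'
#' @param config a [pipelineConfig()].
#' @return a [CaseReport-class].
#' @export
runPipeline <- function(config) {
    stopIfNot1(inherits(config, "PipelineConfig"),
               "config must come from pipelineConfig()")
    labs <- names(config$variant_files)
    skipped <- character()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }

    ## variant_io
    raw <- stage("variant_io", {
        out <- lapply(labs, function(s)
            readVariantTable(config$variant_files[[s]],
                             format = "maf_tsv", sample_id = s))
        names(out) <- labs
        out
    })
    filtered <- lapply(raw, filterSomatic,
                       min_depth = config$min_depth,
                       min_vaf = config$min_vaf,
                       max_normal_vaf = config$max_normal_vaf)
    filterReport <- lapply(filtered, attr, "filter_report")
    somaticKeys <- unique(unlist(lapply(filtered, function(x)
        with(x, variantKey(chrom, pos, ref, alt)))))
    vm <- stage("harmonize",
        harmonizeAcrossSamples(raw, min_depth_all = config$min_depth_all,
                               keys = somaticKeys))

    ## clone_tracking
    partition <- stage("clone_tracking",
        partitionClones(vm, min_clone_size = config$min_clone_size,
                        merge_hamming = config$merge_hamming,
                        presence_vaf = config$presence_vaf))
    events <- detectReplacement(partition)

    ## copy_number
    focalAmps <- list()
    segsBySample <- list()
    if (!is.null(config$seg_file) || !is.null(config$cn_bin_file)) {
        segs <- stage("copy_number", {
            if (!is.null(config$seg_file)) {
                readSegFile(config$seg_file)
            } else {
                bins <- utils::read.delim(config$cn_bin_file,
                                          stringsAsFactors = FALSE)
                grl <- lapply(split(bins, bins$sample_id), function(b)
                    computeLog2Ratios(b, sample_id = b$sample_id[1]))
                do.call(c, unname(grl))
            }
        })
        bySample <- split(segs, S4Vectors::mcols(segs)$sample_id)
        segsBySample <- as.list(bySample)
        focalAmps <- lapply(segsBySample, callFocalAmplifications,
                            min_log2 = config$min_log2,
                            max_span_bp = config$max_span_bp)
        focalAmps <- focalAmps[intersect(labs, names(focalAmps))]
    } else skipped <- c(skipped, "copy_number")

    ## fusion concordance
    fusion <- list()
    if (!is.null(config$fusion_file)) {
        fusion <- stage("fusion", {
            ev <- readFusionTable(config$fusion_file)
            breakpointConcordance(ev,
                                  tolerance_bp = config$fusion_tolerance_bp,
                                  purity = config$purity)
        })
    } else skipped <- c(skipped, "fusion")

    ## mutation_catalog
    geneSummaries <- data.frame()
    if (!is.null(config$catalog_file)) {
        geneSummaries <- stage("mutation_catalog", {
            cat0 <- readMafCatalog(config$catalog_file)
            catF <- filterCatalog(cat0)
            asg <- cloneAssignment(partition)
            vars <- asg[asg$clone != "unassigned",
                        c("gene", "chrom", "pos", "ref", "alt"),
                        drop = FALSE]
            catalogSummaryTable(catF, vars)
        })
    } else skipped <- c(skipped, "mutation_catalog")

    ## expression_rank
    candidates <- data.frame()
    if (!is.null(config$expression_file) &&
        !is.null(config$reference_rpkm_file) &&
        !is.null(config$gene_bed)) {
        candidates <- stage("expression_rank", {
            expr <- readExpressionTable(config$expression_file)
            refM <- readReferenceRpkm(config$reference_rpkm_file)
            anno <- readBedGenes(config$gene_bed)
            fc <- rankAmplifiedGenes(expr, refM)
            ampUnion <- if (length(focalAmps))
                unique(do.call(rbind, lapply(focalAmps, function(g)
                    data.frame(
                        chrom = as.character(GenomicRanges::seqnames(g)),
                        start = GenomicRanges::start(g),
                        end = GenomicRanges::end(g),
                        stringsAsFactors = FALSE))))
            else data.frame(chrom = character(), start = numeric(),
                            end = numeric())
            prioritizeCandidates(ampUnion, anno, fc,
                                 min_fold = config$min_fold)
        })
    } else skipped <- c(skipped, "expression_rank")

    report <- methods::new("CaseReport",
        filterReport = filterReport,
        partition = partition,
        replacementEvents = events,
        focalAmps = focalAmps,
        fusion = fusion,
        geneSummaries = geneSummaries,
        candidates = candidates,
        provenance = list(
            sample_labels = labs,
            thresholds = config[c("min_depth", "min_vaf",
                                  "max_normal_vaf", "min_depth_all",
                                  "presence_vaf", "min_log2",
                                  "max_span_bp", "purity", "min_fold",
                                  "fusion_tolerance_bp")],
            skipped = skipped,
            seed = config$seed,
            package_version =
                as.character(utils::packageVersion("clonetracker"))))

    if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
        writeVafMatrix(vm, file.path(config$out_dir, "vaf_matrix.tsv"))
        utils::write.table(cloneAssignment(partition),
                           file.path(config$out_dir, "clone_assignment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (length(segsBySample))
            writeSegFile(do.call(c, unname(segsBySample)),
                         file.path(config$out_dir, "segments.seg"))
        writeCaseReport(report,
                        file.path(config$out_dir, "case_report.json"))
    }
    report
}

reportAsList <- function(report) {
    part <- report@partition
    fus <- report@fusion
    list(
        filter_report = report@filterReport,
        clone_sizes = as.list(cloneSizes(part)),
        exclusivity_index = exclusivityIndex(part),
        presence_fraction = as.data.frame(part@presenceFraction),
        replacement_events = report@replacementEvents,
        focal_amplifications = lapply(report@focalAmps, function(g)
            data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                       start = GenomicRanges::start(g),
                       end = GenomicRanges::end(g),
                       log2_ratio = S4Vectors::mcols(g)$log2_ratio,
                       stringsAsFactors = FALSE)),
        fusion = if (length(fus))
            list(concordant = fus$concordant,
                 common_founder = fus$common_founder,
                 per_sample = fus$per_sample)
        else NULL,
        gene_summaries = report@geneSummaries,
        candidates = report@candidates,
        provenance = report@provenance)
}

#' Write a case report as JSON
#'
#' Deterministic serialization (no timestamps): identical inputs and
#' thresholds produce byte-identical report files.
#'
#' @param report a [CaseReport-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCaseReport <- function(report, path) {
    jsonlite::write_json(reportAsList(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}

setMethod("show", "CaseReport", function(object) {
    cat("CaseReport —", length(object@provenance$sample_labels),
        "serial samples\n")
    sz <- cloneSizes(object@partition)
    cat("  clones:",
        paste(sprintf("%s=%d", names(sz), sz), collapse = ", "), "\n")
    if (nrow(object@replacementEvents)) {
        ev <- object@replacementEvents
        cat(sprintf("  replacement: %s -> %s between %s and %s\n",
                    ev$clone_out[1], ev$clone_in[1],
                    ev$from_sample[1], ev$to_sample[1]))
    } else cat("  replacement: none detected\n")
    if (length(object@fusion))
        cat("  fusion concordant:", object@fusion$concordant,
            "| copies:",
            paste(object@fusion$per_sample$copy_estimate, collapse = ","),
            "\n")
    nAmp <- vapply(object@focalAmps, length, 0L)
    if (length(nAmp))
        cat("  focal amps per sample:",
            paste(sprintf("%s=%d", names(nAmp), nAmp), collapse = ", "),
            "\n")
    if (nrow(object@candidates))
        cat("  top candidate:", object@candidates$gene[1],
            sprintf("(x%d)", object@candidates$fold_change_display[1]),
            "\n")
    if (length(object@provenance$skipped))
        cat("  skipped stages:",
            paste(object@provenance$skipped, collapse = ", "), "\n")
})

#' Build a pipeline configuration from a fixture directory
#'
#' Convenience for cohorts written by [writeFixtures()]: locates the
#' per-sample variant TSVs, bin/fusion/expression files and gene BED in
#' \code{dir} and assembles a [pipelineConfig()].
#'
#' @param dir directory written by [writeFixtures()].
#' @param sample_labels chronological sample labels.
#' @param ... threshold overrides passed to [pipelineConfig()].
#' @return a \code{PipelineConfig}.
#' @export
pipelineConfigFromFixtures <- function(dir, sample_labels, ...) {
    vf <- file.path(dir, paste0(sample_labels, ".variants.tsv"))
    names(vf) <- sample_labels
    maybe <- function(f) {
        p <- file.path(dir, f)
        if (file.exists(p)) p else NULL
    }
    pipelineConfig(
        variant_files = vf,
        cn_bin_file = maybe("cn_bins.tsv"),
        fusion_file = maybe("fusions.tsv"),
        expression_file = maybe("expression.tsv"),
        reference_rpkm_file = maybe("reference_rpkm.tsv"),
        gene_bed = maybe("genes.bed"),
        ...)
}
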