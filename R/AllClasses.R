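#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' VafMatrix: variant allele fractions across serial samples
#'
#' A \linkS4class{SummarizedExperiment} subclass holding the harmonized
#' variants-by-samples grid that clone tracking operates on. Two assays are
#' mandatory: \code{"vaf"} (variant allele fraction, in \code{[0,1]}) and
#' \code{"depth"} (total read depth at the locus). Cells that were never
#' observed in a sample (locus not covered) are \code{NA} in both assays;
#' this is distinct from a covered locus with no variant reads, which has
#' \code{vaf = 0}. Row metadata carries the variant key (\code{chrom},
#' \code{pos}, \code{ref}, \code{alt}) plus \code{gene}; columns are the
#' serial samples in chronological order.
#'
#' @seealso [harmonizeAcrossSamples()] which constructs the object,
#'   [callPresence()] and [partitionClones()] which consume it.
#' @export
setClass("VafMatrix", contains = "SummarizedExperiment")

setValidity("VafMatrix", function(object) {
    msg <- character()
    an <- names(SummarizedExperiment::assays(object))
    if (!all(c("vaf", "depth") %in% an))
        msg <- c(msg, "assays 'vaf' and 'depth' are required")
    else {
        v <- SummarizedExperiment::assay(object, "vaf")
        d <- SummarizedExperiment::assay(object, "depth")
        if (!identical(dim(v), dim(d)))
            msg <- c(msg, "'vaf' and 'depth' dimensions differ")
        ok <- is.na(v) | (v >= 0 & v <= 1)
        if (!all(ok))
            msg <- c(msg, "observed vaf values must lie in [0,1]")
        if (any(is.na(v) != is.na(d)))
            msg <- c(msg, "missingness of 'vaf' and 'depth' must agree")
    }
    rd <- SummarizedExperiment::rowData(object)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, sprintf("rowData must contain %s",
                              paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' ClonePartition: assignment of variants to subclones
#'
#' Result of [partitionClones()]: each harmonized variant is labeled with
#' exactly one of the clone identifiers (\code{"A"}, \code{"B"}, ...),
#' \code{"shared"} (present in every sample) or \code{"unassigned"}
#' (profile too rare to define a clone). Per-clone consensus presence
#' profiles and per-sample presence fractions support replacement
#' detection, and the exclusivity index quantifies how mutually exclusive
#' the clone-defining sets are across the serial samples.
#'
#' @slot assignment data.frame with columns \code{key}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{gene}, \code{clone}.
#' @slot profiles logical matrix, clones x samples: the consensus presence
#'   profile of each clone.
#' @slot presenceFraction numeric matrix, clones x samples: fraction of the
#'   clone's variants called present in each sample.
#' @slot exclusivityIndex numeric in \code{[0,1]}; 1 means the clone sets
#'   are perfectly mutually exclusive across their characteristic samples.
#' @slot sampleLabels character, chronological sample identifiers.
#' @export
setClass("ClonePartition",
    representation(
        assignment = "data.frame",
        profiles = "matrix",
        presenceFraction = "matrix",
        exclusivityIndex = "numeric",
        sampleLabels = "character"
    )
)

setValidity("ClonePartition", function(object) {
    msg <- character()
    if (!all(c("key", "clone") %in% colnames(object@assignment)))
        msg <- c(msg, "assignment needs 'key' and 'clone' columns")
    if (anyDuplicated(object@assignment$key))
        msg <- c(msg, "every variant must be labeled exactly once")
    ei <- object@exclusivityIndex
    if (length(ei) == 1 && !is.na(ei) && (ei < 0 || ei > 1))
        msg <- c(msg, "exclusivityIndex must lie in [0,1]")
    if (length(msg)) msg else TRUE
})

#' CaseReport: consolidated serial-case analysis report
#'
#' Aggregates the outputs of all pipeline stages for one case. Every number
#' in the report is a stage output; the report performs no computation of
#' its own.
#'
#' @slot filterReport list of per-sample somatic filter counts.
#' @slot partition the [ClonePartition-class] (or \code{NULL} if the clone
#'   stage was skipped).
#' @slot replacementEvents data.frame of clonal replacement events.
#' @slot focalAmps per-sample list of focal-amplification segments
#'   (\code{GRanges}).
#' @slot fusion list: concordance verdict, per-sample breakpoints and copy
#'   estimates.
#' @slot geneSummaries data.frame of per-gene mutation-catalog summaries.
#' @slot candidates data.frame of ranked amplified/overexpressed genes.
#' @slot provenance list: thresholds used, seed, package version.
#' @export
setClass("CaseReport",
    representation(
        filterReport = "list",
        partition = "ANY",
        replacementEvents = "data.frame",
        focalAmps = "list",
        fusion = "list",
        geneSummaries = "data.frame",
        candidates = "data.frame",
        provenance = "list"
    )
)
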