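#' Reads per kilobase per million mapped reads
#'
#' \code{rpkm = count / ((length_bp / 1000) * (total_mapped / 1e6))}.
#' Counts are expected to be unique-read counts (alignment quality
#' filtering happens upstream of this package).
#'
#' @param count reads mapped to the gene (vectorized).
#' @param length_bp transcript length in base pairs (>= 1).
#' @param total_mapped total mapped reads in the library (>= 1).
#' @return RPKM values.
#' @export
#' @examples
#' computeRpkm(10, 1000, 1e6)  # 10
computeRpkm <- function(count, length_bp, total_mapped) {
    stopIfNot1(all(length_bp >= 1), "length_bp must be >= 1")
    stopIfNot1(all(total_mapped >= 1), "total_mapped must be >= 1")
    stopIfNot1(all(count >= 0), "count must be >= 0")
    count / ((length_bp / 1000) * (total_mapped / 1e6))
}

#' Add RPKM to an expression count table
#'
#' @param expression data.frame with \code{gene}, \code{length_bp},
#'   \code{count}, and optionally \code{total_mapped} (library size).
#' @param total_mapped library size; defaults to the table's
#'   \code{total_mapped} column, else the sum of counts (appropriate only
#'   when the table covers the whole transcriptome).
#' @return the table with an \code{rpkm} column.
#' @export
expressionRpkm <- function(expression, total_mapped = NULL) {
    if (is.null(total_mapped))
        total_mapped <- if ("total_mapped" %in% colnames(expression))
            expression$total_mapped[1] else sum(expression$count)
    expression$rpkm <- computeRpkm(expression$count,
                                   expression$length_bp, total_mapped)
    expression
}

#' Fold change of case expression over a reference cohort
#'
#' Divides the case RPKM (median over supplied case samples; a single
#' sample is its own median) by the median RPKM of the reference cohort.
#' Returns both the raw ratio and the nearest-integer display value
#' (rounded half away from zero) used in candidate tables. A reference
#' median of 0 yields an infinite-fold flag rather than a number.
#'
#' @param case_rpkm numeric: the gene's RPKM in the case sample(s).
#' @param reference_rpkms numeric: the gene's RPKM across the reference
#'   cohort (nonempty).
#' @return list: \code{case_value}, \code{reference_median},
#'   \code{fold_change_raw}, \code{fold_change_display} (integer),
#'   \code{infinite} (logical).
#' @export
#' @examples
#' foldChange(274.24, 2.80)$fold_change_display  # 98
foldChange <- function(case_rpkm, reference_rpkms) {
    stopIfNot1(length(reference_rpkms) >= 1,
               "reference cohort must be nonempty")
    caseVal <- stats::median(case_rpkm)
    refMed <- stats::median(reference_rpkms)
    if (refMed == 0) {
        return(list(case_value = caseVal, reference_median = 0,
                    fold_change_raw = NA_real_,
                    fold_change_display = NA_real_, infinite = TRUE))
    }
    raw <- caseVal / refMed
    list(case_value = caseVal, reference_median = refMed,
         fold_change_raw = raw,
         fold_change_display = roundHalfAwayFromZero(raw),
         infinite = FALSE)
}

#' Prioritize candidate genes inside amplified regions
#'
#' Ranks genes located inside focal amplifications by their
#' case-vs-reference expression fold change: genes whose display fold is
#' at least \code{min_fold} are candidates, ranked by raw fold descending
#' (ties broken alphabetically); in-region genes below the threshold are
#' reported as non-candidates with their folds, and in-region genes
#' without an expression record are listed as unquantified. The threshold
#' is a reporting convenience — the full in-region table is always
#' returned so borderline genes stay visible.
#'
#' @param amp_regions \code{GRanges} (e.g. from
#'   [callFocalAmplifications()]) or data.frame with \code{chrom},
#'   \code{start}, \code{end}.
#' @param gene_annotation data.frame with \code{gene}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive; see [readBedGenes()]
#'   for BED input).
#' @param fold_changes data.frame with \code{gene},
#'   \code{fold_change_raw}, \code{fold_change_display} (as built by
#'   [rankAmplifiedGenes()] or manually from [foldChange()]).
#' @param min_fold minimum display fold for candidacy.
#' @return data.frame of all in-region genes: \code{gene}, fold columns,
#'   \code{status} (\code{candidate}/\code{non-candidate}/
#'   \code{unquantified}), \code{rank} (NA unless candidate), ordered
#'   candidates first.
#' @export
prioritizeCandidates <- function(amp_regions, gene_annotation,
                                 fold_changes, min_fold = 5) {
    if (methods::is(amp_regions, "GRanges")) {
        amp_regions <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(amp_regions)),
            start = GenomicRanges::start(amp_regions),
            end = GenomicRanges::end(amp_regions),
            stringsAsFactors = FALSE)
    }
    if (nrow(amp_regions) == 0 || nrow(gene_annotation) == 0) {
        return(data.frame(gene = character(),
                          fold_change_raw = numeric(),
                          fold_change_display = numeric(),
                          status = character(), rank = integer(),
                          stringsAsFactors = FALSE))
    }
    inAmp <- vapply(seq_len(nrow(gene_annotation)), function(i) {
        g <- gene_annotation[i, ]
        any(amp_regions$chrom == g$chrom &
                amp_regions$start <= g$end &
                amp_regions$end >= g$start)
    }, TRUE)
    genes <- unique(gene_annotation$gene[inAmp])
    m <- match(genes, fold_changes$gene)
    out <- data.frame(
        gene = genes,
        fold_change_raw = fold_changes$fold_change_raw[m],
        fold_change_display = fold_changes$fold_change_display[m],
        stringsAsFactors = FALSE)
    out$status <- ifelse(is.na(m), "unquantified",
                         ifelse(!is.na(out$fold_change_display) &
                                    out$fold_change_display >= min_fold,
                                "candidate", "non-candidate"))
    ## candidates ranked by raw fold descending, alphabetical within ties
    ord <- order(out$status != "candidate",
                 -ifelse(is.na(out$fold_change_raw), -Inf,
                         out$fold_change_raw),
                 out$gene)
    out <- out[ord, , drop = FALSE]
    out$rank <- NA_integer_
    isCand <- out$status == "candidate"
    out$rank[isCand] <- seq_len(sum(isCand))
    rownames(out) <- NULL
    out
}

#' Build the fold-change table for a case against a reference matrix
#'
#' Convenience wrapper: computes case RPKM from the count table and the
#' per-gene fold change against a genes x samples reference RPKM matrix.
#'
#' @param expression case count table (\code{gene}, \code{length_bp},
#'   \code{count}).
#' @param reference_rpkm numeric matrix, rownames = genes.
#' @param total_mapped case library size; defaults to the sum of counts.
#' @return data.frame: \code{gene}, \code{rpkm},
#'   \code{reference_median}, \code{fold_change_raw},
#'   \code{fold_change_display}, \code{infinite}.
#' @export
rankAmplifiedGenes <- function(expression, reference_rpkm,
                               total_mapped = NULL) {
    expr <- expressionRpkm(expression, total_mapped)
    rows <- lapply(seq_len(nrow(expr)), function(i) {
        g <- expr$gene[i]
        if (!(g %in% rownames(reference_rpkm))) {
            return(data.frame(gene = g, rpkm = expr$rpkm[i],
                              reference_median = NA_real_,
                              fold_change_raw = NA_real_,
                              fold_change_display = NA_real_,
                              infinite = FALSE, stringsAsFactors = FALSE))
        }
        fc <- foldChange(expr$rpkm[i], reference_rpkm[g, ])
        data.frame(gene = g, rpkm = expr$rpkm[i],
                   reference_median = fc$reference_median,
                   fold_change_raw = fc$fold_change_raw,
                   fold_change_display = fc$fold_change_display,
                   infinite = fc$infinite, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Read a BED gene annotation (0-based half-open) as 1-based inclusive
#'
#' @param path BED file with at least chrom/start/end/name columns.
#' @return data.frame: \code{gene}, \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive).
#' @export
readBedGenes <- function(path) {
    df <- utils::read.delim(path, header = FALSE,
                            stringsAsFactors = FALSE)
    stopIfNot1(ncol(df) >= 4, "BED needs chrom/start/end/name")
    data.frame(gene = as.character(df[[4]]),
               chrom = as.character(df[[1]]),
               start = as.integer(df[[2]]) + 1L,
               end = as.integer(df[[3]]),
               stringsAsFactors = FALSE)
}

#' Read an expression count table / reference RPKM matrix
#'
#' @param path TSV with \code{gene}, \code{length_bp}, \code{count}.
#' @return data.frame.
#' @export
readExpressionTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene", "length_bp", "count")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(sprintf("expression table '%s' lacks column(s) %s", path,
                     paste(miss, collapse = ", ")), call. = FALSE)
    df
}

#' @rdname readExpressionTable
#' @return \code{readReferenceRpkm}: numeric matrix with gene rownames.
#' @export
readReferenceRpkm <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    stopIfNot1("gene" %in% colnames(df),
               "reference RPKM table needs a 'gene' column")
    m <- as.matrix(df[, setdiff(colnames(df), "gene"), drop = FALSE])
    rownames(m) <- df$gene
    storage.mode(m) <- "double"
    m
}
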