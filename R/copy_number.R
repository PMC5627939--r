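#' @importFrom GenomicRanges GRanges start end seqnames width mcols
#' @importFrom IRanges IRanges
NULL

segToGRanges <- function(df) {
    gr <- GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$start, end = df$end))
    S4Vectors::mcols(gr)$sample_id <- df$sample_id
    S4Vectors::mcols(gr)$log2_ratio <- df$log2_ratio
    S4Vectors::mcols(gr)$n_bins <-
        if ("n_bins" %in% colnames(df)) df$n_bins else 1L
    gr
}

#' Compute tumor/normal log2 copy-number ratios
#'
#' Library-size-normalizes per-bin read counts
#' (\code{(tumor/tumor_total) / (normal/normal_total)}), median-smooths
#' the per-bin ratios with a running median of width \code{smooth_k}, and
#' merges adjacent bins into segments while the smoothed log2 values stay
#' within \code{merge_tol} of the running segment mean. Bins with a zero
#' normal count are masked (dropped) rather than producing infinite
#' ratios. The result is invariant to global scaling of either library's
#' total counts.
#'
#' @param bins data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{tumor_count}, \code{normal_count} (and optionally
#'   \code{sample_id}), aligned on identical intervals.
#' @param sample_id sample label for the output segments.
#' @param smooth_k odd window for the running median (1 = no smoothing).
#' @param merge_tol maximum |log2 - segment mean| for extending a segment.
#' @param tumor_total,normal_total library sizes used for normalization;
#'   default to the sums over the supplied bins (appropriate when the
#'   bins tile the captured territory; pass genome-wide totals when they
#'   do not).
#' @return \code{GRanges} of segments with metadata \code{sample_id},
#'   \code{log2_ratio} (mean of member bins) and \code{n_bins}.
#' @export
computeLog2Ratios <- function(bins, sample_id = NULL, smooth_k = 5,
                              merge_tol = 0.25, tumor_total = NULL,
                              normal_total = NULL) {
    stopIfNot1(all(c("chrom", "start", "end", "tumor_count",
                     "normal_count") %in% colnames(bins)),
               "bins need chrom/start/end/tumor_count/normal_count")
    stopIfNot1(all(bins$tumor_count >= 0) && all(bins$normal_count >= 0),
               "read counts must be >= 0")
    if (is.null(sample_id))
        sample_id <- if ("sample_id" %in% colnames(bins))
            bins$sample_id[1] else "sample"
    bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
    tTot <- if (is.null(tumor_total)) sum(bins$tumor_count) else tumor_total
    nTot <- if (is.null(normal_total)) sum(bins$normal_count) else
        normal_total
    stopIfNot1(tTot > 0 && nTot > 0, "all-zero library")
    mask <- bins$normal_count == 0
    segs <- list()
    for (chr in unique(bins$chrom)) {
        b <- bins[bins$chrom == chr & !mask, , drop = FALSE]
        if (!nrow(b)) next
        ratio <- (b$tumor_count / tTot) / (b$normal_count / nTot)
        k <- min(smooth_k, nrow(b))
        if (k %% 2 == 0) k <- k - 1
        sm <- if (k >= 3) stats::runmed(ratio, k, endrule = "median")
              else ratio
        l2 <- log2(pmax(sm, 1e-6))
        ## greedy merge: extend while the next bin stays within merge_tol
        ## of the running mean
        st <- 1L
        runMean <- l2[1]
        n <- nrow(b)
        flush <- function(st, en) {
            data.frame(sample_id = sample_id, chrom = chr,
                       start = b$start[st], end = b$end[en],
                       log2_ratio = mean(l2[st:en]),
                       n_bins = en - st + 1L, stringsAsFactors = FALSE)
        }
        if (n == 1) {
            segs[[length(segs) + 1]] <- flush(1L, 1L)
        } else {
            for (i in 2:n) {
                if (abs(l2[i] - runMean) < merge_tol) {
                    runMean <- mean(l2[st:i])
                } else {
                    segs[[length(segs) + 1]] <- flush(st, i - 1L)
                    st <- i
                    runMean <- l2[i]
                }
            }
            segs[[length(segs) + 1]] <- flush(st, n)
        }
    }
    segToGRanges(do.call(rbind, segs))
}

#' Call focal amplifications
#'
#' Retains segments with \code{log2_ratio >= min_log2} and genomic span
#' \code{<= max_span_bp}; broad (arm-scale) gains are excluded as
#' non-focal.
#'
#' @param segments \code{GRanges} from [computeLog2Ratios()] or
#'   [readSegFile()].
#' @param min_log2 minimum segment log2 ratio (inclusive).
#' @param max_span_bp maximum segment span for "focal".
#' @return \code{GRanges} subset of amplified focal segments.
#' @export
callFocalAmplifications <- function(segments, min_log2 = 0.5,
                                    max_span_bp = 10e6) {
    keep <- S4Vectors::mcols(segments)$log2_ratio >= min_log2 &
        GenomicRanges::width(segments) <= max_span_bp
    segments[keep]
}

#' Convert a log2 ratio to absolute copy number
#'
#' Inverts the log2 tumor/normal ratio under a purity/ploidy model:
#' \code{copies = round((normal_ploidy * 2^L - (1 - purity) *
#' normal_ploidy) / purity)}, rounding half away from zero. At purity 1
#' and diploid normal this is \code{round(2 * 2^L)}: a log2 ratio of 1.4
#' gives 5 copies, 0.5 gives 3, 0 gives 2.
#'
#' @param log2_ratio numeric vector of segment log2 ratios.
#' @param purity tumor purity in \code{(0, 1]}.
#' @param normal_ploidy copies in normal cells (2 for autosomes).
#' @return integer copy numbers.
#' @export
#' @examples
#' estimateAbsoluteCopies(c(1.4, 0.5, 0))  # 5 3 2
estimateAbsoluteCopies <- function(log2_ratio, purity = 1.0,
                                   normal_ploidy = 2) {
    stopIfNot1(all(is.finite(log2_ratio)), "log2 ratios must be finite")
    if (purity <= 0 || purity > 1)
        stop("purity must lie in (0, 1]", call. = FALSE)
    raw <- (normal_ploidy * 2^log2_ratio -
                (1 - purity) * normal_ploidy) / purity
    copies <- roundHalfAwayFromZero(raw)
    as.integer(pmax(copies, 0))
}

#' Test fusion breakpoint concordance across samples
#'
#' A shared breakpoint across serially collected samples implies the
#' rearrangement predates subclonal divergence — the common-founder
#' signature. Events (one per sample, same 5'/3' gene pair) are
#' concordant when all pairwise distances on both partners are
#' \code{<= tolerance_bp}; at tolerance 0 concordance is transitive
#' (identity).
#'
#' @param events data.frame with \code{sample_id}, \code{gene5},
#'   \code{gene3}, \code{chrom5}, \code{pos5}, \code{chrom3},
#'   \code{pos3}, and optionally \code{log2_ratio} and/or
#'   \code{copy_estimate}.
#' @param tolerance_bp maximum pairwise breakpoint distance.
#' @param purity passed to [estimateAbsoluteCopies()] when copy estimates
#'   must be derived from \code{log2_ratio}.
#' @return list: \code{concordant} (logical), \code{common_founder}
#'   (flag, TRUE iff concordant), \code{max_distance_bp}, and
#'   \code{per_sample} (data.frame of coordinates and copy estimates).
#' @export
breakpointConcordance <- function(events, tolerance_bp = 0, purity = 1.0) {
    stopIfNot1(nrow(events) >= 2, "need >= 2 fusion events")
    if (length(unique(paste(events$gene5, events$gene3))) != 1)
        stop("mixed gene pairs; concordance is per fusion", call. = FALSE)
    sameChrom <- length(unique(events$chrom5)) == 1 &&
        length(unique(events$chrom3)) == 1
    d5 <- max(events$pos5) - min(events$pos5)
    d3 <- max(events$pos3) - min(events$pos3)
    concordant <- sameChrom && d5 <= tolerance_bp && d3 <= tolerance_bp
    per <- events[, intersect(colnames(events),
                              c("sample_id", "gene5", "gene3", "chrom5",
                                "pos5", "chrom3", "pos3",
                                "supporting_reads", "log2_ratio",
                                "copy_estimate")), drop = FALSE]
    if (!("copy_estimate" %in% colnames(per)) &&
        "log2_ratio" %in% colnames(per))
        per$copy_estimate <- estimateAbsoluteCopies(per$log2_ratio,
                                                    purity = purity)
    list(concordant = concordant,
         common_founder = concordant,
         max_distance_bp = max(d5, d3, if (sameChrom) 0 else Inf),
         per_sample = per)
}

#' Read / write SEG-format segment files
#'
#' Tab-separated segment tables (\code{sample_id}, \code{chrom},
#' \code{start}, \code{end}, \code{n_bins}, \code{log2_ratio});
#' coordinates 1-based inclusive. The standard \code{ID/loc.start/
#' loc.end/num.mark/seg.mean} header is also accepted on read.
#'
#' @param path file path.
#' @return \code{readSegFile}: \code{GRanges} of segments.
#' @export
readSegFile <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    alias <- c(ID = "sample_id", Sample = "sample_id",
               chrom = "chrom", Chromosome = "chrom",
               loc.start = "start", loc.end = "end",
               num.mark = "n_bins", seg.mean = "log2_ratio")
    for (a in names(alias))
        if (a %in% colnames(df) && !(alias[[a]] %in% colnames(df)))
            colnames(df)[colnames(df) == a] <- alias[[a]]
    need <- c("sample_id", "chrom", "start", "end", "log2_ratio")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(sprintf("SEG file '%s' lacks column(s) %s", path,
                     paste(miss, collapse = ", ")), call. = FALSE)
    if (!("n_bins" %in% colnames(df))) df$n_bins <- 1L
    segToGRanges(df)
}

#' @rdname readSegFile
#' @param segments \code{GRanges} (as from [computeLog2Ratios()]) or a
#'   data.frame with the SEG columns.
#' @return \code{writeSegFile}: \code{path}, invisibly.
#' @export
writeSegFile <- function(segments, path) {
    if (methods::is(segments, "GRanges")) {
        segments <- data.frame(
            sample_id = S4Vectors::mcols(segments)$sample_id,
            chrom = as.character(GenomicRanges::seqnames(segments)),
            start = GenomicRanges::start(segments),
            end = GenomicRanges::end(segments),
            n_bins = S4Vectors::mcols(segments)$n_bins,
            log2_ratio = S4Vectors::mcols(segments)$log2_ratio,
            stringsAsFactors = FALSE)
    }
    cols <- c("sample_id", "chrom", "start", "end", "n_bins", "log2_ratio")
    cols <- intersect(cols, colnames(segments))
    utils::write.table(segments[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a fusion-event TSV
#'
#' Columns: \code{sample_id}, \code{gene5}, \code{gene3}, \code{chrom5},
#' \code{pos5}, \code{chrom3}, \code{pos3}, optionally
#' \code{supporting_reads} and \code{log2_ratio}.
#'
#' @param path file path.
#' @return data.frame of fusion events.
#' @export
readFusionTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "gene5", "gene3", "chrom5", "pos5",
              "chrom3", "pos3")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(sprintf("fusion table '%s' lacks column(s) %s", path,
                     paste(miss, collapse = ", ")), call. = FALSE)
    if ("supporting_reads" %in% colnames(df) &&
        any(df$supporting_reads < 0))
        stop("supporting_reads must be >= 0", call. = FALSE)
    df
}
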