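#' Read a somatic variant table
#'
#' Parses per-sample somatic variant observations from either a MAF-like
#' TSV (columns \code{Chromosome}, \code{Start_Position},
#' \code{Reference_Allele}, \code{Tumor_Seq_Allele2}, \code{Hugo_Symbol},
#' \code{Variant_Classification}, \code{t_depth}, \code{t_alt_count},
#' \code{n_depth}, \code{n_alt_count}) or a VCF (v4.x; the tumor sample's
#' \code{AD}/\code{DP} genotype fields supply alt and total read counts).
#' Deletion alleles are normalized to the \code{"-"} alternative-allele
#' convention; anchored VCF indel records are converted accordingly.
#'
#' @param path file path.
#' @param format \code{"maf_tsv"} or \code{"vcf"}.
#' @param sample_id sample identifier attached to every record; for VCF,
#'   also selects the tumor genotype column (defaults to the first).
#' @return data.frame of variant calls: \code{sample_id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{gene}, \code{aa_change},
#'   \code{variant_class}, \code{t_depth}, \code{t_alt}, \code{n_depth},
#'   \code{n_alt}, \code{vaf}.
#' @export
readVariantTable <- function(path, format = c("maf_tsv", "vcf"),
                             sample_id = NULL) {
    format <- match.arg(format)
    stopIfNot1(file.exists(path), "file not found: '%s'", path)
    if (format == "maf_tsv")
        readMafTsv(path, sample_id)
    else
        readVcfCalls(path, sample_id)
}

readMafTsv <- function(path, sample_id = NULL) {
    ## colClasses = "character" keeps all-"T" allele columns from being
    ## read as logicals; numeric columns are coerced back below
    df <- tryCatch(
        utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#",
                          colClasses = "character"),
        error = function(e) stop(sprintf(
            "malformed variant table '%s': %s", path, conditionMessage(e)),
            call. = FALSE))
    need <- c("Chromosome", "Start_Position", "Reference_Allele",
              "Tumor_Seq_Allele2", "t_depth", "t_alt_count")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(sprintf("malformed header in '%s' (line 1): missing column(s) %s",
                     path, paste(miss, collapse = ", ")), call. = FALSE)
    getCol <- function(nm, default) {
        if (nm %in% colnames(df)) df[[nm]] else rep(default, nrow(df))
    }
    out <- data.frame(
        sample_id = if (is.null(sample_id))
            getCol("Tumor_Sample_Barcode", NA_character_) else sample_id,
        chrom = as.character(df$Chromosome),
        pos = as.integer(df$Start_Position),
        ref = as.character(df$Reference_Allele),
        alt = as.character(df$Tumor_Seq_Allele2),
        gene = as.character(getCol("Hugo_Symbol", NA_character_)),
        aa_change = as.character(getCol("Protein_Change", NA_character_)),
        variant_class = normalizeVariantClass(
            getCol("Variant_Classification", "other")),
        t_depth = as.numeric(df$t_depth),
        t_alt = as.numeric(df$t_alt_count),
        n_depth = as.numeric(getCol("n_depth", NA_real_)),
        n_alt = as.numeric(getCol("n_alt_count", NA_real_)),
        stringsAsFactors = FALSE)
    validateVariantCalls(out, path)
}

readVcfCalls <- function(path, sample_id = NULL) {
    vcf <- VariantAnnotation::readVcf(path)
    n <- length(vcf)
    if (n == 0) {
        return(validateVariantCalls(data.frame(
            sample_id = character(), chrom = character(), pos = integer(),
            ref = character(), alt = character(), gene = character(),
            aa_change = character(), variant_class = character(),
            t_depth = numeric(), t_alt = numeric(),
            n_depth = numeric(), n_alt = numeric(),
            stringsAsFactors = FALSE), path))
    }
    rr <- SummarizedExperiment::rowRanges(vcf)
    geno <- VariantAnnotation::geno(vcf)
    samples <- colnames(vcf)
    tcol <- if (is.null(sample_id) || !(sample_id %in% samples))
        1L else match(sample_id, samples)
    dp <- if ("DP" %in% names(geno)) geno$DP[, tcol] else rep(NA_real_, n)
    ## AD convention: per-allele depths (ref, alt); alt count is the
    ## second element
    ad <- if ("AD" %in% names(geno)) geno$AD[, tcol] else NULL
    t_alt <- if (is.null(ad)) rep(NA_real_, n) else
        vapply(ad, function(x) as.numeric(x[2]), 0)
    ref <- as.character(rr$REF)
    alt <- vapply(seq_len(n), function(i)
        as.character(rr$ALT[[i]][1]), "")
    pos <- GenomicRanges::start(rr)
    ## left-aligned anchored indels -> "-" convention
    del <- nchar(ref) > nchar(alt) & substr(ref, 1, nchar(alt)) == alt
    ins <- nchar(alt) > nchar(ref) & substr(alt, 1, nchar(ref)) == ref
    newRef <- ref; newAlt <- alt; newPos <- pos
    newRef[del] <- substr(ref[del], nchar(alt[del]) + 1, nchar(ref[del]))
    newAlt[del] <- "-"
    newPos[del] <- pos[del] + nchar(alt[del])
    newAlt[ins] <- substr(alt[ins], nchar(ref[ins]) + 1, nchar(alt[ins]))
    newRef[ins] <- "-"
    cls <- rep("other", n)
    cls[del] <- "deletion"
    cls[ins] <- "insertion"
    out <- data.frame(
        sample_id = if (is.null(sample_id)) samples[tcol] else sample_id,
        chrom = as.character(GenomicRanges::seqnames(rr)),
        pos = as.integer(newPos), ref = newRef, alt = newAlt,
        gene = NA_character_, aa_change = NA_character_,
        variant_class = cls,
        t_depth = as.numeric(dp), t_alt = t_alt,
        n_depth = NA_real_, n_alt = NA_real_,
        stringsAsFactors = FALSE)
    validateVariantCalls(out, path)
}

validateVariantCalls <- function(calls, source = "calls") {
    if (nrow(calls)) {
        if (any(calls$t_depth < 0 | calls$t_alt < 0, na.rm = TRUE))
            stop(sprintf("negative read counts in '%s'", source),
                 call. = FALSE)
        if (any(calls$t_alt > calls$t_depth, na.rm = TRUE))
            stop(sprintf("t_alt exceeds t_depth in '%s'", source),
                 call. = FALSE)
        if (any(calls$pos < 1, na.rm = TRUE))
            stop(sprintf("positions must be >= 1 in '%s'", source),
                 call. = FALSE)
    }
    calls$vaf <- ifelse(calls$t_depth > 0, calls$t_alt / calls$t_depth, 0)
    calls
}

#' Somatic competence filter
#'
#' Retains variant calls with tumor depth \code{>= min_depth}, tumor VAF
#' \code{>= min_vaf} (both inclusive) and normal VAF
#' \code{<= max_normal_vaf}; the default \code{max_normal_vaf = 0}
#' requires zero variant reads in the matched blood sample. Calls whose
#' normal depth is 0 cannot be evaluated against a strict normal filter:
#' they are excluded and counted as \code{normal_unevaluable} in the
#' attached report.
#'
#' The filter is idempotent and monotone in \code{min_depth}/\code{min_vaf}
#' (raising either never adds calls).
#'
#' @param calls data.frame from [readVariantTable()].
#' @param min_depth minimum tumor depth (inclusive).
#' @param min_vaf minimum tumor VAF (inclusive).
#' @param max_normal_vaf maximum normal VAF (inclusive).
#' @return filtered data.frame; attribute \code{"filter_report"} carries
#'   counts in/out per rule.
#' @export
#' @examples
#' calls <- data.frame(sample_id = "s", chrom = "chr1", pos = 1:2,
#'   ref = "A", alt = "T", gene = NA, aa_change = NA,
#'   variant_class = "missense", t_depth = c(19, 20), t_alt = c(10, 4),
#'   n_depth = 30, n_alt = 0, vaf = c(10/19, 0.2))
#' nrow(filterSomatic(calls))  # only the 20x / 20% call survives
filterSomatic <- function(calls, min_depth = 20, min_vaf = 0.20,
                          max_normal_vaf = 0.0) {
    n0 <- nrow(calls)
    if (n0 == 0) {
        attr(calls, "filter_report") <- list(
            input = 0L, retained = 0L, fail_depth = 0L, fail_vaf = 0L,
            fail_normal = 0L, normal_unevaluable = 0L)
        return(calls)
    }
    depthOk <- calls$t_depth >= min_depth
    vafOk <- calls$vaf >= min_vaf
    nUneval <- is.na(calls$n_depth) | calls$n_depth == 0
    nVaf <- ifelse(nUneval, NA_real_, calls$n_alt / calls$n_depth)
    normalOk <- !nUneval & nVaf <= max_normal_vaf
    keep <- depthOk & vafOk & normalOk
    out <- calls[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "filter_report") <- list(
        input = n0, retained = sum(keep),
        fail_depth = sum(!depthOk),
        fail_vaf = sum(!vafOk),
        fail_normal = sum(!normalOk & !nUneval),
        normal_unevaluable = sum(nUneval))
    out
}

#' Harmonize variant observations across serial samples
#'
#' Builds the [VafMatrix-class] clone tracking operates on. The variant
#' universe is the union of keys (\code{chrom:pos:ref:alt}) across
#' samples, optionally restricted to \code{keys} (e.g. the union of
#' somatic-pass variants while depth/VAF come from unfiltered
#' observation tables). A variant is retained only if its locus depth is
#' \code{>= min_depth_all} in every sample; a sample with no observation
#' of a retained variant contributes a missing (\code{NA}) cell, distinct
#' from an observed VAF of 0.
#'
#' Output is invariant to sample input order up to column ordering, and
#' raising \code{min_depth_all} never enlarges the retained set.
#'
#' @param call_lists named list (one element per sample, names =
#'   chronological sample labels) of variant-call data.frames.
#' @param min_depth_all minimum per-sample locus depth for retention.
#' @param keys optional character vector restricting the variant universe.
#' @param support_metric \code{"depth"} (default: total locus depth) or
#'   \code{"alt"} (alt-supporting reads) — which count the
#'   \code{min_depth_all} rule applies to.
#' @return a [VafMatrix-class].
#' @export
harmonizeAcrossSamples <- function(call_lists, min_depth_all = 20,
                                   keys = NULL,
                                   support_metric = c("depth", "alt")) {
    support_metric <- match.arg(support_metric)
    stopIfNot1(length(call_lists) >= 2,
               "harmonization needs >= 2 samples")
    labs <- names(call_lists)
    stopIfNot1(!is.null(labs) && all(nzchar(labs)),
               "call_lists must be named by sample")
    for (s in labs) {
        k <- with(call_lists[[s]], variantKey(chrom, pos, ref, alt))
        if (anyDuplicated(k))
            stop(sprintf("duplicate variant key '%s' in sample '%s'",
                         k[duplicated(k)][1], s), call. = FALSE)
    }
    allKeys <- sort(unique(unlist(lapply(call_lists, function(x)
        with(x, variantKey(chrom, pos, ref, alt))))))
    if (!is.null(keys))
        allKeys <- allKeys[allKeys %in% keys]
    nV <- length(allKeys)
    nS <- length(labs)
    vaf <- matrix(NA_real_, nV, nS, dimnames = list(allKeys, labs))
    depth <- matrix(NA_real_, nV, nS, dimnames = list(allKeys, labs))
    alt <- matrix(NA_real_, nV, nS, dimnames = list(allKeys, labs))
    meta <- NULL
    for (s in labs) {
        x <- call_lists[[s]]
        k <- with(x, variantKey(chrom, pos, ref, alt))
        idx <- match(k, allKeys)
        ok <- !is.na(idx)
        vaf[idx[ok], s] <- x$vaf[ok]
        depth[idx[ok], s] <- x$t_depth[ok]
        alt[idx[ok], s] <- x$t_alt[ok]
        m <- x[ok, c("chrom", "pos", "ref", "alt", "gene"), drop = FALSE]
        m$key <- k[ok]
        meta <- rbind(meta, m)
    }
    meta <- meta[!duplicated(meta$key), , drop = FALSE]
    meta <- meta[match(allKeys, meta$key), , drop = FALSE]

    support <- if (support_metric == "depth") depth else alt
    minSupport <- apply(support, 1, function(r)
        if (any(is.na(r))) -Inf else min(r))
    keep <- minSupport >= min_depth_all
    vaf <- vaf[keep, , drop = FALSE]
    depth <- depth[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(vaf = vaf, depth = depth),
        rowData = S4Vectors::DataFrame(
            chrom = meta$chrom, pos = meta$pos, ref = meta$ref,
            alt = meta$alt, gene = meta$gene, row.names = meta$key),
        colData = S4Vectors::DataFrame(sample_id = labs, row.names = labs))
    obj <- methods::new("VafMatrix", se)
    S4Vectors::metadata(obj)$min_depth_all <- min_depth_all
    S4Vectors::metadata(obj)$support_metric <- support_metric
    obj
}

#' Write a harmonized VAF matrix as TSV
#'
#' Variants x samples VAF grid with the variant key columns first;
#' missing (uncovered) cells are written as \code{NA}, observed zero VAF
#' as \code{0}.
#'
#' @param vm a [VafMatrix-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeVafMatrix <- function(vm, path) {
    rd <- as.data.frame(SummarizedExperiment::rowData(vm))
    out <- cbind(key = rownames(vm), rd,
                 as.data.frame(SummarizedExperiment::assay(vm, "vaf")))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
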