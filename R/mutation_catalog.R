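#' Read a MAF-format mutation catalog
#'
#' Loads a TCGA-style .maf table into the catalog record layout used by
#' the per-gene statistics: \code{gene}, variant key columns,
#' \code{variant_class} (normalized to the closed vocabulary),
#' \code{reads} (supporting depth) and \code{aaf} (alternative allele
#' ratio) when the columns are available.
#'
#' @param path file path to a tab-separated MAF (comment lines \code{#}
#'   skipped).
#' @return data.frame of catalog records.
#' @export
readMafCatalog <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#", check.names = FALSE,
                            colClasses = "character")
    getCol <- function(nm, default) {
        if (nm %in% colnames(df)) df[[nm]] else rep(default, nrow(df))
    }
    reads <- as.numeric(getCol("t_depth", NA_real_))
    alt <- as.numeric(getCol("t_alt_count", NA_real_))
    data.frame(
        gene = as.character(getCol("Hugo_Symbol", NA_character_)),
        chrom = as.character(getCol("Chromosome", NA_character_)),
        pos = as.integer(getCol("Start_Position", NA_integer_)),
        ref = as.character(getCol("Reference_Allele", NA_character_)),
        alt = as.character(getCol("Tumor_Seq_Allele2", NA_character_)),
        variant_class = normalizeVariantClass(
            getCol("Variant_Classification", "other")),
        reads = reads,
        aaf = ifelse(!is.na(reads) & reads > 0, alt / reads, NA_real_),
        stringsAsFactors = FALSE)
}

#' Catalog competence filter
#'
#' Retains catalog records supported by at least \code{min_reads} reads
#' and an alternative allele ratio of at least \code{min_aaf} (both
#' inclusive) whose class is protein-coding (missense, nonsense,
#' insertion, deletion, silent); splice, UTR and RNA variants are
#' excluded. Records lacking depth information cannot be evaluated: they
#' are excluded and counted in the attached report.
#'
#' @param records catalog data.frame with \code{variant_class} and,
#'   where available, \code{reads} and \code{aaf}.
#' @param min_reads minimum supporting reads (inclusive).
#' @param min_aaf minimum alternative allele ratio (inclusive).
#' @param support_metric \code{"depth"} (default; \code{reads} is total
#'   locus depth) or \code{"alt"} (the read rule applies to
#'   \code{reads * aaf}, i.e. alt-supporting reads).
#' @return filtered data.frame with a \code{"filter_report"} attribute.
#' @export
filterCatalog <- function(records, min_reads = 20, min_aaf = 0.2,
                          support_metric = c("depth", "alt")) {
    support_metric <- match.arg(support_metric)
    n0 <- nrow(records)
    if (n0 == 0) {
        attr(records, "filter_report") <- list(
            input = 0L, retained = 0L, fail_reads = 0L, fail_aaf = 0L,
            fail_class = 0L, depth_missing = 0L)
        return(records)
    }
    missingDepth <- is.na(records$reads) | is.na(records$aaf)
    support <- if (support_metric == "depth") records$reads
               else records$reads * records$aaf
    readsOk <- !missingDepth & support >= min_reads
    aafOk <- !missingDepth & records$aaf >= min_aaf
    classOk <- records$variant_class %in% codingClasses()
    keep <- readsOk & aafOk & classOk
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "filter_report") <- list(
        input = n0, retained = sum(keep),
        fail_reads = sum(!readsOk & !missingDepth),
        fail_aaf = sum(!aafOk & !missingDepth),
        fail_class = sum(!classOk),
        depth_missing = sum(missingDepth))
    out
}

#' Per-gene silent-mutation fraction
#'
#' Among a gene's filtered coding mutations, the fraction that are silent
#' (synonymous). Genes under positive selection for protein change —
#' driver oncogenes — show very low silent fractions (a few percent),
#' whereas neutrally evolving genes accumulate silent mutations at the
#' genomic background rate (roughly a quarter of coding mutations), so a
#' high silent fraction marks a gene's mutations as likely passengers.
#'
#' @param records filtered catalog records (see [filterCatalog()]).
#' @param gene gene symbol (vectorized).
#' @param driver_max_fraction,passenger_min_fraction,min_total
#'   classification bands, see [classifyDriverLike()].
#' @return data.frame (one row per requested gene): \code{gene},
#'   \code{total_mutations}, \code{silent_count}, \code{silent_fraction}
#'   (NA when the gene is absent — distinct from an observed 0),
#'   \code{silent_percent} (display rounding, half away from zero), and
#'   \code{classification}.
#' @export
#' @examples
#' recs <- data.frame(gene = "G", variant_class =
#'   c("silent", rep("missense", 3)), reads = 50, aaf = 0.5)
#' silentFraction(recs, "G")$silent_percent  # 25
silentFraction <- function(records, gene,
                           driver_max_fraction = 0.05,
                           passenger_min_fraction = 0.15,
                           min_total = 30) {
    out <- do.call(rbind, lapply(gene, function(g) {
        r <- records[records$gene == g, , drop = FALSE]
        total <- nrow(r)
        silent <- sum(r$variant_class == "silent")
        frac <- if (total >= 1) silent / total else NA_real_
        data.frame(gene = g, total_mutations = total,
                   silent_count = silent, silent_fraction = frac,
                   silent_percent = if (is.na(frac)) NA_real_ else
                       roundHalfAwayFromZero(100 * frac),
                   stringsAsFactors = FALSE)
    }))
    out$classification <- classifyDriverLike(
        out, driver_max_fraction = driver_max_fraction,
        passenger_min_fraction = passenger_min_fraction,
        min_total = min_total)
    rownames(out) <- NULL
    out
}

#' Recurrence lookup of case variants in a catalog
#'
#' Exact-key ((chrom, pos, ref, alt)) match counts of queried variants in
#' the catalog; 0 means the variant has never been recorded there — the
#' signature of a private passenger event.
#'
#' @param catalog catalog records with key columns.
#' @param variants data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} (extra columns preserved).
#' @return \code{variants} with a \code{recurrence_count} column.
#' @export
recurrenceLookup <- function(catalog, variants) {
    catKeys <- variantKey(catalog$chrom, catalog$pos, catalog$ref,
                          catalog$alt)
    qKeys <- variantKey(variants$chrom, variants$pos, variants$ref,
                        variants$alt)
    tab <- table(catKeys)
    cnt <- as.integer(tab[qKeys])
    cnt[is.na(cnt)] <- 0L
    variants$recurrence_count <- cnt
    variants
}

#' Driver-like / passenger-like classification from silent fractions
#'
#' Advisory classification of a gene's catalog mutation spectrum:
#' driver-like when the silent fraction is at most
#' \code{driver_max_fraction} with at least \code{min_total} mutations
#' (small denominators are uninformative), passenger-like when the
#' fraction is at least \code{passenger_min_fraction}, otherwise
#' indeterminate. The bands bracket the observed separation between
#' driver oncogenes (a few percent silent) and the per-gene average
#' (about a quarter); known exceptions exist, so the call is advisory.
#'
#' @param summary data.frame with \code{silent_fraction} and
#'   \code{total_mutations} (as from [silentFraction()]).
#' @param driver_max_fraction upper silent fraction for driver-like.
#' @param passenger_min_fraction lower silent fraction for
#'   passenger-like.
#' @param min_total minimum mutation count for a driver-like call.
#' @return character vector: \code{"driver-like"},
#'   \code{"passenger-like"} or \code{"indeterminate"}.
#' @export
classifyDriverLike <- function(summary, driver_max_fraction = 0.05,
                               passenger_min_fraction = 0.15,
                               min_total = 30) {
    frac <- summary$silent_fraction
    total <- summary$total_mutations
    out <- rep("indeterminate", length(frac))
    out[!is.na(frac) & frac >= passenger_min_fraction] <- "passenger-like"
    out[!is.na(frac) & frac <= driver_max_fraction &
            total >= min_total] <- "driver-like"
    out[is.na(frac)] <- "indeterminate"
    out
}

#' Case-variant catalog summary table
#'
#' Combines [recurrenceLookup()] and [silentFraction()] into the
#' per-variant report shape: one row per case variant with its catalog
#' recurrence count and its gene's silent-mutation statistics.
#'
#' @param catalog filtered catalog records.
#' @param variants case variants (key columns + \code{gene}).
#' @param ... passed to [silentFraction()].
#' @return data.frame: variant key columns, \code{gene},
#'   \code{recurrence_count}, \code{silent_percent},
#'   \code{total_mutations}, \code{classification}.
#' @export
catalogSummaryTable <- function(catalog, variants, ...) {
    rec <- recurrenceLookup(catalog, variants)
    sf <- silentFraction(catalog, unique(variants$gene), ...)
    out <- merge(rec, sf, by = "gene", all.x = TRUE, sort = FALSE)
    cols <- c("gene", "chrom", "pos", "ref", "alt", "recurrence_count",
              "silent_percent", "total_mutations", "classification")
    out[, intersect(cols, colnames(out)), drop = FALSE]
}
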