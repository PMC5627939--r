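# Independent brute-force oracles. These deliberately use plain loops and
# no code paths from the package implementations they check.

bruteFilterSomatic <- function(calls, min_depth = 20, min_vaf = 0.20,
                               max_normal_vaf = 0.0) {
    keep <- logical(nrow(calls))
    for (i in seq_len(nrow(calls))) {
        r <- calls[i, ]
        vaf <- if (r$t_depth > 0) r$t_alt / r$t_depth else 0
        nOk <- !is.na(r$n_depth) && r$n_depth > 0 &&
            (r$n_alt / r$n_depth) <= max_normal_vaf
        keep[i] <- r$t_depth >= min_depth && vaf >= min_vaf && nOk
    }
    out <- calls[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

bruteFilterCatalog <- function(records, min_reads = 20, min_aaf = 0.2) {
    coding <- c("missense", "nonsense", "insertion", "deletion", "silent")
    keep <- logical(nrow(records))
    for (i in seq_len(nrow(records))) {
        r <- records[i, ]
        keep[i] <- !is.na(r$reads) && !is.na(r$aaf) &&
            r$reads >= min_reads && r$aaf >= min_aaf &&
            r$variant_class %in% coding
    }
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

bruteSilentFraction <- function(records, gene) {
    total <- 0L; silent <- 0L
    for (i in seq_len(nrow(records))) {
        if (records$gene[i] == gene) {
            total <- total + 1L
            if (records$variant_class[i] == "silent")
                silent <- silent + 1L
        }
    }
    if (total == 0) return(c(total = 0, silent = 0, fraction = NA))
    c(total = total, silent = silent, fraction = silent / total)
}

bruteRecurrence <- function(catalog, variants) {
    counts <- integer(nrow(variants))
    for (i in seq_len(nrow(variants))) {
        n <- 0L
        for (j in seq_len(nrow(catalog))) {
            if (catalog$chrom[j] == variants$chrom[i] &&
                catalog$pos[j] == variants$pos[i] &&
                catalog$ref[j] == variants$ref[i] &&
                catalog$alt[j] == variants$alt[i]) n <- n + 1L
        }
        counts[i] <- n
    }
    counts
}

brutePrioritize <- function(amp_regions, gene_annotation, fold_changes,
                            min_fold = 5) {
    cand <- character(); raw <- numeric()
    for (i in seq_len(nrow(gene_annotation))) {
        g <- gene_annotation[i, ]
        inside <- FALSE
        for (r in seq_len(nrow(amp_regions))) {
            if (amp_regions$chrom[r] == g$chrom &&
                amp_regions$start[r] <= g$end &&
                amp_regions$end[r] >= g$start) inside <- TRUE
        }
        if (!inside) next
        j <- which(fold_changes$gene == g$gene)
        if (!length(j)) next
        if (!is.na(fold_changes$fold_change_display[j]) &&
            fold_changes$fold_change_display[j] >= min_fold) {
            cand <- c(cand, g$gene)
            raw <- c(raw, fold_changes$fold_change_raw[j])
        }
    }
    cand[order(-raw, cand)]
}

# random fixture factories (used by oracle-equivalence and property tests)

randomCalls <- function(n, seed) {
    set.seed(seed)
    depth <- rpois(n, 40)
    out <- data.frame(
        sample_id = "s1",
        chrom = paste0("chr", sample(1:5, n, TRUE)),
        pos = sample.int(1e6, n, replace = TRUE),
        ref = sample(c("A", "C", "G", "T"), n, TRUE),
        alt = sample(c("A", "C", "G", "T"), n, TRUE),
        gene = paste0("G", sample.int(50, n, TRUE)),
        aa_change = NA_character_,
        variant_class = sample(clonetracker::variantClasses(), n, TRUE),
        t_depth = depth,
        t_alt = rbinom(n, depth, runif(n, 0, 0.6)),
        n_depth = sample(c(0L, rpois(5, 40)), n, TRUE),
        n_alt = rbinom(n, 2, 0.2),
        stringsAsFactors = FALSE)
    out$vaf <- ifelse(out$t_depth > 0, out$t_alt / out$t_depth, 0)
    out
}

randomCatalog <- function(n, seed) {
    set.seed(seed)
    reads <- rpois(n, 30)
    rec <- data.frame(
        gene = paste0("G", sample.int(25, n, TRUE)),
        chrom = paste0("chr", sample(1:3, n, TRUE)),
        pos = sample.int(2000, n, TRUE),
        ref = sample(c("A", "C"), n, TRUE),
        alt = sample(c("G", "T"), n, TRUE),
        variant_class = sample(clonetracker::variantClasses(), n, TRUE,
                               prob = c(5, 1, 1, 1, 2, 1, 1, 1, 1)),
        reads = reads,
        stringsAsFactors = FALSE)
    rec$aaf <- round(runif(n, 0, 0.8), 3)
    miss <- runif(n) < 0.05
    rec$reads[miss] <- NA
    rec$aaf[miss] <- NA
    rec
}
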