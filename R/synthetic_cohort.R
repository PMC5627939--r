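#' Configuration for a synthetic serial tumor cohort
#'
#' Builds the parameter set for [simulateCohort()]. The defaults encode a
#' two-subclone serial case: four samples in which a primary subclone (A,
#' carrying 37 private somatic variants and 5 copies of the pathognomonic
#' gene fusion) is replaced after the first sample by a second subclone (B,
#' 21 private variants, 3 fusion copies) that additionally carries a focal
#' chromosome-1 amplification; a small set of variants (default 3) is
#' shared by both subclones. Clone mixture fractions are per sample and
#' need not sum to 1 — the remainder is normal-cell contamination.
#'
#' @param n_samples number of serial samples.
#' @param sample_labels chronological sample identifiers (default years of
#'   collection).
#' @param clone_fractions numeric matrix, \code{n_samples} rows x 2 columns
#'   (\code{A}, \code{B}): fraction of cells belonging to each subclone in
#'   each sample. Row sums must be <= 1.
#' @param n_variants_per_clone integer length-2: private variants per
#'   subclone.
#' @param n_shared_variants variants carried by both subclones.
#' @param depth_mean expected sequencing depth at variant loci (Poisson,
#'   truncated at >= 1).
#' @param normal_contamination fraction of tumor cells contaminating the
#'   matched normal; 0 (default) gives exactly 0 variant reads in normal.
#' @param fusion_breakpoint list with \code{chrom5}, \code{pos5},
#'   \code{chrom3}, \code{pos3}: the genomic fusion breakpoint, identical
#'   in every sample (the common-founder signature).
#' @param fusion_copies_per_clone integer length-2: fusion-gene copies in
#'   subclones A and B.
#' @param amp_regions data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{log2}) of focal amplifications carried only by subclone B;
#'   \code{log2} is the ratio a pure clone-B sample would show.
#' @param cn_bin_size,cn_region_start,cn_region_end,cn_depth_mean
#'   copy-number bin grid (single chromosome \code{chrom = "chr1"}) and
#'   expected per-bin read count in the matched normal.
#' @param expression_folds true DFSP-vs-reference fold changes of the genes
#'   placed inside the first amplified region; the default includes one
#'   ~100-fold overexpressed candidate.
#' @param n_reference_samples reference cohort size for expression.
#' @param total_mapped_reads library size for the case expression sample.
#' @param seed random seed; fixed seed gives bit-identical cohorts.
#' @return a validated \code{CohortConfig} (list).
#' @export
#' @examples
#' cfg <- cohortConfig(seed = 1)
#' cfg$n_samples
cohortConfig <- function(
    n_samples = 4L,
    sample_labels = c("2007", "2009", "2010", "2013"),
    clone_fractions = matrix(
        c(0.90, 0.05, 0.02, 0.02,
          0.05, 0.90, 0.90, 0.90),
        ncol = 2, dimnames = list(NULL, c("A", "B"))),
    n_variants_per_clone = c(A = 37L, B = 21L),
    n_shared_variants = 3L,
    depth_mean = 100,
    normal_contamination = 0,
    fusion_breakpoint = list(chrom5 = "chr17", pos5 = 48267200L,
                             chrom3 = "chr22", pos3 = 23632600L),
    fusion_copies_per_clone = c(A = 5L, B = 3L),
    amp_regions = data.frame(chrom = "chr1", start = 85000001,
                             end = 87000000, log2 = 1.0),
    cn_bin_size = 1e5,
    cn_region_start = 60000001,
    cn_region_end = 110000000,
    cn_depth_mean = 200,
    expression_folds = c(100, 8, 8, 5, 2, 2, 1, 1),
    n_reference_samples = 107L,
    total_mapped_reads = 2e7,
    seed = 20070423L
) {
    n_samples <- as.integer(n_samples)
    stopIfNot1(n_samples >= 1, "n_samples must be >= 1")
    stopIfNot1(length(sample_labels) == n_samples,
               "need one label per sample")
    stopIfNot1(!anyDuplicated(sample_labels), "sample labels must be unique")
    clone_fractions <- as.matrix(clone_fractions)
    stopIfNot1(nrow(clone_fractions) == n_samples,
               "clone_fractions needs one row per sample")
    if (is.null(colnames(clone_fractions)))
        colnames(clone_fractions) <- c("A", "B")
    stopIfNot1(all(clone_fractions >= 0 & clone_fractions <= 1),
               "clone fractions must lie in [0,1]")
    bad <- which(rowSums(clone_fractions) > 1 + 1e-12)
    if (length(bad))
        stop(sprintf(
            "clone fractions in sample(s) %s sum to > 1; the remainder is normal contamination and cannot be negative",
            paste(sample_labels[bad], collapse = ", ")), call. = FALSE)
    stopIfNot1(depth_mean >= 1, "depth_mean must be >= 1")
    stopIfNot1(all(fusion_copies_per_clone >= 0), "fusion copies must be >= 0")
    stopIfNot1(normal_contamination >= 0 && normal_contamination <= 1,
               "normal_contamination must lie in [0,1]")
    cfg <- list(
        n_samples = n_samples, sample_labels = as.character(sample_labels),
        clone_fractions = clone_fractions,
        n_variants_per_clone = n_variants_per_clone,
        n_shared_variants = as.integer(n_shared_variants),
        depth_mean = depth_mean,
        normal_contamination = normal_contamination,
        fusion_breakpoint = fusion_breakpoint,
        fusion_copies_per_clone = fusion_copies_per_clone,
        amp_regions = amp_regions,
        cn_bin_size = cn_bin_size,
        cn_region_start = cn_region_start,
        cn_region_end = cn_region_end,
        cn_depth_mean = cn_depth_mean,
        expression_folds = expression_folds,
        n_reference_samples = as.integer(n_reference_samples),
        total_mapped_reads = total_mapped_reads,
        seed = as.integer(seed))
    class(cfg) <- "CohortConfig"
    cfg
}

#' Expected variant allele fraction under a clone mixture
#'
#' For a variant carried on \code{m} of \code{c_t} tumor copies by a cell
#' population at fraction \code{f} (the rest of the sample being diploid),
#' the expected VAF is \code{f * m / (f * c_t + (1 - f) * 2)}. With a
#' single mutated copy on a diploid background this reduces to \code{f/2}.
#'
#' @param f carrier cell fraction in \code{[0,1]}.
#' @param m mutated copies per carrier cell.
#' @param c_t total tumor copies at the locus in carrier cells.
#' @return expected VAF.
#' @export
#' @examples
#' expectedVaf(1)           # 0.5: clonal het variant, pure tumor
#' expectedVaf(0.8)         # 0.4
expectedVaf <- function(f, m = 1, c_t = 2) {
    denom <- f * c_t + (1 - f) * 2
    ifelse(denom > 0, f * m / denom, 0)
}

rpoisTrunc1 <- function(n, lambda) {
    pmax(1L, stats::rpois(n, lambda))
}

## deterministic synthetic loci: variants avoid chr1 (reserved for the CN
## bin grid) so every variant sits on a locally diploid background
simulateVariantLoci <- function(n, offset = 0L) {
    if (n == 0L) {
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene = character(), aa_change = character(),
                          variant_class = character(),
                          stringsAsFactors = FALSE))
    }
    bases <- c("A", "C", "G", "T")
    chrom <- paste0("chr", sample(2:22, n, replace = TRUE))
    pos <- sample.int(2e8, n)
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    cls <- sample(c("missense", "silent", "nonsense", "deletion",
                    "insertion", "splice", "UTR"),
                  n, replace = TRUE,
                  prob = c(0.62, 0.12, 0.06, 0.06, 0.06, 0.04, 0.04))
    ref[cls == "deletion"] <- vapply(seq_len(sum(cls == "deletion")),
        function(i) paste(sample(bases, 2, replace = TRUE), collapse = ""),
        "")
    alt[cls == "deletion"] <- "-"
    ref[cls == "insertion"] <- "-"
    alt[cls == "insertion"] <- vapply(seq_len(sum(cls == "insertion")),
        function(i) paste(sample(bases, 2, replace = TRUE), collapse = ""),
        "")
    aa <- paste0(sample(LETTERS[c(1, 3:9)], n, TRUE),
                 sample.int(999, n, TRUE),
                 sample(LETTERS[c(1, 3:9)], n, TRUE))
    aa[cls %in% c("deletion", "insertion")] <-
        paste0("E", sample.int(999, sum(cls %in% c("deletion", "insertion")),
                               TRUE), "fs")
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               gene = sprintf("GENE%04d", offset + seq_len(n)),
               aa_change = aa, variant_class = cls,
               stringsAsFactors = FALSE)
}

#' Simulate a serial tumor cohort with known clonal truth
#'
#' Draws a complete multi-stage dataset — per-sample somatic variant
#' tables, copy-number bin counts, fusion records and an expression table
#' with a reference cohort — from the clonal-evolution generative model in
#' [cohortConfig()]. Read counts at variant loci are
#' \code{Binomial(depth, expected VAF)} with Poisson depths (truncated at
#' 1); copy-number bin counts are Poisson with rates proportional to the
#' mixture copy number; the fusion breakpoint is identical in all samples
#' while its copy number follows the dominant subclone. The returned
#' \code{truth} records every latent quantity so downstream stages can be
#' scored against it.
#'
#' @param config a [cohortConfig()].
#' @return list with elements \code{truth}, \code{variants} (named list of
#'   per-sample data.frames), \code{cn_bins} (named list), \code{fusions}
#'   (data.frame), \code{expression} (data.frame), \code{reference_rpkm}
#'   (matrix), \code{gene_annotation} (data.frame), \code{config}.
#' @export
#' @examples
#' sim <- simulateCohort(cohortConfig(seed = 7))
#' table(sim$truth$assignment$clone)
simulateCohort <- function(config = cohortConfig()) {
    stopIfNot1(inherits(config, "CohortConfig"),
               "config must come from cohortConfig()")
    set.seed(config$seed)
    nS <- config$n_samples
    labs <- config$sample_labels
    fr <- config$clone_fractions

    nA <- as.integer(config$n_variants_per_clone[[1]])
    nB <- as.integer(config$n_variants_per_clone[[2]])
    nSh <- config$n_shared_variants
    loci <- simulateVariantLoci(nA + nB + nSh)
    clone <- rep(c("A", "B", "shared"), c(nA, nB, nSh))
    nV <- nrow(loci)

    ## expected VAF per variant per sample: carrier fraction is the clone
    ## fraction (shared variants: both clones), single mutated copy on a
    ## locally diploid background
    carrier <- cbind(A = fr[, "A"], B = fr[, "B"],
                     shared = fr[, "A"] + fr[, "B"])
    expVaf <- matrix(0, nV, nS, dimnames = list(NULL, labs))
    for (s in seq_len(nS))
        expVaf[, s] <- expectedVaf(carrier[s, clone])

    variants <- vector("list", nS)
    names(variants) <- labs
    for (s in seq_len(nS)) {
        t_depth <- rpoisTrunc1(nV, config$depth_mean)
        t_alt <- stats::rbinom(nV, t_depth, expVaf[, s])
        n_depth <- rpoisTrunc1(nV, config$depth_mean)
        n_alt <- stats::rbinom(nV, n_depth,
                               config$normal_contamination * expVaf[, s])
        variants[[s]] <- data.frame(
            sample_id = rep(labs[s], nV),
            chrom = loci$chrom, pos = loci$pos,
            ref = loci$ref, alt = loci$alt,
            gene = loci$gene, aa_change = loci$aa_change,
            variant_class = loci$variant_class,
            t_depth = t_depth, t_alt = t_alt,
            n_depth = n_depth, n_alt = n_alt,
            vaf = ifelse(t_depth > 0, t_alt / t_depth, 0),
            stringsAsFactors = FALSE)
    }

    ## copy-number bins on chr1; subclone B carries the amp regions
    starts <- seq(config$cn_region_start, config$cn_region_end,
                  by = config$cn_bin_size)
    ends <- pmin(starts + config$cn_bin_size - 1, config$cn_region_end)
    nBins <- length(starts)
    ampCopy <- rep(2, nBins)  # copy number inside clone B
    amp <- config$amp_regions
    if (!is.null(amp) && nrow(amp)) {
        for (r in seq_len(nrow(amp))) {
            hit <- amp$chrom[r] == "chr1" &
                starts <= amp$end[r] & ends >= amp$start[r]
            ampCopy[hit] <- 2 * 2^amp$log2[r]
        }
    }
    cn_bins <- vector("list", nS)
    names(cn_bins) <- labs
    expSampleCopy <- matrix(0, nBins, nS, dimnames = list(NULL, labs))
    for (s in seq_len(nS)) {
        fB <- fr[s, "B"]
        cs <- fB * ampCopy + (1 - fB) * 2
        expSampleCopy[, s] <- cs
        cn_bins[[s]] <- data.frame(
            sample_id = labs[s], chrom = "chr1",
            start = starts, end = ends,
            tumor_count = stats::rpois(nBins, config$cn_depth_mean * cs / 2),
            normal_count = stats::rpois(nBins, config$cn_depth_mean),
            stringsAsFactors = FALSE)
    }

    ## fusion: same breakpoint everywhere, copy number from clone mixture
    bp <- config$fusion_breakpoint
    cpc <- config$fusion_copies_per_clone
    fusCopy <- fr[, "A"] * cpc[[1]] + fr[, "B"] * cpc[[2]] +
        (1 - rowSums(fr)) * 2
    fusions <- data.frame(
        sample_id = labs, gene5 = "COL1A1", gene3 = "PDGFB",
        chrom5 = bp$chrom5, pos5 = bp$pos5,
        chrom3 = bp$chrom3, pos3 = bp$pos3,
        supporting_reads = stats::rpois(nS, config$depth_mean * fusCopy / 4),
        log2_ratio = log2(fusCopy / 2),
        stringsAsFactors = FALSE)

    ## expression: genes inside the first amp region, one ~100-fold
    ## candidate, plus diploid background genes
    folds <- config$expression_folds
    nAmpG <- length(folds)
    nBg <- 20L
    geneNames <- c(sprintf("AMPG%02d", seq_len(nAmpG)),
                   sprintf("BGG%02d", seq_len(nBg)))
    lengths_bp <- sample(1000:9000, nAmpG + nBg, replace = TRUE)
    if (nrow(config$amp_regions)) {
        a1 <- config$amp_regions[1, ]
        gStart <- floor(seq(a1$start, a1$end - 2e4,
                            length.out = max(nAmpG, 1)))
        geneAnno <- data.frame(
            gene = geneNames,
            chrom = c(rep(a1$chrom, nAmpG), rep("chr9", nBg)),
            start = c(gStart, seq(1e6, by = 2e5, length.out = nBg)),
            stringsAsFactors = FALSE)
    } else {
        geneAnno <- data.frame(
            gene = geneNames, chrom = rep("chr9", nAmpG + nBg),
            start = seq(1e6, by = 2e5, length.out = nAmpG + nBg),
            stringsAsFactors = FALSE)
    }
    geneAnno$end <- geneAnno$start + lengths_bp - 1
    refMedian <- exp(stats::rnorm(nAmpG + nBg, log(20), 1))
    trueFold <- c(folds, rep(1, nBg))
    nRef <- config$n_reference_samples
    refRpkm <- matrix(
        refMedian * exp(stats::rnorm((nAmpG + nBg) * nRef, 0, 0.3)),
        nrow = nAmpG + nBg,
        dimnames = list(geneNames, sprintf("REF%03d", seq_len(nRef))))
    targetRpkm <- refMedian * trueFold
    expCount <- stats::rpois(
        nAmpG + nBg,
        targetRpkm * (lengths_bp / 1000) * (config$total_mapped_reads / 1e6))
    expression <- data.frame(
        gene = geneNames, length_bp = lengths_bp, count = expCount,
        total_mapped = config$total_mapped_reads,
        stringsAsFactors = FALSE)

    truth <- list(
        assignment = data.frame(
            key = variantKey(loci$chrom, loci$pos, loci$ref, loci$alt),
            chrom = loci$chrom, pos = loci$pos, ref = loci$ref,
            alt = loci$alt, gene = loci$gene, clone = clone,
            stringsAsFactors = FALSE),
        clone_fractions = fr,
        expected_vaf = expVaf,
        amp_regions = amp,
        expected_bin_copy = expSampleCopy,
        fusion = list(breakpoint = bp,
                      copies_per_clone = cpc,
                      sample_copy = fusCopy,
                      sample_log2 = log2(fusCopy / 2)),
        expression = data.frame(gene = geneNames, true_fold = trueFold,
                                in_amp = c(rep(nrow(config$amp_regions) > 0,
                                               nAmpG), rep(FALSE, nBg)),
                                stringsAsFactors = FALSE))

    list(truth = truth, variants = variants, cn_bins = cn_bins,
         fusions = fusions, expression = expression,
         reference_rpkm = refRpkm, gene_annotation = geneAnno,
         config = config)
}

#' Write a simulated cohort to plain-text fixture files
#'
#' Serializes [simulateCohort()] output into the formats the readers
#' consume: one MAF-like TSV per sample, a per-bin copy-number TSV, a
#' truth SEG file of expected log2 ratios, a fusion TSV, expression and
#' reference-RPKM TSVs, a BED (0-based half-open) gene annotation, and a
#' truth JSON. Files round-trip through [readVariantTable()] and
#' [readSegFile()].
#'
#' @param sim output of [simulateCohort()].
#' @param out_dir output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
writeFixtures <- function(sim, out_dir) {
    if (!dir.exists(out_dir))
        dir.create(out_dir, recursive = TRUE)
    stopIfNot1(dir.exists(out_dir), "cannot create directory '%s'", out_dir)
    paths <- c()
    for (s in names(sim$variants)) {
        v <- sim$variants[[s]]
        maf <- data.frame(
            Hugo_Symbol = v$gene, Chromosome = v$chrom,
            Start_Position = v$pos, Reference_Allele = v$ref,
            Tumor_Seq_Allele2 = v$alt,
            Variant_Classification = v$variant_class,
            Protein_Change = v$aa_change,
            t_depth = v$t_depth, t_alt_count = v$t_alt,
            n_depth = v$n_depth, n_alt_count = v$n_alt,
            stringsAsFactors = FALSE)
        p <- file.path(out_dir, paste0(s, ".variants.tsv"))
        utils::write.table(maf, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths[paste0("variants_", s)] <- p
    }
    bins <- do.call(rbind, sim$cn_bins)
    p <- file.path(out_dir, "cn_bins.tsv")
    utils::write.table(bins, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["cn_bins"] <- p

    ## truth SEG: expected log2 per contiguous constant-copy run
    segRows <- list()
    for (s in names(sim$cn_bins)) {
        b <- sim$cn_bins[[s]]
        l2 <- log2(sim$truth$expected_bin_copy[, s] / 2)
        runs <- rle(l2)
        idx <- cumsum(runs$lengths)
        st <- c(1, head(idx, -1) + 1)
        segRows[[s]] <- data.frame(
            sample_id = s, chrom = b$chrom[st],
            start = b$start[st], end = b$end[idx],
            n_bins = runs$lengths, log2_ratio = runs$values,
            stringsAsFactors = FALSE)
    }
    p <- file.path(out_dir, "truth.seg")
    writeSegFile(do.call(rbind, segRows), p)
    paths["truth_seg"] <- p

    p <- file.path(out_dir, "fusions.tsv")
    utils::write.table(sim$fusions, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["fusions"] <- p

    p <- file.path(out_dir, "expression.tsv")
    utils::write.table(sim$expression, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["expression"] <- p

    p <- file.path(out_dir, "reference_rpkm.tsv")
    utils::write.table(
        data.frame(gene = rownames(sim$reference_rpkm),
                   sim$reference_rpkm, check.names = FALSE),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["reference_rpkm"] <- p

    ## BED is 0-based half-open
    bed <- data.frame(chrom = sim$gene_annotation$chrom,
                      start = sim$gene_annotation$start - 1,
                      end = sim$gene_annotation$end,
                      name = sim$gene_annotation$gene)
    p <- file.path(out_dir, "genes.bed")
    utils::write.table(bed, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths["genes_bed"] <- p

    p <- file.path(out_dir, "truth.json")
    jsonlite::write_json(
        list(assignment = sim$truth$assignment,
             clone_fractions = as.data.frame(sim$truth$clone_fractions),
             sample_labels = sim$config$sample_labels,
             fusion_sample_copy = sim$truth$fusion$sample_copy,
             expression = sim$truth$expression),
        p, digits = NA)
    paths["truth"] <- p
    invisible(paths)
}
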