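writeMaf <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

mafRow <- function(gene = "SPTA1", chrom = "chr1", pos = 158644387,
                   ref = "T", alt = "A", class = "Missense_Mutation",
                   t_depth = 100, t_alt = 30, n_depth = 80, n_alt = 0) {
    data.frame(Hugo_Symbol = gene, Chromosome = chrom,
               Start_Position = pos, Reference_Allele = ref,
               Tumor_Seq_Allele2 = alt, Variant_Classification = class,
               t_depth = t_depth, t_alt_count = t_alt,
               n_depth = n_depth, n_alt_count = n_alt,
               stringsAsFactors = FALSE)
}

test_that("MAF-like TSV rows parse into variant calls with VAF", {
    p <- writeMaf(mafRow(), withr::local_tempfile(fileext = ".tsv"))
    calls <- readVariantTable(p, format = "maf_tsv", sample_id = "2009")
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$gene, "SPTA1")
    expect_equal(calls$chrom, "chr1")
    expect_equal(calls$pos, 158644387L)
    expect_equal(calls$ref, "T")
    expect_equal(calls$alt, "A")
    expect_equal(calls$variant_class, "missense")
    expect_equal(calls$vaf, 0.30)
})

test_that("an empty table with a header yields an empty call list", {
    p <- writeMaf(mafRow()[0, ], withr::local_tempfile(fileext = ".tsv"))
    expect_equal(nrow(readVariantTable(p, format = "maf_tsv")), 0L)
})

test_that("malformed headers and invalid counts are rejected by name", {
    p <- withr::local_tempfile(fileext = ".tsv")
    writeLines("Chromosome\tStart_Position\nchr1\t5", p)
    expect_error(readVariantTable(p, format = "maf_tsv"),
                 "Reference_Allele")
    p2 <- writeMaf(mafRow(t_depth = 10, t_alt = 30),
                   withr::local_tempfile(fileext = ".tsv"))
    expect_error(readVariantTable(p2, format = "maf_tsv"),
                 "t_alt exceeds t_depth")
})

test_that("VCF AD/DP map to alt/total depth and indels use '-'", {
    p <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
        "##contig=<ID=chr1>",
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", "TUMOR", sep = "\t"),
        paste("chr1", "100", ".", "A", "T", ".", "PASS", ".",
              "DP:AD", "50:35,15", sep = "\t"),
        paste("chr1", "200", ".", "CA", "C", ".", "PASS", ".",
              "DP:AD", "60:40,20", sep = "\t")), p)
    calls <- readVariantTable(p, format = "vcf", sample_id = "s1")
    expect_equal(calls$t_depth, c(50, 60))
    expect_equal(calls$t_alt, c(15, 20))
    expect_equal(calls$vaf[1], 0.30)
    # left-aligned deletion CA>C becomes pos+1, ref A, alt "-"
    expect_equal(calls$pos[2], 201L)
    expect_equal(calls$ref[2], "A")
    expect_equal(calls$alt[2], "-")
    expect_equal(calls$variant_class[2], "deletion")
})

test_that("somatic filter applies inclusive 20x/20% and strict normal rules", {
    calls <- rbind(
        data.frame(sample_id = "s", chrom = "chr1", pos = 1:4,
                   ref = "A", alt = "T", gene = "G", aa_change = NA,
                   variant_class = "missense",
                   t_depth = c(19, 20, 100, 100),
                   t_alt = c(10, 4, 40, 40),
                   n_depth = c(50, 50, 50, 0),
                   n_alt = c(0, 0, 1, 0), stringsAsFactors = FALSE))
    calls$vaf <- calls$t_alt / calls$t_depth
    out <- filterSomatic(calls)
    # depth 19 fails; 20x at exactly 20% passes; 1 normal read fails;
    # normal depth 0 is unevaluable
    expect_equal(out$pos, 2L)
    rep <- attr(out, "filter_report")
    expect_equal(rep$normal_unevaluable, 1L)
    expect_equal(rep$input, 4L)
    expect_equal(rep$retained, 1L)
})

test_that("somatic filter is idempotent, monotone, and matches brute force", {
    for (seed in 1:5) {
        calls <- randomCalls(300, seed)
        f1 <- filterSomatic(calls)
        f2 <- filterSomatic(f1)
        expect_equal(f1, f2, ignore_attr = TRUE)
        expect_equal(f1, bruteFilterSomatic(calls), ignore_attr = TRUE)
        # raising min_depth never adds calls
        strict <- filterSomatic(calls, min_depth = 40)
        expect_true(all(with(strict, paste(chrom, pos, ref, alt)) %in%
                            with(f1, paste(chrom, pos, ref, alt))))
    }
})

test_that("harmonization enforces depth in every sample", {
    mk <- function(pos, depth, alt, sample) {
        df <- data.frame(sample_id = sample, chrom = "chr1", pos = pos,
                         ref = "A", alt = "T", gene = "G",
                         aa_change = NA, variant_class = "missense",
                         t_depth = depth, t_alt = alt,
                         n_depth = 50, n_alt = 0,
                         stringsAsFactors = FALSE)
        df$vaf <- ifelse(df$t_depth > 0, df$t_alt / df$t_depth, 0)
        df
    }
    lists <- list(
        s1 = mk(c(10, 20), c(25, 30), c(5, 12), "s1"),
        s2 = mk(c(10, 20), c(25, 30), c(0, 0), "s2"),
        s3 = mk(c(10, 20), c(19, 30), c(0, 0), "s3"),
        s4 = mk(c(10, 20), c(25, 30), c(0, 0), "s4"))
    vm <- harmonizeAcrossSamples(lists, min_depth_all = 20)
    # pos 10 has depth 19 in s3 -> dropped; pos 20 retained with
    # vaf (0.4, 0, 0, 0)
    expect_equal(nrow(vm), 1L)
    expect_equal(unname(SummarizedExperiment::assay(vm, "vaf")[1, ]),
                 c(0.4, 0, 0, 0))
})

test_that("harmonization errors on duplicate keys and single samples", {
    df <- randomCalls(5, 1)
    dup <- rbind(df[1, ], df[1, ])
    expect_error(harmonizeAcrossSamples(list(a = dup, b = df)),
                 "duplicate variant key")
    expect_error(harmonizeAcrossSamples(list(a = df)), ">= 2 samples")
})

test_that("harmonization is order-invariant and monotone in depth", {
    sim <- simulateCohort(cohortConfig(seed = 21))
    raw <- sim$variants
    vm <- harmonizeAcrossSamples(raw, min_depth_all = 20)
    vmRev <- harmonizeAcrossSamples(rev(raw), min_depth_all = 20)
    labs <- names(raw)
    expect_equal(SummarizedExperiment::assay(vm, "vaf"),
                 SummarizedExperiment::assay(vmRev, "vaf")[, labs])
    # brute-force oracle: retained set = keys whose min depth across all
    # samples is >= 20
    depths <- sapply(raw, function(x) x$t_depth)
    keys <- with(raw[[1]], paste(chrom, pos, ref, alt, sep = ":"))
    expected <- sort(keys[apply(depths, 1, min) >= 20])
    expect_equal(sort(rownames(vm)), expected)
    # monotonicity
    vm30 <- harmonizeAcrossSamples(raw, min_depth_all = 30)
    expect_true(all(rownames(vm30) %in% rownames(vm)))
})
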