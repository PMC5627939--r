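test_that("RPKM follows its defining arithmetic", {
    expect_equal(computeRpkm(10, 1000, 1e6), 10)
    expect_equal(computeRpkm(0, 1000, 1e6), 0)
    # 349 reads on a 3,495 bp transcript in a 2M-read library
    expect_equal(computeRpkm(349, 3495, 2e6), 349 / (3.495 * 2))
    expect_equal(round(computeRpkm(349, 3495, 2e6), 2), 49.93)
    expect_error(computeRpkm(10, 0, 1e6), "length_bp")
})

test_that("RPKM scales linearly in count, inversely in length and library", {
    base <- computeRpkm(100, 2000, 1e7)
    expect_equal(computeRpkm(200, 2000, 1e7), 2 * base)
    expect_equal(computeRpkm(100, 4000, 1e7), base / 2)
    expect_equal(computeRpkm(100, 2000, 2e7), base / 2)
    # doubling count and library together leaves rpkm fixed
    expect_equal(computeRpkm(200, 2000, 2e7), base)
})

test_that("fold change reproduces the printed display convention", {
    fc <- foldChange(274.24, 2.80)
    expect_equal(fc$fold_change_raw, 274.24 / 2.80)
    expect_equal(fc$fold_change_display, 98)
    expect_equal(foldChange(722.37, 6.54)$fold_change_display, 110)
    expect_equal(foldChange(5, 5)$fold_change_display, 1)
    # the reference median is the median of the supplied cohort
    fc2 <- foldChange(10, c(1, 2, 3))
    expect_equal(fc2$reference_median, 2)
    # zero reference median flags infinity rather than dividing
    fc0 <- foldChange(10, c(0, 0, 0))
    expect_true(fc0$infinite)
    expect_true(is.na(fc0$fold_change_raw))
    # fold_change(x, [x]) = 1 for any x > 0
    for (x in c(0.01, 1, 274.24))
        expect_equal(foldChange(x, x)$fold_change_raw, 1)
})

toyFolds <- function() {
    data.frame(gene = paste0("g", 1:8),
               fold_change_raw = c(98, 8, 8, 5, 2, 2, 1, 1),
               fold_change_display = c(98, 8, 8, 5, 2, 2, 1, 1),
               stringsAsFactors = FALSE)
}

toyAnno <- function() {
    data.frame(gene = paste0("g", 1:8), chrom = "chr1",
               start = seq(100, by = 1000, length.out = 8),
               end = seq(600, by = 1000, length.out = 8),
               stringsAsFactors = FALSE)
}

toyAmp <- function() {
    data.frame(chrom = "chr1", start = 1, end = 1e5,
               stringsAsFactors = FALSE)
}

test_that("candidate prioritization thresholds and ranks the toy set", {
    out <- prioritizeCandidates(toyAmp(), toyAnno(), toyFolds(),
                                min_fold = 5)
    cand <- out[out$status == "candidate", ]
    expect_equal(nrow(cand), 4L)
    expect_equal(cand$fold_change_raw, c(98, 8, 8, 5))
    expect_equal(cand$rank, 1:4)
    # tie at 8 broken alphabetically
    expect_equal(cand$gene[2:3], c("g2", "g3"))
    expect_equal(brutePrioritize(toyAmp(), toyAnno(), toyFolds(), 5),
                 cand$gene)
    # lowering the threshold admits the x2 genes
    out2 <- prioritizeCandidates(toyAmp(), toyAnno(), toyFolds(),
                                 min_fold = 2)
    expect_equal(sum(out2$status == "candidate"), 6L)
    # non-candidates keep their folds in the report
    expect_true(all(c("g7", "g8") %in%
                        out$gene[out$status == "non-candidate"]))
})

test_that("empty amplification lists and unquantified genes are handled", {
    empty <- prioritizeCandidates(toyAmp()[0, ], toyAnno(), toyFolds())
    expect_equal(nrow(empty), 0L)
    anno <- rbind(toyAnno(),
                  data.frame(gene = "g9", chrom = "chr1", start = 200,
                             end = 700, stringsAsFactors = FALSE))
    out <- prioritizeCandidates(toyAmp(), anno, toyFolds())
    expect_equal(out$status[out$gene == "g9"], "unquantified")
})

test_that("prioritization matches brute force on random inputs", {
    for (seed in 1:5) {
        set.seed(seed)
        n <- 30
        anno <- data.frame(gene = paste0("r", 1:n),
                           chrom = sample(c("chr1", "chr2"), n, TRUE),
                           start = sample.int(1e6, n), stringsAsFactors = FALSE)
        anno$end <- anno$start + 5000
        amp <- data.frame(chrom = "chr1", start = c(1, 5e5),
                          end = c(2e5, 8e5), stringsAsFactors = FALSE)
        raw <- round(runif(n, 0, 40), 2)
        fc <- data.frame(gene = anno$gene, fold_change_raw = raw,
                         fold_change_display =
                             clonetracker::roundHalfAwayFromZero(raw),
                         stringsAsFactors = FALSE)
        out <- prioritizeCandidates(amp, anno, fc, min_fold = 5)
        expect_equal(out$gene[out$status == "candidate"],
                     brutePrioritize(amp, anno, fc, 5))
    }
})

test_that("the synthetic ~100-fold candidate gene ranks first", {
    sim <- simulateCohort(cohortConfig(seed = 19))
    fc <- rankAmplifiedGenes(sim$expression, sim$reference_rpkm)
    out <- prioritizeCandidates(sim$config$amp_regions,
                                sim$gene_annotation, fc)
    expect_equal(out$gene[1], "AMPG01")
    expect_equal(out$fold_change_display[1], 100, tolerance = 0.15)
    # background genes sit outside the amplified region
    expect_false(any(grepl("^BGG", out$gene)))
})
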