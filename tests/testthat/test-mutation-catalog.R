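catalogRow <- function(gene = "G1", class = "missense", reads = 50,
                       aaf = 0.5, chrom = "chr1", pos = 100,
                       ref = "A", alt = "T") {
    data.frame(gene = gene, chrom = chrom, pos = pos, ref = ref,
               alt = alt, variant_class = class, reads = reads,
               aaf = aaf, stringsAsFactors = FALSE)
}

test_that("catalog filter enforces reads, ratio and coding class", {
    recs <- rbind(
        catalogRow(reads = 19),                       # below read floor
        catalogRow(reads = 20, aaf = 0.2),            # inclusive bounds
        catalogRow(class = "splice", reads = 100, aaf = 0.5),
        catalogRow(class = "UTR"), catalogRow(class = "RNA"),
        catalogRow(aaf = 0.19),
        catalogRow(reads = NA, aaf = NA))
    out <- filterCatalog(recs)
    expect_equal(nrow(out), 1L)
    expect_equal(out$reads, 20)
    rep <- attr(out, "filter_report")
    expect_equal(rep$depth_missing, 1L)
    expect_equal(rep$fail_class, 3L)
})

test_that("catalog filter matches the brute-force oracle", {
    for (seed in 1:5) {
        recs <- randomCatalog(1000, seed)
        expect_equal(filterCatalog(recs), bruteFilterCatalog(recs),
                     ignore_attr = TRUE)
    }
})

test_that("silent fraction counts and display rounding are exact", {
    recs <- rbind(
        do.call(rbind, replicate(3, catalogRow(class = "silent"),
                                 simplify = FALSE)),
        do.call(rbind, replicate(9, catalogRow(class = "missense"),
                                 simplify = FALSE)))
    sf <- silentFraction(recs, "G1")
    expect_equal(sf$silent_fraction, 0.25)
    expect_equal(sf$silent_percent, 25)
    expect_equal(sf$total_mutations, 12L)
    # a gene with zero silent calls reports 0%, not NA
    recs373 <- do.call(rbind, replicate(373, catalogRow(class = "missense"),
                                        simplify = FALSE))
    sf373 <- silentFraction(recs373, "G1")
    expect_equal(sf373$silent_percent, 0)
    expect_equal(sf373$total_mutations, 373L)
    # an absent gene has an undefined fraction, distinct from 0%
    sfAbs <- silentFraction(recs, "NOPE")
    expect_true(is.na(sfAbs$silent_fraction))
    expect_equal(sfAbs$total_mutations, 0L)
})

test_that("silent fraction is order-invariant and strictly increases with
           one more silent record", {
    for (seed in 1:5) {
        recs <- filterCatalog(randomCatalog(600, seed))
        g <- names(sort(table(recs$gene), decreasing = TRUE))[1]
        sf <- silentFraction(recs, g)
        oracle <- bruteSilentFraction(recs, g)
        expect_equal(sf$silent_fraction, unname(oracle["fraction"]))
        set.seed(seed)
        perm <- recs[sample(nrow(recs)), ]
        expect_equal(silentFraction(perm, g)$silent_fraction,
                     sf$silent_fraction)
        if (sf$silent_fraction < 1) {
            more <- rbind(recs, catalogRow(gene = g, class = "silent"))
            expect_gt(silentFraction(more, g)$silent_fraction,
                      sf$silent_fraction)
        }
    }
})

test_that("recurrence lookup counts exact key matches", {
    cat0 <- rbind(catalogRow(pos = 100), catalogRow(pos = 100),
                  catalogRow(pos = 200))
    q <- data.frame(chrom = "chr1", pos = c(100, 300), ref = "A",
                    alt = "T", stringsAsFactors = FALSE)
    out <- recurrenceLookup(cat0, q)
    expect_equal(out$recurrence_count, c(2L, 0L))
    for (seed in 1:5) {
        cat1 <- randomCatalog(800, seed)
        set.seed(seed + 100)
        q1 <- cat1[sample(nrow(cat1), 20), c("chrom", "pos", "ref", "alt")]
        q1 <- rbind(q1, data.frame(chrom = "chrX", pos = 1, ref = "A",
                                   alt = "T"))
        expect_equal(recurrenceLookup(cat1, q1)$recurrence_count,
                     bruteRecurrence(cat1, q1))
    }
})

test_that("driver/passenger bands classify as documented", {
    sm <- data.frame(silent_fraction = c(0.02, 0.27, 0.02, 0.10, NA),
                     total_mutations = c(373, 100, 10, 100, 0))
    expect_equal(classifyDriverLike(sm),
                 c("driver-like", "passenger-like", "indeterminate",
                   "indeterminate", "indeterminate"))
    # bands are mutually exclusive and exhaustive over defined fractions
    grid <- expand.grid(f = seq(0, 1, by = 0.01), t = c(10, 30, 100))
    cls <- classifyDriverLike(data.frame(silent_fraction = grid$f,
                                         total_mutations = grid$t))
    expect_true(all(cls %in% c("driver-like", "passenger-like",
                               "indeterminate")))
    expect_false(any(cls[grid$f > 0.05] == "driver-like"))
    expect_false(any(cls[grid$f < 0.15] == "passenger-like"))
})

test_that("MAF catalogs load and summarize end to end", {
    maf <- data.frame(
        Hugo_Symbol = c("SPTA1", "SPTA1", "KRAS"),
        Chromosome = "chr1", Start_Position = c(10, 20, 30),
        Reference_Allele = "T", Tumor_Seq_Allele2 = "A",
        Variant_Classification = c("Silent", "Missense_Mutation",
                                   "Missense_Mutation"),
        t_depth = 100, t_alt_count = 40, stringsAsFactors = FALSE)
    p <- withr::local_tempfile(fileext = ".maf")
    write.table(maf, p, sep = "\t", quote = FALSE, row.names = FALSE)
    cat0 <- readMafCatalog(p)
    expect_equal(cat0$variant_class,
                 c("silent", "missense", "missense"))
    expect_equal(cat0$aaf, rep(0.4, 3))
    tab <- catalogSummaryTable(
        filterCatalog(cat0),
        data.frame(gene = "SPTA1", chrom = "chr1", pos = 158644387,
                   ref = "T", alt = "A", stringsAsFactors = FALSE))
    expect_equal(tab$recurrence_count, 0L)
    expect_equal(tab$silent_percent, 50)
})
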