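presenceFixture <- function(mat, samples = paste0("s", seq_len(ncol(mat)))) {
    dimnames(mat) <- list(
        sprintf("chr1:%d:A:T", seq_len(nrow(mat))), samples)
    mat
}

test_that("presence calls are strict at the threshold and propagate NA", {
    sim <- simulateCohort(cohortConfig(seed = 2))
    vm <- harmonizeAcrossSamples(sim$variants)
    v <- SummarizedExperiment::assay(vm, "vaf")
    pres <- callPresence(vm, presence_vaf = 0.10)
    expect_identical(pres, v > 0.10)
    # exactly 0.10 is absent ("greater than"), zero matrix is all-false
    m <- matrix(c(0.10, 0, 0.100001, 0), 2, 2)
    expect_equal(m > 0.10, matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2))
})

test_that("disjoint presence profiles yield two exclusive clones", {
    mat <- presenceFixture(rbind(
        matrix(rep(c(TRUE, FALSE, FALSE, FALSE), 3), 3, byrow = TRUE),
        matrix(rep(c(FALSE, TRUE, TRUE, TRUE), 3), 3, byrow = TRUE)))
    part <- partitionClones(mat)
    sz <- cloneSizes(part)
    expect_equal(unname(sz[c("A", "B")]), c(3L, 3L))
    expect_equal(exclusivityIndex(part), 1.0)
})

test_that("all-present variants collapse to the shared group", {
    mat <- presenceFixture(matrix(TRUE, 5, 3))
    part <- partitionClones(mat)
    expect_true(all(cloneAssignment(part)$clone == "shared"))
})

test_that("partitioning a single sample is an error", {
    expect_error(partitionClones(presenceFixture(matrix(TRUE, 3, 1))),
                 "single sample")
})

test_that("partition recovers the synthetic truth (37/21/3)", {
    sim <- simulateCohort(cohortConfig(seed = 13))
    vm <- harmonizeAcrossSamples(sim$variants)
    pres <- callPresence(vm)
    # presence should match truth membership (expected VAF above the
    # threshold) for >= 95% of cells
    truthPres <- sim$truth$expected_vaf > 0.10
    rownames(truthPres) <- sim$truth$assignment$key
    common <- intersect(rownames(pres), rownames(truthPres))
    agree <- mean(pres[common, ] == truthPres[common, ], na.rm = TRUE)
    expect_gte(agree, 0.95)
    part <- partitionClones(vm)
    asg <- merge(cloneAssignment(part), sim$truth$assignment,
                 by = "key", suffixes = c("_called", "_true"))
    acc <- mean(asg$clone_called == asg$clone_true)
    expect_gte(acc, 0.95)
})

test_that("partition is invariant to variant row order", {
    sim <- simulateCohort(cohortConfig(seed = 17))
    vm <- harmonizeAcrossSamples(sim$variants)
    pres <- callPresence(vm)
    set.seed(1)
    perm <- sample(nrow(pres))
    p1 <- cloneAssignment(partitionClones(pres))
    p2 <- cloneAssignment(partitionClones(pres[perm, ]))
    m <- merge(p1, p2, by = "key")
    expect_true(all(m$clone.x == m$clone.y))
})

test_that("hamming-1 merging absorbs one noisy cell into a clone", {
    mat <- presenceFixture(rbind(
        matrix(rep(c(TRUE, FALSE, FALSE, FALSE), 5), 5, byrow = TRUE),
        c(TRUE, TRUE, FALSE, FALSE),            # one noisy extra cell
        matrix(rep(c(FALSE, TRUE, TRUE, TRUE), 4), 4, byrow = TRUE)))
    part <- partitionClones(mat)
    sz <- cloneSizes(part)
    expect_equal(unname(sz["A"]), 6L)
    expect_equal(unname(sz["B"]), 4L)
})

test_that("abrupt replacement gives one event at the first interval", {
    mat <- presenceFixture(rbind(
        matrix(rep(c(TRUE, FALSE, FALSE, FALSE), 4), 4, byrow = TRUE),
        matrix(rep(c(FALSE, TRUE, TRUE, TRUE), 4), 4, byrow = TRUE)))
    part <- partitionClones(mat)
    ev <- detectReplacement(part)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$clone_out, "A")
    expect_equal(ev$clone_in, "B")
    expect_equal(ev$interval, 1L)
})

test_that("a single persistent clone yields no replacement events", {
    mat <- presenceFixture(
        matrix(rep(c(TRUE, TRUE, TRUE, FALSE), 4), 4, byrow = TRUE))
    part <- partitionClones(mat)
    expect_equal(nrow(detectReplacement(part)), 0L)
})

test_that("gradual replacement is detected exactly once at the crossing", {
    # fractions 0.9/0.1 -> 0.5/0.5 -> 0.1/0.9; expected VAF = f/2 and
    # presence > 0.10 give profiles A: T,T,F and B: F,T,T (brute-force
    # over the fraction series); A's collapse happens at interval 2
    fA <- c(0.9, 0.5, 0.1); fB <- rev(fA)
    profA <- (fA / 2) > 0.10
    profB <- (fB / 2) > 0.10
    expect_equal(profA, c(TRUE, TRUE, FALSE))
    expect_equal(profB, c(FALSE, TRUE, TRUE))
    mat <- presenceFixture(rbind(
        matrix(rep(profA, 5), 5, byrow = TRUE),
        matrix(rep(profB, 5), 5, byrow = TRUE)))
    part <- partitionClones(mat)
    ev <- detectReplacement(part)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$interval, 2L)
    expect_equal(ev$clone_out, "A")
})

test_that("relabeling clones leaves events identical up to label swap", {
    mat <- presenceFixture(rbind(
        matrix(rep(c(TRUE, FALSE, FALSE, FALSE), 3), 3, byrow = TRUE),
        matrix(rep(c(FALSE, TRUE, TRUE, TRUE), 3), 3, byrow = TRUE)))
    # reversing the sample axis swaps which clone appears first
    rev_mat <- mat[, 4:1]
    colnames(rev_mat) <- colnames(mat)
    ev1 <- detectReplacement(partitionClones(mat))
    ev2 <- detectReplacement(partitionClones(rev_mat))
    expect_equal(nrow(ev1), nrow(ev2))
    expect_equal(ev1$clone_out, ev2$clone_out)  # both named A by onset
})

test_that("heat-map export orders variants by clone block", {
    sim <- simulateCohort(cohortConfig(seed = 23))
    vm <- harmonizeAcrossSamples(sim$variants)
    part <- partitionClones(vm)
    hm <- heatmapMatrix(vm, part)
    blocks <- attr(hm, "clone")
    lev <- c("A", "B", "shared", "unassigned")
    expect_false(is.unsorted(match(blocks, lev)))
    expect_equal(dim(hm), dim(vm))
})
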