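test_that("divergent series counts the excess of small p-values on the grid", {
    # p-values exactly at uniform quantiles: no excess anywhere
    expect_equal(divergentSeries(c(0.2, 0.4, 0.6, 0.8, 1.0)), rep(0L, 5))
    expect_equal(divergentSeries(c(0.01, 0.02, 0.5, 0.9)), c(1L, 1L, 0L, 0L))
    # ten duplicates at 0.001: all ten at or below 1/10, minus i = 1
    expect_equal(divergentSeries(rep(0.001, 10))[1], 9L)
    expect_error(divergentSeries(numeric(0)), "empty")
    expect_error(divergentSeries(c(0.5, 1.2)), "0, 1")
})

test_that("divergent count equals its series maximum with smallest-index ties", {
    dc <- divergentCount(rep(0.001, 10))
    expect_s4_class(dc, "DivergentCount")
    expect_identical(divCount(dc), 9L)
    expect_identical(argmaxIndex(dc), 1L)
    expect_identical(divCount(divergentCount(c(0.2, 0.4, 0.6, 0.8, 1.0))),
        0L)
    # accessors agree with the series
    expect_identical(divCount(dc), max(dSeries(dc)))
})

test_that("divergent count matches an independent O(n^2) recount oracle", {
    set.seed(42)
    for (i in 1:200) {
        n <- sample(5:300, 1)
        p <- if (runif(1) < 0.5) runif(n) else
            c(runif(ceiling(n * 0.8)), rbeta(floor(n * 0.2), 0.2, 1))
        expect_identical(max(divergentSeries(p)),
            as.integer(oracleDivergentCount(p)))
    }
})

test_that("grid statistic D/n is sandwiched by the one-sided sup statistic", {
    set.seed(7)
    for (i in 1:100) {
        n <- sample(10:400, 1)
        p <- c(runif(n), rbeta(sample(0:n, 1), 0.3, 1))
        n <- length(p)
        D <- max(divergentSeries(p))
        sup <- max(seq_len(n) / n - sort(p))
        expect_lte(D / n, sup + 1e-12)
        expect_lte(sup, D / n + 1 / n + 1e-12)
    }
})

test_that("injecting zero p-values never decreases the divergent count", {
    set.seed(11)
    for (i in 1:50) {
        p <- runif(sample(20:200, 1))
        D0 <- max(divergentSeries(p))
        k <- sample(1:20, 1)
        D1 <- max(divergentSeries(c(p, rep(0, k))))
        expect_gte(D1, D0)
    }
})

test_that("KS uniform test behaves at the uniform and degenerate limits", {
    n <- 99
    near <- ksUniformTest((1:n) / (n + 1))
    expect_lte(near$statistic, 0.02)
    expect_gt(near$pvalue, 0.99)
    deg <- ksUniformTest(rep(1e-06, 100))
    expect_gte(deg$statistic, 0.99)
    expect_lt(deg$pvalue, 1e-16)
    # strongly anti-conservative sample: the divergence is overwhelming
    set.seed(3)
    skew <- ksUniformTest(rbeta(1e4, 0.1, 1))
    expect_lt(skew$pvalue, 1e-16)
})

test_that("assumption diagnostics detect decreasing and skewed p-value mass", {
    set.seed(5)
    left <- checkAssumptions(rbeta(5000, 0.1, 1))
    expect_true(left$decreasing)
    expect_true(left$significant)
    right <- checkAssumptions(rbeta(5000, 10, 1))
    expect_false(right$decreasing)
    flat <- checkAssumptions((1:500) / 501)
    expect_true(flat$decreasing)   # flat passes within slack
    expect_false(flat$significant)
})

test_that("top-divergent selection returns exactly D genes, planted first", {
    n <- 1000
    uniform <- data.frame(gene_id = sprintf("g%04d", 1:n),
        pvalue = (1:n) / n)
    expect_warning(sel <- selectTopDivergent(uniform), "empty")
    expect_length(sel, 0)
    # 10 planted at 0.001 among 990 uniform: the selected list has length D
    # (planted excess ~10 plus the null sup-fluctuation ~ 0.6*sqrt(n)) and
    # nearly always contains every planted gene
    lens <- integer(0)
    allPlanted <- logical(0)
    for (r in 1:50) {
        set.seed(100 + r)
        p <- c(rep(0.001, 10), runif(990))
        tab <- data.frame(gene_id = sprintf("g%04d", 1:1000), pvalue = p)
        sel <- selectTopDivergent(tab)
        lens <- c(lens, length(sel))
        allPlanted <- c(allPlanted,
            all(sprintf("g%04d", 1:10) %in% sel))
        expect_identical(length(sel), as.integer(max(divergentSeries(p))))
    }
    expect_gte(mean(lens), 10)
    expect_lte(mean(lens), 40)
    expect_gte(sum(allPlanted), 45L)
})

test_that("consensus intersection and Venn counts match set algebra", {
    ci <- consensusIntersection(list(c("g1", "g2"), c("g1", "g3"), "g1"))
    expect_identical(ci$consensus, "g1")
    same <- consensusIntersection(list(c("a", "b"), c("a", "b")))
    expect_identical(same$consensus, c("a", "b"))
    set.seed(9)
    pool <- sprintf("g%04d", 1:1000)
    sets <- lapply(1:3, function(i) sample(pool, 100))
    ci <- consensusIntersection(setNames(sets, c("x", "y", "z")))
    expect_identical(ci$consensus,
        sort(intersect(intersect(sets[[1]], sets[[2]]), sets[[3]])))
    # independent exclusive-region recomputation
    oc <- ci$overlapCounts
    for (i in seq_len(nrow(oc))) {
        inSets <- sets[unlist(oc[i, c("x", "y", "z")])]
        outSets <- sets[!unlist(oc[i, c("x", "y", "z")])]
        region <- Reduce(intersect, inSets)
        for (s in outSets) region <- setdiff(region, s)
        expect_identical(oc$count[i], length(region))
    }
})
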