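test_that("residualized expression is orthogonal to covariates, mean 0, sd 1", {
    se <- makeStudy(seed = 31, nGenes = 40, nSamples = 41)
    Z <- residualizeExpression(se)
    rin <- colData(se)$rin
    age <- colData(se)$age
    for (g in seq_len(nrow(Z))) {
        expect_lt(abs(sum(Z[g, ] * (rin - mean(rin)))), 1e-08)
        expect_lt(abs(sum(Z[g, ] * (age - mean(age)))), 1e-08)
    }
    expect_lt(max(abs(rowMeans(Z))), 1e-10)
    expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-08)
})

test_that("a gene fully explained by covariates is dropped with a warning", {
    se <- makeStudy(seed = 32, nGenes = 10, nSamples = 30)
    le <- assay(se, "logexpr")
    le[1, ] <- 2 * colData(se)$rin
    assay(se, "logexpr") <- le
    expect_warning(Z <- residualizeExpression(se), "zero residual variance")
    expect_false(rownames(le)[1] %in% rownames(Z))
})

test_that("the scan enumerates all unordered pairs symmetrically", {
    se <- makeStudy(seed = 33, nGenes = 30, nSamples = 40)
    Z <- residualizeExpression(se)
    m <- nrow(Z)
    trait <- colData(se)$fcr
    pairs <- pairwiseInteractionScan(Z, trait)
    expect_identical(nrow(pairs), as.integer(m * (m - 1) / 2))
    counts <- table(c(pairs$gene_a, pairs$gene_b))
    expect_true(all(counts == m - 1))
    # reversing gene order gives the same table up to row order and roles
    pairsRev <- pairwiseInteractionScan(Z[rev(seq_len(m)), ], trait)
    key <- function(d) paste(pmin(d$gene_a, d$gene_b),
        pmax(d$gene_a, d$gene_b))
    expect_setequal(key(pairs), key(pairsRev))
    o1 <- order(key(pairs)); o2 <- order(key(pairsRev))
    expect_equal(pairs$beta3[o1], pairsRev$beta3[o2], tolerance = 1e-09)
    expect_equal(pairs$pvalue[o1], pairsRev$pvalue[o2], tolerance = 1e-09)
})

test_that("a planted interaction pair attains the smallest p-value", {
    cfg <- SimulationConfig(nGenes = 50, nSamples = 40, seed = 34,
        nInteractionPairs = 1, interactionBeta = 2, noiseSd = 0.1)
    se <- normalizeCounts(filterMinCount(simulateCounts(cfg)))
    Z <- residualizeExpression(se)
    pairs <- pairwiseInteractionScan(Z, colData(se)$fcr)
    truth <- metadata(se)$groundTruth
    planted <- sort(unlist(truth$interactionPairs[1, 1:2]))
    best <- pairs[which.min(pairs$pvalue), ]
    expect_identical(sort(c(best$gene_a, best$gene_b)), unname(planted))
})

test_that("a trait independent of expression gives uniform beta3 p-values", {
    se <- makeStudy(seed = 35, nGenes = 40, nSamples = 41)
    Z <- residualizeExpression(se)
    set.seed(99)
    trait <- rnorm(ncol(Z))
    pairs <- pairwiseInteractionScan(Z, trait)
    expect_gt(ksUniformTest(pairs$pvalue)$pvalue, 0.01)
})

test_that("perfectly collinear pairs are skipped and reported", {
    se <- makeStudy(seed = 36, nGenes = 10, nSamples = 30)
    Z <- residualizeExpression(se)
    Z[2, ] <- Z[1, ]
    expect_message(pairs <- pairwiseInteractionScan(Z, colData(se)$fcr),
        "collinear")
    expect_identical(nrow(attr(pairs, "skipped")), 1L)
    m <- nrow(Z)
    expect_identical(nrow(pairs), as.integer(m * (m - 1) / 2 - 1))
})

test_that("per-gene divergent counts agree with direct recomputation", {
    se <- makeStudy(seed = 37, nGenes = 25, nSamples = 40)
    Z <- residualizeExpression(se)
    pairs <- pairwiseInteractionScan(Z, colData(se)$fcr)
    pg <- perGeneDivergentCounts(pairs)
    expect_setequal(names(pg), rownames(Z))
    for (g in rownames(Z)[1:5]) {
        p <- pairs$pvalue[pairs$gene_a == g | pairs$gene_b == g]
        expect_length(p, nrow(Z) - 1)
        expect_identical(pg[[g]], max(divergentSeries(p)))
    }
})

test_that("per-gene counts stay modest under the global null", {
    se <- makeStudy(seed = 38, nGenes = 55, nSamples = 40)
    Z <- residualizeExpression(se)[1:50, ]
    set.seed(7)
    pairs <- pairwiseInteractionScan(Z, rnorm(ncol(Z)))
    pg <- perGeneDivergentCounts(pairs)
    expect_true(all(pg <= 15))
})

test_that("the bootstrap null is seeded, sized, and bounded for uniform pools", {
    pooled <- (1:5000) / 5000
    b1 <- bootstrapNullDivergent(pooled, mPerGene = 500, B = 1000, seed = 5)
    b2 <- bootstrapNullDivergent(pooled, mPerGene = 500, B = 1000, seed = 5)
    expect_identical(b1$counts, b2$counts)
    expect_length(b1$counts, 1000)
    expect_lte(b1$max, 0.1 * 500)
    single <- bootstrapNullDivergent(pooled, mPerGene = 100, B = 1)
    expect_length(single$counts, 1)
})

test_that("exceedance flagging is strict and sorted", {
    pg <- c(g3 = 5L, g1 = 10L, g2 = 10L, g4 = 2L)
    fl <- flagExceedingGenes(pg, 4)
    expect_identical(fl$gene, c("g1", "g2", "g3"))
    expect_identical(fl$divergent_count, c(10L, 10L, 5L))
    expect_identical(nrow(flagExceedingGenes(pg, 10)), 0L)
    one <- flagExceedingGenes(pg, 9)
    expect_identical(one$gene, c("g1", "g2"))
})
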