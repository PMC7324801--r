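test_that("correlation matrix matches a covariance-based recomputation", {
    set.seed(41)
    x <- matrix(rnorm(200), nrow = 20,
        dimnames = list(sprintf("g%02d", 1:20), NULL))
    cc <- correlationMatrix(x)
    # independent recomputation from covariance
    cv <- cov(t(x))
    ref <- cv / sqrt(outer(diag(cv), diag(cv)))
    expect_equal(cc, ref, tolerance = 1e-10, ignore_attr = TRUE)
    x2 <- rbind(x, dup = x[1, ], neg = -x[1, ])
    cc2 <- correlationMatrix(x2)
    expect_equal(cc2["g01", "dup"], 1, tolerance = 1e-12)
    expect_equal(cc2["g01", "neg"], -1, tolerance = 1e-12)
    x3 <- rbind(x, flat = rep(1, ncol(x)))
    expect_error(correlationMatrix(x3), "zero-variance")
})

test_that("TOM matches the closed form and a triple-loop oracle", {
    a2 <- matrix(c(1, 1, 1, 1), 2, 2)
    expect_equal(topologicalOverlap(a2)[1, 2], 1)
    id <- diag(5)
    expect_true(all(topologicalOverlap(id)[upper.tri(id)] == 0))
    set.seed(42)
    m <- 30
    a <- matrix(runif(m * m, 0, 0.9), m, m)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- topologicalOverlap(a)
    expect_equal(tom, oracleTOM(a), tolerance = 1e-12, ignore_attr = TRUE)
    expect_lt(max(abs(tom - t(tom))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    bad <- a; bad[1, 2] <- bad[1, 2] + 0.1
    expect_error(topologicalOverlap(bad), "symmetric")
})

test_that("the soft-threshold fit profiles every candidate power reproducibly", {
    se <- makeStudy(seed = 43, nGenes = 300, nSamples = 41,
        meanLogExpression = 8, baselineSd = 1,
        nModules = 5, moduleSize = 30, moduleCor = 0.7,
        method = "median-of-ratios")
    cc <- correlationMatrix(assay(se, "logexpr"))
    fit1 <- fitSoftThreshold(cc, powers = 1:10)
    fit2 <- fitSoftThreshold(cc, powers = 1:10)
    expect_identical(fit1$power, fit2$power)
    expect_identical(nrow(fit1$profile), 10L)
    expect_true(fit1$power %in% 1:10)
    # mean connectivity decreases with power
    expect_true(all(diff(fit1$profile$meanK) < 0))
    expect_error(fitSoftThreshold(matrix(1, 4, 4)), "identical")
})

test_that("module clustering recovers planted TOM blocks and survives edge cases", {
    blockTom <- function() {
        tom <- diag(40)
        tom[1:20, 1:20] <- 0.9
        tom[21:40, 21:40] <- 0.9
        diag(tom) <- 1
        dimnames(tom) <- list(sprintf("g%02d", 1:40), sprintf("g%02d", 1:40))
        tom
    }
    labs <- clusterModules(blockTom(), minModuleSize = 5, cutHeight = 0.5)
    expect_identical(length(unique(labs)), 2L)
    expect_identical(length(unique(labs[1:20])), 1L)
    expect_identical(length(unique(labs[21:40])), 1L)
    expect_false(any(labs == "grey"))
    flat <- matrix(0.5, 10, 10,
        dimnames = list(paste0("g", 1:10), paste0("g", 1:10)))
    diag(flat) <- 1
    expect_no_error(labsFlat <- clusterModules(flat, minModuleSize = 3))
    expect_lte(length(setdiff(unique(labsFlat), "grey")), 1)
    labsBig <- clusterModules(blockTom(), minModuleSize = 100)
    expect_true(all(labsBig == "grey"))
})

test_that("RIN correction removes the RIN signal exactly", {
    se <- makeStudy(seed = 44, nGenes = 30, nSamples = 40, rinEffectSd = 0.5)
    expr <- assay(se, "logexpr")
    rin <- colData(se)$rin
    corrected <- correctForRIN(expr, rin)
    for (g in 1:10)
        expect_lt(abs(cor(corrected[g, ], rin)), 1e-10)
    # RIN-independent gene comes back centered
    flatGene <- rnorm(40)
    flat <- correctForRIN(rbind(g1 = flatGene), rep(8, 40) + rnorm(40))
    exact <- correctForRIN(rbind(g1 = 5 + 2 * rin), rin)
    expect_lt(max(abs(exact)), 1e-10)
    expect_warning(idem <- correctForRIN(expr, rep(8, 40)), "constant")
    expect_equal(idem, expr - rowMeans(expr), ignore_attr = TRUE)
})

test_that("eigengenes summarize modules with unit norm and stable orientation", {
    set.seed(45)
    profile <- rnorm(30)
    X <- matrix(rep(profile, each = 6), nrow = 6, byrow = FALSE) +
        matrix(rnorm(180, sd = 1e-06), nrow = 6)
    rownames(X) <- paste0("g", 1:6)
    colnames(X) <- paste0("s", 1:30)
    labels <- setNames(rep("M1", 6), rownames(X))
    eg <- moduleEigengenes(X, labels)
    e <- eg$eigengenes[, "M1"]
    expect_equal(sum(e^2), 1, tolerance = 1e-09)
    z <- scale(profile)[, 1]
    expect_equal(abs(cor(e, z)), 1, tolerance = 1e-06)
    expect_gte(cor(e, z), 0)  # oriented along the mean profile
    expect_gte(eg$varExplained[["M1"]], 0.99)
})

test_that("RIN-corrected eigengenes are uncorrelated with RIN", {
    se <- makeStudy(seed = 46, nGenes = 300, nSamples = 41,
        meanLogExpression = 8, baselineSd = 1, rinEffectSd = 0.5,
        nModules = 3, moduleSize = 50, moduleCor = 0.7,
        method = "median-of-ratios")
    expr <- assay(se, "logexpr")
    rin <- colData(se)$rin
    nw <- buildCoexpressionNetwork(expr, power = 6)
    corrected <- correctForRIN(expr, rin)
    eg <- moduleEigengenes(corrected, moduleLabels(nw))
    rinCor <- abs(cor(eg$eigengenes, rin))
    expect_true(all(rinCor <= 0.05))
})

test_that("merging collapses near-identical modules and never adds modules", {
    set.seed(47)
    shared <- rnorm(40)
    X <- rbind(
        matrix(rep(shared, each = 10), nrow = 10) + rnorm(400, sd = 0.05),
        matrix(rnorm(400), nrow = 10))
    rownames(X) <- paste0("g", 1:20)
    colnames(X) <- paste0("s", 1:40)
    labels <- setNames(c(rep("A", 5), rep("B", 5), rep("C", 10)),
        rownames(X))
    merged <- mergeModules(X, labels)
    expect_identical(unique(merged$labels[1:10]),
        unique(merged$labels[1:10])[1])  # A and B collapsed to one label
    expect_lte(ncol(merged$eigengenes), 2)
    expect_lte(length(unique(merged$labels)), length(unique(labels)))
    # orthogonal eigengenes stay apart
    merged2 <- mergeModules(X, setNames(c(rep("A", 10), rep("C", 10)),
        rownames(X)))
    expect_identical(ncol(merged2$eigengenes), 2L)
})

test_that("module-trait correlations handle exact, planted, and null traits", {
    se <- makeStudy(seed = 48, nGenes = 300, nSamples = 41,
        meanLogExpression = 8, baselineSd = 1,
        nModules = 2, moduleSize = 50, moduleCor = 0.8,
        method = "median-of-ratios")
    expr <- assay(se, "logexpr")
    truth <- metadata(se)$groundTruth
    nw <- buildCoexpressionNetwork(expr, power = 6)
    eg <- moduleEigengenes(correctForRIN(expr, colData(se)$rin),
        moduleLabels(nw))
    E <- eg$eigengenes
    # the latent factor that generated module 1 is a strong correlate
    latent <- truth$moduleFactors["module1", ]
    mt <- moduleTraitCorrelations(E, data.frame(latent = latent))
    expect_gte(max(abs(mt$correlation)), 0.5)
    # a trait equal to an eigengene correlates exactly
    mtSelf <- moduleTraitCorrelations(E, data.frame(self = E[, 1]))
    expect_equal(max(mtSelf$correlation), 1, tolerance = 1e-09)
    # permuted trait: small correlation, valid p-values
    set.seed(1)
    mtNull <- moduleTraitCorrelations(E,
        data.frame(perm = sample(latent)))
    expect_true(all(mtNull$pvalue >= 0 & mtNull$pvalue <= 1))
    mtConst <- moduleTraitCorrelations(E, data.frame(const = rep(1, nrow(E))))
    expect_true(all(is.na(mtConst$correlation)))
})

test_that("intramodular connectivity identifies hubs and obeys the handshake identity", {
    m <- 10
    a <- matrix(0.1, m, m); diag(a) <- 1
    a[1, ] <- a[, 1] <- 0.9; a[1, 1] <- 1
    dimnames(a) <- list(paste0("g", 1:m), paste0("g", 1:m))
    labels <- setNames(rep("M1", m), rownames(a))
    kw <- intramodularConnectivity(a, labels)
    expect_identical(names(which.max(kw)), "g1")
    expect_identical(topHubGenes(kw, labels, "M1", 1), "g1")
    within <- sum(a[upper.tri(a)])
    expect_equal(sum(kw), 2 * within, tolerance = 1e-10)
    # singleton module has zero connectivity
    labels2 <- setNames(c("M1", rep("M2", m - 1)), rownames(a))
    kw2 <- intramodularConnectivity(a, labels2)
    expect_identical(unname(kw2["g1"]), 0)
})
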