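#' Simulation configuration
#'
#' Parameters of the synthetic feed-efficiency study generator. Defaults
#' emulate the structure of a two-breed pig muscle RNA-seq experiment: 41
#' animals (13 vs 28 per breed), negative-binomial counts with library-size
#' variation, per-gene covariate effects of RIN, slaughter age, batch and
#' breed on log expression, a continuous feed-conversion trait (gain/feed,
#' around 0.35-0.50) with planted per-gene associations, planted
#' expression-pair interaction effects on the trait, and correlated gene
#' modules driven by shared latent factors.
#'
#' @param nGenes,nSamples Matrix dimensions.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical output.
#' @param meanLogExpression Mean of the per-gene baseline on the log2 scale.
#' @param baselineSd Spread of per-gene baselines (log2).
#' @param dispersion Shared negative-binomial dispersion (1/size).
#' @param librarySizeRange Length-2 positive range of library-size factors.
#' @param rinEffectSd,ageEffectSd,batchEffectSd,breedEffectSd Per-gene
#'   covariate effect scales on log2 expression (0 disables the effect).
#' @param nTraitGenes Number of genes with a planted trait association.
#' @param traitEffectSize Per-unit-trait log2 fold change for planted genes.
#' @param nInteractionPairs Planted expression-pair interaction effects on
#'   the trait.
#' @param interactionBeta Interaction coefficient on standardized residual
#'   expression.
#' @param nModules,moduleSize Planted co-expression modules.
#' @param moduleCor Within-module correlation (latent-factor loading
#'   `sqrt(moduleCor)`), in `[0, 1]`.
#' @param noiseSd Trait noise standard deviation, on the trait scale.
#' @return A validated `SimulationConfig` object.
#' @export
SimulationConfig <- function(nGenes = 2000L, nSamples = 41L, seed = 1L,
    meanLogExpression = 6, baselineSd = 1.5, dispersion = 0.05,
    librarySizeRange = c(8e5, 1.2e6),
    rinEffectSd = 0.1, ageEffectSd = 0.005, batchEffectSd = 0.1,
    breedEffectSd = 0.2,
    nTraitGenes = 0L, traitEffectSize = 0,
    nInteractionPairs = 0L, interactionBeta = 0,
    nModules = 0L, moduleSize = 50L, moduleCor = 0.7,
    noiseSd = 1) {
    new("SimulationConfig",
        nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
        seed = as.integer(seed),
        meanLogExpression = meanLogExpression, baselineSd = baselineSd,
        dispersion = dispersion, librarySizeRange = as.numeric(librarySizeRange),
        rinEffectSd = rinEffectSd, ageEffectSd = ageEffectSd,
        batchEffectSd = batchEffectSd, breedEffectSd = breedEffectSd,
        nTraitGenes = as.integer(nTraitGenes),
        traitEffectSize = traitEffectSize,
        nInteractionPairs = as.integer(nInteractionPairs),
        interactionBeta = interactionBeta,
        nModules = as.integer(nModules), moduleSize = as.integer(moduleSize),
        moduleCor = moduleCor, noiseSd = noiseSd)
}

#' @rdname SimulationConfig
#' @export
setClass("SimulationConfig",
    representation(
        nGenes = "integer", nSamples = "integer", seed = "integer",
        meanLogExpression = "numeric", baselineSd = "numeric",
        dispersion = "numeric", librarySizeRange = "numeric",
        rinEffectSd = "numeric", ageEffectSd = "numeric",
        batchEffectSd = "numeric", breedEffectSd = "numeric",
        nTraitGenes = "integer", traitEffectSize = "numeric",
        nInteractionPairs = "integer", interactionBeta = "numeric",
        nModules = "integer", moduleSize = "integer", moduleCor = "numeric",
        noiseSd = "numeric"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nGenes < 1 || object@nSamples < 1)
        msg <- c(msg, "nGenes and nSamples must be positive")
    if (object@nTraitGenes < 0 || object@nTraitGenes > object@nGenes)
        msg <- c(msg, "nTraitGenes must lie in [0, nGenes]")
    if (object@nModules < 0 ||
        object@nModules * object@moduleSize > object@nGenes)
        msg <- c(msg, "nModules * moduleSize must not exceed nGenes")
    if (length(object@librarySizeRange) != 2 ||
        any(object@librarySizeRange <= 0) ||
        diff(object@librarySizeRange) < 0)
        msg <- c(msg, "librarySizeRange must be an increasing positive pair")
    if (object@dispersion <= 0) msg <- c(msg, "dispersion must be positive")
    if (object@moduleCor < 0 || object@moduleCor > 1)
        msg <- c(msg, "moduleCor must lie in [0, 1]")
    if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
    if (any(c(object@rinEffectSd, object@ageEffectSd, object@batchEffectSd,
        object@breedEffectSd) < 0))
        msg <- c(msg, "covariate effect scales must be nonnegative")
    if (object@nInteractionPairs < 0)
        msg <- c(msg, "nInteractionPairs must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' Read a simulation configuration from a YAML key-value file
#'
#' Keys match the arguments of [SimulationConfig()]; missing keys take the
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `SimulationConfig` object.
#' @export
readSimulationConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(SimulationConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown configuration keys: ", paste(bad, collapse = ", "))
    do.call(SimulationConfig, vals)
}

#' Simulate a synthetic feed-efficiency RNA-seq study
#'
#' Draws counts negative-binomially around
#' `2^(baseline + covariate effects + traitEffect * FCR + module factor)`
#' scaled by a per-sample library-size factor. The sample table carries the
#' feed-conversion ratio (gain/feed), RIN, slaughter age, breed (two levels),
#' batch, and the underlying feed records (weights, feed intake, test days)
#' consistent with the planted FCR. All planted structure is recorded as
#' ground truth.
#'
#' @param config A [SimulationConfig()] object.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"`, per-sample covariates in `colData`, per-gene truth flags in
#'   `rowData`, and a `groundTruth` list in `metadata` (trait gene ids,
#'   interaction pairs with coefficients, module assignments, per-gene effect
#'   sizes, the planted trait).
#' @export
simulateCounts <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)
    G <- config@nGenes
    N <- config@nSamples
    geneIds <- sprintf("g%04d", seq_len(G))
    sampleIds <- sprintf("s%02d", seq_len(N))

    # covariates: two breeds at roughly a 1:2 ratio, four slaughter batches
    nDuroc <- max(1L, round(N * 13 / 41))
    breed <- factor(c(rep("duroc", nDuroc), rep("landrace", N - nDuroc)),
        levels = c("duroc", "landrace"))
    batch <- factor(sample(paste0("b", 1:4), N, replace = TRUE))
    rin <- round(pmin(10, pmax(5, rnorm(N, mean = 8, sd = 0.8))), 1)
    age <- round(rnorm(N, mean = 170, sd = 10))
    fcr <- round(rnorm(N, mean = 0.42, sd = 0.04), 4)

    # feed records consistent with FCR = gain / feed
    testDays <- round(runif(N, 45, 65))
    feedIntake <- round(rnorm(N, mean = 165, sd = 12), 1)
    startWeight <- round(rnorm(N, mean = 30, sd = 1.5), 1)
    endWeight <- round(startWeight + fcr * feedIntake, 1)

    baseline <- rnorm(G, config@meanLogExpression, config@baselineSd)
    bRin <- rnorm(G, 0, config@rinEffectSd)
    bAge <- rnorm(G, 0, config@ageEffectSd)
    bBatch <- matrix(rnorm(G * nlevels(batch), 0, config@batchEffectSd),
        nrow = G)
    bBreed <- rnorm(G, 0, config@breedEffectSd)

    traitGenes <- character(0)
    bTrait <- numeric(G)
    if (config@nTraitGenes > 0) {
        idx <- sample.int(G, config@nTraitGenes)
        traitGenes <- geneIds[sort(idx)]
        bTrait[idx] <- config@traitEffectSize
    }

    moduleOf <- rep("none", G)
    moduleLoad <- matrix(0, nrow = G, ncol = max(1L, config@nModules))
    factors <- matrix(0, nrow = max(1L, config@nModules), ncol = N)
    if (config@nModules > 0) {
        factors <- matrix(rnorm(config@nModules * N), ncol = N)
        free <- setdiff(seq_len(G), which(bTrait != 0))
        if (length(free) < config@nModules * config@moduleSize)
            free <- seq_len(G)  # allow overlap with trait genes if cramped
        pick <- sample(free, config@nModules * config@moduleSize)
        for (m in seq_len(config@nModules)) {
            members <- pick[((m - 1) * config@moduleSize + 1):
                            (m * config@moduleSize)]
            moduleOf[members] <- paste0("module", m)
            moduleLoad[members, m] <- sqrt(config@moduleCor)
        }
    }

    # log2-scale mean model; module factor enters with residual sd shrunk so
    # that within-module correlation is moduleCor on the log scale
    ageC <- age - mean(age)
    rinC <- rin - mean(rin)
    logMu <- matrix(baseline, G, N) +
        outer(bRin, rinC) +
        outer(bAge, ageC) +
        bBatch[, as.integer(batch)] +
        outer(bBreed, as.numeric(breed == "landrace")) +
        outer(bTrait, fcr)
    if (config@nModules > 0) {
        # module latent signal sd on log2 scale; large relative to the
        # count-sampling noise so the realized expression correlation of
        # module members approaches moduleCor
        sigmaG <- 2
        inMod <- moduleOf != "none"
        logMu <- logMu + sigmaG * (moduleLoad %*% factors)
        logMu[inMod, ] <- logMu[inMod, ] +
            sigmaG * sqrt(1 - config@moduleCor) *
            matrix(rnorm(sum(inMod) * N), ncol = N)
    }

    libSize <- runif(N, config@librarySizeRange[1], config@librarySizeRange[2])
    sizeFactor <- libSize / mean(libSize)
    mu <- 2^logMu * rep(sizeFactor, each = G)
    counts <- matrix(
        rnbinom(G * N, mu = mu, size = 1 / config@dispersion),
        nrow = G, dimnames = list(geneIds, sampleIds))
    storage.mode(counts) <- "integer"

    colData <- S4Vectors::DataFrame(
        sample_id = sampleIds, fcr = fcr, rin = rin, age = age,
        breed = breed, batch = batch,
        start_weight = startWeight, end_weight = endWeight,
        feed_intake = feedIntake, test_days = testDays,
        lib_size = colSums(counts),
        row.names = sampleIds)
    rowData <- S4Vectors::DataFrame(
        gene_id = geneIds, trait_gene = geneIds %in% traitGenes,
        trait_effect = bTrait, module = moduleOf, row.names = geneIds)

    truth <- list(
        traitGeneIds = traitGenes,
        traitEffectSizes = setNames(bTrait, geneIds),
        interactionPairs = data.frame(gene_a = character(0),
            gene_b = character(0), beta = numeric(0)),
        moduleAssignments = setNames(moduleOf, geneIds),
        fcr = setNames(fcr, sampleIds),
        moduleFactors = if (config@nModules > 0)
            `rownames<-`(factors, paste0("module", seq_len(config@nModules)))
        else NULL,
        config = config)

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = colData, rowData = rowData,
        metadata = list(groundTruth = truth))

    if (config@nInteractionPairs > 0) {
        se <- plantInteractionTrait(se,
            nPairs = config@nInteractionPairs,
            beta = config@interactionBeta,
            noiseSd = config@noiseSd,
            seed = config@seed + 1L)
    }
    se
}

# Replace the trait with one generated from planted expression-pair
# interactions among randomly chosen genes (used by simulateCounts when
# nInteractionPairs > 0).
plantInteractionTrait <- function(se, nPairs, beta, noiseSd, seed) {
    g <- rownames(se)
    set.seed(seed)
    pick <- matrix(sample(g, 2 * nPairs), ncol = 2)
    pairs <- data.frame(gene_a = pick[, 1], gene_b = pick[, 2],
        beta = rep(beta, nPairs))
    expr <- normalizeCounts(se, method = "library-size")
    trait <- simulateTraitFromExpression(
        SummarizedExperiment::assay(expr, "logexpr"),
        pairs = pairs[, 1:2], betas = pairs$beta,
        noiseSd = noiseSd, seed = seed + 1L)
    SummarizedExperiment::colData(se)$fcr <- as.numeric(trait)
    truth <- S4Vectors::metadata(se)$groundTruth
    truth$interactionPairs <- pairs
    truth$fcr <- setNames(as.numeric(trait), colnames(se))
    S4Vectors::metadata(se)$groundTruth <- truth
    se
}

#' Simulate a p-value set with a planted alternative fraction
#'
#' Draws `round(pi0 * n)` values from Uniform(0,1) and the remainder from
#' `Beta(altShape, 1)`; `altShape < 1` skews the alternatives toward zero,
#' giving the approximately decreasing ("anti-conservative") p-value mass the
#' divergent count assumes.
#'
#' @param n Number of p-values (>= 1).
#' @param pi0 Null fraction in `[0, 1]`.
#' @param altShape Positive Beta shape for the alternatives.
#' @param seed Integer seed.
#' @return Numeric vector of `n` p-values; the first `round(pi0 * n)` are
#'   null draws (attribute `nNull` records the split).
#' @export
simulatePValues <- function(n, pi0, altShape = 0.1, seed = 1L) {
    stopifnot(n >= 1, altShape > 0)
    if (pi0 < 0 || pi0 > 1) stop("pi0 must lie in [0, 1]")
    set.seed(seed)
    n0 <- round(pi0 * n)
    p <- c(runif(n0), stats::rbeta(n - n0, altShape, 1))
    attr(p, "nNull") <- n0
    p
}

#' Simulate a trait from planted expression-pair interactions
#'
#' Builds `trait_i = sum_k beta_k * x1_ki * x2_ki + noise`, where `x1`, `x2`
#' are the named genes' expression rows standardized across samples — the
#' pairwise interaction model run in reverse.
#'
#' @param expr Genes x samples numeric matrix with rownames.
#' @param pairs Two-column data frame (or matrix) of gene identifier pairs.
#' @param betas Numeric vector, one coefficient per pair.
#' @param noiseSd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Named numeric trait vector over samples.
#' @export
simulateTraitFromExpression <- function(expr, pairs, betas, noiseSd = 1,
                                        seed = 1L) {
    stopifnot(is.matrix(expr), !is.null(rownames(expr)))
    pairs <- as.data.frame(pairs)
    if (nrow(pairs) != length(betas))
        stop("betas must match the number of pairs")
    unknown <- setdiff(unique(unlist(pairs)), rownames(expr))
    if (length(unknown))
        stop("unknown gene identifiers: ", paste(unknown, collapse = ", "))
    set.seed(seed)
    n <- ncol(expr)
    z <- t(scale(t(expr)))
    trait <- rep(0, n)
    for (k in seq_len(nrow(pairs)))
        trait <- trait +
            betas[k] * z[pairs[[1]][k], ] * z[pairs[[2]][k], ]
    trait <- trait + rnorm(n, 0, noiseSd)
    setNames(as.numeric(trait), colnames(expr))
}
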