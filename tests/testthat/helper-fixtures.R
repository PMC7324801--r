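suppressPackageStartupMessages(library(SummarizedExperiment))

# small simulated study, filtered and normalized
makeStudy <- function(seed = 1, nGenes = 100, nSamples = 41,
                      method = "library-size", ...) {
    cfg <- SimulationConfig(nGenes = nGenes, nSamples = nSamples,
        seed = seed, ...)
    normalizeCounts(filterMinCount(simulateCounts(cfg)), method = method)
}

# experiment with a caller-chosen logexpr matrix (counts kept consistent
# enough for the filters; used for exact-fit tests)
makeExprStudy <- function(logexpr, fcr, rin = NULL, age = NULL,
                          breed = NULL, batch = NULL) {
    n <- ncol(logexpr)
    if (is.null(rownames(logexpr)))
        rownames(logexpr) <- sprintf("g%03d", seq_len(nrow(logexpr)))
    colnames(logexpr) <- sprintf("s%02d", seq_len(n))
    if (is.null(rin)) rin <- 8 + (seq_len(n) %% 3) * 0.4
    if (is.null(age)) age <- 160 + seq_len(n) %% 7
    if (is.null(breed)) breed <- rep(c("duroc", "landrace"), length.out = n)
    if (is.null(batch)) batch <- rep(c("b1", "b1", "b2"), length.out = n)
    counts <- matrix(10L, nrow = nrow(logexpr), ncol = n,
        dimnames = dimnames(logexpr))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts, scaled = counts + 0,
            logexpr = logexpr),
        colData = S4Vectors::DataFrame(
            sample_id = colnames(logexpr), fcr = fcr, rin = rin, age = age,
            breed = breed, batch = batch, row.names = colnames(logexpr)))
    se
}

# independent O(n^2) recount of the divergent count
oracleDivergentCount <- function(p) {
    n <- length(p)
    s <- sort(p)
    max(vapply(seq_len(n), function(i) sum(s <= i / n) - i, numeric(1)))
}

# independent triple-loop topological overlap
oracleTOM <- function(a) {
    m <- nrow(a)
    k <- rowSums(a) - diag(a)
    tom <- diag(m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
        if (i == j) next
        L <- 0
        for (u in seq_len(m)) if (u != i && u != j) L <- L + a[i, u] * a[u, j]
        tom[i, j] <- (L + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    tom
}

# exhaustive hypergeometric enumeration of the two-sided Fisher p-value
oracleFisherP <- function(tab) {
    a <- tab[1, 1]
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
    lo <- max(0, c1 - (N - r1)); hi <- min(r1, c1)
    probs <- stats::dhyper(lo:hi, r1, N - r1, c1)
    pObs <- stats::dhyper(a, r1, N - r1, c1)
    sum(probs[probs <= pObs * (1 + 1e-07)])
}
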