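#' Residualize expression for nuisance covariates
#'
#' Per gene, takes OLS residuals of log2-normalized expression on RIN, age,
#' breed and batch (the same nuisance set as the trait regression, minus the
#' trait), then centers and scales each gene to mean 0, sd 1. Genes whose
#' residual variance is (numerically) zero are dropped with a warning.
#'
#' @param se A normalized `SummarizedExperiment` (see [normalizeCounts()]).
#' @return Genes x samples matrix of standardized residuals, with attributes
#'   `covariates` (the design columns removed) and `scaled = TRUE`.
#' @export
residualizeExpression <- function(se) {
    if (!"logexpr" %in% SummarizedExperiment::assayNames(se))
        stop("no 'logexpr' assay; run normalizeCounts() first")
    Y <- SummarizedExperiment::assay(se, "logexpr")
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    cd$breed <- factor(cd$breed)
    cd$batch <- factor(cd$batch)
    terms <- c("rin", "age",
        if (nlevels(cd$breed) > 1) "breed",
        if (nlevels(cd$batch) > 1) "batch")
    X <- model.matrix(stats::reformulate(terms), data = cd)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("collinear covariate design")
    R <- t(qr.resid(qrX, t(Y)))
    sds <- apply(R, 1, sd)
    degenerate <- sds < 1e-10
    if (any(degenerate)) {
        warning("dropping ", sum(degenerate),
            " gene(s) with zero residual variance: ",
            paste(head(rownames(R)[degenerate], 5), collapse = ", "))
        R <- R[!degenerate, , drop = FALSE]
    }
    Z <- t(scale(t(R)))
    attr(Z, "covariates") <- colnames(X)
    attr(Z, "scaled") <- TRUE
    Z
}

#' Pairwise gene-gene interaction scan on a continuous trait
#'
#' For every unordered gene pair fits
#' `trait = mu + b1*x1 + b2*x2 + b3*(x1*x2) + e` on the standardized residual
#' expression and records the interaction coefficient `b3` with its two-sided
#' t-test p-value. The scan is symmetric in pair order. Pairs whose
#' expression rows are perfectly collinear (`|cor| = 1`) are skipped and
#' reported.
#'
#' @param resid Standardized residual matrix from [residualizeExpression()]
#'   (genes x samples).
#' @param trait Numeric trait vector over the same samples (e.g. FCR).
#' @param maxGenes Guard against accidental full-transcriptome scans
#'   (`m(m-1)/2` model fits); raise explicitly to override.
#' @return Data frame with columns `gene_a`, `gene_b`, `beta1`, `beta2`,
#'   `beta3`, `pvalue` (for `beta3`); `m(m-1)/2` rows minus skipped pairs
#'   (skipped pairs are listed in attribute `skipped`).
#' @export
pairwiseInteractionScan <- function(resid, trait, maxGenes = 2000) {
    stopifnot(is.matrix(resid), !is.null(rownames(resid)))
    m <- nrow(resid); n <- ncol(resid)
    if (length(trait) != n) stop("trait length must match sample count")
    if (!all(is.finite(trait))) stop("trait must be finite")
    if (n < 5) stop("need at least 5 samples for the 4-parameter model")
    if (m > maxGenes)
        stop("scan over ", m, " genes exceeds maxGenes = ", maxGenes,
            "; raise maxGenes to override")
    idx <- t(combn(m, 2))
    nP <- nrow(idx)
    beta1 <- beta2 <- beta3 <- pval <- numeric(nP)
    ok <- rep(TRUE, nP)
    df <- n - 4
    ones <- rep(1, n)
    for (k in seq_len(nP)) {
        x1 <- resid[idx[k, 1], ]
        x2 <- resid[idx[k, 2], ]
        if (abs(cor(x1, x2)) > 1 - 1e-12) {
            ok[k] <- FALSE
            next
        }
        X <- cbind(ones, x1, x2, x1 * x2)
        XtX <- crossprod(X)
        XtXinv <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
        if (is.null(XtXinv)) { ok[k] <- FALSE; next }
        b <- XtXinv %*% crossprod(X, trait)
        r <- trait - X %*% b
        s2 <- sum(r^2) / df
        tstat <- b[4] / sqrt(s2 * XtXinv[4, 4])
        beta1[k] <- b[2]; beta2[k] <- b[3]; beta3[k] <- b[4]
        pval[k] <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
    }
    g <- rownames(resid)
    out <- data.frame(
        gene_a = g[idx[, 1]], gene_b = g[idx[, 2]],
        beta1 = beta1, beta2 = beta2, beta3 = beta3, pvalue = pval,
        stringsAsFactors = FALSE)[ok, , drop = FALSE]
    rownames(out) <- NULL
    skipped <- data.frame(gene_a = g[idx[!ok, 1]], gene_b = g[idx[!ok, 2]])
    if (nrow(skipped))
        message("skipped ", nrow(skipped), " collinear pair(s)")
    attr(out, "skipped") <- skipped
    out
}

#' Per-gene divergent counts over interaction p-values
#'
#' For each gene, collects the p-values of every pair containing it (`m - 1`
#' values in a full scan) and computes the divergent count, summarizing how
#' anti-conservative that gene's interaction p-value distribution is.
#'
#' @param pairs Pair table from [pairwiseInteractionScan()].
#' @return Named integer vector, gene -> divergent count.
#' @export
perGeneDivergentCounts <- function(pairs) {
    stopifnot(all(c("gene_a", "gene_b", "pvalue") %in% names(pairs)))
    byGene <- split(c(pairs$pvalue, pairs$pvalue),
        c(pairs$gene_a, pairs$gene_b))
    vapply(byGene, function(p) max(divergentSeries(p)), integer(1))
}

#' Bootstrap null distribution of the divergent count
#'
#' Draws `B` samples of size `mPerGene` with replacement from the pooled
#' empirical pair p-values, computing the divergent count of each — the null
#' reference against which the per-gene counts are judged. In a full scan of
#' `m` genes each gene contributes `m - 1` pair p-values, so `mPerGene`
#' defaults to that; any size can be supplied.
#'
#' @param pooled Numeric vector of pooled p-values (all pairs).
#' @param mPerGene Bootstrap sample size.
#' @param B Number of bootstrap draws (the reference analysis used 1e5).
#' @param seed Integer seed; identical seed gives an identical distribution.
#' @return List: `counts` (integer vector of length `B`), `max`, `quantiles`
#'   (95/99/99.9%), `B`, `mPerGene`.
#' @export
bootstrapNullDivergent <- function(pooled, mPerGene, B = 100000L, seed = 1L) {
    checkPValues(pooled)
    stopifnot(B >= 1, mPerGene >= 1)
    set.seed(seed)
    counts <- vapply(seq_len(B), function(b) {
        p <- pooled[sample.int(length(pooled), mPerGene, replace = TRUE)]
        max(divergentSeries(p))
    }, integer(1))
    list(counts = counts, max = max(counts),
        quantiles = quantile(counts, c(0.95, 0.99, 0.999)),
        B = as.integer(B), mPerGene = as.integer(mPerGene))
}

#' Flag genes whose divergent count exceeds the bootstrap maximum
#'
#' Returns the genes with a divergent count *strictly* greater than the
#' bootstrap null maximum, sorted by count descending, then identifier.
#'
#' @param perGene Named integer vector from [perGeneDivergentCounts()].
#' @param nullMax Bootstrap maximum divergent count.
#' @return Data frame `gene`, `divergent_count` of the flagged genes (zero
#'   rows if none exceed).
#' @export
flagExceedingGenes <- function(perGene, nullMax) {
    keep <- perGene > nullMax
    g <- names(perGene)[keep]
    d <- perGene[keep]
    ord <- order(-d, g)
    data.frame(gene = g[ord], divergent_count = as.integer(d[ord]),
        row.names = NULL, stringsAsFactors = FALSE)
}
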