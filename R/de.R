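#' Filter genes by a minimum count in every sample
#'
#' Retains exactly the genes whose count is at least `minCount` in *every*
#' sample (the a-priori filter applied before normalization); the sample set
#' is unchanged.
#'
#' @param se A `SummarizedExperiment` with an integer `"counts"` assay.
#' @param minCount Minimum per-sample count (default 5).
#' @return The filtered `SummarizedExperiment` (a warning, not an error, if
#'   no gene survives).
#' @export
filterMinCount <- function(se, minCount = 5) {
    counts <- SummarizedExperiment::assay(se, "counts")
    keep <- rowSums(counts >= minCount) == ncol(counts)
    if (!any(keep))
        warning("no genes pass the minimum-count filter")
    se[keep, ]
}

#' Normalize counts to the log2 scale
#'
#' Scales counts for sequencing depth and returns `log2(scaled + 0.5)`.
#' `"library-size"` scales each sample to counts-per-million;
#' `"median-of-ratios"` divides each sample by the median, over genes with a
#' positive geometric mean, of the ratio of its counts to the gene-wise
#' geometric-mean reference.
#'
#' @inheritParams filterMinCount
#' @param method Normalization method.
#' @return The `SummarizedExperiment` with added assays `"scaled"` (scaled
#'   counts) and `"logexpr"` (`log2(scaled + 0.5)`); the size factors are in
#'   `colData()$size_factor`.
#' @export
normalizeCounts <- function(se, method = c("library-size",
                                           "median-of-ratios")) {
    method <- match.arg(method)
    counts <- SummarizedExperiment::assay(se, "counts")
    tot <- colSums(counts)
    if (any(tot == 0)) stop("sample with zero total count: ",
        paste(colnames(counts)[tot == 0], collapse = ", "))
    if (method == "library-size") {
        scaled <- t(t(counts) / tot) * 1e6
        sf <- tot / 1e6
    } else {
        sf <- medianOfRatiosSizeFactors(counts)
        scaled <- t(t(counts) / sf)
    }
    SummarizedExperiment::assay(se, "scaled") <- scaled
    SummarizedExperiment::assay(se, "logexpr") <- log2(scaled + 0.5)
    SummarizedExperiment::colData(se)$size_factor <- sf
    se
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (those with a
#' positive geometric mean across samples) of `count / geometricMean(gene)`,
#' with the median taken on the log scale (so an even number of genes
#' interpolates geometrically, the standard convention).
#'
#' @param counts Genes x samples count matrix.
#' @return Named numeric vector of size factors.
#' @export
medianOfRatiosSizeFactors <- function(counts) {
    logGeo <- rowMeans(log(counts))
    use <- is.finite(logGeo)
    if (!any(use))
        stop("no gene has a positive count in every sample")
    apply(counts[use, , drop = FALSE], 2, function(cnt)
        exp(median(log(cnt) - logGeo[use])))
}

#' Per-gene covariate-adjusted trait regression
#'
#' Fits, gene by gene, the linear model
#' `logexpr = mu + b1*FCR + b2*RIN + b3*age + breed + batch + e`
#' on log2-normalized expression and tests the trait (FCR) coefficient with a
#' two-sided t-test. Three variants share the design:
#' \describe{
#'   \item{`ols`}{ordinary least squares.}
#'   \item{`weighted`}{weighted least squares with per-observation precision
#'     weights proportional to `scaled count + 0.5` (the delta-method inverse
#'     variance of a log-transformed count), downweighting low-expression
#'     observations.}
#'   \item{`moderated`}{OLS coefficients with per-gene residual variances
#'     shrunk toward their across-gene mean,
#'     `s2* = (d0*mean(s2) + df*s2)/(d0 + df)`, and the t-test on `df + d0`
#'     degrees of freedom (empirical-Bayes style).}
#' }
#' Factor covariates that are constant in the supplied samples (e.g. breed in
#' a single-breed subset) are dropped with a message, so per-breed analyses
#' use the same operation.
#'
#' @param se A normalized `SummarizedExperiment` (see [normalizeCounts()])
#'   whose `colData` contains `fcr`, `rin`, `age`, `breed`, `batch`.
#' @param variant Model variant.
#' @param priorDf Prior degrees of freedom `d0` for the moderated variant.
#' @return Data frame with one row per gene: `gene_id`, `beta_fcr`, `se`,
#'   `stat`, `pvalue`, `fdr` (Benjamini-Hochberg) and `method`.
#' @export
fitDE <- function(se, variant = c("ols", "weighted", "moderated"),
                  priorDf = 4) {
    variant <- match.arg(variant)
    if (!"logexpr" %in% SummarizedExperiment::assayNames(se))
        stop("no 'logexpr' assay; run normalizeCounts() first")
    Y <- SummarizedExperiment::assay(se, "logexpr")
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    need <- c("fcr", "rin", "age", "breed", "batch")
    miss <- setdiff(need, names(cd))
    if (length(miss))
        stop("colData missing covariates: ", paste(miss, collapse = ", "))
    cd$breed <- factor(cd$breed)
    cd$batch <- factor(cd$batch)
    terms <- c("fcr", "rin", "age",
        if (nlevels(cd$breed) > 1) "breed"
        else { message("breed is constant; dropping it from the model"); NULL },
        if (nlevels(cd$batch) > 1) "batch"
        else { message("batch is constant; dropping it from the model"); NULL })
    X <- model.matrix(
        stats::reformulate(terms), data = cd)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("collinear design; aliased columns: ",
            paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]],
                collapse = ", "))
    n <- nrow(X); p <- ncol(X); df <- n - p
    if (df < 1) stop("not enough samples for the design")
    jFcr <- match("fcr", colnames(X))

    if (variant == "weighted") {
        W <- SummarizedExperiment::assay(se, "scaled") + 0.5
        out <- t(vapply(seq_len(nrow(Y)), function(g) {
            sw <- sqrt(W[g, ])
            Xw <- X * sw
            XtWXinv <- chol2inv(chol(crossprod(Xw)))
            b <- XtWXinv %*% crossprod(Xw, Y[g, ] * sw)
            r <- Y[g, ] * sw - Xw %*% b
            s2 <- sum(r^2) / df
            c(b[jFcr], sqrt(s2 * XtWXinv[jFcr, jFcr]))
        }, numeric(2)))
        beta <- out[, 1]; seBeta <- out[, 2]
        tdf <- df
    } else {
        B <- qr.coef(qrX, t(Y))
        R <- qr.resid(qrX, t(Y))
        s2 <- colSums(R^2) / df
        cjj <- chol2inv(chol(crossprod(X)))[jFcr, jFcr]
        beta <- B[jFcr, ]
        if (variant == "moderated") {
            s2 <- (priorDf * mean(s2) + df * s2) / (priorDf + df)
            tdf <- df + priorDf
        } else {
            tdf <- df
        }
        seBeta <- sqrt(s2 * cjj)
    }
    stat <- beta / seBeta
    pvalue <- 2 * pt(abs(stat), df = tdf, lower.tail = FALSE)
    res <- data.frame(
        gene_id = rownames(Y), beta_fcr = unname(beta),
        se = unname(seBeta), stat = unname(stat), pvalue = unname(pvalue),
        fdr = adjustFDR(unname(pvalue)), method = variant,
        row.names = NULL, stringsAsFactors = FALSE)
    res
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @return Vector of BH q-values (`q >= p`, `max(q) <= 1`), in input order.
#' @export
adjustFDR <- function(pvalues) {
    checkPValues(pvalues)
    p.adjust(pvalues, method = "BH")
}

#' Write / read a differential-expression result table as TSV
#'
#' @param results Result table from [fitDE()].
#' @param path File path.
#' @return `writeDEResults` returns `path` invisibly; `readDEResults` the
#'   table.
#' @export
writeDEResults <- function(results, path) {
    write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeDEResults
#' @export
readDEResults <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}
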