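#' Divergence series of a p-value set against the uniform reference
#'
#' For p-values sorted in increasing order, computes
#' \eqn{d_i = \#\{p : p \le i/n\} - i} for \eqn{i = 1, \ldots, n}: the number
#' of observed p-values at or below the grid threshold \eqn{i/n} minus the
#' number a Uniform(0,1) sample of the same size is expected to place there.
#' Positive values indicate an excess of small p-values (an anti-conservative
#' distribution).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`. Duplicates are
#'   allowed; counting uses `<=` with no jitter.
#' @return Integer vector `d` of length `length(pvalues)`.
#' @examples
#' divergentSeries(c(0.01, 0.02, 0.5, 0.9)) # 1 1 0 0
#' @export
divergentSeries <- function(pvalues) {
    checkPValues(pvalues)
    n <- length(pvalues)
    p <- sort(pvalues)
    # findInterval counts entries <= each threshold for sorted p
    d <- findInterval((1:n) / n, p) - (1:n)
    as.integer(d)
}

#' The divergent count of a p-value set
#'
#' The divergent count \eqn{D = \max_i d_i} estimates the excess number of
#' small p-values relative to a Uniform(0,1) reference, evaluated on the grid
#' \eqn{t = i/n} (see [divergentSeries()]). The probability of the observed
#' divergence is the Kolmogorov-Smirnov test of the sample against
#' Uniform(0,1); the grid statistic `D/n` and the sup-norm KS statistic differ
#' by at most `1/n`. The count is meaningful as a gene-set size when the
#' p-value distribution is approximately decreasing toward low p-values and
#' the divergence is significant ([checkAssumptions()]).
#'
#' @inheritParams divergentSeries
#' @param alternative Sidedness of the KS test; `"two.sided"` (default) or
#'   `"greater"` (excess of small p-values only).
#' @return A [DivergentCount-class] object. Argmax ties are broken by the
#'   smallest index.
#' @examples
#' divCount(divergentCount(rep(0.001, 10))) # 9
#' @export
divergentCount <- function(pvalues, alternative = c("two.sided", "greater")) {
    alternative <- match.arg(alternative)
    d <- divergentSeries(pvalues)
    D <- max(d)
    ks <- ksUniformTest(pvalues, alternative = alternative)
    new("DivergentCount",
        n = length(pvalues),
        dSeries = d,
        D = as.integer(D),
        argmaxIndex = as.integer(which.max(d)),
        ksStatistic = unname(ks$statistic),
        ksPvalue = ks$pvalue)
}

#' Kolmogorov-Smirnov test against the Uniform(0,1) distribution
#'
#' Tests whether the p-value sample could have been generated by a Uniform(0,1)
#' distribution (the global null of no trait-expression relation).
#'
#' @inheritParams divergentCount
#' @return List with elements `statistic` (sup-norm divergence) and `pvalue`.
#' @export
ksUniformTest <- function(pvalues, alternative = c("two.sided", "greater")) {
    alternative <- match.arg(alternative)
    checkPValues(pvalues)
    # ties among p-values are expected and harmless here; silence the
    # continuous-distribution warning
    kt <- suppressWarnings(
        ks.test(pvalues, "punif", alternative = alternative))
    list(statistic = unname(kt$statistic), pvalue = kt$p.value)
}

#' Diagnostic check of the divergent-count assumptions
#'
#' The divergent count is interpretable as an excess-discovery estimate under
#' two conditions: (1) the p-value mass is approximately decreasing toward low
#' p-values, and (2) the divergence from uniformity is significant. This
#' reports both; it never errors.
#'
#' @inheritParams divergentSeries
#' @param nBins Number of equal-width histogram bins (>= 2).
#' @param slack Tolerated fractional increase between consecutive bins
#'   before the distribution is declared non-decreasing; judged against the
#'   expected uniform bin count so flat (uniform) histograms pass.
#' @param alpha Significance level for the KS check.
#' @return List: `decreasing` (logical), `binCounts`, `ksStatistic`,
#'   `ksPvalue`, `significant` (logical), `ok` (both conditions hold).
#' @export
checkAssumptions <- function(pvalues, nBins = 20, slack = 0.1, alpha = 0.05) {
    stopifnot(nBins >= 2)
    checkPValues(pvalues)
    breaks <- seq(0, 1, length.out = nBins + 1)
    counts <- tabulate(findInterval(pvalues, breaks, rightmost.closed = TRUE,
        all.inside = TRUE), nbins = nBins)
    tol <- slack * length(pvalues) / nBins
    decreasing <- all(diff(counts) <= tol)
    ks <- ksUniformTest(pvalues)
    significant <- ks$pvalue < alpha
    list(decreasing = decreasing, binCounts = counts,
        ksStatistic = ks$statistic, ksPvalue = ks$pvalue,
        significant = significant, ok = decreasing && significant)
}

#' Select the top genes by p-value, sized by the divergent count
#'
#' Computes the divergent count `D` of the table's p-values and returns the
#' `D` genes with the smallest p-values. P-value ties at the boundary are
#' broken by gene identifier order (stable and documented).
#'
#' @param results A differential-expression result table as returned by
#'   [fitDE()]: columns `gene_id` and `pvalue` are required.
#' @param alternative Passed to [divergentCount()].
#' @return Character vector of gene identifiers (empty, with a warning, when
#'   `D` is 0).
#' @export
selectTopDivergent <- function(results,
                               alternative = c("two.sided", "greater")) {
    stopifnot(is.data.frame(results),
        all(c("gene_id", "pvalue") %in% names(results)),
        nrow(results) >= 1)
    dc <- divergentCount(results$pvalue, alternative = match.arg(alternative))
    D <- divCount(dc)
    if (D <= 0) {
        warning("divergent count is 0; returning an empty gene list")
        return(character(0))
    }
    ord <- order(results$pvalue, results$gene_id)
    results$gene_id[ord][seq_len(D)]
}

#' Consensus intersection of gene lists
#'
#' Intersects the per-method top gene lists (genes found by all methods) and
#' tabulates the full inclusion-exclusion (Venn-style) overlap: for every
#' non-empty combination of input sets, the number of genes in exactly those
#' sets.
#'
#' @param sets Named (or unnamed) list of character vectors of gene
#'   identifiers; at least one set.
#' @return List with `consensus` (sorted character vector present in every
#'   set) and `overlapCounts` (data frame: one row per exclusive Venn region,
#'   with a logical column per set and a `count`).
#' @export
consensusIntersection <- function(sets) {
    stopifnot(is.list(sets), length(sets) >= 1)
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        names(sets) <- paste0("set", seq_along(sets))
    consensus <- sort(Reduce(intersect, sets))
    universe <- unique(unlist(sets))
    member <- vapply(sets, function(s) universe %in% s,
        logical(length(universe)))
    member <- matrix(member, nrow = length(universe),
        dimnames = list(NULL, names(sets)))
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
    names(combos) <- names(sets)
    combos <- combos[rowSums(combos) > 0, , drop = FALSE]
    combos$count <- apply(combos[, names(sets), drop = FALSE], 1, function(m)
        sum(apply(member, 1, function(row) all(row == m))))
    rownames(combos) <- NULL
    list(consensus = consensus, overlapCounts = combos)
}

checkPValues <- function(pvalues) {
    if (length(pvalues) == 0)
        stop("empty p-value set")
    if (!is.numeric(pvalues) || anyNA(pvalues))
        stop("p-values must be numeric and non-missing")
    if (any(pvalues < 0 | pvalues > 1))
        stop("p-values must lie in [0, 1]")
    invisible(TRUE)
}
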