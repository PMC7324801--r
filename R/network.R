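#' Gene-gene Pearson correlation matrix
#'
#' All pairwise Pearson correlations on the (uncorrected) expression values;
#' within-sample comparisons do not need nuisance correction, which is
#' instead applied to the eigengenes via [correctForRIN()].
#'
#' @param expr Genes x samples numeric matrix (>= 3 samples).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(expr) {
    stopifnot(is.matrix(expr), ncol(expr) >= 3)
    v <- apply(expr, 1, sd)
    if (any(v == 0))
        stop("zero-variance gene(s): ",
            paste(head(rownames(expr)[v == 0], 10), collapse = ", "))
    cc <- cor(t(expr))
    (cc + t(cc)) / 2
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted adjacency \eqn{a_{ij} = |r_{ij}|^\beta}.
#'
#' @param corMat Correlation matrix.
#' @param power Positive soft-threshold exponent.
#' @return Adjacency matrix (entries in `[0, 1]`, unit diagonal).
#' @export
adjacencyMatrix <- function(corMat, power) {
    stopifnot(power > 0)
    abs(corMat)^power
}

#' Fit the soft-threshold power for approximate scale-free topology
#'
#' For each candidate power computes the adjacency, the connectivities
#' `k_i = sum_{j != i} a_ij`, bins `k`, and regresses `log10(frequency)` on
#' `log10(mean k)` per bin; the fit R-squared measures how close the degree
#' distribution is to a power law. The chosen power is the smallest one with
#' R-squared at or above `rsqCut`, or the power maximizing R-squared if none
#' qualifies.
#'
#' @param corMat Correlation matrix.
#' @param powers Candidate integer powers.
#' @param nBins Connectivity histogram bins.
#' @param rsqCut Scale-free fit acceptance threshold (default 0.8).
#' @return List: `power` (chosen), `profile` (data frame with one row per
#'   candidate: `power`, `rsq`, `slope`, `meanK`).
#' @export
fitSoftThreshold <- function(corMat, powers = 1:10, nBins = 10,
                             rsqCut = 0.8) {
    stopifnot(length(powers) >= 1)
    offDiag <- corMat[upper.tri(corMat)]
    if (sd(offDiag) == 0 && length(offDiag) > 1)
        stop("all correlations identical; scale-free fit undefined")
    profile <- do.call(rbind, lapply(powers, function(pw) {
        a <- adjacencyMatrix(corMat, pw)
        k <- rowSums(a) - diag(a)
        brk <- seq(min(k), max(k), length.out = nBins + 1)
        bin <- findInterval(k, brk, rightmost.closed = TRUE,
            all.inside = TRUE)
        freq <- tabulate(bin, nbins = nBins)
        meanK <- vapply(seq_len(nBins), function(b)
            mean(k[bin == b]), numeric(1))
        use <- freq > 0 & meanK > 0
        if (sum(use) < 3)
            return(data.frame(power = pw, rsq = NA_real_,
                slope = NA_real_, meanK = mean(k)))
        fit <- lm(log10(freq[use]) ~ log10(meanK[use]))
        data.frame(power = pw, rsq = summary(fit)$r.squared,
            slope = unname(coef(fit)[2]), meanK = mean(k))
    }))
    rsq <- ifelse(is.na(profile$rsq), -Inf, profile$rsq)
    hit <- which(rsq >= rsqCut)
    power <- if (length(hit)) profile$power[hit[1]]
             else profile$power[which.max(rsq)]
    list(power = power, profile = profile)
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{L_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' for \eqn{i \ne j}, where \eqn{L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} is
#' the shared-neighbor weight and \eqn{k_i = \sum_{j \ne i} a_{ij}};
#' `TOM_ii = 1`. The TOM augments direct adjacency with the weight of shared
#' neighborhoods, the final gene-gene relation used for clustering.
#'
#' @param adj Symmetric adjacency with entries in `[0, 1]` and unit diagonal.
#' @return Symmetric TOM with unit diagonal.
#' @export
topologicalOverlap <- function(adj) {
    if (!is.matrix(adj) || max(abs(adj - t(adj))) > 1e-10)
        stop("adjacency must be a symmetric matrix")
    if (min(adj) < -1e-12 || max(adj) > 1 + 1e-12)
        stop("adjacency entries must lie in [0, 1]")
    if (max(abs(diag(adj) - 1)) > 1e-12)
        stop("adjacency must have unit diagonal")
    k <- rowSums(adj) - 1
    # L_ij = sum_{u != i,j} a_iu a_uj = (A^2)_ij - a_ii a_ij - a_ij a_jj
    L <- adj %*% adj - 2 * adj
    kmin <- outer(k, k, pmin)
    tom <- (L + adj) / (kmin + 1 - adj)
    diag(tom) <- 1
    (tom + t(tom)) / 2
}

#' Cluster genes into modules from the TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`
#' with a static cut at `cutHeight`; clusters smaller than `minModuleSize`
#' are labeled `"grey"` (unassigned). Remaining modules are labeled `"M1"`,
#' `"M2"`, ... by decreasing size (ties by first gene), so labels are
#' deterministic.
#'
#' @param tom TOM matrix with gene dimnames.
#' @param minModuleSize Smallest cluster kept as a module.
#' @param cutHeight Static tree-cut height on `1 - TOM`.
#' @return Named character vector gene -> module label.
#' @export
clusterModules <- function(tom, minModuleSize = 20, cutHeight = 0.97) {
    stopifnot(is.matrix(tom), !is.null(rownames(tom)))
    h <- hclust(as.dist(1 - tom), method = "average")
    # ties in the dissimilarity can leave microscopic height inversions
    h$height <- round(h$height, 10)
    cl <- cutree(h, h = cutHeight)
    sizes <- table(cl)
    keep <- names(sizes)[sizes >= minModuleSize]
    labels <- rep("grey", nrow(tom))
    names(labels) <- rownames(tom)
    if (length(keep)) {
        ord <- order(-sizes[keep],
            vapply(keep, function(k) min(which(cl == as.integer(k))),
                numeric(1)))
        for (i in seq_along(ord)) {
            labels[cl == as.integer(keep[ord[i]])] <- paste0("M", i)
        }
    }
    labels
}

#' Remove the RIN effect from expression
#'
#' Per gene, OLS residuals of (log-normalized) expression on RIN:
#' `expression = mu + RIN + e`, keeping the residual. Used before eigengene
#' computation so that RNA-quality variation does not drive the module
#' summaries. A constant RIN makes the correction an identity (centering
#' only), reported with a warning.
#'
#' @param expr Genes x samples matrix.
#' @param rin Numeric RIN vector over samples.
#' @return Matrix of residuals (each row has mean 0).
#' @export
correctForRIN <- function(expr, rin) {
    stopifnot(is.matrix(expr), length(rin) == ncol(expr))
    if (sd(rin) == 0) {
        warning("RIN is constant; returning centered expression")
        return(expr - rowMeans(expr))
    }
    X <- cbind(1, rin)
    qrX <- qr(X)
    t(qr.resid(qrX, t(expr)))
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized gene-by-sample submatrix, with samples as observations,
#' normalized to unit norm and oriented so its correlation with the module's
#' mean expression profile is nonnegative. A single-gene module returns that
#' gene's standardized profile (unit norm).
#'
#' @param expr Genes x samples matrix (typically RIN-corrected,
#'   [correctForRIN()]).
#' @param labels Named module labels from [clusterModules()]; `"grey"` genes
#'   are skipped.
#' @return List: `eigengenes` (samples x modules matrix), `varExplained`
#'   (fraction of module variance carried by the first component).
#' @export
moduleEigengenes <- function(expr, labels) {
    stopifnot(is.matrix(expr), !is.null(rownames(expr)))
    labels <- labels[rownames(expr)]
    mods <- sort(setdiff(unique(labels), "grey"))
    if (!length(mods)) stop("no assigned modules")
    n <- ncol(expr)
    E <- matrix(NA_real_, nrow = n, ncol = length(mods),
        dimnames = list(colnames(expr), mods))
    varExplained <- setNames(numeric(length(mods)), mods)
    for (m in mods) {
        X <- expr[labels == m, , drop = FALSE]
        Z <- t(scale(t(X)))  # genes standardized across samples
        if (nrow(Z) == 1) {
            e <- as.numeric(Z[1, ])
            e <- e / sqrt(sum(e^2))
            varExplained[m] <- 1
        } else {
            sv <- svd(t(Z), nu = 1, nv = 0)
            e <- sv$u[, 1]
            varExplained[m] <- sv$d[1]^2 / sum(sv$d^2)
        }
        meanProfile <- colMeans(Z)
        if (cor(e, meanProfile) < 0) e <- -e
        E[, m] <- e
    }
    list(eigengenes = E, varExplained = varExplained)
}

#' Merge modules with similar eigengenes
#'
#' Modules whose eigengene dissimilarity `1 - cor` falls below `mergeCut`
#' (single linkage over the eigengene dendrogram) are merged into one label
#' (that of the largest constituent); eigengenes are recomputed afterwards.
#'
#' @inheritParams moduleEigengenes
#' @param mergeCut Dissimilarity cut below which modules merge
#'   (default 0.25, i.e. eigengene correlation above 0.75).
#' @return List: `labels` (updated), `eigengenes`, `varExplained`.
#' @export
mergeModules <- function(expr, labels, mergeCut = 0.25) {
    eg <- moduleEigengenes(expr, labels)
    E <- eg$eigengenes
    if (ncol(E) > 1) {
        d <- as.dist(1 - cor(E))
        h <- hclust(d, method = "single")
        grp <- cutree(h, h = mergeCut)
        if (max(grp) < ncol(E)) {
            sizes <- table(labels)
            for (g in unique(grp)) {
                members <- colnames(E)[grp == g]
                if (length(members) > 1) {
                    target <- members[which.max(sizes[members])]
                    labels[labels %in% members] <- target
                }
            }
            eg <- moduleEigengenes(expr, labels)
        }
    }
    c(list(labels = labels), eg)
}

#' Module-trait correlations
#'
#' Pearson correlation (with two-sided p-value) between each module eigengene
#' and each trait or covariate. Two-level factors are coded 0/1; constant
#' traits give `NA` correlations.
#'
#' @param eigengenes Samples x modules matrix.
#' @param traits Data frame of per-sample traits/covariates (numeric or
#'   two-level factors), rows aligned with the eigengene samples.
#' @param adjust Optionally BH-adjust the p-values across the table.
#' @return Data frame: `module`, `trait`, `correlation`, `pvalue` (and
#'   `fdr` when `adjust = TRUE`).
#' @export
moduleTraitCorrelations <- function(eigengenes, traits, adjust = FALSE) {
    stopifnot(is.matrix(eigengenes), nrow(eigengenes) == nrow(traits))
    num <- lapply(traits, function(x) {
        if (is.numeric(x)) return(x)
        f <- factor(x)
        if (nlevels(f) == 2) return(as.numeric(f) - 1)
        stop("traits must be numeric or two-level factors")
    })
    grid <- expand.grid(module = colnames(eigengenes), trait = names(num),
        stringsAsFactors = FALSE)
    res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
        e <- eigengenes[, grid$module[i]]
        x <- num[[grid$trait[i]]]
        if (sd(x) == 0)
            return(data.frame(correlation = NA_real_, pvalue = NA_real_))
        ct <- cor.test(e, x)
        data.frame(correlation = unname(ct$estimate), pvalue = ct$p.value)
    }))
    out <- cbind(grid, res)
    if (adjust) out$fdr <- p.adjust(out$pvalue, method = "BH")
    rownames(out) <- NULL
    out
}

#' Intramodular connectivity
#'
#' `kWithin_i`: the sum of a gene's adjacency weights to the other members of
#' its own module. High `kWithin` defines the module's hub genes.
#'
#' @param adj Adjacency matrix with gene dimnames.
#' @param labels Named module labels.
#' @return Named numeric vector of `kWithin` (0 for singleton modules).
#' @export
intramodularConnectivity <- function(adj, labels) {
    stopifnot(is.matrix(adj), !is.null(rownames(adj)))
    labels <- labels[rownames(adj)]
    k <- setNames(numeric(nrow(adj)), rownames(adj))
    for (m in unique(labels)) {
        idx <- which(labels == m)
        if (length(idx) < 2) next
        sub <- adj[idx, idx, drop = FALSE]
        k[idx] <- rowSums(sub) - diag(sub)
    }
    k
}

#' Top hub genes of a module
#'
#' @param kWithin Named vector from [intramodularConnectivity()].
#' @param labels Named module labels.
#' @param module Module label to rank.
#' @param k Number of hubs to return.
#' @return Character vector of the `k` genes with largest `kWithin` in the
#'   module (identifier tie-break).
#' @export
topHubGenes <- function(kWithin, labels, module, k = 10) {
    genes <- names(labels)[labels == module]
    if (!length(genes)) stop("no genes in module ", module)
    kw <- kWithin[genes]
    ord <- order(-kw, genes)
    genes[ord][seq_len(min(k, length(genes)))]
}

#' Build a weighted co-expression network
#'
#' Convenience wrapper: correlation matrix, soft power (fitted via
#' [fitSoftThreshold()] unless supplied), adjacency, TOM and module labels,
#' returned as a [CoexpressionNetwork-class] object.
#'
#' @param expr Genes x samples matrix.
#' @param power Soft power; `NULL` to fit over `powers`.
#' @param powers Candidate powers for the fit.
#' @param minModuleSize,cutHeight Passed to [clusterModules()].
#' @return A `CoexpressionNetwork` object.
#' @export
buildCoexpressionNetwork <- function(expr, power = NULL, powers = 1:10,
                                     minModuleSize = 20, cutHeight = 0.97) {
    cc <- correlationMatrix(expr)
    profile <- data.frame()
    if (is.null(power)) {
        fit <- fitSoftThreshold(cc, powers = powers)
        power <- fit$power
        profile <- fit$profile
    }
    adj <- adjacencyMatrix(cc, power)
    tom <- topologicalOverlap(adj)
    labels <- clusterModules(tom, minModuleSize = minModuleSize,
        cutHeight = cutHeight)
    new("CoexpressionNetwork", genes = rownames(expr), correlation = cc,
        power = as.numeric(power), adjacency = adj, tom = tom,
        labels = labels, fitProfile = profile)
}
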