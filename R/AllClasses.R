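#' @import methods
#' @importFrom stats aggregate coef complete.cases cor cor.test cutree
#'   fisher.test hclust ks.test lm lm.fit lm.wfit median model.matrix
#'   p.adjust pbeta prcomp pt quantile rbinom residuals rnbinom rnorm
#'   runif sd setNames as.dist
#' @importFrom utils read.delim write.table head combn modifyList
NULL

#' Divergent-count result
#'
#' Holds the divergent count computed from a set of p-values: the series
#' \eqn{d_i = \#\{p \le i/n\} - i} over the grid \eqn{i/n} for the p-values in
#' increasing order, its maximum \eqn{D} (the divergent count, an estimate of
#' the excess of small p-values over a Uniform(0,1) reference), the index
#' attaining it, and the Kolmogorov-Smirnov test of the sample against
#' Uniform(0,1) which gives the divergence its probability.
#'
#' @slot n Number of p-values.
#' @slot dSeries Integer vector \eqn{d_1 \ldots d_n}.
#' @slot D The divergent count, \code{max(dSeries)}.
#' @slot argmaxIndex Smallest index \eqn{i} with \eqn{d_i = D}.
#' @slot ksStatistic Two-sided KS sup-norm statistic against Uniform(0,1).
#' @slot ksPvalue KS p-value.
#'
#' @seealso [divergentCount()]
#' @export
setClass("DivergentCount",
    representation(
        n = "integer",
        dSeries = "integer",
        D = "integer",
        argmaxIndex = "integer",
        ksStatistic = "numeric",
        ksPvalue = "numeric"
    )
)

setValidity("DivergentCount", function(object) {
    msg <- character()
    if (length(object@dSeries) != object@n)
        msg <- c(msg, "dSeries must have length n")
    if (length(object@dSeries) && object@D != max(object@dSeries))
        msg <- c(msg, "D must equal max(dSeries)")
    if (length(object@dSeries) &&
        object@dSeries[object@argmaxIndex] != object@D)
        msg <- c(msg, "argmaxIndex must attain D")
    if (object@ksStatistic < 0 || object@ksStatistic > 1)
        msg <- c(msg, "ksStatistic must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn DivergentCount Compact display.
#' @param object A `DivergentCount` object.
#' @export
setMethod("show", "DivergentCount", function(object) {
    cat("DivergentCount over", object@n, "p-values\n")
    cat("  D =", object@D, "at i =", object@argmaxIndex,
        sprintf("(D/n = %.4f)\n", object@D / object@n))
    cat(sprintf("  KS statistic = %.4f, p-value = %.3g\n",
        object@ksStatistic, object@ksPvalue))
})

#' @rdname DivergentCount
#' @param x A `DivergentCount` object.
#' @export
divCount <- function(x) x@D

#' @rdname DivergentCount
#' @export
dSeries <- function(x) x@dSeries

#' @rdname DivergentCount
#' @export
argmaxIndex <- function(x) x@argmaxIndex

#' @rdname DivergentCount
#' @export
ksStatistic <- function(x) x@ksStatistic

#' @rdname DivergentCount
#' @export
ksPvalue <- function(x) x@ksPvalue

#' Weighted co-expression network model
#'
#' Container for the network stage: the gene-gene Pearson correlation matrix,
#' the soft power used to derive the adjacency \eqn{a_{ij} = |r_{ij}|^\beta},
#' the topological overlap matrix, the module labels ("grey" = unassigned) and
#' the scale-free fit profile across candidate powers.
#'
#' @slot genes Character vector of gene identifiers.
#' @slot correlation Pearson correlation matrix (genes x genes).
#' @slot power Soft-threshold exponent applied to `abs(correlation)`.
#' @slot adjacency Adjacency matrix, entries in `[0, 1]`.
#' @slot tom Topological overlap matrix, unit diagonal.
#' @slot labels Named character vector mapping gene to module label.
#' @slot fitProfile Data frame of the scale-free fit (power, rsq, slope,
#'   mean connectivity) over the candidate powers, or empty if the power
#'   was supplied directly.
#'
#' @seealso [buildCoexpressionNetwork()]
#' @export
setClass("CoexpressionNetwork",
    representation(
        genes = "character",
        correlation = "matrix",
        power = "numeric",
        adjacency = "matrix",
        tom = "matrix",
        labels = "character",
        fitProfile = "data.frame"
    )
)

setValidity("CoexpressionNetwork", function(object) {
    msg <- character()
    m <- length(object@genes)
    for (nm in c("correlation", "adjacency", "tom")) {
        x <- slot(object, nm)
        if (!all(dim(x) == c(m, m)))
            msg <- c(msg, paste(nm, "must be genes x genes"))
        else if (max(abs(x - t(x))) > 1e-10)
            msg <- c(msg, paste(nm, "must be symmetric"))
    }
    if (length(object@adjacency) &&
        (min(object@adjacency) < -1e-12 || max(object@adjacency) > 1 + 1e-12))
        msg <- c(msg, "adjacency entries must lie in [0, 1]")
    if (length(object@tom) && max(abs(diag(object@tom) - 1)) > 1e-12)
        msg <- c(msg, "tom must have unit diagonal")
    if (!setequal(names(object@labels), object@genes))
        msg <- c(msg, "labels must cover exactly the gene list")
    if (length(msg)) msg else TRUE
})

#' @describeIn CoexpressionNetwork Compact display.
#' @param object A `CoexpressionNetwork` object.
#' @export
setMethod("show", "CoexpressionNetwork", function(object) {
    tab <- table(object@labels)
    cat("CoexpressionNetwork:", length(object@genes), "genes, soft power",
        object@power, "\n")
    cat("  modules:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' @rdname CoexpressionNetwork
#' @param x A `CoexpressionNetwork` object.
#' @export
adjacency <- function(x) x@adjacency

#' @rdname CoexpressionNetwork
#' @export
tomMatrix <- function(x) x@tom

#' @rdname CoexpressionNetwork
#' @export
moduleLabels <- function(x) x@labels

#' @rdname CoexpressionNetwork
#' @export
softPower <- function(x) x@power
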