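#' Map a focal gene set across species
#'
#' Translates focal (e.g. pig) gene identifiers into the target (e.g. human)
#' identifier space via an ortholog/symbol mapping table. Many-to-many
#' mappings are allowed; the result is the de-duplicated union of the targets
#' of all focal genes. Focal genes without a map entry are counted as
#' unmapped.
#'
#' @param focal Character vector of focal gene identifiers.
#' @param map Data frame with columns `source_id` and `target_id` (no empty
#'   identifiers).
#' @return List: `mapped` (sorted unique target identifiers), `nUnmapped`,
#'   `unmapped` (focal genes with no entry).
#' @export
mapGenes <- function(focal, map) {
    stopifnot(is.data.frame(map))
    if (!all(c("source_id", "target_id") %in% names(map)))
        stop("map must have columns source_id and target_id")
    if (nrow(map) == 0) stop("empty ortholog map")
    if (any(!nzchar(map$source_id)) || any(!nzchar(map$target_id)))
        stop("empty identifiers in the map")
    hit <- map$source_id %in% focal
    unmapped <- setdiff(focal, map$source_id)
    list(mapped = sort(unique(map$target_id[hit])),
        nUnmapped = length(unmapped), unmapped = unmapped)
}

#' Partition an external DE result against a matched gene set
#'
#' Splits the external (e.g. human exercise) gene table into the matched set
#' and the background (all external genes not matched), and crosses that with
#' the significance flag, producing the 2x2 contingency table for the Fisher
#' test. Every external gene is assigned exactly once.
#'
#' @param external Data frame with columns `gene` and `significant`
#'   (logical, at the caller's chosen threshold).
#' @param matched Character vector of matched target-space identifiers.
#' @return 2x2 integer matrix, rows `c("matched", "background")`, columns
#'   `c("significant", "notSignificant")` (a warning if no external gene is
#'   matched).
#' @export
partitionAndTabulate <- function(external, matched) {
    stopifnot(is.data.frame(external), nrow(external) >= 1,
        all(c("gene", "significant") %in% names(external)))
    inMatched <- external$gene %in% matched
    if (!any(inMatched))
        warning("no external gene matches the focal set")
    sig <- as.logical(external$significant)
    tab <- matrix(c(
        sum(inMatched & sig), sum(inMatched & !sig),
        sum(!inMatched & sig), sum(!inMatched & !sig)),
        nrow = 2, byrow = TRUE,
        dimnames = list(c("matched", "background"),
            c("significant", "notSignificant")))
    storage.mode(tab) <- "integer"
    tab
}

#' Fisher exact enrichment test on a 2x2 table
#'
#' Two-sided Fisher exact p-value (hypergeometric: summing all tables with
#' probability at most that of the observed one) and the sample odds ratio
#' `(a*d)/(b*c)`, reported as `Inf` or `0` for zero cells rather than
#' erroring.
#'
#' Row-order convention: rows are (matched, background) and columns
#' (significant, not), as built by [partitionAndTabulate()]; under this
#' convention an odds ratio above 1 means the matched set is *enriched* for
#' significant genes. Published tables using the transposed contrast report
#' the reciprocal (values below one for enrichment); set `flip = TRUE` to
#' report that orientation.
#'
#' @param table 2x2 matrix of nonnegative integers.
#' @param flip Report the transposed-contrast (reciprocal) odds ratio.
#' @return List: `oddsRatio`, `pvalue`, `table`.
#' @export
fisherEnrichment <- function(table, flip = FALSE) {
    stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
    if (any(table < 0)) stop("table entries must be nonnegative")
    if (any(table != round(table))) stop("table entries must be integers")
    or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
    if (flip) or <- 1 / or
    p <- fisher.test(table, alternative = "two.sided")$p.value
    list(oddsRatio = or, pvalue = p, table = table)
}

#' End-to-end cross-species enrichment
#'
#' Maps the focal set, partitions the external table, and runs the Fisher
#' exact test.
#'
#' @inheritParams mapGenes
#' @inheritParams partitionAndTabulate
#' @inheritParams fisherEnrichment
#' @return List combining the [fisherEnrichment()] result with `nMatched`
#'   and `nUnmapped`.
#' @export
crossSpeciesEnrichment <- function(focal, map, external, flip = FALSE) {
    mp <- mapGenes(focal, map)
    tab <- partitionAndTabulate(external, mp$mapped)
    res <- fisherEnrichment(tab, flip = flip)
    c(res, list(nMatched = sum(tab["matched", ]), nUnmapped = mp$nUnmapped))
}
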