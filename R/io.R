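#' Read and write the pipeline's plain-text tables
#'
#' Counts are stored as TSV with the gene identifier in the first column and
#' a header row of sample identifiers; sample metadata as a TSV keyed by
#' `sample_id`. All intermediates are plain text for inspectability.
#'
#' @param se A `SummarizedExperiment` with a `"counts"` assay.
#' @param path File path.
#' @return Writers return `path` invisibly; `readCounts` returns a counts
#'   matrix, `readSampleTable` a data frame.
#' @export
writeCounts <- function(se, path) {
    counts <- SummarizedExperiment::assay(se, "counts")
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}

#' @rdname writeCounts
#' @export
writeSampleTable <- function(se, path) {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    write.table(cd, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCounts
#' @export
readSampleTable <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}

#' Assemble a SummarizedExperiment from counts and sample metadata
#'
#' @param counts Genes x samples integer matrix.
#' @param samples Data frame with a `sample_id` column matching the count
#'   matrix columns, plus covariates (`fcr`, `rin`, `age`, `breed`,
#'   `batch`).
#' @return A `SummarizedExperiment`.
#' @export
makeExperiment <- function(counts, samples) {
    stopifnot(is.matrix(counts), "sample_id" %in% names(samples))
    if (!setequal(colnames(counts), samples$sample_id))
        stop("count matrix columns and sample_id do not match")
    samples <- samples[match(colnames(counts), samples$sample_id), ]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(samples,
            row.names = samples$sample_id))
}

#' Write the ground truth of a simulated experiment as TSV
#'
#' @param se A simulated `SummarizedExperiment` from [simulateCounts()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(se, path) {
    truth <- S4Vectors::metadata(se)$groundTruth
    df <- data.frame(
        gene_id = names(truth$moduleAssignments),
        trait_gene = names(truth$moduleAssignments) %in% truth$traitGeneIds,
        trait_effect = unname(truth$traitEffectSizes),
        module = unname(truth$moduleAssignments))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
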