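#' Default pipeline configuration
#'
#' Stage toggles and parameters for [runPipeline()]. Every source of
#' randomness derives from the single `seed`: the simulator uses `seed`, the
#' interaction bootstrap `seed + 1000`, and the synthetic cross-species
#' tables `seed + 2000` (fixed documented offsets, all well below 2^31).
#'
#' @param seed Master seed.
#' @param ... Overrides for any default entry (unknown names error).
#' @return Named list of pipeline settings.
#' @export
pipelineConfig <- function(seed = 1L, ...) {
    cfg <- list(
        seed = as.integer(seed),
        countsPath = NULL, samplesPath = NULL,  # NULL => simulate
        sim = SimulationConfig(seed = as.integer(seed)),
        stages = c(simulate = TRUE, de = TRUE, divcount = TRUE,
            interact = TRUE, network = TRUE, crossspecies = TRUE),
        minCount = 5,
        normalization = "library-size",
        deVariants = c("ols", "weighted", "moderated"),
        ksAlternative = "two.sided",
        interactMaxGenes = 200,
        bootstrapB = 2000L,
        networkPower = NULL, networkPowers = 1:10,
        minModuleSize = 20, cutHeight = 0.97, mergeCut = 0.25,
        fisherFlip = FALSE)
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config entries: ",
        paste(bad, collapse = ", "))
    modifyList(cfg, over)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or load counts +
#' metadata), filter/normalize, per-gene trait regression for each model
#' variant, divergent-count consensus selection, pairwise interaction scan
#' with bootstrap calibration, co-expression network with module-trait
#' correlation and hub ranking, and a cross-species Fisher enrichment on a
#' synthetic ortholog map/external table (identity map; external significance
#' enriched among planted trait genes). All intermediates are written as TSV
#' under `outputDir` and listed in a manifest. Reruns with the same
#' configuration are byte-identical for the deterministic stages.
#'
#' @param config List from [pipelineConfig()].
#' @param outputDir Output directory (created if needed).
#' @return The manifest data frame (file, stage, rows, cols), invisibly
#'   written to `manifest.tsv` alongside a `params.tsv` key-value dump.
#' @export
runPipeline <- function(config = pipelineConfig(), outputDir) {
    stopifnot(is.list(config), !missing(outputDir))
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- data.frame(file = character(0), stage = character(0),
        rows = integer(0), cols = integer(0))
    note <- function(file, stage, obj) {
        manifest <<- rbind(manifest, data.frame(file = file, stage = stage,
            rows = NROW(obj), cols = NCOL(obj)))
    }
    emit <- function(df, file, stage) {
        path <- file.path(outputDir, file)
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
        note(file, stage, df)
    }
    fail <- function(stage, e) stop("pipeline stage '", stage, "' failed: ",
        conditionMessage(e), call. = FALSE)
    on.exit({
        write.table(manifest, file.path(outputDir, "manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        writeParams(config, file.path(outputDir, "params.tsv"))
    })

    se <- NULL
    if (isTRUE(config$stages[["simulate"]])) {
        se <- tryCatch(simulateCounts(config$sim),
            error = function(e) fail("simulate", e))
        writeCounts(se, file.path(outputDir, "counts.tsv"))
        note("counts.tsv", "simulate", SummarizedExperiment::assay(se))
        writeSampleTable(se, file.path(outputDir, "samples.tsv"))
        note("samples.tsv", "simulate",
            SummarizedExperiment::colData(se))
        writeGroundTruth(se, file.path(outputDir, "ground_truth.tsv"))
        note("ground_truth.tsv", "simulate", SummarizedExperiment::rowData(se))
    } else if (!is.null(config$countsPath)) {
        counts <- readCounts(config$countsPath)
        samples <- readSampleTable(config$samplesPath)
        se <- makeExperiment(counts, samples)
    }

    needExpr <- any(unlist(config$stages[c("de", "divcount", "interact",
        "network")]))
    if (!is.null(se) && needExpr) {
        se <- filterMinCount(se, config$minCount)
        se <- normalizeCounts(se, method = config$normalization)
    }

    deTables <- list()
    if (isTRUE(config$stages[["de"]]) && !is.null(se)) {
        deTables <- tryCatch(
            lapply(setNames(nm = config$deVariants), function(v)
                fitDE(se, variant = v)),
            error = function(e) fail("de", e))
        for (v in names(deTables))
            emit(deTables[[v]], paste0("de_", v, ".tsv"), "de")
    }

    consensus <- character(0)
    if (isTRUE(config$stages[["divcount"]]) && length(deTables)) {
        sel <- tryCatch({
            lapply(deTables, function(tab) {
                dc <- divergentCount(tab$pvalue,
                    alternative = config$ksAlternative)
                list(dc = dc, genes = suppressWarnings(
                    selectTopDivergent(tab,
                        alternative = config$ksAlternative)))
            })
        }, error = function(e) fail("divcount", e))
        report <- data.frame(
            method = names(sel),
            n = vapply(sel, function(s) s$dc@n, integer(1)),
            divergent_count = vapply(sel, function(s) divCount(s$dc),
                integer(1)),
            ks_statistic = vapply(sel, function(s) ksStatistic(s$dc),
                numeric(1)),
            ks_pvalue = vapply(sel, function(s) ksPvalue(s$dc), numeric(1)))
        emit(report, "divergent_counts.tsv", "divcount")
        ci <- consensusIntersection(lapply(sel, `[[`, "genes"))
        consensus <- ci$consensus
        emit(data.frame(gene_id = consensus), "consensus_genes.tsv",
            "divcount")
        emit(ci$overlapCounts, "consensus_overlap.tsv", "divcount")
    }

    if (isTRUE(config$stages[["interact"]]) && !is.null(se)) {
        res <- tryCatch({
            genes <- if (length(consensus) >= 2) consensus else rownames(se)
            if (length(genes) > config$interactMaxGenes) {
                # cap by smallest ols p-value for tractability
                tab <- if (length(deTables)) deTables[[1]] else fitDE(se)
                ord <- order(tab$pvalue, tab$gene_id)
                genes <- intersect(tab$gene_id[ord], genes)[
                    seq_len(config$interactMaxGenes)]
            }
            resid <- residualizeExpression(se[genes, ])
            trait <- SummarizedExperiment::colData(se)$fcr
            pairs <- pairwiseInteractionScan(resid, trait,
                maxGenes = config$interactMaxGenes)
            perGene <- perGeneDivergentCounts(pairs)
            boot <- bootstrapNullDivergent(pairs$pvalue,
                mPerGene = nrow(resid) - 1L, B = config$bootstrapB,
                seed = config$seed + 1000L)
            flagged <- flagExceedingGenes(perGene, boot$max)
            list(pairs = pairs, perGene = perGene, boot = boot,
                flagged = flagged)
        }, error = function(e) fail("interact", e))
        emit(res$pairs, "interaction_pairs.tsv", "interact")
        emit(data.frame(gene = names(res$perGene),
            divergent_count = as.integer(res$perGene),
            flagged = names(res$perGene) %in% res$flagged$gene),
            "interaction_genes.tsv", "interact")
        emit(data.frame(stat = c("B", "mPerGene", "max",
                names(res$boot$quantiles)),
            value = c(res$boot$B, res$boot$mPerGene, res$boot$max,
                unname(res$boot$quantiles))),
            "interaction_bootstrap.tsv", "interact")
    }

    if (isTRUE(config$stages[["network"]]) && !is.null(se)) {
        net <- tryCatch({
            expr <- SummarizedExperiment::assay(se, "logexpr")
            nw <- buildCoexpressionNetwork(expr,
                power = config$networkPower, powers = config$networkPowers,
                minModuleSize = config$minModuleSize,
                cutHeight = config$cutHeight)
            corrected <- correctForRIN(expr,
                SummarizedExperiment::colData(se)$rin)
            labels <- moduleLabels(nw)
            if (length(setdiff(unique(labels), "grey"))) {
                merged <- mergeModules(corrected, labels,
                    mergeCut = config$mergeCut)
                cd <- as.data.frame(SummarizedExperiment::colData(se))
                traits <- cd[, intersect(c("fcr", "rin", "age", "breed",
                    "batch"), names(cd)), drop = FALSE]
                traits <- traits[, vapply(traits, function(x)
                    is.numeric(x) || nlevels(factor(x)) == 2, logical(1)),
                    drop = FALSE]
                mt <- moduleTraitCorrelations(merged$eigengenes, traits)
                kw <- intramodularConnectivity(adjacency(nw), merged$labels)
                list(nw = nw, merged = merged, mt = mt, kw = kw)
            } else list(nw = nw, merged = NULL, mt = NULL, kw = NULL)
        }, error = function(e) fail("network", e))
        emit(data.frame(gene = names(moduleLabels(net$nw)),
            module = unname(moduleLabels(net$nw)),
            merged = if (is.null(net$merged)) unname(moduleLabels(net$nw))
                else unname(net$merged$labels)),
            "network_modules.tsv", "network")
        if (!is.null(net$mt))
            emit(net$mt, "module_trait_correlations.tsv", "network")
        if (!is.null(net$kw))
            emit(data.frame(gene = names(net$kw),
                module = unname(net$merged$labels[names(net$kw)]),
                k_within = unname(net$kw)), "k_within.tsv", "network")
        if (nrow(net$nw@fitProfile))
            emit(net$nw@fitProfile, "soft_threshold_profile.tsv", "network")
    }

    if (isTRUE(config$stages[["crossspecies"]]) && !is.null(se)) {
        xs <- tryCatch({
            focal <- if (length(consensus)) consensus
                else rownames(se)[seq_len(min(100, nrow(se)))]
            g <- rownames(se)
            map <- data.frame(source_id = g,
                target_id = toupper(g))
            truth <- S4Vectors::metadata(se)$groundTruth
            set.seed(config$seed + 2000L)
            inTruth <- if (!is.null(truth)) g %in% truth$traitGeneIds
                else rep(FALSE, length(g))
            external <- data.frame(gene = toupper(g),
                significant = runif(length(g)) <
                    ifelse(inTruth, 0.4, 0.15))
            res <- crossSpeciesEnrichment(focal, map, external,
                flip = config$fisherFlip)
            list(map = map, external = external, res = res)
        }, error = function(e) fail("crossspecies", e))
        emit(data.frame(key = c("odds_ratio", "pvalue", "n_matched",
                "n_unmapped", "a", "b", "c", "d"),
            value = c(xs$res$oddsRatio, xs$res$pvalue, xs$res$nMatched,
                xs$res$nUnmapped, xs$res$table[1, 1], xs$res$table[1, 2],
                xs$res$table[2, 1], xs$res$table[2, 2])),
            "cross_species.tsv", "crossspecies")
    }

    invisible(manifest)
}

writeParams <- function(config, path) {
    flat <- function(x, prefix = "") {
        if (is(x, "SimulationConfig")) {
            nm <- slotNames(x)
            vals <- lapply(nm, function(s) slot(x, s))
            names(vals) <- paste0("sim.", nm)
            return(unlist(lapply(vals, paste, collapse = ",")))
        }
        if (is.list(x))
            return(unlist(mapply(flat, x,
                paste0(prefix, names(x), "."), SIMPLIFY = FALSE)))
        setNames(paste(x, collapse = ","),
            sub("\\.$", "", prefix))
    }
    kv <- unlist(lapply(seq_along(config), function(i)
        flat(config[[i]], paste0(names(config)[i], "."))))
    names(kv) <- sub("\\.$", "", names(kv))
    write.table(data.frame(param = names(kv), value = unname(kv)), path,
        sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
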