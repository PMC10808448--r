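## Reproducible end-to-end pipeline: validated run configuration, manifest,
## staged execution (load/simulate -> align -> preprocess -> diversity ->
## compare -> mediate) with logging and file outputs.

.RUNCONFIG_KEYS <- c("featureTable", "metadata", "tree", "unit", "simulate",
                     "rank", "prevalenceThreshold", "pseudocount",
                     "confounders", "penalty", "folds", "nPerm", "seed",
                     "outputDir")

#' Validate a pipeline run configuration
#'
#' Checks the configuration against the schema before any computation:
#' unknown keys are rejected, a seed and output directory are mandatory,
#' and the input source must be either file paths (\code{featureTable} +
#' \code{metadata}) or \code{simulate}.
#'
#' @param config named list.
#' @return The validated config (with defaults filled in), invisibly usable.
#' @export
validateRunConfig <- function(config) {
    if (!is.list(config)) stop("config must be a named list")
    unknown <- setdiff(names(config), .RUNCONFIG_KEYS)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    if (is.null(config$seed))
        stop("config must set 'seed'")
    if (is.null(config$outputDir))
        stop("config must set 'outputDir'")
    hasFiles <- !is.null(config$featureTable) && !is.null(config$metadata)
    wantsSim <- isTRUE(config$simulate) || is.list(config$simulate)
    if (!hasFiles && !wantsSim)
        stop("config must give 'featureTable' + 'metadata' paths, ",
             "or 'simulate'")
    defaults <- list(unit = "counts", rank = "genus",
                     prevalenceThreshold = 0.10, pseudocount = "auto",
                     confounders = c("age", "sex"), penalty = "cv",
                     folds = 10, nPerm = 999)
    for (k in names(defaults))
        if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
    config$seed <- as.integer(config$seed)
    config
}

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file.
#' @return The validated configuration list.
#' @export
readRunConfig <- function(path) {
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (!is.null(cfg$confounders))
        cfg$confounders <- unlist(cfg$confounders)
    validateRunConfig(cfg)
}

.writeJSON <- function(x, path)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE, na = "null")

#' Run the full pipeline
#'
#' Freezes the configuration into a manifest (with input checksums, package
#' version and seed), then executes the stages: load or simulate the cohort,
#' align samples, preprocess (relative abundance, rank aggregation,
#' prevalence filter), diversity (alpha metrics with ANOVA; Canberra
#' distance with PERMANOVA; UniFrac when a tree is supplied), cohort
#' comparison and volcano statistics (underweight vs non-underweight within
#' the exposed arm), and the mediation analysis. Each stage logs sample and
#' taxon counts; any stage error aborts with a pointer to the failing stage.
#'
#' @param config run configuration (list, or path to a YAML/JSON file).
#' @return Invisibly, a list with the result objects and the paths written.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    config <- validateRunConfig(config)
    out <- config$outputDir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    logFile <- file.path(out, "log.txt")
    plog <- function(stage, ...) {
        line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                        stage, paste0(...))
        cat(line, "\n", file = logFile, append = TRUE)
        message(line)
    }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            plog(name, "ERROR: ", conditionMessage(e))
            stop("pipeline stage '", name, "' failed (see ", logFile, "): ",
                 conditionMessage(e), call. = FALSE)
        })
    }
    paths <- list(manifest = file.path(out, "manifest.json"))
    ## manifest-first: freeze configuration before stage 1
    manifest <- list(
        package = "mbMediate",
        version = as.character(utils::packageVersion("mbMediate")),
        created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
        seed = config$seed,
        config = config[setdiff(names(config), "outputDir")],
        inputChecksums = local({
            f <- unlist(config[c("featureTable", "metadata", "tree")])
            if (length(f)) as.list(tools::md5sum(f)) else list()
        }))
    .writeJSON(manifest, paths$manifest)
    results <- list()

    stage("load", {
        if (isTRUE(config$simulate) || is.list(config$simulate)) {
            simArgs <- if (is.list(config$simulate)) config$simulate
                       else list()
            simArgs$seed <- config$seed
            simCfg <- do.call(simulationConfig, simArgs)
            sim <- simulateCohort(simCfg)
            table <- sim$table; meta <- sim$meta
            paths$simTable <- writeFeatureTable(
                table, file.path(out, "simulated_counts.tsv"))
            paths$simMeta <- writeSampleMetadata(
                meta, file.path(out, "simulated_metadata.tsv"))
            truth <- sim$truth; class(truth) <- NULL
            .writeJSON(truth, file.path(out, "simulated_truth.json"))
            plog("load", sprintf("simulated %d taxa x %d samples (seed %d)",
                                 nrow(table), ncol(table), config$seed))
        } else {
            table <- readFeatureTable(config$featureTable,
                                      unit = config$unit)
            meta <- readSampleMetadata(config$metadata)
            plog("load", sprintf("read %d taxa x %d samples, %d metadata rows",
                                 nrow(table), ncol(table), nrow(meta)))
        }
        tree <- NULL
        if (!is.null(config$tree)) {
            tree <- readTree(config$tree)
            plog("load", sprintf("tree with %d tips",
                                 length(tree$tip.label)))
        }
        results$table <- table; results$meta <- meta
        results$tree <- tree
    })

    stage("align", {
        al <- alignSamples(results$table, results$meta)
        results$table <- al$table; results$meta <- al$meta
        plog("align", sprintf("%d shared samples (dropped %d + %d)",
                              ncol(al$table), length(al$droppedTable),
                              length(al$droppedMeta)))
    })

    stage("preprocess", {
        tab <- results$table
        counts <- if (abundanceUnit(tab) == "counts") tab else NULL
        ra <- if (is.null(counts)) tab else toRelativeAbundance(counts)
        nIn <- nrow(ra)
        if (!is.null(config$rank) && ncol(lineage(ra)))
            ra <- aggregateTaxa(ra, config$rank)
        nAgg <- nrow(ra)
        filtered <- suppressMessages(
            prevalenceFilter(ra, config$prevalenceThreshold))
        results$counts <- counts
        results$filtered <- filtered
        paths$filtered <- writeFeatureTable(
            filtered, file.path(out, "filtered_relative_abundance.tsv"))
        .writeJSON(list(taxaIn = nIn, taxaAtRank = nAgg,
                        taxaKept = nrow(filtered),
                        rank = config$rank,
                        prevalenceThreshold = config$prevalenceThreshold),
                   file.path(out, "preprocess_provenance.json"))
        plog("preprocess", sprintf("%d taxa -> %d at rank %s -> %d kept",
                                   nIn, nAgg, config$rank, nrow(filtered)))
    })

    stage("diversity", {
        meta <- results$meta
        ## study question: underweight vs non-underweight within the exposed
        sub <- rownames(meta)[meta$exposure == 1 & !is.na(meta$underweight)]
        groups <- meta[sub, "underweight"]
        divOut <- list()
        if (length(unique(groups)) == 2L && min(table(groups)) >= 2L) {
            if (!is.null(results$counts)) {
                alpha <- alphaDiversity(results$counts[, sub],
                                        groups = groups)
                utils::write.table(as.data.frame(alpha),
                                   file.path(out, "alpha_diversity.tsv"),
                                   sep = "\t", quote = FALSE)
                divOut$alphaAnovaP <- as.list(metadata(alpha)$anovaP)
            }
            dCan <- canberraDistance(results$filtered[, sub])
            utils::write.table(as.matrix(dCan),
                               file.path(out, "distance_canberra.tsv"),
                               sep = "\t", quote = FALSE)
            pv <- permanova(dCan, groups, nPerm = config$nPerm,
                            seed = config$seed)
            divOut$canberra <- list(pseudoF = pv$statistic, p = pv$p.value,
                                    nPerm = pv$nPerm)
            if (!is.null(results$tree)) {
                for (w in c(FALSE, TRUE)) {
                    dU <- uniFrac(results$filtered[, sub], results$tree,
                                  weighted = w)
                    pu <- permanova(dU, groups, nPerm = config$nPerm,
                                    seed = config$seed)
                    divOut[[if (w) "weightedUniFrac" else
                            "unweightedUniFrac"]] <-
                        list(pseudoF = pu$statistic, p = pu$p.value)
                }
            }
            plog("diversity", sprintf("groups %d/%d; Canberra PERMANOVA p = %.4g",
                                      sum(groups == 1), sum(groups == 0),
                                      pv$p.value))
        } else {
            plog("diversity", "skipped: fewer than 2 samples per group")
        }
        .writeJSON(divOut, file.path(out, "diversity.json"))
        results$diversity <- divOut
    })

    stage("compare", {
        meta <- results$meta
        vars <- intersect(c("age", "sex", "bmi", "underweight"),
                          colnames(meta))
        cmp <- compareGroups(meta, vars)
        utils::write.table(as.data.frame(cmp),
                           file.path(out, "comparison.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        sub <- rownames(meta)[meta$exposure == 1 & !is.na(meta$underweight)]
        groups <- meta[sub, "underweight"]
        if (length(unique(groups)) == 2L) {
            vol <- taxonVolcano(results$filtered[, sub], groups)
            utils::write.table(as.data.frame(vol),
                               file.path(out, "volcano.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
            results$volcano <- vol
            plog("compare", sprintf("volcano: %d/%d taxa significant",
                                    sum(vol$significant), nrow(vol)))
        } else {
            plog("compare", "volcano skipped: one outcome class")
        }
        results$comparison <- cmp
    })

    stage("mediate", {
        medRes <- suppressMessages(runMediation(
            results$table, results$meta, rank = config$rank,
            confounders = config$confounders,
            prevalenceThreshold = config$prevalenceThreshold,
            pseudocount = config$pseudocount, penalty = config$penalty,
            folds = config$folds, seed = config$seed))
        tab <- mediationTable(medRes)
        f <- file.path(out, sprintf("mediation_%s.tsv", config$rank))
        utils::write.table(tab, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        .writeJSON(c(list(rank = config$rank,
                          teUnadjusted = medRes@teUnadjusted,
                          teAdjusted = medRes@teAdjusted,
                          allRow = medRes@allRow,
                          skipped = as.list(medRes@skipped)),
                     list(rows = as.data.frame(medRes))),
                   file.path(out, sprintf("mediation_%s.json", config$rank)))
        results$mediation <- medRes
        nSig <- if (nrow(medRes)) sum(medRes$significant) else 0L
        plog("mediate", sprintf("%d mediators, %d significant (p < 0.05)",
                                nrow(medRes), nSig))
    })

    invisible(c(results, list(paths = paths, outputDir = out)))
}
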