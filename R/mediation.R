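## The difference-of-coefficients mediation layer: proportion mediated,
## joint-significance testing, and the orchestration that produces the
## per-taxon mediation table.

#' Proportion mediated
#'
#' The indirect (mediation) effect is the difference between the total
#' effect and the direct effect, IE = TE - DE; the proportion mediated is
#' PM = IE / TE. Undefined when |TE| is below \code{eps}.
#'
#' @param te total effect (exposure coefficient without mediators).
#' @param de direct effect (exposure coefficient with mediators).
#' @param eps guard for near-zero total effects.
#' @return (te - de) / te, as a fraction (multiply by 100 for percent).
#' @examples
#' 100 * proportionMediated(1.8079, 1.0433)  # 42.29
#' @export
proportionMediated <- function(te, de, eps = 1e-8) {
    stopifnot(length(te) == length(de) || length(te) == 1L ||
              length(de) == 1L)
    if (any(abs(te) <= eps))
        stop("proportion mediated is undefined: |total effect| <= ", eps)
    (te - de) / te
}

#' Joint-significance (max-p) mediation test
#'
#' The mediation p-value is the maximum of the exposure-to-mediator (alpha
#' path) and mediator-to-outcome (beta path) p-values: mediation is declared
#' only when both paths are individually significant.
#'
#' @param pAlpha,pBeta p-values in [0, 1] (vectorised).
#' @return pmax(pAlpha, pBeta).
#' @export
jointSignificance <- function(pAlpha, pBeta) {
    if (any(c(pAlpha, pBeta) < 0 | c(pAlpha, pBeta) > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    pmax(pAlpha, pBeta)
}

#' Run the full mediation analysis
#'
#' End-to-end difference-of-coefficients mediation with microbial mediators:
#' aligns samples, normalises counts to relative abundance, optionally
#' aggregates to a taxonomic rank, applies the prevalence filter, builds the
#' log relative-abundance mediator matrix, and fits the three models on one
#' common complete-case sample set (so the total effect is identical in
#' every row). Produces the unadjusted and adjusted total effect, the
#' all-mediator ridge row with its overall proportion mediated, and one row
#' per taxon with direct effect, alpha and beta paths, proportion mediated
#' and the joint-significance mediation p-value; rows are sorted by
#' mediation p and flagged at p < 0.05.
#'
#' @param table a \linkS4class{FeatureTable} (counts or relative abundance).
#' @param meta a \linkS4class{SampleData} with \code{underweight},
#'   \code{exposure} and the confounder columns.
#' @param rank optional taxonomic rank to aggregate to (e.g. \code{"genus"},
#'   \code{"species"}).
#' @param confounders confounder column names (default age and sex).
#' @param prevalenceThreshold prevalence filter fraction (default 0.10).
#' @param pseudocount pseudocount for the log transform (\code{"auto"} =
#'   half the smallest nonzero relative abundance).
#' @param penalty ridge penalty for the all-mediator model (\code{"cv"} or a
#'   number).
#' @param folds CV folds for penalty selection.
#' @param seed integer seed (required when \code{penalty = "cv"}).
#' @param includeAll fit the all-mediator ridge row (set FALSE to skip the
#'   most expensive step when only per-taxon results are needed).
#' @param mediatorScale \code{"log"} (default) or \code{"relative"} for raw
#'   relative abundances.
#' @return A \linkS4class{MediationResult}.
#' @export
runMediation <- function(table, meta, rank = NULL,
                         confounders = c("age", "sex"),
                         prevalenceThreshold = 0.10, pseudocount = "auto",
                         penalty = "cv", folds = 10, seed = NULL,
                         includeAll = TRUE,
                         mediatorScale = c("log", "relative")) {
    mediatorScale <- match.arg(mediatorScale)
    al <- alignSamples(table, meta)
    tab <- al$table; met <- al$meta
    if (abundanceUnit(tab) == "counts") tab <- toRelativeAbundance(tab)
    if (!is.null(rank)) tab <- aggregateTaxa(tab, rank)
    tab <- prevalenceFilter(tab, prevalenceThreshold)
    mm <- if (mediatorScale == "log") logTransform(tab, pseudocount)
          else relativeAbundanceMatrix(tab)
    ## one common complete-case set across all three models
    need <- as.data.frame(met[, c("underweight", "exposure", confounders),
                              drop = FALSE])
    cc <- stats::complete.cases(need)
    if (sum(cc) < length(confounders) + 3L) stop("too few complete cases")
    met <- met[cc, , drop = FALSE]
    M <- mediatorValues(mm)[rownames(met), , drop = FALSE]
    message(sprintf("runMediation: %d complete cases, %d candidate mediators",
                    nrow(met), ncol(M)))
    skipped <- character()
    sds <- apply(M, 2L, stats::sd)
    if (any(sds == 0)) {
        skipped[colnames(M)[sds == 0]] <- "constant mediator"
        M <- M[, sds > 0, drop = FALSE]
    }
    mm2 <- new("MediatorMatrix", values = M, pseudocount = mm@pseudocount,
               scale = mm@scale)
    teUFit <- fitModel1(met, confounders = character(0))
    teAFit <- fitModel1(met, confounders = confounders)
    teU <- coefRow(teUFit, "exposure")
    teA <- coefRow(teAFit, "exposure")
    te <- teA$estimate
    allRow <- list()
    if (includeAll && ncol(M)) {
        m2all <- fitModel2All(mm2, met, confounders, penalty = penalty,
                              folds = folds, seed = seed)
        deAll <- coefRow(m2all, "exposure")
        allRow <- list(de = deAll$estimate, ciLower = deAll$ciLower,
                       ciUpper = deAll$ciUpper,
                       pm = proportionMediated(te, deAll$estimate),
                       penalty = m2all@penalty, flags = m2all@flags)
    }
    a3 <- fitModel3(mm2, met, confounders)
    rows <- vector("list", ncol(M))
    for (j in seq_len(ncol(M))) {
        id <- colnames(M)[j]
        m2 <- tryCatch(fitModel2Single(M[, j], met, confounders,
                                       mediatorName = id),
                       error = function(e) conditionMessage(e))
        if (is.character(m2)) { skipped[id] <- m2; next }
        de <- coefRow(m2, "exposure")
        be <- coefRow(m2, id)
        ai <- match(id, a3$mediator)
        rows[[j]] <- DataFrame(
            mediator = id, te = te, teLower = teA$ciLower,
            teUpper = teA$ciUpper, de = de$estimate, deLower = de$ciLower,
            deUpper = de$ciUpper, alpha = a3$estimate[ai],
            alphaLower = a3$ciLower[ai], alphaUpper = a3$ciUpper[ai],
            alphaP = a3$p[ai], beta = be$estimate, betaLower = be$ciLower,
            betaUpper = be$ciUpper, betaP = be$p,
            ie = te - de$estimate,
            pm = proportionMediated(te, de$estimate),
            p = jointSignificance(a3$p[ai], be$p),
            flags = paste(m2@flags, collapse = ","))
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    res <- if (length(rows)) do.call(rbind, rows) else
        DataFrame(mediator = character(), te = numeric(), de = numeric(),
                  alpha = numeric(), beta = numeric(), ie = numeric(),
                  pm = numeric(), p = numeric())
    if (nrow(res)) {
        res <- res[order(res$p), , drop = FALSE]
        res$significant <- res$p < 0.05
        rownames(res) <- res$mediator
    }
    new("MediationResult", res,
        teUnadjusted = teU, teAdjusted = teA, allRow = allRow,
        rank = if (is.null(rank)) NA_character_ else rank,
        params = list(rank = rank, confounders = confounders,
                      prevalenceThreshold = prevalenceThreshold,
                      pseudocount = mm@pseudocount, penalty = penalty,
                      folds = folds, seed = seed, scale = mm@scale,
                      nSamples = nrow(met), nMediators = ncol(M)),
        skipped = skipped)
}

#' Format a MediationResult as a publication-style table
#'
#' One row per mediator with the effect columns on the printed scale:
#' estimates with 95 percent CIs, PM as percent with two decimals, and the
#' mediation p-value; preceded by the unadjusted and all-mediator rows.
#'
#' @param x a \linkS4class{MediationResult}.
#' @return A \code{data.frame} ready for writing as TSV.
#' @export
mediationTable <- function(x) {
    fmt <- function(e, l, u) sprintf("%.4f (%.4f, %.4f)", e, l, u)
    head <- data.frame(
        mediator = "Unadjusted",
        effectOnOutcome = fmt(x@teUnadjusted$estimate,
                              x@teUnadjusted$ciLower, x@teUnadjusted$ciUpper),
        effectOnMediator = "", effectOfMediator = "", PM = "", p = "",
        stringsAsFactors = FALSE)
    if (length(x@allRow))
        head <- rbind(head, data.frame(
            mediator = "ALL",
            effectOnOutcome = fmt(x@allRow$de, x@allRow$ciLower,
                                  x@allRow$ciUpper),
            effectOnMediator = "", effectOfMediator = "",
            PM = sprintf("%.2f %%", 100 * x@allRow$pm), p = ""))
    if (!nrow(x)) return(head)
    body <- data.frame(
        mediator = x$mediator,
        effectOnOutcome = fmt(x$de, x$deLower, x$deUpper),
        effectOnMediator = fmt(x$alpha, x$alphaLower, x$alphaUpper),
        effectOfMediator = fmt(x$beta, x$betaLower, x$betaUpper),
        PM = sprintf("%.2f %%", 100 * x$pm),
        p = sprintf("%.4f", x$p), stringsAsFactors = FALSE)
    rbind(head, body)
}
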