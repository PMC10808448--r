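## Demographic-table comparisons and per-taxon differential abundance with
## volcano statistics.

#' Two-sided Wilcoxon rank-sum test
#'
#' Missing values are dropped. The exact null distribution is used when the
#' smaller group has at most 8 observations and the pooled data have no
#' ties; otherwise the continuity-corrected normal approximation with tie
#' correction is used.
#'
#' @param x,y numeric vectors.
#' @return The two-sided p-value.
#' @examples
#' wilcoxonTest(c(1, 2), c(3, 4))  # exact: 1/3
#' @export
wilcoxonTest <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y))
        stop("both groups must have non-missing values")
    if (length(unique(c(x, y))) == 1L) return(1)  # no rank information
    ties <- anyDuplicated(c(x, y)) > 0L
    useExact <- min(length(x), length(y)) <= 8L && !ties
    suppressWarnings(stats::wilcox.test(x, y, exact = useExact,
                                        correct = !useExact))$p.value
}

#' Pearson chi-square test on an r x c count table
#'
#' Yates continuity correction is applied exactly when the table is 2 x 2,
#' which reproduces published 2 x 2 cohort comparisons.
#'
#' @param tab matrix of non-negative counts with positive row and column
#'   sums.
#' @return The chi-square p-value.
#' @examples
#' chisqTest(matrix(c(9, 2, 183, 125), 2))  # ~0.239
#' @export
chisqTest <- function(tab) {
    tab <- as.matrix(tab)
    if (any(tab < 0)) stop("counts must be non-negative")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("zero row or column margin")
    yates <- all(dim(tab) == 2L)
    suppressWarnings(stats::chisq.test(tab, correct = yates))$p.value
}

#' Confounder-adjusted group test via full-vs-reduced quasi-binomial models
#'
#' Fits the quasi-binomial logistic full model
#' \code{outcome ~ predictor + confounders} and the reduced model without the
#' predictor, on complete cases, and tests the predictor by an
#' analysis-of-deviance F test: the deviance difference divided by the
#' predictor degrees of freedom, scaled by the full model's Pearson
#' dispersion, referred to F(df_predictor, n - p_full).
#'
#' @param outcome binary 0/1 vector.
#' @param predictor numeric vector or factor.
#' @param confounders data.frame of confounder columns (same length).
#' @return list with \code{p}, \code{statistic}, \code{df} (numerator,
#'   denominator) and \code{flags} (e.g. \code{"separation"}, in which case
#'   \code{p} is NA).
#' @export
adjustedGroupTest <- function(outcome, predictor, confounders) {
    df <- data.frame(.y = outcome, .x = predictor, confounders)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    if (!nrow(df)) stop("no complete cases")
    full <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                        family = stats::quasibinomial()))
    red <- suppressWarnings(stats::glm(
        .y ~ ., data = df[setdiff(colnames(df), ".x")],
        family = stats::quasibinomial()))
    dfNum <- red$df.residual - full$df.residual
    if (dfNum <= 0)
        stop("predictor adds no degrees of freedom ",
             "(constant or duplicated in confounders)")
    flags <- .separationFlags(full)
    pearson <- sum(stats::residuals(full, type = "pearson")^2)
    disp <- pearson / full$df.residual
    fstat <- ((red$deviance - full$deviance) / dfNum) / disp
    p <- if (length(flags)) NA_real_ else
        stats::pf(fstat, dfNum, full$df.residual, lower.tail = FALSE)
    list(p = p, statistic = fstat, df = c(dfNum, full$df.residual),
         flags = flags)
}

## heuristic separation check for logistic fits
.separationFlags <- function(fit) {
    mu <- stats::fitted(fit)
    flags <- character()
    if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE) ||
        any(mu < 1e-8 | mu > 1 - 1e-8))
        flags <- "separation"
    if (anyNA(stats::coef(fit)))
        flags <- c(flags, "collinear")
    flags
}

#' Per-taxon volcano statistics between two groups
#'
#' For each taxon: the log2 fold change of mean relative abundance
#' (group 1 over group 0; a pseudocount of half the smallest nonzero group
#' mean across taxa replaces a zero group mean), the two-sided Wilcoxon
#' p-value, -log10(p), a significance flag at p < 0.05, and a
#' Benjamini-Hochberg adjusted column for reference.
#'
#' @param x a \linkS4class{FeatureTable} with unit
#'   \code{"relative_abundance"}, filtered and aggregated to the working
#'   rank.
#' @param groups binary 0/1 labels, one per sample; group 1 is the fold
#'   change numerator.
#' @return A \code{DataFrame} with one row per taxon.
#' @export
taxonVolcano <- function(x, groups) {
    stopifnot(is(x, "FeatureTable"))
    v <- abundance(x)
    g <- as.integer(groups)
    if (length(g) != ncol(v)) stop("groups must match the sample count")
    if (!all(g %in% 0:1)) stop("groups must be binary 0/1")
    if (!any(g == 1) || !any(g == 0)) stop("both groups must be non-empty")
    m1 <- rowMeans(v[, g == 1, drop = FALSE])
    m0 <- rowMeans(v[, g == 0, drop = FALSE])
    nz <- c(m1[m1 > 0], m0[m0 > 0])
    if (!length(nz)) stop("all group means are zero")
    ps <- min(nz) / 2
    log2fc <- unname(log2(ifelse(m1 > 0, m1, ps) / ifelse(m0 > 0, m0, ps)))
    p <- vapply(seq_len(nrow(v)), function(i)
        wilcoxonTest(v[i, g == 1], v[i, g == 0]), numeric(1))
    DataFrame(taxon = rownames(v), log2FoldChange = log2fc,
              meanGroup1 = unname(m1), meanGroup0 = unname(m0), p = p,
              negLog10P = -log10(p), significant = p < 0.05,
              padjBH = stats::p.adjust(p, method = "BH"))
}

#' Demographic comparison table between two groups
#'
#' Builds a cohort-characteristics table: numeric variables are summarised
#' as mean (SD) per group and compared by the Wilcoxon test; categorical
#' variables as count (percent) per category including an explicit Missing
#' category (percentages sum to 100 per variable) and compared by the
#' chi-square test on non-missing categories. When \code{confounders} are
#' given, an adjusted p-value is added from the full-vs-reduced
#' quasi-binomial F test with the group indicator as the dependent variable.
#'
#' @param meta a \linkS4class{SampleData} (or DataFrame).
#' @param variables column names to compare.
#' @param groupVar binary grouping column (default \code{"exposure"}).
#' @param confounders confounder columns for the adjusted p (default age and
#'   sex; skipped for the confounders themselves). Use \code{NULL} to skip.
#' @return A \code{DataFrame} with one row per variable/category: group
#'   summaries, \code{p} and \code{pAdjusted}.
#' @export
compareGroups <- function(meta, variables, groupVar = "exposure",
                          confounders = c("age", "sex")) {
    g <- meta[[groupVar]]
    if (is.null(g)) stop("no grouping column '", groupVar, "'")
    lev <- sort(unique(g[!is.na(g)]))
    if (length(lev) != 2L) stop("grouping variable must have two levels")
    rows <- list()
    for (v in variables) {
        col <- meta[[v]]
        if (is.null(col)) stop("no column '", v, "'")
        conf <- setdiff(confounders, v)
        adj <- NA_real_
        if (is.numeric(col)) {
            p <- wilcoxonTest(col[g == lev[2L]], col[g == lev[1L]])
            if (length(conf))
                adj <- adjustedGroupTest(as.integer(g == lev[2L]), col,
                                         as.data.frame(meta[, conf,
                                                            drop = FALSE]))$p
            summ <- vapply(lev, function(l) {
                z <- col[g == l & !is.na(col)]
                sprintf("%.1f (%.2f)", mean(z), stats::sd(z))
            }, character(1))
            rows[[length(rows) + 1L]] <- DataFrame(
                variable = v, category = "mean (SD)",
                group0 = summ[1L], group1 = summ[2L], p = p, pAdjusted = adj)
        } else {
            col <- as.character(col)
            cat0 <- sort(unique(col[!is.na(col)]))
            tab <- table(factor(col[!is.na(col)], levels = cat0),
                         g[!is.na(col)])
            p <- if (nrow(tab) >= 2L) chisqTest(tab) else NA_real_
            if (length(conf))
                adj <- tryCatch(adjustedGroupTest(
                    as.integer(g == lev[2L]), factor(col),
                    as.data.frame(meta[, conf, drop = FALSE]))$p,
                    error = function(e) NA_real_)
            cats <- c(cat0, if (anyNA(col)) "Missing")
            for (cc in cats) {
                cnt <- vapply(lev, function(l) {
                    if (cc == "Missing") sum(g == l & is.na(col))
                    else sum(g == l & !is.na(col) & col == cc)
                }, numeric(1))
                tot <- vapply(lev, function(l) sum(g == l), numeric(1))
                rows[[length(rows) + 1L]] <- DataFrame(
                    variable = v, category = cc,
                    group0 = sprintf("%d (%.1f%%)", cnt[1L],
                                     100 * cnt[1L] / tot[1L]),
                    group1 = sprintf("%d (%.1f%%)", cnt[2L],
                                     100 * cnt[2L] / tot[2L]),
                    p = p, pAdjusted = adj)
                p <- NA_real_; adj <- NA_real_  # print once per variable
            }
        }
    }
    do.call(rbind, rows)
}
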