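## Alpha and beta diversity with the group tests used in case-control
## microbiome comparisons: per-sample richness/evenness indices with one-way
## ANOVA, Canberra and UniFrac distances, and a permutation PERMANOVA.

#' Per-sample alpha diversity with optional ANOVA group test
#'
#' Computes Observed richness (number of taxa with nonzero count), the
#' bias-corrected Chao1 estimator (S_obs + F1(F1-1) / (2(F2+1)), with F1/F2
#' the singleton/doubleton counts), the Shannon index (-sum p log p, natural
#' log) and the Simpson index (1 - sum p^2). Chao1 requires integer counts;
#' Shannon and Simpson are computed on within-sample proportions. When
#' \code{groups} is given, each metric is compared across groups by one-way
#' ANOVA.
#'
#' @param x a \linkS4class{FeatureTable} with unit \code{"counts"}.
#' @param metrics subset of \code{c("observed", "chao1", "shannon",
#'   "simpson")}.
#' @param groups optional group labels (one per sample) for the ANOVA test.
#' @return A \code{DataFrame} of per-sample metric values; when groups are
#'   supplied, \code{metadata(.)$anovaP} holds the per-metric ANOVA p-values.
#' @examples
#' m <- matrix(c(1, 1, 2, 5), 4, 1, dimnames = list(paste0("t", 1:4), "s1"))
#' alphaDiversity(featureTable(m, unit = "counts"))
#' @export
alphaDiversity <- function(x, metrics = c("observed", "chao1", "shannon",
                                          "simpson"), groups = NULL) {
    stopifnot(is(x, "FeatureTable"))
    metrics <- match.arg(metrics, several.ok = TRUE)
    if (abundanceUnit(x) != "counts")
        stop("alphaDiversity expects unit 'counts'")
    v <- abundance(x)
    if ("chao1" %in% metrics && any(v != floor(v)))
        stop("Chao1 requires integer counts")
    res <- DataFrame(row.names = colnames(v))
    if ("observed" %in% metrics)
        res$observed <- as.integer(colSums(v > 0))
    if ("chao1" %in% metrics) {
        f1 <- colSums(v == 1)
        f2 <- colSums(v == 2)
        res$chao1 <- unname(colSums(v > 0) + f1 * (f1 - 1) / (2 * (f2 + 1)))
    }
    if ("shannon" %in% metrics)
        res$shannon <- as.numeric(vegan::diversity(t(v), index = "shannon"))
    if ("simpson" %in% metrics)
        res$simpson <- as.numeric(vegan::diversity(t(v), index = "simpson"))
    if (!is.null(groups)) {
        stopifnot(length(groups) == ncol(v))
        g <- factor(groups)
        metadata(res)$anovaP <- vapply(colnames(res), function(m) {
            stats::anova(stats::aov(res[[m]] ~ g))[["Pr(>F)"]][1L]
        }, numeric(1))
    }
    res
}

#' Canberra distance between samples
#'
#' d(x, y) = sum over coordinates i with x_i + y_i > 0 of
#' |x_i - y_i| / (x_i + y_i); coordinates where both are zero contribute
#' nothing (no rescaling is applied for skipped terms).
#'
#' @param x a \linkS4class{FeatureTable} (samples are columns) or a numeric
#'   matrix with samples as rows.
#' @return A \code{\link[stats]{dist}} object over samples.
#' @export
canberraDistance <- function(x) {
    m <- if (is(x, "FeatureTable")) t(abundance(x)) else as.matrix(x)
    n <- nrow(m)
    if (n < 2L) stop("need at least two samples")
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
        xi <- m[i, ]
        for (j in seq.int(i + 1L, n)) {
            s <- xi + m[j, ]
            ok <- s > 0
            d[j, i] <- d[i, j] <- sum(abs(xi[ok] - m[j, ok]) / s[ok])
        }
    }
    stats::as.dist(structure(d, dimnames = list(rownames(m), rownames(m))))
}

#' UniFrac distances between samples
#'
#' Phylogenetic beta diversity: the unweighted variant is the fraction of
#' branch length unique to one sample's taxon set over the branch length
#' spanned by either; the weighted (normalized) variant is
#' sum(b_i |A_i - B_i|) / sum(b_i (A_i + B_i)) with A_i, B_i the fraction of
#' each sample's abundance descending from branch i. Computed with
#' \pkg{phyloseq}.
#'
#' @param x a \linkS4class{FeatureTable}; all taxa must be tips of the tree.
#' @param tree rooted \pkg{ape} \code{phylo} with branch lengths.
#' @param weighted logical; abundance-weighted variant.
#' @param normalized logical; for the weighted variant, normalize into
#'   [0, 1].
#' @return A \code{\link[stats]{dist}} object over samples.
#' @export
uniFrac <- function(x, tree, weighted = FALSE, normalized = TRUE) {
    stopifnot(is(x, "FeatureTable"))
    chk <- matchTreeTaxa(tree, x)
    if (length(chk$missingTaxa))
        stop("taxa missing from the tree: ",
             paste(chk$missingTaxa, collapse = ", "))
    if (length(chk$extraTips))
        message("uniFrac: ", length(chk$extraTips),
                " tree tip(s) without table taxa (retained): ",
                paste(utils::head(chk$extraTips, 5L), collapse = ", "))
    otu <- phyloseq::otu_table(abundance(x), taxa_are_rows = TRUE)
    ps <- phyloseq::phyloseq(otu, phyloseq::phy_tree(tree))
    phyloseq::UniFrac(ps, weighted = weighted, normalized = normalized)
}

#' PERMANOVA (ADONIS-style) permutation test on a distance matrix
#'
#' Pseudo-F from the distance decomposition: with total sum of squares
#' SST = sum of squared distances over all pairs divided by n and
#' within-group SSW summed per group, F = (SSA / (g - 1)) / (SSW / (n - g))
#' where SSA = SST - SSW. The p-value is
#' (1 + #\{permuted F >= observed F\}) / (nPerm + 1) under random label
#' permutations drawn with the given seed.
#'
#' @param d a \code{\link[stats]{dist}} or square symmetric matrix.
#' @param groups group labels, at least two groups with two samples each.
#' @param nPerm number of label permutations.
#' @param seed integer seed for the permutations (required for
#'   reproducibility).
#' @return A list of class \code{"PermanovaResult"}: \code{statistic}
#'   (pseudo-F), \code{p.value}, \code{nPerm}, \code{seed}.
#' @export
permanova <- function(d, groups, nPerm = 999, seed) {
    dm <- as.matrix(d)
    n <- nrow(dm)
    g <- factor(groups)
    if (length(g) != n) stop("groups must match the distance matrix size")
    if (nlevels(g) < 2L) stop("need at least two groups")
    if (any(table(g) < 2L)) stop("each group needs at least two samples")
    d2 <- dm^2
    sst <- sum(d2[upper.tri(d2)]) / n
    pseudoF <- function(lab) {
        ssw <- 0
        for (lev in levels(lab)) {
            idx <- which(lab == lev)
            ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) /
                length(idx)
        }
        ssa <- sst - ssw
        (ssa / (nlevels(lab) - 1L)) / (ssw / (n - nlevels(lab)))
    }
    fObs <- pseudoF(g)
    if (!missing(seed) && !is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (b in seq_len(nPerm))
        if (pseudoF(g[sample.int(n)]) >= fObs) exceed <- exceed + 1L
    structure(list(statistic = fObs, p.value = (1 + exceed) / (nPerm + 1),
                   nPerm = nPerm,
                   seed = if (missing(seed)) NA_integer_ else seed),
              class = "PermanovaResult")
}

#' @export
print.PermanovaResult <- function(x, ...) {
    cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%d permutations)\n",
                x$statistic, x$p.value, x$nPerm))
    invisible(x)
}
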