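## Normalisation, prevalence filtering, taxonomic aggregation and the log
## transform that turns a feature table into the mediator matrix.

#' Normalize counts to relative abundance
#'
#' Divides each sample column by its total count, so columns sum to one.
#'
#' @param x a \linkS4class{FeatureTable} with unit \code{"counts"}.
#' @return A \linkS4class{FeatureTable} with unit
#'   \code{"relative_abundance"}.
#' @export
toRelativeAbundance <- function(x) {
    stopifnot(is(x, "FeatureTable"))
    if (abundanceUnit(x) != "counts")
        stop("toRelativeAbundance expects unit 'counts', got '",
             abundanceUnit(x), "'")
    v <- abundance(x)
    cs <- colSums(v)
    if (any(cs == 0))
        stop("all-zero sample(s): ",
             paste(colnames(v)[cs == 0], collapse = ", "))
    featureTable(sweep(v, 2L, cs, "/"), unit = "relative_abundance",
                 lineage = if (ncol(lineage(x))) lineage(x) else NULL)
}

#' Filter taxa by prevalence
#'
#' Keeps taxa detected (nonzero) in strictly more than
#' \code{threshold * n_samples} samples. With 330 samples and the default
#' threshold 0.10, a taxon present in 34 samples is kept and one present in
#' 33 is dropped.
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param threshold prevalence fraction in (0, 1); 0 keeps every taxon with
#'   at least one nonzero value.
#' @return The filtered \linkS4class{FeatureTable}.
#' @export
prevalenceFilter <- function(x, threshold = 0.10) {
    stopifnot(is(x, "FeatureTable"))
    if (threshold < 0 || threshold >= 1)
        stop("threshold must be in [0, 1)")
    v <- abundance(x)
    nPresent <- rowSums(v != 0)
    keep <- nPresent > threshold * ncol(v)
    message(sprintf("prevalenceFilter: kept %d of %d taxa (threshold %g)",
                    sum(keep), length(keep), threshold))
    if (!any(keep))
        warning("prevalence filter removed every taxon")
    x[keep, ]
}

#' Aggregate taxa to a taxonomic rank
#'
#' Sums abundances over taxa sharing the same lineage value at \code{rank}.
#' Taxa unannotated (NA) at that rank are dropped and counted; species-level
#' analyses therefore exclude features without a species assignment.
#'
#' @param x a \linkS4class{FeatureTable} with lineage columns at or above
#'   \code{rank}.
#' @param rank rank label, one of the lineage column names (e.g.
#'   \code{"genus"}, \code{"species"}).
#' @return A \linkS4class{FeatureTable} whose taxa are the distinct lineage
#'   values at \code{rank}; lineage keeps the ranks from kingdom down to
#'   \code{rank}.
#' @export
aggregateTaxa <- function(x, rank) {
    stopifnot(is(x, "FeatureTable"))
    lin <- lineage(x)
    if (!rank %in% colnames(lin))
        stop("rank '", rank, "' is not in the lineage schema (",
             paste(colnames(lin), collapse = ", "), ")")
    lab <- as.character(lin[[rank]])
    keep <- !is.na(lab)
    if (any(!keep))
        message(sprintf("aggregateTaxa: dropped %d taxa unannotated at %s",
                        sum(!keep), rank))
    if (!any(keep)) stop("no taxa annotated at rank '", rank, "'")
    v <- abundance(x)[keep, , drop = FALSE]
    lab <- lab[keep]
    groups <- unique(lab)
    agg <- rowsum(v, group = factor(lab, levels = groups), reorder = FALSE)
    rownames(agg) <- groups
    upper <- colnames(lin)[seq_len(match(rank, colnames(lin)))]
    newLin <- as.data.frame(lin[keep, upper, drop = FALSE])[
        match(groups, lab), , drop = FALSE]
    rownames(newLin) <- groups
    unit <- abundanceUnit(x)
    if (unit == "relative_abundance") {
        ## renormalise: dropped unannotated taxa leave columns summing < 1
        cs <- colSums(agg)
        if (any(cs == 0))
            stop("sample(s) with no annotated abundance at rank '", rank,
                 "': ", paste(colnames(agg)[cs == 0], collapse = ", "))
        agg <- sweep(agg, 2L, cs, "/")
    }
    featureTable(agg, unit = unit, lineage = newLin)
}

#' Log-transform relative abundances into a mediator matrix
#'
#' Computes \code{log(value + pseudocount)} (natural log) and transposes to
#' samples x mediators, the orientation the mediation models consume.
#' \code{pseudocount = "auto"} uses half the smallest nonzero relative
#' abundance in the table.
#'
#' @param x a \linkS4class{FeatureTable} with unit
#'   \code{"relative_abundance"}.
#' @param pseudocount positive number, or \code{"auto"}.
#' @return A \linkS4class{MediatorMatrix}.
#' @export
logTransform <- function(x, pseudocount = "auto") {
    stopifnot(is(x, "FeatureTable"))
    if (abundanceUnit(x) != "relative_abundance")
        stop("logTransform expects unit 'relative_abundance'")
    v <- abundance(x)
    if (identical(pseudocount, "auto")) {
        nz <- v[v > 0]
        if (!length(nz)) stop("table has no nonzero values")
        pseudocount <- min(nz) / 2
    }
    if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
        pseudocount <= 0)
        stop("pseudocount must be a single positive number or 'auto'")
    new("MediatorMatrix", values = t(log(v + pseudocount)),
        pseudocount = pseudocount, scale = "log_relative_abundance")
}

#' Use raw relative abundances as the mediator matrix
#'
#' Alternative mediator scale for sensitivity analyses: the untransformed
#' relative abundances, transposed to samples x mediators.
#'
#' @param x a \linkS4class{FeatureTable} with unit
#'   \code{"relative_abundance"}.
#' @return A \linkS4class{MediatorMatrix} on the raw scale.
#' @export
relativeAbundanceMatrix <- function(x) {
    stopifnot(is(x, "FeatureTable"),
              abundanceUnit(x) == "relative_abundance")
    new("MediatorMatrix", values = t(abundance(x)),
        pseudocount = NA_real_, scale = "relative_abundance")
}
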