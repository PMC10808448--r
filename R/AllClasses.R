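#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData
NULL

.ABUNDANCE_UNITS <- c("counts", "relative_abundance", "log_abundance")

#' Taxon-by-sample abundance table
#'
#' A \code{FeatureTable} is a \linkS4class{SummarizedExperiment} holding one
#' assay named \code{"abundance"} (taxa as rows, samples as columns), optional
#' rank-labelled lineage columns in \code{rowData}, and a declared abundance
#' unit (\code{"counts"}, \code{"relative_abundance"} or
#' \code{"log_abundance"}) in \code{metadata(x)$unit}.
#'
#' Validity requires unique taxon and sample identifiers, non-negative values
#' unless the unit is \code{"log_abundance"}, and, for relative abundances,
#' sample sums equal to 1 within 1e-9 (all-zero samples are disallowed).
#'
#' @seealso [featureTable()] for construction, [readFeatureTable()] for
#'   reading from TSV.
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
    msg <- character()
    if (!"abundance" %in% names(assays(object)))
        msg <- c(msg, "assay 'abundance' is required")
    unit <- metadata(object)$unit
    if (is.null(unit) || length(unit) != 1L || !unit %in% .ABUNDANCE_UNITS)
        msg <- c(msg, sprintf("metadata(x)$unit must be one of: %s",
                              paste(.ABUNDANCE_UNITS, collapse = ", ")))
    tid <- rownames(object); sid <- colnames(object)
    if (is.null(tid) || anyDuplicated(tid))
        msg <- c(msg, "taxon identifiers must be present and unique")
    if (is.null(sid) || anyDuplicated(sid))
        msg <- c(msg, "sample identifiers must be present and unique")
    if (length(msg)) return(msg)
    v <- assay(object, "abundance")
    if (anyNA(v)) msg <- c(msg, "abundance values must not be missing")
    if (!identical(unit, "log_abundance") && !anyNA(v) && any(v < 0))
        msg <- c(msg, "abundance values must be non-negative")
    if (identical(unit, "relative_abundance") && ncol(v) && !anyNA(v)) {
        cs <- colSums(v)
        if (any(abs(cs - 1) > 1e-9))
            msg <- c(msg, sprintf(
                "relative abundances must sum to 1 per sample (worst: %s)",
                colnames(v)[which.max(abs(cs - 1))]))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix, taxa as rows and samples as columns, with
#'   row and column names.
#' @param unit abundance unit, one of \code{"counts"},
#'   \code{"relative_abundance"}, \code{"log_abundance"}.
#' @param lineage optional \code{data.frame}/\code{DataFrame} of rank-labelled
#'   lineage columns (e.g. \code{kingdom} ... \code{species}), one row per
#'   taxon; \code{NA} marks missing annotation at a rank.
#' @return A \linkS4class{FeatureTable}.
#' @examples
#' m <- matrix(c(2, 3, 5, 0), 2, dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' featureTable(m, unit = "counts")
#' @export
featureTable <- function(values, unit = c("counts", "relative_abundance",
                                          "log_abundance"), lineage = NULL) {
    unit <- match.arg(unit)
    values <- as.matrix(values)
    rd <- if (is.null(lineage)) NULL else DataFrame(lineage)
    se <- SummarizedExperiment(assays = list(abundance = values),
                               rowData = rd, metadata = list(unit = unit))
    new("FeatureTable", se)
}

#' @describeIn featureTable The abundance matrix (taxa x samples).
#' @param x a \code{FeatureTable}.
#' @export
abundance <- function(x) assay(x, "abundance")

#' @describeIn featureTable The declared abundance unit.
#' @export
abundanceUnit <- function(x) metadata(x)$unit

#' @describeIn featureTable Taxon identifiers.
#' @export
taxonIds <- function(x) rownames(x)

#' @describeIn featureTable Sample identifiers.
#' @export
sampleIds <- function(x) if (is(x, "SummarizedExperiment")) colnames(x) else
    rownames(x)

#' @describeIn featureTable Lineage annotation (DataFrame, possibly empty).
#' @export
lineage <- function(x) rowData(x)

setMethod("show", "FeatureTable", function(object) {
    cat(sprintf("FeatureTable: %d taxa x %d samples [unit: %s]\n",
                nrow(object), ncol(object), abundanceUnit(object)))
    if (ncol(rowData(object)))
        cat("lineage ranks:", paste(colnames(rowData(object)),
                                    collapse = ", "), "\n")
    callNextMethod()
})

#' Per-sample covariates with a derived underweight outcome
#'
#' A \code{SampleData} is a \code{DataFrame} keyed by unique sample
#' identifiers (rownames). It must carry a binary \code{exposure} column
#' (1 = case/exposed, 0 = control). If a \code{bmi} column is present, an
#' \code{underweight} column is derived as \code{bmi < 18.5} (strict
#' inequality, so BMI exactly 18.5 is not underweight) and is missing exactly
#' where \code{bmi} is missing. Per-column missing-value counts are kept in
#' \code{metadata(x)$missingCounts}.
#'
#' @seealso [sampleData()], [readSampleMetadata()].
#' @export
setClass("SampleData", contains = "DFrame")

setValidity("SampleData", function(object) {
    msg <- character()
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "sample identifiers (rownames) must be unique")
    if (!"exposure" %in% colnames(object)) {
        msg <- c(msg, "an 'exposure' column is required")
    } else {
        e <- object$exposure
        if (!all(e[!is.na(e)] %in% c(0, 1)))
            msg <- c(msg, "'exposure' must be binary 0/1")
    }
    if ("bmi" %in% colnames(object)) {
        if (!"underweight" %in% colnames(object)) {
            msg <- c(msg, "'underweight' must accompany 'bmi'")
        } else {
            b <- object$bmi; u <- object$underweight
            if (!identical(is.na(b), is.na(u)))
                msg <- c(msg, "'underweight' must be missing exactly when 'bmi' is")
            ok <- !is.na(b)
            if (any(u[ok] != as.integer(b[ok] < 18.5)))
                msg <- c(msg, "'underweight' must equal (bmi < 18.5)")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct SampleData from per-sample covariates
#'
#' @param df data.frame or DataFrame of covariates with sample identifiers as
#'   rownames (or in a \code{sample_id} column). Must contain a binary
#'   \code{exposure} column. If a \code{bmi} column is present the binary
#'   \code{underweight} outcome is (re)derived as \code{bmi < 18.5}.
#' @return A \linkS4class{SampleData}.
#' @examples
#' sampleData(data.frame(sample_id = c("a", "b"), exposure = c(1, 0),
#'                       bmi = c(18.4, NA), age = c(70, 65), sex = c(1, 0)))
#' @export
sampleData <- function(df) {
    df <- DataFrame(df, check.names = FALSE)
    if ("sample_id" %in% colnames(df)) {
        rownames(df) <- as.character(df$sample_id)
        df$sample_id <- NULL
    }
    if ("bmi" %in% colnames(df))
        df$underweight <- ifelse(is.na(df$bmi), NA_integer_,
                                 as.integer(df$bmi < 18.5))
    out <- new("SampleData", df)
    metadata(out)$missingCounts <- vapply(as.list(df), function(col)
        sum(is.na(col)), integer(1))
    validObject(out)
    out
}

setMethod("show", "SampleData", function(object) {
    cat(sprintf("SampleData: %d samples x %d covariates\n",
                nrow(object), ncol(object)))
    mc <- metadata(object)$missingCounts
    if (!is.null(mc) && any(mc > 0)) {
        mc <- mc[mc > 0]
        cat("missing:", paste(sprintf("%s=%d", names(mc), mc),
                              collapse = ", "), "\n")
    }
    callNextMethod()
})

#' Samples-by-mediators matrix on the analysis scale
#'
#' Holds the mediator matrix fed to the outcome models: one column per taxon
#' surviving the prevalence filter, values on the log relative-abundance
#' scale (natural log of relative abundance plus a pseudocount), or raw
#' relative abundance when so configured.
#'
#' @slot values numeric samples-by-mediators matrix, finite.
#' @slot pseudocount pseudocount added before the log (NA for raw scale).
#' @slot scale \code{"log_relative_abundance"} or \code{"relative_abundance"}.
#' @export
setClass("MediatorMatrix", slots = c(values = "matrix",
                                     pseudocount = "numeric",
                                     scale = "character"))

setValidity("MediatorMatrix", function(object) {
    msg <- character()
    v <- object@values
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "values must have sample rownames and mediator colnames")
    if (!all(is.finite(v)))
        msg <- c(msg, "mediator values must be finite")
    if (!object@scale %in% c("log_relative_abundance", "relative_abundance"))
        msg <- c(msg, "unknown mediator scale")
    if (length(msg)) msg else TRUE
})

#' @describeIn MediatorMatrix-class the samples-by-mediators matrix.
#' @param x a \code{MediatorMatrix}.
#' @export
mediatorValues <- function(x) x@values

#' @describeIn MediatorMatrix-class mediator (taxon) identifiers.
#' @export
mediatorIds <- function(x) colnames(x@values)

#' @describeIn MediatorMatrix-class the pseudocount used in the log transform.
#' @export
pseudocount <- function(x) x@pseudocount

setMethod("show", "MediatorMatrix", function(object) {
    cat(sprintf("MediatorMatrix: %d samples x %d mediators [%s, pseudocount %.3g]\n",
                nrow(object@values), ncol(object@values), object@scale,
                object@pseudocount))
})

#' Fitted regression model summary
#'
#' Container for any of the three mediation models: coefficient estimates,
#' standard errors, normal-reference 95 percent Wald confidence intervals and
#' p-values, the quasi-likelihood dispersion (Pearson chi-square over
#' residual degrees of freedom) for outcome models, and fit diagnostics.
#' For the ridge direct-effect model the penalty and the set of penalized
#' columns are recorded; penalized (mediator) coefficients are reported
#' without standard errors there.
#'
#' @slot model model label ("model1", "model2_single", "model2_all", "model3").
#' @slot coefficients DataFrame with columns term, estimate, se, ciLower,
#'   ciUpper, p.
#' @slot dispersion dispersion estimate (1 for ordinary least squares rows
#'   the residual variance is reported instead).
#' @slot nUsed number of samples entering the fit.
#' @slot converged logical.
#' @slot flags character vector of diagnostics ("separation", "collinear").
#' @slot penalty ridge penalty (NA when unpenalized).
#' @slot penalizedTerms names of penalized columns (model2_all only).
#' @export
setClass("ModelFit", slots = c(model = "character", coefficients = "DFrame",
                               dispersion = "numeric", nUsed = "integer",
                               converged = "logical", flags = "character",
                               penalty = "numeric", penalizedTerms = "character"))

setValidity("ModelFit", function(object) {
    cf <- object@coefficients
    need <- c("term", "estimate", "se", "ciLower", "ciUpper", "p")
    if (!all(need %in% colnames(cf)))
        return(sprintf("coefficients must have columns: %s",
                       paste(need, collapse = ", ")))
    ok <- !is.na(cf$ciLower) & !is.na(cf$ciUpper)
    if (any(cf$ciLower[ok] > cf$estimate[ok] | cf$estimate[ok] > cf$ciUpper[ok]))
        return("confidence intervals must bracket the estimates")
    if (!is.na(object@dispersion) && object@dispersion <= 0)
        return("dispersion must be positive")
    TRUE
})

#' @describeIn ModelFit-class coefficient table (DataFrame).
#' @param x a \code{ModelFit}.
#' @export
modelCoef <- function(x) x@coefficients

#' @describeIn ModelFit-class extract one coefficient row as a named list.
#' @param term coefficient name, e.g. \code{"exposure"}.
#' @export
coefRow <- function(x, term) {
    cf <- x@coefficients
    i <- match(term, cf$term)
    if (is.na(i)) stop("no coefficient named '", term, "'")
    as.list(cf[i, ])
}

#' @describeIn ModelFit-class fit diagnostics flags.
#' @export
modelFlags <- function(x) x@flags

setMethod("show", "ModelFit", function(object) {
    cat(sprintf("ModelFit [%s], n = %d, dispersion = %.4g%s\n",
                object@model, object@nUsed, object@dispersion,
                if (length(object@flags))
                    paste0(" [", paste(object@flags, collapse = ","), "]")
                else ""))
    print(as.data.frame(object@coefficients), digits = 4, row.names = FALSE)
})

#' Mediation analysis results
#'
#' A DataFrame with one row per mediator taxon (columns: mediator, te, de,
#' alpha, beta with their CIs and p-values, ie = te - de, pm = ie / te,
#' p = joint-significance mediation p, significant), sorted by mediation p.
#' Slots carry the shared total-effect fits, the all-mediator ridge row, the
#' working rank, the run parameters, and taxa skipped because their fits
#' failed.
#'
#' @slot teUnadjusted exposure-only total-effect row (list: estimate,
#'   ciLower, ciUpper, p).
#' @slot teAdjusted confounder-adjusted total effect shared by all rows.
#' @slot allRow all-mediator ridge row (list: de, ciLower, ciUpper, pm,
#'   penalty, flags).
#' @slot rank taxonomic rank analysed (NA if the table was used as-is).
#' @slot params run parameter fingerprint (named list).
#' @slot skipped named character vector of skipped taxa (reason per taxon).
#' @export
setClass("MediationResult", contains = "DFrame",
         slots = c(teUnadjusted = "list", teAdjusted = "list",
                   allRow = "list", rank = "character", params = "list",
                   skipped = "character"))

setValidity("MediationResult", function(object) {
    msg <- character()
    need <- c("mediator", "te", "de", "alpha", "beta", "ie", "pm", "p")
    if (!all(need %in% colnames(object)))
        msg <- c(msg, sprintf("missing columns: %s",
                              paste(setdiff(need, colnames(object)),
                                    collapse = ", ")))
    if (!length(msg) && nrow(object)) {
        if (max(abs(object$ie - (object$te - object$de)), na.rm = TRUE) > 1e-12)
            msg <- c(msg, "ie must equal te - de exactly")
        ok <- !is.na(object$pm)
        if (any(abs(object$pm[ok] * object$te[ok] -
                    (object$te[ok] - object$de[ok])) > 1e-10))
            msg <- c(msg, "pm * te must equal te - de")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "MediationResult", function(object) {
    cat(sprintf("MediationResult: %d mediators at rank '%s'\n",
                nrow(object), object@rank))
    cat(sprintf("  total effect (adjusted): %.4f (%.4f, %.4f)\n",
                object@teAdjusted$estimate, object@teAdjusted$ciLower,
                object@teAdjusted$ciUpper))
    if (length(object@allRow))
        cat(sprintf("  all mediators: DE = %.4f, PM = %.2f%% (penalty %.3g)\n",
                    object@allRow$de, 100 * object@allRow$pm,
                    object@allRow$penalty))
    if (length(object@skipped))
        cat(sprintf("  skipped %d taxa\n", length(object@skipped)))
    callNextMethod()
})
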