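## Reading and writing the tabular and tree artifacts, and sample alignment.

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
            "species")
.MISSING_MARKERS <- c("", "na", "missing")

.isMissingMarker <- function(x) is.na(x) | tolower(trimws(x)) %in%
    .MISSING_MARKERS

#' Read a taxon-by-sample feature table from TSV
#'
#' Expects a tab-delimited UTF-8 file with a header row, taxa as rows and
#' samples as columns; the first column holds taxon identifiers and columns
#' named after taxonomic ranks (kingdom ... species, any case) are treated as
#' lineage annotation. \code{transpose = TRUE} accepts the transposed
#' orientation (samples as rows).
#'
#' @param path file path.
#' @param unit declared abundance unit of the values.
#' @param transpose set to TRUE when the file has samples as rows.
#' @return A \linkS4class{FeatureTable}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("taxon_id\ts1\ts2", "t1\t2\t5", "t2\t3\t0"), tf)
#' readFeatureTable(tf, unit = "counts")
#' @export
readFeatureTable <- function(path, unit = c("counts", "relative_abundance",
                                            "log_abundance"),
                             transpose = FALSE) {
    unit <- match.arg(unit)
    ## read.delim de-duplicates header names; check them from the raw line
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    if (anyDuplicated(header[-1L]))
        stop("duplicate ", if (transpose) "taxon" else "sample",
             " identifier(s): ",
             paste(unique(header[-1L][duplicated(header[-1L])]),
                   collapse = ", "))
    raw <- utils::read.delim(path, check.names = FALSE,
                             colClasses = "character", na.strings = NULL)
    if (ncol(raw) < 2L) stop("feature table needs an id column plus data")
    ids <- trimws(raw[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate ", if (transpose) "sample" else "taxon",
             " identifier(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    body <- raw[-1L]
    lin <- NULL
    rankCols <- tolower(colnames(body)) %in% .RANKS
    if (!transpose && any(rankCols)) {
        lin <- body[rankCols]
        colnames(lin) <- tolower(colnames(lin))
        lin[] <- lapply(lin, function(col) {
            col <- trimws(col)
            col[.isMissingMarker(col)] <- NA_character_
            col
        })
        body <- body[!rankCols]
    }
    if (anyDuplicated(colnames(body)))
        stop("duplicate ", if (transpose) "taxon" else "sample",
             " identifier(s): ",
             paste(unique(colnames(body)[duplicated(colnames(body))]),
                   collapse = ", "))
    vals <- suppressWarnings(
        vapply(body, function(col) as.numeric(col), numeric(nrow(body))))
    vals <- matrix(vals, nrow = nrow(body),
                   dimnames = list(ids, colnames(body)))
    bad <- which(is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-numeric value(s) in feature table at ",
             paste(sprintf("[row %s, column %s]", rownames(vals)[bad[, 1L]],
                           colnames(vals)[bad[, 2L]])[seq_len(min(5L, nrow(bad)))],
                   collapse = ", "))
    if (transpose) vals <- t(vals)
    if (unit != "log_abundance" && any(vals < 0))
        stop("negative abundance values are not allowed for unit '", unit, "'")
    if (!is.null(lin)) rownames(lin) <- rownames(vals)
    featureTable(vals, unit = unit, lineage = lin)
}

#' Write a FeatureTable to TSV
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
    df <- data.frame(taxon_id = taxonIds(x), check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(lineage(x)))
        df <- cbind(df, as.data.frame(lineage(x)))
    df <- cbind(df, as.data.frame(abundance(x), check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Read per-sample metadata from TSV
#'
#' One row per sample; the first column (or a column named \code{sample_id})
#' holds sample identifiers. Empty cells, \code{NA} and \code{Missing}
#' (case-insensitive) are read as missing. Columns whose non-missing entries
#' all parse as numbers become numeric. An \code{exposure} column (binary
#' 0/1) is required; if a \code{bmi} column is present the underweight
#' outcome is derived as \code{bmi < 18.5}.
#'
#' @param path file path.
#' @return A \linkS4class{SampleData}; per-column missing counts are in
#'   \code{metadata(x)$missingCounts}.
#' @export
readSampleMetadata <- function(path) {
    raw <- utils::read.delim(path, check.names = FALSE,
                             colClasses = "character", na.strings = NULL)
    if (!ncol(raw)) stop("empty metadata file")
    idCol <- if ("sample_id" %in% colnames(raw)) "sample_id" else
        colnames(raw)[1L]
    ids <- trimws(raw[[idCol]])
    if (anyDuplicated(ids))
        stop("duplicate sample identifier(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    body <- raw[colnames(raw) != idCol]
    if (!"exposure" %in% colnames(body))
        stop("metadata must contain an 'exposure' column")
    parsed <- lapply(body, function(col) {
        col <- trimws(col)
        col[.isMissingMarker(col)] <- NA_character_
        num <- suppressWarnings(as.numeric(col))
        if (all(is.na(num) == is.na(col))) num else col
    })
    df <- DataFrame(parsed, check.names = FALSE)
    rownames(df) <- ids
    sampleData(df)
}

#' Write SampleData to TSV
#'
#' @param x a \linkS4class{SampleData}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSampleMetadata <- function(x, path) {
    df <- cbind(data.frame(sample_id = rownames(x)),
                as.data.frame(x))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

#' Align a feature table and sample metadata on shared samples
#'
#' Restricts both objects to the intersection of their sample identifiers
#' (exact string match), in the feature table's order, and reports discarded
#' identifiers.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param meta a \linkS4class{SampleData}.
#' @return A list with elements \code{table} and \code{meta}, plus
#'   \code{droppedTable}/\code{droppedMeta} identifier vectors.
#' @export
alignSamples <- function(table, meta) {
    shared <- intersect(sampleIds(table), rownames(meta))
    if (!length(shared))
        stop("no shared sample identifiers between table and metadata")
    dropT <- setdiff(sampleIds(table), shared)
    dropM <- setdiff(rownames(meta), shared)
    if (length(dropT))
        message("alignSamples: dropping ", length(dropT),
                " table sample(s): ", paste(dropT, collapse = ", "))
    if (length(dropM))
        message("alignSamples: dropping ", length(dropM),
                " metadata sample(s): ", paste(dropM, collapse = ", "))
    list(table = table[, shared], meta = meta[shared, , drop = FALSE],
         droppedTable = dropT, droppedMeta = dropM)
}

#' Read a rooted phylogenetic tree from Newick
#'
#' Parses with \pkg{ape} and validates that tip labels are unique and branch
#' lengths are present and non-negative. An unparseable file raises an error
#' reporting the character offset of the first structural problem.
#'
#' @param path Newick file path.
#' @return An \pkg{ape} \code{phylo} object.
#' @export
readTree <- function(path) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
    depth <- 0L
    for (i in seq_len(nchar(txt))) {
        ch <- substr(txt, i, i)
        if (ch == "(") depth <- depth + 1L
        if (ch == ")") depth <- depth - 1L
        if (depth < 0L)
            stop("unparseable Newick: unbalanced ')' at character offset ", i)
    }
    if (depth != 0L)
        stop("unparseable Newick: ", depth,
             " unclosed '(' at character offset ", nchar(txt))
    tree <- tryCatch(ape::read.tree(text = txt), error = function(e)
        stop("unparseable Newick at character offset <= ", nchar(txt), ": ",
             conditionMessage(e)))
    if (is.null(tree)) stop("unparseable Newick: no tree found")
    if (anyDuplicated(tree$tip.label))
        stop("duplicate tip label(s): ",
             paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                   collapse = ", "))
    if (is.null(tree$edge.length))
        stop("tree has no branch lengths")
    if (any(tree$edge.length < 0))
        stop("negative branch length(s) in tree")
    tree
}

#' Report tree tips not matching table taxa (and vice versa)
#'
#' Extra tips are retained by downstream UniFrac computations but flagged
#' here; table taxa absent from the tree make UniFrac impossible and are
#' reported too.
#'
#' @param tree an \pkg{ape} \code{phylo}.
#' @param taxa character vector of taxon identifiers (or a
#'   \linkS4class{FeatureTable}).
#' @return list with \code{extraTips} (tips without a matching taxon) and
#'   \code{missingTaxa} (taxa without a tip).
#' @export
matchTreeTaxa <- function(tree, taxa) {
    if (is(taxa, "FeatureTable")) taxa <- taxonIds(taxa)
    list(extraTips = setdiff(tree$tip.label, taxa),
         missingTaxa = setdiff(taxa, tree$tip.label))
}
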