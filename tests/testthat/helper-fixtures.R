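suppressPackageStartupMessages({
    library(S4Vectors)
})

## tiny deterministic feature table: taxa x samples
tinyTable <- function(values = matrix(c(2, 3, 5, 0), 2, 2,
                                      dimnames = list(c("t1", "t2"),
                                                      c("s1", "s2"))),
                      unit = "counts", lineage = NULL) {
    featureTable(values, unit = unit, lineage = lineage)
}

tinyMeta <- function(ids = c("s1", "s2"), exposure = c(1, 0),
                     bmi = c(17.0, 25.0), age = c(70, 65), sex = c(1, 0)) {
    sampleData(DataFrame(row.names = ids, exposure = exposure, bmi = bmi,
                         age = age, sex = sex))
}

## metadata reproducing the printed underweight-by-disease cohort:
## 9/183/7-missing among 199 exposed, 2/125/4-missing among 131 controls
printedCohortMeta <- function() {
    bmi <- c(rep(17, 9), rep(25, 183), rep(NA, 7),
             rep(17, 2), rep(25, 125), rep(NA, 4))
    expo <- rep(c(1, 0), c(199, 131))
    sampleData(DataFrame(row.names = sprintf("p%03d", seq_along(bmi)),
                         exposure = expo, bmi = bmi))
}

## random relative-abundance matrix (samples as columns sum to 1)
randomRATable <- function(nTaxa, nSamples, seed) {
    set.seed(seed)
    v <- matrix(rexp(nTaxa * nSamples), nTaxa, nSamples,
                dimnames = list(sprintf("t%02d", seq_len(nTaxa)),
                                sprintf("s%02d", seq_len(nSamples))))
    featureTable(sweep(v, 2, colSums(v), "/"), unit = "relative_abundance")
}

writeTempTSV <- function(lines) {
    f <- tempfile(fileext = ".tsv")
    writeLines(lines, f)
    f
}

## independent brute-force PERMANOVA pseudo-F (same decomposition, written
## from scratch against the distance-sum formula)
bruteForceF <- function(dmat, lab) {
    n <- nrow(dmat)
    lab <- factor(lab)
    d2 <- dmat^2
    sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (lev in levels(lab)) {
        i <- which(lab == lev)
        ssw <- ssw + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
    }
    ((sst - ssw) / (nlevels(lab) - 1)) / (ssw / (n - nlevels(lab)))
}

## exact PERMANOVA p by enumerating every distinct label arrangement
exactPermanovaP <- function(dmat, lab) {
    n <- length(lab)
    idx1 <- which(lab == lab[1])
    k <- length(idx1)
    combs <- utils::combn(n, k)
    fObs <- bruteForceF(dmat, lab)
    fAll <- apply(combs, 2, function(ii) {
        l <- rep(0, n); l[ii] <- 1
        bruteForceF(dmat, l)
    })
    mean(fAll >= fObs - 1e-12)
}
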