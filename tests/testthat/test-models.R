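test_that("Model 1 equals the closed-form log odds ratio when saturated", {
    md <- printedCohortMeta()
    fit <- fitModel1(md, confounders = character(0))
    expect_equal(coefRow(fit, "exposure")$estimate,
                 log((9 * 125) / (2 * 183)), tolerance = 1e-6)
    expect_s4_class(fit, "ModelFit")
    expect_gt(fit@dispersion, 0)
    cf <- coefRow(fit, "exposure")
    expect_lte(cf$ciLower, cf$estimate)
    expect_gte(cf$ciUpper, cf$estimate)
})

test_that("Model 1 estimates vanish under the null and cover the truth", {
    set.seed(41)
    n <- 5000
    md <- sampleData(DataFrame(
        row.names = sprintf("s%04d", 1:n),
        exposure = rbinom(n, 1, 0.5),
        bmi = ifelse(rbinom(n, 1, 0.2) == 1, 17, 25),
        age = rnorm(n, 69, 9), sex = rbinom(n, 1, 0.5)))
    fit <- fitModel1(md)
    expect_lt(abs(coefRow(fit, "exposure")$estimate), 0.15)
    ## Wald CI coverage at planted log-odds 1.5, n = 2000
    cover <- logical(200)
    for (r in seq_along(cover)) {
        ex <- rbinom(2000, 1, 0.5)
        y <- rbinom(2000, 1, plogis(-2 + 1.5 * ex))
        mdr <- sampleData(DataFrame(row.names = sprintf("r%04d", 1:2000),
                                    exposure = ex,
                                    bmi = ifelse(y == 1, 17, 25)))
        cf <- coefRow(fitModel1(mdr, confounders = character(0)),
                      "exposure")
        cover[r] <- cf$ciLower <= 1.5 && 1.5 <= cf$ciUpper
    }
    expect_gte(mean(cover), 0.90)
    expect_lte(mean(cover), 0.99)
})

test_that("Model 3 recovers exposure-to-mediator effects", {
    md <- tinyMeta(ids = paste0("s", 1:4), exposure = c(1, 0, 1, 0),
                   bmi = c(17, 25, 25, 25), age = c(70, 65, 68, 72),
                   sex = c(1, 0, 0, 1))
    ## mediator exactly equal to exposure: alpha 1 with zero residual
    M <- matrix(c(1, 0, 1, 0), 4, 1,
                dimnames = list(paste0("s", 1:4), "copy"))
    a <- fitModel3(M, md, confounders = character(0))
    expect_equal(a$estimate, 1)
    expect_equal(a$residualSD, 0)
    ## constant mediator is an error naming the taxon
    Mc <- matrix(1, 4, 1, dimnames = list(paste0("s", 1:4), "flatTaxon"))
    expect_error(fitModel3(Mc, md), "flatTaxon")
    ## sampling oracle: alpha = -2, n = 330, noise SD 1
    set.seed(42)
    est <- numeric(200)
    for (r in seq_along(est)) {
        ex <- rep(c(1, 0), c(199, 131))
        mdr <- sampleData(DataFrame(row.names = sprintf("s%03d", 1:330),
                                    exposure = ex, bmi = 25,
                                    age = rnorm(330, 69, 9),
                                    sex = rbinom(330, 1, 0.5)))
        Mr <- matrix(-2 * ex + rnorm(330), 330, 1,
                     dimnames = list(rownames(mdr), "m"))
        est[r] <- fitModel3(Mr, mdr)$estimate
    }
    expect_lt(abs(mean(est) + 2), 0.15)
})

test_that("Model 3 alpha-path test holds its level under permutation", {
    set.seed(43)
    rej <- logical(500)
    for (r in seq_along(rej)) {
        ex <- sample(rep(c(1, 0), c(199, 131)))  # permuted exposure
        mdr <- sampleData(DataFrame(row.names = sprintf("s%03d", 1:330),
                                    exposure = ex, bmi = 25,
                                    age = rnorm(330, 69, 9),
                                    sex = rbinom(330, 1, 0.5)))
        Mr <- matrix(rnorm(330, 0, 2), 330, 1,
                     dimnames = list(rownames(mdr), "m"))
        rej[r] <- fitModel3(Mr, mdr)$p < 0.05
    }
    expect_gte(mean(rej), 0.02)
    expect_lte(mean(rej), 0.08)
})

test_that("Model 2 single: null mediators leave the direct effect at TE", {
    set.seed(44)
    n <- 4000
    ex <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, plogis(-1.5 + 1 * ex))
    md <- sampleData(DataFrame(row.names = sprintf("s%04d", 1:n),
                               exposure = ex, bmi = ifelse(y == 1, 17, 25),
                               age = rnorm(n, 69, 9),
                               sex = rbinom(n, 1, 0.5)))
    m <- setNames(rnorm(n), rownames(md))
    te <- coefRow(fitModel1(md), "exposure")$estimate
    f2 <- fitModel2Single(m, md)
    expect_lt(abs(coefRow(f2, "exposure")$estimate - te), 0.05)
    ## a mediator that copies the exposure is flagged collinear
    f2c <- fitModel2Single(setNames(as.numeric(ex), rownames(md)), md)
    expect_true("collinear" %in% modelFlags(f2c))
})

test_that("Model 2 single recovers path signs in a rare-outcome cohort", {
    ## single-mediator cohort: alpha = -2, beta = -0.2, direct 1.4
    set.seed(45)
    ok <- logical(200)
    for (r in seq_along(ok)) {
        ex <- rep(c(1, 0), c(199, 131))
        m <- -2 * ex + rnorm(330, 0, 3)
        y <- rbinom(330, 1, plogis(-4.4 + 1.4 * ex - 0.2 * m))
        if (all(y == 0) || all(y == 1)) next
        mdr <- sampleData(DataFrame(row.names = sprintf("s%03d", 1:330),
                                    exposure = ex,
                                    bmi = ifelse(y == 1, 17, 25),
                                    age = rnorm(330, 69, 9),
                                    sex = rbinom(330, 1, 0.5)))
        names(m) <- rownames(mdr)
        f2 <- fitModel2Single(m, mdr)
        a3 <- fitModel3(matrix(m, 330, 1,
                               dimnames = list(rownames(mdr), "m")), mdr)
        ok[r] <- coefRow(f2, "exposure")$estimate > 0 &&
            coefRow(f2, "mediator")$estimate < 0 && a3$estimate < 0
    }
    expect_gte(mean(ok), 0.9)
})

test_that("ridge model 2: infinite penalty recovers the total effect", {
    set.seed(46)
    n <- 330
    ex <- rep(c(1, 0), c(199, 131))
    M <- matrix(rnorm(n * 8, -5, 2), n, 8,
                dimnames = list(sprintf("s%03d", 1:n), paste0("m", 1:8)))
    y <- rbinom(n, 1, plogis(-2 + ex + 0.2 * M[, 1]))
    md <- sampleData(DataFrame(row.names = rownames(M), exposure = ex,
                               bmi = ifelse(y == 1, 17, 25),
                               age = rnorm(n, 69, 9),
                               sex = rbinom(n, 1, 0.5)))
    mm <- new("MediatorMatrix", values = M, pseudocount = 1e-6,
              scale = "log_relative_abundance")
    fInf <- fitModel2All(mm, md, penalty = 1e9)
    cf <- modelCoef(fInf)
    expect_lt(max(abs(cf$estimate[cf$term %in% colnames(M)])), 1e-6)
    te <- coefRow(fitModel1(md), "exposure")$estimate
    expect_lt(abs(coefRow(fInf, "exposure")$estimate - te), 1e-6)
    expect_identical(fInf@penalizedTerms, colnames(M))
    expect_identical(fInf@penalty, 1e9)
})

test_that("ridge model 2 at penalty zero equals the unpenalized GLM", {
    set.seed(47)
    n <- 330
    ex <- rep(c(1, 0), c(199, 131))
    M <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(sprintf("s%03d", 1:n), paste0("m", 1:6)))
    age <- rnorm(n, 69, 9); sex <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, plogis(-1.5 + ex + 0.3 * M[, 1]))
    md <- sampleData(DataFrame(row.names = rownames(M), exposure = ex,
                               bmi = ifelse(y == 1, 17, 25),
                               age = age, sex = sex))
    mm <- new("MediatorMatrix", values = M, pseudocount = 1e-6,
              scale = "log_relative_abundance")
    f0 <- fitModel2All(mm, md, penalty = 0)
    g <- stats::glm(y ~ ., family = stats::quasibinomial(),
                    data = data.frame(y = y, exposure = ex, M,
                                      age = age, sex = sex),
                    control = stats::glm.control(epsilon = 1e-12))
    cf <- modelCoef(f0)
    est <- setNames(cf$estimate, cf$term)
    cg <- stats::coef(g)
    shared <- intersect(names(est), names(cg))
    expect_length(shared, length(cg))
    expect_lt(max(abs(est[shared] - cg[shared])), 1e-6)
    ## unpenalized-term standard errors match the GLM's closely
    seMine <- setNames(cf$se, cf$term)
    sg <- summary(g)$coefficients
    for (term in c("exposure", "age", "sex"))
        expect_equal(seMine[[term]], sg[term, "Std. Error"],
                     tolerance = 1e-3)
})

test_that("cross-validated penalty selection is seeded and stratified", {
    set.seed(48)
    n <- 200
    ex <- rbinom(n, 1, 0.5)
    M <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(sprintf("s%03d", 1:n), paste0("m", 1:10)))
    y <- rbinom(n, 1, plogis(-1 + ex + 0.5 * M[, 1]))
    md <- sampleData(DataFrame(row.names = rownames(M), exposure = ex,
                               bmi = ifelse(y == 1, 17, 25),
                               age = rnorm(n, 69, 9),
                               sex = rbinom(n, 1, 0.5)))
    mm <- new("MediatorMatrix", values = M, pseudocount = 1e-6,
              scale = "log_relative_abundance")
    fa <- fitModel2All(mm, md, penalty = "cv", seed = 7)
    fb <- fitModel2All(mm, md, penalty = "cv", seed = 7)
    expect_identical(fa@penalty, fb@penalty)
    expect_equal(modelCoef(fa)$estimate, modelCoef(fb)$estimate)
    expect_error(fitModel2All(mm, md, penalty = "cv"), "seed")
    ## a single-class outcome cannot be stratified
    mdBad <- sampleData(DataFrame(row.names = rownames(M), exposure = ex,
                                  bmi = c(17, rep(25, n - 1)),
                                  age = rnorm(n, 69, 9),
                                  sex = rbinom(n, 1, 0.5)))
    expect_error(fitModel2All(mm, mdBad, penalty = "cv", seed = 7),
                 "stratif")
})
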