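## The three mediation models.
##
## Model 1: quasi-binomial logistic outcome ~ exposure + confounders
##          (exposure coefficient = total effect TE).
## Model 2: outcome ~ exposure + mediator(s) + confounders
##          (exposure coefficient = direct effect DE, mediator coefficient =
##          beta path); with all mediators at once the mediator block is
##          ridge-penalized while exposure and confounders stay unpenalized.
## Model 3: linear mediator ~ exposure + confounders
##          (exposure coefficient = alpha path).
##
## Wald intervals use the 1.96 normal multiplier and two-sided normal
## p-values throughout; outcome-model dispersion is Pearson chi-square over
## residual degrees of freedom.

.CI_Z <- 1.96

.waldFit <- function(model, est, se, n, dispersion, flags = character(),
                     penalty = NA_real_, penalized = character(),
                     converged = TRUE) {
    seFull <- se[match(names(est), names(se))]
    cf <- DataFrame(term = names(est), estimate = unname(est),
                    se = unname(seFull),
                    ciLower = unname(est - .CI_Z * seFull),
                    ciUpper = unname(est + .CI_Z * seFull),
                    p = unname(2 * stats::pnorm(-abs(est / seFull))))
    new("ModelFit", model = model, coefficients = cf,
        dispersion = dispersion, nUsed = as.integer(n),
        converged = converged, flags = flags, penalty = penalty,
        penalizedTerms = penalized)
}

.outcomeFrame <- function(meta, confounders, outcome = "underweight") {
    need <- c(outcome, "exposure", confounders)
    miss <- setdiff(need, colnames(meta))
    if (length(miss))
        stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
    df <- as.data.frame(meta[, need, drop = FALSE])
    names(df)[1L] <- ".y"
    df[stats::complete.cases(df), , drop = FALSE]
}

.quasiLogit <- function(df, model) {
    fit <- suppressWarnings(stats::glm(
        .y ~ ., data = df, family = stats::quasibinomial(),
        control = stats::glm.control(maxit = 100)))
    if (!fit$converged)
        stop(model, " did not converge after ", fit$iter, " IRLS iterations")
    sm <- summary(fit)$coefficients
    est <- stats::coef(fit)
    se <- rep(NA_real_, length(est)); names(se) <- names(est)
    se[rownames(sm)] <- sm[, "Std. Error"]
    disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
    .waldFit(model, est, se, nrow(df), disp, flags = .separationFlags(fit))
}

#' Fit Model 1: the total-effect outcome model
#'
#' Quasi-binomial logistic regression of the underweight outcome on exposure
#' and confounders, on complete cases. The exposure coefficient is the total
#' effect (TE); with no confounders and a saturated binary design it equals
#' the sample log odds ratio.
#'
#' @param meta a \linkS4class{SampleData} with \code{underweight} and
#'   \code{exposure} columns.
#' @param confounders confounder column names (default age and sex; use
#'   \code{character(0)} for the unadjusted model).
#' @return A \linkS4class{ModelFit}.
#' @export
fitModel1 <- function(meta, confounders = c("age", "sex")) {
    df <- .outcomeFrame(meta, confounders)
    if (!nrow(df)) stop("no complete cases")
    .quasiLogit(df, "model1")
}

#' Fit Model 2 with a single mediator
#'
#' Quasi-binomial logistic regression of the outcome on exposure, one
#' mediator and confounders. The exposure coefficient is the direct effect
#' (DE) with respect to this mediator; the mediator coefficient is the beta
#' path. A mediator collinear with the design (e.g. a copy of the exposure)
#' is flagged \code{"collinear"}.
#'
#' @param mediator numeric vector named by sample id (or a one-column
#'   \linkS4class{MediatorMatrix}).
#' @param meta a \linkS4class{SampleData}.
#' @param confounders confounder column names.
#' @param mediatorName label used for the mediator term.
#' @return A \linkS4class{ModelFit} with terms \code{exposure} and
#'   \code{mediator}.
#' @export
fitModel2Single <- function(mediator, meta, confounders = c("age", "sex"),
                            mediatorName = "mediator") {
    if (is(mediator, "MediatorMatrix")) {
        stopifnot(ncol(mediatorValues(mediator)) == 1L)
        mediator <- mediatorValues(mediator)[, 1L]
    }
    if (!is.null(names(mediator)))
        mediator <- mediator[rownames(meta)]
    stopifnot(length(mediator) == nrow(meta))
    df <- .outcomeFrame(cbind(meta, DataFrame(mediator = mediator)),
                        c("mediator", confounders))
    ## put exposure before the mediator in the design
    df <- df[, c(".y", "exposure", "mediator", confounders), drop = FALSE]
    fit <- .quasiLogit(df, "model2_single")
    cf <- fit@coefficients
    cf$term[cf$term == "mediator"] <- mediatorName
    fit@coefficients <- cf
    fit
}

#' Fit Model 3: exposure effect on each mediator
#'
#' Ordinary least squares of every mediator column on exposure and
#' confounders. The exposure coefficient is the alpha path; its Wald CI and
#' p-value use the residual-variance standard error.
#'
#' @param mediators a \linkS4class{MediatorMatrix} (or samples-by-mediators
#'   matrix with sample rownames).
#' @param meta a \linkS4class{SampleData} aligned to the mediator rows.
#' @param confounders confounder column names.
#' @return A \code{DataFrame} with one row per mediator: \code{mediator},
#'   \code{estimate}, \code{se}, \code{ciLower}, \code{ciUpper}, \code{p},
#'   \code{residualSD}; \code{metadata(.)$nUsed} gives the sample count.
#' @export
fitModel3 <- function(mediators, meta, confounders = c("age", "sex")) {
    Y <- if (is(mediators, "MediatorMatrix")) mediatorValues(mediators)
         else as.matrix(mediators)
    shared <- intersect(rownames(Y), rownames(meta))
    if (!length(shared)) stop("no shared samples")
    need <- c("exposure", confounders)
    df <- as.data.frame(meta[shared, need, drop = FALSE])
    cc <- stats::complete.cases(df)
    df <- df[cc, , drop = FALSE]
    Y <- Y[shared, , drop = FALSE][cc, , drop = FALSE]
    sds <- apply(Y, 2L, stats::sd)
    if (any(sds == 0))
        stop("constant mediator column(s): ",
             paste(colnames(Y)[sds == 0], collapse = ", "))
    X <- stats::model.matrix(~ ., data = df)
    n <- nrow(X); p <- ncol(X)
    if (n <= p) stop("too few complete cases for the design")
    XtXinv <- chol2inv(chol(crossprod(X)))
    B <- XtXinv %*% crossprod(X, Y)
    res <- Y - X %*% B
    sigma2 <- colSums(res^2) / (n - p)
    j <- match("exposure", colnames(X))
    est <- B[j, ]
    se <- sqrt(XtXinv[j, j] * sigma2)
    out <- DataFrame(mediator = colnames(Y), estimate = unname(est),
                     se = unname(se),
                     ciLower = unname(est - .CI_Z * se),
                     ciUpper = unname(est + .CI_Z * se),
                     p = unname(2 * stats::pnorm(-abs(est / se))),
                     residualSD = unname(sqrt(sigma2)))
    metadata(out)$nUsed <- n
    metadata(out)$model <- "model3"
    out
}

## ---- ridge-penalized quasi-binomial IRLS (mediator-only penalty) ----

## Minimises -loglik(beta) + (lambda/2) * sum(beta[penIdx]^2) by iteratively
## reweighted least squares. X must include the intercept column.
.ridgeIRLS <- function(X, y, penIdx, lambda, start = NULL, maxit = 200,
                       tol = 1e-10) {
    n <- nrow(X); p <- ncol(X)
    D <- numeric(p); D[penIdx] <- lambda
    beta <- if (is.null(start)) {
        b0 <- numeric(p)
        b0[1L] <- stats::qlogis((sum(y) + 0.5) / (n + 1))
        b0
    } else start
    ## penalized objective: binomial deviance + lambda * sum(beta_pen^2)
    obj <- function(b) {
        mu <- stats::plogis(drop(X %*% b))
        .binomDeviance(y, mu) + lambda * sum(b[penIdx]^2)
    }
    objOld <- obj(beta)
    converged <- FALSE
    for (it in seq_len(maxit)) {
        eta <- drop(X %*% beta)
        mu <- stats::plogis(eta)
        w <- pmax(mu * (1 - mu), 1e-10)
        z <- eta + (y - mu) / w
        A <- crossprod(X, w * X)
        betaNew <- drop(solve(A + diag(D, p), crossprod(X, w * z)))
        ## step-halving keeps the penalized deviance monotone near
        ## separation, where plain IRLS can overshoot and cycle
        objNew <- obj(betaNew)
        half <- 0L
        while (objNew > objOld + 1e-8 && half < 25L) {
            betaNew <- (beta + betaNew) / 2
            objNew <- obj(betaNew)
            half <- half + 1L
        }
        done <- max(abs(betaNew - beta)) < tol ||
            abs(objOld - objNew) < 1e-11 * (abs(objOld) + 0.1)
        beta <- betaNew
        objOld <- objNew
        if (done) { converged <- TRUE; break }
    }
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    list(beta = beta, mu = mu, converged = converged, iterations = it,
         deviance = .binomDeviance(y, mu))
}

.binomDeviance <- function(y, mu) {
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

## Stratified fold assignment; every training set keeps both outcome classes.
.stratifiedFolds <- function(y, k) {
    if (min(table(y)) < 2L)
        stop("cannot build stratified CV folds: an outcome class has fewer ",
             "than 2 members")
    fold <- integer(length(y))
    for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
}

#' Fit Model 2 with all mediators via a mediator-only ridge penalty
#'
#' Quasi-binomial logistic regression of the outcome on exposure, the full
#' mediator matrix and confounders, fitted by iteratively reweighted least
#' squares with a ridge penalty applied to the mediator coefficients only;
#' the exposure and confounder coefficients are unpenalized so the exposure
#' coefficient remains an unshrunken direct effect (DE). Mediator columns
#' are standardized internally before penalization. The penalty is chosen by
#' stratified K-fold cross-validation minimising mean held-out binomial
#' deviance (seeded), or set explicitly.
#'
#' @param mediators a \linkS4class{MediatorMatrix} (samples x mediators).
#' @param meta a \linkS4class{SampleData}.
#' @param confounders confounder column names.
#' @param penalty \code{"cv"} or a non-negative number (0 reproduces the
#'   unpenalized quasi-binomial fit).
#' @param folds number of CV folds.
#' @param seed integer seed for the CV fold assignment (required when
#'   \code{penalty = "cv"}).
#' @param lambdaGrid candidate penalties for CV (default
#'   \code{10^seq(-2, 4, length.out = 15)}).
#' @return A \linkS4class{ModelFit}; penalized (mediator) coefficients are
#'   reported without standard errors, unpenalized terms with
#'   sandwich-form standard errors scaled by the Pearson dispersion on
#'   \code{n - edf} degrees of freedom.
#' @export
fitModel2All <- function(mediators, meta, confounders = c("age", "sex"),
                         penalty = "cv", folds = 10, seed = NULL,
                         lambdaGrid = NULL) {
    M <- if (is(mediators, "MediatorMatrix")) mediatorValues(mediators)
         else as.matrix(mediators)
    shared <- intersect(rownames(M), rownames(meta))
    df <- .outcomeFrame(meta[shared, , drop = FALSE], confounders)
    ids <- rownames(df)
    M <- M[ids, , drop = FALSE]
    sds <- apply(M, 2L, stats::sd)
    if (any(sds == 0))
        stop("constant mediator column(s): ",
             paste(colnames(M)[sds == 0], collapse = ", "))
    Ms <- scale(M)
    Xu <- stats::model.matrix(~ ., data = df[, c("exposure", confounders),
                                             drop = FALSE])
    X <- cbind(Xu, Ms)
    y <- df$.y
    penIdx <- ncol(Xu) + seq_len(ncol(Ms))
    if (identical(penalty, "cv")) {
        if (is.null(seed))
            stop("a seed is required for cross-validated penalty selection")
        if (is.null(lambdaGrid))
            lambdaGrid <- 10^seq(-2, 4, length.out = 15)
        lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)
        set.seed(seed)
        fold <- .stratifiedFolds(y, folds)
        cvDev <- matrix(NA_real_, length(lambdaGrid), folds)
        for (f in seq_len(folds)) {
            tr <- fold != f
            if (length(unique(y[tr])) < 2L)
                stop("training fold with a single outcome class")
            start <- NULL
            for (li in seq_along(lambdaGrid)) {
                fit <- .ridgeIRLS(X[tr, , drop = FALSE], y[tr], penIdx,
                                  lambdaGrid[li], start = start)
                start <- fit$beta
                muTest <- stats::plogis(drop(X[!tr, , drop = FALSE] %*%
                                             fit$beta))
                cvDev[li, f] <- .binomDeviance(y[!tr], muTest) / sum(!tr)
            }
        }
        lambda <- lambdaGrid[which.min(rowMeans(cvDev))]
    } else {
        if (!is.numeric(penalty) || length(penalty) != 1L || penalty < 0)
            stop("penalty must be 'cv' or a non-negative number")
        lambda <- penalty
    }
    fit <- .ridgeIRLS(X, y, penIdx, lambda)
    if (!fit$converged)
        stop("model2_all did not converge after ", fit$iterations,
             " IRLS iterations")
    w <- pmax(fit$mu * (1 - fit$mu), 1e-10)
    A <- crossprod(X, w * X)
    D <- numeric(ncol(X)); D[penIdx] <- lambda
    Minv <- solve(A + diag(D, ncol(X)))
    edf <- sum(diag(Minv %*% A))
    pearson <- sum((y - fit$mu)^2 / w)
    disp <- pearson / max(nrow(X) - edf, 1)
    covB <- disp * Minv %*% A %*% Minv
    ## back-transform mediator coefficients to the original scale; the
    ## intercept absorbs the centering shift
    est <- fit$beta
    se <- sqrt(diag(covB))
    sc <- attr(Ms, "scaled:scale")
    ctr <- attr(Ms, "scaled:center")
    est[1L] <- est[1L] - sum(fit$beta[penIdx] * ctr / sc)
    est[penIdx] <- est[penIdx] / sc
    se[penIdx] <- NA_real_  # shrunken coefficients: no Wald inference
    names(est) <- names(se) <- colnames(X)
    flags <- character()
    if (abs(est[["exposure"]]) > 15 ||
        any(fit$mu < 1e-8 | fit$mu > 1 - 1e-8))
        flags <- "separation"
    .waldFit("model2_all", est, se, nrow(X), disp, flags = flags,
             penalty = lambda, penalized = colnames(M),
             converged = fit$converged)
}
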