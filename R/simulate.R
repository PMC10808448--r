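## Synthetic case-control microbiome cohorts with planted mediation
## structure: logistic-normal multinomial counts, age/sex confounding of
## exposure, taxa and outcome, and a rare binary outcome driven by the log
## relative abundance of designated mediator taxa.

#' Build a simulation configuration
#'
#' Defaults emulate a two-group cohort of 199 exposed and 131 control
#' samples with a rare outcome (target prevalence 11/319), five mediator
#' taxa among 80 whose latent log abundance is shifted by exposure
#' (alpha = -2) and which in turn shift the outcome log-odds
#' (beta = -0.15 per log unit), a direct exposure effect c' = 1, strong
#' co-variation among mediators (a shared latent factor), and age/sex
#' confounding of exposure, taxa and outcome.
#'
#' @param nExposed,nControl group sizes.
#' @param nTaxa number of taxa (one feature per genus).
#' @param nMediators number of mediator taxa (the first \code{nMediators}
#'   taxa).
#' @param alpha exposure effect on mediator latent log abundance (scalar or
#'   per-mediator vector).
#' @param beta mediator log-relative-abundance effect on the outcome
#'   log-odds (scalar or per-mediator).
#' @param cPrime direct exposure effect on the outcome log-odds.
#' @param targetPrevalence marginal outcome prevalence the intercept is
#'   calibrated to.
#' @param ageMean,ageSD length-2 vectors (exposed, control).
#' @param pMale probability of male sex per group (exposed, control).
#' @param outcomeAge,outcomeFemale confounder effects on the outcome
#'   log-odds (per year of age, and for female sex).
#' @param taxonAge,taxonFemale confounder effects on taxon latent log
#'   abundance (per 10 years, applied to even-indexed taxa; female-sex
#'   shift, applied to every third taxon and all mediators).
#' @param mediatorSharedSD,mediatorUniqueSD mediator latent noise split into
#'   a shared factor loading and a unique component.
#' @param taxonSD latent noise SD of non-mediator taxa.
#' @param baseSpread SD of the baseline log-abundance profile across taxa.
#' @param mediatorMedianRA target median relative abundance of each mediator
#'   in controls.
#' @param depthMeanLog,depthSdLog,minDepth log-normal sequencing depth.
#' @param missingBmi length-2 vector: samples per group (exposed, control)
#'   whose BMI is set missing.
#' @param outcomeScale \code{"log_relative"} (outcome depends on log
#'   relative abundance, the analysis scale) or \code{"absolute"} (latent
#'   absolute log abundance, for misspecification studies).
#' @param speciesNAFrac fraction of non-mediator taxa left unannotated at
#'   species rank.
#' @param maxRedraws outcome redraw attempts before giving up when an
#'   outcome class is empty.
#' @param seed default seed used by [simulateCohort()]/[generateTruth()].
#' @return A list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nExposed = 199, nControl = 131, nTaxa = 80,
                             nMediators = 5, alpha = -2, beta = -0.15,
                             cPrime = 1.0, targetPrevalence = 11 / 319,
                             ageMean = c(68.4, 70.4), ageSD = c(9.14, 8.6),
                             pMale = c(0.668, 0.397), outcomeAge = 0.03,
                             outcomeFemale = 1.2, taxonAge = 0.3,
                             taxonFemale = 0.5, mediatorSharedSD = 1.8,
                             mediatorUniqueSD = 0.87, taxonSD = 1.5,
                             baseSpread = 1.5, mediatorMedianRA = 8e-4,
                             depthMeanLog = log(2e4), depthSdLog = 0.4,
                             minDepth = 1000,
                             missingBmi = c(7, 4),
                             outcomeScale = c("log_relative", "absolute"),
                             speciesNAFrac = 0.4, maxRedraws = 100,
                             seed = 1) {
    cfg <- list(nExposed = nExposed, nControl = nControl, nTaxa = nTaxa,
                nMediators = nMediators,
                alpha = rep_len(alpha, nMediators),
                beta = rep_len(beta, nMediators), cPrime = cPrime,
                targetPrevalence = targetPrevalence, ageMean = ageMean,
                ageSD = ageSD, pMale = pMale, outcomeAge = outcomeAge,
                outcomeFemale = outcomeFemale, taxonAge = taxonAge,
                taxonFemale = taxonFemale,
                mediatorSharedSD = mediatorSharedSD,
                mediatorUniqueSD = mediatorUniqueSD, taxonSD = taxonSD,
                baseSpread = baseSpread,
                mediatorMedianRA = mediatorMedianRA,
                depthMeanLog = depthMeanLog, depthSdLog = depthSdLog,
                minDepth = minDepth, missingBmi = missingBmi,
                outcomeScale = match.arg(outcomeScale),
                speciesNAFrac = speciesNAFrac, maxRedraws = maxRedraws,
                seed = seed)
    stopifnot(nExposed >= 2, nControl >= 2, nTaxa >= 2,
              nMediators >= 0, nMediators <= nTaxa,
              targetPrevalence > 0, targetPrevalence < 1,
              all(pMale > 0 & pMale < 1), minDepth >= 1,
              mediatorMedianRA > 0, mediatorMedianRA < 1,
              speciesNAFrac >= 0, speciesNAFrac <= 1,
              all(missingBmi >= 0),
              missingBmi[1] < nExposed, missingBmi[2] < nControl)
    class(cfg) <- "SimulationConfig"
    cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat(sprintf(
        "SimulationConfig: %d exposed + %d control, %d taxa (%d mediators)\n",
        x$nExposed, x$nControl, x$nTaxa, x$nMediators))
    cat(sprintf("  alpha = %s; beta = %s; c' = %g; target prevalence %.4f\n",
                paste(x$alpha, collapse = ","),
                paste(x$beta, collapse = ","), x$cPrime,
                x$targetPrevalence))
    invisible(x)
}

## baseline latent profile; mediators placed at the configured median
## relative abundance
.baseProfile <- function(cfg) {
    base <- stats::qnorm(stats::ppoints(cfg$nTaxa), 0, cfg$baseSpread)
    med <- seq_len(cfg$nMediators)
    if (cfg$nMediators) {
        lse <- log(sum(exp(base[-med] + cfg$taxonSD^2 / 2)))
        base[med] <- lse + log(cfg$mediatorMedianRA)
    }
    base
}

## draw a latent population of nE exposed + nC control samples; consumes RNG
.simPopulation <- function(cfg, nE, nC) {
    n <- nE + nC
    exposure <- rep(c(1L, 0L), c(nE, nC))
    grp <- 2L - exposure  # 1 = exposed, 2 = control
    sex <- stats::rbinom(n, 1L, cfg$pMale[grp])  # 1 = male
    age <- stats::rnorm(n, cfg$ageMean[grp], cfg$ageSD[grp])
    med <- seq_len(cfg$nMediators)
    base <- .baseProfile(cfg)
    ageCoef <- ifelse(seq_len(cfg$nTaxa) %% 2L == 0L, cfg$taxonAge, 0)
    sexCoef <- ifelse(seq_len(cfg$nTaxa) %% 3L == 0L, cfg$taxonFemale, 0)
    sexCoef[med] <- cfg$taxonFemale
    lat <- matrix(rep(base, each = n), n, cfg$nTaxa)
    if (cfg$nMediators) {
        shared <- stats::rnorm(n)
        lat[, med] <- lat[, med] +
            rep(cfg$alpha, each = n) * exposure +
            cfg$mediatorSharedSD * shared +
            matrix(stats::rnorm(n * cfg$nMediators, 0,
                                cfg$mediatorUniqueSD), n)
    }
    oth <- setdiff(seq_len(cfg$nTaxa), med)
    lat[, oth] <- lat[, oth] +
        matrix(stats::rnorm(n * length(oth), 0, cfg$taxonSD), n)
    lat <- lat + outer((age - 69) / 10, ageCoef) + outer(1 - sex, sexCoef)
    P <- exp(lat - apply(lat, 1L, max))
    P <- P / rowSums(P)
    logRA <- log(P)
    medSignal <- if (cfg$nMediators) {
        scale <- if (cfg$outcomeScale == "log_relative") logRA[, med,
                                                              drop = FALSE]
                 else lat[, med, drop = FALSE]
        drop(scale %*% cfg$beta)
    } else 0
    lp0 <- cfg$cPrime * exposure + medSignal +
        cfg$outcomeAge * (age - 69) + cfg$outcomeFemale * (1 - sex)
    list(exposure = exposure, sex = sex, age = age, P = P, logRA = logRA,
         lp0 = lp0)
}

## Intercept calibration on a fixed reference population drawn with an
## internal constant seed, so the intercept is a deterministic function of
## the configuration (not of the cohort seed); memoized per configuration.
## The caller's RNG state is saved and restored.
.simCache <- new.env(parent = emptyenv())

.calibrateIntercept <- function(cfg, nCal = 20000L) {
    key <- paste(deparse(unclass(cfg)), collapse = "")
    if (!is.null(.simCache[[key]])) return(.simCache[[key]])
    hadSeed <- exists(".Random.seed", globalenv(), inherits = FALSE)
    if (hadSeed) oldSeed <- get(".Random.seed", globalenv())
    on.exit(if (hadSeed) assign(".Random.seed", oldSeed, globalenv()))
    set.seed(190417L)
    frac <- cfg$nExposed / (cfg$nExposed + cfg$nControl)
    nE <- round(nCal * frac)
    pop <- .simPopulation(cfg, nE, nCal - nE)
    intercept <- stats::uniroot(function(b)
        mean(stats::plogis(b + pop$lp0)) - cfg$targetPrevalence,
        c(-50, 20))$root
    .simCache[[key]] <- intercept
    intercept
}

.taxonNames <- function(cfg) {
    ids <- sprintf("asv_%03d", seq_len(cfg$nTaxa))
    genus <- sprintf("Genus_%03d", seq_len(cfg$nTaxa))
    phyla <- c("Firmicutes", "Bacteroidota", "Proteobacteria",
               "Actinobacteriota")
    species <- sprintf("%s_sp", genus)
    ## a deterministic subset of non-mediators lacks species annotation
    naEvery <- if (cfg$speciesNAFrac > 0) max(1L,
        round(1 / cfg$speciesNAFrac)) else Inf
    isNA <- seq_len(cfg$nTaxa) %% naEvery == 0
    isNA[seq_len(cfg$nMediators)] <- FALSE
    species[isNA] <- NA_character_
    list(ids = ids,
         lineage = data.frame(
             kingdom = "Bacteria",
             phylum = phyla[(seq_len(cfg$nTaxa) - 1L) %% length(phyla) + 1L],
             genus = genus, species = species, row.names = ids))
}

#' Generate a synthetic case-control cohort
#'
#' Draws confounders, mediator and background taxa on a latent log scale,
#' forms compositions by softmax, samples multinomial counts at log-normal
#' depths, and draws the rare binary outcome from a logistic model with the
#' planted direct and mediator effects; the intercept is calibrated to the
#' target prevalence on a seeded reference population, so cohort and
#' Monte-Carlo truth share it. BMI is back-filled consistently with the
#' outcome (below/above 18.5) and a configured number of samples per arm
#' have BMI set missing.
#'
#' @param config a \code{SimulationConfig}.
#' @param seed integer seed (defaults to \code{config$seed}); the same seed
#'   reproduces the cohort byte-for-byte.
#' @return A list: \code{table} (\linkS4class{FeatureTable} of counts with
#'   genus/species lineage), \code{meta} (\linkS4class{SampleData}), and
#'   \code{truth} (planted parameters: per-taxon alpha/beta, cPrime,
#'   mediator identities, intercept, seed).
#' @export
simulateCohort <- function(config, seed = config$seed) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(seed)
    intercept <- .calibrateIntercept(config)
    pop <- .simPopulation(config, config$nExposed, config$nControl)
    n <- length(pop$exposure)
    pr <- stats::plogis(intercept + pop$lp0)
    y <- stats::rbinom(n, 1L, pr)
    tries <- 0L
    while ((all(y == 0L) || all(y == 1L)) && tries < config$maxRedraws) {
        y <- stats::rbinom(n, 1L, pr)
        tries <- tries + 1L
    }
    if (all(y == 0L) || all(y == 1L))
        stop("no variation in the outcome after ", config$maxRedraws,
             " redraws; adjust targetPrevalence (intercept ",
             sprintf("%.2f", intercept), ")")
    depth <- pmax(config$minDepth,
                  round(stats::rlnorm(n, config$depthMeanLog,
                                      config$depthSdLog)))
    counts <- vapply(seq_len(n), function(i)
        stats::rmultinom(1L, depth[i], pop$P[i, ])[, 1L],
        integer(config$nTaxa))
    nm <- .taxonNames(config)
    rownames(counts) <- nm$ids
    sampleIdsVec <- sprintf("S%03d", seq_len(n))
    colnames(counts) <- sampleIdsVec
    bmi <- numeric(n)
    bmi[y == 1L] <- stats::runif(sum(y == 1L), 15.5, 18.4)
    bmi[y == 0L] <- 18.5 + stats::rexp(sum(y == 0L), rate = 1 / 8)
    missIdx <- c(sample(which(pop$exposure == 1L), config$missingBmi[1]),
                 sample(which(pop$exposure == 0L), config$missingBmi[2]))
    bmi[missIdx] <- NA_real_
    meta <- sampleData(DataFrame(
        row.names = sampleIdsVec, exposure = pop$exposure, bmi = bmi,
        age = pop$age, sex = pop$sex))
    alphaAll <- betaAll <- numeric(config$nTaxa)
    med <- seq_len(config$nMediators)
    alphaAll[med] <- config$alpha
    betaAll[med] <- config$beta
    names(alphaAll) <- names(betaAll) <- nm$lineage$genus
    truth <- structure(list(
        mediators = nm$lineage$genus[med], mediatorTaxa = nm$ids[med],
        alpha = alphaAll, beta = betaAll, cPrime = config$cPrime,
        intercept = intercept, outcomePrevalence = mean(y),
        redraws = tries, seed = seed), class = "SyntheticTruth")
    list(table = featureTable(counts, unit = "counts",
                              lineage = nm$lineage),
         meta = meta, truth = truth)
}

#' Monte-Carlo ground truth for a simulation configuration
#'
#' Computes the "true" marginal total and direct effects by simulating a
#' large latent population with the same calibrated intercept as
#' [simulateCohort()] and fitting the population-level logistic contrasts
#' with and without the mediators: TE from outcome ~ exposure + age + sex,
#' DE from the model additionally containing the mediators' latent log
#' relative abundances. True PM = (TE - DE) / TE. The product-form indirect
#' effect sum(alpha * beta) / (cPrime + sum(alpha * beta)) is reported for
#' comparison (it ignores non-collapsibility).
#'
#' @param config a \code{SimulationConfig}.
#' @param nMC Monte-Carlo population size (at least 1e5 recommended).
#' @param seed integer seed (defaults to \code{config$seed}, which makes the
#'   calibration draw identical to the cohort's).
#' @return A list of class \code{"SyntheticTruth"} with \code{teMC},
#'   \code{deMC}, \code{pmMC}, \code{pmProduct}, the planted parameters and
#'   the seed.
#' @export
generateTruth <- function(config, nMC = 1e5, seed = config$seed) {
    stopifnot(inherits(config, "SimulationConfig"), nMC >= 1000)
    set.seed(seed)
    intercept <- .calibrateIntercept(config)
    frac <- config$nExposed / (config$nExposed + config$nControl)
    nE <- round(nMC * frac)
    pop <- .simPopulation(config, nE, nMC - nE)
    y <- stats::rbinom(nMC, 1L, stats::plogis(intercept + pop$lp0))
    med <- seq_len(config$nMediators)
    m1 <- stats::glm.fit(cbind(1, pop$exposure, pop$age, pop$sex), y,
                         family = stats::binomial())
    teMC <- m1$coefficients[2L]
    deMC <- if (config$nMediators) {
        m2 <- stats::glm.fit(cbind(1, pop$exposure,
                                   pop$logRA[, med, drop = FALSE],
                                   pop$age, pop$sex), y,
                             family = stats::binomial())
        m2$coefficients[2L]
    } else teMC
    ieProd <- sum(config$alpha * config$beta)
    structure(list(
        teMC = unname(teMC), deMC = unname(deMC),
        pmMC = unname((teMC - deMC) / teMC),
        pmProduct = ieProd / (config$cPrime + ieProd),
        alpha = config$alpha, beta = config$beta, cPrime = config$cPrime,
        intercept = intercept, nMC = nMC, seed = seed),
        class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
    cat("SyntheticTruth (seed", x$seed, ")\n")
    if (!is.null(x$teMC))
        cat(sprintf("  MC: TE = %.4f, DE = %.4f, PM = %.4f (product-form %.4f)\n",
                    x$teMC, x$deMC, x$pmMC, x$pmProduct))
    if (!is.null(x$mediators))
        cat("  mediators:", paste(x$mediators, collapse = ", "), "\n")
    invisible(x)
}
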