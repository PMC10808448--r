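---
title: "Microbiome mediation of disease effects on a rare binary outcome: models and design"
author: "mbMediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbiome mediation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the estimator

Case-control microbiome studies of Parkinson's disease report both an
excess of underweight patients (body-mass index below 18.5 kg/m²) and broad
shifts in gut-microbial composition. `mbMediate` quantifies how much of the
disease–underweight association travels *through* the microbiome: the
disease is the binary exposure, underweight the binary outcome, and the
per-taxon abundances are a high-dimensional set of candidate mediators,
with age and sex as confounders of every arrow in the diagram
(exposure → mediators → outcome, plus a direct exposure → outcome arrow).

Three regression models are fitted on one common complete-case sample set:

* **Model 1** (total effect): quasi-binomial logistic regression of the
  outcome on exposure and confounders. The exposure coefficient is the
  total effect **TE** on the log-odds scale.
* **Model 2** (direct effect): the same outcome model with mediator(s)
  added. The exposure coefficient is the direct effect **DE**; each
  mediator's coefficient is its **β path**. With all taxa entered at once
  the mediator block is ridge-penalized (see below); per-taxon rows use an
  ordinary quasi-binomial fit with that single mediator.
* **Model 3** (exposure → mediator): ordinary least squares of each
  mediator on exposure and confounders. The exposure coefficient is the
  **α path**.

The indirect (mediation) effect is the difference of coefficients
IE = TE − DE, and the proportion mediated is PM = IE / TE, reported as a
percent. Per-taxon mediation p-values use the **joint-significance (max-p)
test**: p = max(p(α), p(β)), which declares mediation only when both paths
are individually significant and is conservative under the composite null.

Quasi-binomial families are used for all outcome models: the binomial
variance is scaled by a free dispersion φ estimated as Pearson χ² over
residual degrees of freedom, so standard errors do not assume exact
binomial variation. All intervals are Wald intervals with the 1.96 normal
multiplier and two-sided normal p-values; with several hundred samples the
normal and t references are practically indistinguishable, and the normal
convention keeps hand-reconstruction of p-values from published intervals
straightforward.

## Ridge with a mediator-only penalty

With m taxa and n samples of comparable size — and an outcome with only a
handful of events — the all-mediator Model 2 is not estimable by ordinary
maximum likelihood. The package fits it by iteratively reweighted least
squares with an L2 penalty **applied to the mediator coefficients only**:
exposure, confounders and the intercept are never penalized, because DE
must remain an unshrunken exposure coefficient for the difference TE − DE
to be interpretable. Mediator columns are standardized internally (the
intercept absorbs the centering; coefficients are reported on the original
scale). The penalty λ is chosen by stratified K-fold cross-validation
(default 10 folds) minimizing mean held-out binomial deviance on a
descending λ path with warm starts; stratification by outcome class is
forced because a rare outcome otherwise yields folds without cases. The
fold assignment is drawn from a mandatory seed, making λ reproducible.

Two numerical safeguards matter near separation (few events, many
columns): IRLS steps are halved whenever the penalized deviance would
increase, and weights are floored at 1e-10. At λ = 0 the fit reproduces
`stats::glm(family = quasibinomial())` to machine precision (this is a
test); as λ → ∞ the mediator coefficients vanish and DE → TE.

Standard errors for the unpenalized terms come from the sandwich form
φ·(XᵀWX + λD)⁻¹ XᵀWX (XᵀWX + λD)⁻¹ with φ computed on n − edf degrees of
freedom, edf = tr((XᵀWX + λD)⁻¹XᵀWX). Penalized coefficients are reported
without standard errors: shrunken estimates do not carry valid Wald
inference, and no conclusion in the workflow depends on them.

## Known behaviour of the difference-of-coefficients estimator

Logistic-regression coefficients are non-collapsible: adding covariates
changes the exposure coefficient even without confounding, so TE − DE is
not a pure mediation measure in general. For a *rare* outcome (a few
percent prevalence, as here) the distortion is small and the
difference-of-coefficients PM tracks the product-of-coefficients
(α·β-based) PM; the test suite checks agreement within 20% relative error
in that regime using Monte-Carlo ground truth, and this agreement should
not be expected for common outcomes.

Two small-sample phenomena are flagged rather than hidden:

* **Separation.** With ~11 events, a substantial minority of resampled
  cohorts put zero cases in one exposure arm; the exposure coefficient then
  diverges. Model fits carry a `"separation"` flag (non-convergence,
  |coefficient| > 15, or fitted probabilities at the boundary), and any
  ratio built from flagged coefficients should be discarded — the test
  suite does exactly that where it averages PM across replicates.
* **CV overfit at the null.** When no mediation exists, cross-validation
  occasionally picks a small λ, and conditioning on noise mediators
  slightly inflates DE (non-collapsibility again), giving the ALL-row PM a
  small negative bias in separated or overfitted replicates. Across
  estimable replicates the ALL-row PM is centred on zero (tested).

# The preprocessing contract

* Counts are normalized to **relative abundance** per sample (columns sum
  to one; an all-zero sample is an error).
* Analyses run at a chosen taxonomic rank; abundances are summed over
  taxa sharing the lineage value at that rank, and taxa unannotated at the
  rank are dropped (their count is logged). Species-rank analyses
  therefore operate on the annotated subset, which 16S data keeps small.
* The **prevalence filter** keeps taxa detected in strictly more than a
  fraction (default 10%) of samples — a taxon present in 34 of 330 samples
  stays, one present in 33 goes.
* The mediator matrix is the **natural log of relative abundance plus a
  pseudocount**, default half the smallest nonzero relative abundance in
  the filtered table. The log scale is an assumption, not a fact about the
  data: published per-taxon exposure effects of magnitude ≈ 2 are
  implausible on the raw relative-abundance scale (bounded by 1) and
  natural on the log scale. The raw scale remains available
  (`mediatorScale = "relative"`) for sensitivity analyses.
* Samples missing the outcome (BMI, hence underweight) are excluded from
  all three models, so the TE printed in every row of the mediation table
  is computed on the identical sample set. The underweight indicator is
  strictly `bmi < 18.5`: a BMI of exactly 18.5 is not underweight.

# Diversity analyses

Alpha diversity is computed on raw (unrarefied) counts — Observed richness,
bias-corrected Chao1 (S_obs + F1(F1−1)/(2(F2+1))), Shannon (natural log)
and Simpson (1 − Σp²) — with a one-way ANOVA group test per metric.
Rarefaction is deliberately not applied; with group tests based on ranks
and ANOVA across samples of broadly similar depth the correction matters
little, and the choice is recorded here.

Beta diversity offers the Canberra distance (coordinate-wise
|x−y|/(x+y), skipping 0/0 terms *without* rescaling — note that base R's
`dist()` rescales by n/NZ when terms are skipped, so the two agree only
when no coordinate is doubly zero) and unweighted/weighted UniFrac
(computed through `phyloseq`; the weighted variant is normalized to [0, 1]).
Group differences are tested by PERMANOVA: the pseudo-F from the standard
distance decomposition, with p = (1 + #{permuted F ≥ observed F}) /
(nPerm + 1) under seeded label permutations (default 999). The
implementation is intentionally in-package so the permutation stream is
controlled by the pipeline seed; `vegan::adonis2` serves as an independent
cross-check in the tests.

# The synthetic cohort generator

No real sequencing data ships with the package; all statistical claims are
validated on synthetic cohorts with known ground truth. The generator
emulates the study design the estimator targets and its defaults *are* the
study conditions:

* **Cohort shape:** 199 exposed and 131 control samples; target outcome
  prevalence 11/319 ≈ 3.4%; 7 exposed and 4 control samples have BMI set
  missing (and hence a missing outcome).
* **Confounding:** age ~ N(68.4, 9.14²) in the exposed and N(70.4, 8.6²)
  in controls; male sex with probability 0.668 vs 0.397. Both feed the
  outcome (log-odds +0.03/year, +1.2 for female sex) and the taxa
  (deterministic subsets of taxa shift with age and with sex), confounding
  every arrow of the mediation diagram.
* **Composition:** each sample's taxon abundances arise as a softmax of
  latent Gaussian log-abundances (logistic-normal), then multinomial
  counts at log-normal depths (median 2×10⁴). This reproduces the closure
  constraint the analysis operates under: shifting mediator taxa
  necessarily shifts everyone else's relative abundance. Mediator taxa are
  kept rare enough (median relative abundance 8×10⁻⁴ each in controls)
  that this closure bias on null taxa stays well below their standard
  errors, yet abundant enough that the count-detection floor rarely
  censors them.
* **Planted mediation:** 5 mediator taxa among 80, each with exposure
  effect α = −2 on latent log abundance and outcome effect β = −0.15 per
  log-relative-abundance unit, plus a direct exposure effect c′ = 1. Half
  of the mediators' latent variance is a shared factor (loading 1.8 of a
  total SD 2.0): short-chain-fatty-acid-producing genera co-occur
  ecologically, and co-varying mediators are what make per-taxon
  proportions mediated overlap (their sum exceeding the all-taxa PM), a
  pattern reported in this literature. Effect sizes were calibrated so
  that the *estimated* quantities match published mediation tables from
  PD-underweight cohorts: a recovered total effect near 1.8 log-odds and a
  β-path z-statistic near 3, after accounting for multinomial sampling and
  pseudocount-floor attenuation. The outcome depends on log *relative*
  abundance — the analysis scale — by default; a switch to absolute latent
  abundance exists to study misspecification.
* **Calibration and determinism:** the logistic intercept is solved by
  root-finding so the marginal outcome prevalence hits the target, on a
  reference population of 20,000 drawn with a fixed internal seed — the
  intercept is a deterministic function of the configuration and is shared
  by cohort generation and ground-truth computation. Given a seed, a
  cohort is reproducible byte-for-byte. The outcome vector is redrawn (up
  to 100 times) only if a whole outcome class is empty.

**Ground truth** (`generateTruth()`) is computed by Monte-Carlo
marginalization: a large population (default 10⁵) is simulated from the
same process, and population-level logistic contrasts with and without the
mediators' latent log relative abundances give TE, DE and hence the "true"
marginal PM — the estimand the difference-of-coefficients procedure
targets, inclusive of non-collapsibility. The product form
Σαβ/(c′ + Σαβ) is reported alongside for comparison.

What the generator does *not* emulate: taxonomic mis-assignment,
zero-inflation beyond what the logistic-normal-multinomial induces, batch
or sequencing-run effects, unmeasured confounding, and longitudinal
structure. Passing the recovery tests therefore demonstrates correctness
of the estimator under its assumed data-generating process, not robustness
to everything real 16S data can do.

# Validation settings and problem sizes

The test suite and the acceptance script size their simulations to run on
a single CPU in minutes while keeping Monte-Carlo error far from the
asserted bounds:

* α-path CI coverage and planted-mediator detection power: 200 cohorts at
  the full default configuration (n = 330, 80 taxa).
* Type-I control: 200 cohorts with all α = β = 0 and c′ = 1.8; the
  per-taxon joint-significance flag rate at 0.05 is compared against 0.08.
* ALL-row PM recovery: 200 (100 in the acceptance script) cohorts with 5
  mediators among 10 taxa, α = −2, β = −0.2, c′ = 1, outcome prevalence
  0.15 — the prevalence is raised for this one check because a ratio of
  coefficients from ~11 events is dominated by separation noise, which is
  a property of the sample size, not of the estimator under test.
* Ridge attenuation (DE < TE): 200 cohorts with 5 true mediators among 50
  taxa at the same raised prevalence.
* PERMANOVA and Wilcoxon are checked against exhaustive enumeration at
  n ≤ 8, where enumeration is feasible.

# Limitations

* The estimator inherits every assumption of the three parametric models;
  exposure–mediator interactions and counterfactual (natural-effects)
  decompositions are out of scope.
* The max-p mediation test is conservative, particularly when both paths
  are weak.
* The ALL-row DE depends on the selected penalty; it is reproducible given
  the seed, but there is no unique "correct" λ, and the overall PM should
  be read as penalty-conditional.
* Bootstrap or otherwise calibrated intervals for PM are not provided; PM
  is reported as a point ratio with its components' intervals.
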