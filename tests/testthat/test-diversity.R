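test_that("alpha diversity matches hand-computed closed forms", {
    ## singletons F1 = 2, doubletons F2 = 1: Chao1 = 4 + 2*1/(2*2) = 4.5
    m <- matrix(c(1, 1, 2, 5), 4, 1,
                dimnames = list(paste0("t", 1:4), "s1"))
    a <- alphaDiversity(featureTable(m, unit = "counts"))
    expect_identical(a$observed, 4L)
    expect_equal(a$chao1, 4.5)
    ## symmetric two-taxon sample: Shannon ln 2, Simpson 1/2
    m2 <- matrix(c(5, 5), 2, 1, dimnames = list(c("t1", "t2"), "s1"))
    a2 <- alphaDiversity(featureTable(m2, unit = "counts"))
    expect_equal(a2$shannon, log(2))
    expect_equal(a2$simpson, 0.5)
    ## single taxon: no evenness
    m3 <- matrix(c(9, 0), 2, 1, dimnames = list(c("t1", "t2"), "s1"))
    a3 <- alphaDiversity(featureTable(m3, unit = "counts"))
    expect_equal(a3$shannon, 0)
    expect_equal(a3$simpson, 0)
    ## Chao1 falls back to Observed when there are no singletons
    m4 <- matrix(c(3, 4, 2), 3, 1, dimnames = list(paste0("t", 1:3), "s1"))
    a4 <- alphaDiversity(featureTable(m4, unit = "counts"))
    expect_equal(a4$chao1, a4$observed)
    expect_error(alphaDiversity(featureTable(m / 2, unit = "counts")),
                 "integer")
})

test_that("alpha metric invariants hold on random tables, with ANOVA", {
    set.seed(21)
    v <- matrix(rpois(20 * 12, 3), 20, 12,
                dimnames = list(sprintf("t%02d", 1:20),
                                sprintf("s%02d", 1:12)))
    v[, 1] <- 0; v[1, 1] <- 10  # keep every sample non-empty
    grp <- rep(c(0, 1), each = 6)
    a <- alphaDiversity(featureTable(v, unit = "counts"), groups = grp)
    expect_true(all(a$chao1 >= a$observed))
    expect_true(all(a$simpson >= 0 & a$simpson <= 1))
    expect_true(all(a$shannon >= 0))
    pv <- metadata(a)$anovaP
    expect_named(pv, c("observed", "chao1", "shannon", "simpson"))
    expect_true(all(pv >= 0 & pv <= 1))
})

test_that("Canberra distance follows the coordinate-wise definition", {
    m <- rbind(s1 = c(1, 0), s2 = c(0, 1))
    expect_equal(as.numeric(canberraDistance(m)), 2)
    m2 <- rbind(s1 = c(0.4, 0.6), s2 = c(0.6, 0.4))
    expect_equal(as.numeric(canberraDistance(m2)), 0.4)
    m3 <- rbind(s1 = c(0.4, 0.6), s2 = c(0.4, 0.6))
    expect_equal(as.numeric(canberraDistance(m3)), 0)
    ## 0/0 coordinates are skipped without rescaling
    m4 <- rbind(s1 = c(1, 0, 0), s2 = c(0, 1, 0))
    expect_equal(as.numeric(canberraDistance(m4)), 2)
    ## oracle: base dist() agrees when no coordinate is doubly zero
    set.seed(22)
    m5 <- matrix(rexp(4 * 6) + 0.01, 4, 6,
                 dimnames = list(paste0("s", 1:4), NULL))
    expect_equal(as.matrix(canberraDistance(m5)),
                 as.matrix(dist(m5, method = "canberra")))
})

test_that("distance outputs are symmetric with a zero diagonal", {
    ra <- randomRATable(15, 8, seed = 23)
    d <- as.matrix(canberraDistance(ra))
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 8))
    expect_true(all(d >= 0))
})

test_that("UniFrac matches tree-based expectations", {
    tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
    ## disjoint subtrees share no branches: unweighted distance 1
    v <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2,
                dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
    ft <- featureTable(v, unit = "counts")
    expect_equal(as.numeric(uniFrac(ft, tr, weighted = FALSE)), 1)
    ## identical presence sets: unweighted 0 (and invariant to rescaling)
    v2 <- matrix(c(2, 1, 1, 0, 20, 10, 10, 0), 4, 2,
                 dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
    ft2 <- featureTable(v2, unit = "counts")
    expect_equal(as.numeric(uniFrac(ft2, tr, weighted = FALSE)), 0)
    ## identical abundance vectors: weighted 0
    v3 <- matrix(c(2, 1, 1, 0, 4, 2, 2, 0), 4, 2,
                 dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
    ft3 <- featureTable(v3, unit = "counts")
    expect_equal(as.numeric(uniFrac(ft3, tr, weighted = TRUE)), 0)
    ## unweighted depends on presence only: rescaling one sample changes
    ## nothing even with partial overlap
    v4 <- matrix(c(1, 1, 1, 0, 0, 3, 5, 2), 4, 2,
                 dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
    ft4 <- featureTable(v4, unit = "counts")
    v5 <- v4; v5[, 2] <- v5[, 2] * 10
    ft5 <- featureTable(v5, unit = "counts")
    expect_equal(as.numeric(uniFrac(ft4, tr, weighted = FALSE)),
                 as.numeric(uniFrac(ft5, tr, weighted = FALSE)))
    ## taxa missing from the tree are an error listing them
    v6 <- matrix(1, 2, 2, dimnames = list(c("A", "X"), c("s1", "s2")))
    expect_error(uniFrac(featureTable(v6, unit = "counts"), tr), "X")
})

test_that("PERMANOVA separates clusters and matches the exact test", {
    ## two tight, well-separated 4+4 clusters
    set.seed(24)
    pts <- rbind(matrix(rnorm(8, 0, 0.05), 4),
                 matrix(rnorm(8, 5, 0.05), 4))
    rownames(pts) <- paste0("s", 1:8)
    d <- dist(pts)
    grp <- rep(c(0, 1), each = 4)
    pv <- permanova(d, grp, nPerm = 999, seed = 1)
    expect_lte(pv$p.value, 0.05)
    expect_gte(pv$p.value, 1 / 1000)
    ## pseudo-F agrees with an independent implementation and with vegan
    expect_equal(pv$statistic, bruteForceF(as.matrix(d), grp))
    ad <- vegan::adonis2(d ~ factor(grp), permutations = 99)
    expect_equal(pv$statistic, ad$F[1], tolerance = 1e-10)
    ## invariance to group relabeling
    pv2 <- permanova(d, c("b", "b", "b", "b", "a", "a", "a", "a"),
                     nPerm = 999, seed = 1)
    expect_equal(pv2$statistic, pv$statistic)
    expect_equal(pv2$p.value, pv$p.value)
    ## sampled p matches the exhaustive enumeration within sampling error
    set.seed(25)
    pts6 <- matrix(rnorm(12), 6)
    rownames(pts6) <- paste0("s", 1:6)
    d6 <- dist(pts6)
    g6 <- rep(c(0, 1), each = 3)
    pExact <- exactPermanovaP(as.matrix(d6), g6)
    pSamp <- permanova(d6, g6, nPerm = 4999, seed = 2)$p.value
    expect_lt(abs(pSamp - pExact), 0.03)
    expect_error(permanova(d6, rep(1, 6), nPerm = 99, seed = 1),
                 "two groups")
})

test_that("PERMANOVA p-values are uniform under a random null", {
    set.seed(26)
    rej <- logical(400)
    for (r in seq_along(rej)) {
        pts <- matrix(rnorm(16 * 3), 16)
        d <- dist(pts)
        grp <- sample(rep(c(0, 1), each = 8))
        rej[r] <- permanova(d, grp, nPerm = 199, seed = r)$p.value <= 0.05
    }
    expect_gte(mean(rej), 0.02)
    expect_lte(mean(rej), 0.08)
})
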