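test_that("LD pruning drops only what the threshold demands", {
    set.seed(20)
    n <- 120
    ## mutually independent variants pass through untouched
    d <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
    dm <- makeDosage(d)
    pr <- ldPrune(dm, window = 10, step = 2, r2_max = 0.1)
    expect_identical(pr$keep, 1:30)

    ## an exact duplicate forces removal of exactly one member
    d2 <- cbind(d[, 1:10], d[, 5])
    pr2 <- ldPrune(makeDosage(d2), window = 11, step = 1, r2_max = 0.2)
    expect_true(xor(5 %in% pr2$keep, 11 %in% pr2$keep))
    expect_length(pr2$keep, 10L)

    ## zero-variance variants are auto-dropped
    d3 <- cbind(d[, 1:5], 1)
    expect_message(pr3 <- ldPrune(makeDosage(d3), 6, 1, 0.1), "zero-variance")
    expect_identical(pr3$dropped_zero_var, 6L)

    expect_error(ldPrune(makeDosage(d), window = 2, step = 5), "window")
    expect_error(ldPrune(makeDosage(d), r2_max = 1.5), "r2_max")
})

test_that("greedy pruning matches the exhaustive oracle on planted blocks", {
    set.seed(22)
    n <- 150; M <- 50
    base <- matrix(rbinom(n * M, 2, 0.5), n, M)
    ## plant correlated blocks by copying with small perturbation
    for (blk in list(3:6, 20:24, 40:43)) {
        src <- base[, blk[1]]
        for (j in blk[-1]) {
            flip <- runif(n) < 0.05
            base[, j] <- ifelse(flip, sample(0:2, n, TRUE), src)
        }
    }
    dm <- makeDosage(base)
    pr <- ldPrune(dm, window = 15, step = 3, r2_max = 0.2)
    orc <- prunedOracle(dosages(dm), window = 15, step = 3, r2max = 0.2)
    expect_identical(pr$keep, orc$keep)
    ## no surviving pair above threshold within any window
    kept <- dosages(dm)[pr$keep, ]
    pos <- pr$keep
    for (i in seq_along(pos)) for (j in seq_along(pos)) {
        if (j <= i || pos[j] - pos[i] >= 15) next
        expect_lt(cor(kept[i, ], kept[j, ])^2, 0.2)
    }
})

test_that("reference PCA satisfies its decomposition contracts", {
    set.seed(24)
    ref <- makeDosage(matrix(rbinom(60 * 300, 2, runif(300, 0.1, 0.9)),
                             60, 300, byrow = FALSE))
    proj <- fitReferencePCA(ref, k = 8, anchor = "EUR")
    ## centroid of the panel's own projections is zero
    expect_lt(max(abs(proj@centroid)), 1e-8)
    ## orthonormal loadings
    k <- ncol(proj@loadings)
    expect_lt(max(abs(crossprod(proj@loadings) - diag(k))), 1e-8)
    ## variance explained is non-increasing
    expect_true(all(diff(proj@varExplained) <= 1e-12))
    ## guards: panel size and available rank
    expect_error(fitReferencePCA(ref, k = 61), "samples")
    wide <- makeDosage(matrix(rbinom(60 * 30, 2, 0.5), 60, 30))
    expect_error(fitReferencePCA(wide, k = 31), "rank")
})

test_that("genetic distance honors centroid, symmetry and overlap guards", {
    set.seed(26)
    ref_d <- matrix(rbinom(80 * 200, 2, runif(200, 0.2, 0.8)), 80, 200)
    ref <- makeDosage(ref_d)
    proj <- fitReferencePCA(ref, k = 5)
    ## a pseudo-sample at the per-SNP reference mean has distance zero
    ph <- rowMeans(dosages(ref))
    center_sample <- makeDosage(matrix(ph, 1, byrow = TRUE))
    expect_lt(geneticDistance(center_sample, proj), 1e-8)
    ## sign flips of principal axes do not change distances
    proj2 <- proj
    proj2@loadings[, c(1, 3)] <- -proj2@loadings[, c(1, 3)]
    cohort <- makeDosage(matrix(rbinom(10 * 200, 2, 0.5), 10, 200))
    expect_equal(geneticDistance(cohort, proj2),
                 geneticDistance(cohort, proj), tolerance = 1e-10)
    ## insufficient SNP overlap is an error stating the fraction
    sub <- cohort[1:100, ]
    expect_error(geneticDistance(sub, proj), "%")
})

test_that("admixture EM preserves the simplex and its likelihood contract", {
    set.seed(28)
    cfg <- smallConfig(seed = 28, n_cohort = 60L)
    f <- simulatePopulationFrequencies(cfg)
    sim <- simulateAdmixedCohort(cfg, f)
    fr <- referenceFrequencies(sim$refs)
    gap <- estimateGAP(sim$cohort, fr, trace = TRUE)
    expect_true(all(gap$q >= 0))
    expect_true(all(abs(rowSums(gap$q) - 1) < 1e-8))
    ## monotone non-decreasing log-likelihood for every sample
    expect_true(all(diff(gap$trace) > -1e-8))

    ## identical component frequencies are flagged unidentifiable
    fr_flat <- fr
    fr_flat[] <- rep(fr[1, ], each = 4)
    expect_warning(g2 <- estimateGAP(sim$cohort, fr_flat), "unidentifiable")
    expect_true(all(g2$q == 0.25))
    expect_false(g2$identifiable)
})

test_that("tertile assignment is balanced and rank-invariant", {
    expect_identical(as.character(assignTertiles(c(1, 2, 3), "gd")),
                     c("closest", "middle", "farthest"))
    set.seed(30)
    x <- rnorm(999)
    t3 <- assignTertiles(x, "gap")
    expect_identical(as.integer(table(t3)), c(333L, 333L, 333L))
    expect_identical(assignTertiles(2 * x + 5, "gap"), t3)
    expect_error(assignTertiles(c(1, 1, 2)), "distinct")
    for (n in c(100L, 1000L))
        expect_true(all(abs(table(assignTertiles(runif(n), "gd")) -
                            n / 3) <= 1))
})

test_that("GD-GAP Spearman matrix matches the rank-Pearson oracle", {
    set.seed(32)
    n <- 50
    gd <- matrix(runif(4 * n), n, 4,
                 dimnames = list(NULL, c("EUR", "AFR", "EAS", "NAM")))
    gap <- matrix(runif(4 * n), n, 4, dimnames = dimnames(gd))
    gap <- gap / rowSums(gap)
    prof <- ancestryProfiles(gd, gap)
    cr <- gdGapCorrelation(prof)
    expect_equal(cr$rho["gd_EUR", "gap_AFR"],
                 spearmanOracle(gd[, "EUR"], gap[, "AFR"]),
                 tolerance = 1e-12)
    expect_equal(cr$rho["gd_NAM", "gd_EAS"],
                 spearmanOracle(gd[, "NAM"], gd[, "EAS"]),
                 tolerance = 1e-12)
    ## perfect monotone association
    prof2 <- prof
    prof2$gap_EUR <- prof2$gd_EUR^3
    prof2$gap_AFR <- -prof2$gd_EUR
    cr2 <- gdGapCorrelation(prof2)
    expect_equal(unname(cr2$rho["gd_EUR", "gap_EUR"]), 1)
    expect_equal(unname(cr2$rho["gd_EUR", "gap_AFR"]), -1)
    ## constant column gives NA
    prof3 <- prof
    prof3$gap_NAM <- 0.25
    expect_true(is.na(gdGapCorrelation(prof3)$rho["gd_EUR", "gap_NAM"]))
    expect_error(gdGapCorrelation(prof[1:5, ]), "10")
})
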