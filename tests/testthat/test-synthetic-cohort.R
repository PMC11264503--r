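test_that("population frequencies follow the Balding-Nichols divergence model", {
    ## near-zero divergence: all populations collapse onto the ancestral
    cfg0 <- simulationConfig(seed = 3, fst = 1e-6, n_snps_grs = 50L,
                             n_snps_ancestry = 450L)
    f0 <- simulatePopulationFrequencies(cfg0)
    expect_true(all(apply(f0, 2, function(col) diff(range(col))) < 0.01))

    ## realized pairwise divergence matches the configured Fst
    cfg <- simulationConfig(seed = 5, fst = 0.15, n_snps_grs = 302L,
                            n_snps_ancestry = 1698L)
    f <- simulatePopulationFrequencies(cfg)
    pairs <- combn(4, 2)
    fst_hat <- apply(pairs, 2, function(p) hudsonFst(f[p[1], ], f[p[2], ]))
    expect_true(all(fst_hat > 0.10 & fst_hat < 0.20))

    ## determinism and bounds
    expect_identical(f, simulatePopulationFrequencies(cfg))
    expect_true(all(f >= 0.01 & f <= 0.99))
})

test_that("admixed cohort genotypes follow the Dirichlet-binomial model", {
    cfg <- smallConfig(seed = 11, n_cohort = 500L,
                       dirichlet_alpha = rbind(
                           NHW = c(1000, 0.001, 0.001, 0.001),
                           NHB = c(1, 1, 1, 1),
                           HISP = c(1, 1, 1, 1),
                           ASIAN = c(1, 1, 1, 1)))
    f <- simulatePopulationFrequencies(cfg)
    sim <- simulateAdmixedCohort(cfg, f,
                                 group_labels = rep("NHW", cfg$n_cohort))
    ## degenerate Dirichlet concentrates on component 1
    expect_gt(mean(sim$truth$q_true[, 1]), 0.99)
    ## binomial support and simplex rows
    d <- dosages(sim$cohort)
    expect_true(all(d %in% c(0, 1, 2)))
    expect_true(all(abs(rowSums(sim$truth$q_true) - 1) < 1e-12))

    ## realized cohort allele frequency matches the analytic mixture
    cfg2 <- smallConfig(seed = 12, n_cohort = 500L)
    f2 <- simulatePopulationFrequencies(cfg2)
    sim2 <- simulateAdmixedCohort(cfg2, f2)
    p_mix <- colMeans(sim2$truth$q_true %*% f2)        # expected per-SNP
    p_obs <- rowMeans(dosages(sim2$cohort)) / 2
    se <- sqrt(p_mix * (1 - p_mix) / (2 * cfg2$n_cohort)) +
        0.25 / sqrt(cfg2$n_cohort)   # allow for q-draw variability
    expect_true(mean(abs(p_obs - p_mix) < 4 * se) > 0.99)

    ## reference panels are pure draws
    expect_equal(length(sim2$refs), 4L)
    expect_true(all(dosages(sim2$refs$EUR) %in% c(0, 1, 2)))
})

test_that("simulated effect weights behave like a GWAS weight table", {
    cfg <- smallConfig(seed = 21)
    f <- simulatePopulationFrequencies(cfg)
    sim <- simulateAdmixedCohort(cfg, f)
    v <- variantInfo(sim$cohort)[seq_len(cfg$n_snps_grs), ]
    w <- simulateEffectWeights(cfg, v)
    expect_identical(w, simulateEffectWeights(cfg, v))
    expect_true(all(w$effect_allele != w$other_allele))

    ## zero effect SD makes the downstream score constant
    cfg0 <- smallConfig(seed = 21, effect_sd = 0)
    w0 <- simulateEffectWeights(cfg0, v)
    expect_true(all(w0$weight == 0))
    grs0 <- computeGRS(harmonizeToWeights(sim$cohort, w0),
                       w0[order(match(w0$id, v$id)), ])
    expect_true(all(grs0$grs == 0))

    ## the default panel size emulates the 302-SNP weight set
    expect_identical(simulationConfig(seed = 1)$n_snps_grs, 302L)
})

test_that("phenotype moments match the emulated cohort description", {
    ## full-size draw: birthweight 3313.92 (529.05) g, delivery 39.16 wk
    cfg <- simulationConfig(seed = 31)
    n <- cfg$n_cohort
    grs <- stats::setNames(rnorm(n), sprintf("W%04d", seq_len(n)))
    ph <- simulateLongitudinalPhenotypes(cfg, grs, biometry = FALSE)
    se_mean <- 529.05 / sqrt(n)
    se_sd <- 529.05 / sqrt(2 * n)
    expect_lt(abs(mean(ph$births$birthweight_g) - 3313.92), 2 * se_mean)
    expect_lt(abs(sd(ph$births$birthweight_g) - 529.05), 2 * se_sd)
    expect_lt(abs(mean(ph$births$ga_delivery_weeks) - 39.16),
              2 * 1.97 / sqrt(n))
    expect_true(all(ph$births$ga_delivery_weeks >= 30 &
                    ph$births$ga_delivery_weeks <= 42))
})

test_that("visit schedule honors the design and the inclusion rule", {
    cfg <- smallConfig(seed = 41, n_cohort = 150L)
    grs <- stats::setNames(rnorm(150), sprintf("W%04d", 1:150))
    ph <- suppressMessages(simulateLongitudinalPhenotypes(cfg, grs))
    nv <- table(ph$visits$sample_id)
    expect_true(all(nv >= 2))                 # at least two fetal measures
    expect_true(all(ph$visits$ga_weeks <= 40))
    ## visits never postdate delivery
    m <- merge(ph$visits, ph$births)
    expect_true(all(m$ga_weeks < m$ga_delivery_weeks))
    ## biometry within Hadlock plausibility bounds
    expect_true(all(ph$visits$hc_cm > 5 & ph$visits$hc_cm < 40))
    expect_true(all(ph$visits$ac_cm > 5 & ph$visits$ac_cm < 45))
    expect_true(all(ph$visits$fl_cm > 0.5 & ph$visits$fl_cm < 9))
})

test_that("the generator is deterministic and the null world carries no effect", {
    cfg <- smallConfig(seed = 51, growth_effect = 0, birthweight_effect = 0)
    s1 <- suppressMessages(simulateCohort(cfg))
    s2 <- suppressMessages(simulateCohort(cfg))
    expect_identical(dosages(s1$cohort), dosages(s2$cohort))
    expect_identical(s1$visits, s2$visits)
    expect_identical(s1$births, s2$births)
    expect_identical(s1$truth$q_true, s2$truth$q_true)
    expect_length(s1$truth$injected$eligible, 0)

    ## config validation
    expect_error(simulationConfig(seed = 1, fst = 1.2), "fst")
    expect_error(simulationConfig(seed = 1,
        visit_windows = list(A = rbind(c(20, 18)))), "disjoint")
    expect_error(simulationConfig(), "seed")
})
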