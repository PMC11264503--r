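test_that("weekly models are equivariant under outcome scaling", {
    rep1 <- latentW40Rep(seed = 101, n = 400)
    est1 <- fitWeeklyModels(rep1$weekly, rep1$risk, rep1$profiles,
                            rep1$covars, weeks = 40, guard = 30)
    wk2 <- rep1$weekly
    wk2$w40 <- wk2$w40 * 3.5
    est2 <- fitWeeklyModels(wk2, rep1$risk, rep1$profiles, rep1$covars,
                            weeks = 40, guard = 30)
    expect_equal(est2$beta, 3.5 * est1$beta, tolerance = 1e-10)
    expect_equal(est2$ci_low, 3.5 * est1$ci_low, tolerance = 1e-10)
    expect_equal(est2$ci_high, 3.5 * est1$ci_high, tolerance = 1e-10)
    expect_equal(est2$p, est1$p, tolerance = 1e-10)
    ## well-formed intervals
    expect_true(all(est1$ci_low <= est1$beta & est1$beta <= est1$ci_high))
    expect_true(all(est1$p > 0 & est1$p <= 1))
})

test_that("covariates orthogonal to the quartile design leave betas alone", {
    rep1 <- latentW40Rep(seed = 103, n = 300)
    cov_const <- rep1$covars
    for (cc in c("years_us", "maternal_age", "prepreg_bmi"))
        cov_const[[cc]] <- 1
    for (cc in c("marital", "parity", "fetal_sex"))
        cov_const[[cc]] <- "same"
    ## all covariates constant: dropped with warnings, quartiles-only fit
    ww <- testthat::capture_warnings(
        est0 <- fitWeeklyModels(rep1$weekly, rep1$risk, rep1$profiles,
                                cov_const, weeks = 40, guard = 5))
    expect_true(any(grepl("constant in stratum", ww)))
    ## add one covariate exactly orthogonal to the quartile design
    Q <- model.matrix(~factor(rep1$risk$quartile))
    set.seed(1)
    z <- rnorm(nrow(Q))
    cov_orth <- cov_const
    cov_orth$years_us <- drop(z - Q %*% qr.solve(crossprod(Q),
                                                 crossprod(Q, z)))
    est1 <- suppressWarnings(
        fitWeeklyModels(rep1$weekly, rep1$risk, rep1$profiles, cov_orth,
                        weeks = 40, guard = 5))
    all0 <- est0[est0$stratum_type == "all", ]
    all1 <- est1[est1$stratum_type == "all", ]
    expect_equal(all1$beta, all0$beta, tolerance = 1e-8)
})

test_that("small strata are skipped under the sample guard", {
    rep1 <- latentW40Rep(seed = 105, n = 120)
    est <- fitWeeklyModels(rep1$weekly, rep1$risk, rep1$profiles,
                           rep1$covars, weeks = 40, guard = 10)
    sk <- attr(est, "skipped")
    ## tertile cells of 40 are below 10 x 11 parameters
    expect_true(all(c("gd", "gap") %in% sk$stratum_type))
    expect_true(all(est$stratum_type == "all"))
    expect_identical(sk$reason, rep("below sample guard", nrow(sk)))
})

test_that("birthweight models add the gestational-age adjustment", {
    rep1 <- latentW40Rep(seed = 107, n = 500, birthweight_effect = 0)
    bw <- fitBirthweightModels(rep1$births, rep1$risk, rep1$profiles,
                               rep1$covars, guard = 30)
    expect_true(all(bw$outcome == "birthweight"))
    expect_identical(sort(unique(bw$contrast)), c("Q2", "Q3", "Q4"))
    ## the GA coefficient is in the model: flattening GA changes estimates
    births2 <- rep1$births
    births2$ga_delivery_weeks <- 39
    bw2 <- suppressWarnings(
        fitBirthweightModels(births2, rep1$risk, rep1$profiles,
                             rep1$covars, guard = 30))
    expect_false(isTRUE(all.equal(bw$beta, bw2$beta)))
})

test_that("interaction models report the product term and are centering-invariant", {
    rep1 <- latentW40Rep(seed = 109, n = 400)
    ia <- fitInteractionModels(rep1$weekly, rep1$risk, rep1$profiles,
                               rep1$covars, outcome_cols = "w40",
                               modifiers = c("gd_EUR", "gap_EUR"))
    expect_identical(ia$contrast, c("GRSxgd_EUR", "GRSxgap_EUR"))
    ## centering GRS and the modifier leaves the product coefficient alone
    risk_c <- rep1$risk
    risk_c$grs <- risk_c$grs - mean(risk_c$grs)
    prof_c <- rep1$profiles
    prof_c$gd_EUR <- prof_c$gd_EUR - mean(prof_c$gd_EUR)
    ia_c <- fitInteractionModels(rep1$weekly, risk_c, prof_c, rep1$covars,
                                 outcome_cols = "w40",
                                 modifiers = "gd_EUR")
    expect_equal(ia_c$beta, ia$beta[1], tolerance = 1e-8)
    expect_equal(ia_c$p, ia$p[1], tolerance = 1e-8)
    ## constant modifier is an error
    prof_k <- rep1$profiles
    prof_k$gd_EUR <- 1
    expect_error(fitInteractionModels(rep1$weekly, rep1$risk, prof_k,
                                      rep1$covars, outcome_cols = "w40",
                                      modifiers = "gd_EUR"), "constant")
})

test_that("the report writes complete tables and flags significance", {
    rep1 <- latentW40Rep(seed = 111, n = 400)
    est <- fitWeeklyModels(rep1$weekly, rep1$risk, rep1$profiles,
                           rep1$covars, weeks = 40, guard = 30)
    dir <- withr::local_tempdir()
    files <- renderReport(est, dir, figures = FALSE)
    tab <- read.delim(file.path(dir, "association_results.tsv"))
    ## row count = strata x outcomes x contrasts actually fitted
    expect_identical(nrow(tab), nrow(est))
    expect_identical(tab$significant, tab$p < 0.05)
    ## skipped strata appear in their own table
    rep2 <- latentW40Rep(seed = 113, n = 120)
    est2 <- fitWeeklyModels(rep2$weekly, rep2$risk, rep2$profiles,
                            rep2$covars, weeks = 40, guard = 10)
    dir2 <- withr::local_tempdir()
    renderReport(est2, dir2, figures = FALSE)
    expect_true(file.exists(file.path(dir2, "skipped_strata.tsv")))
    expect_error(renderReport(data.frame(), withr::local_tempdir()),
                 "empty")
})
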