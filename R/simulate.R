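## Synthetic multi-ancestral pregnancy cohort with known ground truth.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: four ancestral reference panels with Balding-Nichols-divergent
## allele frequencies, a Dirichlet-admixed cohort, a simulated GWAS
## effect-weight table, a five-follow-up randomized ultrasound schedule on
## top of an enrollment scan, lognormal fetal growth with cubic-polynomial
## subject random effects, and injectable stratum-specific risk-score
## effects on growth and birthweight.

## Constants calibrated (once, at design time) so realized moments match the
## reported cohort distributions: birthweight 3313.92 (529.05) g and
## gestational age at delivery 39.16 (1.97) weeks.
.LN_COEF <- c(0.517075, 0.332, -0.00354)  # log-gram mean curve, quadratic in weeks
.BIRTH_NOISE_SD <- 0.038535               # extra lognormal noise at delivery
.GA_DELIVERY <- list(mu = 40.64716, sd = 2.850102, bounds = c(30, 42))

#' Simulation configuration for the synthetic cohort
#'
#' Returns the full set of generator parameters with defaults chosen to
#' emulate a multi-ancestral low-risk pregnancy cohort: cohort size 1,837
#' with four self-identified groups in the reported proportions, 302
#' weighted risk-score SNPs plus 2,000 ancestry-informative SNPs,
#' Balding-Nichols divergence Fst 0.15 between the four ancestral
#' populations, and spiky per-group Dirichlet admixture so the cohort-mean
#' ancestry proportions land near 0.48/0.30/0.12/0.10
#' (European/African/East Asian/Amerindigenous).
#'
#' @param seed integer seed (mandatory); every draw in the generator derives
#'   from it.
#' @param n_cohort number of pregnant women.
#' @param n_ref_per_pop reference-panel size per ancestral population.
#' @param n_snps_grs,n_snps_ancestry SNP counts for the weighted score and
#'   for ancestry inference.
#' @param fst Balding-Nichols divergence per population, in (0, 1).
#' @param dirichlet_alpha 4x4 matrix (self-identified group x ancestral
#'   component) of strictly positive Dirichlet parameters.
#' @param group_probs marginal probabilities of the four groups.
#' @param effect_sd SD of simulated log odds-ratio weights.
#' @param growth_effect injected fetal-weight effect (grams at week 40) of
#'   the top GRS quartile, ramping linearly from `growth_onset_week`.
#' @param growth_onset_week week at which the injected growth effect starts.
#' @param birthweight_effect injected birthweight effect (grams).
#' @param effect_strata character vector of stratum labels that carry the
#'   injected effects; empty (the default) is the null world.
#' @param visit_windows list of four 5x2 matrices of gestational-age windows
#'   (weeks), one per randomization group; disjoint and ordered within
#'   10--40.
#' @param baseline_window enrollment-scan window (weeks), common to all.
#' @param noise_model `"biometry"` perturbs HC/AC/FL with `noise_sd_biometry`
#'   centimetres; `"log_efw"` perturbs log estimated fetal weight directly
#'   with `noise_sd_logefw` (biometry then back-solved exactly), giving a
#'   known residual variance for variance-component recovery studies.
#' @param noise_sd_biometry measurement noise on each biometric, cm.
#' @param noise_sd_logefw residual SD on the log-gram scale.
#' @param re_sd SDs of the subject random effects
#'   (intercept/linear/quadratic/cubic in centred week).
#' @param re_cor_int_lin correlation between the intercept and linear random
#'   effects (negative: catch-up growth).
#' @param knots,boundary_knots natural-spline knots of the mean structure.
#' @param covariate_log_effects named numeric, optional additive log-scale
#'   growth effects of covariates (all zero by default).
#' @return a validated `list` of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(seed,
                             n_cohort = 1837L,
                             n_ref_per_pop = 100L,
                             n_snps_grs = 302L,
                             n_snps_ancestry = 2000L,
                             fst = 0.15,
                             dirichlet_alpha = NULL,
                             group_probs = c(NHW = 0.3059, NHB = 0.3119,
                                             HISP = 0.2749, ASIAN = 0.1073),
                             effect_sd = 0.10,
                             growth_effect = 100,
                             growth_onset_week = 17,
                             birthweight_effect = 117,
                             effect_strata = character(0),
                             visit_windows = NULL,
                             baseline_window = c(12.5, 13.9),
                             noise_model = c("biometry", "log_efw"),
                             noise_sd_biometry = 0.1,
                             noise_sd_logefw = 0.02,
                             re_sd = c(0.09, 0.07, 0.03, 0.02),
                             re_cor_int_lin = -0.6,
                             knots = c(16, 24, 32),
                             boundary_knots = c(10, 40),
                             covariate_log_effects = NULL) {
    if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
    anchors <- c("EUR", "AFR", "EAS", "NAM")
    if (is.null(dirichlet_alpha)) {
        dirichlet_alpha <- rbind(
            NHW   = c(6.00, 0.08, 0.08, 0.08),
            NHB   = c(0.35, 4.00, 0.05, 0.10),
            HISP  = c(1.80, 0.15, 0.05, 1.00),
            ASIAN = c(0.12, 0.05, 3.00, 0.08))
        colnames(dirichlet_alpha) <- anchors
    }
    if (is.null(visit_windows)) {
        visit_windows <- list(
            A = rbind(c(16, 18), c(23, 25), c(30, 32), c(34, 36), c(38, 40)),
            B = rbind(c(17, 19), c(24, 26), c(31, 33), c(35, 37), c(39, 40)),
            C = rbind(c(18, 20), c(25, 27), c(28, 30), c(33, 35), c(37, 39)),
            D = rbind(c(19, 21), c(22, 24), c(29, 31), c(32, 34), c(36, 38)))
    }
    cfg <- list(seed = as.integer(seed),
                n_cohort = assertCount(n_cohort, "n_cohort"),
                n_ref_per_pop = assertCount(n_ref_per_pop, "n_ref_per_pop"),
                n_snps_grs = assertCount(n_snps_grs, "n_snps_grs"),
                n_snps_ancestry = assertCount(n_snps_ancestry,
                                              "n_snps_ancestry"),
                fst = fst, anchors = anchors,
                dirichlet_alpha = dirichlet_alpha,
                group_probs = group_probs, effect_sd = effect_sd,
                growth_effect = growth_effect,
                growth_onset_week = growth_onset_week,
                birthweight_effect = birthweight_effect,
                effect_strata = effect_strata,
                visit_windows = visit_windows,
                baseline_window = baseline_window,
                noise_model = match.arg(noise_model),
                noise_sd_biometry = noise_sd_biometry,
                noise_sd_logefw = noise_sd_logefw,
                re_sd = re_sd, re_cor_int_lin = re_cor_int_lin,
                knots = knots, boundary_knots = boundary_knots,
                covariate_log_effects = covariate_log_effects %||% numeric(0))
    class(cfg) <- "SimulationConfig"
    validateSimulationConfig(cfg)
    cfg
}

#' @rdname simulationConfig
#' @param config a `SimulationConfig`.
#' @export
validateSimulationConfig <- function(config) {
    with(config, {
        if (!is.finite(fst) || fst <= 0 || fst >= 1)
            stop("fst must lie in (0, 1)", call. = FALSE)
        if (any(dirichlet_alpha <= 0))
            stop("dirichlet_alpha must be strictly positive", call. = FALSE)
        if (abs(sum(group_probs) - 1) > 1e-6)
            stop("group_probs must sum to 1", call. = FALSE)
        for (w in visit_windows) {
            if (any(w < 10) || any(w > 40))
                stop("visit windows must lie within weeks 10-40",
                     call. = FALSE)
            if (any(w[, 2] <= w[, 1]) ||
                any(w[-1, 1] < w[-nrow(w), 2]))
                stop("visit windows must be disjoint ordered intervals",
                     call. = FALSE)
        }
        if (noise_sd_biometry < 0 || noise_sd_logefw < 0)
            stop("noise SDs must be non-negative", call. = FALSE)
    })
    invisible(config)
}

opSeed <- function(config, op) {
    offs <- c(freqs = 11L, cohort = 12L, weights = 13L, phenotype = 14L,
              groups = 15L)
    as.integer((as.numeric(config$seed) * 97 + offs[[op]] * 1009) %%
               2147483647)
}

rdirichlet <- function(n, alpha) {
    x <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
                nrow = n)
    x / rowSums(x)
}

#' Balding-Nichols population allele frequencies
#'
#' Draws an ancestral frequency \eqn{p_j \sim U(0.05, 0.95)} per SNP and
#' four population-specific frequencies
#' \eqn{f_{kj} \sim Beta(p_j(1-F)/F,\ (1-p_j)(1-F)/F)} with \eqn{F} the
#' configured Fst, clipped to \[0.01, 0.99\].
#'
#' @param config a [simulationConfig()].
#' @return 4 x M frequency matrix (rows named by anchor) with the ancestral
#'   frequencies attached as `attr(, "ancestral")`.
#' @export
simulatePopulationFrequencies <- function(config) {
    validateSimulationConfig(config)
    M <- config$n_snps_grs + config$n_snps_ancestry
    set.seed(opSeed(config, "freqs"))
    p <- stats::runif(M, 0.05, 0.95)
    shape <- (1 - config$fst) / config$fst
    f <- t(vapply(config$anchors, function(k)
        stats::rbeta(M, p * shape, (1 - p) * shape), numeric(M)))
    if (any(!is.finite(f)))
        stop("non-finite frequency draw; config: fst=", config$fst,
             " M=", M, call. = FALSE)
    f <- pmin(pmax(f, 0.01), 0.99)
    rownames(f) <- config$anchors
    colnames(f) <- sprintf("snp%05d", seq_len(M))
    attr(f, "ancestral") <- p
    ## variant identities travel with the frequencies so that independent
    ## cohort/panel draws from the same frequency matrix share SNPs
    attr(f, "variants") <- simVariantTable(M)
    f
}

## Variant bookkeeping for the simulated SNP set. Allele pairs are drawn
## from the strand-unambiguous combinations (the panels emulate post-QC
## array data from which A/T and C/G SNPs were already removed).
simVariantTable <- function(M) {
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pick <- pairs[sample.int(8L, M, replace = TRUE), , drop = FALSE]
    chrom <- as.character(rep_len(1:22, M))
    pos <- integer(M)
    for (ch in unique(chrom)) {
        i <- which(chrom == ch)
        pos[i] <- sort(sample.int(5e7, length(i)))
    }
    data.frame(id = sprintf("snp%05d", seq_len(M)), chrom = chrom,
               pos = pos, allele_a = pick[, 1], allele_b = pick[, 2],
               counted_allele = pick[, 2], stringsAsFactors = FALSE)
}

#' Dirichlet-admixed cohort and pure reference panels
#'
#' Per woman, admixture proportions \eqn{q_i} are drawn from the Dirichlet
#' of her self-identified group; genotypes are
#' \eqn{g_{ij} \sim Binomial(2,\ \sum_k q_{ik} f_{kj})} independently per
#' SNP. Reference-panel genotypes are drawn with \eqn{q} an indicator
#' vector.
#'
#' @param config a [simulationConfig()].
#' @param pop_freqs 4 x M frequency matrix from
#'   [simulatePopulationFrequencies()].
#' @param group_labels optional per-woman group; drawn from
#'   `config$group_probs` when `NULL`.
#' @return list with `cohort` (a [DosageMatrix-class]), `refs` (named list
#'   of [DosageMatrix-class] panels), and `truth` (the accumulating ground
#'   truth: `q_true`, `pop_freqs`, `group`).
#' @export
simulateAdmixedCohort <- function(config, pop_freqs, group_labels = NULL) {
    validateSimulationConfig(config)
    n <- config$n_cohort
    M <- ncol(pop_freqs)
    set.seed(opSeed(config, "cohort"))
    groups <- rownames(config$dirichlet_alpha)
    if (is.null(group_labels))
        group_labels <- sample(groups, n, replace = TRUE,
                               prob = config$group_probs)
    if (!all(group_labels %in% groups))
        stop("group label without a dirichlet_alpha row", call. = FALSE)
    q <- matrix(NA_real_, n, nrow(pop_freqs),
                dimnames = list(NULL, rownames(pop_freqs)))
    for (g in groups) {
        i <- which(group_labels == g)
        if (length(i))
            q[i, ] <- rdirichlet(length(i), config$dirichlet_alpha[g, ])
    }
    p_mix <- q %*% pop_freqs                     # n x M mixture frequencies
    if (any(p_mix < -1e-12 | p_mix > 1 + 1e-12))
        stop("mixture probability outside [0, 1]", call. = FALSE)
    p_mix <- pmin(pmax(p_mix, 0), 1)
    vars <- attr(pop_freqs, "variants") %||% simVariantTable(M)
    g <- matrix(stats::rbinom(n * M, 2L, p_mix), n, M)
    ids <- sprintf("W%04d", seq_len(n))
    cohort <- DosageMatrix(t(g), vars, sample_ids = ids)
    refs <- lapply(rownames(pop_freqs), function(k) {
        gr <- matrix(stats::rbinom(config$n_ref_per_pop * M, 2L,
                                   rep(pop_freqs[k, ],
                                       each = config$n_ref_per_pop)),
                     config$n_ref_per_pop, M)
        DosageMatrix(t(gr), vars,
                     sample_ids = sprintf("%s%03d", k,
                                          seq_len(config$n_ref_per_pop)))
    })
    names(refs) <- rownames(pop_freqs)
    rownames(q) <- ids
    truth <- list(q_true = q, pop_freqs = pop_freqs, group = group_labels)
    class(truth) <- "GroundTruth"
    list(cohort = cohort, refs = refs, truth = truth)
}

#' Simulated GWAS effect-weight table
#'
#' Log odds-ratio weights are drawn \eqn{N(0, \code{effect\_sd}^2)}; the
#' effect allele is chosen uniformly between the two alleles of each SNP.
#'
#' @param config a [simulationConfig()].
#' @param snp_subset variant table rows (as from [variantInfo()]) of the
#'   `n_snps_grs` scored SNPs.
#' @return a validated effect-weight table (see [effectWeightTable()]).
#' @export
simulateEffectWeights <- function(config, snp_subset) {
    validateSimulationConfig(config)
    if (nrow(snp_subset) != config$n_snps_grs)
        stop("snp_subset must have n_snps_grs rows", call. = FALSE)
    set.seed(opSeed(config, "weights"))
    w <- stats::rnorm(nrow(snp_subset), 0, config$effect_sd)
    flip <- stats::runif(nrow(snp_subset)) < 0.5
    ea <- ifelse(flip, snp_subset$allele_a, snp_subset$allele_b)
    oa <- ifelse(flip, snp_subset$allele_b, snp_subset$allele_a)
    effectWeightTable(data.frame(
        id = snp_subset$id, chrom = snp_subset$chrom, pos = snp_subset$pos,
        effect_allele = ea, other_allele = oa, weight = w,
        stringsAsFactors = FALSE))
}

## Natural-spline coefficients reproducing the calibrated quadratic
## log-weight curve on the model's own basis (so the generator's truth lies
## exactly in the space the trajectory model fits).
trajMeanCoef <- function(knots, boundary) {
    tg <- seq(boundary[1], boundary[2], by = 0.25)
    B <- cbind(1, splines::ns(tg, knots = knots, Boundary.knots = boundary))
    y <- .LN_COEF[1] + .LN_COEF[2] * tg + .LN_COEF[3] * tg^2
    qr.solve(B, y)
}

trajBasis <- function(t, knots, boundary) {
    cbind(1, splines::ns(t, knots = knots, Boundary.knots = boundary))
}

reCovariance <- function(re_sd, re_cor_int_lin) {
    R <- diag(4)
    R[1, 2] <- R[2, 1] <- re_cor_int_lin
    diag(re_sd) %*% R %*% diag(re_sd)
}

rtruncnorm1 <- function(n, mu, sd, bounds) {
    u <- stats::runif(n, stats::pnorm((bounds[1] - mu) / sd),
                      stats::pnorm((bounds[2] - mu) / sd))
    mu + sd * stats::qnorm(u)
}

#' Longitudinal ultrasound visits, delivery records and covariates
#'
#' Each woman gets an enrollment scan plus five follow-up visits drawn
#' uniformly within her randomization group's windows (visits after
#' delivery are dropped; at least two always remain). Her latent log-weight
#' curve is the population spline mean plus a subject cubic-polynomial
#' random effect; women in `config$effect_strata` whose GRS falls in the
#' top quartile additionally receive a linear-in-week injected gram effect
#' and a birthweight shift. Biometry (HC, AC, FL) is back-solved so the
#' Hadlock formula reproduces the latent weight along a fixed gestational
#' age--specific allometric ratio, then perturbed with measurement noise.
#'
#' @param config a [simulationConfig()].
#' @param grs named numeric vector of per-woman risk scores (names are
#'   sample ids), or the `data.frame` returned by [riskScoreResult()].
#' @param strata per-woman stratum labels used only to decide who carries
#'   the injected effect; `NULL` means nobody does.
#' @param truth the `GroundTruth` from [simulateAdmixedCohort()]; returned
#'   augmented with trajectory parameters and latent weekly weights.
#' @param biometry generate the visit schedule and back-solved biometry
#'   (default). `FALSE` skips it (returning `visits = NULL`) and yields
#'   only covariates, delivery records and the latent weekly truth --
#'   the cheap path used by calibration studies that regress directly on
#'   latent outcomes.
#' @return list with `visits`, `births`, `covariates` (`data.frame`s) and
#'   the augmented `truth`.
#' @export
simulateLongitudinalPhenotypes <- function(config, grs, strata = NULL,
                                           truth = NULL, biometry = TRUE) {
    validateSimulationConfig(config)
    if (is.data.frame(grs)) grs <- stats::setNames(grs$grs, grs$sample_id)
    if (any(!is.finite(grs))) stop("grs must be finite", call. = FALSE)
    n <- length(grs)
    ids <- names(grs) %||% sprintf("W%04d", seq_len(n))
    set.seed(opSeed(config, "phenotype"))

    ## covariates, moments matched to the emulated cohort description
    covars <- data.frame(
        sample_id = ids,
        maternal_age = stats::rnorm(n, 27.88, 5.50),
        prepreg_bmi = pmax(stats::rnorm(n, 25.38, 5.13), 15),
        years_us = pmax(stats::rnorm(n, 23.03, 9.47), 0),
        marital = ifelse(stats::runif(n) < 0.7354,
                         "married_or_partner", "other"),
        parity = ifelse(stats::runif(n) < 0.5335, "parous", "nulliparous"),
        fetal_sex = ifelse(stats::runif(n) < 0.4665, "male", "female"),
        rand_group = sample(names(config$visit_windows), n, replace = TRUE),
        stringsAsFactors = FALSE)

    ga_del <- rtruncnorm1(n, .GA_DELIVERY$mu, .GA_DELIVERY$sd,
                          .GA_DELIVERY$bounds)

    ## latent growth curves
    cf <- trajMeanCoef(config$knots, config$boundary_knots)
    G <- reCovariance(config$re_sd, config$re_cor_int_lin)
    b <- MASS::mvrnorm(n, rep(0, 4), G)
    covEff <- rep(0, n)
    cle <- config$covariate_log_effects
    if (length(cle)) {
        mm <- cbind(male = covars$fetal_sex == "male",
                    parous = covars$parity == "parous",
                    age_c = covars$maternal_age - 27.88,
                    bmi_c = covars$prepreg_bmi - 25.38)
        for (nm in names(cle))
            if (nm %in% colnames(mm)) covEff <- covEff + cle[[nm]] * mm[, nm]
    }
    quart <- assignQuartiles(grs)
    eligible <- if (is.null(strata) || !length(config$effect_strata))
        rep(FALSE, n)
    else (strata %in% config$effect_strata) & quart == "Q4"
    rampWeeks <- function(t) {
        on <- config$growth_onset_week
        pmax(0, (t - on)) / (40 - on)
    }
    latentWeight <- function(i, t) {  # vectorized over paired (i, t)
        tc <- (t - 25) / 15
        lw <- drop(trajBasis(t, config$knots, config$boundary_knots) %*% cf) +
            b[i, 1] + b[i, 2] * tc + b[i, 3] * tc^2 + b[i, 4] * tc^3 +
            covEff[i]
        exp(lw) + ifelse(eligible[i], config$growth_effect, 0) *
            rampWeeks(t)
    }

    ## randomized visit schedule
    visits <- NULL
    redraws <- 0L
    if (biometry) {
    vlist <- vector("list", n)
    for (i in seq_len(n)) {
        wmat <- config$visit_windows[[covars$rand_group[i]]]
        ga <- c(stats::runif(1, config$baseline_window[1],
                             config$baseline_window[2]),
                stats::runif(nrow(wmat), wmat[, 1], wmat[, 2]))
        ga <- sort(ga[ga < ga_del[i] & ga <= 40])
        vlist[[i]] <- data.frame(sample_id = ids[i], ga_weeks = ga,
                                 stringsAsFactors = FALSE)
    }
    visits <- do.call(rbind, vlist)

    ## biometry back-solved from the latent weight
    i_of <- match(visits$sample_id, ids)
    target <- latentWeight(i_of, visits$ga_weeks)
    if (config$noise_model == "log_efw")
        target <- target * exp(stats::rnorm(length(target), 0,
                                            config$noise_sd_logefw))
    bio <- hadlockInvert(target, visits$ga_weeks, clamp = TRUE)
    if (attr(bio, "clamped") > 0)
        message(attr(bio, "clamped"),
                " visit weight(s) clamped to the Hadlock-representable range")
    if (config$noise_model == "biometry") {
        lim <- .HADLOCK_BOUNDS
        for (col in c("hc", "ac", "fl")) {
            x <- bio[[col]] + stats::rnorm(nrow(bio), 0,
                                           config$noise_sd_biometry)
            bad <- x <= lim[[col]][1] | x >= lim[[col]][2]
            tries <- 0L
            while (any(bad) && tries < 20L) {
                x[bad] <- bio[[col]][bad] +
                    stats::rnorm(sum(bad), 0, config$noise_sd_biometry)
                redraws <- redraws + sum(bad)
                bad <- x <= lim[[col]][1] | x >= lim[[col]][2]
                tries <- tries + 1L
            }
            x <- pmin(pmax(x, lim[[col]][1] + 0.01), lim[[col]][2] - 0.01)
            bio[[col]] <- x
        }
    }
    visits$hc_cm <- bio$hc
    visits$ac_cm <- bio$ac
    visits$fl_cm <- bio$fl
    }

    ## delivery
    tc_d <- (ga_del - 25) / 15
    lw_del <- drop(trajBasis(ga_del, config$knots,
                             config$boundary_knots) %*% cf) +
        b[, 1] + b[, 2] * tc_d + b[, 3] * tc_d^2 + b[, 4] * tc_d^3 + covEff
    latent_bw <- exp(lw_del) +
        ifelse(eligible, config$birthweight_effect, 0)
    bw <- exp(lw_del + stats::rnorm(n, 0, .BIRTH_NOISE_SD)) +
        ifelse(eligible, config$birthweight_effect, 0)
    births <- data.frame(sample_id = ids, birthweight_g = bw,
                         ga_delivery_weeks = ga_del,
                         stringsAsFactors = FALSE)

    ## latent weekly truth (weeks 10-40)
    weeks <- 10:40
    tc_w <- (weeks - 25) / 15
    mean_w <- drop(trajBasis(weeks, config$knots,
                             config$boundary_knots) %*% cf)
    lat <- exp(matrix(mean_w, n, length(weeks), byrow = TRUE) +
               b %*% rbind(1, tc_w, tc_w^2, tc_w^3) + covEff) +
        outer(ifelse(eligible, config$growth_effect, 0), rampWeeks(weeks))
    dimnames(lat) <- list(ids, paste0("w", weeks))

    if (is.null(truth)) {
        truth <- list()
        class(truth) <- "GroundTruth"
    }
    truth$trajectory_params <- list(coef = cf, knots = config$knots,
                                    boundary = config$boundary_knots,
                                    G = G, sigma_log = config$noise_sd_logefw,
                                    random_effects = b)
    truth$latent_weekly <- lat
    truth$latent_birthweight <- latent_bw
    truth$injected <- list(growth_effect = config$growth_effect,
                           birthweight_effect = config$birthweight_effect,
                           onset_week = config$growth_onset_week,
                           strata = config$effect_strata,
                           eligible = ids[eligible])
    truth$quartile <- quart
    if (biometry) attr(visits, "biometry_redraws") <- redraws
    if (redraws) message(redraws, " biometry redraw(s) at plausibility bounds")
    list(visits = visits, births = births, covariates = covars,
         truth = truth)
}

#' One-call synthetic cohort
#'
#' Runs the full generator: population frequencies, admixed cohort and
#' reference panels, effect weights, risk scores, and longitudinal
#' phenotypes. Stratum labels for effect injection are the self-identified
#' group labels (analyses stratify on genetic distance/ancestry tertiles
#' computed downstream; tests that need genetic strata pass their own
#' labels to [simulateLongitudinalPhenotypes()]).
#'
#' @param config a [simulationConfig()].
#' @return list with `cohort`, `refs`, `weights`, `grs`, `visits`,
#'   `births`, `covariates`, `truth`.
#' @export
simulateCohort <- function(config) {
    f <- simulatePopulationFrequencies(config)
    pan <- simulateAdmixedCohort(config, f)
    v <- variantInfo(pan$cohort)
    weights <- simulateEffectWeights(config,
                                     v[seq_len(config$n_snps_grs), ])
    risk <- riskScoreResult(pan$cohort, weights)
    phen <- simulateLongitudinalPhenotypes(
        config, stats::setNames(risk$grs, risk$sample_id),
        strata = pan$truth$group, truth = pan$truth)
    list(cohort = pan$cohort, refs = pan$refs, weights = weights,
         grs = risk, visits = phen$visits, births = phen$births,
         covariates = phen$covariates, truth = phen$truth)
}
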