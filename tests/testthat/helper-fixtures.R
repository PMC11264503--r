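## Shared fixtures and independent oracles, all built in code.

smallConfig <- function(seed = 1L, n_cohort = 80L, n_ref_per_pop = 30L,
                        n_snps_grs = 20L, n_snps_ancestry = 120L, ...) {
    simulationConfig(seed = seed, n_cohort = n_cohort,
                     n_ref_per_pop = n_ref_per_pop,
                     n_snps_grs = n_snps_grs,
                     n_snps_ancestry = n_snps_ancestry, ...)
}

## Quick DosageMatrix around a samples x variants numeric matrix.
makeDosage <- function(d, chrom = NULL, pos = NULL, a = "A", b = "G",
                       counted = NULL, ids = NULL) {
    M <- ncol(d)
    v <- data.frame(id = sprintf("v%03d", seq_len(M)),
                    chrom = chrom %||% rep("1", M),
                    pos = pos %||% seq_len(M) * 100L,
                    allele_a = rep_len(a, M), allele_b = rep_len(b, M),
                    counted_allele = counted %||% rep_len(b, M),
                    stringsAsFactors = FALSE)
    DosageMatrix(t(d), v,
                 sample_ids = ids %||% sprintf("S%03d", seq_len(nrow(d))))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Hudson-style Fst (ratio of averages) from pure frequency rows.
hudsonFst <- function(fa, fb) {
    num <- (fa - fb)^2
    den <- fa * (1 - fb) + fb * (1 - fa)
    sum(num) / sum(den)
}

## Independent Spearman oracle: midrank then Pearson.
spearmanOracle <- function(x, y) {
    stats::cor(rank(x), rank(y))
}

## Independent greedy LD-pruning oracle (slow, direct transcription of the
## rule: per window, repeatedly drop the higher-missingness member of the
## worst pair, ties to the later position).
prunedOracle <- function(d, window, step, r2max) {
    M <- nrow(d)
    keep <- rep(TRUE, M)
    nmiss <- rowSums(is.na(d))
    v <- apply(d, 1, stats::var, na.rm = TRUE)
    keep[!is.finite(v) | v < .Machine$double.eps] <- FALSE
    zero <- which(!keep)
    starts <- unique(c(seq(1, max(1, M - window + 1), by = step),
                       max(1, M - window + 1)))
    for (s in starts) {
        repeat {
            idx <- which(keep[s:min(s + window - 1, M)]) + s - 1
            if (length(idx) < 2) break
            worst <- c(NA, NA); wr2 <- r2max
            for (i in seq_along(idx)) for (j in seq_along(idx)) {
                if (i >= j) next
                r2 <- suppressWarnings(stats::cor(
                    d[idx[i], ], d[idx[j], ],
                    use = "pairwise.complete.obs"))^2
                if (!is.na(r2) && r2 > wr2) { wr2 <- r2; worst <- c(i, j) }
            }
            if (is.na(worst[1])) break
            pair <- idx[worst]
            out <- if (nmiss[pair[1]] > nmiss[pair[2]]) pair[1]
                   else if (nmiss[pair[2]] > nmiss[pair[1]]) pair[2]
                   else max(pair)
            keep[out] <- FALSE
        }
    }
    list(keep = which(keep), zero = zero)
}

## Minimal single-anchor ancestry-profile table for association tests.
makeProfiles <- function(ids, seed = 99) {
    set.seed(seed)
    n <- length(ids)
    gd <- stats::runif(n)
    gap <- stats::runif(n)
    data.frame(sample_id = ids, gd_EUR = gd,
               gd_tertile_EUR = as.character(assignTertiles(gd, "gd")),
               gap_EUR = gap,
               gap_tertile_EUR = as.character(assignTertiles(gap, "gap")),
               stringsAsFactors = FALSE)
}

## Random covariate table with realistic levels (no true outcome effects).
makeCovars <- function(ids, seed = 7) {
    set.seed(seed)
    n <- length(ids)
    data.frame(sample_id = ids,
               years_us = stats::rnorm(n, 23, 9),
               marital = sample(c("married_or_partner", "other"), n, TRUE),
               maternal_age = stats::rnorm(n, 28, 5.5),
               prepreg_bmi = stats::rnorm(n, 25, 5),
               parity = sample(c("parous", "nulliparous"), n, TRUE),
               fetal_sex = sample(c("male", "female"), n, TRUE),
               ga_delivery_weeks = stats::rnorm(n, 39.2, 1.5),
               stringsAsFactors = FALSE)
}

## One latent-outcome replicate for association calibration: phenotype-only
## generator world (no biometry), outcome = latent week-40 weight.
latentW40Rep <- function(seed, n = 600, growth_effect = 0,
                         birthweight_effect = 0) {
    strata <- if (growth_effect != 0 || birthweight_effect != 0)
        "target" else NULL
    cfg <- simulationConfig(
        seed = seed, n_cohort = n, growth_effect = growth_effect,
        birthweight_effect = birthweight_effect,
        effect_strata = if (!is.null(strata)) "target" else character(0))
    set.seed(seed * 11 + 3)
    grs <- stats::setNames(stats::rnorm(n), sprintf("W%04d", seq_len(n)))
    ph <- simulateLongitudinalPhenotypes(
        cfg, grs, strata = rep("target", n), biometry = FALSE)
    ids <- names(grs)
    list(weekly = data.frame(sample_id = ids,
                             w40 = ph$truth$latent_weekly[, "w40"],
                             stringsAsFactors = FALSE),
         births = ph$births,
         risk = data.frame(sample_id = ids, grs = unname(grs),
                           quartile = as.character(ph$truth$quartile),
                           stringsAsFactors = FALSE),
         covars = ph$covariates,
         profiles = makeProfiles(ids, seed = seed + 1))
}
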