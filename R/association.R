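## Stratified per-gestational-week association of GRS quartiles with fetal
## weight and birthweight, plus continuous interaction models. Ordinary
## least squares with classical (non-robust) Wald intervals; two-sided
## p-values; no multiplicity correction. Complete-case covariates.

.COVARS <- c("years_us", "marital", "maternal_age", "prepreg_bmi",
             "parity", "fetal_sex")

## Single OLS fit with automatic handling of degenerate designs:
## zero-variance covariates are dropped with a warning and the model
## refitted; remaining aliased columns likewise.
.fitOLS <- function(dat, outcome, rhs_terms, contrast_prefix = "quartile") {
    usable <- rhs_terms
    for (tm in rhs_terms) {
        v <- dat[[tm]]
        if ((is.character(v) || is.factor(v)) &&
            length(unique(v[!is.na(v)])) < 2L ||
            is.numeric(v) && stats::var(v, na.rm = TRUE) == 0) {
            warning("covariate '", tm, "' constant in stratum; dropped")
            usable <- setdiff(usable, tm)
        }
    }
    form <- stats::reformulate(usable, response = outcome)
    fit <- stats::lm(form, data = dat)
    if (anyNA(stats::coef(fit))) {
        bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
        drop_tm <- usable[vapply(usable, function(tm)
            any(startsWith(bad, tm)), logical(1))]
        drop_tm <- setdiff(drop_tm, grep(contrast_prefix, usable,
                                         value = TRUE))
        if (length(drop_tm)) {
            warning("aliased covariate(s) dropped: ",
                    paste(drop_tm, collapse = ", "))
            fit <- stats::lm(stats::reformulate(setdiff(usable, drop_tm),
                                                response = outcome),
                             data = dat)
        }
    }
    fit
}

.extractContrasts <- function(fit, pattern) {
    sm <- summary(fit)$coefficients
    ci <- suppressMessages(stats::confint(fit))
    rows <- grep(pattern, rownames(sm), value = TRUE)
    if (!length(rows)) return(NULL)
    data.frame(contrast = rows, beta = sm[rows, "Estimate"],
               ci_low = ci[rows, 1], ci_high = ci[rows, 2],
               p = sm[rows, "Pr(>|t|)"], n = length(stats::resid(fit)),
               row.names = NULL, stringsAsFactors = FALSE)
}

## Enumerate analysis strata from an ancestry-profile table: the whole
## cohort plus every anchor x tertile cell for both GD and GAP.
.strataList <- function(profiles) {
    anchors <- sub("^gd_", "",
                   grep("^gd_[A-Z]+$", names(profiles), value = TRUE))
    out <- list(list(type = "all", anchor = "all", level = "all",
                     idx = seq_len(nrow(profiles))))
    for (ty in c("gd", "gap")) for (a in anchors) {
        col <- paste0(ty, "_tertile_", a)
        for (lv in unique(profiles[[col]])) {
            out[[length(out) + 1L]] <-
                list(type = ty, anchor = a, level = lv,
                     idx = which(profiles[[col]] == lv))
        }
    }
    out
}

.assembleData <- function(outcomes, risk, profiles, covars) {
    d <- merge(outcomes, risk[, c("sample_id", "grs", "quartile")],
               by = "sample_id")
    d <- merge(d, profiles, by = "sample_id")
    d <- merge(d, covars, by = "sample_id")
    d$quartile <- factor(d$quartile, levels = c("Q1", "Q2", "Q3", "Q4"))
    cc <- stats::complete.cases(d[, .COVARS])
    if (any(!cc)) message(sum(!cc), " sample(s) dropped (incomplete covariates)")
    d[cc, , drop = FALSE]
}

#' Per-week stratified association of GRS quartiles with fetal weight
#'
#' Fits, independently for each gestational week and each stratum (whole
#' cohort plus every GD and GAP anchor-tertile cell), the linear model
#' `weight_week ~ Q2 + Q3 + Q4 + covariates` with quartile 1 as the
#' reference group; covariates are years lived in the US, marital status,
#' maternal age, pre-pregnancy BMI, parity and fetal sex. Strata smaller
#' than `guard` times the parameter count are skipped with a log entry.
#'
#' @param weekly a `WeeklyTrajectory` table (columns `w10` ... `w40`, or
#'   `zw*` when `outcome_scale = "sd"`).
#' @param risk risk-score table from [riskScoreResult()].
#' @param profiles ancestry-profile table from [ancestryProfiles()].
#' @param covars covariate table (see Details).
#' @param weeks integer weeks to model.
#' @param outcome_scale `"g"` (grams) or `"sd"` (per-week z-scores).
#' @param guard minimum samples per model parameter (default 10).
#' @return long `data.frame` of class `AssociationEstimates`: one row per
#'   stratum x week x contrast with `beta`, `ci_low`, `ci_high`, `p`, `n`;
#'   skipped strata in `attr(, "skipped")`.
#' @export
fitWeeklyModels <- function(weekly, risk, profiles, covars, weeks = 10:40,
                            outcome_scale = c("g", "sd"), guard = 10) {
    outcome_scale <- match.arg(outcome_scale)
    d <- .assembleData(weekly, risk, profiles, covars)
    pre <- if (outcome_scale == "sd") "zw" else "w"
    res <- list()
    skipped <- list()
    for (st in .strataList(d)) {
        sd_ <- d[st$idx, , drop = FALSE]
        npar <- 3 + length(.COVARS) + 1
        if (nrow(sd_) < guard * npar) {
            skipped[[length(skipped) + 1L]] <- data.frame(
                stratum_type = st$type, stratum_anchor = st$anchor,
                stratum_level = st$level, n = nrow(sd_),
                reason = "below sample guard")
            next
        }
        for (wk in weeks) {
            oc <- paste0(pre, wk)
            if (!oc %in% names(sd_))
                stop("outcome column ", oc, " not found", call. = FALSE)
            fit <- .fitOLS(sd_, oc, c("quartile", .COVARS))
            est <- .extractContrasts(fit, "^quartile")
            if (is.null(est)) next
            est$contrast <- sub("^quartile", "", est$contrast)
            est <- cbind(data.frame(stratum_type = st$type,
                                    stratum_anchor = st$anchor,
                                    stratum_level = st$level,
                                    outcome = paste0("week", wk)), est)
            res[[length(res) + 1L]] <- est
        }
    }
    out <- do.call(rbind, res) %||% data.frame()
    attr(out, "skipped") <- do.call(rbind, skipped) %||%
        data.frame(stratum_type = character(0))
    class(out) <- c("AssociationEstimates", class(out))
    out
}

#' Stratified association of GRS quartiles with birthweight
#'
#' As [fitWeeklyModels()] but with measured birthweight (grams) as the
#' outcome and gestational age at delivery added to the covariate set.
#'
#' @inheritParams fitWeeklyModels
#' @param births outcome table with `sample_id`, `birthweight_g`,
#'   `ga_delivery_weeks` (already part of `weekly` when assembled with
#'   [weeklyTrajectory()]).
#' @return long `data.frame` of class `AssociationEstimates`.
#' @export
fitBirthweightModels <- function(births, risk, profiles, covars,
                                 guard = 10) {
    d <- .assembleData(births, risk, profiles, covars)
    res <- list()
    skipped <- list()
    for (st in .strataList(d)) {
        sd_ <- d[st$idx, , drop = FALSE]
        npar <- 3 + length(.COVARS) + 2
        if (nrow(sd_) < guard * npar) {
            skipped[[length(skipped) + 1L]] <- data.frame(
                stratum_type = st$type, stratum_anchor = st$anchor,
                stratum_level = st$level, n = nrow(sd_),
                reason = "below sample guard")
            next
        }
        fit <- .fitOLS(sd_, "birthweight_g",
                       c("quartile", .COVARS, "ga_delivery_weeks"))
        est <- .extractContrasts(fit, "^quartile")
        if (is.null(est)) next
        est$contrast <- sub("^quartile", "", est$contrast)
        est <- cbind(data.frame(stratum_type = st$type,
                                stratum_anchor = st$anchor,
                                stratum_level = st$level,
                                outcome = "birthweight"), est)
        res[[length(res) + 1L]] <- est
    }
    out <- do.call(rbind, res) %||% data.frame()
    attr(out, "skipped") <- do.call(rbind, skipped) %||%
        data.frame(stratum_type = character(0))
    class(out) <- c("AssociationEstimates", class(out))
    out
}

#' Continuous GRS-by-modifier interaction models
#'
#' Fits, on the full cohort, `outcome ~ grs * modifier + covariates` for
#' each requested outcome and each continuous modifier (a GD or GAP
#' column); the Wald p-value of the product term is the reported
#' interaction p. A high design condition number triggers a collinearity
#' warning with diagnostics.
#'
#' @param outcomes outcome table (`WeeklyTrajectory` and/or birthweight
#'   columns).
#' @param risk,profiles,covars as in [fitWeeklyModels()].
#' @param outcome_cols character, outcome column names (e.g. `"w40"`,
#'   `"birthweight_g"`).
#' @param modifiers character, profile column names (e.g. `"gd_EUR"`,
#'   `"gap_AFR"`).
#' @param kappa_max condition-number guard.
#' @return long `data.frame` of class `AssociationEstimates`, one row per
#'   outcome x modifier with the product-term estimate.
#' @export
fitInteractionModels <- function(outcomes, risk, profiles, covars,
                                 outcome_cols,
                                 modifiers = grep("^(gd|gap)_[A-Z]+$",
                                                  names(profiles),
                                                  value = TRUE),
                                 kappa_max = 1e8) {
    d <- .assembleData(outcomes, risk, profiles, covars)
    if (stats::var(d$grs) == 0)
        stop("GRS is constant; interaction model undefined", call. = FALSE)
    res <- list()
    for (oc in outcome_cols) for (md in modifiers) {
        if (stats::var(d[[md]]) == 0)
            stop("modifier ", md, " is constant", call. = FALSE)
        rhs <- c("grs", md, paste0("grs:", md), .COVARS)
        if (oc == "birthweight_g") rhs <- c(rhs, "ga_delivery_weeks")
        form <- stats::reformulate(rhs, response = oc)
        mm <- stats::model.matrix(form, data = d)
        kap <- kappa(mm, exact = FALSE)
        if (kap > kappa_max)
            warning(sprintf(
                "ill-conditioned design for %s x %s (kappa = %.3g)",
                oc, md, kap))
        fit <- stats::lm(form, data = d)
        est <- .extractContrasts(fit, paste0("^grs:", md, "$"))
        if (is.null(est)) next
        est$contrast <- paste0("GRSx", md)
        est <- cbind(data.frame(stratum_type = "interaction",
                                stratum_anchor = sub("^(gd|gap)_", "", md),
                                stratum_level = sub("_.*$", "", md),
                                outcome = oc), est)
        res[[length(res) + 1L]] <- est
    }
    out <- do.call(rbind, res) %||% data.frame()
    attr(out, "skipped") <- data.frame(stratum_type = character(0))
    class(out) <- c("AssociationEstimates", class(out))
    out
}

#' Render tables and figures from association estimates
#'
#' Writes the long-format results table (significance flagged at p < 0.05,
#' no multiplicity correction), the skipped-strata table, per-stratum
#' effect-trajectory plots with 95% bands and a zero reference line, and a
#' forest-style birthweight plot.
#'
#' @param estimates an `AssociationEstimates` table (rows from the weekly,
#'   birthweight and interaction fitters may be concatenated with
#'   `rbind`).
#' @param dir output directory (created if needed).
#' @param figures also write figures (requires at least one estimate row).
#' @return invisible character vector of files written.
#' @export
renderReport <- function(estimates, dir, figures = TRUE) {
    if (!nrow(as.data.frame(estimates)))
        stop("estimates are empty", call. = FALSE)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    est <- as.data.frame(estimates)
    est$significant <- est$p < 0.05
    files <- character(0)
    f <- file.path(dir, "association_results.tsv")
    writeTSV(est, f)
    files <- c(files, f)
    sk <- attr(estimates, "skipped")
    if (!is.null(sk) && nrow(sk)) {
        f <- file.path(dir, "skipped_strata.tsv")
        writeTSV(sk, f)
        files <- c(files, f)
    }
    if (figures) {
        wk <- est[grepl("^week", est$outcome), , drop = FALSE]
        if (nrow(wk)) {
            wk$week <- as.integer(sub("week", "", wk$outcome))
            wk$stratum <- paste(wk$stratum_anchor, wk$stratum_level)
            pl <- ggplot2::ggplot(wk, ggplot2::aes(
                      x = week, y = beta, colour = contrast,
                      fill = contrast)) +
                ggplot2::geom_hline(yintercept = 0, linetype = 2) +
                ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_low,
                                                  ymax = ci_high),
                                     alpha = 0.15, colour = NA) +
                ggplot2::geom_line() +
                ggplot2::facet_wrap(~stratum) +
                ggplot2::labs(x = "Gestational week",
                              y = "Effect on fetal weight vs Q1",
                              title = "GRS quartile effect trajectories") +
                ggplot2::theme_minimal()
            f <- file.path(dir, "weekly_effects.pdf")
            suppressMessages(ggplot2::ggsave(f, pl, width = 11,
                                             height = 8))
            files <- c(files, f)
        }
        bw <- est[est$outcome == "birthweight", , drop = FALSE]
        if (nrow(bw)) {
            bw$stratum <- paste(bw$stratum_anchor, bw$stratum_level,
                                bw$contrast)
            pl <- ggplot2::ggplot(bw, ggplot2::aes(
                      x = beta, y = stratum, colour = significant)) +
                ggplot2::geom_vline(xintercept = 0, linetype = 2) +
                ggplot2::geom_point() +
                ggplot2::geom_errorbarh(ggplot2::aes(xmin = ci_low,
                                                     xmax = ci_high),
                                        height = 0.2) +
                ggplot2::labs(x = "Birthweight difference vs Q1 (g)",
                              y = NULL,
                              title = "Birthweight associations") +
                ggplot2::theme_minimal()
            f <- file.path(dir, "birthweight_forest.pdf")
            suppressMessages(ggplot2::ggsave(
                f, pl, width = 8,
                height = max(4, 0.25 * nrow(bw))))
            files <- c(files, f)
        }
    }
    invisible(files)
}
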