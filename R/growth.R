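## Fetal-growth trajectory estimation: log estimated fetal weight modelled
## by a linear mixed model with a natural cubic-spline mean structure and a
## cubic-polynomial subject random effect; per-woman weight at integer
## weeks 10-40 by empirical-Bayes (BLUP) prediction.

#' Fit the fetal-growth mixed model
#'
#' Fits, by REML,
#' \deqn{\log w_{ij} = B(t_{ij})^\top\beta +
#'   (1,\tilde t_{ij}, \tilde t_{ij}^2, \tilde t_{ij}^3)^\top b_i
#'   + \epsilon_{ij},\qquad b_i \sim N(0, G),\ \epsilon \sim N(0,\sigma^2)}
#' where \eqn{B} is a natural cubic spline over gestational weeks with
#' interior knots at `knots` and boundary knots at `boundary`, and
#' \eqn{\tilde t = (t - 25)/15} is the centred/scaled week. Estimated
#' fetal weight is computed with [hadlockEFW()] when not already present.
#' Subjects with fewer than two visits are excluded with a message;
#' optimizer non-convergence is reported, never silently accepted.
#'
#' @param visits `data.frame` with `sample_id`, `ga_weeks`, and either
#'   `efw_g` or the biometry columns `hc_cm`, `ac_cm`, `fl_cm`.
#' @param knots interior knots (weeks).
#' @param boundary boundary knots (weeks).
#' @param control an [lme4::lmerControl()]; the default uses `bobyqa`.
#' @return a [TrajectoryModel-class].
#' @export
fitTrajectoryModel <- function(visits, knots = c(16, 24, 32),
                               boundary = c(10, 40),
                               control = lme4::lmerControl(
                                   optimizer = "bobyqa",
                                   calc.derivs = FALSE)) {
    visits <- as.data.frame(visits)
    if (!"efw_g" %in% names(visits))
        visits$efw_g <- hadlockEFW(visits$hc_cm, visits$ac_cm,
                                   visits$fl_cm)
    nv <- table(visits$sample_id)
    few <- names(nv)[nv < 2]
    if (length(few)) {
        message(length(few), " subject(s) with < 2 visits excluded")
        visits <- visits[!visits$sample_id %in% few, , drop = FALSE]
    }
    if (!nrow(visits)) stop("no subjects with >= 2 visits", call. = FALSE)
    dat <- data.frame(id = factor(visits$sample_id),
                      ga = visits$ga_weeks,
                      y = log(visits$efw_g))
    dat$tc <- (dat$ga - 25) / 15
    B <- splines::ns(dat$ga, knots = knots, Boundary.knots = boundary)
    dat <- cbind(dat, stats::setNames(as.data.frame(unclass(B)),
                                      paste0("B", seq_len(ncol(B)))))
    fx <- paste(paste0("B", seq_len(ncol(B))), collapse = " + ")
    form <- stats::as.formula(paste(
        "y ~", fx, "+ (1 + tc + I(tc^2) + I(tc^3) | id)"))
    fit <- lme4::lmer(form, data = dat, REML = TRUE, control = control)
    msgs <- unlist(fit@optinfo$conv$lme4$messages %||% character(0))
    ## boundary (singular) G estimates are legitimate; optimizer failure
    ## and gradient warnings are not
    bad <- msgs[!grepl("boundary \\(singular\\)", msgs)]
    conv <- fit@optinfo$conv$opt == 0 && length(bad) == 0L
    if (!conv)
        warning("trajectory model did not cleanly converge: ",
                paste(bad, collapse = "; "))
    G <- matrix(as.numeric(lme4::VarCorr(fit)$id), 4, 4,
                dimnames = list(c("int", "lin", "quad", "cubic"),
                                c("int", "lin", "quad", "cubic")))
    new("TrajectoryModel", fit = fit,
        beta = lme4::fixef(fit), G = G, sigma2 = stats::sigma(fit)^2,
        knots = knots, boundary = boundary, centerWeek = 25,
        scaleWeek = 15, converged = conv,
        nSubjects = length(unique(dat$id)), nVisits = nrow(dat))
}

#' Population mean curve of a fitted trajectory model
#'
#' @param model a [TrajectoryModel-class].
#' @param weeks gestational weeks at which to evaluate.
#' @param scale `"log"` (log-grams) or `"g"` (grams).
#' @return numeric vector of mean-curve values.
#' @export
meanCurve <- function(model, weeks = 10:40, scale = c("log", "g")) {
    scale <- match.arg(scale)
    B <- cbind(1, splines::ns(weeks, knots = model@knots,
                              Boundary.knots = model@boundary))
    lw <- drop(B %*% model@beta)
    if (scale == "g") exp(lw) else lw
}

#' Per-woman fetal weight at integer gestational weeks
#'
#' Combines the fitted mean curve with each subject's empirical-Bayes
#' (BLUP) random effects and exponentiates, giving strictly positive
#' weights at every requested week. Optionally appends per-week
#' z-standardized weights (cohort mean 0, SD 1 at each week) for SD-unit
#' effect reporting.
#'
#' @param model a [TrajectoryModel-class].
#' @param weeks integer weeks within 10--40 (requests outside are an
#'   error).
#' @param standardize also return per-week z-scores (columns `zw<week>`).
#' @return `data.frame` of class `WeeklyTrajectory`: `sample_id` plus one
#'   `w<week>` column per week.
#' @export
predictWeekly <- function(model, weeks = 10:40, standardize = FALSE) {
    stopifnot(is(model, "TrajectoryModel"))
    if (any(weeks < 10 | weeks > 40))
        stop("prediction requested outside weeks 10-40", call. = FALSE)
    re <- lme4::ranef(model@fit)$id
    ids <- rownames(re)
    B <- cbind(1, splines::ns(weeks, knots = model@knots,
                              Boundary.knots = model@boundary))
    mean_lw <- drop(B %*% model@beta)
    tc <- (weeks - model@centerWeek) / model@scaleWeek
    Zt <- rbind(1, tc, tc^2, tc^3)
    lw <- matrix(mean_lw, nrow(re), length(weeks), byrow = TRUE) +
        as.matrix(re) %*% Zt
    W <- exp(lw)
    colnames(W) <- paste0("w", weeks)
    out <- data.frame(sample_id = ids, W, stringsAsFactors = FALSE,
                      check.names = FALSE)
    if (standardize) {
        Z <- scale(W)
        colnames(Z) <- paste0("z", colnames(W))
        out <- cbind(out, as.data.frame(Z, check.names = FALSE))
    }
    class(out) <- c("WeeklyTrajectory", class(out))
    rownames(out) <- NULL
    out
}

#' Assemble the weekly-trajectory outcome table
#'
#' Merges the weekly predictions with delivery records.
#'
#' @param weekly a `WeeklyTrajectory` from [predictWeekly()].
#' @param births `data.frame` with `sample_id`, `birthweight_g`,
#'   `ga_delivery_weeks`.
#' @return merged `data.frame` (class `WeeklyTrajectory`).
#' @export
weeklyTrajectory <- function(weekly, births) {
    out <- merge(as.data.frame(weekly), births, by = "sample_id",
                 sort = TRUE)
    class(out) <- c("WeeklyTrajectory", "data.frame")
    out
}
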