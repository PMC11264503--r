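## Hadlock estimated fetal weight and its inverse along a fixed allometric
## ratio. The three-parameter HC/AC/FL equation is used throughout:
##   log10(EFW) = 1.326 - 0.00326*AC*FL + 0.0107*HC + 0.0438*AC + 0.158*FL
## with measures in centimetres and EFW in grams.

.HADLOCK_BOUNDS <- list(hc = c(5, 40), ac = c(5, 45), fl = c(0.5, 9))

## Reference biometry medians by gestational week (cm), used only to fix
## the allometric proportions when back-solving biometry from a target
## weight. Monotone-spline interpolated.
.BIOMETRY_REF <- data.frame(
    ga = c(10, 12, 16, 20, 24, 28, 32, 36, 40, 42),
    hc = c(5.5, 7.0, 12.0, 17.5, 22.0, 26.0, 29.5, 32.5, 34.5, 35.2),
    ac = c(4.5, 5.6, 10.5, 15.0, 19.5, 23.5, 27.5, 31.5, 35.0, 36.5),
    fl = c(0.55, 0.8, 2.0, 3.3, 4.4, 5.3, 6.2, 6.9, 7.6, 7.9))

refBiometry <- function(ga) {
    f <- function(col) stats::splinefun(.BIOMETRY_REF$ga, .BIOMETRY_REF[[col]],
                                        method = "monoH.FC")(ga)
    data.frame(hc = f("hc"), ac = f("ac"), fl = f("fl"))
}

#' Hadlock estimated fetal weight
#'
#' Applies the three-parameter Hadlock regression of log10 fetal weight on
#' head circumference, abdominal circumference and femur length. Inputs are
#' checked against plausibility bounds (HC 5--40, AC 5--45, FL 0.5--9 cm);
#' an out-of-bounds value is an error naming the offending measure.
#'
#' @param hc,ac,fl head circumference, abdominal circumference, femur
#'   length (cm); vectors are recycled to a common length.
#' @return estimated fetal weight in grams.
#' @examples
#' hadlockEFW(30, 26, 5.5)
#' @export
hadlockEFW <- function(hc, ac, fl) {
    n <- max(length(hc), length(ac), length(fl))
    hc <- rep_len(hc, n); ac <- rep_len(ac, n); fl <- rep_len(fl, n)
    for (m in c("hc", "ac", "fl")) {
        x <- get(m)
        lim <- .HADLOCK_BOUNDS[[m]]
        if (any(!is.finite(x)) || any(x < lim[1] | x > lim[2]))
            stop(sprintf("%s out of plausibility bounds [%g, %g] cm",
                         toupper(m), lim[1], lim[2]), call. = FALSE)
    }
    10^(1.326 - 0.00326 * ac * fl + 0.0107 * hc + 0.0438 * ac + 0.158 * fl)
}

#' Back-solve biometry from a target fetal weight
#'
#' Given a target weight and gestational age, scales the gestational
#' age--specific reference biometry (HC, AC, FL in fixed proportion) by a
#' common factor so that [hadlockEFW()] reproduces the target exactly. The
#' scale is found by root-finding on the interval where the Hadlock
#' response is increasing in the common factor (the \eqn{-0.00326\,AC\,FL}
#' term makes it eventually decreasing).
#'
#' @param weight_g target fetal weight(s), grams.
#' @param ga_weeks gestational age(s), weeks.
#' @param clamp when the target falls outside the weight range
#'   representable within the plausibility bounds (about 47 g at the low
#'   end), clamp to the nearest attainable weight instead of erroring;
#'   the number of clamped targets is attached as `attr(, "clamped")`.
#' @return `data.frame` with columns `hc`, `ac`, `fl` (cm).
#' @export
hadlockInvert <- function(weight_g, ga_weeks, clamp = FALSE) {
    n <- max(length(weight_g), length(ga_weeks))
    weight_g <- rep_len(weight_g, n)
    ga_weeks <- rep_len(ga_weeks, n)
    ref <- refBiometry(ga_weeks)
    out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("hc", "ac", "fl")))
    lo <- vapply(.HADLOCK_BOUNDS, `[`, numeric(1), 1) * 1.002
    hi_b <- vapply(.HADLOCK_BOUNDS, `[`, numeric(1), 2) * 0.998
    n_clamped <- 0L
    for (i in seq_len(n)) {
        ref_i <- c(hc = ref$hc[i], ac = ref$ac[i], fl = ref$fl[i])
        lt <- log10(weight_g[i])
        pinned <- c(hc = NA_real_, ac = NA_real_, fl = NA_real_)
        ## solve the common scale; measures hitting a plausibility bound
        ## are pinned there and the scale re-solved over the rest, so the
        ## Hadlock formula still reproduces the target weight exactly
        for (pass in 1:3) {
            free <- is.na(pinned)
            val <- function(s) ifelse(free, s * ref_i, pinned)
            g <- function(s) {
                v <- val(s)
                1.326 - 0.00326 * v["ac"] * v["fl"] + 0.0107 * v["hc"] +
                    0.0438 * v["ac"] + 0.158 * v["fl"] - lt
            }
            if (!any(free)) break
            ## stay left of the turning point of the AC*FL cross term
            s_hi <- 3
            if (free[["ac"]] && free[["fl"]])
                s_hi <- 0.98 * (0.0107 * ref_i[["hc"]] * free[["hc"]] +
                                0.0438 * ref_i[["ac"]] +
                                0.158 * ref_i[["fl"]]) /
                    (2 * 0.00326 * ref_i[["ac"]] * ref_i[["fl"]])
            ## attainable range given the pins: the response increases in
            ## every in-bounds measure, so the extremes sit at the bounds
            g_lo <- {
                pl <- pinned; pl[free] <- lo[free]
                1.326 - 0.00326 * pl["ac"] * pl["fl"] +
                    0.0107 * pl["hc"] + 0.0438 * pl["ac"] +
                    0.158 * pl["fl"] - lt
            }
            if (g_lo > 0 || g(s_hi) < 0) {
                if (!clamp)
                    stop("target weight ", round(weight_g[i]),
                         " g not attainable at ", round(ga_weeks[i], 1),
                         " weeks", call. = FALSE)
                n_clamped <- n_clamped + 1L
                pinned[free] <- if (g_lo > 0) lo[free] else
                    pmin(val(s_hi)[free], hi_b[free])
                break
            }
            ## g(0.02) < g at the lower bounds <= 0 <= g(s_hi): bracketed
            s <- stats::uniroot(g, c(0.02, s_hi), tol = 1e-12)$root
            v <- val(s)
            viol <- free & (v < lo | v > hi_b)
            if (!any(viol)) { pinned[free] <- v[free]; break }
            pinned[viol] <- pmin(pmax(v[viol], lo[viol]), hi_b[viol])
        }
        out[i, ] <- pinned[c("hc", "ac", "fl")]
    }
    out <- as.data.frame(out)
    attr(out, "clamped") <- n_clamped
    out
}
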