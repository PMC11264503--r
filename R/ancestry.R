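## Genetic distance (GD) via per-anchor PCA projection, genetic ancestry
## proportion (GAP) via a supervised-frequency admixture EM, LD pruning,
## tertile stratification and the GD-GAP correlation summary.

#' Greedy sliding-window LD pruning
#'
#' Walks windows of `window` variants advancing by `step`; within each
#' window, while any retained pair has squared correlation above `r2_max`,
#' the member of the worst pair with higher missingness is dropped (ties
#' broken toward the later position). Zero-variance variants are dropped
#' up front with a message.
#'
#' @param x a [DosageMatrix-class] (>= 2 variants).
#' @param window,step window and step sizes, in variant counts
#'   (`window >= step >= 1`).
#' @param r2_max squared-correlation threshold in (0, 1].
#' @return list of class `PruneResult`: `keep` (retained variant indices),
#'   `dropped_ld`, `dropped_zero_var`, and the parameters.
#' @export
ldPrune <- function(x, window = 50L, step = 5L, r2_max = 0.1) {
    stopifnot(is(x, "DosageMatrix"))
    M <- nrow(x)
    if (M < 2L) stop("need at least 2 variants", call. = FALSE)
    window <- assertCount(window, "window")
    step <- assertCount(step, "step")
    if (window < step) stop("window must be >= step", call. = FALSE)
    if (!is.finite(r2_max) || r2_max <= 0 || r2_max > 1)
        stop("r2_max must lie in (0, 1]", call. = FALSE)
    d <- dosages(x)
    v <- unname(apply(d, 1, stats::var, na.rm = TRUE))
    zero <- which(!is.finite(v) | v < .Machine$double.eps)
    if (length(zero))
        message(length(zero), " zero-variance variant(s) auto-dropped")
    keep <- rep(TRUE, M)
    keep[zero] <- FALSE
    nmiss <- rowSums(is.na(d))
    starts <- unique(c(seq(1L, max(1L, M - window + 1L), by = step),
                       max(1L, M - window + 1L)))
    for (s in starts) {
        idx <- which(keep[s:min(s + window - 1L, M)]) + s - 1L
        if (length(idx) < 2L) next
        r2 <- suppressWarnings(
            stats::cor(t(d[idx, , drop = FALSE]),
                       use = "pairwise.complete.obs"))^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        while (max(r2) > r2_max) {
            w <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
            pair <- idx[w]
            drop_local <- if (nmiss[pair[1]] > nmiss[pair[2]]) w[1]
                          else if (nmiss[pair[2]] > nmiss[pair[1]]) w[2]
                          else max(w)           # tie -> later position
            keep[idx[drop_local]] <- FALSE
            r2[drop_local, ] <- 0
            r2[, drop_local] <- 0
        }
    }
    structure(list(keep = which(keep), dropped_ld = which(!keep &
                       !(seq_len(M) %in% zero)),
                   dropped_zero_var = zero, r2_max = r2_max,
                   window = window, step = step),
              class = "PruneResult")
}

#' @export
print.PruneResult <- function(x, ...) {
    cat("PruneResult:", length(x$keep), "variants kept;",
        length(x$dropped_ld), "dropped by LD,",
        length(x$dropped_zero_var), "zero-variance\n")
    cat("  window", x$window, "step", x$step, "r2_max", x$r2_max, "\n")
    invisible(x)
}

#' Reference-panel PCA for genetic distance
#'
#' Standardizes the panel's dosages per SNP by its own allele frequency
#' (centre \eqn{2\hat p}, scale \eqn{\sqrt{2\hat p(1-\hat p)}}; monomorphic
#' SNPs excluded), extracts the top `k` principal axes by SVD, and stores
#' the centroid of the panel's own projections (zero by construction).
#'
#' @param x a [DosageMatrix-class] reference panel with at least `k + 1`
#'   samples.
#' @param k number of principal axes.
#' @param anchor label for the panel.
#' @return a [ReferenceProjection-class].
#' @export
fitReferencePCA <- function(x, k = 10L, anchor = "REF") {
    stopifnot(is(x, "DosageMatrix"))
    k <- assertCount(k, "k")
    d <- t(dosages(x))                           # samples x SNPs
    if (nrow(d) < k + 1L)
        stop("reference panel must have at least k + 1 samples",
             call. = FALSE)
    ph <- colMeans(d, na.rm = TRUE) / 2
    poly <- ph > 0 & ph < 1
    if (any(!poly))
        message(sum(!poly), " monomorphic SNP(s) excluded from the PCA")
    d <- d[, poly, drop = FALSE]
    ph <- ph[poly]
    ctr <- 2 * ph
    scl <- sqrt(2 * ph * (1 - ph))
    Z <- sweep(sweep(d, 2, ctr), 2, scl, "/")
    Z[is.na(Z)] <- 0
    rk <- min(dim(Z)) - 1L
    if (k > rk)
        stop("k = ", k, " exceeds available rank ", rk, call. = FALSE)
    sv <- svd(Z, nu = k, nv = k)
    proj_ref <- Z %*% sv$v
    v <- variantInfo(x)[poly, , drop = FALSE]
    new("ReferenceProjection", anchor = anchor,
        variantKey = variantKey(v$chrom, v$pos, v$allele_a, v$allele_b),
        countedAllele = v$counted_allele,
        center = unname(ctr), scale = unname(scl),
        loadings = unname(sv$v), centroid = colMeans(proj_ref),
        varExplained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
        nRef = nrow(d))
}

#' Genetic distance to a reference anchor
#'
#' Standardizes each cohort sample with the reference panel's constants,
#' projects it onto the panel's principal axes, and returns the Euclidean
#' distance from the panel centroid in that k-dimensional space. Cohort
#' variants are matched on (chrom, pos, allele pair) and flipped where the
#' counted allele differs; missing dosages are centred (contribute zero).
#'
#' @param x cohort [DosageMatrix-class].
#' @param proj a [ReferenceProjection-class].
#' @param min_overlap minimum fraction of projection SNPs that must be
#'   present in the cohort (default 0.8).
#' @return named numeric vector of distances, one per sample.
#' @export
geneticDistance <- function(x, proj, min_overlap = 0.8) {
    stopifnot(is(x, "DosageMatrix"), is(proj, "ReferenceProjection"))
    v <- variantInfo(x)
    key <- variantKey(v$chrom, v$pos, v$allele_a, v$allele_b)
    idx <- match(proj@variantKey, key)
    ok <- !is.na(idx)
    frac <- mean(ok)
    if (frac < min_overlap)
        stop(sprintf(
            "only %.1f%% of projection SNPs present in cohort (need %.0f%%)",
            100 * frac, 100 * min_overlap), call. = FALSE)
    d <- dosages(x)[idx[ok], , drop = FALSE]
    flip <- v$counted_allele[idx[ok]] != proj@countedAllele[ok]
    d[flip, ] <- 2 - d[flip, , drop = FALSE]
    Z <- (d - proj@center[ok]) / proj@scale[ok]
    Z[is.na(Z)] <- 0
    P <- crossprod(Z, proj@loadings[ok, , drop = FALSE])  # samples x k
    gd <- sqrt(rowSums(sweep(P, 2, proj@centroid)^2))
    stats::setNames(gd, colnames(x))
}

#' Component allele frequencies from labeled reference panels
#'
#' Estimates per-component allele frequencies (the supervised analogue of
#' the admixture F matrix) as the counted-allele frequency within each
#' panel, clipped to \[0.01, 0.99\] to keep the binomial log-likelihood
#' finite.
#'
#' @param refs named list of [DosageMatrix-class] panels sharing a variant
#'   set.
#' @param clip two-sided clipping bounds.
#' @return K x M frequency matrix with anchors as rows; variant keys and
#'   counted alleles attached as attributes.
#' @export
referenceFrequencies <- function(refs, clip = c(0.01, 0.99)) {
    f <- t(vapply(refs, function(r) rowMeans(dosages(r), na.rm = TRUE) / 2,
                  numeric(nrow(refs[[1]]))))
    f <- pmin(pmax(f, clip[1]), clip[2])
    v <- variantInfo(refs[[1]])
    attr(f, "variantKey") <- variantKey(v$chrom, v$pos, v$allele_a,
                                        v$allele_b)
    attr(f, "countedAllele") <- v$counted_allele
    f
}

#' Genetic ancestry proportions by supervised admixture EM
#'
#' For each sample independently, maximizes the binomial admixture
#' log-likelihood
#' \deqn{\ell(q) = \sum_j [\,g_j \log p_j + (2-g_j)\log(1-p_j)\,],\quad
#'       p_j = \sum_k q_k f_{kj}}
#' over the K-simplex with the component frequencies fixed from labeled
#' reference panels, via the EM update
#' \eqn{q_k \leftarrow \frac{1}{2M'}\sum_j a_{jk}} with
#' \eqn{a_{jk} = g_j q_k f_{kj}/p_j + (2-g_j) q_k(1-f_{kj})/(1-p_j)}.
#' Iteration stops when every sample's log-likelihood gain falls below
#' `tol` or at `max_iter`. A decreasing step (beyond numerical tolerance)
#' aborts; identical component frequencies make the likelihood flat and are
#' flagged with uniform proportions returned.
#'
#' @param x cohort [DosageMatrix-class] (typically LD-pruned).
#' @param ref_freqs K x M frequency matrix from [referenceFrequencies()]
#'   (matched to `x` by variant key, flipped as needed).
#' @param tol per-sample log-likelihood convergence tolerance; converged
#'   samples are frozen while the rest keep iterating.
#' @param max_iter iteration cap.
#' @param trace keep the per-iteration log-likelihood matrix.
#' @return list of class `GAPResult`: `q` (n x K, rows sum to 1),
#'   `loglik`, `iterations`, `converged`, `identifiable`, and optionally
#'   `trace`.
#' @export
estimateGAP <- function(x, ref_freqs, tol = 1e-5, max_iter = 2000L,
                        trace = FALSE) {
    stopifnot(is(x, "DosageMatrix"))
    v <- variantInfo(x)
    key <- variantKey(v$chrom, v$pos, v$allele_a, v$allele_b)
    fkey <- attr(ref_freqs, "variantKey") %||% colnames(ref_freqs)
    idx <- match(key, fkey)
    ok <- !is.na(idx)
    if (!any(ok))
        stop("no SNP overlap between cohort and component frequencies",
             call. = FALSE)
    Fm <- ref_freqs[, idx[ok], drop = FALSE]
    fca <- attr(ref_freqs, "countedAllele")
    G <- t(dosages(x)[ok, , drop = FALSE])          # samples x SNPs
    if (!is.null(fca)) {
        flip <- v$counted_allele[ok] != fca[idx[ok]]
        G[, flip] <- 2 - G[, flip, drop = FALSE]
    }
    K <- nrow(Fm)
    n <- nrow(G)
    flat <- max(apply(Fm, 2, function(col) diff(range(col)))) < 1e-12
    if (flat) {
        warning("component frequencies are identical: ancestry proportions",
                " unidentifiable; returning uniform")
        q <- matrix(1 / K, n, K, dimnames = list(rownames(G), rownames(Fm)))
        return(structure(list(q = q, loglik = rep(NA_real_, n),
                              iterations = 0L, converged = TRUE,
                              identifiable = FALSE), class = "GAPResult"))
    }
    miss <- is.na(G)
    G0 <- G; G0[miss] <- 0
    G2 <- 2 - G; G2[miss] <- 0
    tF <- t(Fm); tF1 <- 1 - tF
    Q <- matrix(1 / K, n, K)
    ll_of <- function(Qa, rows) {
        P <- Qa %*% Fm
        P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
        rowSums(G0[rows, , drop = FALSE] * log(P) +
                G2[rows, , drop = FALSE] * log1p(-P))
    }
    ll <- ll_of(Q, seq_len(n))
    tr <- if (trace) list(ll) else NULL
    it <- 0L
    active <- rep(TRUE, n)   # converged samples are frozen
    while (it < max_iter && any(active)) {
        it <- it + 1L
        rows <- which(active)
        Qa <- Q[rows, , drop = FALSE]
        P <- Qa %*% Fm
        P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
        Qn <- Qa * ((G0[rows, , drop = FALSE] / P) %*% tF +
                    (G2[rows, , drop = FALSE] / (1 - P)) %*% tF1)
        Qn <- Qn / rowSums(Qn)
        ll_new <- ll_of(Qn, rows)
        if (any(ll_new < ll[rows] - 1e-8 * (abs(ll[rows]) + 1)))
            stop("EM contract violated: log-likelihood decreased",
                 call. = FALSE)
        gain <- ll_new - ll[rows]
        Q[rows, ] <- Qn
        ll[rows] <- ll_new
        active[rows[gain < tol]] <- FALSE
        if (trace) tr[[length(tr) + 1L]] <- ll
    }
    converged <- !any(active)
    dimnames(Q) <- list(colnames(x), rownames(Fm))
    out <- list(q = Q, loglik = ll, iterations = it, converged = converged,
                identifiable = TRUE)
    if (trace) out$trace <- do.call(rbind, tr)
    structure(out, class = "GAPResult")
}

#' @export
print.GAPResult <- function(x, ...) {
    cat("GAPResult:", nrow(x$q), "samples x", ncol(x$q), "components;",
        x$iterations, "EM iterations; converged:", x$converged, "\n")
    cat("  mean proportions:",
        paste(sprintf("%s=%.3f", colnames(x$q), colMeans(x$q)),
              collapse = " "), "\n")
    invisible(x)
}

#' Tertile stratification
#'
#' Cuts at the 33.3/66.7 empirical percentiles (linear-interpolation
#' quantiles), boundary ties to the lower tertile. Genetic-distance labels
#' are closest/middle/farthest; ancestry-proportion labels are
#' lowest/medium/highest.
#'
#' @param values numeric with at least 3 distinct values.
#' @param type `"gd"` or `"gap"` label set.
#' @return factor of tertile labels.
#' @export
assignTertiles <- function(values, type = c("gd", "gap")) {
    labels <- switch(match.arg(type),
                     gd = c("closest", "middle", "farthest"),
                     gap = c("lowest", "medium", "highest"))
    rankedGroups(values, probs = c(1, 2) / 3, labels = labels)
}

#' Per-sample ancestry profile table
#'
#' Assembles GD to each anchor with tertile labels and the GAP vector with
#' tertile labels into one table.
#'
#' @param gd n x 4 matrix of distances (columns named by anchor).
#' @param gap n x 4 matrix of ancestry proportions (columns named by
#'   anchor).
#' @param sample_ids sample identifiers.
#' @return `data.frame` with columns `gd_<anchor>`, `gd_tertile_<anchor>`,
#'   `gap_<anchor>`, `gap_tertile_<anchor>`.
#' @export
ancestryProfiles <- function(gd, gap, sample_ids = rownames(gd)) {
    stopifnot(ncol(gd) == ncol(gap))
    anchors <- colnames(gd)
    out <- data.frame(sample_id = sample_ids %||%
                          sprintf("S%04d", seq_len(nrow(gd))),
                      stringsAsFactors = FALSE)
    for (a in anchors) {
        out[[paste0("gd_", a)]] <- gd[, a]
        out[[paste0("gd_tertile_", a)]] <-
            as.character(assignTertiles(gd[, a], "gd"))
    }
    for (a in anchors) {
        out[[paste0("gap_", a)]] <- gap[, a]
        out[[paste0("gap_tertile_", a)]] <-
            as.character(assignTertiles(gap[, a], "gap"))
    }
    out
}

#' Spearman correlation between GD and GAP measures
#'
#' Rank-based (midrank ties) correlation across all eight GD/GAP columns
#' with large-sample p-values. Constant columns give `NA` coefficients.
#'
#' @param profiles the table from [ancestryProfiles()] (>= 10 samples).
#' @return list of class `GDGAPCorrelation` with `rho` and `p` (8 x 8
#'   matrices).
#' @export
gdGapCorrelation <- function(profiles) {
    cols <- grep("^(gd|gap)_(?!tertile)", names(profiles), value = TRUE,
                 perl = TRUE)
    X <- as.matrix(profiles[, cols])
    if (nrow(X) < 10) stop("need at least 10 samples", call. = FALSE)
    p <- ncol(X)
    rho <- pv <- matrix(NA_real_, p, p, dimnames = list(cols, cols))
    for (i in seq_len(p)) for (j in seq_len(p)) {
        if (stats::sd(X[, i]) == 0 || stats::sd(X[, j]) == 0) next
        ct <- suppressWarnings(
            stats::cor.test(X[, i], X[, j], method = "spearman",
                            exact = FALSE))
        rho[i, j] <- unname(ct$estimate)
        pv[i, j] <- ct$p.value
    }
    structure(list(rho = rho, p = pv), class = "GDGAPCorrelation")
}

#' @export
print.GDGAPCorrelation <- function(x, ...) {
    cat("GD-GAP Spearman correlation (", nrow(x$rho), "x", ncol(x$rho),
        ")\n", sep = "")
    print(round(x$rho, 2))
    invisible(x)
}
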