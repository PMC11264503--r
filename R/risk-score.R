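#' Weighted genetic risk score
#'
#' Computes, per sample, the weighted T2D genetic risk score
#' \deqn{GRS_i = \sum_j d_{ij}\,\log OR_j}
#' where \eqn{d_{ij}} is the dosage of the T2D-increasing (effect) allele.
#' The dosage matrix must already be harmonized to the weight table (see
#' [harmonizeToWeights()]); rows are matched to weights by variant id and a
#' mismatch is an error. Missing dosages are excluded SNP-wise from the sum
#' (simple sum over non-missing SNPs); `scale_per_snp = TRUE` divides each
#' score by its `n_snps_used` for cohorts with heavy missingness.
#'
#' @param x a harmonized [DosageMatrix-class].
#' @param weights the matching effect-weight table.
#' @param scale_per_snp report mean-per-SNP score instead of the raw sum.
#' @return `data.frame` with `sample_id`, `grs`, `n_snps_used`.
#' @examples
#' v <- data.frame(id = "rs1", chrom = "1", pos = 1L, allele_a = "A",
#'                 allele_b = "G", counted_allele = "G")
#' w <- effectWeightTable(data.frame(id = "rs1", chrom = "1", pos = 1L,
#'       effect_allele = "G", other_allele = "A", weight = 0.15))
#' dm <- DosageMatrix(matrix(c(0, 2), 1, 2), v, c("a", "b"))
#' computeGRS(dm, w)$grs  # 0.00 0.30
#' @export
computeGRS <- function(x, weights, scale_per_snp = FALSE) {
    stopifnot(is(x, "DosageMatrix"))
    weights <- effectWeightTable(weights)
    if (nrow(x) != nrow(weights) ||
        !identical(rownames(x), as.character(weights$id)))
        stop("dosage rows do not match the weight table; run ",
             "harmonizeToWeights() first", call. = FALSE)
    v <- variantInfo(x)
    if (!identical(v$counted_allele, weights$effect_allele))
        stop("counted allele differs from effect allele; run ",
             "harmonizeToWeights() first", call. = FALSE)
    d <- dosages(x)
    miss <- is.na(d)
    d[miss] <- 0
    grs <- drop(crossprod(d, weights$weight))
    n_used <- nrow(d) - colSums(miss)
    if (scale_per_snp) grs <- grs / pmax(n_used, 1L)
    data.frame(sample_id = colnames(x), grs = as.numeric(grs),
               n_snps_used = as.integer(n_used), stringsAsFactors = FALSE)
}

#' Quartile categories with the lowest quartile as reference
#'
#' Cut points are the 25/50/75 empirical percentiles under the
#' linear-interpolation quantile convention (type 7); values falling exactly
#' on a boundary go to the lower quartile. Labels run `Q1` (lowest, the
#' reference group) to `Q4`.
#'
#' @param scores numeric vector with at least 4 distinct values.
#' @return factor of labels `Q1`--`Q4`, same length as `scores`.
#' @export
assignQuartiles <- function(scores) {
    rankedGroups(scores, probs = c(0.25, 0.5, 0.75),
                 labels = c("Q1", "Q2", "Q3", "Q4"))
}

#' Full risk-score result table
#'
#' Convenience wrapper: harmonize, score, and attach quartile labels.
#'
#' @inheritParams computeGRS
#' @param harmonize run [harmonizeToWeights()] first (default `TRUE`).
#' @return `data.frame` with `sample_id`, `grs`, `quartile`, `n_snps_used`.
#' @export
riskScoreResult <- function(x, weights, harmonize = TRUE,
                            scale_per_snp = FALSE) {
    if (harmonize) {
        x <- harmonizeToWeights(x, weights)
        weights <- metadata(x)$weights
    }
    res <- computeGRS(x, weights, scale_per_snp = scale_per_snp)
    res$quartile <- assignQuartiles(res$grs)
    res[, c("sample_id", "grs", "quartile", "n_snps_used")]
}
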