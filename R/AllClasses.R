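#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' DosageMatrix: effect-allele dosages for a set of variants and samples
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' \code{"dosage"} assay with variants as rows and samples as columns. Each
#' dosage is the expected count (0--2) of the per-variant \emph{counted
#' allele}; hard genotypes are the integers \{0, 1, 2\}, imputed dosages may
#' be fractional. Row metadata records the variant coordinates
#' (\code{chrom}, \code{pos}, 1-based, VCF convention), the two alleles
#' (\code{allele_a}, \code{allele_b}) and the \code{counted_allele}.
#' Missing genotypes are \code{NA} and are never imputed by this package.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @seealso [DosageMatrix()] the constructor, [dosages()], [variantInfo()],
#'   [countedAllele()], [readDosageMatrix()], [readVCFDosages()]
#' @export
setClass("DosageMatrix", contains = "SummarizedExperiment")

.validDosageMatrix <- function(object) {
    msg <- character()
    if (!"dosage" %in% names(assays(object)))
        msg <- c(msg, "assay 'dosage' is required")
    rd <- rowData(object)
    need <- c("chrom", "pos", "allele_a", "allele_b", "counted_allele")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(msg)) {
        d <- assay(object, "dosage")
        rng <- suppressWarnings(range(d, na.rm = TRUE))
        if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
            msg <- c(msg, "dosages must lie in [0, 2]")
        if (any(rd$pos < 1L))
            msg <- c(msg, "positions must be >= 1 (1-based)")
        bad <- !(rd$counted_allele == rd$allele_a |
                 rd$counted_allele == rd$allele_b)
        if (any(bad))
            msg <- c(msg, "counted_allele must equal allele_a or allele_b")
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, "duplicated variant ids")
    }
    if (length(msg)) msg else TRUE
}
setValidity("DosageMatrix", .validDosageMatrix)

#' Construct a DosageMatrix
#'
#' @param dosages numeric matrix, variants in rows and samples in columns
#'   (a samples-by-variants matrix is accepted and transposed when the
#'   dimnames make the orientation unambiguous is \emph{not} attempted:
#'   callers must orient variants-by-samples).
#' @param variants `data.frame` with one row per variant and columns
#'   `id`, `chrom`, `pos`, `allele_a`, `allele_b`, `counted_allele`.
#' @param sample_ids character vector of sample identifiers; defaults to
#'   the column names of `dosages`.
#' @return a [DosageMatrix-class] object.
#' @examples
#' v <- data.frame(id = "rs1", chrom = "1", pos = 100L,
#'                 allele_a = "A", allele_b = "G", counted_allele = "G")
#' dm <- DosageMatrix(matrix(c(0, 1, 2), 1, 3), v,
#'                    sample_ids = paste0("S", 1:3))
#' dosages(dm)
#' @export
DosageMatrix <- function(dosages, variants, sample_ids = colnames(dosages)) {
    dosages <- as.matrix(dosages)
    stopifnot(nrow(dosages) == nrow(variants))
    if (is.null(sample_ids))
        sample_ids <- paste0("S", seq_len(ncol(dosages)))
    variants <- as.data.frame(variants)
    if (!"counted_allele" %in% names(variants))
        variants$counted_allele <- variants$allele_b
    variants$chrom <- as.character(variants$chrom)
    variants$pos <- as.integer(variants$pos)
    dimnames(dosages) <- list(variants$id, sample_ids)
    se <- SummarizedExperiment(
        assays = list(dosage = dosages),
        rowData = DataFrame(variants[setdiff(names(variants), "id")],
                            row.names = variants$id))
    new("DosageMatrix", se)
}

#' ReferenceProjection: the PC space of one ancestral reference panel
#'
#' Stores everything needed to project external genotypes into the principal
#' component space of a single reference panel and measure genetic distance
#' (GD) from its centre: the per-SNP standardization constants derived from
#' the panel's own allele frequencies (centre \eqn{2\hat p}, scale
#' \eqn{\sqrt{2\hat p(1-\hat p)}}), the orthonormal SNP loadings of the top
#' \eqn{k} axes, and the centroid of the panel's own projected coordinates
#' (numerically zero by construction, stored explicitly).
#'
#' @slot anchor single character, panel label (e.g. `"EUR"`).
#' @slot variantKey character, canonical chrom:pos:allele-pair keys of the
#'   SNPs entering the projection (monomorphic SNPs excluded).
#' @slot countedAllele character, counted allele per retained SNP.
#' @slot center,scale numeric, per-SNP standardization constants.
#' @slot loadings numeric matrix (SNPs x k), orthonormal columns.
#' @slot centroid numeric length-k centroid of the panel projections.
#' @slot varExplained numeric length-k proportion of variance per axis.
#' @slot nRef integer, reference panel size.
#' @seealso [fitReferencePCA()], [geneticDistance()]
#' @export
setClass("ReferenceProjection",
    representation(anchor = "character", variantKey = "character",
                   countedAllele = "character",
                   center = "numeric", scale = "numeric",
                   loadings = "matrix", centroid = "numeric",
                   varExplained = "numeric", nRef = "integer"))

setValidity("ReferenceProjection", function(object) {
    msg <- character()
    M <- length(object@variantKey)
    k <- ncol(object@loadings)
    if (length(object@center) != M || length(object@scale) != M ||
        nrow(object@loadings) != M)
        msg <- c(msg, "standardization constants/loadings inconsistent with SNP set")
    if (any(object@scale <= 0))
        msg <- c(msg, "standardization scales must be strictly positive")
    if (length(object@centroid) != k)
        msg <- c(msg, "centroid length must equal number of axes")
    ortho <- crossprod(object@loadings) - diag(k)
    if (max(abs(ortho)) > 1e-8)
        msg <- c(msg, "loading columns must be orthonormal within 1e-8")
    if (length(msg)) msg else TRUE
})

#' TrajectoryModel: fitted fetal-growth mixed model
#'
#' Wraps the restricted-likelihood fit of
#' \deqn{\log w_{ij} = B(t_{ij})^\top \beta
#'       + (1, \tilde t, \tilde t^2, \tilde t^3)^\top b_i + \epsilon_{ij}}
#' where \eqn{B} is a natural cubic spline basis over gestational weeks
#' 10--40 and \eqn{\tilde t} is the centred/scaled week. Holds the fixed
#' coefficients, the 4x4 random-effect covariance \eqn{G}, the residual
#' variance \eqn{\sigma^2} and the underlying `lme4` fit used for
#' empirical-Bayes (BLUP) subject predictions.
#'
#' @slot fit the underlying `merMod` object.
#' @slot beta named numeric fixed-effect coefficients.
#' @slot G 4x4 random-effect covariance (intercept/linear/quad/cubic).
#' @slot sigma2 residual variance on the log-gram scale.
#' @slot knots,boundary interior/boundary knots (gestational weeks).
#' @slot centerWeek,scaleWeek centring/scaling of the random-effect time.
#' @slot converged logical, optimizer convergence (singular fits allowed).
#' @slot nSubjects,nVisits integer bookkeeping.
#' @seealso [fitTrajectoryModel()], [predictWeekly()]
#' @export
setClass("TrajectoryModel",
    representation(fit = "ANY", beta = "numeric", G = "matrix",
                   sigma2 = "numeric", knots = "numeric",
                   boundary = "numeric", centerWeek = "numeric",
                   scaleWeek = "numeric", converged = "logical",
                   nSubjects = "integer", nVisits = "integer"))

setValidity("TrajectoryModel", function(object) {
    msg <- character()
    if (object@sigma2 <= 0) msg <- c(msg, "sigma2 must be > 0")
    G <- object@G
    if (!isTRUE(all.equal(G, t(G), tolerance = 1e-8)))
        msg <- c(msg, "G must be symmetric")
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
        msg <- c(msg, "G must be positive semi-definite")
    if (length(msg)) msg else TRUE
})
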