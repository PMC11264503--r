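#' Extract the dosage matrix
#'
#' @param x a [DosageMatrix-class].
#' @return numeric matrix, variants in rows, samples in columns.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Variant metadata as a data.frame
#'
#' @param x a [DosageMatrix-class] or [ReferenceProjection-class].
#' @return `data.frame` with columns `id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`, `counted_allele`.
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' Counted allele per variant
#'
#' @param x a [DosageMatrix-class].
#' @return character vector, the allele whose copies the dosages count.
#' @export
setGeneric("countedAllele", function(x) standardGeneric("countedAllele"))

#' @rdname dosages
#' @export
setMethod("dosages", "DosageMatrix", function(x) assay(x, "dosage"))

#' @rdname variantInfo
#' @export
setMethod("variantInfo", "DosageMatrix", function(x) {
    rd <- as.data.frame(rowData(x))
    cbind(data.frame(id = rownames(x), stringsAsFactors = FALSE),
          rd[, c("chrom", "pos", "allele_a", "allele_b", "counted_allele")])
})

#' @rdname countedAllele
#' @export
setMethod("countedAllele", "DosageMatrix",
          function(x) rowData(x)$counted_allele)

setMethod("show", "DosageMatrix", function(object) {
    d <- assay(object, "dosage")
    cat("DosageMatrix:", nrow(object), "variants x", ncol(object),
        "samples\n")
    cat("  missing:", sum(is.na(d)), "entries\n")
    frac <- mean(d == round(d), na.rm = TRUE)
    cat("  hard genotypes:", sprintf("%.1f%%", 100 * frac), "\n")
})

setMethod("show", "ReferenceProjection", function(object) {
    cat("ReferenceProjection anchor:", object@anchor, "\n")
    cat("  ", length(object@variantKey), "SNPs,", ncol(object@loadings),
        "axes,", object@nRef, "reference samples\n")
    cat("  var explained (top 3):",
        paste(sprintf("%.3f", utils::head(object@varExplained, 3)),
              collapse = " "), "\n")
})

setMethod("show", "TrajectoryModel", function(object) {
    cat("TrajectoryModel: cubic-spline mean, cubic-polynomial random effects\n")
    cat("  subjects:", object@nSubjects, " visits:", object@nVisits, "\n")
    cat("  knots:", paste(object@knots, collapse = "/"),
        " boundary:", paste(object@boundary, collapse = "/"), "\n")
    cat("  sigma^2 (log-g):", signif(object@sigma2, 4),
        " converged:", object@converged, "\n")
    cat("  RE sd:", paste(signif(sqrt(diag(object@G)), 3), collapse = " "),
        "\n")
})
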