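#' Validate an effect-weight table
#'
#' An effect-weight table drives the weighted genetic risk score: one row per
#' SNP with the variant coordinates, the effect (risk-increasing) allele, the
#' other allele and the log odds-ratio weight from an external GWAS.
#'
#' @param x `data.frame` with columns `id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @return the validated `data.frame` (invisibly coerced types), with a
#'   `variantKey` column added.
#' @export
effectWeightTable <- function(x) {
    need <- c("id", "chrom", "pos", "effect_allele", "other_allele", "weight")
    miss <- setdiff(need, names(x))
    if (length(miss))
        stop("effect-weight table lacks column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    x <- as.data.frame(x)
    x$pos <- as.integer(x$pos)
    x$weight <- as.numeric(x$weight)
    if (any(!is.finite(x$weight)))
        stop("weights must be finite", call. = FALSE)
    if (any(x$effect_allele == x$other_allele))
        stop("effect_allele must differ from other_allele", call. = FALSE)
    ok <- grepl("^[ACGT]+$", x$effect_allele) & grepl("^[ACGT]+$", x$other_allele)
    if (any(!ok))
        stop("alleles must be non-empty strings over {A,C,G,T}", call. = FALSE)
    x$variantKey <- variantKey(x$chrom, x$pos, x$effect_allele, x$other_allele)
    x
}

#' Read / write an effect-weight table
#'
#' Tab-separated with the mandatory header
#' `id  chr  pos  ea  oa  logor`.
#'
#' @param path file path.
#' @return [readEffectWeights()] returns a validated weight `data.frame`
#'   (see [effectWeightTable()]); [writeEffectWeights()] returns `path`
#'   invisibly.
#' @export
readEffectWeights <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    tab <- readTSV(path)
    need <- c("id", "chr", "pos", "ea", "oa", "logor")
    if (!all(need %in% names(tab)))
        stop("weight file must carry header columns: ",
             paste(need, collapse = ", "), call. = FALSE)
    effectWeightTable(data.frame(
        id = tab$id, chrom = as.character(tab$chr), pos = tab$pos,
        effect_allele = tab$ea, other_allele = tab$oa, weight = tab$logor,
        stringsAsFactors = FALSE))
}

#' @rdname readEffectWeights
#' @param weights a validated weight `data.frame`.
#' @export
writeEffectWeights <- function(weights, path) {
    weights <- effectWeightTable(weights)
    writeTSV(data.frame(id = weights$id, chr = weights$chrom,
                        pos = weights$pos, ea = weights$effect_allele,
                        oa = weights$other_allele, logor = weights$weight),
             path)
}

#' Read / write the dosage-matrix text dialect
#'
#' The dialect is a pair of tab-separated files: `<path>` holds the dosages
#' (first column `sample_id`, remaining columns one per variant, header row
#' of variant ids, `NA` for missing), and `<path_without_ext>.vars.tsv`
#' holds the variant table (`id`, `chrom`, `pos`, `allele_a`, `allele_b`,
#' `counted_allele`). Dosages count copies of `counted_allele` and must lie
#' in \[0, 2\].
#'
#' @param path dosage file path.
#' @param variants_path variant table path; defaults to the sidecar next to
#'   `path`.
#' @return a [DosageMatrix-class].
#' @export
readDosageMatrix <- function(path, variants_path = varsPath(path)) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    if (!file.exists(variants_path))
        stop("no variant table next to dosage file: ", variants_path,
             call. = FALSE)
    tab <- readTSV(path)
    if (names(tab)[1] != "sample_id")
        stop("dosage dialect: first column must be 'sample_id'",
             call. = FALSE)
    vars <- readTSV(variants_path)
    d <- as.matrix(tab[, -1, drop = FALSE])
    if (!identical(colnames(d), as.character(vars$id)))
        stop("dosage header ids disagree with the variant table",
             call. = FALSE)
    if (anyDuplicated(vars$id))
        stop("duplicated variant id in ", variants_path, call. = FALSE)
    DosageMatrix(t(d), vars, sample_ids = tab$sample_id)
}

varsPath <- function(path) {
    sub("\\.[^.]+$", "", path) |> paste0(".vars.tsv")
}

#' @rdname readDosageMatrix
#' @param x a [DosageMatrix-class].
#' @export
writeDosageMatrix <- function(x, path, variants_path = varsPath(path)) {
    stopifnot(is(x, "DosageMatrix"))
    d <- t(dosages(x))
    out <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                      stringsAsFactors = FALSE)
    writeTSV(out, path)
    writeTSV(variantInfo(x), variants_path)
    invisible(path)
}

#' Read genotypes from VCF (GT field) as counted-ALT dosages
#'
#' Parses a VCF v4.x via `vcfR` and sums the GT allele pair into a dosage of
#' the ALT allele (`0/0` -> 0, `0/1` -> 1, `1/1` -> 2; `./.` -> `NA`).
#' Multi-allelic records are dropped with a warning (splitting is out of
#' scope); duplicated variant ids are an error.
#'
#' @param path VCF file path (plain text or gzipped).
#' @return a [DosageMatrix-class] with `counted_allele` = ALT.
#' @export
readVCFDosages <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi)) {
        warning(sum(multi), " multi-allelic record(s) dropped")
        vcf <- vcf[!multi, ]
        fix <- fix[!multi, , drop = FALSE]
    }
    id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                 paste0(fix$CHROM, "_", fix$POS), fix$ID)
    if (anyDuplicated(id))
        stop("duplicated variant id in VCF: ",
             paste(unique(id[duplicated(id)]), collapse = ", "),
             call. = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    alt_count <- function(g) {
        a <- strsplit(g, "[/|]")
        vapply(a, function(p) {
            if (length(p) == 0L || anyNA(p) || any(p == "."))
                return(NA_real_)
            sum(p == "1")
        }, numeric(1))
    }
    d <- apply(gt, 2, alt_count)
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(gt),
                                     dimnames = dimnames(gt))
    vars <- data.frame(id = id, chrom = fix$CHROM, pos = as.integer(fix$POS),
                       allele_a = fix$REF, allele_b = fix$ALT,
                       counted_allele = fix$ALT, stringsAsFactors = FALSE)
    DosageMatrix(d, vars, sample_ids = colnames(gt))
}

#' Write hard genotypes as a VCF with GT fields
#'
#' The counted allele is written as ALT; dosages must be integers in
#' \{0, 1, 2\} (or `NA`, written `./.`).
#'
#' @param x a [DosageMatrix-class] with integer dosages.
#' @param path output path (`.vcf`, plain text).
#' @return `path`, invisibly.
#' @export
writeVCFDosages <- function(x, path) {
    stopifnot(is(x, "DosageMatrix"))
    d <- dosages(x)
    if (any(d[!is.na(d)] != round(d[!is.na(d)])))
        stop("VCF GT output requires hard (integer) genotypes", call. = FALSE)
    v <- variantInfo(x)
    ref <- ifelse(v$counted_allele == v$allele_b, v$allele_a, v$allele_b)
    alt <- v$counted_allele
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow(d), ncol(d))
    ok <- !is.na(d)
    gt[ok] <- gt_code[as.character(d[ok])]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", colnames(d)),
                       collapse = "\t")), con)
    body <- cbind(v$chrom, v$pos, v$id, ref, alt, ".", ".", ".", "GT", gt)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
    invisible(path)
}

#' Harmonize a dosage matrix to an effect-weight table
#'
#' Restricts the cohort to the weight-table SNPs and flips dosages so the
#' counted allele is the effect allele. Variants are matched on
#' (chrom, pos, unordered allele pair). Where the cohort counts the other
#' allele, dosage is reflected to `2 - dosage`. Strand-ambiguous SNPs (A/T,
#' C/G) are dropped by default because their orientation cannot be resolved
#' from allele labels alone. Variants absent from the cohort, or with an
#' irreconcilable allele set, are dropped with a message/warning.
#'
#' @param x a [DosageMatrix-class].
#' @param weights a validated effect-weight table (see
#'   [effectWeightTable()]).
#' @param drop_ambiguous drop A/T and C/G SNPs (default `TRUE`).
#' @return a [DosageMatrix-class] restricted to the surviving weight SNPs
#'   (in weight-table order) with `counted_allele` = effect allele. The
#'   matched weight rows are attached as `metadata(x)$weights`.
#' @export
harmonizeToWeights <- function(x, weights, drop_ambiguous = TRUE) {
    stopifnot(is(x, "DosageMatrix"))
    weights <- effectWeightTable(weights)
    if (drop_ambiguous) {
        amb <- isStrandAmbiguous(weights$effect_allele, weights$other_allele)
        if (any(amb)) {
            message(sum(amb), " strand-ambiguous SNP(s) dropped")
            weights <- weights[!amb, , drop = FALSE]
        }
    }
    v <- variantInfo(x)
    ## locate by coordinate, then reconcile the unordered allele pair
    idx <- match(paste(weights$chrom, weights$pos),
                 paste(v$chrom, v$pos))
    absent <- is.na(idx)
    if (any(absent))
        message(sum(absent), " weight SNP(s) absent from the cohort; dropped")
    weights <- weights[!absent, , drop = FALSE]
    idx <- idx[!absent]
    if (!nrow(weights))
        stop("no weight SNPs survive harmonization", call. = FALSE)
    d <- dosages(x)[idx, , drop = FALSE]
    vv <- v[idx, , drop = FALSE]
    pair_ok <- variantKey(vv$chrom, vv$pos, vv$allele_a, vv$allele_b) ==
        weights$variantKey
    same <- pair_ok & vv$counted_allele == weights$effect_allele
    swap <- pair_ok & vv$counted_allele == weights$other_allele
    bad <- !(same | swap)
    if (any(bad)) {
        warning(sum(bad), " variant(s) with irreconcilable allele",
                " set dropped")
        d <- d[!bad, , drop = FALSE]
        vv <- vv[!bad, , drop = FALSE]
        weights <- weights[!bad, , drop = FALSE]
        swap <- swap[!bad]
    }
    if (!nrow(weights))
        stop("no weight SNPs survive harmonization", call. = FALSE)
    d[swap, ] <- 2 - d[swap, , drop = FALSE]
    vv$counted_allele <- weights$effect_allele
    vv$id <- weights$id
    out <- DosageMatrix(d, vv, sample_ids = colnames(x))
    metadata(out)$weights <- weights
    out
}
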