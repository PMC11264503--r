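## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Canonical variant key: chrom:pos plus the unordered allele pair.
## Identity is keyed on coordinates + allele set, never on id strings,
## because id conventions differ across dialects.
variantKey <- function(chrom, pos, a, b) {
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    paste(chrom, pos, lo, hi, sep = ":")
}

isStrandAmbiguous <- function(a, b) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    unname(comp[a] == b)
}

## Deterministic per-stage seed derivation from the single run seed.
## Kept strictly below 2^31 - 1 so it is always a valid R integer.
stageSeed <- function(seed, stage) {
    stages <- c(simulate = 1L, grs = 2L, ancestry = 3L, growth = 4L,
                associate = 5L, report = 6L, phenotype = 7L)
    off <- stages[[stage]]
    as.integer((as.numeric(seed) * 97L + off * 1009L) %% 2147483647)
}

assertCount <- function(x, nm, min = 1L) {
    if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
        stop(sprintf("'%s' must be a single integer >= %d", nm, min),
             call. = FALSE)
    as.integer(x)
}

## Empirical quantile cut with boundary ties assigned to the lower group.
## Uses the linear-interpolation empirical quantile (type 7).
rankedGroups <- function(x, probs, labels) {
    if (length(unique(x[is.finite(x)])) < length(probs) + 1L)
        stop(sprintf("need at least %d distinct values to form %d groups",
                     length(probs) + 1L, length(probs) + 1L), call. = FALSE)
    cuts <- stats::quantile(x, probs = probs, type = 7, names = FALSE,
                            na.rm = TRUE)
    brk <- unique(c(-Inf, cuts, Inf))
    if (length(brk) != length(probs) + 2L)
        stop("degenerate cut points: too many ties to form groups",
             call. = FALSE)
    cut(x, breaks = brk, labels = labels, right = TRUE)
}

writeTSV <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

readTSV <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
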