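test_that("VCF GT parsing matches hand tabulation", {
    vcf <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1", "S2", "S3", sep = "\t"),
             "1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
             "1\t200\trs2\tC\tT\t.\t.\t.\tGT\t1|1\t0|0\t0|1",
             "2\t150\trs3\tG\tA\t.\t.\t.\tGT\t./.\t0/1\t0/0",
             "2\t250\trs4\tT\tC\t.\t.\t.\tGT\t0/1\t0/1\t1/1")
    path <- withr::local_tempfile(fileext = ".vcf")
    writeLines(vcf, path)
    dm <- readVCFDosages(path)
    hand <- rbind(rs1 = c(0, 1, 2), rs2 = c(2, 0, 1),
                  rs3 = c(NA, 1, 0), rs4 = c(1, 1, 2))
    colnames(hand) <- c("S1", "S2", "S3")
    expect_equal(dosages(dm), hand)
    expect_identical(countedAllele(dm), c("G", "T", "A", "C"))
    expect_identical(variantInfo(dm)$pos, c(100L, 200L, 150L, 250L))
})

test_that("VCF and dosage-dialect round trips are identities", {
    set.seed(8)
    d <- matrix(sample(0:2, 60, TRUE), 6, 10)
    dm <- makeDosage(d, chrom = rep(c("1", "2"), each = 5))
    p <- withr::local_tempfile(fileext = ".vcf")
    writeVCFDosages(dm, p)
    back <- readVCFDosages(p)
    expect_equal(dosages(back), dosages(dm))
    expect_equal(variantInfo(back)[, -1], variantInfo(dm)[, -1])

    ## text dialect keeps fractional dosages and missingness
    d2 <- matrix(runif(40, 0, 2), 8, 5)
    d2[2, 3] <- NA
    dm2 <- makeDosage(d2)
    p2 <- withr::local_tempfile(fileext = ".tsv")
    writeDosageMatrix(dm2, p2)
    back2 <- readDosageMatrix(p2)
    expect_equal(dosages(back2), dosages(dm2), tolerance = 1e-12)
    expect_identical(variantInfo(back2), variantInfo(dm2))

    ## dialect errors are informative
    expect_error(readDosageMatrix(withr::local_tempfile()), "no such file")
    bad <- withr::local_tempfile(fileext = ".tsv")
    writeLines("wrong\tv001\n1\t2", bad)
    writeLines("id\tchrom\tpos\tallele_a\tallele_b\tcounted_allele",
               varsBad <- sub("\\.tsv$", ".vars.tsv", bad))
    expect_error(readDosageMatrix(bad), "sample_id")
    ## fractional dosages cannot be written as GT
    expect_error(writeVCFDosages(dm2, withr::local_tempfile()), "hard")
})

test_that("harmonization restricts, reflects and drops correctly", {
    set.seed(9)
    d <- matrix(sample(0:2, 50, TRUE), 5, 10)
    dm <- makeDosage(d, a = rep(c("A", "T"), 5), b = rep(c("G", "C"), 5))
    v <- variantInfo(dm)
    w_al <- effectWeightTable(data.frame(
        id = v$id, chrom = v$chrom, pos = v$pos,
        effect_allele = v$counted_allele, other_allele = v$allele_a,
        weight = rnorm(10)))
    ## already aligned: identity restriction
    h <- harmonizeToWeights(dm, w_al)
    expect_equal(dosages(h), dosages(dm))

    ## swapped orientation reflects: 2 -> 0
    w_sw <- w_al
    w_sw$effect_allele <- v$allele_a
    w_sw$other_allele <- v$counted_allele
    w_sw <- effectWeightTable(w_sw[, names(w_sw) != "variantKey"])
    h_sw <- harmonizeToWeights(dm, w_sw)
    expect_equal(dosages(h_sw), 2 - dosages(dm))
    ## involution: applying the swap rule twice restores dosages
    expect_equal(2 - dosages(h_sw), dosages(dm))

    ## absent variants dropped with a message; none left is an error
    w_miss <- w_al
    w_miss$pos <- w_miss$pos + 7L
    w_miss <- effectWeightTable(w_miss[, names(w_miss) != "variantKey"])
    expect_error(suppressMessages(harmonizeToWeights(dm, w_miss)),
                 "survive")
    ## irreconcilable allele set dropped with a warning
    w_bad <- w_al[1:3, names(w_al) != "variantKey"]
    w_bad$effect_allele <- c("C", w_bad$effect_allele[2:3])
    w_bad$other_allele <- c("T", w_bad$other_allele[2:3])
    expect_warning(h_bad <- harmonizeToWeights(dm, effectWeightTable(w_bad)),
                   "irreconcilable")
    expect_equal(nrow(h_bad), 2L)
})

test_that("strand-ambiguous SNPs are dropped by default, kept on request", {
    d <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2)
    dm <- makeDosage(d, a = c("A", "A"), b = c("T", "G"))
    v <- variantInfo(dm)
    w <- effectWeightTable(data.frame(
        id = v$id, chrom = v$chrom, pos = v$pos,
        effect_allele = v$allele_b, other_allele = v$allele_a,
        weight = c(0.2, 0.3)))
    expect_message(h <- harmonizeToWeights(dm, w), "ambiguous")
    expect_equal(nrow(h), 1L)
    h2 <- harmonizeToWeights(dm, w, drop_ambiguous = FALSE)
    expect_equal(nrow(h2), 2L)
})

test_that("GRS is invariant to allele orientation after harmonization", {
    set.seed(10)
    n <- 40; M <- 60
    d <- matrix(sample(0:2, n * M, TRUE), n, M)
    dm_true <- makeDosage(d, a = rep("A", M), b = rep("G", M))
    v <- variantInfo(dm_true)
    w <- effectWeightTable(data.frame(
        id = v$id, chrom = v$chrom, pos = v$pos, effect_allele = "G",
        other_allele = "A", weight = rnorm(M, 0, 0.1)))
    grs_true <- computeGRS(harmonizeToWeights(dm_true, w), w)$grs

    ## flip the recorded orientation of 30% of SNPs
    flip <- seq_len(M) %in% sample(M, round(0.3 * M))
    d_f <- d
    d_f[, flip] <- 2 - d_f[, flip]
    dm_f <- makeDosage(d_f, a = rep("A", M), b = rep("G", M),
                       counted = ifelse(flip, "A", "G"))
    grs_f <- computeGRS(harmonizeToWeights(dm_f, w), w)$grs
    expect_identical(grs_f, grs_true)
})
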