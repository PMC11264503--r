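## Config-driven end-to-end orchestration: simulate -> genotype I/O -> GRS
## -> ancestry metrics -> growth trajectories -> associations -> report.
## Fully deterministic given the config seed; every stage communicates
## through files in the output directory, ground truth goes to `truth_*`
## sidecar files that no analysis stage reads, and a manifest records the
## config echo and an md5 for every (non-figure) output.

.ANALYSIS_DEFAULTS <- list(
    k_pcs = 10L, prune_window = 50L, prune_step = 5L, prune_r2 = 0.1,
    min_overlap = 0.8, guard = 10, outcome_scale = "g",
    genotype_format = "dosage", gap_tol = 1e-5, gap_max_iter = 2000L,
    interaction_outcomes = c("w40", "birthweight_g"))

#' Build a run configuration
#'
#' @param seed mandatory integer seed for the whole run.
#' @param out_dir output directory.
#' @param simulation named list of [simulationConfig()] overrides (the
#'   seed is injected automatically).
#' @param analysis named list of analysis-switch overrides; see Details.
#' @details Analysis switches: `k_pcs` (PCs for genetic distance),
#'   `prune_window`/`prune_step`/`prune_r2` (LD pruning), `min_overlap`
#'   (GD SNP-overlap guard), `guard` (samples per model parameter),
#'   `outcome_scale` (`"g"` or `"sd"`), `genotype_format` (`"dosage"`,
#'   `"vcf"` or `"both"`), `gap_tol`/`gap_max_iter` (admixture EM),
#'   `interaction_outcomes`.
#' @return validated list of class `RunConfig`.
#' @export
runConfig <- function(seed, out_dir, simulation = list(),
                      analysis = list()) {
    if (missing(seed) || is.null(seed))
        stop("'seed' is mandatory", call. = FALSE)
    an <- utils::modifyList(.ANALYSIS_DEFAULTS, analysis)
    cfg <- list(seed = as.integer(seed), out_dir = out_dir,
                simulation = do.call(simulationConfig,
                                     c(list(seed = as.integer(seed)),
                                       simulation)),
                analysis = an)
    class(cfg) <- "RunConfig"
    validateRunConfig(cfg)
    cfg
}

#' @rdname runConfig
#' @param config a `RunConfig`.
#' @export
validateRunConfig <- function(config) {
    an <- config$analysis
    if (!is.finite(an$prune_r2) || an$prune_r2 <= 0 || an$prune_r2 > 1)
        stop("prune_r2 must lie in (0, 1]", call. = FALSE)
    if (an$k_pcs < 2) stop("k_pcs must be >= 2", call. = FALSE)
    if (an$min_overlap <= 0 || an$min_overlap > 1)
        stop("min_overlap must lie in (0, 1]", call. = FALSE)
    if (!an$outcome_scale %in% c("g", "sd"))
        stop("outcome_scale must be 'g' or 'sd'", call. = FALSE)
    if (!an$genotype_format %in% c("dosage", "vcf", "both"))
        stop("genotype_format must be dosage/vcf/both", call. = FALSE)
    if (an$guard < 1) stop("guard must be >= 1", call. = FALSE)
    invisible(config)
}

#' Read a run configuration from YAML
#'
#' The file carries `seed` (mandatory), `out_dir`, and optional
#' `simulation:` and `analysis:` blocks whose entries override the
#' defaults. Validation happens before any computation.
#'
#' @param path YAML file.
#' @param out_dir optional override of the configured output directory.
#' @return a validated `RunConfig`.
#' @export
readRunConfig <- function(path, out_dir = NULL) {
    y <- yaml::read_yaml(path)
    if (is.null(y$seed)) stop("config must set 'seed'", call. = FALSE)
    sim <- y$simulation %||% list()
    for (nm in c("dirichlet_alpha"))
        if (!is.null(sim[[nm]])) sim[[nm]] <- do.call(rbind, sim[[nm]])
    if (!is.null(sim$visit_windows))
        sim$visit_windows <- lapply(sim$visit_windows,
                                    function(w) do.call(rbind, w))
    runConfig(seed = y$seed,
              out_dir = out_dir %||% y$out_dir %||% "fetalgrs_run",
              simulation = sim, analysis = y$analysis %||% list())
}

.pp <- function(config, ...) file.path(config$out_dir, ...)

stageSimulate <- function(config) {
    sim <- simulateCohort(config$simulation)
    od <- config$out_dir
    writeDosageMatrix(sim$cohort, file.path(od, "cohort_dosages.tsv"))
    for (a in names(sim$refs))
        writeDosageMatrix(sim$refs[[a]],
                          file.path(od, sprintf("ref_%s_dosages.tsv", a)))
    if (config$analysis$genotype_format %in% c("vcf", "both")) {
        writeVCFDosages(sim$cohort, file.path(od, "cohort.vcf"))
        for (a in names(sim$refs))
            writeVCFDosages(sim$refs[[a]],
                            file.path(od, sprintf("ref_%s.vcf", a)))
    }
    writeEffectWeights(sim$weights, file.path(od, "weights.tsv"))
    writeTSV(sim$visits, file.path(od, "visits.tsv"))
    writeTSV(sim$births, file.path(od, "births.tsv"))
    writeTSV(sim$covariates, file.path(od, "covariates.tsv"))
    ## ground-truth sidecars: never read by any analysis stage
    tr <- sim$truth
    writeTSV(data.frame(sample_id = rownames(tr$q_true), tr$q_true,
                        group = tr$group), file.path(od, "truth_q.tsv"))
    writeTSV(data.frame(anchor = rownames(tr$pop_freqs), tr$pop_freqs),
             file.path(od, "truth_freqs.tsv"))
    writeTSV(data.frame(sample_id = rownames(tr$latent_weekly),
                        tr$latent_weekly,
                        latent_birthweight = tr$latent_birthweight,
                        quartile = as.character(tr$quartile),
                        check.names = FALSE),
             file.path(od, "truth_latent.tsv"))
    invisible(NULL)
}

stageGRS <- function(config) {
    cohort <- readDosageMatrix(.pp(config, "cohort_dosages.tsv"))
    weights <- readEffectWeights(.pp(config, "weights.tsv"))
    res <- riskScoreResult(cohort, weights)
    writeTSV(res, .pp(config, "grs.tsv"))
    invisible(NULL)
}

stageAncestry <- function(config) {
    an <- config$analysis
    cohort <- readDosageMatrix(.pp(config, "cohort_dosages.tsv"))
    anchors <- config$simulation$anchors
    refs <- lapply(anchors, function(a)
        readDosageMatrix(.pp(config, sprintf("ref_%s_dosages.tsv", a))))
    names(refs) <- anchors
    ## GD: per-anchor PCA on the full harmonized SNP set
    gd <- vapply(anchors, function(a) {
        proj <- fitReferencePCA(refs[[a]], k = an$k_pcs, anchor = a)
        geneticDistance(cohort, proj, min_overlap = an$min_overlap)
    }, numeric(ncol(cohort)))
    ## GAP: LD-pruned SNPs, component frequencies from the labeled panels
    pr <- ldPrune(cohort, window = an$prune_window, step = an$prune_step,
                  r2_max = an$prune_r2)
    pruned <- cohort[pr$keep, ]
    fr <- referenceFrequencies(lapply(refs, function(r) r[pr$keep, ]))
    gap <- estimateGAP(pruned, fr, tol = an$gap_tol,
                       max_iter = an$gap_max_iter)
    prof <- ancestryProfiles(gd, gap$q, sample_ids = colnames(cohort))
    writeTSV(prof, .pp(config, "profiles.tsv"))
    writeTSV(data.frame(kept_index = pr$keep), .pp(config, "prune_kept.tsv"))
    cr <- gdGapCorrelation(prof)
    writeTSV(data.frame(measure = rownames(cr$rho), cr$rho),
             .pp(config, "gd_gap_rho.tsv"))
    writeTSV(data.frame(measure = rownames(cr$p), cr$p),
             .pp(config, "gd_gap_p.tsv"))
    invisible(NULL)
}

stageGrowth <- function(config) {
    visits <- readTSV(.pp(config, "visits.tsv"))
    births <- readTSV(.pp(config, "births.tsv"))
    model <- fitTrajectoryModel(visits,
                                knots = config$simulation$knots,
                                boundary = config$simulation$boundary_knots)
    weekly <- predictWeekly(model, standardize = TRUE)
    out <- weeklyTrajectory(weekly, births)
    writeTSV(out, .pp(config, "weekly.tsv"))
    gsum <- data.frame(
        param = c("sigma2", paste0("G_", outer(rownames(model@G),
                                               colnames(model@G),
                                               paste, sep = "_")),
                  paste0("beta_", seq_along(model@beta))),
        value = c(model@sigma2, as.numeric(model@G), unname(model@beta)))
    writeTSV(gsum, .pp(config, "trajectory_model.tsv"))
    invisible(NULL)
}

stageAssociate <- function(config) {
    an <- config$analysis
    weekly <- readTSV(.pp(config, "weekly.tsv"))
    risk <- readTSV(.pp(config, "grs.tsv"))
    prof <- readTSV(.pp(config, "profiles.tsv"))
    covars <- readTSV(.pp(config, "covariates.tsv"))
    wk <- fitWeeklyModels(weekly, risk, prof, covars,
                          outcome_scale = an$outcome_scale,
                          guard = an$guard)
    bw <- fitBirthweightModels(weekly, risk, prof, covars,
                               guard = an$guard)
    ia <- fitInteractionModels(weekly, risk, prof, covars,
                               outcome_cols = an$interaction_outcomes)
    est <- rbind(wk, bw, ia)
    attr(est, "skipped") <- rbind(attr(wk, "skipped"),
                                  attr(bw, "skipped"))
    class(est) <- c("AssociationEstimates", "data.frame")
    writeTSV(as.data.frame(est), .pp(config, "estimates.tsv"))
    sk <- attr(est, "skipped")
    if (!is.null(sk) && nrow(sk))
        writeTSV(sk, .pp(config, "skipped_strata.tsv"))
    invisible(NULL)
}

stageReport <- function(config) {
    est <- readTSV(.pp(config, "estimates.tsv"))
    class(est) <- c("AssociationEstimates", "data.frame")
    sk_path <- .pp(config, "skipped_strata.tsv")
    attr(est, "skipped") <- if (file.exists(sk_path)) readTSV(sk_path)
    renderReport(est, .pp(config, "report"))
    invisible(NULL)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (`simulate`, `grs`, `ancestry`, `growth`, `associate`, `report`),
#' each reading its inputs from and writing its outputs to
#' `config$out_dir`, then writes `manifest.json` with the config echo and
#' an md5 hash of every tabular output. A rerun with an identical config
#' reproduces identical hashes. Any stage error aborts with the stage
#' name.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @param stages character vector of stages, or `"all"`.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, stages = "all") {
    validateRunConfig(config)
    all_stages <- c("simulate", "grs", "ancestry", "growth", "associate",
                    "report")
    if (identical(stages, "all")) stages <- all_stages
    stages <- all_stages[all_stages %in% stages]
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fns <- list(simulate = stageSimulate, grs = stageGRS,
                ancestry = stageAncestry, growth = stageGrowth,
                associate = stageAssociate, report = stageReport)
    log <- character(0)
    for (s in stages) {
        log <- c(log, paste0("stage ", s, ": start"))
        ok <- try(fns[[s]](config), silent = TRUE)
        if (inherits(ok, "try-error"))
            stop("pipeline stage '", s, "' failed: ",
                 attr(ok, "condition")$message, call. = FALSE)
        log <- c(log, paste0("stage ", s, ": done"))
    }
    files <- sort(list.files(config$out_dir, recursive = TRUE,
                             full.names = TRUE))
    hashable <- files[!grepl("\\.(pdf|json|log)$", files) &
                      basename(files) != "pipeline.log"]
    hashes <- as.list(tools::md5sum(hashable))
    names(hashes) <- sub(paste0("^", config$out_dir, "/?"), "",
                         names(hashes))
    manifest <- list(
        package_version = as.character(utils::packageVersion("fetalgrs")),
        seed = config$seed,
        stages = stages,
        analysis = config$analysis,
        simulation = config$simulation[
            c("n_cohort", "n_ref_per_pop", "n_snps_grs", "n_snps_ancestry",
              "fst", "effect_sd", "growth_effect", "birthweight_effect",
              "effect_strata", "noise_model")],
        hashes = hashes)
    writeLines(log, .pp(config, "pipeline.log"))
    jsonlite::write_json(manifest, .pp(config, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}
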