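# fetalgrs

Maternal polygenic risk and fetal growth across the ancestry continuum.

Pregnant women carry type-2-diabetes (T2D) risk alleles that can shape the
intrauterine environment and hence fetal growth, and the strength of that
relationship may vary along *continuous* axes of genetic ancestry rather
than across discrete race/ethnicity labels. `fetalgrs` is an R package for
epidemiologists and statistical geneticists who want to run — or stress-test
— that full analysis on longitudinal pregnancy-cohort data:

* **Risk score.** A weighted maternal genetic risk score
  GRS<sub>i</sub> = Σ<sub>j</sub> d<sub>ij</sub> · logOR<sub>j</sub> over
  effect-allele dosages d ∈ [0, 2], with allele harmonization
  (coordinate matching, 2 − d reflection, strand-ambiguous SNP policy) and
  quartile categories with Q1 as reference.
* **Genetic distance (GD).** Per ancestral reference panel
  (European/African/East Asian/Amerindigenous analogues): standardize by
  the panel's allele frequencies, project onto its top-k principal axes,
  and take the Euclidean distance from the panel centroid; tertiles
  closest/middle/farthest.
* **Genetic ancestry proportion (GAP).** A supervised-frequency admixture
  EM maximizing the binomial likelihood p<sub>j</sub> = Σ<sub>k</sub>
  q<sub>k</sub> f<sub>kj</sub> over the 4-simplex, on LD-pruned genotypes;
  tertiles lowest/medium/highest.
* **Growth trajectories.** Hadlock estimated fetal weight from ultrasound
  biometry (log₁₀ EFW = 1.326 − 0.00326·AC·FL + 0.0107·HC + 0.0438·AC +
  0.158·FL), then a linear mixed model on log weight with a natural
  cubic-spline mean (knots 16/24/32 weeks) and cubic-polynomial subject
  random effects; BLUP weights at integer weeks 10–40.
* **Association.** Per-week and birthweight OLS models of outcome on GRS
  quartiles plus covariates, fitted inside every GD/GAP anchor × tertile
  stratum, and continuous GRS × GD/GAP interaction models.
* **Synthetic cohort.** A Balding–Nichols / Dirichlet-admixture generator
  with known ground truth (default: 1,837 women, 302 + 2,000 SNPs,
  F<sub>ST</sub> 0.15, five-visit randomized ultrasound schedule,
  birthweight calibrated to 3,313.92 ± 529.05 g) with injectable
  stratum-specific effects — so every stage above is testable end to end
  without restricted data.

The methods vignette (`vignettes/methods.Rmd`) documents the models,
parameter choices, generator calibration and known limitations.

## Worked example

```r
library(fetalgrs)

cfg <- simulationConfig(seed = 1, n_cohort = 400, n_ref_per_pop = 60,
                        n_snps_grs = 50, n_snps_ancestry = 500)
sim <- simulateCohort(cfg)
sim$cohort
#> DosageMatrix: 550 variants x 400 samples
#>   missing: 0 entries
#>   hard genotypes: 100.0%
head(sim$grs, 3)
#>   sample_id         grs quartile n_snps_used
#> 1     W0001 -0.03394299       Q2          50
#> 2     W0002 -0.36826430       Q1          50
#> 3     W0003 -0.24515034       Q1          50

## ancestry metrics: distance to each anchor, admixture proportions
gd <- sapply(cfg$anchors, function(a)
    geneticDistance(sim$cohort, fitReferencePCA(sim$refs[[a]], k = 10)))
pr <- ldPrune(sim$cohort)
fr <- referenceFrequencies(lapply(sim$refs, function(r) r[pr$keep, ]))
gap <- estimateGAP(sim$cohort[pr$keep, ], fr)
gap
#> GAPResult: 400 samples x 4 components; 1019 EM iterations; converged: TRUE
#>   mean proportions: EUR=0.434 AFR=0.281 EAS=0.151 NAM=0.134
round(diag(cor(gd, gap$q, method = "spearman")), 2)
#>   EUR   AFR   EAS   NAM
#> -0.60 -0.52 -0.31 -0.25
```

Distances to an anchor and ancestry proportions of the same anchor are
negatively correlated, as they should be: women genetically closer to a
panel carry more of its ancestry component.

```r
model <- fitTrajectoryModel(sim$visits)
model
#> TrajectoryModel: cubic-spline mean, cubic-polynomial random effects
#>   subjects: 400  visits: 2241
#>   knots: 16/24/32  boundary: 10/40
#>   sigma^2 (log-g): 0.0004462  converged: TRUE
#>   RE sd: 0.0905 0.0714 0.0402 0.0306

prof <- ancestryProfiles(gd, gap$q, sample_ids = colnames(sim$cohort))
weekly <- weeklyTrajectory(predictWeekly(model), sim$births)
est <- fitBirthweightModels(weekly, sim$grs, prof, sim$covariates, guard = 5)
subset(est, stratum_type == "all")[, c("contrast", "beta", "ci_low",
                                       "ci_high", "p", "n")]
#>   contrast  beta ci_low ci_high      p   n
#> 1       Q2 -79.5   -168     9.0 0.0781 400
#> 2       Q3 -15.8   -106    73.9 0.7288 400
#> 3       Q4 -11.1   -100    77.8 0.8063 400
```

Each row is the adjusted birthweight difference (grams, with 95% CI and
p-value) of that GRS quartile versus the lowest quartile. This seed carries
no injected effect, and none of the contrasts is significant — as a null
world should behave. Setting `effect_strata` and `birthweight_effect` in
`simulationConfig()` plants a known effect that the same models then
recover.

`runPipeline(runConfig(seed, out_dir))` chains all stages
(simulate → GRS → ancestry → growth → associate → report) through files in
`out_dir`, writes a manifest with an md5 for every result table, and is
byte-reproducible for a fixed seed. A command-line wrapper lives at
`inst/scripts/run-pipeline.R`.

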