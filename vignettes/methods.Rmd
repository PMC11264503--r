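---
title: "Methods: maternal polygenic risk and fetal growth across the ancestry continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maternal polygenic risk and fetal growth across the ancestry continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scientific setting

Type-2-diabetes (T2D) risk alleles carried by a pregnant woman can influence
fetal growth through the intrauterine environment, and the strength of that
influence may differ along the continuum of genetic ancestry rather than
across discrete race/ethnicity labels. `fetalgrs` implements the full
analysis chain for studying this question: a weighted maternal genetic risk
score (GRS), two continuous ancestry axes — genetic distance (GD) from
ancestral reference panels and genetic ancestry proportions (GAP) — fetal
weight trajectories estimated from serial ultrasound biometry, and
gestational-week-resolved association models stratified by GD/GAP tertiles.
Because individual-level pregnancy-cohort genotypes are access-restricted,
the package ships a fully specified synthetic-cohort generator with known
ground truth, so every stage is testable end to end.

# The risk score

For each woman $i$, with $d_{ij} \in [0,2]$ the dosage of the T2D-increasing
(effect) allele at SNP $j$ and $w_j$ its log odds ratio from an external
GWAS,
$$\mathrm{GRS}_i = \sum_j d_{ij} \, w_j .$$
The default simulated weight panel has 302 SNPs, the size of the
trans-ancestry T2D panel this design emulates. Before scoring, cohort
genotypes are harmonized to the weight table: variants are located by
chromosome and position, allele sets reconciled (`2 - d` where the counted
allele is the other allele), strand-ambiguous A/T and C/G SNPs dropped by
default (their orientation cannot be resolved from allele labels), and
irreconcilable allele sets dropped with a warning. Missing dosages are
excluded SNP-wise from the sum; no renormalization by default (an optional
flag divides by the number of SNPs used). Quartiles use the
linear-interpolation empirical quantile (R type 7) with boundary ties
assigned to the lower group; quartile 1 (lowest risk) is the reference in
all contrasts. The quantile convention only matters at ties or very small
samples; it is fixed and documented so results are reproducible across
environments.

# Genetic distance

For each of four ancestral anchors (European, African, East Asian,
Amerindigenous analogues), the reference panel's dosages are standardized
per SNP by the panel's own allele frequency ($\mathrm{centre}\ 2\hat p$,
scale $\sqrt{2\hat p(1-\hat p)}$, monomorphic SNPs excluded), the top
$k = 10$ principal axes are extracted by SVD, and each cohort member is
standardized with the panel's constants, projected onto those axes, and
assigned the Euclidean distance from the panel centroid (which is zero by
construction and stored explicitly). Women are then cut into
closest/middle/farthest GD tertiles per anchor.

Standardizing with reference-panel (not cohort) frequencies anchors the
projection: the geometry is a property of the panel, and adding cohort
members never moves it. The number of axes is configurable; $k = 10$ is the
default and the GD ordering is stable across $k$ in the 2–20 range in our
simulations, in the sense that anchor-specific distance rankings are highly
rank-correlated.

**A geometric caveat worth knowing.** When the reference panel is internally
homogeneous — as an idealized, LD-free Balding–Nichols panel is — its top
principal axes are sampling noise, i.e. quasi-random directions. The
standardized between-population mean offset has squared norm of order
$4 F_{ST} M$ across $M$ SNPs, but a projection onto $k$ quasi-random axes
retains only a fraction $k/M$ of it, so the expected squared distance ratio
between a foreign and a native sample is roughly $1 + c\,F_{ST}$ per axis
regardless of $M$. At $k = 10$ and $F_{ST} = 0.15$ this separates anchors
clearly on average (native distances $\approx \sqrt{k}$, foreign distances
visibly larger) but single-individual anchor classification by arg-min GD
retains an error rate of roughly 10–15%. With real panels, genuine internal
structure aligned with continental axes sharpens the separation. The
package reports the classification rate honestly in its acceptance outputs;
GD is used in the analysis as a continuous stratification axis, not as a
classifier, so tertile stratification is unaffected by this.

# Genetic ancestry proportions

GAP is estimated per woman by maximizing the binomial admixture likelihood
$$\ell(q) = \sum_j \big[g_j \log p_j + (2-g_j)\log(1-p_j)\big],
  \qquad p_j = \sum_k q_k f_{kj},$$
over the 4-simplex with an EM algorithm, holding the component frequencies
$f_{kj}$ fixed at the labeled reference-panel estimates (clipped to
$[0.01, 0.99]$ to keep the likelihood finite — standard admixture
practice). The update
$q_k \leftarrow \tfrac{1}{2M'}\sum_j a_{jk}$ with
$a_{jk} = g_j q_k f_{kj}/p_j + (2-g_j) q_k (1-f_{kj})/(1-p_j)$
is run from the uniform start until every sample's log-likelihood gain
falls below `tol` ($10^{-5}$ by default; converged samples are frozen while
the rest iterate, up to 2,000 iterations). A decreasing step aborts the
run, and tests assert the monotonicity invariant explicitly.

This *supervised-frequency* EM deliberately replaces the unsupervised
clustering (ADMIXTURE, k = 4, reference samples included) used in the
design we emulate. The supervised formulation is deterministic, label
identified (components are named by their panels, no post-hoc matching),
convex per sample, and embarrassingly parallel; with labeled panels
available it estimates the same quantity. This is the package's main
methodological substitution and is stated prominently here and in the
function documentation.

GAP estimation runs on LD-pruned genotypes (greedy sliding window, default
window 50 variants, step 5, $r^2 \le 0.1$ — standard practice; within each
window the higher-missingness member of the worst pair is dropped, ties to
the later position). GD uses the full harmonized SNP set; pruning is part
of the admixture workflow, while PCA projection distance does not require
it for the panel sizes used here (the generator produces LD-free SNPs; on
real data with LD the pruner feeds both).

# Fetal weight and its trajectory

Estimated fetal weight (grams) comes from the three-parameter Hadlock
regression on head circumference (HC), abdominal circumference (AC) and
femur length (FL), all in cm:
$$\log_{10} \mathrm{EFW} = 1.326 - 0.00326\,\mathrm{AC}\cdot\mathrm{FL}
  + 0.0107\,\mathrm{HC} + 0.0438\,\mathrm{AC} + 0.158\,\mathrm{FL}.$$
Inputs are checked against plausibility bounds (HC 5–40, AC 5–45,
FL 0.5–9 cm). The 4-parameter Hadlock variant is out of scope; the
coefficients are hard-coded from the published regression.

Per-woman weekly weights are estimated with a linear mixed model on the log
scale,
$$\log w_{ij} = B(t_{ij})^\top \beta +
  (1, \tilde t_{ij}, \tilde t_{ij}^2, \tilde t_{ij}^3)^\top b_i
  + \varepsilon_{ij},$$
with $B$ a natural cubic spline over gestational weeks (interior knots
16/24/32, boundary knots 10/40 — the design gives no knot placement, so we
chose trimester-spaced interior knots; configurable), $\tilde t = (t-25)/15$
the centred/scaled week, $b_i \sim N(0, G)$ a full $4\times4$ random-effect
covariance, and REML estimation via `lme4` (bobyqa optimizer).
Log-scale modelling matches the log-linear Hadlock form and guarantees
positive predictions. Convergence failures are warned about, never
silently accepted; boundary (singular) $G$ estimates are permitted, as
usual for variance components near zero. Weekly weights at integer weeks
10–40 are the exponentiated sum of the fitted mean curve and each woman's
empirical-Bayes (BLUP) random effects; an optional per-week z-standardized
output (cohort mean 0, SD 1 at every week) supports SD-unit effect
reporting alongside grams, because both scales are conventional for this
outcome.

# Association models

All inference is ordinary least squares with classical (non-robust) Wald
95% intervals and two-sided p-values, with no multiple-testing correction —
deliberate, faithful-reproduction choices for an exploratory analysis
design. For each gestational week 10–40 and each stratum (whole cohort and
every anchor × tertile cell of GD and GAP), fetal weight is regressed on
quartile indicators (Q1 reference) adjusted for years lived in the US
(continuous), marital status, maternal age, pre-pregnancy BMI, parity and
fetal sex; birthweight models add gestational age at delivery. Weeks are
fitted independently (no joint longitudinal inference or autocorrelation
adjustment across weeks — also a faithful-reproduction choice, flagged
here). Covariates constant within a stratum are dropped with a warning and
the model refitted; strata smaller than 10 samples per parameter are
skipped and logged. Complete-case covariate handling. Interaction models
regress the outcome on continuous GRS, a continuous modifier (GD or GAP of
one anchor), their product and the covariates, on the full cohort; the
product-term Wald p is the reported interaction p.

# The synthetic cohort

The generator's defaults encode the study conditions it emulates:

* **Cohort**: 1,837 women in four self-identified groups (30.6% / 31.2% /
  27.5% / 10.7%). Admixture proportions are Dirichlet draws per group with
  spiky parameters chosen so cohort-mean GAP lands near 0.48 / 0.30 / 0.12 /
  0.10 (European / African / East Asian / Amerindigenous) with large
  between-woman spread, as in the emulated cohort.
* **Genotypes**: 302 score SNPs + 2,000 ancestry SNPs; ancestral
  frequencies $U(0.05, 0.95)$; Balding–Nichols population frequencies with
  $F_{ST} = 0.15$ (clear but realistic continental-scale divergence),
  clipped to $[0.01, 0.99]$; genotypes binomial given the admixture-mixed
  frequency; reference panels of 100 per anchor drawn with indicator
  admixture. Allele pairs are drawn from the strand-unambiguous
  combinations (panels emulate post-QC array data); the harmonization path
  for ambiguous SNPs is exercised by hand-built fixtures instead. No LD is
  simulated (the pruner must pass unlinked data through unchanged); no
  covariate–genotype confounding by default.
* **Weights**: log odds ratios $N(0, 0.1^2)$ with a uniformly chosen
  effect allele. Because the weights are zero-centred, the simulated score
  is centred near zero rather than at the absolute level a real weight
  panel produces; quartile contrasts are invariant to that location.
* **Growth**: the population mean log-weight curve is a natural cubic
  spline (same knots as the model) calibrated to a standard fetal
  weight-for-age curve and then adjusted so realized birthweight moments
  match the emulated cohort (mean 3,313.92 g, SD 529.05 g at n = 1,837);
  subject random effects have SDs (0.09, 0.07, 0.03, 0.02) for
  intercept/linear/quadratic/cubic in $\tilde t$ with an intercept–slope
  correlation of −0.6 (catch-up growth; also what keeps the term-time
  variance consistent with the birthweight SD). Gestational age at
  delivery is truncated-normal on [30, 42] weeks (a low-risk cohort, and
  the Hadlock validity range) with parameters calibrated so the realized
  mean/SD are 39.16 / 1.97 weeks. Each woman gets an enrollment scan
  (weeks 12.5–13.9) plus five follow-ups in windows determined by one of
  four randomization groups spanning weeks 16–40; visits after delivery
  are dropped, and every woman retains at least two fetal measures (the
  analysis inclusion rule).
* **Biometry**: back-solved from the latent weight through the Hadlock
  inverse along a fixed gestational-age-specific allometric ratio, so the
  growth stage's Hadlock step is exercised end to end; measures are then
  perturbed with 0.1 cm measurement noise (re-drawn, then clamped, at
  plausibility bounds; counts logged). An alternative noise model perturbs
  log EFW directly with a known SD (0.02) and back-solves exactly — used
  by variance-component recovery studies where the residual variance must
  be known. When a measure would leave its plausibility bound under exact
  inversion (tiny early-gestation fetuses), it is pinned at the bound and
  the remaining measures re-solved so the weight is still reproduced
  exactly.
* **Injected effects**: women in configured strata whose GRS is in the top
  quartile receive a gram-scale fetal-weight effect ramping linearly from
  week 17 to `growth_effect` (default 100 g) at week 40, and a
  `birthweight_effect` (default 117 g) shift — the magnitudes echo the
  scale of effects this kind of analysis reports. The default
  `effect_strata` is empty: a null world unless a test or user injects an
  effect. Covariate effects on growth are user-configurable and zero by
  default, since the emulated design does not state them.
* **Covariates**: drawn independently, moments matched to the emulated
  cohort description (age 27.88 ± 5.50, BMI 25.38 ± 5.13, years in US
  23.03 ± 9.47, 53.4% parous, 73.5% married/partnered, 46.7% male).

What the generator does **not** emulate: LD structure, imputation
uncertainty, genotyping error, twin gestations, real reference-panel
substructure, secular or site effects, covariate–outcome confounding.
Passing recovery tests on this synthetic world therefore demonstrates
correctness of the estimators under the stated model, not robustness to
those real-data features.

# Numerical choices

* Quantile convention: type 7 everywhere; boundary ties to the lower
  group; tertile/quartile group sizes differ by at most 1 under distinct
  values.
* EM: uniform initialization, tolerance $10^{-5}$ per-sample log-likelihood
  gain, cap 2,000 iterations, monotonicity asserted; identical component
  frequencies are detected and flagged unidentifiable (uniform GAP
  returned with a warning).
* PCA: exact SVD; loadings orthonormal to $10^{-8}$; monomorphic SNPs
  excluded; distance requires ≥ 80% SNP overlap with the projection
  (configurable), with missing dosages centred.
* Mixed model: REML, bobyqa, derivative checks off for speed; singular
  fits tolerated, non-convergence warned.
* Hadlock inversion: 1-D root-finding restricted to the increasing branch
  of the response in the common scale factor (the $-0.00326\,AC \cdot FL$
  term makes it eventually decreasing), tolerance $10^{-12}$.
* Determinism: every generator operation derives its own seed from the
  single run seed (all derived seeds kept below $2^{31}$); rerunning a
  pipeline config reproduces byte-identical tables, verified by md5 in the
  manifest.

# Problem sizes used by the test suite

The packaged checks run the full design at sizes chosen to make the
Monte-Carlo error a small fraction of each tolerance while keeping a
complete run comfortable on a laptop: frequency/divergence checks at
M = 2,000; GAP recovery at n = 300, M = 2,000; anchor identification at
200 pure-ancestry draws with 100-sample panels; trajectory recovery over
20 replicates of 200 women; association calibration over 500 null and 200
effect replicates at stratum size 600 (regressing on the generator's
latent weekly outcomes, so the calibration isolates the association
machinery from BLUP shrinkage, which attenuates injected effects by only a
few percent at the default noise level); and an end-to-end determinism run
at n = 1,000 with 2,500 SNPs.

# Known limitations

* GD anchor classification accuracy under the idealized generator is
  bounded by the projection geometry discussed above; GD remains a valid
  continuous stratification axis.
* The supervised-frequency EM assumes the reference panels represent the
  true ancestral components; misspecified panels bias GAP (as they do for
  supervised ADMIXTURE).
* Fetal genotypes are not modelled; maternal-score effects on growth are
  marginal with respect to the fetal genome.
* Per-week regressions are not corrected for multiplicity and are serially
  dependent across weeks by construction of the trajectories; effect
  trajectories should be read as descriptive curves, not 31 independent
  discoveries.
* The Hadlock formula itself is known to lose accuracy in the third
  trimester; the package treats it as the measurement standard, not as
  truth.
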