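---
title: "Models and methods: secondary traits in pedigree and genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: secondary traits in pedigree and genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wheat breeding programs evaluate far more lines than they can yield-test.
Aerial high-throughput phenotyping delivers cheap, heritable traits — canopy
temperature (CT) and green/red normalized-difference vegetation indices
(GNDVI, RNDVI), each split into vegetative (VEG) and grain-filling (GF)
growth stages — on every selection candidate. Because these secondary traits
are genetically correlated with grain yield (GY), observing them on the
candidates themselves can sharpen pedigree and genomic predictions of GY
made before any yield plot is harvested. `htpblup` implements the complete
quantitative-genetics pipeline for this idea: phenotype quality control,
relationship matrices, univariate and multi-trait REML, cross-validated
accuracy, and a trial simulator that makes every stage testable.

## Plot-level models and quality control

Within each alpha-lattice trial (30 entries = 28 candidates + 2 repeated
checks, 3 replicates, 6 incomplete blocks of 5), repeatability of a trait on
one measurement date is estimated from

$$y_{ij} = \mu + g_i + r_j + \varepsilon_{ij}, \qquad
  r^2 = \frac{\hat\sigma_g^2}{\hat\sigma_g^2 + \hat\sigma_\varepsilon^2/n_{rep}}$$

with genotype, replicate and residual independent random effects. Across
dates, the model gains date, replicate-within-date and genotype-by-date
terms, and

$$r^2_{overall} = \frac{\hat\sigma_g^2}
  {\hat\sigma_g^2 + \hat\sigma_{gd}^2/n_{date} +
   \hat\sigma_\varepsilon^2/(n_{rep}\,n_{date})}.$$

Note the denominator of $r^2$ deliberately omits the replicate variance; the
replicate effect is absorbed by the model but the repeatability statistic is
defined on the genotype-mean basis shown. `qc_pipeline()` screens each date
for outliers by externally Studentized residuals (two-sided $p < 0.001$; a
single remove-and-refit pass, not iterated, to avoid cascading removals),
drops dates with $r^2 < 0.01$ when doing so improves $r^2_{overall}$
(greedily, worst date first — the criterion does not prescribe an order),
and finally removes any trial in which some trait's overall repeatability
stays below 0.01. The Studentized screen converts internal to external
statistics through the leave-one-out identity with residual degrees of
freedom $n - 2$ (observations minus mean minus one); the random-effect
degrees of freedom are intentionally not charged, which makes the screen
mildly conservative.

`nrep` and `ndate` in all formulas are the *realized* counts in the slice
after removals, not the nominal design values, because outlier removal
unbalances slices.

## Genetic values

Line BLUEs per environment come from the genotype-fixed model with trial,
date, replicate-within-trial-and-date, and block random
(`environment_blues()`). Single-measure traits (GY) drop the date terms;
days to heading (DTHD, scored once on replicate one) keeps only the trial
effect; a per-replicate mode restricts to one replicate and drops replicate
and block terms, emulating unreplicated selection candidates. Each BLUE
carries its observation count as a weight. Across-environment BLUEs add a
random environment main effect and nest every non-genotype term within
environment. Validation BLUPs (`validation_blups()`) switch genotype to an
iid random effect and add a fixed lodging covariate where lodging was scored
(and optionally a DTHD covariate).

For large line sets a genotype-fixed dense design makes the REML fit slow,
so `environment_blues()` then estimates the nuisance variance components
once with genotype random and solves the genotype-fixed generalized least
squares problem through sparse mixed-model equations at those components.
The two parameterizations give nuisance components that differ only
marginally; the small-fixture oracle test verifies the exact path against a
dense GLS solve.

Square roots of broad-sense heritability on the single-plot and line-mean
bases are

$$H_{plot} = \sqrt{\frac{\sigma_g^2}
  {\sigma_g^2 + \sigma_{gd}^2/n_{date} + \sigma_\varepsilon^2/n_{date}}},
\qquad
H_{line} = \sqrt{\frac{\sigma_g^2}
  {\sigma_g^2 + \sigma_{gd}^2/n_{date} +
   \sigma_\varepsilon^2/(n_{rep}\,n_{date})}}$$

with components from the BLUE model with genotype switched to random and a
genotype-by-date interaction added. Zero genetic variance is reported as
$H = 0$ with an `undefined` flag rather than NaN. The heritability model
includes the lodging covariate in environments where lodging was scored,
consistent with the validation model.

## The multi-trait REML engine

The centerpiece is `mt_reml_fit()`: for $t$ traits and a line kernel $K$
(pedigree $A$ = twice the coefficient of parentage by the tabular method;
genomic $G = ZZ'/2\sum_j p_j(1-p_j)$ with column-centered calls; or $I$),

$$y = Xb + Za + e,\qquad a \sim N(0,\, K \otimes H),\qquad
  e \sim N(0,\, I \otimes R)$$

with unstructured $H$ (genetic) and $R$ (residual) covariances. Records may
carry weights: a BLUE built from $w$ plots has residual variance $R_{tt}/w$,
and residual covariances between traits on the same line scale by
$1/\sqrt{w_1 w_2}$ — weights enter the diagonal of $R$. Missing cells are
absent rows of the stacked observation vector, never zeros; predictions for
*all* line-by-trait cells, including masked ones, come from
$\hat a = (K \otimes H) Z' P y$, the mixed-model-equation solution, which
the test suite verifies against brute-force joint-normal conditioning to
$10^{-8}$ relative error on small instances.

Numerical schedule:

* 20 EM iterations for stability, then average-information (AI) updates
  with step halving; convergence at $|\Delta \log L_R| < 10^{-6}$ and
  maximum relative parameter change $< 10^{-5}$; 200-iteration cap.
  Starting values are $H_0 = R_0 = \tfrac12\,\widehat{\mathrm{Cov}}_{phen}$.
* $H$ and $R$ are kept positive definite by eigenvalue bending (floor
  $10^{-6}$ of the mean diagonal) after every update.
* Residual correlations are additionally capped at $|r| \le 0.98$ (genetic
  at $0.9995$). With one BLUE per line and trait, the restricted likelihood
  has degenerate spikes as $R$ approaches singularity — a residual contrast
  that the kernel-structured genetic values can interpolate exactly — and
  the cap is the boundary constraint that excludes them. Residual
  correlations near $\pm 1$ between distinct traits have no biological
  interpretation here.
* Parameters pinned at the zero-variance boundary are frozen out of the AI
  system (they otherwise make it ill-conditioned and stall every
  direction).
* A flat-ridge guard declares convergence when twelve consecutive post-EM
  iterations jointly gain less than 0.015 log-likelihood units. Pedigree
  kernels contain a large identity-like (Mendelian-sampling) component that
  leaves the $H$/$R$ split weakly identified; the remaining crawl along
  that ridge cannot move estimates or predictions meaningfully.
* Two engines share these rules: a rotated engine for complete data (one
  eigendecomposition of $K$ decouples the model into per-line $t \times t$
  blocks) and a dense-covariance engine for masked cells, heterogeneous
  weights, or extra random terms. Their agreement is tested.
* Cross-validation warm-starts each fold's fit from the complete-data
  estimates and then uses pure AI updates; the fold optimum is defined by
  the training records alone.

Genetic correlations (`genetic_correlation_matrix()`) convert $\hat H$ to a
correlation matrix per kernel and average the $A$- and $G$-kernel estimates
elementwise; traits whose genetic variance collapses are flagged undefined
and reported as 0. If a joint fit over many traits fails, pairwise bivariate
fits are used and flagged.

## Prediction and validation

`univariate_predict()` fits $y_i = \mu + \beta\,m_i + g_i + \varepsilon_i$
with $g \sim N(0, K\sigma_g^2)$ on training BLUEs (exact one-dimensional
profile REML after an eigendecomposition) and predicts test lines through
the kernel cross-covariance. `multivariate_predict()` masks GY on the test
lines, keeps secondary-trait BLUEs on everyone, and reads the test lines'
GY genetic values off the multi-trait fit. `unrelated_predict()` stacks
per-replicate BLUEs with $K = I$ plus a random replicate-within-trait
effect; its predictions are of total genetic value.

Accuracy uses five-fold cross-validation with one shared fold assignment:
predictive ability $r_p$ is the Pearson correlation between predictions and
the validation BLUPs, accuracy is $r_g = \bar r_p / H_{line}$, and the
standard error defaults to $\mathrm{sd}(r_p)/(H_{line}\sqrt{k})$ — the
standard error of a mean of $k$ fold abilities. The alternative convention
dividing by $H_{line}\,k$ is available (`se_method = "k"`). $H_{line}$
below 0.05 aborts the scaling rather than producing exploding accuracies.
The gain regression (`gain_regression()`) is ordinary least squares of the
multivariate-minus-univariate gain on kernel kind (reference pedigree),
environment (reference optimal), mean secondary-trait heritability
$\bar H$ (line basis when secondaries were replicated, plot basis when
not), and mean absolute genetic correlation $\bar{|r|}$.

## The simulator

`scenario_presets()` returns configurations for the five trial environments
(optimal, drought, severe drought, late heat, early heat) whose per-trait
heritability targets, secondary-trait/GY genetic correlations, and DTHD/GY
correlations equal the reference tables shipped with the package
(`reference_heritabilities()`, `reference_genetic_correlations()`); the
default population is 557 candidate lines and 12,083 markers, with trials
of 28 candidates plus 2 checks in 3 replicates and 6 blocks, and the
published count of measurement dates per growth stage.

Design choices where the published pairwise values underdetermine the
generator:

* The full trait correlation matrix is completed with a single latent
  factor: each trait loads on a grain-yield factor by its published
  correlation with GY, so all published pairs are preserved exactly and the
  matrix is positive definite by construction (a final eigenvalue bend at
  $10^{-4}$ is a guard). Secondary-trait intercorrelations are therefore
  products of loadings — high for traits that share a strong GY
  correlation, as observed in such trials.
* Multi-environment configurations correlate the latent factors across
  environments at `rho_between` (default 0.6), giving genotype-by-
  environment interaction for GY without per-pair bookkeeping.
* True genetic values follow the scaled marker-effect model
  $a = Z B$ with marker-effect rows drawn from the configured covariance
  divided by the VanRaden denominator, then normalized to unit per-line
  genetic variance (inbred populations have kernel diagonals near
  $1 + F \approx 2$, which would otherwise inflate every cell variance).
  Founders are inbred with allele frequencies from Uniform(0.05, 0.95);
  lines descend from biparental crosses followed by four generations of
  marker-wise independent selfing (no linkage — a stated non-goal), giving
  $F \approx 0.94$ and a pedigree recording the chain.
* Error and genotype-by-date variances are solved from the *pair* of
  heritability targets: $\sigma_{gd}^2/n_{date} + \sigma_\varepsilon^2 /
  n_{date} = \sigma_g^2 (H_{plot}^{-2} - 1)$ together with the analogous
  line-basis equation. When the two targets are jointly infeasible (very
  high $H_{plot}$), $\sigma_{gd}^2$ is clamped at zero and the line-basis
  target kept — $H_{line}$ is the quantity that scales accuracy. When no
  plot-basis target is given, $\sigma_{gd}^2$ defaults to 25% of the
  genetic variance. Nuisance variances (trial 0.5, date 0.5, replicate 0.2,
  block 0.1, in genetic-variance units) are round numbers of the magnitude
  seen in yield trials.
* DTHD is simulated as a once-measured trait on replicate one with
  single-plot heritability 0.9 and written both as trait rows and as a
  per-line covariate column; lodging scores (0–5) appear only in
  environments flagged for lodging and subtract from GY at 0.3 genetic-SD
  units per score point.

What the simulator does *not* emulate: linkage and LD structure, spatial
field trend, selection history, heteroscedastic measurement error across
dates, and check-vs-candidate management differences. Passing tests
therefore demonstrate internal statistical consistency of the pipeline
under its own assumptions, not performance on any particular real dataset.

## Problem sizes in the tests and acceptance script

The test suite exercises parameter recovery with 20 replicates of 500-line
populations (heritability and genetic correlation on the early heat
scenario), 20 replicates of 100-line populations for the directional
multivariate-vs-univariate comparison under both kernels, and 20 replicates
per level for the gain-vs-correlation monotonicity sweep; small-instance
algebraic checks use 5–12 lines. The acceptance script reruns the recovery
at 500 lines (12 replicates) and the five-environment cross-validation
study at 120 lines with the two strongest grain-filling secondary traits.
These sizes were chosen so each study gives stable Monte Carlo averages at
desk scale; all of them are arguments, and the full-size study
configuration (557 lines, 12,083 markers, six secondary traits) is the
generator default.

## Known limitations

* The unstructured-$R$ REML surface is weakly identified when each line
  contributes a single record per trait and the kernel is close to a scaled
  identity; estimates then sit on a flat ridge (predictions are stable, the
  $H$/$R$ split is not). Pedigree kernels are the worst case.
* Across-environment prediction uses pooled across-environment BLUEs for
  the secondary traits on both training and test sets; obtaining test-set
  secondaries from the target environment instead is a one-line change in
  the task construction and changes the question being asked.
* The outlier screen's degrees of freedom ignore the random-effect
  dimension, which is slightly conservative for small slices.
* Genetic correlations from the averaged $A$/$G$ estimates carry no
  standard errors.
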