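---
title: "Methylation population scores: model, training procedure, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation population scores: model, training procedure, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

A methylation population score (MPS) is a sparse linear predictor of a
genetic principal component (GPC) built from CpG beta values:

$$\mathrm{MPS}_k(s) \;=\; \sum_{j \in S_k} w_{kj}\,\beta_{sj},$$

where $\beta_{sj} \in [0,1]$ is sample $s$'s methylated fraction at CpG $j$
and $S_k$ is a small set of CpGs selected during training. The premise is
biological: a subset of CpGs sit under genetic control (mQTLs) whose allele
frequencies differ across populations, so those CpGs carry ancestry
information. The hazard is that methylation also responds to age, sex,
smoking, adiposity, blood cell composition and cohort-level processing;
unsupervised methylation PCA mixes all of these. MPS training therefore
conditions on those factors throughout, so that the score tracks the
genetic axis specifically.

## Stage 1 — covariate-adjusted association scan, meta-analyzed

Within each cohort's training samples we fit, per CpG $j$,

$$\mathrm{GPC}_k = \alpha + \beta_j\,\mathrm{CpG}_j + \gamma^\top C + \varepsilon,$$

with covariates $C$ = age (years), sex, smoking (0 = never, 1 =
former/current), alcohol (when available), BMI (kg/m²), cell-type
proportions (one simplex column dropped), and — across cohorts — study
center and self-reported group as treatment-coded indicators. Putting the
GPC on the left and the CpG on the right is equivalent, for the CpG's
partial effect, to the reverse orientation: by the Frisch–Waugh–Lovell
theorem the covariates are "regressed out" of both sides either way, and a
single-outcome orientation lets one scan serve flexible per-CpG tests. The
scan is implemented exactly that way internally — one QR residualization of
the GPC and of the full CpG matrix on the covariates, then per-CpG simple
regressions — which is algebraically identical to per-CpG OLS (verified
against `lm()` in the tests) and fast enough for epigenome-wide use.

Per-cohort estimates use two-sided $t$ p-values with residual degrees of
freedom. Cohorts are pooled by inverse-variance fixed-effects
meta-analysis, $\hat\beta = \sum_i w_i\hat\beta_i / \sum_i w_i$ with
$w_i = 1/\mathrm{se}_i^2$, and the pooled p-value uses the normal
distribution — conventional for meta-analysis, and at the cohort sizes
involved the $t$/normal distinction is immaterial. CpGs absent (or constant)
in some cohorts are pooled over the cohorts that measured them, maximizing
the CpG universe when arrays differ in coverage. Benjamini–Hochberg
step-up q-values gate selection at $q < 0.05$.

## Stage 2 — two-stage weighted Lasso

On the training data aggregated across cohorts (alcohol excluded from the
covariates here because of partial availability), each GPC is fit by Lasso
with the selected CpGs as penalized predictors and all covariates
unpenalized (penalty factor 0). Covariates enter the Lasso directly rather
than being residualized out beforehand; with no penalty on them, the two
treatments coincide for the CpG coefficients. The penalty $\lambda$
minimizes 10-fold cross-validated (weighted) mean squared error with seeded
fold assignment; predictors are standardized internally and coefficients
are reported on the raw beta-value scale, so the exported weights apply
directly to beta matrices without any standardization step at scoring time.

GPC variance differs across ancestry groups (allele-frequency and LD
structure differ), so a homoskedastic fit is mis-weighted. The second stage
corrects this empirically: the GPC is regressed on the initial score
(no covariates), the squared residuals are truncated at their 90th
percentile, floored at a tiny positive value, and rescaled to sum to $n$;
these become per-observation weights in a second Lasso over the same
selected-CpG universe, which yields the final model. The exported score is
the pure weighted CpG sum — the intercept and covariate terms are stored in
the model but excluded, since every downstream use (correlation,
regression adjustment) is invariant to location and covariate offsets.

## Scoring, evaluation, EWAS

`compute_mps()` applies weights to any beta matrix: CpGs entirely absent
from the target data are dropped from the sum (no reweighting) and the
coverage fraction is reported; sporadically missing cells are imputed by
the target data's own per-CpG mean, the same rule the PCA comparator uses.
Evaluation reports the full Pearson correlation matrix between MPSs and
GPCs, the partial $R^2$ of each MPS for its GPC given covariates
($({\rm RSS}_{\rm reduced}-{\rm RSS}_{\rm full})/{\rm RSS}_{\rm reduced}$),
and an unsupervised comparator: PCA on a user-supplied CpG list with mean
imputation. `run_ewas()` regresses each CpG on a binary exposure plus
covariates and, optionally, structure adjusters (GPCs, MPSs, or in
simulation the latent ancestry itself), and summarizes calibration by the
genomic inflation factor $\lambda_{\rm GC} = \mathrm{median}(\chi^2_1)/0.4549364$.

# Tunable parameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| `n_components` (K) | 10 | — | structure beyond the top ten components is rarely adjusted for in association studies |
| `q_threshold` | 0.05 | FDR | the conventional discovery gate for the selection scan |
| `train_fraction` | 0.85 | per cohort | leaves a test set large enough to estimate correlations while maximizing training data; split stratified by cohort, rounded to nearest with ties toward train |
| `truncation_quantile` | 0.90 | empirical quantile | caps the influence of the worst-predicted samples on the stage-2 loss while keeping 10% of samples up-weighted |
| `cv_folds` | 10 | — | standard bias/variance compromise for `cv.glmnet`; $\lambda$ at the CV minimum |
| `n_adjusters` | 5 | components | EWAS comparisons conventionally adjust for the leading handful of components, not all K |

# What the synthetic data emulates — and what it does not

The generator produces multi-cohort datasets in which one latent structure
drives both genotypes and a CpG subset, which is exactly the situation the
method exploits:

* **Genotypes** follow a Balding–Nichols model: ancestral frequencies
  uniform on the minor-allele-frequency range, population frequencies
  $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ so between-population variance is
  $F\,p(1-p)$, per-sample ancestry proportions Dirichlet (concentration 0.5
  by default — substantial admixture; concentration $\le 0$ is the
  unadmixed one-hot limit), and dosages Binomial(2, mixed frequency). A
  Hudson-type estimator on simulated output recovers the nominal $F_{ST}$
  within ±0.03 (test-verified), and genotype PCA recovers the population
  axis with $|r| > 0.9$.
* **Methylation**: per-CpG baselines uniform on (0.05, 0.95); a chosen
  subset of CpGs is shifted linearly in the ancestry proportion
  (0.2 beta units per unit proportion by default, random sign and target
  population) — a direct stand-in for per-SNP mQTL effects that is
  sufficient to create the CpG–GPC associations the scan must find;
  covariates (age, sex, smoking, BMI, cell proportions) shift random CpG
  subsets by a configured amount per covariate SD; Gaussian noise
  (sd 0.05) is added and values are clipped to [0, 1].
* **Covariates** mimic middle-aged cohort summaries: age ~ N(55, 8) years,
  BMI ~ N(29, 5) kg/m², Bernoulli sex/smoking/alcohol, six blood cell
  proportions from a Dirichlet with a granulocyte-dominated mean. The
  self-reported `group` label is the sample's majority latent population.
* **Confounded-exposure knob**: exposure prevalence can be made logistic in
  the ancestry proportion, which manufactures genuine
  stratification-induced EWAS inflation (unadjusted $\lambda_{\rm GC}
  \approx 1.75$ under the standard confounded design of
  `scripts/acceptance.R`, versus $\approx 1.00$ after adjustment).

Deliberately not emulated: array chemistry and probe bias, normalization
pipelines and batch structure, relatedness/kinship, LD between variants,
per-SNP mQTL architecture, and bimodal beta distributions. Passing tests
therefore demonstrate that the statistical machinery recovers structure
under its stated model — not that real-data preprocessing hazards are
handled; on real arrays the usual normalization and QC must happen
upstream.

Standard problem sizes in the tests and acceptance script: five cohorts of
225/272/330/566/357 samples (mirroring relative real-cohort sizes at ~¼
scale), 2000 CpGs with 50 ancestry-linked (400 in the confounded-EWAS
design), 2000 variants, $F_{ST}$ = 0.1 between two populations. These sizes
keep full runs in minutes while leaving all effects comfortably detectable.

# Numerical choices

* **Quantile rule.** The truncation quantile uses linear interpolation
  between order statistics (R type 7); the documented worked example
  (squared residuals 1, 1, 1, 4 → cap 3.1 → weights ≈ 0.656, 0.656, 0.656,
  2.033) depends on this rule, so it is pinned.
* **Truncate, then normalize.** Capping precedes the rescale so the
  sum-equals-$n$ contract holds exactly after truncation. Weights are
  floored at $10^{-12}\max(\mathrm{cap},1)$ so an exactly-interpolating
  sample cannot produce a zero weight.
* **Genotype standardization** uses $\sqrt{2\hat p(1-\hat p)}$ (the
  Hardy–Weinberg variance), the population-genetics convention, rather than
  the empirical SD; monomorphic variants are dropped with a message.
* **Deterministic SVD with a sign convention**: each component is flipped so
  its largest-magnitude loading is positive, making scores reproducible
  across linear-algebra backends. Requested components beyond the matrix
  rank are truncated with a warning.
* **Degenerate inputs**: constant CpGs give NA scan rows; an empty
  selection or an all-zero cross-validated Lasso path returns an
  empty-weight degenerate model with a warning instead of failing, so null
  components (common when K exceeds the true structure) flow through the
  pipeline.
* **Raw beta scale.** CpGs are not standardized before the scan or the
  Lasso's coefficient reporting, so weights have units "per beta value" and
  transfer to external data without reference statistics; the weight-file
  header records this.
* **Determinism.** One master seed fans out to per-stage seeds through a
  documented hash; identical seeds reproduce byte-identical weight files
  and manifest checksums, which is why emitted files carry no timestamps.
* **MPC comparator scaling.** The PCA comparator centers and unit-variance
  scales CpG columns by default (per-probe beta scales vary); the flag is
  recorded in the result so either convention is reproducible.

# Known limitations

* Weights transfer only as far as CpG overlap allows: absent CpGs are
  dropped, not imputed from neighbors, and coverage is reported so users
  can judge attrition.
* The group-separation ratio (between/within sum-of-squares) is a
  package-level convenience metric for automated comparisons; separation
  quality is usually judged visually.
* With the clean noise model of the simulations, a well-trained MPS is a
  near-perfect proxy of the latent ancestry proportion: in the confounded
  EWAS design, MPS-adjusted and truth-adjusted scans give inflation factors
  that differ by less than the seed-to-seed noise (medians within ~0.01 of
  each other, against an unadjusted median of ~1.75). The simulations can
  therefore demonstrate that MPS adjustment removes stratification-induced
  inflation, but cannot resolve an ordering between MPS and the true
  confounder — on real data, where methylation noise is larger and
  structured, MPSs should be expected to leave more residual inflation
  than genetic adjusters.
* The EWAS engine is a linear model with a 0/1 exposure on the methylation
  side; mixed models, robust standard errors and logistic alternatives are
  out of scope.
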