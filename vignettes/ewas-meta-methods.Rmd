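---
title: "Methods: multi-cohort EWAS meta-analysis with synthetic consortia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort EWAS meta-analysis with synthetic consortia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewasmeta)
```

## The analysis problem

Consortium epigenome-wide association studies (EWAS) of prenatal exposures
ask whether a parental phenotype — here parental body mass index (BMI) — is
associated with offspring blood DNA methylation. Individual-level data
cannot leave the cohorts, so each cohort runs the same pre-specified
analysis plan locally and ships only per-CpG summary statistics (estimate,
SE, p, n) to a coordinating centre, which pools them by fixed-effects
meta-analysis. `ewasmeta` implements both halves of that workflow — the
cohort-level analysis plan and the meta-analysis pipeline — together with a
synthetic consortium generator so that the whole chain can be validated
against known ground truth.

## Cohort-level model

Each cohort analyses normalized, untransformed methylation beta values
(proportions in $[0,1]$). For probe $j$ and exposure $Z$-score $z$ (BMI
standardized *within* the cohort, $n-1$ denominator), the model is ordinary
least squares:

$$\beta_{j} = \alpha + \theta_j z + \gamma^\top C + \delta^\top \hat{\pi} + \eta^\top \mathrm{SV} + \varepsilon$$

with covariates $C$ = {paternal age, maternal age, maternal smoking,
paternal smoking, paternal socio-economic position, parity}, estimated cell
proportions $\hat\pi$ (one cell type dropped, since proportions sum to one),
and $k$ surrogate variables. The mutually adjusted variant adds the other
parent's BMI $Z$-score; secondary models stratify by child sex. The
reported effect is $100\,\hat\theta_j$ — percentage-methylation points per
1 SD of BMI — with $SE$ on the same scale and a two-sided $t$ p-value on
the residual degrees of freedom (small sex strata make the $t$ reference
preferable to the normal).

Pre-processing steps, in order:

* **Outlier removal (Tukey).** Per probe, values outside
  $[Q_1 - 3\,\mathrm{IQR},\, Q_3 + 3\,\mathrm{IQR}]$ are set missing;
  such outliers typically reflect technical error or a rare SNP under the
  probe. Quartiles use the linear-interpolation convention (R quantile
  type 7) — the convention must be pinned for cross-cohort reproducibility.
  Probes with fewer than 4 non-missing values are skipped with a warning.
* **Cell-type deconvolution.** Reference-based constrained projection in
  the Houseman tradition: each sample's betas at the reference probes are
  regressed on the reference profiles under nonnegativity (a Lawson–Hanson
  active-set solver on the normal equations, exact for these small
  full-rank systems) and renormalized to sum to one. A `sum_to_one = FALSE`
  switch leaves the raw nonnegative solution (row sums $\le 1$ up to noise).
* **Surrogate variables.** Each probe is residualized on the covariate
  design *without* the exposure, and the top-$k$ principal directions of
  the residual matrix in sample space are used as SVs ($k = 20$ by
  default). Leaving the exposure out of the residualizing design is a
  deliberate inference choice, settled empirically during development:
  the SVs then track the latent technical factors in full — including
  their chance in-sample correlation with the exposure — so adjusting for
  them removes batch noise from the exposure direction too and the
  exposure's standard errors stay calibrated (null simulations give
  genomic inflation $\lambda \approx 1$). The alternative, residualizing
  on a design that includes the exposure, forces the SVs orthogonal to it;
  the batch noise that happens to align with the exposure then survives
  adjustment while the residual variance shrinks, and standard errors
  become anti-conservative. The cost of the chosen design is that genuine
  exposure effects could in principle leak into the SVs — negligible as
  long as affected probes are a vanishing fraction of the array, which is
  the realistic EWAS regime. This is a
  deterministic simplification of iterative SVA: the number of factors is
  fixed a priori rather than estimated, which makes cohort results exactly
  reproducible. SVs are orthogonal to the covariate design by construction;
  signs are fixed by requiring the first non-negligible loading positive.
  Computationally the SVs are eigenvectors of the $n \times n$ Gram matrix
  of the residualized data, which is much cheaper than a full SVD at array
  scale.

Analysis is complete-case per probe. Sex strata below a minimum size
(default 30) raise a typed condition and the cohort is omitted from that
stratified meta-analysis rather than contributing unstable estimates.

## Meta-analysis pipeline

The coordinating-centre pipeline runs, in order: probe
filtering/harmonization, cohort-results QC, fixed-effects meta-analysis,
FDR adjustment, meta-level QC, leave-one-out stability analysis at top
probes, optional meta-regression on cohort mean age, sensitivity subset
meta-analyses, maternal-vs-paternal comparison and candidate-set
enrichment.

* **Probe filtering.** Retain probes present on both the 450k and EPIC
  arrays, excluding control/QC probes, SNP probes, cross-hybridizing probes
  and the sex chromosomes. Exclusion counts are reported per rule in
  application order without double counting. Real manifest/flag lists enter
  as a user-supplied annotation table; the package ships a simulator for
  testing.
* **Fixed-effects pooling.** With $w_i = 1/SE_i^2$:
  $\hat\beta = \sum w_i \beta_i / \sum w_i$, $SE = (\sum w_i)^{-1/2}$,
  $z = \hat\beta / SE$ with a normal reference (the convention of the
  standard meta-analysis tools for genome-wide summary statistics),
  Cochran's $Q = \sum w_i (\beta_i - \hat\beta)^2$ on $k-1$ df and
  $I^2 = \max(0, (Q - df)/Q) \times 100$. Probes present in a single cohort
  are retained with $k=1$, $I^2=0$ (filter on `k` if undesired). A
  METAL-style direction string (`+`/`-`/`?`) records per-cohort signs.
* **Multiple testing.** Benjamini–Hochberg FDR within each model/stratum
  analysis separately (each analysis answers its own question); the
  significance threshold is FDR $< 0.05$.
* **Genomic inflation.** $\lambda$ = median of the observed 1-df
  $\chi^2$ quantiles divided by the null median ($\approx 0.4549$).
  $\lambda$ is reported, never used to correct p-values.
* **Leave-one-out.** At probes with FDR $< 0.05$ plus a relaxed tier
  ($p < 10^{-5}$), each cohort is omitted in turn and the rest re-pooled. A
  probe survives iff no omission (i) flips the direction of the pooled
  estimate, (ii) changes it by more than 20% (counted in either direction —
  a >20% *increase* also indicates single-cohort dependence), or (iii)
  yields a 95% CI crossing the null.
* **Meta-regression.** Inverse-variance weighted least squares of cohort
  estimates on cohort mean age at sample collection; slope per year,
  normal reference.
* **Sensitivity subsets.** The identical pipeline re-run excluding named
  cohorts (e.g. cohorts whose exposure was reported by the other parent),
  with FDR re-ranked within the subset.
* **Comparison and enrichment.** Between-parent heterogeneity
  $Q = (\beta_p - \beta_m)^2 / (SE_p^2 + SE_m^2)$ on 1 df with the
  two-estimate $I^2$; model-comparison summaries (Spearman correlation,
  per-probe percentage difference with the unadjusted model as baseline,
  share of probes with larger absolute estimates); one-sample
  Kolmogorov–Smirnov tests of candidate-set p-values against Uniform(0,1)
  (two-sided by default, with a one-sided "inflation" option aimed at an
  excess of small p-values); and direction-of-effect concordance with
  within-set BH correction at $m$ = set size. Gene-interval candidate sets
  are mapped to probes on 1-based closed coordinates (probe position
  inside the interval, strand ignored).

## The synthetic consortium generator

The generator emulates the statistical structure of a multi-cohort birth
consortium; its defaults are the study conditions the package is validated
under.

* **Cohorts.** 13 cohorts of 70–982 samples (total 4894), each with its own
  parental-BMI means/SDs; paternal BMI has higher mean and lower SD than
  maternal in every cohort. Parental BMIs are bivariate Gaussian with
  correlation 0.2 (assortative mating / shared environment), truncated to
  15–60 kg/m² — bounds wide enough to cover the realistic range without
  pathological values.
* **Cell composition.** Per-sample proportions are Dirichlet around a
  typical cord-blood composition (granulocyte-dominated, including a
  nucleated-red-blood-cell component); the reference profiles have
  cell-type-specific means at an informative probe subset so deconvolution
  is identifiable.
* **Latent structure.** 20 batch factors (matching the number of SVs
  estimated downstream), each loading on a random ~30% of probes.
* **Signal construction.** The methylation background is built as the
  cell-mixture baseline, mapped to the logistic scale, plus batch loadings
  and noise, then squashed back to $[0,1]$ — the unbounded scale keeps
  betas bounded under additive latent structure. Injected effects are then
  added *on the beta scale* (effect × exposure $Z$, clipped to $[0,1]$
  with a warning), so the ground-truth linear slope equals the requested
  percentage points per SD exactly on the scale the EWAS estimates. This
  is deliberate: constructing effects on the logistic scale and
  calibrating the marginal slope numerically was tried first, but the
  squash curvature makes the effect interact with the latent batch
  factors, so the *covariate-adjusted* slope — what the EWAS actually
  estimates — jitters irreducibly around any marginal calibration target
  (confidence-interval coverage of injected effects stayed well below
  nominal even when adjusting for the true simulated covariates).
  Beta-scale injection removes that interaction and makes recovery
  experiments exact.
* **Noise.** Gaussian on the logistic scale, scaled per probe by
  $1/\max(\mu(1-\mu), 0.05)$ so that the realized *beta-scale* residual SD
  approximately equals `noise_sd` (default 0.02, i.e. 2 percentage points,
  typical for array data) regardless of the probe's baseline methylation.
* **Missingness** is completely at random at a configurable rate (real
  cohort missingness mechanisms are unknown; MCAR is the neutral choice),
  and **sub-seeding** derives each cohort's seed deterministically from the
  master seed and cohort index, so any cohort can be regenerated alone.
* **Injectable effects** specify probe, parent (paternal/maternal/both),
  effect size in percentage points per SD, an optional sex restriction, and
  an optional cohort restriction (for single-cohort artefacts used to test
  leave-one-out and sensitivity exclusions). Effects for "both" parents are
  calibrated sequentially (paternal first), since a joint calibration target
  is not identifiable.

What the generator does **not** emulate: raw array intensities, probe
chemistry or normalization pipelines; SNP-driven methylation structure;
genuine biological covariance between neighbouring CpGs; informative
missingness. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under the stated generative model —
not that any biological preprocessing upstream of beta values is handled.

## Key parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `n_surrogate_variables` | 20 | SVs per cohort model |
| `noise_sd` | 0.02 | beta-scale residual SD |
| `parent_bmi_correlation` | 0.2 | latent Gaussian correlation |
| `n_batch_factors` | 20 | latent technical factors |
| `fdr_threshold` | 0.05 | significance threshold |
| `attenuation_threshold` | 0.20 | leave-one-out change-in-estimate |
| `loo_p_relaxed` | 1e-5 | relaxed tier for leave-one-out reporting |
| `min_stratum_size` | 30 | smallest analysable sex stratum |
| `extreme_bound` (QC) | 10 | flag estimates beyond ±10 pp/SD |

## Numerical and design choices

* Quartiles: R type 7 (linear interpolation); Tukey multiplier 3×IQR.
* Pooled $z$ uses the normal reference; cohort-level p-values use $t$.
* 95% CIs use $z = 1.96$ throughout the leave-one-out analysis.
* One cell-proportion column is dropped from regression designs (exact
  collinearity with the intercept otherwise).
* Rank-deficient designs raise an error naming the collinear columns
  rather than silently dropping them.
* The per-CpG fits use one QR factorization of the design for all
  complete probes (semi-normal equations for the coefficients and RSS);
  probes with missing values use rank-$|S|$ downdates of the normal
  equations. Both paths agree with `lm()` to near machine precision.
* The EWAS exposure estimate for the mutually adjusted and unadjusted
  models coincides exactly when the two exposures are orthogonal in-sample
  (Frisch–Waugh–Lovell); this is exercised as a test invariant.
* BH-FDR and KS tests call the standard R implementations
  (`p.adjust`, `ks.test`); hand-coded step-up/brute-force oracles exist
  only in the test suite as independent checks.

## Validation problem sizes

The test suite validates null calibration on consortia of 5 cohorts × 500
samples × 10,000 probes over 20 seeds (genomic inflation within
[0.9, 1.1] and zero FDR discoveries expected in almost all runs);
parameter recovery with 20 injected effects of 0.2–3 percentage points per
SD at 5 × 500 × 10,000 probes (effects kept to 0.2% of the array so
data-driven adjustment cannot meaningfully absorb them — at consortium
precision, pooled SEs near 0.04 percentage points, even sub-percent signal
absorption by estimated cell proportions or surrogate variables is visible
against nominal confidence intervals, a documented property of
estimated-covariate EWAS rather than a defect); leave-one-out behaviour
over 40 seeded micro-consortia; and
oracle equivalence of all pooling formulas on 1,000 random instances at
1e-10. Recovery and stability checks inject effects only at
mid-methylation CpGs (all reference cell-type means in [0.15, 0.85]): at
boundary-saturated probes a linear percentage-point effect has no room to
move, the logistic construction makes the injected relation step-like, and
the Tukey step legitimately removes the resulting extreme values — the same
reason real EWAS effect estimates at near-0/1 CpGs are hard to interpret. The bundled acceptance script runs the full pipeline on the
13-cohort default consortium (n = 4894) at 2,000 probes.

## Known limitations

* Fixed-effects pooling only; random-effects and sample-size-weighted
  modes are out of scope (cell-proportion meta-analysis exposes the same
  fixed-effects core).
* Plain OLS per CpG — no empirical-Bayes variance moderation; with
  consortium-scale samples the moderation gain is marginal, but cohort SEs
  at very small strata will differ slightly from a moderated analysis.
* The simplified SV estimator protects the exposure by excluding it from
  the residualizing design; whether real consortium cohorts did the same
  is unknowable from summary statistics, so this is a documented
  interpretation, not a reproduction.
* Candidate lists (previously reported CpGs or gene sets) enter as files;
  the package does not re-derive them, and gene-level results reduced to
  CpG positions inherit whatever ambiguity the original mapping had.
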