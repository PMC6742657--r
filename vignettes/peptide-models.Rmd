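---
title: "Peptide-level models for label-free proteomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-level models for label-free proteomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepnet)
library(dplyr)
```

pepnet quantifies protein-level, PTM-site-level and pathway-level responses
from label-free peptide-ion intensity tables of the kind exported by MS
alignment software, for experiments with a handful of biological donors and
a small set of treatment conditions (the motivating setting is mesenchymal
stem cells under cyclic tensile strain, three donors, control versus
strained). This vignette explains the models, the estimation machinery, the
synthetic-data generators used for validation, and the design decisions a
maintainer should know about.

## The peptide-level protein model

Label-free quantification observes each protein only through its peptide
ions, whose intensities differ by orders of magnitude for purely
physico-chemical reasons. pepnet therefore models log2 peptide-ion
intensity directly, one model per protein:

$$
y_{fgd} = \beta_0 + X_f\beta_f + X_g\beta_g + X_d\beta_d
        + X_fX_g\,\beta_{fg} + X_fX_d\,\beta_{fd} + \varepsilon_{fgd},
\qquad \varepsilon \sim N(0, \sigma^2/w)
$$

where $f$ indexes peptide ions, $g$ treatment groups and $d$ donors.
Treatment uses reference-cell coding, so each $\beta_g$ reads directly as
the protein's log2 fold change versus the reference group; peptide and
donor effects use sum-to-zero coding. The peptide-by-treatment interaction
$\beta_{fg}$ captures a peptide that responds differently from its protein
— for a modified peptide this is the log2 change in *site occupancy*, the
fraction of the protein carrying the modification. Rows exist only for
observed intensities; no imputation is performed.

Under sum-to-zero coding, the identified $\beta_{fg}$ of a modified peptide
is deflated by $k/F$ when $k$ of the protein's $F$ peptides carry a
modification (the group effect absorbs the mean shift). The occupancy
estimate reported by `site_occupancy_changes()` is therefore the linear
contrast between the modified peptide's interaction and the mean
interaction of the unmodified peptides, which equals the true occupancy
shift for any $k < F$. Proteins with no unmodified peptide do not identify
occupancy and are skipped with a message. When several peptides cover one
site the per-peptide contrasts are combined by inverse-variance weighting.

## Confidence-weighted Bayesian elastic-net estimation

The model is fitted by a Gibbs sampler with two distinctive features.

**Observation weights.** Each iteration recomputes a weight per
observation from the current standardized residual $r$ and the ion's
identification confidence $q_c = 1 - 10^{-S/10}$ (the Mascot score $S$ is
$-10\log_{10}$ of the random-match probability):

$$ w = q_c + (1 - q_c)\,\frac{1}{1 + (r/c)^2}. $$

A confidently identified ion keeps weight near 1 however large its
residual — a genuine biological outlier (say, a differentially modified
peptide) is not silenced — while a low-confidence ion with a large
residual is down-weighted as a likely misidentification. The scale
constant $c$ defaults to 3 standardized residuals; weights live in
$(0, 1]$ and $w = 1$ at $r = 0$ for any score.

**Elastic-net prior on nuisance parameters.** Peptide ionization effects,
donor effects and peptide-by-donor interactions are numerous and mostly
small; they carry an elastic-net prior in its Gaussian scale-mixture form
(per-coefficient latent scales $\tau_j$ for the lasso part, a shared ridge
penalty $\lambda_2$, gamma(1, 1) hyperpriors on $\lambda_1^2$ and
$\lambda_2$). Two deliberate choices depart from textbook formulations:

* *The prior is not scaled by $\sigma^2$.* With many genuinely large
  coefficients (ionization effects span log2 units) and $p$ comparable to
  $n$, a $\sigma^2$-scaled penalty feeds the penalty quadratic form into
  the $\sigma^2$ conditional at the same order as the residual sum of
  squares; the chain then contracts to a degenerate mode in which every
  coefficient is shrunk and $\sigma^2$ absorbs the signal (we observed
  posterior $\sigma^2$ inflated ~30-fold over the least-squares value).
  Unscaled, $\sigma^2\mid\text{rest}$ is a plain inverse gamma on the
  weighted residuals and no such feedback exists.
* *Inferential targets are unpenalized.* The group effects $\beta_g$ and
  the peptide-by-treatment interactions $\beta_{fg}$ are what the pipeline
  reports and tests; shrinking them would bias exactly those estimates
  (we measured ~4% deflation of occupancy contrasts under a global
  penalty). Regularizing the nuisance families stabilizes the fit without
  touching the estimands — the standard position in penalized effect
  estimation. The intercept is likewise unpenalized.

Chains run 4,000 iterations with 1,000 burn-in by default, no thinning.
Convergence is monitored by split-half $\widehat{R}$ on each $\beta_g$;
fits with $\widehat{R} > 1.1$ are flagged, not discarded. Posterior
summaries carry batch-means Monte Carlo standard errors. With fixed
penalties near zero and informative scores the sampler reproduces ordinary
least squares, which is the basis of its oracle test. Identical seeds give
bit-identical results; batch fits seed one stream and fit proteins in
sorted accession order.

## Moderated inference

Per-protein residual variances from small designs are unstable. pepnet
pools them with the classical empirical-Bayes treatment: the variances are
modeled as draws from a scaled inverse chi-square prior whose parameters
$(d_0, s_0^2)$ are estimated by matching the first two moments of
$\log s^2$, accounting for the chi-square sampling noise of each $s^2$
given its residual degrees of freedom (a Newton solve of the trigamma
equation). Each protein's variance shrinks to
$\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, standard errors scale by
$\tilde{s}/s$, and two-tailed moderated $t$-tests on $d_0 + d$ degrees of
freedom are adjusted by Benjamini–Hochberg across the batch. With fewer
than two distinct variances the state falls back to no moderation
($d_0 = 0$). The implementation is cross-checked in the test suite against
limma's `fitFDist`/`squeezeVar`, which it matches to numerical precision;
limma is only ever the oracle, not the implementation.

## Ingest rules

* Identification-confidence filter: scores map to $p = 10^{-S/10}$,
  BH-adjusted across all peptides; peptides at or above the threshold
  (default 0.2) are removed. The score-to-p identity is the defining
  relation of Mascot ion scores; the threshold is a configuration value.
* Support filter: proteins with fewer than 3 distinct unique peptide
  sequences are removed entirely (boundary inclusive; shared peptides do
  not count and are excluded from fitting).
* Normalization: log2, then subtraction of each sample's median so every
  sample's median is exactly 0. Zero intensities are treated as censored
  non-detections (missing), never measured zeros.
* Pipeline order is confidence filter → support filter → normalization →
  fit. The order of the two filters is configurable in principle; the
  default applies the confidence filter first so that support counts only
  confidently identified peptides.
* PTM sites map to protein coordinates by leftmost exact substring match,
  with an ambiguity flag when a peptide occurs more than once; ambiguous
  sites are excluded from occupancy reporting by default.

## Pathway and morphometry models

Pathway-level responses refit per-protein log2 fold changes with
$y_{gp} = \beta_g + \beta_p + \varepsilon$ (cell-means group coding,
sum-to-zero protein effects), by least squares: the response here carries
no observation-level identification scores, so the weighted Bayesian
machinery would add nothing — this is a deliberate narrowing. Pathways
need at least 3 quantified members; with a single contrast group the model
is saturated (zero residual degrees of freedom), so detection requires two
or more contrasts. Each $\beta_g$ is tested two-tailed and BH-adjusted
across pathways × groups.

Per-cell imaging measures follow
$y_{gd} = \beta_0 + X_g\beta_g + X_d\beta_d + \varepsilon$ on log2 scale,
so group effects read as log2 fold changes after donor adjustment.
Normalization to unstrained controls divides by the control-group mean
within donor before the log transform (the normalization granularity is a
package choice; per-donor is the conservative option given donor-to-donor
baseline differences). Power-law scaling of a measure against expression
is the slope of a per-cell log–log regression, reported with its standard
deviation; a per-condition-means mode is exposed because either reading of
scatter-plot regressions is defensible.

## The synthetic-data generators

`simulate_proteomics()` composes log2 intensities exactly as the model
assumes — protein baseline (log2 mean 20, sd 2), peptide ionization offset
(sd 1.5), treatment effect, donor effects at protein (sd 0.2) and peptide
(sd 0.1) level, PTM occupancy interaction, Gaussian residual — then
exponentiates, draws intensity-correlated identification scores
($15 + 5z + N(0,3)$, floored at 1, $z$ the standardized mean log2
intensity), and masks cells at the missingness rate (10%, completely at
random by default; a left-censoring mode exists because real LFQ
missingness is intensity-dependent). Defaults mirror the motivating study
design: 3 donors, control versus strained, 20% of proteins differential
with |log2 FC| uniform on [0.5, 1.5], peptide counts triangular (3, 5, 30).
The residual sd default of 0.2 log2 units (~15% CV) sits mid-range for
peptide-ion quantification; donor and ionization spreads are set so that
donor variability is visible at both levels the model separates.

What the generator does *not* emulate: retention-time alignment artifacts,
shared/razor peptide ambiguity beyond a uniqueness flag, correlated
missingness across samples, and heavy-tailed contamination. Passing the
validation suite therefore demonstrates correctness of the estimation
machinery under the model's own assumptions, not robustness to every
pathology of real LFQ data — the score-weighting mechanism addresses the
misidentification pathology specifically.

`simulate_null()` forces all effects to zero for false-discovery
calibration. `simulate_morphometry()` draws lognormal per-cell measures
with additive log-scale donor and group effects; its per-cell sd default
of 0.25 log2 (~18% CV) is typical of nuclear-area distributions.

## Validation protocol and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`) and the
reporting script (`scripts/acceptance.R`) run these experiments:

* least-squares agreement of the weak-prior sampler on 50 random balanced
  designs (2–6 peptides, 2 groups, 2–3 donors), judged in Monte-Carlo
  standard errors — since honest MC noise makes individual 3-MCSE
  exceedances expected at the ~0.3% rate, the family-level check is ≥99%
  of coefficients within 3 MCSE and no deviation beyond 5;
* recovery of treatment effects across 200 simulated proteins at default
  conditions (Spearman ≥ 0.9 and RMSE ≤ 0.2 log2 over the differential
  subset — over all proteins the 80% of exactly-zero truths tie and cap
  any estimator's rank correlation near 0.70);
* false-discovery calibration on 20 null simulations of 300 proteins
  (mean fraction at $q < 0.05$ must stay ≤ 0.075); these batch runs use
  shortened chains (1,000–1,500 iterations) since posterior-sd Monte Carlo
  error of a few percent is immaterial to the calibration being measured;
* occupancy recovery of a +1 log2 construction (residual sd 0.1, six
  peptides of which one modified — the low-noise construction isolates
  estimator correctness; at the default sd of 0.2 the same estimator is
  unbiased but the ±0.2 window would mostly measure sampling noise, since
  its standard error $\sigma\sqrt{(2/D)(1 + 1/(F-k))}$ is then ~0.18);
* exact equality of BH adjustment with a brute-force implementation on
  1,000 random vectors;
* Gaussian-fit recovery of a seeded $N(-0.11, 0.61)$ sample within ±0.03
  (center) and ±0.05 (width);
* pathway detection of a −0.4 log2 shift (10 members, member noise sd
  0.2) in a screen of 20 pathways of which 4 respond — strain experiments
  perturb many annotation sets at once, and the multiplicity environment
  is what BH correction acts on;
* morphometry oracle equality (1e-10) on 100 random instances and
  recovery of a 0.3 log2 group effect within ±0.05 at 200 cells/group;
* cluster-count selection on three well-separated synthetic expression
  programs;
* byte-identical reruns of the full pipeline under a fixed seed.

## Numerical notes and limitations

* CSV numerics are parsed with base R's `strtod` path, which round-trips
  doubles exactly; fast approximate float parsers can be one ulp off.
* If missingness empties design cells, aliased columns are dropped by QR
  pivoting and the affected expanded effects are reported as `NA`.
* The Gaussian histogram fit initializes at the sample mean/sd and the
  maximum bin count (Levenberg–Marquardt); "width" is the Gaussian
  $\sigma$, with FWHM also reported since figure captions rarely say
  which they mean. A fit whose residual RMSE exceeds 15% of the amplitude
  is flagged poor.
* K-means cluster counts are chosen by mean silhouette width (Euclidean)
  over the candidate range with multiple restarts; identical profiles
  degenerate to a single cluster with a flag.
* Median normalization leaves a small per-sample remainder (the sample
  median is itself an estimate), which appears as a shared
  group-by-donor-level nuisance of order $\sigma/\sqrt{n_\text{peptides}}$;
  it is negligible for table-scale experiments but visible in single-protein
  constructions, which is why those validation tests skip the
  normalization step.
* The weight function is a contract-faithful blend chosen so that
  high-confidence outliers keep weight ≈ 1; it is isolated behind
  `compute_observation_weights()` so an alternative can be swapped in.
* No protein inference from shared peptides, no absolute quantification,
  no imputation, and no modeling of raw spectra or chromatography.

## A worked mini-run

```{r mini-run}
sim <- simulate_proteomics(proteomics_sim_config(n_proteins = 12, seed = 42))
pep <- sim$peptides |>
  filter_by_confidence(0.2) |>
  filter_by_peptide_count(3) |>
  log_and_normalize(sim$design)
fits <- fit_proteins(pep, sim$design, reference = "control",
                     mcmc_config(iterations = 1000, burn_in = 300, seed = 1))
res <- test_differential(fits, moderate_variances(fits))
res |> arrange(q) |> head(5)
```

```{r volcano, fig.width = 5, fig.height = 3.5}
autoplot(res)
```
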