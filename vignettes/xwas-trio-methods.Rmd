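---
title: "Methods: sex-stratified X-chromosome methylation association in ART trios"
author: "xwastrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-stratified X-chromosome methylation association in ART trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xwastrio)
```

## The problem

Children conceived through assisted reproductive technologies (ART) go
through their earliest, epigenetically most volatile developmental window
under laboratory conditions.  Whether this perturbs DNA methylation (DNAm)
is usually asked genome-wide but almost always with the X chromosome
excluded, because X inactivation (XCI) makes X-linked CpGs statistically
awkward: boys carry one X, so their beta values (methylated fraction in
[0, 1]) are bimodal near 0 and 1; girls carry a silenced second copy, so
at many CpGs their measured value is the average of an active and an
inactive allelic state and the female distribution shows an intermediate
"bump"; a minority of probes escape XCI and are hypomethylated in both
sexes.  Any X-chromosome-wide association study (XWAS) must therefore
stratify by sex everywhere — including quality control — and correct the
resulting test statistics for bias and inflation before selecting hits.

`xwastrio` implements that analysis chain for mother–father–newborn trio
cohorts with an ART / natural-conception contrast, together with a
synthetic trio generator so that every stage is testable without
access-restricted cohort data.

## The models

For each CpG and each sex stratum separately, the child's M-value
($m = \log_2 \beta/(1-\beta)$, the analysis scale throughout) is
regressed on the exposure and confounders with a plate random intercept:

$$ m_{ij} = \alpha + \tau \,\mathrm{ART}_i + \gamma' x_i + u_{p(i)} +
\varepsilon_{ij}, \qquad u_p \sim N(0, \sigma_u^2),\;
\varepsilon \sim N(0, \sigma^2). $$

Four covariate sets are fitted:

* **M1** (main model): maternal age, maternal smoking (four levels,
  reference *Never*), maternal BMI, primiparity.
* **M2**: M1 plus the parental M-values at the same CpG — maternal only
  in the boys stratum, maternal *and* paternal in the girls stratum
  (a boy's X is maternal in origin).
* **M3**: M1 plus birthweight and gestational age.
* **M4**: the union of M2 and M3.

The trio design is what makes M2/M4 possible: if a child–parent DNAm
dependence explains an apparent ART association, conditioning on the
parental methylation removes it.

### Estimation

The single-random-intercept model is fitted by profiled restricted
maximum likelihood: for a given variance ratio
$\lambda = \sigma_u^2/\sigma^2$ the GLS quantities reduce to per-plate
sums, and $\lambda$ is profiled by one-dimensional minimization of the
REML criterion (`fit_cpg()`).  At $\hat\lambda = 0$ the estimates equal
ordinary least squares exactly, which is the boundary contract the tests
pin down; the unit tests also cross-check coefficient and standard error
against `lme4::lmer` on a seeded draw.  Inference uses the large-sample
standard normal reference on $z = \hat\tau/\mathrm{se}(\hat\tau)$,
matching the downstream rescaling of z-statistics.  Covariate
missingness is handled by complete-case exclusion (as is a missing
exposure), and indicator columns of factor levels unobserved within a
stratum are dropped rather than left to make the design singular.

## Quality control and normalization

Stage order is fixed and logged (`preprocess_pipeline()`), and no stage
pools information across sexes:

1. **Exclusion lists** — cross-reactive probes and probes whose last
   three bases overlap a SNP are removed.
2. **Detection p-value masking** — measurements with detection p > 0.01
   become missing; only probes failing in *every* sample are dropped
   outright, partial failure is left to the next stage.
3. **Greedy filtering** — iteratively remove the probe *or* sample with
   the highest unreliable fraction (ties: probe first, then lowest
   index) until the worst fraction is ≤ 5%.  This is a deterministic,
   testable reading of greedy QC trimming; the published description of
   the stopping rule in the framework that inspired it is not
   operational, so the threshold is exposed as a parameter.
4. **Gap hunting** — per sex and per probe, sorted beta values are split
   where consecutive gaps exceed 0.05; a probe is flagged multimodal
   when at least two groups each hold more than 1% of samples.  Flagging
   is the default action (dropping is available via `drop_flagged`),
   since inspection rather than removal is the defensible default when
   the downstream model is robust to mixture-valued CpGs.
5. **Probe-type normalization** — Infinium type II probes have a
   compressed beta distribution relative to type I.  `bmiq_normalize()`
   fits a three-state (unmethylated / hemimethylated / methylated)
   beta mixture by EM per sample and per probe type, keeps type I as the
   reference, quantile-maps type II U- and M-state values onto the
   matching type I components, and carries the middle state by the
   monotone dilation interpolating between the mapped boundaries.
6. **logit2 transform** to M-values (epsilon 1e-6 keeps the transform
   finite; that is below array quantization).

Numerical choices in the EM: states are initialized by distance to the
5%/50%/95% quantiles of the sample's betas — hard beta thresholds such
as 0.2/0.8 fail under strong type II compression, where the whole
distribution can sit inside (0.25, 0.75) — with weighted
method-of-moments updates, at most 100 iterations, and a relative
log-likelihood tolerance of 1e-6.  A degenerate fit (an empty state)
falls back to identity for that sample with a warning.  The
normalization is *distributionally* idempotent: a second application
leaves the type I / type II Kolmogorov–Smirnov distance unchanged (the
tests bound the drift by 0.02) and moves the median probe by well under
0.01.  It is not idempotent value-by-value to arbitrary precision: the
second pass re-estimates mixture components from the mapped type II
values, a different finite sample than type I, so quantile maps differ
by sampling noise of order $n^{-1/2}$, concentrated at state
boundaries.

## Calibrating the test statistics

Raw XWAS z-statistics are biased and inflated in practice.  The
empirical null is estimated by fitting

$$ \pi_0\, N(\mu_0, \sigma_0^2) + \pi_+\, N(\mu_+, \sigma_+^2) +
   \pi_-\, N(\mu_-, \sigma_-^2), \qquad \mu_- < \mu_0 < \mu_+ $$

with a Gibbs sampler (conjugate updates; 5000 iterations, 1000 burn-in,
fixed seed), and the statistics are rescaled affinely:
$z_\mathrm{adj} = (z - \hat\mu_0)/\hat\sigma_0$,
$p_\mathrm{adj} = 2\Phi(-|z_\mathrm{adj}|)$.  The rescaling preserves
ranks; selection applies Benjamini–Hochberg within each stratum and
model at FDR < 0.01.

Two design choices deserve a note.  First, the side components carry
*informative* priors — means pinned near ±4 standardized units with
prior variance 0.15, tight inverse-chi-squared priors on their
variances, and a Dirichlet weight prior expecting ~90% null mass.
A fully diffuse three-component mixture is not identified on pure-null
input: the side components drift into the central bulk, absorb genuine
tail mass, and bias $\hat\sigma_0$ downward by ~5%.  Pinning them away
from the bulk (the same device the Bayesian inflation-correction
literature uses) restores $\hat\sigma_0 \in [0.97, 1.03]$ on a standard
normal sample of 10,000 while still letting the side components absorb
a 10% contamination at $\pm 3$.  Second, sampling runs on median/MAD-
standardized statistics, which makes the pinned prior locations
scale-free; the median and scaled MAD also serve as a robust cross-check
estimator that is reported alongside and agrees with the Gibbs estimates
within 0.05 whenever the null fraction is high.  Estimation requires at
least 500 features (configurable) — below that an empirical null is not
meaningfully estimable.

## Regions and co-methylation

Differentially methylated regions (DMRs) are built from summary
statistics: candidates are maximal runs of consecutive CpGs with
corrected nominal $p < 0.05$, a shared effect sign, and inter-CpG gaps
≤ 500 bp (the published defaults of the inverse-variance DMR framework
this follows; all four knobs are parameters).  Each candidate is
combined with the correlation-adjusted inverse-variance statistic

$$ B = \frac{\sum_i w_i b_i}{\sum_i w_i}, \qquad
\mathrm{var}(B) = \frac{\sum_{ij} w_i w_j R_{ij} s_i s_j}
{(\sum_i w_i)^2}, \qquad w_i = s_i^{-2}, $$

with $R$ the empirical correlation of member M-values across the same
children used in the fits (pairwise-complete; pairs with fewer than 10
complete observations fall back to 0 with a warning).  With $R = I$
this is classical fixed-effect meta-analysis; with perfectly correlated
members the combined standard error equals the member standard error —
both limits are pinned by tests.  BH runs across candidates, and a
region is significant when it has ≥ 3 CpGs and $q < 0.01$.

Co-methylation reports (`comethylation()`) take a 50-kb total window
(±25 kb, closed at the boundaries) around a center CpG — "a 50-kb
region around a hit" is read as total width; the alternative ±50 kb
reading is available by doubling `window_bp` — and adjust the pairwise
correlation p-values of the upper triangle with Benjamini–Yekutieli,
which stays valid under the arbitrary dependence of overlapping windows.

Internal coordinates are 1-based inclusive throughout; only the BED
export converts to 0-based half-open, at a single tested point
(`write_dmr_bed()`).

## Bootstrap consistency

`bootstrap_consistency()` resamples **trios** with replacement,
separately within the ART and non-ART groups of one sex stratum, so
every replicate keeps the original group sizes and every resampled child
still has its parents (without which M2/M4 would be undefined on
replicates).  The *full* analysis is rerun per replicate — model fits,
empirical-null estimation, rescaling, BH — because the inflation
correction is part of the analysis being assessed; freezing the null
from the original data would understate the variability of selection.
Per-replicate seeds derive from the master seed via a seeded draw of
sub-seeds.  The summary is the per-CpG selection proportion with ranks
in descending order (ties broken by probe id).

## The synthetic generator

`generate_trio_dataset()` draws the structure the analysis assumes, all
effects on the M scale with betas derived by inverse-logit2 and clipped
to the open unit interval by 1e-6:

* per-sex probe baselines: male states near beta 0.06 / 0.94; females
  at discordant-allele probes get the beta-scale average of a near-0
  and a near-1 allelic state (the XCI bump; 35% of non-escape probes);
  12% escape probes are hypomethylated in both sexes — fractions chosen
  to match the reported ~12% of X-linked genes escaping XCI and to give
  the female density a clear third mode;
* co-methylation blocks of 5 probes with latent correlation 0.4;
  parent–child correlation 0.3 at 40% of probes (a child shares one
  factor with each parent, so mothers and fathers stay uncorrelated);
* plate intercepts (8 plates, SD 0.15 M-units), residual SD 0.5
  M-units, type II compression factor 0.8, detection failures at rate
  0.002 plus optional "bad" samples/probes for the greedy filter;
* covariates anchored to a typical ART cohort profile: maternal age
  ~N(33, 4) for ART vs ~N(30.5, 4) for non-ART, BMI ~N(23.5, 3.2) in
  both, primiparity 70% vs 47%, smoking distributions with more past
  smokers but fewer pregnancy smokers among ART mothers, birthweight
  ~N(3540, 480) vs ~N(3650, 480), gestational age ~N(39.8, 1.4);
* planted ART effects at chosen probes/spans, per sex, recorded in a
  truth table; planting never consumes randomness, so a configuration
  with and without effects differs only by the planted shifts.

What it does *not* emulate: realistic EPIC probe annotation, imprinting,
cell-composition heterogeneity, chromosome Y, genome-build issues, or
array background/dye biases (the pipeline starts from betas, not
intensities).  Passing tests on this generator therefore demonstrate
correctness of the statistical machinery under the stated structure,
not robustness to every artefact of real arrays.

## Problem sizes used in the checks

The packaged checks run at reduced scale, chosen as the smallest sizes
at which the distributional claims are still sharp: null calibration
uses 2000 CpGs with 200 ART + 200 non-ART trios (one stratum fully
re-analyzed per seed across 50 seeds for the false-discovery rate
check); estimator recovery uses 200 replicates at ~150 children per
exposure group; DMR recovery plants five 4-CpG regions of 0.5 M-units;
the bootstrap stability run uses 100 replicates over 550 CpGs with
planted effects of 0.4/0.8/1.2 M-units at ~120 children per group.
Recovery-oriented checks generate data with the type II compression
disabled and analyze raw logit2 betas, because they quantify the
estimator, not the normalization (which has its own distributional
checks); the pipeline-level checks keep all distortions on.

## Known limitations

* The REML fit profiles a single grouping factor; crossed or nested
  batch structures are out of scope.
* The empirical-null mixture assumes the true-association components
  are well separated from the bulk; a dense field of tiny effects will
  be absorbed into (and widen) the estimated null — which is the
  conservative direction.
* BMIQ-style normalization requires both probe types present in
  sufficient numbers per sample (default ≥ 50) and falls back to
  identity per sample otherwise.
* p-values for correlations in `comethylation()` use the t reference,
  which is approximate under the mixture-shaped marginals of beta
  values; using M-values is recommended.
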