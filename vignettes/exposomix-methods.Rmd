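---
title: "Methods: the exposomix association pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the exposomix association pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

exposomix implements an exposome-omics-wide association study (ExWAS)
for multi-cohort child studies: every exposure of two exposure windows
(pregnancy and childhood) is regressed against every molecular feature
of up to six omics layers, followed by layered multiple-testing
correction, sensitivity analyses, bipartite network integration and
cross-layer comparison. This vignette documents the statistical model,
the tunable parameters, the synthetic-data generator used throughout
the tests, and the numerical and design choices that were genuinely
open.

## The association model

For a continuous exposure $x$ and feature $y$ the engine fits ordinary
least squares

$$ y = \beta \, \frac{x}{\mathrm{IQR}(x)} + \gamma' c + \delta' s + \varepsilon $$

so that $\beta$ is the effect per interquartile-range increase of the
exposure: a log2 fold change when the layer is log2-scaled, a
difference in methylation level when the outcome is a methylation
beta. Categorical exposures enter reference-coded (first declared
level is the reference) and produce one association record per
non-reference level. $c$ collects the adjustment covariates — cohort,
sex, age, zBMI, ancestry, maternal education, plus layer-specific
technical covariates — and $s$ the surrogate variables of genome-wide
layers. Two-sided t-tests give the p-values.

Two deliberate modelling choices:

* **Classical OLS, not variance moderation.** Empirical-Bayes
  moderation of feature variances matters at small $n$; at the
  cohort sizes this design targets (hundreds to ~1300 children) the
  shrinkage is negligible, and classical OLS is fully specifiable and
  testable against a normal-equations oracle (the test-suite checks
  agreement to 1e-8 relative tolerance on random designs). A moderated
  variant could be added behind the same record schema.
* **Per-contrast t-tests for categorical exposures, not omnibus
  F-tests.** An association "exists" when any contrast passes the
  layer's correction. Both conventions are defensible; per-contrast
  keeps the record schema uniform (one effect, one SE, one p per row)
  and is the package default.

### Surrogate variables

Genome-wide layers (methylation, expression, miRNA) carry unmeasured
structure — assay batches and blood cell composition foremost. The
package residualizes the feature matrix on the known covariates and
takes leading left singular vectors of the residual matrix as
surrogate variables. With `n_svs = "auto"` the count is chosen by
permutation parallel analysis: each residual column is permuted
independently 20 times and components are retained while their
singular value exceeds the 95th percentile of the matching permuted
singular values.

One numerical subtlety: the observed residuals live in the rank
$n - p$ subspace orthogonal to the covariate design, while naively
permuted matrices are full-rank, which biases the permutation null
*low* and retains spurious components. The implementation therefore
re-residualizes every permuted matrix on the same design and rescales
it to the observed residual sum of squares. On simulated layers with
two dense latent factors the rule recovers exactly 2 in 20/20 seeded
replicates, and on pure-noise layers it returns 0 in ≥90% of
replicates (both are asserted in the test-suite).

### Layered multiple-testing correction

Correction is applied independently within each (exposure, layer)
stratum, mirroring how exposome studies control error per hypothesis
family:

* genome-wide layers: Benjamini–Hochberg FDR at $\alpha = 0.05$;
* targeted panels (proteins, serum/urine metabolites): Bonferroni at
  $\alpha / \mathrm{ENT}$, where the effective number of tests is the
  eigenvalue floor/fraction estimator on the feature correlation
  matrix, $\mathrm{ENT} = \sum_i [\,\mathbb{1}(\lambda_i \ge 1) +
  (\lambda_i - \lfloor \lambda_i \rfloor)\,]$. Closed forms pin the
  implementation down: independent features give ENT $= M$, $M$
  duplicated features give 1, and four features at exact
  equicorrelation $\rho = 0.5$ give eigenvalues $(2.5, .5, .5, .5)$
  and ENT $= 3.0$ exactly;
* a global flag marks records with $p < 10^{-9}$, the
  everything-at-once Bonferroni-style cutoff such studies quote.

ENT is computed once per layer on the analysis samples, not per
exposure stratum: the thresholds are per-layer constants. A
feature-subset option covers designs where a platform is filtered
before correction.

## Sensitivity machinery

**Percent effect change** between model variants is
$(\beta_{main} - \beta_{alt}) / \beta_{main} \times 100$, flagged when
its magnitude exceeds 100 ("more than a doubling"). A zero main-model
effect yields a missing value with a warning rather than an infinity.

**Per-cohort meta-analysis** refits the models cohort by cohort
(dropping the cohort covariate) and pools by inverse variance: fixed
effects with weights $1/se^2$; DerSimonian–Laird
$\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w))$;
random-effects weights $1/(se^2 + \tau^2)$;
$I^2 = \max(0, (Q - (k-1))/Q) \times 100$. Two conventions that study
write-ups rarely spell out, fixed here as package choices:

* continuous exposures are scaled by the **whole-study IQR** in
  per-cohort refits, not the within-cohort IQR — otherwise per-IQR
  effects sit on different scales per cohort and $I^2$ picks up IQR
  sampling noise as spurious heterogeneity;
* surrogate variables are re-estimated within a cohort only when it
  has at least 100 samples; smaller cohorts reuse the global surrogate
  variables restricted to their rows (a within-cohort SVD on a few
  dozen samples is mostly noise).

With a single cohort the pooled values equal the cohort estimate and
$I^2$ is undefined (`NA`), not 0.

**Multi-exposure models.** For a feature significantly associated with
more than one exposure, the mutually adjusted model includes one
representative per correlation group — the group is the exposure
family, except diet, metals and parabens members, which each form
their own group — and drops the weaker member of any remaining pair
with correlation magnitude ≥ 0.8. Mixed-type correlations are put on a
common $[0,1]$ magnitude scale by using $\sqrt{R^2}$ for
continuous-categorical pairs and Cramér's V for categorical pairs; the
0.8 cutoff is applied on that magnitude scale (a config switch applies
it to $R^2$ instead for designs that prefer the squared scale).
Tie-breaks are by smallest single-exposure p-value, then
lexicographic, so selection is deterministic. Singular joint designs
are refitted after dropping the collinear exposure, and every
exclusion is logged.

## Networks

Significant associations of one period form a bipartite graph:
exposures and features are nodes, signed edges are associations
(multiple categorical contrasts collapse to one edge carrying the sign
of the smallest-p contrast). Statistics follow the standard graph
conventions: degree is incident-edge count; the average shortest path
is the mean breadth-first-search distance in **edges** over unordered
reachable pairs, with pairs in different components excluded (a
`count = "nodes"` switch reports node-counted lengths, i.e. one more).
Topology statistics default to the full period network; the display
convention of keeping only components with at least two molecular
features is available as a flag and marks nodes rather than deleting
them.

Communities come from greedy modularity maximization on the largest
connected component (smaller components keep their component as their
cluster). When no split achieves positive modularity the component
stays one community — the agglomerative merge otherwise stops at an
arbitrary zero-modularity tie, e.g. on stars. Cluster identifiers are
relabelled by decreasing edge count with lexicographic tie-breaks, so
the labelling is a pure function of the input table. Exact membership
parity with layout-aware clusterers used in interactive tools is not a
goal; cluster summaries (exposures ordered by association count,
per-layer feature counts, unique annotated genes across CpGs,
transcript clusters, miRNAs and proteins) are structural.

## Cross-layer integration

* **cis-eQTM**: a CpG is paired with a transcript cluster when both
  sit on the same chromosome and the CpG lies strictly closer than
  500 kb to the transcription start site ("closer than" is read as a
  strict inequality; a distance of exactly 500 kb is excluded). TSSs
  are strand-aware when intervals are supplied (start for +, end for
  −). Each pair is fitted by OLS of expression on methylation adjusted
  for age, sex and cohort, with BH-FDR across all pairs — the
  significance rule is the package's own documented choice, exposed in
  the configuration.
* **miRNA-target concordance**: a triple (exposure, miRNA, target
  gene) is retained when the target transcript is nominally associated
  (p < 0.05) with the same exposure with the opposite effect sign
  (higher miRNA, lower target expression). The validated target map is
  an input, never computed.
* **cross-matrix replication**: a significant exposure-metabolite
  association in one biofluid replicates when the mapped metabolite's
  record in the other fluid is nominally significant *and* carries the
  same sign. Sign agreement is the package's stricter default (a
  switch reduces the rule to nominal significance only). The two
  directions use different denominators and are reported separately.

## The synthetic cohort generator

`sim_scenario()` / `simulate_study()` generate cohorts with exactly
the structure the analysis assumes, so every downstream stage has a
ground truth:

* covariates per child (cohort, sex, age 6–11, standard-normal zBMI,
  ancestry with a dominant European group, maternal education);
* exposure families drawn from block-equicorrelated Gaussians
  (off-block correlation 0), with the same variable's pregnancy and
  childhood copies correlated at `cross_period_correlation`
  (default 0.2 — repeated exposures correlate only weakly across
  periods); categorical exposures arise by tertile-thresholding latent
  Gaussians;
* feature values built as intercept + planted per-IQR effects +
  covariate signal on a random 20% of features + latent-factor
  contributions + Gaussian noise (default SD 0.5). Methylation is
  simulated on the logit scale and squashed by the inverse logit, so
  the $[0,1]$ range is guaranteed; the recorded truth carries the
  logit-scale coefficient, and effect-recovery tests plant on features
  with baseline 0.5 where the link is locally linear;
* dense latent factors stand in for batch and cell composition
  jointly, loading a random 30% of features of each genome-wide layer;
* optional cohort-specific multipliers on planted betas exercise
  meta-analytic heterogeneity, and the adiposity scenario wires
  zBMI → pollutant and zBMI → protein paths with a zero direct
  pollutant-protein effect, so removing the zBMI adjustment creates a
  spurious association by construction.

`helix_mini_scenario()` is the benchmark configuration used by the
test-suite and the acceptance script: 300 children, 2 cohorts, 40
exposures in 4 families across the two periods, and 5 layers with
500/100/50/30/50 features. The heavier calibration and power runs use
1000 children, a 500-feature genome-wide layer, 25 seeds, and 50
replicates for effect recovery — sizes chosen so the Monte-Carlo error
of each check is comfortably below the asserted margins.

What the generator does **not** emulate: real exposure distributions
(log-normality, detection limits, censoring), assay-specific noise
(probe effects, batch-by-plate layouts), missingness (imputation is
declared upstream and out of scope — tables with missing values are
rejected at load time), and genuine biological correlation structure
between layers. Passing tests therefore demonstrate statistical
correctness of the machinery under its stated assumptions, not
robustness to everything real cohort data can do.

## Numerical conventions and degenerate inputs

* IQR uses linear interpolation between order statistics (R quantile
  type 7) — reproducible across mainstream numeric stacks. A zero IQR
  is returned for constant vectors, and per-IQR scaling rejects such
  degenerate exposures with an error.
* p-values are floored at the smallest positive double rather than
  reported as 0 (relevant for signed log-p plot tables).
* Designs need at least 10 samples beyond their column count; the
  guard is adjustable (`min_extra_samples`) so closed-form toy designs
  remain checkable.
* Collinear designs abort naming the offending columns; constant
  covariates (e.g. ancestry after restricting to one ancestry group)
  are dropped from the design rather than crashing the factor
  expansion.
* Zero-variance features are excluded from ENT (with a warning) and
  dropped from eQTM fitting (logged).
* Text round-trips write doubles with 17 significant digits and parse
  them with base R's exact reader, so write/read cycles are
  bit-identical; fixture manifests carry content hashes and the
  scenario hash.
* All internal randomness (surrogate-variable permutations, plot
  jitter, layouts) runs under a preserved-and-restored RNG state, so
  library calls never perturb user simulations; generator output is a
  pure function of the scenario seed.

## Known limitations

* No variance moderation, robust/sandwich errors or mixed models; no
  omnibus tests for categorical exposures.
* The ENT estimator is the eigenvalue floor/fraction form; other
  effective-number estimators (e.g. ratio-based) would shift targeted
  thresholds slightly.
* Greedy modularity is a heuristic; it is deterministic here but not
  guaranteed to find the globally optimal partition.
* $I^2$ from few cohorts is noisy and upward-biased; the forest-plot
  tables exist precisely so pooled numbers are inspected alongside
  per-cohort intervals.
* Cross-matrix replication conditions on the supplied metabolite map;
  no unit harmonization between fluids is attempted beyond it.
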