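---
title: "Candidate-gene discovery from canonical correlations and extreme-score contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene discovery from canonical correlations and extreme-score contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem this package addresses

Ecological transcriptomics experiments often measure a *set* of phenotypic
traits (body mass, structural size, growth rate, development time) on
individuals reared under a *set* of crossed environmental factors (latitude
of origin, temperature, predation risk), together with RNA-seq on a subset
of individuals.  Natural selection does not act on traits one at a time, so
instead of trait-by-trait models this package links the two variable sets
multivariately and then uses the multivariate axes themselves to define
expression contrasts:

1. **Canonical correlation analysis (CCA)** finds paired linear
   combinations — a phenotype variate (CCp) and an environment variate
   (CCe) — maximizing their correlation; successive pairs maximize what is
   left.
2. For each statistically significant canonical axis, the individuals with
   the most extreme canonical scores (default: ten highest vs ten lowest,
   separately for CCp and CCe) define **two paired two-group
   differential-expression contrasts**.
3. Genes significant at FDR < 0.05 in *both* contrasts *in the same
   direction* are the axis's **candidate genes**: expression differences
   that track the phenotype–environment association rather than either
   margin alone.
4. Candidates are interpreted through GO annotation obtained by a
   conservative cross-species transfer rule, hypergeometric enrichment and
   a depth-level functional categorization.

`run_pipeline()` orchestrates the stages; every stage is also exported on
its own.

## The canonical model

Both variable sets are standardized; with $\Sigma_{xx}, \Sigma_{yy},
\Sigma_{xy}$ the within- and cross-covariances, the singular value
decomposition of $\Sigma_{xx}^{-1/2}\Sigma_{xy}\Sigma_{yy}^{-1/2}$ yields
the canonical correlations $\rho_1 \ge \dots \ge \rho_m$ ($m$ = size of the
smaller set) and the canonical weights.  Environmental factors enter as
fixed binary codes (latitude high = 0 / central = 1, temperature 20 = 0 /
24 = 1, predator cue absent = 0 / present = 1); the correlations are
invariant to this coding, but loading *signs* are not, which is why the
coding is fixed and recorded.  Because CCA signs are mathematically
arbitrary, each axis is oriented so the largest-magnitude environment
weight is positive; reported signs elsewhere may differ from a given run by
whole-axis flips, and tests compare magnitudes or flip-normalize.

Canonical **loadings** are correlations of each variable with its own
set's scores, **cross-loadings** with the other set's scores; the identity
cross-loading = loading × $\rho_k$ holds exactly and is used as an internal
consistency check.  With more than 200 individuals a loading is
conventionally read as meaningful when $|loading| > 0.30$ (strict
inequality).

Significance uses the Wilks' lambda ladder: for each starting axis $k$,
$\Lambda_k = \prod_{i \ge k}(1-\rho_i^2)$ with Rao's F approximation.  With
$p' = p-k+1$, $q' = q-k+1$:

$$s = \sqrt{\frac{p'^2q'^2-4}{p'^2+q'^2-5}},\quad
t = (N-1)-\frac{p+q+1}{2},\quad
df_1 = p'q',\quad df_2 = st-\frac{p'q'}{2}+1,$$

$$F = \frac{1-\Lambda_k^{1/s}}{\Lambda_k^{1/s}}\cdot\frac{df_2}{df_1},$$

with $s = 1$ when the denominator vanishes or $p'q' \le 3$.  Note that $t$
is computed from the *original* set sizes at every rung while $p', q'$
enter only $s$ and $df_1$; this matches the behaviour of the standard
asymptotic-test implementations for canonical correlations and reproduces
their printed denominator degrees of freedom exactly.  `df2` is kept
unrounded internally and rounded only for display.

```{r}
library(ccadeg)
wilks_ladder(c(0.87, 0.52, 0.27), N = 272, p = 5, q = 3)
```

## Trait preparation

Growth rates are derived as mass/development time (GRM, mg/day) and head
width/development time (GRH, mm/day).  Head width and wing pad length are
log-transformed; GRM and GRH are arcsine-transformed.  Two deliberate
readings of convention are worth stating:

* the arcsine transform is applied as plain `asin(x)` on a [0, 1] domain
  (not the `asin(sqrt(x))` variance stabilizer) — callers with growth
  rates outside [0, 1] get an explicit error advising rescaling;
* mass and development time enter the canonical model untransformed.

Before fitting, a **collinearity screen** computes all pairwise Spearman
rank correlations and, while any pair exceeds the threshold (default
|r| > 0.9, strict; `>=` only at a threshold of exactly 1 so duplicates
remain removable), removes the member of a violating pair with the largest
mean absolute correlation against all remaining traits, ties broken
alphabetically.  Restricting the victim to members of violating pairs is
what makes the screen behave as a collinearity filter rather than a
generic variance-inflation pruner: in the damselfly-style trait set it is
GRH — nearly a deterministic function of development time because head
width varies little — that is removed, leaving five traits.

## Expression stages

**Extreme-score contrasts.** For axis $k$ the `n_tail` highest- and
lowest-scoring individuals (per variate) form the two groups.  Ties at a
tail boundary are resolved by ascending individual id, so selection is
deterministic.  An individual may appear in both a CCp and a CCe tail;
no exclusion is applied.

**Differential expression** is a from-scratch implementation of the
classic exact-test route for two-group NB counts:

* genes with CPM ≤ 1 in more samples than the smaller group size are
  removed (configurable);
* TMM normalization: reference sample by upper-quartile CPM closest to the
  mean, M/A values over genes nonzero in both samples, 30%/5% two-sided
  trims on M/A, precision-weighted mean of surviving M values, factors
  rescaled to geometric mean 1;
* counts are rescaled to the geometric-mean effective library
  ("equalized"); the *rounded* equalized counts feed the integer
  conditional test while means, logFC and logCPM use the unrounded values
  (the rounding is purely a device for the exact test);
* dispersions by conditional maximum likelihood: the common dispersion
  maximizes the summed per-gene conditional log-likelihood of each group's
  counts given its sum; tagwise values maximize the per-gene likelihood
  plus `prior_df` (default 10) times the average likelihood curve
  (weighted-likelihood shrinkage; as `prior_df` grows all tagwise values
  collapse onto the common one).  Optimization is golden-section search on
  log dispersion over [1e-4, 10], and the shared likelihood curve is
  tabulated on a 120-point grid and splined so the per-gene search stays
  linear in the number of genes;
* the exact test conditions on the per-gene total of the group sums: for
  equal per-sample means the conditional pmf is free of the mean, so it is
  enumerated in full; the two-sided p-value sums all outcomes no more
  likely than the observed split (standard for conditional exact tests);
* Benjamini–Hochberg adjustment over all tested genes; log2 fold changes
  (high vs low group) use a proportional prior of 0.125 counts per million
  to avoid logs of zero.

This is deliberately the simple exact-test route, not a quasi-likelihood
GLM: the contrasts are plain two-group comparisons and the simulation-based
checks below, not bit-compatibility with any particular tool, define
correctness.

**Directional overlap.** A gene is an `up` candidate when significant with
positive logFC in both the CCp and the CCe analysis, `down` symmetrically;
genes significant with opposite signs are excluded but reported.  Only
axes whose ladder p-value is below `gate_p` (default 0.05) reach this
stage.

## The synthetic-data generator

The generator emulates a full-factorial rearing experiment: 2 latitudes ×
2 ponds per latitude × 10 maternal lines per pond × 2 temperatures × 2
predator-cue levels, one phenotyped larva per family × treatment container
plus a second with probability 0.7 — in expectation 272 individuals,
matching the scale of the damselfly experiment the design emulates.

Two phenotype modes exist:

* `simulate_phenotypes()`: a full effects model per trait (main effects,
  all interactions, Gaussian pond and maternal-line random effects;
  Gaussian traits on their natural scale, development time Poisson with a
  log link).  Default magnitudes are chosen as realistic for a temperate
  damselfly larva at its prefinal instar (≈5 mg mass, ≈1 mm head width,
  ≈60 days development shortened by warming).  `null_trait_effects()`
  zeroes every effect and grouping variance for null runs.
* `simulate_planted_phenotypes()`: the parameter-recovery mode.  Latent
  axes $s_k = \rho_k u_k + \sqrt{1-\rho_k^2}\,\epsilon_k$ are built from
  the standardized (and, in the balanced design, mutually orthogonal)
  temperature, latitude and predator codes; each of development time, mass
  and log head width is a monotone function of exactly one axis, so the
  population canonical correlations of the processed trait matrix equal
  the planted $\rho = (0.85, 0.5, 0.25)$ by construction.  Pond and family
  effects are zero in this mode — they would dilute the plant and make the
  "true" value ambiguous.  The trait maps also make GRH ≈ head/dev
  essentially proportional to 1/dev, so the collinearity screen removes it,
  reproducing the five-trait situation.

Counts follow $y_{gi} \sim \mathrm{NB}(L_i\,\pi_g\,e^{\gamma_g z_i},
\phi_g)$ with log-normal library sizes, log-normal relative abundances,
log-normal dispersions (median 0.1, a typical bulk RNA-seq value) and
planted per-axis gene sets (default 50 up + 50 down per axis,
$|\gamma| = 1.5$ per unit latent score).  The latent score $z_i$ is the
same $s_k$ that drives the traits — that shared dependence is what makes
the CCp- and CCe-based DEG lists overlap, which is the property the
directional-overlap rule needs to be testable at all.

What the generator does *not* emulate: sequencing noise at the read level,
GC or length biases, batch effects, sex differences (all genes are
labelled autosomal), and correlated gene-gene expression modules.  Passing
tests therefore demonstrate correctness of the *statistical machinery*
under its own assumptions, not robustness to every artefact of real
RNA-seq data.

## Annotation and enrichment

The transfer rule mirrors a conservative manual curation: a target gene
receives a GO set only when at least three *distinct* reference species
carry a gene with the same normalized name (lowercased, punctuation and a
trailing "-like" stripped) and *exactly* the same GO set; sets are counted
separately, so one divergent species cannot spoil an otherwise qualifying
trio.  "Similar function and name" is operationalized as exact normalized
name equality because any fuzzier similarity would not be reproducible;
the function description is kept only as a sanity-check column.

Annotations are closed over `is_a` ancestry before testing (true-path
rule); only `is_a` edges are used from the OBO — `part_of` and other
relations are deliberately ignored as the conservative default.
Enrichment is the hypergeometric upper tail per term, BH-adjusted within
namespace, with the background defined as the *annotated* genes of the
namespace (unannotated genes are untestable; the choice is configurable).
Terms annotated to fewer than 3 background genes are not tested.  The
functional categorization counts genes under every ancestor at a fixed
depth (default 2) below the namespace root, with multi-membership across
the DAG.

## Numerical and design choices

* Rank-deficiency in either variable set is detected on the eigenvalues of
  the standardized covariance (relative tolerance $\sqrt{\epsilon}$) and
  reported with the name of the dependent column.
* Canonical scores are rescaled to unit sample variance so that
  corr(CCp$_k$, CCe$_k$) = $\rho_k$ exactly.
* The ladder refuses $\rho \ge 1$ ($\Lambda = 0$ is degenerate); a fit with
  a perfect correlation simply carries no ladder.
* TMM trim ranks use average ranks, making factors invariant to gene
  order.
* All randomness flows from one root seed through named per-stage
  substreams (`stage_seed()`), so a rerun with the same configuration is
  byte-identical; the run report records the package version and every
  effective parameter but no wall-clock time, keeping reports comparable
  across reruns.
* Problem sizes used by the package's own checks: 2000 genes, library
  sizes log-normal around $10^4$ (the generator's default is $10^6$; the
  smaller profile keeps simulation-heavy checks at desk scale), 50 seeds
  for canonical-correlation recovery, 20 seeds for the null pipeline, 10
  for planted-gene recovery.

## Worked example

```{r, eval = FALSE}
library(ccadeg)

truth <- expression_truth(planted_per_axis = 50, gamma = 1.5,
                          lib_meanlog = log(1e4), seed = 42)
cfg <- run_config(planted_rho = c(0.85, 0.5, 0.25), truth = truth,
                  seed = 11, max_axes = 1)
report <- run_pipeline(cfg)
report
#> pipeline run
#>   individuals: 276, genes: 2000
#>   canonical correlations: 0.83, 0.46, 0.23
#>   axis1: 46 up, 49 down candidates
```

Of the 100 genes planted on axis 1 in that run, 95 are recovered in the
axis-1 candidate set.

## Known limitations

* The exact test assumes equalized libraries; extreme normalization
  factors (beyond what TMM corrects) degrade its calibration.
* The transfer rule's exact-set matching is strict: reference databases
  with inconsistent GO granularity across species will under-annotate.
* Enrichment treats genes as exchangeable; gene length or expression-level
  bias corrections are out of scope.
* The Wilks ladder is asymptotic; at small $N$ its p-values are only
  approximate (the test suite checks agreement with a permutation null at
  $N = 40$ to within 0.05).
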