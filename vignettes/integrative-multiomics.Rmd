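---
title: "Integrative transcriptome–metabolome module analysis with intermod"
author: "intermod authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative transcriptome-metabolome module analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intermod)
```

# The analysis problem

`intermod` implements an integrative systems-biology workflow for crossed
factorial experiments in which both transcripts and metabolites are profiled
over the same samples — the motivating setting is a crop leaf study with
three genetic backgrounds (varieties), three growing locations and six
developmental stages, with 2–3 biological replicates per cell. The goal is
to move from two abundance matrices to a ranked list of candidate regulator
genes supported by several independent lines of statistical evidence:

1. **Variance filtering.** The coefficient of variation (CV) of each
   transcript across all samples is decomposed into a low- and a
   high-variability Gaussian component with an EM-fitted two-component
   mixture; only the high-variability component is carried forward.
2. **Differential analysis.** Each feature is fitted with the full factorial
   ANOVA $y_{ijkl} = \mu + C_i + l_j + S_k + Cl_{ij} + CS_{ik} + lS_{jk} +
   ClS_{ijk} + \varepsilon_{ijkl}$ on log2 abundances. Per factor, p-values
   are Benjamini–Hochberg adjusted across features (adjusted p < 0.01) and a
   magnitude filter keeps features whose largest level-mean gap reaches two
   standard deviations of the all-feature fold-change distribution.
3. **Co-expression modules.** A weighted, unsigned adjacency
   $a_{ij} = |r_{ij}|^\beta$ (default $\beta = 7$, with a scale-free-fit
   diagnostic over a power ladder), the topological overlap matrix (TOM),
   average-linkage clustering of $1 - \mathrm{TOM}$, a static tree cut,
   module eigengenes (first principal component of standardized member
   profiles, unit variance, sign-oriented), and kME statistics with t-test
   p-values. The same machinery runs on both omics layers.
4. **Regulator networks.** Within each gene module, mutual information
   between a curated regulator list and all module members, thresholded at
   a null-calibrated cutoff (working tail probability $10^{-8}$), then
   pruned by ARACNe's data-processing-inequality triangle rule.
5. **Integration.** Two-way Pearson correlations: every metabolite against
   every gene-module eigengene and every gene against every
   metabolite-module eigengene, flagged at raw p < 0.01, then tabulated
   into reciprocally supported module–module links.
6. **Prioritization.** Fisher's combined probability test over five
   channels per gene — own-module kME p, the three factorial main-effect
   p-values, and the best metabolite-module correlation p:
   $X^2 = -2\sum_i \ln p_i \sim \chi^2_{2k}$, scored as
   $-\log_{10}(p_{\text{combined}})$.
7. **Enrichment.** One-sided hypergeometric over-representation of GMT
   pathway sets with BH FDR < 5%.

```{r example, eval = FALSE}
cfg <- pipelineConfig(seed = 1)
runPipeline(cfg, "results/run1")
```

# The synthetic-data generator

The study's microarray and metabolome matrices are not part of the package,
so every stage is exercised on synthetic data with planted, recoverable
ground truth. The generator's defaults are the study conditions: a
3 × 3 × 6 design with 2 replicates (108 samples), 2,000 transcripts, 500
metabolites, log2-scale abundances.

* **Modules.** Each planted gene module is driven by a latent eigengene
  profile: additive level offsets spanning $\pm$ `effectSize` (1 log2 unit
  by default) for the factors in the module's response pattern, plus unit
  Gaussian noise. Member genes load on the latent with loadings calibrated
  so the expected pairwise member correlation equals `withinModuleCor`
  (0.8); a mild ±10% loading spread makes hub structure non-degenerate.
  Module 1 responds to all three factors and carries one planted
  variety × stage interaction.
* **CV mixture.** Background genes are pure noise; 40% of them get
  five-fold smaller noise, creating the low-variability component the EM
  filter is meant to remove. Planted module members are intentionally left
  in the high-variability regime — the filter's job downstream is to keep
  them.
* **Metabolite coupling.** Metabolite module *j*'s latent profile is the
  (unstandardized) gene-module-*j* latent times an alternating sign, plus
  Gaussian noise sized so the latent-eigengene correlation equals
  `couplingR` (0.8). Coupling to the unstandardized latent preserves the
  factor-effect amplitude on the metabolite side.
* **Regulator.** The first member of module 1 gets a 1.5× loading (a hub);
  five target genes are generated as `2·noiseSd · sigmoid(3·z(regulator))`
  plus noise, a saturating monotone dependence that mutual information
  detects while linear correlation understates.

What the generator deliberately does **not** emulate: probe-level artefacts,
batch or array effects, missingness, heteroscedastic MS noise, non-Gaussian
abundance tails, and correlated background structure. Passing tests
therefore demonstrate correctness of the algorithms under the stated model,
not robustness to everything real data can do.

# Numerical and design choices

* **CV scale.** CV is computed on linear-scale abundances ($2^x$); the CV
  of log2 values is ill-defined near zero mean. `cvScale = "log"` is
  available.
* **EM initialization.** Median split plus five random quantile-split
  restarts, best log-likelihood kept; a component SD collapsing below
  $10^{-6}$ of the data SD voids that start. The log-likelihood is
  asserted non-decreasing at every iteration.
* **ANOVA sums of squares.** Sum-to-zero contrasts; each term's SS is the
  residual-SS increase when the term's columns are dropped from the full
  model (marginal, Type III). Balanced designs reproduce the classical
  orthogonal decomposition exactly, which is what the test oracle checks to
  1e-8. Zero residual variance yields p = 0 where effect SS > 0 and NaN
  (with a warning) where everything is zero.
* **Fold-change filter.** "Two SDs of fold change" is implemented per
  factor: threshold = `sdMult` × SD of that factor's all-feature
  fold-change distribution. The filter only removes calls made by the
  adjusted-p rule. BH is applied per factor across features, not pooled.
* **Tree cut.** The full dynamic-hybrid cut is out of scope; the static
  default cuts at the midpoint of the largest gap in sorted merge heights.
  With tight modules over a diffuse background, module formation and the
  late background/module joins occupy separate height regimes and the
  widest gap separates them; a quantile-height cut (retained as
  `cutMethod = "quantile"`) lands among the late noise merges whenever
  unassigned features dominate and dissolves the modules. When no dominant
  gap exists (≥ 25% of the height range), a coherent tree (all merges below
  0.95 dissimilarity) is one module; an incoherent one dissolves into grey.
  Modules are named by size along the conventional colour order, grey
  meaning unassigned; an optional eigengene-correlation merge step exists
  but is off by default.
* **Mutual information.** Plug-in estimator on rank-based equal-frequency
  bins — deterministic and testable against the closed form
  $\mathrm{MI}(x,x) = \ln B$ — rather than adaptive partitioning. The
  default bin count is the cube-root rule $B = \max(2,
  \lfloor n^{1/3} \rfloor)$: the null bias of the plug-in estimate is
  $\approx (B-1)^2/(2n)$, which vanishes with $n$ under this rule
  (≈ 0.04 nats at $n = 1000$) — a square-root rule such as
  $\sqrt{n/5}$ would pin the bias near 0.1 nats at every sample size.
* **MI threshold.** A working tail probability of $10^{-8}$ is far beyond
  raw permutation counting, so the threshold is extrapolated from a
  generalized Pareto fit to the exceedances over the null 95th percentile
  (100,000 permutation pairings by default). The binned-MI null is
  chi-square-like, with mean excess decreasing in the threshold; a
  constant-rate exponential tail overshoots deep quantiles, while the GPD
  (of which the exponential is the shape-0 case) tracks the curvature —
  calibration is verified empirically at the reachable level $10^{-3}$.
  Bulk targets (p ≥ 0.05) use the empirical null quantile directly.
* **DPI.** All triangles are evaluated on the original edge set; the
  strictly weakest edge of a triangle is marked removed when below
  $(1-\text{tolerance})$ times the smaller of the other two. Strict
  inequality keeps ties intact and makes re-application idempotent.
  Edges are undirected; "regulator → target" is a labelling.
* **Integration.** The t-test for a Pearson correlation (df = n − 2) backs
  the p < 0.01 rule; no multiplicity correction by default (a BH switch
  exists). $R^2$ is reported alongside r.
* **Prioritization.** Channels 2–4 use raw ANOVA p-values: combining
  BH-adjusted values breaks the uniformity Fisher's method assumes
  (`useAdjusted` overrides). The "best-correlated metabolite module" is the
  minimum p over metabolite eigengenes and is not re-calibrated for
  selection — a documented statistical caveat, as is the dependence among
  channels that share data (a Brown-type correction is out of scope).
  Zero p-values are clamped at 1e-300; ties rank lexicographically.
* **Missing values.** Strict by default; with `allowMissing = TRUE`
  correlations use pairwise-complete samples, the ANOVA still requires
  complete rows, nothing is imputed.
* **Metabolite log scale.** The factorial model consumes log2 abundances
  for both layers, so metabolite matrices are treated as log2 as well
  (`inputScale = "linear"` applies the transform at load); whether to
  pre-log metabolite data is genuinely open, and the choice is surfaced
  rather than hidden.
* **Variance filter scope.** The EM filter applies to transcripts only by
  default (metabolite panels are small and curated); it can be invoked on
  any `OmicsSet`.

# Problem sizes

The test-suite and acceptance studies run at deliberately chosen desk
scales: 2,000 transcripts / 500 metabolites / 108 samples for the
end-to-end pipeline, 505 features for planted-module recovery, $10^5$
permutations for MI-threshold calibration, 20–50 replicates for
planted-truth operating characteristics. These sizes make every property
checkable in seconds to a couple of minutes while keeping the statistical
regime (samples per cell, features per module) that of the motivating
study.

# Known limitations

* The static gap cut is a deliberate simplification of dynamic tree
  cutting; heavily nested or overlapping module structure will be merged
  or greyed rather than resolved.
* Fisher's method assumes independent channels; kME, DE and integration
  p-values share data, so combined p-values are optimistic in absolute
  terms — ranks are the intended output.
* The MI estimator's equal-frequency binning discards tie structure beyond
  rank order and is not meant for heavily discretized inputs.
* Unbalanced designs are handled through marginal (Type III) sums of
  squares with sum-to-zero contrasts; severely unbalanced or empty cells
  are not supported.
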