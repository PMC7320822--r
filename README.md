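# intermod

Integrative transcriptome–metabolome co-expression analysis for crossed
factorial experiments, in R.

`intermod` is for systems-biology analysts who profile transcripts **and**
metabolites over the same samples across crossed design factors — genetic
background (variety), environment (location) and developmental stage — and
want to go from two abundance matrices to a ranked list of candidate
regulator genes backed by several independent lines of evidence.

The pipeline:

1. **EM variance filter** — the per-transcript coefficient of variation
   (CV = SD/mean on the linear scale) is decomposed into low/high
   components with a two-Gaussian EM mixture; the high-variability
   component is retained.
2. **Factorial differential analysis** — per feature, the full model
   `y = μ + C + l + S + C:l + C:S + l:S + C:l:S + ε` on log2 abundances;
   per-factor BH-adjusted p < 0.01 plus a fold-change filter at 2 SDs of
   the fold-change distribution define the DEG/DEM sets.
3. **Co-expression modules** — unsigned weighted adjacency `|r|^β`
   (β = 7 by default, with a scale-free-fit diagnostic), topological
   overlap (TOM), average-linkage clustering with a static cut, module
   eigengenes (first PC of the standardized members) and kME membership
   statistics — identically for both omics layers.
4. **Regulator networks** — per gene module, mutual information between
   curated regulators and module members, thresholded at a
   permutation-null-calibrated cutoff (working tail probability 1e-8,
   generalized-Pareto tail extrapolation) and pruned with ARACNe's
   data-processing-inequality triangle rule.
5. **Two-way integration** — Pearson correlation of every metabolite
   against gene-module eigengenes and every gene against metabolite-module
   eigengenes (p < 0.01), tabulated into reciprocally supported
   module–module links.
6. **Fisher prioritization** — per gene, five evidence p-values (own-module
   kME; location, variety and stage ANOVA; best metabolite-module
   correlation) combined as `X² = −2Σln pᵢ ~ χ²(2k)` and scored
   `−log10(p_combined)`.
7. **Enrichment** — hypergeometric over-representation of GMT pathway sets
   at FDR < 5%.

A first-class synthetic-data generator plants recoverable ground truth —
co-expression modules, per-factor differential features, gene–metabolite
module couplings, and one regulator with sigmoid-coupled targets — so the
whole pipeline is testable end-to-end without external data.

## Worked example

```r
library(intermod)

sim <- simulateMultiOmics(simulationConfig(seed = 1))
sim$genes
#> OmicsSet (transcript): 2000 features x 108 samples
#>   design: 3 varieties x 3 locations x 6 stages

cv  <- computeCV(sim$genes)
fit <- fitGaussianMixtureEM(cv, seed = 1)
fit
#> Two-component Gaussian mixture (EM)
#>   weights: 0.338 / 0.662
#>   means:   0.1392 / 1.0505
#>   sds:     0.0095 / 0.6989
#>   loglik -415.242 after 8 iterations (converged)
kept <- selectHighVariance(sim$genes, fit)
#> variance filter: retained 1308 / 2000 features (cutoff 0.50)

runPipeline(pipelineConfig(seed = 1), "results/run1")
head(read.delim("results/run1/top_genes.tsv")[,
     c("gene_id", "module", "k", "x2", "p_combined", "score", "rank")], 5)
#>      gene_id    module k    x2 p_combined score rank
#> 1 gene_00001 turquoise 5 454.1  2.762e-91 90.56    1
#> 2 gene_00039 turquoise 5 412.2  2.383e-82 81.62    2
#> 3 gene_00046 turquoise 5 403.3  1.823e-80 79.74    3
#> 4 gene_00023 turquoise 5 401.2  5.218e-80 79.28    4
#> 5 gene_00012 turquoise 5 400.1  8.949e-80 79.05    5
```

The EM fit separates the planted low-CV background (mean CV ≈ 0.14) from
the high-variability component, and the filter keeps the module genes.
`gene_00001` — the planted regulator, a hub of the largest (turquoise)
module with strong effects for all three factors and five
mutual-information-detectable targets — tops the combined ranking with all
five evidence channels present (`k = 5`). The module-link table shows each
planted gene-module ↔ metabolite-module coupling with reciprocal support
and the alternating planted signs:

```r
head(read.delim("results/run1/module_links.tsv"), 4)
#>   gene_module metab_module n_forward n_reverse support sign_forward sign_reverse sign_consistent reciprocal
#> 1   turquoise    turquoise        40        55      95            1            1            TRUE       TRUE
#> 2       green    turquoise        37        49      86           -1           -1            TRUE       TRUE
#> 3        blue         blue        19        50      69           -1           -1            TRUE       TRUE
#> 4       brown        brown        19        50      69            1            1            TRUE       TRUE
```

`runPipeline()` writes every stage's tables (filtered matrix, DE tables,
module assignments/eigengenes/kME, GRN edge list with `kept_after_dpi`,
correlation and link tables, evidence and top-gene tables, enrichment) plus
a JSON-lines manifest, and can resume from the first missing intermediate.

## The methods vignette

`vignettes/integrative-multiomics.Rmd` documents the statistical model,
the synthetic generator's assumptions and what they do and do not emulate,
all numerical choices (EM initialization, Type-III sums of squares, the
static gap cut, the cube-root MI binning rule, the generalized-Pareto tail
extrapolation) and known limitations.
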