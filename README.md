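# tempodeg

Temporal knockdown transcriptome analysis: two-model ANOVA differential
expression with permutation family-wise error control, self-organizing-map
clustering of temporal log2-ratio profiles, interquartile-box gene-set
selection, and ontology overrepresentation analysis — with a synthetic-data
generator that plants known truth so the whole pipeline is testable offline.

## Who this is for

Analysts of short two-group time courses — the canonical case being an RNAi
knockdown versus control sampled on days 1, 3 and 5 with a few replicate
microarrays per group × day cell. The scientific question the pipeline
answers is *which transcripts respond, in what temporal shape, and which
biological processes they implicate* — with early responders pointing at the
primary target of the silenced gene.

## The method in brief

Given a gene × sample matrix of log2 intensities and a sample sheet
(group ∈ {control, knockdown}, day, replicate):

1. **Quantile normalization** — every array is forced to one common
   intensity distribution.
2. **DEG detection** — per gene, two two-way ANOVA F tests:
   Model 1 tests the group × time interaction in the full model
   ($F$ on $((a{-}1)(b{-}1),\ ab(r{-}1))$ df), Model 2 the group effect in
   the additive model ($F$ on $(a{-}1,\ N{-}a{-}b{+}1)$ df). Each model's
   p-values are adjusted by Westfall–Young step-down maxT over permutations
   of group labels within day strata (all genes relabelled jointly, so
   inter-gene correlation is preserved). A gene is a DEG when either
   model's adjusted p < 0.1.
3. **SOM clustering** — the DEGs' per-day knockdown − control mean log2
   ratios are clustered on a 3 × 2 self-organizing map (Gaussian
   neighbourhood, decaying schedule, zero-radius batch polish), giving up
   to six temporal classes, labelled so cluster 1 is the strongest
   up-profile.
4. **Gene-set selection** — per cluster and day, quartiles of member
   ratios; a cluster is selected when its whole interquartile box lies
   beyond ±0.75 on the log2 scale. Day-3 selections pool into early
   gene-sets, day-5 into late ones (early/down, late/up, late/down).
5. **Enrichment** — each gene-set is tested for term overrepresentation
   BinGO-style: IEA evidence discarded, annotations propagated up the DAG,
   exact binomial tail $P(X \ge k),\ X \sim \mathrm{Bin}(n, K/N)$ per term
   with k ≥ 1, Bonferroni correction at α = 0.05 (hypergeometric tail and
   Benjamini–Hochberg FDR available as sensitivity options).

A comparative-Ct utility (`relative_expression_ddct`) computes
$2^{-\Delta\Delta C_t}$ for qPCR follow-up.

## Worked example

```r
library(tempodeg)

run <- run_pipeline(run_config(seed = 1))
run
```

```
#> tempodeg pipeline run
#>   genes: 2000; DEGs: 14 (m1 13, m2 1, common 0)
#>   cluster sizes: 3, 2, 1, 3, 4, 1
#>   early_up: 3 genes, significant terms:
#>   early_down: 9 genes, significant terms:
#>   late_up: 5 genes, significant terms:
#>   late_down: 8 genes, significant terms:
```

```r
run$truth$planted_term
#> [1] "T0039"
head(as.data.frame(run$enrichment$early_down), 3)
#>    term    N   K n k      p_raw    p_corr significant    selected_genes
#> 1 T0039 1781 105 9 3 0.01315084 0.3287711       FALSE g0147,g0151,g0153
#> 2 T0041 1781 189 9 3 0.06150120 1.0000000       FALSE g0147,g0151,g0153
#> 3 T0036 1781  93 9 2 0.07686409 1.0000000       FALSE       g0113,g0152
```

Reading the output: of 2000 simulated genes (238 carrying planted temporal
archetypes at the default effect magnitudes), 14 pass the FWER-adjusted DEG
call — model 1 catches interaction-shaped responses, model 2 consistent
offsets. That small count is the family-wise error control doing its job:
at three replicates per cell, only the strongest planted effects clear a
maxT threshold computed over 2000 genes. The DEG profiles fall into six
temporal clusters; the clusters whose day-3 interquartile box sits below
−0.75 pool into the early/down set, and its enrichment ranks the planted
term first — though with only nine detected genes it stays above the
Bonferroni 0.05 bar at this seed. The dedicated recovery experiments in
the test suite (which test selection and enrichment on the planted
profiles directly, at the sizes the guarantees are stated for) recover the
early/down set at 97% and the planted term as top-ranked and significant
in ~95–99 of 100 runs. On real data the same call reports the per-model
counts, overlap, cluster sizes, gene-set sizes and significant terms for
the loaded matrix.

Each stage is also exposed directly — `quantile_normalize()`,
`ratio_profiles()`, `deg_anova()` (a classed fit with `print`/`summary`),
`westfall_young()`, `som_fit()` (`print`/`predict`/`plot`),
`cluster_box_stats()`, `select_genesets()`, `enrich_geneset()` — and a thin
CLI (`inst/scripts/tempodeg-cli.R`) wraps them with `simulate`,
`normalize`, `deg`, `cluster`, `genesets`, `enrich`, `run-all` and `ddct`
subcommands.

Real series-matrix-style files load through
`read_series_matrix(file, sample_sheet)`; the package performs no network
access, so the file and the sample sheet describing each column are
supplied by the user.

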