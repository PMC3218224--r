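---
title: "Methods: temporal knockdown transcriptome analysis with tempodeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal knockdown transcriptome analysis with tempodeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempodeg)
```

# The analysis problem

A short knockdown time course asks a deceptively simple question: after a
gene is silenced, *which* transcripts respond and *when*? The design that
tempodeg targets is two groups (control and knockdown) sampled on a few days
(by default days 1, 3 and 5) with a small number of replicate arrays per
group × day cell, summarized as a gene × sample matrix of log2 intensities.
The timing matters biologically: transcripts that move before a downstream
phenotype appears are candidates for the primary target of the silenced
gene, while late responders are more likely secondary consequences.

The pipeline has five stages, each usable on its own:

1. **Quantile normalization** of the arrays.
2. **DEG detection** with two two-way ANOVA models and Westfall–Young
   permutation adjustment.
3. **SOM clustering** of the DEGs' temporal log2-ratio profiles on a 3 × 2
   map.
4. **Gene-set selection** by an interquartile-box threshold on per-cluster,
   per-day box statistics.
5. **Ontology overrepresentation analysis** of the selected gene-sets.

A synthetic-data generator with planted truth makes every stage testable
without any external download, and a comparative-Ct utility supports qPCR
follow-up arithmetic.

# Models and procedures

## Normalization

Quantile normalization forces every array to share one empirical intensity
distribution: each column's sorted values are replaced by the row-wise mean
of all columns' sorted values, re-assigned by within-column rank. Ties
within a column receive the mean of the row-means they span. The transform
is idempotent, and after it the Kolmogorov–Smirnov distance between any two
columns is exactly zero. The package deliberately starts from an
already-summarized log2 matrix: probe-level background correction (RMA) is
a real-data preprocessing step performed upstream by array software and is
out of scope here.

## Two-model ANOVA DEG detection

For each gene $g$ with log2 expression $y_{ijk}$ in group $i$, at day $j$,
replicate $k$, two classical fixed-effects models are considered:

* **Model 1 (full):** $y_{ijk} = \mu + \alpha_i + \beta_j +
  (\alpha\beta)_{ij} + \epsilon_{ijk}$, tested on the interaction term
  $(\alpha\beta)_{ij}$ with $F$ on $((a-1)(b-1),\; ab(r-1))$ degrees of
  freedom. This catches genes whose *temporal pattern* differs between
  groups.
* **Model 2 (additive):** $y_{ijk} = \mu + \alpha_i + \beta_j +
  \epsilon_{ijk}$, tested on the group term $\alpha_i$ with $F$ on
  $(a-1,\; N-a-b+1)$ degrees of freedom. This catches genes with a
  consistent group offset across days.

Designs must be balanced; in the balanced layout the classical sequential
and marginal sums-of-squares decompositions coincide, so no convention
choice is hidden. An unbalanced design raises an explicit error. A gene
with zero residual variance gets $p = 1$ and a flag rather than an
undefined ratio.

### Westfall–Young adjustment

Per-gene p-values are adjusted for family-wise error by step-down maxT:
group labels are permuted *within each day stratum* (which preserves the
time effect under the null of no group or interaction effect), the same
relabeling is applied to all genes jointly (preserving inter-gene
correlation, which is what gives the method its power advantage over
Bonferroni), and all F statistics are recomputed. For the gene ranked $i$
by observed F, the adjusted p is the permutation frequency with which
$\max_{j \ge i} F^{*}_{j}$ meets or exceeds the observed $F_i$, with
step-down monotonicity enforced. When the number of distinct stratified
relabelings — $\binom{2r}{r}^{b}$ for two groups — fits within the requested
permutation budget, they are enumerated exhaustively and exact fractions
reported; otherwise random permutations are drawn and the add-one estimator
$(b+1)/(B+1)$ keeps adjusted p in $[1/(B+1), 1]$. Ties between permuted and
observed statistics count as exceedances, with a $10^{-9}$ relative
tolerance absorbing float jitter between algebraically equivalent
relabelings. A step-down minP variant is available behind
`method = "minP"`.

Each model's p-values are adjusted **separately**, and a gene is a DEG when
either model's adjusted p falls below the threshold (default 0.1). This
mirrors reporting per-model counts plus their overlap. A post-hoc 2-fold
annotation (max |log2 ratio| ≥ 1 over days) is reported and can optionally
gate the flag, but is off by default: the DEG definition is by adjusted p
alone.

A note on power: FWER-adjusted permutation thresholds over families of
hundreds to thousands of genes correspond to per-gene critical F values of
roughly 15–27 at these degrees of freedom. With $r = 3$ replicates,
moderate effects (day-5 log2 shifts around 1.5 at noise sd 0.4) sit near
or below that bar and are flagged with low probability; per-gene power
reaches 80%+ only for strong effects (|log2 shift| around 3 at noise sd
0.3). The tests assert power where the procedure genuinely has it, and
error control everywhere.

## SOM temporal clustering

DEG profiles — the per-day knockdown-minus-control mean log2 ratios, one
3-vector per gene — are clustered on a rectangular 3 × 2 self-organizing
map, giving at most six temporal classes. Training is the classical online
algorithm: codebooks initialized uniformly over the per-day data range,
500 epochs over the genes in random order, Gaussian lattice neighbourhood,
learning rate decaying linearly 0.5 → 0.01 and radius 1 → 0.5. All
schedule parameters are exposed; the original analysis tool's internals are
unpublished, so exact membership reproduction of any particular historical
run is not claimed.

Two refinements stabilize the solution, and both are deliberate design
choices documented here because the design space was genuinely open:

* **Zero-radius batch polish.** After online training, assignment-to-nearest
  and codebook-recomputation-as-member-mean are iterated to a fixed point.
  An online update with final learning rate 0.01 necessarily ends a
  O(learning rate) distance away from the member centroid; the polish makes
  every codebook end exactly at its members' mean (so a 1 × 1 map recovers
  the data centroid to machine precision) and makes assignments a local
  optimum of the quantization error.
* **Empty-node repair.** During the polish, an empty node is reseeded on
  the profile farthest from its assigned codebook, one per pass. Without
  it, the 3 × 2 map reproducibly parked one node empty between two nearby
  archetypes and merged them. Nodes still end empty when there are fewer
  profiles than nodes.

Cluster labels are canonicalized by sorting nodes on their last-day
codebook value, descending — cluster 1 is always the strongest
up-regulated profile, which makes runs comparable.

## Interquartile-box gene-set selection

For each cluster and day, Q1/Q2/Q3 of the member genes' log2 ratios are
computed by linear interpolation between order statistics (`quantile`
type 7: quartiles of (1,2,3,4) are 1.75/2.5/3.25). A cluster is *selected*
at a day when its whole interquartile box lies beyond the threshold band:
Q3 ≤ −τ (down) or Q1 ≥ +τ (up), with τ = 0.75 by default. We read the
selection rule on the box rather than on the interquartile range proper
because an IQR is non-negative by definition, so "IQR smaller than −0.75"
can only describe the box position; the alternative median reading
(|Q2| > τ) is available behind `rule = "median"`.

Selections at the second sampled day (day 3) define the **early**
gene-sets and selections at the last day (day 5) the **late** gene-sets;
co-selected clusters of the same direction are pooled (early/down,
late/up, late/down). Day-1 selections are flagged in the stats table but
produce no set — in a well-calibrated run day-1 boxes straddle zero.
Selection is monotone in τ: raising the threshold never adds genes.

## Overrepresentation analysis

Gene-sets are tested against an ontology DAG the way the classical BinGO
tool does it: electronically inferred (IEA) annotations are discarded
first; remaining annotations are propagated to all ancestors (true-path
rule, idempotent, cycles rejected with a named cycle); genes with no
surviving annotation are dropped from both the set (n) and the background
(N); every term annotating at least one set gene is tested — testing
k = 0 terms would only inflate the family — with the exact binomial upper
tail $P(X \ge k)$, $X \sim \mathrm{Bin}(n, K/N)$ (or the hypergeometric
tail, which agrees within ~10% relative once $N \gtrsim 50\,n$ in the
moderate tail); and raw p-values are Bonferroni-corrected across the tested
terms at significance level 0.05. Benjamini–Hochberg FDR is available as
the sensitivity alternative; since BH-adjusted values never exceed
Bonferroni ones, switching can only grow the significant set — a strongly
planted term stays significant and top-ranked under both.

The background universe defaults to all genes of the expression matrix,
restricted internally to those retaining at least one non-IEA annotation
after propagation. The reference set of any particular historical analysis
is unknown, so this is configurable.

## Comparative Ct

For qPCR validation arithmetic, relative expression is
$2^{-\Delta\Delta C_t}$ with
$\Delta\Delta C_t = (C_t^{\text{target,kd}} - C_t^{\text{ref,kd}}) -
(C_t^{\text{target,ctrl}} - C_t^{\text{ref,ctrl}})$ against a reference
transcript such as rp49. $\Delta\Delta C_t = 3.32$ corresponds to ~10%
residual expression, i.e. ~90% knockdown.

# The synthetic-data generator

The generator is first-class, tested code — it defines the conditions under
which every downstream guarantee is demonstrated.

* **Design:** 2 groups × days (1, 3, 5) × r = 3 replicates. Three
  replicates is the smallest design on which the interaction test is
  defined with reasonable error df and is typical for this kind of array
  experiment; the replicate count is configurable.
* **Signal:** six planted archetypes (label, per-day mean log2 ratio, gene
  count) spanning the qualitative temporal shapes seen in knockdown time
  courses: strong monotone up (day-5 ratio 2.2, i.e. beyond 4-fold),
  moderate up (1.2), transient down-then-up (−1.2 at day 3), an early drop
  that is maintained (−1.3, −1.2), strong monotone down (−1.5, −2.5) and
  moderate down (−0.3, −1.2). Default counts 33/77/9/12/27/80 give 238
  planted genes among 2000.
* **Noise:** i.i.d. Gaussian on the log2 scale, sd 0.3 — the simplest model
  consistent with the ANOVA assumptions and a typical residual sd for
  replicate summarized arrays. A per-gene day effect (sd 0.2) shared by
  both groups exercises the time term without touching any ratio.
* **Ontology:** 50 terms in 3 layers (each non-root term one parent in the
  layer above, acyclic by construction), ~3 annotations per gene, evidence
  codes 30% IEA / 70% experimental, and one deepest-layer term planted at
  8× its background annotation rate inside the early/down truth set, with
  at least two experimentally-coded in-set annotations guaranteed so the
  planted signal survives IEA filtering.
* **Truth records:** every gene's archetype, the planted gene list, the
  early/down truth set (archetypes with second-day mean ≤ −0.75) and the
  planted term id, written as JSON next to the data.

What the generator does **not** emulate: probe-level artifacts, spatial or
batch effects, intensity-dependent variance, correlated gene blocks beyond
the planted archetypes, and realistic ontology topology. Passing tests
therefore demonstrate correctness of the *procedures* and their error
control under the stated noise model — not performance on any particular
real dataset.

# Numerical choices and degenerate inputs

* Permutation p-values use the add-one estimator; exhaustive enumeration
  (triggered automatically when feasible) reports exact fractions.
* Zero residual variance ⇒ p = 1 plus a flag, never 0/0.
* Quartiles: `quantile` type 7, fixed and documented for reproducibility.
* SOM ties in nearest-node assignment break to the lowest node index;
  label canonicalization breaks codebook ties by lattice position.
* Empty clusters: reported with NA quartiles, never as zeros; empty
  gene-sets yield empty enrichment tables, and a set with no annotated
  member warns rather than errors.
* Every stage seed is derived deterministically from one global seed and
  the stage name, so a stage can be re-run in isolation and a full re-run
  is byte-identical.

# Problem sizes used in validation

The shipped validation suite demonstrates error control with 200 null
replicates of 2000 genes at 200 permutations per model; archetype recovery
on 238 profiles; gene-set recovery over 100 simulation replicates of 500
genes (early-down archetypes planted at day-3 mean −1.5); and enrichment
recovery over 100 ontology replicates (universe 2000, set 40, factor 8).
These sizes were chosen to estimate each rate with a Monte-Carlo standard
error small relative to its acceptance margin while keeping a full run
desk-scale.

# Known limitations

* The ANOVA is fixed-effects and requires balance; unbalanced real designs
  are rejected rather than approximated. No empirical-Bayes moderation is
  applied, so with r = 3 the FWER-adjusted caller has high power only for
  strong effects.
* SOM results depend on the training schedule; with the default polish the
  solution is a local optimum of the quantization error, not a global one.
* The OBO reader handles only `id:`/`is_a:` stanza lines; richer
  relationship types are out of scope.
* Real-data mode requires a user-supplied sample sheet; sample-title
  parsing conventions vary too much to guess.
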