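---
title: "Methods: stratified mutual-information co-expression networks"
author: "coexpStrata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified mutual-information co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`coexpStrata` studies how the functional coordination of genes — their
co-expression structure — differs between sexes and changes across age in
bulk RNA-seq cohorts. The analysis unit is a *stratum*: one of the six
sex × age-group sample subsets FY, FM, FE, MY, MM, ME (F/M crossed with
young 20–39, middle-aged 40–59, elderly 60+). Each stratum gets its own
gene co-expression network (GCN); all downstream statements are
comparisons between these six networks: shared and unique interactions,
giant-component organisation, and over-represented processes.

# The synthetic cohort generator

Because the real inputs of such studies are large controlled-access-free
but bulky cohort downloads, the package ships a generator whose defaults
reproduce the design of a muscle aging cohort: six strata with sample
sizes F = 39/134/87 and M = 93/245/205 (803 samples), a configurable gene
count, and planted co-expression modules.

The mechanism, per stratum *s* and sample *j*:

* a library-size factor $L_j = \exp(N(-\sigma^2/2, \sigma^2))$
  (mean fixed at 1; default $\sigma = 0.2$, a typical bulk RNA-seq
  sequencing-depth spread);
* each module *m* active in *s* draws one latent factor
  $z_{mj} \sim N(0,1)$ per sample;
* gene *g* has mean $\mu_{gj} = L_j \exp(\log m_g + \beta z_{mj})$
  (background genes use $\beta = 0$) and counts
  $\mathrm{NB}(\mu_{gj}, \phi)$ with dispersion $\phi = 0.1$
  (variance $\mu + \phi\mu^2$), the overdispersion scale commonly
  estimated for bulk tissue;
* baseline log-means $\log m_g \sim U(\log 5, \log 1000)$, shared across
  strata, so the filtering step has genuine work to do at the low end.

A single latent factor per module is the simplest mechanism that produces
tunable, module-wide co-expression with realistic marginal
overdispersion. $\beta$ is dimensionless; $\beta \approx 0.5$ is a weak
signal, $\beta \ge 1.2$ a strong one. A configurable fraction of modules
(default 0.5) is active in exactly one stratum — these become the planted
"unique transcriptional programs" — and the rest in all strata. Module
membership is assigned in consecutive gene blocks (`G000001`…), which
keeps ground truth human-readable and has no statistical consequence
since genes are exchangeable under the mechanism.

**Determinism.** All randomness flows from one root seed; every stratum
(and every decoy gene-set draw, every null test in the pipeline) uses a
child stream derived by hashing a fixed string key onto 31 bits
(`deriveSeed`). Adding or removing a stratum therefore never perturbs the
counts of the others, and identical configs are bit-for-bit reproducible.

**What the generator does not emulate:** batch effects and other
technical covariates, isoform structure, correlated module overlap,
hub-dominated (scale-free) module topology, and the heavy-tailed
gene-mean distribution of real tissue. Passing tests on this generator
demonstrate that the estimators and set operations do what they claim
under a known truth — not that any particular biological conclusion
transfers to real muscle data.

# Preprocessing

Two gene filters are applied jointly to the full (unsplit) count matrix,
so all six networks share one gene universe: keep genes with mean count
≥ 10 *and* zero counts in at most 50% of samples. Both rules are
evaluated on the same input, which makes the filter idempotent and
order-independent.

Quantile normalization forces every sample onto the reference
distribution defined by the across-column mean of sorted values,
preserving within-sample ranks (delegated to
`limma::normalizeQuantiles(ties = TRUE)`). Tied values receive the mean
of the reference values at their tied rank positions, so the output does
not depend on sort stability. One consequence worth stating explicitly:
for columns *with* ties, tie-averaging replaces *r* reference values by
*r* copies of their mean, so the "identical sorted multiset across
columns" property holds exactly only for tie-free (continuous) columns;
with integer counts it holds up to tie-group averaging. A single-column
matrix is returned unchanged.

Age-to-group mapping accepts Y/M/E labels, numeric ages, or decade
brackets. The elderly boundary is genuinely ambiguous in cohort designs
("60–70" vs. decade brackets extending to 79); the default maps
60–69 and 70–79 to E and is overridable (`mapAgeGroup`), rather than
guessing an intent.

# Network inference

**Estimator.** Plug-in mutual information (nats) over equal-frequency
(quantile) bin assignments, `n_bins = floor(sqrt(n))` clamped to [2, 20]
under the `"auto"` rule. Binning is rank-based: average ranks, then
`bin = floor(B · (rank − 1) / n) + 1`, so a tie group spanning a
boundary falls entirely into the lower bin, a constant vector collapses
into one bin (MI exactly 0), and MI is invariant under strictly monotone
transforms of either vector. The estimator requires `n ≥ 4 · n_bins`;
below that, bin occupancies are too sparse for even rank-based MI to
mean anything, and the call errors rather than degrades. Absolute MI
values depend on this discretization choice; only edge *ranks* are
consumed downstream, and only rank-based results should be compared
across MI estimators.

**All-pairs computation** discretizes each gene once and accumulates the
joint histograms of gene blocks via sparse indicator cross-products
(`Matrix`), using MI = H(i) + H(j) − H(i,j); memory is bounded by the
block size, not the gene count.

**DPI pruning** marks edge (i, j) for removal when some third gene *k*
has `MI(i,j) < min(MI(i,k), MI(j,k)) · (1 − ε)` with all three entries
present in the *input* table (mark-then-sweep), then removes all marks at
once. This makes the result independent of gene enumeration order; ties
survive because the inequality is strict. Default ε = 0.

**Top-k retention** keeps the k strongest surviving edges (default
10,000), with ties at the cutoff broken by canonical
(geneA, geneB) lexicographic order. Size-matching the networks is what
makes cross-stratum edge counts comparable. No MI significance filter is
applied before the cut — the ranking is the statistic.

A deliberate property of DPI worth knowing when interpreting synthetic
runs: within a planted module all pairs are (noisily) equally dependent,
and DPI prunes such near-symmetric cliques down to sparse, noise-selected
subgraphs. Which clique edges survive differs between strata, so
conserved-edge counts between synthetic stratum networks are much smaller
than the planted overlap — at desk scale, often near zero across all six
networks. Real co-expression modules are hub-dominated rather than
symmetric, which is why empirical studies see large conserved sets
despite DPI. For module-recovery benchmarks the package therefore
measures recall on the *raw* top-k network (`dpi = FALSE`): recall of all
within-module pairs is only a meaningful target before triangle pruning.

# Network comparison

Edge identity everywhere is the unordered gene pair; weights are carried
but never compared. Overlap matrices report shared counts and Jaccard
indices for edge sets and for endpoint gene sets of the top-k networks;
conserved edges are the intersection across a network group (weight =
minimum across inputs, a documented convention); unique edges are those
present in no other network. Components are standard undirected connected
components (igraph); since genes exist only as edge endpoints, there are
no isolated vertices.

# The bootstrap LCC null model

The question: is the largest connected component of a unique-interaction
subnetwork larger (or smaller) than expected for *any* random subset of
that many edges from the parent network? Each replicate draws
`subset_size` edges uniformly without replacement from the parent's
edges (with-replacement draws are available behind a flag) and records
the LCC gene count; the default is 100,000 replicates. Empirical
p-values use the add-one rule `p = (#extreme + 1)/(n_sims + 1)` so a
finite simulation never reports 0, and both tails are returned — whether
"larger than chance" or "smaller than chance" is the interesting
direction is a presentation choice, not a property of the test. The
inner loop (partial Fisher–Yates draw + stamped union-find) is compiled
(Rcpp) and consumes R's RNG, so `set.seed`-style reproducibility holds
exactly; results are checked in the test suite against exhaustive subset
enumeration on small parents and against an igraph-independent
union-find oracle.

# Over-representation

Local hypergeometric upper-tail tests against user-supplied GMT
collections, BH-adjusted, significant at adjusted p < 0.05. The universe
is the filtered transcriptome (all genes surviving the count filters),
not the whole annotation — the defensible local choice when no web
service's internal background is available; it is configurable. For
synthetic pipeline runs the collection is built from the planted modules
plus size-matched random decoy sets, so the stage is exercised end to
end. Note that over-representation loses power as the query approaches
the universe: at desk scale (a few hundred genes, networks touching most
of them) saturation is expected and significant-term counts are small.
Absolute term counts always depend on the annotation release supplied
and are not comparable across libraries.

# Pipeline, problem sizes and numerical choices

`runPipeline()` executes simulate (or load) → filter + normalize →
six-way split → infer ×6 → compare → null tests → enrichment, writes all
outputs as plain text, and records a manifest with every parameter, seed
and output MD5. Identical configs give byte-identical trees (weights are
serialised at 12 significant digits).

Problem sizes used by the shipped checks were chosen to keep every run
at interactive scale on one CPU while leaving each statistic clearly
measurable: module recovery uses 100 genes × 100 samples with one
20-gene module (190 true pairs, top-500 edges, raw MI); the null-model
calibration uses a 70-node/100-edge parent, 200 null-drawn observations
and 2,000 replicates each; the end-to-end pipeline demonstration uses
300 genes across the full 803-sample design with k = 400 and 20,000
null replicates. The stratum-specificity check infers the other
stratum's network at k = 200 over ~100 genes so that chance-level recall
(k / #pairs ≈ 0.04) sits well below the 0.1 bound being asserted.

Degenerate inputs are contracts, not accidents: constant genes carry
MI 0 edges nowhere; empty strata are permitted and logged; an empty
unique set skips its null test; an empty query yields an empty (not
failing) enrichment; filters that remove *every* gene abort the
pipeline.

# Limitations

Absolute MI values are estimator-specific; only ranks travel. The
O(G²) pair computation is intended for filtered transcriptomes at most
(tens of thousands of genes imply ~10⁸ pairs; the blocked evaluation
bounds memory but not time — multicore parity with compiled ARACNe
implementations is out of scope). The simulator's module model is
exchangeable and single-factor; it cannot benchmark hub detection,
overlapping modules or batch robustness. GTEx-scale headline counts
(e.g. specific conserved-edge totals) depend on the original data and
MI implementation and are not reproduced at desk scale.
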