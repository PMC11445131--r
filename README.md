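# coexpStrata

Sex- and age-stratified gene co-expression network analysis for bulk
RNA-seq cohorts.

Skeletal muscle is a largely postmitotic tissue, which makes it a natural
model for studying how the *functional coordination* of genes — not just
their expression levels — changes with age and differs between the sexes.
`coexpStrata` implements a complete, reproducible pipeline for that
question: it splits a cohort into six sex × age strata (FY, FM, FE, MY,
MM, ME), infers a mutual-information co-expression network per stratum,
quantifies which interactions are conserved across strata and which are
unique to one, tests whether the unique subnetworks are more organised than
chance, and asks which biological processes their genes over-represent.
A negative-binomial simulator with planted co-expression modules emulates
the cohort design, so the entire pipeline is testable end to end without
any data download.

## The method

**Network inference.** For genes *i*, *j* with expression vectors over the
*n* samples of one stratum, each vector is discretized into *B*
equal-frequency (quantile) bins (`B = floor(sqrt(n))`, clamped to [2, 20])
and the dependence is scored by plug-in mutual information, in nats:

    MI(i, j) = Σ_ab  p(a, b) · log [ p(a, b) / ( p(a) p(b) ) ]

over the joint histogram of bin assignments. The data-processing
inequality (DPI) then removes, in every gene triangle, the weakest edge as
a presumed indirect interaction: edge (i, j) is pruned when
`MI(i,j) < min(MI(i,k), MI(j,k)) · (1 − ε)` for some third gene *k*
(ε = 0 by default, evaluated mark-then-sweep against the input table so the
result is order-independent). The *k* strongest surviving interactions
(default 10,000) form the stratum's network, so all six networks are
size-matched and comparable.

**Comparison.** Edge identity is the unordered gene pair. Shared structure
between networks *A*, *B* is summarised by counts |A ∩ B| and the Jaccard
index |A ∩ B| / |A ∪ B|, for edges and for endpoint genes; conserved
interactions are the intersection across a group of networks and unique
interactions those present in exactly one.

**Null model.** For a unique subnetwork with *s* edges and an observed
largest-connected-component (LCC) size of *L* genes, the null draws *s*
edges uniformly without replacement from the parent stratum network
(100,000 replicates by default) and recomputes the LCC. Empirical
p-values use the add-one rule `p = (#extreme + 1) / (n_sims + 1)`; both
tails are reported.

**Over-representation.** Gene sets are read from GMT; each term is scored
by the hypergeometric upper tail P(X ≥ k) with the filtered transcriptome
as universe, Benjamini–Hochberg adjusted, significant at adjusted p < 0.05.

## Worked example

```r
library(coexpStrata)

cfg <- simulationConfig(nGenes = 120, groupSizes = c(FY = 60, MY = 60),
                        nModules = 2, moduleSize = 10, beta = 1.5,
                        stratumSpecificFraction = 0.5, seed = 101)
sim <- simulateCounts(cfg)                      # counts + ground truth
se  <- quantileNormalize(filterGenes(sim$se))   # mean >= 10, <= 50% zeros
strata <- splitStrata(se)

net <- inferNetwork(strata$FY, k = 150, nBins = "auto", name = "FY")
net
#> CoexpressionNetwork 'FY': 150 edges over 105 genes
#> top edges:
#>    geneA   geneB       mi
#>  G000003 G000007 1.119572
#>  G000013 G000014 1.071192
#>  G000001 G000007 1.070708

uniq <- uniqueEdges(net, list(inferNetwork(strata$MY, k = 150, name = "MY")))
lccNullTest(net, subset = uniq, nSims = 10000, seed = 3)
#> LCCNullResult 'FY_unique': observed LCC = 101 genes (subset of 143 edges)
#>   null over 10000 replicates: mean 103.12, sd 1.47
#>   P(null >= obs) = 0.9428, P(null <= obs) = 0.1375 [add-one]
```

The top edges connect genes of the planted modules (`G000001`–`G000010`
form module 1), and the raw top-150 network recovers every planted
within-module pair of the FY stratum
(`moduleRecall(..., sim$truth, "FY")` returns 1). The null test shows the
FY-unique subnetwork's giant component is compatible with chance in this
toy two-stratum design — with a single other stratum, most strong module
edges are shared rather than unique.

The whole workflow (simulate → preprocess → infer ×6 → compare → null
tests → enrichment) runs from one config and writes a checksummed
manifest:

```r
cfg <- pipelineConfig(outDir = "run1",
                      simulation = simulationConfig(seed = 7), seed = 7)
manifest <- runPipeline(cfg)
```

Re-running an identical config reproduces byte-identical outputs.

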