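# NeuroPepNet

Reconstruction and topological analysis of "wireless" neuropeptide
signaling connectomes.

Neurons communicate not only through wired chemical synapses but also
through extrasynaptic volume transmission: a neuropeptide released by
one neuron diffuses to any neuron expressing a receptor it activates.
NeuroPepNet builds a draft of this signaling network for the 302-neuron
*C. elegans* nervous system — and for synthetic nervous systems with
planted ground truth — by integrating three data layers:

* **ligand-receptor biochemistry**: peptide-receptor activation entries
  with EC50 potencies, reduced to gene-level couples at a potency
  threshold (500 nM default, 100 nM for sensitivity analysis);
* **binary gene expression**: which neurons express each precursor
  (NPP) and receptor (GPCR) gene, with class-level calls broadcast to
  member neurons;
* **anatomy**: process-bundle membership, body region and nerve-ring
  strata, which drive four nested spatial diffusion models
  (`contact ⊆ short ⊆ mid ⊆ long`).

For a couple *N* the connection rule is
`A^N(i,j) = NPP^N(i) × GPCR^N(j)`, filtered by the diffusion model and
summed over couples into a weighted aggregate connectome (edge weight =
number of couples connecting a directed pair). On top of this the
package provides:

* directed topology metrics: density `K/(N²−N)`, reciprocity
  `|E↔|/K`, directed transitivity (triangles over triples), degree
  tables and degree correlations;
* **rich-club analysis**: `φ(k) = M_k/(N_k(N_k−1))` normalized against
  100 degree-preserving edge-swap randomizations (compiled swap kernel,
  10 attempts per edge), with a one-sigma onset rule and member
  extraction;
* per-couple topology classes (local / pervasive / broadcaster /
  integrative, by the 50-neuron expression-breadth rule) and
  minimal-diffusion-range diagnostics for exclusive one-to-one couples;
* mesoscale structure: t-SNE/PCA embedding of incoming-connectivity
  profiles, density-based clustering with an explicit periphery,
  Kruskal-Wallis + Tukey-Kramer group comparisons, intergroup
  connection densities;
* co-expression enrichment (one-sided Fisher exact with BH-FDR across
  the full NPP × GPCR universe), signaling-cascade networks over
  enriched pairs, and autocrine-loop profiling;
* a synthetic-data generator with planted motifs (broadcaster /
  integrative couples, rich-club hub sets, enriched pairs, autocrine
  loops) whose recovery is the package's acceptance surface.

## Worked example

```r
library(NeuroPepNet)

cfg <- synthConfig(seed = 1)        # 302-neuron synthetic conditions
sim <- generateSynthetic(cfg)
sim$expr
#> PeptideExpression: 111 genes x 302 neurons (threshold level 4); 8.1% calls positive
sim$interactions
#> InteractionTable: 497 peptide-receptor entries, 164 unique gene couples

couples <- couplesAtThreshold(sim$interactions, ec50Max = 5e-7)
nrow(couples)
#> [1] 99

nets <- lapply(seq_len(nrow(couples)), function(i)
  applySpatialFilter(buildPairNetwork(sim$expr, couples[i, ]),
                     "short", sim$ann))
agg <- aggregateNetworks(nets, "short")
agg
#> AggregateNetwork [short model]: 99 couples, 6241 edges, density 0.0687

unlist(networkMetrics(agg))[c("density", "transitivity", "reciprocity")]
#>      density transitivity  reciprocity
#>   0.06865636   0.60304872   0.53100465

rc <- richClub(binarize(agg), nNull = 100, swapsPerEdge = 10, seed = 2)
rc
#> RichClubCurve over k = 1 .. 172
#>   onset k = 6; 283 members (degree > onset)
#>   nulls: n = 100, 10 swaps/edge, seed 2, sigma basis 'normalized'

autocrineProfiles(sim$expr, couples)$fractionAutocrine
#> [1] 0.536
```

Reading: of the 164 gene couples in the synthetic screen, 99 have an
activation at or below 500 nM. Under the short-range model (shared
process bundle, sealed pharynx) they form a 6,241-edge directed network
whose transitivity (0.60) and reciprocity (0.53) are far above what its
density (0.069) alone would suggest; the degree-preserving null
comparison finds a rich club spanning most of the network (onset degree
6, 283 members), and 54% of neurons co-express at least one cognate
couple — a putative autocrine loop. `runPipeline(runConfig(...))`
chains all stages and writes a seeded, hash-reproducible JSON report;
real data enter through `loadExpression()`, `loadInteractions()`,
`loadAnnotations()` and `loadWired()` with the canonical 302-neuron
`defaultRoster()`.

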