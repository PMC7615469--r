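---
title: "Reconstructing and analyzing wireless neuropeptide signaling networks"
author: "NeuroPepNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and analyzing wireless neuropeptide signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NeuroPepNet)
```

## The problem

Chemical synapses are only one channel of neuronal communication.
Neuropeptides released from dense-core vesicles act extrasynaptically:
a "wireless" signal travels by diffusion from a releasing neuron to any
neuron that expresses a receptor the peptide activates, within whatever
spatial range diffusion permits. NeuroPepNet reconstructs this signaling
network for the 302-neuron *C. elegans* hermaphrodite nervous system
from three data layers and analyzes its topology:

1. **Biochemistry** — a table of peptide-receptor activation events with
   EC50 potencies from an in vitro screen. Entries are reduced to
   gene-level *couples* (precursor gene, receptor gene) that have at
   least one activation at or below a potency threshold; 500 nM is the
   default (potencies in that range have in vivo support) and 100 nM is
   the stricter sensitivity setting. The couple keeps the minimum EC50
   among its entries.
2. **Expression** — binary gene-by-neuron calls. The most stringent
   threshold level of the upstream single-cell data is used, and the
   level is carried as a provenance tag only; the package never
   re-thresholds counts. Calls made at the level of anatomical classes
   are broadcast to every member neuron of the class.
3. **Anatomy** — for every neuron its process-bundle memberships (27
   fascicles), body region (head, midbody, tail; head includes the
   pharynx), and nerve-ring strata (four layers defined by contact
   patterns).

For a couple \(N\) the unfiltered connection rule is the outer product

\[ A^N(i,j) = \mathrm{NPP}^N(i)\times \mathrm{GPCR}^N(j), \]

i.e. neuron \(i\) connects to neuron \(j\) when \(i\) expresses the
precursor and \(j\) the receptor. Summing the per-couple binary networks
gives the weighted aggregate connectome: the weight of an edge is the
number of distinct couples that can signal along it.

## Spatial diffusion models

Four nested predicates restrict which expression-compatible pairs count
as connected:

* **long** — no restriction.
* **mid** — both neurons in the same body region (the pharynx belongs to
  the head).
* **short** — the neurons share a process bundle, with the pharynx as a
  sealed compartment: pharyngeal neurons connect only to pharyngeal
  neurons.
* **contact** — a shared nerve-ring stratum, or a shared thin
  (non-nerve-ring) bundle.

Two structural choices keep the nesting
`contact ⊆ short ⊆ mid ⊆ long` exact rather than approximate. First,
`contact` is defined as the stratum/thin-bundle condition *conjoined*
with the short predicate. Second, `mid` is defined as same-region *or*
short: processes sharing a bundle are by definition in a shared
territory, even when a long bundle (e.g. the ventral cord) spans the
per-neuron region labels. Self-pairs always pass every predicate — a
neuron shares its own location — so autocrine signaling is never
filtered spatially. Self-loops are kept through construction and
aggregation and are dropped (diagonal zeroed) inside every topology
metric, which is also where the networks are binarized.

For couples whose ligand-receptor relationship is one-to-one
(*exclusive* couples), `minimalRange()` reports, per expressing neuron,
the smallest diffusion class under which it can communicate with at
least one partner-gene neuron, on the ordered scale
`contact_stratum < contact_thin_bundle < short < mid < long`
(`unreachable` when the partner is expressed nowhere). This is the
diagnostic used to ask whether the data are consistent with
contact-limited signaling (they are not, for most receptors: signals
must cross strata, bundles, and into the pharynx).

## Topology metrics

All metrics operate on the binary directed network with the diagonal
zeroed.

* density \(d = K/(N^2-N)\);
* reciprocity \(r = |E^{\leftrightarrow}|/K\) with
  \(|E^{\leftrightarrow}| = \sum_{i \ne j} A_{ij}A_{ji}\) (each directed
  edge of a mutual pair counts);
* directed transitivity \(T = \sum_i t_i / \sum_i
  [k_i^{tot}(k_i^{tot}-1) - 2\sum_j A_{ij}A_{ji}]\) with
  \(t_i = \tfrac12 \sum_{j,h}(A_{ij}+A_{ji})(A_{ih}+A_{hi})(A_{jh}+A_{hj})\).
  The denominator is the standard directed clustering triple count and
  the whole statistic is verified against exhaustive enumeration over
  ordered triples.

### Rich club

For each degree level \(k\), nodes with total degree \(> k\) form a
subnetwork with coefficient \(\phi(k) = M_k / (N_k(N_k-1))\). The curve
is normalized by the mean of \(\phi\) over 100 degree-preserving
randomizations (directed edge swaps, ten attempts per edge; proposals
that would create a self-loop or a duplicate edge are rejected and count
toward the budget — the swap kernel is compiled and uses R's RNG, so
ensembles are reproducible under a seed). The onset is the smallest
\(k\) with \(\phi_{norm}(k) > 1 + \sigma(k)\) and the members are the
neurons with degree above the onset.

Two documented interpretation choices:

* `sigmaBasis = "normalized"` (default) takes \(\sigma\) as the SD of
  the *normalized* coefficient across the ensemble,
  \(SD(\phi_{rand})/\langle\phi_{rand}\rangle\); `"raw"` uses
  \(SD(\phi_{rand})\) directly. Both readings of the one-sigma band are
  defensible, so both are provided, one flag apart.
* The comparison is strictly greater. A graph whose nulls are frozen
  copies of itself (no legal swap exists, e.g. a star) has
  \(\sigma = 0\) and \(\phi_{norm} \equiv 1\); with `>=` the whole graph
  would count as a rich club, which is the wrong answer for a star.

A caveat the tests make explicit: because the onset scans many \(k\)
levels against a one-sigma band, a degree-homogeneous random graph
crosses the band *somewhere* with appreciable probability. The
normalized curve itself stays near 1 (a property test asserts this);
"no onset ever" is not a property the per-level rule can deliver, and
detection claims in this package are therefore always phrased through
planted ground truth (recovered members must contain the planted hub
set), not through the bare existence of an onset.

The k-grid runs over every integer from 1 to the maximum total degree
minus one.

## Mesoscale structure

Neurons are described by their incoming-connection profiles (the
transposed columns of the weighted aggregate; a flag switches to
outgoing profiles) and embedded in two dimensions, by default with an
exact t-SNE (perplexity 30, Euclidean distance, 500 iterations,
early-exaggeration 12, seed-deterministic; Chebychev, cosine and
Mahalanobis distances are available for the robustness harness, whose
agreement is summarized by pairwise adjusted Rand indices). PCA is the
deterministic alternative and is what the permutation-invariance
property test uses. t-SNE is implemented in the package directly (exact
gradient, no approximation) since the embedding itself is small
(302 points).

The embedding is clustered with density-based clustering (DBSCAN;
`minPts = 5`, `eps` adaptive to the embedding scale by default), so
that low-density points become a first-class *periphery* group rather
than being forced into a cluster: dense connectomes typically show a
few coherent cores plus a diffuse cloud, and density-based clustering
is the design choice that makes the cloud an explicit outcome. `nameCores()` optionally maps the generic clusters onto
semantic names (hubs core = highest median indegree; of the two other
largest clusters the one richer in motor neurons is the motor core).

Group indegrees are compared with a Kruskal-Wallis omnibus test and
Tukey-Kramer-style pairwise comparisons on rank means (studentized
range on the large-sample normal approximation with tie correction;
with two groups this reduces exactly to the two-sided normal-approximate
rank-sum test, which a test asserts).

## Co-expression and autocrine analysis

Every precursor gene x receptor gene combination drawn from the
interaction dataset's gene lists (not only cognate couples) is tested
for co-expression enrichment across the neuron panel with the one-sided
Fisher exact test, computed as the hypergeometric upper tail, followed
by Benjamini-Hochberg FDR control across all tested pairs. Cognate
pairs are flagged. Significant pairs become nodes of a cascade network
with an edge u -> v when u's precursor activates v's receptor at the
active threshold (gene-level rule; a peptide-level flag exists but
coincides at gene granularity).

Because the exact test is discrete its p-values are super-uniform under
independence, so raw p-values cannot be used to check calibration
against a uniform reference. `fisherEnrichment(..., calibrated = TRUE)`
returns the randomized probability-integral-transform p-value, which is
exactly Uniform(0,1) precisely when the implementation's null
distribution is correct; the calibration tests use this form, inference
uses the standard exact p.

A neuron harbors an autocrine loop for a couple when it co-expresses
the couple's two genes. The package reports the per-neuron loop counts,
the fraction of neurons with at least one loop, per-type percentages,
and correlations of loop diversity with degree in any supplied network
(with an optional permutation p-value).

## The synthetic generator

`generateSynthetic()` produces a roster, expression matrix, interaction
table and anatomy that the package readers load unchanged, plus a
ground-truth record. Defaults emulate the scale and statistical shape of
the real inputs, chosen once:

* 302 neurons, ~20 of them pharyngeal, mostly bilateral two-neuron
  classes;
* 55 precursor and 56 receptor genes; per-gene expressing-neuron counts
  are a rounded, clipped log-normal (meanlog log 15, sdlog 1);
* receptor promiscuity 1 + Poisson(1.6) ligands with preferential
  attachment (creating versatile ligands), 1 + Poisson(2.1)
  peptide-level entries per couple, couple-level EC50 log-uniform on
  1 pM..1 mM with 0.3 log10 jitter across a couple's entries. This
  yields around 460 entries, around 150 gene couples and around 60% of
  couples at or below 500 nM, matching the deorphanization screen's
  proportions;
* 27 bundles across three regions (head 60%, midbody 15%, tail 25%),
  four nerve-ring strata, one primary bundle per neuron plus a 0.3
  chance of an extra same-region bundle. The nerve ring is up-weighted
  (weight 10) because most real neurons project into it; uniform bundle
  occupancy would make short-range networks unrealistically sparse.

Planted motifs and what they guarantee:

* **broadcaster / integrative couples** — a fresh couple whose precursor
  (resp. receptor) is expressed in 5 neurons and whose partner in
  max(51, 40% of the roster), so the 50-neuron classification rule must
  fire;
* **rich club** — h hubs placed into a shared nerve-ring stratum and
  wired by cognate couples whose genes are each expressed in random 75%
  hub subsets, with enough couples to reach the target hub-hub density;
  every hub is guaranteed at least one planted ligand and one planted
  receptor, otherwise a hub can be left uncovered by chance and its
  degree is not guaranteed to exceed background. Because hub wiring can
  give a hub at most ~2(h-1) internal degree, the planted-recovery
  experiments run on a sparse background (breadth log-normal(log 3,
  0.5) over 100 neurons, wiring density 0.95) so that the background
  degree tail stays below that cap — this is the regime the planted
  construction is meant for;
* **enriched pairs** — a fresh gene pair expressed in an identical
  neuron subset, plus weak decoy interactions (10 uM) that put the
  genes into the tested universe without creating a cognate couple;
* **autocrine loops** — a fresh cognate couple co-expressed in exactly
  m neurons. Exact-recovery experiments additionally strip chance
  cognate co-expression from the background
  (`excludeBackgroundAutocrine`), a condition that is incompatible with
  a planted rich club (whose wiring is itself cognate co-expression in
  hubs) and is therefore used only in the autocrine experiments.

What the generator does *not* emulate: correlated expression across
related genes, realistic worm gene names or lineages, true bundle
geometry, and class-structured expression (synthetic expression is
sampled per neuron). Passing tests therefore certify the machinery —
construction, filtering, aggregation, metrics, detection — under known
ground truth; they do not certify biological conclusions about real
data, which require the deposited expression, interaction and anatomy
tables.

## Numerical and reproducibility choices

* Every stochastic operation takes an explicit integer seed; the
  pipeline (`runPipeline()`) derives all stage seeds from one master
  seed and reruns are hash-identical (`writeRunReport()` md5).
* Edge-swap budget: 10 x K attempted swaps per null, rejections
  included, with the realized-swap tally attached to each null; an
  unswappable network warns and returns copies.
* Reciprocity of an empty network is undefined and returns NA with a
  warning; transitivity of a triple-free network is 0; density needs at
  least two nodes.
* Analyses at scale: the test-suite and acceptance runs use 60-100
  neuron backgrounds for ensemble-heavy experiments and the full
  302-neuron conditions for single runs; these problem sizes are stated
  here as the package's own choices.

## Known limitations

* The 27-bundle vocabulary of the real anatomy is not shipped; real
  reproductions must load the deposited anatomy tables
  (`loadAnnotations()` accepts any vocabulary).
* The classification threshold (50 neurons) is an absolute count tied
  to the 302-neuron roster; for synthetic rosters of other sizes the
  planted breadths are chosen around it rather than rescaling the rule.
* Cascade-network edges are gene-level; peptide-level granularity is
  exposed as a flag but the connectivity property is only asserted for
  the default.
* Modularity maximization and path-length analyses are deliberately out
  of scope.
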