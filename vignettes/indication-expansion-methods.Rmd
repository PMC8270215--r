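---
title: "Network-based indication expansion: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based indication expansion: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netindic)
```

## The problem and the model

A drug that engages a protein target perturbs not one node but a
neighbourhood of the protein-interaction network; a disease with a
genetic architecture is likewise driven by a *module* of interacting
genes. `netindic` operationalises indication expansion — proposing
diseases a target might treat beyond its approved uses — as a comparison
of two node sets on a shared interactome:

* the **target subnetwork**, the target gene(s) plus the nodes most
  strongly connected to them under network flow propagation, plus their
  direct interactors;
* a **disease subnetwork** per disease, grown outward from its
  genetically associated seed genes by iterative connectivity
  significance.

A hypergeometric test on the overlap of the two sets, adjusted across
the disease family and penalised by the amount of genetic evidence,
yields the final ranking. This vignette records the modelling choices,
the defaults and why they are what they are, and what the synthetic
benchmarks do and do not establish.

## Propagation

Flow scores follow the damped diffusion
$F_t = \alpha A' F_{t-1} + (1-\alpha) F_0$, with $A'$ the symmetrically
degree-normalised adjacency ($A'_{ij} = 1/\sqrt{d_i d_j}$ on edges) and
$F_0$ the indicator of the target set. Symmetric normalisation is chosen
over row-stochastic scaling because it keeps $A'$ symmetric with
spectral radius at most 1, so the fixed point
$F = (1-\alpha)(I - \alpha A')^{-1} F_0$ exists for every
$\alpha \in (0,1)$ and the uniform vector is exactly stationary on
regular graphs — both properties the test suite exercises.
`propagate_exact()` implements the fixed point as a dense solve and
serves as the oracle for the iterative path.

* `alpha = 0.5`: the retention fraction is a genuinely free parameter of
  the method; 0.5 is the conventional middle of the propagation
  literature, balancing locality (small $\alpha$: scores concentrate on
  direct neighbours) against network smoothing (large $\alpha$). Results
  in our benchmarks are insensitive across 0.3-0.8, which the oracle
  tests sweep.
* `tolerance = 1e-6` on the L1 change, `max_iterations = 10000` with a
  warning, not an error, on non-convergence.
* Edge confidence weights do not enter $A'$: after confidence filtering
  the adjacency is binary and only degrees matter. Filtering (strictly
  greater than 0.7 by default, on the 0-1 scale with 0-1000 inputs
  auto-detected) is the place where confidence acts.
* The target subnetwork takes the `top_k = 200` highest-flow non-target
  nodes; ties at the cutoff break lexicographically so runs are
  deterministic. `include_neighbors = TRUE` adds the direct interactors
  of both the targets and the selected nodes (the superset reading of
  "their direct interactomes"); the flag exists so the ablation is one
  argument away.
* Target combinations simply set $F_0 = 1$ on every target; nothing else
  changes.

The workflow is fully deterministic, so repeated runs are a no-op rather
than something to average over.

## Disease modules

Module growth is plain DIAMOnD: each round scores every outside node
with at least one link into the module by the upper-tail hypergeometric
probability of its link count (`deg(v)` draws, module members as
successes, population all nodes except the candidate) and admits the
lowest p-value, breaking ties lexicographically. We deliberately omit
the seed-weighting refinement of the original algorithm: the plain
hypergeometric is the form the ranking below actually relies on, and it
keeps the incremental implementation exactly equivalent to a naive
rescan (the equivalence is tested trace-for-trace). The expansion count
is the module-size dial; 200 is the conventional putative size of a
complete disease module on a ~14k-node interactome, and a sweep over
{100, 150, 200, 250, 300} is one argument. Modules are
target-independent and are therefore computed once per catalog and
shared across targets (`compute_disease_modules()`, plus an optional
content-hash-keyed disk cache in `run_expansion()`); cache hits are
observably identical to recomputation. The grown node set is returned
whole — we do not split it into connected components.

## Enrichment, metric and ranking

The overlap test marks the target subnetwork's nodes in a universe of
all filtered-network nodes and draws the disease module; the universe is
the whole network because both subnetworks are sampled from it. The
family of per-disease p-values is Holm-adjusted (reported in the `fdr`
column). Two decisions were genuinely open:

* **What feeds the metric.** The metric
  $\mathrm{Pval}/\log_2(N+1)$ (with value 1 exactly when
  $\mathrm{Pval}=1$, so unenriched diseases stay at the ceiling
  regardless of evidence) uses the *raw* p-value; the Holm value is
  reported alongside and used for the optional `fdr < 0.05` recovery
  filter in evaluation. Raw-p feeding keeps the metric a per-disease
  quantity rather than one entangled with the catalog's size.
* **The weighted variant.** "Counting each seed gene twice" is
  implemented as a virtual duplication: the disease draw grows by the
  seed count, the observed overlap by the target-seed intersection, and
  the universe by the same seed count. This concrete reading reduces
  exactly to the plain test when no seeds are designated and always
  rewards seed hits over expansion-node hits; it is isolated behind
  `variant = "weighted"` so alternative readings are one function away.

Final ordering is ascending by metric, ties by raw p then disease id;
ranks are dense; the association score is exactly $1/\mathrm{rank}$.
MeSH deduplication happens last, keeping the best-ranked term per MeSH
id and re-ranking densely — the score is recomputed from the new ranks
so the $1/\mathrm{rank}$ invariant survives deduplication.

## Baselines

The genetic baseline sorts diseases by their association score for the
target, 0 when absent, descending; multi-target queries take the maximum
over targets (the natural OR of evidence; verified against per-target
brute force). Proximity baselines use unweighted shortest paths:
*closest* averages each disease gene's distance to its nearest target,
*shortest* averages over all pairs, and *kernel* is the exponential form
$-\tfrac{1}{|T|}\sum_{t} \ln \tfrac{1}{|S|}\sum_{s} e^{-(d(s,t)+1)}$
adopted verbatim from the proximity literature, since "exponential
penalty" alone underdetermines it. Significance comes from
degree-matched random disease-gene sets: nodes are binned by degree,
bins widened until they hold `min_bin_size` candidates (100 at full
scale; smaller in desk-scale runs where 100 would swallow the whole
degree range), and z-scores are computed against `n_random` draws
(1000 at full scale). Diseases are ranked by z-score — the cited
definition of proximity significance — with the raw distance reported
alongside.

## Evaluation

AUROC is the probability that a random true indication outranks a random
non-indication, midrank ties at one half; it is validated against
exhaustive pair counting. Sensitivity at a top fraction uses a ceiling
cut so "top 5%" of a short list is never empty. The random-target
background reruns the entire ranking workflow for targets sampled from a
candidate pool — user-supplied when a druggable-gene list is available,
all network nodes otherwise — and per-target AUROCs are averaged (not
pooled). The recommended shortlist is the top 15% of ranks, flagged in a
column by the pipeline.

## What the synthetic benchmarks emulate — and what they do not

`generate_benchmark()` plants ground truth on a preferential-attachment
graph (chosen for the scale-free, small-world character of real
interactomes): diseases are connected random-walk modules of 20 nodes,
densified by adding missing internal edges with probability 0.3, with
half their members designated seed genes scoring uniform(0.3, 1) —
informative but imperfect, so the genetic baseline has signal without
being an oracle. Positive diseases grow with probability `overlap = 0.8`
per step inside the target's closed neighbourhood; negatives avoid it
entirely; which ids are positive is itself randomised. Default sizes —
500-node networks, 10 diseases, `top_k = 50`, 30 expansion iterations,
100 proximity randomisations, 10 background targets, 10 replicates — are
the package's desk-scale choice: scaled from the full-scale defaults in
rough proportion to the network (50/500 vs 200/14000), large enough for
stable statistics and small enough that the whole suite runs in minutes.

Passing these benchmarks shows the machinery recovers a planted signal
and stays at chance on a null construction. It does *not* show
performance on real data: synthetic modules are cleaner and more
assortative than real disease biology, the degree distribution only
qualitatively matches STRING's, association scores carry no ascertainment
bias, and the ground truth is one planted positive rather than a curated
indication list. Numbers from the benchmark characterise the
implementation, not the biology.

## Numerical and degenerate-input choices

* Hypergeometric tails come from `phyper(k - 1, ..., lower.tail =
  FALSE)`; exactness against enumeration is asserted for all universes
  up to 30.
* All order-dependent steps (propagation cutoff, module admission, final
  ranking) break ties lexicographically; two runs of any workflow are
  byte-identical.
* Empty results fail loudly: an empty post-filter network, a catalog
  with no surviving disease, a disease set unreachable from every
  target, or a candidate pool smaller than the requested sample are
  errors naming the cause; seeds missing from the network are dropped
  with a warning (catalog policy) except in `propagate()`, where a
  missing target is a hard error.
* Disconnected graphs are kept whole — no largest-component restriction
  — and propagation and BFS handle unreachable regions explicitly (zero
  flow; excluded pairs with a logged count).

## Known limitations

Gene identifiers are opaque case-sensitive strings: no symbol mapping,
no MeSH ontology traversal beyond key-based deduplication, no download
clients for STRING or DisGeNET. The weighted variant encodes one reading
of seed doubling. The druggable-target pool defaults to all network
nodes when no curated list is supplied, which makes the random
background slightly harder than a true druggable background. Module
detection offers DIAMOnD only; alternative detectors and alternative
node prioritisers were considered out of scope after benchmarking
elsewhere favoured propagation.
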