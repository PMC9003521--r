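---
title: "Simulating cluster-based image annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cluster-based image annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustersim)
```

## The annotation model

Large image collections — plankton imagery is the motivating case — are
annotated far faster when the expert judges *groups* of similar images
instead of single ones. The workflow this package simulates has three
repeating phases acting on deep image representations (an `n x d` feature
matrix, typically `d = 32` after PCA):

1. **Clustering.** A clusterer proposes candidate clusters. It need not
   partition the data: only the densest regions should be labelled, because
   everything it proposes will be judged by a human.
2. **Validation.** The user accepts a candidate if its *purity* — the
   fraction of members sharing the majority label — reaches the validation
   threshold `t_v` and removes the visible mismatches; impure candidates
   are deleted outright. Every removed or deleted object keeps a record of
   the cluster it did *not* belong to (the rejection matrix `R`, a sparse
   boolean object-by-cluster relation).
3. **Growing.** Each accepted cluster is extended: all unclustered objects,
   ordered by distance to the cluster centroid, are cut into batches (50
   objects per judged page). Batches are visited by *exponential search* —
   probe positions 1, 2, 4, 8, ... then binary search between the last
   fitting and first non-fitting probe — so that long fitting prefixes are
   absorbed after only `O(log b)` judgements. A probed batch with purity at
   least `t_gp` fits wholesale; below `t_gu` it is rejected and bounds the
   search; in between, the mismatches are removed individually and the
   search drops to linear scanning.

The simulator replaces the human with a threshold oracle on the
gold-standard labels and counts every interaction as a **click**:
one per cluster decision, one per probed batch, one per individually
removed object. Efficiency is then *objects sorted per click*; the other
run metrics are completeness (assigned fraction), unweighted mean
per-cluster precision, and the final cluster count.

A deliberate property of the exponential/binary phase is that batches
*inside* the accepted region that were never probed join the cluster
unexamined. This is where the workflow trades a little precision for a
large efficiency gain, and it is the only mechanism by which a foreign
object can enter a cluster: a probed batch with purity in `[t_gp, 1)` is
accepted whole, mismatches included. The parameter guidance below follows
from this.

Thresholds default to `t_v = 0.85`, `t_gp = 0.75`, `t_gu = 0.55`,
`batch_size = 50`, the operating point of the interactive application the
simulator mimics. Acceptance is inclusive (`purity >= t_v`), so a 17/20
cluster passes at 0.85. Growing restarts with a recomputed centroid when a
cluster more than doubles (`regrow_trigger = 1`, at most `max_regrows = 2`
restarts) — the restart rule is a bounded reading of "recalculate after a
number of objects were added". Runs stop at `completeness_stop = 0.99`,
after `max_iterations = 12`, or when an iteration assigns nothing new.

## The clusterers

**Shrunken k-means** (`shrunken_kmeans()`): plain Lloyd k-means (k-means++
seeding, empty clusters re-seeded with the point farthest from its
centroid), after which each cluster of size `m` is reduced to its
`max(1, ceiling(p_core * m))` members closest to the centroid (ties broken
by object id; the floor of 1 prevents cluster annihilation). With
`p_core = 1` it *is* k-means — a tested identity.

**Partially labeled k-means** (`pl_kmeans()`): the same engine, but the
expectation step freezes the members of already-validated clusters
(positive information) and skips rejected clusters when assigning free
objects (negative information from `R`); an object rejected everywhere
stays unassigned. The maximisation step uses only the `1 - p_noise`
fraction of members closest to the *previous* centroid, making the update
robust to stragglers. The cluster count follows the schedule
`k0 + iteration * k_delta`, so later iterations hunt smaller structures.
After convergence only the newly formed clusters are shrunken; validated
clusters are returned intact, possibly enlarged by "late assignment" of
previously unclustered objects. Those late additions are re-reviewed at
the next validation step (one click per touched cluster plus one per
removed addition), which keeps every validated cluster pure and the click
ledger well defined. Convergence is declared when no assignment changes,
or after `max_iter = 100` Lloyd steps.

**HDBSCAN\*** (`hdbscan_candidates()`): an adapter around the scikit-learn
implementation with *leaf* cluster selection, which yields fine-grained,
homogeneous clusters and leaves low-density points unassigned. Defaults
are a core-distance neighborhood of `neighborhood_k = 8` and an initial
minimum cluster size `m0 = 128` that decays by `decay_factor = 0.5` per
iteration (floored at 2), so later iterations can still extract clusters
from a shrinking pool. Halving reaches the floor in about `log2(m0)`
iterations; no other decay constant is privileged. The adapter exchanges
plain CSV with a bundled Python helper, so a `python` with scikit-learn
must be on the PATH.

Large-data defaults (`k = 1000`, `p_core = 0.01`; `k0 = 500`,
`k_delta = 100`, `p_noise = 0.1`) suit collections of around a million
objects. For desk-scale experiments set `k` near the expected class count.

## The synthetic generator

`generate_embeddings()` emulates exactly the premise a good representation
space is supposed to satisfy: dense, well-separated, spherical classes of
equal (unit) variance. Class centers are drawn from a standard normal and
rescaled so the *minimum* pairwise center distance equals
`separation` standard deviations — separation is a controlled parameter,
not an accident of sampling. Options add class imbalance (vector
`objects_per_class`), diffuse uniform background noise with singleton gold
labels (drawn from the center bounding box inflated by two standard
deviations, so density-based clustering and shrinkage have something to
leave unclustered), and sub-class structure: a fraction of classes is
split into two half-separated Gaussians labelled `<class>/a` and
`<class>/b`, which reproduces the completeness penalty of interchangeable
labels — the simulator insists on the exact gold label even where a human
would accept the sibling. PCA (`pca_reduce()`) is unwhitened: whitening
would distort the Euclidean geometry every downstream step relies on.

What the generator does *not* model: anisotropic or heavy-tailed classes,
class-dependent scale, manifold structure, or the label noise of real
expert annotations. Passing tests on this generator therefore demonstrates
the correctness of the machinery and the behaviour of the workflow in its
idealised regime, not performance on real imagery.

## Parameter guidance at small scale

Because a probed batch with purity in `[t_gp, 1)` is accepted whole, the
single batch that straddles a class boundary is the precision risk: with
class size `s`, retained core `ceiling(p_core * s)` and batch size `B`,
the straddling batch contains `r = (s - core) mod B` own objects, and
foreign objects slip in exactly when `r / B >= t_gp`. Choosing `p_core`
(or `B`) so that the core plus whole batches tile the class —
e.g. `p_core = 0.5` at `s = 100`, `B = 50`, or `p_core = 0.1` at
`s = 500` — makes the boundary batch purely foreign, which the oracle
rejects, and precision stays at 1. At realistic scale (`s >> B`) the
straddling batch is a vanishing fraction of the class and precision stays
above 95% for any sensible `p_core`; the effect only needs attention in
small benchmarks.

## Numerical choices

* Distances are squared Euclidean throughout; the cross-product form is
  clamped at zero to absorb cancellation error.
* Nearest-centroid ties resolve to the lowest cluster index; distance ties
  in shrinkage and candidate ordering resolve by ascending object id. All
  randomness flows through explicit integer seeds (`withr::with_seed`), so
  every function is a pure function of its inputs and seed.
* Degenerate inputs are handled, not hidden: `k` is clamped to the pool
  size with a warning, an object rejected for every cluster stays
  unassigned, a pool smaller than the minimum cluster size yields no
  candidates, and singleton gold classes go wholly to the training side of
  a stratified split with a warning.
* Cluster ids are never reused across a simulation; rejection records
  referring to deleted clusters are retired with them.

## Problem sizes used in the tests

The test-suite runs complete at desk scale: property checks use a few
hundred objects; the end-to-end recovery runs use 20 classes of 100
objects (`d = 32`, separation 10) for all three clusterers, and the
headline efficiency/precision run uses 20 classes of 500 objects, where
the simulator sorts the 10,000 objects at about 44 objects per click with
mean per-cluster precision above 99% and full completeness. The same run
is what `scripts/acceptance.R` recomputes from scratch.

## Known limitations

* The simulated user is a noiseless threshold oracle; human inconsistency,
  fatigue and the final naming/hierarchy step are out of scope.
* The rejection relation is only consulted for clusters that still exist;
  pairwise (object-object) constraints are not modelled.
* `pl_kmeans` inherits k-means' preference for spherical clusters; on
  elongated classes the shrunken core can be off-center.
* The HDBSCAN* stage requires an external Python runtime; the two k-means
  variants are pure R.
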