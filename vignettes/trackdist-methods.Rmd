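---
title: "Clustering genomic tracks: models, parameters and design choices"
author: "trackdist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering genomic tracks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackdist)
library(GenomicRanges)
library(GenomeInfoDb)
```

## The model

A reference genome is treated as a line of `N` positions (chromosomes
concatenated in the order given by the `chrom.sizes` file). A genomic track
is a set of points or segments on that line — peak calls, occupancy domains,
SNP sets — and is formally the binary occupancy vector `V` of length `N`,
with `V[i] = 1` exactly where some element covers position `i`. `trackdist`
never materializes `V`: every quantity below is computed on the sorted,
merged interval list that induces it, so cost scales with the number of
elements, not with genome size.

Two modelling consequences follow from the binary-vector view:

* **Within-track multiplicity carries no information.** Overlapping or
  abutting records are merged on load. The *number* of original records is
  retained separately (`elementCount`) because count-based aggregation is
  about elements, not covered positions.
* **Points are 1-bp segments.** File formats differ on conventions (BED is
  0-based half-open, GFF 1-based inclusive); internally everything is
  converted to one convention at the file boundary, and a GFF record with
  `start == end` becomes a single covered position.

Validation is deliberately strict: records on unknown chromosomes, records
running past a chromosome end, and zero-length BED records are errors rather
than silently clipped or dropped. These almost always indicate a mismatch
between the track's genome build and the `chrom.sizes` in use, and clipping
would mask that.

## Three notions of track similarity

**Direct (base-pair) similarity.** The Jaccard index of the two covered
position sets, `|A ∩ B| / |A ∪ B|`, converted to the distance `1 − J` for
clustering. Normalization is built into the measure, so tracks of very
different total coverage compare sensibly. Empty tracks are rejected: their
similarity to anything is the constant 0, and the similarity of two empty
sets is undefined.

**Positional distribution.** The genome (or a restricted extent) is tiled
left-to-right into bins of a fixed width; the last bin of each region is
shorter when the width does not divide the region and is *kept* — dropping
or rescaling it would lose coverage mass and break the row-sum invariant
below. Each track becomes the vector of per-bin aggregates, with two
aggregations:

* `coverage` — covered base pairs in the bin;
* `count` — number of original elements whose *start* lies in the bin.
  Start-assignment makes the assignment of boundary-spanning elements
  unique, so counts over a genome partition sum exactly to the track's
  element count.

Under `relative` normalization each row is divided by the track's
genome-wide total (total coverage or total element count). Over a
genome-tiling bin set every relative row therefore sums to 1 and is the
track's positional probability distribution; this is what makes tracks with
different overall densities comparable and is the default.

**Relations to reference tracks.** Feature `j` aggregates the track over the
(possibly non-contiguous) positions covered by reference track `j` — gene
sets of a functional category, chromatin-state domains, etc. This
generalizes binning (a bin is just a single-interval reference), and the
implementation guarantees the consistency: reference features over
single-bin references are identical to bin features. Two deliberate choices:

* Reference tracks may overlap one another; functional categories do, and
  features are not required to be independent.
* `relative` normalization divides by the *genome-wide* track total, exactly
  as in the bin case — not by the total inside the union of references — so
  the two feature types are on the same scale.

A row of zeros (a track disjoint from every reference) is legitimate data;
only a zero *genome-wide* total makes a relative row undefined and is an
error naming the offending track.

**Valued (Function-type) tracks.** Tracks assigning a numeric value to every
base pair (stored sparsely as steps; uncovered positions are 0, making any
bedGraph a total function) extend the model: mean value replaces count as
the aggregation, and the per-base-pair Pearson correlation over a region set
replaces the Jaccard index as the direct measure. The correlation is
computed from sums over step fragments in one sweep; a track that is
constant over the regions has no defined correlation and raises a distinct
degenerate-input condition.

## Distances and clustering

Feature vectors are compared with euclidean, manhattan or maximum distance
(`stats::dist` underneath). All pairwise distances are assembled once into a
full symmetric matrix with zero diagonal; clustering consumes only this
matrix. This architecture is what allows base-pair-resolution similarity for
genomes of any size — the clusterer never sees a feature vector — at the
cost of excluding algorithms that need explicit centroids (k-means and
friends).

Agglomerative clustering is implemented with Lance–Williams updates.
Average linkage is the default and is the *size-weighted* UPGMA mean — the
distance between two clusters equals the mean of all pairwise object
distances between them, which is robust to outliers — not the unweighted
WPGMA variant. For average, single and complete linkage merge heights are
non-decreasing, so the dendrogram is well-formed.

Determinism is pinned down explicitly, because generic library
implementations leave it unspecified:

* among pairs at the minimal distance, the pair with the lexicographically
  smallest `(smaller id, larger id)` merges first;
* the two children of a merge are ordered by their smallest leaf index,
  which fixes the drawn leaf order and makes it permutation-equivariant.

The same distance matrix therefore always yields the same tree, bit for
bit — the foundation of the replay guarantee below.

**Subcluster cuts.** `cutByHeight(h)` severs every merge with height `≥ h`
(strict survival `height < h`), so a cut at 0 gives singletons and a cut
above the root gives one cluster; `cutByK(k)` undoes the last `k − 1`
merges. With strict survival the two are exactly equivalent: `cutByK(k)`
equals `cutByHeight` at any height in the gap between the `(n−k)`-th and
`(n−k+1)`-th merge heights. Labels are numbered `1..k` in drawn leaf order.

**Newick export** writes branch lengths as parent merge height minus child
merge height (leaves at height 0), so every root-to-leaf path length equals
the root height; names containing Newick metacharacters are single-quoted.

## The synthetic benchmark

`generateGroupTracks()` emulates the situation the method targets: replicate
occupancy tracks from the same biological condition share most of their
peaks up to small positional shifts, while different conditions occupy
disjoint parts of the genome. Per group an *archetype* segment set is drawn
uniformly without overlap (across all groups); each member track keeps each
archetype segment with probability `keepProb`, displaces its start by a
rounded `Normal(0, jitterSd)` offset (length preserved, clipped to the
chromosome — jitter models the "peak at `i` vs `i + 1`" problem that
motivates binning), and adds `noiseSegments` uniformly placed extra
segments.

Defaults — 3 groups × 4 tracks, 20 archetype segments of 1000 bp,
`jitterSd = 50` (1/20 of the segment length), `keepProb = 0.95`, 1 noise
segment (5% of the archetype count) — describe well-separated groups with
realistic replicate-level noise: within-group Jaccard similarity ≈ 0.7,
between-group ≈ 0. On a 2 Mb two-chromosome toy genome (the scale used
throughout the test suite, chosen so every pipeline stage runs in seconds)
all three canonical cases recover the planted partition exactly at `k = 3`.
A single integer seed drives one pseudo-random stream consumed in a fixed
order, so generation is byte-deterministic; the caller's RNG state is saved
and restored.

What the generator does *not* emulate: read-level noise, peak-caller
artifacts, signal strength, chromatin-state correlation structure, or the
heavy-tailed segment-length distributions of real occupancy data. Passing
recovery tests on this benchmark shows the pipeline is correct and that the
three similarity notions behave as designed — not that any particular real
data set will cluster cleanly.

One instructive construction the benchmark makes exact: two tracks that
occupy the *same bins* but complementary halves of each bin have positional
(case-2) distance 0 and base-pair (case-1) distance 1. Bin-level
co-clustering does not imply base-pair co-clustering; the converse
implication does hold approximately, since tracks overlapping at base-pair
level necessarily share bins.

A related observation from the benchmark: swapping euclidean for manhattan
distance leaves the recovered group structure unchanged (the `k = 3`
partitions are identical), but the *within-group* merge order may differ —
within a group the pairwise distances are near-ties, and different metrics
resolve near-ties differently. Claims of metric-robustness are therefore
claims about the coarse structure of the dendrogram, not about its exact
shape.

## Runs, batch configs and replay

`runDirect()`, `runPositional()` and `runReference()` execute one case end
to end from a declarative configuration (YAML on disk): read genome and
tracks, optionally clip to a region extent (a chromosome list or a BED
file), extract features, build the distance matrix, cluster, cut, and write
TSV/Newick outputs plus a `run_config.echo`. The echo omits the output
directory, and every writer is deterministic (fixed key order, full-precision
numbers via the shortest round-tripping decimal representation), so
replaying an echo into a fresh directory reproduces every output file byte
for byte. The CLI script (`exec/trackdist`) is a thin flag parser over these
functions; every error path exits non-zero with a single-line reason.

## Numerical and degenerate-input choices

* Overlap coverage between two merged interval sets is computed from a
  single overlap join (`sum(min(ends) − max(starts) + 1)` over overlapping
  pairs); union coverage by inclusion–exclusion. Exact integer arithmetic —
  the per-base-pair oracle tests assert equality, not tolerance.
* Relative rows over genome-tiling bins sum to 1 up to double rounding
  (asserted at `1e-9`).
* The UPGMA Lance–Williams update is algebraically exact for size-weighted
  average linkage; the test suite checks it against a naive agglomerator
  that recomputes all object-pair means at every step, to `1e-12`.
* Pearson correlation declares a track constant when its variance term falls
  below `1e-12` times the magnitude of its sums, rather than dividing by a
  numerically meaningless denominator.
* Archetype placement retries bounded times (1000 per segment) and fails
  loudly if the genome is too crowded; the constructor additionally rejects
  specs demanding ≥ 50% of the genome.

## Limitations

* Only point/segment and stepwise-valued tracks are supported; no BigWig /
  BigBed, no strand, no per-element scores.
* The clusterer is quadratic-time in the number of tracks per merge step
  (cubic overall), appropriate for the tens-to-hundreds of tracks the
  distance-matrix design targets, not for thousands.
* The only direct (case-1) measure is Jaccard; correlation-type direct
  measures exist only for valued tracks.
* Heat-map rendering is left to the caller: the contract is the leaf-ordered
  feature matrix plus the leaf order, which drop directly into
  `pheatmap`/`ComplexHeatmap`.
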