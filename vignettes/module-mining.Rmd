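---
title: "Mining co-expression network modules with NMRS"
author: "modminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining co-expression network modules with NMRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modminer)
```

## The problem

A gene co-expression network represents genes as vertices and joins two
genes by an edge when their expression profiles across conditions are
sufficiently similar. Densely interconnected vertex sets of such a network
— *network modules* — tend to collect functionally related genes, and are
therefore a standard route from a microarray-scale expression matrix to
functional hypotheses. `modminer` implements the full path: a pairwise
similarity tailored to *shifting patterns*, hard thresholding into an
unweighted network, topological-overlap-guided module extraction, and
hypergeometric enrichment of the resulting modules.

## The NMRS similarity

Two genes whose profiles differ only by an additive constant across all
conditions (a shifting pattern) are biologically co-expressed: the shapes
coincide, only the baseline differs. The normalized mean residue
similarity centers each profile by its own mean,
\(\tilde x = x - \bar x\), and scores

$$\mathrm{NMRS}(x, y) \;=\; 1 -
  \frac{\sum_i |\tilde x_i - \tilde y_i|}
       {\sum_i \left(|\tilde x_i| + |\tilde y_i|\right)}.$$

The ratio is at most 1 by the pointwise triangle inequality, so the score
always lies in \([0, 1]\) (a numeric clamp guards rounding only, and
announces itself once per session if it ever fires). The measure is
symmetric, needs no prior normalization of the profiles, equals 1 exactly
for shifting patterns, and equals 0 when the centered profiles are exact
negations — a shifted, perfectly anti-correlated pattern. If both profiles
are constant they are mutual shifts and score 1; if exactly one is
constant the formula yields 0.

The packaged worked example (`pattern_family()`) shows what sets NMRS
apart from the classical measures. Pattern `a` is a 9-condition profile,
`b1 = a + 6` its shifted copy, `b8 = 17 - a` its shifted negation, and
`b2`..`b7` interpolate uniformly between `b1` and `b8`. Every interpolant
is an affine transform of `a`, so Pearson correlation is ±1 across the
whole family and rank correlation likewise saturates, while NMRS decays
from 1 through 5/6, 3/5, 1/4 to 0:

```{r family}
pats <- pattern_family()
round(apply(pats[paste0("b", 1:8), ], 1, nmrs, x = pats["a", ]), 4)
round(apply(pats[paste0("b", 1:8), ], 1, pearson_cor, x = pats["a", ]), 4)
```

`measure_table()` summarises the qualitative contrasts (mutual vs.
aggregate operation, normalization requirements, shifting/scaling
detection) among NMRS, Euclidean distance, Pearson, Spearman and the mean
squared residue; `msr()` is the aggregate residue score that NMRS turns
into a mutual, bounded measure.

### How far `1 - NMRS` is from a metric

`1 - nmrs(x, y)` is nonnegative, symmetric, and zero precisely for mutual
shifts, but it is **not** a metric: for very short profiles the triangle
inequality can fail. A concrete length-3 counterexample:

```{r triangle}
x <- c(0.3, 1.0, 1.9)
y <- c(-3.8, 1.1, -0.1)
z <- c(-3.1, 2.6, -0.1)
(1 - nmrs(x, y)) + (1 - nmrs(y, z)) - (1 - nmrs(x, z))  # negative slack
```

This is intrinsic: any shift- and scale-invariant alternative that *would*
satisfy the triangle inequality exactly would also collapse the strict
decay along `b2`..`b4` above, since those are positive scalings of the
centered reference. At realistic condition counts the failure is
irrelevant in practice — the package's property suite checks
\(10^4\) random triples at the worked example's nine conditions and finds
no violation, and violations were likewise absent in larger sweeps at
\(m \ge 9\). Nothing in the module-mining pipeline relies on metricity;
the similarity is only ever thresholded.

## From similarity to network to regions

`similarity_matrix()` evaluates the measure on each of the
\(n(n-1)/2\) unordered pairs and mirrors the triangle;
`threshold_network()` applies the signum hard threshold: an edge joins two
distinct genes when their similarity reaches a user-chosen
\(\delta \in [0, 1]\). The threshold is deliberately a required argument —
it is the method's one real tuning knob, trading edge density against
specificity, and has no universal default. Boundary pairs (similarity
exactly \(\delta\)) are included; `strict = TRUE` excludes them for users
who prefer a strictly-greater rule. The graph is simple: no self-loops,
so that degrees downstream count neighbours only.

`connected_regions()` partitions the network into maximal connected
components of at least two vertices (igraph supplies the traversal);
isolated genes are reported separately and never modularized.

## Module extraction

Within a region, the *topological overlap* of two vertices combines
direct adjacency with shared neighbourhood:

$$\mathrm{TOM}_{ij} = \frac{l_{ij} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}},$$

with \(l_{ij}\) the number of shared neighbours and \(k_i\) the degree.
It lies in \([0, 1]\), and equals 1 exactly when one vertex's closed
neighbourhood contains the other's. The diagonal is defined as 1 for
completeness; no edge computation uses it.

`extract_modules()` then splits recursively. A candidate vertex set
(initially the region) is scored by its **average TOM** over all pairs.
Its TOM-weighted maximum spanning tree (Prim's algorithm run for maximum
weight, restricted to edges that exist in the region) is cut at its
weakest edge, giving two subtrees. Each child's average TOM is recomputed
on its own induced subgraph — a split child is a fresh connected region.
The acceptance rule is a look-ahead: **a set is emitted as a module when
no single weakest-edge split raises the average TOM of either child above
the parent's (within a tolerance of 1e-12); otherwise both children
re-enter the queue**. Two-vertex sets cannot split and are emitted;
anything below `min_size` is discarded with a log message.

This particular acceptance rule was a genuine design choice. The obvious
alternative — emit a child as soon as its average TOM reaches its
parent's — shatters perfectly homogeneous regions: a clique has average
TOM 1, every split child also has average TOM 1, and the recursion would
peel off vertices instead of returning the clique whole. The look-ahead
rule keeps homogeneous regions intact (a clique never splits, because no
split *improves* it) while still separating two cliques joined by a
bridge, whose TOM is low on both sides of the bridge edge. The predicate
is isolated in one internal function (`split_or_accept()`) so alternative
rules can be swapped in.

Determinism is enforced throughout: Prim tie-breaks choose the smallest
(source index, target index) among equal-weight frontier edges, the
weakest-edge rule breaks ties by (weight, smaller endpoint, larger
endpoint), children are processed smaller-first, and identical inputs
yield byte-identical outputs.

Defaults: `min_size = 4` — below four genes an "interconnected set" is
barely distinguishable from a single edge, and enrichment of pairs or
triples is rarely interpretable; discarded sets are logged, never
silently dropped. Regions that never satisfy the acceptance rule keep
splitting until they either satisfy it or reach two vertices, at which
point they are emitted subject to `min_size`.

## Enrichment

`enrich_module()` scores a module of effective size \(n\) (genes found in
the annotation universe; misses are logged and excluded) against each
category of \(f\) genes in a genome of \(g\) by the upper-tail
hypergeometric probability of observing \(k\) or more annotated members,
delegated to `stats::phyper`, whose log-space tail evaluation is accurate
far below double-precision underflow of the naive sum. Benjamini-Hochberg
q-values (`stats::p.adjust`) are computed per module across all
categories tested — zero-overlap categories contribute p = 1 to the
family — and the report keeps categories with \(k \ge 1\), by default
filtered at a q-value display cutoff of 0.1. The genome size defaults to
the size of the union of all category sets and should be overridden when
the annotated genome is larger than the catalog's universe.

## The synthetic generator

`generate_synthetic()` builds the ground-truth data used to validate
recovery: each implanted module is one template profile (uniform baseline
on \([2, 10]\), a log-intensity-like scale) plus a per-gene constant
shift (uniform on \([-4, 4]\)) plus i.i.d. Gaussian noise; background
genes are independent uniform profiles. Defaults — 20 conditions, modules
of 10 and 15 genes, 20 background genes, noise sd 0.1 — emulate a small
microarray study. At noise 0 module members are exact mutual shifts
(within-module NMRS exactly 1); at noise sd 0.1 within-module NMRS
concentrates near 0.97 while independent background pairs sit near 0.3,
so a threshold of 0.95 cleanly separates structure from noise.

What the generator does *not* emulate: scaling (multiplicative) patterns,
correlated or heteroscedastic noise, missing values, and background genes
with partial co-expression. Passing recovery tests therefore demonstrate
that the pipeline recovers additive-pattern modules under independent
Gaussian noise — not that it resolves overlapping or scaled structure in
real arrays.

## Validation choices and problem sizes

The test suite pins the worked-example values exactly, then checks each
computational core against an independent brute-force oracle: TOM against
a literal triple-loop evaluation on 100 random graphs of up to 20
vertices; the maximum spanning tree against exhaustive enumeration of all
spanning trees on 50 random weightings of graphs with up to 6 vertices;
the hypergeometric tail against full subset enumeration for every
feasible \((k, n, f, g)\) with \(g \le 12\). Measure properties
(symmetry, shift invariance, bounds, monotone decay, the triangle
spot-check) run on \(10^4\) randomized profiles or triples at nine
conditions. Recovery runs 20 replicates per noise level of the default
two-module design at \(\delta = 0.95\), requiring exact recovery at noise
0 and Jaccard \(\ge 0.9\) per implanted module at noise sd 0.1. These
sizes keep the oracles exhaustive where exhaustiveness is the point and
the randomized suites large enough to expose rare failures.

## Known limitations

* Hard thresholding discards the magnitude of supra-threshold
  similarities; soft (weighted) variants are out of scope.
* The module boundary depends on the reconstruction of the acceptance
  rule described above; alternative readings would move boundaries in
  heterogeneous regions (homogeneous cliques and bridge separations are
  stable across readings).
* `1 - NMRS` is not a metric for very short profiles (see above); with
  fewer than ~6 conditions, threshold choices inherit that fragility.
* Enrichment treats categories as flat sets: no ontology-graph
  propagation, and the multiple-testing family is per module, not global.
* Dense matrices throughout: intended for the microarray regime
  (hundreds to a few thousand genes), not single-cell scale.
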