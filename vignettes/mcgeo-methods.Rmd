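---
title: "Markov-cluster community distances and their geochemical correlates: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov-cluster community distances and their geochemical correlates: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Shotgun metagenomes describe whole microbial communities as bags of
protein sequences. To compare communities *as wholes* -- rather than
through a fixed annotation vocabulary such as Pfam or KEGG -- mcgeo
clusters the pooled proteins of all samples by homology and treats the
resulting Markov clusters as the community's units of comparison.
Because homology clusters track evolutionary relatedness beyond
functional categories, the sharing pattern of clusters between two
metagenomes measures their whole-community evolutionary distance. The
second half of the package relates that distance, and three biodiversity
counts, to the geochemistry of the sampled sites: which environmental
gradients (temperature, pH, dissolved ions) covary with community
divergence?

## The pipeline, stage by stage

### 1. Homology graph

Every protein pair is scored with exact Smith-Waterman local alignment
(BLOSUM62, affine gaps, opening 11 and extension 1; residues outside the
20-letter alphabet are mapped to a score-neutral `X`). Raw scores are
converted to expectation values with the Karlin-Altschul formula

$$E = K \, m \, n \, e^{-\lambda S},$$

with the ungapped BLOSUM62 constants $K = 0.134$, $\lambda = 0.3176$ and
$m = n$ the total residue count of the pooled dataset. A graph edge is
kept where the best E-value of a pair is *strictly* below the threshold
(default $10^{-40}$); the edge weight is $\min(-\log_{10} E,\ 200)$, the
standard log-transform recipe for feeding E-values to Markov clustering,
with the cap bounding the dynamic range and absorbing $E = 0$.
Externally computed hits in the common 12-column tabular format can be
substituted for the internal aligner; reciprocal hits keep the smaller
E-value so the graph is symmetric either way. Within-sample and
between-sample edges are both kept, since cluster sharing depends on
both.

Two conventions deserve note. The strict inequality at the threshold is
a choice (a hit exactly at the cutoff is discarded) and is exposed as
configuration. And internal E-values use our own $m,n$ convention, so
they differ numerically from any particular search engine's; only the
thresholded topology matters downstream.

### 2. Markov clustering

MCL is implemented from scratch: the weighted adjacency matrix gains a
self-loop per node equal to its maximum incident edge weight (isolated
nodes get 1) -- the standard default, which also prevents period-2
oscillation -- and is column-normalised. Iterations alternate
*expansion* (matrix squaring: two random-walk steps) and *inflation*
(entry-wise power $r$ with renormalisation, entries below $10^{-6}$
pruned first) until the largest entry change falls below $10^{-8}$ or
200 iterations pass (a non-converged run warns and returns best-effort
clusters). Hard clusters are read off the limit matrix: attractors are
the nodes with nonzero diagonal, attractor systems are merged along
nonzero entries, and every other node joins the system holding its
largest limit-matrix entry, with ties resolved toward the cluster
containing the smallest node id, so the output is fully deterministic.

The default inflation is 1.2 -- deliberately coarse, so that distant
homologs stay in one cluster when whole metagenomes are compared.
Because expansion and inflation act blockwise on a block-diagonal
matrix, the implementation decomposes the graph into connected
components and iterates per component; this is algebraically identical
to whole-matrix iteration (components can never merge) and is asserted
against whole-matrix runs in the tests. Dense matrices are used below
2000 nodes, sparse ones above. The pruning threshold and tolerance were
fixed once so that toy graphs converge in well under 100 iterations at
inflation 1.2; they are exposed but not meant to be tuned per dataset.

### 3. Community distance

A cluster is *present* in a sample if at least one member protein
originates from it. The dissimilarity between two samples is binary
Jaccard over their cluster sets,

$$d(A, B) = 1 - \frac{|A \cap B|}{|A \cup B|},$$

0 for identical cluster complements and 1 for disjoint ones. The
description "shared clusters divided by the total number of clusters in
the pair" admits a second reading with $|A| + |B|$ in the denominator;
the union reading is used because it is the standard binary Jaccard and
is the only one that actually reaches 1 for disjoint sets, matching the
stated endpoints. Jaccard dissimilarity is a metric; the triangle
inequality is verified exhaustively on random presence matrices in the
tests.

The dissimilarity matrix is converted to a dendrogram with Saitou-Nei
neighbor joining, implemented in-package so its determinism is pinned:
Q-criterion ties break toward the lexicographically smallest label pair
(merged nodes carry their smallest leaf label). Negative branch lengths
are kept as computed -- the behaviour of the classic PHYLIP NEIGHBOR
program -- with an optional clamp mode that zeroes a negative branch and
moves the deficit to its sister so the joined pair's path length is
preserved. NJ is consistent on additive matrices; the tests assert
exact (1e-9) recovery of generating trees and agreement with an
independent NJ implementation. The community distance between two
metagenomes is then the *patristic* distance: the total branch length
along the path between their leaves.

An unrooted dendrogram orders its leaves only up to rotations at
internal nodes, so `leaf_order()` defines the canonical reading used
when dendrograms are compared to a gradient: leaves sorted by patristic
distance from one end of the tree diameter.

### 4. Multivariate statistics

Per-parameter geochemical distances are absolute differences between
sites. Mantel tests correlate two distance matrices over their
$n(n-1)/2$ site pairs (Pearson), with significance from jointly
permuting rows and columns of the second matrix; the one-sided p-value
uses the +1 correction, $p = (\#\{r_{perm} \ge r_{obs}\} + 1)/(B + 1)$,
with $B = 1000$ permutations by default. The permutation null is
calibrated: across independent random matrix pairs the rejection rate at
$\alpha = 0.05$ sits inside binomial bounds (asserted in the acceptance
tests against an independent implementation's convention).

PCA is the eigendecomposition of the covariance (`scale = FALSE`) or
correlation (`scale = TRUE`, default) matrix of the site-by-parameter
table. The default follows ordination-with-scaling practice, since
geochemical parameters live on incommensurate scales; both modes are
available because survey texts describe the same analysis sometimes as
"covariance" and sometimes as scaled. Loading signs are fixed so each
column's largest-magnitude entry is positive. `cor_pca()` runs the same
decomposition directly on a *published* correlation matrix when raw
measurements are unavailable -- this is how the shipped twenty-variable
hot-spring table is ordinated; note that a table printed to 2 decimals
perturbs the spectrum by about a percentage point. Overall geochemical
distance between sites is Euclidean distance in (PC1..PCk) score space,
k = 3 by default. Missing values are handled pairwise-complete for
correlation matrices (maximising data use in sparse surveys) and
listwise for PCA (keeping the decomposition well-defined).

### 5. Diversity metrics

Three counts per metagenome: genus count (distinct genera among best
reference hits at the strict E-value bar, after excluding low-abundance
genera), EC count (distinct EC numbers hit by at least two proteins),
and Markov cluster count (the presence-matrix column sum). "Retaining
genera within the 80th percentile of total hits" is ambiguous; the
default reading keeps the smallest set of dominant genera covering 80%
of assignments (which is what "excluding genera with very low counts"
wants), and a per-genus-count-quantile alternative is available. The
counting rules are database-agnostic: any annotated reference FASTA
(headers `genus=... ec=...`) works, and full-scale reference databases
are explicitly out of scope.

## The synthetic generator

`simulate_geochem()` and `simulate_families()` generate data with the
statistical structure the analysis assumes, so every stage is testable
offline and parameter recovery is measurable against known truth.

Geochemistry: all parameters are drawn jointly from a multivariate
normal whose correlation matrix defaults to the shipped twenty-variable
hot-spring table (marginally indefinite from 2-decimal rounding; it is
repaired once by projection to the nearest correlation matrix). Gradient
parameters -- by default temperature spanning 56.1-92.1 degrees C, the
span of a well-studied alkaline hot-spring outflow -- are rank-mapped
onto their exact gradient values, and sites are ordered along the first
gradient so `S1..Sn` is the true gradient order.

Families: each of 300 ortholog families (default) gets a random
ancestral sequence of 100-140 residues, a genus and usually an EC label,
and a Gaussian niche: presence at environmental distance $d$ from the
niche optimum has probability $e^{-d^2/2\sigma^2}$ plus a small
background rate (defaults $\sigma = 0.25$ in normalised gradient units,
background 0.02). Present copies mutate the ancestor with per-residue
substitution probability $\min(0.9,\ 0.05\,d)$, substitutions uniform
over the 19 alternative residues and no indels, keeping alignment scores
analytically predictable. The Gaussian niche is the minimal standard
ecological model that produces the envelope behaviour the analysis
assumes -- large environmental differences force large community
divergence, while similar environments admit both similar and dissimilar
communities.

Deliberately absent from the generator, and hence untested by it:
codon-level evolution, indels, horizontal transfer, read-level noise,
uneven sequencing depth, and annotation error in the reference. Passing
recovery tests therefore show the pipeline's statistics behave correctly
under the model's assumptions, not that real metagenomes satisfy those
assumptions.

Default sizes were chosen so the full sequence-level run (8 sites, 300
families, roughly 1200 protein copies, about half a million alignments)
completes in a few minutes: sequence lengths 100-140 keep perfect and
moderately diverged within-family pairs comfortably below the $10^{-40}$
bar at this dataset size, while unrelated pairs stay far above it.

## Numerical and degenerate-input choices

* Distance matrices are validated on construction and after every read:
  symmetric (1e-8), zero diagonal, finite, non-negative unless
  explicitly patristic (negative NJ branches may produce small negative
  patristic entries).
* PHYLIP output pads labels to 10 characters and refuses silently
  colliding truncations; round trips are exact to 6 decimals.
* A sample with zero clusters has undefined Jaccard dissimilarity and
  errors; a constant distance matrix has undefined Mantel r and errors;
  zero-variance variables get NA rows in correlation matrices with a
  warning.
* All randomness (generator, Mantel permutations) is seed-controlled;
  identical configuration and seed give bit-identical pipeline outputs.

## Problem sizes used by the tests and acceptance script

The suite runs entirely on generated data: toy graphs of 8-20 nodes for
the MCL oracle comparisons, random trees of 4-10 tips for NJ
consistency, 200 random matrix pairs (10 sites each) for Mantel
calibration, 200 simulated sites for correlation-structure recovery, and
one full sequence-level run plus ten presence-level runs of the 8-site,
300-family gradient simulation for end-to-end recovery. These sizes make
the whole suite a desk-scale computation while leaving every algorithmic
property non-trivially exercised.

## Known limitations

* The internal aligner is exact but quadratic; it is meant for
  desk-scale and validation work. For large surveys, import search
  results via the tabular-hit path.
* E-values use fixed ungapped Karlin-Altschul constants; they are not
  calibrated for gapped alignments, which only shifts the effective
  threshold, not the downstream logic.
* MCL granularity interacts with the E-value threshold; the package
  exposes both but does not re-derive any tuning objective for them.
* Patristic distance inherits NJ's behaviour on strongly non-additive
  input, including possible negative branches (clamping is available).
* Three sites are enough for a tree but not for a Mantel test (minimum
  four); per-parameter Mantel rows are NA when too few shared sites
  carry a measurement.
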