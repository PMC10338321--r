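---
title: "Methods: phylogeny-aware covariation scoring and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeny-aware covariation scoring and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covet)
```

## The model

CovET scores a pair of alignment positions by how well its variation
pattern tolerates the branching structure of the family's evolutionary
tree. The intuition is that between two closely related sequences —
sequences that sit together deep in the tree — a coupled pair of residues
should either stay put or change together. A comparison in which exactly
one member of the pair changes (*nonconcerted* variation) is the only
pattern that argues against a coupling, and it argues more strongly the
shorter the evolutionary range over which it is observed. Conservation and
concerted variation are never penalized, which distinguishes the method
from mutual-information and direct-coupling statistics that implicitly
punish jointly conserved pairs.

Concretely, the pipeline is:

1. **ET sequence distance.** For rows $a, b$ of the alignment,
   $\mathrm{Dist}(a,b) = 1 - \frac{\sum_i f(x_{a,i}, x_{b,i})}
   {\min(|a|_{\text{non-gap}}, |b|_{\text{non-gap}})}$, where $f(x,y) = 1$
   iff the BLOSUM62 log-odds of $(x, y)$ is at least 2. Gap log-odds are
   fixed at 0, so a gap never matches anything, including itself.
2. **UPGMA tree.** Size-weighted average-linkage agglomeration on that
   distance matrix; node heights are half the merge distance.
3. **Level partition.** Level $n$ cuts the $n-1$ highest internal nodes,
   dividing the sequences into exactly $n$ groups; level 1 is the whole
   alignment and level $N$ is all singletons. Each level refines the
   previous by splitting exactly one group.
4. **Pair score.** For each pair $(i, j)$ of query-mapped columns,
   $\mathrm{CovET}_{ij} = 1 + \sum_{n=1}^{N-1} \frac{1}{n} \sum_{g}
   \exp\!\big(-\sum_{v \in NC} f_{ij,v} \ln f_{ij,v}\big)$. Within a group
   of $m$ sequences, all $\binom{m}{2}$ unordered comparisons are
   classified; $v$ ranges over the ordered character 4-tuples
   $(x_{a,i}, x_{a,j}, x_{b,i}, x_{b,j})$ in which exactly one position
   differs (17,640 such categories in the 21-letter alphabet), and
   $f_{ij,v}$ is the category's frequency. The inner term is the
   perplexity of the group's nonconcerted variation: 1 when there is none.

Because every group's perplexity is at least 1 and each level $n$
contributes $n$ groups with weight $1/n$, the score has an exact floor of
$N$, attained precisely when no group shows any entropy in its
nonconcerted variation. Lower is more coupled. The comparator ET-MIp runs
the same traversal but scores each group by its average-product-corrected
mutual information; there, higher is more coupled. All downstream code
consumes the orientation flag carried by the score table rather than
assuming a direction.

The implementation evaluates each tree node's group term once and weights
it by $\sum 1/n$ over the contiguous range of levels at which that node is
a group — algebraically identical to the level-by-level sum, and the reason
scoring 64 sequences times 1,225 pairs takes seconds rather than minutes.
An independent brute-force implementation (naive nested loops over levels,
groups, comparisons and categories, in `tests/testthat/helper-oracle.R`)
re-derives the scores literally; the test suite and the acceptance script
require agreement to 1e-9.

## Tunable parameters

* `substitution_rule(threshold = 2)` — BLOSUM62 log-odds cutoff defining a
  "match" in the ET distance. 2 is the ET convention; the table itself
  comes from Biostrings.
* `filter_redundant(max_identity = 0.98)` — redundancy cap. Identity is
  matching non-gap columns over columns where at least one row is
  occupied; clusters above the cap (single linkage) keep the member
  closest to the query, and the query is always kept. The 98% default is
  the usual family-pipeline setting.
* `covet_scores(normalize = "comparisons")` — denominator of $f_{ij,v}$.
  The default divides category counts by all $\binom{m}{2}$ comparisons,
  so frequencies need not sum to 1 and a group with little nonconcerted
  variation is penalized little. The alternative `"events"` renormalizes
  over nonconcerted events only; it is exposed because the frequency
  convention is a genuine modelling choice, but note that under it a group
  with a single dominant category is indistinguishable from a quiet group.
* `build_contact_map(distance_cutoff = 8, min_separation = 6)` — the CASP
  contact convention (Cβ, Cα for glycine), with separation classes short
  6–11, medium 12–23, long 24+.
* `scw_adjacency(cutoff = 4)` — any-atom adjacency for the SCW statistic.
  This 4 Å graph is deliberately distinct from the 8 Å Cβ contact graph;
  the two are never conflated.
* Epistasis models (`product`, `additive`, `log`, `min`) with fitness on
  the wild-type = 1 scale; `preprocess_fitness(base = exp(1))` exposes the
  exponential base because source screens report log fitness in different
  bases.

## Numerical and tie-breaking choices

Scores must be reproducible bit-for-bit under a fixed seed, which forces
several decisions the underlying mathematics leaves open:

* **UPGMA ties** — when two merges are equidistant, the pair whose
  lexicographically least member identifier is smallest merges first.
* **Level-cut ties** — among equally high nodes, the node containing the
  lexicographically least leaf is cut first, and a node only becomes
  eligible once its parent is cut.
* **Comparison direction** — within a group, comparisons run from the
  earlier alignment row to the later one, making the ordered-tuple
  category counts well defined. Reversing the row order maps every
  category to its reversal bijectively and leaves all penalties unchanged;
  arbitrary permutations are not guaranteed to, because a category and its
  reversal can collide.
* **Entropies** — natural log throughout, with $0 \ln 0 = 0$; the
  perplexity of an empty nonconcerted tally is 1. A two-member group whose
  single comparison is nonconcerted also yields penalty 1 (one category,
  $f = 1$, zero entropy) under either normalization — a known degeneracy
  of the entropy form.
* **Pair ranks** — equal raw scores order lexicographically by
  $(i, j)$; coverage targets use $\lceil \text{threshold} \times K
  \rceil$ with $K$ the residues under consideration (structure-resolved
  residues when a structure is involved).
* **APC** — the correction uses each position's mean MI against all other
  positions and the global mean over distinct pairs, the standard
  average-product form; when the global mean is 0 the correction is 0.
* **Degenerate inputs** — an all-gap row has ET-distance denominator 0;
  its distance is defined as 1 (maximally distant) with a warning rather
  than an error. An SCW selection equal to all residues has zero null
  variance and is flagged undefined instead of returning an infinite z.
* **Gaps** are first-class characters in both scores (21-letter alphabet),
  but never match in the ET distance.
* **Mean sequence separation** is reported both raw and normalized by
  protein length; which normalization a comparison should use depends on
  whether protein size is a nuisance variable, so both are computed.

## The SCW null

The selection cluster weighting statistic is
$w = \sum_{i<j} S(i) S(j) A(i,j) b(i,j)$ over residue pairs, with $A$ the
4 Å any-atom adjacency and $b$ either 1 (unbiased) or $|i-j|$ (biased).
Under uniform random selection of the same size, $E[w]$ and
$\mathrm{Var}[w]$ are computed exactly by decomposing pairs of edges by
how many residues they share (two, one, or zero), whose joint selection
probabilities are falling-factorial ratios. The analytic null is the
default because it is deterministic; a seeded Monte-Carlo null (10,000
draws by default) serves as its cross-check, and the test suite requires
the two to agree within three Monte-Carlo standard errors on toy
structures, in both bias modes.

## What the simulators emulate — and what they do not

`simulate_coupled_alignment` draws a random coalescent tree, evolves a
uniform-random root sequence with a fixed per-branch, per-position
substitution probability, and plants coupled pairs: a substitution at one
member triggers a substitution at its partner with the coupling
probability, the partner's new residue drawn uniformly. This produces
exactly the signal the score rewards — concerted change along tree
branches — without committing to any interaction alphabet. The default
condition (64 leaves, 50 columns, substitution 0.05, five planted pairs,
coupling 0.9) gives a family diverse enough for every tree level to carry
information while staying within seconds of compute; it is the reference
condition for the recovery tests and the acceptance script.

The simulator deliberately omits: realistic substitution matrices (WAG/LG
or BLOSUM-biased replacement), indels (alignments are gap-free unless gaps
are placed by hand), rate heterogeneity across sites, and alignment error.
Passing the planted-pair recovery tests therefore shows that the score
detects tree-consistent concerted variation against independent drift — it
does not show robustness to misalignment or to the phylogenetic
confounding structure of real families, which is precisely what real-data
benchmarks are for.

`toy_structure` lays residues on an extended chain (consecutive Cα 3.8 Å
apart) and repositions each planted cluster into a tight ball far from the
chain, so intra-cluster any-atom distances are all below 4 Å, and only
sequence neighbors are adjacent elsewhere. It is a geometry fixture for
the SCW and contact machinery, not a protein model.

## Problem sizes

The test suite scores alignments of 4–16 sequences (32–64 for recovery
checks), evaluates SCW on 20–30-residue toy structures with 10,000-draw
Monte-Carlo nulls, and enumerates the full $21^4$ transition space once.
The acceptance script uses 20 replicate simulations at the 64-leaf
reference condition. These sizes were chosen so each check is decisive
(oracle agreement to 1e-9, null calibration to three standard errors)
while the whole suite remains a couple of minutes of compute.

## Known limitations

* The redundancy filter's identity denominator (occupied columns) and the
  UPGMA/level tie-breaks are this package's own deterministic conventions;
  other ET implementations may order ties differently and produce
  different trees on degenerate inputs.
* CovET scores scale with $N$ and are not comparable across alignments of
  different depth without normalization.
* The structural reader handles single-chain PDB input mapped by residue
  number, explicit position vectors, or exact query substring match;
  inexact mappings are refused rather than re-aligned.
* Average precision is a finite-sample-biased estimator: its permutation
  null mean exceeds the positive rate by roughly $H_n/n$, which the tests
  account for by comparing against the exact closed-form null mean rather
  than against the positive rate itself.
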