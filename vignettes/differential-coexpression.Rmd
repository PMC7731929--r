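---
title: "Differential co-expression networks: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression networks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexdiff)
```

## The analysis in one paragraph

`coexdiff` compares transcriptional coordination between matched normal
and tumor tissue. For each condition it builds a weighted undirected
co-expression network over genes: the Spearman correlation $\rho_{ij}$
of each gene pair across samples is soft-thresholded to a weight
$w_{ij} = \rho_{ij}^6$, and an edge is kept iff $w_{ij} > 0.25$ and
$|\rho_{ij}| \le 0.99$. The two condition subnetworks then go through
the same battery of graph analyses — weighted PageRank centrality,
Louvain community detection, Dijkstra shortest paths between annotated
gene classes (oncogenes, epigenetic regulators, transcription factors)
— and the tumor-versus-normal differences are summarized: network size
collapse, per-gene centrality shifts, community restructuring and
degree change, loss of class–class edges, and path lengthening or
breakage. Communities are annotated by hypergeometric
over-representation against gene-set collections in GMT format, and the
dual graph can be exported as Neo4j bulk-import CSV plus a Cypher
loader script.

## Edge construction

Three rules turn a correlation into an edge, applied in this order:

1. **Discard rule, $|\rho| > 0.99$ (strict).** In FPKM-like data,
   correlations this extreme almost always come from two genes sitting
   at near-zero expression in nearly all samples: the tied ranks
   fabricate a perfect monotone association. Because the artifact is a
   property of the magnitude, the rule is applied to $|\rho|$ even
   though negative values of that size are rare.
2. **Soft thresholding, $w = \rho^6$.** Raising to the sixth power
   suppresses weak correlations smoothly instead of imposing a hard
   cut, and drives the degree distribution toward scale-free topology
   (checked by `scale_free_fit()`, a log–log linear fit over
   logarithmically binned degrees). The even power erases the sign, so
   strong negative co-expression survives as a positive weight; the
   signed $\rho$ is retained as an edge attribute.
3. **Retention rule, $w > 0.25$ (strict).** Algebraically the two
   strict rules retain an edge iff
   $0.25^{1/6} \approx 0.79370 < |\rho| \le 0.99$, which the test suite
   verifies by a fine sweep of $\rho$.

Spearman is computed on average (fractional) ranks; mean-rank tie
handling matters because zero-inflation is pervasive in FPKM data.
Genes constant across samples have no defined correlation and are
excluded (with a message) rather than failing the run; genes with no
retained edge are not counted as nodes of that condition's network.

## Graph-algorithm conventions

**PageRank.** The package uses the unnormalized per-node base-term
formulation: the fixed point of

$$s(n) = (1 - d) + d \sum_{m \in N(n)} s(m)\,\frac{w(m,n)}{S(m)},$$

with damping $d = 0.85$, $S(m)$ the total weight incident to $m$, and
each undirected edge acting as two directed edges. This is the classic
convention of graph-database algorithm libraries: scores are not a
probability distribution, they have floor $1 - d$, an isolated node
scores exactly $0.15$, and over a graph with no isolated nodes the
scores sum to the node count. Iteration starts at $1.0$ and stops when
the maximum absolute change drops below `tol` ($10^{-7}$ by default,
`max_iter` 100); the fixed point itself is the contract, and the tests
pin it against a direct linear-system solution. Genes absent from a
subnetwork are reported with degree 0 and PageRank $1 - d$, exactly as
isolated nodes.

**Louvain.** Standard two-phase weighted-modularity maximization at
resolution 1: seeded shuffled local moves until no gain, then community
aggregation, repeated to convergence. Because the greedy sweep can
stall in local optima on small dense graphs, `louvain()` restarts the
whole multilevel procedure (10 times by default, all driven by one
seed) and keeps the best partition; the reported $Q$ is always
recomputed from scratch from the final assignment. Ties between
candidate communities resolve to the first-listed candidate, making
runs deterministic given the seed.

**Shortest paths.** Dijkstra with unit edge cost (hop count) is the
default: path-length change between conditions is reported in "number
of genes traversed", and using correlation-derived weights as costs
would perversely penalize strong co-expression. An
`inverse_weight` mode (cost $1/w$) is available when a
strength-weighted notion of distance is wanted. Ties break toward the
lexicographically smaller gene so returned paths are deterministic.
Class-pair analysis (`class_pair_paths()`) evaluates every unordered
oncogene–epigenetic-regulator pair from the annotation table in both
conditions; a pair with an endpoint absent from a subnetwork is
infinite there, which is precisely how node loss in tumor converts
short paths into broken ones.

## The synthetic cohort generator

Real matched cohorts (on the order of 50–110 patients per tissue in
public tumor atlases) cannot ship with the package, so
`generate_dataset()` emulates one with fully known ground truth. The
generative model is a latent-factor log-normal: gene $g$ in module $m$
has

$$x_{gs} = \exp\!\big(a\, f_{m s} + (1 - a)\,\sigma\, \varepsilon_{g s}\big),$$

with module factor $f_m$ and residual $\varepsilon$ independent
standard normal, loading $a \in [0, 1)$ and noise scale $\sigma$
(`noise_sd`). The exponential gives positive, right-skewed, FPKM-like
values while leaving Spearman correlations — which are invariant under
monotone transforms — analytically controllable. Background genes are
pure noise.

Tumor matrices redraw all factors and noise and apply four
perturbations, mirroring the phenomena the analysis is designed to
detect:

* **dissolution** — a configured fraction of modules collapses to
  background noise (edge loss, node loss);
* **rewiring** — a fraction of intact-module genes switch to another
  intact module's factor (community re-membership);
* **gained hubs** — background genes acquire a shared tumor-only
  factor (tumor-specific degree gain);
* **attenuation** — every surviving module loading is multiplied by
  `tumor_attenuation`, modeling the global weakening of
  transcriptional coordination expected from tumor heterogeneity.
  Without it, intact tumor modules would be statistically
  indistinguishable from their normal counterparts and path lengths
  between gene classes could not systematically increase; with it,
  intact modules thin out (a few percent of within-module edges drop
  below the retention bound) so paths lengthen while communities
  survive.

Default parameter values and why:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 2000 | desk-scale stand-in for a curated gene panel |
| `n_samples` | 60 | within the 49–112 range of matched tumor cohorts |
| `modules` | five of 40 genes, loading 0.92 | strong planted signal; within-module Spearman ≈ 0.94 |
| `noise_sd` | 2.5 | calibrated by simulation so loadings ≥ 0.9 land inside the retention band and clear of the 0.99 discard rule |
| `dissolve_fraction` | 0.4 | two of five modules lost in tumor |
| `rewire_fraction` | 0.05 | minority re-membership, as observed restructuring is partial |
| `gained_hub_count` | 20 | a small tumor-specific program |
| `tumor_attenuation` | 0.945 | calibrated so intact tumor modules keep ≈ 93% of within-module edges: above the 90% recovery target, below the level at which paths stop lengthening |
| `class_fractions` | 0.10 each | denser than genome-wide prevalence by design: the panel emulates curated cancer-gene collections, and class-pair analyses need non-trivial pair counts at 2,000 genes |

Dissolution is *nested*: a seeded module permutation is truncated at
the configured fraction, so raising `dissolve_fraction` only ever adds
dissolved modules. This makes the edge-fold-change monotonicity
property exactly testable rather than stochastic.

**What the generator does not model:** read counts and library-size
normalization, batch effects, sample outliers, single-cell dropout, and
overlapping or hierarchically nested modules. Passing tests therefore
demonstrate that the pipeline recovers planted structure of this
log-normal factor form, not that it is robust to every artifact of real
RNA-seq. One further caveat: module-level factor draws make within-
module edge retention correlated across pairs, so directional
statements about mean path length hold under the default study
conditions (fixed generator seed) with a clear margin, but can tie at
other seeds when no intact-module edge happens to fall below the
retention bound.

## Enrichment

Community membership is unranked, so "enrichment" is hypergeometric
over-representation: for community of size $n$ and set of size $K$ in a
universe of $N$ genes, the upper tail $P(X \ge k)$ of
$\mathrm{Hypergeometric}(N, K, n)$. The universe is the intersection of
the analysis namespace (all annotated genes) with the collection's own
universe — the conservative standard choice. Benjamini–Hochberg
correction is applied per community across sets. Communities below
`min_size` (50 by default, the conventional cutoff for community-level
enrichment) are skipped; analyses of the synthetic benchmark lower the
cutoff to include its 40-gene planted modules.

## Differential statistics: conventions and degenerate inputs

* Fold changes are normal/tumor, so values above 1 mean tumor loss; an
  empty tumor subnetwork yields infinite folds with a warning rather
  than an error.
* Centrality-shift categories partition genes exactly: *decreased*
  (PageRank down), *relative increase* (PageRank up, degree down),
  *absolute increase* (PageRank up, degree not down), *unchanged*
  (PageRank exactly equal — measure-zero on real data, and computed
  over the union of the annotation namespace and both node sets, so
  fully disconnected genes land here by construction).
* Cross-network score correlations use pairwise-complete shared genes;
  genes absent from a network are excluded, not zero-filled, because
  zero-filling would fabricate correlation. The group comparison is a
  two-sided Welch t-test, with an explicit exclusion list for pairs
  that should not enter (e.g. two normal networks from the same organ).
* Path summaries average finite paths only; infinite paths are counted
  separately; the modal transition is taken over pairs finite in both
  conditions. Mismatched pair universes are an input error, not a
  silent intersection.

## Numerical choices

* Expression and edge-list TSVs are written with 17 significant digits
  so text round trips are exact; Neo4j/Cypher exports use 15
  significant digits (round-trip error below $10^{-12}$) and sort all
  rows, making regenerated artifacts byte-identical.
* PageRank convergence is tolerance-based rather than a fixed
  iteration count; the iteration cap is configurable for
  bit-compatibility experiments with fixed-iteration implementations.
* Louvain move acceptance requires a gain above $10^{-12}$ to avoid
  floating-point churn.
* The BH step-up is monotone and bounded below by the raw p-values; it
  is *not* idempotent in general, so no code relies on re-adjusting an
  adjusted vector.
* `modularity_q()` refuses an empty edge set (undefined $Q$) and an
  assignment that does not cover the node set.

## Problem sizes used in the shipped analyses

The package's own validation runs at desk scale, chosen so the full
suite and the end-to-end benchmark complete in a few minutes on one
CPU: the synthetic benchmark uses the default 2,000-gene, 60-sample
configuration (network construction is $O(G^2 n)$ via a rank-matrix
cross-product and takes about a second at this size); oracle
comparisons use 50 random graphs up to 50 nodes for PageRank's
linear-system check, 100 random graphs up to 10 nodes for exhaustive
path enumeration, and exhaustive partition search up to 8 nodes for
modularity optimality.

## Known limitations

* Only Spearman co-expression is implemented; Pearson and mutual
  information alternatives are deliberately out of scope.
* The Louvain resolution is fixed at 1; no overlapping communities.
* The discard rule is applied to $|\rho|$; whether signed discarding
  is ever preferable is untested because the motivating artifact is
  magnitude-driven.
* No minimum-expression prefilter is applied before correlation; with
  heavily zero-inflated inputs the 0.99 discard rule is the only
  guard.
* The Cypher/CSV export dialect targets the bulk importer of current
  Neo4j releases; it is exercised by a reference parse in the tests,
  not against a live database.
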