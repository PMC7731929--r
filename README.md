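# coexdiff

Differential co-expression network analysis of matched tumor and normal
transcriptomes.

Transcriptional coordination is massively perturbed in cancer: gene
pairs that are tightly co-expressed in healthy tissue lose their
association in tumors, hub genes lose centrality, co-expression modules
dissolve, and regulatory paths between oncogenes and epigenetic
regulators lengthen or break. `coexdiff` is for computational
biologists who want to quantify this perturbation from a pair of
expression matrices (genes × samples, FPKM-like values, one matrix per
condition) with a reproducible, fully tested pipeline — and to load the
resulting networks into a graph database for interactive exploration.

## The model

For each condition, every gene pair's Spearman correlation ρ across
samples is turned into an edge by three rules:

* discard the pair if |ρ| > 0.99 (tied near-zero expression fabricates
  perfect monotone association in FPKM data);
* soft-threshold: weight w = ρ⁶, which drives the network toward
  scale-free topology;
* retain the edge iff w > 0.25 — equivalently
  0.25^(1/6) ≈ 0.7937 < |ρ| ≤ 0.99.

The two condition subnetworks are analyzed with

* **weighted PageRank** in the unnormalized graph-database convention
  s(n) = (1−d) + d·Σₘ s(m)·w(m,n)/S(m), d = 0.85, so an isolated node
  scores exactly 0.15;
* **Louvain** weighted-modularity community detection (seeded,
  multi-restart, Q recomputed from the final assignment);
* **Dijkstra** shortest paths between annotated gene classes
  (oncogene–epigenetic-regulator pairs by default), in hop-count or
  inverse-weight mode;

and compared: node/edge fold changes (normal/tumor), per-gene
centrality-shift categories, lost class–class edges, per-community
degree-change distributions, path-length means, infinite-path counts
and the modal path-length transition. Communities are annotated by
hypergeometric over-representation against GMT gene sets with BH
correction. A seeded synthetic generator produces matched cohorts with
planted modules, tumor-specific module dissolution, rewiring and gained
hubs, so the whole pipeline is testable end to end without external
data.

## Worked example

```r
library(coexdiff)

cfg <- run_config(synthetic = synthetic_config(seed = 42L),
                  min_community_size = 30L, seed = 42L,
                  out_dir = "coexdiff_out")
manifest <- run_pipeline(cfg)
```

or, from the shell, `Rscript exec/coexdiff run-all --out coexdiff_out
--seed 42 --min-community 30`. The run simulates a 2,000-gene,
60-sample matched cohort (five planted 40-gene modules, two dissolving
in tumor), builds both networks, runs all analyses and writes every
artifact (edge lists, centrality table, communities, path table,
enrichment, Neo4j CSV + Cypher export, JSON manifest). The
differential summary it prints:

```
node fold change (normal/tumor): 1.4286
edge fold change (normal/tumor): 1.6373
lost TF-oncogene edges: 17
lost epigenetic-oncogene edges: 30
communities: normal 5 (Q = 0.7996), tumor 4 (Q = 0.7370)
centrality shift fractions:
  decreased: 0.0675
  relative_increase: 0.0155
  absolute_increase: 0.0270
  unchanged: 0.8900
mean finite path length: normal 1.0000, tumor 1.2353
infinite paths: normal 39855, tumor 39875
modal finite path transition: 1 -> 1
```

Reading it: the normal network (200 nodes, 3,900 edges — the five
planted modules) collapses 1.43-fold in nodes and 1.64-fold in edges
when two modules dissolve; 17 transcription-factor–oncogene edges are
lost; Louvain finds exactly the planted modules in each condition (the
tumor's fourth community is the gained-hub clique); and
oncogene–epigenetic-regulator paths both lengthen (mean finite length
1.00 → 1.24) and break (infinite-path count rises). The `unchanged`
fraction is dominated by background genes absent from both networks.
Per-gene scores live in `centrality.tsv` — for example every edgeless
gene shows `pagerank 0.15, degree 0` in both conditions, the isolated
node fixed point of the PageRank convention.

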