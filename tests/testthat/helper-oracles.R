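# Independent oracles and graph builders used across the test suite.
# Every oracle is a direct, brute-force formulation kept deliberately
# separate from the package's own code paths.

# Random weighted undirected graph as a condition_graph; weights drawn in
# the retained band (0.25, 1].
random_graph <- function(n, p = 0.3, seed = 1L, condition = "normal") {
  set.seed(seed)
  genes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(genes, 2L))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1L)] <- TRUE
  condition_graph(data.frame(gene_a = pairs[keep, 1L],
                             gene_b = pairs[keep, 2L],
                             weight = runif(sum(keep), 0.26, 1),
                             stringsAsFactors = FALSE), condition)
}

# PageRank oracle: direct solution of the linear fixed-point system
#   s = (1 - d) 1 + d M s,  M[j, i] = w(i, j) / S(i).
pagerank_solve <- function(graph, damping = 0.85) {
  nodes <- graph$nodes
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    W[e$gene_a[i], e$gene_b[i]] <- W[e$gene_a[i], e$gene_b[i]] + e$weight[i]
    W[e$gene_b[i], e$gene_a[i]] <- W[e$gene_b[i], e$gene_a[i]] + e$weight[i]
  }
  S <- colSums(W)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) if (S[i] > 0) M[, i] <- W[, i] / S[i]
  sol <- solve(diag(n) - damping * M, rep(1 - damping, n))
  stats::setNames(as.numeric(sol), nodes)
}

# Shortest-path oracle: exhaustive depth-first enumeration of simple
# paths with cost-bound pruning (sound for positive costs).
enum_shortest <- function(graph, source, target, mode = "hops") {
  nodes <- graph$nodes
  if (!(source %in% nodes) || !(target %in% nodes)) return(Inf)
  if (source == target) return(0)
  e <- graph$edges
  cost <- if (mode == "hops") rep(1, nrow(e)) else 1 / e$weight
  adj <- list()
  for (i in seq_len(nrow(e))) {
    adj[[e$gene_a[i]]] <- rbind(adj[[e$gene_a[i]]],
                                data.frame(v = e$gene_b[i], c = cost[i]))
    adj[[e$gene_b[i]]] <- rbind(adj[[e$gene_b[i]]],
                                data.frame(v = e$gene_a[i], c = cost[i]))
  }
  best <- Inf
  walk <- function(u, visited, acc) {
    if (acc >= best) return()
    if (u == target) { best <<- acc; return() }
    nb <- adj[[u]]
    if (is.null(nb)) return()
    for (i in seq_len(nrow(nb))) {
      if (!(nb$v[i] %in% visited)) {
        walk(nb$v[i], c(visited, nb$v[i]), acc + nb$c[i])
      }
    }
  }
  walk(source, source, 0)
  best
}

# All set partitions of n labeled items (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxid) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (c in seq_len(maxid + 1L)) {
      grow(c(prefix, c), max(maxid, c))
    }
  }
  grow(1L, 1L)
  out
}

# Exhaustive modularity optimum by scanning every partition.
best_modularity <- function(graph) {
  n <- length(graph$nodes)
  parts <- all_partitions(n)
  best <- -Inf
  for (p in parts) {
    q <- modularity_q(graph, stats::setNames(p, graph$nodes))
    if (q > best) best <- q
  }
  best
}

# Spearman oracle: explicit Pearson formula on average ranks.
rank_pearson <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Hypergeometric upper-tail oracle by direct enumeration of the pmf.
hyper_enum <- function(k, n, K, N) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Tiny dual graph with annotated classes, used by differential tests.
make_dual <- function(normal_edges, tumor_edges, ann) {
  dual_graph(condition_graph(normal_edges, "normal"),
             condition_graph(tumor_edges, "tumor"),
             ann)
}
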