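# Native graph algorithms under Neo4j scoring conventions.

#' Weighted PageRank (unnormalized graph-database convention)
#'
#' Fixed point of
#'   score(n) = (1 - d) + d * sum_m score(m) * w(m, n) / S(m)
#' over neighbors m, where S(m) is the total edge weight incident to m and
#' d the damping factor. Each undirected edge acts as two directed edges.
#' This is the classic unnormalized formulation used by Neo4j's algorithm
#' library: scores have floor (1 - d), an isolated node scores exactly
#' (1 - d), and with no isolated nodes the scores sum to the node count.
#'
#' @param graph A [condition_graph()]; edge weights must be positive.
#' @param damping Damping factor in (0, 1), default 0.85.
#' @param tol Convergence tolerance on the maximum absolute score change.
#' @param max_iter Iteration cap.
#' @return Named numeric vector of scores over `graph$nodes`.
#' @export
pagerank <- function(graph, damping = 0.85, tol = 1e-7, max_iter = 100L) {
  if (!inherits(graph, "condition_graph")) {
    stop_input("`graph` must be a condition_graph")
  }
  if (!(damping > 0 && damping < 1)) {
    stop_input("damping must lie strictly between 0 and 1")
  }
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) return(stats::setNames(numeric(), character()))
  e <- graph$edges
  if (nrow(e) && any(e$weight <= 0)) {
    stop_input("pagerank requires positive edge weights")
  }
  ia <- match(e$gene_a, nodes)
  ib <- match(e$gene_b, nodes)
  src <- c(ia, ib)
  dst <- c(ib, ia)
  w <- c(e$weight, e$weight)
  S <- numeric(n)
  if (length(src)) {
    agg <- rowsum(w, src)
    S[as.integer(rownames(agg))] <- agg[, 1L]
  }
  s <- rep(1, n)
  for (iter in seq_len(max_iter)) {
    out <- ifelse(S > 0, s / S, 0)
    acc <- numeric(n)
    if (length(src)) {
      agg <- rowsum(w * out[src], dst)
      acc[as.integer(rownames(agg))] <- agg[, 1L]
    }
    s_new <- (1 - damping) + damping * acc
    delta <- max(abs(s_new - s))
    s <- s_new
    if (delta < tol) break
  }
  stats::setNames(s, nodes)
}

#' Node degree (count of incident retained edges)
#'
#' @param graph A [condition_graph()].
#' @param genes Optional gene namespace; genes absent from the subnetwork
#'   receive degree 0. Defaults to the graph's own node set.
#' @return Named integer vector.
#' @export
node_degree <- function(graph, genes = NULL) {
  if (!inherits(graph, "condition_graph")) {
    stop_input("`graph` must be a condition_graph")
  }
  genes <- if (is.null(genes)) graph$nodes else as.character(genes)
  deg <- stats::setNames(integer(length(genes)), genes)
  counts <- table(c(graph$edges$gene_a, graph$edges$gene_b))
  hit <- intersect(names(counts), genes)
  deg[hit] <- as.integer(counts[hit])
  deg
}

#' Weighted modularity of a partition
#'
#' Q = (1 / 2W) * sum_ij (w_ij - k_i k_j / 2W) * delta(c_i, c_j), with
#' weighted degrees k and total edge weight W.
#'
#' @param graph A [condition_graph()] with at least one edge.
#' @param assignment Named integer vector mapping every node of `graph`
#'   to a community id.
#' @return Modularity Q.
#' @export
modularity_q <- function(graph, assignment) {
  if (!inherits(graph, "condition_graph")) {
    stop_input("`graph` must be a condition_graph")
  }
  e <- graph$edges
  if (!nrow(e)) stop_input("modularity is undefined for an empty edge set")
  missing <- setdiff(graph$nodes, names(assignment))
  if (length(missing)) {
    stop_input("assignment does not cover node ", missing[1L])
  }
  comm <- assignment[graph$nodes]
  W <- sum(e$weight)
  k <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  for (col in c("gene_a", "gene_b")) {
    agg <- rowsum(e$weight, e[[col]])
    k[rownames(agg)] <- k[rownames(agg)] + agg[, 1L]
  }
  intra <- e$weight[comm[e$gene_a] == comm[e$gene_b]]
  ktot <- tapply(k, comm, sum)
  sum(intra) / W - sum((ktot / (2 * W))^2)
}

# One Louvain level: local moving on the current (possibly aggregated)
# graph. Edges are index pairs i < j with weights; self-loop weight per
# node accumulates merged intra-community edges across levels.
louvain_one_level <- function(ia, ib, w, self_w, n) {
  k <- 2 * self_w
  if (length(ia)) {
    agg <- rowsum(c(w, w), c(ia, ib))
    k[as.integer(rownames(agg))] <- k[as.integer(rownames(agg))] + agg[, 1L]
  }
  two_w <- sum(k)
  nb_from <- c(ia, ib)
  nb_to <- c(ib, ia)
  nb_w <- c(w, w)
  ord <- order(nb_from)
  nb_from <- nb_from[ord]; nb_to <- nb_to[ord]; nb_w <- nb_w[ord]
  ptr <- c(findInterval(seq_len(n) - 1L, nb_from) + 1L,
           length(nb_from) + 1L)  # start index of node i's neighbor block
  comm <- seq_len(n)
  tot <- k
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      lo <- ptr[i]; hi <- ptr[i + 1L] - 1L
      if (hi < lo) next
      nbr <- nb_to[lo:hi]
      wts <- nb_w[lo:hi]
      ci <- comm[i]
      tot[ci] <- tot[ci] - k[i]
      links <- tapply(wts, comm[nbr], sum)
      cand <- as.integer(names(links))
      gains <- links - k[i] * tot[cand] / two_w
      cur <- match(ci, cand)
      base <- if (is.na(cur)) -k[i] * tot[ci] / two_w else gains[cur]
      best <- which.max(gains)
      if (gains[best] > base + 1e-12) {
        comm[i] <- cand[best]
        moved <- TRUE
      }
      tot[comm[i]] <- tot[comm[i]] + k[i]
    }
    if (!moved) break
  }
  match(comm, sort(unique(comm)))
}

# One complete multilevel Louvain run on index-space edges; consumes the
# current RNG stream for sweep orders and returns the membership vector.
louvain_run <- function(ia0, ib0, w0, n0) {
  ia <- ia0; ib <- ib0; w <- w0
  n <- n0
  self_w <- numeric(n)
  membership <- seq_len(n)   # original node -> current-level community
  repeat {
    lev <- louvain_one_level(ia, ib, w, self_w, n)
    n_new <- max(lev)
    membership <- lev[membership]
    if (n_new == n) break
    # aggregate: communities become nodes; intra weight -> self-loops
    ca <- lev[ia]; cb <- lev[ib]
    new_self <- numeric(n_new)
    agg_self0 <- rowsum(self_w, lev)
    new_self[as.integer(rownames(agg_self0))] <- agg_self0[, 1L]
    intra <- ca == cb
    if (any(intra)) {
      agg <- rowsum(w[intra], ca[intra])
      ids <- as.integer(rownames(agg))
      new_self[ids] <- new_self[ids] + agg[, 1L]
    }
    if (any(!intra)) {
      lo <- pmin(ca[!intra], cb[!intra])
      hi <- pmax(ca[!intra], cb[!intra])
      key <- (lo - 1) * n_new + hi
      agg <- rowsum(w[!intra], key)
      keys <- as.numeric(rownames(agg))
      ia <- as.integer((keys - 1) %/% n_new + 1)
      ib <- as.integer((keys - 1) %% n_new + 1)
      w <- agg[, 1L]
    } else {
      ia <- integer(); ib <- integer(); w <- numeric()
    }
    self_w <- new_self
    n <- n_new
  }
  membership
}

#' Louvain community detection
#'
#' Standard two-phase heuristic maximizing weighted modularity at
#' resolution 1: repeated local node moves (sweep order shuffled by the
#' seeded RNG), then aggregation of communities into super-nodes, until
#' no move improves Q. Because the greedy sweep can stall in a local
#' optimum on small dense graphs, the whole multilevel procedure is
#' restarted `restarts` times with fresh sweep orders and the
#' best-modularity partition is returned. The reported Q is recomputed
#' from the final assignment with [modularity_q()].
#'
#' @param graph A non-empty [condition_graph()].
#' @param seed Integer seed controlling the node sweep orders.
#' @param restarts Number of independent multilevel runs (default 10).
#' @return Object of class `community_partition`: `condition`,
#'   `assignment` (named integer over graph nodes) and `modularity`.
#' @export
louvain <- function(graph, seed = 1L, restarts = 10L) {
  if (!inherits(graph, "condition_graph")) {
    stop_input("`graph` must be a condition_graph")
  }
  if (!nrow(graph$edges)) stop_input("louvain needs a non-empty edge set")
  nodes <- graph$nodes
  n <- length(nodes)
  ia <- match(graph$edges$gene_a, nodes)
  ib <- match(graph$edges$gene_b, nodes)
  w <- graph$edges$weight
  best <- NULL
  best_q <- -Inf
  with_seed(seed, {
    for (r in seq_len(max(1L, restarts))) {
      membership <- louvain_run(ia, ib, w, n)
      q <- modularity_q(graph, stats::setNames(membership, nodes))
      if (q > best_q + 1e-12) {
        best_q <- q
        best <- membership
      }
    }
  })
  # renumber communities by first appearance for a stable labeling
  assignment <- stats::setNames(match(best, unique(best)), nodes)
  structure(list(condition = graph$condition,
                 assignment = assignment,
                 modularity = modularity_q(graph, assignment)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %s: %d nodes, %d communities, Q = %.4f\n",
              x$condition, length(x$assignment),
              length(unique(x$assignment)), x$modularity))
  invisible(x)
}

#' Scale-free topology diagnostic
#'
#' Least-squares fit of log10(frequency) against log10(degree) over
#' logarithmically binned node degrees. A good fit (high R-squared) with
#' negative slope indicates an approximately power-law degree
#' distribution, the signature of soft-thresholded co-expression
#' networks.
#'
#' @param graph A [condition_graph()].
#' @param n_bins Number of logarithmic degree bins (default 10).
#' @return List with `r_squared`, `slope` and the binned `fit_data`.
#' @export
scale_free_fit <- function(graph, n_bins = 10L) {
  deg <- node_degree(graph)
  deg <- deg[deg > 0]
  if (length(unique(deg)) < 5L) {
    stop_input("scale-free diagnostic needs >= 5 distinct degree values")
  }
  breaks <- unique(exp(seq(log(min(deg)), log(max(deg)),
                           length.out = n_bins + 1L)))
  bin <- cut(deg, breaks = breaks, include.lowest = TRUE)
  counts <- tapply(deg, bin, length)
  kmean <- tapply(deg, bin, mean)
  ok <- !is.na(counts) & counts > 0
  freq <- counts[ok] / length(deg)
  kmean <- kmean[ok]
  if (sum(ok) < 3L) stop_input("too few occupied degree bins for a fit")
  fit <- stats::lm(log10(freq) ~ log10(kmean))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       fit_data = data.frame(k = as.numeric(kmean),
                             frequency = as.numeric(freq)))
}
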