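# Shortest-path analysis (Dijkstra) between gene classes.
#
# Default cost is one per edge (hop count): path length counts the genes
# traversed, which matches how path-length changes between conditions are
# reported. Using raw correlation weights as costs would perversely
# penalize strong co-expression, so the weighted alternative uses cost
# 1/w per edge (`mode = "inverse_weight"`). Unreachable or absent
# endpoints have infinite length.

# Adjacency in index space, neighbors sorted so lexicographically smaller
# genes are explored first (deterministic tie-breaking).
build_adjacency <- function(graph) {
  nodes <- graph$nodes
  n <- length(nodes)
  ia <- match(graph$edges$gene_a, nodes)
  ib <- match(graph$edges$gene_b, nodes)
  adj <- vector("list", n)
  wl <- vector("list", n)
  from <- c(ia, ib)
  to <- c(ib, ia)
  w <- rep(graph$edges$weight, 2L)
  ord <- order(from, to)
  from <- from[ord]; to <- to[ord]; w <- w[ord]
  sp <- split(seq_along(from), from)
  for (nm in names(sp)) {
    i <- as.integer(nm)
    adj[[i]] <- to[sp[[nm]]]
    wl[[i]] <- w[sp[[nm]]]
  }
  list(nodes = nodes, adj = adj, w = wl)
}

edge_costs <- function(weights, mode) {
  if (mode == "hops") rep(1, length(weights)) else 1 / weights
}

# Single-source breadth-first search: Dijkstra specialization for unit
# costs (hop mode). Sorted adjacency makes predecessors settle toward the
# lexicographically smaller gene.
bfs_single_source <- function(adjacency, source_idx) {
  n <- length(adjacency$nodes)
  dist <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  dist[source_idx] <- 0
  frontier <- source_idx
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) {
      nbr <- adjacency$adj[[u]]
      if (is.null(nbr)) next
      new <- nbr[is.infinite(dist[nbr])]
      if (length(new)) {
        dist[new] <- dist[u] + 1
        pred[new] <- u
        nxt <- c(nxt, new)
      }
    }
    frontier <- sort(unique(nxt))
  }
  list(dist = dist, pred = pred)
}

# Single-source Dijkstra over the prebuilt adjacency; returns distances
# and predecessors. Nodes are scanned in index (= lexicographic) order,
# so equal-cost ties settle toward the smaller gene.
dijkstra_single_source <- function(adjacency, source_idx, mode) {
  if (mode == "hops") return(bfs_single_source(adjacency, source_idx))
  n <- length(adjacency$nodes)
  dist <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[source_idx] <- 0
  repeat {
    active <- which(!done & is.finite(dist))
    if (!length(active)) break
    u <- active[which.min(dist[active])]
    done[u] <- TRUE
    nbr <- adjacency$adj[[u]]
    if (is.null(nbr)) next
    costs <- dist[u] + edge_costs(adjacency$w[[u]], mode)
    better <- costs < dist[nbr]
    if (any(better)) {
      dist[nbr[better]] <- costs[better]
      pred[nbr[better]] <- u
    }
  }
  list(dist = dist, pred = pred)
}

#' Shortest path between two genes
#'
#' Dijkstra's algorithm on the condition subnetwork. Endpoints may be
#' absent from the graph (e.g. genes that lost all co-expression in
#' tumor); absence or disconnection yields an infinite length.
#'
#' @param graph A [condition_graph()].
#' @param source,target Gene symbols.
#' @param mode `"hops"` (cost 1 per edge; length = number of edges,
#'   default) or `"inverse_weight"` (cost `1/w` per edge).
#' @return List of class `path_result`: `source`, `target`, `length`
#'   (non-negative number or `Inf`) and `path` (gene sequence when
#'   finite, else `NULL`).
#' @export
shortest_path <- function(graph, source, target,
                          mode = c("hops", "inverse_weight")) {
  mode <- match.arg(mode)
  res <- list(source = source, target = target, length = Inf, path = NULL)
  class(res) <- "path_result"
  si <- match(source, graph$nodes)
  ti <- match(target, graph$nodes)
  if (is.na(si) || is.na(ti)) return(res)
  if (si == ti) {
    res$length <- 0
    res$path <- source
    return(res)
  }
  adjacency <- build_adjacency(graph)
  sp <- dijkstra_single_source(adjacency, si, mode)
  if (!is.finite(sp$dist[ti])) return(res)
  path <- ti
  while (path[1L] != si) path <- c(sp$pred[path[1L]], path)
  res$length <- sp$dist[ti]
  res$path <- graph$nodes[path]
  res
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf("<path_result> %s -> %s: length %s\n", x$source, x$target,
              format(x$length)))
  if (!is.null(x$path)) cat("  ", paste(x$path, collapse = " - "), "\n")
  invisible(x)
}

#' Shortest paths between all pairs of two gene classes
#'
#' Enumerates every unordered pair with one gene from `class_a` and one
#' from `class_b` (distinct genes; deduplicated when the classes
#' overlap), taken from the annotation table, and evaluates the shortest
#' path in each condition subnetwork. Pairs with an endpoint absent from
#' a subnetwork are reported with infinite length there.
#'
#' @param dual A [dual_graph()].
#' @param class_a,class_b Class labels (`"TF"`, `"EPIGENETIC"`,
#'   `"ONCOGENE"`).
#' @param mode Passed to the path search; see [shortest_path()].
#' @return List with data frames `normal` and `tumor`, each with columns
#'   `source`, `target`, `length` over the identical pair universe.
#' @export
class_pair_paths <- function(dual, class_a = "ONCOGENE",
                             class_b = "EPIGENETIC",
                             mode = c("hops", "inverse_weight")) {
  mode <- match.arg(mode)
  if (!inherits(dual, "dual_graph")) stop_input("`dual` must be a dual_graph")
  genes_a <- class_genes(dual$annotations, class_a)
  genes_b <- class_genes(dual$annotations, class_b)
  if (!length(genes_a) || !length(genes_b)) {
    warning("empty gene class: ",
            if (!length(genes_a)) class_a else class_b)
    empty <- data.frame(source = character(), target = character(),
                        length = numeric(), stringsAsFactors = FALSE)
    return(list(normal = empty, tumor = empty))
  }
  pairs <- expand.grid(a = genes_a, b = genes_b,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  key_lo <- pmin(pairs$a, pairs$b)
  key_hi <- pmax(pairs$a, pairs$b)
  keep <- !duplicated(paste(key_lo, key_hi, sep = "\r"))
  pairs <- data.frame(source = key_lo[keep], target = key_hi[keep],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
  rownames(pairs) <- NULL

  eval_condition <- function(graph) {
    out <- pairs
    out$length <- Inf
    present <- graph$nodes
    adjacency <- build_adjacency(graph)
    for (src in unique(out$source)) {
      si <- match(src, present)
      if (is.na(si)) next
      rows <- which(out$source == src)
      tgt_idx <- match(out$target[rows], present)
      ok <- !is.na(tgt_idx)
      if (!any(ok)) next
      sp <- dijkstra_single_source(adjacency, si, mode)
      out$length[rows[ok]] <- sp$dist[tgt_idx[ok]]
    }
    out
  }
  list(normal = eval_condition(dual$normal),
       tumor = eval_condition(dual$tumor))
}
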