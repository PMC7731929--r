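# Tumor-versus-normal comparison statistics.
#
# Fold changes are defined as normal / tumor (values above 1 mean loss in
# tumor). The centrality table spans the union of the annotation
# namespace and both subnetworks; a gene absent from a subnetwork carries
# degree 0 there and a PageRank equal to the base score (1 - damping),
# exactly as an isolated node would.

#' Per-gene centrality table across both conditions
#'
#' @param dual A [dual_graph()].
#' @param damping,tol,max_iter Passed to [pagerank()].
#' @return Data frame of class `centrality_table` with columns `gene`,
#'   `pagerank_normal`, `pagerank_tumor`, `degree_normal`,
#'   `degree_tumor`, covering the union of the annotation namespace and
#'   both node sets.
#' @export
centrality_table <- function(dual, damping = 0.85, tol = 1e-7,
                             max_iter = 100L) {
  if (!inherits(dual, "dual_graph")) stop_input("`dual` must be a dual_graph")
  genes <- sort(unique(c(dual$annotations$gene, dual$normal$nodes,
                         dual$tumor$nodes)))
  base <- 1 - damping
  fill <- function(scores) {
    out <- stats::setNames(rep(base, length(genes)), genes)
    out[names(scores)] <- scores
    out
  }
  pr_n <- fill(pagerank(dual$normal, damping, tol, max_iter))
  pr_t <- fill(pagerank(dual$tumor, damping, tol, max_iter))
  tab <- data.frame(gene = genes,
                    pagerank_normal = unname(pr_n),
                    pagerank_tumor = unname(pr_t),
                    degree_normal = unname(node_degree(dual$normal, genes)),
                    degree_tumor = unname(node_degree(dual$tumor, genes)),
                    stringsAsFactors = FALSE)
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' Node and edge fold change (normal / tumor)
#'
#' @param dual A [dual_graph()].
#' @return List with `node_fold` and `edge_fold`; an empty tumor
#'   subnetwork yields infinite folds with a warning.
#' @export
size_fold_change <- function(dual) {
  if (!inherits(dual, "dual_graph")) stop_input("`dual` must be a dual_graph")
  if (!length(dual$normal$nodes)) stop_input("empty normal subnetwork")
  if (!length(dual$tumor$nodes)) {
    warning("empty tumor subnetwork: folds are infinite")
  }
  list(node_fold = length(dual$normal$nodes) / length(dual$tumor$nodes),
       edge_fold = nrow(dual$normal$edges) / nrow(dual$tumor$edges))
}

#' Class-pair edges lost in tumor
#'
#' Edges with one endpoint in `class_a` and the other in `class_b` that
#' are present in the normal subnetwork but absent from the tumor
#' subnetwork. Symmetric in the class order.
#'
#' @param dual A [dual_graph()].
#' @param class_a,class_b Class labels.
#' @return List with `count` and `edges` (data frame `gene_a`,
#'   `gene_b`).
#' @export
lost_class_edges <- function(dual, class_a = "TF", class_b = "ONCOGENE") {
  if (!inherits(dual, "dual_graph")) stop_input("`dual` must be a dual_graph")
  a <- class_genes(dual$annotations, class_a)
  b <- class_genes(dual$annotations, class_b)
  en <- dual$normal$edges
  cls <- (en$gene_a %in% a & en$gene_b %in% b) |
    (en$gene_a %in% b & en$gene_b %in% a)
  en <- en[cls, c("gene_a", "gene_b"), drop = FALSE]
  key <- function(e) paste(e$gene_a, e$gene_b, sep = "\r")
  lost <- en[!(key(en) %in% key(dual$tumor$edges)), , drop = FALSE]
  rownames(lost) <- NULL
  list(count = nrow(lost), edges = lost)
}

#' Classify tumor-vs-normal centrality shifts
#'
#' Per gene: `decreased` when the tumor PageRank is lower;
#' `relative_increase` when PageRank rises but degree falls (more central
#' in a sparser neighborhood); `absolute_increase` when PageRank rises
#' without a degree loss; `unchanged` when the PageRank is identical.
#'
#' @param table A [centrality_table()].
#' @return List with `category` (named character over genes) and
#'   `fractions` (summing to 1).
#' @export
centrality_shift_classify <- function(table) {
  if (!inherits(table, "centrality_table")) {
    stop_input("`table` must be a centrality_table")
  }
  category <- ifelse(table$pagerank_tumor < table$pagerank_normal,
                     "decreased",
              ifelse(table$pagerank_tumor > table$pagerank_normal,
                     ifelse(table$degree_tumor < table$degree_normal,
                            "relative_increase", "absolute_increase"),
                     "unchanged"))
  category <- stats::setNames(category, table$gene)
  levels <- c("decreased", "relative_increase", "absolute_increase",
              "unchanged")
  fractions <- vapply(levels, function(l) mean(category == l), numeric(1L))
  list(category = category, fractions = fractions)
}

#' Cross-network correlation of centrality scores
#'
#' Pearson correlation of PageRank score vectors for every within-group
#' pair of networks (tumor-tumor and normal-normal), on pairwise-complete
#' shared genes, followed by a two-sided Welch t-test comparing the two
#' groups of correlations. Listed pair exclusions are dropped from the
#' test.
#'
#' @param scores Named list of named numeric score vectors, one per
#'   network.
#' @param groups Named character vector mapping each network name to
#'   `"normal"` or `"tumor"`.
#' @param exclusions Optional list of length-2 character vectors naming
#'   network pairs to exclude from the t-test.
#' @return List with `pairs` (data frame: network_a, network_b, group,
#'   r, excluded), `group_means` and `p_value`.
#' @export
cross_network_centrality_correlation <- function(scores, groups,
                                                 exclusions = list()) {
  if (is.null(names(scores)) || !all(names(scores) %in% names(groups))) {
    stop_input("every score vector needs a named group")
  }
  if (!all(groups %in% c("normal", "tumor"))) {
    stop_input("groups must be 'normal' or 'tumor'")
  }
  excl_key <- vapply(exclusions, function(p) {
    paste(sort(p), collapse = "\r")
  }, character(1L))
  rows <- list()
  for (grp in c("normal", "tumor")) {
    nets <- names(scores)[groups[names(scores)] == grp]
    if (length(nets) < 2L) next
    cmb <- utils::combn(sort(nets), 2L)
    for (j in seq_len(ncol(cmb))) {
      na <- cmb[1L, j]; nb <- cmb[2L, j]
      shared <- intersect(names(scores[[na]]), names(scores[[nb]]))
      if (length(shared) < 2L) {
        warning("fewer than 2 shared genes for ", na, " vs ", nb,
                "; pair omitted")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        network_a = na, network_b = nb, group = grp,
        r = stats::cor(scores[[na]][shared], scores[[nb]][shared]),
        excluded = paste(na, nb, sep = "\r") %in% excl_key,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) stop_input("need at least two networks per group")
  used <- pairs[!pairs$excluded, , drop = FALSE]
  group_means <- tapply(used$r, used$group, mean)
  p_value <- NA_real_
  rt <- used$r[used$group == "tumor"]
  rn <- used$r[used$group == "normal"]
  if (length(rt) >= 2L && length(rn) >= 2L) {
    p_value <- stats::t.test(rt, rn)$p.value
  }
  list(pairs = pairs,
       group_means = group_means,
       p_value = p_value)
}

#' Genes gaining degree recurrently across cancer types
#'
#' @param tables Named list of [centrality_table()] objects, one per
#'   cancer type.
#' @param min_types Minimum number of types in which
#'   `degree_tumor > degree_normal` must hold (default 5).
#' @return Character vector of gene symbols.
#' @export
recurrent_degree_gain <- function(tables, min_types = 5L) {
  if (length(tables) < min_types) {
    stop_input("need at least min_types = ", min_types, " tables")
  }
  gains <- lapply(tables, function(tab) {
    tab$gene[tab$degree_tumor > tab$degree_normal]
  })
  counts <- table(unlist(gains, use.names = FALSE))
  sort(names(counts)[counts >= min_types])
}

#' Degree-change distribution per tumor community
#'
#' For every community of the tumor partition with at least `min_size`
#' members, summarizes the distribution of `degree_tumor -
#' degree_normal` across its genes.
#'
#' @param partition A tumor-side community partition from [louvain()].
#' @param table A [centrality_table()].
#' @param min_size Minimum community size (default 50).
#' @return Data frame with columns `community`, `size`, `q1`, `median`,
#'   `q3`, `mean_change`; empty (with a warning) when no community is
#'   large enough.
#' @export
community_degree_change <- function(partition, table, min_size = 50L) {
  if (!inherits(partition, "community_partition")) {
    stop_input("`partition` must come from louvain()")
  }
  if (!inherits(table, "centrality_table")) {
    stop_input("`table` must be a centrality_table")
  }
  change <- stats::setNames(table$degree_tumor - table$degree_normal,
                            table$gene)
  sizes <- table(partition$assignment)
  big <- as.integer(names(sizes)[sizes >= min_size])
  if (!length(big)) {
    warning("no community reaches min_size = ", min_size)
    return(data.frame(community = integer(), size = integer(),
                      q1 = numeric(), median = numeric(), q3 = numeric(),
                      mean_change = numeric()))
  }
  rows <- lapply(big, function(cid) {
    members <- names(partition$assignment)[partition$assignment == cid]
    d <- change[intersect(members, names(change))]
    qs <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(community = cid, size = length(members), q1 = qs[1L],
               median = qs[2L], q3 = qs[3L], mean_change = mean(d))
  })
  res <- do.call(rbind, rows)
  res[order(res$community), , drop = FALSE]
}

#' Summarize path-length change between conditions
#'
#' Means are taken over finite paths only; infinite paths are tallied
#' separately; the joint histogram and its modal cell are computed over
#' pairs finite in both conditions.
#'
#' @param paths_normal,paths_tumor Data frames from [class_pair_paths()]
#'   (columns `source`, `target`, `length`) over the identical pair
#'   universe.
#' @return List with `mean_length` (named, `NA` when a condition has no
#'   finite path), `infinite_count`, `joint_histogram` (data frame
#'   `length_normal`, `length_tumor`, `count`) and `modal_transition`.
#' @export
path_length_change_summary <- function(paths_normal, paths_tumor) {
  key <- function(df) paste(df$source, df$target, sep = "\r")
  kn <- key(paths_normal); kt <- key(paths_tumor)
  if (length(kn) != length(kt) || !setequal(kn, kt)) {
    stop_input("path lists cover different pair universes")
  }
  paths_tumor <- paths_tumor[match(kn, kt), , drop = FALSE]
  ln <- paths_normal$length
  lt <- paths_tumor$length
  mean_len <- c(normal = if (any(is.finite(ln))) mean(ln[is.finite(ln)])
                         else NA_real_,
                tumor = if (any(is.finite(lt))) mean(lt[is.finite(lt)])
                        else NA_real_)
  inf_count <- c(normal = sum(is.infinite(ln)),
                 tumor = sum(is.infinite(lt)))
  both <- is.finite(ln) & is.finite(lt)
  joint <- NULL
  modal <- NULL
  if (any(both)) {
    agg <- stats::aggregate(list(count = rep(1L, sum(both))),
                            by = list(length_normal = ln[both],
                                      length_tumor = lt[both]), FUN = sum)
    joint <- agg[order(-agg$count, agg$length_normal, agg$length_tumor),
                 , drop = FALSE]
    rownames(joint) <- NULL
    modal <- c(normal = joint$length_normal[1L],
               tumor = joint$length_tumor[1L])
  }
  list(mean_length = mean_len, infinite_count = inf_count,
       joint_histogram = joint, modal_transition = modal)
}

#' Full tumor-vs-normal differential report
#'
#' Convenience wrapper assembling every comparison statistic for one
#' dual graph: size folds, lost class edges (TF-oncogene and
#' epigenetic-oncogene), centrality shift categories, tumor community
#' degree change and the oncogene / epigenetic-regulator path summary.
#'
#' @param dual A [dual_graph()].
#' @param table Optional precomputed [centrality_table()].
#' @param tumor_partition Optional precomputed tumor [louvain()]
#'   partition.
#' @param min_community_size Community size cutoff for the degree-change
#'   summary.
#' @param path_mode Passed to [class_pair_paths()].
#' @param seed Seed for the Louvain sweep when the partition is computed
#'   here.
#' @return List of class `differential_report`.
#' @export
differential_report <- function(dual, table = NULL, tumor_partition = NULL,
                                min_community_size = 50L,
                                path_mode = c("hops", "inverse_weight"),
                                seed = 1L) {
  path_mode <- match.arg(path_mode)
  if (is.null(table)) table <- centrality_table(dual)
  if (is.null(tumor_partition)) tumor_partition <- louvain(dual$tumor, seed)
  paths <- class_pair_paths(dual, "ONCOGENE", "EPIGENETIC", path_mode)
  structure(list(
    size_fold = size_fold_change(dual),
    lost_tf_oncogene = lost_class_edges(dual, "TF", "ONCOGENE"),
    lost_epigenetic_oncogene = lost_class_edges(dual, "EPIGENETIC",
                                                "ONCOGENE"),
    centrality_shift = centrality_shift_classify(table),
    community_degree_change = community_degree_change(
      tumor_partition, table, min_community_size),
    paths = paths,
    path_summary = path_length_change_summary(paths$normal, paths$tumor)),
    class = "differential_report")
}
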