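# Co-expression edge construction.
#
# Edges are defined by three rules applied to the pairwise Spearman
# correlation rho of each gene pair across samples:
#   1. discard the pair when |rho| > 0.99 (in FPKM data, correlations in
#      this range trace back to near-zero expression of both genes in
#      nearly all samples, i.e. ties, not biology);
#   2. soft-threshold by raising rho to the 6th power, w = rho^6;
#   3. retain the edge iff w > 0.25 (strict).
# Equivalently, an edge survives iff 0.25^(1/6) < |rho| <= 0.99. The even
# power erases the sign, so negative correlations survive as positive
# weights; the signed rho is kept as an edge attribute.

#' Spearman rank correlation of two sample vectors
#'
#' Pearson correlation of average (fractional) ranks; ties receive their
#' mean rank, which matters for FPKM data with many zero ties. Invariant
#' under strictly monotone transforms of either input.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA` when either vector is
#'   constant (undefined correlation; such genes are excluded upstream).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (length(x) < 3L) stop_input("need at least 3 samples for correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Soft-thresholding edge rule
#'
#' Applies the discard / power / retention rules to one or more
#' correlation coefficients.
#'
#' @param rho Numeric vector of finite correlations in \[-1, 1\].
#' @param power Soft-thresholding exponent (default 6).
#' @param retention Minimum retained weight, strict (default 0.25).
#' @param discard Maximum admissible `|rho|`, strict (default 0.99).
#' @return Data frame with columns `rho`, `weight` (`rho^power`) and
#'   `retained`.
#' @export
soft_threshold_edge <- function(rho, power = 6, retention = 0.25,
                                discard = 0.99) {
  if (anyNA(rho) || any(!is.finite(rho)) || any(abs(rho) > 1)) {
    stop_input("rho must be finite and within [-1, 1]")
  }
  weight <- rho^power
  data.frame(rho = rho, weight = weight,
             retained = abs(rho) <= discard & weight > retention)
}

#' Build the co-expression network for one condition
#'
#' Computes Spearman correlations for all unordered gene pairs and applies
#' [soft_threshold_edge()]. Genes that are constant across samples have no
#' defined correlation and are excluded; genes with zero retained edges do
#' not appear in the node set. Cost is O(G^2 * n) through the rank-matrix
#' cross-product, so a few thousand genes run in seconds.
#'
#' @param expr An [expression_matrix()] with >= 3 samples.
#' @inheritParams soft_threshold_edge
#' @return A [condition_graph()] for the matrix's condition.
#' @export
build_network <- function(expr, power = 6, retention = 0.25,
                          discard = 0.99) {
  if (!inherits(expr, "expression_matrix")) {
    stop_input("`expr` must be an expression_matrix")
  }
  if (ncol(expr) < 3L) stop_input("need at least 3 samples to correlate")
  condition <- attr(expr, "condition")
  vals <- unclass(expr)
  sds <- apply(vals, 1L, stats::sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " constant gene(s) excluded from ", condition,
            " network (undefined correlation)")
    vals <- vals[sds > 0, , drop = FALSE]
  }
  if (nrow(vals) < 2L) {
    return(condition_graph(NULL, condition))
  }
  rho <- stats::cor(t(vals), method = "spearman")
  ut <- upper.tri(rho)
  keep <- ut & abs(rho) <= discard & rho^power > retention
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(condition_graph(NULL, condition))
  genes <- rownames(vals)
  edges <- data.frame(gene_a = genes[idx[, 1L]],
                      gene_b = genes[idx[, 2L]],
                      rho = rho[keep],
                      weight = rho[keep]^power,
                      stringsAsFactors = FALSE)
  condition_graph(edges, condition)
}
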