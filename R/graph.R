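# Graph-model containers and plain-text I/O.
#
# A condition graph is a weighted undirected co-expression network for one
# condition (normal or tumor); a dual graph pairs the two condition
# subnetworks over a shared gene namespace together with the gene
# annotation table, mirroring the "two subnetworks within the same graph"
# layout used when the networks are loaded into a graph database.

#' Construct an expression matrix
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). Values must be finite and
#'   non-negative (FPKM-like).
#' @param condition `"normal"` or `"tumor"`.
#' @return A matrix of class `expression_matrix` with a `condition`
#'   attribute.
#' @export
expression_matrix <- function(values, condition = c("normal", "tumor")) {
  condition <- match.arg(condition)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_input("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop_input("duplicated gene id: ", dup)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_input("expression matrix contains missing or non-finite values")
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop_input("negative expression value at gene ", rownames(values)[bad[1L]],
               ", sample ", colnames(values)[bad[2L]])
  }
  structure(values, condition = condition,
            class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %s: %d genes x %d samples\n",
              attr(x, "condition"), nrow(x), ncol(x)))
  invisible(x)
}

#' Read an expression matrix from a tab-separated file
#'
#' Expected layout: header row of sample ids, first column gene symbols,
#' remaining columns numeric non-negative expression values.
#'
#' @param path File path.
#' @param condition Condition label for the matrix.
#' @return An [expression_matrix()].
#' @export
load_expression <- function(path, condition = c("normal", "tumor")) {
  condition <- match.arg(condition)
  if (!file.exists(path)) stop_input("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_input("malformed expression header in ", path,
                                ": need a gene column plus >=1 sample")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1L]
    stop_input("duplicated gene row in ", path, ": ", dup)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop_input("non-numeric expression values in ", path)
  rownames(vals) <- genes
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop_input("missing value in ", path, " at gene ", genes[bad[1L]],
               ", sample ", colnames(vals)[bad[2L]])
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop_input("negative value in ", path, " at gene ", genes[bad[1L]],
               ", sample ", colnames(vals)[bad[2L]])
  }
  expression_matrix(vals, condition)
}

#' Write an expression matrix as TSV
#'
#' Values are written with 17 significant digits so that reading the file
#' back reproduces the matrix exactly.
#'
#' @param expr An [expression_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  header <- paste(c("gene", colnames(expr)), collapse = "\t")
  body <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i], num_full(expr[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

# Canonical edge order: gene_a < gene_b within a row, rows sorted.
canonical_edges <- function(edges) {
  swap <- edges$gene_a > edges$gene_b
  if (any(swap)) {
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
  }
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Construct a condition graph
#'
#' A weighted undirected graph for one condition. Edges are stored with
#' `gene_a < gene_b`; the node set is derived as the genes incident to at
#' least one edge (genes with no retained co-expression do not count as
#' nodes).
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `weight` and
#'   optionally `rho`. Weights must be positive; self-loops are rejected.
#' @param condition `"normal"` or `"tumor"`.
#' @return An object of class `condition_graph` with elements `condition`,
#'   `nodes` (sorted character) and `edges`.
#' @export
condition_graph <- function(edges, condition = c("normal", "tumor")) {
  condition <- match.arg(condition)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        rho = numeric(), weight = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    need <- c("gene_a", "gene_b", "weight")
    if (!all(need %in% names(edges))) {
      stop_input("edge table needs columns gene_a, gene_b, weight")
    }
    edges$gene_a <- as.character(edges$gene_a)
    edges$gene_b <- as.character(edges$gene_b)
    if (any(edges$gene_a == edges$gene_b)) {
      stop_input("self-loop edge at gene ",
                 edges$gene_a[edges$gene_a == edges$gene_b][1L])
    }
    if (anyNA(edges$weight) || any(edges$weight <= 0)) {
      stop_input("edge weights must be positive")
    }
    if (is.null(edges$rho)) edges$rho <- edges$weight^(1 / 6)
    edges <- canonical_edges(edges[, c("gene_a", "gene_b", "rho", "weight")])
    if (anyDuplicated(edges[, c("gene_a", "gene_b")])) {
      stop_input("duplicated edge in edge table")
    }
  }
  structure(list(condition = condition,
                 nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 edges = edges),
            class = "condition_graph")
}

#' @export
print.condition_graph <- function(x, ...) {
  cat(sprintf("<condition_graph> %s: %d nodes, %d edges\n",
              x$condition, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Construct a gene annotation table
#'
#' @param gene Character vector of unique gene symbols.
#' @param uniprot Character vector of protein accessions.
#' @param description Character vector of free-text descriptions.
#' @param is_tf,is_epigenetic_regulator,is_oncogene 0/1 or logical class
#'   flags.
#' @return Data frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene, uniprot = "", description = "",
                            is_tf = 0L, is_epigenetic_regulator = 0L,
                            is_oncogene = 0L) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) {
    stop_input("duplicated gene symbol in annotation: ",
               gene[duplicated(gene)][1L])
  }
  ann <- data.frame(gene = gene,
                    uniprot = rep_len(as.character(uniprot), length(gene)),
                    description = rep_len(as.character(description),
                                          length(gene)),
                    is_tf = as.integer(rep_len(is_tf, length(gene))),
                    is_epigenetic_regulator =
                      as.integer(rep_len(is_epigenetic_regulator,
                                         length(gene))),
                    is_oncogene = as.integer(rep_len(is_oncogene,
                                                     length(gene))),
                    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

# Gene symbols carrying a given class flag.
class_column <- c(TF = "is_tf", EPIGENETIC = "is_epigenetic_regulator",
                  ONCOGENE = "is_oncogene")

#' Genes annotated with a class label
#'
#' @param annotations A [gene_annotation()] table.
#' @param class One of `"TF"`, `"EPIGENETIC"`, `"ONCOGENE"`.
#' @return Character vector of gene symbols.
#' @export
class_genes <- function(annotations, class = names(class_column)) {
  class <- match.arg(class)
  annotations$gene[annotations[[class_column[[class]]]] == 1L]
}

#' Read / write the gene annotation TSV
#'
#' Columns: gene, uniprot, description, is_tf, is_epigenetic_regulator,
#' is_oncogene.
#'
#' @param path File path.
#' @return [read_annotations()] returns a [gene_annotation()] table.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_input("annotation file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  need <- c("gene", "uniprot", "description", "is_tf",
            "is_epigenetic_regulator", "is_oncogene")
  if (!all(need %in% names(df))) {
    stop_input("annotation file ", path, " must have columns ",
               paste(need, collapse = ", "))
  }
  gene_annotation(df$gene, df$uniprot, df$description, df$is_tf,
                  df$is_epigenetic_regulator, df$is_oncogene)
}

#' @rdname read_annotations
#' @param annotations A [gene_annotation()] table.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a dual (normal + tumor) co-expression graph
#'
#' @param normal,tumor [condition_graph()] objects with conditions
#'   `"normal"` and `"tumor"` respectively.
#' @param annotations A [gene_annotation()] table covering the gene
#'   namespace (may include genes absent from either subnetwork).
#' @return Object of class `dual_graph`.
#' @export
dual_graph <- function(normal, tumor, annotations) {
  if (!inherits(normal, "condition_graph") || normal$condition != "normal") {
    stop_input("`normal` must be a condition_graph with condition 'normal'")
  }
  if (!inherits(tumor, "condition_graph") || tumor$condition != "tumor") {
    stop_input("`tumor` must be a condition_graph with condition 'tumor'")
  }
  if (!inherits(annotations, "gene_annotation")) {
    stop_input("`annotations` must be a gene_annotation table")
  }
  structure(list(normal = normal, tumor = tumor, annotations = annotations),
            class = "dual_graph")
}

#' @export
print.dual_graph <- function(x, ...) {
  cat(sprintf(paste0("<dual_graph> normal: %d nodes / %d edges; ",
                     "tumor: %d nodes / %d edges; %d annotated genes\n"),
              length(x$normal$nodes), nrow(x$normal$edges),
              length(x$tumor$nodes), nrow(x$tumor$edges),
              nrow(x$annotations)))
  invisible(x)
}

#' Write / read a co-expression edge list TSV
#'
#' Columns: gene_a, gene_b, rho, weight, condition. Reading validates the
#' co-expression edge invariants: no self-loops, `weight = rho^6` to
#' machine precision, `weight > 0.25` and `|rho| <= 0.99`.
#'
#' @param graph A [condition_graph()].
#' @param path File path.
#' @return [read_edge_list()] returns a [condition_graph()].
#' @export
write_edge_list <- function(graph, path) {
  e <- graph$edges
  header <- "gene_a\tgene_b\trho\tweight\tcondition"
  body <- if (nrow(e)) {
    paste(e$gene_a, e$gene_b, num_full(e$rho), num_full(e$weight),
          graph$condition, sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop_input("edge list not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "rho", "weight", "condition")
  if (!all(need %in% names(df))) {
    stop_input("edge list ", path, " must have columns ",
               paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) stop_input("edge list ", path, " has no edges")
  cond <- unique(df$condition)
  if (length(cond) != 1L || !cond %in% c("normal", "tumor")) {
    stop_input("edge list ", path, " must carry a single condition label")
  }
  bad <- which(df$gene_a == df$gene_b)
  if (length(bad)) {
    stop_input("edge list row ", bad[1L] + 1L, ": self-loop at gene ",
               df$gene_a[bad[1L]])
  }
  bad <- which(!(df$weight > 0.25))
  if (length(bad)) {
    stop_input("edge list row ", bad[1L] + 1L,
               ": weight must exceed the 0.25 retention threshold")
  }
  bad <- which(abs(df$rho) > 0.99)
  if (length(bad)) {
    stop_input("edge list row ", bad[1L] + 1L,
               ": |rho| above the 0.99 discard threshold")
  }
  bad <- which(abs(df$weight - df$rho^6) >
                 1e-12 * pmax(1, abs(df$weight)))
  if (length(bad)) {
    stop_input("edge list row ", bad[1L] + 1L, ": weight is not rho^6")
  }
  condition_graph(df[, c("gene_a", "gene_b", "rho", "weight")], cond)
}
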