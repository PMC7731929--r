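# Neo4j bulk-import CSV and Cypher loader export.
#
# The bulk-import dialect uses the importer's reserved headers (":ID",
# ":LABEL", ":START_ID", ":END_ID", ":TYPE"); the condition is encoded in
# the relationship type (COEXP_NORMAL / COEXP_TUMOR) so both subnetworks
# live in one graph. All writers sort deterministically so regenerated
# artifacts are byte-identical.

node_label_string <- function(ann_row) {
  labels <- "Gene"
  if (!is.null(ann_row)) {
    if (ann_row$is_tf == 1L) labels <- c(labels, "TF")
    if (ann_row$is_epigenetic_regulator == 1L) {
      labels <- c(labels, "EPIGENETIC")
    }
    if (ann_row$is_oncogene == 1L) labels <- c(labels, "ONCOGENE")
  }
  paste(labels, collapse = ";")
}

dual_node_table <- function(dual) {
  genes <- sort(union(dual$normal$nodes, dual$tumor$nodes))
  ann <- dual$annotations
  idx <- match(genes, ann$gene)
  data.frame(
    gene = genes,
    uniprot = ifelse(is.na(idx), "", ann$uniprot[idx]),
    description = ifelse(is.na(idx), "", ann$description[idx]),
    label = vapply(seq_along(genes), function(i) {
      if (is.na(idx[i])) "Gene" else node_label_string(ann[idx[i], ])
    }, character(1L)),
    stringsAsFactors = FALSE)
}

#' Export a dual graph as Neo4j bulk-import CSV files
#'
#' Writes `nodes.csv` (header `geneId:ID,name,uniprot,description,:LABEL`)
#' with one row per gene in the union of the two subnetworks, and
#' `relationships.csv` (header
#' `:START_ID,:END_ID,weight:double,rho:double,:TYPE`) with one row per
#' edge, typed `COEXP_NORMAL` or `COEXP_TUMOR`. Fields are quoted per RFC
#' 4180 when needed.
#'
#' @param dual A [dual_graph()].
#' @param directory Output directory (created if missing).
#' @return Named character vector with the `nodes` and `relationships`
#'   paths.
#' @export
write_neo4j_csv <- function(dual, directory) {
  if (!inherits(dual, "dual_graph")) stop_input("`dual` must be a dual_graph")
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_input("cannot create directory: ", directory)
  }
  nodes_path <- file.path(directory, "nodes.csv")
  rels_path <- file.path(directory, "relationships.csv")

  nt <- dual_node_table(dual)
  node_lines <- paste(csv_quote(nt$gene), csv_quote(nt$gene),
                      csv_quote(nt$uniprot), csv_quote(nt$description),
                      csv_quote(nt$label), sep = ",")
  writeLines(c("geneId:ID,name,uniprot,description,:LABEL", node_lines),
             nodes_path)

  rel_lines <- unlist(lapply(list(dual$normal, dual$tumor), function(g) {
    if (!nrow(g$edges)) return(character())
    type <- if (g$condition == "normal") "COEXP_NORMAL" else "COEXP_TUMOR"
    paste(csv_quote(g$edges$gene_a), csv_quote(g$edges$gene_b),
          num_short(g$edges$weight), num_short(g$edges$rho), type,
          sep = ",")
  }), use.names = FALSE)
  writeLines(c(":START_ID,:END_ID,weight:double,rho:double,:TYPE",
               rel_lines), rels_path)
  c(nodes = nodes_path, relationships = rels_path)
}

#' Export a dual graph as a Cypher loader script
#'
#' Emits a deterministic text script (uniqueness constraint, one `CREATE`
#' statement per gene node with its class labels, one relationship
#' `CREATE` per edge with `rho` and `weight` properties) that rebuilds the
#' dual graph when executed in a Neo4j instance.
#'
#' @param dual A [dual_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cypher_script <- function(dual, path) {
  if (!inherits(dual, "dual_graph")) stop_input("`dual` must be a dual_graph")
  lines <- c(
    "// Co-expression dual graph loader (generated by coexdiff)",
    paste0("CREATE CONSTRAINT gene_id IF NOT EXISTS ",
           "FOR (g:Gene) REQUIRE g.geneId IS UNIQUE;"))
  nt <- dual_node_table(dual)
  if (nrow(nt)) {
    labels <- gsub(";", ":", nt$label, fixed = TRUE)
    lines <- c(lines, sprintf(
      "CREATE (:%s {geneId: %s, name: %s, uniprot: %s, description: %s});",
      labels, cypher_string(nt$gene), cypher_string(nt$gene),
      cypher_string(nt$uniprot), cypher_string(nt$description)))
  }
  for (g in list(dual$normal, dual$tumor)) {
    if (!nrow(g$edges)) next
    type <- if (g$condition == "normal") "COEXP_NORMAL" else "COEXP_TUMOR"
    lines <- c(lines, sprintf(
      paste0("MATCH (a:Gene {geneId: %s}), (b:Gene {geneId: %s}) ",
             "CREATE (a)-[:%s {rho: %s, weight: %s}]->(b);"),
      cypher_string(g$edges$gene_a), cypher_string(g$edges$gene_b), type,
      num_short(g$edges$rho), num_short(g$edges$weight)))
  }
  writeLines(lines, path)
  invisible(path)
}
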