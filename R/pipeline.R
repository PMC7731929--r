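# End-to-end pipeline: simulate (or load) -> build networks -> centrality,
# communities, paths -> differential comparison -> enrichment -> export.
# All stage outputs are pure functions of (inputs, config, seed); a run
# manifest records the configuration and per-stage row counts.

#' Pipeline run configuration
#'
#' @param synthetic A [synthetic_config()] to simulate input data, or
#'   `NULL` to read files.
#' @param normal_path,tumor_path,annotation_path,gene_sets_path Input
#'   file paths (used when `synthetic` is `NULL`).
#' @param power,retention,discard Edge-rule parameters; see
#'   [build_network()].
#' @param damping PageRank damping factor.
#' @param min_community_size Community size cutoff for degree-change and
#'   enrichment summaries.
#' @param path_mode `"hops"` or `"inverse_weight"`.
#' @param seed Top-level seed; per-stage seeds derive from it.
#' @param out_dir Output directory for all artifacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       normal_path = NULL, tumor_path = NULL,
                       annotation_path = NULL, gene_sets_path = NULL,
                       power = 6, retention = 0.25, discard = 0.99,
                       damping = 0.85, min_community_size = 50L,
                       path_mode = c("hops", "inverse_weight"),
                       seed = 42L, out_dir = tempfile("coexdiff_run_")) {
  path_mode <- match.arg(path_mode)
  if (!is_count(power) || power < 1) {
    stop_input("power must be a positive integer")
  }
  for (nm in c("retention", "discard", "damping")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop_input(nm, " must lie strictly between 0 and 1")
    }
  }
  if (is.null(synthetic)) {
    for (p in c(normal_path, tumor_path, annotation_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop_input("missing input file: ", p %||% "(unset path)")
      }
    }
  } else if (!inherits(synthetic, "synthetic_config")) {
    stop_input("`synthetic` must be NULL or a synthetic_config")
  }
  structure(list(synthetic = synthetic, normal_path = normal_path,
                 tumor_path = tumor_path,
                 annotation_path = annotation_path,
                 gene_sets_path = gene_sets_path, power = power,
                 retention = retention, discard = discard,
                 damping = damping,
                 min_community_size = as.integer(min_community_size),
                 path_mode = path_mode, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full differential co-expression pipeline
#'
#' Executes every stage in order and writes all artifacts below
#' `config$out_dir`: expression TSVs (synthetic runs), per-condition edge
#' lists, the centrality table, community assignments, class-pair path
#' table, differential summary, enrichment table, Neo4j CSV/Cypher
#' exports and a JSON manifest. Rerunning with the same configuration and
#' seed reproduces identical artifacts (manifest timestamp aside).
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly: configuration echo, artifact paths,
#'   per-stage counts and headline differential statistics.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) {
    stop_input("`config` must come from run_config()")
  }
  out <- config$out_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE,
                                      showWarnings = FALSE)) {
    stop_input("cannot create output directory: ", out)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_input("pipeline stage '", name, "' failed: ",
                 conditionMessage(e))
    })
  }
  artifacts <- list()

  # -- stage: input ---------------------------------------------------------
  if (!is.null(config$synthetic)) {
    dataset <- stage("simulate", generate_dataset(config$synthetic))
    fix <- stage("simulate", write_fixture(dataset,
                                           file.path(out, "input")))
    artifacts$input <- as.list(fix)
    normal_expr <- dataset$normal
    tumor_expr <- dataset$tumor
    annotations <- dataset$annotations
    collection <- dataset$gene_sets
  } else {
    normal_expr <- stage("load", load_expression(config$normal_path,
                                                 "normal"))
    tumor_expr <- stage("load", load_expression(config$tumor_path,
                                                "tumor"))
    annotations <- stage("load", read_annotations(config$annotation_path))
    collection <- if (!is.null(config$gene_sets_path)) {
      stage("load", read_gmt(config$gene_sets_path))
    }
  }

  # -- stage: build ---------------------------------------------------------
  g_normal <- stage("build", build_network(normal_expr, config$power,
                                           config$retention,
                                           config$discard))
  g_tumor <- stage("build", build_network(tumor_expr, config$power,
                                          config$retention,
                                          config$discard))
  dual <- stage("build", dual_graph(g_normal, g_tumor, annotations))
  artifacts$edges_normal <- file.path(out, "edges_normal.tsv")
  artifacts$edges_tumor <- file.path(out, "edges_tumor.tsv")
  write_edge_list(g_normal, artifacts$edges_normal)
  write_edge_list(g_tumor, artifacts$edges_tumor)

  # -- stage: centrality ----------------------------------------------------
  ctab <- stage("centrality", centrality_table(dual, config$damping))
  artifacts$centrality <- file.path(out, "centrality.tsv")
  utils::write.table(ctab, artifacts$centrality, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # -- stage: communities ---------------------------------------------------
  parts <- stage("communities", list(
    normal = louvain(g_normal, config$seed),
    tumor = louvain(g_tumor, config$seed + 1L)))
  comm_df <- do.call(rbind, lapply(parts, function(p) {
    data.frame(gene = names(p$assignment),
               community = unname(p$assignment),
               condition = p$condition, stringsAsFactors = FALSE)
  }))
  artifacts$communities <- file.path(out, "communities.tsv")
  utils::write.table(comm_df, artifacts$communities, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # -- stage: differential --------------------------------------------------
  report <- stage("differential", differential_report(
    dual, table = ctab, tumor_partition = parts$tumor,
    min_community_size = config$min_community_size,
    path_mode = config$path_mode))
  path_df <- rbind(cbind(report$paths$normal, condition = "normal"),
                   cbind(report$paths$tumor, condition = "tumor"))
  path_df$length <- ifelse(is.infinite(path_df$length), "inf",
                           as.character(path_df$length))
  artifacts$paths <- file.path(out, "class_pair_paths.tsv")
  utils::write.table(path_df, artifacts$paths, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  artifacts$differential <- file.path(out, "differential_summary.txt")
  writeLines(format_differential(report, parts), artifacts$differential)

  # -- stage: enrichment ----------------------------------------------------
  enr <- NULL
  if (!is.null(collection) && length(collection$sets)) {
    enr <- stage("enrichment", suppressWarnings(enrich_communities(
      parts$tumor, collection, universe = annotations$gene,
      min_size = config$min_community_size)))
    artifacts$enrichment <- file.path(out, "enrichment.tsv")
    utils::write.table(enr, artifacts$enrichment, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # -- stage: export --------------------------------------------------------
  neo <- stage("export", write_neo4j_csv(dual, file.path(out, "neo4j")))
  artifacts$neo4j_nodes <- unname(neo[["nodes"]])
  artifacts$neo4j_relationships <- unname(neo[["relationships"]])
  artifacts$cypher <- file.path(out, "load_graph.cypher")
  write_cypher_script(dual, artifacts$cypher)

  manifest <- list(
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("coexdiff")),
    seed = config$seed,
    parameters = list(power = config$power, retention = config$retention,
                      discard = config$discard, damping = config$damping,
                      min_community_size = config$min_community_size,
                      path_mode = config$path_mode),
    synthetic = if (!is.null(config$synthetic)) {
      cfg <- unclass(config$synthetic)
      cfg$modules <- as.list(cfg$modules)
      cfg
    },
    counts = list(
      nodes_normal = length(g_normal$nodes),
      nodes_tumor = length(g_tumor$nodes),
      edges_normal = nrow(g_normal$edges),
      edges_tumor = nrow(g_tumor$edges),
      communities_normal = length(unique(parts$normal$assignment)),
      communities_tumor = length(unique(parts$tumor$assignment)),
      class_pairs = nrow(report$paths$normal),
      enrichment_rows = if (is.null(enr)) 0L else nrow(enr)),
    statistics = list(
      node_fold = report$size_fold$node_fold,
      edge_fold = report$size_fold$edge_fold,
      lost_tf_oncogene_edges = report$lost_tf_oncogene$count,
      lost_epigenetic_oncogene_edges =
        report$lost_epigenetic_oncogene$count,
      centrality_shift_fractions =
        as.list(report$centrality_shift$fractions),
      mean_path_length = as.list(report$path_summary$mean_length),
      infinite_paths = as.list(report$path_summary$infinite_count)),
    artifacts = artifacts)
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  manifest$artifacts$manifest <- manifest_path
  invisible(manifest)
}

format_differential <- function(report, parts) {
  sf <- report$size_fold
  ps <- report$path_summary
  c(sprintf("node fold change (normal/tumor): %.4f", sf$node_fold),
    sprintf("edge fold change (normal/tumor): %.4f", sf$edge_fold),
    sprintf("lost TF-oncogene edges: %d", report$lost_tf_oncogene$count),
    sprintf("lost epigenetic-oncogene edges: %d",
            report$lost_epigenetic_oncogene$count),
    sprintf("communities: normal %d (Q = %.4f), tumor %d (Q = %.4f)",
            length(unique(parts$normal$assignment)),
            parts$normal$modularity,
            length(unique(parts$tumor$assignment)),
            parts$tumor$modularity),
    "centrality shift fractions:",
    sprintf("  %s: %.4f", names(report$centrality_shift$fractions),
            report$centrality_shift$fractions),
    sprintf("mean finite path length: normal %.4f, tumor %.4f",
            ps$mean_length[["normal"]], ps$mean_length[["tumor"]]),
    sprintf("infinite paths: normal %d, tumor %d",
            ps$infinite_count[["normal"]], ps$infinite_count[["tumor"]]),
    if (!is.null(ps$modal_transition)) {
      sprintf("modal finite path transition: %g -> %g",
              ps$modal_transition[["normal"]],
              ps$modal_transition[["tumor"]])
    })
}
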