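test_that("size fold changes are normal over tumor counts", {
  ann <- gene_annotation(letters[1:6])
  e <- data.frame(gene_a = c("a", "a", "b", "c", "d"),
                  gene_b = c("b", "c", "c", "d", "e"), weight = 0.5)
  same <- make_dual(e, e, ann)
  expect_equal(size_fold_change(same), list(node_fold = 1, edge_fold = 1))
  shrunk <- make_dual(e, e[1:2, ], ann)
  sf <- size_fold_change(shrunk)
  expect_equal(sf$node_fold, 5 / 3)
  expect_equal(sf$edge_fold, 5 / 2)
  empty_t <- make_dual(e, NULL, ann)
  expect_warning(sf2 <- size_fold_change(empty_t), "infinite")
  expect_true(is.infinite(sf2$edge_fold))
})

test_that("lost class edges are symmetric and match a set-difference oracle", {
  ann <- gene_annotation(c("t1", "t2", "o1", "o2", "x"),
                         is_tf = c(1L, 1L, 0L, 0L, 0L),
                         is_oncogene = c(0L, 0L, 1L, 1L, 0L))
  norm <- data.frame(gene_a = c("o1", "o1", "o2", "o1"),
                     gene_b = c("t1", "t2", "t2", "x"), weight = 0.5)
  tum <- norm[2, , drop = FALSE]
  dual <- make_dual(norm, tum, ann)
  res <- lost_class_edges(dual, "TF", "ONCOGENE")
  expect_equal(res$count, 2L)  # o1-t1 and o2-t2 lost; o1-x is not class-pair
  expect_setequal(paste(res$edges$gene_a, res$edges$gene_b),
                  c("o1 t1", "o2 t2"))
  rev <- lost_class_edges(dual, "ONCOGENE", "TF")
  expect_identical(res, rev)
  expect_equal(lost_class_edges(make_dual(norm, norm, ann))$count, 0L)
})

test_that("centrality shifts reproduce the published table categories", {
  tab <- data.frame(
    gene = c("TNRC6A", "RIF1", "FLAT", "GROW"),
    pagerank_normal = c(4.426214, 2.503803, 1.0, 1.0),
    pagerank_tumor = c(0.652741, 7.365182, 1.0, 2.0),
    degree_normal = c(653L, 325L, 3L, 3L),
    degree_tumor = c(4L, 80L, 3L, 9L), stringsAsFactors = FALSE)
  class(tab) <- c("centrality_table", "data.frame")
  res <- centrality_shift_classify(tab)
  expect_identical(unname(res$category["TNRC6A"]), "decreased")
  expect_identical(unname(res$category["RIF1"]), "relative_increase")
  expect_identical(unname(res$category["FLAT"]), "unchanged")
  expect_identical(unname(res$category["GROW"]), "absolute_increase")
  expect_equal(sum(res$fractions), 1)
})

test_that("cross-network correlations and the group t-test behave", {
  s <- c(a = 1, b = 2, c = 3)
  res <- cross_network_centrality_correlation(
    list(n1 = s, n2 = s, t1 = s, t2 = s),
    groups = c(n1 = "normal", n2 = "normal", t1 = "tumor", t2 = "tumor"))
  expect_true(all(res$pairs$r == 1))

  # hand-derived Pearson for (1,2,3) vs (1,2,4)
  v1 <- c(g1 = 1, g2 = 2, g3 = 3)
  v2 <- c(g1 = 1, g2 = 2, g3 = 4)
  res2 <- cross_network_centrality_correlation(
    list(n1 = v1, n2 = v2, t1 = v1, t2 = v1),
    groups = c(n1 = "normal", n2 = "normal", t1 = "tumor", t2 = "tumor"))
  rn <- res2$pairs$r[res2$pairs$group == "normal"]
  expect_equal(rn, 0.9819805, tolerance = 1e-6)

  # group comparison: p derives from a Welch test on the pairwise r sets
  set.seed(41)
  genes <- sprintf("g%02d", 1:30)
  rnd <- function() stats::setNames(runif(30), genes)
  scores <- list(n1 = rnd(), n2 = rnd(), n3 = rnd(),
                 t1 = rnd(), t2 = rnd(), t3 = rnd())
  groups <- c(n1 = "normal", n2 = "normal", n3 = "normal",
              t1 = "tumor", t2 = "tumor", t3 = "tumor")
  res3 <- cross_network_centrality_correlation(scores, groups)
  rt <- res3$pairs$r[res3$pairs$group == "tumor"]
  rn2 <- res3$pairs$r[res3$pairs$group == "normal"]
  expect_equal(res3$p_value, t.test(rt, rn2)$p.value)
  expect_equal(res3$group_means[["tumor"]], mean(rt))
})

test_that("pair exclusions are honored in the group comparison", {
  v1 <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 5)
  v2 <- c(g1 = 1, g2 = 2, g3 = 4, g4 = 9)
  v3 <- c(g1 = 2, g2 = 1, g3 = 5, g4 = 4)
  scores <- list(n1 = v1, n2 = v2, n3 = v3, t1 = v1, t2 = v2, t3 = v3)
  groups <- c(n1 = "normal", n2 = "normal", n3 = "normal",
              t1 = "tumor", t2 = "tumor", t3 = "tumor")
  full <- cross_network_centrality_correlation(scores, groups)
  excl <- cross_network_centrality_correlation(
    scores, groups, exclusions = list(c("n1", "n2")))
  expect_true(excl$pairs$excluded[excl$pairs$network_a == "n1" &
                                    excl$pairs$network_b == "n2"])
  expect_false(isTRUE(all.equal(full$group_means[["normal"]],
                                excl$group_means[["normal"]])))
  expect_equal(full$group_means[["tumor"]], excl$group_means[["tumor"]])
})

test_that("recurrent degree gain requires the minimum number of types", {
  mk_tab <- function(gain) {
    tab <- data.frame(gene = c("g1", "g2"),
                      pagerank_normal = 1, pagerank_tumor = 1,
                      degree_normal = c(2L, 2L),
                      degree_tumor = c(ifelse(gain, 5L, 1L), 1L))
    class(tab) <- c("centrality_table", "data.frame")
    tab
  }
  tabs5 <- c(lapply(1:5, function(i) mk_tab(TRUE)), list(mk_tab(FALSE)))
  expect_identical(recurrent_degree_gain(tabs5, 5L), "g1")
  tabs4 <- c(lapply(1:4, function(i) mk_tab(TRUE)),
             lapply(1:2, function(i) mk_tab(FALSE)))
  expect_length(recurrent_degree_gain(tabs4, 5L), 0L)
  expect_error(recurrent_degree_gain(tabs4[1:3], 5L), "min_types")
})

test_that("planted gained hubs show tumor-specific degree gain", {
  cfg <- synthetic_config(n_genes = 200L, n_samples = 40L,
                          modules = data.frame(size = c(25L, 25L),
                                               loading = 0.92),
                          dissolve_fraction = 0, rewire_fraction = 0,
                          gained_hub_count = 10L, seed = 17L)
  ds <- generate_dataset(cfg)
  dual <- dual_graph(build_network(ds$normal), build_network(ds$tumor),
                     ds$annotations)
  tab <- centrality_table(dual)
  hubs <- ds$truth$gained_hubs
  gain <- tab$degree_tumor[match(hubs, tab$gene)] >
    tab$degree_normal[match(hubs, tab$gene)]
  expect_true(all(gain))
})

test_that("community degree change summarizes large communities only", {
  genes <- sprintf("g%03d", 1:70)
  assign <- stats::setNames(c(rep(1L, 60), rep(2L, 10)), genes)
  part <- structure(list(condition = "tumor", assignment = assign,
                         modularity = 0.1),
                    class = "community_partition")
  tab <- data.frame(gene = genes, pagerank_normal = 1, pagerank_tumor = 1,
                    degree_normal = 2L,
                    degree_tumor = c(rep(5L, 60), rep(2L, 10)))
  class(tab) <- c("centrality_table", "data.frame")
  res <- community_degree_change(part, tab, min_size = 50L)
  expect_equal(nrow(res), 1L)
  expect_equal(res$median, 3)
  expect_warning(res2 <- community_degree_change(part, tab,
                                                 min_size = 65L),
                 "min_size")
  expect_equal(nrow(res2), 0L)
})

test_that("gained-hub community has the largest median degree change", {
  cfg <- synthetic_config(n_genes = 200L, n_samples = 40L,
                          modules = data.frame(size = c(25L, 25L),
                                               loading = 0.92),
                          dissolve_fraction = 0, rewire_fraction = 0,
                          gained_hub_count = 12L, seed = 23L)
  ds <- generate_dataset(cfg)
  dual <- dual_graph(build_network(ds$normal), build_network(ds$tumor),
                     ds$annotations)
  part <- louvain(dual$tumor, seed = 1)
  tab <- centrality_table(dual)
  res <- community_degree_change(part, tab, min_size = 10L)
  hub_comm <- unique(part$assignment[intersect(ds$truth$gained_hubs,
                                               names(part$assignment))])
  expect_length(hub_comm, 1L)
  expect_equal(res$community[which.max(res$median)], hub_comm)
  expect_gt(max(res$median), sort(res$median, decreasing = TRUE)[2])
})

test_that("path summaries follow the hand-enumerated example", {
  pn <- data.frame(source = c("a", "b", "c"), target = c("x", "y", "z"),
                   length = c(2, 2, 4))
  pt <- data.frame(source = c("a", "b", "c"), target = c("x", "y", "z"),
                   length = c(4, 4, Inf))
  res <- path_length_change_summary(pn, pt)
  expect_equal(unname(res$mean_length), c(8 / 3, 4))
  expect_equal(unname(res$infinite_count), c(0L, 1L))
  expect_equal(unname(res$modal_transition), c(2, 4))

  # invariant to pair ordering
  res2 <- path_length_change_summary(pn[c(3, 1, 2), ], pt)
  expect_equal(res2$mean_length, res$mean_length)

  same <- path_length_change_summary(pn, pn)
  expect_equal(same$mean_length[["normal"]], same$mean_length[["tumor"]])
  expect_true(all(same$joint_histogram$length_normal ==
                    same$joint_histogram$length_tumor))

  all_inf <- pt; all_inf$length <- Inf
  res3 <- path_length_change_summary(pn, all_inf)
  expect_true(is.na(res3$mean_length[["tumor"]]))
  expect_equal(unname(res3$infinite_count[["tumor"]]), 3L)
  expect_null(res3$modal_transition)

  expect_error(path_length_change_summary(pn, pt[1:2, ]),
               "different pair universes")
})

test_that("edge fold change grows with the dissolution fraction", {
  folds <- vapply(c(0, 0.25, 0.5, 1), function(p) {
    cfg <- synthetic_config(n_genes = 120L, n_samples = 30L,
                            modules = data.frame(size = rep(20L, 4L),
                                                 loading = 0.92),
                            dissolve_fraction = p, rewire_fraction = 0,
                            gained_hub_count = 0L, seed = 31L)
    ds <- generate_dataset(cfg)
    dual <- dual_graph(build_network(ds$normal),
                       build_network(ds$tumor), ds$annotations)
    suppressWarnings(size_fold_change(dual)$edge_fold)
  }, numeric(1L))
  expect_true(all(diff(folds) > 0))
})
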