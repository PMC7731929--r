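test_that("pagerank reproduces closed-form fixed points", {
  # two nodes, one edge: symmetric fixed point of s = (1-d) + d*s is 1
  g2 <- condition_graph(data.frame(gene_a = "a", gene_b = "b",
                                   weight = 0.4), "normal")
  expect_equal(unname(pagerank(g2)), c(1, 1), tolerance = 1e-9)
  # path graph a-b-c with equal weights, solved as a 3x3 linear system
  g3 <- condition_graph(data.frame(gene_a = c("a", "b"),
                                   gene_b = c("b", "c"),
                                   weight = c(0.5, 0.5)), "normal")
  s <- pagerank(g3)
  # solving s_a = 0.15 + 0.425 s_b, s_b = 0.15 + 1.7 s_a by hand:
  expect_equal(unname(s[c("a", "c")]), rep(0.21375 / 0.2775, 2),
               tolerance = 1e-6)
  expect_equal(unname(s[c("a", "c")]), rep(0.7702703, 2), tolerance = 1e-6)
  expect_equal(unname(s["b"]), 1.4594594, tolerance = 1e-6)
  expect_equal(sum(s), 3, tolerance = 1e-6)
})

test_that("pagerank matches the linear-system oracle on random graphs", {
  for (seed in 1:10) {
    g <- random_graph(sample(5:30, 1L), p = 0.25, seed = seed)
    s <- pagerank(g, tol = 1e-10)
    expect_lt(max(abs(s - pagerank_solve(g)[names(s)])), 1e-6)
    expect_true(all(s >= 0.15 - 1e-12))  # monotone floor 1 - d
  }
})

test_that("degree counts incident edges and absent genes score zero", {
  tri <- condition_graph(data.frame(gene_a = c("a", "a", "b"),
                                    gene_b = c("b", "c", "c"),
                                    weight = 0.5), "normal")
  expect_equal(unname(node_degree(tri)), c(2L, 2L, 2L))
  star <- condition_graph(data.frame(gene_a = "hub",
                                     gene_b = paste0("l", 1:5),
                                     weight = 0.5), "normal")
  d <- node_degree(star, genes = c("hub", paste0("l", 1:5), "ghost"))
  expect_equal(unname(d["hub"]), 5L)
  expect_true(all(d[paste0("l", 1:5)] == 1L))
  expect_equal(unname(d["ghost"]), 0L)
})

test_that("modularity matches hand-derived values and rejects bad input", {
  pairg <- condition_graph(data.frame(gene_a = "a", gene_b = "b",
                                      weight = 1), "normal")
  # singleton partition of one unit edge: Q = -2 * (1/2)^2 = -0.5
  expect_equal(modularity_q(pairg, c(a = 1L, b = 2L)), -0.5)
  bridge <- condition_graph(
    data.frame(gene_a = c("a", "a", "b", "d", "d", "e", "c"),
               gene_b = c("b", "c", "c", "e", "f", "f", "d"),
               weight = 1), "normal")
  part <- c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L, f = 2L)
  expect_equal(modularity_q(bridge, part), 2 * (3 / 7 - 0.25),
               tolerance = 1e-12)
  expect_error(modularity_q(bridge, part[-1]), "does not cover")
  empty <- condition_graph(NULL, "normal")
  expect_error(modularity_q(empty, integer()), "undefined")
})

test_that("louvain resolves planted structure and reports recomputed Q", {
  two_tri <- condition_graph(
    data.frame(gene_a = c("a", "a", "b", "d", "d", "e"),
               gene_b = c("b", "c", "c", "e", "f", "f"),
               weight = 1), "normal")
  p <- louvain(two_tri, seed = 1)
  expect_length(unique(p$assignment), 2L)
  expect_length(unique(p$assignment[c("a", "b", "c")]), 1L)
  expect_length(unique(p$assignment[c("d", "e", "f")]), 1L)
  expect_identical(p$modularity, modularity_q(two_tri, p$assignment))

  clique5 <- t(combn(paste0("v", 1:5), 2))
  g5 <- condition_graph(data.frame(gene_a = clique5[, 1],
                                   gene_b = clique5[, 2], weight = 1),
                        "normal")
  expect_length(unique(louvain(g5, seed = 2)$assignment), 1L)

  bridge <- condition_graph(
    data.frame(gene_a = c("a", "a", "b", "d", "d", "e", "c"),
               gene_b = c("b", "c", "c", "e", "f", "f", "d"),
               weight = 1), "normal")
  pb <- louvain(bridge, seed = 3)
  expect_equal(pb$modularity, 2 * (3 / 7 - 0.25), tolerance = 1e-12)
})

test_that("louvain is competitive with an independent implementation", {
  skip_if_not_installed("igraph")
  for (seed in c(4, 9, 21)) {
    g <- random_graph(40, p = 0.12, seed = seed)
    ours <- louvain(g, seed = seed)
    ig <- igraph::graph_from_data_frame(
      g$edges[, c("gene_a", "gene_b", "weight")], directed = FALSE)
    ref <- igraph::cluster_louvain(ig, weights = igraph::E(ig)$weight)
    ref_q <- igraph::modularity(ig, igraph::membership(ref),
                                weights = igraph::E(ig)$weight)
    expect_gte(ours$modularity, ref_q - 0.02)
  }
})

test_that("louvain is deterministic given a seed", {
  g <- random_graph(30, p = 0.15, seed = 12)
  expect_identical(louvain(g, seed = 5)$assignment,
                   louvain(g, seed = 5)$assignment)
})

test_that("scale-free fit separates hub-dominated from uniform graphs", {
  skip_if_not_installed("igraph")
  set.seed(20)
  pa <- igraph::sample_pa(1000, m = 3, directed = FALSE)
  epa <- igraph::as_edgelist(pa)
  gpa <- condition_graph(data.frame(gene_a = paste0("g", epa[, 1]),
                                    gene_b = paste0("g", epa[, 2]),
                                    weight = 0.5), "normal")
  fit_pa <- scale_free_fit(gpa)
  expect_gt(fit_pa$r_squared, 0.8)
  expect_lt(fit_pa$slope, 0)

  er <- igraph::sample_gnm(1000, igraph::ecount(pa))
  eer <- igraph::as_edgelist(er)
  ger <- condition_graph(data.frame(gene_a = paste0("g", eer[, 1]),
                                    gene_b = paste0("g", eer[, 2]),
                                    weight = 0.5), "normal")
  expect_lt(scale_free_fit(ger)$r_squared, fit_pa$r_squared)
})

test_that("scale-free fit rejects degenerate degree distributions", {
  ring <- condition_graph(data.frame(gene_a = paste0("r", 1:6),
                                     gene_b = paste0("r", c(2:6, 1)),
                                     weight = 0.5), "normal")
  expect_error(scale_free_fit(ring), "distinct degree")
})
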