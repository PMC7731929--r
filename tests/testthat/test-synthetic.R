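# Small configuration reused across generator tests.
small_config <- function(seed = 7L) {
  synthetic_config(n_genes = 150L, n_samples = 40L,
                   modules = data.frame(size = c(20L, 20L, 20L),
                                        loading = 0.92),
                   dissolve_fraction = 1 / 3, rewire_fraction = 0.05,
                   gained_hub_count = 8L, seed = seed)
}

test_that("generation is deterministic given seed and config", {
  d1 <- generate_dataset(small_config())
  d2 <- generate_dataset(small_config())
  expect_identical(unclass(d1$normal), unclass(d2$normal))
  expect_identical(unclass(d1$tumor), unclass(d2$tumor))
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(small_config(seed = 8L))
  expect_false(identical(unclass(d1$normal), unclass(d3$normal)))
})

test_that("invalid configurations name the violated invariant", {
  expect_error(synthetic_config(n_genes = 50,
                                modules = data.frame(size = 60,
                                                     loading = 0.9)),
               "module sizes exceeds n_genes")
  expect_error(synthetic_config(modules = data.frame(size = 10,
                                                     loading = 1)),
               "discard rule")
  expect_error(synthetic_config(dissolve_fraction = 1.5), "dissolve")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(n_genes = 100, gained_hub_count = 90,
                                modules = data.frame(size = 50,
                                                     loading = 0.9)),
               "gained_hub_count")
})

test_that("a module-free dataset yields the permutation-null edge count", {
  cfg <- synthetic_config(n_genes = 150L, n_samples = 20L,
                          modules = data.frame(size = integer(),
                                               loading = numeric()),
                          dissolve_fraction = 0, rewire_fraction = 0,
                          gained_hub_count = 0L, seed = 5L)
  ds <- generate_dataset(cfg)
  g <- build_network(ds$normal)
  # null probability of |rho| falling in the retained band, estimated by
  # a permutation simulation at the same sample size
  set.seed(99)
  lo <- 0.25^(1 / 6)
  rho_null <- replicate(20000, cor(sample(20L), sample(20L),
                                   method = "spearman"))
  q <- mean(abs(rho_null) > lo & abs(rho_null) <= 0.99)
  expected <- choose(150, 2) * q
  tol <- 5 * sqrt(expected + 1)
  expect_lte(abs(nrow(g$edges) - expected), tol)
})

test_that("full dissolution destroys within-module correlation in tumor", {
  cfg <- synthetic_config(n_genes = 60L, n_samples = 60L,
                          modules = data.frame(size = 40L, loading = 0.95),
                          dissolve_fraction = 1, rewire_fraction = 0,
                          gained_hub_count = 0L, seed = 3L)
  ds <- generate_dataset(cfg)
  mod_genes <- names(ds$truth$module_assignment)[
    ds$truth$module_assignment == 1L]
  rho_t <- cor(t(unclass(ds$tumor)[mod_genes, ]), method = "spearman")
  expect_lt(mean(abs(rho_t[upper.tri(rho_t)])), 0.3)
  # the same module is strongly correlated in normal
  rho_n <- cor(t(unclass(ds$normal)[mod_genes, ]), method = "spearman")
  expect_gt(mean(rho_n[upper.tri(rho_n)]), 0.8)
})

test_that("planted within-module correlation concentrates in the band", {
  ds <- generate_dataset(small_config())
  lo <- 0.25^(1 / 6)
  for (m in 1:3) {
    genes <- names(ds$truth$module_assignment)[
      ds$truth$module_assignment == m]
    rho <- cor(t(unclass(ds$normal)[genes, ]), method = "spearman")
    up <- rho[upper.tri(rho)]
    expect_gt(mean(up > lo & up <= 0.99), 0.9)
  }
})

test_that("class label counts match configured fractions within rounding", {
  ds <- generate_dataset(small_config())
  fr <- ds$config$class_fractions
  expect_lte(abs(length(ds$truth$class_labels$TF) -
                   fr[["tf"]] * 150), 1)
  expect_lte(abs(length(ds$truth$class_labels$EPIGENETIC) -
                   fr[["epigenetic_regulator"]] * 150), 1)
  expect_lte(abs(length(ds$truth$class_labels$ONCOGENE) -
                   fr[["oncogene"]] * 150), 1)
  # every gene has exactly one module assignment (0 = background)
  expect_identical(sort(names(ds$truth$module_assignment)),
                   sort(ds$annotations$gene))
  expect_true(all(ds$truth$dissolved_modules %in% 1:3))
})

test_that("fixtures round-trip exactly and the GMT has the right shape", {
  ds <- generate_dataset(small_config())
  dir <- withr::local_tempdir()
  paths <- write_fixture(ds, dir)
  expect_true(all(file.exists(paths)))
  back_n <- load_expression(paths[["normal"]], "normal")
  back_t <- load_expression(paths[["tumor"]], "tumor")
  expect_identical(unclass(back_n), unclass(ds$normal))
  expect_identical(unclass(back_t), unclass(ds$tumor))
  gmt <- read_gmt(paths[["gene_sets"]])
  expect_setequal(grep("^MODULE_", names(gmt$sets), value = TRUE),
                  c("MODULE_1", "MODULE_2", "MODULE_3"))
  expect_length(grep("^DECOY_", names(gmt$sets)), 10L)
  expect_setequal(gmt$sets$MODULE_2$genes,
                  names(ds$truth$module_assignment)[
                    ds$truth$module_assignment == 2L])
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_setequal(unlist(truth$gained_hubs), ds$truth$gained_hubs)
})

test_that("an empty module list yields a decoy-only GMT", {
  cfg <- synthetic_config(n_genes = 50L, n_samples = 10L,
                          modules = data.frame(size = integer(),
                                               loading = numeric()),
                          gained_hub_count = 0L, seed = 2L)
  ds <- generate_dataset(cfg)
  expect_true(all(grepl("^DECOY_", names(ds$gene_sets$sets))))
})
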