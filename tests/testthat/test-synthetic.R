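test_that("generated networks plant the promised motifs", {
  cfg <- synthetic_config(seed = 1)
  gn <- generate_network(cfg)
  expect_equal(n_nodes(gn$network), 40L)
  expect_equal(n_edges(gn$network) - n_self_loops(gn$network), 120L)
  expect_equal(n_self_loops(gn$network), 4L)
  expect_length(gn$planted, 8L)
  ## planted sets are vertex-disjoint and tetramer-like
  expect_equal(anyDuplicated(unlist(gn$planted)), 0L)
  expect_gte(count_tetramer_like(gn$network), 8L)
  for (q in gn$planted)
    expect_true(is_connected_subset(gn$network, q))

  ## an exact edge budget yields exactly the disjoint squares
  cfg2 <- synthetic_config(n_nodes = 16, n_edges = 16,
                           n_planted_quads = 4, n_self_loops = 0,
                           n_tissues = 4, seed = 2)
  gn2 <- generate_network(cfg2)
  expect_equal(count_tetramer_like(gn2$network), 4L)
  expect_equal(n_edges(gn2$network), 16L)

  ## fixed seed reproduces the network exactly
  gn3 <- generate_network(cfg)
  expect_identical(gn3$network$edges, gn$network$edges)
  expect_identical(gn3$planted, gn$planted)
})

test_that("configuration validation rejects infeasible designs", {
  expect_error(synthetic_config(n_nodes = 10, n_planted_quads = 4),
               "not enough nodes")
  expect_error(synthetic_config(n_edges = 20, n_planted_quads = 8),
               "edge budget")
  expect_error(synthetic_config(p_in = 1.4), "probabilities")
  expect_error(synthetic_config(threshold = 9), "expr_low < threshold")
  expect_error(synthetic_config(n_tissues = 4, n_planted_quads = 8),
               "tissue per planted set")
})

test_that("extreme call probabilities give deterministic co-expression", {
  cfg <- synthetic_config(p_in = 1, p_out = 0, seed = 3)
  study <- generate_synthetic_study(cfg)
  ## every planted set is co-expressed, every other 4-set never
  keyp <- vapply(study$planted, paste, "", collapse = "|")
  df <- connected_foursets(study$network, study$calls, study$gene_map)
  keys <- apply(df[, 1:4], 1, paste, collapse = "|")
  expect_true(all((df$n_joint_tissues > 0) == (keys %in% keyp)))

  ## p_in = 0 silences the planted sets entirely
  cfg0 <- synthetic_config(p_in = 0, p_out = 0, seed = 4)
  study0 <- generate_synthetic_study(cfg0)
  pro <- prospective_tetramers(study0$network, study0$calls,
                               study0$gene_map)
  expect_equal(nrow(pro), 0L)
})

test_that("thresholding the generated matrix recovers the designed calls", {
  study <- generate_synthetic_study(synthetic_config(seed = 5))
  ## values sit in narrow bands around the high and low levels
  expect_true(all(study$expression[study$calls] > 7))
  expect_true(all(study$expression[!study$calls] < 2))
})

test_that("clade annotation respects the planted-in-MIKC contract", {
  study <- generate_synthetic_study(synthetic_config(seed = 6))
  counts <- partition_by_clade(study$planted, study$annotation)
  expect_equal(unname(counts["MIKC-only"]), 8L)
  expect_equal(sum(study$annotation == "MIKC"), round(0.85 * 40))
  ## frac_mikc = 1 leaves no non-MIKC proteins at all
  s1 <- generate_synthetic_study(synthetic_config(frac_mikc = 1, seed = 7))
  expect_true(all(s1$annotation == "MIKC"))
  ## too small a MIKC fraction cannot hold the planted members
  cfg_bad <- synthetic_config(frac_mikc = 0.5, seed = 8)
  gn <- generate_network(cfg_bad)
  expect_error(generate_annotation(cfg_bad, gn$network$nodes, gn$planted),
               "frac_mikc too small")
  ## reproducible under a fixed seed
  s2 <- generate_synthetic_study(synthetic_config(seed = 6))
  expect_identical(s2$annotation, study$annotation)
  expect_identical(s2$expression, study$expression)
})

test_that("fixture directories round-trip through the text formats", {
  study <- generate_synthetic_study(
    synthetic_config(n_nodes = 12, n_edges = 14, n_planted_quads = 2,
                     n_self_loops = 1, n_tissues = 4, seed = 9))
  dir <- withr::local_tempdir()
  write_fixture_dir(study, dir)
  net <- read_edge_list(file.path(dir, "network.tsv"))
  expect_identical(net$edges, study$network$edges)
  mat <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(mat, study$expression, tolerance = 1e-6)
  gmap <- read_gene_map(file.path(dir, "genemap.tsv"))
  expect_identical(gmap, study$gene_map)
  ann <- read_clade_annotation(file.path(dir, "clades.tsv"))
  expect_identical(ann, study$annotation)
  truth <- readLines(file.path(dir, "truth.json"))
  expect_match(truth, "\"planted\"")
})
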