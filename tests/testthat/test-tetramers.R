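test_that("prospective tetramers require the 4-cycle and joint expression", {
  fix <- square_fixture()  # all four genes share tissue t1
  pro <- prospective_tetramers(fix$net, fix$calls)
  expect_equal(nrow(pro), 1L)
  expect_equal(pro$n_tissues, 1L)
  expect_equal(pro$tissues, "t1")
  expect_equal(attr(pro, "n_not_coexpressed"), 0L)

  ## one silent gene: the set is tetramer-like but never co-expressed
  silent <- square_fixture(expressed = c(TRUE, TRUE, TRUE, FALSE))
  pro2 <- prospective_tetramers(silent$net, silent$calls)
  expect_equal(nrow(pro2), 0L)
  expect_equal(attr(pro2, "n_not_coexpressed"), 1L)

  ## a co-expressed path is not tetramer-like
  path <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  pro3 <- prospective_tetramers(path, fix$calls)
  expect_equal(nrow(pro3), 0L)
  expect_equal(attr(pro3, "n_not_coexpressed"), 0L)

  ## uncovered proteins draw a warning before the missing-data error
  bigger <- ppi_network(rbind(fix$net$edges, c("A", "Z")))
  expect_warning(try(prospective_tetramers(bigger, fix$calls),
                     silent = TRUE), "without expression data")
})

test_that("prospective count plus never-co-expressed equals the tetramer count", {
  study <- generate_synthetic_study(synthetic_config(seed = 31))
  pro <- prospective_tetramers(study$network, study$calls, study$gene_map)
  expect_equal(nrow(pro) + attr(pro, "n_not_coexpressed"),
               count_tetramer_like(study$network))
  ## deterministic lexicographic ordering
  keys <- apply(pro[, 1:4], 1, paste, collapse = "|")
  expect_identical(keys, sort(keys))
})

test_that("clade partition counts conserve totals", {
  ann <- c(A = "MIKC", B = "MIKC", C = "MIKC", D = "MIKC",
           E = "non-MIKC", F = "non-MIKC", G = "non-MIKC", H = "non-MIKC")
  sets <- list(c("A", "B", "C", "D"), c("A", "B", "C", "E"),
               c("E", "F", "G", "H"), c("A", "E", "F", "G"))
  counts <- partition_by_clade(sets, ann)
  expect_equal(unname(counts),  c(1L, 2L, 1L))
  expect_equal(sum(counts), length(sets))
  expect_error(partition_by_clade(list(c("A", "B", "C", "Q")), ann),
               "without clade annotation")
})

test_that("degree-matched sampling accepts identities and rejects impossibles", {
  net <- random_network(8, 12, n_loops = 1)
  ## the source's own degree sequence at full size accepts the whole network
  got <- sample_degree_matched_subnetworks(
    net, sort(unname(stub_degrees(net))), n_keep = 1, max_attempts = 5,
    seed = 3)
  expect_length(got, 1L)
  expect_identical(got[[1]]$edges, net$edges)
  ## an unattainable target returns empty with a warning
  expect_warning(
    bad <- sample_degree_matched_subnetworks(net, c(10, 10, 10, 10),
                                             n_keep = 1,
                                             max_attempts = 50, seed = 4),
    "no degree-matched")
  expect_length(bad, 0L)
  expect_error(sample_degree_matched_subnetworks(net, rep(1, 99)),
               "longer than")
})

test_that("degree-matched subnetworks carry the source's motif excess", {
  ## planted fixture: subnetworks of the planted network keep more
  ## tetramer-like sets than switching-randomized counterparts of the
  ## same degree sequence
  study <- generate_synthetic_study(
    synthetic_config(n_nodes = 24, n_edges = 30, n_planted_quads = 5,
                     n_self_loops = 0, seed = 11))
  net <- study$network
  target <- sort(unname(stub_degrees(net)))
  subs <- sample_degree_matched_subnetworks(net, target, n_keep = 1,
                                            max_attempts = 2, seed = 1)
  obs <- count_tetramer_like(subs[[1]])
  nulls <- unlist(generate_ensemble(subs[[1]], 100, seed = 2,
                                    FUN = count_tetramer_like))
  expect_gt(obs, median(nulls))
})

test_that("balanced clade sampling tallies by composition reproducibly", {
  study <- generate_synthetic_study(
    synthetic_config(n_nodes = 44, n_edges = 110, n_planted_quads = 6,
                     frac_mikc = 0.55, seed = 17))
  a <- balanced_clade_sampling(study$network, study$calls,
                               study$gene_map, study$annotation,
                               n_each = 15, reps = 30, seed = 5)
  b <- balanced_clade_sampling(study$network, study$calls,
                               study$gene_map, study$annotation,
                               n_each = 15, reps = 30, seed = 5)
  expect_identical(a$counts, b$counts)
  ## planting inside the MIKC clade drives MIKC-only prospective
  ## tetramers far above non-MIKC-only ones
  expect_gt(mean(a$counts[["MIKC-only"]]),
            mean(a$counts[["non-MIKC-only"]]))
  expect_gt(a$mw$z, 0)
  expect_error(balanced_clade_sampling(study$network, study$calls,
                                       study$gene_map, study$annotation,
                                       n_each = 30, reps = 2),
               "at least 30")
})

test_that("retrodiction scores substitutes under the five-gene condition", {
  ## two prospective tetramers sharing three partners; all five genes
  ## share tissue t1
  vals <- matrix(1, 6, 2,
                 dimnames = list(c("X", "Y", "A", "B", "C", "Z"),
                                 c("t1", "t2")))
  vals[c("X", "Y", "A", "B", "C"), "t1"] <- 8
  calls <- call_expressed(vals)
  tet <- data.frame(p1 = c("A", "A"), p2 = c("B", "B"),
                    p3 = c("C", "C"), p4 = c("X", "Y"))
  out <- retrodict_substitutes("X", tet, calls)
  expect_equal(out, data.frame(protein = "Y", count = 1L))

  ## Y never co-expressed with X in one tissue: excluded
  vals2 <- vals
  vals2["Y", ] <- c(1, 8)  # Y expressed only in t2, X only in t1
  out2 <- retrodict_substitutes("X", tet, call_expressed(vals2))
  expect_equal(nrow(out2), 0L)

  ## absent protein warns and returns empty
  expect_warning(out3 <- retrodict_substitutes("Q", tet, calls),
                 "no prospective tetramer")
  expect_equal(nrow(out3), 0L)
})

test_that("retrodiction ranks by substitution count with lexical ties", {
  ## X occurs in four tetramers; Y substitutes in three, Z in one
  tet <- data.frame(
    p1 = c("A", "D", "G", "J", "A", "D", "G", "J"),
    p2 = c("B", "E", "H", "K", "B", "E", "H", "K"),
    p3 = c("C", "F", "I", "L", "C", "F", "I", "L"),
    p4 = c("X", "X", "X", "X", "Y", "Y", "Y", "Z"))
  genes <- unique(unlist(tet))
  vals <- matrix(8, length(genes), 1, dimnames = list(genes, "t1"))
  calls <- call_expressed(vals)
  out <- retrodict_substitutes("X", tet, calls)
  expect_equal(out$protein, c("Y", "Z"))
  expect_equal(out$count, c(3L, 1L))
  ## counts never exceed the number of X-containing tetramers
  expect_true(all(out$count <= 4L))
  ## interchangeable proteins retrodict each other symmetrically
  back <- retrodict_substitutes("Y", tet, calls)
  expect_equal(back$protein[1], "X")
})
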