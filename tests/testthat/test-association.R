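test_that("uncorrected Pearson chi-square reproduces the reference values", {
  expect_equal(unname(chi2_2x2(rbind(c(1134, 217),
                                     c(4388, 1896)))$statistic),
               110.6, tolerance = 0.05 / 110.6)
  expect_equal(unname(chi2_2x2(rbind(c(1347, 7),
                                     c(270, 1127)))$statistic),
               1823.3, tolerance = 0.05 / 1823.3)
  expect_equal(unname(chi2_2x2(rbind(c(213, 16),
                                     c(752, 170)))$statistic),
               17.75, tolerance = 0.005 / 17.75)
  expect_equal(unname(chi2_2x2(rbind(c(14, 0),
                                     c(131, 16)))$statistic),
               1.69, tolerance = 0.005 / 1.69)
  expect_equal(unname(chi2_2x2(rbind(c(97, 80),
                                     c(4, 5)))$statistic),
               0.37, tolerance = 0.005 / 0.37)
  expect_equal(unname(chi2_2x2(rbind(c(1134, 217),
                                     c(4388, 1896)))$parameter), 1)
})

test_that("chi-square is zero for proportional rows and rejects degenerates", {
  expect_equal(unname(chi2_2x2(rbind(c(10, 20), c(30, 60)))$statistic), 0)
  expect_error(chi2_2x2(rbind(c(0, 0), c(3, 4))), "degenerate")
  expect_error(chi2_2x2(rbind(c(0, 3), c(0, 4))), "degenerate")
  expect_error(chi2_2x2(c(1, 2, 3)), "2x2")
  ## invariant under simultaneous row and column swaps
  m <- rbind(c(13, 4), c(7, 21))
  expect_equal(chi2_2x2(m)$statistic,
               chi2_2x2(m[2:1, 2:1])$statistic)
})

test_that("co-expression ratios match the reference figures", {
  expect_equal(round(coexpression_ratio(1134, 217), 2), 5.23)
  expect_equal(round(coexpression_ratio(4388, 1896), 2), 2.31)
  expect_equal(coexpression_ratio(0, 5), 0)
  expect_error(coexpression_ratio(3, 0), "positive")
})

test_that("Mann-Whitney U and z behave on hand-checked cases", {
  ## complete separation: first group entirely below the second
  mw <- tetranet:::mann_whitney_uz(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_lt(mw$z, 0)
  ## identical groups: no shift
  mw0 <- tetranet:::mann_whitney_uz(rep(1:3, 4), rep(1:3, 4))
  expect_equal(mw0$z, 0)
  expect_equal(mw0$p, 1)
  ## shifting one group up increases z
  set.seed(131)
  x <- rpois(30, 4); y <- rpois(25, 4)
  z1 <- tetranet:::mann_whitney_uz(x, y)$z
  z2 <- tetranet:::mann_whitney_uz(x + 2, y)$z
  expect_gt(z2, z1)
  ## U and the approximate p agree with the standard implementation
  for (i in 1:10) {
    x <- rpois(sample(5:20, 1), 5); y <- rpois(sample(5:20, 1), 5)
    mine <- tetranet:::mann_whitney_uz(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                        correct = FALSE))
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("connected 4-sets carry tetramer status and joint tissue counts", {
  fix <- square_fixture()
  df <- connected_foursets(fix$net, fix$calls)
  expect_equal(nrow(df), 1L)
  expect_true(df$tetramer_like)
  expect_equal(df$n_joint_tissues, 1L)
  ## a path is connected but not tetramer-like
  path <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  dfp <- connected_foursets(path, fix$calls)
  expect_false(dfp$tetramer_like)
  ## missing expression rows are reported
  expect_error(connected_foursets(path, call_expressed(
    matrix(8, 1, 1, dimnames = list("A", "t1")))), "no expression data")
})

test_that("all-true calls give degenerate co-expression fractions", {
  net <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("C", "D"),
                           c("A", "D"), c("A", "E"), c("E", "B")))
  calls <- call_expressed(matrix(8, 5, 2,
    dimnames = list(LETTERS[1:5], c("t1", "t2"))))
  fn <- fraction_coexpression_null(net, calls, reps = 50, seed = 2)
  expect_equal(fn$observed_fraction, 1)
  expect_true(all(fn$null_fractions == 1))
  expect_equal(fn$p, 1)
  expect_error(fraction_coexpression_null(net, calls, k = 10^6, reps = 2),
               "exceeds")
})

test_that("planted co-expression is detected by the resampling null", {
  study <- generate_synthetic_study(synthetic_config(seed = 5))
  fn <- fraction_coexpression_null(study$network, study$calls,
                                   study$gene_map, reps = 500, seed = 9)
  expect_lt(fn$p, 0.05)
  expect_gt(fn$observed_fraction, mean(fn$null_fractions))
})

test_that("resampling p-values are calibrated for an exchangeable group", {
  ## when the observed group of 4-sets is itself exchangeable with the
  ## resamples and calls are independent of structure, the empirical p
  ## of the fraction-of-co-expression null is approximately uniform.
  ## (For the tetramer-like group itself the p-value is over-dispersed
  ## because overlapping 4-sets share proteins; see the vignette.)
  set.seed(141)
  net <- random_network(16, 45, name = "nullnet")
  df <- connected_foursets(net)
  k <- 110
  ps <- numeric(120)
  for (i in seq_along(ps)) {
    vals <- matrix(ifelse(runif(16 * 6) < 0.4, 8, 1), 16, 6,
                   dimnames = list(net$nodes, paste0("t", 1:6)))
    dfc <- connected_foursets(net, call_expressed(vals))
    co <- dfc$n_joint_tissues > 0
    set.seed(5000 + i)
    obs <- mean(co[sample.int(nrow(dfc), k)])
    null <- replicate(99, mean(co[sample.int(nrow(dfc), k)]))
    ps[i] <- mean(null >= obs)
  }
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("tissue-count comparison separates shifted groups", {
  study <- generate_synthetic_study(synthetic_config(seed = 6))
  tc <- tissue_count_comparison(study$network, study$calls,
                                study$gene_map)
  expect_length(tc$counts_tetramer_like,
                count_tetramer_like(study$network))
  ## planted tetramers push the tetramer-like distribution right
  expect_gt(tc$z, 0)
  expect_lt(tc$p, 0.05)
  expect_error(tissue_count_comparison(
    square_fixture()$net, square_fixture()$calls), "nonempty")
})
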