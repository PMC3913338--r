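test_that("edge-list reading deduplicates, handles loops and dialects", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "A\tB", "# comment", "", "C\tC"), tsv)
  net <- read_edge_list(tsv)
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(n_edges(net), 2L)
  expect_equal(n_self_loops(net), 1L)

  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A pp B", "B pp C", "D"), sif)
  nsif <- read_edge_list(sif, dialect = "sif")
  expect_setequal(nsif$nodes, c("A", "B", "C", "D"))
  expect_equal(n_edges(nsif), 2L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "A\tB\tC"), bad)
  expect_error(read_edge_list(bad), "line 2")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_equal(n_nodes(read_edge_list(empty)), 0L)
})

test_that("a square parses to 4 nodes, 4 edges, degree 2 each", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC", "C\tD", "D\tA"), tsv)
  net <- read_edge_list(tsv)
  expect_equal(n_nodes(net), 4L)
  expect_equal(n_edges(net), 4L)
  for (v in net$nodes) expect_equal(interaction_count(net, v), 2L)
})

test_that("write/read edge list round-trips arbitrary networks", {
  set.seed(11)
  for (i in 1:20) {
    net <- random_network(sample(3:10, 1), sample(2:12, 1),
                          n_loops = sample(0:2, 1))
    for (d in c("tsv", "sif")) {
      f <- withr::local_tempfile(fileext = paste0(".", d))
      write_edge_list(net, f, dialect = d)
      back <- read_edge_list(f, dialect = d)
      expect_identical(back$nodes, net$nodes)
      expect_identical(back$edges, net$edges)
    }
  }
})

test_that("three-hybrid expansion follows the direct-edge conditional", {
  pw <- ppi_network(rbind(c("A", "C")))
  rec <- data.frame(bait = "A", bridge = "B", prey = "C", positive = TRUE)
  ## direct bait-prey edge present: nothing added
  expect_equal(nrow(expand_three_hybrid(rec, pw)), 0L)
  ## direct edge absent: both bridge edges added
  pw2 <- ppi_network(rbind(c("A", "X")))
  got <- expand_three_hybrid(rec, pw2)
  expect_setequal(paste(got[, 1], got[, 2]), c("A B", "B C"))
  ## negative result adds nothing
  recn <- transform(rec, positive = FALSE)
  expect_equal(nrow(expand_three_hybrid(recn, pw2)), 0L)
  ## duplicated records collapse
  got2 <- expand_three_hybrid(rbind(rec, rec), pw2)
  expect_equal(nrow(got2), 2L)
  ## validation
  expect_error(expand_three_hybrid(
    data.frame(bait = "", bridge = "B", prey = "C", positive = TRUE), pw2),
    "empty identifier")
  expect_error(expand_three_hybrid(
    data.frame(bait = "A", bridge = "A", prey = "A", positive = TRUE), pw2),
    "degenerate")
})

test_that("interaction_count counts a self-loop once", {
  net <- ppi_network(rbind(c("A", "A"), c("A", "B")), nodes = "Z")
  expect_equal(interaction_count(net, "A"), 2L)
  expect_equal(interaction_count(net, "B"), 1L)
  expect_equal(interaction_count(net, "Z"), 0L)
  expect_error(interaction_count(net, "Q"), "unknown node")
})

test_that("interaction counts and stub degrees satisfy the handshake sums", {
  set.seed(21)
  for (i in 1:30) {
    net <- random_network(sample(4:9, 1), sample(2:12, 1),
                          n_loops = sample(0:3, 1))
    loops <- n_self_loops(net)
    plain <- n_edges(net) - loops
    total <- sum(vapply(net$nodes, interaction_count, 0L, net = net))
    expect_equal(total, 2L * plain + loops)
    expect_equal(sum(stub_degrees(net)), 2L * n_edges(net))
  }
})

test_that("is_connected_subset matches a breadth-first-search oracle", {
  sq <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("C", "D"),
                          c("A", "D")))
  expect_true(is_connected_subset(sq, c("A", "B", "C", "D")))
  dis <- ppi_network(rbind(c("A", "B"), c("C", "D")))
  expect_false(is_connected_subset(dis, c("A", "B", "C", "D")))
  lp <- ppi_network(rbind(c("A", "A")))
  expect_true(is_connected_subset(lp, "A"))
  expect_error(is_connected_subset(sq, c("A", "Q")), "not in network")

  set.seed(31)
  for (i in 1:30) {
    net <- random_network(sample(5:12, 1), sample(3:18, 1),
                          n_loops = sample(0:2, 1))
    k <- sample(2:min(5, n_nodes(net)), 1)
    S <- sample(net$nodes, k)
    A <- adjacency_matrix(net)[S, S, drop = FALSE]
    em <- which(A == 1L & upper.tri(A, diag = TRUE), arr.ind = TRUE)
    expect_equal(is_connected_subset(net, S),
                 oracle_connected(k, matrix(as.integer(em), ncol = 2)))
  }
})
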