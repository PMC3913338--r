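## Independent oracles and fixture builders. The oracles deliberately
## avoid the package's certificate machinery: isomorphism is decided by
## direct permutation matching of edge sets, connectivity by an
## explicit breadth-first search.

## random network with optional self-loops
random_network <- function(n_nodes, n_edges, n_loops = 0L,
                           name = "random") {
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2L))
  m <- min(n_edges, nrow(pairs))
  em <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
  if (n_loops > 0L) {
    lp <- sample(nodes, min(n_loops, n_nodes))
    em <- rbind(em, cbind(lp, lp))
  }
  ppi_network(em, nodes = nodes, name = name)
}

## edge matrices (integer, normalized key strings) for oracle use
edge_key <- function(em) {
  if (nrow(em) == 0L) return(character(0))
  lo <- pmin(em[, 1L], em[, 2L]); hi <- pmax(em[, 1L], em[, 2L])
  sort(paste(lo, hi, sep = "-"))
}

## brute-force isomorphism of two graphs on 1..n (loops map to loops)
oracle_isomorphic <- function(n, edges1, edges2) {
  if (nrow(edges1) != nrow(edges2)) return(FALSE)
  k2 <- edge_key(edges2)
  for (p in combinat_perms(n)) {
    mapped <- cbind(p[edges1[, 1L]], p[edges1[, 2L]])
    if (identical(edge_key(mapped), k2)) return(TRUE)
  }
  FALSE
}

## all permutations of 1..n as a matrix (rows), simple recursion
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in combinat_perms(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

## breadth-first-search connectivity of an induced loop-free subgraph
oracle_connected <- function(n, edges) {
  em <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  if (n == 1L) return(TRUE)
  if (nrow(em) == 0L) return(FALSE)
  seen <- logical(n); seen[1L] <- TRUE
  queue <- 1L
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- c(em[em[, 1L] == v, 2L], em[em[, 2L] == v, 1L])
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

## memoized per-subset brute-force classifier: classifies the induced
## subgraph of each connected n-subset against the catalogue patterns
## by direct permutation isomorphism (not certificates), and tallies
## counts per pattern id
oracle_memo <- new.env(parent = emptyenv())

oracle_census <- function(net, n, cat = pattern_catalogue(2:4)) {
  A <- adjacency_matrix(net)
  nn <- nrow(A)
  sz <- vapply(cat$patterns, function(p) p$size, 1L)
  pats <- cat$patterns[sz == n]
  ids <- vapply(pats, function(p) p$pattern_id, "")
  counts <- setNames(integer(length(ids)), ids)
  if (nn < n) return(counts)
  for (S in combn(nn, n, simplify = FALSE)) {
    B <- A[S, S, drop = FALSE]
    em <- which(B == 1L & upper.tri(B, diag = TRUE), arr.ind = TRUE)
    em <- matrix(as.integer(em), ncol = 2L)
    key <- paste(n, paste(em[, 1L], em[, 2L], sep = "-", collapse = ","),
                 sep = ":")
    hit <- oracle_memo[[key]]
    if (is.null(hit)) {
      hit <- "none"
      if (oracle_connected(n, em)) {
        for (j in seq_along(pats)) {
          if (oracle_isomorphic(n, em, pats[[j]]$edges)) {
            hit <- ids[j]; break
          }
        }
      }
      oracle_memo[[key]] <- hit
    }
    if (hit != "none") counts[hit] <- counts[hit] + 1L
  }
  counts
}

## small square fixture with expression over two tissues
square_fixture <- function(expressed = c(TRUE, TRUE, TRUE, TRUE)) {
  net <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("C", "D"),
                           c("A", "D")))
  vals <- matrix(1, 4, 2, dimnames = list(LETTERS[1:4], c("t1", "t2")))
  vals[expressed, "t1"] <- 8
  list(net = net, calls = call_expressed(vals))
}
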