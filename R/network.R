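#' Construct a protein-protein interaction network
#'
#' A \code{ppi_network} is an undirected graph over protein identifiers.
#' Self-loops (edges joining a node to itself) are allowed and represent
#' self-interactions, i.e. the ability of a protein to homodimerize.
#' Duplicate edges and symmetric duplicates (\code{A-B} vs \code{B-A})
#' collapse to a single edge.
#'
#' @param edges two-column character matrix (or data.frame) of endpoint
#'   pairs; rows with two identical entries become self-loops. May have
#'   zero rows.
#' @param nodes optional character vector of node identifiers; the final
#'   node set is the union of \code{nodes} and all edge endpoints, so
#'   isolated nodes can be declared here.
#' @param name label for the network, used in printing and result tables.
#' @return An object of class \code{ppi_network}: a list with elements
#'   \code{nodes} (character), \code{edges} (two-column character matrix,
#'   each row sorted, rows deduplicated and ordered) and \code{name}.
#' @examples
#' net <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("C", "C")))
#' net
#' interaction_count(net, "C")
#' @export
ppi_network <- function(edges = NULL, nodes = character(), name = "network") {
  if (is.null(edges)) {
    em <- matrix(character(), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    if (length(em) == 0L) em <- matrix(character(), ncol = 2L)
    if (ncol(em) != 2L)
      stop("'edges' must have exactly two columns", call. = FALSE)
    storage.mode(em) <- "character"
  }
  if (any(is.na(em)) || any(em == ""))
    stop("edge endpoints must be non-empty identifiers", call. = FALSE)
  ## canonical row order: lexicographically smaller endpoint first
  if (nrow(em) > 0L) {
    swap <- em[, 1L] > em[, 2L]
    em[swap, ] <- em[swap, c(2L, 1L)]
    em <- em[!duplicated(paste(em[, 1L], em[, 2L], sep = "\r")), , drop = FALSE]
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  }
  nodes <- sort(unique(c(as.character(nodes), as.vector(em))))
  dimnames(em) <- NULL
  structure(list(nodes = nodes, edges = em, name = as.character(name)[1L]),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  nl <- n_self_loops(x)
  cat(sprintf("ppi_network '%s': %d nodes, %d edges (%d self-loop%s)\n",
              x$name, length(x$nodes), nrow(x$edges), nl,
              if (nl == 1L) "" else "s"))
  invisible(x)
}

#' Number of nodes, edges and self-loops
#'
#' @param net a \code{ppi_network}.
#' @return \code{n_nodes}/\code{n_edges}/\code{n_self_loops}: integer counts.
#'   \code{n_edges} counts self-loops as single edges.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_nodes
#' @export
n_self_loops <- function(net) sum(net$edges[, 1L] == net$edges[, 2L])

stopifnot_network <- function(net) {
  if (!inherits(net, "ppi_network"))
    stop("expected a 'ppi_network' object", call. = FALSE)
  invisible(net)
}

#' Read an interaction network from an edge-list file
#'
#' Supports a plain two-column tab-separated dialect (\code{tsv}) and the
#' simple interaction format (\code{sif}) in which each line reads
#' \code{A pp B}. Lines starting with \code{#} and blank lines are skipped.
#' A line whose two node tokens are equal yields a self-loop. Duplicate
#' lines collapse to one edge. A \code{tsv} line with a single token
#' declares an isolated node.
#'
#' @param path path to the edge-list file.
#' @param dialect \code{"tsv"} or \code{"sif"}.
#' @param name network label; defaults to the file name.
#' @return a \code{ppi_network}.
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif"),
                           name = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  edges <- matrix(character(), ncol = 2L)
  singletons <- character()
  elist <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    tok <- strsplit(lines[i], if (dialect == "tsv") "\t" else "\\s+")[[1]]
    tok <- tok[nzchar(tok)]
    if (dialect == "tsv") {
      if (length(tok) == 1L) { singletons <- c(singletons, tok); next }
      if (length(tok) != 2L)
        stop(sprintf("malformed line %d in %s: expected 2 tab-separated tokens, got %d",
                     i, path, length(tok)), call. = FALSE)
      elist[[k]] <- tok
    } else {
      if (length(tok) == 1L) { singletons <- c(singletons, tok); next }
      if (length(tok) != 3L)
        stop(sprintf("malformed line %d in %s: expected 'node relation node', got %d tokens",
                     i, path, length(tok)), call. = FALSE)
      elist[[k]] <- tok[c(1L, 3L)]
    }
  }
  elist <- elist[!vapply(elist, is.null, logical(1))]
  if (length(elist) > 0L) edges <- do.call(rbind, elist)
  ppi_network(edges, nodes = singletons, name = name)
}

#' Write a network as a sorted, deduplicated edge list
#'
#' The writer emits one edge per line with the lexicographically smaller
#' endpoint first, lines sorted, so that output is byte-stable for a given
#' network. Isolated nodes are written as single-token lines (tsv) or
#' single-node lines (sif).
#'
#' @param net a \code{ppi_network}.
#' @param path output file path.
#' @param dialect \code{"tsv"} or \code{"sif"}.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(net, path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  stopifnot_network(net)
  deg <- tabulate(match(as.vector(net$edges), net$nodes), length(net$nodes))
  isolated <- net$nodes[deg == 0L]
  lines <- if (dialect == "tsv") {
    c(paste(net$edges[, 1L], net$edges[, 2L], sep = "\t"), isolated)
  } else {
    c(paste(net$edges[, 1L], "pp", net$edges[, 2L]), isolated)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a yeast three-hybrid record table
#'
#' Expects a tab-separated file with header \code{bait, bridge, prey,
#' result}, where \code{result} is \code{pos} or \code{neg}.
#'
#' @param path path to the table.
#' @return data.frame with columns \code{bait}, \code{bridge}, \code{prey}
#'   and logical \code{positive}.
#' @export
read_three_hybrid <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("bait", "bridge", "prey", "result")
  if (!all(need %in% names(df)))
    stop("three-hybrid table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(df$result %in% c("pos", "neg")))
    stop("three-hybrid 'result' must be 'pos' or 'neg'", call. = FALSE)
  data.frame(bait = df$bait, bridge = df$bridge, prey = df$prey,
             positive = df$result == "pos", stringsAsFactors = FALSE)
}

#' Expand yeast three-hybrid records into pairwise edges
#'
#' A positive three-hybrid assay with bait A, bridge B and prey C is read
#' as evidence for the pairwise interactions A-B and B-C, provided no
#' direct two-hybrid interaction between A and C is already known: if the
#' pairwise network already contains A-C, the record contributes nothing
#' (the positive result is then explained by the direct interaction).
#' Negative records contribute nothing.
#'
#' @param records data.frame as returned by [read_three_hybrid()] (columns
#'   \code{bait}, \code{bridge}, \code{prey}, \code{positive}).
#' @param pairwise a \code{ppi_network} of already-known pairwise (e.g.
#'   two-hybrid) interactions.
#' @return two-column character matrix of new edges, deduplicated; zero
#'   rows when nothing is added.
#' @export
expand_three_hybrid <- function(records, pairwise) {
  stopifnot_network(pairwise)
  need <- c("bait", "bridge", "prey", "positive")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ids <- c(records$bait, records$bridge, records$prey)
  if (any(is.na(ids)) || any(ids == ""))
    stop("three-hybrid record with empty identifier", call. = FALSE)
  allsame <- records$bait == records$bridge & records$bridge == records$prey
  if (any(allsame))
    stop("degenerate three-hybrid record: bait, bridge and prey all equal",
         call. = FALSE)
  has_edge <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    paste(lo, hi, sep = "\r") %in%
      paste(pairwise$edges[, 1L], pairwise$edges[, 2L], sep = "\r")
  }
  pos <- records[records$positive, , drop = FALSE]
  if (nrow(pos) == 0L) return(matrix(character(), ncol = 2L))
  direct <- has_edge(pos$bait, pos$prey)
  pos <- pos[!direct, , drop = FALSE]
  if (nrow(pos) == 0L) return(matrix(character(), ncol = 2L))
  em <- rbind(cbind(pos$bait, pos$bridge), cbind(pos$bridge, pos$prey))
  swap <- em[, 1L] > em[, 2L]
  em[swap, ] <- em[swap, c(2L, 1L)]
  em <- em[!duplicated(paste(em[, 1L], em[, 2L], sep = "\r")), , drop = FALSE]
  dimnames(em) <- NULL
  em
}

#' Number of distinct interactions of a protein
#'
#' Counts distinct edges incident to a node; a self-loop counts once, so a
#' protein with one self-interaction and one partner has 2 interactions.
#'
#' @param net a \code{ppi_network}.
#' @param v node identifier.
#' @return nonnegative integer.
#' @export
interaction_count <- function(net, v) {
  stopifnot_network(net)
  if (!v %in% net$nodes) stop("unknown node: ", v, call. = FALSE)
  sum(net$edges[, 1L] == v | net$edges[, 2L] == v)
}

#' Stub-degree sequence
#'
#' Degrees in the stub (half-edge) sense used by the switching null model:
#' an ordinary edge contributes one stub to each endpoint, a self-loop
#' contributes two stubs to its node.
#'
#' @param net a \code{ppi_network}.
#' @return named integer vector over \code{net$nodes}.
#' @export
stub_degrees <- function(net) {
  stopifnot_network(net)
  d <- tabulate(match(as.vector(net$edges), net$nodes), length(net$nodes))
  names(d) <- net$nodes
  d
}

#' Adjacency matrix with loop diagonal
#'
#' @param net a \code{ppi_network}.
#' @return symmetric integer 0/1 matrix over \code{net$nodes}; the diagonal
#'   marks self-loops.
#' @export
adjacency_matrix <- function(net) {
  stopifnot_network(net)
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges[, 1L], net$nodes)
    j <- match(net$edges[, 2L], net$nodes)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  A
}

#' Is a node subset connected in the induced subgraph?
#'
#' Self-loops are ignored for connectivity: a single node is always a
#' single component, with or without a self-interaction.
#'
#' @param net a \code{ppi_network}.
#' @param S character vector of node identifiers, nonempty.
#' @return \code{TRUE} iff the induced loop-free subgraph on \code{S} is a
#'   single connected component.
#' @export
is_connected_subset <- function(net, S) {
  stopifnot_network(net)
  S <- unique(as.character(S))
  if (length(S) == 0L) stop("'S' must be nonempty", call. = FALSE)
  miss <- setdiff(S, net$nodes)
  if (length(miss) > 0L)
    stop("node(s) not in network: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(S) == 1L) return(TRUE)
  A <- adjacency_matrix(net)[S, S, drop = FALSE]
  diag(A) <- 0L
  ## breadth-first search from the first node
  seen <- logical(length(S)); seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0L) {
    nb <- which(rowSums(A[, frontier, drop = FALSE]) > 0L & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' Induced subnetwork on a node subset
#'
#' @param net a \code{ppi_network}.
#' @param S character vector of node identifiers.
#' @param name label for the result.
#' @return a \code{ppi_network} on \code{S} with all edges of \code{net}
#'   internal to \code{S} (self-loops included).
#' @export
induced_subnetwork <- function(net, S, name = paste0(net$name, "[subset]")) {
  stopifnot_network(net)
  S <- unique(as.character(S))
  miss <- setdiff(S, net$nodes)
  if (length(miss) > 0L)
    stop("node(s) not in network: ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- net$edges[, 1L] %in% S & net$edges[, 2L] %in% S
  ppi_network(net$edges[keep, , drop = FALSE], nodes = S, name = name)
}
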