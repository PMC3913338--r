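## Catalogue of connected small-graph isomorphism classes (2-4 nodes,
## self-loops allowed). At these sizes canonical labels are obtained by
## brute force over all node permutations, which is exact and cheap
## (at most 4! = 24 relabelings per graph).

## all permutations of 1..n as a list of integer vectors
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

## normalize an edge matrix: each row (i, j) with i <= j, rows sorted, unique
normalize_edges <- function(edges) {
  if (length(edges) == 0L) return(matrix(integer(), ncol = 2L))
  em <- matrix(as.integer(edges), ncol = 2L)
  swap <- em[, 1L] > em[, 2L]
  em[swap, ] <- em[swap, c(2L, 1L)]
  em <- unique(em)
  em[order(em[, 1L], em[, 2L]), , drop = FALSE]
}

encode_edges <- function(size, edges) {
  em <- normalize_edges(edges)
  paste0("n", size, ":", paste(em[, 1L], em[, 2L], sep = "-", collapse = ","))
}

#' Canonical certificate of a small graph
#'
#' Computes a string that is identical for two graphs on \code{size}
#' labeled nodes if and only if they are isomorphic (self-loops map to
#' self-loops). The certificate is the lexicographically minimal edge-set
#' encoding over all node permutations, prefixed with the node count so
#' certificates of different sizes never collide. Exact by exhaustive
#' permutation; supported up to \code{size = 4}.
#'
#' @param size number of nodes (1 to 4).
#' @param edges two-column integer matrix of node-index pairs in
#'   \code{1..size}; a row \code{(i, i)} is a self-loop. May be empty.
#' @return certificate string.
#' @examples
#' # two labelings of the 3-path get the same certificate
#' canonical_certificate(3, rbind(c(1, 2), c(2, 3)))
#' canonical_certificate(3, rbind(c(2, 1), c(1, 3)))
#' @export
canonical_certificate <- function(size, edges) {
  size <- as.integer(size)
  if (size < 1L || size > 4L)
    stop("canonical certificates are supported for sizes 1 to 4 only",
         call. = FALSE)
  em <- normalize_edges(edges)
  if (nrow(em) > 0L && (max(em) > size || min(em) < 1L))
    stop("edge endpoints must index nodes 1..size", call. = FALSE)
  best <- NULL
  for (p in all_perms(size)) {
    enc <- encode_edges(size, cbind(p[em[, 1L]], p[em[, 2L]]))
    if (is.null(best) || enc < best) best <- enc
  }
  best
}

new_connection_pattern <- function(size, edges, pattern_id = NA_character_) {
  em <- normalize_edges(edges)
  structure(list(size = as.integer(size), edges = em,
                 certificate = canonical_certificate(size, em),
                 pattern_id = pattern_id),
            class = "connection_pattern")
}

#' Build a connection pattern from an edge list
#'
#' A connection pattern is an isomorphism class of a connected graph on
#' 2 to 4 nodes, self-loops allowed; it is the unit of the subgraph
#' census. The loop-free skeleton must connect all \code{size} nodes.
#'
#' @param size number of nodes (2 to 4).
#' @param edges two-column integer matrix over \code{1..size}; rows
#'   \code{(i, i)} are self-loops.
#' @return object of class \code{connection_pattern} with fields
#'   \code{size}, \code{edges} (normalized), \code{certificate} and
#'   \code{pattern_id} (\code{NA} until the pattern is placed in a
#'   catalogue).
#' @examples
#' connection_pattern(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
#' @export
connection_pattern <- function(size, edges) {
  size <- as.integer(size)
  if (size < 2L || size > 4L)
    stop("connection patterns have 2 to 4 nodes", call. = FALSE)
  em <- normalize_edges(edges)
  if (nrow(em) == 0L)
    stop("a connection pattern must have at least one edge", call. = FALSE)
  if (max(em) > size || min(em) < 1L)
    stop("edge endpoints must index nodes 1..size", call. = FALSE)
  if (!skeleton_connected(size, em))
    stop("the loop-free skeleton must connect all nodes", call. = FALSE)
  new_connection_pattern(size, em)
}

#' @export
print.connection_pattern <- function(x, ...) {
  loops <- sum(x$edges[, 1L] == x$edges[, 2L])
  cat(sprintf("connection_pattern %s: %d nodes, %d edges (%d self-loop%s)\n  %s\n",
              if (is.na(x$pattern_id)) "<uncatalogued>" else x$pattern_id,
              x$size, nrow(x$edges), loops, if (loops == 1L) "" else "s",
              x$certificate))
  invisible(x)
}

## is the loop-free skeleton a single component covering all `size` nodes?
skeleton_connected <- function(size, edges) {
  em <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  if (size == 1L) return(TRUE)
  if (nrow(em) == 0L) return(FALSE)
  seen <- logical(size)
  seen[em[1L, 1L]] <- TRUE
  repeat {
    hit <- seen[em[, 1L]] | seen[em[, 2L]]
    newly <- unique(c(em[hit, 1L], em[hit, 2L]))
    if (all(seen[newly])) break
    seen[newly] <- TRUE
  }
  all(seen)
}

#' Enumerate all connected patterns on n nodes
#'
#' Exhaustively enumerates every edge subset on \code{n} labeled nodes
#' (the \code{choose(n, 2)} ordinary edges, plus the \code{n} self-loops
#' when \code{allow_loops}), keeps those whose loop-free skeleton joins
#' all \code{n} nodes in a single component, and deduplicates by
#' canonical certificate. With loops the counts are 3, 10 and 50 classes
#' for sizes 2, 3 and 4; without loops they are 1, 2 and 6.
#'
#' @param n number of nodes (2 to 4).
#' @param allow_loops include self-loop configurations?
#' @return list of \code{connection_pattern}, ordered by certificate.
#' @export
enumerate_connected_patterns <- function(n, allow_loops = TRUE) {
  n <- as.integer(n)
  if (n < 2L || n > 4L)
    stop("pattern enumeration is supported for n in 2..4", call. = FALSE)
  pairs <- t(utils::combn(n, 2L))
  m <- nrow(pairs)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (mask in seq_len(2L^m) - 1L) {
    sel <- bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L
    skel <- pairs[sel, , drop = FALSE]
    if (!skeleton_connected(n, skel)) next
    loop_masks <- if (allow_loops) seq_len(2L^n) - 1L else 0L
    for (lmask in loop_masks) {
      lsel <- bitwAnd(lmask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L
      em <- rbind(skel, cbind(which(lsel), which(lsel)))
      cert <- canonical_certificate(n, em)
      if (!exists(cert, envir = seen, inherits = FALSE)) {
        assign(cert, TRUE, envir = seen)
        out[[length(out) + 1L]] <- new_connection_pattern(n, em)
      }
    }
  }
  out[order(vapply(out, `[[`, "", "certificate"))]
}

#' Catalogue of connected patterns for sizes 2-4
#'
#' Builds the complete catalogue of connection-pattern classes for the
#' requested sizes, assigning stable pattern identifiers \code{p<size>-<k>}
#' in certificate order. With self-loops allowed the catalogue holds
#' 3 + 10 + 50 = 63 classes.
#'
#' @param sizes integer vector of sizes, subset of 2:4.
#' @param allow_loops include self-loop configurations?
#' @return object of class \code{pattern_catalogue}: list with
#'   \code{patterns} (list of \code{connection_pattern}) and \code{index}
#'   (named integer vector, certificate to position).
#' @examples
#' cat4 <- pattern_catalogue(4)
#' cat4
#' @export
pattern_catalogue <- function(sizes = 2:4, allow_loops = TRUE) {
  sizes <- sort(unique(as.integer(sizes)))
  if (!all(sizes %in% 2:4))
    stop("catalogue sizes must be within 2..4", call. = FALSE)
  patterns <- list()
  for (s in sizes) {
    ps <- enumerate_connected_patterns(s, allow_loops)
    for (k in seq_along(ps)) ps[[k]]$pattern_id <- sprintf("p%d-%d", s, k)
    patterns <- c(patterns, ps)
  }
  certs <- vapply(patterns, `[[`, "", "certificate")
  index <- seq_along(patterns)
  names(index) <- certs
  structure(list(patterns = patterns, index = index,
                 sizes = sizes, allow_loops = allow_loops),
            class = "pattern_catalogue")
}

#' @export
print.pattern_catalogue <- function(x, ...) {
  sz <- vapply(x$patterns, `[[`, 1L, "size")
  cat(sprintf("pattern_catalogue: %d classes (%s)%s\n", length(x$patterns),
              paste(sprintf("size %d: %d", x$sizes, tabulate(sz)[x$sizes]),
                    collapse = ", "),
              if (x$allow_loops) ", self-loops allowed" else ", loop-free"))
  invisible(x)
}

#' Look up a pattern in a catalogue
#'
#' @param cat a \code{pattern_catalogue}.
#' @param pattern a \code{connection_pattern}, a certificate string, or a
#'   pattern id.
#' @return the catalogued \code{connection_pattern} (with its id), or an
#'   error if absent.
#' @export
catalogue_lookup <- function(cat, pattern) {
  if (inherits(pattern, "connection_pattern")) pattern <- pattern$certificate
  i <- cat$index[pattern]
  if (is.na(i)) {
    ids <- vapply(cat$patterns, `[[`, "", "pattern_id")
    i <- match(pattern, ids)
  }
  if (is.na(i)) stop("pattern not in catalogue: ", pattern, call. = FALSE)
  cat$patterns[[i]]
}

#' @export
as.data.frame.pattern_catalogue <- function(x, ...) {
  c4 <- pattern_c4()
  data.frame(
    pattern_id = vapply(x$patterns, `[[`, "", "pattern_id"),
    size = vapply(x$patterns, `[[`, 1L, "size"),
    edges = vapply(x$patterns, function(p)
      paste(p$edges[, 1L], p$edges[, 2L], sep = "-", collapse = ","), ""),
    n_loops = vapply(x$patterns, function(p)
      sum(p$edges[, 1L] == p$edges[, 2L]), 0L),
    tetramer_like = vapply(x$patterns, function(p)
      p$size == 4L && contains_pattern(p, c4), NA),
    certificate = vapply(x$patterns, `[[`, "", "certificate"),
    stringsAsFactors = FALSE)
}

#' Export the catalogue as a TSV table
#'
#' Writes one row per pattern class: id, size, edge list, loop count,
#' tetramer-like flag and certificate.
#'
#' @param cat a \code{pattern_catalogue}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
export_catalogue <- function(cat, path) {
  utils::write.table(as.data.frame(cat), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Does one pattern embed another?
#'
#' \code{contains_pattern(host, motif)} is \code{TRUE} iff some bijection
#' of motif nodes onto host nodes maps every motif edge onto a host edge
#' (self-loops onto self-loops). Both patterns must have the same size;
#' the host may have additional edges.
#'
#' @param host,motif \code{connection_pattern} objects of equal size.
#' @return logical.
#' @export
contains_pattern <- function(host, motif) {
  if (!inherits(host, "connection_pattern") ||
      !inherits(motif, "connection_pattern"))
    stop("arguments must be connection_pattern objects", call. = FALSE)
  if (host$size != motif$size)
    stop("host and motif must have the same size", call. = FALSE)
  hostkeys <- paste(host$edges[, 1L], host$edges[, 2L], sep = "-")
  for (p in all_perms(motif$size)) {
    me <- cbind(p[motif$edges[, 1L]], p[motif$edges[, 2L]])
    me <- normalize_edges(me)
    if (all(paste(me[, 1L], me[, 2L], sep = "-") %in% hostkeys))
      return(TRUE)
  }
  FALSE
}

#' Reference motifs
#'
#' \code{pattern_c4()} is the loop-free 4-cycle, the connection pattern
#' compatible with a heterotetramer in which every protein binds two
#' others. \code{pattern_2ntp()} is a pair of interacting proteins each
#' with a self-interaction (a tetramer of two homodimers);
#' \code{pattern_3ntp()} is a triangle with one self-interaction (a
#' tetramer incorporating one homodimer).
#'
#' @return a \code{connection_pattern}.
#' @export
pattern_c4 <- function()
  connection_pattern(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))

#' @rdname pattern_c4
#' @export
pattern_2ntp <- function()
  connection_pattern(2, rbind(c(1, 2), c(1, 1), c(2, 2)))

#' @rdname pattern_c4
#' @export
pattern_3ntp <- function()
  connection_pattern(3, rbind(c(1, 2), c(1, 3), c(2, 3), c(1, 1)))

#' Tetramer-like pattern classes
#'
#' Returns the size-4 classes of the catalogue whose edge set embeds the
#' loop-free 4-cycle, i.e. those compatible with tetramer formation. Of
#' the 6 loop-free size-4 classes these are the 4-cycle, the 4-cycle with
#' a chord and the complete graph; with self-loops allowed, 20 of the 50
#' classes qualify.
#'
#' @param cat a \code{pattern_catalogue} including size 4.
#' @return list of \code{connection_pattern}.
#' @export
tetramer_like_patterns <- function(cat) {
  if (!4L %in% cat$sizes)
    stop("catalogue does not include size-4 patterns", call. = FALSE)
  c4 <- pattern_c4()
  keep <- vapply(cat$patterns, function(p)
    p$size == 4L && contains_pattern(p, c4), NA)
  cat$patterns[keep]
}
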