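## Exact subgraph census by exhaustive subset enumeration. Each k-subset
## of nodes is summarized as a bit code over its induced pair edges and
## member self-loops (see src/tetranet.cpp for the shared bit order); a
## precomputed code -> certificate table then classifies every subset at
## once. The counting unit is the node set: each connected subset counts
## exactly once, under the isomorphism class of its induced subgraph.

.tetranet_cache <- new.env(parent = emptyenv())

subset_pairs <- function(k) t(utils::combn(k, 2L))

## decode a bit code into an edge matrix on 1..k
decode_code <- function(code, k) {
  pairs <- subset_pairs(k)
  m <- nrow(pairs)
  pe <- pairs[bitwAnd(code, bitwShiftL(1L, seq_len(m) - 1L)) > 0L, ,
              drop = FALSE]
  lsel <- which(bitwAnd(code, bitwShiftL(1L, m + seq_len(k) - 1L)) > 0L)
  rbind(pe, cbind(lsel, lsel))
}

## per-code certificate (NA for disconnected skeletons), cached per size
census_code_info <- function(k) {
  key <- paste0("codes", k)
  if (!is.null(.tetranet_cache[[key]])) return(.tetranet_cache[[key]])
  nbits <- k * (k - 1L) / 2L + k
  certs <- rep(NA_character_, 2L^nbits)
  for (code in seq_len(2L^nbits) - 1L) {
    em <- decode_code(code, k)
    if (skeleton_connected(k, em))
      certs[code + 1L] <- canonical_certificate(k, em)
  }
  .tetranet_cache[[key]] <- certs
  certs
}

## codes (0-based) of size-4 subsets whose induced subgraph embeds the 4-cycle
tetramer_like_codes <- function() {
  if (!is.null(.tetranet_cache$tlcodes)) return(.tetranet_cache$tlcodes)
  certs <- census_code_info(4L)
  tl <- vapply(tetramer_like_patterns(full_catalogue()), `[[`, "",
               "certificate")
  .tetranet_cache$tlcodes <- which(certs %in% tl) - 1L
  .tetranet_cache$tlcodes
}

## the complete loop-allowing catalogue, built once
full_catalogue <- function() {
  if (is.null(.tetranet_cache$catalogue))
    .tetranet_cache$catalogue <- pattern_catalogue(2:4, allow_loops = TRUE)
  .tetranet_cache$catalogue
}

#' Induced subgraph census
#'
#' Classifies every connected \code{n}-node subset of the network by the
#' isomorphism class of its induced subgraph (self-loops on member nodes
#' included) and counts subsets per class. Subsets whose loop-free
#' induced subgraph is not a single component are skipped.
#'
#' @param net a \code{ppi_network}.
#' @param n subset size, 2 to 4.
#' @param cat a \code{pattern_catalogue} covering size \code{n}; defaults
#'   to the complete loop-allowing catalogue.
#' @return object of class \code{census_result}: list with
#'   \code{network_name}, \code{size}, \code{counts} (named integer
#'   vector over the catalogue's size-\code{n} pattern ids) and
#'   \code{total_connected_sets}.
#' @examples
#' sq <- ppi_network(rbind(c("A","B"), c("B","C"), c("C","D"), c("A","D")))
#' induced_census(sq, 4)
#' @export
induced_census <- function(net, n, cat = full_catalogue()) {
  stopifnot_network(net)
  n <- as.integer(n)
  if (!n %in% cat$sizes)
    stop("catalogue does not cover size ", n, call. = FALSE)
  codes <- cpp_code_census(adjacency_matrix(net), n)
  certs <- census_code_info(n)
  keep <- which(!is.na(certs) & codes > 0L)
  agg <- tapply(codes[keep], certs[keep], sum)
  sz <- vapply(cat$patterns, `[[`, 1L, "size")
  ids <- vapply(cat$patterns, `[[`, "", "pattern_id")[sz == n]
  catcerts <- vapply(cat$patterns, `[[`, "", "certificate")[sz == n]
  unknown <- setdiff(names(agg), catcerts)
  if (length(unknown) > 0L)
    stop("induced class not in catalogue (is the catalogue loop-free ",
         "while the network has self-loops?): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  counts <- integer(length(ids))
  names(counts) <- ids
  counts[match(names(agg), catcerts)] <- as.integer(agg)
  structure(list(network_name = net$name, size = n, counts = counts,
                 total_connected_sets = sum(counts)),
            class = "census_result")
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf("census_result: network '%s', size %d, %d connected sets\n",
              x$network_name, x$size, x$total_connected_sets))
  nz <- x$counts[x$counts > 0L]
  if (length(nz) > 0L)
    print(sort(nz, decreasing = TRUE))
  invisible(x)
}

#' @export
as.data.frame.census_result <- function(x, ...) {
  data.frame(network = x$network_name, size = x$size,
             pattern_id = names(x$counts), count = as.integer(x$counts),
             stringsAsFactors = FALSE)
}

#' Count node sets embedding a motif
#'
#' Counts the \code{motif$size}-node subsets whose induced subgraph
#' contains the motif's edges under some correspondence (loops onto
#' loops), i.e. subsets with at least the motif's interactions and
#' possibly more. Each subset counts once regardless of how many
#' embeddings it admits, so the count equals the sum of induced-census
#' counts over the classes that embed the motif.
#'
#' @param net a \code{ppi_network}.
#' @param motif a \code{connection_pattern}.
#' @return nonnegative integer.
#' @export
count_embedded <- function(net, motif) {
  if (!inherits(motif, "connection_pattern"))
    stop("'motif' must be a connection_pattern", call. = FALSE)
  cat <- full_catalogue()
  cen <- induced_census(net, motif$size, cat)
  sz <- vapply(cat$patterns, `[[`, 1L, "size")
  hosts <- cat$patterns[sz == motif$size]
  embeds <- vapply(hosts, contains_pattern, NA, motif = motif)
  sum(cen$counts[vapply(hosts, `[[`, "", "pattern_id")[embeds]])
}

#' Count tetramer-like 4-node sets
#'
#' A 4-node set is tetramer-like when its induced subgraph contains the
#' loop-free 4-cycle: each protein binds two others, the connection
#' pattern compatible with a heterotetramer. This is a fast path
#' equivalent to \code{count_embedded(net, pattern_c4())}.
#'
#' @param net a \code{ppi_network}.
#' @return nonnegative integer.
#' @export
count_tetramer_like <- function(net) {
  stopifnot_network(net)
  cpp_count_c4sets(adjacency_matrix(net))
}

#' Count homodimer-based tetramer patterns
#'
#' \code{2NTP} (two-node tetramer pattern): pairs of interacting
#' proteins, each with a self-interaction — the signature of a tetramer
#' built from two homodimers. \code{3NTP} (three-node tetramer pattern):
#' triangles with at least one self-interacting member — a tetramer
#' incorporating one homodimer. Counted per node set.
#'
#' @param net a \code{ppi_network}.
#' @param kind \code{"2NTP"} or \code{"3NTP"}.
#' @return nonnegative integer.
#' @export
count_ntp <- function(net, kind = c("2NTP", "3NTP")) {
  kind <- match.arg(kind)
  stopifnot_network(net)
  A <- adjacency_matrix(net)
  if (kind == "2NTP") {
    codes <- cpp_code_census(A, 2L)
    ## pair bit + both loop bits: code 0b111 = 7
    as.integer(codes[7L + 1L])
  } else {
    codes <- cpp_code_census(A, 3L)
    idx <- seq_along(codes) - 1L
    triangle <- bitwAnd(idx, 7L) == 7L
    has_loop <- bitwAnd(idx, bitwShiftL(7L, 3L)) > 0L
    sum(codes[triangle & has_loop])
  }
}
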