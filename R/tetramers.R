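## Prospective tetramers, clade partitioning, degree-matched subnetwork
## sampling, balanced clade resampling, and redundancy retrodiction.

#' Read a protein clade annotation
#'
#' Tab-separated file with columns \code{protein} and \code{clade},
#' clade values \code{MIKC} or \code{non-MIKC}.
#'
#' @param path path to the TSV file.
#' @return named character vector, protein id -> clade.
#' @export
read_clade_annotation <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("protein", "clade") %in% names(df)))
    stop("clade table must have columns 'protein' and 'clade'",
         call. = FALSE)
  if (!all(df$clade %in% c("MIKC", "non-MIKC")))
    stop("clade values must be 'MIKC' or 'non-MIKC'", call. = FALSE)
  stats::setNames(df$clade, df$protein)
}

clade_class_of <- function(members, annotation) {
  miss <- setdiff(members, names(annotation))
  if (length(miss) > 0L)
    stop("protein(s) without clade annotation: ",
         paste(miss, collapse = ", "), call. = FALSE)
  n_mikc <- sum(annotation[members] == "MIKC")
  if (n_mikc == length(members)) "MIKC-only"
  else if (n_mikc == 0L) "non-MIKC-only"
  else "mixed"
}

#' List prospective tetramers
#'
#' A prospective tetramer is a tetramer-like 4-protein set (induced
#' subgraph embeds the 4-cycle) whose encoding genes are co-expressed in
#' at least one tissue. The list is deterministically ordered,
#' lexicographically on the sorted member identifiers. Run this on the
#' expression-filtered network (see [expression_filtered_network()]); a
#' warning is issued when proteins without expression coverage are
#' present, and missing data then raise an error downstream.
#'
#' @param net a \code{ppi_network}.
#' @param calls logical call matrix from [call_expressed()].
#' @param gmap optional protein-to-gene map.
#' @param annotation optional clade annotation; adds a
#'   \code{clade_class} column.
#' @return data.frame of class \code{prospective_tetramers} with columns
#'   \code{p1..p4}, \code{n_tissues}, \code{tissues} (comma-separated),
#'   and optionally \code{clade_class}; the number of tetramer-like sets
#'   that are never co-expressed is attached as attribute
#'   \code{"n_not_coexpressed"}.
#' @export
prospective_tetramers <- function(net, calls, gmap = NULL,
                                  annotation = NULL) {
  stopifnot_network(net)
  genes <- map_genes(net$nodes, gmap)
  if (!all(genes %in% rownames(calls)))
    warning("network has proteins without expression data; ",
            "consider expression_filtered_network()", call. = FALSE)
  df <- connected_foursets(net, calls, gmap)
  tl <- df[df$tetramer_like, , drop = FALSE]
  keep <- tl$n_joint_tissues > 0L
  out <- tl[keep, c("p1", "p2", "p3", "p4"), drop = FALSE]
  out$n_tissues <- tl$n_joint_tissues[keep]
  tissues <- character(nrow(out))
  if (nrow(out) > 0L) {
    for (i in seq_len(nrow(out)))
      tissues[i] <- paste(joint_tissues(unlist(out[i, 1:4]), calls, gmap),
                          collapse = ",")
  }
  out$tissues <- tissues
  if (!is.null(annotation))
    out$clade_class <- if (nrow(out) == 0L) character(0) else
      apply(out[, 1:4], 1L, clade_class_of, annotation = annotation)
  ord <- do.call(order, out[, 1:4])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_not_coexpressed = sum(!keep),
            network_name = net$name,
            class = c("prospective_tetramers", "data.frame"))
}

#' @export
print.prospective_tetramers <- function(x, ...) {
  cat(sprintf(paste0("prospective tetramers: %d co-expressed tetramer-like ",
                     "sets (%d never co-expressed) in '%s'\n"),
              nrow(x), attr(x, "n_not_coexpressed"),
              attr(x, "network_name")))
  if (nrow(x) > 0L) {
    print.data.frame(utils::head(as.data.frame(x)[
      setdiff(names(x), "tissues")], 10L))
    if (nrow(x) > 10L) cat("  ... and", nrow(x) - 10L, "more\n")
  }
  invisible(x)
}

#' Partition 4-sets by clade composition
#'
#' @param sets data.frame with columns \code{p1..p4} (e.g. a
#'   [prospective_tetramers()] result) or a list of 4-vectors.
#' @param annotation named clade vector covering all member proteins.
#' @return named integer vector with counts \code{MIKC-only},
#'   \code{mixed}, \code{non-MIKC-only}; sums to the number of sets.
#' @export
partition_by_clade <- function(sets, annotation) {
  members <- if (is.data.frame(sets))
    lapply(seq_len(nrow(sets)), function(i)
      as.character(unlist(sets[i, c("p1", "p2", "p3", "p4")])))
  else sets
  cls <- vapply(members, clade_class_of, "", annotation = annotation)
  out <- c(`MIKC-only` = sum(cls == "MIKC-only"),
           mixed = sum(cls == "mixed"),
           `non-MIKC-only` = sum(cls == "non-MIKC-only"))
  out
}

#' Sample subnetworks matching a target degree sequence
#'
#' Rejection sampling used to compare networks of different sizes: node
#' subsets of the source network are drawn uniformly and kept when the
#' sorted stub-degree sequence of their induced subnetwork equals the
#' target (exact multiset equality). The reference analysis drew over
#' 10^6 subsets of the large network to obtain 50 matches to a 20-node
#' network.
#'
#' @param source a \code{ppi_network}.
#' @param target_degseq integer vector, the target sorted degree
#'   multiset (any order; sorted internally).
#' @param n_keep stop after this many accepted subnetworks.
#' @param max_attempts stop after this many draws regardless.
#' @param seed integer seed.
#' @return list of accepted \code{ppi_network} objects, with attributes
#'   \code{"attempts"} and \code{"acceptance_rate"}; empty (with a
#'   warning) when nothing was accepted.
#' @export
sample_degree_matched_subnetworks <- function(source, target_degseq,
                                              n_keep = 50L,
                                              max_attempts = 10000L,
                                              seed = 1L) {
  stopifnot_network(source)
  target <- sort(as.integer(target_degseq))
  m <- length(target)
  if (m > length(source$nodes))
    stop("target degree sequence longer than the source node set",
         call. = FALSE)
  set.seed(as.integer(seed))
  kept <- list()
  attempts <- 0L
  while (length(kept) < n_keep && attempts < max_attempts) {
    attempts <- attempts + 1L
    S <- sample(source$nodes, m)
    sub <- induced_subnetwork(source, S)
    if (identical(sort(unname(stub_degrees(sub))), target))
      kept[[length(kept) + 1L]] <- sub
  }
  if (length(kept) == 0L)
    warning("no degree-matched subnetwork found in ", attempts,
            " attempts", call. = FALSE)
  structure(kept, attempts = attempts,
            acceptance_rate = length(kept) / attempts)
}

#' Balanced clade resampling of prospective tetramers
#'
#' Controls for unequal clade representation: each replicate samples
#' \code{n_each} MIKC and \code{n_each} non-MIKC proteins, restricts the
#' network to those proteins, recomputes the prospective tetramers of
#' the restriction, and tallies them by clade composition. The MIKC-only
#' and non-MIKC-only per-replicate counts are compared with a
#' Mann-Whitney rank test.
#'
#' @param net a \code{ppi_network} (expression-filtered).
#' @param calls logical call matrix from [call_expressed()].
#' @param gmap optional protein-to-gene map.
#' @param annotation named clade vector covering the network's nodes.
#' @param n_each proteins sampled per clade (reference: 15).
#' @param reps number of replicates (reference: 10^4).
#' @param seed integer seed.
#' @return object of class \code{balanced_clade_sampling}: list with
#'   \code{counts} (reps x 3 data.frame), \code{summary} (mean, median,
#'   sd per class) and \code{mw} (U, z, p comparing MIKC-only vs
#'   non-MIKC-only counts).
#' @export
balanced_clade_sampling <- function(net, calls, gmap = NULL, annotation,
                                    n_each = 15L, reps = 1000L, seed = 1L) {
  stopifnot_network(net)
  miss <- setdiff(net$nodes, names(annotation))
  if (length(miss) > 0L)
    stop("protein(s) without clade annotation: ",
         paste(miss, collapse = ", "), call. = FALSE)
  mikc <- net$nodes[annotation[net$nodes] == "MIKC"]
  nonm <- net$nodes[annotation[net$nodes] == "non-MIKC"]
  if (length(mikc) < n_each || length(nonm) < n_each)
    stop(sprintf("need at least %d proteins of each clade (have %d MIKC, %d non-MIKC)",
                 n_each, length(mikc), length(nonm)), call. = FALSE)
  set.seed(as.integer(seed))
  counts <- matrix(0L, reps, 3L,
                   dimnames = list(NULL, c("MIKC-only", "mixed",
                                           "non-MIKC-only")))
  for (i in seq_len(reps)) {
    S <- c(sample(mikc, n_each), sample(nonm, n_each))
    sub <- induced_subnetwork(net, S)
    df <- connected_foursets(sub, calls, gmap)
    pro <- df[df$tetramer_like & df$n_joint_tissues > 0L, , drop = FALSE]
    if (nrow(pro) > 0L)
      counts[i, ] <- partition_by_clade(pro, annotation)[colnames(counts)]
  }
  counts <- as.data.frame(counts, check.names = FALSE)
  summ <- t(vapply(counts, function(v)
    c(mean = mean(v), median = stats::median(v), sd = stats::sd(v)),
    numeric(3)))
  mw <- mann_whitney_uz(counts[["MIKC-only"]], counts[["non-MIKC-only"]])
  structure(list(counts = counts, summary = summ, mw = mw,
                 n_each = as.integer(n_each), reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "balanced_clade_sampling")
}

#' @export
print.balanced_clade_sampling <- function(x, ...) {
  cat(sprintf(paste0("balanced clade sampling: %d replicates of %d + %d ",
                     "proteins\nprospective tetramers per replicate:\n"),
              x$reps, x$n_each, x$n_each))
  print(round(x$summary, 3))
  cat(sprintf("MIKC-only vs non-MIKC-only: U = %.4g, z = %.4g, p = %.3g\n",
              x$mw$U, x$mw$z, x$mw$p))
  invisible(x)
}

#' Retrodict candidate redundant proteins
#'
#' For a protein X, scans the prospective-tetramer list: whenever both
#' \{X, A, B, C\} and \{Y, A, B, C\} are prospective tetramers, Y scores
#' one substitution — provided (default, strict reading) there is at
#' least one tissue where the genes of all five proteins (Y plus the
#' original four) are expressed. With \code{pairwise_overlap = TRUE} the
#' looser reading is used instead: Y must share at least one expressed
#' tissue with each of X, A, B, C separately, in possibly different
#' tissues. Proteins that substitute X most often are candidates for
#' functional redundancy with X.
#'
#' @param X protein identifier.
#' @param tetramers a [prospective_tetramers()] data.frame.
#' @param calls logical call matrix from [call_expressed()].
#' @param gmap optional protein-to-gene map.
#' @param pairwise_overlap use the per-protein pairwise overlap reading
#'   of the co-expression condition.
#' @return data.frame with columns \code{protein} and \code{count},
#'   sorted by count descending, ties lexicographic; zero rows (with a
#'   warning) if X occurs in no prospective tetramer.
#' @export
retrodict_substitutes <- function(X, tetramers, calls, gmap = NULL,
                                  pairwise_overlap = FALSE) {
  mem <- as.matrix(tetramers[, c("p1", "p2", "p3", "p4")])
  inX <- rowSums(mem == X) > 0L
  if (!any(inX)) {
    warning("protein '", X, "' occurs in no prospective tetramer",
            call. = FALSE)
    return(data.frame(protein = character(0), count = integer(0)))
  }
  scores <- new.env(parent = emptyenv())
  xsets <- mem[inX, , drop = FALSE]
  for (i in seq_len(nrow(xsets))) {
    abc <- setdiff(xsets[i, ], X)
    ## candidate rows: contain the three partners but not X; the
    ## remaining member is the substitute Y
    hits <- rowSums(matrix(mem %in% abc, nrow(mem))) == 3L & !inX
    for (r in which(hits)) {
      Y <- setdiff(mem[r, ], abc)
      if (length(Y) != 1L) next
      ok <- if (pairwise_overlap) {
        all(vapply(c(X, abc), function(p)
          length(joint_tissues(c(Y, p), calls, gmap)) > 0L, NA))
      } else {
        length(joint_tissues(c(Y, X, abc), calls, gmap)) > 0L
      }
      if (ok) {
        prev <- if (is.null(scores[[Y]])) 0L else scores[[Y]]
        scores[[Y]] <- prev + 1L
      }
    }
  }
  prot <- ls(scores)
  out <- data.frame(protein = prot,
                    count = vapply(prot, function(p) scores[[p]], 0L),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}
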