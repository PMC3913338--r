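#' Read a gene-by-tissue expression matrix
#'
#' Expects a tab-separated file whose first column holds gene
#' identifiers and whose header row names the tissues; values are log2
#' expression (replicates are assumed averaged upstream; see
#' [collapse_replicates()] for a helper).
#'
#' @param path path to the TSV file.
#' @return numeric matrix, rows = genes, columns = tissues.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (anyDuplicated(colnames(mat)))
    stop("duplicate tissue labels in expression matrix", call. = FALSE)
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))),
                 arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-numeric expression value at gene '%s', tissue '%s'",
                 genes[bad[1L]], colnames(mat)[bad[2L]]), call. = FALSE)
  }
  rownames(mat) <- genes
  mat
}

#' Average replicate columns into one column per tissue
#'
#' @param mat numeric matrix as from [read_expression_matrix()].
#' @param groups character vector of tissue labels, one per column of
#'   \code{mat}; columns sharing a label are averaged.
#' @return matrix with one column per unique label, in first-appearance
#'   order.
#' @export
collapse_replicates <- function(mat, groups) {
  if (length(groups) != ncol(mat))
    stop("'groups' must have one label per column", call. = FALSE)
  labs <- unique(groups)
  out <- vapply(labs, function(g)
    rowMeans(mat[, groups == g, drop = FALSE]), numeric(nrow(mat)))
  colnames(out) <- labs
  out
}

#' Threshold expression values into presence calls
#'
#' A gene is called expressed in a tissue when its log2 expression is
#' strictly greater than the threshold. The default threshold of 4
#' follows the reference analysis of the developmental expression atlas.
#'
#' @param mat numeric gene-by-tissue matrix (log2 scale).
#' @param threshold finite numeric threshold.
#' @return logical matrix of calls with the same dimnames, carrying the
#'   threshold as attribute \code{"threshold"}.
#' @examples
#' m <- matrix(c(4, 4.1), 1, dimnames = list("g", c("t1", "t2")))
#' call_expressed(m)  # 4 is not expressed, 4.1 is
#' @export
call_expressed <- function(mat, threshold = 4) {
  if (!is.numeric(mat) || !is.matrix(mat))
    stop("'mat' must be a numeric matrix", call. = FALSE)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at row %d, column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  structure(mat > threshold, threshold = threshold)
}

#' Read a protein-to-gene map
#'
#' Tab-separated file with columns \code{protein} and \code{gene};
#' splice variants of one gene map to the same gene identifier.
#'
#' @param path path to the TSV file.
#' @return named character vector, protein id -> gene id.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("protein", "gene") %in% names(df)))
    stop("gene map must have columns 'protein' and 'gene'", call. = FALSE)
  stats::setNames(df$gene, df$protein)
}

## map proteins to genes; unmapped proteins default to identity (the
## protein id doubles as its gene id), reported once per call
map_genes <- function(proteins, gmap = NULL) {
  if (is.null(gmap)) return(stats::setNames(proteins, proteins))
  g <- gmap[proteins]
  missing <- is.na(g)
  if (any(missing)) {
    message("gene map: identity mapping assumed for ",
            sum(missing), " protein(s): ",
            paste(utils::head(proteins[missing], 5L), collapse = ", "),
            if (sum(missing) > 5L) ", ..." else "")
    g[missing] <- proteins[missing]
  }
  stats::setNames(as.character(g), proteins)
}

#' Tissues where a protein set is jointly expressed
#'
#' Maps each protein to its encoding gene and returns the tissues in
#' which every gene of the set is called expressed. An empty result
#' means the set is never co-expressed. The length of the result is the
#' set's tissue count used in the tissue-count distribution analyses.
#'
#' @param S character vector of protein identifiers (any size >= 1).
#' @param calls logical call matrix from [call_expressed()].
#' @param gmap optional protein-to-gene map; proteins absent from the
#'   map use their own id as gene id.
#' @return character vector of tissue labels (possibly empty).
#' @export
joint_tissues <- function(S, calls, gmap = NULL) {
  genes <- unique(unname(map_genes(unique(as.character(S)), gmap)))
  miss <- setdiff(genes, rownames(calls))
  if (length(miss) > 0L)
    stop("no expression data for gene(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  joint <- colSums(!calls[genes, , drop = FALSE]) == 0L
  colnames(calls)[joint]
}

#' Restrict a network to proteins with expression data
#'
#' Drops every protein whose encoding gene has no row in the call
#' matrix, then iteratively drops proteins left without any interaction
#' (their only partners lacked data), mirroring the construction of the
#' expression-filtered interaction network. A protein whose only edge is
#' its self-interaction is kept.
#'
#' @param net a \code{ppi_network}.
#' @param calls logical call matrix from [call_expressed()].
#' @param gmap optional protein-to-gene map.
#' @param name label for the filtered network.
#' @return a \code{ppi_network}.
#' @export
expression_filtered_network <- function(net, calls, gmap = NULL,
                                        name = paste0(net$name, "_exp")) {
  stopifnot_network(net)
  genes <- map_genes(net$nodes, gmap)
  covered <- net$nodes[genes %in% rownames(calls)]
  keep <- net$edges[, 1L] %in% covered & net$edges[, 2L] %in% covered
  em <- net$edges[keep, , drop = FALSE]
  repeat {
    deg <- table(factor(as.vector(em), levels = covered))
    alive <- names(deg)[deg > 0L]
    if (length(alive) == length(covered)) break
    covered <- alive
    keep <- em[, 1L] %in% covered & em[, 2L] %in% covered
    em <- em[keep, , drop = FALSE]
  }
  ppi_network(em, nodes = character(), name = name)
}
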