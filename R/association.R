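## Co-expression statistics over connected 4-node subsets: contingency
## tests, co-expression ratios, the resampled fraction-of-co-expression
## null, and tissue-count rank comparisons.

#' Enumerate connected 4-node subsets with co-expression annotation
#'
#' The working table behind all 4-set co-expression analyses: one row
#' per connected 4-node subset of the network, with its tetramer-like
#' status (induced subgraph embeds the 4-cycle) and the number of
#' tissues in which the four encoding genes are jointly expressed.
#'
#' @param net a \code{ppi_network}.
#' @param calls optional logical call matrix from [call_expressed()];
#'   when supplied every network protein's gene must have a row.
#' @param gmap optional protein-to-gene map.
#' @return data.frame with columns \code{p1..p4} (member ids, sorted
#'   within each row), \code{tetramer_like} (logical) and, when calls
#'   are supplied, \code{n_joint_tissues} (integer).
#' @export
connected_foursets <- function(net, calls = NULL, gmap = NULL) {
  stopifnot_network(net)
  certs <- census_code_info(4L)
  keep <- !is.na(certs)
  sets <- cpp_foursets(adjacency_matrix(net), keep)
  df <- data.frame(matrix(net$nodes[sets[, 1:4]], ncol = 4L,
                          dimnames = list(NULL, paste0("p", 1:4))),
                   stringsAsFactors = FALSE)
  df$tetramer_like <- sets[, 5L] %in% tetramer_like_codes()
  if (!is.null(calls)) {
    genes <- map_genes(net$nodes, gmap)
    miss <- setdiff(unique(unname(genes)), rownames(calls))
    if (length(miss) > 0L)
      stop("no expression data for gene(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    rowidx <- match(genes, rownames(calls))
    if (nrow(sets) > 0L) {
      J <- calls[rowidx[sets[, 1L]], , drop = FALSE] &
           calls[rowidx[sets[, 2L]], , drop = FALSE] &
           calls[rowidx[sets[, 3L]], , drop = FALSE] &
           calls[rowidx[sets[, 4L]], , drop = FALSE]
      df$n_joint_tissues <- as.integer(rowSums(J))
    } else {
      df$n_joint_tissues <- integer(0)
    }
  }
  df
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction) with
#' one degree of freedom, as used for all printed association tests
#' between subgraph class and co-expression.
#'
#' @param tab 2x2 numeric matrix of nonnegative counts, or the four
#'   counts \code{c(a, b, c, d)} filled row-wise.
#' @return an object of class \code{htest} from [stats::chisq.test()].
#' @examples
#' chi2_2x2(rbind(c(1134, 217), c(4388, 1896)))  # X-squared = 110.6
#' @export
chi2_2x2 <- function(tab) {
  if (!is.matrix(tab) && length(tab) != 4L)
    stop("expected a 2x2 table", call. = FALSE)
  m <- if (is.matrix(tab)) tab else matrix(tab, 2L, 2L, byrow = TRUE)
  if (!all(dim(m) == c(2L, 2L)))
    stop("expected a 2x2 table", call. = FALSE)
  if (any(m < 0) || any(!is.finite(m)))
    stop("cell counts must be finite and nonnegative", call. = FALSE)
  if (sum(m) <= 0) stop("empty table", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: zero row or column marginal", call. = FALSE)
  suppressWarnings(stats::chisq.test(m, correct = FALSE))
}

#' Co-expression ratio
#'
#' Ratio of jointly expressed to never co-expressed protein sets, e.g.
#' 1134:217 = 5.23 for tetramer-like sets in the reference analysis.
#'
#' @param n_co number of co-expressed sets.
#' @param n_not number of never co-expressed sets (> 0).
#' @return numeric ratio \code{n_co / n_not}.
#' @export
coexpression_ratio <- function(n_co, n_not) {
  if (n_not <= 0) stop("'n_not' must be positive", call. = FALSE)
  n_co / n_not
}

#' Resampling null for the fraction of co-expression
#'
#' The observed statistic is the fraction of tetramer-like 4-sets whose
#' encoding genes share at least one expressed tissue. Each replicate
#' draws the same number of connected 4-sets uniformly without
#' replacement from all connected 4-sets of the network and records its
#' co-expressed fraction; the empirical p-value is the fraction of
#' replicates at least as co-expressed as observed.
#'
#' @param net a \code{ppi_network}.
#' @param calls logical call matrix from [call_expressed()].
#' @param gmap optional protein-to-gene map.
#' @param k sample size per replicate; defaults to the number of
#'   tetramer-like sets (the reference analysis samples 1351 sets from
#'   7635).
#' @param reps number of replicates (reference: 10^4).
#' @param seed integer seed.
#' @param replace sample with replacement within a replicate? Default
#'   \code{FALSE}.
#' @return object of class \code{coexpression_null}: list with
#'   \code{observed_fraction}, \code{null_fractions}, \code{p},
#'   \code{n_tetramer_like}, \code{n_foursets}, \code{k}, \code{reps}.
#' @export
fraction_coexpression_null <- function(net, calls, gmap = NULL, k = NULL,
                                       reps = 1000L, seed = 1L,
                                       replace = FALSE) {
  df <- connected_foursets(net, calls, gmap)
  co <- df$n_joint_tissues > 0L
  ntl <- sum(df$tetramer_like)
  if (ntl == 0L)
    stop("network has no tetramer-like 4-sets", call. = FALSE)
  if (is.null(k)) k <- ntl
  if (!replace && k > nrow(df))
    stop("k exceeds the number of connected 4-sets", call. = FALSE)
  observed <- mean(co[df$tetramer_like])
  set.seed(as.integer(seed))
  null <- vapply(seq_len(reps), function(i)
    mean(co[sample.int(nrow(df), k, replace = replace)]), numeric(1))
  structure(list(observed_fraction = observed, null_fractions = null,
                 p = mean(null >= observed),
                 n_tetramer_like = ntl, n_foursets = nrow(df),
                 k = as.integer(k), reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "coexpression_null")
}

#' @export
print.coexpression_null <- function(x, ...) {
  ep <- empirical_p(x$observed_fraction,
                    c(x$null_fractions, x$observed_fraction))
  lab <- if (all(x$null_fractions < x$observed_fraction))
    paste0("<", format(1 / x$reps)) else format(x$p)
  cat(sprintf(paste0(
    "fraction-of-co-expression null\n",
    "  observed fraction (tetramer-like sets): %.4g  [%d of %d sets]\n",
    "  resampling null: %d samples of %d from %d connected 4-sets\n",
    "  null mean %.4g, range [%.4g, %.4g];  empirical p %s\n"),
    x$observed_fraction, round(x$observed_fraction * x$n_tetramer_like),
    x$n_tetramer_like, x$reps, x$k, x$n_foursets,
    mean(x$null_fractions), min(x$null_fractions), max(x$null_fractions),
    lab))
  invisible(x)
}

## Mann-Whitney U with tie-corrected normal approximation; U is the
## statistic of the first sample (number of (x, y) pairs with x > y,
## ties counting 1/2)
mann_whitney_uz <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, z = 0, p = 1))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Tissue-count distributions of 4-sets, tetramer-like vs other
#'
#' For every connected 4-node subset, counts the tissues in which the
#' four encoding genes are jointly expressed, and compares the
#' distribution for tetramer-like subsets against all other connected
#' subsets with a two-sided Mann-Whitney rank test (normal approximation
#' with tie correction). Both the raw U statistic of the tetramer-like
#' group and the standardized z are reported.
#'
#' @param net a \code{ppi_network}.
#' @param calls logical call matrix from [call_expressed()].
#' @param gmap optional protein-to-gene map.
#' @return object of class \code{tissue_count_comparison}: list with
#'   \code{counts_tetramer_like} and \code{counts_other} (integer
#'   vectors of per-set tissue counts), \code{hist_tetramer_like} and
#'   \code{hist_other} (tables), \code{U}, \code{z}, \code{p}.
#' @export
tissue_count_comparison <- function(net, calls, gmap = NULL) {
  df <- connected_foursets(net, calls, gmap)
  x <- df$n_joint_tissues[df$tetramer_like]
  y <- df$n_joint_tissues[!df$tetramer_like]
  if (length(x) == 0L || length(y) == 0L)
    stop("both the tetramer-like and the other group must be nonempty",
         call. = FALSE)
  mw <- mann_whitney_uz(x, y)
  structure(list(counts_tetramer_like = x, counts_other = y,
                 hist_tetramer_like = table(x), hist_other = table(y),
                 U = mw$U, z = mw$z, p = mw$p),
            class = "tissue_count_comparison")
}

#' @export
print.tissue_count_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "tissue-count comparison (connected 4-sets)\n",
    "  tetramer-like: n = %d, median %g tissues; other: n = %d, median %g\n",
    "  Mann-Whitney U = %.4g, z = %.4g, two-sided p = %.3g\n"),
    length(x$counts_tetramer_like),
    stats::median(x$counts_tetramer_like),
    length(x$counts_other), stats::median(x$counts_other),
    x$U, x$z, x$p))
  invisible(x)
}
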