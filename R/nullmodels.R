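#' Configuration for switching randomization
#'
#' The null model rewires the observed network by repeated double-edge
#' swaps. The number of successful swaps \code{s} is drawn uniformly from
#' \code{[multiplier_low * E, multiplier_high * E]}, where \code{E} is the
#' edge count; the defaults (100 and 200) give heavy mixing so no trace
#' of the original wiring survives while every node keeps its stub degree
#' (a self-loop carries two stubs). With \code{preserve_self_loops} the
#' swap proposals that would create or destroy a self-interaction are
#' rejected, so the randomized ensemble also conserves the number of
#' self-interactions.
#'
#' @param multiplier_low,multiplier_high positive swap multipliers,
#'   \code{multiplier_low <= multiplier_high}.
#' @param preserve_self_loops conserve the self-loop count?
#' @param seed integer seed recorded in the config; may be \code{NULL}.
#' @return object of class \code{switch_config}.
#' @export
switch_config <- function(multiplier_low = 100, multiplier_high = 200,
                          preserve_self_loops = FALSE, seed = NULL) {
  if (!(multiplier_low > 0 && multiplier_low <= multiplier_high))
    stop("need 0 < multiplier_low <= multiplier_high", call. = FALSE)
  structure(list(multiplier_low = multiplier_low,
                 multiplier_high = multiplier_high,
                 preserve_self_loops = isTRUE(preserve_self_loops),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "switch_config")
}

#' Degree-preserving switching randomization
#'
#' Returns a randomized network with the same node set, edge count and
#' stub-degree sequence as the input: pairs of edges are picked at random
#' and two of their ends exchanged (both rewiring pairings equally
#' likely). Proposals that would duplicate an existing edge, or merely
#' recreate the removed pair, are rejected and redrawn; only successful
#' swaps count toward \code{s}. Self-loops carry two stubs, so a swap may
#' legitimately create or absorb a self-interaction unless
#' \code{preserve_self_loops} is set in the config. Networks that admit
#' no legal swap (e.g. a triangle) are returned unchanged.
#'
#' @param net a \code{ppi_network} with at least 2 edges.
#' @param config a [switch_config()].
#' @param seed optional integer seed; defaults to the config's seed. When
#'   \code{NULL} the current RNG state is used.
#' @return a randomized \code{ppi_network}.
#' @export
switch_randomize <- function(net, config = switch_config(),
                             seed = config$seed) {
  stopifnot_network(net)
  E <- n_edges(net)
  if (E < 2L) stop("randomization requires at least 2 edges", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lo <- as.integer(ceiling(config$multiplier_low * E))
  hi <- as.integer(floor(config$multiplier_high * E))
  s <- if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
  idx <- matrix(match(net$edges, net$nodes) - 1L, ncol = 2L)
  out <- cpp_switch_randomize(idx, length(net$nodes), s,
                              config$preserve_self_loops,
                              max_attempts = 100 * s + 1000)
  em <- matrix(net$nodes[out + 1L], ncol = 2L)
  ppi_network(em, nodes = net$nodes, name = paste0(net$name, "[randomized]"))
}

#' Generate an ensemble of randomized networks
#'
#' Produces \code{size} independent randomizations, each starting from
#' the original network and re-seeded deterministically from
#' \code{seed + replicate index}, so a fixed seed reproduces the whole
#' ensemble and replicates are independent of evaluation order.
#'
#' @param net a \code{ppi_network}.
#' @param size ensemble size (the reference analyses use 10^4).
#' @param config a [switch_config()].
#' @param seed base integer seed (required for reproducibility).
#' @param FUN optional function applied to each randomized network; when
#'   supplied, the list of \code{FUN} values is returned instead of the
#'   networks, avoiding storage of the whole ensemble.
#' @return list of \code{ppi_network}, or of \code{FUN} values.
#' @export
generate_ensemble <- function(net, size, config = switch_config(),
                              seed = 1L, FUN = NULL) {
  stopifnot_network(net)
  size <- as.integer(size)
  if (size < 1L) stop("ensemble size must be >= 1", call. = FALSE)
  seed <- as.integer(seed)
  lapply(seq_len(size), function(i) {
    r <- switch_randomize(net, config, seed = seed + i)
    if (is.null(FUN)) r else FUN(r)
  })
}

#' Empirical p-value against an ensemble
#'
#' The empirical p-value of an observed count is the fraction of
#' ensemble replicates whose count is at least the observed one. When no
#' replicate reaches the observed count the p-value is below the
#' resolution of the ensemble and is reported as \code{"<1/N"} (e.g.
#' \code{"<1e-04"} for an ensemble of 10^4).
#'
#' @param observed observed count.
#' @param ensemble_counts numeric vector of replicate counts, nonempty.
#' @return list with \code{p} (numeric, \code{k/N}), \code{n_ensemble},
#'   \code{below_resolution} (logical) and \code{label} (the rendered
#'   p-value string).
#' @export
empirical_p <- function(observed, ensemble_counts) {
  if (length(ensemble_counts) == 0L)
    stop("ensemble must be nonempty", call. = FALSE)
  N <- length(ensemble_counts)
  k <- sum(ensemble_counts >= observed)
  below <- k == 0L
  list(p = k / N, n_ensemble = N, below_resolution = below,
       label = if (below) paste0("<", format(1 / N)) else format(k / N))
}

#' Summary statistics of an ensemble of counts
#'
#' Reports the mean, median (mid-point rule for even lengths), sample
#' standard deviation (denominator \code{N - 1}) and standard error
#' \code{sd / sqrt(N)} of replicate counts.
#'
#' @param counts numeric vector, length at least 2.
#' @return named list \code{mean}, \code{median}, \code{sd}, \code{se},
#'   \code{n}.
#' @export
summarize_ensemble <- function(counts) {
  if (length(counts) < 2L)
    stop("ensemble summaries need at least 2 replicates", call. = FALSE)
  n <- length(counts)
  s <- stats::sd(counts)
  list(mean = mean(counts), median = stats::median(counts),
       sd = s, se = s / sqrt(n), n = n)
}

#' Multiple-testing correction for motif p-values
#'
#' Adjusts a vector of per-pattern empirical p-values, by default with
#' the Benjamini-Hochberg step-up false-discovery-rate procedure
#' (Bonferroni available via \code{method}). Thin wrapper over
#' [stats::p.adjust()] with input validation.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @param method \code{"BH"} or \code{"bonferroni"}.
#' @return adjusted p-values, same order and length.
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = method)
}

resolve_statistic <- function(statistic, size) {
  if (is.function(statistic)) return(statistic)
  switch(statistic,
    induced = function(net) induced_census(net, size)$counts,
    tetramer = function(net) c(tetramer_like = count_tetramer_like(net)),
    ntp = function(net) c(`2NTP` = count_ntp(net, "2NTP"),
                          `3NTP` = count_ntp(net, "3NTP")),
    stop("unknown statistic: ", statistic, call. = FALSE))
}

#' Motif over-representation test against the switching null model
#'
#' The central significance machinery: computes a count statistic on the
#' observed network, recomputes it on an ensemble of degree-preserving
#' randomizations, and reports per-pattern ensemble summaries, empirical
#' p-values and multiple-testing-adjusted p-values, in the style of the
#' reference motif analyses (observed count, ensemble mean / median /
#' sd / se, empirical p).
#'
#' @param net a \code{ppi_network}.
#' @param statistic \code{"induced"} (per-class induced census at
#'   \code{size}), \code{"tetramer"} (tetramer-like embedded count),
#'   \code{"ntp"} (2NTP and 3NTP counts; combine with a loop-preserving
#'   config), or a function \code{net -> named numeric vector}.
#' @param size subset size for the induced census statistic.
#' @param ensemble_size number of randomized replicates (reference
#'   analyses use 10^4).
#' @param config a [switch_config()].
#' @param seed base integer seed for the ensemble.
#' @param adjust multiple-testing method passed to [adjust_pvalues()].
#' @return object of class \code{motif_test}: a list with the result
#'   \code{table} (data.frame: pattern, observed, mean, median, sd, se,
#'   p_empirical, p_label, p_adjusted), \code{ensemble} (matrix of
#'   replicate counts, patterns x replicates), and the call settings.
#' @examples
#' \donttest{
#' study <- generate_synthetic_study(synthetic_config(seed = 1))
#' mt <- motif_test(study$network, "tetramer", ensemble_size = 100, seed = 1)
#' mt
#' }
#' @export
motif_test <- function(net, statistic = c("induced", "tetramer", "ntp"),
                       size = 4L, ensemble_size = 1000L,
                       config = switch_config(), seed = 1L,
                       adjust = c("BH", "bonferroni")) {
  stopifnot_network(net)
  if (!is.function(statistic)) statistic <- match.arg(statistic)
  adjust <- match.arg(adjust)
  fn <- resolve_statistic(statistic, size)
  observed <- fn(net)
  reps <- generate_ensemble(net, ensemble_size, config, seed = seed,
                            FUN = fn)
  ens <- do.call(cbind, reps)
  rownames(ens) <- names(observed)
  res <- lapply(seq_along(observed), function(i) {
    s <- summarize_ensemble(ens[i, ])
    e <- empirical_p(observed[i], ens[i, ])
    data.frame(pattern = names(observed)[i], observed = observed[i],
               mean = s$mean, median = s$median, sd = s$sd, se = s$se,
               p_empirical = e$p, p_label = e$label,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  tab$p_adjusted <- adjust_pvalues(tab$p_empirical, adjust)
  structure(list(table = tab, ensemble = ens,
                 network_name = net$name, statistic = statistic,
                 size = size, ensemble_size = as.integer(ensemble_size),
                 config = config, seed = as.integer(seed),
                 adjust = adjust),
            class = "motif_test")
}

#' @export
print.motif_test <- function(x, digits = 4, ...) {
  cat(sprintf("motif_test: network '%s', statistic %s, %d randomized replicates\n",
              x$network_name,
              if (is.function(x$statistic)) "<function>" else
                sprintf("'%s'", x$statistic),
              x$ensemble_size))
  cat(sprintf("null model: degree-preserving switching (s ~ U[%gE, %gE])%s\n",
              x$config$multiplier_low, x$config$multiplier_high,
              if (x$config$preserve_self_loops)
                ", self-loop count conserved" else ""))
  tab <- x$table
  tab$p_adjusted <- signif(tab$p_adjusted, 3)
  num <- c("mean", "median", "sd", "se")
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print(tab[, c("pattern", "observed", "mean", "median", "sd", "se",
                "p_label", "p_adjusted")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.motif_test <- function(object, alpha = 0.05, ...) {
  sig <- object$table$pattern[object$table$p_adjusted < alpha]
  cat(sprintf("%d of %d patterns over-represented at adjusted p < %g (%s)\n",
              length(sig), nrow(object$table), alpha, object$adjust))
  if (length(sig) > 0L) cat("  ", paste(sig, collapse = ", "), "\n")
  invisible(object$table)
}

#' @export
as.data.frame.motif_test <- function(x, ...) x$table
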