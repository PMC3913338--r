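## End-to-end orchestration: assemble the network, run the census and
## null-model tests, the co-expression analyses and the tetramer
## listing, writing one TSV per analysis plus a machine-readable
## summary. Every output file carries a header with package version,
## seed and a configuration digest.

config_digest <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

output_header <- function(seed, digest) {
  sprintf("# tetranet %s | seed=%d | config=%s",
          as.character(utils::packageVersion("tetranet")), seed, digest)
}

write_tsv_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full tetramer-motif analysis pipeline
#'
#' Executes the analysis stages end to end on in-memory inputs:
#' three-hybrid expansion (optional), induced census for sizes 2-4,
#' motif over-representation against the switching null (per-pattern
#' induced census and the embedded tetramer-like count), the
#' tetramer-like / census identity check, expression filtering,
#' co-expression association statistics, the resampled
#' fraction-of-co-expression null, the tissue-count rank comparison,
#' the prospective-tetramer list (with clade partition when an
#' annotation is given) and 2NTP/3NTP counts under the loop-preserving
#' null. One TSV per analysis is written to \code{out_dir}.
#'
#' @param net a \code{ppi_network}.
#' @param expression numeric gene-by-tissue log2 matrix.
#' @param gene_map optional protein-to-gene map.
#' @param clades optional clade annotation vector.
#' @param three_hybrid optional three-hybrid record data.frame (see
#'   [read_three_hybrid()]); positive records are expanded into edges
#'   and merged into the network before analysis.
#' @param out_dir output directory; created if needed. \code{NULL}
#'   skips file output.
#' @param ensemble_size randomized replicates for the null-model tests.
#' @param null_reps replicates for the fraction-of-co-expression null.
#' @param threshold expression call threshold.
#' @param preserve_self_loops use the loop-conserving null for the
#'   per-pattern and tetramer tests as well (the 2NTP/3NTP test always
#'   conserves loops).
#' @param seed integer seed governing all randomization.
#' @return object of class \code{pipeline_result} (list of all stage
#'   results), invisibly when \code{out_dir} is given.
#' @export
run_pipeline <- function(net, expression, gene_map = NULL, clades = NULL,
                         three_hybrid = NULL, out_dir = NULL,
                         ensemble_size = 1000L, null_reps = 1000L,
                         threshold = 4, preserve_self_loops = FALSE,
                         seed = 1L) {
  stopifnot_network(net)
  seed <- as.integer(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  digest <- config_digest(list(net$name, dim(expression), ensemble_size,
                               null_reps, threshold, preserve_self_loops,
                               seed))
  hdr <- output_header(seed, digest)

  ## -- assemble ------------------------------------------------------
  if (!is.null(three_hybrid)) {
    extra <- stage("assemble", expand_three_hybrid(three_hybrid, net))
    net <- ppi_network(rbind(net$edges, extra), nodes = net$nodes,
                       name = net$name)
  }
  calls <- stage("expression", call_expressed(expression, threshold))

  ## -- census --------------------------------------------------------
  censuses <- stage("census", lapply(2:4, induced_census, net = net))
  tl_count <- count_tetramer_like(net)
  ## set-counting identity: embedded tetramer count equals the summed
  ## induced counts over the 4-cycle-embedding classes
  tl_ids <- vapply(tetramer_like_patterns(full_catalogue()), `[[`, "",
                   "pattern_id")
  stopifnot(tl_count == sum(censuses[[3L]]$counts[tl_ids]))

  ## -- null-model tests ---------------------------------------------
  cfg <- switch_config(preserve_self_loops = preserve_self_loops)
  mt_induced <- stage("nulltest", motif_test(
    net, "induced", size = 4L, ensemble_size = ensemble_size,
    config = cfg, seed = seed))
  mt_tet <- stage("nulltest", motif_test(
    net, "tetramer", ensemble_size = ensemble_size, config = cfg,
    seed = seed + 1L))
  mt_ntp <- stage("nulltest", motif_test(
    net, "ntp", ensemble_size = ensemble_size,
    config = switch_config(preserve_self_loops = TRUE), seed = seed + 2L))

  ## -- co-expression -------------------------------------------------
  net_exp <- stage("coexpress",
                   expression_filtered_network(net, calls, gene_map))
  foursets <- stage("coexpress", connected_foursets(net_exp, calls,
                                                    gene_map))
  co <- foursets$n_joint_tissues > 0L
  assoc_tab <- rbind(`tetramer-like` = c(sum(co & foursets$tetramer_like),
                                         sum(!co & foursets$tetramer_like)),
                     other = c(sum(co & !foursets$tetramer_like),
                               sum(!co & !foursets$tetramer_like)))
  colnames(assoc_tab) <- c("co-expressed", "not co-expressed")
  assoc <- if (all(rowSums(assoc_tab) > 0) && all(colSums(assoc_tab) > 0))
    chi2_2x2(assoc_tab) else NULL
  frac_null <- stage("coexpress", fraction_coexpression_null(
    net_exp, calls, gene_map, reps = null_reps, seed = seed + 3L))
  tissue_cmp <- if (any(foursets$tetramer_like) &&
                    any(!foursets$tetramer_like))
    stage("coexpress", tissue_count_comparison(net_exp, calls, gene_map))
  else NULL

  ## -- tetramers -----------------------------------------------------
  pro <- stage("tetramers", prospective_tetramers(net_exp, calls,
                                                  gene_map, clades))
  clade_counts <- if (!is.null(clades))
    stage("tetramers", partition_by_clade(pro, clades)) else NULL

  out <- structure(list(
    network = net, network_exp = net_exp, censuses = censuses,
    tetramer_like_count = tl_count, motif_test_induced = mt_induced,
    motif_test_tetramer = mt_tet, motif_test_ntp = mt_ntp,
    association_table = assoc_tab, association_chi2 = assoc,
    fraction_null = frac_null, tissue_comparison = tissue_cmp,
    prospective_tetramers = pro, clade_counts = clade_counts,
    seed = seed, config_digest = digest),
    class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_report(do.call(rbind, lapply(censuses, as.data.frame)),
                     file.path(out_dir, "census.tsv"), hdr)
    write_tsv_report(mt_induced$table,
                     file.path(out_dir, "motif_test_induced.tsv"), hdr)
    write_tsv_report(mt_tet$table,
                     file.path(out_dir, "motif_test_tetramer.tsv"), hdr)
    write_tsv_report(mt_ntp$table,
                     file.path(out_dir, "motif_test_ntp.tsv"), hdr)
    write_tsv_report(as.data.frame.table(assoc_tab,
                                         responseName = "count"),
                     file.path(out_dir, "association.tsv"), hdr)
    write_tsv_report(as.data.frame(pro),
                     file.path(out_dir, "prospective_tetramers.tsv"), hdr)
    summary_df <- data.frame(
      quantity = c("n_nodes", "n_edges", "n_self_loops",
                   "n_nodes_exp", "n_edges_exp",
                   "tetramer_like_count", "tetramer_like_p",
                   "observed_coexpression_fraction", "fraction_null_p",
                   "association_chi2", "association_p",
                   "n_prospective_tetramers", "n_not_coexpressed"),
      value = c(n_nodes(net), n_edges(net), n_self_loops(net),
                n_nodes(net_exp), n_edges(net_exp),
                tl_count, mt_tet$table$p_empirical[1L],
                frac_null$observed_fraction, frac_null$p,
                if (is.null(assoc)) NA else unname(assoc$statistic),
                if (is.null(assoc)) NA else assoc$p.value,
                nrow(pro), attr(pro, "n_not_coexpressed")))
    write_tsv_report(summary_df, file.path(out_dir, "summary.tsv"), hdr)
    return(invisible(out))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("tetranet pipeline result\n")
  print(x$network)
  cat(sprintf("  tetramer-like 4-sets: %d (empirical p %s)\n",
              x$tetramer_like_count, x$motif_test_tetramer$table$p_label))
  cat(sprintf("  co-expressed fraction %.3f vs null p %s\n",
              x$fraction_null$observed_fraction,
              if (x$fraction_null$p == 0)
                paste0("<", format(1 / x$fraction_null$reps))
              else format(x$fraction_null$p)))
  cat(sprintf("  prospective tetramers: %d\n",
              nrow(x$prospective_tetramers)))
  invisible(x)
}
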