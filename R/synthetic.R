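#' Configuration of the synthetic study generator
#'
#' Defines the conditions under which the whole pipeline is exercised
#' without external data: a random interaction network with planted
#' tetramer-compatible 4-cycles, a matched gene-by-tissue expression
#' matrix in which planted sets are co-expressed with high probability
#' and background sets only rarely, and a clade annotation.
#'
#' Defaults: 40 proteins, 120 ordinary edges of which 8 vertex-disjoint
#' planted 4-cycles account for 32, 4 self-loops, 20 tissues; a planted
#' set is jointly switched on in a tissue with probability
#' \code{p_in = 0.9}, background genes are expressed independently with
#' \code{p_out = 0.2}; expressed and silent log2 levels are drawn near 8
#' and 1 so that the standard threshold of 4 recovers the designed calls
#' exactly; 85\% of proteins are MIKC and planted sets are placed inside
#' the MIKC clade, mirroring the predominance of MIKC proteins among
#' tetramer candidates.
#'
#' @param n_nodes,n_edges network size (ordinary, non-loop edges).
#' @param n_planted_quads number of vertex-disjoint planted 4-cycles.
#' @param n_self_loops number of random self-loops added.
#' @param n_tissues number of tissues in the expression matrix.
#' @param p_in per-tissue probability, within a planted set's own
#'   tissue block, that the set is jointly expressed (see
#'   [generate_expression()]).
#' @param p_out per-tissue background expression probability.
#' @param expr_high,expr_low log2 levels for expressed / silent calls.
#' @param threshold call threshold; must satisfy
#'   \code{expr_low < threshold < expr_high}.
#' @param frac_mikc fraction of proteins annotated MIKC.
#' @param plant_in_mikc force planted-set members into the MIKC clade?
#' @param seed integer seed.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_nodes = 40L, n_edges = 120L,
                             n_planted_quads = 8L, n_self_loops = 4L,
                             n_tissues = 20L, p_in = 0.9, p_out = 0.2,
                             expr_high = 8, expr_low = 1, threshold = 4,
                             frac_mikc = 0.85, plant_in_mikc = TRUE,
                             seed = NULL) {
  cfg <- list(n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
              n_planted_quads = as.integer(n_planted_quads),
              n_self_loops = as.integer(n_self_loops),
              n_tissues = as.integer(n_tissues),
              p_in = p_in, p_out = p_out,
              expr_high = expr_high, expr_low = expr_low,
              threshold = threshold, frac_mikc = frac_mikc,
              plant_in_mikc = isTRUE(plant_in_mikc),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$n_planted_quads * 4L > cfg$n_nodes)
    stop("not enough nodes for vertex-disjoint planted 4-cycles",
         call. = FALSE)
  if (cfg$n_edges < cfg$n_planted_quads * 4L)
    stop("edge budget smaller than the planted edges", call. = FALSE)
  if (cfg$n_edges > choose(cfg$n_nodes, 2L))
    stop("edge budget exceeds the number of node pairs", call. = FALSE)
  if (cfg$n_self_loops > cfg$n_nodes)
    stop("more self-loops than nodes", call. = FALSE)
  if (cfg$n_planted_quads > 0L && cfg$n_tissues < cfg$n_planted_quads)
    stop("need at least one tissue per planted set", call. = FALSE)
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!(expr_low < threshold && threshold < expr_high))
    stop("need expr_low < threshold < expr_high", call. = FALSE)
  if (frac_mikc < 0 || frac_mikc > 1)
    stop("frac_mikc must lie in [0, 1]", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Generate a network with planted tetramer-compatible motifs
#'
#' Plants \code{n_planted_quads} vertex-disjoint 4-cycles on randomly
#' chosen nodes, fills the remaining edge budget with uniform random
#' non-duplicate node pairs, and adds random self-loops. The planted
#' sets are returned as ground truth; each is tetramer-like by
#' construction (background edges can only add interactions).
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed; defaults to the config's seed.
#' @return list with \code{network} (a \code{ppi_network}) and
#'   \code{planted} (list of sorted 4-vectors of protein ids).
#' @export
generate_network <- function(cfg, seed = cfg$seed) {
  if (!inherits(cfg, "synthetic_config"))
    stop("'cfg' must be a synthetic_config", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nodes <- sprintf("P%02d", seq_len(cfg$n_nodes))
  quad_nodes <- sample(nodes, 4L * cfg$n_planted_quads)
  planted <- split(quad_nodes,
                   rep(seq_len(cfg$n_planted_quads), each = 4L))
  planted <- unname(lapply(planted, sort))
  edges <- do.call(rbind, lapply(planted, function(q) {
    q <- sample(q)  # random cyclic order
    cbind(q, c(q[-1L], q[1L]))
  }))
  if (is.null(edges)) edges <- matrix(character(), ncol = 2L)
  have <- function(em) paste(pmin(em[, 1L], em[, 2L]),
                             pmax(em[, 1L], em[, 2L]), sep = "\r")
  known <- have(edges)
  need <- cfg$n_edges - nrow(edges)
  while (need > 0L) {
    a <- sample(nodes, 2L)
    k <- paste(min(a), max(a), sep = "\r")
    if (!k %in% known) {
      edges <- rbind(edges, a)
      known <- c(known, k)
      need <- need - 1L
    }
  }
  if (cfg$n_self_loops > 0L) {
    lp <- sample(nodes, cfg$n_self_loops)
    edges <- rbind(edges, cbind(lp, lp))
  }
  list(network = ppi_network(edges, nodes = nodes, name = "synthetic"),
       planted = planted)
}

#' Generate an expression matrix matched to planted sets
#'
#' The tissues are partitioned into one contiguous block per planted
#' set (as equally as possible). Within its own block, a planted set is
#' jointly switched on per tissue with probability \code{p_in} (all
#' member genes expressed together); outside its block its genes are
#' silent. Background genes are expressed independently with
#' probability \code{p_out} in every tissue. This gives planted sets a
#' high probability of sharing at least one tissue while any other
#' 4-set — background or a mixture of planted sets — co-expresses only
#' rarely, the designed contrast of the co-expression analyses. Values
#' are drawn from narrow uniform bands around \code{expr_high} and
#' \code{expr_low}, so thresholding at \code{cfg$threshold} recovers the
#' designed calls deterministically — the randomness lives in the calls,
#' not in the thresholding.
#'
#' @param cfg a [synthetic_config()].
#' @param nodes character vector of protein ids.
#' @param planted_sets list of 4-vectors of protein ids (subsets of
#'   \code{nodes}).
#' @param gmap optional protein-to-gene map (identity by default).
#' @param seed integer seed; defaults to the config's seed.
#' @return numeric gene-by-tissue log2 matrix.
#' @export
generate_expression <- function(cfg, nodes, planted_sets, gmap = NULL,
                                seed = cfg$seed) {
  if (!all(unlist(planted_sets) %in% nodes))
    stop("planted sets must be subsets of 'nodes'", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  genes <- unique(unname(map_genes(nodes, gmap)))
  tissues <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
  on <- matrix(stats::runif(length(genes) * cfg$n_tissues) < cfg$p_out,
               length(genes), cfg$n_tissues,
               dimnames = list(genes, tissues))
  planted_genes <- unique(unname(map_genes(unique(unlist(planted_sets)),
                                           gmap)))
  on[planted_genes, ] <- FALSE
  nq <- length(planted_sets)
  if (nq > 0L) {
    ## one contiguous tissue block per planted set
    block <- sort(rep_len(seq_len(nq), cfg$n_tissues))
    for (i in seq_len(nq)) {
      qg <- unique(unname(map_genes(planted_sets[[i]], gmap)))
      bt <- which(block == i)
      block_on <- bt[stats::runif(length(bt)) < cfg$p_in]
      on[qg, block_on] <- TRUE
    }
  }
  jitter <- matrix(stats::runif(length(on), -0.5, 0.5), nrow(on))
  mat <- ifelse(on, cfg$expr_high, cfg$expr_low) + jitter
  dimnames(mat) <- dimnames(on)
  mat
}

#' Generate a clade annotation matched to planted sets
#'
#' Labels approximately \code{frac_mikc} of the proteins MIKC. When
#' \code{plant_in_mikc} is set, all planted-set members are MIKC and the
#' remaining MIKC slots are drawn from the other proteins.
#'
#' @param cfg a [synthetic_config()].
#' @param nodes character vector of protein ids.
#' @param planted_sets list of 4-vectors of protein ids.
#' @param seed integer seed; defaults to the config's seed.
#' @return named character vector, protein -> \code{"MIKC"} or
#'   \code{"non-MIKC"}.
#' @export
generate_annotation <- function(cfg, nodes, planted_sets,
                                seed = cfg$seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_mikc <- round(cfg$frac_mikc * length(nodes))
  ann <- stats::setNames(rep("non-MIKC", length(nodes)), nodes)
  if (cfg$plant_in_mikc) {
    pm <- unique(unlist(planted_sets))
    if (length(pm) > n_mikc)
      stop("frac_mikc too small to hold all planted-set members",
           call. = FALSE)
    extra <- sample(setdiff(nodes, pm), n_mikc - length(pm))
    ann[c(pm, extra)] <- "MIKC"
  } else {
    ann[sample(nodes, n_mikc)] <- "MIKC"
  }
  ann
}

#' Generate a complete synthetic study
#'
#' Bundles [generate_network()], [generate_expression()] and
#' [generate_annotation()] under sub-seeds derived from the config seed,
#' with an identity protein-to-gene map.
#'
#' @param cfg a [synthetic_config()]; its \code{seed} drives all three
#'   generators deterministically.
#' @return object of class \code{synthetic_study}: list with
#'   \code{network}, \code{planted}, \code{expression} (log2 matrix),
#'   \code{calls}, \code{annotation}, \code{gene_map}, \code{config}.
#' @examples
#' study <- generate_synthetic_study(synthetic_config(seed = 1))
#' study$network
#' @export
generate_synthetic_study <- function(cfg = synthetic_config()) {
  base <- if (is.null(cfg$seed)) stats::runif(1, 0, 2^20) else cfg$seed
  base <- as.integer(base)
  gn <- generate_network(cfg, seed = base)
  gmap <- stats::setNames(gn$network$nodes, gn$network$nodes)
  mat <- generate_expression(cfg, gn$network$nodes, gn$planted,
                             gmap = gmap, seed = base + 1L)
  ann <- generate_annotation(cfg, gn$network$nodes, gn$planted,
                             seed = base + 2L)
  structure(list(network = gn$network, planted = gn$planted,
                 expression = mat,
                 calls = call_expressed(mat, cfg$threshold),
                 annotation = ann, gene_map = gmap, config = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d nodes, %d edges, %d planted ",
                     "4-cycles, %d tissues\n"),
              n_nodes(x$network), n_edges(x$network),
              length(x$planted), ncol(x$expression)))
  invisible(x)
}

#' Write a synthetic study as a fixture directory
#'
#' Writes \code{network.tsv}, \code{expression.tsv}, \code{genemap.tsv},
#' \code{clades.tsv} and \code{truth.json} (planted sets and config
#' echo) into a directory, in the package's plain-text formats.
#'
#' @param study a [generate_synthetic_study()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_fixture_dir <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(study$network, file.path(dir, "network.tsv"))
  em <- data.frame(gene = rownames(study$expression),
                   study$expression, check.names = FALSE)
  utils::write.table(em, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(protein = names(study$gene_map),
                                gene = unname(study$gene_map)),
                     file.path(dir, "genemap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(protein = names(study$annotation),
                                clade = unname(study$annotation)),
                     file.path(dir, "clades.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- study$config
  cfg <- cfg[!vapply(cfg, is.null, NA)]
  scalar <- function(v) if (is.character(v)) paste0("\"", v, "\"") else
    if (is.logical(v)) tolower(as.character(v)) else format(v)
  cfg_json <- paste(sprintf("\"%s\": %s", names(cfg),
                            vapply(cfg, scalar, "")), collapse = ", ")
  planted_json <- paste(vapply(study$planted, function(q)
    paste0("[", paste0("\"", q, "\"", collapse = ", "), "]"), ""),
    collapse = ", ")
  writeLines(sprintf("{\"planted\": [%s], \"config\": {%s}}",
                     planted_json, cfg_json),
             file.path(dir, "truth.json"))
  invisible(dir)
}
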