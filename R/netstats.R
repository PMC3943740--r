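# Network summaries, herb-level statistics and hypergeometric enrichment.

#' Connected-component summary of a network
#'
#' "Clusters" are connected components with at least two nodes; isolated
#' nodes are counted separately. Percentages are of the whole network and
#' reported to one decimal (half-up), matching the convention of
#' reporting e.g. a largest cluster of 148/156 nodes as 94.9%.
#'
#' @param g interactome (`igraph`).
#' @return an object of class `component_summary`: list with integer
#'   fields `n_nodes`, `n_edges`, `n_isolated`, `n_clusters`,
#'   `largest_nodes`, `largest_edges` and one-decimal percentages
#'   `largest_node_pct`, `largest_edge_pct`.
#' @export
component_summary <- function(g) {
  .check_interactome(g)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0L) {
    out <- list(n_nodes = 0L, n_edges = 0L, n_isolated = 0L,
                n_clusters = 0L, largest_nodes = 0L, largest_edges = 0L,
                largest_node_pct = 0, largest_edge_pct = 0)
    class(out) <- "component_summary"
    return(out)
  }
  comp <- igraph::components(g)
  sizes <- comp$csize
  big <- which.max(sizes)
  largest_nodes <- as.integer(sizes[big])
  largest_edges <- if (largest_nodes >= 2L) {
    igraph::ecount(igraph::induced_subgraph(g, which(comp$membership == big)))
  } else 0L
  out <- list(
    n_nodes = n,
    n_edges = e,
    n_isolated = as.integer(sum(sizes == 1L)),
    n_clusters = as.integer(sum(sizes >= 2L)),
    largest_nodes = largest_nodes,
    largest_edges = as.integer(largest_edges),
    largest_node_pct = round_half_up(100 * largest_nodes / n, 1),
    largest_edge_pct = if (e > 0) round_half_up(100 * largest_edges / e, 1) else 0
  )
  class(out) <- "component_summary"
  out
}

#' @export
print.component_summary <- function(x, ...) {
  cat("<component_summary: ", x$n_nodes, " nodes, ", x$n_edges, " edges; ",
      x$n_isolated, " isolated + ", x$n_clusters, " cluster(s); largest ",
      x$largest_nodes, " nodes (", x$largest_node_pct, "%) / ",
      x$largest_edges, " edges (", x$largest_edge_pct, "%)>\n", sep = "")
  invisible(x)
}

#' Per-herb statistics of a compound-target network
#'
#' For every herb: the number of its compounds present in the network,
#' the mean number of targets per networked compound (one decimal,
#' half-up), the union of targets hit, and the targets hit by this herb
#' only. Compounds belonging to several herbs contribute to every member
#' herb's statistics.
#'
#' @param net a `bipartite_net`.
#' @param catalog compound catalog with `compound_id` and `herbs`
#'   (semicolon-separated) columns; every networked compound must appear.
#' @return named list (one element per herb) of lists with fields
#'   `n_compounds_networked`, `mean_targets_per_compound`, `target_set`,
#'   `unique_targets`.
#' @export
herb_stats <- function(net, catalog) {
  stopifnot(inherits(net, "bipartite_net"))
  miss <- setdiff(net$compounds$compound_id, catalog$compound_id)
  if (length(miss)) {
    stop("networked compound(s) missing from catalog: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  deg <- table(net$edges$compound)
  membership <- strsplit(as.character(catalog$herbs), ";", fixed = TRUE)
  membership <- lapply(membership, trimws)
  herbs <- sort(unique(unlist(membership)))
  herbs <- herbs[nzchar(herbs)]
  per_herb <- lapply(herbs, function(h) {
    comps <- catalog$compound_id[vapply(membership, function(m) h %in% m,
                                        logical(1))]
    comps <- intersect(comps, net$compounds$compound_id)
    targets <- sort(unique(net$edges$target[net$edges$compound %in% comps]))
    list(
      n_compounds_networked = length(comps),
      mean_targets_per_compound = if (length(comps)) {
        round_half_up(sum(deg[comps]) / length(comps), 1)
      } else NA_real_,
      target_set = targets,
      unique_targets = character()  # filled below
    )
  })
  names(per_herb) <- herbs
  all_targets <- unlist(lapply(per_herb, `[[`, "target_set"))
  once <- names(which(table(all_targets) == 1L))
  for (h in herbs) {
    per_herb[[h]]$unique_targets <-
      intersect(per_herb[[h]]$target_set, once)
  }
  per_herb
}

#' Multi-herb membership count from per-herb totals
#'
#' Given per-herb compound counts and the number of unique compounds
#' overall, the excess `sum(counts) - n_unique` counts extra herb
#' memberships; it equals the number of multi-herb compounds exactly when
#' each such compound belongs to two herbs.
#'
#' @param per_herb_counts named integer vector of per-herb compound counts.
#' @param n_unique number of distinct compounds across all herbs.
#' @return list with `extra_memberships` (integer) and `note` explaining
#'   the two-herb interpretation.
#' @export
overlap_count <- function(per_herb_counts, n_unique) {
  counts <- as.integer(per_herb_counts)
  if (any(counts <= 0L)) stop("all per-herb counts must be positive")
  total <- sum(counts)
  if (total < n_unique) {
    stop("sum of per-herb counts (", total, ") is smaller than the number ",
         "of unique compounds (", n_unique, "); inputs are inconsistent")
  }
  list(
    extra_memberships = total - as.integer(n_unique),
    note = paste0("equals the number of multi-herb compounds when each ",
                  "belongs to exactly two herbs")
  )
}

#' Mean number of interacting compounds per target
#'
#' @param n_edges number of compound-target edges.
#' @param n_targets_hit number of targets with at least one edge.
#' @return one-decimal (half-up) mean.
#' @export
edges_per_target <- function(n_edges, n_targets_hit) {
  if (n_targets_hit <= 0) stop("n_targets_hit must be positive")
  round_half_up(n_edges / n_targets_hit, 1)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test per gene set: with universe size `N`,
#' set size `K` (after intersecting with the universe), query size `n`
#' and overlap `k`, the p-value is `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. Raw p-values are flagged at
#' `p <= alpha` (default 0.01); Benjamini-Hochberg adjusted p-values are
#' reported alongside.
#'
#' @param query query proteins ([protein_set] or character); must lie
#'   within the universe.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe background proteins.
#' @param alpha raw-p significance threshold, default 0.01.
#' @return `data.frame` with columns `set`, `k`, `K`, `n`, `N`,
#'   `p_value`, `p_adj`, `significant`, ordered by `p_value` then set
#'   name.
#' @export
hypergeom_enrich <- function(query, gene_sets, universe, alpha = 0.01) {
  q <- .sym(query)
  u <- .sym(universe)
  off <- setdiff(q, u)
  if (length(off)) {
    stop("query symbols outside the universe: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    stop("gene_sets must be a named list")
  }
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(.sym(gene_sets[[nm]]), u)
    k <- length(intersect(q, s))
    K <- length(s)
    n <- length(q)
    N <- length(u)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value <= alpha
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#' @param path GMT file (set name, description, then member symbols,
#'   tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fgsea::gmtPathways(path)
}
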