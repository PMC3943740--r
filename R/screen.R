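# Target-prioritization pipeline: PPI -> EPPI -> CPPI -> centrality
# ranking -> predictive-rate curves -> top-fraction putative targets.

#' Disease PPI induced on seed genes
#'
#' Node set is the full seed list (seeds absent from the interactome are
#' retained as isolated nodes — isolation is itself informative); edges
#' are the interactome edges with both endpoints in the seed set.
#'
#' @param seeds a [protein_set] or character vector of seed-gene symbols.
#' @param interactome background interactome (`igraph`).
#' @return an interactome (`igraph`).
#' @export
assemble_ppi <- function(seeds, interactome) {
  s <- .sym(seeds)
  if (length(s) == 0L) stop("seed set is empty")
  .check_interactome(interactome)
  present <- intersect(s, igraph::V(interactome)$name)
  g <- igraph::induced_subgraph(interactome, present)
  missing <- setdiff(s, present)
  if (length(missing)) g <- g + igraph::vertices(missing)
  g
}

#' Extended PPI: known targets plus first neighbors
#'
#' Node set is the known-target symbols together with their first
#' interactome neighbors; edges are the interactome edges induced on that
#' node set. Known targets absent from the interactome are kept as
#' isolated nodes.
#'
#' @param known a [protein_set] or character vector of known drug targets.
#' @inheritParams assemble_ppi
#' @return an interactome (`igraph`).
#' @export
expand_eppi <- function(known, interactome) {
  k <- .sym(known)
  if (length(k) == 0L) stop("known-target set is empty")
  .check_interactome(interactome)
  present <- intersect(k, igraph::V(interactome)$name)
  nbrs <- character()
  if (length(present)) {
    hood <- igraph::ego(interactome, order = 1, nodes = present)
    nbrs <- unique(unlist(lapply(hood, function(v) v$name)))
  }
  nodes <- union(k, nbrs)
  in_graph <- intersect(nodes, igraph::V(interactome)$name)
  g <- igraph::induced_subgraph(interactome, in_graph)
  missing <- setdiff(nodes, in_graph)
  if (length(missing)) g <- g + igraph::vertices(missing)
  g
}

#' Core PPI on the PPI/EPPI node intersection
#'
#' Node set is exactly `V(ppi) intersect V(eppi)`; edges are re-induced
#' from the full background interactome on that intersection (not from
#' the PPI/EPPI edge union). Intersection nodes missing from the
#' interactome stay as isolated nodes so the node-set identity holds
#' exactly.
#'
#' @param ppi,eppi interactomes from [assemble_ppi()] and [expand_eppi()].
#' @inheritParams assemble_ppi
#' @return an interactome (`igraph`).
#' @export
build_cppi <- function(ppi, eppi, interactome) {
  .check_interactome(ppi); .check_interactome(eppi)
  .check_interactome(interactome)
  inter <- intersect(igraph::V(ppi)$name, igraph::V(eppi)$name)
  if (length(inter) == 0L) {
    stop("PPI and EPPI node sets are disjoint (|PPI| = ",
         igraph::vcount(ppi), ", |EPPI| = ", igraph::vcount(eppi),
         "); no core network can be formed")
  }
  in_graph <- intersect(inter, igraph::V(interactome)$name)
  g <- igraph::induced_subgraph(interactome, in_graph)
  missing <- setdiff(inter, in_graph)
  if (length(missing)) g <- g + igraph::vertices(missing)
  g
}

# shared ranking rule: measure descending, ties broken by symbol ascending
.rank_nodes <- function(table, measure) {
  measure <- match.arg(measure, CENTRALITY_MEASURES)
  if (nrow(table) == 0L) stop("centrality table is empty")
  table$node[order(-table[[measure]], table$node)]
}

#' Predictive-rate curve of a centrality ranking
#'
#' Nodes are sorted by the chosen measure (descending, symbol-ascending
#' tie-break); point `k` is the number of known targets among the top
#' `k`. The curve measures how strongly a topological measure enriches
#' known drug targets near the top of its ranking.
#'
#' @param table centrality table from [centrality_table()].
#' @param known known drug targets ([protein_set] or character).
#' @param measure one of `"degree"`, `"clustering"`, `"betweenness"`,
#'   `"bridging"`, `"closeness"`.
#' @return a `data.frame` with columns `measure`, `rank`, `node`, `hits`.
#' @export
predictive_rate <- function(table, known, measure = "betweenness") {
  measure <- match.arg(measure, CENTRALITY_MEASURES)
  ranked <- .rank_nodes(table, measure)
  hits <- cumsum(ranked %in% .sym(known))
  data.frame(measure = measure, rank = seq_along(ranked), node = ranked,
             hits = hits, stringsAsFactors = FALSE)
}

#' Select putative targets from the top fraction of a ranking
#'
#' Takes the top `ceiling(top_fraction * N)` nodes of the ranking and
#' removes known targets; what remains are the putative targets.
#'
#' @inheritParams predictive_rate
#' @param top_fraction fraction of nodes to keep, in `(0, 1]`.
#' @return a [protein_set] labelled `"putative_target"` (possibly empty).
#' @export
select_putative <- function(table, known, top_fraction = 0.30,
                            measure = "betweenness") {
  stopifnot(is.numeric(top_fraction), length(top_fraction) == 1L,
            top_fraction > 0, top_fraction <= 1)
  ranked <- .rank_nodes(table, measure)
  k <- ceiling(top_fraction * length(ranked))
  putative <- setdiff(ranked[seq_len(k)], .sym(known))
  protein_set(putative, label = "putative_target", allow_empty = TRUE)
}

#' Run the full target-prioritization screen
#'
#' Executes, in order: seed-gene PPI, known-target network, extended PPI
#' (known targets + first neighbors), core PPI on the PPI/EPPI node
#' intersection, the five-measure centrality table on the core network,
#' one predictive-rate curve per measure, and the top-fraction putative
#' target selection. All intermediates are retained in the result.
#'
#' @param seeds seed genes ([protein_set] or character).
#' @param known known drug targets ([protein_set] or character).
#' @param interactome background interactome (`igraph`).
#' @param top_fraction fraction of core-network nodes selected, default 0.30.
#' @param measure ranking measure for the putative selection, default
#'   `"betweenness"` (the measure with the best predictive rate for known
#'   targets in this workflow); all five remain available.
#' @return an object of class `screen_result`: list with elements `ppi`,
#'   `known_net`, `eppi`, `cppi`, `centralities`, `curves` (one
#'   `data.frame`, all five measures stacked), `putative`,
#'   `component_summary` (per network), `top_fraction`, `measure`.
#' @export
run_screen <- function(seeds, known, interactome, top_fraction = 0.30,
                       measure = "betweenness") {
  measure <- match.arg(measure, CENTRALITY_MEASURES)
  ppi <- assemble_ppi(seeds, interactome)
  known_net <- assemble_ppi(known, interactome)
  eppi <- expand_eppi(known, interactome)
  cppi <- build_cppi(ppi, eppi, interactome)
  tab <- centrality_table(cppi)
  curves <- do.call(rbind, lapply(CENTRALITY_MEASURES, function(m) {
    predictive_rate(tab, known, m)
  }))
  putative <- select_putative(tab, known, top_fraction, measure)
  nets <- list(ppi = ppi, known_net = known_net, eppi = eppi, cppi = cppi)
  res <- list(
    ppi = ppi, known_net = known_net, eppi = eppi, cppi = cppi,
    centralities = tab, curves = curves, putative = putative,
    component_summary = lapply(nets, component_summary),
    top_fraction = top_fraction, measure = measure
  )
  class(res) <- "screen_result"
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cnt <- function(g) paste0(igraph::vcount(g), " nodes / ",
                            igraph::ecount(g), " edges")
  cat("<screen_result>\n",
      "  PPI:   ", cnt(x$ppi), "\n",
      "  known: ", cnt(x$known_net), "\n",
      "  EPPI:  ", cnt(x$eppi), "\n",
      "  CPPI:  ", cnt(x$cppi), "\n",
      "  putative targets (top ", 100 * x$top_fraction, "% by ",
      x$measure, "): ", length(x$putative$symbols), "\n", sep = "")
  invisible(x)
}

#' Serialize a screen result to a directory
#'
#' Writes, with deterministic ordering: each network as SIF and GraphML
#' (the core network's GraphML carries the five centralities and a `role`
#' vertex attribute), the centrality table and predictive-rate curves as
#' CSV, the putative-target list as plain text, and a JSON summary of
#' node/edge/component counts.
#'
#' @param res a `screen_result`.
#' @param dir output directory (created if needed).
#' @param known optional known-target set used to annotate roles in the
#'   core-network export.
#' @return `dir`, invisibly.
#' @export
write_screen_result <- function(res, dir, known = NULL) {
  stopifnot(inherits(res, "screen_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nets <- list(ppi = res$ppi, known_net = res$known_net,
               eppi = res$eppi, cppi = res$cppi)
  cppi <- res$cppi
  tab <- res$centralities
  idx <- match(igraph::V(cppi)$name, tab$node)
  for (m in CENTRALITY_MEASURES) {
    cppi <- igraph::set_vertex_attr(cppi, m, value = tab[[m]][idx])
  }
  role <- rep("candidate", igraph::vcount(cppi))
  if (!is.null(known)) role[igraph::V(cppi)$name %in% .sym(known)] <- "known_target"
  role[igraph::V(cppi)$name %in% res$putative$symbols] <- "putative_target"
  cppi <- igraph::set_vertex_attr(cppi, "role", value = role)
  nets$cppi <- cppi
  for (nm in names(nets)) {
    write_interactome(nets[[nm]], file.path(dir, paste0(nm, ".sif")), "sif")
    write_interactome(nets[[nm]], file.path(dir, paste0(nm, ".graphml")),
                      "graphml")
  }
  utils::write.csv(res$centralities, file.path(dir, "centralities.csv"),
                   row.names = FALSE)
  utils::write.csv(res$curves, file.path(dir, "predictive_rate.csv"),
                   row.names = FALSE)
  write_symbol_list(res$putative, file.path(dir, "putative_targets.txt"))
  jsonlite::write_json(
    lapply(res$component_summary, unclass),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}
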