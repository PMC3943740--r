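# Five topological measures used to rank candidate drug targets.
#
# Conventions (all ranking-relevant choices are deterministic and total):
#   * betweenness is the unnormalized sum over unordered vertex pairs,
#     endpoints excluded; pairs in different components contribute 0
#   * clustering is 0 (not NaN) for degree < 2
#   * closeness is computed within each connected component,
#     (n_c - 1) / sum of distances; isolated nodes score 0
#   * bridging = betweenness * bridging coefficient, where
#     BC(v) = (1/deg(v)) / sum_{u in N(v)} 1/deg(u); degree-0 nodes get 0

#' Node degrees
#' @param g interactome (`igraph`).
#' @return named numeric vector, one entry per node.
#' @export
degree_all <- function(g) {
  .check_interactome(g)
  igraph::degree(g)
}

#' Local clustering coefficients
#'
#' For a node with `k >= 2` neighbors joined by `n_i` edges:
#' `2 n_i / (k (k - 1))`. Nodes of degree 0 or 1 score 0 so that rankings
#' are total.
#'
#' @inheritParams degree_all
#' @return named numeric vector in `[0, 1]`.
#' @export
clustering_all <- function(g) {
  .check_interactome(g)
  if (igraph::vcount(g) == 0L) return(stats::setNames(numeric(), character()))
  cc <- igraph::transitivity(g, type = "localundirected",
                             vids = igraph::V(g), isolates = "zero")
  stats::setNames(cc, igraph::V(g)$name)
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness: for every unordered pair
#' `{s, t}` with `s != v != t`, the fraction of shortest `s`-`t` paths
#' passing through `v` is accumulated.
#'
#' @inheritParams degree_all
#' @return named nonnegative numeric vector.
#' @export
betweenness_all <- function(g) {
  .check_interactome(g)
  igraph::betweenness(g, directed = FALSE, weights = NA)
}

#' Bridging centrality
#'
#' Betweenness multiplied by the bridging coefficient
#' `BC(v) = (1/deg(v)) / sum_{u in N(v)} 1/deg(u)`. High values mark nodes
#' that sit on information bottlenecks between densely connected regions.
#' Degree-0 nodes score 0.
#'
#' @inheritParams degree_all
#' @return named nonnegative numeric vector.
#' @export
bridging_all <- function(g) {
  .check_interactome(g)
  n <- igraph::vcount(g)
  if (n == 0L) return(stats::setNames(numeric(), character()))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  bc <- numeric(n)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  for (i in seq_len(n)) {
    if (deg[i] == 0) next
    denom <- sum(1 / deg[as.integer(adj[[i]])])
    bc[i] <- (1 / deg[i]) / denom
  }
  stats::setNames(btw * bc, igraph::V(g)$name)
}

#' Closeness centrality (per component)
#'
#' For a node `v` in a connected component of size `n_c >= 2`:
#' `(n_c - 1) / sum_j d(v, j)` over the component members. Isolated nodes
#' score 0. Computing within components keeps the measure finite on the
#' disconnected networks this pipeline routinely produces.
#'
#' @inheritParams degree_all
#' @return named numeric vector in `[0, 1]`.
#' @export
closeness_all <- function(g) {
  .check_interactome(g)
  n <- igraph::vcount(g)
  out <- stats::setNames(numeric(n), igraph::V(g)$name)
  if (n == 0L) return(out)
  comp <- igraph::components(g)
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    if (length(members) < 2L) next
    d <- igraph::distances(g, v = members, to = members)
    out[members] <- (length(members) - 1) / rowSums(d)
  }
  out
}

#' Full five-measure centrality table
#'
#' @inheritParams degree_all
#' @return a `data.frame` with columns `node`, `degree`, `clustering`,
#'   `betweenness`, `bridging`, `closeness`, one row per node, ordered by
#'   node symbol.
#' @export
centrality_table <- function(g) {
  .check_interactome(g)
  if (igraph::vcount(g) == 0L) {
    return(data.frame(node = character(), degree = numeric(),
                      clustering = numeric(), betweenness = numeric(),
                      bridging = numeric(), closeness = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- data.frame(
    node = igraph::V(g)$name,
    degree = as.numeric(degree_all(g)),
    clustering = as.numeric(clustering_all(g)),
    betweenness = as.numeric(betweenness_all(g)),
    bridging = as.numeric(bridging_all(g)),
    closeness = as.numeric(closeness_all(g)),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# the measures a ranking may use, in reporting order
CENTRALITY_MEASURES <- c("degree", "clustering", "betweenness",
                         "bridging", "closeness")
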