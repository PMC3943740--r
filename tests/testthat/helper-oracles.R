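# Independent brute-force oracles for the five topological measures and
# the hypergeometric tail. These deliberately avoid the package's (and
# igraph's) algorithms: plain BFS over an adjacency list plus direct
# formula evaluation.

oracle_adj <- function(g) {
  n <- igraph::vcount(g)
  adj <- rep(list(integer()), n)
  el <- igraph::as_edgelist(g, names = FALSE)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# BFS from s: geodesic distances and shortest-path counts to every node
oracle_bfs <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n)
  sigma <- rep(0, n)
  dist[s] <- 0
  sigma[s] <- 1
  queue <- s
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
      if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
    }
  }
  list(dist = dist, sigma = sigma)
}

oracle_degree <- function(g) {
  stats::setNames(lengths(oracle_adj(g)), igraph::V(g)$name)
}

oracle_clustering <- function(g) {
  adj <- oracle_adj(g)
  n <- length(adj)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (nb[j] %in% adj[[nb[i]]]) links <- links + 1
    }
    out[v] <- 2 * links / (k * (k - 1))
  }
  stats::setNames(out, igraph::V(g)$name)
}

# sum over unordered pairs {s,t} of sigma_st(v)/sigma_st, with
# sigma_st(v) = sigma_sv * sigma_vt whenever v lies on a geodesic
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- oracle_adj(g)
  bfs <- lapply(seq_len(n), function(s) oracle_bfs(adj, s))
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || is.infinite(bfs[[s]]$dist[t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (bfs[[s]]$dist[v] + bfs[[v]]$dist[t] == bfs[[s]]$dist[t]) {
        btw[v] <- btw[v] +
          bfs[[s]]$sigma[v] * bfs[[v]]$sigma[t] / bfs[[s]]$sigma[t]
      }
    }
  }
  stats::setNames(btw, igraph::V(g)$name)
}

oracle_bridging <- function(g) {
  deg <- oracle_degree(g)
  btw <- oracle_betweenness(g)
  adj <- oracle_adj(g)
  n <- length(adj)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] == 0) next
    bc[v] <- (1 / deg[v]) / sum(1 / deg[adj[[v]]])
  }
  stats::setNames(btw * bc, igraph::V(g)$name)
}

oracle_closeness <- function(g) {
  n <- igraph::vcount(g)
  adj <- oracle_adj(g)
  out <- numeric(n)
  for (v in seq_len(n)) {
    d <- oracle_bfs(adj, v)$dist
    reach <- which(is.finite(d) & seq_len(n) != v)
    if (length(reach)) out[v] <- length(reach) / sum(d[reach])
  }
  stats::setNames(out, igraph::V(g)$name)
}

# exhaustive-enumeration hypergeometric upper tail: probability that a
# uniform size-n draw from N items contains >= k of the K marked ones
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% marked)) >= k)
}

# small random test graph with named vertices
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p, directed = FALSE)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

# independent half-up rounding for checking reported one-decimal values
round_half_up_test <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
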