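# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph): brute-force BFS path enumeration,
# direct rank-formula correlation, and naive triangle counting.

# Spearman's rho via the classical rank-difference formula (no ties assumed)
rank_formula_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# all shortest-path counts s -> t in a directed adjacency matrix by BFS
# level expansion; returns list(dist, npaths) matrices
bfs_shortest_counts <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  npaths <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    npaths[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] == 1)) {
          if (is.infinite(dist[s, v])) {
            dist[s, v] <- d
            nxt <- c(nxt, v)
          }
          if (dist[s, v] == d) {
            npaths[s, v] <- npaths[s, v] + npaths[s, u]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  list(dist = dist, npaths = npaths)
}

# unnormalized directed betweenness by explicit enumeration over ordered
# pairs (s, t), s != t != v, counting shortest paths through v via the
# dist(s,v) + dist(v,t) == dist(s,t) decomposition
brute_betweenness <- function(adj) {
  diag(adj) <- 0
  n <- nrow(adj)
  sp <- bfs_shortest_counts(adj)
  bet <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s == t || s == v || t == v) next
        if (is.infinite(sp$dist[s, t]) || sp$npaths[s, t] == 0) next
        if (sp$dist[s, v] + sp$dist[v, t] == sp$dist[s, t]) {
          bet[v] <- bet[v] + sp$npaths[s, v] * sp$npaths[v, t] / sp$npaths[s, t]
        }
      }
    }
  }
  bet
}

# density and mean local clustering coefficient on the undirected
# projection, nodes with degree < 2 contributing 0, by triangle counting
brute_density_clustering <- function(adj) {
  diag(adj) <- 0
  n <- nrow(adj)
  und <- (adj + t(adj)) > 0
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(und[v, ])
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (und[nb[i], nb[j]]) tri <- tri + 1
      }
    }
    cc[v] <- tri / (k * (k - 1) / 2)
  }
  list(density = sum(adj) / (n * (n - 1)), mean_clustering = mean(cc))
}

random_digraph_adj <- function(n, p = 0.3) {
  adj <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(adj) <- 0
  adj
}

# adjacency matrix -> igraph object with named nodes
graph_from_adj <- function(adj) {
  rownames(adj) <- colnames(adj) <- paste0("n", seq_len(nrow(adj)))
  igraph::graph_from_adjacency_matrix(adj, mode = "directed")
}

# small four-condition curve set for classifier tests
toy_curves <- function(K = 14) {
  t <- seq(0, 24, length.out = K)
  list(
    CTRL = rep(0.1, K) + 0.01 * seq_len(K),
    SHH = 2 * sin(t / 4),
    EGF = 2 * cos(t / 4),
    EGF_SHH = 2 * sin(t / 2.2 + 1)
  )
}
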