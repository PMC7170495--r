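# Network statistics over the module regulatory network.
#
# All metrics are topological (unweighted) and ignore self-loops: in-degree
# counts the modules regulating a module, out-degree the modules it
# regulates, and betweenness sums, over ordered node pairs (s, t) with at
# least one shortest path and s, t both different from v, the fraction of
# shortest s->t paths passing through v (endpoints never count as passed
# through; unnormalized).

.drop_self_loops <- function(graph) {
  igraph::simplify(graph, remove.multiple = FALSE, remove.loops = TRUE)
}

#' Betweenness centrality of every node
#'
#' @param graph a directed [igraph::graph]; self-loops are ignored.
#' @return named numeric vector of unnormalized betweenness values.
#' @export
network_betweenness <- function(graph) {
  g <- .drop_self_loops(graph)
  igraph::betweenness(g, directed = TRUE, normalized = FALSE, weights = NA)
}

#' In- and out-degree of every node
#'
#' @param graph a directed [igraph::graph]; self-loops are ignored.
#' @return `data.frame` with `node`, `in_degree`, `out_degree`.
#' @export
degree_stats <- function(graph) {
  g <- .drop_self_loops(graph)
  data.frame(
    node = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))),
    in_degree = unname(igraph::degree(g, mode = "in")),
    out_degree = unname(igraph::degree(g, mode = "out")),
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Graph density and mean clustering coefficient
#'
#' Density is the fraction of possible directed non-self edges present,
#' `m / (n (n - 1))`. The clustering coefficient is computed per node on
#' the undirected projection (triangles through the node over possible
#' pairs of its neighbours) and averaged over all nodes, with nodes of
#' degree below 2 contributing 0.
#'
#' @param graph a directed [igraph::graph].
#' @return list with `density` and `mean_clustering`.
#' @export
density_and_clustering <- function(graph) {
  g <- .drop_self_loops(graph)
  n <- igraph::vcount(g)
  if (n < 2L) stop("density is undefined for graphs with fewer than 2 nodes")
  density <- igraph::ecount(g) / (n * (n - 1))
  und <- igraph::as_undirected(g, mode = "collapse")
  cc <- igraph::transitivity(und, type = "local")
  cc[!is.finite(cc)] <- 0
  list(density = density, mean_clustering = mean(cc))
}

#' Per-node and graph-level network statistics
#'
#' @param graph a directed [igraph::graph].
#' @return list with `nodes` (a `data.frame`: `node`, `in_degree`,
#'   `out_degree`, `betweenness`) and graph-level `density`,
#'   `mean_clustering`.
#' @export
network_stats <- function(graph) {
  deg <- degree_stats(graph)
  deg$betweenness <- unname(network_betweenness(graph))
  dc <- density_and_clustering(graph)
  list(nodes = deg, density = dc$density, mean_clustering = dc$mean_clustering)
}

#' Identify important modules of the regulatory network
#'
#' A module is important when it ranks highly on at least one of
#' in-degree (I), out-degree (O) or betweenness (B): either among the top
#' `k` per criterion (`mode = "top_k"`) or at or above the 95th percentile
#' of the criterion (`mode = "percentile"`). Ties at the cutoff are all
#' included.
#'
#' @param stats result of [network_stats()] (or its `nodes` data frame).
#' @param mode `"top_k"` or `"percentile"`.
#' @param k modules per criterion for `mode = "top_k"` (default 20).
#' @param probs percentile for `mode = "percentile"` (default 0.95).
#' @return `data.frame` with `node`, logical `I`, `O`, `B`, and an
#'   `importance` label such as `"I, B"`; only flagged modules are listed.
#' @export
important_grms <- function(stats, mode = c("top_k", "percentile"), k = 20L,
                           probs = 0.95) {
  mode <- match.arg(mode)
  nodes <- if (is.data.frame(stats)) stats else stats$nodes
  flag <- function(x) {
    if (mode == "top_k") {
      if (length(x) <= k) return(rep(TRUE, length(x)))
      cutoff <- sort(x, decreasing = TRUE)[k]
      x >= cutoff
    } else {
      x >= stats::quantile(x, probs, type = 7)
    }
  }
  I <- flag(nodes$in_degree)
  O <- flag(nodes$out_degree)
  B <- flag(nodes$betweenness)
  sel <- I | O | B
  lab <- vapply(which(sel), function(i) {
    paste(c("I", "O", "B")[c(I[i], O[i], B[i])], collapse = ", ")
  }, "")
  data.frame(node = nodes$node[sel], I = I[sel], O = O[sel], B = B[sel],
             importance = lab, row.names = NULL)
}
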