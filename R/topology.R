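#' Shortest-path distance matrix of the wiring digraph
#'
#' Distances follow the convention used throughout the centrality
#' definitions: `d(i, j)` is the length (number of edges) of the shortest
#' directed path from `i` to `j`, and `d(i, j) = 0` when no path exists.
#' Self-loops are excluded from paths; the diagonal is set to 0 and is not
#' used by any downstream measure.
#'
#' @param net a `boolean_network`.
#' @return numeric matrix with `d[i, j]` the distance from node `i` to `j`.
#' @export
shortest_path_matrix <- function(net) {
  g <- wiring_graph(net, include_self = FALSE)
  D <- igraph::distances(g, mode = "out")
  D[!is.finite(D)] <- 0
  diag(D) <- 0
  D[net$nodes, net$nodes, drop = FALSE]
}

#' In- and out-closeness centralities
#'
#' `C_in(i) = (A_in(i) / (n-1))^2 / F_in(i)` where `A_in(i)` counts the
#' nodes from which `i` is reachable and `F_in(i)` is the farness, the sum of
#' their shortest-path distances to `i`; `C_in(i) = 0` when nothing reaches
#' `i`. `C_out` is symmetric, over nodes reachable *from* `i`. Note the
#' unreachable-pair convention `d = 0`: unreachable nodes simply drop out of
#' the farness sum, which inflates closeness for poorly connected nodes
#' relative to conventions that penalize unreachability.
#'
#' @param net a `boolean_network` with at least 2 nodes.
#' @return data.frame with columns `node`, `A_in`, `F_in`, `C_in`, `A_out`,
#'   `F_out`, `C_out`.
#' @export
closeness_centralities <- function(net) {
  n <- length(net$nodes)
  if (n < 2) stop("closeness requires at least 2 nodes")
  D <- shortest_path_matrix(net)
  A_in <- colSums(D > 0)
  F_in <- colSums(D)
  A_out <- rowSums(D > 0)
  F_out <- rowSums(D)
  cin <- ifelse(A_in > 0, (A_in / (n - 1))^2 / ifelse(F_in > 0, F_in, 1), 0)
  cout <- ifelse(A_out > 0, (A_out / (n - 1))^2 / ifelse(F_out > 0, F_out, 1), 0)
  data.frame(node = net$nodes, A_in = as.integer(A_in), F_in = as.numeric(F_in),
             C_in = cin, A_out = as.integer(A_out), F_out = as.numeric(F_out),
             C_out = cout, row.names = NULL)
}

#' Betweenness centrality
#'
#' `BC(i)` sums, over every ordered pair of distinct nodes `(j, k)` with
#' `j, k != i` joined by at least one directed path, the fraction of shortest
#' `j -> k` paths on which `i` is an interior node. Computed by
#' breadth-first shortest-path counting with dependency accumulation
#' (Brandes' algorithm); self-loops are ignored.
#'
#' @param net a `boolean_network`.
#' @return named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (nm in names(net$rules)) {
    to <- match(nm, nodes)
    for (inp in net$rules[[nm]]$inputs) {
      from <- match(inp, nodes)
      if (from != to) adj[[from]] <- c(adj[[from]], to)
    }
  }
  adj <- lapply(adj, unique)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    pred <- lapply(seq_len(n), function(i) integer(0))
    queue <- integer(n); qh <- 1L; qt <- 1L; queue[1] <- s
    order_visited <- integer(0)
    while (qh <= qt) {
      v <- queue[qh]; qh <- qh + 1L
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          qt <- qt + 1L; queue[qt] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          pred[[w]] <- c(pred[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in pred[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc, nodes)
}

#' In/out-degree counts and edge total
#'
#' `k_j` is the number of inputs of node `j`'s rule (0 for external nodes),
#' `o_j` the number of nodes listing `j` as an input. Self-inputs count
#' toward both. The edge total `E` is the sum of either.
#'
#' @param net a `boolean_network`.
#' @return list with named integer vectors `in_degree`, `out_degree`, and
#'   scalar `E`.
#' @examples
#' degree_counts(example1_network())$E # 8
#' @export
degree_counts <- function(net) {
  k <- stats::setNames(integer(length(net$nodes)), net$nodes)
  o <- k
  for (nm in names(net$rules)) {
    inputs <- net$rules[[nm]]$inputs
    k[[nm]] <- length(inputs)
    for (j in inputs) o[[j]] <- o[[j]] + 1L
  }
  list(in_degree = k, out_degree = o, E = sum(k))
}

#' Full per-node centrality table
#'
#' Joins degrees, closeness, betweenness — and determinative power when a
#' `dp_table` is supplied — into one data.frame suitable for CSV export.
#'
#' @param net a `boolean_network`.
#' @param dp optional `dp_table` from [determinative_power()].
#' @return data.frame with one row per node: `node, k, o, A_in, F_in, C_in,
#'   A_out, F_out, C_out, BC` (+ `dp`).
#' @export
centrality_table <- function(net, dp = NULL) {
  deg <- degree_counts(net)
  cl <- closeness_centralities(net)
  out <- data.frame(node = net$nodes,
                    k = as.integer(deg$in_degree[net$nodes]),
                    o = as.integer(deg$out_degree[net$nodes]))
  out <- merge(out, cl, by = "node", sort = FALSE)
  out$BC <- as.numeric(betweenness_centrality(net)[out$node])
  if (!is.null(dp)) {
    stopifnot(inherits(dp, "dp_table"))
    out$dp <- dp$dp$dp[match(out$node, dp$dp$node)]
  }
  out[match(net$nodes, out$node), , drop = FALSE]
}
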