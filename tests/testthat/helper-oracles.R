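# Independent brute-force oracles. These deliberately share no code with the
# implementation paths they check: paths are enumerated by depth-first
# search, entropies by explicit joint-state enumeration, tail probabilities
# by direct summation.

# Enumerate every simple directed path between all ordered node pairs of an
# adjacency matrix (self-loops ignored). Returns shortest-path distances D
# (0 = unreachable), shortest-path counts N, and Int[j, k, i] = number of
# shortest j->k paths with i interior.
oracle_path_census <- function(adj) {
  n <- nrow(adj)
  diag(adj) <- 0
  D <- matrix(0, n, n)
  N <- matrix(0, n, n)
  Int <- array(0, c(n, n, n))
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    paths <- list()
    dfs <- function(path) {
      v <- path[length(path)]
      if (v == k) {
        paths[[length(paths) + 1L]] <<- path
        return(invisible())
      }
      for (w in which(adj[v, ] == 1)) if (!(w %in% path)) dfs(c(path, w))
    }
    dfs(j)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1)) - 1L
    dmin <- min(lens)
    sp <- paths[lens == dmin]
    D[j, k] <- dmin
    N[j, k] <- length(sp)
    for (p in sp) for (i in setdiff(p, c(j, k))) Int[j, k, i] <- Int[j, k, i] + 1
  }
  list(D = D, N = N, Int = Int)
}

oracle_closeness <- function(adj) {
  cen <- oracle_path_census(adj)
  n <- nrow(adj)
  A_in <- colSums(cen$D > 0); F_in <- colSums(cen$D)
  A_out <- rowSums(cen$D > 0); F_out <- rowSums(cen$D)
  list(C_in = ifelse(A_in > 0, (A_in / (n - 1))^2 / F_in, 0),
       C_out = ifelse(A_out > 0, (A_out / (n - 1))^2 / F_out, 0),
       A_in = A_in, F_in = F_in, A_out = A_out, F_out = F_out,
       census = cen)
}

oracle_betweenness <- function(adj) {
  cen <- oracle_path_census(adj)
  n <- nrow(adj)
  bc <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == k || j == i || k == i || cen$N[j, k] == 0) next
      bc[i] <- bc[i] + cen$Int[j, k, i] / cen$N[j, k]
    }
  }
  bc
}

# Per-node conditional entropy H(f_i(X) | X_S) by full 2^n enumeration of the
# joint law of (f_i(X), X_S) -- the independent route to the terms summed by
# entropy_bound_curve().
oracle_node_conditional_entropy <- function(net, i, S, dist = NULL) {
  dist <- if (is.null(dist)) input_distribution(net) else dist
  n <- length(net$nodes)
  states <- rule_assignments(n)
  colnames(states) <- net$nodes
  p <- rep(1, 2^n)
  for (m in seq_len(n))
    p <- p * ifelse(states[, m] == 1L, dist[[net$nodes[m]]],
                    1 - dist[[net$nodes[m]]])
  y <- apply(states, 1, function(x) evaluate_rule(net$rules[[i]], x))
  skey <- if (length(S) > 0)
    apply(states[, S, drop = FALSE], 1, paste, collapse = "") else
    rep("", 2^n)
  hp <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hp(tapply(p, paste(y, skey), sum)) - hp(tapply(p, skey, sum))
}

# Literal re-evaluation of the cutoff conditions at every rank.
oracle_cutoff_scan <- function(A, d, t_factor) {
  n <- length(A)
  B <- abs(A[-1] - A[-n])
  m <- length(B)
  means <- sapply(seq_len(m - d + 1), function(u) mean(B[u:(u + d - 1)]))
  MA <- c(rep(means[1], floor((d - 1) / 2)), means,
          rep(means[length(means)], ceiling((d - 1) / 2)))
  Tval <- t_factor * max(MA)
  for (l in seq_len(n - 1)) {
    cond1 <- MA[l] <= Tval
    cond2 <- sum(MA[l:min(l + d - 1, n - 1)]) / d <= Tval
    if (cond1 && cond2) return(l)
  }
  n
}

# Hypergeometric upper tail P(X >= x) by direct summation.
oracle_hyper_tail <- function(x, K, N, k) {
  sum(sapply(x:min(k, K), function(t)
    choose(K, t) * choose(N - K, k - t) / choose(N, k)))
}
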