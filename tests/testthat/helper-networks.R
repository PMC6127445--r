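# Small construction helpers shared across test files.

# Boolean network whose wiring digraph equals the 0/1 adjacency matrix
# adj[j, i] = 1  <=>  edge j -> i. Rule content is an OR of the inputs
# (irrelevant for topology). Nodes with no inputs become external.
digraph_network <- function(adj) {
  n <- nrow(adj)
  nodes <- sprintf("g%d", seq_len(n))
  rules <- list()
  for (i in seq_len(n)) {
    preds <- which(adj[, i] == 1)
    if (length(preds) > 0) {
      k <- length(preds)
      tab <- as.integer(rowSums(rule_assignments(k)) > 0)
      rules[[nodes[i]]] <- list(inputs = nodes[preds], table = tab)
    }
  }
  boolean_network(rules = rules, external = setdiff(nodes, names(rules)),
                  nodes = nodes)
}

random_adjacency <- function(n, p, seed, self_loops = FALSE) {
  set.seed(seed)
  adj <- matrix(rbinom(n * n, 1, p), n, n)
  if (!self_loops) diag(adj) <- 0
  adj
}

chain_network <- function(n = 3) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- 1L
  digraph_network(adj)
}

# 1 -> 2 -> 4 and 1 -> 3 -> 4
diamond_network <- function() {
  adj <- matrix(0L, 4, 4)
  adj[1, 2] <- adj[1, 3] <- adj[2, 4] <- adj[3, 4] <- 1L
  digraph_network(adj)
}

# 2-input XOR target with external inputs
xor_network <- function() {
  boolean_network(rules = list(t = list(inputs = c("a", "b"),
                                        table = c(0L, 1L, 1L, 0L))))
}

# Permute the stored input order of a rule, rewiring the truth table
# consistently, so the represented Boolean function is unchanged.
permute_rule <- function(rule, perm) {
  k <- length(rule$inputs)
  stopifnot(length(perm) == k)
  new_inputs <- rule$inputs[perm]
  asn_new <- rule_assignments(k)
  new_table <- integer(2^k)
  for (r in seq_len(2^k)) {
    bits_new <- asn_new[r, ]                    # assignment of new_inputs
    bits_old <- integer(k)
    bits_old[perm] <- bits_new                  # same values, old order
    r_old <- sum(bits_old * 2^((k - 1):0)) + 1L
    new_table[r] <- rule$table[r_old]
  }
  list(inputs = new_inputs, table = new_table)
}
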