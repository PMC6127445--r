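#' The four-node worked-example network
#'
#' `x1 <- x2 AND x3 AND NOT x4`, `x2 <- x1 AND (x2 OR x3)`,
#' `x3 <- x1 OR x2`; `x4` has no rule and is an external input with the
#' single output `x1`. Under the uniform distribution the determinative
#' powers rank the nodes `x1 > x2 > x3 > x4`.
#'
#' @return a `boolean_network` with nodes `x1..x4`.
#' @examples
#' determinative_power(example1_network())
#' @export
example1_network <- function() {
  parse_expression_file(text = c(
    "x1, x2 & x3 & !x4",
    "x2, x1 & (x2 | x3)",
    "x3, x1 | x2"
  ))
}

#' Generate a seeded random Boolean network
#'
#' Draws, for each regulated node, an in-degree (fixed or uniform over a
#' range), a set of distinct inputs, and i.i.d. Bernoulli truth-table bits
#' with the given bias. A fraction of nodes carries no rule (external
#' inputs). Self-inputs are excluded by default and forced with probability
#' `self_prob` to exercise that code path deliberately. The generator is
#' fully reproducible: the same seed yields the same network, and the
#' caller's RNG state is left untouched.
#'
#' @param n number of nodes.
#' @param k in-degree: a single value or a `c(min, max)` range.
#' @param bias probability that a truth-table entry is 1.
#' @param external_fraction fraction of nodes left without a rule.
#' @param self_prob probability that a regulated node includes itself among
#'   its inputs.
#' @param seed integer RNG seed (required for reproducibility).
#' @return a validated `boolean_network` with nodes `v1..vn`.
#' @examples
#' net <- generate_random_network(8, k = 3, seed = 1)
#' length(regulated_nodes(net))
#' @export
generate_random_network <- function(n, k = 2, bias = 0.5,
                                    external_fraction = 0, self_prob = 0,
                                    seed = NULL) {
  stopifnot(n >= 1, bias >= 0, bias <= 1,
            external_fraction >= 0, external_fraction < 1,
            self_prob >= 0, self_prob <= 1)
  if (length(k) == 1) k <- c(k, k)
  if (k[1] < 0 || k[2] >= n + 1) stop("infeasible in-degree range")
  build <- function() {
    nodes <- sprintf("v%d", seq_len(n))
    n_ext <- floor(external_fraction * n)
    external <- if (n_ext > 0) sample(nodes, n_ext) else character()
    regulated <- setdiff(nodes, external)
    if (length(regulated) == 0) stop("all nodes external; nothing to regulate")
    rules <- lapply(regulated, function(nm) {
      ki <- if (k[1] == k[2]) k[1] else sample(k[1]:k[2], 1)
      others <- setdiff(nodes, nm)
      ki <- min(ki, length(others) + 1L)
      inputs <- if (ki >= 1 && stats::runif(1) < self_prob)
        c(nm, if (ki > 1) sample(others, ki - 1L) else character())
      else
        sample(others, min(ki, length(others)))
      list(inputs = inputs,
           table = stats::rbinom(2^length(inputs), 1, bias))
    })
    names(rules) <- regulated
    boolean_network(rules = rules, external = external, nodes = nodes)
  }
  if (is.null(seed)) return(build())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  build()
}

# Enumerate all 2^n network states with their probabilities under an
# independent distribution. Returns list(states = 2^n x n matrix, p = vector).
enumerate_states <- function(net, dist) {
  n <- length(net$nodes)
  if (n > 20) stop("state enumeration limited to 20 nodes")
  states <- rule_assignments(n)
  colnames(states) <- net$nodes
  p <- rep(1, 2^n)
  for (m in seq_len(n)) {
    pm <- dist[[net$nodes[m]]]
    p <- p * ifelse(states[, m] == 1L, pm, 1 - pm)
  }
  list(states = states, p = p)
}

entropy_from_probs <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Brute-force mutual information by joint-state enumeration
#'
#' Independent oracle for [mutual_information()]: enumerates all `2^n`
#' network states, builds the explicit 2 x 2 joint distribution of
#' `(f_i(X), X_j)`, and computes `MI = H(Y) + H(X_j) - H(Y, X_j)` directly.
#' Exponential in `n`; intended for verification on small networks.
#'
#' @param net a `boolean_network` with at most 20 nodes.
#' @param i target node name (regulated).
#' @param j conditioning node name.
#' @param dist optional [input_distribution()]; default uniform 1/2.
#' @return mutual information in bits.
#' @export
oracle_mutual_information <- function(net, i, j, dist = NULL) {
  dist <- resolve_dist(net, dist)
  rule <- net$rules[[i]]
  if (is.null(rule)) stop("node '", i, "' is external and has no update rule")
  if (!j %in% net$nodes) stop("unknown node '", j, "'")
  es <- enumerate_states(net, dist)
  y <- apply(es$states, 1, function(x) evaluate_rule(rule, x))
  xj <- es$states[, j]
  joint <- tapply(es$p, list(factor(y, 0:1), factor(xj, 0:1)), sum,
                  default = 0)
  entropy_from_probs(rowSums(joint)) + entropy_from_probs(colSums(joint)) -
    entropy_from_probs(as.vector(joint))
}

#' Brute-force joint conditional entropy of the next state
#'
#' Independent oracle for the quantity that [entropy_bound_curve()] bounds
#' from above: the exact `H(Y | X_S)` by full joint-state enumeration, where
#' `Y` collects the next values of all regulated nodes together with the
#' (exogenous) states of the external nodes. Used to verify that the bound
#' curve is a true upper bound.
#'
#' @param net a `boolean_network` with at most 12 nodes.
#' @param S character vector of conditioning node names.
#' @param dist optional [input_distribution()]; default uniform 1/2.
#' @return entropy in bits.
#' @export
oracle_joint_conditional_entropy <- function(net, S, dist = NULL) {
  dist <- resolve_dist(net, dist)
  if (length(net$nodes) > 12) stop("joint enumeration limited to 12 nodes")
  if (!all(S %in% net$nodes)) stop("'S' must contain node names")
  es <- enumerate_states(net, dist)
  reg <- names(net$rules)
  ext <- external_nodes(net)
  ykey <- apply(es$states, 1, function(x) {
    nxt <- vapply(reg, function(i) evaluate_rule(net$rules[[i]], x), integer(1))
    paste(c(nxt, x[ext]), collapse = "")
  })
  skey <- if (length(S) > 0)
    apply(es$states[, S, drop = FALSE], 1, paste, collapse = "") else
    rep("", length(es$p))
  h_joint <- entropy_from_probs(tapply(es$p, paste(ykey, skey), sum))
  h_s <- entropy_from_probs(tapply(es$p, skey, sum))
  h_joint - h_s
}
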