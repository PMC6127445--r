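#' Binary (Shannon) entropy in bits
#'
#' `h(p) = -p log2(p) - (1-p) log2(1-p)` with the `0 log 0 = 0` convention,
#' so `h(0) = h(1) = 0` and `h(1/2) = 1`.
#'
#' @param p probability (vectorized), each in `[0, 1]`.
#' @return entropy in bits, same length as `p`.
#' @examples
#' binary_entropy(c(0, 0.5, 0.75, 1))
#' @export
binary_entropy <- function(p) {
  if (anyNA(p) || any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("probabilities must lie in [0, 1]")
  p <- pmin(pmax(p, 0), 1)
  term <- function(q) ifelse(q > 0, -q * log2(q), 0)
  term(p) + term(1 - p)
}

# Probability of each truth-table row under independent inputs:
# w[r] = prod over inputs m of (p_m if bit set else 1-p_m).
row_probs <- function(rule, dist) {
  k <- length(rule$inputs)
  miss <- setdiff(rule$inputs, names(dist))
  if (length(miss) > 0) stop("distribution missing input '", miss[1], "'")
  asn <- rule_assignments(k)
  w <- rep(1, 2^k)
  for (m in seq_len(k)) {
    pm <- dist[[rule$inputs[m]]]
    w <- w * ifelse(asn[, m] == 1L, pm, 1 - pm)
  }
  w
}

#' Activation probability of an update rule
#'
#' The probability that the rule evaluates to 1 under an independent input
#' distribution: the sum, over the assignments in the rule's support, of the
#' product of per-input activation probabilities. Under the uniform
#' distribution this is `|supp f| / 2^k`.
#'
#' @param rule an update rule (`list(inputs=, table=)`).
#' @param dist an [input_distribution()] (or any named probability vector
#'   covering the rule's inputs).
#' @return probability in `[0, 1]`.
#' @examples
#' net <- example1_network()
#' d <- input_distribution(net)
#' activation_probability(net$rules[["x2"]], d) # 3/8
#' @export
activation_probability <- function(rule, dist) {
  sum(row_probs(rule, dist)[rule$table == 1L])
}

#' Mutual information between an update rule and a node state
#'
#' Computes `MI(f_i(X); X_j)` in bits, exactly and from the local truth table
#' only: the entropy of the rule's activation probability minus the
#' probability-weighted entropies of the activation probability conditioned on
#' `X_j = 1` and `X_j = 0`. When `j` is not an input of `i` the two variables
#' are independent and the MI is 0. Self-inputs (`j = i`) condition on the
#' *current* state of `i`, which is legitimate under one-step semantics.
#'
#' @param net a `boolean_network`.
#' @param i name of the target node (must be regulated).
#' @param j name of the conditioning node.
#' @param dist optional [input_distribution()]; default uniform 1/2.
#' @return mutual information in bits, in `[0, 1]`.
#' @examples
#' net <- example1_network()
#' mutual_information(net, "x2", "x1") # 0.5488
#' mutual_information(net, "x3", "x1") # 0.3113
#' @export
mutual_information <- function(net, i, j, dist = NULL) {
  dist <- resolve_dist(net, dist)
  if (!j %in% net$nodes) stop("unknown node '", j, "'")
  rule <- net$rules[[i]]
  if (is.null(rule)) {
    if (!i %in% net$nodes) stop("unknown node '", i, "'")
    stop("node '", i, "' is external and has no update rule")
  }
  jm <- match(j, rule$inputs)
  if (is.na(jm)) return(0)
  w <- row_probs(rule, dist)
  asn <- rule_assignments(length(rule$inputs))
  supp <- rule$table == 1L
  pj <- dist[[j]]
  mi <- binary_entropy(sum(w[supp]))
  for (b in c(1L, 0L)) {
    pb <- if (b == 1L) pj else 1 - pj
    if (pb <= 0) next
    sb <- sum(w[supp & asn[, jm] == b]) / pb
    mi <- mi - pb * binary_entropy(sb)
  }
  # clamp away float negatives of order 1e-16
  max(mi, 0)
}

#' Conditional entropy of an update rule given a set of node states
#'
#' `H(f_i(X) | X_{S})` in bits. Only `S`'s intersection with the rule's
#' inputs matters (conditioning on independent non-inputs changes nothing);
#' the remaining free inputs are marginalized under `dist`. With `S` equal to
#' the full input set the rule is deterministic and the entropy is 0; with
#' `S` empty it is the rule's unconditional entropy `h(activation)`.
#'
#' @param net a `boolean_network`.
#' @param i name of the target node (must be regulated).
#' @param S character vector of conditioning node names.
#' @param dist optional [input_distribution()]; default uniform 1/2.
#' @return entropy in bits.
#' @export
conditional_rule_entropy <- function(net, i, S, dist = NULL) {
  dist <- resolve_dist(net, dist)
  rule <- net$rules[[i]]
  if (is.null(rule)) {
    if (!i %in% net$nodes) stop("unknown node '", i, "'")
    stop("node '", i, "' is external and has no update rule")
  }
  cond <- intersect(rule$inputs, S)
  if (length(cond) == 0)
    return(binary_entropy(activation_probability(rule, dist)))
  k <- length(rule$inputs)
  ci <- match(cond, rule$inputs)
  asn <- rule_assignments(k)
  # split the row probability into conditioned and free factors
  w_cond <- rep(1, 2^k)
  w_free <- rep(1, 2^k)
  for (m in seq_len(k)) {
    pm <- dist[[rule$inputs[m]]]
    f <- ifelse(asn[, m] == 1L, pm, 1 - pm)
    if (m %in% ci) w_cond <- w_cond * f else w_free <- w_free * f
  }
  key <- as.vector(asn[, ci, drop = FALSE] %*% 2^(seq_along(ci) - 1))
  supp <- rule$table == 1L
  p_y <- tapply(w_cond, key, `[`, 1)         # P(X_cond = y), constant per group
  p_f1 <- tapply(w_free * supp, key, sum)    # P(f = 1 | y); free weights sum to 1
  sum(p_y * binary_entropy(pmin(pmax(p_f1, 0), 1)))
}

#' Determinative power of every node
#'
#' The determinative power of node `j` is the total information gain it
#' provides about the network's next state:
#' `DP(j) = sum_i MI(f_i(X); X_j)`, the sum running over the nodes `i` that
#' have `j` as an input. External nodes are included — they have no rule of
#' their own but can determine other nodes. The ranking sorts nodes by DP,
#' descending, ties broken by original node order.
#'
#' @param net a `boolean_network`.
#' @param dist optional [input_distribution()]; default uniform 1/2.
#' @return an object of class `dp_table`: list with components
#'   \describe{
#'     \item{dp}{data.frame with columns `node`, `dp`, `out_degree`, `rank`}
#'     \item{mi}{long-format data.frame `target`, `input`, `mi` (one row per
#'       wiring edge)}
#'     \item{h_rule}{named vector of rule entropies `H(f_i)`}
#'     \item{ranking}{node names in DP-descending order}
#'   }
#' @examples
#' dpt <- determinative_power(example1_network())
#' dpt$dp
#' @export
determinative_power <- function(net, dist = NULL) {
  validate_network(net)
  dist <- resolve_dist(net, dist)
  dp <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  mi_rows <- list()
  h_rule <- stats::setNames(numeric(length(net$rules)), names(net$rules))
  for (i in names(net$rules)) {
    h_rule[[i]] <- binary_entropy(activation_probability(net$rules[[i]], dist))
    for (j in net$rules[[i]]$inputs) {
      m <- mutual_information(net, i, j, dist)
      dp[[j]] <- dp[[j]] + m
      mi_rows[[length(mi_rows) + 1L]] <- data.frame(target = i, input = j,
                                                    mi = m)
    }
  }
  out_deg <- degree_counts(net)$out_degree
  ord <- order(-dp)  # stable: ties keep original node order
  dp_df <- data.frame(node = net$nodes, dp = as.numeric(dp),
                      out_degree = as.integer(out_deg[net$nodes]),
                      rank = match(seq_along(dp), ord))
  mi_df <- if (length(mi_rows) > 0) do.call(rbind, mi_rows) else
    data.frame(target = character(), input = character(), mi = numeric())
  structure(list(dp = dp_df, mi = mi_df, h_rule = h_rule,
                 ranking = net$nodes[ord]),
            class = "dp_table")
}

#' @export
print.dp_table <- function(x, ...) {
  cat("Determinative power,", nrow(x$dp), "nodes\n")
  print(x$dp[order(x$dp$rank), ], row.names = FALSE)
  invisible(x)
}

#' Write a DP table to CSV
#'
#' @param x a `dp_table`.
#' @param dp_file path for the per-node table (`node, dp, out_degree, rank`).
#' @param mi_file optional path for the long-format MI table
#'   (`target, input, mi`).
#' @return `dp_file`, invisibly.
#' @export
write_dp_table <- function(x, dp_file, mi_file = NULL) {
  stopifnot(inherits(x, "dp_table"))
  utils::write.csv(x$dp, dp_file, row.names = FALSE, quote = FALSE)
  if (!is.null(mi_file))
    utils::write.csv(x$mi, mi_file, row.names = FALSE, quote = FALSE)
  invisible(dp_file)
}
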