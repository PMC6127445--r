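#' Construct a Boolean network
#'
#' A Boolean network is an ordered set of named binary nodes. A *regulated*
#' node carries an update rule: an ordered list of input node names and a
#' truth table over those inputs. A node with no rule is an *external*
#' component (an input-only node, e.g. a ligand): its state is exogenous, but
#' it is a full member of the network and may determine other nodes.
#'
#' Truth tables are stored as 0/1 integer vectors of length `2^k`, where `k`
#' is the number of inputs, in ascending binary row order with the **first
#' listed input as the most significant bit**. Row `r` (1-based) therefore
#' encodes the assignment whose bits are the binary digits of `r - 1`.
#' A rule with `k = 0` is a constant and has a one-entry table.
#'
#' @param rules named list; one element per regulated node, each a list with
#'   components `inputs` (character vector of node names, possibly empty) and
#'   `table` (integer 0/1 vector of length `2^length(inputs)`).
#' @param external character vector of additional node names that carry no
#'   rule. Input names referenced by a rule but not otherwise declared are
#'   added as external nodes automatically.
#' @param nodes optional character vector fixing the node order; must be a
#'   permutation of all declared node names. Defaults to rule order followed
#'   by externals in first-reference order.
#' @return an object of class `boolean_network` with components `nodes`
#'   (ordered character vector) and `rules` (named list of update rules for
#'   the regulated nodes).
#' @examples
#' net <- boolean_network(
#'   rules = list(a = list(inputs = c("a", "b"), table = c(0L, 0L, 0L, 1L))),
#'   external = "b"
#' )
#' regulated_nodes(net)
#' external_nodes(net)
#' @seealso [parse_expression_file()], [parse_truth_table_dir()],
#'   [example1_network()]
#' @export
boolean_network <- function(rules = list(), external = character(), nodes = NULL) {
  if (length(rules) > 0 && is.null(names(rules)))
    stop("'rules' must be a named list")
  referenced <- unique(unlist(lapply(rules, `[[`, "inputs"), use.names = FALSE))
  implicit <- setdiff(referenced, c(names(rules), external))
  all_nodes <- c(names(rules), external, implicit)
  if (!is.null(nodes)) {
    if (!setequal(nodes, all_nodes) || anyDuplicated(nodes))
      stop("'nodes' must be a permutation of all declared node names")
    all_nodes <- as.character(nodes)
  }
  rules <- lapply(rules, function(r) {
    list(inputs = as.character(r$inputs), table = as.integer(r$table))
  })
  net <- structure(list(nodes = all_nodes, rules = rules),
                   class = "boolean_network")
  validate_network(net)
  net
}

#' Validate a Boolean network
#'
#' Checks the structural invariants: unique non-empty node names, every rule
#' input resolving to a network node, no duplicated inputs within a rule, and
#' truth tables of length exactly `2^k` containing only 0/1.
#'
#' @param net a `boolean_network`.
#' @return `net`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  nodes <- net$nodes
  if (length(nodes) < 1) stop("network must contain at least one node")
  if (any(!nzchar(nodes)) || anyNA(nodes)) stop("node names must be non-empty")
  if (anyDuplicated(nodes)) stop("duplicate node name: ",
                                 nodes[duplicated(nodes)][1])
  if (!all(names(net$rules) %in% nodes))
    stop("rule for unknown node: ",
         setdiff(names(net$rules), nodes)[1])
  for (nm in names(net$rules)) {
    r <- net$rules[[nm]]
    if (anyDuplicated(r$inputs))
      stop("duplicate input in rule for '", nm, "'")
    bad <- setdiff(r$inputs, nodes)
    if (length(bad) > 0)
      stop("rule for '", nm, "' references unknown node '", bad[1], "'")
    k <- length(r$inputs)
    if (length(r$table) != 2^k)
      stop("rule for '", nm, "': table has ", length(r$table),
           " entries, expected 2^", k, " = ", 2^k)
    if (anyNA(r$table) || !all(r$table %in% c(0L, 1L)))
      stop("rule for '", nm, "': table entries must be 0 or 1")
  }
  invisible(net)
}

#' @export
print.boolean_network <- function(x, ...) {
  n <- length(x$nodes)
  reg <- regulated_nodes(x)
  cat("Boolean network:", n, "nodes (", length(reg), "regulated,",
      n - length(reg), "external ),", n_edges(x), "edges\n")
  for (nm in utils::head(x$nodes, 12)) {
    if (nm %in% reg) {
      r <- x$rules[[nm]]
      cat(sprintf("  %s <- f(%s)  |supp| = %d/%d\n", nm,
                  paste(r$inputs, collapse = ","), sum(r$table),
                  length(r$table)))
    } else {
      cat(sprintf("  %s (external)\n", nm))
    }
  }
  if (n > 12) cat("  ...\n")
  invisible(x)
}

#' Node classification helpers
#'
#' @param net a `boolean_network`.
#' @return character vector of node names.
#' @export
regulated_nodes <- function(net) {
  net$nodes[net$nodes %in% names(net$rules)]
}

#' @rdname regulated_nodes
#' @export
external_nodes <- function(net) {
  setdiff(net$nodes, names(net$rules))
}

n_edges <- function(net) {
  sum(vapply(net$rules, function(r) length(r$inputs), integer(1)))
}

#' Enumerate rule input assignments in canonical row order
#'
#' Returns the `2^k` by `k` 0/1 matrix whose rows list all assignments of `k`
#' binary inputs in ascending binary order, first input as most significant
#' bit. Row `r` of a rule's truth table corresponds to row `r` of this matrix.
#'
#' @param k number of inputs (non-negative integer).
#' @return integer matrix with `2^k` rows and `k` columns.
#' @export
rule_assignments <- function(k) {
  stopifnot(k >= 0)
  if (k == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  if (k > 24) stop("rules with more than 24 inputs are not supported (2^k blow-up)")
  m <- vapply(seq_len(k), function(j) {
    rep(rep(0:1, each = 2^(k - j)), times = 2^(j - 1))
  }, integer(2^k))
  matrix(as.integer(m), nrow = 2^k, ncol = k)
}

#' Evaluate an update rule on one assignment
#'
#' Looks up the truth-table entry for a named assignment of the rule's inputs.
#' A single synchronous step of the whole network applies this map to every
#' regulated node simultaneously (see [network_step()]).
#'
#' @param rule a rule as stored in `net$rules`: list with `inputs` and `table`.
#' @param assignment named 0/1 vector (or list) covering all rule inputs.
#' @return 0 or 1.
#' @examples
#' net <- example1_network()
#' evaluate_rule(net$rules[["x1"]], c(x2 = 1, x3 = 1, x4 = 0))
#' @export
evaluate_rule <- function(rule, assignment) {
  assignment <- unlist(assignment)
  missing <- setdiff(rule$inputs, names(assignment))
  if (length(missing) > 0)
    stop("assignment is missing input '", missing[1], "'")
  k <- length(rule$inputs)
  bits <- as.integer(assignment[rule$inputs])
  if (anyNA(bits) || !all(bits %in% c(0L, 1L)))
    stop("assignment values must be 0 or 1")
  r <- if (k == 0) 1L else sum(bits * 2^((k - 1):0)) + 1L
  rule$table[[r]]
}

#' Synchronous network step
#'
#' Applies every regulated node's rule to the current state simultaneously;
#' external nodes keep their current value (their next value is exogenous and
#' is here held fixed).
#'
#' @param net a `boolean_network`.
#' @param state named 0/1 vector covering all nodes.
#' @return named 0/1 integer vector, the next state.
#' @export
network_step <- function(net, state) {
  state <- unlist(state)
  if (!all(net$nodes %in% names(state)))
    stop("state must cover every node")
  nxt <- state[net$nodes]
  for (nm in names(net$rules)) nxt[[nm]] <- evaluate_rule(net$rules[[nm]], state)
  storage.mode(nxt) <- "integer"
  nxt
}

#' Uniform or custom independent input distribution
#'
#' The node states are modelled as mutually independent Bernoulli variables;
#' `activation[j]` is the probability that node `j`'s current state is 1. The
#' default of 1/2 everywhere makes all `2^n` states equally likely (the
#' ergodic assumption under which the worked values of the method are
#' reported).
#'
#' @param net a `boolean_network`.
#' @param p default activation probability applied to every node.
#' @param overrides optional named numeric vector of per-node probabilities.
#' @return named numeric vector over all nodes, class `input_distribution`.
#' @export
input_distribution <- function(net, p = 0.5, overrides = NULL) {
  stopifnot(p >= 0, p <= 1)
  d <- stats::setNames(rep(p, length(net$nodes)), net$nodes)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), net$nodes)
    if (length(bad) > 0) stop("override for unknown node '", bad[1], "'")
    if (any(overrides < 0 | overrides > 1))
      stop("activation probabilities must lie in [0, 1]")
    d[names(overrides)] <- overrides
  }
  structure(d, class = c("input_distribution", "numeric"))
}

# Resolve a dist argument: NULL means uniform 1/2.
resolve_dist <- function(net, dist) {
  if (is.null(dist)) return(input_distribution(net))
  miss <- setdiff(net$nodes, names(dist))
  if (length(miss) > 0) stop("distribution missing node '", miss[1], "'")
  if (any(dist < 0 | dist > 1)) stop("activation probabilities must lie in [0, 1]")
  dist
}
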