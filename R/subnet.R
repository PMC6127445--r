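#' Conditional-entropy bound curve A(l)
#'
#' For a ranking of candidate nodes, `A(l)` is an upper bound on the entropy
#' of the network's next state given the current states of the top-`l` nodes
#' `S_l`: the sum over regulated nodes of `H(f_i(X) | X_{S_l})` plus, for
#' every external node not yet in `S_l`, its own state entropy `h(p)`.
#' Subadditivity of entropy makes this an upper bound on the joint
#' conditional entropy; conditioning on more nodes never increases it, and
#' once every node is selected the curve reaches 0.
#'
#' @param net a `boolean_network`.
#' @param ranking character vector of distinct node names (typically the
#'   DP-descending ranking); may be a subset of the nodes under a restricted
#'   candidate policy.
#' @param dist optional [input_distribution()]; default uniform 1/2.
#' @return numeric vector `A` of length `length(ranking)`.
#' @seealso [select_subnetwork()] for the full pipeline.
#' @export
entropy_bound_curve <- function(net, ranking, dist = NULL) {
  validate_network(net)
  dist <- resolve_dist(net, dist)
  if (anyDuplicated(ranking) || !all(ranking %in% net$nodes))
    stop("'ranking' must be distinct node names of the network")
  ext <- external_nodes(net)
  ext_h <- binary_entropy(as.numeric(dist[ext]))
  vapply(seq_along(ranking), function(l) {
    S <- ranking[seq_len(l)]
    reg_sum <- sum(vapply(names(net$rules), function(i)
      conditional_rule_entropy(net, i, S, dist), numeric(1)))
    reg_sum + sum(ext_h[!(ext %in% S)])
  }, numeric(1))
}

#' Consecutive-distance sequence B(l)
#'
#' `B(l) = |A(l+1) - A(l)|`, the per-step entropy decrement of the bound
#' curve (the absolute value is redundant for a non-increasing `A`).
#'
#' @param A numeric sequence of length at least 2.
#' @return numeric vector of length `length(A) - 1`.
#' @export
distance_sequence <- function(A) {
  if (length(A) < 2) stop("'A' must have at least 2 elements")
  abs(diff(A))
}

#' Padded moving average
#'
#' Windowed means of `d` consecutive terms, padded back to the input length
#' by repeating the first windowed mean `floor((d-1)/2)` times at the front
#' and the last one `ceiling((d-1)/2)` times at the back — so an even `d`
#' repeats the last element once more than the first.
#'
#' @param x numeric sequence.
#' @param d window size, `1 <= d <= length(x)`.
#' @return numeric vector of length `length(x)`.
#' @examples
#' moving_average(10:1, 3) # 9 9 8 7 6 5 4 3 2 2
#' moving_average(10:1, 4) # 8.5 8.5 7.5 ... 2.5 2.5 2.5
#' @export
moving_average <- function(x, d) {
  m <- length(x)
  if (d < 1 || d > m) stop("'d' must lie in [1, length(x)]")
  d <- as.integer(d)
  means <- vapply(seq_len(m - d + 1L), function(u) mean(x[u:(u + d - 1L)]),
                  numeric(1))
  c(rep(means[1], (d - 1L) %/% 2L), means,
    rep(means[length(means)], d %/% 2L))
}

#' Default moving-average window for a bound curve of length n
#'
#' One tenth of the decrement-sequence length, rounded up, with a floor of 1.
#'
#' @param n number of ranked nodes.
#' @return integer window size.
#' @export
default_window <- function(n) {
  max(1L, as.integer(ceiling(0.1 * (n - 1))))
}

#' Threshold cutoff on the smoothed decrement sequence
#'
#' Finds the smallest rank `L` at which the smoothed entropy decrements have
#' dropped, and on average stay, below the threshold: both `MA_d(L) <= T` and
#' `(1/d) * sum_{j=L}^{min(L+d-1, n-1)} MA_d(j) <= T` must hold. The trailing
#' sum divides by `d` even when the window is truncated at `n - 1`. If no
#' rank satisfies the conditions, `L = n` (the whole network).
#'
#' @param A the bound curve (length `n >= 2`).
#' @param d moving-average window; default `ceiling(0.1 * (n - 1))`, floor 1.
#' @param t_factor threshold as a fraction of `max(MA_d)`; default 1/4.
#' @param threshold absolute threshold `T` in bits, overriding `t_factor`.
#' @return list with components `B`, `MA`, `d`, `t_factor`, `T`, `L`.
#' @export
find_cutoff <- function(A, d = NULL, t_factor = 0.25, threshold = NULL) {
  n <- length(A)
  if (n < 2) stop("'A' must have at least 2 elements")
  if (is.null(d)) d <- default_window(n)
  if (d <= 0) stop("'d' must be positive")
  if (is.null(threshold) && t_factor <= 0) stop("'t_factor' must be positive")
  B <- distance_sequence(A)
  MA <- moving_average(B, d)
  Tval <- if (is.null(threshold)) t_factor * max(MA) else threshold
  L <- n
  for (l in seq_len(n - 1L)) {
    trail <- sum(MA[l:min(l + d - 1L, n - 1L)]) / d
    if (MA[l] <= Tval && trail <= Tval) {
      L <- l
      break
    }
  }
  list(B = B, MA = MA, d = as.integer(d),
       t_factor = if (is.null(threshold)) t_factor else NA_real_,
       T = Tval, L = as.integer(L))
}

#' Select the most determinative subnetwork
#'
#' The full pipeline: rank all candidate nodes by determinative power,
#' compute the conditional-entropy bound curve `A(l)` along the ranking,
#' smooth its decrements with a window-`d` moving average, and cut at the
#' first rank where the smoothed decrements fall and stay below
#' `T = t_factor * max(MA_d)`. The selected subnetwork is the top-`L` nodes.
#'
#' @param net a `boolean_network`.
#' @param dist optional [input_distribution()]; default uniform 1/2.
#' @param d moving-average window; default `ceiling(0.1 * (n - 1))` where `n`
#'   is the number of candidates.
#' @param t_factor threshold fraction of `max(MA_d)`; default 1/4.
#' @param candidates `"all"` (default: every node, external included, may be
#'   ranked and selected) or `"regulated"` (external nodes are never
#'   selected, so their state entropy remains in the bound curve).
#' @return an object of class `selection_trace`: list with components
#'   `ranking`, `A`, `B`, `MA`, `d`, `t_factor`, `T`, `L`, `selected`,
#'   `candidates`, and the underlying `dp_table` as `dp`.
#' @examples
#' tr <- select_subnetwork(example1_network())
#' tr$ranking
#' tr$L
#' @export
select_subnetwork <- function(net, dist = NULL, d = NULL, t_factor = 0.25,
                              candidates = c("all", "regulated")) {
  candidates <- match.arg(candidates)
  dist <- resolve_dist(net, dist)
  dpt <- determinative_power(net, dist)
  ranking <- dpt$ranking
  if (candidates == "regulated")
    ranking <- ranking[ranking %in% names(net$rules)]
  if (length(ranking) < 2)
    stop("need at least 2 candidate nodes to select a subnetwork")
  A <- entropy_bound_curve(net, ranking, dist)
  cut <- find_cutoff(A, d = d, t_factor = t_factor)
  structure(c(list(ranking = ranking, A = A), cut,
              list(selected = ranking[seq_len(cut$L)],
                   candidates = candidates, dp = dpt)),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Subnetwork selection: L =", x$L, "of", length(x$ranking),
      sprintf("candidates (d = %d, T = %.4g bits)\n", x$d, x$T))
  cat("Selected:", paste(utils::head(x$selected, 15), collapse = ", "),
      if (length(x$selected) > 15) "..." else "", "\n")
  invisible(x)
}

#' Sweep the cutoff over a parameter grid
#'
#' Recomputes the cutoff `L` for every combination of moving-average window
#' `d` and absolute threshold `T`, reusing one DP ranking and bound curve.
#' Mirrors the parameter-sensitivity surface of the selection algorithm:
#' `L` is non-increasing in `T` for fixed `d`.
#'
#' @param net a `boolean_network`.
#' @param dist optional [input_distribution()]; default uniform 1/2.
#' @param d_grid integer vector of window sizes.
#' @param t_grid numeric vector of absolute thresholds (bits).
#' @param candidates as in [select_subnetwork()].
#' @return numeric matrix of `L` values, rows indexed by `d_grid`, columns by
#'   `t_grid`.
#' @export
sweep_cutoff <- function(net, dist = NULL, d_grid, t_grid,
                         candidates = c("all", "regulated")) {
  candidates <- match.arg(candidates)
  if (length(d_grid) == 0 || length(t_grid) == 0)
    stop("parameter grids must be non-empty")
  dist <- resolve_dist(net, dist)
  dpt <- determinative_power(net, dist)
  ranking <- dpt$ranking
  if (candidates == "regulated")
    ranking <- ranking[ranking %in% names(net$rules)]
  A <- entropy_bound_curve(net, ranking, dist)
  L <- matrix(NA_real_, length(d_grid), length(t_grid),
              dimnames = list(d = d_grid, T = signif(t_grid, 6)))
  for (a in seq_along(d_grid))
    for (b in seq_along(t_grid))
      L[a, b] <- find_cutoff(A, d = d_grid[a], threshold = t_grid[b])$L
  L
}

#' Write a selection trace to CSV
#'
#' The table holds one row per rank (`l, node, A, B, MA`); the scalar
#' parameters `d`, `T`, `t_factor`, `L` are written as `#`-prefixed header
#' lines above it. The selected node list goes to `selected_file`, one name
#' per line.
#'
#' @param x a `selection_trace`.
#' @param trace_file path for the trace CSV.
#' @param selected_file optional path for the plain-text selected-node list.
#' @return `trace_file`, invisibly.
#' @export
write_selection_trace <- function(x, trace_file, selected_file = NULL) {
  stopifnot(inherits(x, "selection_trace"))
  n <- length(x$ranking)
  df <- data.frame(l = seq_len(n), node = x$ranking, A = x$A,
                   B = c(x$B, NA), MA = c(x$MA, NA))
  con <- file(trace_file, "w")
  on.exit(close(con))
  writeLines(sprintf("# d,%d", x$d), con)
  writeLines(sprintf("# t_factor,%s", format(x$t_factor)), con)
  writeLines(sprintf("# T,%.12g", x$T), con)
  writeLines(sprintf("# L,%d", x$L), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  if (!is.null(selected_file)) writeLines(x$selected, selected_file)
  invisible(trace_file)
}
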