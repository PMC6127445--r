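#' Per-network summary variables
#'
#' The eight quantities used to characterize a network and its selected
#' subnetwork across a cohort: size `n`, subnetwork size `L`, edge count `E`,
#' maximum and average determinative power, the reduction ratio `L/n`, and
#' the wiring density `E/n^2` (self-inputs are allowed, so `n^2` is the
#' number of possible edges).
#'
#' @param net a `boolean_network`.
#' @param dp_table a `dp_table` from [determinative_power()].
#' @param trace a `selection_trace` from [select_subnetwork()].
#' @param name label for the network.
#' @return one-row data.frame: `name, n, L, E, max_dp, avg_dp, ratio_ln,
#'   density`.
#' @export
summarize_network <- function(net, dp_table, trace, name = "network") {
  stopifnot(inherits(dp_table, "dp_table"), inherits(trace, "selection_trace"))
  if (!setequal(dp_table$dp$node, net$nodes) ||
      !all(trace$ranking %in% net$nodes))
    stop("'dp_table' and 'trace' must come from the same network as 'net'")
  n <- length(net$nodes)
  E <- degree_counts(net)$E
  data.frame(name = name, n = n, L = trace$L, E = E,
             max_dp = max(dp_table$dp$dp), avg_dp = mean(dp_table$dp$dp),
             ratio_ln = trace$L / n, density = E / n^2,
             stringsAsFactors = FALSE)
}

#' Ordinary least-squares line fit
#'
#' Fits `y = intercept + slope * x` and reports the coefficient of
#' determination (the squared Pearson correlation).
#'
#' @param x,y numeric vectors of equal length, at least 3 points, `x` not
#'   constant.
#' @return list of class `regression_fit`: `slope`, `intercept`, `r_squared`.
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("'x' is constant; no line can be fitted")
  fit <- stats::lm(y ~ x)
  # collinear y triggers a "perfect fit" warning in summary.lm; r.squared
  # itself is well-defined there
  r2 <- if (stats::sd(y) == 0) 0 else
    suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("y = %.4g %+.4g x   (R^2 = %.1f%%)\n",
              x$intercept, x$slope, 100 * x$r_squared))
  invisible(x)
}

#' Cohort regression grid
#'
#' Regresses each of the response summaries `L`, `L/n`, `max_dp`, `avg_dp`
#' on each of the predictors `n`, `E`, `E/n^2` across a cohort of network
#' summaries, mirroring the standard 3 x 4 report of fitted lines and
#' coefficients of determination.
#'
#' @param summaries data.frame of rows from [summarize_network()] (one per
#'   network, at least 3).
#' @return tidy data.frame: `response, predictor, slope, intercept,
#'   r_squared`.
#' @export
cohort_regressions <- function(summaries) {
  responses <- c(L = "L", ratio_ln = "ratio_ln", max_dp = "max_dp",
                 avg_dp = "avg_dp")
  predictors <- c(n = "n", E = "E", density = "density")
  rows <- list()
  for (pv in predictors) for (rv in responses) {
    f <- fit_line(summaries[[pv]], summaries[[rv]])
    rows[[length(rows) + 1L]] <- data.frame(response = rv, predictor = pv,
                                            slope = f$slope,
                                            intercept = f$intercept,
                                            r_squared = f$r_squared)
  }
  do.call(rbind, rows)
}

#' Essential-node enrichment among the top-ranked nodes
#'
#' Compares the proportion of essential nodes among the `k` top-ranked
#' (highest-DP) nodes with the background proportion over the whole network,
#' and reports a one-sided hypergeometric (Fisher) enrichment p-value: the
#' probability of observing at least as many essential nodes in a random
#' draw of `k` from the background.
#'
#' @param ranking node names in DP-descending order.
#' @param essential character vector of essential node names (a subset of
#'   `background`).
#' @param k number of top-ranked nodes to examine, `1 <= k <= length(ranking)`.
#' @param background universe of nodes; defaults to `ranking`.
#' @return list: `proportion_top`, `proportion_background`, `p_value`,
#'   `n_top_essential`.
#' @export
essential_overlap <- function(ranking, essential, k, background = ranking) {
  if (k < 1 || k > length(ranking)) stop("'k' out of range")
  if (!all(essential %in% background))
    stop("'essential' must be a subset of 'background'")
  if (!all(ranking %in% background))
    stop("'ranking' must be drawn from 'background'")
  top <- ranking[seq_len(k)]
  x <- sum(top %in% essential)
  K <- length(unique(essential))
  N <- length(unique(background))
  list(proportion_top = x / k,
       proportion_background = K / N,
       p_value = stats::phyper(x - 1, K, N - K, k, lower.tail = FALSE),
       n_top_essential = x)
}
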