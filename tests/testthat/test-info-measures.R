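# Reference values below were verified by two independent routes (the
# support-sum formula and full joint-state enumeration) before being frozen.

test_that("binary entropy has the right shape and conventions", {
  expect_identical(binary_entropy(0.5), 1)
  expect_identical(binary_entropy(0), 0)
  expect_identical(binary_entropy(1), 0)
  expect_equal(binary_entropy(0.75), 0.8112781245, tolerance = 1e-9)
  expect_equal(binary_entropy(0.25), binary_entropy(0.75))
  expect_error(binary_entropy(1.2), "\\[0, 1\\]")
  expect_error(binary_entropy(-0.1), "\\[0, 1\\]")
})

test_that("activation probabilities are support sums", {
  net <- example1_network()
  d <- input_distribution(net)
  expect_equal(activation_probability(net$rules$x2, d), 3 / 8)
  expect_equal(activation_probability(net$rules$x3, d), 3 / 4)
  expect_equal(activation_probability(net$rules$x1, d), 1 / 8)
  const0 <- list(inputs = character(), table = 0L)
  expect_identical(activation_probability(const0, d), 0)
  # biased inputs: P(x2=1)P(x3=1)(1-P(x4=1)) for the single-support AND rule
  db <- input_distribution(net, overrides = c(x2 = 0.9, x3 = 0.8, x4 = 0.3))
  expect_equal(activation_probability(net$rules$x1, db), 0.9 * 0.8 * 0.7)
})

test_that("mutual information reproduces the worked-example terms", {
  net <- example1_network()
  expect_equal(mutual_information(net, "x2", "x1"), 0.5487949407, tolerance = 1e-8)
  expect_equal(mutual_information(net, "x3", "x1"), 0.3112781245, tolerance = 1e-8)
  expect_equal(round(mutual_information(net, "x2", "x1"), 4), 0.5488)
  expect_equal(round(mutual_information(net, "x3", "x1"), 4), 0.3113)
})

test_that("mutual information vanishes for XOR targets and non-inputs", {
  xnet <- xor_network()
  expect_equal(mutual_information(xnet, "t", "a"), 0)
  expect_equal(mutual_information(xnet, "t", "b"), 0)
  net <- example1_network()
  expect_identical(mutual_information(net, "x3", "x4"), 0)  # x4 not an input of f3
  expect_error(mutual_information(net, "x4", "x1"), "external")
  expect_error(mutual_information(net, "x1", "zz"), "unknown node")
})

test_that("conditional rule entropy matches its limits and the MI identity", {
  net <- example1_network()
  d <- input_distribution(net)
  for (i in regulated_nodes(net)) {
    rule <- net$rules[[i]]
    # fully conditioned -> deterministic
    expect_equal(conditional_rule_entropy(net, i, rule$inputs, d), 0)
    # unconditioned -> rule entropy
    expect_equal(conditional_rule_entropy(net, i, character(), d),
                 binary_entropy(activation_probability(rule, d)))
    # conditioning on a non-input changes nothing
    non_input <- setdiff(net$nodes, rule$inputs)[1]
    expect_equal(conditional_rule_entropy(net, i, non_input, d),
                 conditional_rule_entropy(net, i, character(), d))
    # MI identity against every single node
    for (j in net$nodes) {
      h0 <- conditional_rule_entropy(net, i, character(), d)
      hj <- conditional_rule_entropy(net, i, j, d)
      expect_equal(mutual_information(net, i, j, d), h0 - hj, tolerance = 1e-12)
    }
  }
})

test_that("determinative power reproduces the verified worked-example values", {
  dpt <- determinative_power(example1_network())
  expect_identical(dpt$dp$node, c("x1", "x2", "x3", "x4"))
  expect_equal(dpt$dp$dp, c(0.8600731, 0.4979984, 0.1867203, 0.1379254),
               tolerance = 1e-6)
  expect_identical(dpt$ranking, c("x1", "x2", "x3", "x4"))
  expect_identical(dpt$dp$rank, 1:4)
  expect_identical(dpt$dp$out_degree, c(2L, 3L, 2L, 1L))
  # DP of the external node comes from its single output
  expect_equal(dpt$dp$dp[4],
               mutual_information(example1_network(), "x1", "x4"))
})

test_that("DP satisfies its structural bounds on random networks", {
  for (s in 1:10) {
    net <- generate_random_network(n = 8, k = c(1, 4), bias = 0.4,
                                   external_fraction = 0.25, seed = 100 + s)
    dpt <- determinative_power(net)
    expect_true(all(dpt$dp$dp >= 0))
    expect_true(all(dpt$dp$dp <= dpt$dp$out_degree + 1e-12))
    expect_true(all(dpt$mi$mi >= 0 & dpt$mi$mi <= 1 + 1e-12))
    # ranking is a DP-descending permutation of all nodes
    expect_setequal(dpt$ranking, net$nodes)
    expect_true(all(diff(dpt$dp$dp[match(dpt$ranking, dpt$dp$node)]) <= 1e-12))
    # MI bounded by both marginal entropies
    d <- input_distribution(net)
    for (r in seq_len(nrow(dpt$mi))) {
      i <- dpt$mi$target[r]
      expect_lte(dpt$mi$mi[r], dpt$h_rule[[i]] + 1e-12)
      expect_lte(dpt$mi$mi[r], binary_entropy(d[[dpt$mi$input[r]]]) + 1e-12)
    }
  }
})

test_that("a node with no outputs has zero determinative power", {
  net <- boolean_network(rules = list(a = list(inputs = "b", table = c(0L, 1L))),
                         external = "b")
  dpt <- determinative_power(net)
  expect_identical(dpt$dp$dp[dpt$dp$node == "a"], 0)
})

test_that("DP is invariant under node renaming and input-order permutation", {
  net <- generate_random_network(n = 7, k = 3, bias = 0.5, seed = 42)
  dpt <- determinative_power(net)

  # renaming
  map <- setNames(sprintf("renamed_%s", net$nodes), net$nodes)
  rules2 <- lapply(net$rules, function(r)
    list(inputs = unname(map[r$inputs]), table = r$table))
  names(rules2) <- map[names(net$rules)]
  net2 <- boolean_network(rules = rules2,
                          external = unname(map[external_nodes(net)]),
                          nodes = unname(map[net$nodes]))
  dpt2 <- determinative_power(net2)
  expect_equal(dpt2$dp$dp, dpt$dp$dp, tolerance = 1e-12)
  expect_identical(dpt2$ranking, unname(map[dpt$ranking]))

  # permuting the stored input order (table rewired consistently)
  rules3 <- lapply(net$rules, function(r)
    permute_rule(r, rev(seq_along(r$inputs))))
  net3 <- boolean_network(rules = rules3, external = external_nodes(net),
                          nodes = net$nodes)
  dpt3 <- determinative_power(net3)
  expect_equal(dpt3$dp$dp, dpt$dp$dp, tolerance = 1e-12)
})

test_that("DP tables export to CSV", {
  dpt <- determinative_power(example1_network())
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dp_table(dpt, f1, f2)
  back <- read.csv(f1)
  expect_identical(back$node, dpt$dp$node)
  expect_equal(back$dp, dpt$dp$dp, tolerance = 1e-6)
  expect_identical(nrow(read.csv(f2)), 8L)
})
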