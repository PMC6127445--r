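test_that("the padded moving average reproduces the three worked sequences", {
  expect_equal(moving_average(10:1, 3), c(9, 9, 8, 7, 6, 5, 4, 3, 2, 2))
  expect_equal(moving_average(10:1, 4),
               c(8.5, 8.5, 7.5, 6.5, 5.5, 4.5, 3.5, 2.5, 2.5, 2.5))
  expect_equal(moving_average(10:1, 5), c(8, 8, 8, 7, 6, 5, 4, 3, 3, 3))
})

test_that("moving average edge cases behave", {
  expect_equal(moving_average(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_equal(moving_average(1:4, 4), rep(2.5, 4))
  expect_error(moving_average(1:4, 5), "\\[1, length")
  expect_error(moving_average(1:4, 0), "\\[1, length")
})

test_that("the distance sequence is elementwise absolute differences", {
  expect_equal(distance_sequence(c(3, 1, 0, 0)), c(2, 1, 0))
  expect_equal(distance_sequence(rep(2, 5)), rep(0, 4))
  A <- sort(runif(8), decreasing = TRUE)
  expect_equal(distance_sequence(A), A[-8] - A[-1])  # |.| redundant when non-increasing
  expect_error(distance_sequence(1), "at least 2")
})

test_that("the bound curve matches per-node enumeration on the worked example", {
  net <- example1_network()
  ranking <- determinative_power(net)$ranking
  A <- entropy_bound_curve(net, ranking)
  # independent route: full joint-state enumeration of each H(f_i | X_S),
  # plus 1 bit for the external node while it is unselected
  expected <- sapply(seq_along(ranking), function(l) {
    S <- ranking[seq_len(l)]
    sum(sapply(regulated_nodes(net), function(i)
      oracle_node_conditional_entropy(net, i, S))) +
      sum(!(external_nodes(net) %in% S))
  })
  expect_equal(A, expected, tolerance = 1e-9)
  expect_equal(A[4], 0)
  # the external node contributes exactly 1 bit while unselected
  A_no_ext <- entropy_bound_curve(net, c("x1", "x2", "x3", "x4"))
  expect_equal(A_no_ext[3], 0.25 + 1)  # f1 given {x2,x3} plus unselected x4
})

test_that("the bound curve is a true upper bound and non-increasing", {
  nets <- c(list(example1_network()),
            lapply(1:6, function(s)
              generate_random_network(n = sample(4:6, 1), k = c(1, 3),
                                      bias = 0.5, external_fraction = 0.2,
                                      seed = 500 + s)))
  for (net in nets) {
    ranking <- determinative_power(net)$ranking
    A <- entropy_bound_curve(net, ranking)
    expect_true(all(diff(A) <= 1e-9))
    expect_true(all(A >= -1e-12))
    expect_equal(A[length(A)], 0, tolerance = 1e-12)
    for (l in seq_along(ranking)) {
      joint <- oracle_joint_conditional_entropy(net, ranking[seq_len(l)])
      expect_gte(A[l], joint - 1e-9)
    }
  }
})

test_that("cutoff detection handles degenerate curves", {
  # constant A: no decrements, threshold 0, stop immediately
  cut <- find_cutoff(rep(2, 6))
  expect_identical(cut$L, 1L)
  expect_identical(cut$T, 0)
  expect_equal(cut$MA, rep(0, 5))
  # linear ramp: MA constant at max, T = max/4 below it everywhere -> L = n
  cut2 <- find_cutoff(seq(10, 1, length.out = 10))
  expect_identical(cut2$L, 10L)
  expect_error(find_cutoff(c(1)), "at least 2")
  expect_error(find_cutoff(1:4, t_factor = 0), "positive")
})

test_that("cutoff equals a literal scan of both threshold conditions", {
  for (s in 1:5) {
    net <- generate_random_network(n = 20, k = c(1, 4), bias = 0.35,
                                   external_fraction = 0.15, seed = 700 + s)
    ranking <- determinative_power(net)$ranking
    A <- entropy_bound_curve(net, ranking)
    for (d in c(1, 2, 3, 5)) {
      got <- find_cutoff(A, d = d, t_factor = 0.25)$L
      expect_identical(as.integer(got),
                       as.integer(oracle_cutoff_scan(A, d, 0.25)))
    }
  }
})

test_that("the cutoff is non-increasing in the threshold factor", {
  for (s in 1:5) {
    net <- generate_random_network(n = 15, k = c(1, 3), bias = 0.4,
                                   external_fraction = 0.2, seed = 900 + s)
    A <- entropy_bound_curve(net, determinative_power(net)$ranking)
    Ls <- sapply(c(0.05, 0.1, 0.25, 0.5, 1), function(tf)
      find_cutoff(A, t_factor = tf)$L)
    expect_true(all(diff(Ls) <= 0))
  }
})

test_that("select_subnetwork composes the individual steps", {
  net <- example1_network()
  tr <- select_subnetwork(net)
  expect_s3_class(tr, "selection_trace")
  expect_identical(tr$ranking, c("x1", "x2", "x3", "x4"))
  expect_true(tr$L >= 1 && tr$L <= 4)
  # step-by-step recomposition
  dpt <- determinative_power(net)
  A <- entropy_bound_curve(net, dpt$ranking)
  cut <- find_cutoff(A)
  expect_equal(tr$A, A)
  expect_identical(tr$L, cut$L)
  expect_identical(tr$selected, tr$ranking[seq_len(tr$L)])
  expect_identical(tr$d, default_window(4))
})

test_that("isolated constant nodes collapse the curve to zero", {
  net <- boolean_network(rules = list(a = list(inputs = character(), table = 1L),
                                      b = list(inputs = character(), table = 0L)))
  tr <- select_subnetwork(net)
  expect_equal(tr$A, c(0, 0))
  expect_identical(tr$L, 1L)
})

test_that("the regulated-only policy keeps external uncertainty in the curve", {
  net <- example1_network()
  tr <- select_subnetwork(net, candidates = "regulated")
  expect_identical(sort(tr$ranking), c("x1", "x2", "x3"))
  expect_length(tr$A, 3)
  # x4 is never selected, so its 1 bit of state entropy persists
  expect_gte(min(tr$A), 1)
})

test_that("the parameter sweep is consistent with the default pipeline", {
  net <- example1_network()
  tr <- select_subnetwork(net)
  surf <- sweep_cutoff(net, d_grid = c(1, 2), t_grid = c(tr$T, 2 * tr$T))
  expect_identical(dim(surf), c(2L, 2L))
  expect_equal(surf[tr$d, 1], tr$L)
  # 1x1 grid
  one <- sweep_cutoff(net, d_grid = tr$d, t_grid = tr$T)
  expect_equal(as.vector(one), tr$L)
  # L non-increasing in T along every row, on a random network
  net2 <- generate_random_network(n = 15, k = 2, bias = 0.4, seed = 1234)
  A2 <- entropy_bound_curve(net2, determinative_power(net2)$ranking)
  tg <- seq(0.01, max(distance_sequence(A2)), length.out = 6)
  surf2 <- sweep_cutoff(net2, d_grid = c(1, 2, 4), t_grid = tg)
  expect_true(all(apply(surf2, 1, function(r) all(diff(r) <= 0))))
  expect_error(sweep_cutoff(net, d_grid = integer(), t_grid = 1), "non-empty")
})

test_that("selection traces export to CSV with a parameter header", {
  tr <- select_subnetwork(example1_network())
  f <- withr::local_tempfile(fileext = ".csv")
  sel <- withr::local_tempfile(fileext = ".txt")
  write_selection_trace(tr, f, sel)
  lines <- readLines(f)
  expect_true(any(grepl("^# L,", lines)))
  body <- read.csv(f, comment.char = "#")
  expect_identical(nrow(body), 4L)
  expect_identical(readLines(sel), tr$selected)
})
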