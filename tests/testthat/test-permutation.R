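test_that("a data-stream swap exchanges two individuals and keeps margins", {
  roster <- toy_roster(c("A", "B", "C", "D"))
  gbi <- gbi_from_groups(list(c("A", "B"), c("C", "D")), roster)
  set.seed(1)
  swapped <- datastream_swap(gbi)
  expect_equal(colSums(swapped), colSums(gbi))
  expect_equal(unname(rowSums(swapped)), unname(rowSums(gbi)))
  expect_false(identical(unclass(swapped), unclass(gbi)))
  # the swap moves exactly one individual out of each period
  expect_equal(sum(unclass(swapped) != unclass(gbi)), 4)
})

test_that("degenerate GBIs admit no swap", {
  roster <- toy_roster(c("A", "B"))
  one_period <- gbi_from_groups(list(c("A", "B")), roster)
  expect_error(datastream_swap(one_period), "fewer than two periods")
  identical_periods <- gbi_from_groups(list(c("A", "B"), c("A", "B")), roster)
  expect_error(datastream_swap(identical_periods, max_tries = 50), "degenerate")
})

test_that("long swap chains conserve row and column sums exactly", {
  set.seed(11)
  gbi <- random_gbi(n = 6, n_periods = 15)
  mat <- groupness:::gbi_matrix(gbi)
  cur <- mat
  for (i in 1:1000) cur <- groupness:::swap_once(cur)
  expect_identical(colSums(cur), colSums(mat))
  expect_identical(rowSums(cur), rowSums(mat))
  expect_true(all(cur %in% c(0L, 1L)))
})

test_that("a swap-invariant statistic gives p = 1", {
  set.seed(3)
  gbi <- random_gbi(n = 5, n_periods = 10)
  res <- network_randomization_test(gbi, statistic = function(m) sum(m >= 0),
                                    iterations = 20, burn_in = 20,
                                    swaps_per_iteration = 2, seed = 5)
  expect_true(all(res$null_values == res$observed))
  expect_equal(res$p_lower, 1)
  expect_equal(res$p_upper, 1)
  expect_equal(res$p_two_tailed, 1)
})

test_that("perfect assortativity drives the mixed-dyad SRI to its lower tail", {
  roster <- toy_roster(LETTERS[1:6], species = rep(c("s1", "s2"), each = 3))
  cliques <- c(rep(list(c("A", "B", "C")), 10), rep(list(c("D", "E", "F")), 10))
  gbi <- gbi_from_groups(cliques, roster)
  stat <- function(m) mean_association_rate(m, mixed_species_dyads)$mean
  res <- network_randomization_test(gbi, stat, iterations = 100, burn_in = 200,
                                    swaps_per_iteration = 5, seed = 9)
  expect_equal(res$observed, 0)
  expect_true(all(res$null_values >= 0))
  # every null network mixes the cliques, so the observed value is minimal
  expect_lt(res$p_lower, 0.05)
  expect_equal(res$p_lower, mean(res$null_values <= 0))
})

test_that("identical inputs and seed give bit-identical permutation results", {
  set.seed(21)
  gbi <- random_gbi(n = 5, n_periods = 12)
  stat <- function(m) mean_association_rate(m)$mean
  r1 <- network_randomization_test(gbi, stat, iterations = 30, burn_in = 50,
                                   swaps_per_iteration = 3, seed = 123)
  r2 <- network_randomization_test(gbi, stat, iterations = 30, burn_in = 50,
                                   swaps_per_iteration = 3, seed = 123)
  expect_identical(r1, r2)
  values <- rnorm(10)
  v1 <- node_label_permutation_test(values, rep(c("a", "b"), 5),
                                    iterations = 50, seed = 7)
  v2 <- node_label_permutation_test(values, rep(c("a", "b"), 5),
                                    iterations = 50, seed = 7)
  expect_identical(v1[setdiff(names(v1), "null_values")],
                   v2[setdiff(names(v2), "null_values")])
})

test_that("node-label test matches exhaustive enumeration", {
  res <- node_label_permutation_test(c(10, 11, 1, 2), c("a", "a", "b", "b"),
                                     method = "exhaustive")
  expect_equal(res$observed, 9)
  expect_equal(res$iterations, 6)
  expect_equal(res$p_two_tailed, 2 / 6)

  # independent enumeration oracle on a larger input
  set.seed(4)
  values <- rnorm(8)
  labels <- rep(c("x", "y"), each = 4)
  res8 <- node_label_permutation_test(values, labels, method = "exhaustive")
  combos <- combn(8, 4)
  oracle <- apply(combos, 2, function(idx) mean(values[idx]) - mean(values[-idx]))
  obs <- mean(values[1:4]) - mean(values[5:8])
  expect_equal(res8$observed, obs)
  expect_equal(res8$p_two_tailed, mean(abs(oracle) >= abs(obs) - 1e-12))
  expect_equal(res8$p_lower, mean(oracle <= obs + 1e-12))
  expect_equal(res8$p_upper, mean(oracle >= obs - 1e-12))
})

test_that("identical groups give an observed difference of zero and p = 1", {
  res <- node_label_permutation_test(rep(2.5, 8), rep(c("a", "b"), 4),
                                     iterations = 50, seed = 1)
  expect_equal(res$observed, 0)
  expect_equal(res$p_two_tailed, 1)
})

test_that("the label test is exchangeable under relabelling of inputs", {
  set.seed(31)
  values <- rnorm(12)
  labels <- rep(c("a", "b"), 6)
  perm <- sample.int(12)
  # fixed factor levels keep the direction of the difference stable
  r1 <- node_label_permutation_test(values, factor(labels, c("a", "b")),
                                    method = "exhaustive")
  r2 <- node_label_permutation_test(values[perm], factor(labels[perm], c("a", "b")),
                                    method = "exhaustive")
  expect_equal(r1$p_two_tailed, r2$p_two_tailed)
  expect_equal(r1$observed, r2$observed)
})

test_that("non-finite metric values are dropped with their labels", {
  res <- node_label_permutation_test(c(1, 2, NaN, 3, 4), c("a", "a", "a", "b", "b"),
                                     method = "exhaustive")
  expect_equal(res$settings$n_first, 2)
  expect_equal(res$observed, mean(c(1, 2)) - mean(c(3, 4)))
})

test_that("label tests reject degenerate label sets", {
  expect_error(node_label_permutation_test(1:4, rep("a", 4), iterations = 10, seed = 1),
               "two levels")
  expect_error(node_label_permutation_test(1:4, c("a", "a", "a", "b")[c(1, 2, 3, 3)],
                                           iterations = 10, seed = 1),
               "two levels")
})

test_that("a large injected species difference is detected with high power", {
  set.seed(55)
  rejections <- 0
  for (i in 1:50) {
    values <- c(rnorm(10, mean = 5, sd = 0.5), rnorm(8, mean = 0, sd = 0.5))
    labels <- rep(c("big", "small"), c(10, 8))
    res <- node_label_permutation_test(values, labels, iterations = 200, seed = i)
    if (res$p_two_tailed < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / 50, 0.95)
})

test_that("bonferroni_adjust divides alpha by the family size", {
  expect_equal(bonferroni_adjust(0.05, 4), 0.0125)
  expect_equal(bonferroni_adjust(0.05, 1), 0.05)
  expect_equal(bonferroni_adjust(0.01, 5), 0.002)
  expect_error(bonferroni_adjust(0.05, 0), "positive integer")
  expect_error(bonferroni_adjust(1.2, 2), "alpha")
})

test_that("permutation results serialize to JSON with their settings", {
  res <- node_label_permutation_test(c(1, 5, 2, 6), c("a", "b", "a", "b"),
                                     iterations = 20, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_permutation_result(res, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$observed, res$observed)
  expect_equal(back$iterations, 20)
  expect_equal(back$method, "node_label_sampled")
  expect_true(back$add_one_correction)
  expect_gt(back$p_two_tailed_add_one, 0)
})
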