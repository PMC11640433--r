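test_that("build_network thresholds edges on SRI", {
  roster <- toy_roster(c("A", "B", "C"))
  zero <- matrix(0, 3, 3, dimnames = list(roster$id, roster$id))
  expect_equal(igraph::ecount(net_from_adjacency(zero, roster)$graph), 0)

  ones <- matrix(1, 3, 3, dimnames = list(roster$id, roster$id)); diag(ones) <- 0
  triangle <- net_from_adjacency(ones, roster)
  expect_equal(igraph::ecount(triangle$graph), 3)
  expect_equal(network_density(triangle), 1)

  adj <- zero; adj["A", "B"] <- adj["B", "A"] <- 0.4
  adj["B", "C"] <- adj["C", "B"] <- 0.6
  thresholded <- net_from_adjacency(adj, roster, threshold = 0.5)
  expect_equal(igraph::ecount(thresholded$graph), 1)
  expect_error(build_network(adj, threshold = -1), "non-negative")
})

test_that("density and degree follow their definitions", {
  roster <- toy_roster(c("A", "B", "C"))
  adj <- matrix(0, 3, 3, dimnames = list(roster$id, roster$id))
  adj["A", "B"] <- adj["B", "A"] <- 0.2
  net <- net_from_adjacency(adj, roster)
  expect_equal(network_density(net), 1 / 3)
  expect_equal(degree_centrality(net), c(A = 1, B = 1, C = 0))

  # star: centre degree 3, leaves 1
  star <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  star[1, 2:4] <- star[2:4, 1] <- 0.5
  expect_equal(unname(degree_centrality(net_from_adjacency(star))), c(3, 1, 1, 1))
})

test_that("eigenvector centrality matches closed forms and is max-scaled", {
  complete <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(complete) <- 0
  expect_equal(unname(eigenvector_centrality(net_from_adjacency(complete))),
               rep(1, 4), tolerance = 1e-9)

  star <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  star[1, 2:4] <- star[2:4, 1] <- 1
  ev <- eigenvector_centrality(net_from_adjacency(star))
  expect_equal(unname(ev), c(1, rep(1 / sqrt(3), 3)), tolerance = 1e-9)

  # two disjoint cliques of unequal weight: the heavier one carries max 1
  two <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  two[1:3, 1:3] <- 0.9; two[4:6, 4:6] <- 0.3; diag(two) <- 0
  ev2 <- eigenvector_centrality(net_from_adjacency(two))
  expect_equal(max(ev2[1:3]), 1, tolerance = 1e-9)
  expect_lt(max(ev2[4:6]), 1e-6)

  edgeless <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(ev3 <- eigenvector_centrality(net_from_adjacency(edgeless)),
                 "no edges")
  expect_equal(unname(ev3), rep(0, 3))
})

test_that("betweenness uses SRI weights as geodesic edge lengths", {
  # path a-b-c: b lies on the single a..c geodesic
  path3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path3["a", "b"] <- path3["b", "a"] <- 0.1
  path3["b", "c"] <- path3["c", "b"] <- 0.2
  expect_equal(betweenness_centrality(net_from_adjacency(path3)),
               c(a = 0, b = 1, c = 0))

  complete <- matrix(0.4, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(complete) <- 0
  expect_equal(unname(betweenness_centrality(net_from_adjacency(complete))),
               rep(0, 5))

  # weighted geodesics differ between the sri and inverse conventions:
  # heavy direct edge vs light two-step detour
  tri <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tri["a", "c"] <- tri["c", "a"] <- 0.9
  tri["a", "b"] <- tri["b", "a"] <- 0.1
  tri["b", "c"] <- tri["c", "b"] <- 0.1
  net <- net_from_adjacency(tri)
  expect_equal(betweenness_centrality(net, "sri")[["b"]], 1)
  expect_equal(betweenness_centrality(net, "inverse")[["b"]], 0)
})

test_that("clustering coefficient counts neighbour ties", {
  triangle <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(triangle) <- 0
  expect_equal(unname(clustering_coefficient(net_from_adjacency(triangle))),
               rep(1, 3))

  star <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  star[1, 2:4] <- star[2:4, 1] <- 0.5
  cc <- clustering_coefficient(net_from_adjacency(star))
  expect_equal(cc[["a"]], 0)
  expect_true(all(is.nan(cc[2:4])))  # degree-1 nodes undefined
})

test_that("average path length enumerates weighted geodesics", {
  single <- matrix(0, 2, 2, dimnames = list(letters[1:2], letters[1:2]))
  single["a", "b"] <- single["b", "a"] <- 0.37
  expect_equal(average_path_length(net_from_adjacency(single))$mean, 0.37)

  path3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path3["a", "b"] <- path3["b", "a"] <- 0.1
  path3["b", "c"] <- path3["c", "b"] <- 0.2
  apl <- average_path_length(net_from_adjacency(path3))
  expect_equal(apl$mean, mean(c(0.1, 0.2, 0.3)))
  expect_equal(apl$n_pairs, 3)

  # two components: cross pairs excluded but counted
  two <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  two["a", "b"] <- two["b", "a"] <- 0.5
  two["c", "d"] <- two["d", "c"] <- 0.5
  apl2 <- average_path_length(net_from_adjacency(two))
  expect_equal(apl2$n_pairs, 2)
  expect_equal(apl2$n_unreachable, 4)

  # subset: pairs touching the subset only
  apl3 <- average_path_length(net_from_adjacency(path3), subset = "a")
  expect_equal(apl3$n_pairs, 2)
  expect_equal(apl3$mean, mean(c(0.1, 0.3)))
})

test_that("all metrics agree with brute-force oracles on random small graphs", {
  set.seed(2024)
  for (i in 1:150) {
    n <- sample(3:6, 1)
    adj <- random_adjacency(n)
    net <- net_from_adjacency(adj)
    expect_equal(network_density(net), bf_density(adj), tolerance = 1e-9)
    expect_equal(degree_centrality(net), bf_degree(adj), tolerance = 1e-9)
    expect_equal(betweenness_centrality(net), bf_betweenness(adj), tolerance = 1e-9)
    expect_equal(clustering_coefficient(net), bf_clustering(adj), tolerance = 1e-9)
    if (sum(adj) > 0) {
      expect_equal(eigenvector_centrality(net), bf_eigenvector(adj), tolerance = 1e-9)
      d <- bf_distances(adj)
      vals <- d[upper.tri(d)]
      if (any(is.finite(vals))) {
        expect_equal(average_path_length(net)$mean,
                     mean(vals[is.finite(vals)]), tolerance = 1e-9)
      }
    }
  }
})

test_that("node metrics respect the degree-density identity and weight rescaling", {
  set.seed(99)
  for (i in 1:20) {
    adj <- random_adjacency(sample(3:6, 1))
    net <- net_from_adjacency(adj)
    n <- nrow(adj)
    expect_equal(mean(degree_centrality(net)),
                 network_density(net) * (n - 1), tolerance = 1e-12)
    if (sum(adj) == 0) next
    scaled <- net_from_adjacency(adj * 0.5)
    expect_equal(degree_centrality(scaled), degree_centrality(net))
    expect_equal(clustering_coefficient(scaled), clustering_coefficient(net))
    expect_equal(network_density(scaled), network_density(net))
    expect_equal(eigenvector_centrality(scaled), eigenvector_centrality(net),
                 tolerance = 1e-6)
    expect_equal(average_path_length(scaled)$mean,
                 0.5 * average_path_length(net)$mean, tolerance = 1e-9)
  }
})

test_that("species_summary reports per-species means with sample SD", {
  metrics <- tibble::tibble(
    id = letters[1:3], species = c("s1", "s1", "s2"), sex = "F", group = "G",
    degree = c(1, 3, 2), eigenvector = c(1, 1, 1),
    betweenness = c(0, 0, 0), clustering = c(NaN, 0.5, 1)
  )
  s <- species_summary(metrics)
  expect_equal(s$degree_mean, c(2, 2))
  expect_equal(s$degree_sd, c(sd(c(1, 3)), NA_real_), tolerance = 1e-12)
  expect_equal(s$eigenvector_sd, c(0, NA_real_))
  # NaN clustering excluded from the mean
  expect_equal(s$clustering_mean[s$species == "s1"], 0.5)
})
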