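test_that("metrics match closed forms on canonical small graphs", {
  ## clustering
  expect_equal(clusteringCoefficient(completeAdjacency(3))$node, rep(1, 3))
  expect_equal(clusteringCoefficient(starAdjacency(5))$mean, 0)
  kite <- kiteAdjacency()
  expect_equal(clusteringCoefficient(kite)$node, c(1, 1, 1 / 3, 0))
  expect_equal(clusteringCoefficient(kite)$mean, 7 / 12)

  ## characteristic path length
  expect_equal(characteristicPathLength(completeAdjacency(6)), 1)
  expect_equal(characteristicPathLength(pathAdjacency(3)), 4 / 3)
  expect_equal(characteristicPathLength(ringAdjacency(5)), 1.5)
  expect_error(characteristicPathLength(matrix(0, 3, 3)), "disconnected")

  ## transitivity
  expect_equal(transitivityCoefficient(completeAdjacency(3)), 1)
  expect_equal(transitivityCoefficient(starAdjacency(4)), 0)
  expect_equal(transitivityCoefficient(kite), 0.6)
  expect_warning(t0 <- transitivityCoefficient(matrix(0, 3, 3)),
                 "no connected triples")
  expect_equal(t0, 0)

  ## global efficiency
  expect_equal(globalEfficiency(completeAdjacency(5)), 1)
  expect_equal(globalEfficiency(pathAdjacency(3)), 5 / 6)
  expect_equal(globalEfficiency(matrix(0, 2, 2)), 0)

  ## betweenness
  expect_equal(unname(betweennessCentrality(pathAdjacency(3))), c(0, 1, 0))
  expect_equal(unname(betweennessCentrality(starAdjacency(5))),
               c(6, 0, 0, 0, 0))  # (n-1)(n-2)/2 through the hub
  ## ring of 5: every node interior to exactly one shortest path
  expect_equal(unname(betweennessCentrality(ringAdjacency(5))), rep(1, 5))
})

test_that("metrics agree exactly with brute-force enumeration on random graphs", {
  set.seed(41)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    adj <- randomAdjacency(n, runif(1, 0.2, 0.9))
    expect_equal(clusteringCoefficient(adj)$node, bfClustering(adj),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(transitivityCoefficient(adj)),
                 bfTransitivity(adj), tolerance = 1e-12)
    expect_equal(globalEfficiency(adj), bfEfficiency(adj),
                 tolerance = 1e-12)
    expect_equal(unname(betweennessCentrality(adj)), bfBetweenness(adj),
                 tolerance = 1e-12)
    D <- bfDistances(adj)
    if (all(is.finite(D)))
      expect_equal(characteristicPathLength(adj), bfPathLength(adj),
                   tolerance = 1e-12)
  }
})

test_that("modularity matches exhaustive partition search and its own formula", {
  ## two disjoint triangles: best partition is the two components, Q = 0.5
  two <- adjFromEdgeList(6, list(c(1, 2), c(1, 3), c(2, 3),
                                 c(4, 5), c(4, 6), c(5, 6)))
  res <- modularityQ(two, seed = 3)
  expect_equal(res$Q, 0.5, tolerance = 1e-12)
  expect_equal(res$Q, bfBestModularity(two), tolerance = 1e-12)

  ## complete graph: no structure, Q = 0
  expect_equal(modularityQ(completeAdjacency(5), seed = 3)$Q, 0,
               tolerance = 1e-12)

  ## reported Q always equals the formula applied to the returned partition
  set.seed(43)
  for (i in 1:20) {
    adj <- randomAdjacency(sample(5:12, 1), 0.4)
    if (sum(adj) == 0) next
    res <- modularityQ(adj, seed = i)
    expect_equal(res$Q, partitionModularity(adj, res$partition),
                 tolerance = 1e-12)
  }
  expect_error(modularityQ(matrix(0, 4, 4)), "edgeless")
})

test_that("relabeling nodes permutes nodal outputs and fixes scalar metrics", {
  set.seed(47)
  adj <- randomAdjacency(9, 0.5)
  perm <- sample(9)
  padj <- adj[perm, perm]
  expect_equal(unname(betweennessCentrality(padj)),
               unname(betweennessCentrality(adj))[perm], tolerance = 1e-12)
  expect_equal(clusteringCoefficient(padj)$mean,
               clusteringCoefficient(adj)$mean, tolerance = 1e-12)
  expect_equal(suppressWarnings(transitivityCoefficient(padj)),
               suppressWarnings(transitivityCoefficient(adj)),
               tolerance = 1e-12)
  expect_equal(globalEfficiency(padj), globalEfficiency(adj),
               tolerance = 1e-12)
})

test_that("Maslov-Sneppen rewiring preserves the degree sequence exactly", {
  set.seed(53)
  for (i in 1:30) {
    n <- sample(8:25, 1)
    adj <- randomAdjacency(n, runif(1, 0.15, 0.6))
    if (sum(adj) < 4) next
    rw <- maslovSneppenRewire(adj, rewiresPerEdge = 10, seed = i)
    expect_identical(rowSums(rw), rowSums(adj))
    expect_true(all(diag(rw) == 0))
    expect_identical(rw, t(rw))
  }
  ## determinism under a fixed seed
  adj <- randomAdjacency(15, 0.4)
  expect_identical(maslovSneppenRewire(adj, 10, seed = 5),
                   maslovSneppenRewire(adj, 10, seed = 5))
  ## a ring is randomized away from a pure lattice while keeping degrees
  ring <- ringAdjacency(20)
  rw <- maslovSneppenRewire(ring, rewiresPerEdge = 10, seed = 2)
  expect_identical(unname(rowSums(rw)), rep(2, 20))
  expect_false(identical(rw, ring))
  ## graphs without a valid swap come back unchanged with a warning
  expect_warning(sw <- maslovSneppenRewire(starAdjacency(5), 10, seed = 1),
                 "unchanged")
  expect_identical(sw, starAdjacency(5))
  expect_warning(cw <- maslovSneppenRewire(completeAdjacency(5), 10, 1),
                 "unchanged")
  expect_identical(cw, completeAdjacency(5))
})

test_that("small-world normalization behaves at its limits", {
  ## a Watts-Strogatz-style construction is small-world: sigma > 1
  set.seed(59)
  ws <- igraph::as_adjacency_matrix(
    igraph::sample_smallworld(1, 86, 5, 0.1), sparse = FALSE)
  sw <- normalizedSmallWorld(ws, ensembleSize = 10, seed = 61)
  expect_gt(sw$sigma, 1)
  expect_gt(sw$gamma, 1)

  ## an already-random graph sits at the self-comparison limit
  er <- maslovSneppenRewire(ws, rewiresPerEdge = 20, seed = 67)
  swr <- normalizedSmallWorld(er, ensembleSize = 10, seed = 71)
  expect_lt(abs(swr$sigma - 1), 0.15)
  expect_error(normalizedSmallWorld(rbind(cbind(completeAdjacency(3), 0),
                                          0), seed = 1),
               "connected")
})
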