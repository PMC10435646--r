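residualExperimentFrom <- function(mat, group) {
  cat <- toyCatalogue(ncol(mat))
  colnames(mat) <- cat$label
  rownames(mat) <- sprintf("s%02d", seq_len(nrow(mat)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(residuals = t(mat)),
    rowData = S4Vectors::DataFrame(cat, row.names = cat$label),
    colData = S4Vectors::DataFrame(
      group = group, age = seq_len(nrow(mat)), icv = 1.5e6,
      row.names = rownames(mat)))
  new("ResidualExperiment", se)
}

test_that("association matrix is Pearson correlation with negatives zeroed", {
  a <- c(-0.1, 0.3, -0.3, 0.1)
  m <- cbind(a, 2 * a, -2 * a, c(0.5, -0.5, 0.5, -0.5))
  res <- residualExperimentFrom(m, rep("A", 4))
  R <- associationMatrix(res, "A")
  r <- assocValues(R)
  expect_equal(r[1, 2], 1.0)            # proportional columns
  expect_equal(r[1, 3], 0.0)            # raw r = -1, zeroed
  expect_equal(r[2, 3], 0.0)
  expect_true(all(r[upper.tri(r)] >= 0))
  expect_equal(unname(r[upper.tri(r)]),
               unname(pmax(cor(m)[upper.tri(r)], 0)), tolerance = 1e-12)

  ## zero-variance region: zeroed correlations plus a warning
  m2 <- cbind(m, 1)
  res2 <- residualExperimentFrom(m2, rep("A", 4))
  expect_warning(R2 <- associationMatrix(res2, "A"), "zero-variance")
  expect_equal(max(assocValues(R2)[5, -5]), 0)

  expect_error(associationMatrix(res, "B"), "fewer than 3")
})

test_that("binarization hits the exact density with the sort-and-cut edges", {
  vals <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  R <- toyAssociation(symmetricFromUpper(4, vals))
  A <- binarizeAtDensity(R, 0.5)
  expect_equal(networkDensity(A), 0.5)
  adj <- adjacency(A)
  expect_equal(adj[1, 2], 1)  # 0.9
  expect_equal(adj[1, 3], 1)  # 0.8
  expect_equal(adj[1, 4], 1)  # 0.7
  expect_equal(sum(adj) / 2, 3)

  ## d = 1 on an all-positive matrix: complete graph
  Rfull <- toyAssociation(symmetricFromUpper(4, rep(0.5, 6)))
  expect_equal(networkDensity(binarizeAtDensity(Rfull, 1)), 1)

  ## infeasible density names the achievable maximum
  Rneg <- toyAssociation(symmetricFromUpper(4, c(0.9, 0.8, 0, 0, 0, 0)))
  expect_error(binarizeAtDensity(Rneg, 0.9), "maximum achievable")
})

test_that("exact-density contract and monotone nesting hold on random draws", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    P <- n * (n - 1) / 2
    R <- toyAssociation(symmetricFromUpper(n, runif(P, 0.01, 1)))
    ds <- sort(runif(3, 0.05, 1))
    prev <- NULL
    for (d in ds) {
      A <- binarizeAtDensity(R, d)
      adj <- adjacency(A)
      expect_identical(adj, t(adj))
      expect_equal(sum(diag(adj)), 0)
      expect_equal(networkDensity(A), round(d * P) / P)
      if (!is.null(prev)) expect_true(all(adj[prev == 1] == 1))
      prev <- adj
    }
  }
})

test_that("tied correlations are broken deterministically and reproducibly", {
  R <- toyAssociation(symmetricFromUpper(4, rep(0.5, 6)))
  A1 <- binarizeAtDensity(R, 0.5)
  A2 <- binarizeAtDensity(R, 0.5)
  expect_identical(adjacency(A1), adjacency(A2))
  ## lexicographically first pairs win: (1,2), (1,3), (1,4)
  expect_equal(unname(rowSums(adjacency(A1))), c(3, 1, 1, 1))
})

test_that("minimum density finds the connection threshold of a planted chain", {
  ## 5 regions, chain correlations strictly largest: connects at 4/10 edges
  vals <- rep(0.1, 10)
  chainPairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5))
  m <- matrix(0.1, 5, 5)
  m[chainPairs] <- 0.9; m[chainPairs[, 2:1]] <- 0.9
  diag(m) <- 1
  R <- toyAssociation(m)
  expect_equal(minimumDensity(R, step = 0.1), 0.4)
  ## connectivity criterion agrees with brute-force BFS reachability
  A <- binarizeAtDensity(R, 0.4)
  expect_true(all(is.finite(bfDistances(adjacency(A)))))
  A3 <- binarizeAtDensity(R, 0.3)
  expect_false(all(is.finite(bfDistances(adjacency(A3)))))

  ## shared across groups: the max of per-group minima
  RB <- toyAssociation(symmetricFromUpper(5, c(
    0.9, 0.1, 0.1, 0.8, 0.1, 0.1, 0.85, 0.1, 0.1, 0.7)))
  dA <- minimumDensity(R, step = 0.1)
  dB <- minimumDensity(RB, step = 0.1)
  expect_equal(minimumDensity(list(R, RB), step = 0.1), max(dA, dB))

  ## no-isolates criterion is weaker than connectedness
  expect_lte(minimumDensity(R, step = 0.1, criterion = "no_isolates"),
             minimumDensity(R, step = 0.1))
})

test_that("connectivity check agrees with brute-force BFS on random graphs", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    adj <- randomAdjacency(n, runif(1, 0.1, 0.8))
    expect_equal(scnet:::.isConnectedAdj(adj),
                 all(is.finite(bfDistances(adj))))
  }
})

test_that("network density reports edge fraction", {
  expect_equal(networkDensity(toyNetwork(completeAdjacency(4))), 1)
  expect_equal(networkDensity(toyNetwork(pathAdjacency(4))), 0.5)
  expect_equal(networkDensity(toyNetwork(matrix(0, 4, 4))), 0)
})

test_that("density grid and export formats are well-formed", {
  expect_equal(densityGrid(0.24, 0.44, 0.01), seq(0.24, 0.44, by = 0.01))
  A <- toyNetwork(pathAdjacency(4))
  dir <- withr::local_tempdir()
  ep <- writeEdgeList(A, file.path(dir, "edges.tsv"))
  el <- read.delim(ep)
  expect_equal(nrow(el), 3L)
  gp <- writeGraphML(A, file.path(dir, "net.graphml"))
  g <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::ecount(g), 3)
  expect_equal(igraph::vcount(g), 4)
})
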