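## Brute-force graph oracles, deliberately independent of the package's
## implementations: Floyd-Warshall distances, direct triangle/triple
## enumeration, all-simple-path betweenness, and exhaustive partition
## search for modularity. Only usable on small graphs.

randomAdjacency <- function(n, p = 0.4) {
  adj <- matrix(0, n, n)
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  on <- runif(nrow(pairs)) < p
  adj[pairs[on, , drop = FALSE]] <- 1
  adj + t(adj)
}

adjFromEdgeList <- function(n, edges) {
  adj <- matrix(0, n, n)
  for (e in edges) { adj[e[1], e[2]] <- 1; adj[e[2], e[1]] <- 1 }
  adj
}

pathAdjacency <- function(n)
  adjFromEdgeList(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))

ringAdjacency <- function(n)
  adjFromEdgeList(n, c(lapply(seq_len(n - 1), function(i) c(i, i + 1)),
                       list(c(n, 1))))

starAdjacency <- function(n)
  adjFromEdgeList(n, lapply(seq_len(n - 1) + 1, function(i) c(1, i)))

completeAdjacency <- function(n) {
  adj <- matrix(1, n, n); diag(adj) <- 0; adj
}

## triangle {1,2,3} with pendant node 4 attached to node 3
kiteAdjacency <- function()
  adjFromEdgeList(4, list(c(1, 2), c(1, 3), c(2, 3), c(3, 4)))

bfDistances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

bfPathLength <- function(adj) {
  d <- bfDistances(adj)[upper.tri(adj)]
  mean(d)
}

bfEfficiency <- function(adj) {
  d <- bfDistances(adj)[upper.tri(adj)]
  if (!length(d)) return(0)
  mean(1 / d)
}

bfClustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nbrs <- which(adj[v, ] == 1)
    k <- length(nbrs)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      links <- links + adj[nbrs[a], nbrs[b]]
    2 * links / (k * (k - 1))
  }, numeric(1))
}

bfTransitivity <- function(adj) {
  n <- nrow(adj)
  triangles <- 0; triples <- 0
  for (v in seq_len(n)) {
    nbrs <- which(adj[v, ] == 1)
    k <- length(nbrs)
    if (k < 2) next
    triples <- triples + k * (k - 1) / 2
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      triangles <- triangles + adj[nbrs[a], nbrs[b]]
  }
  ## each triangle counted once per corner => triangles var holds 3T
  if (triples == 0) 0 else triangles / triples
}

## betweenness by enumerating every simple shortest path
bfBetweenness <- function(adj) {
  n <- nrow(adj)
  D <- bfDistances(adj)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || D[s, t] < 2) next
    paths <- list()
    recur <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        if (length(path) == D[s, t] + 1)
          paths[[length(paths) + 1]] <<- path
        return()
      }
      if (length(path) > D[s, t]) return()
      for (v in which(adj[last, ] == 1))
        if (!(v %in% path)) recur(c(path, v))
    }
    recur(s)
    sigma <- length(paths)
    for (pth in paths)
      for (v in pth[-c(1, length(pth))]) bc[v] <- bc[v] + 1 / sigma
  }
  bc
}

## exhaustive best-partition modularity by restricted-growth enumeration
bfBestModularity <- function(adj) {
  n <- nrow(adj)
  best <- -Inf
  recur <- function(assign, maxC) {
    i <- length(assign) + 1
    if (i > n) {
      q <- partitionModularity(adj, assign)
      if (q > best) best <<- q
      return()
    }
    for (c in seq_len(maxC + 1))
      recur(c(assign, c), max(maxC, c))
  }
  recur(integer(0), 0L)
  best
}

## Brute-force Benjamini-Hochberg step-up
bfBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

## small helpers to lift plain adjacency matrices into package classes
toyCatalogue <- function(n) {
  data.frame(label = sprintf("region%02d", seq_len(n)),
             hemisphere = rep(c("left", "right"), length.out = n),
             lobe = "frontal", measure_kind = "thickness",
             stringsAsFactors = FALSE)
}

toyAssociation <- function(r, group = "A", nSubjects = 10L) {
  new("AssociationMatrix", r = r, catalogue = toyCatalogue(nrow(r)),
      group = group, nSubjects = nSubjects)
}

toyNetwork <- function(adj) {
  p <- nrow(adj) * (nrow(adj) - 1) / 2
  new("BinaryNetwork", adjacency = adj,
      density = sum(adj[upper.tri(adj)]) / p, catalogue = toyCatalogue(nrow(adj)))
}

## symmetric matrix with given upper-triangle values (lexicographic order)
symmetricFromUpper <- function(n, vals) {
  m <- matrix(0, n, n)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  m[pairs] <- vals
  m <- m + t(m)
  diag(m) <- 1
  m
}
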