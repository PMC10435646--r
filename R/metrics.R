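## Binary undirected graph metrics and degree-preserving null normalization.
## Graph primitives (shortest paths, betweenness, triangle counts, Louvain
## communities) are delegated to igraph behind this module's surface.

.asIgraph <- function(A) {
  adj <- .asAdjacency(A)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

## All-pairs shortest-path hop counts (BFS from every source, compiled).
.adjDistances <- function(adj) .cppBfsDistances(adj)

#' Local clustering coefficient
#'
#' Watts-Strogatz clustering: per node, the fraction of possible links
#' among its neighbours that exist, 2 t(v) / (k(v)(k(v)-1)); nodes with
#' degree < 2 score 0. The mean is taken over all nodes (degree-<2 nodes
#' included as 0).
#'
#' @param A a \linkS4class{BinaryNetwork} or adjacency matrix
#' @return list with \code{node} (per-node vector) and \code{mean}
#' @export
clusteringCoefficient <- function(A) {
  adj <- .asAdjacency(A)
  k <- rowSums(adj)
  twoTriangles <- rowSums((adj %*% adj) * adj)  # diag(A^3) = 2 t(v)
  cc <- ifelse(k < 2, 0, twoTriangles / (k * (k - 1)))
  names(cc) <- rownames(adj)
  list(node = cc, mean = mean(cc))
}

#' Characteristic path length
#'
#' Mean shortest-path length (in hops) over all unordered node pairs. The
#' analyzed density range guarantees connected networks; by default a
#' disconnected input is an error. \code{mode = "exclude_infinite"}
#' averages over reachable pairs only, for exploratory use.
#'
#' @param A a \linkS4class{BinaryNetwork} or adjacency matrix
#' @param mode "error" (default) or "exclude_infinite"
#' @export
characteristicPathLength <- function(A, mode = c("error",
                                                 "exclude_infinite")) {
  mode <- match.arg(mode)
  d <- .adjDistances(.asAdjacency(A))
  dd <- d[upper.tri(d)]
  if (any(is.infinite(dd))) {
    if (mode == "error")
      stop("network is disconnected; characteristic path length undefined")
    dd <- dd[is.finite(dd)]
    if (!length(dd)) return(NaN)
  }
  mean(dd)
}

#' Transitivity (whole-graph clustering)
#'
#' 3 x triangles / connected triples. Returns 0 with a warning when the
#' graph has no connected triple.
#'
#' @param A a \linkS4class{BinaryNetwork} or adjacency matrix
#' @export
transitivityCoefficient <- function(A) {
  adj <- .asAdjacency(A)
  k <- rowSums(adj)
  triples2 <- sum(k * (k - 1))             # 2 x connected triples
  if (triples2 == 0) {
    warning("no connected triples; transitivity set to 0")
    return(0)
  }
  traceA3 <- sum((adj %*% adj) * adj)      # 6 x triangles
  traceA3 / triples2                       # = 3 triangles / triples
}

#' Modularity of the best community partition found
#'
#' Newman modularity Q of the partition found by seeded Louvain community
#' detection. Deterministic given the seed.
#'
#' @param A a \linkS4class{BinaryNetwork} or adjacency matrix
#' @param seed RNG seed for the community search
#' @return list with \code{Q} and \code{partition} (integer membership)
#' @export
modularityQ <- function(A, seed = 1L) {
  g <- .asIgraph(A)
  if (igraph::ecount(g) == 0L) stop("modularity is undefined on an edgeless graph")
  cl <- withSeed(seed, igraph::cluster_louvain(g))
  memb <- igraph::membership(cl)
  list(Q = igraph::modularity(g, memb), partition = as.integer(memb))
}

#' Modularity of a given partition
#'
#' Q = sum_c [ e_c/m - (d_c/2m)^2 ]; used to check internal consistency of
#' \code{\link{modularityQ}} and to score external partitions.
#'
#' @param A a \linkS4class{BinaryNetwork} or adjacency matrix
#' @param partition integer community membership per node
#' @export
partitionModularity <- function(A, partition) {
  adj <- .asAdjacency(A)
  m <- sum(adj) / 2
  if (m == 0) stop("modularity is undefined on an edgeless graph")
  q <- 0
  for (c in unique(partition)) {
    keep <- partition == c
    ec <- sum(adj[keep, keep, drop = FALSE]) / 2
    dc <- sum(adj[keep, , drop = FALSE])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over unordered pairs; unreachable
#' pairs contribute 0, so the measure is defined on fragmented graphs.
#'
#' @param A a \linkS4class{BinaryNetwork} or adjacency matrix
#' @export
globalEfficiency <- function(A) {
  d <- .adjDistances(.asAdjacency(A))
  dd <- d[upper.tri(d)]
  if (!length(dd)) return(0)
  mean(1 / dd)
}

#' Nodal betweenness centrality
#'
#' BC(v) = sum over unordered pairs s != v != t of the fraction of shortest
#' s-t paths passing through v (Brandes accumulation via igraph). Reported
#' unnormalized; hub detection standardizes within network, so the
#' normalization convention cannot change hub calls.
#'
#' @param A a \linkS4class{BinaryNetwork} or adjacency matrix
#' @return per-node numeric vector
#' @export
betweennessCentrality <- function(A) {
  adj <- .asAdjacency(A)
  bc <- .cppBetweenness(adj)
  names(bc) <- rownames(adj)
  bc
}

#' Degree-preserving Maslov-Sneppen rewiring
#'
#' Randomizes a binary undirected network by repeated double-edge swaps,
#' rejecting swaps that would create self-loops or multi-edges, so the full
#' degree sequence is preserved exactly. \code{rewiresPerEdge * |E|} swaps
#' are attempted. If no swap succeeds (e.g. a star or complete graph has no
#' valid swap) the input is returned unchanged with a warning.
#'
#' @param A a \linkS4class{BinaryNetwork} or adjacency matrix
#' @param rewiresPerEdge attempted swaps per edge, default 10
#' @param seed RNG seed; identical seeds give identical rewirings
#' @return rewired object of the same class as the input
#' @export
maslovSneppenRewire <- function(A, rewiresPerEdge = 10, seed = 1L) {
  adj <- .asAdjacency(A)
  pairs <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  m <- nrow(pairs)
  if (m < 2L) stop("at least 2 edges are required for rewiring")
  attempts <- as.integer(rewiresPerEdge * m)
  successes <- 0L
  withSeed(seed, {
    i1 <- sample.int(m, attempts, replace = TRUE)
    i2 <- sample.int(m, attempts, replace = TRUE)
    flip <- sample(c(TRUE, FALSE), attempts, replace = TRUE)
    for (t in seq_len(attempts)) {
      e1 <- i1[t]; e2 <- i2[t]
      if (e1 == e2) next
      a <- pairs[e1, 1L]; b <- pairs[e1, 2L]
      c <- pairs[e2, 1L]; d <- pairs[e2, 2L]
      if (flip[t]) { tmp <- c; c <- d; d <- tmp }
      ## propose (a,d) and (c,b)
      if (a == d || c == b) next
      if (adj[a, d] == 1 || adj[c, b] == 1) next
      adj[a, b] <- 0; adj[b, a] <- 0; adj[c, d] <- 0; adj[d, c] <- 0
      adj[a, d] <- 1; adj[d, a] <- 1; adj[c, b] <- 1; adj[b, c] <- 1
      pairs[e1, ] <- c(min(a, d), max(a, d))
      pairs[e2, ] <- c(min(c, b), max(c, b))
      successes <- successes + 1L
    }
  })
  if (successes == 0L)
    warning("no valid double-edge swap found; returning input unchanged")
  if (is(A, "BinaryNetwork"))
    methods::new("BinaryNetwork", adjacency = adj, density = A@density,
                 catalogue = A@catalogue)
  else adj
}

#' Small-world metrics normalized against a rewired null ensemble
#'
#' gamma = C / <C_rand> and lambda = L / <L_rand> where the angle brackets
#' average over an ensemble of degree-preserving Maslov-Sneppen rewirings
#' of the network itself (matched nodes, edges and degree distribution);
#' sigma = gamma / lambda is the small-world index. A small-world network
#' has sigma > 1: clustering well above random at near-random path length.
#' Disconnected nulls are rejected and resampled (up to 10x the ensemble
#' size in total attempts) so L is always finite in the ensemble mean.
#'
#' @param A a connected \linkS4class{BinaryNetwork} or adjacency matrix
#' @param ensembleSize number of null networks, default 20
#' @param rewiresPerEdge attempted swaps per edge in each null, default 10
#' @param seed RNG seed
#' @return list with gamma, lambda, sigma, C, L, ensemble C/L vectors,
#'   rejected-null count and provenance fields (ensembleSize,
#'   rewiresPerEdge, seed)
#' @export
normalizedSmallWorld <- function(A, ensembleSize = 20, rewiresPerEdge = 10,
                                 seed = 1L) {
  adj <- .asAdjacency(A)
  if (!.isConnectedAdj(adj))
    stop("network must be connected for small-world normalization")
  C <- clusteringCoefficient(adj)$mean
  L <- characteristicPathLength(adj)
  Cs <- numeric(0); Ls <- numeric(0)
  rejected <- 0L
  attempt <- 0L
  maxAttempts <- 10L * ensembleSize
  while (length(Cs) < ensembleSize) {
    attempt <- attempt + 1L
    if (attempt > maxAttempts)
      stop("null-ensemble exhaustion: ", rejected,
           " disconnected nulls in ", maxAttempts, " attempts")
    nullAdj <- maslovSneppenRewire(adj, rewiresPerEdge,
                                   seed = deriveSeed(seed, attempt))
    if (!.isConnectedAdj(nullAdj)) { rejected <- rejected + 1L; next }
    Cs <- c(Cs, clusteringCoefficient(nullAdj)$mean)
    Ls <- c(Ls, characteristicPathLength(nullAdj))
  }
  gamma <- C / mean(Cs)
  lambda <- L / mean(Ls)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       C = C, L = L, ensembleC = Cs, ensembleL = Ls,
       rejectedNulls = rejected, ensembleSize = as.integer(ensembleSize),
       rewiresPerEdge = rewiresPerEdge, seed = as.integer(seed))
}

#' All global metrics of one network
#'
#' Convenience wrapper returning the full metric set at the network's
#' density: mean clustering C, characteristic path length L, transitivity
#' T, modularity Q, global efficiency Eglob, and the per-node betweenness
#' vector.
#'
#' @param A a \linkS4class{BinaryNetwork} or adjacency matrix
#' @param seed seed for the community search in Q
#' @export
metricSet <- function(A, seed = 1L) {
  list(clustering_mean = clusteringCoefficient(A)$mean,
       path_length = characteristicPathLength(A, mode = "exclude_infinite"),
       transitivity = transitivityCoefficient(A),
       modularity = modularityQ(A, seed = seed)$Q,
       global_efficiency = globalEfficiency(A),
       betweenness = betweennessCentrality(A),
       density = networkDensity(A))
}

## Scalar metric dispatcher used by the permutation engine. Returns NA
## where the metric is undefined for the replicate (e.g. path length on a
## fragmented permuted network) so the caller can apply its skip policy.
.globalMetricValue <- function(adj, metric, seed = 1L) {
  switch(metric,
    clustering_mean = clusteringCoefficient(adj)$mean,
    path_length = {
      dd <- .adjDistances(adj)[upper.tri(adj)]
      if (any(is.infinite(dd))) NA_real_ else mean(dd)
    },
    transitivity = suppressWarnings(transitivityCoefficient(adj)),
    modularity = if (sum(adj) > 0) modularityQ(adj, seed = seed)$Q
      else NA_real_,
    global_efficiency = globalEfficiency(adj),
    stop("unknown metric: ", metric))
}

.globalMetricNames <- c("clustering_mean", "path_length", "transitivity",
                        "modularity", "global_efficiency")
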