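## Ranked edge order of an association matrix: node pairs (i < j,
## lexicographic) sorted by decreasing correlation, ties broken by the
## lexicographic pair order itself. Shared by binarization, density scans
## and the permutation engine so edge sets nest monotonically in density.
.edgeOrder <- function(r) {
  n <- nrow(r)
  pairs <- nodePairs(n)
  vals <- r[pairs]
  ord <- order(-vals, seq_along(vals))
  list(pairs = pairs[ord, , drop = FALSE], vals = vals[ord],
       nPositive = sum(vals > 0), P = nrow(pairs), n = n)
}

.adjFromEdges <- function(eo, K) {
  adj <- matrix(0, eo$n, eo$n)
  if (K > 0) {
    sel <- eo$pairs[seq_len(K), , drop = FALSE]
    adj[sel] <- 1
    adj[sel[, c(2L, 1L), drop = FALSE]] <- 1
  }
  adj
}

#' Group-level association matrix from residuals
#'
#' Computes, for one group, the Pearson correlation between the
#' age-residualized values of every pair of regions across that group's
#' subjects, then replaces negative correlations by zero. Regions whose
#' residuals have zero variance get all-zero correlations with a warning,
#' so degenerate synthetic cases and permutation replicates do not abort.
#'
#' @param res a \linkS4class{ResidualExperiment}
#' @param group group label to subset subjects by
#' @return \linkS4class{AssociationMatrix}
#' @export
associationMatrix <- function(res, group) {
  stopifnot(is(res, "ResidualExperiment"))
  covs <- subjectInfo(res)
  keep <- covs$group == group
  if (sum(keep) < 3L) stop("fewer than 3 subjects in group ", group)
  m <- t(SummarizedExperiment::assay(res, "residuals"))[keep, , drop = FALSE]
  r <- .zeroedCorrelation(m)
  methods::new("AssociationMatrix", r = r,
               catalogue = regionCatalogue(res),
               group = as.character(group), nSubjects = sum(keep))
}

## Pearson correlation with zero-variance guard and negative zeroing;
## the raw numeric core used by both the public constructor and the
## permutation engine.
.zeroedCorrelation <- function(m, warnDegenerate = TRUE) {
  sds <- apply(m, 2L, sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  r <- suppressWarnings(cor(m))
  if (length(degenerate)) {
    if (warnDegenerate)
      warning("zero-variance residual column(s): ",
              paste(colnames(m)[degenerate], collapse = ", "),
              "; their correlations are set to 0")
    r[degenerate, ] <- 0
    r[, degenerate] <- 0
  }
  r[r < 0] <- 0
  diag(r) <- 1
  r
}

#' Threshold an association matrix to an exact edge density
#'
#' Keeps the K = round(d * P) largest off-diagonal correlations as edges,
#' P = N(N-1)/2, so the achieved density is exactly K/P. Ties at the cutoff
#' are broken deterministically (higher correlation first, then the
#' lexicographically smaller region-index pair), which also makes edge sets
#' nest monotonically across densities.
#'
#' @param R an \linkS4class{AssociationMatrix}
#' @param d target density in (0, 1]
#' @return \linkS4class{BinaryNetwork}
#' @export
binarizeAtDensity <- function(R, d) {
  stopifnot(is(R, "AssociationMatrix"), d > 0, d <= 1)
  eo <- .edgeOrder(R@r)
  K <- round(d * eo$P)
  if (K > eo$nPositive)
    stop(sprintf(paste0("only %d positive correlations available; maximum ",
                        "achievable density is %.4f"),
                 eo$nPositive, eo$nPositive / eo$P))
  adj <- .adjFromEdges(eo, K)
  dimnames(adj) <- list(R@catalogue$label, R@catalogue$label)
  methods::new("BinaryNetwork", adjacency = adj, density = K / eo$P,
               catalogue = R@catalogue)
}

#' Edge density of a binary network
#'
#' Fraction of realized connections out of all potential connections
#' N(N-1)/2.
#'
#' @param A a \linkS4class{BinaryNetwork} or a square 0/1 adjacency matrix
#' @export
networkDensity <- function(A) {
  adj <- .asAdjacency(A)
  n <- nrow(adj)
  if (n < 2L) return(0)
  sum(adj[upper.tri(adj)]) / (n * (n - 1) / 2)
}

.asAdjacency <- function(A) {
  if (is(A, "BinaryNetwork")) A@adjacency
  else if (is.matrix(A)) A
  else stop("expected a BinaryNetwork or adjacency matrix")
}

.isConnectedAdj <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(TRUE)
  ## vectorized BFS reachability from node 1
  reached <- c(TRUE, rep(FALSE, n - 1L))
  frontier <- reached
  while (any(frontier)) {
    nxt <- (colSums(adj[frontier, , drop = FALSE]) > 0) & !reached
    reached <- reached | nxt
    frontier <- nxt
  }
  all(reached)
}

.passesCriterion <- function(adj, criterion) {
  if (criterion == "connected") .isConnectedAdj(adj)
  else all(colSums(adj) > 0)
}

#' Minimum analyzable density across groups
#'
#' Scans the density grid {step, 2*step, ..., 1} from below and returns the
#' smallest density at which every group's thresholded network is not
#' fragmented. The default criterion demands a single connected component
#' (so characteristic path length is defined); the weaker
#' \code{"no_isolates"} criterion only demands that every node has at least
#' one connection. The returned value is shared across groups (the maximum
#' of the per-group minima).
#'
#' @param Rs an \linkS4class{AssociationMatrix} or a list of them (one per
#'   group)
#' @param step grid step, default 0.01
#' @param criterion "connected" (default) or "no_isolates"
#' @return smallest feasible grid density
#' @export
minimumDensity <- function(Rs, step = 0.01,
                           criterion = c("connected", "no_isolates")) {
  criterion <- match.arg(criterion)
  if (is(Rs, "AssociationMatrix")) Rs <- list(Rs)
  stopifnot(length(Rs) >= 1L, step > 0)
  eos <- lapply(Rs, function(R) .edgeOrder(R@r))
  grid <- round(seq(step, 1, by = step), 10)
  for (d in grid) {
    ok <- vapply(eos, function(eo) {
      K <- round(d * eo$P)
      K <= eo$nPositive && .passesCriterion(.adjFromEdges(eo, K), criterion)
    }, logical(1))
    if (all(ok)) return(d)
  }
  stop("no density on the grid yields ", criterion, " networks for all groups")
}

#' Maximum analyzable density across groups
#'
#' Upper bound of the analyzed density range. Under the default
#' \code{"sigma_threshold"} rule, densities are scanned upward from
#' \code{dMin} and the largest grid density is returned at which the
#' small-world index sigma of every group's network still exceeds
#' \code{sigmaThreshold} (above it, networks become increasingly random and
#' edges are unlikely to be biologically meaningful). A \code{"fixed"} rule
#' returns \code{fixedValue} unchanged.
#'
#' @param Rs an \linkS4class{AssociationMatrix} or list of them
#' @param dMin lower bound of the scan (e.g. from
#'   \code{\link{minimumDensity}})
#' @param step grid step, default 0.01
#' @param rule "sigma_threshold" (default) or "fixed"
#' @param sigmaThreshold sigma cutoff, default 1.5
#' @param fixedValue density returned under the "fixed" rule
#' @param ensembleSize,rewiresPerEdge,seed null-ensemble settings passed to
#'   \code{\link{normalizedSmallWorld}}
#' @return largest analyzable grid density (at least dMin)
#' @export
maximumDensity <- function(Rs, dMin, step = 0.01,
                           rule = c("sigma_threshold", "fixed"),
                           sigmaThreshold = 1.5, fixedValue = 0.44,
                           ensembleSize = 20, rewiresPerEdge = 10,
                           seed = 1L) {
  rule <- match.arg(rule)
  if (rule == "fixed") return(fixedValue)
  if (is(Rs, "AssociationMatrix")) Rs <- list(Rs)
  grid <- round(seq(dMin, 1, by = step), 10)
  dMax <- dMin
  for (d in grid) {
    sigmas <- vapply(seq_along(Rs), function(i) {
      A <- tryCatch(binarizeAtDensity(Rs[[i]], d), error = function(e) NULL)
      if (is.null(A) || !.isConnectedAdj(A@adjacency)) return(NA_real_)
      normalizedSmallWorld(A, ensembleSize = ensembleSize,
                           rewiresPerEdge = rewiresPerEdge,
                           seed = deriveSeed(seed, i))$sigma
    }, numeric(1))
    if (anyNA(sigmas) || any(sigmas < sigmaThreshold)) break
    dMax <- d
  }
  dMax
}

#' Density grid between bounds
#'
#' @param dMin,dMax density bounds
#' @param step grid step
#' @return ordered vector dMin, dMin + step, ..., <= dMax
#' @export
densityGrid <- function(dMin, dMax, step = 0.01) {
  stopifnot(dMin > 0, dMin <= dMax, dMax <= 1, step > 0)
  round(seq(dMin, dMax + 1e-9, by = step), 10)
}

## ---- export helpers ----

#' Write a binary network as GraphML
#' @param A a \linkS4class{BinaryNetwork}
#' @param path output path
#' @export
writeGraphML <- function(A, path) {
  g <- .asIgraph(A)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a binary network as a labeled edge list
#' @param A a \linkS4class{BinaryNetwork}
#' @param path output TSV path
#' @export
writeEdgeList <- function(A, path) {
  adj <- .asAdjacency(A)
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  labs <- rownames(adj) %||% as.character(seq_len(nrow(adj)))
  write.table(data.frame(from = labs[idx[, 1]], to = labs[idx[, 2]]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association matrix as labeled CSV
#' @param R an \linkS4class{AssociationMatrix}
#' @param path output path
#' @export
writeAssociationCSV <- function(R, path) {
  m <- R@r
  dimnames(m) <- list(R@catalogue$label, R@catalogue$label)
  write.csv(m, path, quote = TRUE)
  invisible(path)
}
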