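#' Identify hub regions from betweenness centrality
#'
#' A region is a hub when its nodal betweenness centrality lies 1 SD
#' (liberal) or 2 SDs (strict) above the network mean. Betweenness is
#' standardized within the network, z(v) = (BC(v) - mean BC) / SD BC, so
#' the betweenness normalization convention cannot affect hub calls. The
#' SD uses the population (n) denominator by default; the sample (n-1)
#' denominator is a logged switch.
#'
#' @param bc per-node betweenness vector (named by region label), e.g. from
#'   \code{\link{betweennessCentrality}}
#' @param catalogue optional region catalogue supplying lobes
#' @param sdType "population" (default) or "sample" SD denominator
#' @return data.frame with columns region, lobe, betweenness, z, hub_1sd,
#'   hub_2sd; attribute \code{sdType} records the denominator used
#' @export
identifyHubs <- function(bc, catalogue = NULL,
                         sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  if (length(bc) < 2L) stop("at least 2 nodes are required")
  mu <- mean(bc)
  sdv <- if (sdType == "population") sqrt(mean((bc - mu)^2)) else sd(bc)
  if (sdv == 0) {
    warning("betweenness has zero SD; no hubs can be identified")
    z <- rep(0, length(bc))
  } else z <- (bc - mu) / sdv
  labels <- names(bc) %||% as.character(seq_along(bc))
  lobe <- if (!is.null(catalogue))
    catalogue$lobe[match(labels, catalogue$label)] else NA_character_
  out <- data.frame(region = labels, lobe = lobe, betweenness = as.numeric(bc),
                    z = as.numeric(z), hub_1sd = z > 1, hub_2sd = z > 2,
                    stringsAsFactors = FALSE)
  attr(out, "sdType") <- sdType
  out
}

## Shared permutation machinery ------------------------------------------

## Permutation shuffles derived once from the seed, independent of group
## labels, so global and regional tests with the same seed share the same
## reallocation scheme (required for maximal-statistic correction).
.permIndices <- function(n, nPerm, seed) {
  withSeed(seed, vapply(seq_len(nPerm), function(i) sample.int(n),
                        integer(n)))
}

.residualMatrix <- function(res) {
  stopifnot(is(res, "ResidualExperiment"))
  t(SummarizedExperiment::assay(res, "residuals"))  # subjects x regions
}

## Scalar metric difference (groups[1] - groups[2]) at each density, NA
## where the metric is undefined for a replicate. The four distance/
## triangle metrics run through the compiled nested-density kernel;
## modularity needs the community search and stays on the R path.
.metricDiff <- function(m, labels, groups, densities, metric, seed) {
  cppCol <- match(metric, c("clustering_mean", "path_length",
                            "transitivity", "global_efficiency"))
  vals <- vapply(groups, function(g) {
    r <- .zeroedCorrelation(m[labels == g, , drop = FALSE],
                            warnDegenerate = FALSE)
    eo <- .edgeOrder(r)
    Ks <- as.integer(round(densities * eo$P))
    feasible <- Ks <= eo$nPositive
    out <- rep(NA_real_, length(Ks))
    if (!any(feasible)) return(out)
    if (is.na(cppCol)) {
      out[feasible] <- vapply(Ks[feasible], function(K)
        .globalMetricValue(.adjFromEdges(eo, K), metric, seed), numeric(1))
    } else {
      out[feasible] <- .cppDensityMetrics(eo$pairs, Ks[feasible],
                                          eo$n)[, cppCol]
    }
    out
  }, numeric(length(densities)))
  vals <- matrix(vals, nrow = length(densities))
  vals[, 1L] - vals[, 2L]
}

.betweennessDiff <- function(m, labels, groups, density) {
  vals <- vapply(groups, function(g) {
    r <- .zeroedCorrelation(m[labels == g, , drop = FALSE],
                            warnDegenerate = FALSE)
    eo <- .edgeOrder(r)
    K <- round(density * eo$P)
    if (K > eo$nPositive) return(rep(NA_real_, eo$n))
    .cppBetweenness(.adjFromEdges(eo, K))
  }, numeric(ncol(m)))
  vals[, 1L] - vals[, 2L]
}

.percentileP <- function(observed, nulls) {
  if (is.na(observed)) return(NA_real_)
  valid <- !is.na(nulls)
  (1 + sum(abs(nulls[valid]) >= abs(observed))) / (sum(valid) + 1)
}

#' Residual-reallocation permutation test for a global metric
#'
#' Builds the null distribution of the between-group difference in a global
#' network metric by randomly re-allocating subjects' residual profiles to
#' the two groups (retaining the original group sizes), rebuilding both
#' association matrices, thresholding at each density of the fixed observed
#' grid, and recomputing the metric. The two-tailed p-value is the
#' percentile position of the observed difference with +1 smoothing, so
#' p >= 1/(nPerm + 1). Replicates where the metric is undefined at a
#' density (e.g. a fragmented permuted network for path length) are skipped
#' with a log count.
#'
#' @param res a \linkS4class{ResidualExperiment} with two groups
#' @param metric one of "clustering_mean", "path_length", "transitivity",
#'   "modularity", "global_efficiency"
#' @param densities density grid (e.g. \code{\link{densityGrid}} from the
#'   observed minimum density); permuted replicates are evaluated on this
#'   fixed grid
#' @param nPerm number of permutations, default 1000
#' @param seed RNG seed for the shuffles
#' @return \linkS4class{PermutationResult}
#' @export
permutationTestGlobal <- function(res, metric, densities, nPerm = 1000,
                                  seed = 1L) {
  stopifnot(metric %in% .globalMetricNames, nPerm >= 100)
  m <- .residualMatrix(res)
  labels <- subjectInfo(res)$group
  groups <- sort(unique(labels))
  if (length(groups) != 2L) stop("exactly two groups are required")
  observed <- .metricDiff(m, labels, groups, densities, metric, seed)
  perms <- .permIndices(nrow(m), nPerm, seed)
  nulls <- t(vapply(seq_len(nPerm), function(i)
    .metricDiff(m, labels[perms[, i]], groups, densities, metric, seed),
    numeric(length(densities))))
  nulls <- matrix(nulls, nrow = nPerm)
  p <- vapply(seq_along(densities), function(j)
    .percentileP(observed[j], nulls[, j]), numeric(1))
  skipped <- sum(is.na(nulls))
  if (skipped > 0)
    message(skipped, " permuted metric evaluations skipped (undefined ",
            "metric on the replicate)")
  methods::new("PermutationResult", metric = metric,
               densities = as.numeric(densities), observed = observed,
               nulls = nulls, p = p, nPerm = as.integer(nPerm),
               seed = as.integer(seed), groups = as.character(groups))
}

#' Maximal-statistic correction across the density grid
#'
#' Permutation tests over a family of densities inherently support
#' familywise correction: per permutation, the maximum absolute difference
#' across the grid forms the corrected null, and corrected
#' p = (1 + #\{max-null >= |observed|\}) / (nPerm + 1). With a single
#' density the corrected p equals the uncorrected p. When several
#' \linkS4class{PermutationResult}s are supplied they must share the same
#' permutation scheme (same seed and nPerm).
#'
#' @param results a \linkS4class{PermutationResult} or list of them
#' @return data.frame with columns metric, density, observed, p,
#'   p_corrected
#' @export
maxStatisticCorrection <- function(results) {
  if (is(results, "PermutationResult")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, is, logical(1), "PermutationResult")))
  seeds <- vapply(results, function(r) r@seed, integer(1))
  nPerms <- vapply(results, function(r) r@nPerm, integer(1))
  if (length(unique(seeds)) != 1L || length(unique(nPerms)) != 1L)
    stop("results use mismatched permutation schemes (seed or nPerm differ)")
  do.call(rbind, lapply(results, function(r) {
    maxNull <- apply(abs(r@nulls), 1L, function(row)
      if (all(is.na(row))) NA_real_ else max(row, na.rm = TRUE))
    valid <- !is.na(maxNull)
    pCorr <- vapply(seq_along(r@densities), function(j) {
      if (is.na(r@observed[j])) return(NA_real_)
      (1 + sum(maxNull[valid] >= abs(r@observed[j]))) / (sum(valid) + 1)
    }, numeric(1))
    data.frame(metric = r@metric, density = r@densities,
               observed = r@observed, p = r@p, p_corrected = pCorr,
               stringsAsFactors = FALSE)
  }))
}

#' Regional permutation test on betweenness with FDR correction
#'
#' Per region, the between-group difference in nodal betweenness centrality
#' at the minimum network density is tested with the same
#' residual-reallocation scheme as the global test; raw two-tailed p-values
#' are adjusted across regions by Benjamini-Hochberg FDR. Raw and adjusted
#' values are reported side by side.
#'
#' @param res a \linkS4class{ResidualExperiment} with two groups
#' @param density the single density (typically the minimum density) at
#'   which betweenness is compared
#' @param nPerm number of permutations, default 1000
#' @param seed RNG seed for the shuffles
#' @return data.frame with columns region, observed_diff, p, q; attributes
#'   density, nPerm, seed, groups
#' @export
permutationTestRegional <- function(res, density, nPerm = 1000, seed = 1L) {
  stopifnot(length(density) == 1L, nPerm >= 100)
  m <- .residualMatrix(res)
  labels <- subjectInfo(res)$group
  groups <- sort(unique(labels))
  if (length(groups) != 2L) stop("exactly two groups are required")
  observed <- .betweennessDiff(m, labels, groups, density)
  perms <- .permIndices(nrow(m), nPerm, seed)
  nulls <- t(vapply(seq_len(nPerm), function(i)
    .betweennessDiff(m, labels[perms[, i]], groups, density),
    numeric(ncol(m))))
  p <- vapply(seq_len(ncol(m)), function(j)
    .percentileP(observed[j], nulls[, j]), numeric(1))
  out <- data.frame(region = colnames(m), observed_diff = observed,
                    p = p, q = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  attr(out, "density") <- density
  attr(out, "nPerm") <- nPerm
  attr(out, "seed") <- seed
  attr(out, "groups") <- groups
  out
}

#' Recovery of planted group differences
#'
#' Validation harness for synthetic cohorts: compares hub calls and
#' regional detections against the generator's planted ground truth.
#'
#' @param truth ground-truth list as stored by \code{\link{generateCohort}}
#'   in \code{metadata(x)$truth} (uses \code{plantedHubs})
#' @param hubReports named list of \code{\link{identifyHubs}} data.frames,
#'   one per group
#' @param regional optional \code{\link{permutationTestRegional}} result
#' @param qThreshold FDR threshold for regional detection, default 0.05
#' @return list with hub sensitivity/specificity per group and, when
#'   \code{regional} is given, the detected fraction of planted regions
#' @export
recoverPlantedDifferences <- function(truth, hubReports, regional = NULL,
                                      qThreshold = 0.05) {
  planted <- truth$plantedHubs
  perGroup <- lapply(names(hubReports), function(g) {
    rep <- hubReports[[g]]
    plant <- planted[[g]] %||% character()
    isPlant <- rep$region %in% plant
    list(group = g,
         sensitivity_2sd = if (any(isPlant))
           mean(rep$hub_2sd[isPlant]) else NA_real_,
         specificity_2sd = mean(!rep$hub_2sd[!isPlant]),
         hubs_2sd = rep$region[rep$hub_2sd])
  })
  names(perGroup) <- names(hubReports)
  out <- list(perGroup = perGroup)
  if (!is.null(regional)) {
    allPlanted <- unique(unlist(planted))
    isPlant <- regional$region %in% allPlanted
    out$regional <- list(
      detected_planted = if (any(isPlant))
        mean(regional$q[isPlant] < qThreshold) else NA_real_,
      false_positive_regions =
        regional$region[!isPlant & regional$q < qThreshold])
  }
  out
}
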