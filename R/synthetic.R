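#' Specification of a synthetic two-group morphometry cohort
#'
#' Collects every parameter of the synthetic-cohort generator: group sizes,
#' region catalogue, block-structured inter-regional correlation (within- vs
#' between-community), group-specific planted hub regions with elevated
#' cross-community correlation, a linear age effect, intracranial-volume
#' (ICV) scaling of volumetric regions, and an RNG seed. The generator's
#' defaults emulate a small two-group adult cohort (23 vs 16 subjects) of 86
#' regional measures.
#'
#' @param nPerGroup integer vector of length 2, subjects per group (named or
#'   not; defaults c(A = 23, B = 16)); each must be >= 3
#' @param catalogue region catalogue data.frame (default
#'   \code{\link{defaultRegionCatalogue}()}); an integer \code{community}
#'   column assigns regions to covariance communities (default: lobes)
#' @param withinCommunityR population correlation between regions of the
#'   same community, in [0, 1)
#' @param betweenCommunityR population correlation between regions of
#'   different communities, in [0, 1); must be < \code{withinCommunityR}
#' @param plantedHubs named list (one element per group) of region labels
#'   given elevated correlation to all regions in that group
#' @param hubBoost additive correlation boost for planted hubs
#' @param ageSlope age effect in measure units per year: a single number, a
#'   length-2 vector c(thickness, volume), or one value per region
#' @param ageDistribution c(mean, sd) of subject age in years
#' @param icvDistribution c(mean, sd) of intracranial volume in mm^3
#' @param noiseSd additional independent noise SD in latent (unit-SD) scale
#' @param groupConfounds optional named list of per-group additive offsets
#'   to the age and icv means, e.g. \code{list(A = c(age = 5, icv = 0))};
#'   default none, so age and ICV are independent of group (confound-free
#'   null, under which the permutation test's type-I error is clean)
#' @param seed integer RNG seed; identical specs give bit-identical cohorts
#' @return object of class \code{CohortSpec} (a validated list)
#' @export
cohortSpec <- function(nPerGroup = c(A = 23, B = 16),
                       catalogue = defaultRegionCatalogue(),
                       withinCommunityR = 0.4,
                       betweenCommunityR = 0.1,
                       plantedHubs = list(),
                       hubBoost = 0.4,
                       ageSlope = c(thickness = -0.005, volume = -10),
                       ageDistribution = c(mean = 35, sd = 12),
                       icvDistribution = c(mean = 1.5e6, sd = 1.5e5),
                       noiseSd = 0,
                       groupConfounds = list(),
                       seed = 1L) {
  ## accept YAML-style lists for vector arguments
  nPerGroup <- unlist(nPerGroup)
  ageDistribution <- unlist(ageDistribution)
  icvDistribution <- unlist(icvDistribution)
  ageSlope <- unlist(ageSlope)
  if (length(nPerGroup) != 2L || any(nPerGroup < 3))
    stop("nPerGroup must give two group sizes, each >= 3")
  if (is.null(names(nPerGroup))) names(nPerGroup) <- c("A", "B")
  msg <- .checkCatalogue(catalogue)
  if (length(msg)) stop(paste(msg, collapse = "; "))
  if (is.null(catalogue$community))
    catalogue$community <- match(catalogue$lobe, .lobeLevels)
  if (withinCommunityR < 0 || withinCommunityR >= 1 ||
      betweenCommunityR < 0 || betweenCommunityR >= 1)
    stop("community correlations must lie in [0, 1)")
  if (withinCommunityR > 0 && withinCommunityR <= betweenCommunityR)
    stop("withinCommunityR must exceed betweenCommunityR")
  badHubs <- setdiff(unlist(plantedHubs), catalogue$label)
  if (length(badHubs))
    stop("plantedHubs not in catalogue: ", paste(badHubs, collapse = ", "))
  spec <- list(nPerGroup = nPerGroup, catalogue = catalogue,
               withinCommunityR = withinCommunityR,
               betweenCommunityR = betweenCommunityR,
               plantedHubs = plantedHubs, hubBoost = hubBoost,
               ageSlope = ageSlope, ageDistribution = ageDistribution,
               icvDistribution = icvDistribution, noiseSd = noiseSd,
               groupConfounds = groupConfounds, seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  spec
}

## Block-structured target correlation matrix for one group, hub rows
## boosted, repaired to positive semidefiniteness by eigenvalue clipping
## with re-normalized unit diagonal.
.targetCorrelation <- function(spec, group) {
  comm <- spec$catalogue$community
  p <- length(comm)
  sigma <- matrix(spec$betweenCommunityR, p, p)
  same <- outer(comm, comm, "==")
  sigma[same] <- spec$withinCommunityR
  hubs <- match(spec$plantedHubs[[group]] %||% character(), spec$catalogue$label)
  for (h in hubs) {
    ## the plant elevates the hub's cross-community covariance; its
    ## within-community correlation is already high by construction
    cross <- comm != comm[h]
    sigma[h, cross] <- pmin(0.9, sigma[h, cross] + spec$hubBoost)
    sigma[cross, h] <- sigma[h, cross]
  }
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 0)
    sigma <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(sigma))
    if (any(d <= 0))
      stop("implied correlation matrix is not repairable; check ",
           "withinCommunityR/betweenCommunityR/hubBoost")
    sigma <- sigma / tcrossprod(d)
    if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8)
      stop("implied correlation matrix remains indefinite after repair; ",
           "check withinCommunityR/betweenCommunityR/hubBoost")
  }
  sigma
}

## Symmetric square root, used to colour iid normals with the target
## correlation.
.corFactor <- function(sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

#' Generate a synthetic two-group morphometry cohort
#'
#' Draws regional measures from a multivariate normal whose correlation
#' follows the spec's community structure (planted hubs boosted), then maps
#' the latent unit-SD values onto realistic measurement scales (thickness
#' base 2.5 mm, SD 0.15; volume base 4000 mm^3, SD 400), adds the linear
#' age effect \code{ageSlope * (age - mean age)}, and multiplies volumetric
#' regions by each subject's ICV relative to the population mean ICV.
#' Identical specs (including the seed) produce bit-identical tables.
#'
#' @param spec a \code{\link{cohortSpec}}
#' @return \linkS4class{MorphometryExperiment}; ground truth (communities,
#'   planted hubs, spec parameters) is stored in
#'   \code{S4Vectors::metadata(x)$truth}
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  cat <- spec$catalogue
  p <- nrow(cat)
  groups <- names(spec$nPerGroup)
  baseMean <- ifelse(cat$measure_kind == "thickness", 2.5, 4000)
  baseSd <- ifelse(cat$measure_kind == "thickness", 0.15, 400)
  slope <- spec$ageSlope
  if (length(slope) == 2L && !is.null(names(slope)))
    slope <- unname(slope[cat$measure_kind])
  else if (length(slope) == 1L) slope <- rep(slope, p)
  if (length(slope) != p) stop("ageSlope must be scalar, per-kind or per-region")

  withSeed(spec$seed, {
    rows <- list(); ages <- list(); icvs <- list(); labels <- list()
    for (g in groups) {
      n <- spec$nPerGroup[[g]]
      conf <- spec$groupConfounds[[g]] %||% c(age = 0, icv = 0)
      confVal <- function(key) if (key %in% names(conf)) conf[[key]] else 0
      age <- rnorm(n, spec$ageDistribution[["mean"]] + confVal("age"),
                   spec$ageDistribution[["sd"]])
      icv <- rnorm(n, spec$icvDistribution[["mean"]] + confVal("icv"),
                   spec$icvDistribution[["sd"]])
      icv <- pmax(icv, 0.5 * spec$icvDistribution[["mean"]])
      fac <- .corFactor(.targetCorrelation(spec, g))
      z <- matrix(rnorm(n * p), n, p) %*% fac
      if (spec$noiseSd > 0) z <- z + matrix(rnorm(n * p, sd = spec$noiseSd), n, p)
      vals <- sweep(sweep(z, 2L, baseSd, "*"), 2L, baseMean, "+")
      vals <- vals + outer(age - spec$ageDistribution[["mean"]], slope)
      isVol <- cat$measure_kind == "volume"
      if (any(isVol))
        vals[, isVol] <- vals[, isVol] *
          (icv / spec$icvDistribution[["mean"]])
      rows[[g]] <- vals; ages[[g]] <- age; icvs[[g]] <- icv
      labels[[g]] <- rep(g, n)
    }
  })
  values <- do.call(rbind, rows)
  subjects <- sprintf("sub%03d", seq_len(nrow(values)))
  rownames(values) <- subjects
  colnames(values) <- cat$label
  if (any(values <= 0))
    stop("generated non-positive measure values; reduce noiseSd or ageSlope")
  truth <- list(communities = setNames(cat$community, cat$label),
                plantedHubs = spec$plantedHubs, spec = spec)
  MorphometryExperiment(values = values, catalogue = cat,
                        covariates = data.frame(
                          subject_id = subjects,
                          group = unlist(labels, use.names = FALSE),
                          age = unlist(ages, use.names = FALSE),
                          icv = unlist(icvs, use.names = FALSE),
                          stringsAsFactors = FALSE),
                        truth = truth)
}

#' Construct a MorphometryExperiment from a subjects x regions matrix
#'
#' @param values subjects x regions matrix (columns in catalogue order)
#' @param catalogue region catalogue data.frame
#' @param covariates data.frame with columns subject_id, group, age, icv
#' @param truth optional ground-truth list stored in metadata
#' @export
MorphometryExperiment <- function(values, catalogue, covariates,
                                  truth = NULL) {
  stopifnot(nrow(values) == nrow(covariates),
            ncol(values) == nrow(catalogue))
  cd <- S4Vectors::DataFrame(covariates[c("group", "age", "icv")],
                             row.names = covariates$subject_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(morphometry = t(values)),
    rowData = S4Vectors::DataFrame(catalogue, row.names = catalogue$label),
    colData = cd)
  if (!is.null(truth)) S4Vectors::metadata(se)$truth <- truth
  methods::new("MorphometryExperiment", se)
}

#' Write a cohort as FreeSurfer-style stats tables
#'
#' Emits tab-delimited tables in the dialect of FreeSurfer's
#' \code{aparcstats2table} (thickness) and \code{asegstats2table} (volume):
#' first column the subject ID, one column per region, a single header row
#' of region labels. Subject covariates go to a CSV with columns
#' subject_id, group, age, icv. Round-trips losslessly through
#' \code{\link{readMorphometry}} up to text-serialization precision.
#'
#' @param x a \linkS4class{MorphometryExperiment}
#' @param dir output directory (created if needed)
#' @return named character vector of written paths (thickness, volume,
#'   covariates; a measure file is omitted when no region carries that kind)
#' @export
writeFreeSurferTables <- function(x, dir) {
  stopifnot(is(x, "MorphometryExperiment"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  cat <- regionCatalogue(x)
  values <- t(SummarizedExperiment::assay(x, "morphometry"))
  covs <- subjectInfo(x)
  paths <- c()
  for (kind in c("thickness", "volume")) {
    keep <- cat$measure_kind == kind
    if (!any(keep)) next
    fname <- if (kind == "thickness") "aparc_thickness.tsv" else
      "aseg_volume.tsv"
    path <- file.path(dir, fname)
    df <- data.frame(subject = rownames(values),
                     values[, keep, drop = FALSE],
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("subject", cat$label[keep])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[kind] <- path
  }
  covPath <- file.path(dir, "covariates.csv")
  write.csv(data.frame(subject_id = rownames(covs), covs,
                       stringsAsFactors = FALSE),
            covPath, quote = FALSE, row.names = FALSE)
  paths["covariates"] <- covPath
  paths
}

#' Simulate a cohort and write an ingestible dataset directory
#'
#' Runs \code{\link{generateCohort}} and writes the measurement tables and
#' covariates via \code{\link{writeFreeSurferTables}}, plus a ground-truth
#' sidecar (\code{truth.yaml}: planted hubs, community assignment, generator
#' parameters) for validation harnesses.
#'
#' @param spec a \code{\link{cohortSpec}} or path to a YAML file of
#'   cohortSpec arguments
#' @param dir output directory
#' @return named character vector of written paths
#' @export
simulateDataset <- function(spec, dir) {
  if (is.character(spec)) {
    args <- yaml::read_yaml(spec)
    spec <- do.call(cohortSpec, args)
  }
  stopifnot(inherits(spec, "CohortSpec"))
  x <- generateCohort(spec)
  paths <- writeFreeSurferTables(x, dir)
  truthPath <- file.path(dir, "truth.yaml")
  truth <- S4Vectors::metadata(x)$truth
  yaml::write_yaml(list(
    planted_hubs = lapply(truth$plantedHubs, as.character),
    communities = as.list(truth$communities),
    parameters = list(
      n_per_group = as.list(spec$nPerGroup),
      within_community_r = spec$withinCommunityR,
      between_community_r = spec$betweenCommunityR,
      hub_boost = spec$hubBoost,
      age_distribution = as.list(spec$ageDistribution),
      icv_distribution = as.list(spec$icvDistribution),
      noise_sd = spec$noiseSd,
      seed = spec$seed)), truthPath)
  c(paths, truth = truthPath)
}
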