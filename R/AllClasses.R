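#' @import methods
#' @importFrom stats cor sd qr.resid rnorm p.adjust setNames quantile
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

.catalogueColumns <- c("label", "hemisphere", "lobe", "measure_kind")
.lobeLevels <- c("frontal", "parietal", "temporal-limbic-striatal",
                 "occipital", "subcortical")

.checkCatalogue <- function(cat) {
  msg <- character()
  if (!all(.catalogueColumns %in% colnames(cat)))
    msg <- c(msg, paste("region catalogue must have columns",
                        paste(.catalogueColumns, collapse = ", ")))
  else {
    if (anyDuplicated(cat$label))
      msg <- c(msg, paste("duplicated region label(s):",
                          paste(unique(cat$label[duplicated(cat$label)]),
                                collapse = ", ")))
    if (!all(cat$hemisphere %in% c("left", "right")))
      msg <- c(msg, "hemisphere must be 'left' or 'right'")
    if (!all(cat$lobe %in% .lobeLevels))
      msg <- c(msg, "unknown lobe value")
    if (!all(cat$measure_kind %in% c("thickness", "volume")))
      msg <- c(msg, "measure_kind must be 'thickness' or 'volume'")
  }
  msg
}

#' Container for regional morphometry with subject covariates
#'
#' Extends \linkS4class{SummarizedExperiment}: one assay \code{"morphometry"}
#' (regions x subjects; thickness in mm, volume in mm^3), \code{rowData}
#' carrying the region catalogue (label, hemisphere, lobe, measure_kind) and
#' \code{colData} carrying subject covariates (group, age, icv).
#'
#' @export
setClass("MorphometryExperiment",
         contains = "SummarizedExperiment")

setValidity("MorphometryExperiment", function(object) {
  msg <- character()
  if (!"morphometry" %in% SummarizedExperiment::assayNames(object))
    return("assay 'morphometry' is required")
  m <- SummarizedExperiment::assay(object, "morphometry")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "age", "icv") %in% colnames(cd)))
    msg <- c(msg, "colData must have columns group, age, icv")
  if (anyNA(m)) msg <- c(msg, "missing cells are not allowed")
  msg <- c(msg, .checkCatalogue(as.data.frame(
    SummarizedExperiment::rowData(object))))
  if (!anyNA(m) && any(m <= 0))
    msg <- c(msg, "all thickness/volume values must be positive")
  if (length(msg)) msg else TRUE
})

#' Age-residualized regional measures
#'
#' Extends \linkS4class{SummarizedExperiment}: assay \code{"residuals"}
#' (regions x subjects, unitless), same rowData/colData layout as
#' \linkS4class{MorphometryExperiment}. Residuals have (numerically) zero
#' mean and zero sample correlation with age over each regression sample.
#'
#' @export
setClass("ResidualExperiment",
         contains = "SummarizedExperiment")

setValidity("ResidualExperiment", function(object) {
  if (!"residuals" %in% SummarizedExperiment::assayNames(object))
    return("assay 'residuals' is required")
  msg <- .checkCatalogue(as.data.frame(SummarizedExperiment::rowData(object)))
  if (length(msg)) msg else TRUE
})

#' Group-level inter-regional association matrix
#'
#' Symmetric matrix of Pearson correlations between age-residualized regional
#' measures across the subjects of one group, with negative values replaced
#' by zero. The diagonal is excluded from all edge operations.
#'
#' @slot r regions x regions numeric matrix in [0, 1] off-diagonal
#' @slot catalogue region catalogue data.frame
#' @slot group group label the matrix was computed in
#' @slot nSubjects number of subjects contributing to the correlations
#' @export
setClass("AssociationMatrix",
         representation(r = "matrix", catalogue = "data.frame",
                        group = "character", nSubjects = "integer"))

setValidity("AssociationMatrix", function(object) {
  msg <- character()
  r <- object@r
  if (nrow(r) != ncol(r)) msg <- c(msg, "matrix must be square")
  else {
    if (max(abs(r - t(r))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
    off <- r[upper.tri(r)]
    if (length(off) && (min(off) < 0 || max(off) > 1 + 1e-12))
      msg <- c(msg, "off-diagonal entries must lie in [0, 1] after zeroing")
  }
  if (nrow(object@catalogue) != nrow(r))
    msg <- c(msg, "catalogue length must match matrix dimension")
  if (length(msg)) msg else TRUE
})

#' Binary undirected network at a fixed density
#'
#' Adjacency matrix obtained by keeping the K = round(d * P) strongest
#' positive associations, P = N(N-1)/2. Undirected, no self-loops.
#'
#' @slot adjacency regions x regions 0/1 matrix, zero diagonal, symmetric
#' @slot density achieved edge density K/P
#' @slot catalogue region catalogue data.frame
#' @export
setClass("BinaryNetwork",
         representation(adjacency = "matrix", density = "numeric",
                        catalogue = "data.frame"))

setValidity("BinaryNetwork", function(object) {
  msg <- character()
  a <- object@adjacency
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  else {
    if (!all(a %in% c(0, 1))) msg <- c(msg, "adjacency must be binary")
    if (any(diag(a) != 0)) msg <- c(msg, "self-loops are not allowed")
    if (!identical(a, t(a))) msg <- c(msg, "adjacency must be symmetric")
    p <- nrow(a) * (nrow(a) - 1) / 2
    if (p > 0 && abs(sum(a[upper.tri(a)]) - round(object@density * p)) > 0)
      msg <- c(msg, "edge count must equal round(density * P)")
  }
  if (length(msg)) msg else TRUE
})

#' Permutation-test result for one metric over a density grid
#'
#' Holds the observed group difference, the full null distribution from
#' residual-reallocation permutations (one row per permutation, one column
#' per density), and two-tailed p-values by percentile position with +1
#' smoothing, so p >= 1/(nPerm + 1) always.
#'
#' @slot metric metric name
#' @slot densities density grid the test was evaluated on
#' @slot observed observed difference (group A - group B) per density
#' @slot nulls nPerm x length(densities) matrix of null differences (NA where
#'   a permuted replicate was skipped, e.g. a disconnected network for path
#'   length)
#' @slot p two-tailed p-value per density
#' @slot nPerm number of permutations
#' @slot seed RNG seed the permutation shuffles derive from
#' @slot groups the two group labels, difference is groups[1] - groups[2]
#' @export
setClass("PermutationResult",
         representation(metric = "character", densities = "numeric",
                        observed = "numeric", nulls = "matrix",
                        p = "numeric", nPerm = "integer", seed = "integer",
                        groups = "character"))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (nrow(object@nulls) != object@nPerm)
    msg <- c(msg, "nulls must have nPerm rows")
  if (ncol(object@nulls) != length(object@densities))
    msg <- c(msg, "nulls must have one column per density")
  pOK <- object@p[!is.na(object@p)]
  if (length(pOK) && (any(pOK <= 0) || any(pOK > 1)))
    msg <- c(msg, "p must lie in (0, 1] where defined")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' Region catalogue of a network object
#' @param x a MorphometryExperiment, ResidualExperiment, AssociationMatrix or
#'   BinaryNetwork
#' @return data.frame with columns label, hemisphere, lobe, measure_kind
#' @export
setGeneric("regionCatalogue", function(x) standardGeneric("regionCatalogue"))

#' @rdname regionCatalogue
#' @export
setMethod("regionCatalogue", "SummarizedExperiment", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname regionCatalogue
#' @export
setMethod("regionCatalogue", "AssociationMatrix", function(x) x@catalogue)

#' @rdname regionCatalogue
#' @export
setMethod("regionCatalogue", "BinaryNetwork", function(x) x@catalogue)

#' Correlation values of an association matrix
#' @param x an AssociationMatrix
#' @export
assocValues <- function(x) {
  stopifnot(is(x, "AssociationMatrix"))
  x@r
}

#' Adjacency matrix of a binary network
#' @param x a BinaryNetwork
#' @export
adjacency <- function(x) {
  stopifnot(is(x, "BinaryNetwork"))
  x@adjacency
}

#' Subject covariates of an experiment
#' @param x a MorphometryExperiment or ResidualExperiment
#' @return data.frame with columns group, age, icv (rownames = subject IDs)
#' @export
subjectInfo <- function(x) {
  stopifnot(is(x, "SummarizedExperiment"))
  as.data.frame(SummarizedExperiment::colData(x))
}

## ---- show methods ----

setMethod("show", "AssociationMatrix", function(object) {
  cat("AssociationMatrix:", nrow(object@r), "regions, group",
      sQuote(object@group), "(n =", object@nSubjects, "subjects)\n")
  off <- object@r[upper.tri(object@r)]
  cat(sprintf("  off-diagonal r: %d positive / %d total, max %.3f\n",
              sum(off > 0), length(off), if (length(off)) max(off) else NA))
})

setMethod("show", "BinaryNetwork", function(object) {
  n <- nrow(object@adjacency)
  cat(sprintf("BinaryNetwork: %d nodes, %d edges, density %.3f\n",
              n, sum(object@adjacency) / 2, object@density))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: metric %s, %d permutations, %d densit%s\n",
    sQuote(object@metric), object@nPerm, length(object@densities),
    if (length(object@densities) == 1L) "y" else "ies"))
  df <- data.frame(density = object@densities, observed = object@observed,
                   p = object@p)
  print(df, row.names = FALSE)
})
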