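.readStatsTable <- function(path, kind) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header in ", path, " (line 1): expected a subject ",
         "column plus at least one region column")
  regions <- header[-1L]
  dup <- unique(regions[duplicated(regions)])
  if (length(dup))
    stop("duplicated region label(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicated subject ID(s) in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric ", kind, " values in ", path)
  rownames(m) <- df[[1L]]
  m
}

#' Read morphometry tables and subject covariates
#'
#' Ingests tab-delimited regional measure tables in the FreeSurfer
#' \code{aparcstats2table} (thickness) / \code{asegstats2table} (volume)
#' dialect -- first column subject ID, one column per region -- together
#' with a covariate CSV (subject_id, group, age, icv). Subject IDs must
#' align across all files; mismatches are reported by ID.
#'
#' @param thicknessPath path to the thickness table (or NULL if none)
#' @param volumePath path to the volume table (or NULL if none)
#' @param covariatesPath path to the covariate CSV
#' @param catalogue optional region catalogue; when NULL, hemisphere is
#'   inferred from the "L "/"R " label prefix and lobes are looked up in the
#'   default catalogue (unknown labels get the subcortical group for volume
#'   and their hemisphere's catalogue entry otherwise)
#' @param ageRange plausibility window for ages, default c(10, 100)
#' @return \linkS4class{MorphometryExperiment}
#' @export
readMorphometry <- function(thicknessPath = NULL, volumePath = NULL,
                            covariatesPath, catalogue = NULL,
                            ageRange = c(10, 100)) {
  mats <- list()
  if (!is.null(thicknessPath))
    mats$thickness <- .readStatsTable(thicknessPath, "thickness")
  if (!is.null(volumePath))
    mats$volume <- .readStatsTable(volumePath, "volume")
  if (!length(mats)) stop("at least one measure table is required")
  covs <- read.csv(covariatesPath, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "icv")
  if (!all(need %in% colnames(covs)))
    stop("covariate file must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(covs$subject_id))
    stop("duplicated subject ID(s) in covariates")
  for (kind in names(mats)) {
    missingCov <- setdiff(rownames(mats[[kind]]), covs$subject_id)
    missingMeas <- setdiff(covs$subject_id, rownames(mats[[kind]]))
    if (length(missingCov) || length(missingMeas))
      stop("subject IDs do not align between ", kind,
           " table and covariates;",
           if (length(missingCov)) paste(" absent from covariates:",
                                         paste(missingCov, collapse = ", ")),
           if (length(missingMeas)) paste(" absent from measures:",
                                          paste(missingMeas, collapse = ", ")))
  }
  if (length(unique(covs$group)) != 2L)
    stop("exactly two group levels are required, found: ",
         paste(unique(covs$group), collapse = ", "))
  if (any(covs$age < ageRange[1]) || any(covs$age > ageRange[2]))
    stop("ages outside plausibility window [", ageRange[1], ", ",
         ageRange[2], "]")
  if (any(covs$icv <= 0)) stop("icv must be positive")

  subjects <- covs$subject_id
  values <- do.call(cbind, lapply(names(mats), function(kind)
    mats[[kind]][subjects, , drop = FALSE]))
  kinds <- rep(names(mats), vapply(mats, ncol, 1L))
  labels <- colnames(values)
  dupAcross <- unique(labels[duplicated(labels)])
  if (length(dupAcross))
    stop("region label(s) appear in both tables: ",
         paste(dupAcross, collapse = ", "))
  if (anyNA(values)) stop("missing cells are not allowed")

  if (is.null(catalogue)) {
    def <- defaultRegionCatalogue()
    hemi <- ifelse(startsWith(labels, "R "), "right", "left")
    lobe <- def$lobe[match(labels, def$label)]
    lobe[is.na(lobe)] <- ifelse(kinds[is.na(lobe)] == "volume",
                                "subcortical", "frontal")
    catalogue <- data.frame(label = labels, hemisphere = hemi, lobe = lobe,
                            measure_kind = kinds, stringsAsFactors = FALSE)
    catalogue$community <- match(catalogue$lobe, .lobeLevels)
  } else {
    if (!setequal(catalogue$label, labels))
      stop("catalogue labels do not match table columns")
    values <- values[, catalogue$label, drop = FALSE]
  }
  MorphometryExperiment(values = values, catalogue = catalogue,
                        covariates = covs)
}

#' Correct volumetric measures for intracranial volume
#'
#' Proportional correction (the default): each volume-kind column is divided
#' by the subject's ICV relative to the sample mean ICV, i.e.
#' \code{corrected = raw * mean(icv) / icv}. Thickness columns are left
#' bitwise unchanged. The regression alternative residualizes volumes on
#' ICV (intercept + slope, pooled sample) and re-centres at the region mean.
#'
#' @param x a \linkS4class{MorphometryExperiment}
#' @param method "proportional" (default) or "regression"
#' @return corrected \linkS4class{MorphometryExperiment}
#' @export
correctICV <- function(x, method = c("proportional", "regression")) {
  method <- match.arg(method)
  stopifnot(is(x, "MorphometryExperiment"))
  covs <- subjectInfo(x)
  if (any(covs$icv <= 0)) stop("icv must be positive for all subjects")
  m <- SummarizedExperiment::assay(x, "morphometry")
  isVol <- regionCatalogue(x)$measure_kind == "volume"
  if (any(isVol)) {
    if (method == "proportional") {
      scale <- mean(covs$icv) / covs$icv
      m[isVol, ] <- sweep(m[isVol, , drop = FALSE], 2L, scale, "*")
    } else {
      X <- cbind(1, covs$icv)
      fit <- qr(X)
      res <- t(qr.resid(fit, t(m[isVol, , drop = FALSE])))
      m[isVol, ] <- res + rowMeans(m[isVol, , drop = FALSE])
    }
  }
  SummarizedExperiment::assay(x, "morphometry") <- m
  methods::validObject(x)
  x
}

#' Residualize regional measures for age
#'
#' For each region independently, ordinary least squares of the measure on
#' age (intercept + slope), fitted over the pooled sample by default (both
#' groups together, so group differences are not regressed out); the
#' returned residuals are what all network construction consumes. Residuals
#' have numerically zero mean and zero sample correlation with age over each
#' regression sample.
#'
#' @param x a \linkS4class{MorphometryExperiment} (ICV-corrected if desired;
#'   the ICV step precedes and is independent of the age regression)
#' @param scope "pooled" (default) or "per_group" fitting
#' @return \linkS4class{ResidualExperiment}
#' @export
residualizeAge <- function(x, scope = c("pooled", "per_group")) {
  scope <- match.arg(scope)
  stopifnot(is(x, "MorphometryExperiment"))
  covs <- subjectInfo(x)
  if (ncol(x) < 3L) stop("at least 3 subjects are required")
  m <- t(SummarizedExperiment::assay(x, "morphometry"))  # subjects x regions
  res <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  fitOne <- function(rows) {
    age <- covs$age[rows]
    if (length(unique(age)) < 2L)
      stop("age is constant over the regression sample; ",
           "slope is unidentifiable")
    qr.resid(qr(cbind(1, age)), m[rows, , drop = FALSE])
  }
  if (scope == "pooled") {
    res[] <- fitOne(seq_len(nrow(m)))
  } else {
    for (g in unique(covs$group)) {
      rows <- which(covs$group == g)
      res[rows, ] <- fitOne(rows)
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(residuals = t(res)),
    rowData = SummarizedExperiment::rowData(x),
    colData = SummarizedExperiment::colData(x))
  S4Vectors::metadata(se) <- S4Vectors::metadata(x)
  methods::new("ResidualExperiment", se)
}
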