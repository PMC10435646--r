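test_that("default catalogue has 86 bilateral regions with expected lobes", {
  cat86 <- defaultRegionCatalogue()
  expect_equal(nrow(cat86), 86L)
  expect_equal(sum(cat86$hemisphere == "left"), 43L)
  expect_equal(sum(cat86$hemisphere == "right"), 43L)
  expect_false(anyDuplicated(cat86$label) > 0)
  expect_equal(sum(cat86$measure_kind == "thickness"), 68L)
  expect_equal(sum(cat86$measure_kind == "volume"), 18L)
  lobeOf <- function(lab) cat86$lobe[cat86$label == lab]
  ## spot checks against the lobe groupings used in hub reporting
  expect_equal(lobeOf("L Inferior temporal"), "temporal-limbic-striatal")
  expect_equal(lobeOf("R Cuneus"), "occipital")
  expect_equal(lobeOf("R Pars opercularis"), "frontal")
  expect_equal(lobeOf("L Postcentral"), "parietal")
  expect_equal(lobeOf("R Posterior cingulate"), "parietal")
  expect_equal(lobeOf("R Entorhinal"), "temporal-limbic-striatal")
  expect_equal(lobeOf("L Caudate"), "temporal-limbic-striatal")
  expect_equal(lobeOf("R Ventral diencephalon"), "temporal-limbic-striatal")
  expect_equal(lobeOf("R Precuneus"), "occipital")
  expect_equal(lobeOf("R Paracentral"), "parietal")
})

test_that("cohort generation is deterministic and respects independence", {
  spec <- cohortSpec(nPerGroup = c(A = 10, B = 8), seed = 99)
  x1 <- generateCohort(spec)
  x2 <- generateCohort(spec)
  expect_identical(SummarizedExperiment::assay(x1, "morphometry"),
                   SummarizedExperiment::assay(x2, "morphometry"))
  expect_identical(subjectInfo(x1), subjectInfo(x2))

  ## independence case: zero target correlations, no age effect
  cat20 <- defaultRegionCatalogue()[1:20, ]
  specInd <- cohortSpec(nPerGroup = c(A = 300, B = 3),
                        catalogue = cat20, withinCommunityR = 0,
                        betweenCommunityR = 0, ageSlope = 0, seed = 5)
  x <- generateCohort(specInd)
  vals <- t(SummarizedExperiment::assay(x, "morphometry"))
  r <- cor(vals[subjectInfo(x)$group == "A", ])
  expect_lt(max(abs(r[upper.tri(r)])), 0.25)  # sampling error at n = 300
})

test_that("sample correlations recover the generating parameters", {
  cat20 <- defaultRegionCatalogue()[1:20, ]
  cat20$community <- rep(1:2, each = 10)
  spec <- cohortSpec(nPerGroup = c(A = 200, B = 200), catalogue = cat20,
                     withinCommunityR = 0.8, betweenCommunityR = 0.1,
                     ageSlope = 0, seed = 21)
  x <- generateCohort(spec)
  vals <- t(SummarizedExperiment::assay(x, "morphometry"))
  r <- cor(vals[subjectInfo(x)$group == "A", ])
  same <- outer(cat20$community, cat20$community, "==") & upper.tri(r)
  within <- mean(r[same])
  between <- mean(r[!same & upper.tri(r)])
  expect_gt(within, 0.7)
  expect_lt(within, 0.9)
  expect_lt(abs(within - 0.8), 0.05)
  expect_lt(abs(between - 0.1), 0.06)
})

test_that("planted hubs stand out in the group correlation matrix", {
  cat30 <- defaultRegionCatalogue()[1:30, ]
  cat30$community <- rep(1:3, each = 10)
  hits <- vapply(1:20, function(s) {
    spec <- cohortSpec(nPerGroup = c(A = 150, B = 3), catalogue = cat30,
                       withinCommunityR = 0.4, betweenCommunityR = 0.1,
                       plantedHubs = list(A = "L Cuneus"), hubBoost = 0.4,
                       ageSlope = 0, seed = 1000 + s)
    x <- generateCohort(spec)
    vals <- t(SummarizedExperiment::assay(x, "morphometry"))
    r <- cor(vals[subjectInfo(x)$group == "A", ])
    diag(r) <- NA
    strength <- rowMeans(abs(r), na.rm = TRUE)
    hub <- which(cat30$label == "L Cuneus")
    strength[hub] > max(strength[-hub])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("invalid cohort specs are rejected with informative errors", {
  expect_error(cohortSpec(nPerGroup = c(2, 10)), ">= 3")
  expect_error(cohortSpec(withinCommunityR = 0.2, betweenCommunityR = 0.5),
               "exceed")
  expect_error(cohortSpec(plantedHubs = list(A = "not a region")),
               "not a region")
})

test_that("written tables round-trip and have the documented shape", {
  spec <- cohortSpec(nPerGroup = c(A = 3, B = 3), seed = 4)
  x <- generateCohort(spec)
  dir <- withr::local_tempdir()
  paths <- writeFreeSurferTables(x, dir)
  thickLines <- readLines(paths[["thickness"]])
  expect_length(thickLines, 7L)  # header + 6 subjects
  expect_equal(length(strsplit(thickLines[1], "\t")[[1]]), 69L)
  volLines <- readLines(paths[["volume"]])
  expect_equal(length(strsplit(volLines[1], "\t")[[1]]), 19L)

  x2 <- readMorphometry(paths[["thickness"]], paths[["volume"]],
                        paths[["covariates"]])
  expect_equal(t(SummarizedExperiment::assay(x2, "morphometry")),
               t(SummarizedExperiment::assay(x, "morphometry")),
               tolerance = 1e-12)
  expect_equal(subjectInfo(x2)$age, subjectInfo(x)$age, tolerance = 1e-12)
  expect_equal(regionCatalogue(x2)$lobe, regionCatalogue(x)$lobe)
})

test_that("simulateDataset writes an ingestible directory with truth sidecar", {
  dir <- withr::local_tempdir()
  spec <- cohortSpec(nPerGroup = c(A = 4, B = 4),
                     plantedHubs = list(A = "L Cuneus"), seed = 8)
  paths <- simulateDataset(spec, dir)
  expect_true(all(file.exists(paths)))
  truth <- yaml::read_yaml(paths[["truth"]])
  expect_equal(truth$planted_hubs$A, "L Cuneus")
  expect_equal(length(truth$communities), 86L)
  ## a different seed changes values but not the planted truth
  paths2 <- simulateDataset(cohortSpec(nPerGroup = c(A = 4, B = 4),
                                       plantedHubs = list(A = "L Cuneus"),
                                       seed = 9),
                            withr::local_tempdir())
  truth2 <- yaml::read_yaml(paths2[["truth"]])
  expect_equal(truth2$planted_hubs, truth$planted_hubs)
  expect_false(identical(readLines(paths[["thickness"]])[2],
                         readLines(paths2[["thickness"]])[2]))
})
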