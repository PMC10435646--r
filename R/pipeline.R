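#' Default run configuration
#'
#' One flat configuration list drives the whole pipeline; every decision
#' switch left open by convention (connectivity criterion, SD denominator,
#' ICV method, residualization scope, maximum-density rule) is explicit
#' here and is serialized into the output directory, so each run's
#' provenance record is complete.
#'
#' @param ... named overrides of the defaults
#' @return named list of class \code{RunConfig}
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    input = NULL,                 # list(thickness=, volume=, covariates=)
    synthetic = NULL,             # cohortSpec arguments, used if no input
    icv_method = "proportional",  # proportional | regression
    residualize_scope = "pooled", # pooled | per_group
    density_step = 0.01,
    min_density_criterion = "connected",  # connected | no_isolates
    max_density_rule = "sigma_threshold", # sigma_threshold | fixed
    sigma_threshold = 1.5,
    fixed_max_density = 0.44,
    ensemble_size = 20,
    rewires_per_edge = 10,
    metrics = .globalMetricNames,
    n_perm = 1000,
    sd_type = "population",       # population | sample
    seed = 1L,
    output_dir = NULL)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file of \code{\link{defaultRunConfig}} keys
#' @export
readRunConfig <- function(path) defaultRunConfig(yaml::read_yaml(path))

.validateConfig <- function(cfg) {
  if (!is.numeric(cfg$n_perm) || cfg$n_perm < 100)
    stop("config validation: n_perm must be >= 100")
  if (is.null(cfg$output_dir)) stop("config validation: output_dir is required")
  if (is.null(cfg$input) && is.null(cfg$synthetic))
    stop("config validation: either input paths or a synthetic spec is required")
  if (cfg$density_step <= 0 || cfg$density_step > 1)
    stop("config validation: density_step must lie in (0, 1]")
  invisible(cfg)
}

#' Run the full structural covariance network pipeline
#'
#' Executes ingest (or synthetic generation) -> ICV correction -> age
#' residualization -> group association matrices -> density range ->
#' graph metrics with null-ensemble normalization -> hub detection ->
#' permutation inference (global with maximal-statistic correction,
#' regional with FDR), and writes all result tables, networks and a run
#' log into the output directory. Identical configurations produce
#' byte-identical CSV artifacts.
#'
#' @param config a \code{RunConfig} list (\code{\link{defaultRunConfig}}),
#'   a path to a YAML config, or named arguments via \code{...}
#' @param ... overrides applied on top of \code{config}
#' @return invisible list of in-memory results (experiment, residuals,
#'   association matrices, density range, metrics, hubs, inference tables,
#'   output paths)
#' @export
runPipeline <- function(config = defaultRunConfig(), ...) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- defaultRunConfig(unclass(config))
  over <- list(...)
  if (length(over)) cfg[names(over)] <- over
  .validateConfig(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log <- list(seed = cfg$seed,
              versions = list(R = R.version.string,
                              scnet = as.character(
                                utils::packageVersion("scnet"))),
              stages = list())
  stamp <- function(stage, ...) {
    log$stages[[stage]] <<- list(...)
  }

  ## ingest / simulate
  if (!is.null(cfg$input)) {
    x <- readMorphometry(cfg$input$thickness, cfg$input$volume,
                         cfg$input$covariates)
    stamp("ingest", subjects = ncol(x), regions = nrow(x))
  } else {
    spec <- do.call(cohortSpec, cfg$synthetic)
    x <- generateCohort(spec)
    stamp("simulate", subjects = ncol(x), regions = nrow(x),
          seed = spec$seed)
  }

  ## preprocess
  x <- correctICV(x, method = cfg$icv_method)
  res <- residualizeAge(x, scope = cfg$residualize_scope)
  groups <- unique(subjectInfo(res)$group)
  if (length(groups) != 2L) stop("pipeline requires exactly two groups")
  stamp("preprocess", icv_method = cfg$icv_method,
        residualize_scope = cfg$residualize_scope)

  ## association + density range
  Rs <- lapply(groups, function(g) associationMatrix(res, g))
  names(Rs) <- groups
  dMin <- minimumDensity(Rs, step = cfg$density_step,
                         criterion = cfg$min_density_criterion)
  dMax <- maximumDensity(Rs, dMin, step = cfg$density_step,
                         rule = cfg$max_density_rule,
                         sigmaThreshold = cfg$sigma_threshold,
                         fixedValue = cfg$fixed_max_density,
                         ensembleSize = cfg$ensemble_size,
                         rewiresPerEdge = cfg$rewires_per_edge,
                         seed = cfg$seed)
  grid <- densityGrid(dMin, dMax, cfg$density_step)
  stamp("density_range", d_min = dMin, d_max = dMax,
        criterion = cfg$min_density_criterion, grid_size = length(grid))

  ## metrics + normalization + hubs at minimum density
  networks <- lapply(Rs, binarizeAtDensity, d = dMin)
  metrics <- lapply(networks, metricSet, seed = cfg$seed)
  smallWorld <- lapply(seq_along(networks), function(i)
    normalizedSmallWorld(networks[[i]], ensembleSize = cfg$ensemble_size,
                         rewiresPerEdge = cfg$rewires_per_edge,
                         seed = deriveSeed(cfg$seed, i)))
  names(smallWorld) <- groups
  hubs <- lapply(groups, function(g)
    identifyHubs(metrics[[g]]$betweenness, regionCatalogue(res),
                 sdType = cfg$sd_type))
  names(hubs) <- groups
  stamp("metrics", densities_analyzed = length(grid),
        nulls_rejected = vapply(smallWorld, function(s) s$rejectedNulls, 0L))

  ## permutation inference
  global <- lapply(cfg$metrics, function(metric)
    permutationTestGlobal(res, metric, grid, nPerm = cfg$n_perm,
                          seed = cfg$seed))
  globalTable <- maxStatisticCorrection(global)
  regional <- permutationTestRegional(res, dMin, nPerm = cfg$n_perm,
                                      seed = cfg$seed)
  stamp("inference", n_perm = cfg$n_perm, metrics = cfg$metrics)

  ## ---- artifacts ----
  out <- cfg$output_dir
  paths <- c(config = file.path(out, "config.yaml"))
  cfgOut <- unclass(cfg)
  cfgOut$metrics <- as.list(cfgOut$metrics)
  yaml::write_yaml(cfgOut, paths[["config"]])

  metricRows <- do.call(rbind, lapply(groups, function(g) {
    ms <- metrics[[g]]; sw <- smallWorld[[g]]
    rbind(
      data.frame(group = g, density = dMin,
                 metric = c(.globalMetricNames, "gamma", "lambda", "sigma"),
                 node = NA_character_,
                 value = c(ms$clustering_mean, ms$path_length,
                           ms$transitivity, ms$modularity,
                           ms$global_efficiency, sw$gamma, sw$lambda,
                           sw$sigma), stringsAsFactors = FALSE),
      data.frame(group = g, density = dMin, metric = "betweenness",
                 node = names(ms$betweenness),
                 value = as.numeric(ms$betweenness),
                 stringsAsFactors = FALSE))
  }))
  paths["metrics"] <- file.path(out, "metrics.csv")
  write.csv(metricRows, paths[["metrics"]], row.names = FALSE)

  hubTable <- do.call(rbind, lapply(groups, function(g)
    cbind(group = g, density = dMin, hubs[[g]])))
  hubTable <- hubTable[order(hubTable$group, hubTable$lobe,
                             -hubTable$z), ]
  paths["hubs"] <- file.path(out, "hubs.csv")
  write.csv(hubTable, paths[["hubs"]], row.names = FALSE)

  paths["global_inference"] <- file.path(out, "global_inference.csv")
  write.csv(globalTable, paths[["global_inference"]], row.names = FALSE)
  paths["regional_inference"] <- file.path(out, "regional_inference.csv")
  write.csv(regional, paths[["regional_inference"]], row.names = FALSE)

  for (g in groups) {
    paths[paste0("association_", g)] <-
      writeAssociationCSV(Rs[[g]], file.path(out, paste0("association_", g,
                                                         ".csv")))
    paths[paste0("network_", g)] <-
      writeGraphML(networks[[g]], file.path(out, paste0("network_", g,
                                                        ".graphml")))
    paths[paste0("edges_", g)] <-
      writeEdgeList(networks[[g]], file.path(out, paste0("edges_", g,
                                                         ".tsv")))
  }

  log$density <- list(d_min = dMin, d_max = dMax, step = cfg$density_step)
  log$elapsed_sec <- round(as.numeric(difftime(Sys.time(), t0,
                                               units = "secs")), 2)
  paths["log"] <- file.path(out, "run_log.json")
  jsonlite::write_json(log, paths[["log"]], auto_unbox = TRUE, pretty = TRUE)

  invisible(list(experiment = x, residuals = res, association = Rs,
                 dMin = dMin, dMax = dMax, grid = grid,
                 networks = networks, metrics = metrics,
                 smallWorld = smallWorld, hubs = hubs,
                 global = globalTable, regional = regional,
                 paths = paths, config = cfg))
}
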