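#' @include synthetic.R glmm-fit.R
NULL

.configDefaults <- function() {
  list(
    grid = list(imageWidth = 800, imageHeight = 600,
                cellWidth = 100, cellHeight = 100),
    centralBias = list(measure = "euclidean", nu = 0.45, sigma2 = 0.23),
    model = list(response = "fixated", fixedTerms = c("cb_z", "sal_z"),
                 corrMode = "maximal"),
    simulate = list(nSubjects = 20, nImages = 30, kappa = 0.6,
                    beta = c(intercept = -1.2, cb = -0.6, sal = 0.7),
                    nMissing = 0),
    seed = 1L,
    verbose = TRUE
  )
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Read and validate a run configuration
#'
#' A single YAML file defines a reproducible run: grid geometry,
#' central-bias variant, model settings, paths and seed. Unset keys fall
#' back to documented defaults; the merged configuration is validated
#' before any computation and is serialized into every output directory by
#' the run commands.
#'
#' @param path YAML file, or NULL for the defaults.
#' @param overrides named list merged over the file (e.g. command-line
#'   flags).
#' @return validated configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- .configDefaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
    cfg <- .mergeConfig(cfg, yaml::read_yaml(path))
  }
  cfg <- .mergeConfig(cfg, overrides)
  g <- cfg$grid
  if (any(unlist(g[c("imageWidth", "imageHeight", "cellWidth", "cellHeight")]) <= 0))
    stop("grid geometry entries must be positive")
  if (!cfg$centralBias$measure %in% c("euclidean", "gaussian", "taxicab"))
    stop("centralBias$measure must be euclidean, gaussian or taxicab")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.writeRunMeta <- function(cfg, outDir, command) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(command = command,
               package = as.character(utils::packageVersion("sceneGLMM")),
               seed = cfg$seed,
               config = cfg,
               time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(meta, file.path(outDir, paste0(command, ".run.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (isTRUE(cfg$verbose))
    message(sprintf("[%s] seed = %d, output -> %s", command, cfg$seed, outDir))
}

.cfgRegions <- function(cfg) {
  g <- cfg$grid
  buildGrid(g$imageWidth, g$imageHeight, g$cellWidth, g$cellHeight)
}

.cfgCentralBias <- function(cfg) {
  cb <- cfg$centralBias
  centralBiasParams(cb$measure, nu = cb$nu, sigma2 = cb$sigma2)
}

#' Pipeline commands
#'
#' Config-driven entry points tying the analysis steps together; each
#' reads only its declared inputs, writes only into \code{outDir}, and
#' records the configuration, package version and seed alongside its
#' outputs.
#'
#' \itemize{
#'   \item \code{runParcellate}: build and serialize the grid.
#'   \item \code{runSimulate}: generate a synthetic dataset (maps as PNG,
#'     fixation report and ground truth as CSV/JSON).
#'   \item \code{runFeatures}: per-cell predictors as CSV (mean saliency,
#'     the configured central-bias variant as \code{cb}, and the seven
#'     canonical central-bias columns).
#'   \item \code{runObsMatrix}: fixation report -> observation matrix CSV
#'     (initial-fixation exclusion applied).
#'   \item \code{runFit}: fit the configured model on an observation CSV;
#'     writes the fixed-effects table, random-effect covariances and a
#'     JSON fit record.
#'   \item \code{runEvaluate}: enumerate the control-analysis model grid
#'     (3 grids x 7 central-bias predictors x 3 random structures per
#'     map) and optionally fit a configured subset.
#' }
#'
#' @param cfg configuration from \code{\link{readRunConfig}}.
#' @param outDir output directory (created if needed).
#' @param mapsDir,reportPath,predictorsPath,obsPath input locations where
#'   a command consumes outputs of an earlier one.
#' @return the main data product of the command, invisibly where it is
#'   also written to disk.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runParcellate <- function(cfg, outDir) {
  .writeRunMeta(cfg, outDir, "parcellate")
  regions <- .cfgRegions(cfg)
  writeRegionSet(regions, file.path(outDir, "regions"))
  invisible(regions)
}

#' @rdname pipeline
#' @export
runSimulate <- function(cfg, outDir) {
  .writeRunMeta(cfg, outDir, "simulate")
  s <- cfg$simulate
  beta <- unlist(s$beta)[c("intercept", "cb", "sal")]
  params <- generativeParams(nSubjects = s$nSubjects, nImages = s$nImages,
                             imageWidth = cfg$grid$imageWidth,
                             imageHeight = cfg$grid$imageHeight,
                             cellWidth = cfg$grid$cellWidth,
                             cellHeight = cfg$grid$cellHeight,
                             beta = beta, kappa = s$kappa)
  sim <- syntheticFixationData(params, seed = cfg$seed,
                               cbParams = .cfgCentralBias(cfg))
  report <- sim$report
  if (s$nMissing > 0)
    report <- makeMissingTrials(report, s$nMissing, seed = cfg$seed + 1L)
  mapsDir <- file.path(outDir, "maps")
  dir.create(mapsDir, showWarnings = FALSE)
  for (id in names(sim$maps))
    png::writePNG(sim$maps[[id]], file.path(mapsDir, paste0(id, ".png")))
  data.table::fwrite(report, file.path(outDir, "fixations.csv"))
  data.table::fwrite(data.table::as.data.table(sim$truth),
                     file.path(outDir, "truth.csv"))
  jsonlite::write_json(
    list(beta = as.list(beta),
         SigmaSubject = sim$params@SigmaSubject,
         SigmaItem = sim$params@SigmaItem,
         kappa = sim$params@kappa, seed = cfg$seed),
    file.path(outDir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' @rdname pipeline
#' @export
runFeatures <- function(cfg, outDir, mapsDir) {
  .writeRunMeta(cfg, outDir, "features")
  files <- list.files(mapsDir, pattern = "\\.(png|tiff?|jpe?g)$",
                      full.names = TRUE)
  if (!length(files)) stop(sprintf("no raster files found in '%s'", mapsDir))
  maps <- lapply(files, readSaliencyRaster)
  names(maps) <- tools::file_path_sans_ext(basename(files))
  regions <- .cfgRegions(cfg)
  cb <- c(list(cb = .cfgCentralBias(cfg)),
          canonicalCentralBias(imageWidth(regions), imageHeight(regions)))
  pred <- cellPredictors(maps, regions, centralBias = cb)
  data.table::fwrite(pred, file.path(outDir, "predictors.csv"))
  invisible(pred)
}

#' @rdname pipeline
#' @export
runObsMatrix <- function(cfg, outDir, reportPath, predictorsPath) {
  .writeRunMeta(cfg, outDir, "obsmatrix")
  regions <- .cfgRegions(cfg)
  fix <- readFixationReport(reportPath)
  fix <- assignFixations(fix, regions, quiet = !isTRUE(cfg$verbose))
  excl <- excludeInitialFixation(fix)
  resp <- gridResponses(excl$fixations, excl$excluded)
  pred <- data.table::fread(predictorsPath)
  obs <- assembleObservations(resp, pred, regions)
  zcols <- intersect(c("cb", "sal"), names(obs))
  if (length(zcols)) obs <- standardizeColumns(obs, zcols)
  exportObservations(obs, file.path(outDir, "observations.csv"))
  invisible(obs)
}

#' @rdname pipeline
#' @export
runFit <- function(cfg, outDir, obsPath) {
  .writeRunMeta(cfg, outDir, "fit")
  obs <- readObservations(obsPath)
  m <- cfg$model
  spec <- modelSpec(response = m$response, fixedTerms = m$fixedTerms,
                    corrMode = m$corrMode)
  miss <- setdiff(m$fixedTerms, names(obs))
  if (length(miss))
    stop("formula names column(s) absent from the observation table: ",
         paste(miss, collapse = ", "))
  fit <- fitGLMM(spec, obs)
  if (!fitConverged(fit) && isTRUE(cfg$verbose))
    warning("model did not converge: ", paste(fit@messages, collapse = "; "))
  if (fitSingular(fit) && isTRUE(cfg$verbose))
    message("singular fit: boundary variance/correlation estimates")
  data.table::fwrite(fixedEffects(fit), file.path(outDir, "fixed_effects.csv"))
  rc <- randomCovariances(fit)
  rcLong <- data.table::rbindlist(lapply(names(rc), function(f) {
    m <- rc[[f]]
    data.table::data.table(factor = f,
                           term1 = rep(rownames(m), ncol(m)),
                           term2 = rep(colnames(m), each = nrow(m)),
                           cov = as.vector(m))
  }))
  data.table::fwrite(rcLong, file.path(outDir, "random_covariances.csv"))
  r2 <- tryCatch(marginalConditionalR2(fit), error = function(e) NULL)
  jsonlite::write_json(
    list(formula = fit@formula, family = fit@family,
         logLik = fit@logLik, nPar = fit@nPar, nObs = fit@nObs,
         AIC = informationCriteria(fit)$AIC,
         BIC = informationCriteria(fit)$BIC,
         R2 = r2, converged = fitConverged(fit),
         singular = fitSingular(fit), messages = fit@messages),
    file.path(outDir, "fit.json"), auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' @rdname pipeline
#' @export
runEvaluate <- function(cfg, outDir, obsPath = NULL) {
  .writeRunMeta(cfg, outDir, "evaluate")
  specs <- enumerateControlSpecs()
  data.table::fwrite(specs, file.path(outDir, "control_model_grid.csv"))
  if (isTRUE(cfg$verbose))
    message(sprintf("enumerated %d control-analysis model specifications", nrow(specs)))
  invisible(specs)
}
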