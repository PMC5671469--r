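#' @include fixations.R centralbias.R
NULL

#' Per-cell predictor table for a set of saliency maps
#'
#' Computes, for every (image, cell), the mean normalized saliency of each
#' map and the requested central-bias predictors, yielding the predictor
#' side of the observation matrix.
#'
#' @param maps an \code{\linkS4class{ImageSet}} or a named list of saliency
#'   matrices (one map per image).
#' @param regions a \code{\linkS4class{RegionSet}}.
#' @param centralBias named list of \code{\linkS4class{CentralBiasParams}}
#'   (default: the seven canonical predictors); names become columns.
#' @param normalize min-max normalize each map before averaging (default
#'   TRUE).
#' @return data.table keyed by (image, cell) with one saliency column per
#'   model (\code{sal_<model>}, or \code{sal} for plain lists) and one
#'   column per central-bias predictor.
#' @export
cellPredictors <- function(maps, regions,
                           centralBias = canonicalCentralBias(
                             imageWidth(regions), imageHeight(regions)),
                           normalize = TRUE) {
  stopifnot(is(regions, "RegionSet"))
  if (is(maps, "ImageSet")) {
    ids <- imageIDs(maps)
    models <- mapNames(maps)
    getRaster <- function(id, m) getMap(maps, id, m)
    salNames <- paste0("sal_", models)
  } else {
    ids <- names(maps)
    if (is.null(ids)) stop("maps list must be named by image ID")
    models <- "map"
    getRaster <- function(id, m) maps[[id]]
    salNames <- "sal"
  }
  n <- nRegions(regions)
  cbCols <- lapply(centralBias, function(p) centralBiasVector(regions, p))
  rows <- lapply(ids, function(id) {
    out <- data.table::data.table(image = id, cell = seq_len(n))
    for (k in seq_along(models)) {
      r <- getRaster(id, models[k])
      if (normalize)
        r <- withCallingHandlers(normalizeMap(r), warning = function(w) {
          warning(sprintf("image '%s': %s", id, conditionMessage(w)), call. = FALSE)
          invokeRestart("muffleWarning")
        })
      out[[salNames[k]]] <- extractMeanFeature(r, regions)
    }
    for (nm in names(cbCols)) out[[nm]] <- cbCols[[nm]]
    out
  })
  data.table::rbindlist(rows)
}

#' Assemble the long-format observation matrix
#'
#' Builds one row per (subject, image, cell) for every trial with fixation
#' data, minus the cell excluded by the initial-fixation rule, and joins
#' the per-(image, cell) predictors. A complete design of 42 subjects x
#' 150 images on a 48-cell grid yields 302,400 rows; missing trials and
#' excluded cells reduce the count accordingly.
#'
#' @param responses result of \code{\link{gridResponses}}.
#' @param predictors data.frame/data.table keyed by (image, cell) covering
#'   every (image, cell) present in the trials; missing coverage is an
#'   error.
#' @param regions a \code{\linkS4class{RegionSet}} (defines the cell
#'   range).
#' @return data.frame with columns subject, image, cell, fixated, count
#'   and all predictor columns; (subject, image, cell) unique.
#' @export
assembleObservations <- function(responses, predictors, regions) {
  stopifnot(is(regions, "RegionSet"))
  trials <- data.table::as.data.table(responses$trials)
  counts <- data.table::as.data.table(responses$counts)
  excluded <- data.table::as.data.table(responses$excluded)
  pred <- data.table::as.data.table(predictors)
  if (!all(c("image", "cell") %in% names(pred)))
    stop("predictors must have image and cell columns")
  n <- nRegions(regions)

  grid <- trials[, list(cell = seq_len(n)), by = c("subject", "image")]
  if (nrow(excluded)) {
    excl <- excluded[!is.na(excludedCell)]
    if (nrow(excl)) {
      grid <- grid[!excl, on = c(subject = "subject", image = "image",
                                 cell = "excludedCell")]
    }
  }
  grid <- merge(grid, counts, by = c("subject", "image", "cell"), all.x = TRUE)
  grid$count[is.na(grid$count)] <- 0L
  grid$fixated <- as.integer(grid$count >= 1L)

  pred$image <- as.character(pred$image)
  grid$image <- as.character(grid$image)
  out <- merge(grid, pred, by = c("image", "cell"), all.x = TRUE, sort = FALSE)
  predCols <- setdiff(names(pred), c("image", "cell"))
  if (length(predCols)) {
    bad <- !stats::complete.cases(out[, predCols, with = FALSE])
    if (any(bad)) {
      miss <- unique(out[bad, c("image", "cell"), with = FALSE])
      stop(sprintf("predictors missing for %d (image, cell) combination(s), e.g. image '%s' cell %d",
                   nrow(miss), miss$image[1L], miss$cell[1L]))
    }
  }
  data.table::setcolorder(out, c("subject", "image", "cell", "fixated", "count"))
  data.table::setorderv(out, c("subject", "image", "cell"))
  as.data.frame(out)
}

#' Standardize predictor columns
#'
#' Adds z-transformed copies of the named columns (centred at the sample
#' mean, scaled by the sample standard deviation with the n-1
#' denominator), suffixed \code{_z}; the raw columns are retained.
#' Standardization is computed over the rows of the table as given, i.e.
#' the rows that actually enter the model.
#'
#' @param table observation table (data.frame).
#' @param columns character vector of numeric column names.
#' @param suffix suffix for the standardized columns (default "_z").
#' @return the table with added standardized columns.
#' @export
standardizeColumns <- function(table, columns, suffix = "_z") {
  for (cl in columns) {
    if (!cl %in% names(table)) stop(sprintf("no column '%s'", cl))
    x <- table[[cl]]
    if (!is.numeric(x)) stop(sprintf("column '%s' is not numeric", cl))
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop(sprintf("column '%s' is constant; cannot standardize", cl))
    table[[paste0(cl, suffix)]] <- (x - mean(x)) / s
  }
  table
}

#' Rank correlation between two per-cell predictors
#'
#' Spearman's rank correlation between two predictor columns, computed
#' over unique (image, cell) pairs -- each cell of each image enters once,
#' not once per subject. Used to quantify the photographer bias: a
#' negative correlation between cell saliency and distance from centre
#' means high-salience content sits near the image centre.
#'
#' @param table a table with image, cell and the two columns (e.g. an
#'   observation table or a \code{\link{cellPredictors}} result).
#' @param colA,colB column names.
#' @return Spearman's rho.
#' @export
predictorCorrelation <- function(table, colA, colB) {
  dt <- data.table::as.data.table(table)
  for (cl in c(colA, colB))
    if (!cl %in% names(dt)) stop(sprintf("no column '%s'", cl))
  u <- unique(dt[, c("image", "cell", colA, colB), with = FALSE],
              by = c("image", "cell"))
  if (nrow(u) < 3L)
    stop("need at least 3 distinct (image, cell) pairs")
  a <- u[[colA]]
  b <- u[[colB]]
  if (length(unique(a)) == 1L || length(unique(b)) == 1L)
    stop("cannot rank-correlate a constant column")
  stats::cor(a, b, method = "spearman")
}

#' Export / read an observation table as CSV
#'
#' Comma-separated with a header row, stable column order and a
#' locale-independent decimal point.
#'
#' @param table observation table.
#' @param path output file.
#' @export
exportObservations <- function(table, path) {
  data.table::fwrite(data.table::as.data.table(table), path, sep = ",",
                     dec = ".", quote = "auto")
  invisible(path)
}

#' @rdname exportObservations
#' @export
readObservations <- function(path) {
  as.data.frame(data.table::fread(path, sep = ",", dec = "."))
}
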