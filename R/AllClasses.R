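#' @import methods
NULL

#' RegionSet: a parcellation of an image into labelled pixel regions
#'
#' A \code{RegionSet} partitions an image into disjoint pixel regions, here
#' the cells of a regular grid. Internally the partition is stored as an
#' integer label matrix (one entry per pixel, 0 = not covered); per-region
#' binary masks are materialised on demand by \code{\link{regionMask}}, so
#' the representation extends to irregular regions (e.g. object outlines)
#' without API changes.
#'
#' Pixel coordinates are 0-based; a grid cell is the half-open rectangle
#' \code{[x0, x0+cw) x [y0, y0+ch)}, so every interior pixel belongs to
#' exactly one cell. Raster matrices are indexed \code{[y+1, x+1]}.
#'
#' @slot labels integer matrix (height x width); entry = region index
#'   (1..n) of the pixel, 0 if uncovered (only possible with truncation).
#' @slot centers numeric matrix (n x 2) of region centre coordinates
#'   (x, y) in pixels.
#' @slot shape integer(2): grid columns, rows.
#' @slot cellSize numeric(2): cell width, height in pixels.
#' @slot imageWidth,imageHeight image dimensions in pixels.
#'
#' @seealso \code{\link{buildGrid}}, \code{\link{extractMeanFeature}}
#' @export
setClass("RegionSet",
  representation(
    labels = "matrix",
    centers = "matrix",
    shape = "integer",
    cellSize = "numeric",
    imageWidth = "numeric",
    imageHeight = "numeric"
  )
)

setValidity("RegionSet", function(object) {
  msg <- character()
  n <- nrow(object@centers)
  if (ncol(object@centers) != 2L)
    msg <- c(msg, "centers must have two columns (x, y)")
  if (length(object@shape) != 2L || any(object@shape < 1L))
    msg <- c(msg, "shape must be two positive integers (columns, rows)")
  if (prod(object@shape) != n)
    msg <- c(msg, "number of regions must equal columns x rows")
  if (nrow(object@labels) != object@imageHeight ||
      ncol(object@labels) != object@imageWidth)
    msg <- c(msg, "label matrix must be imageHeight x imageWidth")
  lab <- object@labels
  if (length(lab) && (min(lab) < 0L || max(lab) > n))
    msg <- c(msg, "labels out of range")
  if (length(msg)) msg else TRUE
})

#' ImageSet: scenes and saliency maps keyed by image ID
#'
#' Associates each image ID with zero or one scene raster and any number of
#' named saliency maps. All rasters for an ID must share the set's
#' dimensions. Saliency rasters are numeric matrices indexed
#' \code{[y+1, x+1]}.
#'
#' @slot saliency named list; \code{saliency[[imageID]][[modelName]]} is a
#'   numeric matrix.
#' @slot scenes named list of scene rasters (may be empty).
#' @slot width,height image dimensions in pixels.
#' @export
setClass("ImageSet",
  representation(
    saliency = "list",
    scenes = "list",
    width = "numeric",
    height = "numeric"
  )
)

setValidity("ImageSet", function(object) {
  msg <- character()
  ids <- names(object@saliency)
  if (length(object@saliency) && (is.null(ids) || anyDuplicated(ids)))
    msg <- c(msg, "image IDs must be unique and named")
  for (id in ids) {
    for (m in object@saliency[[id]]) {
      if (!is.matrix(m) ||
          nrow(m) != object@height || ncol(m) != object@width) {
        msg <- c(msg, sprintf("raster dimensions for image '%s' differ from set dimensions", id))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' CentralBiasParams: a distance-to-centre predictor definition
#'
#' Defines one member of the distance-to-centre family used to model the
#' central fixation bias: Euclidean, (negated) Gaussian, or taxicab
#' distance of a cell centre to the image centre, with optional vertical
#' anisotropy. Coordinates are normalised so that half the image width
#' equals 1 and the image centre is (0, 0); the Gaussian variance
#' \code{sigma2} is expressed in those units (default 0.23), and \code{nu}
#' scales the vertical dimension (1 = isotropic, image height/width =
#' aspect-ratio scaling, 0.45 = default anisotropic value reflecting the
#' horizontally elongated spread of scene-viewing fixations).
#'
#' The taxicab measure has no anisotropic variant; constructing one is an
#' error rather than a silent extension.
#'
#' @slot measure one of "euclidean", "gaussian", "taxicab".
#' @slot nu vertical anisotropy parameter (> 0, dimensionless).
#' @slot sigma2 horizontal Gaussian variance in units of half the image
#'   width (> 0; ignored by the Euclidean and taxicab measures).
#' @seealso \code{\link{centralBiasParams}}, \code{\link{centralBiasVector}}
#' @export
setClass("CentralBiasParams",
  representation(measure = "character", nu = "numeric", sigma2 = "numeric")
)

setValidity("CentralBiasParams", function(object) {
  msg <- character()
  if (!object@measure %in% c("euclidean", "gaussian", "taxicab"))
    msg <- c(msg, "measure must be 'euclidean', 'gaussian' or 'taxicab'")
  if (!is.finite(object@nu) || object@nu <= 0)
    msg <- c(msg, "nu must be a positive number")
  if (!is.finite(object@sigma2) || object@sigma2 <= 0)
    msg <- c(msg, "sigma2 must be a positive number")
  if (object@measure == "taxicab" && object@nu != 1)
    msg <- c(msg, "the taxicab measure has no anisotropic variant (nu must be 1)")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: a mixed-model specification
#'
#' Describes a generalized linear mixed model for grid-cell fixation data:
#' the response and family, the fixed-effect terms (intercept always
#' included), an optional treatment-coded saliency-map factor with its
#' interactions, and per-grouping-factor random-effect structures.
#'
#' Random structures follow the standard taxonomy: \code{"maximal"} (all
#' slopes plus correlations), \code{"zcp"} (slopes, zero correlations) and
#' \code{"intercept"} (random intercepts only).
#'
#' @slot response response column name ("fixated" or "count").
#' @slot family "binomial" (logit link) or "poisson" (log link).
#' @slot fixedTerms character vector of fixed-effect column names,
#'   excluding the intercept. For map-comparison models these include the
#'   expanded interaction dummy columns (see \code{\link{expandMapDummies}}).
#' @slot mapFactor name of the saliency-map factor column, or NA.
#' @slot mapLevels,reference factor levels and reference level.
#' @slot randomTerms named list (one entry per grouping factor) of slope
#'   column names; the random intercept is always included.
#' @slot corrMode named character; per grouping factor one of "maximal",
#'   "zcp", "intercept".
#' @slot groups named character mapping grouping-factor names to data
#'   columns, e.g. c(subject = "subject", item = "image").
#' @seealso \code{\link{modelSpec}}, \code{\link{comparisonSpec}},
#'   \code{\link{fitGLMM}}
#' @export
setClass("ModelSpec",
  representation(
    response = "character",
    family = "character",
    fixedTerms = "character",
    mapFactor = "character",
    mapLevels = "character",
    reference = "character",
    randomTerms = "list",
    corrMode = "character",
    groups = "character"
  )
)

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@family %in% c("binomial", "poisson"))
    msg <- c(msg, "family must be 'binomial' or 'poisson'")
  if (!all(object@corrMode %in% c("maximal", "zcp", "intercept")))
    msg <- c(msg, "corrMode entries must be 'maximal', 'zcp' or 'intercept'")
  if (length(object@groups) < 1L || is.null(names(object@groups)))
    msg <- c(msg, "groups must be a named character vector")
  if (!identical(sort(names(object@randomTerms)), sort(names(object@groups))))
    msg <- c(msg, "randomTerms must have one entry per grouping factor")
  if (!identical(sort(names(object@corrMode)), sort(names(object@groups))))
    msg <- c(msg, "corrMode must have one entry per grouping factor")
  for (f in names(object@randomTerms)) {
    extra <- setdiff(object@randomTerms[[f]], object@fixedTerms)
    if (length(extra))
      msg <- c(msg, sprintf("random slope term(s) %s for factor '%s' are not fixed terms",
                            paste(sQuote(extra), collapse = ", "), f))
  }
  if (!is.na(object@mapFactor)) {
    if (length(object@mapLevels) < 2L)
      msg <- c(msg, "a map factor needs at least two levels")
    if (!object@reference %in% object@mapLevels)
      msg <- c(msg, sprintf("reference level '%s' is not among the map levels", object@reference))
  }
  if (length(msg)) msg else TRUE
})

#' GLMMFit: a fitted generalized linear mixed model
#'
#' Container for everything the downstream inferential tools need: the
#' Wald table of fixed effects, random-effect covariance matrices,
#' log-likelihood and parameter/observation counts, conditional modes and
#' conditional variances of the random effects, and convergence/singularity
#' diagnostics. The underlying fit object (if any) is kept in \code{@fit}
#' for methods that need the model matrices.
#'
#' @slot fixed data.frame with columns term, b, se, z, p.
#' @slot vcovRandom named list of random-effect covariance matrices.
#' @slot logLik maximised log-likelihood (Laplace approximation).
#' @slot nPar number of estimated parameters (fixed + variances +
#'   correlations).
#' @slot nObs number of observations.
#' @slot condModes named list; per grouping factor a matrix
#'   (levels x terms) of conditional modes.
#' @slot condVars named list; matching matrices of conditional variances.
#' @slot linPredFixed numeric; fixed-effects linear predictor per row.
#' @slot family,formula character descriptors.
#' @slot converged,singular logical diagnostics.
#' @slot messages character; optimizer/convergence messages, if any.
#' @slot fit underlying \code{merMod} object or NULL.
#' @export
setClass("GLMMFit",
  representation(
    fixed = "data.frame",
    vcovRandom = "list",
    logLik = "numeric",
    nPar = "integer",
    nObs = "integer",
    condModes = "list",
    condVars = "list",
    linPredFixed = "numeric",
    family = "character",
    formula = "character",
    converged = "logical",
    singular = "logical",
    messages = "character",
    fit = "ANY"
  )
)

setValidity("GLMMFit", function(object) {
  msg <- character()
  if (!all(c("term", "b", "se", "z", "p") %in% names(object@fixed)))
    msg <- c(msg, "fixed must have columns term, b, se, z, p")
  for (v in object@vcovRandom) {
    ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-6 * max(abs(ev), 1)))
      msg <- c(msg, "random-effect covariance matrices must be positive semi-definite")
  }
  if (length(msg)) msg else TRUE
})

#' GenerativeParams: ground truth for the synthetic-data generator
#'
#' Parameters of the generative binomial (or Poisson) mixed model used to
#' simulate per-cell fixation data, plus the saliency-map generator
#' settings. Fixed effects are on the standardized-predictor scale;
#' random-effect covariance matrices are 3 x 3 over (intercept,
#' central-bias slope, saliency slope).
#'
#' @slot nSubjects,nImages design size.
#' @slot imageWidth,imageHeight,cellWidth,cellHeight geometry in pixels.
#' @slot beta named numeric: intercept, cb, sal (log-odds / log scale).
#' @slot SigmaSubject,SigmaItem 3 x 3 random-effect covariance matrices.
#' @slot kappa photographer-bias strength (>= 0; 0 = blob centres uniform).
#' @slot nBlobs,blobSigma saliency-map blob count and width (pixels).
#' @slot response "binary" or "count".
#' @slot fixationsPerCell mean extra fixations per fixated cell (count
#'   response only).
#' @seealso \code{\link{generativeParams}}, \code{\link{syntheticFixationData}}
#' @export
setClass("GenerativeParams",
  representation(
    nSubjects = "integer",
    nImages = "integer",
    imageWidth = "numeric",
    imageHeight = "numeric",
    cellWidth = "numeric",
    cellHeight = "numeric",
    beta = "numeric",
    SigmaSubject = "matrix",
    SigmaItem = "matrix",
    kappa = "numeric",
    nBlobs = "integer",
    blobSigma = "numeric",
    response = "character",
    fixationsPerCell = "numeric"
  )
)

setValidity("GenerativeParams", function(object) {
  msg <- character()
  if (object@nSubjects < 1L || object@nImages < 1L)
    msg <- c(msg, "nSubjects and nImages must be positive")
  if (!identical(names(object@beta), c("intercept", "cb", "sal")))
    msg <- c(msg, "beta must be named c('intercept','cb','sal')")
  for (nm in c("SigmaSubject", "SigmaItem")) {
    S <- slot(object, nm)
    if (!identical(dim(S), c(3L, 3L)) || any(abs(S - t(S)) > 1e-10))
      msg <- c(msg, sprintf("%s must be a symmetric 3 x 3 matrix", nm))
    else if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
      msg <- c(msg, sprintf("%s must be positive semi-definite", nm))
  }
  if (!is.finite(object@kappa) || object@kappa < 0)
    msg <- c(msg, "kappa must be >= 0")
  if (!object@response %in% c("binary", "count"))
    msg <- c(msg, "response must be 'binary' or 'count'")
  if (length(msg)) msg else TRUE
})
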