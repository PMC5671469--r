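#' @include AllClasses.R
NULL

#' Number of regions in a RegionSet
#' @param x a \code{\linkS4class{RegionSet}}
#' @return integer
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname nRegions
#' @export
setMethod("nRegions", "RegionSet", function(x) nrow(x@centers))

#' Region centre coordinates
#' @param x a \code{\linkS4class{RegionSet}}
#' @return n x 2 matrix of (x, y) pixel coordinates
#' @export
setGeneric("regionCenters", function(x) standardGeneric("regionCenters"))

#' @rdname regionCenters
#' @export
setMethod("regionCenters", "RegionSet", function(x) x@centers)

#' Grid shape (columns, rows)
#' @param x a \code{\linkS4class{RegionSet}}
#' @export
setGeneric("regionShape", function(x) standardGeneric("regionShape"))

#' @rdname regionShape
#' @export
setMethod("regionShape", "RegionSet", function(x) x@shape)

#' Cell size in pixels (width, height)
#' @param x a \code{\linkS4class{RegionSet}}
#' @export
setGeneric("regionCellSize", function(x) standardGeneric("regionCellSize"))

#' @rdname regionCellSize
#' @export
setMethod("regionCellSize", "RegionSet", function(x) x@cellSize)

#' Integer label matrix of a RegionSet
#'
#' One entry per pixel giving the 1-based region index (0 = uncovered).
#' @param x a \code{\linkS4class{RegionSet}}
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname regionLabels
#' @export
setMethod("regionLabels", "RegionSet", function(x) x@labels)

#' Binary mask of one region
#' @param x a \code{\linkS4class{RegionSet}}
#' @param i region index (1-based)
#' @return logical matrix (height x width)
#' @export
setGeneric("regionMask", function(x, i) standardGeneric("regionMask"))

#' @rdname regionMask
#' @export
setMethod("regionMask", "RegionSet", function(x, i) {
  i <- as.integer(i)
  stopifnot(length(i) == 1L, i >= 1L, i <= nRegions(x))
  x@labels == i
})

#' Image dimensions of a RegionSet or ImageSet
#' @param x a \code{\linkS4class{RegionSet}} or \code{\linkS4class{ImageSet}}
#' @export
setGeneric("imageWidth", function(x) standardGeneric("imageWidth"))
#' @rdname imageWidth
#' @export
setGeneric("imageHeight", function(x) standardGeneric("imageHeight"))

#' @rdname imageWidth
#' @export
setMethod("imageWidth", "RegionSet", function(x) x@imageWidth)
#' @rdname imageWidth
#' @export
setMethod("imageHeight", "RegionSet", function(x) x@imageHeight)
#' @rdname imageWidth
#' @export
setMethod("imageWidth", "ImageSet", function(x) x@width)
#' @rdname imageWidth
#' @export
setMethod("imageHeight", "ImageSet", function(x) x@height)

#' Image IDs of an ImageSet
#' @param x an \code{\linkS4class{ImageSet}}
#' @export
setGeneric("imageIDs", function(x) standardGeneric("imageIDs"))

#' @rdname imageIDs
#' @export
setMethod("imageIDs", "ImageSet", function(x) names(x@saliency))

#' Saliency model names available in an ImageSet
#' @param x an \code{\linkS4class{ImageSet}}
#' @export
setGeneric("mapNames", function(x) standardGeneric("mapNames"))

#' @rdname mapNames
#' @export
setMethod("mapNames", "ImageSet", function(x) {
  unique(unlist(lapply(x@saliency, names), use.names = FALSE))
})

#' Retrieve one saliency map
#' @param x an \code{\linkS4class{ImageSet}}
#' @param image image ID
#' @param model saliency model name; if omitted and the image has exactly
#'   one map, that map is returned
#' @return numeric matrix
#' @export
setGeneric("getMap", function(x, image, model) standardGeneric("getMap"))

#' @rdname getMap
#' @export
setMethod("getMap", "ImageSet", function(x, image, model) {
  maps <- x@saliency[[as.character(image)]]
  if (is.null(maps))
    stop(sprintf("no image with ID '%s'", image))
  if (missing(model)) {
    if (length(maps) != 1L)
      stop("image has several saliency maps; name one")
    return(maps[[1L]])
  }
  m <- maps[[model]]
  if (is.null(m))
    stop(sprintf("image '%s' has no saliency map '%s'", image, model))
  m
})

#' Fixed-effects Wald table of a fit
#' @param object a \code{\linkS4class{GLMMFit}}
#' @return data.frame with columns term, b, se, z, p
#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))

#' @rdname fixedEffects
#' @export
setMethod("fixedEffects", "GLMMFit", function(object) object@fixed)

#' Random-effect covariance matrices of a fit
#' @param object a \code{\linkS4class{GLMMFit}}
#' @return named list of covariance matrices, one per grouping factor
#' @export
setGeneric("randomCovariances", function(object) standardGeneric("randomCovariances"))

#' @rdname randomCovariances
#' @export
setMethod("randomCovariances", "GLMMFit", function(object) object@vcovRandom)

#' @export
setMethod("logLik", "GLMMFit", function(object, ...) {
  structure(object@logLik, df = object@nPar, nobs = object@nObs,
            class = "logLik")
})

#' Number of estimated parameters / observations of a fit
#' @param object a \code{\linkS4class{GLMMFit}}
#' @export
setGeneric("nPar", function(object) standardGeneric("nPar"))
#' @rdname nPar
#' @export
setMethod("nPar", "GLMMFit", function(object) object@nPar)

#' @rdname nPar
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))
#' @rdname nPar
#' @export
setMethod("nObs", "GLMMFit", function(object) object@nObs)

#' Convergence and singularity diagnostics
#' @param object a \code{\linkS4class{GLMMFit}}
#' @export
setGeneric("fitConverged", function(object) standardGeneric("fitConverged"))
#' @rdname fitConverged
#' @export
setMethod("fitConverged", "GLMMFit", function(object) object@converged)

#' @rdname fitConverged
#' @export
setGeneric("fitSingular", function(object) standardGeneric("fitSingular"))
#' @rdname fitConverged
#' @export
setMethod("fitSingular", "GLMMFit", function(object) object@singular)

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet: %d x %d grid (%d regions) of %g x %g px cells on a %g x %g px image\n",
              object@shape[1L], object@shape[2L], nRegions(object),
              object@cellSize[1L], object@cellSize[2L],
              object@imageWidth, object@imageHeight))
})

setMethod("show", "ImageSet", function(object) {
  cat(sprintf("ImageSet: %d image(s), %g x %g px; saliency models: %s\n",
              length(object@saliency), object@width, object@height,
              paste(mapNames(object), collapse = ", ")))
})

setMethod("show", "CentralBiasParams", function(object) {
  cat(sprintf("CentralBiasParams: measure = %s, nu = %g, sigma2 = %g\n",
              object@measure, object@nu, object@sigma2))
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec (", object@family, "):\n  ", buildFormula(object), "\n", sep = "")
})

setMethod("show", "GLMMFit", function(object) {
  cat(sprintf("GLMMFit (%s): %d obs, %d parameters, logLik = %.2f\n",
              object@family, object@nObs, object@nPar, object@logLik))
  if (!object@converged) cat("  ** did not converge **\n")
  if (object@singular) cat("  ** singular fit (boundary variance/correlation) **\n")
  cat("Fixed effects:\n")
  print(object@fixed, row.names = FALSE, digits = 4)
})

setMethod("show", "GenerativeParams", function(object) {
  cat(sprintf("GenerativeParams: %d subjects x %d images, %g x %g px, %g x %g px cells\n",
              object@nSubjects, object@nImages, object@imageWidth,
              object@imageHeight, object@cellWidth, object@cellHeight))
  cat(sprintf("  beta = (%.3f, %.3f, %.3f), kappa = %g, response = %s\n",
              object@beta[["intercept"]], object@beta[["cb"]],
              object@beta[["sal"]], object@kappa, object@response))
})
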