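#' @include AllClasses.R
NULL

#' Construct central-bias parameters
#'
#' @param measure "euclidean", "gaussian" or "taxicab".
#' @param nu vertical anisotropy (> 0): 1 for the isotropic variant, the
#'   inverse aspect ratio (image height / width) for the aspect-ratio
#'   variant, and 0.45 as the default anisotropic value. The aspect-ratio
#'   and anisotropic variants coincide when \code{nu} equals the inverse
#'   aspect ratio.
#' @param sigma2 horizontal Gaussian variance in units of half the image
#'   width (default 0.23). The Gaussian's vertical variance is
#'   \code{nu * sigma2} (0.1035 with the defaults, i.e. about 0.10).
#' @return a \code{\linkS4class{CentralBiasParams}}
#' @examples
#' centralBiasParams("gaussian", nu = 0.45)           # anisotropic Gaussian
#' centralBiasParams("euclidean", nu = 1)             # isotropic Euclidean
#' @export
centralBiasParams <- function(measure = c("euclidean", "gaussian", "taxicab"),
                              nu = 1, sigma2 = 0.23) {
  measure <- match.arg(measure)
  new("CentralBiasParams", measure = measure, nu = nu, sigma2 = sigma2)
}

#' Anisotropic Euclidean distance to the image centre
#'
#' \code{sqrt(dx^2 + dy^2 / nu)} for normalized offsets (dx, dy) of a cell
#' centre from the image centre. \code{nu = 1} gives the isotropic
#' distance; smaller \code{nu} penalizes vertical offsets more, reflecting
#' the horizontally elongated spread of fixations in scene viewing.
#'
#' @param dx,dy normalized offsets (half image width = 1); vectorized.
#' @param nu vertical anisotropy (> 0).
#' @return numeric vector of distances (>= 0).
#' @export
euclideanCB <- function(dx, dy, nu = 1) {
  if (!is.finite(nu) || nu <= 0) stop("nu must be a positive number")
  sqrt(dx^2 + dy^2 / nu)
}

#' Negated Gaussian central-bias value
#'
#' \code{-exp(-dx^2 / (2 sigma2) - dy^2 / (2 sigma2 nu))}: the density
#' shape of a centre-anchored bivariate Gaussian, negated so that
#' increasing values correspond to more peripheral locations (like the
#' distance measures). Values lie in (-1, 0], with -1 exactly at the image
#' centre.
#'
#' @inheritParams euclideanCB
#' @param sigma2 horizontal variance in units of half the image width.
#' @export
gaussianCB <- function(dx, dy, sigma2 = 0.23, nu = 1) {
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be a positive number")
  if (!is.finite(nu) || nu <= 0) stop("nu must be a positive number")
  -exp(-dx^2 / (2 * sigma2) - dy^2 / (2 * sigma2 * nu))
}

#' Taxicab (Manhattan, L1) distance to the image centre
#'
#' \code{|dx| + |dy|}; the natural block distance on a grid. No
#' aspect-ratio or anisotropic variant exists for this measure.
#'
#' @inheritParams euclideanCB
#' @export
taxicabCB <- function(dx, dy) {
  abs(dx) + abs(dy)
}

#' Normalized cell-centre offsets from the image centre
#'
#' Converts cell-centre pixel coordinates to the coordinate convention the
#' central-bias measures are defined in: the image centre is (0, 0) and
#' half the image width equals 1 (both axes are scaled by half the image
#' width, so the vertical extent of a 4:3 image runs to +/- 0.75). A single
#' convention keeps all central-bias variants commensurable before
#' standardization.
#'
#' @param regions a \code{\linkS4class{RegionSet}}
#' @return n x 2 matrix with columns dx, dy.
#' @export
normalizeCellCenters <- function(regions) {
  stopifnot(is(regions, "RegionSet"))
  half <- regions@imageWidth / 2
  cbind(dx = (regions@centers[, "x"] - regions@imageWidth / 2) / half,
        dy = (regions@centers[, "y"] - regions@imageHeight / 2) / half)
}

#' Per-cell central-bias predictor values
#'
#' Applies the selected distance-to-centre measure to every cell centre of
#' the grid, in region order.
#'
#' @param regions a \code{\linkS4class{RegionSet}}
#' @param params a \code{\linkS4class{CentralBiasParams}}
#' @return numeric vector of length \code{nRegions(regions)}.
#' @export
centralBiasVector <- function(regions, params) {
  stopifnot(is(params, "CentralBiasParams"))
  validObject(params)
  d <- normalizeCellCenters(regions)
  switch(params@measure,
    euclidean = euclideanCB(d[, "dx"], d[, "dy"], nu = params@nu),
    gaussian = gaussianCB(d[, "dx"], d[, "dy"], sigma2 = params@sigma2,
                          nu = params@nu),
    taxicab = taxicabCB(d[, "dx"], d[, "dy"])
  )
}

#' The seven canonical central-bias predictor definitions
#'
#' Enumerates the canonical family: Euclidean and Gaussian measures in
#' isotropic (\code{nu = 1}), aspect-ratio (\code{nu = height/width}) and
#' anisotropic (\code{nu = 0.45}) variants, plus the taxicab distance --
#' seven predictors in total.
#'
#' @param imageWidth,imageHeight image dimensions in pixels (set the
#'   aspect-ratio variant's \code{nu}).
#' @param sigma2 Gaussian horizontal variance (default 0.23).
#' @param nuAnisotropic anisotropy default (0.45).
#' @return named list of \code{\linkS4class{CentralBiasParams}}.
#' @export
canonicalCentralBias <- function(imageWidth, imageHeight, sigma2 = 0.23,
                                 nuAnisotropic = 0.45) {
  aspect <- imageHeight / imageWidth
  list(
    cb_euclidean_iso = centralBiasParams("euclidean", nu = 1, sigma2 = sigma2),
    cb_euclidean_aspect = centralBiasParams("euclidean", nu = aspect, sigma2 = sigma2),
    cb_euclidean_aniso = centralBiasParams("euclidean", nu = nuAnisotropic, sigma2 = sigma2),
    cb_gaussian_iso = centralBiasParams("gaussian", nu = 1, sigma2 = sigma2),
    cb_gaussian_aspect = centralBiasParams("gaussian", nu = aspect, sigma2 = sigma2),
    cb_gaussian_aniso = centralBiasParams("gaussian", nu = nuAnisotropic, sigma2 = sigma2),
    cb_taxicab = centralBiasParams("taxicab")
  )
}
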