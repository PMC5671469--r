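#' @include AllClasses.R
NULL

#' Parcellate an image into a regular grid of rectangular regions
#'
#' Builds the grid of scene patches over which fixation responses and
#' per-cell predictors are defined. Cells are produced in row-major order
#' (left to right, then top to bottom); cell \code{(col, row)} covers the
#' half-open pixel rectangle \code{[col*cw, (col+1)*cw) x [row*ch,
#' (row+1)*ch)} and its centre is the rectangle midpoint. An 800 x 600
#' image with 100-px cells yields the default 8 x 6 grid of 48 quadratic
#' patches.
#'
#' By default the image dimensions must be divisible by the cell
#' dimensions, so the grid partitions the image exactly; partial cells at
#' the right/bottom margin would bias cell means. Set \code{truncate =
#' TRUE} to drop the remainder instead.
#'
#' @param imageWidth,imageHeight image dimensions in pixels.
#' @param cellWidth,cellHeight cell dimensions in pixels.
#' @param truncate if TRUE, a non-divisible right/bottom remainder is left
#'   uncovered (label 0) instead of raising an error.
#' @return a \code{\linkS4class{RegionSet}}
#' @examples
#' g <- buildGrid(800, 600, 100, 100)
#' nRegions(g)        # 48
#' regionShape(g)     # 8 columns, 6 rows
#' @export
buildGrid <- function(imageWidth, imageHeight, cellWidth, cellHeight,
                      truncate = FALSE) {
  if (any(c(imageWidth, imageHeight, cellWidth, cellHeight) <= 0))
    stop("image and cell dimensions must be positive")
  if (cellWidth > imageWidth || cellHeight > imageHeight)
    stop("cell dimensions must not exceed image dimensions")
  rx <- imageWidth %% cellWidth
  ry <- imageHeight %% cellHeight
  if ((rx != 0 || ry != 0) && !truncate)
    stop(sprintf(paste0("image dimensions (%g x %g) are not divisible by cell ",
                        "dimensions (%g x %g); set truncate = TRUE to drop the remainder"),
                 imageWidth, imageHeight, cellWidth, cellHeight))
  cols <- as.integer(imageWidth %/% cellWidth)
  rows <- as.integer(imageHeight %/% cellHeight)

  labels <- matrix(0L, nrow = imageHeight, ncol = imageWidth)
  colOfX <- rep(0:(cols - 1L), each = cellWidth)          # covered columns
  rowOfY <- rep(0:(rows - 1L), each = cellHeight)
  covX <- seq_along(colOfX)
  covY <- seq_along(rowOfY)
  labels[covY, covX] <- outer(rowOfY * cols, colOfX + 1L, `+`)

  cellCol <- rep(0:(cols - 1L), times = rows)             # row-major
  cellRow <- rep(0:(rows - 1L), each = cols)
  centers <- cbind(x = cellCol * cellWidth + cellWidth / 2,
                   y = cellRow * cellHeight + cellHeight / 2)

  new("RegionSet", labels = labels, centers = centers,
      shape = c(cols, rows), cellSize = c(cellWidth, cellHeight),
      imageWidth = as.numeric(imageWidth), imageHeight = as.numeric(imageHeight))
}

#' Min-max normalize a saliency map to [0, 1]
#'
#' Affine rescaling per map: the minimum maps to 0 and the maximum to 1.
#' Saliency algorithms emit values on arbitrary scales; a common range
#' makes cell means comparable across maps (the GLMM standardization later
#' absorbs any remaining scale). A constant map has no defined scale and is
#' returned as all zeros with a warning.
#'
#' @param raster numeric matrix with finite values.
#' @return numeric matrix of the same dimensions with values in [0, 1].
#' @export
normalizeMap <- function(raster) {
  if (!is.matrix(raster) || !is.numeric(raster))
    stop("raster must be a numeric matrix")
  if (!all(is.finite(raster)))
    stop("raster contains non-finite values")
  rng <- range(raster)
  if (rng[1L] == rng[2L]) {
    warning("constant raster: no scale defined, returning all zeros")
    return(array(0, dim(raster)))
  }
  (raster - rng[1L]) / (rng[2L] - rng[1L])
}

#' Mean raster value per region
#'
#' Local saliency of a patch is the arithmetic mean of the saliency map's
#' values under the patch mask. Returns one value per region, in region
#' order.
#'
#' @param raster numeric matrix matching the RegionSet's image dimensions.
#' @param regions a \code{\linkS4class{RegionSet}}.
#' @return numeric vector of length \code{nRegions(regions)}.
#' @export
extractMeanFeature <- function(raster, regions) {
  stopifnot(is(regions, "RegionSet"))
  if (!is.matrix(raster) ||
      nrow(raster) != regions@imageHeight || ncol(raster) != regions@imageWidth)
    stop(sprintf("raster dimensions (%d x %d) do not match the RegionSet image (%g x %g)",
                 nrow(raster), ncol(raster),
                 regions@imageHeight, regions@imageWidth))
  lab <- as.vector(regions@labels)
  keep <- lab > 0L
  n <- nRegions(regions)
  sums <- rowsum(as.vector(raster)[keep], lab[keep], reorder = TRUE)
  counts <- tabulate(lab[keep], nbins = n)
  out <- rep(NA_real_, n)
  out[as.integer(rownames(sums))] <- sums[, 1L] / counts[as.integer(rownames(sums))]
  out
}

#' Read a saliency raster from a PNG, TIFF or JPEG file
#'
#' Multi-channel images are collapsed to a single luminance channel with
#' Rec. 709 weights (0.2126 R + 0.7152 G + 0.0722 B); an alpha channel is
#' ignored. The paper's workflow treats saliency maps as single-channel
#' grayscale rasters, so any conversion policy beyond this default is left
#' to the user (convert upstream and save grayscale).
#'
#' @param path file path; format inferred from the extension.
#' @return numeric matrix indexed \code{[y+1, x+1]} with values in [0, 1]
#'   as stored in the file.
#' @export
readSaliencyRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported raster format '%s' (use PNG, TIFF or JPEG)", ext))
  )
  if (length(dim(img)) == 2L) return(img)
  nc <- dim(img)[3L]
  if (nc >= 3L)
    0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
  else
    img[, , 1L]
}

#' Construct an ImageSet
#'
#' @param saliency named list (by image ID) of named lists (by model) of
#'   numeric matrices, or a named list of single matrices (wrapped as model
#'   \code{"map"}).
#' @param scenes optional named list of scene rasters.
#' @param width,height image dimensions; inferred from the first raster if
#'   omitted.
#' @return an \code{\linkS4class{ImageSet}}
#' @export
imageSet <- function(saliency, scenes = list(), width = NULL, height = NULL) {
  saliency <- lapply(saliency, function(x) if (is.matrix(x)) list(map = x) else x)
  if (is.null(width) || is.null(height)) {
    first <- saliency[[1L]][[1L]]
    height <- nrow(first)
    width <- ncol(first)
  }
  new("ImageSet", saliency = saliency, scenes = scenes,
      width = as.numeric(width), height = as.numeric(height))
}

#' Serialize / read a RegionSet
#'
#' The partition is written as a plain-text label matrix (CSV of integers,
#' one row per pixel row) plus a JSON sidecar holding the grid shape, cell
#' size and image dimensions.
#'
#' @param regions a \code{\linkS4class{RegionSet}}
#' @param path basename; writes \code{<path>.labels.csv} and
#'   \code{<path>.json}.
#' @return invisibly, the two file paths.
#' @export
writeRegionSet <- function(regions, path) {
  stopifnot(is(regions, "RegionSet"))
  labPath <- paste0(path, ".labels.csv")
  metaPath <- paste0(path, ".json")
  data.table::fwrite(data.table::as.data.table(regions@labels), labPath,
                     col.names = FALSE)
  meta <- list(shape = regions@shape, cellSize = regions@cellSize,
               imageWidth = regions@imageWidth, imageHeight = regions@imageHeight,
               centers = unname(apply(regions@centers, 1L, as.numeric, simplify = FALSE)))
  jsonlite::write_json(meta, metaPath, auto_unbox = FALSE, digits = NA)
  invisible(c(labels = labPath, meta = metaPath))
}

#' @rdname writeRegionSet
#' @export
readRegionSet <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lab <- as.matrix(data.table::fread(paste0(path, ".labels.csv"), header = FALSE))
  dimnames(lab) <- NULL
  storage.mode(lab) <- "integer"
  new("RegionSet", labels = lab,
      centers = cbind(x = meta$centers[, 1L], y = meta$centers[, 2L]),
      shape = as.integer(meta$shape), cellSize = as.numeric(meta$cellSize),
      imageWidth = meta$imageWidth, imageHeight = meta$imageHeight)
}
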