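#' @include obsmatrix.R glmm-spec.R
NULL

# symmetric square root of a PSD matrix (for drawing from singular
# covariances too)
.sqrtPSD <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
}

.rmvnorm0 <- function(n, Sigma) {
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% .sqrtPSD(Sigma)
}

.defaultSigmaSubject <- function() {
  v <- c(0.031, 0.026, 0.0025)
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.83
  r[1, 3] <- r[3, 1] <- 0.43
  r[2, 3] <- r[3, 2] <- 0.39
  diag(sqrt(v)) %*% r %*% diag(sqrt(v))
}

.defaultSigmaItem <- function() {
  v <- c(0.103, 0.081, 0.186)
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.50
  r[1, 3] <- r[3, 1] <- 0.20
  r[2, 3] <- r[3, 2] <- 0.35
  diag(sqrt(v)) %*% r %*% diag(sqrt(v))
}

#' Construct generative parameters for the synthetic-data generator
#'
#' Defaults emulate the statistical structure of a central-bias--saliency
#' analysis of scene viewing: fixed effects of magnitude beta_cb = -0.6
#' and beta_sal = 0.7 on the standardized scale with an intercept of -1.2
#' (overall fixation probability below one half), random-effect
#' covariances of the magnitude observed for such models (item variances
#' several times larger than subject variances, moderate positive
#' intercept--central-bias correlations), and a moderate photographer
#' bias.
#'
#' @param nSubjects,nImages design size (defaults 20 x 30: a desk-scale
#'   version of a full eye-tracking corpus).
#' @param imageWidth,imageHeight,cellWidth,cellHeight geometry (defaults:
#'   800 x 600 px images, 100 px cells, i.e. an 8 x 6 grid).
#' @param beta named fixed effects c(intercept=, cb=, sal=).
#' @param SigmaSubject,SigmaItem 3 x 3 random-effect covariance matrices
#'   over (intercept, cb slope, sal slope).
#' @param kappa photographer-bias strength (>= 0; 0 = none). The default
#'   of 0.6 yields a saliency/centre-distance rank correlation near -0.3,
#'   the modest bias typical of natural-scene photographs.
#' @param nBlobs,blobSigma saliency-map generator settings.
#' @param response "binary" or "count".
#' @param fixationsPerCell mean number of extra (re)fixations added per
#'   fixated cell when emitting fixation points (Poisson; exercises the
#'   count response without changing the binary one).
#' @return a \code{\linkS4class{GenerativeParams}}
#' @export
generativeParams <- function(nSubjects = 20L, nImages = 30L,
                             imageWidth = 800, imageHeight = 600,
                             cellWidth = 100, cellHeight = 100,
                             beta = c(intercept = -1.2, cb = -0.6, sal = 0.7),
                             SigmaSubject = .defaultSigmaSubject(),
                             SigmaItem = .defaultSigmaItem(),
                             kappa = 0.6, nBlobs = 8L, blobSigma = 80,
                             response = "binary",
                             fixationsPerCell = 0.5) {
  new("GenerativeParams",
      nSubjects = as.integer(nSubjects), nImages = as.integer(nImages),
      imageWidth = imageWidth, imageHeight = imageHeight,
      cellWidth = cellWidth, cellHeight = cellHeight,
      beta = beta, SigmaSubject = SigmaSubject, SigmaItem = SigmaItem,
      kappa = kappa, nBlobs = as.integer(nBlobs), blobSigma = blobSigma,
      response = response, fixationsPerCell = fixationsPerCell)
}

#' Generate synthetic saliency maps with controllable photographer bias
#'
#' Each map is a sum of isotropic Gaussian blobs, min-max normalized to
#' [0, 1]. Blob centres are drawn uniformly from the image extended by a
#' two-sigma margin (so that, without bias, expected saliency is
#' stationary across the image rather than depressed at the edges) and
#' then shrunk toward the image centre by the factor 1/(1 + kappa):
#' kappa = 0 leaves the centres uniform, and increasing kappa concentrates
#' high salience in the centre, reproducing the photographer bias of
#' natural-scene photographs with a single knob.
#'
#' @param nImages number of maps.
#' @param width,height image dimensions in pixels.
#' @param kappa photographer-bias strength (>= 0).
#' @param nBlobs blobs per map.
#' @param blobSigma blob standard deviation in pixels.
#' @param seed optional RNG seed (identical seeds give identical maps).
#' @param ids image IDs (default img001, img002, ...).
#' @return named list of numeric matrices (height x width) in [0, 1].
#' @export
syntheticSaliencyMaps <- function(nImages, width = 800, height = 600,
                                  kappa = 0, nBlobs = 8L, blobSigma = 80,
                                  seed = NULL,
                                  ids = sprintf("img%03d", seq_len(nImages))) {
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be >= 0")
  if (width < 1 || height < 1 || nBlobs < 1 || blobSigma <= 0)
    stop("invalid map geometry")
  if (!is.null(seed)) set.seed(seed)
  margin <- 2 * blobSigma
  shrink <- 1 / (1 + kappa)
  xs <- seq_len(width) - 0.5
  ys <- seq_len(height) - 0.5
  maps <- lapply(seq_len(nImages), function(i) {
    cx <- width / 2 + (width / 2 + margin) * stats::runif(nBlobs, -1, 1) * shrink
    cy <- height / 2 + (height / 2 + margin) * stats::runif(nBlobs, -1, 1) * shrink
    m <- matrix(0, height, width)
    for (b in seq_len(nBlobs)) {
      gx <- exp(-(xs - cx[b])^2 / (2 * blobSigma^2))
      gy <- exp(-(ys - cy[b])^2 / (2 * blobSigma^2))
      m <- m + outer(gy, gx)
    }
    normalizeMap(m)
  })
  stats::setNames(maps, ids)
}

#' Rank correlation between cell saliency and distance from centre
#'
#' Convenience wrapper measuring the photographer bias of a set of maps:
#' Spearman's rho between per-cell mean saliency and the chosen
#' distance-to-centre predictor, over all (image, cell) pairs.
#'
#' @param maps named list of saliency matrices or an
#'   \code{\linkS4class{ImageSet}} with a single model.
#' @param regions a \code{\linkS4class{RegionSet}}.
#' @param params central-bias definition (default isotropic Euclidean).
#' @return Spearman's rho (negative = centre-biased salience).
#' @export
saliencyCenterCorrelation <- function(maps, regions,
                                      params = centralBiasParams("euclidean")) {
  pred <- cellPredictors(maps, regions,
                         centralBias = list(cbdist = params))
  salCol <- grep("^sal", names(pred), value = TRUE)[1L]
  predictorCorrelation(pred, salCol, "cbdist")
}

#' Calibrate the photographer-bias strength to a correlation band
#'
#' Finds kappa such that the saliency/centre-distance Spearman correlation
#' of freshly generated maps falls inside a requested band (e.g. [-0.5,
#' -0.25], the range real saliency algorithms without an intrinsic centre
#' preference show on natural scenes). The correlation is a monotone
#' non-increasing function of kappa, so a bracketing bisection with common
#' random numbers converges quickly.
#'
#' @param band numeric(2), the target correlation interval (negative).
#' @param nImages maps per evaluation (more = smoother curve).
#' @param width,height,cellWidth,cellHeight,nBlobs,blobSigma generator
#'   geometry.
#' @param seed RNG seed reused for every evaluation (common random
#'   numbers).
#' @param maxIter bisection iterations.
#' @return list with kappa and the achieved rho.
#' @export
calibratePhotographerBias <- function(band = c(-0.5, -0.25), nImages = 40L,
                                      width = 800, height = 600,
                                      cellWidth = 100, cellHeight = 100,
                                      nBlobs = 8L, blobSigma = 80,
                                      seed = 1L, maxIter = 40L) {
  band <- sort(band)
  if (band[2L] > 0) stop("the target band must be negative (centre-biased salience)")
  regions <- buildGrid(width, height, cellWidth, cellHeight)
  rho <- function(k) {
    maps <- syntheticSaliencyMaps(nImages, width, height, kappa = k,
                                  nBlobs = nBlobs, blobSigma = blobSigma,
                                  seed = seed)
    saliencyCenterCorrelation(maps, regions)
  }
  target <- mean(band)
  lo <- 0
  hi <- 1
  rhoHi <- rho(hi)
  while (rhoHi > target && hi < 512) {
    hi <- hi * 2
    rhoHi <- rho(hi)
  }
  if (rhoHi > target)
    stop("cannot reach the requested correlation band with this geometry")
  k <- hi
  r <- rhoHi
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    r <- rho(mid)
    k <- mid
    if (r >= band[1L] && r <= band[2L]) break
    if (r > target) lo <- mid else hi <- mid
  }
  list(kappa = k, rho = r)
}

#' Generate fixation data from a known generative GLMM
#'
#' The inverse of the analysis pipeline: per-cell fixation indicators (or
#' counts) are sampled from a binomial (Poisson) mixed model with crossed
#' subject and item random effects, and fixation points are then emitted
#' uniformly inside the sampled cells, with an initial central fixation
#' prepended to each trial to exercise the exclusion rule. The generator
#' returns the complete ground truth alongside the fixation report, so
#' pipeline inversion and parameter recovery are directly testable.
#'
#' Predictors: the central-bias predictor (anisotropic Euclidean by
#' default) and the per-cell mean of the generated saliency maps, both
#' standardized over the (image, cell) design.
#'
#' @param params a \code{\linkS4class{GenerativeParams}}.
#' @param maps optional pre-generated saliency maps (named list, one per
#'   image); generated from \code{params} when NULL.
#' @param seed optional RNG seed; the whole generation is
#'   seed-deterministic.
#' @param cbParams central-bias definition for the generative predictor.
#' @param initialFixation prepend the central fixation to every trial
#'   (default TRUE).
#' @return list with elements \code{report} (fixation report
#'   data.table), \code{truth} (data.frame: subject, image, cell, cb_z,
#'   sal_z, fixated and -- for the count response -- count),
#'   \code{predictors} (per image x cell), \code{randomEffects} (realized
#'   subject and item effects), \code{regions}, \code{maps} and
#'   \code{params}.
#' @export
syntheticFixationData <- function(params, maps = NULL, seed = NULL,
                                  cbParams = centralBiasParams("euclidean",
                                                               nu = 0.45),
                                  initialFixation = TRUE) {
  stopifnot(is(params, "GenerativeParams"))
  validObject(params)
  if (!is.null(seed)) set.seed(seed)
  regions <- buildGrid(params@imageWidth, params@imageHeight,
                       params@cellWidth, params@cellHeight)
  n <- nRegions(regions)
  imgIDs <- sprintf("img%03d", seq_len(params@nImages))
  subjIDs <- sprintf("S%02d", seq_len(params@nSubjects))
  if (is.null(maps)) {
    maps <- syntheticSaliencyMaps(params@nImages, params@imageWidth,
                                  params@imageHeight, kappa = params@kappa,
                                  nBlobs = params@nBlobs,
                                  blobSigma = params@blobSigma, ids = imgIDs)
  }
  if (!identical(sort(names(maps)), sort(imgIDs)))
    imgIDs <- names(maps)

  sal <- lapply(imgIDs, function(id)
    extractMeanFeature(normalizeMap(maps[[id]]), regions))
  pred <- data.table::data.table(
    image = rep(imgIDs, each = n),
    cell = rep(seq_len(n), length(imgIDs)),
    cb = rep(centralBiasVector(regions, cbParams), length(imgIDs)),
    sal = unlist(sal, use.names = FALSE))
  pred <- standardizeColumns(pred, c("cb", "sal"))

  bS <- .rmvnorm0(params@nSubjects, params@SigmaSubject)
  rownames(bS) <- subjIDs
  bI <- .rmvnorm0(params@nImages, params@SigmaItem)
  rownames(bI) <- imgIDs

  truth <- data.table::CJ(subject = subjIDs, image = imgIDs, sorted = TRUE)
  truth <- merge(truth, pred, by = "image", allow.cartesian = TRUE)
  si <- match(truth$subject, subjIDs)
  ii <- match(truth$image, imgIDs)
  eta <- (params@beta[["intercept"]] + bS[si, 1L] + bI[ii, 1L]) +
    (params@beta[["cb"]] + bS[si, 2L] + bI[ii, 2L]) * truth$cb_z +
    (params@beta[["sal"]] + bS[si, 3L] + bI[ii, 3L]) * truth$sal_z
  if (params@response == "binary") {
    truth$fixated <- stats::rbinom(nrow(truth), 1L, stats::plogis(eta))
  } else {
    truth$count <- stats::rpois(nrow(truth), exp(eta))
    truth$fixated <- as.integer(truth$count >= 1L)
  }
  data.table::setorderv(truth, c("subject", "image", "cell"))

  report <- .emitFixationReport(truth, regions, params, initialFixation)

  list(report = report,
       truth = as.data.frame(truth),
       predictors = as.data.frame(pred),
       randomEffects = list(subject = bS, item = bI),
       regions = regions, maps = maps, params = params)
}

# place fixation points uniformly inside the sampled cells; trial order:
# initial central fixation first (if requested), then fixated cells in
# random order
.emitFixationReport <- function(truth, regions, params, initialFixation) {
  cw <- regions@cellSize[1L]
  ch <- regions@cellSize[2L]
  cols <- regions@shape[1L]
  cx <- regions@imageWidth / 2
  cy <- regions@imageHeight / 2
  fx <- truth[truth$fixated == 1L, c("subject", "image", "cell"),
              with = FALSE]
  if ("count" %in% names(truth)) {
    reps <- truth$count[truth$fixated == 1L]
  } else if (params@fixationsPerCell > 0) {
    reps <- 1L + stats::rpois(nrow(fx), params@fixationsPerCell)
  } else {
    reps <- rep(1L, nrow(fx))
  }
  fx <- fx[rep(seq_len(nrow(fx)), reps)]
  # jitter inside the half-open cell rectangle
  col0 <- (fx$cell - 1L) %% cols
  row0 <- (fx$cell - 1L) %/% cols
  fx$fix_x <- col0 * cw + stats::runif(nrow(fx)) * cw
  fx$fix_y <- row0 * ch + stats::runif(nrow(fx)) * ch
  fx <- fx[sample.int(nrow(fx))]           # shuffle within/across trials
  data.table::setorderv(fx, c("subject", "image"))

  if (initialFixation) {
    trials <- unique(truth[, c("subject", "image"), with = FALSE])
    init <- data.table::data.table(subject = trials$subject,
                                   image = trials$image,
                                   cell = NA_integer_,
                                   fix_x = cx, fix_y = cy)
    fx <- rbind(init, fx)
    # the initial fixation (cell NA) must come first in each trial
    fx$initrow <- is.na(fx$cell)
    fx <- fx[order(fx$subject, fx$image, !fx$initrow)]
    fx$initrow <- NULL
  }
  fx[, fix_index := seq_len(.N), by = c("subject", "image")]
  fx$onset_ms <- 250 * (fx$fix_index - 1L)
  fx$duration_ms <- 200
  fx$cell <- NULL
  data.table::setcolorder(fx, c("subject", "image", "fix_index",
                                "fix_x", "fix_y", "onset_ms", "duration_ms"))
  fx[]
}

#' Remove whole trials from a fixation report
#'
#' Deletes all fixations of randomly chosen (subject, image) trials,
#' emulating missing trials in a real corpus: the observation matrix
#' downstream then loses one full grid of rows per missing trial.
#' Removing an already-removed trial is a no-op, so the operation is
#' idempotent.
#'
#' @param report fixation report (data.frame/data.table).
#' @param nMissing number of trials to remove.
#' @param seed optional RNG seed for the trial choice.
#' @return the report without the chosen trials.
#' @export
makeMissingTrials <- function(report, nMissing, seed = NULL) {
  dt <- data.table::as.data.table(report)
  if (nMissing == 0L) return(dt)
  if (!is.null(seed)) set.seed(seed)
  trials <- unique(dt[, c("subject", "image"), with = FALSE])
  if (nMissing > nrow(trials))
    stop("cannot remove more trials than exist")
  drop <- trials[sample.int(nrow(trials), nMissing)]
  dt[!drop, on = c("subject", "image")]
}
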