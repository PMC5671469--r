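#' @include AllClasses.R
NULL

#' Construct a mixed-model specification
#'
#' Convenience constructor for \code{\linkS4class{ModelSpec}}. The default
#' grouping structure is the crossed subject/item design of grid-cell
#' fixation data: random effects by subject and by scene item (the image).
#'
#' @param response response column ("fixated" for the binomial model,
#'   "count" for the Poisson model).
#' @param fixedTerms character vector of fixed-effect predictor columns
#'   (the intercept is implicit).
#' @param family "binomial" (logit) or "poisson" (log); defaults to
#'   binomial for "fixated" and poisson for "count".
#' @param randomTerms slopes per grouping factor; either a single
#'   character vector applied to every factor (default: all fixed terms,
#'   the maximal choice) or a named list.
#' @param corrMode "maximal", "zcp" or "intercept", recycled over factors
#'   or a named vector.
#' @param groups named character mapping factor names to data columns.
#' @param mapFactor,mapLevels,reference saliency-map factor metadata (used
#'   by \code{\link{comparisonSpec}}; NA for ordinary models).
#' @return a \code{\linkS4class{ModelSpec}}
#' @examples
#' modelSpec("fixated", c("cb_z", "sal_z"))                  # maximal
#' modelSpec("fixated", c("cb_z", "sal_z"), corrMode = "zcp")
#' modelSpec("fixated", c("cb_z", "sal_z"), corrMode = "intercept")
#' @export
modelSpec <- function(response = "fixated",
                      fixedTerms = character(),
                      family = if (response == "count") "poisson" else "binomial",
                      randomTerms = fixedTerms,
                      corrMode = "maximal",
                      groups = c(subject = "subject", item = "image"),
                      mapFactor = NA_character_,
                      mapLevels = character(),
                      reference = NA_character_) {
  if (!is.list(randomTerms))
    randomTerms <- stats::setNames(rep(list(randomTerms), length(groups)),
                                   names(groups))
  if (is.null(names(corrMode)) || length(corrMode) == 1L)
    corrMode <- stats::setNames(rep(corrMode, length.out = length(groups)),
                                names(groups))
  for (f in names(randomTerms))
    if (identical(corrMode[[f]], "intercept"))
      randomTerms[[f]] <- character()
  new("ModelSpec", response = response, family = family,
      fixedTerms = fixedTerms, mapFactor = mapFactor,
      mapLevels = mapLevels, reference = reference,
      randomTerms = randomTerms, corrMode = corrMode, groups = groups)
}

#' Wilkinson-style model formula of a ModelSpec
#'
#' Random terms appear as \code{(1 + a + b | g)} for the maximal
#' structure, \code{(1 + a + b || g)} for the zero-correlation structure
#' and \code{(1 | g)} for random intercepts only.
#'
#' @param spec a \code{\linkS4class{ModelSpec}}
#' @return character(1) formula text
#' @export
buildFormula <- function(spec) {
  stopifnot(is(spec, "ModelSpec"))
  fixed <- paste(c("1", spec@fixedTerms), collapse = " + ")
  rparts <- vapply(names(spec@groups), function(f) {
    col <- spec@groups[[f]]
    slopes <- spec@randomTerms[[f]]
    if (spec@corrMode[[f]] == "intercept" || length(slopes) == 0L)
      sprintf("(1 | %s)", col)
    else if (spec@corrMode[[f]] == "zcp")
      sprintf("(1 + %s || %s)", paste(slopes, collapse = " + "), col)
    else
      sprintf("(1 + %s | %s)", paste(slopes, collapse = " + "), col)
  }, character(1))
  paste(spec@response, "~", paste(c(fixed, rparts), collapse = " + "))
}

#' Count model parameters of a specification
#'
#' Bookkeeping for random-effects model selection: a grouping factor with
#' m random terms (intercept included) contributes m variance components
#' plus m(m-1)/2 correlation parameters under the maximal structure, m
#' variances under the zero-correlation structure, and a single intercept
#' variance under the intercept-only structure. Fixed-effect columns are
#' counted with the intercept.
#'
#' For the three-map comparison model with its 7 fixed effects, the
#' maximal structure requires 2 x (7 + 21) = 56 random-effect parameters
#' and the zero-correlation structure 14.
#'
#' @param spec a \code{\linkS4class{ModelSpec}}
#' @return list with elements fixed, variance, correlation and total
#'   (fixed + variance + correlation).
#' @export
countParameters <- function(spec) {
  stopifnot(is(spec, "ModelSpec"))
  kf <- 1L + length(spec@fixedTerms)
  kv <- 0L
  kc <- 0L
  for (f in names(spec@groups)) {
    m <- 1L + length(spec@randomTerms[[f]])
    mode <- spec@corrMode[[f]]
    if (mode == "intercept") {
      kv <- kv + 1L
    } else if (mode == "zcp") {
      kv <- kv + m
    } else {
      kv <- kv + m
      kc <- kc + m * (m - 1L) %/% 2L
    }
  }
  list(fixed = kf, variance = kv, correlation = kc, total = kf + kv + kc)
}

#' Specification of the saliency-map comparison model
#'
#' Builds the treatment-coded comparison model that tests whether saliency
#' maps differ significantly: the continuous central-bias and saliency
#' predictors give the simple effects for the reference map, and their
#' interactions with the map factor give per-map differences from the
#' reference. With k maps the fixed part has 1 + 2 + 2(k-1) coefficients
#' (7 for three maps); the actual per-map coefficient is the simple effect
#' plus the relevant interaction (see
#' \code{\link{derivedFixedCoefficient}}).
#'
#' Interaction terms are represented as explicit dummy-slope columns named
#' \code{<pred>_x_<level>} (predictor times the level indicator), created
#' on the stacked data by \code{\link{expandMapDummies}}; this makes every
#' random structure (maximal, zcp, intercept-only) expressible in plain
#' formula syntax.
#'
#' @param maps character vector of map labels (order kept).
#' @param reference reference level (must be among \code{maps}).
#' @param cb,sal central-bias and saliency column names in the stacked
#'   table.
#' @param response,corrMode,groups as in \code{\link{modelSpec}};
#'   \code{corrMode} defaults to "zcp" (the maximal structure of this
#'   model rarely converges).
#' @return a \code{\linkS4class{ModelSpec}}
#' @export
comparisonSpec <- function(maps, reference, cb = "cb_z", sal = "sal_z",
                           response = "fixated", corrMode = "zcp",
                           groups = c(subject = "subject", item = "image")) {
  if (!reference %in% maps)
    stop(sprintf("reference '%s' is not among the map labels", reference))
  others <- setdiff(maps, reference)
  inter <- c(vapply(others, function(l) paste0(cb, "_x_", l), character(1),
                    USE.NAMES = FALSE),
             vapply(others, function(l) paste0(sal, "_x_", l), character(1),
                    USE.NAMES = FALSE))
  fixed <- c(cb, sal, inter)
  modelSpec(response = response, fixedTerms = fixed,
            randomTerms = fixed, corrMode = corrMode, groups = groups,
            mapFactor = "map", mapLevels = maps, reference = reference)
}

#' Create treatment-coded dummy-slope columns for the map factor
#'
#' For a stacked observation table (each (subject, image, cell) row
#' replicated once per saliency map, with a \code{map} label column),
#' creates, for each non-reference level L and each continuous predictor
#' p, the column \code{p_x_L = p * (map == L)}. This is exactly the
#' treatment-contrast interaction column of the comparison model.
#'
#' @param table stacked observation table with a \code{map} column.
#' @param spec a comparison \code{\linkS4class{ModelSpec}}.
#' @return the table with the dummy columns added (existing ones are left
#'   untouched).
#' @export
expandMapDummies <- function(table, spec) {
  stopifnot(is(spec, "ModelSpec"))
  if (is.na(spec@mapFactor)) return(table)
  if (!spec@mapFactor %in% names(table))
    stop(sprintf("no map factor column '%s' in the table", spec@mapFactor))
  lev <- unique(as.character(table[[spec@mapFactor]]))
  unknown <- setdiff(lev, spec@mapLevels)
  if (length(unknown))
    stop("unknown map level(s): ", paste(unknown, collapse = ", "))
  for (trm in spec@fixedTerms) {
    if (!grepl("_x_", trm, fixed = TRUE)) next
    if (trm %in% names(table)) next
    parts <- strsplit(trm, "_x_", fixed = TRUE)[[1L]]
    base <- paste(parts[-length(parts)], collapse = "_x_")
    level <- parts[length(parts)]
    if (!base %in% names(table))
      stop(sprintf("base predictor '%s' for term '%s' not in the table", base, trm))
    table[[trm]] <- table[[base]] * as.numeric(table[[spec@mapFactor]] == level)
  }
  table
}

#' Stack an observation table across saliency maps
#'
#' Replicates each (subject, image, cell) row once per saliency map,
#' adding a \code{map} label column and a single \code{sal} column taken
#' from the per-map saliency columns (\code{sal_<map>}). The binary
#' response is shared across the replicates; this stacked long format is
#' what the treatment-coded comparison model is fitted on.
#'
#' @param table observation table with per-map saliency columns.
#' @param maps character vector of map labels; column \code{sal_<label>}
#'   must exist for each.
#' @param salPrefix prefix of the per-map columns (default "sal_").
#' @return stacked data.frame with columns map and sal added, per-map
#'   saliency columns removed.
#' @export
stackMaps <- function(table, maps, salPrefix = "sal_") {
  cols <- paste0(salPrefix, maps)
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop("missing saliency column(s): ", paste(miss, collapse = ", "))
  dt <- data.table::as.data.table(table)
  pieces <- lapply(seq_along(maps), function(k) {
    p <- data.table::copy(dt)
    p$map <- maps[k]
    p$sal <- p[[cols[k]]]
    p[, (cols) := NULL]
    p
  })
  as.data.frame(data.table::rbindlist(pieces))
}

#' Enumerate the control-analysis model grid
#'
#' The robustness sweep fits one central-bias--saliency model for every
#' combination of saliency map, grid resolution, central-bias predictor
#' and random-effects structure. With the defaults (3 maps x 3 grids x 7
#' central-bias predictors x 3 structures) this enumerates 189 model
#' specifications.
#'
#' @param maps saliency map labels.
#' @param grids named list of c(cellWidth, cellHeight) pairs (default the
#'   fine 16x12, default 8x6 and coarse 4x3 grids of an 800 x 600 image).
#' @param centralBias names of the central-bias predictors (default the
#'   seven canonical ones).
#' @param structures random-effects structures to cross.
#' @return data.frame with one row per specification: map, grid,
#'   cellWidth, cellHeight, centralBias, structure, formula.
#' @export
enumerateControlSpecs <- function(maps = c("IKN98", "AWS", "GBVS"),
                                  grids = list(`16x12` = c(50, 50),
                                               `8x6` = c(100, 100),
                                               `4x3` = c(200, 200)),
                                  centralBias = names(canonicalCentralBias(800, 600)),
                                  structures = c("maximal", "zcp", "intercept")) {
  g <- expand.grid(map = maps, grid = names(grids),
                   centralBias = centralBias, structure = structures,
                   stringsAsFactors = FALSE)
  g$cellWidth <- vapply(g$grid, function(k) grids[[k]][1L], numeric(1))
  g$cellHeight <- vapply(g$grid, function(k) grids[[k]][2L], numeric(1))
  g$formula <- vapply(seq_len(nrow(g)), function(i) {
    buildFormula(modelSpec("fixated", c("cb_z", "sal_z"),
                           corrMode = g$structure[i]))
  }, character(1))
  g
}
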