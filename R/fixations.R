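#' @include regions.R
NULL

#' Read a fixation report
#'
#' Reads a tab- or comma-delimited fixation report (one row per fixation)
#' as exported by standard eye-tracker analysis software, mapping arbitrary
#' column names onto the canonical ones: subject, image, fix_index, fix_x,
#' fix_y, onset_ms, duration_ms. Fixation indices must be strictly
#' increasing within each (subject, image) trial and coordinates finite.
#'
#' @param path file path (delimiter sniffed by \code{data.table::fread}).
#' @param columns named character vector mapping canonical names to the
#'   file's column names; defaults to the canonical names themselves.
#'   onset_ms/duration_ms are optional and filled with NA when absent.
#' @return a \code{data.table} with the canonical columns.
#' @export
readFixationReport <- function(path,
                               columns = c(subject = "subject", image = "image",
                                           fix_index = "fix_index",
                                           fix_x = "fix_x", fix_y = "fix_y",
                                           onset_ms = "onset_ms",
                                           duration_ms = "duration_ms")) {
  dt <- data.table::fread(path)
  required <- c("subject", "image", "fix_index", "fix_x", "fix_y")
  miss <- setdiff(required, names(columns))
  if (length(miss))
    stop("column mapping must cover: ", paste(miss, collapse = ", "))
  absent <- setdiff(columns[required], names(dt))
  if (length(absent))
    stop("fixation report lacks column(s): ", paste(absent, collapse = ", "))
  out <- data.table::data.table(
    subject = as.character(dt[[columns[["subject"]]]]),
    image = as.character(dt[[columns[["image"]]]]),
    fix_index = as.integer(dt[[columns[["fix_index"]]]]),
    fix_x = as.numeric(dt[[columns[["fix_x"]]]]),
    fix_y = as.numeric(dt[[columns[["fix_y"]]]])
  )
  for (opt in c("onset_ms", "duration_ms")) {
    cn <- if (opt %in% names(columns)) columns[[opt]] else NA_character_
    out[[opt]] <- if (!is.na(cn) && cn %in% names(dt)) as.numeric(dt[[cn]]) else NA_real_
  }
  if (!all(is.finite(out$fix_x)) || !all(is.finite(out$fix_y)))
    stop("fixation coordinates must be finite")
  bad <- out[, list(ok = !is.unsorted(fix_index, strictly = TRUE)),
             by = c("subject", "image")]
  if (any(!bad$ok))
    stop("fixation indices must be strictly increasing within each trial")
  out
}

#' Assign fixations to grid cells
#'
#' Adds a \code{cell} column: the 1-based index of the region whose
#' half-open rectangle contains the fixation point (boundary points belong
#' to the cell to the right/below, matching the grid convention). Points
#' outside the image -- which occur in real eye-tracking reports -- get
#' \code{NA} and are counted in a message rather than raising an error.
#'
#' @param fixations data.table/data.frame with fix_x, fix_y columns
#'   (pixels, 0-based).
#' @param regions a \code{\linkS4class{RegionSet}} built for the image.
#' @param quiet suppress the out-of-image message.
#' @return the input with a \code{cell} integer column added.
#' @export
assignFixations <- function(fixations, regions, quiet = FALSE) {
  stopifnot(is(regions, "RegionSet"))
  dt <- data.table::as.data.table(fixations)
  x <- dt$fix_x
  y <- dt$fix_y
  inside <- x >= 0 & x < regions@imageWidth & y >= 0 & y < regions@imageHeight
  cell <- rep(NA_integer_, nrow(dt))
  if (any(inside)) {
    idx <- cbind(floor(y[inside]) + 1L, floor(x[inside]) + 1L)
    lab <- regions@labels[idx]
    lab[lab == 0L] <- NA_integer_   # uncovered truncation remainder
    cell[inside] <- lab
  }
  nOut <- sum(!inside)
  if (nOut > 0L && !quiet)
    message(sprintf("%d fixation(s) outside the image were assigned no cell", nOut))
  dt$cell <- cell
  dt
}

#' Exclude the initial (central) fixation and its cell
#'
#' The fixation on the pre-trial fixation cross typically extends into the
#' scene-presentation period and falls on a central image patch. Per
#' trial, the first fixation (smallest index) is removed, and the cell it
#' fell on is excluded from analysis for that trial entirely: later
#' revisits to that cell are dropped from the responses too, irrespective
#' of whether the cell was refixated. If the initial fixation landed
#' outside the image, only the fixation is dropped and no cell is
#' excluded.
#'
#' The operation is idempotent: fixations carry an \code{initial_excluded}
#' marker so re-applying it is a no-op.
#'
#' @param fixations a data.table with columns subject, image, fix_index,
#'   cell (from \code{\link{assignFixations}}).
#' @return list with \code{fixations} (retained rows) and \code{excluded}
#'   (data.table: subject, image, excludedCell with NA for none).
#' @export
excludeInitialFixation <- function(fixations) {
  dt <- data.table::as.data.table(fixations)
  if (nrow(dt) == 0L)
    stop("cannot apply the initial-fixation exclusion to an empty trial set")
  if (isTRUE(attr(dt, "initial_excluded"))) {
    return(list(fixations = dt, excluded = attr(dt, "excluded_cells")))
  }
  data.table::setorderv(dt, c("subject", "image", "fix_index"))
  first <- dt[, list(firstIndex = fix_index[1L], excludedCell = cell[1L]),
              by = c("subject", "image")]
  dt <- merge(dt, first, by = c("subject", "image"), sort = FALSE)
  keep <- dt$fix_index != dt$firstIndex &
    (is.na(dt$excludedCell) | is.na(dt$cell) | dt$cell != dt$excludedCell)
  out <- dt[keep, !c("firstIndex", "excludedCell"), with = FALSE]
  excluded <- first[, !"firstIndex", with = FALSE]
  data.table::setattr(out, "initial_excluded", TRUE)
  data.table::setattr(out, "excluded_cells", excluded)
  list(fixations = out, excluded = excluded)
}

#' Per-trial grid responses
#'
#' Counts retained fixations per (subject, image, cell): the count
#' response includes immediate refixations and later revisits as separate
#' fixations, and the binary fixated response is the indicator of a
#' positive count. Out-of-image fixations (cell NA) are ignored. Trials
#' enter via the fixation rows only; (subject, image) combinations without
#' fixation data produce no trials.
#'
#' @param fixations retained fixations (after
#'   \code{\link{excludeInitialFixation}}) with a cell column.
#' @param excluded data.table (subject, image, excludedCell) as returned
#'   by \code{\link{excludeInitialFixation}}; also defines trials that
#'   retained no fixations.
#' @return list with \code{counts} (subject, image, cell, count for cells
#'   with count >= 1), \code{trials} (unique subject x image) and
#'   \code{excluded} (passed through).
#' @export
gridResponses <- function(fixations, excluded = NULL) {
  dt <- data.table::as.data.table(fixations)
  counts <- dt[!is.na(dt$cell),
               list(count = .N), by = c("subject", "image", "cell")]
  trials <- unique(dt[, c("subject", "image"), with = FALSE])
  if (!is.null(excluded)) {
    trials <- unique(data.table::rbindlist(list(
      trials, excluded[, c("subject", "image"), with = FALSE])))
  } else {
    excluded <- data.table::data.table(subject = character(), image = character(),
                                       excludedCell = integer())
  }
  data.table::setorderv(trials, c("subject", "image"))
  list(counts = counts, trials = trials, excluded = excluded)
}
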