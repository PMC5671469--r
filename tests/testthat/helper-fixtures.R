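# shared fixtures, built in code

# a small generative setting used across tests: 4x3 grid of 50-px cells
tinyParams <- function(...) {
  args <- list(...)
  defaults <- list(nSubjects = 6L, nImages = 8L,
                   imageWidth = 200, imageHeight = 150,
                   cellWidth = 50, cellHeight = 50,
                   nBlobs = 4L, blobSigma = 30, kappa = 0.6)
  do.call(generativeParams, utils::modifyList(defaults, args))
}

zeroSigma <- function() matrix(0, 3, 3)

# fixation rows hitting given cell indices of a RegionSet (cell centres)
fixationsAtCells <- function(cells, regions, subject = "S01", image = "img001") {
  ctr <- regionCenters(regions)
  data.table::data.table(
    subject = subject, image = image,
    fix_index = seq_along(cells),
    fix_x = ctr[cells, "x"], fix_y = ctr[cells, "y"],
    onset_ms = 250 * (seq_along(cells) - 1), duration_ms = 200)
}

# empty response set for a full crossed design (no fixations at all)
designResponses <- function(subjects, images) {
  list(trials = data.table::CJ(subject = subjects, image = images),
       counts = data.table::data.table(subject = character(),
                                       image = character(),
                                       cell = integer(), count = integer()),
       excluded = data.table::data.table(subject = character(),
                                         image = character(),
                                         excludedCell = integer()))
}

constantPredictors <- function(images, nCells) {
  data.table::CJ(image = images, cell = seq_len(nCells))[, pred := 0][]
}
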