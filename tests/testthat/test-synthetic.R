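test_that("synthetic maps are seed-deterministic, bounded and well-formed", {
  m1 <- syntheticSaliencyMaps(3, 200, 150, kappa = 0.6, nBlobs = 4,
                              blobSigma = 30, seed = 7)
  m2 <- syntheticSaliencyMaps(3, 200, 150, kappa = 0.6, nBlobs = 4,
                              blobSigma = 30, seed = 7)
  m3 <- syntheticSaliencyMaps(3, 200, 150, kappa = 0.6, nBlobs = 4,
                              blobSigma = 30, seed = 8)
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))
  expect_named(m1, c("img001", "img002", "img003"))
  for (m in m1) {
    expect_equal(dim(m), c(150, 200))
    expect_gte(min(m), 0)
    expect_equal(max(m), 1)
  }
  expect_error(syntheticSaliencyMaps(3, 200, 150, kappa = -1), "kappa")
  expect_error(syntheticSaliencyMaps(3, 0, 150), "geometry")
})

test_that("photographer bias vanishes at kappa 0 and deepens monotonically", {
  g <- buildGrid(200, 150, 50, 50)
  rho <- function(k) {
    maps <- syntheticSaliencyMaps(30, 200, 150, kappa = k, nBlobs = 4,
                                  blobSigma = 30, seed = 99)
    saliencyCenterCorrelation(maps, g)
  }
  r0 <- rho(0)
  r1 <- rho(1)
  r4 <- rho(4)
  expect_lt(abs(r0), 0.2)      # uniform blob centres: no centre preference
  expect_lt(r1, r0 - 0.1)      # increasing kappa deepens the bias
  expect_lt(r4, r1 - 0.1)
  expect_lt(r4, -0.5)
})

test_that("bias calibration lands the correlation inside the target band", {
  cal <- calibratePhotographerBias(band = c(-0.5, -0.25), nImages = 20,
                                   width = 200, height = 150,
                                   cellWidth = 50, cellHeight = 50,
                                   nBlobs = 4, blobSigma = 30, seed = 3)
  expect_gte(cal$rho, -0.5)
  expect_lte(cal$rho, -0.25)
  expect_gt(cal$kappa, 0)
  expect_error(calibratePhotographerBias(band = c(0.1, 0.3)), "negative")
})

test_that("generativeParams validates its inputs", {
  expect_error(generativeParams(beta = c(a = 1, b = 2, c = 3)))
  expect_error(generativeParams(kappa = -0.5))
  badS <- diag(3)
  badS[1, 2] <- 0.5            # asymmetric
  expect_error(generativeParams(SigmaSubject = badS))
  notPSD <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_error(generativeParams(SigmaItem = notPSD))
  expect_s4_class(tinyParams(), "GenerativeParams")
})

test_that("zeroed random effects and slopes reduce to a constant Bernoulli rate", {
  p <- tinyParams(beta = c(intercept = qlogis(0.3), cb = 0, sal = 0),
                  SigmaSubject = zeroSigma(), SigmaItem = zeroSigma())
  sim <- syntheticFixationData(p, seed = 5)
  expect_true(all(sim$randomEffects$subject == 0))
  expect_true(all(sim$randomEffects$item == 0))
  n <- nrow(sim$truth)
  expect_equal(n, 6 * 8 * 12)
  # observed rate within 4 binomial standard errors of 0.3
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(sim$truth$fixated) - 0.3), 4 * se)
})

test_that("the fixation report starts each trial with the central fixation", {
  sim <- syntheticFixationData(tinyParams(), seed = 11)
  rep1 <- sim$report
  expect_equal(names(rep1), c("subject", "image", "fix_index", "fix_x",
                              "fix_y", "onset_ms", "duration_ms"))
  first <- rep1[rep1$fix_index == 1L, ]
  expect_equal(nrow(first), 6 * 8)                    # one per trial
  expect_true(all(first$fix_x == 100 & first$fix_y == 75))
  expect_true(all(rep1$fix_x >= 0 & rep1$fix_x < 200))
  expect_true(all(rep1$fix_y >= 0 & rep1$fix_y < 150))
  # report parses through the reader, i.e. indices are strictly increasing
  d <- withr::local_tempdir()
  data.table::fwrite(rep1, file.path(d, "r.csv"))
  expect_silent(readFixationReport(file.path(d, "r.csv")))
  # without the initial fixation no trial starts at the exact centre row
  set.seed(11)
  sim2 <- syntheticFixationData(tinyParams(), initialFixation = FALSE)
  f2 <- sim2$report[sim2$report$fix_index == 1L, ]
  expect_false(any(f2$fix_x == 100 & f2$fix_y == 75))
})

test_that("the generation is seed-deterministic end to end", {
  s1 <- syntheticFixationData(tinyParams(), seed = 21)
  s2 <- syntheticFixationData(tinyParams(), seed = 21)
  expect_identical(s1$report, s2$report)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$randomEffects, s2$randomEffects)
})

test_that("the analysis pipeline inverts the binary generator exactly", {
  sim <- syntheticFixationData(tinyParams(), seed = 31)
  fx <- assignFixations(sim$report, sim$regions, quiet = TRUE)
  res <- excludeInitialFixation(fx)
  resp <- gridResponses(res$fixations, res$excluded)
  pred <- data.table::as.data.table(sim$predictors)
  obs <- assembleObservations(resp, pred, sim$regions)
  # the initial central fixation excludes its cell from every trial
  expect_true(all(res$excluded$excludedCell ==
                    res$excluded$excludedCell[1L]))
  truth <- data.table::as.data.table(sim$truth)
  m <- merge(data.table::as.data.table(obs)[, c("subject", "image", "cell",
                                                "fixated"), with = FALSE],
             truth[, c("subject", "image", "cell", "fixated"), with = FALSE],
             by = c("subject", "image", "cell"), suffixes = c("", ".truth"))
  expect_equal(nrow(m), nrow(obs))          # every assembled row has truth
  expect_identical(m$fixated, m$fixated.truth)
  # row count: full design minus one excluded cell per trial
  expect_equal(nrow(obs), 6 * 8 * 12 - 6 * 8)
})

test_that("the count response round-trips through the emitted fixations", {
  sim <- syntheticFixationData(tinyParams(response = "count"), seed = 41)
  fx <- assignFixations(sim$report, sim$regions, quiet = TRUE)
  res <- excludeInitialFixation(fx)
  obs <- assembleObservations(gridResponses(res$fixations, res$excluded),
                              data.table::as.data.table(sim$predictors),
                              sim$regions)
  truth <- data.table::as.data.table(sim$truth)
  m <- merge(data.table::as.data.table(obs)[, c("subject", "image", "cell",
                                                "count"), with = FALSE],
             truth[, c("subject", "image", "cell", "count"), with = FALSE],
             by = c("subject", "image", "cell"), suffixes = c("", ".truth"))
  expect_identical(as.integer(m$count), as.integer(m$count.truth))
})

test_that("missing-trial removal drops whole grids of rows and is idempotent", {
  sim <- syntheticFixationData(tinyParams(), seed = 51)
  rep1 <- sim$report
  rep2 <- makeMissingTrials(rep1, 3, seed = 9)
  t1 <- unique(rep1[, c("subject", "image")])
  t2 <- unique(rep2[, c("subject", "image")])
  expect_equal(nrow(t2), nrow(t1) - 3)
  # removed trials lose all their fixations, others keep all of theirs
  kept <- merge(rep1, t2, by = c("subject", "image"))
  expect_equal(nrow(kept), nrow(rep2))
  expect_identical(makeMissingTrials(rep2, 0), rep2)
  expect_error(makeMissingTrials(rep1, 10000), "more trials")
})
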