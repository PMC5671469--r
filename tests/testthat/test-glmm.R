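# one small end-to-end dataset and its three fits, shared across blocks
tinyObservations <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- syntheticFixationData(tinyParams(), seed = 42)
      fx <- assignFixations(sim$report, sim$regions, quiet = TRUE)
      res <- excludeInitialFixation(fx)
      pred <- cellPredictors(sim$maps, sim$regions,
                             centralBias = list(
                               cb = centralBiasParams("euclidean", nu = 0.45)))
      obs <- assembleObservations(gridResponses(res$fixations, res$excluded),
                                  pred, sim$regions)
      obs <- standardizeColumns(obs, c("cb", "sal"))
      cache <<- obs
    }
    cache
  }
})

quickControl <- function() lme4::glmerControl(calc.derivs = FALSE)

tinyFits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      obs <- tinyObservations()
      cache <<- list(
        maximal = fitGLMM(modelSpec("fixated", c("cb_z", "sal_z")), obs,
                          control = quickControl()),
        zcp = fitGLMM(modelSpec("fixated", c("cb_z", "sal_z"),
                                corrMode = "zcp"), obs,
                      control = quickControl()),
        intercept = fitGLMM(modelSpec("fixated", c("cb_z", "sal_z"),
                                      corrMode = "intercept"), obs,
                            control = quickControl()))
    }
    cache
  }
})

test_that("buildFormula renders the three random-effects structures", {
  expect_equal(buildFormula(modelSpec("fixated", c("cb_z", "sal_z"))),
               "fixated ~ 1 + cb_z + sal_z + (1 + cb_z + sal_z | subject) + (1 + cb_z + sal_z | image)")
  expect_equal(buildFormula(modelSpec("fixated", c("cb_z", "sal_z"),
                                      corrMode = "zcp")),
               "fixated ~ 1 + cb_z + sal_z + (1 + cb_z + sal_z || subject) + (1 + cb_z + sal_z || image)")
  expect_equal(buildFormula(modelSpec("fixated", c("cb_z", "sal_z"),
                                      corrMode = "intercept")),
               "fixated ~ 1 + cb_z + sal_z + (1 | subject) + (1 | image)")
  expect_equal(buildFormula(modelSpec("count", character())),
               "count ~ 1 + (1 | subject) + (1 | image)")
})

test_that("parameter bookkeeping follows m variances plus m(m-1)/2 correlations", {
  # two predictors, two crossed factors
  two <- countParameters(modelSpec("fixated", c("cb_z", "sal_z")))
  expect_equal(two$fixed, 3L)
  expect_equal(two$variance, 6L)      # 3 per factor
  expect_equal(two$correlation, 6L)   # 3*2/2 per factor
  expect_equal(two$total, 15L)
  expect_equal(two$variance + two$correlation, 12L)

  zcp <- countParameters(modelSpec("fixated", c("cb_z", "sal_z"),
                                   corrMode = "zcp"))
  expect_equal(zcp$variance + zcp$correlation, 6L)
  expect_equal(zcp$total, 9L)

  int <- countParameters(modelSpec("fixated", c("cb_z", "sal_z"),
                                   corrMode = "intercept"))
  expect_equal(int$variance + int$correlation, 2L)
  expect_equal(int$total, 5L)

  # three-map comparison model: 7 fixed effects, 56 maximal / 14 zcp
  cmpMax <- comparisonSpec(c("A", "B", "C"), reference = "A",
                           corrMode = "maximal")
  pMax <- countParameters(cmpMax)
  expect_equal(pMax$fixed, 7L)
  expect_equal(pMax$variance, 14L)        # 2 x 7
  expect_equal(pMax$correlation, 42L)     # 2 x 7*6/2
  expect_equal(pMax$variance + pMax$correlation, 56L)
  cmpZcp <- comparisonSpec(c("A", "B", "C"), reference = "A")
  pZcp <- countParameters(cmpZcp)
  expect_equal(pZcp$variance + pZcp$correlation, 14L)
})

test_that("comparisonSpec builds the treatment-coded fixed part", {
  spec <- comparisonSpec(c("IKN98", "AWS", "GBVS"), reference = "AWS")
  expect_equal(spec@fixedTerms,
               c("cb_z", "sal_z", "cb_z_x_IKN98", "cb_z_x_GBVS",
                 "sal_z_x_IKN98", "sal_z_x_GBVS"))
  expect_length(spec@fixedTerms, 6L)   # 7 fixed effects with the intercept
  expect_equal(spec@reference, "AWS")
  expect_equal(spec@mapLevels, c("IKN98", "AWS", "GBVS"))
  # two maps: 1 + 2 + 2 = 5 fixed effects
  expect_equal(countParameters(comparisonSpec(c("A", "B"), "A"))$fixed, 5L)
  expect_error(comparisonSpec(c("A", "B"), reference = "C"), "not among")
})

test_that("expandMapDummies creates predictor-times-indicator columns", {
  spec <- comparisonSpec(c("A", "B", "C"), reference = "A")
  tab <- data.frame(map = c("A", "B", "C", "B"),
                    cb_z = c(1, 2, 3, 4), sal_z = c(0.5, -1, 2, 0))
  out <- expandMapDummies(tab, spec)
  expect_equal(out$cb_z_x_B, c(0, 2, 0, 4))
  expect_equal(out$cb_z_x_C, c(0, 0, 3, 0))
  expect_equal(out$sal_z_x_B, c(0, -1, 0, 0))
  expect_equal(out$sal_z_x_C, c(0, 0, 2, 0))
  # reference rows contribute zero to every dummy column
  expect_true(all(out[out$map == "A",
                      grep("_x_", names(out), value = TRUE)] == 0))
  tab2 <- tab
  tab2$map[1] <- "Z"
  expect_error(expandMapDummies(tab2, spec), "unknown map level")
})

test_that("stackMaps replicates rows per map with a single sal column", {
  tab <- data.frame(subject = "S01", image = "img001", cell = 1:3,
                    fixated = c(1, 0, 1),
                    sal_A = c(0.1, 0.2, 0.3), sal_B = c(0.9, 0.8, 0.7))
  st <- stackMaps(tab, c("A", "B"))
  expect_equal(nrow(st), 6L)
  expect_equal(st$sal[st$map == "A"], tab$sal_A)
  expect_equal(st$sal[st$map == "B"], tab$sal_B)
  expect_false(any(c("sal_A", "sal_B") %in% names(st)))
  expect_equal(st$fixated[st$map == "A"], st$fixated[st$map == "B"])
  expect_error(stackMaps(tab, c("A", "C")), "sal_C")
})

test_that("the control-analysis grid enumerates 189 specifications", {
  specs <- enumerateControlSpecs()
  expect_equal(nrow(specs), 3 * 3 * 7 * 3)
  expect_equal(nrow(specs), 189L)
  expect_equal(anyDuplicated(specs[, c("map", "grid", "centralBias",
                                       "structure")]), 0L)
  expect_setequal(unique(specs$structure), c("maximal", "zcp", "intercept"))
  expect_setequal(unique(specs$cellWidth), c(50, 100, 200))
  expect_equal(length(unique(specs$formula)), 3L)  # one per structure
  expect_true(all(grepl("^fixated ~", specs$formula)))
})

test_that("fitted structures carry the expected parameter counts and LRT dfs", {
  fits <- tinyFits()
  expect_equal(fits$maximal@nPar, 15L)
  expect_equal(fits$zcp@nPar, 9L)
  expect_equal(fits$intercept@nPar, 5L)

  lrt1 <- likelihoodRatioTest(fits$zcp, fits$maximal)
  expect_equal(lrt1$df, 6L)
  expect_equal(lrt1$chisq, 2 * (fits$maximal@logLik - fits$zcp@logLik))
  expect_equal(lrt1$p, pchisq(max(lrt1$chisq, 0), 6, lower.tail = FALSE))

  lrt2 <- likelihoodRatioTest(fits$intercept, fits$zcp)
  expect_equal(lrt2$df, 4L)
  expect_true(lrt2$p >= 0 && lrt2$p <= 1)

  # nesting: the richer structure cannot have lower maximized likelihood
  expect_gte(fits$maximal@logLik + 1e-6, fits$zcp@logLik)
  expect_gte(fits$zcp@logLik + 1e-6, fits$intercept@logLik)

  expect_error(likelihoodRatioTest(fits$maximal, fits$intercept),
               "fewer parameters")
  short <- fits$intercept
  short@nObs <- short@nObs - 1L
  expect_error(likelihoodRatioTest(short, fits$maximal), "different data")
})

test_that("Wald and information-criterion identities hold on a real fit", {
  fit <- tinyFits()$intercept
  w <- waldTable(fit)
  expect_equal(w$z, w$b / w$se)
  expect_equal(w$p, 2 * pnorm(-abs(w$b / w$se)))
  ic <- informationCriteria(fit)
  expect_equal(ic$AIC, -2 * fit@logLik + 2 * fit@nPar)
  expect_equal(ic$BIC, -2 * fit@logLik + fit@nPar * log(fit@nObs))
  expect_equal(ic$AIC, AIC(fit@fit))
  expect_equal(ic$BIC, BIC(fit@fit))
  expect_gt(ic$BIC, ic$AIC)  # log(nObs) > 2 here
})

test_that("the pinned-theta fit agrees with an ordinary GLM", {
  obs <- tinyObservations()
  spec <- modelSpec("fixated", c("cb_z", "sal_z"), corrMode = "intercept")
  pinned <- fitGLMM(spec, obs, pinThetaZero = TRUE)
  ref <- glm(fixated ~ cb_z + sal_z, family = binomial(), data = obs)
  expect_equal(pinned@fixed$b, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(pinned@fixed$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-3)
  expect_equal(pinned@logLik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_true(fitSingular(pinned))
  expect_true(all(unlist(pinned@condModes) == 0))
})

test_that("R-squared follows the latent-scale variance decomposition", {
  obs <- tinyObservations()
  pinned <- fitGLMM(modelSpec("fixated", c("cb_z", "sal_z"),
                              corrMode = "intercept"), obs,
                    pinThetaZero = TRUE)
  r2 <- marginalConditionalR2(pinned)
  varF <- var(pinned@linPredFixed)
  expect_equal(r2$R2marginal, varF / (varF + pi^2 / 3))
  expect_equal(r2$R2conditional, r2$R2marginal)  # no random variance pinned

  fit <- tinyFits()$intercept
  r2f <- marginalConditionalR2(fit)
  expect_gte(r2f$R2conditional, r2f$R2marginal)
  expect_true(r2f$R2marginal > 0 && r2f$R2conditional < 1)
  # intercept-only random structure: varR is the sum of the two variances
  vcs <- randomCovariances(fit)
  varR <- sum(vapply(vcs, function(m) m[1, 1], numeric(1)))
  varF2 <- var(fit@linPredFixed)
  expect_equal(r2f$R2conditional,
               (varF2 + varR) / (varF2 + varR + pi^2 / 3), tolerance = 1e-10)

  bad <- fit
  bad@converged <- FALSE
  expect_error(marginalConditionalR2(bad), "non-converged")
})

test_that("conditional-mode intervals are mode +/- z * sqrt(condVar)", {
  fit <- tinyFits()$intercept
  ci <- conditionalModeIntervals(fit, "image")
  expect_equal(nrow(ci), 8L)
  expect_true(all(ci$lower < ci$mode & ci$mode < ci$upper))
  v <- fit@condVars[["image"]][, "(Intercept)"]
  expect_equal(ci$upper - ci$mode, unname(qnorm(0.975) * sqrt(v)))
  ci50 <- conditionalModeIntervals(fit, "image", level = 0.5)
  expect_true(all(ci50$upper - ci50$lower < ci$upper - ci$lower))
  # shrinkage: conditional modes are centred near zero
  expect_lt(abs(mean(ci$mode)), 0.5)
  expect_error(conditionalModeIntervals(fit, "session"), "session")
})

test_that("individual coefficients are fixed effect plus conditional mode", {
  fit <- tinyFits()$maximal
  ic <- individualCoefficients(fit, "image", "sal_z")
  b <- fit@fixed$b[fit@fixed$term == "sal_z"]
  expect_equal(unname(ic), unname(b + fit@condModes[["image"]][, "sal_z"]))
  expect_named(ic, rownames(fit@condModes[["image"]]))
  expect_error(individualCoefficients(fit, "image", "nope"), "no fixed term")
  expect_error(individualCoefficients(tinyFits()$intercept, "image", "sal_z"),
               "no random term")
})

test_that("derived coefficients sum the simple effect and the interaction", {
  coefs <- c("(Intercept)" = -1.7, "sal_z" = -0.570, "sal_z_x_GBVS" = 0.293)
  expect_equal(derivedFixedCoefficient(coefs, "sal_z", "sal_z_x_GBVS"),
               -0.277)
  expect_equal(derivedFixedCoefficient(coefs, "sal_z_x_GBVS", "sal_z"),
               -0.277)
  expect_error(derivedFixedCoefficient(coefs, "sal_z", "sal_z_x_AWS"),
               "no fixed term")
  fit <- tinyFits()$maximal
  expect_equal(derivedFixedCoefficient(fit, "cb_z", "sal_z"),
               sum(fit@fixed$b[fit@fixed$term %in% c("cb_z", "sal_z")]))
})

test_that("partial effects evaluate the fixed-only linear predictor", {
  fit <- tinyFits()$maximal
  cf <- setNames(fit@fixed$b, fit@fixed$term)
  grid <- data.frame(cb_z = seq(-2, 2, by = 1))
  pe <- partialEffects(fit, c("(Intercept)", "cb_z"), grid)
  expect_equal(pe$eta, cf[["(Intercept)"]] + cf[["cb_z"]] * grid$cb_z)
  peNoInt <- partialEffects(fit, "cb_z", grid)
  expect_equal(peNoInt$eta, cf[["cb_z"]] * grid$cb_z)
  peInt <- partialEffects(fit, "(Intercept)")
  expect_equal(peInt$eta, unname(cf["(Intercept)"]))
  expect_error(partialEffects(fit, c("(Intercept)", "cb_z")), "values")
  expect_error(partialEffects(fit, "zzz"), "unknown fixed term")
})

test_that("refitting identical data reproduces identical estimates", {
  obs <- tinyObservations()
  spec <- modelSpec("fixated", c("cb_z", "sal_z"), corrMode = "intercept")
  f1 <- fitGLMM(spec, obs, control = quickControl())
  f2 <- fitGLMM(spec, obs, control = quickControl())
  expect_identical(f1@fixed$b, f2@fixed$b)
  expect_identical(f1@logLik, f2@logLik)
  expect_identical(randomCovariances(f1), randomCovariances(f2))
})

test_that("input validation catches malformed responses and missing columns", {
  obs <- tinyObservations()
  spec <- modelSpec("nonexistent", c("cb_z"))
  expect_error(fitGLMM(spec, obs), "not in the table")
  obs2 <- obs
  obs2$fixated[1] <- 2
  expect_error(fitGLMM(modelSpec("fixated", "cb_z", corrMode = "intercept"),
                       obs2), "0/1")
  obs3 <- obs
  obs3$count <- obs$fixated + 0.5
  expect_error(fitGLMM(modelSpec("count", "cb_z", corrMode = "intercept"),
                       obs3), "non-negative integers")
})
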