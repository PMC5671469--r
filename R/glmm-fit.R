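#' @include glmm-spec.R
NULL

.familyObject <- function(family) {
  switch(family,
    binomial = stats::binomial(link = "logit"),
    poisson = stats::poisson(link = "log"),
    stop(sprintf("unsupported family '%s'", family))
  )
}

# collect conditional modes/variances per grouping factor, merging the
# separate diagonal blocks a zero-correlation (||) fit produces
.collectRanef <- function(mer) {
  re <- lme4::ranef(mer, condVar = TRUE)
  modes <- list()
  vars <- list()
  for (k in seq_along(re)) {
    f <- names(re)[k]
    blk <- re[[k]]
    pv <- attr(blk, "postVar")
    m <- as.matrix(blk)
    v <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
    if (is.list(pv)) {                      # merged factor with sub-blocks
      j <- 0L
      for (p in pv) {
        d <- dim(p)[1L]
        for (a in seq_len(d)) v[, j + a] <- p[a, a, ]
        j <- j + d
      }
    } else {
      for (a in seq_len(dim(pv)[1L])) v[, a] <- pv[a, a, ]
    }
    if (is.null(modes[[f]])) {
      modes[[f]] <- m
      vars[[f]] <- v
    } else {                                # second block of the same factor
      modes[[f]] <- cbind(modes[[f]], m[rownames(modes[[f]]), , drop = FALSE])
      vars[[f]] <- cbind(vars[[f]], v[rownames(vars[[f]]), , drop = FALSE])
    }
  }
  list(modes = modes, vars = vars)
}

.vcovRandomFromMer <- function(mer) {
  vc <- lme4::VarCorr(mer)
  lapply(vc, function(m) {
    out <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
    out
  })
}

#' Fit a generalized linear mixed model
#'
#' Fits the binomial-logit (or Poisson-log) mixed model described by a
#' \code{\linkS4class{ModelSpec}} (or a formula) by maximizing the
#' Laplace-approximated marginal likelihood, with crossed grouping
#' factors, via \code{lme4::glmer}. Estimation is deterministic: no
#' randomness enters the optimization, so refitting identical data yields
#' identical estimates.
#'
#' Non-convergence never passes silently: optimizer and convergence
#' messages are collected in the returned object and flip
#' \code{fitConverged()} to FALSE. Boundary fits (a variance component
#' estimated at ~0 or a correlation at +/-1) set the singularity flag,
#' mirroring the rule of thumb that such parameters are candidates for
#' removal when selecting a parsimonious random structure.
#'
#' With \code{pinThetaZero = TRUE} all random-effect parameters are fixed
#' at zero and only the fixed effects are profiled out, using the modular
#' deviance function with a quasi-Newton optimizer. This degenerate path
#' is useful as a diagnostic: its estimates must agree with an ordinary
#' generalized linear model fit.
#'
#' @param spec a \code{\linkS4class{ModelSpec}}, or a formula (with
#'   \code{family} then taken from the \code{family} argument).
#' @param table observation table (data.frame).
#' @param family family name, used only when \code{spec} is a formula.
#' @param nAGQ integrator order passed to \code{glmer} (1 = Laplace; 0 =
#'   faster PIRLS-only estimation for large simulation sweeps).
#' @param pinThetaZero fix all random-effect parameters at zero.
#' @param control optional \code{lme4::glmerControl} object.
#' @return a \code{\linkS4class{GLMMFit}}
#' @export
fitGLMM <- function(spec, table, family = "binomial", nAGQ = 1L,
                    pinThetaZero = FALSE, control = NULL) {
  if (is(spec, "ModelSpec")) {
    validObject(spec)
    if (!is.na(spec@mapFactor))
      table <- expandMapDummies(table, spec)
    formula <- stats::as.formula(buildFormula(spec))
    family <- spec@family
    groupCols <- unname(spec@groups)
    need <- unique(c(spec@response, spec@fixedTerms, groupCols))
  } else {
    formula <- stats::as.formula(spec)
    bars <- lme4::findbars(formula)
    groupCols <- unique(vapply(bars, function(b) deparse(b[[3L]]), character(1)))
    need <- setdiff(all.vars(formula), character())
  }
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("column(s) not in the table: ", paste(miss, collapse = ", "))
  df <- as.data.frame(table)
  for (g in groupCols) df[[g]] <- factor(df[[g]])
  fam <- .familyObject(family)
  y <- df[[all.vars(formula)[1L]]]
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial response must be 0/1")
  if (family == "poisson" && (any(y < 0) || any(y != floor(y))))
    stop("poisson response must be non-negative integers")

  if (pinThetaZero)
    return(.fitPinned(formula, df, fam))

  msgs <- character()
  if (is.null(control)) control <- lme4::glmerControl()
  mer <- withCallingHandlers(
    lme4::glmer(formula, data = df, family = fam, nAGQ = nAGQ,
                control = control),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  cf <- stats::coef(summary(mer))
  fixed <- data.frame(term = rownames(cf), b = cf[, 1L], se = cf[, 2L],
                      z = cf[, 3L], p = cf[, 4L], row.names = NULL,
                      stringsAsFactors = FALSE)
  ll <- stats::logLik(mer)
  ranefs <- .collectRanef(mer)
  optMsgs <- unlist(mer@optinfo$conv$lme4$messages)
  converged <- mer@optinfo$conv$opt == 0 && length(optMsgs) == 0L
  new("GLMMFit",
      fixed = fixed,
      vcovRandom = .vcovRandomFromMer(mer),
      logLik = as.numeric(ll),
      nPar = as.integer(attr(ll, "df")),
      nObs = nrow(df),
      condModes = ranefs$modes,
      condVars = ranefs$vars,
      linPredFixed = as.vector(lme4::getME(mer, "X") %*% lme4::fixef(mer)),
      family = family,
      formula = paste(deparse(formula), collapse = " "),
      converged = converged,
      singular = lme4::isSingular(mer, tol = 1e-4),
      messages = c(msgs, optMsgs),
      fit = mer)
}

# degenerate fit: random-effect parameters pinned at zero; only the fixed
# effects are optimized, on lme4's Laplace deviance surface
.fitPinned <- function(formula, df, fam) {
  gf <- lme4::glFormula(formula, data = df, family = fam)
  devfun <- do.call(lme4::mkGlmerDevfun, gf)
  devfun2 <- lme4::updateGlmerDevfun(devfun, gf$reTrms)
  nth <- length(gf$reTrms$theta)
  X <- gf$X
  p <- ncol(X)
  y <- stats::model.response(gf$fr)
  mu0 <- if (fam$family == "binomial") (sum(y) + 0.5) / (length(y) + 1)
         else max(mean(y), 1e-3)
  start <- c(fam$linkfun(mu0), rep(0, p - 1L))
  obj <- function(beta) devfun2(c(rep(0, nth), beta))
  opt <- stats::nlminb(start, obj,
                       control = list(rel.tol = 1e-12, iter.max = 500L))
  beta <- opt$par
  H <- numDeriv::hessian(obj, beta)
  vcv <- 2 * solve(H)                      # deviance = -2 logLik
  se <- sqrt(pmax(diag(vcv), 0))
  z <- beta / se
  fixed <- data.frame(term = colnames(X), b = beta, se = se, z = z,
                      p = 2 * stats::pnorm(-abs(z)), row.names = NULL,
                      stringsAsFactors = FALSE)
  cn <- gf$reTrms$cnms
  fl <- gf$reTrms$flist
  modes <- list()
  vars <- list()
  vcovR <- list()
  for (k in seq_along(cn)) {
    f <- names(cn)[k]
    lv <- levels(fl[[f]])
    m <- matrix(0, length(lv), length(cn[[k]]),
                dimnames = list(lv, cn[[k]]))
    if (is.null(modes[[f]])) {
      modes[[f]] <- m
      vars[[f]] <- m
      vcovR[[f]] <- matrix(0, length(cn[[k]]), length(cn[[k]]),
                           dimnames = list(cn[[k]], cn[[k]]))
    }
  }
  new("GLMMFit",
      fixed = fixed, vcovRandom = vcovR,
      logLik = -opt$objective / 2,
      nPar = as.integer(p), nObs = nrow(X),
      condModes = modes, condVars = vars,
      linPredFixed = as.vector(X %*% beta),
      family = fam$family,
      formula = paste(deparse(formula), collapse = " "),
      converged = opt$convergence == 0,
      singular = TRUE,
      messages = character(),
      fit = NULL)
}

#' Wald z-tests for the fixed effects
#'
#' The Wald z-test scales each estimate by its standard error (z = b/SE)
#' and refers it to the standard normal for a two-sided p-value.
#'
#' @param fit a \code{\linkS4class{GLMMFit}}
#' @return data.frame with columns term, b, se, z, p.
#' @export
waldTable <- function(fit) {
  stopifnot(is(fit, "GLMMFit"))
  out <- fit@fixed
  out$z <- out$b / out$se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out
}

#' Likelihood-ratio test between nested fits
#'
#' chi-square = 2 (logLik_full - logLik_nested), df = difference in
#' estimated parameter counts, p from the chi-square distribution (no
#' boundary correction: variance components tested this way sit on the
#' boundary of the parameter space, so the chi-square reference is
#' conservative there).
#'
#' @param nested,full \code{\linkS4class{GLMMFit}} objects on the same
#'   data; the nested model must be a restriction of the full one.
#' @return data.frame with columns chisq, df, p.
#' @export
likelihoodRatioTest <- function(nested, full) {
  stopifnot(is(nested, "GLMMFit"), is(full, "GLMMFit"))
  if (nested@nObs != full@nObs)
    stop("models were fitted to different data (observation counts differ)")
  if (!all(nested@fixed$term %in% full@fixed$term))
    stop("models are not nested: the reduced model has fixed terms the full model lacks")
  df <- full@nPar - nested@nPar
  if (df < 0)
    stop("models are not nested: the 'full' model has fewer parameters")
  chisq <- 2 * (full@logLik - nested@logLik)
  p <- if (df == 0L) NA_real_ else stats::pchisq(max(chisq, 0), df,
                                                 lower.tail = FALSE)
  data.frame(chisq = chisq, df = df, p = p)
}

#' Information criteria of a fit
#'
#' AIC = -2 logLik + 2k penalizes the parameter count k; BIC = -2 logLik
#' + k log(N) additionally scales the penalty with the number of
#' observations N. Both decrease with goodness of fit.
#'
#' @param fit a \code{\linkS4class{GLMMFit}}
#' @return named list with AIC and BIC.
#' @export
informationCriteria <- function(fit) {
  stopifnot(is(fit, "GLMMFit"))
  list(AIC = -2 * fit@logLik + 2 * fit@nPar,
       BIC = -2 * fit@logLik + fit@nPar * log(fit@nObs))
}

#' Marginal and conditional R-squared of a GLMM
#'
#' Variance-explained measures on the latent (link) scale: the marginal
#' R2 is the share of the fixed-effect linear-predictor variance in the
#' total latent variance (fixed + random + distribution-specific residual
#' variance), and the conditional R2 adds the random-effect variance to
#' the numerator. The residual variance is pi^2/3 for the binomial-logit
#' model and log(1 + 1/lambda-bar) for the Poisson-log model (lambda-bar =
#' mean observed count). Random-slope contributions are included via the
#' observation-level average of the random-effect design variance.
#'
#' @param fit a converged \code{\linkS4class{GLMMFit}}
#' @return named list with R2marginal and R2conditional.
#' @export
marginalConditionalR2 <- function(fit) {
  stopifnot(is(fit, "GLMMFit"))
  if (!fit@converged)
    stop("R-squared is undefined for a non-converged fit")
  varF <- stats::var(fit@linPredFixed)
  varR <- 0
  if (!is.null(fit@fit)) {
    mm <- lme4::getME(fit@fit, "mmList")
    vc <- lme4::VarCorr(fit@fit)
    for (k in seq_along(mm)) {
      S <- matrix(as.numeric(vc[[k]]), nrow(vc[[k]]), ncol(vc[[k]]))
      M <- mm[[k]]
      varR <- varR + mean(rowSums((M %*% S) * M))
    }
  }
  varD <- if (fit@family == "binomial") {
    pi^2 / 3
  } else {
    lam <- if (!is.null(fit@fit)) mean(lme4::getME(fit@fit, "y"))
           else mean(exp(fit@linPredFixed))
    log(1 + 1 / lam)
  }
  tot <- varF + varR + varD
  list(R2marginal = varF / tot, R2conditional = (varF + varR) / tot)
}

#' Conditional modes with 95% prediction intervals
#'
#' The conditional mode of a group level is the most likely value of its
#' random effect given the data (the mixed-model "prediction" for that
#' subject or scene). Prediction intervals are mode +/- z * sqrt(conditional
#' variance); levels whose interval excludes zero deviate reliably from
#' the population fixed effect. This is the data product behind
#' caterpillar plots.
#'
#' @param fit a \code{\linkS4class{GLMMFit}}
#' @param factor grouping-factor name (e.g. "subject" or "image").
#' @param level coverage of the interval (default 0.95).
#' @return data.frame with columns level (group level), term, mode,
#'   lower, upper.
#' @export
conditionalModeIntervals <- function(fit, factor, level = 0.95) {
  stopifnot(is(fit, "GLMMFit"))
  if (!factor %in% names(fit@condModes))
    stop(sprintf("no random effects for grouping factor '%s'", factor))
  m <- fit@condModes[[factor]]
  v <- fit@condVars[[factor]]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- do.call(rbind, lapply(colnames(m), function(trm) {
    data.frame(level = rownames(m), term = trm, mode = m[, trm],
               lower = m[, trm] - zq * sqrt(v[, trm]),
               upper = m[, trm] + zq * sqrt(v[, trm]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Individual coefficients per group level
#'
#' The coefficient of a subject or scene item for a given term is the sum
#' of the fixed-effect estimate and that level's conditional mode. A value
#' near zero for a saliency slope means salience has no impact on fixation
#' selection for that particular scene.
#'
#' @param fit a \code{\linkS4class{GLMMFit}}
#' @param factor grouping-factor name.
#' @param term fixed-effect term name (must also be a random term of the
#'   factor).
#' @return named numeric vector (one value per group level).
#' @export
individualCoefficients <- function(fit, factor, term) {
  stopifnot(is(fit, "GLMMFit"))
  b <- fit@fixed$b[match(term, fit@fixed$term)]
  if (is.na(b)) stop(sprintf("no fixed term '%s'", term))
  m <- fit@condModes[[factor]]
  if (is.null(m) || !term %in% colnames(m))
    stop(sprintf("factor '%s' has no random term '%s'", factor, term))
  stats::setNames(b + m[, term], rownames(m))
}

#' Derived fixed-effect coefficient under treatment coding
#'
#' In the treatment-coded comparison model the coefficient of a
#' non-reference saliency map is the simple-effect coefficient (reference
#' level) plus the relevant interaction coefficient. Accepts a fit or a
#' plain named coefficient vector.
#'
#' @param fit a \code{\linkS4class{GLMMFit}} or a named numeric vector of
#'   fixed-effect estimates.
#' @param baseTerm,interactionTerm the two term names to sum (order
#'   irrelevant).
#' @return numeric(1)
#' @export
derivedFixedCoefficient <- function(fit, baseTerm, interactionTerm) {
  coefs <- if (is(fit, "GLMMFit"))
    stats::setNames(fit@fixed$b, fit@fixed$term)
  else fit
  for (trm in c(baseTerm, interactionTerm))
    if (!trm %in% names(coefs)) stop(sprintf("no fixed term '%s'", trm))
  unname(coefs[[baseTerm]] + coefs[[interactionTerm]])
}

#' Partial fixed-effect predictions
#'
#' Evaluates the linear predictor (link scale, e.g. log-odds) using only a
#' chosen subset of the fixed effects, with all random-effect
#' contributions removed: the partial effect of a predictor with all other
#' model terms statistically controlled. Supply the term values at which
#' to evaluate; keeping only the intercept yields a constant.
#'
#' @param fit a \code{\linkS4class{GLMMFit}}
#' @param keepTerms character vector of fixed terms to retain; include
#'   \code{"(Intercept)"} to keep the intercept.
#' @param values data.frame with one column per kept non-intercept term
#'   (the predictor grid); may be omitted if only the intercept is kept.
#' @return data.frame: the value grid plus an \code{eta} column with the
#'   partial linear predictor.
#' @export
partialEffects <- function(fit, keepTerms, values = NULL) {
  stopifnot(is(fit, "GLMMFit"))
  coefs <- stats::setNames(fit@fixed$b, fit@fixed$term)
  miss <- setdiff(keepTerms, names(coefs))
  if (length(miss))
    stop("unknown fixed term(s): ", paste(miss, collapse = ", "))
  slopeTerms <- setdiff(keepTerms, "(Intercept)")
  if (length(slopeTerms)) {
    if (is.null(values) || !all(slopeTerms %in% names(values)))
      stop("values must supply a column for every kept non-intercept term")
    values <- as.data.frame(values)
    eta <- rep(0, nrow(values))
    for (trm in slopeTerms) eta <- eta + coefs[[trm]] * values[[trm]]
  } else {
    values <- data.frame(row.names = 1L)
    eta <- 0
  }
  if ("(Intercept)" %in% keepTerms) eta <- eta + coefs[["(Intercept)"]]
  out <- values
  out$eta <- eta
  out
}
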