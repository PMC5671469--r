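---
title: "Methods: grid-based GLMM evaluation of saliency and central bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-based GLMM evaluation of saliency and central bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sceneGLMM)
```

# The statistical problem

Computational saliency models assign every image location a conspicuity
value, and they are routinely evaluated by how well those values predict
where people fixate. Two confounds make naive evaluations optimistic.
First, observers fixate near the image centre regardless of content (the
*central fixation bias*). Second, photographers place interesting,
high-salience content near the centre (the *photographer bias*), so
saliency and centrality are correlated in natural photographs. A saliency
model can therefore look predictive while merely re-describing the
centre preference.

sceneGLMM implements an analysis that separates these influences. The
image is parcellated into a regular grid of rectangular patches, each
(subject, image, patch) triplet becomes one observation with a binary
*fixated* indicator (or a fixation count), and the indicator is modelled
with a generalized linear mixed model (GLMM) containing both a
distance-to-centre predictor and the patch's mean saliency. The saliency
effect is then the part that survives statistical control of centrality,
with subject- and image-level heterogeneity absorbed by crossed random
effects.

# The model

For subject $s$, image $i$ and patch $c$ the binary model is

$$
\mathrm{logit}\, P(\text{fixated}_{sic} = 1)
  = (\beta_0 + S_{0s} + I_{0i})
  + (\beta_1 + S_{1s} + I_{1i})\, \mathrm{cb}_{ic}
  + (\beta_2 + S_{2s} + I_{2i})\, \mathrm{sal}_{ic},
$$

with $(S_{0s}, S_{1s}, S_{2s}) \sim N(0, \Sigma_S)$ per subject and
$(I_{0i}, I_{1i}, I_{2i}) \sim N(0, \Sigma_I)$ per image, crossed. A
Poisson--log variant replaces the indicator with the per-patch fixation
count. Estimation maximizes the Laplace-approximated marginal likelihood
(`fitGLMM()`, which drives `lme4::glmer` behind an S4 surface).
Predictors are z-standardized over the rows entering the model
(`standardizeColumns()`, $n-1$ denominator), so fixed effects are
comparable across predictors and models.

## Central-bias predictors

Patch centres are expressed in a normalized frame: the image centre is
$(0, 0)$ and half the image width equals 1. Three measures, each a
function of the normalized offsets $(dx, dy)$:

* **Euclidean** $\sqrt{dx^2 + dy^2/\nu}$,
* **Gaussian** $-\exp\!\big(-dx^2/(2\sigma^2) - dy^2/(2\sigma^2\nu)\big)$,
* **taxicab** $|dx| + |dy|$ (no anisotropic variant; requesting one is an
  error).

The anisotropy $\nu$ takes three canonical values: $1$ (isotropic), the
inverse aspect ratio $h/w$ (aspect-ratio variant; $0.75$ for $4{:}3$
images), and the default $0.45$, a stronger horizontal elongation matching
the empirically flattened fixation distribution in scene viewing. With the
default horizontal variance $\sigma^2 = 0.23$, the Gaussian's vertical
variance is $\nu\sigma^2 = 0.1035 \approx 0.10$. Two measures with three
variants each, plus the taxicab distance, give the seven canonical
predictors of `canonicalCentralBias()`.

## Grid parcellation and the observation matrix

`buildGrid()` divides a $w \times h$ image into half-open cells
$[x_0, x_0 + c_w) \times [y_0, y_0 + c_h)$ in row-major order, so every
pixel belongs to exactly one cell and boundary fixations resolve
deterministically (to the cell right/below). The default grid for
$800 \times 600$ images uses 100-px cells, an $8 \times 6 = 48$-cell
parcellation; $16 \times 12$ (50 px) and $4 \times 3$ (200 px) grids serve
as resolution controls.

The first fixation of each trial sits on the pre-trial fixation cross and
spills into scene onset, so `excludeInitialFixation()` removes it *and*
excludes its cell from that trial entirely -- later revisits to that cell
are dropped too, because a revisit cannot be distinguished from a
continuation of the initial dwell. If the initial fixation landed outside
the image only the fixation is dropped. A complete design of 42 subjects
$\times$ 150 images $\times$ 48 cells yields 302,400 rows before
exclusions; per-trial excluded cells and missing trials shrink the table
accordingly (8 missing trials: 302,016).

## Random-effects structures and model selection

Three structures per grouping factor: **maximal** (correlated intercept
and slopes), **zcp** (zero-correlation parameterization, `||`) and
**intercept-only**. A factor with $m$ random terms contributes $m$
variances plus $m(m-1)/2$ correlations under the maximal structure
(`countParameters()`); for the three-map comparison model with 7 fixed
effects this is $2 \times (7 + 21) = 56$ random-effect parameters, against
14 for the zcp structure. Structures are compared by likelihood-ratio
tests (`likelihoodRatioTest()`; for the two-predictor model the
maximal-vs-zcp test has 6 df and zcp-vs-intercept 4 df) and by AIC/BIC.
Variance components tested this way lie on the boundary of the parameter
space, making the $\chi^2$ reference conservative; we report the
uncorrected p-value and document the conservatism rather than applying a
mixture correction, keeping the test identical to standard practice.
Singular fits (variances at $\sim 0$, correlations at $\pm 1$) are flagged
via `lme4::isSingular` with tolerance $10^{-4}$.

## Comparing saliency models

To test whether maps differ, the observation table is stacked
(`stackMaps()`): each row is replicated once per map with a single `sal`
column, and a treatment-coded map factor distinguishes replicates. Rather
than relying on formula-level factor expansion, `expandMapDummies()`
materializes each interaction as an explicit column
$p \times \mathbf{1}[\text{map} = L]$ named `<pred>_x_<level>`; this makes
all three random structures expressible in plain formula syntax and makes
the coefficient bookkeeping visible in the data. With three maps the fixed
part has $1 + 2 + 2 \times 2 = 7$ coefficients; a non-reference map's own
slope is the simple effect plus its interaction
(`derivedFixedCoefficient()`). The robustness sweep over 3 maps $\times$ 3
grids $\times$ 7 central-bias predictors $\times$ 3 structures enumerates
189 specifications (`enumerateControlSpecs()`).

## Effect summaries

`marginalConditionalR2()` reports latent-scale variance decompositions:
marginal $R^2$ is the fixed-effect share of fixed + random +
distribution-specific residual variance ($\pi^2/3$ for the logit,
$\log(1 + 1/\bar\lambda)$ for the Poisson log link), conditional $R^2$
adds the random share to the numerator; random-slope contributions enter
via the observation-level average of the random-effect design variance.
`conditionalModeIntervals()` returns conditional modes with
mode $\pm z\sqrt{\text{conditional variance}}$ prediction intervals
(caterpillar-plot data), and `individualCoefficients()` adds fixed effect
and mode into per-subject or per-scene coefficients.

# The synthetic-data generator

Because real eye-tracking corpora and saliency algorithms are heavy
external dependencies, the package ships a generator that inverts the
analysis model exactly, giving ground truth for end-to-end validation.

**Saliency maps** are sums of isotropic Gaussian blobs, min-max
normalized. Blob centres are drawn uniformly from the image *extended by a
two-sigma margin* -- without the margin, maps at $\kappa = 0$ would have
depressed salience at the edges and a spurious negative
salience--centrality correlation; with it, $\kappa = 0$ gives
$|\rho| < 0.1$. The photographer bias is a single knob: centres are shrunk
toward the image centre by $1/(1 + \kappa)$. The correlation deepens
monotonically in $\kappa$; the default $\kappa = 0.6$ produces a Spearman
correlation near $-0.3$, the modest bias typical of natural photographs,
and `calibratePhotographerBias()` bisects $\kappa$ into any requested band
(e.g. $[-0.5, -0.25]$) using common random numbers.

**Responses** are sampled from the GLMM above with known $\beta$ and
covariances; the default covariances use item variances several times the
subject variances and moderate positive intercept--slope correlations, the
magnitudes such analyses report. Fixation *points* are then emitted
uniformly inside each fixated cell (with optional Poisson refixations to
exercise the count response), shuffled, and prefixed with an initial
central fixation so the exclusion rule is exercised. Everything is
seed-deterministic. The generator's realism is deliberately limited: no
saccadic dynamics, no spatial correlation between neighbouring cells
beyond what the map induces, and fixation durations are constant -- it
targets the *statistical* structure the estimator sees, not oculomotor
realism.

## Validation suite sizes

The test and acceptance suites size their simulations for a single desk
CPU; the sizes are the package's own choice of a convincing-but-quick
demonstration, and all of them can be scaled up by editing one number:

* **Oracle check**: 50 random small GLM datasets; the pinned-theta fit
  (below) must match `stats::glm` within $10^{-4}$.
* **Parameter recovery**: 12 replicates of a 20-subject $\times$ 30-image
  $\times$ 12-cell design, maximal structure; means must lie within 2
  Monte-Carlo SEs of the generating $\beta_{cb} = -0.6$,
  $\beta_{sal} = 0.7$.
* **Type-I error**: 200 replicates of a 10 $\times$ 15 $\times$ 12 design
  with $\beta_{sal} = 0$ and a correctly specified intercept-only
  structure; the Wald rejection rate must fall in $0.05 \pm 0.03$.

# Numerical choices

* **Optimizer hygiene.** Maximal fits use
  `glmerControl(calc.derivs = FALSE)` in the simulation suites: the
  finite-difference derivative check at the optimum is the dominant cost
  on these fits and occasionally raises spurious convergence warnings;
  disabling it changes no estimates. Convergence and singularity flags are
  always carried in the fit object -- non-convergence never passes
  silently, and `marginalConditionalR2()` refuses non-converged fits.
* **Pinned-theta diagnostic route.** `fitGLMM(..., pinThetaZero = TRUE)`
  fixes all random-effect parameters at zero and optimizes only the fixed
  effects on lme4's modular deviance surface (`nlminb`, relative tolerance
  $10^{-12}$), with standard errors from a numerical Hessian of the
  deviance. This degenerate GLMM must agree with an independently fitted
  GLM (IRLS) -- a dual-route check that exercises the deviance machinery
  end to end rather than comparing a function to itself.
* **Determinism.** Estimation is deterministic; generation is
  deterministic given a seed; `runSimulate()` output is byte-identical
  across runs with the same configuration.
* **Raster input.** PNG/TIFF/JPEG rasters are collapsed to luminance with
  Rec. 709 weights (0.2126, 0.7152, 0.0722); maps are min-max normalized
  before cell means are taken so that heterogeneous map scales cannot leak
  into coefficients. JPEG is accepted because saliency maps are smooth and
  compression artefacts are negligible at the cell-mean level, but PNG is
  the recommended interchange format.

# Reproducible runs

`readRunConfig()` merges a YAML file over documented defaults and
validates before any computation; each `run*()` command writes its
configuration, package version and seed alongside its outputs, and the
`inst/scripts/scene-glmm` script exposes the commands
(parcellate, simulate, features, obsmatrix, fit, evaluate) on the command
line with exit codes 0 (success), 1 (user error), 2 (internal error).
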