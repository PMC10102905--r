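#' Study period for a tropical cyclone
#'
#' Holds the ten contiguous two-week intervals that make up the analysis
#' window around a storm's first US approach.  The final interval is pinned
#' to begin 2 days before and end 11 days after first approach; the nine
#' earlier intervals are anchored backwards from it, so the window opens 128
#' days before first approach.
#'
#' @slot firstApproach `Date`, the storm's first US approach.
#' @slot intervalStart,intervalEnd `Date` vectors of length 10 giving the
#'   inclusive bounds of each two-week interval.
#' @slot treatmentIndex integer, index of the treatment interval (always the
#'   last, 10).
#' @seealso [defineStudyPeriod()]
#' @export
setClass("StudyPeriod",
  representation(
    firstApproach = "Date",
    intervalStart = "Date",
    intervalEnd = "Date",
    treatmentIndex = "integer"
  )
)

setValidity("StudyPeriod", function(object) {
  msg <- character()
  ns <- length(object@intervalStart)
  if (ns != 10L || length(object@intervalEnd) != 10L)
    msg <- c(msg, "exactly 10 intervals are required")
  if (ns == 10L) {
    len <- as.integer(object@intervalEnd - object@intervalStart) + 1L
    if (!all(len == 14L))
      msg <- c(msg, "every interval must span 14 days")
    gap <- as.integer(object@intervalStart[-1] - object@intervalEnd[-ns])
    if (!all(gap == 1L))
      msg <- c(msg, "intervals must be contiguous and non-overlapping")
    if (object@intervalStart[10] != object@firstApproach - 2L)
      msg <- c(msg, "final interval must begin 2 days before first approach")
    if (object@intervalEnd[10] != object@firstApproach + 11L)
      msg <- c(msg, "final interval must end 11 days after first approach")
  }
  if (!identical(object@treatmentIndex, 10L))
    msg <- c(msg, "treatmentIndex must be 10")
  if (length(msg)) msg else TRUE
})

#' Analytic treated/control set for one storm
#'
#' The result of applying the eligibility and exclusion rules to the
#' candidate counties of a single storm: which counties are analytic treated
#' units, which are analytic controls, and why each excluded county was
#' dropped (first triggering rule).
#'
#' @slot stormId character storm identifier.
#' @slot treated,control character vectors of retained county ids.
#' @slot exclusions `data.frame` with columns `county_id`, `role`
#'   (treated/control at classification) and `reason`.
#' @seealso [selectAnalyticSet()], [qualifyStorm()]
#' @export
setClass("AnalyticSet",
  representation(
    stormId = "character",
    treated = "character",
    control = "character",
    exclusions = "data.frame"
  )
)

setValidity("AnalyticSet", function(object) {
  if (length(intersect(object@treated, object@control)))
    return("treated and control sets must be disjoint")
  TRUE
})

#' County-by-interval panel for one storm
#'
#' A [SummarizedExperiment::SummarizedExperiment] with counties as rows and
#' two-week intervals as columns, carrying three assays:
#' \describe{
#'   \item{`counts`}{observed event counts \eqn{Y_{it}} (non-negative
#'     integers);}
#'   \item{`mask`}{the treatment indicator \eqn{D_{it}}, 1 exactly for
#'     treated counties in the treatment interval(s) \eqn{t \ge T_0} (cells
#'     whose counterfactual is imputed);}
#'   \item{`offset`}{positive population denominators \eqn{p_{it}}.}
#' }
#' `rowData` records the county role ("treated"/"control") and population;
#' metadata stores the storm id, the treatment start column `T0`, the
#' [StudyPeriod] (when known) and the exclusion log.
#'
#' @param x a `StormPanel`.
#' @return `panelCounts`, `treatmentMask` and `panelOffsets` return the
#'   respective assay matrix; `treatedIds`/`controlIds` the county ids by
#'   role; `treatmentStart` the column index \eqn{T_0}; `stormId` the storm
#'   identifier.
#' @seealso [buildPanel()], [fitMCModel()]
#' @aliases panelCounts treatmentMask panelOffsets treatedIds controlIds
#'   treatmentStart stormId
#' @export
setClass("StormPanel", contains = "SummarizedExperiment")

setValidity("StormPanel", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c("counts", "mask", "offset")
  if (!all(need %in% an))
    return(sprintf("assays must include %s", paste(need, collapse = ", ")))
  Y <- SummarizedExperiment::assay(object, "counts")
  D <- SummarizedExperiment::assay(object, "mask")
  p <- SummarizedExperiment::assay(object, "offset")
  if (any(!is.finite(Y)) || any(Y < 0) || any(Y != round(Y)))
    msg <- c(msg, "counts must be finite non-negative integers")
  if (!all(D %in% c(0, 1)))
    msg <- c(msg, "mask must be binary")
  if (any(!is.finite(p)) || any(p <= 0))
    msg <- c(msg, "offsets must be positive and finite")
  T0 <- S4Vectors::metadata(object)$T0
  if (is.null(T0) || T0 < 1L || T0 > ncol(object))
    msg <- c(msg, "metadata$T0 must index a column")
  else if (ncol(object) > 0) {
    pre <- D[, seq_len(T0 - 1L), drop = FALSE]
    if (any(pre != 0))
      msg <- c(msg, "mask must be zero before the treatment start T0")
    post <- D[, T0:ncol(object), drop = FALSE]
    rowAny <- rowSums(post) > 0
    if (any(rowAny & rowSums(post) != ncol(post)))
      msg <- c(msg, "treated rows must be masked for all t >= T0")
  }
  if (length(msg)) msg else TRUE
})

#' Model specification for the count matrix-completion fit
#'
#' Bundles the latent dimension, likelihood, prior scales and MCMC settings
#' of the Bayesian matrix-completion model fit by [fitMCModel()].
#'
#' @slot K integer number of latent factors (0 gives a two-way
#'   county + interval model).
#' @slot likelihood `"negbin"` (default) or `"poisson"`.
#' @slot priorScales named numeric: SDs of the normal priors on the
#'   intercept, county and interval effects and the latent factor loadings,
#'   and the half-normal scale on the inverse-root dispersion.
#' @slot chains,drawsPerChain,warmup,adapt MCMC settings.
#' @slot seed integer sampler seed.
#' @seealso [mcModelSpec()]
#' @export
setClass("MCModelSpec",
  representation(
    K = "integer",
    likelihood = "character",
    priorScales = "numeric",
    chains = "integer",
    drawsPerChain = "integer",
    warmup = "integer",
    adapt = "integer",
    seed = "integer"
  )
)

setValidity("MCModelSpec", function(object) {
  msg <- character()
  if (object@K < 0L) msg <- c(msg, "K must be >= 0")
  if (!object@likelihood %in% c("negbin", "poisson"))
    msg <- c(msg, "likelihood must be 'negbin' or 'poisson'")
  need <- c("intercept", "county", "interval", "factor", "dispersion")
  if (!all(need %in% names(object@priorScales)) ||
      any(object@priorScales[need] <= 0))
    msg <- c(msg, "priorScales must name positive intercept/county/interval/factor/dispersion scales")
  if (object@chains < 1L) msg <- c(msg, "chains must be >= 1")
  if (object@drawsPerChain < 1L) msg <- c(msg, "drawsPerChain must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Posterior draws of the matrix-completion model
#'
#' MCMC output of [fitMCModel()].  Parameter draws are stored flattened
#' across chains (M = chains x drawsPerChain rows); the per-draw linear
#' predictor \eqn{\alpha + \gamma_i + \psi_t + U_i \cdot V_t + \log p_{it}}
#' can be reconstructed exactly with [linearPredictor()].  Convergence is
#' assessed on the predicted counterfactual means of the masked cells, not
#' on the unidentifiable raw factors.
#'
#' @slot panel the [StormPanel] the model was fit to.
#' @slot spec the [MCModelSpec] used.
#' @slot alpha numeric M; global intercept draws.
#' @slot gamma,psi M x N and M x T matrices of county and interval effects.
#' @slot U,V M x N x K and M x T x K arrays of latent factors.
#' @slot phi numeric M; NB dispersion draws (empty for Poisson likelihood).
#' @slot chain integer M; chain of origin of each draw.
#' @slot diagnostics list: split-Rhat of masked-cell predictive means
#'   (`rhat`), `maxRhat`, `converged` flag, notices.
#' @param x an `MCFit`.
#' @aliases nDraws mcDiagnostics
#' @seealso [fitMCModel()], [imputeCounterfactuals()]
#' @export
setClass("MCFit",
  representation(
    panel = "StormPanel",
    spec = "MCModelSpec",
    alpha = "numeric",
    gamma = "matrix",
    psi = "matrix",
    U = "array",
    V = "array",
    phi = "numeric",
    chain = "integer",
    diagnostics = "list"
  )
)

setValidity("MCFit", function(object) {
  M <- length(object@alpha)
  msg <- character()
  if (nrow(object@gamma) != M || nrow(object@psi) != M)
    msg <- c(msg, "gamma/psi must have one row per draw")
  if (length(object@phi) && length(object@phi) != M)
    msg <- c(msg, "phi must have one value per draw")
  if (length(object@chain) != M)
    msg <- c(msg, "chain must label every draw")
  if (length(msg)) msg else TRUE
})

#' Posterior-predictive counterfactual draws
#'
#' M posterior-predictive samples of the counterfactual count
#' \eqn{Y_{it}(0)} for every masked (treated) cell of a panel, drawn from
#' the negative binomial with each posterior draw's mean and dispersion.
#'
#' @slot Y0 M x C integer matrix of counterfactual samples; columns are
#'   masked cells.
#' @slot cells `data.frame` with columns `county_id`, `row`, `interval`
#'   locating each column of `Y0` in the panel.
#' @slot stormId character.
#' @param x a `CounterfactualDraws`.
#' @aliases counterfactualCells counterfactualMatrix
#' @seealso [imputeCounterfactuals()], [computeIEE()]
#' @export
setClass("CounterfactualDraws",
  representation(
    Y0 = "matrix",
    cells = "data.frame",
    stormId = "character"
  )
)

setValidity("CounterfactualDraws", function(object) {
  msg <- character()
  if (ncol(object@Y0) != nrow(object@cells))
    msg <- c(msg, "one cells row is required per Y0 column")
  if (ncol(object@Y0) > 0 &&
      (any(object@Y0 < 0) || any(object@Y0 != round(object@Y0))))
    msg <- c(msg, "counterfactual draws must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Posterior excess events and excess rates for one storm
#'
#' Per treated county, M posterior draws of the individual excess events
#' (IEE) \eqn{\theta_i = \sum_{t \ge T_0} (Y_{it} - Y_{it}(0))} and of the
#' individual excess rate \eqn{\theta^*_i = 100\,000 \, \theta_i / p_{iT}}.
#'
#' @slot stormId character.
#' @slot countyIds character, treated county ids (columns of the draw
#'   matrices).
#' @slot theta M x n matrix of excess-event draws.
#' @slot thetaStar M x n matrix of excess-rate draws (per 100 000).
#' @slot populations numeric n, the denominators \eqn{p_{iT}}.
#' @param x an `EffectPosterior`.
#' @aliases ieeDraws excessRateDraws
#' @seealso [computeIEE()], [summarizeStorm()], [summarizeStudy()]
#' @export
setClass("EffectPosterior",
  representation(
    stormId = "character",
    countyIds = "character",
    theta = "matrix",
    thetaStar = "matrix",
    populations = "numeric"
  )
)

setValidity("EffectPosterior", function(object) {
  msg <- character()
  n <- length(object@countyIds)
  if (ncol(object@theta) != n || ncol(object@thetaStar) != n ||
      length(object@populations) != n)
    msg <- c(msg, "theta, thetaStar and populations must cover every county")
  if (nrow(object@theta) != nrow(object@thetaStar))
    msg <- c(msg, "theta and thetaStar must hold the same number of draws")
  if (any(object@populations <= 0))
    msg <- c(msg, "populations must be positive")
  ok <- all(abs(object@thetaStar - 1e5 * sweep(object@theta, 2,
              object@populations, "/")) < 1e-8)
  if (!ok)
    msg <- c(msg, "thetaStar must equal 100000 * theta / population per draw")
  if (length(msg)) msg else TRUE
})

#' Specification of the predictive (second-stage) model
#'
#' Describes the Bayesian linear model \eqn{\theta^* = g(X;\beta)} relating
#' county-level excess rates to storm and community features: which features
#' enter linearly, which through a restricted cubic spline, the knot rule,
#' and the normal--inverse-gamma prior.
#'
#' @slot linearVars,splineVars character vectors of feature names.
#' @slot nKnots integer, knots per spline (default 4, at the 5/35/65/95
#'   percentiles of the training values).
#' @slot priorCoefScale numeric; prior SD multiplier g in
#'   \eqn{\beta | \sigma^2 \sim N(0, g^2 \sigma^2 I)} on standardized
#'   columns.
#' @slot priorSigmaA,priorSigmaB inverse-gamma shape/rate on \eqn{\sigma^2}.
#' @slot standardize logical; center/scale design columns by training
#'   statistics (stored in the schema for prediction-time reuse).
#' @seealso [predictiveModelSpec()], [fitModular()]
#' @export
setClass("PredictiveModelSpec",
  representation(
    linearVars = "character",
    splineVars = "character",
    nKnots = "integer",
    priorCoefScale = "numeric",
    priorSigmaA = "numeric",
    priorSigmaB = "numeric",
    standardize = "logical"
  )
)

setValidity("PredictiveModelSpec", function(object) {
  msg <- character()
  if (length(intersect(object@linearVars, object@splineVars)))
    msg <- c(msg, "a feature may enter linearly or through a spline, not both")
  if (object@nKnots < 3L)
    msg <- c(msg, "restricted cubic splines need at least 3 knots")
  if (object@priorCoefScale <= 0 || object@priorSigmaA <= 0 ||
      object@priorSigmaB <= 0)
    msg <- c(msg, "prior scales must be positive")
  if (length(msg)) msg else TRUE
})

#' Modularized (or plug-in) predictive-model posterior
#'
#' Coefficient draws of the second-stage Bayesian linear model.  In the
#' modular (cut-posterior) fit, draw m of \eqn{\beta} is the single exact
#' posterior sample conditioned on the m-th causal draw of all excess
#' rates, so first-stage uncertainty is inherited but never flows back.  In
#' the plug-in fit all draws condition on the posterior-mean excess rates.
#'
#' @slot beta M x p matrix of coefficient draws (standardized design space).
#' @slot sigma numeric M residual-SD draws.
#' @slot schema list describing the design: term names, spline knots,
#'   column centers/scales.
#' @slot spec the [PredictiveModelSpec].
#' @slot mode `"modular"` or `"plugin"`.
#' @param x a `ModularFit`.
#' @param ... passed on; `scale = "original"` (default) or
#'   `"standardized"` selects the coefficient scale.
#' @aliases coefDraws coefSummary
#' @seealso [fitModular()], [fitPlugin()], [predictNew()]
#' @export
setClass("ModularFit",
  representation(
    beta = "matrix",
    sigma = "numeric",
    schema = "list",
    spec = "PredictiveModelSpec",
    mode = "character"
  )
)

setValidity("ModularFit", function(object) {
  msg <- character()
  if (nrow(object@beta) != length(object@sigma))
    msg <- c(msg, "one sigma draw is required per beta draw")
  if (!object@mode %in% c("modular", "plugin"))
    msg <- c(msg, "mode must be 'modular' or 'plugin'")
  if (length(msg)) msg else TRUE
})

#' Posterior-predictive risk prediction for new exposures
#'
#' Excess-rate predictions \eqn{\theta^*_{new}} for new storm/county
#' feature vectors: one posterior-predictive draw per retained coefficient
#' draw, plus summaries.
#'
#' @slot draws M x n matrix of predictive draws (rows = draws, columns =
#'   new exposures).
#' @slot summary `data.frame` with posterior mean and central 95% bounds
#'   per new exposure.
#' @slot newdata the feature rows the prediction was made for.
#' @seealso [predictNew()]
#' @export
setClass("RiskPrediction",
  representation(
    draws = "matrix",
    summary = "data.frame",
    newdata = "data.frame"
  )
)

## ---- show methods -------------------------------------------------------

setMethod("show", "StudyPeriod", function(object) {
  cat("StudyPeriod: 10 two-week intervals,",
      format(object@intervalStart[1]), "to",
      format(object@intervalEnd[10]), "\n")
  cat("  first approach:", format(object@firstApproach),
      "| treatment interval:", object@treatmentIndex, "\n")
})

setMethod("show", "AnalyticSet", function(object) {
  cat("AnalyticSet for storm", object@stormId, ":",
      length(object@treated), "treated,",
      length(object@control), "control,",
      nrow(object@exclusions), "excluded\n")
})

setMethod("show", "StormPanel", function(object) {
  cat("StormPanel:", nrow(object), "counties x", ncol(object),
      "intervals (storm ", S4Vectors::metadata(object)$stormId, ")\n",
      sep = "")
  cat("  treated:", length(treatedIds(object)),
      "| control:", length(controlIds(object)),
      "| T0 =", treatmentStart(object), "\n")
})

setMethod("show", "MCFit", function(object) {
  d <- object@diagnostics
  cat("MCFit: K =", object@spec@K, object@spec@likelihood,
      "likelihood,", nDraws(object), "draws (",
      object@spec@chains, "chains )\n")
  if (!is.null(d$maxRhat))
    cat(sprintf("  max split-Rhat of counterfactual means: %.3f (%s)\n",
                d$maxRhat, if (isTRUE(d$converged)) "converged"
                else "NOT converged"))
})

setMethod("show", "CounterfactualDraws", function(object) {
  cat("CounterfactualDraws:", nrow(object@Y0), "draws x",
      ncol(object@Y0), "treated cells (storm", object@stormId, ")\n")
})

setMethod("show", "EffectPosterior", function(object) {
  cat("EffectPosterior: storm", object@stormId, "-",
      length(object@countyIds), "treated counties,",
      nrow(object@theta), "draws\n")
})

setMethod("show", "ModularFit", function(object) {
  cat("ModularFit (", object@mode, "): ", nrow(object@beta), " draws x ",
      ncol(object@beta), " coefficients\n", sep = "")
})

setMethod("show", "RiskPrediction", function(object) {
  cat("RiskPrediction:", ncol(object@draws), "exposures,",
      nrow(object@draws), "draws each\n")
  print(utils::head(object@summary))
})

## ---- accessors ----------------------------------------------------------

#' @rdname StormPanel-class
#' @export
setMethod("panelCounts", "StormPanel", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @rdname StormPanel-class
#' @export
setMethod("treatmentMask", "StormPanel", function(x)
  SummarizedExperiment::assay(x, "mask"))

#' @rdname StormPanel-class
#' @export
setMethod("panelOffsets", "StormPanel", function(x)
  SummarizedExperiment::assay(x, "offset"))

#' @rdname StormPanel-class
#' @export
setMethod("treatedIds", "StormPanel", function(x)
  rownames(x)[rowSums(treatmentMask(x)) > 0])

#' @rdname StormPanel-class
#' @export
setMethod("controlIds", "StormPanel", function(x)
  rownames(x)[rowSums(treatmentMask(x)) == 0])

#' @rdname StormPanel-class
#' @export
setMethod("treatmentStart", "StormPanel", function(x)
  S4Vectors::metadata(x)$T0)

#' @rdname StormPanel-class
#' @export
setMethod("stormId", "StormPanel", function(x)
  S4Vectors::metadata(x)$stormId)

#' @rdname AnalyticSet-class
#' @param x an `AnalyticSet`.
#' @export
setMethod("exclusionLog", "AnalyticSet", function(x) x@exclusions)

#' @rdname AnalyticSet-class
#' @export
setMethod("treatedIds", "AnalyticSet", function(x) x@treated)

#' @rdname AnalyticSet-class
#' @export
setMethod("controlIds", "AnalyticSet", function(x) x@control)

#' @rdname AnalyticSet-class
#' @export
setMethod("stormId", "AnalyticSet", function(x) x@stormId)

#' @rdname MCFit-class
#' @export
setMethod("nDraws", "MCFit", function(x) length(x@alpha))

#' @rdname MCFit-class
#' @export
setMethod("mcDiagnostics", "MCFit", function(x) x@diagnostics)

#' @rdname CounterfactualDraws-class
#' @export
setMethod("counterfactualCells", "CounterfactualDraws", function(x) x@cells)

#' @rdname CounterfactualDraws-class
#' @export
setMethod("counterfactualMatrix", "CounterfactualDraws", function(x) x@Y0)

#' @rdname CounterfactualDraws-class
#' @export
setMethod("nDraws", "CounterfactualDraws", function(x) nrow(x@Y0))

#' @rdname CounterfactualDraws-class
#' @export
setMethod("stormId", "CounterfactualDraws", function(x) x@stormId)

#' @rdname EffectPosterior-class
#' @export
setMethod("ieeDraws", "EffectPosterior", function(x) x@theta)

#' @rdname EffectPosterior-class
#' @export
setMethod("excessRateDraws", "EffectPosterior", function(x) x@thetaStar)

#' @rdname EffectPosterior-class
#' @export
setMethod("nDraws", "EffectPosterior", function(x) nrow(x@theta))

#' @rdname EffectPosterior-class
#' @export
setMethod("stormId", "EffectPosterior", function(x) x@stormId)

#' @rdname EffectPosterior-class
#' @export
setMethod("treatedIds", "EffectPosterior", function(x) x@countyIds)

#' @rdname ModularFit-class
#' @export
setMethod("nDraws", "ModularFit", function(x) nrow(x@beta))
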