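## Modularized predictive stage: a Bayesian linear model relating
## county-level excess rates to storm and community features, fit once per
## causal posterior draw (cut posterior: information flows only from the
## causal stage into this one), plus prediction for new exposures and a
## cross-validated model menu.

#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline basis in the standard truncated-power
#' form: the function is linear beyond the boundary knots.  With k knots
#' \eqn{t_1 < \dots < t_k}, the basis has k - 1 columns: x itself and, for
#' \eqn{j = 1, \dots, k-2},
#' \deqn{\frac{(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1}) +
#'   (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})}{(t_k-t_1)^2}.}
#'
#' @param x numeric vector.
#' @param knots numeric vector of at least 3 distinct knot locations.
#' @return matrix with `length(knots) - 1` columns.
#' @seealso [rcsKnots()]
#' @export
rcsBasis <- function(x, knots) {
  knots <- sort(unique(knots))
  k <- length(knots)
  if (k < 3L) stop("restricted cubic splines need at least 3 distinct knots")
  pos3 <- function(u) pmax(u, 0)^3
  norm <- (knots[k] - knots[1])^2
  B <- matrix(0, length(x), k - 1L)
  B[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    B[, j + 1L] <- (pos3(x - knots[j]) -
      pos3(x - knots[k - 1L]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1L]) +
      pos3(x - knots[k]) * (knots[k - 1L] - knots[j]) / (knots[k] - knots[k - 1L])) / norm
  }
  colnames(B) <- c("lin", paste0("nl", seq_len(k - 2L)))
  B
}

#' Default knot rule for restricted cubic splines
#'
#' Knots at the 5th, 35th, 65th and 95th percentiles of the training
#' values (evenly spread quantiles for other knot counts).
#'
#' @param x numeric training values.
#' @param nKnots number of knots (default 4).
#' @return numeric vector of knots.
#' @export
rcsKnots <- function(x, nKnots = 4L) {
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct values to place spline knots")
  probs <- if (nKnots == 4L) c(0.05, 0.35, 0.65, 0.95)
  else seq(0.05, 0.95, length.out = nKnots)
  kn <- unique(stats::quantile(x, probs, names = FALSE, type = 7))
  if (length(kn) < 3L)
    stop("knot rule produced fewer than 3 distinct knots")
  kn
}

#' Create a predictive-model specification
#'
#' @param linear character vector of features entering linearly.
#' @param spline character vector of features entering through a
#'   restricted cubic spline (default rule: 4 knots at windspeed/year
#'   quantiles, see [rcsKnots()]).
#' @param nKnots knots per spline (default 4).
#' @param priorCoefScale prior SD multiplier on standardized coefficients
#'   (default 10).
#' @param priorSigmaA,priorSigmaB inverse-gamma shape/rate on the residual
#'   variance (default 0.01/0.01, vague).
#' @param standardize center/scale design columns by training statistics
#'   (default TRUE).
#' @return a [PredictiveModelSpec].
#' @export
predictiveModelSpec <- function(linear = character(), spline = character(),
                                nKnots = 4, priorCoefScale = 10,
                                priorSigmaA = 0.01, priorSigmaB = 0.01,
                                standardize = TRUE) {
  methods::new("PredictiveModelSpec",
    linearVars = as.character(linear), splineVars = as.character(spline),
    nKnots = as.integer(nKnots), priorCoefScale = priorCoefScale,
    priorSigmaA = priorSigmaA, priorSigmaB = priorSigmaB,
    standardize = standardize)
}

## Assemble the design matrix.  With schema = NULL the schema (knots,
## centers, scales, term names) is learned from X; otherwise it is reused
## so prediction evaluates the training basis.
buildDesign <- function(X, spec, schema = NULL) {
  X <- as.data.frame(X)
  need <- c(spec@linearVars, spec@splineVars)
  miss <- setdiff(need, names(X))
  if (length(miss))
    stop("features missing from the table: ", paste(miss, collapse = ", "))
  if (any(vapply(X[need], function(v) any(!is.finite(v)), logical(1))))
    stop("features must be complete (no missing values) after assembly")
  learn <- is.null(schema)
  if (learn)
    schema <- list(linearVars = spec@linearVars,
                   splineVars = spec@splineVars, knots = list())
  blocks <- list(`(Intercept)` = matrix(1, nrow(X), 1))
  for (v in spec@linearVars)
    blocks[[v]] <- matrix(X[[v]], ncol = 1, dimnames = list(NULL, v))
  for (v in spec@splineVars) {
    if (learn) schema$knots[[v]] <- rcsKnots(X[[v]], spec@nKnots)
    B <- rcsBasis(X[[v]], schema$knots[[v]])
    colnames(B) <- paste0("rcs(", v, ")", colnames(B))
    blocks[[v]] <- B
  }
  Z <- do.call(cbind, blocks)
  colnames(Z)[1] <- "(Intercept)"
  if (learn) {
    if (spec@standardize && nrow(Z) > 1L) {
      ctr <- colMeans(Z); ctr[1] <- 0
      scl <- apply(Z, 2, stats::sd); scl[1] <- 1
      scl[scl == 0 | !is.finite(scl)] <- 1
    } else {
      ctr <- rep(0, ncol(Z)); scl <- rep(1, ncol(Z))
    }
    schema$center <- structure(ctr, names = colnames(Z))
    schema$scale <- structure(scl, names = colnames(Z))
    schema$terms <- colnames(Z)
  }
  Z <- sweep(sweep(Z, 2, schema$center[colnames(Z)], "-"), 2,
             schema$scale[colnames(Z)], "/")
  if (learn && qr(Z)$rank < ncol(Z))
    stop("design matrix is rank deficient on the training exposures")
  list(Z = Z, schema = schema)
}

## Exact normal-inverse-gamma posterior of the linear-Gaussian model:
## beta | sigma2 ~ N(0, g^2 sigma2 I) on standardized columns,
## sigma2 ~ IG(a0, b0).  Returns what is needed to sample.
nigPosterior <- function(Z, spec) {
  p <- ncol(Z)
  L0 <- diag(1 / spec@priorCoefScale^2, p)
  Ln <- crossprod(Z) + L0
  ch <- chol(Ln)
  list(Ln = Ln, chol = ch, p = p,
       a0 = spec@priorSigmaA, b0 = spec@priorSigmaB)
}

## one exact draw of (beta, sigma) given response y
nigDraw <- function(post, Zty, yty, n) {
  mn <- backsolve(post$chol, forwardsolve(t(post$chol), Zty))
  an <- post$a0 + n / 2
  bn <- post$b0 + max(0, yty - sum(mn * (post$Ln %*% mn))) / 2
  sigma2 <- 1 / stats::rgamma(1, shape = an, rate = bn)
  beta <- mn + backsolve(post$chol, stats::rnorm(post$p)) * sqrt(sigma2)
  list(beta = as.vector(beta), sigma = sqrt(sigma2), mean = as.vector(mn))
}

#' Fit the modularized predictive model
#'
#' For each causal posterior draw m, conditions the Bayesian linear model
#' \eqn{\theta^{*(m)} = Z\beta + \epsilon} on the m-th draw of all excess
#' rates and retains exactly one exact posterior sample of
#' \eqn{(\beta, \sigma)} (normal--inverse-gamma conjugate update).  The
#' causal draws are read-only: nothing flows back into the causal stage.
#'
#' @param thetaStarDraws M x n matrix of excess-rate draws; columns must
#'   align with the rows of `X` (see [thetaStarMatrix()]).
#' @param X feature `data.frame`, one row per county-level exposure.
#' @param spec a [PredictiveModelSpec].
#' @param seed integer RNG seed.
#' @return a [ModularFit] with `mode = "modular"`.
#' @export
fitModular <- function(thetaStarDraws, X, spec, seed = 1) {
  thetaStarDraws <- as.matrix(thetaStarDraws)
  if (ncol(thetaStarDraws) != nrow(as.data.frame(X)))
    stop("columns of thetaStarDraws must align with rows of X")
  des <- buildDesign(X, spec)
  post <- nigPosterior(des$Z, spec)
  M <- nrow(thetaStarDraws)
  n <- ncol(thetaStarDraws)
  beta <- matrix(0, M, post$p, dimnames = list(NULL, colnames(des$Z)))
  sigma <- numeric(M)
  set.seed(as.integer(seed) %% 2147483647L)
  for (m in seq_len(M)) {
    y <- thetaStarDraws[m, ]
    dr <- nigDraw(post, crossprod(des$Z, y), sum(y * y), n)
    beta[m, ] <- dr$beta
    sigma[m] <- dr$sigma
  }
  methods::new("ModularFit", beta = beta, sigma = sigma,
               schema = des$schema, spec = spec, mode = "modular")
}

#' Fit the plug-in predictive model
#'
#' The uncertainty-propagation comparator: the same Bayesian linear model
#' conditioned once on the posterior-mean excess rates, with M draws taken
#' from that single posterior.  First-stage uncertainty is ignored.
#'
#' @param thetaStarMeans numeric vector of posterior-mean excess rates.
#' @param X feature `data.frame` aligned to `thetaStarMeans`.
#' @param spec a [PredictiveModelSpec].
#' @param M number of posterior draws to retain.
#' @param seed integer RNG seed.
#' @return a [ModularFit] with `mode = "plugin"`.
#' @export
fitPlugin <- function(thetaStarMeans, X, spec, M = 2000, seed = 1) {
  y <- as.numeric(thetaStarMeans)
  if (length(y) != nrow(as.data.frame(X)))
    stop("thetaStarMeans must align with rows of X")
  des <- buildDesign(X, spec)
  post <- nigPosterior(des$Z, spec)
  Zty <- crossprod(des$Z, y); yty <- sum(y * y)
  beta <- matrix(0, M, post$p, dimnames = list(NULL, colnames(des$Z)))
  sigma <- numeric(M)
  set.seed(as.integer(seed) %% 2147483647L)
  for (m in seq_len(M)) {
    dr <- nigDraw(post, Zty, yty, length(y))
    beta[m, ] <- dr$beta
    sigma[m] <- dr$sigma
  }
  methods::new("ModularFit", beta = beta, sigma = sigma,
               schema = des$schema, spec = spec, mode = "plugin")
}

## standardized-space draws -> original-scale coefficients (exact for the
## linear map implied by column centering/scaling)
originalScaleBeta <- function(fit) {
  b <- fit@beta
  s <- fit@schema$scale[colnames(b)]
  ctr <- fit@schema$center[colnames(b)]
  bo <- sweep(b, 2, s, "/")
  bo[, 1] <- b[, 1] - as.vector(bo[, -1, drop = FALSE] %*%
                                ctr[-1])
  bo
}

#' @rdname ModularFit-class
#' @export
setMethod("coefDraws", "ModularFit", function(x, scale = c("original",
                                                           "standardized")) {
  scale <- match.arg(scale)
  if (scale == "standardized") x@beta else originalScaleBeta(x)
})

#' @rdname ModularFit-class
#' @export
setMethod("coefSummary", "ModularFit", function(x, scale = "original") {
  b <- coefDraws(x, scale = scale)
  q <- apply(b, 2, stats::quantile, c(0.025, 0.975), names = FALSE)
  data.frame(term = colnames(b), mean = colMeans(b),
             lower = q[1, ], upper = q[2, ], row.names = NULL)
})

#' Predict excess rates for new exposures
#'
#' One posterior-predictive draw of \eqn{\theta^*_{new}} per retained
#' coefficient draw: the linear predictor under draw m's \eqn{\beta} plus
#' a residual draw with that draw's \eqn{\sigma}.  Spline bases are
#' evaluated at the training knots; design columns use the training
#' centers and scales.
#'
#' @param fit a [ModularFit].
#' @param newdata feature `data.frame` conforming to the training schema.
#' @param seed integer RNG seed for the residual draws.
#' @param residual set `FALSE` to omit residual noise (mean prediction).
#' @return a [RiskPrediction].
#' @export
predictNew <- function(fit, newdata, seed = 1, residual = TRUE) {
  stopifnot(methods::is(fit, "ModularFit"))
  des <- buildDesign(newdata, fit@spec, schema = fit@schema)
  eta <- fit@beta %*% t(des$Z)              # M x n
  if (residual) {
    set.seed(as.integer(seed) %% 2147483647L)
    eta <- eta + matrix(stats::rnorm(length(eta), 0, fit@sigma),
                        nrow(eta), ncol(eta))
  }
  sm <- apply(eta, 2, function(d) {
    q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
    c(mean(d), q)
  })
  methods::new("RiskPrediction", draws = eta,
               summary = data.frame(mean = sm[1, ], lower = sm[2, ],
                                    upper = sm[3, ]),
               newdata = as.data.frame(newdata))
}

#' Rank candidate predictive models by cross-validation
#'
#' K-fold cross-validation of each candidate specification against the
#' posterior-mean excess rates: each fold is predicted from the posterior
#' mean coefficients fitted on the remaining folds (schema re-learned per
#' fold).  Fold assignment is deterministic given `seed`; identical
#' candidates tie exactly.
#'
#' @param candidates list of [PredictiveModelSpec].
#' @param thetaStarMeans numeric response vector.
#' @param X feature `data.frame`.
#' @param folds number of folds (default 5; use `length(thetaStarMeans)`
#'   for leave-one-out).
#' @param seed integer seed for the fold shuffle.
#' @return `data.frame` ranked by mean held-out squared error, with
#'   fold-wise SDs.
#' @export
crossvalidateModelMenu <- function(candidates, thetaStarMeans, X,
                                   folds = 5, seed = 1) {
  if (length(candidates) < 2L)
    stop("need at least 2 candidate models")
  y <- as.numeric(thetaStarMeans)
  n <- length(y)
  if (folds > n) stop("more folds than observations")
  if (folds < 2L) stop("need at least 2 folds")
  set.seed(as.integer(seed) %% 2147483647L)
  foldId <- sample(rep(seq_len(folds), length.out = n))
  res <- lapply(seq_along(candidates), function(ci) {
    spec <- candidates[[ci]]
    mse <- vapply(seq_len(folds), function(f) {
      tr <- foldId != f
      des <- buildDesign(as.data.frame(X)[tr, , drop = FALSE], spec)
      post <- nigPosterior(des$Z, spec)
      mn <- backsolve(post$chol,
                      forwardsolve(t(post$chol), crossprod(des$Z, y[tr])))
      te <- buildDesign(as.data.frame(X)[!tr, , drop = FALSE], spec,
                        schema = des$schema)
      mean((y[!tr] - as.vector(te$Z %*% mn))^2)
    }, numeric(1))
    data.frame(candidate = ci, meanMSE = mean(mse), sdMSE = stats::sd(mse))
  })
  out <- do.call(rbind, res)
  out[order(out$meanMSE), , drop = FALSE]
}
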