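## Bayesian matrix completion for count panels: a negative-binomial
## latent-factor model with a log link,
##   log E[Y_it(0)] = alpha + gamma_i + psi_t + U_i . V_t + log p_it,
## fit by MCMC with treated (masked) cells excluded from the likelihood,
## and posterior-predictive imputation of their counterfactual counts.

#' Create a matrix-completion model specification
#'
#' @param K number of latent factors (default 4; `K = 0` gives a plain
#'   two-way county + interval model).
#' @param likelihood `"negbin"` (default) or `"poisson"`.
#' @param chains number of MCMC chains (default 2).
#' @param drawsPerChain post-warmup draws per chain (default 1000).
#' @param warmup burn-in iterations per chain (default 500).
#' @param adapt adaptation iterations (default 300).
#' @param priorScales named numeric overriding the default weakly
#'   informative prior SDs: `intercept`, `county`, `interval` (normal, SD
#'   5), `factor` (normal, SD 1) and `dispersion` (half-normal scale 5 on
#'   the inverse-root dispersion, so the Poisson is the small-scale limit).
#' @param seed integer sampler seed.
#' @return an [MCModelSpec].
#' @export
mcModelSpec <- function(K = 4, likelihood = c("negbin", "poisson"),
                        chains = 2, drawsPerChain = 1000, warmup = 500,
                        adapt = 300, priorScales = NULL, seed = 1) {
  likelihood <- match.arg(likelihood)
  ps <- c(intercept = 5, county = 5, interval = 5, factor = 1, dispersion = 5)
  if (!is.null(priorScales)) {
    bad <- setdiff(names(priorScales), names(ps))
    if (length(bad)) stop("unknown priorScales: ", paste(bad, collapse = ", "))
    ps[names(priorScales)] <- priorScales
  }
  methods::new("MCModelSpec",
    K = as.integer(K), likelihood = likelihood, priorScales = ps,
    chains = as.integer(chains), drawsPerChain = as.integer(drawsPerChain),
    warmup = as.integer(warmup), adapt = as.integer(adapt),
    seed = as.integer(seed))
}

## JAGS model source.  The negative binomial (mean mu, dispersion phi,
## Var = mu + mu^2/phi) is coded as its exact Poisson-gamma mixture.
mcModelString <- function(K, likelihood, ps) {
  prec <- function(s) sprintf("%.10g", 1 / s^2)
  lik <- if (likelihood == "negbin") "
    y[c] ~ dpois(lam[c])
    lam[c] ~ dgamma(phi, phi / mu[c])" else "
    y[c] ~ dpois(mu[c])"
  fac <- if (K > 0) " + inprod(U[ci[c],], V[ti[c],])" else ""
  facPriors <- if (K > 0) sprintf("
  for (i in 1:N) { for (k in 1:K) { U[i,k] ~ dnorm(0, %s) } }
  for (t in 1:T) { for (k in 1:K) { V[t,k] ~ dnorm(0, %s) } }",
    prec(ps["factor"]), prec(ps["factor"])) else ""
  dispPrior <- if (likelihood == "negbin") sprintf("
  sphi ~ dnorm(0, %s) T(1e-6,)
  phi <- 1 / (sphi * sphi)", prec(ps["dispersion"])) else ""
  sprintf("model {
  for (c in 1:C) {%s
    log(mu[c]) <- alpha + gam[ci[c]] + psi[ti[c]]%s + lo[c]
  }
  alpha ~ dnorm(0, %s)
  for (i in 1:N) { gam[i] ~ dnorm(0, %s) }
  for (t in 1:T) { psi[t] ~ dnorm(0, %s) }%s%s
}", lik, fac, prec(ps["intercept"]), prec(ps["county"]),
    prec(ps["interval"]), facPriors, dispPrior)
}

## flatten an rjags mcarray (dims [... , iter, chain]) to draws-first
flattenDraws <- function(arr) {
  d <- dim(arr)
  nd <- length(d)
  iter <- d[nd - 1L]; ch <- d[nd]
  par <- if (nd > 2L) prod(d[seq_len(nd - 2L)]) else 1L
  m <- matrix(aperm(array(arr, c(par, iter, ch)), c(2, 3, 1)),
              nrow = iter * ch, ncol = par)
  m
}

## split-Rhat of a draws vector given chain labels
splitRhat <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- n * stats::var(means)
  Wn <- mean(vars)
  if (Wn == 0) return(1)
  sqrt(((n - 1) / n * Wn + B / n) / Wn)
}

#' Fit the count matrix-completion model
#'
#' Fits the Bayesian latent-factor model
#' \deqn{\log E[Y_{it}(0)] = \alpha + \gamma_i + \psi_t + U_i^T V_t +
#'   \log p_{it}}
#' by MCMC with a negative binomial (or Poisson) likelihood.  Only
#' unmasked cells enter the likelihood: the observed outcomes of treated
#' cells are treated as fixed and known and are omitted, so they cannot
#' influence the counterfactual model.  The raw factors are left
#' unidentified (the model is used as a black box for prediction);
#' convergence is gated on the split-Rhat of the masked cells' predicted
#' means.
#'
#' @param panel a [StormPanel].
#' @param spec an [MCModelSpec]; see [mcModelSpec()].
#' @return an [MCFit].
#' @examples
#' \donttest{
#' sim <- simulatePanel(simConfig(S = 1, N = 25, seed = 7), storm = 1)
#' fit <- fitMCModel(sim$panel, mcModelSpec(K = 2, drawsPerChain = 200,
#'                                          seed = 7))
#' fit
#' }
#' @export
fitMCModel <- function(panel, spec = mcModelSpec()) {
  stopifnot(methods::is(panel, "StormPanel"), methods::is(spec, "MCModelSpec"))
  Y <- panelCounts(panel)
  D <- treatmentMask(panel)
  p <- panelOffsets(panel)
  N <- nrow(Y); T <- ncol(Y); K <- spec@K
  if (K >= min(N, T))
    warning("K should be well below min(N, T) for a low-rank model")
  obs <- which(D == 0)
  if (!length(obs)) stop("panel has no unmasked cells")
  zr <- rowSums(Y * (D == 0)) == 0
  if (any(zr))
    message(sum(zr), " county row(s) are all zero over unmasked cells; ",
            "the NB likelihood handles these, proceeding")
  dat <- list(y = as.integer(Y[obs]), ci = row(Y)[obs], ti = col(Y)[obs],
              lo = log(p[obs]), C = length(obs), N = N, T = T)
  if (K > 0) dat$K <- K
  inits <- lapply(seq_len(spec@chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((as.numeric(spec@seed) * 1009 + ch) %%
                                2147483629)))
  model <- rjags::jags.model(
    textConnection(mcModelString(K, spec@likelihood, spec@priorScales)),
    data = dat, inits = inits, n.chains = spec@chains,
    n.adapt = spec@adapt, quiet = TRUE)
  if (spec@warmup > 0) update(model, spec@warmup, progress.bar = "none")
  vars <- c("alpha", "gam", "psi", if (K > 0) c("U", "V"),
            if (spec@likelihood == "negbin") "phi")
  sm <- rjags::jags.samples(model, vars, n.iter = spec@drawsPerChain,
                            progress.bar = "none")
  M <- spec@drawsPerChain * spec@chains
  fit <- methods::new("MCFit",
    panel = panel, spec = spec,
    alpha = as.vector(flattenDraws(sm$alpha)),
    gamma = flattenDraws(sm$gam),
    psi = flattenDraws(sm$psi),
    U = if (K > 0) array(flattenDraws(sm$U), c(M, N, K)) else array(0, c(M, N, 0)),
    V = if (K > 0) array(flattenDraws(sm$V), c(M, T, K)) else array(0, c(M, T, 0)),
    phi = if (spec@likelihood == "negbin") as.vector(flattenDraws(sm$phi)) else numeric(),
    chain = rep(seq_len(spec@chains), each = spec@drawsPerChain),
    diagnostics = list())
  fit@diagnostics <- mcConvergence(fit)
  if (!isTRUE(fit@diagnostics$converged))
    warning("split-Rhat of counterfactual predictive means exceeds 1.05 (max ",
            sprintf("%.3f", fit@diagnostics$maxRhat),
            "); consider more warmup/draws", call. = FALSE)
  fit
}

## split-Rhat over the masked cells' predicted means
mcConvergence <- function(fit) {
  D <- treatmentMask(fit@panel)
  cells <- which(D == 1)
  if (!length(cells))
    return(list(rhat = numeric(), maxRhat = NA_real_, converged = TRUE))
  rhat <- vapply(cells, function(cl) {
    lp <- linearPredictor(fit, row(D)[cl], col(D)[cl])
    splitRhat(exp(lp), fit@chain)
  }, numeric(1))
  list(rhat = rhat, maxRhat = max(rhat),
       converged = max(rhat) < 1.05)
}

#' Per-draw linear predictor of a fitted cell
#'
#' Reconstructs, for every retained posterior draw, the log mean
#' \eqn{\alpha + \gamma_i + \psi_t + U_i^T V_t + \log p_{it}} of cell
#' (i, t).  This is exact: the stored draws fully determine the
#' predictor.
#'
#' @param fit an [MCFit].
#' @param i county row index.
#' @param t interval column index.
#' @param offset optional positive offset overriding the panel's
#'   \eqn{p_{it}}.
#' @return numeric vector of M log-mean draws.
#' @export
linearPredictor <- function(fit, i, t, offset = NULL) {
  stopifnot(methods::is(fit, "MCFit"))
  N <- nrow(fit@panel); T <- ncol(fit@panel)
  if (i < 1 || i > N || t < 1 || t > T) stop("cell index out of range")
  p <- if (is.null(offset)) panelOffsets(fit@panel)[i, t] else offset
  if (!is.finite(p) || p <= 0) stop("offset must be positive")
  lp <- fit@alpha + fit@gamma[, i] + fit@psi[, t] + log(p)
  K <- dim(fit@U)[3]
  if (K > 0)
    lp <- lp + rowSums(fit@U[, i, , drop = FALSE] *
                       fit@V[, t, , drop = FALSE], dims = 1)
  as.vector(lp)
}

#' Draw posterior-predictive counterfactual counts for masked cells
#'
#' For each masked (treated) cell and each posterior draw m, samples one
#' counterfactual count from the negative binomial with that draw's mean
#' \eqn{\exp(\alpha + \gamma_i + \psi_t + U_i^T V_t + \log p_{it})} and
#' dispersion (Poisson under the Poisson likelihood).  Reproducible given
#' `seed`.
#'
#' @param fit an [MCFit].
#' @param seed integer RNG seed for the predictive draws.
#' @return a [CounterfactualDraws].
#' @export
imputeCounterfactuals <- function(fit, seed = fit@spec@seed) {
  stopifnot(methods::is(fit, "MCFit"))
  D <- treatmentMask(fit@panel)
  cells <- which(D == 1)
  M <- nDraws(fit)
  cellsDf <- data.frame(
    county_id = rownames(fit@panel)[row(D)[cells]],
    row = row(D)[cells], interval = col(D)[cells],
    stringsAsFactors = FALSE)
  ord <- order(cellsDf$row, cellsDf$interval)
  cellsDf <- cellsDf[ord, , drop = FALSE]
  rownames(cellsDf) <- NULL
  Y0 <- matrix(0L, M, nrow(cellsDf))
  set.seed(as.integer(seed) %% 2147483647L)
  for (j in seq_len(nrow(cellsDf))) {
    mu <- exp(linearPredictor(fit, cellsDf$row[j], cellsDf$interval[j]))
    Y0[, j] <- if (length(fit@phi))
      stats::rnbinom(M, size = fit@phi, mu = mu)
    else stats::rpois(M, mu)
  }
  methods::new("CounterfactualDraws", Y0 = Y0, cells = cellsDf,
               stormId = stormId(fit@panel))
}

#' Advisory choice of the latent dimension by exploratory PCA
#'
#' Runs a principal component analysis of each panel's log-rate matrix
#' (counts + 0.5 over offsets, column-centered) and reports the smallest K
#' whose mean cumulative variance explained across panels reaches the
#' target.  Advisory only: the user sets K in [mcModelSpec()].
#'
#' @param panels a [StormPanel] or list of them.
#' @param varianceTarget fraction of variance to explain, in (0, 1)
#'   (default 0.7).
#' @return list with elements `K` and `table` (per-component mean variance
#'   explained, cumulative).
#' @export
chooseKByPCA <- function(panels, varianceTarget = 0.7) {
  if (methods::is(panels, "StormPanel")) panels <- list(panels)
  stopifnot(length(panels) >= 1L,
            varianceTarget > 0, varianceTarget < 1)
  props <- lapply(panels, function(pn) {
    X <- log((panelCounts(pn) + 0.5) / panelOffsets(pn))
    X <- scale(X, center = TRUE, scale = FALSE)
    if (all(abs(X) < 1e-12))
      stop("degenerate (constant) panel matrix; PCA undefined")
    d2 <- svd(X, nu = 0, nv = 0)$d^2
    prop <- d2 / sum(d2)
    length(prop) <- ncol(X)           # pad with NA -> treat as 0
    prop[is.na(prop)] <- 0
    prop
  })
  meanProp <- Reduce(`+`, props) / length(props)
  cum <- cumsum(meanProp)
  K <- which(cum >= varianceTarget)[1]
  list(K = as.integer(K),
       table = data.frame(component = seq_along(meanProp),
                          varExplained = meanProp, cumulative = cum))
}
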