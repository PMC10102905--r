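## Synthetic multi-storm panel generator.  Baselines are exact draws from
## the matrix-completion model class (low-rank log-linear NB with
## population offsets); treatment effects are injected additively on the
## count scale with rate-scale targeting, so every causal and predictive
## quantity has a known ground truth.

#' Configuration of the synthetic study generator
#'
#' Defaults describe a plausible Medicare-scale outcome: a baseline of 100
#' events per 100 000 per two-week interval in counties of ~50 000
#' enrollees (mean interval counts near 50), moderate NB overdispersion
#' (\eqn{\phi = 25}), a rank-2 space-time baseline of modest amplitude,
#' and treated windspeeds from a shifted gamma at or above gale force.
#' Default effects act through windspeed on the excess-rate scale:
#' \eqn{E[\theta^*] = \beta_0 + \beta_w \times} windspeed with
#' \eqn{\beta_w = 2} per 100 000 per m/s and \eqn{\beta_0 = -14.8}, i.e.
#' 20 per 100 000 at the 17.4 m/s threshold.
#'
#' @param S number of storms.
#' @param N counties per storm.
#' @param nTreated treated counties per storm.
#' @param T intervals (10 mirrors the two-week design).
#' @param KTrue rank of the true baseline factor structure.
#' @param factorScale SD of the latent factor entries.
#' @param countySd,intervalSd SDs of the county and interval effects.
#' @param baselineRate baseline events per 100 000 per interval.
#' @param dispersion NB dispersion \eqn{\phi} (Var = \eqn{\mu + \mu^2/\phi});
#'   `Inf` gives Poisson counts.
#' @param betaTrue named effects on the excess-rate scale; must include
#'   `intercept`, other names refer to feature columns.
#' @param effectNoiseSd SD of the centered count-scale noise added to each
#'   cell's injected effect.
#' @param windShape,windScale gamma parameters of the treated windspeed
#'   excess above 17.4 m/s.
#' @param popMeanLog,popSdLog log-normal population parameters.
#' @param seed master seed; per-storm seeds are expanded from it
#'   deterministically.
#' @return a `SimConfig` (list with class).
#' @export
simConfig <- function(S = 3, N = 30, nTreated = 10, T = 10, KTrue = 2,
                      factorScale = 0.3, countySd = 0.3, intervalSd = 0.2,
                      baselineRate = 100, dispersion = 25,
                      betaTrue = c(intercept = -14.8, windspeed = 2),
                      effectNoiseSd = 5,
                      windShape = 2, windScale = 6,
                      popMeanLog = log(5e4), popSdLog = 0.5, seed = 1) {
  if (!"intercept" %in% names(betaTrue))
    stop("betaTrue must name an intercept")
  cfg <- list(S = as.integer(S), N = as.integer(N),
              nTreated = as.integer(nTreated), T = as.integer(T),
              KTrue = as.integer(KTrue), factorScale = factorScale,
              countySd = countySd, intervalSd = intervalSd,
              baselineRate = baselineRate, dispersion = dispersion,
              betaTrue = betaTrue, effectNoiseSd = effectNoiseSd,
              windShape = windShape, windScale = windScale,
              popMeanLog = popMeanLog, popSdLog = popSdLog,
              seed = as.integer(seed))
  stopifnot(cfg$S >= 1, cfg$N >= 2, cfg$nTreated >= 1, cfg$nTreated < cfg$N,
            cfg$T >= 2, cfg$KTrue >= 0, cfg$baselineRate > 0,
            cfg$dispersion > 0)
  class(cfg) <- "SimConfig"
  cfg
}

#' Deterministic seed expansion
#'
#' Expands one master seed into independent per-storm, per-stage sampler
#' seeds (kept below 2^31), so parallel per-storm fits are individually
#' reproducible.
#'
#' @param seed master integer seed.
#' @param storm storm index.
#' @param stage integer stage code (0 data, 1 causal fit, 2 imputation,
#'   3 predictive).
#' @return integer seed.
#' @export
expandSeed <- function(seed, storm, stage = 0L) {
  (((as.integer(seed) %% 100000L) * 10007L + storm * 101L + stage * 13L)
   %% 2147483629L) + 1L
}

rnbinomSafe <- function(n, size, mu) {
  if (is.infinite(size)) stats::rpois(n, mu) else
    stats::rnbinom(n, size = size, mu = mu)
}

#' Simulate one storm panel with known truth
#'
#' Draws county populations, a rank-`KTrue` log-linear baseline with NB
#' noise and population offsets (an exact draw from the model class the
#' causal stage fits), then injects treatment effects into the final
#' interval of the treated counties: the injected count is
#' round(expected excess rate x p / 100 000 + centered noise), clamped so
#' \eqn{Y(1) \ge 0}.  The realized effect \eqn{\theta = Y(1) - Y(0)} is
#' recorded cell-wise as ground truth.
#'
#' @param config a [simConfig()].
#' @param storm storm index (drives the expanded seed).
#' @return list: `panel` ([StormPanel]), `features` (one row per treated
#'   county: storm_id, county_id, windspeed, duration20, year,
#'   exposureCount, poverty), `truth` (list with `y0`, `y1`, `theta`,
#'   `thetaStar`, `populations`, `expectedRate`, `clamped`).
#' @export
simulatePanel <- function(config, storm = 1L) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(expandSeed(config$seed, storm, 0L))
  N <- config$N; T <- config$T; K <- config$KTrue
  ids <- sprintf("S%02dC%03d", storm, seq_len(N))
  treatedIdx <- seq_len(config$nTreated)     # ids are already sorted
  pop <- round(stats::rlnorm(N, config$popMeanLog, config$popSdLog))
  pop <- pmax(pop, 500)
  gamma <- stats::rnorm(N, 0, config$countySd)
  psi <- stats::rnorm(T, 0, config$intervalSd)
  UV <- if (K > 0) {
    U <- matrix(stats::rnorm(N * K, 0, config$factorScale), N, K)
    V <- matrix(stats::rnorm(T * K, 0, config$factorScale), T, K)
    U %*% t(V)
  } else matrix(0, N, T)
  alpha <- log(config$baselineRate / 1e5)
  eta <- alpha + outer(gamma, psi, "+") + UV + log(pop)  # log p_i, constant in t
  mu <- exp(eta)
  if (any(!is.finite(mu)))
    stop("configuration produced non-finite expected counts")
  Y0 <- matrix(rnbinomSafe(N * T, config$dispersion, mu), N, T)

  ## storm/county features
  wind <- numeric(N)
  wind[treatedIdx] <- 17.4 + stats::rgamma(config$nTreated,
                                           shape = config$windShape,
                                           scale = config$windScale)
  wind[-treatedIdx] <- stats::runif(N - config$nTreated, 2, 15)
  year <- sample(1999:2015, 1)
  features <- data.frame(
    storm_id = sprintf("TC%02d", storm),
    county_id = ids[treatedIdx],
    windspeed = wind[treatedIdx],
    duration20 = pmax(0, wind[treatedIdx] - 20) *
      stats::runif(config$nTreated, 1, 3),
    year = year,
    exposureCount = stats::rpois(config$nTreated, 2) + 1L,
    poverty = stats::runif(config$nTreated, 5, 25),
    stringsAsFactors = FALSE)

  ## injected effects, rate-scale targeting
  bt <- config$betaTrue
  vars <- setdiff(names(bt), "intercept")
  bad <- setdiff(vars, names(features))
  if (length(bad))
    stop("betaTrue names unknown features: ", paste(bad, collapse = ", "))
  expectedRate <- rep(bt[["intercept"]], config$nTreated)
  for (v in vars) expectedRate <- expectedRate + bt[[v]] * features[[v]]
  pT <- pop[treatedIdx]
  effect <- round(expectedRate * pT / 1e5 +
                  stats::rnorm(config$nTreated, 0, config$effectNoiseSd))
  y0T <- Y0[treatedIdx, T]
  y1T <- y0T + effect
  clamped <- y1T < 0
  if (any(clamped)) {
    warning(sum(clamped), " treated cell(s) clamped at zero (Y(1) >= 0)",
            call. = FALSE)
    y1T <- pmax(y1T, 0L)
  }
  theta <- y1T - y0T                        # realized effect, exact
  Y <- Y0
  Y[treatedIdx, T] <- y1T
  D <- matrix(0, N, T)
  D[treatedIdx, T] <- 1
  offs <- matrix(pop, N, T)
  dimnames(Y) <- dimnames(D) <- dimnames(offs) <-
    list(ids, paste0("I", seq_len(T)))
  panel <- stormPanel(Y, D, offs, stormId = sprintf("TC%02d", storm), T0 = T)
  list(panel = panel, features = features,
       truth = list(y0 = y0T, y1 = y1T, theta = theta,
                    thetaStar = excessRate(theta, pT),
                    populations = pT, expectedRate = expectedRate,
                    clamped = clamped))
}

#' Simulate a multi-storm study with known truth
#'
#' Applies [simulatePanel()] across `S` storms and aggregates the ground
#' truth: per-exposure effects, the true total excess events (sum of all
#' realized \eqn{\theta}) and the true average excess rate (mean of all
#' realized \eqn{\theta^*}), plus the generating coefficients.
#'
#' @param config a [simConfig()].
#' @return list: `panels` (list of [StormPanel]), `features` (stacked
#'   feature table), `truth` (list with `exposures` data frame, `tee`,
#'   `aer`, `beta`).
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  sims <- lapply(seq_len(config$S), function(s) simulatePanel(config, s))
  features <- do.call(rbind, lapply(sims, `[[`, "features"))
  exposures <- do.call(rbind, lapply(seq_along(sims), function(s) {
    tr <- sims[[s]]$truth
    data.frame(storm_id = sims[[s]]$features$storm_id,
               county_id = sims[[s]]$features$county_id,
               theta = tr$theta, thetaStar = tr$thetaStar,
               y0 = tr$y0, y1 = tr$y1, population = tr$populations,
               stringsAsFactors = FALSE)
  }))
  list(panels = lapply(sims, `[[`, "panel"),
       features = features,
       truth = list(exposures = exposures,
                    tee = sum(exposures$theta),
                    aer = mean(exposures$thetaStar),
                    beta = config$betaTrue))
}
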