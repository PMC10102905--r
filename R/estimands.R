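## Causal estimands built from the counterfactual posterior: individual
## excess events (IEE), excess rates per 100 000, storm-level totals, and
## the study-wide TEE and AER.  Every summary draw is an exact
## deterministic transformation of the theta draws.

#' Posterior draws of the individual excess events
#'
#' For each treated county i, the IEE draw is
#' \eqn{\theta_i^{(m)} = \sum_{t \ge T_0} (Y_{it} - Y_{it}^{(m)}(0))}:
#' observed minus counterfactual, summed over the treatment interval(s)
#' (here the single final interval).  Excess rates
#' \eqn{\theta^{*(m)}_i = 100\,000 \, \theta_i^{(m)} / p_{iT}} are attached.
#'
#' @param cf a [CounterfactualDraws].
#' @param panel the [StormPanel] the draws were imputed for.
#' @return an [EffectPosterior].
#' @export
computeIEE <- function(cf, panel) {
  stopifnot(methods::is(cf, "CounterfactualDraws"),
            methods::is(panel, "StormPanel"))
  cells <- counterfactualCells(cf)
  Y <- panelCounts(panel)
  D <- treatmentMask(panel)
  if (nrow(cells) == 0L) stop("no treated cells")
  if (any(D[cbind(cells$row, cells$interval)] != 1))
    stop("counterfactual cells are misaligned with the panel mask")
  if (any(rownames(panel)[cells$row] != cells$county_id))
    stop("counterfactual cells are misaligned with the panel rows")
  yObs <- Y[cbind(cells$row, cells$interval)]
  diffs <- sweep(-counterfactualMatrix(cf), 2, yObs, "+") # y - Y0, per draw
  counties <- sort(unique(cells$county_id))
  theta <- sapply(counties, function(id) {
    cols <- which(cells$county_id == id)
    if (length(cols) == 1L) diffs[, cols] else rowSums(diffs[, cols])
  })
  theta <- matrix(theta, nrow = nrow(diffs),
                  dimnames = list(NULL, counties))
  T0 <- treatmentStart(panel)
  pT <- panelOffsets(panel)[match(counties, rownames(panel)), ncol(panel)]
  methods::new("EffectPosterior",
    stormId = stormId(panel), countyIds = counties, theta = theta,
    thetaStar = sweep(theta, 2, pT, function(th, p) excessRate(th, p)),
    populations = as.numeric(pT))
}

#' Excess events per 100 000 population
#'
#' @param theta excess-event count(s).
#' @param p positive population denominator.
#' @return \eqn{100\,000 \times \theta / p}.
#' @examples
#' excessRate(5, 100000)  # 5
#' excessRate(2, 50000)   # 4
#' @export
excessRate <- function(theta, p) {
  if (any(!is.finite(p)) || any(p <= 0)) stop("population must be positive")
  1e5 * theta / p
}

postSummary <- function(draws) {
  q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  c(mean = mean(draws), lower = q[1], upper = q[2])
}

#' Storm-level excess events and excess rate
#'
#' The storm's excess-event draw is the sum of the county IEE draws; its
#' excess-rate draw is, by default, the pooled rate
#' \eqn{100\,000 \sum_i \theta_i / \sum_i p_{iT}} across impacted counties
#' (`rate = "mean"` instead averages the county rates).
#'
#' @param effects an [EffectPosterior] for one storm.
#' @param rate `"pooled"` (default) or `"mean"`.
#' @return list with `eventsDraws`, `rateDraws` and a one-row `summary`
#'   data frame (posterior means and central 95% intervals).
#' @export
summarizeStorm <- function(effects, rate = c("pooled", "mean")) {
  rate <- match.arg(rate)
  stopifnot(methods::is(effects, "EffectPosterior"))
  th <- ieeDraws(effects)
  eventsDraws <- rowSums(th)
  rateDraws <- if (rate == "pooled")
    excessRate(eventsDraws, sum(effects@populations))
  else rowMeans(excessRateDraws(effects))
  se <- postSummary(eventsDraws); sr <- postSummary(rateDraws)
  list(eventsDraws = eventsDraws, rateDraws = rateDraws,
       summary = data.frame(
         storm_id = effects@stormId, n_counties = length(effects@countyIds),
         events_mean = se["mean"], events_lower = se["lower"],
         events_upper = se["upper"], rate_mean = sr["mean"],
         rate_lower = sr["lower"], rate_upper = sr["upper"],
         row.names = NULL))
}

#' Study-wide total excess events (TEE) and average excess rate (AER)
#'
#' The TEE draw is the grand sum of all county IEE draws over all storms;
#' the AER draw is the unweighted mean of the excess-rate draws over all
#' county-level exposures (each storm-county pair counts once).  Draw m of
#' every storm is combined with draw m of every other (common M required).
#'
#' @param effectsList list of [EffectPosterior], one per storm.
#' @return list with `teeDraws`, `aerDraws`, a one-row `summary` data
#'   frame, and `countyTable`: per-exposure posterior means and 95%
#'   intervals of \eqn{\theta} and \eqn{\theta^*}.
#' @export
summarizeStudy <- function(effectsList) {
  if (methods::is(effectsList, "EffectPosterior"))
    effectsList <- list(effectsList)
  stopifnot(length(effectsList) >= 1L,
            all(vapply(effectsList, methods::is, logical(1), "EffectPosterior")))
  Ms <- vapply(effectsList, nDraws, integer(1))
  if (length(unique(Ms)) != 1L)
    stop("all storms must carry the same number of draws")
  thetaAll <- do.call(cbind, lapply(effectsList, ieeDraws))
  starAll <- do.call(cbind, lapply(effectsList, excessRateDraws))
  teeDraws <- rowSums(thetaAll)
  aerDraws <- rowMeans(starAll)
  st <- postSummary(teeDraws); sa <- postSummary(aerDraws)
  countyTable <- do.call(rbind, lapply(effectsList, function(ef) {
    thS <- apply(ieeDraws(ef), 2, postSummary)
    rtS <- apply(excessRateDraws(ef), 2, postSummary)
    data.frame(storm_id = ef@stormId, county_id = ef@countyIds,
               theta_mean = thS["mean", ], theta_lower = thS["lower", ],
               theta_upper = thS["upper", ], rate_mean = rtS["mean", ],
               rate_lower = rtS["lower", ], rate_upper = rtS["upper", ],
               row.names = NULL)
  }))
  list(teeDraws = teeDraws, aerDraws = aerDraws,
       summary = data.frame(
         n_storms = length(effectsList), n_exposures = ncol(thetaAll),
         tee_mean = st["mean"], tee_lower = st["lower"],
         tee_upper = st["upper"], aer_mean = sa["mean"],
         aer_lower = sa["lower"], aer_upper = sa["upper"],
         row.names = NULL),
       countyTable = countyTable)
}

#' Align excess-rate draws with a feature table
#'
#' Builds the M x (exposures) matrix of \eqn{\theta^*} draws whose columns
#' follow the rows of a (storm_id, county_id) feature table, ready for
#' [fitModular()].
#'
#' @param effectsList list of [EffectPosterior].
#' @param features `data.frame` with columns `storm_id` and `county_id`.
#' @return numeric matrix, M rows, one column per feature row.
#' @export
thetaStarMatrix <- function(effectsList, features) {
  if (methods::is(effectsList, "EffectPosterior"))
    effectsList <- list(effectsList)
  cols <- do.call(cbind, lapply(effectsList, excessRateDraws))
  key <- unlist(lapply(effectsList, function(ef)
    paste(ef@stormId, ef@countyIds, sep = "\r")))
  want <- paste(features$storm_id, features$county_id, sep = "\r")
  idx <- match(want, key)
  if (anyNA(idx))
    stop("features rows without matching excess-rate draws: ",
         paste(utils::head(want[is.na(idx)]), collapse = ", "))
  cols[, idx, drop = FALSE]
}
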