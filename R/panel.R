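## Panel construction: exposure classification, study period, aggregation,
## analytic-set filtering and assembly of the StormPanel object.

GALE_FORCE_MS <- 17.4
CONTROL_RADIUS_MILES <- 150
EARTH_RADIUS_M <- 6371000          # haversine on county centroids
MILES_PER_KM <- 0.621371

#' Classify county exposure by maximum sustained windspeed
#'
#' A county is treated for a storm when its maximum sustained windspeed at
#' the population mean center reaches gale force, 17.4 m/s, and is a
#' control otherwise.
#'
#' @param windspeed numeric vector of maximum sustained windspeeds (m/s).
#' @return character vector, `"treated"` or `"control"`.
#' @examples
#' classifyExposure(c(0, 17.3999, 17.4, 42))
#' @export
classifyExposure <- function(windspeed) {
  if (!is.numeric(windspeed) || any(!is.finite(windspeed)) ||
      any(windspeed < 0))
    stop("windspeed must be finite and non-negative (m/s)")
  ifelse(windspeed >= GALE_FORCE_MS, "treated", "control")
}

#' Define the ten-interval study period around a storm
#'
#' The study window around a storm's first US approach is split into 10
#' contiguous two-week intervals.  The final (treatment) interval begins 2
#' days before and ends 11 days after first approach; the remaining nine
#' intervals are anchored backwards from it, so the window opens 128 days
#' before the approach and closes 11 days after it.
#'
#' @param firstApproach a `Date` (or string coercible to one): the earliest
#'   date the storm makes its closest approach to an exposed US county.
#' @return a [StudyPeriod].
#' @examples
#' defineStudyPeriod(as.Date("2005-08-29"))
#' @export
defineStudyPeriod <- function(firstApproach) {
  fa <- as.Date(firstApproach)
  if (length(fa) != 1L || is.na(fa))
    stop("firstApproach must be a single valid date")
  finalStart <- fa - 2L
  starts <- finalStart - 14L * (9L:0L)
  methods::new("StudyPeriod",
    firstApproach = fa,
    intervalStart = starts,
    intervalEnd = starts + 13L,
    treatmentIndex = 10L)
}

#' Aggregate a daily count series to two-week interval totals
#'
#' Sums daily event counts within each interval of a study period.  Every
#' day of the period must be present; missing days are a hard error by
#' default because silently zero-filling would bias baseline trends.
#'
#' @param dates `Date` vector of the daily series.
#' @param counts non-negative integer counts aligned to `dates`.
#' @param period a [StudyPeriod].
#' @param missing `"error"` (default) or `"zero"`: policy for days of the
#'   period absent from `dates`.
#' @return integer vector of length 10, one total per interval.
#' @export
aggregateDailyToIntervals <- function(dates, counts, period,
                                      missing = c("error", "zero")) {
  missing <- match.arg(missing)
  stopifnot(methods::is(period, "StudyPeriod"))
  dates <- as.Date(dates)
  if (length(dates) != length(counts))
    stop("dates and counts must be aligned")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (anyDuplicated(dates))
    stop("duplicate dates in daily series")
  allDays <- seq(period@intervalStart[1], period@intervalEnd[10], by = "day")
  idx <- match(allDays, dates)
  if (anyNA(idx) && missing == "error")
    stop(sum(is.na(idx)), " day(s) of the study period are missing from the daily series")
  daily <- ifelse(is.na(idx), 0L, counts[idx])
  interval <- rep(seq_len(10L), each = 14L)
  as.integer(tapply(daily, interval, sum))
}

#' Great-circle distance between county centroids, in miles
#'
#' Haversine distance (Earth radius 6371 km) between points given as
#' (longitude, latitude) degrees.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees; vectors recycle.
#' @return distance in miles.
#' @export
centroidDistanceMiles <- function(lon1, lat1, lon2, lat2) {
  m <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                r = EARTH_RADIUS_M)
  m / 1000 * MILES_PER_KM
}

#' Select the analytic treated/control set for one storm
#'
#' Applies the eligibility rules to the candidate counties of a single
#' storm: any county with population below 100, or with 5 or fewer events
#' of any studied outcome during the study period, is excluded; controls
#' are then retained only if their centroid lies within 150 miles of at
#' least one retained treated county.  The exclusion log records the first
#' rule each dropped county triggered.
#'
#' @param exposures `data.frame` for one storm with columns `county_id`,
#'   `max_windspeed` (m/s) and optionally `storm_id` (must be unique).
#' @param counties `data.frame` with columns `county_id`, `population`,
#'   `lat`, `lon` covering every candidate county.
#' @param eventMinima named numeric: per county, the minimum event count
#'   across the studied outcomes over the study period.
#' @return an [AnalyticSet].
#' @seealso [qualifyStorm()], [buildPanel()]
#' @export
selectAnalyticSet <- function(exposures, counties, eventMinima) {
  if (nrow(exposures) == 0L)
    stop("storm has no candidate counties")
  sid <- unique(as.character(
    if ("storm_id" %in% names(exposures)) exposures$storm_id else "storm"))
  if (length(sid) != 1L)
    stop("exposures must describe a single storm")
  ids <- as.character(exposures$county_id)
  if (anyDuplicated(ids))
    stop("duplicate county_id in exposures")
  ci <- match(ids, as.character(counties$county_id))
  if (anyNA(ci))
    stop("counties table must cover every candidate county")
  em <- eventMinima[ids]
  if (anyNA(em))
    stop("eventMinima must cover every candidate county")

  role <- classifyExposure(exposures$max_windspeed)
  pop <- counties$population[ci]
  lat <- counties$lat[ci]
  lon <- counties$lon[ci]

  reason <- rep(NA_character_, length(ids))
  reason[pop < 100] <- "population_lt_100"
  reason[is.na(reason) & em <= 5] <- "events_le_5"

  keptTreated <- which(role == "treated" & is.na(reason))
  candControl <- which(role == "control" & is.na(reason))
  if (length(keptTreated) && length(candControl)) {
    dmin <- vapply(candControl, function(j) {
      min(centroidDistanceMiles(lon[j], lat[j],
                                lon[keptTreated], lat[keptTreated]))
    }, numeric(1))
    reason[candControl[dmin > CONTROL_RADIUS_MILES]] <- "control_gt_150mi"
  } else if (length(candControl)) {
    # no treated county survives: every control is unanchored
    reason[candControl] <- "control_gt_150mi"
  }

  drop <- !is.na(reason)
  methods::new("AnalyticSet",
    stormId = sid,
    treated = sort(ids[role == "treated" & !drop]),
    control = sort(ids[role == "control" & !drop]),
    exclusions = data.frame(
      county_id = ids[drop], role = role[drop], reason = reason[drop],
      stringsAsFactors = FALSE))
}

#' Does a storm qualify for analysis?
#'
#' A storm is analyzed only if it has at least one treated county, at
#' least 20 analytic counties in total, and at least 5 controls.
#'
#' @param analytic an [AnalyticSet].
#' @return logical.
#' @export
qualifyStorm <- function(analytic) {
  stopifnot(methods::is(analytic, "AnalyticSet"))
  nt <- length(analytic@treated)
  nc <- length(analytic@control)
  nt >= 1L && (nt + nc) >= 20L && nc >= 5L
}

#' Assemble the panel matrix for one storm
#'
#' Builds the county-by-interval [StormPanel] from the analytic set, the
#' per-county interval count vectors and the population offsets.  Rows are
#' ordered deterministically: treated counties first, then controls, each
#' sorted by county id.  The treatment mask is 1 exactly for treated
#' counties in the final interval.
#'
#' @param analytic an [AnalyticSet] (must qualify, see [qualifyStorm()]).
#' @param intervalCounts numeric matrix of counts with one named row per
#'   analytic county and 10 columns.
#' @param offsets either a named vector of per-county populations (used for
#'   all intervals) or a matrix shaped like `intervalCounts`.
#' @param period optional [StudyPeriod] stored in the panel metadata.
#' @param requireQualify set `FALSE` to build panels for non-qualifying
#'   storms (e.g. toy examples).
#' @return a [StormPanel].
#' @export
buildPanel <- function(analytic, intervalCounts, offsets, period = NULL,
                       requireQualify = TRUE) {
  stopifnot(methods::is(analytic, "AnalyticSet"))
  if (requireQualify && !qualifyStorm(analytic))
    stop("storm does not qualify (need >=1 treated, >=20 total, >=5 controls)")
  ord <- c(sort(analytic@treated), sort(analytic@control))
  if (!all(ord %in% rownames(intervalCounts)))
    stop("intervalCounts must have a named row for every analytic county")
  Y <- as.matrix(intervalCounts)[ord, , drop = FALSE]
  T <- ncol(Y)
  if (T != 10L)
    stop("expected 10 interval columns")
  if (is.matrix(offsets)) {
    if (!all(ord %in% rownames(offsets)))
      stop("offset matrix must cover every analytic county")
    p <- offsets[ord, , drop = FALSE]
    if (ncol(p) != T) stop("offset matrix must match interval columns")
  } else {
    if (!all(ord %in% names(offsets)))
      stop("offsets must be named for every analytic county")
    p <- matrix(offsets[ord], nrow = length(ord), ncol = T,
                dimnames = list(ord, NULL))
  }
  if (any(p <= 0)) stop("offsets must be positive")
  D <- matrix(0, nrow(Y), T, dimnames = dimnames(Y))
  D[rownames(Y) %in% analytic@treated, T] <- 1
  storage.mode(Y) <- "integer"
  colnames(Y) <- colnames(D) <- colnames(p) <- paste0("I", seq_len(T))
  role <- ifelse(rownames(Y) %in% analytic@treated, "treated", "control")
  cd <- S4Vectors::DataFrame(interval = seq_len(T),
                             row.names = colnames(Y))
  if (!is.null(period)) {
    cd$start <- period@intervalStart
    cd$end <- period@intervalEnd
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = Y, mask = D, offset = p),
    rowData = S4Vectors::DataFrame(role = role, population = p[, T],
                                   row.names = rownames(Y)),
    colData = cd,
    metadata = list(stormId = analytic@stormId, T0 = T,
                    exclusions = analytic@exclusions, period = period))
  methods::new("StormPanel", se)
}

#' Construct a StormPanel directly from components
#'
#' Low-level constructor used by the synthetic generator and the readers:
#' wraps ready-made count, mask and offset matrices into a [StormPanel].
#'
#' @param counts,mask,offset matrices of identical dimension with county
#'   row names.
#' @param stormId character storm identifier.
#' @param T0 treatment start column (default: last column).
#' @param period optional [StudyPeriod].
#' @return a [StormPanel].
#' @export
stormPanel <- function(counts, mask, offset, stormId = "storm",
                       T0 = ncol(counts), period = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  mask <- as.matrix(mask)
  offset <- as.matrix(offset)
  role <- ifelse(rowSums(mask) > 0, "treated", "control")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, mask = mask, offset = offset),
    rowData = S4Vectors::DataFrame(role = role,
                                   population = offset[, ncol(offset)],
                                   row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(interval = seq_len(ncol(counts)),
                                   row.names = colnames(counts)),
    metadata = list(stormId = stormId, T0 = as.integer(T0),
                    exclusions = data.frame(), period = period))
  methods::new("StormPanel", se)
}

#' Build a storm panel from raw daily data
#'
#' End-to-end convenience: classifies exposures, applies the analytic-set
#' filters, defines the study period from the storm's first approach date,
#' aggregates each retained county's daily series to two-week totals, and
#' assembles the [StormPanel].
#'
#' @param daily `data.frame` with columns `county_id`, `date` (ISO-8601),
#'   `count`; one studied outcome.
#' @param exposures `data.frame` for one storm: `county_id`,
#'   `max_windspeed`, `first_approach_date`, optionally `storm_id`.
#' @param counties `data.frame`: `county_id`, `population`, `lat`, `lon`.
#' @param eventMinima optional named per-county minima across all studied
#'   outcomes; computed from `daily` alone when omitted.
#' @param missing policy passed to [aggregateDailyToIntervals()].
#' @return list with elements `panel` ([StormPanel]), `analytic`
#'   ([AnalyticSet]) and `period` ([StudyPeriod]).
#' @export
buildStormPanel <- function(daily, exposures, counties, eventMinima = NULL,
                            missing = "error") {
  fa <- unique(as.Date(exposures$first_approach_date))
  if (length(fa) != 1L)
    stop("all exposure rows of one storm must share the first approach date")
  period <- defineStudyPeriod(fa)
  daily$date <- as.Date(daily$date)
  inPeriod <- daily$date >= period@intervalStart[1] &
    daily$date <= period@intervalEnd[10]
  if (is.null(eventMinima)) {
    tot <- tapply(daily$count[inPeriod], as.character(daily$county_id[inPeriod]), sum)
    eventMinima <- structure(as.numeric(tot), names = names(tot))
    missingIds <- setdiff(as.character(exposures$county_id), names(eventMinima))
    if (length(missingIds))
      eventMinima[missingIds] <- 0
  }
  analytic <- selectAnalyticSet(exposures, counties, eventMinima)
  if (!qualifyStorm(analytic))
    stop("storm ", analytic@stormId, " does not qualify for analysis")
  ids <- c(analytic@treated, analytic@control)
  counts <- t(vapply(ids, function(id) {
    d <- daily[as.character(daily$county_id) == id, ]
    aggregateDailyToIntervals(d$date, d$count, period, missing = missing)
  }, integer(10)))
  rownames(counts) <- ids
  pop <- counties$population[match(ids, as.character(counties$county_id))]
  names(pop) <- ids
  panel <- buildPanel(analytic, counts, pop, period = period)
  list(panel = panel, analytic = analytic, period = period)
}
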