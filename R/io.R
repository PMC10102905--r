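## Plain-text artifacts: panels as CSV + JSON sidecar, estimand tables as
## CSV, study summaries as JSON.

#' Write a storm panel to disk
#'
#' Writes the count matrix as CSV (`<prefix>_counts.csv`, county_id +
#' interval columns) and a JSON sidecar (`<prefix>_panel.json`) carrying
#' the mask, offsets, labels, T0, storm id and exclusion log.
#'
#' @param panel a [StormPanel].
#' @param prefix path prefix (directories must exist).
#' @return invisibly, the two file paths.
#' @export
writePanel <- function(panel, prefix) {
  stopifnot(methods::is(panel, "StormPanel"))
  countsFile <- paste0(prefix, "_counts.csv")
  sideFile <- paste0(prefix, "_panel.json")
  df <- data.frame(county_id = rownames(panel), panelCounts(panel),
                   check.names = FALSE)
  utils::write.csv(df, countsFile, row.names = FALSE)
  side <- list(
    storm_id = stormId(panel),
    T0 = treatmentStart(panel),
    county_ids = rownames(panel),
    interval_labels = colnames(panel),
    mask = lapply(seq_len(nrow(panel)), function(i)
      as.integer(treatmentMask(panel)[i, ])),
    offsets = lapply(seq_len(nrow(panel)), function(i)
      as.numeric(panelOffsets(panel)[i, ])),
    exclusions = S4Vectors::metadata(panel)$exclusions)
  jsonlite::write_json(side, sideFile, auto_unbox = TRUE, digits = NA)
  invisible(c(countsFile, sideFile))
}

#' Read a storm panel written by [writePanel()]
#'
#' @param prefix the path prefix used when writing.
#' @return a [StormPanel].
#' @export
readPanel <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, "_counts.csv"), check.names = FALSE)
  side <- jsonlite::read_json(paste0(prefix, "_panel.json"),
                              simplifyVector = TRUE)
  Y <- as.matrix(df[, -1, drop = FALSE])
  rownames(Y) <- df$county_id
  toMat <- function(x) {
    m <- if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
    dimnames(m) <- dimnames(Y)
    m
  }
  stormPanel(Y, toMat(side$mask), toMat(side$offsets),
             stormId = side$storm_id, T0 = side$T0)
}

#' Write county-level estimand table as CSV
#'
#' @param study result of [summarizeStudy()].
#' @param file output CSV path.
#' @export
writeEffectsTable <- function(study, file) {
  utils::write.csv(study$countyTable, file, row.names = FALSE)
  invisible(file)
}

#' Write study-level summary (TEE/AER with intervals) as JSON
#'
#' @param study result of [summarizeStudy()].
#' @param file output JSON path.
#' @export
writeStudySummary <- function(study, file) {
  jsonlite::write_json(as.list(study$summary), file, auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read a tidy daily-count CSV
#'
#' Expects columns `county_id`, `date` (ISO-8601) and `count`.
#'
#' @param file CSV path.
#' @return validated `data.frame`.
#' @export
readDailyCounts <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("county_id", "date", "count")
  if (!all(need %in% names(df)))
    stop("daily counts CSV must have columns ", paste(need, collapse = ", "))
  df$date <- tryCatch(as.Date(df$date),
                      error = function(e) rep(NA, nrow(df)))
  if (anyNA(df$date)) stop("unparseable dates in daily counts")
  df
}

#' Read a storm-exposure CSV
#'
#' Expects columns `storm_id`, `county_id`, `first_approach_date`,
#' `max_windspeed` (m/s).
#'
#' @param file CSV path.
#' @return validated `data.frame`.
#' @export
readExposures <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("storm_id", "county_id", "first_approach_date", "max_windspeed")
  if (!all(need %in% names(df)))
    stop("exposure CSV must have columns ", paste(need, collapse = ", "))
  df
}

#' Read a county table CSV
#'
#' Expects columns `county_id`, `population`, `lat`, `lon`.
#'
#' @param file CSV path.
#' @return validated `data.frame`.
#' @export
readCounties <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("county_id", "population", "lat", "lon")
  if (!all(need %in% names(df)))
    stop("county CSV must have columns ", paste(need, collapse = ", "))
  df
}
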