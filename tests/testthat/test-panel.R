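test_that("exposure classification uses the gale-force threshold strictly", {
  expect_equal(classifyExposure(17.4), "treated")
  expect_equal(classifyExposure(17.3999), "control")
  expect_equal(classifyExposure(0), "control")
  expect_equal(classifyExposure(c(50, 3)), c("treated", "control"))
  expect_error(classifyExposure(-1), "non-negative")
  expect_error(classifyExposure(Inf), "finite")
  expect_error(classifyExposure(NA_real_), "finite")
})

test_that("study period pins the final interval to day -2 .. +11", {
  sp <- defineStudyPeriod(as.Date("2005-08-29"))
  expect_equal(sp@intervalStart[10], as.Date("2005-08-27"))
  expect_equal(sp@intervalEnd[10], as.Date("2005-09-09"))
  expect_equal(sp@treatmentIndex, 10L)
})

test_that("study period yields 10 contiguous 14-day intervals for any date", {
  dates <- as.Date("1999-01-01") + c(0, 58, 365, 1000, 4018, 6200)
  for (d in dates) {
    sp <- defineStudyPeriod(as.Date(d, origin = "1970-01-01"))
    expect_true(validObject(sp))
    expect_length(sp@intervalStart, 10)
    expect_equal(as.integer(sp@intervalEnd - sp@intervalStart),
                 rep(13L, 10))
    expect_equal(as.integer(sp@intervalStart[-1] - sp@intervalEnd[-10]),
                 rep(1L, 10 - 1))
    # window opens 128 days before first approach (anchored backwards from
    # the fixed treatment interval)
    expect_equal(as.integer(sp@firstApproach - sp@intervalStart[1]), 128L)
  }
  expect_error(defineStudyPeriod("not-a-date"))
})

test_that("daily-to-interval aggregation preserves totals and flags gaps", {
  sp <- defineStudyPeriod(as.Date("2011-08-27"))
  days <- seq(sp@intervalStart[1], sp@intervalEnd[10], by = "day")
  expect_equal(aggregateDailyToIntervals(days, rep(1L, 140), sp),
               rep(14L, 10))
  expect_equal(aggregateDailyToIntervals(days, rep(0L, 140), sp),
               rep(0L, 10))
  set.seed(1)
  cnt <- rpois(140, 3)
  agg <- aggregateDailyToIntervals(days, cnt, sp)
  expect_equal(sum(agg), sum(cnt))
  # counts outside the window are ignored; gaps inside it are fatal
  expect_error(aggregateDailyToIntervals(days[-7], cnt[-7], sp), "missing")
  expect_equal(sum(aggregateDailyToIntervals(days[-7], cnt[-7], sp,
                                             missing = "zero")),
               sum(cnt[-7]))
  expect_error(aggregateDailyToIntervals(c(days, days[1]), c(cnt, 1L), sp),
               "duplicate")
  expect_error(aggregateDailyToIntervals(days, cnt - 5L, sp), "non-negative")
})

test_that("centroid distances agree with a hand-coded haversine", {
  hav <- function(lon1, lat1, lon2, lat2) {
    r <- 6371
    toRad <- pi / 180
    dlat <- (lat2 - lat1) * toRad; dlon <- (lon2 - lon1) * toRad
    a <- sin(dlat / 2)^2 +
      cos(lat1 * toRad) * cos(lat2 * toRad) * sin(dlon / 2)^2
    2 * r * asin(sqrt(a)) * 0.621371
  }
  pts <- cbind(lon1 = c(-90, -80.1, -75), lat1 = c(29.9, 25.7, 40),
               lon2 = c(-89.1, -81.3, -75), lat2 = c(30.4, 28.5, 40))
  for (i in seq_len(nrow(pts))) {
    expect_equal(
      unname(centroidDistanceMiles(pts[i, 1], pts[i, 2], pts[i, 3],
                                   pts[i, 4])),
      unname(hav(pts[i, 1], pts[i, 2], pts[i, 3], pts[i, 4])),
      tolerance = 1e-6)
  }
})

# a line of counties along a meridian: 1 degree of latitude ~ 69.09 miles
# under the 6371 km haversine, so offsets in degrees give known distances
toyExposures <- function() {
  data.frame(
    storm_id = "T1",
    county_id = c("A", "B", "c100", "c149", "c151"),
    max_windspeed = c(30, 25, 5, 5, 5),
    stringsAsFactors = FALSE)
}

toyCounties <- function(popA = 5000) {
  milesPerDeg <- 2 * pi * 6371 / 360 * 0.621371
  data.frame(
    county_id = c("A", "B", "c100", "c149", "c151"),
    population = c(popA, 5000, 5000, 5000, 5000),
    lat = 30 + c(0, 0.1, 100, 149, 151) / milesPerDeg,
    lon = rep(-85, 5),
    stringsAsFactors = FALSE)
}

test_that("analytic-set rules drop small, quiet and distant counties", {
  em <- c(A = 50, B = 50, c100 = 50, c149 = 50, c151 = 50)
  as1 <- selectAnalyticSet(toyExposures(), toyCounties(), em)
  expect_setequal(treatedIds(as1), c("A", "B"))
  expect_setequal(controlIds(as1), c("c100", "c149"))
  expect_equal(exclusionLog(as1)$reason, "control_gt_150mi")

  # population below 100 excludes even a treated county
  as2 <- selectAnalyticSet(toyExposures(), toyCounties(popA = 99), em)
  expect_false("A" %in% treatedIds(as2))
  lg <- exclusionLog(as2)
  expect_equal(lg$reason[lg$county_id == "A"], "population_lt_100")

  # 5 events of any studied outcome excludes; 6 retains
  em2 <- em; em2["c100"] <- 5
  as3 <- selectAnalyticSet(toyExposures(), toyCounties(), em2)
  expect_false("c100" %in% controlIds(as3))
  em2["c100"] <- 6
  expect_true("c100" %in% controlIds(
    selectAnalyticSet(toyExposures(), toyCounties(), em2)))

  expect_error(selectAnalyticSet(toyExposures()[0, ], toyCounties(), em),
               "no candidate")
})

test_that("storm qualification needs >=1 treated, >=20 total, >=5 controls", {
  mk <- function(nt, nc) methods::new("AnalyticSet", stormId = "q",
    treated = sprintf("t%02d", seq_len(nt)),
    control = sprintf("c%02d", seq_len(nc)),
    exclusions = data.frame())
  expect_false(qualifyStorm(mk(0, 30)))
  expect_false(qualifyStorm(mk(15, 4)))
  expect_true(qualifyStorm(mk(15, 5)))
  expect_false(qualifyStorm(mk(14, 5)))
  expect_true(qualifyStorm(mk(1, 19)))
})

test_that("panel assembly places the mask and orders rows deterministically", {
  nt <- 3; nc <- 17
  ids <- c(sprintf("t%02d", seq_len(nt)), sprintf("c%02d", seq_len(nc)))
  as1 <- methods::new("AnalyticSet", stormId = "P", treated = ids[1:nt],
                      control = ids[-(1:nt)], exclusions = data.frame())
  set.seed(2)
  counts <- matrix(rpois(20 * 10, 30), 20, 10, dimnames = list(ids, NULL))
  pop <- setNames(rep(1000, 20), ids)
  pan <- buildPanel(as1, counts, pop)
  D <- treatmentMask(pan)
  expect_equal(sum(D), nt)
  expect_equal(unname(colSums(D)), c(rep(0, 9), nt))
  expect_equal(rownames(pan), c(sort(ids[1:nt]), sort(ids[-(1:nt)])))
  expect_equal(treatmentStart(pan), 10L)

  # permuting the input row order changes nothing
  perm <- sample(nrow(counts))
  pan2 <- buildPanel(as1, counts[perm, ], pop[perm])
  expect_identical(panelCounts(pan), panelCounts(pan2))
  expect_identical(treatmentMask(pan), treatmentMask(pan2))

  # all-control panel is possible when qualification is waived
  as0 <- methods::new("AnalyticSet", stormId = "P", treated = character(),
                      control = ids, exclusions = data.frame())
  pan0 <- buildPanel(as0, counts, pop, requireQualify = FALSE)
  expect_equal(sum(treatmentMask(pan0)), 0)

  expect_error(buildPanel(as1, counts[, 1:9], pop), "10 interval")
  badPop <- pop; badPop["t01"] <- 0
  expect_error(buildPanel(as1, counts, badPop), "positive")
})

test_that("invalid panels are rejected by the validity method", {
  counts <- matrix(5L, 4, 10,
                   dimnames = list(sprintf("C%d", 1:4), NULL))
  D <- matrix(0, 4, 10); D[1, 4] <- 1   # mask before T0
  offs <- matrix(100, 4, 10)
  expect_error(stormPanel(counts, D, offs, T0 = 10), "before the treatment")
  D2 <- matrix(0, 4, 10); D2[1, 10] <- 0.5
  expect_error(stormPanel(counts, D2, offs, T0 = 10), "binary")
  expect_error(stormPanel(counts, matrix(0, 4, 10), offs * 0, T0 = 10),
               "positive")
})

test_that("raw daily data can be assembled end to end", {
  sp <- defineStudyPeriod(as.Date("2004-09-05"))
  milesPerDeg <- 2 * pi * 6371 / 360 * 0.621371
  nT <- 4; nC <- 18
  ids <- c(sprintf("t%02d", 1:nT), sprintf("c%02d", 1:nC))
  counties <- data.frame(county_id = ids, population = 5000,
                         lat = 30 + seq(0, 2, length.out = nT + nC),
                         lon = -85)
  expo <- data.frame(storm_id = "E2E", county_id = ids,
                     first_approach_date = "2004-09-05",
                     max_windspeed = c(rep(25, nT), rep(4, nC)))
  days <- seq(sp@intervalStart[1], sp@intervalEnd[10], by = "day")
  set.seed(3)
  daily <- do.call(rbind, lapply(ids, function(id)
    data.frame(county_id = id, date = days, count = rpois(140, 2))))
  out <- buildStormPanel(daily, expo, counties)
  expect_s4_class(out$panel, "StormPanel")
  expect_equal(dim(out$panel), c(nT + nC, 10L))
  expect_equal(sum(treatmentMask(out$panel)), nT)
  expect_equal(sum(panelCounts(out$panel)), sum(daily$count))
})
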