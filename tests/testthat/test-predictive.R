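test_that("restricted cubic spline basis is natural and spans ns()", {
  kn <- c(20, 28, 36, 48)
  x <- seq(10, 60, by = 0.5)
  B <- rcsBasis(x, kn)
  expect_equal(ncol(B), 3L)
  # below the first knot every nonlinear column vanishes: pure linearity
  low <- x < min(kn)
  expect_true(all(abs(B[low, -1]) < 1e-12))
  # beyond the last knot the basis is linear: second differences vanish
  hi <- which(x > max(kn))
  for (j in seq_len(ncol(B))) {
    d2 <- diff(diff(B[hi, j]))
    expect_true(all(abs(d2) < 1e-8))
  }
  # independent oracle: the basis spans the same function space as the
  # natural spline basis of the splines package (equal projections)
  set.seed(4)
  y <- sin(x / 9) + rnorm(length(x), 0, 0.2)
  fitRcs <- lm(y ~ B)
  fitNs <- lm(y ~ splines::ns(x, knots = kn[2:3],
                              Boundary.knots = kn[c(1, 4)]))
  expect_equal(fitted(fitRcs), fitted(fitNs), tolerance = 1e-8)
  expect_error(rcsBasis(x, c(1, 2)), "at least 3")
  expect_error(rcsKnots(rep(5, 10)), "distinct")
})

test_that("knot rule uses the 5/35/65/95 percentiles for 4 knots", {
  set.seed(5)
  x <- rnorm(500)
  expect_equal(rcsKnots(x),
               unname(quantile(x, c(0.05, 0.35, 0.65, 0.95))))
})

test_that("modular fit recovers a noiseless linear signal exactly", {
  set.seed(11)
  n <- 30; M <- 200
  X <- data.frame(windspeed = runif(n, 18, 50))
  y <- -5 + 1.5 * X$windspeed
  draws <- matrix(y, M, n, byrow = TRUE)     # no first-stage uncertainty
  fit <- fitModular(draws, X, predictiveModelSpec(linear = "windspeed"),
                    seed = 2)
  cs <- coefSummary(fit)
  expect_equal(cs$mean[cs$term == "windspeed"], 1.5, tolerance = 1e-3)
  expect_equal(cs$mean[cs$term == "(Intercept)"], -5, tolerance = 0.05)
  # posterior near-collapses (tiny floor from the vague variance prior)
  expect_lt(cs$upper[2] - cs$lower[2], 0.1)
  expect_equal(nDraws(fit), M)
})

test_that("intercept-only fit centers on the per-draw mean", {
  set.seed(12)
  M <- 500; n <- 25
  draws <- matrix(rnorm(M * n, 10, 2), M, n)
  fit <- fitModular(draws, data.frame(id = seq_len(n)),
                    predictiveModelSpec(), seed = 3)
  expect_equal(ncol(fit@beta), 1L)
  expect_equal(mean(coefDraws(fit)[, 1]), mean(draws), tolerance = 0.2)
})

test_that("exposure order does not affect the modular draws", {
  set.seed(13)
  n <- 20; M <- 50
  X <- data.frame(windspeed = runif(n, 18, 45), poverty = runif(n, 5, 25))
  draws <- matrix(rnorm(M * n, 20, 5), M, n)
  spec <- predictiveModelSpec(linear = c("windspeed", "poverty"))
  f1 <- fitModular(draws, X, spec, seed = 9)
  perm <- sample(n)
  f2 <- fitModular(draws[, perm], X[perm, , drop = FALSE], spec, seed = 9)
  expect_equal(f1@beta, f2@beta, tolerance = 1e-10)
  expect_equal(f1@sigma, f2@sigma, tolerance = 1e-10)
})

test_that("plug-in equals modular when first-stage uncertainty vanishes", {
  set.seed(14)
  n <- 30; M <- 100
  X <- data.frame(windspeed = runif(n, 18, 50))
  y <- 3 + 0.8 * X$windspeed + rnorm(n, 0, 2)
  draws <- matrix(y, M, n, byrow = TRUE)     # degenerate causal posterior
  spec <- predictiveModelSpec(linear = "windspeed")
  fm <- fitModular(draws, X, spec, seed = 21)
  fp <- fitPlugin(colMeans(draws), X, spec, M = M, seed = 21)
  expect_identical(fm@beta, fp@beta)          # same posterior, same stream
  expect_identical(fm@sigma, fp@sigma)
  # determinism
  expect_identical(fp@beta, fitPlugin(colMeans(draws), X, spec, M = M,
                                      seed = 21)@beta)
})

test_that("first-stage variance widens modular intervals beyond plug-in", {
  set.seed(15)
  n <- 40; M <- 400
  X <- data.frame(windspeed = runif(n, 18, 50))
  center <- -10 + 2 * X$windspeed + rnorm(n, 0, 4)
  draws <- matrix(center, M, n, byrow = TRUE) + matrix(rnorm(M * n, 0, 15), M, n)
  spec <- predictiveModelSpec(linear = "windspeed")
  wm <- coefSummary(fitModular(draws, X, spec, seed = 6))
  wp <- coefSummary(fitPlugin(colMeans(draws), X, spec, M = M, seed = 6))
  expect_gt(wm$upper[2] - wm$lower[2], wp$upper[2] - wp$lower[2])
})

test_that("predictions interpolate training data and respect the schema", {
  set.seed(16)
  n <- 25; M <- 300
  X <- data.frame(windspeed = runif(n, 18, 50))
  y <- -5 + 1.5 * X$windspeed
  draws <- matrix(y, M, n, byrow = TRUE)
  spec <- predictiveModelSpec(linear = "windspeed")
  fit <- fitModular(draws, X, spec, seed = 4)
  pr <- predictNew(fit, X[1:3, , drop = FALSE], residual = FALSE)
  expect_equal(pr@summary$mean, y[1:3], tolerance = 0.01)
  # batch prediction without residual equals concatenated singles
  p1 <- predictNew(fit, X[1, , drop = FALSE], residual = FALSE)
  expect_equal(pr@draws[, 1], p1@draws[, 1])
  # intercept-only, all-zero covariates: prediction = intercept + noise
  fit0 <- fitModular(matrix(rnorm(M * n, 7, 1), M, n),
                     data.frame(id = seq_len(n)), predictiveModelSpec(),
                     seed = 5)
  pr0 <- predictNew(fit0, data.frame(id = 1), seed = 8)
  expect_equal(mean(pr0@draws), 7, tolerance = 0.3)
  expect_error(predictNew(fit, data.frame(bogus = 1)), "missing")
})

test_that("feature tables must be complete and full rank", {
  M <- 10; n <- 8
  draws <- matrix(rnorm(M * n), M, n)
  Xna <- data.frame(windspeed = c(NA, runif(n - 1, 18, 40)))
  spec <- predictiveModelSpec(linear = "windspeed")
  expect_error(fitModular(draws, Xna, spec), "complete")
  Xdup <- data.frame(windspeed = runif(n, 18, 40))
  Xdup$copy <- Xdup$windspeed
  expect_error(fitModular(draws, Xdup,
    predictiveModelSpec(linear = c("windspeed", "copy"))), "rank deficient")
  expect_error(fitModular(draws[, 1:4], Xdup, spec), "align")
})

test_that("cross-validation ties duplicates and matches a hand calculation", {
  set.seed(17)
  n <- 24
  X <- data.frame(windspeed = runif(n, 18, 50))
  y <- -10 + 2 * X$windspeed + rnorm(n, 0, 1)
  sl <- predictiveModelSpec(linear = "windspeed")
  s0 <- predictiveModelSpec()
  tab <- crossvalidateModelMenu(list(sl, sl, s0), y, X, folds = 4, seed = 5)
  expect_equal(nrow(tab), 3L)
  dup <- tab$meanMSE[tab$candidate %in% 1:2]
  expect_identical(dup[1], dup[2])            # duplicates tie exactly
  expect_equal(tab$candidate[1] %in% 1:2, TRUE) # true model wins here
  # leave-one-out, n = 3, intercept-only: hand-computed ridge means
  y3 <- c(1, 2, 9)
  X3 <- data.frame(id = 1:3)
  g2 <- predictiveModelSpec()@priorCoefScale^2
  handMSE <- mean(sapply(1:3, function(i) {
    mn <- sum(y3[-i]) / (2 + 1 / g2)   # conjugate posterior mean
    (y3[i] - mn)^2
  }))
  tab3 <- crossvalidateModelMenu(list(s0, s0), y3, X3, folds = 3, seed = 1)
  expect_equal(tab3$meanMSE[1], handMSE, tolerance = 1e-10)
  expect_error(crossvalidateModelMenu(list(s0, sl), y3, X3, folds = 5),
               "more folds")
  expect_error(crossvalidateModelMenu(list(s0), y, X), "at least 2")
})

test_that("the true model family usually wins cross-validation", {
  wins <- 0
  for (r in 1:20) {
    set.seed(600 + r)
    n <- 60
    X <- data.frame(windspeed = runif(n, 18, 50))
    y <- -10 + 2 * X$windspeed + rnorm(n, 0, 3)
    tab <- crossvalidateModelMenu(
      list(predictiveModelSpec(linear = "windspeed"),
           predictiveModelSpec()),
      y, X, folds = 5, seed = r)
    wins <- wins + (tab$candidate[1] == 1)
  }
  expect_gte(wins, 16)   # >= 80% of replicates
})
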