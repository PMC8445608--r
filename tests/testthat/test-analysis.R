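test_that("segmentation recovers the breakpoint of a constructed biphasic series", {
  t <- 1:12
  a <- 14.02; k <- 0.714; tb <- 5.6
  ## exponential phase continuing into a slope-continuous linear phase
  y <- ifelse(t <= tb, a * exp(k * t),
              a * exp(k * tb) * (1 + k * (t - tb)))
  fit <- segmentGrowthPhases(data.frame(time = t, value = y))
  expect_lte(abs(fit@transitionTime - tb), 0.5)
  expect_equal(fit@splitIndex, 5L)          # last purely exponential sample
  expect_equal(fit@expK, k, tolerance = 0.02)
  expect_equal(fit@expA, a, tolerance = 0.02)
  expect_gt(fit@r2Exp, 0.999)
})

test_that("a purely exponential series degenerates to a full-series fit", {
  t <- 1:10
  y <- 3 * exp(0.5 * t)
  fit <- segmentGrowthPhases(data.frame(time = t, value = y))
  expect_equal(fit@splitIndex, 10L)
  expect_equal(fit@transitionTime, 10)
  expect_gte(fit@r2Exp, 0.999)
  expect_true(is.na(fit@linK))
})

test_that("segmentation input validation", {
  expect_error(segmentGrowthPhases(data.frame(time = 1:4, value = 1:4)),
               "too short")
  y <- c(1, 2, 0, 4, 8, 16, 20, 24, 28, 30)
  expect_error(segmentGrowthPhases(data.frame(time = 1:10, value = y)),
               "non-positive")
})

test_that("doubling time arithmetic matches the reported conversions", {
  expect_equal(doublingTime(log(2)), 24)
  expect_equal(doublingTime(0.714), 23.30, tolerance = 1e-3)
  expect_equal(doublingTime(0.633), 26.28, tolerance = 1e-3)
  expect_error(doublingTime(0), "positive")
  expect_error(doublingTime(-1), "positive")
})

test_that("advance rate recovers exact and noisy linear extents", {
  t <- 0:12
  exact <- advanceRate(data.frame(time = t, extent = 20 * t))
  expect_equal(exact[["um_per_day"]], 20)
  expect_equal(exact[["mm_per_yr"]], 7.3)
  ## noisy line: slope recovered within 3 standard errors
  set.seed(8)
  y <- 5 + 20 * t + rnorm(length(t), 0, 4)
  ft <- lm(y ~ t)
  se <- summary(ft)$coefficients["t", "Std. Error"]
  got <- advanceRate(data.frame(time = t, extent = y))[["um_per_day"]]
  expect_lt(abs(got - 20), 3 * se + 1e-9)
  expect_error(advanceRate(data.frame(time = 1:2, extent = 1:2)), "3 points")
})

test_that("calcification rate handles absent and linear calcified volume", {
  m0 <- data.frame(time_days = 0:10, calcified_volume = 0)
  expect_equal(calcificationRate(m0), 0)
  ## m merges/day of mature-cell residuals at 30% volume
  Vc <- 0.30 * 4 / 3 * pi * 5^3
  m <- 7
  mm <- data.frame(time_days = 0:10, calcified_volume = Vc * m * (0:10))
  expect_equal(calcificationRate(mm), Vc * m, tolerance = 1e-9)
})

test_that("sensitivity coefficient arithmetic and scale invariance", {
  ## dM/M = 0.2 at dp/p = 0.1 -> S = 2
  expect_equal(sensitivityCoefficient(1.2, 1, 1.1), 2, tolerance = 1e-12)
  ## invariant under output rescaling
  M0 <- 3.7; M <- 4.4; v <- 0.95
  expect_equal(sensitivityCoefficient(10 * M, 10 * M0, v),
               sensitivityCoefficient(M, M0, v))
  expect_error(sensitivityCoefficient(1, 0, 1.1), "zero")
  expect_error(sensitivityCoefficient(1, 1, 1), "variation")
})

test_that("sensitivity sweep uses common random numbers across variations", {
  base <- simConfig(luminalDiameter = 100, axialLength = 250, days = 2,
                    thresholdsEnabled = FALSE, seed = 3)
  finalCount <- list(count = function(res)
    tail(metricsTable(res)$dcis_count, 1))
  ## an output that cannot depend on the parameter: S is exactly 0
  sw0 <- sensitivitySweep(base, "fgfThreshold", variations = c(0.8, 1.2),
                          seeds = 3L, outputs = finalCount)
  expect_true(all(sw0@grid$S == 0))
  expect_equal(sw0@maxS[["count"]], 0)
  ## a parameter that must matter: shorter cycle -> more cells
  sw1 <- sensitivitySweep(base, "tauP", variations = c(0.8, 1.2),
                          seeds = 3L, outputs = finalCount)
  g <- sw1@grid
  expect_gt(g$M[g$variation == 0.8], sw1@baseline[["count"]])
  expect_true(all(is.finite(g$S)))
  expect_error(sensitivitySweep(base, "notAParameter"), "parameter")
})
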