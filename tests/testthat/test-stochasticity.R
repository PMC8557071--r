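test_that("closed-form MLEs match hand computations", {
  x <- rep(c(1, 2, 3), 3) # n = 9 >= 8; same mean and spread shape as {1,2,3}
  f <- fitDistribution(x, "normal")
  expect_equal(unname(f$params["mean"]), 2)
  expect_equal(unname(f$params["sd"]), sqrt(sum((x - 2)^2) / 9))
  expect_equal(f$bic, -2 * f$loglik + 2 * log(9))

  lx <- exp(c(0.1, 0.5, 0.9, 0.2, 0.6, 1.0, 0.3, 0.7))
  fl <- fitDistribution(lx, "lognormal")
  expect_equal(unname(fl$params["meanlog"]), mean(log(lx)))
  expect_equal(unname(fl$params["sdlog"]),
               sqrt(mean((log(lx) - mean(log(lx)))^2)))
})

test_that("degenerate and domain errors are raised", {
  expect_error(fitDistribution(1:5, "normal"), "n >= 8")
  expect_error(fitDistribution(rep(2, 10), "normal"), "zero variance")
  expect_error(fitDistribution(c(-1, rexp(9)), "gamma"), "positive")
  expect_error(fitDistribution(rep(exp(1), 10), "lognormal"), "zero variance")
})

test_that("gamma MLE recovers generating parameters and beats the oracle's likelihood", {
  set.seed(42)
  x <- rgamma(1e5, shape = 3.026, rate = 4.520)
  f <- fitDistribution(x, "gamma")
  expect_equal(unname(f$params["shape"]), 3.026, tolerance = 0.02)
  expect_equal(unname(f$params["rate"]), 4.520, tolerance = 0.02)

  # independent oracle: fitdistrplus' optimiser on a small fixture; our
  # Newton solution must agree to 4 decimals and its likelihood can only be
  # equal or higher (it solves the score equation exactly)
  set.seed(7)
  y <- rgamma(200, shape = 5, rate = 2)
  ours <- fitDistribution(y, "gamma")
  ref <- fitdistrplus::fitdist(y, "gamma", method = "mle")
  expect_equal(unname(ours$params["shape"]), unname(ref$estimate["shape"]),
               tolerance = 1e-4)
  expect_equal(unname(ours$params["rate"]), unname(ref$estimate["rate"]),
               tolerance = 1e-4)
  expect_gte(ours$loglik, ref$loglik - 1e-6)
})

test_that("BIC selection picks the generating family and zeroes its delta", {
  set.seed(1)
  x <- rlnorm(5000, 3.905, 0.388)
  s <- bestFitAuto(x)
  expect_equal(s$best, "lognormal")
  expect_equal(unname(s$delta_bic[s$best]), 0)
  expect_true(all(s$delta_bic >= 0))

  xn <- rnorm(5000, 10, 1)
  xn <- xn[xn > 0]
  expect_equal(bestFitAuto(xn)$best, "normal")

  xg <- rgamma(5000, 3.026, 4.520)
  expect_equal(bestFitAuto(xg)$best, "gamma")
})

test_that("samples straddling zero exclude the log-families entirely", {
  set.seed(2)
  x <- rnorm(500, 0, 1)
  # gamma and lognormal both drop out, leaving < 2 candidates
  expect_error(suppressWarnings(bestFitAuto(x)), "fewer than 2")
})

test_that("delta-BIC annotations follow Jeffreys' scale", {
  set.seed(3)
  x <- rlnorm(4000, 1, 0.6)
  s <- suppressWarnings(bestFitAuto(x))
  expect_true(all(s$evidence[s$delta_bic > 10 & names(s$delta_bic) != s$best] == "decisive"))
  expect_equal(unname(s$evidence[s$best]), "best")
})

test_that("the dominant family is the one most often within delta-BIC 5", {
  fake <- function(best, db) {
    structure(list(best = best, delta_bic = db), class = "modelSelection")
  }
  sels <- list(
    A = fake("gamma", c(normal = 40, gamma = 0, lognormal = 3)),
    B = fake("lognormal", c(normal = 30, gamma = 12, lognormal = 0)))
  expect_equal(dominantFamily(sels), "lognormal") # credited in 2 groups vs 1
  expect_equal(dominantFamily(sels["A"]), "gamma") # single group: its best
  allg <- list(A = fake("gamma", c(normal = 20, gamma = 0, lognormal = 11)),
               B = fake("gamma", c(normal = 25, gamma = 0, lognormal = 15)))
  expect_equal(dominantFamily(allg), "gamma")
  expect_error(dominantFamily(list()), "at least one")
})

test_that("distribution means and dispersions follow the stated formulas", {
  expect_equal(distMeanSd("normal", c(mean = 3, sd = 2)),
               c(mean = 3, sd = 2, variance = 4))
  g <- distMeanSd("gamma", c(shape = 10.666, rate = 3.474))
  expect_equal(unname(g["mean"]), 10.666 / 3.474, tolerance = 1e-12)
  expect_equal(unname(g["variance"]), 10.666 / 3.474^2, tolerance = 1e-12)
  expect_equal(unname(g["sd"]), sqrt(10.666) / 3.474, tolerance = 1e-12)
  ln <- distMeanSd("lognormal", c(meanlog = 3.905, sdlog = 0.388))
  expect_equal(unname(ln["mean"]), exp(3.905 + 0.388^2 / 2), tolerance = 1e-12)
  expect_equal(unname(ln["mean"]), 53.5316, tolerance = 1e-4)
  expect_equal(unname(ln["variance"]),
               (exp(0.388^2) - 1) * exp(2 * 3.905 + 0.388^2), tolerance = 1e-12)
  expect_error(distMeanSd("gamma", c(shape = -1, rate = 2)), "invalid")
})

test_that("group-wise fitting reports the dominant family over generations", {
  sim <- simulateMovie(simConfig(seed = 13, nProgenitors = 4, nFrames = 70,
                                 maxCells = 10000))
  flt <- buildFLT(sim$cells)
  fdt <- computeLifeAttributes(flt, buildFDT(flt, minLife = 3))
  res <- fitAttrDistributions(fdt, "length_division", by = "generation")
  expect_true(res$dominant %in% c("normal", "gamma", "lognormal"))
  expect_true(all(c("group", "best", "bic", "mean", "sd") %in% names(res$table)))
  expect_gt(nrow(res$table), 1)
})
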