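test_that("constant series gives y0 = value, k = 0, zero rmse", {
  f <- fitCellGrowth(seq(0, 50, 5), rep(2, 11), "exp")
  expect_true(f$converged)
  expect_equal(f$y0, 2, tolerance = 1e-10)
  expect_equal(f$k, 0, tolerance = 1e-10)
  expect_equal(f$rmse, 0, tolerance = 1e-10)
})

test_that("noiseless exponential parameters are recovered to 1e-6", {
  t_min <- seq(0, 600, 60) # 0..10 h
  y <- 2 * exp(0.05 * t_min / 60)
  f <- fitCellGrowth(t_min, y, "exp")
  expect_equal(f$y0, 2, tolerance = 1e-6)
  expect_equal(f$k, 0.05, tolerance = 1e-6)
  expect_lt(f$rmse, 1e-8)
})

test_that("short series fail gracefully and are reported by id", {
  f <- fitCellGrowth(c(0, 5), c(1, 2), "exp")
  expect_false(f$converged)
  expect_error(fitCellGrowth(c(0, 5), c(1, 2, 3)), "differ in length")
  expect_error(fitCellGrowth(c(5, 5, 5), c(1, 2, 3)), "degenerate")

  sim <- smallSim(seed = 2, nFrames = 40)
  fits <- fitGrowthForest(buildFLT(sim$cells), "length", "exp")
  short <- cellTable(buildFLT(sim$cells))
  shortIds <- short$cell_id[short$last_frame - short$birth_frame + 1 < 3]
  expect_true(all(shortIds %in% failedIds(fits)))
})

test_that("linear fit equals the closed-form regression oracle", {
  set.seed(3)
  t_min <- seq(0, 100, 10)
  y <- 1.5 + 0.02 * t_min + rnorm(length(t_min), 0, 0.05)
  f <- fitCellGrowth(t_min, y, "linear")
  oracle <- lm(y ~ I(t_min / 60))
  expect_equal(f$y0, unname(coef(oracle)[1]), tolerance = 1e-12)
  expect_equal(f$k, unname(coef(oracle)[2]), tolerance = 1e-12)
})

test_that("population summary reproduces hand-computed moments and the band", {
  fits <- data.frame(cell_id = c("a", "b"), model = "exp",
                     y0 = c(1, 3), k = c(0.4, 0.6), rmse = 0,
                     n_points = 10, converged = TRUE)
  s <- populationGrowthSummary(fits)
  expect_equal(s$k_mean, 0.5)
  expect_equal(s$k_var, 0.02)
  expect_equal(s$y0_mean, 2)
  expect_equal(s$y0_var, 2)
  crv <- s$curve(c(0, 1))
  expect_equal(crv$mean, 2 * exp(0.5 * c(0, 1)))
  expect_equal(crv$upper, (2 + 2) * exp((0.5 + 0.02) * c(0, 1)))
  expect_equal(crv$lower, (2 - 2) * exp((0.5 - 0.02) * c(0, 1)))

  # identical fits: variances vanish and the band collapses onto the mean
  same <- data.frame(cell_id = c("a", "b"), model = "exp", y0 = 2, k = 0.5,
                     rmse = 0, n_points = 10, converged = TRUE)
  s2 <- populationGrowthSummary(same)
  crv2 <- s2$curve(seq(0, 2, 0.5))
  expect_equal(crv2$upper, crv2$mean)
  expect_equal(crv2$lower, crv2$mean)
  expect_error(populationGrowthSummary(same[1, ]), "at least 2")
})

test_that("colony counts match direct tallies", {
  one <- newCellList(list(makeRecord("a", frames = 1:6)), 5)
  expect_equal(colonyCounts(buildFLT(one))$population, rep(1, 6))

  cl <- newCellList(list(
    makeRecord("m", frames = 1:3),
    makeRecord("d1", mother = "m", frames = 4:6, l0 = 1),
    makeRecord("d2", mother = "m", frames = 4:6, l0 = 1)), 5)
  expect_equal(colonyCounts(buildFLT(cl))$population, c(1, 1, 1, 2, 2, 2))

  sim <- smallSim(seed = 5, nFrames = 45)
  cc <- colonyCounts(buildFLT(sim$cells))
  brute <- tabulate(unlist(lapply(sim$cells@cells, `[[`, "frames")),
                    nbins = nFrames(sim$cells))
  expect_equal(cc$population, brute)
})

test_that("Baranyi-Roberts parameters are recovered from noiseless curves", {
  t <- seq(0, 6, 0.1)
  y <- cellforest:::baranyiCurve(t, 0, 3, 2, 1)
  f <- fitBaranyi(t, y)
  expect_true(f$converged)
  expect_equal(f$log10_N0, 0, tolerance = 1e-3)
  expect_equal(f$log10_Nmax, 3, tolerance = 1e-3)
  expect_equal(f$mu_max, 2, tolerance = 1e-3)
  expect_equal(f$lambda, 1, tolerance = 1e-3)
})

test_that("the fitted curve honours the lag and stationary limits", {
  t <- seq(0, 8, 0.05)
  y <- cellforest:::baranyiCurve(t, 0.3, 2.7, 1.5, 0.8)
  f <- fitBaranyi(t, y)
  expect_equal(cellforest:::baranyiCurve(0, f$log10_N0, f$log10_Nmax,
                                         f$mu_max, f$lambda),
               f$log10_N0, tolerance = 1e-6)
  expect_equal(cellforest:::baranyiCurve(1e6, f$log10_N0, f$log10_Nmax,
                                         f$mu_max, f$lambda),
               f$log10_Nmax, tolerance = 1e-6)
})

test_that("non-growing and still-exponential colonies fail to fit, flagged", {
  t <- seq(0, 6, 0.1)
  f1 <- fitBaranyi(t, rep(0, length(t))) # single cell throughout
  expect_false(f1$converged)
  expect_match(f1$reason, "no growth")
  f2 <- fitBaranyi(t, 0.4 * t) # pure exponential, no plateau
  expect_false(f2$converged)
  expect_error(fitBaranyi(t[1:3], c(0, 1, 2)), "at least 5")
  expect_error(fitBaranyi(t, rep(-1, length(t))), "not valid")
})

test_that("per-colony fitting flags non-growing colonies like persisters", {
  # two growing colonies + one division-disabled single cell colony
  sim <- simulateMovie(simConfig(seed = 10, nProgenitors = 2, nFrames = 70,
                                 maxCells = 5000))
  still <- simulateMovie(simConfig(seed = 11, nProgenitors = 1, nFrames = 70,
                                   divisionLength = Inf))
  recs <- c(sim$cells@cells, lapply(still$cells@cells, function(r) {
    r$cell_id <- paste0("s", r$cell_id); r$colony_id <- "static"; r
  }))
  flt <- buildFLT(newCellList(recs, 5, nFrames = 70L))
  fits <- fitBaranyiForest(flt)
  expect_false(fits$converged[fits$colony == "static"])
})
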