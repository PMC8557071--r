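test_that("the same seed reproduces the movie exactly", {
  a <- simulateMovie(simConfig(seed = 31, nProgenitors = 2, nFrames = 40))
  b <- simulateMovie(simConfig(seed = 31, nProgenitors = 2, nFrames = 40))
  expect_equal(a$cells@cells, b$cells@cells)
  expect_equal(a$truth$cells, b$truth$cells)
  c <- simulateMovie(simConfig(seed = 32, nProgenitors = 2, nFrames = 40))
  expect_false(isTRUE(all.equal(a$cells@cells, c$cells@cells)))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(100)
  before <- runif(1)
  set.seed(100)
  invisible(simulateMovie(simConfig(seed = 1, nProgenitors = 1, nFrames = 10)))
  expect_equal(runif(1), before)
})

test_that("disabling division leaves one single-node branch per progenitor", {
  sim <- simulateMovie(simConfig(seed = 2, nProgenitors = 3, nFrames = 30,
                                 divisionLength = Inf))
  expect_length(sim$cells@cells, 3)
  flt <- buildFLT(sim$cells)
  fdt <- buildFDT(flt, minLife = 1)
  expect_equal(nrow(cellTable(fdt)), 3)
  expect_true(all(cellTable(fdt)$generation == 0))
  expect_true(all(cellTable(fdt)$lifespan_frames == 30))
})

test_that("deterministic doubling config divides on the closed-form schedule", {
  cfg <- simConfig(seed = 1, nProgenitors = 2, nFrames = 26, framePeriod = 5,
                   elongationRate = 2 * log(2), # one doubling per 30 min
                   divisionLength = 4,
                   birthLength = list(mean = 2, sd = 0),
                   asymmetrySd = 0, lengthNoiseSd = 0)
  sim <- simulateMovie(cfg)
  cc <- colonyCounts(buildFLT(sim$cells))
  # 4 synchronous doublings by 125 min: 16 cells per progenitor at the end
  expect_equal(cc$population[26], 2 * 16)
  expect_equal(cc$`1`[26], 16)
  # interdivision time matches ln(2 L_div / L_div) / k = 30 min exactly
  flt <- buildFLT(sim$cells)
  fdt <- buildFDT(flt, minLife = 1, requireComplete = TRUE)
  expect_true(all(cellTable(fdt)$division_duration %in% c(30, 35)))
})

test_that("degenerate configs are refused and the cell cap truncates", {
  expect_error(simConfig(divisionLength = 1, birthLength = list(mean = 2, sd = 0)),
               "degenerate")
  expect_warning(
    sim <- simulateMovie(simConfig(seed = 3, nProgenitors = 2, nFrames = 60,
                                   maxCells = 20)),
    "maxCells")
  expect_true(sim$truth$truncated)
  expect_lte(nrow(sim$truth$cells), 20)
})

test_that("ground truth is consistent with the emitted cell list", {
  sim <- smallSim(seed = 7, nFrames = 50)
  tc <- sim$truth$cells
  ids <- vapply(sim$cells@cells, `[[`, "", "cell_id")
  expect_setequal(tc$cell_id, ids)
  for (r in sim$cells@cells) {
    i <- match(r$cell_id, tc$cell_id)
    expect_equal(r$frames[1], tc$birth_frame[i])
    expect_equal(r$frames[length(r$frames)], tc$last_frame[i])
    expect_equal(r$mother_id, tc$mother_id[i])
  }
  ev <- sim$truth$events
  expect_equal(nrow(ev), sum(tc$divided))
  expect_true(all(ev$daughter1 %in% tc$cell_id))
})

test_that("fitted elongation rates recover the configured gamma distribution", {
  # noise-free with fine (2-min) sampling so essentially no lifespan is too
  # short to fit: the per-cell fits then return each cell's k exactly and the
  # estimated population distribution must match the generator's
  sim <- simulateMovie(simConfig(seed = 17, nProgenitors = 8, nFrames = 285,
                                 framePeriod = 2, lengthNoiseSd = 0,
                                 maxCells = 30000))
  flt <- buildFLT(sim$cells)
  fits <- fitGrowthForest(flt, "length", "exp")
  ks <- fits$k[fits$converged]
  expect_gt(length(ks), 2000)
  f <- fitDistribution(ks, "gamma")
  expect_equal(unname(f$params["shape"]), 3.026, tolerance = 0.05)
  expect_equal(unname(f$params["rate"]), 4.520, tolerance = 0.05)
})

test_that("generation-indexed division-length means fall as configured", {
  shrinking <- lapply(0:6, function(g) list(shape = 10.666, rate = 3.474 * 1.25^g))
  sim <- simulateMovie(simConfig(seed = 19, nProgenitors = 4, nFrames = 80,
                                 divisionLength = shrinking, maxCells = 20000))
  flt <- buildFLT(sim$cells)
  fdt <- computeLifeAttributes(flt, buildFDT(flt, minLife = 2,
                                             requireComplete = TRUE))
  gm <- tapply(cellTable(fdt)$length_division, cellTable(fdt)$generation, mean)
  gm <- gm[!is.na(gm)]
  big <- names(gm)[table(cellTable(fdt)$generation)[names(gm)] >= 10]
  expect_true(all(diff(gm[big]) < 0))
})

test_that("the expression marker anti-correlates with division length", {
  sim <- simulateMovie(simConfig(
    seed = 23, nProgenitors = 4, nFrames = 80, maxCells = 20000,
    expressionMarker = list(gainPerGen = 1, lengthSlope = 1, noiseSd = 0.3)))
  flt <- buildFLT(sim$cells)
  fdt <- computeLifeAttributes(flt, buildFDT(flt, minLife = 2))
  st <- plotScatter(fdt, "length_division", "marker_division")
  expect_lt(st$r, -0.2)
})

test_that("zero corruptions is the identity and repair closes the loop", {
  sim <- smallSim(seed = 25, nFrames = 50)
  same <- corruptTracking(sim$cells, 0)
  expect_equal(same$cells@cells, sim$cells@cells)
  expect_error(corruptTracking(sim$cells, 10000), "division event")
})
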