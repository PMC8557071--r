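test_that("forest plots are deterministic and respect the level conventions", {
  flt <- buildFLT(binaryMovie(gens = 2, span = 3))
  fdt <- buildFDT(flt, minLife = 1)
  p1 <- withr::local_tempfile(fileext = ".png")
  a <- plotForest(fdt, "generation", file = p1)
  expect_gt(file.size(p1), 0)
  b <- plotForest(fdt, "generation")
  expect_equal(a$layout, b$layout) # same forest, same layout
  # FLT rings are frames (+2), FDT rings are generations (+3)
  aF <- plotForest(flt, "colony")
  expect_equal(max(aF$layout$level), max(instanceTable(flt)$frame) + 2)
  expect_equal(max(a$layout$level), max(cellTable(fdt)$generation) + 3)
  # synthetic nodes carry no attribute value (uncoloured)
  expect_true(all(is.na(a$layout$value[a$layout$id == "master" |
                                         grepl("^colony:", a$layout$id)])))
  expect_error(plotForest(fdt, "ghost"), "unknown attribute")
})

test_that("the colony palette is stable across figures and runs", {
  pal1 <- cellforest:::.paletteFor(c("c1", "c2", "c3"))
  pal2 <- cellforest:::.paletteFor(c("c3", "c1", "c2", "c1"))
  expect_equal(pal1[sort(names(pal1))], pal2[sort(names(pal2))])
})

test_that("scatter statistics equal the closed-form least-squares oracle", {
  fdt <- local({
    flt <- buildFLT(binaryMovie(gens = 3, span = 3))
    computeLifeAttributes(flt, buildFDT(flt, minLife = 1))
  })
  n <- nrow(fdt@cells)
  set.seed(9)
  fdt@cells$u <- rnorm(n)
  fdt@cells$w <- 2 * fdt@cells$u + rnorm(n, 0, 0.3)
  st <- plotScatter(fdt, "u", "w")
  X <- cbind(1, fdt@cells$u)
  beta <- solve(crossprod(X), crossprod(X, fdt@cells$w))
  expect_equal(st$intercept, beta[1], tolerance = 1e-10)
  expect_equal(st$slope, beta[2], tolerance = 1e-10)
  expect_equal(st$r, cor(fdt@cells$u, fdt@cells$w))

  fdt@cells$v <- fdt@cells$u
  expect_equal(plotScatter(fdt, "u", "v")$r, 1)
  fdt@cells$nv <- -fdt@cells$u + 3
  expect_equal(plotScatter(fdt, "u", "nv")$r, -1)
})

test_that("density-binned scatter still returns the statistics and a file", {
  sim <- smallSim(seed = 10, nFrames = 50)
  flt <- buildFLT(sim$cells)
  fdt <- computeLifeAttributes(flt, buildFDT(flt, minLife = 2))
  p <- withr::local_tempfile(fileext = ".png")
  st <- plotScatter(fdt, "length_birth", "length_division",
                    densityBins = 80, diagonal = TRUE, file = p)
  expect_gt(file.size(p), 0)
  expect_true(all(c("r", "slope", "intercept", "r_squared", "n") %in% names(st)))
})

test_that("the regression plane is exact on exact data and null on noise", {
  fdt <- local({
    flt <- buildFLT(binaryMovie(gens = 3, span = 3))
    computeLifeAttributes(flt, buildFDT(flt, minLife = 1))
  })
  n <- nrow(fdt@cells)
  set.seed(4)
  fdt@cells$x1 <- rnorm(n); fdt@cells$x2 <- rnorm(n)
  fdt@cells$z <- 2 * fdt@cells$x1 + 3 * fdt@cells$x2 + 1
  st <- plotScatter3(fdt, "x1", "x2", "z")
  expect_equal(st$a, 2, tolerance = 1e-10)
  expect_equal(st$b, 3, tolerance = 1e-10)
  expect_equal(st$c, 1, tolerance = 1e-10)
  expect_equal(st$r_squared, 1)

  fdt@cells$zn <- rnorm(n)
  expect_lt(plotScatter3(fdt, "x1", "x2", "zn")$r_squared, 0.5)

  small <- fdt; small@cells <- small@cells[1:3, ]
  expect_error(plotScatter3(small, "x1", "x2", "z"), "insufficient")
  fdt@cells$x3 <- fdt@cells$x1 # collinear
  expect_warning(plotScatter3(fdt, "x1", "x3", "z"), "collinear")
})

test_that("group summaries share axes semantics and return per-group numbers", {
  sim <- smallSim(seed = 11, nFrames = 55)
  flt <- buildFLT(sim$cells)
  fdt <- computeLifeAttributes(flt, buildFDT(flt, minLife = 2))
  p <- withr::local_tempfile(fileext = ".png")
  gs <- plotGroupSummaries(fdt, "division_duration", kind = "violin", file = p)
  expect_gt(file.size(p), 0)
  oracle <- tapply(cellTable(fdt)$division_duration,
                   as.character(cellTable(fdt)$generation), mean)
  expect_equal(gs$mean, as.vector(oracle[gs$group]))
  # identical groups summarise identically
  n <- nrow(fdt@cells)
  dup <- rep(c("A", "B"), length.out = n)
  cst <- numeric(n)
  cst[dup == "A"] <- rep(c(1, 2, 3), length.out = sum(dup == "A"))
  cst[dup == "B"] <- rep(c(1, 2, 3), length.out = sum(dup == "B"))
  fdt@cells$dup <- dup; fdt@cells$cst <- cst
  gs2 <- plotGroupSummaries(fdt, "cst", by = "dup", kind = "box")
  expect_equal(gs2$mean[1], gs2$mean[2], tolerance = 0.1)
  expect_warning(plotGroupSummaries(
    local({ f <- fdt; f@cells$cst[f@cells$dup == "B"] <- NA; f }),
    "cst", by = "dup", kind = "box"), "empty group")
})

test_that("pdf overlay reports the fitted family per group", {
  sim <- simulateMovie(simConfig(seed = 12, nProgenitors = 4, nFrames = 70,
                                 maxCells = 10000))
  flt <- buildFLT(sim$cells)
  fdt <- computeLifeAttributes(flt, buildFDT(flt, minLife = 3))
  gs <- plotGroupSummaries(fdt, "length_division", by = "colony",
                           kind = "pdf_overlay")
  expect_true(any(!is.na(gs$family)))
  expect_true(all(gs$family[!is.na(gs$family)] %in%
                    c("normal", "gamma", "lognormal")))
})

test_that("figure export honours width, height and dpi exactly", {
  flt <- buildFLT(oneDivisionMovie())
  p <- withr::local_tempfile(fileext = ".png")
  plotForest(flt, "colony", file = p, width = 4, height = 3, dpi = 100)
  img <- png::readPNG(p)
  expect_equal(dim(img)[1:2], c(300, 400))
})
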