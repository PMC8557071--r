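test_that("a single 5-frame cell yields the 7-node chain forest", {
  cl <- newCellList(list(makeRecord("a", frames = 1:5)), 5)
  flt <- buildFLT(cl)
  expect_equal(nodeCount(flt), 7) # 5 instances + colony root + master root
  expect_equal(nrow(instanceTable(flt)), 5)
  expect_length(motherlessBranches(flt), 0)
  expect_equal(cellTable(flt)$generation, 0L)
})

test_that("division links mother's last instance to daughters' first", {
  flt <- buildFLT(oneDivisionMovie())
  cl <- cellTable(flt)
  expect_equal(cl$generation[cl$cell_id %in% c("d1", "d2")], c(1L, 1L))
  expect_equal(cl$last_frame[cl$cell_id == "m"], 3L)
  expect_equal(cl$birth_frame[cl$cell_id == "d1"], 4L)
  expect_equal(nodeCount(flt), 3 + 4 + 4 + 2)
})

test_that("tree levels follow the frame (FLT) and generation (FDT) conventions", {
  # independent oracle: shortest-path depth from the master root in the
  # exported graph must equal frame + 2 (FLT) / generation + 3 (FDT)
  sim <- smallSim(seed = 8, nFrames = 40)
  flt <- buildFLT(sim$cells)
  g <- cellforest:::.forestToIgraph(flt)
  d <- igraph::distances(g, v = "master", mode = "out")[1, ]
  it <- instanceTable(flt)
  keys <- paste0(it$cell_id, "@", it$frame)
  expect_equal(unname(d[keys]) + 1, it$frame + 2)

  fdt <- buildFDT(flt, minLife = 1)
  g2 <- cellforest:::.forestToIgraph(fdt)
  d2 <- igraph::distances(g2, v = "master", mode = "out")[1, ]
  cl <- cellTable(fdt)
  expect_equal(unname(d2[cl$cell_id]) + 1, cl$generation + 3)
})

test_that("FDT collapses lifespans and filters short and incomplete cells", {
  flt <- buildFLT(oneDivisionMovie())
  fdt <- buildFDT(flt, minLife = 1)
  expect_equal(nrow(cellTable(fdt)), 3)
  expect_equal(sum(cellTable(fdt)$lifespan_frames), nrow(instanceTable(flt)))

  # 3-frame mother excluded at minLife = 5; long-lived daughters are orphaned
  cl5 <- newCellList(list(
    makeRecord("m", frames = 1:3),
    makeRecord("d1", mother = "m", frames = 4:9, l0 = 1),
    makeRecord("d2", mother = "m", frames = 4:9, l0 = 1)), 5)
  fdt5 <- buildFDT(buildFLT(cl5), minLife = 5)
  ex <- excludedCells(fdt5)
  expect_equal(ex$reason[ex$cell_id == "m"], "short_life")
  expect_setequal(ex$reason[ex$cell_id %in% c("d1", "d2")],
                  c("orphaned", "orphaned"))
  expect_equal(nrow(cellTable(fdt5)), 0)

  # requireComplete drops cells with no observed division
  fdtc <- buildFDT(flt, minLife = 1, requireComplete = TRUE)
  expect_equal(cellTable(fdtc)$cell_id, "m")
})

test_that("a complete binary fixture to generation 2 has 7 cells per colony", {
  flt <- buildFLT(binaryMovie(gens = 2, span = 3, colonies = 2))
  fdt <- buildFDT(flt, minLife = 1)
  cl <- cellTable(fdt)
  expect_equal(nrow(cl), 14)
  expect_equal(as.integer(table(cl$colony)), c(7L, 7L))
  expect_equal(as.integer(table(cl$generation)), c(2L, 4L, 8L))
})

test_that("FLT node-count identity holds on seeded simulations", {
  for (s in 1:5) {
    sim <- smallSim(seed = s, nFrames = 45)
    flt <- buildFLT(sim$cells)
    lifespans <- sim$truth$cells$last_frame - sim$truth$cells$birth_frame + 1L
    nCol <- length(unique(sim$truth$cells$colony))
    expect_equal(nodeCount(flt), sum(lifespans) + nCol + 1L)
    expect_length(motherlessBranches(flt), 0)
    fdt <- buildFDT(flt, minLife = 1)
    expect_equal(nodeCount(fdt), nrow(cellTable(fdt)) + nCol + 1L)
    expect_equal(sum(cellTable(fdt)$lifespan_frames), nrow(instanceTable(flt)))
  }
})

test_that("extracting a leaf detaches exactly one node", {
  sim <- smallSim(seed = 2, nFrames = 40)
  flt <- buildFLT(sim$cells)
  cl <- cellTable(flt)
  leafCell <- cl$cell_id[!cl$cell_id %in% cl$mother_id][1]
  n0 <- nodeCount(flt)
  ex <- extractBranch(flt, leafCell, cl$last_frame[cl$cell_id == leafCell])
  expect_equal(nrow(ex$branch$instances), 1)
  expect_equal(nodeCount(ex$flt), n0 - 1)
  expect_length(motherlessBranches(ex$flt), 1)
})

test_that("extracting a daughter's first instance moves its whole subtree", {
  flt <- buildFLT(binaryMovie(gens = 2, span = 3))
  ex <- extractBranch(flt, "c1_r.1") # daughter at generation 1
  expect_setequal(ex$branch$cells$cell_id, c("c1_r.1", "c1_r.1.1", "c1_r.1.2"))
  expect_false(any(cellTable(ex$flt)$cell_id %in% ex$branch$cells$cell_id))
  expect_length(motherlessBranches(ex$flt), 1)
})

test_that("extract then add at the same site is the identity", {
  sim <- smallSim(seed = 4, nFrames = 45)
  flt <- buildFLT(sim$cells)
  cl <- cellTable(flt)
  # whole-cell extraction of a generation-1 cell
  target <- cl[cl$generation == 1, ][1, ]
  ex <- extractBranch(flt, target$cell_id)
  back <- addBranch(ex$flt, ex$branch, target$mother_id,
                    ex$branch$root_frame - 1L)
  expect_true(forestIdentical(flt, back))
  # mid-lifespan split and re-merge
  long <- cl[cl$last_frame - cl$birth_frame >= 3, ][1, ]
  f <- long$birth_frame + 2L
  ex2 <- extractBranch(flt, long$cell_id, f)
  back2 <- addBranch(ex2$flt, ex2$branch, long$cell_id, f - 1L)
  expect_true(forestIdentical(flt, back2))
})

test_that("addBranch rejects frame discontinuity and cycles", {
  flt <- buildFLT(binaryMovie(gens = 2, span = 3))
  ex <- extractBranch(flt, "c1_r.1")
  expect_error(addBranch(ex$flt, ex$branch, "c1_r", 1L), "discontinuity")
  # a target inside the branch is unattachable (already detached)
  expect_error(addBranch(ex$flt, ex$branch, "c1_r.1.1", 6L), "not attached")
})

test_that("a mid-life target refuses a foreign daughter branch", {
  cl <- newCellList(list(
    makeRecord("m", frames = 1:4),
    makeRecord("d1", mother = "m", frames = 5:8, l0 = 1),
    makeRecord("d2", mother = "m", frames = 5:8, l0 = 1),
    makeRecord("x", colony = "B", frames = 1:8)), 5)
  ex <- extractBranch(buildFLT(cl), "d1")
  # x persists past frame 4: a mother-daughter edge must leave a LAST instance
  expect_error(addBranch(ex$flt, ex$branch, "x", 4L), "last instance")
})

test_that("cellLifeTable reports the lifespan chronologically", {
  flt <- buildFLT(oneDivisionMovie())
  rep <- cellLifeTable(flt, "m")
  expect_equal(nrow(rep$table), 3)
  expect_equal(rep$table$event, c("birth", "", "division"))
  expect_setequal(rep$daughters, c("d1", "d2"))
  expect_true(is.na(rep$mother))
  expect_false(rep$motherless) # frame-1 progenitor, not an error signature
  expect_error(cellLifeTable(flt, "nope"), "unknown cell_id")
})

test_that("a merged lost division leaves a visible length drop in the life report", {
  sim <- smallSim(seed = 9, nFrames = 50)
  cor <- corruptTracking(sim$cells, 1, seed = 2, mode = "merge")
  flt <- buildFLT(cor$cells)
  rep <- cellLifeTable(flt, cor$log$mother[1])
  tab <- rep$table
  i <- match(cor$log$frame[1], tab$frame)
  # the mother swallowed one daughter: length roughly halves at the missed
  # division frame
  expect_lt(tab$length[i], 0.75 * tab$length[i - 1])
})
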