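# FLT / FDT construction and branch surgery.

.instancesFromRecords <- function(records) {
  rows <- lapply(records, function(r) {
    d <- data.frame(cell_id = r$cell_id, frame = r$frames,
                    stringsAsFactors = FALSE)
    for (a in names(r$numeric_attrs)) d[[a]] <- r$numeric_attrs[[a]]
    for (a in names(r$boolean_attrs)) d[[a]] <- r$boolean_attrs[[a]]
    if (!is.null(r$centroid)) { d$x <- r$centroid[, 1]; d$y <- r$centroid[, 2] }
    d
  })
  as.data.frame(data.table::rbindlist(rows, fill = TRUE))
}

.cellsFromRecords <- function(records) {
  data.frame(
    cell_id = vapply(records, `[[`, character(1), "cell_id"),
    colony_id = vapply(records, `[[`, character(1), "colony_id"),
    mother_id = vapply(records, `[[`, character(1), "mother_id"),
    birth_frame = vapply(records, function(r) r$frames[1], integer(1)),
    last_frame = vapply(records, function(r) r$frames[length(r$frames)], integer(1)),
    stringsAsFactors = FALSE)
}

# colony labels inherited from the progenitor; generation = divisions since it.
# Cells whose mother is absent from the table are treated as roots
# (generation 0, colony = own colony_id).
.relabelCells <- function(cells) {
  n <- nrow(cells)
  cells$colony <- cells$colony_id
  cells$generation <- rep(0L, n)
  if (n == 0) return(cells)
  ord <- order(cells$birth_frame)
  gen <- setNames(rep(0L, n), cells$cell_id)
  col <- setNames(cells$colony_id, cells$cell_id)
  for (i in ord) {
    m <- cells$mother_id[i]
    if (!is.na(m) && m %in% names(gen)) {
      id <- cells$cell_id[i]
      gen[[id]] <- gen[[m]] + 1L
      col[[id]] <- col[[m]]
    }
  }
  cells$generation <- unname(gen[cells$cell_id])
  cells$colony <- unname(col[cells$cell_id])
  cells
}

# all cells reachable from rootIds via mother links (roots included)
.descendantCells <- function(cells, rootIds) {
  out <- rootIds
  frontier <- rootIds
  while (length(frontier)) {
    nxt <- cells$cell_id[cells$mother_id %in% frontier & !is.na(cells$mother_id)]
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

.newBranch <- function(cells, instances, rootCell, rootFrame) {
  list(cells = cells, instances = instances,
       root_cell = rootCell, root_frame = as.integer(rootFrame),
       branch_id = paste0(rootCell, "@", rootFrame))
}

#' Build the forest of lineage trees (FLT) from a CellList
#'
#' Each cell instance (cell x frame) becomes a node; a synthetic master root
#' and one synthetic root per colony sit above the progenitors, so the node at
#' frame `f` is at tree level `f + 2`. Progenitors are cells without a mother
#' observed at frame 1. A cell that appears after frame 1 without a resolved
#' mother roots a *motherless branch*: its whole subtree is kept in a separate
#' store (see [motherlessBranches()], [addBranch()]) rather than in the main
#' forest — these are tracking-error or field-of-view-entry signatures.
#' Colony labels are inherited from the progenitor (so they survive colony
#' merges in the tracker's own labels); the generation label counts division
#' events on the path from the progenitor.
#'
#' @param cells a validated [CellList-class]
#' @return a [LineageForest-class]
#' @export
buildFLT <- function(cells) {
  stopifnot(is(cells, "CellList"))
  v <- .validCellList(cells)
  if (!isTRUE(v)) stop("invalid CellList: ", v[[1]])
  recs <- cells@cells
  ctab <- .cellsFromRecords(recs)
  itab <- .instancesFromRecords(recs)
  numA <- unique(unlist(lapply(recs, function(r) names(r$numeric_attrs))))
  booA <- unique(unlist(lapply(recs, function(r) names(r$boolean_attrs))))
  motherlessRoots <- ctab$cell_id[is.na(ctab$mother_id) & ctab$birth_frame > 1L]
  store <- list()
  if (length(motherlessRoots)) {
    for (rt in motherlessRoots) {
      ids <- .descendantCells(ctab, rt)
      bc <- .relabelCells(ctab[ctab$cell_id %in% ids, , drop = FALSE])
      bi <- itab[itab$cell_id %in% ids, , drop = FALSE]
      store[[length(store) + 1L]] <-
        .newBranch(bc, bi, rt, ctab$birth_frame[ctab$cell_id == rt])
    }
    detachedIds <- unlist(lapply(store, function(b) b$cells$cell_id))
    ctab <- ctab[!ctab$cell_id %in% detachedIds, , drop = FALSE]
    itab <- itab[!itab$cell_id %in% detachedIds, , drop = FALSE]
  }
  ctab <- .relabelCells(ctab)
  new("LineageForest",
      cells = ctab, instances = itab, motherless = store,
      framePeriod = cells@framePeriod, nFrames = cells@nFrames,
      attrNames = list(numeric = as.character(numA %||% character()),
                       boolean = as.character(booA %||% character())),
      provenance = if (nzchar(cells@provenance)) cells@provenance else "celllist")
}

#' Collapse an FLT into the forest of division trees (FDT)
#'
#' Every retained cell lifespan becomes one node at level `generation + 3`
#' (master root level 1, colony roots level 2, progenitors = generation 0 at
#' level 3). Cells living fewer than `minLife` frames are excluded; with
#' `requireComplete = TRUE`, cells with no recorded daughter (trajectories
#' terminating in a leaf, i.e. no observed division) are excluded as well.
#' Excluding a cell orphans its FDT descendants, which are dropped too and
#' reported in [excludedCells()].
#'
#' Life timing attributes are computed here: `birth_time = (birth_frame-1)*dt`,
#' `division_time_abs = (last_frame-1)*dt` and the interdivision time
#' `division_duration`, which under the default `"inclusive"` convention is
#' `lifespan_frames * dt` (durations of back-to-back generations then tile the
#' movie); `"exclusive"` uses `(lifespan_frames - 1) * dt`.
#'
#' @param flt a [LineageForest-class]
#' @param minLife minimum lifespan in frames (>= 1); shorter cells are dropped.
#' @param requireComplete drop cells with no observed division.
#' @param durationConvention `"inclusive"` (default) or `"exclusive"`.
#' @return a [DivisionForest-class]
#' @export
buildFDT <- function(flt, minLife = 5L, requireComplete = FALSE,
                     durationConvention = c("inclusive", "exclusive")) {
  stopifnot(is(flt, "LineageForest"))
  durationConvention <- match.arg(durationConvention)
  if (minLife < 1) stop("minLife must be >= 1 frame")
  cl <- flt@cells
  dt <- flt@framePeriod
  lifespan <- cl$last_frame - cl$birth_frame + 1L
  nDaughters <- tabulate(match(cl$mother_id, cl$cell_id), nbins = nrow(cl))
  reason <- rep(NA_character_, nrow(cl))
  reason[lifespan < minLife] <- "short_life"
  if (requireComplete) {
    inc <- nDaughters == 0L & is.na(reason)
    reason[inc] <- "incomplete"
  }
  # cascade: descendants of an excluded cell are orphaned
  excl <- cl$cell_id[!is.na(reason)]
  orphans <- setdiff(.descendantCells(cl, excl), excl)
  reason[cl$cell_id %in% orphans] <- "orphaned"
  keep <- is.na(reason)
  fdtCells <- cl[keep, c("cell_id", "colony_id", "mother_id", "birth_frame",
                         "last_frame", "colony", "generation")]
  ls <- lifespan[keep]
  fdtCells$lifespan_frames <- ls
  fdtCells$birth_time <- (fdtCells$birth_frame - 1) * dt
  fdtCells$division_time_abs <- (fdtCells$last_frame - 1) * dt
  fdtCells$division_duration <-
    if (durationConvention == "inclusive") ls * dt else (ls - 1) * dt
  fdtCells$n_daughters <- nDaughters[keep]
  rownames(fdtCells) <- NULL
  new("DivisionForest",
      cells = fdtCells, framePeriod = dt, nFrames = flt@nFrames,
      filters = list(minLife = as.integer(minLife),
                     requireComplete = requireComplete,
                     durationConvention = durationConvention),
      excluded = data.frame(cell_id = cl$cell_id[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE),
      provenance = flt@provenance)
}

#' Detach the subtree rooted at an instance node
#'
#' The node `(cellId, frame)` and everything below it — later instances of the
#' same cell and all descendant cells — are detached into the motherless store
#' and also returned. Detaching mid-lifespan splits the cell: instances before
#' `frame` stay in the forest, the rest root the branch. [addBranch()] at the
#' same site restores the original forest exactly.
#'
#' @param flt a [LineageForest-class]
#' @param cellId cell whose instance roots the extraction.
#' @param frame frame of the root instance; default the cell's birth frame
#'   (whole-cell subtree).
#' @return list with elements `flt` (forest without the subtree) and `branch`.
#' @export
extractBranch <- function(flt, cellId, frame = NULL) {
  stopifnot(is(flt, "LineageForest"))
  cl <- flt@cells
  i <- match(cellId, cl$cell_id)
  if (is.na(i)) stop("no attached cell '", cellId, "' in forest")
  if (is.null(frame)) frame <- cl$birth_frame[i]
  frame <- as.integer(frame)
  if (frame < cl$birth_frame[i] || frame > cl$last_frame[i]) {
    stop("cell '", cellId, "' has no instance at frame ", frame)
  }
  desc <- setdiff(.descendantCells(cl, cellId), cellId)
  it <- flt@instances
  if (frame == cl$birth_frame[i]) {
    ids <- c(cellId, desc)
    bCells <- cl[cl$cell_id %in% ids, , drop = FALSE]
    bCells$mother_id[bCells$cell_id == cellId] <- NA_character_
    bInst <- it[it$cell_id %in% ids, , drop = FALSE]
    cl <- cl[!cl$cell_id %in% ids, , drop = FALSE]
    it <- it[!it$cell_id %in% ids, , drop = FALSE]
  } else {
    # split the lifespan at `frame`
    bCells <- cl[cl$cell_id %in% c(cellId, desc), , drop = FALSE]
    j <- bCells$cell_id == cellId
    bCells$mother_id[j] <- NA_character_
    bCells$birth_frame[j] <- frame
    bInst <- it[it$cell_id %in% desc |
                  (it$cell_id == cellId & it$frame >= frame), , drop = FALSE]
    cl$last_frame[i] <- frame - 1L
    cl <- cl[!cl$cell_id %in% desc, , drop = FALSE]
    it <- it[!(it$cell_id %in% desc |
                 (it$cell_id == cellId & it$frame >= frame)), , drop = FALSE]
  }
  bCells <- .relabelCells(bCells)
  branch <- .newBranch(bCells, bInst, cellId, frame)
  flt@cells <- .relabelCells(cl)
  flt@instances <- it
  flt@motherless <- c(flt@motherless, list(branch))
  list(flt = flt, branch = branch)
}

#' Glue a detached branch under an instance node
#'
#' Attaches `branch` as a child of the instance `(targetCell, targetFrame)`.
#' The branch root's frame must be `targetFrame + 1` (frame continuity). If
#' the branch root is a later fragment of the target cell itself, the split
#' lifespan is re-merged; otherwise the branch root becomes a daughter of the
#' target cell, and the target instance must be the cell's last observed
#' instance (a mother-daughter edge runs from a mother's last instance). A
#' target that thereby reaches two or more children records a recovered
#' division event. Generation and colony labels of the re-attached subtree are
#' recomputed.
#'
#' @param flt a [LineageForest-class]
#' @param branch a branch, from [extractBranch()] or [motherlessBranches()].
#' @param targetCell,targetFrame the attachment instance.
#' @return the updated [LineageForest-class]
#' @export
addBranch <- function(flt, branch, targetCell, targetFrame) {
  stopifnot(is(flt, "LineageForest"))
  targetFrame <- as.integer(targetFrame)
  cl <- flt@cells
  i <- match(targetCell, cl$cell_id)
  if (is.na(i)) stop("target cell '", targetCell, "' is not attached")
  if (targetFrame < cl$birth_frame[i] || targetFrame > cl$last_frame[i]) {
    stop("target cell '", targetCell, "' has no instance at frame ", targetFrame)
  }
  if (branch$root_frame != targetFrame + 1L) {
    stop("frame discontinuity: branch root frame ", branch$root_frame,
         " != target frame + 1 (", targetFrame + 1L, ")")
  }
  inBranch <- targetCell %in% branch$cells$cell_id &&
    !(branch$root_cell == targetCell) # root can be the split-off same cell
  if (inBranch) stop("cycle: target instance lies inside the branch")
  merging <- identical(branch$root_cell, targetCell)
  if (merging) {
    if (cl$last_frame[i] != targetFrame) {
      stop("cannot re-merge: target frame ", targetFrame,
           " is not the cell's current last frame (", cl$last_frame[i], ")")
    }
    j <- branch$cells$cell_id == targetCell
    cl$last_frame[i] <- branch$cells$last_frame[j]
    addC <- branch$cells[!j, , drop = FALSE]
  } else {
    if (cl$last_frame[i] != targetFrame) {
      stop("target instance must be the mother's last instance (cell '",
           targetCell, "' persists past frame ", targetFrame,
           "); extract the later part first")
    }
    addC <- branch$cells
    addC$mother_id[addC$cell_id == branch$root_cell] <- targetCell
  }
  clash <- intersect(addC$cell_id, cl$cell_id)
  if (length(clash)) stop("cell id(s) already attached: ",
                          paste(clash, collapse = ", "))
  cl <- rbind(cl[, c("cell_id", "colony_id", "mother_id", "birth_frame",
                     "last_frame")],
              addC[, c("cell_id", "colony_id", "mother_id", "birth_frame",
                       "last_frame")])
  flt@cells <- .relabelCells(cl)
  flt@instances <- as.data.frame(
    data.table::rbindlist(list(flt@instances, branch$instances), fill = TRUE))
  keep <- vapply(flt@motherless, function(b) !identical(b$branch_id, branch$branch_id),
                 logical(1))
  flt@motherless <- flt@motherless[keep]
  validObject(flt)
  flt
}

#' Chronological life report for one cell
#'
#' Per-frame listing of a cell's instances and attribute values with birth and
#' division frames marked, plus its mother, daughters and — when centroids are
#' present — the nearest neighbouring cell per frame. Supports visual
#' inspection of suspected tracking errors without the raw images.
#'
#' @param flt a [LineageForest-class]
#' @param cellId the cell to report.
#' @return an object of class `cellLife`: list with `cell_id`, `mother`
#'   (NA and flagged if motherless), `daughters`, `motherless`, `generation`,
#'   `colony` and `table` (one row per frame, `event` column marks
#'   birth/division).
#' @export
cellLifeTable <- function(flt, cellId) {
  stopifnot(is(flt, "LineageForest"))
  cl <- flt@cells
  it <- flt@instances
  inStore <- FALSE
  if (!cellId %in% cl$cell_id) {
    for (b in flt@motherless) {
      if (cellId %in% b$cells$cell_id) {
        cl <- b$cells; it <- b$instances; inStore <- TRUE; break
      }
    }
  }
  i <- match(cellId, cl$cell_id)
  if (is.na(i)) stop("unknown cell_id: ", cellId)
  rows <- it[it$cell_id == cellId, , drop = FALSE]
  rows <- rows[order(rows$frame), , drop = FALSE]
  rows$age_min <- (rows$frame - cl$birth_frame[i]) * flt@framePeriod
  daughters <- cl$cell_id[!is.na(cl$mother_id) & cl$mother_id == cellId]
  rows$event <- ""
  rows$event[1] <- "birth"
  if (length(daughters)) rows$event[nrow(rows)] <- "division"
  if (all(c("x", "y") %in% names(it))) {
    nn <- vapply(seq_len(nrow(rows)), function(k) {
      f <- rows$frame[k]
      oth <- it[it$frame == f & it$cell_id != cellId, , drop = FALSE]
      if (!nrow(oth)) return(NA_character_)
      d2 <- (oth$x - rows$x[k])^2 + (oth$y - rows$y[k])^2
      oth$cell_id[which.min(d2)]
    }, character(1))
    rows$nearest_cell <- nn
  }
  rownames(rows) <- NULL
  structure(list(cell_id = cellId,
                 mother = cl$mother_id[i],
                 motherless = is.na(cl$mother_id[i]) && cl$birth_frame[i] > 1L,
                 in_store = inStore,
                 daughters = daughters,
                 generation = cl$generation[i],
                 colony = cl$colony[i],
                 table = rows),
            class = "cellLife")
}

#' @export
print.cellLife <- function(x, ...) {
  cat("Cell", x$cell_id, "| colony", x$colony, "| generation", x$generation, "\n")
  cat("  mother:", if (is.na(x$mother)) "<absent>" else x$mother,
      if (x$motherless) "(MOTHERLESS)" else "", "\n")
  cat("  daughters:", if (length(x$daughters)) paste(x$daughters, collapse = ", ")
      else "<none>", "\n")
  if (x$in_store) cat("  NOTE: cell currently lives in the motherless store\n")
  print(x$table, ...)
  invisible(x)
}

#' Value-identity of two forests (structure and attributes)
#'
#' Canonicalises both forests (rows sorted by cell and frame, columns
#' ordered, motherless branches sorted by root) and compares all structural
#' fields, labels and attribute values. Used to verify that surgery round
#' trips and tracking-error repair restore the original forest exactly.
#'
#' @param a,b [LineageForest-class] objects
#' @return TRUE or FALSE
#' @export
forestIdentical <- function(a, b) {
  canonC <- function(d) {
    d <- d[order(d$cell_id), sort(names(d)), drop = FALSE]
    rownames(d) <- NULL
    d
  }
  canonI <- function(d) {
    d <- d[order(d$cell_id, d$frame), sort(names(d)), drop = FALSE]
    rownames(d) <- NULL
    d
  }
  eq <- function(x, y) isTRUE(all.equal(x, y, check.attributes = FALSE))
  if (!eq(canonC(a@cells), canonC(b@cells))) return(FALSE)
  if (!eq(canonI(a@instances), canonI(b@instances))) return(FALSE)
  if (length(a@motherless) != length(b@motherless)) return(FALSE)
  key <- function(s) order(vapply(s, `[[`, character(1), "branch_id"))
  sa <- a@motherless[key(a@motherless)]
  sb <- b@motherless[key(b@motherless)]
  for (k in seq_along(sa)) {
    if (!eq(canonC(sa[[k]]$cells), canonC(sb[[k]]$cells))) return(FALSE)
    if (!eq(canonI(sa[[k]]$instances), canonI(sb[[k]]$instances))) return(FALSE)
  }
  TRUE
}

#' Export a forest as GraphML or an edge-list CSV
#'
#' Materialises the synthetic master and colony roots and writes the full
#' graph; instance nodes are keyed `cell@frame`, FDT nodes by `cell_id`.
#'
#' @param forest a [LineageForest-class] or [DivisionForest-class]
#' @param path output file
#' @param format `"graphml"` or `"csv"` (edge list)
#' @return invisibly, `path`
#' @export
exportForest <- function(forest, path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  g <- .forestToIgraph(forest)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    write.csv(el, path, row.names = FALSE)
  }
  invisible(path)
}

.forestToIgraph <- function(forest) {
  if (is(forest, "LineageForest")) {
    cl <- forest@cells; it <- forest@instances
    colonies <- unique(cl$colony)
    vid <- c("master", paste0("colony:", colonies),
             paste0(it$cell_id, "@", it$frame))
    vdf <- data.frame(name = vid, stringsAsFactors = FALSE)
    vdf$synthetic <- c(TRUE, rep(TRUE, length(colonies)), rep(FALSE, nrow(it)))
    vdf$cell_id <- c(NA, rep(NA, length(colonies)), it$cell_id)
    vdf$frame <- c(NA, rep(NA, length(colonies)), it$frame)
    m <- match(it$cell_id, cl$cell_id)
    vdf$colony <- c(NA, colonies, cl$colony[m])
    vdf$generation <- c(NA, rep(NA, length(colonies)), cl$generation[m])
    for (a in c(forest@attrNames$numeric, forest@attrNames$boolean)) {
      if (a %in% names(it)) vdf[[a]] <- c(NA, rep(NA, length(colonies)), it[[a]])
    }
    edges <- character(0)
    addE <- function(e, from, to) c(e, rbind(from, to))
    e <- c()
    e <- addE(e, "master", paste0("colony:", colonies))
    prog <- cl[is.na(cl$mother_id), , drop = FALSE]
    if (nrow(prog)) {
      e <- addE(e, paste0("colony:", prog$colony),
                paste0(prog$cell_id, "@", prog$birth_frame))
    }
    # same-cell persistence edges
    it2 <- it[order(it$cell_id, it$frame), c("cell_id", "frame")]
    same <- it2$cell_id[-1] == it2$cell_id[-nrow(it2)] &
      it2$frame[-1] == it2$frame[-nrow(it2)] + 1L
    if (any(same)) {
      from <- paste0(it2$cell_id[-nrow(it2)], "@", it2$frame[-nrow(it2)])[same]
      to <- paste0(it2$cell_id[-1], "@", it2$frame[-1])[same]
      e <- addE(e, from, to)
    }
    dau <- cl[!is.na(cl$mother_id), , drop = FALSE]
    if (nrow(dau)) {
      mi <- match(dau$mother_id, cl$cell_id)
      e <- addE(e, paste0(dau$mother_id, "@", cl$last_frame[mi]),
                paste0(dau$cell_id, "@", dau$birth_frame))
    }
    igraph::graph_from_data_frame(
      data.frame(from = e[c(TRUE, FALSE)], to = e[c(FALSE, TRUE)]),
      directed = TRUE, vertices = vdf)
  } else {
    cl <- forest@cells
    colonies <- unique(cl$colony)
    vdf <- data.frame(name = c("master", paste0("colony:", colonies), cl$cell_id),
                      stringsAsFactors = FALSE)
    vdf$synthetic <- c(TRUE, rep(TRUE, length(colonies)), rep(FALSE, nrow(cl)))
    for (a in setdiff(names(cl), c("cell_id"))) {
      if (is.numeric(cl[[a]]) || is.logical(cl[[a]]) || is.character(cl[[a]])) {
        vdf[[a]] <- c(NA, rep(NA, length(colonies)), cl[[a]])
      }
    }
    roots <- cl[is.na(cl$mother_id) | !(cl$mother_id %in% cl$cell_id), , drop = FALSE]
    dau <- cl[!is.na(cl$mother_id) & cl$mother_id %in% cl$cell_id, , drop = FALSE]
    ed <- rbind(
      data.frame(from = "master", to = paste0("colony:", colonies)),
      data.frame(from = paste0("colony:", roots$colony), to = roots$cell_id),
      data.frame(from = dau$mother_id, to = dau$cell_id))
    igraph::graph_from_data_frame(ed, directed = TRUE, vertices = vdf)
  }
}
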