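#' @import methods
#' @importFrom stats sd var coef lm cor dnorm dlnorm dgamma rnorm rgamma rlnorm runif setNames aggregate quantile median optimize
#' @importFrom utils head tail read.csv write.csv
#' @importFrom data.table as.data.table rbindlist setorder
NULL

.datatable.aware <- TRUE

#' CellList: validated cell-tracking output of a single-cell movie
#'
#' A `CellList` holds one record per tracked cell: its colony, its mother (if
#' resolved by the tracker), the contiguous 1-based frame range over which it
#' was observed, and per-frame numeric/boolean attribute series (length in um,
#' area, fluorescence, ...). It is the canonical interchange object between
#' tracker output and the lineage-forest representations.
#'
#' Invariants enforced by the validity method:
#' * `cell_id` values are unique;
#' * every cell's frames are strictly increasing with step 1 and lie in
#'   `[1, nFrames]`;
#' * every attribute series has one value per frame;
#' * a non-missing `mother_id` names a record whose last frame is the
#'   daughter's first frame minus one. A missing mother is legal (progenitor
#'   at frame 1, or an unresolved link that becomes a motherless branch).
#'
#' @slot cells list of cell records (named lists with elements `cell_id`,
#'   `colony_id`, `mother_id`, `frames`, `numeric_attrs`, `boolean_attrs`,
#'   `centroid`).
#' @slot framePeriod minutes between consecutive frames (Delta-t).
#' @slot nFrames number of frames in the movie.
#' @slot provenance free-text source tag.
#' @export
setClass("CellList",
  representation(
    cells = "list",
    framePeriod = "numeric",
    nFrames = "integer",
    provenance = "character"
  ),
  prototype(cells = list(), framePeriod = 1, nFrames = 1L, provenance = "")
)

.validCellList <- function(object) {
  msgs <- character()
  if (length(object@framePeriod) != 1 || !is.finite(object@framePeriod) ||
      object@framePeriod <= 0) {
    msgs <- c(msgs, "frame_period must be a single positive number")
  }
  if (length(object@nFrames) != 1 || is.na(object@nFrames) || object@nFrames < 1) {
    msgs <- c(msgs, "n_frames must be a positive integer")
  }
  ids <- vapply(object@cells, function(r) as.character(r$cell_id %||% NA_character_),
                character(1))
  if (anyNA(ids) || any(!nzchar(ids))) {
    msgs <- c(msgs, "every cell record needs a non-empty cell_id")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    msgs <- c(msgs, paste0("duplicate cell_id: ", paste(dup, collapse = ", ")))
  }
  lastFrame <- setNames(rep(NA_integer_, length(ids)), ids)
  for (r in object@cells) {
    fr <- r$frames
    if (length(fr)) lastFrame[[as.character(r$cell_id)]] <- fr[length(fr)]
  }
  for (r in object@cells) {
    id <- as.character(r$cell_id)
    fr <- r$frames
    if (!length(fr)) {
      msgs <- c(msgs, paste0("cell ", id, ": empty frame list"))
      next
    }
    if (any(diff(fr) != 1L)) {
      msgs <- c(msgs, paste0("cell ", id, ": non-contiguous frames"))
    }
    if (fr[1] < 1L || fr[length(fr)] > object@nFrames) {
      msgs <- c(msgs, paste0("cell ", id, ": frames outside [1, n_frames]"))
    }
    for (a in names(r$numeric_attrs)) {
      if (length(r$numeric_attrs[[a]]) != length(fr)) {
        msgs <- c(msgs, paste0("cell ", id, ": numeric attribute '", a,
                               "' length != lifespan"))
      }
    }
    for (a in names(r$boolean_attrs)) {
      if (length(r$boolean_attrs[[a]]) != length(fr)) {
        msgs <- c(msgs, paste0("cell ", id, ": boolean attribute '", a,
                               "' length != lifespan"))
      }
    }
    if (!is.null(r$centroid) && nrow(r$centroid) != length(fr)) {
      msgs <- c(msgs, paste0("cell ", id, ": centroid rows != lifespan"))
    }
    mid <- r$mother_id
    if (!is.null(mid) && !is.na(mid)) {
      mid <- as.character(mid)
      if (!mid %in% ids) {
        msgs <- c(msgs, paste0("cell ", id, ": mother_id '", mid,
                               "' does not name a record"))
      } else if (!is.na(lastFrame[[mid]]) && lastFrame[[mid]] != fr[1] - 1L) {
        msgs <- c(msgs, paste0("cell ", id, ": mother '", mid,
                               "' last frame ", lastFrame[[mid]],
                               " != first frame - 1 (", fr[1] - 1L, ")"))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("CellList", .validCellList)

#' LineageForest: forest of lineage trees (FLT)
#'
#' Per-frame representation of a single-cell movie: one node per cell
#' *instance* (a cell observed at one frame). A synthetic master root (level 1)
#' has one synthetic root per colony (level 2) as children; the node at frame
#' `f` sits at tree level `f + 2`. Edges connect consecutive instances of the
#' same cell and a mother's last instance to each daughter's first instance.
#' Branches whose root cell appears after frame 1 without a resolved mother
#' are kept apart in the motherless store so they can be inspected and glued
#' back with [addBranch()].
#'
#' Synthetic nodes carry no attributes and are materialised only on export and
#' plotting; internally the forest is a pair of tables (per-cell, per-instance).
#'
#' @slot cells data.frame, one row per attached cell: `cell_id`, `colony_id`
#'   (as reported by the tracker), `mother_id`, `birth_frame`, `last_frame`,
#'   `colony` (inherited from the progenitor, stable under colony merges),
#'   `generation` (divisions since the progenitor).
#' @slot instances data.frame, one row per attached cell instance: `cell_id`,
#'   `frame`, plus one column per attribute (and `x`,`y` centroids when given).
#' @slot motherless list of detached branches (each a list with `cells`,
#'   `instances`, `root_cell`, `root_frame`, `branch_id`).
#' @slot framePeriod,nFrames movie timing.
#' @slot attrNames list(numeric=, boolean=) attribute name registry.
#' @slot provenance token identifying the source movie; selections inherit it.
#' @export
setClass("LineageForest",
  representation(
    cells = "data.frame",
    instances = "data.frame",
    motherless = "list",
    framePeriod = "numeric",
    nFrames = "integer",
    attrNames = "list",
    provenance = "character"
  )
)

.validLineageForest <- function(object) {
  msgs <- character()
  cl <- object@cells
  needC <- c("cell_id", "colony_id", "mother_id", "birth_frame", "last_frame",
             "colony", "generation")
  if (!all(needC %in% names(cl))) {
    return(paste("cells table missing columns:",
                 paste(setdiff(needC, names(cl)), collapse = ", ")))
  }
  if (!all(c("cell_id", "frame") %in% names(object@instances))) {
    return("instances table missing cell_id/frame")
  }
  if (anyDuplicated(cl$cell_id)) msgs <- c(msgs, "duplicate cell_id in forest")
  # every attached non-progenitor must have its mother attached
  att <- cl$cell_id
  bad <- !is.na(cl$mother_id) & !(cl$mother_id %in% att)
  if (any(bad)) {
    msgs <- c(msgs, paste0("attached cell(s) with detached mother: ",
                           paste(cl$cell_id[bad], collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("LineageForest", .validLineageForest)

#' DivisionForest: forest of division trees (FDT)
#'
#' The FLT with every retained cell lifespan collapsed to a single node.
#' Level `n >= 3` corresponds to generation `n - 3` (generations count from
#' 0 at the progenitors). Nodes carry life attributes: birth/division times,
#' lifespan, interdivision time, per-attribute summary statistics, and any
#' per-cell growth-fit parameters merged in.
#'
#' @slot cells data.frame, one row per retained cell with life attributes.
#' @slot framePeriod,nFrames movie timing.
#' @slot filters list recording `minLife` and `requireComplete` used to build.
#' @slot excluded data.frame reporting excluded cells and the reason
#'   (short life, incomplete, orphaned by an excluded ancestor).
#' @slot provenance token inherited from the source forest.
#' @export
setClass("DivisionForest",
  representation(
    cells = "data.frame",
    framePeriod = "numeric",
    nFrames = "integer",
    filters = "list",
    excluded = "data.frame",
    provenance = "character"
  )
)

setValidity("DivisionForest", function(object) {
  need <- c("cell_id", "colony", "generation", "mother_id",
            "lifespan_frames", "birth_time", "division_time_abs",
            "division_duration")
  if (!all(need %in% names(object@cells))) {
    return(paste("cells table missing columns:",
                 paste(setdiff(need, names(object@cells)), collapse = ", ")))
  }
  if (any(object@cells$lifespan_frames < 1)) return("lifespan_frames must be >= 1")
  TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- accessors ----

#' @export
setGeneric("framePeriod", function(x) standardGeneric("framePeriod"))
#' Frame period (minutes per frame)
#' @param x a CellList, LineageForest or DivisionForest
#' @export
setMethod("framePeriod", "CellList", function(x) x@framePeriod)
#' @rdname framePeriod-CellList-method
#' @export
setMethod("framePeriod", "LineageForest", function(x) x@framePeriod)
#' @rdname framePeriod-CellList-method
#' @export
setMethod("framePeriod", "DivisionForest", function(x) x@framePeriod)

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' Number of movie frames
#' @param x a CellList, LineageForest or DivisionForest
#' @export
setMethod("nFrames", "CellList", function(x) x@nFrames)
#' @rdname nFrames-CellList-method
#' @export
setMethod("nFrames", "LineageForest", function(x) x@nFrames)
#' @rdname nFrames-CellList-method
#' @export
setMethod("nFrames", "DivisionForest", function(x) x@nFrames)

#' Per-cell table of a forest
#'
#' For a [LineageForest-class] the attached cells with colony/generation
#' labels; for a [DivisionForest-class] the life-attribute table (one row per
#' retained cell).
#' @param x a forest
#' @return data.frame
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))
#' @rdname cellTable
#' @export
setMethod("cellTable", "LineageForest", function(x) x@cells)
#' @rdname cellTable
#' @export
setMethod("cellTable", "DivisionForest", function(x) x@cells)

#' Per-instance table of an FLT (one row per cell per frame)
#' @param x a LineageForest
#' @return data.frame with cell_id, frame and attribute columns
#' @export
setGeneric("instanceTable", function(x) standardGeneric("instanceTable"))
#' @rdname instanceTable
#' @export
setMethod("instanceTable", "LineageForest", function(x) x@instances)

#' Motherless branch store of an FLT
#' @param x a LineageForest
#' @return list of detached branches
#' @export
setGeneric("motherlessBranches", function(x) standardGeneric("motherlessBranches"))
#' @rdname motherlessBranches
#' @export
setMethod("motherlessBranches", "LineageForest", function(x) x@motherless)

#' Total node count of a forest, synthetic roots included
#'
#' For the FLT this is the number of attached cell instances plus one synthetic
#' root per colony plus the master root; for the FDT, retained cells plus
#' colony roots plus the master root. Instances held in the motherless store
#' are not part of the attached forest and are not counted.
#' @param x a forest
#' @return integer
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))
#' @rdname nodeCount
#' @export
setMethod("nodeCount", "LineageForest", function(x) {
  nrow(x@instances) + length(unique(x@cells$colony)) + 1L
})
#' @rdname nodeCount
#' @export
setMethod("nodeCount", "DivisionForest", function(x) {
  nrow(x@cells) + length(unique(x@cells$colony)) + 1L
})

## ---- show ----

setMethod("show", "CellList", function(object) {
  cat("CellList:", length(object@cells), "cells,",
      object@nFrames, "frames @", object@framePeriod, "min/frame\n")
  if (nzchar(object@provenance)) cat("  provenance:", object@provenance, "\n")
  nm <- unique(unlist(lapply(object@cells, function(r) names(r$numeric_attrs))))
  if (length(nm)) cat("  numeric attributes:", paste(nm, collapse = ", "), "\n")
  bm <- unique(unlist(lapply(object@cells, function(r) names(r$boolean_attrs))))
  if (length(bm)) cat("  boolean attributes:", paste(bm, collapse = ", "), "\n")
})

setMethod("show", "LineageForest", function(object) {
  cat("LineageForest (FLT):", nrow(object@cells), "cells /",
      nrow(object@instances), "instances in",
      length(unique(object@cells$colony)), "colonies;",
      "node count", nodeCount(object), "\n")
  cat("  frames:", object@nFrames, "@", object@framePeriod, "min;",
      "generations 0..", suppressWarnings(max(object@cells$generation, 0)), "\n")
  if (length(object@motherless)) {
    cat("  motherless store:", length(object@motherless), "branch(es)\n")
  }
})

setMethod("show", "DivisionForest", function(object) {
  cat("DivisionForest (FDT):", nrow(object@cells), "cells in",
      length(unique(object@cells$colony)), "colonies;",
      "generations 0..", suppressWarnings(max(object@cells$generation, 0)), "\n")
  cat("  filters: minLife =", object@filters$minLife %||% 1,
      "frames; requireComplete =", isTRUE(object@filters$requireComplete), "\n")
  if (nrow(object@excluded)) {
    cat("  excluded:", nrow(object@excluded), "cell(s) (see excludedCells())\n")
  }
})

#' Cells excluded when building the FDT, with reasons
#' @param fdt a DivisionForest
#' @return data.frame with cell_id and reason
#' @export
excludedCells <- function(fdt) {
  stopifnot(is(fdt, "DivisionForest"))
  fdt@excluded
}
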