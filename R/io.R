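# Canonical cell-list interchange: JSON schema + long-format CSV adapter.
#
# JSON (UTF-8): {"frame_period_minutes": num, "n_frames": int, "cells": [
#   {"cell_id": str, "colony_id": str, "mother_id": str|null,
#    "frames": [int...], "numeric_attrs": {name: [num...]},
#    "boolean_attrs": {name: [bool...]}, "centroid": [[x,y]...]|null} ]}

#' Construct a CellList from records
#'
#' Low-level constructor; validates all invariants (contiguous frames,
#' attribute lengths, mother-frame adjacency, unique ids).
#'
#' @param cells list of cell records (see [CellList-class]).
#' @param framePeriod minutes per frame.
#' @param nFrames number of frames; defaults to the largest frame seen.
#' @param provenance free-text source tag.
#' @return a validated [CellList-class]
#' @export
newCellList <- function(cells, framePeriod, nFrames = NULL, provenance = "") {
  cells <- lapply(cells, .normalizeRecord)
  if (is.null(nFrames)) {
    nFrames <- if (length(cells)) {
      max(vapply(cells, function(r) max(r$frames), numeric(1)))
    } else 1
  }
  new("CellList", cells = cells, framePeriod = as.numeric(framePeriod),
      nFrames = as.integer(nFrames), provenance = as.character(provenance))
}

.normalizeRecord <- function(r) {
  r$cell_id <- as.character(r$cell_id)
  r$colony_id <- as.character(r$colony_id %||% NA_character_)
  m <- r$mother_id
  r$mother_id <- if (is.null(m) || length(m) == 0 || is.na(m)) NA_character_ else as.character(m)
  r$frames <- as.integer(r$frames)
  normAttrs <- function(l, f) {
    l <- lapply(l %||% list(), f)
    names(l) <- as.character(names(l) %||% character(0))
    l
  }
  r$numeric_attrs <- normAttrs(r$numeric_attrs, as.numeric)
  r$boolean_attrs <- normAttrs(r$boolean_attrs, as.logical)
  if (!is.null(r$centroid)) {
    r$centroid <- matrix(as.numeric(unlist(r$centroid)), ncol = 2, byrow = !is.matrix(r$centroid))
    colnames(r$centroid) <- c("x", "y")
  } else {
    r$centroid <- NULL
  }
  r[c("cell_id", "colony_id", "mother_id", "frames",
      "numeric_attrs", "boolean_attrs", "centroid")]
}

#' Read a canonical cell-list JSON file
#'
#' @param path path to a `.json` file following the canonical schema.
#' @return a validated [CellList-class]; schema violations raise an error
#'   naming the offending cell and field.
#' @export
readCellList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE),
    error = function(e) stop("cell-list JSON parse failure: ", conditionMessage(e))
  )
  for (f in c("frame_period_minutes", "n_frames", "cells")) {
    if (is.null(obj[[f]])) stop("cell-list JSON missing field '", f, "'")
  }
  recs <- lapply(obj$cells, function(c0) {
    list(cell_id = c0$cell_id, colony_id = c0$colony_id,
         mother_id = c0$mother_id, frames = unlist(c0$frames),
         numeric_attrs = lapply(c0$numeric_attrs, unlist),
         boolean_attrs = lapply(c0$boolean_attrs, unlist),
         centroid = if (is.null(c0$centroid)) NULL else
           do.call(rbind, lapply(c0$centroid, unlist)))
  })
  newCellList(recs, framePeriod = obj$frame_period_minutes,
              nFrames = obj$n_frames,
              provenance = obj$provenance %||% path)
}

#' Write a CellList to canonical JSON
#'
#' The file round-trips: `readCellList(writeCellList(x, p))` is value-identical
#' to `x`. An invalid CellList is refused.
#'
#' @param cells a [CellList-class]
#' @param path output path
#' @return invisibly, `path`
#' @export
writeCellList <- function(cells, path) {
  stopifnot(is(cells, "CellList"))
  v <- .validCellList(cells)
  if (!isTRUE(v)) stop("refusing to write invalid CellList: ", v[[1]])
  recs <- lapply(cells@cells, function(r) {
    list(cell_id = jsonlite::unbox(r$cell_id),
         colony_id = jsonlite::unbox(r$colony_id),
         mother_id = if (is.na(r$mother_id)) NULL else jsonlite::unbox(r$mother_id),
         frames = r$frames,
         numeric_attrs = r$numeric_attrs,
         boolean_attrs = r$boolean_attrs,
         centroid = if (is.null(r$centroid)) NULL else
           lapply(seq_len(nrow(r$centroid)), function(i) unname(r$centroid[i, ])))
  })
  obj <- list(frame_period_minutes = jsonlite::unbox(cells@framePeriod),
              n_frames = jsonlite::unbox(cells@nFrames),
              provenance = jsonlite::unbox(cells@provenance),
              cells = recs)
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot open path for writing: ", path))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, null = "null", digits = NA, pretty = FALSE), con)
  invisible(path)
}

#' Import a long-format tracker CSV export
#'
#' One row per cell instance. `columnMap` maps CSV column names to the
#' canonical fields `cell_id`, `frame`, `colony_id`, `mother_id`; every
#' unmapped remaining column named in `numericAttrs`/`booleanAttrs` becomes an
#' attribute series. Rows are grouped by cell and sorted by frame; a gap in a
#' cell's frame sequence splits the cell into separate records — the later
#' fragment loses its mother link (it will surface as a motherless branch) and
#' a warning is emitted, because tracking discontinuities must be visible, not
#' interpolated away.
#'
#' @param path CSV path (header row; `NA` is the missing-value token).
#' @param framePeriod minutes per frame.
#' @param columnMap named character vector, e.g.
#'   `c(cell_id = "id", frame = "t", colony_id = "col", mother_id = "parent")`.
#'   `mother_id` may be omitted if the file has no lineage column.
#' @param numericAttrs,booleanAttrs names of CSV columns to import as numeric /
#'   boolean attribute series (defaults: every unmapped numeric / logical
#'   column).
#' @param sep field delimiter.
#' @param nFrames movie length; default max frame seen.
#' @return a validated [CellList-class]
#' @export
importTrackerCSV <- function(path, framePeriod, columnMap,
                             numericAttrs = NULL, booleanAttrs = NULL,
                             sep = ",", nFrames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty tracker CSV: ", path)
  need <- c("cell_id", "frame")
  if (!all(need %in% names(columnMap))) {
    stop("columnMap must map at least: ", paste(need, collapse = ", "))
  }
  miss <- setdiff(unname(columnMap), names(df))
  if (length(miss)) stop("mapped column(s) absent from CSV: ",
                         paste(miss, collapse = ", "))
  canon <- function(field) if (field %in% names(columnMap)) df[[columnMap[[field]]]] else NULL
  core <- data.frame(cell_id = as.character(canon("cell_id")),
                     frame = as.integer(canon("frame")),
                     stringsAsFactors = FALSE)
  core$colony_id <- if (!is.null(canon("colony_id"))) as.character(canon("colony_id")) else "1"
  core$mother_id <- if (!is.null(canon("mother_id"))) {
    m <- as.character(canon("mother_id"))
    m[m %in% c("", "NA")] <- NA_character_
    m
  } else NA_character_
  rest <- setdiff(names(df), unname(columnMap))
  if (is.null(numericAttrs)) {
    numericAttrs <- rest[vapply(df[rest], is.numeric, logical(1))]
  }
  if (is.null(booleanAttrs)) {
    booleanAttrs <- rest[vapply(df[rest], is.logical, logical(1))]
  }
  recs <- list()
  split_warned <- character()
  for (id in unique(core$cell_id)) {
    idx <- which(core$cell_id == id)
    idx <- idx[order(core$frame[idx])]
    fr <- core$frame[idx]
    # split at gaps; later fragments become motherless
    brk <- c(0L, which(diff(fr) != 1L), length(fr))
    nseg <- length(brk) - 1L
    if (nseg > 1L) split_warned <- c(split_warned, id)
    for (s in seq_len(nseg)) {
      take <- idx[(brk[s] + 1L):brk[s + 1L]]
      sid <- if (s == 1L) id else paste0(id, ".part", s)
      recs[[length(recs) + 1L]] <- list(
        cell_id = sid,
        colony_id = core$colony_id[take[1]],
        mother_id = if (s == 1L) core$mother_id[take[1]] else NA_character_,
        frames = core$frame[take],
        numeric_attrs = setNames(lapply(numericAttrs, function(a) as.numeric(df[[a]][take])),
                                 numericAttrs),
        boolean_attrs = setNames(lapply(booleanAttrs, function(a) as.logical(df[[a]][take])),
                                 booleanAttrs),
        centroid = NULL)
    }
  }
  if (length(split_warned)) {
    warning("frame gap(s) split cell(s) into motherless fragments: ",
            paste(split_warned, collapse = ", "))
  }
  newCellList(recs, framePeriod = framePeriod, nFrames = nFrames,
              provenance = path)
}

#' Export a CellList as a long-format CSV
#'
#' One row per cell instance, columns `cell_id`, `frame`, `colony_id`,
#' `mother_id`, then one column per attribute. The inverse of
#' [importTrackerCSV()] under the identity column map.
#'
#' @param cells a [CellList-class]
#' @param path output path
#' @return invisibly, `path`
#' @export
exportTrackerCSV <- function(cells, path) {
  stopifnot(is(cells, "CellList"))
  rows <- lapply(cells@cells, function(r) {
    d <- data.frame(cell_id = r$cell_id, frame = r$frames,
                    colony_id = r$colony_id, mother_id = r$mother_id,
                    stringsAsFactors = FALSE)
    for (a in names(r$numeric_attrs)) d[[a]] <- r$numeric_attrs[[a]]
    for (a in names(r$boolean_attrs)) d[[a]] <- r$boolean_attrs[[a]]
    d
  })
  out <- data.table::rbindlist(rows, fill = TRUE)
  write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}
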