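# Tracking/segmentation error spotting: motherless branches, RMSE outliers,
# abrupt frame-to-frame attribute changes. QC only reports — repair is
# explicit surgery via extractBranch()/addBranch().

#' Report motherless branches with candidate attachment sites
#'
#' One row per branch in the motherless store. Candidate mothers are attached
#' cells alive at the branch's first frame minus one that either end their
#' trajectory exactly there (a lost division leaves the mother's track
#' truncated) or show an abrupt relative drop of `attr` at that transition
#' (the signature of a mother whose trajectory wrongly swallowed a daughter).
#' Candidates are ranked by a transparent score combining track-end adjacency,
#' drop magnitude, and — when centroids are present — spatial proximity to
#' the branch root; the weights are configuration, equal by default.
#'
#' @param flt a [LineageForest-class]
#' @param attr numeric attribute used for the drop signature
#' @param dropThreshold relative drop (fraction) regarded as abrupt
#' @param weights numeric length-3: track-end, drop, proximity
#' @return data.frame: `branch_id, root_cell, first_frame, n_cells,
#'   n_instances, candidates` (comma-separated, best first)
#' @export
listMotherless <- function(flt, attr = "length", dropThreshold = 0.2,
                           weights = c(end = 1, drop = 1, proximity = 1)) {
  stopifnot(is(flt, "LineageForest"))
  store <- flt@motherless
  out <- data.frame(branch_id = character(), root_cell = character(),
                    first_frame = integer(), n_cells = integer(),
                    n_instances = integer(), candidates = character(),
                    stringsAsFactors = FALSE)
  if (!length(store)) return(out)
  hasAttr <- attr %in% names(flt@instances)
  hasXY <- all(c("x", "y") %in% names(flt@instances))
  for (b in store) {
    f <- b$root_frame
    # candidate mothers may themselves sit inside *another* detached branch
    # (cascaded tracking errors), so search the whole movie except this branch
    others <- store[!vapply(store, function(o) identical(o$branch_id, b$branch_id),
                            logical(1))]
    cl <- rbind(flt@cells[, c("cell_id", "birth_frame", "last_frame")],
                do.call(rbind, lapply(others, function(o)
                  o$cells[, c("cell_id", "birth_frame", "last_frame")])))
    it <- as.data.frame(data.table::rbindlist(
      c(list(flt@instances), lapply(others, `[[`, "instances")), fill = TRUE))
    alive <- cl[cl$birth_frame <= f - 1L & cl$last_frame >= f - 1L, , drop = FALSE]
    score <- numeric(nrow(alive))
    if (nrow(alive)) {
      score <- score + weights[["end"]] * as.numeric(alive$last_frame == f - 1L)
      if (hasAttr) {
        drop <- vapply(seq_len(nrow(alive)), function(i) {
          id <- alive$cell_id[i]
          v1 <- it[[attr]][it$cell_id == id & it$frame == f - 1L]
          v2 <- it[[attr]][it$cell_id == id & it$frame == f]
          if (!length(v1) || !length(v2) || v1 == 0) return(0)
          max(0, (v1 - v2) / v1)
        }, numeric(1))
        score <- score + weights[["drop"]] * as.numeric(drop >= dropThreshold)
      }
      if (hasXY) {
        rx <- b$instances$x[b$instances$cell_id == b$root_cell &
                              b$instances$frame == f]
        ry <- b$instances$y[b$instances$cell_id == b$root_cell &
                              b$instances$frame == f]
        if (length(rx)) {
          d <- vapply(alive$cell_id, function(id) {
            cx <- it$x[it$cell_id == id & it$frame == f - 1L]
            cy <- it$y[it$cell_id == id & it$frame == f - 1L]
            if (!length(cx)) return(Inf)
            sqrt((cx - rx)^2 + (cy - ry)^2)
          }, numeric(1))
          prox <- 1 / (1 + d / max(1e-9, stats::median(d[is.finite(d)])))
          prox[!is.finite(prox)] <- 0
          score <- score + weights[["proximity"]] * prox
        }
      }
    }
    cand <- alive$cell_id[score > 0][order(-score[score > 0])]
    out <- rbind(out, data.frame(
      branch_id = b$branch_id, root_cell = b$root_cell, first_frame = f,
      n_cells = nrow(b$cells), n_instances = nrow(b$instances),
      candidates = paste(cand, collapse = ","), stringsAsFactors = FALSE))
  }
  out
}

#' Flag cells whose growth fit is missing or poor
#'
#' Returns the ids of cells that failed to fit the growth model plus those
#' whose RMSE exceeds the threshold. `threshold = "auto"` proposes
#' `mean + 2*sd` of the converged cells' RMSE values — a histogram-tail
#' heuristic; the choice is deliberately exposed.
#'
#' @param fits fit table from [fitGrowthForest()]
#' @param threshold numeric RMSE cutoff, or `"auto"`
#' @return list with `suspects` (cell ids), `threshold` (the value used)
#' @export
detectBadFits <- function(fits, threshold = "auto") {
  if (!nrow(fits)) stop("insufficient data: no fits")
  ok <- fits[fits$converged, , drop = FALSE]
  if (identical(threshold, "auto")) {
    if (nrow(ok) < 2) stop("auto threshold needs >= 2 converged fits")
    threshold <- mean(ok$rmse) + 2 * stats::sd(ok$rmse)
  }
  suspects <- unique(c(fits$cell_id[!fits$converged],
                       ok$cell_id[ok$rmse > threshold]))
  list(suspects = suspects, threshold = threshold)
}

#' Flag abrupt frame-to-frame attribute changes
#'
#' Instances whose normalized rate of change of `attr` exceeds
#' `pctThreshold` percent in absolute value, grouped by cell. A large drop in
#' length or area from one frame to the next marks a likely segmentation or
#' tracking error (e.g. a missed division).
#'
#' @param flt a [LineageForest-class]
#' @param attr numeric instance attribute
#' @param pctThreshold percent change cutoff
#' @return data.frame: `cell_id, frame, roc_pct`
#' @export
detectRocAnomalies <- function(flt, attr = "length", pctThreshold = 30) {
  flt <- addRoc(flt, attr, normalized = TRUE)
  col <- paste0("roc_", attr, "_pct")
  it <- flt@instances
  hit <- !is.na(it[[col]]) & abs(it[[col]]) > pctThreshold
  out <- it[hit, c("cell_id", "frame", col)]
  names(out)[3] <- "roc_pct"
  out <- out[order(out$cell_id, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Repair lost-division corruptions from a corruption log
#'
#' For each logged cut, glues the motherless branch rooted at the severed
#' daughter back under its true mother's last pre-division instance via
#' [addBranch()] — recovering the missed division event. After repairing
#' every cut of a `"cut"`-mode corruption, the forest is value-identical to
#' the uncorrupted build (see [forestIdentical()]).
#'
#' @param flt a [LineageForest-class] built from the corrupted movie
#' @param log corruption log from [corruptTracking()]
#' @return the repaired forest
#' @export
repairLostDivisions <- function(flt, log) {
  # repair earliest cuts first: a later cut's mother may itself live inside an
  # earlier cut's detached branch and only becomes attachable after that one
  log <- log[order(log$frame), , drop = FALSE]
  for (i in seq_len(nrow(log))) {
    rc <- log$daughter[i]
    br <- NULL
    for (b in flt@motherless) if (identical(b$root_cell, rc)) { br <- b; break }
    if (is.null(br)) stop("no motherless branch rooted at '", rc, "'")
    flt <- addBranch(flt, br, log$mother[i], log$frame[i] - 1L)
  }
  flt
}
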