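# Instance-level derived attributes and lifespan-collapsed life attributes.

#' Add the age instance attribute
#'
#' Each instance gains `age = (frame - birth_frame) * framePeriod` minutes,
#' so every lifespan starts at age 0 and ages step by one frame period.
#'
#' @param flt a [LineageForest-class]
#' @return the forest with an `age` column on its instance table (motherless
#'   branches included)
#' @export
addAge <- function(flt) {
  stopifnot(is(flt, "LineageForest"))
  ageOf <- function(inst, cells) {
    birth <- setNames(cells$birth_frame, cells$cell_id)
    (inst$frame - unname(birth[inst$cell_id])) * flt@framePeriod
  }
  flt@instances$age <- ageOf(flt@instances, flt@cells)
  flt@motherless <- lapply(flt@motherless, function(b) {
    b$instances$age <- ageOf(b$instances, b$cells)
    b
  })
  flt
}

.rocOne <- function(inst, attr, dt, normalized) {
  if (!attr %in% names(inst)) {
    stop("attribute '", attr, "' not on instances; available: ",
         paste(setdiff(names(inst), c("cell_id", "frame")), collapse = ", "))
  }
  inst <- inst[order(inst$cell_id, inst$frame), , drop = FALSE]
  x <- inst[[attr]]
  nxt <- c(x[-1], NA)
  sameCell <- c(inst$cell_id[-1] == inst$cell_id[-nrow(inst)], FALSE)
  if (normalized) {
    roc <- 100 * (nxt - x) / x
    if (any(x == 0 & sameCell, na.rm = TRUE)) {
      warning("normalized roc undefined where ", attr, " = 0; set to NA")
      roc[x == 0] <- NA_real_
    }
  } else {
    roc <- (nxt - x) / dt
  }
  roc[!sameCell] <- NA_real_ # last instance of every lifespan; never cross divisions
  inst[[paste0("roc_", attr, if (normalized) "_pct" else "")]] <- roc
  inst
}

#' Add the instantaneous rate of change (roc) of an attribute
#'
#' Forward difference along each lifespan: `roc_f = (x_{f+1} - x_f) / dt` per
#' minute, or in normalized form the percent change
#' `100 * (x_{f+1} - x_f) / x_f`. The last instance of every lifespan gets NA;
#' division boundaries are never crossed. Abrupt drops in length/area roc are
#' the classic segmentation/tracking-error signature used by
#' [detectRocAnomalies()].
#'
#' @param flt a [LineageForest-class]
#' @param attr numeric instance attribute name (e.g. `"length"`).
#' @param normalized if TRUE compute percent change per frame instead of
#'   units per minute.
#' @return the forest with a `roc_<attr>` (or `roc_<attr>_pct`) column
#' @export
addRoc <- function(flt, attr, normalized = FALSE) {
  stopifnot(is(flt, "LineageForest"))
  flt@instances <- .rocOne(flt@instances, attr, flt@framePeriod, normalized)
  flt@motherless <- lapply(flt@motherless, function(b) {
    b$instances <- .rocOne(b$instances, attr, flt@framePeriod, normalized)
    b
  })
  flt
}

#' Populate per-attribute life statistics on the FDT
#'
#' For every retained cell, each numeric instance attribute is reduced to
#' `<attr>_min`, `<attr>_max`, `<attr>_mean`, `<attr>_sd` (sample sd, n-1
#' denominator; the MLE fits in the stochasticity functions use n and are
#' documented there) plus `<attr>_birth` and `<attr>_division` (first/last
#' instance values). Each boolean attribute is reduced to its strict-majority
#' value `<attr>_majority`; ties resolve to FALSE and are flagged in
#' `<attr>_tie` — conservative for flags like "touching other cells".
#'
#' @param flt the [LineageForest-class] the FDT was built from
#' @param fdt the [DivisionForest-class] to populate
#' @return the FDT with life-attribute columns added
#' @export
computeLifeAttributes <- function(flt, fdt) {
  stopifnot(is(flt, "LineageForest"), is(fdt, "DivisionForest"))
  it <- data.table::as.data.table(flt@instances)
  it <- it[it$cell_id %in% fdt@cells$cell_id]
  data.table::setorder(it, cell_id, frame)
  cl <- fdt@cells
  for (a in fdt@cells$cell_id[0]) NULL # no-op, keeps R CMD check quiet
  for (a in flt@attrNames$numeric) {
    if (!a %in% names(it)) next
    agg <- it[, list(mn = min(.SD[[1]]), mx = max(.SD[[1]]),
                     av = mean(.SD[[1]]),
                     s = stats::sd(.SD[[1]]),
                     b = .SD[[1]][1],
                     d = .SD[[1]][.N]),
              by = "cell_id", .SDcols = a]
    m <- match(cl$cell_id, agg$cell_id)
    cl[[paste0(a, "_min")]] <- agg$mn[m]
    cl[[paste0(a, "_max")]] <- agg$mx[m]
    cl[[paste0(a, "_mean")]] <- agg$av[m]
    cl[[paste0(a, "_sd")]] <- agg$s[m]
    cl[[paste0(a, "_birth")]] <- agg$b[m]
    cl[[paste0(a, "_division")]] <- agg$d[m]
  }
  for (a in flt@attrNames$boolean) {
    if (!a %in% names(it)) next
    agg <- it[, list(ntrue = sum(.SD[[1]]), n = .N), by = "cell_id", .SDcols = a]
    m <- match(cl$cell_id, agg$cell_id)
    cl[[paste0(a, "_majority")]] <- agg$ntrue[m] > agg$n[m] / 2
    cl[[paste0(a, "_tie")]] <- agg$ntrue[m] * 2 == agg$n[m]
  }
  fdt@cells <- cl
  fdt
}

#' Merge per-cell growth-fit parameters into the FDT as life attributes
#'
#' Adds `<attr>_y0`, `<attr>_k`, `<attr>_rmse` and `<attr>_fit_converged`
#' columns from a fit table produced by [fitGrowthForest()].
#'
#' @param fdt a [DivisionForest-class]
#' @param fits a growth-fit data.frame (see [fitGrowthForest()])
#' @param attr the attribute name the fits describe (column prefix)
#' @return the updated FDT
#' @export
addGrowthFits <- function(fdt, fits, attr = "length") {
  stopifnot(is(fdt, "DivisionForest"), is.data.frame(fits))
  m <- match(fdt@cells$cell_id, fits$cell_id)
  fdt@cells[[paste0(attr, "_y0")]] <- fits$y0[m]
  fdt@cells[[paste0(attr, "_k")]] <- fits$k[m]
  fdt@cells[[paste0(attr, "_rmse")]] <- fits$rmse[m]
  fdt@cells[[paste0(attr, "_fit_converged")]] <- fits$converged[m]
  fdt
}

#' Export the life-attribute table
#'
#' @param fdt a [DivisionForest-class] (after [computeLifeAttributes()])
#' @param path CSV output path
#' @return invisibly, `path`
#' @export
exportLifeTable <- function(fdt, path) {
  stopifnot(is(fdt, "DivisionForest"))
  write.csv(fdt@cells, path, row.names = FALSE, na = "NA")
  invisible(path)
}
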