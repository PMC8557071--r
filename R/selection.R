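# Constraint-based subpopulation selection with AND composition and OR union.

#' Build a selection constraint
#'
#' A constraint is `attr op value`, e.g. `constraint("length", ">", 2)`.
#' Ordering operators require a numeric attribute; `=` / `!=` work for
#' numerics, booleans and identifiers (`colony`, `generation`, `cell_id`,
#' `frame` are selectable alongside measured attributes). `=~` is approximate
#' numeric equality with absolute tolerance `atol`, for float-valued measured
#' attributes.
#'
#' @param attr attribute name
#' @param op one of `<`, `<=`, `=`, `==`, `>=`, `>`, `!=`, `=~`
#' @param value comparison value
#' @param atol absolute tolerance used by `=~`
#' @return a `constraint` object
#' @export
constraint <- function(attr, op, value, atol = 1e-8) {
  op <- as.character(op)
  if (!op %in% c("<", "<=", "=", "==", ">=", ">", "!=", "=~")) {
    stop("unknown comparison operator: ", op)
  }
  structure(list(attr = attr, op = op, value = value, atol = atol),
            class = "constraint")
}

#' Parse a constraint from a string like `"length>2"` or `"touching=true"`
#' @param s constraint string
#' @return a `constraint` object
#' @export
parseConstraint <- function(s) {
  m <- regmatches(s, regexec("^\\s*([^<>=!~ ]+)\\s*(<=|>=|!=|=~|==|<|>|=)\\s*(.+?)\\s*$", s))[[1]]
  if (length(m) != 4) stop("cannot parse constraint: ", s)
  val <- m[4]
  val <- if (tolower(val) %in% c("true", "false")) as.logical(toupper(val)) else
    if (!is.na(suppressWarnings(as.numeric(val)))) as.numeric(val) else val
  constraint(m[2], m[3], val)
}

.applyConstraint <- function(values, con) {
  if (con$op %in% c("<", "<=", ">=", ">", "=~") && !is.numeric(values)) {
    stop("operator '", con$op, "' needs a numeric attribute; '",
         con$attr, "' is ", class(values)[1])
  }
  ok <- switch(con$op,
    "<" = values < con$value, "<=" = values <= con$value,
    ">" = values > con$value, ">=" = values >= con$value,
    "=" = , "==" = values == con$value,
    "!=" = values != con$value,
    "=~" = abs(values - con$value) <= con$atol)
  ok & !is.na(ok)
}

.selectableTable <- function(forest) {
  if (is(forest, "LineageForest")) {
    m <- match(forest@instances$cell_id, forest@cells$cell_id)
    cbind(forest@instances,
          colony = forest@cells$colony[m],
          generation = forest@cells$generation[m],
          mother_id = forest@cells$mother_id[m],
          stringsAsFactors = FALSE)
  } else {
    forest@cells
  }
}

#' Select a subpopulation satisfying all constraints (logical AND)
#'
#' Keeps the nodes (cell instances for an FLT, cell lives for an FDT)
#' satisfying every constraint; the synthetic roots are implicit and always
#' retained. Constraints compose as AND — sequential selections and a single
#' multi-constraint selection give the same node set. The result can be an
#' unconnected sub-forest; it stays a valid input for all analytics and for
#' further selection, and remembers its parent movie for [uniteTrees()].
#' Selections never mutate the parent forest. The motherless store is not
#' carried into selections.
#'
#' @param forest a [LineageForest-class] or [DivisionForest-class]
#' @param constraints a list of [constraint()] objects (or strings parsed by
#'   [parseConstraint()]). Empty list = identity.
#' @return a forest of the same class containing the selected nodes
#' @export
selectSubtree <- function(forest, constraints = list()) {
  if (inherits(constraints, "constraint")) constraints <- list(constraints)
  constraints <- lapply(constraints, function(cn) {
    if (is.character(cn)) parseConstraint(cn) else cn
  })
  tab <- .selectableTable(forest)
  keep <- rep(TRUE, nrow(tab))
  for (cn in constraints) {
    if (!cn$attr %in% names(tab)) {
      stop("unknown attribute '", cn$attr, "'; available: ",
           paste(sort(setdiff(names(tab), NULL)), collapse = ", "))
    }
    keep <- keep & .applyConstraint(tab[[cn$attr]], cn)
  }
  if (is(forest, "LineageForest")) {
    inst <- forest@instances[keep, , drop = FALSE]
    forest@instances <- inst
    forest@cells <- forest@cells[forest@cells$cell_id %in% inst$cell_id, , drop = FALSE]
    forest@motherless <- list()
  } else {
    forest@cells <- forest@cells[keep, , drop = FALSE]
  }
  forest
}

#' Node-set union of selections (logical OR)
#'
#' All forests must derive from the same parent movie (matching provenance);
#' their node sets are united and edges are implicit wherever both endpoints
#' are present.
#'
#' @param forests a list of forests of the same class and provenance
#' @return a forest of the same class
#' @export
uniteTrees <- function(forests) {
  stopifnot(length(forests) >= 1)
  cls <- class(forests[[1]])
  prov <- forests[[1]]@provenance
  for (f in forests) {
    if (!is(f, cls)) stop("cannot unite forests of different classes")
    if (!identical(f@provenance, prov)) {
      stop("cannot unite forests from different parents (provenance mismatch)")
    }
  }
  out <- forests[[1]]
  if (is(out, "LineageForest")) {
    inst <- as.data.frame(data.table::rbindlist(
      lapply(forests, function(f) f@instances), fill = TRUE))
    inst <- inst[!duplicated(inst[, c("cell_id", "frame")]), , drop = FALSE]
    cells <- as.data.frame(data.table::rbindlist(
      lapply(forests, function(f) f@cells), fill = TRUE))
    cells <- cells[!duplicated(cells$cell_id), , drop = FALSE]
    out@instances <- inst
    out@cells <- cells
  } else {
    cells <- as.data.frame(data.table::rbindlist(
      lapply(forests, function(f) f@cells), fill = TRUE))
    out@cells <- cells[!duplicated(cells$cell_id), , drop = FALSE]
  }
  out
}

#' Select outliers by the mean-and-standard-deviation method
#'
#' Keeps nodes whose attribute value lies below `mean - k*sd` or above
#' `mean + k*sd`, with mean and sample sd computed over the queried forest's
#' own nodes. With the default `k = 1` this is the outlier rule used to pick
#' out, e.g., abnormally small or large cell areas.
#'
#' @param forest a forest
#' @param attr numeric attribute
#' @param k band half-width in standard deviations
#' @return forest of the selected outlier nodes
#' @export
flagOutliersMeanSd <- function(forest, attr, k = 1) {
  tab <- .selectableTable(forest)
  if (!attr %in% names(tab)) stop("unknown attribute '", attr, "'")
  v <- tab[[attr]]
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 values to compute mean/sd")
  m <- mean(v); s <- stats::sd(v)
  lo <- constraint(attr, "<", m - k * s)
  hi <- constraint(attr, ">", m + k * s)
  uniteTrees(list(selectSubtree(forest, list(lo)),
                  selectSubtree(forest, list(hi))))
}
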