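# Kin-pair enumeration on the FDT and per-generation correlation/regression
# of life attributes between pair members.

#' Enumerate kin pairs on a division forest
#'
#' Exhaustive, duplicate-free enumeration of related-cell pairs among the
#' retained FDT cells:
#' * `sibling` — same mother (unordered; exist from generation 1);
#' * `cousin` — same grandmother, different mothers (unordered; from
#'   generation 2);
#' * `mother_daughter`, `grandmother_granddaughter` — ordered
#'   ancestor-descendant pairs.
#'
#' `generation` is the common generation for same-generation relations and
#' the descendant's generation for cross-generation ones. Cells excluded from
#' the FDT never appear.
#'
#' @param fdt a [DivisionForest-class]
#' @param relation one of the four relation names
#' @return data.frame: `relation, cell_a, cell_b, generation` (for ordered
#'   relations `cell_a` is the ancestor)
#' @export
enumeratePairs <- function(fdt, relation = c("sibling", "cousin",
                                             "mother_daughter",
                                             "grandmother_granddaughter")) {
  stopifnot(is(fdt, "DivisionForest"))
  relation <- match.arg(relation)
  cl <- fdt@cells
  inSet <- function(x) !is.na(x) & x %in% cl$cell_id
  gen <- setNames(cl$generation, cl$cell_id)
  mom <- setNames(cl$mother_id, cl$cell_id)
  emptyOut <- data.frame(relation = character(), cell_a = character(),
                         cell_b = character(), generation = integer(),
                         stringsAsFactors = FALSE)
  pairRows <- function(a, b) {
    data.frame(relation = relation, cell_a = a, cell_b = b,
               generation = unname(gen[b]), stringsAsFactors = FALSE)
  }
  if (relation == "mother_daughter") {
    d <- cl[inSet(cl$mother_id), ]
    if (!nrow(d)) return(emptyOut)
    return(pairRows(d$mother_id, d$cell_id))
  }
  if (relation == "grandmother_granddaughter") {
    d <- cl[inSet(cl$mother_id), ]
    gm <- unname(mom[d$mother_id])
    keep <- !is.na(gm) & gm %in% cl$cell_id
    if (!any(keep)) return(emptyOut)
    return(pairRows(gm[keep], d$cell_id[keep]))
  }
  if (relation == "sibling") {
    d <- cl[inSet(cl$mother_id), ]
    fam <- split(d$cell_id, d$mother_id)
  } else { # cousin: group by grandmother, exclude same-mother pairs below
    d <- cl[inSet(cl$mother_id), ]
    gm <- unname(mom[d$mother_id])
    keep <- !is.na(gm)
    d <- d[keep, ]; gm <- gm[keep]
    fam <- split(d$cell_id, gm)
  }
  out <- list()
  for (ids in fam) {
    if (length(ids) < 2) next
    cmb <- utils::combn(sort(ids), 2)
    a <- cmb[1, ]; b <- cmb[2, ]
    if (relation == "cousin") {
      sameMom <- unname(mom[a]) == unname(mom[b])
      a <- a[!sameMom]; b <- b[!sameMom]
    }
    if (length(a)) out[[length(out) + 1L]] <- pairRows(a, b)
  }
  if (!length(out)) return(emptyOut)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlation and regression of a life attribute over kin pairs
#'
#' Pearson r, the least-squares regression of member b on member a, and R^2,
#' overall and (optionally) per generation. Same-generation relations
#' (siblings, cousins) are unordered, so statistics are computed on the
#' symmetrized set — each pair contributes as (a, b) and (b, a) — making r
#' and the slope orientation-invariant; `n_pairs` still counts unique pairs.
#' Cross-generation relations regress the descendant on the ancestor. Groups
#' with fewer than 3 pairs report NA with their count.
#'
#' @param fdt the [DivisionForest-class] carrying the attribute
#' @param pairs pair table from [enumeratePairs()]
#' @param attr life-attribute column (e.g. `"length_division"`,
#'   `"division_duration"`)
#' @param perGeneration if TRUE group by generation, else one overall row
#' @return data.frame: `generation` (or "all"), `n_pairs, r, slope, intercept,
#'   r_squared`
#' @export
pairStats <- function(fdt, pairs, attr, perGeneration = TRUE) {
  stopifnot(is(fdt, "DivisionForest"))
  if (!nrow(pairs)) stop("insufficient data: empty pair set")
  cl <- fdt@cells
  if (!attr %in% names(cl)) stop("unknown life attribute '", attr, "'")
  val <- setNames(cl[[attr]], cl$cell_id)
  a <- unname(val[pairs$cell_a])
  b <- unname(val[pairs$cell_b])
  ok <- !is.na(a) & !is.na(b)
  pairs <- pairs[ok, ]; a <- a[ok]; b <- b[ok]
  symmetric <- all(pairs$relation %in% c("sibling", "cousin"))
  groups <- if (perGeneration) split(seq_along(a), pairs$generation) else
    list(all = seq_along(a))
  rows <- lapply(names(groups), function(g) {
    ix <- groups[[g]]
    n <- length(ix)
    if (n < 3) {
      return(data.frame(generation = g, n_pairs = n, r = NA_real_,
                        slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, stringsAsFactors = FALSE))
    }
    xa <- a[ix]; xb <- b[ix]
    if (symmetric) { x <- c(xa, xb); y <- c(xb, xa) } else { x <- xa; y <- xb }
    r <- suppressWarnings(stats::cor(x, y))
    fit <- stats::lm(y ~ x)
    data.frame(generation = g, n_pairs = n, r = r,
               slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
               r_squared = suppressWarnings(summary(fit)$r.squared),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
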