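# Publication-style figures. Every plotting function RETURNS its computed
# statistics (fit parameters, correlations, group means, layout) so analyses
# assert numbers, not pixels; the figure file is a side effect.

.savePlot <- function(p, file, width, height, dpi) {
  if (!is.null(file)) {
    ggplot2::ggsave(file, plot = p, width = width, height = height,
                    dpi = dpi, units = "in")
  }
  invisible(file)
}

# stable label -> colour mapping: hash-based hue so a colony/generation keeps
# its colour across every figure of the same dataset
.paletteFor <- function(labels) {
  labels <- as.character(sort(unique(labels)))
  hue <- vapply(labels, function(l) {
    h <- sum(utf8ToInt(l) * seq_along(utf8ToInt(l)) * 47) %% 360
    h / 360
  }, numeric(1))
  setNames(grDevices::hsv(hue, s = 0.65, v = 0.85), labels)
}

# radial layout: master root at the origin, node radius = tree level - 1,
# leaves get equal angular slots (deterministic child order by cell id/frame)
.radialLayout <- function(forest) {
  if (is(forest, "LineageForest")) {
    it <- forest@instances[order(forest@instances$cell_id,
                                 forest@instances$frame), ]
    id <- paste0(it$cell_id, "@", it$frame)
    cl <- forest@cells
    m <- match(it$cell_id, cl$cell_id)
    sameCellParent <- ifelse(it$frame > cl$birth_frame[m],
                             paste0(it$cell_id, "@", it$frame - 1L), NA)
    momLast <- cl$last_frame[match(cl$mother_id[m], cl$cell_id)]
    parent <- ifelse(!is.na(sameCellParent), sameCellParent,
                     ifelse(is.na(cl$mother_id[m]), paste0("colony:", cl$colony[m]),
                            paste0(cl$mother_id[m], "@", momLast)))
    level <- it$frame + 2L
    colonies <- unique(cl$colony)
    nodes <- data.frame(
      id = c("master", paste0("colony:", colonies), id),
      parent = c(NA, rep("master", length(colonies)), parent),
      level = c(1L, rep(2L, length(colonies)), level),
      stringsAsFactors = FALSE)
  } else {
    cl <- forest@cells[order(forest@cells$cell_id), ]
    colonies <- unique(cl$colony)
    parent <- ifelse(is.na(cl$mother_id) | !(cl$mother_id %in% cl$cell_id),
                     paste0("colony:", cl$colony), cl$mother_id)
    nodes <- data.frame(
      id = c("master", paste0("colony:", colonies), cl$cell_id),
      parent = c(NA, rep("master", length(colonies)), parent),
      level = c(1L, rep(2L, length(colonies)), cl$generation + 3L),
      stringsAsFactors = FALSE)
  }
  kids <- split(nodes$id, nodes$parent)
  angle <- setNames(rep(NA_real_, nrow(nodes)), nodes$id)
  leafCounter <- new.env(); leafCounter$n <- 0
  nLeaves <- sum(!nodes$id %in% nodes$parent)
  assignAngle <- function(v) {
    ch <- kids[[v]]
    if (is.null(ch)) {
      leafCounter$n <- leafCounter$n + 1
      angle[[v]] <<- 2 * pi * (leafCounter$n - 0.5) / max(1, nLeaves)
    } else {
      for (c0 in sort(ch)) assignAngle(c0)
      angle[[v]] <<- mean(angle[ch])
    }
    invisible()
  }
  old <- options(expressions = 500000); on.exit(options(old))
  assignAngle("master")
  nodes$angle <- unname(angle[nodes$id])
  nodes$xx <- (nodes$level - 1) * cos(nodes$angle)
  nodes$yy <- (nodes$level - 1) * sin(nodes$angle)
  nodes
}

#' Plot a forest radially with an attribute colormap
#'
#' Master root at the centre, one ring per level (frames for an FLT,
#' generations for an FDT), equal angular slots per leaf with deterministic
#' child ordering, so the layout is reproducible for a given forest.
#' Synthetic nodes are uncoloured. Colony and generation colourings use a
#' stable hash-based palette, consistent across every figure of a dataset.
#'
#' @param forest a [LineageForest-class] or [DivisionForest-class]
#' @param attr attribute to colour by (`"colony"`, `"generation"`, or any
#'   node attribute)
#' @param file image path (`.png`/`.pdf`) or NULL for no file
#' @param width,height inches
#' @param dpi resolution
#' @return invisibly, list with `layout` (node coordinates) and `file`
#' @export
plotForest <- function(forest, attr = "generation", file = NULL,
                       width = 7, height = 7, dpi = 150) {
  lay <- .radialLayout(forest)
  tab <- if (is(forest, "LineageForest")) {
    it <- forest@instances
    m <- match(it$cell_id, forest@cells$cell_id)
    data.frame(id = paste0(it$cell_id, "@", it$frame),
               colony = forest@cells$colony[m],
               generation = forest@cells$generation[m],
               it, stringsAsFactors = FALSE)
  } else {
    data.frame(id = forest@cells$cell_id, forest@cells,
               stringsAsFactors = FALSE)
  }
  if (!attr %in% names(tab)) {
    stop("unknown attribute '", attr, "' for colouring")
  }
  lay$value <- tab[[attr]][match(lay$id, tab$id)]
  edges <- merge(lay, lay[, c("id", "xx", "yy")],
                 by.x = "parent", by.y = "id", suffixes = c("", "_p"))
  xx <- yy <- xx_p <- yy_p <- value <- NULL # NSE bindings
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = xx_p, y = yy_p, xend = xx, yend = yy),
                          linewidth = 0.2, colour = "grey60") +
    ggplot2::coord_equal() + ggplot2::theme_void()
  discrete <- attr %in% c("colony", "generation") || !is.numeric(lay$value)
  syn <- is.na(lay$value)
  p <- p + ggplot2::geom_point(data = lay[syn, ],
                               ggplot2::aes(xx, yy), shape = 21,
                               fill = "white", colour = "grey40", size = 1.2)
  if (discrete) {
    lay$value <- as.character(lay$value)
    pal <- .paletteFor(lay$value[!syn])
    p <- p + ggplot2::geom_point(data = lay[!syn, ],
                                 ggplot2::aes(xx, yy, colour = value), size = 0.8) +
      ggplot2::scale_colour_manual(values = pal, name = attr)
  } else {
    p <- p + ggplot2::geom_point(data = lay[!syn, ],
                                 ggplot2::aes(xx, yy, colour = value), size = 0.8) +
      ggplot2::scale_colour_viridis_c(name = attr)
  }
  .savePlot(p, file, width, height, dpi)
  invisible(list(layout = lay, file = file))
}

.vizValues <- function(forest, attrs) {
  tab <- .selectableTable(forest)
  for (a in attrs) if (!a %in% names(tab)) stop("unknown attribute '", a, "'")
  tab
}

#' Scatter plot of two attributes with regression and density binning
#'
#' Returns the plotted statistics — Pearson r and the least-squares line —
#' alongside the optional figure. `densityBins` switches to 2-D binned
#' density colouring (that style typically uses 80 bins per axis); `diagonal`
#' draws the bounding-box diagonal in grey.
#'
#' @param forest a forest
#' @param xAttr,yAttr numeric attributes
#' @param densityBins bins per axis, or NULL for plain points
#' @param regression draw/return the least-squares line
#' @param diagonal draw the plot-area diagonal
#' @param colorBy optional discrete attribute for point colours
#' @param file,width,height,dpi figure output
#' @return list: `r, slope, intercept, r_squared, n`
#' @export
plotScatter <- function(forest, xAttr, yAttr, densityBins = NULL,
                        regression = TRUE, diagonal = FALSE, colorBy = NULL,
                        file = NULL, width = 6, height = 5, dpi = 150) {
  tab <- .vizValues(forest, c(xAttr, yAttr))
  keep <- stats::complete.cases(tab[, c(xAttr, yAttr)])
  d <- data.frame(x = tab[[xAttr]][keep], y = tab[[yAttr]][keep])
  if (!is.null(colorBy)) d$col <- as.character(tab[[colorBy]][keep])
  if (nrow(d) < 3) stop("insufficient data: need >= 3 points")
  fit <- stats::lm(y ~ x, data = d)
  stats <- list(r = stats::cor(d$x, d$y),
                slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]),
                # summary.lm warns on numerically perfect fits; R^2 is still 1
                r_squared = suppressWarnings(summary(fit)$r.squared),
                n = nrow(d))
  x <- y <- col <- NULL
  p <- ggplot2::ggplot(d, ggplot2::aes(x, y))
  if (!is.null(densityBins)) {
    p <- p + ggplot2::geom_bin2d(bins = densityBins) +
      ggplot2::scale_fill_viridis_c(name = "count")
  } else if (!is.null(colorBy)) {
    p <- ggplot2::ggplot(d, ggplot2::aes(x, y, colour = col)) +
      ggplot2::geom_point(size = 0.7) +
      ggplot2::scale_colour_manual(values = .paletteFor(d$col), name = colorBy)
  } else {
    p <- p + ggplot2::geom_point(size = 0.7, alpha = 0.6)
  }
  if (diagonal) {
    p <- p + ggplot2::annotate("segment", x = min(d$x), y = min(d$y),
                               xend = max(d$x), yend = max(d$y),
                               colour = "grey55")
  }
  if (regression) {
    p <- p + ggplot2::geom_abline(slope = stats$slope,
                                  intercept = stats$intercept, colour = "black")
  }
  p <- p + ggplot2::labs(x = xAttr, y = yAttr) + ggplot2::theme_minimal()
  .savePlot(p, file, width, height, dpi)
  stats
}

#' Least-squares plane for three attributes
#'
#' Fits `z = a*x + b*y + c` and reports the coefficients and R^2; the figure
#' (when requested) is a 3-D perspective scatter with the fitted plane.
#' Collinear predictors yield a rank-deficiency warning and the pseudo-inverse
#' solution.
#'
#' @param forest a forest
#' @param xAttr,yAttr,zAttr numeric attributes (>= 4 points)
#' @param file,width,height,dpi figure output (PNG)
#' @return list: `a, b, c, r_squared, n`
#' @export
plotScatter3 <- function(forest, xAttr, yAttr, zAttr, file = NULL,
                         width = 6, height = 5, dpi = 150) {
  tab <- .vizValues(forest, c(xAttr, yAttr, zAttr))
  d <- data.frame(x = tab[[xAttr]], y = tab[[yAttr]], z = tab[[zAttr]])
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 4) stop("insufficient data: need >= 4 points")
  X <- cbind(x = d$x, y = d$y, c = 1)
  qx <- qr(X)
  if (qx$rank < 3) {
    warning("collinear predictors; reporting the minimum-norm solution")
    cf <- drop(MASS_ginv(X) %*% d$z)
  } else {
    cf <- drop(solve(qr.R(qx), t(qr.Q(qx)) %*% d$z))
  }
  fitted <- drop(X %*% cf)
  ss_res <- sum((d$z - fitted)^2)
  ss_tot <- sum((d$z - mean(d$z))^2)
  stats <- list(a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3]),
                r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                n = nrow(d))
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height, units = "in", res = dpi)
    on.exit(grDevices::dev.off())
    pm <- graphics::persp(x = range(d$x), y = range(d$y),
                          z = outer(range(d$x), range(d$y),
                                    function(a, b) cf[1] * a + cf[2] * b + cf[3]),
                          xlab = xAttr, ylab = yAttr, zlab = zAttr,
                          theta = 35, phi = 20, col = grDevices::adjustcolor("steelblue", 0.3))
    pts <- grDevices::trans3d(d$x, d$y, d$z, pm)
    graphics::points(pts, pch = 16, cex = 0.5, col = "grey20")
  }
  stats
}

# tiny pseudo-inverse (avoids pulling MASS into Imports for one corner case)
MASS_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Group summaries: violin, box, pdf overlay or per-time dot plots
#'
#' One glyph per group on a shared y-axis so groups are directly comparable;
#' group colours use the same stable palette as [plotForest()]. The
#' `pdf_overlay` kind draws a density histogram per group with the fitted
#' best family curve from [bestFitAuto()] on top. Empty groups are skipped
#' with a warning. The per-group summary statistics are always returned.
#'
#' @param forest a forest
#' @param attr numeric attribute to summarise
#' @param by grouping attribute (default `"generation"`)
#' @param kind `"violin"`, `"box"`, `"pdf_overlay"` or `"time_dots"`
#' @param file,width,height,dpi figure output
#' @return data.frame: `group, n, mean, sd, median` (+ fitted family/params
#'   for `pdf_overlay`)
#' @export
plotGroupSummaries <- function(forest, attr, by = "generation",
                               kind = c("violin", "box", "pdf_overlay",
                                        "time_dots"),
                               file = NULL, width = 7, height = 5, dpi = 150) {
  kind <- match.arg(kind)
  tab <- .vizValues(forest, c(attr, by))
  d <- data.frame(g = as.character(tab[[by]]), v = tab[[attr]])
  d <- d[!is.na(d$v), ]
  empty <- setdiff(as.character(unique(tab[[by]])), unique(d$g))
  if (length(empty)) warning("skipping empty group(s): ",
                             paste(empty, collapse = ", "))
  if (!nrow(d)) stop("no data to summarise")
  gs <- do.call(rbind, lapply(split(d$v, d$g), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               median = stats::median(v))
  }))
  gs <- cbind(group = rownames(gs), gs)
  rownames(gs) <- NULL
  gs <- gs[order(suppressWarnings(as.numeric(gs$group)), gs$group), ]
  pal <- .paletteFor(d$g)
  g <- v <- NULL
  p <- ggplot2::ggplot(d, ggplot2::aes(g, v, fill = g)) +
    ggplot2::scale_fill_manual(values = pal, guide = "none") +
    ggplot2::labs(x = by, y = attr) + ggplot2::theme_minimal()
  if (kind == "violin") {
    p <- p + ggplot2::geom_violin(scale = "width")
  } else if (kind == "box") {
    p <- p + ggplot2::geom_boxplot()
  } else if (kind == "time_dots") {
    p <- p + ggplot2::geom_jitter(ggplot2::aes(colour = g), width = 0.15,
                                  size = 0.5, show.legend = FALSE) +
      ggplot2::scale_colour_manual(values = pal)
  } else {
    fits <- lapply(split(d$v, d$g), function(v) {
      tryCatch(suppressWarnings(bestFitAuto(v)), error = function(e) NULL)
    })
    gs$family <- NA_character_
    curves <- list()
    for (gname in names(fits)) {
      s <- fits[[gname]]
      if (is.null(s)) next
      fit <- s$fits[[s$best]]
      xs <- seq(min(d$v), max(d$v), length.out = 200)
      dens <- switch(fit$family,
        normal = dnorm(xs, fit$params[["mean"]], fit$params[["sd"]]),
        gamma = dgamma(xs, fit$params[["shape"]], fit$params[["rate"]]),
        lognormal = dlnorm(xs, fit$params[["meanlog"]], fit$params[["sdlog"]]))
      curves[[gname]] <- data.frame(g = gname, xs = xs, dens = dens)
      gs$family[gs$group == gname] <- fit$family
    }
    cd <- do.call(rbind, curves)
    xs <- dens <- NULL
    p <- ggplot2::ggplot(d, ggplot2::aes(v)) +
      ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density),
                                           fill = g),
                              bins = 30, alpha = 0.5, position = "identity") +
      ggplot2::geom_line(data = cd, ggplot2::aes(xs, dens, colour = g)) +
      ggplot2::scale_fill_manual(values = pal, name = by) +
      ggplot2::scale_colour_manual(values = pal, guide = "none") +
      ggplot2::labs(x = attr, y = "density") + ggplot2::theme_minimal()
  }
  .savePlot(p, file, width, height, dpi)
  gs
}
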