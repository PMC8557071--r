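# Single-cell growth-model fitting and colony-level population growth.

.minutesToHours <- function(t) t / 60

#' Fit a linear or exponential growth model to one cell trajectory
#'
#' Exponential mode fits `y = y0 * exp(k * t)` by nonlinear least squares
#' (Levenberg-Marquardt), initialised from the log-linear regression; time is
#' converted to hours internally so `k` is per hour regardless of the frame
#' period. Linear mode is the closed-form least-squares line (slope in units
#' per hour). `rmse = sqrt(sum(resid^2)/n)`. Fewer than 3 points, or solver
#' failure, yields `converged = FALSE` rather than an error, so that mapping
#' over a movie can report the failing cell ids.
#'
#' @param times observation times in minutes
#' @param values attribute values (must be positive for the exponential model)
#' @param model `"exp"` or `"linear"`
#' @return one-row data.frame: `model, y0, k, rmse, n_points, converged`
#' @export
fitCellGrowth <- function(times, values, model = c("exp", "linear")) {
  model <- match.arg(model)
  if (length(times) != length(values)) stop("times and values differ in length")
  n <- length(values)
  fail <- data.frame(model = model, y0 = NA_real_, k = NA_real_,
                     rmse = NA_real_, n_points = n, converged = FALSE)
  if (n < 3) return(fail)
  if (length(unique(times)) < 2) stop("degenerate time vector (all equal)")
  th <- .minutesToHours(times)
  if (model == "linear") {
    X <- cbind(1, th)
    cf <- solve(crossprod(X), crossprod(X, values))
    res <- values - X %*% cf
    return(data.frame(model = model, y0 = cf[1], k = cf[2],
                      rmse = sqrt(sum(res^2) / n), n_points = n,
                      converged = TRUE))
  }
  if (any(values <= 0)) return(fail)
  ly <- log(values)
  X <- cbind(1, th)
  cf <- solve(crossprod(X), crossprod(X, ly))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = list(y0 = exp(cf[1]), k = cf[2]),
                       fn = function(p) values - p$y0 * exp(p$k * th),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(fail)
  p <- fit$par
  data.frame(model = model, y0 = p$y0, k = p$k,
             rmse = sqrt(sum(fit$fvec^2) / n), n_points = n, converged = TRUE)
}

#' Fit a growth model to every cell of an FLT
#'
#' Maps [fitCellGrowth()] over the attached cells' trajectories of `attr`
#' (time measured from each cell's birth). Cells that fail (too few
#' time-points or non-convergence) are retained in the table with
#' `converged = FALSE`; their ids are also available via `failedIds()`.
#'
#' @param flt a [LineageForest-class]
#' @param attr numeric instance attribute, default `"length"`
#' @param model `"exp"` or `"linear"`
#' @param minPoints cells with fewer instances are reported as failed
#' @return data.frame, one row per cell: `cell_id` + [fitCellGrowth()] columns
#' @export
fitGrowthForest <- function(flt, attr = "length", model = c("exp", "linear"),
                            minPoints = 3L) {
  stopifnot(is(flt, "LineageForest"))
  model <- match.arg(model)
  it <- flt@instances
  if (!attr %in% names(it)) stop("attribute '", attr, "' not on instances")
  it <- it[order(it$cell_id, it$frame), c("cell_id", "frame", attr)]
  birth <- setNames(flt@cells$birth_frame, flt@cells$cell_id)
  sp <- split(seq_len(nrow(it)), it$cell_id)
  rows <- lapply(names(sp), function(id) {
    ix <- sp[[id]]
    tmin <- (it$frame[ix] - birth[[id]]) * flt@framePeriod
    f <- if (length(ix) < minPoints) {
      data.frame(model = model, y0 = NA_real_, k = NA_real_, rmse = NA_real_,
                 n_points = length(ix), converged = FALSE)
    } else {
      fitCellGrowth(tmin, it[[attr]][ix], model)
    }
    cbind(cell_id = id, f, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ids of cells whose growth fit failed
#' @param fits a fit table from [fitGrowthForest()]
#' @return character vector of cell ids
#' @export
failedIds <- function(fits) fits$cell_id[!fits$converged]

#' Average population growth curve with variance band
#'
#' Means and sample variances (n-1) of `y0` and `k` over the converged fits.
#' The band is `ybar = y0bar * exp(kbar * t)` with
#' `y+- = (y0bar +- s2_y0) * exp((kbar +- s2_k) * t)`; by default the band
#' offsets are the *variances* (`band = "variance"`), with `band = "sd"`
#' offering the dimensionally conventional standard-deviation form.
#'
#' @param fits fit table from [fitGrowthForest()] (or rows shaped like it)
#' @param band `"variance"` or `"sd"`
#' @return object of class `populationGrowth`: list with `y0_mean, y0_var,
#'   k_mean, k_var, n_cells, failed_ids, band` and a `curve(t_hours)` closure
#'   returning `mean`, `upper`, `lower`
#' @export
populationGrowthSummary <- function(fits, band = c("variance", "sd")) {
  band <- match.arg(band)
  ok <- fits[fits$converged, , drop = FALSE]
  if (nrow(ok) < 2) stop("need at least 2 converged fits")
  y0m <- mean(ok$y0); y0v <- stats::var(ok$y0)
  km <- mean(ok$k); kv <- stats::var(ok$k)
  dy <- if (band == "variance") y0v else sqrt(y0v)
  dk <- if (band == "variance") kv else sqrt(kv)
  obj <- list(y0_mean = y0m, y0_var = y0v, k_mean = km, k_var = kv,
              n_cells = nrow(ok),
              failed_ids = fits$cell_id[!fits$converged] %||% character(),
              band = band,
              curve = function(t_hours) {
                data.frame(t = t_hours,
                           mean = y0m * exp(km * t_hours),
                           upper = (y0m + dy) * exp((km + dk) * t_hours),
                           lower = (y0m - dy) * exp((km - dk) * t_hours))
              })
  class(obj) <- "populationGrowth"
  obj
}

#' @export
print.populationGrowth <- function(x, ...) {
  cat(sprintf("Population exponential growth (%d cells):\n", x$n_cells))
  cat(sprintf("  k_mean = %.4g /h   k_var = %.4g\n", x$k_mean, x$k_var))
  cat(sprintf("  y0_mean = %.4g     y0_var = %.4g\n", x$y0_mean, x$y0_var))
  if (length(x$failed_ids)) {
    cat("  failed fits:", paste(x$failed_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-colony (and whole-population) cell counts per frame
#'
#' Tallies attached cell instances per frame for each colony label and for the
#' whole population (column `population`).
#'
#' @param flt a [LineageForest-class]
#' @return data.frame: `frame`, `time_min`, one column per colony, `population`
#' @export
colonyCounts <- function(flt) {
  stopifnot(is(flt, "LineageForest"))
  it <- flt@instances
  m <- match(it$cell_id, flt@cells$cell_id)
  col <- flt@cells$colony[m]
  frames <- seq_len(flt@nFrames)
  out <- data.frame(frame = frames, time_min = (frames - 1) * flt@framePeriod)
  for (cc in sort(unique(col))) {
    out[[as.character(cc)]] <- tabulate(it$frame[col == cc], nbins = flt@nFrames)
  }
  out$population <- tabulate(it$frame, nbins = flt@nFrames)
  out
}

# Baranyi-Roberts curve in log10 cell counts. t in hours; lag lambda in hours;
# mu_max in 1/h (natural-log units, the slope of ln N in the exponential
# phase); l0/lmax are log10 N0 / log10 Nmax.
baranyiCurve <- function(t, log10_N0, log10_Nmax, mu_max, lambda) {
  a <- exp(pmin(mu_max * lambda, 700))
  b <- exp(pmin(mu_max * t, 700))
  log10_Nmax + log10((-1 + a + b) / (-1 + b + a * 10^(log10_Nmax - log10_N0)))
}

#' Fit the Baranyi-Roberts population growth model
#'
#' Fits, in log10 count space by nonlinear least squares, the three-phase
#' (lag / exponential / stationary) growth curve
#' \deqn{y(t) = \log_{10} N_{max} + \log_{10}
#'   \frac{-1 + e^{\mu_{max}\lambda} + e^{\mu_{max} t}}
#'        {-1 + e^{\mu_{max} t} + e^{\mu_{max}\lambda}\,
#'         10^{\log_{10} N_{max} - \log_{10} N_0}}}
#' with lag time `lambda` (hours; interpretable as the mean life of
#' generation-0 cells) and maximum specific growth rate `mu_max` (1/h).
#' Initialisation: `log10_N0` = first value, `log10_Nmax` = max value,
#' `mu_max` = steepest slope of the natural-log count series, `lambda` = time
#' of first sustained increase.
#'
#' A colony that never grows (count range below one doubling) or whose curve
#' shows no approach to a plateau (fitted `log10_Nmax` far above the data) is
#' reported `converged = FALSE` with a reason — the behaviour of non-growing
#' or still-exponential colonies.
#'
#' @param times hours
#' @param log10_counts log10 cell counts (counts must be >= 1)
#' @return one-row data.frame: `log10_N0, log10_Nmax, lambda, mu_max, rmse,
#'   converged, reason`
#' @export
fitBaranyi <- function(times, log10_counts) {
  if (length(times) != length(log10_counts)) stop("length mismatch")
  if (length(times) < 5) stop("need at least 5 time points")
  if (any(log10_counts < 0)) stop("counts below 1 (log10 < 0) are not valid")
  y <- log10_counts; t <- times
  fail <- function(reason) data.frame(log10_N0 = NA_real_, log10_Nmax = NA_real_,
                                      lambda = NA_real_, mu_max = NA_real_,
                                      rmse = NA_real_, converged = FALSE,
                                      reason = reason)
  if (max(y) - min(y) < log10(2)) return(fail("no growth (range < one doubling)"))
  l0 <- y[1]; lmax <- max(y)
  sl <- diff(y * log(10)) / diff(t)
  mu0 <- max(sl[is.finite(sl)], 1e-3)
  ilag <- which(y > y[1] + log10(1.2))
  lam0 <- if (length(ilag)) max(t[ilag[1]] , 1e-3) else max(t) / 4
  fit <- suppressWarnings(tryCatch(
    minpack.lm::nls.lm(
      par = list(l0p = l0, lmaxp = lmax, mup = mu0, lamp = lam0),
      fn = function(p) y - baranyiCurve(t, p$l0p, p$lmaxp, p$mup, p$lamp),
      lower = c(-20, -20, 1e-6, 0),
      upper = c(20, lmax + 3, 100, max(t)),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) NULL))
  if (is.null(fit) || !fit$info %in% 1:4) return(fail("solver failure"))
  p <- setNames(as.list(unlist(fit$par)), names(fit$par))
  rmse <- sqrt(sum(fit$fvec^2) / length(y))
  # plateau must be supported by the data: stationary phase not yet reached
  # (still-exponential colonies) is a failure to fit, not a parameter estimate
  if (p[["lmaxp"]] > max(y) + 0.5 * (max(y) - min(y)) + 0.1) {
    return(fail("no stationary phase in the data"))
  }
  if (p[["lmaxp"]] < p[["l0p"]]) return(fail("Nmax < N0"))
  data.frame(log10_N0 = p[["l0p"]], log10_Nmax = p[["lmaxp"]],
             lambda = p[["lamp"]], mu_max = p[["mup"]],
             rmse = rmse, converged = TRUE, reason = "")
}

#' Fit the Baranyi-Roberts model to every colony of an FLT
#'
#' Builds each colony's cell-count growth curve with [colonyCounts()] and fits
#' [fitBaranyi()] per colony (frames with zero cells are dropped).
#'
#' @param flt a [LineageForest-class]
#' @return data.frame, one row per colony
#' @export
fitBaranyiForest <- function(flt) {
  cc <- colonyCounts(flt)
  cols <- setdiff(names(cc), c("frame", "time_min", "population"))
  th <- .minutesToHours(cc$time_min)
  rows <- lapply(cols, function(cn) {
    n <- cc[[cn]]
    keep <- n >= 1
    f <- if (sum(keep) < 5) {
      data.frame(log10_N0 = NA_real_, log10_Nmax = NA_real_, lambda = NA_real_,
                 mu_max = NA_real_, rmse = NA_real_, converged = FALSE,
                 reason = "too few time points")
    } else {
      fitBaranyi(th[keep], log10(n[keep]))
    }
    cbind(colony = cn, f, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
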