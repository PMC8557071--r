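# Seeded agent-based simulator of growing bacterial micro-colonies with
# stochastic, generation-indexed growth parameters, plus a corruption tool
# that injects lost-division tracking errors for QC testing.

#' Simulation configuration
#'
#' Defaults emulate a multi-colony *S.* Typhimurium movie: 5-minute frames,
#' 78 frames, 8 independent progenitors, per-cell elongation rates drawn from
#' Gamma(shape 3.026, rate 4.520) per hour and division lengths from
#' Gamma(shape 10.666, rate 3.474) micrometres — the fitted population
#' distributions such movies produce — with progenitor birth lengths
#' Normal(1.907, 0.522) um and 2% multiplicative measurement noise.
#'
#' `elongationRate` and `divisionLength` each accept: a single number
#' (deterministic), a `list(shape=, rate=)` Gamma spec, or an unnamed list of
#' either indexed by generation (last entry reused beyond). Division is
#' disabled by `divisionLength = Inf` (cells then stay single for the whole
#' movie, like non-proliferating persister colonies).
#'
#' `inheritance` controls how daughters obtain parameters at division:
#' * `"generation"` — independent draws from their generation's distribution;
#' * `"lineage"` — a family value is drawn once per division centred on the
#'   mother's value (`*(1 + N(0, inheritLineSd))`) and each daughter perturbs
#'   it by `*(1 + N(0, inheritSibSd))`: siblings share a draw up to small
#'   noise, which makes kin correlations strong (siblings above cousins).
#'
#' `expressionMarker`, if a `list(gainPerGen=, lengthSlope=, noiseSd=)`, adds
#' a synthetic per-cell expression attribute `marker` that increases with
#' generation and is anti-correlated with division length — a stand-in for a
#' virulence-marker readout.
#'
#' @param seed RNG seed (same seed, same movie, byte for byte)
#' @param nProgenitors independent colonies
#' @param framePeriod minutes per frame
#' @param nFrames movie length in frames
#' @param elongationRate per-hour rate spec (see Details)
#' @param divisionLength division-length spec in um (Inf disables division)
#' @param birthLength `list(mean=, sd=)` progenitor birth length (um)
#' @param asymmetrySd division asymmetry: daughters get `L/2*(1±eps)`,
#'   `eps ~ N(0, asymmetrySd)`
#' @param lengthNoiseSd multiplicative (lognormal) measurement noise fraction
#' @param inheritance `"generation"` or `"lineage"`
#' @param inheritLineSd,inheritSibSd lineage-mode noise fractions
#' @param expressionMarker NULL or marker spec (see Details)
#' @param maxCells safety cap; divisions stop (with a warning) beyond it
#' @return a validated `simConfig` list
#' @export
simConfig <- function(seed = 1L, nProgenitors = 8L, framePeriod = 5,
                      nFrames = 78L,
                      elongationRate = list(shape = 3.026, rate = 4.520),
                      divisionLength = list(shape = 10.666, rate = 3.474),
                      birthLength = list(mean = 1.907, sd = 0.522),
                      asymmetrySd = 0.02, lengthNoiseSd = 0.02,
                      inheritance = c("generation", "lineage"),
                      inheritLineSd = 0.10, inheritSibSd = 0.05,
                      expressionMarker = NULL, maxCells = 20000L) {
  inheritance <- match.arg(inheritance)
  stopifnot(framePeriod > 0, nFrames >= 1, nProgenitors >= 1,
            asymmetrySd >= 0, lengthNoiseSd >= 0, maxCells >= nProgenitors,
            birthLength$mean > 0)
  if (is.numeric(divisionLength) && is.finite(divisionLength) &&
      divisionLength <= birthLength$mean) {
    stop("degenerate config: divisionLength <= birth length")
  }
  cfg <- list(seed = as.integer(seed), nProgenitors = as.integer(nProgenitors),
              framePeriod = framePeriod, nFrames = as.integer(nFrames),
              elongationRate = elongationRate, divisionLength = divisionLength,
              birthLength = birthLength, asymmetrySd = asymmetrySd,
              lengthNoiseSd = lengthNoiseSd, inheritance = inheritance,
              inheritLineSd = inheritLineSd, inheritSibSd = inheritSibSd,
              expressionMarker = expressionMarker,
              maxCells = as.integer(maxCells))
  class(cfg) <- "simConfig"
  cfg
}

# draw n values from a parameter spec for a given generation
.drawParam <- function(spec, gen, n) {
  if (is.list(spec) && is.null(names(spec))) {
    spec <- spec[[min(gen + 1L, length(spec))]]
  }
  if (is.numeric(spec) && length(spec) == 1) return(rep(spec, n))
  if (is.list(spec) && all(c("shape", "rate") %in% names(spec))) {
    return(rgamma(n, shape = spec$shape, rate = spec$rate))
  }
  stop("cannot interpret parameter spec")
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a single-cell movie
#'
#' Each cell elongates exponentially, `L(t) = L_birth * exp(k * age)`, with
#' its own rate `k`; it divides at the first sampled frame where its (true)
#' length reaches its drawn division length. The two daughters receive
#' `L/2 * (1 + eps)` and `L/2 * (1 - eps)` and draw their own `k` and
#' division length per the configured inheritance mode; their first instance
#' is observed one frame after the mother's last. Observed lengths carry
#' multiplicative lognormal measurement noise. Colonies are independent
#' progenitor trees.
#'
#' @param config a [simConfig()]
#' @return list with `cells` (a validated [CellList-class]) and `truth`
#'   (list: `cells` data.frame of every drawn parameter per cell, `events`
#'   data.frame of division events, `truncated` flag)
#' @export
simulateMovie <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  .withSeed(config$seed, .simulateMovieImpl(config))
}

.simulateMovieImpl <- function(cfg) {
  dt <- cfg$framePeriod
  nF <- cfg$nFrames
  cap <- cfg$maxCells
  # per-cell state arrays (preallocated, grown on demand)
  N <- 0L
  alloc <- max(64L, 2L * cfg$nProgenitors)
  colony <- mother <- character(alloc)
  gen <- birthF <- lastF <- integer(alloc)
  t0 <- Lb <- k <- Ldiv <- numeric(alloc)
  divided <- alive <- logical(alloc)
  Ltrue_div <- numeric(alloc)
  growTo <- function(m) {
    if (m <= alloc) return(invisible())
    newAlloc <- max(m, 2L * alloc)
    pad <- function(v, fill) c(v, rep(fill, newAlloc - alloc))
    colony <<- pad(colony, ""); mother <<- pad(mother, NA_character_)
    gen <<- pad(gen, 0L); birthF <<- pad(birthF, 0L); lastF <<- pad(lastF, 0L)
    t0 <<- pad(t0, 0); Lb <<- pad(Lb, 0); k <<- pad(k, 0); Ldiv <<- pad(Ldiv, 0)
    divided <<- pad(divided, FALSE); alive <<- pad(alive, FALSE)
    Ltrue_div <<- pad(Ltrue_div, 0)
    alloc <<- newAlloc
    invisible()
  }
  newCell <- function(col, mom, g, bF, tt0, lb, kk, ld) {
    growTo(N + 1L)
    N <<- N + 1L
    colony[N] <<- col; mother[N] <<- mom; gen[N] <<- g
    birthF[N] <<- bF; lastF[N] <<- NA_integer_
    t0[N] <<- tt0; Lb[N] <<- lb; k[N] <<- kk; Ldiv[N] <<- ld
    alive[N] <<- TRUE; divided[N] <<- FALSE
    N
  }
  # a drawn division threshold at or below the birth length can never trigger:
  # redraw from the same distribution (truncated-draw semantics, keeping
  # daughters' parameters independent); fall back to one doubling only if the
  # distribution barely exceeds the birth length at all
  drawDivisible <- function(spec, g, lb) {
    ld <- .drawParam(spec, g, length(lb))
    for (tries in 1:20) {
      bad <- is.finite(ld) & ld <= lb * 1.05
      if (!any(bad)) break
      ld[bad] <- .drawParam(spec, g, sum(bad))
    }
    bad <- is.finite(ld) & ld <= lb * 1.05
    ld[bad] <- lb[bad] * 2
    ld
  }
  ensureDivisible <- function(ld, lb) {
    ifelse(is.finite(ld) & ld <= lb * 1.05, lb * 2, ld)
  }
  # progenitors
  for (i in seq_len(cfg$nProgenitors)) {
    lb <- -1
    while (lb < 0.25 * cfg$birthLength$mean) {
      lb <- rnorm(1, cfg$birthLength$mean, cfg$birthLength$sd)
    }
    kk <- max(.drawParam(cfg$elongationRate, 0L, 1L), 1e-4)
    ld <- drawDivisible(cfg$divisionLength, 0L, lb)
    newCell(as.character(i), NA_character_, 0L, 1L, 0, lb, kk, ld)
  }
  instC <- vector("list", nF); instL <- vector("list", nF)
  events <- list()
  truncated <- FALSE
  for (f in seq_len(nF)) {
    idx <- which(alive[seq_len(N)] & birthF[seq_len(N)] <= f)
    if (!length(idx)) break
    tmin <- (f - 1) * dt
    L <- Lb[idx] * exp(k[idx] * (tmin - t0[idx]) / 60)
    obs <- if (cfg$lengthNoiseSd > 0) {
      L * exp(rnorm(length(idx), 0, cfg$lengthNoiseSd))
    } else L
    instC[[f]] <- idx; instL[[f]] <- obs
    if (f < nF) {
      # tiny relative tolerance so an exact-threshold configuration divides on
      # the intended frame despite float roundoff
      dv <- idx[L >= Ldiv[idx] * (1 - 1e-9)]
      for (ci in dv) {
        if (N + 2L > cap) { truncated <- TRUE; next }
        Lnow <- Lb[ci] * exp(k[ci] * (tmin - t0[ci]) / 60)
        lastF[ci] <- f; alive[ci] <- FALSE
        divided[ci] <- TRUE; Ltrue_div[ci] <- Lnow
        eps <- rnorm(1, 0, cfg$asymmetrySd)
        lbs <- c(Lnow / 2 * (1 + eps), Lnow / 2 * (1 - eps))
        g <- gen[ci] + 1L
        if (cfg$inheritance == "generation") {
          ks <- pmax(.drawParam(cfg$elongationRate, g, 2L), 1e-4)
          lds <- drawDivisible(cfg$divisionLength, g, lbs)
        } else {
          famK <- k[ci] * (1 + rnorm(1, 0, cfg$inheritLineSd))
          famL <- Ldiv[ci] * (1 + rnorm(1, 0, cfg$inheritLineSd))
          ks <- pmax(famK * (1 + rnorm(2, 0, cfg$inheritSibSd)), 1e-4)
          lds <- ensureDivisible(famL * (1 + rnorm(2, 0, cfg$inheritSibSd)), lbs)
        }
        d1 <- newCell(colony[ci], as.character(ci), g, f + 1L, tmin,
                      lbs[1], ks[1], lds[1])
        d2 <- newCell(colony[ci], as.character(ci), g, f + 1L, tmin,
                      lbs[2], ks[2], lds[2])
        events[[length(events) + 1L]] <-
          c(frame = f + 1L, mother = ci, d1 = d1, d2 = d2)
      }
    }
  }
  lastF[which(alive[seq_len(N)])] <- nF
  if (truncated) warning("maxCells cap reached; further divisions suppressed")
  # assemble instance series per cell
  allC <- unlist(instC); allF <- rep(seq_len(nF), lengths(instC))
  allL <- unlist(instL)
  ord <- order(allC, allF)
  allC <- allC[ord]; allF <- allF[ord]; allL <- allL[ord]
  splitIdx <- split(seq_along(allC), allC)
  marker <- NULL
  if (!is.null(cfg$expressionMarker)) {
    em <- cfg$expressionMarker
    marker <- em$gainPerGen * gen[seq_len(N)] -
      em$lengthSlope * Ldiv[seq_len(N)] +
      rnorm(N, 0, em$noiseSd)
  }
  recs <- lapply(seq_len(N), function(ci) {
    ix <- splitIdx[[as.character(ci)]]
    na <- list(length = allL[ix])
    if (!is.null(marker)) na$marker <- rep(marker[ci], length(ix))
    list(cell_id = as.character(ci), colony_id = colony[ci],
         mother_id = mother[ci], frames = allF[ix],
         numeric_attrs = na, boolean_attrs = list(), centroid = NULL)
  })
  cells <- newCellList(recs, framePeriod = dt, nFrames = nF,
                       provenance = sprintf("simulateMovie(seed=%d)", cfg$seed))
  truthCells <- data.frame(
    cell_id = as.character(seq_len(N)), colony = colony[seq_len(N)],
    generation = gen[seq_len(N)], mother_id = mother[seq_len(N)],
    birth_frame = birthF[seq_len(N)], last_frame = lastF[seq_len(N)],
    birth_length = Lb[seq_len(N)], k = k[seq_len(N)],
    division_length_drawn = Ldiv[seq_len(N)], divided = divided[seq_len(N)],
    division_length_true = ifelse(divided[seq_len(N)],
                                  Ltrue_div[seq_len(N)], NA_real_),
    stringsAsFactors = FALSE)
  ev <- if (length(events)) {
    e <- as.data.frame(do.call(rbind, events))
    data.frame(frame = as.integer(e$frame),
               mother = as.character(e$mother),
               daughter1 = as.character(e$d1), daughter2 = as.character(e$d2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(frame = integer(), mother = character(),
               daughter1 = character(), daughter2 = character(),
               stringsAsFactors = FALSE)
  }
  list(cells = cells,
       truth = list(cells = truthCells, events = ev, truncated = truncated))
}

#' Inject lost-division tracking errors into a movie
#'
#' Samples `nLostDivisions` division events and severs one (randomly chosen)
#' daughter's mother link in each — building the FLT then leaves that
#' daughter's whole subtree in the motherless store. In `"merge"` mode the
#' mother's trajectory additionally swallows the other daughter (her
#' instances are appended to the mother's record and her daughters re-point
#' to the mother), mimicking the failure where a missed division leaves one
#' over-long track with an abrupt length drop. The log records the true links
#' so QC recall and repair can be scored.
#'
#' @param cells a [CellList-class] containing at least `nLostDivisions`
#'   division events
#' @param nLostDivisions number of divisions to corrupt
#' @param seed RNG seed for sampling the events
#' @param mode `"cut"` (sever one daughter) or `"merge"` (also absorb the
#'   other daughter)
#' @return list with `cells` (corrupted [CellList-class]) and `log`
#'   (data.frame: `mother, daughter, other_daughter, frame, mode`)
#' @export
corruptTracking <- function(cells, nLostDivisions, seed = 1L,
                            mode = c("cut", "merge")) {
  stopifnot(is(cells, "CellList"))
  mode <- match.arg(mode)
  emptyLog <- data.frame(mother = character(), daughter = character(),
                         other_daughter = character(), frame = integer(),
                         mode = character(), stringsAsFactors = FALSE)
  if (nLostDivisions == 0) return(list(cells = cells, log = emptyLog))
  recs <- cells@cells
  ids <- vapply(recs, `[[`, character(1), "cell_id")
  moms <- vapply(recs, function(r) r$mother_id %||% NA_character_, character(1))
  byMom <- split(ids[!is.na(moms)], moms[!is.na(moms)])
  byMom <- byMom[lengths(byMom) >= 2]
  if (length(byMom) < nLostDivisions) {
    stop("movie has only ", length(byMom), " division event(s), need ",
         nLostDivisions)
  }
  .withSeed(seed, {
    pool <- sample(names(byMom)) # random order; skip conflicts in merge mode
    log <- list()
    while (length(log) < nLostDivisions && length(pool)) {
      m <- pool[1]; pool <- pool[-1]
      if (!m %in% ids) next # absorbed by an earlier merge
      ds <- byMom[[m]]
      if (!all(ds %in% ids)) next
      cut <- sample(ds, 1)
      other <- setdiff(ds, cut)[1]
      ci <- match(cut, ids)
      log[[length(log) + 1L]] <- data.frame(
        mother = m, daughter = cut, other_daughter = other,
        frame = recs[[ci]]$frames[1], mode = mode, stringsAsFactors = FALSE)
      recs[[ci]]$mother_id <- NA_character_
      if (mode == "merge") {
        mi <- match(m, ids); oi <- match(other, ids)
        recs[[mi]]$frames <- c(recs[[mi]]$frames, recs[[oi]]$frames)
        for (a in names(recs[[mi]]$numeric_attrs)) {
          recs[[mi]]$numeric_attrs[[a]] <-
            c(recs[[mi]]$numeric_attrs[[a]], recs[[oi]]$numeric_attrs[[a]])
        }
        for (a in names(recs[[mi]]$boolean_attrs)) {
          recs[[mi]]$boolean_attrs[[a]] <-
            c(recs[[mi]]$boolean_attrs[[a]], recs[[oi]]$boolean_attrs[[a]])
        }
        granddaughters <- ids[!is.na(moms) & moms == other]
        for (gd in granddaughters) recs[[match(gd, ids)]]$mother_id <- m
        recs[[oi]] <- NULL
        ids <- vapply(recs, `[[`, character(1), "cell_id")
        moms <- vapply(recs, function(r) r$mother_id %||% NA_character_,
                       character(1))
      }
    }
    if (length(log) < nLostDivisions) {
      stop("could not corrupt ", nLostDivisions,
           " independent division events (", length(log), " available)")
    }
    corrupted <- newCellList(recs, framePeriod = cells@framePeriod,
                             nFrames = cells@nFrames,
                             provenance = paste0(cells@provenance, "+corrupted"))
    list(cells = corrupted, log = do.call(rbind, log))
  })
}
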