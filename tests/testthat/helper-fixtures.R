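# Fixtures are built in code: small hand-specified movies with known structure
# and seeded simulations.

# one cell record with an exponential (or given) length series
makeRecord <- function(id, colony = "A", mother = NA_character_,
                       frames, length = NULL, k_per_h = 0.7, l0 = 2,
                       dt = 5, extraNum = list(), extraBool = list()) {
  if (is.null(length)) {
    age_h <- (frames - frames[1]) * dt / 60
    length <- l0 * exp(k_per_h * age_h)
  }
  list(cell_id = id, colony_id = colony, mother_id = mother,
       frames = as.integer(frames),
       numeric_attrs = c(list(length = length), extraNum),
       boolean_attrs = extraBool, centroid = NULL)
}

# mother (frames 1-3) dividing into two daughters (frames 4-7)
oneDivisionMovie <- function(dt = 5) {
  newCellList(list(
    makeRecord("m", frames = 1:3, l0 = 2),
    makeRecord("d1", mother = "m", frames = 4:7, l0 = 1.1),
    makeRecord("d2", mother = "m", frames = 4:7, l0 = 1.0)
  ), framePeriod = dt, nFrames = 7L)
}

# complete binary division tree per colony: every cell lives `span` frames,
# divides synchronously, down to `gens` generations (gens = 0 is just roots)
binaryMovie <- function(gens = 2, span = 3, colonies = 1, dt = 5) {
  recs <- list()
  for (cc in seq_len(colonies)) {
    addCell <- function(id, mother, g) {
      f0 <- g * span + 1L
      recs[[length(recs) + 1L]] <<-
        makeRecord(id, colony = paste0("c", cc), mother = mother,
                   frames = f0:(f0 + span - 1L), l0 = 2 / (1 + g))
      if (g < gens) {
        addCell(paste0(id, ".1"), id, g + 1L)
        addCell(paste0(id, ".2"), id, g + 1L)
      }
    }
    addCell(paste0("c", cc, "_r"), NA_character_, 0L)
  }
  newCellList(recs, framePeriod = dt, nFrames = (gens + 1L) * span)
}

# small seeded simulation used across tests
smallSim <- function(seed = 1, nFrames = 50, nProgenitors = 2, ...) {
  simulateMovie(simConfig(seed = seed, nProgenitors = nProgenitors,
                          nFrames = nFrames, maxCells = 10000, ...))
}
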