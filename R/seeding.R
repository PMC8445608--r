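## Procedural seeding of the mature duct bilayer and the TIC niche.

.PHEN <- c(mature = 0L, TIC = 1L, progenitor = 2L, differentiated = 3L)
.LAYER <- c(luminal = 1L, myoepithelial = 2L, intraductal = 3L)
.STATE <- c(normal = 1L, hypoxic = 2L, necrotic = 3L, lysed = 4L,
            calcified = 5L)

## sphere volume from radius and back
.volOf <- function(r) 4 / 3 * pi * r^3
.radOf <- function(v) (3 * v / (4 * pi))^(1 / 3)

.newCellTable <- function(n = 0L) {
  data.frame(id = integer(n), x = numeric(n), y = numeric(n), z = numeric(n),
             radius = numeric(n), volume = numeric(n), layer = integer(n),
             phenotype = integer(n), cancer = logical(n), er = integer(n),
             state = integer(n), quiescent = logical(n), cycle = numeric(n),
             hypoxia = numeric(n), necrosis = numeric(n), vol0 = numeric(n),
             generation = integer(n), prolif = integer(n),
             mobile = logical(n), capFrozen = logical(n))
}

#' Seed the initial duct cell population
#'
#' Builds the mature duct bilayer as two concentric single-cell-thick rings
#' of spherical agents (inner luminal ring at radius `d/2 + r`, outer
#' myoepithelial ring at `d/2 + 3r`) tiling the full axial length with
#' near-close packing (alternate axial slices are staggered by half the
#' angular pitch). A compact contiguous patch of `nTics` luminal agents at
#' the axial centre is replaced by tumor-initiating cells (TICs); every
#' other agent
#' is assigned ER+ or ER- status stochastically. Each TIC starts at a
#' uniformly random point of its cell cycle.
#'
#' Mature duct agents are immobile (the duct wall is rigid; duct dilation is
#' out of scope) and never proliferate; they consume oxygen, ER+ agents in
#' both layers consume estrogen and produce AREG, and ER- agents consume FGF.
#'
#' @param mesh A [DuctMesh-class] (used for domain checks only).
#' @param geometry The [DuctGeometry-class].
#' @param nTics Number of TICs placed contiguously at the axial centre of the
#'   luminal ring (baseline 5). `0` seeds a healthy, static duct.
#' @param seed Optional integer RNG seed for reproducible seeding; if `NULL`
#'   the current RNG state is used.
#' @param cellRadius Mature cell radius, um (5).
#' @param erPositiveProb Probability that a non-TIC agent is ER+ (0.5; the
#'   ER ratio is not constrained further and is exposed here).
#' @param tauP Cell cycle time, hours (16); TIC cycle clocks start uniform
#'   in `[0, tauP)`.
#' @return A [CellPopulation-class].
#' @examples
#' geom <- ductGeometry(100, axialLength = 200)
#' mesh <- buildDuctMesh(geom, 10)
#' pop <- seedInitialPopulation(mesh, geom, nTics = 5, seed = 1)
#' pop
#' @export
seedInitialPopulation <- function(mesh, geometry, nTics = 5, seed = NULL,
                                  cellRadius = 5, erPositiveProb = 0.5,
                                  tauP = 16) {
  stopifnot(is(geometry, "DuctGeometry"))
  if (nTics < 0) stop("nTics must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  r <- cellRadius
  L <- geometry@axialLength
  d <- geometry@luminalDiameter

  ringRadii <- c(luminal = d / 2 + r, myoepithelial = d / 2 + 3 * r)
  nSlices <- floor(L / (2 * r))
  xs <- -L / 2 + r + (seq_len(nSlices) - 1L) * 2 * r

  buildRing <- function(R, layerCode) {
    nPer <- floor(2 * pi * R / (2 * r))     # non-overlapping angular pitch
    if (nPer < 3) stop("duct too narrow for ring at radius ", R)
    rows <- vector("list", nSlices)
    for (j in seq_len(nSlices)) {
      ang <- 2 * pi * (seq_len(nPer) - 1L) / nPer +
        (j %% 2L) * pi / nPer               # stagger alternate slices
      rows[[j]] <- data.frame(x = xs[j], y = R * cos(ang), z = R * sin(ang),
                              slice = j, layer = layerCode)
    }
    do.call(rbind, rows)
  }
  lum <- buildRing(ringRadii[1L], .LAYER[["luminal"]])
  myo <- buildRing(ringRadii[2L], .LAYER[["myoepithelial"]])
  allpos <- rbind(lum, myo)

  n <- nrow(allpos)
  cells <- .newCellTable(n)
  cells$id <- seq_len(n)
  cells$x <- allpos$x; cells$y <- allpos$y; cells$z <- allpos$z
  cells$radius <- r
  cells$volume <- .volOf(r)
  cells$layer <- allpos$layer
  cells$phenotype <- .PHEN[["mature"]]
  cells$cancer <- FALSE
  cells$state <- .STATE[["normal"]]
  cells$er <- as.integer(runif(n) < erPositiveProb)
  cells$vol0 <- cells$volume
  cells$mobile <- FALSE

  if (nTics > 0) {
    ## compact contiguous patch of luminal agents at the axial centre:
    ## the agent nearest (x=0, angle=0) and its nearest luminal neighbours
    lumIdx <- which(cells$layer == .LAYER[["luminal"]])
    ## central slices can hold nTics agents within a ~2-cell-diameter patch
    capacity <- sum(abs(cells$x[lumIdx]) <= 2 * r + 1e-9)
    if (nTics > capacity)
      stop("nTics (", nTics, ") exceeds luminal-ring capacity (",
           capacity, ") at the axial centre")
    seedCell <- lumIdx[order(abs(cells$x[lumIdx]), abs(atan2(
      cells$z[lumIdx], cells$y[lumIdx])))][1L]
    d2 <- (cells$x[lumIdx] - cells$x[seedCell])^2 +
      (cells$y[lumIdx] - cells$y[seedCell])^2 +
      (cells$z[lumIdx] - cells$z[seedCell])^2
    tics <- lumIdx[order(d2, lumIdx)][seq_len(nTics)]
    cells$phenotype[tics] <- .PHEN[["TIC"]]
    cells$cancer[tics] <- TRUE
    cells$cycle[tics] <- runif(nTics, 0, tauP)
  }

  pop <- new("CellPopulation", cells = cells, geometry = geometry)
  validObject(pop)
  pop
}

#' Export a cell table in the snapshot CSV schema
#'
#' Columns: id, x, y, z, radius_um, layer, phenotype, er_status, state,
#' cycle_h, generation, prolif_count. Living agents blocked by density are
#' reported in state "quiescent".
#'
#' @param cells A [CellPopulation-class] or raw cell data.frame.
#' @return A data.frame in the exchange schema.
#' @export
asCellTable <- function(cells) {
  if (is(cells, "CellPopulation")) cells <- cells@cells
  stateChr <- names(.STATE)[cells$state]
  stateChr[cells$state == .STATE[["normal"]] & cells$quiescent] <- "quiescent"
  data.frame(id = cells$id, x = cells$x, y = cells$y, z = cells$z,
             radius_um = cells$radius,
             layer = names(.LAYER)[cells$layer],
             phenotype = names(.PHEN)[cells$phenotype + 1L],
             er_status = ifelse(cells$er == 1L, "ER+", "ER-"),
             state = stateChr, cycle_h = cells$cycle,
             generation = cells$generation, prolif_count = cells$prolif)
}
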