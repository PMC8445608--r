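# Shared fixtures: small duct domains, hand-built cell tables, and a
# session-level cache so acceptance checks can share expensive simulations.

smallGeometry <- function(d = 100, L = 200) ductGeometry(d, L)

smallMesh <- function(d = 100, L = 200, h = 10) buildDuctMesh(ductGeometry(d, L), h)

# a bare cancer cell table at given positions (mature size, mobile)
cancerCells <- function(pos, radius = 5, state = 1L, er = 1L,
                        phenotype = 2L, mobile = TRUE) {
  pos <- matrix(pos, ncol = 3)
  n <- nrow(pos)
  cells <- dcisim:::.newCellTable(n)
  cells$id <- seq_len(n)
  cells$x <- pos[, 1]; cells$y <- pos[, 2]; cells$z <- pos[, 3]
  cells$radius <- radius
  cells$volume <- 4 / 3 * pi * radius^3
  cells$layer <- 3L
  cells$phenotype <- phenotype
  cells$cancer <- TRUE
  cells$er <- er
  cells$state <- state
  cells$vol0 <- cells$volume
  cells$mobile <- mobile
  cells
}

# FCC-like close packing inside a ball of given radius (spacing = diameter)
fccBall <- function(R = 30, r = 5) {
  a <- 2 * r / sqrt(2)          # fcc lattice constant scaling
  g <- seq(-R, R, by = a)
  pts <- expand.grid(x = g, y = g, z = g)
  pts <- pts[(round((pts$x + pts$y + pts$z) / a) %% 2) == 0, ]
  pts <- pts[sqrt(pts$x^2 + pts$y^2 + pts$z^2) <= R, ]
  as.matrix(pts)
}

# session cache for expensive simulations shared across acceptance blocks
.simCache <- new.env(parent = emptyenv())

cachedRun <- function(key, config) {
  if (!exists(key, envir = .simCache))
    assign(key, runSimulation(config), envir = .simCache)
  get(key, envir = .simCache)
}

baselineConfig <- function(d, days, seed)
  simConfig(luminalDiameter = d, days = days, thresholdsEnabled = FALSE,
            seed = seed)
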