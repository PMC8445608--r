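thr <- list(estrogen = 0.85, fgf = 0.5, enabled = TRUE)

test_that("mitosis gating: cycle clock, binary thresholds, density, potential", {
  cells <- cancerCells(rbind(c(0, 0, 0)))
  noQ <- FALSE
  env1 <- list(estrogen = 1, FGF = 1)
  ## incomplete cycle blocks division
  cells$cycle <- 10
  expect_false(decideMitosis(cells, env1, thr, noQ))
  cells$cycle <- 16
  expect_true(decideMitosis(cells, env1, thr, noQ))
  ## binary step on estrogen for an ER+ agent
  expect_false(decideMitosis(cells, list(estrogen = 0.84, FGF = 1), thr, noQ))
  expect_true(decideMitosis(cells, list(estrogen = 0.86, FGF = 1), thr, noQ))
  expect_true(decideMitosis(cells, list(estrogen = 0.85, FGF = 1), thr, noQ))
  ## ER- agent consults FGF instead
  erNeg <- cells; erNeg$er <- 0L
  expect_false(decideMitosis(erNeg, list(estrogen = 1, FGF = 0.49), thr, noQ))
  expect_true(decideMitosis(erNeg, list(estrogen = 1, FGF = 0.5), thr, noQ))
  ## thresholds disabled: signals ignored
  off <- list(estrogen = 0.85, fgf = 0.5, enabled = FALSE)
  expect_true(decideMitosis(cells, list(estrogen = 0, FGF = 0), off, noQ))
  ## density quiescence blocks
  expect_false(decideMitosis(cells, env1, thr, TRUE))
  ## exhausted progenitor: refused and flagged for differentiation
  worn <- cells; worn$prolif <- 50L
  ok <- decideMitosis(worn, env1, thr, noQ)
  expect_false(ok[1])
  expect_true(attr(ok, "differentiated")[1])
  ## dead or differentiated agents are an error
  dead <- cells; dead$state <- 3L
  expect_error(decideMitosis(dead, env1, thr, noQ), "dead")
})

test_that("mitosis splits volume evenly and respects the lineage hierarchy", {
  cfg <- simConfig()
  set.seed(1)
  parent <- cancerCells(c(0, 0, 0)); parent$cycle <- 16
  V <- parent$volume
  out <- performMitosis(parent, 1L, cfg)
  expect_equal(out$nBirths, 1L)
  expect_equal(nrow(out$cells), 2L)
  expect_equal(out$cells$volume, rep(V / 2, 2))
  expect_equal(out$cells$cycle, c(0, 0))
  expect_equal(out$cells$generation[2], 1L)
  ## progenitor division: symmetric, both sides carry the incremented count
  expect_equal(out$cells$phenotype[2], 2L)
  expect_equal(out$cells$prolif, c(1L, 1L))
  ## daughter placed one (post-division) parent radius away
  d <- sqrt(sum((out$cells[2, c("x", "y", "z")] -
                 out$cells[1, c("x", "y", "z")])^2))
  expect_equal(d, out$cells$radius[1], tolerance = 1e-9)
})

test_that("TIC symmetric-division frequency matches omega_SC = 0.12", {
  cfg <- simConfig()
  set.seed(99)
  n <- 1e4
  tics <- cancerCells(cbind(runif(n, -400, 400), 0, 0), phenotype = 1L)
  tics$cycle <- 16
  out <- performMitosis(tics, seq_len(n), cfg)
  daughters <- out$cells[(n + 1):(2 * n), ]
  symFrac <- mean(daughters$phenotype == 1L)
  expect_equal(symFrac, 0.12, tolerance = 0.01 / 0.12)  # 0.12 +- 0.01
  ## the other daughters are progenitors; parents remain TICs
  expect_true(all(daughters$phenotype %in% c(1L, 2L)))
  expect_true(all(out$cells$phenotype[seq_len(n)] == 1L))
  ## TIC-division daughters draw a fresh ER status around 50/50
  expect_equal(mean(daughters$er), 0.5, tolerance = 0.05)
})

test_that("interphase growth ramps linearly to mature volume", {
  Vm <- 4 / 3 * pi * 125
  baby <- cancerCells(c(0, 0, 0))
  baby$volume <- Vm / 2
  baby$radius <- (3 * baby$volume / (4 * pi))^(1 / 3)
  ## half a cycle after birth: 75% of mature volume
  mid <- growInterphase(baby, dt = 8)
  expect_equal(mid$volume, 0.75 * Vm, tolerance = 1e-12)
  ## a full cycle after birth: exactly mature volume, then unchanged
  full <- growInterphase(baby, dt = 16)
  expect_equal(full$volume, Vm, tolerance = 1e-12)
  expect_equal(growInterphase(full, dt = 5)$volume, Vm)
  expect_equal(full$radius, 5, tolerance = 1e-12)
})

test_that("death cascade follows the timer table with hypoxia recovery", {
  cfg <- simConfig()
  V0 <- 4 / 3 * pi * 125      # 523.6 um^3 mature volume
  cell <- cancerCells(c(0, 0, 0))

  ## 12 h continuously below threshold (33.3 mmHg) -> necrosis
  x <- cell
  for (i in 1:119) x <- updateDeathCascade(x, 25, 0.1, cfg)$cells
  expect_equal(x$state, 2L)                  # 11.9 h: still (just) hypoxic
  x <- updateDeathCascade(x, 25, 0.1, cfg)$cells
  expect_equal(x$state, 3L)                  # 12 h: necrotic
  expect_equal(x$vol0, V0)

  ## 11 h hypoxia, recovery, then 11 h more: no necrosis (clock resets)
  y <- cell
  for (i in 1:110) y <- updateDeathCascade(y, 25, 0.1, cfg)$cells
  expect_equal(y$state, 2L)
  y <- updateDeathCascade(y, 40, 0.1, cfg)$cells
  expect_equal(y$state, 1L)
  expect_equal(y$hypoxia, 0)
  for (i in 1:110) y <- updateDeathCascade(y, 25, 0.1, cfg)$cells
  expect_equal(y$state, 2L)   # hypoxic again but alive

  ## lysis swells to 2x pre-lysis volume, residual condenses to 30%
  z <- x                      # freshly necrotic
  for (i in 1:59) z <- updateDeathCascade(z, 25, 0.1, cfg)$cells
  expect_equal(z$state, 3L)
  expect_equal(z$volume, V0 * (1 + 5.9 / 6), tolerance = 1e-6)  # 5.9 h in
  z <- updateDeathCascade(z, 25, 0.1, cfg)$cells             # 6 h: burst
  expect_equal(z$state, 4L)
  expect_equal(z$volume, 0.30 * V0, tolerance = 1e-9)        # 157.1 um^3
  ## calcification at 14 days after necrosis onset
  for (i in seq_len(3360 - 61)) z <- updateDeathCascade(z, 25, 0.1, cfg)$cells
  expect_equal(z$state, 4L)
  z <- updateDeathCascade(z, 25, 0.1, cfg)$cells
  expect_equal(z$state, 5L)
  expect_equal(z$volume, 0.30 * V0, tolerance = 1e-9)

  expect_error(updateDeathCascade(cell, -5, 0.1, cfg), "negative oxygen")
})

test_that("residual material within one node region merges to a single agent", {
  mesh <- smallMesh(100, 100)
  two <- cancerCells(rbind(c(1, 1, 0), c(-1, 0, 1)), state = 4L,
                     mobile = FALSE)
  two$volume <- c(100, 200); two$vol0 <- c(300, 400)
  out <- mergeResiduals(two, mesh)
  expect_equal(out$nMerged, 1L)
  expect_equal(nrow(out$cells), 1L)
  expect_equal(out$cells$volume, 300)
  expect_equal(out$cells$vol0, 700)
  ## volume-weighted centroid
  expect_equal(out$cells$x, (1 * 100 - 1 * 200) / 300)
  ## far-apart residuals stay separate
  far <- cancerCells(rbind(c(0, 0, 0), c(40, 0, 0)), state = 4L,
                     mobile = FALSE)
  expect_equal(mergeResiduals(far, mesh)$nMerged, 0L)
})

test_that("density quiescence separates packed interiors from free edges", {
  ## isolated agent: never quiescent
  one <- cancerCells(c(0, 0, 0))
  expect_false(evaluateQuiescence(one))
  ## close-packed ball: centre agent has 12 touching neighbours and is
  ## quiescent; an agent at the surface with a free hemisphere is not
  ball <- fccBall(R = 25)
  cells <- cancerCells(ball)
  q <- evaluateQuiescence(cells)
  centre <- which.min(rowSums(ball^2))
  edge <- which.max(ball[, 1])
  cnt <- dcisim:::neighbor_count_cpp(ball, rep(TRUE, nrow(ball)), 10.001)
  expect_gte(cnt[centre], 12)       # touching shell of a close packing
  expect_true(q[centre])
  expect_false(q[edge])
  ## dead agents are never quiescent
  cells$state[centre] <- 3L
  expect_false(evaluateQuiescence(cells)[centre])
})
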