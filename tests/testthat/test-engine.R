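shortConfig <- function(...) {
  args <- modifyList(list(luminalDiameter = 100, axialLength = 300, days = 1,
                          thresholdsEnabled = FALSE, seed = 5), list(...))
  do.call(simConfig, args)
}

test_that("a duct seeded without TICs is static for all time", {
  cfg <- shortConfig(nTics = 0)
  res <- runSimulation(cfg)
  m <- metricsTable(res)
  expect_true(all(m$dcis_count == 0))
  expect_true(all(m$axial_extent == 0))
  expect_true(all(m$n_hypoxic == 0))
  ## final agent positions identical to the seeded configuration
  set.seed(5)
  ref <- cellTable(seedInitialPopulation(
    buildDuctMesh(ductGeometry(100, 300), 10), ductGeometry(100, 300),
    nTics = 0, seed = NULL))
  fin <- cellTable(res)
  expect_identical(fin[, c("x", "y", "z", "er", "state")],
                   ref[, c("x", "y", "z", "er", "state")])
})

test_that("runs are byte-identical for a fixed seed and diverge across seeds", {
  a <- runSimulation(shortConfig())
  b <- runSimulation(shortConfig())
  expect_identical(metricsTable(a), metricsTable(b))
  expect_identical(cellTable(a), cellTable(b))
  expect_identical(a@bookkeeping, b@bookkeeping)
  c <- runSimulation(shortConfig(seed = 6))
  expect_false(identical(cellTable(a)$x, cellTable(c)$x))
})

test_that("with quiescence off and signals saturated the population doubles
           on the cell-cycle clock (per-lineage timer oracle)", {
  cfg <- shortConfig(days = 2.5, quiescenceEnabled = FALSE)
  res <- runSimulation(cfg)
  m <- metricsTable(res)
  ## reconstruct the seeded TIC cycle phases from the same RNG stream
  set.seed(5)
  pop <- seedInitialPopulation(buildDuctMesh(ductGeometry(100, 300), 10),
                               ductGeometry(100, 300), nTics = 5,
                               seed = NULL)
  u <- cellTable(pop)$cycle[cellTable(pop)$phenotype == 1L]
  oracle <- function(Tsteps) {
    sum(vapply(u, function(ui) {
      s1 <- ceiling((16 - ui) / 0.1 - 1e-9)   # step of first division
      if (Tsteps < s1) 1 else 2^(1 + floor((Tsteps - s1) / 160))
    }, numeric(1)))
  }
  for (k in seq_len(nrow(m))) {
    Tsteps <- round(m$time_days[k] * 240)
    ## allow one step of floating-point timer slack
    expect_gte(m$dcis_count[k], oracle(Tsteps - 1))
    expect_lte(m$dcis_count[k], oracle(Tsteps + 1))
  }
  ## and the classical envelope: N(t) ~ 5 * 2^(t/16h)
  Tend <- tail(m$time_days, 1) * 24
  expect_lt(abs(log2(tail(m$dcis_count, 1) / (5 * 2^(Tend / 16)))), 1)
})

test_that("population bookkeeping balances births, deaths and merges", {
  cfg <- shortConfig(days = 2.5, quiescenceEnabled = FALSE)
  res <- runSimulation(cfg)
  bk <- res@bookkeeping
  m <- metricsTable(res)
  ## audit up to the last recorded step (recording is daily)
  lastStep <- round(tail(m$time_days, 1) * 240)
  bk <- bk[bk$step <= lastStep, ]
  expect_equal(tail(m$dcis_count, 1),
               5L + sum(bk$births) - sum(bk$necroses))
  expect_equal(tail(m$total_cancer, 1), 5L + sum(bk$births) - sum(bk$merges))
  ## axial extent is non-decreasing
  expect_true(all(diff(m$axial_extent) >= 0))
})

test_that("snapshots round-trip and the manifest hash tracks the config", {
  dir <- withr::local_tempdir()
  geom <- ductGeometry(100, 200)
  mesh <- buildDuctMesh(geom, 10)
  pop <- seedInitialPopulation(mesh, geom, nTics = 5, seed = 2)
  o2 <- makeField(mesh, "oxygen", 2.5e-6, bcValue = 100)
  files <- writeSnapshot(pop, list(o2), t = 0, dir = dir)
  expect_true(all(file.exists(files)))
  back <- readCellSnapshot(files[1])
  expect_equal(back, asCellTable(pop), tolerance = 1e-12)
  ## field CSV carries one value per node
  fcsv <- read.csv(files[2])
  expect_equal(nrow(fcsv), nrow(nodeCoordinates(mesh)))
  expect_equal(fcsv$value, fieldValues(o2))
  ## VTK header declares the full structured grid
  vtk <- readLines(files[3], n = 10)
  expect_match(vtk[4], "STRUCTURED_POINTS")

  cfg1 <- simConfig(seed = 1)
  cfg2 <- simConfig(seed = 2)
  expect_identical(configHash(cfg1), configHash(simConfig(seed = 1)))
  expect_false(identical(configHash(cfg1), configHash(cfg2)))
})

test_that("a zero-day run snapshots exactly the seeded population", {
  dir <- withr::local_tempdir()
  cfg <- shortConfig(days = 0)
  res <- runSimulation(cfg, snapshotDir = dir)
  snap <- readCellSnapshot(list.files(dir, "^cells_", full.names = TRUE)[1])
  set.seed(5)
  ref <- asCellTable(seedInitialPopulation(
    buildDuctMesh(ductGeometry(100, 300), 10), ductGeometry(100, 300),
    nTics = 5, seed = NULL))
  expect_equal(snap, ref, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$config_hash, configHash(cfg))
})

test_that("configuration rejects unknown or invalid parameters", {
  expect_error(simConfig(nonsense = 1), "unknown parameter")
  expect_error(simConfig(tauP = -1), "non-negative")
  expect_error(simConfig(omegaSC = 2), "omegaSC")
  cfg <- simConfig()
  expect_equal(simParam(cfg, "tauP"), 16)
  expect_equal(simParam(cfg, "Pmax"), 50)
  expect_equal(simParam(cfg, "omegaSC"), 0.12)
  expect_equal(simParam(cfg, "hypoxiaThreshold"), 100 / 3)
  expect_error(simParam(cfg, "nope"), "unknown")
  simParam(cfg, "tauP") <- 12
  expect_equal(simParam(cfg, "tauP"), 12)
})
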