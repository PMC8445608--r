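test_that("nearest-node assignment matches the brute-force oracle", {
  mesh <- smallMesh(100, 100)
  co <- nodeCoordinates(mesh)
  ## an agent exactly at a node maps to that node
  ids <- c(5L, 101L, 750L)
  expect_equal(assignAgentsToNodes(co[ids, , drop = FALSE], mesh), ids)
  ## random positions against exhaustive argmin with lowest-index ties
  set.seed(11)
  n <- 300
  pts <- cbind(runif(n, -45, 45), runif(n, -40, 40), runif(n, -40, 40))
  got <- assignAgentsToNodes(pts, mesh)
  oracle <- vapply(seq_len(n), function(i) {
    d2 <- (co[, 1] - pts[i, 1])^2 + (co[, 2] - pts[i, 2])^2 +
      (co[, 3] - pts[i, 3])^2
    which(d2 <= min(d2) + 1e-12)[1L]
  }, integer(1))
  expect_equal(got, oracle)
})

test_that("equidistant agents map to the lowest node index deterministically", {
  mesh <- smallMesh(100, 100)
  co <- nodeCoordinates(mesh)
  ## midpoint between two axially adjacent interior nodes
  int <- boundaryNodes(mesh, "interior")
  i <- int[which(co[int, 1] < 40)][1]
  j <- which(co[, 1] == co[i, 1] + 10 & co[, 2] == co[i, 2] &
             co[, 3] == co[i, 3])
  mid <- (co[i, ] + co[j, ]) / 2
  expect_equal(assignAgentsToNodes(rbind(mid), mesh), min(i, j))
})

test_that("agents outside the domain are rejected with their index", {
  mesh <- smallMesh(100, 100)
  expect_error(assignAgentsToNodes(rbind(c(0, 100, 0)), mesh), "outside")
  expect_error(senseEnvironment(rbind(c(500, 0, 0)),
                                makeField(mesh, "oxygen", 2.5e-6,
                                          bcValue = 100)),
               "outside")
})

test_that("deposition lumps each agent at its node, scaled by region volume", {
  mesh <- smallMesh(100, 100)
  cfg <- simConfig()
  ## no agents -> zero deposit everywhere
  none <- dcisim:::.newCellTable(0)
  dep0 <- depositReactions(none, integer(), mesh, agentRates(none, cfg))
  expect_true(all(dep0$o2Clearance == 0))

  ## one healthy vs one cancer agent: 4.5x the oxygen clearance at one node
  healthy <- cancerCells(c(0, 0, 0)); healthy$cancer <- FALSE
  cancer <- cancerCells(c(0, 0, 0))
  mapH <- assignAgentsToNodes(healthy, mesh)
  rH <- agentRates(healthy, cfg); rC <- agentRates(cancer, cfg)
  depH <- depositReactions(healthy, mapH, mesh, rH)
  depC <- depositReactions(cancer, mapH, mesh, rC)
  k <- mapH[1]
  expect_equal(depH$o2Clearance[k],
               simParam(cfg, "lambdaH") * simParam(cfg, "o2UptakeScale") /
                 regionVolumes(mesh)[k])
  expect_equal(sum(depH$o2Clearance != 0), 1L)
  expect_equal(depC$o2Clearance[k] / depH$o2Clearance[k], 4.5)

  ## many agents: nodal sums equal brute-force accumulation; conservation
  set.seed(21)
  n <- 200
  pts <- cbind(runif(n, -45, 45), runif(n, -40, 40), runif(n, -40, 40))
  cells <- cancerCells(pts, er = rep(c(1L, 0L), length.out = n))
  map <- assignAgentsToNodes(cells, mesh)
  rates <- agentRates(cells, cfg)
  dep <- depositReactions(cells, map, mesh, rates)
  brute <- numeric(nrow(nodeCoordinates(mesh)))
  for (i in seq_len(n))
    brute[map[i]] <- brute[map[i]] + rates$o2Clearance[i]
  expect_equal(dep$o2Clearance, brute / regionVolumes(mesh))
  for (sp in names(rates))
    expect_equal(sum(dep[[sp]] * regionVolumes(mesh)), sum(rates[[sp]]))

  ## dead agents neither consume nor produce
  dead <- cancerCells(pts[1:5, ], state = 3L)
  expect_true(all(as.matrix(agentRates(dead, cfg)) == 0))
})

test_that("trilinear interpolation is exact on linear fields", {
  mesh <- smallMesh(100, 100)
  co <- nodeCoordinates(mesh)
  ## nodal values are returned exactly
  f <- makeField(mesh, "test", 1e-6, "neumann",
                 initial = runif(nrow(co)))
  got <- senseEnvironment(co[c(3, 77, 1000), ], f)
  expect_equal(got, fieldValues(f)[c(3, 77, 1000)], tolerance = 1e-12)
  ## linear field reproduced at arbitrary interior points
  lin <- function(x, y, z) 60 + 0.3 * x - 0.2 * y + 0.05 * z
  g <- makeField(mesh, "lin", 1e-6, "neumann",
                 initial = lin(co[, 1], co[, 2], co[, 3]))
  ## ghost-filled region breaks linearity outside the mask: probe well inside
  set.seed(31)
  pts <- cbind(runif(50, -30, 30), runif(50, -25, 25), runif(50, -25, 25))
  expect_equal(senseEnvironment(pts, g), lin(pts[, 1], pts[, 2], pts[, 3]),
               tolerance = 1e-9)
  ## uniform field returns the constant everywhere
  u <- makeField(mesh, "unif", 1e-6, "neumann",
                 initial = rep(3.14, nrow(co)))
  expect_equal(senseEnvironment(pts, u), rep(3.14, 50))
})

test_that("a consuming agent lowers the concentration at its own location", {
  mesh <- smallMesh(100, 100)
  cfg <- simConfig()
  cells <- cancerCells(c(5, 3, -2))
  map <- assignAgentsToNodes(cells, mesh)
  dep <- depositReactions(cells, map, mesh, agentRates(cells, cfg))
  f0 <- makeField(mesh, "oxygen", 2.5e-6, bcValue = 100)
  f1 <- solveFieldSteady(f0, list(uptake = dep$o2Clearance), tol = 1e-8)
  at <- function(f) senseEnvironment(cells, f)
  expect_lt(at(f1), at(f0))
})
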