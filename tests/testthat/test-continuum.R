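test_that("uniform Dirichlet field with no reaction is a steady state", {
  mesh <- smallMesh()
  f <- makeField(mesh, "oxygen", D = 2.5e-6, bcValue = 100)
  g <- stepDiffusion(f, NULL, dt = maxStableDt(f))
  expect_equal(fieldValues(g), fieldValues(f), tolerance = 1e-12)
})

test_that("steady radial profile matches the closed-form cylinder solution", {
  ## uniform volumetric sink q, Dirichlet C at the outer radius:
  ## u(rho) = C - q/(4D) (Ro^2 - rho^2)
  geom <- smallGeometry(); mesh <- buildDuctMesh(geom, 10)
  D <- 2.5e-6; Dum <- D * 1e8; C <- 100; Ro <- outerRadius(geom); q <- 0.5
  f <- makeField(mesh, "oxygen", D, bcValue = C)
  f <- solveFieldSteady(f, list(production = rep(-q, nrow(nodeCoordinates(mesh)))),
                        tol = 1e-9, maxSweeps = 5e4)
  co <- nodeCoordinates(mesh)
  rho2 <- co[, 2]^2 + co[, 3]^2
  exact <- C - q / (4 * Dum) * (Ro^2 - rho2)
  int <- boundaryNodes(mesh, "interior")
  relErr <- abs(fieldValues(f)[int] - exact[int]) / exact[int]
  expect_lt(max(relErr), 0.02)
})

test_that("Dirichlet boundary values are re-imposed after every operation", {
  mesh <- smallMesh()
  f <- makeField(mesh, "oxygen", D = 2.5e-6, bcValue = 100)
  n <- length(fieldValues(f))
  f <- solveFieldSteady(f, list(uptake = rep(1e-3, n)))
  expect_true(all(fieldValues(f)[boundaryNodes(mesh, "outer_radial")] == 100))
  f <- stepDiffusion(f, list(uptake = rep(1e-3, n)), dt = maxStableDt(f))
  expect_true(all(fieldValues(f)[boundaryNodes(mesh, "outer_radial")] == 100))
})

test_that("degradation follows the scalar exponential-decay oracle", {
  mesh <- smallMesh()
  f <- makeField(mesh, "AREG", D = 3.18e-7, bcType = "neumann",
                 initial = runif(nrow(nodeCoordinates(mesh)), 0.5, 2))
  expect_equal(fieldValues(applyDegradation(f, 0, 100)), fieldValues(f))
  h <- applyDegradation(f, kdeg = log(2) / 100, dt = 100)
  expect_equal(fieldValues(h), fieldValues(f) / 2, tolerance = 1e-12)
  ## arbitrary rate against per-node ODE u' = -k u
  k <- 3.7e-4; dt <- 537
  g <- applyDegradation(f, k, dt)
  expect_equal(fieldValues(g), fieldValues(f) * exp(-k * dt),
               tolerance = 1e-12)
})

test_that("FGF boundary is the previous step's AREG at the same nodes", {
  mesh <- smallMesh()
  n <- nrow(nodeCoordinates(mesh))
  areg <- makeField(mesh, "AREG", 3.18e-7, "neumann", initial = numeric(n))
  fgf <- makeField(mesh, "FGF", 3.18e-7, "dirichlet", bcValue = 0)
  ## AREG identically zero -> all FGF boundary values zero
  fgf0 <- updateFgfBoundary(fgf, areg)
  expect_true(all(fieldValues(fgf0)[boundaryNodes(mesh, "outer_radial")] == 0))
  ## a specific AREG boundary value maps through identically
  br <- boundaryNodes(mesh, "outer_radial")
  areg@values[br[3]] <- 0.7
  fgf1 <- updateFgfBoundary(fgf, areg)
  expect_equal(fieldValues(fgf1)[br[3]], 0.7)
  ## interior untouched
  int <- boundaryNodes(mesh, "interior")
  expect_equal(fieldValues(fgf1)[int], fieldValues(fgf)[int])
  ## sustained constant AREG boundary relaxes interior FGF to that constant
  areg@values[] <- 0.6
  fgf2 <- solveFieldSteady(updateFgfBoundary(fgf, areg), tol = 1e-10)
  expect_equal(max(abs(fieldValues(fgf2) - 0.6)), 0, tolerance = 1e-6)
  ## mismatched meshes are rejected
  other <- makeField(smallMesh(L = 100), "AREG", 3.18e-7, "neumann")
  expect_error(updateFgfBoundary(fgf, other), "mismatch")
})

test_that("quasi-steady solve agrees with the explicit time-stepped solution", {
  geom <- smallGeometry(100, 100); mesh <- buildDuctMesh(geom, 10)
  n <- nrow(nodeCoordinates(mesh))
  set.seed(5)
  uptake <- ifelse(runif(n) < 0.3, 0.05, 0)    # patchy consumption
  fQS <- makeField(mesh, "oxygen", 2.5e-6, bcValue = 100)
  fQS <- solveFieldSteady(fQS, list(uptake = uptake), tol = 1e-9,
                          maxSweeps = 5e4)
  fEX <- makeField(mesh, "oxygen", 2.5e-6, bcValue = 100)
  fEX <- advanceField(fEX, list(uptake = uptake), dt = 120)  # ~3 diffusion times
  relErr <- abs(fieldValues(fEX) - fieldValues(fQS)) /
    pmax(fieldValues(fQS), 1)
  expect_lt(max(relErr), 0.02)
})

test_that("explicit stepping enforces stability, positivity and NaN checks", {
  mesh <- smallMesh()
  f <- makeField(mesh, "oxygen", 2.5e-6, bcValue = 100)
  expect_error(stepDiffusion(f, NULL, dt = 10 * maxStableDt(f) / 0.2),
               "maximum stable dt")
  n <- length(fieldValues(f))
  expect_error(stepDiffusion(f, list(uptake = rep(-1, n)), maxStableDt(f)),
               ">= 0")
  ## huge constant sink cannot push concentrations negative
  g <- f
  for (i in 1:20)
    g <- stepDiffusion(g, list(production = rep(-1e3, n)), maxStableDt(g))
  expect_true(all(fieldValues(g) >= 0))
})

test_that("steady oxygen profile is grid-converged (halved spacing, <2% RMS)", {
  geom <- smallGeometry(100, 100)
  probe <- expand.grid(x = c(-20, 0, 20), y = seq(-40, 40, 20),
                       z = seq(-40, 40, 20))
  vals <- lapply(c(10, 5), function(h) {
    mesh <- buildDuctMesh(geom, h)
    n <- nrow(nodeCoordinates(mesh))
    f <- makeField(mesh, "oxygen", 2.5e-6, bcValue = 100)
    f <- solveFieldSteady(f, list(production = rep(-0.5, n)), tol = 1e-9,
                          maxSweeps = 1e5)
    senseEnvironment(as.matrix(probe), f)
  })
  rms <- sqrt(mean((vals[[1]] - vals[[2]])^2)) / mean(vals[[2]])
  expect_lt(rms, 0.02)
})
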