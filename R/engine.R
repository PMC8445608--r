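## Simulation configuration and the coupled time loop.

.defaultParams <- function() list(
  ## geometry (um)
  luminalDiameter   = 100,
  axialLength       = 1000,
  layerThickness    = 10,
  meshSpacing       = 10,
  ## cell parameters
  cellRadius        = 5,      # mature mammary cell radius, um
  tauP              = 16,     # cell cycle time, h
  fp                = NA,     # proliferation frequency floor, h (>= tauP; NA = tauP)
  Pmax              = 50,     # progenitor proliferation cycles before differentiation
  omegaSC           = 0.12,   # stem cell symmetric proliferation probability
  omegaP            = 1.0,    # progenitor symmetric proliferation probability
  nTics             = 5,
  erPositiveProb    = 0.5,
  ## oxygen
  DOxygen           = 2.5e-6, # cm^2/s
  bloodO2           = 100,    # mmHg, constant Dirichlet at the duct surface
  lambdaH           = 45,     # healthy-cell oxygen consumption, attoMol/cell/s
  o2UptakeScale     = 0.5,    # clearance um^3/s per (attoMol/cell/s); effective
                              # inverse solubility, calibrated to the oxygen
                              # penetration depth (see vignette)
  cancerO2Factor    = 4.5,    # cancer cell oxygen consumption, x healthy
  hypoxiaThreshold  = 100/3,  # mmHg (1/3 normoxia)
  kdegOxygen        = 1e-5,   # molecular sinks, 1/s (small)
  ## estrogen (normalized: boundary = 1)
  DEstrogen         = 2.45e-6,
  estrogenBoundary  = 1.0,
  estrogenUptake    = 120,    # ER+ receptor clearance, um^3/s
  kdegEstrogen      = 1e-5,
  ## AREG (normalized)
  DAreg             = 3.18e-7,
  aregProduction    = 0.39,   # ER+ production, conc um^3/s per cell
  aregDegradation   = 2e-4,   # 1/s; sets the AREG equilibrium level
  ## FGF (normalized; boundary derived from AREG)
  DFgf              = 3.18e-7,
  fgfUptake         = 40,     # ER- receptor clearance, um^3/s
  kdegFgf           = 1e-5,
  ## signaling thresholds (normalized concentrations)
  estrogenThreshold = 0.85,
  fgfThreshold      = 0.5,
  thresholdsEnabled = TRUE,
  ## density-induced quiescence
  quiescenceEnabled = TRUE,
  quiescenceRadius  = 4,      # sensing radius, mature cell radii
  quiescenceLimit   = 30,     # N_q: neighbours above this induce quiescence
  quiescentClockPause = TRUE, # cycle clock pauses while density-quiescent
  ## death cascade
  tauN              = 12,     # h of sustained hypoxia to necrosis
  tauL              = 6,      # h lysis duration
  tauC              = 336,    # h (14 d) necrosis onset to calcification
  lysisSwell        = 1.0,    # fractional volume increase during lysis
  calcFrac          = 0.30,   # calcified volume fraction of pre-lysis volume
  ## engine
  abmDt             = 0.1,    # h
  days              = 12,
  recordIntervalHours = 24,
  seed              = 1,
  ## mechanics
  overlapTolerance  = 0.1,    # um
  mechanicsMaxIter  = 50,
  ## continuum solver
  fieldStride       = 5,      # steps between field re-solves when conditions
                              # are slack (oxygen returns to every-step
                              # resolution whenever hypoxia is near)
  solverTol         = 1e-5,
  solverMaxSweeps   = 400,
  solverInitSweeps  = 20000,
  solverOmega       = NA  # NULL/NA: grid-optimal
)

#' Create a simulation configuration
#'
#' All parameters default to the literature baseline values; any can be
#' overridden by name. Print the object to see every default.
#'
#' @param ... Named parameter overrides (see [SimConfig-class]; unknown names
#'   are an error).
#' @return A [SimConfig-class].
#' @examples
#' cfg <- simConfig(luminalDiameter = 150, days = 2, seed = 7)
#' simParam(cfg, "tauP")
#' @export
simConfig <- function(...) {
  over <- list(...)
  def <- .defaultParams()
  unknown <- setdiff(names(over), names(def))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- modifyList(def, over)
  num <- c("luminalDiameter", "axialLength", "layerThickness", "meshSpacing",
           "cellRadius", "tauP", "Pmax", "omegaSC", "omegaP", "nTics",
           "abmDt", "days", "tauN", "tauL", "tauC")
  for (nm in num)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop("parameter ", nm, " must be a single non-negative number")
  if (p$omegaSC < 0 || p$omegaSC > 1) stop("omegaSC must be in [0, 1]")
  if (p$estrogenThreshold < 0 || p$fgfThreshold < 0)
    stop("thresholds must be >= 0")
  new("SimConfig", params = p)
}

.cycleGate <- function(p) max(p$tauP, p$fp, na.rm = TRUE)

#' Run the coupled hybrid simulation
#'
#' Per agent time step, in order: (1) continuum fields advance under the
#' current agent deposits, with the FGF boundary refreshed from the previous
#' step's AREG; (2) living agents sense their interpolated microenvironment;
#' (3) the death cascade advances and residual material merges; (4) density
#' quiescence is re-evaluated; (5) cycle clocks advance and interphase
#' growth proceeds; (6) mitosis decisions and divisions; (7) overlap
#' relaxation and duct confinement; (8) deposits are recomputed for the next
#' step. Metrics are recorded at the configured cadence (daily by default).
#' The run is fully reproducible for a fixed seed.
#'
#' @param config A [SimConfig-class].
#' @param snapshotDir Optional directory for cell-table/field snapshots at
#'   each recording time (plus a manifest); `NULL` disables snapshots.
#' @param progress Print a line per recording time.
#' @return A [SimulationResult-class].
#' @export
runSimulation <- function(config, snapshotDir = NULL, progress = FALSE) {
  stopifnot(is(config, "SimConfig"))
  p <- config@params
  t0 <- proc.time()[["elapsed"]]
  set.seed(p$seed %% .Machine$integer.max)
  geom <- ductGeometry(p$luminalDiameter, p$axialLength, p$layerThickness)
  mesh <- buildDuctMesh(geom, p$meshSpacing)
  pop <- seedInitialPopulation(mesh, geom, nTics = p$nTics, seed = NULL,
                               cellRadius = p$cellRadius,
                               erPositiveProb = p$erPositiveProb,
                               tauP = .cycleGate(p))
  cells <- pop@cells

  o2  <- makeField(mesh, "oxygen",   p$DOxygen,   "dirichlet", p$bloodO2,
                   p$kdegOxygen)
  est <- makeField(mesh, "estrogen", p$DEstrogen, "dirichlet",
                   p$estrogenBoundary, p$kdegEstrogen)
  areg <- makeField(mesh, "AREG",    p$DAreg,     "neumann", 0,
                    p$aregDegradation)
  fgf <- makeField(mesh, "FGF",      p$DFgf,      "dirichlet", 0, p$kdegFgf)

  thresholds <- list(estrogen = p$estrogenThreshold, fgf = p$fgfThreshold,
                     enabled = isTRUE(p$thresholdsEnabled))
  dtH <- p$abmDt
  dtS <- dtH * 3600
  nSteps <- ceiling(p$days * 24 / dtH)
  recEvery <- max(1L, round(p$recordIntervalHours / dtH))

  omega <- if (is.na(p$solverOmega)) .optimalOmega(mesh) else p$solverOmega
  ## when thresholding is disabled the signaling fields gate no rule and are
  ## refreshed only at recording times; when enabled they are re-solved every
  ## `fieldStride` steps (signals gate 16-hour mitosis decisions, so
  ## sub-hour staleness is immaterial). Oxygen follows the same stride until
  ## any agent approaches the hypoxia threshold, then returns to every-step
  ## resolution for the death-cascade clocks.
  stride <- max(1L, as.integer(p$fieldStride))
  lastSignalStep <- 0L
  o2Guard <- FALSE
  map <- assignAgentsToNodes(cells, mesh)
  dep <- depositReactions(cells, map, mesh, agentRates(cells, config))
  ## oxygen at the node of the first necrotic agent, per step from onset
  ## (the necrosis-as-hypoxia-relief observable)
  necroseNode <- NA_integer_
  necroseO2 <- numeric()

  ## initial solve (cold start gets a generous sweep budget)
  o2  <- solveFieldSteady(o2,  list(uptake = dep$o2Clearance),
                          p$solverTol, p$solverInitSweeps, omega)
  est <- solveFieldSteady(est, list(uptake = dep$estClearance),
                          p$solverTol, p$solverInitSweeps, omega)
  ## ghost-filled full-grid arrays for interpolation, refreshed on solve
  arrO2 <- expandToGrid(mesh, o2@values)
  arrEst <- expandToGrid(mesh, est@values)
  arrFgf <- expandToGrid(mesh, fgf@values)
  senseArr <- function(arr, pts)
    trilinear_cpp(arr, mesh@dims, mesh@origin, mesh@spacing, pts)

  extPos <- extNeg <- 0
  nRec <- floor(nSteps / recEvery) + 1L
  metrics <- list(time_days = numeric(nRec), dcis_count = integer(nRec),
                  total_cancer = integer(nRec), axial_extent = numeric(nRec),
                  extent_pos = numeric(nRec), extent_neg = numeric(nRec),
                  n_quiescent = integer(nRec), n_hypoxic = integer(nRec),
                  n_necrotic = integer(nRec), n_lysed = integer(nRec),
                  n_calcified = integer(nRec), calcified_volume = numeric(nRec),
                  n_erpos = integer(nRec), n_erneg = integer(nRec))
  book <- list(step = integer(nSteps), births = integer(nSteps),
               necroses = integer(nSteps), merges = integer(nSteps),
               maxOverlap = numeric(nSteps), mechConverged = logical(nSteps),
               minO2 = numeric(nSteps))
  snapFiles <- character()

  recordRow <- function(k, tH) {
    alive <- cells$state %in% .aliveStates()
    liveCa <- alive & cells$cancer
    intra <- liveCa & cells$layer == .LAYER[["intraductal"]]
    if (any(intra)) {
      extPos <<- max(extPos, max(cells$x[intra]))
      extNeg <<- max(extNeg, max(-cells$x[intra]))
    }
    metrics$time_days[k] <<- tH / 24
    metrics$dcis_count[k] <<- sum(liveCa)
    metrics$total_cancer[k] <<- sum(cells$cancer)
    metrics$axial_extent[k] <<- extPos + extNeg
    metrics$extent_pos[k] <<- extPos
    metrics$extent_neg[k] <<- extNeg
    metrics$n_quiescent[k] <<- sum(cells$quiescent & liveCa)
    metrics$n_hypoxic[k] <<- sum(cells$state == .STATE[["hypoxic"]])
    metrics$n_necrotic[k] <<- sum(cells$state == .STATE[["necrotic"]])
    metrics$n_lysed[k] <<- sum(cells$state == .STATE[["lysed"]])
    metrics$n_calcified[k] <<- sum(cells$state == .STATE[["calcified"]])
    metrics$calcified_volume[k] <<-
      sum(cells$volume[cells$state == .STATE[["calcified"]]])
    metrics$n_erpos[k] <<- sum(liveCa & cells$er == 1L)
    metrics$n_erneg[k] <<- sum(liveCa & cells$er == 0L)
    if (!is.null(snapshotDir)) {
      fieldsNow <- list(o2, est, areg, fgf)
      snapFiles <<- c(snapFiles,
                      writeSnapshot(cells, fieldsNow, tH, snapshotDir))
    }
    if (progress)
      message(sprintf("day %5.1f: %d DCIS cells, extent %.0f um",
                      tH / 24, metrics$dcis_count[k], metrics$axial_extent[k]))
  }
  recordRow(1L, 0)

  step <- 0L
  while (step < nSteps) {
    step <- step + 1L
    tH <- step * dtH
    stepResult <- tryCatch({
      ## (1) fields under current deposits; FGF boundary from previous AREG
      if (o2Guard || step %% stride == 0L || step %% recEvery == 0L) {
        o2 <- solveFieldSteady(o2, list(uptake = dep$o2Clearance),
                               p$solverTol, p$solverMaxSweeps, omega)
        arrO2 <- expandToGrid(mesh, o2@values)
      }
      if ((thresholds$enabled && step %% stride == 0L) ||
          step %% recEvery == 0L) {
        fgf <- updateFgfBoundary(fgf, areg)
        est <- solveFieldSteady(est, list(uptake = dep$estClearance),
                                p$solverTol, p$solverMaxSweeps, omega)
        fgf <- solveFieldSteady(fgf, list(uptake = dep$fgfClearance),
                                p$solverTol, p$solverMaxSweeps, omega)
        areg <- stepDiffusionImplicit(areg,
                                      list(production = dep$aregProduction),
                                      dtS * (step - lastSignalStep),
                                      p$solverTol, p$solverMaxSweeps, omega)
        lastSignalStep <- step
        arrEst <- expandToGrid(mesh, est@values)
        arrFgf <- expandToGrid(mesh, fgf@values)
      }

      ## (2) sense (cached ghost-filled arrays; agents stay confined, so the
      ## domain check lives in the node assignment below)
      alive <- cells$state <= 2L
      env <- list(oxygen = rep(NA_real_, length(alive)),
                  estrogen = rep(NA_real_, length(alive)),
                  FGF = rep(NA_real_, length(alive)))
      if (any(alive)) {
        pts <- cbind(cells$x, cells$y, cells$z)[alive, , drop = FALSE]
        sensedO2 <- senseArr(arrO2, pts)
        env$oxygen[alive] <- sensedO2
        if (thresholds$enabled) {
          env$estrogen[alive] <- senseArr(arrEst, pts)
          env$FGF[alive] <- senseArr(arrFgf, pts)
        }
        ## hypoxia guard: any living agent within 1.5x of the threshold
        ## forces every-step oxygen resolution
        minO2Now <- min(sensedO2)
        o2Guard <- minO2Now < 1.5 * p$hypoxiaThreshold
      } else minO2Now <- NA_real_

      ## (3) death cascade + residual merging
      nNecBefore <- sum(cells$state >= .STATE[["necrotic"]])
      dc <- updateDeathCascade(cells, env$oxygen, dtH, config)
      cells <- dc$cells
      if (is.na(necroseNode) && dc$nNecrosed > 0) {
        first <- which(cells$state == .STATE[["necrotic"]])[1L]
        necroseNode <- assignAgentsToNodes(
          cbind(cells$x[first], cells$y[first], cells$z[first]), mesh)
        necroseO2 <- o2@values[necroseNode]
      } else if (!is.na(necroseNode)) {
        necroseO2 <- c(necroseO2, o2@values[necroseNode])
      }
      mg <- mergeResiduals(cells, mesh)
      if (mg$nMerged) {
        keepIdx <- cells$id %in% mg$cells$id     # realign after removals
        env <- lapply(env, function(v) v[keepIdx])
        map <- map[keepIdx]
      }
      cells <- mg$cells

      ## (4) quiescence (only cancer agents proliferate, so only they are
      ## queried; the wall still counts as neighbours)
      if (isTRUE(p$quiescenceEnabled)) {
        canIdx <- which(cells$cancer)
        q <- evaluateQuiescence(cells, p$quiescenceRadius, p$quiescenceLimit,
                                p$cellRadius, query = canIdx)
        cells$quiescent <- q & cells$cancer
      } else cells$quiescent[] <- FALSE

      ## (5) clocks + interphase growth
      cyc <- cells$state == 1L &
        (cells$phenotype == 1L | cells$phenotype == 2L)
      cyc <- cyc | (cells$state == 2L &
                    (cells$phenotype == 1L | cells$phenotype == 2L))
      if (isTRUE(p$quiescentClockPause)) cyc <- cyc & !cells$quiescent
      cells$cycle[cyc] <- cells$cycle[cyc] + dtH
      cells <- growInterphase(cells, dtH, p$tauP, p$cellRadius)

      ## (6) mitosis
      nBirths <- 0L
      cand <- which(cells$state == .STATE[["normal"]] & !cells$quiescent &
                    cells$phenotype %in% c(.PHEN[["TIC"]],
                                           .PHEN[["progenitor"]]))
      if (length(cand)) {
        ok <- decideMitosis(cells[cand, , drop = FALSE],
                            list(estrogen = env$estrogen[cand],
                                 FGF = env$FGF[cand]),
                            thresholds, quiescent = rep(FALSE, length(cand)),
                            tauP = .cycleGate(p), Pmax = p$Pmax)
        dif <- attr(ok, "differentiated")
        if (any(dif))
          cells$phenotype[cand[dif]] <- .PHEN[["differentiated"]]
        if (any(ok)) {
          pm <- performMitosis(cells, cand[ok], config)
          cells <- pm$cells
          nBirths <- pm$nBirths
          map <- c(map, integer(nBirths))
        }
      }

      ## (7) mechanics
      mech <- list(maxOverlap = 0, converged = TRUE)
      if (any(cells$mobile)) {
        rx <- resolveOverlaps(cells, p$overlapTolerance, p$mechanicsMaxIter,
                              warn = FALSE)
        cells <- confineToDuct(rx$cells, geom)
        mech <- rx
      }

      ## (8) deposits for the next step (node map refreshed only for
      ## agents that can have moved; the rigid wall keeps its assignment)
      upd <- cells$mobile | cells$state >= .STATE[["lysed"]] | map == 0L
      if (any(upd))
        map[upd] <- assignAgentsToNodes(
          cbind(cells$x[upd], cells$y[upd], cells$z[upd]), mesh)
      dep <- depositReactions(cells, map, mesh, agentRates(cells, config))

      list(births = nBirths, necroses = dc$nNecrosed, merges = mg$nMerged,
           mech = mech, minO2 = minO2Now)
    }, error = function(e) {
      stop(sprintf("simulation aborted at step %d (t = %.2f h): %s [%d agents]",
                   step, tH, conditionMessage(e), length(cells$id)),
           call. = FALSE)
    })

    book$step[step] <- step
    book$births[step] <- stepResult$births
    book$necroses[step] <- stepResult$necroses
    book$merges[step] <- stepResult$merges
    book$maxOverlap[step] <- stepResult$mech$maxOverlap
    book$mechConverged[step] <- stepResult$mech$converged
    book$minO2[step] <- stepResult$minO2

    if (step %% recEvery == 0L) recordRow(step %/% recEvery + 1L, tH)
  }

  liveCa <- cells$state %in% .aliveStates() & cells$cancer
  saturated <- if (any(liveCa)) mean(cells$capFrozen[liveCa]) > 0.01 else FALSE
  if (!is.null(snapshotDir))
    writeSnapshotManifest(snapshotDir, snapFiles, config)
  nNonConv <- sum(!book$mechConverged)
  if (nNonConv)
    attr(saturated, "mechanics") <- nNonConv
  new("SimulationResult",
      metrics = as.data.frame(metrics),
      bookkeeping = as.data.frame(book),
      cells = new("CellPopulation", cells = cells, geometry = geom),
      config = config,
      info = list(runtimeSeconds = proc.time()[["elapsed"]] - t0,
                  saturated = isTRUE(saturated),
                  mechanicsNonConverged = nNonConv,
                  nSteps = nSteps,
                  necrosisNode = necroseNode,
                  necrosisNodeO2 = necroseO2))
}
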