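## Discrete cell rules: proliferation gating, division, interphase growth,
## density quiescence, and the hypoxia -> necrosis -> lysis -> calcification
## cascade. Apoptosis is off in the cancer population: all death flows
## through the hypoxia pathway.

.aliveStates <- function() c(.STATE[["normal"]], .STATE[["hypoxic"]])

#' Decide whether agents may undergo mitosis
#'
#' An agent divides only when all gates pass: (i) a full cell cycle since
#' its last mitosis (`cycle >= tauP`); (ii) its signaling threshold is
#' satisfied as a binary step - local estrogen >= threshold for ER+ agents,
#' local FGF >= threshold for ER- agents (skipped when thresholding is
#' disabled); (iii) it is not density-quiescent; and (iv) progenitors have
#' proliferation potential remaining. A progenitor that completes its cycle
#' with exhausted potential differentiates terminally (returned in the
#' `differentiated` attribute).
#'
#' @param cells Cell data.frame (rows must be living TICs or progenitors;
#'   anything else is an error).
#' @param localEnv data.frame with per-agent `estrogen` and `FGF` columns.
#' @param thresholds list(estrogen=, fgf=, enabled=).
#' @param quiescent Logical per-agent density-quiescence flags.
#' @param tauP Cell cycle time, hours.
#' @param Pmax Progenitor proliferation potential (divisions).
#' @return Logical vector; attribute `differentiated` marks progenitors that
#'   must switch phenotype to differentiated.
#' @export
decideMitosis <- function(cells, localEnv, thresholds, quiescent,
                          tauP = 16, Pmax = 50) {
  if (is(cells, "CellPopulation")) cells <- cells@cells
  if (any(cells$state != .STATE[["normal"]]) ||
      any(!cells$phenotype %in% c(.PHEN[["TIC"]], .PHEN[["progenitor"]])))
    stop("decideMitosis called on dead, hypoxic or non-proliferative agents")
  cycled <- cells$cycle >= tauP
  if (isTRUE(thresholds$enabled)) {
    sig <- ifelse(cells$er == 1L, localEnv$estrogen >= thresholds$estrogen,
                  localEnv$FGF >= thresholds$fgf)
  } else sig <- rep(TRUE, length(cells$id))
  isProg <- cells$phenotype == .PHEN[["progenitor"]]
  exhausted <- isProg & cells$prolif >= Pmax
  ok <- cycled & sig & !quiescent & !exhausted
  attr(ok, "differentiated") <- cycled & exhausted
  ok
}

#' Evaluate density-induced quiescence
#'
#' An agent is quiescent (mitosis blocked, reversibly) when the number of
#' living agent centres within the sensing radius exceeds the limit. An
#' interior agent of a close-packed aggregate (12 touching neighbours)
#' is quiescent under the defaults; an agent with a free hemisphere at the
#' leading edge is not.
#'
#' @param cells Cell data.frame or [CellPopulation-class].
#' @param radiusFactor Sensing radius in units of the mature cell radius
#'   (default 4, i.e. 20 um: about one cell diameter of clearance around a
#'   touching neighbour shell, wide enough to read local packing reliably).
#' @param limit Neighbour-count limit N_q; more than this many neighbours
#'   induces quiescence.
#' @param cellRadius Mature cell radius, um.
#' @param query Optional integer indices: evaluate only these agents
#'   (others return FALSE).
#' @return Logical vector over all agents (FALSE for dead agents).
#' @export
evaluateQuiescence <- function(cells, radiusFactor = 4, limit = 30,
                               cellRadius = 5, query = NULL) {
  if (is(cells, "CellPopulation")) cells <- cells@cells
  alive <- cells$state %in% .aliveStates()
  cnt <- neighbor_count_cpp(cbind(cells$x, cells$y, cells$z), alive,
                            radiusFactor * cellRadius,
                            if (!is.null(query)) as.integer(query))
  alive & cnt > limit
}

#' Advance interphase growth
#'
#' Newborn cells carry half the mature volume and grow linearly in time so
#' the mature volume is reached after one full cell cycle; the radius
#' follows from the volume. Growth never exceeds the mature volume and only
#' applies to living cancer agents.
#'
#' @param cells Cell data.frame or [CellPopulation-class].
#' @param dt Interval, hours.
#' @param tauP Cell cycle time, hours.
#' @param matureRadius Mature cell radius, um.
#' @return Updated cell data.frame.
#' @export
growInterphase <- function(cells, dt, tauP = 16, matureRadius = 5) {
  pop <- NULL
  if (is(cells, "CellPopulation")) { pop <- cells; cells <- cells@cells }
  Vm <- .volOf(matureRadius)
  g <- cells$cancer & cells$state %in% .aliveStates() & cells$volume < Vm
  if (any(g)) {
    cells$volume[g] <- pmin(Vm, cells$volume[g] + dt * Vm / (2 * tauP))
    cells$radius[g] <- .radOf(cells$volume[g])
  }
  if (!is.null(pop)) { pop@cells <- cells; pop } else cells
}

#' Perform mitosis for a set of parent agents
#'
#' Each parent splits its volume evenly with its daughter; both restart
#' their cycle clocks. A TIC divides symmetrically (two TICs) with
#' probability `omegaSC`, otherwise asymmetrically (TIC + progenitor);
#' progenitor divisions are always symmetric (`omegaP` = 100%) and both
#' sides carry the incremented division count. Daughters of wall-resident
#' parents are placed into the luminal cavity (inward-biased random
#' direction); intraductal daughters are placed isotropically at one parent
#' radius. Daughters of TIC divisions draw a fresh ER status; progenitor
#' daughters inherit the parent's.
#'
#' @param cells Cell data.frame.
#' @param idx Integer row indices of the dividing parents (must satisfy
#'   [decideMitosis()]).
#' @param config A [SimConfig-class] (uses omegaSC, erPositiveProb,
#'   cellRadius).
#' @return list(cells = updated table including daughters, nBirths).
#' @export
performMitosis <- function(cells, idx, config) {
  p <- config@params
  nb <- length(idx)
  if (!nb) return(list(cells = cells, nBirths = 0L))
  if (any(cells$state[idx] != .STATE[["normal"]]))
    stop("performMitosis called on non-dividing agents")

  halfV <- cells$volume[idx] / 2
  newR <- .radOf(halfV)
  cells$volume[idx] <- halfV
  cells$radius[idx] <- newR
  cells$cycle[idx] <- 0

  ## daughter placement directions
  z <- runif(nb, -1, 1)
  phi <- runif(nb, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  dir <- cbind(z, s * cos(phi), s * sin(phi))   # x along duct axis
  inWall <- cells$layer[idx] != .LAYER[["intraductal"]]
  if (any(inWall)) {
    ## reflect outward-pointing directions into the cavity
    w <- which(inWall)
    rr <- sqrt(cells$y[idx[w]]^2 + cells$z[idx[w]]^2)
    ey <- cells$y[idx[w]] / rr; ez <- cells$z[idx[w]] / rr
    dotr <- dir[w, 2L] * ey + dir[w, 3L] * ez
    flip <- dotr > 0
    dir[w, 2L] <- dir[w, 2L] - 2 * flip * dotr * ey
    dir[w, 3L] <- dir[w, 3L] - 2 * flip * dotr * ez
  }

  ## phenotype of daughters
  parentTIC <- cells$phenotype[idx] == .PHEN[["TIC"]]
  symDraw <- runif(nb)
  dPhen <- ifelse(parentTIC,
                  ifelse(symDraw < p$omegaSC, .PHEN[["TIC"]],
                         .PHEN[["progenitor"]]),
                  .PHEN[["progenitor"]])
  ## progenitor division: both sides carry the incremented count
  isProgParent <- !parentTIC
  cells$prolif[idx[isProgParent]] <- cells$prolif[idx[isProgParent]] + 1L

  dEr <- ifelse(parentTIC, as.integer(runif(nb) < p$erPositiveProb),
                cells$er[idx])

  d <- .newCellTable(nb)
  maxId <- max(cells$id)
  d$id <- maxId + seq_len(nb)
  d$x <- cells$x[idx] + dir[, 1L] * newR
  d$y <- cells$y[idx] + dir[, 2L] * newR
  d$z <- cells$z[idx] + dir[, 3L] * newR
  d$radius <- newR
  d$volume <- halfV
  d$layer <- .LAYER[["intraductal"]]
  d$phenotype <- dPhen
  d$cancer <- TRUE
  d$er <- dEr
  d$state <- .STATE[["normal"]]
  d$vol0 <- halfV
  d$generation <- cells$generation[idx] + 1L
  d$prolif <- ifelse(isProgParent, cells$prolif[idx], 0L)
  d$mobile <- TRUE

  list(cells = rbind(cells, d), nBirths = nb)
}

#' Advance the hypoxia death cascade
#'
#' Living agents below the hypoxia threshold become hypoxic and accumulate
#' hypoxic time; recovery above the threshold returns them to normal and
#' resets the clock (hypoxia must persist continuously to kill). After
#' `tauN` hours of sustained hypoxia the agent becomes necrotic
#' (irreversibly; all molecular exchange stops), swells during lysis to
#' `1 + lysisSwell` times its pre-lysis volume over `tauL` hours, then
#' bursts to a condensed residual of `calcFrac` times the pre-lysis volume,
#' and calcifies `tauC` hours after necrosis onset.
#'
#' @param cells Cell data.frame or [CellPopulation-class].
#' @param localOxygen Per-agent local oxygen, mmHg (only consulted for
#'   living agents).
#' @param dt Interval, hours.
#' @param config A [SimConfig-class].
#' @return list(cells, nNecrosed).
#' @export
updateDeathCascade <- function(cells, localOxygen, dt, config) {
  pop <- NULL
  if (is(cells, "CellPopulation")) { pop <- cells; cells <- cells@cells }
  p <- config@params
  if (any(localOxygen < -1e-9, na.rm = TRUE))
    stop("negative oxygen input to death cascade")
  alive <- cells$state %in% .aliveStates()
  hypNow <- alive & localOxygen < p$hypoxiaThreshold
  ## recovery: hypoxic agents back above threshold return to normal
  rec <- cells$state == .STATE[["hypoxic"]] & !hypNow
  cells$state[rec] <- .STATE[["normal"]]
  cells$hypoxia[rec] <- 0
  ## (continued) hypoxia
  cells$state[hypNow] <- .STATE[["hypoxic"]]
  cells$hypoxia[hypNow] <- cells$hypoxia[hypNow] + dt
  ## necrosis after sustained hypoxia
  nec <- cells$state == .STATE[["hypoxic"]] & cells$hypoxia >= p$tauN - 1e-9
  nNec <- sum(nec)
  if (nNec) {
    cells$state[nec] <- .STATE[["necrotic"]]
    cells$vol0[nec] <- cells$volume[nec]
    cells$necrosis[nec] <- 0
    cells$quiescent[nec] <- FALSE
  }
  ## progress necrosis clocks (newly necrosed agents start at 0 this step)
  dead <- cells$state >= .STATE[["necrotic"]] &
    cells$state < .STATE[["calcified"]] & !nec
  cells$necrosis[dead] <- cells$necrosis[dead] + dt
  ## lysis swelling
  sw <- cells$state == .STATE[["necrotic"]]
  if (any(sw)) {
    frac <- pmin(1, cells$necrosis[sw] / p$tauL)
    cells$volume[sw] <- cells$vol0[sw] * (1 + p$lysisSwell * frac)
    cells$radius[sw] <- .radOf(cells$volume[sw])
    burst <- sw & cells$necrosis >= p$tauL - 1e-9
    if (any(burst)) {
      cells$state[burst] <- .STATE[["lysed"]]
      cells$volume[burst] <- p$calcFrac * cells$vol0[burst]
      cells$radius[burst] <- .radOf(cells$volume[burst])
      cells$mobile[burst] <- FALSE       # residual material is immobile
    }
  }
  ## calcification
  calc <- cells$state == .STATE[["lysed"]] & cells$necrosis >= p$tauC - 1e-9
  cells$state[calc] <- .STATE[["calcified"]]
  if (!is.null(pop)) { pop@cells <- cells; list(cells = pop, nNecrosed = nNec) }
  else list(cells = cells, nNecrosed = nNec)
}

#' Merge residual material within node regions
#'
#' All residual material (lysed or calcified remains) owned by one mesh node
#' is summed and represented by a single agent at the volume-weighted
#' centroid; the merged agent carries the earliest necrosis onset.
#'
#' @param cells Cell data.frame.
#' @param mesh A [DuctMesh-class].
#' @return list(cells, nMerged) where nMerged counts removed agents.
#' @export
mergeResiduals <- function(cells, mesh) {
  res <- which(cells$state >= .STATE[["lysed"]])
  if (length(res) < 2L) return(list(cells = cells, nMerged = 0L))
  nodes <- nearest_node_cpp(cbind(cells$x[res], cells$y[res], cells$z[res]),
                            mesh@nodeId, mesh@dims, mesh@origin, mesh@spacing)
  dup <- split(res, nodes)
  dup <- dup[lengths(dup) > 1L]
  if (!length(dup)) return(list(cells = cells, nMerged = 0L))
  drop <- integer()
  for (grp in dup) {
    keep <- grp[which.min(cells$id[grp])]
    w <- cells$volume[grp]
    cells$x[keep] <- sum(cells$x[grp] * w) / sum(w)
    cells$y[keep] <- sum(cells$y[grp] * w) / sum(w)
    cells$z[keep] <- sum(cells$z[grp] * w) / sum(w)
    cells$volume[keep] <- sum(w)
    cells$vol0[keep] <- sum(cells$vol0[grp])
    cells$radius[keep] <- .radOf(cells$volume[keep])
    cells$necrosis[keep] <- max(cells$necrosis[grp])
    cells$state[keep] <- max(cells$state[grp])
    drop <- c(drop, setdiff(grp, keep))
  }
  list(cells = cells[-drop, , drop = FALSE], nMerged = length(drop))
}
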