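## Off-lattice mechanics: pairwise overlap relaxation and duct confinement.

#' Resolve cell-cell overlaps
#'
#' Iterative position-based relaxation: overlapping pairs are pushed apart
#' along their centre line by a displacement proportional to the overlap,
#' split by inverse radius (larger cells move less). Mature duct wall agents
#' and residual (lysed/calcified) material are immobile; a symmetric mobile
#' pair displaces symmetrically with zero net centre-of-mass drift.
#' Iteration stops when the maximum overlap is at most `tolerance` or after
#' `maxIter` iterations (non-convergence yields a warning and proceeds).
#'
#' @param cells Cell data.frame or [CellPopulation-class].
#' @param tolerance Maximum residual overlap, um.
#' @param maxIter Iteration budget per call.
#' @param warn Emit a warning on non-convergence (the engine logs instead).
#' @return list(cells, iterations, maxOverlap, converged).
#' @export
resolveOverlaps <- function(cells, tolerance = 0.1, maxIter = 50,
                            warn = TRUE) {
  pop <- NULL
  if (is(cells, "CellPopulation")) { pop <- cells; cells <- cells@cells }
  stopifnot(tolerance > 0)
  res <- relax_overlaps_cpp(cbind(cells$x, cells$y, cells$z), cells$radius,
                            cells$mobile, tolerance, as.integer(maxIter))
  cells$x <- res$pos[, 1L]; cells$y <- res$pos[, 2L]; cells$z <- res$pos[, 3L]
  if (!res$converged && warn)
    warning(sprintf("overlap relaxation not converged: max overlap %.3g um",
                    res$maxOverlap))
  if (!is.null(pop)) { pop@cells <- cells; cells <- pop }
  list(cells = cells, iterations = res$iterations,
       maxOverlap = res$maxOverlap, converged = res$converged)
}

#' Confine agents to the duct interior
#'
#' Intraductal agents that breach the rigid duct wall are projected back so
#' their centre lies within the luminal cavity radius minus their radius.
#' Axial positions are clamped to the duct section; agents reaching an end
#' cap are frozen there and flagged (the simulated section is saturated when
#' a noticeable fraction of live agents touch a cap).
#'
#' @param cells Cell data.frame or [CellPopulation-class].
#' @param geometry A [DuctGeometry-class].
#' @return Updated cells (same class as input).
#' @export
confineToDuct <- function(cells, geometry) {
  pop <- NULL
  if (is(cells, "CellPopulation")) { pop <- cells; cells <- cells@cells }
  intra <- cells$layer == .LAYER[["intraductal"]]
  if (any(intra)) {
    lim <- cavityRadius(geometry) - cells$radius[intra]
    rr <- sqrt(cells$y[intra]^2 + cells$z[intra]^2)
    breach <- rr > lim & rr > 0
    if (any(breach)) {
      i <- which(intra)[breach]
      sc <- (lim[breach]) / rr[breach]
      cells$y[i] <- cells$y[i] * sc
      cells$z[i] <- cells$z[i] * sc
    }
    xlim <- geometry@axialLength / 2 - cells$radius[intra]
    hit <- abs(cells$x[intra]) > xlim
    if (any(hit)) {
      i <- which(intra)[hit]
      cells$x[i] <- sign(cells$x[i]) * xlim[hit]
      cells$capFrozen[i] <- TRUE
      cells$mobile[i] <- FALSE
    }
  }
  if (!is.null(pop)) { pop@cells <- cells; pop } else cells
}

#' Audit pairwise overlaps
#'
#' @param cells Cell data.frame or [CellPopulation-class].
#' @return list(energy = sum of squared overlaps, maxOverlap, pairs).
#' @export
overlapAudit <- function(cells) {
  if (is(cells, "CellPopulation")) cells <- cells@cells
  overlap_audit_cpp(cbind(cells$x, cells$y, cells$z), cells$radius)
}
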