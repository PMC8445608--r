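## Agent <-> continuum exchange: Voronoi deposition and interpolation.
##
## Each agent's entire molecular contribution is lumped at its nearest mesh
## node (the Dirac-delta simplification of the Heaviside-ball reaction term)
## and normalized by the node's Voronoi region volume. Agents sense their
## microenvironment at their centre of mass by trilinear interpolation (the
## regular-grid analogue of linear barycentric interpolation on simplices).

#' Map agents to their nearest mesh nodes
#'
#' Voronoi ownership: each agent belongs to the node nearest its centre of
#' mass; ties are broken deterministically toward the lowest node index.
#'
#' @param cells A [CellPopulation-class], cell data.frame, or n x 3 position
#'   matrix.
#' @param mesh A [DuctMesh-class].
#' @return Integer vector of node ids, one per agent.
#' @export
assignAgentsToNodes <- function(cells, mesh) {
  pos <- .positionsOf(cells)
  if (nrow(pos) == 0L) return(integer())
  geom <- mesh@geometry
  r <- sqrt(pos[, 2L]^2 + pos[, 3L]^2)
  out <- r > outerRadius(geom) + 1e-9 |
    abs(pos[, 1L]) > geom@axialLength / 2 + 1e-9
  if (any(out))
    stop("agent(s) outside domain: ", paste(which(out)[1:min(5, sum(out))],
                                            collapse = ", "))
  nearest_node_cpp(pos, mesh@nodeId, mesh@dims, mesh@origin, mesh@spacing)
}

.positionsOf <- function(cells) {
  if (is(cells, "CellPopulation")) cells <- cells@cells
  if (is.data.frame(cells) || is.list(cells))
    cbind(cells$x, cells$y, cells$z)
  else as.matrix(cells)
}

#' Per-phenotype molecular exchange rates
#'
#' Consumption is first-order in the local concentration: an agent with
#' clearance lambda (um^3/s) removes `lambda * u` per second, deposited at
#' its node as an uptake rate `lambda / V_region` (1/s). Production is a
#' constant source `lambda / V_region` (conc/s). Dead agents (necrotic,
#' lysed, calcified) neither consume nor produce.
#'
#' @param cells Cell data.frame or [CellPopulation-class].
#' @param config A [SimConfig-class] supplying the rate table.
#' @return data.frame with per-agent columns `o2Clearance`, `estClearance`,
#'   `fgfClearance` (um^3/s) and `aregProduction` (conc um^3/s).
#' @export
agentRates <- function(cells, config) {
  if (is(cells, "CellPopulation")) cells <- cells@cells
  p <- config@params
  n <- length(cells$id)
  alive <- cells$state <= .STATE[["hypoxic"]]
  o2c <- p$lambdaH * p$o2UptakeScale *
    ifelse(cells$cancer, p$cancerO2Factor, 1)
  est <- ifelse(cells$er == 1L, p$estrogenUptake, 0)
  fgf <- ifelse(cells$er == 0L, p$fgfUptake, 0)
  areg <- ifelse(cells$er == 1L, p$aregProduction, 0)
  z <- !alive
  o2c[z] <- est[z] <- fgf[z] <- areg[z] <- 0
  data.frame(o2Clearance = o2c, estClearance = est, fgfClearance = fgf,
             aregProduction = areg)
}

#' Deposit agent reaction terms onto mesh nodes
#'
#' Sums each agent's rates at its assigned node, normalized by the node's
#' Voronoi region volume. The deposition conserves the total: for every
#' species, `sum(nodal rate * region volume)` equals the sum of per-agent
#' rates.
#'
#' @param cells Cell data.frame or [CellPopulation-class].
#' @param mapping Node assignment from [assignAgentsToNodes()].
#' @param mesh A [DuctMesh-class].
#' @param rates Per-agent rate table from [agentRates()] (columns ending in
#'   `Clearance` are uptake, others production).
#' @return Named list per rate column: per-node uptake (1/s) or production
#'   (conc/s) vectors.
#' @export
depositReactions <- function(cells, mapping, mesh, rates) {
  n <- nrow(mesh@coords)
  V <- mesh@regionVolume
  if (!length(mapping))
    return(setNames(rep(list(numeric(n)), length(rates)), names(rates)))
  s <- deposit_sum_cpp(as.integer(mapping), as.matrix(rates), n)
  out <- lapply(seq_along(rates), function(j) s[, j] / V)
  names(out) <- names(rates)
  out
}

#' Sense the microenvironment at agent positions
#'
#' Interpolates each field at the agent centres of mass by trilinear
#' interpolation over the enclosing grid cell; exact for fields linear in
#' space.
#'
#' @param cells A [CellPopulation-class], cell data.frame or position matrix.
#' @param fields A [MolecularField-class] or list of them.
#' @return Numeric vector (single field) or data.frame (list of fields) of
#'   local concentrations.
#' @export
senseEnvironment <- function(cells, fields) {
  pos <- .positionsOf(cells)
  single <- is(fields, "MolecularField")
  if (single) fields <- list(fields)
  mesh <- fields[[1L]]@mesh
  geom <- mesh@geometry
  if (nrow(pos)) {
    r <- sqrt(pos[, 2L]^2 + pos[, 3L]^2)
    if (any(r > outerRadius(geom) + 1e-9 |
            abs(pos[, 1L]) > geom@axialLength / 2 + 1e-9))
      stop("agent(s) outside domain")
  }
  vals <- lapply(fields, function(f)
    trilinear_cpp(expandToGrid(f@mesh, f@values), f@mesh@dims, f@mesh@origin,
                  f@mesh@spacing, pos))
  if (single) vals[[1L]]
  else as.data.frame(setNames(vals, vapply(fields, slot, "", "species")))
}
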