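## Duct geometry and mesh construction.

#' Create a duct geometry
#'
#' @param luminalDiameter Luminal cavity diameter, um (100, 150 or 200 at
#'   baseline). The mature cell layers surround a cavity of this diameter.
#' @param axialLength Duct section length, um (baseline 1000).
#' @param layerThickness Thickness of each of the two mature layers, um;
#'   one mature cell diameter (10 um) by default.
#' @return A [DuctGeometry-class].
#' @examples
#' ductGeometry(100)
#' @export
ductGeometry <- function(luminalDiameter, axialLength = 1000,
                         layerThickness = 10) {
  new("DuctGeometry", luminalDiameter = luminalDiameter,
      axialLength = axialLength, layerThickness = layerThickness)
}

#' Build the computational mesh for a duct section
#'
#' Discretizes the full duct cylinder (luminal cavity plus both mature cell
#' layers) as a regular Cartesian grid masked to the cylinder, with node
#' spacing of about one mature cell diameter. Node region ownership is the
#' Voronoi (nearest-node) partition of the continuous cylinder; region
#' volumes are computed from a subsampled cross-section and normalized so
#' they sum exactly to the cylinder volume. The outer curved surface nodes
#' (`outer_radial`) carry Dirichlet conditions for blood-borne species; the
#' truncated end caps are zero-flux and excluded from `outer_radial`.
#'
#' @param geometry A [DuctGeometry-class].
#' @param spacing Node spacing, um; must not exceed a quarter of the luminal
#'   diameter.
#' @return A [DuctMesh-class].
#' @examples
#' mesh <- buildDuctMesh(ductGeometry(100), 10)
#' mesh
#' @export
buildDuctMesh <- function(geometry, spacing = 10) {
  stopifnot(is(geometry, "DuctGeometry"))
  if (spacing <= 0) stop("spacing must be positive")
  Ro <- outerRadius(geometry)
  L <- geometry@axialLength
  if (spacing > geometry@luminalDiameter / 4 || spacing > L / 2)
    stop("mesh too coarse: spacing ", spacing,
         " um exceeds a quarter of the luminal diameter")

  h <- spacing
  nx <- as.integer(floor(L / h + 1e-9)) + 1L
  xg <- -L / 2 + (seq_len(nx) - 1L) * h
  nr <- as.integer(floor(Ro / h + 1e-9))
  yg <- (-nr:nr) * h
  ny <- nz <- length(yg)
  origin <- c(xg[1L], yg[1L], yg[1L])
  dims <- c(nx, ny, nz)

  ## cross-section mask (identical for every axial slice)
  yz <- expand.grid(y = yg, z = yg)
  r2 <- yz$y^2 + yz$z^2
  sliceMask <- r2 <= Ro^2 + 1e-9
  nSlice <- sum(sliceMask)

  mask <- rep(sliceMask, each = nx)           # column-major: x fastest
  nodeId <- integer(nx * ny * nz)
  nodeId[mask] <- seq_len(sum(mask))
  dim(nodeId) <- dims

  inMask <- which(mask)
  nIn <- length(inMask)
  ## coordinates
  idx <- arrayInd(inMask, dims)
  coords <- cbind(x = xg[idx[, 1L]], y = yg[idx[, 2L]], z = yg[idx[, 3L]])

  ## 6-neighbour table
  nbr <- matrix(0L, nIn, 6L)
  off <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 1L, 0L),
              c(0L, 0L, -1L), c(0L, 0L, 1L))
  for (k in seq_along(off)) {
    ii <- idx[, 1L] + off[[k]][1L]
    jj <- idx[, 2L] + off[[k]][2L]
    kk <- idx[, 3L] + off[[k]][3L]
    ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny & kk >= 1L & kk <= nz
    lin <- (kk - 1L) * nx * ny + (jj - 1L) * nx + ii
    v <- integer(nIn)
    v[ok] <- nodeId[lin[ok]]
    nbr[, k] <- v
  }

  ## boundary sets: a node is on the outer curved surface if any lateral
  ## (y/z) grid neighbour lies outside the cylinder; end-cap membership
  ## (x = +-L/2 planes) takes precedence.
  lateralMissing <- rowSums(nbr[, 3:6] == 0L) > 0L
  onCap <- idx[, 1L] == 1L | idx[, 1L] == nx
  outerRadial <- which(lateralMissing & !onCap)
  endCaps <- which(onCap)
  interior <- setdiff(seq_len(nIn), c(outerRadial, endCaps))

  ## region volumes: 2D Voronoi areas of the cross-section lattice inside the
  ## disc (subsampled), extruded by h (h/2 at caps), then normalized to the
  ## exact cylinder volume.
  sliceIds <- matrix(0L, ny, nz)
  sliceIds[sliceMask] <- seq_len(nSlice)
  d <- h / 20
  sg <- seq(-Ro + d / 2, Ro - d / 2, by = d)
  sp <- expand.grid(y = sg, z = sg)
  sp <- sp[sp$y^2 + sp$z^2 <= Ro^2, , drop = FALSE]
  own <- nearest_node_cpp(cbind(0, sp$y, sp$z),
                          as.integer(sliceIds), c(1L, ny, nz),
                          c(0, yg[1L], yg[1L]), h)
  area <- tabulate(own, nbins = nSlice) * d^2
  volPerNode <- numeric(nIn)
  sliceOf <- nodeId[inMask]                  # identity, placeholder
  ## map each 3D node to its 2D slice node
  lin2d <- (idx[, 3L] - 1L) * ny + idx[, 2L]
  node2d <- sliceIds[cbind(idx[, 2L], idx[, 3L])]
  axialW <- ifelse(onCap, h / 2, h)
  volPerNode <- area[node2d] * axialW
  exact <- pi * Ro^2 * L
  volPerNode <- volPerNode * (exact / sum(volPerNode))

  ## ghost fill for interpolation: nearest in-mask node for each out-of-mask
  ## grid point (2D problem again, extruded)
  ghost <- which(!mask)
  gidx <- arrayInd(ghost, dims)
  gown2d <- nearest_node_cpp(cbind(0, yg[gidx[, 2L]], yg[gidx[, 3L]]),
                             as.integer(sliceIds), c(1L, ny, nz),
                             c(0, yg[1L], yg[1L]), h)
  ## convert (slice node, axial index) to 3D node id
  id2dTo3d <- function(n2d, ix) {
    ## 2D node n2d has (j,k); 3D linear index -> nodeId
    jk <- arrayInd(which(sliceIds > 0), c(ny, nz))
    ord <- order(sliceIds[sliceIds > 0])
    jk <- jk[ord, , drop = FALSE]
    j <- jk[n2d, 1L]; k <- jk[n2d, 2L]
    lin <- (k - 1L) * nx * ny + (j - 1L) * nx + ix
    nodeId[lin]
  }
  ghostSrc <- id2dTo3d(gown2d, gidx[, 1L])

  mesh <- new("DuctMesh", geometry = geometry, spacing = h, dims = dims,
              origin = origin, nodeId = as.integer(nodeId), coords = coords,
              nbr = nbr, regionVolume = volPerNode,
              outerRadial = as.integer(outerRadial),
              endCaps = as.integer(endCaps), interior = as.integer(interior),
              inMask = as.integer(inMask), ghost = as.integer(ghost),
              ghostSrc = as.integer(ghostSrc))
  validObject(mesh)
  mesh
}

#' Expand nodal values to the full grid array (ghost-filled)
#'
#' Out-of-mask grid points copy the value of their nearest in-mask node so
#' that trilinear interpolation is well defined up to the curved surface.
#'
#' @param mesh A [DuctMesh-class].
#' @param values Nodal values (one per mesh node).
#' @return A numeric array of dimension `mesh@dims`.
#' @keywords internal
expandToGrid <- function(mesh, values) {
  arr <- numeric(prod(mesh@dims))
  arr[mesh@inMask] <- values
  arr[mesh@ghost] <- values[mesh@ghostSrc]
  dim(arr) <- mesh@dims
  arr
}
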