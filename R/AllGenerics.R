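## Generics and accessors.

#' @export
setGeneric("cellTable", function(x, ...) standardGeneric("cellTable"))

#' @export
setGeneric("metricsTable", function(x, ...) standardGeneric("metricsTable"))

#' @export
setGeneric("fieldValues", function(x, ...) standardGeneric("fieldValues"))

#' @export
setGeneric("nodeCoordinates", function(x, ...) standardGeneric("nodeCoordinates"))

#' @export
setGeneric("regionVolumes", function(x, ...) standardGeneric("regionVolumes"))

#' @export
setGeneric("boundaryNodes", function(x, which = "outer_radial", ...)
  standardGeneric("boundaryNodes"))

#' Outer and luminal radii of the duct domain
#'
#' `outerRadius` is the computational radius (luminal radius plus two mature
#' cell layers); `cavityRadius` is the luminal cavity radius the intraductal
#' population is confined to.
#'
#' @param x A [DuctGeometry-class].
#' @return Radius in um.
#' @rdname outerRadius
#' @export
setGeneric("outerRadius", function(x) standardGeneric("outerRadius"))

#' @rdname outerRadius
#' @export
setGeneric("cavityRadius", function(x) standardGeneric("cavityRadius"))

#' Get or set a configuration parameter
#'
#' @param x A [SimConfig-class].
#' @param name Parameter name.
#' @param value Replacement value.
#' @rdname simParam
#' @export
setGeneric("simParam", function(x, name) standardGeneric("simParam"))

#' @rdname simParam
#' @export
setGeneric("simParam<-", function(x, name, value) standardGeneric("simParam<-"))

## ---- accessors -----------------------------------------------------------

#' @rdname outerRadius
#' @export
setMethod("outerRadius", "DuctGeometry", function(x)
  x@luminalDiameter / 2 + 2 * x@layerThickness)

#' @rdname outerRadius
#' @export
setMethod("cavityRadius", "DuctGeometry", function(x) x@luminalDiameter / 2)

#' @export
setMethod("nodeCoordinates", "DuctMesh", function(x, ...) x@coords)

#' @export
setMethod("regionVolumes", "DuctMesh", function(x, ...) x@regionVolume)

#' Boundary node sets of a duct mesh
#' @param x A DuctMesh.
#' @param which "outer_radial", "end_caps" or "interior".
#' @param ... unused.
#' @return Integer vector of node ids.
#' @export
setMethod("boundaryNodes", "DuctMesh", function(x, which = "outer_radial", ...) {
  switch(match.arg(which, c("outer_radial", "end_caps", "interior")),
         outer_radial = x@outerRadial, end_caps = x@endCaps,
         interior = x@interior)
})

#' @export
setMethod("fieldValues", "MolecularField", function(x, ...) x@values)

#' @export
setMethod("cellTable", "CellPopulation", function(x, ...) x@cells)

#' @export
setMethod("cellTable", "SimulationResult", function(x, ...) x@cells@cells)

#' @export
setMethod("metricsTable", "SimulationResult", function(x, ...) x@metrics)

#' @rdname simParam
#' @export
setMethod("simParam", "SimConfig", function(x, name) {
  if (!name %in% names(x@params)) stop("unknown parameter: ", name)
  x@params[[name]]
})

#' @rdname simParam
#' @export
setMethod("simParam<-", "SimConfig", function(x, name, value) {
  if (!name %in% names(x@params)) stop("unknown parameter: ", name)
  x@params[[name]] <- value
  x
})

## ---- show methods --------------------------------------------------------

setMethod("show", "DuctGeometry", function(object) {
  cat(sprintf("DuctGeometry: luminal cavity %g um, axial length %g um\n",
              object@luminalDiameter, object@axialLength))
  cat(sprintf("  layer thickness %g um, outer radius %g um\n",
              object@layerThickness, outerRadius(object)))
})

setMethod("show", "DuctMesh", function(object) {
  cat(sprintf("DuctMesh: %d nodes, spacing %g um (grid %s)\n",
              nrow(object@coords), object@spacing,
              paste(object@dims, collapse = " x ")))
  cat(sprintf("  boundary nodes: %d outer radial, %d end caps\n",
              length(object@outerRadial), length(object@endCaps)))
  cat(sprintf("  total region volume %.4g um^3\n", sum(object@regionVolume)))
})

setMethod("show", "MolecularField", function(object) {
  cat(sprintf("MolecularField '%s': D = %g cm^2/s, %s BC, kdeg = %g /s\n",
              object@species, object@D, object@bcType, object@kdeg))
  cat(sprintf("  values: [%.4g, %.4g], %d nodes\n", min(object@values),
              max(object@values), length(object@values)))
})

setMethod("show", "CellPopulation", function(object) {
  phen <- factor(names(.PHEN)[object@cells$phenotype + 1L],
                 levels = names(.PHEN))
  tab <- table(phen)
  tab <- tab[tab > 0]
  cat(sprintf("CellPopulation: %d agents (%s)\n", nrow(object@cells),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig with parameters:\n")
  p <- object@params
  for (nm in names(p))
    cat(sprintf("  %-22s %s\n", nm, paste(format(p[[nm]]), collapse = ", ")))
})

setMethod("show", "SimulationResult", function(object) {
  m <- object@metrics
  cat(sprintf("SimulationResult: %d days recorded, final DCIS count %d\n",
              nrow(m) - 1L, tail(m$dcis_count, 1L)))
  cat(sprintf("  final axial extent %.1f um; hypoxic ever: %s\n",
              tail(m$axial_extent, 1L),
              if (any(m$n_hypoxic > 0)) "yes" else "no"))
})

setMethod("show", "GrowthPhaseFit", function(object) {
  cat(sprintf("GrowthPhaseFit: transition at %.2f d\n", object@transitionTime))
  cat(sprintf("  exponential %.3g*exp(%.3g t), R2 = %.4f (doubling %.2f h)\n",
              object@expA, object@expK, object@r2Exp, object@doublingTime))
  cat(sprintf("  linear slope %.4g per day, R2 = %.4f\n",
              object@linK, object@r2Lin))
})

setMethod("show", "SensitivityResult", function(object) {
  cat(sprintf("SensitivityResult for '%s':\n", object@parameter))
  for (nm in names(object@maxS))
    cat(sprintf("  %s: max |S| = %.4g at variation %.2f\n", nm,
                object@maxS[[nm]], object@argMax[[nm]]))
})
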