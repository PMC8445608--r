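## S4 classes for the duct domain, fields, cells and results.

#' Cylindrical duct geometry
#'
#' The duct section is a cylinder with its axis along x and the axial origin
#' at the duct midpoint. The stated diameter is that of the luminal cavity;
#' the mature luminal and myoepithelial cell layers surround this cavity, so
#' the outer (computational) radius is `luminalDiameter/2 + 2*layerThickness`.
#'
#' @slot luminalDiameter Luminal cavity diameter, um (100/150/200 at baseline).
#' @slot axialLength Duct section length, um (baseline 1000).
#' @slot layerThickness Thickness of each mature cell layer, um
#'   (= one mature cell diameter, 10 um).
#' @export
setClass("DuctGeometry",
  representation(luminalDiameter = "numeric", axialLength = "numeric",
                 layerThickness = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@luminalDiameter) != 1L || object@luminalDiameter <= 0)
      msg <- c(msg, "luminalDiameter must be a single positive number")
    if (length(object@axialLength) != 1L || object@axialLength <= 0)
      msg <- c(msg, "axialLength must be a single positive number")
    if (length(object@layerThickness) != 1L || object@layerThickness <= 0)
      msg <- c(msg, "layerThickness must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Discretized duct domain
#'
#' A regular Cartesian grid masked to the duct cylinder. Node region
#' ownership is Voronoi (nearest node); region volumes partition the
#' continuous cylinder. Boundary node sets distinguish the outer curved
#' surface (where Dirichlet conditions apply) from the truncated end caps
#' (zero flux).
#'
#' @slot geometry The [DuctGeometry-class] the mesh discretizes.
#' @slot spacing Node spacing, um (approximately one mature cell diameter).
#' @slot dims Grid dimensions (nx, ny, nz) of the enclosing box.
#' @slot origin Coordinates of grid node (1,1,1), um.
#' @slot nodeId Full-grid integer array; 0 outside the cylinder, else the
#'   node index 1..nNodes in column-major order.
#' @slot coords nNodes x 3 matrix of node coordinates, um.
#' @slot nbr nNodes x 6 integer matrix of face-neighbour node ids (0 absent).
#' @slot regionVolume Voronoi region volume per node, um^3.
#' @slot outerRadial,endCaps,interior Node-id sets; end-cap membership takes
#'   precedence over the curved surface.
#' @slot inMask Linear indices (full grid) of in-mask nodes.
#' @slot ghost Linear indices of out-of-mask grid points and @slot ghostSrc
#'   the in-mask node each copies from when fields are expanded for
#'   interpolation.
#' @export
setClass("DuctMesh",
  representation(geometry = "DuctGeometry", spacing = "numeric",
                 dims = "integer", origin = "numeric", nodeId = "integer",
                 coords = "matrix", nbr = "matrix", regionVolume = "numeric",
                 outerRadial = "integer", endCaps = "integer",
                 interior = "integer", inMask = "integer", ghost = "integer",
                 ghostSrc = "integer"),
  validity = function(object) {
    n <- nrow(object@coords)
    msg <- character()
    if (length(object@regionVolume) != n)
      msg <- c(msg, "regionVolume length must match node count")
    if (any(object@regionVolume <= 0))
      msg <- c(msg, "region volumes must be positive")
    if (length(intersect(object@outerRadial, object@endCaps)))
      msg <- c(msg, "outerRadial and endCaps must be disjoint")
    if (length(msg)) msg else TRUE
  })

#' A molecular concentration field on a duct mesh
#'
#' @slot species One of "oxygen", "estrogen", "AREG", "FGF" (free names
#'   allowed for testing). Oxygen is in mmHg; the signaling species use a
#'   normalized scale where the boundary/baseline level is ~1.
#' @slot values Nodal concentrations (one per mesh node), always >= 0.
#' @slot D Diffusion constant, cm^2/s.
#' @slot bcType "dirichlet" (constant value on the outer curved surface) or
#'   "neumann" (zero flux everywhere).
#' @slot bcValue Scalar, or one value per `outerRadial` node (used for the
#'   AREG-derived FGF boundary).
#' @slot kdeg First-order degradation rate, 1/s (molecular sinks; small).
#' @slot mesh The [DuctMesh-class] the field lives on.
#' @export
setClass("MolecularField",
  representation(species = "character", values = "numeric", D = "numeric",
                 bcType = "character", bcValue = "numeric", kdeg = "numeric",
                 mesh = "DuctMesh"),
  validity = function(object) {
    msg <- character()
    if (!object@bcType %in% c("dirichlet", "neumann"))
      msg <- c(msg, "bcType must be 'dirichlet' or 'neumann'")
    if (length(object@values) != nrow(object@mesh@coords))
      msg <- c(msg, "values length must match mesh node count")
    if (any(object@values < 0)) msg <- c(msg, "concentrations must be >= 0")
    if (object@D <= 0) msg <- c(msg, "diffusion constant must be positive")
    if (object@kdeg < 0) msg <- c(msg, "kdeg must be >= 0")
    if (object@bcType == "dirichlet" &&
        !length(object@bcValue) %in% c(1L, length(object@mesh@outerRadial)))
      msg <- c(msg, "bcValue must be scalar or one value per outerRadial node")
    if (length(msg)) msg else TRUE
  })

#' A population of cell agents
#'
#' Backed by a data.frame with one row per agent (see [cellTable()] for the
#' column schema).
#'
#' @slot cells The agent table.
#' @slot geometry The duct the population lives in.
#' @export
setClass("CellPopulation",
  representation(cells = "data.frame", geometry = "DuctGeometry"),
  validity = function(object) {
    need <- c("id", "x", "y", "z", "radius", "volume", "layer", "phenotype",
              "cancer", "er", "state", "quiescent", "cycle", "hypoxia",
              "necrosis", "vol0", "generation", "prolif", "mobile",
              "capFrozen")
    miss <- setdiff(need, names(object@cells))
    if (length(miss))
      paste("cell table missing columns:", paste(miss, collapse = ", "))
    else TRUE
  })

#' Simulation configuration
#'
#' All run parameters with literature-baseline defaults; see [simConfig()].
#'
#' @slot params Named list of parameters.
#' @export
setClass("SimConfig", representation(params = "list"))

#' Result of a simulation run
#'
#' @slot metrics Daily (by default) time series of population metrics.
#' @slot bookkeeping Per-step audit (births, necroses, merges, mechanics).
#' @slot cells Final [CellPopulation-class].
#' @slot config The [SimConfig-class] used.
#' @slot info List: runtime, solver statistics, cap-saturation flag.
#' @export
setClass("SimulationResult",
  representation(metrics = "data.frame", bookkeeping = "data.frame",
                 cells = "CellPopulation", config = "SimConfig",
                 info = "list"))

#' Biphasic growth segmentation fit
#'
#' Exponential-phase fit y = a*exp(k*t) (log-linear least squares), linear
#' phase fit y = k*t (through the origin), split chosen to maximize the
#' joint R-squared across both subsets.
#'
#' @slot transitionTime days
#' @slot expA,expK,r2Exp exponential-phase parameters (k per day)
#' @slot linK,r2Lin linear-phase slope (cells/day)
#' @slot doublingTime exponential-phase population doubling time, hours
#' @slot splitIndex index of the last point in the exponential subset
#' @slot series the series that was segmented (time days, value)
#' @export
setClass("GrowthPhaseFit",
  representation(transitionTime = "numeric", expA = "numeric",
                 expK = "numeric", r2Exp = "numeric", linK = "numeric",
                 r2Lin = "numeric", doublingTime = "numeric",
                 splitIndex = "integer", series = "data.frame"),
  validity = function(object) {
    msg <- character()
    r2s <- c(object@r2Exp, object@r2Lin)
    if (any(r2s > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "R-squared values cannot exceed 1")
    tr <- range(object@series$time)
    if (object@transitionTime < tr[1] - 1e-9 ||
        object@transitionTime > tr[2] + 1e-9)
      msg <- c(msg, "transition time outside the series time range")
    if (length(msg)) msg else TRUE
  })

#' Local sensitivity sweep result
#'
#' Sensitivity coefficient S = (dM/M)/(dp/p) of an output M to a parameter p,
#' evaluated on a multiplicative variation grid around baseline.
#'
#' @slot parameter Parameter name.
#' @slot grid data.frame: variation, output value(s), S value(s).
#' @slot baseline Named baseline output value(s).
#' @slot maxS Named max |S| per output.
#' @slot argMax Named variation at which max |S| occurs.
#' @export
setClass("SensitivityResult",
  representation(parameter = "character", grid = "data.frame",
                 baseline = "numeric", maxS = "numeric", argMax = "numeric"))
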