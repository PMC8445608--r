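## Reaction-diffusion fields: du/dt = D lap(u) + R(u), R = U(u,x) - L(u).
##
## Oxygen and estrogen enter as constant Dirichlet values on the outer curved
## surface (capillaries on the duct surface); AREG is produced inside the
## duct and carries homogeneous Neumann conditions; FGF carries a
## time-dependent Dirichlet condition derived from the previous step's AREG
## boundary values (the epithelial-to-stromal relay). End caps are zero-flux
## for all species.

CM2_TO_UM2 <- 1e8   # cm^2/s -> um^2/s

## near-optimal SOR over-relaxation factor for the 7-point Laplacian on this
## grid (Jacobi spectral radius from the grid dimensions)
.optimalOmega <- function(mesh) {
  mu <- mean(cos(pi / mesh@dims))
  2 / (1 + sqrt(max(1e-12, 1 - mu^2)))
}

#' Create a molecular field on a duct mesh
#'
#' @param mesh A [DuctMesh-class].
#' @param species Field name ("oxygen", "estrogen", "AREG", "FGF", or any
#'   label for testing).
#' @param D Diffusion constant, cm^2/s.
#' @param bcType "dirichlet" or "neumann".
#' @param bcValue Dirichlet value on the outer curved surface (scalar or one
#'   value per `outer_radial` node); ignored for Neumann fields.
#' @param kdeg First-order degradation rate, 1/s. Molecular sinks are small;
#'   defaults to 0.
#' @param initial Initial nodal values; defaults to `bcValue` for Dirichlet
#'   fields and 0 for Neumann fields.
#' @return A [MolecularField-class].
#' @examples
#' mesh <- buildDuctMesh(ductGeometry(100, 200), 10)
#' o2 <- makeField(mesh, "oxygen", D = 2.5e-6, bcValue = 100)
#' @export
makeField <- function(mesh, species, D, bcType = "dirichlet", bcValue = 1,
                      kdeg = 0, initial = NULL) {
  n <- nrow(mesh@coords)
  if (is.null(initial))
    initial <- if (bcType == "dirichlet") rep(bcValue[1L], n) else numeric(n)
  f <- new("MolecularField", species = species, values = initial, D = D,
           bcType = bcType, bcValue = as.numeric(bcValue), kdeg = kdeg,
           mesh = mesh)
  f <- .imposeDirichlet(f)
  validObject(f)
  f
}

.imposeDirichlet <- function(field) {
  if (field@bcType == "dirichlet")
    field@values[field@mesh@outerRadial] <- field@bcValue
  field
}

.fixedMask <- function(field) {
  fx <- logical(length(field@values))
  if (field@bcType == "dirichlet") fx[field@mesh@outerRadial] <- TRUE
  fx
}

.reactionVectors <- function(field, reaction) {
  n <- length(field@values)
  uptake <- production <- numeric(n)
  if (!is.null(reaction)) {
    if (!is.null(reaction$uptake)) {
      stopifnot(length(reaction$uptake) == n)
      uptake <- reaction$uptake
    }
    if (!is.null(reaction$production)) {
      stopifnot(length(reaction$production) == n)
      production <- reaction$production
    }
  }
  if (any(uptake < 0)) stop("uptake rates must be >= 0")
  list(uptake = uptake, production = production)
}

#' Maximum stable explicit time step for a field
#'
#' Forward-time central-space stability bound `h^2 / (6 D)` scaled by the
#' safety factor used throughout the package (0.2).
#'
#' @param field A [MolecularField-class].
#' @param safety Safety factor applied to the FTCS bound.
#' @return Time step in seconds.
#' @export
maxStableDt <- function(field, safety = 0.2) {
  h <- field@mesh@spacing
  safety * h^2 / (6 * field@D * CM2_TO_UM2)
}

#' Advance a field by one explicit diffusion step
#'
#' One forward-time central-space step of `du/dt = D lap(u) - uptake*u +
#' production - kdeg*u`. Uptake and degradation are applied implicitly
#' (exponential factor) so values remain non-negative. Dirichlet nodes are
#' re-imposed after the step; absent neighbours (end caps, curved surface of
#' Neumann species) are zero-flux.
#'
#' @param field A [MolecularField-class].
#' @param reaction `list(uptake=, production=)` per-node rates (1/s and
#'   conc/s); `NULL` for pure diffusion.
#' @param dt Time step, seconds; must satisfy the stability criterion (see
#'   [maxStableDt()]).
#' @return The advanced field.
#' @export
stepDiffusion <- function(field, reaction = NULL, dt) {
  dtMax <- maxStableDt(field) / 0.2          # hard FTCS bound
  if (dt > dtMax)
    stop(sprintf("unstable dt = %g s; maximum stable dt is %g s", dt, dtMax))
  rv <- .reactionVectors(field, reaction)
  h <- field@mesh@spacing
  u <- ftcs_step_cpp(field@values, field@mesh@nbr, .fixedMask(field),
                     rv$uptake + field@kdeg, rv$production,
                     field@D * CM2_TO_UM2, h^2, dt)
  if (anyNA(u)) stop("NaN in diffusion solution")
  field@values <- u
  .imposeDirichlet(field)
}

#' Advance a field over an interval by explicit sub-stepping
#'
#' Splits `dt` into stable FTCS sub-steps (continuum time steps are shorter
#' than agent time steps).
#'
#' @inheritParams stepDiffusion
#' @param dt Interval, seconds.
#' @return The advanced field.
#' @export
advanceField <- function(field, reaction = NULL, dt) {
  sub <- maxStableDt(field)
  nSub <- max(1L, ceiling(dt / sub))
  dtSub <- dt / nSub
  for (i in seq_len(nSub)) field <- stepDiffusion(field, reaction, dtSub)
  field
}

#' Solve a field to its quasi-steady profile
#'
#' Solves `D lap(u) - (uptake + kdeg) u + production = 0` with the field's
#' boundary conditions by SOR relaxation, warm-started from the current
#' values. Molecular diffusion across the duct equilibrates in tens of
#' seconds, far below the agent time step, so the quasi-steady profile is
#' the operative solution for the Dirichlet species.
#'
#' @inheritParams stepDiffusion
#' @param tol Relative max-update convergence tolerance.
#' @param maxSweeps Sweep budget.
#' @param omega SOR over-relaxation factor; `NULL` uses the grid-optimal value.
#' @return The solved field; attribute "sweeps" records the sweep count.
#' @export
solveFieldSteady <- function(field, reaction = NULL, tol = 1e-6,
                             maxSweeps = 20000, omega = NULL) {
  if (is.null(omega) || is.na(omega)) omega <- .optimalOmega(field@mesh)
  rv <- .reactionVectors(field, reaction)
  field <- .imposeDirichlet(field)
  h <- field@mesh@spacing
  sol <- sor_solve_cpp(field@values, field@mesh@nbr, .fixedMask(field),
                       rv$uptake + field@kdeg, rv$production,
                       field@D * CM2_TO_UM2, h^2, tol, maxSweeps, omega)
  u <- sol$values
  if (anyNA(u)) stop("NaN in diffusion solution")
  field@values <- u
  field <- .imposeDirichlet(field)
  attr(field, "sweeps") <- sol$sweeps
  field
}

#' Backward-Euler step of a field
#'
#' Implicit step of `du/dt = D lap(u) - (uptake + kdeg) u + production`,
#' unconditionally stable; used for AREG, whose pure-Neumann slow mode
#' (degradation-limited) must be time-resolved rather than assumed steady.
#'
#' @inheritParams solveFieldSteady
#' @param dt Time step, seconds.
#' @return The advanced field.
#' @export
stepDiffusionImplicit <- function(field, reaction = NULL, dt, tol = 1e-6,
                                  maxSweeps = 20000, omega = NULL) {
  if (is.null(omega) || is.na(omega)) omega <- .optimalOmega(field@mesh)
  rv <- .reactionVectors(field, reaction)
  h <- field@mesh@spacing
  sol <- sor_solve_cpp(field@values, field@mesh@nbr, .fixedMask(field),
                       rv$uptake + field@kdeg + 1 / dt,
                       rv$production + field@values / dt,
                       field@D * CM2_TO_UM2, h^2, tol, maxSweeps, omega)
  u <- sol$values
  if (anyNA(u)) stop("NaN in diffusion solution")
  field@values <- u
  .imposeDirichlet(field)
}

#' Apply first-order degradation to a field
#'
#' Multiplies non-Dirichlet nodal values by `exp(-kdeg * dt)` (the molecular
#' sink term L(u)).
#'
#' @param field A [MolecularField-class].
#' @param kdeg Degradation rate, 1/s.
#' @param dt Interval, seconds.
#' @return The degraded field.
#' @export
applyDegradation <- function(field, kdeg, dt) {
  if (kdeg < 0) stop("kdeg must be >= 0")
  fx <- .fixedMask(field)
  field@values[!fx] <- field@values[!fx] * exp(-kdeg * dt)
  field
}

#' Derive the FGF boundary condition from the previous AREG solution
#'
#' The AREG that leaves the duct stimulates stromal FGF production, which
#' re-enters the duct; numerically the FGF Dirichlet values on the outer
#' curved surface are set to the AREG values at those same nodes from the
#' previous time step. Interior FGF values are untouched.
#'
#' @param fgf The FGF [MolecularField-class] (Dirichlet).
#' @param aregPreviousStep The AREG field solution from time t-1.
#' @return The FGF field with updated boundary values.
#' @export
updateFgfBoundary <- function(fgf, aregPreviousStep) {
  m1 <- fgf@mesh; m2 <- aregPreviousStep@mesh
  if (!identical(m1@dims, m2@dims) || !identical(m1@spacing, m2@spacing) ||
      !identical(m1@origin, m2@origin))
    stop("mismatched meshes between FGF and AREG fields")
  fgf@bcValue <- aregPreviousStep@values[m1@outerRadial]
  .imposeDirichlet(fgf)
}
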