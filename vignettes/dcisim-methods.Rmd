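---
title: "Modeling early ductal carcinoma in situ with dcisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling early ductal carcinoma in situ with dcisim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

dcisim simulates the earliest stage of comedo-type ductal carcinoma in situ
(DCIS): a small niche of tumor-initiating cells (TICs) in the luminal layer
of a mammary duct section seeds a lesion that expands into the luminal
cavity and advances axially along the duct. The model is hybrid and
multiscale:

* **Discrete scale.** Every cell is an off-lattice spherical agent with its
  own position, size, layer (luminal, myoepithelial, intraductal), phenotype
  (TIC, progenitor, terminally differentiated, or mature duct cell),
  estrogen-receptor status (ER+ or ER-), life-cycle state and clocks.
* **Continuum scale.** Four molecular species are reaction-diffusion fields
  on the duct domain: oxygen and estrogen enter from the vascularized duct
  surface as constant Dirichlet values; amphiregulin (AREG) is produced
  inside the duct by ER+ cells and carries zero-flux conditions; FGF
  re-enters the duct with a time-dependent Dirichlet boundary equal to the
  previous step's AREG boundary values, a compact surrogate for the
  epithelial-to-stromal AREG-to-FGF relay.

The scales are coupled both ways each time step: agents interpolate nodal
concentrations at their centre of mass (trilinear interpolation, the
regular-grid analogue of barycentric interpolation on simplices), and each
agent's consumption or production is lumped at its nearest node (Voronoi
ownership) and normalized by the node's region volume. Consumption is
first-order in the local concentration, so uptake can never overdraw a node.

## Cell rules

A living TIC or progenitor divides when four gates pass simultaneously:
a full cell cycle since its last mitosis (`tauP` = 16 h); its signaling
threshold, a binary step on the interpolated local concentration (estrogen
for ER+ cells, FGF for ER- cells); no density-induced quiescence; and, for
progenitors, remaining proliferation potential (`Pmax` = 50 divisions,
exhaustion differentiates the cell terminally). Division splits the volume
evenly; daughters complete interphase by growing linearly back to the mature
volume over one cycle. A TIC division is symmetric (two TICs) with
probability `omegaSC` = 12%, asymmetric otherwise; progenitor divisions are
always symmetric. Wall-resident TICs place daughters into the luminal
cavity; intraductal daughters are placed isotropically and the mechanics
resolve the overlap.

Apoptosis is off: all death flows through hypoxia. An agent below the
hypoxia threshold (1/3 of the 100 mmHg boundary oxygen) accumulates hypoxic
time and becomes necrotic after 12 continuously hypoxic hours; return above
the threshold resets the clock (cells can survive transient hypoxia). A
necrotic cell swells to twice its pre-lysis volume over the 6-hour lysis,
bursts to a condensed residual of 30% of the pre-lysis volume, and calcifies
14 days after necrosis onset. Residual material within one node region is
merged into a single agent.

Density-induced quiescence is the population brake: an agent whose count of
living neighbours within the sensing radius exceeds `quiescenceLimit`
(N_q) is reversibly blocked from mitosis. Mature duct cells never
proliferate; the duct wall is rigid and intraductal agents are confined to
the luminal cavity. Agents that reach a truncated duct end are frozen there
and the run is flagged as saturated if they exceed 1% of the population.

## Numerical choices

* **Mesh.** A regular Cartesian grid (spacing = one mature cell diameter,
  10 um) masked to the duct cylinder replaces a general tetrahedral mesh;
  nodal fields, nearest-node ownership and region volumes are what the
  results depend on, not element type. Region volumes come from a
  subsampled cross-section partition, normalized so they sum exactly to the
  cylinder volume. Outer curved-surface nodes carry the Dirichlet
  conditions; the truncated end caps are zero-flux, as is the curved
  surface for AREG.
* **Field solves.** Molecular diffusion equilibrates across the duct in
  tens of seconds, far below the 0.1 h agent step, so the Dirichlet species
  (oxygen, estrogen, FGF) are solved to their quasi-steady profile each
  step (SOR relaxation with the grid-optimal over-relaxation factor,
  warm-started from the previous step). Explicit forward-time central-space
  stepping with sub-stepping is implemented and exported
  ([stepDiffusion()], [advanceField()]); a test verifies the quasi-steady
  and time-stepped solutions agree within 2%. AREG is different: its
  pure-Neumann slow mode relaxes on the degradation time scale (~1.4 h),
  so AREG is advanced by an unconditionally stable backward-Euler step at
  the agent time step instead of being assumed steady.
* **Field refresh cadence.** Signals gate mitosis decisions that occur at
  most once per 16 h cycle, so when thresholding is enabled the signaling
  fields are re-solved every 5 steps (0.5 h); with thresholding disabled
  they gate nothing and are refreshed at recording times only. Oxygen
  follows the same stride until any living agent senses oxygen within 1.5x
  of the hypoxia threshold, after which it is re-solved every step so the
  12-hour persistence clocks are resolved accurately.
* **Mechanics.** Overlaps are resolved by damped position-based relaxation:
  overlapping pairs separate along their centre line proportionally to the
  overlap, split by inverse radius, with immobile classes (duct wall,
  residual material, cap-frozen agents) never moving; iteration stops at a
  0.1 um residual overlap or 50 iterations. Neighbour search uses uniform
  spatial hashing. The relaxation is deterministic, so a fixed seed
  reproduces a run byte-for-byte.
* **Time step.** The agent step is 0.1 h; cell-cycle, hypoxia, lysis and
  calcification clocks are all integer multiples of it. Halving the step to
  0.05 h moves the headline 100 um metrics by under 2% (transition
  unchanged, doubling time -0.3%, linear slope +1.3%, advance rate +1.5%). Timer comparisons
  carry a 1e-9 h tolerance so accumulated floating-point error cannot delay
  a transition by a step.

# Parameters and calibration

Literature-baseline values (cycle time 16 h, 50 progenitor cycles, 12%
symmetric TIC division, 5 um mature radius, hypoxia threshold 1/3 normoxia,
12 h to necrosis, 6 h lysis with 100% swelling, calcification at 14 days
with 30% residual volume, diffusion constants per species) are the package
defaults; print `simConfig()` to see all of them. Four quantities the
source literature leaves unquantified were fixed once, as follows, and are
config-exposed:

* **Oxygen uptake scale** (`o2UptakeScale`). The printed healthy-cell
  consumption (45 attoMol/cell/s) needs an effective solubility to become
  the model's first-order clearance. The default (0.5 um^3/s per
  attoMol/s, i.e. a healthy clearance of 22.5 um^3/s and 4.5x that for
  cancer cells) was calibrated once against the oxygen penetration depth:
  a duct whose cavity is filled with cancer cells stays normoxic everywhere
  at 100 and 150 um luminal diameter and drops below the hypoxia threshold
  at 200 um, reproducing the reported hypoxia geography.
* **Quiescence criterion.** The sensing radius is 4 mature cell radii
  (20 um) with N_q = 30. A 12.5 um radius (1.25 diameters) was evaluated
  first and rejected: at that range the neighbour count cannot distinguish
  a packed interior (~9-11) from the advancing front (~5-10), which blurs
  the exponential-to-linear transition. At 20 um the compact interior
  (~38-42), the wall-hugging sleeve (~26-30) and the free leading edge
  (~12-22) separate cleanly. N_q was then calibrated once so the 100 um
  duct transitions between growth phases at 5-7 days, and frozen. A
  close-packed interior (12 touching neighbours) is quiescent under these
  defaults; an agent with a free hemisphere is not. The cycle clock pauses
  while an agent is quiescent (a released cell completes its remaining
  cycle before dividing); letting the clock run during quiescence converts
  packing jitter into a diffuse interior birth leak that destroys the
  linear phase.
* **Signaling rates.** AREG production and degradation are set so a mature
  duct sustains a normalized AREG level (hence FGF boundary level) near
  0.5, the scale on which the FGF thresholds (low 0.3 / medium 0.4 / high
  0.5) operate. ER+ estrogen clearance (120 um^3/s) is set so a dense ER+
  region depletes local estrogen by 10-20%, making the estrogen thresholds
  (0.8 / 0.85 / 0.9 on a boundary value of 1) operative — an
  estrogen-limited ER+ rim slows while the ER- rim does not. ER- FGF
  clearance mirrors the estrogen value class at 40 um^3/s.
* **ER ratio.** Non-TIC agents are ER+ with probability 0.5 in both mature
  layers (the source states only that the assignment is stochastic), and
  ER+ cells of both layers produce AREG.

# Growth-phase segmentation

Daily DCIS counts are segmented into an exponential phase `y = a e^{kt}`
(log-linear least squares) and a linear phase by scanning every candidate
split and maximizing the R-squared of the combined piecewise model, with
residuals pooled on the original scale across both subsets. The transition
time is the intersection of the two fitted curves inside the boundary
interval (midpoint fallback), which recovers the breakpoint of noiseless
constructed biphasic series to within half the sampling interval and yields
continuous (non-grid) transition estimates. Two plausible alternatives were
evaluated and rejected: scoring the linear phase through the origin (the
printed tabular form of the linear fits) makes the linear R-squared improve
monotonically as the split moves late, biasing the estimated transition
several days late even on constructed series; scoring the phases separately
with an intercepted linear fit over-rewards early splits. The through-origin
variant remains available (`combine = "product"`). The exponential-phase
doubling time is `24 ln 2 / k` hours; axial advance rates are OLS slopes of
the bidirectional axial extent over the post-transition window, with
`mm/yr = um/day * 365/1000`.

Local sensitivity uses `S = (dM/M)/(dp/p)` with forward differences from
baseline, one parameter varied multiplicatively at a time, and common random
numbers (the same seed set at every variation) to suppress Monte-Carlo noise
in S.

# Reference study conditions

The reference conditions the package's acceptance checks (and
`scripts/acceptance.R`) run are: 5 TICs seeded contiguously at the axial
centre of the luminal layer; duct sections 1 mm long with luminal diameters
100/150/200 um; signaling thresholds disabled for the growth-phase runs;
12 simulated days at 100 um, 13 at 150 um; 3-4 seeds per condition with
medians reported. The 200 um check runs 22 days: its tumor mass must exceed
the radial oxygen penetration depth before hypoxia can appear, which under
these calibrated conditions happens at about day 20 (the corresponding
source analyses of the 200 um duct ran 30 days). Threshold experiments
compare minimal (estrogen 0.8, FGF 0.3) against high (0.9, 0.5) thresholds
over 10 days in the 100 um duct. The desk-scale sensitivity check compares
cell-cycle-time against FGF-threshold sensitivity of the advance rate on
100 um/12-day runs at a single 0.8-fold variation; the full variation grid
(0.8-1.2 in 0.05 steps over 30-day 200 um runs) is implemented in
[sensitivitySweep()] but is cluster-scale work.

# What the generator emulates — and what it does not

The procedural seeding builds an idealized mature duct: two perfectly
cylindrical single-cell-thick rings, uniform cell size, a rigid wall, and a
contiguous TIC niche. Real ducts taper, branch and dilate under tumor load
(reported DCIS-bearing ducts average ~3x the healthy diameter), myoepithelial
coverage is discontinuous, and stromal signaling is spatially heterogeneous
rather than the instantaneous boundary relay modeled here. Passing checks
therefore demonstrate internal consistency of the mechanism — biphasic
growth from density restriction, advance rates in the clinically reported
band, hypoxia geography set by duct caliber — not calibration against any
patient-level data beyond the literature ranges above.

## Known limitations

* The duct is rigid: no dilation, so late-time cell densities exceed what a
  compliant duct would show.
* Quiescence is a hard neighbour-count step; graded contact inhibition
  would smooth the transition region.
* The stromal compartment is the Eq.-style boundary relay only; no spatial
  stroma, no p63 myoepithelial suppression, no de-differentiation, no
  invasive transition, no therapy.
* Agent time step and mesh spacing are tuned for cell-scale questions;
  subcellular signaling dynamics are intentionally out of scope.
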