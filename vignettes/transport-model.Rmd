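---
title: "The oxychip transport model: assumptions, calibration and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The oxychip transport model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The device and the modelling question

The chip is a 20 × 20 mm (5 mm thick) gelatin hydrogel laced with void
microchannels left behind by sacrificial polymer fibers. Supply channels run
along opposite sides of the gel: one perfuses normoxic medium
(5.45 mg/L dissolved O₂) at a nominal channel velocity of 100 mm/s, the
other holds deoxygenated medium at zero net velocity. Embedded tumour tissue
consumes oxygen. The questions the model answers are:

1. What is the gel's *effective* oxygen diffusion coefficient as a function
   of fiber density, given probe readings taken 10 mm from a single inlet
   after 1 min of perfusion?
2. What steady oxygen gradient develops between the two supply channels
   once cellular consumption is accounted for, and does it cover the
   physiological range from portal vein (0.6–0.7 mg/L) through liver tissue
   (1.5–2.0 mg/L) to hepatic artery (4.4–5.2 mg/L)?
3. What joint (O₂, drug) exposure does each location receive when a drug
   gradient is superposed perpendicular to the oxygen gradient?

# Governing equations and the 2-D reduction

Flow through the gel obeys Darcy's law with permeability equal to the
reciprocal of the viscous resistance, `k = 1/R_v` with
`R_v = 7.5 × 10¹¹ m⁻²`; the incompressible pressure problem
`∇·((k/μ)∇P) = 0` is solved with prescribed inflow fluxes, a gauge-zero
outflow and no-flux walls. Species transport is

```
φ ∂c/∂t + ∇·(u c) − ∇·(D_eff ∇c) = 0,     D_eff = D_ratio · D_OM,
```

with porosity `φ` scaling storage only, `u` the superficial Darcy velocity
and `D_OM = 2.88 × 10⁻⁹ m² s⁻¹` the oxygen-in-medium coefficient at 37 °C.
Porosity is the measured function of fiber density (38.8, 44.4, 54.6 and
73.0 % at 0–3 mg/mL, linearly interpolated); `D_ratio` is deliberately *not*
derived from porosity — it is the free material parameter the probe
calibration estimates, so that every fiber-density-dependent transport
effect is lumped into one measurable coefficient.

The in-plane gradients are the object of interest, so the 3-D chip is
depth-averaged into a plan-view cell-centered grid (origin at the lower-left
corner, x rightward, y upward). Ports become boundary strips of width equal
to the port diameter (1 mm). Concentrations are carried in mg/L throughout;
supply concentrations quoted per mL in some sources are physically
dissolved-oxygen levels and are treated as mg/L.

## The supply duct is resolved, not boundary-averaged

An early design iteration applied the 100 mm/s inlet directly to the gel
boundary. In a homogeneous Darcy medium the port-to-port flow is a corner
source/sink potential flow whose streamlines sweep the entire gel; at the
resulting Péclet numbers (10³–10⁵) the gel is simply flushed to the inlet
concentration and no transverse gradient can form — contradicting what the
physical device does. The resolution is the physics of the device itself:
perfusion flows along an *open duct*, not through the gel. The duct is
therefore resolved in-domain as a strip of cells (one port-diameter deep,
along the top edge) with open-channel properties: permeability
`d²/3.2` — an order of magnitude above the circular-tube equivalent
`d²/32`, so that duct conduction dominates gel seepage; behaviour is
insensitive to the exact value once it does — porosity 1 and free-medium
diffusivity. With the duct resolved, >99 % of the perfusion stays in the
duct, the gel below remains diffusion-dominated, and the steady field is a
near-linear transverse gradient between the duct (≈5.45 mg/L) and the
hypoxic contact (0 mg/L), which is exactly the regime the device is built
to produce.

The hypoxic channel carries no net flow, so it enters the model as a
zero-flow concentration contact along the full bottom edge (its inlet port
sits at the bottom-left). The oxygen outlet is the duct's outflow port at
the top right.

# Inverse calibration of the diffusion coefficient

## Scenario design

The single-inlet calibration chip is deoxygenated, then perfused with
normoxic medium for 60 s while a probe reads dissolved oxygen 10 mm from the
inlet. Two transport facts pin down the regime the model must be in:

* pure diffusion cannot reach the probe in a minute
  (`erfc(x/(2√(D_OM t))) ≈ 10⁻⁶³` at x = 10 mm, t = 60 s), and
* full 100 mm/s perfusion through the gel would flush it to the inlet
  concentration within seconds, making the probe reading independent of D.

Since measured probe profiles *are* strongly sensitive to fiber density,
transport to the probe must be advection-assisted but diffusion-limited:
the advective front must sit near the probe at read-out time, so that the
reading samples the diffusive shoulder of the front. The 100 mm/s figure is
therefore interpreted as the supply-channel velocity, and the gel seepage in
the calibration scenario is a free model parameter, defaulted to
`1.15 × 10⁻⁴ m/s` superficial — placing the 1-min interstitial front
(`u/φ · 60 s ≈ 9.4 mm`) just short of the 10 mm probe. This value was fixed
from that front-position argument. The inlet manifold is modelled as a strip
spanning the inlet face, giving plug flow on a quasi-1-D column
(2400 × 3 cells by default).

## Sweep, regression curve and inversion

`sweep_diffusion()` runs the forward transient at diffusivity ratios
{1, 0.5, 0.2, 0.1, 0.05} and records the probe oxygen; the curve must be
strictly increasing in D or an error identifies the offending pair.
`fit_calibration()` interpolates with a shape-preserving monotone
(Hyman-filtered) cubic spline of **log(O₂) against log(D)**: the probe
response decays near-exponentially at the low-D end, so the log transform
linearizes the curve and keeps 5-node interpolation accurate there (off-node
inversion errors ≲0.5 % versus several percent without the transform). A
log-linear least-squares fit is available behind `method = "loglinear"`.
`estimate_D()` inverts a measured reading numerically; measurements outside
the curve span are clamped to the nearest endpoint and flagged
`in_range = FALSE` rather than extrapolated — a 5-point curve is no basis
for extrapolation.

One *reference* curve (porosity of the working 3 mg/mL gel) serves all
fiber densities: readings from any gel are inverted on the same curve, so
density-dependent transport differences are attributed entirely to the
estimated D. This mirrors how the probe measurements are integrated into a
single regression curve in practice; a per-point mode is available through
the `probe_x` argument.

# Cellular consumption

The consumption chain is plain arithmetic with explicit units:
cells/chip × per-cell rate (μg/s) = chip rate (μg/s), divided by a
reference oxygen concentration (mg/L ≡ μg/mL) = influx volume (mL/s). The
working defaults — per-cell rate 3.2 × 10⁻⁹ μg/s and reference
concentration 16/7 mg/L — are back-computed so that 5 × 10⁶ cells give
1.6 × 10⁻² μg/s and 0.007 mL/s; both carry a `"paper-implied"` provenance
tag in configurations and logs because only the end points of the chain are
published.

Consumption enters transport in one of two ways:

* **Influx boundary (default):** deoxygenated medium enters through the
  upper-wall strip at the computed volume rate. This is the representation
  used for the headline steady two-inlet solve. The influx water joins the
  supply duct, so its direct effect is a small dilution of the normoxic
  stream.
* **Distributed sink (alternative):** first-order uptake
  `k_c = Q_influx / V_gel ≈ 3.5 × 10⁻³ s⁻¹` applied to hydrogel cells
  (`sink_rate` argument, `distributed_sink_rate()`). This represents the
  biology directly — cells consume where they sit — and produces the
  sinh-shaped profiles whose linearity improves with diffusivity. It is the
  mode of choice for studying how uptake shapes the gradient.

# Dual gradient, zones and viability

The drug gradient is perpendicular to the oxygen gradient: a drug-bearing
channel contacts the gel along one perpendicular edge at 3 × IC50 and a
drug-free channel holds the opposite edge at zero. The steady drug field is
solved **without Darcy flow**: drug delivery into the gel is diffusive from
the flanking channels, and the oxygen-perfusion duct does not run through
the drug axis. (Solving the drug species under the oxygen duct's flow would
smear the drug gradient along the duct and destroy the mirror symmetry the
configuration is designed to have.) Drug diffusivity defaults to a
Stokes–Einstein-style molecular-weight scaling
`D_drug = D_OM (32/MW)^{1/3}` (doxorubicin 543.5, sorafenib 464.8 g/mol),
overridable.

IC50 is read off the dose–response trendline by log-linear interpolation
between the doses bracketing 50 % viability; a four-parameter logistic fit
(`minpack.lm`) is available for synthetic-data work. Zone classification
uses the closed physiological intervals with gaps labelled `intermediate`
and out-of-range values `below_portal`/`above_artery`; the six labels
partition the line, so classification is total and idempotent. Viability
binning uses half-open bins `[edge, next)` with the final edge closed,
rejects (and counts) out-of-domain points, and leaves empty bins `NA`.

# Numerics

* **Spatial discretization:** finite volumes, harmonic-mean face
  permeabilities and diffusivities (layered media exact), first-order upwind
  advection. Upwinding is chosen for monotonicity: together with implicit
  diffusion it guarantees the discrete maximum principle, which the tests
  assert on randomized boundary data. The price is numerical diffusivity
  `u Δx/2`; the calibration column uses Δx ≈ 8 μm to keep it a fraction of
  the smallest swept physical diffusivity, and because the same forward
  model generates and inverts the calibration curve, the residual bias
  cancels in the round trip.
* **Time stepping:** explicit upwind advection under an advective CFL of
  0.9 (`dt = "auto"` picks the largest stable step, capped at `t_end/200`
  so diffusion-only columns still resolve their transient; a user-fixed
  `dt` violating the bound errors with the admissible value). Diffusion is
  backward-Euler implicit; the operator is factorized once per run
  (sparse Cholesky) and reused every step.
* **Steady states** are solved directly as one sparse linear system; the
  upwind/harmonic discretization is an M-matrix, so the direct solution
  obeys the same bounds as the time-marched one. The residual is verified
  against a 10⁻⁶ relative tolerance.
* **Degenerate inputs:** zero-velocity inlets act as pure concentration
  contacts; a constant probe profile has linearity R² defined as 1 (a flat
  line describes it perfectly); boundary concentration ties at shared zone
  endpoints cannot occur because the stated ranges are disjoint; solver
  outputs are checked against negative undershoot beyond round-off.
* **Problem sizes** (chosen as the package's working resolutions): 101 × 101
  cells for steady chip solves, 2400 × 3 for calibration transients,
  800 × 3 for the diffusion-column verification; the full test suite and the
  acceptance pipeline each run in well under a minute on one CPU.

# What the synthetic data do and do not show

The generators emulate the *structure* of the real measurements — probe
profiles with multiplicative 1 % noise, logistic dose–response tables with
additive 2 % noise clipped to [0, 1.2], live/dead point clouds whose
survival follows a hypoxia-protective logistic response — with ground truth
known and every draw seeded. The ground-truth diffusivity ratios per fiber
density (0.06, 0.15, 0.35, 0.80 at 0–3 mg/mL) encode the qualitative
stepwise rise of D with fiber density; they are synthetic-world choices, not
measured values. Passing the recovery tests therefore demonstrates that the
*pipeline* is correct and well-conditioned (the inverse problem round-trips
within a few percent at realistic noise), not that the noise models match
any particular instrument. Real probe data may carry position errors,
drift and boundary-layer artefacts that the generators deliberately omit.

# Known limitations

* The 2-D depth-averaged reduction cannot represent vertical stratification
  across the 5 mm thickness, nor the 1 mm cylindrical port geometry.
* Consumption is either a boundary influx or a linear sink; saturable
  (Michaelis–Menten) kinetics and proliferation/death feedback are out of
  scope, as are Henry's-law partial-pressure conversions, CO₂/pH transport
  and temperature dependence.
* The drug solve ignores pharmacokinetic decay, binding and any mechanistic
  link from (O₂, drug) exposure to death; the package measures and bins
  viability, it does not predict it.
* The duct-strip idealization replaces channel hydrodynamics with Darcy
  conduction; it preserves fluxes and residence times at the fidelity the
  plan-view model needs, not wall shear or entrance effects.
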