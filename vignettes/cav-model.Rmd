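---
title: "The cavsim model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cavsim model: assumptions, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cavsim` is a stochastic agent-based model of cardiac allograft vasculopathy
(CAV): the accelerated, inflammation-driven intimal thickening that narrows
the coronary arteries of transplanted hearts.  The model represents an
idealized cross-section of a mouse left coronary artery and follows it for
four simulated weeks at one-hour steps.  This vignette records the model's
assumptions, the meaning and defaults of every tunable parameter, and the
design decisions taken where the underlying biology or published material
leaves the implementation open.

## The lattice and the vessel

The cross-section lives on a 141 x 141 hexagonal lattice with one cell per
site and a physical pitch of 2 um per site.  Distances and angles are
computed from the real-space site centres, so the six neighbours of a site
all sit at distance exactly 1.  The vessel is concentric: a lumen of radius
40 sites (80 um), an intima, a one-site internal elastic lamina (IEL) of
inert agents, and a media, for a total wall thickness of 16 sites (32 um).
The published material does not state how the 16-site wall divides between
intima and media; `cavsim` defaults to 5 sites of intima and 10 of media,
configurable through `layer_split`.  A multi-site intima is required for
the macrophage infiltration rearrangement, which needs a "deeper intimal
site" below the lumen wall.

Intima and media are populated at 60% smooth muscle cells (SMC) and 40%
extracellular matrix (ECM), with the realized count per layer equal to the
rounded fraction and random placement.  Each agent carries a cell-cycle
clock drawn uniformly over its cycle (SMC 12 h, ECM 2 h, macrophage 12 h),
so the population starts desynchronized; an agent is tested for events when
its clock completes and the clock then resets whether or not an event
fired, fixing the per-agent testing rate at one per cycle.

## Stimuli

**Inflammation.** `I_input` in [0, 1] is either absent, uniform at a level
(the symmetric stimulus; 0.5 represents mid-level inflammation), or a 2D
Gaussian `exp(-d^2 / (2 sigma^2))` peaking at 1 at a random site of the
top-right intima (the non-symmetric stimulus, default sigma 15 sites).
The field is spatial and time-independent, and it is pinned to the
*initial* intima band: tissue that grows into the lumen later carries no
inflammatory input.  This is deliberate.  If newly grown intima inherited
the stimulus, event counts would grow with the intima and the lumen loss
would self-accelerate into occlusion in every stimulated scenario; with the
fixed support the loss is linear in time, which is the published behaviour
of the model and the reason calibrated probability coefficients can hold
over four weeks.

**Wall shear stress.** The lumen wall (the first intima layer) receives a
Poiseuille WSS profile at constant flow: the equivalent radius comes from
the current lumen area, `Umax = 2 Q / (pi R_eq^2)`, and per wall site
`WSS_i = 2 mu Umax / R_I` with `R_I` the physical distance to the peak
velocity location and `mu = 3.5 cP`.  A non-symmetric profile displaces
the peak by 0.4 `R_eq`; the displacement points toward the bottom-left so
the *low*-WSS, high-dysfunction region falls at the top-right, co-located
with the non-symmetric inflammation.  The sigmoid
`D(WSS) = 1 - 1/(1 + exp(L1 (WSS - L2)))` maps WSS to an endothelial
dysfunction level in (0, 1) (`D(L2) = 0.5` exactly), and the intimal input
is the cosine-decayed sum `sum_i D_i Amp (1 + cos(pi x / dist))` over wall
sites within `dist = 20` sites, clamped to [0, 1].  The profile is
recomputed every hour against the remodeled lumen, keeping `Q` constant.
Note that with this Poiseuille scaling the absolute WSS levels come out
higher than the display ranges quoted for the flow rates used here; the
flow rates are honoured as configuration, and dysfunction responds to the
levels the model computes.  In practice WSS contributes materially only at
the lowest flow (the severe case), which matches the model's
inflammation-dominated behaviour.

**Chemoattractant.** Once the macrophage cluster peaks (one week), it
releases a generic chemoattractant that diffuses from the frozen cluster
centroid as a free 2D Gaussian,
`Ca = Ca0/(4 pi D td) exp(-d^2/(4 D td))`, normalized to [0, 1] over the
current intima.  The published diffusion constant 0.45 (lattice units) has
an ambiguous time base; `cavsim` measures `td` in days since release,
which keeps the field concentrated (spread about 4 sites at 4 weeks) and
the chemoattractant-driven growth local.  A broader reading (hours) makes
the normalized field cover the whole intima and drives every
chemoattractant scenario into occlusion, which contradicts the published
localized invaginations; the narrower published-formula reading (fractions
of the window) collapses the field to under one site and inactivates the
mechanism entirely.

## Events and probabilities

All events are Monte Carlo tested.  The published procedure describes test
numbers with two significant digits; at two decimals every probability in
(0, 0.01] collapses to the same effective rate and the gamma calibration
grid becomes indistinguishable, so the engine draws continuous uniforms
(the exported `monte_carlo_test()` retains a `digits` argument, default 2,
for the literal contract).  Where one agent can experience competing
events (mitosis/apoptosis/production), a single draw is partitioned into
disjoint intervals after joint clamping, so contradictory events cannot
fire together.

In the intima, SMC mitosis is
`alpha1 + alpha3 I + alpha4 n_MP + alpha11 WSS + alpha13 Ca` against
baseline apoptosis `alpha1`; ECM production is
`alpha2 + alpha5 I + alpha6 n_MP + alpha12 WSS + alpha14 Ca` against
degradation `gamma alpha2`.  In the media every probability is baseline,
so the media stays in homeostasis and keeps its area.  ECM production is
tested on every eligible wall agent at its site's production probability —
SMCs synthesize matrix on their 12-hour cycle and matrix sites turn over
on their 2-hour cycle — while degradation is tested on ECM agents only.
At the 60/40 composition this makes the analytic homeostasis balance
`gamma = 1 + S/(6E) = 1.25`, and the package default `gamma = 1.25` is the
value the calibration procedure (`calibrate_gamma()`) recovers: five grid
values, replicated baseline runs, linear interpolation of the mean
final/initial ECM ratio at 1.

Macrophages infiltrate through the lumen wall between day 2 and week 1 (at
most one per hour): the `try` highest-probability wall sites are tested in
descending order of
`alpha7 (1 + I)(1 + alpha8 e^{-dist_MP})(1 + MP_group/alpha9)`, and the
access site triggers the three-site rearrangement that places a macrophage
in the deeper intima.  Their two-phase dynamics favour mitosis
(`alpha10` vs `alpha10/2`) until the week-1 peak and apoptosis afterwards,
reproducing the rise-and-decline of graft-infiltrating cells.  From week 1,
one medial SMC per hour may migrate to the intima: the source is drawn
within `c_radius` of the chemoattractant centroid, the end site among
intima sites whose normalized concentration does not round to zero at the
model's two-decimal probability resolution (>= 0.005), and the move is
accepted against `Ca_norm` at the end site.  The draw is retried (up to 10
times) within the hour so the realized rate approaches the nominal one
migrating SMC per hour; the vacated medial site is refilled with ECM, so
the media progressively trades SMC for matrix.

## Remodeling and regularization

Intimal events remodel inward (lumen area changes one site per event),
medial events outward (lumen-neutral).  A growth or shrinkage event shifts
the column of tissue between the event site and the border along a
6-neighbour ray.  The exit site of the ray is chosen within a 9-site
window along the border to equalize the border radius — additions deposit
where the border lags, removals take tissue from where it runs ahead, with
tissue contact breaking ties.  This is the package's reconstruction of the
local agent redistribution that keeps the published borders smooth: it
suppresses the stochastic lobes that an unregularized +/-1 random walk
accumulates over 672 hours, while genuinely driven invaginations, which
are wider than the window, persist.  A bounded post-hoc pass additionally
relocates border agents with fewer than three tissue neighbours into
nearby higher-contact positions, and any IEL site that lost its inert
agent is restored.  Regularization preserves all agent counts and never
moves an agent across the IEL.  The window length is the model's smoothing
scale; 9 sites reproduces both published anchors available for this
mechanism (the low symmetric-scenario asymmetry and the deep scenario-14
invagination) and is not otherwise tuned.

## Scenarios and CAV cases

`build_scenario()` encodes the fourteen published testing scenarios
(inflammation absent / uniform 0.5 / Gaussian; WSS absent / centered
Q = 0.13 / off-centered Q = 0.20 mL/min; macrophage and chemoattractant
events on or off) and three CAV cases derived from scenario 14 by varying
the inflammation exposure region and the flow rate.  The published
material specifies the case regions only as small, mid-sized and large;
`cavsim` uses Gaussian spreads of 12, 15 and 65 sites at flow rates 0.30,
0.20 and 0.10 mL/min.  The moderate case keeps the scenario-14 inputs; the
severe spread exposes most of the circumference, consistent with the
diffuse concentric thickening of severe CAV, and the triplet was chosen
once so that the three cases span the published mild/moderate/severe
lumen-loss classes under this engine's event arithmetic.  The severe flow
rate is implemented as 0.10 mL/min (the published "10 mL/min" alongside a
5-10 Pa display range is taken as a typographical slip).

What the generator emulates: geometry and composition of a healthy mouse
coronary cross-section, desynchronized cell cycles, localized or uniform
inflammatory exposure, flow-dependent dysfunction, and the timing of
graft-infiltrating cells.  What it does not: real vessels are neither
circular nor 2D, the media responds to stimuli in vivo, immune phenotypes
beyond a generic macrophage are absent, and flow is steady rather than
pulsatile.  Passing tests therefore certify the model's internal
mechanics and its agreement with the published simulated behaviour, not
agreement with histology.

## Sensitivity analysis

`lhs_sample()` draws a stratified Latin hypercube over the 17 sampled
parameters (`param_ranges()`); the integer parameter `try` is sampled
continuously and rounded.  `sensitivity_study()` runs the simulator per
design row (scenario-14-like template by default — the most general
configuration; the published description does not state the scenario used),
averages replicates, extracts the five outputs (lumen area, intima area,
intimal SMC/ECM/MP contents) at 1 and 4 weeks, and computes partial rank
correlation coefficients: rank-transform everything, residualize the
target column and the output on the remaining columns by least squares,
correlate the residuals, and take p-values from the t statistic with
`k - j - 1` degrees of freedom.  Significance uses Benjamini-Hochberg FDR
at 0.05 within each horizon (the correction method is not specified in the
published material; BH is the standard default).

## Numerical choices and problem sizes

* Probabilities are clamped to [0, 1] after summation; competing events on
  one agent share a partitioned draw.
* The WSS distance `R_I` is floored at half a site pitch to avoid division
  blow-up at the near wall; occluded lumens raise a condition rather than
  returning non-finite fields.
* Event sites displaced by earlier rearrangements within the same hour are
  remapped through the shift maps, so an agent's pending event follows the
  agent; events whose agent no longer exists are skipped and counted.
* Per-hour agent conservation is asserted inside the engine (`check_ledger`)
  against the fired-event tally.
* Polar profiles use 360 angular bins with circular interpolation of empty
  bins; the NS-index is the binned-range of the lumen radius over the
  initial radius.  On a lattice a perfect circle retains a ~2-3% residual
  from quantization.
* Band boundaries carry a 1e-6 epsilon so knife-edge sites cannot straddle
  a layer.
* The test suite exercises full 4-week runs on the 141 x 141 lattice for
  the homeostasis, scenario-class and CAV-case checks, and uses a 41 x 41
  lattice (lumen radius 10, wall 6) for unit, property, calibration and
  sensitivity checks; these reduced sizes are the package's chosen
  trade-off between statistical power and suite turnaround.

## Known limitations

The calibrated degradation coefficient depends on which agents test
matrix production; published values for the calibration (1.301), the
severe-case composition (42% SMC) and the case-wise lumen losses
(30/50/80%) cannot all be produced by a single production-testing scheme
in this reconstruction.  `cavsim` adopts the scheme whose analytic balance
(1.25) matches the published calibration, and documents that the mild and
moderate case severities and the severe-case SMC share sit below the
published figures under it.  WSS enters only as magnitude; oscillatory or
multidirectional descriptors, 3D geometry, immunosuppression and
additional immune phenotypes are out of scope.
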