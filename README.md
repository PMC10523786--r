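# cavsim

Stochastic agent-based simulation of **cardiac allograft vasculopathy
(CAV)** — the accelerated, inflammation-driven coronary disease of
transplanted hearts — in an idealized mouse left-coronary-artery
cross-section.

The model lays a vessel (lumen radius 40 sites, wall 16 sites, 2 µm/site)
on a 141 × 141 hexagonal lattice and follows it hourly over a 4-week
follow-up. Smooth muscle cells (SMC), extracellular matrix (ECM) and
macrophages (MP) undergo probabilistic events whose rates are perturbed by
two stimuli:

* an **inflammatory input** `I ∈ [0,1]`, uniform or a spatial Gaussian
  `exp(−d²/2σ²)` localized at the top-right intima, and
* a **wall-shear-stress input**: a Poiseuille WSS profile at constant flow
  `Q` (`WSS_i = 2 µ U_max / R_I`), mapped through the endothelial
  dysfunction sigmoid `D(WSS) = 1 − 1/(1 + e^{L1 (WSS − L2)})` and
  propagated into the intima by a cosine decay.

Intimal events remodel inward (each net event moves the lumen area by one
site), medial events outward. SMC mitosis in the intima follows
`α1 + α3 I + α4 n_MP + α11 WSS + α13 Ca`; ECM production follows
`α2 + α5 I + α6 n_MP + α12 WSS + α14 Ca` against degradation `γ α2`;
macrophages infiltrate through the lumen wall between day 2 and week 1 and
then release a diffusing chemoattractant `Ca` that drives local growth and
medial-to-intimal SMC migration. Under absent stimuli the rules balance —
homeostasis — with `γ` the calibrated degradation coefficient.

The package is intended for computational modellers studying vascular
mechanobiology and chronic transplant rejection: it provides the full
simulation engine, the 14-scenario testing grid and the mild/moderate/
severe CAV cases, lumen-asymmetry metrics (NS-index), the γ calibration
procedure, and a Latin-hypercube / PRCC global sensitivity analysis, all
returning tidy tibbles with `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(cavsim)

# the most general published configuration: non-symmetric inflammation,
# non-symmetric WSS at Q = 0.20 mL/min, macrophage + chemoattractant events
r <- run_simulation(build_scenario(14), seed = 1)
r
#> <cav_simulation> 'scenario-14', seed 1: 672 h simulated, time_elapsed
#>   lumen area 5815 -> 4334 sites (25.5% reduction); intima 1518 -> 2999

ns_index(r$section)
#> # A tibble: 1 x 3
#>   r_min r_max ns_index
#>   <dbl> <dbl>    <dbl>
#> 1  24.9  41.0     40.2
```

The lumen lost a quarter of its area, almost all of it in a deep
invagination at the inflamed top-right sector: the binned polar lumen
radius spans 24.9 to 41.0 sites, an NS-index (radius spread over the
initial 40-site radius) of 40% — a strongly non-symmetric lesion, against
≈5% for the uniformly
inflamed scenario 1. `tidy(r)` returns the hourly series of areas and
intimal contents, `autoplot(r)` plots them, and
`autoplot(r$section)` renders the remodeled cross-section.

Calibration and sensitivity analysis run the same way:

```r
cal <- calibrate_gamma(reps = 10, seed = 1)   # grid {1..1.5}, 10 runs each
attr(cal, "gamma_star")

design <- lhs_sample(param_ranges(), k = 100, seed = 1)
prcc_tab <- sensitivity_study(design, reps_per_sample = 3)
plot_prcc(prcc_tab)
```

A thin command-line front end is installed with the package
(`exec/cavsim`): `simulate`, `calibrate-gamma`, `sensitivity` and
`metrics` subcommands emit CSV series/tables and a JSON run manifest.

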