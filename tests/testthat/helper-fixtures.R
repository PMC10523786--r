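# Reduced-lattice fixtures shared across the suite.  A 41 x 41 grid with a
# 10-site lumen and a 6-site wall (2 intima / 1 IEL / 3 media) keeps whole
# 4-week runs fast while exercising every code path.

tiny_spec <- function() lattice_spec(41L, 41L)

tiny_split <- c(intima = 2L, iel = 1L, media = 3L)

tiny_section <- function(seed = 1, smc_fraction = 0.6) {
  build_cross_section(tiny_spec(), lumen_radius_sites = 10,
                      wall_thickness_sites = 6, smc_fraction = smc_fraction,
                      layer_split = tiny_split, rng_seed = seed)
}

tiny_run <- function(scenario, seed = 1, params = param_midpoints(),
                     tl = timeline(), ...) {
  run_simulation(scenario, params = params, tl = tl, seed = seed,
                 spec = tiny_spec(), lumen_radius_sites = 10,
                 wall_thickness_sites = 6, layer_split = tiny_split,
                 snapshot_times = integer(0), ...)
}

# occupancy / layer code helpers mirroring the package's internal coding
OCC <- c(lumen = 0L, SMC = 1L, ECM = 2L, IEL = 3L, MP = 4L, exterior = 5L)
LAY <- c(lumen = 0L, intima = 1L, IEL = 2L, media = 3L, exterior = 4L)

# independent coordinate oracle for the odd-row-offset hex layout
hex_xy_oracle <- function(row, col) {
  cbind(x = col + 0.5 * (row %% 2), y = row * sqrt(3) / 2)
}
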