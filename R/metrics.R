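# Quantitative outputs: NS-index, composition fractions, lumen-area
# reduction, representative-replicate selection and gamma calibration.

#' Non-symmetry (NS) index of the lumen
#'
#' Percentage ratio between the spread of the lumen radius in polar
#' coordinates and the initial lumen radius:
#' `NS = (R_max - R_min) / R0 * 100`, with the radii taken from the binned
#' [polar_profile].  A perfectly concentric lumen scores near zero (lattice
#' quantization leaves a small residual); strongly eccentric growth scores
#' above 20.
#'
#' @param v A [vessel_section].
#' @param R0 Initial lumen radius, sites (defaults to the section's).
#' @param n_bins Angular bins of the polar profile.
#' @return A one-row tibble with `r_min`, `r_max` (sites) and `ns_index`
#'   (percent).
#' @export
ns_index <- function(v, R0 = NULL, n_bins = 360L) {
  if (is.null(R0)) R0 <- v$lumen_radius_sites
  pp <- polar_profile(v, n_bins)
  tibble::tibble(r_min = min(pp$radius), r_max = max(pp$radius),
                 ns_index = (max(pp$radius) - min(pp$radius)) / R0 * 100)
}

#' Intimal composition at a time point
#'
#' Percentages of SMC, ECM and macrophage agents among the intimal agents at
#' hour `t` of a simulation; the three percentages sum to 100.
#'
#' @param result A `cav_simulation`.
#' @param t Hour (must be within the recorded series).
#' @return A one-row tibble with `t`, `smc_pct`, `ecm_pct`, `mp_pct`.
#' @export
composition <- function(result, t) {
  s <- result$series
  row <- s[s$t == t, ]
  if (nrow(row) != 1L)
    stop("hour ", t, " is not within the recorded series", call. = FALSE)
  tot <- row$intima_smc + row$intima_ecm + row$intima_mp
  if (tot == 0L) stop("empty intima at hour ", t, call. = FALSE)
  tibble::tibble(t = t,
                 smc_pct = 100 * row$intima_smc / tot,
                 ecm_pct = 100 * row$intima_ecm / tot,
                 mp_pct = 100 * row$intima_mp / tot)
}

#' Lumen area reduction at the end of a run
#'
#' @param result A `cav_simulation`.
#' @return Percent reduction of the lumen area from its initial value.
#' @export
lumen_area_reduction <- function(result) {
  s <- result$series
  100 * (1 - s$lumen_area[nrow(s)] / s$lumen_area[1L])
}

#' Select the representative replicate
#'
#' Averages the final lumen polar profiles bin-wise across replicates and
#' returns the replicate whose profile has the smallest mean squared
#' deviation from that average (ties broken by the lowest index).
#'
#' @param results A `cav_replicates` list (>= 2 runs).
#' @param n_bins Angular bins for the profiles.
#' @return The index of the representative replicate.
#' @export
representative_run <- function(results, n_bins = 360L) {
  stopifnot(length(results) >= 2L)
  profs <- lapply(results, function(r) polar_profile(r$section, n_bins)$radius)
  len <- lengths(profs)
  if (length(unique(len)) != 1L)
    stop("replicate profiles have unequal binning", call. = FALSE)
  avg <- Reduce(`+`, profs) / length(profs)
  mse <- vapply(profs, function(p) mean((p - avg)^2), numeric(1))
  which.min(mse)   # which.min takes the first minimum: lowest index on ties
}

#' Calibrate the ECM degradation balance coefficient
#'
#' Runs replicated baseline simulations (no stimuli, macrophage and
#' chemoattractant events off) for each value of `gamma` on a grid, computes
#' the mean final/initial ECM ratio per value, and linearly interpolates the
#' coefficient at which the ratio crosses 1 — the homeostasis point at which
#' matrix degradation balances the production sustained by the larger SMC
#' pool.
#'
#' @param params A [parameter_set]; `gamma` is overridden by the grid.
#' @param tl A [timeline].
#' @param reps Baseline simulations per grid value (10 in the published
#'   procedure).
#' @param seed Base seed; replicate `r` of grid point `g` uses
#'   `seed + r - 1` so grid points share the same replicate seeds.
#' @param gamma_grid Grid of candidate coefficients.
#' @param ... Geometry arguments passed to [run_simulation] (e.g. a reduced
#'   `spec` for fast studies).
#' @return A `gamma_calibration` object: tibble of per-gamma mean ratios with
#'   `gamma_star` as an attribute.
#' @export
calibrate_gamma <- function(params = param_midpoints(), tl = timeline(),
                            reps = 10L, seed = 1L,
                            gamma_grid = c(1, 1.2, 1.275, 1.345, 1.5), ...) {
  base <- build_scenario("baseline")
  ratios <- purrr::map_dfr(gamma_grid, function(g) {
    p <- params
    p$gamma <- g
    rr <- vapply(seq_len(reps), function(r) {
      res <- run_simulation(base, params = p, tl = tl, seed = seed + r - 1L,
                            snapshot_times = integer(0), ...)
      s <- res$series
      ecm0 <- s$intima_ecm[1L] + s$media_ecm[1L]
      ecm1 <- s$intima_ecm[nrow(s)] + s$media_ecm[nrow(s)]
      ecm1 / ecm0
    }, numeric(1))
    tibble::tibble(gamma = g, ecm_ratio = mean(rr), sd = stats::sd(rr),
                   reps = reps)
  })
  gamma_star <- interpolate_crossing(ratios$gamma, ratios$ecm_ratio, 1)
  structure(ratios, gamma_star = gamma_star,
            class = c("gamma_calibration", class(ratios)))
}

# linear interpolation of the first downward crossing of `target`
interpolate_crossing <- function(x, y, target) {
  for (i in seq_len(length(x) - 1L)) {
    if ((y[i] - target) * (y[i + 1L] - target) <= 0) {
      if (y[i] == y[i + 1L]) return(x[i])
      return(x[i] + (target - y[i]) * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i]))
    }
  }
  stop("ECM ratio never crosses ", target,
       " on the gamma grid; ratios: ", paste(round(y, 3), collapse = ", "),
       call. = FALSE)
}

#' @export
print.gamma_calibration <- function(x, ...) {
  cat(sprintf("<gamma_calibration> gamma* = %.3f\n", attr(x, "gamma_star")))
  print(tibble::as_tibble(x))
  invisible(x)
}
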