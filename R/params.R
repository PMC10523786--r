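# Model parameters, ranges and the simulation timeline.

# agent cycle durations, hours
T_SMC <- 12L
T_ECM <- 2L
T_MP  <- 12L

#' Model parameter set
#'
#' Probability coefficients and hemodynamic constants of the model.  The
#' baseline coefficients `alpha1` (SMC mitosis/apoptosis) and `alpha2` (ECM
#' production) are fixed; `gamma` multiplies `alpha2` to give the ECM
#' degradation probability and defaults to the calibrated balance value (see
#' [calibrate_gamma]).  All remaining coefficients default to the midpoints of
#' their admissible ranges (see [param_ranges]), the values used throughout
#' the scenario suite.
#'
#' @param alpha1 Baseline SMC mitosis and apoptosis probability.
#' @param alpha2 Baseline ECM production probability.
#' @param gamma ECM degradation balance coefficient (degradation probability
#'   is `gamma * alpha2`).
#' @param alpha3,alpha4,alpha5,alpha6 Inflammation and macrophage-neighbour
#'   effects on SMC mitosis / ECM production.
#' @param alpha7,alpha8,alpha9,alpha10 Macrophage infiltration and dynamics
#'   coefficients.
#' @param alpha11,alpha12 Wall-shear-stress input effects.
#' @param alpha13,alpha14 Chemoattractant effects.
#' @param L1,L2 Slope and half-decay (Pa) of the endothelial dysfunction
#'   sigmoid `D(WSS)`.
#' @param Amp Amplitude of the cosine decay propagating `D(WSS)` into the
#'   intima.
#' @param try Number of candidate access sites explored per hour for
#'   macrophage infiltration.
#' @param c_radius Radius of chemoattractant action for SMC migration, sites.
#' @param mu Blood viscosity, cP.
#' @param dist Reach of the wall-shear-stress input decay, sites.
#' @param D_coeff Chemoattractant diffusion coefficient, sites^2/hour.
#' @param Ca0 Chemoattractant source amplitude (cancels under normalization).
#' @return A `parameter_set` object (named list).
#' @export
parameter_set <- function(alpha1 = 0.014, alpha2 = 0.006, gamma = 1.25,
                          alpha3 = 0.017, alpha4 = 0.0028, alpha5 = 0.018,
                          alpha6 = 0.003, alpha7 = 0.0095, alpha8 = 0.825,
                          alpha9 = 33, alpha10 = 0.075, alpha11 = 0.017,
                          alpha12 = 0.018, alpha13 = 0.017, alpha14 = 0.018,
                          L1 = -1.64, L2 = 10, Amp = 0.055, try = 55,
                          c_radius = 30.275, mu = 3.5, dist = 20,
                          D_coeff = 0.45, Ca0 = 1) {
  p <- as.list(environment())
  stopifnot(p$alpha1 >= 0, p$alpha2 >= 0, p$gamma >= 0, p$try >= 1,
            p$c_radius > 0, p$mu > 0, p$dist > 0, p$D_coeff > 0)
  if (p$L1 >= 0)
    stop("L1 must be negative: dysfunction decreases with WSS", call. = FALSE)
  p$try <- as.integer(round(p$try))
  structure(p, class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  print(unlist(x))
  invisible(x)
}

#' Admissible parameter ranges
#'
#' The ranges explored by the global sensitivity analysis: the 17 sampled
#' parameters with their lower and upper bounds.
#'
#' @return A tibble with columns `parameter`, `low`, `high` and `integer`
#'   (whether the parameter is rounded to an integer after sampling).
#' @export
param_ranges <- function() {
  tibble::tribble(
    ~parameter, ~low,   ~high,  ~integer,
    "alpha3",   0,      0.034,  FALSE,
    "alpha4",   0,      0.0056, FALSE,
    "alpha5",   0,      0.036,  FALSE,
    "alpha6",   0,      0.006,  FALSE,
    "alpha7",   0,      0.019,  FALSE,
    "alpha8",   0,      1.65,   FALSE,
    "alpha9",   6,      60,     FALSE,
    "alpha10",  0,      0.15,   FALSE,
    "alpha11",  0,      0.034,  FALSE,
    "alpha12",  0,      0.036,  FALSE,
    "alpha13",  0,      0.034,  FALSE,
    "alpha14",  0,      0.036,  FALSE,
    "L1",       -3,     -0.28,  FALSE,
    "L2",       8,      12,     FALSE,
    "Amp",      0.01,   0.10,   FALSE,
    "try",      10,     100,    TRUE,
    "c_radius", 4.55,   56,     FALSE
  )
}

#' Midpoint parameter set
#'
#' Parameter set with every sampled coefficient at the arithmetic midpoint of
#' its range — the configuration used for the scenario suite.
#'
#' @param ... Overrides passed on to [parameter_set].
#' @return A `parameter_set`.
#' @export
param_midpoints <- function(...) {
  r <- param_ranges()
  mids <- stats::setNames(as.list((r$low + r$high) / 2), r$parameter)
  do.call(parameter_set, utils::modifyList(mids, list(...)))
}

#' Simulation timeline
#'
#' Event windows of the 4-week follow-up: macrophage infiltration starts at
#' `t_i` (2 days) and stops at the infiltration peak `t_c` (1 week);
#' macrophage mitosis/apoptosis runs from `t_i` to the end; chemoattractant
#' diffusion and SMC media-to-intima migration run from `t_c` to the end.
#' The simulation stops early once the lumen loses `occlusion_frac` of its
#' initial area.
#'
#' @param dt Time step, hours (the model is defined at 1 h).
#' @param t_i Infiltration start, hours.
#' @param t_c Infiltration peak / chemoattractant release, hours.
#' @param t_sim Total simulated time, hours.
#' @param occlusion_frac Lumen-area reduction fraction that counts as
#'   critical occlusion.
#' @return A `cav_timeline` object.
#' @export
timeline <- function(dt = 1L, t_i = 48L, t_c = 168L, t_sim = 672L,
                     occlusion_frac = 0.99) {
  stopifnot(dt == 1L, t_i < t_c, t_c < t_sim,
            t_i %% dt == 0, t_c %% dt == 0, t_sim %% dt == 0,
            occlusion_frac > 0, occlusion_frac <= 1)
  structure(list(dt = as.integer(dt), t_i = as.integer(t_i),
                 t_c = as.integer(t_c), t_sim = as.integer(t_sim),
                 t_D = as.integer(t_sim - t_c),
                 occlusion_frac = occlusion_frac),
            class = "cav_timeline")
}

#' @export
print.cav_timeline <- function(x, ...) {
  cat(sprintf(
    "<cav_timeline> dt %dh | infiltration %d-%dh | follow-up %dh (%g weeks)\n",
    x$dt, x$t_i, x$t_c, x$t_sim, x$t_sim / 168))
  invisible(x)
}
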