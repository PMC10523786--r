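# Agent clocks, Monte Carlo event testing and the probability laws for
# SMC/ECM dynamics, macrophage infiltration and dynamics, chemoattractant
# diffusion and SMC migration selection.

T_AGENT <- c(`1` = 12, `2` = 2, `4` = 12)  # by occupancy code: SMC, ECM, MP

agent_cycle_hours <- function(kind) {
  out <- rep(NA_real_, length(kind))
  out[kind == .SMC] <- T_SMC
  out[kind == .ECM] <- T_ECM
  out[kind == .MP]  <- T_MP
  out
}

#' Advance agent clocks by one step
#'
#' Every agent clock is incremented by `dt` (capped at the agent's cycle
#' duration); agents whose clock reaches the cycle duration become
#' potentially active and their clocks are reset to zero for the next cycle.
#'
#' @param v A [vessel_section].
#' @param dt Time step, hours (must be 1).
#' @return A list with the updated `section` and `eligible`, a tibble of
#'   potentially active agents (`site`, `kind`).
#' @export
advance_clocks <- function(v, dt = 1) {
  stopifnot(dt == 1)
  agents <- which(v$occ == .SMC | v$occ == .ECM | v$occ == .MP)
  v$clock[agents] <- v$clock[agents] + dt
  tmax <- agent_cycle_hours(v$occ[agents])
  hit <- v$clock[agents] >= tmax
  elig <- agents[hit]
  v$clock[elig] <- 0
  list(section = v,
       eligible = tibble::tibble(site = elig,
                                 kind = factor(.OCC_LEVELS[v$occ[elig] + 1L],
                                               levels = .OCC_LEVELS)))
}

#' Monte Carlo event test
#'
#' Draws a uniform test number and reports whether the event fires
#' (`test < p`).  By default the draw is discretized to two decimals,
#' i.e. uniform on \{0.00, 0.01, ..., 1.00\}; pass `digits = Inf` for a
#' continuous draw (the engine's choice, since two-decimal resolution cannot
#' distinguish baseline-scale probabilities).
#'
#' @param p Event probability (vectorized), clamped to \[0, 1\].
#' @param n Number of draws when `p` has length 1.
#' @param digits Decimal resolution of the test draw; `Inf` for continuous.
#' @return Logical vector of event occurrences.
#' @export
monte_carlo_test <- function(p, n = length(p), digits = 2) {
  p <- pmin(pmax(p, 0), 1)
  if (length(p) == 1L && n > 1L) p <- rep(p, n)
  u <- stats::runif(length(p))
  if (is.finite(digits)) {
    m <- 10^digits
    u <- floor(u * (m + 1)) / m   # uniform on {0, 1/m, ..., 1}
  }
  u < p
}

#' SMC mitosis and apoptosis probabilities
#'
#' In the intima, mitosis is the baseline plus the inflammatory, macrophage-
#' neighbour, WSS-input and chemoattractant contributions
#' (`alpha1 + alpha3 I + alpha4 n_MP + alpha11 WSS_input + alpha13 Ca_norm`),
#' while apoptosis stays at baseline; in the media both are baseline, so the
#' medial population is in homeostasis.  The pair is jointly clamped so the
#' two probabilities can share one test draw.
#'
#' @param layer `"intima"` or `"media"`.
#' @param I_input,n_mp,wss_input,ca_norm Stimulus values at the site
#'   (vectorized).
#' @param params A [parameter_set].
#' @return A tibble with `p_mitosis` and `p_apoptosis`.
#' @export
smc_event_probabilities <- function(layer, I_input = 0, n_mp = 0,
                                    wss_input = 0, ca_norm = 0,
                                    params = parameter_set()) {
  layer <- match.arg(layer, c("intima", "media"))
  base <- params$alpha1
  p_mit <- if (layer == "intima") {
    base + params$alpha3 * I_input + params$alpha4 * n_mp +
      params$alpha11 * wss_input + params$alpha13 * ca_norm
  } else rep(base, max(length(I_input), 1L))
  p_apo <- rep(base, length(p_mit))
  cl <- clamp_pair(p_mit, p_apo)
  tibble::tibble(p_mitosis = cl[[1L]], p_apoptosis = cl[[2L]])
}

#' ECM production and degradation probabilities
#'
#' Production at an intima site is
#' `alpha2 + alpha5 I + alpha6 n_MP + alpha12 WSS_input + alpha14 Ca_norm`;
#' degradation is `gamma * alpha2` everywhere; in the media both are
#' baseline.
#'
#' @inheritParams smc_event_probabilities
#' @return A tibble with `p_production` and `p_degradation`.
#' @export
ecm_event_probabilities <- function(layer, I_input = 0, n_mp = 0,
                                    wss_input = 0, ca_norm = 0,
                                    params = parameter_set()) {
  layer <- match.arg(layer, c("intima", "media"))
  p_prod <- if (layer == "intima") {
    params$alpha2 + params$alpha5 * I_input + params$alpha6 * n_mp +
      params$alpha12 * wss_input + params$alpha14 * ca_norm
  } else rep(params$alpha2, max(length(I_input), 1L))
  p_deg <- rep(params$gamma * params$alpha2, length(p_prod))
  cl <- clamp_pair(p_prod, p_deg)
  tibble::tibble(p_production = cl[[1L]], p_degradation = cl[[2L]])
}

# joint clamp so p1 + p2 <= 1 while each stays >= 0
clamp_pair <- function(p1, p2) {
  p1 <- pmax(p1, 0); p2 <- pmax(p2, 0)
  s <- p1 + p2
  over <- s > 1
  if (any(over)) {
    p1[over] <- p1[over] / s[over]
    p2[over] <- p2[over] / s[over]
  }
  list(p1, p2)
}

#' Macrophage infiltration probability
#'
#' Probability that a lumen-wall site admits a macrophage into the intima:
#' `alpha7 (1 + I_input) (1 + alpha8 exp(-dist_MP)) (1 + MP_group / alpha9)`,
#' clamped to \[0, 1\].  `dist_MP` is the distance in sites to the nearest
#' intimal macrophage and `MP_group` the total intimal macrophage count; with
#' no macrophages present the distance factor collapses to 1 and
#' `MP_group = 0`.
#'
#' @param I_input Inflammatory input at the wall site (vectorized).
#' @param dist_mp Distance to the nearest intimal macrophage, sites
#'   (`Inf` when none are present).
#' @param mp_group Total intimal macrophage count.
#' @param params A [parameter_set].
#' @return Infiltration probabilities.
#' @export
mp_infiltration_probability <- function(I_input, dist_mp = Inf, mp_group = 0,
                                        params = parameter_set()) {
  near <- ifelse(is.finite(dist_mp), 1 + params$alpha8 * exp(-dist_mp), 1)
  p <- params$alpha7 * (1 + I_input) * near * (1 + mp_group / params$alpha9)
  pmin(pmax(p, 0), 1)
}

#' Select the macrophage access site
#'
#' The `try` wall sites with the highest infiltration probability are tested
#' in descending order with [monte_carlo_test]; the first success is the
#' access site.  At most one macrophage invades per time step.
#'
#' @param sites Candidate wall sites (linear indices).
#' @param probabilities Their infiltration probabilities.
#' @param try Number of candidates to explore.
#' @param digits Test-draw resolution passed to [monte_carlo_test].
#' @return The chosen site index, or `NA_integer_` when all attempts fail.
#' @export
select_mp_access_site <- function(sites, probabilities, try = 55,
                                  digits = Inf) {
  stopifnot(length(sites) == length(probabilities))
  if (length(sites) == 0L) return(NA_integer_)
  ord <- order(probabilities, decreasing = TRUE)
  n <- min(as.integer(round(try)), length(sites))
  for (k in ord[seq_len(n)]) {
    if (monte_carlo_test(probabilities[k], digits = digits))
      return(sites[k])
  }
  NA_integer_
}

#' Macrophage mitosis and apoptosis probabilities
#'
#' Two-phase dynamics mirroring the graft-infiltrating cell trend: growth
#' (`p_mitosis = alpha10`, `p_apoptosis = alpha10 / 2`) while
#' `t_i < t <= t_c`, decline (the reverse) for `t > t_c`, inactive before
#' `t_i`.
#'
#' @param t Simulation time, hours.
#' @param params A [parameter_set].
#' @param tl A [timeline].
#' @return A tibble with `p_mitosis` and `p_apoptosis`.
#' @export
mp_dynamics_probabilities <- function(t, params = parameter_set(),
                                      tl = timeline()) {
  if (t <= tl$t_i) {
    p <- c(0, 0)
  } else if (t <= tl$t_c) {
    p <- c(params$alpha10, 0.5 * params$alpha10)
  } else {
    p <- c(0.5 * params$alpha10, params$alpha10)
  }
  tibble::tibble(p_mitosis = p[1L], p_apoptosis = p[2L])
}

#' Chemoattractant concentration field
#'
#' Free 2D diffusion from the macrophage-cluster centroid:
#' `Ca(d, td) = Ca0 / (4 pi D td) exp(-d^2 / (4 D td))` with `td` the time
#' elapsed since the release at the infiltration peak (in days, the natural
#' unit of the normalized diffusion coefficient `D = 0.45` sites^2/day),
#' evaluated from the first step after release (never at the `td = 0`
#' singularity).  The normalized field
#' `Ca_norm = (Ca - Ca_min) / (Ca_max - Ca_min)` is computed over the
#' current intima sites; an all-equal field normalizes to zero.  The field
#' stays concentrated around the cluster — a spread of about 4 sites by the
#' end of the 3-week diffusion window — so chemoattractant-driven growth is
#' local, as in the published non-symmetric invaginations.
#'
#' @param v A [vessel_section].
#' @param centroid Cluster centroid as real-space `c(x, y)` coordinates (see
#'   [run_simulation]; frozen at the infiltration peak).
#' @param td Hours elapsed since the chemoattractant release (>= 1).
#' @param params A [parameter_set] supplying `D_coeff` (sites^2/day) and
#'   `Ca0`.
#' @return A `chemoattractant_field`: tibble with `site`, `ca`, `ca_norm`
#'   for every intima site, centroid and `td` as attributes.
#' @export
chemoattractant_field <- function(v, centroid, td, params = parameter_set()) {
  stopifnot(td >= 1)
  idx <- which(v$layer == .LY_INT & v$occ != .LUMEN)
  geo <- v$geo
  d2 <- (geo$x[idx] - centroid[1L])^2 + (geo$y[idx] - centroid[2L])^2
  denom <- 4 * params$D_coeff * (td / 24)
  ca <- params$Ca0 / (pi * denom) * exp(-d2 / denom)
  rng <- range(ca)
  ca_norm <- if (diff(rng) > 0) (ca - rng[1L]) / diff(rng) else rep(0, length(ca))
  out <- tibble::tibble(site = idx, ca = ca, ca_norm = ca_norm)
  attr(out, "centroid") <- centroid
  attr(out, "td") <- td
  class(out) <- c("chemoattractant_field", class(out))
  out
}

#' Select an SMC media-to-intima migration pair
#'
#' The source is drawn uniformly among medial SMCs within `c_radius` of the
#' chemoattractant centroid; the target uniformly among intima sites with a
#' non-zero normalized concentration, where "non-zero" is taken at the
#' model's probability resolution of two decimals (`Ca_norm >= 0.005`, i.e.
#' concentrations that do not round to zero) rather than floating-point
#' underflow.  The pair is accepted when a Monte Carlo test passes against
#' `Ca_norm` at the target; at most one migration occurs per hour.
#'
#' @param v A [vessel_section].
#' @param ca A `chemoattractant_field`.
#' @param c_radius Radius of chemoattractant action, sites.
#' @param digits Test-draw resolution.
#' @return A list `(source, target)` of site indices, or `NULL` when no
#'   eligible pair exists or the acceptance test fails.
#' @export
select_smc_migration <- function(v, ca, c_radius, digits = Inf) {
  centroid <- attr(ca, "centroid")
  geo <- v$geo
  med_smc <- which(v$occ == .SMC & v$layer == .LY_MED)
  if (length(med_smc) == 0L) return(NULL)
  d <- sqrt((geo$x[med_smc] - centroid[1L])^2 +
              (geo$y[med_smc] - centroid[2L])^2)
  src_pool <- med_smc[d <= c_radius]
  tgt_pool <- ca$site[ca$ca_norm >= 0.005]
  if (length(src_pool) == 0L || length(tgt_pool) == 0L) return(NULL)
  source <- src_pool[sample.int(length(src_pool), 1L)]
  ti <- sample.int(length(tgt_pool), 1L)
  target <- tgt_pool[ti]
  p <- ca$ca_norm[match(target, ca$site)]
  if (!monte_carlo_test(p, digits = digits)) return(NULL)
  list(source = source, target = target)
}

# distance from each of `idx` to the nearest site in `ref` (Inf when empty)
nearest_distance <- function(geo, idx, ref) {
  if (length(ref) == 0L) return(rep(Inf, length(idx)))
  dx <- outer(geo$x[idx], geo$x[ref], "-")
  dy <- outer(geo$y[idx], geo$y[ref], "-")
  sqrt(matrixStats_rowMins(dx * dx + dy * dy))
}

# minimal row minimum without extra dependencies
matrixStats_rowMins <- function(m) {
  if (is.null(dim(m))) return(min(m))
  do.call(pmin, c(as.data.frame(m), list(na.rm = TRUE)))
}

# count of MP agents among the 6 neighbours of each site
mp_neighbour_count <- function(v, idx) {
  if (length(idx) == 0L) return(integer(0))
  nb <- v$geo$nb[idx, , drop = FALSE]
  occ_nb <- matrix(0L, nrow(nb), 6L)
  on <- nb > 0L
  occ_nb[on] <- as.integer(v$occ[nb[on]] == .MP)
  as.integer(rowSums(occ_nb))
}
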