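# Inflammatory input, wall shear stress profile and the intimal WSS input.

#' Inflammatory input field
#'
#' The inflammatory input `I_input` lives on the intima and takes values in
#' \[0, 1\].  Three modes are supported: `"absent"` (zero everywhere),
#' `"uniform"` (a symmetric stimulus equal to `level` on every intima site)
#' and `"gaussian"` (a non-symmetric stimulus `exp(-d^2 / (2 sigma^2))`
#' peaking at 1 at `center`).  The field is spatial, time-independent, and
#' pinned to the initial intima band: sites that join the intima as the wall
#' grows inward carry no inflammatory input, which is what makes the lumen
#' loss of the stimulated scenarios linear in time rather than
#' self-accelerating.
#'
#' @param v A [vessel_section].
#' @param mode `"absent"`, `"uniform"` or `"gaussian"`.
#' @param center For the gaussian mode, the peak site as a `(row, col)` pair
#'   or linear index; must lie in the intima.  Defaults to a random intima
#'   site in the top-right quadrant.
#' @param sigma Gaussian spread, sites.
#' @param level Uniform level for the symmetric mode.
#' @return An `inflammation_field` object.
#' @export
make_inflammation_field <- function(v, mode = c("absent", "uniform",
                                                "gaussian"),
                                    center = NULL, sigma = 15, level = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(v, "vessel_section"))
  if (mode == "gaussian") {
    if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
    geo <- v$geo
    if (is.null(center)) {
      cand <- which(v$layer == .LY_INT & geo$angle > 0 &
                      geo$angle < pi / 2)
      center <- cand[sample.int(length(cand), 1L)]
    } else {
      center <- site_index(geo, center)
      if (v$layer[center] != .LY_INT)
        stop("gaussian inflammation center must lie in the intima",
             call. = FALSE)
    }
  } else {
    center <- NA_integer_
  }
  if (mode == "uniform" && (level < 0 || level > 1))
    stop("uniform inflammation level must lie in [0, 1]", call. = FALSE)
  structure(list(mode = mode, center = center, sigma = sigma, level = level),
            class = "inflammation_field")
}

# evaluate I_input at linear site indices (0 outside the initial intima band)
inflammation_at <- function(field, v, idx) {
  out <- numeric(length(idx))
  int <- v$layer[idx] == .LY_INT & v$stimulus_support[idx]
  if (!any(int)) return(out)
  out[int] <- switch(field$mode,
    absent  = 0,
    uniform = field$level,
    gaussian = {
      geo <- v$geo
      d2 <- (geo$x[idx[int]] - geo$x[field$center])^2 +
            (geo$y[idx[int]] - geo$y[field$center])^2
      exp(-d2 / (2 * field$sigma^2))
    })
  out
}

#' Per-site values of an inflammation field
#'
#' @param field An `inflammation_field`.
#' @param v The [vessel_section] to evaluate on.
#' @return A tibble with `site` (linear index) and `I_input` for every
#'   current intima site.
#' @export
inflammation_values <- function(field, v) {
  idx <- which(v$layer == .LY_INT & v$occ != .LUMEN)
  tibble::tibble(site = idx, I_input = inflammation_at(field, v, idx))
}

#' Endothelial dysfunction transfer
#'
#' Sigmoid mapping of wall shear stress to dysfunction level:
#' `D(WSS) = 1 - 1 / (1 + exp(L1 (WSS - L2)))`, bounded in (0, 1) and
#' decreasing in WSS for `L1 < 0`, with `D(L2) = 0.5` exactly.
#'
#' @param wss Wall shear stress, Pa (vectorized).
#' @param L1 Sigmoid slope (negative).
#' @param L2 WSS at which dysfunction equals 0.5, Pa.
#' @return Dysfunction values in (0, 1).
#' @export
endothelial_dysfunction <- function(wss, L1, L2) {
  if (L1 >= 0) stop("L1 must be negative", call. = FALSE)
  stats::plogis(L1 * (wss - L2))
}

#' Poiseuille wall shear stress profile with endothelial dysfunction
#'
#' Computes the WSS profile on the lumen wall from a constant flow rate.  The
#' equivalent lumen radius comes from the current lumen area
#' (`R_eq = sqrt(area / pi)`), the peak velocity from the Poiseuille mean
#' relation `Umax = 2 Q / (pi R_eq^2)`, and the per-site WSS from
#' `WSS_i = 2 mu Umax / R_I^i` with `R_I` the physical distance between wall
#' site `i` and the peak-velocity location.  For a non-symmetric profile the
#' peak is off-centred by `off_center_fraction * R_eq` along `direction`;
#' the default direction (bottom-left) places the low-WSS, high-dysfunction
#' region at the top-right of the cross-section.
#'
#' @param v A [vessel_section].
#' @param Q Flow rate, mL/min.
#' @param params A [parameter_set] supplying `mu`, `L1`, `L2`, `Amp`, `dist`.
#' @param off_center_fraction Fraction of `R_eq` by which the peak velocity
#'   is displaced (0 for a symmetric profile).
#' @param direction Unit-direction of the displacement in lattice real-space
#'   coordinates.
#' @return A `hemodynamic_state` object with per-wall-site `wss` and
#'   `dysfunction`, per-intima-site `wss_input`, and the scalars `Q`, `Umax`,
#'   `R_eq_sites`.
#' @export
compute_wss_profile <- function(v, Q, params = parameter_set(),
                                off_center_fraction = 0,
                                direction = c(-1, -1) / sqrt(2)) {
  lumen_area <- sum(v$occ == .LUMEN)
  if (lumen_area == 0L) stop("lumen is occluded", call. = FALSE)
  stopifnot(Q > 0)
  geo <- v$geo
  pitch_m <- v$spec$site_pitch_um * 1e-6

  # physical lumen area: each hex site covers sqrt(3)/2 unit^2
  area_m2 <- lumen_area * (sqrt(3) / 2) * pitch_m^2
  R_eq_m <- sqrt(area_m2 / pi)
  Q_m3s <- Q * 1e-6 / 60
  Umax <- 2 * Q_m3s / (pi * R_eq_m^2)

  lum <- which(v$occ == .LUMEN)
  cx <- mean(geo$x[lum]); cy <- mean(geo$y[lum])
  R_eq_sites <- R_eq_m / pitch_m
  ux <- cx + off_center_fraction * R_eq_sites * direction[1L]
  uy <- cy + off_center_fraction * R_eq_sites * direction[2L]

  wall <- lumen_wall_sites(v)
  ri_sites <- pmax(sqrt((geo$x[wall] - ux)^2 + (geo$y[wall] - uy)^2), 0.5)
  wss <- 2 * (params$mu * 1e-3) * Umax / (ri_sites * pitch_m)
  dys <- endothelial_dysfunction(wss, params$L1, params$L2)

  h <- structure(
    list(Q = Q, mu = params$mu, Umax = Umax, Umax_xy = c(ux, uy),
         R_eq_sites = R_eq_sites,
         off_center_fraction = off_center_fraction, direction = direction,
         wall_sites = wall, wss = wss, dysfunction = dys,
         L1 = params$L1, L2 = params$L2, Amp = params$Amp,
         dist = params$dist),
    class = "hemodynamic_state")
  h$wss_input <- propagate_wss_input(v, h, params$Amp)
  h
}

#' Propagate endothelial dysfunction into the intima
#'
#' The intimal WSS input is the cosine-decayed sum of wall dysfunction:
#' for each intima site, `sum over wall sites i with x < dist of
#' D(WSS_i) * Amp * (1 + cos(pi x / dist))`, clamped to \[0, 1\],
#' where `x` is the site distance in sites.
#'
#' @param v A [vessel_section].
#' @param h A `hemodynamic_state` with `wall_sites` and `dysfunction`.
#' @param Amp Cosine amplitude.
#' @return A tibble with `site` and `wss_input` for every intima site.
#' @export
propagate_wss_input <- function(v, h, Amp = h$Amp) {
  idx <- which(v$layer == .LY_INT & v$occ != .LUMEN)
  tibble::tibble(site = idx,
                 wss_input = wss_input_at(v, h, idx, Amp))
}

# wss_input evaluated at arbitrary site indices
wss_input_at <- function(v, h, idx, Amp = h$Amp) {
  if (length(idx) == 0L) return(numeric(0))
  geo <- v$geo
  wall <- h$wall_sites
  dx <- outer(geo$x[idx], geo$x[wall], "-")
  dy <- outer(geo$y[idx], geo$y[wall], "-")
  x <- sqrt(dx * dx + dy * dy)
  w <- (x < h$dist) * (1 + cos(pi * pmin(x, h$dist) / h$dist))
  val <- as.numeric(w %*% h$dysfunction) * Amp
  pmin(pmax(val, 0), 1)
}

#' Recompute hemodynamics against the current geometry
#'
#' Re-evaluates the equivalent radius, peak velocity and location, WSS,
#' dysfunction and intimal WSS input against the current lumen border,
#' keeping the flow rate, viscosity and off-centring configuration fixed.
#'
#' @param v A [vessel_section] (possibly remodeled).
#' @param h The previous `hemodynamic_state`.
#' @param params A [parameter_set].
#' @return An updated `hemodynamic_state`.
#' @export
update_hemodynamics <- function(v, h, params = parameter_set()) {
  params$mu <- h$mu
  params$L1 <- h$L1; params$L2 <- h$L2
  params$Amp <- h$Amp; params$dist <- h$dist
  compute_wss_profile(v, h$Q, params,
                      off_center_fraction = h$off_center_fraction,
                      direction = h$direction)
}
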