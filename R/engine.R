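# Scenario assembly and the hourly simulation engine.

#' Scenario specification
#'
#' A scenario combines an inflammatory input mode, a WSS input mode, and the
#' activation flags of the macrophage and chemoattractant events.  Labelled
#' scenarios 1-14 reproduce the published testing grid; `"mild"`,
#' `"moderate"` and `"severe"` are the CAV cases derived from scenario 14 by
#' varying the inflammation exposure region and the flow rate.
#'
#' @param inflammation_mode `"absent"`, `"uniform"` (symmetric) or
#'   `"gaussian"` (non-symmetric).
#' @param level Uniform inflammation level.
#' @param sigma Gaussian inflammation spread, sites.
#' @param wss_mode `"absent"`, `"centered"` (symmetric) or `"offcenter"`
#'   (non-symmetric).
#' @param Q Flow rate, mL/min.
#' @param mp_events Are macrophage infiltration/dynamics active?
#' @param chemoattractant Is chemoattractant diffusion (and SMC migration)
#'   active?  Requires `mp_events`.
#' @param off_center_fraction Peak-velocity displacement as a fraction of
#'   the equivalent radius, for the non-symmetric WSS mode.
#' @param label Free-text label.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(inflammation_mode = c("absent", "uniform",
                                                "gaussian"),
                          level = 0.5, sigma = 15,
                          wss_mode = c("absent", "centered", "offcenter"),
                          Q = 0.13, mp_events = FALSE,
                          chemoattractant = FALSE,
                          off_center_fraction = 0.4,
                          label = "custom") {
  inflammation_mode <- match.arg(inflammation_mode)
  wss_mode <- match.arg(wss_mode)
  if (chemoattractant && !mp_events)
    stop("chemoattractant diffusion requires active macrophage events",
         call. = FALSE)
  structure(list(inflammation_mode = inflammation_mode, level = level,
                 sigma = sigma, wss_mode = wss_mode, Q = Q,
                 mp_events = mp_events, chemoattractant = chemoattractant,
                 off_center_fraction = off_center_fraction, label = label),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> '%s': I=%s, WSS=%s (Q=%g mL/min), MP=%s, Ca=%s\n",
    x$label, x$inflammation_mode, x$wss_mode, x$Q,
    if (x$mp_events) "Prs" else "Abs",
    if (x$chemoattractant) "Prs" else "Abs"))
  invisible(x)
}

#' Build a labelled scenario
#'
#' Returns the configuration of one of the fourteen testing scenarios, one
#' of the CAV cases (`"mild"`, `"moderate"`, `"severe"`), or `"baseline"`
#' (all inputs absent, all events off — the homeostasis / calibration
#' condition).
#'
#' @param label Scenario id: `1:14` (or their character forms), `"mild"`,
#'   `"moderate"`, `"severe"`, `"baseline"`.
#' @return A [scenario_spec].
#' @export
build_scenario <- function(label) {
  lab <- tolower(as.character(label))
  i_modes <- c("uniform", "absent", "gaussian", "absent", "uniform",
               "gaussian", "uniform", "uniform", "gaussian", "gaussian",
               "uniform", "uniform", "gaussian", "gaussian")
  w_modes <- c("absent", "centered", "absent", "offcenter", "centered",
               "offcenter", "absent", "absent", "absent", "absent",
               "centered", "centered", "offcenter", "offcenter")
  mp <- c(rep(FALSE, 6), rep(TRUE, 8))
  ca <- c(rep(FALSE, 7), TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  if (lab %in% as.character(1:14)) {
    k <- as.integer(lab)
    return(scenario_spec(
      inflammation_mode = i_modes[k], level = 0.5, sigma = 15,
      wss_mode = w_modes[k],
      Q = if (w_modes[k] == "offcenter") 0.20 else 0.13,
      mp_events = mp[k], chemoattractant = ca[k],
      label = paste0("scenario-", k)))
  }
  switch(lab,
    baseline = scenario_spec("absent", wss_mode = "absent",
                             mp_events = FALSE, chemoattractant = FALSE,
                             label = "baseline"),
    mild     = scenario_spec("gaussian", sigma = 12, wss_mode = "offcenter",
                             Q = 0.30, mp_events = TRUE,
                             chemoattractant = TRUE, label = "mild"),
    moderate = scenario_spec("gaussian", sigma = 15, wss_mode = "offcenter",
                             Q = 0.20, mp_events = TRUE,
                             chemoattractant = TRUE, label = "moderate"),
    severe   = scenario_spec("gaussian", sigma = 65, wss_mode = "offcenter",
                             Q = 0.10, mp_events = TRUE,
                             chemoattractant = TRUE, label = "severe"),
    stop("unknown scenario label '", label,
         "'; valid labels: 1-14, 'mild', 'moderate', 'severe', 'baseline'",
         call. = FALSE)
  )
}

# engine-internal event application with displacement maps.
# returns NULL when the ray is blocked (event skipped).
apply_event_kernel <- function(v, s, action, payload = .ECM) {
  if (v$layer[s] == .LY_INT) {
    if (action == "add") shift_add(v, s, payload, .LUMEN, .LY_INT)
    else shift_remove(v, s, .LUMEN, .LY_LUMEN)
  } else {
    if (action == "add") shift_add(v, s, payload, .EXT, .LY_MED)
    else shift_remove(v, s, .EXT, .LY_EXT)
  }
}

# remap pending event sites through a displacement map
remap_sites <- function(sites, from, to) {
  if (length(from) == 0L || length(sites) == 0L) return(sites)
  m <- match(sites, from)
  hit <- !is.na(m)
  sites[hit] <- to[m[hit]]
  sites
}

#' Run one CAV simulation
#'
#' Executes the hourly loop over the follow-up: stimuli update, macrophage
#' infiltration (between `t_i` and `t_c`), macrophage mitosis/apoptosis
#' (after `t_i`), SMC/ECM dynamics, chemoattractant diffusion and SMC
#' media-to-intima migration (after `t_c`), then border regularization.  The
#' run stops at `t_sim` or at critical occlusion.  All randomness flows from
#' `seed`.
#'
#' @param scenario A [scenario_spec] (or a label accepted by
#'   [build_scenario]).
#' @param params A [parameter_set]; defaults to range midpoints.
#' @param tl A [timeline].
#' @param seed Integer seed for the replicate.
#' @param spec A [lattice_spec].
#' @param lumen_radius_sites,wall_thickness_sites,smc_fraction,layer_split
#'   Geometry, passed to [build_cross_section].
#' @param snapshot_times Hours at which to store occupancy snapshots
#'   (`0` and week marks by default).
#' @param check_ledger Verify the per-hour agent conservation ledger
#'   (cheap; aborts with a diagnostic on violation).
#' @return A `cav_simulation` object: hourly `series` tibble, final
#'   `section`, `snapshots`, event tallies, seed and termination reason.
#' @export
run_simulation <- function(scenario, params = param_midpoints(),
                           tl = timeline(), seed = 1L,
                           spec = lattice_spec(),
                           lumen_radius_sites = 40,
                           wall_thickness_sites = 16,
                           smc_fraction = 0.6,
                           layer_split = NULL,
                           snapshot_times = c(0L, 168L, 336L, 504L, 672L),
                           check_ledger = TRUE) {
  if (!inherits(scenario, "scenario_spec")) scenario <- build_scenario(scenario)
  stopifnot(inherits(params, "parameter_set"), inherits(tl, "cav_timeline"))
  set.seed(seed)
  if (is.null(layer_split)) {
    w <- wall_thickness_sites
    layer_split <- c(intima = max(2L, round(w * 5 / 16)), iel = 1L, media = 0L)
    layer_split["media"] <- w - layer_split[["intima"]] - 1L
  }
  v <- build_cross_section(spec, lumen_radius_sites, wall_thickness_sites,
                           smc_fraction, layer_split)
  infl <- make_inflammation_field(
    v, mode = scenario$inflammation_mode,
    sigma = scenario$sigma, level = scenario$level)
  hemo <- if (scenario$wss_mode != "absent") {
    compute_wss_profile(
      v, scenario$Q, params,
      off_center_fraction =
        if (scenario$wss_mode == "offcenter") scenario$off_center_fraction
        else 0)
  } else NULL

  n_hours <- tl$t_sim
  series <- matrix(0L, n_hours + 1L, 9L)
  colnames(series) <- c("t", "lumen_area", "intima_area", "media_area",
                        "intima_smc", "intima_ecm", "intima_mp",
                        "media_smc", "media_ecm")
  tally_names <- c("smc_mitosis", "smc_apoptosis", "ecm_production",
                   "ecm_degradation", "mp_infiltration", "mp_mitosis",
                   "mp_apoptosis", "migration", "skipped")
  tallies <- matrix(0L, n_hours, length(tally_names),
                    dimnames = list(NULL, tally_names))
  record <- function(row, t) {
    a <- count_state(v)
    series[row, ] <<- c(t, a)
  }
  record(1L, 0L)
  initial_lumen <- v$initial_lumen_area
  snapshots <- list()
  if (0L %in% snapshot_times) snapshots[["0"]] <- occupancy_matrix(v)

  centroid <- NULL
  termination <- "time_elapsed"
  dig <- Inf   # continuous Monte Carlo draws (see monte_carlo_test)

  for (t in seq_len(n_hours)) {
    hour_tally <- stats::setNames(integer(length(tally_names)), tally_names)
    counts_before <- count_state(v)

    ## 1. clocks ---------------------------------------------------------
    agents <- which(!is.na(v$clock))
    v$clock[agents] <- v$clock[agents] + 1
    tmax <- agent_cycle_hours(v$occ[agents])
    elig <- agents[v$clock[agents] >= tmax]
    v$clock[elig] <- 0
    elig_kind <- v$occ[elig]

    ## 2. stimuli --------------------------------------------------------
    if (!is.null(hemo)) hemo <- update_hemodynamics(v, hemo, params)

    ## 3. macrophage infiltration ---------------------------------------
    if (scenario$mp_events && t >= tl$t_i && t <= tl$t_c) {
      wall <- lumen_wall_sites(v)
      if (length(wall) > 0L) {
        mp_sites <- which(v$occ == .MP & v$layer == .LY_INT)
        p <- mp_infiltration_probability(
          inflammation_at(infl, v, wall),
          dist_mp = nearest_distance(v$geo, wall, mp_sites),
          mp_group = length(mp_sites), params = params)
        acc <- select_mp_access_site(wall, p, params$try, digits = dig)
        if (!is.na(acc)) {
          v2 <- infiltration_kernel(v, acc)
          if (!is.null(v2)) {
            elig <- remap_sites(elig, v2$moved_from, v2$moved_to)
            v <- v2$section
            hour_tally["mp_infiltration"] <- 1L
          }
        }
      }
    }

    ## 4. macrophage dynamics -------------------------------------------
    if (scenario$mp_events && t > tl$t_i) {
      mp_elig <- elig[elig_kind == .MP]
      if (length(mp_elig) > 0L) {
        pr <- mp_dynamics_probabilities(t, params, tl)
        u <- stats::runif(length(mp_elig))
        ev <- ifelse(u < pr$p_mitosis, 1L,
                     ifelse(u < pr$p_mitosis + pr$p_apoptosis, 2L, 0L))
        fired <- mp_elig[ev > 0L]
        actions <- ev[ev > 0L]
        for (j in seq_along(fired)) {
          s <- fired[j]
          if (v$occ[s] != .MP) { hour_tally["skipped"] <- hour_tally["skipped"] + 1L; next }
          res <- apply_event_kernel(v, s,
                                    if (actions[j] == 1L) "add" else "remove",
                                    payload = .MP)
          if (is.null(res)) { hour_tally["skipped"] <- hour_tally["skipped"] + 1L; next }
          elig <- remap_sites(elig, res$moved_from, res$moved_to)
          if (j < length(fired))
            fired[(j + 1L):length(fired)] <-
              remap_sites(fired[(j + 1L):length(fired)],
                          res$moved_from, res$moved_to)
          v <- res$section
          key <- if (actions[j] == 1L) "mp_mitosis" else "mp_apoptosis"
          hour_tally[key] <- hour_tally[key] + 1L
        }
      }
    }

    ## chemoattractant release point ------------------------------------
    if (scenario$chemoattractant && is.null(centroid) && t >= tl$t_c) {
      mp_sites <- which(v$occ == .MP & v$layer == .LY_INT)
      if (length(mp_sites) > 0L)
        centroid <- c(mean(v$geo$x[mp_sites]), mean(v$geo$y[mp_sites]))
    }
    ca <- NULL
    if (scenario$chemoattractant && !is.null(centroid) && t > tl$t_c)
      ca <- chemoattractant_field(v, centroid, t - tl$t_c, params)

    ## 5. SMC / ECM dynamics --------------------------------------------
    sel <- elig_kind == .SMC | elig_kind == .ECM
    sw <- elig[sel]; swk <- elig_kind[sel]
    keep <- v$occ[sw] == swk
    sw <- sw[keep]
    if (length(sw) > 0L) {
      kind <- swk[keep]
      lay <- v$layer[sw]
      int <- lay == .LY_INT
      I <- numeric(length(sw)); W <- I; C <- I; nmp <- integer(length(sw))
      if (any(int)) {
        I[int] <- inflammation_at(infl, v, sw[int])
        if (!is.null(hemo)) W[int] <- wss_input_at(v, hemo, sw[int])
        if (!is.null(ca)) C[int] <- ca$ca_norm[match(sw[int], ca$site)]
        C[is.na(C)] <- 0
        nmp[int] <- mp_neighbour_count(v, sw[int])
      }
      # per-site probabilities: SMC agents test mitosis/apoptosis and matrix
      # production; ECM agents test production/degradation (one shared draw,
      # disjoint intervals)
      p_prod <- params$alpha2 + params$alpha5 * I + params$alpha6 * nmp +
        params$alpha12 * W + params$alpha14 * C
      p_prod[!int] <- params$alpha2
      p_mit <- params$alpha1 + params$alpha3 * I + params$alpha4 * nmp +
        params$alpha11 * W + params$alpha13 * C
      p_mit[!int] <- params$alpha1
      p_apo <- rep(params$alpha1, length(sw))
      p_deg <- rep(params$gamma * params$alpha2, length(sw))

      is_smc <- kind == .SMC
      ev <- integer(length(sw))   # 1 mit, 2 apo, 3 prod, 4 deg
      u <- stats::runif(length(sw))
      if (any(is_smc)) {
        tot <- pmax(p_mit + p_apo + p_prod, 1)
        a <- p_mit / tot; b <- (p_mit + p_apo) / tot
        cc <- (p_mit + p_apo + p_prod) / tot
        ii <- which(is_smc)
        ev[ii] <- ifelse(u[ii] < a[ii], 1L,
                         ifelse(u[ii] < b[ii], 2L,
                                ifelse(u[ii] < cc[ii], 3L, 0L)))
      }
      if (any(!is_smc)) {
        tot <- pmax(p_prod + p_deg, 1)
        a <- p_prod / tot; b <- (p_prod + p_deg) / tot
        ii <- which(!is_smc)
        ev[ii] <- ifelse(u[ii] < a[ii], 3L,
                         ifelse(u[ii] < b[ii], 4L, 0L))
      }
      fired <- which(ev > 0L)
      if (length(fired) > 0L) {
        fired <- fired[sample.int(length(fired))]   # random visit order
        f_sites <- sw[fired]
        f_ev <- ev[fired]
        f_kind <- kind[fired]
        for (j in seq_along(f_sites)) {
          s <- f_sites[j]
          if (v$occ[s] != f_kind[j]) {
            hour_tally["skipped"] <- hour_tally["skipped"] + 1L
            next
          }
          res <- switch(f_ev[j],
            apply_event_kernel(v, s, "add", payload = .SMC),     # mitosis
            apply_event_kernel(v, s, "remove"),                  # apoptosis
            apply_event_kernel(v, s, "add", payload = .ECM),     # production
            apply_event_kernel(v, s, "remove"))                  # degradation
          if (is.null(res)) {
            hour_tally["skipped"] <- hour_tally["skipped"] + 1L
            next
          }
          if (j < length(f_sites))
            f_sites[(j + 1L):length(f_sites)] <-
              remap_sites(f_sites[(j + 1L):length(f_sites)],
                          res$moved_from, res$moved_to)
          v <- res$section
          key <- tally_names[f_ev[j]]
          hour_tally[key] <- hour_tally[key] + 1L
        }
      }
    }

    ## 6. SMC media-to-intima migration ---------------------------------
    ## one SMC migrates per hour; the Monte Carlo gate rejects weak targets,
    ## so the (source, target) draw is retried within the hour to sustain
    ## the 1 cell/h migration rate while still favouring high-Ca end sites
    if (!is.null(ca)) {
      pair <- NULL
      for (try_mig in 1:10) {
        pair <- select_smc_migration(v, ca, params$c_radius, digits = dig)
        if (!is.null(pair)) break
      }
      if (!is.null(pair) && v$layer[pair$target] == .LY_INT &&
          v$occ[pair$target] != .LUMEN) {
        res <- shift_add(v, pair$target, .SMC, .LUMEN, .LY_INT)
        if (!is.null(res)) {
          v <- res$section
          v$clock[pair$target] <- 0
          src <- remap_sites(pair$source, res$moved_from, res$moved_to)
          v$occ[src] <- .ECM
          v$clock[src] <- 0
          hour_tally["migration"] <- 1L
        }
      }
    }

    ## 7. regularization -------------------------------------------------
    v <- regularize(v)

    ## bookkeeping -------------------------------------------------------
    record(t + 1L, t)
    tallies[t, ] <- hour_tally
    if (check_ledger) {
      counts_after <- count_state(v)
      d_smc <- (counts_after[4L] + counts_after[7L]) -
        (counts_before[4L] + counts_before[7L])
      d_ecm <- (counts_after[5L] + counts_after[8L]) -
        (counts_before[5L] + counts_before[8L])
      d_mp <- counts_after[6L] - counts_before[6L]
      ok <- d_smc == hour_tally["smc_mitosis"] - hour_tally["smc_apoptosis"] &&
        d_ecm == hour_tally["ecm_production"] - hour_tally["ecm_degradation"] +
          hour_tally["migration"] &&
        d_mp == hour_tally["mp_infiltration"] + hour_tally["mp_mitosis"] -
          hour_tally["mp_apoptosis"]
      if (!ok)
        stop(sprintf("agent conservation ledger violated at hour %d", t),
             call. = FALSE)
    }
    if (t %in% snapshot_times)
      snapshots[[as.character(t)]] <- occupancy_matrix(v)
    if (series[t + 1L, "lumen_area"] <=
        (1 - tl$occlusion_frac) * initial_lumen) {
      termination <- "occlusion"
      series <- series[seq_len(t + 1L), , drop = FALSE]
      tallies <- tallies[seq_len(t), , drop = FALSE]
      break
    }
  }

  structure(
    list(series = tibble::as_tibble(as.data.frame(series)),
         section = v, snapshots = snapshots,
         tallies = tibble::as_tibble(as.data.frame(tallies)),
         seed = seed, scenario = scenario, params = params, timeline = tl,
         centroid = centroid, termination = termination),
    class = "cav_simulation")
}

# fast per-layer counts: lumen, intima, media areas + agent counts,
# in the order used by the series matrix
count_state <- function(v) {
  # single tabulate pass over a combined occupancy/layer key
  key <- v$occ + 6L * v$layer
  tab <- tabulate(key + 1L, nbins = 30L)
  cell <- function(occ, layer) tab[occ + 6L * layer + 1L]
  int <- sum(tab[(6L * .LY_INT + 1L):(6L * .LY_INT + 6L)])
  med <- sum(tab[(6L * .LY_MED + 1L):(6L * .LY_MED + 6L)])
  c(cell(.LUMEN, .LY_LUMEN), int, med,
    cell(.SMC, .LY_INT), cell(.ECM, .LY_INT), cell(.MP, .LY_INT),
    cell(.SMC, .LY_MED), cell(.ECM, .LY_MED))
}

# infiltration with displacement map (engine internal; the exported
# infiltration_rearrangement wraps the same kernel)
infiltration_kernel <- function(v, i) {
  v2 <- infiltration_rearrangement(v, i)
  if (!isTRUE(attr(v2, "infiltrated"))) return(NULL)
  map <- attr(v2, "map")
  attr(v2, "map") <- NULL
  list(section = v2, moved_from = map$from, moved_to = map$to)
}

#' @export
print.cav_simulation <- function(x, ...) {
  s <- x$series
  n <- nrow(s)
  cat(sprintf(
    "<cav_simulation> '%s', seed %d: %d h simulated, %s\n",
    x$scenario$label, x$seed, s$t[n], x$termination))
  cat(sprintf(
    "  lumen area %d -> %d sites (%.1f%% reduction); intima %d -> %d\n",
    s$lumen_area[1L], s$lumen_area[n],
    100 * (1 - s$lumen_area[n] / s$lumen_area[1L]),
    s$intima_area[1L], s$intima_area[n]))
  invisible(x)
}

#' Run replicate simulations
#'
#' Independent seeded repetitions of one scenario (three by default,
#' matching the published protocol).
#'
#' @inheritParams run_simulation
#' @param n_reps Number of replicates.
#' @param seeds Integer seeds, one per replicate (default `1:n_reps`).
#' @param ... Passed on to [run_simulation].
#' @return A `cav_replicates` list of `cav_simulation` objects.
#' @export
run_replicates <- function(scenario, params = param_midpoints(),
                           tl = timeline(), n_reps = 3L, seeds = NULL, ...) {
  if (is.null(seeds)) seeds <- seq_len(n_reps)
  if (anyDuplicated(seeds)) warning("duplicate replicate seeds")
  out <- lapply(seeds, function(s)
    run_simulation(scenario, params = params, tl = tl, seed = s, ...))
  class(out) <- "cav_replicates"
  out
}

#' @export
print.cav_replicates <- function(x, ...) {
  cat(sprintf("<cav_replicates> %d runs of '%s'\n", length(x),
              x[[1L]]$scenario$label))
  for (r in x) print(r)
  invisible(x)
}
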