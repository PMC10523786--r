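test_that("labelled scenarios reproduce the published configuration grid", {
  s1 <- build_scenario(1)
  expect_equal(s1$inflammation_mode, "uniform")
  expect_equal(s1$level, 0.5)
  expect_equal(s1$wss_mode, "absent")
  expect_false(s1$mp_events); expect_false(s1$chemoattractant)
  s14 <- build_scenario(14)
  expect_equal(s14$inflammation_mode, "gaussian")
  expect_equal(s14$wss_mode, "offcenter")
  expect_equal(s14$Q, 0.20)
  expect_true(s14$mp_events); expect_true(s14$chemoattractant)
  # scenarios 1-6 have no events; 7-14 have macrophages; Ca on evens 8-14
  for (k in 1:6) expect_false(build_scenario(k)$mp_events)
  for (k in 7:14) expect_true(build_scenario(k)$mp_events)
  for (k in c(8, 10, 12, 14)) expect_true(build_scenario(k)$chemoattractant)
  for (k in c(7, 9, 11, 13)) expect_false(build_scenario(k)$chemoattractant)
  expect_equal(build_scenario("mild")$Q, 0.30)
  expect_equal(build_scenario("severe")$Q, 0.10)
  expect_error(build_scenario("nope"), "valid labels")
  expect_error(scenario_spec("absent", mp_events = FALSE,
                             chemoattractant = TRUE), "requires")
})

test_that("identical seeds give bit-identical runs", {
  a <- tiny_run(14, seed = 42)
  b <- tiny_run(14, seed = 42)
  expect_identical(a$series, b$series)
  expect_identical(a$section$occ, b$section$occ)
  c <- tiny_run(14, seed = 43)
  expect_false(identical(a$series, c$series))
})

test_that("event windows gate macrophage and migration activity exactly", {
  r <- tiny_run(14, seed = 1)
  tal <- r$tallies
  tl <- timeline()
  mp_cols <- c("mp_infiltration", "mp_mitosis", "mp_apoptosis")
  # no macrophage event before t_i = 48 h
  expect_true(all(tal[seq_len(tl$t_i - 1), mp_cols] == 0))
  expect_true(all(r$series$intima_mp[r$series$t < tl$t_i] == 0))
  # no infiltration after the peak t_c
  expect_true(all(tal$mp_infiltration[seq(tl$t_c + 1, nrow(tal))] == 0))
  # no migration before t_c = 168 h
  expect_true(all(tal$migration[seq_len(tl$t_c)] == 0))
  # the MP series rises after t_i in an event-active scenario
  expect_gt(max(r$series$intima_mp), 0)
})

test_that("macrophage content rises to a peak near one week then declines", {
  r <- tiny_run(14, seed = 2)
  s <- r$series
  tl <- timeline()
  peak_window <- s$intima_mp[s$t >= tl$t_c - 36 & s$t <= tl$t_c + 36]
  late <- utils::tail(s$intima_mp, max(3, nrow(s) %/% 10))
  expect_gt(max(peak_window), 0)
  expect_lt(mean(late), max(peak_window))
  expect_lt(s$intima_mp[nrow(s)], max(s$intima_mp))
})

test_that("per-hour ledger reconciliation holds on a full event-rich run", {
  # check_ledger = TRUE raises on any violation; a clean finish is the assert
  r <- tiny_run(14, seed = 3, check_ledger = TRUE)
  expect_s3_class(r, "cav_simulation")
  # cross-check the cumulative ledger against the series
  s <- r$series; tal <- r$tallies
  d_total_agents <-
    (s$intima_smc + s$intima_ecm + s$intima_mp + s$media_smc + s$media_ecm)
  expect_equal(d_total_agents[nrow(s)] - d_total_agents[1],
               sum(tal$smc_mitosis) - sum(tal$smc_apoptosis) +
                 sum(tal$ecm_production) - sum(tal$ecm_degradation) +
                 sum(tal$migration) +
                 sum(tal$mp_infiltration) + sum(tal$mp_mitosis) -
                 sum(tal$mp_apoptosis))
  # lumen change balances the intima/infiltration/migration bookkeeping:
  # medial events cancel out of the lumen entirely
  expect_equal(s$lumen_area[1] - s$lumen_area[nrow(s)],
               s$intima_area[nrow(s)] - s$intima_area[1])
})

test_that("homeostatic baseline holds the lumen on the reduced lattice", {
  r <- tiny_run("baseline", seed = 4)
  s <- r$series
  expect_equal(r$termination, "time_elapsed")
  drift <- abs(s$lumen_area[nrow(s)] / s$lumen_area[1] - 1)
  expect_lt(drift, 0.15)
  # no macrophages, no migration in the baseline
  expect_true(all(s$intima_mp == 0))
  expect_true(all(r$tallies$migration == 0))
})

test_that("occlusion terminates the run at the 99% threshold", {
  # drive the tiny vessel hard: maximal inflammation effects
  p <- param_midpoints(alpha3 = 0.2, alpha5 = 0.25, gamma = 0.5)
  sc <- scenario_spec("uniform", level = 1, wss_mode = "absent",
                      label = "overdrive")
  r <- tiny_run(sc, seed = 5, params = p)
  expect_equal(r$termination, "occlusion")
  s <- r$series
  expect_lte(s$lumen_area[nrow(s)], 0.01 * s$lumen_area[1])
  expect_lt(s$t[nrow(s)], timeline()$t_sim)
})

test_that("replicates are independent and tidy into long tables", {
  rr <- run_replicates(build_scenario("baseline"), n_reps = 2,
                       spec = tiny_spec(), lumen_radius_sites = 10,
                       wall_thickness_sites = 6, layer_split = tiny_split,
                       snapshot_times = integer(0))
  expect_length(rr, 2)
  expect_false(identical(rr[[1]]$series, rr[[2]]$series))
  td <- tidy(rr)
  expect_true(all(c("replicate", "t", "lumen_area") %in% names(td)))
  expect_equal(sort(unique(td$replicate)), 1:2)
  gl <- glance(rr)
  expect_equal(nrow(gl), 2)
  expect_true(all(c("lumen_reduction_pct", "termination") %in% names(gl)))
  expect_warning(run_replicates(build_scenario("baseline"), n_reps = 2,
                                seeds = c(1, 1), spec = tiny_spec(),
                                lumen_radius_sites = 10,
                                wall_thickness_sites = 6,
                                layer_split = tiny_split,
                                snapshot_times = integer(0)),
                 "duplicate")
})
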