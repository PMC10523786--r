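test_that("agent clocks advance, trigger at the cycle length, and reset", {
  v <- tiny_section(seed = 1)
  # force a known clock state: one ECM one step from eligibility, one SMC
  # freshly reset
  ecm <- which(v$occ == OCC[["ECM"]])[1]
  smc <- which(v$occ == OCC[["SMC"]])[1]
  v$clock[ecm] <- 1; v$clock[smc] <- 0
  out <- advance_clocks(v)
  expect_true(ecm %in% out$eligible$site)     # T_ECM = 2 h
  expect_false(smc %in% out$eligible$site)    # T_SMC = 12 h: 11 steps to go
  expect_equal(out$section$clock[ecm], 0)     # reset after eligibility
  for (k in 1:10) out <- advance_clocks(out$section)
  expect_false(smc %in% out$eligible$site)
  out <- advance_clocks(out$section)
  expect_true(smc %in% out$eligible$site)
})

test_that("per-step eligible fraction approximates the renewal rate", {
  v <- tiny_section(seed = 2)
  n_smc <- sum(v$occ == OCC[["SMC"]])
  n_ecm <- sum(v$occ == OCC[["ECM"]])
  smc_elig <- ecm_elig <- 0
  out <- list(section = v)
  for (k in 1:48) {
    out <- advance_clocks(out$section)
    smc_elig <- smc_elig + sum(out$eligible$kind == "SMC")
    ecm_elig <- ecm_elig + sum(out$eligible$kind == "ECM")
  }
  expect_equal(smc_elig / (48 * n_smc), 1 / 12, tolerance = 0.15)
  expect_equal(ecm_elig / (48 * n_ecm), 1 / 2, tolerance = 0.05)
})

test_that("Monte Carlo test honours the two-decimal discretization", {
  set.seed(1)
  expect_false(any(monte_carlo_test(0, n = 1000)))
  # p = 1 fails only when the discretized draw equals 1.00 (prob 1/101)
  hits <- monte_carlo_test(1, n = 20000, digits = 2)
  expect_equal(mean(!hits), 1 / 101, tolerance = 0.25)
  # p = 0.3: empirical rate within 3 binomial sigmas
  n <- 1e5
  got <- mean(monte_carlo_test(0.3, n = n, digits = 2))
  expect_lt(abs(got - 30 / 101), 3 * sqrt(0.3 * 0.7 / n) + 0.001)
  # continuous mode
  got_c <- mean(monte_carlo_test(0.3, n = n, digits = Inf))
  expect_lt(abs(got_c - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("SMC and ECM probability laws evaluate term by term", {
  p <- parameter_set(alpha1 = 0.014, alpha2 = 0.006, gamma = 1.301,
                     alpha3 = 0.02, alpha4 = 0.003, alpha5 = 0.021,
                     alpha6 = 0.004, alpha11 = 0.015, alpha12 = 0.02,
                     alpha13 = 0.018, alpha14 = 0.022)
  # media: baseline homeostasis regardless of stimuli
  m <- smc_event_probabilities("media", I_input = 1, n_mp = 4,
                               wss_input = 1, ca_norm = 1, params = p)
  expect_equal(m$p_mitosis, 0.014)
  expect_equal(m$p_apoptosis, 0.014)
  # intima with zero stimuli: homeostasis
  i0 <- smc_event_probabilities("intima", params = p)
  expect_equal(i0$p_mitosis, i0$p_apoptosis)
  # hand computation for a stimulated intima site
  i1 <- smc_event_probabilities("intima", I_input = 1, n_mp = 2,
                                wss_input = 0.5, ca_norm = 0.25, params = p)
  expect_equal(i1$p_mitosis,
               0.014 + 0.02 * 1 + 0.003 * 2 + 0.015 * 0.5 + 0.018 * 0.25,
               tolerance = 1e-12)
  e <- ecm_event_probabilities("media", params = p)
  expect_equal(e$p_production, 0.006)
  expect_equal(e$p_degradation, 1.301 * 0.006, tolerance = 1e-12)
  e1 <- ecm_event_probabilities("intima", I_input = 0.8, n_mp = 1,
                                wss_input = 0.3, ca_norm = 0.6, params = p)
  expect_equal(e1$p_production,
               0.006 + 0.021 * 0.8 + 0.004 * 1 + 0.02 * 0.3 + 0.022 * 0.6,
               tolerance = 1e-12)
  # gamma = 1 balances the ECM baselines
  eb <- ecm_event_probabilities("media", params = parameter_set(gamma = 1))
  expect_equal(eb$p_production, eb$p_degradation)
})

test_that("probabilities stay in [0,1] across the sampled parameter ranges", {
  rng <- param_ranges()
  set.seed(5)
  for (k in 1:40) {
    draw <- stats::setNames(
      stats::runif(nrow(rng), rng$low, rng$high), rng$parameter)
    p <- do.call(parameter_set, as.list(draw))
    s <- smc_event_probabilities("intima", I_input = 1, n_mp = 6,
                                 wss_input = 1, ca_norm = 1, params = p)
    e <- ecm_event_probabilities("intima", I_input = 1, n_mp = 6,
                                 wss_input = 1, ca_norm = 1, params = p)
    probs <- c(s$p_mitosis, s$p_apoptosis, e$p_production, e$p_degradation)
    expect_true(all(probs >= 0 & probs <= 1))
    expect_lte(s$p_mitosis + s$p_apoptosis, 1 + 1e-12)
    expect_lte(e$p_production + e$p_degradation, 1 + 1e-12)
    inf <- mp_infiltration_probability(1, dist_mp = 0.5, mp_group = 500,
                                       params = p)
    expect_true(inf >= 0 && inf <= 1)
  }
})

test_that("macrophage infiltration probability composes its three factors", {
  p <- parameter_set(alpha7 = 0.01, alpha8 = 1.2, alpha9 = 20)
  # no macrophages anywhere: all amplification factors collapse to 1
  expect_equal(mp_infiltration_probability(0, Inf, 0, p), 0.01)
  # full inflammation doubles the baseline
  expect_equal(mp_infiltration_probability(1, Inf, 0, p), 0.02)
  # hand product with macrophages present
  expect_equal(mp_infiltration_probability(0.5, 2, 5, p),
               0.01 * 1.5 * (1 + 1.2 * exp(-2)) * (1 + 5 / 20),
               tolerance = 1e-12)
})

test_that("access-site selection tests candidates in descending order", {
  sites <- 101:110
  expect_equal(select_mp_access_site(integer(0), numeric(0)), NA_integer_)
  expect_equal(select_mp_access_site(sites, rep(0, 10)), NA_integer_)
  set.seed(2)
  expect_equal(select_mp_access_site(sites, c(rep(0, 4), 1, rep(0, 5)),
                                     try = 10), 105L)
  # frequency oracle: sequential Bernoulli over the sorted list
  probs <- c(0.5, 0.3, 0.1)
  sites3 <- c(7L, 8L, 9L)
  set.seed(7)
  got <- table(factor(replicate(4000, {
    s <- select_mp_access_site(sites3, probs, try = 3)
    if (is.na(s)) "none" else as.character(s)
  }), levels = c("7", "8", "9", "none")))
  expected <- c(0.5, 0.5 * 0.3, 0.5 * 0.7 * 0.1, 0.5 * 0.7 * 0.9)
  expect_equal(as.numeric(got) / 4000, expected, tolerance = 0.12)
})

test_that("macrophage dynamics switch phase at the infiltration peak", {
  p <- param_midpoints()
  tl <- timeline()
  before <- mp_dynamics_probabilities(tl$t_i, p, tl)
  expect_equal(unlist(before), c(p_mitosis = 0, p_apoptosis = 0))
  growth <- mp_dynamics_probabilities(tl$t_c, p, tl)
  expect_equal(growth$p_mitosis, p$alpha10)
  expect_equal(growth$p_apoptosis, 0.5 * p$alpha10)
  decline <- mp_dynamics_probabilities(tl$t_c + 1, p, tl)
  expect_equal(decline$p_mitosis, 0.5 * p$alpha10)
  expect_equal(decline$p_apoptosis, p$alpha10)
  frozen <- mp_dynamics_probabilities(tl$t_c, parameter_set(alpha10 = 0), tl)
  expect_equal(unlist(frozen), c(p_mitosis = 0, p_apoptosis = 0))
})

test_that("chemoattractant field is a normalized diffusion Gaussian", {
  v <- tiny_section(seed = 3)
  geo <- v$geo
  int <- which(v$layer == LAY[["intima"]])
  ctr <- c(geo$x[int[5]], geo$y[int[5]])
  p <- param_midpoints()
  ca <- chemoattractant_field(v, ctr, td = 120, params = p)
  expect_true(all(ca$ca >= 0))
  expect_equal(max(ca$ca_norm), 1)
  expect_equal(min(ca$ca_norm), 0)
  # the argmax site is the one nearest the centroid
  d <- sqrt((geo$x[ca$site] - ctr[1])^2 + (geo$y[ca$site] - ctr[2])^2)
  expect_equal(ca$site[which.max(ca$ca_norm)], ca$site[which.min(d)])
  # pairwise ratios match the closed-form Gaussian kernel
  a <- 4 * p$D_coeff * (120 / 24)
  i1 <- which.min(abs(d - 3)); i2 <- which.min(abs(d - 6))
  expect_equal(ca$ca[i1] / ca$ca[i2],
               exp(-(d[i1]^2 - d[i2]^2) / a), tolerance = 1e-10)
  # monotone decay in distance
  expect_gt(ca$ca[i1], ca$ca[i2])
  expect_error(chemoattractant_field(v, ctr, td = 0), "td")
})

test_that("migration selection respects the radius and the acceptance law", {
  v <- tiny_section(seed = 4)
  geo <- v$geo
  int <- which(v$layer == LAY[["intima"]])
  ctr <- c(geo$x[int[1]], geo$y[int[1]])
  ca <- chemoattractant_field(v, ctr, td = 240, params = param_midpoints())
  # radius too small to reach any medial SMC: never a pair
  set.seed(1)
  expect_null(select_smc_migration(v, ca, c_radius = 0.1))
  # acceptance frequency tracks the mean Ca_norm over eligible targets
  set.seed(2)
  n_try <- 600
  acc <- sum(!vapply(seq_len(n_try), function(i)
    is.null(select_smc_migration(v, ca, c_radius = 30)), logical(1)))
  pool <- ca$ca_norm[ca$ca_norm >= 0.005]
  expect_equal(acc / n_try, mean(pool), tolerance = 0.12)
  # a successful pair has a medial SMC source within reach and intima target
  set.seed(3)
  pair <- NULL
  while (is.null(pair)) pair <- select_smc_migration(v, ca, c_radius = 30)
  expect_equal(v$occ[pair$source], OCC[["SMC"]])
  expect_equal(v$layer[pair$source], LAY[["media"]])
  expect_equal(v$layer[pair$target], LAY[["intima"]])
})
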