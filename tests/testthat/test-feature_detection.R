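# Default trapezoid geometry (1.5 ms sampling): ramp-up midpoint at 100/2 ms
# = sample 33, ramp duration ~67 samples, so tau = 30 (half the ramp or
# slightly less).
TAU <- 30

test_that("default_bands follows the stated arithmetic", {
  # synthesise a slope series with known extremes +-2
  sim <- trapezoid_sim(n_cycles = 3, plateau_height = 1)
  sl <- slope_series(sim$trace, TAU)
  sc <- 2 / max(sl$centered, na.rm = TRUE)
  sl$centered <- sl$centered * sc   # now max 2; min scales symmetrically
  mn <- min(sl$centered, na.rm = TRUE)
  b <- default_bands(sl, epsilon = 0.1, fraction = 0.5)
  expect_equal(b$max_slope_band, c(1, Inf))
  expect_equal(b$min_slope_band, c(-Inf, 0.5 * mn))
  expect_equal(b$m_max, max(2, abs(mn)))
  expect_equal(b$zero_range, c(-0.1, 0.1) * b$m_max)
  expect_equal(b$epsilon, 0.1)
  # sign flip swaps and negates the two bands
  sl2 <- sl; sl2$centered <- -sl$centered
  b2 <- default_bands(sl2, epsilon = 0.1, fraction = 0.5)
  expect_equal(b2$max_slope_band, c(-0.5 * mn, Inf))
  expect_equal(b2$min_slope_band, c(-Inf, -1))
  expect_error(default_bands(slope_series(rep(3, 20), 2)), "degenerate")
})

test_that("max/min slope points take the interval extremum, earliest on ties", {
  sim <- trapezoid_sim(n_cycles = 2)
  sl <- slope_series(sim$trace, TAU)
  p <- max_slope_point(sl, 0 + TAU, 300)
  expect_equal(p$kind, "max_slope")
  expect_lte(abs(p$t - sim$truth$t_rampup_mid[1]), 1)
  expect_equal(p$slope_value, sl$centered[p$t + 1])
  q <- min_slope_point(sl, 200, 400)
  expect_lte(abs(q$t - sim$truth$t_rampdown_mid[1]), 1)
  # flat series: extremum slope 0, earliest index wins
  flat <- slope_series(rep(1, 50), 3)
  pf <- max_slope_point(flat, 3, 46)
  expect_equal(pf$t, 3L)
  expect_equal(pf$slope_value, 0)
  expect_error(max_slope_point(sl, 100, 100), "T2 > T1")
  expect_error(max_slope_point(sl, 0, 10), "valid")
})

test_that("classify_points applies the band matching each kind", {
  b <- acceptance_bands(c(0.5, Inf), c(-Inf, -0.5), c(-0.1, 0.1))
  pts <- rbind(
    data.frame(kind = "max_slope", t = 1L, slope_value = 0, valid = NA),
    data.frame(kind = "max_slope", t = 2L, slope_value = 0.8, valid = NA),
    data.frame(kind = "min_slope", t = 3L, slope_value = -0.7, valid = NA),
    data.frame(kind = "min_slope", t = 4L, slope_value = -0.1, valid = NA),
    data.frame(kind = "plateau_begin", t = 5L, slope_value = 0.05, valid = NA))
  out <- classify_points(pts, b)
  expect_equal(out$valid, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(out[names(out) != "valid"], pts[names(pts) != "valid"])
})

test_that("detect_cycles finds every trapezoid cycle and obeys alternation", {
  sim <- trapezoid_sim(n_cycles = 5)
  cyc <- detect_features(sim$trace, TAU)
  expect_equal(nrow(cyc), 5L)
  expect_lte(max(abs(cyc$t_max - sim$truth$t_rampup_mid)), 1)
  expect_lte(max(abs(cyc$t_min - sim$truth$t_rampdown_mid)), 1)
  # constant trace has no candidate runs at all
  sl <- slope_series(rnorm(100, sd = 1e-12) + 5, 4)
  bands <- acceptance_bands(c(0.5, Inf), c(-Inf, -0.5), c(-0.1, 0.1))
  expect_equal(nrow(detect_cycles(sl, bands)), 0L)
  # trace beginning mid-plateau: leading min candidate discarded
  half <- round(400 / 1.5)   # drop up to mid-plateau of cycle 1
  tr2 <- trace(sim$trace$values[-(1:half)])
  cyc2 <- detect_features(tr2, TAU)
  expect_equal(nrow(cyc2), 4L)  # only complete max->min pairs remain
  expect_true(all(cyc2$t_max < cyc2$t_min))
})

test_that("plateau bounds respect ordering and flag undetermined cycles", {
  sim <- trapezoid_sim(n_cycles = 5)
  cyc <- detect_features(sim$trace, TAU)
  expect_true(all(!cyc$plateau_undetermined))
  expect_true(all(cyc$t_max < cyc$t_begin & cyc$t_begin <= cyc$t_end &
                    cyc$t_end < cyc$t_min))
  expect_lte(max(abs(cyc$t_begin - sim$truth$t_plateau_begin)), TAU)
  expect_lte(max(abs(cyc$t_end - sim$truth$t_plateau_end)), TAU)
  # pure triangle wave: no flat top, tight zero range -> undetermined
  tri <- trapezoid_sim(n_cycles = 4, ramp_up = 240, plateau = 1,
                       ramp_down = 240, period = 500)
  sl <- slope_series(smooth_trace(tri$trace), TAU)
  b <- default_bands(sl, epsilon = 1e-9)
  cy <- plateau_bounds(sl, detect_cycles(sl, b), b)
  expect_true(all(cy$plateau_undetermined))
  expect_true(all(is.na(cy$t_begin)))
  # t_max >= t_min is rejected
  bad <- data.frame(t_max = 100L, t_min = 90L)
  expect_error(plateau_bounds(sl, bad, b), "before")
})

test_that("noisy detection degrades gracefully with sigma", {
  # 3 noise levels x traces: detection rate >= 95 % everywhere and the SD of
  # (detected - true) midpoint time increases with sigma
  sigmas <- c(0.02, 0.05, 0.10)     # up to 10 % of plateau height
  spread <- numeric(length(sigmas))
  rate <- numeric(length(sigmas))
  n_tr <- 20; n_cyc <- 10
  for (k in seq_along(sigmas)) {
    errs <- c(); found <- 0; total <- 0
    for (r in 1:n_tr) {
      sim <- trapezoid_sim(n_cycles = n_cyc, noise_sigma = sigmas[k],
                           seed = 1000 * k + r)
      cyc <- detect_features(sim$trace, TAU)
      total <- total + n_cyc
      # match detected to true midpoints within half a period
      for (i in seq_len(nrow(cyc))) {
        d <- abs(sim$truth$t_rampup_mid - cyc$t_max[i])
        if (min(d) < 333) {
          found <- found + 1
          errs <- c(errs, cyc$t_max[i] - sim$truth$t_rampup_mid[which.min(d)])
        }
      }
    }
    rate[k] <- found / total
    spread[k] <- sd(errs)
  }
  expect_true(all(rate >= 0.95))
  expect_gt(cor(sigmas, spread, method = "spearman"), 0)
})

test_that("spike-dominant regime: bands bracketing ramp slopes reject spikes", {
  # spikes much larger than the plateau deflection; a narrow band around the
  # known ramp-slope magnitude excludes spike-induced slope extrema, and the
  # count of valid max/min slope points equals the number of true bursts
  tpl <- cycle_template(ramp_up = 180, plateau = 300, ramp_down = 180,
                        plateau_height = 0.3, spike_amplitude = 1,
                        spike_rate = 0.015, spike_width = 3)
  tau <- 60   # half the 120-sample ramp
  # calibrate the band from the noise-free, spike-free slope distribution
  ref <- slope_series(smooth_trace(trapezoid_sim(
    n_cycles = 1, ramp_up = 180, plateau = 300, ramp_down = 180,
    plateau_height = 0.3)$trace), tau)
  m_ramp <- max(ref$centered, na.rm = TRUE)
  b <- acceptance_bands(c(0.65, 1.35) * m_ramp, c(-1.35, -0.65) * m_ramp,
                        c(-0.1, 0.1) * m_ramp)
  for (seed in 11:16) {
    sim <- generate_trace(tpl, n_cycles = 6, seed = seed)
    sl <- slope_series(smooth_trace(sim$trace), tau)
    cyc <- detect_cycles(sl, b)
    expect_equal(nrow(cyc), 6L)   # one valid max/min pair per true burst
    expect_lt(max(abs(cyc$t_max - sim$truth$t_rampup_mid)), tau)
  }
  # regime sanity: the raw trace is spike-dominated — spike deflections
  # clearly exceed the plateau depolarisation
  sim <- generate_trace(tpl, n_cycles = 6, seed = 11)
  expect_gt(max(sim$trace$values), 2 * tpl$plateau_height)
})

test_that("feature_table flattens cycles with ms conversion", {
  sim <- trapezoid_sim(n_cycles = 2)
  cyc <- detect_features(sim$trace, TAU)
  tab <- feature_table(cyc)
  expect_setequal(unique(tab$kind),
                  c("max_slope", "min_slope", "plateau_begin", "plateau_end"))
  expect_equal(nrow(tab), 8L)
  expect_equal(tab$t_ms, tab$t_samples * 1.5)
  expect_false(is.unsorted(tab$t_samples))
})
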