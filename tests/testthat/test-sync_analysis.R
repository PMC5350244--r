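test_that("match_points pairs corresponding points and reports delays", {
  a <- c(100, 300, 500, 700)
  # identical lists: all delays 0
  d0 <- match_points(a, a, max_lag = 20)
  expect_equal(d0$delays, rep(0, 4))
  expect_equal(d0$n, 4L)
  # constant shift: all delays equal the shift
  d7 <- match_points(a, a + 7, max_lag = 20)
  expect_equal(d7$delays, rep(7, 4))
  # dropout in b: one a point unmatched, no delay beyond max_lag
  db <- match_points(a, (a + 3)[-2], max_lag = 20)
  expect_equal(db$n, 3L)
  expect_equal(db$n_unmatched_a, 1L)
  expect_true(all(abs(db$delays) <= 20))
  # default max_lag is half the median inter-point interval of a
  dd <- match_points(a, a + 7)
  expect_equal(dd$max_lag, 100)
  # each point used at most once even with crowded b
  dc <- match_points(c(100, 110), c(104, 105), max_lag = 20)
  expect_equal(dc$n, 2L)
  expect_setequal(dc$delays, c(104 - 100, 105 - 110))
})

test_that("match_points honours kind and validity filters on feature tables", {
  ta <- data.frame(kind = c("max_slope", "max_slope", "min_slope"),
                   t_samples = c(10, 110, 60),
                   valid = c(TRUE, FALSE, TRUE))
  tb <- data.frame(kind = c("max_slope", "min_slope"),
                   t_samples = c(12, 63), valid = TRUE)
  d <- match_points(ta, tb, kind = "max_slope", max_lag = 10)
  expect_equal(d$delays, 2)   # invalid point at 110 excluded
  expect_equal(d$kind, "max_slope")
})

test_that("delay_stats gives sample mean and n-1 standard deviation", {
  expect_equal(delay_stats(c(0, 0, 0, 0)), list(mean = 0, sd = 0, n = 4L))
  expect_equal(delay_stats(c(1, 3)), list(mean = 2, sd = sqrt(2), n = 2L))
  expect_equal(delay_stats(c(-2, 0, 2)), list(mean = 0, sd = 2, n = 3L))
  expect_error(delay_stats(5), "insufficient")
  d <- match_points(c(0, 100, 200), c(3, 103, 203), max_lag = 50)
  expect_equal(delay_stats(d, units = "ms")$mean, 3 * 1.5)
})

test_that("f_test matches independent F-distribution oracles", {
  # identical samples: F = 1, p = 1, no direction
  x <- c(1, 2, 3, 4, 5)
  r <- f_test(x, x)
  expect_equal(r$f_statistic, 1)
  expect_equal(r$p_value, 1)
  expect_equal(r$direction, "none")
  # n = 61 each, variance ratio 2: check p against numerical integration of
  # the F density and against stats::var.test
  set.seed(21)
  c0 <- rnorm(61); t0 <- rnorm(61)
  t0 <- t0 / sd(t0) * sd(c0) * sqrt(2)   # exact variance ratio 2
  r2 <- f_test(c0, t0)
  expect_equal(r2$f_statistic, 2)
  expect_equal(r2$p_value, f_p_numint(2, 60, 60), tolerance = 1e-8)
  vt <- stats::var.test(t0, c0)
  expect_equal(r2$p_value, vt$p.value, tolerance = 1e-12)
  # orientation: treatment variance over control variance, direction follows
  r3 <- f_test(rep(c(0, 10), 10), c(1:20) * 0.01)
  expect_equal(r3$direction, "lower")
  expect_lt(r3$f_statistic, 1)
  expect_error(f_test(c(1, 1), c(2, 2)), "degenerate")
  expect_error(f_test(1, c(1, 2)), "insufficient")
})

test_that("f_test keeps its nominal type-I error", {
  set.seed(33)
  rej <- mean(replicate(1000, f_test(rnorm(60), rnorm(60))$significant))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("count_significant partitions and conserves", {
  grid <- data.frame(p_value = c(0.01, 0.2, 0.03, 0.8),
                     sd_control = c(1, 1, 2, 1),
                     sd_treatment = c(2, 2, 1, 1))
  ct <- count_significant(grid, alpha = 0.05)
  expect_equal(ct$n_larger, 1L)
  expect_equal(ct$n_lower, 1L)
  expect_equal(ct$n_ns, 2L)
  expect_equal(ct$n_larger + ct$n_lower + ct$n_ns, ct$n_total)
  # empty input and all-nonsignificant input
  expect_equal(count_significant(numeric(0))$n_total, 0L)
  all1 <- count_significant(rep(1, 5))
  expect_equal(all1$n_significant, 0L)
  expect_equal(all1$n_ns, 5L)
})

test_that("the published dopamine p-values yield 22 significant comparisons", {
  pv <- py_delay_pvalues(long = TRUE)
  expect_equal(nrow(pv), 44L)
  ct <- count_significant(pv, alpha = 0.05)
  expect_equal(ct$n_significant, 22L)
  expect_equal(ct$n_ns, 22L)
})

test_that("event_triggered_average reduces noise like 1/sqrt(k)", {
  # constant trace stays constant
  trig <- seq(0, 900, by = 100)
  cst <- event_triggered_average(trace(rep(4, 1000)), trig)
  expect_true(all(cst$values == 4))
  expect_equal(length(cst$values), 300L)   # 3 cycles of 100 samples
  # perfectly periodic trace: average equals any single 3-cycle window
  per <- rep(sin(2 * pi * (0:99) / 100), 12)
  eta <- event_triggered_average(trace(per), trig)
  expect_equal(eta$values, per[1:300])
  # noisy periodic trace: residual noise shrinks about 1/sqrt(k)
  set.seed(5)
  n_rep <- 40; k <- 8
  shrink <- replicate(n_rep, {
    noisy <- per[1:1100] + rnorm(1100, sd = 0.3)
    trig2 <- seq(0, 1000, by = 100)
    eta2 <- event_triggered_average(trace(noisy), trig2)
    sd(eta2$values - per[1:300]) / 0.3
  })
  expect_equal(mean(shrink), 1 / sqrt(k), tolerance = 0.1)
  expect_error(event_triggered_average(trace(rep(1, 50)), c(0, 10, 20)),
               "insufficient")
  expect_error(event_triggered_average(trace(rep(1, 50)), c(10, 5, 20)),
               "increasing")
})

test_that("run_sync_experiment produces the pair-by-kind comparison grid", {
  cfg <- population_config(n_neurons = 3, n_cycles = 25, jitter_sd = 6,
                           noise_sigma = 0, seed = 101)
  pp <- make_condition_pair(cfg, desync_factor = 3)
  res <- run_sync_experiment(pp$control, pp$treatment, tau = 30)
  expect_s3_class(res, "sync_comparison")
  expect_equal(nrow(res$grid), 3 * 4)      # 3 pairs x 4 feature kinds
  expect_setequal(unique(res$grid$pair), c("PY1:PY2", "PY1:PY3", "PY2:PY3"))
  expect_equal(res$counts$n_larger + res$counts$n_lower + res$counts$n_ns,
               res$counts$n_total)
  # strong de-synchronisation: max/min-slope comparisons flag "larger"
  ms <- res$grid[res$grid$kind %in% c("max_slope", "min_slope"), ]
  expect_gte(mean(ms$direction == "larger"), 0.5)
  # identical conditions: no significant direction anywhere
  res0 <- run_sync_experiment(pp$control, pp$control, tau = 30)
  expect_true(all(res0$grid$direction[!is.na(res0$grid$direction)] == "none"))
  expect_true(all(na.omit(res0$grid$f_statistic) == 1))
})
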