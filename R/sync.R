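#' Match corresponding salient points of two neurons
#'
#' Pairs same-kind salient points of two neurons by greedy nearest-neighbour
#' matching: candidate pairs within `max_lag` of each other are accepted in
#' order of increasing absolute delay, each point being used at most once.
#' The matched temporal delay is `t_b - t_a` (positive when neuron `b` lags
#' neuron `a`). Unmatched points are dropped and counted. Greedy symmetric
#' matching is deterministic and robust to single missed cycles in either
#' neuron.
#'
#' @param a,b salient-point tables (data frames with columns `kind`,
#'   `t_samples` or `t`, and optionally `valid`; only valid points are used),
#'   or bare numeric vectors of times in samples.
#' @param kind which salient-point kind to match when tables are given
#'   (`"max_slope"`, `"min_slope"`, `"plateau_begin"`, `"plateau_end"`).
#' @param max_lag maximum allowed |delay| in samples; default is half the
#'   median inter-point interval of neuron `a`.
#' @param pair_id length-2 character vector naming the two neurons.
#' @param condition text label for the recording condition (e.g. "control",
#'   "DA").
#' @param sampling_interval ms per sample, used only for reporting.
#' @return an object of class `delay_series`: list with `pair_id`, `kind`,
#'   `condition`, `delays` (signed delays in samples), `n`, `n_unmatched_a`,
#'   `n_unmatched_b`, `max_lag`, `sampling_interval`.
#' @examples
#' a <- c(100, 300, 500, 700)
#' d <- match_points(a, a + 7, max_lag = 20)
#' d$delays
#' @export
match_points <- function(a, b, kind = NULL, max_lag = NULL,
                         pair_id = c("a", "b"), condition = "control",
                         sampling_interval = 1.5) {
  ta <- extract_times(a, kind)
  tb <- extract_times(b, kind)
  ta <- sort(ta); tb <- sort(tb)
  if (is.null(max_lag)) {
    if (length(ta) < 3L)
      stop("max_lag must be given when neuron 'a' has fewer than 3 points",
           call. = FALSE)
    max_lag <- stats::median(diff(ta)) / 2
  }
  if (!(max_lag > 0)) stop("max_lag must be positive", call. = FALSE)
  delays <- numeric(0)
  if (length(ta) && length(tb)) {
    d <- outer(tb, ta, "-")                     # d[j, i] = tb_j - ta_i
    cand <- which(abs(d) <= max_lag, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(abs(d[cand]), ta[cand[, 2L]])  # closest first, then time
      used_a <- logical(length(ta)); used_b <- logical(length(tb))
      keep <- numeric(0)
      for (k in ord) {
        j <- cand[k, 1L]; i <- cand[k, 2L]
        if (!used_a[i] && !used_b[j]) {
          used_a[i] <- TRUE; used_b[j] <- TRUE
          keep <- c(keep, d[j, i])
        }
      }
      delays <- keep
    }
  }
  structure(
    list(pair_id = pair_id, kind = kind %||% "point", condition = condition,
         delays = as.numeric(delays), n = length(delays),
         n_unmatched_a = length(ta) - length(delays),
         n_unmatched_b = length(tb) - length(delays),
         max_lag = max_lag, sampling_interval = sampling_interval),
    class = "delay_series")
}

extract_times <- function(x, kind) {
  if (is.numeric(x)) return(as.numeric(x))
  stopifnot(is.data.frame(x))
  if (!is.null(kind) && "kind" %in% names(x)) x <- x[x$kind == kind, ]
  if ("valid" %in% names(x)) x <- x[is.na(x$valid) | x$valid, ]
  tcol <- if ("t_samples" %in% names(x)) "t_samples" else "t"
  as.numeric(x[[tcol]])
}

#' @export
print.delay_series <- function(x, ...) {
  cat(sprintf("<delay_series> %s vs %s, kind '%s', condition '%s'\n",
              x$pair_id[1], x$pair_id[2], x$kind, x$condition))
  cat(sprintf("  n = %d matched (unmatched: %d in a, %d in b), max_lag = %.3g samples\n",
              x$n, x$n_unmatched_a, x$n_unmatched_b, x$max_lag))
  if (x$n >= 2L) {
    s <- delay_stats(x)
    cat(sprintf("  mean = %.4g, sd = %.4g samples (%.4g, %.4g ms)\n",
                s$mean, s$sd, s$mean * x$sampling_interval,
                s$sd * x$sampling_interval))
  }
  invisible(x)
}

#' Mean and standard deviation of matched delays
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of a delay
#' series. A small SD indicates phase locking of the pair; an increase in SD
#' between conditions indicates de-synchronisation.
#'
#' @param d a [match_points()] result, or a numeric vector of delays.
#' @param units `"samples"` (default) or `"ms"`.
#' @return list with `mean`, `sd`, `n`.
#' @export
delay_stats <- function(d, units = c("samples", "ms")) {
  units <- match.arg(units)
  dt <- 1
  if (inherits(d, "delay_series")) {
    if (units == "ms") dt <- d$sampling_interval
    d <- d$delays
  } else if (units == "ms") {
    stop("units = 'ms' needs a delay_series with a sampling interval",
         call. = FALSE)
  }
  if (length(d) < 2L)
    stop("insufficient data: need at least 2 delays", call. = FALSE)
  list(mean = mean(d) * dt, sd = stats::sd(d) * dt, n = length(d))
}

#' F-test for a change in delay variance between conditions
#'
#' Compares the delay standard deviations of one neuron pair and one
#' salient-point kind between two conditions with a variance-ratio F-test.
#' The statistic is oriented as `F = s_treatment^2 / s_control^2` with
#' `(n_t - 1, n_c - 1)` degrees of freedom; the test is two-sided
#' (`p = 2 * min(P(F <= f), P(F >= f))`, capped at 1) because both
#' significant increases (de-synchronisation) and decreases of delay
#' variability are of interest.
#'
#' @param control,treatment delay series ([match_points()] results) or
#'   numeric vectors of delays; each needs at least 2 values.
#' @param alpha significance level (default 0.05).
#' @return an object of class `variance_comparison`: one-row data frame with
#'   columns `pair`, `kind`, `n_control`, `n_treatment`, `sd_control`,
#'   `sd_treatment`, `f_statistic`, `p_value`, `direction` (`"larger"`,
#'   `"lower"` or `"none"`), `significant`, `alpha`.
#' @examples
#' set.seed(1)
#' f_test(rnorm(60), rnorm(60, sd = 2))
#' @export
f_test <- function(control, treatment, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  meta <- list(pair = "a:b", kind = "point")
  if (inherits(control, "delay_series")) {
    meta$pair <- paste(control$pair_id, collapse = ":")
    meta$kind <- control$kind
    control <- control$delays
  }
  if (inherits(treatment, "delay_series")) treatment <- treatment$delays
  nc <- length(control); nt <- length(treatment)
  if (nc < 2L || nt < 2L)
    stop("insufficient data: both conditions need at least 2 delays",
         call. = FALSE)
  sc <- stats::sd(control); st <- stats::sd(treatment)
  if (sc == 0 && st == 0)
    stop("degenerate input: zero variance in both conditions", call. = FALSE)
  f <- st^2 / sc^2
  p <- if (is.infinite(f)) 0 else
    min(1, 2 * min(stats::pf(f, nt - 1L, nc - 1L),
                   stats::pf(f, nt - 1L, nc - 1L, lower.tail = FALSE)))
  sig <- p < alpha
  dir <- if (!sig) "none" else if (st > sc) "larger" else "lower"
  out <- data.frame(pair = meta$pair, kind = meta$kind,
                    n_control = nc, n_treatment = nt,
                    sd_control = sc, sd_treatment = st,
                    f_statistic = f, p_value = p,
                    direction = dir, significant = sig, alpha = alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("variance_comparison", "data.frame")
  out
}

#' Count significant variance changes
#'
#' Partitions a set of variance comparisons into significantly larger,
#' significantly lower and non-significant at level `alpha`. Input may be a
#' comparison grid (rows from [f_test()] or [run_sync_experiment()]), or a
#' bare numeric vector of p-values — in which case only the total
#' significant/non-significant split is available and the direction counts
#' are `NA`.
#'
#' @param comparisons a data frame with a `p_value` column (and ideally
#'   `sd_control`/`sd_treatment`), or a numeric vector of p-values.
#' @param alpha significance level (default 0.05). Comparisons are counted
#'   as significant iff `p < alpha`, strictly.
#' @return list with `n_larger`, `n_lower`, `n_ns`, `n_significant`,
#'   `n_total`. When directions are available,
#'   `n_larger + n_lower + n_ns == n_total`.
#' @export
count_significant <- function(comparisons, alpha = 0.05) {
  if (is.numeric(comparisons))
    comparisons <- data.frame(p_value = as.numeric(comparisons))
  stopifnot(is.data.frame(comparisons), "p_value" %in% names(comparisons))
  p <- comparisons$p_value
  sig <- !is.na(p) & p < alpha
  have_dir <- all(c("sd_control", "sd_treatment") %in% names(comparisons))
  if (have_dir) {
    larger <- sig & comparisons$sd_treatment > comparisons$sd_control
    lower <- sig & comparisons$sd_treatment < comparisons$sd_control
    list(n_larger = sum(larger), n_lower = sum(lower),
         n_ns = sum(!sig), n_significant = sum(sig), n_total = length(p))
  } else {
    list(n_larger = NA_integer_, n_lower = NA_integer_,
         n_ns = sum(!sig), n_significant = sum(sig), n_total = length(p))
  }
}

#' Event-triggered average of a trace
#'
#' Averages trace windows aligned to analyst-marked trigger events (e.g. the
#' beginnings of LP phases of the pyloric rhythm). Window `i` runs from
#' trigger `i` up to (but excluding) trigger `i + cycles_per_window`; all
#' windows are truncated to the shortest window length (no resampling, which
#' would introduce interpolation artefacts) and averaged elementwise. With
#' `k` windows of independent noise the residual noise SD shrinks by about
#' `1/sqrt(k)`.
#'
#' @param tr a [trace()].
#' @param triggers strictly increasing integer vector of trigger sample
#'   indices (0-based).
#' @param cycles_per_window number of rhythm cycles per averaging window
#'   (default 3, i.e. consecutive triplets of cycles).
#' @return a `vsd_trace` holding the averaged window (t0 = 0).
#' @export
event_triggered_average <- function(tr, triggers, cycles_per_window = 3L) {
  tr <- as_trace(tr)
  triggers <- as.integer(triggers)
  if (any(diff(triggers) <= 0))
    stop("triggers must be strictly increasing", call. = FALSE)
  k <- length(triggers) - cycles_per_window
  if (k < 1L)
    stop(sprintf("insufficient data: need at least %d triggers, got %d",
                 cycles_per_window + 1L, length(triggers)), call. = FALSE)
  n <- length(tr$values)
  starts <- triggers[seq_len(k)] + 1L                      # 1-based
  ends <- pmin(triggers[seq_len(k) + cycles_per_window], n)
  wlen <- min(ends - starts + 1L)
  if (wlen < 1L) stop("trigger windows fall outside the trace", call. = FALSE)
  acc <- rowMeans(vapply(starts, function(s)
    tr$values[s:(s + wlen - 1L)], numeric(wlen)))
  trace(acc, sampling_interval = tr$sampling_interval,
        neuron_id = paste0(tr$neuron_id, "_eta"), t0 = 0L)
}

#' Pairwise de-synchronisation analysis of two multi-neuron recordings
#'
#' Runs the complete workflow on a control and a treatment recording of the
#' same neurons: smoothing, slope estimation, cycle detection, plateau
#' bounds, matched temporal delays for every neuron pair and salient-point
#' kind, and a variance-ratio F-test per (pair, kind) cell. This mirrors the
#' analysis of dopamine-induced de-synchronisation of PY neurons: each pair
#' contributes up to four comparisons (maximum slope, minimum slope, plateau
#' begin, plateau end points).
#'
#' @param control,treatment named lists of [trace()] objects with identical
#'   names (one per neuron), or `population` objects from
#'   [generate_population()].
#' @param tau positive integer slope half-window.
#' @param smoothing a [smoothing_spec()], plain window length, or `NULL`.
#' @param bands an [acceptance_bands()], or `NULL` for [default_bands()]
#'   derived per neuron and condition.
#' @param fraction,epsilon passed to [default_bands()].
#' @param max_lag matching window in samples, or `NULL` for the automatic
#'   half-median-period rule.
#' @param alpha F-test significance level (per comparison; no
#'   multiple-testing correction by default).
#' @param bonferroni if `TRUE`, `alpha` is divided by the number of
#'   comparisons before significance is assessed.
#' @param units `"ms"` (default) or `"samples"` for the reported SDs.
#' @return an object of class `sync_comparison`: list with `grid` (one row
#'   per pair and kind: `pair`, `kind`, counts, SDs, `f_statistic`,
#'   `p_value`, `direction`, `significant`), `counts` (from
#'   [count_significant()]), and `params`.
#' @examples
#' \donttest{
#' pp <- make_condition_pair(population_config(n_neurons = 2, n_cycles = 20,
#'                                             seed = 7), desync_factor = 2)
#' run_sync_experiment(pp$control, pp$treatment, tau = 30)
#' }
#' @export
run_sync_experiment <- function(control, treatment, tau,
                                smoothing = smoothing_spec(), bands = NULL,
                                fraction = 0.5, epsilon = 0.1,
                                max_lag = NULL, alpha = 0.05,
                                bonferroni = FALSE,
                                units = c("ms", "samples")) {
  units <- match.arg(units)
  control <- as_trace_list(control)
  treatment <- as_trace_list(treatment)
  if (!identical(sort(names(control)), sort(names(treatment))))
    stop("control and treatment must share neuron labels", call. = FALSE)
  ids <- names(control)
  if (length(ids) < 2L) stop("need at least two neurons", call. = FALSE)
  feats <- list(
    control = lapply(control, function(tr)
      feature_table(detect_features(tr, tau, smoothing = smoothing,
                                    bands = bands, epsilon = epsilon,
                                    fraction = fraction))),
    treatment = lapply(treatment, function(tr)
      feature_table(detect_features(tr, tau, smoothing = smoothing,
                                    bands = bands, epsilon = epsilon,
                                    fraction = fraction))))
  kinds <- c("max_slope", "min_slope", "plateau_begin", "plateau_end")
  pairs <- utils::combn(ids, 2L, simplify = FALSE)
  dt <- control[[1]]$sampling_interval
  scale <- if (units == "ms") dt else 1
  rows <- list()
  for (pr in pairs) {
    for (kd in kinds) {
      ds <- lapply(c("control", "treatment"), function(cond) {
        match_points(feats[[cond]][[pr[1]]], feats[[cond]][[pr[2]]],
                     kind = kd, max_lag = max_lag, pair_id = pr,
                     condition = cond, sampling_interval = dt)
      })
      if (ds[[1]]$n < 2L || ds[[2]]$n < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          pair = paste(pr, collapse = ":"), kind = kd,
          n_control = ds[[1]]$n, n_treatment = ds[[2]]$n,
          sd_control = NA_real_, sd_treatment = NA_real_,
          f_statistic = NA_real_, p_value = NA_real_,
          direction = NA_character_, significant = NA, alpha = alpha,
          stringsAsFactors = FALSE)
      } else {
        cmp <- f_test(ds[[1]], ds[[2]], alpha = alpha)
        cmp$sd_control <- cmp$sd_control * scale
        cmp$sd_treatment <- cmp$sd_treatment * scale
        rows[[length(rows) + 1L]] <- as.data.frame(cmp)
      }
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  eff_alpha <- if (bonferroni) alpha / sum(!is.na(grid$p_value)) else alpha
  grid$significant <- !is.na(grid$p_value) & grid$p_value < eff_alpha
  grid$direction <- ifelse(!grid$significant, "none",
                           ifelse(grid$sd_treatment > grid$sd_control,
                                  "larger", "lower"))
  grid$direction[is.na(grid$p_value)] <- NA_character_
  counts <- count_significant(grid[!is.na(grid$p_value), , drop = FALSE],
                              alpha = eff_alpha)
  structure(
    list(grid = grid, counts = counts,
         params = list(tau = tau, fraction = fraction, epsilon = epsilon,
                       max_lag = max_lag, alpha = alpha,
                       bonferroni = bonferroni, units = units,
                       sampling_interval = dt)),
    class = "sync_comparison")
}

as_trace_list <- function(x) {
  if (inherits(x, "population")) x <- x$traces
  stopifnot(is.list(x), all(vapply(x, is_trace, logical(1))))
  if (is.null(names(x)) || any(names(x) == ""))
    names(x) <- vapply(x, function(tr) tr$neuron_id, character(1))
  x
}

#' @export
print.sync_comparison <- function(x, ...) {
  cat(sprintf("<sync_comparison> %d comparison(s), alpha = %g (%s)\n",
              nrow(x$grid), x$params$alpha, x$params$units))
  print.data.frame(x$grid, digits = 4)
  with(x$counts, cat(sprintf(
    "significant: %s larger, %s lower; %s non-significant of %d\n",
    n_larger, n_lower, n_ns, n_total)))
  invisible(x)
}

#' @export
summary.sync_comparison <- function(object, ...) {
  c(object$counts, list(alpha = object$params$alpha))
}
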