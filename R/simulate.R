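#' Template for one activity cycle of a bursting neuron
#'
#' Describes one cycle of the rhythm as a piecewise-linear trapezoid: a
#' linear ramp-up from baseline to the plateau, a flat plateau on which
#' spikes ride, a linear ramp-down back to baseline, and a silent phase for
#' the remainder of the period. Spikes are brief triangular deflections at
#' Poisson times on the plateau — their shape is irrelevant to the slope
#' method, only their amplitude regime matters (plateau-dominant,
#' `plateau_height >> spike_amplitude`, versus spike-dominant,
#' `spike_amplitude >> plateau_height`).
#'
#' Defaults describe a pyloric-like rhythm: 1000 ms period, 100 ms ramps,
#' 300 ms plateau, unit plateau height with 0.2-amplitude spikes at 30 Hz.
#'
#' @param period cycle period in ms.
#' @param ramp_up,plateau,ramp_down phase durations in ms; their sum must
#'   not exceed `period`.
#' @param baseline,plateau_height amplitudes (arbitrary units).
#' @param spike_amplitude spike height above the plateau (0 for none).
#' @param spike_rate expected spikes per ms of plateau (default 0.03,
#'   i.e. 30 Hz).
#' @param spike_width full width of the triangular spike in ms.
#' @return an object of class `cycle_template`.
#' @export
cycle_template <- function(period = 1000, ramp_up = 100, plateau = 300,
                           ramp_down = 100, baseline = 0, plateau_height = 1,
                           spike_amplitude = 0.2, spike_rate = 0.03,
                           spike_width = 6) {
  if (any(c(period, ramp_up, plateau, ramp_down, spike_width) <= 0))
    stop("all durations must be positive", call. = FALSE)
  if (ramp_up + plateau + ramp_down > period)
    stop("ramp_up + plateau + ramp_down must not exceed the period",
         call. = FALSE)
  if (spike_amplitude < 0 || spike_rate < 0)
    stop("spike_amplitude and spike_rate must be nonnegative", call. = FALSE)
  structure(
    list(period = period, ramp_up = ramp_up, plateau = plateau,
         ramp_down = ramp_down, baseline = baseline,
         plateau_height = plateau_height, spike_amplitude = spike_amplitude,
         spike_rate = spike_rate, spike_width = spike_width),
    class = "cycle_template")
}

#' @export
print.cycle_template <- function(x, ...) {
  cat(sprintf(
    "<cycle_template> period %g ms: ramp-up %g / plateau %g / ramp-down %g ms\n",
    x$period, x$ramp_up, x$plateau, x$ramp_down))
  cat(sprintf("  baseline %g, plateau height %g, spikes %g @ %g/ms (width %g ms)\n",
              x$baseline, x$plateau_height, x$spike_amplitude, x$spike_rate,
              x$spike_width))
  invisible(x)
}

#' Generate a synthetic bursting trace with exact ground truth
#'
#' Renders `n_cycles` repetitions of a [cycle_template()] onto a uniform
#' sample grid, optionally adds plateau spikes and additive i.i.d. Gaussian
#' measurement noise, and records the exact ground-truth feature times: the
#' ramp-up midpoint, plateau begin, plateau end and ramp-down midpoint of
#' every cycle (0-based sample indices).
#'
#' @param template a [cycle_template()].
#' @param n_cycles number of cycles (default 60, within the 50-80 cycles a
#'   typical recording contains).
#' @param noise_sigma SD of the additive Gaussian noise (same units as the
#'   amplitudes; 0 for a noise-free trace).
#' @param sampling_interval ms per sample (default 1.5).
#' @param seed integer seed; required whenever the trace is stochastic
#'   (noise or spikes). Pass `NA` to draw from the current RNG state instead
#'   (used internally by [generate_population()], which seeds once).
#' @param cycle_starts optional numeric vector of cycle start times in ms
#'   (overrides the regular grid `k * period`; used by
#'   [generate_population()] to impose phase offsets and per-cycle jitter).
#' @param n_samples optional total trace length in samples (defaults to
#'   `round(n_cycles * period / sampling_interval)`).
#' @param neuron_id label for the generated trace.
#' @return list with `trace` (a [trace()]) and `truth` (data frame: `cycle`,
#'   `t_rampup_mid`, `t_plateau_begin`, `t_plateau_end`, `t_rampdown_mid`,
#'   `start_ms`).
#' @examples
#' sim <- generate_trace(cycle_template(), n_cycles = 3, seed = 1)
#' sim$truth
#' @export
generate_trace <- function(template, n_cycles = 60, noise_sigma = 0,
                           sampling_interval = 1.5, seed = NULL,
                           cycle_starts = NULL, n_samples = NULL,
                           neuron_id = "sim") {
  stopifnot(inherits(template, "cycle_template"))
  if (is.null(seed) && (noise_sigma > 0 ||
                        (template$spike_amplitude > 0 && template$spike_rate > 0)))
    stop("a seed is required for stochastic traces", call. = FALSE)
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  dt <- sampling_interval
  if (is.null(cycle_starts))
    cycle_starts <- (seq_len(n_cycles) - 1) * template$period
  n_cycles <- length(cycle_starts)
  n <- n_samples %||% round(n_cycles * template$period / dt)
  t_ms <- (seq_len(n) - 1) * dt
  x <- rep(template$baseline, n)
  ru <- template$ramp_up; pl <- template$plateau; rd <- template$ramp_down
  h <- template$plateau_height
  for (s in cycle_starts) {
    i1 <- max(1L, ceiling(s / dt) + 1L)
    i2 <- min(n, floor((s + ru + pl + rd) / dt) + 1L)
    if (i1 > i2) next
    rel <- t_ms[i1:i2] - s
    dep <- ifelse(rel < ru, h * rel / ru,
                  ifelse(rel <= ru + pl, h,
                         h * (1 - (rel - ru - pl) / rd)))
    seg <- i1:i2
    x[seg] <- pmax(x[seg], template$baseline + dep)
  }
  if (template$spike_amplitude > 0 && template$spike_rate > 0) {
    half <- template$spike_width / 2
    for (s in cycle_starts) {
      k <- stats::rpois(1, template$spike_rate * pl)
      if (k == 0) next
      st <- s + ru + sort(stats::runif(k, 0, pl))
      for (ts in st) {
        i1 <- max(1L, ceiling((ts - half) / dt) + 1L)
        i2 <- min(n, floor((ts + half) / dt) + 1L)
        if (i1 > i2) next
        bump <- template$spike_amplitude *
          pmax(0, 1 - abs(t_ms[i1:i2] - ts) / half)
        x[i1:i2] <- x[i1:i2] + bump
      }
    }
  }
  if (noise_sigma > 0) x <- x + stats::rnorm(n, sd = noise_sigma)
  truth <- data.frame(
    cycle = seq_len(n_cycles),
    t_rampup_mid = round((cycle_starts + ru / 2) / dt),
    t_plateau_begin = round((cycle_starts + ru) / dt),
    t_plateau_end = round((cycle_starts + ru + pl) / dt),
    t_rampdown_mid = round((cycle_starts + ru + pl + rd / 2) / dt),
    start_ms = cycle_starts)
  list(trace = trace(x, sampling_interval = dt, neuron_id = neuron_id),
       truth = truth)
}

#' Configuration of a simulated multi-neuron rhythm
#'
#' Describes a population of neurons sharing one rhythm: each neuron is a
#' phase-offset copy of the template whose cycle `k` starts at
#' `k * period + offset_i + Normal(0, jitter_sd_i)`. Independent per-cycle
#' Gaussian timing jitter models imperfect phase locking; scaling it up
#' (see [make_condition_pair()]) emulates neuromodulator-induced
#' de-synchronisation. Measurement noise is independent across neurons.
#'
#' @param n_neurons number of neurons (default 3, as identified per
#'   preparation in typical recordings).
#' @param template a [cycle_template()].
#' @param n_cycles cycles per neuron (default 60).
#' @param phase_offsets per-neuron phase offsets in ms (default
#'   `20 * (0:(n_neurons-1))`, small offsets within the rhythm).
#' @param jitter_sd per-cycle timing jitter SD in ms, scalar or per-neuron
#'   (default 6 ms, about 1 percent of the period).
#' @param noise_sigma additive measurement-noise SD (default 0.02, i.e. 2
#'   percent of the default plateau height).
#' @param sampling_interval ms per sample.
#' @param seed integer seed (mandatory: the population is stochastic).
#' @return an object of class `population_config`.
#' @export
population_config <- function(n_neurons = 3L, template = cycle_template(),
                              n_cycles = 60L, phase_offsets = NULL,
                              jitter_sd = 6, noise_sigma = 0.02,
                              sampling_interval = 1.5, seed) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory for reproducibility", call. = FALSE)
  n_neurons <- as.integer(n_neurons)
  stopifnot(n_neurons >= 1L, inherits(template, "cycle_template"))
  phase_offsets <- phase_offsets %||% (20 * (seq_len(n_neurons) - 1))
  jitter_sd <- rep_len(jitter_sd, n_neurons)
  phase_offsets <- rep_len(phase_offsets, n_neurons)
  if (any(jitter_sd < 0)) stop("jitter_sd must be nonnegative", call. = FALSE)
  structure(
    list(n_neurons = n_neurons, template = template,
         n_cycles = as.integer(n_cycles), phase_offsets = phase_offsets,
         jitter_sd = jitter_sd, noise_sigma = noise_sigma,
         sampling_interval = sampling_interval, seed = as.integer(seed)),
    class = "population_config")
}

#' Generate a multi-neuron rhythm dataset
#'
#' Realises a [population_config()]: each neuron gets its own jittered,
#' phase-offset cycle-start sequence and independent measurement noise, and
#' the exact ground-truth feature times of every neuron and cycle are
#' retained, so true pairwise delays are derivable exactly.
#'
#' @param config a [population_config()].
#' @return an object of class `population`: list with `traces` (named list
#'   of [trace()]s), `truth` (named list of ground-truth data frames) and
#'   `config`.
#' @examples
#' pop <- generate_population(population_config(n_neurons = 2, n_cycles = 5,
#'                                              seed = 42))
#' names(pop$traces)
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  tpl <- config$template
  dt <- config$sampling_interval
  n_samples <- round(config$n_cycles * tpl$period / dt)
  ids <- sprintf("PY%d", seq_len(config$n_neurons))
  traces <- vector("list", config$n_neurons)
  truth <- vector("list", config$n_neurons)
  for (i in seq_len(config$n_neurons)) {
    starts <- (seq_len(config$n_cycles) - 1) * tpl$period +
      config$phase_offsets[i] +
      stats::rnorm(config$n_cycles, sd = config$jitter_sd[i])
    sim <- generate_trace(tpl, noise_sigma = config$noise_sigma,
                          sampling_interval = dt, cycle_starts = starts,
                          n_samples = n_samples, neuron_id = ids[i],
                          seed = NA)  # population RNG already seeded
    traces[[i]] <- sim$trace
    truth[[i]] <- sim$truth
  }
  names(traces) <- ids
  names(truth) <- ids
  structure(list(traces = traces, truth = truth, config = config),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d neuron(s) x %d cycle(s), jitter SD %s ms, noise sigma %g\n",
              x$config$n_neurons, x$config$n_cycles,
              paste(format(x$config$jitter_sd), collapse = "/"),
              x$config$noise_sigma))
  invisible(x)
}

#' Matched control/treatment dataset pair
#'
#' Generates two populations identical in structure except that the
#' treatment condition has its per-cycle jitter SD multiplied by
#' `desync_factor` — the stand-in for neuromodulator exposure that relaxes
#' phase locking. Seeds for the two conditions are derived deterministically
#' from the configured base seed, so the pair is reproducible.
#'
#' @param config a [population_config()] describing the control condition.
#' @param desync_factor multiplier (>= 1) applied to `jitter_sd` in the
#'   treatment condition; `desync_factor = 2` gives a true delay-variance
#'   ratio of 4 between conditions.
#' @return list with `control` and `treatment` (both `population` objects).
#' @export
make_condition_pair <- function(config, desync_factor = 2) {
  stopifnot(inherits(config, "population_config"))
  if (desync_factor < 1)
    stop("desync_factor must be at least 1", call. = FALSE)
  derive <- function(k)  # stay inside 32-bit integer range
    as.integer((as.numeric(config$seed) * 2 + k) %% .Machine$integer.max)
  ctrl_cfg <- config
  ctrl_cfg$seed <- derive(1)
  trt_cfg <- config
  trt_cfg$jitter_sd <- config$jitter_sd * desync_factor
  trt_cfg$seed <- derive(2)
  list(control = generate_population(ctrl_cfg),
       treatment = generate_population(trt_cfg))
}
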