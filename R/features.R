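#' Slope-value acceptability bands
#'
#' Detected slope extrema are only accepted as genuine ramp midpoints when
#' their slope value falls inside an analyst-chosen band; extrema outside the
#' band are spurious (e.g. produced by spikes or by flat stretches of the
#' recording). A symmetric zero-value range `[-z*, z*]` additionally defines
#' which forward/backward slope values count as "near zero" when locating the
#' activity plateau.
#'
#' @param max_slope_band length-2 numeric `c(lo, hi)`, entirely positive:
#'   acceptable centered-slope values for maximum slope points.
#' @param min_slope_band length-2 numeric `c(lo, hi)`, entirely negative:
#'   acceptable centered-slope values for minimum slope points.
#' @param zero_range length-2 numeric, symmetric about 0: the `[-z*, z*]`
#'   band of near-zero forward/backward slopes.
#' @param epsilon small positive number used when deriving `zero_range` as
#'   `[-epsilon * m_max, epsilon * m_max]` (default 0.1).
#' @param m_max maximal absolute slope value over the accepted extrema
#'   (informational; filled in by [default_bands()]).
#' @return an object of class `acceptance_bands`.
#' @seealso [default_bands()] for the data-driven construction.
#' @export
acceptance_bands <- function(max_slope_band, min_slope_band, zero_range,
                             epsilon = 0.1, m_max = NA_real_) {
  stopifnot(length(max_slope_band) == 2L, length(min_slope_band) == 2L,
            length(zero_range) == 2L)
  if (!(epsilon > 0))
    stop("epsilon must be positive", call. = FALSE)
  if (!(max_slope_band[1] > 0) || max_slope_band[2] < max_slope_band[1])
    stop("max_slope_band must be an entirely positive interval", call. = FALSE)
  if (!(min_slope_band[2] < 0) || min_slope_band[1] > min_slope_band[2])
    stop("min_slope_band must be an entirely negative interval", call. = FALSE)
  if (abs(zero_range[1] + zero_range[2]) > 1e-12 * max(abs(zero_range), 1) ||
      zero_range[2] < 0)
    stop("zero_range must be symmetric about 0", call. = FALSE)
  structure(
    list(max_slope_band = as.numeric(max_slope_band),
         min_slope_band = as.numeric(min_slope_band),
         zero_range = as.numeric(zero_range),
         epsilon = as.numeric(epsilon),
         m_max = as.numeric(m_max)),
    class = "acceptance_bands")
}

#' @export
print.acceptance_bands <- function(x, ...) {
  cat("<acceptance_bands>\n")
  cat(sprintf("  max-slope band  [%.4g, %.4g]\n",
              x$max_slope_band[1], x$max_slope_band[2]))
  cat(sprintf("  min-slope band  [%.4g, %.4g]\n",
              x$min_slope_band[1], x$min_slope_band[2]))
  cat(sprintf("  zero range      [%.4g, %.4g] (epsilon = %.3g, m_max = %.4g)\n",
              x$zero_range[1], x$zero_range[2], x$epsilon, x$m_max))
  invisible(x)
}

#' Derive acceptability bands from a slope series
#'
#' Sets the maximum-slope band to `[fraction * max(m_t), Inf)` and the
#' minimum-slope band to `(-Inf, fraction * min(m_t)]`, takes `m_max` as the
#' largest absolute slope among the band-passing extrema, and derives the
#' zero-value range as `[-epsilon * m_max, epsilon * m_max]`.
#'
#' This rule is appropriate for the plateau-dominant regime where the ramp
#' slopes dominate everything else; in the spike-dominant regime the bands
#' must be supplied explicitly via [acceptance_bands()] after inspecting the
#' slope-value distribution case by case.
#'
#' @param slopes a [slope_series()].
#' @param epsilon small positive number for the zero range (default 0.1).
#' @param fraction band lower edge as a share of the global extreme slope,
#'   strictly between 0 and 1 (default 0.5).
#' @return an `acceptance_bands` object.
#' @examples
#' tr <- trace(rep(c(0, 0.5, 1, 1, 1, 0.5, 0, 0), 5))
#' default_bands(slope_series(tr, tau = 1))
#' @export
default_bands <- function(slopes, epsilon = 0.1, fraction = 0.5) {
  stopifnot(inherits(slopes, "slope_series"))
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  if (!(epsilon > 0))
    stop("epsilon must be positive", call. = FALSE)
  m <- slopes$centered
  if (all(is.na(m)) || all(abs(m) < .Machine$double.eps^0.75, na.rm = TRUE))
    stop("degenerate input: all slope values are zero", call. = FALSE)
  mx <- max(m, na.rm = TRUE)
  mn <- min(m, na.rm = TRUE)
  if (!(mx > 0) || !(mn < 0))
    stop("degenerate input: slope series lacks both rising and falling parts",
         call. = FALSE)
  m_max <- max(abs(c(mx, mn)))
  acceptance_bands(
    max_slope_band = c(fraction * mx, Inf),
    min_slope_band = c(-Inf, fraction * mn),
    zero_range = c(-epsilon * m_max, epsilon * m_max),
    epsilon = epsilon, m_max = m_max)
}

in_band <- function(v, band) !is.na(v) & v >= band[1] & v <= band[2]

new_salient_point <- function(kind, t, slope_value, valid = NA) {
  data.frame(kind = kind, t = as.integer(t),
             slope_value = as.numeric(slope_value), valid = valid,
             stringsAsFactors = FALSE)
}

check_interval <- function(slopes, T1, T2) {
  ok <- which(!is.na(slopes$centered)) - 1L  # 0-based valid indices
  if (length(ok) == 0L) stop("slope series has no valid values", call. = FALSE)
  if (!(T2 > T1))
    stop("detection interval must satisfy T2 > T1", call. = FALSE)
  if (T1 < min(ok) || T2 > max(ok))
    stop(sprintf("interval [%d, %d] extends outside the valid slope range [%d, %d]",
                 T1, T2, min(ok), max(ok)), call. = FALSE)
}

#' Maximum and minimum slope points on an interval
#'
#' `max_slope_point()` returns the time step `t*` attaining the maximum
#' centered slope on the interval `[T1, T2]`; `min_slope_point()` the time
#' step `t**` attaining the minimum. The maximum slope point estimates the
#' midpoint of a ramp-up phase, the minimum slope point the midpoint of a
#' ramp-down phase. Ties are broken by the earliest index. The `valid` flag
#' is left unset; apply [classify_points()] with acceptability bands to mark
#' spurious points.
#'
#' @param slopes a [slope_series()].
#' @param T1,T2 0-based sample indices delimiting the search interval,
#'   `T2 > T1`, both inside the valid range of the centered slope.
#' @return a one-row data frame with columns `kind`, `t` (0-based sample
#'   index), `slope_value`, `valid`.
#' @export
max_slope_point <- function(slopes, T1, T2) {
  stopifnot(inherits(slopes, "slope_series"))
  check_interval(slopes, T1, T2)
  idx <- (T1:T2) + 1L
  v <- slopes$centered[idx]
  k <- which.max(v)  # earliest on ties
  new_salient_point("max_slope", T1 + k - 1L, v[k])
}

#' @rdname max_slope_point
#' @export
min_slope_point <- function(slopes, T1, T2) {
  stopifnot(inherits(slopes, "slope_series"))
  check_interval(slopes, T1, T2)
  idx <- (T1:T2) + 1L
  v <- slopes$centered[idx]
  k <- which.min(v)
  new_salient_point("min_slope", T1 + k - 1L, v[k])
}

#' Mark salient points as valid or spurious
#'
#' A point is valid when its slope value lies inside the band matching its
#' kind: the maximum-slope band for `max_slope` points, the minimum-slope
#' band for `min_slope` points, and the zero-value range for plateau
#' begin/end points. All other fields are left unchanged.
#'
#' @param points a data frame of salient points (columns `kind`, `t`,
#'   `slope_value`, `valid`), as produced by [max_slope_point()] and friends.
#' @param bands an [acceptance_bands()] object.
#' @return the same data frame with the `valid` column filled in.
#' @export
classify_points <- function(points, bands) {
  stopifnot(inherits(bands, "acceptance_bands"))
  if (nrow(points) == 0L) return(points)
  band_for <- list(max_slope = bands$max_slope_band,
                   min_slope = bands$min_slope_band,
                   plateau_begin = bands$zero_range,
                   plateau_end = bands$zero_range)
  points$valid <- vapply(seq_len(nrow(points)), function(i) {
    b <- band_for[[points$kind[i]]]
    if (is.null(b)) stop("unknown salient point kind: ", points$kind[i],
                         call. = FALSE)
    in_band(points$slope_value[i], b)
  }, logical(1))
  points
}

# candidate extrema: runs are delimited by the band's inner edge (slope
# beyond fraction*extreme); within a run the candidate is the largest local
# extremum whose slope value lies inside the full band (earliest on ties).
# Monotone band crossings are not local extrema and spike-induced peaks
# overshoot a finite outer edge, so neither seeds a spurious candidate,
# while a genuine ramp extremum merged into the same run survives.
band_run_candidates <- function(m, band, take_max) {
  s <- if (take_max) m else -m
  b <- if (take_max) band else sort(-band)
  beyond <- !is.na(s) & s >= b[1]
  if (!any(beyond)) return(integer(0))
  r <- rle(beyond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    v <- s[idx]
    nl <- length(v)
    locext <- v >= c(-Inf, v[-nl]) & v >= c(v[-1], -Inf)
    ok <- locext & v <= b[2]
    if (any(ok)) out <- c(out, idx[ok][which.max(v[ok])])
  }
  out
}

#' Detect activity cycles over a whole recording
#'
#' Generalises the single-interval extremum search to an entire slope
#' series. Maximal contiguous runs where the centered slope exceeds the
#' inner edge of the maximum-slope band (resp. falls below the inner edge of
#' the minimum-slope band) each contribute at most one candidate point: the
#' largest local extremum inside the run whose slope value lies in the full
#' band, earliest on ties. Candidates whose extremum overshoots a finite
#' outer band edge are spurious (typically spike-induced) and are dropped,
#' as are monotone band crossings, which are not local extrema. Alternating
#' max -> min candidates are then paired into activity cycles; unpaired
#' leading or trailing candidates are discarded, as are later max candidates
#' arriving before a min closes the open cycle. The procedure is
#' deterministic.
#'
#' @param slopes a [slope_series()].
#' @param bands an [acceptance_bands()] object.
#' @return an object of class `activity_cycles`: a data frame with one row
#'   per cycle and columns `cycle`, `t_max`, `slope_max`, `t_min`,
#'   `slope_min`, `t_begin`, `t_end`, `plateau_undetermined` (plateau columns
#'   are `NA` until [plateau_bounds()] is applied). Sample indices are
#'   0-based. An empty data frame (zero rows) if no candidate runs exist.
#' @export
detect_cycles <- function(slopes, bands) {
  stopifnot(inherits(slopes, "slope_series"),
            inherits(bands, "acceptance_bands"))
  m <- slopes$centered
  imax <- band_run_candidates(m, bands$max_slope_band, take_max = TRUE)
  imin <- band_run_candidates(m, bands$min_slope_band, take_max = FALSE)
  cand_t <- c(imax, imin)
  cand_kind <- rep(c("max", "min"), c(length(imax), length(imin)))
  o <- order(cand_t)
  cand_t <- cand_t[o]; cand_kind <- cand_kind[o]
  t_max <- integer(0); t_min <- integer(0)
  pending <- NA_integer_
  for (i in seq_along(cand_t)) {
    if (cand_kind[i] == "max") {
      if (is.na(pending)) pending <- cand_t[i]  # keep earliest open max
    } else if (!is.na(pending)) {
      t_max <- c(t_max, pending); t_min <- c(t_min, cand_t[i])
      pending <- NA_integer_
    }  # leading min candidates (no open max) are discarded
  }
  cycles <- data.frame(
    cycle = seq_along(t_max),
    t_max = t_max - 1L, slope_max = m[t_max],
    t_min = t_min - 1L, slope_min = m[t_min],
    t_begin = rep(NA_integer_, length(t_max)),
    t_end = rep(NA_integer_, length(t_max)),
    plateau_undetermined = rep(NA, length(t_max)))
  attr(cycles, "tau") <- slopes$tau
  attr(cycles, "sampling_interval") <- slopes$sampling_interval
  attr(cycles, "neuron_id") <- slopes$neuron_id
  class(cycles) <- c("activity_cycles", "data.frame")
  cycles
}

#' Estimate activity-plateau begin and end points
#'
#' Using the zero-value range `[-z*, z*]`, forms the sets of time steps with
#' near-zero forward slope and near-zero backward slope. For each cycle the
#' plateau begin is the first near-zero-forward-slope step after the maximum
#' slope point, and the plateau end is the last near-zero-backward-slope step
#' before the minimum slope point. Cycles for which either bound is missing,
#' or for which the ordering `t* < t_begin <= t_end < t**` fails, are flagged
#' plateau-undetermined with both bounds absent; their max/min slope points
#' remain usable for downstream delay analysis.
#'
#' @param slopes a [slope_series()] (supplies the forward/backward series).
#' @param cycles an `activity_cycles` data frame from [detect_cycles()], or
#'   any data frame with `t_max`/`t_min` columns (0-based).
#' @param bands an [acceptance_bands()] with the zero-value range.
#' @return `cycles` with `t_begin`, `t_end` and `plateau_undetermined`
#'   filled in.
#' @export
plateau_bounds <- function(slopes, cycles, bands) {
  stopifnot(inherits(slopes, "slope_series"),
            inherits(bands, "acceptance_bands"))
  if (nrow(cycles) == 0L) return(cycles)
  if (any(cycles$t_max >= cycles$t_min))
    stop("each cycle must have its maximum slope point before its minimum",
         call. = FALSE)
  zr <- bands$zero_range
  t_zf <- which(in_band(slopes$forward, zr)) - 1L   # 0-based
  t_zb <- which(in_band(slopes$backward, zr)) - 1L
  for (i in seq_len(nrow(cycles))) {
    ts <- cycles$t_max[i]; te <- cycles$t_min[i]
    beg <- t_zf[t_zf > ts]
    beg <- if (length(beg)) min(beg) else NA_integer_
    end <- t_zb[t_zb < te]
    end <- if (length(end)) max(end) else NA_integer_
    ok <- !is.na(beg) && !is.na(end) && ts < beg && beg <= end && end < te
    if (ok) {
      cycles$t_begin[i] <- beg
      cycles$t_end[i] <- end
      cycles$plateau_undetermined[i] <- FALSE
    } else {
      cycles$t_begin[i] <- NA_integer_
      cycles$t_end[i] <- NA_integer_
      cycles$plateau_undetermined[i] <- TRUE
    }
  }
  cycles
}

#' @export
print.activity_cycles <- function(x, ...) {
  cat(sprintf("<activity_cycles> neuron '%s': %d cycle(s), tau = %s\n",
              attr(x, "neuron_id") %||% "?", nrow(x),
              format(attr(x, "tau") %||% NA)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full single-neuron feature detection
#'
#' Convenience pipeline: smooth the trace, compute the slope series, derive
#' (or accept) acceptability bands, detect cycles and estimate plateau
#' bounds.
#'
#' @inheritParams slope_series
#' @param smoothing a [smoothing_spec()], a plain window length, or `NULL`
#'   to skip smoothing.
#' @param bands an [acceptance_bands()], or `NULL` to derive them with
#'   [default_bands()].
#' @param epsilon,fraction passed to [default_bands()] when `bands` is NULL.
#' @return an `activity_cycles` data frame with plateau bounds; the slope
#'   series and bands used are attached as attributes `slopes` and `bands`.
#' @examples
#' sim <- generate_trace(cycle_template(), n_cycles = 5, seed = 1)
#' cyc <- detect_features(sim$trace, tau = 30)
#' nrow(cyc)
#' @export
detect_features <- function(tr, tau, smoothing = smoothing_spec(),
                            bands = NULL, epsilon = 0.1, fraction = 0.5) {
  tr <- as_trace(tr)
  if (!is.null(smoothing)) tr <- smooth_trace(tr, smoothing)
  sl <- slope_series(tr, tau)
  if (is.null(bands)) bands <- default_bands(sl, epsilon = epsilon,
                                             fraction = fraction)
  cyc <- detect_cycles(sl, bands)
  cyc <- plateau_bounds(sl, cyc, bands)
  attr(cyc, "slopes") <- sl
  attr(cyc, "bands") <- bands
  cyc
}

#' Long-format salient-point table for one neuron
#'
#' Flattens an `activity_cycles` data frame into one row per salient point,
#' with times in both samples and milliseconds — the delimited-text feature
#' table written by the pipeline.
#'
#' @param cycles an `activity_cycles` data frame.
#' @param neuron_id label override (defaults to the one recorded on `cycles`).
#' @param sampling_interval ms per sample (defaults likewise).
#' @return data frame with columns `neuron_id`, `cycle_index`, `kind`,
#'   `t_samples`, `t_ms`, `slope_value`, `valid`.
#' @export
feature_table <- function(cycles, neuron_id = NULL, sampling_interval = NULL) {
  neuron_id <- neuron_id %||% attr(cycles, "neuron_id") %||% "neuron"
  dt <- sampling_interval %||% attr(cycles, "sampling_interval") %||% 1.5
  if (nrow(cycles) == 0L)
    return(data.frame(neuron_id = character(), cycle_index = integer(),
                      kind = character(), t_samples = integer(),
                      t_ms = numeric(), slope_value = numeric(),
                      valid = logical(), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(cycles)), function(i) {
    r <- cycles[i, ]
    out <- data.frame(
      kind = c("max_slope", "min_slope", "plateau_begin", "plateau_end"),
      t_samples = c(r$t_max, r$t_min, r$t_begin, r$t_end),
      slope_value = c(r$slope_max, r$slope_min, NA_real_, NA_real_),
      stringsAsFactors = FALSE)
    out <- out[!is.na(out$t_samples), , drop = FALSE]
    out$cycle_index <- r$cycle
    out
  })
  tab <- do.call(rbind, rows)
  tab$neuron_id <- neuron_id
  tab$t_ms <- tab$t_samples * dt
  tab$valid <- TRUE
  tab <- tab[order(tab$t_samples),
             c("neuron_id", "cycle_index", "kind", "t_samples", "t_ms",
               "slope_value", "valid")]
  rownames(tab) <- NULL
  tab
}
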