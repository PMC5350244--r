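#' Windowed least-squares slope series of a trace
#'
#' For each time step `t` the centered local slope `m_t` is the slope of the
#' ordinary least-squares line fitted to the `2*tau + 1` samples in the window
#' `[t - tau, t + tau]`. Because the window is symmetric, the estimator has
#' the closed form
#' \deqn{m_t = \frac{3}{\tau(\tau+1)(2\tau+1)} \sum_{u=t-\tau}^{t+\tau} (u-t)\, x_u,}
#' a linear filter that is evaluated here by discrete convolution.
#'
#' The forward slope `m_t^f` is the least-squares slope over the window
#' `[t, t + 2*tau]` (the fit "starting from" `t`), and the backward slope
#' `m_t^b` over `[t - 2*tau, t]`. Both are shifted copies of the centered
#' series: `m_t^f = m_{t+tau}` and `m_t^b = m_{t-tau}`.
#'
#' Positions where a full window does not fit inside the trace are flagged
#' `NA` (missing); they are never zero-filled, since padding would fabricate
#' spurious slope extrema at the trace edges.
#'
#' @param tr a [trace()] object or numeric vector.
#' @param tau positive integer half-window; the window spans `2*tau + 1`
#'   samples. Choose `tau` about half the ramp duration (in samples) or
#'   slightly less.
#' @return an object of class `slope_series`: a list with elements `tau`,
#'   `centered`, `forward`, `backward` (numeric vectors of the trace length
#'   with `NA` outside the valid range), `n`, `sampling_interval`,
#'   `neuron_id`. Slopes are in activity units per sample.
#' @examples
#' tr <- trace(3 * (0:20) + 7)
#' s <- slope_series(tr, tau = 4)
#' unique(round(s$centered[!is.na(s$centered)], 12))  # exactly 3
#' @seealso [centered_slope()], [forward_slope()], [backward_slope()]
#' @export
slope_series <- function(tr, tau) {
  tr <- as_trace(tr)
  tau <- as.integer(tau)
  if (is.na(tau) || tau < 1L)
    stop("tau must be a positive integer", call. = FALSE)
  x <- tr$values
  n <- length(x)
  if (n < 2L * tau + 1L)
    stop(sprintf("trace has %d samples; need at least 2*tau + 1 = %d",
                 n, 2L * tau + 1L), call. = FALSE)
  coefs <- 3 / (tau * (tau + 1) * (2 * tau + 1)) * seq(tau, -tau)
  centered <- as.numeric(stats::filter(x, coefs, method = "convolution",
                                       sides = 2))
  # forward/backward are the centered slope of the shifted window midpoint
  forward <- c(centered[(1L + tau):n], rep(NA_real_, tau))
  backward <- c(rep(NA_real_, tau), centered[seq_len(n - tau)])
  structure(
    list(tau = tau, centered = centered, forward = forward,
         backward = backward, n = n,
         sampling_interval = tr$sampling_interval,
         neuron_id = tr$neuron_id),
    class = "slope_series")
}

#' @export
print.slope_series <- function(x, ...) {
  rng <- range(x$centered, na.rm = TRUE)
  cat(sprintf(
    "<slope_series> neuron '%s': n = %d, tau = %d (window %d samples)\n",
    x$neuron_id, x$n, x$tau, 2L * x$tau + 1L))
  cat(sprintf("  centered slope range [%.4g, %.4g] per sample\n",
              rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.slope_series <- function(x, which = c("centered", "forward", "backward"),
                              ...) {
  which <- match.arg(which)
  t_ms <- (seq_len(x$n) - 1) * x$sampling_interval
  plot(t_ms, x[[which]], type = "l", xlab = "time (ms)",
       ylab = sprintf("%s slope (a.u./sample)", which),
       main = x$neuron_id, ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Centered, forward and backward local slopes
#'
#' Convenience accessors computing one slope variant; see [slope_series()]
#' for definitions and the closed form. Each returns a numeric vector of the
#' trace length with `NA` at positions where the window does not fit:
#' `centered` is defined for `tau <= t <= T-1-tau`, `forward` for
#' `t <= T-1-2*tau` and `backward` for `t >= 2*tau` (0-based indices).
#'
#' @inheritParams slope_series
#' @return numeric vector of local slopes (activity units per sample).
#' @export
centered_slope <- function(tr, tau) slope_series(tr, tau)$centered

#' @rdname centered_slope
#' @export
forward_slope <- function(tr, tau) slope_series(tr, tau)$forward

#' @rdname centered_slope
#' @export
backward_slope <- function(tr, tau) slope_series(tr, tau)$backward
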