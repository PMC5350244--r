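#' Analytic noise level of the windowed slope estimator
#'
#' With additive i.i.d. Gaussian measurement noise of standard deviation
#' `sigma`, the noise component of the centered least-squares slope over a
#' `2*tau + 1` window is Gaussian with mean zero and standard deviation
#' \deqn{\sigma_\mu = \sigma \sqrt{\frac{3}{\tau(\tau+1)(2\tau+1)}},}
#' obtained from the closed-form estimator and the identity
#' \eqn{\sum_{u=-\tau}^{\tau} u^2 = \tau(\tau+1)(2\tau+1)/3}. (Some
#' presentations print the denominator as `2*tau + 2`; the derivation above
#' gives `2*tau + 1`, which Monte-Carlo simulation confirms — see
#' [slope_noise_mc()].)
#'
#' @param sigma nonnegative noise standard deviation (activity units).
#' @param tau positive integer half-window.
#' @return the slope-noise standard deviation (activity units per sample).
#' @examples
#' slope_noise_sd(1, 5)            # sqrt(3/330) ~ 0.0953
#' mean_noise_sd(1, 5)             # 1/sqrt(11)  ~ 0.3015
#' robustness_ratio(5)             # sqrt(3/30)  ~ 0.316 < 1
#' @export
slope_noise_sd <- function(sigma, tau) {
  check_noise_model(sigma, tau)
  sigma * sqrt(3 / (tau * (tau + 1) * (2 * tau + 1)))
}

#' Analytic noise level of the local-average comparator
#'
#' The `2*tau + 1`-point local average, the natural baseline statistic for
#' spike detection, carries noise of standard deviation
#' `sigma / sqrt(2*tau + 1)`.
#'
#' @inheritParams slope_noise_sd
#' @return the local-average noise standard deviation (activity units).
#' @export
mean_noise_sd <- function(sigma, tau) {
  check_noise_model(sigma, tau)
  sigma / sqrt(2 * tau + 1)
}

#' Relative robustness of slope versus local average
#'
#' Ratio of the slope-noise SD to the local-average noise SD,
#' `sqrt(3 / (tau * (tau + 1)))`, independent of `sigma`. It is below 1 for
#' every `tau > 1` — the slope estimate is then the more noise-robust
#' statistic — and above 1 only at `tau = 1`.
#'
#' @param tau positive integer half-window.
#' @return the (dimensionless) noise-SD ratio.
#' @export
robustness_ratio <- function(tau) {
  check_noise_model(0, tau)
  sqrt(3 / (tau * (tau + 1)))
}

check_noise_model <- function(sigma, tau) {
  if (!is.numeric(sigma) || any(sigma < 0) || any(!is.finite(sigma)))
    stop("sigma must be nonnegative and finite", call. = FALSE)
  if (!is.numeric(tau) || any(tau < 1) || any(tau != round(tau)))
    stop("tau must be a positive integer", call. = FALSE)
  invisible(TRUE)
}

#' Monte-Carlo check of the slope-noise model
#'
#' Draws `reps` independent Gaussian noise windows of length `2*tau + 1`,
#' applies the closed-form slope estimator to each and summarises the
#' empirical distribution of the resulting slope noise.
#'
#' @inheritParams slope_noise_sd
#' @param reps number of independent windows (default 1e5).
#' @param seed optional integer seed for reproducibility.
#' @return list with `sd` (empirical SD), `mean` (empirical mean),
#'   `se_mean` (Monte-Carlo standard error of the mean), `analytic_sd`,
#'   `reps`.
#' @export
slope_noise_mc <- function(sigma, tau, reps = 1e5, seed = NULL) {
  check_noise_model(sigma, tau)
  if (!is.null(seed)) set.seed(seed)
  w <- 3 / (tau * (tau + 1) * (2 * tau + 1)) * seq(-tau, tau)
  z <- matrix(stats::rnorm(reps * (2 * tau + 1), sd = sigma),
              nrow = reps)
  mu <- as.numeric(z %*% w)
  list(sd = stats::sd(mu), mean = mean(mu),
       se_mean = stats::sd(mu) / sqrt(reps),
       analytic_sd = slope_noise_sd(sigma, tau), reps = reps)
}

#' Analytic versus empirical noise table over a parameter grid
#'
#' Convenience grid used by the `noise-check` command-line subcommand.
#'
#' @param taus integer vector of half-windows.
#' @param sigmas numeric vector of noise SDs.
#' @param reps Monte-Carlo windows per cell.
#' @param seed integer seed.
#' @return data frame with columns `tau`, `sigma`, `analytic_sd`,
#'   `empirical_sd`, `mean_noise_sd`, `robustness_ratio`.
#' @export
noise_check_grid <- function(taus = c(2, 3, 5, 10, 20), sigmas = c(0.1, 1),
                             reps = 1e5, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(tau = taus, sigma = sigmas)
  grid$analytic_sd <- slope_noise_sd(grid$sigma, grid$tau)
  grid$empirical_sd <- vapply(seq_len(nrow(grid)), function(i)
    slope_noise_mc(grid$sigma[i], grid$tau[i], reps = reps)$sd, numeric(1))
  grid$mean_noise_sd <- mean_noise_sd(grid$sigma, grid$tau)
  grid$robustness_ratio <- robustness_ratio(grid$tau)
  grid
}
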