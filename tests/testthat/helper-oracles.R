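# Independent oracles used across the suite.

# Brute-force ordinary-least-squares slope of x over 1-based indices lo:hi,
# fitted as a line in the sample index. Independent of the package's
# convolution implementation.
ols_slope <- function(x, lo, hi) {
  u <- lo:hi
  unname(stats::coef(stats::lm(x[u] ~ u))[2])
}

# Centered slope series computed entirely via the brute-force oracle
# (NA where the window does not fit).
ols_centered <- function(x, tau) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in (tau + 1):(n - tau)) out[t] <- ols_slope(x, t - tau, t + tau)
  out
}

# Two-sided F-test p-value by numerical integration of the F density,
# independent of pf().
f_p_numint <- function(f, df1, df2) {
  lower <- stats::integrate(stats::df, 0, f, df1 = df1, df2 = df2,
                            rel.tol = 1e-10)$value
  min(1, 2 * min(lower, 1 - lower))
}

# A deterministic trapezoid-train fixture used by feature tests.
trapezoid_sim <- function(n_cycles = 5, noise_sigma = 0, seed = NULL,
                          spike_amplitude = 0, ...) {
  tpl <- cycle_template(spike_amplitude = spike_amplitude, ...)
  generate_trace(tpl, n_cycles = n_cycles, noise_sigma = noise_sigma,
                 seed = seed)
}
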