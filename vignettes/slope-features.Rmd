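---
title: "Slope-based feature extraction and de-synchronisation analysis of optical imaging traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slope-based feature extraction and de-synchronisation analysis of optical imaging traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdtrace)
```

## The problem

Voltage-sensitive dye (VSD) imaging records the membrane-potential dynamics
of many neurons simultaneously in physiologically valid settings — for
example several pyloric constrictor (PY) neurons of the crustacean
stomatogastric ganglion at once — but the fluorescence traces are noisy
enough that individual spikes cannot be detected reliably. Spike times are
therefore a poor basis for quantifying how the temporal relationship between
neurons changes, e.g. whether a neuromodulator de-synchronises a pair of
neurons that normally fire in lock-step.

Bursting neurons, however, offer more robust landmarks than spikes. Their
activity follows a stereotyped cycle: a ramp-up of the membrane potential, a
depolarisation plateau on which the spikes ride, a ramp-down, and a silent
phase. This package extracts four salient points per cycle —

* the **maximum slope point** `t*` (midpoint of the ramp-up, a burst-onset
  proxy),
* the **minimum slope point** `t**` (midpoint of the ramp-down, a
  burst-offset proxy),
* the **plateau begin** `t_b0` and **plateau end** `t_e0`,

and quantifies synchronisation between neuron pairs through the statistics
of the temporal delays between corresponding salient points.

## The slope estimator

All four landmarks derive from windowed least-squares slopes of the
(smoothed) trace $x_t$. For a half-window of $\tau$ samples, the centered
local slope is the slope of the ordinary least-squares line through the
$2\tau + 1$ samples around $t$. Because the window is symmetric, it has the
closed form

$$m_t = \frac{3}{\tau(\tau+1)(2\tau+1)} \sum_{u=t-\tau}^{t+\tau} (u-t)\,x_u,$$

which the package evaluates as a linear convolution filter
(`centered_slope()`, `slope_series()`). The **forward** slope $m_t^f$ fits
the window $[t, t+2\tau]$ and the **backward** slope $m_t^b$ the window
$[t-2\tau, t]$; both are index-shifted copies of the centered series. The
maximum/minimum slope points are the extrema of $m_t$ on a detection
interval; the plateau begin is the first time after $t^*$ at which the
forward slope enters a near-zero band $[-z^*, z^*]$, and the plateau end the
last time before $t^{**}$ at which the backward slope is in that band.

Positions where a full window does not fit are reported as missing (`NA`),
never zero-filled: padding would fabricate slope extrema at the trace edges.

## Why slopes and not averages: the noise model

For additive i.i.d. Gaussian measurement noise of SD $\sigma$, the noise
component of $m_t$ is Gaussian, unbiased, with standard deviation

$$\sigma_\mu = \sigma\sqrt{\frac{3}{\tau(\tau+1)(2\tau+1)}},$$

versus $\sigma/\sqrt{2\tau+1}$ for the $(2\tau+1)$-point local average that
a spike-detection approach would use. Their ratio,
$\sqrt{3/(\tau(\tau+1))}$ (`robustness_ratio()`), is below 1 for every
$\tau > 1$: slope landmarks are intrinsically more noise-robust than
average-based ones, and increasingly so for wider windows.

A note on the derivation: one published statement of this result prints the
denominator of the variance as $\tau(\tau+1)(2\tau+2)$ in one place and
$(2\tau+1)$ in another. Applying
$\sum_{u=-\tau}^{\tau} u^2 = \tau(\tau+1)(2\tau+1)/3$ to the closed form
above gives $(2\tau+1)$ exactly; the package implements that form, and
`slope_noise_mc()` (Monte-Carlo over $10^5$ windows, exercised in the test
suite) confirms it to well under 1 %. The $(2\tau+2)$ variant appears to be
a typographical slip and is deliberately not implemented.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `sampling_interval` | 1.5 | ms | acquisition resolution (666 frames/s) |
| `smoothing.window` | 10 | samples | pre-smoothing of the raw trace |
| `tau` | user-set | samples | slope half-window; about half the ramp duration or slightly less |
| `fraction` | 0.5 | – | inner band edge as a share of the global extreme slope |
| `epsilon` | 0.1 | – | zero-range half-width as a share of `m_max` |
| `max_lag` | half median period | samples | matching window for pairing points across neurons |
| `alpha` | 0.05 | – | per-comparison F-test significance level |

`tau` is deliberately not defaulted: it must reflect the ramp duration of
the rhythm under study (`tau = ramp_duration / 2` in samples, or slightly
less). For the default simulated rhythm (100 ms ramps at 1.5 ms sampling,
i.e. 67 samples) `tau = 30` is appropriate.

There is no data-driven rule for the smoothing window; 10 samples is the
conventional choice at this acquisition rate and is applied identically
before all three slope variants (centered, forward, backward), so all
detected features see the same filtered trace.

## Spurious points and acceptability bands

Slope extrema also arise where no ramp exists (flat stretches, spikes).
Points are accepted only when their slope value falls inside an
analyst-chosen band (`acceptance_bands()`, `classify_points()`).

* **Plateau-dominant regime** (plateau depolarisation much larger than spike
  deflections): ramp slopes dominate, and `default_bands()` derives the
  bands automatically as `[fraction * max(m_t), Inf)` and
  `(-Inf, fraction * min(m_t)]` with `fraction = 0.5`, plus the zero range
  `[-0.1 m_max, 0.1 m_max]`.
* **Spike-dominant regime** (spikes much larger than the plateau): spike
  slopes exceed ramp slopes, so the band must be set case by case, narrow,
  and *bracketing* the ramp-slope magnitude (both edges finite). The test
  suite uses `[0.65, 1.35]` times the known ramp slope.

`detect_cycles()` generalises the single-interval extremum definition to a
whole recording: runs of slope values beyond the band's inner edge each
contribute at most one candidate — the largest local extremum inside the run
whose value lies within the full band, earliest on ties. Two consequences of
this design were chosen deliberately: monotone crossings of a finite band
(e.g. the flank of a spike-induced slope excursion) are not local extrema
and can never seed a candidate; and when a spike extremum merges into the
same run as a genuine ramp extremum, the ramp extremum (in band) is still
found while the spike peak (overshooting the band) is rejected. Candidate
maxima and minima are then paired by strict alternation: a cycle is a
max-candidate followed by the next min-candidate; leading minima, trailing
maxima, and later maxima arriving before the open cycle closes are
discarded. Detection is fully deterministic.

Plateau bounds additionally require the ordering
$t^* < t_b^0 \le t_e^0 < t^{**}$; cycles violating it (e.g. a triangle wave
with no flat top under a tight zero range) are flagged
`plateau_undetermined` and keep contributing their max/min slope points to
the delay analysis.

## Delay statistics and the de-synchronisation assay

For each neuron pair and each salient-point kind, `match_points()` pairs
points across neurons by greedy nearest-neighbour matching within
`max_lag` (each point used at most once; deterministic; robust to single
missed cycles — the matching rule itself is this package's choice, as no
canonical rule exists). `delay_stats()` reports the sample mean and SD
(n−1) of the matched delays: a small SD is phase locking; an SD increase
between conditions is de-synchronisation.

`f_test()` compares delay variances between conditions:
$F = s_t^2 / s_c^2$ with $(n_t-1, n_c-1)$ degrees of freedom, two-sided
($p = 2\min(P(F \le f), P(F \ge f))$, capped at 1). Two-sided is the
appropriate choice because both significant increases and decreases are
reported outcomes of the assay. No multiple-testing correction is applied
by default, matching the per-comparison $\alpha = 0.05$ convention; a
Bonferroni option exists in `run_sync_experiment()`.

`run_sync_experiment()` executes the whole workflow per pair and kind and
tabulates SDs, $F$, $p$, direction and significance; `count_significant()`
summarises. Applied to the published table of 44 F-test p-values from the
dopamine experiment on PY neuron pairs (`py_delay_pvalues()`), strict
`p < 0.05` counting gives 22 significant comparisons. (The accompanying
prose tallies 22 increases *plus* one decrease; the table's own
significance marking supports 22, and this package counts strictly.)

## The synthetic generator: what it emulates, and what not

`generate_trace()` renders cycles as piecewise-linear trapezoids with
optional triangular spikes at Poisson times on the plateau, plus i.i.d.
Gaussian noise — chosen over a biophysical (conductance-based) model so
that ground-truth corner and midpoint times are *exact*, which is what the
detector must be judged against. `generate_population()` makes each neuron
a phase-offset copy of the rhythm whose cycle $k$ starts at
$k \cdot P + \mathrm{offset}_i + \mathcal{N}(0, j_i)$; the per-cycle jitter
$j_i$ models imperfect phase locking, and `make_condition_pair()` scales it
by a de-synchronisation factor in the treatment condition.

Defaults state the intended world: 1.5 ms sampling, 1000 ms period with
100/300/100 ms ramp-up/plateau/ramp-down, 60 cycles per recording (within
the 50–80 a typical preparation yields), 2 % measurement noise, 6 ms jitter
(about 1 % of the period, realistic for a strongly coupled pyloric rhythm),
spikes of 0.2 amplitude at 30 Hz on a unit plateau. Noise levels spanning
1–10 % of the plateau height are used where a grid is needed, since VSD
noise magnitudes are not standardised.

What the generator does **not** emulate: slow baseline drift and bleaching,
correlated (shared) noise across neurons, spike-rate adaptation within the
plateau, cycle-to-cycle waveform changes, and synaptic coupling between the
simulated neurons (their jitters are independent). A green simulation test
therefore establishes correctness of the numerics and the stated
statistical behaviour under the model's assumptions — not performance on
every pathology of real recordings.

## Numerical choices

* Ties in arg-max/arg-min are broken by the earliest index (deterministic,
  order-stable).
* Smoothing is centered by default to avoid a systematic phase lag in
  feature times; a trailing mode exists for comparison.
* All computation is in 0-based sample indices; milliseconds appear only in
  reports (`sampling_interval` times samples).
* Event-triggered averaging truncates windows to the shortest window
  instead of resampling, avoiding interpolation artefacts.
* Degenerate inputs fail loudly: all-zero slope series, zero variance in
  both F-test samples, traces shorter than the window, unknown config keys.

## Known limitations

* Feature times are integer samples; no sub-sample interpolation is
  attempted.
* In the spike-dominant regime, automatic band derivation is not offered —
  the bands genuinely require case-by-case inspection, and densely
  overlapping spikes can in principle produce compound slope fluctuations
  inside any bracketing band.
* The matching rule and the whole-recording cycle detection generalise
  operations that are otherwise interval- and analyst-driven; both are
  documented choices rather than published prescriptions.
* The combined overall p-value sometimes quoted for the dopamine experiment
  has no described derivation and is not reproduced here.

## A worked example

```{r example, eval = FALSE}
library(vsdtrace)

pp <- make_condition_pair(
  population_config(n_neurons = 3, n_cycles = 60,
                    jitter_sd = 6, noise_sigma = 0.02, seed = 1),
  desync_factor = 2)
res <- run_sync_experiment(pp$control, pp$treatment, tau = 30)
res$counts
```

The treatment condition doubles the per-cycle jitter, so true delay SDs
scale by 2 (variance ratio 4); with about 60 matched cycles per pair the
F-test detects this in essentially every (pair, kind) cell, and `counts`
reports all comparisons as significantly "larger".
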