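# vsdtrace

Slope-based salient-point analysis of optical neuro-imaging traces, and
quantification of the dynamics of temporal relationships (phase locking /
de-synchronisation) between rhythmically bursting neurons.

## The problem

Voltage-sensitive dye imaging records many neurons at once — e.g. the
pyloric constrictor (PY) neurons of the crab stomatogastric ganglion — but
the traces are too noisy for reliable spike detection. Bursting neurons
offer sturdier landmarks: each activity cycle has a ramp-up, a
depolarisation plateau carrying the spikes, and a ramp-down. `vsdtrace`
extracts, per cycle,

* the **maximum slope point** `t*` — midpoint of the ramp-up (burst-onset proxy),
* the **minimum slope point** `t**` — midpoint of the ramp-down (burst-offset proxy),
* the **plateau begin/end** `t_b0`, `t_e0` — first/last near-zero
  forward/backward slope between them,

using the windowed least-squares slope

```
m_t = 3 / (tau (tau+1) (2 tau+1)) * sum_{u = t-tau}^{t+tau} (u - t) x_u
```

whose additive-noise SD, `sigma * sqrt(3 / (tau (tau+1) (2 tau+1)))`, is
smaller than that of a `(2 tau+1)`-point local average for every `tau > 1`
— the analytic basis for the method's robustness.

Synchronisation between two neurons is then quantified by the temporal
delays between corresponding salient points: the delay SD measures phase
locking, and a variance-ratio F-test (`F = s_treatment^2 / s_control^2`,
two-sided, per-comparison alpha 0.05) detects de-synchronisation between
conditions (e.g. before/after dopamine exposure).

The package also ships the analytic noise model with Monte-Carlo checks, a
trapezoid trace generator with exact ground truth (including per-cycle
phase jitter and a control/treatment "de-synchronisation" pair generator),
event-triggered averaging, delimited-text trace I/O, a key-value config
reader, and a CLI (`exec/vsdtrace`: `simulate`, `detect`, `sync`, `eta`,
`noise-check`).

## Worked example

Simulate a three-PY-neuron rhythm (1.5 ms sampling, 1 s period, 60 cycles,
6 ms per-cycle jitter) and a treatment condition with the jitter doubled,
then run the full pairwise analysis:

```r
library(vsdtrace)
pp <- make_condition_pair(
  population_config(n_neurons = 3, n_cycles = 60,
                    template = cycle_template(spike_amplitude = 0),
                    jitter_sd = 6, noise_sigma = 0.02, seed = 1),
  desync_factor = 2)
res <- run_sync_experiment(pp$control, pp$treatment, tau = 30)
res
```

```
<sync_comparison> 12 comparison(s), alpha = 0.05 (ms)
      pair          kind n_control n_treatment sd_control sd_treatment f_statistic   p_value direction significant
1  PY1:PY2     max_slope        60          60      8.082        17.52       4.697 1.544e-08    larger        TRUE
2  PY1:PY2     min_slope        60          60      8.651        17.31       4.002 3.186e-07    larger        TRUE
...
12 PY2:PY3   plateau_end        60          60      8.347        15.38       3.395 5.612e-06    larger        TRUE
significant: 12 larger, 0 lower; 0 non-significant of 12
```

Reading the numbers: with two independent 6 ms jitters the true control
delay SD is `sqrt(6^2 + 6^2) ~ 8.5 ms` (the `sd_control` column), doubling
the treatment jitter doubles it (`sd_treatment ~ 17 ms`, variance ratio
~4), and every one of the 3 pairs x 4 feature kinds is flagged as a
significant variance increase — de-synchronisation detected.

Single-neuron feature extraction works the same way from files:

```r
traces <- read_traces("recording.csv")        # time + one column per neuron
cyc <- detect_features(traces[[1]], tau = 30) # smooth, slopes, cycles, plateaus
feature_table(cyc)                            # long table, samples and ms
```

The 44 published F-test p-values from the dopamine experiment on PY neuron
pairs are included for reference:

```r
count_significant(py_delay_pvalues(long = TRUE), alpha = 0.05)$n_significant
#> [1] 22
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline analyses from scratch: the significance
count over the published p-value table, the full simulate → detect → match
→ F-test pipeline on a seeded three-neuron condition pair, and the
analytic-vs-Monte-Carlo slope-noise check, writing the JSON report to
`--out`.

## Documentation

The methods vignette (`vignettes/slope-features.Rmd`) describes the
estimator, the noise model (including a documented typographical
discrepancy in one published variance denominator), band-based spurious
point filtering in the plateau- and spike-dominant regimes, the matching
rule, what the synthetic generator does and does not emulate, and known
limitations.
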