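---
title: "Benchmarking spiking substrates with a binary associative memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking spiking substrates with a binary associative memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binamr)
```

## The model

A binary neural associative memory (BiNAM) stores `N` key/value pairs of
sparse binary vectors, `x_k` (length `m`, exactly `c` ones) mapped to `y_k`
(length `n`, exactly `d` ones), in a clipped Hebbian matrix

    M[i, j] = 1  iff some pair k has x_k[i] = 1 and y_k[j] = 1.

Recall of a key `x` thresholds the matrix-vector product: output bit `j` is
set iff `sum_i x[i] M[i, j] >= c`. For a stored key this never misses a
stored one (no false negatives); it may add spurious ones (false
positives), whose expected number per sample is approximately

    alpha_tilde = (n - d) * (1 - (1 - c*d/(m*n))^N)^c.

The information recallable from the memory, given per-sample false-positive
and false-negative counts `alpha_k`, `beta_k`, is

    I = sum_k [ log2 C(n,d) - log2 C(alpha_k + d - beta_k, d - beta_k)
                - log2 C(n - alpha_k - d + beta_k, beta_k) ]  bits.

`optimal_sample_count()` maximizes `I` over integer `N` with
`alpha_k = alpha_tilde(N)` and `beta = 0`, using log-gamma-generalized
binomial coefficients so the objective is smooth in the non-integer
expectation. The objective is extremely flat near its optimum — within a
few parts in 10^6 over a ±1 band for the standard configurations — so any
two implementations may legitimately disagree by one sample in the integer
argmax; `optimal_sample_count(..., profile = TRUE)` exposes the full
profile for such comparisons.

The package turns this memory into a *benchmark for spiking substrates*:
the same network description and the same input spike trains are executed
on any back-end (the built-in reference simulator, or external hardware
through a black-box contract), and the decoded output is scored against the
exact binary memory. A perfect substrate reproduces the McCulloch-Pitts
behavior bit for bit.

## From bits to spikes

`encode_patterns()` presents one key every `T = 100` ms. Each set bit
becomes a burst of `s` spikes at `delta_t = 2` ms spacing (500/s per
synapse within a burst) on each of `omega` redundant channels (population
coding), and every spike receives independent Gaussian jitter with
`sigma_t = 2` ms. These defaults are the standard operating conditions of
the benchmark; four canonical modes are provided by `benchmark_setup()`:

| setup | s | omega | parameter set |
|-------|---|-------|---------------|
| (a) single spike, single neuron | 1 | 1 | I |
| (b) single spike, population    | 1 | 4 | II |
| (c) burst, single neuron        | 4 | 1 | II |
| (d) burst, population           | 4 | 4 | III |

`build_network()` creates one output neuron per value bit (times `omega`)
and `omega^2` excitatory synapses per one-entry of `M`. `decode_spikes()`
counts output spikes per population per 100 ms window; a bit is set when
the count reaches `omega`. (The decision threshold is *at least* `omega`
rather than *more than* `omega`: with `s = 1` a correct neuron emits
exactly one spike per member, so a strictly-greater rule could never set a
bit in the single-spike modes.)

Windows are half-open `[kT, (k+1)T)`. Jittered times are clamped at zero
and re-sorted; a jittered spike may cross a window boundary, which is
accepted as part of the modeled noise. The jitter RNG is a dedicated
stream, decoupled from data generation, so the same spike schedule is
reproducible independently of the dataset seed.

## The reference simulator

The built-in substrate is a conductance-based leaky integrate-and-fire
neuron with exponentially decaying excitatory synapses:

    C_m dv/dt = g_leak (v_rest - v) + g (e_exc - v) + I_offset
    dg/dt     = -g / tau_exc,        input spike: g <- g + w

in mV, nS, nF, ms, nA. Spike delivery and threshold detection are
*synchronous* on a grid of width `dt` (default 0.1 ms): an input spike at
time `t` takes effect at `ceil(t/dt)*dt`, and `v >= v_th` is tested only at
grid points (no root-finding for the exact crossing). Between grid points
the ODE is advanced either by an adaptive Runge-Kutta-Fehlberg 4(5) step
controller with absolute error target `1e-3` (`rkf45`, the reference), or
by a single naive explicit Euler step per grid interval (`euler`). The
Euler mode is deliberately unsophisticated — no exact exponential update
for the conductance — because the point of the comparison is to expose what
a fixed-step first-order integrator does to the benchmark at `dt = 1` ms.
During the refractory period (1 ms) the membrane is clamped at `v_reset`
while the conductance continues to decay; the refractory window is rounded
up to whole grid steps. Synaptic transmission delay is zero in the network
description: the network is a feed-forward single layer decoded over
100 ms windows, so sub-millisecond delays are immaterial.

The simulator core is written in C++ (via Rcpp). Neurons whose state sits
exactly at its fixed point (zero conductance, membrane at the
current-shifted rest) are skipped analytically, which makes the large
silent phases of the benchmark cheap.

## Neuron parameter sets and calibration

Each output neuron must implement a threshold function: stay silent for
`s*omega*(c-1)` input spikes and fire for `s*omega*c` (and
`s*omega*(c+1)`). The package ships three presets (`parameter_set()`)
sharing `v_rest = v_reset = -80` mV, `tau_ref = 1` ms, `C_m = 0.2` nF
(`tau_m = 10` ms at `g_leak = 20` nS), `e_exc = 0` mV, `tau_exc = 2` ms:

| set | v_th (mV) | g_leak (nS) | w (nS) | tuned for |
|-----|-----------|-------------|--------|-----------|
| I   | -65.6     | 20          | 10     | (a) |
| II  | -73.8     | 20          | 1      | (b) and (c) |
| III | -70.6     | 89          | 1      | (d) |

The threshold potentials are this package's own calibration against the
built-in reference integrator: for each set, `v_th` was chosen to maximize
the joint probability, over 2 ms-jittered stimulus ensembles, that the
neuron is silent at `s*omega*(c-1)` input spikes and emits at least one
spike at `s*omega*c` and `s*omega*(c+1)` — the event the windowed decoder
actually observes. (The stricter ideal of exactly `s` output spikes per
burst is not enforced: under this membrane model a sustained burst drive
produces a variable number of threshold crossings, and the decoder only
requires the count to reach `omega`.) Set II deliberately serves two
operating modes; its feasible threshold window is the intersection of the
simultaneous-volley window of mode (b) and the burst window of mode (c)
and is less than 1 mV wide, which is why mode (c) — unlike (b) — retains a
small residual error rate under jitter even in the reference simulator.

`optimize_neuron()` automates this kind of tuning for arbitrary objective
sets. Because the output spike count is integer-valued, it is smoothed by
the *fractional spike count* `q = n + j⁻/(j⁺ + j⁻)`, where `j⁺` is the
smallest constant excitatory offset current that increases the count and
`j⁻` the smallest inhibitory current that decreases it (or, for a silent
neuron, suppresses the membrane below rest everywhere). Both currents are
located by a doubling bracket from 1e-4 nA up to a 10 nA cap and a binary
search to 1e-3 relative width; the perturbation is a constant current over
the whole window, the simplest waveform compatible with the whole-trace
suppression condition. The surrogate objective scores `q - 1/2` against
each integer target under a Student-t density (`df = 2`, `scale = 0.5`,
recorded configuration rather than theory: heavy tails keep a parameter
set that is several spikes off target on a finite, informative gradient,
with one missing spike costing about two nats) and is maximized by
Nelder-Mead from the supplied start plus random restarts. The empirical
per-objective success probabilities are reported alongside for manual
fine-tuning, as automatic optimization of a surrogate is only ever an
approximation.

## Benchmark metrics

`run_benchmark()` executes generate → train → build → encode → simulate →
decode → score. The theoretical baseline for a dataset is the *exact
binary recall of each trained key from the trained matrix* (per-sample
false-positive counts `alpha_th_k`, no false negatives); `I_th` is the
information at that baseline. The normalized measures are

    I_n = I / I_th,   beta_n = beta_bar / d,
    alpha_n = alpha_bar/alpha_th - 1                      if alpha_bar <= alpha_th
              (alpha_bar - alpha_th)/(n - d - alpha_th)   otherwise

so a substrate that reproduces the binary memory exactly — including its
genuine false positives — scores `I_n = 1, alpha_n = 0, beta_n = 0`, a
shortage of false positives gives `alpha_n < 0`, a surplus `alpha_n > 0`.
Using the dataset's own recall baseline (rather than the `alpha_tilde`
expectation, which a finite random dataset never hits exactly) is what
makes a perfect score exactly 1.

`run_benchmark()` also computes the random-matrix information baseline
`I_rand` (from the binomial tail `p = P(Binom(m, c/(2m)) >= c_th)`) and
warns when `I_rand/I_th > 0.05`: a saturated memory can appear to "recall"
information from noise, and `I_n` stops being meaningful. Note that for
the standard `c = c_th = 4` configurations this ratio evaluates to roughly
0.08-0.10 — the tail probability depends on `c` and `c_th` but hardly on
`m` — so the warning fires on perfectly ordinary runs; it marks a limit of
the normalization, not a defect of the run. On the error-count
orientation: with `p` the probability of a recalled one, a stored one is
missed with probability `1 - p`, so the package uses
`alpha_rand = (n-d) p`, `beta_rand = d (1-p)`; the transposed assignment
is available as `eq12_as_printed = TRUE` for comparison with conventions
that state it the other way around.

The energy-efficiency measure is `E_eff = I_n * N / (P * t)` — recalled
samples per joule, weighted by recall quality. The package implements the
arithmetic (`energy_efficiency()`); measuring `P` is out of scope, and `t`
is wall-clock time around the back-end call including its setup/teardown.

## The synthetic data generator

`generate_dataset()` draws the key and value patterns from independent RNG
streams. The default *balanced* mode places each new pattern's ones on the
currently least-used columns (uniform random tie-break), retrying with
usage-weighted sampling when a duplicate row would arise; this keeps the
column sums of every dataset prefix within a spread of one and makes the
workload uniform across neurons, at the cost of a small dependence between
patterns. `balance = FALSE` gives plain uniform sampling of distinct
patterns, matching the independence assumptions of the capacity formula.

What the generator does *not* emulate: real-world key statistics
(correlated or non-uniform patterns), variable pattern weights, or any
structure in the key-value association. Tests that pass on this generator
therefore certify the substrate's reproduction of the threshold dynamics,
not performance on naturally structured data.

On the accuracy of the `alpha_tilde` formula: it treats the `c` relevant
storage-matrix rows as independent, but they share the column-usage
fluctuations of the stored values. Empirically the formula underestimates
the true mean false-positive count by ~25% at light loads (one-entry
density around 0.3-0.6) and is accurate (within Monte-Carlo error at 50
datasets) once the memory is loaded to density ≳ 0.85. The package's
Monte-Carlo validation therefore runs on loaded small memories; the formula
is used elsewhere only to choose `N`, for which only the location of its
maximum matters.

## Numerical choices and degenerate inputs

* Recall of an all-zero key with the default threshold is an error (a zero
  threshold would set every output bit).
* `N = 0` experiments are rejected; an empty storage matrix builds a valid
  zero-synapse network with a warning and simulates to silence.
* Infeasible sweep values mark their row as failed; the sweep continues.
* Binomial coefficients in the information formula are evaluated through
  `lgamma`, exact for integer arguments and smooth for the theoretical
  non-integer false-positive expectation.
* The Euler error guard reports a diverged (non-finite) state together
  with the step size; in practice the threshold reset and the conductance
  floor bound the state, so the guard is defensive.
* Optimal-sample-count ties break toward smaller `N`; the integer scan
  runs to the `N` at which the memory is 99% saturated and widens
  automatically if the maximum lies on the boundary.

## Problem sizes used by the shipped tests

The test-suite exercises the full pipeline at the published reference
dimensions — (28, 32, 54) for the population mode and (112, 128, 735) for
the single-neuron modes, about 5.4 s and 73.5 s of biological time — and
smaller (≤ 32 × 32) instances for property-style checks, chosen so the
whole suite completes in a few minutes on one core. The acceptance script
averages the stochastic reference quantities over three data/jitter seeds.

## Known limitations

* Only excitatory feed-forward connectivity; no recurrent clean-up
  memories, no inhibition, no plasticity.
* The fractional spike count is implemented for the built-in
  conductance-based LIF model only (behind the model interface of
  `simulate_single_neuron()`).
* No adapters for specific neuromorphic platforms are included; external
  substrates connect through the JSON network description and the spike
  CSV exchange format (`write_network_json()`, `read_spike_csv()`,
  `score_output()`).
* `sweep_2d()` executes grid cells sequentially; multiplexing many
  independent networks into one back-end invocation — a throughput
  optimization for hardware with expensive setup — is not implemented.
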