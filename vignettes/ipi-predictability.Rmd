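---
title: "Measuring the predictability of EEG inter-peak-interval dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the predictability of EEG inter-peak-interval dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the measurement

How regular are the internal dynamics of the brain in different states of
consciousness? One operational answer: take a single-channel EEG trace,
reduce it to a sequence of discrete events — the local maxima of the lightly
smoothed signal — and ask how well the time to the next peak can be forecast
from the recent past. The inter-peak interval (IPI) sits on a ~100–150 ms
scale, far slower than action potentials, and behaves like a point-process
summary of the ongoing oscillatory activity. A state whose IPI sequence is
easy to forecast one step ahead has, in this sense, more predictable
internal dynamics.

`ipipredict` implements that measurement end to end: signal I/O (EDF and
plain text), Gaussian smoothing, strict local-maximum detection, interval
construction, one-step-ahead forecasting with a small feed-forward network
trained by Levenberg–Marquardt, and the cross-state statistics (Welch
t-tests and Cohen's *d* on log-transformed absolute errors, moment
skewness, Welch power spectra). A synthetic three-state generator — awake,
REM sleep, slow-wave sleep (SWS) analogues — provides ground-truth data so
every stage is testable without any recording downloads.

## The pipeline, stage by stage

**Smoothing.** The trace is convolved with a discretized Gaussian kernel,
σ = 1 sample (10 ms at the 100 Hz default rate), truncated at 4σ and
normalized to unit sum. This removes sharp one-sample peaks that would
otherwise dominate the interval sequence with unpredictable jitter, while
leaving the peak structure itself intact. Boundaries use reflect padding:
zero padding would attenuate the signal near the edges and manufacture
spurious boundary peaks. σ is expressed in samples; users working at other
sampling rates should rescale it accordingly.

**Peak detection.** Index *t* is a peak iff
`x[t] > x[t-1]` and `x[t] > x[t+1]`, strictly on both sides. Endpoints are
never peaks, and a flat-topped plateau yields no peak rather than an
arbitrarily assigned one — with continuous-valued, smoothed data exact ties
have measure zero, so this convention costs nothing while keeping the
definition unambiguous. No amplitude or prominence threshold is applied.

**Intervals.** IPIs are differences of consecutive peak indices, kept as
integers in sample units throughout the pipeline; conversion to
milliseconds (10 ms per sample at 100 Hz) happens only in reports.

**Windowing and splits.** The interval series is traversed with a window of
k = 10 past values; the value following each window is the target, giving
`n − k` pairs. Pairs are tagged chronologically: first 60 % training, next
15 % validation, final 25 % test. Adjacent windows share nine of ten
values, so a shuffled split would leak test information into training;
chronological splitting is the conservative choice. Inputs and targets are
z-scored using statistics of the training portion only — raw interval
magnitudes (~12 samples) sit far outside the sensitive range of tanh units
and make the damped normal equations ill-conditioned — and predictions are
mapped back to sample units before any error is computed.

**The predictor.** A 10–10–1 multilayer perceptron (tanh hidden units,
linear output; 121 weights) is trained per condition by full-batch
Levenberg–Marquardt on the training sum of squared errors: per epoch the
Jacobian of the network output is assembled by backpropagation and the step
solves `(JᵀJ + λI) δ = Jᵀr`. A step is accepted only if it lowers the
training SSE — so accepted-step SSE is non-increasing by construction —
after which λ is multiplied by 0.1; a rejected step multiplies λ by 10 and
retries within the epoch. Training stops after 6 consecutive epochs without
validation improvement (the canonical use of a validation split when no
explicit stopping rule is otherwise fixed), at 1000 epochs, or when λ
exceeds 10¹⁰ (a flat or degenerate error surface). The returned weights are
those with the best validation error. Weights are initialized uniformly in
[−0.5, 0.5] scaled by 1/√fan-in from a user-supplied seed; training is
bit-reproducible given that seed.

**Errors and statistics.** Errors are computed on the test pairs only, as
`error = true − predicted` in sample units, so positive error means the
next interval was underestimated. Absolute errors are strongly positively
skewed; for inference they are log-transformed (`log(|e| + 1e-8)`; the ε
guard keeps the transform total on exact zeros, which continuous-valued
predictions hit with probability zero). Cross-state comparison uses Welch's
unequal-variance t-test — group variances visibly differ between states, so
the pooled-variance t-test's assumption is not defensible — while Cohen's
*d* keeps its standard pooled-SD definition. The sign convention is first
group minus second; pipeline reports order each pair as (SWS, AWAKE, REM),
so positive *d* reads "the first-listed state is less predictable". No
multiple-testing correction is applied across the three state pairs; the
report files flag this. Skewness is the plain moment estimator
`g1 = m3/m2^1.5`; with roughly 750–2000 errors per condition the
small-sample correction would change the third decimal.

**Spectra.** Power spectra use Welch averaging — Hann window, 50 % overlap,
segment length `min(4096, N)`, per-segment mean removal — on the raw,
unsmoothed trace. The alpha-band summary reports the fraction of total
power in 7.5–12.5 Hz; its purpose is to check that predictability
differences are not simply a proxy for alpha-wave content.

## What the synthetic generator emulates

Each state profile generates intervals from a mean-centered AR(2) process,
`x_t = 0.5 x_{t−1} + 0.2 x_{t−2} + η_t`, with standardized lognormal
innovations (shape 0.6) so interval distributions are positively skewed,
rounded onto a 12-sample (120 ms) mean and clipped at 2 samples. The state
differences live entirely in the innovation SD — REM 0.6, AWAKE 1.0, SWS
2.5 samples — giving a generative ground truth in which the conscious-state
analogues are strictly more predictable, with a well-defined optimal
predictor (the AR conditional mean) whose error floor the network should
approach. The waveform renderer places a peak at each cumulative interval
position and joins consecutive peaks through two raised-cosine half-arcs
via a zero trough, so each cycle contributes exactly one strict local
maximum before noise; peak heights are Gaussian (20 ± 4 µV for REM/AWAKE,
60 ± 10 µV for SWS, the slow-wave amplitude regime), white measurement
noise is 1 µV, and the SWS profile adds a random-phase 8 µV sinusoid at
0.75 Hz so its dominant spectral power sits below 3 Hz.

Defaults were fixed by two requirements measured during design: extraction
through the full smoothing-and-detection chain must reproduce the
ground-truth intervals with at least 95 % exact agreement (noiseless
rendering is exactly recoverable by construction; 1 µV noise leaves
~97–99.9 % agreement depending on state), and the recovered interval
distributions must stay positively skewed. Noise much above this (e.g.
2 µV on a 20 µV profile) seeds spurious peaks in the flat trough regions,
shreds intervals, and even flips the apparent skewness — a useful reminder
that the IPI measure degrades gracefully but not indefinitely with SNR.

What the generator does **not** emulate: 1/f background activity, spindles
or K-complexes, non-stationarity across the night, volume-conduction mixing
of sources, or any dependence of the waveform shape on the interval
process. Passing tests on synthetic data therefore demonstrate that the
pipeline measures what it claims on data with known structure — not that
real EEG satisfies that structure.

## Numerical choices and degenerate inputs

* Degenerate normal equations during training fall back to a larger λ
  rather than aborting; λ exceeding 10¹⁰ stops the run with the best
  validated weights so far.
* A constant training series gives zero normalization SD; the scaler then
  shifts without scaling rather than dividing by zero.
* Non-finite samples cause the loaders to reject the file outright — no
  silent interpolation — because downstream stages assume clean continuous
  traces.
* Very short series: windowing needs at least k + 2 intervals; training
  additionally requires 10 training pairs and 1 validation pair and says
  so explicitly.
* EDF values round-trip within one quantization step of the declared
  physical range divided by 2¹⁶ (the format stores 16-bit integers).

## A known spectral limitation

The alpha-band power fraction of the synthetic SWS traces is ~0.5, far
above what real slow-wave sleep would show. The cause is structural: the
shared 12-sample mean interval puts the peak-rate line at ~8.3 Hz — inside
the 7.5–12.5 Hz band — and because detected peaks must remain the strict
local maxima of the trace, any added slow oscillation strong enough to
drown that line out (about twenty times the arc power) would have slopes
that displace or destroy the peaks and break ground-truth recovery; the
trade-off is scale-invariant in amplitude. The 0.75 Hz component is
therefore sized to dominate the spectral *argmax* (matching the
low-frequency regime of slow-wave EEG) while leaving the alpha *fraction*
unrealistically high. Conclusions about alpha content should be drawn from
real recordings, not from this generator.

## Problem sizes

The packaged study runs 3,000 intervals per state (≈ 360 s of 100 Hz
signal, ≈ 2,990 windowed pairs, 748 test errors) with three replicate
seeds; the analysis scripts extend this to a 4-subject × 3-state grid.
These sizes give the t-tests roughly the same per-condition n (~2,000–3,000
intervals) as a typical overnight-recording excerpt while keeping a full
replication under a minute of CPU.
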