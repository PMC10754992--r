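---
title: "Methods: threshold-sharpened spiking detectors for parkinsonian spike timing"
author: "spikesharp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-sharpened spiking detectors for parkinsonian spike timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Closed-loop deep brain stimulation for Parkinson's disease needs a fast,
energy-frugal monitor of the parkinsonian state. The established biomarker
is excess beta-band (13--30 Hz) oscillatory power in basal-ganglia
structures, classically the subthalamic nucleus (STN). Spectral estimation
is expensive on implanted hardware, so `spikesharp` implements the
alternative this package is built around: classify the *raw spike timing*
of STN neurons in the time domain with a spiking neural network whose
activations are binary thresholds, and map the trained weights onto
simulated memristive crossbar arrays for in-memory inference.

The classifier's unit of input is one neuron's spike-time vector over a
fixed window (default 0--2,500 ms), zero-padded to length `L_max = 128` and
scaled into `[0, 1]` by the window length. A labeled dataset pairs each
vector with a binary state (0 healthy, 1 parkinsonian).

## Synthetic data

No electrophysiology ships with the package; both generators are
first-class, tested code.

### Phenomenological generator

Healthy trains are refractory-modified Poisson processes; parkinsonian (PD)
trains are inhomogeneous renewal processes with hazard

$$\lambda(t) = \lambda_{PD}\,\bigl(1 + m\,\sin(2\pi f_\beta t + \varphi)\bigr),$$

with a uniform random phase per sample. Inter-spike gaps are a refractory
period plus an exponential variate whose rate is corrected so the long-run
mean rate equals the nominal rate exactly (at modulation depth 0 the mean
spike count over 2.5 s at 10 Hz is 25, a property the tests check against
the Poisson mean).

Shipped defaults: `rate_healthy` 10 Hz, `rate_pd` 25 Hz, `beta_freq` 20 Hz,
`mod_depth` 0.8, `refractory` 3 ms. The source recordings this emulates
constrain the rates only qualitatively (sparser healthy firing, elevated PD
beta power), so the defaults were chosen once to sit in the physiological
range for rodent STN (healthy ~10 Hz, parkinsonian STN hyperactivity in the
tens of Hz) and to reproduce both biomarkers robustly; they are
configuration, not conclusions, and every figure-level property the tests
assert (denser PD firing, higher PD beta power) is computed from these
defaults at run time.

### Circuit generator

`circuit_config()`/`build_network()`/`simulate_circuit()` implement a
reduced cortico-basal-ganglia-thalamus network: eight populations (regular
and inhibitory cortex, direct- and indirect-pathway striatum, STN, GPe,
GPi, thalamus) of 10 neurons each. Since the detector's acceptance is
defined on biomarker properties rather than voltage trajectories, neurons
are Izhikevich single-compartment units with region presets (regular
spiking for cortex/striatum/thalamus-like populations, fast spiking for
interneurons and pallidum) rather than a full conductance-based model.
Synapses are signed exponential-decay current kicks (tau 5 ms excitatory,
10 ms inhibitory) with fixed axonal delays (1 ms within a region, 6 ms
between regions), integrated at `dt = 0.1` ms with two half-steps on the
membrane equation for stability.

Wiring follows the stated region rules: stochastic in-degree-3 connections
for cortex and striatum (the source describes these only as "randomly
selected", so the in-degree is a package choice, drawn without replacement
with self-edges forbidden); structured rules elsewhere — every GPe neuron
is inhibited by exactly two other GPe neurons and by all indirect-pathway
striatal neurons, every GPi neuron by all direct-pathway striatal neurons
and by GPe, every STN neuron receives GPe inhibition and cortical
excitation, thalamic neurons receive GPi inhibition only, and a
configurable fraction (default 0.5) of GPe/GPi neurons receives excitatory
STN feedback.

The parkinsonian state is a dopamine scalar (healthy 1, PD 0.2). Dopamine
depletion multiplies the efficacy of the indirect-pathway striatal
inhibition of GPe, the cortico-subthalamic gain, and the reciprocal
STN-GPe coupling by `1 + k (1 - dopamine)`. The last of these is the
package's mechanism choice: the STN-GPe loop is the standard circuit-level
generator of pathological beta, and with 6-ms inter-regional delays and a
10-ms inhibitory tau its resonance falls in the beta band. At the shipped
constants the PD state raises mean STN rate from ~11 to ~18 Hz and roughly
doubles per-train beta-band power, with the population rhythm visible in
the pooled spike train; halving `dt` moves per-region mean rates by < 10%
(averaged over seeds), which is the package's operational reading of
time-step robustness. These constants were fixed once, while building the
simulator, against those three targets.

What the generators do *not* emulate: recording noise and unit-sorting
artifacts, non-stationary symptom severity, within-class rate
heterogeneity beyond the point-process variance, and any LFP. Consequences
for interpretation are discussed under Limitations.

## Detectors and sharpening

Three presets: `slstm8` (two recurrent spiking LSTM layers of width 64,
dense spiking stack 256-128-64-32-16, 2-unit output), `slstm7` (one dense
layer fewer) and `snn7` (six dense spiking layers on the flattened input).
Layer counts are fixed by the architecture family; widths are not stated
by the source and are shipped as overridable presets.

Every layer carries a bounded-ReLU (bRELU) activation

$$h_{\alpha,\beta}(x)=\begin{cases}1 & x \ge \beta\\ \frac{x-\alpha}{\beta-\alpha} & \alpha \le x \le \beta\\ 0 & x \le \alpha\end{cases}, \qquad |\beta - 0.5| = |\alpha - 0.5|,$$

starting at $(\alpha,\beta)=(0,1)$ and narrowing during training until it
is a step at 0.5 (the value at exactly 0.5 is defined as 1). *Sharpening*
reduces the half-width $w=(\beta-\alpha)/2$ by a per-epoch increment,
layer-sequentially from the input side; once $w=0$ the unit emits only 0/1
— a spiking unit. The adaptive schedule evaluates the training loss at the
end of each epoch and pauses sharpening whenever the relative loss change
over a trailing patience window (default 3 epochs) exceeds the tolerance
(default 5%): sharpening proceeds only while the loss is settling. (The
prose this rule derives from can be read in either direction; the
implemented direction is the one under which the schedule protects
accuracy.) Total sharpness is therefore monotone non-decreasing, a
property the tests assert.

Implementation choices that the architecture family leaves open:

* **Recurrent layers.** Threshold training is defined for feedforward
  nets; the minimal consistent extension used here keeps the LSTM gate
  nonlinearities smooth and applies the bRELU only to each recurrent
  layer's *emitted* activation (what the next layer consumes, and the
  final-step feature vector). The LSTM output $h_t = o_t \tanh(c_t)$ lives
  in $[-1,1]$, so it is mapped affinely onto $[0,1]$ before the bRELU;
  fully sharpened, the unit emits $\mathbf{1}[h_t \ge 0]$.
* **Initialization.** Glorot-uniform weights with two bounded-activation
  amendments. The output layer starts mid-ramp (bias 0.5, weights scaled
  by 0.25) so neither class unit is born beyond a bRELU knee, where the
  gradient is exactly zero and a dead output unit is unrecoverable; hidden
  dense layers keep standard Glorot with zero bias. The LSTM forget-gate
  bias starts at 3 ($f \approx 0.95$) so the cell can integrate evidence
  across the full 128-step padded sequence from the first epoch. Without
  these choices the detectors reliably stall in constant-output minima
  under the prescribed optimizer settings.
* **Loss and optimizer.** Mean squared error against one-hot targets
  (natural for bounded `[0,1]` outputs), adadelta
  ($\rho = 0.95$, $\varepsilon = 10^{-6}$) with learning-rate multiplier
  0.05, batch size 128, 100 epochs by default. Training is bit-reproducible
  from `cfg$seed`: weight init and batch shuffling draw from derived
  streams, and the compiled forward/backward pass is deterministic.
* **Prediction.** Binary mode takes the arg-max of the two output units'
  pre-threshold activations (ties resolve to class 0 with a warning);
  score mode returns the PD unit's pre-threshold activation. The source
  reports AUC for binary-output networks without saying how; using the
  pre-threshold score is the package's resolution, and the AUC is computed
  by the rank (Mann-Whitney) statistic with midranks, never from a
  fabricated curve.

### Reduced study sizes

The full protocol (30,000 samples, full widths, 100 epochs) is what the
package defaults encode. The test-suite and the acceptance script run the
same pipeline at the package's reduced study size — 4,000 samples (200
groups x 10 neurons per condition), halved widths, 25 epochs — which
preserves the qualitative regime (classes strongly rate-separated,
validation accuracy > 0.98) while keeping a complete run in minutes on one
CPU. The vignette states these sizes as the package's choice of desk-scale
experiment; nothing about the method depends on them.

## Evaluation kit

`confusion()` counts with PD as the positive class — forced by the printed
precision of the reference confusion matrices, which only reproduces if PD
is positive. `metrics_from_confusion()` derives ACC, MCR, precision,
recall, specificity, FPR, FNR, F1 and MCC; any metric with a zero
denominator is reported as undefined (`NA`, flagged), never invented.
Display rounding is 4 decimals; stored values are full precision.

`spike_psd()` bins a train into a binary sequence (12-ms bins) and
averages mean-detrended, Hann-windowed 1-s periodogram segments with 50%
overlap. The bin width is the one spectral choice that matters: the ~42-Hz
Nyquist covers the full beta band while cutting off the harmonic series of
regular trains above it, so a 20-Hz-paced train is dominated by its
fundamental rather than by harmonics falling in a higher comparison band.
`beta_band_power()` integrates the PSD over `[13, 30]` Hz; an empty train
has zero power by construction.

### Timing-noise protocol

`add_timing_noise()` replaces every nonzero entry `v` by `v + N(mu, sigma)`
— one independent draw per entry, padding zeros untouched, entry order
deliberately *not* re-sorted (the protocol replaces values in place), and
results clipped into `(0, T_max]` at the 0.001-ms file resolution so no
spike is ever dropped. The three study settings are (7, 4), (15, 12) and
(30, 25) ms. Whether the original study jittered the training partition,
the validation partition or both is not stated; the package default is
both, with `applies_to` exposed. `noise_robustness_report()` retrains a
fresh detector per setting per seed under one split fraction and training
protocol and tabulates all ten measures.

## Crossbar inference

A crossbar computes $I_j = \sum_i V_i G_{i,j}$ in one analog step. Signed
weights use a differential pair: positive parts map to `G_pos`, magnitudes
of negative parts to `G_neg`, each linearly from `[0, max|W|]` onto
`[1/R_off, 1/R_on]` and rounded to one of $2^{\text{bits}}$ uniform
conductance levels (device default: 2 bits, R_on 6 kOhm, R_off/R_on 150,
0.5 V read voltage, 128 x 128 subarrays). Because both arrays share the
`1/R_off` baseline, the subtraction cancels the offset exactly and
`conductance_to_weight()` is the exact inverse up to quantization (error
at most half a level times the recorded scale). Larger matrices are tiled
into subarray-sized blocks whose partial currents are summed; tiled and
untiled results agree to float associativity (~1e-12 relative), which is
the package's reading of "exact" for analog summation reordered by
blocking. `crossbar_predict()` routes every dense and recurrent projection
of a trained detector through the tiled differential product — input
activations scaled by the read voltage, currents rescaled back — with
biases and thresholds in software, so at fine quantization crossbar and
software inference coincide.

## Degenerate inputs and tie-breaks

* Zero-rate generators return fully padded samples; classifying an
  all-zero sample is defined (no exception).
* Output ties resolve to class 0 and are logged via a warning.
* An all-zero weight matrix maps to minimum conductance on both arrays
  with scale 0 (weights reconstruct to exactly 0).
* Sub-0.001-ms times cannot be represented in files; jittered times are
  floored at 0.001 ms.
* A sharpening schedule whose start epoch equals the epoch count never
  fires (sharpening is applied only between epochs), leaving the network
  identical to an unsharpened run.

## Limitations

The synthetic classes are separated primarily by firing rate, with
beta-band structure as a secondary cue. That makes the classification task
*easier* than discriminating real parkinsonian recordings, where rate
distributions overlap and symptom severity drifts: the near-ceiling
validation accuracies the tests assert demonstrate that the pipeline —
generator, sharpened training, evaluation, crossbar mapping — is
internally correct, not that the detector would reach the same accuracy on
clinical data. The same caveat applies to the held-out shifted-window test
(10 neurons over 0--2,000 ms): under a rate-separated generator the shift
barely degrades accuracy, whereas a detector trained on real recordings
shows a substantially larger generalization gap. Timing-jitter robustness
is likewise flattered by the generator: jitter perturbs spike times but
conserves spike counts, so the dominant class cue survives even the
harshest setting. Finally, hardware cost modeling (area, latency, energy)
is out of scope; the crossbar module models the arithmetic of memristive
inference, not its silicon.
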