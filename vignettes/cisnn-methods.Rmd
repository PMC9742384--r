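---
title: "Methods: a cerebellum-inspired spiking network for classification and trajectory prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cerebellum-inspired spiking network for classification and trajectory prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cisnn` implements a spiking abstraction of the cerebellar microcircuit —
mossy fibers (MF) feeding a granule-cell (GrC) layer under Golgi-cell (GoC)
inhibition, pooled by Purkinje cells (PC) — wrapped in an encoder that turns
tabular features into drive currents and a rate-coded sigmoid decoder that
turns PC spike trains back into labels or motor commands. The same circuit is
used two ways: as a supervised pattern classifier and as an implicit
inverse-kinematics solver for a six degree-of-freedom (6-DOF) virtual arm.
This vignette records the model equations, the tunable parameters with their
defaults and rationale, what the synthetic data emulate, and the design
decisions taken where the design was genuinely open.

## Neuron model

All spiking units are adaptive exponential integrate-and-fire (AdEx) neurons:

$$C\,\dot V = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} + I - w,
\qquad
\tau_w\,\dot w = a (V - E_L) - w,$$

with a reset rule: when $V$ crosses 0 mV, $V \leftarrow V_r$ and
$w \leftarrow w + b$. Each cell type (GrC, GoC, PC) has its own nine
parameters (`adex_params()`); MF input units reuse the GrC set. Two choices
are worth recording:

* **Adaptation relaxation.** The adaptation equation includes the $-w$
  relaxation term of the canonical AdEx formulation. Without it $w$
  integrates without bound, which (i) silences every cell permanently after
  a few spikes when $b$ is large and (ii) diverges for the GoC and PC
  parameter sets, whose negative $a$ makes them intrinsically active. The
  canonical form reproduces the intended behaviours: GrCs are quiescent at
  rest (the exponential drive at $E_L$ is $\approx 0.27$ pA) and fire
  repetitively above their $\approx 350$ pA rheobase; GoCs and PCs are
  spontaneously active pacemakers.
* **Numerics.** Forward Euler at `dt = 0.1` ms over a 300 ms window, with
  the exponential argument clamped at 20 so the spike-initiation term cannot
  overflow — any voltage beyond the clamped region triggers the reset branch
  on the same step. $V_r$ defaults to $E_L$ per cell type (it is the one
  symbol of the reset rule without a published value). Halving `dt` moves
  individual spike times by under 1 ms at the published granule-cell
  operating current (350 pA); the phase error of forward Euler accumulates
  with firing rate, reaching a few ms per 300 ms window at two to three
  times that drive. The test suite pins the integrator against an
  independent scalar-loop reference.

## Encoding

Features are min-max normalized to $[0,1]$ (bounds from training data only;
test values are clipped; constant features map to the midpoint). Each
normalized value $\mu$ is expanded into 7 MF units at positions
$\mu + k\sigma$, $k = -3 \dots 3$, with kernel weight
$w_j = 1/(\sigma\sqrt{2\pi})$ (the normal density at its own mean). The unit
at offset $k$ receives drive current

$$I_k = g \cdot w_j \cdot \mu \cdot e^{-k^2/2},$$

so the center unit receives the full $g\,w_j \mu$ and excitation falls off
with the Gaussian profile — the center-surround structure in which the
central neuron is excited most strongly. Negative currents are floored at
zero, and the full convolution of the kernel samples with the instance is
computed and used as a non-emptiness guard on the encoding.

Two parameters here are genuinely free and were fixed once, from the AdEx
f–I curve rather than from any downstream result:

* **Receptive-field spread** $\sigma$: per-feature standard deviation of the
  normalized training values, floored at 0.05 (configurable constant
  override; trajectory mode uses a constant 0.1 over workspace-normalized
  coordinates).
* **Current gain** $g$: calibrated on the training set so the largest drive
  current is `target_max_pA = 1200` pA. Under the GrC AdEx parameters the
  rheobase is $\approx 353$ pA and 1200 pA yields $\approx 100$ Hz, so
  feature values map onto the rising part of the f–I curve: weakly driven
  units stay silent, strongly driven ones fire up to $\sim$100 Hz. (A
  calibration target at the rheobase itself would leave the input layer
  almost entirely silent, which is why the target sits well above it.)

## Network

`build_topology()` sizes the circuit from the data: $N_{MF} = $ features
$\times$ 7, one GoC, one PC per output, and
$N_{GrC} = \lceil N_{MF} \cdot 53/4 \rceil$ — each MF diverges to 53 GrCs
while each GrC pools exactly 4 MFs (the ceiling reproduces both reference
sizes, 371 GrCs for 28 MFs and 279 for 21). MF→GoC and GoC→GrC weights are
uniform on $[0.01, 0.09]$; MF→GrC weights are uniform on the same range over
the 4 sampled afferents (the published range for the neighbouring matrices,
adopted because the MF→GrC range is unstated); GrC→PC weights start at 0.01
over 48 sampled afferents (all of them if the layer is smaller). All
sampling is seeded; construction and simulation are bit-reproducible.

Synapses are delta-pulses: at each time step a presynaptic spike injects
`gain * w` pA for one step (Golgi input with negative sign). The granule
drive restricts the sum to each cell's 4 afferents (the operative reading of
the construction algorithm, which activates 4 MFs per GrC, rather than the
all-MF sum of the layer equation). The **synaptic gain** (8e5 pA per unit
weight) is the second free scale: one volley at the mean weight then moves a
granule cell by tens of mV — a strong, relay-like MF→GrC synapse — which
places active GrCs in the physiological 10–50 Hz band with sparse
population participation and parallel-fiber-driven PCs in the 30–500 Hz
band. It was frozen at that value from those rate targets alone.

## Decoding and the inverted threshold

PC spike trains are rate-coded into 50 ms bins (6 counts over 300 ms) and
fed to a per-output feed-forward net: 6 inputs, one hidden layer of 2
logistic units, one logistic output (`decoder_net()`, weights
$0.1\,\mathcal N(0,1)$, biases 0). The decoding rule assigns label 1
when $y' \le 0.5$ — inverted with respect to the usual convention. The
package keeps that threshold exactly and restores coherence in the trainer:
each decoder is taught the *complement* of its label, so the trained output
approaches $1 - y$ and the inverted threshold recovers $y$. The same
convention makes the motor readout $1 - y'$. Multiclass problems get one PC
and one decoder per class with an `argmax(1 - y')` readout (lowest index
wins ties).

## Learning

Three plastic sites, with learning rates 0.1 (MF–GrC), 0.35 (GrC–PC) and
0.15 (decoder):

* **Spiking sites** use the multiplicative rule
  $w \leftarrow w\,(1 - \lambda e)$: zero error is a fixed point, silenced
  synapses stay silenced, and signs are preserved whenever
  $|\lambda e| < 1$. Errors entering this rule are dimensionless — the raw
  label error for classification, and in trajectory mode the motor error on
  the 0–1 angle scale and the sensory error normalized by the workspace
  extents — because the sign-preservation bound only holds for unit-scale
  errors (radian- or cm-scale errors at these rates would saturate the
  clamp and collapse the Purkinje drive). Out-of-bound errors are clamped
  to $0.95/\lambda$ and counted in the run report.
* **The decoder** trains by two-layer backpropagation
  (`decoder_backprop()`): output error signal
  $e_s = (y - y')\,y'(1-y')$, hidden deltas $e_s\,w\,h(1-h)$, and a
  gradient-descent step $w \leftarrow w + \lambda\,\delta\,x$. The descent
  direction is deliberate: an update that instead subtracts the
  delta-times-input term (as this rule is sometimes transcribed) is
  gradient *ascent*, whose dynamics flee the target and saturate
  every output (verified during development — all outputs collapse to one
  extreme within a few epochs and accuracy pins at chance), contradicting
  every reported learning behaviour. The test suite pins the implemented
  step against an independently written analytic gradient.
* **Scheduling.** Classification updates the decoder online (after every
  instance) and the spiking sites once per epoch from the accumulated mean
  error. A batch-mean decoder update was tried first and is inert — with
  balanced classes the increments cancel almost exactly (measured
  $\sim 5\times10^{-6}$ error change per epoch) — so the online schedule,
  the standard reading of delta-rule training, is used. Early stopping
  triggers when the mean absolute training error changes by less than
  `1e-4`; the best-epoch weights are kept.
* **Trajectory mode** computes the dual error after each epoch's forward
  pass: motor error $e_m$ = desired − predicted joint angles (radians),
  sensory error $e_s$ = target − realized end-effector position (cm,
  realized = forward kinematics of the prediction). $e_s$ drives the
  MF–GrC site, per-joint $e_m$ the matching GrC–PC row, and the decoder's
  output delta is the plain radian-scale motor error — the dual-error
  formulation is linear in the error, without the classification rule's
  sigmoid-derivative factor. That linearity matters: it is what lets
  near-saturated angle targets converge within the 50-epoch budget.
* An optional trace-based rule (`kernel_trace()`,
  `kernel_weight_update()`, causal exponential kernel, $\tau_\kappa = 10$
  ms) implements the kernel-convolved form $\Delta w = \lambda\,\tilde x\,e$
  as an opt-in alternative; it is off by default because the kernel shape is
  otherwise unspecified.

## Trajectory prediction

The virtual arm is a serial chain of six revolute joints with alternating
yaw/pitch axes and link lengths (10, 10, 8, 8, 7, 7) cm — 50 cm total so the
25 × 30 × 40 cm cuboid workspace is reachable. Only the workspace extents
are published; the cuboid is centered at (−2, 2, −2) cm, the componentwise
median end-effector position under uniformly drawn in-range angles (about
two-thirds of uniform draws land inside). Joint angles live in
$[0, 4.45]$ rad, the decoder range mapped affinely onto it.

Each trajectory point gets its own 307-neuron network (21 MF, 279 GrC,
1 GoC, 6 PC) plus six decoders — a 4-point path instantiates 1,228 spiking
neurons — trained for up to 50 epochs on its point, keeping the best epoch
(smallest maximum per-coordinate deviation). An option shares weights
sequentially along the path instead. Inverse kinematics is ill-posed; no
explicit regularizer is added beyond the bounded angle range — redundancy is
resolved implicitly by learning.

## Synthetic data

The generators stand in for the small tabular datasets and the robotic-arm
recordings the method is aimed at; nothing is downloaded.

* `make_classification()`: Gaussian class-conditional features, class means
  equally spaced along the feature-space diagonal with consecutive
  separation `separation * noise_sd`, isotropic noise, balanced shuffled
  labels. The diagonal placement makes every feature carry the class signal
  (as in screening questionnaires, where most items correlate with the
  outcome) and makes `separation` the exact between-class mean distance.
  Scales mirror the study sizes (4–19 features, tens to ~170 instances);
  the learning-efficacy checks use n = 100, d = 4, k = 2, separation = 3.
* `make_arm_dataset()`: rejection-samples uniform in-range joint angles,
  keeps those whose forward kinematics lands in the workspace cuboid, and
  emits FK-consistent (xyz, angles) pairs, so exact errors are computable
  downstream. `make_trajectory()` extracts a short smooth path (consecutive
  spacing ≤ 10 cm) via greedy nearest-neighbour ordering.
* Splits are 66% train after a seeded shuffle.

What passing on these fixtures does *not* show: robustness to label noise,
to correlated or categorical features, to unreachable targets, or to sensor
noise on real arm data — the fixtures are clean by construction.

## Analytics

The granule-layer **sparseness index** for rates $v_i$ over $n$ stimuli is
$SI = (1 - A)/(1 - 1/n)$ with $A = (\sum v_i/n)^2 / \sum(v_i^2/n)$: 0 for
uniform rates, 1 for a single active stimulus, scale-invariant. Training
reports record per-neuron SI before and after learning and the number of
granule cells silenced by learning; the published SI means are not asserted
as targets because they depend on the original datasets and seeds.

**Storage capacity** uses the stability constant
$\kappa = T/\sqrt{\tau_s \tau_m}$ and
$\alpha_c = \ln\ln(\kappa^2) / (2\ln 2)$, with $\tau_s = \tau_m/4$,
$\tau_m$ = 64 ms (PC) and 1.4 ms (GrC). Both published formulas are
typographically ambiguous; the parses are pluggable
(`stability_constant()`, `storage_capacity()`) and every capacity report
embeds the interpretation identifiers that produced it. The
capacity-versus-rate transform $\alpha_c/(r_{out}\tau)$ is exposed as a
labelled transform, non-increasing in the rate–time product, with the
regime guards $r_{out}\tau \le 0.1$ (GrC) and $\ge 1$ (PC).

## Problem sizes and reproducibility

All shipped analyses run at desk scale: 300 ms windows at 0.1 ms steps,
networks of a few hundred neurons, fixtures of ≤ 100 instances, trajectory
runs of 4 points × 50 epochs (tens of seconds on one core), classification
runs of ~66 training instances × ~a dozen epochs (a few minutes). Every
random draw funnels through explicit seeds; reports embed the resolved
configuration and seed.

## Known limitations

* One GoC and delta-pulse synapses: no conductance-based or delayed
  transmission, no 3-D geometry, no unipolar brush/stellate/basket cells;
  the deep-nuclei/olivary error path exists only as the decoder and error
  signals.
* The two current-scale constants (encoder target, synaptic gain) are
  calibrated conventions, not fitted quantities; changing them rescales
  firing rates and would need re-checking against the 10–50 Hz / 30–500 Hz
  bands.
* Classification information reaching a single PC is bottlenecked by
  pooling; datasets whose class signal cancels across features will
  classify near chance regardless of training.
* The capacity formulas are implemented under documented parses of
  ambiguous sources; absolute capacity values should be read relative to
  the recorded interpretation, with the published comparison value
  ($\sim$0.2–0.3) a plausibility note only.
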