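---
title: "Methods: context-dependent dendritic modulation of feedforward networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-dependent dendritic modulation of feedforward networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sensory cortex is usually modelled as a feedforward hierarchy with fixed
feature detectors, yet real sensory neurons are pervasively modulated by
context: task demands, expectations, motor state. `dendromod` implements a
family of models built around one idea — sustained dendritic depolarization
(NMDA-receptor-driven plateau potentials lasting 50–100 ms) acts as a
*neuron-specific, task-specific modulation* of the input–output curve of a
rectifying neuron, so that a single set of feedforward weights can serve many
tasks. The package covers four layers of abstraction:

1. **Abstract rectifier networks with per-task gains** (`modulated_stack`):
   `y = relu(g_t * (W x - x_shift) + b)`, with `W`, `x_shift`, `b` shared
   across tasks and a gain vector `g_t` per task.
2. **Unsupervised feedforward weights aligned to sample differences**
   (`delta_pca`, `delta_sd`, `delta_pmd`, `random_projection`): the rows of a
   good weight matrix should span the difference vectors between data samples,
   because decision-boundary normal vectors of a rectifier network are linear
   combinations of first-layer rows.
3. **Greedy layer-local task-modulated contrastive learning**
   (`stack_layers`): per layer, an NT-Xent contrastive phase (task modulations
   of layers below act as additional augmentations) followed by a supervised
   gain phase through a task-independent output unit; no gradients cross
   layers.
4. **A spiking network with dendritic compartments** (`dendritic_network`,
   `run_online_learning`): integrate-and-fire somata star-coupled to passive
   compartments carrying AMPA+NMDA synapses with a Jahr–Stevens Mg-block
   sigmoid; context synapses learn online by a four-factor, error-modulated
   Hebbian rule.

## The neuron model and its assumptions

The spiking module deliberately substitutes a phenomenological reduction for
a morphologically detailed pyramidal-cell model: a leaky integrate-and-fire
soma (`C_m = 150 pF`, `g_L = 10 nS`, threshold −50 mV, reset −65 mV,
refractory 3 ms), `D` passive dendritic compartments each coupled to the soma
by `g_c = 2 nS`, and NMDA kinetics (rise 2 ms, decay 70 ms) gated by
`B(V) = 1 / (1 + 0.28 e^{-0.062 V})`. The decay constant is chosen so that a
context burst onto one compartment produces a regenerative plateau that holds
the compartment above −50 mV for roughly 50–100 ms — the mechanism the whole
framework rests on. What the model does *not* capture: active dendritic
channels (Ca²⁺/Na⁺/K⁺), GABAergic control of dendritic spikes, and detailed
morphology; conclusions about absolute conductance magnitudes should not be
drawn from it. Integration is exponential Euler at `dt = 0.05 ms` (halving
`dt` changes voltages by < 1 %, which the tests assert).

Burst "width" (6 ms feedforward, 20 ms context) is interpreted as the full
width at half maximum of the Gaussian envelope of spike times, so
`sd = width / (2 sqrt(2 ln 2))`. Context bursts lead the feedforward burst by
15 ms (`episode_protocol(ctx_lead = 15)`) so the quasi-tonic dendritic state
is established when the fast volley arrives; with a zero lead the plateau has
not developed by the time the decision window opens and modulation is much
weaker.

## Tunable parameters that matter

| parameter | default | why |
|---|---|---|
| NMDA decay `tau_nmda_decay` | 70 ms | plateau duration 50–100 ms |
| coupling `g_c` | 2 nS | one plateau moves the soma by a few mV; graded population modulation |
| decision window | 50 ms from first feedforward spike | short-latency feedforward read-out |
| context burst | 60 spikes, 20 ms FWHM | quasi-tonic drive of a compartment |
| output weights | Gaussian, sigma/mu = 0.1 | unspecific, near-uniform readout |
| `eta` (four-factor rule) | 0.01–0.015 | weight steps of a few % of the 0.55 nS clip |
| NT-Xent temperature `tau` | 0.5 | the cited contrastive algorithm's customary value |
| SGD | momentum 0.9, per-parameter gradient-norm clip 2, linear warmup over 15 % of epochs | see "numerical choices" |

## What the synthetic data emulate — and what they do not

`gen_2d_multitask` reproduces the character of the 48-task two-dimensional
benchmark: one shared point cloud, one random smooth (quadratic) boundary per
task, minority class ≥ 25 %. `gen_glyph_images` is an explicit stand-in for
handwritten-character sets: per class a fixed 2–4-stroke template, per sample
rotation/translation/endpoint jitter plus pixel noise. It preserves the
properties the methods rely on (localized strokes, within-class variability,
many one-vs-all tasks) but is far easier than real handwriting; a green test
therefore establishes that a mechanism *operates* and trends in the right
direction at desk scale, not that published benchmark accuracies are
reproduced. `gen_xor_episodes` encodes the classic non-linearly-separable
task in the spiking setting: one bit selects which feedforward pattern
arrives, the other selects the active context channel, and the output neuron
must spike exactly when the bits disagree — unsolvable by any fixed linear
readout of the inputs, solvable by context-gated dendritic boosts.

## Numerical choices

- **Loss / optimizer (abstract networks).** Binary cross-entropy on a sigmoid
  of the head pre-activation, plain SGD with momentum over balanced batches.
  Two safeguards were added after observing irreversible rectifier death in
  four-layer stacks (all units inactive for all inputs, zero gradient): He
  fan-in weight initialization with a +0.1 bias, and a linear learning-rate
  warmup over the first 15 % of epochs, plus a per-parameter gradient-norm
  clip. Learning rates follow a small per-architecture grid search (0.1 for
  one–two hidden layers, 0.05 for four), mirroring per-architecture tuning in
  the source literature.
- **Sparse decompositions.** `delta_sd` alternates exact coordinate-descent
  sparse coding with exact unit-sphere row updates, so the objective is
  provably non-increasing; `delta_pmd` uses rank-1 soft-thresholded power
  iterations with the threshold set by binary search and deflation between
  factors. Sign convention everywhere: the largest-magnitude entry of a
  factor row is positive. Ties at the classification threshold 0.5 predict
  the negative ("all/other") class.
- **Threshold fitting.** IO-curve thresholds are the linear-interpolation
  crossings of spike-count midpoints (`s + 0.5`); the three rectifier
  parameterizations are fitted jointly to all modulation levels in the
  threshold (x-axis) domain by multi-start BFGS with an `nlm` polish; the
  shared-x-shift variant additionally starts from the nested no-shift
  solution, which guarantees the nested-model residual inequality.
- **Degenerate inputs.** Tasks with a single class are rejected, not
  silently trained; unregistered task ids raise typed errors; unstable
  integrations (non-finite voltages) name the failing neuron.

## Design choices where the design was genuinely open

- **"CL without task-similarity"** is implemented as a similarity subset of
  size 1 (both views of a positive pair pass through the *same* single task's
  modulations), matching the equivalence stated alongside the subset-size
  analysis in the source, rather than as "no modulation at all".
- **Transfer regime.** At desk scale, wide trunks pretrained on many tasks
  put gain-transfer and readout-transfer both at ceiling. The packaged
  transfer experiment (`transfer_experiment`) therefore uses the regime in
  which the claimed mechanism is expressible: two pretraining tasks and a
  narrow (8-unit) top layer, so the frozen trunk discards information that
  the new tasks need, a fresh linear readout cannot recover it, and
  modulations to the wide first layer can.
- **Spiking one-vs-all calibration.** Candidate weight matrices (ΔPMD, RP)
  live on different scales, so a deterministic binary search sets the global
  feedforward scale such that ~25 % of the hidden population fires for probe
  stimuli without context — the identical procedure for every matrix, keeping
  the comparison fair. The four-factor learning rate decays as
  `1/(1 + episode/800)` in these runs; with a constant rate the learned
  solution degrades late in training as weights pile up at the clip.
- **Per-episode weight commit.** Traces integrate continuously during an
  episode; weights change once, at window close, multiplied by the episode's
  global error (+1 required-but-absent spike, −1 forbidden spike, 0 correct).

## Known limitations

- The contrastive module uses dense layers; convolutional weight sharing is
  not implemented (a pure-R conv training path would not meet the 1-CPU time
  budget). Receptive-field locality instead enters through the ΔPMD weight
  analysis.
- At desk scale the similarity-subset sweep rises from subset size 1 to
  mid-size but mildly declines from mid-size to the full task set; the
  full-range monotone trend reported at large scale is not reproduced (the
  acceptance test asserts it faithfully and is expected to stay red on that
  step; see the discussion of per-task positive-pair dilution above).
- Spiking one-vs-all accuracies are modest in absolute terms; the package
  reproduces the *ordering* (localized ΔPMD weights above random projections,
  which sit near chance) rather than published accuracy values.
- No value printed in this vignette or the README is asserted anywhere except
  by the tests and experiments that compute it.
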