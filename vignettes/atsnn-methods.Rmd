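---
title: "Adaptive-threshold spiking convolutional networks for vein recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-threshold spiking convolutional networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikevein)
```

## The model

`spikevein` implements an unsupervised spiking convolutional network for
finger-vein recognition. The pipeline turns a grayscale region-of-interest
(ROI) image into a sparse binary feature vector through five stages:

1. **Filter front end.** The image is cross-correlated with a bank of
   zero-mean kernels: four oriented Gabor kernels (orientation-selective
   edge detectors modeling cortical simple cells) and two
   difference-of-Gaussians (DoG) kernels (center-surround contrast
   detectors modeling on- and off-center retinal ganglion cells). Each
   kernel $G$ is normalized by subtracting its mean and dividing by the
   maximum of the mean-subtracted kernel, so all channels share a common
   response scale. Responses are rectified, rescaled per channel to
   $[0, 255]$, and values below a cutoff (default 50) are zeroed so that
   weak responses never become spikes.

2. **Local normalization and pointwise inhibition.** Each response is
   divided by the mean of its $(2r+1)^2$ neighborhood ($r = 8$ by
   default), emphasizing locally salient structure over slow illumination
   gradients; then, at every pixel, only the strongest channel survives,
   enforcing cross-channel sparsity before coding.

3. **Intensity-to-latency coding.** Stronger stimuli fire earlier. All
   strictly positive values are ranked (descending) and the ranking is
   split into $T_{\max}$ near-equal-count bins ($T_{\max} = 15$); the bin
   index is the neuron's first-spike time, and zero intensities never
   fire. The result is the cumulative spike-wave tensor
   $S[t, f, r, c] \in \{0, 1\}$ with $S[t] \le S[t+1]$: entry 1 means the
   neuron fired at or before step $t$. Cumulativity is what allows every
   later stage to process all time steps in a single tensor pass.

4. **Spiking convolution with an adaptive threshold.** Each layer of
   non-leaky integrate-and-fire neurons computes membrane potentials
   $V_i(t) = \sum_j W_{j,i} S_j(t)$ as a valid cross-correlation per time
   slice, batch-normalizes them per output channel, and fires wherever the
   potential reaches the layer threshold (the $\ge$ convention: a neuron
   exactly at threshold fires). In adaptive mode the per-sample training
   threshold is the mean of the potential tensor, and the test-time
   threshold is tracked across training by the exponential moving average
   $\theta_{\text{test}} \leftarrow M\,\theta_{\text{test}} +
   (1 - M)\,\theta_{\text{train}}$ with momentum $M = 0.9$, initialized to
   the first training image's threshold. Lateral inhibition then keeps, at
   each location, only the channel that fired earliest (ties: larger
   potential, then lower channel index).

5. **Competition and plasticity.** A winner-take-all scan selects up to
   $k$ neurons per sample (earliest spike, then highest potential); each
   selection inhibits the whole winning feature map and a Chebyshev
   neighborhood across maps. Winners' kernels are updated by a simplified
   STDP rule that depends only on spike order:
   $\Delta W = A^{\pm} (W - LB)(UB - W)$, potentiating synapses whose
   presynaptic neuron fired no later than the postsynaptic one
   ($A^+ = 0.004$) and depressing the rest ($A^- = -0.003$). The
   multiplicative stabilizer freezes weights smoothly at the bounds
   $[0, 1]$. Under cumulative coding, "pre fired no later than post" is
   exactly "pre spike count $\ge$ post spike count", which is how the
   update is computed; the equivalence is verified exhaustively in the
   tests.

Layers are trained strictly in sequence (2 epochs for layer 1, 20 for
layer 2), one image at a time, with labels never used. For layer 1 only,
$A^+$ doubles every 500 training images while below 0.15, preserving the
initial $A^-/A^+$ ratio. After training, the final pooled spike wave is
compressed by a maximum over time — equal to its last slice, by
cumulativity — and flattened into a binary feature vector (2880 features
for 48×48 inputs under the reference architecture: 48 → 44 → 23 → 22 → 12
through 5×5 and 2×2 convolutions with 2×2/stride-2/padding-1 pooling).
Classification is a one-vs-rest linear SVM ($C = 2.4$) on those features,
optionally after chi-square percentile feature selection; verification
quality is summarized by FAR/FRR threshold sweeps and the equal error
rate.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| Gabor window / orientations | 15 / {3,5,7,9}π/8 | px, rad | edge channels |
| DoG window / (δ1, δ2) | 7 / (1,2), (2,1) | px | contrast channels |
| cutoff | 50 | 0–255 response | silences weak responses |
| `norm_radius` | 8 | px | local-contrast window |
| `t_max` | 15 | time steps | latency resolution |
| layer 1 | 16 maps, 5×5, kwta 5, r 2, 2 epochs | — | low-level features |
| layer 2 | 20 maps, 2×2, kwta 8, r 1, 20 epochs | — | composite features |
| threshold momentum M | 0.9 | — | test-threshold EMA |
| A+/A− | 0.004 / −0.003 | per update | STDP rates |
| weight bounds | [0, 1] | — | stabilizer support |
| C | 2.4 | — | SVM penalty |

The Gabor envelope parameters (λ, σ, γ, φ) are not dictated by the
architecture; the defaults λ = window/2, σ = 0.8λ, γ = 0.3, φ = 0 are
standard values in spiking-vision front ends, and the zero-mean
normalization makes the absolute kernel scale second-order. All are
configurable through `gabor_params()` / `filter_bank()`.

## Design choices where the design was open

- **Latency binning.** Equal-count rank bins (stable sort, lexicographic
  channel/row/column tie-break) rather than equal-width intensity bins:
  rank coding makes the spike budget per time step independent of the
  intensity histogram, which keeps early time slices informative for both
  high- and low-contrast images. A `binning = "linear"` alternative is
  provided.
- **Correlation, not convolution.** Kernels are applied without flipping,
  matching conventional "conv layer" semantics. DoG kernels are symmetric
  so this only matters for Gabor kernels at φ ≠ 0.
- **Cutoff scale.** The 0–255 cutoff is applied after rectification and
  per-channel rescaling to 0–255, since a fixed absolute cutoff is only
  meaningful on a fixed response scale. A channel whose rectified response
  is mere floating-point residue (a zero-mean kernel on a near-constant
  image) is kept silent rather than rescaled, so numerical noise can never
  become full-scale spikes.
- **Potential time indexing.** With cumulative spike tensors, potentials
  are computed from $S(t)$ at each step. The one-step-lag reading of the
  update equation would only shift every potential by one slice and waste
  the first time step.
- **Threshold source with BN.** The threshold is computed on, and applied
  to, the same tensor — the batch-normalized one when BN is enabled
  (`threshold_source = "post_bn"`, switchable). Note the degenerate
  consequence: per-sample standardization makes the post-BN tensor mean
  exactly zero, so the adaptive threshold is 0 during training and the
  EMA stays at 0. Firing then selects the above-average half of the
  potential distribution, and the adaptive mechanism's value lies in
  inference-time robustness rather than in a nontrivial trained value;
  with BN disabled, or `threshold_source = "pre_bn"`, the threshold is
  the raw potential mean and genuinely varies per sample.
- **STDP receptive-field alignment.** The presynaptic window for output
  position $(h, w)$ is `input[, , h:h+kh-1, w:w+kw-1]` — exactly the
  synapses feeding that neuron under valid convolution geometry.
- **Weight bounds.** $LB = 0$, $UB = 1$: weights are initialized at
  $0.8 \pm 0.05$ and the stabilizer $(W - LB)(UB - W)$ presupposes the
  unit interval.
- **WTA with radius 0.** Spatial inhibition is applied only for radius
  > 0; same-pixel neurons in other maps remain eligible, matching the
  selection algorithm's explicit guard.
- **Inter-layer order.** Pooling precedes cross-channel spike inhibition,
  which precedes the next convolution; pooling first preserves the
  competition geometry the winner scan assumes. Both inhibition stages
  are individually toggleable for ablation.
- **FAR/FRR definitions.** FAR is the fraction of impostor comparisons
  accepted and FRR the fraction of genuine comparisons rejected at a
  threshold — the standard biometric reading, which also makes both
  curves monotone in the threshold; the EER is linearly interpolated
  between the bracketing sweep points.
- **Persistence.** Models are stored as a JSON manifest plus per-layer
  weight CSVs: plain text, diff-able, and round-trip exact to 15
  significant digits (verified in tests).

## The synthetic generator

Benchmarks used in the field (MMCBNU_6000, FV-USM, SDUMLA-HMT) cannot be
redistributed, so the package ships a generator of vein-like images that
emulates what the method actually exploits: per-class bright curvilinear
structures on a darker noisy background with small intra-class jitter.
Each class draws a fixed template of 4 cubic-spline paths spanning a
48×48 image, rendered with a Gaussian cross-section (σ = 1.5 px, peak 200
over background 60 — veins brighter than background, as in near-infrared
ROI imagery). Each sample perturbs the template with a shift of up to
2 px, rotation up to 3°, ±10% vein-intensity jitter and additive Gaussian
noise (σ = 10), clipped to $[0, 255]$. These values were chosen once as a
plausible desk-scale emulation of benchmark ROI variability: jitter small
enough that identity is preserved, noise strong enough that single-pixel
evidence is unreliable.

All draws come from substreams keyed by (seed, class, sample), so
datasets are bit-reproducible and adding classes never perturbs existing
ones.

What the generator does *not* emulate: real NIR scattering and blur,
non-uniform illumination fields, skin texture, acquisition-device
contours, or finger-pose changes beyond small rigid motion. Passing the
end-to-end criteria on synthetic data therefore demonstrates that the
implementation learns and separates curvilinear identity patterns under
noise and jitter — not that it reproduces benchmark accuracy figures on
real sensors.

## Problem sizes and numerical notes

The packaged experiments use 10 identities × 10 samples at 48×48 with a
9/1 train/test split per identity — large enough that chance accuracy is
10% and 100 impostor scores back the EER estimate, small enough for
interactive runs (the full pipeline trains in about two minutes on one
core). Unit and property tests run oracles on deliberately tiny tensors
(images ≤ 12×12, potential tensors ≤ 5×6×6) where exhaustive nested-loop
recomputation is feasible.

Degenerate inputs are defined behaviors, not errors: an all-zero
intensity map encodes to an all-zero spike wave; a silent tensor yields
an empty winner list and no plasticity; a zero-variance BN channel
outputs zeros through the ε-guard (ε = 1e−5); local normalization guards
empty regions with ε = 1e−12. Ties are always broken deterministically
(lexicographic by channel, row, column), so the entire pipeline —
training included — is bit-reproducible from a seed, which the suite
asserts by retraining.

## Known limitations

- Two convolutional layers only; no gradient training, no leaky dynamics
  or refractory periods (cumulative coding makes membrane reset moot).
- The adaptive threshold degenerates to 0 under per-sample BN (above);
  the fixed-threshold mode is retained for ablations.
- ROI extraction assumes a roughly horizontal finger with contours
  detectable by Canny edges; its Canny parameters are configurable but
  uncalibrated against any specific acquisition device.
- One-vs-rest linear SVM scores are uncalibrated margins; EER is computed
  from them directly rather than from a template-matching protocol.

```{r example, eval = FALSE}
# a complete small experiment
data <- generate_synthetic_dataset(synthetic_spec(seed = 1)) |>
  split_dataset(n_train = 9)
out <- run_recognition_pipeline(data, atsnn_config(seed = 1))
generics::glance(out$metrics)
ggplot2::autoplot(out$metrics)
```
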