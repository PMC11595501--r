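---
title: "Methods: topographic-map sequences and hybrid 3DCNN-RNN decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topographic-map sequences and hybrid 3DCNN-RNN decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific model behind `topodecode`, the
assumptions baked into each stage, the numerical choices where the
procedure admitted more than one reasonable reading, and the limits of
what the package's own tests establish.

## 1. From EEG trials to image sequences

An imagined-speech trial is a channels × samples voltage matrix (µV),
sampled at 256 Hz for 2 s (512 samples). Scalp potential topographies are
known to remain quasi-stable for roughly 60–120 ms ("microstates") before
switching; a 125 ms window is therefore long enough to average out sample
noise while still tracking the trial's dynamics, and 16 such windows tile
a 2 s trial. The first window starts 4 ms after onset.

**Windowing arithmetic.** Sample indices are derived with
`round(ms · rate / 1000)`: at 256 Hz the window length is
W = round(32) = 32 samples and the offset is round(1.024) = 1 sample, so
frame *k* (1-based) covers 0-based samples `[1 + (k−1)·32, 1 + k·32)`.
Frame 16 would end at sample 513 and is clipped to the trial end, keeping
31 samples. The per-window statistic is the arithmetic **mean** of each
channel over the window — a window-level summary consistent with the
microstate framing — rather than an instantaneous snapshot; a snapshot is
more noise-sensitive and would make the map depend on a single sample.

**Electrode geometry.** Imagined speech is decoded from 15 frontal
channels (Fp1, AF3, Fp2, AF4, AF7, AF8, F1, Fz, F2, F7, F5, F3, F4, F6,
F8). No coordinate table is assumed from outside: the package ships a
plain-text idealized spherical 10-10 table constructed geometrically —
vertex Cz at the pole, the circumferential ring (Fpz, F7/8, T7/8, …) at
90° inclination, midline electrodes every 22.5°, and intermediate
electrodes (F3, AF3, …) by great-circle interpolation between the midline
and ring electrode of the same row at fractions 1/4, 1/2, 3/4. This is not
a digitized head shape; it is the standard schematic sphere, and it
satisfies exactly the symmetries a schematic must have (midline x = 0,
left/right mirror pairs). The head is flattened by the
azimuthal-equidistant projection (radius = inclination / 90°, azimuth
preserved), the convention of EEG topoplot software, which keeps the
radial ordering of electrode rings.

**Interpolation.** The field on a 64 × 64 raster over [−1, 1]² is
inverse-distance weighting with exponent 2 over all 15 electrodes. IDW was
chosen because it is deterministic, dependency-free, exact at electrode
positions, and — being a convex combination — provably bounded by the
electrode values, which gives sharp, testable invariants. Spherical
splines (the other common choice) extrapolate beyond the data range and
would make bit-exact golden tests implementation-dependent. Pixel centers
sit at −1 + (2i − 1)/64; pixels outside the unit disk are masked and
render white.

**Colour mapping.** Each frame's values are normalized symmetrically,
u = clamp((v + vmax)/(2·vmax), 0, 1), with vmax the maximum |windowed
value| **across the whole trial**, then mapped by a closed-form
jet-like map (R = clamp(1.5 − |4u − 3|), G = clamp(1.5 − |4u − 2|),
B = clamp(1.5 − |4u − 1|), each clamped to [0, 1]). Per-trial (not
per-frame) scaling keeps the 16 frames on one scale so the classifier can
read temporal dynamics; symmetry about zero keeps polarity information. A
consequence worth knowing: scaling a trial by any c > 0 produces identical
images (amplitude is deliberately normalized away; only spatial pattern
and relative dynamics survive). An all-zero trial falls back to vmax = 1
and renders uniformly mid-scale. 8-bit storage is emulated by
`quantize_roundtrip()` (`round(v·255)/255`), matching pipelines that save
frames as image files and reload them divided by 255.

## 2. Splitting protocol

Classes are balanced by seeded uniform downsampling to the minimum
per-class count, then split 80/20. The published per-task counts (112/28,
168/42, 280/70 from 70 trials per word) are only achievable when the split
is **stratified by class**, so stratification is the default, with the
seed recorded on the split object; per class the train count is
round(0.8 · n). There is no validation set in this protocol and no k-fold
cross-validation (a deliberate choice at the reference scale because of
training cost); consequently early stopping during training monitors the
training loss.

## 3. The hybrid models

All three variants share the convolutional stack

```
input (16, 64, 64, 3)
→ Conv3D(16, 3×3×3, ReLU, same) → MaxPool3D(2×2×2)
→ Conv3D(32, 3×3×3, ReLU, same) → MaxPool3D(2×2×2)
→ Conv3D(64, 3×3×3, ReLU, same) → MaxPool3D(2×2×2)   # → (2, 8, 8, 64)
→ Flatten (8192) → Reshape (16 timesteps × 512)
```

and differ only in the recurrent head: a single 64-unit LSTM keeping its
final state; two stacked 64-unit LSTMs (the first returning its full
sequence); or a bidirectional pair of 64-unit LSTMs whose final states are
concatenated (128 features). The head output passes through 40 % dropout
and a dense softmax over the classes.

Choices the architecture description leaves open, fixed here:

* **Conv activation.** The textbook formulation of 3D convolution is
  written with tanh, but the architectures specify ReLU for every layer;
  the activation is a per-layer parameter defaulting to ReLU.
* **Flatten/reshape order.** The (2, 8, 8, 64) volume is flattened in
  row-major order (channel index fastest) and cut into 16 contiguous
  512-vectors. Any fixed order satisfies the stated 8192 = 16 × 512
  arithmetic; this one is documented and frozen. Each "timestep" the LSTM
  sees is therefore a learned feature block, not literally one input
  frame — the reshape re-imposes a 16-step sequential structure on the
  pooled features.
* **Pooling.** Max pooling, non-overlapping stride-2: the only reading
  under which 16 → 8 → 4 → 2 and 64 → 32 → 16 → 8.
* **BiLSTM merge.** Concatenation of final forward and backward states
  (the standard default, giving the 128-dim head).
* **Dropout placement.** After the recurrent head only, rate 0.4.
* **Output layer.** A single dense softmax with no hidden layer before it.
* **Initialization.** Seeded fan-in schemes — He-normal for the ReLU
  convolutions, Glorot-uniform for recurrent and dense weights, forget-gate
  bias 1 — so every build is bit-reproducible from its seed.

Parameter counts are fixed integers per variant (218,370 for `lstm`;
251,394 for `stack_lstm`; 366,210 for `bilstm` at 2 classes); only head
parameters differ across variants.

**Implementation and verification.** No deep-learning framework is used:
conv/pool forward and backward passes are RcppArmadillo (im2col + GEMM),
LSTM BPTT, dropout, Adam and softmax/cross-entropy are base R. Correctness
rests on two independent routes in the test suite: naive septuple-loop
convolution and direct gate-formula LSTM evaluators as oracles, and
central-difference numerical gradient checks through the *entire* network
(worst relative error < 2 × 10⁻⁷ across all three variants).

## 4. Training and evaluation

Adam (lr 1e-4, batch 32) minimizing categorical cross-entropy — the loss
implied by a softmax output — with shuffling and dropout drawn from a
private seeded RNG stream, so a (seed, data, config) triple reproduces the
run bit-for-bit. Epoch budget and stopping are implementation choices: 50
epochs maximum with early stopping (patience 10) on training loss, both
configurable. Evaluation is subject-dependent — one model per subject —
with per-subject accuracy 100·correct/total and the cross-subject
arithmetic mean; tables print accuracies rounded half-up (2 decimals for
subjects, 1 for averages), while full precision is kept internally.

## 5. The synthetic generator: what it emulates, what it does not

`generate_trials()` draws trials from a rank-1 spatiotemporal model:
class *c* contributes `amplitude · pattern_c[e] · env_c(t)` plus white
Gaussian noise. `pattern_c` is a fixed unit-norm weight vector over the 15
electrodes (redrawn from a seeded stream until |correlation| < 0.7 with
every earlier class); `env_c` is a 1 s Hann window centered at a
class-specific latency spread over [0.25, 0.75] of the trial; the noise
variance is set so signal power / noise power equals the requested SNR
(default 5, the regime in which the pipeline should separate classes
clearly; amplitude 10 µV, a typical scalp EEG scale). Defaults otherwise
mirror the reference recording geometry: 256 Hz, 2 s, 70 trials per class,
the 15 frontal channels.

This stated world gives classes that differ in *where* and *when*
activity peaks — exactly the two feature families the 3D-convolutional and
recurrent parts are meant to capture — and it is deliberately easy at
SNR 5. What it does **not** contain: 1/f spectra, alpha rhythms, trial-to-
trial latency jitter, volume-conduction mixing, artifacts, or any
inter-subject variability structure. A green end-to-end test therefore
establishes that the implementation is correct and that the pipeline can
recover known spatiotemporal class structure; it says nothing about
accuracy on real imagined-speech EEG, where reference accuracies are far
from ceiling (e.g. ~78 % for the best word pair, ~45 % for five classes).

## 6. Numerical and degenerate-input conventions

* Frame indices are 1-based in the R API; the underlying sample
  arithmetic is 0-based as documented above.
* A pixel center within 1e-9 of an electrode takes the electrode's value
  (IDW's limit value); duplicate electrode coordinates are an error.
* An all-zero trial renders at mid-scale (vmax fallback 1.0).
* `snr = Inf` is allowed and yields noiseless, class-identical trials.
* Ties in `max.col` classification resolve to the first class.
* Printed tables round half-up, the convention of the published tables.
* All RNG consumption (balancing, splitting, patterns, noise, shuffling,
  dropout, initialization) goes through private seeded streams that save
  and restore the caller's RNG state.

## 7. Desk-scale protocol for the end-to-end criterion

One fwd+bwd pass of a 32-trial batch at the full 64 × 64 raster costs
roughly 13 s on a single CPU, so the reference training protocol is a
GPU-scale affair. The end-to-end acceptance test and the examples
therefore run the identical pipeline at a 32 × 32 raster (4× cheaper;
every architectural ratio unchanged) with learning rate 1e-3 compensating
for a step budget ~100× smaller than a full training run, and ≤ 20–25
epochs. These scale-downs were fixed from the runtime measurement before
any accuracy was measured; the ≥ 90 % recovery bar, SNR 5 and 40
trials/class of the stated world are untouched.

## 8. Known limitations

* IDW with exponent 2 produces flat plateaus near electrodes and is not
  the spherical-spline interpolant of classical topoplot figures; images
  are qualitatively similar but not pixel-identical to such figures.
* The montage is schematic; no per-subject digitization is supported.
* Per-trial colour normalization discards absolute amplitude by design.
* Training is CPU-bound R/C++; it is meant for desk-scale experiments and
  correctness work, not for reproducing GPU-scale benchmark accuracies.
* The container format is R-serialized (RDS); an HDF5 adapter would be a
  thin translation of the documented field layout but is not included.
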