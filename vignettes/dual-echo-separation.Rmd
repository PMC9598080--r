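---
title: "Dual-echo Dixon water-fat separation: model, solver, and phantoms"
author: "DualDixon maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-echo Dixon water-fat separation: model, solver, and phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DualDixon)
```

# The problem

Two-point (dual-echo) Dixon imaging acquires an in-phase and an
out-of-phase gradient-echo image and reconstructs separate water and fat
images from the known chemical-shift phase evolution between the echoes.
Per pixel the signal model is

$$S_1 = (W + C_1 F)\,e^{i\phi_1}, \qquad S_2 = (W + C_2 F)\,e^{i\phi_2},$$

with $W, F \ge 0$ the water and fat amplitudes,
$C_k = e^{i 2\pi \Delta f\, \mathrm{TE}_k}$ the fat dephasing factor at
echo time $\mathrm{TE}_k$ ($\Delta f$ the fat frequency offset in Hz), and
$\phi_k = \phi_0 + 2\pi b_0 \mathrm{TE}_k$ the receive phase plus the
phase accrued from the B0 field-map error $b_0$ (Hz). The magnitudes alone
determine $(W, F)$ only up to a swap; each of the two amplitude orderings
implies its own inter-echo phasor candidate

$$P_k = \frac{\overline{S_1} S_2}{(W_k + \overline{C_1}F_k)(W_k + C_2 F_k)},$$

and choosing the wrong candidate exchanges water and fat. Field-map
estimation is therefore a per-pixel binary choice, regularized by the
physical smoothness of $b_0$.

# The selection energy and its solver

Selection is posed as a binary quadratic program. With one-hot selection
vectors $X(r)$ the energy is
$f(x) = \sum_{r,s} X(r)^\top V(r,s) X(s)$, where for $s$ in the neighbor
set of $r$,

$$V_{ij}(r,s) = \frac{\min(|S_1(r)|, |S_1(s)|)}{d(r,s)}\,
  \lvert P_i(r) - P_j(s)\rvert^2 ,$$

and $V(r,s) = 0$ otherwise. The magnitude weight silences background; the
distance weight makes agreement between near pixels matter more. Two
conventions here were genuinely open and are package decisions:

* **Distance weighting divides.** A smoothness weight must decay with
  pixel separation, so $d(r,s)$ divides the magnitude weight; a
  `distanceWeight = "multiply"` switch exists for sensitivity analyses.
* **Neighbor set.** The default neighborhood is every offset within
  Euclidean radius 4 (48 offsets, 2D). The radius is configurable through
  `neighborSpec()`; border neighbors are dropped (no padding, no
  wraparound), and each unordered pair is counted twice (both ordered
  directions), consistently in the solver and the exhaustive oracle.

## Projected power iteration

At one-hot points the pair penalty decomposes as
$V_{ij} = 2w - 2w\,\mathrm{Re}(P_i(r)\overline{P_j(s)})$ with $w$ the
magnitude/distance weight, so minimizing $f$ is equivalent to maximizing
the phasor-agreement form $x^\top A x$,
$A_{ij} = w\,\mathrm{Re}(P_i(r)\overline{P_j(s)})$ (the $2w$ part is the
same for every labeling). `projectedPowerSelect()` exploits this in two
phases:

1. **Relaxed consensus.** A projected power iteration $Y \leftarrow A X$
   over per-pixel non-negative 2-vectors of unit Euclidean norm, started
   from the uncommitted uniform state $(1/\sqrt2, 1/\sqrt2)$. Negative
   components are clamped, each pixel renormalized; a vanished vector
   keeps its previous state and exact ties keep the previous label. The
   uniform start matters: one-hot states are fixed points of the clamped
   iteration, whereas the uniform state lets phasor consensus propagate
   outward from high-signal regions. A spectral shift was evaluated and
   rejected — any shift large enough to guarantee monotonicity of the
   relaxed objective also freezes the iteration at its starting corner.
2. **Monotone discrete refinement.** The binarized consensus and the two
   canonical one-hot labelings (all candidate 1, all candidate 2) are each
   polished by coordinate sweeps over classes of mutually non-adjacent
   pixels (pixels congruent modulo a stride exceeding the largest offset),
   with the pull vector maintained incrementally. Every accepted flip
   strictly decreases $f$, so the recorded energy history is
   non-increasing, and the reported energy always equals
   `selectionEnergy()` recomputed from the labels. On graphs with few
   pixels the consensus phase has little to propagate, so a size-adaptive
   number of seeded random restarts (none at image scale) is refined as
   well; the lowest-energy labeling wins.

`bruteForceSelect()` enumerates all $2^N$ labelings for graphs of at most
20 pixels and serves as the independent optimality oracle in the tests;
ties resolve to the lexicographically smallest label vector.

## Multiresolution acceleration

For speed the selection can run on block-mean downsampled echoes
(`downsampleFactor`, default 1 in the functions, 2D integer factors). The
selected low-resolution phasor field is bilinearly upsampled (real and
imaginary parts, then renormalized; pixel-center alignment), and at full
resolution each pixel re-selects the candidate phasor closest to the
upsampled field before the final linear amplitude solve. This re-solve is
exact in the noiseless limit — the candidates at full resolution are exact,
only the binary choice is guided by the coarse field — which is why the
pipeline prefers it over upsampling the coarse water/fat images directly
(that literal route remains available behind `upsampleAmplitudes = TRUE`).
Both resize primitives are written out explicitly in the package because
their coordinate conventions (block means with partial trailing blocks,
pixel-center bilinear mapping) are part of the algorithm's contract and
are asserted by tests. As a worked number, pooling $\sim0.6 \times 0.6
\times 1\,$mm$^3$ voxels into $6 \times 6 \times 6\,$mm$^3$ cells reduces
the voxel count by `voxelReductionFactor(c(0.6, 0.6, 1), c(6, 6, 6))`
$= 600$.

# Acquisition defaults and units

Echo times are milliseconds everywhere in the interface and seconds only
inside formulas; B0 maps are Hz. The default acquisition is 3 T with
$\mathrm{TE}_1 = 2.23$ ms (in-phase) and $\mathrm{TE}_2 = 1.31$ ms
(out-of-phase); a second out-of-phase cluster at 3.35 ms is exercised by
the training-set generator. The fat spectral model is a single resonance
at $-3.5$ ppm (fat below water, phase accrual $e^{+i2\pi\Delta f
\mathrm{TE}}$), giving $\Delta f = -3.5 \times 42.577 \times B_0$ Hz.
These in-phase/out-of-phase echo times are not exactly consistent with any
single shift value — clinical TE pairs never are — so the single-peak
default is a documented assumption, configurable in
`acquisitionParams()`; multi-peak fat modeling and $R_2^*$ are out of
scope. Amplitude outputs are magnitudes (clinical display convention); the
complex solution feeds the reported phase-consistency residual. All
operations are per 2D slice; volumes are loops over slices.

Degenerate pixels — zero signal, or noise pushing the candidate product or
discriminant negative — are clamped to zero amplitude, given unit phasor,
flagged in the degenerate mask, and left unselected (label 0) in results,
rather than raising errors: the noise floor of a magnitude image is data,
not an exception.

# The synthetic phantom module

No clinical data ship with the package; every empirical statement its
tests make is about seeded synthetic phantoms emulating the structure the
method assumes:

* piecewise-smooth elliptical anatomy: a water-dominant interior
  (amplitude $\approx 1$ with $\pm 15\%$ smooth texture), an optional
  fat-dominant rim (the subcutaneous-fat analogue; fat fraction $\approx
  0.9$), and mixed inclusions at fat fraction 0.35 — distinct enough from
  0.5 that the candidate phasors of marrow-like tissue stay separable;
* a smooth B0 map: a random polynomial (order 2 by default) scaled to a
  maximum amplitude in Hz (60 Hz default, a realistic 3 T shim residual),
  plus an optional metal-like term with the far-field dipole pattern
  $\Delta B \propto (3\cos^2\theta - 1)/\max(d, d_\mathrm{core})^3$,
  clipped inside a small core;
* a low-order polynomial receive phase and i.i.d. complex Gaussian noise
  (default $\sigma = 0.03$ per component, about 30 dB tissue pSNR at unit
  amplitude).

Defaults are 64 x 64 slices for tests and examples. Two properties define
the presets: in the `"default"` regime every noiseless phantom separates
exactly ($< 10^{-6}$) through the classical pipeline — the generator must
not produce inherently ambiguous cases — while the `"swap"` preset (thick
fat rim, 150 Hz B0, a 250 Hz dipole) makes the no-smoothness baseline
(`baselineSelect()`, which always picks the lower-fat candidate) mislabel
well over 10% of unambiguous pixels. Swapped pixels are counted against
ground truth, excluding background and pixels with $|W - F|$ below 10% of
the tissue amplitude, where the notion of a swap is ill-defined.

What the phantoms do **not** emulate: anatomical realism, k-space
sampling and parallel-imaging reconstruction, coil-array geometry beyond
smooth random sensitivities, $T_1/T_2^*$ weighting, motion, and partial
volume at tissue interfaces. Passing tests therefore demonstrate
correctness of the algorithms under the model's own assumptions, not
clinical performance. Multicoil simulation applies smooth random complex
sensitivities per coil; `compressCoils()` performs SVD coil compression in
image space (equivalent to the k-space operation under linearity),
projecting both echoes with the same singular-vector matrix so the
inter-echo phase — the quantity the whole method rests on — is preserved.

# The learned route

The network is a densely connected hierarchical encoder-decoder with two
output heads. Inputs are six channels: $|S_1|/m$, $|S_2|/m$, wrapped
phases divided by $\pi$, and two constant echo-time maps in units of
10 ms (clinical TEs then sit around 0.1-0.5, the same order as the other
channels). The magnitude scale $m$ is the 99th percentile of $|S_1|$
pooled over the training set, stored with the model and used to
de-normalize predictions. Wrapped phase is the paper-faithful encoding of
"magnitude and phase" inputs; wrap discontinuities are a known hazard,
and the targets here are magnitudes, so no sin/cos encoding is used by
default.

Per hierarchical level there are three 3 x 3 convolution blocks with
PReLU; the level input and every block output are concatenated and
projected back to the level width by a 1 x 1 convolution — the concrete
reading of dense local shortcuts used here, chosen because it keeps level
widths fixed and makes the parameter count analytic. Downsampling and
upsampling are 2 x 2 stride-2 convolutions and their transposes; global
shortcuts concatenate matching encoder/decoder levels, fused by 1 x 1
convolutions; the two 1 x 1 heads are linear, with predictions clamped to
non-negative after de-normalization (the clamped fraction is reported).
The full-scale preset has 5 levels with 16/32/64/128/256 channels; the
`"desk"` preset keeps the identical topology at 3 levels with 8/16/32
channels (58,562 parameters), which trains in minutes on one CPU. All
layers (forward and backward) are implemented on im2col/GEMM primitives
in the package's own compiled code and verified against finite
differences in the test suite.

Training uses He initialization (PReLU slopes 0.25), the $\ell_1$ loss,
and Adam at learning rate 0.001 ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$) with no schedule beyond Adam's own adaptivity and no
augmentation. The standard desk run trains on 256 phantoms (64 x 64,
varied B0 severity 20-150 Hz, occasional metal, both out-of-phase TE
clusters mixed so the echo-time conditioning channels are live) against
the phantom ground truth, with 64 held-out phantoms for validation; 12
epochs at batch size 8 take the validation $\ell_1$ (in normalized units)
well below 0.07 with mean per-image water correlation above 0.98. Problem
sizes were chosen so the whole standard run completes in a few minutes;
the topology, not the capacity, is the point of the desk preset. Whether
the targets should be magnitudes or complex images was an open choice;
magnitudes match the classical pipeline's output convention.

# Metrics

`evaluatePair()` pins the evaluation conventions: both images are scaled
by the 99th percentile of the reference (making all four metrics
invariant under joint positive rescaling), Pearson correlation and mean
absolute error are computed over all pixels (an optional mask argument
exists; none is applied by default), SSIM uses the standard 11 x 11
Gaussian window ($\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, data range 1
after scaling) averaged over the fully supported interior, and pSNR is
$20\log_{10}(1/\mathrm{rmse})$ capped at 99 dB so identical images have a
defined value. The normalization rule and cap are package conventions —
published numbers rarely state theirs — and are recorded inside every
`MetricsRecord`.

# Reproducibility and I/O

Every stochastic stage takes a seed; multi-stage runs fan one base seed
out by stage-name hashing (`stageSeed()`), so stages are independent yet
jointly reproducible, and `runReferencePipeline()` writes a manifest with
config, seeds, per-stage wall-clock and MD5 hashes of outputs. Two runs
with the same seed produce byte-identical metrics files. Complex images
are stored as real/imaginary float pairs — either a single-file archive
with pinned key names or NIfTI pairs with a YAML sidecar — because NIfTI
complex support is not portable across tools; results are written as
uncompressed NIfTI so output bytes are deterministic. A thin command-line
front end (`inst/cli/dixonsep.R`) chains `simulate`, `separate`, `train`,
`predict` and `eval` over these formats.

# Known limitations

* The selector is a local heuristic for an NP-hard problem: on tiny
  random graphs it matches the exhaustive oracle in 97-100% of seeded
  instances (never observed above 1.01 times the optimal energy), but no
  global guarantee exists.
* Single-peak fat, no $R_2^*$, 2D neighbor systems only; three-plus-echo
  separation is out of scope.
* The `"auto"` global swap correction encodes a subcutaneous-fat-rim
  prior; anatomies without a fat rim (or water-rim phantoms) defeat it,
  which is why `"keep"` is the CLI default.
* Network results are desk-scale statements about synthetic phantoms; no
  claim transfers to clinical images without retraining and revalidation.
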