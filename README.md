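# DualDixon

Two-point (dual-echo) Dixon water–fat separation for chemical-shift-encoded
MRI, in R. The package is aimed at MR-physics and image-reconstruction work:
it provides the classical model-based pipeline (candidate enumeration plus
field-map phasor selection by binary quadratic optimization), a seeded
synthetic phantom module to test it against, a compact learned alternative
(a densely connected hierarchical encoder–decoder trained on those
phantoms), and pinned image-fidelity metrics.

## The model

Per pixel, the in-phase and out-of-phase echoes obey

    S1 = (W + C1 F) exp(i φ1),   S2 = (W + C2 F) exp(i φ2)

with water/fat amplitudes `W, F ≥ 0`, fat dephasing factors
`Ck = exp(i 2π Δf TEk)`, and phases `φk = φ0 + 2π b0 TEk` driven by the B0
field-map error `b0` (Hz). Magnitudes determine `(W, F)` only up to a swap;
each ordering implies its own inter-echo phasor candidate

    Pk = conj(S1) S2 / ((Wk + conj(C1) Fk)(Wk + C2 Fk)),

and picking the wrong one swaps water and fat. The package resolves the
choice by minimizing the smoothness energy `f(x) = Σ X(r)' V(r,s) X(s)`,
where `V(r,s) = min(|S1(r)|,|S1(s)|)/d(r,s) · |Pi(r) − Pj(s)|²` over a
configurable neighbor set (48 offsets within radius 4 by default), solved
with a projected power iteration plus monotone discrete refinement
(`projectedPowerSelect()`), optionally on block-mean downsampled images
with bilinear phasor upsampling for speed. An exhaustive oracle
(`bruteForceSelect()`) backs the solver in the tests. The learned route
(`trainModel()` / `predictWaterFat()`) maps six input channels — both echo
magnitudes and wrapped phases plus two constant echo-time maps — straight
to water/fat images.

## Worked example

```r
library(DualDixon)

params <- acquisitionParams()          # 3 T, TE 2.23 / 1.31 ms, -3.5 ppm fat
truth  <- generatePhantom(shape = c(64, 64), b0AmplitudeHz = 90, seed = 7)
img    <- simulatePhantom(truth, params, noiseSigma = 0.03, seed = 1)

res <- separateDualEcho(img, downsampleFactor = 2)
evaluatePair(water(res), water(truth))
evaluatePair(fat(res),   fat(truth))
swappedFraction(res, truth)
swappedFraction(baselineSelect(img), truth)
```

prints

```
MetricsRecord: corr=0.9985, l1=0.0226, ssim=0.5347, psnr=31.40 dB (n=4096)
MetricsRecord: corr=0.9967, l1=0.0272, ssim=0.5822, psnr=29.71 dB (n=4096)
[1] 0
[1] 0.328125
```

Reading: against ground truth, the separated water/fat maps correlate at
0.997–0.999 with a normalized mean absolute error of about 0.02–0.03 (the
residual is the 30 dB acquisition noise; SSIM is depressed by that same
per-pixel noise), and **no** pixels are water/fat-swapped — while the
no-smoothness baseline, which always trusts the water-dominant candidate,
swaps 33% of this phantom (its entire subcutaneous-like fat rim). On
noiseless phantoms the pipeline recovers the ground truth to below 1e−6.

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "dixonsep.R", package = "DualDixon"))')
Rscript $CLI simulate --out sim --n 4 --seed 1
Rscript $CLI separate --input sim/case001.rds --output out/case001 --downsample 2
Rscript $CLI eval     --pred out/case001 --ref sim/case001 --out metrics.json
```

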