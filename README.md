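# klrcs — kernel low-rank compressed sensing for preclinical diffusion MRI

`klrcs` is an R package for accelerating 3-D diffusion-weighted MRI by
undersampling k-space and reconstructing with structural priors, aimed at
the preclinical regime (multi-hour, multi-coil, ex-vivo acquisitions) where
scan-time reduction also limits resonance-frequency drift. It is built
around a **kernel low-rank (KLR) reconstruction** for complex multi-coil
data and ships everything needed to study it end to end on synthetic data:
undersampling-mask design, a multi-coil k-space simulator, a conventional
compressed-sensing baseline, diffusion-tensor mapping, and comparison
metrics.

## The methods in brief

Only the two phase-encode axes are undersampled. A `MaskSet` holds one
binary PE-plane pattern per volume (Monte-Carlo variable-density or
Poisson-disk; single- or multi-mask; b0 volumes optionally fully sampled,
in which case the per-direction factor follows
`1/AF = f + (1-f)/AF_diff`, `f = n_b0/(n_b0+n_dir)` — e.g. 3 b0 + 30
directions at AF 4 need `AF_diff = 40/7 ≈ 5.71`).

The KLR reconstruction assumes each voxel's signal series across diffusion
volumes lies near a low-dimensional manifold. A Gaussian-kernel PCA model is
self-trained on the fully sampled k-space centre, and reconstruction
alternates manifold denoising (projection + fixed-point preimage) with hard
k-space data consistency. Complex data are handled either by **LRP maps**
(low-resolution phases from the k-space centre reattached to denoised
magnitudes) or **composite KPCA** (training on stacked real/imaginary
parts); a magnitude-filtered variant exists for comparison only. The
baseline (`csReconstruct`) is per-volume regularised SENSE with
L1-wavelet (db4) and total-variation penalties minimised by monotone FISTA
(defaults λ1 = 0.005, λ2 = 0.002, 200 iterations). FA/MD maps come from a
log-linear tensor fit; comparisons use subpixel rigid registration, percent
error, 3-D SSIM, brain-median summaries and peak SNR.

## Worked example

```r
library(klrcs)

# simulate a 32 x 32 x 16 tensor phantom, 3 b0 + 12 directions, 4 coils
phantom <- makePhantom(c(32, 32, 16))
scheme  <- makeScheme(nB0 = 3, nDir = 12, b = 1000)
coils   <- makeCoilProfiles(c(32, 32, 16), 4, seed = 1)
ks      <- simulateKspace(dwiSignal(phantom, scheme), coils, scheme,
                          phaseOrder = 2, noiseSigma = 0.004, seed = 1,
                          centerHalfwidths = c(2, 1))

# undersample at AF 2 (multi-mask Monte-Carlo) and reconstruct
masks <- buildMaskSet(acquisitionGrid(ks), scheme, af = 2,
                      fsB0 = FALSE, seed = 1)
usk   <- retrospectiveUndersample(ks, masks)
rec   <- klrReconstruct(usk, masks, variant = "lrp", seed = 1)

# FA/MD error against the fully sampled reference
mask <- brainMask(phantom)
fs   <- zeroFillRecon(ks)
ref  <- scalarMaps(fitTensor(fs, scheme, mask))
est  <- scalarMaps(fitTensor(rec$volumes, scheme, mask))
e    <- errorMap(mdMap(est), mdMap(ref), mask)
s    <- ssimMap(mdMap(est), mdMap(ref), mask)
medianMetrics(e, s, mask)
```

On this seeded phantom the example prints

```
$medianError
[1] 2.926933

$medianSSIM
[1] 0.9924821
```

— a median MD error of about 2.9% with a median SSIM of about 0.993 for the
KLR reconstruction, against roughly 4.4% / 0.983 for the plain zero-filled
reconstruction of the same undersampled data: the KLR prior recovers most of
what undersampling at AF 2 destroys. `achievedAF(masks)` confirms the
realised acceleration is within 2% of the target.

The whole pipeline is also available as one call
(`runExperiment(experimentConfig(...))`, which writes reconstructions,
FA/MD maps and a metrics CSV) and as a thin command-line dispatcher
(`inst/scripts/klrcs.R`) with subcommands `phantom`, `mask`, `undersample`,
`recon-klr`, `recon-cs`, `dti`, `evaluate` and `experiment`.

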