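# cupflim

Snapshot compressive reconstruction and fluorescence-lifetime fitting for
widefield FLIM acquired by compressed ultrafast photography (CUP).

## The problem

Widefield fluorescence lifetime imaging (FLIM) of non-repeatable transient
events needs the whole decay movie from a *single* exposure. A CUP system
gets it by imaging the scene through a fixed binary mask, sweeping the coded
image down a streak camera's detector (one row per frame) and integrating,
while a beam-splitter arm records the plain time integral on an external
CCD. That leaves two 2D measurements of one 3D cube `I(x, y, t)`:

```
E_s = C S T I        (coded, sheared, integrated — streak camera)
E_c = ∫ I dt         (unsheared time integral — external CCD)
```

Recovering the cube is an ill-posed inverse problem,

```
min_I ||A_s I − b_s||² + μ ||A_c I − b_c||² + λ Ψ(I),
```

solved here by plug-and-play generalized alternating projection (PnP-GAP):
each iteration applies an exact Euclidean projection onto the
measurement-consistent set (both Gram operators are diagonal, so the
projection is closed-form), then a TV-family prior step implemented as a
dual clip update, then an optional second-stage denoiser plugin. The prior
family covers TV, TGV, 3DTV, TpV and the combined second-order
spatio-temporal ℓp prior

```
Ψ(u) = ( Σ |Δ²_i u|^p + |Δ²_j u|^p + τ |Δ²_t u|^p )^(1/p),   0 < p < 1,
```

with defaults λ = 0.07, μ = 0.1, τ = 0.2, p = 0.8, 250 iterations. Per-pixel
lifetimes are then fitted to the reconstructed decays with a
mono-exponential model `A·exp(−t/τ)` (delta instrument response) by weighted
log-linear least squares with Gauss–Newton refinement.

The package is aimed at computational-imaging and FLIM researchers who want
a self-contained, fully seeded simulation-to-lifetime pipeline: forward
model with exact adjoints, solver, denoiser plugins, phantom generators,
PSNR/SSIM metrics and lifetime statistics. Arrays are indexed
`(row, column, frame)`, 1-based; the shear runs down the row axis.

## Worked example

```r
library(cupflim)

cube <- make_moving_phantom(c(32, 32), 8, "two_objects", speed = 1, seed = 1)
mask <- make_mask(c(32, 32), 0.25, seed = 2)       # 25% transmittance encoder
meas <- simulate_acquisition(cube, mask, seed = 3) # adds 1% Gaussian noise
res  <- gap_pnp(meas, mask, solver_config(n_iter = 250), ground_truth = cube)
res
#> PnP-GAP reconstruction: 32 x 32 x 8 cube, 250 iterations
#>   final streak residual: 1.344
#>   PSNR 7.603 dB (init) -> 18.82 dB (final)
quality_report(res$cube, cube)
#> Quality report over 8 frames
#>   mean PSNR: 18.821 dB
#>   mean SSIM: 0.90463
```

The initialization (`A_s' b_s`) scores 7.6 dB against the ground truth; 250
PnP-GAP iterations with the combined prior raise it to 18.8 dB / SSIM 0.90 —
the moving objects are recovered from one coded streak image plus the CCD
integral.

Lifetime recovery through the full pipeline (two-dye regime, 330 ps frames):

```r
spec <- flim_phantom_spec(c(24, 24), 16, dt = 0.33e-9,
  regions = list(list(type = "rect", rows = 3:10,  cols = 3:20, A = 1, tau = 3.9e-9),
                 list(type = "rect", rows = 14:21, cols = 3:20, A = 1, tau = 1.7e-9)),
  noise = "none")
ph    <- make_flim_phantom(spec)
mask  <- make_mask(c(24, 24), 0.25, seed = 5)
meas  <- simulate_acquisition(ph$cube, mask, "gaussian", sigma = 0.01, seed = 6)
res   <- gap_pnp(meas, mask, solver_config(n_iter = 250))
lmap  <- lifetime_map(pmax(res$cube, 0), dt = 0.33e-9)
median(lmap$tau[3:10,  3:20], na.rm = TRUE) * 1e9   # 3.916  (truth 3.9 ns)
median(lmap$tau[14:21, 3:20], na.rm = TRUE) * 1e9   # 1.764  (truth 1.7 ns)
```

Both region lifetimes come back within a few percent of the generating
values after compression, reconstruction and refitting.

A command-line front end over the same functions ships at
`inst/cli/cupflim.R` with `reconstruct`, `simulate`, `evaluate` and
`lifetime` subcommands; run it with `Rscript` and `--help`-style flags (see
the header of that file).

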