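---
title: "Snapshot compressive FLIM: model, priors, solver and lifetime fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snapshot compressive FLIM: model, priors, solver and lifetime fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupflim)
```

## The acquisition model

Compressed ultrafast photography (CUP) records an entire fluorescence video
$I(x, y, t)$ in one exposure. The scene is imaged through a fixed binary mask
(operator $T$), swept across the detector by a streak camera so that each
frame lands one row lower than the previous one (operator $S$), and
integrated during the exposure (operator $C$). A beam splitter feeds a second,
unsheared camera that records the plain time integral. The two measurements
are

$$E_s = C\,S\,T\,I, \qquad E_c = \textstyle\int I \, dt .$$

With an $n_y \times n_x \times n_t$ cube and a one-row-per-frame sweep, $E_s$
lives on an enlarged canvas of $n_y + n_t - 1$ rows (zero padding; nothing is
clipped) and $E_c$ on the original $n_y$ rows. Both operators are linear with
simple exact adjoints, and both Gram operators $A A^\top$ are diagonal: for
the streak channel the diagonal counts the squared sheared mask values
overlapping each measurement pixel (`gram_diagonal_streak()`), for the CCD
channel it is $n_t$ times the identity. This diagonal structure is what makes
the Euclidean projection below exact and cheap. Entries of the streak Gram
diagonal below $10^{-12}$ mean no coded frame touches that pixel; such pixels
contribute no correction.

Conventions used throughout: arrays are indexed `(row, column, frame)`,
1-based; the sweep runs down the row axis, top to bottom, one detector row
per frame (the canonical discretization — the sweep rate in rows per frame is
what defines $n_t$).

## Reconstruction: PnP-GAP with a TV-family prior

Reconstruction solves

$$\min_I \; \|A_s I - b_s\|_2^2 + \mu \|A_c I - b_c\|_2^2 + \lambda\, \Psi(I)$$

by generalized alternating projection (GAP): each iteration first projects
the current estimate onto the measurement-consistent set,

$$u = \frac{u_{\text{streak}} + \mu\, u_{\text{ccd}}}{1 + \mu},
\qquad u_{\text{ch}} = v + A^\top (A A^\top)^{-1} (b - A v),$$

then applies the prior as a denoising step, then an optional second-stage
denoiser plugin. Initialization is $v^{(0)} = A_s^\top b_s$. With $\mu = 0$
the projection satisfies the streak data exactly wherever the Gram diagonal
is nonzero.

### The prior family

All priors are gradient sparsity penalties built from forward differences
with zero beyond-edge values:

* **TV** — first differences along rows and columns, $\ell_1$;
* **TGV** — second differences (difference-of-differences) along rows and
  columns, $\ell_1$;
* **3DTV** — first differences including the frame axis, temporally weighted
  by $\tau \in [0, 1]$;
* **TpV** — first differences under the non-convex $\ell_p$ sum, $0 < p < 1$;
* **3DTGpV** — the combined prior: second differences along rows, columns and
  the $\tau$-weighted frame axis under the $\ell_p$ sum,
  $\big( \sum |\Delta^2_i|^p + |\Delta^2_j|^p + \tau |\Delta^2_t|^p \big)^{1/p}$.

The anisotropic (per-axis) form is used for all priors so that the $\ell_p$
members are well defined; an isotropic coupling is available as an option for
$p = 1$. The second-order operator is implemented as the composition of two
zero-padded first differences, so at the second row/column/frame it reduces
to a first difference; this keeps the transform/adjoint pair exact by
transpose composition, which the dual update requires.

### The denoising step

The prior step is a dual (Chambolle-style) clip update, warm-started across
outer iterations:

$$z \leftarrow \mathrm{clip}\!\big(z + \tfrac{1}{\alpha} \Psi v,\ \tfrac{\lambda}{2}\big),
\qquad v_1 = u - \Psi^\top z,$$

where $\mathrm{clip}(\sigma, T)$ saturates magnitudes at $T$. After every
update $\max |z| \le \lambda/2$ holds exactly. With $\lambda = 0$ the step is
a bit-exact identity.

For $p < 1$ no closed-form proximal operator exists; the clip is reweighted
per element (iteratively reweighted $\ell_1$): thresholds are
$\tfrac{\lambda}{2} w$ with $w = (|\Psi v| + \varepsilon)^{p-1}$ normalized to
a maximum of 1, so flat regions receive the full threshold while strong edges
are penalized less. Two numerical choices matter here and were set by
benchmarking reconstruction quality on seeded phantoms:

* **Dual step $1/\alpha$.** The default $\alpha$ is the stability bound of
  the configured stencil, $\sum_{\text{active axes}} 4^{\text{order}}$ — 8
  for first-order spatial (the classical value), 12 with the temporal axis,
  32/48 for the second-order variants. A fixed $\alpha = 8$ is unstable for
  second-order stencils and measurably degrades those reconstructions by
  several dB.
* **Reweighting floor $\varepsilon$.** $\varepsilon$ is scaled to the
  gradient field, $\varepsilon = 10^{-6} \max |\Psi v| + 10^{-12}$. A tiny
  absolute floor makes the weight at exactly-zero gradients dominate the
  max-normalization and collapses every other threshold, silently
  under-regularizing the $p < 1$ priors.

Remaining defaults: $p = 0.8$ (the exponent is a free parameter of the
method; any value in $(0,1)$ is accepted), $\tau = 0.2$, $\lambda = 0.07$,
$\mu = 0.1$, one dual sweep per outer iteration, 250 outer iterations. The
solver is deterministic; a seed is only consumed by stochastic plugins.

### Second-stage denoisers

The plugin registry decouples the solver from any particular denoiser. The
shipped plugins are `identity`, and `fallback` — an edge-preserving 3×3
bilateral smoother (uniform spatial window, Gaussian range kernel of width
$3 \times$ the assumed noise level) with optional replicated temporal
windowing. A `deep` slot dispatches a pretrained video denoiser; it requires
external weights and raises an explicit error naming the expected weights
path when they are absent — never a silent substitution. Everything in this
package, including all tests, runs with the weight-free plugins.

## Quality metrics

`psnr()` uses the fixed 255 peak, $10 \log_{10}(255^2 mn / \sum (x-y)^2)$;
images supplied in $[0,1]$ are placed on the 8-bit scale first, and identical
images return `Inf`. `ssim()` is the global (single-window) form computed
from whole-image means, population variances and covariance with the
standard stabilizers $c_1 = (0.01 \cdot 255)^2$, $c_2 = (0.03 \cdot 255)^2$;
a conventional 11×11 sliding-window variant is available behind a flag for
comparability, but the global form is the default and the tested one.
`quality_report()` lets the ground truth decide the scaling convention so
that the raw initialization (whose values overshoot $[0,1]$) and the final
estimate are measured on one consistent scale.

## Lifetime analysis

Each reconstructed pixel trace is modeled as $A e^{-t/\tau}$ — the
instrument response is treated as a delta function, appropriate when the
excitation pulse (hundreds of femtoseconds) is orders of magnitude shorter
than nanosecond lifetimes. The fit window starts at the per-pixel peak
(pre-peak rise excluded), keeps strictly positive samples, and requires at
least three of them. The solver is weighted log-linear least squares
(weights $y^2$, the standard variance correction after the log transform)
followed by a few Gauss–Newton steps on the original scale; noiseless
exponential data is recovered to machine precision. Degenerate pixels —
constant, non-positive, or rising traces — are marked invalid rather than
raising. Map-level statistics (`lifetime_stats()`) report the mean and
*population* standard deviation over valid pixels, and the bias against a
reference lifetime when one is supplied. The intensity threshold for fitting
defaults to 10% of the cube's global peak.

## What the synthetic generators emulate

`make_mask()` draws i.i.d. Bernoulli masks at 25% transmittance by default,
matching the encoding density of the modeled system. `make_moving_phantom()`
produces piecewise-constant objects translating orthogonally to the shear
axis — deliberately in-model for TV-family priors, with a `textured` option
for stress tests. `make_flim_phantom()` builds decay videos from region-wise
$(A, \tau)$ ground truth at `dt` = 330 ps per frame. `simulate_acquisition()`
applies the exact forward operators plus, by default, Gaussian measurement
noise at 1% of each channel's peak (a Poisson photon-noise mode exists for
photon-limited realism).

What these phantoms do **not** contain: optical blur, sweep nonlinearity,
photocathode response, texture, or multi-exponential decays. Passing tests on
them therefore validates the algebra, the solver contract, and parameter
recovery in-model — not performance on real streak-camera data.

A consequence worth stating plainly: on strictly piecewise-constant phantoms
the plain TV prior is exactly in-model and is measured here to edge out the
combined second-order prior by about 1 dB (second differences do not
penalize the smooth ramp-like artifacts that first differences remove). The
combined prior's advantage reported for natural video — which contains the
smooth shading that second-order penalties favor — does not transfer to this
phantom class; the package reports the measured ordering as is.

## Problem sizes and reproducibility

The shipped studies use 32×32×8 phantoms with 25% masks and 250 iterations
(five seeds per condition), a 24×24×16 two-lifetime phantom
($\tau$ = 3.9 ns and 1.7 ns, the two-dye regime) for the end-to-end
simulate–reconstruct–fit check, and cubes up to 6×6×4 for dense-matrix
operator oracles. These sizes were chosen so the whole study re-runs in
well under a minute on one core while every phenomenon of interest —
projection exactness, prior ordering, lifetime bias — is already visible at
that scale. Every stochastic component is seeded; repeated runs are
bit-identical.

```{r example, eval = FALSE}
cube <- make_moving_phantom(c(32, 32), 8, "two_objects", speed = 1, seed = 1)
mask <- make_mask(c(32, 32), 0.25, seed = 2)
meas <- simulate_acquisition(cube, mask, seed = 3)
res <- gap_pnp(meas, mask, solver_config(n_iter = 250), ground_truth = cube)
res$history[res$iterations, ]
```

## Known limitations

* The forward model is the idealized mask–shear–integrate composition; no
  optical point-spread function or sweep nonlinearity.
* The non-convex $\ell_p$ penalty is handled by reweighted clipping, not an
  exact proximal map (none exists in closed form); the $p = 1$ path is
  classical Chambolle clipping, bit for bit.
* The second-order penalty is the plain linear difference-of-differences; no
  auxiliary-field total generalized variation.
* Mono-exponential fitting only; no phasor or multi-exponential analysis, no
  IRF deconvolution.
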