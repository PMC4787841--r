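---
title: "Joint ring-artifact correction in iterative tomographic reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint ring-artifact correction in iterative tomographic reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ringtomo)
```

## The problem

Parallel-beam tomography measures a sinogram $d$ — one row of detector
readings per projection angle $\theta$ — and asks for the slice $x$ with
$P x \approx d$, where $P$ is the forward projector. Detector defects
(dead pixels, dust on the scintillator, drifting gain) add offsets to
individual detector bins that are nearly constant in $\theta$. In the
sinogram these are vertical stripes; after reconstruction they become
concentric rings centred on the rotation axis, which can dominate the
image of a weakly absorbing specimen.

The classical remedies either filter the sinogram before reconstruction
(and risk damaging genuine structure that happens to be smooth along the
angle) or filter rings out of the reconstructed slice (and risk deleting
genuinely annular features of the specimen). `ringtomo` instead makes the
artifact part of the reconstruction model. The data are explained as

$$ d \;\approx\; P x + R u, $$

where $u$ is a **ring vector** with one entry per detector bin and
$R$ replicates it across all angle rows. The slice and the ring vector are
estimated jointly:

$$ \min_{x,u}\; \tfrac12\,\langle P x + R u - d,\; M\,(P x + R u - d)\rangle
   \;+\; \beta\,\mathrm{TV}(x) \;+\; \beta_r \lVert u\rVert_1 . $$

The L1 penalty on $u$ keeps the stripe component sparse — only bins that
behave like defective detector elements acquire a nonzero offset — while
the Total Variation (TV) prior keeps the slice piecewise smooth with sharp
edges. $M$ is an optional ramp-filter preconditioner discussed below. The
acquired data are never modified: at the end the decomposition returns the
slice together with the identified per-bin offsets, and
`corrected_sinogram = d - R u` is available for inspection.

Because the squared norm is separable across the two blocks, a FISTA
iteration splits cleanly: one gradient step on the fidelity for both
blocks, then a TV proximal step (an inner dual denoising solve) on the
image block and a closed-form soft threshold on the ring block, followed
by the usual FISTA momentum. The same construction works when the spatial
prior is patch sparsity in a learned dictionary; there the non-smooth part
is L1 in both blocks, both proximal steps are soft thresholds, and a
single FISTA loop suffices (`reconstruct_dl_rings()`).

## Operators and numerical choices

**Projector.** `project()` is a Joseph-style ray driver: each ray is
sampled once per crossed row (or column, whichever axis is better aligned
with it), with linear interpolation across the other axis and a per-step
path-length weight. `backproject()` executes the identical loops with
gather replaced by scatter, so the pair is adjoint *to rounding error* —
the dot-test residual is at the $10^{-16}$ level. This matters because
FISTA's convergence theory assumes a true adjoint pair; an independent
pixel-driven backprojector would make the "gradient" only approximately a
gradient. The image is centred at pixel $((N-1)/2, (N-1)/2)$, detector
bins are 0-based, the rotation centre defaults to $(n_\mathrm{bins}-1)/2$,
angles live in $[0, \pi)$, and rays leaving the image support contribute
zero. One practical consequence: line integrals (and hence the per-row
mass) are only complete when the detector spans the image diagonal —
with `n_bins` equal to the image side, the corners of the square fall
outside the detector at oblique angles.

**Ramp filter and preconditioning.** `ramp_filter()` convolves each row
with the band-limited spatial-domain ramp kernel ($1/4$ at lag 0,
$-1/(\pi^2 n^2)$ at odd lags, 0 at even lags), applied by FFT with
zero-padding to at least twice the bin count so the convolution is linear
rather than circular. Truncated to a finite window this kernel has a
small **positive** DC gain, which is kept by default: constant offsets
are attenuated, not annihilated, so the preconditioned fidelity remains
positive definite on the stripe component. Back-projected residuals
over-represent low spatial frequencies, which makes the plain normal
operator badly conditioned; applying the ramp to the residual — the
quadratic form $\langle r, M r\rangle$ above, with $M$ the ramp — evens
the spectrum out. Two consequences are used as correctness checks: with
preconditioning on and zero initialisation, the very first gradient step
is exactly the filtered back-projection direction (cosine similarity 1
in the test suite), and the ring-block gradient is the per-bin sum over
angles of the *filtered* residual, so the stripe estimate sees the same
rebalanced spectrum as the slice.

**Step size.** The gradient step is $1/L$ with $L$ the largest eigenvalue
of the augmented normal operator
$(x, u) \mapsto (P^{\!\top} M (Px + Ru),\, R^{\!\top} M (Px + Ru))$,
estimated by the power method from a seeded random start
(`estimate_lipschitz()`). The ring block contributes an
$n_\mathrm{angles} \cdot I$ diagonal through $R^{\!\top} R$, which the
augmented estimate picks up automatically. The estimate depends only on
the geometry and the preconditioning flag, so it is cached per session.
On a toy geometry small enough to assemble densely, the estimate agrees
with a dense eigendecomposition to $10^{-13}$ relative.

**TV prox.** `prox_tv()` solves the denoising subproblem
$\min_y \tfrac12\lVert y - z\rVert^2 + \lambda\,\mathrm{TV}(y)$ by
accelerated projected gradient on the Chambolle dual with the standard
step $1/8$ (the squared norm bound of the 2-D forward-difference gradient)
and FISTA momentum on the dual field. The TV convention is isotropic
forward differences with a zero difference past the last row/column
(Neumann); a $1 \times N$ input degenerates cleanly to
$\sum \lvert\Delta x\rvert$. The default inner budget is 20 iterations per
outer step — enough because the prox is re-solved from the previous outer
iterate every iteration; the test suite additionally verifies that a
200-iteration solve lands within $10^{-4}$ of a $10\times$ longer
reference run of the same dual ascent.

**Stopping and momentum.** The outer solver runs a fixed `n_iter`
(iteration counts, not tolerances, are what practitioners report for this
family of solvers); a restart-on-energy-increase variant is available but
off by default, so the energy trace may oscillate locally while the
best-so-far value is non-increasing. Initialisation is $x = 0$, $u = 0$
for reproducibility, with an FBP warm start as an option. The fidelity
carries a factor $\tfrac12$ so the gradient is exactly
$A^{\!\top}(Av - d)$; formulations without the half correspond to halving
$\beta$ and $\beta_r$.

**Turning the correction off.** `correct_rings = FALSE` freezes $u$ at
zero but changes nothing else — including the augmented step size — so a
run with an overwhelming `beta_rings` is *bitwise* identical to the
frozen solver, a property the tests assert exactly. This makes
corrected/uncorrected comparisons a one-parameter switch, at the price
that the frozen solver uses a slightly more conservative step than an
image-only Lipschitz constant would allow.

## Dictionary prior

The slice can instead be synthesised from $w \times w$ patches on a
regular grid (default $w = 8$, stride $w/2$, i.e. 50% overlap), each
patch a sparse combination of unit-norm atoms. Overlapping patch
reconstructions are averaged uniformly, and a quadratic
**overlap-coherence** penalty $h(W)$ — the summed squared deviation of
each patch's value from the overlap average at every shared pixel (for
two patches disagreeing by $a - b$ at one pixel, $(a-b)^2/2$) — keeps
the patches consistent where they meet. $h$ is smooth with an analytic
gradient, so it joins the fidelity in the smooth part of the splitting;
its weight `rho` is exposed independently of the sparsity weight because
no canonical coupling exists.

The trainer (`learn_dictionary()`) is standard K-SVD: orthogonal matching
pursuit at a fixed per-patch sparsity alternating with sequential rank-one
SVD atom updates, dead atoms re-seeded to the worst-represented patch.
An enhanced variant of K-SVD exists, but a plain trainer is sufficient
here: the reconstruction quality is insensitive to trainer refinements
(one fixed dictionary serves across all fixtures), which the planted
dictionary-recovery test (mean best-match $\lvert\cos\rvert > 0.99$ at
sparsity 1) supports. Training images are the package's own generated
phantoms; no external image is shipped or required.

## What the synthetic data emulates

`ring_scenario()` regenerates, bit-identically from a seed, three
corruption regimes of increasing difficulty:

1. **constant stripes** — six single-bin offsets, constant in angle, at
   5% of the sinogram maximum: the regime sinogram pre-processing handles
   best, and the baseline for support-recovery checks;
2. **variable-intensity stripes** — the same bins, with a smooth seeded
   per-angle modulation (a low-order random cosine series; the functional
   form is a package choice since none is canonical): harder for filters
   keyed to exact angle-constancy;
3. **genuine ring features plus stripes** — the phantom itself contains
   a black disk and a thin bright annulus that a correction method must
   *not* remove, while the injected stripes may be several bins wide.

Phantoms are piecewise-constant disk compositions (optionally with a
smooth oscillatory texture), which favours the TV prior by construction.
The default fixture scale is $128 \times 128$ pixels with 180 angles —
chosen so the full corrected/uncorrected comparison runs on a desktop in
seconds per hundred iterations; the generators accept any size. What
passing these tests shows is that the *mechanism* works: angle-constant
corruption is captured in $u$ with exact support recovery and a large
PSNR gain. What it cannot show is performance on real detectors, where
stripes drift with angle, photon noise is present, and the object is not
piecewise constant; the angle-constant model is a first-order
approximation, and partially varying stripes are only partially absorbed
into $u$.

The quality metric is PSNR with the reference's dynamic range as peak,
$10\log_{10}(\mathrm{peak}^2/\mathrm{MSE})$, with an infinite sentinel
for identical images. PSNR over-rewards smooth errors and under-rewards
local ones, so it is used for relative comparisons on matched fixtures,
not as an absolute quality claim.

## The wavelet–Fourier baseline

`munch_destripe()` implements the classic combined wavelet–Fourier
filter used as the pre-processing comparator: a separable Daubechies
decomposition of the sinogram; at each level the band that is low-pass
along the angle axis and high-pass across bins (where angle-constant
narrow lines concentrate) is Fourier-transformed along the angle axis and
damped by the high-pass Gaussian $1 - e^{-k^2/2\sigma^2}$ (so the
angle-constant component is removed exactly, $g(0) = 0$); the sinogram is
rebuilt by the inverse transform. Daubechies filters of any order are
constructed at run time by spectral factorisation of the binomial
half-band polynomial (`daubechies_filter()`), and verified orthonormal in
the tests. The transform is periodized rather than symmetrically
extended: periodization gives exact perfect reconstruction for any even
length with a ten-line implementation, which in turn makes the baseline
exactly linear and energy-conserving — properties the tests rely on;
odd-sized inputs are replicate-padded and cropped. On the constant-stripe
fixture the standard setting ($\sigma = 3.5$, 2 levels, Daubechies 15)
removes over 90% of the stripe energy at the affected bins, while the
residual that leaks into the coarse approximation band illustrates why
such filtering can both under-correct strong stripes and blur genuine
structure — the motivation for the joint approach.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `beta` | spatial regularization weight | 0.1 | scales with sinogram magnitude; raise for noisy/undersampled data at the cost of smoothing |
| `beta_rings` | L1 weight on the ring vector | 0.1–0.5 | too small lets genuine signal leak into `u`; overwhelming values reproduce the uncorrected solver exactly |
| `n_iter` | outer FISTA iterations | 100–500 | ring capture converges more slowly than the slice itself; the energy-transfer into `u` is the slow mode |
| `precondition` | ramp-filter the residual | `TRUE` | dramatically faster convergence; first step equals FBP |
| `inner_tv` | TV prox inner budget | 20 | warm-started across outer iterations |
| `rho` | overlap-coherence weight (DL) | 1 | 0 decouples the patches |

## Limitations

* The stripe model is strictly constant in angle; slowly varying stripes
  are absorbed only partially (the variable-intensity fixture quantifies
  this), and extending `u` to angle-dependent profiles is out of scope.
* Parallel-beam, single-slice geometry only; the rotation centre must be
  correct, since centre errors themselves generate ring-like artifacts in
  any iterative scheme.
* No automatic selection of `beta`/`beta_rings`; they are data-dependent
  and chosen manually, typically on one representative slice.
* The per-iteration cost is dominated by one projection and one
  back-projection; with ring correction enabled the cost per iteration is
  unchanged, but more iterations are needed to the same energy tolerance
  (the test suite asserts the ordering).
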