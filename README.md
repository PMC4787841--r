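# ringtomo

Iterative parallel-beam tomographic reconstruction in which **ring-artifact
correction is part of the optimization itself**.

Defective detector bins add offsets to sinogram columns that are nearly
constant along the projection angle; after reconstruction they appear as
concentric rings centred on the rotation axis. Instead of filtering the
sinogram beforehand or scrubbing rings from the slice afterwards — both of
which can damage genuine structure — `ringtomo` models the acquired
sinogram *d* as the sum of a genuine component and an angle-constant stripe
component, and estimates both jointly:

    min over (x, u) of  ½⟨Px + Ru − d, M(Px + Ru − d)⟩ + β·TV(x) + β_r·‖u‖₁

Here *x* is the slice, *P* the forward projector, *u* a per-detector-bin
**ring vector** replicated across angles by *R*, TV the isotropic total
variation, and *M* an optional ramp-filter preconditioner (with it, the
first gradient step from zero is exactly filtered back-projection). The L1
penalty keeps *u* sparse, so only genuinely defective bins are touched, and
the data themselves are never modified. The problem is solved by FISTA with
a separable proximal step: a TV denoising prox on the image block and a
closed-form soft threshold on the ring block. A learned-dictionary sparsity
prior is available in place of TV (`reconstruct_dl_rings()`), with K-SVD /
orthogonal-matching-pursuit training included.

The package is aimed at synchrotron/lab micro-CT practitioners and method
developers who want ring correction that preserves genuinely annular
specimen features, plus the classical comparators (filtered
back-projection, wavelet–Fourier destriping) and seeded phantom/corruption
generators for benchmarking.

## Worked example

Six constant stripes (amplitude 5% of the sinogram maximum) are injected
into the projections of a 128×128 piecewise phantom over 180 angles; the TV
solver recovers slice and ring vector jointly:

```r
library(ringtomo)

sc <- ring_scenario(case = 1, n = 128, n_angles = 180, seed = 1)
sc$stripe_bins
#> [1]  34  53  66  89  97 105

res <- reconstruct_tv_rings(sc$corrupt,
         solver_config(beta = 0.1, beta_rings = 0.5, n_iter = 300))
res
#> TV reconstruction: 128 x 128 slice, 300 iterations
#>   energy 17619.5 -> 44.075; ring vector: 8 nonzero of 128 bins

round(res$u[sc$stripe_bins + 1], 3)
#> [1] 3.067 3.069 3.064 3.070 3.069 3.069   # injected amplitude: 3.080
```

The six largest entries of `res$u` sit exactly at the injected bins and
recover the stripe amplitude to 0.5%. Against the ground-truth phantom:

```r
psnr(sc$phantom, res$x)                                   # 61.1 dB
psnr(sc$phantom, fbp(sc$corrupt))                         # 23.9 dB (FBP, rings)
# same solver with the ring vector frozen at zero:
base <- reconstruct_tv_rings(sc$corrupt,
          solver_config(beta = 0.1, beta_rings = 0.5, n_iter = 300,
                        correct_rings = FALSE))
psnr(sc$phantom, base$x)                                  # 22.7 dB
```

so the joint correction buys ~38 dB over the identical solver without it on
this fixture. `res$corrected_sinogram` holds `d − Ru`, and
`res$energy_components` the per-iteration fidelity / regularization /
ring-L1 trace.

Thin command-line wrappers live in `inst/cli/`
(`reconstruct.R`, `destripe.R`, `make-fixtures.R`), operating on 32-bit
TIFF sinograms with YAML geometry sidecars.

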