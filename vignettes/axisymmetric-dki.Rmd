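---
title: "Axisymmetric frequency-dependent diffusional kurtosis: model, solver and phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Axisymmetric frequency-dependent diffusional kurtosis: model, solver and phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axdki)
```

# The signal model

Diffusional kurtosis imaging represents the log of the diffusion-weighted
signal along a unit direction $\mathbf{n}$ as a quadratic in the b-value,

$$
\log S(b, \mathbf{n}) = \log S_0
  \;-\; b\, D(\mathbf{n})
  \;+\; \tfrac{b^2}{6}\, \bar D^2\, W(\mathbf{n}),
$$

where $D(\mathbf{n}) = \mathbf{n}^\top \mathbf{D}\, \mathbf{n}$ is the
apparent diffusivity of the rank-2 diffusion tensor $\mathbf{D}$, $\bar D =
\operatorname{tr}(\mathbf{D})/3$, and $W(\mathbf{n}) = \sum_{ijkl} n_i n_j
n_k n_l W_{ijkl}$ contracts a fully symmetric rank-4 kurtosis tensor. The
unconstrained representation has $1 + 6 + 15 = 22$ free parameters per voxel
and demands at least two non-zero b-shells with 15 well-distributed
directions (`fit_full_dki()` implements this baseline and raises an error on
rank-deficient designs).

## The axisymmetric reduction

When the diffusion tensor has an axis of symmetry $\mathbf{u}$ (two equal
minor eigenvalues), the kurtosis tensor inherits that symmetry and the model
collapses to 8 parameters: $D_\perp$, $D_\parallel$, three scalar tensor
kurtosis parameters, and the two-angle axis. Writing $\theta$ for the polar
angle between $\mathbf{n}$ and $\mathbf{u}$,

$$
D(\theta) = D_\perp + \cos^2\theta\,(D_\parallel - D_\perp),
$$

$$
W(\theta) = \tfrac{1}{16}\big[
  \cos 4\theta\,(10 W_\perp + 5 W_\parallel - 15 \bar W)
  + 8 \cos 2\theta\,(W_\parallel - W_\perp)
  - 2 W_\perp + 3 W_\parallel + 15 \bar W \big].
$$

$W(\theta)$ is the unique axisymmetric quartic form satisfying the three
defining limits simultaneously — $W(0) = W_\parallel$ (axial),
$W(\pi/2) = W_\perp$ (radial), and spherical mean $\bar W$ — which the test
suite verifies analytically at the endpoints and by quadrature for the mean.
Note these are *tensor* quantities (contractions of $\mathbf{W}$), distinct
from numerically averaged directional kurtosis. The conventional kurtosis
metrics rescale them by diffusivities:

$$
K_\parallel = \frac{\bar D^2}{D_\parallel^2} W_\parallel,
\qquad
K_\perp = \frac{\bar D^2}{D_\perp^2} W_\perp .
$$

## Frequency dependence

Oscillating-gradient (OGSE) encoding probes diffusion at a short effective
diffusion time, $\Delta t_{\mathrm{eff}} = 9/(64 f)$ for cosine-modulated
gradients (2.3 ms at 60 Hz, 1.2 ms at 120 Hz; `effective_diffusion_time()`),
making the fitted parameters functions of the oscillation frequency $f$. The
package treats frequency as a first-class axis of the acquisition: schemes
carry a per-volume frequency column, fits are per frequency, and the phantom
can program a known frequency dispersion of the kurtosis parameters.

# The two-step fit

Step one (`fit_dti()`) fits the 7-parameter log-linear tensor model; its
principal eigenvector fixes the per-voxel symmetry axis. Step two
(`fit_dki()`) holds the axis fixed and fits the six linear parameters
$(\log S_0, D_\perp, D_\parallel, \bar D^2 W_\perp, \bar D^2 W_\parallel,
\bar D^2 \bar W)$ per frequency. Fitting $U = \bar D^2 W$ keeps step two
linear; the $\bar D^2$ factor cancels exactly in $K_\parallel$ and $K_\perp$
and is divided out for $\bar W$.

Three pooling strategies control which volumes feed the axis estimate
(`compute_axes()`): AFAB pools all frequencies and b-values into one tensor
fit (most data, most robust — the recommended default), SFAB fits per
frequency, SFLB fits per frequency from the low b-shell only. The underlying
assumption, testable with `axis_agreement()`, is that the principal diffusion
direction depends negligibly on frequency.

## A bias worth knowing about

On noiseless axisymmetric data the plain tensor step does *not* recover the
exact axis: the $b^2$ kurtosis term acts as a direction-dependent
perturbation of the log-linear model and tilts the principal eigenvector by
roughly a degree at typical parameter values. For map-making this is
negligible against noise; for exact-recovery studies it is not. The package
therefore offers a fixed-point refinement (`compute_axes(refine = TRUE)`):
fit the axisymmetric parameters given the current axes, subtract the fitted
quadratic-in-b term from the log signals, refit the tensor on the corrected
data, and iterate. On noiseless data this converges to the exact axis, and
with it the nine-direction two-shell protocol recovers all eight parameters
to solver precision. The default (`refine = FALSE`) matches the plain
two-step method.

# Spatial regularization and the solver

Both steps minimize, jointly over all masked voxels,

$$
\lVert A x - y \rVert_2^2 + \gamma \lVert T x \rVert_2^2 ,
$$

where $A$ is voxel-separable (a shared design in step one; per-voxel designs
in step two, because $\theta$ varies with the axis) and $T$ takes weighted
spatial first differences of selected parameter components between each voxel
and its in-mask forward neighbors (zero coupling across the mask boundary).
$\log S_0$ is never penalized. In step one, diagonal tensor components carry
weight 1 and off-diagonal components weight 2, compensating their smaller
magnitude while keeping the penalty rotationally unbiased within each group;
in step two the five diffusion/kurtosis parameters carry weight 1. Base
weights follow the published defaults, $\gamma_{DT} = 0.5$ and
$\gamma_{DK} = 0.075$ for preclinical protocols ($0.2$ for human-like
protocols), with a single net multiplier exposed in `fit_config()`.

The normal equations $(A^\top A + \gamma T^\top T)\,x = A^\top y$ are solved
matrix-free by conjugate gradients (`solve_regularized()`): the only
ingredients are the small per-voxel Gram blocks and the difference stencil,
so memory stays linear in the voxel count. Choices made where the method
description is silent:

- **Normal-equations CG** rather than LSQR/LSMR, mirroring the stated
  conjugate-gradient approach; the systems here are small and well enough
  conditioned that the squared condition number is not a concern. Relative
  residual tolerance 1e-8 and 500 iterations by default, both configurable.
- **Forward differences with zero boundary**, adjoint = negative backward
  difference; correctness is pinned by dense-matrix oracles in the tests
  (the CG solution matches a dense solve of the fully coupled system to
  1e-8, and $\gamma = 0$ reproduces per-voxel OLS).
- **Ordinary (unweighted) least squares** throughout, for its reduced bias
  relative to weighted least squares at these SNRs.
- **b-values in ms/µm²** internally so that the $b$ and $b^2/6$ design
  columns have comparable magnitude; FSL files in s/mm² are converted at the
  I/O boundary.

Gaussian pre-smoothing (`gaussian_presmooth()`, separable kernel, reflective
boundaries) is provided as the conventional alternative that regularized
fitting is compared against, not as a recommended preprocessing step.

# The efficient direction scheme

For fixed waveform timing, $b \propto \lVert \mathbf{g} \rVert^2$. A
direction like $(0, 1, 1)$ — two gradient channels at maximum amplitude —
therefore reaches exactly twice the b-value of $(1, 0, 0)$
(`b_efficiency_ratio()`). `ten_direction_scheme()` combines six such
two-channel directions with four tetrahedral directions at amplitude $2/3$:
ten directions per shell, enough for the 8-parameter axisymmetric model with
headroom, all at high gradient efficiency. This matters most for OGSE, where
the achievable b-value falls rapidly with oscillation frequency.

For synthetic direction sets of arbitrary size, `uniform_directions()` starts
from a spherical Fibonacci spiral and refines it by electrostatic repulsion
of antipodally symmetric point pairs. The refinement is not cosmetic: the raw
spiral lies close to a symmetric configuration with degenerate fourth-order
moments, and two-shell 22-column designs built from 15 or 16 spiral
directions are numerically rank deficient, while repulsion-refined sets reach
full rank at 15 directions — the documented minimum — with a healthy smallest
singular value.

# The synthetic phantom

`generate_phantom()` builds a two-region study object designed to exercise
every failure mode the fitting path cares about, while staying honest about
what it is — a forward-model phantom, not a tissue simulation:

- **Geometry.** A curved anisotropic tube (one to two voxels of curvature per
  voxel of length, emulating a corpus-callosum-like bend) through an
  isotropic background, so axis estimation faces a spatially varying
  orientation and regularization faces a genuine edge.
- **Parameters.** White-matter-like ($D_\parallel = 1.5$, $D_\perp = 0.4$
  µm²/ms, $W_\perp = 1.6$, $W_\parallel = 0.6$, $\bar W = 1.0$) and
  grey-matter-like ($D = 0.8$ µm²/ms isotropic, $W = 0.7$) values in the
  physiologic range for in vivo brain. These are fixture choices, not
  measured claims.
- **Frequency dispersion.** Kurtosis parameters decrease linearly with
  frequency (30% at the highest frequency by default), emulating the loss of
  non-Gaussianity at shorter diffusion times, while diffusivities and
  orientation stay fixed. The generator records the exact programmed profile
  so recovery can be tested quantitatively.
- **Noise.** Rician by default (magnitude of a complex Gaussian — the correct
  model for magnitude MRI, including its signal-dependent bias), Gaussian or
  none on request; SNR is defined at b = 0; multi-average acquisition is
  emulated by averaging independent repetitions.

Everything is seeded and bit-reproducible, and the complete ground truth
(labels, axes, per-frequency parameter fields) ships with the signal, on disk
too (`write_phantom()`).

# Evaluation utilities

- `csr()` — contrast-to-standard-deviation ratio between two ROIs,
  $(\mu_A - \mu_B)/\sqrt{\sigma_A^2 + \sigma_B^2}$, the map-quality summary
  used throughout; non-finite voxels are excluded and counted, since the
  prevalence of undefined or negative-kurtosis ("blackened") voxels is itself
  a noise measure.
- `snr_map()` — voxelwise mean/sd across repeated b = 0 volumes.
- `axis_agreement()` / `axis_agreement_histogram()` — central angles between
  per-frequency axis fields, stratified by FA, for checking the
  frequency-independence assumption behind axis pooling.

# Limitations

- One symmetry axis per voxel: crossing fibers and near-isotropic voxels
  violate the model; there the axis is arbitrary (noise-determined) and
  axisymmetric parameters are approximations. FA-stratified reporting exists
  precisely because low-FA axes should not be over-interpreted.
- The quadratic-in-b representation itself is a truncation; no claim is made
  beyond the fitted b-range.
- The phantom's two-tissue geometry is deliberately simple; it validates the
  estimator, not biology.
- Scanner-frame versus image-frame gradient reorientation, DICOM ingestion,
  and preprocessing (denoising, Gibbs ringing, eddy currents) are out of
  scope — upstream tools own those stages.
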