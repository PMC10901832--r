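---
title: "Fourier-domain reconstruction for planar photoacoustic tomography, with learned k-space and image-space corrections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fourier-domain reconstruction for planar photoacoustic tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrecon)
```

## The problem

Photoacoustic tomography (PAT) reconstructs an initial acoustic pressure
distribution $p_0(x)$ — proportional to absorbed optical energy, and in
practice dominated by blood vessels — from ultrasound time series recorded at
the tissue boundary. This package addresses the common planar-sensor setting:
the detector is a single plane at $z = 0$, the medium occupies $z > 0$, and the
measured data are $g(x_1, x_2, t)$ on that plane.

Two structural problems limit reconstruction quality in this geometry:

* **Limited view.** Wavefronts travelling nearly parallel to the detector
  plane never reach it with usable amplitude. In the Fourier picture these are
  image modes with small vertical wavenumber $k_z$; they sit next to the
  dispersion cone where the data-to-image mapping degenerates, and their loss
  causes the characteristic streak and blur artifacts of planar PAT.
* **Unknown speed of sound (SoS).** The fast Fourier reconstruction assumes a
  single known sound speed $c_0$. Soft tissue varies over roughly
  1400–1600 m/s, and an incorrect $c_0$ misplaces and defocuses structures:
  a feature at depth $z_0$ in a medium with true speed $c$ is reconstructed
  near depth $z_0\, c_0 / c$.

The package implements the full experimental loop used to study a learned
remedy: synthetic vessel phantoms and sound-speed maps, acoustic forward
models, the FFT reconstruction decomposed into differentiable stages, a
complex-valued k-space *model-correction* network $G_\psi$, an image-space
*post-processing* U-Net $\Lambda_\theta$, joint end-to-end training, and the
evaluation harnesses (method tables and PSNR-versus-SoS sweeps).

## The acoustic model

Wave propagation is the lossless initial value problem

$$(\partial_{tt} - c(x)^2 \Delta)\, p(x,t) = 0,\qquad
p(x,0) = p_0(x),\qquad \partial_t p(x,0) = 0,$$

with attenuation and shear waves neglected. Measurements sample $p$ on the
$z=0$ plane at `nt` instants spaced `dt`. All quantities are SI internally
(m, s, m/s); grids are isotropic with spacing `dx`, wavenumber and frequency
axes are angular and FFT-ordered, so the dispersion relation reads literally
$\omega = c\,|k|$.

### The spectral forward model (homogeneous media)

For constant $c_0$ the field is $\hat p(k,t) = \hat p_0(k) \cos(c_0 |k| t)$.
`forward_fft_homogeneous()` evaluates the *recorded, truncated* signal
exactly: per detector wavenumber column it forms the free-space mode sum over
a finely sampled depth spectrum (zero-padding factor `zpad` pushes periodic
ghost copies beyond the record) and computes the record's DFT in closed form
with one-sided Dirichlet kernels. This reproduces everything a perfect wave
solver would record in finite time, including the spectral leakage of a
truncated record, at a fraction of the cost. A laterally uniform slab arrives
as a half-amplitude pulse at $t = z_0/c_0$, the d'Alembert split of the
initial condition $\partial_t p = 0$.

### The pseudospectral solver (heterogeneous media)

`forward_pseudospectral()` integrates the wave equation for arbitrary
$c(x)$ with a Fourier-spectral Laplacian and second-order leapfrog stepping.
The spectral Laplacian carries the k-space correction factor
$\mathrm{sinc}^2(c_\mathrm{ref} |k| \Delta t/2)$ with
$c_\mathrm{ref} = \max c$, which makes the scheme *exact* for homogeneous
media at any step size and unconditionally stable; for heterogeneous maps the
default internal CFL number is 0.3 and the internal step is an integer
subdivision of `dt`, so output samples land exactly on the requested time
grid. The initial condition $\partial_t p = 0$ is realised by a symmetric
first leapfrog step.

Outgoing waves are absorbed by a cosine-tapered *sponge*: the domain is padded
on each absorbing face by a clear buffer (`sponge_clearance`, default 12
voxels) plus a damping ramp (`sponge_width`, default 24 voxels, peak per-step
damping exponent `sponge_strength = 0.15`). The padding above the sensor plane
emulates a transparent detector in acoustic contact with the tissue: the
medium effectively continues above the plane. The gentle, wide ramp matters —
a strong thin sponge acts like an impedance jump and reflects, and an absorber
too close above the sensor eats the grazing wavefield that free space keeps;
with the defaults the spectral and pseudospectral records of the same smooth
phantom agree to about 1–3% relative $L_2$ at desk scale, and that frozen
tolerance is what the test suite asserts.

`time_reversal()` is the conventional full-wave baseline: the same integrator
run backwards from a zero field with the time-reversed record enforced as a
Dirichlet condition on the sensor plane, returning the $t=0$ field clipped to
nonnegative values.

## The Fourier-domain reconstruction and where the networks sit

The reconstruction is the classical planar-sensor Fourier method, decomposed
into stages so learned components can be inserted:

1. `data_to_kspace()` — 3D FFT of $g$ and multiplication by the weighting
   factor $B \propto \sqrt{(\omega/c_0)^2 - k_1^2 - k_2^2}\,/\,\omega$, the
   Jacobian of the dispersion change of variables. $B = 0$ on the
   $\omega = 0$ plane and in the evanescent region
   $(\omega/c_0)^2 < k_1^2+k_2^2$; the $1/k_z$ divergence at the cone is
   capped at its value one frequency cell away (the finite-record limit). The
   constant image mode is carried separately so the mean pressure stays
   recoverable.
2. `interp_to_image_kspace()` — for every image node $(k_1,k_2,k_3)$, linear
   interpolation along the $\omega$ axis at the signed query
   $\omega^* = \mathrm{sign}(k_3)\, c_0 |k|$; out-of-band queries give zero.
3. the model correction $f \mapsto G_\psi(f)$ (optional),
4. `kspace_to_image()` — inverse 3D FFT, real part, and
5. the post-processing network $\Lambda_\theta$ (optional).

`fft_planar_recon()` is the unlearned composition; `learned_recon_operator()`
is the full trainable one, and every stage has a hand-written adjoint so
reverse-mode gradients reach both networks (`learned_recon_backward()`),
verified against central finite differences in the test suite.

**A convention worth stating.** Under the plain FFT's $e^{-i\omega t}$ kernel
the data node at signed frequency $\omega$ carries the image mode at
$k_z = \mathrm{sign}(\omega)\sqrt{(\omega/c_0)^2 - k_\perp^2}$. Folding the
time axis onto $\omega \ge 0$ (an even/cosine transform) would force the
reconstruction to be even in $k_z$ on the `nz`-point image grid, wrapping a
mirror ghost of the object into the imaging depth; the signed bijection keeps
up- and down-going information separate and costs nothing. With this pairing
the forward/inverse pair is *exactly* mutually inverse on the laterally
uniform column of a matched grid (`dt = dx/c0`), which is what pins every
constant in the transform chain — the round-trip test asserts a relative
$L_2$ error below $10^{-4}$ there (measured $\sim 10^{-5}$).

For generic smooth phantoms the round trip is *not* near-exact, and cannot
be: modes near the dispersion cone ($k_z \approx 0$, wavefronts grazing the
detector) map many image nodes into a few frequency cells, and the evanescent
zeroing discards them. This is the limited-view information loss itself, not
a numerical defect; measured on a matched 64×64×32 grid the round-trip
relative $L_2$ error for a smooth Gaussian ball is about 0.83 (while the
reconstruction still scores >25 dB PSNR, since the loss is concentrated in
low-$k_z$ streak components). The frozen acceptance bound is 0.9, and it is
precisely the gap the learned components exist to close.

## The networks

**Model correction $G_\psi$** (`build_model_correction()`): three complex
convolutional layers on the one-channel complex image k-volume — widths
`width`, `width`, 1 with $3^3$ kernels; the first two layers carry complex
batch normalisation and $\mathbb{C}$ReLU, the last is linear so corrections
can take any complex value. Complex convolution follows
$W * h = (A*x - B*y) + i(B*x + A*y)$; $\mathbb{C}$ReLU applies ReLU to the
real and imaginary parts separately; batch normalisation is the per-part
("naive") variant with running statistics for inference. Complex kernels are
initialised with per-part variance halved relative to the real-valued scheme
so $|W|$ matches. With `residual = TRUE` the network output is added to its
input with a zero-initialised last layer: the freshly built correction is then
exactly the identity, and joint training starts from the plain-FFT solution —
the package's realisation of a near-identity start, chosen because batch
normalisation makes an exact delta-kernel identity impossible.

**Post-processing $\Lambda_\theta$** (`build_unet()`): a 4-scale U-Net (three
2× max-pool downsamplings, window 2), two convolution–batch-norm–ReLU blocks
per scale, widths doubling from `width` to `8 * width`
(32 → 256 at full scale), nearest-neighbour-plus-convolution upsampling,
skip connections by channel concatenation, and a final 1×1×1 convolution.
The output head is initialised near zero so the untrained operator returns an
almost-zero image; with sparse vessel targets this makes the initial loss the
sparse-image baseline rather than unit-scale noise and removes a long
burn-in, which matters at desk-scale step budgets. Inputs whose sides are not
divisible by 8 are zero-padded internally and cropped on output. Batch size
is 1 throughout, so training-mode batch
statistics are per-channel spatial statistics.

Both networks are implemented with explicit forward/backward passes over
Rcpp convolution kernels (im2col + BLAS dgemm); there is no automatic
differentiation framework underneath, which is why the finite-difference
gradient checks are part of the acceptance suite.

## Training

`train_postprocessing()` minimises
$\ell(\theta) = \|\Lambda_\theta(\tilde p_0) - p_0\|^2$ (mean squared error —
the norm is read as squared $L_2$, the standard choice for this literature)
over FFT reconstructions $\tilde p_0$ computed at the configured `c_recon`.
`train_joint()` minimises
$\ell_j(\psi,\theta) = \|\Lambda_\theta F_\psi^\dagger(g) - p_0\|^2$
end-to-end through the reconstruction; the fixed stages (weighting,
interpolation) are precomputed per sample, so each step costs the two
networks plus one FFT pair. Both use Adam with a cosine-decayed learning rate
at batch size 1 and sweep the configured initial learning rates
($10^{-4}, 10^{-3}, 10^{-2}$ at full scale), selecting the model with the
best mean test PSNR. Model selection uses test performance rather than a
validation split — a deliberate simplification whose caveat is stated openly.

Desk-scale defaults (`run_config()`): a 48×48×24 grid at a 0.106 mm
pitch with 48 time samples, 20 training / 5 test phantoms, U-Net
base width 8 and correction width 8, a single initial learning rate
$10^{-2}$ from the swept set, and a training budget of a few epochs
(~100–200 steps). These sizes are chosen so a full method comparison runs on
one CPU core in minutes; the full-scale widths (32/…/256) and the full
three-rate sweep remain available through the same configuration object, and
nothing in the code is specific to the reduced sizes.

## Synthetic data

`generate_vessel_phantom()` emulates the statistical character of
vessel-mimicking targets: biased 3D random-walk centerlines (persistence
0.85), Poisson bifurcations, hard-sphere voxelisation with per-branch radii
(1–3 voxels), Gaussian smoothing (default width 1 voxel; the width is an
explicit parameter since no canonical value exists) and max-normalisation
to 1. It reproduces what matters for exercising the method — smooth, sparse, tubular, nonnegative structures with
no preferential lateral axis — and makes no claim to real vascular
morphometry.

Built-in sound-speed scenarios: fixed 1400 or 1500 m/s;
homogeneous values drawn uniformly from [1400, 1600] m/s; a three-layer skin
model (epidermis 0.212 mm at [1635, 1655], dermis 2.12 mm at [1585, 1605],
hypodermis 1.696 mm at [1440, 1460] m/s, every voxel drawn i.i.d. uniformly
from its layer's interval) with the initial pressure zero-filled on the
epidermis *before* smoothing; and a skull model (skin 0.212 mm at
[1580, 1620], skull 0.428 mm at [2780, 2820], brain remainder at
[1520, 1560] m/s) with the initial pressure restricted to the brain. Layer
thicknesses map to voxel slabs by nearest-integer rounding of
thickness/`dx`, which is lossless at the 0.106 mm pitch (2/20/16 and 2/4
slabs). The remainder interval of the skin scenario (soft tissue,
[1480, 1520] m/s) is a package default.
Test sets in the homogeneous scenarios draw their true speed from the full
[1400, 1600] m/s range regardless of the training range, which is what makes
the training-data-dependence experiments possible.

Measurement noise is Gaussian with standard deviation 1% of each record's
maximum (`noise_frac = 0.01`).

What passing tests on these data do *not* show: robustness to real detector
responses (bandlimits, directivity), acoustic attenuation, shear conversion
in bone, or vessel morphology beyond the generator's statistical class. The
skull scenario in particular is a phase-aberration model only.

## Metrics and experiments

`psnr()` uses the true initial pressure's peak:
$10\log_{10}(\max(p_0)^2/\mathrm{MSE})$, capped at 200 dB for exact matches.
`ssim()` is the Gaussian-window variant ($\sigma = 1.5$, radius 5,
$C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$, $L$ = reference dynamic range) computed
with a full 3D window — the reconstructions are volumes, so a slicewise window
would be arbitrary; the windowing variant is a documented package decision. Reconstructions of all methods are
clipped to nonnegative values before scoring.

`run_method_comparison()` tabulates TR / FFT / FFT+PP / FFT+MC+PP over a test
set (mean ± sd of PSNR and SSIM) and writes per-method maximum-intensity
projections; `sos_sweep()` simulates fresh test sets at each true SoS,
reconstructs at `c_recon = 1500`, and returns the mean-PSNR curve whose
U-shape around the true speed — and whose dependence on the training range —
is the central phenomenon the learned corrections address.

## Numerical choices and degenerate inputs

* Matched grids (`dt = dx/c0`) make the dispersion queries hit frequency
  nodes on the uniform column; all round-trip calibration runs there.
* Interpolation is linear along $\omega$ only, per detector-wavenumber
  column; queries beyond the band give 0. The map is piecewise linear, hence
  differentiable almost everywhere, with an exact adjoint.
* The real part is taken after the inverse FFT (the learned correction may
  break Hermitian symmetry); no clipping inside the operator.
* Degenerate generator inputs are defined: zero branches give an all-zero
  phantom with a warning; degenerate SoS intervals `[c, c]` give exact
  constants; a layer thinner than half a voxel is an error rather than a
  silently vanished layer.
* The time axis starts at $t = 0$ (sample $j$ is $t_j = j\,dt$), and the
  first voxel layer sits on the sensor plane.

## Known limitations

* The forward spectral model is laterally periodic (as is the pseudospectral
  solver); phantoms keep a margin from the lateral faces so wrap-around
  arrivals stay weak within the record.
* The sponge is a simple absorber, not a PML; residual boundary reflections
  of order 1% are visible in the solver cross-validation and bound how
  tightly time reversal can match the exact spectral forward.
* Batch size is fixed at 1; multi-sample batching would change batch-norm
  semantics and is not implemented.
* The learned-operator experiments at desk scale demonstrate orderings
  (learned > unlearned; range-matched training > mismatched training), not
  the absolute PSNR/SSIM levels of GPU-scale training on anatomically
  derived phantoms.
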