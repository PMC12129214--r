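---
title: "Methods: self-supervised unrolled reconstruction for accelerated quantitative MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-supervised unrolled reconstruction for accelerated quantitative MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The reconstruction problem

Quantitative MRI estimates tissue parameters — proton density (PD), T1 and T2 —
from a series of images acquired with varying sequence parameters (echo times,
flip angles). Because a full series takes long to acquire, k-space is
undersampled and the missing information is recovered by reconstruction.

`qmapnet` models the acquisition with the multi-coil, multi-contrast Cartesian
encoding operator

$$ y_{\Omega}[p, c] = M_{\Omega_p}\, F\, (C_c \odot x_p), $$

where $x_p$ is the complex image of contrast $p$ ($P \times H \times W$ stack),
$C_c$ the complex sensitivity of coil $c$ (RSS-normalized so
$\sum_c |C_c|^2 = 1$ inside the support), $F$ the centered orthonormal 2D DFT,
and $M_{\Omega_p}$ the per-contrast sampling operator that zero-fills
unmeasured points. All modules share one DFT convention (DC at the matrix
center, unitary scaling), so Parseval identities and adjointness are exact and
are enforced by property tests.

Reconstruction solves

$$ \hat x = \arg\min_x \; \lVert E_\Omega x - y_\Omega \rVert_2^2
   + \lambda \lVert x - D_w(x) \rVert_2^2 $$

by alternating a learned denoiser $z_n = D_w(x_n)$ with a data-consistency
(DC) solve $x_{n+1} = (E^H E + \lambda I)^{-1}(E^H y + \lambda z_n)$, run for a
fixed number of unrolls. The DC solve uses conjugate gradients warm-started at
$z_n$ with a fixed iteration count (no tolerance-based exit), which keeps the
forward pass deterministic.

### Denoiser

The denoiser is a residual CNN. The complex stack is split into $2P$ real
channels (`[Re(1..P), Im(1..P)]`), passed through an input 3×3 convolution,
`n_blocks` residual blocks (conv → ReLU → conv → scale by `alpha_scale`, plus
a block skip), an output 3×3 convolution, and a global skip that adds the
input. Defaults follow the reference design: 10 blocks, 64 filters, 3×3
kernels, residual scaling 0.1, 10 unrolls, 10 CG iterations. With all weights
zero the network is exactly the identity, a property the tests rely on.

There is no normalization layer anywhere: the blocks are plain
conv/ReLU/conv/scale, and per-case intensity normalization (below) makes the
input scale predictable.

Forward and backward passes are written explicitly (the convolution kernels in
compiled code), with Adam as the optimizer. This makes the package
self-contained and — more importantly — makes the gradient-checkpointing
contract *checkable*: both training modes share one code path and the tape
contents are inspectable.

### Gradients through the DC layer

The gradient of the CG solve with respect to $z$ uses the implicit (adjoint)
form: since $Q = E^H E + \lambda I$ is self-adjoint,
$\partial \mathcal{L}/\partial z = \lambda\, Q^{-1} g$, computed by a second
CG solve with the incoming gradient $g$ as right-hand side and the same
iteration budget. The dependence of a *truncated* CG solve on its warm start
is neglected; finite-difference checks on full reconstructions show relative
gradient errors of order $10^{-4}$ at 25 CG iterations, which is ample for
training.

### Memory-efficient training (gradient checkpointing)

During a plain taped forward pass, every denoiser activation is retained
(memory grows with the number of residual blocks). In checkpointed mode, only
the per-unroll denoiser *inputs* are stored; activations are recomputed from
those checkpoints during the backward pass. The contract, enforced by tests:

* forward results are bit-identical in both modes;
* gradients agree (identical up to recomputation, in practice bit-identical);
* the checkpointed tape holds exactly `n_unrolls` arrays regardless of block
  count, while the plain tape grows linearly with blocks;
* the denoiser runs exactly `2 * n_unrolls` forward evaluations per
  optimization step (one forward + one recomputation each), versus
  `n_unrolls` without checkpointing.

The reverse recomputation of the DC layer itself is deliberately not
implemented; the DC solve stores no activations beyond its inputs, so there is
nothing to gain.

For 3D Cartesian data with a fully sampled readout, `decouple_readout()`
applies a 1D inverse DFT along the readout and yields independent 2D problems;
`recombine_readout()` inverts it exactly.

## Training regimes

All three regimes minimize the normalized L1 + L2 k-space loss
$\mathcal{L}(u, v) = \lVert u-v \rVert_1 / \lVert u \rVert_1 +
\lVert u-v \rVert_2 / \lVert u \rVert_2$, which is invariant to a common
rescaling — important because each case is normalized so its zero-filled
adjoint has maximum magnitude 1 (the factor is recorded and undone on output).

* **Supervised (SL)**: input $y_\Omega$, loss against the fully sampled
  reference over all of k-space.
* **Self-supervised (SSL)**: the measured region $\Omega$ is split into a
  disjoint 60/40 pair $\Theta$ (network input) / $\Lambda$ (loss target). No
  fully sampled data is touched; the training cases physically exclude it and
  an access guard raises an error on any attempted read.
* **Zero-shot (ZSSSL)**: a single case; $\Omega$ first yields a 20% validation
  subset $\Gamma$ (leaving $\Xi$), then $\Xi$ splits 60/40 into
  $\Theta/\Lambda$. Training runs $\Theta \to \Lambda$, validation
  $\Xi \to \Gamma$, and stops once validation has failed to improve for more
  than `patience` (default 25) consecutive epochs. Inference always uses the
  full measured data $y_\Omega$.

Split points are drawn uniformly by default (a Gaussian-weighted draw
concentrated at the k-space center is available); autocalibration (ACS) points
always stay in $\Theta$ — assigning calibration lines to the loss set would
make the loss trivially easy and starve the input. Partitions are drawn once
per case and fixed across epochs. Default learning rates are 1e-4 (SL, SSL)
and 5e-4 (ZSSSL); batch size 2 with gradient accumulation that reproduces the
full-batch update exactly (the accumulated sum is divided by the batch size
once). Best-validation weights are returned for every strategy. Training
visits cases in a fixed order, so a fixed seed reproduces losses bit for bit.

## Synthetic data

The generator emulates a realistic multi-coil acquisition without any external
dataset:

* **Phantom**: a brain-like nested-ellipse label map (outer CSF ring, GM
  ribbon, WM interior, randomized elliptical WM lesions). Outer anatomy is
  deterministic; only lesions depend on the seed. Default tissue values
  (PD/T1/T2: WM 0.7/800/70, GM 0.85/950/100, CSF 1.0/4000/1800, lesion
  0.9/1400/250) are package defaults chosen to be physiologically plausible
  and so that the threshold regions used in evaluation (T1 ≤ 1000 ms,
  T2 ≤ 120 ms) select exactly WM + GM.
* **Coils**: loop coils (radius 100 mm) on a ring outside the field of view,
  normals pointing at the center. Sensitivities come from discretized
  Biot–Savart line integrals evaluated on the image plane; the on-axis closed
  form validates the discretization to < 1%. The complex phase is taken from
  the transverse field components ($B_x - iB_y$) — a modeling choice, since a
  static-field calculation alone does not fix a receive phase. The set is
  RSS-normalized. Six coils are the default; an eight-coil ring suits
  knee-like cases.
* **Contrasts**: analytic signal models evaluated on the phantom's parameter
  grids — mono-exponential decay for multi-echo spin echo (MSME),
  the SPGR steady state for variable flip angles, and the echo/FID ratio with
  optional T1/diffusion correction for qDESS. The qDESS FID contrast is
  modeled as PD with the steady-state prefactor absorbed; only the echo/FID
  *ratio* carries T2 information, which is what the fitter inverts.
* **Noise**: complex Gaussian noise with standard deviation equal to
  `noise_fraction` (default 1e-4, i.e. 0.01%) of the maximum clean k-space
  magnitude, added independently to real and imaginary parts.
* **Undersampling**: retrospective masks — whole phase-encode lines or
  individual points, uniformly drawn outside a fully sampled central ACS
  region; acceleration factor = fraction of k-space retained. Masks are drawn
  independently per contrast by default (complementary sampling across
  contrasts is the realistic and favorable regime for joint reconstruction).

What the generator does **not** emulate: B0/B1 inhomogeneity, motion, slice
profiles, Rician magnitude bias, realistic anatomy texture, or
scanner-estimated (ESPIRiT) sensitivities — the true simulated sensitivities
are used throughout. Passing tests therefore demonstrate the correctness and
internal consistency of the method, not clinical-grade performance on scanner
data.

## Map fitting

* **MSME T2**: log-linear initialization, then bounded Levenberg–Marquardt on
  the mono-exponential model; default T2 bounds (1, 5000] ms; invalid when
  any signal is non-positive, the optimizer fails, or a bound is hit.
* **VFA T1**: the DESPOT1 linearization ($S/\sin\alpha$ on $S/\tan\alpha$;
  slope $= e^{-TR/T1}$). The sin-α numerator is included by default (the
  physically standard SPGR form); the variant without it is selectable and the
  fit adapts its linearization accordingly. A slope outside (0, 1) is
  non-physical → invalid.
* **qDESS T2**: closed-form inversion of the echo/FID ratio; the echo time
  entering the exponent is the first (FID) echo time; assumed T1 defaults to
  1000 ms and diffusivity to 0 (the diffusion terms then vanish; the
  "(TR − τ/3)" diffusion attenuation is implemented for nonzero D). Default
  bounds (1, 500] ms.

Fewer than 16 MSME echoes are spread evenly across the 10–160 ms train rather
than truncated, preserving T2-fit conditioning at reduced contrast counts
(16 echoes reproduce the standard 10–160-every-10 protocol exactly).

## Evaluation

NRMSE on maps is $\lVert (p - g)\mathbf{1}_\Phi \rVert_2 /
\lVert g \mathbf{1}_\Phi \rVert_2$ (Euclidean normalization; mean- and
range-based variants would be monotone transformations on a fixed region).
The evaluation region $\Phi$ combines a region-of-interest variant (whole
image, GT T2 ≤ 120 ms, GT T1 ≤ 1000 ms, or an external mask) with exclusion
rules: predicted T1 > 5000 ms or T2 > 500 ms (outlier suppression), GT
first-contrast magnitude below 5% of its maximum (no reliable estimate
there), and fit-validity masks. The threshold comparisons default to
non-strict (≤), with strict variants selectable.

SSIM on magnitude images is single-scale with an 11×11 Gaussian window
(σ = 1.5), K1 = 0.01, K2 = 0.03, data range = max of the reference, averaged
over the valid interior; an independently coded reference implementation in
the tests agrees to 1e-6.

## The toy verification suite

The full-scale configuration (256×256, 16 contrasts, 64 filters, 10 blocks,
10 unrolls, 100 epochs) is a GPU-scale workload. The package's quantitative
self-checks instead run a scaled-down suite chosen once and documented here:

* 32×32 nested-ellipse phantom, 4 loop coils, MSME with 4 spread echoes
  (TE 10/60/110/160 ms), noise 0.01%;
* random-point undersampling at AF 4 with a 4×4 ACS block — incoherent
  aliasing is the standard operating regime for learned reconstruction;
  whole-line undersampling of a 32-line phase-encode axis leaves coherent
  fold-over that a 2-block toy denoiser cannot be expected to resolve;
* network: 16 filters, 2 residual blocks, 3 unrolls, 8 CG iterations,
  λ = 0.05;
* zero-shot training: ≤ 50 epochs, patience 25, learning rate 5e-3 — one
  epoch here is a single Adam step on a single case, so the full-scale rate
  of 5e-4 would leave training far from convergence within the budget.

Under this suite, zero-shot training beats the zero-filled adjoint baseline on
both the contrast-image NRMSE and the fitted-T2 NRMSE over the WM+GM region.

For the strategy comparison, each regime's *native* validation loss lives on a
different target (the SSL loss is evaluated only on the Λ subset, which
excludes the ACS and is systematically inflated), so the suite compares all
three trained models with a common supervised validation objective
$\mathcal{L}(y_{full}, E_{full} f(y_\Omega))$ on the same held-out case, and
gives every strategy the same optimizer budget (same learning rate, same
number of Adam steps). With equal budgets the mean ordering over five seeds is
SL ≤ SSL ≤ ZSSSL, reflecting the information available to each regime: full
supervision > a 60% input split across a training set > 48% of a single case.
(With unequal step sizes the comparison degenerates into a measurement of
optimizer budgets: a zero-shot model taking 5× larger steps on the evaluation
case itself dominates both others.)

## Numerical choices and edge cases

* λ defaults to 0.05 and is held fixed; the prior-dominated limit
  (λ → ∞ ⇒ output → z) and the identity limit (full mask, uniform coil,
  λ → 0) are tested.
* CG iteration counts are fixed (no early exit) for determinism; residual
  norms are non-increasing and reach 1e-6 relative on well-conditioned toy
  systems within 40 iterations.
* Weight sharing across unrolls is the default (and only mode exercised);
  per-unroll weights are a configuration flag.
* Degenerate fits (flat decay, non-physical VFA slope, non-decaying qDESS
  ratio, zero FID) are flagged invalid rather than clipped silently.
* All randomness flows through explicit integer seeds (phantom lesions, mask
  draws, partition draws, noise, weight init); RNG state is restored after
  each seeded operation, so library calls never perturb a caller's stream.

## Known limitations

* Training is CPU-bound and intended for small problems; the full-scale
  configuration is expressible but not practical without hardware
  acceleration.
* Sensitivities are the simulated ground truth; no ESPIRiT-style calibration
  from data is provided.
* Single-component relaxation models only; no B1 correction, no Rician bias
  handling, no non-Cartesian trajectories.
* The zero-shot early-stopping rule assumes the validation split is
  informative; with extremely small Γ sets the stop can be noisy.
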