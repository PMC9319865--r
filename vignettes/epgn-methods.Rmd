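---
title: "Unrolled extra proximal-gradient networks: model, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unrolled extra proximal-gradient networks: model, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epgnet)
```

## The reconstruction problem

Compressive sensing recovers an image $x \in [0,1]^{H \times W}$ from
$m < n = HW$ linear measurements $y = A x$. The package supports two
sensing models:

* **Block CS** — 33×33 luminance patches, vectorised and measured by a
  random Gaussian matrix whose rows are orthonormalized
  (`make_gaussian_operator()`), with $m = \mathrm{round}(\rho n)$ at
  sampling ratio $\rho$. Orthonormal rows give $A A^\top = I$, which fixes
  the Lipschitz constant of the data-fidelity gradient at 1 and makes unit
  step sizes safe.
* **CS-MRI** — whole images measured through $\Phi = P F$, where $F$ is the
  orthonormal 2-D DFT ($1/\sqrt{n}$ scaling both ways, so the full-mask
  operator is an isometry) and $P$ selects the coefficients on a binary
  radial mask (`make_radial_mask()` + `make_fourier_operator()`).

The objective is $f(x;y) + g(x)$ with fidelity
$f(x;y) = \tfrac12 \lVert A x - y\rVert^2$, so $\nabla f = A^H (Ax - y)$.
The unsquared-halved convention differs from $\lVert \Phi x - y \rVert^2$
only by a factor of two, which the learned (or user-chosen) step sizes
absorb; we state it explicitly because every gradient in the package
follows it. For the Fourier operator the measurements are complex while the
image is real, so the gradient takes the real part of the adjoint residual;
magnitude images are assumed throughout.

## The classical optimizer

`epg_solve()` implements the accelerated extra proximal-gradient scheme:
each iteration performs a momentum extrapolation, a gradient step of size
$\alpha_k$, a proximal step, a second extrapolation, a gradient step of
size $\beta_k$, and a second proximal step. It is a predictor–corrector
scheme: the half iterate $x_{k+1/2}$ predicts, the full iterate corrects
using a gradient evaluated at the extrapolated prediction. Design choices
where the scheme itself leaves room:

* **Initialization** $x_0 = A^H y$ (the adjoint, i.e. zero-filled,
  reconstruction), with $x_{-1/2} = x_0$.
* $\alpha_k$ and $\beta_k$ are kept **independent** even though setting
  them equal is a common simplification; constant schedules are the
  default and per-iteration vectors are accepted.
* **Divergence guard**: the solver aborts when the iterate norm exceeds
  $10^6$ times the initial norm, or when a sub-step produces non-finite
  values (the error names the sub-step).
* The objective trace records $f + g$ at the full iterates only.

`fista_reference()` and `ista_reference()` provide standard accelerated and
plain proximal-gradient solvers. They exist as high-accuracy oracles for
the test suite (the solver is checked against FISTA and against a cyclic
coordinate-descent LASSO solver on small problems) and are not tuned for
production use.

## The unrolled network

`epgn_network()` builds $K$ phases, each mirroring one iteration with the
two proximal steps replaced by the learned residual update
$x = b + \tilde G_k(S_k(G_k(b)))$ (plain) or
$x = b + \tilde G_k(N_k(S_k(G_k(b))))$ (nonlocal). Structural decisions,
most of them forced by the exact per-phase parameter budget:

* All six convolutions per phase are **3×3, stride 1, zero same-padding,
  bias-free**. Any bias terms would add 32–65 scalars per phase and break
  the 37,475 count at $N_f = 32$; padding is count-neutral, and zero
  padding is adopted. The encoder composition $B\circ\mathrm{ReLU}\circ
  A\circ D$ has a 7×7 receptive field (verified by impulse response in the
  tests).
* **Sharing**: the two residual updates inside a phase share one parameter
  set; phases share nothing with each other.
* **Thresholds** $\theta_{k,j}$ are per-channel, initialized at 0.01, and
  left unconstrained during training: the shrinkage formula
  $\max(|z|-\theta, 0)\,\mathrm{sign}(z)$ stays well defined for negative
  thresholds (it then acts as identity-minus-nothing on a widened band),
  which deviates from a strict proximal interpretation but keeps the
  optimization unconstrained.
* **Momentum** $\gamma_k$ starts at 0, so untrained phases are plain
  proximal-gradient steps; both step sizes start at 1, appropriate for
  operators with unit-norm rows.
* $x_0 = A^H y$, as in the classical solver.

### The nonlocal operator

$N_k$ computes embedded-Gaussian attention in an $N_f/2$ bottleneck: row
$i$ of the attention matrix is the softmax over $j$ of
$\langle W_\alpha z_i, W_\beta z_j\rangle$ (computed with row-max
subtraction for stability), applied to the $W_\varphi$ projection, expanded
back to $N_f$ channels, concatenated pixelwise with the local features and
projected $2N_f \to N_f$ by $C_k$ with a ReLU. Two points were genuinely
ambiguous at an identical parameter budget and are resolved as follows:

* The **bottleneck factorization** uses $W_\varphi: N_f \to N_f/2$ followed
  by an expansion $N_f/2 \to N_f$ (rather than a full-width $W_\varphi$
  with no expansion, which has the same scalar count), because the
  bottleneck's purpose is to reduce the $O((HW)^2)$ attention cost.
* The **fusion projection** $C_k$ outputs $N_f$ channels (one scalar per
  output channel per pixel). A literal scalar-per-pixel output would be
  incompatible with the decoder's $N_f$-channel input and with the
  4,096-parameter block budget ($3 \times 16\cdot32 + 16\cdot32 + 64\cdot32$
  at $N_f = 32$).
* There is **no residual connection inside** the block; the only skip is
  the outer one around the whole residual update. Attention runs over all
  pixels of the input (a 33×33 patch yields a 1089×1089 attention matrix);
  no windowing or subsampling is applied.

### Parameter accounting

Per plain phase: encoder $9 N_f (1 + 2 N_f)$ + decoder the same + 1
momentum + 2 step sizes + $N_f$ thresholds; the nonlocal block adds
$4 N_f^2$. At $N_f = 32$: 37,475 and 41,571; the 9-phase plain and 7-phase
nonlocal networks total 337,275 and 290,997. `count_parameters()` evaluates
the formula and `enumerate_parameters()` independently walks every stored
tensor; the acceptance script reports the enumeration, not the formula.

## Training

`epgn_train()` minimizes the mean over the batch of
$\lVert x_K(y^{(i)}) - x^{(i)}\rVert^2$ (summed over pixels within an
image). Gradients are hand-derived reverse-mode: every layer (convolution,
ReLU, shrinkage, attention softmax, momentum extrapolation, gradient step)
has an explicit adjoint, and the Jacobian of the gradient step
$b = x - s\,A^H(Ax-y)$ reuses the symmetric normal operator $A^H A$. The
implementation is validated against central finite differences on every
parameter class, including the attention projections. The 3×3 convolutions
— the hot path — run in compiled code as im2col gathers feeding BLAS
matrix products.

Full-scale defaults: Adam with learning rate $10^{-4}$,
200 epochs, and Xavier-uniform initialization of all convolution kernels
(bounds $\sqrt{6/(\mathrm{fan_{in}}+\mathrm{fan_{out}})}$ with fans counted
over the full kernel support). Batch size (64) and the Adam moment
constants (0.9, 0.999) are
package defaults, exposed in `train_config()`; there is no learning-rate
schedule, weight decay, or gradient clipping. Measurements are simulated on
the fly as $y = Ax$ per minibatch; shuffling is seeded per epoch so a run
can be resumed from any checkpoint and replay the uninterrupted trajectory
bit for bit. A non-finite loss aborts training with the last good
parameters retained.

## Synthetic phantoms

`make_phantoms()` generates piecewise-constant scenes (random ellipses,
rectangles and thin bars at random intensities over a flat background) plus
a low-amplitude smooth sinusoidal texture and optional Gaussian noise,
clipped to $[0,1]$. Defaults: 64×64 images, 6 shapes, texture amplitude
0.03 (two sinusoids with wavelengths of at least half the image, so the
texture gradient stays below the piecewise-constant edge scale), no noise.
These defaults emulate what the learned regularizer exploits in natural
images — sparsity of gradients and repeated geometric structure — and give
gradient histograms in which well over half the pixels are flat to within
0.01. For MRI-style whole-image work, 190×190 is the intended size
(`phantom_spec(size = c(190, 190))`).

What phantoms do *not* emulate: natural-image textures with broadband
spectra, scanner noise statistics, complex-valued MRI phase, and the sheer
scale of real training corpora (a full-scale training corpus runs to ~90k patches;
the desk-scale suite uses 200). Passing tests therefore demonstrate that
the implementation learns and that the architecture behaves as specified —
not that it reaches full-scale reconstruction quality on real data, which
requires the original datasets and GPU-scale training and is out of scope
here.

## Problem sizes used by the test suite

The suite trains a 3-phase, 8-channel plain network on 200 phantom patches
(33×33, 25% Gaussian sampling) for 30 epochs with Adam at $10^{-3}$ and
batch size 16 — a configuration chosen so the whole suite runs in minutes
on one CPU while leaving wide margins on its assertions (the trained
network must halve its first-epoch loss and beat the adjoint baseline by at
least 1 dB on held-out phantoms; observed margins are roughly 17× and
11 dB). The learning rate is higher than the full-scale default because
the run is two orders of magnitude shorter; it is a property of the test
configuration, not a recommendation for full-scale training.

## Numerical details and edge cases

* Soft shrinkage at $z = 0$ returns 0 (the `sign` convention handles the
  removable singularity); its derivative at the kink is taken as 0.
* Attention softmax subtracts the row maximum before exponentiation.
* `make_radial_mask()` finds the spoke count by bisection so the sampled
  fraction lands within ±2% of the target; at very small grids the spoke
  quantization can make ±2% unreachable, in which case the constructor
  errors with the achieved fraction (callers that only need a valid mask,
  not an exact ratio, can widen `tol`). The DC coefficient is always
  sampled.
* PSNR uses peak 1.0 on normalized images and caps identical pairs at
  99 dB with a `capped` attribute; SSIM is single-scale with the standard
  11×11 Gaussian window (σ = 1.5), constants $K_1 = 0.01$, $K_2 = 0.03$,
  computed on valid windows only.
* Block-CS evaluation pads test images to a multiple of 33 by edge
  replication, reconstructs non-overlapping blocks, reassembles, and crops;
  per-image (not per-block) metrics are reported as mean ± sd.
* Checkpoints use R's native serialization (`.rds`), which round-trips all
  tensors bit-exactly; training settings can be read from YAML files with
  `read_train_config()` (suggested `yaml` package).

## Known limitations

Attention cost grows quadratically in pixel count, so the nonlocal variant
is practical here for patches and small frames (a config-level cap on
attention size is advisable for frames beyond ~96×96 on modest hardware).
Training is single-device and double-precision; no mixed precision or
multi-device support. Color images are handled only via luminance
conversion (BT.601). True non-Cartesian MRI gridding, coil sensitivities,
and scanner noise models are out of scope.
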