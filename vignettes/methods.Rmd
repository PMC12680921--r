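---
title: "Conditional equivariant graph networks for heterogeneous soft-tissue indentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional equivariant graph networks for heterogeneous soft-tissue indentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pressing a probe into soft tissue that covers a rigid structure (bone under
silicone, in the physical phantom this package emulates) produces a surface
deformation field and a reaction force. Finite-element contact simulation
predicts both accurately but at seconds per static state; interactive surgical
simulation needs milliseconds. `deformgnn` implements a learned surrogate: a
graph neural network that maps a sparse surface point cloud, per-point tissue
composition features and a probe condition to the deformed cloud and the
scalar contact force.

Two things distinguish the architecture from a plain point-cloud regressor:

* **Tissue conditioning.** Every surface point carries a 128-sample binary
  depth profile (0 = soft, 1 = rigid) plus the sampled z positions, so the
  model knows how much compliant material lies beneath it. The probe line
  from the surface contact `Cs` to the probe end `Ce` is sampled the same way
  (`Ch`, a flattened 4 x 128 block of x, y, z, occupancy), telling the model
  *where* and *through what* the load is applied.
* **Equivariant message passing.** Coordinates are updated with difference
  vectors — neighbour differences weighted by a learned scalar of the
  message, plus two condition terms anchored at `Cs` and `Ce` — so the
  geometric structure of the update is carried by vectors that rotate with
  the scene, not by raw coordinates.

## The layer

With node features $h_i$, coordinates $x_i$ and a dynamic kNN graph
($k = 5$, self excluded, rebuilt from the current coordinates at every
layer), one conditional equivariant graph convolution layer computes

$$m_{ij} = \phi_e\!\left(h_i, h_j, \lVert x_i - x_j\rVert^2\right),$$

$$x_i \leftarrow x_i + \phi_{cs}(x_i - C_s) + \phi_{ce}(x_i - C_e)
  + \tfrac{1}{k-1}\textstyle\sum_{j}(x_i - x_j)\,\phi_x(m_{ij}),$$

$$h_i \leftarrow h_i + \phi_h\!\left(h_i, \textstyle\sum_j m_{ij}\right),$$

with $\phi_e$ (two SiLU layers), $\phi_x$ (scalar-valued), $\phi_h$
(residual) and the condition MLPs $\phi_{cs}, \phi_{ce}$ all hidden width
64. After $L = 4$ layers the displacement branch concatenates the per-point
coordinates of all layers with $C_s$, $C_e$ and $C_h$
(width $4\cdot3 + 3 + 3 + 512 = 530$) and regresses the per-point
displacement through a 530→512→256→128→3 ReLU MLP with dropout 0.3;
$\hat y = x_0 + u$. The force branch encodes
$z_i = \phi_{feat}(\hat y_i - C_e,\; \tilde h^0_i - C_h)$ per point
(input width $3 + 512 = 515$), pools with global max **and** mean, and
regresses the force through a 256→512→256→128→1 MLP with dropout 0.2.
Dropout is active only in training; inference is deterministic.

### Literal and strict modes

The coordinate update above can be read two ways, and the package implements
both:

* **literal** (default): $\phi_{cs}, \phi_{ce}$ are vector-valued
  3→64→3 MLPs and the displacement readout consumes absolute coordinates.
  This reading is *not* exactly rotation-equivariant — consistent with the
  observed degradation of such models on rotated test sets, which would be
  impossible if they were exact.
* **strict**: the condition terms become scalar gates
  $(x_i - C_s)\,\tilde\phi_{cs}(\lVert x_i-C_s\rVert^2)$, the prediction is
  $\hat y = x^L$ directly (no absolute-coordinate readout), and the force
  branch consumes rotation-invariant reductions of its difference vectors:
  the in-plane norm and z component of $\hat y_i - C_e$, and per-sample
  in-plane norms of the x,y blocks of $\tilde h^0_i - C_h$. The raw x,y
  pairs rotate with the scene, so a literal Eq.-style force branch cannot be
  rotation-invariant; replacing each rotating 2-vector by its norm is the
  minimal invariantisation that preserves the block structure. Strict-mode
  models are equivariant to z-rotations and in-plane translations to
  numerical precision (the tissue features contain z positions and binary
  labels only, which such transforms leave fixed), and the test suite
  verifies this at 1e-5 mm / 1e-6 N on both untrained and trained weights.

Node features enter the ablation switch `tissue_features = FALSE` as zeros,
which reproduces a "no anatomy" baseline with identical wiring.

### Numerical choices

* kNN ties are broken by lower node index; `k` is clamped to the cloud size.
* The readout concatenates $x^1 \dots x^L$ (the layer *outputs*), not $x^0$.
* Weight init: He-normal for ReLU layers, Xavier-uniform otherwise. The
  output layers of $\phi_x$, $\phi_{cs}$, $\phi_{ce}$, the readout and the
  force regressor start at zero in training init, so the untrained model
  predicts the identity deformation and zero force — a stable fixed point to
  learn from. First-layer weights on millimetre-valued inputs (squared
  distances up to ~10^3 mm^2, coordinates up to 100 mm) are shrunk at init
  to balance them against binary features; this is initialisation only, the
  functional form is untouched.
* All gradients are hand-derived reverse-mode passes over the exact forward
  computation (no autodiff framework is involved); finite-difference checks
  guard every parameter group at 1e-4 relative tolerance.

## The training objective

Per sample, the displacement loss weights each point's squared error by its
relative ground-truth deformation magnitude,

$$L_d = \frac1N \sum_i w_i\,\lVert \hat y_i - y_i \rVert^2,\qquad
  w_i = \frac{\lVert y_i - x_i \rVert}{\max_i \lVert y_i - x_i \rVert + \varepsilon},$$

with $\varepsilon = 10^{-8}$, so the contact region dominates and the large
almost-static far field does not drown the signal. The total loss is
$L = \alpha L_d + \beta L_f$ with $\alpha = 1000$, $\beta = 100$ and $L_f$
the batch-mean squared force error (the batch-mean is our reading; a
per-sample normalisation would only rescale $\beta$). Training uses Adam,
200 epochs, batch 64 (dense grid data) or 16 (sparse experimental-like
data), learning rate 1e-3, reduced to 1e-4 for fine-tuning; the schedule is
constant since none is stated. Reported metrics are always *unweighted*
Euclidean distances — the weighting is a training device only. Best-epoch
selection uses validation mean Euclidean distance (no selection rule is
prescribed; this matches the headline metric).

A degenerate sample with zero deformation makes every $w_i \approx 0$ and
$L_d = 0$ regardless of the prediction; the loss function warns when this
happens.

Splits are stratified by probe location — every static state of a location
lands in one partition — in three schemes: 7:2:1 holdout (rounded to
nearest, remainder to train), five-fold CV, and leave-one-location-out for
small experimental-like sets.

### Batching and point subsampling

A training batch is assembled as one disconnected graph (block-diagonal kNN
edges with a per-node sample index), so the shared MLPs run as single BLAS
calls; this is numerically identical to per-sample evaluation and tested as
such. Because no layer assumes a fixed point count, training steps may
legitimately draw a random subset of each cloud's points
(`point_subsample`): the model is then trained across densities, which is
exactly the cross-resolution robustness the architecture claims. Evaluation
always uses full clouds.

The subsample can be importance-biased (`subsample_bias`): a fraction of
the drawn points is sampled with probability proportional to the point's
ground-truth deformation magnitude. With a compactly supported contact
field, a uniform draw spends almost every point on the static far field
where the weighted loss is ~0; biasing the draw concentrates compute where
the loss actually lives. Each step still minimises the exact weighted loss
of the drawn cloud — only the training clouds' density changes, which is a
dataset-protocol choice of the same kind as training on marker subsets.

### Optimizer safeguards

Two safeguards keep the default Adam loop healthy, both standard practice
and both off the loss-function definition:

* **Gradient clipping** (`clip_norm`, default 5e5 — a few times the
  healthy per-step gradient-norm maximum at the default loss weights, so
  nominal steps are never touched). Without it an
  occasional exploding step (the force head can transiently predict
  hundreds of newtons early in training) inflates Adam's second moments by
  orders of magnitude and silently freezes learning for hundreds of steps.
* **Decoupled weight decay** (`weight_decay`, AdamW-style, applied to
  weight matrices only). The relative weighting in $L_d$ gives
  almost-static points almost-zero gradient, so nothing in the loss stops
  the readout from drifting on the far field — an error the *unweighted*
  reported metrics do count. Shrinkage pulls unsupervised outputs toward
  zero displacement, which is the physically correct far-field limit.
  Validation curves without it show the signature: weighted training loss
  falls while validation mean Euclidean distance rises.

## The synthetic indentation generator

The original experiments use a silicone phantom over a 3D-printed bone shape
(100 x 100 mm footprint, 32 mm total height, 40 tracked markers, 39 poke
locations, states kept at 0.1 N increments) plus quasi-static FEM runs (1024
grid points, 592 probe locations, depths to 30 mm, inclinations to 41°,
12,387 retained states). Neither dataset is deposited, so the package ships
a generator that emulates their *statistical structure* with an analytic
contact surrogate:

* **Phantoms**: 1–4 rigid primitives (boxes, spheres, vertical cylinders)
  fully inside the domain, tops at least 4 mm below the surface so a soft
  layer always exists.
* **Displacement field**: a point at perpendicular distance $r$ from the
  probe axis moves $\delta\,e^{-r^2/2\sigma_c^2}$ along the probe direction
  ($\sigma_c = 8$ mm), clamped to $0.9\times$ the soft column remaining
  above the rigid structure (0.5 mm margin) — the stand-in for tissue–bone
  contact — plus a small outward radial bulge (amplitude 0.1) conserving a
  visual impression of volume.
* **Force law**: $F = k_s\delta + k_c(\delta / \max(t_p-\delta,\,t_{min}))^p$
  with $k_s = 0.08$ N/mm, $k_c = 0.5$ N, $p = 2$, $t_{min} = 1$ mm and
  $t_p$ the soft thickness under the contact point: linear surface
  stiffness plus thin-layer stiffening, strictly increasing in depth and
  stiffer over shallow bone.
* **Depth schedule**: loading steps grow linearly to a per-location target
  depth drawn as a fraction (0.4–1) of the feasible depth
  $\min(30\,\text{mm},\ 0.8\,(t_p - m),\ 0.9\,(d_{bone} - m))$, where
  $d_{bone}$ is the free path along the probe line. A physical probe cannot
  pass through bone, and this cap also keeps maximum forces in the few-newton
  range of the reference phantom (about 3–9 N at full indentation depending
  on soft thickness) rather than the hundreds of newtons the force law would
  produce if $\delta$ were driven far past $t_p$.
* **Retention**: the first contact state is always kept; later states only
  when force has grown ≥ 0.1 N since the last kept state. Optional marker
  noise is isotropic Gaussian (0.2 mm emulates motion-capture accuracy).

Everything is a pure function of (spec, seed); regeneration is bit-identical
and the manifest records the spec, seed, per-location max force
(mean ± sd), mean nearest-neighbour spacing and mean probe travel — the
summary statistics the reference datasets are described by. At defaults the
generated numbers land in the same range (max force ≈ 3 ± 2 N, probe travel
≈ 10 ± 6 mm).

What the surrogate deliberately does **not** model: hyperelastic
constitutive behaviour, friction, dynamic response, FEM-grade contact
mechanics. Tests passing on generated data therefore demonstrate that the
*learning machinery* works — equation fidelity, symmetry, protocol
correctness, trainability — not that the model reproduces the absolute
errors reported on the original FEM/phantom data, which would require those
datasets and GPU-scale training.

## Evaluation protocols

`evaluate_metrics()` reports the four standard columns (force absolute
error, mean and max Euclidean distance, relative tip error). The "tip" is
the rest point nearest to `Cs` and the tip distance is the probe travel
$\lVert C_e - C_s\rVert$; the alternative reading (marker displacement at
the tip) is available from the same per-sample records, but probe travel is
the default since the reference tip distances (≈ 17 mm mean, 30 mm max
depth) match travel better than marker motion. Rotated tests apply 90°
increments about the vertical axis through the domain centre — features
transform in closed form, nothing is recomputed from the volume — and
cross-resolution tests evaluate a sparse-trained model on dense grids.
`equivariance_check()` audits arbitrary z-rotations plus in-plane
translations.

## Problem sizes used in the shipped tests

The test-suite and acceptance-script runs are scaled to a single CPU: the
overfit check uses 16 samples of 40 points for 500 steps; the
generalisation check trains on a 32x32-grid dataset with 50 probe locations
(~650 retained states) using 64-point uniform subsampling, weight decay
0.3 and validation-selected early stopping for 800 steps, then evaluates
on full 1024-point clouds; the cross-resolution check trains the same
architecture on 40-point scattered clouds for 800 steps. Oracle and
symmetry checks run on clouds of 4–30 points with reduced feature widths
(the layer mathematics is width-agnostic). These sizes are the package's
own choices for fast, deterministic verification; nothing in the
implementation depends on them.

At these sizes the trained surrogate clearly beats the zero-displacement
baseline on held-out probe locations (~0.39 mm vs 0.46 mm mean error,
with the residual concentrated in the contact region) and transfers
across point densities within a factor two, but it does not reach the
~20 % relative error that full-scale training attains. Two structural
reasons compound: the relative weighting removes essentially all
supervision from the ~70 % of grid points the contact kernel never moves,
and the CPU budget affords roughly three orders of magnitude fewer
optimisation steps x points than the reference training runs. Weight
decay bounds the unsupervised far-field drift but cannot substitute for
contact-region optimisation.

## Known limitations

* The analytic surrogate's displacement field is axisymmetric around the
  probe axis apart from the bone clamp; real FEM fields are not.
* Literal mode's rotation robustness is an empirical property of training,
  not a guarantee; only strict mode is provably equivariant, and only under
  z-rotations/in-plane translations (full 3D equivariance would require
  tissue features without absolute z positions).
* Force prediction shares parameters across probe inclinations; no temporal
  modelling (each static state is independent).
* Training is single-threaded CPU BLAS; the implementation favours
  correctness and auditability over speed and is not a haptic-rate engine.
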