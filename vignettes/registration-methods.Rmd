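---
title: "Rigid slice-to-volume ultrasound registration: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid slice-to-volume ultrasound registration: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The registration model

A 3D ultrasound volume $I_{3D}$ is acquired once; live 2D frames
$I_{2D,t}$ arrive with a tracked pose $\theta^{tracked}_t$ that ignores
internal organ motion. The task is the rigid correction
$\delta\theta_t$ minimizing a dissimilarity between the frame and the
resampled volume,
$$\delta\theta_t \;=\; \arg\min_{\delta\theta}\;
  L\bigl\{\,R[I_{3D},\,T(\theta^{tracked}_t)\cdot T(\delta\theta_{t-1})\cdot T(\delta\theta)],\;
  I_{2D,t}\,\bigr\},$$
where $R[\cdot,\cdot]$ extracts the 2D plane of the slice frame from the
volume and the previous frame's correction $\delta\theta_{t-1}$ enters the
initial transform (motion is temporally smooth, so last frame's correction
is a good starting point — the temporal-chaining property verified in the
test suite).

**Conventions.** All transforms are elements of SE(3) acting on physical
coordinates in mm *relative to the 3D volume center*, as
$y = Rx + t$; the rotation center is carried explicitly and composition
across different centers is rejected. Euler angles, where exposed, are
intrinsic rotations applied in $x \to y \to z$ order; this convention is
not dictated by the method (any fixed choice only relabels perturbation
fixtures) and is recorded here so fixtures are reproducible. Angles are
radians internally and degrees at API boundaries.

# Differentiable volume slicing

`make_reference_grid()` / `transform_grid()` / `interpolate()` implement
the spatial-transformer resampler: the slice's centered $z=0$ lattice is
mapped by the pose into volume coordinates and trilinearly interpolated,
with zero fill and a validity flag outside the volume extent. Masks are
interpolated with the same scheme and re-binarized at 0.5, which keeps
them binary while tolerating sub-voxel plane positions.

Numerical choices:

* The lerp is computed in the $(1-f)a + fb$ form, which is exact at
  $f \in \{0, 1\}$, and sampling coordinates within $10^{-9}$ voxel of a
  lattice plane are snapped onto it — together these make resampling a
  volume onto its own lattice bit-exact, a property the tests rely on.
* Trilinear interpolation is $C^0$ but not $C^1$ across lattice planes;
  gradients use the within-cell derivative. On band-limited images the
  analytic pose gradient matches central finite differences to about
  $10^{-3}$ relative error (verified in the tests); on raw speckle the
  agreement is looser, which is why smoothing is part of the phantom
  design (below).
* The interpolation order and fill value are not uniquely determined by
  the method description; trilinear with zero fill is the package's
  choice, matching common practice in learning-based registration.

The backward path `slice_pose_backward()` accumulates
$\partial L/\partial t = \sum_p w_p g_p$ and
$\partial L/\partial R = \sum_p w_p g_p x_p^\top$ from the per-pixel loss
gradient $w_p$ and intensity gradient $g_p$, and
`sixd_jacobian()` chains into the 6D rotation parameters, so the full
pipeline network → pose → resampler → similarity is differentiable.

# The 6D rotation representation

Rotations are regressed as the first two columns $(a_1, a_2)$ of the
rotation matrix and recovered by Gram–Schmidt:
$b_1 = N(a_1)$, $b_2 = N(a_2 - (b_1\!\cdot\!a_2) b_1)$,
$b_3 = b_1 \times b_2$, assembled as *columns*. The printed form of this
construction is ambiguous about row versus column assembly (a trailing
transpose in the typesetting); the column reading is the one consistent
with dropping a column in the forward map, and the round-trip property
(identity on SO(3) to $10^{-9}$ over 1000 random rotations) pins it down.
This parameterization is continuous on SO(3) — unlike Euler angles or
quaternions — and the mapped output is orthonormal by construction, so
refinement iterates and network outputs never drift off the manifold.

The geodesic angular error is
$\mathrm{GA} = \arccos\bigl((\mathrm{tr}(R_a R_b^{-1}) - 1)/2\bigr)$, with
the arccos argument clamped to $[-1, 1]$ because the trace can exceed the
bound by $\sim 10^{-16}$. Its gradient has a $1/\sqrt{1 - c^2}$ factor
that diverges at perfect alignment; inside the training loss the
denominator is floored at $10^{-6}$, which caps the gradient magnitude
without changing its direction.

# Masked-intersection LNCC

The local normalized cross-correlation is computed on windows centered at
*every* pixel, restricted to the joint validity mask
$m = m_a \wedge m_b$: window means, variances and covariances are
mask-weighted, and a window contributes to the average only if at least
half of its in-image pixels are inside $m$. Two points deserve comment:

* **"Window area"** is the number of in-image pixels of the
  boundary-clipped window, not the nominal kernel$^2$. Besides treating
  boundary windows sensibly, this makes the metric collapse exactly to the
  global NCC when the kernel covers the whole image (a test property).
  The half-occupancy threshold itself is a package choice — the method
  description prescribes computing the metric on the intersection but no
  occupancy rule — selected to suppress near-empty, high-variance windows.
* **Variance stabilization** uses
  $\mathrm{ncc} = \mathrm{cov}/\sqrt{\max(v_a,\varepsilon)\max(v_b,\varepsilon)}$
  with $\varepsilon = 10^{-5}$ rather than adding $\varepsilon$: flat
  (speckle-free) windows are pushed to 0 instead of dividing by ~0, while
  genuinely correlated windows score exactly 1 — an additive
  $\varepsilon$ would bias even identical images below 1.

Joint overlap below `min_overlap_fraction` (default 0.05 of the smaller
input mask) raises a typed condition rather than returning an unreliable
number; training skips such samples' image term and counts them, and the
workflow reports a failed frame while passing the tracked pose through.

The backward pass is the standard windowed-NCC gradient extended with mask
weights, evaluated with four box-filter passes (summed-area tables), so a
$96^2$ slice with a 51-pixel kernel costs a few milliseconds.

The combined training loss is
$\alpha (1 - \mathrm{LNCC}) + \beta \|t - t^{gt}\|^2 + \gamma\,\mathrm{GeoErr}$
with $\alpha\!:\!\beta\!:\!\gamma = 20\!:\!1\!:\!10$ normalized to sum 1,
translations in mm and the geodesic term in radians. The sign of the LNCC
term is implemented as $1-\mathrm{LNCC}$: the metric is maximal at
alignment, so minimizing $+\mathrm{LNCC}$ would reward misalignment; the
constant 1 keeps the term nonnegative and zero at a perfect match.

# The regression network

Defaults (`network_config()`): $64^3$ volume and $64^2$ frame inputs, four
stride-2 $3^3$ (or $3^2$) convolution + ReLU stages with channels
8→16→32→64, linear projections to a $16\times16$ 3D-feature matrix and a
length-64 2D-feature vector, outer-product fusion to a
$16\times16\times64$ "volume", a three-stage 3D decoder (8, 16, 32
channels) and two fully-connected layers emitting 9 numbers. The head's
bias is initialized to the 6D identity rotation with zero translation and
its weights at scale $10^{-3}$, so an untrained network predicts
(near-)identity corrections — the safe default in a correction workflow.

Points where the published architecture is under-determined, and the
package's resolutions:

* Layer counts, channel widths, normalization and activation choices are
  not specified; the defaults above are the smallest stack that preserves
  the fusion topology and trains in minutes on one CPU core. Everything
  is configurable.
* The fusion indexes a 3D feature map with two indices $(i,j)$; the
  package realizes this as a learned linear projection of the flattened
  encoder output to a $16\times16$ matrix. The fusion itself is exactly
  the outer product and has zero parameters.
* The previous correction $\delta\theta_{t-1}$ enters *only* through the
  composed initial transform applied to the volume before encoding, never
  as an extra input vector.

Training uses Adam with a step-decay schedule; the configuration defaults
mirror the reference schedule (learning rate $10^{-6}$, decay 0.8 every 80
epochs, batch 2, LNCC kernel 51) appropriate for long training runs at
clinical image sizes. The desk-scale experiments in the tests and the
acceptance script instead train for 10 epochs at learning rate $10^{-3}$,
batch 4, LNCC kernel 21 on $64^2$ frames — a from-scratch schedule sized
for small images; at $10^{-6}$ a 10-epoch run would not move the fresh
weights measurably. Ground-truth corrections come from the phantom
generator's exact poses, which replaces the human-confirmed ground truth
used with clinical data (a stronger oracle).

# Iterative refinement and the classical baseline

`refine_correction()` performs gradient *ascent* on the masked LNCC over
the 9 pose parameters (6D rotation + translation) through the analytic
gradient chain. Steps are applied to normalized parameter-block gradients
— rotation and translation scaled separately — with initial step sizes
0.5 mm and 0.02 (6D units), halved whenever a candidate step fails to
improve the similarity, up to 200 iterations or until both steps fall
below $10^{-3}$ of their initial values; the best-seen pose is returned,
so the similarity trace is nondecreasing by construction. The step sizes
and budget are package choices (no published values exist): with
normalized steps the total travel is bounded by
(iterations × step), and these defaults give ~100 mm of reach —
comfortably covering the half-augmentation-range starts used in the
recovery experiments — while halving drives the final precision orders of
magnitude below the initial step. "Stochastic" gradient descent with a
single image pair has no batching dimension; this full-gradient scheme is
the faithful single-pair reading.

`gncc_baseline()` is the classical-toolkit counterpart: global NCC over
the joint masks, optimized over Euler angles + translation with central
finite differences (half-steps 0.05 mm / 0.05°) and the same
step-halving policy (initial steps 0.5 mm / 0.5°).

# The synthetic phantom generator

`generate_phantom()` emulates the gross appearance of abdominal B-mode
volumes: a smooth background parenchyma (level 0.5) with a low-frequency
intensity drift, 4 dark vessel tubes (level 0.12, radii 1.5–3.5 mm)
following smooth random walks, one bright curved diaphragm-like sheet
(level 0.95, ~1.5 mm thick), multiplicative Rayleigh-like speckle
(strength 0.35) and Gaussian smoothing of 0.8 mm. The default grid is
$96^3$ at 0.5 mm — the preprocessing target spacing. The speckle law is
deliberately simple: the LNCC is invariant to local positive affine
intensity maps, so the precise noise distribution is not critical to the
registration behavior being tested; the smoothing sigma matters more,
since it sets the capture range of intensity-based refinement.

`make_pair()` draws an exact slicing pose uniformly within an envelope
that keeps at least 50% of the slice valid (low-overlap draws are
rejected and redrawn, mirroring the exclusion of low-overlap clinical
pairs; the published exclusion threshold is unstated, 50% is the
package's choice), extracts the reference frame, and composes a tracking
perturbation drawn from the augmentation distribution — translations
$U(-10,10)$, $U(-10,10)$, $U(-5,5)$ mm and rotations $U(-5,5)$,
$U(-5,5)$, $U(-10,10)$ degrees on the $x,y,z$ axes — so that
$\theta^{tracked} = \theta^{true} \cdot P$ and the ground-truth correction
is exactly $P^{-1}$. By default the reference slice is the exact
extraction (no extra noise): the perturbed start, not sensor noise on the
reference, is the difficulty being modeled; slice noise can be enabled.

`make_sequence()` models breathing-like motion: the true pose follows a
smooth sinusoidal rigid trajectory (default 5 mm / 2° amplitude, 20-frame
period) around a base pose while the tracked pose stays at the base pose
plus small independent per-frame jitter (10% of the augmentation ranges)
— i.e. the tracker does not see the organ motion, which is exactly the
situation the temporal workflow addresses.

`candidate_poses()` reproduces the evaluation-fixture protocol of
perturbing a registered pose with $N(0, 1)$ mm translation and
$N(0, 1.5)$° rotation noise (units are the package's reading; the source
omits them), 100 candidates by default; `rank_candidates()` scores them by
masked LNCC as an automated proxy for the human visual selection, which is
out of scope.

**What the phantoms do not model:** fan/curvilinear scan geometry,
attenuation and shadowing, speckle decorrelation between the 3D sweep and
the live 2D frames, tissue deformation, and out-of-volume anatomy.
Passing the recovery experiments therefore demonstrates the correctness
and capture behavior of the optimization and learning machinery, not
clinical accuracy; the headline clinical numbers of the motivating
application (ED ≈ 2.3 mm on 193 pairs) are measured on unshared patient
data and are not reproducible here.

# Preprocessing

`preprocess()` resamples isotropically to 0.5 mm, center-crops/zero-pads
to 400×320 (2D) or 400×320×240 (3D), rescales intensities to $[0,1]$ by
the per-image min–max (the scaling rule is unstated in the source; min–max
is the package's choice) and transports + re-binarizes the mask, with
padded regions masked out. The output lattice is centered on the input
center, so the operation is idempotent — verified bit-exactly in the
tests.

# Experiment sizes

The test suite and `scripts/acceptance.R` use desk-scale problem sizes
chosen once as part of the experimental design: recovery experiments on
$96^3$ phantoms at 0.5 mm with 50 (tests) or 25 (script) pairs perturbed
at half the augmentation ranges; network training on 200 pairs from four
$64^3$ phantoms at 1 mm spacing (full-range perturbations keep usable
overlap on the 64 mm extent, which the 32 mm extent of a $64^3$ half-mm
grid would not), 20 held-out pairs drawn from the same phantoms at new
poses, 10 epochs, three training seeds with a majority criterion; and a
20-frame sequence for the temporal-chaining comparison. Held-out pairs
share the phantom volumes (not the poses) with training, so the network
is evaluated on pose generalization only; generalization to unseen
textures or anatomy is a harder problem that these desk-scale
configurations do not attempt, and it is listed under limitations.

# Known limitations

* Trilinear interpolation's piecewise linearity makes similarity
  gradients noisy on raw speckle; refinement relies on the phantom's
  smoothing and on step-halving for robustness.
* The LNCC landscape is non-convex; starts far outside the augmentation
  ranges can converge to local optima (the GNCC baseline more so, lacking
  local normalization). No multi-resolution pyramid is provided.
* The network generalizes across poses but is not expected to generalize
  to unseen phantom textures or clinical images at the default desk-scale
  configuration.
* Only rigid motion is modeled; liver deformation is treated as
  negligible for the slice-correction task.
* Rotation centers must match for composition; transforms about other
  centers must be re-centered by the caller.
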