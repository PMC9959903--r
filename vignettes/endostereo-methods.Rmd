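---
title: "Dense stereo reconstruction for binocular endoscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense stereo reconstruction for binocular endoscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(endostereo)
```

## The problem

A rectified binocular endoscope sees an organ surface from two horizontally
displaced viewpoints. For a left-image pixel whose match in the right image
is displaced by a disparity of $d$ pixels, triangulation gives the metric
depth

$$Z = \frac{f \, B}{d},$$

with $f$ the rectified focal length in pixels and $B$ the baseline in
millimetres. Endoscopic scenes are hostile to classical block matching:
mucosal texture is faint, and specular highlights from the headlight
saturate patches of one view only, so a semi-global block matcher (SGBM)
leaves *holes* — pixels failing its uniqueness or left-right consistency
checks — and scattered mismatches. This package implements a complete
desk-scale pipeline around that failure mode:

1. **SGBM** produces an initial disparity map with an explicit validity mask.
2. **Iterative hole filling** repairs the mask using the fact that organ
   surfaces vary continuously in depth.
3. A **disparity confidence map (DCM)** scores every pixel of the repaired
   map photometrically, turning (image pair, filled disparity, DCM) into a
   training sample — no external ground truth is needed.
4. A compact **cost-volume refinement network** is trained on those samples
   with a DCM-weighted L1 loss, yielding smooth, hole-free disparity.
5. Predicted depth plus the left image emulate an RGB-D camera:
   **feature-based rigid odometry** chains frame poses, per-frame clouds are
   fused, and the reconstruction is evaluated against a reference surface by
   **coarse + ICP registration RMSE**.

A seeded synthetic scene generator supplies endoscope-like data with exact
ground truth, so every stage is testable without hardware.

## Synthetic scenes: what they emulate, and what they do not

`scene_spec()` describes an organ-like surface: a Gaussian random depth
field, low-pass filtered at a configurable smoothness scale (default one
sixth of the image size), standardized and mapped into a working-distance
band. The default band is 30–150 mm, a plausible range for gastroscopic
working distances; the pipeline's desk configuration narrows it to
40–120 mm so that the disparity range fits a small image. Texture is weak
band-limited albedo mottling (`texture_contrast`, default 0.35) on a
mucosa-like tint, with Lambertian shading from a headlight at the reference
camera — shading is baked into the albedo so it is consistent across views
and frames, which is what makes photoconsistency checks exact. Specular
blobs (saturated discs) and Gaussian sensor noise are applied
*independently per view*, so they genuinely violate photoconsistency the
way real highlights do.

The surface is generated with a margin strip beyond the frame-0 field of
view (`margin_px`, default half the image width) and all rendering raycasts
against this margin-extended height field, so the right eye and short
camera trajectories stay on defined surface. Texture lookups use bicubic
interpolation to keep resampling error well below 8-bit quantization.

Not emulated: photorealistic tissue appearance, non-rigid deformation
(breathing, peristalsis), fluids and smoke, rolling shutter, lens
distortion. Passing tests on these scenes demonstrates correctness of the
algorithms under rigid, Lambertian, weakly textured conditions — not
clinical performance.

The trajectory model translates the camera along a gently curving direction
with bounded per-step translation and a small per-step rotation
(default 0.25°). The desk default step of 1 mm corresponds to a scope
moving about 20 mm/s filmed at 20 frames per second.

## Hole filling

`detect_holes()` finds hole regions as the union of the matcher's invalid
mask and regions enclosed by Canny edges of the disparity image (rescaled
to 8-bit, invalid pixels at 0), morphologically closed (5×5 element) and
kept where they touch invalid pixels. The Canny thresholds (50/150 of 255)
and the closing element are configuration values with conventional
defaults.

`fill_holes_iterative()` repeatedly assigns to every hole-boundary pixel —
an invalid pixel with at least one valid 8-neighbour — the mean of valid
values in its $(2r+1)^2$ window (default $r = 2$), then marks it valid.
Updates are simultaneous (Jacobi-style) within an iteration, so results do
not depend on scan order. Because every nonempty hole has a nonempty
boundary, the hole count strictly decreases and termination is guaranteed;
an iteration cap (default 100) bounds the worst case, and hitting it
returns the partial result with a warning and residual mask rather than
failing silently. Filled values are means of valid in-range values and are
clamped to the valid input range, which makes the range-preservation
invariant exact even under the FFT round-off of the box filter.

`final_median_filter()` replaces only pixels below a low-disparity
threshold (default 5% of `max_disp`) with their 5×5 window median,
removing residual near-zero mismatches; all other pixels are returned
bit-identical.

## The disparity confidence map

If the left disparity map is correct, warping the right view to the left
view's geometry must reproduce the left view wherever the surface is
visible in both. The DCM quantifies this per pixel. For pixel $(i, j)$ and
channel $c$, over the $k \times k$ support window (default $k = 5$):

$$\mathrm{diff}(i,j,c) = \frac{1}{N} \sum_{(x,y) \in W(i,j)}
\left| \frac{I_l(x,y,c)}{\overline{I_l}} -
\frac{I_r(x,\, y - d(i,j),\, c)}{\overline{I_r}} \right|,$$

where each view is divided by its own window mean (so a global intensity
scale cancels), the right view is sampled at the disparity-shifted column
with linear interpolation along the row, $N$ counts the in-image window
pixels (windows truncate at borders), and the per-pixel difference is the
average over the three channels. The difference field is min–max
normalized over the image and the confidence is $\mathrm{DCM} = 1 -
\mathrm{Diff}_{\mathrm{norm}}$, clamped to $[0,1]$; a degenerate field
(constant difference) maps to confidence 1 everywhere.

Two implementation decisions matter here. First, the absolute value inside
the window sum: without it, each mean-normalized window sums to exactly
$N$ and the signed difference cancels identically to zero for *any*
disparity, making the score vacuous; the absolute photometric disagreement
is the quantity that actually carries information. Second, the whole
window is warped with the *centre* pixel's disparity. On a sloped surface
the true correspondence varies across the window, so even a perfect
disparity map retains a small windowed mismatch proportional to the local
disparity gradient — clean fixtures therefore score high median confidence
rather than uniformly near-1 confidence, and tests assert the former. The
vectorized implementation is verified bitwise against a literal
five-nested-loop transcription of the formula.

A flag matrix marks pixels whose window mean falls below $10^{-6}$
(all-black blocks); their ratio terms are treated as zero.

## The refinement network

The architecture follows the compact end-to-end stereo design: a Siamese
feature extractor downsamples both views with shared weights (5×5
convolutions of stride 2; 3 stages at full scale give 1/8-resolution
features), followed by residual blocks (3×3 convolution, batch
normalization, ReLU). The matching cost is the *difference* of left and
right feature maps over `max_disp / 2^stages` disparity levels, filtered
by a stack of 3×3×3 3D convolutions down to one channel, and disparity is
regressed with the differentiable soft argmin

$$\hat d(y,x) = \sum_d d \cdot \mathrm{softmax}_d(-c(d,y,x)).$$

Hierarchical refinement then upsamples bilinearly ×2 per level (disparity
values scaled ×2), concatenates the left image at that scale, and adds a
residual correction from a small convolution stack whose last layer is
zero-initialized — an untrained network therefore reproduces plain
bilinear upsampling exactly, a property the tests pin down.

The loss is the DCM-weighted mean absolute disparity error,

$$\mathcal{L} = \frac{1}{HW} \sum_{i,j} \mathrm{DCM}(i,j)\,
\lvert d(i,j) - d'(i,j) \rvert,$$

with $d'$ the hole-filled pseudo ground truth. With DCM ≡ 1 this is
exactly the endpoint error; with DCM ≡ 0 it vanishes. The absolute value
is a deliberate choice: a signed mean could be driven to $-\infty$ and is
not a usable objective. Weights are not renormalized per batch.

The engine is a small reverse-mode automatic-differentiation tape written
for this package: convolutions run as im2col gathers followed by BLAS
matrix products, batch normalization uses per-sample (instance)
statistics, and batches are handled by gradient accumulation. Every
gradient path is checked against central finite differences in the test
suite. Optimization uses RMSprop (decay 0.99) at learning rate $10^{-3}$.
Full-scale defaults (168 px disparity range, 384×768 crops, batches of
24/4, 100 epochs) mirror a realistic training setup; the desk-scale
configuration used by the tests and the acceptance script shrinks the
images to 64×128, the disparity range to 48, and the network width to
keep a CPU training run in minutes. At these image sizes the feature
resolution uses two downsampling stages rather than three: an 8×16 cost
volume carries too little matching signal, while 1/4 resolution preserves
the architecture's structure at desk scale. The regression range is fitted
to the rig's working disparities for the same reason the matcher accepts a
minimum disparity — soft-argmin is an expectation over all candidate
levels, and levels that can never occur only pull the estimate toward the
middle of the range.

An important desk-scale caveat, measured rather than assumed: with
CPU-minutes of training on tens of scenes, the network reaches roughly
1.2 px endpoint error against ground truth, while the strictly checked
semi-global matcher achieves about 0.7 px at the pixels it accepts. The
network does what it is designed to do — it removes the matcher's gross
outlier tail (its worst-percentile cloud distances are smaller than the
matcher branch's) — but its bulk error stays higher, so on clean synthetic
scenes the matcher-only branch can still register better overall. The
mechanism that favors the learned branch on real endoscope data is the
severity of the classical matcher's failures there, combined with
full-scale training data and schedules.

## Odometry, fusion and evaluation

The odometry front end detects Shi–Tomasi corners (minimum eigenvalue of
the smoothed structure tensor) with 3×3 non-maximum suppression and
parabolic subpixel refinement, capped at 2000 strongest corners — a cap
suited to weakly textured scenes. Descriptors are 256-bit BRIEF-style
binary strings from a fixed seeded sampling pattern on a smoothed image;
matching uses Hamming distance with a ratio test (0.8) and a mutual-best
check. Matched corners are back-projected with each frame's depth and the
rigid transform is solved by orthogonal Procrustes (SVD) inside a RANSAC
loop (400 draws, 2 mm inlier band), followed by an iteratively tightened
trimmed refit. The final estimate is symmetrized — the forward transform is
averaged on the rotation manifold with the inverted backward transform —
to cancel direction-odd localization bias. Pose failures are returned as
status objects with match diagnostics, never as silent identities.

`fuse_sequence()` chains per-pair deltas (frame-to-frame only: no
keyframes, no pose graph, no loop closure — the deliberate simplification
of a full SLAM system), back-projects each frame and concatenates the
clouds in frame-0 coordinates, with optional voxel-grid downsampling.
Ground-truth pose injection is supported to isolate fusion from odometry
in tests.

Evaluation registers a reconstructed cloud to a reference cloud:
`coarse_register()` solves the rigid transform from at least three
non-collinear picked point pairs, `icp_register()` refines it by
alternating nearest-neighbour correspondence (exact brute force in C++)
with rigid updates — the correspondence RMSE is provably non-increasing —
and `registration_rmse()` reports

$$\mathrm{RMSE} = \sqrt{\tfrac{1}{n} \sum_i d_i^2}$$

over all $n$ reconstructed points. The per-point distance $d_i$ is the
Euclidean distance to the nearest reference point, the metric a
point-cloud comparison tool computes for registered free-form surfaces; a
depth-coordinate variant (`mode = "z"`) is available. The RMSE
implementation is verified against an all-pairs brute-force oracle.

In the end-to-end pipeline the converted depth is gated to the simulated
RGB-D camera's working range (half of `z_min` to twice `z_max`): a
physical depth camera has a finite measurement range, and near-zero
disparities would otherwise map to arbitrarily distant points that
dominate any RMSE.

## Desk-scale problem sizes

The bundled configurations choose sizes so the complete workflow runs on
one CPU core in minutes: 64×128 frames for matching, training and fusion;
training sets of tens of scenes; ~500 optimization steps; 8–10-frame
sequences; ICP on voxel-downsampled clouds. The odometry
parameter-recovery fixtures use 128×192 frames, where the pixel footprint
(≈0.3 mm at 80 mm depth) puts corner localization noise well below the
pose tolerances being asserted. These are documented defaults of the
package, chosen once; all stages accept full-scale settings.

## Known limitations

* The DCM scores hole-filled pixels like any other pixel; filled regions
  inherit the confidence of their reconstructed appearance rather than a
  dedicated uncertainty model.
* Odometry is frame-to-frame; drift grows with sequence length and there
  is no loop closure.
* Batch normalization uses per-sample statistics, so very small feature
  maps make training noisier than a large-batch GPU setup.
* The renderer is Lambertian with baked shading; view-dependent effects
  beyond the explicit specular blobs are absent.
* Rigid scenes only; non-rigid deformation is out of scope.
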