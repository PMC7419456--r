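---
title: "Monocular placental pose estimation and autonomous distal-tip alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monocular placental pose estimation and autonomous distal-tip alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Endoscopic laser ablation of placental anastomoses (the standard therapy
for twin-to-twin transfusion syndrome) works best when the laser fiber is
held close to perpendicular to the placental surface, at a 10–20 mm
stand-off. A fetoscope inserted through a ~3 mm entry port loses two
degrees of freedom to the fulcrum effect, so a rigid scope frequently
cannot reach perpendicularity — most severely for anterior placentas. A
flexible distal tip with two actuated joints (R1, the roll of the shaft
about its own axis, and R2, the distal bending) restores the missing
freedom, provided something can tell the controller how the surface is
oriented relative to the camera.

`fetopose` implements that estimator and everything around it: a
synthetic fetoscopic scene generator emitting images jointly with exact
orientation labels, a minimal two-component orientation representation, a
small convolutional regressor, and a closed-loop shared-control
simulation in which the regressor autonomously aligns the flexible tip
while scripted gross motion stands in for the operator.

The premise the estimator rests on: the in-utero scene is dark and lit
only by a source fixed to the camera, so the shading pattern (the
projected light cone) of a single monocular image carries information
about the relative orientation of the surface.

## The orientation representation

The placenta is locally planar at fetoscopic working distances. Let frame
{C} be the camera (x right, y down, z along the viewing direction) and
{P} the surface frame, with the convention that −P~z~ is the surface
normal pointing into the cavity. Because twist about P~z~ is redundant
(the laser is axi-symmetric), the orientation that matters has only two
degrees of freedom, and the package represents it by the x and y
components of P~z~ expressed in camera coordinates:

    label = ( ^C Z_P · e_x , ^C Z_P · e_y )

`(0, 0)` means perpendicular viewing. The label lives in the closed unit
disc, avoids Euler-angle and quaternion singularities, and doubles as the
control error: when the bending axis of R2 is aligned with C~x~, the two
components directly drive R2 and R1. `components_from_rotation()`,
`label_from_scene()` and `rotate_label()` implement the algebra;
`combined_error()` is the single-angle misalignment metric
`acos(^W Z_C · ^W Z_P)` used for control evaluation, and `is_accurate()`
the per-axis ±5° rule used for estimator evaluation.

Two conventions were genuinely open and are fixed here once:

* **Angle conversion.** The ±5° accuracy rule needs per-axis angles; the
  package uses the per-axis arcsine of each component
  (`components_to_angles()`), which inverts the projection exactly for
  single-axis tilts. A decomposition of the combined error would be the
  main alternative; the per-axis form is stricter near the rim of the
  disc and is what the controller actually sees.
* **Rotation sign.** Positive `rotate_label()` angles are
  counter-clockwise in (x, y) label coordinates — with the y-down image
  axis this is clockwise as displayed. What matters is consistency:
  rotating an image by θ and rotating its label by θ must correspond to
  the same physical camera roll, and the test suite pins image rotation,
  label rotation and scene-side camera roll to each other.

## The synthetic scene generator

`render_view()` ray-casts a finite textured plane under a spotlight
co-located with the camera origin. Pixel intensity is

    cone(α) · cos θ / r² · exposure,

modulated by the texture reflectance, where α is the pixel angle off the
optical axis (smooth cone attenuation, half-angle 50°, exponent 1.2), θ
the Lambertian incidence angle and r the range to the surface; a soft
tone map x/(1+x) and 8-bit quantization follow (quantizing at render time
makes the on-disk PNG and the in-memory image bit-identical). Defaults:
200 px, 90° field of view, square pixels, no distortion; distances
10–50 mm; label components spanning ±0.6 via an outward golden-angle
spiral in component space (`sample_poses()`, "conical" family), uniform
random distances, uniform random camera roll, and a ±24 mm jitter of the
targeted surface point. The jitter spans the same ±0.3 × extent field the
control episodes' landmarks cover: the estimator must have seen the
texture regions it later servos over, and an early narrower default
produced confidently wrong zero-crossings on unseen regions. The
exposure default (900) is set so the image saturates softly at 10 mm and
remains visible at 50 mm. Optional additive Gaussian sensor noise and
vignetting are off by default.

Textures are procedural (`generate_texture()`): a reddish mottled base
with a branching tree of darker vessel-like curves. They are synthetic
stand-ins for ex-vivo placenta photographs — they reproduce color
statistics and vessel-like structure, not real anatomy. Users can supply
their own photographs as textures.

Every emitted sample stores the exact label of its geometry, and
`generate_dataset()` asserts at generation time that the stored label
reproduces `label_from_scene()` of the stored pose to 1e-9.

**What passing tests on this data do and do not show.** The generator
emulates the dominant monocular cue (shading under co-located
illumination) with exact labels. It does not model amniotic-fluid
turbidity, floating particles, fetus or cord geometry, laser spots,
specular wetness, or sensor artifacts beyond optional Gaussian noise and
vignetting. Accuracy measured on this distribution bounds what the same
network would do on real fetoscopic video only loosely; domain shift is
the reason the mixed-data property (adding target-style samples to the
training set) is demonstrated on synthetic domain pairs rather than
claimed for the clinic.

## Dataset assembly

`preprocess_image()` fixes the network input contract: single-channel
luminance, 200×200, intensities in [0, 1] (the normalization is a
deliberate fixed contract so checkpoints are portable).
`apply_fov_mask()` reproduces the two fielded sensor geometries: square
chip-on-tip images pass through; circular rod-lens/fiber-bundle fields
zero everything outside the inscribed disc.

`augment_by_rotation()` enriches sparsely sampled orientation data: each
sample yields 360/increment copies, the image rotated about its center
(bilinear, out-of-frame pixels black, matching the dark endoscopic
background) and the label rotated by the matching angle. 40 base frames
at 5° increments give exactly 2880 samples, 10 give 720. Splits
(`split_dataset()`) assign whole source images to train/validation/test
so rotated copies can never leak across splits.

## The regressor

`network_spec()` fixes the architecture contract: 4 convolutional and 3
fully connected layers, a 2-unit linear output (no squashing — the
components are regressed directly), leaky-ReLU activations everywhere,
stride-2 max-pooling in convolutional layers 3 and 4, and 20% dropout on
layers 3–6. Channel widths, kernels and convolution strides are
configuration, not contract; the defaults (12/24/32/64 channels, kernels
5/3/3/3, conv strides 3/2/1/1, hidden FC 128/64) were chosen, before any
acceptance measurement, as the widest stack that trains at desk scale on
one CPU; width ablations at the same training recipe plateaued lower. The loss is mean-squared error on
the two components — the natural choice for this bounded Cartesian
encoding.

Training (`train_network()`) uses Adam with learning rate 1e-4 and batch
size 100, per-epoch validation, best-validation parameter retention and
early stopping (default patience 10). The implementation is single
precision (im2col + BLAS GEMM with exact gradients); all stochastic
elements — initialization, shuffling, dropout — derive from explicit
seeds. Training is deterministic for a fixed seed and BLAS build, but
acceptance-style checks should use tolerance bands, not bit equality.
Transfer initialization (`training_config(init_from = )`) starts a run
from a donor model's weights, the mechanism by which a
simulation-trained network seeds networks for other imaging sources.

Inference (`predict()`) disables dropout, is deterministic, and clamps
the output to the closed unit disc — the representation's domain — before
any control use. `evaluate_model()` scores a labeled set with the
both-angles ±5° rule and persists per-sample angular errors so the
reported accuracy is re-derivable.

At desk scale (4800 training images, 200×200), a training epoch takes
roughly 16 s on one CPU; the accuracy checks train for 52 epochs
(best-validation weights retained) on 4800/300/300 train/val/test
samples from 3 textures. Training is not saturated there: the same
recipe left to run to ~110 epochs reaches a noticeably lower validation
loss, so the desk-scale accuracy understates the converged model. These problem sizes are the
package's reduced-scale study conditions; the generating distribution
(distances, component range, augmentation increments) is never reduced.

## Kinematics and shared control

The instrument model (`instrument_state()`, `forward_kinematics()`)
parameterizes the shaft by its direction through the fulcrum and an
insertion depth — the fulcrum constraint holds by construction, and the
test suite verifies the shaft line passes within 1e-6 mm of the entry
port at every logged tick. The flexible segment uses a constant-curvature
model (length 10 mm by default): R1 rolls the bending plane about the
shaft axis, R2 bends the tip along a circular arc whose tangent carries
the camera; R2 = 0 degenerates exactly to a straight scope. The bending
range defaults to [0°, 90°].

`inverse_kinematics()` is closed-form: the measured label, lifted back to
the placenta axis in camera coordinates and expressed in the shaft-end
frame, yields absolute joint targets (R2 from an arccosine — for small
errors with an aligned bending axis this reduces to the arcsine of the
error component — and R1 from an atan2 aligning the bending plane with
the error direction). One application zeroes a truthful label exactly;
the loop needs iterations only because joints are rate-limited and
measurements are noisy.

Joint targets feed a standard discrete PID per joint (clamping
anti-windup; `kp = 1, ki = kd = 0` reduces to a proportional
passthrough). Commands are joint rates, saturated and integrated through
a first-order rate-limited joint model — the physical actuator (a
McKibben muscle in the fielded instrument) is not modeled. Default gains
(kp 8, ki 0.5, kd 0.05 at 40 Hz, ±360°/s) were tuned for near-critical
damping of the simulated plant; the loop runs at 40 Hz.

`run_episode()` scripts the gross motion a surgeon would provide: the
shaft aim slerps between landmarks spread over a placenta plane placed at
45° to the entry axis (`tilted_scene()`), holding the 10–20 mm stand-off
on the *camera-to-surface* distance (with a bent tip the camera looks
off-shaft, so a shaft-based stand-off would carry it out of the working
range), with optional seeded jitter standing in for hand tremor.
Measured labels pass through an exponential low-pass (new-sample weight
0.6) before the inverse kinematics, the filtering a real-time deployment
of a per-frame estimator needs. Autonomous episodes start from the
aligned configuration: the instrument is steered into position before
the task begins, and the log measures task performance, not deployment.
When the required bending direction flips (the shaft crossing the
surface-perpendicular ray makes the roll target swing by up to 180°),
the controller retracts the bend while the roll swings — bending through
zero re-orients with a bounded excursion. Three tip
configurations reproduce the fielded comparisons: `straight` (R2 locked
at 0), `fixed` (R2 locked at a constant curve, default 30°), and
`autonomous` (closed loop through the oracle label or a trained model).
With the plane at 45°, the straight scope's combined error exceeds 30°
over the far landmark field — a purely geometric consequence of the
fulcrum constraint — while the autonomous configuration holds the error
near zero between transients.

## Evaluation and reproduction

`error_heatmap()` bins combined error by the tip's projection on the
surface (default 25×25), `summarize_episodes()` reports per-episode RMS
plus pooled RMS/STD (both granularities, since summary tables of this
kind are otherwise ambiguous), and `reproduce_all()` chains
generate → split → train → evaluate → three control episodes → summary
under one seed. `scripts/acceptance.R` recomputes the two headline
quantities from scratch: the held-out synthetic-test accuracy of the
trained regressor, and the maximum straight-scope combined error on the
45° plane.

## Numerical choices and degenerate inputs

* Rotation-matrix validation: column orthonormality and determinant +1
  within 1e-6 for inputs, 1e-9 where the package constructs rotations.
* `combined_error()` re-normalizes near-unit inputs (within 1e-3) with a
  warning and rejects worse.
* `components_to_angles()` clamps out-of-range components (possible for
  raw network output) with a warning; `predict()` clamps to the unit
  disc radially.
* Inverse kinematics at R2 ≈ 0: R1 is undefined (any roll works); the
  previous R1 is kept to avoid chatter.
* R1 errors are wrapped to (−180°, 180°] before the PID.
* Pool windows that do not tile the activation exactly drop the trailing
  row/column (floor division), as is conventional.
* Labels are stored as dimensionless components everywhere; angles exist
  only inside metrics.

## Known limitations

* The renderer's plane is finite and textured; a curved-cavity geometry
  is approximated only insofar as labels always use the normal at the
  optical-axis intersection. Real uterine cavities curve.
* No physically based rendering of fluid turbidity or particles; no
  laser-spot or instrument-shadow rendering.
* The accuracy criterion is measured on the same synthetic distribution
  the network trains on (held-out split); it is a same-distribution
  figure by design.
* Phantom and in-vivo accuracies require the physical phantom and
  operating-room recordings and are out of scope; the domain-adaptation
  effect is shown as a property on synthetic domain pairs (square vs
  circular field of view) instead.
* Depth along the optical axis is neither regressed nor controlled; the
  autonomy covers orientation only.
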