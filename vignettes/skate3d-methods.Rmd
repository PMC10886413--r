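---
title: "Methods: markerless vs marker-based skiing kinematics in skate3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: markerless vs marker-based skiing kinematics in skate3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skate3d)
```

## The measurement problem

Two-camera video plus a pose-estimation network yields per-frame 2D pixel
keypoints for a skier on a treadmill. `skate3d` implements the processing
chain that turns those keypoints into 3D joint kinematics, the parallel
reference computation from an optical marker system, and the statistics
used to quantify how well the two agree. The chain is:

1. **DLT calibration.** Each camera is an 11-parameter direct linear
   transformation (DLT), the general projective pinhole mapping
   \[
   u = \frac{L_1X + L_2Y + L_3Z + L_4}{L_9X + L_{10}Y + L_{11}Z + 1},
   \qquad
   v = \frac{L_5X + L_6Y + L_7Z + L_8}{L_9X + L_{10}Y + L_{11}Z + 1},
   \]
   fitted by linear least squares from at least six digitized reference
   points (a 2 m calibration cube with one corner at the laboratory
   origin provides eight). Coordinates are centered and scaled before the
   solve and the coefficients back-transformed; this conditioning step is
   part of the estimator's definition here. No lens-distortion terms and
   no nonlinear refinement are used by default (`estimate_dlt(refine =
   TRUE)` polishes the same algebraic cost).
2. **Filtering and triangulation.** Pixel trajectories are low-pass
   filtered (4th-order Butterworth, 12 Hz cutoff, zero phase), then each
   point is triangulated per frame by unweighted linear least squares on
   the stacked DLT equations of all cameras whose keypoint confidence
   exceeds 0.6, and the 3D trajectories are filtered again at 6 Hz.
   Frames seen by fewer than two cameras are marked missing and excluded,
   never interpolated.
3. **Reference kinematics.** Marker trajectories are filtered at 6 Hz;
   wrist, elbow, knee and ankle centers are midpoints of lateral/medial
   marker pairs, the shoulder the midpoint of anterior/posterior markers,
   and the hip follows the Bell regression: offsets of 0.36, −0.19 and
   −0.30 times the inter-ASIS distance along the pelvis lateral, anterior
   and superior axes. The coefficients are configuration data
   (`bell_coefficients()`), not constants baked into the code, because
   published variants differ.
4. **Synchronization, events, toe correction.** The two systems share a
   clock only through the pole: both detect right-pole treadmill contacts
   (downward crossing of the pole-tip height below the 5th percentile +
   10 mm, 0.3 s refractory) and are aligned on the first strike by an
   integer frame shift. Cycle boundaries for *both* systems then come
   from the marker-based pole strikes, which is also what keeps the
   zero-noise oracle chain exact: independently detected boundaries could
   legitimately differ by a frame, and a one-frame offset in cycle
   definition swamps every other error source. The toe keypoint (boot
   tip) and toe marker (boot top) sit at systematically different places;
   a quiet-standing static trial estimates that fixed offset, which is
   added to the markerless toe before distances *and* angles are
   computed.
5. **Cycles and angles.** Cycles start at right-pole strikes — every
   strike for G1 (one pole impact per cycle), every second strike for G3
   (two impacts per cycle). The first ten complete cycles are linearly
   resampled to 101 samples (0–100% inclusive). Five joint vector angles
   are computed with the two-argument arctangent of cross and dot
   products (stable near 0°/180°, unlike arccos): elbow, hip and knee as
   supplements of the apex angle, shoulder as the raw vector angle, ankle
   as the complement.
6. **Agreement statistics.** Joint centers and toe are compared by 3D
   Euclidean distance per cycle and normalized sample, pooled, and
   summarized as mean (a magnitude, not a signed bias), SD, and two
   interval conventions. Angles use signed differences plus RMSE, Pearson
   r (t-transform p-value; bands negligible/low/moderate/high/very high at
   0.30/0.50/0.70/0.90) and ICC(A,1), the absolute-agreement single-score
   intraclass correlation from the two-way ANOVA mean squares, with an
   F-based Satterthwaite confidence interval (bands
   poor/moderate/good/excellent at 0.50/0.75/0.90).

## The two "limits of agreement"

The classical Bland–Altman 95% limits are `bias ± 1.96·SD` and do not
shrink with the number of pooled samples. A t-based 95% confidence
interval of the bias, `bias ± t(0.975, n−1)·SD/√n`, collapses onto the
bias for the tens of thousands of pooled cycle-samples a full comparison
produces (e.g. SD 30 mm at n = 40 000 gives a half-width of about
0.3 mm). Published agreement tables in this area sometimes carry the
second convention under the "LoA" heading — recognizable exactly by that
near-degenerate pattern. `bland_altman()` therefore returns both,
labeled `loa_classic` and `loa_tci`, and the paper-shaped tables carry
the t-based one.

## The synthetic skier

Real sessions of this kind are not publicly available, so the package
ships a deterministic simulator that provides ground truth for every
stage rather than a biomechanically validated gait model.

**Skeleton.** Trunk and arm coordinates are single sinusoids (arms at the
poling frequency: once per cycle for G1, twice for G3); the legs are a
sagittal segment-angle chain (thigh tilt 20° ± 25°, knee flexion
50° ± 38°, foot pitch) driven by single sinusoids. This keeps the
spectrum essentially band-limited below ~3 Hz (angle-to-position
composition adds Bessel-decaying harmonics) while giving plausible
ranges: knee vector angle ≈ 12–88°, elbow 27–128°, shoulder 14–63°, hip
14–48°, ankle −7–17°. All five angles stay clear of the 0°/180°
degeneracies, where measurement noise can only increase an angle and
therefore rectifies into spurious bias. Cycle durations default to 1.5 s
(G1) and 1.2 s (G3), i.e. roughly 30 s trials at the protocol's cycle
counts (20 and 15).

**Cameras.** Ideal pinhole cameras at the laboratory poses — a side
camera perpendicular to the skiing direction at 1.05 m height and 2.0 m
distance, and an oblique 45° camera at 2.5 m height and 1.9 m distance,
both 1280 × 720 at 100 Hz — expressed directly as DLT coefficient
vectors, so the fitted model class contains the generating cameras
exactly. Focal lengths (700 and 550 px) were chosen so both the skier
and the full calibration cube project inside the sensor.

**Error model and defaults.** Four error terms, each with a fixed seed:

* white pixel noise, SD 2 px — per-frame detection jitter at the scale of
  the reported 2D-model test errors (2.27/2.63 px);
* a smooth cycle-locked pixel error, amplitude 1.5 px (random phase per
  point, camera and axis) — pose-estimation error is temporally
  correlated, and a purely white model would be almost entirely removed
  by the 12/6 Hz filters, making the markerless arm unrealistically
  accurate;
* marker white noise, SD 1 mm, plus a cycle-locked soft-tissue
  displacement of amplitude 20 mm (fixed random direction and phase per
  skin/boot marker), the displacement scale reported for skin markers;
* a fixed toe-marker mounting offset, default (0, 30, 40) mm, recovered
  by the static-trial correction.

With these defaults the simulated comparison lands where a real session
of this design lands: mean joint-center distances around 15–21 mm
(published two-camera markerless systems report ~15–50 mm), angle RMSEs
of about 2–7.5° with the elbow largest, and Pearson/ICC in the very
high/excellent bands with the smallest-range angles lowest — the same
ordering the real validation shows.

**What passing tests do not show.** The simulator has no occlusion by
default, no left side, no out-of-plane pelvis rotation, no non-stationary
noise, and its soft-tissue term is a pure sinusoid. Agreement numbers
from the simulator therefore validate the *computational chain*, not the
field accuracy of any particular pose-estimation model.

## Numerical choices

* **Zero-phase filtering** is the forward–backward (dual-pass)
  application; the single-pass magnitude response is −3 dB at the cutoff,
  so the dual pass is ≈ −6 dB there. Ends are handled by odd-reflection
  padding whose length scales with the filter time constant
  (`8·rate/cutoff` samples), with steady-state initial conditions; edge
  transients decay inside the pad. A series must be longer than 15
  samples.
* **In-band attenuation is not zero.** A 4th-order dual pass attenuates a
  component at frequency *f* by `(f/fc)^8/(1+(f/fc)^8)`. At the G3 poling
  frequency (1.67 Hz) through the 6 Hz stage this is ~3.5 × 10⁻⁵ —
  about 7 µm on a 0.2 m arm swing. Both arms of the comparison share the
  6 Hz stage, so this cancels between systems, but the 12 Hz pixel stage
  exists only in the markerless arm; its effect on the perspective
  harmonics of G3 arm motion leaves ~10⁻⁴ ° angle biases even at zero
  noise. The zero-noise exactness demonstrations therefore use G1
  sessions (fundamental 0.67 Hz), where the chain is exact to ~10⁻⁸ m
  and ~10⁻⁶ °; the corresponding G3 floor is asserted at its analytic
  level in the tests.
* **Triangulation conditioning:** a warning is attached when the 3 × 3
  normal matrix condition number exceeds 10³ (rays a few degrees apart;
  the default rig sits near 10).
* **Ties and degeneracies:** coincident defining points give an
  undefined-angle mark (`NA`), not an error; frames with fewer than two
  confident cameras are missing marks; a trial is rejected only when a
  required point is unusable on more than 20% of frames.
* **Determinism:** all writers use fixed-precision formatting, so
  identical inputs give byte-identical files; marker TRC fixtures are
  written in mm (meter-precision files would quantize at 0.5 µm, which
  the static toe correction would convert into a visible constant bias).

## Problem sizes

The shipped tests and the acceptance script run desk-scale versions of
the study design: sessions of 12 cycles (so ten complete cycles remain
after segmentation) instead of full 30 s trials, ten seed-replicates per
technique for the stochastic magnitude checks, and 100-instance
randomized oracles for the statistics layer. These sizes were chosen so
the whole suite exercises every stage end to end while each individual
check stays attributable when it fails.

## Known limitations

* Single-participant, right-side geometry; no gap filling (vendor
  gap-filled input is assumed, gaps are excluded otherwise).
* Integer-frame synchronization only; at 100 Hz a residual half-frame
  offset contributes up to ~10 mm of apparent error at hand speed, which
  is part of what the method-agreement numbers measure, exactly as in a
  real session.
* The ICC confidence interval uses the standard F/Satterthwaite
  approximation, which is anti-conservative for heavily pooled,
  serially correlated cycle samples; the point estimate is unaffected.
* C3D input is not implemented; TRC (and the documented CSV/JSON
  schemas) are the interchange formats.
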