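---
title: "Methods: integer tilt transformation, posture events and gait analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integer tilt transformation, posture events and gait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturekit)
```

`posturekit` models the signal path of a wearable posture-monitoring vest:
five 3-axis accelerometers (lower cervical spine, chest, lumbar centre of
mass, both waist sides) sampled at 100 Hz with ±2 g range and 12-bit
resolution, reduced on integer hardware to tilt angles, posture states,
alerts and gait parameters. This vignette documents the models, the
parameters that matter, and the choices made where the design was open.

## Sensor model and frames

The body frame puts Z up along the spine, X anterior, Y to the wearer's
left; at rest an accelerometer measures the gravity reaction, so an upright
sensor reads (0, 0, 1) g. A trunk pitched forward by $p$ and rolled by $r$
measures

$$a = (\sin p,\; \cos p \sin r,\; \cos p \cos r)\,g,$$

which has unit magnitude for any orientation — the basis of the steady-state
stability checks (mean $\sqrt{A_x^2+A_y^2+A_z^2}$ within 3% of 1 g, sd below
3% of 1 g). The front end adds a per-axis bias, i.i.d. Gaussian noise
(default sd 0.005 g; the hardware description gives no noise figure, and
5 mg is a typical MEMS accelerometer noise floor at this bandwidth),
divides by the LSB size and rounds half away from zero — an odd-symmetric
quantizer — then saturates at the two's-complement bounds. The defaults tie
together as $\mathrm{lsb} \cdot 2^{\mathrm{bits}-1} = \mathrm{range}$:
$2^{-10}\,g \times 2^{11} = 2\,g$, i.e. 1 count = 1 mg and 1 g = 1024
counts. Mounting orientations per placement are exposed as rotation-matrix
parameters (identity by default) rather than asserted, since the garment's
true mounting is not part of the public hardware description.

## Integer CORDIC tilt transformation

Tilt is computed entirely in integer arithmetic, as the target
microcontroller does. Vectoring-mode CORDIC rotates a vector onto the
positive x axis through micro-rotations $\arctan 2^{-i}$, deciding each
rotation's direction by the sign of the residual $y$ (ties broken as
$\mathrm{sign}(0)=+1$, making the iteration total and deterministic), and
accumulates the angle from a lookup table. The magnitude emerges inflated by
the CORDIC gain $K=\prod_i\sqrt{1+2^{-2i}} \approx 1.6468$, removed by a
fixed-point multiply with $\mathrm{round}(2^{15}/K)$ — accurate to one count.

Numerical choices:

* **Angle unit.** LUT entries are integers in micro-degrees (scale $10^6$
  per degree), directly readable against degree-denominated specifications;
  the tilt pipeline runs its accumulator at $2\times10^6$ per degree — one
  guard bit — and converts to degrees only at the boundary. With 180° × 2e6
  ≈ 3.6×10⁸ everything stays well inside 32 bits.
* **Pre-scaling.** Inputs are shifted left by 16 bits before iterating.
  Without this, the truncating arithmetic shifts dominate the error for
  small vectors (the pair (1, 1) would err by almost 2°); with it, 10,000
  random 12-bit vectors stay within 0.0018° of the floating-point `atan2`.
  An interval-analysis bound (asserted in the tests) shows the worst-case
  state is about 3× the up-shifted input, ≈ 1.61×10⁹ < 2³¹, so the core is
  arithmetically closed over 32-bit integers up to 20 iterations and 13-bit
  inputs.
* **Iteration count.** 16 iterations by default: the residual rotation
  $2^{-15}$ rad ≈ 0.0018° is far below the 0.5° system specification while
  leaving 32-bit headroom.
* **Quadrants.** Vectoring converges only for $|\theta| \lesssim 99.9°$, so
  inputs are pre-rotated into the right half plane by sign swaps (±90° or
  180°), the offset folded back afterwards; roll covers (−180°, 180°],
  inclination [0°, 180°]. An exact on-axis vector can undershoot its
  boundary angle by the residual rotation, so inclination is clamped to its
  admissible range at the output.

The decomposition is two-stage: vectoring (Az, Ay) gives roll and the
gain-compensated in-plane magnitude $\sqrt{A_y^2+A_z^2}$; vectoring that
magnitude against Ax gives pitch in [−90°, 90°]; the analogous pairing of
$\sqrt{A_x^2+A_y^2}$ with Az gives the inclination (the "tilting angle").
End-to-end over a 5° pitch×roll grid quantized at 12 bits, the maximum
inclination error is ≈ 0.054°: quantization (≈ 0.056° per count near 1 g)
dominates, CORDIC contributes ≈ 0.002°, comfortably inside the 0.5° system
specification. The precision-enhancement of the hardware algorithm is
realized here as round-to-nearest LUT entries plus the accumulator guard
bit.

## Posture classification and alerts

All thresholds live in `alert_rules()`; the monitoring concept specifies
"bent by a certain degree for a default amount of time" without numbers, so
the defaults are this package's documented, configurable choices:

| parameter | default | rationale |
|---|---|---|
| lying threshold | 60° chest inclination | splits recumbent from upright with margin over deep bends |
| head-down | 30° for 60 s | sustained neck flexion (e.g. phone use) |
| trunk-bend | 30° for 10 s | sustained forward bend |
| lying-to-sitting crossing | 45° | halfway between lying and sitting bands |
| free fall / impact | < 0.5 g for ≥ 0.2 s; ≥ 1.8 g | canonical fall-signature stages |
| post-fall lying hold | 5 s | distinguishes a fall from a stumble |
| release hysteresis | 5° | keeps threshold jitter from splitting excursions |

Classification uses 1 s windows with 0.5 s step (median tilt per window);
alerts are evaluated per sample. Design choices worth noting:

* **Head-down measures neck flexion relative to the trunk** (cervical tilt
  minus chest inclination), so a deliberate trunk bend — where the head
  correctly follows the trunk — does not double-report as head-down.
* **Duration warnings are gated on "not lying"**: a recumbent trunk has a
  large pitch too and must not raise posture warnings.
* **Falls require all three stages in order** (free-fall dip on chest and
  centre-of-mass magnitude, impact at ≥ 1.8 g or saturation, then ≥ 90% of
  the following 5 s above the lying threshold). Walking, deliberate lying
  and impacts without a preceding dip produce no alert.
* **Lying-to-sitting onset** is backtracked from the lying-band exit to the
  last sample near the lying plateau (plateau median − 3°), which locates
  the start of the actual motion rather than the 60° crossing.
* **Sitting vs standing** cannot be separated by trunk orientation alone;
  the split uses the centre-of-mass channel orientation (> 20° reads as
  pelvic tilt while seated) and is flagged as a heuristic.

A posture held exactly at an alert threshold is genuinely ambiguous under
sensor noise; the event-detection validation therefore uses negatives well
inside the no-alert bands (upright, 20° bend, lying) and positives well
beyond the thresholds.

## Gait analysis

Steps are detected per waist channel: the acceleration magnitude is
band-passed 0.5–3 Hz with a zero-phase 2nd-order Butterworth filter
(`signal::filtfilt`), and local maxima above an adaptive threshold — median
+ 3·MAD per 5 s block, floored at 0.05 g so a motionless wearer never
accumulates steps — are kept with a 250 ms per-side refractory period.
Walking bouts are spans of ≥ 4 steps with inter-step gaps under 2 s.

The step symmetry index uses *step times* (interval from the immediately
preceding contralateral step): with strictly alternating gait the
ipsilateral-to-ipsilateral interval equals the stride time on both sides and
would make any interval-based index identically zero, while step times
expose the left/right split (0.55 s vs 0.45 s → 20%). The index
$SI = |\bar L - \bar R| / \tfrac12(\bar L + \bar R) \times 100$ is zero for
perfect symmetry, scale-invariant and side-symmetric. The walking simulator
injects asymmetry $a$ as step times $T(1 \pm a/2)$ around the mean step time
$T = 60/\mathrm{cadence}$, so the injected index is exactly $100a$ percent —
what the recovery tests compare against. `sd_symmetry` within a recording is
the sample sd (n−1) of the signed per-step deviation; monthly aggregation
(`aggregate_trend()`) likewise uses the n−1 sd across summaries and keeps
empty months explicit, mirroring the long-term festination-tracking plot
(mean symmetry line, sd bars, mean forward-lean line).

Forward lean is the mean chest pitch over detected walking bouts only — lean
while standing still is a different quantity and is deliberately excluded.

## What the simulator does and does not emulate

The generator reproduces: rotated gravity with white noise and quantization;
alternating raised-cosine step impulses (0.4 g, 300 ms) on the ipsilateral
waist with ~10 ms timing jitter; gait oscillation (±2°) superimposed on the
chest lean; a vertical bounce on the centre-of-mass channel; and the
kinematic signatures of falls (0.3 s at 0.05 g, a 3.5 g saturating impact,
then lying), lying-to-sitting ramps, trunk bends and head-down holds, each
with its exact window in the labels. It does *not* model soft-tissue
artifact, sensor drift, garment slip, double support, non-sagittal motion or
pathological gaits beyond timing asymmetry — so passing tests demonstrate
the correctness of the computation under the stated kinematics, not clinical
performance on real patients.

Validation problem sizes, chosen to characterize the estimators densely
while remaining quick to re-run: a 37×37 orientation sweep for the tilt
error; 20 static recordings of 10 s for the steady-state figures; 10,000
random vectors for CORDIC–oracle equivalence; a {0, 0.05, 0.1, 0.2} × 10
seed grid of 60 s walks for parameter recovery; 20 seeds × 4 event kinds
plus 40 negative recordings for event sensitivity/specificity.

## Known limitations

* Roll is ill-conditioned near ±90° pitch (gimbal alignment): with
  $A_y, A_z$ both near zero its quantization error grows; inclination is
  unaffected.
* The frame protocol is exercised in its tabular form (round-robin order,
  contiguous sequence numbers, gap reporting); no binary transport is
  implemented.
* Whether the original system reported one inclination per sensor or full
  pitch/roll is unknowable from the outside; both are exposed.
* The symmetry index is one of several definitions in use (interval-, count-
  and amplitude-based); the interval-based form is implemented and the
  summary layer would accept a replacement without interface change.
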