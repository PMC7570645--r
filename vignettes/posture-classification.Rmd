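---
title: "Gaussian confidence-region posture classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian confidence-region posture classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturewatch)
```

## The classification model

posturewatch implements a one-class, per-pose classifier for a wearable
spine monitor. The sensing unit sits on the thoracic spine and carries a
3-axis accelerometer and a 3-axis magnetometer; two permanent magnets ride
on the shoulder blades above it. Two posture signals result: the orientation
of the torso relative to gravity (accelerometer) and the position of the
shoulder blades relative to the sensor, encoded in the magnets' field
(magnetometer).

Only *correct* posture can be demonstrated by a wearer during calibration,
so there is no labelled bad-posture class to discriminate against. The
method therefore fits, for each sensor and each of eight reference poses
(standing and sitting, each with arms down, right arm up, left arm up and
both arms up), a trivariate Gaussian to the readings recorded while the pose
is held: the arithmetic mean $\mu_i$ and the unbiased sample covariance
$\Sigma_i$ (divisor $N-1$). The arm poses are included so that ordinary
arm and hand movement does not trip the classifier.

For a confidence level $c$ the squared Mahalanobis distance of an in-model
point is $\chi^2_3$-distributed, so the $c$-level equiprobability ellipsoid
has principal semi-axes $\delta_j = \sqrt{\chi^2_3(c)\,\lambda_j}\; v_j$
with $(\lambda_j, v_j)$ the eigenpairs of $\Sigma_i$, and every semi-axis
endpoint carries the same density

$$\tau_i \;=\; (2\pi)^{-3/2}\,\lvert\Sigma_i\rvert^{-1/2}\,
  e^{-\chi^2_3(c)/2}.$$

A reading $x$ is *correct for a sensor* when $N_i(x) \ge \tau_i$ for at
least one pose region $i$ — equivalently, when its minimum squared
Mahalanobis distance over regions is at most $\chi^2_3(c)$. The region is
closed: a boundary tie classifies as correct. `compute_threshold()` uses the
closed form above; the semi-axis-endpoint construction is retained in the
test suite as an oracle, where axis-independence of $\tau$ is asserted to
$10^{-10}$ relative.

Two readings of the two sensors are fused by a truth table: the posture is
**incorrect only when both sensors vote incorrect**. The rationale is the
complementarity of the failure modes. The accelerometer sees only the
gravity direction, so a *tilted but straight* back (leaning forward over a
desk, say) leaves its calibrated regions even though the posture is fine.
The magnet field at the sensor (about 2.2 mT with the shoulders retracted)
is fixed in the body frame, so it is untouched by tilt — but it shifts by
about 1 mT when the shoulders slump, which is what actually distinguishes a
degraded posture. Fusion keeps the accelerometer's sensitivity to real
bends (which move *both* sensors out of region, since slumping accompanies
them) while forgiving pure tilts.

A monitoring session is scored as the percentage of fused-correct records
inside the scoring window (up to 24 h), every record weighted equally.
Separately, the back angle $\alpha = \arccos(a\cdot g/|a||g|)$ between the
measured acceleration and a fixed gravity reference provides an
angle-based ground truth: under the adopted orientation convention an
upright back reads near $180^\circ$, and angles strictly below $160^\circ$
are labelled crooked. The normalized dot product is clamped to $[-1,1]$
before `acos`, so roundoff on nearly collinear vectors never yields `NaN`.

### Interpreting the ellipsoid semi-axis

The semi-axis definition is implemented as
$|\delta_j| = \sqrt{\chi^2_3(c)\,\lambda_j}$. Writing the scale factor
without the square root (i.e. $\chi^2_3(c)\,\lambda_j$ directly) is
dimensionally inconsistent — it would make the threshold depend on which
eigen-axis is chosen and the region would not cover probability $c$. The
square-root reading is the standard confidence-ellipsoid geometry and is the
only one under which the three axis endpoints are isodense; the test suite
checks exactly this property.

### Union versus intersection of regions

Membership could be demanded in *all* pose regions rather than *any*. The
eight pose clusters are disjoint in sensor space (different arm positions
tilt the torso and shift the garment by design), so an intersection test
would reject nearly every point including the calibration data itself. The
union reading is therefore the default; `mode = "all"` is available on the
classifying functions for comparison.

### Stream pairing

Nothing in the sensing model synchronises the two streams, so
`classify_stream()` pairs samples by nearest timestamp within a tolerance
defaulting to half the median accelerometer sampling period. A sample with
no partner degrades to single-sensor fusion (its record is flagged) rather
than being dropped, so the score denominator is preserved. No smoothing or
debouncing is applied to the per-sample labels by default.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `conf` (c) | 0.95 | — | confidence level of every region; the only classification tuning knob |
| `mode` | `"any"` | — | union vs intersection of pose regions |
| `pairing_tol` | half median period | s | stream-pairing tolerance |
| angle `threshold` | 160 | degrees | crooked-posture rule for ground-truth labels |
| `ridge_epsilon` | 1e-6 | — | relative diagonal ridge for degenerate covariances |

A covariance that is singular or conditioned worse than $10^{12}$ (constant
or near-constant recordings) receives a diagonal ridge of
$\varepsilon\,\mathrm{tr}(\Sigma)/3$ and the region is flagged `ridged`
instead of failing; only fewer than four samples is a hard error. Units are
carried as model metadata (m/s² and µT by default) — fit and test must share
them, and the classifier is then unit-consistent because both sides scale
together (the acceptance region is exactly equivariant under invertible
linear maps, a property the tests assert).

## The simulator

`physics_config()`, `sensor_readings()`, `simulate_calibration()` and
`simulate_scenario()` generate the data a hardware device would record, so
the full pipeline runs without one.

**Accelerometer.** A quasi-static pose measures the gravity reaction rotated
into the sensor frame: upright reads $(0, 0, +9.81)$ m/s², a forward tilt
of $\theta$ about the lateral axis moves the back angle to $180^\circ -
\theta$. Arm poses and sitting add small deterministic pitch/roll offsets
(1.5–3°), which is what separates the eight calibration clusters.

**Magnetometer.** The reading is the Earth field (≈47 µT, 60° dip) rotated
into the sensor frame, plus the point-dipole fields of the two magnets at
their body-frame positions. The dipole moment is solved analytically so the
magnet contribution at the ideal posture is exactly 2.2 mT; the slump
geometry (magnets moving away as `shoulder_state` goes 0 → 1) gives a
correct↔slumped swing of ≈1.0 mT. Both figures are configuration targets,
not measurements: the true magnet-to-sensor geometry of such a device is a
stand-in chosen to reproduce those two field scales. Readings are checked
against the ±5 mT dynamic range and a saturation warning is raised beyond
it.

**Variability.** Three stochastic components act on every sample, in
calibration and test alike:

* per-axis sensor noise — 0.05 m/s² (accelerometer), 3 µT (the
  magnetometer's sensitivity floor);
* postural sway — Gaussian pitch/roll jitter of sd 0.8° while a pose is
  held;
* magnet-position jitter — Gaussian, sd 1.5 mm per axis. Clothing-mounted
  magnets sit in a millitesla field with gradients of order 0.1 mT/mm, so
  millimetre-scale garment motion produces tens-to-hundreds of µT of
  magnetometer variance, far above the sensor floor.

The last two matter structurally, not just cosmetically. With only the 3 µT
noise floor, the fitted magnetometer covariance would be so tight that the
~25 µT rotation of the *Earth-field* component under a 30° straight-back
tilt would eject the reading from its region, and fusion could never rescue
the tilting protocol. With physically plausible pose-holding variability the
magnetometer covariance (≈90–120 µT per principal axis) absorbs the Earth
term while the 1 mT slump shift remains a ≈7–10 σ excursion — which is
precisely the separation of scales the magnet design exploits.

**Scenarios.** `tilting_scenario()` holds an upright pose and interleaves
straight-back tilts of 10°, 20° and 30° (50 s at 10 Hz; ground truth all
correct — the posture never degrades). `crooked_scenario()` alternates
upright and crooked (30° bend, shoulders 85% slumped) segments five times
(80 s at 10 Hz); crooked segments have a true angle of 150°, below the
160° rule. `simulate_calibration()` records 200 samples per pose (20 s at
10 Hz) by default. All outputs are pure functions of (scenario, config,
seed).

**What the simulator does not model** — and hence what passing tests do and
do not show about real data: no musculoskeletal dynamics, gait, breathing
or soft-tissue artefacts; quasi-static poses with white Gaussian
variability only; no gyroscope synthesis (stance detection is out of scope
and the classifier ignores gyroscope data); no sensor bias, drift,
temperature effects or hard/soft-iron distortion; instantaneous transitions
between segments. Results on simulated scenarios demonstrate the
*statistical mechanics* of the method — coverage, thresholding, fusion
logic, separation of the two failure modes — not field performance on human
subjects, which in the motivating hardware study was measured on a single
wearer.

## Numerical choices

* Densities and Mahalanobis distances go through a Cholesky factorization;
  a non-SPD covariance raises a classed degeneracy error rather than
  propagating `NaN`. The independent test oracles use explicit
  inverse/determinant arithmetic and `stats::mahalanobis`.
* $\chi^2_3$ quantiles come from `stats::qchisq`; no table lookup.
* Boundary ties ($N_i(x) = \tau_i$ exactly) classify as correct; the
  classification-oracle tests exclude a $10^{-10}$ band around the
  threshold where the two routes may legitimately disagree in the last ulp.
* Serialized numbers (trace CSV, model JSON) are written with 17
  significant digits, making every round trip bit-lossless; the test suite
  asserts `identical()` on round-tripped models and traces.
* Test problem sizes: coverage is checked at $10^5$ draws (5σ binomial
  band), parameter recovery at $10^5$ draws, the classification oracle at
  $10^4$ points × 20 random models, and the scenario-level properties over
  a fixed set of 10 seeds — sizes at which the whole suite runs in well
  under a minute on one core.

## Limitations

The classifier is per-sample and memoryless: it neither smooths labels nor
adapts the calibration during a session (re-calibration is a new model).
The score assumes uniform sampling; no time-weighted integration is done.
The 160° rule, the pose set and all physics defaults are conventions fixed
in configuration — reasonable for the simulated device geometry, but any
real deployment would re-measure them. Gyroscope-based stance detection is
explicitly out of scope.
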