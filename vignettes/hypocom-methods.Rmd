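---
title: "Methods: seated center of mass under simulated hypogravity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seated center of mass under simulated hypogravity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypocom)
```

## The problem

When people work in hypogravity — gravity between 0 and 1 g, such as the
1/6 g of the lunar surface — their postural control changes. One way to
quantify this for a seated worker is the whole-body center of mass (CoM)
relative to the pelvis: a downward CoM shift along the proximodistal (Y)
axis or a posterior shift along the anterior–posterior (Z) axis indicates a
change in trunk posture. Hypogravity can be simulated underwater by adding
lead ballast to body segments until each segment's apparent weight
(weight minus buoyancy) matches its lunar weight; the seated subject then
performs static (outstretched-arm hold) or dynamic (load manipulation)
tasks until muscular fatigue ends the trial, while a ring of calibrated
cameras records the body markerlessly. `hypocom` implements every
computational stage of that chain: ballast design, multi-view keypoint
geometry, segmental CoM estimation, endurance-time windowing, the
statistical model, and a synthetic-data generator that exercises all of it.

## The segmental CoM model

Each modeled body segment connects two keypoints of the 25-keypoint
skeleton. Segment mass is a sex-specific fraction of total body mass
(Plagenhoef water-immersion statistics), and the segment's own CoM sits at
fraction $k$ of the segment length from the proximal joint. The whole-body
estimate is the mass-weighted sum

$$\mathrm{CoM} = \frac{1}{M}\sum_{(i,j)} m_{ij}\,
  \bigl[P_i + k_{ij}\,(P_j - P_i)\bigr],$$

with $P_i$ the proximal joint, $m_{ij}$ the segment mass and
$M = \sum m_{ij}$. The default $k$ values are 43 %, 43.6 % and 63 % of
segment length for the male forearm, upper arm and trunk, and 43.4 %,
45.8 % and 56.9 % for females; the trunk spans the hip joint to the
shoulder line (its full length is 100 % of that span).

The modeled segment set defaults to the upper body above the hip joint:
trunk, head + neck, and both upper arms and forearms. Hands are excluded
because the 25-keypoint layout carries no keypoint distal to the wrist, so
a hand segment has no definable joint pair; lower limbs are excluded
because the seated analysis is referenced to the hip. Both choices are
configuration, not code: `default_segment_table()` reads a plain CSV that
can be replaced wholesale. The printed form of the weighted-sum equation in
the source literature divides by $k$, which is dimensionally inconsistent
with $k$ being a proximal fraction; the affine form above is the standard
segmental method and is consistent with the printed $k$ values.

```{r}
default_segment_table("female")
```

## Ballast design

A submerged segment of mass $m$ and volume $V$ receives ballast mass $m_b$
(density $\rho_b$, lead by default) so that its apparent weight equals its
target-gravity weight:

$$(m + m_b)\,g - \rho_w\,(V + m_b/\rho_b)\,g = m\,g_t
  \;\Rightarrow\;
  m_b = \frac{m\,(g_t - g) + \rho_w V g}{g\,(1 - \rho_w/\rho_b)}.$$

`validate_balance()` re-evaluates the net force independently of the
solver; residuals are at machine precision (~1e-13 N, far below the 1e-9 N
acceptance bound). The default accounting treats ballast as pure
compensation hardware (the right-hand side is the segment's lunar weight);
`include_ballast_in_target = TRUE` switches to the variant in which the
ballast itself is part of the simulated mass — the source material does not
state which was used, so both are available. A segment already heavier than
its lunar apparent weight has no non-negative ballast solution; the error
reports the flotation that would be required instead. Ballasts above 3 kg
are flagged by `inertia_flag()` (point-mass $I = m_b r^2$), the mass above
which ballast inertia noticeably affects movement. The drag-limited maximum
hand speed $v = \sqrt{2 f W / (\rho_w C_d A)}$ caps dynamic-task speed; the
reported 47 cm/s figure cannot be re-derived without the original drag
area and coefficient, so all drag parameters are explicit arguments with
documented defaults ($C_d = 1$, cylindrical forearm area).

## Camera geometry

Cameras are standard pinhole models (intrinsics, world-to-camera rotation
and translation, optional radial distortion), serialized to a YAML
calibration file. World coordinates are right-handed, in cm: Y up
(proximodistal), Z anterior, X mediolateral. Triangulation is
confidence-weighted linear DLT — each observation contributes two
homogeneous equations scaled by its confidence, and the point is the null
vector of the stacked system — with the reprojection RMS reported per
keypoint. Keypoints observed by fewer than `min_views` cameras (default 2)
are marked invalid rather than raising an error, and frames missing any
keypoint required by the body model become missing CoM samples rather than
being interpolated: markerless dropout underwater is expected, and an
imputation policy would be a modeling decision this package deliberately
does not make. Calibration is taken as already valid in-medium; flat-port
water refraction is not modeled.

PCK (percentage of correct keypoints) evaluates 2D pose quality: the
fraction of predicted keypoints within `alpha` times a reference distance
(annotated torso diagonal by default, `alpha = 0.2`) of the annotation.
The threshold behind published PCK figures for this kind of footage is
generally unstated, so the metric is fully parameterized and no particular
printed value is treated as reproducible.

## Windows and the statistical model

A trial lasts its endurance time (ET). Three windows — the first
`window_s` seconds (default 5 s, capped at 60 s), the same span centred at
ET/2, and the final span before ET — each contribute one window-mean of the
pelvis-relative displacements $dY$ (downward positive) and $dZ$ (posterior
positive; both conventions flippable). The signs are chosen so that the
reported positive gravity effects read as positive regression
coefficients. Window rows pool into per-sex OLS:

$$d = \beta_0 + \beta_g\,\mathbb{1}(\text{1 g}) +
      \beta_t\,\mathbb{1}(\text{dynamic}) + \varepsilon,$$

fit by the closed-form normal equations with classical standard errors;
the three windows of a trial enter as independent observations, matching
the degrees of freedom of the published analysis, and a cluster-robust
covariance (clustered on participant) is available for sensitivity checks
but off by default. Constant indicator columns are dropped with a record;
collinear designs are an error. The Shapiro–Wilk screen wraps the AS R94
implementation in base R and is reported, never used to branch the
analysis automatically. `table3_report()` renders the conventional
coefficient-(SE) grid; its default star legend reproduces the reported
convention (`*** p < 0.1`, `** p < 0.05`), whose nested thresholds mean the
triple star always wins — exact p-values should therefore be read from
`summary()`, which is why they are always carried numerically.

## What the synthetic generator emulates

`generate_study()` produces a complete study with no external data:

* a cohort drawn from sex-stratified truncated normals (male height
  1.83 ± 0.07 m, mass 82.92 ± 13.02 kg; female 1.66 ± 0.06 m,
  56.19 ± 5.95 kg; cohort-wide min/max bounds), with segment volumes
  scaling with drawn mass;
* endurance times, log-normal around the per-(task, gravity, load) means
  (e.g. 14.93 min for male dynamic 1 kg at 1/6 g). Only the means come
  from the study conditions; the coefficient of variation (default 0.3) is
  a generator choice, since ETs are positive and right-skewed;
* window-level displacement targets drawn from the effect model above,
  with defaults equal to the published coefficients (male $dY$:
  $\beta_g = 17.06$, residual SD 8.45 cm; female $dY$: 5.87 / 2.11 cm;
  female $dZ$: 6.02 / 5.26 cm) and row counts 114 (male) / 56 (female);
* a seated skeleton template scaled to participant height, posed per
  window by 1-D root finds, rendered through a three-camera rig (2 m
  radius, 120° apart, 1920×1080, 30 Hz) with Gaussian pixel noise
  (1 px), keypoint dropout (2 %), and written as per-frame JSON in the
  pose software's dialect.

### Geometric realizability and the primary axis

A rigid articulated chain referenced to its own pelvis keeps its CoM
inside a narrow annular band around the torso arc: torso pitch moves the
CoM along an arc of roughly 35 cm radius, and the arms can shift it only a
few centimetres across that arc. Independent noise of the published
magnitude on *both* axes simultaneously (up to 8.45 cm SD) is therefore
geometrically unrealizable — a genuine property of pelvis-referenced
kinematics, and a strong hint that the published displacement table mixes
scales (its header says degrees while the accompanying text says cm; this
package treats all displacements as cm). The generator therefore
designates a **primary axis** per study (`primary_axis`): the torso-pitch
root-find realizes the primary-axis window target exactly (to 1e-6 cm,
verified by feeding the posed skeleton back through `body_com()`), and the
arm-direction root-find brings the secondary axis as close as its reach
allows, with both drawn and realized values recorded in the ground truth.
Studies analyzing $dY$ and $dZ$ are generated with the respective primary
axis.

Targets are drawn as displacements from a neutral reference posture (the
midpoint of the template's reachable span, recorded in the ground truth);
the offset moves only the regression constant, leaving the gravity and
task coefficients and the residual SD — the quantities under study —
untouched. Draws beyond the template's reachable span (≈2 standard
deviations out for the widest male configuration) are clamped to it; the
clamping probability is about 2 % per window and biases a group mean by
under 0.1 cm, an order of magnitude below the estimator's own standard
error. Within a window, the static pose holds with mean-centred 3D keypoint
jitter (0.3 cm), and the dynamic task swings the forearm through one
oscillation cycle with wrist speed capped at 47 cm/s; because the CoM is
linear in keypoint positions and jitter and oscillation are mean-centred
per window, window means reproduce the posed targets exactly on the
noiseless path.

Randomness is streamed per trial (`derive_seed()` hashes the master seed
with the trial identifier), so regenerating any subset of trials is
stable. Fixing the seed makes the whole study byte-reproducible.

### What passing tests do and do not show

The generator injects effects at the level the regression consumes and
realizes them geometrically, so a successful end-to-end recovery exercises
the JSON parsing, triangulation, CoM, windowing and OLS stages against one
shared ground truth. It does not validate what real underwater footage
would add: refraction and visibility errors, pose-estimator biases,
fatigue dynamics within a trial beyond the injected window means, or any
correlation structure between windows of one participant. Recovery results
therefore certify the computational chain, not the field protocol.

## Numerical choices and problem sizes

* Triangulation solves the DLT null vector via the smallest eigenvector of
  the 4×4 normal matrix; systems whose second-smallest eigenvalue is at
  relative machine scale are reported degenerate. Nonlinear reprojection
  refinement exists in the test suite as an independent oracle but is not
  the default path, keeping the pipeline deterministic and fast.
* Pose solving alternates a torso-pitch `uniroot` (tolerance 1e-12 rad)
  with an arm-direction `optimize`, typically converging in 3–4 rounds;
  an unreachable primary target errors with the reachable range.
* OLS uses the closed-form normal equations with an `rcond` guard at
  1e-12; the test suite checks it against the QR path in `lm()` at 1e-9.
* Demonstration and verification studies in the tests and the acceptance
  script render at 10 Hz (window means are invariant to frame rate on the
  noiseless path, and at 1 px pixel noise the window-mean error is
  ~0.02 cm); the generator default remains the 30 Hz of the camera rig.
* Replicate simulations for bias checks use 100 antithetic pairs: the OLS
  coefficient is linear in the injected residuals, so the pair mean cancels
  first-order Monte-Carlo noise and the replicate mean probes genuine
  pipeline bias rather than simulation noise.

## A small worked example

```{r}
cst <- sim_constants()  # g = 9.81, lunar 1.626 m/s^2, freshwater, lead
segments <- data.frame(name = c("forearm", "upper_arm", "torso"),
                       mass_kg = c(1.55, 2.70, 36.0),
                       volume_dm3 = c(1.37, 2.70, 44.71))
plan <- ballast_plan(segments, cst)
plan[, c("name", "ballast_mass", "residual_force")]
validate_balance(plan, cst)
```

```{r}
cfg <- generator_config(n_rows = c(male = 0, female = 56), fps = 10, seed = 1)
study <- generate_study(cfg, sexes = "female")
rows <- analyze_study(study)
fit <- com_gravfit(rows, "dY", sex = "female")
summary(fit)
```

The recovered gravity-level coefficient sits within two standard errors of
the generating value (5.87 cm), and the residual standard error recovers
the generating noise level (2.11 cm).

## Known limitations

* The secondary displacement axis of a generated study is best-effort, not
  exact; analyses of a generated study should target its primary axis.
* Repeated windows of one trial are pooled as independent observations (by
  design, for fidelity to the published degrees of freedom); the
  cluster-robust option quantifies, but does not remove, the resulting
  optimism of classical standard errors under within-trial correlation.
* The underwater optical path (refraction through flat ports) is not
  modeled; calibration is assumed valid in-medium.
* Subject-specific segment parameters from photogrammetry are out of
  scope; segment volumes are numeric inputs only.
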