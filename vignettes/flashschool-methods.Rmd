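---
title: "Modelling and measuring bioluminescent fish schooling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring bioluminescent fish schooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashschool)
```

The flashlight fish *Anomalops katoptron* schools at night using
bioluminescent flashes from its subocular light organs as the visual cue
that ordinarily requires daylight. This package models that behaviour
with a 3-D agent-based school whose social forces are gated by flashing,
measures synchrony with the polarization order parameter `mSync`, and
provides the image-analysis chain needed to extract the same quantities
from low-light video: fixed-pattern-noise correction, blob detection,
track linking, and flash-kinetics statistics. Because no field footage
is distributed, a ground-truthed synthetic-scene generator stands in
for the recordings in every end-to-end analysis.

## The school model

Each of `n` fish carries a position $\mathbf r$, velocity $\mathbf v$
and acceleration $\mathbf a$ in units of body lengths; mass is 1, so
$\mathbf a = \mathbf f_{tot}$. At every step of $\Delta t = 1/30$ s each
fish is updated synchronously from the previous frame's state:

* **Cohesion** $\;\mathbf f_c = \hat{\mathbf s}_c\,v_{max} - \mathbf v$,
  where $\mathbf s_c$ is the displacement to the centroid of visible
  neighbours. The centroid is taken *relative to the focal fish* so the
  force is translation-invariant (a sum of absolute position vectors
  would depend on the origin, contradicting the force's meaning as a
  tendency to move towards nearby fish).
* **Alignment** $\;\mathbf f_a = \hat{\mathbf s}_a\,v_{max} - \mathbf v$
  with $\mathbf s_a$ the mean neighbour velocity.
* **Separation** $\;\mathbf f_s = \hat{\mathbf s}_s\,v_{max} - \mathbf v$
  with $\mathbf s_s$ the mean of
  $(\mathbf r - \mathbf r_k)/|\mathbf r - \mathbf r_k|^2$.
* **Friction** $-\mathbf v$ and **speed control**
  $\hat{\mathbf v}(v_{cruise} - |\mathbf v|)$; the functional forms of
  the two internal forces are a design choice (the simplest resistive
  force and the simplest speed regulator), each configurable.

Weights default to $w_c = 7$, $w_a = 6$, $w_s = 9$, $w_f = 1.05$,
$w_v = 5$. After the Euler update the speed is rescaled to $v_{max}$
whenever it exceeds it. When a force's neighbour set is empty or its
direction vector vanishes, that force contributes the zero vector — an
undefined direction should not brake the fish.

**Flashing and visibility.** Each frame, a fish flashes with
probability `P` (0.5 in nature, matching the observed ~50% duty cycle);
a square-wave mode with per-fish random phase reproduces the measured
on/off timing instead. A fraction `D` of fish is drawn *dark* at
initialization and never flashes. Non-flashing fish are invisible to
the social forces of others. Gating all three forces is the default:
with alignment un-gated the school's order becomes independent of
flashing altogether (we measured steady mSync above 0.9 even with 99%
of fish dark), which would erase the dark-fraction dependence that is
the model's central result. The flag `flash_gates_all_forces = FALSE`
exempts the lateral-line-mediated forces for sensitivity analysis.
A consequence of full gating worth knowing: two dark fish are mutually
invisible, so nothing prevents them from converging onto the same
attractor trajectory and eventually coinciding; coincident agents are
therefore an error only when the pair could actually perceive each
other.

**Vision regions.** Cohesion (vision-mediated) reaches furthest and
excludes a 90° cone behind the fish; alignment (lateral line) spans an
intermediate range and misses 60° cones in front and behind; separation
is short-range and misses 60° behind. A fish at rest has no heading and
no blind cones that frame. The radii are not published; the defaults
are 25, 3 and 1 body lengths. The cohesion radius was deliberately set
*larger than the initialization cube's diameter* (fish start at rest,
uniform in a 20-unit cube): if cohesion cannot reach across the school,
any subgroup that drifts out of range is lost forever, and at high dark
fractions the school fragments irreversibly — we measured runs at
`D = 0.95` splitting into dozens of clusters with a cohesion radius of
10. A school held together by a handful of flashers presupposes that
those flashers can be seen across the school.

**Speeds.** $v_{max} = 2$ BL/s and $v_{cruise} = 0.8\,v_{max}$ are
unpublished; these values give stable, visibly moving schools (steady
mean speed ≈ 0.75 BL/s, steady mSync ≈ 0.89 for 200 fish).

**Motivated fish.** Informed leaders ignore all forces and swim at
`direction * min(speed_factor * v_cruise, v_max)`. They must not be
dark — an invisible leader cannot recruit followers. Interventions
(motivating fish, changing `D` mid-run) are applied between frames by
`run_simulation()`.

The per-frame update is implemented twice: a documented pure-R
reference step (`step_school()`) that defines the model, and a compiled
kernel used by `run_simulation()` for the 200-fish × 2000-step sweeps.
Both consume the same RNG stream and agree to ~1e-15 per coordinate
(summation order differs); the test suite compares them directly.

## Synchrony statistics

`msync()` is the polarization order parameter: the magnitude of the
mean velocity divided by the mean speed, 0 for perfectly cancelling
motion and 1 exactly when all moving fish share one direction. It is
rotation- and scale-invariant and dimension-agnostic (2-D for tracked
video, 3-D for the model). `direction_correlation()` measures alignment
with leaders as $\sum_i \langle \mathbf v_L, \mathbf v_i\rangle /
(|\mathbf v_L| \sum_i |\mathbf v_i|)$; although often described as
lying in $[0,1]$, the formula admits negative values for anti-aligned
fish, and we report it unclamped. The random-motion null
(`random_motion_null()`) draws uniformly random directions with speeds
resampled from data; its per-frame mSync scales as $n^{-1/2}$.
`rank_sum_test()` compares two mSync samples: an exact two-sided null
by enumeration of rank assignments when both samples have at most 8
observations, otherwise the normal approximation with tie correction.

## The video pipeline

The recordings this pipeline targets are extreme: flashes use at most
~1% of the 16-bit range, so the sensor's fixed-pattern noise (offsets
of mean ≈ 100, sd ≈ 5 counts) dominates the signal. Because flashing
fish are sparse, the per-pixel *temporal mean* of the whole stack
estimates the offset map (`estimate_fpn()`); the sparse flash content
biases the spatial mean by well under one count at the default scene
scale. Correction subtracts the map and clips at zero.

Detection thresholds each corrected frame and cleans it by
morphological opening with a 3×3 cross (the minimal operator that
removes isolated hot pixels; note it also shaves the corners off a
square blob). The default threshold is noise-referenced:
median + 5 robust standard deviations. One subtlety: after clipping at
zero, more than half of the background pixels can be exactly zero and
the MAD collapses, so the robust scale is the larger of the MAD and an
upper-quantile spread estimate $(q_{0.975} - \mathrm{med})/z_{0.975}$,
which still sees the noise on a clipped background. Connected
components use 8-connectivity, and only components strictly larger than
20 px become detections (unweighted centroid, area, peak intensity;
0-based row/col with integer pixel centres).

Linking is globally greedy nearest-distance within a maximum radius
(a Crocker–Grier-style cost without global optimization): closest
(track, detection) pairs are committed first, each used once. A track
undetected for more than `max_gap` frames is closed — 0 by default,
because non-flashing fish cannot be tracked; for flash-kinetics work
the gap is raised to bridge the ~5-frame off-phase, with the allowed
displacement growing as `max_radius * (gap + 1)`. There is no default
`max_radius`: it depends on the pixel scale of the footage and must be
supplied (the synthetic scenes calibrate it).

## Flash kinetics

Per track, the peak-intensity series (missing frames = off) is
thresholded at half the track's 95th-percentile intensity — robust both
to single hot frames and to the near-zero off-phase floor — and
run-length encoded. The first and last runs are truncated by the
observation window and are excluded from interval statistics; a
complete flash is an interior on-run plus its following off-run, each
contributing one duty cycle on/(on+off). The blink rate divides the
number of complete flashes by the total time they span, so a clean
square wave recovers 1/(on+off). The power spectrum is the periodogram
of each train's mean-removed *binary* state (not raw intensity),
averaged across fish (power discards phase, so phases need not align),
with the peak sought above 0.5 Hz to skip slow drift; trains are
truncated to a common length and must span at least 2 s (~0.5 Hz
resolution). Blink rate and spectral peak are deliberately both
reported, since "flash frequency" can mean either.

## Synthetic scenes

`render_stack()` emulates the recordings: per-pixel Normal(100, 5²)
offsets truncated at zero, isotropic Gaussian blobs (σ = 2 px, peak 655
counts ≈ 1% of the range) at the true fish positions while their train
is on, optional per-fish brightness factors (closer fish are brighter),
and Gaussian read noise (sd 2 counts — at ~1% of the dynamic range the
Poisson contribution is well approximated as Gaussian), quantized to
16 bits. Ground truth (centroids, on/off states, the true offset map)
is returned alongside. Trajectories are constant-velocity, random-walk,
or orthographic projections of simulated schools. What the generator
does *not* emulate: optics (PSF shape, vignetting), depth-dependent
blur, occlusions between fish, rolling shutter, or compression — so
passing tests demonstrate correctness of the measurement chain on
idealized scenes, not robustness to every artefact of real footage.
The real recordings' background level, noise and blob sizes are not
published; the scene defaults are declared fixtures, not estimates.

## Numerical choices and scales

* Synchronous explicit Euler at 1/30 s mirrors the 30 fps recordings.
* The sweep scale used throughout (200 fish, 2000 steps, steady state
  averaged over the final 500, 5 seeds per condition) polarizes from
  rest in well under 1500 steps at the default parameters.
* All randomness flows through R's RNG; every generator accepts a seed
  and identical seeds give identical output (the renderer and simulator
  are exercised for this in the tests).
* Degenerate inputs are contractual: a school where no fish ever moves
  has undefined mSync (the dark-fraction sweep scores such runs as 0 —
  no motion, no schooling); an all-off intensity series is a valid
  empty train; a spectrum is refused below 2 s of data.

## Known limitations

* The mSync–speed relation deserves honesty: in *raw* model
  trajectories, steady-state mSync and mean speed are negatively
  rank-correlated under these force laws (more ordered moments are
  slightly slower). The positive association seen in the field data —
  slow school ≈ disordered, fast school ≈ polarized — reappears when
  the model school is measured the way the field data had to be
  measured: rendered to low-light video, tracked, and differentiated,
  where near-standstill velocities are noise-dominated. The package
  tests the relation at that observation level and makes no claim about
  the raw-trajectory sign.
* The Beer–Lambert utility reproduces the reported irradiance at 20 m
  exactly from the reported transmittance (1.46e-10 W/cm² × 7.5% =
  1.10e-11 W/cm²), but the three reported transmittances (7.5%, 2.1%,
  0.15% at 20, 30, 100 m) are mutually inconsistent with
  $\exp(-0.0562\,z)$, which gives 32.5%, 18.5% and 0.36%; internally
  they imply k ≈ 0.13 m⁻¹ at 20–30 m but ≈ 0.065 m⁻¹ at 100 m. The
  package therefore computes strict Beer–Lambert and lets the caller
  supply any transmittance to `irradiance_at_depth()`.
* Exact field-scale statistics (the ~10⁻¹⁰⁰ Wilcoxon p-value for
  observed vs random motion) depend on footage that was never
  deposited; the package provides the machinery and synthetic
  analogues only.
* The linker is single-hypothesis and greedy; crossing fish at high
  density can swap identities. The cost function of the original tracking
  adaptation is unpublished, and no Kalman/multi-hypothesis tracking is
  attempted.
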