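# flashschool

Tools for studying how the flashlight fish *Anomalops katoptron*
schools in darkness using bioluminescent flashes — an agent-based model
of a flash-gated school, synchrony statistics, and the low-light video
analysis chain needed to measure the same quantities from 16-bit
night recordings.

## What it does

**Model.** A 3-D boids-style school: each fish feels weighted cohesion,
alignment and separation forces (weights 7/6/9), plus linear friction
(weight 1.05) and a speed-control force (weight 5), integrated with
synchronous explicit Euler at 1/30 s and a hard speed cap. The twist is
visibility: a fish flashes each frame with probability `P` (0.5 in
nature) and is perceivable by others *only while flashing*; a fraction
`D` of fish is permanently dark. Informed leaders ("motivated fish")
can be injected mid-run and ignore all social forces.

**Statistics.** Per-frame synchrony is the polarization order parameter

    mSync(n) = |mean velocity| / mean speed,

0 for shoaling, 1 for ideal schooling. Alignment with leaders is the
direction correlation `sum(<v_L, v_i>) / (|v_L| sum |v_i|)`. A
random-motion null model and a Wilcoxon rank-sum comparison (exact by
enumeration for small samples) complete the inference machinery.

**Video pipeline.** Flashes use ~1% of the camera's 16-bit range, so
fixed-pattern noise (offsets ~ Normal(100, 5²) counts) is estimated by
temporal averaging and subtracted; frames are thresholded
(noise-referenced default), cleaned by morphological opening (3×3
cross), reduced to centroids of 8-connected components larger than
20 px, linked into tracks by greedy nearest-distance matching within a
maximum radius, and each track's intensity series is segmented into
on/off flash intervals with duty cycles, blink rate and an across-fish
averaged power spectrum.

**Synthetic scenes.** No footage was deposited with the study, so a
ground-truthed generator renders moving Gaussian-blob fish with
square-wave flashing (on 0.166 s / off 0.168 s), fixed-pattern noise
and read noise; every end-to-end claim is tested against its ground
truth. A Beer–Lambert utility reproduces the starlight-at-depth
arithmetic.

## Worked example

Simulate a 200-fish school with 95% dark fish and measure its steady
synchrony:

```r
library(flashschool)

cfg <- sim_config(n_fish = 200, D = 0.95, seed = 1)
tr  <- run_simulation(cfg, 2000)
ks  <- kinematics_series(tr)
mean(ks$msync[1502:2001])
#> [1] 0.9927495
```

Even with only ~5% of the school flashing, steady-state mSync matches
the all-flashing baseline (0.894 for the same seed with `D = 0`): a few
flashers hold the school together. Recover flash kinetics from rendered video:

```r
cfg   <- scene_config(n_fish = 5, seed = 501)
traj  <- constant_velocity_trajectories(
           cbind(seq(40, 216, length.out = 5), rep(40, 5)),
           cbind(rep(0, 5), rep(0.25, 5)), n_frames = 600)
trains <- lapply(1:5, function(i)
  flash_train_signal(0.166, 0.168, 30, 600, phase_s = (i - 1) * 0.07))
scene  <- render_stack(cfg, traj, trains)

det    <- detect_stack(scene$stack)                 # FPN + detect
tracks <- build_tracks(det, link_config(max_radius = 3, max_gap = 8))
kin    <- recover_flash_kinetics(tracks, fps = 30)
kin$stats
#> flash_stats: 291 flashes, mean on 0.166 s, mean off 0.168 s, duty 49.7%, rate 2.99 Hz
kin$spectrum$peak_frequency_hz
#> [1] 2.97479
```

The pipeline recovers the rendered on/off timing to within one frame
period and the ~3 Hz blink fundamental.

The `analysis/` directory holds numbered narrative drivers
(`01_school_formation.R` … `06_starlight.R`) that run the study's
analyses at desk scale — school formation, the dark-fraction sweep,
motivated-fish leadership, flash kinetics, the full video pipeline, and
starlight attenuation — and write their tables under `results/`.

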