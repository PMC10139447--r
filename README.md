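# vrdisparity

Statistics of binocular eye movements and retinal disparities in
virtual-reality displays — for vision scientists and HMD/content designers
who want to know what the two eyes actually experience during VR use, and
what that implies for fusion, comfort and screen placement.

## What it computes

Given per-frame depth buffers (16-bit nonlinearly encoded PNG) and
binocular gaze logs (per-eye origins and Helmholtz gaze angles at 90 Hz),
the package produces:

* **Fixation statistics** — directions (head frame) and distances in
  diopters, with saccades removed by a 60 °/s velocity criterion plus
  2 %/98 % amplitude trimming, and binocular distance from triangulation of
  the two gaze rays (midpoint of the common perpendicular).
* **Retinal disparity fields** — the scene is reconstructed from the depth
  buffer, both eyes are posed on the fixation point including torsion from
  Listing's extended law (L2, gain 0.8), and per-point Helmholtz disparities
  are computed where both eyes can see the point. Convention: horizontal
  disparity = left − right azimuth, so *crossed* (nearer than fixation) is
  positive. Field maps report per-cell median/SD in arcmin over the central
  ±10°.
* **Diplopia probability** — the fitted horopter surface
  `DH = −0.0485·Y − 0.0036·X² − 0.0017·Y²` (deg) with a Panum fusional band
  of half-width `0.16 + 0.095·ε + ε^1.35` centered on it; per field cell,
  the proportion of disparities outside the band.
* **Vergence–accommodation conflict** — the percentage of fixations whose
  dioptric distance differs from a candidate screen distance by more than
  ±0.5 D, profiled over screen distances, and the conflict-minimizing
  screen distance.
* **Field-of-view geometry** — monocular, binocular (retinal-overlap) and
  total widths of per-eye screens as a function of width, optical distance,
  nasal/temporal shift, inter-ocular distance and vergence.

A synthetic-world module (`build_scene()`, `simulate_gaze()`,
`simulate_session()`) generates game-archetype scenes, depth buffers and
gaze traces with configurable fixation-distance laws, saccade kinematics
and tracker noise, and an exact ray-casting oracle
(`ground_truth_disparity()`) validates the discretized pipeline to
sub-arcminute agreement. See the methods vignette
(`vignettes/vr-disparity-methods.Rmd`) for models, conventions and design
choices.

## Worked example

```r
library(vrdisparity)

cam <- camera_model(121, 135, hfov = 90, near = 0.3, far = 50)
ses <- simulate_session("shooter", duration = 6, seed = 42, camera = cam)

fs <- fixation_samples(ses$trace)          # saccade-gated, triangulated
st <- fixation_statistics(fs)
ds <- session_disparity_samples(ses$frames, ses$trace, every = 20)
fm <- bin_field_map(ds)
prof <- conflict_profile(fs$dist_D)
```

This prints (via the summaries shown):

```
fixations: 132 samples, median 0.91 D (IQR 0.66-1.32)
disparity samples: 3735; central-field median range [-563.7, 306.2] arcmin
H:V anisotropy: 2.5 (IQR-based)
mean diplopia probability: 0.046
optimal screen: 0.99 D; conflict at a 1.54 D screen: 60.6%
```

Reading the numbers: this short simulated shooter session fixates at a
median of 0.91 D (~1.1 m). A screen at the common 1.54 D (65 cm) optical
distance would put 60.6 % of these fixations outside the ±0.5 D comfort
zone, while a screen near 1 D would minimize conflicts for this particular
session (longer, multi-game runs pooled with equal weight per game push
the optimum farther, near 0.5 D). The disparity field of this
near-dominated scene spans several degrees, and about 5 % of disparities
fall outside the fusable band — double vision would be common. The screen
geometry itself is deterministic:

```r
s <- screen_geometry(width = 117, distance = 65, iod = 6.33)
binocular_width(s, 0)                      # 83.97 deg, eyes at infinity
binocular_width(s, 0.7)                    # 81.44 deg at the median VR fixation
binocular_width(screen_geometry(shift = -10), 0.7)   # 70.92 deg, temporal shift
```

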