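---
title: "Binocular statistics of VR gaming: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binocular statistics of VR gaming: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrdisparity)
```

## The problem

The binocular visual system is tuned to the statistical regularities of
natural scenes: people mostly fixate near straight ahead, the ground plane
puts near objects in the lower visual field, and the resulting pattern of
binocular disparities is pitched "top back" — crossed (near) disparities
below fixation, uncrossed (far) above. Head-mounted displays can violate
these regularities, and they add their own constraints: the screens sit at a
fixed optical distance (so vergence and accommodation conflict whenever the
virtual content is nearer or farther), and the per-eye screens' horizontal
placement trades binocular field of view against total field of view.

`vrdisparity` implements the full measurement pipeline for these
statistics: from per-frame depth buffers and binocular gaze traces to
retinal disparity fields, diplopia (double-vision) probability maps,
vergence–accommodation-conflict profiles, and screen-placement geometry.
Because recorded game sessions are large and proprietary, the package also
contains a first-class synthetic-world module that generates scenes, depth
buffers and gaze traces with the relevant statistical structure, plus an
exact ray-casting oracle used to validate the discretized pipeline.

## Coordinate conventions

All 3-D geometry is in head coordinates: x rightward, y upward, z forward,
units of centimeters. Depth frames store *view-space* depth in meters — the
distance along the camera's optical axis, not the ray length — which makes
back-projection a pure pinhole inverse.

Angles use **Helmholtz coordinates**: azimuth is measured by latitude and
elevation by longitude, i.e. the elevation rotation (about the interaural
x-axis) is applied before azimuth. The direction for azimuth $H$ and
elevation $V$ is $(\sin H,\ \cos H \sin V,\ \cos H \cos V)$; positive
azimuth is rightward and positive elevation upward. Two consequences matter:

* **Head-centric vertical disparities vanish identically.** Helmholtz
  elevation depends only on the $y$ and $z$ coordinates relative to the eye
  center, and the two eye centers differ only in $x$. So for any rendered
  content, the difference in head-referenced elevation between the eyes is
  exactly zero. `head_centric_check()` exploits this as a
  rendering-correctness audit: any nonzero head-centric vertical disparity
  signals a geometry bug, at tolerance $10^{-9}$ degrees.
* **Retinal disparities do not vanish.** Once the eyes rotate onto a
  fixation point, both horizontal and vertical Helmholtz differences can be
  nonzero, and both depend on scene structure and fixation.

Disparity signs follow the crossed-positive convention: horizontal
disparity is left-eye azimuth minus right-eye azimuth, so points nearer
than fixation are positive (crossed), farther negative (uncrossed).
Vertical disparity is left minus right elevation.

## The depth-buffer codec

Game engines store depth non-linearly to concentrate precision near the
camera. The package fixes the reversed projective form

$$v = \frac{f\,(z - n)}{z\,(f - n)}, \qquad
  z = \frac{f\,n}{f - v\,(f - n)},$$

scaled to 16-bit integers, with the near/far constants $n, f$ recorded in
the session manifest so the codec is self-describing. The mapping is
strictly monotone and invertible up to quantization; the analytic
round-trip bound (half a code step times the derivative
$dz/dv = z^2 (f-n)/(f n)$, taken at the far end of the half-step interval)
is exported as `depth_quantization_bound()` and asserted in the tests. At
the default $n = 0.3$ m, $f = 50$ m the worst-case error is about 6 cm at
50 m and 25 µm at 1 m; propagated through triangulation this perturbs
disparities by well under a second of arc, which is why the pipeline can be
validated against a continuous oracle at arcminute tolerances.

Depth frames are written as single-channel 16-bit grayscale PNG. The PNG
*writer* is implemented in-package (IHDR/IDAT/IEND chunks, zlib stream,
CRC32) because no installed writer emits 16-bit grayscale PNG; files are
read back through the standard `png` reader and are byte-compatible with
other PNG tooling.

## From gaze traces to fixation samples

Disparity statistics must only include samples in which the visual system
can actually process disparity, so saccadic intervals are removed:

1. **Angular speed** of the cyclopean gaze direction by central differences
   (one-sided at the endpoints).
2. **Saccade cores**: contiguous runs exceeding 60 deg/s.
3. **2%/98% amplitude trimming**: each core is grown outward to the nearest
   local speed minima to delimit the movement; the reported interval spans
   from where the movement's cumulative amplitude crosses 2% to where it
   crosses 98%. The "movement window" definition (local minima) is the
   package's own choice, since the trimming rule presupposes a movement but
   no window definition is standard; it is deterministic and matched by the
   brute-force oracle in the tests. Intervals shorter than 2 samples at
   90 Hz are discarded as below the tracker's temporal resolution.

Remaining binocular samples are triangulated by `vergence_geometry()`: the
binocular fixation point is the midpoint of the common perpendicular of the
two (generally skew) gaze rays — the standard symmetric choice. Distance is
measured from the cyclopean point (midpoint of the eye centers) and
reported in meters and diopters ($D = 1/\text{m}$). Numerical policy:
near-parallel rays ($1 - (\hat d_L \cdot \hat d_R)^2 < 10^{-12}$) and
distances beyond a 100 m cap are treated as infinitely far (0 D) rather
than risking unstable triangulation; diverging rays (closest approach
behind an eye) are flagged and excluded.

Calibration quality control mirrors standard practice: RMS angular error
over ten targets (five positions at two distances), sessions accepted only
if the pre-test RMS is at most 0.8°, and repeated if the pre/post drift RMS
exceeds 1.0° (headset slippage). A constant azimuth/elevation offset, when
known from the tracker's own calibration, can be supplied and is removed
before scoring; the routine deliberately does not estimate one.

Fixation statistics use 1° direction cells over ±30° and 0.1 D distance
bins over 0–4 D, matching the ranges over which such distributions are
usually displayed. The 50% highest-density direction region is grown
greedily in descending cell-probability order (ties broken by cell index,
for determinism); for histograms the greedy set is exactly the smallest
set reaching the target mass.

## Eye poses: Listing's extended law (L2)

With the head upright and gaze far, eye orientations obey Listing's law:
rotations from primary position about axes in a plane. Under convergence
the law extends (L2): each eye's Listing plane rotates *temporally* by
$(g/2)\,\gamma$, where $\gamma$ is the vergence angle and the gain $g$ is
about 0.8 in observers with normal binocular vision. The implementation is
an exact rotation composition: yaw the primary direction temporally by
$(g/2)\gamma$, then apply the single rotation about an axis perpendicular
to both that carries the yawed primary direction to the target direction.
At $g = 0$ this reduces to pure Listing's law; disparities vary
continuously with the gain. The familiar small-angle consequence — a
cyclovergence of roughly $(g/2)\,\gamma\,V$ at gaze elevation $V$ — is used
only as a test-side sanity check against an independent quaternion
implementation; the pipeline always uses the exact composition. Whether
the two Listing planes rotate symmetrically is not settled by the
formulation; symmetric rotation is assumed.

Visual-field positions are referenced to a **cyclopean eye** at the
midpoint of the eye centers. Its reference pose is the pure Listing pose
onto the same fixation point: the cyclopean eye has no temporal side, so
no Listing-plane rotation is applied to it.

## Disparity fields and their validation

For each paired depth frame and fixation sample the pipeline back-projects
the buffer to a point cloud, poses the eyes with L2, removes points not
visible to both eyes, and takes per-point Helmholtz angle differences.
The occlusion test is a z-buffer at the depth buffer's own angular
resolution: a point is invisible to an eye if another cloud point projects
into the same angular cell (cell size = camera pixel pitch) at a smaller
eye distance. A relative depth tolerance (default ratio 1.05) prevents
same-surface neighbours from shadowing each other — a strict nearest-only
rule would spuriously occlude coplanar points. The buffer cannot resolve
occlusions finer than its pixel pitch in any case.

Validation is dual-route. `ground_truth_disparity()` recomputes disparity
by casting cyclopean rays directly against the scene primitives — no
depth-buffer discretization — under the *same* eye poses, with per-eye
shadow-ray occlusion. The test suite requires pipeline-vs-oracle agreement
below 0.5 arcmin across the central ±10° for all four scene archetypes,
excluding a 1-pixel zone around depth discontinuities (neighbouring depth
ratio > 1.1, dilated by one pixel), where back-projection of a discretized
buffer is inherently ill-defined.

Field maps bin disparities into 0.5° cells over the central ±10° (the
extent over which such maps are usually reported; both are configurable),
with per-cell median, standard deviation and count in arcminutes; empty
cells stay NA rather than zero. When sessions from several games are
combined, each game receives equal total weight regardless of sample
count: every sample from game $g$ gets weight $1/(n_g G)$ and the per-cell
statistics are weighted. A field map built from medians alone cannot be
re-pooled this way, so `bin_field_map()` retains per-cell sample values by
default and `aggregate_sessions()` consumes those.

The horizontal:vertical anisotropy of the pooled disparity distribution
(`anisotropy_ratio()`) uses interquartile ranges by default — robust to
the heavy tails that occluded edges induce — switchable to standard
deviations; a zero vertical spread is reported as an infinite ratio with a
flag rather than an error.

## Horopter, Panum's band and diplopia

The empirical horopter — the surface of zero disparity between
corresponding retinal points — is pitched top-back and curved laterally.
The package encodes it as the fitted surface

$$D_H(X, Y) = -0.0485\,Y - 0.0036\,X^2 - 0.0017\,Y^2
  \quad\text{(degrees)},$$

and the fusable range (Panum's area) as a band centered on the horopter
with half-width

$$w(\epsilon) = 0.16 + 0.095\,\epsilon + \epsilon^{1.35},
  \qquad \epsilon = \sqrt{X^2 + Y^2}.$$

The printed growth term $\epsilon^{1.35}$ is kept literally as the default
(fidelity first), but it grows far faster at 10° eccentricity than
classical Panum measurements suggest, and its units are ambiguous as
printed; a scaled variant $(\epsilon/\epsilon_0)^{1.35}$ is therefore
available as an explicit opt-in. Diplopia probability is, per field cell,
the proportion of observed horizontal disparities strictly outside the
band evaluated at the cell center (evaluating at each sample's exact
position would be equally defensible; the cell center was chosen and is
what the tests pin down). The band is closed: samples exactly on a limit
count as fused, so the computation is deterministic.

## Vergence–accommodation conflict

All conflict computations are dioptric, because both accommodation demand
and the comfort criterion are naturally dioptric; lengths are converted at
the API boundary. A fixation conflicts uncomfortably when its vergence
distance differs from the screen's optical distance by more than 0.5 D
(boundary counts as comfortable). `conflict_profile()` evaluates the
conflict percentage over a screen-distance grid — default 0–3 D in 0.01 D
steps, finer than the rounding of any plausible optimum — and
`optimal_screen_distance()` returns the grid minimum, breaking ties toward
the smallest diopter value (the farthest screen), which favours the
relaxed accommodation state.

## HMD field-of-view geometry

Each eye views its own screen of width $w$ at optical distance $d$,
optionally shifted nasally (+) or temporally (−) by $s$ cm. The monocular
span is the arctangent interval of the screen edges; converging at
$F$ diopters rotates each eye nasally by $\eta = \arctan(\tfrac{iod/2}{100/F})$,
and spans are re-expressed in each eye's rotated (retinal) frame. The
**binocular** field is the measure of the intersection of the two retinal
spans — the regions imaged on corresponding areas of the two retinas — and
the **total** field the measure of their union, so
$\text{total} + \text{binocular} = \text{left} + \text{right}$ exactly
(interval inclusion–exclusion), an identity the tests check on $10^4$
random configurations. The model is single-point (projection and rotation
centers coincide) and horizontal-plane only, consistent with how such
geometry is usually diagrammed; the ~1° effect of the real eye's
rotation-center offset is absorbed by the reported tolerances. With the
default 117 cm screens at 65 cm and iod 6.33 cm, the symmetric binocular
field is 84.0° at infinity, 81.4° at 0.7 D, and 70.9° at 0.7 D with 10 cm
temporal shifts — and nasal shifts of a few cm widen the binocular field
at the distances people actually fixate, at the cost of total field.

## The synthetic world: what it does and does not emulate

The generator stands in for recorded game sessions. It emulates the
properties the pipeline is sensitive to:

* **Archetype depth structure.** Four parametric archetypes
  (`rhythm`, `shooter`, `environmental`, `action_rhythm`) with object
  distances confined to 0.5–10 m, 0.5–50 m, 0.3–3 m and 0.5–50 m
  respectively (config-overridable); every scene has a ground plane 1.6 m
  below the eyes, a closing back wall, and 4–8 boxes/spheres of roughly
  fixed angular size.
* **Fixation-distance laws.** No generative law for fixation distances
  during gaming is established, so the generator exposes it as
  configuration. The defaults, chosen once from the qualitative shape of
  observed per-game distributions and not revisited: the three far-capable
  archetypes use an exponential in diopters (rate 1.2 D⁻¹ — mode at 0 D,
  i.e. distant gaze, with a near tail), the environmental archetype a
  lognormal in diopters (median 1.6 D, $\sigma_{\log} = 0.35$), each
  truncated to the archetype's depth range. Pooled with equal weight per
  game these defaults give a median fixation distance of ~0.8 D and a
  conflict-minimizing screen distance of ~0.5 D, which is what the
  acceptance tests assert.
* **Saccade kinematics and tracker noise.** Raised-cosine speed profiles
  with controllable peak velocity (default 300 deg/s), 90 Hz sampling, and
  isotropic Gaussian angular noise per eye and sample (default sd 0.8°,
  the midpoint of the 0.5–1.1° accuracy quoted for consumer HMD eye
  trackers).

It deliberately does not emulate: textures, shading or depth-of-field
blur (fusion is blur-sensitive in reality); smooth pursuit and
vestibulo-ocular slow phases (fixations are piecewise-static); head
movement (the head frame is the world frame); blinks beyond validity
flags; or the temporal correlation structure of real tracker noise.
Passing tests therefore demonstrate geometric and statistical correctness
of the pipeline, not ecological completeness of the simulated sessions.

Every stochastic operation takes an explicit seed and runs on a private
RNG stream (`.Random.seed` is saved and restored), so traces are
bit-reproducible and independent of caller state.

## Problem sizes and determinism in the test suite

The suite validates geometry on 121×135-pixel depth buffers (the
acquisition-resolution 363×403 default is exercised for shape only), 300–500
oracle directions per archetype, 500-fixation recovery runs and $10^4$
random screen configurations; these sizes were chosen so the whole suite
exercises every dual-route check while remaining quick enough to run on
every edit. All randomized tests fix their seeds; tolerance choices are
stated inline next to the assertions they justify (float-exactness checks
at $10^{-9}$–$10^{-12}$, discretization-limited checks at 0.5 arcmin,
sampling-limited checks at 2–4 binomial standard errors).

## Known limitations

* Scenes are axis-aligned primitive sets; there is no mesh import, so
  validation covers analytic geometry only.
* The occlusion test inherits the depth buffer's angular resolution;
  half-occlusion bands narrower than one pixel are invisible to it.
* The eye model is a single point: no corneal refraction, no
  rotation-center/nodal-point separation, no pupil-size dependence of
  Panum's band.
* Torsional tracker noise is not simulated (only azimuth/elevation), so
  calibration QC cannot detect cyclorotational slippage.
* The horopter and Panum coefficients are fixed constants; the package
  does not refit them to individual observers.
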