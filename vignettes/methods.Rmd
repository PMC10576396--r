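---
title: "Speckle-stereo surface reconstruction and instrument pose navigation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereonav)
```

`stereonav` addresses a concrete surgical problem: during arthroscopic
osteochondral autograft transplantation the harvesting chisel must stay
perpendicular to the cartilage surface, but the surgeon sees the scene
through a narrow endoscope with no depth perception.  The package
reconstructs the joint surface in metric 3D from one speckle-illuminated
stereo frame, anchors it to a patient-fixed coordinate frame supplied by an
EM tracker, and turns any tracked instrument pose into an angle-to-normal
readout.  This vignette explains each stage's model, the tunable parameters,
the synthetic data the package is validated on, and the design decisions
taken where the problem left latitude.

## Coordinate frames and the patient tracking chain

Every cloud and transform carries a frame tag drawn from
`camera, sensor1, sensor2, sensor3, transmitter, femur`, and operations
refuse mismatched frames outright — the central failure mode this pipeline
exists to prevent is silent frame confusion.  Tracked poses are always
stored in the sensor-to-transmitter direction; inverse maps are derived by
`invert_transform()` (transpose rotation, rotated negated translation),
never stored.

A camera point $P_c$ reaches the transmitter frame through the hand–eye
calibration $(R_{cs1}, d_{s1})$ — the fixed rotation and offset between the
left camera and sensor-1 in the endoscope tip, with $d_{s1}$ expressed in
the sensor-1 frame — and the tracked sensor-1 pose:

$$P_t = R_{s1t}\,(d_{s1} + R_{cs1} P_c) + P_{ts1}.$$

Sensor-3 is screwed to the femur, so its frame *is* the patient frame:
$P_{s3} = R_{s3t}^{\top}(P_t - P_{ts3})$.  Because both tracked poses are
expressed relative to the transmitter, a common rigid motion $M$ applied to
both (a knocked transmitter, or the whole specimen moving with its sensors)
cancels algebraically; the test suite verifies invariance to $10^{-9}$ mm.
This is the property that frees the workflow from re-registration after
intraoperative disturbances.

Rotations are accepted as matrices or unit quaternions `(qw, qx, qy, qz)`;
quaternions off unit norm by less than $10^{-6}$ are renormalised, larger
deviations rejected.  All lengths are millimetres; interfaces use degrees,
internals radians.

## Stereo matching

The articular surface is texture-less, so matching relies on a projected
pseudo-random dot pattern (~5000 dots).  The chain is: undistort and rectify
(Brown radial/tangential model, epipolar alignment along the baseline with a
shared averaged intrinsic matrix, bilinear resampling), then semi-global
matching, then `Z = fB/d` triangulation back into the original left-camera
frame.

The matching cost is a 7×7 census transform compared by Hamming distance — a
deterministic, single-pass surrogate for mutual information that the SGM
literature treats as standard; the cost function sits behind
`.sgm_cost_volume_cpp` and can be swapped.  Costs are aggregated along 8
paths with the usual recurrence (penalty `P1 = 10` for ±1 disparity steps,
`P2 = 120` for jumps, on 8-bit census costs).  No reference values for these
penalties exist for this instrument; they are exposed in `sgm_params()` and
the defaults were chosen once as mid-range values for census costs.

Three validity mechanisms matter, and two of them are deliberate choices:

* **Left–right consistency (1 px):** the right-image cost volume is derived
  from the left one (`C_R(x, d) = C_L(x + d, d)`), aggregated identically,
  and a pixel survives only if the two disparities agree within a pixel.
* **Ambiguity ties:** candidates whose window leaves the image get *neutral*
  (zero) cost, and a pixel whose aggregated minimum recurs at a non-adjacent
  disparity is invalid.  Featureless regions tie everywhere and are thereby
  rejected; this replaces a fractional uniqueness-ratio test with its exact
  limit, keeping all arithmetic integer and oracle-checkable.  (A pure
  left-right check cannot reject a uniform scene: it is self-consistent.)
* **Speckle coverage (`mask_disparity_by_intensity`, default level 40):**
  unlit background pixels bordering the speckle field can lock onto the dots
  of the neighbouring surface and pass both checks; only pixels the
  projector actually lit carry signal, so triangulation is restricted to
  them in the pipeline.

All SGM arithmetic is integer, and the test suite holds the compiled
implementation equal — exactly, not approximately — to an independent
loop-based R implementation of the same recurrence on small images.
Subpixel refinement fits a parabola through the aggregated costs around the
winner; invalidity is an explicit mask, never a sentinel value.

## Voxel rearrangement and isosurface extraction

The femur-frame cloud is snapped to a uniform cubic grid of spacing `t`
anchored at the per-axis cloud minima and padded by one cell: each point
moves per axis to the nearer grid vertex, with exact half-interval ties
going to the lower vertex (deterministic).  Every point lands on exactly one
vertex, the L∞ snap distance is at most `t/2`, and the occupied vertex set
is within `(√3/2)·t` Hausdorff distance of the cloud — all property-tested.
The default `t = 0.3` mm is half the 0.6 mm normal-search diameter, so the
grid never undersamples the neighbourhood the pose estimator reads.

Surface extraction is non-interpolating: each grid cube's eight corner
occupancies form a byte indexing a 256-case triangle table, with vertices at
cut-edge midpoints.  Rather than transcribing a published table, the table
is generated at load time from first principles: on every cube face
(corners ordered counter-clockwise from outside) each maximal run of
occupied corners contributes a directed crossing segment; because the two
faces sharing an edge traverse it in opposite directions, these segments
close into consistently oriented polygons, which are fan-triangulated with
normals pointing from occupied to empty.  Faces with two diagonally
occupied corners are ambiguous; the generator always keeps diagonal corners
separated, the same resolution in every cube, which keeps neighbouring
cubes' polylines compatible (an isolated occupied vertex meshes to a closed
octahedron with Euler characteristic 2, verified in tests).

Reconstruction quality is graded the way 3D measurement units are graded:
total-least-squares plane fits (RMSE of orthogonal distances, R² on the
depth residuals of `z ~ x + y`) and sphere fits (algebraic linear
initialisation refined by Gauss–Newton on radial residuals).

## Normal estimation and AngDif

The surface normal at a contact point comes from an inscribed triangle: all
point triples within a 0.6 mm-diameter neighbourhood are enumerated
(exhaustively up to 30 neighbours, else over the 30 nearest) and the
maximum-area non-degenerate triangle wins; its edge cross product,
normalised, is the estimate.  The two criteria in tension — a small
neighbourhood for local fidelity, a large triangle for noise robustness —
are resolved by bounding the neighbourhood first and maximising area inside
it.  On an analytically sampled 98 mm shell at clinical point densities the
estimator stays below 1°, dominated by the curvature bound
$\arcsin(0.3/98) \approx 0.18°$ plus sampling geometry.

The sign of a cross product is arbitrary, and the hardware description
never fixes one; `estimate_normal()` takes a reference direction and flips
the normal to agree with it.  `navigate()` passes the instrument axis
$c_h$ (butt→tip, pointing into the surface) as the reference, so the
reported AngDif lies in [0°, 90°] and reads 0° at perpendicular placement.
Contact triggers within 1.0 mm of the nearest cloud point (configurable);
the reported position is that cloud point, so the normal is always defined
where it is displayed.  Errors distinguish "fewer than 3 neighbours" from
"all neighbours collinear".

## The hemisphere tabulation protocol

The evaluation geometry puts the sphere centre $O$ at the origin with the
base (ECG-paper) plane at $z = 0$, shell apex at $z = r = 98$ mm.  Markers
sit at polar angles $\theta_s = s\,(\pi/2)/\text{sections}$ (five markers
for the default six sections, i.e. $\theta_s = s\pi/12$) on arcs spaced
$\varphi = \pi/12$ apart; the default six arcs reproduce the 30-sample
protocol (six captures × five positions).  Whether the first arc sits at
$\varphi = 0$ or $\pi/12$ is not determined by the geometry; the azimuth
origin is configurable with default 0.

The instrument's axis ray is projected from marker $P$ to its landing point
$E$ on the base plane, and the error angle follows from the law of cosines
in triangle $OPE$ (side $OP = r$):

$$\beta = \arccos\!\left(\frac{|EP|^2 + r^2 - |OE|^2}{2\,r\,|EP|}\right),$$

which is identically the angle at $P$ between the ray $PE$ and the true
inward normal $PO$ — the package asserts this equivalence against a direct
vector-angle computation to $10^{-9}$° over ten thousand random
configurations, and defines $\beta = 0$ in the coincident-point limit
$|EP| < 10^{-12}$.

`run_evaluate()` drives a simulated harvester at each marker: sensor poses
are constructed so the calibrated tip touches the marker with the axis
along either the analytic normal tilted by a configurable angle (protocol
characterisation) or the normal estimated from the shell cloud (closure
mode, where the measured $\beta$ distribution is exactly the normal
estimator's own error).  The injected tilt carries 0.1° Gaussian pointing
jitter — the orientation noise grade of the EM tracker the system uses —
chosen a priori so a 30-sample mean resolves the tilt to well within 0.1°.
Steep markers ($\theta_5 = 75°$) with an unlucky tilt azimuth can point
above the horizon; such rays are recorded as missing and excluded from the
statistics, which leaves the mean unbiased because every valid sample's
$\beta$ equals the tilt plus its jitter.

## The synthetic scene generator

The simulator replaces three pieces of hardware:

* **Surfaces** — plane, sphere, hemisphere shell, and a smooth Gaussian-bump
  height field standing in for a femur condyle (bump amplitudes ≤ 3 mm; no
  claim of anatomical fidelity).  Each provides exact signed distance (for
  the height field, vertical distance), an exact surface sampler, and
  analytic normals, so reconstruction error is measured against truth, not
  against another estimate.
* **The speckle stereo endoscope** — two identical pinhole cameras with mild
  radial/tangential distortion, parallel axes, 4 mm baseline (the physical
  tip circle of 7.40 mm bounds the true, unpublished value; configurable).
  The projector sits midway along the baseline, as the physical illuminator
  does, and casts 5000 dots splatted as σ = 0.8 px Gaussians so the census
  matcher sees realistic multi-pixel support.  A dot is drawn only if it is
  the first surface intersection along its camera ray.  Ground-truth depth
  and disparity are computed analytically per rectified pixel and satisfy
  `disparity = f·B/depth` by construction.
* **The EM tracker** — per-axis Gaussian position noise (default σ = 0.55 mm)
  and a random-axis rotation with Gaussian-magnitude angle (default
  σ = 0.1°), matching tracker-grade performance figures; the mean position
  error of this sampler is $\sigma\sqrt{8/\pi}$, verified by Monte-Carlo.

Synthetic images are 320 × 240 at 60° field of view rather than the
hardware's 720P/120°: at a 40 mm working distance the narrower view puts
the test object across most of the frame, and the smaller image keeps the
full test suite and the acceptance script comfortably fast on one core.
All sampling is seeded and restores the caller's RNG state; every fixture
is reproducible from its configuration alone.

What the simulator deliberately omits — sensor noise and blur, specular and
subsurface scattering, underwater refraction, rolling-shutter and
synchronisation artefacts, EM field distortion near metal — bounds what
green tests demonstrate: they validate the algorithms and their composition
on geometrically faithful, photometrically idealised data, not the physical
instrument.  Hardware-scale error figures (hundreds of μm reconstruction
RMSE, double-digit-degree pose error) arise from those omitted physics, so
the synthetic pipeline's smaller numbers are expected and are not evidence
about any physical device.

## Numerical choices and degenerate inputs

* Rotation validity: $\|R^{\top}R - I\|_{\max} < 10^{-9}$ and
  $\det R = 1 \pm 10^{-9}$, enforced at construction.
* Undistortion inverts the Brown model by 20 fixed-point iterations, ample
  at endoscope-scale distortion (forward–inverse agreement well under
  0.05 px in tests).
* SGM winner-take-all breaks exact ties toward the smaller disparity
  (deterministic, mirrored by the oracle); subpixel refinement is skipped at
  search-range boundaries and for non-convex cost triples.
* Sphere fits refuse coplanar inputs, plane fits refuse collinear ones (via
  singular-value thresholds at $10^{-9}$ relative); the law-of-cosines
  argument is clamped within $10^{-9}$ slack and an inconsistent-geometry
  error is raised beyond it.
* The disparity store format is ×16 fixed point split into high/low bytes of
  an RGB PNG (the PNG writer available here has no 16-bit channel mode);
  the validity mask is a separate PNG, so no sentinel ever enters the
  disparity array.
* Pipeline runs are reproducible byte-for-byte from config plus seed; the
  run log records a config fingerprint (FNV-1a) that excludes the output
  directory.

## Known limitations

* Single-frame reconstruction only: no multi-frame fusion or SLAM, by scope.
* The height-field ray solver assumes gentle slopes and camera rays with a
  dominant depth component; it is not a general ray tracer.
* The left-right check reuses one cost volume rather than recomputing
  right-referenced census costs; this is the standard economy and can keep
  half-occluded pixels near depth discontinuities.
* `fit_plane()`'s R² is computed on depth residuals and is uninformative for
  fronto-parallel planes (no depth variance to explain); the orthogonal RMSE
  is the robust figure.
* The marching-cubes ambiguity rule (diagonal corners always separated) is a
  consistent topological choice, not a curvature-adaptive one; thin
  one-voxel structures mesh as separated blobs rather than tunnels.
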