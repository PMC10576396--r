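# stereonav

Surgical-navigation pipeline for keeping a bone harvester perpendicular to a
joint surface, built around a speckle-illuminated stereo endoscope and an
electromagnetic (EM) tracking system.  In osteochondral autograft
transplantation (OAT) the tubular harvester must enter the cartilage surface
perpendicularly; `stereonav` reconstructs the articular surface in 3D from a
single stereo frame, expresses it in a patient-fixed coordinate frame that
survives specimen and transmitter motion, and reports the angle (**AngDif**)
between the instrument axis and the local surface normal.

The package implements the full chain plus a synthetic-scene simulator that
stands in for all hardware, so every stage runs and is tested without an
endoscope or tracker.

## The method

1. **Speckle stereo matching.** The articular surface is texture-less, so a
   projector casts ~5000 pseudo-random dots onto it.  After undistortion and
   epipolar rectification, dense correspondence is found by semi-global
   matching (SGM): per-pixel census (7×7) Hamming costs `C(p, d)` are
   aggregated along 8 image paths with the standard smoothness recurrence

   `L_r(p, d) = C(p, d) + min( L_r(p−r, d), L_r(p−r, d±1) + P1, min_k L_r(p−r, k) + P2 ) − min_k L_r(p−r, k)`

   followed by winner-take-all, a left–right consistency check, and parabolic
   subpixel refinement.  Depth follows the rectified closed form
   `Z = f·B/d`.

2. **Patient tracking frame.** With hand–eye calibration `(R_cs1, d_s1)` and
   tracked sensor poses, a camera point `P_c` reaches the transmitter frame as
   `P_t = R_s1t (d_s1 + R_cs1 P_c) + P_ts1` and the patient (femur) frame —
   realised by sensor-3 rigidly fixed to the bone — by applying the inverse
   of the sensor-3 pose.  Because both poses are referenced to the
   transmitter, any common motion (a knocked transmitter, a moved specimen)
   cancels exactly.

3. **Surface rearrangement.** The femur-frame cloud is snapped onto a uniform
   cubic grid (interval `t`, nearest-vertex rule, halves to the lower
   vertex); each grid cube's 8-bit corner-occupancy indicator indexes a
   256-case table and triangles are emitted at cut-edge midpoints
   (non-interpolating isosurface extraction).

4. **Pose estimation.** At the contact point, candidate point triples inside
   a 0.6 mm-diameter neighbourhood are searched exhaustively; the
   maximum-area non-degenerate inscribed triangle gives the surface normal
   `n_e` as the normalised cross product of its edges, and
   `AngDif = arccos(c_h · n_e)` with `c_h` the instrument axis.

5. **Hemisphere tabulation.** Accuracy protocol on a transparent shell of
   radius r = 98 mm resting on millimetre (ECG) paper: markers at polar
   angles `θ_s = s·π/12` along arcs spaced `φ = π/12` apart; the instrument's
   ray is projected from marker `P` to the landing point `E` on the base
   plane and converted to the error angle by the law of cosines,
   `β = arccos((|EP|² + r² − |OE|²) / (2 r |EP|))`.

## Worked example

Reconstruct a synthetic ping-pong-scale sphere (diameter 40.09 mm at 40 mm
working distance) end to end, then run the pose protocol with the instrument
tilted 15.4° from the true normal:

```r
library(stereonav)

cfg <- pipeline_config(out_dir = tempfile())
res <- run_reconstruct(cfg)
fit <- fit_sphere(res$cloud_femur$points)
round(c(diameter_mm = fit$diameter_mm, rmse_mm = fit$rmse_mm), 3)
#> diameter_mm     rmse_mm
#>      40.158       0.207

ev <- run_evaluate(pipeline_config(out_dir = tempfile(), tilt_deg = 15.4,
                                   seed = 3))
unlist(ev$summary[c("mean_deg", "sd_deg", "min_deg", "max_deg", "n")])
#>   mean_deg     sd_deg    min_deg    max_deg          n
#> 15.3942271  0.0945987 15.1870158 15.5994696 29.0000000
```

The fitted diameter recovers the simulated ball to ~0.1 mm, and the protocol
reports the injected 15.4° tilt back with the tracker-grade 0.1° pointing
jitter; one of the 30 markers is recorded missing because its tilted ray
misses the base plane (steepest marker, unlucky tilt azimuth) and is excluded
from the statistics.

A thin command-line front end is installed at `inst/cli/stereonav`
(`stereonav simulate|reconstruct|navigate|evaluate --config cfg.yaml`).

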