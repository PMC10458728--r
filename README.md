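# flytunnel

Simulation and analysis pipeline for studying **visual–motor coordination
(VMC)** of flying insects — honeybees in particular — negotiating a
**dynamically moving obstacle gap** in a flight tunnel.

Compound-eyed insects steer by optic flow, and they actively shape that flow
with their own movement: wide lateral "scanning" in front of a static
obstacle, much calmer flight when the obstacle itself moves. Measuring this
requires an automated rig: a tunnel with a motor-driven gap, a low-rate
detector camera whose motion trigger fires a high-speed camera only for
correctly-directed crossings, image analysis that extracts per-frame pose
(centroid, yaw) and the instantaneous gap width, a virtual mapping of the
pixel track into world coordinates, and a reconstruction of the visual input:
the geometric optic-flow field over the spherical field of view and the
gap-expansion parameters.

`flytunnel` implements the entire chain in R, with the hardware replaced by a
seeded synthetic renderer so every stage is testable and reproducible.

## The models at the core

* **Gap kinematics** — the gap edge moves at `vc = 2π·fp·rc / i` (pulse
  frequency `fp`, gear radius `rc`, reduction ratio `i`), alternating
  direction at constant speed: a triangle wave in gap width between `d_min`
  and `d_max`.
* **Trigger statistic** — centroid x-positions fill a queue of length `n`;
  the mean per-frame displacement `PxS = Σ(Px_k − Px_{k−1})/n =
  (last − first)/n` telescopes; its sign drives a direction counter (Flag)
  that gates the capture decision after the insect leaves the field.
* **Gap decoding** — with the gap's axial extent fixed, pixel area is
  proportional to width: `ds = (As / Amax) · dmax`, calibrated on a
  fully-open frame.
* **Geometric optic flow** — for each ommatidial direction **d** (5° grid), a
  ray cast into the scene gives range `r` and surface velocity `Vs`; the
  motion field `V = −ω×d − (T_rel − (T_rel·d)d)/r` with `T_rel = T − Vs` is
  projected into horizontal/vertical components `Vx`, `Vy` (rad/s).
* **Expansion parameters** — retinal size `γ = |wrap(α − β)|` of the gap
  boundaries seen from the insect (atan2 construction), its rate `γ̇` (central
  differences), and the relative retinal expansion velocity `RREV = γ̇/γ`,
  which approaches the inverse time-to-contact `v/D` head-on.

## Worked example

```r
library(flytunnel)

scene <- tunnel_scene()                       # 1.56 x 0.28 x 0.28 m tunnel
kin   <- barrier_kinematics("dynamic", d_min = 0.02, d_max = 0.10, vc = 0.04)
cam   <- framing_camera(scene)                # 163 fps over the barrier

# calibrate the gap ROI on a fully-open reference render
corner <- world_to_pixel(cam, cbind(scene$barrier_x + c(-0.02, 0.02), c(0.06, -0.06)))
rect <- c(floor(min(corner[,1])), floor(min(corner[,2])),
          ceiling(diff(range(corner[,1]))) + 1, ceiling(diff(range(corner[,2]))) + 1)
ref <- render_sequence(scene, barrier_kinematics("static", d_min = 0.10, d_max = 0.101),
                       simulate_flight(duration = 0.02, speed = 0.5, start = c(0.2, 0), seed = 1),
                       cam, noise_sd = 0, seed = 1)
roi <- calibrate_gap_roi(ref$frames[[1]], rect, d_max = 0.10)

# simulate, render and analyse one gap approach
trk <- simulate_flight(duration = 0.7, speed = 0.7, start = c(1.02, 0.01),
                       lateral_amplitude = 0.02, noise_sd = 0.003, seed = 11)
sq <- render_sequence(scene, kin, trk, cam, seed = 12)
pt <- track_pose(sq, roi = roi)               # pixel pose + decoded gap width
wt <- map_track(pt, cam, scene)               # world coordinates (planar mapping)
roundtrip_error(pt, wt, cam)$max_px           # mapping fidelity
vp <- visual_param_series(wt, scene, kin)     # gamma, gamma_dot, RREV
trajectory_stats(wt)
```

This prints (seeds as above):

```
valid: 107 of 115 frames
roundtrip max: 1.14e-13 px
   time_s gamma_rad gamma_dot   rrev defined
5  0.0245    0.0876    0.3227 3.6852       1
15 0.0859    0.1126    0.6132 5.4442       1
25 0.1472    0.1564    0.7973 5.0966       1
  flight_time straightness dispersion
1      0.6994       0.9262     0.0121
```

107 of 115 frames carry a valid detection (the rest are occluded by the
barrier strip or dropped); the planar mapping re-projects to the detected
pixels to machine precision; the gap's retinal size grows along the approach
with `RREV` in the 4–5 s⁻¹ range (inverse time-to-contact); the flight is
fairly straight (0.93) with 1.2 cm lateral dispersion.

The trigger side:

```r
sw <- run_speed_sweep(speeds = c(2, 6, 8, 10), n_trials = 10, n_reps = 1, seed = 42)
#   speed trials fires accuracy
#       2     10    10      1.0
#       6     10     9      0.9
#       8     10    10      1.0
#      10     10     9      0.9
```

A command-line wrapper over the same functions lives at
`inst/cli/flydetector.R` (subcommands `trigger`, `track`, `map`, `flow`,
`params`, `eval-trigger`).

See `vignettes/flytunnel-methods.Rmd` for the models, assumptions, parameter
choices and known limitations.

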