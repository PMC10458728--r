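---
title: "Methods: simulating and analysing insect flight in a dynamic-obstacle tunnel"
author: "flytunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing insect flight in a dynamic-obstacle tunnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flytunnel)
```

## The measurement problem

Flying insects shape their own visual input: by modulating forward speed,
lateral "scanning" excursions and head yaw, they control the optic flow their
compound eyes receive, and that flow in turn guides the flight — visual-motor
coordination (VMC). Studying this loop in front of a *moving* obstacle
requires a rig that (i) presents a dynamically changing gap, (ii) notices an
insect crossing a wide detection field and triggers a high-speed camera only
for correctly-directed crossings, (iii) extracts per-frame pose (centroid,
yaw) and the instantaneous gap width from the recorded images, (iv) maps the
pixel trajectory back into world coordinates, and (v) reconstructs what the
eye saw: the geometric optic-flow field and the gap-expansion parameters
$\gamma$, $\dot\gamma$ and RREV.

`flytunnel` implements that whole chain in software. The physical rig —
stepper motor, cameras, embedded board — is replaced by a seeded synthetic
renderer, so every stage of the pipeline can be exercised, measured and
regression-tested deterministically, with no hardware and no downloads.

## World model

The tunnel is an axis-aligned box, by default $1.56 \times 0.28 \times
0.28$ m, with the origin at the centre of the entrance floor; $x$ runs toward
the exit, $y$ is lateral (left-positive), $z$ is up. A barrier plane sits
0.30 m before the exit and carries two door panels leaving a horizontal gap.

**Gap kinematics.** The gap edge is driven through a gear of radius $r_c$ by
a stepper at pulse frequency $f_p$ behind a reduction ratio $i$ (default 64),
so its linear speed is

$$v_c = \frac{2 \pi f_p\, r_c}{i}.$$

The drive alternates direction at constant speed, which makes the gap width a
symmetric triangle wave between configurable limits $d_{min}$ and $d_{max}$
with slope magnitude $v_c$ — the simplest waveform consistent with
"constant speed, alternating direction". One gap edge is fixed (at
$y = -d_{max}/2$) and the other moves; this matches a single rack-driven door
plate, and makes the fully open gap centred on the tunnel axis. The moving
edge carries velocity $\pm v_c$, which matters later for the optic flow of a
stationary observer.

**Detectability geometry.** An ommatidium subtends roughly $\delta = 5^\circ$.
A gap of width $d$ becomes resolvable at the distance where it subtends one
ommatidial angle,

$$D = \frac{d}{\tan(\delta/2)},$$

and the tunnel must be longer than $2D$ to leave room for approach and
reaction. (The source rig literature typesets this formula ambiguously as a
product; the quotient is the only reading under which the tunnel-length
constraint and the monotonicity in $\delta$ make physical sense, so the
quotient is what `obstacle_detection_distance()` computes.)

**Wall pattern.** The walls carry a two-tone random pattern whose amplitude
spectrum falls as $1/f$ — the naturalistic statistic standard in insect-vision
stimuli. `make_wall_texture()` filters white Gaussian noise in the Fourier
domain with a $1/f$ amplitude envelope and binarises at the median, giving
two tones covering 50% each. The measured log–log radial spectral slope of
generated instances is close to $-1$ (the test suite requires
$[-1.3, -0.7]$); binarisation flattens the slope slightly relative to the
pre-threshold field, which is acceptable for a two-tone stimulus.

## Synthetic imaging

`simulate_flight()` generates ground-truth trajectories: constant mean
forward speed, optional sinusoidal lateral scanning, smooth correlated
positional noise (white noise low-pass filtered over ~50 ms), constant
height, yaw following the velocity heading. `render_sequence()` draws, per
frame: the tiled wall pattern (4 mm texture pixels), the two door panels with
the bright open gap between them at their kinematic positions, and the insect
as a soft-edged dark ellipse (13 x 5 mm body, the size of a honeybee) at its
projected position and yaw, plus additive Gaussian pixel noise
($\sigma = 0.01$ of full scale) and an optional Gaussian blur of the
silhouette. A per-frame *miss probability* (default 2%) omits the insect
entirely, emulating real-camera dropout; it is the only failure channel the
renderer injects deliberately.

Two camera models mirror the rig: a 30 fps detector camera spanning 620 mm of
the tunnel (the trigger's field of view, rendered at 310 x 72 px — a
region-of-interest crop at about 0.5 px/mm, which is all the trigger needs),
and a 163 fps framing camera centred on the barrier (500 x 288 px at about
1 px/mm). Both are nadir-mounted pinholes; image $x$ aligns with world $x$
and image $y$ (downward) with world $-y$, so world yaw equals minus image
yaw. All pixel coordinates are 0-based pixel centres.

What the renderer deliberately does *not* emulate: wing beats, body pitch and
roll, motion blur, illumination gradients, shadows, lens distortion and
multiple insects. Tests passing on these renders therefore certify the
algorithmic chain — segmentation thresholds and moment estimators behave as
designed — not robustness to photometric effects absent from the model.

## The direction-gated trigger

Per detector frame: a running-median background (initialised from the
pixel-wise median of warm-up frames, then updated by a $\pm 1/255$ signed
step per frame) is subtracted; pixels deviating by more than 0.15 become
foreground; connected components outside configurable area limits (default
$[10, 5000]$ px²) are discarded, which also suppresses the moving door
panels; exactly one qualifying contour yields a centroid, more than one is an
"ambiguous" frame that is skipped with state preserved (the multiple-insect
guard).

Centroid $x$-positions fill a sliding queue of length $n = 5$. Whenever the
queue is full, the displacement statistic

$$PxS = \frac{1}{n}\sum_{k} (Px_k - Px_{k-1}) = \frac{Px_{last} - Px_{first}}{n}$$

is evaluated (the sum telescopes; the denominator is $n$ as the rig defines
it, not $n-1$). A signed counter Flag is incremented when the sign of $PxS$
matches the configured crossing direction and decremented otherwise; values
within $\pm 0.1$ px/frame are treated as no movement (a deadband below
rasterisation jitter — real crossings displace by several px/frame). When
the insect has left the field — two consecutive frames without a detection,
a debounce so that a single dropped frame cannot split one passage into two
events — the trigger fires if Flag favours the configured direction
($|Flag| \geq 1$ by default), then resets.

Two design points deserve justification:

* **Partial-queue decision at exit.** A 620 mm field at 30 fps yields only
  $620 \cdot 30 / v$ mm-frames: at 8 m/s just above two detection frames, and
  below two frames past ~9.3 m/s, where triggering becomes impossible. A
  5-deep queue would never fill on such crossings, so when a crossing ends
  before the queue ever filled, one statistic is evaluated over the partial
  queue (at least 2 entries) at exit time. Slow crossings are decided purely
  by full-queue statistics; this keeps the entry/exit windows symmetric, so
  an insect that enters and retreats the way it came accumulates a net Flag
  of zero and does not trigger.
* **Known limitation.** With the default $|Flag| \geq 1$ threshold, a
  perfectly balanced in-and-out excursion sits one noisy window away from
  firing; raising `flag_threshold` trades that robustness against the
  ability to trigger on two-frame crossings.

The speed-adaptability harness (`run_speed_sweep()`) renders repeated
crossings per target speed with a uniform random sub-frame launch phase (the
mock target is not synchronised to the camera clock) and counts crossings
producing exactly one event. With the default conditions — 620 mm field,
30 fps, 2% miss — accuracy is at ceiling through 7 m/s, sustains $\geq 95\%$
through 8–9 m/s, and collapses above ~9.3 m/s exactly where the two-frame
geometric bound bites. The 100-passage acquisition harness
(`simulate_passages()`) draws forward speeds uniformly from 0.5–2 m/s with
3 cm lateral scanning at 2 Hz.

## Pose and gap extraction

`track_pose()` applies the same segmentation/centroid operators per
high-speed frame. Its default background is the pixel-wise median of five
frames sampled evenly across the sequence: the insect occupies any given
pixel only briefly, so the median is insect-free even when the insect is
already in view at the first frame (a first-frames background is available
as an option when insect-free warm-up frames exist).

**Yaw** comes from the second central moments of the segmented blob,
$\theta = \tfrac{1}{2}\,\mathrm{atan2}(2\mu_{11}, \mu_{20}-\mu_{02})$ — the
orientation of the equivalent ellipse. The 180° axis ambiguity is resolved
toward the current centroid motion (falling back to the previous frame's yaw
when stationary); nearly isotropic blobs ($\sqrt{(\mu_{20}-\mu_{02})^2 +
4\mu_{11}^2} < 0.05\,(\mu_{20}+\mu_{02})$) have no defined axis and carry the
previous yaw with a low-confidence flag.

**Gap width** uses the pixel-area calibration: a rectangle is fixed over the
gap region in the first frame; on a reference frame with the gap fully open
the bright-region area $A_{max}$ is stored against the known metric width
$d_{max}$; thereafter each frame's largest bright contour area $A_s$ inside
the rectangle decodes as

$$d_s = \frac{A_s}{A_{max}}\, d_{max},$$

clipped to $[0, d_{max}]$. This is exact because the gap's extent along the
tunnel axis is fixed by the panel geometry — only the lateral width changes —
so area is proportional to width. The segmentation threshold (0.85) sits at
the midpoint between panel and open-gap grey levels. The ROI rectangle is
also *excluded* from the insect's foreground mask, so the moving door edge is
never mistaken for the insect; the cost is that frames where the insect is
inside the ROI strip are marked invalid and propagate as gaps in the track.
On noiseless renders the decoded width tracks the kinematics with RMSE below
1% of $d_{max}$ (the tests require < 3%).

## Virtual mapping

With one camera there is no height information, so pixel tracks are
back-projected onto a fixed horizontal plane at mid-tunnel height
(`pixel_to_world()`, the exact inverse of the pinhole projection restricted
to that plane). `map_track()` applies this per valid frame and flips the yaw
sign into the world convention. The mapping-fidelity check
(`roundtrip_error()`) re-projects the world track and reports per-point pixel
distances to the detected track. Under a single planar calibration this
round trip is an analytic inverse, so its error is numerically zero; it
becomes informative exactly when the world model and the camera view
disagree — the tests construct such a case (an insect flying 5 cm above the
assumed plane under a 15°-oblique camera) and verify a systematic offset, the
height-loss limitation inherent to single-camera planar mapping.

## Geometric optic flow and expansion parameters

`geometric_flow_field()` reconstructs the instantaneous angular motion field
over a latitude–longitude grid of view directions at the ommatidial spacing
$\delta = 5^\circ$ (poles excluded, where the azimuth basis degenerates). For
each head-frame direction $\mathbf{d}$, a ray is cast from the eye through
the yaw rotation into the scene (`cast_ray()`), returning the range $r$, the
surface hit (walls, floor, ceiling, fixed/moving door panel, or nothing
through the open gap and tunnel ends) and the surface's own velocity
$\mathbf{V}_s$ (zero except on the moving panel, which carries the gap edge
velocity). The rigid-scene motion field with a moving surface is

$$\mathbf{V}(\mathbf{d}) = -\boldsymbol\omega \times \mathbf{d}
  - \frac{\mathbf{T}_{rel} - (\mathbf{T}_{rel}\cdot\mathbf{d})\,\mathbf{d}}{r},
  \qquad \mathbf{T}_{rel} = \mathbf{T} - \mathbf{V}_s,$$

projected onto the local azimuth/elevation unit vectors to give $V_x$ and
$V_y$ in rad/s ($V_x > 0$ = environmental motion toward increasing azimuth,
i.e. leftward in the head frame). Directions that hit nothing keep only the
rotational term. This formula has the properties the geometry demands, each
asserted in the tests: rotational flow has magnitude $|\omega|$ at zero
elevation independent of scene distances; translational flow vanishes at the
focus of expansion and halves when all scene distances double; the field is
exactly linear in $(\mathbf{T}, \omega)$ at fixed geometry; and for a
stationary eye in front of a moving barrier, all nonzero flow lies on the
moving-panel directions.

The gap-expansion parameters use the two gap boundary positions $A$ and $C$
and the insect position $B$ in the horizontal plane:

$$\alpha = \mathrm{atan2}(C_y - B_y, C_x - B_x),\quad
  \beta = \mathrm{atan2}(A_y - B_y, A_x - B_x),\quad
  \gamma = |\mathrm{wrap}(\alpha - \beta)|,$$

with `atan2` so every quadrant is valid and the absolute wrapped difference
so the $A/C$ labelling cannot flip the sign. $\dot\gamma$ is computed by
central finite differences (one-sided at the series ends, where the
truncation error is one order worse — analyses should prefer interior
samples), and

$$\mathrm{RREV} = \frac{\dot\gamma}{\gamma},$$

which in the symmetric head-on small-angle limit equals the inverse
time-to-contact $v/D$. Where $\gamma < \gamma_{eps} = 10^{-4}$ rad the ratio
is reported as undefined rather than clipped, because near-zero RREV
crossings are themselves behaviourally meaningful. A cross-validation ties
the two submodules together: $\gamma$ computed from the gap edges agrees with
the angular extent of the no-hit ("gap") sector of a horizontal flow-field
slice to within one grid spacing.

## Evaluation statistics

`trajectory_stats()` reduces a world track to flight time, straightness (net
displacement over path length) and lateral dispersion. Dispersion is the RMS
perpendicular residual about the *principal-axis* (total-least-squares) line
through the track — not a $y$-on-$x$ regression — so the statistic is
invariant under rigid rotations and translations; for a sinusoidal lateral
oscillation of amplitude $a$ it equals $a/\sqrt{2}$. Neither "straightness"
nor "dispersion" has a canonical rig definition; these are the standard
readings of those axis labels.

`compare_conditions()` runs paired two-sided t-tests per statistic (Welch
unpaired with a warning when group sizes differ; all-zero difference vectors
are reported as no-difference rather than NaN). The dynamic-vs-static
contrast is reproduced in silico by `simulate_condition_stats()`: flights
facing a static obstacle are generated with large lateral scanning amplitude
(3 cm) and flights facing a dynamic obstacle with small amplitude (0.8 cm),
matched forward speed and duration — the behavioural pattern of interest
(dispersion differs strongly; flight time does not). This module is
explicitly plumbing around standard statistics; the science is in the
generator's contrast, not the test.

## Numerical choices and problem sizes

* Angles: degrees at all interfaces, wrapped to $(-180, 180]$; radians
  internally and for $\gamma$/flow outputs.
* Foreground threshold 0.15, gap threshold 0.85, both in image units on
  $[0,1]$ renders with ~0.5 contrast between insect and background.
* The speed sweep runs 12 speeds x 60 crossings (~half a minute), the
  acquisition harness 100 passages (~10 s), the round-trip check one 115
  frame 163 fps sequence (~5 s) — sizes chosen so the whole verification
  chain runs in about a minute on one core while keeping Monte-Carlo
  fractions at the 1/60 resolution the accuracy bounds need.
* All stochastic stages (trajectory noise, pixel noise, dropout, launch
  phase, trial seeds) derive from one explicit integer seed per entry point.

## Known limitations

* Single-camera planar mapping loses height; oblique mounting turns height
  error into lateral bias (quantified in the tests).
* The renderer's photometric simplicity means segmentation thresholds need
  re-tuning for real footage; the *algorithmic* contracts (moments,
  telescoping statistic, area calibration) transfer unchanged.
* The trigger's default majority threshold of 1 can fire on a balanced
  in-and-out excursion under unlucky noise; see the trigger section.
* $\dot\gamma$ at the first/last sample uses one-sided differences (2nd- vs
  3rd-order truncation); interior samples should be preferred.
* Insect-inside-ROI frames are invalid rather than tracked-through; a
  joint insect/gap segmentation would recover them.
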