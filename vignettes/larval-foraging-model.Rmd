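---
title: "A crawl/turn/pause model of larval foraging and its trajectory analysis"
author: "larvaforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A crawl/turn/pause model of larval foraging and its trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaforage)
```

## The scientific problem

Third-instar *Drosophila* larvae forage by stringing together three motor
programs: straight crawling bouts, discrete reorientation turns, and pauses.
How much time a larva spends exploiting a patch of food versus exploring the
substrate around it depends on how these programs are modulated by the local
substrate (its nutritional quality) and by the spatial arrangement of food.
`larvaforage` implements both halves of the computational workflow used to
study this question:

* a **stochastic agent model** of a crawling larva in a rectangular arena
  with circular food patches, parameterized per genotype (rover/sitter) and
  substrate (agar, sucrose, yeast, apple juice), optionally with a
  distance-dependent bias to turn toward the nearest patch center; and
* a **trajectory-analysis pipeline** that treats a centroid track — recorded
  by a tracker at 2 frames/s or produced by the simulator — identically:
  Kalman smoothing, per-frame kinematics, turn detection by
  Ramer–Douglas–Peucker (RDP) polyline simplification, signed turning
  angles, handedness, inward/outward turn classification, and
  patch-residence metrics.

## The model

At each time step $t_k$ (step length $\Delta t = 0.5$ s; a 50-minute
session is 6000 steps) the larva is in exactly one state:

* **crawl**, with probability $P_\mathrm{crawl} = 1 - (P_\mathrm{turn} +
  P_\mathrm{pause})$: the position advances by $\hat h \, v \, \Delta t$
  where the speed $v > 0$ is drawn from a normal distribution
  $\mathcal N(\mu_v, \sigma_v)$ truncated to positive values and
  $\hat h$ is the current unit heading;
* **turn**, with probability $P_\mathrm{turn}$: the heading rotates by an
  angle $\theta \sim \mathrm{vonMises}(\mu, \kappa)$; no translation occurs
  during a turn step;
* **pause**, with probability $P_\mathrm{pause}$: nothing moves and the
  heading is preserved.

The per-step probabilities are the tabulated per-second rates multiplied by
$\Delta t$. This linear scaling is exact for the purpose that matters here —
it reproduces $60 \cdot P_\mathrm{turn}/\mathrm{s}$ turns per minute — and is
an excellent approximation of $1 - e^{-r\Delta t}$ at the small tabulated
rates.

The motor parameters per genotype and substrate ship with the package:

```{r}
motor_params_table("homogeneous")
```

In a **patchy arena**, the parameters are looked up at the larva's current
position at every step: the patch substrate's parameters apply inside any
patch (patches are closed discs — the boundary counts as inside), the
outside substrate's (agar) elsewhere. The same turning-angle distribution is
used on both sides of the patch border. Runs start at a uniformly random
point inside a uniformly chosen patch, matching how animals were placed in
the experiments, with a uniform initial heading.

A second parameter set (`motor_params_table("patchy")`), fitted
inside/outside patches in patchy arenas, ships as an alternative
configuration.

### Inward-turn bias

Recorded larvae at a patch border preferentially turn back toward the food.
The model implements this as follows: when a turn of magnitude $|\theta|$ is
drawn at distance $d$ from the nearest patch center, the two candidate
post-turn headings are $h \pm |\theta|$. The candidate whose direction makes
the smaller angle with the vector $\vec u$ from the larva to the patch
center is the *inward* option. With probability $P_\mathrm{bias}(d)$ the
inward option is taken; otherwise the outward one. $P_\mathrm{bias}$ is a
piecewise-constant profile over half-open distance bins, zero beyond a
60 mm cutoff (beyond which recorded data were too sparse to estimate a
bias). Under this rule the realized inward fraction of biased turns equals
$P_\mathrm{bias}$ — which is exactly how the profile was measured, as the
fraction of inward turns per distance bin.

Two boundary conventions are deliberate: a bin with $P_\mathrm{bias} = 0$
applies *no* bias (it reproduces the unbiased draw, not "always outward"),
and a larva standing exactly on a patch center gets no bias (the inward
direction is undefined there). The experimentally measured profiles were
published only as figures, so the package ships an explicitly synthetic
illustrative profile (`bias_profile_synthetic.yaml`) and treats real
profiles as user-supplied configuration.

### Patch fragmentation

The reference design distributes food over two patches of radius
$R = 25$ mm, a total area $S = 2\pi R^2$. Fragmenting the same food into
$N$ patches gives each patch radius $R' = \sqrt{S/(N\pi)}$ (e.g. 12.5 mm
for $N = 8$), placed disjointly at random by rejection sampling. Because
the bias profile is tied to the patch scale, its distance bins and cutoff
are multiplied by $R'/R$ when the radius changes.

### Walls and other numerical choices

* **Rigid boundaries**: a crawl step that would exit the 240 × 240 mm arena
  is truncated at the wall and the heading is resampled uniformly over the
  directions pointing back into the interior. This avoids the wall-sticking
  artifact of simply clamping positions while remaining agnostic about the
  (unreported) details of wall behavior; specular reflection was the
  alternative considered.
* **Speed memory**: the crawl speed is redrawn every crawl step
  (memoryless). Whether speed persists within a crawl bout is not
  determined by the tabulated statistics; the memoryless reading is the
  simplest consistent one, and the synthetic-recording generator implements
  the per-bout alternative, so both are available.
* **von Mises sampling** uses the Best–Fisher rejection algorithm
  ($\kappa = 0$ degenerating to the circular uniform); truncated-normal
  speeds are drawn by resampling. All randomness flows through R's RNG, so
  a single `set.seed()` makes entire simulation campaigns bit-reproducible.
* **arccos arguments** are clamped to $[-1, 1]$ throughout.

### The per-larva turning-angle stand-in

In the original study each simulated larva inherited the turning-angle
distribution fitted to one recorded larva; those per-larva fits were never
published. The package's default stand-in draws each larva's mean direction
$\mu \sim \mathrm{U}(-0.3, 0.3)$ rad — individual handedness of either
sign — with a common concentration $\kappa = 1$, both configurable
(`draw_turn_model()`). This is the one structural unknown of the model, and
it matters unevenly: residence in sucrose and agar-control patches is
dominated by speed and pause modulation and barely responds to the angle
model, while residence in yeast patches shifts by several percentage points
across plausible $\kappa$ (run `analysis/06_turn_model_sensitivity.R` to
quantify this). Reproduction of published yeast residence values should
therefore be read with that slack in mind; the package does not tune the
stand-in toward any published number.

## The analysis pipeline

Tracker-style input is one CSV row per frame (`larva_id`, `frame`, `x_mm`,
`y_mm`, 2 frames/s). The stages, each exposed as its own function:

1. **Kalman smoothing** (`kalman_smooth`): a constant-velocity
   linear-Gaussian filter on $(x, y, v_x, v_y)$, defaults
   $\sigma_\mathrm{meas} = 0.1$ mm and $\sigma_\mathrm{proc} = 0.05$ mm/s
   per step (the filter was named in the original pipeline without
   parameters; defaults are configurable and logged in the output). A
   Rauch–Tung–Striebel backward pass is optional; the forward filter is the
   default.
2. **Kinematics** (`kinematics`): backward-difference velocity
   $\vec V(t_j) = (\vec R(t_j) - \vec R(t_{j-1}))/\Delta t$, speed
   $s = \lVert \vec V \rVert$, unit heading, and turn rate
   $\arccos(\hat H(t_{j-1}) \cdot \hat H(t_j))/\Delta t \in [0, \pi/\Delta t]$.
   Zero-displacement frames have undefined heading (flagged); the last
   defined heading is carried forward for turn-rate purposes only and the
   turn rate at such frames is reported as 0, flagged.
3. **Turn detection** (`rdp_simplify`): recursive RDP with
   $\varepsilon = 2.5$ mm (1.25 mm on yeast, where tracks are short and
   tortuous); retained interior vertices are the turn locations.
4. **Turn characterization** (`turning_angles`, `handedness`,
   `turns_per_minute`): signed angles via `atan2` of the cross and dot
   products of consecutive segment vectors, CCW positive, in
   $[-\pi, \pi]$; the handedness score $H = N_\mathrm{CCW} /
   (N_\mathrm{CCW} + N_\mathrm{CW})$ (angles of exactly 0 count as
   neither; $H$ is flagged undefined with no turns); turns per minute as
   the mean over all full 120-frame rolling windows of the within-window
   turn counts.
5. **Inward/outward classification** (`classify_turn`,
   `inward_fraction_by_distance`): at turn vertex $\vec S(t_k)$, with
   $\vec V_1 = \vec S(t_k) - \vec S(t_{k-1})$,
   $\vec V_2 = \vec S(t_{k+1}) - \vec S(t_k)$ and
   $\vec U = \vec P - \vec S(t_k)$ toward the nearest patch center, the
   turn is *inward* iff $\theta_2 < \theta_1$ where
   $\theta_i = \angle(\vec V_i, \vec U)$. Exact ties (within $10^{-12}$) go
   to *outward*, the conservative label; degenerate zero-length vectors are
   flagged unclassifiable. Fractions are tabulated over half-open 10-mm
   distance bins up to 60 mm (beyond which events are excluded, as larvae
   rarely reached such distances).
6. **Residence metrics** (`fraction_time_inside`, `fraction_visited`,
   `distance_traveled`, `pause_fraction`): per-frame point-in-disc
   residence; distinct non-source patches visited over $N_p - 1$; summed
   displacements; pause frames by a speed threshold (default 0.1 mm/s —
   the operational definition for recordings is a package choice, as none
   was published) or exactly from the simulator's state log.

## The synthetic-recording generator

`generate_recording()` emulates what the tracking pipeline hands the
analysis: a piecewise-ballistic centroid track — crawl bouts at a constant
per-bout speed, instantaneous heading changes at turns, frozen pauses —
plus isotropic Gaussian centroid jitter (default SD 0.1 mm, matching the
Kalman measurement default), with the full ground truth returned alongside.
`scripted_recording()` is its deterministic sibling for exact round-trip
tests, and `make_fixture_suite()` writes a seed-pinned set of fixture CSVs.

What the generator deliberately does **not** emulate: posture and contour
(head casts, bending), peristalsis-scale position flicker, tracker
artifacts such as identity swaps or dropped frames, and any
sensory feedback. Passing round-trip tests therefore demonstrates that the
analysis recovers the motor-program structure it assumes, not that it is
robust to every artifact of real video tracking.

## Study conditions and problem sizes

The packaged experiment wrappers default to the study design: 30 larvae
× 30 runs × 6000 steps per condition
(`patch_residence_experiment`), two 25-mm patches on the arena midline
separated by 120 mm (the published design shows, but does not print, the
patch coordinates; the separation is configurable), and fragmentation
grids of 1–64 patches. The bundled analysis scripts (`analysis/`) use these
sizes for the headline unbiased-model table and reduced cohort sizes
(8–15 larvae, 4–15 runs) for the bias, fragmentation, and sensitivity
scans, which are trend analyses rather than point estimates.

## Known limitations

* The inward-bias profile shipped is illustrative; quantitative
  biased-model results require user-supplied measured profiles.
* The unbiased yeast-patch residence depends on the unpublished per-larva
  turning-angle fits (see the sensitivity section above); sucrose and
  agar-control residence do not.
* Multiple larvae in one arena are independent agents; no interaction,
  ingestion dynamics, odor gradients, or internal state.
* Patches are uniform closed discs; substrate diffusion at patch edges is
  not modeled.

## A minimal session

```{r, eval = FALSE}
set.seed(1)
lay <- two_patch_layout("yeast")
sim <- simulate_larva(lay,
                      params = list(yeast = get_motor_params("sitter", "yeast"),
                                    agar = get_motor_params("sitter", "agar")),
                      turn_model = draw_turn_model(),
                      n_steps = 6000)
fraction_time_inside(sim$trajectory, lay)
ev <- detect_turns(sim$trajectory, layout = lay)
handedness(ev$angle_rad)
inward_fraction_by_distance(ev)
```
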