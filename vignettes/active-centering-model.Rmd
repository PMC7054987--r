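---
title: "The active-diffusion centering model and its trajectory statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The active-diffusion centering model and its trajectory statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oocenter)
```

## The biological question and the model

Mouse oocytes center their nucleus — a 25-µm organelle — across tens of
micrometres of cytoplasm without any microtubule-based machinery, using an
actin-dependent process. The working physical picture is *active diffusion
with a gradient*: Rab11a-positive vesicles nucleate actin and are propelled
by myosin-Vb, behaving as self-propelled particles. Their motion persistence
increases from the cell center to the cortex. A gas of self-propelled
particles exerts a "swim pressure" that grows with persistence, so a
persistence gradient creates a pressure gradient, and any object large
enough to average over many vesicle collisions feels a net push toward the
center — an Archimedes-like, non-specific force.

`oocenter` implements this picture as a 3D off-lattice, center-based agent
model. Each agent is a sphere with a centroid and radius. The velocity of
agent $i$ follows the overdamped force balance

$$\vec v_i \;=\; \frac{1}{\eta_i}\Big(\textstyle\sum_j \vec F_r^{\,ij} + \vec F_c^{\,i}\Big) + \vec B_i,$$

where $\eta_i = 6\pi r_i \gamma$ is the Stokes friction (viscosity $\gamma$,
1 Pa·s for the oocyte cytoplasm), $\vec F_r$ is a linear hard-core contact
repulsion acting as soon as spheres overlap,

$$\vec F_r = c_r\Big(1 - \tfrac{\lVert\vec d\rVert}{d_{eq}}\Big)\,\hat d,
\qquad d_{eq} = r_i + r_j,$$

$\vec F_c$ is an analogous confinement force applied by the cortex as soon
as an agent touches the boundary sphere (quadratic in the penetration by
default), and $\vec B_i = v_0\,\hat b_i$ is the self-propulsion of vesicles
(the passive object has no propulsion: every bit of its motion comes from
collisions). The heading $\hat b_i$ is redrawn uniformly on the unit sphere
at random times controlled by the local persistence time

$$\tau_i = \tau_0\,(1 + \tau_r\,\lVert\vec r_i\rVert),$$

with $\tau_0 = 0.001$ min at the center and slope $\tau_r = 0.25\,\mu m^{-1}$,
i.e. $\tau$ rises to about 0.0098 min at the 35-µm cortex. Positions advance
with the two-step Adams–Bashforth scheme
$x \leftarrow x + \Delta t\,(\tfrac32 v_{now} - \tfrac12 v_{prev})$,
bootstrapped with an explicit Euler step.

### Why the multiplicative gradient

The persistence gradient can be read in two dimensionally plausible ways:
additive ($\tau_0 + \tau_r r$, with $\tau_r$ in min/µm) or multiplicative
($\tau_0(1+\tau_r r)$, with $\tau_r$ in 1/µm). We implement both
(`gradient_form`), but the default is multiplicative, for a physical reason
discovered during development: with the additive reading, cortical
persistence times reach ~8.75 min, giving persistence lengths far larger
than the cell at any propulsion speed capable of centering the object. Such
quasi-ballistic swimmers pile up massively at the boundary (we measured
~90% of vesicles in the outermost decile shell), which contradicts the
spatially uniform vesicle density this mechanism is known to maintain, and
the centering stalls in a noisy, saturated regime. The multiplicative
reading keeps persistence lengths sub-micron; constant-speed run-and-tumble
particles with a space-dependent tumbling rate then relax to a *uniform*
density (a classic result for this class of models), while the persistence
gradient still produces the centering pressure. Only this reading
simultaneously reproduces uniform density, the rising squared-velocity
profile, and centering on the reported timescale.

### Heading-redraw rule

The probability of redrawing a heading per step is `1 - exp(-dt/tau)` by
default rather than the linear `min(1, dt/tau)` (which remains available as
`redraw_model = "linear"`). The geometric redraw with the exponential
probability gives *exactly* exponential heading decorrelation with time
constant $\tau$ at any step size, whereas the linear rule distorts the
effective persistence by 25–40% wherever $\tau \lesssim \Delta t$ — which,
with $\tau_0 = 0.001$ min, is precisely the cell center where the object
ends up. With the default `dt = 0.001` min the two rules agree closely
everywhere else.

### Parameter choices and units

Units are µm, minutes and pN throughout, so force/friction is µm/min and
1 Pa·s = 1/60 pN·min/µm². The geometry and population parameters are fixed
by the biology: a 70-µm cell, 500 vesicles of 1-µm mean diameter and a
25-µm object for prophase I; 200 vesicles for meiosis I. For the meiosis
vesicle size, the sources conflict internally: a stated mean "1.4 µm"
coexists with the statement that vesicle volume *triples* after NEBD, which
from a 0.5-µm prophase radius gives a 0.7-µm radius, i.e. 1.4 µm mean
*diameter*. We adopt the diameter reading (`meiosis_config()`:
`vesicle_radius_mean = 0.7`), because the radius reading implies a 22-fold
volume increase and, in simulation, centers the object as fast as prophase
(the product of vesicle count and radius, which sets the push, would barely
change) — contradicting the known ~2× slower meiotic centering that the
diameter reading reproduces.

Parameters not printed in the available sources — the intrinsic speed `v0`
and the contact stiffnesses — were fixed once by calibration, mirroring how
the original model was tuned to experiments: `c_r = 100` pN and
`c_c = 200` pN keep steady-state overlaps below ~10% of an agent radius at
the working propulsion forces while remaining well inside the stable-step
regime of the integrator; `v0 = 30` µm/min (0.5 µm/s, the upper range of
myosin-V cargo speeds) is the value at which the emergent observables land
on the published ones — a rising squared-velocity profile of the right
shape, prophase centering in roughly 400 min with a residual radial speed
near 0.04 µm/min, and a centering velocity growing as the object surface.
`calibrate_speed()` exposes the same calibration against any target
squared-velocity profile, and `reference_velocity_profile()` generates a
synthetic closed-form target when no measured profile is available.

### Numerical choices

* `dt = 0.001` min resolves $\tau_0$ and keeps contact-spring dynamics
  stable (`c_r/(d_{eq}\eta)\,dt \lesssim 0.6` for typical vesicle pairs).
  Rare contacts between unusually small vesicles can sit at the stability
  margin; the bounded force law turns these into local, bounded chatter
  rather than divergence.
* An optional automatic step check (`auto_dt`) halves `dt` and reruns when
  any per-step displacement exceeds 10% of the smallest agent radius. It is
  off by default because at the calibrated speed the *free-flight* step
  $v_0\Delta t$ is itself of that order — harmless, since headings persist
  across steps and free flight integrates exactly — so the check is mainly
  useful for slow-motility, stiff-contact configurations.
* Contact detection uses a cell grid feeding a Verlet candidate-pair list
  with a 0.5-µm skin, rebuilt whenever twice the accumulated maximum
  per-step displacement reaches the skin; this is exact (no contact can be
  missed) and keeps the 500-agent, million-step runs at ~20 s each.
  Per-step displacements are additionally capped at 45% of the skin
  (~0.2 µm): ordinary dynamics never approaches the cap, but it prevents a
  pathological transient (a deep overlap, or an agent momentarily pushed
  past the cortex where the confinement force grows without bound) from
  running away, and guarantees no displacement can outrun the pair list.
* All randomness flows through R's RNG: a configuration plus its seed
  reproduces a simulation bitwise, and the test suite holds the compiled
  kernel to bitwise agreement with a pure-R reference integrator.
* Initial conditions: the object starts tangent to the cortex along +x;
  vesicles are placed uniformly, rejecting overlaps with the cortex, the
  object and each other.
* The gradient-off control uses a homogeneous persistence equal to the
  volume-weighted spatial mean of the gradient profile
  (`mean_persistence_time()`), so both conditions have the same average
  motility.

## Trajectory statistics

The analysis half consumes `track_set` objects — tables of timestamped
positions with a frame interval — whether they come from the simulator, the
synthetic generators, or tracking software via `read_tracks()`.

* **MSD and diffusion.** `msd()` uses the overlapping all-pairs
  time-averaged estimator per track; `ensemble_msd()` averages per-track
  curves unweighted, with lags capped at a quarter of the track length.
  `fit_diffusion()` fits the first 20 lags with an intercept and divides
  the slope by $2d$ (4 in 2D: $MSD = 4Dt$); `msd_loglog()` returns the
  anomalous exponent $\alpha$ over the first 100 lags.
* **Radial kinematics.** `radial_components()` projects displacements on
  the inward radial axis at their start point ($d\cos\theta$, positive
  toward the center); `radial_velocity_profile()` and
  `squared_velocity_profile()` bin these by start distance (2-µm half-open
  bins by default; the squared-velocity profile uses the 30–60 min window
  and the 5-min recording cadence, matching how the simulation is
  calibrated). `mean_instantaneous_radial_velocity()` pools *non-overlapping*
  `lag`-frame windows — overlapping windows would overstate the effective
  sample size and miscalibrate its z-test, whose null is a zero-centered
  normal with the sample's standard error.
* **Centering kinetics.** `off_centering()` normalises distance-to-center
  by the cell radius (1 at the cortex, 0 at the center; "centered" means
  < 0.2, i.e. within 7 µm for the 35-µm oocyte). `centering_velocity()`
  fits $d(t) = a e^{bt}$ by nonlinear least squares (log-linear fallback)
  and reports $v = |ab|$, keeping the sign of $b$ for direction; $b$ is
  deliberately not constrained negative so outward drift fits honestly.
  In the object-size sweep (`size_sweep()`) the fit is restricted by
  default to the approach phase (up to 1.2× the first-passage centering
  time): experimental recordings end near centering, while long
  simulations append a plateau that would otherwise flatten $b$ and make
  the velocity depend on how long the run happened to continue after
  arrival.
* **Directional bias.** `classify_displacement()` labels displacements
  toward-center / toward-cortex / not-directional. The default convention
  uses three equal-measure bins on $\cos\theta$ (thresholds ±1/2), under
  which isotropic motion lands in each class with probability exactly 1/3.
  The historical ±30°/±60° angular bounds are available as
  `convention = "literal"`, but they are *not* equiprobable under isotropy
  (1/6, 2/3, 1/6 in the plane) — the package treats the equal-measure
  convention as the one consistent with a 1/3 null. `cumulative_bias()`
  pools classified displacement counts across tracks; `build_null()`
  generates the matched Brownian ensemble (1000 simulations by default);
  `bootstrap_ci()` draws N simulations without replacement 10,000 times and
  takes the 1% and 99% quantiles; `bias_test()` flags observed fractions
  outside that interval. A length-weighted bias and per-object averaging
  are provided as options since the verbal definition admits both readings.
* **Peclet numbers.** `peclet()` computes $P = Lv/D = \tau_D/\tau_A$ with
  $\tau_D = L^2/D$, $\tau_A = L/v$. For simulated objects the package's
  convention is $L$ = oocyte radius, $v$ = centering velocity from the
  exponential fit, and $D$ = the diffusion fit of the same object in a
  matched gradient-off run; these inputs are recorded with every result.

## The synthetic generators

`gen_brownian()`, `gen_biased_radial()`, `gen_persistent()` and
`gen_exponential_approach()` produce tracks with known structure: Gaussian
increments of variance $2D\Delta t$ per axis (with optional mirror
reflection at a spherical boundary), an added deterministic inward drift
that stops at the center, constant-speed runs with geometric redraws
(long-time $D_{eff} = v^2\tau/\text{dim}$), and noisy exponentials for the
centering fit. They are the fixtures for every estimator test and the
engine behind the Brownian null. They emulate the *statistics* of tracked
centroids, not the microscopy: no localisation noise, no missed detections,
no drift or registration error. Passing tests on these fixtures therefore
validates the estimators, not the upstream tracking.

## Problem sizes used by the tests and the acceptance script

The validation suite runs the real study conditions at desk scale, chosen
once: 10 prophase replicates of 1000–1500 min and 5 meiosis replicates of
2500 min for the centering-time ensembles; a six-diameter size sweep
(2–36 µm, two replicates each, 2000 min) for the $v = k d^2$ law; 400-min
gradient-off runs sampled every minute for the diffusion coefficients
behind the Peclet numbers; and reduced bootstrap/null sizes (hundreds of
simulations, ~10³ draws) for the coverage checks, against full-size
(1000 × 10,000) nulls in the user-facing defaults.

## Known limitations

* No hydrodynamic interactions, no explicit actin filaments, no adhesion,
  no deformable objects: collisions and confinement are the only couplings.
* No thermal noise on the passive object; its diffusion is purely
  collision-driven, which is the model's own prediction for large objects
  but underestimates the mobility of sub-micron ones.
* The small-$\tau$ regime near the center is resolved to within ~8% of the
  ideal decorrelation at the default `dt`; halve `dt` for studies that
  focus on the centered steady state.
* The size-sweep threshold ("objects below ~6 µm do not center") is a
  statement about 5000-min simulations; the reduced-duration sweeps used in
  the test suite can only assert the robust ends of that claim.
* At this calibration the centering velocity follows the surface law
  $v \propto d^2$ up to roughly 18–25 µm and then saturates: a 36-µm
  object spans half the cell, outside the local-pressure picture behind
  the $d^2$ scaling, so origin-forced fits of $k$ over the full 2–36 µm
  range come out below the mid-size slope.
* Peclet numbers for objects that never center are ratios of two
  near-zero quantities — a noise-floor fit velocity over a collision-only
  diffusivity — and should be read qualitatively (well below the
  advection-dominated regime), not as precise values.
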