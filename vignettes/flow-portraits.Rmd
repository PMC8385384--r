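---
title: "FLOW portraits: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FLOW portraits: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Widefield optical imaging records the whole cortical surface at once, and the
most striking feature of such movies is propagation: activity ignites
somewhere, spreads as a coherent front, and dies out somewhere else. Modal
decompositions (PCA, NNMF) factor the movie into static spatial modes and
lose exactly this travelling structure. `flowportrait` takes the opposite
view and treats the movie as a *flow*: frame-to-frame intensity motion
defines a time-varying velocity field, and the Lagrangian geometry of that
field — where virtual particles separate or accumulate — summarizes the
recording in a single diagram, the FLOW portrait. Forward-time ridges
(rendered orange) repel the flow and mark where activity originates;
backward-time ridges (purple) attract it and mark where activity terminates.

# The model and its stages

## Optical flow

Let $I(\mathbf{x}, t)$ be the $\Delta F/F$ movie. Horn–Schunck optical flow
solves, per frame pair, for the velocity field
$\mathbf{v} = (u, v)$ minimizing

$$\int \left( I_x u + I_y v + I_t \right)^2
  + \alpha^2 \left( \lVert \nabla u \rVert^2 + \lVert \nabla v \rVert^2 \right)
  \, d\mathbf{x},$$

via the classical Jacobi-style iteration on the original 2×2×2 gradient
stencil. Defaults are $\alpha = 1$ and 100 iterations (with an additional
mean-square-update stopping tolerance of $10^{-6}$, since only the iteration
cap is standard). Brightness constancy never holds exactly for fluorescence
data — activity appears and disappears rather than being transported — so two
denoising steps follow:

* **Activity scaling.** Each pixel's vectors are scaled by the absolute
  change of its raw intensity over a configurable look-back delay (1.5 s for
  slow developmental waves, 0.5 s for adult data), normalized by that pixel's
  maximum observed change, then averaged over a 0.25 s sliding window. The
  normalization is per pixel; a global-maximum variant sits behind
  `global_norm = TRUE`. A flow step between frames $k$ and $k+1$ is weighted
  by the change measured at the arrival frame $k+1$.
* **Temporal smoothing.** Each component is convolved in time with a
  five-point Gaussian window $w(k) \propto \exp(-\tfrac12 (\alpha_s k /
  \tfrac{L-1}{2})^2)$ with shape $\alpha_s = 1.25$; at the series ends the
  kernel is renormalized over the taps that exist.

## FTLE

The flow map $\Phi_{t_0}^{T}$ advects a particle from $\mathbf{x}(t_0)$
through $\mathbf{v}$ for $T$ frames. We integrate it with 4th-order
Runge–Kutta (2 substeps/frame by default), sampling velocities bilinearly in
space and linearly in time between the per-step samples; backward horizons
use a negative step, which is arithmetically identical to integrating the
time-reversed, negated series (the package's tests check this equality is
exact). Particles that reach the frame edge are clamped there — discarding
them would leave holes in the finite-difference stencil — and clamped pixels
are flagged, since clamping flattens stretching at the boundary.

The Jacobian $D\Phi$ is approximated by central differences over immediate
grid neighbours (one-sided at image borders), and the exponent is

$$\sigma(\mathbf{x}_0, t_0, T)
  = \frac{1}{\lvert T \rvert} \ln s_{\max}\!\left( D\Phi_{t_0}^{T} \right),$$

with $s_{\max}$ the maximum singular value. Two conventions circulate — the
largest eigenvalue of the Cauchy–Green tensor $C = (D\Phi)^\top D\Phi$ is the
*square* of $s_{\max}$ — and we adopt the singular-value reading because it
is the one for which the perturbation bound
$\lVert \Phi(\mathbf{x}_0 + \epsilon) - \Phi(\mathbf{x}_0) \rVert
\le e^{\sigma \lvert T \rvert} \lVert \epsilon \rVert$ is tight; the
eigenvalue convention (which simply doubles $\sigma$) is available via
`convention = "eigenvalue"`. Because the activity-derived field is
compressible, both local exponents can share a sign; only non-negative
exponents are kept (negatives are set to 0), matching the interpretation of
forward ridges as repelling and backward ridges as attracting structures.

Base times sweep the recording: forward fields at every $t_0$ with
$t_0 + T \le n_\text{steps}$, backward fields with $t_0 - T \ge 1$; bouts
shorter than the horizon are refused outright. The integration length is the
key user choice: longer $T$ low-pass filters the dynamics, shorter $T$ admits
faster waves. The practical heuristic is to sweep $T$ over a range and pick
the smallest value whose mean-FTLE ridges look sharp and well resolved;
we use 15 frames for the synthetic plane wave, 12 for the circular wave, and
40 frames (2 s at 20 Hz) as the pipeline default appropriate for slow
developmental waves.

## Ridge extraction

Mathematical ridge definitions (gradient/Hessian conditions) are brittle on
noisy FTLE fields of activity data, so the portrait uses a deliberately
simple morphological pipeline on the *mean* FTLE field of each direction:

1. threshold at a percentile of the ROI values (93 by default; the synthetic
   plane and circular waves use 91 and 93) with ties kept via $\ge$ and
   linear interpolation between order statistics;
2. close (3×3 dilation then erosion, repeated until stable) to bridge 1-px
   gaps;
3. thin to convergence (two-subiteration Guo–Hall), then skeletonize for 4
   passes (sequential border thinning preserving connectivity and
   endpoints);
4. diagonal-fill to convergence, one spur-removal pass, and a final close.

All "until stable" iterations are capped at 100 passes with a warning. One
deviation from the obvious until-stable default deserves a note: iterating
spur removal to convergence deletes *every open curve entirely* (each pass
removes both endpoints), which would erase precisely the line-like ridges the
portrait exists to show; a single pass removes 1-px spurs and stops, and the
iteration count is exposed for users who want more. The operators follow the
classical 3×3 lookup-table semantics; exact pixel-level agreement with any
particular legacy implementation is not promised, and the tests assert
topological and distance properties (connectivity preserved, skeleton within
1 px of a bar's midline, output inside the closing of the input) instead of
bit patterns.

# Preprocessing and events

$\Delta F/F$ uses a per-pixel moving-*minimum* baseline over a centred 40 s
window (truncated at the ends; the centred choice treats onsets and offsets
symmetrically), a baseline floor of $10^{-6} \cdot \max(\text{raw})$ against
division by zero, and an optional 1 px Gaussian blur against speckle. The ROI
mask excludes pixels whose temporal mean-to-variance ratio exceeds 400:1
(quiet pixels outside the tissue); excluded pixels carry `NA` through the
pipeline and are omitted from all statistics and percentiles. Pixel binning
averages $f \times f$ blocks and conserves the global mean when $f$ divides
both dimensions.

Pan-cortical waves are segmented from the active-fraction trace (a pixel is
active when it exceeds its own temporal mean by one standard deviation; the
threshold is computed on $\Delta F/F$): each upward crossing of 50% defines
an event extending to the surrounding 10% crossings, overlapping events
merge, and events shorter than the integration length plus the scaling delay
are dropped. Intervals are half-open `[start, end)` in 1-based frames. The
movement score is the max-normalized total absolute difference between
consecutive behaviour-video frames (backward difference by default; the
signed sum would cancel, and a forward-difference variant is available). The
ridge count score — components divided by ridge area — quantifies portrait
consolidation, and group comparisons use a two-sided paired t-test with
explicit handling of degenerate (zero-variance) differences.

# Synthetic data: what it does and does not show

The three generators emulate the archetypes of widefield activity: a plane
wave that ignites at a column, travels rightward and extinguishes where it
stops; a circular wave expanding from the centre to a maximal radius; and a
Gaussian blob that appears, grows, translates and shrinks in four equal
phases (the equal-quarters schedule is a free choice). Fronts are rendered
as smooth Gaussian-profile crests (width 2 px) because piecewise-constant
images give Horn–Schunck no gradients to track, and waves that visibly
*begin* and *end* hold their front position during brief ignition and
extinction phases while the amplitude ramps — without such phases the
forward/backward ridges smear along the whole trajectory instead of
concentrating at the initiation and termination sites. Defaults are 64×64 px,
64 frames at 20 Hz, speed 1 px/frame; noise is additive i.i.d. Gaussian per
pixel and frame, seeded for bit-identical reproduction.

Passing the ground-truth geometry checks on these movies shows that the
machinery recovers initiation/termination structure for *clean, single-wave,
fully observed* activity. It does not demonstrate robustness to haemodynamic
contamination, indicator kinetics, multiple interacting waves, or activity
entering from outside the field of view — none of which the generators
simulate.

The analytic benchmark fields validate the Lagrangian core independently of
optical flow: the linear saddle has closed-form FTLE equal to its rate
($D\Phi = \mathrm{diag}(e^{aT}, e^{-aT})$), rigid translations and the zero
field must give $\sigma = 0$, and the standard time-periodic double gyre
exercises genuinely unsteady transport with zero boundary-normal velocity.
The double-gyre defaults (65×129 grid, i.e. 1/64 domain spacing; amplitude
0.005 giving ~1 px/frame peak speeds, comparable to optical-flow magnitudes)
are chosen so the FTLE structures are resolved by the grid: on a coarser
grid a half-pixel perturbation of a particle seed probes the flow map beyond
its locally linear regime and the $e^{\sigma T}$ bound is only marginally
respected, which is a resolution artifact, not a property of the method.

# Numerical choices and edge cases

* RK4 with 2 substeps/frame; the package carries a 1000-substep Euler
  brute-force integrator used as an independent oracle in the tests
  (agreement to < 0.1 px on the double gyre over 20 frames).
* Percentiles: `stats::quantile` type 7 (linear interpolation); degenerate
  all-equal fields binarize to an empty mask with a warning.
* A velocity series with `NA` outside the ROI is integrated with those
  velocities treated as zero; FTLE values outside the ROI are reported `NA`.
* Traces that never re-cross the low threshold close their event at the
  recording end with a warning; zero-variance pixels are excluded from the
  ROI (ratio treated as infinite); empty ridge masks score 0 by convention.
* Test and example problem sizes (64×64 movies, 65×129 benchmark grids,
  horizons of 12–20 frames) are chosen so the full validation suite runs on
  a single CPU in a few minutes while still exercising every stage at the
  default parameters.

# Known limitations

The method inherits the assumptions of its fluid-dynamics ancestry:
neighbouring pixels must be neighbours on the cortical sheet, the indicator
must be faster than the activity flow of interest, and the frame rate high
enough that consecutive frames are similar — otherwise optical flow confuses
jumps with motion. FTLE ridges of a compressible activity field are
approximate accumulation lines, not material transport barriers, and the
approximation degrades over long integration windows. Boundary clamping
flattens stretching at the frame edge (flagged in the output), and the
morphological clean-up trades pixel-exact reproducibility across
implementations for robustness, which is the reason the package's guarantees
are stated as geometric properties rather than bit patterns.

# Reproducing the headline checks

```{r, eval = FALSE}
library(flowportrait)

# analytic saddle: interior FTLE equals the rate a = 0.05 within 1e-3
fl <- generate_analytic_field(analytic_field_spec("linear_saddle", 64, 64), 25)
f <- ftle_field(fl, t0 = 1, T_frames = 20, direction = "forward")
max(abs(f$sigma[24:41, 24:41] - 0.05))

# portrait of the synthetic plane wave
mv <- generate_movie(synthetic_movie_spec("plane_wave"))
flow <- temporal_smooth(compute_flow_series(mv$stack))
fwd <- ftle_series(flow, 15, "forward")
bwd <- ftle_series(flow, 15, "backward")
p <- compose_portrait(fwd, bwd, apply(mv$stack$data, c(1, 2), mean), 91)
render_portrait(p, "plane_wave_portrait.png")
```

The repository's `scripts/acceptance.R` recomputes every validation quantity
from scratch against the installed package and writes them as JSON.
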