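---
title: "Methods: temporal root phenotyping from label-mask sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal root phenotyping from label-mask sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizolapse)
```

rhizolapse analyses time-lapse plant phenotyping experiments whose raw
output is one multi-class segmentation mask per frame: integer grids where
0 is background, 1 the main root, 2 lateral roots, 3 the seed, 4 the
hypocotyl, and 5–6 leaves and petiole. The package assumes the segmentation
itself has already been produced (by a neural network or any other source);
everything downstream of the masks — temporal stabilization, root-system
architecture, screening kinetics, functional data analysis, interchange —
is implemented and tested here. A synthetic seedling renderer with exact
ground truth stands in for the camera-plus-network front end, so every
stage of the pipeline can be verified offline.

## Temporal consistency model

Segmentation masks of thin, slowly growing structures flicker: water
droplets and condensation appear for single frames, occlusions hide tissue
briefly. The root classes (1 and 2) are therefore stabilized with a
weighted trailing average of their binary masks,

$$a^t = s^t + \alpha\, a^{t-1}, \qquad a^1 = s^1,$$

where $s^t$ is the current binary segmentation of the class and $\alpha \in
[0,1)$ a memory weight. A pixel is considered present when $a^t \ge \tau$.
Two parameters matter:

* **α** (unitless). The weight is tied to wall-clock time through a
  one-hour half-life, $\alpha = 0.5^{\,dt/60}$ with $dt$ the frame interval
  in minutes, so a 15-min cadence gives $\alpha \approx 0.841$. This keeps
  the temporal memory of the filter invariant to the acquisition rate.
* **τ** (unitless, default 1). With $\tau = 1$ every currently observed
  pixel is kept (since $s^t = 1$ implies $a^t \ge 1$), pixels with
  sustained history survive dropouts of a few frames, and an isolated
  one-frame blob decays below threshold immediately after its frame.
  Because $a^t \le 1/(1-\alpha)$ for binary input, $\tau$ has a natural
  scale; values above 1 demand history as well as current evidence.

Only classes 1 and 2 are smoothed; all other classes pass through
bit-identically. The accumulator output is thresholded rather than
propagated as weights — the downstream graph machinery needs crisp masks,
and the alternative (soft evidence) is noted as out of scope.

## Root-system architecture

Within a user-supplied region of interest (one plant per ROI), the root
mask (classes 1 ∪ 2) is refined by a 3×3 morphological closing and reduced
to the single connected component associated with the user-marked origin —
the root start position, typically just below the seed. The mask is then
thinned to a 1-px skeleton (Zhang–Suen-style two-subiteration thinning,
idempotent on its own output).

**Reduced skeleton adjacency.** Raster skeletons contain staircase pixels
whose naive 8-neighbour count is 3 although they lie mid-path. All degree
computations and traversals therefore use a reduced adjacency: orthogonal
neighbours always count; a diagonal neighbour counts only when neither of
the two shared orthogonal pixels is set. This leaves connectivity intact
while making junction detection meaningful.

**Spur pruning.** Skeleton branches shorter than 5 px (≈0.2 mm at
0.04 mm/px) from a junction to a tip are removed iteratively, with a
re-thinning pass per round so that 1-px nubs left at junction zones
dissolve. Junction-free paths are never pruned, whatever their length.

**Graph construction.** Pixels whose reduced degree differs from 2 are
clustered into nodes (tips, junction zones) along with the origin pixel;
maximal junction-free chains become edges carrying their ordered pixel
path and geodesic length (1 per axial step, √2 per diagonal). A
depth-first traversal from the origin with the fixed neighbour order N,
NE, E, SE, S, SW, W, NW makes construction fully deterministic. Cycles are
allowed and recorded.

**Main/lateral classification.** The main root is the geodesic from the
origin to the tip of greatest geodesic depth (ties: lowest tip in the
image, then smallest column). In an acyclic graph this is exactly the
longest origin-to-tip path; when a lateral re-connects to the main axis
(a loop), the geodesic keeps the main path on the direct route instead of
detouring through the lateral, so the main-root length is insensitive to
loop formation. All non-main edges are grouped into laterals, connected
through non-main nodes only (two laterals sharing a junction stay
distinct); a component's base is its attachment with the smallest
main-path arc position, and extra attachments or internal cycles mark it
as a loop without creating new lateral bases.

**Sub-pixel measurement.** Three systematic raster biases are corrected,
each by a standard centreline/endpoint refinement:

1. *Zigzag inflation* — the pixel-path length of a smooth curve
   overestimates its arc length. Main-root length is measured on a
   window-5 moving average of the path coordinates (collinear stretches
   are unaffected).
2. *End erosion* — thinning eats roughly half the stroke width at each
   axis end. The measured length adds the gap from the marked origin to
   the first skeleton pixel and the extension of the root cap beyond the
   skeleton tip, both read off the refined mask (capped at 3 px).
3. *Branch-point drag* — thinning fills the acute wedge between a lateral
   and the main root, sliding the junction a few pixels down the main
   axis. The lateral base is re-estimated by back-projecting the
   lateral's initial direction (a chord over its smoothed path between
   5 and 24 px of arc) onto the main path.

**Angles.** With image coordinates (y increases downward, 0° = straight
down), the base–tip angle of a lateral is
$\theta_{bt} = \arccos\big((y_t-y_b)/\lVert t-b \rVert\big)\cdot 180/\pi$
from the (refined) base to the tip, and the emergence angle $\theta_e$ is
the same expression evaluated at the point reached at a fixed arc distance
$d$ (default 2 mm) along the smoothed path from the base. Laterals shorter
than $d$ defer the measurement (missing value) rather than reporting a
biased one. On synthetic plants these estimators recover the generator's
angles to well under a degree once laterals pass ~2.5 mm; the acceptance
checks run them at 2° ($\theta_{bt}$) and 3° ($\theta_e$).

**Identity over time.** Laterals are matched frame-to-frame by base
position along the main path (Hungarian assignment, gate 15 px of arc,
ties broken by tip displacement). A lateral that disappears briefly — a
droplet disrupting one frame — may re-attach to its dormant identity for
up to 8 frames (2 h) at the same base; identities are never reused. A
lateral is *validated* only if one contiguous presence run exceeds 6 h
(strict inequality; a run of $k$ frames spans $(k-1)\,dt$ minutes). All
counted traits use validated laterals only; raw per-frame series are kept
alongside.

**Traits.** Main-root, lateral and total lengths (mm), lateral count,
discrete density (10·count/MR-length, i.e. laterals per cm), main-over-
total ratio, growth speed (finite differences at interval midpoints),
daily convex-hull area/width/height/density/aspect, and the angle tables.
Length-like series pass through the monotone-growth constraint (running
maximum). Degenerate cases yield missing values, never zeros: density and
ratio are undefined at zero main-root length, hull density is undefined
for collinear point sets.

## Growth rhythms

Growth speeds are detrended by subtracting a centred running median and
the residual is Fourier-transformed (one-sided amplitude spectrum,
amplitude $2|X_k|/N$). Two practical rules matter, both established by
direct computation in the test suite:

* The filter window should span one full period of the slowest rhythm of
  interest — 24 h for circadian work — so the median of a full cycle
  (≈ the trend) is removed and the rhythm passes unattenuated. The
  12-h default window is kept for general trend removal, but it halves a
  circadian amplitude and is not used for spectra.
* The margins where the centred window is unsupported distort the
  residual; `detrend_series(..., trim_edges = TRUE)` drops half a window
  at each end before the transform.

The running median is nonlinear: its interaction with a background trend
grows with (slope × half-window / amplitude). The rhythm acceptance
conditions — baseline 0.35 mm/h, drift +0.036 mm/h over six days,
amplitudes 0.06 (24 h) and 0.03 (12 h) mm/h at 15-min sampling — keep that
ratio small; the recovered amplitudes land within ~3% and both planted
periods are the two dominant non-DC peaks. Stronger drifts degrade
amplitude fidelity gracefully (documented, not hidden: at ten times the
drift the error is ~12%).

## Multi-plant screening

Seeds are detected per frame as connected components of class 3 with area
inside a configurable gate; merged blobs (two touching seeds) exceed the
upper gate and are flagged rather than tracked. Identity across frames is
a SORT-style tracker: a constant-velocity Kalman filter per track (state
$x, y, v_x, v_y$; process noise 1 px, measurement noise 2 px; velocity
initialized from the first two assigned detections, which makes the
zero-noise filter an exact observer), Hungarian association under a 50-px
Euclidean gate, new tracks from unassigned detections, and loss after 8
consecutive misses (2 h at 15-min cadence). The Hungarian solver is the
$O(n^3)$ potential/augmenting-path formulation, cross-checked against
brute-force enumeration in the tests.

Quality control removes tracks whose plants touch (their pixels share an
8-connected component of classes 1–6 in any checked frame; both
participants are removed with the first-contact frame recorded) or whose
observed centroid jumps more than 40 px/frame. Removals never renumber
surviving tracks.

Germination is "time to radicle emergence", operationalized as the first
frame at which class-1 pixels inside the expanded seed box start a
presence run that passes the 6-h persistence rule (a run still open at the
end of the sequence is accepted provisionally). The cumulative percentage
curve is fitted with the 4-parameter Hill model

$$G(t) = G_0 + \frac{G_{\max}\, t^n}{t_{50}^n + t^n},$$

by Levenberg–Marquardt least squares (`minpack.lm`), initialized at
$G_0$ = first value, $G_{\max}$ = observed range, $n = 4$, $t_{50}$ = time
of the half-range crossing, with box bounds keeping every parameter in its
valid domain. The time of maximum germination rate has the closed form
$\mathrm{TMGR} = t_{50}\,((n-1)/(n+1))^{1/n}$, defined for $n > 1$ and
always below $t_{50}$; the tests verify it against the numeric argmax of
$dG/dt$. Degenerate all-zero curves are refused with a diagnostic.

Hypocotyl length is the longest geodesic path through the skeleton of the
track's own class-4 pixels — "own" meaning the connected component
attached to the seed, so a neighbour growing into the analysis window is
never measured. Raw increments exceeding a physiological gate (default
1 mm/h) are replaced by the previous value before the monotone constraint;
the raw series is always preserved alongside the cleaned one. Whole-plant
area, simple root length (longest class-1 skeleton path, no graph build)
and seed size at the first frame complete the screening traits.

## Functional PCA

Any collection of trait series sharing a time domain can be compared as
curves. Each curve is aligned to a common grid by linear interpolation and
projected by least squares onto a monomial basis $1, u, u^2, \dots$ of the
unit-rescaled time $u = (t - t_{\min})/(t_{\max} - t_{\min})$; degree 4
(five coefficients) is the default, enough for sigmoidal growth. Rescaling
conditions the Gram matrix (a 5×5 Hilbert matrix, comfortably within
double precision) and makes the decomposition invariant to affine time
reparameterization. With coefficient rows $c_i$, mean $\bar c$ and Gram
matrix $W$, the eigen-decomposition of
$W^{1/2}\,\mathrm{cov}(c)\,W^{1/2}$ yields component coefficient vectors
$\phi_k = W^{-1/2} u_k$ that are orthonormal under the domain inner
product, explained-variance ratios $\lambda_k / \sum \lambda$, and scores
$(c_i - \bar c)^\top W \phi_k$. Components are ranked by explained
variance; the default retained set is the smallest reaching 95%. Each
component's sign is fixed so its value at the domain end is non-negative.
Collections with numerically zero total variance are flagged degenerate
and return no components rather than noise.

Quantile reconstructions draw $\mu(t) + q_p(\text{scores})\,\phi_k(t)$ for
chosen quantiles $p$ — the standard visualization of how a mode bends the
trajectory. Group comparison applies the two-sided Mann–Whitney test to
each component's scores per group pair with Benjamini–Hochberg adjustment
across components. The Mann–Whitney statistic is enumerated exactly (all
$\binom{n_A+n_B}{n_A}$ labelings, ties half-counted) when both groups have
at most 8 observations, and uses the tie-corrected normal approximation
otherwise.

## The synthetic generator

`generate_sequence()` renders plants as polylines rasterized by Bresenham
stepping and dilated to organ-specific widths (main root 3 px, laterals
2 px, hypocotyl 3–4 px, seed a 5-px disk), on a persistent canvas so plant
pixel sets never shrink. Main roots grow straight down under a
user-supplied non-decreasing growth function; laterals emerge at scheduled
frames and positions, hold their emergence angle for a configurable arc
(default 2 mm) and then bend toward the vertical with an exponential angle
decay — the gravitropic behaviour that makes $\theta_e$ and $\theta_{bt}$
diverge. Label priority within a plant is main root > lateral > hypocotyl
> seed; pixels of an earlier-listed plant are never overwritten, and
collisions are logged (plants overlapping at the first frame are
rejected). Droplets are one-frame class-1 disks (radius 2–5 px) placed
overlapping a root; occlusions erase a 10×10 window for 1–2 frames. All
randomness flows from a single integer seed; identical configurations are
bit-identical.

Ground truth records, per plant and frame, the analytic main-root,
lateral and hypocotyl lengths, the emergence frame and the analytic
$\theta_{bt}$/$\theta_e$ of every lateral, organ pixel areas, and the seed
centroid. Truth lengths come from the growth functions themselves, so
rendered-versus-truth agreement (within ~2 px × scale) is a property the
tests verify, not an assumption.

The reference experiments bundled with the package define the study
conditions used throughout the tests: a standard-mode plate of ten
seedlings on a 600×600 px canvas at 0.04 mm/px and 15-min frames over six
days (577 frames), with plants already germinated at imaging start (initial
main roots 2.5–3.5 mm, elongation 0.04–0.05 mm/h, laterals emerging
between day 1.25 and day 2 at 30–48° with 0.028–0.034 mm/h growth —
edge-column plants grow laterals toward the canvas centre so nothing is
clipped); and a screening-mode plate of twenty seeds at 160-px row spacing
germinating on a Hill schedule ($t_{50}$ = 20 h, $n$ = 4, 10% dormant).
What the generator does **not** emulate: photorealistic infrared
appearance, segmentation-probability noise at organ boundaries, root
waviness and curling, crossing roots between neighbouring plants, plate
drift or registration error, and 3-D geometry. Passing the synthetic
checks therefore demonstrates the correctness of the measurement chain on
clean-topology inputs, not robustness to segmentation errors beyond the
transient-artifact classes modelled.

## Numerical choices and degenerate inputs

* Coordinates are (row, col), 1-based, row increasing downward; exported
  ROI/group CSVs use the external 0-based, half-open (x, y) convention.
* Pixel-path lengths use per-step Euclidean distances; gaps across
  junction clusters count their true distance.
* The assignment solver pads rectangular problems with a constant; gated
  (infinite) cells are replaced by a cost larger than any feasible total.
* `fit_fpca` rejects curves with fewer samples than basis coefficients,
  and flags zero-variance collections as degenerate.
* `skeleton_scores` with empty reference returns completeness `NA` with
  an `undefined` attribute rather than inventing a number.
* Empty ROI masks are flagged, not errors; an origin farther than 10 px
  from the skeleton is an error naming the distance.
* RSML output is deterministic (fixed number formatting), so
  write→read→write is byte-identical; `validate_rsml()` checks the
  structural contract (metadata with unit and resolution, scene, order-1
  top-level roots, non-empty numeric polylines, laterals nested inside
  their parent).

## Problem sizes used in the checks

The bundled verification runs use: the full 10-plant, 577-frame standard
experiment for end-to-end recovery; a 1-plant, 577-frame run with droplet
rate 0.05/frame for artifact rejection; 100 binomial replicates of 100
seeds for Hill robustness; 1,000 random cost matrices up to 6×6 against
brute force for the assignment solver; a 20-seed screen with 10% of
detections dropped for identity preservation; 6-day, 15-min planted
rhythm series; and 40-curve two-mode functional data. The acceptance
script scales the standard experiment to six plants; all other checks run
at the sizes above.

## Known limitations

* One plant per ROI in standard mode; crossing roots from neighbouring
  plants are resolved only by the component-selection rule.
* The main-path criterion assumes the main root is the deepest axis; in
  systems where a lateral outgrows the primary root the alternative
  criterion (minimal angular deviation from vertical) would be needed —
  the classification rule is isolated in `classify_axes()`.
* Amplitude fidelity of the rhythm pipeline degrades when the background
  trend is strong relative to the rhythm (see above); spectral *peak
  location* is much more robust than amplitude.
* The Hill fit reports the plateau `G0 + Gmax` clamped to the observed
  maximum; extrapolating final germination beyond the observation window
  is not attempted.
* FPCA assumes curves are sampled densely enough for the linear
  interpolation to the common grid to be benign; sparse irregular designs
  would need a different estimator.
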