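---
title: "Models and methods behind mukaxis"
author: "mukaxis authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mukaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mukaxis)
```

mukaxis studies how the E. coli SMC complex MukBEF organizes the chromosome
into a thin axial core. It combines a stochastic loop-extrusion simulator
with the quantitative analyses used on single-molecule tracking data and on
super-resolution images of the core, plus synthetic-data generators that make
every analysis testable against known ground truth. This vignette documents
the models, the parameters that matter, and the numerical choices, so that a
user can judge what the package computes and what its tests do and do not
demonstrate.

## The loop-extrusion model

The circular 4,641 kbp chromosome is discretized into `n_segments = 4641`
segments of 1 kbp. MukBEF functions as a dimer of dimers; each functional
complex occupies two DNA segments. The model is a continuous-time Markov
chain simulated exactly with the Gillespie direct method (compiled C++ core):

* **Binding** — a cytosolic complex binds two adjacent free segments,
  anywhere on the chromosome with equal probability. Propensity:
  `k_bind * n_eligible_adjacent_free_pairs * n_free`, with
  `k_bind = 3.9e-6 /s` per pair per free complex. A fresh complex starts
  with a loop spanning its two occupied segments (span = 2 segments).
* **Extrusion** — each dimer independently translocates away from the anchor
  one segment at a time at `k_move = 0.6` segments/s (600 bp/s, the in vitro
  condensin estimate), releasing its previous segment, which becomes free
  for further binding (loops within loops). A dimer whose next segment is
  occupied is stalled and carries zero propensity — head-on collided
  complexes block each other while their outer dimers continue.
* **Unbinding** — each bound complex dissociates at
  `k_unbind = 0.0154 /s` (65 s mean residency), releasing both segments and
  destroying the loop.
* **MatP displacement** — with `matp_active = TRUE`, binding to or moving
  into the *ter* interval dissociates the complex instantly and destroys the
  loop. Displaced binding events are never counted as bound time; they are
  tallied separately as displacements.

With wild-type copy numbers (110 dimers of dimers) these rates put about 48%
of MukBEF on the chromosome at steady state, and reading the state out at
`t_end = 500 s` (roughly eight residency times) gives a matured loop
structure. The expected loop size of an isolated, non-colliding complex has
the closed form `2 + 2 k_move / k_unbind` segments (bidirectional; about 80
kbp) or `2 + k_move / k_unbind` (unidirectional; about 40 kbp), because each
actively extruding dimer makes `k_move / k_unbind` steps on average before
dissociation; the simulator reproduces this to within sampling error
(`simulate_unbind_events()`), which is the package's primary engine
validation.

Choices made where the model statement leaves freedom:

* **Initial loop span of 2** (both occupied segments counted) — this is the
  convention under which the closed form above reproduces the 80/40 kbp
  no-collision expectations, and all loop-size statistics use it
  consistently.
* ***ter* interval** — the exact simulated boundaries are not fixed by the
  biology beyond "the MatP-occupied region"; the default is an 800 kbp arc
  centered on the *ter3* coordinate (1644 kb), segments `[1244, 2044)`, and
  it is configurable.
* **Unidirectional mode** — one dimer is anchored; the moving side is chosen
  uniformly at random at binding. A hypothetical variant with two fully
  independent, unconnected dimers is sometimes mentioned for asymmetric
  extrusion, but without a connection between the dimers there is no defined
  loop to account for, so that variant is not implemented.
* **Stalled dimers carry zero propensity** rather than firing null events;
  the two schemes are statistically identical and this one is cheaper.

### The increased-occupancy (IO) condition

The IO condition corresponds to a 6.3-fold overexpression in which 25.4% of
molecules are chromosome-bound, i.e. about `110 * 6.3 * 0.254 ~ 176` bound
complexes — a 3.3-fold increase over the wild-type ~53. Binding kinetics in
the model are linear, so simply multiplying the total copy number by 6.3
would put roughly twice too many complexes on the chromosome; the
experimental saturation that limits binding at high expression is not part
of the model. The simulated IO ensembles are therefore defined by the
*bound* count: `calibrate_copy_number(176)` finds the total copy number
whose steady-state bound mean matches the target (about 385–390 with the
default rates) using a short seeded pilot ensemble and a secant step. This
matching-by-bound-numbers is also how the loop statistics are parameterized
in `occupancy_sweep()` (statistics as a function of chromosome-bound
complexes).

## Loop-state analytics

* `looped_fraction()` — size of the union of loop spans over the chromosome;
  nested loops count once.
* `loop_sizes()` — one span per complex, nested loops reported
  independently, in kbp.
* `find_clusters()` — a cluster is a set of complexes with no unlooped DNA
  between them. Operationally two complexes join when (a) their occupied
  segments are adjacent on the ring (a collision), or (b) neither is nested
  inside the other and their footprints lie in the same maximal run of
  loop-covered segments. A nested complex joins the enclosing loop's cluster
  only through rule (a): it must have extruded far enough to collide with
  the stem from at least one side. DNA content of a cluster is the union of
  member spans. Ties for the largest cluster break towards the lowest
  member id.
* `locus_distance()` — shortest path on the segment graph in which
  consecutive segments are 1 kbp apart and each bound complex adds a
  zero-weight shortcut between its two dimer segments (a loop collapses to
  a point when traversed through its stem; the weight is configurable).
  Distances are measured to the nearest occupied segment of the largest
  cluster. `distance_profile()` averages this over replicas on a locus grid
  with a seeded percentile bootstrap (1,000 resamples) for the 95% CI.
* `random_link_chromosome()` — the null model with uniformly random
  connections (52 at wild-type occupancy), and `chromosome_layout()` — a
  seeded Fruchterman–Reingold embedding of the segment graph; visualization
  only.

## Single-molecule tracking

Localizations (frame, position, elliptical fit widths) are linked into
tracks when they fall within a 0.48 um window in consecutive frames; a
single missing frame is tolerated in fast mode (blinking), none in
long-exposure residency mode. When several localizations compete, links are
chosen to maximize the number of links and then minimize the summed step
distance; conflicts are solved exactly by enumeration within connected
conflict components (a greedy fallback handles components larger than nine
tracks, which essentially never occur at single-molecule densities).

The apparent diffusion coefficient of a track is
`D* = 1/(4 n dt) * sum of squared one-frame displacements`; tracks with
fewer than 4 steps are omitted. Molecules with `D*` below a threshold are
classified bound. The threshold convention is the lower 5% quantile of `D*`
in a reference strain that cannot bind the chromosome; the packaged constant
0.0875 um^2/s is that quantile for the original MukBEF reference data. By
construction this convention accepts ~5% of free molecules as false bound
classifications, which is visible as a small (+0.02) systematic in the
synthetic recovery tests.

Residency analysis works on immobile tracks from 1 s exposure movies: the
spot-width filter keeps localizations with short-axis width < 160 nm and
long-axis width < 200 nm (strict), gap-free linking measures durations
(frames times frame time, no partial-frame correction), and the survival
curve (1 − CDF) is fitted by `A1 exp(-t/tau_fast) + A2 exp(-t/tau_slow)`
with weights `1/y`, multi-start initialization over a grid of time-constant
pairs. The slow component is the specific-binding time. With effectively
single-exponential input the two components degenerate (equal taus or a
vanishing amplitude); `tau_dominant` (the component carrying most of the
integrated survival mass `A*tau`) is the robust summary in that case and is
what `measure_bleach_time()` reports for fixed-sample movies. Tracks
starting in the final 10% of the movie are excluded: their durations are
right-censored by the observation window, and excluding *late-starting*
tracks (rather than tracks that happen to reach the last frame) removes the
censoring without survivor bias.

Bleaching competes with unbinding, so the measured time constant
underestimates the true one; the correction is
`t_bound = t_measured * t_bleach / (t_bleach - t_measured)`, with a pole
when the measured time reaches the bleaching time. The effective
`t_bleach` should be measured under identical imaging conditions from a
fixed (immobilized) sample — it then absorbs bleaching, blinking and
detection losses together, which is exactly what the correction needs.
`mature_fraction()` gives the fluorescently visible fraction of a fusion
protein at expression equilibrium, `1/(1 + maturation_halftime /
generation_time)` (0.91 for mYPet at a 116 min generation time).

## Morphometrics of axial cores

Images (40 nm pixels) are segmented with Otsu's threshold. The centerline is
obtained by Zhang–Suen thinning — implemented in C++ because no installed
package provides binary thinning — followed by removal of length-1 branches
(endpoint pixels hanging off a branch point). The skeleton's pixel graph
connects 8-neighbours, with diagonal edges that merely shortcut two cardinal
steps removed so thin curves become simple paths or cycles. Topology is
circular when the graph's 2-core covers at least 80% of the pixels.

Length is the polyline length of the traced centerline after a 3-pixel
moving-average smoothing (which removes the staircase bias of digitized
curves while keeping the shrinkage of small circles well inside the tested
5% accuracy band). For linear
structures, thinning erodes the rounded end caps inward by about one
half-width; the measurement walks from each skeleton end along the local
tangent to the mask boundary and adds the walked distance minus the measured
mask half-width, which is unbiased for blunt-capped filaments. For circular
structures the traced-cycle polygon is used; the convex hull would be the
minimal polygon for convex rings but underestimates non-convex ones, so the
traced cycle is the default.

Thickness is measured per interior centerline pixel (excluding 2 pixels at
ends and around branch points): the "linegraph" across the structure is the
scatter of raw pixel values against their signed perpendicular distance to
the local centerline direction — raw values, because an interpolated profile
is convolved with the interpolation kernel and reads systematically too
wide. The
orientation is searched within +/- 30 degrees of the local normal in 5
degree steps for the direction minimizing a second-moment width proxy, and a
1-D Gaussian (with offset) is fitted by Nelder–Mead (derivative-free: exact,
noise-free profiles give singular gradients in Gauss–Newton fitting).
`FWHM = 2.355 sigma`. Near and below the ~120 nm resolution of structured
illumination microscopy the measured width of a real image saturates at the
point-spread function; the synthetic renderer draws the cross-section
directly (no optics model), so synthetic recovery tests validate the
estimator, not the microscope.

`compaction_ratio()` uses a DNA rise of 0.34 nm/bp (4.64 Mbp of chromosome
is 1.58 mm of contour), and `occupancy_report()` collects the derived
arithmetic: bound counts (~53 wild type, ~176 at increased occupancy), the
3.3-fold occupancy change, and ~6 nm of axial core per bound complex.

## Synthetic data generators

`simulate_tracks()` emulates a tracking experiment: molecules are assigned
bound (fraction `f_bound`) or free, activated at uniformly random frames,
and disappear at bleaching, unbinding, or the movie end. Free molecules
diffuse (default `D_free = 0.5 um^2/s`). Bound molecules are tethered: an
Ornstein–Uhlenbeck process with short-time diffusion `D_bound = 0.01
um^2/s` inside a 100 nm confinement radius, which reproduces free-like
steps at 15 ms exposures while keeping long-exposure positions confined as
chromosomal loci are. Tethered trajectories are sampled at 10 sub-steps per
frame and averaged, because the camera integrates over the exposure: the
recorded localization of a confined molecule is its motion-blurred centroid,
whose frame-to-frame jitter is far smaller than an instantaneous
OU step at 1 s exposures. Binding durations mix specific (65 s) and non-specific
(3 s) events. Localization error is 25 nm per axis; widths are
diffraction-limited for immobile molecules and blurred for mobile ones, so
the residency-mode width filter separates them. Blinking is a per-frame
missed detection: 0.02 in fast mode, 0.005 in residency mode (1 s exposures
integrate over sub-millisecond dark states). Two mode presets set frame
time, effective fluorophore on-time (0.3 s under high-power fast imaging;
48.8 s bleaching in low-power residency mode), movie length and sample
size. `fixed = TRUE` immobilizes everything with infinite residency — the
fixed-cell control used to calibrate the effective bleaching constant.

What the generator does **not** emulate: cell boundaries (free molecules are
unconfined), raw-image spot detection and its failure modes, non-Gaussian
localization errors, and z. Passing recovery tests therefore demonstrates
the correctness of the analysis chain on data satisfying its model
assumptions, not robustness to every artifact of real movies.

`render_filament()` draws a line or circle of exact centerline length with a
Gaussian cross-section (`sigma_nm = 56` by default, FWHM 132 nm) sampled at
pixel centers, plus background and Gaussian or Poisson noise.
`toy_loop_state()` builds hand-specified loop states for exhaustive
analytics testing.

## Problem sizes, tolerances, determinism

All randomness flows from explicit seeds; replica `i` of an ensemble uses
`base_seed + i - 1`, so any subset reproduces in isolation. The packaged
analyses use 200 replicas for ensemble means (sampling error of the mean
loop size ~0.5 kbp, well inside the 10% bands of interest) and 500 replicas
for distribution-shape comparisons and distance profiles; profile extrema
are located after a +/-250 kb circular moving average because the profile is
flat near its minimum and the raw argmin wanders by a few hundred kb between
ensembles. Synthetic tracking recoveries use movies of 3,000–96,000
molecules: the survival-curve fit with `1/y` weights is noticeably less
efficient than a likelihood fit on raw durations (which the tests use only
as a cross-check), and the bleach correction amplifies its relative error
by a factor `t_bleach / (t_bleach - t_measured)` (about 2.7 at the default
rates), so tight recovery of the 65 s residency requires tens of thousands
of immobile tracks. The double-exponential fit uses 12 multi-start
initializations; the Gaussian profile fit runs Nelder–Mead to `reltol
1e-12`.

## Known limitations

* The binding model is linear in free copies; expression-dependent
  saturation is outside the model, hence the bound-count-matched definition
  of the IO ensemble.
* Cluster detection and loop statistics operate on the 1-D segment state;
  no 3-D polymer mechanics, excluded volume, or contact-map prediction.
* The curve-based survival fit is the field's convention but statistically
  inefficient; uncertainty on bleach-corrected residency times is dominated
  by it.
* Length measurement assumes blunt-capped filaments for the end correction;
  sharply pointed structures would be slightly overextended.
* The thickness estimator reports the imaged width; deconvolution of the
  microscope's point-spread function is out of scope.
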