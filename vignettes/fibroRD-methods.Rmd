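---
title: "fibroRD: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fibroRD: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fibroRD implements an image-based workflow for locating re-entrant
drivers (RDs) of atrial fibrillation relative to atrial fibrosis: a
monodomain Fenton-Karma simulation on a voxelized left-atrium-like
domain whose conduction is slowed where an LGE-like image is bright,
phase-singularity tip tracking, probability-map-derived target areas
(TAs), and virtual catheter ablation with quantitative outcome
classification. This vignette records the science and every design
choice a maintainer would want to revisit.

## The electrophysiological model

Tissue is the monodomain reaction-diffusion equation with a scalar,
isotropic diffusion coefficient $D$ (mm$^2$/ms),

$$\partial_t u = \nabla \cdot (D \nabla u) - (J_{fi} + J_{so} + J_{si}),$$

on a regular voxel grid, integrated with explicit Euler in time and a
7-point central-difference Laplacian in space. The membrane model is the
three-current Fenton-Karma formulation in normalized voltage ($u = 0$
rest, $u \approx 1$ peak) with Heaviside gating on the activation
threshold $u_c$: a fast inward (depolarizing) current gated by $v$, a
slow outward (repolarizing) current, and a slow inward (plateau) current
gated by $w$ through a steep sigmoid around $u_{c,si}$.

Two numerical details differ from a textbook transcription:

* **Saturated slow-inward activation.** The plateau activation
  $(1+\tanh(k(u-u_{c,si})))/2$ is evaluated as a logistic with exact
  0/1 tails beyond $|k(u-u_{c,si})| = 6$. The truncation error is below
  $10^{-5}$ in the gate (invisible against discretization error), and it
  makes the rest state an exact fixed point of the reaction terms, so
  quiescent tissue stays at rest to machine precision — a property the
  test suite asserts directly.
* **Heterogeneous-D face flux.** The flux across a voxel face uses the
  arithmetic mean of the two adjacent diffusion coefficients (a
  harmonic-mean option is available). Faces leaving the wall, and faces
  into a zero-$D$ (lesion) voxel, carry zero flux; that is the whole
  no-flux boundary treatment, and it conserves the spatial mean of $u$
  exactly in diffusion-only runs.

Stability requires $\max(D)\,\Delta t/\Delta x^2 \le 1/6$ in 3-D; the
solver refuses to run otherwise. The study resolution is
$\Delta x = 0.3$ mm, $\Delta t = 0.005$ ms; coarser desk-scale runs use
$\Delta x = 0.6$ mm with $\Delta t$ = 0.02–0.05 ms, which is both
CFL-safe and reaction-stable for the shipped parameters.

## Cell parameters and calibration

The published workflow this package operationalizes used an
AF-remodelled atrial Fenton-Karma variant whose numeric parameters are
not printed; the only printed electrophysiological constraints are a
conduction velocity (CV) of 0.6 m/s at $D = 0.1$ mm$^2$/ms and capture
at a basic cycle length (BCL) of 130 ms. The package therefore ships
one named set, `afkParams("af1")`, tuned against those constraints:

* single-cell APD90 of 110.5 ms (reference trajectory at
  $\Delta t = 0.001$ ms, frozen as a test oracle);
* 1:1 capture over 8 stimuli at BCL 130 ms;
* stable, non-breaking spiral waves on 2-D sheets (rotor cycle length
  near 75 ms — AF-like rapid re-entry);
* `tau_d = 0.1583`, the value `calibrateCV()` converges to for a planar
  CV of 0.6 m/s on the reference strip (30 × 3 × 0.9 mm, $D = 0.1$,
  $\Delta x = 0.3$ mm). The default is thus pre-calibrated;
  `calibrateCV()` re-verifies (bisection on `tau_d` in [0.05, 2] ms,
  CV monotone decreasing in `tau_d`) and is run before any quantitative
  measurement.

At the dense-fibrosis coefficient $D = 0.017$ mm$^2$/ms the same cell
still conducts at about 0.20 m/s on the study lattice, inside the
0.1–0.6 m/s range expected for fibrotic atrial tissue.

## Fibrosis mapping

The image intensity ratio (IIR) is voxel intensity over the mean
blood-pool intensity. Voxels are labelled healthy (IIR < 1.08), border
zone (BZ), or dense fibrosis (IIR ≥ 1.24); because the literature uses
strict and non-strict inequalities inconsistently at the two cutoffs,
the package adopts the convention that matches the operational
diffusion assignment: dense iff IIR ≥ 1.24, healthy iff IIR < 1.08,
border zone in between (so the exact lower-threshold value is border
zone). $D$ is 0.1 mm$^2$/ms for healthy tissue, 0.017 for dense
fibrosis (an 83% reduction), and linearly interpolated in IIR across
the BZ, clamped to [0.017, 0.1]. The thresholds are stored constants;
their derivations (1.08 as the average of proposed values 1.2 and 0.97,
printed to two decimals; 1.24 as the dense-scar threshold 1.32 reduced
6% for post-ablation imaging) are documented in `deriveUpperIIR()` but
not recomputed at run time.

Labels are projected transmurally: every wall voxel inherits the label
of its nearest endocardial-surface voxel via a multi-source
breadth-first wave over the wall graph. Within a wave, face neighbours
claim voxels before edge/corner neighbours, so columns project straight
through the wall rather than drifting diagonally. Patch statistics use
26-connected components (face-only connectivity fragments thin
transmural patches), and all volumes are percentages of wall volume;
the PV and wall fractions of fibrosis are forced to partition 100%.
Utah staging is the standard four-stage rule with half-open intervals
at 5, 20 and 35%.

## Synthetic data

Patient imaging is replaced by a generator with two fixtures:

* `makeLAShell()`: an ellipsoidal endocardial chamber (default inner
  semi-axes 30 × 25 × 20 mm) dilated outward by the 3 mm average AF
  atrial wall thickness, with four pulmonary-vein (PV) openings and one
  mitral (MV) opening carved as cylinders along fixed anatomical
  directions. PV regions are 3 mm bands around each opening rim.
  Thickness is 3 mm along the semi-axes and within about ±10%
  elsewhere (offset ellipsoids are not exactly parallel surfaces);
  the tests measure it by ray-marching.
* `makeSheet()` / `makeStrip()`: 2-D sheets with prescribed circular
  IIR patches, and uniform strips for CV work.

The LGE-like intensity is blood-pool mean times
`baseline + offset + amplitude · G + w_pv · B`, where `G` is a
unit-variance Gaussian random field made by Gaussian-kernel smoothing
of white noise (kernel sd = correlation length / 2, so the
autocorrelation reaches 1/e at the stated length, 8 mm by default —
the scale of dominant fibrotic patches) and `B` is a sum of Gaussian
bumps at the PV rims for PV-dominant patterns. `tuneFB()` bisects the
offset until the fraction of wall voxels at or above the lower IIR
threshold hits a target burden; because the field is deterministic
given the seed and the offset enters affinely, the bisection runs on a
cached field. Everything is bit-reproducible from (spec, seed).

What the generator does **not** emulate: anatomical LA shape detail
(appendage, vein antra geometry), MRI partial-volume and bias-field
artifacts, non-transmural (endomysial) fibrosis, and fibre anisotropy.
Passing tests therefore demonstrate the pipeline's internal
correctness and the qualitative fibrosis–RD interactions, not clinical
per-patient numbers.

## Initiation protocols

Both study protocols are implemented: cross-field S1/S2 (default; an
S1 plane wave followed by a half-space S2 in the refractory tail) and
ectopic pacing (7 beats at BCL 130 ms near a PV, then a plane wave
20 ms after the last beat). For the shipped cell set the measured
vulnerable window on sheets is roughly 125–155 ms after S1, i.e.
centred near 1.25 × the single-cell APD90 — later than naive APD
reasoning suggests because electrotonic coupling prolongs tissue APD —
so the default S2 delay is `1.25 * APD90`. Initiation sites are spread
by farthest-point sampling (deterministic given a seed). An S2 outside
the window simply produces no RD; the tracker reports that, it is not
an error.

## Tip tracking and target areas

Tips are phase singularities of the time-delay-embedded phase
$\theta = \mathrm{atan2}(u(t-\tau) - u^*,\; u(t) - u^*)$ with
$\tau = 10$ ms and $u^* = 0.5$: a tip sits where the plaquette line
integral of $\nabla\theta$ is $\pm 2\pi$. 3-D walls are processed
layer-wise and same-chirality detections within 3 mm (the wall
thickness) merge into a filament whose centroid is reported. An
isoline-intersection detector ($u = u^*$ crossed by $du/dt = 0$) ships
as an independent cross-check. Tracking associates tips across frames
(≤ 5 ms apart) by Hungarian assignment gated at 5 mm and chirality;
trajectories survive detection drop-outs up to 30 ms (the gate grows
with the gap), and anything shorter than 50 ms is discarded as noise.

One detector limitation matters for ablation analysis: a rotor pinned
*around* an unexcitable obstacle (anatomical re-entry) has its
singularity inside the hole and is invisible to plaquette winding. The
outcome classifier therefore also checks residual activity: sustained
activation without any free-wall singularity is classified as
obstacle-anchored re-entry (AT), and "terminated" additionally requires
end-of-run quiescence.

Per-run visit counts accumulate into a tip-frequency map; runs whose
persistent RD stabilized at a PV opening are excluded (vein clipping
makes PV anchoring non-physiological; exclusion is run-level by
default, voxel-level as a sensitivity mode). The combined map is
normalized by its maximum, thresholded at 0.2 (the printed default;
a mean + 2 SD mode ships as the standardized alternative that motivates
that value), and 26-connected components become TAs. Desk-scale runs
are short, so transit voxels are visited only a handful of times;
`extractTAs()` therefore offers a sub-patch-scale Gaussian smooth
(default 1.2 mm in the pipeline) and a minimum component size (4
voxels) to suppress speckle. Both default to off in the bare function.

Final RD location is a majority vote over the last second of the
recording (PV region > fibrotic voxel > healthy, with that precedence
on ties); a trajectory that dies before the window is "extinguished".

## Virtual ablation

Lesions are transmural, 3 mm-wide, zero-conductance and clamped at rest
("perfect lesions"). Five strategies: (1) circumferential PV rings
(bands at ring radius `pv_radius + 2` to `+5` mm around each opening —
each vein is individually encircled, which the closure test verifies by
flood fill); (2) plus a geodesic roof line joining the left and right
rings and a line to the MV; (3) 3 mm cylinders tiling each TA; (4) plus
a geodesic connector from each TA centroid to the nearest PV/MV rim
(shortest path over the wall voxel graph, then dilated); (5) = 4 + 1.
Construction is additive, so masks nest (3 ⊂ 4 ⊂ 5). Lesions apply
instantaneously to a running state.

Mean frequency (MF) is the wall average of per-voxel dominant
frequency: spectral peak of mean-removed $u(t)$ over the last 1 s
(rectangular window), with voxels below a 0.05 peak-to-peak amplitude
floor excluded; the window must cover two periods of 3 Hz. The AT
anchoring radius (5 mm, half the lesion-ring width) and the amplitude
floor are package choices recorded in the function signatures.

## Problem sizes and study conditions

The package's own test and acceptance conditions, chosen once:

* CV measurements: 30 × 3 × 0.9 mm strip at the study resolution.
* Sheet dynamics: 60–80 mm sheets at $\Delta x = 0.6$ mm,
  $\Delta t = 0.05$ ms. The rotor-anchoring demonstration uses an
  80 mm sheet because on 60 mm sheets boundary interactions alone
  drag the control rotor ~8 mm per 6 s; at 80 mm the control drifts
  under 3 mm, cleanly separating patch-driven drift.
* Synthetic atria: fibrosis burdens set to the study's printed values
  (0.39, 0.29, 0.11 as targets), correlation length 8 mm,
  $\Delta x = 0.6$ mm. The full-atrium re-inducibility comparison uses
  the default-size shell with 3 mapping sites and 2 paired
  re-induction sites at 2 s per run — the smallest configuration in which AF reliably sustains;
  smaller chambers self-terminate or sustain purely functional
  re-entry that no lesion set can address, which distorts
  strategy comparisons.

## Known limitations

* Isotropic conduction only; no fibre architecture, no
  electrophysiological heterogeneity, no bidomain effects.
* Only fully transmural fibrosis; thin-wall assumption underlies the
  layer-wise filament treatment.
* The rotor cycle length (~75 ms) is faster than clinically typical AF;
  relative comparisons (MF drops, strategy orderings) are meaningful,
  absolute frequencies are model-specific.
* Lesions are simultaneous and perfect; no gaps or reconnection.
* The ellipsoidal shell is a phantom: per-patient percentages from the
  imaging study are out of reach by construction, and only directional
  properties (where RDs stabilize, how strategies rank) are asserted.
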