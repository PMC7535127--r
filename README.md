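# fibroRD

Image-based computational mapping of re-entrant drivers (RDs) of atrial
fibrillation (AF) relative to atrial fibrosis, for cardiac
electrophysiology modellers. Persistent AF is widely thought to be
sustained by rotors whose tips anchor at or near slow-conducting
fibrotic tissue; where they anchor is patient-specific and is exactly
what catheter ablation would like to target. fibroRD implements the
full in-silico workflow:

1. **Substrate** — a voxelized left-atrium-like shell (or 2-D sheet)
   whose per-voxel diffusion coefficient is derived from an LGE-MRI-like
   intensity volume through the image intensity ratio (IIR):
   healthy for IIR < 1.08 (D = 0.1 mm²/ms, conduction velocity 0.6 m/s),
   dense fibrosis for IIR ≥ 1.24 (D = 0.017 mm²/ms, an 83% reduction),
   and a linearly interpolated border zone in between; fibrosis is fully
   transmural and the burden maps onto the Utah I–IV staging.
2. **Electrophysiology** — the monodomain equation
   ∂ₜu = ∇·(D∇u) − (J_fi + J_so + J_si) with a three-current
   Fenton–Karma atrial cell model (normalized voltage, Heaviside
   gating), explicit Euler / 7-point finite differences, CV-calibrated
   by bisection on the fast-inward time constant.
3. **RD mapping** — cross-field or ectopic-pacing initiation from many
   sites, phase-singularity tip tracking
   (θ = atan2(u(t−τ)−u*, u(t)−u*), plaquette winding ±2π), per-voxel
   tip-visit maps combined into a normalized RD probability map, and
   target areas (TAs) as the 26-connected components above the 0.2
   cutoff.
4. **Virtual ablation** — five lesion strategies (PV isolation, PVI +
   lines, TA cylinders, TA + connectors to the nearest PV/MV, all
   combined), applied as transmural unexcitable tissue to a running
   simulation, with outcomes classified as terminated / atrial
   tachycardia (AT) / unaffected and quantified by dominant-frequency
   (MF) analysis and re-inducibility testing.

Patient imaging is replaced by a first-class synthetic-data module:
LA-like shells with four pulmonary-vein and one mitral opening, and
Gaussian-random-field LGE-like volumes tuned to a prescribed fibrosis
burden — everything is testable end to end without clinical data.

## Worked example

```r
library(fibroRD)

## calibrate the cell model to the atrial conduction velocity
params <- calibrateCV(0.6)
#> calibrated tau_d = 0.1583 ms, CV = 0.596 m/s

## synthetic atrium at a 29% fibrosis burden (Utah 3)
geom   <- makeLAShell(laGeometrySpec(semi_axes = c(22, 18, 15)))
spec   <- tuneFB(geom, syntheticLGESpec(seed = 7), target_fb = 0.29)
vol    <- makeSyntheticLGE(geom, spec)
atrium <- applyFibrosis(geom, vol$intensity, vol$bloodPool)
patchStats(tissueLabels(atrium), atrium)
#>   fb_percent largest_patch_percent pv_fraction_percent wall_fraction_percent
#> 1   28.77757              8.295331            18.61991              81.38009
#>   dense_percent n_patches utah_score
#> 1      2.154234         5          3

## induce a re-entrant driver and see where it stabilizes
plan  <- enumerateSites(atrium, 3, seed = 11)[[1]]
rec   <- runPlan(atrium, plan, params, duration = 2000, dt = 0.05)
trajs <- trackTips(rec)
classifyFinalLocation(trajs[[1]], atrium, end = max(snapshotTimes(rec)))
#> TipTrajectory 'site01': 371 samples, t = [150, 2000] ms, final region: fibrosis

## target areas from the normalized tip-probability map
pmap <- combineMaps(list(buildTipFrequencyMap(trajs, atrium)))
tas  <- extractTAs(pmap, threshold = 0.2, tissue = atrium,
                   smooth_mm = 1.2, min_voxels = 4)
tas
#> TargetAreaSet: 1 TA(s) at threshold 0.2 (fixed mode)
taStats(tas)[, c("volume_mm3", "percent_wall", "bz_pct", "dense_pct")]
#>   volume_mm3 percent_wall   bz_pct dense_pct
#> 1     75.168     0.592159 87.37864  12.62136
```

The RD initiated at a site far from the main patch drifts and
stabilizes on fibrotic tissue; the resulting TA covers 0.6% of the wall
(versus a 29% fibrosis burden) and lies almost entirely on border-zone
and dense voxels — small, fibrosis-collocated ablation targets, which
is the point of the workflow. `runPipeline(pipelineConfig(...))` chains
all stages (including virtual ablation) and writes NIfTI/CSV/JSON
outputs; `inst/scripts/fibrord.R` wraps it for the shell.

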