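## Shared fixtures, built once per session and memoized (several are
## expensive simulations reused across test files).

.fx <- new.env(parent = emptyenv())

memoFixture <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

## Calibrated default cell parameters.
fxParams <- function() afkParams()

## 60 x 60 mm uniform sheet with a 2 s cross-field AF run (single RD).
fxSheetRun <- function() memoFixture("sheetRun", function() {
  tis <- makeSheet(60, 60, dx = 0.6)
  plan <- initiationPlan("cross_field", site = c(30, 30, 0.3),
                         s1_direction = c(1, 0, 0),
                         s2_direction = c(0, 1, 0), s2_delay = 135)
  rec <- runPlan(tis, plan, fxParams(), duration = 2000, dt = 0.05)
  list(tissue = tis, plan = plan, rec = rec, trajs = trackTips(rec))
})

## 80 x 80 mm uniform sheet, 6 s control run (stationary RD after the
## formation transient).
fxBigSheetControl <- function() memoFixture("bigSheetControl", function() {
  tis <- makeSheet(80, 80, dx = 0.6)
  plan <- initiationPlan("cross_field", site = c(40, 40, 0.3),
                         s1_direction = c(1, 0, 0),
                         s2_direction = c(0, 1, 0), s2_delay = 135)
  rec <- runPlan(tis, plan, fxParams(), duration = 6000, dt = 0.05)
  list(tissue = tis, plan = plan, rec = rec, trajs = trackTips(rec))
})

## Synthetic Utah-3 atrium: default-size LA shell, burden tuned to 29%,
## with the RD-probability map and TAs from 3 cross-field runs.
fxUtah3 <- function() memoFixture("utah3", function() {
  g <- makeLAShell(laGeometrySpec())
  spec <- tuneFB(g, syntheticLGESpec(seed = 7), 0.29)
  v <- makeSyntheticLGE(g, spec)
  tis <- applyFibrosis(g, v$intensity, v$bloodPool)
  plans <- enumerateSites(tis, 3, seed = 11)
  fmaps <- list(); regions <- character(0)
  for (i in seq_along(plans)) {
    rec <- runPlan(tis, plans[[i]], fxParams(), duration = 2000, dt = 0.05,
                   recordInterval = 5)
    trs <- trackTips(rec)
    endT <- max(rec@times)
    trs <- lapply(trs, classifyFinalLocation, tissue = tis, window = 1000,
                  end = endT)
    per <- Filter(function(tr) max(tipSamples(tr)$t) >= endT - 100, trs)
    regions <- c(regions,
                 if (length(per)) finalRegion(per[[1]]) else "extinguished")
    fmaps[[i]] <- buildTipFrequencyMap(trs, tis)
  }
  pmap <- combineMaps(fmaps, finalRegions = regions)
  tas <- extractTAs(pmap, 0.2, tissue = tis, smooth_mm = 1.2, min_voxels = 4L)
  list(tissue = tis, stats = patchStats(tissueLabels(tis), tis),
       regions = regions, pmap = pmap, tas = tas)
})

## Small shell used for geometry-level checks (fast to build).
fxSmallShell <- function() memoFixture("smallShell", function() {
  g <- makeLAShell(laGeometrySpec(semi_axes = c(22, 18, 15)))
  g@meta$wallColumns <- fibroRD:::.wallColumns(wallMask(g), g@meta$bloodPool)
  g
})
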