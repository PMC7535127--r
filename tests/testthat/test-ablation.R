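mkDiscLesion <- function(tis, cen, r) {
  dm <- dim(wallMask(tis)); dx <- spacing(tis)
  idx <- which(wallMask(tis))
  xyz <- fibroRD:::.voxCoords(idx, dm, dx)
  m <- array(FALSE, dm)
  m[idx[(xyz[, 1] - cen[1])^2 + (xyz[, 2] - cen[2])^2 <= r^2]] <- TRUE
  new("LesionSet", mask = m, strategyId = 3L,
      components = list(ta_cylinders = m),
      ablatedPercent = 100 * sum(m) / sum(wallMask(tis)))
}

test_that("lesion application zeroes conductance and clamps the membrane", {
  fx <- fxSheetRun()
  les <- mkDiscLesion(fx$tissue, c(30, 30), 5)
  ab <- applyLesions(fx$tissue, les, finalState(fx$rec))
  expect_true(all(diffusion(ab$tissue)[lesionMask(les)] == 0))
  expect_true(all(ab$state@u[lesionMask(les)] == 0))
  expect_true(validObject(ab$tissue))
  ## lesion voxels stay at rest for all later times
  cfg <- solverConfig(duration = 300, dt = 0.05, recordInterval = 2)
  post <- runSimulation(ab$tissue, cfg, fxParams(), init = ab$state, t0 = 2000)
  lesActive <- which(lesionMask(les)[post@activeIdx])
  expect_length(lesActive, 0L)   # lesions are out of the active set
  full <- frameAt(post, 2300)
  expect_true(all(full[lesionMask(les)] == 0))
  ## empty lesion set: tissue unchanged
  none <- applyLesions(fx$tissue, array(FALSE, dim(wallMask(fx$tissue))))
  expect_identical(diffusion(none), diffusion(fx$tissue))
  expect_equal(ablatedPercent(les),
               100 * sum(lesionMask(les)) / sum(wallMask(fx$tissue)))
})

test_that("a transmural lesion line blocks a planar wave", {
  tis <- makeStrip(30, 6, 1.2, dx = 0.6, D = 0.1)
  block <- array(FALSE, dim(wallMask(tis)))
  block[ceiling(15 / 0.6) + 0:1, , ] <- TRUE
  tis2 <- applyLesions(tis, block)
  stim <- stimulusSpec(tis2, function(xyz) xyz[, 1] <= 1.5, amplitude = 0.6)
  cfg <- solverConfig(duration = 80, dt = 0.05, recordInterval = 1,
                      stimuli = list(stim))
  m <- measureCV(runSimulation(tis2, cfg, fxParams()), planes = c(10, 25))
  expect_true(m$blocked)        # proximal activates, distal never does
  expect_false(is.na(m$t_planes[1]))
})

test_that("dominant frequency analysis recovers tones and the pacing fundamental", {
  ## synthetic 5 Hz sinusoid at every voxel
  dm <- c(5, 5, 1)
  tt <- seq(0, 1998, by = 2)
  u <- 0.5 + 0.3 * sin(2 * pi * 5 * tt / 1000)
  rec <- new("Recording", uSnaps = matrix(rep(u, each = prod(dm)),
                                          prod(dm), length(tt)),
             times = tt, activeIdx = seq_len(prod(dm)), dims = as.integer(dm),
             dx = 1, finalState = restState(dm), meta = list())
  mf <- meanFrequency(rec, window = 1000)
  expect_equal(mf$mf, 5, tolerance = 0.11)   # within one spectral bin
  expect_lte(mf$mf, 250)                      # Nyquist of 2 ms sampling
  expect_error(meanFrequency(rec, window = 300), "667")
  ## planar pacing at BCL 130 -> fundamental near 7.7 Hz
  p <- fxParams()
  tis <- makeStrip(30, 3, 1.2, dx = 0.6, D = 0.1)
  stims <- lapply(0:9, function(b)
    stimulusSpec(tis, function(xyz) xyz[, 1] <= 1.5, onset = b * 130,
                 amplitude = 0.6))
  cfg <- solverConfig(duration = 1400, dt = 0.05, recordInterval = 2,
                      stimuli = stims)
  mfp <- meanFrequency(runSimulation(tis, cfg, p), window = 1000)
  expect_equal(mfp$mf, 1000 / 130, tolerance = 0.5 / 7.7)
  ## quiescent tissue: amplitude floor excludes everything
  cfgq <- solverConfig(duration = 800, dt = 0.05, recordInterval = 2)
  mq <- meanFrequency(runSimulation(tis, cfgq, p), window = 700)
  expect_identical(mq$mf, 0)
  expect_true(mq$quiescent)
})

test_that("ablation outcomes classify termination, AT pinning and failure", {
  fx <- fxSheetRun()
  endT <- max(fx$rec@times)
  per <- Filter(function(tr) max(tipSamples(tr)$t) >= endT - 100, fx$trajs)
  expect_length(per, 1L)
  s <- tipSamples(per[[1]])
  core <- c(mean(s$x[s$t > 1500]), mean(s$y[s$t > 1500]))
  runPost <- function(les, dur = 2000) {
    ab <- applyLesions(fx$tissue, les, finalState(fx$rec))
    cfg <- solverConfig(duration = dur, dt = 0.05, recordInterval = 2)
    post <- runSimulation(ab$tissue, cfg, fxParams(), init = ab$state,
                          t0 = endT)
    evaluateOutcome(fx$rec, post, ab$tissue, les)
  }
  ## a large disc over the core pins the rotor around the new scar: AT
  atOut <- runPost(mkDiscLesion(fx$tissue, core, 3))
  expect_identical(atOut@classification, "at")
  expect_identical(atOut@nRDsBefore, 1L)
  ## a small far-corner lesion leaves the rotor untouched
  farOut <- runPost(mkDiscLesion(fx$tissue, c(52, 8), 4))
  expect_identical(farOut@classification, "unaffected")
  expect_identical(farOut@nRDsAfter, 1L)
  ## a quiescent post state is terminated
  cfgRest <- solverConfig(duration = 1200, dt = 0.05, recordInterval = 2)
  rest <- runSimulation(fx$tissue, cfgRest, fxParams(), t0 = endT)
  les <- mkDiscLesion(fx$tissue, c(52, 8), 4)
  termOut <- evaluateOutcome(fx$rec, rest, fx$tissue, les)
  expect_identical(termOut@classification, "terminated")
  expect_identical(termOut@nRDsAfter, 0L)
})

## Hand-made TA set on a shell: two compact blobs on the wall.
syntheticTAs <- function(tis) {
  dm <- dim(wallMask(tis)); dx <- spacing(tis)
  idx <- which(wallMask(tis))
  xyz <- fibroRD:::.voxCoords(idx, dm, dx)
  cen <- tis@meta$center
  lab <- array(0L, dm)
  ## two antipodal spots away from the openings
  for (k in 1:2) {
    d <- if (k == 1) c(0.9, -0.2, 0.4) else c(-0.9, -0.3, -0.2)
    d <- d / sqrt(sum(d^2))
    target <- cen + d * tis@meta$spec$semi_axes * 0.95
    dist <- sqrt(rowSums(sweep(xyz, 2, target, "-")^2))
    lab[idx[dist <= min(dist) + 2.5]] <- k
  }
  new("TargetAreaSet", labelArr = lab, threshold = 0.2, mode = "fixed",
      dx = dx, stats = data.frame())
}

test_that("the five lesion strategies nest and isolate the veins", {
  tis <- fxSmallShell()
  tas <- syntheticTAs(tis)
  expect_identical(taCount(tas), 2L)
  l3 <- buildStrategy(tis, tas, 3)
  l4 <- buildStrategy(tis, tas, 4)
  l5 <- buildStrategy(tis, tas, 5)
  expect_gt(sum(lesionMask(l3)), 0L)
  expect_true(all(lesionMask(l4)[lesionMask(l3)]))   # 3 subset 4
  expect_true(all(lesionMask(l5)[lesionMask(l4)]))   # 4 subset 5
  expect_gt(ablatedPercent(l5), ablatedPercent(l4))
  expect_error(buildStrategy(tis, NULL, 3), "require")
  ## strategy 3 with an empty TA set gives an empty lesion set
  emptyTAs <- new("TargetAreaSet",
                  labelArr = array(0L, dim(wallMask(tis))), threshold = 0.2,
                  mode = "fixed", dx = spacing(tis), stats = data.frame())
  l3e <- buildStrategy(tis, emptyTAs, 3)
  expect_identical(sum(lesionMask(l3e)), 0L)
  ## strategy 2 adds the roof and mitral lines on top of the rings
  l2 <- buildStrategy(tis, NULL, 2)
  expect_true(all(c("pvi_rings", "roof_line", "mv_line") %in%
                    names(lesionComponents(l2))))
  ## PVI rings close each vein off from the atrial body
  l1 <- buildStrategy(tis, NULL, 1)
  expect_true(all(lesionMask(l2)[lesionMask(l1)]))   # 1 subset 2
  open <- wallMask(tis) & !lesionMask(l1)
  comp <- fibroRD:::labelComponents(open, 26L)
  dm <- dim(wallMask(tis)); dx <- spacing(tis)
  idx <- which(open)
  xyz <- fibroRD:::.voxCoords(idx, dm, dx)
  bodyLab <- comp[which(open & mvMask(tis))[1]]
  for (k in seq_len(nrow(pvCenters(tis)))) {
    near <- idx[sqrt(rowSums(sweep(xyz, 2, pvCenters(tis)[k, ], "-")^2)) <= 6.5]
    expect_true(length(near) > 0)
    expect_false(bodyLab %in% comp[near])
  }
})

test_that("re-inducibility on a fully protected substrate reports no AF", {
  ## ablate everything except a small patch: no re-entry is possible there
  tis <- makeSheet(40, 40, dx = 0.6)
  keep <- array(FALSE, dim(wallMask(tis)))
  keep[1:17, 1:17, 1] <- TRUE   # a 10 x 10 mm corner stays alive
  les <- new("LesionSet", mask = !keep & wallMask(tis), strategyId = 3L,
             components = list(ta_cylinders = !keep & wallMask(tis)),
             ablatedPercent = 100 * sum(!keep & wallMask(tis)) /
               sum(wallMask(tis)))
  abl <- applyLesions(tis, les)
  tab <- reinducibilityTest(abl, les, fxParams(), n_sites = 2, seed = 4,
                            duration = 900, dt = 0.05)
  expect_true(all(tab$outcome == "no_af"))
})
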