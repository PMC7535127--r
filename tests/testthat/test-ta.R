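mkFreqMap <- function(counts) new("TipFrequencyMap", counts = counts,
                                  totalSamples = sum(counts))

test_that("map combination normalizes by the maximum and excludes PV runs", {
  dm <- c(6, 6, 1)
  a <- array(0L, dm); a[2, 2, 1] <- 4L
  b <- array(0L, dm); b[5, 5, 1] <- 8L
  ## single map with one hot voxel
  p1 <- combineMaps(list(mkFreqMap(a)))
  expect_equal(p1@values[2, 2, 1], 1)
  expect_equal(sum(p1@values > 0), 1)
  ## two identical maps: scale invariance
  p2 <- combineMaps(list(mkFreqMap(a), mkFreqMap(a)))
  expect_equal(p2@values, p1@values)
  ## a PV-anchored run is excluded at run level
  p3 <- combineMaps(list(mkFreqMap(a), mkFreqMap(b)),
                    finalRegions = c("fibrosis", "pv"))
  expect_equal(p3@values, p1@values)
  expect_identical(p3@nRuns, 1L)
  ## voxel-level exclusion mode instead zeroes the PV region
  pvArr <- array(FALSE, dm); pvArr[5, 5, 1] <- TRUE
  p4 <- combineMaps(list(mkFreqMap(a), mkFreqMap(b)), exclude = "voxel",
                    pvMaskArr = pvArr)
  expect_equal(p4@values[5, 5, 1], 0)
  expect_equal(p4@values[2, 2, 1], 1)
  ## all-zero combination errors
  z <- array(0L, dm)
  expect_error(combineMaps(list(mkFreqMap(z))), "no RDs")
  expect_error(combineMaps(list(mkFreqMap(a), mkFreqMap(b)),
                           finalRegions = c("pv", "pv")), "no RDs")
})

test_that("TA extraction separates plateaus and respects the threshold", {
  dm <- c(20, 20, 1)
  v <- array(0.05, dm)
  v[3:6, 3:6, 1] <- 0.9; v[3, 3, 1] <- 1
  pmap <- new("RDProbabilityMap", values = v, nRuns = 1L,
              normalization = "max")
  tas <- extractTAs(pmap, 0.2)
  expect_identical(taCount(tas), 1L)
  expect_identical(sum(taLabels(tas) > 0), 16L)
  ## two plateaus with a low valley: two TAs
  v2 <- array(0, dm)
  v2[2:4, 2:4, 1] <- 0.5; v2[10:12, 10:12, 1] <- 0.3; v2[6:8, 6:8, 1] <- 0.1
  pm2 <- new("RDProbabilityMap", values = v2 / max(v2), nRuns = 1L,
             normalization = "max")
  expect_identical(taCount(extractTAs(pm2, 0.2)), 2L)
  ## threshold 1.0 keeps nothing (strict inequality)
  expect_identical(taCount(extractTAs(pmap, 1.0)), 0L)
  ## mean + 2 SD mode reports the threshold it used
  tms <- extractTAs(pm2, mode = "mean_sd")
  nz <- pm2@values[pm2@values > 0]
  expect_equal(tms@threshold, min(mean(nz) + 2 * sd(nz), 1))
})

test_that("TA sets shrink monotonically as the threshold rises", {
  set.seed(7)
  v <- array(0, c(15, 15, 3))
  for (k in 1:4) {
    cen <- sample(3:13, 2)
    v[cen[1] + (-1:1), cen[2] + (-1:1), sample(1:3, 1)] <-
      runif(1, 0.3, 1)
  }
  v <- v / max(v)
  pmap <- new("RDProbabilityMap", values = v, nRuns = 1L,
              normalization = "max")
  prev <- NULL
  for (th in c(0.1, 0.25, 0.5, 0.8)) {
    cur <- which(taLabels(extractTAs(pmap, th)) > 0)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("Dice matches brute-force set arithmetic and its closed forms", {
  dm <- c(8, 8, 2)
  a <- array(FALSE, dm); a[1:3, 1, 1] <- TRUE
  expect_equal(diceScore(a, a), 1)
  b <- array(FALSE, dm); b[5:7, 5, 1] <- TRUE
  expect_equal(diceScore(a, b), 0)
  ## |A| = |B| = 2 sharing one voxel
  a2 <- array(FALSE, dm); a2[1:2, 1, 1] <- TRUE
  b2 <- array(FALSE, dm); b2[2:3, 1, 1] <- TRUE
  expect_equal(diceScore(a2, b2), 0.5)
  ## both empty: defined as 1 and flagged
  e <- array(FALSE, dm)
  expect_equal(as.numeric(diceScore(e, e)), 1)
  expect_true(attr(diceScore(e, e), "both_empty"))
  ## random sets against naïve formula; symmetry and bounds
  set.seed(9)
  for (rep in 1:5) {
    x <- array(runif(prod(dm)) > 0.6, dm)
    y <- array(runif(prod(dm)) > 0.6, dm)
    ref <- 2 * sum(x & y) / (sum(x) + sum(y))
    expect_equal(diceScore(x, y), ref)
    expect_equal(diceScore(y, x), diceScore(x, y))
    expect_gte(diceScore(x, y), 0); expect_lte(diceScore(x, y), 1)
  }
})

test_that("TA reports pair volumes with burden and flag fibrotic composition", {
  ## no TAs: zeros
  dm <- c(10, 10, 1)
  pm <- new("RDProbabilityMap",
            values = array(c(1, rep(0, prod(dm) - 1)), dm),
            nRuns = 1L, normalization = "max")
  tis <- makeSheet(10, 10, dx = 1)
  tas0 <- extractTAs(pm, 2, tissue = tis)  # nothing survives
  rep0 <- taReport(tas0, tis)
  expect_equal(rep0$total_ta_percent, 0)
  ## a TA fully inside dense tissue reports 100% dense
  tis2 <- makeSheet(10, 10, dx = 1, patches = list(
    list(center = c(5, 5), radius = 3, iir = 1.3)))
  v <- array(0, dm); v[4:6, 4:6, 1] <- 1
  pm2 <- new("RDProbabilityMap", values = v, nRuns = 1L,
             normalization = "max")
  tas2 <- extractTAs(pm2, 0.2, tissue = tis2)
  expect_equal(taStats(tas2)$dense_pct, 100)
  expect_equal(taReport(tas2, tis2)$majority_fibrotic, 1)
})

test_that("on the synthetic Utah-3 atrium TAs are small, fibrotic and map-faithful", {
  fx <- fxUtah3()
  expect_gte(taCount(fx$tas), 1L)
  rep <- taReport(fx$tas, fx$tissue, fx$stats)
  ## total TA volume far below the fibrosis burden
  expect_lt(rep$total_ta_percent, rep$fb_percent)
  ## majority of TA volume on border-zone or dense voxels
  expect_gt(rep$majority_fibrotic, 0.5)
})

test_that("with low burden and PV-enriched fibrosis RDs avoid the small patches", {
  ## Utah-2 analogue: 11% burden concentrated near the PV ostia; the
  ## persistent drivers settle at anatomical/healthy sites, not fibrosis
  g <- makeLAShell(laGeometrySpec(semi_axes = c(22, 18, 15)))
  spec <- tuneFB(g, syntheticLGESpec(seed = 5, pv_fibrosis_weight = 0.12),
                 0.11)
  v <- makeSyntheticLGE(g, spec)
  tis <- applyFibrosis(g, v$intensity, v$bloodPool)
  st <- patchStats(tissueLabels(tis), tis)
  expect_identical(st$utah_score, 2L)
  plans <- enumerateSites(tis, 2, seed = 3)
  regions <- vapply(plans, function(pl) {
    rec <- runPlan(tis, pl, fxParams(), duration = 2000, dt = 0.05)
    endT <- max(rec@times)
    per <- fibroRD:::.persistent(trackTips(rec), endT)
    if (!length(per)) return("extinguished")
    finalRegion(classifyFinalLocation(per[[1]], tis, window = 1000,
                                      end = endT))
  }, character(1))
  settled <- regions[regions != "extinguished"]
  expect_gt(length(settled), 0L)
  expect_true(all(settled %in% c("pv", "healthy")))
})
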