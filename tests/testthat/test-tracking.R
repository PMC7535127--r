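test_that("a uniform field contains no phase singularity", {
  u <- array(0.7, c(20, 20, 1))
  mask <- array(TRUE, c(20, 20, 1))
  expect_identical(nrow(detectTips(u, u * 0.9, mask, 1)), 0L)
})

test_that("an analytic spiral yields one tip at its center with consistent chirality", {
  mask <- array(TRUE, c(50, 50, 1))
  for (chir in c(1, -1)) {
    fr <- spiralFrames(50, 50, 1, center = c(25, 25), chir = chir)
    tips <- detectTips(fr$now, fr$delayed, mask, 1)
    expect_identical(nrow(tips), 1L)
    expect_lt(abs(tips$x - 25), 1.01)
    expect_lt(abs(tips$y - 25), 1.01)
  }
  ## opposite senses give opposite chirality
  t1 <- detectTips(spiralFrames(50, 50, 1, c(25, 25), chir = 1)$now,
                   spiralFrames(50, 50, 1, c(25, 25), chir = 1)$delayed,
                   mask, 1)
  t2 <- detectTips(spiralFrames(50, 50, 1, c(25, 25), chir = -1)$now,
                   spiralFrames(50, 50, 1, c(25, 25), chir = -1)$delayed,
                   mask, 1)
  expect_identical(t1$chirality, -t2$chirality)
})

test_that("a figure-of-eight has two tips of opposite chirality and zero net charge", {
  ## smooth doublet field: phase = angle(z - z1) - angle(z - z2) carries a
  ## +1 singularity at z1 and a -1 singularity at z2
  nx <- 80; ny <- 40; dx <- 1
  xs <- (seq_len(nx) - 0.5); ys <- (seq_len(ny) - 0.5)
  gx <- matrix(xs, nx, ny); gy <- matrix(ys, nx, ny, byrow = TRUE)
  phi <- atan2(gy - 20, gx - 25) - atan2(gy - 20, gx - 55)
  now <- array(0.5 + 0.45 * cos(phi), c(nx, ny, 1))
  del <- array(0.5 + 0.45 * cos(phi - pi / 2), c(nx, ny, 1))
  mask <- array(TRUE, c(nx, ny, 1))
  tips <- detectTips(now, del, mask, dx)
  expect_identical(nrow(tips), 2L)
  expect_identical(sum(tips$chirality), 0L)
})

test_that("the plaquette detector matches the brute-force winding oracle exactly", {
  mask <- array(TRUE, c(40, 40, 1))
  set.seed(6)
  for (rep in 1:4) {
    centers <- matrix(runif(4, 8, 32), 2, 2)
    fr1 <- spiralFrames(40, 40, 1, centers[1, ], pitch = runif(1, 3, 6),
                        chir = sample(c(-1, 1), 1))
    fr2 <- spiralFrames(40, 40, 1, centers[2, ], pitch = runif(1, 3, 6),
                        chir = sample(c(-1, 1), 1))
    now <- (fr1$now + fr2$now) / 2
    del <- (fr1$delayed + fr2$delayed) / 2
    got <- detectTips(now, del, mask, 1, cluster_mm = 0)
    ref <- bruteWindingTips(now[, , 1], del[, , 1],
                            mask[, , 1, drop = TRUE], 1)
    if (is.null(ref)) {
      expect_identical(nrow(got), 0L)
    } else {
      o1 <- order(got$x, got$y); o2 <- order(ref[, 1], ref[, 2])
      expect_equal(got$x[o1], ref[o2, 1])
      expect_equal(got$y[o1], ref[o2, 2])
      expect_equal(got$chirality[o1], as.integer(ref[o2, 3]))
    }
  }
})

test_that("the isoline-intersection detector agrees with phase mapping on a spiral", {
  mask <- array(TRUE, c(50, 50, 1))
  fr <- spiralFrames(50, 50, 1, center = c(25, 25), chir = 1)
  iso <- detectTipsIsoline(fr$now, fr$delayed, mask, 1)
  expect_gt(nrow(iso), 0L)
  d <- sqrt((iso$x - 25)^2 + (iso$y - 25)^2)
  expect_lt(min(d), 2.01)
})

test_that("tracking follows a drifting spiral as a single trajectory", {
  ## synthesize a recording: spiral core moving at 5 mm/s, frames every 2 ms
  nx <- 40L; ny <- 40L; dx <- 1
  dm <- c(nx, ny, 1L)
  nfr <- 151
  snaps <- matrix(0, nx * ny, nfr)
  tt <- seq(0, by = 2, length.out = nfr)
  for (i in seq_len(nfr)) {
    cen <- c(15 + 0.005 * tt[i] * 2, 20)
    phase0 <- -2 * pi * tt[i] / 100
    xs <- (seq_len(nx) - 0.5); ys <- (seq_len(ny) - 0.5)
    gx <- matrix(xs, nx, ny); gy <- matrix(ys, nx, ny, byrow = TRUE)
    r <- sqrt((gx - cen[1])^2 + (gy - cen[2])^2)
    phi <- atan2(gy - cen[2], gx - cen[1]) - r / 4 + phase0
    snaps[, i] <- as.vector(0.5 + 0.45 * cos(phi))
  }
  rec <- new("Recording", uSnaps = snaps, times = tt,
             activeIdx = seq_len(nx * ny), dims = dm, dx = dx,
             finalState = restState(dm), meta = list(site_id = "synthetic"))
  trs <- trackTips(rec, tau = 10, min_ms = 50)
  expect_length(trs, 1L)
  s <- tipSamples(trs[[1]])
  expect_gt(max(s$t) - min(s$t), 250)
  ## the recovered core tracks the prescribed drift
  expect_equal(s$x[nrow(s)] - s$x[1],
               0.01 * (max(s$t) - min(s$t)), tolerance = 0.5)
})

test_that("final-location classification votes by region with pv precedence", {
  tis <- makeSheet(30, 30, dx = 0.6, patches = list(
    list(center = c(20, 15), radius = 4, iir = 1.3)))
  mk <- function(xs, ts) new("TipTrajectory", runId = "t",
    samples = data.frame(t = ts, x = xs, y = rep(15, length(ts)),
                         z = 0.3, chirality = 1L), finalRegion = "unclassified")
  ## all samples on the dense patch -> fibrosis
  tr <- classifyFinalLocation(mk(rep(20, 11), seq(0, 1000, by = 100)), tis,
                              window = 1000, end = 1000)
  expect_identical(finalRegion(tr), "fibrosis")
  ## 60/40 healthy majority -> healthy
  xs <- c(rep(5, 6), rep(20, 4))
  tr2 <- classifyFinalLocation(mk(xs, seq(100, 1000, by = 100)), tis,
                               window = 1000, end = 1000)
  expect_identical(finalRegion(tr2), "healthy")
  ## died before the window -> extinguished
  tr3 <- classifyFinalLocation(mk(rep(5, 3), c(100, 150, 200)), tis,
                               window = 1000, end = 2000)
  expect_identical(finalRegion(tr3), "extinguished")
  ## pv wins exact ties: build a tissue with a pv sphere
  g <- fxSmallShell()
  idx <- which(pvMask(g))[1]
  pvPos <- fibroRD:::.voxCoords(idx, dim(wallMask(g)), spacing(g))[1, ]
  hIdx <- which(wallMask(g) & !pvMask(g) &
                  tissueLabels(g) == 0L)[1]
  hPos <- fibroRD:::.voxCoords(hIdx, dim(wallMask(g)), spacing(g))[1, ]
  s <- data.frame(t = seq(100, 1000, by = 100),
                  x = c(rep(pvPos[1], 5), rep(hPos[1], 5)),
                  y = c(rep(pvPos[2], 5), rep(hPos[2], 5)),
                  z = c(rep(pvPos[3], 5), rep(hPos[3], 5)), chirality = 1L)
  tr4 <- classifyFinalLocation(new("TipTrajectory", runId = "t",
                                   samples = s, finalRegion = "unclassified"),
                               g, window = 1000, end = 1000)
  expect_identical(finalRegion(tr4), "pv")
})

test_that("tip-frequency maps accumulate visits per voxel", {
  tis <- makeSheet(20, 20, dx = 1)
  stat <- new("TipTrajectory", runId = "s", finalRegion = "unclassified",
              samples = data.frame(t = seq(2, 100, by = 2), x = 10.2,
                                   y = 10.7, z = 0.5, chirality = 1L))
  fm <- buildTipFrequencyMap(list(stat), tis)
  expect_identical(max(fm@counts), 50L)
  expect_identical(sum(fm@counts), 50L)
  ## circular meander visits an annulus of radius r
  th <- seq(0, 4 * pi, length.out = 200)
  circ <- new("TipTrajectory", runId = "c", finalRegion = "unclassified",
              samples = data.frame(t = seq_along(th) * 2,
                                   x = 10 + 5 * cos(th), y = 10 + 5 * sin(th),
                                   z = 0.5, chirality = 1L))
  fmc <- buildTipFrequencyMap(list(circ), tis)
  vis <- which(fmc@counts > 0)
  xy <- fibroRD:::.voxCoords(vis, dim(fmc@counts), 1)
  rr <- sqrt((xy[, 1] - 10)^2 + (xy[, 2] - 10)^2)
  expect_true(all(abs(rr - 5) <= 1.01))
  ## no trajectories: an all-zero map
  fm0 <- buildTipFrequencyMap(list(), tis)
  expect_identical(sum(fm0@counts), 0L)
})
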