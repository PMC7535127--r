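test_that("IIR is the intensity over the blood-pool mean and is scale invariant", {
  dm <- c(4, 4, 2)
  intensity <- array(100, dm)
  bp <- array(FALSE, dm); bp[, , 2] <- TRUE
  intensity[, , 2] <- 200
  intensity[1, 1, 1] <- 248
  iir <- computeIIR(intensity, bp)
  expect_equal(iir[1, 1, 1], 1.24)
  expect_equal(iir[2, 2, 1], 0.5)
  expect_identical(computeIIR(intensity * 3.7, bp), iir)
  expect_error(computeIIR(intensity * 0, bp), "positive")
  expect_error(computeIIR(intensity, bp & FALSE), "empty")
})

test_that("voxel labelling follows the printed IIR bands and boundary conventions", {
  iir <- array(c(1.00, 1.16, 1.30, 1.08, 1.24, 0.9), c(6, 1, 1))
  lab <- labelVoxels(iir)
  expect_identical(as.vector(lab), c(0L, 1L, 2L, 1L, 2L, 0L))
  expect_error(iirThresholds(1.3, 1.2))
})

test_that("diffusion interpolation reproduces the printed endpoints and midpoint", {
  expect_equal(iirToDiffusion(1.079), 0.1)
  expect_equal(iirToDiffusion(1.08), 0.1)    # interpolation start
  expect_equal(iirToDiffusion(1.24), 0.017)
  expect_equal(iirToDiffusion(1.40), 0.017)  # clamped above
  expect_equal(iirToDiffusion(1.16), 0.0585) # midpoint of the linear map
  ## monotone non-increasing with range exactly [0.017, 0.1]
  grid <- seq(0.9, 1.5, by = 0.001)
  D <- iirToDiffusion(grid)
  expect_true(all(diff(D) <= 1e-15))
  expect_equal(range(D), c(0.017, 0.1))
  ## agreement with labelling: dense <=> d_dense; healthy voxels keep the
  ## healthy D, and any reduced D implies a fibrotic label
  lab <- labelVoxels(array(grid, c(length(grid), 1, 1)))
  expect_true(all((lab == 2L) == (D <= 0.017 + 1e-15)))
  expect_true(all(D[lab == 0L] == 0.1))
  expect_true(all(lab[D < 0.1 - 1e-12] >= 1L))
  ## derived constants: 83% slowing and the 1.24 upper threshold
  expect_equal(denseDReductionPercent(), 83)
  expect_equal(deriveUpperIIR(), 1.24)
})

test_that("Utah staging is a step function with jumps at 5, 20 and 35", {
  expect_identical(utahClassify(c(39, 29, 25, 22, 16, 11)),
                   c(4L, 3L, 3L, 3L, 2L, 2L))
  expect_identical(utahClassify(c(0, 5, 5.01, 20, 20.01, 35, 35.01, 100)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(utahClassify(-1))
  expect_error(utahClassify(101))
})

test_that("patch statistics agree with a brute-force flood fill", {
  for (s in 1:3) {
    set.seed(s)
    dm <- c(12, 12, 6)
    wall <- array(runif(prod(dm)) > 0.25, dm)
    lab <- array(NA_integer_, dm)
    lab[wall] <- sample(0:2, sum(wall), replace = TRUE,
                        prob = c(0.6, 0.25, 0.15))
    tis <- tissueModel(wall, D = 0.1, dx = 0.5, labels = lab)
    st <- patchStats(lab, tis)
    fib <- wall & !is.na(lab) & lab >= 1L
    ref <- bruteFloodFill(fib)
    refSizes <- tabulate(ref[ref > 0])
    expect_equal(st$n_patches, length(refSizes))
    expect_equal(st$largest_patch_percent,
                 100 * max(refSizes) / sum(wall))
    expect_equal(st$fb_percent, 100 * sum(fib) / sum(wall))
    expect_equal(st$pv_fraction_percent + st$wall_fraction_percent, 100)
  }
  ## empty and degenerate cases
  wall <- array(TRUE, c(4, 4, 2))
  lab0 <- array(0L, c(4, 4, 2))
  tis <- tissueModel(wall, D = 0.1, dx = 0.5, labels = lab0)
  st0 <- patchStats(lab0, tis)
  expect_equal(st0$fb_percent, 0)
  expect_identical(st0$utah_score, 1L)
  lab2 <- array(2L, c(4, 4, 2))
  st2 <- patchStats(lab2, tissueModel(wall, D = 0.1, dx = 0.5, labels = lab2))
  expect_equal(st2$pv_fraction_percent + st2$wall_fraction_percent, 100)
  expect_equal(st2$fb_percent, 100)
})

test_that("transmural projection builds full-thickness columns and is idempotent", {
  ## single-voxel-thick sheet: identity
  tis <- makeSheet(12, 12, dx = 0.6)
  lab <- tissueLabels(tis)
  lab[3, 3, 1] <- 2L
  out <- transmuralProjection(lab, wallMask(tis))
  expect_identical(out, lab)

  ## flat 3 mm slab over a blood pool: an endocardial dense disc becomes a
  ## full-thickness column
  dm <- c(20, 20, 7)
  wall <- array(FALSE, dm); wall[, , 3:7] <- TRUE   # 5 voxels = 3 mm at 0.6
  bp <- array(FALSE, dm); bp[, , 1:2] <- TRUE
  lab <- array(NA_integer_, dm); lab[wall] <- 0L
  for (i in 8:12) for (j in 8:12)
    if ((i - 10)^2 + (j - 10)^2 <= 4) lab[i, j, 3] <- 2L
  out <- transmuralProjection(lab, wall, bp)
  for (k in 3:7) expect_identical(out[10, 10, k], 2L)
  expect_identical(out[2, 2, 5], 0L)
  ## idempotent
  expect_identical(transmuralProjection(out, wall, bp), out)
})

test_that("fibrosis statistics export uses the study column names", {
  wall <- array(TRUE, c(4, 4, 2))
  lab <- array(0L, dim(wall)); lab[1:2, 1, 1] <- 1L
  tis <- tissueModel(wall, D = 0.1, dx = 0.5, labels = lab)
  f <- tempfile(fileext = ".csv")
  writeFibrosisStats(patchStats(lab, tis), f)
  got <- utils::read.csv(f, check.names = FALSE)
  expect_true(all(c("% FB", "% Volume of largest patch", "% FB of PVs",
                    "% FB of LA wall", "% Volume of dense tissue")
                  %in% names(got)))
})
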