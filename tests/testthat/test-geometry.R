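test_that("the default LA shell is one connected wall with five openings", {
  g <- makeLAShell(laGeometrySpec())
  comp <- fibroRD:::labelComponents(wallMask(g), 26L)
  expect_identical(attr(comp, "n"), 1L)
  ## the carved voxels form exactly 5 opening plugs (4 PVs + MV), each
  ## punching through the full wall thickness
  carved <- g@meta$carved
  oc <- fibroRD:::labelComponents(carved, 26L)
  expect_identical(attr(oc, "n"), 5L)
  bp <- g@meta$bloodPool
  full <- wallMask(g) | carved
  outside <- !full & !bp
  for (k in seq_len(5)) {
    plug <- oc == k
    touchesEndo <- length(fibroRD:::surfaceVoxels(plug, against = bp)) > 0
    touchesEpi <- length(fibroRD:::surfaceVoxels(plug, against = outside)) > 0
    expect_true(touchesEndo && touchesEpi)
  }
  expect_identical(nrow(pvCenters(g)), 4L)
  expect_true(any(pvMask(g)))
  expect_true(any(mvMask(g)))
})

test_that("wall thickness matches the 3 mm dilation", {
  g <- makeLAShell(laGeometrySpec(semi_axes = c(15, 13, 11), mv_radius = 6,
                                  dx = 0.3))
  dm <- dim(wallMask(g))
  cen <- g@meta$center
  spec <- g@meta$spec
  dirs <- rbind(spec$pv_directions, spec$mv_direction)
  radii <- c(rep(spec$pv_radius, 4), spec$mv_radius)
  ## skip rays inside the angular cone of any opening (plus margin)
  cosLim <- cos(asin(pmin(0.9, (radii + 2.5) / min(spec$semi_axes))))
  set.seed(8)
  nOk <- 0; th <- numeric(0)
  for (rep in 1:150) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    if (any(dirs %*% d > cosLim)) next
    ts <- seq(5, 25, by = 0.02)
    pts <- cbind(cen[1] + ts * d[1], cen[2] + ts * d[2], cen[3] + ts * d[3])
    vox <- cbind(ceiling(pts[, 1] / 0.3), ceiling(pts[, 2] / 0.3),
                 ceiling(pts[, 3] / 0.3))
    ok <- vox[, 1] >= 1 & vox[, 1] <= dm[1] & vox[, 2] >= 1 &
      vox[, 2] <= dm[2] & vox[, 3] >= 1 & vox[, 3] <= dm[3]
    lin <- fibroRD:::.linIndex(vox[ok, , drop = FALSE], dm)
    inWall <- wallMask(g)[lin]
    if (!any(inWall)) next
    ext <- max(ts[ok][inWall]) - min(ts[ok][inWall])
    ## only keep clean single crossings (no interior gap)
    if (abs(ext - (sum(inWall) - 1) * 0.02) > 0.05) next
    th <- c(th, ext)
    nOk <- nOk + 1
  }
  expect_gt(nOk, 15)
  ## 3 mm = 10 voxels at dx 0.3; allow one voxel either way (plus the
  ## obliquity of a center ray against the local surface normal)
  expect_true(all(th > 3 - 0.31 & th < 3 + 1.2))
})
test_that("a shell without openings is closed and degenerate specs error", {
  spec <- laGeometrySpec(semi_axes = c(12, 10, 9), pv_radius = 0.01,
                         mv_radius = 0.01, dx = 0.6)
  g <- makeLAShell(spec)
  ## blood pool is sealed off from the exterior
  notWall <- !wallMask(g)
  comp <- fibroRD:::labelComponents(notWall, 6L)
  bpLab <- unique(comp[g@meta$bloodPool])
  outLab <- comp[1, 1, 1]
  expect_false(outLab %in% bpLab)
  expect_error(makeLAShell(laGeometrySpec(semi_axes = c(8, 7, 6),
                                          mv_radius = 7)),
               "larger than the chamber")
  expect_error(laGeometrySpec(wall_thickness = 0.5, dx = 0.6), "2 voxels")
})

test_that("sheet fixtures carry prescribed patches through the IIR pipeline", {
  ## one dense-core patch: labelled dense inside, healthy elsewhere
  tis <- makeSheet(30, 30, dx = 0.6, patches = list(
    list(center = c(15, 15), radius = 5, iir = 1.3)))
  lab <- tissueLabels(tis)
  dm <- dim(lab)
  cen <- lab[ceiling(15 / 0.6), ceiling(15 / 0.6), 1]
  expect_identical(cen, 2L)
  expect_identical(lab[2, 2, 1], 0L)
  expect_equal(diffusion(tis)[2, 2, 1], 0.1)
  expect_equal(diffusion(tis)[ceiling(15 / 0.6), ceiling(15 / 0.6), 1], 0.017)
  ## no patches: all healthy
  tis0 <- makeSheet(20, 20, dx = 0.6)
  expect_true(all(tissueLabels(tis0)[wallMask(tis0)] == 0L))
  expect_true(all(diffusion(tis0)[wallMask(tis0)] == 0.1))
  ## border-zone patches get the interpolated diffusion value
  tis2 <- makeSheet(30, 30, dx = 0.6, patches = list(
    list(center = c(10, 15), radius = 2.5, iir = 1.16),
    list(center = c(20, 15), radius = 2.5, iir = 1.16)))
  i1 <- ceiling(10 / 0.6); j1 <- ceiling(15 / 0.6)
  expect_identical(tissueLabels(tis2)[i1, j1, 1], 1L)
  expect_equal(diffusion(tis2)[i1, j1, 1],
               iirToDiffusion(1.16), tolerance = 1e-12)
  expect_error(makeSheet(20, 20, dx = 0.6, patches = list(
    list(center = c(50, 50), radius = 2, iir = 1.2))), "outside")
})
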