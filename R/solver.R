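#' Construct a tissue model
#'
#' @param wallMask logical 3-D array of wall voxels.
#' @param D diffusion coefficient, mm^2/ms: a scalar (uniform) or an array.
#' @param dx grid spacing, mm.
#' @param labels optional integer array (0 healthy / 1 border zone / 2
#'   dense); defaults to all-healthy on the wall.
#' @param pvCenters numeric matrix of PV opening centers (mm), may have 0 rows.
#' @param pvMask,mvMask,lesionMask optional logical arrays (default empty).
#' @param meta provenance list.
#' @return a [TissueModel-class] object.
#' @export
tissueModel <- function(wallMask, D = 0.1, dx = 0.3, labels = NULL,
                        pvCenters = matrix(numeric(0), 0, 3),
                        pvMask = NULL, mvMask = NULL, lesionMask = NULL,
                        meta = list()) {
  dm <- dim(wallMask)
  if (length(D) == 1) {
    Da <- array(0, dm); Da[wallMask] <- D
  } else Da <- D
  Da[!wallMask] <- 0
  if (is.null(labels)) {
    labels <- array(NA_integer_, dm); labels[wallMask] <- 0L
  }
  empty <- array(FALSE, dm)
  new("TissueModel", wallMask = wallMask, D = Da, dx = dx,
      labelArr = labels, pvCenters = pvCenters,
      pvMask = if (is.null(pvMask)) empty else pvMask,
      mvMask = if (is.null(mvMask)) empty else mvMask,
      lesionMask = if (is.null(lesionMask)) empty else lesionMask,
      meta = meta)
}

#' Solver configuration constructor
#'
#' The explicit scheme requires the 3-D CFL condition
#' max(D) dt / dx^2 <= 1/6; it is checked against the tissue in
#' [runSimulation()].
#'
#' @param duration ms.
#' @param dt time step, ms (default 0.005).
#' @param recordInterval u-snapshot interval, ms (default 2).
#' @param stimuli list of [StimulusSpec-class] objects.
#' @param seed integer provenance seed.
#' @return a [SolverConfig-class].
#' @export
solverConfig <- function(duration, dt = 0.005, recordInterval = 2,
                         stimuli = list(), seed = 1L) {
  new("SolverConfig", dt = dt, duration = duration,
      recordInterval = recordInterval, stimuli = stimuli,
      seed = as.integer(seed))
}

#' Stimulus constructor
#'
#' @param tissue [TissueModel-class] (used to validate the region).
#' @param region logical array, linear indices, or a function of the voxel
#'   center coordinates (n x 3 matrix, mm) returning a logical vector.
#' @param onset,duration ms.
#' @param amplitude forcing on du/dt, 1/ms (default 0.6).
#' @return a [StimulusSpec-class].
#' @export
stimulusSpec <- function(tissue, region, onset = 0, duration = 1,
                         amplitude = 0.6) {
  dm <- dim(wallMask(tissue))
  if (is.function(region)) {
    idx <- which(wallMask(tissue))
    sel <- region(.voxCoords(idx, dm, spacing(tissue)))
    idx <- idx[sel]
  } else if (is.logical(region)) {
    idx <- which(region & wallMask(tissue))
  } else idx <- as.integer(region)
  if (!all(wallMask(tissue)[idx]))
    stop("stimulus region must lie inside the wall")
  new("StimulusSpec", onset = onset, duration = duration,
      amplitude = amplitude, idx = as.integer(idx))
}

#' CFL stability limit
#' @param D max diffusion coefficient, mm^2/ms.
#' @param dx grid spacing, mm.
#' @return the largest stable dt (ms) for the 3-D 7-point explicit scheme.
#' @export
cflLimit <- function(D, dx) dx^2 / (6 * D)

## Precompute neighbour ranks and face diffusivities on the active set
## (wall minus lesions). Face scheme: arithmetic (default) or harmonic mean
## of the two adjacent voxels' D; both are zero across faces leaving the
## active set, which implements the no-flux boundary.
.solverArrays <- function(tissue, faceScheme = c("arithmetic", "harmonic")) {
  faceScheme <- match.arg(faceScheme)
  dm <- dim(wallMask(tissue))
  active <- wallMask(tissue) & !lesionMask(tissue)
  idx <- which(active)
  n <- length(idx)
  rank <- integer(prod(dm)); rank[idx] <- seq_len(n)
  coords <- arrayInd(idx, dm)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  nb <- matrix(-1L, n, 6)
  Dface <- matrix(0, n, 6)
  Dv <- diffusion(tissue)[idx]
  for (f in 1:6) {
    lin <- .linIndex(sweep(coords, 2, offs[f, ], "+"), dm)
    ok <- !is.na(lin)
    ok[ok] <- active[lin[ok]]
    nb[ok, f] <- rank[lin[ok]] - 1L  # 0-based for C++
    Dj <- diffusion(tissue)[lin[ok]]
    Di <- Dv[ok]
    Dface[ok, f] <- if (faceScheme == "arithmetic") (Di + Dj) / 2 else
      ifelse(Di + Dj > 0, 2 * Di * Dj / (Di + Dj), 0)
    Dface[ok, f][Di == 0 | Dj == 0] <- 0  # no-flux across D = 0 faces
  }
  list(nb = nb, Dface = Dface, idx = idx, rank = rank, n = n)
}

#' Heterogeneous-D Laplacian of a field
#'
#' 7-point finite-difference divergence of D grad(u) with face diffusivity
#' the arithmetic (or harmonic) mean of the adjacent voxels' D, and
#' zero-flux faces at the wall boundary and across D = 0 (lesion) faces.
#'
#' @param u numeric array (full grid).
#' @param tissue [TissueModel-class].
#' @param faceScheme "arithmetic" (default) or "harmonic".
#' @return numeric array, zero outside the active set.
#' @export
laplacianField <- function(u, tissue, faceScheme = "arithmetic") {
  sa <- .solverArrays(tissue, faceScheme)
  out <- array(0, dim(u))
  out[sa$idx] <- .het_laplacian(sa$nb, sa$Dface, u[sa$idx], spacing(tissue))
  out
}

#' Run a monodomain simulation
#'
#' Explicit-Euler integration of the Fenton-Karma monodomain model on the
#' active voxel set of `tissue`. Refuses to run when the CFL condition
#' max(D) dt / dx^2 <= 1/6 is violated; aborts with the time index when a
#' non-finite state is detected.
#'
#' @param tissue [TissueModel-class].
#' @param cfg [SolverConfig-class].
#' @param params [AFKParams-class].
#' @param init optional initial [CellStateField-class] (defaults to rest);
#'   used to continue runs (e.g. after [applyLesions()]).
#' @param reaction logical; FALSE integrates diffusion only (testing).
#' @param faceScheme face-diffusivity scheme, see [laplacianField()].
#' @param t0 start time, ms (recording timestamps are offset by it).
#' @return a [Recording-class].
#' @export
runSimulation <- function(tissue, cfg, params, init = NULL, reaction = TRUE,
                          faceScheme = "arithmetic", t0 = 0) {
  stopifnot(is(tissue, "TissueModel"), is(cfg, "SolverConfig"))
  dmax <- max(diffusion(tissue))
  if (dmax > 0 && cfg@dt > cflLimit(dmax, spacing(tissue)) + 1e-12)
    stop(sprintf(
      "CFL violation: dt = %g ms exceeds the stable limit %g ms (max D = %g, dx = %g)",
      cfg@dt, cflLimit(dmax, spacing(tissue)), dmax, spacing(tissue)))
  dm <- dim(wallMask(tissue))
  if (is.null(init)) init <- restState(dm)
  sa <- .solverArrays(tissue, faceScheme)
  stims <- lapply(cfg@stimuli, function(s) {
    ar <- sa$rank[s@idx]
    list(onset = s@onset, duration = s@duration, amplitude = s@amplitude,
         idx = as.integer(ar[ar > 0] - 1L))
  })
  r <- .fk_run(sa$nb, sa$Dface, init@u[sa$idx], init@v[sa$idx],
               init@w[sa$idx], .paramsList(params), spacing(tissue),
               cfg@dt, cfg@duration, cfg@recordInterval, stims,
               reaction, t0)
  fu <- array(0, dm); fv <- array(1, dm); fw <- array(1, dm)
  fu[sa$idx] <- r$u; fv[sa$idx] <- r$v; fw[sa$idx] <- r$w
  new("Recording", uSnaps = r$u_snaps, times = r$times,
      activeIdx = as.integer(sa$idx), dims = as.integer(dm),
      dx = spacing(tissue),
      finalState = new("CellStateField", u = fu,
                       v = pmin(pmax(fv, 0), 1), w = pmin(pmax(fw, 0), 1)),
      meta = list(dt = cfg@dt, recordInterval = cfg@recordInterval,
                  seed = cfg@seed, paramsHash = .hashConfig(.paramsList(params))))
}

#' Extract one snapshot as a 3-D array
#' @param recording a [Recording-class].
#' @param t time, ms (nearest snapshot is used).
#' @return numeric array of u over the full grid (rest value 0 outside the
#'   active set).
#' @export
frameAt <- function(recording, t) {
  i <- which.min(abs(recording@times - t))
  out <- array(0, recording@dims)
  out[recording@activeIdx] <- recording@uSnaps[, i]
  out
}

#' Write a recording to disk
#'
#' Stores the u snapshots as a single 4-D NIfTI volume (or a stack of 3-D
#' volumes) plus a JSON metadata sidecar (dt, dx, record interval,
#' parameter hash).
#'
#' @param recording a [Recording-class].
#' @param path output path without extension.
#' @param fourD write one 4-D file (default) or one 3-D file per snapshot.
#' @return invisibly, the paths written.
#' @export
writeRecording <- function(recording, path, fourD = TRUE) {
  dm <- recording@dims
  nt <- length(recording@times)
  paths <- character(0)
  if (fourD) {
    arr <- array(0, c(dm, nt))
    for (i in seq_len(nt))
      arr[, , , i][recording@activeIdx] <- recording@uSnaps[, i]
    f <- paste0(path, ".nii.gz")
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(rep(recording@dx, 3),
                             diff(recording@times[1:2]))
    RNifti::writeNifti(img, f)
    paths <- f
  } else {
    for (i in seq_len(nt)) {
      a <- array(0, dm); a[recording@activeIdx] <- recording@uSnaps[, i]
      f <- sprintf("%s_%04d.nii.gz", path, i)
      img <- RNifti::asNifti(a)
      RNifti::pixdim(img) <- rep(recording@dx, 3)
      RNifti::writeNifti(img, f)
      paths <- c(paths, f)
    }
  }
  meta <- c(recording@meta, list(times = recording@times, dx = recording@dx))
  jf <- paste0(path, ".json")
  jsonlite::write_json(meta, jf, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jf))
}
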