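## Virtual catheter ablation: lesion geometry, application, and outcome
## classification.

## Make a lesion seed transmural: every wall voxel whose nearest
## endocardial-surface projection coincides with that of a seed voxel is
## included. Falls back to the seed when no blood pool is available
## (sheets are single-voxel thick already).
.transmuralize <- function(seed, tissue) {
  bp <- tissue@meta$bloodPool
  if (is.null(bp) || !any(seed)) return(seed)
  wall <- wallMask(tissue)
  cols <- tissue@meta$wallColumns
  if (is.null(cols)) cols <- .wallColumns(wall, bp)
  seedCols <- unique(cols$colId[which(seed)])
  out <- array(FALSE, dim(wall))
  w <- which(wall)
  out[w] <- cols$colId[w] %in% seedCols
  out | seed
}

## Circumferential band around one opening center: wall voxels whose
## Euclidean distance to the center lies in [r0, r0 + 3 mm].
.ringMask <- function(tissue, center, r0) {
  dm <- dim(wallMask(tissue)); dx <- spacing(tissue)
  idx <- which(wallMask(tissue))
  d <- sqrt(rowSums(sweep(.voxCoords(idx, dm, dx), 2, center, "-")^2))
  out <- array(FALSE, dm)
  out[idx[d >= r0 & d <= r0 + 3]] <- TRUE
  out
}

## Rasterized 3 mm-wide lesion line along a voxel path.
.lineMask <- function(tissue, pathIdx) {
  dm <- dim(wallMask(tissue))
  m <- array(FALSE, dm)
  m[pathIdx] <- TRUE
  dilateMask(m, 1.5, spacing(tissue)) & wallMask(tissue)
}

## Anatomical-boundary voxels: wall voxels on the rims of the PV and MV
## openings (adjacent to the carved opening volume when available,
## otherwise the inner edges of the PV/MV bands).
.boundaryVoxels <- function(tissue) {
  wall <- wallMask(tissue)
  carved <- tissue@meta$carved
  if (!is.null(carved)) return(surfaceVoxels(wall, against = carved))
  which(pvMask(tissue) | mvMask(tissue))
}

#' Build an ablation lesion set for one strategy
#'
#' Five strategies of transmural, 3 mm-wide unexcitable lesions:
#' \enumerate{
#'   \item circumferential rings around the PV openings (PVI);
#'   \item PVI plus a roof line joining the left and right rings and a
#'     line from the roof to the mitral opening;
#'   \item 3 mm cylinders tiling each target area;
#'   \item strategy 3 plus a geodesic connector line from each TA to the
#'     nearest PV or MV boundary;
#'   \item strategy 4 plus the strategy-1 rings.
#' }
#' Construction is additive: the masks are nested 3 subset 4 subset 5.
#'
#' @param tissue a [TissueModel-class] (an LA shell with PV/MV openings).
#' @param tas a [TargetAreaSet-class]; required for strategies 3-5.
#' @param strategy_id integer 1-5.
#' @return a [LesionSet-class].
#' @export
buildStrategy <- function(tissue, tas = NULL, strategy_id) {
  stopifnot(strategy_id %in% 1:5)
  if (strategy_id >= 3 && is.null(tas))
    stop("strategies 3-5 require a TargetAreaSet")
  dm <- dim(wallMask(tissue)); dx <- spacing(tissue)
  comps <- list()
  empty <- array(FALSE, dm)

  pviRings <- function() {
    spec <- tissue@meta$spec
    r0 <- (if (!is.null(spec)) spec$pv_radius else 5) + 2
    rings <- empty
    for (k in seq_len(nrow(pvCenters(tissue))))
      rings <- rings | .ringMask(tissue, pvCenters(tissue)[k, ], r0)
    rings
  }
  if (strategy_id %in% c(1, 2)) comps$pvi_rings <- pviRings()
  if (strategy_id == 2) {
    rings <- comps$pvi_rings
    ringIdx <- which(rings)
    xyz <- .voxCoords(ringIdx, dm, dx)
    cen <- tissue@meta$center %||% (dm / 2 * dx)
    left <- ringIdx[xyz[, 1] < cen[1]]
    right <- ringIdx[xyz[, 1] >= cen[1]]
    ## roof line: highest-z representative of each side, joined geodesically
    topOf <- function(ix) ix[which.max(.voxCoords(ix, dm, dx)[, 3])]
    wall <- wallMask(tissue)
    roofPath <- geodesicPath(wall, topOf(left), topOf(right), dx)
    comps$roof_line <- .lineMask(tissue, roofPath)
    mvIdx <- which(mvMask(tissue))
    if (length(mvIdx)) {
      dMV <- geodesicDistance(wall, mvIdx, dx)
      start <- roofPath[which.min(dMV[roofPath])]
      mvPath <- geodesicPath(wall, start, mvIdx[which.min(
        sqrt(rowSums(sweep(.voxCoords(mvIdx, dm, dx), 2,
                           .voxCoords(start, dm, dx)[1, ], "-")^2)))], dx)
      comps$mv_line <- .lineMask(tissue, mvPath)
    }
  }
  if (strategy_id >= 3) {
    taMask <- taLabels(tas) > 0
    comps$ta_cylinders <- dilateMask(taMask, 1.5, dx) & wallMask(tissue)
  }
  if (strategy_id >= 4) {
    bnd <- .boundaryVoxels(tissue)
    if (!length(bnd)) stop("no anatomical boundary reachable")
    wall <- wallMask(tissue)
    lab <- taLabels(tas)
    cvoxs <- vapply(seq_len(taCount(tas)), function(k) {
      taIdx <- which(lab == k)
      xyz <- .voxCoords(taIdx, dm, dx)
      taIdx[which.min(rowSums(sweep(xyz, 2, colMeans(xyz), "-")^2))]
    }, integer(1))
    if (length(cvoxs)) {
      ## one Dijkstra from a virtual node attached to every boundary voxel
      ## yields, for each TA centroid, the shortest path to the nearest
      ## PV/MV rim
      e <- .maskEdges(wall, 26L)
      nW <- length(e$idx)
      g <- igraph::make_graph(rbind(e$from, e$to), n = nW + 1L,
                              directed = FALSE)
      igraph::E(g)$weight <- e$weight * dx
      src <- unique(e$rank[bnd]); src <- src[src > 0]
      g <- igraph::add_edges(g, rbind(rep(nW + 1L, length(src)), src),
                             weight = rep(0, length(src)))
      paths <- igraph::shortest_paths(g, from = nW + 1L,
                                      to = e$rank[cvoxs])$vpath
      conn <- empty
      for (k in seq_along(paths)) {
        pk <- as.integer(paths[[k]])
        pk <- pk[pk <= nW]
        if (length(pk) < 1)
          stop(sprintf("no boundary reachable from TA %d", k))
        conn <- conn | .lineMask(tissue, e$idx[pk])
      }
      comps$connector_lines <- conn
    } else comps$connector_lines <- empty
  }
  if (strategy_id == 5) comps$pvi_rings <- pviRings()

  mask <- Reduce(`|`, comps, empty)
  mask <- .transmuralize(mask, tissue) & wallMask(tissue)
  new("LesionSet", mask = mask, strategyId = as.integer(strategy_id),
      components = comps,
      ablatedPercent = 100 * sum(mask) / sum(wallMask(tissue)))
}

#' Apply ablation lesions to a tissue model
#'
#' Lesion voxels become unexcitable: D = 0 and the membrane is clamped at
#' rest (they are removed from the active solver set). When a running
#' state is supplied it is returned with the lesion voxels reset to rest,
#' so lesions can be applied instantaneously mid-simulation.
#'
#' @param tissue a [TissueModel-class].
#' @param lesions a [LesionSet-class] (or logical mask).
#' @param state optional [CellStateField-class] of a running simulation.
#' @return the ablated tissue, or (when `state` is given) a list
#'   `list(tissue =, state =)`.
#' @export
applyLesions <- function(tissue, lesions, state = NULL) {
  mask <- if (is(lesions, "LesionSet")) lesionMask(lesions) else lesions
  newLesion <- lesionMask(tissue) | (mask & wallMask(tissue))
  D <- diffusion(tissue)
  D[newLesion] <- 0
  out <- tissueModel(wallMask(tissue), D = D, dx = spacing(tissue),
                     labels = tissueLabels(tissue),
                     pvCenters = pvCenters(tissue), pvMask = pvMask(tissue),
                     mvMask = mvMask(tissue), lesionMask = newLesion,
                     meta = tissue@meta)
  if (is.null(state)) return(out)
  state@u[newLesion] <- 0
  state@v[newLesion] <- 1
  state@w[newLesion] <- 1
  list(tissue = out, state = state)
}

#' Dominant-frequency map and mean frequency
#'
#' Per-voxel dominant frequency (DF): the spectral-peak frequency of the
#' mean-removed u(t) over the analysis window (rectangular window, FFT).
#' The mean frequency (MF) averages DF over wall voxels whose
#' peak-to-peak amplitude exceeds `floor`; quiescent recordings (no voxel
#' above the floor) report MF = 0 with `quiescent = TRUE`.
#'
#' @param recording a [Recording-class] sampled at >= 200 Hz.
#' @param window analysis window at the end of the recording, ms
#'   (default 1000; must cover two periods of 3 Hz).
#' @param floor amplitude floor on u (default 0.05).
#' @return list with `mf` (Hz), `df` (numeric array of per-voxel DF, NA
#'   below floor), and `quiescent`.
#' @export
meanFrequency <- function(recording, window = 1000, floor = 0.05) {
  if (window < 2 / 3 * 1000)
    stop("window must cover at least two periods of 3 Hz (>= 667 ms)")
  tt <- recording@times
  dtms <- stats::median(diff(tt))
  if (dtms > 5 + 1e-9) stop("recording must be sampled at >= 200 Hz")
  sel <- which(tt >= max(tt) - window)
  n <- length(sel)
  U <- recording@uSnaps[, sel, drop = FALSE]
  amp <- apply(U, 1, max) - apply(U, 1, min)
  good <- which(amp > floor)
  dfArr <- array(NA_real_, recording@dims)
  if (!length(good))
    return(list(mf = 0, df = dfArr, quiescent = TRUE))
  freqs <- (seq_len(n) - 1) / (n * dtms) * 1000  # Hz
  kmax <- floor(n / 2)
  band <- 2:kmax                                 # exclude DC
  X <- stats::mvfft(t(U[good, , drop = FALSE] -
                        rowMeans(U[good, , drop = FALSE])))
  pk <- band[apply(abs(X[band, , drop = FALSE]), 2, which.max)]
  dfv <- freqs[pk]
  dfArr[recording@activeIdx[good]] <- dfv
  list(mf = mean(dfv), df = dfArr, quiescent = FALSE)
}

## Persistent trajectories: those surviving through the final `window` ms.
.persistent <- function(trajs, end, window = 1000) {
  Filter(function(tr) max(tipSamples(tr)$t) >= end - 0.05 * window &&
           (end - min(tipSamples(tr)$t)) >= window * 0.5, trajs)
}

## Fraction of active voxels still activating near the end of a recording.
## A rotor pinned around an unexcitable obstacle (anatomical re-entry) has
## its phase singularity inside the hole, invisible to the tip detector;
## sustained activity without free-wall tips therefore indicates an
## obstacle-anchored re-entry, not termination.
.residualActivity <- function(recording, window = 300, floor = 0.2) {
  tt <- recording@times
  sel <- which(tt >= max(tt) - window)
  U <- recording@uSnaps[, sel, drop = FALSE]
  amp <- apply(U, 1, max) - apply(U, 1, min)
  mean(amp > floor)
}

#' Classify the outcome of an ablation
#'
#' Tracks RDs in the post-ablation recording: "terminated" when no
#' trajectory survives the final second; "at" (atrial tachycardia) when
#' exactly one survives and its last-second positions stay within
#' `anchor_mm` of lesion, PV or MV voxels (a single RD anchored to scar
#' or an anatomical boundary); otherwise "unaffected". Mean frequencies
#' before and after are attached.
#'
#' @param preRec,postRec [Recording-class] before and after lesion
#'   application (post recording at least 2 s).
#' @param tissue the ablated [TissueModel-class].
#' @param lesions the applied [LesionSet-class].
#' @param anchor_mm anchoring radius (default 5 mm, half the lesion-ring
#'   width).
#' @param mf_window MF analysis window, ms.
#' @return an [AblationOutcome-class].
#' @export
evaluateOutcome <- function(preRec, postRec, tissue, lesions,
                            anchor_mm = 5, mf_window = 1000) {
  endPre <- max(preRec@times); endPost <- max(postRec@times)
  preTr <- .persistent(trackTips(preRec), endPre)
  postTr <- .persistent(trackTips(postRec), endPost)
  mfB <- meanFrequency(preRec, mf_window)$mf
  mfA <- meanFrequency(postRec, mf_window)$mf
  nB <- length(preTr); nA <- length(postTr)
  cls <- "unaffected"
  if (nA == 0) {
    if (.residualActivity(postRec) > 0.05) {
      ## activity persists with no free-wall singularity: a single
      ## obstacle-anchored (anatomical) re-entry, i.e. AT
      cls <- "at"; nA <- 1L
    } else cls <- "terminated"
  }
  else if (nA == 1) {
    anchorMask <- lesionMask(lesions) | pvMask(tissue) | mvMask(tissue)
    aIdx <- which(anchorMask)
    if (length(aIdx)) {
      axyz <- .voxCoords(aIdx, dim(wallMask(tissue)), spacing(tissue))
      s <- tipSamples(postTr[[1]])
      s <- s[s$t >= endPost - 1000, , drop = FALSE]
      dmin <- vapply(seq_len(nrow(s)), function(i)
        min(sqrt((axyz[, 1] - s$x[i])^2 + (axyz[, 2] - s$y[i])^2 +
                   (axyz[, 3] - s$z[i])^2)), numeric(1))
      if (all(dmin <= anchor_mm)) cls <- "at"
    }
  }
  new("AblationOutcome", classification = cls,
      nRDsBefore = as.integer(nB), nRDsAfter = as.integer(nA),
      mfBefore = mfB, mfAfter = mfA,
      mfReductionPercent = if (mfB > 0) 100 * (mfB - mfA) / mfB else NA_real_)
}

#' Re-inducibility test after ablation
#'
#' Repeats the initiation protocol from `n_sites` sites on the ablated
#' tissue and classifies each attempt: "no_af" (no persistent RD), "at"
#' (one persistent RD anchored to scar or boundary) or "af" (otherwise).
#'
#' @param tissue ablated [TissueModel-class] (lesions applied).
#' @param lesions the [LesionSet-class] in effect.
#' @param params [AFKParams-class].
#' @param n_sites number of initiation sites (default 10).
#' @param seed integer site-sampling seed.
#' @param duration per-run duration, ms.
#' @param dt time step, ms.
#' @param anchor_mm anchoring radius for the AT call.
#' @return data.frame with columns site_id, outcome, n_rds, mf.
#' @export
reinducibilityTest <- function(tissue, lesions, params, n_sites = 10,
                               seed = 1L, duration = 2000, dt = 0.02,
                               anchor_mm = 5, recordInterval = 5) {
  plans <- enumerateSites(tissue, n_sites, seed)
  anchorMask <- lesionMask(tissue) | pvMask(tissue) | mvMask(tissue)
  aIdx <- which(anchorMask)
  axyz <- if (length(aIdx))
    .voxCoords(aIdx, dim(wallMask(tissue)), spacing(tissue)) else NULL
  rows <- lapply(plans, function(pl) {
    rec <- runPlan(tissue, pl, params, duration = duration, dt = dt,
                   recordInterval = recordInterval)
    endT <- max(rec@times)
    per <- .persistent(trackTips(rec), endT)
    mfw <- min(1000, duration)
    mf <- if (mfw >= 667) meanFrequency(rec, mfw)$mf else NA_real_
    outcome <- "af"
    if (length(per) == 0)
      outcome <- if (.residualActivity(rec) > 0.05) "at" else "no_af"
    else if (length(per) == 1 && !is.null(axyz)) {
      s <- tipSamples(per[[1]])
      s <- s[s$t >= endT - 1000, , drop = FALSE]
      dmin <- vapply(seq_len(nrow(s)), function(i)
        min(sqrt((axyz[, 1] - s$x[i])^2 + (axyz[, 2] - s$y[i])^2 +
                   (axyz[, 3] - s$z[i])^2)), numeric(1))
      if (all(dmin <= anchor_mm)) outcome <- "at"
    }
    data.frame(site_id = pl$site_id, outcome = outcome,
               n_rds = length(per), mf = mf)
  })
  do.call(rbind, rows)
}
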