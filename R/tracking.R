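## Phase-singularity detection and RD tip tracking.

.wrapPi <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Detect RD tips (phase singularities) in a snapshot pair
#'
#' Time-delay-embedding phase mapping: per voxel the activation phase is
#' theta = atan2(u(t - tau) - u*, u(t) - u*); a tip sits where the
#' line integral of grad(theta) around a 2x2 voxel plaquette is +/- 2 pi.
#' 3-D walls are processed layer-wise along z and tips within
#' `cluster_mm` are merged into filaments whose centroid is reported.
#'
#' @param uNow,uDelayed numeric arrays (full grid), two snapshots
#'   separated by the embedding delay.
#' @param wallMask logical array.
#' @param dx spacing, mm.
#' @param uStar phase-space origin (default 0.5).
#' @param cluster_mm transmural clustering radius (default 3 mm, the wall
#'   thickness).
#' @return data.frame with columns x, y, z (mm) and chirality (+1/-1);
#'   zero rows when no singularity is present.
#' @export
detectTips <- function(uNow, uDelayed, wallMask, dx, uStar = 0.5,
                       cluster_mm = 3) {
  dm <- dim(uNow)
  raw <- .detect_tips_raw(as.vector(uNow), as.vector(uDelayed),
                          as.vector(wallMask), as.integer(dm), dx, uStar)
  if (!nrow(raw))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      chirality = integer(0)))
  tips <- data.frame(x = raw[, 1], y = raw[, 2], z = raw[, 3],
                     chirality = as.integer(raw[, 4]))
  if (dm[3] == 1L || nrow(tips) == 1L) return(tips)
  ## cluster across layers into filaments (same chirality, within radius)
  dmat <- as.matrix(stats::dist(tips[, c("x", "y", "z")]))
  same <- outer(tips$chirality, tips$chirality, "==")
  adj <- dmat <= cluster_mm & same
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  mem <- igraph::components(g)$membership
  agg <- lapply(split(seq_len(nrow(tips)), mem), function(rows) {
    data.frame(x = mean(tips$x[rows]), y = mean(tips$y[rows]),
               z = mean(tips$z[rows]),
               chirality = as.integer(sign(sum(tips$chirality[rows]))))
  })
  do.call(rbind, agg)
}

#' Isoline-intersection tip detector (cross-check)
#'
#' Finds plaquettes crossed by both the u = uStar isoline of the current
#' frame and the zero isoline of the inter-frame difference (du/dt = 0),
#' the classical optical-mapping tip definition. Coarser than
#' [detectTips()] (no sub-plaquette chirality), used as an independent
#' detector in validation.
#'
#' @inheritParams detectTips
#' @return data.frame with columns x, y, z (mm).
#' @export
detectTipsIsoline <- function(uNow, uDelayed, wallMask, dx, uStar = 0.5) {
  dm <- dim(uNow)
  f <- uNow - uStar
  g <- uNow - uDelayed
  f[!wallMask] <- NA_real_; g[!wallMask] <- NA_real_
  res <- list()
  for (k in seq_len(dm[3])) {
    fk <- f[, , k, drop = TRUE]; gk <- g[, , k, drop = TRUE]
    nx <- nrow(fk); ny <- ncol(fk)
    if (nx < 2 || ny < 2) next
    corners <- function(m) list(m[-nx, -ny], m[-1, -ny], m[-1, -1], m[-nx, -1])
    cf <- corners(fk); cg <- corners(gk)
    mixed <- function(cs) {
      mx <- pmax(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
      mn <- pmin(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
      !is.na(mx) & !is.na(mn) & mx > 0 & mn < 0
    }
    hit <- which(mixed(cf) & mixed(cg))
    if (!length(hit)) next
    ij <- arrayInd(hit, c(nx - 1L, ny - 1L))
    res[[k]] <- data.frame(x = ij[, 1] * dx, y = ij[, 2] * dx,
                           z = (k - 0.5) * dx)
  }
  if (!length(res)) return(data.frame(x = numeric(0), y = numeric(0),
                                      z = numeric(0)))
  do.call(rbind, res)
}

#' Track RD tips through a recording
#'
#' Detects tips in every snapshot (delay-embedded against the frame
#' `tau` ms earlier) and associates them across frames by minimal total
#' displacement (Hungarian assignment via `clue`), gated by `gate_mm` and
#' chirality compatibility. Trajectories shorter than `min_ms` are
#' discarded as detection noise.
#'
#' @param recording a [Recording-class] with frame interval <= 5 ms.
#' @param tau embedding delay, ms (default 10).
#' @param gate_mm association gating radius per frame (default 5 mm).
#' @param min_ms minimum trajectory duration, ms (default 50).
#' @param uStar phase origin (default 0.5).
#' @param max_gap_ms tolerated detection drop-out before a trajectory is
#'   closed (default 30 ms); the gating radius grows with the gap.
#' @return list of [TipTrajectory-class] (finalRegion "unclassified";
#'   see [classifyFinalLocation()]).
#' @export
trackTips <- function(recording, tau = 10, gate_mm = 5, min_ms = 50,
                      uStar = 0.5, max_gap_ms = 30) {
  tt <- recording@times
  frameInt <- stats::median(diff(tt))
  if (frameInt > 5 + 1e-9)
    stop("frame interval must be <= 5 ms for tracking")
  lag <- max(1L, round(tau / frameInt))
  dm <- recording@dims
  mask <- array(FALSE, dm); mask[recording@activeIdx] <- TRUE

  live <- list()    # open trajectories: list(rows = data.frame, missed = n)
  done <- list()
  ## ring buffer of reconstructed frames (each frame is built once)
  ring <- vector("list", lag + 1L)
  frameArr <- function(i) {
    a <- array(0, dm); a[recording@activeIdx] <- recording@uSnaps[, i]; a
  }
  for (i in seq_len(lag)) ring[[(i - 1L) %% (lag + 1L) + 1L]] <- frameArr(i)
  for (i in seq((lag + 1L), length(tt))) {
    ring[[(i - 1L) %% (lag + 1L) + 1L]] <- frameArr(i)
    tips <- detectTips(ring[[(i - 1L) %% (lag + 1L) + 1L]],
                       ring[[(i - lag - 1L) %% (lag + 1L) + 1L]],
                       mask, recording@dx, uStar = uStar)
    nT <- nrow(tips); nL <- length(live)
    assignLive <- rep(NA_integer_, nT)
    if (nT > 0 && nL > 0) {
      last <- do.call(rbind, lapply(live, function(l)
        l$rows[nrow(l$rows), c("x", "y", "z", "chirality")]))
      cost <- matrix(1e6, nL, nT)
      for (a in seq_len(nL)) for (b in seq_len(nT)) {
        d <- sqrt(sum((as.numeric(last[a, 1:3]) -
                         as.numeric(tips[b, 1:3]))^2))
        gate <- gate_mm * (1 + live[[a]]$missed)
        if (d <= gate && last$chirality[a] == tips$chirality[b])
          cost[a, b] <- d
      }
      sol <- if (nL <= nT) clue::solve_LSAP(cost) else
        clue::solve_LSAP(t(cost))
      if (nL <= nT) {
        for (a in seq_len(nL))
          if (cost[a, sol[a]] < 1e5) assignLive[sol[a]] <- a
      } else {
        for (b in seq_len(nT))
          if (cost[sol[b], b] < 1e5) assignLive[b] <- sol[b]
      }
    }
    matchedLive <- stats::na.omit(assignLive)
    ## extend matched, start new, coast or close unmatched
    newLive <- list()
    for (b in seq_len(nT)) {
      row <- data.frame(t = tt[i], x = tips$x[b], y = tips$y[b],
                        z = tips$z[b], chirality = tips$chirality[b])
      if (!is.na(assignLive[b])) {
        l <- live[[assignLive[b]]]
        l$rows <- rbind(l$rows, row)
        l$missed <- 0L
        newLive[[length(newLive) + 1L]] <- l
      } else {
        newLive[[length(newLive) + 1L]] <- list(rows = row, missed = 0L)
      }
    }
    maxMiss <- max(1L, round(max_gap_ms / frameInt))
    if (nL > 0) for (a in setdiff(seq_len(nL), matchedLive)) {
      l <- live[[a]]
      l$missed <- l$missed + 1L
      if (l$missed > maxMiss) done[[length(done) + 1L]] <- l
      else newLive[[length(newLive) + 1L]] <- l
    }
    live <- newLive
  }
  done <- c(done, live)
  trajs <- list()
  for (k in seq_along(done)) {
    rows <- done[[k]]$rows
    if (nrow(rows) < 2) next
    if (max(rows$t) - min(rows$t) < min_ms) next
    trajs[[length(trajs) + 1L]] <- new(
      "TipTrajectory", runId = as.character(recording@meta$site_id %||% "run"),
      samples = rows, finalRegion = "unclassified")
  }
  trajs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify where an RD stabilized
#'
#' Majority vote over the per-sample region in the last `window` ms of the
#' recording: a sample is "pv" inside a PV 3 mm spherical region, else
#' "fibrosis" on a border-zone or dense voxel, else "healthy"; exact ties
#' resolve with precedence pv > fibrosis > healthy. A trajectory that dies
#' before the window is "extinguished".
#'
#' @param traj a [TipTrajectory-class].
#' @param tissue a [TissueModel-class].
#' @param window ms (default 1000).
#' @param end end time of the recording, ms; defaults to the last
#'   trajectory sample.
#' @return the trajectory with `finalRegion` set.
#' @export
classifyFinalLocation <- function(traj, tissue, window = 1000, end = NULL) {
  s <- tipSamples(traj)
  if (is.null(end)) end <- max(s$t)
  if (max(s$t) < end - window) {
    traj@finalRegion <- "extinguished"
    return(traj)
  }
  sel <- s[s$t >= end - window, , drop = FALSE]
  dm <- dim(wallMask(tissue)); dx <- spacing(tissue)
  vox <- cbind(pmin(pmax(ceiling(sel$x / dx), 1L), dm[1]),
               pmin(pmax(ceiling(sel$y / dx), 1L), dm[2]),
               pmin(pmax(ceiling(sel$z / dx), 1L), dm[3]))
  lin <- .linIndex(vox, dm)
  lab <- tissueLabels(tissue)[lin]
  region <- ifelse(pvMask(tissue)[lin], "pv",
                   ifelse(!is.na(lab) & lab >= 1L, "fibrosis", "healthy"))
  counts <- c(pv = sum(region == "pv"), fibrosis = sum(region == "fibrosis"),
              healthy = sum(region == "healthy"))
  traj@finalRegion <- names(counts)[which.max(counts)]  # precedence by order
  traj
}

#' Tip-visit frequency map
#'
#' Increments, for each tip sample of each trajectory, the voxel
#' containing the tip.
#'
#' @param trajs list of [TipTrajectory-class].
#' @param tissue a [TissueModel-class] (grid reference).
#' @return a [TipFrequencyMap-class].
#' @export
buildTipFrequencyMap <- function(trajs, tissue) {
  dm <- dim(wallMask(tissue)); dx <- spacing(tissue)
  counts <- array(0L, dm)
  total <- 0L
  for (tr in trajs) {
    s <- tipSamples(tr)
    vox <- cbind(pmin(pmax(ceiling(s$x / dx), 1L), dm[1]),
                 pmin(pmax(ceiling(s$y / dx), 1L), dm[2]),
                 pmin(pmax(ceiling(s$z / dx), 1L), dm[3]))
    lin <- .linIndex(vox, dm)
    for (l in lin) counts[l] <- counts[l] + 1L
    total <- total + length(lin)
  }
  new("TipFrequencyMap", counts = counts, totalSamples = total)
}

#' Write trajectories to CSV
#' @param trajs list of [TipTrajectory-class].
#' @param path output CSV.
#' @return invisibly, `path`.
#' @export
writeTrajectories <- function(trajs, path) {
  rows <- do.call(rbind, lapply(trajs, function(tr) {
    s <- tipSamples(tr)
    cbind(run_id = tr@runId, s, final_region = finalRegion(tr))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
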