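#' Re-entrant driver initiation plan
#'
#' Describes one reproducible RD-initiation attempt: either cross-field
#' stimulation (an S1 plane wave followed by an S2 quadrant stimulus timed
#' into the S1 refractory tail) or ectopic pacing near a PV followed by a
#' plane wave.
#'
#' @param protocol "cross_field" or "pace_and_plane".
#' @param site voxel-center coordinate (mm) around which the plan is
#'   oriented (pacing site, or cross-field frame origin).
#' @param s1_direction unit vector of S1 plane-wave propagation.
#' @param s2_direction unit vector (orthogonal to s1) defining the S2
#'   half-space; defaults to an arbitrary orthogonal direction.
#' @param s2_delay S2 onset, ms after S1; NULL means "1.25 x APD90"
#'   (mid vulnerable window), resolved against the cell parameters at run
#'   time.
#' @param bcl basic cycle length for pacing, ms (default 130).
#' @param n_beats number of ectopic beats (default 7).
#' @param plane_delay delay of the plane wave after the last beat, ms
#'   (default 20).
#' @param site_id identifier.
#' @return a list of class `InitiationPlan`.
#' @export
initiationPlan <- function(protocol = c("cross_field", "pace_and_plane"),
                           site = c(0, 0, 0), s1_direction = c(1, 0, 0),
                           s2_direction = NULL, s2_delay = NULL,
                           bcl = 130, n_beats = 7, plane_delay = 20,
                           site_id = "site1") {
  protocol <- match.arg(protocol)
  stopifnot(bcl > 0, n_beats >= 1)
  s1 <- s1_direction / sqrt(sum(s1_direction^2))
  if (is.null(s2_direction)) {
    ## orthogonal direction in the plane normal to z where possible (so
    ## sheet fixtures get an in-plane S2 quadrant)
    ref <- if (abs(s1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    s2 <- c(ref[2] * s1[3] - ref[3] * s1[2],
            ref[3] * s1[1] - ref[1] * s1[3],
            ref[1] * s1[2] - ref[2] * s1[1])
  } else s2 <- s2_direction - sum(s2_direction * s1) * s1
  s2 <- s2 / sqrt(sum(s2^2))
  structure(list(protocol = protocol, site = site, s1_direction = s1,
                 s2_direction = s2, s2_delay = s2_delay, bcl = bcl,
                 n_beats = n_beats, plane_delay = plane_delay,
                 site_id = site_id),
            class = "InitiationPlan")
}

## Single-cell APD90 for the given parameters (used to time S2).
.apd90 <- function(params) {
  tr <- simulateCell(params, duration = 400, dt = 0.01)
  a <- apd(tr, 0.9)
  if (is.na(a)) stop("no action potential elicited for these parameters")
  a
}

#' Build cross-field stimuli
#'
#' S1: a plane stimulus on the 2 mm slab at the rear of the tissue along
#' the plan's S1 direction. S2: a half-space stimulus covering the
#' quadrant behind the S1 wavefront, delivered `s2_delay` ms after S1
#' (default 1.25 x single-cell APD90, mid vulnerable window). If S2
#' lands outside the vulnerable window no RD forms; that outcome is
#' reported downstream by the tracker, not raised here.
#'
#' @param tissue [TissueModel-class].
#' @param plan an [initiationPlan()].
#' @param params [AFKParams-class] (used to resolve the default S2 timing).
#' @return list of [StimulusSpec-class].
#' @export
buildCrossField <- function(tissue, plan, params) {
  dm <- dim(wallMask(tissue))
  dx <- spacing(tissue)
  idx <- which(wallMask(tissue))
  xyz <- .voxCoords(idx, dm, dx)
  p1 <- xyz %*% plan$s1_direction
  p2 <- xyz %*% plan$s2_direction
  ## the center of the vulnerable window sits past full single-cell
  ## repolarization because electrotonic coupling prolongs the tissue APD;
  ## 1.25 x APD90 lands mid-window for the shipped parameter set
  s2_delay <- if (is.null(plan$s2_delay)) 1.25 * .apd90(params) else plan$s2_delay
  s1idx <- idx[p1 <= min(p1) + 2]
  s2idx <- idx[p1 <= stats::median(p1) & p2 <= stats::median(p2)]
  list(new("StimulusSpec", onset = 0, duration = 1, amplitude = 0.6,
           idx = as.integer(s1idx)),
       new("StimulusSpec", onset = s2_delay, duration = 1, amplitude = 0.6,
           idx = as.integer(s2idx)))
}

#' Build an ectopic pacing + plane-wave protocol
#'
#' `n_beats` point stimuli (1.5 mm radius sphere at the pacing site) at
#' intervals of `bcl`, followed by a plane stimulus `plane_delay` ms after
#' the last beat.
#'
#' @param tissue [TissueModel-class].
#' @param pacing_site coordinate (mm); when the tissue has PV openings the
#'   site must lie within 10 mm of a PV rim.
#' @param bcl,n_beats,plane_delay see [initiationPlan()].
#' @param plane_direction direction of the closing plane wave.
#' @return list of [StimulusSpec-class].
#' @export
buildPacingPlan <- function(tissue, pacing_site, bcl = 130, n_beats = 7,
                            plane_delay = 20, plane_direction = c(1, 0, 0)) {
  dm <- dim(wallMask(tissue)); dx <- spacing(tissue)
  idx <- which(wallMask(tissue))
  xyz <- .voxCoords(idx, dm, dx)
  d2 <- rowSums(sweep(xyz, 2, pacing_site, "-")^2)
  siteIdx <- idx[d2 <= 1.5^2]
  if (!length(siteIdx)) stop("pacing site not inside the wall")
  if (any(lesionMask(tissue)[siteIdx])) stop("pacing site lies on a lesion")
  if (nrow(pvCenters(tissue)) > 0) {
    dpv <- min(sqrt(rowSums(sweep(pvCenters(tissue), 2, pacing_site, "-")^2)))
    if (dpv > 10 + spacing(tissue))
      stop("pacing site must lie within 10 mm of a PV opening")
  }
  beats <- lapply(seq_len(n_beats) - 1L, function(b)
    new("StimulusSpec", onset = b * bcl, duration = 1, amplitude = 0.6,
        idx = as.integer(siteIdx)))
  proj <- xyz %*% (plane_direction / sqrt(sum(plane_direction^2)))
  plane <- new("StimulusSpec", onset = (n_beats - 1) * bcl + plane_delay,
               duration = 1, amplitude = 0.6,
               idx = as.integer(idx[proj <= min(proj) + 2]))
  c(beats, list(plane))
}

#' Enumerate initiation sites by farthest-point sampling
#'
#' Deterministically (given `seed`) spreads `n_sites` initiation sites
#' over the wall, maximizing the minimum pairwise Euclidean distance, and
#' returns one [initiationPlan()] per site with a local orthogonal
#' stimulus frame.
#'
#' @param tissue [TissueModel-class].
#' @param n_sites number of sites (the study protocol uses 8-12).
#' @param seed integer.
#' @param protocol plan protocol (default "cross_field").
#' @return list of `InitiationPlan`s.
#' @export
enumerateSites <- function(tissue, n_sites = 10, seed = 1L,
                           protocol = "cross_field") {
  dm <- dim(wallMask(tissue)); dx <- spacing(tissue)
  idx <- which(wallMask(tissue) & !lesionMask(tissue))
  if (n_sites > length(idx)) stop("more sites requested than wall voxels")
  .withSeed(seed, {
    cand <- if (length(idx) > 4000) sort(sample(idx, 4000)) else idx
    xyz <- .voxCoords(cand, dm, dx)
    picked <- sample.int(nrow(xyz), 1)
    mind <- sqrt(rowSums(sweep(xyz, 2, xyz[picked, ], "-")^2))
    while (length(picked) < n_sites) {
      nxt <- which.max(mind)
      picked <- c(picked, nxt)
      mind <- pmin(mind, sqrt(rowSums(sweep(xyz, 2, xyz[nxt, ], "-")^2)))
    }
    cen <- if (!is.null(tissue@meta$center)) tissue@meta$center
           else dm / 2 * dx
    lapply(seq_along(picked), function(i) {
      p <- xyz[picked[i], ]
      d1 <- p - cen
      n1 <- sqrt(sum(d1^2))
      d1 <- if (n1 > 1e-9) d1 / n1 else c(1, 0, 0)
      initiationPlan(protocol = protocol, site = p, s1_direction = d1,
                     site_id = sprintf("site%02d", i))
    })
  })
}

#' Run an initiation plan
#'
#' Builds the stimuli for `plan`, runs the simulation for `duration` ms
#' and returns the [Recording-class]. Pure function of its inputs:
#' repeated calls are bit-identical.
#'
#' @param tissue [TissueModel-class].
#' @param plan an [initiationPlan()].
#' @param params [AFKParams-class].
#' @param duration ms.
#' @param dt time step, ms.
#' @param recordInterval snapshot interval, ms (default 5, the coarsest
#'   rate the tracker accepts; memory scales inversely with it).
#' @param init optional starting state.
#' @return a [Recording-class] with the plan id in `meta`.
#' @export
runPlan <- function(tissue, plan, params, duration = 2000, dt = 0.02,
                    recordInterval = 5, init = NULL) {
  stims <- switch(plan$protocol,
    cross_field = buildCrossField(tissue, plan, params),
    pace_and_plane = buildPacingPlan(tissue, plan$site, plan$bcl,
                                     plan$n_beats, plan$plane_delay,
                                     plan$s1_direction))
  cfg <- solverConfig(duration = duration, dt = dt,
                      recordInterval = recordInterval, stimuli = stims)
  rec <- runSimulation(tissue, cfg, params, init = init)
  rec@meta$site_id <- plan$site_id
  rec
}

#' Count captured beats at a probe ring
#'
#' Counts wavefronts emitted from a pacing site as upward threshold
#' crossings of u at probe voxels 5 mm from the site (median count over
#' probes).
#'
#' @param recording [Recording-class].
#' @param site pacing-site coordinate, mm.
#' @param radius probe ring radius, mm (default 5).
#' @param threshold activation threshold (default 0.5).
#' @return integer number of wavefronts observed.
#' @export
countCaptures <- function(recording, site, radius = 5, threshold = 0.5) {
  dm <- recording@dims; dx <- recording@dx
  xyz <- .voxCoords(recording@activeIdx, dm, dx)
  d <- sqrt(rowSums(sweep(xyz, 2, site, "-")^2))
  rows <- which(abs(d - radius) <= dx)
  if (!length(rows)) stop("no probe voxels at the requested radius")
  counts <- vapply(rows, function(r) {
    u <- recording@uSnaps[r, ]
    sum(u[-1] >= threshold & u[-length(u)] < threshold)
  }, integer(1))
  as.integer(round(stats::median(counts)))
}

#' Serialize initiation plans to JSON
#' @param plans list of `InitiationPlan`s.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePlans <- function(plans, path) {
  jsonlite::write_json(lapply(plans, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
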