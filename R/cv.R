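#' Measure planar conduction velocity on a strip recording
#'
#' Activation time at a plane is the median (over voxels within half a
#' voxel of the plane) of the first upward crossing of `threshold`,
#' linearly interpolated between snapshots. CV = plane separation /
#' activation-time difference, in m/s (mm/ms is numerically equal to m/s
#' in these units).
#'
#' @param recording a [Recording-class] from a strip simulation.
#' @param planes two x-positions (mm) at which activation is timed; they
#'   should be at least 10 mm apart and away from the stimulus and the far
#'   boundary.
#' @param threshold activation level on u (default 0.5).
#' @return a list with elements `cv` (m/s, NA when blocked), `blocked`
#'   (logical), and `t_planes` (the two activation times, ms).
#' @export
measureCV <- function(recording, planes = c(10, 20), threshold = 0.5) {
  dm <- recording@dims
  dx <- recording@dx
  xpos <- (arrayInd(recording@activeIdx, dm)[, 1] - 0.5) * dx
  tt <- recording@times
  tPlane <- rep(NA_real_, 2)
  for (p in 1:2) {
    rows <- which(abs(xpos - planes[p]) <= dx / 2 + 1e-9)
    if (!length(rows)) stop("no voxels at plane x = ", planes[p])
    tcross <- rep(NA_real_, length(rows))
    for (i in seq_along(rows)) {
      u <- recording@uSnaps[rows[i], ]
      k <- which(u[-1] >= threshold & u[-length(u)] < threshold)
      if (length(k)) {
        k <- k[1]
        frac <- (threshold - u[k]) / (u[k + 1] - u[k])
        tcross[i] <- tt[k] + frac * (tt[k + 1] - tt[k])
      }
    }
    if (all(is.na(tcross))) return(list(cv = NA_real_, blocked = TRUE,
                                        t_planes = tPlane))
    tPlane[p] <- stats::median(tcross, na.rm = TRUE)
  }
  dtms <- abs(tPlane[2] - tPlane[1])
  if (dtms <= 0) return(list(cv = NA_real_, blocked = TRUE, t_planes = tPlane))
  list(cv = abs(diff(planes)) / dtms, blocked = FALSE, t_planes = tPlane)
}

## One strip CV measurement for a given parameter set.
.stripCV <- function(params, D = 0.1, dx = 0.3, dt = 0.005,
                     duration = 150, planes = c(10, 20)) {
  tis <- makeStrip(30, 3, 0.9, dx = dx, D = D)
  stim <- stimulusSpec(tis, function(xyz) xyz[, 1] <= 1.5,
                       onset = 0, duration = 1, amplitude = 0.6)
  cfg <- solverConfig(duration = duration, dt = dt, recordInterval = 1,
                      stimuli = list(stim))
  rec <- runSimulation(tis, cfg, params)
  measureCV(rec, planes = planes)
}

#' Calibrate conduction velocity by tuning tau_d
#'
#' Bisection on `tau_d` (within \[0.05, 2\] ms) so that planar CV measured
#' on the reference strip (30 x 3 x 0.9 mm, D = 0.1 mm^2/ms, dx = 0.3 mm,
#' dt = 0.005 ms) matches `target` to within `tol` (relative). CV decreases
#' monotonically with `tau_d`.
#'
#' @param target target CV in m/s (the model default is 0.6, typical of
#'   AF-remodelled atria).
#' @param params starting [AFKParams-class]; all slots except `tau_d` are
#'   kept.
#' @param tol relative tolerance (default 0.01).
#' @param D,dx,dt reference-strip conditions.
#' @param range search bracket for tau_d, ms.
#' @return the calibrated [AFKParams-class], with attributes
#'   `measured_cv` (m/s) and `achievable` (the CV bracket) on failure the
#'   function stops and reports the achievable range.
#' @export
calibrateCV <- function(target, params = afkParams(), tol = 0.01,
                        D = 0.1, dx = 0.3, dt = 0.005,
                        range = c(0.05, 2)) {
  if (target <= 0) stop("target CV must be > 0")
  f <- function(tau) {
    m <- .stripCV(afkParams0 <- do.call(afkParams, utils::modifyList(
      .paramsList(params), list(set = "af1", tau_d = tau))),
      D = D, dx = dx, dt = dt)
    if (m$blocked) 0 else m$cv
  }
  ## current params already close?
  cv0 <- f(params@tau_d)
  if (abs(cv0 - target) <= tol * target) {
    out <- params; attr(out, "measured_cv") <- cv0; return(out)
  }
  lo <- range[1]; hi <- range[2]
  cvLo <- f(lo); cvHi <- f(hi)   # cvLo = fastest, cvHi = slowest
  if (target > cvLo || target < cvHi)
    stop(sprintf("target CV %.3f m/s unreachable; achievable range [%.3f, %.3f] m/s",
                 target, cvHi, cvLo))
  for (i in 1:40) {
    mid <- sqrt(lo * hi)
    cv <- f(mid)
    if (abs(cv - target) <= tol * target) {
      out <- do.call(afkParams, utils::modifyList(
        .paramsList(params), list(set = "af1", tau_d = mid)))
      attr(out, "measured_cv") <- cv
      return(out)
    }
    if (cv > target) lo <- mid else hi <- mid
  }
  stop("calibration did not converge")
}
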