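#' Atrial Fenton-Karma parameter sets
#'
#' Returns an [AFKParams-class] object. The default set `"af1"` is the
#' package's AF-remodelled atrial parameterization of the three-current
#' Fenton-Karma model: a short action potential (APD90 near 110 ms in the
#' single cell) that supports 1:1 capture at a basic cycle length of 130 ms
#' and sustains stable (non-breaking) spiral waves on 2-D sheets. Its
#' `tau_d` is a nominal value; before quantitative use it should be pinned
#' with [calibrateCV()] so that planar conduction velocity is 0.6 m/s at
#' D = 0.1 mm^2/ms and dx = 0.3 mm.
#'
#' @param set name of the base set (currently only `"af1"`).
#' @param ... named slot overrides (e.g. `tau_d = 0.2`).
#' @return an [AFKParams-class] object.
#' @export
#' @examples
#' p <- afkParams()
#' p2 <- afkParams(tau_d = 0.25)
afkParams <- function(set = "af1", ...) {
  sets <- list(
    af1 = list(
      tau_d = 0.1583, tau_r = 32, tau_si = 30, tau_0 = 12.5,
      tau_v_plus = 10, tau_v1_minus = 18.2, tau_v2_minus = 60,
      tau_w_plus = 1020, tau_w_minus = 80,
      u_c = 0.13, u_v = 0.025, u_c_si = 0.85, k = 10))
  if (!set %in% names(sets)) stop("unknown parameter set: ", set)
  vals <- utils::modifyList(sets[[set]], list(...))
  do.call(new, c(list(Class = "AFKParams"), vals))
}

.paramsList <- function(params) {
  stopifnot(is(params, "AFKParams"))
  sapply(slotNames(params), function(s) slot(params, s), simplify = FALSE)
}

#' One reaction (membrane) Euler step
#'
#' Advances the gates and returns the updated state for one explicit Euler
#' step of the Fenton-Karma reaction terms only (no diffusion). Gates are
#' clamped to \[0, 1\].
#'
#' @param state a [CellStateField-class] object.
#' @param params an [AFKParams-class] object.
#' @param dt time step, ms.
#' @return the updated [CellStateField-class].
#' @export
afkStep <- function(state, params, dt) {
  stopifnot(is(state, "CellStateField"), dt > 0)
  if (any(!is.finite(state@u)) || any(!is.finite(state@v)) ||
      any(!is.finite(state@w)))
    stop("non-finite values in cell state")
  r <- .fk_reaction_step(as.vector(state@u), as.vector(state@v),
                         as.vector(state@w), .paramsList(params), dt)
  dm <- dim(state@u)
  new("CellStateField", u = array(r$u, dm), v = array(r$v, dm),
      w = array(r$w, dm))
}

#' Cell state at rest
#' @param dims integer dimension of the grid.
#' @return a [CellStateField-class] at (u, v, w) = (0, 1, 1).
#' @export
restState <- function(dims) {
  dims <- as.integer(dims)
  new("CellStateField", u = array(0, dims), v = array(1, dims),
      w = array(1, dims))
}

#' Single-cell action potential
#'
#' Integrates the 0-D Fenton-Karma model with square current-like stimuli
#' on u.
#'
#' @param params [AFKParams-class].
#' @param duration ms.
#' @param dt ms.
#' @param stim_times onset times of the stimuli, ms.
#' @param stim_duration per-stimulus duration, ms.
#' @param stim_amplitude forcing amplitude on du/dt (1/ms).
#' @param record_every snapshot interval, ms.
#' @return data.frame with columns t, u, v, w.
#' @export
simulateCell <- function(params, duration = 500, dt = 0.005,
                         stim_times = 10, stim_duration = 1,
                         stim_amplitude = 0.6, record_every = 0.5) {
  r <- .fk_cell(.paramsList(params), dt, duration,
                as.numeric(stim_times),
                rep_len(stim_duration, length(stim_times)),
                rep_len(stim_amplitude, length(stim_times)),
                record_every, 0, 1, 1)
  data.frame(t = r$t, u = r$u, v = r$v, w = r$w)
}

#' APD at a repolarization fraction
#'
#' Action-potential duration from the last suprathreshold upstroke: time
#' from crossing `frac`-repolarization level on the upstroke until return
#' below it, where the level is `(1 - frac)` of the AP peak (APD90 uses
#' frac = 0.9).
#'
#' @param trace data.frame from [simulateCell()] (or any t/u data.frame).
#' @param frac repolarization fraction (default 0.9).
#' @return APD in ms (NA when no complete AP found).
#' @export
apd <- function(trace, frac = 0.9) {
  u <- trace$u; t <- trace$t
  peak <- max(u)
  if (peak < 0.4) return(NA_real_)
  lev <- (1 - frac) * peak
  above <- u >= lev
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- which(runs$values)
  if (!length(iv)) return(NA_real_)
  ## last completed suprathreshold run
  iv <- iv[ends[iv] < length(u)]
  if (!length(iv)) iv <- which(runs$values)
  i <- iv[length(iv)]
  t[ends[i]] - t[starts[i]]
}
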