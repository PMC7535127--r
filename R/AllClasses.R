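#' @import methods
NULL

#' Atrial Fenton-Karma cell-model parameters
#'
#' Parameter set for the three-current (fast inward, slow outward, slow
#' inward) Fenton-Karma membrane model with Heaviside gating, in the
#' normalized-voltage formulation (u = 0 rest, u = 1 peak). All time
#' constants are in ms; thresholds are dimensionless.
#'
#' @slot tau_d fast inward (depolarization) time constant, ms. This is the
#'   parameter tuned by [calibrateCV()] to pin conduction velocity.
#' @slot tau_r,tau_si,tau_0 repolarization, slow-inward and baseline outward
#'   time constants, ms.
#' @slot tau_v_plus,tau_v1_minus,tau_v2_minus fast-gate (v) time constants, ms.
#' @slot tau_w_plus,tau_w_minus slow-gate (w) time constants, ms.
#' @slot u_c,u_v,u_c_si activation, fast-gate and slow-inward thresholds.
#' @slot k steepness of the slow-inward activation sigmoid.
#' @exportClass AFKParams
setClass("AFKParams", representation(
  tau_d = "numeric", tau_r = "numeric", tau_si = "numeric", tau_0 = "numeric",
  tau_v_plus = "numeric", tau_v1_minus = "numeric", tau_v2_minus = "numeric",
  tau_w_plus = "numeric", tau_w_minus = "numeric",
  u_c = "numeric", u_v = "numeric", u_c_si = "numeric", k = "numeric"))

setValidity("AFKParams", function(object) {
  taus <- c(object@tau_d, object@tau_r, object@tau_si, object@tau_0,
            object@tau_v_plus, object@tau_v1_minus, object@tau_v2_minus,
            object@tau_w_plus, object@tau_w_minus)
  if (any(!is.finite(taus)) || any(taus <= 0))
    return("all time constants must be finite and > 0")
  thr <- c(object@u_c, object@u_v, object@u_c_si)
  if (any(thr <= 0) || any(thr >= 1))
    return("thresholds u_c, u_v, u_c_si must lie in (0, 1)")
  if (object@k <= 0) return("k must be > 0")
  TRUE
})

#' Per-voxel membrane state (u, v, w)
#'
#' Holds the normalized transmembrane potential u and the two gating
#' variables of the Fenton-Karma model on the full voxel grid. Values
#' outside the wall are kept at rest.
#'
#' @slot u,v,w numeric 3-D arrays of identical dimension.
#' @exportClass CellStateField
setClass("CellStateField",
         representation(u = "array", v = "array", w = "array"))

setValidity("CellStateField", function(object) {
  if (!identical(dim(object@u), dim(object@v)) ||
      !identical(dim(object@u), dim(object@w)))
    return("u, v, w must share dimensions")
  if (any(object@v < -1e-12) || any(object@v > 1 + 1e-12) ||
      any(object@w < -1e-12) || any(object@w > 1 + 1e-12))
    return("gates v, w must lie in [0, 1]")
  if (any(object@u < -0.2) || any(object@u > 1.2))
    return("u out of physiological bounds [-0.2, 1.2]")
  TRUE
})

#' Voxelized tissue model
#'
#' Geometry plus electrophysiological substrate: a boolean wall mask on a
#' regular grid with spacing `dx` (mm), a per-voxel isotropic diffusion
#' coefficient D (mm^2/ms), fibrosis labels, pulmonary-vein (PV) region
#' masks, the mitral-valve (MV) boundary mask and an (initially empty)
#' ablation lesion mask.
#'
#' @slot wallMask logical 3-D array; TRUE on atrial wall voxels.
#' @slot D numeric 3-D array, diffusion coefficient in mm^2/ms (0 outside
#'   wall and on lesions).
#' @slot dx grid spacing, mm.
#' @slot labelArr integer 3-D array: 0 healthy, 1 border zone, 2 dense
#'   fibrosis; NA outside the wall.
#' @slot pvCenters numeric matrix (one row per PV opening) of opening
#'   centers, mm.
#' @slot pvMask logical array, union of the 3 mm spherical PV regions.
#' @slot mvMask logical array, mitral boundary voxels.
#' @slot lesionMask logical array of ablated voxels.
#' @slot meta list of provenance (geometry spec, config hash, ...).
#' @exportClass TissueModel
setClass("TissueModel", representation(
  wallMask = "array", D = "array", dx = "numeric", labelArr = "array",
  pvCenters = "matrix", pvMask = "array", mvMask = "array",
  lesionMask = "array", meta = "list"))

setValidity("TissueModel", function(object) {
  dm <- dim(object@wallMask)
  for (s in c("D", "labelArr", "pvMask", "mvMask", "lesionMask"))
    if (!identical(dim(slot(object, s)), dm))
      return(sprintf("slot '%s' dimension mismatch", s))
  if (object@dx <= 0) return("dx must be > 0")
  if (any(object@D < 0) || any(object@D > 0.1 + 1e-12))
    return("D must lie in [0, 0.1] mm^2/ms")
  if (any(object@D[object@lesionMask] != 0))
    return("D must be exactly 0 on lesion voxels")
  if (any(object@pvMask & !object@wallMask))
    return("pvMask must be a subset of wallMask")
  if (any(object@mvMask & !object@wallMask))
    return("mvMask must be a subset of wallMask")
  if (any(object@lesionMask & !object@wallMask))
    return("lesionMask must be a subset of wallMask")
  TRUE
})

#' Stimulus specification
#'
#' A forcing term on u: `amplitude` (1/ms) is added to du/dt on the voxels
#' of `region` for `onset <= t < onset + duration`.
#'
#' @slot onset,duration ms.
#' @slot amplitude dimensionless forcing rate on u (1/ms).
#' @slot idx integer vector of linear grid indices of the stimulated voxels.
#' @exportClass StimulusSpec
setClass("StimulusSpec", representation(
  onset = "numeric", duration = "numeric", amplitude = "numeric",
  idx = "integer"))

setValidity("StimulusSpec", function(object) {
  if (object@duration <= 0) return("stimulus duration must be > 0")
  if (length(object@idx) < 1) return("stimulus region is empty")
  TRUE
})

#' Solver configuration
#'
#' @slot dt time step, ms (default 0.005).
#' @slot duration total simulated time, ms.
#' @slot recordInterval u-snapshot interval, ms (default 2).
#' @slot stimuli list of [StimulusSpec-class] objects.
#' @slot seed integer seed recorded for provenance.
#' @exportClass SolverConfig
setClass("SolverConfig", representation(
  dt = "numeric", duration = "numeric", recordInterval = "numeric",
  stimuli = "list", seed = "integer"))

setValidity("SolverConfig", function(object) {
  if (object@dt <= 0 || object@duration <= 0) return("dt, duration must be > 0")
  if (object@recordInterval < object@dt)
    return("recordInterval must be >= dt")
  ok <- vapply(object@stimuli, is, logical(1), class2 = "StimulusSpec")
  if (!all(ok)) return("stimuli must all be StimulusSpec objects")
  TRUE
})

#' Simulation recording
#'
#' u snapshots on the active (wall minus lesion) voxel set at a regular
#' interval, plus the full final (u, v, w) state so a run can be continued
#' (e.g. to apply ablation lesions mid-simulation).
#'
#' @slot uSnaps numeric matrix, active voxels x time points.
#' @slot times snapshot times, ms.
#' @slot activeIdx linear grid indices of the rows of `uSnaps`.
#' @slot dims full grid dimension.
#' @slot dx grid spacing, mm.
#' @slot finalState [CellStateField-class] at the end of the run.
#' @slot meta list (dt, params hash, ...).
#' @exportClass Recording
setClass("Recording", representation(
  uSnaps = "matrix", times = "numeric", activeIdx = "integer",
  dims = "integer", dx = "numeric", finalState = "CellStateField",
  meta = "list"))

#' Re-entrant driver tip trajectory
#'
#' @slot runId identifier of the initiation run.
#' @slot samples data.frame with columns t (ms), x, y, z (mm), chirality
#'   (+1/-1).
#' @slot finalRegion one of "fibrosis", "pv", "healthy", "extinguished".
#' @exportClass TipTrajectory
setClass("TipTrajectory", representation(
  runId = "character", samples = "data.frame", finalRegion = "character"))

setValidity("TipTrajectory", function(object) {
  s <- object@samples
  need <- c("t", "x", "y", "z", "chirality")
  if (!all(need %in% names(s))) return("samples must have t,x,y,z,chirality")
  if (nrow(s) > 1 && any(diff(s$t) <= 0)) return("times must be strictly increasing")
  TRUE
})

#' RD tip visit-count map
#' @slot counts non-negative integer 3-D array of tip visits per voxel.
#' @slot totalSamples total number of tip samples accumulated.
#' @exportClass TipFrequencyMap
setClass("TipFrequencyMap",
         representation(counts = "array", totalSamples = "integer"))

#' Normalized RD probability map
#' @slot values 3-D array in [0, 1] (max-normalized visit frequency).
#' @slot nRuns number of initiation runs combined.
#' @slot normalization "max" or "mean_sd".
#' @exportClass RDProbabilityMap
setClass("RDProbabilityMap", representation(
  values = "array", nRuns = "integer", normalization = "character"))

#' Target-area set
#'
#' Connected components of the thresholded normalized tip-probability map.
#'
#' @slot labelArr integer array: 0 background, 1..K the TA ids.
#' @slot threshold normalized-probability cutoff used.
#' @slot mode "fixed" (printed default 0.2) or "mean_sd" (mean + 2 SD of
#'   nonzero values).
#' @slot dx grid spacing, mm.
#' @slot stats per-TA data.frame (volume mm^3, percent of wall, region
#'   breakdown).
#' @exportClass TargetAreaSet
setClass("TargetAreaSet", representation(
  labelArr = "array", threshold = "numeric", mode = "character",
  dx = "numeric", stats = "data.frame"))

#' Ablation lesion set
#' @slot mask logical array of lesion voxels (transmural, 3 mm diameter
#'   cylinders / bands).
#' @slot strategyId 1-5.
#' @slot components named list of logical arrays (pvi_rings, roof_line,
#'   mv_line, ta_cylinders, connector_lines) actually present.
#' @slot ablatedPercent percent of wall volume ablated.
#' @exportClass LesionSet
setClass("LesionSet", representation(
  mask = "array", strategyId = "integer", components = "list",
  ablatedPercent = "numeric"))

#' Post-ablation outcome
#' @slot classification "terminated", "at" or "unaffected".
#' @slot nRDsBefore,nRDsAfter persistent RD counts before/after ablation.
#' @slot mfBefore,mfAfter mean frequency, Hz.
#' @slot mfReductionPercent percent MF drop (NA when mfBefore is 0).
#' @exportClass AblationOutcome
setClass("AblationOutcome", representation(
  classification = "character", nRDsBefore = "integer", nRDsAfter = "integer",
  mfBefore = "numeric", mfAfter = "numeric", mfReductionPercent = "numeric"))
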