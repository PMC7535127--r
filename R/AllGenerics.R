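#' Accessor generics
#'
#' Standard accessors for the core data classes; slot access in user code
#' is discouraged.
#'
#' @param object an object of one of the fibroRD classes.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wallMask", function(object) standardGeneric("wallMask"))
#' @rdname accessors
#' @export
setGeneric("diffusion", function(object) standardGeneric("diffusion"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("tissueLabels", function(object) standardGeneric("tissueLabels"))
#' @rdname accessors
#' @export
setGeneric("lesionMask", function(object) standardGeneric("lesionMask"))
#' @rdname accessors
#' @export
setGeneric("pvMask", function(object) standardGeneric("pvMask"))
#' @rdname accessors
#' @export
setGeneric("mvMask", function(object) standardGeneric("mvMask"))
#' @rdname accessors
#' @export
setGeneric("pvCenters", function(object) standardGeneric("pvCenters"))

setMethod("wallMask", "TissueModel", function(object) object@wallMask)
setMethod("diffusion", "TissueModel", function(object) object@D)
setMethod("spacing", "TissueModel", function(object) object@dx)
setMethod("tissueLabels", "TissueModel", function(object) object@labelArr)
setMethod("lesionMask", "TissueModel", function(object) object@lesionMask)
setMethod("pvMask", "TissueModel", function(object) object@pvMask)
setMethod("mvMask", "TissueModel", function(object) object@mvMask)
setMethod("pvCenters", "TissueModel", function(object) object@pvCenters)
setMethod("spacing", "Recording", function(object) object@dx)
setMethod("spacing", "TargetAreaSet", function(object) object@dx)

#' @rdname accessors
#' @export
setGeneric("snapshotTimes", function(object) standardGeneric("snapshotTimes"))
setMethod("snapshotTimes", "Recording", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("finalState", function(object) standardGeneric("finalState"))
setMethod("finalState", "Recording", function(object) object@finalState)

#' @rdname accessors
#' @export
setGeneric("tipSamples", function(object) standardGeneric("tipSamples"))
setMethod("tipSamples", "TipTrajectory", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("finalRegion", function(object) standardGeneric("finalRegion"))
setMethod("finalRegion", "TipTrajectory", function(object) object@finalRegion)

#' @rdname accessors
#' @export
setGeneric("taLabels", function(object) standardGeneric("taLabels"))
setMethod("taLabels", "TargetAreaSet", function(object) object@labelArr)

#' @rdname accessors
#' @export
setGeneric("taStats", function(object) standardGeneric("taStats"))
setMethod("taStats", "TargetAreaSet", function(object) object@stats)

#' @rdname accessors
#' @export
setGeneric("taCount", function(object) standardGeneric("taCount"))
setMethod("taCount", "TargetAreaSet",
          function(object) max(0L, object@labelArr, na.rm = TRUE))

#' @rdname accessors
#' @export
setGeneric("lesionComponents", function(object) standardGeneric("lesionComponents"))
setMethod("lesionComponents", "LesionSet", function(object) object@components)
setMethod("lesionMask", "LesionSet", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("ablatedPercent", function(object) standardGeneric("ablatedPercent"))
setMethod("ablatedPercent", "LesionSet", function(object) object@ablatedPercent)

setMethod("show", "TissueModel", function(object) {
  nw <- sum(object@wallMask)
  cat("TissueModel:", paste(dim(object@wallMask), collapse = " x "),
      "grid, dx =", object@dx, "mm\n")
  cat("  wall voxels:", nw,
      sprintf("(%.1f mm^3)", nw * object@dx^3), "\n")
  lab <- object@labelArr[object@wallMask]
  cat(sprintf("  labels: %d healthy, %d border-zone, %d dense\n",
              sum(lab == 0, na.rm = TRUE), sum(lab == 1, na.rm = TRUE),
              sum(lab == 2, na.rm = TRUE)))
  cat("  PV openings:", nrow(object@pvCenters),
      "| lesion voxels:", sum(object@lesionMask), "\n")
})

setMethod("show", "AFKParams", function(object) {
  cat("AFKParams (atrial Fenton-Karma, normalized voltage)\n")
  for (s in slotNames(object))
    cat(sprintf("  %-13s %g\n", s, slot(object, s)))
})

setMethod("show", "Recording", function(object) {
  cat("Recording:", length(object@activeIdx), "active voxels,",
      length(object@times), "snapshots,",
      sprintf("t = [%g, %g] ms\n", min(object@times), max(object@times)))
})

setMethod("show", "TipTrajectory", function(object) {
  s <- object@samples
  cat(sprintf("TipTrajectory '%s': %d samples, t = [%g, %g] ms, final region: %s\n",
              object@runId, nrow(s),
              if (nrow(s)) min(s$t) else NA, if (nrow(s)) max(s$t) else NA,
              object@finalRegion))
})

setMethod("show", "TargetAreaSet", function(object) {
  cat(sprintf("TargetAreaSet: %d TA(s) at threshold %.3g (%s mode)\n",
              taCount(object), object@threshold, object@mode))
})

setMethod("show", "LesionSet", function(object) {
  cat(sprintf("LesionSet (strategy %d): %d voxels, %.2f%% of wall [%s]\n",
              object@strategyId, sum(object@mask), object@ablatedPercent,
              paste(names(object@components), collapse = ", ")))
})

setMethod("show", "AblationOutcome", function(object) {
  cat(sprintf("AblationOutcome: %s | RDs %d -> %d | MF %.2f -> %.2f Hz (%.0f%% drop)\n",
              object@classification, object@nRDsBefore, object@nRDsAfter,
              object@mfBefore, object@mfAfter, object@mfReductionPercent))
})
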