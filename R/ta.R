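#' Combine tip-frequency maps into a normalized RD probability map
#'
#' Voxelwise sum of visit counts over runs, divided by its maximum.
#' Runs whose trajectory stabilized at a PV opening are excluded by
#' default (PV anchoring is an artifact of vein clipping); exclusion
#' operates at run level (`exclude = "run"`) or, for sensitivity
#' analysis, by masking PV-region voxels (`exclude = "voxel"`).
#'
#' @param freqMaps list of [TipFrequencyMap-class], one per run.
#' @param finalRegions character vector (one per map) of the run's RD
#'   final region; required for run-level exclusion.
#' @param excludePV logical (default TRUE).
#' @param exclude "run" (default) or "voxel".
#' @param pvMaskArr logical array of PV-region voxels (for voxel mode).
#' @return an [RDProbabilityMap-class].
#' @export
combineMaps <- function(freqMaps, finalRegions = NULL, excludePV = TRUE,
                        exclude = c("run", "voxel"), pvMaskArr = NULL) {
  exclude <- match.arg(exclude)
  stopifnot(length(freqMaps) >= 1)
  keep <- seq_along(freqMaps)
  if (excludePV && exclude == "run" && !is.null(finalRegions))
    keep <- which(finalRegions != "pv")
  if (!length(keep)) stop("no RDs recorded (all runs PV-anchored)")
  total <- array(0, dim(freqMaps[[1]]@counts))
  for (i in keep) total <- total + freqMaps[[i]]@counts
  if (excludePV && exclude == "voxel") {
    if (is.null(pvMaskArr)) stop("voxel-level exclusion needs pvMaskArr")
    total[pvMaskArr] <- 0
  }
  m <- max(total)
  if (m == 0) stop("no RDs recorded")
  new("RDProbabilityMap", values = total / m,
      nRuns = length(keep), normalization = "max")
}

#' Extract target areas from a probability map
#'
#' Voxels above the cutoff form 26-connected components, each a target
#' area (TA). The default fixed cutoff is 0.2 of the maximum visit
#' frequency; alternatively the cutoff is recomputed as mean + 2 SD of
#' the nonzero map values (`mode = "mean_sd"`), the standardized rule
#' that motivates the 0.2 default.
#'
#' @param pmap an [RDProbabilityMap-class].
#' @param threshold cutoff in normalized probability (default 0.2; ignored
#'   in mean_sd mode).
#' @param mode "fixed" or "mean_sd".
#' @param tissue optional [TissueModel-class] for per-TA statistics.
#' @param smooth_mm Gaussian smoothing (sd, mm) applied to the visit map
#'   before renormalizing and thresholding; 0 (default) disables. Short
#'   desk-scale runs visit transit voxels only a handful of times, so a
#'   sub-voxel-scale smooth suppresses speckle without moving the hot
#'   spots.
#' @param min_voxels discard components smaller than this many voxels
#'   (default 1 = keep all).
#' @return a [TargetAreaSet-class] (possibly with zero TAs).
#' @export
extractTAs <- function(pmap, threshold = 0.2, mode = c("fixed", "mean_sd"),
                       tissue = NULL, smooth_mm = 0, min_voxels = 1L) {
  mode <- match.arg(mode)
  v <- pmap@values
  if (smooth_mm > 0) {
    dxs <- if (!is.null(tissue)) spacing(tissue) else 1
    dm <- dim(v)
    sig <- smooth_mm / dxs
    ax <- lapply(dm, function(n) {
      i <- 0:(n - 1); pmin(i, n - i)^2
    })
    r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
    ker <- exp(-r2 / (2 * sig^2)); ker <- ker / sum(ker)
    v <- Re(stats::fft(stats::fft(v) * stats::fft(ker), inverse = TRUE)) /
      prod(dm)
    v <- pmax(v, 0); v <- v / max(v)
  }
  if (mode == "mean_sd") {
    nz <- v[v > 0]
    threshold <- min(mean(nz) + 2 * stats::sd(nz), 1)
  }
  mask <- v > threshold
  lab <- labelComponents(mask, 26L)
  nTA <- attr(lab, "n")
  if (nTA > 0 && min_voxels > 1L) {
    sizes <- tabulate(lab[lab > 0], nbins = nTA)
    keep <- which(sizes >= min_voxels)
    relab <- integer(nTA); relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
    attr(lab, "n") <- length(keep)
    nTA <- length(keep)
  }
  dx <- if (!is.null(tissue)) spacing(tissue) else 1
  stats <- data.frame()
  if (nTA > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = nTA)
    stats <- data.frame(ta = seq_len(nTA), n_voxels = sizes,
                        volume_mm3 = sizes * dx^3)
    if (!is.null(tissue)) {
      nWall <- sum(wallMask(tissue))
      stats$percent_wall <- 100 * sizes / nWall
      labT <- tissueLabels(tissue)
      stats$dense_pct <- stats$bz_pct <- stats$healthy_pct <- NA_real_
      for (k in seq_len(nTA)) {
        lt <- labT[lab == k]
        stats$dense_pct[k] <- 100 * mean(lt == 2L, na.rm = TRUE)
        stats$bz_pct[k] <- 100 * mean(lt == 1L, na.rm = TRUE)
        stats$healthy_pct[k] <- 100 * mean(lt == 0L, na.rm = TRUE)
      }
    }
  }
  new("TargetAreaSet", labelArr = lab, threshold = threshold, mode = mode,
      dx = dx, stats = stats)
}

#' Dice overlap score
#'
#' 2 |A intersect B| / (|A| + |B|) between two voxel sets on the same
#' grid; two empty sets are defined as identical (score 1, flagged via
#' attribute `both_empty`).
#'
#' @param a,b logical arrays (or index vectors).
#' @return numeric in \[0, 1\].
#' @export
diceScore <- function(a, b) {
  if (is.logical(a)) a <- which(a)
  if (is.logical(b)) b <- which(b)
  if (!length(a) && !length(b))
    return(structure(1, both_empty = TRUE))
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Target-area summary report
#'
#' Per-TA and total volumes as percent of wall, region breakdown, and the
#' pairing with the fibrosis burden for the burden-versus-TA-volume
#' comparison.
#'
#' @param tas a [TargetAreaSet-class] built with a tissue reference.
#' @param tissue a [TissueModel-class].
#' @param fibStats optional data.frame from [patchStats()].
#' @return list with `per_ta` (data.frame), `total_ta_percent`,
#'   `fb_percent` and `majority_fibrotic` (fraction of TA volume on
#'   border-zone or dense voxels).
#' @export
taReport <- function(tas, tissue, fibStats = NULL) {
  st <- taStats(tas)
  if (!nrow(st))
    return(list(per_ta = st, total_ta_percent = 0,
                fb_percent = if (!is.null(fibStats)) fibStats$fb_percent else NA_real_,
                majority_fibrotic = NA_real_))
  tot <- sum(st$percent_wall)
  lab <- tissueLabels(tissue)
  taVox <- taLabels(tas) > 0
  fibFrac <- mean(lab[taVox] >= 1L, na.rm = TRUE)
  list(per_ta = st, total_ta_percent = tot,
       fb_percent = if (!is.null(fibStats)) fibStats$fb_percent else NA_real_,
       majority_fibrotic = fibFrac)
}
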