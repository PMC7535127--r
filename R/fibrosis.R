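#' IIR thresholds for fibrosis segmentation
#'
#' The lower threshold (healthy / border-zone boundary) is 1.08, the
#' average of two previously proposed enhancement thresholds (1.2 and
#' 0.97) rounded to the stored operational value; the upper threshold
#' (border-zone / dense boundary) is 1.24, the dense-scar threshold 1.32
#' reduced by 6% for post-ablation imaging. Both are stored as constants;
#' [deriveUpperIIR()] documents the upper derivation.
#'
#' Boundary convention: a voxel is healthy iff IIR < lower and dense iff
#' IIR >= upper (the convention that matches the diffusion assignment
#' "IIR >= 1.24 has D = 0.017").
#'
#' @param lower,upper dimensionless IIR cutoffs.
#' @return list with elements `lower`, `upper`.
#' @export
iirThresholds <- function(lower = 1.08, upper = 1.24) {
  if (!(1 < lower && lower < upper))
    stop("need 1 < lower < upper")
  list(lower = lower, upper = upper)
}

#' Derivation of the upper IIR threshold
#'
#' The dense-scar IIR threshold of 1.32 reduced by 6% (post-ablation
#' enhancement attenuation), rounded to the stored precision.
#'
#' @param scar_iir literature dense-scar threshold (1.32).
#' @param reduction fractional reduction (0.06).
#' @return the derived upper threshold (1.24).
#' @export
deriveUpperIIR <- function(scar_iir = 1.32, reduction = 0.06) {
  round(scar_iir * (1 - reduction), 2)
}

#' Diffusion map for fibrotic slowing
#'
#' Healthy tissue conducts with D = 0.1 mm^2/ms (CV 0.6 m/s); dense
#' fibrosis with D = 0.017 mm^2/ms, an 83% reduction
#' ([denseDReductionPercent()]).
#'
#' @param d_healthy,d_dense mm^2/ms.
#' @return list with elements `d_healthy`, `d_dense`.
#' @export
diffusionMap <- function(d_healthy = 0.1, d_dense = 0.017) {
  if (!(0 < d_dense && d_dense < d_healthy))
    stop("need 0 < d_dense < d_healthy")
  list(d_healthy = d_healthy, d_dense = d_dense)
}

#' Percent reduction of D in dense fibrosis relative to healthy tissue
#' @param dmap a [diffusionMap()] list.
#' @return percent reduction (83 for the defaults).
#' @export
denseDReductionPercent <- function(dmap = diffusionMap()) {
  100 * (dmap$d_healthy - dmap$d_dense) / dmap$d_healthy
}

#' Image intensity ratio
#'
#' IIR = voxel intensity / mean blood-pool intensity; scale-invariant in
#' the global image intensity.
#'
#' @param intensity numeric 3-D array.
#' @param bloodPoolMask logical array of blood-pool voxels.
#' @return numeric array of IIR (same dimension as `intensity`).
#' @export
computeIIR <- function(intensity, bloodPoolMask) {
  if (!any(bloodPoolMask)) stop("blood pool mask is empty")
  m <- mean(intensity[bloodPoolMask])
  if (!is.finite(m) || m <= 0) stop("blood-pool mean must be positive")
  intensity / m
}

#' Three-way fibrosis labelling from IIR
#'
#' healthy (0) iff IIR < lower; dense (2) iff IIR >= upper; border zone
#' (1) in between (so IIR exactly at the lower threshold is border zone).
#'
#' @param iir numeric array.
#' @param thresholds an [iirThresholds()] list.
#' @return integer array of labels 0/1/2.
#' @export
labelVoxels <- function(iir, thresholds = iirThresholds()) {
  lab <- array(1L, dim(iir))
  lab[iir < thresholds$lower] <- 0L
  lab[iir >= thresholds$upper] <- 2L
  lab
}

#' IIR to diffusion coefficient
#'
#' D = d_healthy below the lower threshold, d_dense at or above the upper
#' threshold, and linearly interpolated in IIR between the two; the result
#' is clamped to \[d_dense, d_healthy\].
#'
#' @param iir numeric array (or vector).
#' @param thresholds an [iirThresholds()] list.
#' @param dmap a [diffusionMap()] list.
#' @return numeric array of D, mm^2/ms.
#' @export
iirToDiffusion <- function(iir, thresholds = iirThresholds(),
                           dmap = diffusionMap()) {
  frac <- (iir - thresholds$lower) / (thresholds$upper - thresholds$lower)
  frac <- pmin(pmax(frac, 0), 1)
  D <- dmap$d_healthy + frac * (dmap$d_dense - dmap$d_healthy)
  if (!is.null(dim(iir))) D <- array(D, dim(iir))
  D
}

#' Project endocardial-surface labels through the wall
#'
#' Every wall voxel inherits the label of its nearest endocardial-surface
#' voxel (breadth-first wave from the endocardial surface over the wall),
#' making the fibrosis patches fully transmural. Idempotent.
#'
#' @param labels integer array of labels (NA outside the wall allowed).
#' @param wallMask logical array.
#' @param bloodPoolMask logical array defining the endocardial side; when
#'   NULL the labels are propagated from the full wall surface.
#' @return integer array of transmural labels (NA outside the wall).
#' @export
transmuralProjection <- function(labels, wallMask, bloodPoolMask = NULL) {
  src <- if (is.null(bloodPoolMask)) surfaceVoxels(wallMask)
         else surfaceVoxels(wallMask, against = bloodPoolMask)
  if (!length(src)) return(labels)
  val <- .bfsPropagate(wallMask, src, labels[src])
  out <- array(NA_integer_, dim(labels))
  w <- which(wallMask)
  out[w] <- val[w]
  ## voxels unreachable from the surface keep their own label
  miss <- w[is.na(out[w])]
  out[miss] <- labels[miss]
  out
}

#' Utah fibrosis stage
#'
#' Utah 1: FB <= 5%; Utah 2: 5 < FB <= 20; Utah 3: 20 < FB <= 35;
#' Utah 4: FB > 35 (half-open intervals).
#'
#' @param fb_percent fibrosis burden as percent of wall volume (vectorized).
#' @return integer score(s) 1-4.
#' @export
utahClassify <- function(fb_percent) {
  if (any(fb_percent < 0 | fb_percent > 100))
    stop("fibrosis burden must be within [0, 100] percent")
  score <- rep(1L, length(fb_percent))
  score[fb_percent > 5] <- 2L
  score[fb_percent > 20] <- 3L
  score[fb_percent > 35] <- 4L
  score
}

#' Fibrosis patch statistics
#'
#' Connected components (26-connectivity) of the fibrotic set (border zone
#' plus dense). All volumes are reported as percent of the atrial wall
#' volume; the PV fraction is the percent of fibrotic voxels inside the
#' 3 mm PV spherical regions and the wall fraction is its complement, so
#' the two always partition 100%.
#'
#' @param labels integer array of 0/1/2 fibrosis labels.
#' @param tissue a [TissueModel-class] (for wall mask, PV regions, dx).
#' @return one-row data.frame with columns fb_percent,
#'   largest_patch_percent, pv_fraction_percent, wall_fraction_percent,
#'   dense_percent, n_patches, utah_score.
#' @export
patchStats <- function(labels, tissue) {
  wall <- wallMask(tissue)
  nWall <- sum(wall)
  fib <- wall & !is.na(labels) & labels >= 1L
  nFib <- sum(fib)
  fb <- 100 * nFib / nWall
  dense <- 100 * sum(wall & !is.na(labels) & labels == 2L) / nWall
  if (nFib == 0) {
    return(data.frame(fb_percent = 0, largest_patch_percent = 0,
                      pv_fraction_percent = 0, wall_fraction_percent = 0,
                      dense_percent = 0, n_patches = 0L,
                      utah_score = 1L))
  }
  comp <- labelComponents(fib, 26L)
  sizes <- tabulate(comp[comp > 0])
  pvFib <- sum(fib & pvMask(tissue))
  data.frame(fb_percent = fb,
             largest_patch_percent = 100 * max(sizes) / nWall,
             pv_fraction_percent = 100 * pvFib / nFib,
             wall_fraction_percent = 100 * (nFib - pvFib) / nFib,
             dense_percent = dense,
             n_patches = length(sizes),
             utah_score = utahClassify(fb))
}

#' Apply a fibrosis map to a tissue model
#'
#' Computes IIR, labels voxels, optionally projects the labels
#' transmurally, converts to per-voxel diffusion, and returns the updated
#' tissue.
#'
#' @param tissue a [TissueModel-class].
#' @param intensity LGE-like intensity array.
#' @param bloodPoolMask logical array.
#' @param thresholds an [iirThresholds()] list.
#' @param dmap a [diffusionMap()] list.
#' @param transmural apply [transmuralProjection()] (default TRUE).
#' @return the tissue with labels and D updated; the IIR array is stored
#'   in `meta`.
#' @export
applyFibrosis <- function(tissue, intensity, bloodPoolMask,
                          thresholds = iirThresholds(),
                          dmap = diffusionMap(), transmural = TRUE) {
  iir <- computeIIR(intensity, bloodPoolMask)
  lab <- labelVoxels(iir, thresholds)
  lab[!wallMask(tissue)] <- NA_integer_
  cols <- NULL
  if (transmural) {
    ## project through the wall columns (each voxel takes the label of
    ## its endocardial representative; equivalent to
    ## transmuralProjection() but the columns are kept for reuse)
    cols <- .wallColumns(wallMask(tissue), bloodPoolMask)
    w <- which(wallMask(tissue))
    rep_ <- cols$endo[cols$colId[w]]
    lab[w] <- ifelse(is.na(rep_), lab[w], lab[rep_])
  }
  ## diffusion consistent with the (possibly projected) labels: healthy
  ## and dense take the map endpoints; border-zone voxels keep the linear
  ## interpolation of their own IIR, clamped to the open BZ band
  w <- which(wallMask(tissue))
  D <- array(0, dim(iir))
  D[w] <- dmap$d_healthy
  D[w][lab[w] == 2L] <- dmap$d_dense
  bz <- w[!is.na(lab[w]) & lab[w] == 1L]
  bzIIR <- pmin(pmax(iir[bz], thresholds$lower),
                thresholds$upper - 1e-9)
  D[bz] <- iirToDiffusion(bzIIR, thresholds, dmap)
  tissueModel(wallMask(tissue), D = D, dx = spacing(tissue), labels = lab,
              pvCenters = pvCenters(tissue), pvMask = pvMask(tissue),
              mvMask = mvMask(tissue), lesionMask = lesionMask(tissue),
              meta = c(tissue@meta, list(iir = iir, wallColumns = cols)))
}

#' Write fibrosis statistics to CSV
#' @param stats data.frame from [patchStats()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeFibrosisStats <- function(stats, path) {
  out <- data.frame(`% FB` = stats$fb_percent,
                    `% Volume of largest patch` = stats$largest_patch_percent,
                    `% FB of PVs` = stats$pv_fraction_percent,
                    `% FB of LA wall` = stats$wall_fraction_percent,
                    `% Volume of dense tissue` = stats$dense_percent,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
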