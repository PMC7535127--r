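#' Left-atrium-like shell geometry specification
#'
#' An idealized LA: an ellipsoidal endocardial chamber dilated outward by
#' `wall_thickness` (3 mm, the average LA wall thickness reported in AF
#' patients), with four pulmonary-vein openings punched through the
#' posterior-superior wall and one mitral-valve opening inferiorly. The
#' openings are carved as cylinders along fixed anatomical directions.
#'
#' @param semi_axes inner (endocardial) ellipsoid semi-axes, mm.
#' @param wall_thickness mm (default 3; must be >= 2 dx).
#' @param pv_radius radius of each PV opening, mm.
#' @param mv_radius radius of the MV opening, mm.
#' @param dx voxel spacing, mm.
#' @param pv_directions 4 x 3 matrix of unit directions of the PV openings.
#' @param mv_direction MV opening direction.
#' @return a list of class `LAGeometrySpec`.
#' @export
laGeometrySpec <- function(semi_axes = c(30, 25, 20), wall_thickness = 3,
                           pv_radius = 5, mv_radius = 10, dx = 0.6,
                           pv_directions = rbind(
                             c(-0.55, 0.65, 0.52), c(-0.70, 0.60, -0.38),
                             c(0.55, 0.65, 0.52), c(0.70, 0.60, -0.38)),
                           mv_direction = c(0, -0.90, -0.44)) {
  if (wall_thickness < 2 * dx)
    stop("wall thickness must be at least 2 voxels")
  norm <- function(v) v / sqrt(sum(v^2))
  pv_directions <- t(apply(pv_directions, 1, norm))
  structure(list(semi_axes = semi_axes, wall_thickness = wall_thickness,
                 pv_radius = pv_radius, mv_radius = mv_radius, dx = dx,
                 pv_directions = pv_directions,
                 mv_direction = norm(mv_direction)),
            class = "LAGeometrySpec")
}

#' Build the voxelized LA shell
#'
#' Voxelizes the shell between the inner ellipsoid and its outward
#' dilation, removes the PV and MV openings (cylindrical punches along the
#' spec directions), and populates the PV region masks as 3 mm bands
#' around each opening rim and the MV boundary mask. Diffusion is uniform
#' (healthy, 0.1 mm^2/ms).
#'
#' @param spec an `LAGeometrySpec` from [laGeometrySpec()].
#' @return a [TissueModel-class]; the blood-pool (endocardial cavity) mask
#'   is available in `meta(...)$bloodPool`.
#' @export
makeLAShell <- function(spec) {
  a <- spec$semi_axes; wt <- spec$wall_thickness; dx <- spec$dx
  if (spec$mv_radius >= min(a) || spec$pv_radius >= min(a))
    stop("opening radius larger than the chamber")
  ext <- a + wt + 2 * dx
  dm <- as.integer(ceiling(2 * ext / dx))
  cen <- dm / 2 * dx
  idx <- seq_len(prod(dm))
  co <- arrayInd(idx, dm)
  xyz <- sweep((co - 0.5) * dx, 2, cen, "-")
  fIn <- (xyz[, 1] / a[1])^2 + (xyz[, 2] / a[2])^2 + (xyz[, 3] / a[3])^2
  ao <- a + wt
  fOut <- (xyz[, 1] / ao[1])^2 + (xyz[, 2] / ao[2])^2 + (xyz[, 3] / ao[3])^2
  wall <- array(fIn >= 1 & fOut <= 1, dm)
  bloodPool <- array(fIn < 1, dm)

  ## carve cylindrical openings along each direction
  dirs <- rbind(spec$pv_directions, spec$mv_direction)
  radii <- c(rep(spec$pv_radius, 4), spec$mv_radius)
  carved <- array(FALSE, dm)
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    proj <- xyz %*% d
    perp2 <- rowSums(xyz^2) - proj^2
    hole <- proj > 0 & perp2 <= radii[k]^2
    carved <- carved | (wall & array(hole, dm))
  }
  wallOpen <- wall & !carved

  ## opening centers: intersection of the direction ray with the mid-wall
  amid <- a + wt / 2
  centers <- t(apply(dirs, 1, function(d) {
    t_ <- 1 / sqrt(sum((d / amid)^2))
    d * t_
  }))
  pvCenters <- centers[1:4, , drop = FALSE]

  ## PV regions: wall voxels within (pv_radius + 3 mm) of an opening center
  pvMask <- array(FALSE, dm)
  for (k in 1:4) {
    d2 <- rowSums(sweep(xyz, 2, pvCenters[k, ], "-")^2)
    pvMask <- pvMask | (wallOpen & array(d2 <= (spec$pv_radius + 3)^2, dm))
  }
  mvMask <- array(FALSE, dm)
  d2 <- rowSums(sweep(xyz, 2, centers[5, ], "-")^2)
  mvMask <- mvMask | (wallOpen & array(d2 <= (spec$mv_radius + 3)^2, dm))

  tissueModel(wallOpen, D = 0.1, dx = dx,
              pvCenters = sweep(pvCenters, 2, cen, "+"),
              pvMask = pvMask, mvMask = mvMask,
              meta = list(spec = unclass(spec), bloodPool = bloodPool,
                          center = cen, carved = carved))
}

#' 2-D sheet fixture with prescribed fibrotic patches
#'
#' A single-voxel-thick rectangular tissue with circular patches of a
#' prescribed image-intensity ratio (IIR); the remaining sheet carries the
#' healthy baseline IIR of 1. The returned tissue already has labels and
#' interpolated diffusion applied via the IIR-to-D map, and the raw IIR
#' field is attached as `meta(...)$iir`.
#'
#' @param width,height mm.
#' @param dx voxel spacing, mm.
#' @param patches list of lists with elements `center` (xy mm), `radius`
#'   (mm) and `iir`.
#' @param thresholds an [iirThresholds()] list.
#' @param dmap a [diffusionMap()] list.
#' @return a [TissueModel-class].
#' @export
makeSheet <- function(width = 60, height = 60, dx = 0.6, patches = list(),
                      thresholds = iirThresholds(), dmap = diffusionMap()) {
  nx <- as.integer(round(width / dx)); ny <- as.integer(round(height / dx))
  dm <- c(nx, ny, 1L)
  wall <- array(TRUE, dm)
  iir <- array(1.0, dm)
  co <- arrayInd(seq_len(prod(dm)), dm)
  xy <- (co[, 1:2] - 0.5) * dx
  for (p in patches) {
    d2 <- (xy[, 1] - p$center[1])^2 + (xy[, 2] - p$center[2])^2
    inside <- d2 <= p$radius^2
    if (!any(inside)) stop("patch outside sheet")
    iir[inside] <- p$iir
  }
  lab <- labelVoxels(iir, thresholds)
  lab[!wall] <- NA_integer_
  D <- iirToDiffusion(iir, thresholds, dmap)
  tissueModel(wall, D = D, dx = dx, labels = lab,
              meta = list(iir = iir, width = width, height = height))
}

#' Rectangular strip fixture
#'
#' The reference conduction-velocity testbed: a `length_mm` x `width_mm` x
#' `thickness_mm` box of uniform tissue.
#'
#' @param length_mm,width_mm,thickness_mm strip dimensions, mm.
#' @param dx voxel spacing, mm.
#' @param D uniform diffusion coefficient, mm^2/ms.
#' @return a [TissueModel-class].
#' @export
makeStrip <- function(length_mm = 30, width_mm = 3, thickness_mm = 0.9,
                      dx = 0.3, D = 0.1) {
  dm <- as.integer(pmax(1, round(c(length_mm, width_mm, thickness_mm) / dx)))
  tissueModel(array(TRUE, dm), D = D, dx = dx,
              meta = list(strip = c(length_mm, width_mm, thickness_mm)))
}
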