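#' Read/write voxel volumes as NIfTI
#'
#' @param arr numeric or logical 3-D array.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param dx voxel spacing, mm.
#' @return invisibly, `path`.
#' @export
writeVolume <- function(arr, path, dx) {
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- rep(dx, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @return for `readVolume`, a list with `data` (array) and `dx`.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       dx = RNifti::pixdim(img)[1])
}

#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs. All stochastic stages
#' derive their streams from `seed`.
#'
#' @param geometry an `LAGeometrySpec`, or a ready [TissueModel-class]
#'   (e.g. a sheet fixture).
#' @param lge a [syntheticLGESpec()], or NULL to skip fibrosis (control
#'   model).
#' @param target_fb optional burden fraction; when set, [tuneFB()] is run
#'   before generating the volume.
#' @param n_sites number of RD initiation sites.
#' @param duration per-run simulated time, ms.
#' @param dt solver time step, ms.
#' @param ta_threshold normalized-probability TA cutoff (default 0.2).
#' @param ta_mode "fixed" or "mean_sd".
#' @param ta_smooth Gaussian smoothing (sd, mm) of the visit map before
#'   thresholding (see [extractTAs()]); default 1.2.
#' @param ta_min_voxels minimum TA component size in voxels (default 4).
#' @param strategies integer vector of ablation strategies to evaluate
#'   (empty = stop after the TA report).
#' @param ablation_duration post-ablation observation, ms.
#' @param seed master seed.
#' @param outdir output directory (NULL = no files written).
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(geometry = laGeometrySpec(), lge = syntheticLGESpec(),
                           target_fb = NA, n_sites = 8, duration = 2000,
                           dt = 0.02, ta_threshold = 0.2, ta_mode = "fixed",
                           ta_smooth = 1.2, ta_min_voxels = 4L,
                           strategies = integer(0), ablation_duration = 2000,
                           seed = 1L, outdir = NULL) {
  stopifnot(ta_threshold > 0, ta_threshold <= 1)
  structure(list(geometry = geometry, lge = lge, target_fb = target_fb,
                 n_sites = n_sites, duration = duration, dt = dt,
                 ta_threshold = ta_threshold, ta_mode = ta_mode,
                 ta_smooth = ta_smooth, ta_min_voxels = as.integer(ta_min_voxels),
                 strategies = strategies,
                 ablation_duration = ablation_duration,
                 seed = as.integer(seed), outdir = outdir),
            class = "PipelineConfig")
}

#' Generate and store the synthetic imaging stage
#'
#' Builds the geometry, generates the synthetic LGE volume (tuning the
#' burden when requested), applies the fibrosis mapping, and (when
#' `outdir` is set) writes the intensity, wall, blood-pool and label
#' volumes as NIfTI plus a JSON manifest echoing the spec and realized
#' burden.
#'
#' @param config a [pipelineConfig()].
#' @return list with `tissue` (fibrotic [TissueModel-class]), `volume`
#'   (LGE output), `stats` ([patchStats()] row) and `manifest`.
#' @export
runSynthStage <- function(config) {
  geom <- if (is(config$geometry, "TissueModel")) config$geometry
          else makeLAShell(config$geometry)
  if (is.null(config$lge)) {
    stats <- patchStats(tissueLabels(geom), geom)
    return(list(tissue = geom, volume = NULL, stats = stats,
                manifest = list(fb_percent = stats$fb_percent)))
  }
  spec <- config$lge
  spec$seed <- config$seed
  if (!is.na(config$target_fb))
    spec <- tuneFB(geom, spec, config$target_fb)
  vol <- makeSyntheticLGE(geom, spec)
  tissue <- applyFibrosis(geom, vol$intensity, vol$bloodPool)
  stats <- patchStats(tissueLabels(tissue), tissue)
  manifest <- list(spec = unclass(spec), fb_percent = stats$fb_percent,
                   utah_score = stats$utah_score,
                   config_hash = .hashConfig(unclass(config)))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    dx <- spacing(tissue)
    writeVolume(vol$intensity, file.path(config$outdir, "lge.nii.gz"), dx)
    writeVolume(vol$bloodPool, file.path(config$outdir, "bloodpool.nii.gz"), dx)
    writeVolume(wallMask(tissue), file.path(config$outdir, "wall.nii.gz"), dx)
    lab <- tissueLabels(tissue); lab[is.na(lab)] <- -1L
    writeVolume(lab, file.path(config$outdir, "labels.nii.gz"), dx)
    writeVolume(diffusion(tissue), file.path(config$outdir, "D.nii.gz"), dx)
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(tissue = tissue, volume = vol, stats = stats, manifest = manifest)
}

#' Run the full RD-mapping pipeline
#'
#' Stages: synthetic imaging and fibrosis mapping; RD initiation from
#' `n_sites` sites; tip tracking and final-region classification;
#' combined normalized probability map; TA extraction and report; and,
#' when strategies are configured, virtual ablation with outcome
#' classification. Deterministic given the config seed; per-stage outputs
#' are returned (and written to `outdir` when set).
#'
#' @param config a [pipelineConfig()].
#' @param params cell parameters; default is the calibrated-at-0.6 m/s
#'   nominal set.
#' @return list with elements `tissue`, `stats`, `trajectories`,
#'   `regions`, `pmap`, `tas`, `report`, `outcomes` (NULL unless
#'   strategies were run).
#' @export
runPipeline <- function(config, params = afkParams()) {
  synth <- runSynthStage(config)
  tissue <- synth$tissue
  plans <- enumerateSites(tissue, config$n_sites, config$seed)
  recs <- lapply(plans, function(pl)
    runPlan(tissue, pl, params, duration = config$duration, dt = config$dt))
  trajAll <- list(); regions <- character(0); fmaps <- list()
  for (i in seq_along(recs)) {
    trs <- trackTips(recs[[i]])
    endT <- max(recs[[i]]@times)
    trs <- lapply(trs, classifyFinalLocation, tissue = tissue,
                  window = min(1000, config$duration / 2), end = endT)
    per <- .persistent(trs, endT, min(1000, config$duration / 2))
    reg <- if (length(per)) finalRegion(per[[1]]) else "extinguished"
    fmaps[[i]] <- buildTipFrequencyMap(trs, tissue)
    regions <- c(regions, reg)
    trajAll <- c(trajAll, trs)
  }
  if (all(vapply(fmaps, function(f) f@totalSamples, 1L) == 0L))
    stop("pipeline recorded no RD tips; initiation failed at every site")
  pmap <- combineMaps(fmaps, finalRegions = regions)
  tas <- extractTAs(pmap, threshold = config$ta_threshold,
                    mode = config$ta_mode, tissue = tissue,
                    smooth_mm = config$ta_smooth %||% 0,
                    min_voxels = config$ta_min_voxels %||% 1L)
  report <- taReport(tas, tissue, synth$stats)
  outcomes <- NULL
  if (length(config$strategies)) {
    outcomes <- lapply(config$strategies, function(sid) {
      les <- buildStrategy(tissue, tas, sid)
      ## continue the first AF run on the ablated substrate
      ab <- applyLesions(tissue, les, finalState(recs[[1]]))
      cfgPost <- solverConfig(duration = config$ablation_duration,
                              dt = config$dt, recordInterval = 2)
      post <- runSimulation(ab$tissue, cfgPost, params, init = ab$state,
                            t0 = max(recs[[1]]@times))
      evaluateOutcome(recs[[1]], post, ab$tissue, les)
    })
    names(outcomes) <- paste0("strategy", config$strategies)
  }
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    dx <- spacing(tissue)
    writeVolume(pmap@values, file.path(config$outdir, "rd_probability.nii.gz"), dx)
    writeVolume(taLabels(tas), file.path(config$outdir, "target_areas.nii.gz"), dx)
    writeTrajectories(trajAll, file.path(config$outdir, "trajectories.csv"))
    utils::write.csv(data.frame(site = vapply(plans, `[[`, "", "site_id"),
                                final_region = regions),
                     file.path(config$outdir, "rd_regions.csv"),
                     row.names = FALSE)
    if (nrow(taStats(tas)))
      utils::write.csv(taStats(tas), file.path(config$outdir, "ta_report.csv"),
                       row.names = FALSE)
  }
  list(tissue = tissue, stats = synth$stats, trajectories = trajAll,
       regions = regions, pmap = pmap, tas = tas, report = report,
       outcomes = outcomes)
}
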