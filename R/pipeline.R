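## End-to-end orchestration: phantom or file inputs -> preprocess ->
## velocimetry -> expansion -> quantify -> global function -> cohort report.

#' Build a pipeline run configuration
#'
#' Assembles and validates the settings for [runPipeline()]. Exactly one
#' input source is used: `phantom` (a cohort of synthetic animals) or
#' `manifest` (a CSV listing per-animal expansion-map files with columns
#' `id`, `group`, `path` and optional `mask_path`).
#'
#' @param phantom `NULL`, or a list with `nLittermates`, `nDiseased`,
#'   `diseaseProfile` (`"heterogeneous"` or `"clustered"`), and optional
#'   overrides passed to [phantomConfig()] (e.g. `gridShape`,
#'   `tidalFraction`, `heartBlur`).
#' @param manifest `NULL`, or path to the cohort manifest CSV.
#' @param route `"direct"` scores the phantom's ground-truth expansion
#'   scenes (fast); `"velocimetry"` synthesises breathing image sequences
#'   and runs the full measurement chain per animal.
#' @param windowSize,overlap velocimetry settings.
#' @param nBins histogram bins.
#' @param tauThreshold expired fraction defining tau.
#' @param zeroTol,blobThreshold heart-blur QC settings.
#' @param seed master seed for the run.
#' @param outDir output directory (created if missing); `NULL` disables
#'   file output.
#' @param plots write per-animal histogram/fit and curve figures (PNG).
#' @return A validated configuration list of class `xvRunConfig`.
#' @export
runConfig <- function(phantom = NULL, manifest = NULL,
                      route = c("direct", "velocimetry"),
                      windowSize = 64L, overlap = 0.5, nBins = 50L,
                      tauThreshold = 0.67, zeroTol = 0.05,
                      blobThreshold = 0.05, seed = 1L, outDir = NULL,
                      plots = FALSE) {
  route <- match.arg(route)
  if (is.null(phantom) && is.null(manifest))
    stop("validation: provide either phantom settings or a manifest path")
  if (!is.null(manifest) && !file.exists(manifest))
    stop("validation: manifest file not found: ", manifest)
  if (!is.null(phantom)) {
    if (is.null(phantom$nLittermates) || phantom$nLittermates < 1)
      stop("validation: phantom cohorts need at least one littermate")
    phantom$nDiseased <- phantom$nDiseased %||% 0L
    phantom$diseaseProfile <- phantom$diseaseProfile %||% "heterogeneous"
  }
  structure(list(phantom = phantom, manifest = manifest, route = route,
                 windowSize = as.integer(windowSize), overlap = overlap,
                 nBins = as.integer(nBins), tauThreshold = tauThreshold,
                 zeroTol = zeroTol, blobThreshold = blobThreshold,
                 seed = as.integer(seed), outDir = outDir, plots = plots),
            class = "xvRunConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One phantom animal through the chosen route; returns a cohortScores
# record.
phantomAnimal <- function(cfgRun, id, group, profile, animalSeed) {
  ph <- cfgRun$phantom
  extra <- ph[setdiff(names(ph),
                      c("nLittermates", "nDiseased", "diseaseProfile"))]
  cfg <- do.call(phantomConfig,
                 c(list(profile = profile, seed = animalSeed), extra))
  mask <- makeLungMask(cfg)
  scene <- makeExpansionScene(cfg, mask)
  curve <- makeBreathCurve(cfg)
  totalVol <- lungVolume(mask)
  if (cfgRun$route == "direct") {
    curve <- expiratoryTimeConstant(curve, cfgRun$tauThreshold)
    blur <- scene$truth@params$blurFraction >= cfgRun$blobThreshold
    return(list(id = id, group = group, map = scene$map,
                tau = curve@tau, fractionalTidalVolume = curve@tidalFraction,
                heartBlur = blur, truth = scene$truth))
  }
  seq <- makeSpeckleSequence(scene, curve, cfg)
  fields <- estimateDisplacements(seq$volumes, cfgRun$windowSize,
                                  cfgRun$overlap, mask = gridData(mask))
  vtc <- volumeTimeCurve(fields, curve@times, totalLungVolume = totalVol,
                         xvVoxelVolume = prod(fields[[1]]@gridStride) *
                           prod(cfg@voxelSize))
  # normalisation: XV voxel volume and lung volume both in mm^3
  vtc <- expiratoryTimeConstant(vtc, cfgRun$tauThreshold)
  peak <- which.max(vtc@fractionalVolume)
  emap <- fractionalExpansion(fields[seq_len(max(peak - 1L, 1L))])
  # QC on the frame with the most motion: blur regions stay near zero there
  meanMag <- vapply(fields, function(f) {
    v <- f@vectors
    mean(sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2), na.rm = TRUE)
  }, numeric(1))
  qc <- detectHeartBlur(fields[[which.max(meanMag)]],
                        zeroTol = cfgRun$zeroTol,
                        blobThreshold = cfgRun$blobThreshold)
  list(id = id, group = group, map = emap, tau = vtc@tau,
       fractionalTidalVolume = vtc@tidalFraction,
       heartBlur = qc@heartBlurFlag, truth = seq$truth)
}

manifestRecords <- function(cfgRun) {
  man <- utils::read.csv(cfgRun$manifest, stringsAsFactors = FALSE)
  need <- c("id", "group", "path")
  if (!all(need %in% names(man)))
    stop("validation: manifest must have columns id, group, path")
  lapply(seq_len(nrow(man)), function(i) {
    vol <- readVolume(man$path[i])
    vals <- gridData(vol)
    mask <- if ("mask_path" %in% names(man) && nzchar(man$mask_path[i]))
      gridData(readVolume(man$mask_path[i])) > 0 else is.finite(vals)
    map <- new("ExpansionMap", values = vals, mask = mask,
               exclusion = array(FALSE, dim(vals)),
               voxelVolume = prod(voxelSize(vol)))
    list(id = man$id[i], group = man$group[i], map = map)
  })
}

#' Run the full XV quantification pipeline over a cohort
#'
#' Executes, per animal, the configured route (phantom generation or file
#' loading, optionally preprocessing + velocimetry + expansion), then the
#' histogram/fit/score analysis and cohort normalisation, and writes the
#' cohort table, a config snapshot, a log, and optional figures to
#' `outDir`. A failing animal in a multi-animal cohort is flagged and
#' skipped with a warning; the cohort continues.
#'
#' @param config an `xvRunConfig` from [runConfig()].
#' @return The cohort `data.frame` (invisibly carries `iqr_L` as an
#'   attribute), with a `failed` attribute naming any skipped animals.
#' @examples
#' cfg <- runConfig(phantom = list(nLittermates = 2, nDiseased = 1,
#'                                 diseaseProfile = "clustered",
#'                                 gridShape = c(48L, 48L, 48L)),
#'                  seed = 1)
#' \donttest{tab <- runPipeline(cfg)}
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "xvRunConfig"))
    config <- do.call(runConfig, config)
  t0 <- Sys.time()
  records <- list()
  failed <- character(0)
  if (!is.null(config$phantom)) {
    ph <- config$phantom
    ids <- c(sprintf("L%02d", seq_len(ph$nLittermates)),
             if (ph$nDiseased > 0) sprintf("D%02d", seq_len(ph$nDiseased)))
    groups <- c(rep("littermate", ph$nLittermates),
                rep("disease", ph$nDiseased))
    profiles <- ifelse(groups == "littermate", "healthy",
                       ph$diseaseProfile)
    for (i in seq_along(ids)) {
      rec <- tryCatch(
        phantomAnimal(config, ids[i], groups[i], profiles[i],
                      childSeed(config$seed, 10L + i)),
        error = function(e) {
          warning(sprintf("animal %s failed (%s); skipped", ids[i],
                          conditionMessage(e)))
          NULL
        })
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
      else failed <- c(failed, ids[i])
    }
  } else {
    records <- manifestRecords(config)
  }
  if (!length(records)) stop("stage failure [cohort]: no animal succeeded")
  tab <- cohortScores(records, nBins = config$nBins)
  attr(tab, "failed") <- failed
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeCohortTable(tab, file.path(config$outDir, "cohort.csv"))
    snap <- unclass(config)
    snap$outDir <- NULL
    snap <- snap[!vapply(snap, is.null, logical(1))]
    jsonlite::write_json(snap, file.path(config$outDir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(c(sprintf("xvlung %s",
                         as.character(utils::packageVersion("xvlung"))),
                 sprintf("R %s", as.character(getRversion())),
                 sprintf("seed %d", config$seed),
                 sprintf("animals %d (failed: %s)", nrow(tab),
                         if (length(failed)) paste(failed, collapse = ",")
                         else "none"),
                 sprintf("elapsed %.1f s",
                         as.numeric(difftime(Sys.time(), t0, units = "secs")))),
               file.path(config$outDir, "log.txt"))
    if (isTRUE(config$plots)) {
      for (rec in records) {
        h <- expansionHistogram(rec$map, nBins = config$nBins)
        fit <- tryCatch(fitDoubleGaussian(h), error = function(e) NULL)
        row <- tab[tab$id == rec$id, ]
        grDevices::png(file.path(config$outDir,
                                 sprintf("hist_%s.png", rec$id)),
                       width = 600, height = 450)
        plotExpansionFit(h, fit, hd = row$hd, cd = row$cd,
                         main = sprintf("%s (%s)", rec$id, rec$group))
        grDevices::dev.off()
      }
    }
  }
  tab
}
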