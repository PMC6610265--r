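#' Read / write a run configuration
#'
#' Run configurations and simulation manifests are plain YAML: they
#' round-trip losslessly and are human-readable and versioned.
#'
#' @param config A named list.
#' @param path File path.
#' @return `readRunConfig` returns the list; `writeRunConfig` returns
#'   `path` invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

.defaultBiasModels <- function(seed) {
  list(
    Dixon = biasFieldSpec("smooth_random", correlationLength = 25,
                          amplitude = 0.05, seed = seed + 101L),
    UTE = biasFieldSpec("radial", centerScale = 1.02, edgeScale = 0.90),
    ModelBased = biasFieldSpec("uniform", s = 0.97))
}

#' Simulate a phantom study
#'
#' Builds the phantom scene, applies one bias field per attenuation
#' stand-in, and writes everything to disk: the reference dynamic image
#' (`CT.nii.gz`), the biased variants, the shared frame-schedule sidecar,
#' one truth mask per structure, and a YAML manifest describing the run.
#' The same seed always produces byte-identical image payloads.
#'
#' @param outDir Output directory (created if missing).
#' @param seed Integer seed driving noise and random bias fields.
#' @param spec A [phantomSpec()]; default [defaultPhantomSpec()] with this
#'   seed.
#' @param biasModels Named list of [biasFieldSpec()]s, one per attenuation
#'   stand-in. The defaults use magnitudes of at most 10%, the literature
#'   scale of MRI-based attenuation bias, but are uncalibrated stand-ins.
#' @return The manifest list, invisibly; written to `manifest.yaml`.
#' @export
runSimulate <- function(outDir, seed = 1L, spec = NULL, biasModels = NULL) {
  seed <- as.integer(seed)
  if (is.null(spec)) spec <- defaultPhantomSpec(seed = seed)
  if (is.null(biasModels)) biasModels <- .defaultBiasModels(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  ph <- buildPhantom(spec)
  schedPath <- file.path(outDir, "schedule.txt")
  writeFrameSchedule(spec$schedule, schedPath)
  writeDynamicImage(ph$image, file.path(outDir, "CT.nii.gz"))
  for (nmb in names(biasModels)) {
    field <- makeBiasField(biasModels[[nmb]], spec$geometry)
    writeDynamicImage(applyBias(ph$image, field),
                      file.path(outDir, paste0(nmb, ".nii.gz")))
  }
  maskFiles <- list()
  for (nms in names(ph$truth)) {
    f <- paste0("mask_", nms, ".nii.gz")
    writeMask(ph$truth[[nms]], spec$geometry, file.path(outDir, f))
    maskFiles[[nms]] <- f
  }
  lesionNames <- vapply(spec$lesions, `[[`, character(1), "name")
  manifest <- list(
    format = "dynFET-manifest v1",
    seed = seed,
    reference = "CT",
    methods = c("CT", names(biasModels)),
    schedule = as.list(frameEnds(spec$schedule)),
    images = c(list(CT = "CT.nii.gz"),
               stats::setNames(as.list(paste0(names(biasModels), ".nii.gz")),
                               names(biasModels))),
    masks = maskFiles,
    lesions = as.list(lesionNames),
    labels = as.list(ph$labels))
  writeRunConfig(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}

#' Analyse all lesions of a simulated (or assembled) study
#'
#' Reads a run manifest, evaluates every lesion on the reference image, and
#' re-evaluates it on each test image with the fixed-sphere and manual
#' 1-cm-sphere placements copied from the reference (the paper-style
#' procedure isolating the attenuation effect for fixed regions). Writes
#' one metrics row per (lesion, definition, attenuation method).
#'
#' @param runDir Directory holding `manifest.yaml` and the files it names.
#' @param outFile Output CSV path (default `metrics.csv` in `runDir`).
#' @param segConfig A [segmentationConfig()].
#' @param clsConfig A [classifierConfig()].
#' @return The metrics data.frame, invisibly.
#' @export
runAnalyze <- function(runDir, outFile = file.path(runDir, "metrics.csv"),
                       segConfig = segmentationConfig(),
                       clsConfig = classifierConfig()) {
  manifest <- readRunConfig(file.path(runDir, "manifest.yaml"))
  schedPath <- file.path(runDir, "schedule.txt")
  imgs <- lapply(manifest$images, function(f)
    readDynamicImage(file.path(runDir, f), schedPath))
  brainFile <- manifest$masks$brain_envelope
  if (is.null(brainFile)) brainFile <- manifest$masks$brain
  brainMask <- if (!is.null(brainFile))
    readMask(file.path(runDir, brainFile)) else NULL
  refName <- manifest$reference

  # The fixed ~2 mL sphere follows each reconstruction's own uptake maximum
  # (its clinical definition); the reader-style 1-cm sphere is placed once
  # on the reference and copied to every variant, isolating the pure
  # attenuation effect from delineation differences.
  summedRef <- windowedMeanImage(imgs[[refName]], 21, 40)
  allRows <- list()
  for (les in unlist(manifest$lesions)) {
    hint <- readMask(file.path(runDir, manifest$masks[[les]]))
    maxW <- gridToWorld(imgs[[refName]]@geometry,
                         findMaxVoxel(summedRef, hint))
    bgC <- mirrorContralateral(imgs[[refName]]@geometry, maxW)
    for (m in names(imgs)) {
      tm <- analyzeLesion(imgs[[m]], tumourHint = hint,
                          backgroundCenter = bgC, brainMask = brainMask,
                          manualCenters = list(maxW),
                          segConfig = segConfig, clsConfig = clsConfig,
                          lesionId = paste(les, m))
      allRows[[paste(les, m)]] <- metricsTable(tm, lesionId = les, acMethod = m)
    }
  }
  metrics <- do.call(rbind, c(allRows, list(make.row.names = FALSE)))
  utils::write.csv(metrics, outFile, row.names = FALSE)
  invisible(metrics)
}

.metricsFromRow <- function(row) {
  new("LesionMetrics", definition = row$definition,
      pattern2 = row$pattern2, pattern3 = row$pattern3,
      ttpFrame = as.integer(row$ttp_frame), ttpMin = as.numeric(row$ttp_min),
      tbr = as.numeric(row$tbr), volumeML = as.numeric(row$volume_ml),
      lateDescent = isTRUE(row$late_descent), excluded = isTRUE(row$excluded),
      exclusionReason = as.character(row$exclusion_reason))
}

#' Compare attenuation variants against the reference and summarise
#'
#' Builds per-lesion change records of every non-reference method against
#' the reference and aggregates them into the summary grid
#' (definitions x methods): pattern-change percentages, TTP summaries
#' (`"changed/evaluated (shifts...)"`), and relative TBR / volume
#' differences. Optionally writes the records, the summary and a plot of
#' the TBR and volume differences per method.
#'
#' @param metrics Metrics data.frame from [runAnalyze()], or a path to its
#'   CSV.
#' @param reference Label of the reference method (default `"CT"`).
#' @param outDir Optional output directory for `changes.csv`,
#'   `summary.csv` and `differences.pdf`.
#' @return List with `records` and `summary` data.frames.
#' @export
runCompare <- function(metrics, reference = "CT", outDir = NULL) {
  if (is.character(metrics)) metrics <- utils::read.csv(metrics)
  methods <- setdiff(unique(metrics$ac_method), reference)
  if (length(methods) == 0) {
    warning("only the reference method is present; nothing to compare")
    empty <- data.frame()
    return(list(records = empty, summary = empty))
  }
  toList <- function(sub) {
    out <- lapply(seq_len(nrow(sub)), function(i) .metricsFromRow(sub[i, ]))
    stats::setNames(out, sub$definition)
  }
  records <- list()
  for (les in unique(metrics$lesion_id)) {
    refSub <- metrics[metrics$lesion_id == les & metrics$ac_method == reference, ]
    for (m in methods) {
      tSub <- metrics[metrics$lesion_id == les & metrics$ac_method == m, ]
      defs <- intersect(refSub$definition, tSub$definition)
      records[[paste(les, m)]] <- compareToReference(
        toList(refSub[match(defs, refSub$definition), ]),
        toList(tSub[match(defs, tSub$definition), ]),
        lesionId = les, acMethod = m)
    }
  }
  records <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  summary <- aggregateChanges(records)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(outDir, "changes.csv"), row.names = FALSE)
    utils::write.csv(summary, file.path(outDir, "summary.csv"), row.names = FALSE)
    ev <- records[!records$excluded, ]
    grDevices::pdf(file.path(outDir, "differences.pdf"), width = 9, height = 4.5)
    graphics::par(mfrow = c(1, 2))
    graphics::boxplot(100 * tbr_rel_diff ~ ac_method, data = ev,
                      ylab = "TBR difference vs reference (%)",
                      xlab = "AC method", main = "TBR")
    graphics::abline(h = 0, lty = 2)
    graphics::boxplot(100 * volume_rel_diff ~ ac_method, data = ev,
                      ylab = "Volume difference vs reference (%)",
                      xlab = "AC method", main = "Delineated volume")
    graphics::abline(h = 0, lty = 2)
    grDevices::dev.off()
  }
  list(records = records, summary = summary)
}
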