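#' Full per-lesion evaluation under all region definitions
#'
#' Runs the complete single-lesion pipeline on one dynamic image: late
#' summed image (last 20 min, snapped to frame boundaries), the five region
#' definitions (ROI90, VOI90, ROI_TBR, VOI_TBR, VOI_FIX and optionally
#' reader-style 1-cm spheres), the plausibility check, TAC extraction, and
#' the pattern / TTP / TBR / volume metrics.
#'
#' The fixed sphere is centred on the in-tumour maximum unless `fixCenter`
#' is given; passing the reference image's centre reproduces the
#' copied-to-all-variants placement used to isolate the attenuation effect
#' from the delineation effect. A definition whose segmentation fails the
#' plausibility check (or cannot be grown at all) is returned as an excluded
#' [LesionMetrics-class] carrying the reason.
#'
#' @param img A [DynamicImage-class].
#' @param tumourHint Optional [RegionMask-class] restricting the max search
#'   (the visually selected lesion); `NULL` searches the whole volume.
#' @param backgroundCenter World centre (mm) of the contralateral background
#'   sphere; `NULL` mirrors the maximum across the mid-sagittal plane (the
#'   synthetic-mode auto-placement).
#' @param brainMask Optional brain [RegionMask-class] for the plausibility
#'   check.
#' @param fixCenter Optional world centre (mm) for the fixed ~2 mL sphere.
#' @param manualCenters Optional list of world centres for 1-cm spheres
#'   (evaluated as `SPHERE_MANUAL`, first centre only is reported under that
#'   tag; supply one per lesion).
#' @param segConfig A [segmentationConfig()].
#' @param clsConfig A [classifierConfig()].
#' @param lesionId Identifier used in log messages.
#' @param windowStart,windowEnd Summation window in minutes (default the
#'   paper-style last 20 min, 21-40, snapped to the 20-min boundary).
#' @return Named list of [LesionMetrics-class], one per evaluated
#'   definition; attribute `maxWorld` carries the in-tumour maximum's world
#'   coordinates so callers can propagate fixed placements.
#' @export
analyzeLesion <- function(img, tumourHint = NULL, backgroundCenter = NULL,
                          brainMask = NULL, fixCenter = NULL,
                          manualCenters = NULL,
                          segConfig = segmentationConfig(),
                          clsConfig = classifierConfig(),
                          lesionId = "lesion",
                          windowStart = 21, windowEnd = 40) {
  if (!is.null(tumourHint) && nrow(tumourHint@voxels) == 0L)
    stop("empty tumour hint")
  geom <- img@geometry
  summed <- windowedMeanImage(img, windowStart, windowEnd)
  maxIdx <- findMaxVoxel(summed, tumourHint)
  maxWorld <- gridToWorld(geom, maxIdx)
  if (is.null(backgroundCenter))
    backgroundCenter <- mirrorContralateral(geom, maxWorld)
  bg <- backgroundMean(summed, backgroundCenter, segConfig$backgroundDiameter)
  bgSphere <- sphereVOI(geom, backgroundCenter, segConfig$backgroundDiameter,
                        definition = "MANUAL")
  bgLast <- extractTAC(img, bgSphere)@meanSUV[nFrames(img)]

  grow <- function(fun) tryCatch(fun(), error = function(e) e)
  masks <- list(
    ROI90 = grow(function() segmentROI90(summed, tumourHint, segConfig)),
    VOI90 = grow(function() segmentVOI90(summed, tumourHint, segConfig)),
    ROI_TBR = grow(function() segmentTBR(summed, tumourHint, bg, "2D", segConfig)),
    VOI_TBR = grow(function() segmentTBR(summed, tumourHint, bg, "3D", segConfig)),
    VOI_FIX = grow(function() sphereVOI(geom,
                                        if (is.null(fixCenter)) maxWorld else fixCenter,
                                        segConfig$fixDiameter, "VOI_FIX")))
  if (!is.null(manualCenters)) {
    mc <- if (is.list(manualCenters)) manualCenters[[1L]] else manualCenters
    masks$SPHERE_MANUAL <- grow(function()
      sphereVOI(geom, mc, segConfig$manualSphereDiameter, "SPHERE_MANUAL"))
  }

  excludedMetrics <- function(def, reason) {
    logNote("[%s] %s excluded: %s", lesionId, def, reason)
    new("LesionMetrics", definition = def, pattern2 = NA_character_,
        pattern3 = NA_character_, ttpFrame = NA_integer_, ttpMin = NA_real_,
        tbr = NA_real_, volumeML = NA_real_, lateDescent = FALSE,
        excluded = TRUE, exclusionReason = reason)
  }

  out <- list()
  for (def in names(masks)) {
    m <- masks[[def]]
    if (inherits(m, "error")) {
      out[[def]] <- excludedMetrics(def, conditionMessage(m))
      next
    }
    chk <- plausibilityCheck(m, geom, segConfig, brainMask)
    if (!chk$pass) {
      out[[def]] <- excludedMetrics(def, chk$reason)
      next
    }
    tac <- extractTAC(img, m)
    ttp <- timeToPeak(tac)
    p2 <- classifyPattern2(tac, clsConfig)
    p3 <- classifyPattern3(tac, clsConfig)
    late <- isTRUE(attr(p3, "lateDescent"))
    if (late)
      logNote("[%s] %s: late peak with strong descent, outside the 3-class scheme; reported as PLATEAU",
              lesionId, def)
    out[[def]] <- new("LesionMetrics", definition = def,
                      pattern2 = p2, pattern3 = as.character(p3),
                      ttpFrame = ttp$frame, ttpMin = ttp$min,
                      tbr = tac@meanSUV[nFrames(img)] / bgLast,
                      volumeML = maskVolume(m, geom), lateDescent = late,
                      excluded = FALSE, exclusionReason = NA_character_)
  }
  attr(out, "maxWorld") <- maxWorld
  attr(out, "backgroundCenter") <- backgroundCenter
  out
}

#' Tabulate one lesion's metrics
#'
#' @param metrics Named list of [LesionMetrics-class] from [analyzeLesion()].
#' @param lesionId,acMethod Identifier columns added to each row.
#' @return A data.frame, one row per definition.
#' @export
metricsTable <- function(metrics, lesionId = "lesion", acMethod = "CT") {
  rows <- lapply(metrics, function(m) data.frame(
    lesion_id = lesionId, ac_method = acMethod, definition = m@definition,
    pattern2 = m@pattern2, pattern3 = m@pattern3,
    ttp_frame = m@ttpFrame, ttp_min = m@ttpMin, tbr = m@tbr,
    volume_ml = m@volumeML, late_descent = m@lateDescent,
    excluded = m@excluded, exclusion_reason = m@exclusionReason,
    stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Change records of one attenuation variant against the reference
#'
#' One record per region definition comparing a lesion's metrics under a
#' test attenuation method against the designated reference: pattern-label
#' changes, the TTP shift in units of time frames (`test - ref`), and the
#' relative TBR and volume differences (`(test - ref) / ref`). A definition
#' excluded in either evaluation yields an excluded record.
#'
#' @param ref,test Named lists of [LesionMetrics-class] with the same
#'   definitions evaluated.
#' @param lesionId,acMethod Identifier columns.
#' @return A data.frame of change records.
#' @export
compareToReference <- function(ref, test, lesionId = "lesion",
                               acMethod = "test") {
  defs <- names(ref)
  if (!setequal(defs, names(test)))
    stop("reference and test must carry the same definitions")
  rows <- lapply(defs, function(def) {
    r <- ref[[def]]; t <- test[[def]]
    if (r@excluded || t@excluded) {
      return(data.frame(
        lesion_id = lesionId, ac_method = acMethod, definition = def,
        pattern2_changed = NA, pattern3_changed = NA,
        delta_ttp_frames = NA_integer_, tbr_rel_diff = NA_real_,
        volume_rel_diff = NA_real_, excluded = TRUE,
        exclusion_reason = paste(stats::na.omit(c(r@exclusionReason,
                                                  t@exclusionReason)),
                                 collapse = "; "),
        stringsAsFactors = FALSE))
    }
    data.frame(
      lesion_id = lesionId, ac_method = acMethod, definition = def,
      pattern2_changed = t@pattern2 != r@pattern2,
      pattern3_changed = t@pattern3 != r@pattern3,
      delta_ttp_frames = t@ttpFrame - r@ttpFrame,
      tbr_rel_diff = (t@tbr - r@tbr) / r@tbr,
      volume_rel_diff = (t@volumeML - r@volumeML) / r@volumeML,
      excluded = FALSE, exclusion_reason = NA_character_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Aggregate change records into a summary table
#'
#' Per (definition, attenuation method): the percentage of evaluated lesions
#' whose two- and three-class patterns changed (rounded to whole percent,
#' with the raw fractions also emitted), the TTP summary formatted as
#' `"changed/evaluated (shifts...)"` where the bracketed multiset lists the
#' absolute frame shifts of the changed cases, the mean and range of the
#' relative TBR and volume differences, and the exclusion count.
#'
#' @param records Data.frame from [compareToReference()] (rows from several
#'   lesions/methods concatenated).
#' @return A summary data.frame, one row per (definition, ac_method).
#' @export
aggregateChanges <- function(records) {
  stopifnot(nrow(records) >= 1L)
  keys <- unique(records[, c("definition", "ac_method")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- records[records$definition == keys$definition[i] &
                     records$ac_method == keys$ac_method[i], ]
    ev <- sub[!sub$excluded, ]
    n <- nrow(ev)
    shifts <- abs(ev$delta_ttp_frames[ev$delta_ttp_frames != 0])
    ttpStr <- if (n == 0) "0/0" else sprintf(
      "%d/%d%s", length(shifts), n,
      if (length(shifts)) paste0(" (", paste(sort(shifts), collapse = ", "), ")")
      else "")
    pct <- function(x) if (n == 0) NA_real_ else round(100 * sum(x) / n)
    frac <- function(x) if (n == 0) NA_real_ else sum(x) / n
    data.frame(
      definition = keys$definition[i], ac_method = keys$ac_method[i],
      n_evaluated = n, n_excluded = sum(sub$excluded),
      pattern2_changed_pct = pct(ev$pattern2_changed),
      pattern3_changed_pct = pct(ev$pattern3_changed),
      pattern2_changed_frac = frac(ev$pattern2_changed),
      pattern3_changed_frac = frac(ev$pattern3_changed),
      ttp_summary = ttpStr,
      tbr_rel_diff_mean = if (n) mean(ev$tbr_rel_diff) else NA_real_,
      tbr_rel_diff_min = if (n) min(ev$tbr_rel_diff) else NA_real_,
      tbr_rel_diff_max = if (n) max(ev$tbr_rel_diff) else NA_real_,
      volume_rel_diff_mean = if (n) mean(ev$volume_rel_diff) else NA_real_,
      volume_rel_diff_min = if (n) min(ev$volume_rel_diff) else NA_real_,
      volume_rel_diff_max = if (n) max(ev$volume_rel_diff) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
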