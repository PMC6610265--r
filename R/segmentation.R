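#' Segmentation configuration
#'
#' Parameters of the five region definitions and the plausibility check.
#' Thresholds are inclusive (voxels with value equal to the threshold are
#' included).
#'
#' @param relThresholdMax Fraction of the in-tumour maximum used by the
#'   ROI90/VOI90 definitions (default 0.90).
#' @param tbrThreshold Background multiplier of the TBR definitions
#'   (default 1.6).
#' @param backgroundDiameter Diameter (mm) of the contralateral background
#'   sphere (default 20).
#' @param fixDiameter Diameter (mm) of the fixed spherical volume centred on
#'   the maximum uptake, ~2 mL (default 15.6).
#' @param manualSphereDiameter Diameter (mm) of reader-placed spheres
#'   (default 10).
#' @param connectivity3D Neighbour count for 3D growing: 6, 18 or 26
#'   (default 26).
#' @param connectivity2D Neighbour count for in-slice growing: 4 or 8
#'   (default 8).
#' @param maxPlausibleVolumeML Volume (mL) above which a segmentation is
#'   excluded as implausible (default 50).
#' @param maxOutsideBrainFraction Fraction of voxels outside a supplied
#'   brain mask above which a segmentation is excluded (default 0.20).
#' @return A `SegmentationConfig` list.
#' @export
segmentationConfig <- function(relThresholdMax = 0.90, tbrThreshold = 1.6,
                               backgroundDiameter = 20, fixDiameter = 15.6,
                               manualSphereDiameter = 10,
                               connectivity3D = 26, connectivity2D = 8,
                               maxPlausibleVolumeML = 50,
                               maxOutsideBrainFraction = 0.20) {
  stopifnot(relThresholdMax > 0, relThresholdMax <= 1, tbrThreshold > 0,
            backgroundDiameter > 0, fixDiameter > 0, manualSphereDiameter > 0,
            maxPlausibleVolumeML > 0, maxOutsideBrainFraction >= 0,
            maxOutsideBrainFraction <= 1)
  structure(list(relThresholdMax = relThresholdMax, tbrThreshold = tbrThreshold,
                 backgroundDiameter = backgroundDiameter,
                 fixDiameter = fixDiameter,
                 manualSphereDiameter = manualSphereDiameter,
                 connectivity3D = connectivity3D,
                 connectivity2D = connectivity2D,
                 maxPlausibleVolumeML = maxPlausibleVolumeML,
                 maxOutsideBrainFraction = maxOutsideBrainFraction),
            class = "SegmentationConfig")
}

#' Locate the hottest voxel
#'
#' Index of the maximum value within a search region (a [RegionMask-class]
#' or the whole volume). Ties are broken by the lexicographically smallest
#' (i, j, k) index, so the result is deterministic.
#'
#' @param img A [StaticImage-class].
#' @param searchMask Optional [RegionMask-class] restricting the search —
#'   the "within the tumour" hint. `NULL` searches the whole volume.
#' @return Integer vector (i, j, k).
#' @export
findMaxVoxel <- function(img, searchMask = NULL) {
  d <- dim(img@values)
  if (is.null(searchMask)) {
    lin <- seq_len(prod(d))
  } else {
    if (nrow(searchMask@voxels) == 0L) stop("empty search region")
    lin <- maskLinearIndices(searchMask, d)
  }
  vals <- img@values[lin]
  best <- lin[vals == max(vals)]
  # column-major linear order is lexicographic in (k, j, i); re-order to
  # lexicographic (i, j, k) as the tie-break rule requires
  ind <- arrayInd(best, d)
  o <- order(ind[, 1L], ind[, 2L], ind[, 3L])
  as.integer(ind[o[1L], ])
}

#' Threshold-based region growing
#'
#' Grows from a seed voxel to the connected component, under the configured
#' connectivity, of all voxels with value greater than or equal to the
#' threshold. `"2D"` mode restricts growth to the seed's axial (fixed-z)
#' slice with in-plane connectivity.
#'
#' @param img A [StaticImage-class].
#' @param seed Integer (i, j, k) seed voxel; its value must be >= threshold.
#' @param threshold Absolute SUV threshold (inclusive).
#' @param mode `"3D"` or `"2D"`.
#' @param config A [segmentationConfig()] supplying the connectivity.
#' @param definition Definition tag for the resulting mask.
#' @return A [RegionMask-class] (one connected component containing seed).
#' @export
regionGrow <- function(img, seed, threshold, mode = c("3D", "2D"),
                       config = segmentationConfig(), definition = "MANUAL") {
  mode <- match.arg(mode)
  d <- dim(img@values)
  seed <- as.integer(seed)
  stopifnot(length(seed) == 3L, all(seed >= 1L), all(seed <= d))
  if (img@values[seed[1L], seed[2L], seed[3L]] < threshold)
    stop("seed voxel is below the threshold")
  conn <- if (mode == "2D") config$connectivity2D else config$connectivity3D
  offs <- neighbourOffsets(conn, mode)
  above <- img@values >= threshold
  if (mode == "2D") {
    keep <- array(FALSE, dim = d)
    keep[, , seed[3L]] <- TRUE
    above <- above & keep
  }
  visited <- array(FALSE, dim = d)
  visited[seed[1L], seed[2L], seed[3L]] <- TRUE
  frontier <- matrix(seed, nrow = 1L)
  while (nrow(frontier) > 0) {
    cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), , drop = FALSE] +
      offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), , drop = FALSE]
    ok <- cand[, 1L] >= 1L & cand[, 1L] <= d[1L] &
      cand[, 2L] >= 1L & cand[, 2L] <= d[2L] &
      cand[, 3L] >= 1L & cand[, 3L] <= d[3L]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) break
    lin <- (cand[, 3L] - 1L) * (d[1L] * d[2L]) + (cand[, 2L] - 1L) * d[1L] + cand[, 1L]
    keep <- !duplicated(lin) & above[lin] & !visited[lin]
    lin <- lin[keep]
    if (length(lin) == 0) break
    visited[lin] <- TRUE
    frontier <- arrayInd(lin, d)
  }
  vox <- which(visited, arr.ind = TRUE)
  regionMask(vox, dimensionality = if (mode == "2D") "2D" else "3D",
             definition = definition)
}

#' Relative-to-maximum region definitions (ROI90 / VOI90)
#'
#' `segmentROI90` grows a 2D region in the axial slice holding the maximum
#' uptake, including all connected voxels at or above
#' `relThresholdMax x max`; `segmentVOI90` does the same in 3D. The maximum
#' is searched within the tumour hint when one is supplied.
#'
#' @param summed The late summed [StaticImage-class].
#' @param tumourHint Optional [RegionMask-class] restricting the max search.
#' @param config A [segmentationConfig()].
#' @return A [RegionMask-class] tagged `ROI90` / `VOI90`.
#' @export
segmentROI90 <- function(summed, tumourHint = NULL,
                         config = segmentationConfig()) {
  seed <- findMaxVoxel(summed, tumourHint)
  thr <- config$relThresholdMax *
    summed@values[seed[1L], seed[2L], seed[3L]]
  regionGrow(summed, seed, thr, mode = "2D", config = config,
             definition = "ROI90")
}

#' @rdname segmentROI90
#' @export
segmentVOI90 <- function(summed, tumourHint = NULL,
                         config = segmentationConfig()) {
  seed <- findMaxVoxel(summed, tumourHint)
  thr <- config$relThresholdMax *
    summed@values[seed[1L], seed[2L], seed[3L]]
  regionGrow(summed, seed, thr, mode = "3D", config = config,
             definition = "VOI90")
}

#' Background uptake in a contralateral sphere
#'
#' Mean summed-image SUV over a spherical volume (default 2 cm diameter)
#' placed on unaffected brain contralateral to the lesion.
#'
#' @param summed The late summed [StaticImage-class].
#' @param centerWorld Sphere centre in world mm.
#' @param diameter Sphere diameter in mm.
#' @return Mean SUV (scalar).
#' @export
backgroundMean <- function(summed, centerWorld, diameter = 20) {
  sph <- sphereVOI(summed@geometry, centerWorld, diameter,
                   definition = "MANUAL", requireInside = TRUE)
  mean(summed@values[maskLinearIndices(sph, dim(summed@values))])
}

#' Tissue-to-background threshold definitions (ROI_TBR / VOI_TBR)
#'
#' Region growing from the in-tumour maximum at the absolute threshold
#' `tbrThreshold x background` (default 1.6 x).
#'
#' @param summed The late summed [StaticImage-class].
#' @param tumourHint Optional [RegionMask-class] restricting the max search.
#' @param background Background SUV from [backgroundMean()]; must be > 0.
#' @param mode `"2D"` (ROI) or `"3D"` (VOI).
#' @param config A [segmentationConfig()].
#' @return A [RegionMask-class] tagged `ROI_TBR` / `VOI_TBR`.
#' @export
segmentTBR <- function(summed, tumourHint = NULL, background,
                       mode = c("3D", "2D"), config = segmentationConfig()) {
  mode <- match.arg(mode)
  stopifnot(background > 0)
  seed <- findMaxVoxel(summed, tumourHint)
  thr <- config$tbrThreshold * background
  if (summed@values[seed[1L], seed[2L], seed[3L]] < thr)
    stop("in-tumour maximum is below the TBR threshold; no region to grow")
  regionGrow(summed, seed, thr, mode = mode, config = config,
             definition = if (mode == "2D") "ROI_TBR" else "VOI_TBR")
}

#' Spherical volume of interest
#'
#' All voxels whose centres lie within `diameter / 2` of a world-space
#' centre (voxel-centre inclusion, no partial volumes). The default
#' 15.6 mm diameter realises the ~2 mL fixed volume centred on the maximum
#' uptake; 10 mm spheres realise reader-placed volumes.
#'
#' @param geometry An [ImageGeometry-class].
#' @param centerWorld Sphere centre in world mm.
#' @param diameter Sphere diameter in mm.
#' @param definition Definition tag (default `VOI_FIX`).
#' @param requireInside Error if the sphere extends beyond the volume.
#' @return A [RegionMask-class].
#' @export
sphereVOI <- function(geometry, centerWorld, diameter, definition = "VOI_FIX",
                      requireInside = FALSE) {
  r <- diameter / 2
  if (requireInside) {
    lo <- gridToWorld(geometry, c(1, 1, 1))
    hi <- gridToWorld(geometry, geometry@dim)
    if (any(centerWorld - r < lo - geometry@spacing / 2) ||
        any(centerWorld + r > hi + geometry@spacing / 2))
      stop("sphere exceeds the volume bounds")
  }
  arr <- ellipsoidArray(geometry, centerWorld, r)
  vox <- which(arr, arr.ind = TRUE)
  if (nrow(vox) == 0)
    stop("sphere contains no voxel centres (diameter below voxel spacing?)")
  regionMask(vox, dimensionality = "3D", definition = definition)
}

#' Plausibility check for threshold segmentations
#'
#' Operationalises the exclusion of segmentations whose threshold was too
#' low to be meaningful (regions flooding into extracerebral structures):
#' a mask is excluded when its volume exceeds `maxPlausibleVolumeML`, or
#' when a brain mask is supplied and more than `maxOutsideBrainFraction` of
#' its voxels fall outside the brain.
#'
#' @param mask A [RegionMask-class].
#' @param geometry The reference [ImageGeometry-class].
#' @param config A [segmentationConfig()].
#' @param brainMask Optional brain [RegionMask-class].
#' @return A list with `pass` (logical) and `reason` (`NA` when passing).
#' @export
plausibilityCheck <- function(mask, geometry, config = segmentationConfig(),
                              brainMask = NULL) {
  vol <- maskVolume(mask, geometry)
  if (vol > config$maxPlausibleVolumeML)
    return(list(pass = FALSE,
                reason = sprintf("volume %.1f mL exceeds %.1f mL",
                                 vol, config$maxPlausibleVolumeML)))
  if (!is.null(brainMask)) {
    d <- geometry@dim
    lin <- maskLinearIndices(mask, d)
    brainLin <- maskLinearIndices(brainMask, d)
    frac <- mean(!(lin %in% brainLin))
    if (frac > config$maxOutsideBrainFraction)
      return(list(pass = FALSE,
                  reason = sprintf("%.0f%% of voxels outside the brain mask",
                                   100 * frac)))
  }
  list(pass = TRUE, reason = NA_character_)
}

# Mirror a world point across the mid-sagittal (x = centre) plane: the
# automatic contralateral background placement for synthetic scenes.
mirrorContralateral <- function(geometry, world) {
  ax <- axisCoords(geometry)
  cx <- (ax[[1L]][1L] + ax[[1L]][length(ax[[1L]])]) / 2
  c(2 * cx - world[1L], world[2L], world[3L])
}
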