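#' @import methods
NULL

#' Frame schedule of a dynamic acquisition
#'
#' An ordered partition of the acquisition into contiguous, non-overlapping
#' reconstruction time frames, in minutes post injection (injection coincides
#' with acquisition start). The standard 40-min protocol uses eight frames of
#' 2 x 2, 4 x 4 and 2 x 10 minutes.
#'
#' @slot frames numeric matrix with columns \code{start} and \code{end}
#'   (minutes), one row per frame.
#' @seealso [frameSchedule()], [standardSchedule()]
#' @export
setClass("FrameSchedule", representation(frames = "matrix"))

setValidity("FrameSchedule", function(object) {
  f <- object@frames
  if (!is.numeric(f) || ncol(f) != 2L) return("frames must be a numeric matrix with 2 columns")
  if (nrow(f) < 1L) return("schedule must contain at least one frame")
  if (any(!is.finite(f))) return("frame times must be finite")
  if (abs(f[1L, 1L]) > 1e-9) return("first frame must start at 0 min")
  if (any(f[, 2L] - f[, 1L] <= 0)) return("all frame durations must be > 0")
  if (nrow(f) > 1L && any(abs(f[-1L, 1L] - f[-nrow(f), 2L]) > 1e-9))
    return("frames must be contiguous: each start must equal the previous end")
  TRUE
})

#' Voxel grid geometry
#'
#' Axis-aligned voxel lattice: grid dimensions, spacing and the world
#' coordinates (mm) of the centre of voxel (1, 1, 1). Axes are ordered
#' (x, y, z); axial slices are fixed-z planes.
#'
#' @slot dim integer of length 3, voxel counts (nx, ny, nz).
#' @slot spacing numeric of length 3, voxel edge lengths (dx, dy, dz) in mm.
#' @slot origin numeric of length 3, world coordinates of the first voxel
#'   centre in mm.
#' @seealso [imageGeometry()]
#' @export
setClass("ImageGeometry",
         representation(dim = "integer", spacing = "numeric", origin = "numeric"))

setValidity("ImageGeometry", function(object) {
  if (length(object@dim) != 3L || any(object@dim <= 0L)) return("dim must be 3 positive integers")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 positive numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite numbers (mm)")
  TRUE
})

#' Dynamic PET image
#'
#' A 4D standardised-uptake-value (SUV) voxel grid: one 3D volume per
#' reconstruction frame, with its geometry and frame schedule.
#'
#' @slot geometry an [ImageGeometry-class].
#' @slot schedule a [FrameSchedule-class]; its length equals the 4th array dim.
#' @slot values 4D numeric array indexed (x, y, z, frame), SUV (dimensionless).
#' @seealso [dynamicImage()], [readDynamicImage()]
#' @export
setClass("DynamicImage",
         representation(geometry = "ImageGeometry", schedule = "FrameSchedule",
                        values = "array"))

setValidity("DynamicImage", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L) return("values must be a 4D array (x, y, z, frame)")
  if (!all(d[1:3] == object@geometry@dim)) return("spatial dims must match geometry")
  if (d[4L] != nrow(object@schedule@frames))
    return("number of frames must equal schedule length")
  if (any(!is.finite(object@values))) return("all values must be finite")
  TRUE
})

#' Static (time-windowed) PET image
#'
#' A 3D SUV volume derived from a dynamic image over a stated time window,
#' e.g. the late summed image used for lesion delineation.
#'
#' @slot geometry an [ImageGeometry-class].
#' @slot values 3D numeric array indexed (x, y, z), SUV.
#' @slot window numeric of length 2, (start_min, end_min) provenance.
#' @seealso [windowedMeanImage()]
#' @export
setClass("StaticImage",
         representation(geometry = "ImageGeometry", values = "array",
                        window = "numeric"))

setValidity("StaticImage", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3D array (x, y, z)")
  if (!all(d == object@geometry@dim)) return("dims must match geometry")
  if (any(!is.finite(object@values))) return("all values must be finite")
  if (length(object@window) != 2L) return("window must have length 2")
  TRUE
})

#' Region of interest as a voxel set
#'
#' A set of voxel indices on a reference geometry. 2D masks live in a single
#' axial (fixed-z) slice; 3D masks may span slices. Region-growing
#' constructors guarantee a single connected component under the configured
#' connectivity; hand-built masks need not be connected.
#'
#' @slot voxels integer matrix with columns (i, j, k), 1-based voxel indices.
#' @slot dimensionality \code{"2D"} or \code{"3D"}.
#' @slot definition one of ROI90, VOI90, ROI_TBR, VOI_TBR, VOI_FIX,
#'   SPHERE_MANUAL, MANUAL.
#' @slot sliceIndex the z index for 2D masks; \code{NA} for 3D masks.
#' @seealso [regionMask()], [regionGrow()], [sphereVOI()]
#' @export
setClass("RegionMask",
         representation(voxels = "matrix", dimensionality = "character",
                        definition = "character", sliceIndex = "integer"))

.maskDefinitions <- c("ROI90", "VOI90", "ROI_TBR", "VOI_TBR", "VOI_FIX",
                      "SPHERE_MANUAL", "MANUAL")

setValidity("RegionMask", function(object) {
  v <- object@voxels
  if (!is.matrix(v) || ncol(v) != 3L || !is.integer(v))
    return("voxels must be an integer matrix with 3 columns (i, j, k)")
  if (nrow(v) > 0 && any(v < 1L)) return("voxel indices are 1-based and must be >= 1")
  if (!object@dimensionality %in% c("2D", "3D")) return("dimensionality must be 2D or 3D")
  if (!object@definition %in% .maskDefinitions)
    return(paste("definition must be one of:", paste(.maskDefinitions, collapse = ", ")))
  if (object@dimensionality == "2D") {
    if (is.na(object@sliceIndex)) return("2D masks need a sliceIndex")
    if (nrow(v) > 0 && any(v[, 3L] != object@sliceIndex))
      return("2D mask voxels must all lie in sliceIndex")
  }
  TRUE
})

#' Time-activity curve
#'
#' Mean SUV over a region per reconstruction frame, paired with the time
#' elapsed from acquisition start to the end of each frame.
#'
#' @slot frameEnd numeric, frame end times in minutes, strictly increasing.
#' @slot meanSUV numeric, mean regional SUV per frame.
#' @slot nVoxels integer, voxel count of the source region.
#' @slot definition the definition tag of the source region.
#' @seealso [extractTAC()], [timeToPeak()], [classifyPattern3()]
#' @export
setClass("TimeActivityCurve",
         representation(frameEnd = "numeric", meanSUV = "numeric",
                        nVoxels = "integer", definition = "character"))

setValidity("TimeActivityCurve", function(object) {
  if (length(object@frameEnd) != length(object@meanSUV))
    return("frameEnd and meanSUV must have equal length")
  if (length(object@frameEnd) < 1L) return("curve must be non-empty")
  if (any(diff(object@frameEnd) <= 0)) return("frameEnd must be strictly increasing")
  if (object@nVoxels < 1L) return("nVoxels must be >= 1")
  TRUE
})

#' Per-lesion metrics bundle
#'
#' Metrics for one lesion under one region definition: the two- and
#' three-class pattern labels, time to peak, tissue-to-background ratio and
#' delineated volume, plus an exclusion flag when the segmentation failed the
#' plausibility check.
#'
#' @slot definition region definition tag.
#' @slot pattern2 \code{"INCREASING"} or \code{"DECREASING"}.
#' @slot pattern3 \code{"INCREASING"}, \code{"PLATEAU"} or \code{"DECREASING"}.
#' @slot ttpFrame 1-based index of the earliest frame attaining the maximum.
#' @slot ttpMin end time (min) of that frame.
#' @slot tbr lesion-to-background ratio in the last 10-min frame.
#' @slot volumeML delineated volume in mL.
#' @slot lateDescent TRUE when the curve peaked after the early-peak cutoff
#'   but then fell by more than the descent fraction (a shape outside the
#'   three-class scheme, reported as PLATEAU with this flag raised).
#' @slot excluded TRUE when the segmentation was excluded.
#' @slot exclusionReason reason string, \code{NA} when not excluded.
#' @seealso [analyzeLesion()]
#' @export
setClass("LesionMetrics",
         representation(definition = "character", pattern2 = "character",
                        pattern3 = "character", ttpFrame = "integer",
                        ttpMin = "numeric", tbr = "numeric",
                        volumeML = "numeric", lateDescent = "logical",
                        excluded = "logical", exclusionReason = "character"))

setValidity("LesionMetrics", function(object) {
  if (!object@definition %in% .maskDefinitions) return("unknown definition tag")
  if (!object@excluded) {
    if (!object@pattern2 %in% c("INCREASING", "DECREASING")) return("bad pattern2")
    if (!object@pattern3 %in% c("INCREASING", "PLATEAU", "DECREASING")) return("bad pattern3")
    if (object@volumeML <= 0) return("volumeML must be > 0")
    if (is.finite(object@tbr) && object@tbr <= 0) return("tbr must be > 0")
  }
  TRUE
})

## show methods -------------------------------------------------------------

setMethod("show", "FrameSchedule", function(object) {
  f <- object@frames
  cat(sprintf("FrameSchedule: %d frames, 0-%g min\n", nrow(f), f[nrow(f), 2L]))
  cat("  ends (min): ", paste(signif(f[, 2L], 4), collapse = ", "), "\n", sep = "")
})

setMethod("show", "ImageGeometry", function(object) {
  cat(sprintf("ImageGeometry: %d x %d x %d voxels @ %g x %g x %g mm\n",
              object@dim[1], object@dim[2], object@dim[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "DynamicImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("DynamicImage: %d x %d x %d voxels, %d frames, SUV range [%.3g, %.3g]\n",
              d[1], d[2], d[3], d[4], min(object@values), max(object@values)))
  show(object@schedule)
})

setMethod("show", "StaticImage", function(object) {
  cat(sprintf("StaticImage (window %g-%g min): %d x %d x %d voxels, SUV range [%.3g, %.3g]\n",
              object@window[1], object@window[2],
              dim(object@values)[1], dim(object@values)[2], dim(object@values)[3],
              min(object@values), max(object@values)))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask [%s, %s]: %d voxels%s\n", object@definition,
              object@dimensionality, nrow(object@voxels),
              if (object@dimensionality == "2D")
                sprintf(" in slice z=%d", object@sliceIndex) else ""))
})

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve [%s], %d voxels:\n", object@definition,
              object@nVoxels))
  print(data.frame(end_min = object@frameEnd, mean_suv = signif(object@meanSUV, 5)))
})

setMethod("show", "LesionMetrics", function(object) {
  if (object@excluded) {
    cat(sprintf("LesionMetrics [%s]: EXCLUDED (%s)\n", object@definition,
                object@exclusionReason))
  } else {
    cat(sprintf(
      "LesionMetrics [%s]: pattern2=%s pattern3=%s%s TTP=frame %d (%g min) TBR=%.3f vol=%.3f mL\n",
      object@definition, object@pattern2, object@pattern3,
      if (object@lateDescent) "(late-descent)" else "",
      object@ttpFrame, object@ttpMin, object@tbr, object@volumeML))
  }
})
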