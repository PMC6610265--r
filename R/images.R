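#' Construct a dynamic image
#'
#' @param values 4D numeric array indexed (x, y, z, frame), SUV units.
#' @param geometry An [ImageGeometry-class] matching the spatial dims.
#' @param schedule A [FrameSchedule-class] matching the 4th dim.
#' @return A [DynamicImage-class].
#' @export
dynamicImage <- function(values, geometry, schedule) {
  new("DynamicImage", geometry = geometry, schedule = schedule,
      values = values)
}

#' Construct a static image
#'
#' @param values 3D numeric array (x, y, z), SUV units.
#' @param geometry An [ImageGeometry-class].
#' @param window Length-2 numeric, the (start, end) minutes the volume
#'   represents.
#' @return A [StaticImage-class].
#' @export
staticImage <- function(values, geometry, window = c(NA_real_, NA_real_)) {
  new("StaticImage", geometry = geometry, values = values,
      window = as.numeric(window))
}

#' Construct a region mask
#'
#' @param voxels Integer n x 3 matrix of 1-based (i, j, k) voxel indices.
#' @param dimensionality `"2D"` (single axial slice) or `"3D"`.
#' @param definition A definition tag (default `"MANUAL"`).
#' @return A [RegionMask-class].
#' @export
regionMask <- function(voxels, dimensionality = "3D", definition = "MANUAL") {
  if (is.null(dim(voxels))) voxels <- matrix(voxels, nrow = 1L)
  voxels <- as.matrix(voxels)
  storage.mode(voxels) <- "integer"
  colnames(voxels) <- c("i", "j", "k")
  slice <- if (dimensionality == "2D" && nrow(voxels) > 0)
    voxels[1L, 3L] else NA_integer_
  new("RegionMask", voxels = voxels, dimensionality = dimensionality,
      definition = definition, sliceIndex = as.integer(slice))
}

#' @rdname accessors
#' @export
setMethod("geometry", "DynamicImage", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "StaticImage", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("schedule", "DynamicImage", function(x) x@schedule)
#' @rdname accessors
#' @export
setMethod("voxelData", "DynamicImage", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("voxelData", "StaticImage", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("nFrames", "DynamicImage", function(x) nFrames(x@schedule))
#' @rdname accessors
#' @export
setMethod("maskVoxels", "RegionMask", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("definitionTag", "RegionMask", function(x) x@definition)
#' @rdname accessors
#' @export
setMethod("definitionTag", "TimeActivityCurve", function(x) x@definition)
#' @rdname accessors
#' @export
setMethod("definitionTag", "LesionMetrics", function(x) x@definition)
#' @rdname accessors
#' @export
setMethod("meanSUV", "TimeActivityCurve", function(x) x@meanSUV)
#' @rdname accessors
#' @export
setMethod("frameEnds", "TimeActivityCurve", function(x) x@frameEnd)

#' @rdname accessors
#' @export
setMethod("maskVolume", signature("RegionMask", "ImageGeometry"),
          function(x, geometry) nrow(x@voxels) * voxelVolume(geometry))

# Linear (column-major) indices of mask voxels in a 3D array of dims `d`.
maskLinearIndices <- function(mask, d) {
  v <- mask@voxels
  if (any(v[, 1L] > d[1L] | v[, 2L] > d[2L] | v[, 3L] > d[3L]))
    stop("mask voxels fall outside the image grid")
  (v[, 3L] - 1L) * (d[1L] * d[2L]) + (v[, 2L] - 1L) * d[1L] + v[, 1L]
}

#' Duration-weighted mean image over a time window
#'
#' Collapses the frames covering `[startMin, endMin]` into a single 3D SUV
#' volume using duration weights. SUV is an intensive quantity, so a weighted
#' mean (rather than a raw sum) preserves its units; relative thresholds such
#' as 90% of the maximum are unaffected by this choice. Window endpoints that
#' do not coincide with frame boundaries are snapped to the nearest boundary
#' with a warning: frames are the atomic unit of reconstructed data.
#'
#' @param img A [DynamicImage-class].
#' @param startMin,endMin Window in minutes post injection.
#' @param snap If `FALSE`, non-boundary endpoints are an error instead of
#'   being snapped.
#' @return A [StaticImage-class] carrying the (snapped) window.
#' @examples
#' geom <- imageGeometry(c(4, 4, 4), 2)
#' vals <- array(1, dim = c(4, 4, 4, 8))
#' img <- dynamicImage(vals, geom, standardSchedule())
#' windowedMeanImage(img, 20, 40)
#' @export
windowedMeanImage <- function(img, startMin, endMin, snap = TRUE) {
  idx <- frameWindow(img@schedule, startMin, endMin, snap = snap)
  w <- frameDurations(img@schedule)[idx]
  d <- dim(img@values)
  acc <- array(0, dim = d[1:3])
  for (n in seq_along(idx))
    acc <- acc + w[n] * img@values[, , , idx[n], drop = TRUE]
  acc <- acc / sum(w)
  staticImage(acc, img@geometry,
              window = c(frameStarts(img@schedule)[idx[1L]],
                         frameEnds(img@schedule)[idx[length(idx)]]))
}

#' Extract the 3D volume of a single frame
#'
#' @param img A [DynamicImage-class].
#' @param frame 1-based frame index.
#' @return A [StaticImage-class] whose window is that frame's span.
#' @export
frameImage <- function(img, frame) {
  stopifnot(frame >= 1L, frame <= nFrames(img))
  staticImage(img@values[, , , frame, drop = TRUE], img@geometry,
              window = c(frameStarts(img@schedule)[frame],
                         frameEnds(img@schedule)[frame]))
}
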