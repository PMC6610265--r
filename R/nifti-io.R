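# NIfTI I/O via RNifti. The affine is a diagonal voxel-size matrix plus the
# origin translation (axis-aligned grids only; orientation handling beyond
# that is out of scope here).

.geometryAffine <- function(geometry) {
  m <- diag(c(geometry@spacing, 1))
  m[1:3, 4L] <- geometry@origin
  m
}

.affineGeometry <- function(img) {
  x <- RNifti::xform(img)
  d <- dim(img)[1:3]
  spacing <- abs(diag(x)[1:3])
  if (any(spacing <= 0)) spacing <- RNifti::pixdim(img)[1:3]
  imageGeometry(d, spacing, x[1:3, 4L])
}

#' Read / write dynamic images as 4D NIfTI plus a schedule sidecar
#'
#' `readDynamicImage` loads a 4D NIfTI volume (SUV units) and a frame
#' schedule sidecar (see [readFrameSchedule()]) and validates them against
#' each other: the frame counts must match, the schedule must be contiguous
#' and strictly increasing, and no frame may be entirely NaN.
#'
#' @param imagePath Path to a 4D NIfTI file.
#' @param schedulePath Path to the schedule sidecar.
#' @param img A [DynamicImage-class] to write.
#' @return `readDynamicImage` returns a [DynamicImage-class];
#'   `writeDynamicImage` returns `imagePath` invisibly.
#' @export
readDynamicImage <- function(imagePath, schedulePath) {
  if (!file.exists(imagePath)) stop("image file not found: ", imagePath)
  sched <- readFrameSchedule(schedulePath)
  nim <- RNifti::readNifti(imagePath)
  vals <- array(as.vector(nim), dim = dim(nim))
  if (length(dim(vals)) == 3L) dim(vals) <- c(dim(vals), 1L)
  if (length(dim(vals)) != 4L) stop("expected a 4D NIfTI image")
  if (dim(vals)[4L] != nFrames(sched))
    stop(sprintf("frame-count mismatch: image has %d frames, schedule has %d",
                 dim(vals)[4L], nFrames(sched)))
  for (f in seq_len(dim(vals)[4L]))
    if (all(is.nan(vals[, , , f])))
      stop(sprintf("frame %d is entirely NaN", f))
  if (any(!is.finite(vals)))
    stop("image contains non-finite voxel values")
  dynamicImage(vals, .affineGeometry(nim), sched)
}

#' @rdname readDynamicImage
#' @export
writeDynamicImage <- function(img, imagePath, schedulePath = NULL) {
  nim <- RNifti::asNifti(img@values)
  RNifti::pixdim(nim) <- c(img@geometry@spacing, 1)
  RNifti::qform(nim) <- structure(.geometryAffine(img@geometry), code = 2L)
  RNifti::writeNifti(nim, imagePath, datatype = "float")
  if (!is.null(schedulePath)) writeFrameSchedule(img@schedule, schedulePath)
  invisible(imagePath)
}

#' Write / read region masks as 3D label NIfTI
#'
#' `writeMask` rasterises a [RegionMask-class] onto its reference geometry as
#' a 0/1 volume; `readMask` recovers the voxel set from such a volume.
#'
#' @param mask A [RegionMask-class].
#' @param geometry The reference [ImageGeometry-class].
#' @param path Output NIfTI path.
#' @param definition Definition tag attached to the mask on reading.
#' @return `writeMask` returns `path` invisibly; `readMask` a
#'   [RegionMask-class].
#' @export
writeMask <- function(mask, geometry, path) {
  arr <- array(0L, dim = geometry@dim)
  if (nrow(mask@voxels) > 0)
    arr[maskLinearIndices(mask, geometry@dim)] <- 1L
  nim <- RNifti::asNifti(arr)
  RNifti::pixdim(nim) <- geometry@spacing
  RNifti::qform(nim) <- structure(.geometryAffine(geometry), code = 2L)
  RNifti::writeNifti(nim, path, datatype = "uint8")
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path, definition = "MANUAL") {
  nim <- RNifti::readNifti(path)
  arr <- array(as.vector(nim), dim = dim(nim))
  vox <- which(arr > 0, arr.ind = TRUE)
  regionMask(vox, dimensionality = "3D", definition = definition)
}
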