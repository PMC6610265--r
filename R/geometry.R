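#' Construct a voxel-grid geometry
#'
#' @param dim Voxel counts (nx, ny, nz).
#' @param spacing Voxel edge lengths (dx, dy, dz) in mm; a scalar is recycled.
#' @param origin World coordinates (mm) of the centre of voxel (1, 1, 1).
#' @return An [ImageGeometry-class].
#' @examples
#' imageGeometry(c(96, 96, 64), 2)
#' @export
imageGeometry <- function(dim, spacing = 1, origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageGeometry", dim = as.integer(dim), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @rdname accessors
#' @export
setMethod("voxelVolume", "ImageGeometry",
          function(x) prod(x@spacing) / 1000)  # mm^3 -> mL

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 1-based; world coordinates are voxel-centre positions in
#' mm. `gridToWorld` accepts a vector of length 3 or an n x 3 matrix.
#' `worldToGrid` returns the nearest voxel index (not clamped to the grid).
#'
#' @param geometry An [ImageGeometry-class].
#' @param idx Voxel indices (vector or n x 3 matrix).
#' @param xyz World coordinates in mm (vector or n x 3 matrix).
#' @return A vector or matrix of the converted coordinates.
#' @export
gridToWorld <- function(geometry, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1L)
  out <- sweep(sweep(idx - 1, 2L, geometry@spacing, "*"), 2L, geometry@origin, "+")
  if (nrow(out) == 1L) drop(out) else out
}

#' @rdname gridToWorld
#' @export
worldToGrid <- function(geometry, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  out <- round(sweep(sweep(xyz, 2L, geometry@origin, "-"), 2L,
                     geometry@spacing, "/")) + 1
  storage.mode(out) <- "integer"
  if (nrow(out) == 1L) drop(out) else out
}

# Per-axis vectors of voxel-centre world coordinates.
axisCoords <- function(geometry) {
  lapply(1:3, function(a)
    geometry@origin[a] + (seq_len(geometry@dim[a]) - 1) * geometry@spacing[a])
}

# Logical 3D array of voxels whose centres lie inside the given ellipsoid
# (world-space centre and semiaxes in mm). A sphere is the equal-axes case.
ellipsoidArray <- function(geometry, center, semiaxes) {
  if (length(semiaxes) == 1L) semiaxes <- rep(semiaxes, 3L)
  ax <- axisCoords(geometry)
  u2 <- lapply(1:3, function(a) ((ax[[a]] - center[a]) / semiaxes[a])^2)
  d <- geometry@dim
  arr <- array(rep(u2[[1L]], times = d[2L] * d[3L]), dim = d)
  arr <- arr + array(rep(rep(u2[[2L]], each = d[1L]), times = d[3L]), dim = d)
  arr <- arr + array(rep(u2[[3L]], each = d[1L] * d[2L]), dim = d)
  arr <= 1
}

# Logical array of a z-axis-aligned cylinder: world centre, radius (mm) in
# the xy-plane, half-length (mm) along z.
cylinderArray <- function(geometry, center, radius, halfLength) {
  ax <- axisCoords(geometry)
  d <- geometry@dim
  r2 <- outer((ax[[1L]] - center[1L])^2, (ax[[2L]] - center[2L])^2, "+")
  inXY <- r2 <= radius^2
  inZ <- abs(ax[[3L]] - center[3L]) <= halfLength
  arr <- array(inXY, dim = d)
  zmask <- array(rep(inZ, each = d[1L] * d[2L]), dim = d)
  arr & zmask
}

# Logical array of an ellipsoidal shell between inner and outer semiaxes.
shellArray <- function(geometry, center, outerSemiaxes, innerSemiaxes) {
  ellipsoidArray(geometry, center, outerSemiaxes) &
    !ellipsoidArray(geometry, center, innerSemiaxes)
}
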