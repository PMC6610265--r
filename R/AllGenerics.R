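#' @include utils.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the image, mask and curve classes.
#'
#' @param x,object An object of one of the package's classes.
#' @param ... Further arguments for methods.
#' @return The slot content described by each method's documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geometry", function(x, ...) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("schedule", function(x, ...) standardGeneric("schedule"))

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x, ...) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x, ...) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameStarts", function(x, ...) standardGeneric("frameStarts"))

#' @rdname accessors
#' @export
setGeneric("frameEnds", function(x, ...) standardGeneric("frameEnds"))

#' @rdname accessors
#' @export
setGeneric("frameDurations", function(x, ...) standardGeneric("frameDurations"))

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x, ...) standardGeneric("voxelVolume"))

#' @rdname accessors
#' @export
setGeneric("maskVoxels", function(x, ...) standardGeneric("maskVoxels"))

#' @rdname accessors
#' @export
setGeneric("maskVolume", function(x, geometry, ...) standardGeneric("maskVolume"))

#' @rdname accessors
#' @export
setGeneric("definitionTag", function(x, ...) standardGeneric("definitionTag"))

#' @rdname accessors
#' @export
setGeneric("meanSUV", function(x, ...) standardGeneric("meanSUV"))
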