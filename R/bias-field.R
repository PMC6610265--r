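#' Attenuation-correction bias field specification
#'
#' In dynamic PET every reconstructed frame is corrected with the same
#' attenuation map, so an imperfect map produces one spatially varying,
#' time-independent multiplicative error field applied to all frames. Three
#' field models are provided as stand-ins for MRI-based attenuation methods
#' compared against a CT reference:
#' \describe{
#'   \item{uniform}{constant scale `s` everywhere (a pure global bias).}
#'   \item{radial}{linear interpolation from `centerScale` at the volume
#'     centre to `edgeScale` on the bounding-sphere surface — mimics the
#'     centre-vs-skull gradient of maps that misrepresent bone.}
#'   \item{smooth_random}{Gaussian-filtered white noise rescaled to
#'     `1 +/- amplitude` — mimics spatially structured local bias with a
#'     chosen correlation length.}
#' }
#' Field values are strictly positive for any `amplitude < 1`.
#'
#' @param model `"uniform"`, `"radial"` or `"smooth_random"`.
#' @param s Scale of the uniform field.
#' @param centerScale,edgeScale Radial field scales at centre / edge.
#' @param correlationLength Gaussian smoothing length in mm (smooth_random).
#' @param amplitude Half-range of the smooth_random field about 1; must be
#'   in (0, 1).
#' @param seed Integer seed; fully determines a smooth_random field.
#' @return A `BiasFieldSpec` object.
#' @examples
#' makeBiasField(biasFieldSpec("radial", centerScale = 1, edgeScale = 0.9),
#'               imageGeometry(c(16, 16, 16), 4))[8, 8, 8]
#' @export
biasFieldSpec <- function(model = c("uniform", "radial", "smooth_random"),
                          s = 1, centerScale = 1, edgeScale = 0.9,
                          correlationLength = 20, amplitude = 0.1,
                          seed = 1L) {
  model <- match.arg(model)
  if (model == "uniform") stopifnot_scalar_number(s, "s", positive = TRUE)
  if (model == "radial") {
    stopifnot_scalar_number(centerScale, "centerScale", positive = TRUE)
    stopifnot_scalar_number(edgeScale, "edgeScale", positive = TRUE)
  }
  if (model == "smooth_random") {
    stopifnot_scalar_number(correlationLength, "correlationLength", positive = TRUE)
    stopifnot_scalar_number(amplitude, "amplitude", positive = TRUE)
    if (amplitude >= 1) stop("amplitude must be < 1 to keep the field positive")
  }
  structure(list(model = model, s = s, centerScale = centerScale,
                 edgeScale = edgeScale, correlationLength = correlationLength,
                 amplitude = amplitude, seed = as.integer(seed)),
            class = "BiasFieldSpec")
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
# Edge handling: kernel truncated at the boundary and renormalised.
gaussSmooth3D <- function(arr, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  convMatrix <- function(n, sg) {
    if (sg <= 0) return(diag(n))
    half <- max(1L, ceiling(3 * sg))
    off <- -half:half
    k <- exp(-off^2 / (2 * sg^2))
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + off
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    K
  }
  d <- dim(arr)
  # axis 1
  m <- convMatrix(d[1L], sigma[1L]) %*% matrix(arr, d[1L])
  arr <- array(m, d)
  # axis 2
  a2 <- aperm(arr, c(2L, 1L, 3L))
  m <- convMatrix(d[2L], sigma[2L]) %*% matrix(a2, d[2L])
  arr <- aperm(array(m, d[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
  # axis 3
  a3 <- aperm(arr, c(3L, 1L, 2L))
  m <- convMatrix(d[3L], sigma[3L]) %*% matrix(a3, d[3L])
  aperm(array(m, d[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
}

#' Realise a bias field on a geometry
#'
#' @param spec A [biasFieldSpec()].
#' @param geometry An [ImageGeometry-class].
#' @return A 3D numeric array of strictly positive multiplicative factors.
#' @export
makeBiasField <- function(spec, geometry) {
  stopifnot(inherits(spec, "BiasFieldSpec"))
  d <- geometry@dim
  switch(spec$model,
    uniform = array(spec$s, dim = d),
    radial = {
      ax <- axisCoords(geometry)
      ctr <- vapply(ax, function(v) (v[1L] + v[length(v)]) / 2, numeric(1))
      # bounding sphere: radius to the farthest voxel centre
      u2 <- lapply(1:3, function(a) (ax[[a]] - ctr[a])^2)
      r2 <- array(rep(u2[[1L]], times = d[2L] * d[3L]), dim = d) +
        array(rep(rep(u2[[2L]], each = d[1L]), times = d[3L]), dim = d) +
        array(rep(u2[[3L]], each = d[1L] * d[2L]), dim = d)
      R <- sqrt(max(r2))
      frac <- if (R > 0) pmin(sqrt(r2) / R, 1) else array(0, dim = d)
      spec$centerScale + (spec$edgeScale - spec$centerScale) * frac
    },
    smooth_random = {
      field <- withSeed(spec$seed, {
        g <- array(stats::rnorm(prod(d)), dim = d)
        sg <- spec$correlationLength / geometry@spacing
        g <- gaussSmooth3D(g, sg)
        g <- g - mean(g)
        mx <- max(abs(g))
        if (mx == 0) g else g / mx
      })
      1 + spec$amplitude * field
    })
}

#' Apply a time-independent bias field to a dynamic image
#'
#' Every frame is multiplied voxelwise by the same strictly positive 3D
#' field; geometry and schedule are unchanged. This is the error model for
#' an imperfect attenuation map: a stable relative bias per location across
#' all reconstructed time frames.
#'
#' @param img A [DynamicImage-class].
#' @param field A 3D array matching the image's spatial dims, all values > 0.
#' @return A biased [DynamicImage-class].
#' @export
applyBias <- function(img, field) {
  d <- dim(img@values)
  if (!all(dim(field) == d[1:3]))
    stop("field dims must match the image's spatial dims")
  if (any(field <= 0)) stop("bias field must be strictly positive")
  out <- img@values * as.vector(field)  # field recycles over frames
  dynamicImage(out, img@geometry, img@schedule)
}
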